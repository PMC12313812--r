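# In-code fixtures shared across test files.

# minimal canonical call table from onset/offset vectors
make_calls <- function(onsets, offsets, individual = "A",
                       source_file = "rec.txt", flags = "") {
  tibble::tibble(
    individual = individual,
    population = "pop1",
    group = "grp1",
    source_file = source_file,
    onset_s = onsets,
    offset_s = offsets,
    flags = flags
  )
}

# calls laid out so consecutive inter-call silences equal `gaps`
calls_with_gaps <- function(gaps, dur = 0.3, ...) {
  onsets <- numeric(length(gaps) + 1)
  for (i in seq_along(gaps)) onsets[i + 1] <- onsets[i] + dur + gaps[i]
  make_calls(onsets, onsets + dur, ...)
}

write_audacity <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}

write_raven <- function(rows, path = tempfile(fileext = ".txt"),
                        header = c("Selection", "View", "Channel",
                                   "Begin Time (s)", "End Time (s)")) {
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, "", collapse = "\t")), path)
  path
}

agonistic_row <- function(winner, loser, date = as.Date("2012-01-01"),
                          behavior = "threat") {
  tibble::tibble(date = date, category = "agonistic", behavior = behavior,
                 initiator = winner, receiver = loser, winner = winner)
}

affiliative_row <- function(a, b, behavior = "allopreen", n = 1,
                            date = as.Date("2012-01-01")) {
  tibble::tibble(date = rep(date, n), category = "affiliative",
                 behavior = behavior, initiator = a, receiver = b,
                 winner = NA_character_)
}

toy_meta <- function(ids, sex = "F", group = "grp1") {
  tibble::tibble(
    individual = ids,
    hatch_year = 2008L,
    sex = rep_len(sex, length(ids)),
    subspecies = "carrion",
    population = "pop1",
    group = rep_len(group, length(ids))
  )
}
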