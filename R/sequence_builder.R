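#' Partition calls into sequences by the inter-call silence rule
#'
#' A call sequence is a run of calls by one individual on one recording
#' in which no silent interval between consecutive calls exceeds
#' `gap_threshold`. The gap is the silence between calls — next onset
#' minus previous offset — and a gap *strictly greater* than the
#' threshold starts a new sequence, so a gap exactly equal to the
#' threshold does not split (the segmentation rule is "more than" one
#' second of inter-call silence at the default). Sequences never span
#' source files or individuals.
#'
#' Same-individual calls that overlap in time (onset before the previous
#' offset) are not merged; both calls are flagged `overlapping` so that
#' [apply_exclusions()] can drop the affected sequence.
#'
#' @param calls A call table (see [read_call_table()]).
#' @param gap_threshold Silence duration, in seconds, above which a new
#'   sequence starts. Default 1.0 s.
#' @return A sequence table: one row per call with the call-table
#'   columns plus `sequence_id` (deterministic: source file, individual
#'   and ordinal), `call_index` (position within its sequence), `length`
#'   (number of calls in the sequence) and `duration_s`. The rows are a
#'   partition of the input calls.
#' @export
segment_sequences <- function(calls, gap_threshold = 1.0) {
  stopifnot(is.numeric(gap_threshold), length(gap_threshold) == 1,
            gap_threshold > 0)
  validate_call_table(calls)
  if (nrow(calls) == 0) {
    out <- calls
    out$sequence_id <- character()
    out$call_index <- integer()
    out$length <- integer()
    out$duration_s <- double()
    return(out)
  }
  calls <- dplyr::arrange(calls, .data$source_file, .data$individual,
                          .data$onset_s)
  segmented <- calls |>
    dplyr::group_by(.data$source_file, .data$individual) |>
    dplyr::group_modify(function(g, key) {
      prev_offset <- dplyr::lag(g$offset_s)
      gap <- g$onset_s - prev_offset
      overlap <- !is.na(gap) & gap < 0
      if (any(overlap)) {
        g$flags <- flag_add(g$flags, "overlapping", overlap)
        g$flags <- flag_add(g$flags, "overlapping", dplyr::lead(overlap, default = FALSE))
      }
      new_seq <- is.na(gap) | gap > gap_threshold
      ord <- cumsum(new_seq)
      g$sequence_id <- sprintf("%s#%s#%04d", key$source_file, key$individual, ord)
      g$call_index <- stats::ave(ord, ord, FUN = seq_along)
      g$length <- stats::ave(ord, ord, FUN = length)
      g
    }) |>
    dplyr::ungroup()
  segmented$call_index <- as.integer(segmented$call_index)
  segmented$length <- as.integer(segmented$length)
  segmented$duration_s <- segmented$offset_s - segmented$onset_s
  dplyr::relocate(segmented, dplyr::all_of(names(calls)))
}

#' Apply the study exclusion filters to segmented sequences
#'
#' Drops whole sequences in a fixed, auditable order: (1) sequences
#' containing any call from an unknown caller; (2) sequences containing
#' overlapping calls; (3) sequences flagged as recorded in incomplete
#' context; (4) single-call sequences, which are known to depart from
#' the Menzerath-Altmann law and are excluded from all model fitting.
#' A sequence is tallied under the first rule it violates, so the audit
#' reproduces the filter cascade; the final kept set does not depend on
#' the order because the rules are applied to disjoint remainders.
#'
#' @param sequences A sequence table from [segment_sequences()].
#' @return A list with `kept` (the filtered sequence table) and `audit`,
#'   a named integer vector counting sequences dropped per rule plus
#'   `kept`/`total` sequence counts and `calls_kept`/`calls_total`.
#' @export
apply_exclusions <- function(sequences) {
  assert_columns(sequences, c("sequence_id", "flags", "length"), "sequence table")
  per_seq <- sequences |>
    dplyr::group_by(.data$sequence_id) |>
    dplyr::summarise(
      unknown = any(flag_has(.data$flags, "unknown_caller")),
      overlapping = any(flag_has(.data$flags, "overlapping")),
      incomplete = any(flag_has(.data$flags, "incomplete_context")),
      singleton = dplyr::first(.data$length) == 1L,
      n_calls = dplyr::n(),
      .groups = "drop"
    )
  rule <- with(per_seq, dplyr::case_when(
    unknown ~ "unknown_caller",
    overlapping ~ "overlapping",
    incomplete ~ "incomplete_context",
    singleton ~ "singleton",
    TRUE ~ "kept"
  ))
  audit <- c(
    unknown_caller = sum(rule == "unknown_caller"),
    overlapping = sum(rule == "overlapping"),
    incomplete_context = sum(rule == "incomplete_context"),
    singleton = sum(rule == "singleton"),
    kept = sum(rule == "kept"),
    total = nrow(per_seq),
    calls_kept = sum(per_seq$n_calls[rule == "kept"]),
    calls_total = sum(per_seq$n_calls)
  )
  keep_ids <- per_seq$sequence_id[rule == "kept"]
  list(
    kept = sequences[sequences$sequence_id %in% keep_ids, , drop = FALSE],
    audit = audit
  )
}

#' Per-individual call and sequence counts
#'
#' Summarises a (typically filtered) sequence table into one row per
#' individual — or per individual and group when the table carries a
#' `group` column — with the number of sequences and calls contributed,
#' in the style of a study-subjects table. Individuals missing from the
#' metadata are kept and marked unmatched rather than dropped.
#'
#' @param sequences A sequence table.
#' @param meta Optional metadata ([read_metadata()]) to join sex,
#'   hatch year and subspecies onto the summary.
#' @return A list with `by_individual` (the summary tibble, including a
#'   `matched` column when `meta` is given) and `totals` (named vector:
#'   `n_individuals`, `n_sequences`, `n_calls`).
#' @export
dataset_summary <- function(sequences, meta = NULL) {
  group_cols <- intersect(c("individual", "population", "group"),
                          names(sequences))
  by_ind <- sequences |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      n_sequences = dplyr::n_distinct(.data$sequence_id),
      n_calls = dplyr::n(),
      .groups = "drop"
    )
  if (!is.null(meta)) {
    validate_metadata(meta)
    by_ind <- dplyr::left_join(
      by_ind,
      meta[, intersect(c("individual", "sex", "hatch_year", "subspecies"),
                       names(meta))],
      by = "individual"
    )
    by_ind$matched <- by_ind$individual %in% meta$individual
  }
  totals <- c(
    n_individuals = dplyr::n_distinct(by_ind$individual),
    n_sequences = sum(by_ind$n_sequences),
    n_calls = sum(by_ind$n_calls)
  )
  list(by_individual = by_ind, totals = totals)
}
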