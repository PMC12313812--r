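test_that("segmentation splits strictly above the gap threshold", {
  # gaps 0.5 s and 1.4 s: only the second exceeds 1 s
  seqs <- segment_sequences(calls_with_gaps(c(0.5, 1.4)))
  expect_equal(sort(unique(seqs$length)), c(1L, 2L))
  expect_equal(dplyr::n_distinct(seqs$sequence_id), 2)

  # a gap of exactly 1.0 s does not split ("more than" one second)
  seqs <- segment_sequences(calls_with_gaps(1.0))
  expect_equal(dplyr::n_distinct(seqs$sequence_id), 1)
  expect_equal(unique(seqs$length), 2L)
  # ... but infinitesimally above it does
  seqs <- segment_sequences(calls_with_gaps(1.0 + 1e-9))
  expect_equal(dplyr::n_distinct(seqs$sequence_id), 2)

  seqs <- segment_sequences(calls_with_gaps(rep(0.2, 9)))
  expect_equal(unique(seqs$length), 10L)
  expect_equal(seqs$call_index, 1:10)
})

test_that("overlapping same-individual calls are flagged, not merged", {
  calls <- make_calls(c(0, 0.2, 2), c(0.3, 0.5, 2.3))  # call 2 starts inside call 1
  seqs <- segment_sequences(calls)
  expect_equal(grepl("overlapping", seqs$flags), c(TRUE, TRUE, FALSE))
  expect_equal(nrow(seqs), 3)  # nothing dropped or merged at this stage
})

test_that("sequences never span individuals or source files", {
  calls <- dplyr::bind_rows(
    make_calls(c(0, 0.5), c(0.3, 0.8), individual = "A"),
    make_calls(c(0.4, 0.9), c(0.7, 1.2), individual = "B"),
    make_calls(c(0, 0.5), c(0.3, 0.8), individual = "A", source_file = "r2.txt")
  )
  seqs <- segment_sequences(calls)
  per_seq <- unique(seqs[, c("sequence_id", "individual", "source_file")])
  expect_equal(nrow(per_seq), 3)
  expect_equal(anyDuplicated(per_seq$sequence_id), 0)
})

test_that("exclusion cascade drops flagged and singleton sequences with an audit", {
  lengths <- c(1, 2, 3, 1, 4)
  calls <- dplyr::bind_rows(lapply(seq_along(lengths), function(i) {
    calls_with_gaps(rep(0.2, lengths[i] - 1), source_file = paste0("r", i, ".txt"))
  }))
  res <- apply_exclusions(segment_sequences(calls))
  expect_equal(res$audit[["singleton"]], 2)
  expect_equal(res$audit[["kept"]], 3)
  expect_equal(sum(res$kept$length >= 2), nrow(res$kept))

  # one unknown-caller call contaminates its whole sequence
  calls <- calls_with_gaps(c(0.2, 0.2))
  calls$flags[2] <- "unknown_caller"
  res <- apply_exclusions(segment_sequences(calls))
  expect_equal(nrow(res$kept), 0)
  expect_equal(res$audit[["unknown_caller"]], 1)
})

test_that("exclusion audit matches a constructed 100-sequence fixture", {
  # 20 singletons, 5 unknown-caller multi-call sequences, 75 clean
  mk <- function(i, len, flag = "") {
    c <- calls_with_gaps(rep(0.2, len - 1), source_file = sprintf("f%03d.txt", i))
    c$flags <- flag
    c
  }
  calls <- dplyr::bind_rows(
    lapply(1:20, mk, len = 1),
    lapply(21:25, mk, len = 3, flag = "unknown_caller"),
    lapply(26:100, mk, len = 2)
  )
  res <- apply_exclusions(segment_sequences(calls))
  expect_equal(res$audit[["total"]], 100)
  expect_equal(res$audit[["singleton"]], 20)
  expect_equal(res$audit[["unknown_caller"]], 5)
  expect_equal(res$audit[["kept"]], 75)
  expect_equal(res$audit[["calls_kept"]], 150)
})

test_that("segmentation is a partition, idempotent, and monotone in the threshold", {
  set.seed(404)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    onsets <- cumsum(runif(n, 0.05, 2.5))
    calls <- make_calls(onsets, onsets + runif(n, 0.05, 0.4) * 0.1,
                        individual = sample(c("A", "B"), n, replace = TRUE))
    seqs <- segment_sequences(calls)
    # partition: every call appears exactly once, lengths sum to n
    expect_equal(nrow(seqs), n)
    expect_equal(sum(unique(seqs[, c("sequence_id", "length")])$length), n)
    # within-sequence gaps never exceed the threshold
    gaps <- seqs |>
      dplyr::group_by(.data$sequence_id) |>
      dplyr::summarise(max_gap = max(c(-Inf, diff(.data$onset_s) -
                                         .data$duration_s[-dplyr::n()])))
    expect_true(all(gaps$max_gap <= 1.0))
    # idempotence: re-segmenting changes nothing
    again <- segment_sequences(seqs[, names(calls)])
    expect_equal(again$sequence_id, seqs$sequence_id)
    expect_equal(again$length, seqs$length)
    # monotonicity: a larger threshold never yields more sequences
    n_at <- vapply(c(0.3, 0.6, 1.0, 2.0), function(thr) {
      dplyr::n_distinct(segment_sequences(calls, thr)$sequence_id)
    }, numeric(1))
    expect_true(all(diff(n_at) <= 0))
  }
})

test_that("dataset summary is additive and reports unmatched individuals", {
  calls <- dplyr::bind_rows(
    lapply(1:3, function(i) calls_with_gaps(rep(0.2, 3), individual = "A",
                                            source_file = paste0("a", i, ".txt"))),
    lapply(1:2, function(i) calls_with_gaps(rep(0.2, 1), individual = "B",
                                            source_file = paste0("b", i, ".txt")))
  )
  seqs <- apply_exclusions(segment_sequences(calls))$kept
  summ <- dataset_summary(seqs, meta = toy_meta("A"))
  by_ind <- summ$by_individual
  expect_equal(by_ind$n_sequences[by_ind$individual == "A"], 3)
  expect_equal(by_ind$n_calls[by_ind$individual == "A"], 12)
  expect_equal(by_ind$n_calls[by_ind$individual == "B"], 4)
  expect_false(by_ind$matched[by_ind$individual == "B"])
  expect_equal(unname(summ$totals["n_calls"]), sum(by_ind$n_calls))
  expect_equal(unname(summ$totals["n_sequences"]), sum(by_ind$n_sequences))

  empty <- dataset_summary(segment_sequences(make_calls(numeric(), numeric())))
  expect_equal(unname(empty$totals["n_calls"]), 0)
  expect_equal(nrow(empty$by_individual), 0)
})
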