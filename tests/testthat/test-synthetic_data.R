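test_that("noiseless generation reproduces the law exactly", {
  cfg <- sim_config(seed = 9, n_individuals = 4, n_groups = 2,
                    sequences_per_individual = 10, singleton_fraction = 0,
                    law = list(a = 1, b = -0.5, c = 0),
                    sd_population = 0, sd_group = 0, sd_individual = 0,
                    sd_sequence = 0, sd_residual = 0)
  d <- generate_dataset(cfg)
  durations <- d$calls$offset_s - d$calls$onset_s
  seqs <- segment_sequences(d$calls)
  expect_equal(durations, seqs$length^(-0.5))
  # every call in a length-4 sequence lasts exactly 4^(-1/2) = 0.5 s
  expect_equal(unique(durations[seqs$length == 4]), 0.5)
})

test_that("the generator is deterministic in its seed", {
  cfg <- sim_config(seed = 123, n_individuals = 5, sequences_per_individual = 8)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$calls, d2$calls)
  expect_identical(d1$meta, d2$meta)
  expect_identical(d1$truth$sequences, d2$truth$sequences)

  dir1 <- tempfile(); dir2 <- tempfile()
  generate_dataset(cfg, out_dir = dir1)
  generate_dataset(cfg, out_dir = dir2)
  f <- list.files(dir1, recursive = TRUE)
  expect_true(length(f) > 0)
  for (fn in setdiff(f, "truth.json")) {
    expect_identical(readLines(file.path(dir1, fn)),
                     readLines(file.path(dir2, fn)))
  }

  d3 <- generate_dataset(sim_config(seed = 124, n_individuals = 5,
                                    sequences_per_individual = 8))
  expect_false(identical(d1$calls$onset_s, d3$calls$onset_s))
})

test_that("generated label files round-trip through ingest and segmentation", {
  cfg <- sim_config(seed = 31, n_individuals = 6, n_groups = 2,
                    sequences_per_individual = 20, singleton_fraction = 0.2)
  dir <- tempfile()
  d <- generate_dataset(cfg, out_dir = dir)

  files <- list.files(file.path(dir, "labels"), full.names = TRUE)
  ingested <- dplyr::bind_rows(lapply(files, function(f) {
    read_audacity_labels(f, caller_id = sub("\\.txt$", "", basename(f)))
  }))
  expect_equal(nrow(ingested), nrow(d$calls))

  seqs <- segment_sequences(ingested)
  # counts match the generator's bookkeeping exactly
  expect_equal(nrow(seqs), d$truth$counts$n_calls)
  expect_equal(dplyr::n_distinct(seqs$sequence_id), d$truth$counts$n_sequences)
  got_lengths <- seqs |>
    dplyr::arrange(.data$individual, .data$onset_s) |>
    dplyr::distinct(.data$individual, .data$sequence_id, .data$length)
  want_lengths <- dplyr::arrange(d$truth$sequences, .data$individual,
                                 .data$gen_sequence)
  expect_equal(got_lengths$length, want_lengths$length)
  # durations survive the text round trip to 1e-9 s
  by_onset <- dplyr::arrange(seqs, .data$individual, .data$onset_s)
  orig <- dplyr::arrange(d$calls, .data$individual, .data$onset_s)
  expect_equal(by_onset$duration_s, orig$offset_s - orig$onset_s,
               tolerance = 1e-9)

  # exclusion filter recovers the generator's singleton audit exactly
  res <- apply_exclusions(seqs)
  expect_equal(unname(res$audit["singleton"]), d$truth$counts$n_singletons)
  expect_equal(unname(res$audit["kept"]), d$truth$counts$n_multicall_sequences)
  expect_equal(unname(res$audit["calls_kept"]), d$truth$counts$n_calls_multicall)
})

test_that("synthetic interactions express the latent hierarchy", {
  # an overwhelming rank gap: the dominant individual wins every bout
  inter <- generate_interactions(seed = 1, true_ranks = c(top = 50, low = 0),
                                 n_events = 100)
  expect_true(all(inter$winner == "top"))

  # equal ranks: win fraction near one half over 1,000 bouts
  inter <- generate_interactions(seed = 2, true_ranks = c(A = 0, B = 0),
                                 n_events = 1000)
  expect_equal(mean(inter$winner == "A"), 0.5, tolerance = 0.05)

  # affiliative events arrive at the requested dyadic rates
  inter <- generate_interactions(seed = 3, true_ranks = c(A = 0, B = 0, C = 0),
                                 n_events = 10, affiliation_rates = 20)
  aff <- inter[inter$category == "affiliative", ]
  expect_gt(nrow(aff), 30)
  expect_true(all(aff$behavior %in% c("allopreen", "contact_sit")))
  expect_true(!is.unsorted(inter$date))

  expect_error(generate_interactions(seed = 1, true_ranks = c(A = 1)),
               "at least 2")
  expect_error(generate_interactions(seed = 1, true_ranks = c(A = 1, B = 0),
                                     n_events = 0), "n_events")
})

test_that("Elo recovers a well-separated synthetic hierarchy", {
  ranks <- setNames(seq(8, 1) * 2, paste0("id", 1:8))  # 28 dyads
  inter <- generate_interactions(seed = 44, true_ranks = ranks,
                                 n_events = 50 * 28)
  st <- elo_ratings(inter, individuals = names(ranks))
  tau <- cor(ranks, st$ratings[names(ranks)], method = "kendall")
  expect_gte(tau, 0.9)
})

test_that("generator configuration is validated", {
  expect_error(sim_config(sd_residual = -1), "nonnegative")
  expect_error(sim_config(law = list(a = -2)), "positive")
  expect_error(sim_config(intersequence_gap = 0.8), "exceed 1 s")
  expect_error(sim_config(singleton_fraction = 1), "\\[0, 1\\)")
  expect_error(sim_config(covariate_effects = list(color = 1)),
               "unknown covariate effect")
})

test_that("fitted slopes are unbiased under the null and sharpen with data", {
  # law neutrality: b = 0 yields slope estimates centred on zero
  cfg0 <- sim_config(seed = 52, n_individuals = 8, n_groups = 2,
                     sequences_per_individual = 40,
                     law = list(a = 1, b = 0, c = 0))
  rec0 <- recovery_experiment(cfg0, n_replicates = 10, fit_spec = "simple")
  expect_lt(abs(rec0$summary$bias), 0.05)
  expect_equal(rec0$summary$truth, 0)

  # monotone power: recovery error shrinks as sequences accumulate
  rmse_at <- vapply(c(10, 40, 160), function(n_seq) {
    cfg <- sim_config(seed = 53, n_individuals = 8, n_groups = 2,
                      sequences_per_individual = n_seq)
    recovery_experiment(cfg, n_replicates = 6, fit_spec = "simple")$summary$rmse
  }, numeric(1))
  expect_true(all(diff(rmse_at) < 0))
})

test_that("recovery experiment tracks interaction effects through eq5", {
  cfg <- sim_config(seed = 54, n_individuals = 12, n_groups = 4,
                    sequences_per_individual = 50,
                    covariate_effects = list(`ln_len:sex` = 0.3))
  rec <- recovery_experiment(cfg, n_replicates = 5, fit_spec = "eq5",
                             term = "ln_len:sexM")
  expect_equal(rec$summary$truth, 0.3)
  expect_equal(rec$summary$n_failed, 0)
  expect_lt(abs(rec$summary$bias), 0.15)
  expect_gte(rec$summary$ci_coverage, 0.6)
})
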