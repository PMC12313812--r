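# Ground-truth simulator: annotation files, call tables, metadata and
# interaction logs generated from a known Menzerath-Altmann law with
# nested Gaussian random effects, so every pipeline stage can be tested
# against its own bookkeeping.

#' Configuration for the synthetic call-sequence generator
#'
#' Defaults describe a captive-corvid-style study: a few dozen
#' individuals housed in groups within two populations, each
#' contributing on the order of a hundred call sequences, with per-call
#' log-durations following `ln(y) = ln(a) + b ln(x) + c x` plus nested
#' Gaussian deviations (population, group, individual, sequence,
#' residual) and optional covariate effects on duration and on the
#' slope. Kept-sequence lengths default to 2 plus a geometric draw with
#' mean 3.25 calls per sequence (the study-scale mean of ~12,100 calls
#' over ~3,700 multi-call sequences), with a settable fraction of
#' singleton sequences mixed in to exercise the exclusion filter.
#'
#' @param seed Integer seed; fully determines the generated dataset.
#' @param n_populations,n_groups,n_individuals Hierarchy sizes; groups
#'   are split across populations and individuals across groups.
#' @param sequences_per_individual Sequences generated per individual.
#' @param singleton_fraction Fraction of sequences of length 1.
#' @param length_mean Mean length of non-singleton sequences (>= 2).
#' @param law List with `a` (scale, > 0), `b` (power exponent) and `c`
#'   (exponential rate) of the Menzerath-Altmann curve.
#' @param sd_population,sd_group,sd_individual,sd_sequence,sd_residual
#'   Standard deviations of the nested Gaussian intercept deviates and
#'   the residual, on the log-duration scale.
#' @param sd_slope Standard deviation of the per-individual random
#'   slope on `ln(length)` (0 = no individual variation in the law).
#' @param covariate_effects Named list of effects on the log scale:
#'   main effects `sex` (male minus female), `group_size`, `age`,
#'   `elo`, `csi`, and interaction effects on the slope named
#'   `"ln_len:<covariate>"` (e.g. `"ln_len:sex"`). Unlisted terms are 0.
#' @param gap_seconds Silence between calls within a sequence (s).
#' @param intersequence_gap Silence between sequences (s); must exceed
#'   1 s so that segmentation at the default threshold inverts the
#'   generator exactly.
#' @param base_year Recording year used to derive ages from hatch years.
#' @return A validated config list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_populations = 2L,
                       n_groups = 6L,
                       n_individuals = 30L,
                       sequences_per_individual = 120L,
                       singleton_fraction = 0.15,
                       length_mean = 3.25,
                       law = list(a = 1, b = -0.5, c = 0),
                       sd_population = 0.1,
                       sd_group = 0.1,
                       sd_individual = 0.2,
                       sd_sequence = 0.1,
                       sd_residual = 0.3,
                       sd_slope = 0,
                       covariate_effects = list(),
                       gap_seconds = 0.3,
                       intersequence_gap = 3,
                       base_year = 2013L) {
  cfg <- list(
    seed = as.integer(seed), n_populations = as.integer(n_populations),
    n_groups = as.integer(n_groups), n_individuals = as.integer(n_individuals),
    sequences_per_individual = as.integer(sequences_per_individual),
    singleton_fraction = singleton_fraction, length_mean = length_mean,
    law = modifyList(list(a = 1, b = -0.5, c = 0), law),
    sd_population = sd_population, sd_group = sd_group,
    sd_individual = sd_individual, sd_sequence = sd_sequence,
    sd_residual = sd_residual, sd_slope = sd_slope,
    covariate_effects = covariate_effects,
    gap_seconds = gap_seconds, intersequence_gap = intersequence_gap,
    base_year = as.integer(base_year)
  )
  sds <- c(cfg$sd_population, cfg$sd_group, cfg$sd_individual,
           cfg$sd_sequence, cfg$sd_residual, cfg$sd_slope)
  if (any(sds < 0)) {
    stop_vocaleff("standard deviations must be nonnegative",
                  class = "vocaleff_config_error")
  }
  if (cfg$law$a <= 0) {
    stop_vocaleff("law scale a must be positive", class = "vocaleff_config_error")
  }
  if (cfg$intersequence_gap <= 1) {
    stop_vocaleff("intersequence_gap must exceed 1 s so the default ",
                  "segmentation threshold recovers the generated sequences",
                  class = "vocaleff_config_error")
  }
  if (cfg$singleton_fraction < 0 || cfg$singleton_fraction >= 1) {
    stop_vocaleff("singleton_fraction must be in [0, 1)",
                  class = "vocaleff_config_error")
  }
  if (cfg$length_mean < 2) {
    stop_vocaleff("length_mean of non-singleton sequences must be >= 2",
                  class = "vocaleff_config_error")
  }
  allowed <- c("sex", "group_size", "age", "elo", "csi",
               paste0("ln_len:", c("sex", "group_size", "age", "elo", "csi")))
  bad <- setdiff(names(cfg$covariate_effects), allowed)
  if (length(bad) > 0) {
    stop_vocaleff("unknown covariate effect(s): ", paste(bad, collapse = ", "),
                  class = "vocaleff_config_error")
  }
  structure(cfg, class = c("sim_config", "list"))
}

effect_of <- function(cfg, term) {
  as.numeric(cfg$covariate_effects[[term]] %||% 0)
}

#' Generate a synthetic annotated-call dataset with known ground truth
#'
#' Draws the hierarchy (populations, groups, individuals with sex, age,
#' dominance and sociality covariates), then for every sequence of
#' length `x` generates per-call log-durations
#' `ln(a) + (b + individual slope deviate + interaction effects) ln(x)
#'  + c x + main covariate effects + nested intercept deviates +
#'  residual`, exponentiates (with a 1 ms floor so logs stay finite
#' under extreme noise draws), and lays the calls on a per-individual
#' timeline: `gap_seconds` of silence within sequences and
#' `intersequence_gap` between them, one recording (source file) per
#' individual. Continuous covariate effects are applied to z-scored
#' covariates so effect sizes are per standard deviation.
#'
#' When `out_dir` is given, Audacity label files (one per individual,
#' nine-decimal times), the canonical call table, metadata, membership
#' and truth tables are written there, so the ingest and segmentation
#' stages can be exercised end to end.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory to write `labels/*.txt`,
#'   `calls.csv`, `meta.csv`, `memberships.csv` and `truth.json`.
#' @return List with `calls` (canonical call table), `meta` (metadata
#'   including `group`, true `elo`, `csi`), `memberships`, and `truth`
#'   (list: the config, per-individual latent effects, per-sequence
#'   bookkeeping, and counts before/after singleton exclusion).
#' @export
generate_dataset <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  pops <- sprintf("pop%02d", seq_len(cfg$n_populations))
  groups <- tibble::tibble(
    group = sprintf("grp%02d", seq_len(cfg$n_groups)),
    population = pops[(seq_len(cfg$n_groups) - 1L) %% cfg$n_populations + 1L],
    u_group = rnorm(cfg$n_groups, 0, cfg$sd_group)
  )
  u_pop <- setNames(rnorm(cfg$n_populations, 0, cfg$sd_population), pops)

  # every group seeded with one member, the rest placed at random so
  # group sizes vary (pairs up to flocks, as in captive housing)
  group_of <- c(groups$group,
                sample(groups$group, max(0L, cfg$n_individuals - cfg$n_groups),
                       replace = TRUE))[seq_len(cfg$n_individuals)]
  ind <- tibble::tibble(
    individual = sprintf("ind%02d", seq_len(cfg$n_individuals)),
    group = group_of,
    sex = sample(c("F", "M"), cfg$n_individuals, replace = TRUE),
    hatch_year = cfg$base_year - sample(1:10, cfg$n_individuals, replace = TRUE),
    elo = rnorm(cfg$n_individuals),
    csi = rnorm(cfg$n_individuals),
    u_individual = rnorm(cfg$n_individuals, 0, cfg$sd_individual),
    slope_dev = rnorm(cfg$n_individuals, 0, cfg$sd_slope)
  )
  ind <- dplyr::left_join(ind, groups, by = "group")
  ind$group_size <- as.numeric(table(ind$group)[ind$group])
  ind$age <- cfg$base_year - ind$hatch_year

  zscore <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  z <- list(
    sex = as.numeric(ind$sex == "M"),
    group_size = zscore(ind$group_size),
    age = zscore(ind$age),
    elo = zscore(ind$elo),
    csi = zscore(ind$csi)
  )
  ind$main_shift <- Reduce(`+`, lapply(names(z), function(v) {
    effect_of(cfg, v) * z[[v]]
  }))
  ind$slope_shift <- Reduce(`+`, lapply(names(z), function(v) {
    effect_of(cfg, paste0("ln_len:", v)) * z[[v]]
  }))

  n_seq <- cfg$sequences_per_individual
  p_geo <- 1 / (cfg$length_mean - 1)  # lengths are 2 + Geom(p), mean 2 + (1-p)/p

  calls <- vector("list", cfg$n_individuals)
  seq_truth <- vector("list", cfg$n_individuals)
  for (i in seq_len(cfg$n_individuals)) {
    singleton <- runif(n_seq) < cfg$singleton_fraction
    lengths <- ifelse(singleton, 1L, 2L + rgeom(n_seq, p_geo))
    u_seq <- rnorm(n_seq, 0, cfg$sd_sequence)
    slope_i <- cfg$law$b + ind$slope_dev[i] + ind$slope_shift[i]
    base_i <- log(cfg$law$a) + u_pop[[ind$population[i]]] + ind$u_group[i] +
      ind$u_individual[i] + ind$main_shift[i]
    x <- rep.int(lengths, lengths)
    seq_ord <- rep.int(seq_len(n_seq), lengths)
    ln_dur <- base_i + slope_i * log(x) + cfg$law$c * x +
      u_seq[seq_ord] + rnorm(length(x), 0, cfg$sd_residual)
    dur <- pmax(exp(ln_dur), 1e-3)
    # timeline: gap_seconds within a sequence, intersequence_gap between
    gap_before <- ifelse(seq_ord != dplyr::lag(seq_ord, default = 0L),
                         cfg$intersequence_gap, cfg$gap_seconds)
    gap_before[1] <- 0
    onset <- cumsum(gap_before) + c(0, cumsum(dur)[-length(dur)])
    calls[[i]] <- tibble::tibble(
      individual = ind$individual[i],
      population = ind$population[i],
      group = ind$group[i],
      source_file = paste0(ind$individual[i], ".txt"),
      onset_s = onset,
      offset_s = onset + dur,
      flags = "",
      gen_sequence = seq_ord
    )
    seq_truth[[i]] <- tibble::tibble(
      individual = ind$individual[i],
      gen_sequence = seq_len(n_seq),
      length = lengths,
      u_sequence = u_seq
    )
  }
  calls <- dplyr::bind_rows(calls)
  seq_truth <- dplyr::bind_rows(seq_truth)

  meta <- tibble::tibble(
    individual = ind$individual,
    hatch_year = ind$hatch_year,
    sex = ind$sex,
    subspecies = "carrion",
    population = ind$population,
    group = ind$group,
    elo = ind$elo,
    csi = ind$csi
  )
  memberships <- tibble::tibble(
    individual = ind$individual,
    group = ind$group,
    date_start = as.Date(paste0(cfg$base_year, "-01-01")),
    date_end = as.Date(paste0(cfg$base_year, "-12-31"))
  )
  truth <- list(
    config = unclass(cfg),
    individuals = ind[, c("individual", "population", "group", "sex", "age",
                          "group_size", "elo", "csi", "u_individual",
                          "slope_dev", "main_shift", "slope_shift")],
    sequences = seq_truth,
    counts = list(
      n_calls = nrow(calls),
      n_sequences = nrow(seq_truth),
      n_singletons = sum(seq_truth$length == 1L),
      n_multicall_sequences = sum(seq_truth$length >= 2L),
      n_calls_multicall = sum(seq_truth$length[seq_truth$length >= 2L])
    )
  )
  out <- list(calls = calls, meta = meta, memberships = memberships,
              truth = truth)
  if (!is.null(out_dir)) write_dataset(out, out_dir)
  out
}

write_dataset <- function(dataset, out_dir) {
  dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  calls <- dataset$calls
  for (f in unique(calls$source_file)) {
    rows <- calls[calls$source_file == f, ]
    writeLines(sprintf("%.9f\t%.9f\tcaw", rows$onset_s, rows$offset_s),
               file.path(out_dir, "labels", f))
  }
  write_call_table(calls[, call_table_columns], file.path(out_dir, "calls.csv"))
  write_metadata(dataset$meta, file.path(out_dir, "meta.csv"))
  write_memberships(dataset$memberships, file.path(out_dir, "memberships.csv"))
  jsonlite::write_json(dataset$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(out_dir)
}

#' Generate synthetic interaction logs with a known dominance order
#'
#' Agonistic events pick a dyad uniformly at random and draw the winner
#' with probability logistic in the latent rank difference,
#' `P(i beats j) = plogis((rank_i - rank_j) / rank_scale)`; as the rank
#' gap grows the higher-ranked individual wins every event. Affiliative
#' events are drawn per dyad as Poisson counts at the given rates, split
#' evenly between allopreening and contact sitting. Events are dated on
#' consecutive days and returned chronologically.
#'
#' @param seed Integer seed.
#' @param true_ranks Named numeric: latent dominance rank per
#'   individual (at least 2).
#' @param n_events Number of agonistic events (>= 1).
#' @param affiliation_rates Optional named numeric of expected
#'   affiliative event counts per dyad, names `"idA|idB"` with the two
#'   ids sorted, or a single number applied to every dyad.
#' @param rank_scale Logistic scale of the win probability.
#' @param start_date First event date.
#' @return An interaction table in the [read_interactions()] schema.
#' @export
generate_interactions <- function(seed, true_ranks, n_events = 200,
                                  affiliation_rates = NULL, rank_scale = 1,
                                  start_date = as.Date("2012-01-01")) {
  set.seed(as.integer(seed))
  ids <- names(true_ranks)
  if (length(ids) < 2) {
    stop_vocaleff("need at least 2 individuals", class = "vocaleff_config_error")
  }
  if (n_events < 1) {
    stop_vocaleff("n_events must be >= 1", class = "vocaleff_config_error")
  }
  a <- character(n_events); b <- character(n_events); w <- character(n_events)
  for (e in seq_len(n_events)) {
    pair <- sample(ids, 2)
    p_first <- plogis((true_ranks[[pair[1]]] - true_ranks[[pair[2]]]) / rank_scale)
    a[e] <- pair[1]; b[e] <- pair[2]
    w[e] <- if (runif(1) < p_first) pair[1] else pair[2]
  }
  ago <- tibble::tibble(
    date = start_date + seq_len(n_events) - 1L,
    category = "agonistic",
    behavior = sample(interaction_behaviors$agonistic, n_events, replace = TRUE),
    initiator = a, receiver = b, winner = w
  )
  aff <- NULL
  if (!is.null(affiliation_rates)) {
    pairs <- utils::combn(sort(ids), 2)
    keys <- paste(pairs[1, ], pairs[2, ], sep = "|")
    rates <- if (length(affiliation_rates) == 1 && is.null(names(affiliation_rates))) {
      setNames(rep(affiliation_rates, length(keys)), keys)
    } else {
      affiliation_rates
    }
    counts <- rpois(length(keys), rates[keys])
    counts[is.na(counts)] <- 0L
    aff <- purrr::map_dfr(seq_along(keys), function(j) {
      n <- counts[j]
      if (n == 0) return(NULL)
      tibble::tibble(
        date = start_date + n_events + seq_len(n),
        category = "affiliative",
        behavior = rep_len(interaction_behaviors$affiliative, n),
        initiator = pairs[1, j], receiver = pairs[2, j],
        winner = NA_character_
      )
    })
  }
  out <- dplyr::bind_rows(ago, aff)
  out <- out[order(out$date), ]
  validate_interactions(out)
  out
}

#' Parameter-recovery experiment for the Menzerath model fits
#'
#' For each replicate: generate a dataset from `config` (with a
#' replicate-specific seed derived from `config$seed`), re-segment its
#' call table through [segment_sequences()], apply the exclusion
#' filters, fit the requested model, and record the estimated
#' log-length slope against the generating value. Reports per-replicate
#' estimates and a summary of bias, RMSE, and Wald-CI coverage;
#' replicates that fail to converge are counted, never silently
#' dropped.
#'
#' @param config A [sim_config()].
#' @param n_replicates Number of replicates.
#' @param fit_spec `"simple"` for [fit_simple()] or one of `"eq4"`,
#'   `"eq5"`, `"eq6"` for [fit_complex()].
#' @param term Fixed-effect term tracked for recovery; default
#'   `"ln_len"` (the law's exponent b). Its generating value is taken
#'   from the config (`law$b`, plus the matching interaction effect for
#'   `ln_len:` terms).
#' @param gap_threshold Segmentation threshold (s).
#' @return List of class `recovery_report`: `replicates` (tibble with
#'   estimate, se, CI, coverage and convergence per replicate),
#'   `summary` (tibble: truth, mean estimate, bias, rmse, ci_coverage,
#'   n_converged) and the config.
#' @export
recovery_experiment <- function(config = sim_config(), n_replicates = 20,
                                fit_spec = c("simple", "eq4", "eq5", "eq6"),
                                term = "ln_len", gap_threshold = 1.0) {
  fit_spec <- match.arg(fit_spec)
  truth <- recovery_truth(config, term)
  reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    cfg_r <- config
    cfg_r$seed <- (config$seed * 1000L + r) %% .Machine$integer.max
    d <- generate_dataset(cfg_r)
    seqs <- segment_sequences(d$calls, gap_threshold = gap_threshold)
    kept <- apply_exclusions(seqs)$kept
    fit <- tryCatch({
      if (fit_spec == "simple") {
        fit_simple(kept)
      } else {
        frame <- build_model_frame(kept, d$meta, ref_year = config$base_year)
        fit_complex(frame, spec = fit_spec)
      }
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      return(tibble::tibble(replicate = r, seed = cfg_r$seed,
                            estimate = NA_real_, se = NA_real_,
                            ci_lower = NA_real_, ci_upper = NA_real_,
                            covered = NA, converged = FALSE,
                            error = conditionMessage(fit)))
    }
    row <- fit$estimates[fit$estimates$term == term, ]
    if (nrow(row) != 1) {
      stop_vocaleff("term '", term, "' not in fitted model",
                    class = "vocaleff_validation_error")
    }
    tibble::tibble(
      replicate = r, seed = cfg_r$seed,
      estimate = row$estimate, se = row$se,
      ci_lower = row$ci_lower, ci_upper = row$ci_upper,
      covered = row$ci_lower <= truth & truth <= row$ci_upper,
      converged = fit$converged, error = NA_character_
    )
  })
  ok <- !is.na(reps$estimate)
  summary <- tibble::tibble(
    term = term,
    truth = truth,
    mean_estimate = mean(reps$estimate[ok]),
    bias = mean(reps$estimate[ok]) - truth,
    rmse = sqrt(mean((reps$estimate[ok] - truth)^2)),
    ci_coverage = mean(reps$covered[ok]),
    n_replicates = n_replicates,
    n_converged = sum(reps$converged, na.rm = TRUE),
    n_failed = sum(!ok)
  )
  structure(list(replicates = reps, summary = summary, config = config,
                 fit_spec = fit_spec),
            class = "recovery_report")
}

recovery_truth <- function(config, term) {
  if (term == "ln_len") return(config$law$b)
  if (startsWith(term, "ln_len:")) {
    v <- sub("^ln_len:", "", term)
    v <- sub("^sexM$", "sex", v)
    return(effect_of(config, paste0("ln_len:", v)))
  }
  v <- sub("^sexM$", "sex", term)
  effect_of(config, v)
}

#' @exportS3Method base::print
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery (", x$fit_spec, ", ",
      x$summary$n_replicates, " replicates)\n", sep = "")
  s <- x$summary
  cat(sprintf("  %s: truth %.3f, mean estimate %.3f, bias %+.4f, RMSE %.4f\n",
              s$term, s$truth, s$mean_estimate, s$bias, s$rmse))
  cat(sprintf("  Wald 95%% CI coverage: %.2f (%d converged, %d failed)\n",
              s$ci_coverage, s$n_converged, s$n_failed))
  invisible(x)
}
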