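# Dominance and affiliation covariates from focal-observation logs.

#' Sequential Elo dominance ratings from agonistic interactions
#'
#' Processes agonistic interactions in chronological order (ties in date
#' keep input order). Before each interaction the expected probability
#' that the eventual winner wins is
#' `p = 1 / (1 + exp(-(r_winner - r_loser) / steepness))`;
#' the winner then gains `k * (1 - p)` points and the loser loses the
#' same amount, so updates are zero-sum and surprising outcomes move
#' ratings more. Individuals never observed interacting keep
#' `initial_rating`.
#'
#' The default `steepness`, 400/ln(10), reproduces the classical Elo
#' logistic in which a 200-point gap corresponds to a win probability of
#' about 0.76.
#'
#' @param interactions An interaction table ([read_interactions()]);
#'   only `category == "agonistic"` rows are used.
#' @param k Update magnitude (points transferred for a maximally
#'   surprising outcome). Default 100.
#' @param steepness Logistic scale, in rating points, of the expected
#'   outcome. Default `400 / log(10)`.
#' @param initial_rating Rating assigned to every individual before any
#'   interaction. Default 0.
#' @param individuals Optional character vector of all known ids; an
#'   interaction involving an id outside it is an error, and ids with no
#'   interactions appear in the output at `initial_rating`.
#' @return An object of class `elo_state`: list with `ratings` (named
#'   numeric), `n_interactions` (named integer), and the parameters.
#' @export
elo_ratings <- function(interactions, k = 100, steepness = 400 / log(10),
                        initial_rating = 0, individuals = NULL) {
  stopifnot(k > 0, steepness > 0)
  validate_interactions(interactions)
  ago <- interactions[interactions$category == "agonistic", , drop = FALSE]
  ago <- ago[order(ago$date), , drop = FALSE]
  ids <- unique(c(individuals, ago$initiator, ago$receiver))
  if (!is.null(individuals)) {
    unknown <- setdiff(unique(c(ago$initiator, ago$receiver)), individuals)
    if (length(unknown) > 0) {
      stop_vocaleff("interaction involves individual(s) absent from metadata: ",
                    paste(unknown, collapse = ", "),
                    class = "vocaleff_validation_error")
    }
  }
  ratings <- setNames(rep(initial_rating, length(ids)), ids)
  n_int <- setNames(rep(0L, length(ids)), ids)
  for (i in seq_len(nrow(ago))) {
    w <- ago$winner[i]
    l <- if (w == ago$initiator[i]) ago$receiver[i] else ago$initiator[i]
    p <- 1 / (1 + exp(-(ratings[[w]] - ratings[[l]]) / steepness))
    delta <- k * (1 - p)
    ratings[[w]] <- ratings[[w]] + delta
    ratings[[l]] <- ratings[[l]] - delta
    n_int[[w]] <- n_int[[w]] + 1L
    n_int[[l]] <- n_int[[l]] + 1L
  }
  structure(
    list(ratings = ratings, n_interactions = n_int, k = k,
         steepness = steepness, initial_rating = initial_rating),
    class = "elo_state"
  )
}

#' @exportS3Method base::print
print.elo_state <- function(x, ...) {
  cat("Elo ratings (k =", x$k, ", steepness =", round(x$steepness, 2),
      ", initial =", x$initial_rating, ")\n")
  print(round(sort(x$ratings, decreasing = TRUE), 1))
  invisible(x)
}

#' Composite sociality index from affiliative interactions
#'
#' For each dyad and each affiliative behaviour category (allopreening
#' and contact sitting by default), the interaction rate is the number
#' of events divided by the dyadic observation time. The dyadic CSI is
#' the mean over categories of each rate divided by its mean across
#' dyads, so the population mean of dyadic CSI is 1 by construction: a
#' dyad with CSI 2 affiliates twice as much as the average dyad. An
#' individual's CSI is the mean of its dyadic values.
#'
#' Dyadic observation time is approximated as the smaller of the two
#' individuals' focal-observation times — the time during which both
#' could have been seen interacting. This is a documented approximation;
#' it is exact when co-housed individuals are observed in the same focal
#' sessions. A category with no events across all dyads has an undefined
#' normalisation and is dropped with a warning.
#'
#' @param interactions Interaction table; only `affiliative` rows used.
#' @param observation_time Named numeric: focal-observation time
#'   (minutes) per individual. Scaling all times by a constant leaves
#'   the CSI unchanged.
#' @param dyads Optional two-column data frame (`id_a`, `id_b`) of dyads
#'   to score, e.g. co-housed pairs; defaults to all pairs of
#'   `names(observation_time)`.
#' @param categories Behaviour categories included. Default
#'   `c("allopreen", "contact_sit")`.
#' @return An object of class `csi_table`: list with `dyadic` (tibble:
#'   `id_a`, `id_b`, per-category rates, `csi`), `mean_csi` (named
#'   numeric per individual) and `categories` actually used.
#' @export
csi <- function(interactions, observation_time, dyads = NULL,
                categories = c("allopreen", "contact_sit")) {
  validate_interactions(interactions)
  stopifnot(is.numeric(observation_time), !is.null(names(observation_time)),
            all(observation_time > 0))
  aff <- interactions[interactions$category == "affiliative" &
                        interactions$behavior %in% categories, , drop = FALSE]
  ids <- names(observation_time)
  if (is.null(dyads)) {
    if (length(ids) < 2) {
      stop_vocaleff("need at least 2 individuals to form dyads",
                    class = "vocaleff_validation_error")
    }
    pairs <- utils::combn(sort(ids), 2)
    dyads <- tibble::tibble(id_a = pairs[1, ], id_b = pairs[2, ])
  }
  dyads <- tibble::as_tibble(dyads)
  assert_columns(dyads, c("id_a", "id_b"), "dyads")
  # unordered dyad key
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  dyads$dyad <- key(dyads$id_a, dyads$id_b)
  if (anyDuplicated(dyads$dyad)) {
    stop_vocaleff("duplicated dyad", class = "vocaleff_validation_error")
  }
  dyads$obs_time <- pmin(observation_time[dyads$id_a],
                         observation_time[dyads$id_b])
  aff$dyad <- key(aff$initiator, aff$receiver)
  kept_categories <- character()
  for (cat in categories) {
    events <- table(aff$dyad[aff$behavior == cat])
    n <- as.integer(events[dyads$dyad])
    n[is.na(n)] <- 0L
    rate <- n / dyads$obs_time
    if (mean(rate) == 0) {
      warning("no '", cat, "' events in any dyad; category dropped")
      next
    }
    dyads[[paste0("rate_", cat)]] <- rate
    dyads[[paste0("norm_", cat)]] <- rate / mean(rate)
    kept_categories <- c(kept_categories, cat)
  }
  if (length(kept_categories) == 0) {
    stop_vocaleff("no affiliative events in any included category",
                  class = "vocaleff_validation_error")
  }
  norm_cols <- paste0("norm_", kept_categories)
  dyads$csi <- rowMeans(as.matrix(dyads[, norm_cols, drop = FALSE]))
  mean_csi <- vapply(ids, function(id) {
    mine <- dyads$csi[dyads$id_a == id | dyads$id_b == id]
    if (length(mine) == 0) NA_real_ else mean(mine)
  }, numeric(1))
  structure(
    list(dyadic = dyads[, c("id_a", "id_b", "obs_time",
                            paste0("rate_", kept_categories), "csi")],
         mean_csi = mean_csi, categories = kept_categories),
    class = "csi_table"
  )
}

#' @exportS3Method base::print
print.csi_table <- function(x, ...) {
  cat("Composite sociality index over", nrow(x$dyadic), "dyads; categories:",
      paste(x$categories, collapse = ", "), "\n")
  print(round(sort(x$mean_csi, decreasing = TRUE), 3))
  invisible(x)
}

#' Correct an index for unequal observation effort
#'
#' Individuals observed more often accumulate more interactions, which
#' biases raw Elo and CSI values. The corrected index is the residual of
#' an ordinary least-squares regression of the index on the number of
#' observations per individual, so it is mean-zero and exactly
#' uncorrelated with effort. When effort is constant across individuals
#' the regression is degenerate and the mean-centred index is returned
#' with a warning.
#'
#' @param index Named numeric: raw index per individual.
#' @param n_observations Named numeric: observation count (or time) per
#'   individual; names must cover those of `index`.
#' @return Named numeric of residuals, aligned with `index`.
#' @export
effort_correct <- function(index, n_observations) {
  stopifnot(!is.null(names(index)), !is.null(names(n_observations)))
  missing <- setdiff(names(index), names(n_observations))
  if (length(missing) > 0) {
    stop_vocaleff("no observation count for: ", paste(missing, collapse = ", "),
                  class = "vocaleff_validation_error")
  }
  if (length(index) < 3) {
    stop_vocaleff("effort correction needs at least 3 individuals",
                  class = "vocaleff_validation_error")
  }
  effort <- n_observations[names(index)]
  if (var(effort) == 0) {
    warning("observation effort is constant; returning mean-centred index")
    return(index - mean(index))
  }
  fit <- lm(index ~ effort)
  setNames(residuals(fit), names(index))
}
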