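#' Cohort-adjusted association of one score with pCR
#'
#' Fits `pCR ~ z_score + cohort` by logistic regression on the analysis
#' subset (ER-positive/HER2-negative samples with non-missing response) and
#' reports the odds ratio per 1 standard deviation of the score with a 95%
#' Wald confidence interval (`exp(beta +/- 1.96 SE)`) and a two-sided Wald
#' p-value. Cohort enters as reference-coded dummies (alphabetically first
#' cohort as reference); score results are invariant to that choice.
#'
#' @param scores A `score_table` from [compute_scores()].
#' @param clinical Pooled clinical tibble covering the scored samples.
#' @param which `"ms12"` or `"rs21"`.
#' @return An `assoc_result` object; see [tidy.assoc_result()] and
#'   [glance.assoc_result()].
#' @export
single_score_association <- function(scores, clinical, which = c("ms12", "rs21")) {
  which <- match.arg(which)
  dat <- analysis_data(scores, clinical)
  zcol <- paste0("z_", which)
  fit_association(dat, predictors = setNames(zcol, which),
                  model = "single",
                  percentile = attr(scores, "percentile"))
}

#' Cohort-adjusted association of both scores jointly
#'
#' Fits `pCR ~ z_ms12 + z_rs21 + cohort` on the analysis subset. The joint
#' model asks whether either score carries predictive information not present
#' in the other. Near-collinear scores (|r| > 0.999) are refused with advice
#' to use single-score models.
#'
#' @inheritParams single_score_association
#' @return An `assoc_result` with two predictor rows.
#' @export
combined_association <- function(scores, clinical) {
  dat <- analysis_data(scores, clinical)
  r <- cor(dat$z_ms12, dat$z_rs21)
  if (abs(r) > 0.999) {
    abort(paste0("scores are nearly collinear (r = ", format(r, digits = 4),
                 "); fit single-score models instead"))
  }
  fit_association(dat, predictors = c(ms12 = "z_ms12", rs21 = "z_rs21"),
                  model = "combined",
                  percentile = attr(scores, "percentile"))
}

analysis_data <- function(scores, clinical) {
  eligible <- select_er_pos_her2_neg(clinical, require_response = TRUE)
  dat <- dplyr::inner_join(tibble::as_tibble(scores), eligible,
                           by = c("sample_id", "cohort"))
  if (nrow(dat) == 0L) {
    abort("analysis subset is empty: no scored ER+/HER2- samples with response")
  }
  dat
}

fit_association <- function(dat, predictors, model, percentile = NULL) {
  X <- build_design(dat[, unname(predictors), drop = FALSE], dat$cohort)
  fit <- fit_logistic(dat$pcr, X)
  est <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  stat <- est / se
  terms <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * stats::pnorm(-abs(unname(stat))),
    or = exp(unname(est)),
    conf.low = exp(unname(est) - 1.96 * unname(se)),
    conf.high = exp(unname(est) + 1.96 * unname(se))
  )
  cohorts <- dat |>
    dplyr::count(.data$cohort, name = "n") |>
    dplyr::left_join(
      dat |> dplyr::filter(.data$pcr == 1L) |>
        dplyr::count(.data$cohort, name = "events"),
      by = "cohort") |>
    dplyr::mutate(events = dplyr::coalesce(.data$events, 0L))
  eff <- est[paste0("cohort", cohorts$cohort)]
  cohorts$effect <- ifelse(is.na(eff), 0, unname(eff))
  structure(list(terms = terms,
                 predictors = predictors,
                 model = model,
                 n = nrow(dat),
                 events = sum(dat$pcr),
                 cohorts = cohorts,
                 loglik = fit$loglik,
                 converged = fit$converged,
                 percentile = percentile),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("<assoc_result> ", x$model, "-score logistic model, cohort-adjusted\n",
      "  n = ", x$n, " (", x$events, " pCR events) across ",
      nrow(x$cohorts), " cohort(s)\n", sep = "")
  rows <- tidy(x)
  for (i in seq_len(nrow(rows))) {
    cat(sprintf("  %-6s OR per SD %5.2f (95%% CI %4.2f-%4.2f), p = %s\n",
                rows$signature[i], rows$or[i], rows$conf.low[i],
                rows$conf.high[i], format_pvalue(rows$p.value[i])))
  }
  invisible(x)
}

#' Tidy an association result
#'
#' @param x An `assoc_result`.
#' @param ... Unused.
#' @return A tibble with one row per score predictor: `signature`, `term`,
#'   `estimate` (log-odds per 1 SD), `std.error`, `statistic`, `p.value`,
#'   `or`, `conf.low`, `conf.high`.
#' @method tidy assoc_result
#' @export
tidy.assoc_result <- function(x, ...) {
  x$terms |>
    dplyr::filter(.data$term %in% unname(x$predictors)) |>
    dplyr::mutate(signature = names(x$predictors)[match(.data$term, unname(x$predictors))],
                  .before = 1L)
}

#' One-row model summary of an association result
#'
#' @param x An `assoc_result`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `n`, `events`, `n_cohorts`, `loglik`,
#'   `converged`, `percentile`.
#' @method glance assoc_result
#' @export
glance.assoc_result <- function(x, ...) {
  tibble::tibble(model = x$model, n = x$n, events = x$events,
                 n_cohorts = nrow(x$cohorts), loglik = x$loglik,
                 converged = x$converged,
                 percentile = x$percentile %||% NA_real_)
}

#' Predicted probability of pCR along the score axis
#'
#' Converts a fitted single-score model into a response-probability curve by
#' marginal standardization: at each grid value of the z-score, the fitted
#' probability is averaged over the analysis samples' observed cohort
#' distribution, `mean_c w_c inv_logit(alpha + beta z + gamma_c)`. This gives
#' a population-level curve rather than one conditional on an arbitrary
#' reference cohort.
#'
#' @param result A single-score `assoc_result`.
#' @param grid Numeric z-score grid (default `seq(-3, 3, by = 0.1)`). Values
#'   outside \[-5, 5\] trigger a warning but are still computed.
#' @return A `response_curve` tibble: `signature`, `z`, `probability`.
#' @export
response_probability_curve <- function(result, grid = seq(-3, 3, by = 0.1)) {
  stopifnot(inherits(result, "assoc_result"))
  if (result$model != "single") {
    abort("response_probability_curve() expects a single-score model")
  }
  if (any(grid < -5 | grid > 5)) {
    warn("grid extends beyond [-5, 5] SD; extrapolating the fitted model")
  }
  beta <- result$terms$estimate[result$terms$term == unname(result$predictors)]
  alpha <- result$terms$estimate[result$terms$term == "(Intercept)"]
  w <- result$cohorts$n / sum(result$cohorts$n)
  probs <- vapply(grid, function(z) {
    sum(w * plogis(alpha + beta * z + result$cohorts$effect))
  }, numeric(1))
  out <- tibble::tibble(signature = names(result$predictors),
                        z = grid, probability = probs)
  class(out) <- c("response_curve", class(out))
  out
}

#' Correlation between the two scores
#'
#' Pearson correlation of the per-cohort z-scores of the two signatures,
#' pooled across cohorts (z-scoring removes cohort location and scale, so
#' pooling is not confounded by platform shifts), plus the per-cohort
#' correlations. Computed over the analysis subset.
#'
#' @param scores A `score_table` from [compute_scores()].
#' @return A list of class `score_correlation`: `pooled` (scalar r), `n`,
#'   and `by_cohort` (tibble `cohort`, `r`, `n`).
#' @export
score_correlation <- function(scores) {
  dat <- tibble::as_tibble(scores)
  if ("analysis" %in% names(dat)) {
    dat <- dplyr::filter(dat, .data$analysis)
  }
  if (nrow(dat) < 3L) {
    abort("score_correlation() needs at least 3 samples")
  }
  if (sd(dat$z_ms12) == 0 || sd(dat$z_rs21) == 0) {
    abort("zero variance in a score; correlation undefined")
  }
  by_cohort <- dat |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(r = cor(.data$z_ms12, .data$z_rs21), n = dplyr::n(),
                     .groups = "drop")
  structure(list(pooled = cor(dat$z_ms12, dat$z_rs21),
                 n = nrow(dat),
                 by_cohort = by_cohort),
            class = "score_correlation")
}

#' @export
print.score_correlation <- function(x, ...) {
  cat("<score_correlation> pooled r =", sprintf("%.2f", x$pooled),
      "over", x$n, "samples\n")
  print(x$by_cohort)
  invisible(x)
}

#' Sensitivity of results to the proliferation floor percentile
#'
#' Re-runs the recurrence-score pipeline (re-threshold, re-combine,
#' re-standardize) at each percentile of the grid and refits the single-score
#' recurrence-score model and the combined model. Molecular-score results
#' change only through the combined model (the molecular score itself has no
#' threshold).
#'
#' @param study A study object (see [compute_scores()]).
#' @param grid Percentile grid, default `c(75, 80, 85, 90)`.
#' @param ms12,rs21 Signature definitions.
#' @param normalize Passed to [compute_scores()].
#' @return A `sensitivity_table` tibble with one row per percentile, model
#'   and score: `percentile`, `model` (`"single"`/`"combined"`),
#'   `signature`, `estimate`, `or`, `conf.low`, `conf.high`, `p.value`.
#' @export
sensitivity_sweep <- function(study, grid = c(75, 80, 85, 90),
                              ms12 = ms12_signature(), rs21 = rs21_signature(),
                              normalize = FALSE) {
  if (any(grid < 0 | grid > 100)) {
    abort("percentile grid must lie in [0, 100]")
  }
  clinical <- study_clinical(study)
  rows <- purrr::map(grid, function(p) {
    st <- compute_scores(study, ms12 = ms12, rs21 = rs21, percentile = p,
                         normalize = normalize)
    single_rs <- single_score_association(st, clinical, "rs21")
    comb <- combined_association(st, clinical)
    dplyr::bind_rows(
      tidy(single_rs) |> dplyr::mutate(model = "single"),
      tidy(comb) |> dplyr::mutate(model = "combined")
    ) |>
      dplyr::mutate(percentile = p)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::select("percentile", "model", "signature", "estimate", "or",
                  "conf.low", "conf.high", "p.value")
  class(out) <- c("sensitivity_table", class(out))
  out
}
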