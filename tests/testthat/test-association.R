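# a small three-cohort study with an elevated event rate for stable toy fits
small_study <- function(seed) {
  cfg <- default_paperlike_config(seed = seed)
  cfg$cohorts <- cfg$cohorts[1:3, ]
  cfg$cohorts$n <- c(150L, 150L, 150L)
  cfg$cohorts$alpha <- qlogis(0.15)
  generate_study(validate_simulation_config(cfg))
}

test_that("single-score association reports OR per SD with Wald CI", {
  st <- small_study(21)
  clin <- study_clinical(st)
  sc <- compute_scores(st)
  res <- single_score_association(sc, clin, "ms12")
  td <- tidy(res)
  expect_equal(nrow(td), 1L)
  expect_equal(td$or, exp(td$estimate))
  expect_equal(td$conf.low, exp(td$estimate - 1.96 * td$std.error))
  expect_equal(td$conf.high, exp(td$estimate + 1.96 * td$std.error))
  expect_true(td$conf.low <= td$or && td$or <= td$conf.high)
  expect_true(td$p.value > 0 && td$p.value <= 1)
  g <- glance(res)
  expect_equal(g$n_cohorts, 3L)
  expect_equal(g$n, sum(select_er_pos_her2_neg(clin)$sample_id %in% sc$sample_id))
  expect_true(g$converged)

  # independent check against glm on the identical analysis data
  dat <- dplyr::inner_join(tibble::as_tibble(sc),
                           select_er_pos_her2_neg(clin),
                           by = c("sample_id", "cohort"))
  ref <- glm(pcr ~ z_ms12 + factor(cohort), family = binomial(), data = dat)
  expect_equal(td$estimate, unname(coef(ref)["z_ms12"]), tolerance = 1e-6)
  expect_equal(td$std.error,
               unname(sqrt(diag(vcov(ref))["z_ms12"])), tolerance = 1e-5)
})

test_that("flipping a score's sign inverts the OR and keeps the p-value", {
  st <- small_study(22)
  clin <- study_clinical(st)
  sc <- compute_scores(st)
  base <- tidy(single_score_association(sc, clin, "ms12"))
  flipped <- sc
  flipped$z_ms12 <- -flipped$z_ms12
  flip <- tidy(single_score_association(flipped, clin, "ms12"))
  expect_equal(flip$or, 1 / base$or, tolerance = 1e-8)
  expect_equal(flip$p.value, base$p.value, tolerance = 1e-10)
})

test_that("score ORs are invariant to cohort relabeling", {
  st <- small_study(23)
  clin <- study_clinical(st)
  sc <- compute_scores(st)
  base <- tidy(single_score_association(sc, clin, "rs21"))
  relabel <- c(cohort01 = "zeta", cohort02 = "alpha", cohort03 = "mid")
  sc2 <- sc; sc2$cohort <- unname(relabel[sc$cohort])
  clin2 <- clin; clin2$cohort <- unname(relabel[clin$cohort])
  re <- tidy(single_score_association(sc2, clin2, "rs21"))
  expect_equal(re$estimate, base$estimate, tolerance = 1e-8)
  expect_equal(re$std.error, base$std.error, tolerance = 1e-8)
})

test_that("combined model returns both scores and refuses collinear inputs", {
  st <- small_study(24)
  clin <- study_clinical(st)
  sc <- compute_scores(st)
  res <- combined_association(sc, clin)
  expect_setequal(tidy(res)$signature, c("ms12", "rs21"))
  dup <- sc
  dup$z_rs21 <- dup$z_ms12
  expect_error(combined_association(dup, clin), "collinear")
})

test_that("response curves are marginally standardized over cohorts", {
  st <- small_study(25)
  clin <- study_clinical(st)
  sc <- compute_scores(st)
  res <- single_score_association(sc, clin, "ms12")
  curve <- response_probability_curve(res, grid = seq(-2, 2, by = 0.5))
  expect_true(all(curve$probability > 0 & curve$probability < 1))
  beta <- tidy(res)$estimate
  if (beta > 0) expect_true(all(diff(curve$probability) > 0))

  # brute-force oracle: average per-sample cohort-specific inverse logits
  dat <- dplyr::inner_join(tibble::as_tibble(sc),
                           select_er_pos_her2_neg(clin),
                           by = c("sample_id", "cohort"))
  alpha <- res$terms$estimate[res$terms$term == "(Intercept)"]
  eff <- setNames(res$cohorts$effect, res$cohorts$cohort)
  for (k in seq_len(nrow(curve))) {
    hand <- mean(plogis(alpha + beta * curve$z[k] + eff[dat$cohort]))
    expect_equal(curve$probability[k], unname(hand), tolerance = 1e-12)
  }

  expect_warning(response_probability_curve(res, grid = c(-6, 0)), "-5, 5")
})

test_that("a null slope gives a flat curve at the marginal event rate", {
  cohorts <- tibble::tibble(cohort = c("A", "B"), n = c(40L, 60L),
                            events = c(4L, 6L), effect = c(0, 0.3))
  res <- structure(list(
    terms = tibble::tibble(term = c("(Intercept)", "z"),
                           estimate = c(qlogis(0.1), 0)),
    predictors = c(ms12 = "z"), model = "single", n = 100L, events = 10L,
    cohorts = cohorts, loglik = NA_real_, converged = TRUE,
    percentile = 80), class = "assoc_result")
  curve <- response_probability_curve(res, grid = seq(-3, 3, 1))
  expect_equal(diff(range(curve$probability)), 0)
  expect_equal(curve$probability[1],
               sum(c(0.4, 0.6) * plogis(qlogis(0.1) + c(0, 0.3))))
})

test_that("score correlation is computed on pooled per-cohort z-scores", {
  ident <- tibble::tibble(sample_id = sprintf("s%d", 1:30),
                          cohort = rep(c("A", "B"), each = 15),
                          z_ms12 = rnorm(30))
  ident$z_rs21 <- ident$z_ms12
  expect_equal(score_correlation(ident)$pooled, 1)

  withr::local_seed(4242)
  indep <- tibble::tibble(sample_id = as.character(1:10000),
                          cohort = rep(c("A", "B"), each = 5000),
                          z_ms12 = rnorm(10000), z_rs21 = rnorm(10000))
  expect_lt(abs(score_correlation(indep)$pooled), 0.05)

  const <- ident; const$z_rs21 <- 0
  expect_error(score_correlation(const), "zero variance")
  expect_error(score_correlation(ident[1:2, ]), "at least 3")
})

test_that("the sensitivity sweep re-thresholds, refits, and keeps its shape", {
  st <- small_study(26)
  clin <- study_clinical(st)
  grid <- c(70, 80, 90)
  sw <- sensitivity_sweep(st, grid = grid)
  expect_equal(nrow(sw), length(grid) * 3L)
  expect_equal(sort(unique(sw$percentile)), grid)
  counts <- dplyr::count(sw, .data$percentile)
  expect_true(all(counts$n == 3L))

  # grid {0}: identical to an unthresholded analysis
  sw0 <- sensitivity_sweep(st, grid = 0)
  sc0 <- compute_scores(st, percentile = 0)
  direct <- tidy(single_score_association(sc0, clin, "rs21"))
  row <- sw0[sw0$model == "single" & sw0$signature == "rs21", ]
  expect_equal(row$estimate, direct$estimate, tolerance = 1e-12)
  expect_equal(row$p.value, direct$p.value, tolerance = 1e-12)

  expect_error(sensitivity_sweep(st, grid = c(80, 120)), "\\[0, 100\\]")
})
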