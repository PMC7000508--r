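#' Maximum-likelihood logistic regression by IRLS
#'
#' A small, strict binomial-logit fitter used for all association models in
#' this package. Estimates are obtained by Newton iterations on the
#' log-likelihood (iteratively reweighted least squares) with step halving;
#' convergence is declared when the largest absolute score-gradient
#' component falls below `1e-10` or the relative log-likelihood change falls
#' below `1e-13`, so the returned estimates carry a score gradient far below
#' the `1e-8` accuracy contract. The Wald covariance is the inverse observed
#' information at the optimum.
#'
#' Degenerate problems are refused rather than silently mishandled: a
#' single-class outcome, a rank-deficient design, apparent perfect
#' separation (coefficients diverging while the fit approaches a perfect
#' classifier), and failure to converge within `max_iter` iterations are all
#' errors.
#'
#' @param y Binary outcome vector (0/1).
#' @param X Design matrix including an intercept column.
#' @param weights Optional non-negative case weights (e.g. cell counts of an
#'   aggregated table).
#' @param max_iter Maximum Newton iterations (default 100).
#' @return A list of class `logit_fit`: `coefficients`, `vcov`, `loglik`,
#'   `converged`, `iterations`, `n` (sum of weights), `fitted` (probabilities).
#' @export
fit_logistic <- function(y, X, weights = NULL, max_iter = 100L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  stopifnot(length(y) == nrow(X), length(w) == length(y), all(w >= 0))
  if (any(!y %in% c(0, 1))) {
    abort("outcome must be binary (0/1)")
  }
  events <- sum(w * y)
  if (events == 0 || events == sum(w)) {
    abort("degenerate outcome: all observations in one class")
  }
  qr_x <- qr(X * sqrt(pmax(w, .Machine$double.eps)))
  if (qr_x$rank < ncol(X)) {
    abort("rank-deficient design matrix")
  }

  beta <- numeric(ncol(X))
  ll_old <- logit_loglik(y, X, beta, w)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    grad <- drop(crossprod(X, w * (y - mu)))
    info <- crossprod(X, X * (w * mu * (1 - mu)))
    step <- tryCatch(solve(info, grad), error = function(e) {
      abort(paste0("information matrix singular at iteration ", it,
                   " (possible perfect separation)"))
    })
    # step halving keeps the likelihood monotone
    ll_new <- -Inf
    for (h in 0:10) {
      cand <- beta + step / 2^h
      ll_new <- logit_loglik(y, X, cand, w)
      if (ll_new >= ll_old - 1e-12) break
    }
    beta <- cand
    if (separation_suspected(y, X, beta, w)) {
      abort(paste0("perfect separation suspected: |coefficients| diverging ",
                   "(max |beta| = ", format(max(abs(beta)), digits = 3),
                   "); the score effect is not estimable"))
    }
    grad <- drop(crossprod(X, w * (y - plogis(drop(X %*% beta)))))
    if (max(abs(grad)) < 1e-10 ||
        abs(ll_new - ll_old) < 1e-13 * (abs(ll_old) + 1e-13)) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  if (!converged) {
    abort(paste0("IRLS failed to converge in ", max_iter, " iterations"))
  }
  mu <- plogis(drop(X %*% beta))
  info <- crossprod(X, X * (w * mu * (1 - mu)))
  structure(list(coefficients = setNames(beta, colnames(X)),
                 vcov = solve(info),
                 loglik = ll_old,
                 converged = converged,
                 iterations = it,
                 n = sum(w),
                 fitted = mu),
            class = "logit_fit")
}

logit_loglik <- function(y, X, beta, w) {
  eta <- drop(X %*% beta)
  # numerically stable: log(p) = -log1p(exp(-eta)), log(1-p) = -log1p(exp(eta))
  sum(w * (y * -log1p(exp(-eta)) + (1 - y) * -log1p(exp(eta))))
}

separation_suspected <- function(y, X, beta, w) {
  if (max(abs(beta)) < 15) return(FALSE)
  mu <- plogis(drop(X %*% beta))
  keep <- w > 0
  all(abs(y[keep] - mu[keep]) < 1e-4)
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("<logit_fit> n =", x$n, " loglik =", format(x$loglik, digits = 6),
      " iterations =", x$iterations, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Build a cohort-adjusted design matrix
#'
#' Intercept, score columns, then reference-coded cohort dummies with the
#' alphabetically first cohort as reference (a pinned, arbitrary choice:
#' score coefficients are invariant to it, and pinning makes output stable).
#'
#' @param scores Matrix or data frame of score columns (may be NULL).
#' @param cohort Cohort labels.
#' @return Numeric design matrix with named columns.
#' @keywords internal
build_design <- function(scores, cohort) {
  cohort <- as.character(cohort)
  levels <- sort(unique(cohort))
  X <- cbind(`(Intercept)` = rep(1, length(cohort)))
  if (!is.null(scores)) {
    X <- cbind(X, as.matrix(scores))
  }
  if (length(levels) > 1L) {
    dummies <- vapply(levels[-1L], function(l) as.numeric(cohort == l),
                      numeric(length(cohort)))
    colnames(dummies) <- paste0("cohort", levels[-1L])
    X <- cbind(X, dummies)
  }
  X
}
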