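#' Compute gene-group scores for a signature
#'
#' For each sample, each gene group's score is the weighted mean of its
#' member genes (weights from the signature's `targets`, normalized by the
#' sum of the weights of the genes actually used), and each singleton gene is
#' passed through unchanged.
#'
#' Missing-gene policy: a grouped gene absent from `gene_expr` is dropped and
#' the group mean is taken over the remaining members (renormalized weights).
#' A group whose members are all missing, or a missing singleton gene, is an
#' error — there is no sensible fallback for either.
#'
#' @param gene_expr Gene-level tibble from [collapse_probes()] (`gene`,
#'   `n_probes`, sample columns).
#' @param sig A `signature_definition`.
#' @return A tibble with `sample_id` followed by one numeric column per group
#'   label and one per singleton gene.
#' @export
compute_group_scores <- function(gene_expr, sig) {
  validate_signature(sig)
  m <- expr_as_matrix(gene_expr)
  present <- rownames(m)
  out <- tibble::tibble(sample_id = colnames(m))
  for (grp in names(sig$group_weights)) {
    members <- sig$targets[sig$targets$group == grp, ]
    avail <- members[members$gene %in% present, ]
    if (nrow(avail) == 0L) {
      abort(paste0("signature '", sig$name, "': all genes of group '", grp,
                   "' are missing from the expression data"))
    }
    w <- avail$weight / sum(avail$weight)
    out[[grp]] <- unname(drop(crossprod(m[avail$gene, , drop = FALSE], w)))
  }
  for (g in names(sig$singleton_weights)) {
    if (!g %in% present) {
      abort(paste0("signature '", sig$name, "': singleton gene '", g,
                   "' is missing from the expression data"))
    }
    out[[g]] <- unname(m[g, ])
  }
  out
}

#' Floor values at a percentile of a reference population
#'
#' Computes the p-th percentile of `x` over the reference subset using linear
#' interpolation between order statistics (`h = (n - 1) p / 100 + 1`, i.e.
#' [stats::quantile()] type 7) and replaces every value below it — in all
#' samples, not just the reference — by that threshold. `p = 0` returns the
#' input unchanged. Flooring removes discrimination below the threshold,
#' which is exactly its purpose in the recurrence-score algorithm.
#'
#' @param x Numeric vector of per-sample values.
#' @param reference Indices or logical mask selecting the reference
#'   population within `x` (default: all of `x`).
#' @param p Percentile in \[0, 100\].
#' @return Numeric vector, `pmax(x, threshold)`.
#' @export
apply_percentile_floor <- function(x, reference = seq_along(x), p) {
  if (p < 0 || p > 100) {
    abort("percentile must be in [0, 100]")
  }
  ref <- x[reference]
  if (length(ref) == 0L || all(is.na(ref))) {
    abort("apply_percentile_floor(): empty reference population")
  }
  if (p == 0) {
    return(x)
  }
  t <- unname(quantile(ref, probs = p / 100, type = 7, names = FALSE))
  pmax(x, t)
}

#' Compute the raw 12-gene molecular score
#'
#' The weighted sum of the eight target genes' expression values. All eight
#' genes must be resolvable: at least one probe was available for each on all
#' commercial array platforms considered, so a missing gene indicates an
#' annotation problem rather than a platform limitation, and no drop policy
#' applies.
#'
#' @param gene_expr Gene-level tibble from [collapse_probes()].
#' @param sig Signature definition; default [ms12_signature()].
#' @return Named numeric vector of raw scores, one per sample.
#' @export
compute_ms12 <- function(gene_expr, sig = ms12_signature()) {
  validate_signature(sig)
  w <- sig$singleton_weights
  m <- expr_as_matrix(gene_expr)
  absent <- setdiff(names(w), rownames(m))
  if (length(absent) > 0L) {
    abort(paste0("compute_ms12(): required genes missing: ",
                 paste(absent, collapse = ", ")))
  }
  drop(crossprod(m[names(w), , drop = FALSE], w))
}

#' Combine group scores into the raw 21-gene recurrence score
#'
#' The linear combination of group scores and singleton gene values with the
#' signature's weights. The proliferation group is expected to have been
#' floor-thresholded already (see [apply_percentile_floor()]); above the
#' floor the score is linear in every input.
#'
#' @param group_scores Tibble from [compute_group_scores()].
#' @param sig Signature definition; default [rs21_signature()].
#' @return Named numeric vector of raw scores, one per sample.
#' @export
compute_rs21 <- function(group_scores, sig = rs21_signature()) {
  validate_signature(sig)
  w <- c(sig$group_weights, sig$singleton_weights)
  absent <- setdiff(names(w), names(group_scores))
  if (length(absent) > 0L) {
    abort(paste0("compute_rs21(): missing group or singleton columns: ",
                 paste(absent, collapse = ", ")))
  }
  m <- as.matrix(group_scores[, names(w)])
  setNames(drop(m %*% w), group_scores$sample_id)
}

#' Standardize scores within cohort
#'
#' Transforms raw scores to z-scores within each cohort: `(x - m) / s`, where
#' `m` and `s` are the mean and sample standard deviation (denominator
#' n - 1) computed over the analysis subset only. All samples receive a
#' z-score on their cohort's analysis-subset scale, so effect sizes
#' downstream are per 1 SD of the analysis population and cohort
#' location/scale differences (platform effects) are removed.
#'
#' @param x Numeric vector of raw scores.
#' @param cohort Cohort label per element of `x`.
#' @param subset Logical mask (or indices) selecting the analysis subset;
#'   default: all samples.
#' @return Numeric vector of z-scores, same length and order as `x`.
#' @export
zscore_by_cohort <- function(x, cohort, subset = NULL) {
  stopifnot(length(x) == length(cohort))
  in_subset <- rep(FALSE, length(x))
  in_subset[if (is.null(subset)) seq_along(x) else subset] <- TRUE
  z <- rep(NA_real_, length(x))
  for (co in unique(cohort)) {
    idx <- cohort == co
    ref <- x[idx & in_subset]
    if (length(ref) < 2L) {
      abort(paste0("cohort '", co, "': fewer than 2 analysis samples, cannot standardize"))
    }
    s <- sd(ref)
    if (!is.finite(s) || s == 0) {
      abort(paste0("cohort '", co, "': zero variance, cannot standardize"))
    }
    z[idx] <- (x[idx] - mean(ref)) / s
  }
  z
}

#' Score all samples of a multi-cohort study
#'
#' Runs the full scoring pipeline for every cohort: optional between-array
#' scaling normalization, probe-to-gene collapsing for the union of the two
#' signatures' genes, the raw 12-gene molecular score, the raw 21-gene
#' recurrence score (with the proliferation group floored at the configured
#' percentile of that cohort's ER-positive patients), and per-cohort
#' z-standardization of both scores over the analysis subset
#' (ER-positive/HER2-negative with non-missing response).
#'
#' @param study A study object: a named list of cohorts, each a list with
#'   elements `expression` (probe tibble), `annotation` (probe-to-gene
#'   tibble), and `clinical` (clinical tibble). [generate_study()] returns
#'   this structure; for real data assemble it from [read_expression()],
#'   [read_clinical()] and an annotation table.
#' @param ms12,rs21 Signature definitions (defaults: the shipped configs).
#' @param percentile Proliferation floor percentile; default: the value in
#'   `rs21`'s threshold policy. Use 0 for no floor.
#' @param normalize If `TRUE`, apply [scale_normalize()] per cohort first.
#' @return A `score_table` tibble: `sample_id`, `cohort`, `raw_ms12`,
#'   `raw_rs21`, `z_ms12`, `z_rs21`, plus logical `analysis` flagging the
#'   analysis subset. The floor percentile used is attached as attribute
#'   `percentile`.
#' @export
compute_scores <- function(study, ms12 = ms12_signature(),
                           rs21 = rs21_signature(), percentile = NULL,
                           normalize = FALSE) {
  percentile <- percentile %||% (sig_threshold_percentile(rs21) %||% 80)
  genes <- union(signature_genes(ms12), signature_genes(rs21))
  thr_group <- if (!is.null(rs21$threshold)) rs21$threshold$group else NULL
  per_cohort <- purrr::imap(study_cohorts(study), function(co, co_name) {
    expr <- co$expression
    if (normalize) expr <- scale_normalize(expr)
    g <- collapse_probes(expr, co$annotation, genes)
    raw_ms <- compute_ms12(g, ms12)
    gs <- compute_group_scores(g, rs21)
    if (!is.null(thr_group) && percentile > 0) {
      er_pos <- co$clinical$sample_id[co$clinical$er_status == "positive"]
      ref <- which(gs$sample_id %in% er_pos)
      gs[[thr_group]] <- apply_percentile_floor(gs[[thr_group]], ref, percentile)
    }
    raw_rs <- compute_rs21(gs, rs21)
    analysis_ids <- select_er_pos_her2_neg(co$clinical)$sample_id
    tibble::tibble(sample_id = gs$sample_id,
                   cohort = co_name,
                   raw_ms12 = unname(raw_ms[gs$sample_id]),
                   raw_rs21 = unname(raw_rs),
                   analysis = gs$sample_id %in% analysis_ids)
  })
  out <- dplyr::bind_rows(per_cohort)
  out$z_ms12 <- zscore_by_cohort(out$raw_ms12, out$cohort, out$analysis)
  out$z_rs21 <- zscore_by_cohort(out$raw_rs21, out$cohort, out$analysis)
  out <- out[, c("sample_id", "cohort", "raw_ms12", "raw_rs21",
                 "z_ms12", "z_rs21", "analysis")]
  attr(out, "percentile") <- percentile
  class(out) <- c("score_table", class(out))
  out
}

sig_threshold_percentile <- function(sig) {
  if (is.null(sig$threshold)) NULL else sig$threshold$percentile
}

study_cohorts <- function(study) {
  cohorts <- if (!is.null(study$cohorts)) study$cohorts else study
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts)))) {
    abort("study cohorts must be a named list")
  }
  cohorts
}

#' Pooled clinical table of a study
#' @param study A study object (see [compute_scores()]).
#' @return One clinical tibble with all cohorts' samples.
#' @export
study_clinical <- function(study) {
  dplyr::bind_rows(purrr::map(study_cohorts(study), "clinical"))
}
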