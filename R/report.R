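#' Published sample counts of the six public neoadjuvant series
#'
#' The per-cohort overview counts reported for the six GEO microarray series
#' used in the head-to-head score comparison (GSE20194, GSE20271, GSE25066,
#' GSE32646, GSE34138, GSE41998): total patients profiled, pCR events,
#' the ER-positive/HER2-negative subset with evaluable response, and pCR
#' events within that subset. These counts parameterize the default
#' simulation configuration and allow the pooled response-rate arithmetic to
#' be reproduced without downloading the series.
#'
#' @return A tibble with columns `accession`, `platform`, `n_patients`,
#'   `n_pcr`, `n_er_pos_her2_neg`, `n_pcr_er_pos_her2_neg`.
#' @export
geo_cohort_counts <- function() {
  readr::read_tsv(system.file("extdata", "geo_cohort_counts.tsv",
                              package = "neoscore", mustWork = TRUE),
                  col_types = "cciiii", progress = FALSE)
}

#' Per-cohort sample accounting of a study
#'
#' The study-overview analog: per cohort, total samples, the
#' ER-positive/HER2-negative subset, the evaluable subset (additionally
#' non-missing response), and pCR events among the evaluable; plus a pooled
#' row. Pooled counts are exact sums of the per-cohort counts.
#'
#' @param clinical A clinical tibble (possibly pooled over cohorts).
#' @return A tibble: `cohort`, `n`, `n_er_pos_her2_neg`, `n_evaluable`,
#'   `n_pcr`, with a final `"(pooled)"` row.
#' @export
cohort_summary <- function(clinical) {
  per <- clinical |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_er_pos_her2_neg = sum(.data$er_status == "positive" &
                                .data$her2_status == "negative"),
      n_evaluable = sum(.data$er_status == "positive" &
                          .data$her2_status == "negative" & !is.na(.data$pcr)),
      n_pcr = sum(.data$pcr == 1L & .data$er_status == "positive" &
                    .data$her2_status == "negative", na.rm = TRUE),
      .groups = "drop") |>
    dplyr::arrange(.data$cohort)
  pooled <- per |>
    dplyr::summarise(cohort = "(pooled)",
                     n = sum(.data$n),
                     n_er_pos_her2_neg = sum(.data$n_er_pos_her2_neg),
                     n_evaluable = sum(.data$n_evaluable),
                     n_pcr = sum(.data$n_pcr))
  dplyr::bind_rows(per, pooled)
}

#' Run the full head-to-head analysis on a study
#'
#' Executes the whole pipeline: (optional) scaling normalization, probe
#' collapsing, score computation with the proliferation floor, per-cohort
#' z-standardization, both single-score models, the combined model, the
#' score correlation, response-probability curves, and the
#' proliferation-threshold sensitivity sweep. The analysis path is fully
#' deterministic: identical inputs produce identical reports.
#'
#' @param study A study object (see [compute_scores()]).
#' @param ms12,rs21 Signature definitions.
#' @param percentile Proliferation floor percentile (default from `rs21`).
#' @param sweep_grid Percentile grid for [sensitivity_sweep()]; use
#'   `numeric(0)` to skip the sweep.
#' @param normalize Apply [scale_normalize()] per cohort.
#' @param curve_grid z grid for [response_probability_curve()].
#' @return An `analysis_report`: list with `cohort_summary`, `scores`,
#'   `single` (list of two `assoc_result`s), `combined`, `correlation`,
#'   `curves`, `sensitivity`, and `provenance`.
#' @export
run_full_analysis <- function(study, ms12 = ms12_signature(),
                              rs21 = rs21_signature(), percentile = NULL,
                              sweep_grid = c(75, 80, 85, 90),
                              normalize = FALSE,
                              curve_grid = seq(-3, 3, by = 0.1)) {
  clinical <- study_clinical(study)
  scores <- compute_scores(study, ms12 = ms12, rs21 = rs21,
                           percentile = percentile, normalize = normalize)
  single <- list(
    ms12 = single_score_association(scores, clinical, "ms12"),
    rs21 = single_score_association(scores, clinical, "rs21")
  )
  combined <- combined_association(scores, clinical)
  curves <- dplyr::bind_rows(
    response_probability_curve(single$ms12, curve_grid),
    response_probability_curve(single$rs21, curve_grid)
  )
  class(curves) <- c("response_curve", class(tibble::tibble()))
  sensitivity <- if (length(sweep_grid) > 0L) {
    sensitivity_sweep(study, grid = sweep_grid, ms12 = ms12, rs21 = rs21,
                      normalize = normalize)
  } else {
    NULL
  }
  structure(list(
    cohort_summary = cohort_summary(clinical),
    scores = scores,
    single = single,
    combined = combined,
    correlation = score_correlation(scores),
    curves = curves,
    sensitivity = sensitivity,
    provenance = list(
      package_version = as.character(utils::packageVersion("neoscore")),
      percentile = attr(scores, "percentile"),
      sweep_grid = sweep_grid,
      normalize = normalize,
      reference_cohort = sort(unique(clinical$cohort))[1L],
      signatures = c(ms12$name, rs21$name)
    )
  ), class = "analysis_report")
}

#' Association summary table of a report
#'
#' The head-to-head association table: one row per score and model block
#' (single-score and combined), with OR per 1 SD, 95% CI, and p-value.
#'
#' @param report An `analysis_report`.
#' @return A tibble: `model`, `signature`, `or`, `conf.low`, `conf.high`,
#'   `p.value`, `n`, `events`.
#' @export
association_table <- function(report) {
  dplyr::bind_rows(
    tidy(report$single$ms12) |> dplyr::mutate(model = "single"),
    tidy(report$single$rs21) |> dplyr::mutate(model = "single"),
    tidy(report$combined) |> dplyr::mutate(model = "combined")
  ) |>
    dplyr::mutate(n = report$combined$n, events = report$combined$events) |>
    dplyr::select("model", "signature", "or", "conf.low", "conf.high",
                  "p.value", "n", "events")
}

#' @export
print.analysis_report <- function(x, ...) {
  cs <- x$cohort_summary
  pooled <- cs[cs$cohort == "(pooled)", ]
  cat("<analysis_report>\n")
  cat("  ", nrow(cs) - 1L, " cohorts; ", pooled$n_evaluable,
      " evaluable ER+/HER2- samples, ", pooled$n_pcr, " pCR (",
      sprintf("%.1f%%", 100 * pooled$n_pcr / pooled$n_evaluable), ")\n",
      sep = "")
  cat("  score correlation (pooled z): r = ",
      sprintf("%.2f", x$correlation$pooled), "\n", sep = "")
  cat("  association with response (OR per 1 SD):\n")
  at <- association_table(x)
  for (i in seq_len(nrow(at))) {
    cat(sprintf("    %-8s %-5s %5.2f (%4.2f, %4.2f)  p = %s\n",
                at$model[i], at$signature[i], at$or[i], at$conf.low[i],
                at$conf.high[i], format_pvalue(at$p.value[i])))
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `cohort_summary.tsv`, `scores.tsv`, `association.tsv` (OR and CI
#' bounds to 2 decimals, p to 2 significant figures), `correlation.tsv`,
#' `curves.tsv`, `sensitivity.tsv` (omitted, with a message, when no sweep
#' was run), and a human-readable `report.txt`.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(df, file) {
    p <- file.path(dir, file)
    readr::write_tsv(df, p, progress = FALSE)
    paths[[file]] <<- p
  }
  emit(report$cohort_summary, "cohort_summary.tsv")
  emit(tibble::as_tibble(report$scores), "scores.tsv")
  at <- association_table(report) |>
    dplyr::mutate(dplyr::across(c("or", "conf.low", "conf.high"),
                                ~ sprintf("%.2f", .x)),
                  p.value = vapply(.data$p.value, format_pvalue, character(1)))
  emit(at, "association.tsv")
  emit(dplyr::bind_rows(
    tibble::tibble(cohort = "(pooled)", r = report$correlation$pooled,
                   n = report$correlation$n),
    report$correlation$by_cohort), "correlation.tsv")
  emit(tibble::as_tibble(report$curves), "curves.tsv")
  if (!is.null(report$sensitivity) && nrow(report$sensitivity) > 0L) {
    emit(tibble::as_tibble(report$sensitivity), "sensitivity.tsv")
  } else {
    inform("no sensitivity sweep in report; sensitivity.tsv omitted")
  }
  txt <- utils::capture.output(print(report))
  prov <- report$provenance
  txt <- c(txt, "",
           paste0("proliferation floor percentile: ", prov$percentile),
           paste0("sweep grid: ", paste(prov$sweep_grid, collapse = ", ")),
           paste0("reference cohort: ", prov$reference_cohort),
           paste0("normalized: ", prov$normalize),
           paste0("neoscore version: ", prov$package_version))
  writeLines(txt, file.path(dir, "report.txt"))
  paths[["report.txt"]] <- file.path(dir, "report.txt")
  invisible(paths)
}

#' Format a p-value to two significant figures
#'
#' `0.00412` renders as `"0.0041"`; very small values switch to scientific
#' notation (`9.4e-05`).
#'
#' @param p A p-value.
#' @return Character scalar.
#' @export
format_pvalue <- function(p) {
  stopifnot(p >= 0, p <= 1)
  s <- signif(p, 2)
  if (s >= 1e-4) {
    format(s, scientific = FALSE, drop0trailing = TRUE)
  } else {
    format(s, scientific = TRUE)
  }
}
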