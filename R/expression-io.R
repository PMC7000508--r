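#' Read a probe-level expression matrix
#'
#' Reads a delimited text file of log2 expression intensities with probes in
#' rows and samples in columns. Two dialects are supported: `plain_tsv`, a
#' tab-separated table whose header row holds sample identifiers and whose
#' first column holds probe identifiers, and `series_matrix`, the GEO
#' series-matrix text layout in which the numeric block is delimited by
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers and all
#' other lines are metadata.
#'
#' @param path Path to the file.
#' @param dialect One of `"plain_tsv"` or `"series_matrix"`.
#'
#' @return A tibble with a character `probe_id` column followed by one numeric
#'   column per sample, in file order.
#'
#' @details Validation is strict: duplicated probe or sample identifiers,
#'   non-numeric cells (the error names the offending probe and sample),
#'   non-finite values, and matrices with fewer than two samples are all
#'   rejected.
#'
#' @seealso [write_expression()], [scale_normalize()], [collapse_probes()]
#' @export
read_expression <- function(path, dialect = c("plain_tsv", "series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("expression file not found: ", path))
  }
  lines <- readLines(path)
  if (dialect == "series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
      abort("series_matrix dialect: missing or malformed table begin/end markers")
    }
    lines <- lines[(begin + 1L):(end - 1L)]
  }
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  sample_ids <- gsub('^"|"$', "", header[-1L])
  body <- fields[-1L]
  probe_ids <- gsub('^"|"$', "", vapply(body, `[[`, character(1), 1L))
  validate_ids(probe_ids, "probe")
  validate_ids(sample_ids, "sample")
  if (length(sample_ids) < 2L) {
    abort("expression matrix must contain at least 2 samples")
  }
  n_col <- length(header)
  bad_len <- which(lengths(body) != n_col)
  if (length(bad_len) > 0L) {
    abort(paste0("row for probe ", probe_ids[bad_len[1L]],
                 " has ", lengths(body)[bad_len[1L]] - 1L,
                 " values; expected ", n_col - 1L))
  }
  values <- matrix(NA_real_, nrow = length(body), ncol = n_col - 1L,
                   dimnames = list(probe_ids, sample_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0L) {
      abort(paste0("non-numeric or non-finite value for probe ",
                   probe_ids[i], ", sample ", sample_ids[bad[1L]]))
    }
    values[i, ] <- v
  }
  expr_as_tibble(values)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()] for the `plain_tsv` dialect. Values are
#' written with enough significant digits that a read/write round trip
#' reproduces the matrix to the stated precision.
#'
#' @param expr Expression tibble (`probe_id` column plus sample columns).
#' @param path Output path.
#' @param digits Significant digits written (default 10).
#' @return The input, invisibly.
#' @export
write_expression <- function(expr, path, digits = 10) {
  m <- expr_as_matrix(expr)
  header <- paste(c("probe_id", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], formatC(m[i, ], digits = digits, format = "g")),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(expr)
}

#' Between-array normalization by simple scaling
#'
#' Shifts each sample column (on the log2 scale) so that its mean equals the
#' grand mean of all column means. This is the simple-scaling (SSN) step used
#' to put bead-array samples on a common scale; it changes per-sample
#' location only, never within-sample variance.
#'
#' @param expr Expression tibble as returned by [read_expression()].
#' @return An expression tibble whose sample column means are all equal (to
#'   1e-9). Idempotent.
#' @export
scale_normalize <- function(expr) {
  m <- expr_as_matrix(expr)
  if (ncol(m) < 2L) {
    abort("scale_normalize() needs at least 2 samples")
  }
  col_means <- colMeans(m)
  m <- sweep(m, 2L, col_means - mean(col_means))
  expr_as_tibble(m)
}

#' Collapse probe-level rows to gene-level rows
#'
#' For each requested gene, averages (unweighted arithmetic mean, per sample)
#' all probes whose annotation maps to that gene symbol. No probe filtering is
#' applied: every mapped probe contributes. Genes with no mapped probe are
#' reported in the `missing_genes` attribute rather than silently dropped;
#' the policy for handling them belongs to the scoring layer.
#'
#' @param expr Expression tibble (probes x samples).
#' @param annotation A data frame with columns `probe_id` and `gene` mapping
#'   each probe to at most one gene symbol; probes absent from the table (or
#'   with `NA`/empty gene) are unmapped.
#' @param genes Character vector of gene symbols to collapse to.
#'
#' @return A tibble with columns `gene`, `n_probes` (provenance: number of
#'   probes averaged), then one numeric column per sample. The attribute
#'   `missing_genes` lists requested genes with zero mapped probes; see
#'   [missing_genes()].
#' @export
collapse_probes <- function(expr, annotation, genes) {
  if (length(genes) == 0L) {
    abort("collapse_probes(): empty gene list")
  }
  stopifnot(all(c("probe_id", "gene") %in% names(annotation)))
  if (anyDuplicated(annotation$probe_id)) {
    dup <- unique(annotation$probe_id[duplicated(annotation$probe_id)])
    abort(paste0("annotation maps probes to more than one gene: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  m <- expr_as_matrix(expr)
  genes <- unique(genes)
  ann <- annotation[!is.na(annotation$gene) & nzchar(annotation$gene), ]
  ann <- ann[ann$probe_id %in% rownames(m) & ann$gene %in% genes, ]
  if (nrow(ann) == 0L) {
    out <- tibble::tibble(gene = character(), n_probes = integer())
    attr(out, "missing_genes") <- genes
    return(out)
  }
  sums <- rowsum(m[ann$probe_id, , drop = FALSE], group = ann$gene)
  counts <- tabulate(factor(ann$gene, levels = rownames(sums)))
  avg <- sums / counts
  keep <- intersect(genes, rownames(avg))
  out <- dplyr::bind_cols(
    tibble::tibble(gene = keep,
                   n_probes = counts[match(keep, rownames(avg))]),
    tibble::as_tibble(as.data.frame(avg[keep, , drop = FALSE],
                                    optional = TRUE))
  )
  attr(out, "missing_genes") <- setdiff(genes, out$gene)
  out
}

#' Genes a probe collapse could not resolve
#'
#' @param gene_expr Result of [collapse_probes()].
#' @return Character vector of requested gene symbols with no mapped probe.
#' @export
missing_genes <- function(gene_expr) {
  attr(gene_expr, "missing_genes") %||% character()
}

#' Read a clinical annotation table
#'
#' Reads a tab-separated clinical table with required columns `sample_id`,
#' `cohort`, `er_status`, `her2_status` and `pcr`. Receptor-status encodings
#' vary across public series, so parsing is permissive but explicit:
#' `P/pos/positive/1` map to `"positive"`, `N/neg/negative/0` to
#' `"negative"` (case-insensitively), and anything else to `"unknown"`.
#' `pcr` is parsed to 1/0 with unparseable or empty entries set to `NA`
#' (missing response).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample_id`, `cohort`, `er_status`,
#'   `her2_status` (each `"positive"`/`"negative"`/`"unknown"`), and integer
#'   `pcr` (1, 0, or `NA`).
#' @export
read_clinical <- function(path) {
  clin <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  required <- c("sample_id", "cohort", "er_status", "her2_status", "pcr")
  missing_cols <- setdiff(required, names(clin))
  if (length(missing_cols) > 0L) {
    abort(paste0("clinical table missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::tibble(
    sample_id = clin$sample_id,
    cohort = clin$cohort,
    er_status = parse_receptor_status(clin$er_status),
    her2_status = parse_receptor_status(clin$her2_status),
    pcr = parse_pcr(clin$pcr)
  )
  validate_clinical(out)
}

parse_receptor_status <- function(x) {
  x <- tolower(trimws(as.character(x)))
  dplyr::case_when(
    x %in% c("p", "pos", "positive", "1") ~ "positive",
    x %in% c("n", "neg", "negative", "0") ~ "negative",
    TRUE ~ "unknown"
  )
}

parse_pcr <- function(x) {
  x <- tolower(trimws(as.character(x)))
  dplyr::case_when(
    x %in% c("1", "pcr", "yes", "true") ~ 1L,
    x %in% c("0", "rd", "no", "false") ~ 0L,
    TRUE ~ NA_integer_
  )
}

validate_clinical <- function(clin) {
  dup <- clin |>
    dplyr::count(.data$cohort, .data$sample_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(paste0("duplicated sample ids within cohort: ",
                 paste(head(dup$sample_id, 5), collapse = ", ")))
  }
  stopifnot(all(clin$pcr %in% c(0L, 1L, NA_integer_)))
  clin
}

#' Select the ER-positive, HER2-negative analysis population
#'
#' Filters a clinical table to samples with positive estrogen-receptor status
#' and negative HER2 status, the population in which response to neoadjuvant
#' chemotherapy is evaluated here. Samples with unknown status never pass the
#' filter.
#'
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @param require_response If `TRUE` (default), additionally requires a
#'   non-missing pCR outcome.
#' @return The filtered clinical tibble (possibly empty).
#' @export
select_er_pos_her2_neg <- function(clinical, require_response = TRUE) {
  out <- dplyr::filter(clinical,
                       .data$er_status == "positive",
                       .data$her2_status == "negative")
  if (require_response) {
    out <- dplyr::filter(out, !is.na(.data$pcr))
  }
  out
}

## internal helpers -----------------------------------------------------------

expr_as_matrix <- function(expr) {
  id_col <- intersect(c("probe_id", "gene"), names(expr))[1]
  if (is.na(id_col)) {
    abort("expression table must have a 'probe_id' or 'gene' column")
  }
  value_cols <- setdiff(names(expr), c("probe_id", "gene", "n_probes"))
  m <- as.matrix(expr[, value_cols])
  storage.mode(m) <- "double"
  rownames(m) <- expr[[id_col]]
  m
}

expr_as_tibble <- function(m) {
  tibble::tibble(probe_id = rownames(m),
                 !!!as.data.frame(m, optional = TRUE))
}

validate_ids <- function(ids, what) {
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicated ", what, " ids: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  if (any(!nzchar(ids))) {
    abort(paste0("empty ", what, " id"))
  }
  invisible(ids)
}
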