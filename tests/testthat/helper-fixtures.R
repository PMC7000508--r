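# fixtures are built in code; no files are shipped

expr_tbl <- function(values, probes = NULL, samples = NULL) {
  values <- as.matrix(values)
  rownames(values) <- probes %||% sprintf("p%02d", seq_len(nrow(values)))
  colnames(values) <- samples %||% sprintf("s%02d", seq_len(ncol(values)))
  tibble::tibble(probe_id = rownames(values),
                 !!!as.data.frame(values, optional = TRUE))
}

random_expr <- function(n_probes, n_samples, seed = 42) {
  withr::with_seed(seed, expr_tbl(matrix(rnorm(n_probes * n_samples, 8, 2),
                                         n_probes, n_samples)))
}

clinical_tbl <- function(n, cohort = "A", er = "positive", her2 = "negative",
                         pcr = 0L, ids = NULL) {
  tibble::tibble(sample_id = ids %||% sprintf("s%02d", seq_len(n)),
                 cohort = cohort,
                 er_status = rep_len(er, n),
                 her2_status = rep_len(her2, n),
                 pcr = rep_len(as.integer(pcr), n))
}

# one-cohort study with genes measured perfectly (one probe per gene)
toy_study <- function(gene_values, clinical) {
  genes <- rownames(gene_values)
  expr <- expr_tbl(gene_values, probes = paste0(genes, "_p1"),
                   samples = clinical$sample_id)
  ann <- tibble::tibble(probe_id = paste0(genes, "_p1"), gene = genes)
  setNames(list(list(expression = expr, annotation = ann,
                     clinical = clinical)),
           clinical$cohort[1])
}

# independently coded oracles -------------------------------------------------

oracle_weighted_mean <- function(values, weights) {
  # values: genes x samples; plain loop, no shared code with the package
  out <- numeric(ncol(values))
  for (j in seq_len(ncol(values))) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(values))) {
      num <- num + weights[i] * values[i, j]
      den <- den + weights[i]
    }
    out[j] <- num / den
  }
  out
}

oracle_dot <- function(values, weights) {
  out <- numeric(ncol(values))
  for (j in seq_len(ncol(values))) {
    s <- 0
    for (i in seq_len(nrow(values))) s <- s + weights[i] * values[i, j]
    out[j] <- s
  }
  out
}

oracle_quantile_type7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
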