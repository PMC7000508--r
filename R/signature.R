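#' Define a multi-gene expression signature
#'
#' A signature definition describes how gene-level expression values combine
#' into a single score: genes grouped into weighted gene groups (each group
#' score is the weighted mean of its member genes), singleton genes entering
#' the score directly, a weight per group and per singleton, and an optional
#' percentile floor threshold applied to one group before combination.
#'
#' @param name Signature name.
#' @param targets A data frame with columns `gene`, `group`, `weight`
#'   describing group membership and within-group weights. May be empty for a
#'   signature made of singletons only.
#' @param group_weights Named numeric vector: weight of each group score in
#'   the final combination. Names must match `targets$group`.
#' @param singleton_weights Named numeric vector: weight of each singleton
#'   gene (genes entering the score directly, outside any group).
#' @param threshold Optional list with elements `group` (group label to
#'   floor), `percentile` (in \[0, 100\]), and `reference` (rule naming the
#'   reference population for the percentile; currently `"er_positive"`).
#'
#' @return An object of class `signature_definition`.
#' @seealso [ms12_signature()], [rs21_signature()], [read_signature()]
#' @export
signature_definition <- function(name, targets = NULL, group_weights = NULL,
                                 singleton_weights = NULL, threshold = NULL) {
  targets <- if (is.null(targets)) {
    tibble::tibble(gene = character(), group = character(), weight = numeric())
  } else {
    tibble::as_tibble(targets)
  }
  group_weights <- unlist(group_weights) %||% numeric()
  singleton_weights <- unlist(singleton_weights) %||% numeric()
  sig <- structure(list(name = name,
                        targets = targets,
                        group_weights = group_weights,
                        singleton_weights = singleton_weights,
                        threshold = threshold),
                   class = "signature_definition")
  validate_signature(sig)
}

#' Validate a signature definition
#'
#' Checks structural invariants: every gene appears in exactly one place
#' (either one group or the singleton set), every group referenced by a group
#' weight exists and vice versa, and any threshold percentile lies in
#' \[0, 100\].
#'
#' @param sig A `signature_definition`.
#' @return `sig`, invisibly usable, after validation (errors otherwise).
#' @export
validate_signature <- function(sig) {
  stopifnot(inherits(sig, "signature_definition"))
  all_genes <- c(sig$targets$gene, names(sig$singleton_weights))
  if (anyDuplicated(all_genes)) {
    dup <- unique(all_genes[duplicated(all_genes)])
    abort(paste0("signature '", sig$name, "': genes appear more than once: ",
                 paste(dup, collapse = ", ")))
  }
  if (length(all_genes) == 0L) {
    abort(paste0("signature '", sig$name, "' has no genes"))
  }
  groups_used <- unique(sig$targets$group)
  if (!setequal(groups_used, names(sig$group_weights))) {
    abort(paste0("signature '", sig$name,
                 "': group_weights and target groups disagree"))
  }
  if (nrow(sig$targets) > 0L && any(sig$targets$weight <= 0)) {
    abort("within-group weights must be positive")
  }
  if (!is.null(sig$threshold)) {
    thr <- sig$threshold
    if (!thr$group %in% groups_used) {
      abort(paste0("threshold group '", thr$group, "' is not a signature group"))
    }
    if (thr$percentile < 0 || thr$percentile > 100) {
      abort("threshold percentile must be in [0, 100]")
    }
  }
  sig
}

#' All gene symbols a signature requires
#' @param sig A `signature_definition`.
#' @return Character vector of gene symbols.
#' @export
signature_genes <- function(sig) {
  unique(c(sig$targets$gene, names(sig$singleton_weights)))
}

#' Read a signature definition from a config file
#'
#' Signature configs are YAML files with fields `name`, `targets` (list of
#' `gene`/`group`/`weight` records), `group_weights`, `singleton_weights`,
#' and optional `threshold`. The shipped defaults are editable copies under
#' `system.file("extdata", package = "neoscore")`.
#'
#' @param path Path to a YAML signature config.
#' @return A validated `signature_definition`.
#' @export
read_signature <- function(path) {
  cfg <- yaml::read_yaml(path)
  targets <- if (length(cfg$targets) > 0L) {
    dplyr::bind_rows(lapply(cfg$targets, tibble::as_tibble))
  } else {
    NULL
  }
  signature_definition(name = cfg$name,
                       targets = targets,
                       group_weights = cfg$group_weights,
                       singleton_weights = cfg$singleton_weights,
                       threshold = cfg$threshold)
}

#' The 12-gene molecular score (microarray approximation)
#'
#' Eight target genes spanning two biological axes: proliferation (BIRC5,
#' UBE2C, DHCR7; positive weights) and ER signaling (AZGP1, IL6ST, MGP,
#' RBBP8, STC2; negative weights). Gene-level values enter the score directly
#' as a weighted sum; there is no group structure and no threshold. The
#' assay's normalization/control genes are not used here because matrices
#' arrive already between-array normalized.
#'
#' Because every downstream analysis standardizes scores within cohort, only
#' the sign pattern and relative magnitude of the weights matter; the shipped
#' weights are transcribed from the published algorithm and validated for
#' sign and structure.
#'
#' @return A `signature_definition`.
#' @export
ms12_signature <- function() {
  read_signature(system.file("extdata", "ms12.cfg", package = "neoscore",
                             mustWork = TRUE))
}

#' The 21-gene recurrence score (microarray approximation)
#'
#' Sixteen target genes organized into four gene groups — proliferation
#' (BIRC5, MKI67, MYBL2, CCNB1, AURKA), ER (ESR1, PGR, BCL2, SCUBE2; PGR and
#' ESR1 carry the published 1.2 and 0.8 within-group weights), HER2 (GRB7
#' 0.9, ERBB2 0.1), invasion (CTSL2, MMP11) — plus three singleton genes
#' (CD68, GSTM1, BAG1). Group scores are weighted means of member genes; the
#' proliferation group is floor-thresholded at the 80th percentile of
#' ER-positive patients before combination; groups and singletons combine
#' with the published weights (+1.04 proliferation, −0.34 ER, +0.47 HER2,
#' +0.10 invasion, +0.05 CD68, −0.08 GSTM1, −0.07 BAG1). The five
#' housekeeper genes of the RT-PCR assay are not used on normalized
#' microarray data.
#'
#' @return A `signature_definition`.
#' @export
rs21_signature <- function() {
  read_signature(system.file("extdata", "rs21.cfg", package = "neoscore",
                             mustWork = TRUE))
}

#' @export
print.signature_definition <- function(x, ...) {
  cat("<signature_definition> ", x$name, "\n", sep = "")
  n_grp <- length(x$group_weights)
  cat("  ", nrow(x$targets), " grouped genes in ", n_grp, " group(s); ",
      length(x$singleton_weights), " singleton(s)\n", sep = "")
  if (n_grp > 0L) {
    cat("  group weights: ",
        paste(sprintf("%s=%+.2f", names(x$group_weights), x$group_weights),
              collapse = ", "), "\n", sep = "")
  }
  if (length(x$singleton_weights) > 0L) {
    cat("  singletons: ",
        paste(sprintf("%s=%+.2f", names(x$singleton_weights),
                      x$singleton_weights), collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$threshold)) {
    cat("  floor: ", x$threshold$group, " group at p", x$threshold$percentile,
        " of ", x$threshold$reference, " samples\n", sep = "")
  }
  invisible(x)
}
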