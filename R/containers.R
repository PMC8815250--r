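#' Assemble a count matrix with sample metadata
#'
#' Bundles a gene-by-sample matrix of raw read counts with the per-sample
#' phenotype (sensitive `"S"` / resistant `"R"`), sequencing batch and cohort
#' labels that the differential-expression stage needs.
#'
#' @param counts Integer-like matrix, genes in rows, samples in columns.
#'   Row and column names are required and must be unique.
#' @param phenotype Character vector, one of `"S"` or `"R"` per sample.
#' @param batch Batch (sequencing run) label per sample. Defaults to a single
#'   batch.
#' @param cohort Optional cohort label per sample (e.g. `"discovery"`).
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (the matrix) and `meta` (a `data.frame` with `sample_id`, `phenotype`,
#'   `batch`, `cohort`).
#' @export
count_matrix <- function(counts, phenotype, batch = NULL, cohort = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  n <- ncol(counts)
  phenotype <- as.character(phenotype)
  if (length(phenotype) != n) stop("'phenotype' must have one entry per sample")
  if (!all(phenotype %in% c("S", "R")))
    stop("phenotype labels must be 'S' or 'R'")
  if (is.null(batch)) batch <- rep("batch1", n)
  if (length(batch) != n) stop("'batch' must have one entry per sample")
  if (is.null(cohort)) cohort <- rep(NA_character_, n)
  meta <- data.frame(sample_id = colnames(counts),
                     phenotype = phenotype,
                     batch = as.character(batch),
                     cohort = as.character(cohort),
                     stringsAsFactors = FALSE)
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d S, %d R; %d batch%s)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$meta$phenotype == "S"), sum(x$meta$phenotype == "R"),
              length(unique(x$meta$batch)),
              if (length(unique(x$meta$batch)) == 1) "" else "es"))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Assemble a Ct table
#'
#' Wraps a sample-by-gene matrix of qPCR cycle-threshold (Ct) values together
#' with the names of the reference genes used for normalization and the
#' per-sample phenotype. Missing measurements are `NA`.
#'
#' @param ct Numeric matrix, samples in rows, genes in columns (targets and
#'   reference genes together). Dimnames required.
#' @param ref_genes Character vector of reference-gene column names (e.g.
#'   `c("RPL13A", "RPL4", "GAPDH")`).
#' @param phenotype `"S"`/`"R"` per sample.
#'
#' @return Object of class `ct_table`: list with `ct`, `ref_genes`, `meta`.
#' @export
ct_table <- function(ct, ref_genes, phenotype) {
  ct <- as.matrix(ct)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("'ct' must have sample row names and gene column names")
  if (!all(ref_genes %in% colnames(ct)))
    stop("reference genes missing from Ct table: ",
         paste(setdiff(ref_genes, colnames(ct)), collapse = ", "))
  if (length(ref_genes) < 1) stop("at least one reference gene required")
  phenotype <- as.character(phenotype)
  if (length(phenotype) != nrow(ct)) stop("'phenotype' must match samples")
  if (!all(phenotype %in% c("S", "R"))) stop("phenotype labels must be 'S' or 'R'")
  meta <- data.frame(sample_id = rownames(ct), phenotype = phenotype,
                     stringsAsFactors = FALSE)
  structure(list(ct = ct, ref_genes = ref_genes, meta = meta),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d samples x %d genes (%d reference: %s)\n",
              nrow(x$ct), ncol(x$ct), length(x$ref_genes),
              paste(x$ref_genes, collapse = ", ")))
  invisible(x)
}
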