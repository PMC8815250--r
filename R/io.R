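#' Read a counts TSV plus sample sheet into a count matrix
#'
#' The counts file is tab-separated with gene ids in the first column and
#' one column per sample; the sample sheet is a CSV with columns
#' `sample_id`, `phenotype` (`S`/`R`) and optionally `batch` and `cohort`.
#'
#' @param counts_path Path to the counts TSV.
#' @param samples_path Path to the sample sheet CSV.
#' @return A [count_matrix] with samples ordered as in the counts file.
#' @export
read_counts <- function(counts_path, samples_path) {
  tab <- read.delim(counts_path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  sheet <- read.csv(samples_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "phenotype") %in% names(sheet)))
    stop("sample sheet needs 'sample_id' and 'phenotype' columns")
  idx <- match(colnames(m), sheet$sample_id)
  if (anyNA(idx)) stop("samples missing from sheet: ",
                       paste(colnames(m)[is.na(idx)], collapse = ", "))
  count_matrix(m, sheet$phenotype[idx],
               batch = if ("batch" %in% names(sheet)) sheet$batch[idx],
               cohort = if ("cohort" %in% names(sheet)) sheet$cohort[idx])
}

#' Write a count matrix and its sample sheet
#'
#' @param counts A [count_matrix].
#' @param counts_path,samples_path Output paths (TSV and CSV).
#' @return Invisibly, the two paths.
#' @export
write_counts <- function(counts, counts_path, samples_path) {
  stopifnot(inherits(counts, "count_matrix"))
  df <- data.frame(gene = rownames(counts$counts), counts$counts,
                   check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(counts$meta, samples_path, row.names = FALSE, quote = FALSE)
  invisible(c(counts_path, samples_path))
}

#' Read a wide Ct CSV plus sample sheet into a Ct table
#'
#' The Ct file is a CSV with sample ids in the first column and one column
#' per gene (targets and references together); empty cells are missing
#' measurements.
#'
#' @param ct_path Path to the Ct CSV.
#' @param samples_path Path to the sample sheet CSV (`sample_id`,
#'   `phenotype`).
#' @param ref_genes Reference-gene column names.
#' @return A [ct_table].
#' @export
read_ct <- function(ct_path, samples_path,
                    ref_genes = c("RPL13A", "RPL4", "GAPDH")) {
  tab <- read.csv(ct_path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- tab[[1]]
  sheet <- read.csv(samples_path, stringsAsFactors = FALSE)
  idx <- match(rownames(m), sheet$sample_id)
  if (anyNA(idx)) stop("samples missing from sheet")
  ct_table(m, ref_genes, sheet$phenotype[idx])
}

#' Write a Ct table and its sample sheet
#' @param ct A [ct_table].
#' @param ct_path,samples_path Output paths (both CSV).
#' @return Invisibly, the two paths.
#' @export
write_ct <- function(ct, ct_path, samples_path) {
  stopifnot(inherits(ct, "ct_table"))
  df <- data.frame(sample_id = rownames(ct$ct), ct$ct, check.names = FALSE)
  write.csv(df, ct_path, row.names = FALSE, quote = FALSE)
  write.csv(ct$meta, samples_path, row.names = FALSE, quote = FALSE)
  invisible(c(ct_path, samples_path))
}
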