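#' geNorm stability measure M
#'
#' For each candidate reference gene, the geNorm M value is the mean, over
#' all other candidates, of the standard deviation across samples of the
#' pairwise Ct difference. Lower M indicates a more stable reference.
#'
#' @param ct_refs Numeric matrix, samples x candidate reference genes
#'   (>= 3 candidates, >= 2 samples).
#' @return Named numeric vector of M values.
#' @export
genorm_m <- function(ct_refs) {
  ct_refs <- as.matrix(ct_refs)
  if (ncol(ct_refs) < 3) stop("geNorm needs at least 3 candidate reference genes")
  if (nrow(ct_refs) < 2) stop("geNorm needs at least 2 samples")
  p <- ncol(ct_refs)
  m <- numeric(p)
  for (g in seq_len(p)) {
    others <- setdiff(seq_len(p), g)
    m[g] <- mean(vapply(others, function(h) sd(ct_refs[, g] - ct_refs[, h]),
                        numeric(1)))
  }
  setNames(m, colnames(ct_refs))
}

#' Delta-Ct normalization against a geometric-mean reference
#'
#' For each sample, the reference value is the geometric mean of the
#' reference-gene Ct values and `dCt = Ct_target - gmeanref`. A sample with
#' any missing reference measurement gets `NA` for all its dCt values.
#'
#' @param ct A [ct_table].
#' @return Object of class `delta_ct`: list with `dct` (samples x target
#'   genes), `neg_dct` (its negation, the quantity used for testing),
#'   `gmeanref` per sample, `meta`.
#' @export
delta_ct <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  refs <- ct$ct[, ct$ref_genes, drop = FALSE]
  gmeanref <- exp(rowMeans(log(refs)))
  gmeanref[apply(refs, 1, function(r) any(!is.finite(r)))] <- NA_real_
  targets <- setdiff(colnames(ct$ct), ct$ref_genes)
  dct <- ct$ct[, targets, drop = FALSE] - gmeanref
  structure(list(dct = dct, neg_dct = -dct, gmeanref = gmeanref,
                 meta = ct$meta),
            class = "delta_ct")
}

#' @export
print.delta_ct <- function(x, ...) {
  cat(sprintf("delta_ct: %d samples x %d target genes\n",
              nrow(x$dct), ncol(x$dct)))
  invisible(x)
}

#' Fold change by the 2^-ddCt method
#'
#' `ddCt = mean dCt(R) - mean dCt(S)` per gene and `FC = 2^-ddCt`, so one
#' cycle less in the resistant group doubles the fold change.
#'
#' @param dct A `delta_ct` object.
#' @param baseline Baseline group (default `"S"`).
#' @return Named per-gene fold-change vector (resistant over sensitive when
#'   `baseline = "S"`).
#' @export
fold_change_ddct <- function(dct, baseline = "S") {
  stopifnot(inherits(dct, "delta_ct"))
  other <- setdiff(c("S", "R"), baseline)
  gb <- dct$meta$phenotype == baseline
  go <- dct$meta$phenotype == other
  if (!any(gb) || !any(go)) stop("both phenotype groups must be non-empty")
  ddct <- colMeans(dct$dct[go, , drop = FALSE], na.rm = TRUE) -
    colMeans(dct$dct[gb, , drop = FALSE], na.rm = TRUE)
  2^(-ddct)
}

#' Wilcoxon rank-sum test with Hodges-Lehmann shift
#'
#' Two-sided rank-sum comparison of resistant versus sensitive values
#' (conventionally on the negative-delta-Ct scale). The location effect is
#' the Hodges-Lehmann estimate — the median of all pairwise R minus S
#' differences — with a distribution-free confidence interval obtained by
#' inverting the rank-sum test. The exact null distribution is used when
#' there are no ties and `n_S * n_R <= 10000`; otherwise the normal
#' approximation with tie correction.
#'
#' @param x_S,x_R Numeric vectors (>= 2 values each): sensitive and resistant
#'   group values.
#' @param conf Confidence level (default 0.95).
#' @return List of class `shift_test`: `p`, `shift`, `ci_low`, `ci_high`,
#'   `exact` (logical), `degenerate` (all values identical).
#' @export
wilcoxon_shift <- function(x_S, x_R, conf = 0.95) {
  x_S <- x_S[is.finite(x_S)]; x_R <- x_R[is.finite(x_R)]
  if (length(x_S) < 2 || length(x_R) < 2)
    stop("each group needs at least 2 finite values")
  diffs <- as.vector(outer(x_R, x_S, "-"))
  shift <- median(diffs)
  if (length(unique(c(x_S, x_R))) == 1) {
    return(structure(list(p = 1, shift = 0, ci_low = 0, ci_high = 0,
                          exact = TRUE, degenerate = TRUE),
                     class = "shift_test"))
  }
  ties <- anyDuplicated(c(x_S, x_R)) > 0
  use_exact <- !ties && length(x_S) * length(x_R) <= 10000
  wt <- suppressWarnings(
    wilcox.test(x_R, x_S, conf.int = TRUE, conf.level = conf,
                exact = use_exact, correct = !use_exact))
  ci <- unname(wt$conf.int)
  structure(list(p = unname(wt$p.value), shift = shift,
                 ci_low = ci[1], ci_high = ci[2],
                 exact = use_exact, degenerate = FALSE),
            class = "shift_test")
}

#' @export
print.shift_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): p = %.4g, HL shift = %.3f [%.3f, %.3f]\n",
              if (x$exact) "exact" else "normal approx.",
              x$p, x$shift, x$ci_low, x$ci_high))
  invisible(x)
}

#' Cross-platform concordance regression
#'
#' Simple linear regression of standardized qPCR negative-delta-Ct values on
#' standardized RNA-seq counts for one phenotype group. Because both inputs
#' are standardized, the fitted slope equals the Pearson correlation of the
#' unstandardized pairs; the slope's 95 percent confidence interval and
#' p-value quantify the cross-platform agreement.
#'
#' @param rnaseq_std,qpcr_std Paired numeric vectors (length >= 3), each
#'   standardized to mean 0 and SD 1.
#' @param conf Confidence level.
#' @return List: `slope`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
concordance_regression <- function(rnaseq_std, qpcr_std, conf = 0.95) {
  if (length(rnaseq_std) != length(qpcr_std) || length(rnaseq_std) < 3)
    stop("inputs must be paired with length >= 3")
  if (sd(rnaseq_std) == 0 || sd(qpcr_std) == 0)
    stop("zero variance in an input vector")
  fit <- lm(qpcr_std ~ rnaseq_std)
  # a perfect fit (y = +/- x) is legitimate here; silence lm's complaint
  sm <- suppressWarnings(summary(fit))$coefficients
  ci <- suppressWarnings(confint(fit, "rnaseq_std", level = conf))
  list(slope = unname(sm["rnaseq_std", "Estimate"]),
       ci_low = ci[1], ci_high = ci[2],
       p = unname(sm["rnaseq_std", "Pr(>|t|)"]),
       n = length(rnaseq_std))
}

#' Validation-stage per-gene qPCR statistics
#'
#' For every target gene with at least `min_n` measured values per group,
#' runs [wilcoxon_shift()] on the negative-delta-Ct values (resistant vs
#' sensitive), adds BH-adjusted p-values and the 2^-ddCt fold change.
#'
#' @param ct A [ct_table].
#' @param conf Confidence level for the shift interval.
#' @param min_n Minimum measured values per group for a gene to be tested
#'   (default 2).
#' @return Object of class `qpcr_validation`: list with `table` (gene, n_S,
#'   n_R, p, padj, shift, ci_low, ci_high, fc_ddct) and `delta` (the
#'   `delta_ct` object).
#' @export
qpcr_validate <- function(ct, conf = 0.95, min_n = 2) {
  stopifnot(inherits(ct, "ct_table"))
  d <- delta_ct(ct)
  fc <- fold_change_ddct(d)
  is_S <- d$meta$phenotype == "S"
  genes <- colnames(d$neg_dct)
  rows <- lapply(genes, function(g) {
    xs <- d$neg_dct[is_S, g]; xr <- d$neg_dct[!is_S, g]
    xs <- xs[is.finite(xs)]; xr <- xr[is.finite(xr)]
    if (length(xs) < min_n || length(xr) < min_n)
      return(data.frame(gene = g, n_S = length(xs), n_R = length(xr),
                        p = NA_real_, shift = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, stringsAsFactors = FALSE))
    st <- wilcoxon_shift(xs, xr, conf)
    data.frame(gene = g, n_S = length(xs), n_R = length(xr),
               p = st$p, shift = st$shift, ci_low = st$ci_low,
               ci_high = st$ci_high, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$padj <- bh_adjust(tab$p)
  tab$fc_ddct <- unname(fc[tab$gene])
  tab <- tab[, c("gene", "n_S", "n_R", "p", "padj", "shift",
                 "ci_low", "ci_high", "fc_ddct")]
  structure(list(table = tab, delta = d), class = "qpcr_validation")
}

#' @export
print.qpcr_validation <- function(x, ...) {
  sig <- sum(x$table$p < 0.05, na.rm = TRUE)
  cat(sprintf("qPCR validation: %d genes tested, %d with Wilcoxon p < 0.05\n",
              sum(!is.na(x$table$p)), sig))
  invisible(x)
}

#' @export
summary.qpcr_validation <- function(object, ...) {
  ord <- order(object$table$p)
  print(head(object$table[ord, ], 10), row.names = FALSE, digits = 4)
  invisible(object)
}
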