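#' Filter genes with low average raw counts
#'
#' Removes genes whose mean raw count across all samples is below
#' `min_mean` (strictly less than; a gene averaging exactly `min_mean` is
#' kept). Gene order is preserved.
#'
#' @param counts A [count_matrix].
#' @param min_mean Threshold on the mean raw count (default 50).
#' @return A [count_matrix] restricted to retained genes.
#' @export
filter_low_counts <- function(counts, min_mean = 50) {
  stopifnot(inherits(counts, "count_matrix"))
  keep <- rowMeans(counts$counts) >= min_mean
  out <- counts
  out$counts <- counts$counts[keep, , drop = FALSE]
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for each gene positive in every sample,
#' the ratio of its count to its across-sample geometric mean is formed, and
#' the size factor of a sample is the median of these ratios. Genes with any
#' zero count are excluded from the reference set.
#'
#' @param counts A [count_matrix] or bare counts matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  pos <- rowSums(m <= 0) == 0
  if (!any(pos))
    stop("cannot compute size factors: no gene has positive counts in all samples")
  logm <- log(m[pos, , drop = FALSE])
  loggeo <- rowMeans(logm)
  apply(exp(sweep(logm, 1, loggeo)), 2, median)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1. Thin validating wrapper used by every stage of the workflow
#' so that all adjusted p-values share one definition.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Method-of-moments dispersion with trend shrinkage
#'
#' Per-gene NB dispersion estimated on size-factor-normalized counts via
#' `(var - mean * mean(1/sf)) / mean^2`, floored at `1e-8`, then averaged
#' 50/50 with a fitted mean-dispersion trend `a0 + a1 / mean` (the classical
#' gamma-family parametric trend) to stabilize the small-sample estimates.
#'
#' @param counts A [count_matrix].
#' @param sf Size factors (default computed by [size_factors()]).
#' @return Named per-gene dispersion vector.
#' @export
estimate_dispersion <- function(counts, sf = size_factors(counts)) {
  stopifnot(inherits(counts, "count_matrix"))
  if (ncol(counts$counts) < 3) stop("dispersion estimation needs >= 3 samples")
  floor_d <- 1e-8
  norm <- sweep(counts$counts, 2, sf, "/")
  m <- rowMeans(norm)
  v <- apply(norm, 1, var)
  mom <- (v - m * mean(1 / sf)) / m^2          # can be negative by chance
  mom[!is.finite(mom)] <- floor_d
  raw <- pmax(mom, floor_d)

  # trend fitted on the unfloored estimates so flooring does not bias it up
  use <- is.finite(mom) & m > 0
  if (sum(use) >= 10) {
    fit <- lm(mom[use] ~ I(1 / m[use]))
    a <- pmax(coef(fit), 0)
    trend <- pmax(a[1] + a[2] / m, floor_d)
  } else {
    trend <- rep(max(median(raw), floor_d), length(raw))
  }
  out <- 0.5 * raw + 0.5 * trend
  setNames(pmax(out, floor_d), rownames(counts$counts))
}

#' Empirical-Bayes batch adjustment of a log-expression matrix
#'
#' Removes additive (location) and multiplicative (scale) batch effects from
#' a gene-by-sample matrix on the `log2(normalized count + 1)` scale.
#' Per-gene batch means and variances are estimated, shrunk toward their
#' across-gene moments with parametric empirical-Bayes priors (normal prior
#' for locations, inverse-gamma for scales), and removed; the grand mean and
#' pooled variance structure are restored. A single batch is returned
#' unchanged; if any batch has fewer than 2 samples the adjustment falls back
#' to location-only removal with a warning.
#'
#' @param log_expr Numeric matrix, genes x samples.
#' @param batch Batch labels, one per sample.
#' @return Adjusted matrix with the same dimensions and dimnames.
#' @export
batch_adjust <- function(log_expr, batch) {
  log_expr <- as.matrix(log_expr)
  batch <- factor(batch)
  if (ncol(log_expr) != length(batch)) stop("one batch label per sample required")
  if (nlevels(batch) < 2) return(log_expr)

  n_b <- table(batch)
  location_only <- any(n_b < 2)
  if (location_only)
    warning("batch with a single sample: falling back to location-only adjustment")

  bm <- sapply(levels(batch), function(b)
    rowMeans(log_expr[, batch == b, drop = FALSE]))  # genes x batches
  alpha <- as.vector(bm %*% (as.numeric(n_b) / ncol(log_expr)))
  resid <- log_expr - bm[, as.integer(batch), drop = FALSE]
  sigma2 <- rowSums(resid^2) / ncol(log_expr)

  flat <- sigma2 < 1e-12                      # noiseless genes: pure shift removal
  out <- log_expr
  if (any(flat)) {
    out[flat, ] <- resid[flat, , drop = FALSE] + alpha[flat]
  }
  act <- which(!flat)
  if (length(act) == 0) return(out)

  s <- sqrt(sigma2[act])
  z <- (log_expr[act, , drop = FALSE] - alpha[act]) / s

  z_adj <- z
  for (b in levels(batch)) {
    jb <- which(batch == b)
    gamma_hat <- rowMeans(z[, jb, drop = FALSE])
    if (location_only || length(jb) < 2) {
      z_adj[, jb] <- z[, jb, drop = FALSE] - gamma_hat
      next
    }
    delta2_hat <- apply(z[, jb, drop = FALSE], 1, var)
    # parametric EB priors from across-gene moments
    g_bar <- mean(gamma_hat); t2 <- var(gamma_hat)
    d_bar <- mean(delta2_hat); s2_d <- var(delta2_hat)
    if (!is.finite(t2) || t2 <= 0) t2 <- 1e-8
    if (!is.finite(s2_d) || s2_d <= 0) s2_d <- 1e-8
    a_pr <- (2 * s2_d + d_bar^2) / s2_d
    b_pr <- (d_bar * s2_d + d_bar^3) / s2_d
    nb <- length(jb)
    gamma_star <- (nb * t2 * gamma_hat + delta2_hat * g_bar) /
      (nb * t2 + delta2_hat)
    ss <- rowSums((z[, jb, drop = FALSE] - gamma_star)^2)
    delta2_star <- (b_pr + 0.5 * ss) / (nb / 2 + a_pr - 1)
    delta2_star <- pmax(delta2_star, 1e-8)
    z_adj[, jb] <- (z[, jb, drop = FALSE] - gamma_star) / sqrt(delta2_star)
  }
  out[act, ] <- z_adj * s + alpha[act]
  out
}

#' Negative-binomial Wald test for differential expression
#'
#' Per gene, fits an NB generalized linear model with log link,
#' `log(sf)` offset and phenotype (S/R) as the single covariate, with the
#' dispersion plugged in. The Wald statistic is the phenotype coefficient
#' over its standard error, with a two-sided standard-normal p-value;
#' adjusted p-values are Benjamini-Hochberg. The coefficient is estimated on
#' the natural-log scale and converted, so `log2FC` is in log2 units
#' (resistant over sensitive).
#'
#' @param counts A [count_matrix] with both phenotypes present (>= 2 samples
#'   each).
#' @param sf Size factors.
#' @param dispersion Per-gene dispersion vector (see [estimate_dispersion()]).
#' @return `data.frame` with one row per gene: `gene`, `baseMean`, `log2FC`,
#'   `se` (log2 scale), `wald`, `p`, `padj`, `flag` (`"ok"`, `"all_zero"` or
#'   `"no_fit"`).
#' @export
nb_wald_test <- function(counts, sf = size_factors(counts),
                         dispersion = estimate_dispersion(counts, sf)) {
  stopifnot(inherits(counts, "count_matrix"))
  pheno <- factor(counts$meta$phenotype, levels = c("S", "R"))
  if (any(table(pheno) < 2)) stop("need >= 2 samples per phenotype group")
  genes <- rownames(counts$counts)
  dispersion <- rep_len(dispersion, length(genes))
  off <- log(sf)
  base_mean <- rowMeans(sweep(counts$counts, 2, sf, "/"))

  res <- data.frame(gene = genes, baseMean = base_mean,
                    log2FC = 0, se = NA_real_, wald = 0, p = 1,
                    padj = NA_real_, flag = "ok",
                    stringsAsFactors = FALSE, row.names = NULL)
  ln2 <- log(2)
  for (i in seq_along(genes)) {
    y <- counts$counts[i, ]
    if (all(y == 0)) { res$flag[i] <- "all_zero"; next }
    fit <- tryCatch(
      suppressWarnings(glm(y ~ pheno + offset(off),
                           family = MASS::negative.binomial(
                             theta = 1 / max(dispersion[i], 1e-8)))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { res$flag[i] <- "no_fit"; next }
    # dispersion = 1: the NB variance function already carries the
    # overdispersion; summary.glm would otherwise rescale the SEs by a
    # noisy Pearson factor
    sm <- summary(fit, dispersion = 1)$coefficients
    if (nrow(sm) < 2) { res$flag[i] <- "no_fit"; next }
    b <- sm["phenoR", "Estimate"]; se <- sm["phenoR", "Std. Error"]
    res$log2FC[i] <- b / ln2
    res$se[i] <- se / ln2
    res$wald[i] <- b / se
    res$p[i] <- 2 * pnorm(-abs(b / se))
  }
  res$padj <- bh_adjust(res$p)
  res
}

#' Two-tier DEG selection
#'
#' Applies the study's two significance tiers to a differential-expression
#' table: tier 1 (`padj < padj1` and `|log2FC| > lfc`) and the stricter
#' tier 2 panel (`padj < padj2` and `|log2FC| > lfc`). All inequalities are
#' strict. Direction is the sign of `log2FC` (resistant over sensitive).
#'
#' @param results `data.frame` from [nb_wald_test()].
#' @param padj1,padj2 Adjusted-p thresholds for the two tiers (defaults 0.05
#'   and 5e-3).
#' @param lfc Absolute log2-fold-change threshold (default 1).
#' @return List of class `deg_selection`: `tier1`, `tier2` (gene vectors,
#'   tier2 a subset of tier1 when `padj2 <= padj1`), `direction` (named
#'   `"up"`/`"down"` for tier-1 genes), and the thresholds used.
#' @export
select_degs <- function(results, padj1 = 0.05, padj2 = 5e-3, lfc = 1.0) {
  stopifnot(all(c("gene", "log2FC", "padj") %in% names(results)))
  ok <- !is.na(results$padj)
  t1 <- ok & results$padj < padj1 & abs(results$log2FC) > lfc
  t2 <- ok & results$padj < padj2 & abs(results$log2FC) > lfc
  structure(list(
    tier1 = results$gene[t1],
    tier2 = results$gene[t2],
    direction = setNames(ifelse(results$log2FC[t1] > 0, "up", "down"),
                         results$gene[t1]),
    thresholds = c(padj1 = padj1, padj2 = padj2, lfc = lfc)),
    class = "deg_selection")
}

#' @export
print.deg_selection <- function(x, ...) {
  cat(sprintf("DEG selection: %d tier-1 (padj < %g), %d tier-2 (padj < %g), |log2FC| > %g\n",
              length(x$tier1), x$thresholds["padj1"],
              length(x$tier2), x$thresholds["padj2"], x$thresholds["lfc"]))
  invisible(x)
}

#' Discovery-stage differential expression analysis
#'
#' Full count-based pipeline: low-count filtering, median-of-ratios size
#' factors, optional empirical-Bayes batch adjustment (performed on
#' `log2(normalized + 1)` values and mapped back to adjusted counts),
#' trend-shrunk dispersion estimation, per-gene NB Wald tests and two-tier
#' DEG selection.
#'
#' @param counts A [count_matrix].
#' @param min_mean Low-count filter threshold (mean raw count).
#' @param adjust_batch Apply batch adjustment when more than one batch is
#'   present (default `TRUE`).
#' @param padj1,padj2,lfc Selection thresholds, see [select_degs()].
#' @return Object of class `chemosig_de`: list with `results` (the per-gene
#'   table), `selection`, `size_factors`, `dispersion`, `n_filtered`,
#'   `params`.
#' @export
de_analysis <- function(counts, min_mean = 50, adjust_batch = TRUE,
                        padj1 = 0.05, padj2 = 5e-3, lfc = 1.0) {
  stopifnot(inherits(counts, "count_matrix"))
  n_in <- nrow(counts$counts)
  fc <- filter_low_counts(counts, min_mean)
  if (nrow(fc$counts) == 0) stop("no genes pass the low-count filter")
  sf <- size_factors(fc)

  work <- fc
  if (adjust_batch && length(unique(fc$meta$batch)) > 1) {
    lg <- log2(sweep(fc$counts, 2, sf, "/") + 1)
    adj <- batch_adjust(lg, fc$meta$batch)
    newc <- pmax(round(sweep(2^adj - 1, 2, sf, "*")), 0)
    work$counts <- newc
    sf <- size_factors(work)
  }
  disp <- estimate_dispersion(work, sf)
  res <- nb_wald_test(work, sf, disp)
  sel <- select_degs(res, padj1, padj2, lfc)
  structure(list(results = res, selection = sel, size_factors = sf,
                 dispersion = disp,
                 n_filtered = c(input = n_in, kept = nrow(fc$counts)),
                 params = list(min_mean = min_mean, adjust_batch = adjust_batch,
                               padj1 = padj1, padj2 = padj2, lfc = lfc)),
            class = "chemosig_de")
}

#' @export
print.chemosig_de <- function(x, ...) {
  cat(sprintf("NB Wald differential expression: %d/%d genes tested (mean count >= %g)\n",
              x$n_filtered["kept"], x$n_filtered["input"], x$params$min_mean))
  print(x$selection)
  invisible(x)
}

#' @export
summary.chemosig_de <- function(object, n = 10, ...) {
  ord <- order(object$results$padj, object$results$p)
  cat("Top genes by adjusted p-value:\n")
  print(head(object$results[ord, c("gene", "baseMean", "log2FC", "p", "padj")], n),
        row.names = FALSE, digits = 4)
  invisible(object)
}
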