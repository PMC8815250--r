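# four-parameter logistic: decreasing in c for hill > 0
four_pl <- function(conc, top, bottom, hill, ic50) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Nonlinear least squares on log concentration for the model
#' `v(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill)`.
#' Initialization: `top` at the maximum response, `bottom` at the minimum,
#' `ic50` at the concentration whose mean response is nearest the midpoint,
#' `hill = 1`. The IC50 is bounded within `[min(conc)/10, max(conc)*10]`
#' and the Hill slope within `[0.1, 10]`. The reported IC50 is the relative
#' EC50 (the curve's inflection parameter). A response range below
#' `min_range` (flat curve) or a failed fit yields `converged = FALSE` and
#' no IC50.
#'
#' @param conc Concentrations (uM), >= 4 distinct positive values (with any
#'   number of replicates each).
#' @param viability Percent viability, same length as `conc`.
#' @param min_range Minimum response range for a meaningful fit (default 10,
#'   percent units).
#' @return Object of class `fit_4pl`: `top`, `bottom`, `hill`, `ic50`,
#'   `rss`, `converged`, plus the data.
#' @export
fit_4pl <- function(conc, viability, min_range = 10) {
  if (length(conc) != length(viability)) stop("conc and viability lengths differ")
  ok <- is.finite(conc) & is.finite(viability) & conc > 0
  conc <- conc[ok]; viability <- viability[ok]
  if (length(unique(conc)) < 4)
    stop("need at least 4 distinct positive concentrations")
  out <- structure(list(top = NA_real_, bottom = NA_real_, hill = NA_real_,
                        ic50 = NA_real_, rss = NA_real_, converged = FALSE,
                        conc = conc, viability = viability),
                   class = "fit_4pl")
  mean_by_c <- tapply(viability, conc, mean)
  rng <- max(mean_by_c) - min(mean_by_c)
  if (rng < min_range) return(out)

  mid <- (max(mean_by_c) + min(mean_by_c)) / 2
  cs <- as.numeric(names(mean_by_c))
  lic0 <- log(cs[which.min(abs(mean_by_c - mid))])
  lo <- c(top = -Inf, bottom = -Inf, hill = 0.1, lic50 = log(min(conc) / 10))
  hi <- c(top = Inf, bottom = Inf, hill = 10, lic50 = log(max(conc) * 10))
  # several starts: a start sitting on an (almost) zero-residual solution can
  # abort the Gauss-Newton machinery, so mildly displaced starts are retried
  starts <- list(
    list(top = max(mean_by_c), bottom = min(mean_by_c), hill = 1, lic50 = lic0),
    list(top = max(mean_by_c) * 0.95, bottom = min(mean_by_c) + 2,
         hill = 1.3, lic50 = lic0 + 0.5),
    list(top = max(mean_by_c) + 5, bottom = min(mean_by_c) - 5,
         hill = 0.7, lic50 = median(log(cs))))
  fit <- NULL
  for (st in starts) {
    st$lic50 <- min(max(st$lic50, lo["lic50"]), hi["lic50"])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        viability ~ bottom + (top - bottom) / (1 + exp(hill * (log(conc) - lic50))),
        start = st, lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(out)
  cf <- coef(fit)
  out$top <- unname(cf["top"]); out$bottom <- unname(cf["bottom"])
  out$hill <- unname(cf["hill"]); out$ic50 <- exp(unname(cf["lic50"]))
  out$rss <- sum(residuals(fit)^2)
  out$converged <- TRUE
  out
}

#' @export
print.fit_4pl <- function(x, ...) {
  if (!x$converged) {
    cat("4PL fit: not converged (flat or degenerate curve), no IC50\n")
  } else {
    cat(sprintf("4PL fit: IC50 = %.4g uM, hill = %.3g, top = %.1f, bottom = %.1f (RSS %.3g)\n",
                x$ic50, x$hill, x$top, x$bottom, x$rss))
  }
  invisible(x)
}

#' @export
coef.fit_4pl <- function(object, ...) {
  c(top = object$top, bottom = object$bottom, hill = object$hill,
    ic50 = object$ic50)
}

#' @export
predict.fit_4pl <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$conc else
    if (is.list(newdata)) newdata$conc else newdata
  if (!object$converged) return(rep(NA_real_, length(conc)))
  four_pl(conc, object$top, object$bottom, object$hill, object$ic50)
}

#' @export
residuals.fit_4pl <- function(object, ...) {
  object$viability - predict(object)
}

#' @export
plot.fit_4pl <- function(x, ...) {
  plot(x$conc, x$viability, log = "x", xlab = "concentration (uM)",
       ylab = "viability (%)", ...)
  if (x$converged) {
    grid_c <- exp(seq(log(min(x$conc)), log(max(x$conc)), length.out = 100))
    lines(grid_c, predict(x, grid_c))
    abline(v = x$ic50, lty = 2)
  }
  invisible(x)
}

#' Resistance call against the plasma Css/Cmax threshold
#'
#' A cell line is called resistant to a drug when its fitted IC50 is
#' strictly higher than the clinically achievable plasma concentration
#' (Css/Cmax); an IC50 equal to the threshold is called sensitive. Also
#' returns the waterfall-plot quantity `log10(ic50) - log10(threshold)`.
#'
#' @param fit A converged [fit_4pl()] (or a bare positive IC50 value).
#' @param css_cmax Plasma threshold (uM).
#' @return List: `ic50`, `threshold`, `call` (`"resistant"`/`"sensitive"`,
#'   `NA` if the fit did not converge), `log10_ratio`.
#' @export
classify_resistance <- function(fit, css_cmax) {
  ic50 <- if (inherits(fit, "fit_4pl")) {
    if (!fit$converged) return(list(ic50 = NA_real_, threshold = css_cmax,
                                    call = NA_character_,
                                    log10_ratio = NA_real_))
    fit$ic50
  } else as.numeric(fit)
  if (!is.finite(ic50) || ic50 <= 0) stop("IC50 must be positive")
  list(ic50 = ic50, threshold = css_cmax,
       call = if (ic50 > css_cmax) "resistant" else "sensitive",
       log10_ratio = log10(ic50) - log10(css_cmax))
}

#' Fit and classify a whole dose-response panel
#'
#' Runs [fit_4pl()] and [classify_resistance()] for every cell line / drug
#' combination in a long-format viability table.
#'
#' @param dr `data.frame` with columns `cell_line`, `drug`, `conc_uM`,
#'   `viability_pct` (replicates as extra rows).
#' @param thresholds `data.frame` with columns `drug`, `css_cmax_uM`.
#' @return `data.frame`: `cell_line`, `drug`, `ic50`, `hill`, `converged`,
#'   `threshold`, `call`, `log10_ratio`.
#' @export
dose_response_panel <- function(dr, thresholds) {
  stopifnot(all(c("cell_line", "drug", "conc_uM", "viability_pct") %in% names(dr)),
            all(c("drug", "css_cmax_uM") %in% names(thresholds)))
  combos <- unique(dr[, c("cell_line", "drug")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- dr[dr$cell_line == combos$cell_line[i] & dr$drug == combos$drug[i], ]
    f <- fit_4pl(sub$conc_uM, sub$viability_pct)
    thr <- thresholds$css_cmax_uM[match(combos$drug[i], thresholds$drug)]
    cl <- classify_resistance(f, thr)
    data.frame(cell_line = combos$cell_line[i], drug = combos$drug[i],
               ic50 = cl$ic50, hill = f$hill, converged = f$converged,
               threshold = thr, call = cl$call, log10_ratio = cl$log10_ratio,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Label cell lines as resistant or sensitive models
#'
#' A line is a resistant model when it is called resistant to every drug
#' (`rule = "both"`, the default, matching a panel where the two resistant
#' lines resisted both agents) or to at least one drug (`rule = "either"`).
#'
#' @param calls Output of [dose_response_panel()].
#' @param rule `"both"` or `"either"`.
#' @return Named character vector, `"resistant"`/`"sensitive"` per cell line.
#' @export
resistance_labels <- function(calls, rule = c("both", "either")) {
  rule <- match.arg(rule)
  agg <- tapply(calls$call == "resistant", calls$cell_line,
                if (rule == "both") all else any)
  setNames(ifelse(agg, "resistant", "sensitive"), names(agg))
}

#' Randomization test for group differences in cell-line expression
#'
#' Per gene, the statistic is the difference of group means (resistant minus
#' sensitive) and the two-sided p-value is the proportion of group-label
#' assignments whose absolute statistic is at least the observed one. All
#' `choose(n, n_resistant)` assignments are enumerated when there are at
#' most `max_exhaustive`; otherwise `n_perm` random assignments are drawn
#' and the observed labelling is included in both numerator and denominator.
#'
#' @param expr Genes x cell-lines numeric matrix (e.g. negative delta-Ct).
#' @param labels `"resistant"`/`"sensitive"` per cell line (>= 2 each).
#' @param n_perm Random assignments when not exhaustive (default 10000).
#' @param seed Seed for the sampled mode.
#' @param max_exhaustive Enumeration limit (default 10000 assignments).
#' @return `data.frame`: `gene`, `effect` (resistant - sensitive mean),
#'   `p`, `exhaustive`.
#' @export
randomization_group_test <- function(expr, labels, n_perm = 10000, seed = 1,
                                     max_exhaustive = 10000) {
  expr <- as.matrix(expr)
  labels <- as.character(labels)
  if (ncol(expr) != length(labels)) stop("one label per cell line required")
  if (!all(labels %in% c("resistant", "sensitive")))
    stop("labels must be 'resistant' or 'sensitive'")
  n_r <- sum(labels == "resistant"); n_s <- sum(labels == "sensitive")
  if (n_r < 2 || n_s < 2) stop("need >= 2 cell lines per group")
  n <- ncol(expr)
  exhaustive <- choose(n, n_r) <= max_exhaustive
  assign_sets <- if (exhaustive) combn(n, n_r, simplify = FALSE) else {
    set.seed(as.integer(seed))
    lapply(seq_len(n_perm), function(i) sample.int(n, n_r))
  }
  obs_idx <- which(labels == "resistant")
  eps <- 1e-12
  gene_ids <- rownames(expr)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%d", seq_len(nrow(expr)))
  res <- data.frame(gene = gene_ids, effect = NA_real_, p = NA_real_,
                    exhaustive = exhaustive, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(expr))) {
    v <- expr[i, ]
    tot <- sum(v)
    stat <- function(idx) sum(v[idx]) / n_r - (tot - sum(v[idx])) / n_s
    obs <- stat(obs_idx)
    perm <- vapply(assign_sets, stat, numeric(1))
    if (exhaustive) {
      p <- mean(abs(perm) >= abs(obs) - eps)
    } else {
      p <- (1 + sum(abs(perm) >= abs(obs) - eps)) / (1 + n_perm)
    }
    res$effect[i] <- obs
    res$p[i] <- p
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Patient / cell-line concordance evidence levels
#'
#' Combines the patient-level Wilcoxon results with the cell-line
#' randomization test: evidence level 2 requires cell-line `p <= alpha` and
#' the same deregulation direction as in patients; level 1 means patient
#' evidence only; genes missing from the cell-line table stay at level <= 1.
#'
#' @param patient `data.frame` with columns `gene`, `shift`, `p` (patient
#'   Wilcoxon results, shift = R - S on negative delta-Ct).
#' @param cell `data.frame` with columns `gene`, `effect`, `p` (from
#'   [randomization_group_test()]).
#' @param alpha Significance level (default 0.05). Patient significance is
#'   strict (`p < alpha`); cell-line significance is `p <= alpha` so that
#'   the minimum attainable exhaustive p on a small panel still counts.
#' @return `data.frame`: `gene`, `patient_dir`, `patient_sig`, `cell_dir`,
#'   `cell_p`, `cell_sig`, `evidence` (0, 1 or 2).
#' @export
concordance_with_patients <- function(patient, cell, alpha = 0.05) {
  stopifnot(all(c("gene", "shift", "p") %in% names(patient)),
            all(c("gene", "effect", "p") %in% names(cell)))
  m <- match(patient$gene, cell$gene)
  patient_sig <- !is.na(patient$p) & patient$p < alpha
  patient_dir <- ifelse(patient$shift > 0, "up", "down")
  cell_p <- cell$p[m]
  cell_dir <- ifelse(cell$effect[m] > 0, "up", "down")
  cell_sig <- !is.na(cell_p) & cell_p <= alpha
  evidence <- integer(nrow(patient))
  evidence[patient_sig] <- 1L
  both <- patient_sig & cell_sig & !is.na(cell_dir) & cell_dir == patient_dir
  evidence[both] <- 2L
  data.frame(gene = patient$gene, patient_dir = patient_dir,
             patient_sig = patient_sig, cell_dir = cell_dir,
             cell_p = cell_p, cell_sig = cell_sig, evidence = evidence,
             stringsAsFactors = FALSE)
}
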