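#' Simulate an RNA-seq count cohort with planted differential genes
#'
#' Generates a gene-by-sample matrix of negative-binomial counts for a
#' two-group (sensitive/resistant) cohort, with optional sequencing batches
#' and a recorded ground truth. The NB parameterization is
#' `Var = mu + dispersion * mu^2`. Gene base abundances are drawn
#' log-uniformly and normalized so that `depth` is the expected library size;
#' the expected count for gene g in sample j is
#' `depth * q_g * 2^(lfc_g * I[R]) * 2^(shift_gb)` where `shift_gb` is a
#' gene-by-batch offset drawn `N(0, batch_sd)` on the log2 scale.
#'
#' Half of the planted differential genes are up-regulated in the resistant
#' group and half down (ties to up). Batches are assigned round-robin within
#' each phenotype group so batch is balanced with respect to phenotype.
#'
#' @param n_genes Number of genes.
#' @param n_S,n_R Samples in the sensitive and resistant groups. Defaults
#'   mirror the discovery cohort (7 vs 7).
#' @param n_deg Number of planted differentially expressed genes.
#' @param lfc_magnitude Absolute log2 fold change (resistant over sensitive)
#'   of planted genes.
#' @param dispersion NB dispersion, scalar or per-gene vector.
#' @param depth Expected per-sample library size (total counts).
#' @param n_batches Number of sequencing batches.
#' @param batch_sd SD (log2 units) of the gene-by-batch location shifts;
#'   0 means no batch effect.
#' @param seed Integer RNG seed; the same seed reproduces the output exactly.
#' @param truth Optional `sim_truth` from a previous call: reuses its gene
#'   abundances, planted effects and dispersions (e.g. to draw a validation
#'   cohort governed by the discovery cohort's ground truth) while drawing
#'   fresh counts under `seed`.
#'
#' @return A list with elements `counts` (a [count_matrix]) and `truth`
#'   (class `sim_truth`: `deg_genes`, per-gene `lfc`, `dispersion`,
#'   `q` base abundances, `batch_shift` matrix, `seed`).
#' @export
simulate_counts <- function(n_genes, n_S = 7, n_R = 7, n_deg = 0,
                            lfc_magnitude = 2, dispersion = 0.1,
                            depth = 1e6, n_batches = 1, batch_sd = 0,
                            seed = 1, truth = NULL) {
  if (n_genes < 1 || n_S < 1 || n_R < 1 || n_batches < 1 || depth <= 0)
    stop("sizes and depth must be positive")
  if (n_deg > n_genes) stop("n_deg must not exceed n_genes")
  if (any(dispersion <= 0)) stop("dispersion must be > 0")
  set.seed(as.integer(seed))

  genes <- sprintf("gene%05d", seq_len(n_genes))
  n <- n_S + n_R
  samples <- c(sprintf("S%02d", seq_len(n_S)), sprintf("R%02d", seq_len(n_R)))
  phenotype <- rep(c("S", "R"), c(n_S, n_R))
  # balanced batch assignment within each group
  batch <- paste0("batch", c(rep_len(seq_len(n_batches), n_S),
                             rep_len(seq_len(n_batches), n_R)))

  if (!is.null(truth)) {
    stopifnot(inherits(truth, "sim_truth"), length(truth$lfc) == n_genes)
    q <- truth$q
    lfc <- unname(truth$lfc)
    deg_genes <- truth$deg_genes
    disp <- unname(truth$dispersion)
  } else {
    # base abundances: log-uniform over ~4 orders of magnitude, sum to 1
    q <- 2^runif(n_genes, min = 0, max = 14)
    q <- q / sum(q)

    lfc <- rep(0, n_genes)
    deg_genes <- character(0)
    if (n_deg > 0) {
      idx <- sample.int(n_genes, n_deg)
      deg_genes <- genes[idx]
      n_up <- ceiling(n_deg / 2)                     # ties to up
      sign <- rep(c(1, -1), c(n_up, n_deg - n_up))
      lfc[idx] <- sign * lfc_magnitude
    }
    disp <- rep_len(dispersion, n_genes)
  }

  shift <- matrix(0, n_genes, n_batches,
                  dimnames = list(genes, paste0("batch", seq_len(n_batches))))
  if (n_batches > 1 && batch_sd > 0)
    shift[] <- rnorm(n_genes * n_batches, 0, batch_sd)

  mu <- matrix(0, n_genes, n)
  for (j in seq_len(n)) {
    fc <- if (phenotype[j] == "R") 2^lfc else rep(1, n_genes)
    mu[, j] <- depth * q * fc * 2^shift[, match(batch[j], colnames(shift))]
  }
  counts <- matrix(rnbinom(n_genes * n, mu = mu, size = 1 / disp),
                   n_genes, n, dimnames = list(genes, samples))

  truth <- structure(list(deg_genes = deg_genes,
                          lfc = setNames(lfc, genes),
                          dispersion = setNames(disp, genes),
                          q = q,
                          batch_shift = shift,
                          seed = as.integer(seed)),
                     class = "sim_truth")
  list(counts = count_matrix(counts, phenotype, batch),
       truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d planted DEGs, seed %d\n",
              length(x$deg_genes), x$seed))
  invisible(x)
}

#' Simulate a qPCR Ct table from simulated counts
#'
#' Maps size-factor-normalized expression of a gene panel to cycle-threshold
#' values through `Ct = intercept - slope * log2(norm + 0.5) + offset + noise`
#' so that higher expression yields lower Ct. A per-sample loading offset
#' (`N(0, sample_offset_sd)`) is shared by targets and reference genes and is
#' therefore removed by delta-Ct normalization. Reference genes are generated
#' with no group effect and low variance (noise SD `noise_sd / 2`).
#'
#' @param truth `sim_truth` from [simulate_counts()] (used for the seed
#'   bookkeeping; may be `NULL`).
#' @param counts A [count_matrix].
#' @param panel Character vector of target genes, must exist in `counts`.
#' @param ref_genes Names for the simulated reference genes (not in `counts`).
#' @param noise_sd Gaussian measurement noise on target Ct values (cycles).
#' @param intercept,slope Calibration of the expression-to-Ct map; `slope > 0`.
#' @param sample_offset_sd SD of the per-sample loading offset (cycles).
#' @param seed Integer RNG seed.
#'
#' @return A [ct_table] with columns `panel` then `ref_genes`.
#' @export
simulate_ct <- function(truth, counts, panel,
                        ref_genes = c("RPL13A", "RPL4", "GAPDH"),
                        noise_sd = 0.25, intercept = 30, slope = 1,
                        sample_offset_sd = 0.5, seed = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  if (slope <= 0) stop("'slope' must be positive")
  missing <- setdiff(panel, rownames(counts$counts))
  if (length(missing))
    stop("panel genes absent from counts: ", paste(missing, collapse = ", "))
  if (length(intersect(panel, ref_genes)))
    stop("reference genes must be disjoint from the target panel")
  set.seed(as.integer(seed))

  sf <- size_factors(counts)
  norm <- sweep(counts$counts[panel, , drop = FALSE], 2, sf, "/")
  n <- ncol(counts$counts)
  off <- rnorm(n, 0, sample_offset_sd)

  ct_t <- intercept - slope * log2(t(norm) + 0.5) +
    off + matrix(rnorm(n * length(panel), 0, noise_sd), n, length(panel))
  ref_base <- rnorm(length(ref_genes), 20, 0.5)
  ct_r <- matrix(rep(ref_base, each = n), n, length(ref_genes)) +
    off + matrix(rnorm(n * length(ref_genes), 0, noise_sd / 2),
                 n, length(ref_genes))
  ct <- cbind(ct_t, ct_r)
  dimnames(ct) <- list(colnames(counts$counts), c(panel, ref_genes))
  ct_table(ct, ref_genes, counts$meta$phenotype)
}

#' Simulate dose-response viability tables for a cell-line panel
#'
#' Viability follows the four-parameter logistic curve
#' `v(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill)` with additive
#' Gaussian noise, measured in triplicate at each concentration as in a
#' standard cytotoxicity assay.
#'
#' @param panel `data.frame` with columns `cell_line`, `drug`, `ic50_uM`
#'   (true IC50s, uM, positive).
#' @param hill Hill slope (> 0 gives a decreasing curve).
#' @param top,bottom Upper/lower viability asymptotes (percent).
#' @param conc Strictly positive, sorted concentration grid (uM); the default
#'   is the standard half-log serial dilution spanning 0.001 to 100 uM.
#' @param n_rep Replicates per concentration (default 3, triplicate).
#' @param noise_sd Measurement noise SD (percent viability).
#' @param seed Integer RNG seed.
#'
#' @return `data.frame` with columns `cell_line`, `drug`, `conc_uM`,
#'   `replicate`, `viability_pct`.
#' @export
simulate_dose_response <- function(panel, hill = 1, top = 100, bottom = 0,
                                   conc = 10^seq(-3, 2, by = 0.5),
                                   n_rep = 3, noise_sd = 5, seed = 1) {
  stopifnot(is.data.frame(panel),
            all(c("cell_line", "drug", "ic50_uM") %in% names(panel)))
  if (any(panel$ic50_uM <= 0)) stop("true IC50s must be positive")
  if (any(conc <= 0) || is.unsorted(conc)) stop("'conc' must be positive and sorted")
  set.seed(as.integer(seed))
  out <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    v <- four_pl(rep(conc, each = n_rep), top, bottom, hill, panel$ic50_uM[i])
    out[[i]] <- data.frame(
      cell_line = panel$cell_line[i], drug = panel$drug[i],
      conc_uM = rep(conc, each = n_rep),
      replicate = rep(seq_len(n_rep), times = length(conc)),
      viability_pct = v + rnorm(length(v), 0, noise_sd),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Default synthetic cell-line panel
#'
#' A seven-line primary-culture panel with two lines resistant to both drugs,
#' matching the study design: resistant lines get true IC50s above the plasma
#' Css/Cmax threshold, sensitive lines below.
#'
#' @param drugs Drug names.
#' @param css_cmax Named numeric, plasma Css/Cmax threshold per drug (uM).
#' @return List with `panel` (cell_line, drug, ic50_uM), `thresholds`
#'   (drug, css_cmax_uM) and `resistant_lines`.
#' @export
default_cell_panel <- function(drugs = c("cisplatin", "paclitaxel"),
                               css_cmax = c(cisplatin = 14.4, paclitaxel = 4.3)) {
  lines <- sprintf("OVGEM-%d", 1:7)
  resistant <- lines[c(3, 6)]
  rows <- list()
  for (d in drugs) {
    thr <- css_cmax[[d]]
    ic50 <- ifelse(lines %in% resistant, thr * 4, thr / 8)
    rows[[d]] <- data.frame(cell_line = lines, drug = d, ic50_uM = ic50,
                            stringsAsFactors = FALSE)
  }
  list(panel = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       thresholds = data.frame(drug = drugs,
                               css_cmax_uM = unname(css_cmax[drugs]),
                               stringsAsFactors = FALSE),
       resistant_lines = resistant)
}

#' Simulate a feature matrix for classifier benchmarking
#'
#' Generates subject-by-gene Gaussian features (on the negative-delta-Ct
#' scale) with a chosen number of informative genes whose group means differ
#' by `effect` within-group standard deviations, plus pure-noise genes.
#'
#' @param n_S,n_R Group sizes; defaults mirror the validation cohort
#'   (25 sensitive, 19 resistant).
#' @param n_informative,n_noise Numbers of informative and noise genes.
#' @param effect Standardized group-mean difference of informative genes
#'   (resistant minus sensitive, in within-group SD units); signs alternate
#'   so roughly half the informative genes are up in the resistant group.
#' @param seed Integer RNG seed.
#'
#' @return List with `x` (matrix, subjects x genes; informative genes first,
#'   named `inf*`/`noise*`), `labels` (factor S/R) and `informative` (names).
#' @export
simulate_signature_features <- function(n_S = 25, n_R = 19,
                                        n_informative = 4, n_noise = 6,
                                        effect = 1.5, seed = 1) {
  if (n_S < 2 || n_R < 2) stop("need at least two subjects per group")
  set.seed(as.integer(seed))
  n <- n_S + n_R
  p <- n_informative + n_noise
  x <- matrix(rnorm(n * p), n, p)
  genes <- c(if (n_informative) sprintf("inf%02d", seq_len(n_informative)),
             if (n_noise) sprintf("noise%02d", seq_len(n_noise)))
  colnames(x) <- genes
  rownames(x) <- c(sprintf("S%02d", seq_len(n_S)), sprintf("R%02d", seq_len(n_R)))
  labels <- factor(rep(c("S", "R"), c(n_S, n_R)), levels = c("S", "R"))
  if (n_informative > 0) {
    dir <- rep_len(c(1, -1), n_informative)
    for (g in seq_len(n_informative))
      x[labels == "R", g] <- x[labels == "R", g] + dir[g] * effect
  }
  list(x = x, labels = labels,
       informative = head(genes, n_informative))
}
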