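make_cm <- function(m, pheno = NULL, batch = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(pheno)) pheno <- rep(c("S", "R"), length.out = ncol(m))
  count_matrix(m, pheno, batch)
}

test_that("low-count filter removes means below 50 and keeps the boundary", {
  m <- rbind(g_low = rep(49, 4), g_edge = rep(50, 4), g_hi = rep(500, 4))
  colnames(m) <- paste0("s", 1:4)
  out <- filter_low_counts(make_cm(m))
  expect_identical(rownames(out$counts), c("g_edge", "g_hi"))
  empty <- filter_low_counts(make_cm(m), min_mean = 1e6)
  expect_equal(nrow(empty$counts), 0)
})

test_that("median-of-ratios size factors match hand-derived values", {
  # sample2 = 2 x sample1: per-gene geomean = c*sqrt(2), ratios 1/sqrt2, sqrt2
  m <- cbind(s1 = c(10, 20, 40), s2 = c(20, 40, 80))
  rownames(m) <- paste0("g", 1:3)
  sf <- size_factors(make_cm(m, c("S", "R")))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  # identical samples: all factors 1
  m2 <- cbind(s1 = c(5, 9), s2 = c(5, 9), s3 = c(5, 9))
  rownames(m2) <- c("a", "b")
  expect_equal(unname(size_factors(make_cm(m2, c("S", "S", "R")))), c(1, 1, 1))
  # single sample: ratio to itself
  m3 <- matrix(c(3, 8), dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(size_factors(m3)), 1)
})

test_that("size factors obey order-invariance and scaling properties", {
  set.seed(1)
  m <- matrix(rpois(60, 100) + 1, 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  sf <- size_factors(m)
  perm <- sample(nrow(m))
  expect_equal(size_factors(m[perm, ]), sf)
  # scaling one sample by c scales its factor by c relative to the others
  # (the per-gene geometric means absorb a factor c^(1/n))
  m2 <- m; m2[, 3] <- m2[, 3] * 4
  sf2 <- size_factors(m2)
  expect_equal(unname(sf2[3] / sf2[1]), unname(4 * sf[3] / sf[1]))
  expect_equal(unname(sf2[2] / sf2[1]), unname(sf[2] / sf[1]))
  expect_true(all(sf > 0))
  # all-zero reference set is an error
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2,
                                   dimnames = list(c("a", "b"), c("x", "y")))),
               "size factors")
})

test_that("BH adjustment matches the step-up oracle and hand examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.05), 0.05)
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  p <- sort(runif(15))
  expect_true(!is.unsorted(bh_adjust(p)))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("dispersion estimates track the simulation truth", {
  sim_p <- simulate_counts(600, 7, 7, dispersion = 1e-6, seed = 21)
  fcp <- filter_low_counts(sim_p$counts)
  dp <- estimate_dispersion(fcp)
  expect_lt(median(dp), 0.05)                    # near-Poisson data
  sim_n <- simulate_counts(600, 7, 7, dispersion = 0.4, seed = 22)
  fcn <- filter_low_counts(sim_n$counts)
  dn <- estimate_dispersion(fcn)
  expect_gt(median(dn), 0.2)
  expect_lt(median(dn), 0.6)
  # constant gene collapses to the floor-dominated estimate
  m <- rbind(flat = rep(100, 6), other = c(60, 80, 100, 120, 140, 160))
  colnames(m) <- paste0("s", 1:6)
  d <- estimate_dispersion(make_cm(m))
  expect_lt(d["flat"], d["other"])
})

test_that("batch adjustment removes planted location shifts", {
  # single batch: identity
  m <- matrix(rnorm(40), 4, 10)
  expect_identical(batch_adjust(m, rep("b1", 10)), m)
  # two batches differing by a constant gene-wise shift, no noise
  base <- matrix(rep(c(5, 8, 11), 4), 3, 4)
  shifted <- cbind(base, base + c(2, -1, 3))
  rownames(shifted) <- paste0("g", 1:3)
  colnames(shifted) <- paste0("s", 1:8)
  adj <- batch_adjust(shifted, rep(c("b1", "b2"), each = 4))
  bm1 <- rowMeans(adj[, 1:4]); bm2 <- rowMeans(adj[, 5:8])
  expect_lt(max(abs(bm1 - bm2)), 1e-8)
  # singleton batch falls back to location-only with a warning
  expect_warning(batch_adjust(matrix(rnorm(30), 3, 10),
                              c(rep("b1", 9), "b2")),
                 "single sample")
})

test_that("batch adjustment restores DE calibration on batch-affected nulls", {
  sim <- simulate_counts(800, 7, 7, n_deg = 0, n_batches = 2, batch_sd = 1,
                         seed = 31)
  de_adj <- de_analysis(sim$counts, adjust_batch = TRUE)
  frac_adj <- mean(de_adj$results$p < 0.05)
  expect_gt(frac_adj, 0.01)
  expect_lt(frac_adj, 0.09)
})

test_that("NB Wald test handles degenerate genes and trivial BH", {
  m <- rbind(zero = rep(0, 8), ok = rpois(8, 200))
  colnames(m) <- paste0("s", 1:8)
  cm <- make_cm(m, rep(c("S", "R"), each = 4))
  res <- nb_wald_test(cm, sf = rep(1, 8), dispersion = c(0.1, 0.1))
  expect_equal(res$flag[res$gene == "zero"], "all_zero")
  expect_equal(res$p[res$gene == "zero"], 1)
  expect_equal(res$log2FC[res$gene == "zero"], 0)
  # single-gene BH: padj equals p
  single <- nb_wald_test(make_cm(m[2, , drop = FALSE],
                                 rep(c("S", "R"), each = 4)),
                         sf = rep(1, 8), dispersion = 0.1)
  expect_equal(single$padj, single$p)
  expect_error(nb_wald_test(make_cm(m, c("S", rep("R", 7)))), ">= 2 samples")
})

test_that("planted log2 fold changes are recovered within half a unit", {
  hits <- 0; total <- 0
  for (s in 1:5) {
    sim <- simulate_counts(400, 7, 7, n_deg = 20, lfc_magnitude = 2,
                           dispersion = 0.05, seed = 100 + s)
    fc <- filter_low_counts(sim$counts)
    res <- nb_wald_test(fc)
    up <- intersect(names(which(sim$truth$lfc == 2)), res$gene)
    est <- res$log2FC[match(up, res$gene)]
    hits <- hits + sum(abs(est - 2) <= 0.5)
    total <- total + length(up)
  }
  expect_gte(hits / total, 0.9)
})

test_that("DEG selection applies strict two-tier thresholds", {
  res <- data.frame(
    gene = c("a", "b", "c", "d"),
    log2FC = c(1.2, 1.0, -1.5, 0.2),
    padj = c(0.004, 0.004, 0.01, 0.001))
  sel <- select_degs(res)
  expect_identical(sel$tier2, "a")                 # strict on both thresholds
  expect_identical(sel$tier1, c("a", "c"))         # b excluded: |lfc| not > 1
  expect_identical(unname(sel$direction[c("a", "c")]), c("up", "down"))
  expect_true(all(sel$tier2 %in% sel$tier1))
})

test_that("tier2 is nested in tier1 for any threshold pair with padj2 <= padj1", {
  set.seed(7)
  res <- data.frame(gene = paste0("g", 1:200),
                    log2FC = rnorm(200, sd = 1.5),
                    padj = runif(200))
  for (pair in list(c(0.1, 0.01), c(0.05, 0.05), c(0.2, 0.001))) {
    sel <- select_degs(res, padj1 = pair[1], padj2 = pair[2])
    expect_true(all(sel$tier2 %in% sel$tier1))
  }
})

test_that("counts and sample sheets round-trip through TSV/CSV", {
  sim <- simulate_counts(30, 3, 3, n_batches = 2, batch_sd = 0.5, seed = 2)
  td <- withr::local_tempdir()
  write_counts(sim$counts, file.path(td, "c.tsv"), file.path(td, "s.csv"))
  back <- read_counts(file.path(td, "c.tsv"), file.path(td, "s.csv"))
  expect_equal(back$counts, sim$counts$counts)
  expect_equal(back$meta$phenotype, sim$counts$meta$phenotype)
  expect_equal(back$meta$batch, sim$counts$meta$batch)
})
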