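sep_data <- function(n_per = 20, d = 10, gap = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = gap), n_per, d))
  rownames(x) <- sprintf("s%02d", seq_len(2 * n_per))
  colnames(x) <- sprintf("g%02d", seq_len(d))
  list(x = x, labels = factor(rep(c("S", "R"), each = n_per),
                              levels = c("S", "R")))
}

test_that("two-class Brier score semantics make the discard rule attainable", {
  # brier = 2 (1 - p_true)^2 on a probability grid, range [0, 2]
  p_true <- seq(0, 1, by = 0.01)
  brier <- (p_true - 1)^2 + ((1 - p_true) - 0)^2
  expect_equal(brier, 2 * (1 - p_true)^2)
  expect_true(all(brier >= 0 & brier <= 2))
  expect_true(all(diff(brier) < 0))                     # monotone in p_true
  # discard iff brier > 1 iff p_true < 1 - 1/sqrt(2)
  cut <- 1 - 1 / sqrt(2)
  expect_equal(brier > 1, p_true < cut)
  # spot values: confident wrong (0.2 for truth) and maximal uncertainty
  expect_equal(2 * (1 - 0.2)^2, 1.28)
  expect_equal(2 * (1 - 0.5)^2, 0.5)
})

test_that("brier_filter excludes strictly above the threshold", {
  sc <- data.frame(subject = c("a", "b", "c"),
                   brier = c(0, 1, 1.0001))
  expect_identical(brier_filter(sc), c("a", "b"))
})

test_that("cross-validation predicts each subject exactly once", {
  d <- sep_data(10, d = 5, gap = 0, seed = 2)
  sc <- cv_predict(d$x, d$labels, rf_config(n_trees = 50, seed = 3))
  expect_setequal(sc$subject, rownames(d$x))
  expect_equal(anyDuplicated(sc$subject), 0)
  expect_equal(sort(unique(sc$fold)), 1:4)
  expect_true(all(sc$p_R >= 0 & sc$p_R <= 1))
  expect_equal(sc$brier, 2 * (1 - ifelse(sc$label == "R", sc$p_R, 1 - sc$p_R))^2)
  few <- c(1:3, 11:13)                  # 3 per class, fewer than k_folds = 4
  expect_error(cv_predict(d$x[few, ], d$labels[few], rf_config(k_folds = 4)),
               "k_folds")
})

test_that("well-separated clouds are classified perfectly out of fold", {
  d <- sep_data(20, d = 10, gap = 10, seed = 4)
  sc <- cv_predict(d$x, d$labels, rf_config(n_trees = 200, seed = 5))
  acc <- mean((sc$p_R > 0.5) == (sc$label == "R"))
  expect_equal(acc, 1)
  expect_true(all(sc$brier < 1))
})

test_that("permuted labels yield chance-level accuracy", {
  accs <- sapply(1:10, function(s) {
    d <- sep_data(20, d = 10, gap = 10, seed = 100)
    set.seed(s)
    labs <- sample(d$labels)
    sc <- cv_predict(d$x, labs, rf_config(n_trees = 100, seed = s))
    mean((sc$p_R > 0.5) == (labs == "R"))
  })
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("importance separates signal from noise features", {
  # one informative gene among noise: top MDA and MDG
  set.seed(6)
  fs <- simulate_signature_features(20, 20, n_informative = 1, n_noise = 5,
                                    effect = 3, seed = 6)
  imp <- rf_importance(fs$x, fs$labels, rf_config(n_trees = 500, seed = 7))
  tab <- imp$importance
  expect_equal(tab$gene[which.max(tab$mda)], "inf01")
  expect_equal(tab$gene[which.max(tab$mdg)], "inf01")
  # a pure-noise feature's MDA is centred at zero across seeds
  noise_mda <- sapply(1:10, function(s) {
    fs <- simulate_signature_features(15, 15, n_informative = 1, n_noise = 3,
                                      effect = 3, seed = 200 + s)
    im <- rf_importance(fs$x, fs$labels, rf_config(n_trees = 300, seed = s))
    im$importance$mda[im$importance$gene == "noise01"]
  })
  expect_lt(abs(mean(noise_mda)), 2 * sd(noise_mda) / sqrt(length(noise_mda)) + 0.5)
})

test_that("duplicating a noise gene leaves the signal gene on top", {
  for (s in 1:3) {
    fs <- simulate_signature_features(15, 15, n_informative = 1, n_noise = 3,
                                      effect = 3, seed = 300 + s)
    x2 <- cbind(fs$x, noise_dup = fs$x[, "noise01"])
    imp <- rf_importance(x2, fs$labels, rf_config(n_trees = 300, seed = s))
    expect_equal(imp$importance$gene[which.max(imp$importance$mda)], "inf01")
  }
})

test_that("importance normalization is an exact min-max map", {
  expect_equal(normalize_importance(c(0, 1)), c(0, 100))
  v <- c(3, 7, 5, 11)
  expect_equal(normalize_importance(2.5 * v - 4), normalize_importance(v))
  expect_equal(range(normalize_importance(v)), c(0, 100))
  expect_error(normalize_importance(rep(2, 4)), "all values equal")
  expect_error(normalize_importance(3), "at least 2")
})

test_that("ranking score averages the two percent columns", {
  expect_equal(ranking_score(96.49, 100.00), 98.245)
  expect_equal(ranking_score(6.94, 0.00), 3.47)
  expect_equal(ranking_score(0, 0), 0)
  expect_error(ranking_score(120, 50), "\\[0, 100\\]")
})

test_that("confusion metrics match hand-computed values and identities", {
  perfect <- confusion_metrics(10, 10, 0, 0)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$f1, 100)
  expect_equal(perfect$fpr, 0)
  even <- confusion_metrics(1, 1, 1, 1)
  expect_equal(even$sensitivity, 50)
  expect_equal(even$specificity, 50)
  expect_equal(even$accuracy, 50)
  cm <- confusion_metrics(15, 24, 1, 2)
  expect_equal(cm$fpr + cm$specificity / 100, 1)
  expect_equal(cm$fnr + cm$sensitivity / 100, 1)
  # F1 is the harmonic mean of precision and sensitivity
  expect_equal(cm$f1, 2 / (1 / cm$precision + 1 / cm$sensitivity))
  # undefined metrics are NA, not zero
  none <- confusion_metrics(0, 5, 0, 0)
  expect_true(is.na(none$sensitivity))
  expect_true(is.na(none$precision))
  expect_error(confusion_metrics(-1, 2, 3, 4), "non-negative")
})

test_that("the signature fit is deterministic and keeps separable structure", {
  fs <- simulate_signature_features(16, 16, n_informative = 2, n_noise = 4,
                                    effect = 3, seed = 8)
  cfg <- rf_config(n_trees = 200, seed = 9)
  a <- rf_signature(fs$x, fs$labels, cfg)
  b <- rf_signature(fs$x, fs$labels, cfg)
  expect_identical(a$importance, b$importance)
  expect_identical(a$scores, b$scores)
  expect_true(all(c("inf01", "inf02") %in% head(a$importance$gene, 2)))
  expect_true(all(a$importance$rank_score >= 0 & a$importance$rank_score <= 100))
  expect_equal(min(a$importance$pct_mda), 0)
  expect_equal(max(a$importance$pct_mda), 100)
  # subjects flagged excluded are exactly those above the Brier threshold
  expect_identical(a$scores$excluded, a$scores$brier > 1)
})

test_that("Brier filtering does not degrade held-out accuracy on average", {
  pre <- numeric(6); post <- numeric(6)
  for (s in 1:6) {
    fs <- simulate_signature_features(25, 19, n_informative = 4, n_noise = 6,
                                      effect = 1.5, seed = 400 + s)
    fit <- rf_signature(fs$x, fs$labels,
                        rf_config(n_trees = 300, seed = s))
    pre[s] <- fit$confusion_pre$accuracy
    post[s] <- fit$confusion$accuracy
  }
  # expectation-level trend: finite-sample tolerance of two percentage points
  expect_gte(mean(post), mean(pre) - 2)
})
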