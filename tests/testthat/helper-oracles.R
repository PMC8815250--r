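# Independent brute-force oracles used to check the package's statistics.

# step-up BH by direct computation of the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# exact two-sided rank-sum p by full enumeration of label assignments
wilcox_p_oracle <- function(x_S, x_R) {
  n_s <- length(x_S); n_r <- length(x_R)
  pooled <- c(x_S, x_R)
  r <- rank(pooled)
  w_obs <- sum(r[(n_s + 1):(n_s + n_r)]) - n_r * (n_r + 1) / 2
  sets <- combn(n_s + n_r, n_r, simplify = FALSE)
  w_all <- vapply(sets, function(idx) sum(r[idx]) - n_r * (n_r + 1) / 2,
                  numeric(1))
  lo <- mean(w_all <= w_obs)
  hi <- mean(w_all >= w_obs)
  min(1, 2 * min(lo, hi))
}

# Hodges-Lehmann shift by explicit double loop
hl_oracle <- function(x_S, x_R) {
  d <- numeric(0)
  for (r in x_R) for (s in x_S) d <- c(d, r - s)
  median(d)
}

# two-sided Fisher exact p by enumeration with choose() arithmetic:
# sum of probabilities of tables as or less probable than the observed one
fisher_p_oracle <- function(k, q, s, N) {
  support <- max(0, q + s - N):min(q, s)
  pr <- vapply(support, function(i)
    choose(s, i) * choose(N - s, q - i) / choose(N, q), numeric(1))
  obs <- pr[support == k]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# geNorm M by direct transcription of the definition
genorm_oracle <- function(ct) {
  p <- ncol(ct)
  out <- numeric(p)
  for (g in seq_len(p)) {
    sds <- numeric(0)
    for (h in seq_len(p)) {
      if (h == g) next
      sds <- c(sds, sd(ct[, g] - ct[, h]))
    }
    out[g] <- mean(sds)
  }
  out
}

# difference-of-means randomization p by explicit enumeration
perm_p_oracle <- function(v, labels) {
  idx_r <- which(labels == "resistant")
  n_r <- length(idx_r)
  stat <- function(idx) mean(v[idx]) - mean(v[-idx])
  obs <- stat(idx_r)
  all_sets <- combn(length(v), n_r, simplify = FALSE)
  mean(vapply(all_sets, function(i) abs(stat(i)) >= abs(obs) - 1e-12,
              logical(1)))
}
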