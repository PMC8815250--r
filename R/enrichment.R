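#' Read a GMT gene-set file
#'
#' Each line of a GMT file is `set name <tab> description <tab> member genes
#' ...`. Gene symbols are upper-cased; duplicate members within a set are
#' dropped with a warning.
#'
#' @param path Path to the GMT file.
#' @return Object of class `gene_set_collection`: list with `sets` (named
#'   list of character vectors), `description` (named), `source` (the path).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d: expected at least 3 tab-separated fields", i))
    genes <- toupper(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate members in set '%s' dropped", f[1]))
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  structure(list(sets = sets, description = desc, source = path),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (%s)\n", length(x$sets),
              x$source))
  invisible(x)
}

# two-sided Fisher exact p: total probability of hypergeometric tables with
# point probability <= that of the observed table (with fisher.test's
# relative tolerance)
fisher_two_sided_p <- function(k, q, s, N) {
  support <- max(0, q + s - N):min(q, s)
  d <- dhyper(support, s, N - s, q)
  sum(d[d <= d[support == k] * (1 + 1e-7)])
}

#' Fisher-exact over-representation analysis
#'
#' Tests each gene set for over-representation of a query gene list against
#' a background universe. Per set: the overlap count, a two-sided exact
#' p-value (hypergeometric mass of tables as or more extreme), the sample
#' odds ratio with Haldane 0.5 correction when a 2x2 cell is zero, a normal
#' approximation 95 percent CI on the log odds ratio, BH adjustment across
#' sets, and the combined score of [combined_score()].
#'
#' @param query Character vector of query gene symbols (non-empty; outside
#'   the background they are dropped with a warning).
#' @param collection A [read_gmt()] collection (set members outside the
#'   background are ignored).
#' @param background Character vector: the gene universe (e.g. all genes
#'   measured after the low-count filter).
#' @param conf Confidence level for the odds-ratio interval.
#' @return `data.frame`, one row per set, sorted by combined score:
#'   `set`, `k`, `set_size`, `odds_ratio`, `or_low`, `or_high`, `p`, `padj`,
#'   `combined`, `overlap` (comma-separated genes).
#' @export
fisher_ora <- function(query, collection, background, conf = 0.95) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(toupper(query))
  background <- unique(toupper(background))
  if (length(query) == 0) stop("empty query gene list")
  drop <- setdiff(query, background)
  if (length(drop)) {
    warning(sprintf("%d query genes outside the background dropped", length(drop)))
    query <- intersect(query, background)
    if (length(query) == 0) stop("no query genes in the background")
  }
  N <- length(background); q <- length(query)
  zc <- qnorm(1 - (1 - conf) / 2)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- intersect(collection$sets[[nm]], background)
    s <- length(set)
    hits <- intersect(query, set)
    k <- length(hits)
    a <- k; b <- q - k; cc <- s - k; d <- N - q - s + k
    p <- if (s == 0) 1 else fisher_two_sided_p(k, q, s, N)
    corr <- if (any(c(a, b, cc, d) == 0)) 0.5 else 0
    or <- (a + corr) * (d + corr) / ((b + corr) * (cc + corr))
    se <- sqrt(1 / (a + corr) + 1 / (b + corr) + 1 / (cc + corr) + 1 / (d + corr))
    cs <- combined_score(p, k, q, s, N)
    data.frame(set = nm, k = k, set_size = s, odds_ratio = or,
               or_low = exp(log(or) - zc * se), or_high = exp(log(or) + zc * se),
               p = p, padj = NA_real_, combined = cs,
               overlap = paste(hits, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out[order(-out$combined), ]
}

#' Combined enrichment score
#'
#' `combined = -log10(p) * z`, where `z` standardizes the overlap count
#' under the hypergeometric null given the 2x2 margins:
#' `E[k] = q*s/N`, `Var[k] = q*s/N * (N-s)/N * (N-q)/(N-1)`.
#' Degenerate margins (zero variance) yield `NA`.
#'
#' @param p Fisher p-value in `(0, 1]`.
#' @param k Observed overlap count.
#' @param query_size,set_size,background_size The 2x2 margins.
#' @return The combined score (0 when `p = 1` or `k` equals its
#'   expectation).
#' @export
combined_score <- function(p, k, query_size, set_size, background_size) {
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
  N <- background_size; q <- query_size; s <- set_size
  ek <- q * s / N
  vk <- q * s / N * ((N - s) / N) * ((N - q) / (N - 1))
  if (!is.finite(vk) || vk <= 0) return(NA_real_)
  (-log10(p)) * (k - ek) / sqrt(vk)
}
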