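#' Default pipeline configuration
#'
#' Per-stage settings for [run_pipeline()]. Thresholds default to the
#' study's printed values: low-count filter at mean 50, DEG tiers at
#' adjusted p < 0.05 and < 5e-3 with |log2FC| > 1, Wilcoxon alpha 0.05,
#' 4-fold cross-validation with 1000 trees and a Brier discard threshold
#' of 1, randomization alpha 0.05. Cohort sizes mirror the study design
#' (7 + 7 discovery, 25 + 19 validation, 7 cell lines).
#'
#' @param outdir Output directory for stage tables and the run report.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("chemosig_run_"), seed = 1) {
  structure(list(
    outdir = outdir, seed = as.integer(seed),
    simulate = list(enabled = TRUE, n_genes = 2000, n_S = 7, n_R = 7,
                    n_deg = 50, lfc_magnitude = 2, dispersion = 0.1,
                    depth = 1e6, n_batches = 1, batch_sd = 0,
                    val_n_S = 25, val_n_R = 19, ct_noise_sd = 0.25),
    de = list(enabled = TRUE, min_mean = 50, padj1 = 0.05, padj2 = 5e-3,
              lfc = 1, counts = NULL, samples = NULL),
    qpcr = list(enabled = TRUE, alpha = 0.05, max_panel = 42,
                ref_genes = c("RPL13A", "RPL4", "GAPDH"),
                ct = NULL, samples = NULL),
    rf = list(enabled = TRUE, k_folds = 4, n_trees = 1000,
              brier_threshold = 1.0),
    cellline = list(enabled = TRUE, n_perm = 10000, rule = "both",
                    effect = 1.5, dr = NULL, thresholds = NULL, expr = NULL),
    ora = list(enabled = FALSE, gmt = NULL, alpha = 0.05)),
    class = "pipeline_config")
}

# overlay user values (list or YAML path) onto the defaults, recursively
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the end-to-end signature-discovery workflow
#'
#' Orchestrates the stages in study order: synthetic cohort generation (or
#' user-supplied input files), count-based differential expression, qPCR
#' validation statistics, Brier-filtered random-forest signature ranking,
#' cell-line dose-response and concordance analysis, and optional
#' over-representation analysis. Each stage writes its tables under
#' `outdir` and the machine-readable run report (JSON) records per-stage
#' parameters, input file checksums, gene counts at each filter and the
#' final ranked signature. Reruns with the same configuration produce an
#' identical report.
#'
#' @param config A [pipeline_config()], a nested list overriding parts of
#'   it, or the path to a YAML file with the same structure.
#' @return The run report, invisibly (also written to
#'   `outdir/run_report.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "pipeline_config"))
    config <- merge_config(pipeline_config(), config)
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed, stages = list())
  fail <- function(stage, msg) stop(sprintf("pipeline stage '%s' failed: %s",
                                            stage, msg), call. = FALSE)
  path <- function(...) file.path(cfg$outdir, ...)

  ## ---- simulate -------------------------------------------------------
  truth <- NULL; discovery <- NULL; validation <- NULL
  if (isTRUE(cfg$simulate$enabled)) {
    s <- cfg$simulate
    sim <- simulate_counts(s$n_genes, s$n_S, s$n_R, s$n_deg, s$lfc_magnitude,
                           s$dispersion, s$depth, s$n_batches, s$batch_sd,
                           seed = cfg$seed)
    truth <- sim$truth; discovery <- sim$counts
    validation <- simulate_counts(s$n_genes, s$val_n_S, s$val_n_R,
                                  seed = cfg$seed + 1L, truth = truth)$counts
    write_counts(discovery, path("discovery_counts.tsv"),
                 path("discovery_samples.csv"))
    jsonlite::write_json(
      list(deg_genes = truth$deg_genes,
           lfc = as.list(truth$lfc[truth$deg_genes]), seed = truth$seed),
      path("truth.json"), auto_unbox = TRUE, digits = NA)
    report$stages$simulate <- list(
      params = s[setdiff(names(s), "enabled")],
      n_genes = s$n_genes, n_deg = length(truth$deg_genes))
  }

  ## ---- differential expression ---------------------------------------
  de <- NULL
  if (isTRUE(cfg$de$enabled)) {
    d <- cfg$de
    if (is.null(discovery)) {
      if (is.null(d$counts) || is.null(d$samples))
        fail("de", "no simulated cohort and no counts/samples paths supplied")
      discovery <- read_counts(d$counts, d$samples)
    }
    de <- de_analysis(discovery, min_mean = d$min_mean,
                      padj1 = d$padj1, padj2 = d$padj2, lfc = d$lfc)
    write.table(de$results, path("de_table.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(de$selection$tier1, path("degs_tier1.txt"))
    writeLines(de$selection$tier2, path("degs_tier2.txt"))
    report$stages$de <- list(
      params = d[c("min_mean", "padj1", "padj2", "lfc")],
      thresholds = sprintf("padj<%g & |log2FC|>%g (tier1); padj<%g & |log2FC|>%g (tier2)",
                           d$padj1, d$lfc, d$padj2, d$lfc),
      genes_input = unname(de$n_filtered["input"]),
      genes_tested = unname(de$n_filtered["kept"]),
      n_tier1 = length(de$selection$tier1),
      n_tier2 = length(de$selection$tier2))
  }

  ## ---- qPCR validation ------------------------------------------------
  qp <- NULL; panel <- NULL
  if (isTRUE(cfg$qpcr$enabled)) {
    qcfg <- cfg$qpcr
    if (!is.null(qcfg$ct) && !is.null(qcfg$samples)) {
      ct <- read_ct(qcfg$ct, qcfg$samples, qcfg$ref_genes)
    } else {
      if (is.null(de)) fail("qpcr", "needs the DE stage (or ct/samples paths)")
      if (is.null(validation)) fail("qpcr", "no validation cohort available")
      panel <- de$selection$tier2
      if (length(panel) == 0) {
        ord <- order(de$results$padj)
        panel <- head(de$results$gene[ord], 10)
      }
      panel <- head(panel, qcfg$max_panel)
      if (length(panel) == 0) fail("qpcr", "empty validation panel")
      ct <- simulate_ct(truth, validation, panel, qcfg$ref_genes,
                        noise_sd = cfg$simulate$ct_noise_sd,
                        seed = cfg$seed + 2L)
      write_ct(ct, path("validation_ct.csv"), path("validation_samples.csv"))
    }
    qp <- qpcr_validate(ct)
    write.table(qp$table, path("qpcr_validation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$stages$qpcr <- list(
      params = list(alpha = qcfg$alpha, ref_genes = qcfg$ref_genes),
      n_panel = nrow(qp$table),
      n_significant = sum(qp$table$p < qcfg$alpha, na.rm = TRUE))
  }

  ## ---- random-forest signature ---------------------------------------
  sig <- NULL
  if (isTRUE(cfg$rf$enabled)) {
    if (is.null(qp)) fail("rf", "needs the qPCR stage's feature matrix")
    keep <- qp$table$gene[!is.na(qp$table$p) & qp$table$p < cfg$qpcr$alpha]
    if (length(keep) < 2) fail("rf", "fewer than 2 validated genes")
    feats <- qp$delta$neg_dct[, keep, drop = FALSE]
    feats <- feats[complete.cases(feats), , drop = FALSE]
    labs <- qp$delta$meta$phenotype[match(rownames(feats),
                                          qp$delta$meta$sample_id)]
    rcfg <- rf_config(n_trees = cfg$rf$n_trees, k_folds = cfg$rf$k_folds,
                      brier_threshold = cfg$rf$brier_threshold,
                      seed = cfg$seed + 3L)
    sig <- rf_signature(feats, labs, rcfg)
    write.table(sig$importance, path("rf_importance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sig$scores, path("rf_subject_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(sig$confusion), path("rf_confusion.json"),
                         auto_unbox = TRUE, digits = NA)
    report$stages$rf <- list(
      params = cfg$rf[c("k_folds", "n_trees", "brier_threshold")],
      n_features = ncol(feats),
      n_excluded = sum(sig$scores$excluded),
      signature = lapply(seq_len(nrow(sig$importance)), function(i)
        list(gene = sig$importance$gene[i],
             rank_score = sig$importance$rank_score[i])),
      confusion = unclass(sig$confusion))
  }

  ## ---- cell lines -----------------------------------------------------
  if (isTRUE(cfg$cellline$enabled)) {
    ccfg <- cfg$cellline
    if (!is.null(ccfg$dr) && !is.null(ccfg$thresholds)) {
      dr <- read.csv(ccfg$dr, stringsAsFactors = FALSE)
      thr <- read.csv(ccfg$thresholds, stringsAsFactors = FALSE)
    } else {
      pan <- default_cell_panel()
      dr <- simulate_dose_response(pan$panel, seed = cfg$seed + 4L)
      thr <- pan$thresholds
      write.csv(dr, path("dose_response.csv"), row.names = FALSE, quote = FALSE)
    }
    calls <- dose_response_panel(dr, thr)
    write.table(calls, path("cellline_calls.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    labels <- resistance_labels(calls, ccfg$rule)
    evid <- NULL
    if (!is.null(sig)) {
      genes <- sig$importance$gene
      if (!is.null(ccfg$expr)) {
        expr <- as.matrix(read.csv(ccfg$expr, row.names = 1))
      } else {
        # synthetic cell-line expression: resistant lines shifted in the
        # patients' direction for each signature gene
        set.seed(cfg$seed + 5L)
        dir <- sign(qp$table$shift[match(genes, qp$table$gene)])
        expr <- matrix(rnorm(length(genes) * length(labels)),
                       length(genes), length(labels),
                       dimnames = list(genes, names(labels)))
        expr <- expr + outer(dir * ccfg$effect,
                             as.numeric(labels == "resistant"))
      }
      rt <- randomization_group_test(expr, labels[colnames(expr)],
                                     n_perm = ccfg$n_perm,
                                     seed = cfg$seed + 6L)
      patient <- qp$table[match(genes, qp$table$gene),
                          c("gene", "shift", "p")]
      evid <- concordance_with_patients(patient, rt, cfg$qpcr$alpha)
      write.table(evid, path("evidence.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    report$stages$cellline <- list(
      params = ccfg[c("n_perm", "rule")],
      n_lines = length(labels),
      resistant_lines = names(labels)[labels == "resistant"],
      n_evidence2 = if (is.null(evid)) NA else sum(evid$evidence == 2))
  }

  ## ---- over-representation -------------------------------------------
  if (isTRUE(cfg$ora$enabled)) {
    ocfg <- cfg$ora
    if (is.null(ocfg$gmt)) fail("ora", "no GMT collection supplied")
    if (is.null(de)) fail("ora", "needs the DE stage for query and background")
    coll <- read_gmt(ocfg$gmt)
    query <- de$selection$tier2
    if (length(query) == 0) fail("ora", "empty query gene list")
    background <- de$results$gene
    ora <- fisher_ora(query, coll, background)
    write.table(ora, path("ora.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$stages$ora <- list(params = list(alpha = ocfg$alpha),
                              n_sets = nrow(ora),
                              n_significant = sum(ora$padj < ocfg$alpha))
  }

  report$outputs <- sort(list.files(cfg$outdir))
  hashes <- tools::md5sum(file.path(cfg$outdir,
                                    setdiff(report$outputs, "run_report.json")))
  report$output_md5 <- as.list(hashes)
  names(report$output_md5) <- basename(names(hashes))
  jsonlite::write_json(report, path("run_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
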