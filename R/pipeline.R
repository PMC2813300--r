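#' Run the full amplicon-to-driver analysis pipeline
#'
#' Orchestrates every stage on a simulated study: cohort-level aCGH
#' mapping (state calls, frequency maps, peak amplification),
#' tiling-array amplicon extraction and consensus-region delineation,
#' gene-content lookup over the packaged annotation, RT-qPCR driver
#' nomination, differential signature definition, gene-set enrichment
#' of the embedded stemness module, correlated-target recovery, and
#' the IHC cohort summary. All randomness flows from `config$seed`,
#' so two runs with the same configuration produce identical reports.
#'
#' @param config A [run_config()].
#' @param simulate Must currently be `TRUE`: inputs are produced by
#'   the packaged generators. Passing `FALSE` without an `inputs`
#'   list is an error before any stage runs.
#' @param inputs Reserved for pre-loaded inputs (a list mirroring the
#'   generator outputs).
#' @return A list of class `pipeline_report`; written to
#'   `config$output_dir/report.json` when an output directory is set.
#' @export
run_pipeline <- function(config = run_config(), simulate = TRUE,
                         inputs = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!simulate && is.null(inputs)) {
    stopf("no inputs: supply an inputs list or use simulate = TRUE")
  }
  seed <- config$seed
  thr <- config$thresholds
  quiet <- identical(config$log_level, "QUIET")
  say <- function(...) if (!quiet) log_msg(...)

  say("stage 1/6: aCGH cohort and amplification frequency")
  cgh <- if (simulate) make_cgh_cohort(seed = seed) else inputs$cgh
  freq <- amplification_frequency(cgh$cohort, thr)
  peak <- freq[which.max(freq$freq), ]
  ab_freq <- aberration_frequency(cgh$cohort, config$bin_size, thr)

  say("stage 2/6: tiling profiles, amplicons, consensus region")
  tiling <- if (simulate) make_tiling_cohort(seed = seed) else inputs$tiling
  segs <- extract_amplicons(tiling$cohort, thresholds = thr)
  consensus <- consensus_region(segs)

  say("stage 3/6: gene content of the consensus region")
  anno <- read_gene_annotation(
    system.file("extdata", "genes_3q26_synthetic.bed",
                package = "ampliconmap", mustWork = TRUE))
  genes <- genes_in_region(consensus, anno)

  say("stage 4/6: qPCR fold changes and driver nomination")
  qpcr <- if (simulate) make_qpcr_fixture(seed = seed) else inputs$qpcr
  fc <- relative_fold_changes(qpcr$expr, qpcr$reference_ids)
  drivers <- classify_driver_candidates(fc, qpcr$amplified_ids)

  say("stage 5/6: expression signature and enrichment")
  expr <- if (simulate) make_expression_dataset(seed = seed) else inputs$expr
  sig <- define_signature(expr$matrix, expr$labels)
  module_set <- list(esc_module = expr$truth$module_genes)
  enr <- gsea(expr$matrix, expr$labels, module_set,
              n_perm = config$n_perm, seed = seed)
  targets <- target_list(expr$truth$targets_activated,
                         expr$truth$targets_repressed)
  corr <- correlated_target_lists(expr$matrix, expr$truth$sox2_gene, targets)
  overlap <- hypergeometric_overlap(
    sig$up, targets$activated, rownames(expr$matrix))

  say("stage 6/6: IHC scoring")
  ihc <- if (simulate) make_ihc_fixture(seed = seed) else inputs$ihc
  calls <- score_case(ihc$records)
  ihc_summary <- summarize_cohort(calls)

  report <- list(
    schema_version = "1.0",
    provenance = list(
      seed = seed,
      thresholds = unclass(thr),
      bin_size = config$bin_size,
      n_perm = config$n_perm,
      package_version = as.character(utils::packageVersion("ampliconmap")),
      config_hash = config_hash(config)
    ),
    amplification = list(
      peak_clone = peak$clone_id,
      n_amplified = peak$n_amp,
      n_informative = peak$n_informative,
      frequency = peak$freq
    ),
    aberration_frequency = ab_freq,
    consensus_region = unclass(consensus),
    candidate_genes = genes$gene,
    driver_calls = drivers,
    strong_drivers = drivers$gene[drivers$strong_over5],
    signature = list(n_up = length(sig$up), n_down = length(sig$down)),
    enrichment = as.data.frame(enr),
    correlated_targets = list(
      n_activated = length(corr$activated),
      n_repressed = length(corr$repressed),
      n_total = target_list_size(corr)
    ),
    target_overlap = unclass(overlap),
    ihc_summary = ihc_summary
  )
  class(report) <- "pipeline_report"
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config)[c("bin_size", "seed", "n_perm")],
                         auto_unbox = TRUE)
  sprintf("%08x", sum(utf8ToInt(js) * seq_len(nchar(js))) %% .Machine$integer.max)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== amplicon mapping pipeline report ==\n")
  cat(sprintf("peak clone %s: %d/%d tumors amplified (%.1f%%)\n",
              x$amplification$peak_clone, x$amplification$n_amplified,
              x$amplification$n_informative,
              100 * x$amplification$frequency))
  cat(sprintf("consensus region: %s %.1f-%.1f Mb (%.2f Mb), support %d\n",
              x$consensus_region$chrom, x$consensus_region$start / 1e6,
              x$consensus_region$end / 1e6, x$consensus_region$width_mb,
              x$consensus_region$support))
  cat(sprintf("candidate genes (%d): %s\n", length(x$candidate_genes),
              paste(x$candidate_genes, collapse = ", ")))
  cat(sprintf("strong drivers: %s\n",
              paste(x$strong_drivers, collapse = ", ")))
  cat(sprintf("signature: %d up / %d down genes\n",
              x$signature$n_up, x$signature$n_down))
  cat(sprintf("module enrichment: ES %.2f, NES %.2f, FDR %.3g\n",
              x$enrichment$es[1], x$enrichment$nes[1], x$enrichment$fdr[1]))
  cat(sprintf("correlated targets: %d (+%d / -%d)\n",
              x$correlated_targets$n_total,
              x$correlated_targets$n_activated,
              x$correlated_targets$n_repressed))
  cat(sprintf("IHC: %d/%d activated (%d%%), %d cytoplasmic-only (%d%%)\n",
              x$ihc_summary$n_activated, x$ihc_summary$n_total,
              x$ihc_summary$pct_activated, x$ihc_summary$n_cytoplasmic_only,
              x$ihc_summary$pct_cytoplasmic_only))
  invisible(x)
}
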