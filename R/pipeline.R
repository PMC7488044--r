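## End-to-end demo pipeline on synthetic data: simulate -> enrich ->
## matched background / empirical FDR -> differential -> classify ->
## summary. Every output file carries the config hash and master seed in a
## comment header; a fixed seed reproduces every file byte for byte.

config_hash <- function(config) {
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  ## small stable FNV-1a style hash, dependency-free
  h <- 216613626
  for (b in utf8ToInt(txt)) h <- (bitwXor(h, b) * 16777619) %% 268435456
  sprintf("%07x", h)
}

demo_header <- function(config, seed) {
  sprintf("starrkit config=%s seed=%d", config_hash(config), seed)
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the self-contained synthetic demo pipeline
#'
#' Simulates a genome, candidate regions, counts and chromatin annotations;
#' calls enhancers; estimates the empirical FDR from GC/length-matched
#' background; tests differential activity; classifies loci; and writes
#' all tables, BED files and a summary under `outdir`. Deterministic given
#' `seed`: stage seeds are derived from the master seed.
#'
#' @param config a [sim_config()].
#' @param seed master integer seed.
#' @param outdir output directory (created).
#' @param thresholds a [starr_thresholds()]; `background_n` controls the
#'   size of the sampled background set.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with all stage results and the `summary`
#'   data.frame.
#' @export
run_demo <- function(config = sim_config(), seed = 1, outdir = NULL,
                     thresholds = starr_thresholds(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  stage_seed <- function(i) (seed * 97L + i * 1009L) %% 2147483647L
  hdr <- demo_header(config, seed)

  say("simulating genome and regions (n=", config$n_regions, ")")
  gen <- simulate_genome(config, stage_seed(1))
  say("simulating counts")
  exp <- simulate_experiment(config, gen$regions, seed = stage_seed(2))
  chrom <- simulate_chromatin(exp$truth, gen$regions, config, stage_seed(3))

  say("calling enhancers")
  call <- call_starr_peaks(gen$regions, exp$counts, exp$libraries, thresholds)

  say("sampling ", thresholds$background_n, " matched background regions")
  fdr <- background_fdr(gen$regions, gen$genome, config, exp$libraries,
                        call$priors, thresholds, seed = stage_seed(4))

  say("differential analysis")
  diffres <- differential_analysis(exp$counts, exp$libraries)

  say("classifying loci")
  cls <- lapply(stats::setNames(config$conditions, config$conditions),
                function(cn) {
                  classify_loci(call$per_condition[[cn]], call$per_library,
                                chrom, cn, regions = gen$regions,
                                c3_min_p = thresholds$c3_min_p)
                })

  summary_df <- demo_summary(exp, call, fdr, diffres, cls, thresholds)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    writeLines(c(paste0("#", hdr),
                 paste0(names(unclass(config)), "=",
                        vapply(unclass(config), function(v)
                          paste(deparse(v), collapse = ""), character(1)))),
               p("config.txt"))
    write_tsv_with_header(exp$counts, p("counts.tsv"), hdr)
    write_tsv_with_header(exp$truth, p("truth.tsv"), hdr)
    write_tsv_with_header(exp$libraries, p("libraries.tsv"), hdr)
    write_tsv_with_header(call$records, p("enrichment.tsv"), hdr)
    write_tsv_with_header(diffres$records, p("differential.tsv"), hdr)
    for (cn in config$conditions) {
      peaks <- call$per_condition[[cn]]
      if (length(peaks)) {
        sc <- call$records$e_shrunk[match(peaks$name, call$records$region_id)]
        peaks$score <- round(log2(sc), 4)
      }
      write_bed(peaks, p(paste0("final_peaks_", cn, ".bed")), hdr)
      write_tsv_with_header(cls[[cn]], p(paste0("classification_", cn, ".tsv")),
                            hdr)
    }
    write_bed(call$merged_union, p("union_peaks.bed"), hdr)
    write_bed(fdr$background, p("background.bed"), hdr)
    write_tsv_with_header(summary_df, p("summary.tsv"), hdr)
    write_chrom_sizes(gen$genome$chrom_sizes, p("genome.chrom.sizes"))
    Biostrings::writeXStringSet(gen$genome$seqs, p("genome.fa"))
    write_bed(gen$regions, p("regions.bed"), hdr)
  }
  invisible(list(genome = gen$genome, regions = gen$regions,
                 experiment = exp, chromatin = chrom, call = call,
                 fdr = fdr, differential = diffres, classification = cls,
                 summary = summary_df, config = config, seed = seed))
}

#' Empirical FDR from matched background
#'
#' Samples GC/length-matched background regions, generates null counts for
#' them under the experiment's input model, computes merged-replicate
#' shrunken enrichment with the condition priors, and reports the fraction
#' reaching the fold cutoff.
#'
#' @param peaks candidate (or final) peaks whose GC/length distribution is
#'   matched.
#' @param genome a [genome_index()].
#' @param config the [sim_config()] that generated the experiment (the
#'   background inherits its input model; enhancer activity is 1 by
#'   definition of background).
#' @param libraries library metadata (depths reused for the null counts).
#' @param priors per-condition shrinkage priors fitted on the candidates.
#' @param thresholds a [starr_thresholds()].
#' @param seed integer seed.
#' @return list: `background` (`GRanges`), `records`, `exceedance`
#'   (fraction of background enrichments at or above `background_fold`).
#' @export
background_fdr <- function(peaks, genome, config, libraries, priors,
                           thresholds, seed = 1) {
  n <- thresholds$background_n
  bg <- sample_matched_background(peaks, genome, n, seed = seed)
  null_truth <- data.frame(region_id = bg$name,
                           class_true = "none",
                           e_true_2iL = 1, e_true_SL = 1,
                           is_differential = FALSE, log2fc_true = 0,
                           stringsAsFactors = FALSE)
  bgexp <- simulate_experiment(config, bg, truth = null_truth,
                               seed = seed + 1)
  ## reuse the experiment's library depths so scaling matches
  bgexp$libraries <- libraries
  et <- enrichment_table(bgexp$counts, libraries)
  merged <- et$per_condition
  merged$e_shrunk <- NA_real_
  for (cn in names(priors)) {
    i <- merged$condition == cn
    merged$e_shrunk[i] <- shrunken_enrichment(merged$k[i], merged$T[i],
                                              priors[[cn]])
  }
  exc <- empirical_exceedance(merged$e_shrunk, thresholds$background_fold)
  list(background = bg, records = merged, exceedance = exc)
}

demo_summary <- function(exp, call, fdr, diffres, cls, thresholds) {
  truth <- exp$truth
  active_ids <- truth$region_id[truth$class_true %in% c("C1", "C2")]
  called_ids <- unique(call$records$region_id[call$records$pass])
  recall <- if (length(active_ids)) mean(active_ids %in% called_ids) else NA
  null_ids <- truth$region_id[!truth$region_id %in% active_ids]
  false_frac <- if (length(null_ids)) mean(null_ids %in% called_ids) else NA

  dr <- diffres$records
  dtruth <- truth$is_differential[match(dr$region_id, truth$region_id)]
  called_diff <- dr$call != "ns"
  dpower <- if (any(dtruth)) mean(called_diff[dtruth]) else NA
  dfdr <- if (any(called_diff)) mean(!dtruth[called_diff]) else NA

  class_counts <- unlist(lapply(names(cls), function(cn) {
    tab <- table(factor(cls[[cn]]$label, levels = c("C1", "C2", "C3")))
    stats::setNames(as.integer(tab), paste0(cn, "_", names(tab)))
  }))
  data.frame(metric = c("n_final_union", "empirical_fdr",
                        "enhancer_recall", "null_call_fraction",
                        "differential_power", "differential_fdr",
                        names(class_counts)),
             value = c(length(call$merged_union), fdr$exceedance,
                       recall, false_frac, dpower, dfdr,
                       unname(class_counts)),
             stringsAsFactors = FALSE)
}
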