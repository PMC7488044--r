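#!/usr/bin/env Rscript

# Stage 1 — simulate the study dataset.
#
# Generates a synthetic whole-genome STARR-seq experiment at the study
# conditions: 5,000 candidate regions with a median length of ~850 bp,
# mean transfected-input coverage of 9 reads per region, two culture
# conditions (2iL, SL) with two replicates each, ~30% of regions with
# planted enhancer activity, a quarter of those differential at 4-fold,
# and chromatin annotations consistent with the planted C1/C2/C3 classes.
# Everything downstream (02-05) reads the files written here.

suppressMessages(library(starrkit))

seed <- 20260921L
outdir <- "results/simulation"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_regions = 5000)
gen <- simulate_genome(cfg, seed)
ex <- simulate_experiment(cfg, gen$regions, seed = seed + 1)
chrom <- simulate_chromatin(ex$truth, gen$regions, cfg, seed + 2)

message(sprintf("genome: %s", paste(sprintf("%s=%dbp",
  names(gen$genome$chrom_sizes), gen$genome$chrom_sizes), collapse = ", ")))
message(sprintf("regions: %d (median %d bp), planted classes: %s",
  length(gen$regions), median(GenomicRanges::width(gen$regions)),
  paste(names(table(ex$truth$class_true)), table(ex$truth$class_true),
        sep = "=", collapse = " ")))
message(sprintf("differential regions: %d (|log2FC| = %g)",
  sum(ex$truth$is_differential), cfg$differential_log2fc))

Biostrings::writeXStringSet(gen$genome$seqs, file.path(outdir, "genome.fa"))
write_chrom_sizes(gen$genome$chrom_sizes,
                  file.path(outdir, "genome.chrom.sizes"))
write_bed(gen$regions, file.path(outdir, "regions.bed"))
utils::write.table(ex$counts, file.path(outdir, "counts.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(ex$libraries, file.path(outdir, "libraries.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ex$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
for (nm in names(chrom)) {
  write_bed(chrom[[nm]], file.path(outdir, paste0(nm, ".bed")))
}
message("wrote ", outdir)
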