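#!/usr/bin/env Rscript

# Stage 5 — descriptive statistics on the classified loci.
#
# Mutual overlap between class BED sets and chromatin marks; mean CpG
# methylation in 250-bp summit flanks (on a synthetic methylation track
# with class-dependent levels); a GC-matched motif-analysis background set
# of 500-bp regions with >= 10 input fragments per library; and a
# synthetic luciferase validation panel (n = 39 loci) scaled onto the
# STARR log2 enrichment axis.

suppressMessages(library(starrkit))

simdir <- "results/simulation"
endir <- "results/enrichment"
clsdir <- "results/classification"
outdir <- "results/annotation"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260925L
set.seed(seed)

regions <- read_bed(file.path(simdir, "regions.bed"))
truth <- utils::read.delim(file.path(simdir, "truth.tsv"))
sizes <- read_chrom_sizes(file.path(simdir, "genome.chrom.sizes"))
genome <- genome_index(Biostrings::readDNAStringSet(file.path(simdir, "genome.fa")))
k27 <- read_bed(file.path(simdir, "k27ac.bed"))
records <- utils::read.delim(file.path(endir, "enrichment.tsv"))

## mutual overlap of each class with H3K27ac (2iL classes)
for (lb in c("C1", "C2", "C3")) {
  f <- file.path(clsdir, sprintf("%s_2iL.bed", lb))
  if (!file.exists(f)) next
  cl <- read_bed(f)
  mo <- mutual_overlap(cl, k27)
  message(sprintf("%s vs H3K27ac: %.2f of loci covered, %.2f of peaks hit",
                  lb, mo[["frac_a"]], mo[["frac_b"]]))
}

## synthetic CpG methylation: hypomethylated at C1, intermediate at C3,
## high at C2 and background (a chromatin-masked enhancer sits in
## methylated genomic context)
cpg_n <- 40000
pos <- sort(sample(0:(sizes[[1]] - 1), cpg_n))
track <- data.frame(chrom = names(sizes)[1], pos = pos,
                    frac = stats::rbeta(cpg_n, 8, 2),
                    coverage = stats::rpois(cpg_n, 12) + 1)
cls1 <- regions[truth$class_true[match(regions$name, truth$region_id)] == "C1"]
hypo <- overlaps_any(interval_set(track$chrom, track$pos, track$pos + 1), cls1)
track$frac[hypo] <- stats::rbeta(sum(hypo), 1, 9)
meth <- methylation_at_windows(regions, track, sizes)
meth$class <- truth$class_true[match(meth$region_id, truth$region_id)]
agg <- stats::aggregate(mean_mCpG ~ class, data = meth[!meth$missing, ], FUN = mean)
message("mean mCpG in 250-bp summit flanks by planted class:")
for (i in seq_len(nrow(agg))) {
  message(sprintf("  %s: %.3f", agg$class[i], agg$mean_mCpG[i]))
}
utils::write.table(meth, file.path(outdir, "methylation_windows.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

## motif background: 500-bp regions, >= 10 input fragments per library.
## Synthetic input fragments are re-drawn around the regions' intensities.
counts <- utils::read.delim(file.path(simdir, "counts.tsv"))
libs <- unique(counts$library[grepl("rep", counts$library)])
frags <- lapply(setNames(libs, libs), function(l) {
  sub <- counts[counts$library == l, ]
  sub <- sub[match(regions$name, sub$region_id), ]
  reps <- pmax(sub$r, 0)
  anchor <- rep(GenomicRanges::start(regions) - 1L, reps)
  w <- rep(GenomicRanges::width(regions), reps)
  st <- pmax(anchor + sample(-200:200, sum(reps), replace = TRUE), 0)
  interval_set(rep(as.character(GenomicRanges::seqnames(regions)), reps),
               st, st + pmin(w, 850))
})
union_peaks <- read_bed(file.path(endir, "union_peaks.bed"))
bg <- export_motif_background(union_peaks, genome, frags, 2000,
                              min_reads = 10, seed = seed + 1)
message(sprintf("motif background: %d regions of 500 bp, GC-matched, >= 10 input fragments/library",
                length(bg)))
write_bed(bg, file.path(outdir, "motif_background.bed"))

## luciferase panel: 39 called loci, synthetic measurements around the
## STARR log2 enrichment with realistic noise, two experimental batches
called <- records[records$pass & records$condition == "2iL", ]
called <- called[order(called$e_shrunk), ]
## a validation panel spans the enrichment range rather than only the top
panel <- called[unique(round(seq(1, nrow(called), length.out = 39))), ]
starr <- setNames(log2(panel$e_shrunk), panel$region_id)
batch <- rep(1:2, length.out = length(starr))
meas <- do.call(rbind, lapply(seq_along(starr), function(i) {
  true_l2 <- starr[i] + rnorm(1, 0, 0.4) + ifelse(batch[i] == 2, 1.3, 0)
  data.frame(locus = names(starr)[i], replicate = 1:3,
             firefly = 2^(true_l2 + rnorm(3, 0, 0.08)), renilla = 1,
             batch = batch[i], stringsAsFactors = FALSE)
}))
luc <- scale_luciferase(meas, control_fvr = 1, starr = starr)
message(sprintf("luciferase vs STARR on n = %d loci: Pearson r = %.3f",
                length(starr), luc$pearson_r))
utils::write.table(luc$table, file.path(outdir, "luciferase_scaled.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", outdir)
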