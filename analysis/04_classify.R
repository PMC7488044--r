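#!/usr/bin/env Rscript

# Stage 4 — chromatin-context classification.
#
# APK elements are ATAC peaks that also carry P300 and H3K27ac. Per
# condition: a final STARR peak overlapping an "active" segmentation
# interval is C1 (active enhancer), otherwise C2 (chromatin-masked); an
# APK element without STARR signal in any of the four libraries
# (binomial p > 0.1) and at least 1 kb from a TSS is C3 (dormant).

suppressMessages(library(starrkit))

simdir <- "results/simulation"
endir <- "results/enrichment"
outdir <- "results/classification"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

regions <- read_bed(file.path(simdir, "regions.bed"))
truth <- utils::read.delim(file.path(simdir, "truth.tsv"))
per_library <- utils::read.delim(file.path(endir, "enrichment_per_library.tsv"))
annotation <- list(atac = read_bed(file.path(simdir, "atac.bed")),
                   p300 = read_bed(file.path(simdir, "p300.bed")),
                   k27ac = read_bed(file.path(simdir, "k27ac.bed")),
                   active = read_bed(file.path(simdir, "active.bed")),
                   tss = read_bed(file.path(simdir, "tss.bed")))

apk <- apk_elements(annotation$atac, annotation$p300, annotation$k27ac)
message(sprintf("APK elements (ATAC x P300 x H3K27ac): %d", length(apk)))

for (cn in c("2iL", "SL")) {
  final <- read_bed(file.path(endir, paste0("final_peaks_", cn, ".bed")))
  cls <- classify_loci(final, per_library, annotation, cn, regions = regions)
  lab <- cls[!is.na(cls$label), ]
  tab <- table(lab$label)
  message(sprintf("%s: %s; dropped with reason: %s", cn,
                  paste(names(tab), tab, sep = "=", collapse = " "),
                  paste(names(table(cls$reason)), table(cls$reason),
                        sep = "=", collapse = " ")))
  truth_of <- truth$class_true[match(lab$region_id, truth$region_id)]
  consistent <- (lab$label %in% c("C1", "C2")) == (truth_of %in% c("C1", "C2"))
  message(sprintf("  label agreement with planted classes (call-consistent loci): %.3f",
                  mean(lab$label[consistent] == truth_of[consistent])))
  utils::write.table(cls, file.path(outdir, paste0("classification_", cn, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (lb in c("C1", "C2", "C3")) {
    sel <- lab[lab$label == lb, ]
    if (nrow(sel)) {
      write_bed(interval_set(sel$chrom, sel$start, sel$end, name = sel$region_id),
                file.path(outdir, sprintf("%s_%s.bed", lb, cn)))
    }
  }
}
message("wrote ", outdir)
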