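## Descriptive statistics on classified loci: mutual peak-set overlap,
## CpG-methylation windows, motif-background export, luciferase scaling.

#' Mutual overlap between two peak sets
#'
#' Interval-level by default: an interval counts as overlapped when it
#' shares at least 1 bp with the other set. Returns the fraction of `a`
#' overlapped by `b` and the fraction of `b` overlapped by `a`. A bp-level
#' mode reports the fraction of covered bases instead.
#'
#' @param a,b non-empty `GRanges`.
#' @param mode `"interval"` or `"bp"`.
#' @return named numeric vector `c(frac_a = ..., frac_b = ...)`.
#' @export
mutual_overlap <- function(a, b, mode = c("interval", "bp")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) stop("both interval sets must be non-empty")
  if (mode == "interval") {
    c(frac_a = mean(overlaps_any(a, b)), frac_b = mean(overlaps_any(b, a)))
  } else {
    ia <- GenomicRanges::intersect(merge_intervals(a), merge_intervals(b),
                                   ignore.strand = TRUE)
    cov <- sum(GenomicRanges::width(ia))
    c(frac_a = cov / sum(GenomicRanges::width(merge_intervals(a))),
      frac_b = cov / sum(GenomicRanges::width(merge_intervals(b))))
  }
}

#' Rank external peak sets by overlap with a locus set
#'
#' Cistrome-style screen: loops [mutual_overlap()] over a list of peak
#' sets and ranks them by the fraction of `loci` they cover.
#'
#' @param loci `GRanges`.
#' @param peak_sets named list of `GRanges`.
#' @return data.frame sorted by decreasing `frac_loci`.
#' @export
rank_overlaps <- function(loci, peak_sets) {
  stopifnot(length(peak_sets) > 0, !is.null(names(peak_sets)))
  rows <- lapply(names(peak_sets), function(nm) {
    mo <- mutual_overlap(loci, peak_sets[[nm]])
    data.frame(set = nm, frac_loci = mo[["frac_a"]],
               frac_peaks = mo[["frac_b"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$frac_loci), ]
}

#' Mean CpG methylation in summit windows
#'
#' Coverage-weighted mean methylated fraction over CpGs falling in
#' `[summit - flank, summit + flank)` of each locus (midpoint when no
#' summit is recorded). Loci without qualifying CpGs are flagged missing.
#'
#' @param loci `GRanges`, optionally with a `summit` column.
#' @param track data.frame with `chrom`, `pos` (0-based CpG position),
#'   `frac` in `[0, 1]`, `coverage`.
#' @param chrom_sizes named vector for window clipping.
#' @param flank half-window in bp.
#' @param min_coverage CpGs below this coverage are ignored.
#' @param weighted coverage-weighted (default) or unweighted mean.
#' @return data.frame with `region_id`, `mean_mCpG`, `n_cpg`, `missing`.
#' @export
methylation_at_windows <- function(loci, track, chrom_sizes, flank = 250,
                                   min_coverage = 1, weighted = TRUE) {
  stopifnot(all(track$frac >= 0 & track$frac <= 1))
  win <- window_around_summit(loci, flank, chrom_sizes)
  keep <- track$coverage >= min_coverage
  tr <- track[keep, ]
  cpg <- interval_set(tr$chrom, tr$pos, tr$pos + 1)
  hits <- GenomicRanges::findOverlaps(win, cpg, ignore.strand = TRUE)
  ids <- if (!is.null(loci$name)) loci$name else as.character(seq_along(loci))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  res <- vapply(seq_along(win), function(i) {
    j <- sh[qh == i]
    if (!length(j)) return(c(NA_real_, 0))
    w <- if (weighted) tr$coverage[j] else rep(1, length(j))
    c(sum(tr$frac[j] * w) / sum(w), length(j))
  }, numeric(2))
  data.frame(region_id = ids, mean_mCpG = res[1, ], n_cpg = as.integer(res[2, ]),
             missing = is.na(res[1, ]), stringsAsFactors = FALSE)
}

#' Export a motif-analysis background set
#'
#' Random 500-bp regions with a GC distribution matching the peaks and at
#' least `min_reads` input fragments in every library: the background set
#' for external motif scanners. Delegates to
#' [sample_matched_background()] with a coverage filter built from
#' per-library input fragment positions.
#'
#' @param peaks `GRanges` whose GC distribution is matched.
#' @param genome a [genome_index()].
#' @param input_fragments named list of `GRanges`, one per input library.
#' @param n number of regions.
#' @param region_length region length in bp.
#' @param min_reads minimum overlapping fragments per library
#'   (0 disables the filter).
#' @param seed integer seed.
#' @return `GRanges` background set.
#' @export
export_motif_background <- function(peaks, genome, input_fragments, n,
                                    region_length = 500, min_reads = 10,
                                    seed = 1) {
  filt <- NULL
  if (min_reads > 0) {
    filt <- function(gr) {
      ok <- rep(TRUE, length(gr))
      for (fr in input_fragments) {
        ok <- ok & GenomicRanges::countOverlaps(gr, fr,
                                                ignore.strand = TRUE) >= min_reads
      }
      ok
    }
  }
  out <- tryCatch(
    sample_matched_background(peaks, genome, n,
                              region_length = region_length,
                              coverage_filter = filt, seed = seed),
    error = function(e) stop("background sampling failed (", conditionMessage(e),
                             "); fewer than ", n,
                             " regions satisfy the coverage filter"))
  out
}

#' Scale luciferase measurements to STARR enrichment
#'
#' Per locus: the Firefly/Renilla ratio averaged over technical replicates
#' and normalized by the control-region ratio, log2 transformed; batch
#' effects removed by regressing the log2 values on batch indicators and
#' subtracting the fitted batch offsets; finally mapped onto the STARR
#' log2 enrichment scale by affine least squares. Reports the mapped
#' values and the Pearson correlation (invariant to the affine map).
#'
#' @param measurements data.frame with `locus`, `replicate`, `firefly`,
#'   `renilla`, `batch`.
#' @param control_fvr Firefly/Renilla ratio at the control region.
#' @param starr named vector of STARR log2 enrichment values per locus.
#' @param min_replicates minimum technical replicates per locus.
#' @return list: `table` (locus, batch, log2_fvr, log2_fvr_corrected,
#'   scaled), `pearson_r`, `fit` coefficients.
#' @export
scale_luciferase <- function(measurements, control_fvr, starr,
                             min_replicates = 3) {
  stopifnot(all(measurements$firefly > 0), all(measurements$renilla > 0),
            control_fvr > 0)
  fvr <- measurements$firefly / measurements$renilla
  agg <- stats::aggregate(fvr, by = list(locus = measurements$locus,
                                         batch = measurements$batch),
                          FUN = mean)
  nrep <- stats::aggregate(fvr, by = list(locus = measurements$locus),
                           FUN = length)
  low <- nrep$locus[nrep$x < min_replicates]
  if (length(low)) {
    stop("locus with fewer than ", min_replicates,
         " technical replicates: ", low[1])
  }
  agg$log2_fvr <- log2(agg$x / control_fvr)
  if (any(!agg$locus %in% names(starr))) {
    stop("locus without a matched STARR value: ",
         setdiff(agg$locus, names(starr))[1])
  }
  ## batch correction: subtract fitted batch offsets (identity for 1 batch)
  agg$batch <- factor(agg$batch)
  if (nlevels(agg$batch) > 1) {
    fit_b <- stats::lm(log2_fvr ~ batch, data = agg)
    off <- stats::predict(fit_b) - mean(stats::predict(fit_b))
    agg$log2_fvr_corrected <- agg$log2_fvr - off
  } else {
    agg$log2_fvr_corrected <- agg$log2_fvr
  }
  sv <- starr[as.character(agg$locus)]
  if (stats::sd(sv) == 0) {
    warning("constant STARR vector; correlation undefined")
    r <- NA_real_
    ab <- c(intercept = mean(sv), slope = 0)
  } else {
    fit <- stats::lm(sv ~ agg$log2_fvr_corrected)
    ab <- stats::setNames(stats::coef(fit), c("intercept", "slope"))
    r <- stats::cor(agg$log2_fvr_corrected, sv)
  }
  agg$scaled <- ab[["intercept"]] + ab[["slope"]] * agg$log2_fvr_corrected
  list(table = agg[, c("locus", "batch", "log2_fvr", "log2_fvr_corrected",
                       "scaled")],
       pearson_r = r, fit = ab)
}
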