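## Chromatin-context classification of loci: C1 (STARR-active with active
## chromatin), C2 (STARR-active without it, "chromatin-masked"), C3 (active
## chromatin without STARR activity, "dormant", kept TSS-distal).

#' Putative enhancers from chromatin marks (APK elements)
#'
#' The intersection of ATAC, P300 and H3K27ac peak sets. By default the
#' reported elements are the ATAC peaks that carry at least 1 bp of overlap
#' with both other marks (anchor-set convention, so downstream signal is
#' computed on the accessibility peak); `mode = "intersection"` emits the
#' bp-level triple overlap instead.
#'
#' @param atac,p300,k27ac merged `GRanges`.
#' @param mode `"anchor"` or `"intersection"`.
#' @return `GRanges` of putative enhancer elements.
#' @export
apk_elements <- function(atac, p300, k27ac, mode = c("anchor", "intersection")) {
  mode <- match.arg(mode)
  if (!length(atac) || !length(p300) || !length(k27ac)) {
    warning("empty input mark set; no APK elements")
    return(GenomicRanges::GRanges())
  }
  if (mode == "anchor") {
    atac[overlaps_any(atac, p300) & overlaps_any(atac, k27ac)]
  } else {
    i1 <- GenomicRanges::intersect(GenomicRanges::granges(atac),
                                   GenomicRanges::granges(p300),
                                   ignore.strand = TRUE)
    GenomicRanges::intersect(i1, GenomicRanges::granges(k27ac),
                             ignore.strand = TRUE)
  }
}

#' Distance to the nearest TSS
#'
#' @param x `GRanges`.
#' @param tss `GRanges` of TSS positions.
#' @return integer distances (0 when overlapping; `Inf` when `tss` is
#'   empty or shares no chromosome).
#' @export
tss_distance <- function(x, tss) {
  if (!length(tss)) return(rep(Inf, length(x)))
  d <- suppressWarnings(GenomicRanges::distanceToNearest(x, tss,
                                                         ignore.strand = TRUE))
  out <- rep(Inf, length(x))
  out[S4Vectors::queryHits(d)] <- S4Vectors::elementMetadata(d)$distance
  out
}

#' Classify loci into C1 / C2 / C3
#'
#' For one condition: a final STARR peak overlapping an "active"
#' segmentation interval is C1, otherwise C2. An APK element that is not a
#' final STARR peak is C3 when its unadjusted binomial p value exceeds
#' `c3_min_p` in every library (no STARR signal in any replicate of either
#' condition) and it lies at least `tss_min_distance` from any annotated
#' TSS. APK elements failing these rules are returned unlabeled with the
#' reason recorded (`ambiguous_signal` for p values in
#' `[max_padj_zone, c3_min_p]`, `starr_signal`, `tss_proximal`,
#' `no_records`).
#'
#' @param starr_final `GRanges` of final STARR peaks for the condition
#'   (names matching `region_id` when records are keyed by region).
#' @param per_library per-library enrichment records (all four libraries)
#'   with `region_id` and `p`.
#' @param annotation list with `active`, `atac`, `p300`, `k27ac`, `tss`
#'   `GRanges` (see [simulate_chromatin()]), or a precomputed `apk` set.
#' @param condition label stored in the output.
#' @param regions optional `GRanges` of counted candidate regions with
#'   `name`; APK elements without their own `name` are matched to records
#'   through the region they overlap.
#' @param tss_min_distance minimum TSS distance for C3 (bp).
#' @param c3_min_p minimum per-library binomial p for "no signal".
#' @param ambiguous_zone lower edge of the ambiguous p zone; elements with
#'   any library p between this and `c3_min_p` are dropped as ambiguous
#'   rather than mislabeled.
#' @return data.frame: locus coordinates, `region_id`, `condition`,
#'   `label` (`C1`, `C2`, `C3` or `NA`), `evidence`, `tss_distance`,
#'   `reason` for unlabeled loci.
#' @export
classify_loci <- function(starr_final, per_library, annotation, condition,
                          regions = NULL, tss_min_distance = 1000,
                          c3_min_p = 0.1, ambiguous_zone = 0.05) {
  apk <- if (!is.null(annotation$apk)) annotation$apk else
    apk_elements(annotation$atac, annotation$p300, annotation$k27ac)

  gr_row <- function(gr, id, label, evidence, tssd, reason) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               region_id = id, condition = condition, label = label,
               evidence = evidence, tss_distance = tssd, reason = reason,
               stringsAsFactors = FALSE)
  }
  out <- list()
  if (length(starr_final)) {
    act <- overlaps_any(starr_final, annotation$active)
    tssd <- tss_distance(starr_final, annotation$tss)
    ids <- if (!is.null(starr_final$name)) starr_final$name else
      as.character(seq_along(starr_final))
    out[[1]] <- gr_row(starr_final, ids,
                       ifelse(act, "C1", "C2"),
                       ifelse(act, "starr+active_chromatin", "starr_only"),
                       tssd, NA_character_)
  }
  if (length(apk)) {
    is_peak <- overlaps_any(apk, starr_final)
    cand <- apk[!is_peak]
    if (length(cand)) {
      ## map candidate elements to per-library records: use the element's
      ## own name, else the id of the counted region it overlaps
      ids <- if (!is.null(cand$name)) {
        cand$name
      } else if (!is.null(regions) && !is.null(regions$name)) {
        hit <- GenomicRanges::findOverlaps(cand, regions,
                                           ignore.strand = TRUE,
                                           select = "first")
        ifelse(is.na(hit), NA_character_, regions$name[hit])
      } else as.character(seq_along(cand))
      tssd <- tss_distance(cand, annotation$tss)
      pmin_lib <- vapply(ids, function(id) {
        if (is.na(id)) return(NA_real_)
        ps <- per_library$p[per_library$region_id == id]
        if (!length(ps)) return(NA_real_)
        min(ps)
      }, numeric(1))
      n_lib <- length(unique(per_library$library))
      n_rec <- vapply(ids, function(id) {
        if (is.na(id)) return(0)
        sum(per_library$region_id == id)
      }, numeric(1))
      label <- rep(NA_character_, length(cand))
      reason <- rep(NA_character_, length(cand))
      ok_rec <- n_rec == n_lib & !is.na(pmin_lib)
      quiet <- ok_rec & pmin_lib > c3_min_p
      distal <- tssd >= tss_min_distance
      label[quiet & distal] <- "C3"
      reason[!ok_rec] <- "no_records"
      reason[ok_rec & pmin_lib < ambiguous_zone] <- "starr_signal"
      reason[ok_rec & pmin_lib >= ambiguous_zone & pmin_lib <= c3_min_p] <-
        "ambiguous_signal"
      reason[quiet & !distal] <- "tss_proximal"
      out[[2]] <- gr_row(cand, ids, label,
                         ifelse(!is.na(label), "apk_no_starr", NA_character_),
                         tssd, reason)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), region_id = character(),
                      condition = character(), label = character(),
                      evidence = character(), tss_distance = numeric(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
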