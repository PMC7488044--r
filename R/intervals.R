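## Interval sets are GRanges. Coordinates are BED 0-based half-open at every
## file boundary and converted to the 1-based closed GRanges convention in
## memory. An optional `summit` metadata column holds a 0-based genomic
## position (as in a BED file), so summit s corresponds to the 1-based
## base s + 1.

#' Construct a genomic interval set
#'
#' Builds a `GRanges` from BED-style (0-based, half-open) coordinates.
#' Malformed intervals (`start >= end`, negative `start`) are rejected with
#' the offending locus named.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param name optional identifiers.
#' @param score optional numeric scores.
#' @param strand optional strand (`+`, `-` or `.`); strand is carried but
#'   ignored by all overlap logic.
#' @param summit optional 0-based summit positions, must lie in
#'   `[start, end)`.
#' @return a `GRanges`.
#' @export
interval_set <- function(chrom, start, end, name = NULL, score = NULL,
                         strand = NULL, summit = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop("malformed interval at ", chrom[bad[1]], ":", start[bad[1]], "-",
         end[bad[1]], " (need 0 <= start < end)")
  }
  if (!is.null(summit)) {
    sbad <- which(!is.na(summit) & (summit < start | summit >= end))
    if (length(sbad)) {
      stop("summit outside interval at ", chrom[sbad[1]], ":",
           start[sbad[1]], "-", end[sbad[1]])
    }
  }
  str <- if (is.null(strand)) rep("*", length(chrom)) else
    ifelse(strand == ".", "*", strand)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L, end),
                               strand = str)
  if (!is.null(name)) gr$name <- name
  if (!is.null(score)) gr$score <- score
  if (!is.null(summit)) gr$summit <- as.numeric(summit)
  gr
}

#' Merge an interval set
#'
#' Sorts and collapses overlapping intervals; book-ended intervals (the end
#' of one equals the start of the next in half-open coordinates) are merged,
#' matching `bedtools merge` defaults. The union of covered bases is
#' preserved. Metadata columns are dropped.
#'
#' @param x a `GRanges`.
#' @return a sorted, non-overlapping `GRanges`.
#' @export
merge_intervals <- function(x) {
  GenomicRanges::reduce(GenomicRanges::granges(x), min.gapwidth = 1L,
                        ignore.strand = TRUE)
}

#' Per-interval overlap indicator
#'
#' For each interval of `a`, whether it shares at least one base with any
#' interval of `b`. Chromosomes absent from `b` yield `FALSE`. Strand is
#' ignored.
#'
#' @param a,b `GRanges`.
#' @return logical vector along `a`.
#' @export
overlaps_any <- function(a, b) {
  ## disjoint seqlevel sets are an expected situation, not a warning
  suppressWarnings(IRanges::overlapsAny(a, b, ignore.strand = TRUE))
}

#' Fixed window around each interval summit
#'
#' Returns `[summit - flank, summit + flank)` for every locus, clipped to
#' chromosome bounds. Loci without a recorded summit use the interval
#' midpoint `floor((start + end) / 2)` (0-based). A window falling entirely
#' outside its chromosome is an error.
#'
#' @param x a `GRanges`, optionally with a 0-based `summit` metadata column.
#' @param flank positive flank size in bp.
#' @param chrom_sizes named integer vector of chromosome lengths used for
#'   clipping.
#' @return a `GRanges` of clipped windows, same length and order as `x`.
#' @export
window_around_summit <- function(x, flank, chrom_sizes) {
  stopifnot(flank > 0)
  start0 <- GenomicRanges::start(x) - 1L
  end0 <- GenomicRanges::end(x)
  centre <- floor((start0 + end0) / 2)
  if (!is.null(x$summit)) {
    has <- !is.na(x$summit)
    centre[has] <- x$summit[has]
  }
  chrom <- as.character(GenomicRanges::seqnames(x))
  sizes <- chrom_sizes[chrom]
  if (anyNA(sizes)) stop("chromosome missing from chrom_sizes: ",
                         chrom[which(is.na(sizes))[1]])
  ws <- pmax(centre - flank, 0)
  we <- pmin(centre + flank, sizes)
  dead <- which(ws >= we | centre < 0 | centre >= sizes)
  if (length(dead)) {
    stop("summit window falls outside chromosome for locus ",
         chrom[dead[1]], ":", start0[dead[1]], "-", end0[dead[1]])
  }
  out <- interval_set(chrom, ws, we)
  if (!is.null(x$name)) out$name <- x$name
  out
}

#' GC fraction of intervals
#'
#' `(G + C) / (non-N bases)` of each interval's sequence. Intervals whose
#' sequence is entirely ambiguous (all N) are flagged `NA`.
#'
#' @param x a `GRanges` within genome bounds.
#' @param genome a [genome_index()].
#' @return numeric vector in `[0, 1]`, `NA` where undefined.
#' @export
gc_fraction <- function(x, genome) {
  seqs <- genome_sequences(genome, x)
  counts <- Biostrings::letterFrequency(seqs, c("G", "C", "A", "T"))
  acgt <- rowSums(counts)
  out <- ifelse(acgt == 0, NA_real_, (counts[, "G"] + counts[, "C"]) / acgt)
  as.numeric(out)
}

#' Count fragments over peaks
#'
#' Total count is the number of fragment records overlapping each peak
#' (duplicates included); unique count collapses fragments with identical
#' (chrom, start, end) coordinates first. A fragment overlapping two peaks
#' counts in both.
#'
#' @param fragments `GRanges` of fragment records, possibly with duplicated
#'   coordinates (PCR duplicates).
#' @param peaks merged `GRanges`.
#' @return data.frame with columns `total` and `unique`, one row per peak.
#' @export
count_fragments_in_peaks <- function(fragments, peaks) {
  total <- suppressWarnings(
    GenomicRanges::countOverlaps(peaks, fragments, ignore.strand = TRUE))
  uniq <- suppressWarnings(
    GenomicRanges::countOverlaps(peaks, unique(GenomicRanges::granges(fragments)),
                                 ignore.strand = TRUE))
  data.frame(total = as.integer(total), unique = as.integer(uniq))
}

## ---- genome index -------------------------------------------------------

#' Indexed genome
#'
#' Bundles sequences, chromosome sizes, and a mask of assembly gaps (runs of
#' N) for sequence access, GC computation, and background sampling.
#'
#' @param seqs a named `DNAStringSet`.
#' @return an object of class `genome_index`.
#' @export
genome_index <- function(seqs) {
  stopifnot(methods::is(seqs, "DNAStringSet"), !is.null(names(seqs)))
  sizes <- stats::setNames(Biostrings::width(seqs), names(seqs))
  gaps <- find_n_runs(seqs)
  structure(list(seqs = seqs, chrom_sizes = sizes, gaps = gaps),
            class = "genome_index")
}

find_n_runs <- function(seqs) {
  hits <- lapply(seq_along(seqs), function(i) {
    m <- Biostrings::vmatchPattern("N", seqs[i], fixed = TRUE)[[1]]
    if (length(m) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(GenomicRanges::GRanges(names(seqs)[i], m),
                          min.gapwidth = 1L)
  })
  out <- suppressWarnings(do.call(c, hits))
  if (is.null(out)) GenomicRanges::GRanges() else out
}

#' Extract sequences for intervals
#'
#' @param genome a [genome_index()].
#' @param x a `GRanges` within genome bounds.
#' @return a `DNAStringSet`, one entry per interval, each of width
#'   `end - start`.
#' @export
genome_sequences <- function(genome, x) {
  chrom <- as.character(GenomicRanges::seqnames(x))
  miss <- setdiff(unique(chrom), names(genome$seqs))
  if (length(miss)) stop("chromosome not in genome: ", miss[1])
  sizes <- genome$chrom_sizes[chrom]
  if (any(GenomicRanges::end(x) > sizes) || any(GenomicRanges::start(x) < 1)) {
    stop("interval outside genome bounds")
  }
  ## batch extraction per chromosome, restored to input order
  idx <- split(seq_along(x), chrom)
  parts <- lapply(names(idx), function(cn) {
    i <- idx[[cn]]
    Biostrings::extractAt(genome$seqs[[cn]],
                          IRanges::IRanges(GenomicRanges::start(x)[i],
                                           GenomicRanges::end(x)[i]))
  })
  res <- do.call(c, parts)
  res[order(unlist(idx, use.names = FALSE))]
}

## ---- file formats -------------------------------------------------------

#' Read a BED file
#'
#' BED3/BED6 tab-separated, no header; an optional 7th column is taken as an
#' absolute 0-based summit coordinate. Coordinates are converted from
#' 0-based half-open to the in-memory convention.
#'
#' @param path file path.
#' @return a `GRanges`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character", fill = TRUE)
  nc <- ncol(df)
  interval_set(df[[1]], as.numeric(df[[2]]), as.numeric(df[[3]]),
               name = if (nc >= 4) df[[4]] else NULL,
               score = if (nc >= 5) suppressWarnings(as.numeric(df[[5]])) else NULL,
               strand = if (nc >= 6) df[[6]] else NULL,
               summit = if (nc >= 7) as.numeric(df[[7]]) else NULL)
}

#' Write a BED file
#'
#' Emits BED3, BED6, or BED6 + summit depending on available columns.
#'
#' @param x a `GRanges`.
#' @param path output path.
#' @param header optional comment lines (each written prefixed with `#`).
#' @export
write_bed <- function(x, path, header = NULL) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                   start = GenomicRanges::start(x) - 1L,
                   end = GenomicRanges::end(x),
                   stringsAsFactors = FALSE)
  has_summit <- !is.null(x$summit)
  if (!is.null(x$name) || !is.null(x$score) || has_summit) {
    df$name <- if (is.null(x$name)) "." else x$name
    df$score <- if (is.null(x$score)) 0 else x$score
    df$strand <- {
      s <- as.character(GenomicRanges::strand(x))
      ifelse(s == "*", ".", s)
    }
  }
  if (has_summit) df$summit <- x$summit
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("#", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read/write two-column chrom.sizes text
#'
#' @param path file path.
#' @return named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df[[2]]), df[[1]])
}

#' @rdname read_chrom_sizes
#' @param sizes named integer vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), unname(sizes)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}
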