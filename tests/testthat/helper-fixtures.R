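# Fixture builders and brute-force oracles shared across tests. Oracles are
# deliberately naive (all-pairs scans, sweep lines, exact summations) and
# independent of the package code paths they check.

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000,
                           max_len = 120) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

df_to_gr <- function(df) interval_set(df$chrom, df$start, df$end)

# half-open overlap of two intervals on the same chromosome
.ov1 <- function(s1, e1, s2, e2) max(s1, s2) < min(e1, e2)

brute_overlaps <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(vapply(seq_len(nrow(b)), function(j) {
      a$chrom[i] == b$chrom[j] &&
        .ov1(a$start[i], a$end[i], b$start[j], b$end[j])
    }, logical(1)))
  }, logical(1))
}

# sweep-line merge with book-ended joining, per chromosome
brute_merge <- function(df) {
  out <- lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start, d$end), ]
    res <- d[1, , drop = FALSE]
    if (nrow(d) > 1) for (i in 2:nrow(d)) {
      last <- nrow(res)
      if (d$start[i] <= res$end[last]) {
        res$end[last] <- max(res$end[last], d$end[i])
      } else {
        res <- rbind(res, d[i, ])
      }
    }
    res
  })
  d <- do.call(rbind, out)
  d <- d[order(d$chrom, d$start), ]
  rownames(d) <- NULL
  d
}

gr_to_df <- function(gr) {
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$start), ]
  rownames(d) <- NULL
  d
}

tiny_genome <- function(seqs) {
  genome_index(Biostrings::DNAStringSet(seqs))
}

# small simulated experiment shared by several tests
small_sim <- function(n_regions = 400, seed = 7, ...) {
  cfg <- sim_config(n_regions = n_regions,
                    genome_length_bp = max(2e6, 4 * n_regions * 850), ...)
  gen <- simulate_genome(cfg, seed)
  ex <- simulate_experiment(cfg, gen$regions, seed = seed + 1)
  list(cfg = cfg, genome = gen$genome, regions = gen$regions,
       counts = ex$counts, libraries = ex$libraries, truth = ex$truth)
}
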