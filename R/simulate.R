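## Synthetic STARR-seq experiments with planted truth. The generator emulates
## the statistical structure the downstream models assume: per-region input
## intensity with Gamma overdispersion, Poisson sequencing given intensity,
## reporter counts proportional to a latent enhancer strength, PCR
## duplication bounded by input fragment diversity, block-wise GC
## heterogeneity, and chromatin annotations consistent with planted
## C1/C2/C3 classes.

#' Simulation configuration
#'
#' Central parameter object for the synthetic-data generator. Defaults are
#' the study conditions the pipeline is designed for: fragments with a
#' median length of about 850 bp, a mean transfected-input coverage of 9
#' reads per region, two culture conditions (`2iL`, `SL`) with two
#' replicates each, and per-library sequencing depths jittered log-uniformly
#' within 2-fold to exercise normalization.
#'
#' @param n_regions number of candidate regions.
#' @param region_length_median,region_length_sdlog log-normal length model
#'   (bp); lengths are clipped to `[200, 4 * median]`.
#' @param genome_length_bp total genome length; default scales with the
#'   region footprint so placement succeeds.
#' @param gc_block_bp block size of GC heterogeneity.
#' @param gc_profile function(n) returning per-block GC probabilities;
#'   default uniform in `[0.35, 0.65]`.
#' @param input_depth mean input coverage per region (reads).
#' @param starr_depth mean STARR coverage per region at enrichment 1.
#' @param input_dispersion Gamma shape of the per-region input intensity;
#'   smaller is more overdispersed.
#' @param enhancer_fraction fraction of regions with true activity
#'   (`e_true > 1`); 0 gives a pure-null experiment.
#' @param masked_fraction fraction of active regions that are
#'   chromatin-masked (planted class C2); the rest are C1.
#' @param dormant_fraction fraction of inactive regions carrying full active
#'   chromatin but no STARR activity (planted class C3).
#' @param effect_meanlog,effect_sdlog log-normal model of true enrichment
#'   for active regions; draws below `effect_min` are resampled.
#' @param effect_min lower truncation of planted enrichment.
#' @param differential_fraction fraction of active regions whose activity
#'   differs between conditions.
#' @param differential_log2fc planted absolute log2 fold change (SL vs 2iL),
#'   applied symmetrically around the region's base strength; direction is
#'   split evenly.
#' @param complexity_factor library complexity per region as a multiple of
#'   its input intensity: a region with intensity `lambda` carries
#'   `max(complexity_factor * lambda, 1)` distinct clonable fragments.
#' @param depth_jitter_fold per-library depth multipliers are drawn
#'   log-uniformly within this fold range.
#' @param conditions,replicates design labels.
#' @param tss_count number of annotated TSS positions.
#' @param tss_clear_bp minimum distance between a TSS and any planted C3
#'   region.
#' @param chromatin_noise probability that a region's planted chromatin
#'   coverage is flipped (robustness knob; 0 = noise-free).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 5000,
                       region_length_median = 850,
                       region_length_sdlog = 0.25,
                       genome_length_bp = NULL,
                       gc_block_bp = 10000,
                       gc_profile = function(n) stats::runif(n, 0.35, 0.65),
                       input_depth = 9,
                       starr_depth = 9,
                       input_dispersion = 2,
                       enhancer_fraction = 0.3,
                       masked_fraction = 0.3,
                       dormant_fraction = 0.1,
                       effect_meanlog = log(6),
                       effect_sdlog = 0.4,
                       effect_min = 3,
                       differential_fraction = 0.25,
                       differential_log2fc = 2,
                       complexity_factor = 1,
                       depth_jitter_fold = 2,
                       conditions = c("2iL", "SL"),
                       replicates = 2,
                       tss_count = NULL,
                       tss_clear_bp = 5000,
                       chromatin_noise = 0) {
  cfg <- as.list(environment())
  if (is.null(cfg$genome_length_bp)) {
    cfg$genome_length_bp <- max(2e6, ceiling(4 * n_regions * region_length_median))
  }
  if (is.null(cfg$tss_count)) cfg$tss_count <- max(20L, ceiling(n_regions / 5))
  with(cfg, {
    stopifnot(n_regions >= 0, input_depth > 0, starr_depth > 0,
              input_dispersion > 0, complexity_factor > 0,
              enhancer_fraction >= 0, enhancer_fraction <= 1,
              masked_fraction >= 0, masked_fraction <= 1,
              dormant_fraction >= 0, dormant_fraction <= 1,
              differential_fraction >= 0, differential_fraction <= 1,
              chromatin_noise >= 0, chromatin_noise <= 1,
              replicates >= 1, length(conditions) == 2)
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a genome and non-overlapping candidate regions
#'
#' Generates random DNA with block-wise GC heterogeneity over two
#' chromosomes, then places `n_regions` non-overlapping regions uniformly.
#' Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `genome` (a [genome_index()]) and `regions` (a
#'   `GRanges` with `name` and 0-based `summit` columns).
#' @export
simulate_genome <- function(config, seed) {
  set.seed(seed)
  glen <- config$genome_length_bp
  lens <- c(ceiling(glen * 0.6), glen - ceiling(glen * 0.6))
  names(lens) <- c("chrS1", "chrS2")
  seqs <- Biostrings::DNAStringSet(vapply(lens, function(L) {
    nb <- ceiling(L / config$gc_block_bp)
    gc <- pmin(pmax(config$gc_profile(nb), 0.01), 0.99)
    block_len <- c(rep(config$gc_block_bp, nb - 1),
                   L - (nb - 1) * config$gc_block_bp)
    paste(vapply(seq_len(nb), function(b) {
      p <- gc[b]
      paste(sample(c("G", "C", "A", "T"), block_len[b], replace = TRUE,
                   prob = c(p / 2, p / 2, (1 - p) / 2, (1 - p) / 2)),
            collapse = "")
    }, character(1)), collapse = "")
  }, character(1)))
  names(seqs) <- names(lens)
  genome <- genome_index(seqs)

  n <- config$n_regions
  if (n == 0) {
    return(list(genome = genome,
                regions = GenomicRanges::GRanges(seqlengths = lens)))
  }
  rl <- pmin(pmax(round(stats::rlnorm(n, log(config$region_length_median),
                                      config$region_length_sdlog)), 200),
             4 * config$region_length_median)
  ## split regions over chromosomes proportionally to length, then place
  ## each chromosome's regions by distributing the free space among gaps
  chrom_of <- sample(names(lens), n, replace = TRUE,
                     prob = lens / sum(lens))
  place <- function(chrom) {
    idx <- which(chrom_of == chrom)
    if (!length(idx)) return(NULL)
    L <- lens[[chrom]]
    tot <- sum(rl[idx])
    free <- L - tot
    if (free < length(idx) + 1) {
      stop("regions cannot be placed without overlap; increase genome_length_bp")
    }
    gaps <- free * diff(c(0, sort(stats::runif(length(idx))), 1))
    ord <- sample(idx)  # random order along the chromosome
    starts <- floor(cumsum(gaps[-length(gaps)]) +
                    cumsum(c(0, rl[ord[-length(ord)]])))
    data.frame(chrom = chrom, start = starts, end = starts + rl[ord],
               idx = ord)
  }
  placed <- do.call(rbind, lapply(names(lens), place))
  placed <- placed[order(placed$idx), ]
  summit_off <- floor(rl[placed$idx] *
                      stats::rbeta(nrow(placed), 8, 8))
  regions <- interval_set(placed$chrom, placed$start, placed$end,
                          name = sprintf("region_%05d", seq_len(n)),
                          summit = placed$start + summit_off)
  GenomeInfoDb::seqlevels(regions) <- names(lens)
  GenomeInfoDb::seqlengths(regions) <- lens
  list(genome = genome, regions = GenomicRanges::sort(regions))
}

#' Plant per-region truth
#'
#' Assigns each region a class (`C1`, `C2`, `C3`, `none`), a true enrichment
#' per condition, and a differential flag. `C3` and `none` regions have
#' `e_true = 1` in both conditions; differential regions carry the planted
#' log2 fold change symmetrically around their base strength.
#'
#' @param config a [sim_config()].
#' @param n number of regions (defaults to `config$n_regions`).
#' @return data.frame: `region_id`, `class_true`, `e_true_2iL`, `e_true_SL`,
#'   `is_differential`, `log2fc_true`.
#' @export
simulate_truth <- function(config, n = config$n_regions) {
  ids <- sprintf("region_%05d", seq_len(n))
  cls <- rep("none", n)
  n_act <- round(config$enhancer_fraction * n)
  act <- if (n_act > 0) sample(n, n_act) else integer(0)
  if (n_act > 0) {
    n_c2 <- round(config$masked_fraction * n_act)
    c2 <- if (n_c2 > 0) sample(act, n_c2) else integer(0)
    cls[act] <- "C1"; cls[c2] <- "C2"
  }
  inact <- setdiff(seq_len(n), act)
  n_c3 <- round(config$dormant_fraction * length(inact))
  if (n_c3 > 0) cls[sample(inact, n_c3)] <- "C3"

  e_base <- rep(1, n)
  if (n_act > 0) {
    draw <- function(m) {
      x <- stats::rlnorm(m, config$effect_meanlog, config$effect_sdlog)
      while (any(x < config$effect_min)) {
        i <- x < config$effect_min
        x[i] <- stats::rlnorm(sum(i), config$effect_meanlog, config$effect_sdlog)
      }
      x
    }
    e_base[act] <- draw(n_act)
  }
  lfc <- rep(0, n)
  if (n_act > 0 && config$differential_fraction > 0) {
    n_d <- round(config$differential_fraction * n_act)
    dif <- if (n_d > 0) sample(act, n_d) else integer(0)
    lfc[dif] <- config$differential_log2fc *
      sample(c(-1, 1), length(dif), replace = TRUE)
  }
  data.frame(region_id = ids,
             class_true = cls,
             e_true_2iL = e_base * 2^(-lfc / 2),
             e_true_SL = e_base * 2^(lfc / 2),
             is_differential = lfc != 0,
             log2fc_true = lfc,
             stringsAsFactors = FALSE)
}

#' Simulate per-library STARR-seq counts
#'
#' Count model, per region i and library j: input intensity
#' `lambda_i ~ Gamma(shape = input_dispersion, mean = input_depth)`; raw
#' input reads `r_ij ~ Pois(lambda_i d^in_j)`; total STARR reads
#' `k_ij ~ Pois(e_ic lambda_i (starr_depth / input_depth) d^st_j)` with `e_ic`
#' the region's true enrichment in the library's condition; unique STARR
#' reads follow the finite-complexity duplication model
#' `u = round(C (1 - (1 - 1/C)^k))` capped at `k`, with complexity
#' `C_i = max(complexity_factor * lambda_i, 1)` shared across libraries
#' (all libraries derive from one plasmid pool). Library totals are
#' genome-wide sequencing totals, so the input-to-STARR scaling ratio
#' reflects depth, not peak enrichment.
#'
#' @param config a [sim_config()].
#' @param regions `GRanges` of regions (only length/names used).
#' @param truth optional truth table from [simulate_truth()]; generated when
#'   `NULL`. Pass a table with `e_true_* = 1` to obtain null counts for
#'   arbitrary regions (e.g. sampled background).
#' @param seed integer seed.
#' @param duplication one of `"expected"` (closed-form expected distinct
#'   count, default) or `"resample"` (exact fragment-level resampling; slow,
#'   for validation at small n).
#' @return list with `counts` (long data.frame: `region_id`, `library`,
#'   `condition`, `replicate`, `k`, `u`, `r`), `libraries` (per-library
#'   metadata with genome-wide `starr_total` and `input_total`), and
#'   `truth`.
#' @export
simulate_experiment <- function(config, regions, truth = NULL, seed = 1,
                                duplication = c("expected", "resample")) {
  duplication <- match.arg(duplication)
  set.seed(seed)
  n <- length(regions)
  if (is.null(truth)) truth <- simulate_truth(config, n)
  stopifnot(nrow(truth) == n)
  ids <- if (!is.null(regions$name)) regions$name else truth$region_id
  ## align truth rows to the region order (regions may be coordinate-sorted)
  if (!all(ids == truth$region_id)) {
    if (!all(ids %in% truth$region_id)) stop("regions and truth do not match")
    truth <- truth[match(ids, truth$region_id), ]
    rownames(truth) <- NULL
  }

  libs <- expand.grid(replicate = seq_len(config$replicates),
                      condition = config$conditions,
                      stringsAsFactors = FALSE)
  libs$library <- paste0(libs$condition, "_rep", libs$replicate)
  J <- nrow(libs)
  half <- log(config$depth_jitter_fold) / 2
  libs$d_starr <- exp(stats::runif(J, -half, half))
  libs$d_input <- exp(stats::runif(J, -half, half))
  ## genome-wide totals: depth multiplier times a nominal library size
  nominal <- 1e7
  libs$starr_total <- round(libs$d_starr * nominal)
  libs$input_total <- round(libs$d_input * nominal)

  lambda <- stats::rgamma(n, shape = config$input_dispersion,
                          scale = config$input_depth / config$input_dispersion)
  Ccplx <- pmax(config$complexity_factor * lambda, 1)
  dr <- config$starr_depth / config$input_depth

  out <- vector("list", J)
  for (j in seq_len(J)) {
    e <- if (libs$condition[j] == config$conditions[1]) truth$e_true_2iL else truth$e_true_SL
    r <- stats::rpois(n, lambda * libs$d_input[j])
    k <- stats::rpois(n, e * lambda * dr * libs$d_starr[j])
    u <- switch(duplication,
      expected = pmin(round(Ccplx * (1 - (1 - 1 / Ccplx)^k)), k),
      resample = vapply(seq_len(n), function(i) {
        if (k[i] == 0) return(0L)
        length(unique(sample.int(max(round(Ccplx[i]), 1), k[i],
                                 replace = TRUE)))
      }, integer(1)))
    out[[j]] <- data.frame(region_id = ids, library = libs$library[j],
                           condition = libs$condition[j],
                           replicate = libs$replicate[j],
                           k = as.integer(k), u = as.integer(u),
                           r = as.integer(r), stringsAsFactors = FALSE)
  }
  list(counts = do.call(rbind, out),
       libraries = libs[, c("library", "condition", "replicate",
                            "starr_total", "input_total",
                            "d_starr", "d_input")],
       truth = truth)
}

#' Simulate chromatin annotations consistent with planted classes
#'
#' Regions planted as C1 or C3 are covered by ATAC, P300, and H3K27ac peaks
#' and by an "active" segmentation interval; C2 and unlabeled regions carry
#' none. C3 regions are kept TSS-distal: annotated TSS positions are placed
#' at least `tss_clear_bp` from any C3 region. A label-noise rate flips a
#' region's coverage status for robustness tests.
#'
#' @param truth truth table from [simulate_truth()].
#' @param regions matching `GRanges`.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list of `GRanges`: `atac`, `p300`, `k27ac`, `active`, `tss`.
#' @export
simulate_chromatin <- function(truth, regions, config, seed = 1) {
  set.seed(seed)
  n <- length(regions)
  stopifnot(nrow(truth) == n)
  covered <- truth$class_true %in% c("C1", "C3")
  if (config$chromatin_noise > 0) {
    flip <- stats::runif(n) < config$chromatin_noise
    covered <- xor(covered, flip)
  }
  mark_set <- function(jit) {
    ## mark peaks jitter inward so they never bleed onto a neighbouring
    ## region (uncovered regions must stay bare)
    idx <- which(covered)
    if (!length(idx)) return(GenomicRanges::GRanges())
    g <- GenomicRanges::granges(regions[idx])
    room <- pmax(floor((GenomicRanges::width(g) - 150) / 2), 0)
    pad <- pmin(sample(0:jit, length(idx), replace = TRUE), room)
    GenomicRanges::start(g) <- GenomicRanges::start(g) + pad
    GenomicRanges::end(g) <- GenomicRanges::end(g) - pad
    merge_intervals(g)
  }
  atac <- mark_set(100); p300 <- mark_set(150); k27ac <- mark_set(300)
  active <- mark_set(400)

  sizes <- genome_region_sizes(regions, config)
  c3 <- regions[truth$class_true == "C3"]
  forbid <- if (length(c3)) {
    g <- GenomicRanges::granges(c3)
    GenomicRanges::start(g) <- pmax(GenomicRanges::start(g) - config$tss_clear_bp, 1)
    GenomicRanges::end(g) <- GenomicRanges::end(g) + config$tss_clear_bp
    merge_intervals(g)
  } else GenomicRanges::GRanges()
  tss_pos <- list()
  need <- config$tss_count
  guard <- 0
  while (need > 0 && guard < 50) {
    chrom <- sample(names(sizes), need * 2, replace = TRUE,
                    prob = sizes / sum(sizes))
    pos <- floor(stats::runif(need * 2, 0, sizes[chrom] - 1))
    cand <- interval_set(chrom, pos, pos + 1)
    ok <- !overlaps_any(cand, forbid)
    keep <- cand[ok]
    if (length(keep) > need) keep <- keep[seq_len(need)]
    tss_pos[[length(tss_pos) + 1]] <- keep
    need <- need - length(keep)
    guard <- guard + 1
  }
  tss <- suppressWarnings(do.call(c, tss_pos))
  list(atac = atac, p300 = p300, k27ac = k27ac, active = active,
       tss = GenomicRanges::sort(tss))
}

genome_region_sizes <- function(regions, config) {
  sl <- GenomeInfoDb::seqlengths(regions)
  if (!length(sl) || anyNA(sl)) {
    sl <- stats::setNames(rep(config$genome_length_bp,
                              length(GenomeInfoDb::seqlevels(regions))),
                          GenomeInfoDb::seqlevels(regions))
  }
  sl
}
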