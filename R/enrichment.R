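## Per-peak enrichment of STARR-seq transcription over transfected input:
## right-tailed binomial significance, beta-binomial empirical-Bayes
## shrinkage of the enrichment ratio, matched-background empirical FDR, and
## the replicate-consistent final peak call.

#' Threshold set for enhancer calling
#'
#' @param min_enrichment minimum (shrunken) enrichment over input per
#'   condition, computed on merged replicates.
#' @param max_padj maximum BH-adjusted binomial p value, required in each
#'   replicate library separately.
#' @param background_n number of matched background regions for the
#'   empirical FDR (1e6 at full scale; 1e5 is the desk default).
#' @param background_fold fold cutoff whose background exceedance rate is
#'   the empirical FDR.
#' @param c3_min_p minimum unadjusted binomial p in every library for a
#'   locus to count as having no STARR signal (dormant class C3).
#' @return list of thresholds.
#' @export
starr_thresholds <- function(min_enrichment = 3, max_padj = 0.05,
                             background_n = 1e5, background_fold = 3,
                             c3_min_p = 0.1) {
  stopifnot(min_enrichment > 0, max_padj > 0, background_n >= 0,
            background_fold > 0, c3_min_p > 0)
  list(min_enrichment = min_enrichment, max_padj = max_padj,
       background_n = background_n, background_fold = background_fold,
       c3_min_p = c3_min_p)
}

#' Scale input counts to STARR library depth
#'
#' `m = ceil(r * starr_library_total / input_library_total)`, so that under
#' the null (no enhancer activity) the scaled input matches the expected
#' STARR count and the binomial success probability is 1/2.
#'
#' @param r raw input read counts (non-negative integers).
#' @param starr_library_total,input_library_total genome-wide library sizes.
#' @return integer vector `m`; `m = 0` iff `r = 0`.
#' @export
scale_input_counts <- function(r, starr_library_total, input_library_total) {
  if (starr_library_total <= 0 || input_library_total <= 0) {
    stop("library totals must be positive")
  }
  stopifnot(all(r >= 0))
  as.integer(ceiling(r * starr_library_total / input_library_total))
}

#' Right-tailed binomial enrichment p value
#'
#' Tests whether STARR reads exceed depth-scaled input at a locus:
#' `p = P(X >= k)` for `X ~ Binomial(n = k + T, p = 0.5)`, where `k` is the
#' total STARR read count (successes) and `T` the trials bound
#' `max(scaled input, unique STARR)`. After library scaling half of the
#' reads are expected to be input, hence success probability 0.5. `k = 0`
#' gives `p = 1`.
#'
#' @param k,T non-negative integer vectors (recycled).
#' @return p values in `[0, 1]`.
#' @export
binomial_enrichment_pvalue <- function(k, T) {
  if (any(k < 0) || any(T < 0)) stop("counts must be non-negative")
  n <- k + T
  ## survival function: P(X >= k) = P(X > k - 1)
  p <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  p[k == 0] <- 1
  pmin(pmax(p, 0), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control; monotone, capped at 1,
#' order-preserving with the original indexing.
#'
#' @param p vector of p values in `[0, 1]`.
#' @return adjusted p values.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stop("NA p values not allowed")
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Fit the beta-binomial shrinkage prior
#'
#' Maximizes `sum log BetaBinomial(k | n = k + T, alpha, beta)` over
#' `alpha, beta > 0` by quasi-Newton optimization on log-parameters,
#' initialized by method of moments on `k / (k + T)`. The fitted prior mean
#' odds `alpha / beta` is the enrichment value that zero-count loci shrink
#' to.
#'
#' @param k,T integer vectors of successes and trials bounds; records with
#'   `k + T = 0` are dropped.
#' @param min_records minimum number of usable records.
#' @return list of class `shrinkage_prior`: `alpha`, `beta`, `loglik`,
#'   `loglik_init`, `converged`, `iterations`, `n_records`.
#' @export
fit_shrinkage_prior <- function(k, T, min_records = 100) {
  n <- k + T
  keep <- n > 0
  k <- k[keep]; n <- n[keep]
  if (length(k) < min_records) {
    stop("need at least ", min_records, " records with k + T > 0")
  }
  if (all(k == 0)) stop("degenerate data: all successes are zero")
  theta <- k / n
  mbar <- mean(theta); vbar <- stats::var(theta)
  ## moments of the beta mixing distribution (theta variance in excess of
  ## binomial sampling noise); fall back to a weak symmetric prior
  s0 <- (mbar * (1 - mbar) - vbar) /
    max(vbar - mean(mbar * (1 - mbar) / n), 1e-8)
  if (!is.finite(s0) || s0 <= 0) s0 <- 2
  a0 <- max(mbar * s0, 1e-3); b0 <- max((1 - mbar) * s0, 1e-3)

  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
  }
  init <- c(log(a0), log(b0))
  fit <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  ll <- -fit$value; ll0 <- -nll(init)
  if (!is.finite(ll) || ll < ll0 - 1e-6) {
    stop("beta-binomial fit failed to improve on the moments initializer ",
         "(best alpha=", exp(fit$par[1]), ", beta=", exp(fit$par[2]), ")")
  }
  structure(list(alpha = exp(fit$par[1]), beta = exp(fit$par[2]),
                 loglik = ll, loglik_init = ll0,
                 converged = fit$convergence == 0,
                 iterations = fit$counts[["function"]],
                 n_records = length(k)),
            class = "shrinkage_prior")
}

#' @export
print.shrinkage_prior <- function(x, ...) {
  cat(sprintf("beta-binomial prior: alpha=%.4g beta=%.4g (mean odds %.3g), %d records, logLik %.2f\n",
              x$alpha, x$beta, x$alpha / x$beta, x$n_records, x$loglik))
  invisible(x)
}

#' Shrunken enrichment
#'
#' Posterior-mean odds of the beta-binomial success probability:
#' `(k + alpha) / (T + beta)`. Reproduces the raw ratio `k / T` in the
#' data-rich limit and pulls low-count loci toward the prior mean odds.
#'
#' @param k,T counts as in [binomial_enrichment_pvalue()].
#' @param prior a [fit_shrinkage_prior()] result, or a list with `alpha`
#'   and `beta`.
#' @return numeric vector of shrunken enrichment values.
#' @export
shrunken_enrichment <- function(k, T, prior) {
  stopifnot(prior$alpha > 0, prior$beta > 0)
  (k + prior$alpha) / (T + prior$beta)
}

#' Fraction of background enrichments exceeding a fold cutoff
#'
#' The empirical false discovery rate of an enrichment threshold: the
#' fraction of matched random background regions whose enrichment reaches
#' the cutoff.
#'
#' @param background_e numeric vector of background enrichment values.
#' @param fold cutoff.
#' @return fraction in `[0, 1]`.
#' @export
empirical_exceedance <- function(background_e, fold) {
  if (!length(background_e)) stop("empty background vector")
  mean(background_e >= fold)
}

## ---- matched background sampling ---------------------------------------

#' Sample GC- and length-matched background regions
#'
#' Draws `n` random regions whose GC histogram (2% bins) matches that of
#' the peaks, with all regions at the peaks' median length (or a fixed
#' length), avoiding assembly gaps. Sampling is batched rejection per GC
#' bin; an unreachable bin raises an error naming it.
#'
#' @param peaks `GRanges` whose GC distribution is the target.
#' @param genome a [genome_index()].
#' @param n number of regions.
#' @param region_length `"median"` (of peak widths) or an integer length.
#' @param bin_width GC bin width (default 0.02).
#' @param coverage_filter optional `function(GRanges) -> logical` which
#'   candidate windows must satisfy (e.g. minimum input coverage).
#' @param max_batches cap on rejection batches before erroring.
#' @param slack fraction of `n` that may be redistributed from unreachable
#'   GC bins to the nearest reachable ones (the GC histogram then still
#'   matches within 0.01 per bin); a larger unmet quota is an error.
#' @param seed integer seed.
#' @return `GRanges` of background regions with a `gc` metadata column.
#' @export
sample_matched_background <- function(peaks, genome, n,
                                      region_length = "median",
                                      bin_width = 0.02,
                                      coverage_filter = NULL,
                                      max_batches = 200, slack = 0.005,
                                      seed = 1) {
  if (!length(peaks)) stop("peaks must be non-empty")
  set.seed(seed)
  if (n == 0) return(GenomicRanges::GRanges())
  L <- if (identical(region_length, "median")) {
    as.integer(stats::median(GenomicRanges::width(peaks)))
  } else as.integer(region_length)
  stopifnot(L > 0)

  gc_peak <- gc_fraction(peaks, genome)
  gc_peak <- gc_peak[!is.na(gc_peak)]
  if (!length(gc_peak)) stop("no peak has a defined GC fraction")
  breaks <- seq(0, 1, by = bin_width)
  target <- tabulate(findInterval(gc_peak, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  quota <- floor(n * target / sum(target))
  ## distribute the remainder over the largest bins
  short <- n - sum(quota)
  if (short > 0) {
    ord <- order(target, decreasing = TRUE)
    quota[ord[seq_len(short)]] <- quota[ord[seq_len(short)]] + 1
  }

  sizes <- genome$chrom_sizes[genome$chrom_sizes >= L]
  if (!length(sizes)) stop("genome too small for region length ", L)
  got <- vector("list", max_batches + 1L)
  remaining <- quota
  spare <- NULL  # unselected candidates kept for tail redistribution
  batch <- max(2L * n, 1000L)
  stall <- 0L
  for (b in seq_len(max_batches)) {
    if (sum(remaining) == 0 || stall >= 20L) break
    before <- sum(remaining)
    chrom <- sample(names(sizes), batch, replace = TRUE,
                    prob = (sizes - L + 1) / sum(sizes - L + 1))
    start0 <- floor(stats::runif(batch, 0, sizes[chrom] - L))
    cand <- interval_set(chrom, start0, start0 + L)
    if (length(genome$gaps)) cand <- cand[!overlaps_any(cand, genome$gaps)]
    if (!is.null(coverage_filter) && length(cand)) {
      cand <- cand[coverage_filter(cand)]
    }
    if (!length(cand)) next
    gc <- gc_fraction(cand, genome)
    keep <- !is.na(gc)
    cand <- cand[keep]; gc <- gc[keep]
    bin <- findInterval(gc, breaks, rightmost.closed = TRUE)
    sel <- logical(length(cand))
    for (bb in unique(bin)) {
      if (remaining[bb] == 0) next
      idx <- which(bin == bb)
      take <- utils::head(idx, remaining[bb])
      sel[take] <- TRUE
      remaining[bb] <- remaining[bb] - length(take)
    }
    picked <- cand[sel]
    picked$gc <- gc[sel]
    got[[b]] <- picked
    if (sum(remaining) > 0 && any(!sel)) {
      keep_n <- min(sum(!sel), 4L * sum(remaining))
      sp <- cand[!sel][seq_len(keep_n)]
      sp$gc <- gc[!sel][seq_len(keep_n)]
      spare <- sp
    }
    stall <- if (sum(remaining) < before) 0L else stall + 1L
  }
  if (sum(remaining) > 0) {
    ## a thin tail of the peak GC histogram can be unreachable at the
    ## sampled window length; fill from the closest available GC instead,
    ## as long as the displaced mass stays within the per-bin tolerance
    if (sum(remaining) <= max(ceiling(slack * n), 1) && length(spare) > 0) {
      centres <- (breaks[-length(breaks)] + breaks[-1]) / 2
      want_gc <- rep(centres, remaining)
      take <- integer(0)
      avail <- seq_along(spare)
      for (wg in want_gc) {
        if (!length(avail)) break
        pick <- avail[which.min(abs(spare$gc[avail] - wg))]
        take <- c(take, pick)
        avail <- setdiff(avail, pick)
      }
      if (length(take) == sum(remaining)) {
        got[[max_batches + 1L]] <- spare[take]
        remaining[] <- 0
      }
    }
    if (sum(remaining) > 0) {
      worst <- which.max(remaining)
      stop(sprintf(
        "GC bin [%.2f, %.2f) unreachable after %d batches (%d regions missing)",
        breaks[worst], breaks[worst + 1], max_batches, remaining[worst]))
    }
  }
  out <- suppressWarnings(do.call(c, got[!vapply(got, is.null, logical(1))]))
  out$name <- sprintf("bg_%06d", seq_along(out))
  out
}

## ---- enrichment tables and peak calling --------------------------------

#' Per-library and merged-replicate enrichment records
#'
#' Computes, for every region and library: the scaled input `m`, the trials
#' bound `T = max(m, u)`, the raw enrichment `k / T`, the right-tailed
#' binomial p value, and the BH-adjusted p value (adjusted per library
#' across all regions). Replicates are also merged per condition (counts
#' summed, `T = max(sum m, sum u)`) for the enrichment threshold.
#'
#' @param counts long counts data.frame from [simulate_experiment()] (or
#'   equivalent with columns `region_id`, `library`, `condition`,
#'   `replicate`, `k`, `u`, `r`).
#' @param libraries library metadata with `library`, `starr_total`,
#'   `input_total`.
#' @param literal_trials if `TRUE`, use the strict reading in which the
#'   successes are clamped to the trials (`k <= T`), rather than the
#'   ratio-vs-1 test on `n = k + T`.
#' @return list with `per_library` and `per_condition` data.frames.
#' @export
enrichment_table <- function(counts, libraries, literal_trials = FALSE) {
  stopifnot(all(c("region_id", "library", "condition", "k", "u", "r") %in%
                names(counts)))
  lib <- libraries[match(counts$library, libraries$library), ]
  m <- scale_input_counts_vec(counts$r, lib$starr_total, lib$input_total)
  T <- pmax(m, counts$u)
  k <- counts$k
  if (literal_trials) {
    ## strict reading: k successes out of T trials, successes clamped to T
    kc <- pmin(k, T)
    p <- stats::pbinom(kc - 1, T, 0.5, lower.tail = FALSE)
    p[kc == 0] <- 1
  } else {
    p <- binomial_enrichment_pvalue(k, T)
  }
  per_lib <- data.frame(region_id = counts$region_id,
                        library = counts$library,
                        condition = counts$condition,
                        replicate = counts$replicate,
                        k = k, u = counts$u, r = counts$r, m = m, T = T,
                        e_raw = ifelse(T > 0, k / T, NA_real_),
                        p = p, stringsAsFactors = FALSE)
  per_lib$p_adj <- stats::ave(per_lib$p, per_lib$library,
                              FUN = function(z) bh_adjust(z))

  grp <- paste(per_lib$region_id, per_lib$condition, sep = "\r")
  sums <- rowsum(cbind(k = per_lib$k, u = per_lib$u, m = per_lib$m), grp)
  key <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
  agg <- data.frame(region_id = key[, 1], condition = key[, 2],
                    k = sums[, "k"], u = sums[, "u"], m = sums[, "m"],
                    row.names = NULL, stringsAsFactors = FALSE)
  agg$T <- pmax(agg$m, agg$u)
  agg$e_raw <- ifelse(agg$T > 0, agg$k / agg$T, NA_real_)
  agg$p <- binomial_enrichment_pvalue(agg$k, agg$T)
  list(per_library = per_lib, per_condition = agg)
}

scale_input_counts_vec <- function(r, starr_total, input_total) {
  if (any(starr_total <= 0) || any(input_total <= 0)) {
    stop("library totals must be positive")
  }
  as.integer(ceiling(r * starr_total / input_total))
}

#' Call final STARR-seq peaks
#'
#' A candidate is a final peak in a condition when its merged-replicate
#' shrunken enrichment reaches `min_enrichment` and its BH-adjusted binomial
#' p value is below `max_padj` in each replicate library separately. The
#' union across conditions is the merged final peak set.
#'
#' @param candidates `GRanges` of candidate regions with `name` matching
#'   `region_id`.
#' @param counts,libraries as in [enrichment_table()].
#' @param thresholds a [starr_thresholds()].
#' @param priors optional named list of [fit_shrinkage_prior()] objects per
#'   condition; fitted on the merged-replicate candidate counts when `NULL`.
#' @param use_shrunken apply the enrichment threshold to shrunken (default)
#'   or raw enrichment.
#' @return list: `per_condition` (named list of `GRanges`), `union`
#'   (`GRanges` with `conditions` annotation), `records` (merged-replicate
#'   table with `e_shrunk` and `pass`), `priors`.
#' @export
call_starr_peaks <- function(candidates, counts, libraries, thresholds,
                             priors = NULL, use_shrunken = TRUE) {
  conds <- unique(libraries$condition)
  for (cn in conds) {
    nrep <- length(unique(libraries$replicate[libraries$condition == cn]))
    if (nrep < 2) stop("need two replicates per condition; missing in ", cn)
  }
  et <- enrichment_table(counts, libraries)
  merged <- et$per_condition
  if (is.null(priors)) {
    priors <- lapply(stats::setNames(conds, conds), function(cn) {
      sub <- merged[merged$condition == cn, ]
      fit_shrinkage_prior(sub$k, sub$T)
    })
  }
  merged$e_shrunk <- NA_real_
  for (cn in conds) {
    i <- merged$condition == cn
    merged$e_shrunk[i] <- shrunken_enrichment(merged$k[i], merged$T[i],
                                              priors[[cn]])
  }
  ## per-replicate adjusted-p rule: worst adjusted p across replicates
  grp <- paste(et$per_library$region_id, et$per_library$condition, sep = "\r")
  worst <- tapply(et$per_library$p_adj, grp, max)
  merged$p_adj_worst <-
    as.numeric(worst[paste(merged$region_id, merged$condition, sep = "\r")])
  e_crit <- if (use_shrunken) merged$e_shrunk else merged$e_raw
  merged$pass <- !is.na(e_crit) & e_crit >= thresholds$min_enrichment &
    merged$p_adj_worst < thresholds$max_padj

  per_condition <- lapply(stats::setNames(conds, conds), function(cn) {
    ids <- merged$region_id[merged$condition == cn & merged$pass]
    candidates[candidates$name %in% ids]
  })
  passing <- unique(merged$region_id[merged$pass])
  union_gr <- candidates[candidates$name %in% passing]
  if (length(union_gr)) {
    by_id <- split(merged$condition[merged$pass],
                   merged$region_id[merged$pass])
    union_gr$conditions <- vapply(by_id[union_gr$name], paste,
                                  character(1), collapse = ",")
  }
  merged_union <- merge_intervals(union_gr)
  list(per_condition = per_condition, union = GenomicRanges::sort(union_gr),
       merged_union = merged_union, records = merged, priors = priors,
       per_library = et$per_library)
}

#' Sequencing-depth convergence of the peak call
#'
#' Thins every count by independent binomial sampling at each fraction (a
#' count-level stand-in for alignment-file downsampling), re-derives unique
#' counts through the duplication model so that `u <= k` is preserved,
#' refits the shrinkage priors, and repeats the full peak call.
#'
#' @param candidates,counts,libraries,thresholds as in [call_starr_peaks()].
#' @param fractions vector of retention fractions in `(0, 1]`.
#' @param complexity per-region library complexity used to re-derive unique
#'   counts (named by `region_id`); defaults to the observed
#'   per-region max of `u` across libraries.
#' @param seed integer seed.
#' @return data.frame with `fraction` and `n_peaks` (size of the merged
#'   final union).
#' @export
depth_convergence <- function(candidates, counts, libraries, thresholds,
                              fractions = seq(0.2, 0.9, by = 0.1),
                              complexity = NULL, seed = 1) {
  stopifnot(all(fractions > 0 & fractions <= 1))
  set.seed(seed)
  if (is.null(complexity)) {
    complexity <- tapply(counts$u, counts$region_id, max)
    complexity <- pmax(complexity, 1)
  }
  out <- lapply(fractions, function(f) {
    thin <- counts
    if (f < 1) {
      thin$k <- stats::rbinom(nrow(thin), thin$k, f)
      thin$r <- stats::rbinom(nrow(thin), thin$r, f)
      Ci <- as.numeric(complexity[thin$region_id])
      thin$u <- pmin(round(Ci * (1 - (1 - 1 / Ci)^thin$k)), thin$k)
      libs <- libraries
      libs$starr_total <- pmax(round(libs$starr_total * f), 1)
      libs$input_total <- pmax(round(libs$input_total * f), 1)
    } else libs <- libraries
    res <- call_starr_peaks(candidates, thin, libs, thresholds)
    data.frame(fraction = f, n_peaks = length(res$merged_union))
  })
  do.call(rbind, out)
}
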