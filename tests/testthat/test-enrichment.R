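test_that("input scaling ceils to integers and preserves zeros", {
  expect_equal(scale_input_counts(7, 1, 3), 3L)     # ceil(7/3)
  expect_equal(scale_input_counts(0, 5, 3), 0L)
  expect_equal(scale_input_counts(10, 7, 7), 10L)
  expect_error(scale_input_counts(1, 0, 5), "positive")
})

test_that("binomial p values match exact pmf summation on frozen examples", {
  expect_equal(binomial_enrichment_pvalue(8, 2), 56 / 1024)
  expect_equal(binomial_enrichment_pvalue(0, 50), 1.0)
  expect_equal(binomial_enrichment_pvalue(10, 10),
               (1 + dbinom(10, 20, 0.5)) / 2)
  expect_equal(binomial_enrichment_pvalue(0, 0), 1.0)
  expect_error(binomial_enrichment_pvalue(-1, 5), "non-negative")
})

test_that("binomial p value is monotone in k and in T", {
  k <- 0:60
  p_k <- binomial_enrichment_pvalue(k, 20)
  expect_true(all(diff(p_k) < 0))
  T <- 0:60
  p_T <- binomial_enrichment_pvalue(rep(25, length(T)), T)
  expect_true(all(diff(p_T) > 0))
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  ## order preserved with original indexing
  p <- c(0.9, 0.001, 0.5, 0.02)
  expect_equal(order(bh_adjust(p)), order(p))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.1, NA)), "NA")
})

test_that("beta-binomial prior fit recovers planted parameters and beats its initializer", {
  set.seed(201)
  n <- rpois(20000, 40)
  theta <- rbeta(20000, 5, 5)
  k <- rbinom(20000, n, theta)
  pr <- fit_shrinkage_prior(k, n - k)
  expect_equal(pr$alpha, 5, tolerance = 0.1)
  expect_equal(pr$beta, 5, tolerance = 0.1)
  expect_gte(pr$loglik, pr$loglik_init)
  ## symmetric degenerate data centres the prior mean at 1/2
  pr2 <- fit_shrinkage_prior(rep(20, 500), rep(20, 500))
  expect_equal(pr2$alpha / (pr2$alpha + pr2$beta), 0.5, tolerance = 0.02)
  expect_error(fit_shrinkage_prior(rep(0, 500), rep(10, 500)), "degenerate")
  expect_error(fit_shrinkage_prior(1:10, 1:10), "at least")
})

test_that("shrunken enrichment is the posterior mean odds and vanishes with evidence", {
  pr <- list(alpha = 1, beta = 2)
  expect_equal(shrunken_enrichment(30, 10, pr), 31 / 12)
  expect_equal(shrunken_enrichment(0, 0, list(alpha = 1, beta = 1)), 1.0)
  expect_equal(shrunken_enrichment(3000, 1000, list(alpha = 0.5, beta = 0.5)),
               3, tolerance = 0.002)
  ## monotone in k, anti-monotone in T; ordering of e_raw preserved at equal T
  expect_true(all(diff(shrunken_enrichment(0:50, 10, pr)) > 0))
  expect_true(all(diff(shrunken_enrichment(20, 0:50, pr)) < 0))
})

test_that("exceedance fraction counts the background tail", {
  expect_equal(empirical_exceedance(c(0.5, 1, 2, 3.5, 4), 3), 0.4)
  expect_equal(empirical_exceedance(c(0.1, 0.2), 3), 0)
  expect_equal(empirical_exceedance(c(0.1, 0.2), 0), 1)
  expect_error(empirical_exceedance(numeric(0), 3), "empty")
})

test_that("matched background reproduces the peak GC histogram on a bimodal genome", {
  set.seed(202)
  block <- function(p, n) paste(sample(c("G", "C", "A", "T"), n, TRUE,
                                       prob = c(p / 2, p / 2, (1 - p) / 2, (1 - p) / 2)),
                                collapse = "")
  seqs <- c(lo = block(0.30, 3e5), hi = block(0.62, 3e5))
  g <- tiny_genome(seqs)
  starts <- sample(0:(3e5 - 300), 300)
  peaks <- suppressWarnings(
    c(interval_set("lo", starts[1:150], starts[1:150] + 300),
      interval_set("hi", starts[151:300], starts[151:300] + 300)))
  bg <- sample_matched_background(peaks, g, 20000, seed = 203)
  expect_length(bg, 20000)
  expect_true(all(GenomicRanges::width(bg) ==
                  median(GenomicRanges::width(peaks))))
  br <- seq(0, 1, by = 0.02)
  hp <- tabulate(findInterval(gc_fraction(peaks, g), br), nbins = length(br))
  hb <- tabulate(findInterval(bg$gc, br), nbins = length(br))
  expect_lt(max(abs(hp / sum(hp) - hb / sum(hb))), 0.01)
  ## determinism and the n = 0 edge
  bg2 <- sample_matched_background(peaks, g, 20000, seed = 203)
  expect_identical(gr_to_df(bg), gr_to_df(bg2))
  expect_length(sample_matched_background(peaks, g, 0, seed = 1), 0)
})

test_that("unreachable GC bins fail with the bin named", {
  ## a tiny GC island in an AT-only genome: the peaks' GC bin is nearly
  ## unreachable by uniform sampling, so the sampler must give up and name it
  g <- tiny_genome(c(s = paste0(paste(rep("AT", 50000), collapse = ""),
                                paste(rep("GC", 250), collapse = ""),
                                paste(rep("AT", 50000), collapse = ""))))
  peaks <- interval_set("s", 100000, 100500)
  expect_error(
    sample_matched_background(peaks, g, 500, region_length = 500,
                              max_batches = 2, seed = 1),
    "GC bin")
})

test_that("background sampling avoids assembly gaps and honours coverage filters", {
  set.seed(204)
  seq1 <- paste(sample(c("G", "C", "A", "T"), 2e5, TRUE), collapse = "")
  gapseq <- paste0(substr(seq1, 1, 1e5),
                   paste(rep("N", 5000), collapse = ""),
                   substr(seq1, 100001, 2e5))
  g <- tiny_genome(c(s = gapseq))
  peaks <- interval_set("s", seq(0, 9e4, by = 3000), seq(0, 9e4, by = 3000) + 400)
  bg <- sample_matched_background(peaks, g, 2000, seed = 205)
  expect_false(any(overlaps_any(bg, g$gaps)))
  ## windows restricted to the first half via a coverage filter
  filt <- function(gr) GenomicRanges::end(gr) <= 1e5
  bgf <- sample_matched_background(peaks, g, 500, coverage_filter = filt,
                                   seed = 206)
  expect_true(all(GenomicRanges::end(bgf) <= 1e5))
})

test_that("final peak call applies both rules and unions conditions", {
  ## hand-constructed toy: 4 candidates, 2 conditions x 2 replicates.
  ## library totals equal so m = r.
  cand <- interval_set("chr1", c(0, 1000, 2000, 3000), c(500, 1500, 2500, 3500),
                       name = paste0("p", 1:4))
  libs <- data.frame(library = c("2iL_rep1", "2iL_rep2", "SL_rep1", "SL_rep2"),
                     condition = rep(c("2iL", "SL"), each = 2),
                     replicate = rep(1:2, 2),
                     starr_total = 1e6, input_total = 1e6,
                     stringsAsFactors = FALSE)
  mk <- function(lib, cond, repl, k, u, r) {
    data.frame(region_id = paste0("p", 1:4), library = lib, condition = cond,
               replicate = repl, k = k, u = u, r = r, stringsAsFactors = FALSE)
  }
  ## p1, p2 strongly enriched everywhere; p3 enriched in replicate 1 only;
  ## p4 null
  counts <- rbind(
    mk("2iL_rep1", "2iL", 1, c(90, 80, 85, 10), c(12, 11, 12, 8), c(10, 10, 10, 10)),
    mk("2iL_rep2", "2iL", 2, c(95, 85, 11, 11), c(12, 12, 9, 9), c(10, 10, 10, 10)),
    mk("SL_rep1", "SL", 1, c(88, 82, 84, 9), c(12, 11, 12, 7), c(10, 10, 10, 10)),
    mk("SL_rep2", "SL", 2, c(90, 88, 12, 10), c(12, 12, 8, 8), c(10, 10, 10, 10)))
  pr <- list(alpha = 1, beta = 1)
  res <- call_starr_peaks(cand, counts, libs, starr_thresholds(),
                          priors = list(`2iL` = pr, SL = pr))
  got <- sort(res$per_condition[["2iL"]]$name)
  expect_identical(got, c("p1", "p2"))
  expect_identical(sort(res$union$name), c("p1", "p2"))
  ## p3 significant in one replicate only: excluded by the both-libraries rule
  expect_false("p3" %in% res$union$name)
  ## appears once even though both conditions pass
  expect_equal(sum(res$union$name == "p1"), 1)
  expect_true(all(res$records$pass[res$records$region_id %in% c("p1", "p2")]))
})

test_that("planted enhancers are recovered and nulls rarely called", {
  sim <- small_sim(n_regions = 2000, seed = 211)
  call <- call_starr_peaks(sim$regions, sim$counts, sim$libraries,
                           starr_thresholds())
  tr <- sim$truth
  active <- tr$region_id[tr$class_true %in% c("C1", "C2") &
                         pmax(tr$e_true_2iL, tr$e_true_SL) >= 4]
  called <- unique(call$records$region_id[call$records$pass])
  expect_gte(mean(active %in% called), 0.8)
  nulls <- tr$region_id[!tr$class_true %in% c("C1", "C2")]
  expect_lte(mean(nulls %in% called), 0.03)
})

test_that("zero-coverage candidates are reported but never called", {
  libs <- data.frame(library = c("2iL_rep1", "2iL_rep2", "SL_rep1", "SL_rep2"),
                     condition = rep(c("2iL", "SL"), each = 2),
                     replicate = rep(1:2, 2),
                     starr_total = 1e6, input_total = 1e6,
                     stringsAsFactors = FALSE)
  counts <- do.call(rbind, lapply(seq_len(4), function(j) {
    data.frame(region_id = "z", library = libs$library[j],
               condition = libs$condition[j], replicate = libs$replicate[j],
               k = 0L, u = 0L, r = 0L, stringsAsFactors = FALSE)
  }))
  et <- enrichment_table(counts, libs)
  expect_true(all(is.na(et$per_library$e_raw)))
  expect_true(all(et$per_library$p == 1))
})

test_that("depth convergence is flat at fraction 1 and counts peaks per fraction", {
  sim <- small_sim(n_regions = 600, seed = 221)
  th <- starr_thresholds()
  full <- call_starr_peaks(sim$regions, sim$counts, sim$libraries, th)
  tab <- depth_convergence(sim$regions, sim$counts, sim$libraries, th,
                           fractions = c(0.2, 0.6, 1.0), seed = 222)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$n_peaks[tab$fraction == 1], length(full$merged_union))
  expect_lte(tab$n_peaks[tab$fraction == 0.2], tab$n_peaks[tab$fraction == 1])
  ## the canonical fraction grid yields an 8-row table
  tab8 <- depth_convergence(sim$regions, sim$counts, sim$libraries, th,
                            seed = 223)
  expect_equal(nrow(tab8), 8)
  expect_equal(tab8$fraction, seq(0.2, 0.9, by = 0.1))
})
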