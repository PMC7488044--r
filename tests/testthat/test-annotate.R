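test_that("mutual overlap matches hand counts and is symmetric", {
  a <- interval_set("chr1", c(0, 200), c(100, 300))
  b <- interval_set("chr1", c(50, 400), c(60, 500))
  expect_equal(mutual_overlap(a, b), c(frac_a = 0.5, frac_b = 0.5))
  expect_equal(mutual_overlap(a, a), c(frac_a = 1, frac_b = 1))
  disj <- interval_set("chr2", 0, 10)
  expect_equal(mutual_overlap(a, disj), c(frac_a = 0, frac_b = 0))
  swapped <- mutual_overlap(b, a)
  expect_equal(unname(swapped), unname(mutual_overlap(a, b)[c(2, 1)]))
  expect_error(mutual_overlap(a, GenomicRanges::GRanges()), "non-empty")
  ## brute-force check on random sets
  set.seed(501)
  for (i in 1:100) {
    da <- rand_intervals(sample(1:20, 1)); db <- rand_intervals(sample(1:20, 1))
    got <- mutual_overlap(df_to_gr(da), df_to_gr(db))
    expect_equal(unname(got), c(mean(brute_overlaps(da, db)),
                                mean(brute_overlaps(db, da))))
  }
})

test_that("bp-level mutual overlap reports covered base fractions", {
  a <- interval_set("chr1", 0, 100)
  b <- interval_set("chr1", 50, 250)
  expect_equal(mutual_overlap(a, b, mode = "bp"),
               c(frac_a = 0.5, frac_b = 0.25))
})

test_that("overlap screen ranks peak sets by locus coverage", {
  loci <- interval_set("chr1", seq(0, 900, 100), seq(0, 900, 100) + 50)
  sets <- list(good = loci[1:8], poor = loci[1:2])
  rk <- rank_overlaps(loci, sets)
  expect_equal(rk$set, c("good", "poor"))
  expect_equal(rk$frac_loci, c(0.8, 0.2))
})

test_that("methylation windows take coverage-weighted means and flag empty windows", {
  sizes <- c(chr1 = 10000)
  loci <- interval_set("chr1", c(1000, 5000), c(1400, 5400),
                       name = c("a", "b"), summit = c(1200, 5200))
  track <- data.frame(chrom = "chr1",
                      pos = c(1100, 1300, 600, 2000),
                      frac = c(1.0, 0.0, 0.8, 0.9),
                      coverage = c(10, 30, 5, 50))
  got <- methylation_at_windows(loci, track, sizes)
  expect_equal(got$mean_mCpG[1], 0.25)         # (1*10 + 0*30) / 40
  expect_true(got$missing[2])
  ## single CpG window and the weighting switch
  one <- methylation_at_windows(interval_set("chr1", 500, 700, summit = 600),
                                track, sizes, flank = 100)
  expect_equal(one$mean_mCpG, 0.8)
  uw <- methylation_at_windows(loci, track, sizes, weighted = FALSE)
  expect_equal(uw$mean_mCpG[1], 0.5)
  ## low-coverage CpGs can be excluded
  mc <- methylation_at_windows(loci, track, sizes, min_coverage = 11)
  expect_equal(mc$mean_mCpG[1], 0.0)           # only the covered CpG remains
})

test_that("methylation means are invariant to splitting a CpG into half-coverage records", {
  sizes <- c(chr1 = 10000)
  loci <- interval_set("chr1", 1000, 1400, summit = 1200)
  track <- data.frame(chrom = "chr1", pos = c(1100, 1250),
                      frac = c(0.9, 0.3), coverage = c(20, 12))
  split_track <- data.frame(chrom = "chr1", pos = c(1100, 1100, 1250),
                            frac = c(0.9, 0.9, 0.3),
                            coverage = c(10, 10, 12))
  expect_equal(methylation_at_windows(loci, track, sizes)$mean_mCpG,
               methylation_at_windows(loci, split_track, sizes)$mean_mCpG)
})

test_that("motif background honours the per-library input coverage filter", {
  set.seed(502)
  seq1 <- paste(sample(c("G", "C", "A", "T"), 2e5, TRUE), collapse = "")
  g <- tiny_genome(c(s = seq1))
  peaks <- interval_set("s", seq(0, 9e4, 3000), seq(0, 9e4, 3000) + 500)
  ## dense fragments over the first half only, two libraries
  dense <- function() {
    st <- sort(sample(0:(1e5 - 300), 8000, replace = TRUE))
    interval_set("s", st, st + 300)
  }
  frags <- list(lib1 = dense(), lib2 = dense())
  bg <- export_motif_background(peaks, g, frags, 300, min_reads = 10,
                                seed = 503)
  expect_length(bg, 300)
  expect_true(all(GenomicRanges::width(bg) == 500))
  expect_true(all(GenomicRanges::start(bg) <= 1e5))
  for (fr in frags) {
    expect_true(all(GenomicRanges::countOverlaps(bg, fr) >= 10))
  }
  ## with the filter off it reduces to plain matched background
  bg0 <- export_motif_background(peaks, g, frags, 300, min_reads = 0,
                                 seed = 503)
  expect_length(bg0, 300)
  ## an unsatisfiable filter reports the failure
  expect_error(export_motif_background(peaks, g, frags, 300, min_reads = 1e6,
                                       seed = 504), "filter")
})

test_that("luciferase scaling recovers affine-transformed signals exactly", {
  starr <- setNames(c(1.2, 2.5, 0.4, 3.3, 1.9, 0.8), paste0("L", 1:6))
  mk <- function(locus, log2fvr, batch) {
    fvr <- 2^log2fvr
    data.frame(locus = locus, replicate = 1:3,
               firefly = fvr * c(1, 1, 1), renilla = 1, batch = batch,
               stringsAsFactors = FALSE)
  }
  ## measurements equal to STARR values, one batch: identity map, r = 1
  meas <- do.call(rbind, Map(mk, names(starr), starr, 1))
  out <- scale_luciferase(meas, control_fvr = 1, starr = starr)
  expect_equal(out$pearson_r, 1.0)
  expect_equal(sort(out$table$scaled), sort(unname(starr)), tolerance = 1e-9)
  ## affine transform on the log2 scale is undone by the scaling
  meas2 <- do.call(rbind, Map(mk, names(starr), 2 * starr + 3, 1))
  out2 <- scale_luciferase(meas2, control_fvr = 1, starr = starr)
  expect_equal(out2$pearson_r, 1.0)
  expect_equal(sort(out2$table$scaled), sort(unname(starr)), tolerance = 1e-9)
})

test_that("batch offsets are removed before scaling", {
  set.seed(504)
  starr <- setNames(rnorm(20, 1.5, 1), paste0("L", 1:20))
  batch <- rep(1:2, each = 10)
  shift <- ifelse(batch == 1, 0, 1.7)
  mk <- function(i) {
    fvr <- 2^(starr[i] + shift[i] + rnorm(3, 0, 1e-6))
    data.frame(locus = names(starr)[i], replicate = 1:3, firefly = fvr,
               renilla = 1, batch = batch[i], stringsAsFactors = FALSE)
  }
  meas <- do.call(rbind, lapply(1:20, mk))
  out <- scale_luciferase(meas, control_fvr = 1, starr = starr)
  ## the batch regression also removes the (small) signal difference that is
  ## confounded with batch, so recovery is near- but not exactly perfect
  expect_gt(out$pearson_r, 0.99)
  expect_error(scale_luciferase(meas[meas$replicate < 3, ], 1, starr),
               "replicates")
})

test_that("luciferase correlation is recovered under calibrated noise", {
  set.seed(505)
  rs <- replicate(20, {
    starr <- setNames(rnorm(39, 1.5, 1.2), paste0("L", 1:39))
    noisy <- starr + rnorm(39, 0, 0.9)  # sigma chosen for r ~ 0.8
    meas <- do.call(rbind, lapply(1:39, function(i) {
      data.frame(locus = names(starr)[i], replicate = 1:3,
                 firefly = 2^noisy[i] * exp(rnorm(3, 0, 0.01)), renilla = 1,
                 batch = 1, stringsAsFactors = FALSE)
    }))
    scale_luciferase(meas, 1, starr)$pearson_r
  })
  target <- 1.2 / sqrt(1.2^2 + 0.9^2) * sqrt(1)  # population correlation
  expect_equal(mean(rs), 0.8, tolerance = 0.05)
})
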