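test_that("putative-enhancer intersection matches a brute-force triple overlap", {
  atac <- interval_set("chr1", c(0, 100, 300), c(50, 200, 400))
  expect_identical(gr_to_df(apk_elements(atac, atac, atac)), gr_to_df(atac))
  disjoint <- apk_elements(interval_set("chr1", 0, 10),
                           interval_set("chr1", 20, 30),
                           interval_set("chr1", 40, 50))
  expect_length(disjoint, 0)
  set.seed(401)
  for (i in 1:50) {
    da <- brute_merge(rand_intervals(10, chroms = "chr1"))
    db <- brute_merge(rand_intervals(10, chroms = "chr1"))
    dc <- brute_merge(rand_intervals(10, chroms = "chr1"))
    got <- apk_elements(df_to_gr(da), df_to_gr(db), df_to_gr(dc))
    want <- da[brute_overlaps(da, db) & brute_overlaps(da, dc), ]
    rownames(want) <- NULL
    expect_identical(gr_to_df(got), want)
  }
  expect_warning(apk_elements(GenomicRanges::GRanges(),
                              df_to_gr(rand_intervals(3)),
                              df_to_gr(rand_intervals(3))), "empty")
})

test_that("classification applies the C1/C2/C3 rules on constructed records", {
  sizes <- c(chr1 = 100000)
  final <- interval_set("chr1", c(1000, 3000), c(1500, 3500),
                        name = c("pk1", "pk2"))
  active <- interval_set("chr1", 1100, 1200)  # covers pk1 only
  apk <- interval_set("chr1", c(10000, 20000, 30000, 40000),
                      c(10500, 20500, 30500, 40500),
                      name = paste0("apk", 1:4))
  tss <- interval_set("chr1", c(30100, 90000), c(30101, 90001))
  mk_rec <- function(id, ps) data.frame(region_id = id,
                                        library = paste0("L", 1:4),
                                        p = ps, stringsAsFactors = FALSE)
  per_lib <- rbind(mk_rec("apk1", c(0.5, 0.9, 0.3, 0.8)),   # quiet, distal -> C3
                   mk_rec("apk2", c(0.5, 0.9, 0.02, 0.8)),  # signal in one library
                   mk_rec("apk3", c(0.5, 0.9, 0.3, 0.8)),   # quiet but TSS-proximal
                   mk_rec("apk4", c(0.5, 0.07, 0.3, 0.8)))  # ambiguous zone
  ann <- list(active = active, tss = tss, apk = apk)
  out <- classify_loci(final, per_lib, ann, "2iL")
  lab <- setNames(out$label, out$region_id)
  expect_equal(lab[["pk1"]], "C1")
  expect_equal(lab[["pk2"]], "C2")
  expect_equal(lab[["apk1"]], "C3")
  expect_true(is.na(lab[["apk2"]]))
  expect_true(is.na(lab[["apk3"]]))
  expect_true(is.na(lab[["apk4"]]))
  rs <- setNames(out$reason, out$region_id)
  expect_equal(rs[["apk2"]], "starr_signal")
  expect_equal(rs[["apk3"]], "tss_proximal")
  expect_equal(rs[["apk4"]], "ambiguous_signal")
  ## emptying the active set moves pk1 from C1 to C2 (monotonicity)
  ann2 <- ann; ann2$active <- GenomicRanges::GRanges()
  out2 <- classify_loci(final, per_lib, ann2, "2iL")
  expect_equal(setNames(out2$label, out2$region_id)[["pk1"]], "C2")
})

test_that("noise-free synthetic chromatin yields labels that match the planted classes", {
  sim <- small_sim(n_regions = 1000, seed = 411, effect_meanlog = log(8),
                   differential_fraction = 0)
  chrom <- simulate_chromatin(sim$truth, sim$regions, sim$cfg, 412)
  call <- call_starr_peaks(sim$regions, sim$counts, sim$libraries,
                           starr_thresholds())
  tr <- sim$truth
  for (cn in c("2iL", "SL")) {
    cls <- classify_loci(call$per_condition[[cn]], call$per_library, chrom,
                         cn, regions = sim$regions)
    lab <- cls[!is.na(cls$label), ]
    truth_of <- tr$class_true[match(lab$region_id, tr$region_id)]
    ## restrict to loci whose call status agrees with planted activity: a
    ## planted enhancer whose input coverage was too thin to call carries
    ## no signal to classify and is indistinguishable from dormant
    consistent <- (lab$label %in% c("C1", "C2")) ==
      (truth_of %in% c("C1", "C2"))
    expect_gt(mean(consistent), 0.85)
    expect_identical(lab$label[consistent], truth_of[consistent])
  }
})

test_that("label partition invariants hold on random fixtures", {
  set.seed(421)
  for (i in 1:200) {
    nf <- sample(2:8, 1)
    final <- df_to_gr(brute_merge(rand_intervals(nf, chroms = "chr1",
                                                 max_pos = 5000, max_len = 200)))
    final$name <- paste0("pk", seq_along(final))
    napk <- sample(2:8, 1)
    apk <- df_to_gr(brute_merge(rand_intervals(napk, chroms = "chr1",
                                               max_pos = 5000, max_len = 200)))
    apk$name <- paste0("apk", seq_along(apk))
    active <- df_to_gr(rand_intervals(sample(0:4, 1), chroms = "chr1",
                                      max_pos = 5000, max_len = 300))
    tss <- df_to_gr(rand_intervals(sample(1:3, 1), chroms = "chr1",
                                   max_pos = 5000, max_len = 1))
    ids <- c(final$name, apk$name)
    per_lib <- do.call(rbind, lapply(1:4, function(j) {
      data.frame(region_id = ids, library = paste0("L", j),
                 p = runif(length(ids)), stringsAsFactors = FALSE)
    }))
    out <- classify_loci(final, per_lib, list(active = active, tss = tss,
                                              apk = apk), "2iL",
                         tss_min_distance = 500)
    ## exactly one row (label or recorded drop reason) per evaluated locus
    expect_false(any(duplicated(out$region_id[out$region_id %in% final$name])))
    expect_true(all(!is.na(out$label) | !is.na(out$reason) |
                    out$region_id %in% final$name))
    ## C1 u C2 = the final peaks; C3 never overlaps a final peak
    expect_setequal(out$region_id[out$label %in% c("C1", "C2") &
                                  !is.na(out$label)], final$name)
    c3 <- out[!is.na(out$label) & out$label == "C3", ]
    if (nrow(c3)) {
      c3gr <- interval_set(c3$chrom, c3$start, c3$end)
      expect_false(any(overlaps_any(c3gr, final)))
    }
  }
})

test_that("classification recovers planted labels despite modest chromatin noise", {
  sim <- small_sim(n_regions = 1000, seed = 431, effect_meanlog = log(8),
                   differential_fraction = 0, chromatin_noise = 0.05)
  chrom <- simulate_chromatin(sim$truth, sim$regions, sim$cfg, 432)
  call <- call_starr_peaks(sim$regions, sim$counts, sim$libraries,
                           starr_thresholds())
  cls <- classify_loci(call$per_condition[["2iL"]], call$per_library, chrom,
                       "2iL", regions = sim$regions)
  lab <- cls[!is.na(cls$label), ]
  truth_of <- sim$truth$class_true[match(lab$region_id, sim$truth$region_id)]
  consistent <- (lab$label %in% c("C1", "C2")) == (truth_of %in% c("C1", "C2"))
  expect_gte(mean(lab$label[consistent] == truth_of[consistent]), 0.9)
})
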