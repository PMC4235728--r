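test_that("default binning scheme tiles the window with the three regimes", {
  sch <- binning_scheme()
  bins <- sch$bins
  # contiguous tiling, no overlap, covering [200, 1150]
  expect_equal(bins$lo[1], 200)
  expect_equal(bins$hi[nrow(bins)], 1150)
  expect_equal(bins$lo[-1], bins$hi[-nrow(bins)])
  expect_equal(n_bins(sch), 167 + 60 + 15)
  # regime boundary bins are truncated: [698, 700) ends the 3-bp regime
  expect_true(any(bins$lo == 698 & bins$hi == 700))
  expect_true(any(bins$lo == 700 & bins$hi == 705))
  expect_true(any(bins$lo == 1140 & bins$hi == 1150))
})

test_that("the RFU floor excludes intensity <= 10 strictly", {
  pt <- peak_table(data.frame(sample_id = "S1", replicate_id = "r1",
                              size_bp = c(300, 301, 302),
                              intensity_rfu = c(9, 10, 10.5)))
  out <- filter_min_rfu(pt, filter_params(min_rfu = 10))
  expect_equal(out$intensity_rfu, 10.5)
  expect_equal(attr(out, "n_removed"), 2)

  # min_rfu = 0 keeps every strictly positive peak
  pos <- peak_table(random_peaks(100))
  pos$intensity_rfu <- pos$intensity_rfu + 0.01
  expect_equal(nrow(filter_min_rfu(peak_table(pos), filter_params(min_rfu = 0))),
               100)

  # retained set equals a literal comprehension filter on random peaks
  set.seed(7)
  big <- peak_table(random_peaks(1000))
  kept <- filter_min_rfu(big, filter_params())
  expect_equal(kept$intensity_rfu,
               big$intensity_rfu[big$intensity_rfu > 10])
})

test_that("window clip keeps both endpoints and removes outside peaks", {
  pt <- peak_table(data.frame(sample_id = "S1", replicate_id = "r1",
                              size_bp = c(150, 200.0, 1150.0, 1200),
                              intensity_rfu = rep(100, 4)))
  out <- clip_to_window(pt)
  expect_equal(out$size_bp, c(200.0, 1150.0))
  expect_equal(attr(out, "n_removed"), 2)
  inside <- peak_table(data.frame(sample_id = "S1", replicate_id = "r1",
                                  size_bp = c(400, 900), intensity_rfu = c(5, 5)))
  expect_equal(nrow(clip_to_window(inside)), 2)
  empty <- pt[pt$size_bp < 0, ]
  expect_equal(nrow(clip_to_window(peak_table(empty))), 0)
})

test_that("bin assignment follows the anchored grid and regime boundaries", {
  pt <- peak_table(data.frame(sample_id = "S1", replicate_id = "r1",
                              size_bp = c(250.4, 251.0),
                              intensity_rfu = c(500, 300)))
  prof <- assign_bins(pt)
  expect_equal(prof$bin, c("bp0248_0251", "bp0251_0254"))
  expect_equal(prof$intensity, c(500, 300))

  # regime boundary: 699.9 in the truncated [698,700), 700.2 in [700,705)
  pt2 <- peak_table(data.frame(sample_id = "S1", replicate_id = "r1",
                               size_bp = c(699.9, 700.2),
                               intensity_rfu = c(50, 50)))
  expect_equal(assign_bins(pt2)$bin, c("bp0698_0700", "bp0700_0705"))

  # exactly 700 and 1000 fall into the higher regime's first bin
  pt3 <- peak_table(data.frame(sample_id = "S1", replicate_id = "r1",
                               size_bp = c(700, 1000, 1150),
                               intensity_rfu = c(1, 2, 3)))
  expect_equal(assign_bins(pt3)$bin,
               c("bp0700_0705", "bp1000_1010", "bp1140_1150"))

  # single peak: conservation
  single <- peak_table(data.frame(sample_id = "S1", replicate_id = "r1",
                                  size_bp = 512.3, intensity_rfu = 77))
  p <- assign_bins(single)
  expect_equal(nrow(p), 1)
  expect_equal(p$intensity, 77)

  # unclipped peak violates the precondition
  outside <- peak_table(data.frame(sample_id = "S1", replicate_id = "r1",
                                   size_bp = 1500, intensity_rfu = 50))
  expect_error(assign_bins(outside), class = "arisacomp_internal_error")
})

test_that("bin intensities conserve the total of retained peaks", {
  set.seed(11)
  pt <- clip_to_window(filter_min_rfu(peak_table(random_peaks(1000))))
  prof <- assign_bins(pt)
  expect_equal(sum(prof$intensity), sum(pt$intensity_rfu), tolerance = 1e-9)
})

test_that("the 0.1% filter uses the pre-filter total, single pass, then renormalizes", {
  # total 920.9 RFU; the 0.9 RFU bin is 0.098% < 0.1% and must drop
  pt <- peak_table(data.frame(sample_id = "S1", replicate_id = "r1",
                              size_bp = c(300, 400, 500, 600),
                              intensity_rfu = c(500, 300, 120, 0.9)))
  prof <- relative_intensity_filter(assign_bins(pt), filter_params())
  expect_equal(nrow(prof), 3)
  expect_false(any(grepl("bp0599", prof$bin)))
  expect_equal(sum(prof$rel_intensity), 1, tolerance = 1e-9)

  # all bins equal -> nothing dropped
  eq <- peak_table(data.frame(sample_id = "S1", replicate_id = "r1",
                              size_bp = seq(300, 390, by = 10),
                              intensity_rfu = rep(100, 10)))
  expect_equal(nrow(relative_intensity_filter(assign_bins(eq), filter_params())), 10)

  # zero-total profile cannot be normalized
  zero <- assign_bins(peak_table(data.frame(sample_id = "S1", replicate_id = "r1",
                                            size_bp = 300, intensity_rfu = 0)))
  expect_error(relative_intensity_filter(zero, filter_params()),
               class = "arisacomp_empty_input_error")
})

test_that("composed pipeline matches the brute-force oracle on random peak sets", {
  set.seed(101)
  for (trial in 1:20) {
    df <- random_peaks(500)
    got <- package_process_profile(df)
    want <- oracle_process_profile(df$size_bp, df$intensity_rfu)
    want <- want[order(as.numeric(names(want)))]
    expect_equal(as.numeric(names(got)), as.numeric(names(want)))
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("every retained bin clears 0.1% of the pre-filter total", {
  set.seed(5)
  df <- random_peaks(800)
  pt <- clip_to_window(filter_min_rfu(peak_table(df)))
  prof0 <- assign_bins(pt)
  total <- sum(prof0$intensity)
  prof <- relative_intensity_filter(prof0, filter_params())
  expect_true(all(prof$intensity / total >= 0.001))
})

test_that("replicate QC computes Bray-Curtis on the bin union and merges by mean", {
  mk <- function(rep_id, bins, rel) {
    p <- data.frame(sample_id = "S1", replicate_id = rep_id, bin = bins,
                    intensity = NA_real_, rel_intensity = rel)
    class(p) <- c("binned_profiles", "data.frame")
    p
  }
  # identical replicates: similarity 1, merge = input
  p1 <- mk("r1", c("a", "b"), c(0.6, 0.4))
  res <- merge_technical_replicates(p1, mk("r2", c("a", "b"), c(0.6, 0.4)))
  expect_equal(res$similarity, 1)
  expect_true(res$passed)
  expect_equal(res$merged_profile$rel_intensity, c(0.6, 0.4))

  # disjoint bins: similarity 0, no merge
  res0 <- merge_technical_replicates(p1, mk("r2", c("c", "d"), c(0.5, 0.5)))
  expect_equal(res0$similarity, 0)
  expect_false(res0$passed)
  expect_null(res0$merged_profile)

  # hand-computed 3-bin case: x=(0.5,0.5,0), y=(0.35,0.5,0.15)
  # BC similarity = 2*(0.35+0.5)/(1+1) = 0.85 >= 0.8 -> pass
  p3 <- mk("r1", c("a", "b"), c(0.5, 0.5))
  p4 <- mk("r2", c("a", "b", "c"), c(0.35, 0.5, 0.15))
  res3 <- merge_technical_replicates(p3, p4, min_similarity = 0.8)
  expect_equal(res3$similarity, 0.85, tolerance = 1e-12)
  expect_true(res3$passed)
  expect_equal(sum(res3$merged_profile$rel_intensity), 1, tolerance = 1e-12)
  # same pair against a stricter threshold fails QC without error
  expect_false(merge_technical_replicates(p3, p4, min_similarity = 0.9)$passed)
})

test_that("profile assembly yields a relative-intensity OTU table with zeros filled", {
  p <- data.frame(sample_id = c("S1", "S1", "S2", "S2"),
                  replicate_id = "merged",
                  bin = c("bp0200_0203", "bp0300_0303", "bp0300_0303", "bp0400_0403"),
                  intensity = NA_real_,
                  rel_intensity = c(0.7, 0.3, 0.4, 0.6))
  class(p) <- c("binned_profiles", "data.frame")
  tab <- profiles_to_otu_table(p)
  expect_equal(dim(tab), c(2, 3))
  expect_equal(unclass(tab)["S1", ], c(bp0200_0203 = 0.7, bp0300_0303 = 0.3,
                                       bp0400_0403 = 0))
  expect_equal(unclass(tab)["S2", "bp0200_0203"], 0)
  expect_equal(abundance_kind(tab), "relative_intensity")

  one <- profiles_to_otu_table(p[p$sample_id == "S1", ])
  expect_equal(rowSums(unclass(one)), c(S1 = 1), tolerance = 1e-9)

  expect_error(profiles_to_otu_table(p[0, ]), class = "arisacomp_empty_input_error")
})

test_that("per-sample ARISA richness never exceeds the scheme's bin count", {
  sim <- simulate_dataset(seed = 4)
  res <- process_arisa(sim$peaks)
  expect_true(all(observed_otus(res$otu_table)$per_sample <= n_bins(binning_scheme())))
})
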