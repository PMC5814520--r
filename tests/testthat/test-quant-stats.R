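test_that("cv_percent follows the sample-sd definition", {
  expect_equal(cv_percent(c(5, 5, 5)), 0)
  expect_equal(cv_percent(c(1, 2, 3)), 50) # sd 1, mean 2
  expect_equal(cv_percent(10 * c(1, 2, 3)), cv_percent(c(1, 2, 3)))
  expect_warning(expect_true(is.na(cv_percent(c(1)))), "undefined")
  expect_warning(expect_true(is.na(cv_percent(c(-2, 1)))), "undefined")
})

test_that("residue-pair CV is the median of member feature CVs", {
  expect_equal(residue_pair_cv(c(10, 20, 40)), 20)
  expect_equal(residue_pair_cv(c(10, 30)), 20) # midpoint convention
  expect_equal(residue_pair_cv(14), 14)
  expect_true(is.na(residue_pair_cv(NA_real_)))
})

test_that("saturation matches brute-force subset enumeration", {
  sets <- list(c("A", "B"), c("B", "C"))
  sc <- saturation_curve(sets)
  expect_equal(sc$mean_pairs, c(2, 3))
  set.seed(15)
  rand_sets <- lapply(1:6, function(i)
    sample(LETTERS[1:12], sample(3:8, 1)))
  sc <- saturation_curve(rand_sets)
  for (k in 1:6) {
    expect_equal(sc$mean_pairs[k], oracle_saturation(rand_sets, k))
  }
  # monotone, and exhaustive at k = n
  expect_true(all(diff(sc$mean_pairs) >= 0))
  expect_equal(sc$mean_pairs[6], length(unique(unlist(rand_sets))))
  ident <- replicate(4, c("X", "Y", "Z"), simplify = FALSE)
  expect_true(all(saturation_curve(ident)$mean_pairs == 3))
  expect_error(saturation_curve(sets, k = 5), "out of range")
})

test_that("observation frequency partitions the union", {
  of <- observation_frequency(list(c("A", "B"), c("B", "C")))
  expect_equal(of$count, c(2, 1))
  expect_equal(observation_frequency(list(c("A", "B")))$count, 2)
  set.seed(16)
  rand_sets <- lapply(1:7, function(i) sample(LETTERS, sample(4:10, 1)))
  of <- observation_frequency(rand_sets)
  expect_equal(of$count, oracle_observation_frequency(rand_sets))
  expect_equal(sum(of$count), length(unique(unlist(rand_sets))))
})

test_that("overlap counts reproduce the replica-comparison partition", {
  rr <- as.character(1:196)
  ir <- as.character(c(1:155, 1000:1024))
  expect_equal(overlap_counts(rr, ir),
               c(only1 = 41, shared = 155, only2 = 25))
  expect_equal(overlap_counts(c("a", "b"), c("c")),
               c(only1 = 2, shared = 0, only2 = 1))
  expect_equal(overlap_counts(rr, rr),
               c(only1 = 0, shared = 196, only2 = 0))
})

test_that("CV decreases across intensity bins when generated that way", {
  set.seed(17)
  area <- 10^runif(120, 4, 8)
  cv <- 60 - 6 * log2(area) / 2 + rnorm(120, 0, 2)
  pt <- data.frame(res_pair = paste0("p", 1:120), n_features = 1,
                   median_area = area, pair_cv = cv)
  bins <- cv_by_intensity_bins(pt)
  expect_gt(nrow(bins), 3)
  expect_lt(suppressWarnings(
    cor(bins$bin, bins$median_cv, method = "spearman")), 0)
  # all pairs in one bin when areas are equal
  one <- cv_by_intensity_bins(data.frame(res_pair = "a", n_features = 1,
                                         median_area = rep(1024, 5),
                                         pair_cv = 1:5))
  expect_identical(nrow(one), 1L)
  # permutation invariance
  perm <- sample(nrow(pt))
  expect_equal(cv_by_intensity_bins(pt[perm, ]), bins)
  expect_warning(cv_by_intensity_bins(
    data.frame(res_pair = c("a", "b"), n_features = 1,
               median_area = c(-1, 8), pair_cv = c(5, 5))), "non-positive")
})

test_that("co-elution and complete-quantitation filters act on planted pairs", {
  truth <- simulate_truth(n_pairs = 10, n_runs = 4, experiment = "injection",
                          n_decoys = 0, seed = 55)
  runs <- simulate_runs(truth)
  lf <- linearize_psms(truth$psms)
  q <- suppressWarnings(quantify_features(lf, runs))
  fc <- feature_cv_table(lf, q)
  co <- filter_coeluting_alternatives(fc, q)
  expect_setequal(co$removed, truth$coelute_pairs)
  expect_true(all(truth$separated_pairs %in% co$retained))
  cq <- filter_complete_quant(fc, q, n_runs = 4)
  absent_pair <-
    truth$features$res_pair[truth$features$feature == truth$absent$feature]
  expect_true(absent_pair %in% cq$removed)
  expect_false(absent_pair %in% cq$retained)
})

test_that("pair CVs are invariant to uniform area rescaling", {
  truth <- simulate_truth(n_pairs = 8, n_runs = 3, experiment = "injection",
                          n_decoys = 0, seed = 56)
  runs <- simulate_runs(truth)
  lf <- linearize_psms(truth$psms)
  q <- suppressWarnings(quantify_features(lf, runs))
  fc1 <- feature_cv_table(lf, q)
  q2 <- q
  q2$area <- q2$area * 7
  fc2 <- feature_cv_table(lf, q2)
  expect_equal(fc2$cv, fc1$cv, tolerance = 1e-10)
  expect_equal(pair_cv_table(fc2)$pair_cv, pair_cv_table(fc1)$pair_cv,
               tolerance = 1e-10)
})
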