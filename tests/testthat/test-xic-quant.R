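test_that("ms1_run validates its retention-time axis", {
  expect_error(ms1_run("r", c(1, 1), list(cbind(500, 1), cbind(500, 1))),
               "strictly increasing")
  r <- ms1_run("r", c(1, 2), list(cbind(c(502, 500), c(1, 2)), cbind(501, 3)))
  expect_equal(r$peaks[[1]][, "mz"], c(500, 502)) # sorted on construction
})

test_that("XIC extraction honours the m/z tolerance window", {
  rt <- c(1, 2, 3)
  mono <- 500
  run <- make_run("r", rt, list(
    cbind(mono, 10),                     # exactly on M
    cbind(mono + 0.056, 99),             # just outside the 0.055 window
    cbind(c(mono - 0.054, mono + 0.03), c(5, 7)) # two inside -> summed
  ))
  tr <- extract_xic(run, mono, charge = 2)
  expect_equal(tr$intensity[, 1], c(10, 0, 12))
  expect_equal(tr$intensity[, 2], c(0, 0, 0)) # nothing at M+1
  # precursor outside the instrument range: flagged, not an error
  low <- extract_xic(run, 399, charge = 2)
  expect_false(low$quantifiable)
  expect_true(all(low$intensity == 0))
})

test_that("XIC extraction matches a brute-force window sum", {
  set.seed(8)
  rt <- seq(1, 5, by = 0.2)
  peaks <- lapply(rt, function(t)
    cbind(runif(30, 495, 505), runif(30, 1, 100)))
  run <- make_run("r", rt, peaks)
  mono <- 499.7
  z <- 3
  tol <- 0.055
  tr <- extract_xic(run, mono, z, tolerance = tol)
  for (k in 0:2) {
    centre <- mono + k * 1.003355 / z
    brute <- vapply(peaks, function(p)
      sum(p[abs(p[, 1] - centre) <= tol, 2]), numeric(1))
    expect_equal(tr$intensity[, k + 1], brute)
  }
})

test_that("enlarging the m/z window never decreases intensities", {
  set.seed(9)
  rt <- seq(1, 3, by = 0.1)
  peaks <- lapply(rt, function(t) cbind(runif(50, 498, 502), runif(50, 1, 10)))
  run <- make_run("r", rt, peaks)
  tols <- c(0.02, 0.055, 0.2, 1)
  prev <- NULL
  for (tol in tols) {
    tr <- extract_xic(run, 500, 2, tolerance = tol)
    if (!is.null(prev)) expect_true(all(tr$intensity >= prev - 1e-12))
    prev <- tr$intensity
  }
})

test_that("peak areas match the analytic Gaussian integral", {
  rt <- seq(0, 10, by = 0.05)
  amp <- 1e6
  sigma <- 0.12
  y <- amp * exp(-(rt - 5)^2 / (2 * sigma^2))
  pk <- pick_peak(make_trace(rt, y), rt_seed = 5)
  expect_true(pk$matched)
  expect_equal(pk$apex_rt, 5, tolerance = 0.05)
  expect_lt(abs(pk$area - gaussian_area(amp, sigma)) /
              gaussian_area(amp, sigma), 0.01)
  expect_true(pk$rt_start < pk$apex_rt && pk$apex_rt < pk$rt_end)
})

test_that("baseline-separated peaks are integrated independently", {
  rt <- seq(0, 10, by = 0.05)
  sigma <- 0.1
  y <- 5e5 * exp(-(rt - 3)^2 / (2 * sigma^2)) +
       2e5 * exp(-(rt - 7)^2 / (2 * sigma^2))
  pk <- pick_peak(make_trace(rt, y), rt_seed = 7)
  expect_equal(pk$apex_rt, 7, tolerance = 0.05)
  expect_lt(abs(pk$area - gaussian_area(2e5, sigma)) /
              gaussian_area(2e5, sigma), 0.01)
  expect_gt(pk$rt_start, 4) # the first peak stays outside the boundaries
})

test_that("an all-zero trace yields a zero, unmatched result", {
  pk <- pick_peak(make_trace(seq(0, 5, 0.1), rep(0, 51)), rt_seed = 2)
  expect_false(pk$matched)
  expect_identical(pk$area, 0)
})

test_that("summed-trace area equals the sum of per-isotope areas", {
  rt <- seq(0, 4, by = 0.05)
  m <- cbind(1e5 * exp(-(rt - 2)^2 / 0.02),
             5e4 * exp(-(rt - 2)^2 / 0.02),
             1e4 * exp(-(rt - 2)^2 / 0.02))
  l <- 20; r <- 60
  total <- pracma::trapz(rt[l:r], rowSums(m)[l:r])
  per_iso <- sum(vapply(1:3, function(k)
    pracma::trapz(rt[l:r], m[l:r, k]), numeric(1)))
  expect_equal(total, per_iso)
})

test_that("area scales linearly with spectral intensity", {
  rt <- seq(0, 6, by = 0.05)
  y <- 1e5 * exp(-(rt - 3)^2 / (2 * 0.01))
  peaks <- lapply(y, function(v) cbind(500, v))
  run1 <- make_run("a", rt, peaks)
  run3 <- make_run("a", rt, lapply(peaks, function(p) cbind(p[, 1], 3 * p[, 2])))
  a1 <- pick_peak(extract_xic(run1, 500, 2), 3)$area
  a3 <- pick_peak(extract_xic(run3, 500, 2), 3)$area
  expect_equal(a3, 3 * a1)
})

test_that("RT alignment recovers a constant offset", {
  set.seed(4)
  t_ref <- sort(runif(12, 2, 20))
  anchors <- rbind(
    data.frame(run_id = "ref", feature = paste0("f", 1:12), apex_rt = t_ref),
    data.frame(run_id = "shift", feature = paste0("f", 1:10),
               apex_rt = t_ref[1:10] + 0.5))
  al <- align_rt(anchors)
  expect_identical(attr(al, "reference"), "ref")
  mapped <- map_rt(al, "shift", t_ref[1:10] + 0.5)
  expect_true(all(abs(mapped - t_ref[1:10]) < 0.05))
  # zero-offset replicates map to themselves
  al0 <- align_rt(rbind(
    data.frame(run_id = "a", feature = paste0("f", 1:8), apex_rt = t_ref[1:8]),
    data.frame(run_id = "b", feature = paste0("f", 1:8), apex_rt = t_ref[1:8])))
  expect_true(all(abs(map_rt(al0, "b", t_ref[1:8]) - t_ref[1:8]) < 1e-6))
  # single run: identity
  al1 <- align_rt(data.frame(run_id = "a", feature = "f1", apex_rt = 5))
  expect_equal(map_rt(al1, "a", 5), 5)
  # too few anchors: identity with a warning
  expect_warning(align_rt(rbind(
    data.frame(run_id = "a", feature = c("f1", "f2", "f3"), apex_rt = 1:3),
    data.frame(run_id = "b", feature = c("f1", "f2"), apex_rt = c(1.1, 2.1)))),
    "anchors")
})

test_that("match between runs quantifies unidentified replicas", {
  truth <- simulate_truth(n_pairs = 6, n_runs = 3, cv_target = 0,
                          rt_jitter_sd = 0, noise_floor_rel = 0,
                          n_decoys = 0, id_prob = 0.5, seed = 31)
  runs <- simulate_runs(truth)
  lf <- linearize_psms(truth$psms)
  q <- suppressWarnings(quantify_features(lf, runs))
  # every (feature, run) combination is present
  expect_identical(nrow(q), length(unique(lf$feature)) * 3L)
  mbr <- q[!q$identified, ]
  expect_gt(nrow(mbr), 0)
  # features present in the sample are recovered even where unidentified
  truth_area <- truth$areas[cbind(match(q$feature, rownames(truth$areas)),
                                  match(q$run_id, colnames(truth$areas)))]
  present <- truth_area > 0
  expect_true(all(q$area[present & !q$identified] > 0))
  # a feature truly absent in a run stays near zero
  ab <- q[q$feature == truth$absent$feature &
            q$run_id == sprintf("run%02d", truth$absent$run), ]
  expect_false(ab$above_floor)
})

test_that("mzML files round-trip through write and read", {
  truth <- simulate_truth(n_pairs = 6, n_runs = 1, cv_target = 0,
                          rt_jitter_sd = 0, n_decoys = 0, seed = 13)
  run <- simulate_runs(truth)[[1]]
  path <- withr::local_tempfile(fileext = ".mzML")
  write_run_mzml(run, path)
  back <- read_ms1_run(path, run_id = run$run_id)
  expect_equal(back$rt, run$rt, tolerance = 1e-6)
  expect_identical(length(back$peaks), length(run$peaks))
  i <- which.max(vapply(run$peaks, nrow, integer(1)))
  expect_equal(back$peaks[[i]], run$peaks[[i]], tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_error(read_ms1_run(withr::local_tempfile(fileext = ".mzML")),
               "not found")
})
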