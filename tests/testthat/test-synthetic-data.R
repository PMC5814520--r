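test_that("tryptic digestion matches the brute-force cleavage oracle", {
  # proline suppression: K2 cleaves, R3 before P does not
  akrp <- digest("AKRP", max_missed = 0, min_length = 1)
  expect_setequal(akrp$sequence, c("AK", "RP"))
  aak <- digest("AAKAA", max_missed = 0, min_length = 1)
  expect_setequal(aak$sequence, c("AAK", "AA"))
  # default length window drops short peptides
  expect_false("AAK" %in% digest("AAKAA")$sequence)

  set.seed(23)
  alphabet <- names(amino_acid_masses())
  for (i in 1:15) {
    seqn <- paste(sample(alphabet, sample(30:200, 1), replace = TRUE,
                         prob = ifelse(alphabet %in% c("K", "R", "P"),
                                       3, 1)),
                  collapse = "")
    mm <- sample(0:4, 1)
    got <- digest(seqn, max_missed = mm, min_length = 1)
    expect_identical(sort(got$sequence), oracle_digest(seqn, mm))
    # coordinates are consistent
    expect_true(all(substring(seqn, got$start, got$end) == got$sequence))
  }
})

test_that("digest respects the peptide length window", {
  got <- digest("AAAAKBB", max_missed = 0) # default window 6..60
  expect_true(all(nchar(got$sequence) >= 6 & nchar(got$sequence) <= 60))
})

test_that("synthetic truth is deterministic under its seed", {
  t1 <- simulate_truth(n_pairs = 8, n_runs = 3, experiment = "reaction",
                       seed = 77)
  t2 <- simulate_truth(n_pairs = 8, n_runs = 3, experiment = "reaction",
                       seed = 77)
  expect_identical(t1$protein, t2$protein)
  expect_identical(t1$psms, t2$psms)
  expect_identical(t1$areas, t2$areas)
  expect_identical(t1$pdb_coords, t2$pdb_coords)
  t3 <- simulate_truth(n_pairs = 8, n_runs = 3, experiment = "reaction",
                       seed = 78)
  expect_false(identical(t1$areas, t3$areas))
})

test_that("experiment presets carry the replica-design noise levels", {
  ti <- simulate_truth(n_pairs = 6, n_runs = 2, experiment = "injection",
                       seed = 1)
  tr <- simulate_truth(n_pairs = 6, n_runs = 2, experiment = "reaction",
                       seed = 1)
  expect_equal(ti$params$cv_target, 14)
  expect_equal(tr$params$cv_target, 32)
  expect_equal(ti$params$rt_jitter_sd, 0.1)
  expect_equal(tr$params$rt_jitter_sd, 0.3)
  expect_error(simulate_truth(n_pairs = 6, n_runs = 2), "seed")
  expect_error(simulate_truth(n_pairs = 3, n_runs = 2, seed = 1),
               "at least 6")
})

test_that("all generated PSMs pass mass equivalence and site rules", {
  truth <- simulate_truth(n_pairs = 10, n_runs = 3, experiment = "injection",
                          seed = 41)
  lt <- linearize_psms(truth$psms)
  expect_true(all(lt$mass_error < 1e-4))
  targets <- truth$psms[!truth$psms$is_decoy, ]
  aa_at <- function(pep, pos) substr(pep, pos, pos)
  expect_true(all(aa_at(targets$pep_a, targets$site_a) %in%
                    c("K", "S", "T", "Y")))
  expect_true(all(aa_at(targets$pep_b, targets$site_b) %in%
                    c("K", "S", "T", "Y")))
})

test_that("rendered spectra stay inside the instrument m/z range", {
  truth <- simulate_truth(n_pairs = 6, n_runs = 1, experiment = "injection",
                          seed = 19)
  run <- simulate_runs(truth)[[1]]
  mzs <- unlist(lapply(run$peaks, function(p) p[, 1]))
  expect_true(all(mzs >= 400 & mzs <= 1600))
})

test_that("noiseless rendering recovers ground-truth areas within 1%", {
  truth <- simulate_truth(n_pairs = 8, n_runs = 2, cv_target = 0,
                          rt_jitter_sd = 0, noise_floor_rel = 0,
                          n_decoys = 0, seed = 5)
  runs <- simulate_runs(truth)
  lf <- linearize_psms(truth$psms)
  q <- suppressWarnings(quantify_features(lf, runs))
  truth_area <- truth$areas[cbind(match(q$feature, rownames(truth$areas)),
                                  match(q$run_id, colnames(truth$areas)))]
  # co-eluting alternative linkages share one m/z and RT: their signals are
  # inseparable by construction (the co-elution filter removes them);
  # everything else must recover within 1%
  coel_feats <-
    truth$features$feature[truth$features$res_pair %in% truth$coelute_pairs]
  ok <- !(q$feature %in% coel_feats) & truth_area > 0
  rel <- abs(q$area[ok] - truth_area[ok]) / truth_area[ok]
  expect_lt(max(rel), 0.01)
  # with zero noise, per-feature areas are identical across replicas
  areas_wide <- tapply(q$area[ok], list(q$feature[ok], q$run_id[ok]), sum)
  spread <- apply(areas_wide, 1, function(v) diff(range(v)) / mean(v))
  expect_lt(max(spread, na.rm = TRUE), 0.005)
})

test_that("a rendered world materializes on disk and reloads", {
  truth <- simulate_truth(n_pairs = 6, n_runs = 2, experiment = "injection",
                          seed = 61)
  dir <- withr::local_tempdir()
  paths <- render_world(truth, dir)
  expect_true(all(file.exists(unlist(paths))))
  psms <- read_psm_table(paths$psms)
  expect_equal(psms, truth$psms, ignore_attr = TRUE)
  model <- load_ca_coords(paths$pdb, chain = "A")
  expect_identical(nrow(model), nchar(truth$protein))
  run1 <- read_ms1_run(paths$mzml[1])
  expect_identical(length(run1$rt), length(simulate_runs(truth)[[1]]$rt))
  tj <- jsonlite::read_json(paths$truth)
  expect_equal(tj$params$cv_target, 14)
})

test_that("planted structure violations sit beyond the linker limit", {
  truth <- simulate_truth(n_pairs = 10, n_runs = 2, experiment = "injection",
                          n_distance_violations = 3, seed = 83)
  model <- structure(truth$pdb_coords,
                     class = c("structure_model", "data.frame"), chain = "A")
  ij <- do.call(rbind, strsplit(truth$pairs$res_pair, "-"))
  d <- ca_distance(model, as.integer(ij[, 1]), as.integer(ij[, 2]))
  viol <- truth$pairs$res_pair %in% truth$violating_pairs
  expect_true(all(d[viol] >= 30))
  expect_true(all(d[!viol] < 30))
})
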