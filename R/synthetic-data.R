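# Self-contained synthetic test worlds: a random protein, its tryptic
# peptides, cross-linked pairs with ground-truth areas, replicate MS1 runs
# rendered as centroided spectra (in memory or as mzML), a matching PSM
# table, and a toy PDB whose distances are arranged so a configurable
# subset of pairs violates the cross-linker limit. Everything is
# regenerable bit-identically from (parameters, seed).

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P, and enumerates
#' all peptides with up to `max_missed` missed cleavages, then applies the
#' peptide length window.
#'
#' @param sequence Protein residue string.
#' @param max_missed Maximum missed cleavages (default 4).
#' @param min_length,max_length Peptide length window (defaults 6 and 60).
#' @return data.frame: `sequence`, `start`, `end` (protein coordinates,
#'   1-based inclusive), `missed`.
#' @export
#' @examples
#' digest("AAKAA", max_missed = 0, min_length = 1)
digest <- function(sequence, max_missed = 4L, min_length = 6L,
                   max_length = 60L) {
  stopifnot(nzchar(sequence))
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- unique(c(0L, cut_after, n))
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  n_seg <- length(starts)
  rows <- list()
  for (i in seq_len(n_seg)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > n_seg) break
      s <- starts[i]; e <- ends[j]
      len <- e - s + 1L
      if (len < min_length || len > max_length) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(sequence, s, e), start = s, end = e, missed = m,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(sequence = character(), start = integer(),
                      end = integer(), missed = integer()))
  }
  do.call(rbind, rows)
}

# expected sample sd of n draws understates the population sd by c4(n);
# the generator inflates sigma accordingly so the *sample* CV of the
# rendered replicas lands on the target
.c4 <- function(n) sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)

.lognormal_sigma <- function(cv_percent, n_runs) {
  if (cv_percent <= 0) return(0)
  cv <- cv_percent / 100
  if (n_runs >= 2L) cv <- cv / .c4(n_runs)
  sqrt(log(1 + cv^2))
}

# random residue block ending in K/R, with two internal S/T/Y so every
# peptide offers at least two linkable side chains; P and C excluded from
# the synthetic protein (digest() handles them, see its tests)
.random_block <- function(len) {
  pool <- c("A", "D", "E", "F", "G", "H", "I", "L", "M", "N", "Q", "V", "W")
  aa <- sample(pool, len - 1L, replace = TRUE)
  sty <- sample(2:(len - 2L), 2L)
  aa[sty] <- sample(c("S", "T", "Y"), 2L, replace = TRUE)
  c(aa, sample(c("K", "R"), 1L))
}

#' Build a synthetic ground-truth world
#'
#' Defines a random protein, cross-linked tryptic peptide pairs, charge
#' states, ground-truth peak areas with multiplicative log-normal
#' between-replica noise, a retention-time schedule with per-replica
#' jitter, an identification schedule (so match-between-runs is
#' exercised), decoy PSMs, and toy structure coordinates. Two filter
#' challenges are always planted: one pair of alternative linkage variants
#' that co-elute (same peptides, same charge, same apex) and one variant
#' pair fully separated in RT; plus one feature absent from one run.
#'
#' @param n_pairs Number of target residue pairs (>= 6).
#' @param n_runs Number of replicate runs.
#' @param experiment `"injection"` (defaults: CV 14%, RT jitter sd 0.1 min)
#'   or `"reaction"` (CV 32%, jitter sd 0.3 min) replica design.
#' @param cv_target Between-replica CV target in percent; overrides the
#'   experiment default.
#' @param rt_jitter_sd RT jitter standard deviation in minutes; overrides
#'   the experiment default.
#' @param gradient_min Gradient length in minutes.
#' @param cycle_s MS1 cycle time in seconds (default 3).
#' @param charges Candidate precursor charge states.
#' @param n_decoys Decoy PSMs appended to the PSM table.
#' @param n_distance_violations Pairs placed beyond the 30 A limit in the
#'   toy structure.
#' @param intensity_dependent_cv If `TRUE`, the per-feature CV decreases
#'   log-linearly with base area across `cv_range` instead of being
#'   constant.
#' @param cv_range CV range (percent) used when `intensity_dependent_cv`.
#' @param log10_area_range Base-area range, log10 units.
#' @param id_prob Per-run identification probability of each feature.
#' @param peak_sigma_min Chromatographic peak sigma in minutes.
#' @param noise_floor_rel Noise-centroid intensity relative to the median
#'   feature apex height; 0 renders noiseless runs.
#' @param seed Mandatory RNG seed.
#' @return Object of class `synthetic_truth` (a list; see fields in the
#'   implementation) with the PSM table in `$psms`, per-feature truth in
#'   `$features`, per-run truth areas in `$areas`, and structure
#'   coordinates in `$pdb_coords`.
#' @export
simulate_truth <- function(n_pairs = 20L, n_runs = 10L,
                           experiment = c("injection", "reaction"),
                           cv_target = NULL, rt_jitter_sd = NULL,
                           gradient_min = 24, cycle_s = 3,
                           charges = 3:5, n_decoys = 3L,
                           n_distance_violations = 3L,
                           intensity_dependent_cv = FALSE,
                           cv_range = c(8, 45),
                           log10_area_range = c(5, 7),
                           id_prob = 0.7, peak_sigma_min = 0.1,
                           noise_floor_rel = 0.002, seed) {
  experiment <- match.arg(experiment)
  if (missing(seed)) stop("a seed is mandatory")
  if (n_pairs < 6L) stop("need at least 6 pairs (filter plants need 4)")
  if (is.null(cv_target)) {
    cv_target <- if (experiment == "injection") 14 else 32
  }
  if (is.null(rt_jitter_sd)) {
    rt_jitter_sd <- if (experiment == "injection") 0.1 else 0.3
  }
  set.seed(seed)

  # protein from tryptic blocks; need one peptide per pair end
  n_blocks <- 2L * n_pairs + 6L
  blocks <- lapply(sample(9:13, n_blocks, replace = TRUE), .random_block)
  protein <- paste(unlist(blocks), collapse = "")
  peps <- digest(protein, max_missed = 0L)
  if (nrow(peps) < 2L * n_pairs + 2L) stop("infeasible parameters: too few peptides for ", n_pairs, " pairs")

  pep_sites <- function(p) {
    aa <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
    which(aa %in% c("K", "S", "T", "Y"))
  }

  # assign peptides: indices 1..4 feed the planted variant pairs
  ord <- sample(nrow(peps))
  pick <- function(k) peps[ord[k], , drop = FALSE]

  pairs <- list()
  add_pair <- function(pa, sa, pb, sb, tag) {
    list(pep_a = pa$sequence, site_a = sa,
         pep_b = pb$sequence, site_b = sb,
         prot_a = pa$start - 1L + sa, prot_b = pb$start - 1L + sb,
         tag = tag)
  }
  # co-eluting alternative linkages: same peptides, two sites in pep A
  p1 <- pick(1L); p2 <- pick(2L)
  s1 <- pep_sites(p1); s2 <- pep_sites(p2)
  pairs[[1L]] <- add_pair(p1, s1[1L], p2, s2[1L], "coelute")
  pairs[[2L]] <- add_pair(p1, s1[2L], p2, s2[1L], "coelute")
  # separated alternative linkages
  p3 <- pick(3L); p4 <- pick(4L)
  s3 <- pep_sites(p3); s4 <- pep_sites(p4)
  pairs[[3L]] <- add_pair(p3, s3[1L], p4, s4[1L], "separated")
  pairs[[4L]] <- add_pair(p3, s3[2L], p4, s4[1L], "separated")
  # plain pairs on fresh peptides
  for (k in seq_len(n_pairs - 4L)) {
    pa <- pick(3L + 2L * k); pb <- pick(4L + 2L * k)
    sa <- pep_sites(pa); sb <- pep_sites(pb)
    pairs[[4L + k]] <- add_pair(pa, sample(sa, 1L), pb, sample(sb, 1L),
                                "plain")
  }

  pair_df <- do.call(rbind, lapply(pairs, function(p)
    data.frame(pep_a = p$pep_a, site_a = p$site_a, pep_b = p$pep_b,
               site_b = p$site_b, prot_a = p$prot_a, prot_b = p$prot_b,
               tag = p$tag, stringsAsFactors = FALSE)))
  pair_df$res_pair <- vapply(seq_len(nrow(pair_df)), function(i)
    paste(sort(c(pair_df$prot_a[i], pair_df$prot_b[i])), collapse = "-"),
    character(1))
  if (anyDuplicated(pair_df$res_pair)) {
    stop("internal: duplicate residue pairs generated")
  }

  # RT schedule per pair (features of a pair co-elute)
  apex <- stats::runif(nrow(pair_df), 3, gradient_min - 8)
  apex[2L] <- apex[1L]                     # co-eluting plant
  apex[4L] <- apex[3L] + 4                 # separated plant

  # features: plants get one shared charge; plain pairs 1-2 charges
  spacer <- mass_constants()$bs3_spacer
  feat_rows <- list()
  for (i in seq_len(nrow(pair_df))) {
    mass <- peptide_mass(pair_df$pep_a[i]) + peptide_mass(pair_df$pep_b[i]) +
      spacer
    feas <- charges[mz_from_mass(mass, charges) >= 420 &
                      mz_from_mass(mass, charges) <= 1580]
    if (!length(feas)) feas <- max(charges)
    zs <- if (pair_df$tag[i] != "plain") feas[1L]
          else sort(sample(feas, min(length(feas), sample(1:2, 1L))))
    for (z in zs) {
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        pair_idx = i, charge = z, neutral_mass = mass,
        mz = mz_from_mass(mass, z), apex = apex[i],
        stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, feat_rows)
  # plants share mass and charge by construction; give partners one charge
  features$charge[features$pair_idx == 2L] <-
    features$charge[features$pair_idx == 1L][1L]
  features$charge[features$pair_idx == 4L] <-
    features$charge[features$pair_idx == 3L][1L]
  features$mz <- mz_from_mass(features$neutral_mass, features$charge)
  nf <- nrow(features)

  # canonical feature keys via the pipeline's own keying
  features$feature <- vapply(seq_len(nf), function(fi) {
    i <- features$pair_idx[fi]
    psm <- crosslink_psm(run_id = "truth", scan = 1L,
                         charge = features$charge[fi],
                         pep_a = pair_df$pep_a[i], pep_b = pair_df$pep_b[i],
                         site_a = pair_df$site_a[i], site_b = pair_df$site_b[i],
                         prot_pos_a = pair_df$prot_a[i],
                         prot_pos_b = pair_df$prot_b[i])
    feature_key(psm)
  }, character(1))
  features$res_pair <- pair_df$res_pair[features$pair_idx]

  # ground-truth areas: base area x lognormal multiplier per run
  features$base_area <- 10^stats::runif(nf, log10_area_range[1L],
                                        log10_area_range[2L])
  features$cv_target <- if (intensity_dependent_cv) {
    frac <- (log10(features$base_area) - log10_area_range[1L]) /
      diff(log10_area_range)
    cv_range[2L] + frac * (cv_range[1L] - cv_range[2L])
  } else rep(cv_target, nf)
  sigmas <- vapply(features$cv_target, .lognormal_sigma, numeric(1), n_runs)
  areas <- matrix(0, nf, n_runs,
                  dimnames = list(features$feature,
                                  sprintf("run%02d", seq_len(n_runs))))
  for (fi in seq_len(nf)) {
    s <- sigmas[fi]
    areas[fi, ] <- features$base_area[fi] *
      stats::rlnorm(n_runs, meanlog = -s^2 / 2, sdlog = s)
  }
  # planted absence: first plain pair's first feature, last run
  absent_fi <- which(features$pair_idx ==
                       which(pair_df$tag == "plain")[1L])[1L]
  absent_run <- n_runs
  areas[absent_fi, absent_run] <- 0

  # RT jitter per (feature, run); co-eluting partners share jitter so the
  # planted overlap survives every replica
  jitter <- matrix(stats::rnorm(nf * n_runs, 0, rt_jitter_sd), nf, n_runs)
  jitter[features$pair_idx == 2L, ] <-
    jitter[which(features$pair_idx == 1L)[1L], ]

  # identification schedule
  identified <- matrix(stats::runif(nf * n_runs) < id_prob, nf, n_runs)
  no_id <- rowSums(identified) == 0L
  identified[no_id, 1L] <- TRUE
  identified[absent_fi, absent_run] <- FALSE

  # toy structure: initial coordinates in a sphere, then each pair's free
  # residue placed at a controlled distance (violators >= 33 A)
  n_res <- nchar(protein)
  u <- matrix(stats::rnorm(3L * n_res), ncol = 3L)
  u <- u / sqrt(rowSums(u^2))
  rad <- 22 * stats::runif(n_res)^(1 / 3)
  coords <- u * rad
  plain_idx <- which(pair_df$tag == "plain")
  violators <- if (n_distance_violations > 0L) {
    sort(sample(plain_idx, min(n_distance_violations, length(plain_idx))))
  } else integer()
  fixed <- logical(n_res)
  rand_dir <- function() {
    v <- stats::rnorm(3L); v / sqrt(sum(v^2))
  }
  for (i in seq_len(nrow(pair_df))) {
    d <- if (i %in% violators) stats::runif(1, 33, 44) else stats::runif(1, 8, 22)
    a <- pair_df$prot_a[i]; b <- pair_df$prot_b[i]
    if (!fixed[b]) {
      coords[b, ] <- coords[a, ] + d * rand_dir()
    } else if (!fixed[a]) {
      coords[a, ] <- coords[b, ] + d * rand_dir()
    }
    fixed[a] <- TRUE; fixed[b] <- TRUE
  }

  # PSM table for identified (feature, run) combinations, plus decoys
  rt_grid <- seq(cycle_s / 60, by = cycle_s / 60,
                 length.out = floor(gradient_min * 60 / cycle_s))
  psm_rows <- list()
  for (fi in seq_len(nf)) {
    i <- features$pair_idx[fi]
    for (r in which(identified[fi, ])) {
      scan <- which.min(abs(rt_grid - (features$apex[fi] + jitter[fi, r])))
      psm_rows[[length(psm_rows) + 1L]] <- data.frame(
        run_id = sprintf("run%02d", r), scan = scan,
        charge = features$charge[fi],
        pep_a = pair_df$pep_a[i], pep_b = pair_df$pep_b[i],
        site_a = pair_df$site_a[i], site_b = pair_df$site_b[i],
        mods_a = "", mods_b = "",
        prot_pos_a = pair_df$prot_a[i], prot_pos_b = pair_df$prot_b[i],
        score = round(stats::runif(1, 5, 15), 3), is_decoy = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if (n_decoys > 0L) {
    rev_protein <- paste(rev(strsplit(protein, "", fixed = TRUE)[[1]]),
                         collapse = "")
    dpeps <- digest(rev_protein, max_missed = 0L)
    for (k in seq_len(n_decoys)) {
      da <- dpeps[sample(nrow(dpeps), 1L), ]
      db <- dpeps[sample(nrow(dpeps), 1L), ]
      dsa <- pep_sites(da); dsb <- pep_sites(db)
      psm_rows[[length(psm_rows) + 1L]] <- data.frame(
        run_id = "run01", scan = sample(length(rt_grid), 1L), charge = 3L,
        pep_a = da$sequence, pep_b = db$sequence,
        site_a = if (length(dsa)) dsa[1L] else 1L,
        site_b = if (length(dsb)) dsb[1L] else 1L,
        mods_a = "", mods_b = "",
        prot_pos_a = 9000L + 2L * k, prot_pos_b = 9001L + 2L * k,
        score = round(stats::runif(1, 5, 10), 3), is_decoy = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  psms <- do.call(crosslink_psm, do.call(rbind, psm_rows))

  structure(list(
    protein = protein,
    pairs = pair_df,
    features = features,
    areas = areas,
    jitter = jitter,
    identified = identified,
    psms = psms,
    pdb_coords = data.frame(resno = seq_len(n_res), x = coords[, 1L],
                            y = coords[, 2L], z = coords[, 3L]),
    violating_pairs = pair_df$res_pair[violators],
    coelute_pairs = pair_df$res_pair[pair_df$tag == "coelute"],
    separated_pairs = pair_df$res_pair[pair_df$tag == "separated"],
    absent = list(feature = features$feature[absent_fi], run = absent_run),
    params = list(n_pairs = n_pairs, n_runs = n_runs,
                  experiment = experiment, cv_target = cv_target,
                  rt_jitter_sd = rt_jitter_sd, gradient_min = gradient_min,
                  cycle_s = cycle_s, peak_sigma_min = peak_sigma_min,
                  noise_floor_rel = noise_floor_rel,
                  intensity_dependent_cv = intensity_dependent_cv,
                  cv_range = cv_range, seed = seed)
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "synthetic_truth: %d residue pairs, %d features, %d runs (%s, CV %s%%)\n",
    nrow(x$pairs), nrow(x$features), p$n_runs, p$experiment,
    if (p$intensity_dependent_cv) "intensity-dependent" else p$cv_target))
  cat(sprintf("  protein: %d residues; seed %d\n", nchar(x$protein), p$seed))
  invisible(x)
}

#' Render the replicate MS1 runs of a synthetic world
#'
#' Each feature becomes a Gaussian elution profile times a three-peak
#' isotope envelope at its charge's m/z, sampled on the MS1 cycle grid;
#' per-spectrum uniform noise centroids form the noise floor. The summed
#' three-isotope area of each feature equals its ground-truth area. The
#' isotope abundance model is a crude mass heuristic (M+1/M ~ 0.0005 x
#' mass, capped), sufficient because quantitation sums the isotopes.
#'
#' @param truth A [simulate_truth()] object.
#' @return List of [ms1_run()] objects, one per replicate.
#' @export
simulate_runs <- function(truth) {
  p <- truth$params
  rt_grid <- seq(p$cycle_s / 60, by = p$cycle_s / 60,
                 length.out = floor(p$gradient_min * 60 / p$cycle_s))
  n_scan <- length(rt_grid)
  sigma <- p$peak_sigma_min
  feats <- truth$features
  r1 <- pmin(0.0005 * feats$neutral_mass, 1.2)
  r2 <- pmin((0.0005 * feats$neutral_mass)^2 / 2, 1.0)
  wsum <- 1 + r1 + r2
  apex_height <- feats$base_area / (sigma * sqrt(2 * pi))
  noise_level <- p$noise_floor_rel * stats::median(apex_height)

  runs <- vector("list", p$n_runs)
  for (r in seq_len(p$n_runs)) {
    acc <- vector("list", n_scan)
    for (fi in seq_len(nrow(feats))) {
      area <- truth$areas[fi, r]
      if (area <= 0) next
      mu <- feats$apex[fi] + truth$jitter[fi, r]
      idx <- which(abs(rt_grid - mu) <= 4 * sigma)
      if (!length(idx)) next
      g <- exp(-(rt_grid[idx] - mu)^2 / (2 * sigma^2))
      amp <- area / (sigma * sqrt(2 * pi)) / wsum[fi]
      w <- c(1, r1[fi], r2[fi])
      for (k in 0:2) {
        mzk <- isotope_mz(feats$mz[fi], feats$charge[fi], k)
        block <- cbind(mz = rep(mzk, length(idx)),
                       intensity = amp * w[k + 1L] * g, scan = idx)
        acc[[length(acc) + 1L]] <- block
      }
    }
    if (noise_level > 0) {
      set.seed(p$seed + 104729L + r)
      n_noise <- 40L
      for (s in seq_len(n_scan)) {
        acc[[length(acc) + 1L]] <- cbind(
          mz = stats::runif(n_noise, 400, 1600),
          intensity = noise_level * stats::runif(n_noise, 0.5, 1.5),
          scan = rep(s, n_noise))
      }
    }
    all <- do.call(rbind, acc[!vapply(acc, is.null, logical(1))])
    spectra <- vector("list", n_scan)
    if (!is.null(all)) {
      split_idx <- split(seq_len(nrow(all)), factor(all[, "scan"],
                                                    levels = seq_len(n_scan)))
      spectra <- lapply(split_idx, function(ii)
        all[ii, c("mz", "intensity"), drop = FALSE])
    } else {
      spectra <- lapply(seq_len(n_scan), function(s)
        matrix(numeric(), ncol = 2L))
    }
    runs[[r]] <- ms1_run(sprintf("run%02d", r), rt_grid, spectra)
  }
  runs
}

.AA3 <- c(G = "GLY", A = "ALA", S = "SER", P = "PRO", V = "VAL", T = "THR",
          C = "CYS", L = "LEU", I = "ILE", N = "ASN", D = "ASP", Q = "GLN",
          K = "LYS", E = "GLU", M = "MET", H = "HIS", F = "PHE", R = "ARG",
          Y = "TYR", W = "TRP")

#' Write the toy structure of a synthetic world as PDB
#'
#' One C-alpha ATOM record per residue of the synthetic protein, chain A.
#' The coordinates are synthetic (see [simulate_truth()]); the file exists
#' solely to exercise distance validation.
#'
#' @param truth A [simulate_truth()] object.
#' @param path Output PDB path.
#' @return The path, invisibly.
#' @export
write_toy_pdb <- function(truth, path) {
  aa <- strsplit(truth$protein, "", fixed = TRUE)[[1]]
  co <- truth$pdb_coords
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(co)), .AA3[aa[co$resno]], co$resno,
    co$x, co$y, co$z, 1, 0)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Materialize a synthetic world on disk
#'
#' Writes per-replica mzML files, the PSM table, the toy PDB and a truth
#' summary JSON into a directory.
#'
#' @param truth A [simulate_truth()] object.
#' @param dir Output directory (created if needed).
#' @return Named list of paths: `mzml` (vector), `psms`, `pdb`, `truth`.
#' @export
render_world <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  runs <- simulate_runs(truth)
  mzml <- vapply(runs, function(r) {
    path <- file.path(dir, paste0(r$run_id, ".mzML"))
    write_run_mzml(r, path)
    path
  }, character(1))
  psm_path <- file.path(dir, "psms.tsv")
  write_psm_table(truth$psms, psm_path)
  pdb_path <- file.path(dir, "toy.pdb")
  write_toy_pdb(truth, pdb_path)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    params = truth$params,
    pairs = truth$pairs,
    features = truth$features[, c("feature", "res_pair", "charge",
                                  "base_area", "cv_target", "apex")],
    areas = as.data.frame(truth$areas),
    violating_pairs = truth$violating_pairs,
    coelute_pairs = truth$coelute_pairs,
    separated_pairs = truth$separated_pairs,
    absent = truth$absent
  ), truth_path, auto_unbox = TRUE, digits = NA)
  list(mzml = mzml, psms = psm_path, pdb = pdb_path, truth = truth_path)
}

#' Random cross-link PSMs for property testing
#'
#' Generates random tryptic-like peptide pairs with random link sites on
#' K/S/T/Y, random charges 3-7 and a sprinkling of modifications
#' (carbamidomethyl on every C, oxidation on some M, an occasional BS3-OH
#' mono-link or N-terminal mod), to exercise linearization bookkeeping.
#'
#' @param n Number of PSMs.
#' @param seed RNG seed.
#' @return A [crosslink_psm()] data.frame.
#' @export
random_crosslink_psms <- function(n, seed) {
  set.seed(seed)
  random_pep <- function() {
    len <- sample(6:15, 1L)
    aa <- sample(names(amino_acid_masses()), len, replace = TRUE)
    if (!any(aa %in% c("K", "S", "T", "Y"))) {
      aa[sample(2:(len - 1L), 1L)] <- "K"
    }
    paste(aa, collapse = "")
  }
  random_side <- function(pep) {
    aa <- strsplit(pep, "", fixed = TRUE)[[1]]
    linkable <- which(aa %in% c("K", "S", "T", "Y"))
    site <- sample(rep(linkable, 2L), 1L)
    mods <- data.frame(position = which(aa == "C"),
                       name = rep("carbamidomethyl-C", sum(aa == "C")),
                       stringsAsFactors = FALSE)
    mpos <- which(aa == "M")
    mpos <- mpos[stats::runif(length(mpos)) < 0.5]
    if (length(mpos)) {
      mods <- rbind(mods, data.frame(position = mpos, name = "oxidation-M"))
    }
    extra <- setdiff(linkable, c(site, mods$position))
    if (length(extra) && stats::runif(1) < 0.2) {
      mods <- rbind(mods, data.frame(position = sample(rep(extra, 2L), 1L),
                                     name = "BS3-OH"))
    }
    if (stats::runif(1) < 0.1 && !1L %in% mods$position) {
      mods <- rbind(mods, data.frame(position = 0L, name = "BS3-NH2"))
    }
    list(pep = pep, site = site, mods = format_mods(mods))
  }
  rows <- lapply(seq_len(n), function(i) {
    a <- random_side(random_pep())
    b <- random_side(random_pep())
    data.frame(run_id = "sim", scan = i, charge = sample(3:7, 1L),
               pep_a = a$pep, pep_b = b$pep,
               site_a = a$site, site_b = b$site,
               mods_a = a$mods, mods_b = b$mods,
               prot_pos_a = sample(500L, 1L), prot_pos_b = sample(500L, 1L),
               score = round(stats::runif(1, 1, 20), 3),
               is_decoy = FALSE, stringsAsFactors = FALSE)
  })
  do.call(crosslink_psm, do.call(rbind, rows))
}
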