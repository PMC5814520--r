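# MS1-filtering quantitation: per-isotope extracted ion chromatograms from
# centroided MS1 spectra, deterministic peak picking and trapezoidal
# integration, robust retention-time alignment, and match-between-runs.

.MZ_RANGE <- c(400, 1600) # instrument precursor window, m/z

#' In-memory MS1 run
#'
#' A centroided MS1 acquisition: strictly increasing retention times (in
#' minutes) and one centroid list per spectrum.
#'
#' @param run_id Run identifier.
#' @param rt Numeric vector of retention times in minutes, strictly
#'   increasing.
#' @param peaks List (same length as `rt`) of 2-column matrices
#'   `(mz, intensity)`; centroids are sorted by m/z on construction.
#' @return Object of class `ms1_run`.
#' @export
ms1_run <- function(run_id, rt, peaks) {
  stopifnot(length(rt) == length(peaks))
  if (length(rt) > 1L && any(diff(rt) <= 0)) {
    stop("retention times must be strictly increasing")
  }
  peaks <- lapply(peaks, function(p) {
    p <- matrix(as.numeric(p), ncol = 2L,
                dimnames = list(NULL, c("mz", "intensity")))
    p[order(p[, 1L]), , drop = FALSE]
  })
  structure(list(run_id = run_id, rt = as.numeric(rt), peaks = peaks),
            class = "ms1_run")
}

#' @export
print.ms1_run <- function(x, ...) {
  cat(sprintf("MS1 run '%s': %d spectra, RT %.2f-%.2f min\n",
              x$run_id, length(x$rt),
              min(x$rt), max(x$rt)))
  invisible(x)
}

#' Read MS1 spectra from an mzML file
#'
#' Loads MS-level-1 spectra only; retention times are converted to minutes.
#' Profile-mode spectra are rejected: the extraction model assumes
#' centroided data.
#'
#' @param path mzML file path.
#' @param run_id Run identifier; defaults to the file name without
#'   extension.
#' @return An [ms1_run()] object.
#' @export
read_ms1_run <- function(path, run_id = NULL) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  if (is.null(run_id)) run_id <- sub("\\.[^.]*$", "", basename(path))
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  ms1 <- which(hd$msLevel == 1L)
  if (!length(ms1)) stop("no MS1 spectra in ", path)
  if (any(hd$centroided[ms1] %in% FALSE)) {
    stop("profile-mode MS1 spectra in ", path,
         "; centroid the data before quantitation")
  }
  pk <- mzR::peaks(fh, ms1)
  if (is.matrix(pk)) pk <- list(pk)
  ms1_run(run_id, hd$retentionTime[ms1] / 60, pk)
}

#' Write an MS1 run to mzML
#'
#' @param run An [ms1_run()] object.
#' @param path Output mzML path.
#' @return The path, invisibly.
#' @export
write_run_mzml <- function(run, path) {
  n <- length(run$rt)
  counts <- vapply(run$peaks, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = counts,
    totIonCurrent = vapply(run$peaks, function(p) sum(p[, 2L]), numeric(1)),
    retentionTime = run$rt * 60,
    basePeakMZ = vapply(run$peaks, function(p)
      if (nrow(p)) p[which.max(p[, 2L]), 1L] else 0, numeric(1)),
    basePeakIntensity = vapply(run$peaks, function(p)
      if (nrow(p)) max(p[, 2L]) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = .MZ_RANGE[1L], highMZ = .MZ_RANGE[2L],
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = .MZ_RANGE[1L], scanWindowUpperLimit = .MZ_RANGE[2L]
  )
  mzR::writeMSData(object = unclass(run$peaks), file = path, header = hdr)
  invisible(path)
}

#' Extract per-isotope ion chromatograms
#'
#' For each isotope peak (M, M+1, M+2 by default) and each MS1 spectrum,
#' sums the intensities of all centroids within the m/z tolerance window.
#' Precursors outside the instrument m/z range 400-1600 are flagged
#' unquantifiable (zero trace) rather than raising an error.
#'
#' @param run An [ms1_run()].
#' @param precursor_mz Monoisotopic precursor m/z.
#' @param charge Precursor charge.
#' @param tolerance m/z half-window around each isotope (default 0.055).
#' @param n_isotopes Number of isotope peaks extracted (default 3).
#' @param rt_window Optional `c(lo, hi)` retention-time restriction in
#'   minutes; the full run is used when `NULL`.
#' @return Object of class `xic_trace`: list with `rt`, `intensity`
#'   (matrix, one column per isotope), `precursor_mz`, `charge`,
#'   `quantifiable` flag.
#' @export
extract_xic <- function(run, precursor_mz, charge, tolerance = 0.055,
                        n_isotopes = 3L, rt_window = NULL) {
  idx <- seq_along(run$rt)
  if (!is.null(rt_window)) {
    idx <- which(run$rt >= rt_window[1L] & run$rt <= rt_window[2L])
  }
  mzs <- isotope_mz(precursor_mz, charge, seq_len(n_isotopes) - 1L,
                    max_isotope = n_isotopes - 1L)
  quantifiable <- precursor_mz >= .MZ_RANGE[1L] && precursor_mz <= .MZ_RANGE[2L]
  inten <- matrix(0, nrow = length(idx), ncol = n_isotopes)
  if (quantifiable && length(idx)) {
    for (s in seq_along(idx)) {
      p <- run$peaks[[idx[s]]]
      if (!nrow(p)) next
      mzcol <- p[, 1L]
      for (k in seq_len(n_isotopes)) {
        lo <- findInterval(mzs[k] - tolerance, mzcol) + 1L
        hi <- findInterval(mzs[k] + tolerance, mzcol)
        if (hi >= lo) inten[s, k] <- sum(p[lo:hi, 2L])
      }
    }
  }
  structure(list(rt = run$rt[idx], intensity = inten,
                 precursor_mz = precursor_mz, charge = charge,
                 quantifiable = quantifiable),
            class = "xic_trace")
}

# centered moving average used only for apex/boundary search; the raw
# summed trace is what gets integrated
.smooth_trace <- function(y, width = 5L) {
  if (length(y) < width) return(y)
  s <- as.numeric(stats::filter(y, rep(1 / width, width), sides = 2))
  s[is.na(s)] <- y[is.na(s)]
  s
}

#' Pick and integrate a chromatographic peak
#'
#' Searches the isotope-summed trace for the local maximum nearest
#' `rt_seed` (within `search_window` minutes); tiny bumps below 5% of the
#' in-window maximum are not considered apex candidates, so an isolated
#' noise centroid cannot outrank a real peak. Boundaries extend from the
#' apex until the smoothed trace falls below `boundary_fraction` of the
#' apex height or starts rising again (a valley). The area is the
#' trapezoidal integral of the raw summed trace between the boundaries.
#'
#' @param trace An [extract_xic()] trace.
#' @param rt_seed Seed retention time in minutes (e.g. from the identifying
#'   scan, or from aligned runs for match-between-runs).
#' @param search_window Half-width of the apex search window (minutes).
#' @param boundary_fraction Boundary threshold as a fraction of apex height.
#' @param smooth Moving-average width (points) for apex/boundary search.
#' @return List of class `peak_result`: `apex_rt`, `rt_start`, `rt_end`,
#'   `area`, `height`, `matched` (TRUE when a nonzero peak was found).
#' @export
pick_peak <- function(trace, rt_seed, search_window = 2,
                      boundary_fraction = 0.01, smooth = 5L) {
  y <- rowSums(trace$intensity)
  rt <- trace$rt
  empty <- list(apex_rt = NA_real_, rt_start = NA_real_, rt_end = NA_real_,
                area = 0, height = 0, matched = FALSE)
  class(empty) <- "peak_result"
  if (!length(y) || all(y == 0)) return(empty)
  ys <- .smooth_trace(y, smooth)
  n <- length(ys)
  in_win <- which(abs(rt - rt_seed) <= search_window)
  if (!length(in_win)) return(empty)
  left <- c(-Inf, ys[-n])
  right <- c(ys[-1L], -Inf)
  is_max <- ys >= left & ys >= right & ys > 0
  floor_h <- 0.05 * max(ys[in_win])
  cand <- in_win[is_max[in_win] & ys[in_win] >= floor_h]
  if (!length(cand)) return(empty)
  apex <- cand[which.min(abs(rt[cand] - rt_seed))]
  thr <- boundary_fraction * ys[apex]
  l <- apex
  while (l > 1L && ys[l - 1L] > thr && ys[l - 1L] <= ys[l]) l <- l - 1L
  r <- apex
  while (r < n && ys[r + 1L] > thr && ys[r + 1L] <= ys[r]) r <- r + 1L
  if (l == apex && l > 1L) l <- l - 1L
  if (r == apex && r < n) r <- r + 1L
  area <- if (r > l) pracma::trapz(rt[l:r], y[l:r]) else 0
  structure(list(apex_rt = rt[apex], rt_start = rt[l], rt_end = rt[r],
                 area = area, height = y[apex], matched = TRUE),
            class = "peak_result")
}

#' @export
print.peak_result <- function(x, ...) {
  if (!x$matched) cat("peak_result: no peak found\n")
  else cat(sprintf("peak_result: apex %.3f min [%.3f, %.3f], area %.4g\n",
                   x$apex_rt, x$rt_start, x$rt_end, x$area))
  invisible(x)
}

#' Align retention times across runs
#'
#' Fits a robust linear map from each run's RT axis onto a reference run
#' (the run with the most anchor apexes), using features picked in at least
#' two runs as anchors. Runs with fewer than 3 shared anchors fall back to
#' the identity mapping with a warning.
#'
#' @param anchors data.frame with columns `run_id`, `feature`, `apex_rt`.
#' @return Object of class `rt_alignment`: data.frame `run_id`, `slope`,
#'   `intercept` mapping run RT onto the reference axis, with the reference
#'   run id as attribute `reference`.
#' @export
align_rt <- function(anchors) {
  anchors <- anchors[!is.na(anchors$apex_rt), , drop = FALSE]
  runs <- unique(anchors$run_id)
  counts <- table(anchors$run_id)
  reference <- names(counts)[which.max(counts)]
  ref <- anchors[anchors$run_id == reference, c("feature", "apex_rt")]
  out <- data.frame(run_id = runs, slope = 1, intercept = 0,
                    n_anchors = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(runs)) {
    r <- runs[i]
    if (r == reference) { out$n_anchors[i] <- nrow(ref); next }
    cur <- anchors[anchors$run_id == r, c("feature", "apex_rt")]
    m <- merge(cur, ref, by = "feature", suffixes = c("_run", "_ref"))
    out$n_anchors[i] <- nrow(m)
    if (nrow(m) < 3L) {
      warning("run '", r, "': only ", nrow(m),
              " shared anchors; using identity RT mapping")
      next
    }
    fit <- tryCatch(
      MASS::rlm(apex_rt_ref ~ apex_rt_run, data = m, maxit = 50),
      error = function(e) stats::lm(apex_rt_ref ~ apex_rt_run, data = m)
    )
    cf <- stats::coef(fit)
    out$intercept[i] <- cf[[1L]]
    out$slope[i] <- cf[[2L]]
  }
  structure(out, class = c("rt_alignment", "data.frame"),
            reference = reference)
}

#' Map retention times through an alignment
#'
#' @param alignment An [align_rt()] object.
#' @param run_id Run whose RT axis `rt` lives on.
#' @param rt Retention times (minutes).
#' @param invert If `TRUE`, map from the reference axis back into the run's
#'   own axis.
#' @return Mapped retention times.
#' @export
map_rt <- function(alignment, run_id, rt, invert = FALSE) {
  i <- match(run_id, alignment$run_id)
  if (is.na(i)) return(rt)
  a <- alignment$slope[i]
  b <- alignment$intercept[i]
  if (invert) (rt - b) / a else a * rt + b
}

#' Per-run noise-floor intensity
#'
#' Median of the lowest decile of positive centroid intensities across the
#' run; multiplied by a peak's width, it provides the area threshold below
#' which a feature does not count as quantified.
#'
#' @param run An [ms1_run()].
#' @return Noise-floor intensity (same units as centroid intensities).
#' @export
noise_floor_intensity <- function(run) {
  ints <- unlist(lapply(run$peaks, function(p) p[, 2L]), use.names = FALSE)
  ints <- ints[ints > 0]
  if (!length(ints)) return(0)
  dec <- stats::quantile(ints, 0.1, names = FALSE)
  stats::median(ints[ints <= dec])
}

#' Quantify features across runs with match-between-runs
#'
#' Two passes. First, every feature is picked in each run where it was
#' identified, seeded at the identifying scan's retention time; those
#' apexes anchor a robust RT alignment ([align_rt()]). Second, runs lacking
#' an identification are quantified at the aligned median apex of the runs
#' that have one. Every (feature, run) combination yields one row, possibly
#' with zero area.
#'
#' @param lf_table Linearized PSM table ([linearize_psms()]); identified
#'   runs and seed scans are taken from its `run_id`/`scan` columns.
#' @param runs List of [ms1_run()] objects.
#' @param tolerance m/z half-window (default 0.055).
#' @param n_isotopes Isotope peaks per precursor (default 3).
#' @param search_window Apex search half-width, minutes.
#' @param rt_pad Extra minutes of trace extracted beyond the search window.
#' @return data.frame, one row per (feature, run): `feature`, `run_id`,
#'   `apex_rt`, `rt_start`, `rt_end`, `area`, `matched`, `identified`,
#'   `above_floor`; the RT alignment as attribute `alignment`.
#' @export
quantify_features <- function(lf_table, runs, tolerance = 0.055,
                              n_isotopes = 3L, search_window = 2,
                              rt_pad = 1) {
  run_ids <- vapply(runs, function(r) r$run_id, character(1))
  names(runs) <- run_ids
  floors <- vapply(runs, noise_floor_intensity, numeric(1))
  feats <- lf_table[!duplicated(lf_table$feature),
                    c("feature", "precursor_mz", "charge")]
  ext_win <- search_window + rt_pad

  seed_for <- function(feature, run) {
    scans <- lf_table$scan[lf_table$feature == feature &
                             lf_table$run_id == run$run_id]
    scans <- scans[scans >= 1L & scans <= length(run$rt)]
    if (!length(scans)) return(NA_real_)
    stats::median(run$rt[scans])
  }

  # pass 1: identified (feature, run) combinations
  pass1 <- list()
  for (fi in seq_len(nrow(feats))) {
    f <- feats[fi, ]
    for (r in runs) {
      seed <- seed_for(f$feature, r)
      if (is.na(seed)) next
      tr <- extract_xic(r, f$precursor_mz, f$charge, tolerance, n_isotopes,
                        rt_window = seed + c(-ext_win, ext_win))
      pk <- pick_peak(tr, seed, search_window)
      pass1[[length(pass1) + 1L]] <- data.frame(
        feature = f$feature, run_id = r$run_id, apex_rt = pk$apex_rt,
        rt_start = pk$rt_start, rt_end = pk$rt_end, area = pk$area,
        matched = pk$matched, identified = TRUE, stringsAsFactors = FALSE)
    }
  }
  pass1 <- do.call(rbind, pass1)
  anchors <- pass1[pass1$matched, c("run_id", "feature", "apex_rt")]
  alignment <- align_rt(anchors)

  # pass 2: match between runs at aligned median apex
  pass2 <- list()
  for (fi in seq_len(nrow(feats))) {
    f <- feats[fi, ]
    have <- pass1[pass1$feature == f$feature & pass1$matched, , drop = FALSE]
    ref_apexes <- vapply(seq_len(nrow(have)), function(i)
      map_rt(alignment, have$run_id[i], have$apex_rt[i]), numeric(1))
    missing_runs <- setdiff(run_ids, pass1$run_id[pass1$feature == f$feature])
    for (rid in missing_runs) {
      r <- runs[[rid]]
      if (!length(ref_apexes)) {
        pass2[[length(pass2) + 1L]] <- data.frame(
          feature = f$feature, run_id = rid, apex_rt = NA_real_,
          rt_start = NA_real_, rt_end = NA_real_, area = 0,
          matched = FALSE, identified = FALSE, stringsAsFactors = FALSE)
        next
      }
      seed <- map_rt(alignment, rid, stats::median(ref_apexes), invert = TRUE)
      tr <- extract_xic(r, f$precursor_mz, f$charge, tolerance, n_isotopes,
                        rt_window = seed + c(-ext_win, ext_win))
      pk <- pick_peak(tr, seed, search_window)
      pass2[[length(pass2) + 1L]] <- data.frame(
        feature = f$feature, run_id = rid, apex_rt = pk$apex_rt,
        rt_start = pk$rt_start, rt_end = pk$rt_end, area = pk$area,
        matched = pk$matched, identified = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- rbind(pass1, if (length(pass2)) do.call(rbind, pass2))
  width <- ifelse(is.na(out$rt_end - out$rt_start), 0,
                  out$rt_end - out$rt_start)
  out$above_floor <- out$area > floors[out$run_id] * width & out$area > 0
  rownames(out) <- NULL
  attr(out, "alignment") <- alignment
  out
}
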