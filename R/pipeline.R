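# End-to-end orchestration: PSM table -> linearization -> .ssl ->
# structure validation -> XIC quantitation with match-between-runs ->
# filters -> reproducibility statistics. The result object carries every
# intermediate table plus per-stage counts.

#' Pipeline configuration
#'
#' Collects the tunable parameters of the workflow with the instrument and
#' search settings of the underlying acquisition design as defaults: m/z
#' tolerance 0.055, three isotope peaks, precursor charges 3-7, 30 A
#' distance threshold.
#'
#' @param psm_table Path to the PSM table, or a [crosslink_psm()]
#'   data.frame.
#' @param mzml Character vector of mzML paths, or a list of [ms1_run()]
#'   objects.
#' @param pdb Optional PDB path (or `NULL` to skip structure validation).
#' @param chain PDB chain id.
#' @param tolerance XIC m/z half-window.
#' @param n_isotopes Isotope peaks per precursor.
#' @param charge_range Accepted precursor charges.
#' @param distance_threshold Cross-linker distance limit in Angstrom.
#' @param numbering_offset Sequence-to-structure residue numbering offset.
#' @param experiment Free-text experiment label (e.g. `"injection"`).
#' @param out_dir Optional directory for report tables.
#' @param seed Seed echoed into the run log.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(psm_table, mzml, pdb = NULL, chain = "A",
                            tolerance = 0.055, n_isotopes = 3L,
                            charge_range = 3:7, distance_threshold = 30,
                            numbering_offset = 0L, experiment = "experiment",
                            out_dir = NULL, seed = 1L) {
  structure(list(psm_table = psm_table, mzml = mzml, pdb = pdb,
                 chain = chain, tolerance = tolerance,
                 n_isotopes = n_isotopes, charge_range = charge_range,
                 distance_threshold = distance_threshold,
                 numbering_offset = numbering_offset,
                 experiment = experiment, out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

.res_pair_ij <- function(res_pair) {
  parts <- strsplit(res_pair, "-", fixed = TRUE)
  data.frame(res_pair = res_pair,
             i = as.integer(vapply(parts, `[[`, "", 1L)),
             j = as.integer(vapply(parts, `[[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' Run the complete quantitation workflow
#'
#' Stages: read PSMs; restrict to the configured charge range; linearize
#' every PSM (mass equivalence asserted below 1e-4 Da); build .ssl records;
#' validate unique residue pairs against the structure (decoys and pairs at
#' or beyond the distance limit removed); quantify the surviving features
#' across all runs with match-between-runs; apply the co-elution and
#' complete-quantitation filters; summarise CVs, saturation, observation
#' frequency and CV-versus-intensity bins. Counts are monotone
#' non-increasing along the filter chain.
#'
#' @param config A [pipeline_config()] (or arguments forwarded to it).
#' @param ... Used to build a config when `config` is not one.
#' @return Object of class `qclms_result`; see [summary.qclms_result()].
#' @export
run_pipeline <- function(config, ...) {
  if (!inherits(config, "pipeline_config")) {
    config <- pipeline_config(config, ...)
  }
  log_lines <- character()
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  psms <- config$psm_table
  if (is.character(psms)) psms <- read_psm_table(psms)
  say("stage psms: %d PSM rows", nrow(psms))

  in_charge <- psms$charge %in% config$charge_range
  psms <- psms[in_charge, , drop = FALSE]
  say("stage charge-filter: %d PSMs within charges %s", nrow(psms),
      paste(range(config$charge_range), collapse = "-"))

  lf <- linearize_psms(psms)
  if (any(lf$mass_error >= 1e-4)) {
    stop("stage linearize: mass equivalence violated (max error ",
         format(max(lf$mass_error)), " Da)")
  }
  say("stage linearize: %d linear forms, max mass error %.2e Da",
      nrow(lf), max(lf$mass_error))
  ssl <- make_ssl(lf)

  # unique residue pairs incl. decoys -> FDR, then structure validation
  upairs <- lf[!duplicated(lf$res_pair), c("res_pair", "is_decoy")]
  fdr <- decoy_fdr(upairs$is_decoy)
  n_identified <- nrow(upairs)
  say("stage identify: %d unique residue pairs (%d decoys, FDR %.2f%%)",
      n_identified, attr(fdr, "n_decoy"), as.numeric(fdr))

  distance_tbl <- NULL
  if (!is.null(config$pdb)) {
    model <- load_ca_coords(config$pdb, config$chain)
    ij <- .res_pair_ij(upairs$res_pair)
    ij$is_decoy <- upairs$is_decoy
    dres <- distance_filter(ij, model, config$distance_threshold,
                            config$numbering_offset)
    retained_pairs <- dres$retained$res_pair
    distance_tbl <- rbind(
      cbind(dres$retained, retained = TRUE),
      cbind(dres$removed, retained = FALSE))
    say("stage distance-filter: %d pairs within %g A (removed %d)",
        length(retained_pairs), config$distance_threshold,
        nrow(dres$removed))
  } else {
    retained_pairs <- upairs$res_pair[!upairs$is_decoy]
    say("stage distance-filter: skipped (no structure); %d target pairs",
        length(retained_pairs))
    if (any(upairs$is_decoy)) say("  decoys excluded from quantitation")
  }
  n_distance <- length(retained_pairs)

  lf_quant <- lf[lf$res_pair %in% retained_pairs & !lf$is_decoy, ,
                 drop = FALSE]

  runs <- config$mzml
  if (is.character(runs)) runs <- lapply(runs, read_ms1_run)
  n_runs <- length(runs)
  quant <- quantify_features(lf_quant, runs, tolerance = config$tolerance,
                             n_isotopes = config$n_isotopes)
  say("stage quantify: %d features x %d runs",
      length(unique(quant$feature)), n_runs)

  fc <- feature_cv_table(lf_quant, quant)
  co <- filter_coeluting_alternatives(fc, quant)
  say("stage coelution-filter: %d pairs retained (removed %d)",
      length(co$retained), length(co$removed))
  fc_co <- fc[fc$res_pair %in% co$retained, , drop = FALSE]
  cq <- filter_complete_quant(fc_co, quant, n_runs)
  say("stage complete-quant-filter: %d pairs quantified in all %d runs",
      length(cq$retained), n_runs)

  fc_final <- fc_co[fc_co$res_pair %in% cq$retained, , drop = FALSE]
  pair_cvs <- pair_cv_table(fc_final)
  cv_bins <- cv_by_intensity_bins(pair_cvs)

  per_run_sets <- lapply(split(lf_quant$res_pair, lf_quant$run_id), unique)
  saturation <- saturation_curve(per_run_sets)
  frequency <- observation_frequency(per_run_sets)

  res <- structure(list(
    config = config,
    log = log_lines,
    psms = psms,
    linear_forms = lf,
    ssl = ssl,
    decoy_fdr = fdr,
    distance_table = distance_tbl,
    quant_table = quant,
    feature_cvs = fc,
    coelution = co,
    complete_quant = cq,
    pair_cvs = pair_cvs,
    cv_bins = cv_bins,
    saturation = saturation,
    frequency = frequency,
    counts = c(identified = n_identified,
               distance_passed = n_distance,
               coelution_passed = length(co$retained),
               complete_quantified = length(cq$retained)),
    median_cv = stats::median(pair_cvs$pair_cv, na.rm = TRUE),
    mean_cv = mean(pair_cvs$pair_cv, na.rm = TRUE)
  ), class = "qclms_result")

  if (!is.null(config$out_dir)) write_report(res, config$out_dir)
  res
}

#' @export
print.qclms_result <- function(x, ...) {
  cat("Label-free cross-link quantitation result (",
      x$config$experiment, ")\n", sep = "")
  cn <- x$counts
  cat(sprintf("  residue pairs: %d identified -> %d within distance limit -> %d after co-elution filter -> %d quantified in all runs\n",
              cn["identified"], cn["distance_passed"],
              cn["coelution_passed"], cn["complete_quantified"]))
  cat(sprintf("  median pair CV %.1f%%  (mean %.1f%%)\n",
              x$median_cv, x$mean_cv))
  invisible(x)
}

#' Summarise a pipeline result
#'
#' @param object A `qclms_result`.
#' @param ... Unused.
#' @return The result, invisibly; prints stage counts, decoy FDR, median
#'   and mean pair CV and the saturation endpoint.
#' @export
summary.qclms_result <- function(object, ...) {
  print(object)
  cat(sprintf("  decoy FDR: %.2f%% (%d of %d unique pairs)\n",
              as.numeric(object$decoy_fdr),
              attr(object$decoy_fdr, "n_decoy"),
              attr(object$decoy_fdr, "n_total")))
  sat <- object$saturation
  cat(sprintf("  saturation: %.1f pairs at k=1 -> %.1f at k=%d\n",
              sat$mean_pairs[1L], sat$mean_pairs[nrow(sat)],
              sat$k[nrow(sat)]))
  cat("  run log:\n")
  cat(paste0("    ", object$log, collapse = "\n"), "\n")
  invisible(object)
}

#' Write the report tables of a pipeline result
#'
#' Emits delimited summary tables: the quantitation table (one row per
#' feature and run), per-feature and per-pair CVs, CV-by-intensity bins,
#' the saturation curve, the observation-frequency histogram, the .ssl
#' records, the distance annotations (when a structure was supplied) and
#' the run log with stage counts.
#'
#' @param res A `qclms_result`.
#' @param dir Output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_report <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    path
  }
  paths <- c(
    quant = w(res$quant_table, "quant_table.tsv"),
    feature_cvs = w(res$feature_cvs, "feature_cvs.tsv"),
    pair_cvs = w(res$pair_cvs, "pair_cvs.tsv"),
    cv_bins = w(res$cv_bins, "cv_bins.tsv"),
    saturation = w(res$saturation, "saturation.tsv"),
    frequency = w(res$frequency, "frequency.tsv"))
  paths <- c(paths, ssl = write_ssl(res$ssl, file.path(dir, "library.ssl")))
  if (!is.null(res$distance_table)) {
    paths <- c(paths, distances = w(res$distance_table, "distances.tsv"))
  }
  log_path <- file.path(dir, "run_log.txt")
  writeLines(c(res$log,
               sprintf("median_pair_cv_percent\t%.1f", res$median_cv),
               sprintf("mean_pair_cv_percent\t%.1f", res$mean_cv),
               sprintf("config_seed\t%d", res$config$seed)), log_path)
  paths <- c(paths, log = log_path)
  invisible(paths)
}

#' Compare two replica experiments
#'
#' Overlap of identified and quantified residue pairs between two pipeline
#' results (e.g. reaction vs injection replica).
#'
#' @param res1,res2 `qclms_result` objects.
#' @return List with `identified` and `quantified` overlap counts
#'   (`only1`, `shared`, `only2`).
#' @export
compare_experiments <- function(res1, res2) {
  id1 <- unique(res1$linear_forms$res_pair[!res1$linear_forms$is_decoy])
  id2 <- unique(res2$linear_forms$res_pair[!res2$linear_forms$is_decoy])
  list(identified = overlap_counts(id1, id2),
       quantified = overlap_counts(res1$complete_quant$retained,
                                   res2$complete_quant$retained))
}
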