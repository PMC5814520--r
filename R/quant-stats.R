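# Reproducibility statistics on quantified cross-linking features:
# coefficients of variation per feature and per residue pair, the
# co-elution and complete-quantitation filters, saturation and overlap of
# identified residue pairs across replicate runs, and CV-versus-intensity
# binning.

#' Coefficient of variation in percent
#'
#' 100 times the sample standard deviation (n-1 denominator) divided by the
#' mean. Undefined (NA with a warning) for fewer than two values or a
#' non-positive mean.
#'
#' @param values Numeric vector of peak areas.
#' @return CV in percent, or `NA_real_` when undefined.
#' @export
#' @examples
#' cv_percent(c(1, 2, 3)) # 50
cv_percent <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L || mean(values) <= 0) {
    warning("CV undefined: need >= 2 values with positive mean")
    return(NA_real_)
  }
  100 * stats::sd(values) / mean(values)
}

#' Residue-pair CV
#'
#' The CV of a residue pair is the median of the CVs of all cross-linking
#' features mapping to that pair (midpoint convention for even counts).
#'
#' @param feature_cvs Numeric vector of member-feature CVs (percent).
#' @return Median CV in percent; `NA_real_` if no member CV is defined.
#' @export
residue_pair_cv <- function(feature_cvs) {
  feature_cvs <- feature_cvs[!is.na(feature_cvs)]
  if (!length(feature_cvs)) return(NA_real_)
  stats::median(feature_cvs)
}

#' Per-feature CV table
#'
#' Computes each feature's CV over its per-run areas and attaches the
#' feature's residue pair, peptide pair, charge and median area.
#'
#' @param lf_table Linearized PSM table ([linearize_psms()]).
#' @param quant_table Quantitation table ([quantify_features()]).
#' @return data.frame: `feature`, `res_pair`, `pep_pair`, `charge`,
#'   `median_area`, `cv`, `n_quantified` (runs above the noise floor).
#' @export
feature_cv_table <- function(lf_table, quant_table) {
  meta <- lf_table[!duplicated(lf_table$feature),
                   c("feature", "res_pair", "pep_pair", "charge")]
  feats <- unique(quant_table$feature)
  rows <- lapply(feats, function(f) {
    q <- quant_table[quant_table$feature == f, ]
    data.frame(
      feature = f,
      median_area = stats::median(q$area),
      cv = suppressWarnings(cv_percent(q$area)),
      n_quantified = sum(q$above_floor),
      stringsAsFactors = FALSE
    )
  })
  merge(meta, do.call(rbind, rows), by = "feature")
}

#' Residue-pair summary table
#'
#' Aggregates feature CVs to the residue-pair level: pair CV is the median
#' of member-feature CVs, pair area the median of member median areas.
#'
#' @param feature_cvs Output of [feature_cv_table()].
#' @return data.frame: `res_pair`, `n_features`, `median_area`, `pair_cv`.
#' @export
pair_cv_table <- function(feature_cvs) {
  pairs <- unique(feature_cvs$res_pair)
  rows <- lapply(pairs, function(p) {
    fc <- feature_cvs[feature_cvs$res_pair == p, ]
    data.frame(
      res_pair = p,
      n_features = nrow(fc),
      median_area = stats::median(fc$median_area),
      pair_cv = residue_pair_cv(fc$cv),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Filter residue pairs with co-eluting alternative linkages
#'
#' A residue pair is removed when any of its features shares the unordered
#' peptide-sequence pair and charge with a feature of a *different* residue
#' pair and their integration boundaries overlap in any run: such
#' alternative linkage variants are not separated in the LC dimension and
#' cannot be quantified independently. Pairs whose alternatives are fully
#' separated (disjoint boundaries in every run) are retained.
#'
#' @param feature_cvs Output of [feature_cv_table()] (supplies the
#'   feature-to-pair and peptide-pair mapping).
#' @param quant_table Quantitation table with boundaries.
#' @return List with `retained` and `removed` residue-pair ids.
#' @export
filter_coeluting_alternatives <- function(feature_cvs, quant_table) {
  removed <- character()
  groups <- split(feature_cvs, paste(feature_cvs$pep_pair, feature_cvs$charge))
  for (g in groups) {
    if (length(unique(g$res_pair)) < 2L) next
    for (i in seq_len(nrow(g) - 1L)) {
      for (j in seq(i + 1L, nrow(g))) {
        if (g$res_pair[i] == g$res_pair[j]) next
        qi <- quant_table[quant_table$feature == g$feature[i] &
                            quant_table$matched, ]
        qj <- quant_table[quant_table$feature == g$feature[j] &
                            quant_table$matched, ]
        m <- merge(qi[, c("run_id", "rt_start", "rt_end")],
                   qj[, c("run_id", "rt_start", "rt_end")],
                   by = "run_id", suffixes = c("_i", "_j"))
        if (!nrow(m)) next
        overlap <- m$rt_start_i < m$rt_end_j & m$rt_start_j < m$rt_end_i
        if (any(overlap, na.rm = TRUE)) {
          removed <- union(removed, c(g$res_pair[i], g$res_pair[j]))
        }
      }
    }
  }
  list(retained = setdiff(unique(feature_cvs$res_pair), removed),
       removed = removed)
}

#' Keep only residue pairs quantified in every replicate
#'
#' A pair survives when each of its member features has an area above the
#' run's noise floor in all `n_runs` replicates.
#'
#' @param feature_cvs Output of [feature_cv_table()].
#' @param quant_table Quantitation table.
#' @param n_runs Number of replicate runs required.
#' @return List with `retained` and `removed` residue-pair ids.
#' @export
filter_complete_quant <- function(feature_cvs, quant_table, n_runs) {
  ok_feature <- vapply(feature_cvs$feature, function(f) {
    q <- quant_table[quant_table$feature == f, ]
    sum(q$above_floor) >= n_runs
  }, logical(1))
  pair_ok <- tapply(ok_feature, feature_cvs$res_pair, all)
  retained <- names(pair_ok)[pair_ok]
  list(retained = retained,
       removed = setdiff(unique(feature_cvs$res_pair), retained))
}

#' Identification saturation curve
#'
#' Mean number of unique residue pairs accumulated over k runs, averaged
#' over all size-k subsets of the runs (exhaustive while the subset count
#' stays small, Monte Carlo with a fixed seed beyond that).
#'
#' @param per_run_sets List (one element per run) of residue-pair id
#'   vectors identified in that run.
#' @param k Subset sizes; defaults to `1:n`.
#' @param max_exhaustive Largest number of subsets enumerated exhaustively
#'   per k.
#' @param seed Seed for Monte Carlo subset sampling.
#' @return data.frame: `k`, `mean_pairs`, `sd_pairs`.
#' @export
saturation_curve <- function(per_run_sets, k = NULL,
                             max_exhaustive = 100000L, seed = 1L) {
  n <- length(per_run_sets)
  if (is.null(k)) k <- seq_len(n)
  if (any(k < 1L | k > n)) stop("k out of range 1..", n)
  rows <- lapply(k, function(kk) {
    if (choose(n, kk) <= max_exhaustive) {
      subsets <- utils::combn(n, kk, simplify = FALSE)
    } else {
      set.seed(seed + kk)
      subsets <- replicate(2000L, sample.int(n, kk), simplify = FALSE)
    }
    sizes <- vapply(subsets, function(s)
      length(unique(unlist(per_run_sets[s]))), numeric(1))
    data.frame(k = kk, mean_pairs = mean(sizes),
               sd_pairs = if (length(sizes) > 1L) stats::sd(sizes) else 0)
  })
  do.call(rbind, rows)
}

#' Observation-frequency histogram
#'
#' For each unique residue pair, counts in how many runs it was observed;
#' the histogram mass over m = 1..n equals the union size.
#'
#' @param per_run_sets List of per-run residue-pair id vectors.
#' @return data.frame: `m` (number of runs), `count` (pairs seen in exactly
#'   m runs).
#' @export
observation_frequency <- function(per_run_sets) {
  n <- length(per_run_sets)
  all_pairs <- unlist(lapply(per_run_sets, unique), use.names = FALSE)
  counts <- table(all_pairs)
  data.frame(m = seq_len(n),
             count = vapply(seq_len(n), function(m) sum(counts == m),
                            numeric(1)))
}

#' Overlap between two residue-pair sets
#'
#' @param set1,set2 Vectors of residue-pair ids.
#' @return Named numeric vector `c(only1, shared, only2)`.
#' @export
overlap_counts <- function(set1, set2) {
  set1 <- unique(set1); set2 <- unique(set2)
  shared <- length(intersect(set1, set2))
  c(only1 = length(set1) - shared, shared = shared,
    only2 = length(set2) - shared)
}

#' Median CV in bins of log2 peak area
#'
#' Bins residue pairs by log2 of their median peak area and reports the
#' per-bin median CV; pairs with non-positive area are excluded with a
#' warning. Empty bins are omitted.
#'
#' @param pair_table Output of [pair_cv_table()] (columns `median_area`,
#'   `pair_cv`).
#' @param bin_width Bin width in log2 units.
#' @return data.frame: `bin` (index), `log2_area_mid`, `n`, `median_cv`.
#' @export
cv_by_intensity_bins <- function(pair_table, bin_width = 1) {
  keep <- !is.na(pair_table$pair_cv) & pair_table$median_area > 0
  if (any(pair_table$median_area <= 0, na.rm = TRUE)) {
    warning("excluding ", sum(pair_table$median_area <= 0, na.rm = TRUE),
            " pair(s) with non-positive area from intensity binning")
  }
  pt <- pair_table[keep, ]
  if (!nrow(pt)) return(data.frame(bin = integer(), log2_area_mid = numeric(),
                                   n = integer(), median_cv = numeric()))
  bins <- floor(log2(pt$median_area) / bin_width)
  agg <- split(pt$pair_cv, bins)
  idx <- as.integer(names(agg))
  data.frame(
    bin = idx,
    log2_area_mid = (idx + 0.5) * bin_width,
    n = vapply(agg, length, integer(1)),
    median_cv = vapply(agg, stats::median, numeric(1)),
    row.names = NULL
  )
}
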