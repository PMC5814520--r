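# Conversion of cross-linked peptide pairs into mass-equivalent linear
# forms: the two peptides are joined by an inserted lysine carrying the
# K_xlink modification (delta = BS3 spacer - lysine + water), so the linear
# peptide has exactly the mass of the cross-linked species and can be
# quantified by any tool built for linear peptides.

.PSM_COLUMNS <- c("run_id", "scan", "charge", "pep_a", "pep_b",
                  "site_a", "site_b", "mods_a", "mods_b",
                  "prot_pos_a", "prot_pos_b", "score", "is_decoy")

#' Construct a cross-link PSM table
#'
#' One row per peptide-spectrum match of a cross-linked peptide pair.
#' Columns: `run_id`, `scan`, `charge` (precursor charge), `pep_a`/`pep_b`
#' (residue strings), `site_a`/`site_b` (1-based link positions within each
#' peptide), `mods_a`/`mods_b` (modification strings, see [parse_mods()]),
#' `prot_pos_a`/`prot_pos_b` (1-based link positions in the protein),
#' `score`, `is_decoy`.
#'
#' @param ... Vectors for the columns above (recycled per data.frame rules).
#' @return data.frame of class `crosslink_psm` with the canonical columns.
#' @export
crosslink_psm <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  missing_cols <- setdiff(.PSM_COLUMNS, names(df))
  defaults <- list(mods_a = "", mods_b = "", score = 0, is_decoy = FALSE)
  for (col in missing_cols) {
    if (col %in% names(defaults)) df[[col]] <- defaults[[col]]
    else stop("missing PSM column(s): ", col)
  }
  df <- df[, .PSM_COLUMNS]
  df$scan <- as.integer(df$scan)
  df$charge <- as.integer(df$charge)
  df$site_a <- as.integer(df$site_a)
  df$site_b <- as.integer(df$site_b)
  df$is_decoy <- as.logical(df$is_decoy)
  class(df) <- c("crosslink_psm", "data.frame")
  df
}

#' Read / write a cross-link PSM table
#'
#' Delimited text with the header columns of [crosslink_psm()]. The dialect
#' (tab or comma) is auto-detected from the header line; extra columns are
#' ignored on read.
#'
#' @param path File path.
#' @return `read_psm_table()`: a `crosslink_psm` data.frame.
#' @export
read_psm_table <- function(path) {
  if (!file.exists(path)) stop("PSM table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  missing_cols <- setdiff(setdiff(.PSM_COLUMNS, c("mods_a", "mods_b", "score", "is_decoy")),
                          names(df))
  if (length(missing_cols)) {
    stop("PSM table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("mods_a", "mods_b")) {
    if (!col %in% names(df)) df[[col]] <- ""
    df[[col]][is.na(df[[col]])] <- ""
  }
  do.call(crosslink_psm, df[, intersect(.PSM_COLUMNS, names(df))])
}

#' @rdname read_psm_table
#' @param psms `crosslink_psm` data.frame.
#' @param sep Field separator, tab by default.
#' @export
write_psm_table <- function(psms, path, sep = "\t") {
  utils::write.table(psms, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mass of the intact cross-linked species
#'
#' Sum of the two modified peptide masses plus the BS3 spacer that bridges
#' them. This is the reference against which the linear form's mass is
#' checked.
#'
#' @param psm One or more PSM rows ([crosslink_psm()]).
#' @param registry Modification registry.
#' @return Numeric vector of neutral masses in Da.
#' @export
crosslinked_mass <- function(psm, registry = default_modifications()) {
  spacer <- mass_constants()$bs3_spacer
  vapply(seq_len(nrow(psm)), function(i) {
    peptide_mass(psm$pep_a[i], psm$mods_a[i], registry) +
      peptide_mass(psm$pep_b[i], psm$mods_b[i], registry) + spacer
  }, numeric(1))
}

# Canonical peptide order: lexicographically smaller peptide string first,
# ties broken by smaller link site. Guarantees that the same cross-link
# observed with peptides swapped collapses to one linear form / feature.
.canonical_order <- function(pep_a, site_a, pep_b, site_b) {
  if (pep_a < pep_b) TRUE
  else if (pep_a > pep_b) FALSE
  else site_a <= site_b
}

#' Linearize a cross-linked PSM
#'
#' Builds the linear representation `pep1 + K + pep2` with the inserted
#' lysine carrying the `K_xlink` modification. Peptide order is canonical
#' (lexicographic, tie on link site) so swapped inputs yield the identical
#' form. Source modifications are re-mapped: first-peptide positions are
#' unchanged (0 stays the linear N-terminus), second-peptide position `p`
#' maps to `len(pep1) + 1 + p`, and a second-peptide N-terminal mod is
#' placed on that peptide's first residue. A remapping collision (two mods
#' landing on one position) signals malformed input and is rejected.
#'
#' @param psm A single PSM row ([crosslink_psm()]).
#' @param registry Modification registry.
#' @return Object of class `linear_form`: list with `sequence`,
#'   `kxlink_position`, `mods` (data.frame), `neutral_mass`, `charge`,
#'   `precursor_mz`, plus provenance (`sites`, `prot_pos`, link-site order).
#' @export
to_linear_form <- function(psm, registry = default_modifications()) {
  stopifnot(nrow(psm) == 1L)
  if (!nzchar(psm$pep_a) || !nzchar(psm$pep_b)) {
    stop("both peptides of a cross-link must be non-empty")
  }
  a_first <- .canonical_order(psm$pep_a, psm$site_a, psm$pep_b, psm$site_b)
  if (a_first) {
    pep1 <- psm$pep_a; pep2 <- psm$pep_b
    site1 <- psm$site_a; site2 <- psm$site_b
    mods1 <- parse_mods(psm$mods_a); mods2 <- parse_mods(psm$mods_b)
    prot1 <- psm$prot_pos_a; prot2 <- psm$prot_pos_b
  } else {
    pep1 <- psm$pep_b; pep2 <- psm$pep_a
    site1 <- psm$site_b; site2 <- psm$site_a
    mods1 <- parse_mods(psm$mods_b); mods2 <- parse_mods(psm$mods_a)
    prot1 <- psm$prot_pos_b; prot2 <- psm$prot_pos_a
  }
  n1 <- nchar(pep1)
  kpos <- n1 + 1L
  seq_lin <- paste0(pep1, "K", pep2)
  remap2 <- mods2
  if (nrow(remap2)) {
    remap2$position <- ifelse(remap2$position == 0L,
                              kpos + 1L, kpos + remap2$position)
  }
  mods <- rbind(
    mods1,
    data.frame(position = kpos, name = "K_xlink", stringsAsFactors = FALSE),
    remap2
  )
  if (anyDuplicated(mods$position)) {
    dup <- mods$position[duplicated(mods$position)]
    stop("modification position collision after remapping at linear position ",
         paste(unique(dup), collapse = ", "))
  }
  neutral_mass <- peptide_mass(seq_lin, mods, registry)
  structure(list(
    sequence = seq_lin,
    kxlink_position = kpos,
    mods = mods[order(mods$position), , drop = FALSE],
    neutral_mass = neutral_mass,
    charge = psm$charge,
    precursor_mz = mz_from_mass(neutral_mass, psm$charge),
    sites = c(site1, kpos + site2),
    prot_pos = c(prot1, prot2),
    is_decoy = isTRUE(psm$is_decoy)
  ), class = "linear_form")
}

#' @export
print.linear_form <- function(x, ...) {
  cat("Linear form of a cross-linked peptide pair\n")
  cat("  sequence:", render_modified_sequence(x$sequence, x$mods), "\n")
  cat(sprintf("  neutral mass: %.5f Da   charge: %d+   m/z: %.5f\n",
              x$neutral_mass, x$charge, x$precursor_mz))
  cat("  protein residue pair:", paste(sort(x$prot_pos), collapse = "-"), "\n")
  invisible(x)
}

#' Check linear-form mass equivalence
#'
#' The central bookkeeping identity: inserted lysine residue + K_xlink delta
#' - water = BS3 spacer, so the linear form's mass must equal the
#' cross-linked mass. Returns the absolute deviation; the pipeline asserts
#' it stays below 1e-4 Da.
#'
#' @param lf `linear_form` produced from `psm`.
#' @param psm The source PSM row.
#' @param registry Modification registry.
#' @return Absolute mass difference in Da.
#' @export
verify_mass_equivalence <- function(lf, psm,
                                    registry = default_modifications()) {
  abs(lf$neutral_mass - crosslinked_mass(psm, registry))
}

#' Linearize a whole PSM table
#'
#' Applies [to_linear_form()] row-wise and returns a flat feature-level
#' table used by the .ssl writer and the quantitation driver. The
#' `feature` column is the canonical feature key (linear modified
#' sequence + charge + protein linkage sites); `pep_pair` identifies the
#' unordered peptide-sequence pair (used by the co-elution filter) and
#' `res_pair` the unordered protein residue pair.
#'
#' @param psms `crosslink_psm` data.frame.
#' @param registry Modification registry.
#' @return data.frame, one row per PSM, with columns `run_id`, `scan`,
#'   `charge`, `sequence`, `mod_sequence`, `kxlink_position`,
#'   `neutral_mass`, `precursor_mz`, `feature`, `pep_pair`, `res_pair`,
#'   `score`, `is_decoy`, `mass_error`.
#' @export
linearize_psms <- function(psms, registry = default_modifications()) {
  rows <- lapply(seq_len(nrow(psms)), function(i) {
    psm <- psms[i, , drop = FALSE]
    lf <- to_linear_form(psm, registry)
    data.frame(
      run_id = psm$run_id,
      scan = psm$scan,
      charge = psm$charge,
      sequence = lf$sequence,
      mod_sequence = render_modified_sequence(lf$sequence, lf$mods, registry),
      kxlink_position = lf$kxlink_position,
      neutral_mass = lf$neutral_mass,
      precursor_mz = lf$precursor_mz,
      feature = feature_key(psm, registry),
      pep_pair = paste(sort(c(psm$pep_a, psm$pep_b)), collapse = "|"),
      res_pair = paste(sort(c(psm$prot_pos_a, psm$prot_pos_b)), collapse = "-"),
      score = psm$score,
      is_decoy = psm$is_decoy,
      mass_error = verify_mass_equivalence(lf, psm, registry),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
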