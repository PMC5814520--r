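# Monoisotopic mass arithmetic: residues, modifications, charge states,
# isotope envelopes. Everything downstream (linearization, XIC extraction,
# .ssl rendering) builds on these few numbers, so they are fixed in code at
# 5+ decimal precision rather than derived at run time.

# Monoisotopic elemental masses (Da). Used only to derive modification
# deltas from compositions; peptide arithmetic uses the residue table.
.ELEMENT_MASS <- c(
  H = 1.00782503,
  C = 12.00000000,
  N = 14.00307401,
  O = 15.99491462,
  S = 31.97207100
)

# Standard IUPAC monoisotopic residue masses (Da), 5-decimal precision.
.AA_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.PROTON <- 1.007276
.WATER <- 18.010565
.ISOTOPE_SPACING <- 1.003355 # C13 - C12

.elemental_mass <- function(counts) {
  sum(.ELEMENT_MASS[names(counts)] * unlist(counts))
}

#' Monoisotopic residue mass table
#'
#' Masses of the 20 standard amino acid residues (the mass a residue adds to
#' a peptide chain; a free peptide additionally carries one water).
#'
#' @return Named numeric vector of residue masses in Da.
#' @export
#' @examples
#' amino_acid_masses()[["K"]] # lysine residue, 128.09496
amino_acid_masses <- function() .AA_MASS

#' Mass constants used throughout the package
#'
#' @return Named list with `proton` (1.007276 Da), `water` (18.010565 Da),
#'   `isotope_spacing` (1.003355 Da, the C13-C12 gap) and `bs3_spacer`
#'   (the BS3 spacer that bridges two residues, composition C8H10O2).
#' @export
mass_constants <- function() {
  list(
    proton = .PROTON,
    water = .WATER,
    isotope_spacing = .ISOTOPE_SPACING,
    bs3_spacer = .elemental_mass(list(C = 8, H = 10, O = 2))
  )
}

#' Built-in modification registry
#'
#' The fixed and variable modifications of the workflow, with mass deltas
#' derived from elemental compositions:
#' \itemize{
#'   \item `carbamidomethyl-C` (+C2H3NO, 57.02146): fixed Cys alkylation.
#'   \item `oxidation-M` (+O, 15.99491): variable Met oxidation.
#'   \item `K_xlink` (27.98367): the delta carried by the lysine residue
#'     inserted during linearization; equals BS3 spacer - lysine + water so
#'     that the inserted modified lysine is mass-equivalent to the bridge.
#'   \item `BS3-OH` (156.07864): mono-link with the second ester hydrolyzed
#'     (spacer + H2O).
#'   \item `BS3-NH2` (155.09463): mono-link with the second ester aminated
#'     (spacer + NH3).
#'   \item `BS3-loop` (138.06808): both ends reacted within one peptide
#'     (the bare spacer).
#' }
#'
#' Users may extend the table with additional cross-linker chemistries; any
#' data frame with columns `name`, `delta_mass`, `targets` is accepted
#' wherever a registry argument appears.
#'
#' @return data.frame with columns `name`, `delta_mass` (Da), `targets`
#'   (residue letters; `"nterm"` marks peptide N-terminus applicability).
#' @export
default_modifications <- function() {
  spacer <- .elemental_mass(list(C = 8, H = 10, O = 2))
  water <- .elemental_mass(list(H = 2, O = 1))
  ammonia <- .elemental_mass(list(N = 1, H = 3))
  data.frame(
    name = c("carbamidomethyl-C", "oxidation-M", "K_xlink",
             "BS3-OH", "BS3-NH2", "BS3-loop"),
    delta_mass = c(
      .elemental_mass(list(C = 2, H = 3, N = 1, O = 1)),
      .ELEMENT_MASS[["O"]],
      spacer - .AA_MASS[["K"]] + water,
      spacer + water,
      spacer + ammonia,
      spacer
    ),
    targets = c("C", "M", "K", "K,S,T,Y,nterm", "K,S,T,Y,nterm", "K,S,T,Y"),
    stringsAsFactors = FALSE
  )
}

.mod_delta <- function(names, registry = default_modifications()) {
  idx <- match(names, registry$name)
  if (anyNA(idx)) {
    stop("unknown modification name(s): ",
         paste(unique(names[is.na(idx)]), collapse = ", "))
  }
  registry$delta_mass[idx]
}

#' Parse and format modification annotations
#'
#' Modifications on a peptide are carried as a compact text field
#' `"pos:name;pos:name"` (1-based positions, 0 for the peptide N-terminus),
#' e.g. `"3:oxidation-M;5:BS3-OH"`. An empty string means no modifications.
#'
#' @param txt Single modification string.
#' @return `parse_mods()`: data.frame with integer `position` and character
#'   `name`; zero rows for an empty string.
#' @export
parse_mods <- function(txt) {
  if (is.null(txt) || is.na(txt) || !nzchar(txt)) {
    return(data.frame(position = integer(), name = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(txt, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("malformed modification annotation: ", txt)
  data.frame(
    position = as.integer(vapply(parts, `[[`, "", 1L)),
    name = vapply(parts, `[[`, "", 2L),
    stringsAsFactors = FALSE
  )
}

#' @rdname parse_mods
#' @param mods data.frame with columns `position` and `name`.
#' @export
format_mods <- function(mods) {
  if (is.null(mods) || nrow(mods) == 0L) return("")
  ord <- order(mods$position, mods$name)
  paste(sprintf("%d:%s", mods$position[ord], mods$name[ord]), collapse = ";")
}

#' Monoisotopic mass of a (modified) peptide
#'
#' Sum of residue masses plus one water plus all modification deltas.
#' Monoisotopic only; average masses are not supported.
#'
#' @param sequence Residue string (1-letter codes, standard 20).
#' @param mods Optional modifications: a data.frame with columns `position`
#'   (1-based; 0 = N-terminus) and `name` (looked up in `registry`), or a
#'   string in the [parse_mods()] format.
#' @param registry Modification registry, see [default_modifications()].
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' peptide_mass("G")                      # 75.03203
#' peptide_mass("K", "1:K_xlink")         # lysine + water + 27.98367
peptide_mass <- function(sequence, mods = NULL,
                         registry = default_modifications()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty peptide sequence")
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- .AA_MASS[aa]
  if (anyNA(m)) {
    stop("unknown residue code: ",
         paste(unique(aa[is.na(m)]), collapse = ", "))
  }
  total <- sum(m) + .WATER
  if (is.character(mods)) mods <- parse_mods(mods)
  if (!is.null(mods) && nrow(mods) > 0L) {
    if (any(mods$position < 0L | mods$position > nchar(sequence))) {
      stop("modification position out of range for peptide of length ",
           nchar(sequence))
    }
    total <- total + sum(.mod_delta(mods$name, registry))
  }
  total
}

#' m/z of a charged species
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param z Positive integer charge.
#' @return (neutral_mass + z * proton) / z.
#' @export
mz_from_mass <- function(neutral_mass, z) {
  if (any(z < 1)) stop("charge must be >= 1")
  (neutral_mass + z * .PROTON) / z
}

#' m/z of an isotope peak
#'
#' Position of the k-th isotope of a precursor: the monoisotopic m/z shifted
#' by k C13-C12 spacings divided by the charge. The envelope is limited to
#' three peaks (M, M+1, M+2) by default, matching MS1-filtering practice.
#'
#' @param mono_mz Monoisotopic m/z.
#' @param z Charge (>= 1).
#' @param k Isotope index, 0-based.
#' @param max_isotope Largest allowed `k` (default 2).
#' @return m/z of the k-th isotope peak.
#' @export
isotope_mz <- function(mono_mz, z, k, max_isotope = 2L) {
  if (any(z < 1)) stop("charge must be >= 1")
  if (any(k < 0L | k > max_isotope)) {
    stop("isotope index outside supported envelope 0..", max_isotope)
  }
  mono_mz + k * .ISOTOPE_SPACING / z
}
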