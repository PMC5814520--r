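# Spectral-library input (.ssl) writing and parsing. One record per PSM:
# file, scan, charge, modified linear sequence, score type, score. The
# modified-sequence dialect renders every mass delta as a signed bracketed
# decimal with 5 places immediately after the residue it sits on
# (N-terminal deltas as a leading bracket), e.g. "GKK[+27.98367]AK".

.SSL_COLUMNS <- c("file", "scan", "charge", "sequence", "score.type", "score")

#' Render / parse modified peptide sequences
#'
#' `render_modified_sequence()` turns a plain sequence plus a modification
#' table into bracketed text with signed 5-decimal deltas
#' (`"GKK[+27.98367]AK"`); a position-0 modification becomes a leading
#' bracket. `parse_modified_sequence()` inverts it, recovering the plain
#' sequence and per-position deltas; delta values are matched back to
#' registry names within 1e-3 Da where possible.
#'
#' @param sequence Plain residue string.
#' @param mods data.frame with `position` and `name` (or `delta_mass`).
#' @param registry Modification registry for name/delta lookup.
#' @return `render_modified_sequence()`: a single string.
#' @export
render_modified_sequence <- function(sequence, mods,
                                     registry = default_modifications()) {
  if (is.character(mods)) mods <- parse_mods(mods)
  deltas <- if (!is.null(mods$delta_mass)) mods$delta_mass
            else .mod_delta(mods$name, registry)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- character(length(aa) + 1L)
  out[-1L] <- aa
  if (!is.null(mods) && nrow(mods) > 0L) {
    for (i in seq_len(nrow(mods))) {
      p <- mods$position[i] + 1L
      out[p] <- paste0(out[p], sprintf("[%+.5f]", deltas[i]))
    }
  }
  paste(out, collapse = "")
}

#' @rdname render_modified_sequence
#' @param text Bracketed modified-sequence string.
#' @return `parse_modified_sequence()`: list with `sequence` (plain string)
#'   and `mods` (data.frame `position`, `delta_mass`, `name` where matched).
#' @export
parse_modified_sequence <- function(text, registry = default_modifications()) {
  stopifnot(is.character(text), length(text) == 1L)
  pos <- integer()
  delta <- numeric()
  seq_chars <- character()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "[") {
      close <- regexpr("]", substr(text, i, n), fixed = TRUE)
      if (close < 0L) stop("unclosed modification bracket in: ", text)
      body <- substr(text, i + 1L, i + close - 2L)
      val <- suppressWarnings(as.numeric(body))
      if (is.na(val)) stop("malformed bracketed modification '", body, "'")
      pos <- c(pos, length(seq_chars))
      delta <- c(delta, val)
      i <- i + close
    } else {
      if (!ch %in% names(.AA_MASS)) stop("unknown residue code: ", ch)
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    }
  }
  mods <- data.frame(position = pos, delta_mass = delta,
                     stringsAsFactors = FALSE)
  idx <- vapply(delta, function(d) {
    hit <- which(abs(registry$delta_mass - d) < 1e-3)
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  mods$name <- ifelse(is.na(idx), NA_character_, registry$name[idx])
  list(sequence = paste(seq_chars, collapse = ""), mods = mods)
}

#' Canonical feature key
#'
#' A cross-linking feature is a unique combination of cross-linked peptide
#' sequence (with modifications), charge state, and linkage sites: two
#' charge states of one cross-link are two features, as are two linkage
#' sites on the same peptide pair. The key is built from the canonical
#' linear modified sequence, so swapping the input peptide order does not
#' change it.
#'
#' @param psm A single PSM row ([crosslink_psm()]).
#' @param registry Modification registry.
#' @return Character key, e.g. `"GKK[+27.98367]AK/3+/12-245"`.
#' @export
feature_key <- function(psm, registry = default_modifications()) {
  lf <- to_linear_form(psm, registry)
  sprintf("%s/%d+/%s",
          render_modified_sequence(lf$sequence, lf$mods, registry),
          lf$charge,
          paste(sort(lf$prot_pos), collapse = "-"))
}

#' Build .ssl records from linearized PSMs
#'
#' One record is generated per PSM (no deduplication: the library layer
#' keeps every spectrum). Scores are passed through verbatim with a generic
#' score type, since search-engine scores are not a library-native score.
#'
#' @param lf_table Output of [linearize_psms()].
#' @param file_map Named character vector mapping `run_id` to the mzML path
#'   recorded in the `file` column; unmapped run ids are used as-is.
#' @param score_type Score-type tag written for every record.
#' @return data.frame with columns `file`, `scan`, `charge`, `sequence`,
#'   `score.type`, `score`.
#' @export
make_ssl <- function(lf_table, file_map = NULL, score_type = "UNKNOWN") {
  files <- lf_table$run_id
  if (!is.null(file_map)) {
    mapped <- file_map[files]
    files <- ifelse(is.na(mapped), files, mapped)
  }
  data.frame(
    file = files,
    scan = lf_table$scan,
    charge = lf_table$charge,
    sequence = lf_table$mod_sequence,
    score.type = score_type,
    score = lf_table$score,
    stringsAsFactors = FALSE
  )
}

#' Write / read a .ssl spectrum sequence list
#'
#' Tab-separated with header `file  scan  charge  sequence  score-type
#' score`. `read_ssl()` inverts `write_ssl()` on files it produced, also
#' accepts the comma dialect, and tolerates extra columns.
#'
#' @param records data.frame of .ssl records ([make_ssl()]).
#' @param path Output path.
#' @return `write_ssl()`: the path, invisibly.
#' @export
write_ssl <- function(records, path) {
  if (nrow(records) == 0L) stop("no .ssl records to write")
  if (any(records$charge < 1L | records$charge > 9L)) {
    stop("record charge outside 1..9")
  }
  out <- records[, .SSL_COLUMNS]
  names(out) <- c("file", "scan", "charge", "sequence", "score-type", "score")
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ssl
#' @export
read_ssl <- function(path) {
  if (!file.exists(path)) stop(".ssl file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  names(df) <- sub("^score.type$", "score.type", names(df))
  missing_cols <- setdiff(.SSL_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop(".ssl file missing required column(s): ",
         paste(gsub(".", "-", missing_cols, fixed = TRUE), collapse = ", "))
  }
  charge <- suppressWarnings(as.integer(df$charge))
  if (anyNA(charge)) {
    bad <- which(is.na(charge))[1L]
    stop("malformed charge at data line ", bad, " of ", path)
  }
  df$charge <- charge
  scan <- suppressWarnings(as.integer(df$scan))
  if (anyNA(scan)) {
    bad <- which(is.na(scan))[1L]
    stop("malformed scan at data line ", bad, " of ", path)
  }
  df$scan <- scan
  for (i in seq_len(nrow(df))) {
    parsed <- tryCatch(parse_modified_sequence(df$sequence[i]),
                       error = function(e) e)
    if (inherits(parsed, "error")) {
      stop("bad sequence at data line ", i, ": ", conditionMessage(parsed))
    }
  }
  df[, .SSL_COLUMNS]
}
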