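# Independent oracles used across tests. These deliberately take different
# computational routes than the package implementation.

# brute-force tryptic digest: test every substring against the cleavage
# predicate instead of enumerating cleavage segments
oracle_digest <- function(sequence, max_missed, min_length = 1L,
                          max_length = 60L) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  is_site <- function(p) {
    p >= 1L && p < n && aa[p] %in% c("K", "R") && aa[p + 1L] != "P"
  }
  out <- character()
  for (s in seq_len(n)) {
    for (e in s:n) {
      # boundaries must be cleavage sites (or termini)
      if (s > 1L && !is_site(s - 1L)) next
      ok_end <- e == n || is_site(e)
      if (!ok_end) next
      internal <- sum(vapply(s:(e - 1L), is_site, logical(1)))
      if (e == s) internal <- 0L
      if (internal > max_missed) next
      len <- e - s + 1L
      if (len < min_length || len > max_length) next
      out <- c(out, substr(sequence, s, e))
    }
  }
  sort(out)
}

# brute-force mean union size over all size-k subsets, via bitmask
# enumeration (different route than combn)
oracle_saturation <- function(sets, k) {
  n <- length(sets)
  sizes <- numeric()
  for (mask in seq_len(2^n) - 1L) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(members) != k) next
    sizes <- c(sizes, length(unique(unlist(sets[members]))))
  }
  mean(sizes)
}

oracle_observation_frequency <- function(sets) {
  ids <- unique(unlist(sets))
  seen <- vapply(ids, function(id)
    sum(vapply(sets, function(s) id %in% s, logical(1))), numeric(1))
  vapply(seq_along(sets), function(m) sum(seen == m), numeric(1))
}

# analytic area of a Gaussian elution profile
gaussian_area <- function(amplitude, sigma) amplitude * sigma * sqrt(2 * pi)

# an xic_trace holding a given summed-intensity profile in isotope 0
make_trace <- function(rt, intensity_matrix, mz = 500, z = 2) {
  structure(list(rt = rt, intensity = as.matrix(intensity_matrix),
                 precursor_mz = mz, charge = z, quantifiable = TRUE),
            class = "xic_trace")
}

# a single-feature synthetic run from explicit centroid lists
make_run <- function(run_id, rt, peaks) linkquant::ms1_run(run_id, rt, peaks)

# a toy structure model without touching PDB files
make_model <- function(resno, x, y = 0, z = 0) {
  structure(data.frame(resno = resno, x = x, y = y, z = z),
            class = c("structure_model", "data.frame"), chain = "A")
}
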