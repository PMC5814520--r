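simple_psm <- function(pep_a = "GK", pep_b = "AK", site_a = 2L, site_b = 2L,
                       mods_a = "", mods_b = "", charge = 3L,
                       prot_a = 10L, prot_b = 20L) {
  crosslink_psm(run_id = "r1", scan = 5L, charge = charge,
                pep_a = pep_a, pep_b = pep_b,
                site_a = site_a, site_b = site_b,
                mods_a = mods_a, mods_b = mods_b,
                prot_pos_a = prot_a, prot_pos_b = prot_b,
                score = 1, is_decoy = FALSE)
}

test_that("crosslinked mass is the two peptides plus the spacer", {
  psm <- simple_psm()
  # hand sum from table entries: GK + AK + spacer
  expected <- (57.02146 + 128.09496 + 18.010565) +
    (71.03711 + 128.09496 + 18.010565) + 138.0681
  expect_equal(crosslinked_mass(psm), expected, tolerance = 1e-3)
  expect_error(to_linear_form(simple_psm(pep_a = "")), "non-empty")
  with_ox <- simple_psm(pep_a = "MK", mods_a = "1:oxidation-M")
  without <- simple_psm(pep_a = "MK")
  expect_equal(crosslinked_mass(with_ox) - crosslinked_mass(without),
               15.99491, tolerance = 1e-5)
})

test_that("linearization inserts a modified lysine and conserves mass", {
  psm <- simple_psm()
  lf <- to_linear_form(psm)
  expect_identical(lf$sequence, "AKKGK") # canonical: "AK" < "GK"
  expect_identical(lf$kxlink_position, 3L)
  expect_identical(nchar(lf$sequence),
                   nchar(psm$pep_a) + nchar(psm$pep_b) + 1L)
  expect_true("K_xlink" %in% lf$mods$name[lf$mods$position == 3L])
  expect_lt(verify_mass_equivalence(lf, psm), 1e-4)
})

test_that("linearization is invariant under peptide order swap", {
  psm <- simple_psm()
  swapped <- simple_psm(pep_a = "AK", pep_b = "GK",
                        prot_a = 20L, prot_b = 10L)
  lf1 <- to_linear_form(psm)
  lf2 <- to_linear_form(swapped)
  expect_identical(lf1$sequence, lf2$sequence)
  expect_identical(lf1$mods, lf2$mods)
  expect_equal(lf1$neutral_mass, lf2$neutral_mass)
  expect_identical(feature_key(psm), feature_key(swapped))
})

test_that("mono-link modifications land at the remapped index", {
  # BS3-OH on the non-bridging K2 of pep_a "GKSK" (link at K4);
  # canonical order puts "AK" first, so pep_a positions shift by +3
  psm <- simple_psm(pep_a = "GKSK", site_a = 4L, mods_a = "2:BS3-OH")
  lf <- to_linear_form(psm)
  expect_identical(lf$sequence, "AKKGKSK")
  expect_true(any(lf$mods$position == 3L + 2L & lf$mods$name == "BS3-OH"))
  expect_lt(verify_mass_equivalence(lf, psm), 1e-4)
})

test_that("remapping collisions are rejected", {
  # N-terminal mod of the second peptide maps onto its first residue,
  # which already carries a mod
  psm <- simple_psm(pep_a = "AK", pep_b = "CK", site_a = 2L, site_b = 2L,
                    mods_b = "0:BS3-NH2;1:carbamidomethyl-C")
  expect_error(to_linear_form(psm), "collision")
})

test_that("dropping the inserted-lysine mod shifts mass by the printed delta", {
  psm <- simple_psm()
  lf <- to_linear_form(psm)
  mods_wo <- lf$mods[lf$mods$name != "K_xlink", , drop = FALSE]
  stripped <- peptide_mass(lf$sequence, mods_wo)
  expect_equal(lf$neutral_mass - stripped, 27.983, tolerance = 1e-3)
  # replacing K_xlink by the loop-link delta changes mass by their difference
  mods_loop <- lf$mods
  mods_loop$name[mods_loop$name == "K_xlink"] <- "BS3-loop"
  reg <- default_modifications()
  expect_equal(peptide_mass(lf$sequence, mods_loop) - lf$neutral_mass,
               reg$delta_mass[reg$name == "BS3-loop"] -
                 reg$delta_mass[reg$name == "K_xlink"],
               tolerance = 1e-9)
})

test_that("mass conservation holds over many random PSMs", {
  psms <- random_crosslink_psms(300, seed = 99)
  lt <- linearize_psms(psms)
  expect_true(all(lt$mass_error < 1e-4))
  # protein linkage positions survive the round trip
  expected_pairs <- vapply(seq_len(nrow(psms)), function(i)
    paste(sort(c(psms$prot_pos_a[i], psms$prot_pos_b[i])), collapse = "-"),
    character(1))
  expect_identical(lt$res_pair, expected_pairs)
})

test_that("decoy PSMs flow through linearization unchanged", {
  psm <- simple_psm()
  psm$is_decoy <- TRUE
  lt <- linearize_psms(psm)
  expect_true(lt$is_decoy)
  expect_lt(lt$mass_error, 1e-4)
})

test_that("PSM tables round-trip in both dialects", {
  psms <- random_crosslink_psms(10, seed = 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(psms, tsv)
  expect_equal(read_psm_table(tsv), psms, ignore_attr = TRUE)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_psm_table(psms, csv, sep = ",")
  expect_equal(read_psm_table(csv), psms, ignore_attr = TRUE)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("run_id\tscan", bad)
  expect_error(read_psm_table(bad), "missing required column")
})
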