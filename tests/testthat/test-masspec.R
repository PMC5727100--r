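# Mass arithmetic, adducts, fragment prediction and spectral inference.

test_that("monoisotopic masses match an independent summation oracle", {
  expect_equal(monoisotopic_mass(elemental_formula(0, 2, 1)),
               oracle_mass(0, 2, 1), tolerance = 1e-6)
  expect_equal(round(monoisotopic_mass(elemental_formula(0, 2, 1)), 4),
               18.0106)
  # formate adduct of sucrose and [M-H]- of the diacylsucrose
  expect_equal(round(adduct_mz(elemental_formula(12, 22, 11),
                               "M+formate"), 4), 387.1144)
  expect_equal(round(adduct_mz(elemental_formula(22, 38, 13), "M-H"), 4),
               509.2240)
  expect_equal(adduct_mz(elemental_formula(22, 38, 13), "M-H"),
               oracle_mass(22, 37, 13, charge = -1), tolerance = 1e-6)
})

test_that("molecular formulas follow the sucrose-plus-ester rule", {
  f210 <- molecular_formula(parse_annotation("S2:10 (5, 5)"))
  expect_identical(format(f210), "C22H38O13")
  f322 <- molecular_formula(parse_annotation("S3:22 (5, 5, 12)"))
  expect_identical(format(f322), "C34H60O14")
  expect_identical(format(molecular_formula(acyl_sucrose())), "C12H22O11")
})

test_that("formula arithmetic commutes with mass and rejects negatives", {
  set.seed(3)
  for (i in 1:25) {
    a <- elemental_formula(sample(0:30, 1), sample(0:60, 1), sample(0:20, 1))
    b <- elemental_formula(sample(0:30, 1), sample(0:60, 1), sample(0:20, 1))
    expect_equal(monoisotopic_mass(a + b),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-9)
  }
  expect_error(elemental_formula(1, 0, 0) - elemental_formula(0, 1, 0),
               "negative")
  expect_error(adduct_mz(elemental_formula(1, 0, 0), "M-H"),
               "cannot be formed")
  expect_error(adduct_mz(elemental_formula(5, 9, 2, charge = -1), "M-H"),
               "neutral")
})

test_that("negative-mode carboxylate fragments reveal chain lengths", {
  fr <- predict_fragments(S322_P, "negative")
  expect_identical(fr$label, c("C5-carboxylate", "C12-carboxylate"))
  expect_equal(round(fr$mz, 4), c(101.0608, 199.1704))
  expect_identical(fr$multiplicity, c(2L, 1L))
  # composition suffices in negative mode
  fr2 <- predict_fragments(acyl_sucrose(composition = c(5, 5, 12)),
                           "negative")
  expect_equal(fr2$mz, fr$mz)
  expect_identical(nrow(predict_fragments(acyl_sucrose(), "negative")), 0L)
})

test_that("positive-mode glycosidic cleavage splits chains by ring", {
  fr <- predict_fragments(S315_P, "positive")
  pyr <- fr[grepl("^pyranose", fr$label), ]
  expect_identical(pyr$label, "pyranose+C5+C5+C5")
  expect_equal(round(pyr$mz, 4), 415.2326)
  fur <- fr[grepl("^furanose", fr$label), ]
  expect_equal(round(fur$mz, 4), 163.0601)  # bare fructosyl core

  frF <- predict_fragments(S315_F, "positive")
  expect_setequal(frF$label, c("pyranose+C5+C5", "furanose+C5"))

  expect_error(predict_fragments(acyl_sucrose(composition = c(5, 5)),
                                 "positive"), "negative-mode")
})

test_that("composition inference recovers the printed study annotations", {
  top <- infer_composition(555.2273, c(101.061))
  expect_identical(format_annotation(top[[1]]), "S2:10 (5, 5)")
  top2 <- infer_composition(737.3952, c(101.061, 199.170))
  expect_identical(format_annotation(top2[[1]]), "S3:22 (5, 5, 12)")
  expect_length(infer_composition(1000.0000, numeric(), tol_ppm = 5), 0)
})

test_that("composition inference inverts adduct_mz over the candidate space", {
  # brute-force oracle equivalence: every composition in the bounded
  # space is recovered as the unique zero-ppm top hit from its own
  # noise-free formate precursor and carboxylate set
  comps <- acylsugars:::enumerate_compositions(c(2L, 4L, 5L, 10L, 12L), 4L)
  for (comp in comps) {
    s <- acyl_sucrose(composition = comp)
    prec <- adduct_mz(molecular_formula(s), "M+formate")
    carbs <- predict_fragments(s, "negative")$mz
    hits <- infer_composition(prec, carbs)
    expect_identical(chain_composition(hits[[1]]), sort(comp))
    expect_equal(attr(hits[[1]], "ppm"), 0, tolerance = 1e-9)
  }
})

test_that("ring-distribution inference resolves P- and F-type splits", {
  pyr3 <- predict_fragments(S315_P, "positive")
  rd <- infer_ring_distribution(pyr3$mz[grepl("C5", pyr3$label)],
                                acyl_sucrose(composition = c(5, 5, 5)))
  expect_identical(rd$status, "unique")
  expect_identical(rd$pyranose, c(5L, 5L, 5L))
  expect_length(rd$furanose, 0)

  frF <- predict_fragments(S315_F, "positive")
  rdF <- infer_ring_distribution(frF$mz,
                                 acyl_sucrose(composition = c(5, 5, 5)))
  expect_identical(rdF$status, "unique")
  expect_identical(rdF$pyranose, c(5L, 5L))
  expect_identical(rdF$furanose, 5L)

  # unconstrained: every admissible split is reported
  rd0 <- infer_ring_distribution(numeric(),
                                 acyl_sucrose(composition = c(5, 5, 5)))
  expect_identical(rd0$status, "ambiguous")
  expect_length(rd0$splits, 2)  # (5,5,5 | -) and (5,5 | 5)
})

test_that("peak annotation respects the ppm tolerance", {
  s210 <- parse_annotation("S2:10 (5, 5)")
  pk <- peak_list(mz = 555.2294, intensity = 100)
  ann <- annotate_peaklist(pk, s210, tol_ppm = 5)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$role, "precursor")
  expect_equal(ann$ppm, 0, tolerance = 0.1)  # printed 4-d.p. precision

  # internal-standard-only list: nothing to annotate
  is_only <- peak_list(mz = 179.0708, intensity = 500)
  ann0 <- annotate_peaklist(is_only, s210, tol_ppm = 10)
  expect_identical(nrow(ann0), 0L)
  expect_identical(nrow(attr(ann0, "unmatched")), 1L)

  # no emitted annotation ever exceeds the tolerance
  g <- generate_peaklist(list(S315_P, S322_P), polarity = "negative",
                         ppm_sigma = 3, n_decoys = 30, seed = 5)
  annG <- annotate_peaklist(g$peaks, list(S315_P, S322_P), tol_ppm = 10)
  expect_true(all(abs(annG$ppm) <= 10))
  expect_true(nrow(annG) > 0)
})

test_that("peak lists round-trip through the delimited format", {
  pk <- peak_list(mz = c(555.2294, 101.0608), intensity = c(10, 5),
                  polarity = "negative", rt = c(3.2, 3.2))
  path <- tempfile(fileext = ".tsv")
  write_peaklist(pk, path)
  back <- read_peaklist(path)
  expect_equal(back$mz, pk$mz)
  expect_identical(back$polarity, pk$polarity)
  expect_equal(back$rt, pk$rt)
  # missing header column is an error
  bad <- tempfile(fileext = ".tsv")
  writeLines("mz\tintensity\n1\t2", bad)
  expect_error(read_peaklist(bad), "polarity")
})
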