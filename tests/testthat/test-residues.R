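# Position mapping via global alignment, diagnostic-residue rules,
# mutation operators and sequence-to-chemotype prediction.

test_that("position mapping reads the diagnostic residues off alignments", {
  r <- map_positions(seq_chr("Sl-ASAT2-like"), SCHEME2)
  expect_identical(unname(unclass(r)[c("135", "136", "304")]),
                   c("Q", "Y", "C"))
  expect_equal(attr(r, "identity"), 100)

  # the P-type ASAT3 allele maps V/S at 354/381 with an adjacent gap
  r3 <- map_positions(seq_chr("Sp-ASAT3-like"), SCHEME3)
  expect_identical(as.character(r3),
                   c("H", "S", "V", "V", "S", "-"))
  expect_true(is.na(attr(r3, "query_positions")[["382"]]))

  # mutating one diagnostic site changes only that site's map
  mut <- apply_mutations(seq_chr("Sl-ASAT2-like"), "C304G")
  rm_ <- map_positions(mut, SCHEME2)
  expect_identical(as.character(rm_), c("Q", "Y", "G"))

  expect_error(map_positions("MKT", SCHEME2), "shorter")
  shuffled <- paste(rev(strsplit(seq_chr("Sl-ASAT2-like"), "")[[1]]),
                    collapse = "")
  expect_error(map_positions(shuffled, SCHEME2), "not a recognizable")
})

test_that("ASAT2 residue rules reproduce the characterized enzymes", {
  call_of <- function(res) classify_asat2(stats::setNames(res,
                                                          c("135", "136",
                                                            "304")))
  sl <- call_of(c("Q", "Y", "C"))          # F only
  expect_true(sl$profile$has_F); expect_false(sl$profile$has_P)
  sp <- call_of(c("H", "C", "G"))          # P only
  expect_false(sp$profile$has_F); expect_true(sp$profile$has_P)
  hyb <- call_of(c("Q", "Y", "G"))         # natural hybrid / C304G mutant
  expect_true(hyb$profile$has_F && hyb$profile$has_P)
  la1926 <- call_of(c("P", "C", "G"))      # P only, Pro variant at 135
  expect_false(la1926$profile$has_F); expect_true(la1926$profile$has_P)
  expect_false(any(sl$exception, sp$exception, hyb$exception,
                   la1926$exception))
  # unknown letters at diagnostic sites raise the exception flag
  expect_true(call_of(c("A", "Y", "C"))$exception)
})

test_that("ASAT3 residue rules reproduce the characterized enzymes", {
  nm <- c("161", "162", "289", "354", "381", "382")
  call_of <- function(res) classify_asat3(stats::setNames(res, nm))
  sl <- call_of(c("Y", "C", "T", "L", "H", "P"))
  expect_true(sl$profile$has_F); expect_false(sl$profile$has_P)
  sp <- call_of(c("H", "S", "V", "V", "S", "-"))
  expect_true(sp$profile$has_P); expect_false(sp$profile$has_F)
  triple <- call_of(c("H", "S", "V", "L", "H", "P"))  # Sl triple mutant
  expect_true(triple$profile$has_F && triple$profile$has_P)
  dead <- call_of(c("Y", "C", "T", "V", "S", "-"))    # Sp triple mutant
  expect_false(dead$profile$has_F || dead$profile$has_P)
  # partial P-triad matches are weak evidence only, never has_P
  weak <- call_of(c("H", "C", "T", "L", "H", "P"))
  expect_false(weak$profile$has_P)
  expect_match(weak$notes, "weak P evidence")
  # user-extensible exception patterns
  exc <- classify_asat3(stats::setNames(c("H", "S", "V", "L", "S", "-"),
                                        nm),
                        exceptions = "H,S,V,L,S,-")
  expect_true(exc$exception)
})

test_that("classification is a pure function of the residue set", {
  r <- map_positions(seq_chr("Sp-ASAT3-like"), SCHEME3)
  expect_identical(classify_asat3(r)$evidence, classify_asat3(r)$evidence)
  expect_identical(format(classify_asat3(r)$profile), "P only")
})

test_that("mutation operators commute with classification", {
  sl2 <- seq_chr("Sl-ASAT2-like")
  before <- classify_asat2(map_positions(sl2, SCHEME2))
  after <- classify_asat2(map_positions(apply_mutations(sl2, "C304G"),
                                        SCHEME2))
  expect_false(before$profile$has_P)
  expect_true(after$profile$has_P)   # gains P...
  expect_true(after$profile$has_F)   # ...while keeping F (promiscuity)

  # Sp-ASAT2 H135Q + C136Y regains the F-type activity
  sp2 <- seq_chr("Sp-ASAT2-like")
  gained <- classify_asat2(map_positions(
    apply_mutations(sp2, c("H135Q", "C136Y")), SCHEME2))
  expect_true(gained$profile$has_F)

  # wild-type letter mismatches are refused
  expect_error(apply_mutations(sl2, "W304G"), "not 'W'")
  expect_error(apply_mutations(sl2, "c304g"), "cannot parse")
})

test_that("reference-coordinate editing crosses the ASAT3 indel correctly", {
  sp3 <- seq_chr("Sp-ASAT3-like")
  gained <- mutate_at_reference(sp3, SCHEME3,
                                list(`354` = "L", `381` = "HP"))
  expect_identical(nchar(gained), nchar(sp3) + 1L)  # HP restores length
  call <- classify_asat3(map_positions(gained, SCHEME3))
  expect_true(call$profile$has_F)  # gains F-type activity
  expect_error(mutate_at_reference(sp3, SCHEME3, list(`382` = "P")),
               "gap")
})

test_that("percent identity uses the gap-inclusive global alignment", {
  sl2 <- seq_chr("Sl-ASAT2-like")
  expect_equal(percent_identity(sl2, sl2), 100)
  pid <- percent_identity(seq_chr("Sp-ASAT2-like"), sl2)
  expect_gt(pid, 92)  # orthologs share >92% amino-acid identity
  expect_lt(pid, 100)
  rev_ctrl <- paste(rev(strsplit(sl2, "")[[1]]), collapse = "")
  expect_lt(percent_identity(sl2, rev_ctrl), 40)
})

test_that("plant chemotypes are predicted from sequences end to end", {
  seqs <- c(
    "plantF|ASAT2|a" = seq_chr("Sl-ASAT2-like"),
    "plantF|ASAT3|a" = seq_chr("Sl-ASAT3-like"),
    "plantP|ASAT2|a" = seq_chr("Sp-ASAT2-like"),
    "plantP|ASAT3|a" = seq_chr("Sp-ASAT3-like"))
  pred <- predict_phenotype(seqs)
  expect_identical(pred$plants$phenotype[pred$plants$plant == "plantF"],
                   "F")
  expect_identical(pred$plants$phenotype[pred$plants$plant == "plantP"],
                   "P")

  # multi-allele plant: hybrid + F ASAT2 alleles with F and P ASAT3
  # alleles accumulates both types (co-dominant allele union)
  mix <- c(
    "mix|ASAT2|hyb" = apply_mutations(seq_chr("Sl-ASAT2-like"), "C304G"),
    "mix|ASAT2|f" = seq_chr("Sl-ASAT2-like"),
    "mix|ASAT3|f" = seq_chr("Sl-ASAT3-like"),
    "mix|ASAT3|p" = seq_chr("Sp-ASAT3-like"))
  predmix <- predict_phenotype(mix)
  expect_identical(predmix$plants$phenotype, "F+P")

  # hybrid ASAT2 with P-only ASAT3: P chemotype (stranded F diacyl)
  north <- c(
    "north|ASAT2|hyb" = apply_mutations(seq_chr("Sl-ASAT2-like"),
                                        "C304G"),
    "north|ASAT3|p" = seq_chr("Sp-ASAT3-like"))
  expect_identical(predict_phenotype(north)$plants$phenotype, "P")

  # family must be determinable; plants need both families
  expect_error(predict_phenotype(c("x|bad|1" = seq_chr("Sl-ASAT2-like"))),
               "family")
  expect_error(predict_phenotype(seqs[1]), "at least one ASAT2 and one")

  # the TSV report carries the evidence
  path <- tempfile(fileext = ".tsv")
  write_phenotype_report(pred, path)
  rep_ <- utils::read.delim(path)
  expect_true(all(c("residues", "has_F", "has_P", "phenotype") %in%
                    names(rep_)))
})
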