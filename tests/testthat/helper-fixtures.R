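# Shared fixtures for the test suite: reference structures from the study
# system and sequence fixtures with the diagnostic residue letters.

# named reference structures (positions established by NMR)
S1_5   <- parse_annotation("S1:5 (iC5R4)")
S210_P <- parse_annotation("S2:10 (iC5R2, iC5R4)")       # Sp-ASAT3 product
S210_F <- parse_annotation("S2:10 (aiC5R3, iC5R4)")      # Sl-ASAT2 product
S315_P <- parse_annotation("S3:15 (iC5R2, iC5R3, iC5R4)")
S322_P <- parse_annotation("S3:22 (iC5R2, nC12R3, iC5R4)")
S315_F <- parse_annotation("S3:15 (aiC5R3, iC5R4, iC5R3p)")

FIXTURES <- make_reference_fixtures()
SCHEME2 <- reference_scheme("ASAT2")
SCHEME3 <- reference_scheme("ASAT3")

seq_chr <- function(name) as.character(FIXTURES[[name]])

# independent monoisotopic masses for the oracle tests (summation with
# atomic masses transcribed separately from the implementation)
oracle_mass <- function(C, H, O, charge = 0) {
  C * 12 + H * 1.0078250319 + O * 15.9949146221 - charge * 0.0005485799
}

# a random acylsucrose for property tests
random_acylsucrose <- function(placed = TRUE) {
  if (placed) {
    k <- sample(1:4, 1)
    pos <- sample(RING_POSITIONS, k)
    chains <- lapply(seq_len(k), function(i) {
      n <- sample(c(2L, 4L, 5L, 10L, 12L), 1)
      br <- if (n >= 4) sample(c("iso", "anteiso", "normal",
                                 "unspecified"), 1)
            else sample(c("normal", "unspecified"), 1)
      acyl_chain(n, br)
    })
    acyl_sucrose(placements = stats::setNames(chains, pos))
  } else {
    k <- sample(1:4, 1)
    acyl_sucrose(composition = sample(c(2L, 4L, 5L, 10L, 12L), k,
                                      replace = TRUE))
  }
}
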