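# Rule-based pathway simulation: single rule applications, BFS closure,
# mass conservation, emergent reaction-order reversal, dead-end logic.

rules <- builtin_rules()

test_that("single enzyme applications follow the acceptor patterns", {
  # pathway start: sucrose -> S1:5 (iC5R4)
  p <- apply_enzyme(rules$ASAT1, acyl_sucrose(), "iC5")
  expect_identical(format_annotation(p), "S1:5 (iC5R4)-P")

  # the flip: ASAT3-P acylates the monoacyl acceptor at R2
  p2 <- apply_enzyme(rules[["ASAT3-P"]], S1_5, "iC5")
  expect_identical(format_annotation(p2), format_annotation(S210_P))

  # ASAT2-P completes the P-type triacylsucrose at R3
  p3 <- apply_enzyme(rules[["ASAT2-P"]], S210_P, "nC12")
  expect_identical(format_annotation(p3), format_annotation(S322_P))

  # ASAT3-F extends the F-pathway diacyl at R3'
  p4 <- apply_enzyme(rules[["ASAT3-F"]], S210_F, "iC5")
  expect_identical(names(p4$placements), c("R3", "R4", "R3p"))
  expect_identical(classify_type(p4), "F")

  # non-matching acceptors return no-match, not an error
  expect_null(apply_enzyme(rules[["ASAT2-F"]], S210_P, "iC5"))
  expect_null(apply_enzyme(rules$ASAT4, S315_P, "C2"))

  # a disallowed donor is an error, distinct from no-match
  expect_error(apply_enzyme(rules$ASAT1, acyl_sucrose(), "nC12"),
               "does not accept donor")
  expect_error(apply_enzyme(rules$ASAT4, S315_F, "iC5"), "does not accept")
})

test_that("the P-type diacylsucrose is inert under all cultivated-tomato rules", {
  sl <- rules[c("ASAT1", "ASAT2-F", "ASAT3-F", "ASAT4")]
  for (r in sl)
    for (d in vapply(r$donors, format, character(1)))
      expect_null(apply_enzyme(r, S210_P, d))
  # while the two S2:10 regio-isomers are distinct states
  expect_false(format_annotation(S210_P) == format_annotation(S210_F))
})

test_that("every simulation edge conserves the molecular formula", {
  sim <- simulate_pathway(c("ASAT1", "ASAT2-F", "ASAT3-F", "ASAT3-P",
                            "ASAT2-P", "ASAT4"),
                          donors = c("iC5", "aiC5", "nC12", "C2"))
  expect_gt(nrow(sim$edges), 10)
  for (i in seq_len(nrow(sim$edges))) {
    sub <- parse_annotation(sim$edges$substrate[i])
    prod <- parse_annotation(sim$edges$product[i])
    n <- parse_chain_token(sim$edges$donor[i])$carbons
    dm <- monoisotopic_mass(molecular_formula(prod)) -
      monoisotopic_mass(molecular_formula(sub))
    expect_equal(dm, monoisotopic_mass(elemental_formula(n, 2 * n - 2, 1)),
                 tolerance = 1e-9)
    # chain count strictly increases by one per application
    expect_identical(length(prod$composition), length(sub$composition) + 1L)
  }
})

test_that("the cultivated-tomato enzyme set makes F-type triacylsucroses", {
  sim <- simulate_pathway(c("ASAT1", "ASAT2-F", "ASAT3-F"),
                          donors = c("iC5", "aiC5", "nC12"))
  term <- sim$states[sim$states$terminal & !sim$states$dead_end, ]
  expect_identical(sim$phenotype, "F")
  expect_true(all(term$type == "F"))
  # S3:15-F and S3:22-F compositions among the terminals
  comps <- vapply(term$annotation, function(a)
    paste(chain_composition(parse_annotation(a)), collapse = ","),
    character(1))
  expect_true("5,5,5" %in% comps)
  expect_true("5,5,12" %in% comps)
  # reaction order is emergent: R3 is always acylated before R3p
  r3 <- sim$edges[sim$edges$position == "R3", ]
  expect_true(all(r3$enzyme == "ASAT2-F"))
  r3p <- sim$edges[sim$edges$position == "R3p", ]
  expect_true(all(lengths(lapply(r3p$substrate, function(a)
    parse_annotation(a)$composition)) == 2L))
})

test_that("the S. pennellii set yields exactly the two P-type products", {
  sim <- simulate_pathway(c("ASAT1", "ASAT3-P", "ASAT2-P"),
                          donors = c("iC5", "nC12"))
  term <- sim$states[sim$states$terminal, ]
  expect_setequal(term$annotation,
                  c("S3:15 (iC5R2, iC5R3, iC5R4)-P",
                    "S3:22 (iC5R2, nC12R3, iC5R4)-P"))
  expect_identical(sim$phenotype, "P")
  expect_false(any(sim$states$dead_end))
  # flipped order: R2 is acylated from the monoacyl state, before R3
  r2 <- sim$edges[sim$edges$position == "R2", ]
  expect_true(all(r2$enzyme == "ASAT3-P"))
  expect_true(all(vapply(r2$substrate, function(a)
    length(parse_annotation(a)$composition), integer(1)) == 1L))
})

test_that("the union of both enzyme sets makes both acylsucrose types", {
  sim <- simulate_pathway(c("ASAT1", "ASAT2-F", "ASAT3-F", "ASAT3-P",
                            "ASAT2-P"),
                          donors = c("iC5", "aiC5", "nC12"))
  expect_setequal(sim$phenotype, c("F", "P"))
})

test_that("hybrid ASAT2 with P-only ASAT3 strands the F-type diacyl", {
  phen <- phenotype_from_profiles(activity_profile(has_F = TRUE,
                                                   has_P = TRUE),
                                  activity_profile(has_P = TRUE))
  expect_identical(as.character(phen), "P")
  sim <- attr(phen, "simulation")
  dead <- sim$states[sim$states$dead_end, ]
  expect_gt(nrow(dead), 0)
  # the stranded intermediates are the R3-acylated (F-pathway) diacyls
  expect_true(all(vapply(dead$annotation, function(a)
    "R3" %in% names(parse_annotation(a)$placements), logical(1))))
})

test_that("profile combinations reproduce the clade chemotype table", {
  F_only <- activity_profile(has_F = TRUE)
  P_only <- activity_profile(has_P = TRUE)
  both <- activity_profile(has_F = TRUE, has_P = TRUE)
  expect_identical(as.character(phenotype_from_profiles(F_only, F_only)),
                   "F")
  expect_identical(as.character(phenotype_from_profiles(P_only, P_only)),
                   "P")
  expect_setequal(as.character(phenotype_from_profiles(both, both)),
                  c("F", "P"))
  expect_identical(as.character(phenotype_from_profiles(both, P_only)),
                   "P")
  # dead enzymes yield no chemotype at all
  expect_length(phenotype_from_profiles(activity_profile(),
                                        activity_profile()), 0)
})

test_that("ASAT4 acetylates R2 of the F-type triacylsucrose only", {
  sim <- simulate_pathway(c("ASAT1", "ASAT2-F", "ASAT3-F", "ASAT4"),
                          donors = c("iC5", "nC12", "C2"))
  tetra <- sim$states[sim$states$chains == 4L, ]
  expect_gt(nrow(tetra), 0)
  expect_true(all(vapply(tetra$annotation, function(a) {
    pl <- parse_annotation(a)$placements
    pl$R2$carbons == 2L && "R3p" %in% names(pl)
  }, logical(1))))
})

test_that("simulation is deterministic and respects its caps", {
  a <- simulate_pathway(c("ASAT1", "ASAT2-F"), donors = c("iC5", "aiC5"))
  b <- simulate_pathway(c("ASAT1", "ASAT2-F"), donors = c("iC5", "aiC5"))
  expect_identical(a$states, b$states)
  expect_identical(a$edges, b$edges)
  expect_error(simulate_pathway("ASAT1", donors = "iC5", max_states = 1),
               "cap")
  expect_error(simulate_pathway("ASAT9", donors = "iC5"), "unknown")
})

test_that("scenario configs run end to end", {
  cfg <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    enzymes = c("ASAT1", "ASAT3-P", "ASAT2-P"),
    donors = c("iC5", "nC12"), max_steps = 6), auto_unbox = TRUE), cfg)
  sim <- run_scenario(cfg)
  expect_identical(sim$phenotype, "P")
  out1 <- tempfile(); out2 <- tempfile()
  write_simulation(sim, out1, out2)
  expect_true(file.exists(out1) && file.exists(out2))
})
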