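## Seeded synthetic-data generators: ASAT-like protein variants with
## planted diagnostic residues, and LC-MS peak lists with ppm-scale mass
## noise and decoy peaks. Every other module is testable against the
## ground truth these emit, with no downloads.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## Tiny deterministic linear congruential generator, independent of R's
## RNG stream, so the reference fixtures are bit-identical regardless of
## the session's random state.
lcg_stream <- function(seed) {
  state <- as.double(seed %% 2147483647)
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (state * 48271) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
}

lcg_letters <- function(n, seed) {
  rng <- lcg_stream(seed)
  AA_ALPHABET[ceiling(rng(n) * length(AA_ALPHABET))]
}

plant_residues <- function(letters, planted) {
  for (p in names(planted)) {
    i <- as.integer(p)
    if (planted[[p]] == "-") next  # deletions handled separately
    letters[i] <- planted[[p]]
  }
  letters
}

## deterministic background substitutions at fixed non-diagnostic sites
lcg_substitute <- function(letters, n_subs, avoid, seed) {
  rng <- lcg_stream(seed)
  done <- 0L
  while (done < n_subs) {
    i <- ceiling(rng(1) * length(letters))
    if (i %in% avoid) next
    repl <- AA_ALPHABET[ceiling(rng(1) * length(AA_ALPHABET))]
    if (repl == letters[i]) next
    letters[i] <- repl
    avoid <- c(avoid, i)
    done <- done + 1L
  }
  letters
}

#' Synthetic ASAT reference fixtures
#'
#' Deterministically generates four BAHD-length (>= 430 aa) synthetic
#' stand-in sequences — `Sl-ASAT2-like`, `Sp-ASAT2-like`,
#' `Sl-ASAT3-like`, `Sp-ASAT3-like` — carrying the diagnostic residue
#' letters of the corresponding enzymes at the reference positions
#' (ASAT2: Q135/Y136/C304 for the Sl type vs H135/C136/G304 for the Sp
#' type; ASAT3: Y161/C162/T289 + L354/H381/P382 vs H161/S162/V289 +
#' V354/S381 with the residue at 382 deleted). The Sp-type sequences
#' additionally carry a fixed set of background substitutions so that
#' the within-family pairs sit at a realistic ~95% identity. These are
#' synthetic sequences, not the GenBank records; they reproduce the
#' diagnostic-site logic, not the real enzymes.
#'
#' @return An `AAStringSet` of the four fixtures, named
#'   `Sl-ASAT2-like`, `Sp-ASAT2-like`, `Sl-ASAT3-like`,
#'   `Sp-ASAT3-like`.
#' @export
make_reference_fixtures <- function() {
  len <- 460L
  ## ASAT2 family
  base2 <- plant_residues(lcg_letters(len, seed = 20317),
                          c(`135` = "Q", `136` = "Y", `304` = "C"))
  sp2 <- plant_residues(base2, c(`135` = "H", `136` = "C", `304` = "G"))
  sp2 <- lcg_substitute(sp2, n_subs = 18L,
                        avoid = ASAT2_POSITIONS, seed = 40231)
  ## ASAT3 family
  base3 <- plant_residues(lcg_letters(len, seed = 30571),
                          c(`161` = "Y", `162` = "C", `289` = "T",
                            `354` = "L", `381` = "H", `382` = "P"))
  sp3 <- plant_residues(base3, c(`161` = "H", `162` = "S", `289` = "V",
                                 `354` = "V", `381` = "S"))
  sp3 <- sp3[-382L]  # the one-residue deletion adjacent to the His site
  sp3 <- lcg_substitute(sp3, n_subs = 18L,
                        avoid = ASAT3_POSITIONS, seed = 50119)
  seqs <- c("Sl-ASAT2-like" = paste(base2, collapse = ""),
            "Sp-ASAT2-like" = paste(sp2, collapse = ""),
            "Sl-ASAT3-like" = paste(base3, collapse = ""),
            "Sp-ASAT3-like" = paste(sp3, collapse = ""))
  Biostrings::AAStringSet(seqs)
}

## evaluate `code` under a seed without disturbing the caller's RNG
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = .GlobalEnv,
                     inherits = FALSE)
  if (has_seed)
    old <- get(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv,
                    inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

## preset diagnostic residue sets per family and activity profile
PLANT_PRESETS <- list(
  ASAT2 = list(
    F      = c(`135` = "Q", `136` = "Y", `304` = "C"),
    P      = c(`135` = "H", `136` = "C", `304` = "G"),
    hybrid = c(`135` = "Q", `136` = "Y", `304` = "G")),
  ASAT3 = list(
    F      = c(`161` = "Y", `162` = "C", `289` = "T",
               `354` = "L", `381` = "H", `382` = "P"),
    P      = c(`161` = "H", `162` = "S", `289` = "V",
               `354` = "V", `381` = "S", `382` = "-"),
    hybrid = c(`161` = "H", `162` = "S", `289` = "V",
               `354` = "L", `381` = "H", `382` = "P"),
    dead   = c(`161` = "Y", `162` = "C", `289` = "T",
               `354` = "V", `381` = "S", `382` = "-"))
)

#' Generate synthetic ASAT sequence variants with known truth
#'
#' Builds `n` variants of the family's Sl-type reference fixture with a
#' planted diagnostic-residue profile and seeded random background
#' substitutions that never touch the diagnostic sites. A planted
#' `"-"` at position 382 (the P-type ASAT3 allele) is realised as a true
#' deletion, exercising the indel-aware position mapping.
#'
#' @param family `"ASAT2"` or `"ASAT3"`.
#' @param profile Planted activity profile: `"F"`, `"P"`, `"hybrid"` or
#'   (ASAT3 only) `"dead"`; alternatively pass `residues` directly.
#' @param n Number of variants.
#' @param rate Per-site background substitution probability, in
#'   \[0, 0.2\].
#' @param seed Integer seed (mandatory; generation is bit-reproducible
#'   given the scenario and seed).
#' @param residues Optional named character vector of planted residues
#'   (names = reference positions) overriding `profile`.
#' @return A list with `sequences` (an `AAStringSet`, headers
#'   `var<i>|<family>|<profile>`) and `truth` (data frame: id, family,
#'   profile, expected has_F / has_P).
#' @export
generate_variants <- function(family = c("ASAT2", "ASAT3"),
                              profile = "F", n = 10L, rate = 0.02,
                              seed, residues = NULL) {
  family <- match.arg(family)
  if (missing(seed)) stop("a seed is mandatory")
  if (rate < 0 || rate > 0.2)
    stop("background substitution rate must be in [0, 0.2]")
  if (is.null(residues)) {
    residues <- PLANT_PRESETS[[family]][[profile]]
    if (is.null(residues))
      stop("no '", profile, "' preset for ", family)
  }
  template <- strsplit(as.character(
    make_reference_fixtures()[[paste0("Sl-", family, "-like")]]),
    "")[[1]]
  template <- plant_residues(template, residues)
  diag_pos <- as.integer(names(residues))
  delete_at <- diag_pos[residues == "-"]
  expected <- if (family == "ASAT2")
    classify_asat2(residues) else classify_asat3(residues)
  seqs <- with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      letters <- template
      mutable <- setdiff(seq_along(letters), diag_pos)
      hit <- mutable[stats::runif(length(mutable)) < rate]
      for (j in hit) {
        repl <- sample(setdiff(AA_ALPHABET, letters[j]), 1L)
        letters[j] <- repl
      }
      if (length(delete_at)) letters <- letters[-delete_at]
      paste(letters, collapse = "")
    })
  })
  ids <- sprintf("var%03d|%s|%s", seq_len(n), family, profile)
  truth <- data.frame(id = ids, family = family, profile = profile,
                      has_F = expected$profile$has_F,
                      has_P = expected$profile$has_P,
                      stringsAsFactors = FALSE)
  list(sequences = Biostrings::AAStringSet(
         stats::setNames(unlist(seqs), ids)),
       truth = truth)
}

#' Generate a synthetic LC-MS peak list with known truth
#'
#' Emits, for each metabolite, its precursor adduct peaks and
#' mode-appropriate CID fragment peaks ([M-H]- and [M+formate]- plus
#' carboxylates in negative mode; [M+H]+ plus glycosidic-cleavage ring
#' fragments in positive mode), each m/z perturbed by Gaussian ppm noise
#' (mirroring ToF mass-error behaviour), plus uniformly distributed
#' decoy peaks. The truth table records every real peak's metabolite and
#' ion identity; at `ppm_sigma = 0` the peak list is exactly consistent
#' with the package's mass theory.
#'
#' @param metabolites List of [acyl_sucrose] objects (placements
#'   required for positive mode).
#' @param abundances Positive numeric intensities, one per metabolite.
#' @param polarity `"negative"` or `"positive"`.
#' @param ppm_sigma Standard deviation of the mass noise in ppm (>= 0).
#' @param n_decoys Number of uniform decoy peaks.
#' @param mz_range Numeric length-2 range for decoys (default: the span
#'   of the real peaks, widened by 10 Th).
#' @param seed Integer seed (mandatory).
#' @return A list with `peaks` (a [peak_list()]) and `truth` (data
#'   frame: mz, theoretical_mz, metabolite, role, label; decoys have
#'   metabolite `NA`).
#' @export
generate_peaklist <- function(metabolites, abundances = NULL,
                              polarity = c("negative", "positive"),
                              ppm_sigma = 2, n_decoys = 0L,
                              mz_range = NULL, seed) {
  polarity <- match.arg(polarity)
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(ppm_sigma >= 0)
  if (inherits(metabolites, "acyl_sucrose"))
    metabolites <- list(metabolites)
  if (is.null(abundances)) abundances <- rep(1000, length(metabolites))
  stopifnot(length(abundances) == length(metabolites),
            all(abundances > 0))
  rows <- list()
  for (i in seq_along(metabolites)) {
    s <- metabolites[[i]]
    ions <- candidate_ions(s, polarity)
    rel <- ifelse(ions$role == "precursor", 1, 0.4)
    rows[[length(rows) + 1L]] <- data.frame(
      theoretical_mz = ions$mz,
      intensity = abundances[i] * rel,
      metabolite = format_annotation(s),
      role = ions$role, label = ions$label, stringsAsFactors = FALSE)
  }
  real <- do.call(rbind, rows)
  peaks_truth <- with_local_seed(seed, {
    noise <- stats::rnorm(nrow(real), 0, ppm_sigma)
    real$mz <- real$theoretical_mz * (1 + noise * 1e-6)
    if (n_decoys > 0L) {
      rng <- if (is.null(mz_range))
        range(real$mz) + c(-10, 10) else mz_range
      decoys <- data.frame(
        theoretical_mz = NA_real_,
        intensity = stats::runif(n_decoys, 1,
                                 max(real$intensity) * 0.2),
        metabolite = NA_character_, role = "decoy",
        label = "decoy",
        mz = stats::runif(n_decoys, rng[1], rng[2]),
        stringsAsFactors = FALSE)
      real <- rbind(real, decoys)
    }
    real
  })
  pk <- peak_list(mz = peaks_truth$mz,
                  intensity = peaks_truth$intensity,
                  polarity = polarity)
  truth <- peaks_truth[, c("mz", "theoretical_mz", "metabolite",
                           "role", "label")]
  rownames(truth) <- NULL
  list(peaks = pk, truth = truth)
}
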