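## CID fragment prediction and spectral inference: chain composition from
## negative-mode carboxylates + precursor, ring distribution from
## positive-mode glycosidic-cleavage fragments.

## Formula increment contributed by an ester-linked chain of n carbons.
chain_increment <- function(n) elemental_formula(n, 2L * n - 2L, 1L)

## Carboxylate anion CnH(2n-1)O2- of an n-carbon acyl chain.
carboxylate_formula <- function(n)
  elemental_formula(n, 2L * n - 1L, 2L, charge = -1L)

## Glycosidic-cleavage oxocarbenium core (glucosyl or fructosyl), C6H11O5+.
sugar_cation_core <- function() elemental_formula(6L, 11L, 5L, charge = 1L)

#' Predict CID fragment ions of an acylsucrose
#'
#' In negative mode, collision-induced dissociation releases one
#' carboxylate anion CnH(2n-1)O2- per distinct chain length n, revealing
#' the number and lengths of acyl chains. In positive mode, cleavage of
#' the glycosidic linkage yields a glucosyl (pyranose) oxocarbenium
#' C6H11O5+ carrying the formula increments of the pyranose-ring chains,
#' and a fructosyl (furanose) fragment analogously; the split of chains
#' between the two fragments reveals the ring acylation pattern.
#' Duplicate species are collapsed with their multiplicity recorded.
#'
#' @param s An [acyl_sucrose]. Negative mode needs only the composition;
#'   positive mode requires placements.
#' @param polarity `"negative"` or `"positive"`.
#' @return A data frame with columns `label`, `formula`, `mz`,
#'   `multiplicity`.
#' @export
predict_fragments <- function(s, polarity = c("negative", "positive")) {
  stopifnot(inherits(s, "acyl_sucrose"))
  polarity <- match.arg(polarity)
  if (polarity == "negative") {
    comp <- chain_composition(s)
    if (length(comp) == 0L)
      return(data.frame(label = character(), formula = character(),
                        mz = numeric(), multiplicity = integer()))
    tab <- table(comp)
    ns <- as.integer(names(tab))
    fs <- lapply(ns, carboxylate_formula)
    data.frame(
      label = sprintf("C%d-carboxylate", ns),
      formula = vapply(fs, format, character(1)),
      mz = vapply(fs, monoisotopic_mass, numeric(1)),
      multiplicity = as.integer(tab),
      stringsAsFactors = FALSE)
  } else {
    if (!has_placements(s))
      stop("positive-mode fragments need chain positions; for a ",
           "composition-only structure use negative-mode carboxylates")
    pos <- names(s$placements)
    ring_frag <- function(ring_pos, core_label) {
      f <- sugar_cation_core()
      chains <- s$placements[ring_pos]
      for (ch in chains) f <- f + chain_increment(ch$carbons)
      lens <- sort(vapply(chains, `[[`, integer(1), "carbons"))
      lab <- if (length(lens))
        sprintf("%s+%s", core_label,
                paste0("C", lens, collapse = "+"))
      else core_label
      data.frame(label = lab, formula = format(f),
                 mz = monoisotopic_mass(f), multiplicity = 1L,
                 stringsAsFactors = FALSE)
    }
    out <- rbind(ring_frag(pos[is_pyranose(pos)], "pyranose"),
                 ring_frag(pos[is_furanose(pos)], "furanose"))
    ## collapse mass-identical species (e.g. bare cores of both rings)
    dup <- duplicated(out$formula)
    if (any(dup)) {
      for (f in unique(out$formula[dup])) {
        idx <- which(out$formula == f)
        out$multiplicity[idx[1]] <- length(idx)
      }
      out <- out[!dup, , drop = FALSE]
    }
    rownames(out) <- NULL
    out
  }
}

## All multisets of given sizes drawn (with repetition) from `values`.
enumerate_compositions <- function(chain_lengths, max_chains) {
  out <- list()
  for (k in seq_len(max_chains)) {
    combs <- utils::combn(length(chain_lengths) + k - 1L, k,
                          simplify = FALSE)
    ## stars-and-bars: multisets of size k from the sorted value set
    sorted <- sort(chain_lengths)
    for (cmb in combs) {
      idx <- cmb - seq_len(k) + 1L
      out[[length(out) + 1L]] <- sorted[idx]
    }
  }
  out
}

#' Infer acyl chain composition from negative-mode spectra
#'
#' Enumerates chain-count/length multisets over a bounded candidate space
#' and keeps those whose [M+formate]- or [M-H]- adduct matches the
#' observed precursor within `tol_ppm` and whose chain lengths account
#' for the observed carboxylate fragments. When carboxylates are given
#' the constraint runs both ways — every observed carboxylate must be
#' explained by a candidate chain and every distinct candidate chain
#' length must be witnessed by an observed carboxylate (CID releases a
#' carboxylate for each chain) — which resolves compositions that are
#' isobaric at the precursor level (equal chain count and total
#' carbons). Candidates are ranked by absolute precursor ppm error,
#' ties broken by fewer chains then ascending composition.
#'
#' @param precursor_mz Observed precursor m/z (negative mode).
#' @param carboxylate_mzs Observed carboxylate fragment m/z values
#'   (possibly empty).
#' @param tol_ppm Mass tolerance in ppm (default 10).
#' @param chain_lengths Candidate chain lengths (default c(2,4,5,10,12)).
#' @param max_chains Maximum chain count considered (default 4).
#' @param adducts Precursor adducts tried (default formate and M-H).
#' @return A list of composition-only [acyl_sucrose] candidates, best
#'   first, each with attributes `ppm` (precursor error) and `adduct`;
#'   empty list when nothing matches.
#' @export
infer_composition <- function(precursor_mz, carboxylate_mzs = numeric(),
                              tol_ppm = 10,
                              chain_lengths = c(2L, 4L, 5L, 10L, 12L),
                              max_chains = 4L,
                              adducts = c("M+formate", "M-H")) {
  stopifnot(tol_ppm > 0)
  ## observed carboxylates -> the chain lengths they implicate
  obs_lengths <- lapply(carboxylate_mzs, function(mz) {
    hits <- chain_lengths[vapply(chain_lengths, function(n)
      abs(ppm_error(mz, monoisotopic_mass(carboxylate_formula(n)))) <=
        tol_ppm, logical(1))]
    if (length(hits) == 0L) NA_integer_ else hits
  })
  hits <- list()
  for (comp in enumerate_compositions(chain_lengths, max_chains)) {
    f <- molecular_formula(acyl_sucrose(composition = comp))
    for (a in adducts) {
      ppm <- ppm_error(precursor_mz, adduct_mz(f, a))
      if (abs(ppm) > tol_ppm) next
      if (length(obs_lengths)) {
        ## every observed carboxylate must be explainable by some chain
        covered <- all(vapply(obs_lengths, function(ls)
          !all(is.na(ls)) && any(ls %in% comp), logical(1)))
        ## and every chain length must be witnessed by a carboxylate
        witnessed <- all(unique(comp) %in%
                           unlist(obs_lengths[!is.na(obs_lengths)]))
        if (!covered || !witnessed) next
      }
      cand <- acyl_sucrose(composition = comp)
      attr(cand, "ppm") <- ppm
      attr(cand, "adduct") <- a
      hits[[length(hits) + 1L]] <- cand
      break  # one adduct match per composition is enough
    }
  }
  if (length(hits) == 0L) return(list())
  key <- vapply(hits, function(h) {
    comp <- chain_composition(h)
    sprintf("%012.6f|%02d|%s", abs(attr(h, "ppm")), length(comp),
            paste(sprintf("%03d", comp), collapse = ","))
  }, character(1))
  hits[order(key)]
}

#' Infer the pyranose/furanose ring distribution of chains
#'
#' Tests every admissible split of a known chain composition between the
#' pyranose and furanose rings against observed positive-mode
#' glycosidic-cleavage fragment m/z values. A split is consistent when
#' the predicted ion of every chain-bearing ring fragment matches an
#' observed peak within `tol_ppm` (a ring carrying no chains imposes no
#' constraint; its bare sugar core is routinely unreported). Because the
#' glucosyl and fructosyl cores are isobaric, the split space is
#' restricted to at most `max_furanose` furanose chains (default 1,
#' matching the single-R3' furanose acylation seen throughout the tomato
#' clade); see the package vignette.
#'
#' @param positive_fragments Observed positive-mode fragment m/z values.
#' @param candidate A composition-only (or placed) [acyl_sucrose].
#' @param tol_ppm Mass tolerance in ppm (default 10).
#' @param max_furanose Maximum chains allowed on the furanose ring
#'   (default 1).
#' @return A list with elements `status` (`"unique"`, `"ambiguous"` or
#'   `"none"`), `pyranose` and `furanose` (chain-length vectors, only for
#'   a unique split) and `splits` (all consistent splits, each a list
#'   with `pyranose` and `furanose`).
#' @export
infer_ring_distribution <- function(positive_fragments, candidate,
                                    tol_ppm = 10, max_furanose = 1L) {
  stopifnot(inherits(candidate, "acyl_sucrose"))
  comp <- chain_composition(candidate)
  if (length(comp) == 0L)
    stop("candidate has no acyl chains to distribute")
  ## enumerate distinct multiset splits: choose the furanose sub-multiset
  splits <- list()
  seen <- character(0)
  for (k in 0:min(max_furanose, length(comp), 4L)) {
    if (length(comp) - k > 4L) next  # more pyranose chains than positions
    sel <- if (k == 0L) list(integer(0))
           else utils::combn(length(comp), k, simplify = FALSE)
    for (idx in sel) {
      fur <- sort(comp[idx])
      pyr <- sort(comp[setdiff(seq_along(comp), idx)])
      key <- paste(paste(pyr, collapse = ","), "|",
                   paste(fur, collapse = ","))
      if (key %in% seen) next
      seen <- c(seen, key)
      splits[[length(splits) + 1L]] <- list(pyranose = pyr, furanose = fur)
    }
  }
  frag_mz <- function(lens) {
    f <- sugar_cation_core()
    for (n in lens) f <- f + chain_increment(n)
    monoisotopic_mass(f)
  }
  matched <- function(theor)
    any(abs(ppm_error(positive_fragments, theor)) <= tol_ppm)
  if (length(positive_fragments) == 0L)
    return(list(status = "ambiguous", pyranose = NULL, furanose = NULL,
                splits = splits))
  ok <- vapply(splits, function(sp) {
    need <- Filter(length, list(sp$pyranose, sp$furanose))
    all(vapply(need, function(lens) matched(frag_mz(lens)), logical(1)))
  }, logical(1))
  consistent <- splits[ok]
  if (length(consistent) == 1L)
    list(status = "unique", pyranose = consistent[[1]]$pyranose,
         furanose = consistent[[1]]$furanose, splits = consistent)
  else if (length(consistent) == 0L)
    list(status = "none", pyranose = NULL, furanose = NULL,
         splits = list())
  else
    list(status = "ambiguous", pyranose = NULL, furanose = NULL,
         splits = consistent)
}
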