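## Peak-list I/O and annotation of observed peaks against a candidate
## acylsucrose space.

#' Construct a peak list
#'
#' @param mz Numeric m/z values (> 0).
#' @param intensity Non-negative intensities (arbitrary units).
#' @param polarity `"negative"` or `"positive"`, recycled.
#' @param rt Optional retention times; carried through I/O, never used in
#'   scoring.
#' @return A data frame of class `peak_list` with columns `mz`,
#'   `intensity`, `polarity` and optionally `rt`.
#' @export
peak_list <- function(mz, intensity, polarity = "negative", rt = NULL) {
  stopifnot(all(mz > 0), all(intensity >= 0))
  polarity <- rep_len(polarity, length(mz))
  if (!all(polarity %in% c("negative", "positive")))
    stop("polarity must be 'negative' or 'positive'")
  out <- data.frame(mz = as.numeric(mz),
                    intensity = as.numeric(intensity),
                    polarity = polarity, stringsAsFactors = FALSE)
  if (!is.null(rt)) out$rt <- as.numeric(rt)
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Read / write a peak list
#'
#' Delimited table with required header columns `mz`, `intensity`,
#' `polarity` and optional `rt`; tab-separated, UTF-8.
#'
#' @param path File path.
#' @param peaks A [peak_list()] (or compatible data frame).
#' @return `read_peaklist()` returns a `peak_list`; `write_peaklist()`
#'   returns `path` invisibly.
#' @export
read_peaklist <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("mz", "intensity", "polarity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("peak list ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$polarity), c("negative", "positive"))
  if (length(bad))
    stop("unknown polarity value(s): ", paste(bad, collapse = ", "))
  class(df) <- c("peak_list", "data.frame")
  df
}

#' @rdname read_peaklist
#' @export
write_peaklist <- function(peaks, path) {
  utils::write.table(as.data.frame(peaks), path, sep = "\t",
                     row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

## Theoretical ion table for one candidate at one polarity.
candidate_ions <- function(s, polarity) {
  rows <- list()
  f <- molecular_formula(s)
  precs <- if (polarity == "negative") c("M-H", "M+formate")
           else c("M+H", "M+Na")
  for (a in precs) {
    af <- adduct_formula(f, a)
    rows[[length(rows) + 1L]] <- data.frame(
      role = "precursor", label = a,
      formula = if (is.null(af)) NA_character_ else format(af),
      mz = adduct_mz(f, a), stringsAsFactors = FALSE)
  }
  if (polarity == "negative") {
    fr <- predict_fragments(s, "negative")
    if (nrow(fr))
      rows[[length(rows) + 1L]] <- data.frame(
        role = "carboxylate-fragment", label = fr$label,
        formula = fr$formula, mz = fr$mz, stringsAsFactors = FALSE)
  } else if (has_placements(s)) {
    fr <- predict_fragments(s, "positive")
    role <- ifelse(grepl("^pyranose", fr$label), "pyranose-fragment",
                   "furanose-fragment")
    rows[[length(rows) + 1L]] <- data.frame(
      role = role, label = fr$label, formula = fr$formula, mz = fr$mz,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Annotate a peak list against candidate acylsucroses
#'
#' For every candidate, theoretical precursor adduct ions ([M-H]- and
#' [M+formate]- in negative mode, [M+H]+ and [M+Na]+ in positive mode)
#' and CID fragment ions are matched to observed peaks of the same
#' polarity within `tol_ppm`. Every match is reported (one row per
#' candidate ion x peak), ranked by absolute ppm error; peaks that match
#' nothing are available in the `unmatched` attribute.
#'
#' @param peaks A [peak_list()].
#' @param candidates A list of [acyl_sucrose] candidates (or a single
#'   one).
#' @param tol_ppm Mass tolerance in ppm (default 10).
#' @return A data frame of class `annotation_table` with columns
#'   `candidate` (nomenclature string), `role`, `label`, `formula`,
#'   `theoretical_mz`, `observed_mz`, `ppm`, `intensity`; attribute
#'   `unmatched` holds the unannotated peaks.
#' @export
annotate_peaklist <- function(peaks, candidates, tol_ppm = 10) {
  if (inherits(candidates, "acyl_sucrose")) candidates <- list(candidates)
  stopifnot(nrow(peaks) > 0, tol_ppm > 0)
  rows <- list()
  matched_peak <- rep(FALSE, nrow(peaks))
  for (s in candidates) {
    for (pol in unique(peaks$polarity)) {
      if (pol == "positive" && !has_placements(s) &&
          n_chains(s) > 0L) {
        ## composition-only candidates still get positive precursors
        ions <- candidate_ions(acyl_sucrose(composition =
                                              chain_composition(s)),
                               "positive")
      } else {
        ions <- candidate_ions(s, pol)
      }
      idx <- which(peaks$polarity == pol)
      for (i in seq_len(nrow(ions))) {
        ppm <- ppm_error(peaks$mz[idx], ions$mz[i])
        hit <- which(abs(ppm) <= tol_ppm)
        if (length(hit) == 0L) next
        matched_peak[idx[hit]] <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(
          candidate = format_annotation(s), role = ions$role[i],
          label = ions$label[i], formula = ions$formula[i],
          theoretical_mz = ions$mz[i], observed_mz = peaks$mz[idx[hit]],
          ppm = ppm[hit], intensity = peaks$intensity[idx[hit]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(candidate = character(), role = character(),
                         label = character(), formula = character(),
                         theoretical_mz = numeric(),
                         observed_mz = numeric(), ppm = numeric(),
                         intensity = numeric(), stringsAsFactors = FALSE)
  out <- out[order(abs(out$ppm)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- as.data.frame(peaks)[!matched_peak, ,
                                                 drop = FALSE]
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Write an annotation report
#'
#' TSV report with candidate nomenclature, ion role, adduct/fragment
#' label, theoretical and observed m/z, ppm error and intensity.
#'
#' @param annotations An `annotation_table` from [annotate_peaklist()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(as.data.frame(annotations), path, sep = "\t",
                     row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
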