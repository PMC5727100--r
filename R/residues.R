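## Diagnostic-residue classification of ASAT2/ASAT3 protein sequences.
## Queries are projected onto the cultivated-tomato (Sl) reference
## coordinates by global pairwise alignment; the residues at a handful of
## specificity-determining positions then decide whether the enzyme has
## F-type activity, P-type activity, both (promiscuous/hybrid) or
## neither. Chained with the pathway simulator this predicts the plant
## chemotype from sequence alone.

## Diagnostic positions, 1-based in the Sl reference:
##   ASAT2: 135/136 (F-type requires Q135 Y136), 304 (P-type requires G).
##   ASAT3: 161/162/289 (P-type requires H/S/V), 354/381/382 (F-type
##   requires L/H/P; the P-type allele carries V/S plus a one-residue
##   deletion adjacent to the His site).
ASAT2_POSITIONS <- c(135L, 136L, 304L)
ASAT3_POSITIONS <- c(161L, 162L, 289L, 354L, 381L, 382L)

## Residue alphabets observed in nature at each diagnostic site; letters
## outside these raise the exception flag (the rules say nothing about
## them).
ASAT2_ALPHABET <- list(`135` = c("Q", "H", "P"), `136` = c("Y", "C"),
                       `304` = c("C", "G"))
ASAT3_ALPHABET <- list(`161` = c("Y", "H"), `162` = c("C", "S"),
                       `289` = c("T", "V"), `354` = c("L", "V"),
                       `381` = c("H", "S"), `382` = c("P", "-"))

#' Reference scheme for a BAHD ASAT family
#'
#' Bundles the family's synthetic reference sequence (the Sl-type
#' fixture from [make_reference_fixtures()], or a user-supplied real
#' reference) with its diagnostic positions in 1-based reference
#' coordinates.
#'
#' @param family `"ASAT2"` or `"ASAT3"`.
#' @param reference Optional reference protein sequence (single
#'   character string); defaults to the packaged synthetic Sl-type
#'   fixture.
#' @return An object of class `reference_scheme`.
#' @export
reference_scheme <- function(family = c("ASAT2", "ASAT3"),
                             reference = NULL) {
  family <- match.arg(family)
  if (is.null(reference)) {
    fx <- make_reference_fixtures()
    reference <- as.character(fx[[paste0("Sl-", family, "-like")]])
  }
  positions <- if (family == "ASAT2") ASAT2_POSITIONS else ASAT3_POSITIONS
  if (max(positions) > nchar(reference))
    stop("reference sequence shorter than its diagnostic positions")
  structure(list(family = family, reference = reference,
                 positions = positions,
                 id = paste0("Sl-", family, "-like")),
            class = "reference_scheme")
}

## Global affine-gap protein alignment (BLOSUM62, gap open 10 /
## extend 0.5) with deterministic output; the workhorse behind position
## mapping and percent identity.
align_global <- function(query, reference, gap_open = 10,
                         gap_ext = 0.5) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_ext)
  list(query = strsplit(as.character(Biostrings::alignedPattern(pa)),
                        "")[[1]],
       reference = strsplit(as.character(Biostrings::alignedSubject(pa)),
                            "")[[1]])
}

alignment_identity <- function(aln) {
  100 * sum(aln$query == aln$reference) / length(aln$query)
}

#' Map diagnostic reference positions onto a query sequence
#'
#' Globally aligns the query to the scheme's reference (affine gaps,
#' BLOSUM62, gap open 10 / extend 0.5) and reads off the query residue
#' aligned to each diagnostic reference position (`"-"` where the query
#' has a deletion). Deterministic under the fixed scoring parameters.
#'
#' @param query Protein sequence (character string, or anything
#'   `as.character()`-coercible such as an `AAString`).
#' @param scheme A [reference_scheme()].
#' @param min_length Minimum plausible query length (default 300, a
#'   BAHD-length guard).
#' @param min_identity Homology floor in percent (default 40); alignment
#'   identity below it is an error.
#' @return A named character vector (names = reference positions) of
#'   class `residue_set`, with attributes `identity` (percent, gap
#'   inclusive), `family`, and `query_positions` (1-based query indices
#'   of the mapped residues, `NA` at deletions).
#' @export
map_positions <- function(query, scheme, min_length = 300L,
                          min_identity = 40) {
  stopifnot(inherits(scheme, "reference_scheme"))
  query <- as.character(query)
  if (nchar(query) < min_length)
    stop("query (", nchar(query), " aa) is shorter than the plausible ",
         "BAHD length floor of ", min_length)
  aln <- align_global(query, scheme$reference)
  ident <- alignment_identity(aln)
  if (ident < min_identity)
    stop("query is not a recognizable ", scheme$family, " homolog ",
         sprintf("(alignment identity %.1f%% < %.0f%%)", ident,
                 min_identity))
  ref_idx <- cumsum(aln$reference != "-")
  qry_idx <- cumsum(aln$query != "-")
  residues <- character(length(scheme$positions))
  qpos <- integer(length(scheme$positions))
  for (i in seq_along(scheme$positions)) {
    col <- match(scheme$positions[i], ref_idx *
                   (aln$reference != "-"))
    residues[i] <- aln$query[col]
    qpos[i] <- if (aln$query[col] == "-") NA_integer_ else qry_idx[col]
  }
  structure(stats::setNames(residues, scheme$positions),
            identity = ident, family = scheme$family,
            query_positions = stats::setNames(qpos, scheme$positions),
            class = "residue_set")
}

#' Percent identity of two protein sequences
#'
#' Identical aligned columns divided by the full alignment length (gaps
#' included in the denominator), from the same global alignment used for
#' position mapping, on a 0-100 scale.
#'
#' @param a,b Protein sequences (character strings or `AAString`s).
#' @return Percent identity.
#' @export
percent_identity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(nzchar(a), nzchar(b))
  alignment_identity(align_global(a, b))
}

new_enzyme_call <- function(family, profile, evidence, exception,
                            notes = character()) {
  structure(list(family = family, profile = profile,
                 evidence = evidence, exception = exception,
                 notes = notes),
            class = "enzyme_call")
}

#' @export
print.enzyme_call <- function(x, ...) {
  cat("<", x$family, " call> ", format(x$profile), sep = "")
  if (x$exception) cat("  [EXCEPTION: residues match no rule row]")
  cat("\n  residues: ",
      paste(names(x$evidence), x$evidence, sep = ":", collapse = " "),
      "\n", sep = "")
  if (length(x$notes)) cat("  note: ", paste(x$notes, collapse = "; "),
                           "\n", sep = "")
  invisible(x)
}

#' Classify an ASAT2 residue set
#'
#' F-type activity (use of the monoacyl acceptor S1:5) requires Q135 and
#' Y136; P-type activity (use of the R2-acylated diacyl S2:10) requires
#' G304. G304 alongside Q135/Y136 gives a promiscuous hybrid. Residues
#' outside the naturally observed alphabets ({Q,H,P} at 135, {Y,C} at
#' 136, {C,G} at 304) set the exception flag.
#'
#' @param r A `residue_set` from [map_positions()] (or a named character
#'   vector with names `"135"`, `"136"`, `"304"`).
#' @return An `enzyme_call` with the [activity_profile()], evidence and
#'   exception flag.
#' @export
classify_asat2 <- function(r) {
  need <- as.character(ASAT2_POSITIONS)
  if (!all(need %in% names(r)))
    stop("residue set lacks ASAT2 positions ",
         paste(setdiff(need, names(r)), collapse = ", "))
  rr <- as.character(r[need]); names(rr) <- need
  has_F <- rr["135"] == "Q" && rr["136"] == "Y"
  has_P <- rr["304"] == "G"
  exception <- any(vapply(need, function(p)
    !rr[p] %in% ASAT2_ALPHABET[[p]], logical(1)))
  new_enzyme_call("ASAT2",
                  activity_profile(has_F = has_F, has_P = has_P),
                  evidence = rr, exception = exception)
}

#' Classify an ASAT3 residue set
#'
#' P-type activity (use of the monoacyl acceptor S1:5) requires the full
#' triad H161, S162, V289; one or two matches are reported as weak
#' evidence (natural single-site variants show only partial activity)
#' but never set `has_P`. F-type activity (furanose R3' acylation of the
#' diacyl acceptor) requires L354, H381, P382. The P-type allele carries
#' V and S at 354/381 with a deletion at 382. Residues outside the
#' observed alphabets, or a user-supplied nonconforming pattern, set the
#' exception flag.
#'
#' @param r A `residue_set` from [map_positions()] (or a named character
#'   vector with names `"161"`, `"162"`, `"289"`, `"354"`, `"381"`,
#'   `"382"`).
#' @param exceptions Optional character vector of known nonconforming
#'   residue patterns (each a string like `"H,S,V,V,S,-"` over the six
#'   positions); ships empty and user-extensible.
#' @return An `enzyme_call`.
#' @export
classify_asat3 <- function(r, exceptions = character()) {
  need <- as.character(ASAT3_POSITIONS)
  if (!all(need %in% names(r)))
    stop("residue set lacks ASAT3 positions ",
         paste(setdiff(need, names(r)), collapse = ", "))
  rr <- as.character(r[need]); names(rr) <- need
  p_matches <- sum(rr["161"] == "H", rr["162"] == "S", rr["289"] == "V")
  has_P <- p_matches == 3L
  has_F <- rr["354"] == "L" && rr["381"] == "H" && rr["382"] == "P"
  notes <- character()
  if (!has_P && p_matches > 0L)
    notes <- sprintf("weak P evidence (%d of 3 P-triad residues)",
                     p_matches)
  pattern <- paste(rr, collapse = ",")
  exception <- any(vapply(need, function(p)
    !rr[p] %in% ASAT3_ALPHABET[[p]], logical(1))) ||
    pattern %in% exceptions
  new_enzyme_call("ASAT3",
                  activity_profile(has_F = has_F, has_P = has_P),
                  evidence = rr, exception = exception, notes = notes)
}

## family from a FASTA header: "...|ASAT2|..." or "...|ASAT3|..."
family_from_header <- function(header) {
  if (grepl("\\|ASAT2\\|", header) || grepl("\\|ASAT2$", header))
    "ASAT2"
  else if (grepl("\\|ASAT3\\|", header) || grepl("\\|ASAT3$", header))
    "ASAT3"
  else NA_character_
}

plant_from_header <- function(header) strsplit(header, "|",
                                               fixed = TRUE)[[1]][1]

#' Predict plant chemotypes from ASAT2/ASAT3 sequences
#'
#' Classifies every sequence via [map_positions()] and
#' [classify_asat2()]/[classify_asat3()], forms per-plant activity
#' profiles as the union over alleles (the F- and P-contributing loci
#' are co-dominant), and predicts each plant's acylsucrose chemotype
#' with [phenotype_from_profiles()].
#'
#' @param sequences Protein sequences: an `AAStringSet`, a named
#'   character vector, or a FASTA file path. Headers of the form
#'   `plant|FAMILY|allele` assign family and plant; alternatively supply
#'   `family` and `plant` vectors.
#' @param family,plant Optional character vectors (recycled names not
#'   allowed; one entry per sequence) overriding header parsing.
#' @param exceptions Passed to [classify_asat3()].
#' @param ... Passed to [map_positions()].
#' @return A list of class `chemotype_prediction`: `calls` (per-sequence
#'   data frame with diagnostic residues, has_F, has_P, exception flag)
#'   and `plants` (per-plant data frame with family profiles and the
#'   predicted phenotype string, e.g. `"F+P"`).
#' @export
predict_phenotype <- function(sequences, family = NULL, plant = NULL,
                              exceptions = character(), ...) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences))
    sequences <- Biostrings::readAAStringSet(sequences)
  seqs <- vapply(as.list(sequences), as.character, character(1))
  ids <- names(seqs)
  if (is.null(ids)) stop("sequences must be named (FASTA headers)")
  if (is.null(family))
    family <- vapply(ids, family_from_header, character(1))
  if (any(is.na(family)))
    stop("cannot determine ASAT family for: ",
         paste(ids[is.na(family)], collapse = ", "),
         " (tag headers with |ASAT2| / |ASAT3| or pass `family`)")
  if (is.null(plant))
    plant <- vapply(ids, plant_from_header, character(1))
  schemes <- list(ASAT2 = reference_scheme("ASAT2"),
                  ASAT3 = reference_scheme("ASAT3"))
  calls <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    rs <- map_positions(seqs[i], schemes[[family[i]]], ...)
    calls[[i]] <- if (family[i] == "ASAT2") classify_asat2(rs)
                  else classify_asat3(rs, exceptions = exceptions)
  }
  call_df <- data.frame(
    id = ids, plant = plant, family = family,
    residues = vapply(calls, function(cl)
      paste(names(cl$evidence), cl$evidence, sep = ":",
            collapse = " "), character(1)),
    has_F = vapply(calls, function(cl) cl$profile$has_F, logical(1)),
    has_P = vapply(calls, function(cl) cl$profile$has_P, logical(1)),
    exception = vapply(calls, function(cl) cl$exception, logical(1)),
    stringsAsFactors = FALSE)
  rownames(call_df) <- NULL
  plants <- unique(plant)
  plant_rows <- lapply(plants, function(pl) {
    sub <- call_df[call_df$plant == pl, ]
    prof <- function(fam)
      activity_profile(has_F = any(sub$has_F[sub$family == fam]),
                       has_P = any(sub$has_P[sub$family == fam]))
    if (!all(c("ASAT2", "ASAT3") %in% sub$family))
      stop("plant '", pl, "' needs at least one ASAT2 and one ASAT3 ",
           "sequence")
    a2 <- prof("ASAT2"); a3 <- prof("ASAT3")
    phen <- phenotype_from_profiles(a2, a3)
    data.frame(plant = pl,
               asat2 = format(a2), asat3 = format(a3),
               phenotype = if (length(phen))
                 paste(phen, collapse = "+") else "none",
               any_exception = any(sub$exception),
               stringsAsFactors = FALSE)
  })
  plant_df <- do.call(rbind, plant_rows)
  rownames(plant_df) <- NULL
  structure(list(calls = call_df, plants = plant_df,
                 alignment = c(matrix = "BLOSUM62", gap_open = 10,
                               gap_extend = 0.5)),
            class = "chemotype_prediction")
}

#' @export
print.chemotype_prediction <- function(x, ...) {
  cat("<chemotype prediction> ", nrow(x$calls), " sequences, ",
      nrow(x$plants), " plant(s)\n", sep = "")
  print(x$plants)
  invisible(x)
}

#' Write a chemotype prediction report
#'
#' TSV with one row per sequence: id, family, diagnostic residues,
#' has_F, has_P, exception flag and the plant-level phenotype.
#'
#' @param prediction A `chemotype_prediction`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_report <- function(prediction, path) {
  df <- merge(prediction$calls,
              prediction$plants[, c("plant", "phenotype")],
              by = "plant", sort = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Apply point mutations, insertions and deletions to a protein sequence
#'
#' Mutation specs are strings in the sequence's own 1-based coordinates:
#' `"C304G"` substitutes, `"S380HP"` replaces one residue with two (an
#' insertion), `"P382-"` deletes. The stated wild-type letter must match
#' the sequence at that position (an error otherwise). Multiple specs
#' are applied left-to-right in the coordinates of the successive
#' intermediates.
#'
#' @param sequence Protein sequence (character string or `AAString`).
#' @param specs Character vector of mutation specs.
#' @return The mutated sequence as a character string.
#' @examples
#' apply_mutations("MKTC", "C4G")
#' @export
apply_mutations <- function(sequence, specs) {
  s <- strsplit(as.character(sequence), "")[[1]]
  for (spec in specs) {
    m <- regmatches(spec,
                    regexec("^([A-Z])([0-9]+)([A-Z]+|-)$", spec))[[1]]
    if (length(m) == 0L)
      stop("cannot parse mutation spec '", spec, "'")
    wt <- m[2]; pos <- as.integer(m[3]); new <- m[4]
    if (pos > length(s) || s[pos] != wt)
      stop("mutation ", spec, ": position ", pos, " is '",
           if (pos <= length(s)) s[pos] else "", "', not '", wt, "'")
    s <- append(s[-pos],
                if (new == "-") character(0)
                else strsplit(new, "")[[1]],
                after = pos - 1L)
  }
  paste(s, collapse = "")
}

#' Mutate a query at reference-coordinate positions
#'
#' Projects reference (Sl-numbering) positions onto the query through
#' the same global alignment as [map_positions()] and edits the query
#' there. Replacement by several letters inserts; `"-"` deletes. This is
#' how alleles described in a reference numbering are applied to
#' sequences whose own numbering differs (e.g. across the one-residue
#' deletion of the P-type ASAT3 allele).
#'
#' @param query Protein sequence.
#' @param scheme A [reference_scheme()] (its reference sequence defines
#'   the coordinates).
#' @param edits Named character vector/list: names are reference
#'   positions, values replacement strings.
#' @return The mutated query as a character string.
#' @export
mutate_at_reference <- function(query, scheme, edits) {
  stopifnot(inherits(scheme, "reference_scheme"))
  query <- as.character(query)
  aln <- align_global(query, scheme$reference)
  ref_idx <- cumsum(aln$reference != "-")
  qry_idx <- cumsum(aln$query != "-")
  positions <- as.integer(names(edits))
  ## apply right-to-left so earlier query indices stay valid
  ord <- order(positions, decreasing = TRUE)
  s <- strsplit(query, "")[[1]]
  for (i in ord) {
    col <- match(positions[i], ref_idx * (aln$reference != "-"))
    if (is.na(col))
      stop("reference position ", positions[i],
           " is outside the alignment")
    if (aln$query[col] == "-")
      stop("reference position ", positions[i],
           " aligns to a gap in the query; cannot edit")
    qp <- qry_idx[col]
    new <- as.character(edits[[i]])
    s <- append(s[-qp],
                if (new == "-") character(0)
                else strsplit(new, "")[[1]],
                after = qp - 1L)
  }
  paste(s, collapse = "")
}

#' Fetch protein sequences from GenBank (online helper)
#'
#' Convenience downloader for the real ASAT accessions via the NCBI
#' efetch service. This function needs network access and is entirely
#' optional: nothing else in the package (and none of its tests) calls
#' it. Offline workflows use the synthetic fixtures from
#' [make_reference_fixtures()] instead.
#'
#' @param accessions Character vector of GenBank protein/nucleotide
#'   accessions.
#' @param db NCBI database (default `"protein"`).
#' @return An `AAStringSet`.
#' @export
fetch_genbank_proteins <- function(accessions, db = "protein") {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/",
                "efetch.fcgi?db=", db, "&rettype=fasta&retmode=text",
                "&id=", paste(accessions, collapse = ","))
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  utils::download.file(url, tmp, quiet = TRUE)
  Biostrings::readAAStringSet(tmp)
}
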