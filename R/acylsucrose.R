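## The acylsucrose structural model: placements on ring positions (or a
## composition-only multiset), S n:m nomenclature, F/P classification and
## isomer enumeration.

#' Create an acylsucrose
#'
#' An acylsucrose is a sucrose backbone carrying acyl chains at named ring
#' positions. When positions are unknown (the usual LC-MS situation) a
#' composition-only object records just the multiset of chain lengths.
#'
#' @param placements Named list mapping ring positions (see
#'   [RING_POSITIONS]) to [acyl_chain] objects; at most one chain per
#'   position, at most 8 chains total. Chains may also be given as plain
#'   integers (carbon counts, unspecified branching) or chain label strings
#'   such as `"iC5"`.
#' @param composition Integer vector of chain carbon counts for
#'   composition-only objects. When `placements` is non-empty the
#'   composition is derived from it; supplying both requires them to agree.
#' @param type_tag Optional declared ring type (`"F"` or `"P"`), as carried
#'   by a `-F`/`-P` nomenclature suffix. Cross-checked against the
#'   placements when both are present.
#' @return An object of class `acyl_sucrose`.
#' @examples
#' # the P-type triacylsucrose S3:15 (5R2, 5R3, 5R4)
#' acyl_sucrose(list(R2 = 5, R3 = 5, R4 = 5))
#' # composition-only S3:22 (5, 5, 12)
#' acyl_sucrose(composition = c(5, 5, 12))
#' @export
acyl_sucrose <- function(placements = list(), composition = integer(),
                         type_tag = NULL) {
  if (length(placements)) {
    pos <- names(placements)
    if (is.null(pos) || any(!nzchar(pos)))
      stop("placements must be a named list keyed by ring position")
    bad <- setdiff(pos, RING_POSITIONS)
    if (length(bad))
      stop("unknown ring position(s): ", paste(bad, collapse = ", "))
    if (anyDuplicated(pos))
      stop("at most one acyl chain per ring position")
    placements <- lapply(placements, function(ch) {
      if (inherits(ch, "acyl_chain")) ch
      else if (is.numeric(ch)) acyl_chain(ch)
      else if (is.character(ch)) parse_chain_token(ch)
      else stop("placements must contain acyl_chain objects")
    })
    ## canonical order: pyranose R2..R6 then furanose R1p..R6p
    placements <- placements[RING_POSITIONS[RING_POSITIONS %in% pos]]
  }
  if (length(placements) > 8L)
    stop("an acylsucrose carries at most 8 chains (one per hydroxyl)")
  derived <- sort(vapply(placements, function(ch) ch$carbons, integer(1)))
  names(derived) <- NULL
  composition <- sort(as.integer(composition))
  if (length(placements)) {
    if (length(composition) && !identical(composition, derived))
      stop("composition ", paste(composition, collapse = ","),
           " does not match the placed chains ",
           paste(derived, collapse = ","))
    composition <- derived
  }
  if (any(composition < 2L))
    stop("all chain carbon counts must be >= 2")
  if (length(composition) > 8L)
    stop("an acylsucrose carries at most 8 chains (one per hydroxyl)")
  s <- structure(list(placements = placements, composition = composition,
                      type_tag = NULL),
                 class = "acyl_sucrose")
  if (!is.null(type_tag)) {
    type_tag <- match.arg(type_tag, c("F", "P"))
    if (length(placements)) {
      actual <- classify_type(s)
      if (actual != type_tag)
        stop("declared type -", type_tag,
             " contradicts the placed chains (which classify as ",
             actual, ")")
    }
    s$type_tag <- type_tag
  }
  s
}

#' Chain composition of an acylsucrose
#'
#' @param s An [acyl_sucrose].
#' @return Sorted integer vector of chain carbon counts.
#' @export
chain_composition <- function(s) {
  stopifnot(inherits(s, "acyl_sucrose"))
  s$composition
}

n_chains <- function(s) length(s$composition)
total_carbons <- function(s) sum(s$composition)
has_placements <- function(s) length(s$placements) > 0L

#' Classify an acylsucrose as F-type, P-type or other
#'
#' F-type acylsucroses carry exactly one furanose-ring chain, at the R3'
#' position, plus at least one pyranose chain; P-type acylsucroses carry
#' at least one chain, all on the pyranose ring. Any other placed pattern
#' is `"other"`; composition-only objects (no placements) are
#' `"unclassifiable"`. Classification depends only on positions, never on
#' chain branching.
#'
#' @param s An [acyl_sucrose].
#' @return One of `"F"`, `"P"`, `"other"`, `"unclassifiable"`.
#' @export
classify_type <- function(s) {
  stopifnot(inherits(s, "acyl_sucrose"))
  if (!has_placements(s)) return("unclassifiable")
  pos <- names(s$placements)
  fur <- pos[is_furanose(pos)]
  pyr <- pos[is_pyranose(pos)]
  if (length(fur) == 1L && fur == "R3p" && length(pyr) >= 1L) "F"
  else if (length(fur) == 0L && length(pyr) >= 1L) "P"
  else "other"
}

#' Parse S n:m acylsucrose nomenclature
#'
#' Parses strings of the form `S<k>:<m>` optionally followed by a
#' parenthesised chain list and an optional `-F`/`-P` suffix, e.g.
#' `"S3:22 (5, 5, 12)"`, `"S3:15 (5R2, 5R3, 5R4)"`,
#' `"S3:22 (iC5R2, nC12R3, iC5R4)-P"`, `"S1:5 (iC5R4)"`. `k` is the chain
#' count and `m` the total acyl carbons; both are cross-checked against
#' the listed chains. Position superscripts (`R2`...`R6p`, with `R3p` for
#' R3') attach chains to positions; either all chains or none may carry
#' positions.
#'
#' @param text A nomenclature string.
#' @return An [acyl_sucrose].
#' @export
parse_annotation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  m <- regmatches(txt, regexec(
    "^S([0-9]+):([0-9]+)\\s*(\\(([^)]*)\\))?\\s*(-([FP]))?$", txt))[[1]]
  if (length(m) == 0L)
    stop("cannot parse acylsucrose annotation: '", text, "'")
  k <- as.integer(m[2]); total <- as.integer(m[3])
  type_tag <- if (nzchar(m[7])) m[7] else NULL
  placements <- list(); composition <- integer()
  if (nzchar(m[4])) {
    tokens <- trimws(strsplit(m[5], ",", fixed = TRUE)[[1]])
    tokens <- tokens[nzchar(tokens)]
    parsed <- lapply(tokens, function(tok) {
      pm <- regmatches(tok, regexec("^(.*?)(R[0-9]+p?)?$", tok))[[1]]
      list(chain = parse_chain_token(pm[2]),
           pos = if (nzchar(pm[3])) pm[3] else NA_character_)
    })
    pos <- vapply(parsed, function(p) p$pos, character(1))
    if (all(!is.na(pos))) {
      bad <- setdiff(pos, RING_POSITIONS)
      if (length(bad))
        stop("unknown position token(s): ", paste(bad, collapse = ", "))
      placements <- stats::setNames(lapply(parsed, `[[`, "chain"), pos)
    } else if (all(is.na(pos))) {
      composition <- vapply(parsed, function(p) p$chain$carbons, integer(1))
      branched <- vapply(parsed, function(p)
        p$chain$branching != "unspecified", logical(1))
      if (any(branched)) {
        ## keep branching information by storing chains, composition-only
        ## objects only track carbon counts; branching without a position
        ## is accepted but reduced to the carbon count
        composition <- sort(composition)
      }
    } else {
      stop("either all chains or none may carry ring positions in '",
           text, "'")
    }
    ncheck <- if (length(placements)) length(placements)
              else length(composition)
    tcheck <- if (length(placements))
                sum(vapply(placements, `[[`, integer(1), "carbons"))
              else sum(composition)
    if (ncheck != k)
      stop("annotation '", text, "' declares ", k, " chains but lists ",
           ncheck)
    if (tcheck != total)
      stop("annotation '", text, "' declares ", total,
           " acyl carbons but the listed chains sum to ", tcheck)
  } else {
    if (k == 0L && total == 0L) {
      composition <- integer()
    } else {
      stop("annotation '", text, "' gives no chain list; counts cannot ",
           "be verified (use e.g. 'S", k, ":", total, " (...)')")
    }
  }
  acyl_sucrose(placements = placements, composition = composition,
               type_tag = type_tag)
}

#' Format an acylsucrose in S n:m nomenclature
#'
#' Inverse of [parse_annotation()]: produces the canonical nomenclature
#' string, with placed chains in canonical position order (pyranose R2 to
#' R6, then furanose R1p to R6p) and a `-F`/`-P` suffix when the structure
#' classifies as F- or P-type. Composition-only objects list chain lengths
#' ascending.
#'
#' @param s An [acyl_sucrose].
#' @param ... Unused.
#' @return A nomenclature string; `parse_annotation()` of the result
#'   reproduces `s`.
#' @export
format_annotation <- function(s, ...) {
  stopifnot(inherits(s, "acyl_sucrose"))
  head <- sprintf("S%d:%d", n_chains(s), total_carbons(s))
  if (has_placements(s)) {
    toks <- vapply(names(s$placements), function(p)
      paste0(format(s$placements[[p]]), p), character(1))
    cls <- classify_type(s)
    suffix <- if (cls %in% c("F", "P")) paste0("-", cls) else ""
    paste0(head, " (", paste(toks, collapse = ", "), ")", suffix)
  } else if (n_chains(s) > 0L) {
    suffix <- if (!is.null(s$type_tag)) paste0("-", s$type_tag) else ""
    paste0(head, " (", paste(s$composition, collapse = ", "), ")", suffix)
  } else {
    head
  }
}

#' @exportS3Method base::format
format.acyl_sucrose <- function(x, ...) format_annotation(x)

#' @export
as.character.acyl_sucrose <- function(x, ...) format_annotation(x)

#' @export
print.acyl_sucrose <- function(x, ...) {
  cat("<acylsucrose> ", format_annotation(x), sep = "")
  cls <- classify_type(x)
  cat("  [", cls, "-type]\n", sep = "")
  invisible(x)
}

#' Enumerate branching isomers of an acylsucrose
#'
#' Expands every chain of unspecified branching into each allowed
#' branching for its carbon count, returning all fully specified
#' structures. Mirrors the LC-MS situation where co-eluting iC5/aiC5
#' isomers are only resolved by NMR.
#'
#' @param s An [acyl_sucrose] with placements (branching possibly
#'   unspecified).
#' @param allowed_branchings Named list mapping carbon counts (as
#'   character keys, e.g. `"5"`) to allowed branching vectors. Default:
#'   C5 may be iso or anteiso; other lengths default to `"normal"`.
#' @return List of `acyl_sucrose` objects in deterministic lexicographic
#'   order by (position, branching); length is the product of the number
#'   of choices per unspecified chain.
#' @export
enumerate_isomers <- function(s,
                              allowed_branchings = list(`5` = c("iso",
                                                                "anteiso"))) {
  stopifnot(inherits(s, "acyl_sucrose"))
  if (!has_placements(s))
    stop("enumerate_isomers needs placements; composition-only ",
         "structures have no positional isomer space here")
  pos <- names(s$placements)
  choices <- lapply(pos, function(p) {
    ch <- s$placements[[p]]
    if (ch$branching != "unspecified") return(list(ch))
    key <- as.character(ch$carbons)
    opts <- if (!is.null(allowed_branchings[[key]]))
      allowed_branchings[[key]] else "normal"
    if (length(opts) == 0L)
      stop("empty allowed branching set for C", key, " chains")
    lapply(sort(opts), function(b) acyl_chain(ch$carbons, b))
  })
  ## lexicographic by position order: later positions vary fastest
  idx <- expand.grid(rev(lapply(choices, seq_along)),
                     KEEP.OUT.ATTRS = FALSE)
  idx <- idx[, rev(seq_along(choices)), drop = FALSE]
  idx <- idx[do.call(order, as.list(idx)), , drop = FALSE]
  lapply(seq_len(nrow(idx)), function(i) {
    pl <- stats::setNames(lapply(seq_along(pos), function(j)
      choices[[j]][[idx[i, j]]]), pos)
    acyl_sucrose(placements = pl)
  })
}

#' JSON serialization of acylsucroses
#'
#' Serializes an acylsucrose to a JSON object with ring positions as keys
#' and `{carbons, branching}` chains as values (plus a `composition`
#' array for composition-only objects); `acylsucrose_from_json()` is the
#' inverse.
#'
#' @param s An [acyl_sucrose].
#' @param json A JSON string produced by `acylsucrose_to_json()`.
#' @return `acylsucrose_to_json()` a JSON string; `acylsucrose_from_json()`
#'   an `acyl_sucrose`.
#' @export
acylsucrose_to_json <- function(s) {
  stopifnot(inherits(s, "acyl_sucrose"))
  obj <- list()
  if (has_placements(s)) {
    obj$placements <- lapply(s$placements, function(ch)
      list(carbons = ch$carbons, branching = ch$branching))
  } else {
    obj$composition <- s$composition
  }
  if (!is.null(s$type_tag)) obj$type <- s$type_tag
  jsonlite::toJSON(obj, auto_unbox = TRUE)
}

#' @rdname acylsucrose_to_json
#' @export
acylsucrose_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!is.null(obj$placements)) {
    pl <- lapply(obj$placements, function(ch)
      acyl_chain(ch$carbons, ch$branching))
    acyl_sucrose(placements = pl, type_tag = obj$type)
  } else {
    acyl_sucrose(composition = unlist(obj$composition),
                 type_tag = obj$type)
  }
}

## structural equality on the modeled fields
acylsucrose_eq <- function(a, b) {
  identical(format_annotation(a), format_annotation(b))
}
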