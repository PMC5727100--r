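## Acyl chain objects and the eight-position sucrose ring vocabulary.

#' Sucrose ring positions
#'
#' Symbolic hydroxyl positions of the sucrose backbone used throughout the
#' package: `R2`, `R3`, `R4`, `R6` on the six-membered pyranose (glucose)
#' ring and `R1p`, `R3p`, `R4p`, `R6p` on the five-membered furanose
#' (fructose) ring ("p" is the prime, rendered R3' in reports).
#'
#' @format Character vectors of position symbols.
#' @name ring_positions
NULL

#' @rdname ring_positions
#' @export
PYRANOSE_POSITIONS <- c("R2", "R3", "R4", "R6")

#' @rdname ring_positions
#' @export
FURANOSE_POSITIONS <- c("R1p", "R3p", "R4p", "R6p")

#' @rdname ring_positions
#' @export
RING_POSITIONS <- c(PYRANOSE_POSITIONS, FURANOSE_POSITIONS)

BRANCHINGS <- c("iso", "anteiso", "normal", "unspecified")

#' Create an acyl chain
#'
#' An acyl chain is described by its carbon count and branching type. The
#' branching vocabulary follows the field's chain labels: `iso` (e.g. iC5,
#' 3-methylbutanoyl), `anteiso` (aiC5, 2-methylbutanoyl), `normal` (nC12,
#' straight chain) and `unspecified` for chains whose branching is not
#' resolved (LC-MS alone cannot distinguish iC5 from aiC5).
#'
#' @param carbons Integer chain length in carbons, at least 2.
#' @param branching One of `"iso"`, `"anteiso"`, `"normal"`,
#'   `"unspecified"`. Branched types require at least 4 carbons; acetyl
#'   (C2) is therefore always normal or unspecified.
#' @return An object of class `acyl_chain`.
#' @examples
#' acyl_chain(5, "iso")      # iC5
#' acyl_chain(12, "normal")  # nC12
#' @export
acyl_chain <- function(carbons, branching = "unspecified") {
  carbons <- as.integer(carbons)
  branching <- match.arg(branching, BRANCHINGS)
  if (length(carbons) != 1L || is.na(carbons) || carbons < 2L)
    stop("an acyl chain must have an integer carbon count >= 2")
  if (branching %in% c("iso", "anteiso") && carbons < 4L)
    stop("branched (iso/anteiso) chains require at least 4 carbons")
  structure(list(carbons = carbons, branching = branching),
            class = "acyl_chain")
}

#' @exportS3Method base::format
format.acyl_chain <- function(x, ...) {
  prefix <- switch(x$branching,
                   iso = "i", anteiso = "ai", normal = "n",
                   unspecified = "")
  if (prefix == "") as.character(x$carbons)
  else paste0(prefix, "C", x$carbons)
}

#' @export
print.acyl_chain <- function(x, ...) {
  cat("<acyl chain ", format(x), ">\n", sep = "")
  invisible(x)
}

#' @export
as.character.acyl_chain <- function(x, ...) format(x)

## Parse one chain token such as "5", "C5", "iC5", "aiC5", "nC12".
parse_chain_token <- function(token) {
  m <- regmatches(token, regexec("^(i|ai|n)?C?([0-9]+)$", token))[[1]]
  if (length(m) == 0L)
    stop("cannot parse acyl chain token: '", token, "'")
  branching <- switch(m[2],
                      i = "iso", ai = "anteiso", n = "normal",
                      "unspecified")
  acyl_chain(as.integer(m[3]), branching)
}

chain_eq <- function(a, b) {
  a$carbons == b$carbons && a$branching == b$branching
}

is_pyranose <- function(pos) pos %in% PYRANOSE_POSITIONS
is_furanose <- function(pos) pos %in% FURANOSE_POSITIONS
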