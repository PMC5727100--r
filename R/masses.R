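## Elemental-formula (CHO) arithmetic and exact monoisotopic ion masses.
##
## Atomic masses: C = 12 exactly, standard monoisotopic H and O; ion
## masses include the electron mass. These constants reproduce printed
## HRMS calcd values for acylsucrose formate adducts to 4 decimal places.

MONO_MASS <- c(C = 12, H = 1.00782503, O = 15.99491462)
ELECTRON_MASS <- 0.00054858
NA_MASS <- 22.98976928  # sodium, for the M+Na adduct only

#' Create a CHO elemental formula
#'
#' Acylsucroses and their fragments contain only carbon, hydrogen and
#' oxygen; this is the unit of all mass arithmetic in the package.
#' Formulas add and subtract element-wise with `+` and `-`; subtraction
#' below zero for any element is an error.
#'
#' @param C,H,O Non-negative integer element counts.
#' @param charge Signed integer charge (0 for neutral molecules).
#' @return An object of class `chno_formula`.
#' @examples
#' elemental_formula(12, 22, 11)            # sucrose
#' elemental_formula(23, 39, 15, charge = -1)
#' @export
elemental_formula <- function(C = 0L, H = 0L, O = 0L, charge = 0L) {
  counts <- c(C = as.integer(C), H = as.integer(H), O = as.integer(O))
  if (any(is.na(counts)) || any(counts < 0L))
    stop("element counts must be non-negative integers")
  structure(list(counts = counts, charge = as.integer(charge)),
            class = "chno_formula")
}

#' @export
`+.chno_formula` <- function(e1, e2) {
  stopifnot(inherits(e1, "chno_formula"), inherits(e2, "chno_formula"))
  elemental_formula(e1$counts["C"] + e2$counts["C"],
                    e1$counts["H"] + e2$counts["H"],
                    e1$counts["O"] + e2$counts["O"],
                    charge = e1$charge + e2$charge)
}

#' @export
`-.chno_formula` <- function(e1, e2) {
  stopifnot(inherits(e1, "chno_formula"), inherits(e2, "chno_formula"))
  counts <- e1$counts - e2$counts
  if (any(counts < 0L))
    stop("formula subtraction would yield negative element counts")
  elemental_formula(counts["C"], counts["H"], counts["O"],
                    charge = e1$charge - e2$charge)
}

#' @exportS3Method base::format
format.chno_formula <- function(x, ...) {
  parts <- character(0)
  for (el in c("C", "H", "O")) {
    n <- x$counts[[el]]
    if (n > 0L) parts <- c(parts, paste0(el, if (n > 1L) n else ""))
  }
  body <- if (length(parts)) paste(parts, collapse = "") else "(empty)"
  sign <- if (x$charge == 0L) ""
          else paste0(if (abs(x$charge) > 1L) abs(x$charge) else "",
                      if (x$charge > 0L) "+" else "-")
  paste0(body, sign)
}

#' @export
print.chno_formula <- function(x, ...) {
  cat("<formula ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a formula
#'
#' Sum of element counts times monoisotopic atomic masses, minus
#' `charge` electron masses (so ion masses are true ion masses, i.e. m/z
#' for singly charged species).
#'
#' @param f A [elemental_formula()] object.
#' @return Mass in Da (equivalently m/z for |charge| = 1).
#' @examples
#' monoisotopic_mass(elemental_formula(23, 39, 15, charge = -1)) # 555.2294
#' @export
monoisotopic_mass <- function(f) {
  stopifnot(inherits(f, "chno_formula"))
  sum(f$counts * MONO_MASS[names(f$counts)]) - f$charge * ELECTRON_MASS
}

## Supported ESI adducts. The formate adduct is +CHO2 with charge -1,
## which reproduces the printed adduct formulas
## (e.g. C22H38O13 -> C23H39O15-).
ADDUCTS <- list(
  "M-H"       = list(dC = 0L,  dH = -1L, dO = 0L, extra = 0,       charge = -1L),
  "M+formate" = list(dC = 1L,  dH = 1L,  dO = 2L, extra = 0,       charge = -1L),
  "M+H"       = list(dC = 0L,  dH = 1L,  dO = 0L, extra = 0,       charge = +1L),
  "M+Na"      = list(dC = 0L,  dH = 0L,  dO = 0L, extra = NA_MASS, charge = +1L)
)

#' Names of the supported adducts
#' @return Character vector: `"M-H"`, `"M+formate"`, `"M+H"`, `"M+Na"`.
#' @export
adduct_names <- function() names(ADDUCTS)

#' Neutral molecular formula of an acylsucrose
#'
#' The neutral formula is sucrose (C12H22O11) plus, per acyl chain of n
#' carbons, CnH(2n-2)O (esterification of a hydroxyl by the acyl group
#' with loss of water). Only the chain composition is needed.
#'
#' @param s An [acyl_sucrose] with placements or composition.
#' @return A neutral [elemental_formula()].
#' @examples
#' molecular_formula(parse_annotation("S2:10 (5, 5)"))   # C22H38O13
#' @export
molecular_formula <- function(s) {
  stopifnot(inherits(s, "acyl_sucrose"))
  f <- elemental_formula(12L, 22L, 11L)
  for (n in chain_composition(s))
    f <- f + elemental_formula(n, 2L * n - 2L, 1L)
  f
}

#' m/z of an adduct ion of a neutral formula
#'
#' Applies the adduct's elemental change and charge, then computes the
#' monoisotopic ion mass (electron mass included). Only singly charged
#' adducts are supported.
#'
#' @param f A neutral [elemental_formula()].
#' @param adduct One of [adduct_names()].
#' @return Theoretical m/z.
#' @examples
#' adduct_mz(molecular_formula(parse_annotation("S2:10 (5, 5)")),
#'           "M+formate")  # 555.2294
#' @export
adduct_mz <- function(f, adduct) {
  stopifnot(inherits(f, "chno_formula"))
  if (f$charge != 0L)
    stop("adduct_mz expects a neutral formula")
  a <- ADDUCTS[[match.arg(adduct, names(ADDUCTS))]]
  counts <- f$counts + c(C = a$dC, H = a$dH, O = a$dO)
  if (any(counts < 0L))
    stop("adduct ", adduct, " cannot be formed from ", format(f))
  ion <- elemental_formula(counts["C"], counts["H"], counts["O"],
                           charge = a$charge)
  monoisotopic_mass(ion) + a$extra
}

## Formula of an adduct ion where it is CHO-representable (not M+Na).
adduct_formula <- function(f, adduct) {
  a <- ADDUCTS[[match.arg(adduct, names(ADDUCTS))]]
  if (a$extra != 0) return(NULL)
  counts <- f$counts + c(C = a$dC, H = a$dH, O = a$dO)
  elemental_formula(counts["C"], counts["H"], counts["O"],
                    charge = a$charge)
}

ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
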