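## Rule-based simulator of acylsucrose biosynthesis. Each ASAT activity is
## an acceptor-pattern -> product-position rewrite with an allowed
## acyl-CoA donor set; a breadth-first closure from sucrose enumerates all
## reachable products for a given enzyme complement and donor pool. The
## F- and P-type pathway orders (ASAT2 before ASAT3 in cultivated tomato,
## the reverse in S. pennellii) emerge from the occupancy patterns alone.

#' Create an enzyme rule
#'
#' An enzyme rule rewrites an acylsucrose acceptor by adding a donor
#' chain at a product position. The acceptor pattern is expressed purely
#' as ring-position occupancy: positions that must be occupied, positions
#' that must be free, and optionally the requirement that the occupied
#' set matches exactly.
#'
#' @param name Enzyme name, e.g. `"ASAT2-P"`.
#' @param occupied Ring positions that must carry a chain.
#' @param free Ring positions that must be unoccupied (the product
#'   position is always implicitly required free).
#' @param product_position Position at which the donor chain is added.
#' @param donors List of fully specified [acyl_chain] donors (acyl-CoA
#'   pool members this enzyme accepts); chain labels such as `"iC5"` are
#'   also accepted.
#' @param exact If `TRUE` the acceptor's occupied positions must equal
#'   `occupied` exactly (not merely contain it).
#' @return An object of class `enzyme_rule`.
#' @export
enzyme_rule <- function(name, occupied = character(), free = character(),
                        product_position, donors, exact = FALSE) {
  stopifnot(all(occupied %in% RING_POSITIONS),
            all(free %in% RING_POSITIONS),
            product_position %in% RING_POSITIONS)
  if (product_position %in% occupied)
    stop("product position must be free in any matching acceptor")
  donors <- lapply(donors, function(d) {
    d <- if (inherits(d, "acyl_chain")) d else parse_chain_token(d)
    if (d$branching == "unspecified")
      stop("donor chains must be fully specified (got ", format(d), ")")
    d
  })
  structure(list(name = name, occupied = occupied, free = free,
                 product_position = product_position, donors = donors,
                 exact = exact),
            class = "enzyme_rule")
}

#' @export
print.enzyme_rule <- function(x, ...) {
  occ <- if (length(x$occupied)) paste(x$occupied, collapse = "+")
         else "none"
  cat("<enzyme rule ", x$name, "> acceptor occupied: ", occ,
      if (x$exact) " (exactly)", "; free: ",
      if (length(x$free)) paste(x$free, collapse = ",") else "-",
      "; adds at ", x$product_position, "; donors: ",
      paste(vapply(x$donors, format, character(1)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

donor_labels <- function(rule)
  vapply(rule$donors, format, character(1))

## coerce a donor spec to a fully specified chain; acetyl (and C3) have
## no branching ambiguity, so a bare "C2" means the straight chain
as_donor <- function(d) {
  d <- if (inherits(d, "acyl_chain")) d else parse_chain_token(d)
  if (d$branching == "unspecified" && d$carbons < 4L)
    d <- acyl_chain(d$carbons, "normal")
  d
}

rule_matches <- function(rule, s) {
  pos <- names(s$placements)
  if (!all(rule$occupied %in% pos)) return(FALSE)
  if (rule$exact && !setequal(pos, rule$occupied)) return(FALSE)
  if (any(rule$free %in% pos)) return(FALSE)
  !(rule$product_position %in% pos)
}

#' The six canonical ASAT rules
#'
#' Returns the characterized acylsucrose acyltransferase activities of
#' the tomato clade as [enzyme_rule] objects:
#' \describe{
#'   \item{ASAT1}{sucrose (no chains), adds at R4; donors iC5, aiC5.}
#'   \item{ASAT2-F}{R4 occupied with R2 and R3 free, adds at R3; donors
#'     iC5, aiC5, nC12. The cultivated-tomato second step.}
#'   \item{ASAT3-F}{the diacyl acceptor with exactly R3+R4 occupied, adds
#'     at R3' (R3p); donors iC5, aiC5, nC12. Completes the F-type
#'     triacylsucrose.}
#'   \item{ASAT3-P}{the monoacyl acceptor with exactly R4 occupied, adds
#'     at R2; donors iC5, aiC5. The S. pennellii-type second step — the
#'     "flip".}
#'   \item{ASAT2-P}{R2+R4 occupied with R3 free, adds at R3; donors iC5,
#'     aiC5, nC12. Completes the P-type triacylsucrose.}
#'   \item{ASAT4}{R3' occupied with R2 free, acetylates R2; donor C2
#'     (acetyl-CoA) only.}
#' }
#' The P-type diacylsucrose S2:10 (iC5R2, iC5R4) matches none of the
#' F-pathway rules — it is not an acceptor for any characterized
#' cultivated tomato enzyme — and conversely, so the reversed reaction
#' order of the two pathways is emergent, not hard-coded.
#'
#' @return Named list of `enzyme_rule` objects.
#' @export
builtin_rules <- function() {
  iC5 <- acyl_chain(5, "iso"); aiC5 <- acyl_chain(5, "anteiso")
  nC12 <- acyl_chain(12, "normal"); C2 <- acyl_chain(2, "normal")
  list(
    "ASAT1" = enzyme_rule("ASAT1", occupied = character(),
                          product_position = "R4",
                          donors = list(iC5, aiC5), exact = TRUE),
    "ASAT2-F" = enzyme_rule("ASAT2-F", occupied = "R4",
                            free = c("R2", "R3"),
                            product_position = "R3",
                            donors = list(iC5, aiC5, nC12)),
    "ASAT3-F" = enzyme_rule("ASAT3-F", occupied = c("R3", "R4"),
                            product_position = "R3p",
                            donors = list(iC5, aiC5, nC12),
                            exact = TRUE),
    "ASAT3-P" = enzyme_rule("ASAT3-P", occupied = "R4",
                            product_position = "R2",
                            donors = list(iC5, aiC5), exact = TRUE),
    "ASAT2-P" = enzyme_rule("ASAT2-P", occupied = c("R2", "R4"),
                            free = "R3", product_position = "R3",
                            donors = list(iC5, aiC5, nC12)),
    "ASAT4" = enzyme_rule("ASAT4", occupied = "R3p", free = "R2",
                          product_position = "R2",
                          donors = list(C2))
  )
}

#' Apply one enzyme rule to a substrate
#'
#' @param rule An [enzyme_rule].
#' @param substrate An [acyl_sucrose] with placements (use
#'   `acyl_sucrose()` for sucrose itself).
#' @param donor An [acyl_chain] (or chain label) in the rule's allowed
#'   donor set; a disallowed donor is an error, distinct from a
#'   non-matching acceptor.
#' @return The product `acyl_sucrose`, or `NULL` when the acceptor
#'   pattern does not match. The product's molecular formula always
#'   equals the substrate's plus CnH(2n-2)O for the n-carbon donor.
#' @export
apply_enzyme <- function(rule, substrate, donor) {
  stopifnot(inherits(rule, "enzyme_rule"),
            inherits(substrate, "acyl_sucrose"))
  donor <- as_donor(donor)
  if (!format(donor) %in% donor_labels(rule))
    stop(rule$name, " does not accept donor ", format(donor),
         " (allowed: ", paste(donor_labels(rule), collapse = ", "), ")")
  if (!rule_matches(rule, substrate)) return(NULL)
  pl <- substrate$placements
  pl[[rule$product_position]] <- donor
  acyl_sucrose(placements = pl)
}

#' Simulate an acylsucrose pathway
#'
#' Breadth-first closure from sucrose over all (rule, donor)
#' applications. Terminal states (no applicable rule) are classified with
#' [classify_type()]; terminal mono- and di-acylsucrose intermediates are
#' flagged as dead ends (subject to degradation in planta — neither the
#' monoacyl S1:5 nor stranded diacylsucroses accumulate), and the
#' phenotype call is the set of F/P classes among the remaining
#' terminals.
#'
#' @param enzymes List of [enzyme_rule]s (or names into
#'   [builtin_rules()]).
#' @param donors List of [acyl_chain] donors (or chain labels) available
#'   as acyl-CoA pool; each rule uses the intersection with its own
#'   allowed set.
#' @param max_steps Maximum chain additions from sucrose (default 6).
#' @param max_states State-space cap (default 10000); exceeding it is an
#'   error.
#' @return An object of class `asat_simulation`: list with `states` (data
#'   frame: annotation, chains, type, terminal, dead_end), `edges` (data
#'   frame: substrate, enzyme, donor, product), `phenotype` (subset of
#'   c("F","P")), and `reachable` (named list of `acyl_sucrose` objects).
#' @examples
#' sim <- simulate_pathway(c("ASAT1", "ASAT3-P", "ASAT2-P"),
#'                         donors = c("iC5", "nC12"))
#' sim$phenotype
#' @export
simulate_pathway <- function(enzymes, donors = c("iC5", "aiC5", "nC12"),
                             max_steps = 6L, max_states = 10000L) {
  stopifnot(max_steps >= 1L)
  if (is.character(enzymes)) {
    all_rules <- builtin_rules()
    bad <- setdiff(enzymes, names(all_rules))
    if (length(bad))
      stop("unknown builtin enzyme(s): ", paste(bad, collapse = ", "))
    enzymes <- all_rules[enzymes]
  }
  donors <- lapply(donors, as_donor)
  seed <- acyl_sucrose()
  key <- function(s) format_annotation(s)
  states <- stats::setNames(list(seed), key(seed))
  frontier <- list(seed)
  edges <- list()
  step <- 0L
  while (length(frontier) && step < max_steps) {
    step <- step + 1L
    nxt <- list()
    for (s in frontier) {
      for (rule in enzymes) {
        usable <- donors[vapply(donors, function(d)
          format(d) %in% donor_labels(rule), logical(1))]
        for (d in usable) {
          prod <- apply_enzyme(rule, s, d)
          if (is.null(prod)) next
          pk <- key(prod)
          edges[[length(edges) + 1L]] <- data.frame(
            substrate = key(s), enzyme = rule$name, donor = format(d),
            product = pk, position = rule$product_position,
            stringsAsFactors = FALSE)
          if (!pk %in% names(states)) {
            if (length(states) >= max_states)
              stop("state-space cap of ", max_states, " states exceeded")
            states[[pk]] <- prod
            nxt[[length(nxt) + 1L]] <- prod
          }
        }
      }
    }
    frontier <- nxt
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(substrate = character(), enzyme = character(),
                           donor = character(), product = character(),
                           position = character(), stringsAsFactors = FALSE)
  ord <- order(names(states))
  states <- states[ord]
  applicable <- function(s) {
    for (rule in enzymes) {
      usable <- any(vapply(donors, function(d)
        format(d) %in% donor_labels(rule), logical(1)))
      if (usable && rule_matches(rule, s)) return(TRUE)
    }
    FALSE
  }
  df <- data.frame(
    annotation = names(states),
    chains = vapply(states, n_chains, integer(1)),
    type = vapply(states, classify_type, character(1)),
    terminal = !vapply(states, applicable, logical(1)),
    stringsAsFactors = FALSE)
  df$dead_end <- df$terminal & df$chains >= 1L & df$chains <= 2L
  rownames(df) <- NULL
  phen <- sort(unique(df$type[df$terminal & !df$dead_end]))
  phen <- intersect(c("F", "P"), phen)
  structure(list(states = df, edges = edges, phenotype = phen,
                 reachable = states),
            class = "asat_simulation")
}

#' @export
print.asat_simulation <- function(x, ...) {
  cat("<acylsucrose pathway simulation>\n")
  cat("  reachable states: ", nrow(x$states), "; terminal: ",
      sum(x$states$terminal), "; dead ends: ", sum(x$states$dead_end),
      "\n", sep = "")
  term <- x$states[x$states$terminal & !x$states$dead_end, ]
  if (nrow(term)) {
    cat("  terminal products:\n")
    for (i in seq_len(nrow(term)))
      cat("    ", term$annotation[i], "  [", term$type[i], "]\n",
          sep = "")
  }
  de <- x$states[x$states$dead_end, ]
  if (nrow(de))
    cat("  dead-end intermediates (degraded): ",
        paste(de$annotation, collapse = "; "), "\n", sep = "")
  cat("  phenotype call: {",
      paste(x$phenotype, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Create an F/P activity profile
#'
#' @param has_F,has_P Logical capability flags; both `TRUE` is a hybrid
#'   (promiscuous) enzyme, both `FALSE` a dead one.
#' @return An object of class `activity_profile`.
#' @export
activity_profile <- function(has_F = FALSE, has_P = FALSE) {
  structure(list(has_F = isTRUE(has_F), has_P = isTRUE(has_P)),
            class = "activity_profile")
}

#' @exportS3Method base::format
format.activity_profile <- function(x, ...) {
  if (x$has_F && x$has_P) "hybrid (F+P)"
  else if (x$has_F) "F only"
  else if (x$has_P) "P only"
  else "dead (no F/P activity)"
}

#' @export
print.activity_profile <- function(x, ...) {
  cat("<activity profile> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Predict a plant chemotype from ASAT2/ASAT3 activity profiles
#'
#' Builds the enzyme complement implied by the two profiles (an F
#' capability contributes the F-type rule, a P capability the P-type
#' rule, hybrids both) plus ASAT1, runs [simulate_pathway()], and returns
#' the phenotype call. This reproduces the genotype-to-chemotype
#' combination logic of the tomato clade, including the degraded dead-end
#' F-type diacylsucrose that arises when a hybrid ASAT2 meets a P-only
#' ASAT3.
#'
#' @param asat2,asat3 [activity_profile()] objects.
#' @param donors Donor pool (default iC5, aiC5, nC12).
#' @param include_asat4 Also include the ASAT4 acetylation rule (default
#'   `FALSE`; whether ASAT4 acts in P-type backgrounds is an open
#'   scenario, not a default claim).
#' @param ... Passed to [simulate_pathway()].
#' @return Character subset of `c("F", "P")`, with the full
#'   `asat_simulation` attached as attribute `"simulation"`.
#' @export
phenotype_from_profiles <- function(asat2, asat3,
                                    donors = c("iC5", "aiC5", "nC12"),
                                    include_asat4 = FALSE, ...) {
  stopifnot(inherits(asat2, "activity_profile"),
            inherits(asat3, "activity_profile"))
  rules <- builtin_rules()
  complement <- rules["ASAT1"]
  if (asat2$has_F) complement <- c(complement, rules["ASAT2-F"])
  if (asat2$has_P) complement <- c(complement, rules["ASAT2-P"])
  if (asat3$has_F) complement <- c(complement, rules["ASAT3-F"])
  if (asat3$has_P) complement <- c(complement, rules["ASAT3-P"])
  if (include_asat4) {
    complement <- c(complement, rules["ASAT4"])
    donors <- unique(c(donors, "C2"))
  }
  sim <- simulate_pathway(complement, donors = donors, ...)
  structure(sim$phenotype, simulation = sim)
}

#' Write simulation results to TSV
#'
#' Writes the reachable-state table (nomenclature, type, terminal and
#' dead-end flags) and the provenance edge list (substrate, enzyme,
#' donor, product) as two TSV files.
#'
#' @param sim An `asat_simulation`.
#' @param states_path,edges_path Output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_simulation <- function(sim, states_path, edges_path) {
  stopifnot(inherits(sim, "asat_simulation"))
  utils::write.table(sim$states, states_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(sim$edges, edges_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(states_path, edges_path))
}
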