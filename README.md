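# acylsugars

Tools for the acylated sucroses of tomato-clade (*Solanum*) glandular
trichomes: structural modeling and `S n:m` nomenclature, exact-mass and
CID-fragment annotation of LC-MS peak lists, rule-based simulation of the
ASAT (acylsucrose acyltransferase) biosynthetic pathway — including the
"flipped" reaction order that produces pyranose-only (P-type)
acylsucroses — and a diagnostic-residue classifier that predicts enzyme
activity type and plant chemotype from ASAT2/ASAT3 protein sequence.

## Who this is for

Researchers working on Solanaceae trichome metabolites and BAHD
acyltransferase specificity who need to (a) annotate acylsucrose ions in
negative/positive-mode CID data, (b) reason about which acylsucroses an
enzyme complement can make, or (c) screen ASAT2/ASAT3 sequences for F- vs
P-type activity residues.

## The model in brief

An acylsucrose `S k:m` is sucrose carrying `k` acyl chains with `m` total
acyl carbons at ring positions R2/R3/R4/R6 (pyranose) and
R1′/R3′/R4′/R6′ (furanose). **F-type** structures have exactly one
furanose chain, at R3′; **P-type** structures are acylated only on the
pyranose ring.

* Masses: a chain of *n* carbons adds C*n*H(2*n*−2)O to sucrose's
  C12H22O11; monoisotopic ion masses use C = 12, H = 1.00782503,
  O = 15.99491462 and include the electron mass; the formate adduct is
  +CHO2, charge −1. Negative-mode CID yields carboxylates CnH(2n−1)O2⁻
  (chain lengths); positive-mode glycosidic cleavage yields C6H11O5⁺
  cores plus per-ring chain increments (ring distribution).
* Pathway: each ASAT activity is an occupancy-pattern → position rewrite
  with an allowed acyl-CoA donor set. Breadth-first closure from sucrose
  enumerates reachable products; terminal mono-/di-acyl intermediates
  are flagged as degraded dead ends. The F-pathway order (R4→R3→R3′) and
  the flipped P-pathway order (R4→R2→R3) both emerge from the same
  engine.
* Residues (Sl reference coordinates): ASAT2 F-activity ⇔ Q135∧Y136,
  P-activity ⇔ G304; ASAT3 P-activity ⇔ H161∧S162∧V289, F-activity ⇔
  L354∧H381∧P382 (the P-type allele carries V/S with a one-residue
  deletion). Per-plant profiles combine co-dominantly and feed the
  pathway engine for the chemotype call.

## Worked example

```r
library(acylsugars)

# exact mass of the triacylsucrose S3:22 as its formate adduct
s <- parse_annotation("S3:22 (5, 5, 12)")
adduct_mz(molecular_formula(s), "M+formate")
#> 737.3965

# annotate an observed precursor + carboxylate fragments (negative mode)
hits <- infer_composition(737.3952, c(101.0607, 199.1702))
format_annotation(hits[[1]]); attr(hits[[1]], "ppm")
#> "S3:22 (5, 5, 12)"   -1.78 ppm

# the flipped (P-type) pathway from its enzyme complement
simulate_pathway(c("ASAT1", "ASAT3-P", "ASAT2-P"), donors = c("iC5", "nC12"))
#> <acylsucrose pathway simulation>
#>   reachable states: 5; terminal: 2; dead ends: 0
#>   terminal products:
#>     S3:15 (iC5R2, iC5R3, iC5R4)-P  [P]
#>     S3:22 (iC5R2, nC12R3, iC5R4)-P  [P]
#>   phenotype call: {P}
```

The first number is the theoretical m/z of the [M+formate]⁻ ion at the
conventional 4-decimal precision; the annotation call recovers the
chain composition (two C5, one C12) from the observed ions at −1.78 ppm;
and the simulation shows that the P-type enzyme complement makes exactly
the two pyranose-only triacylsucroses, with the second chain added at R2
before R3 — the reversed reaction order.

Sequence-side, `predict_phenotype()` takes a FASTA of `plant|ASAT2|…` /
`plant|ASAT3|…` sequences and returns per-sequence activity calls plus
the per-plant chemotype; see the vignette in `vignettes/` for the full
methods account.

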