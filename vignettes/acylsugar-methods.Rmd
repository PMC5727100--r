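---
title: "Acylsucrose structures, mass spectra, pathway logic and residue rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acylsucrose structures, mass spectra, pathway logic and residue rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acylsugars)
```

## The system

Glandular trichomes of cultivated tomato (*Solanum lycopersicum*) and its
wild relatives secrete acylsucroses: sucrose esterified with short- and
medium-chain aliphatic acids. Four trichome-expressed BAHD
acyltransferases (ASAT1–ASAT4) build these metabolites stepwise from
sucrose and acyl-CoA donors. Two structural classes occur in the clade:
**F-type** acylsucroses carry one chain on the furanose (fructose) ring at
the R3′ position plus chains on the pyranose (glucose) ring, while
**P-type** acylsucroses are acylated exclusively on the pyranose ring. The
P-type class arises from variant ASAT2 and ASAT3 enzymes whose acceptor
preferences are swapped relative to the cultivated-tomato enzymes, so the
two enzymes act in the reverse order — a "flipped" pathway. A handful of
active-site residues decide which acceptor each enzyme uses, which makes
the plant's chemotype predictable from sequence.

This package implements the four computational layers of that story:

1. a structural model and `S n:m` nomenclature for acylsucroses,
2. exact-mass arithmetic and CID fragment logic for annotating LC-MS
   peak lists,
3. a rule-rewriting simulator of the biosynthetic network, and
4. a diagnostic-residue classifier chaining into chemotype prediction,

plus seeded synthetic-data generators that make all of it testable
offline.

## Structural model and nomenclature

An acylsucrose is a partial mapping from eight ring positions (`R2 R3 R4
R6` pyranose; `R1p R3p R4p R6p` furanose, `p` = prime) to acyl chains
(carbon count ≥ 2; branching `iso`, `anteiso`, `normal` or
`unspecified`). `S<k>:<m>` names a sucrose with `k` chains totalling `m`
acyl carbons; chain lengths, branching prefixes and position superscripts
are optional, e.g.

```{r}
s <- parse_annotation("S3:22 (iC5R2, nC12R3, iC5R4)")
s
classify_type(s)
```

Design choices worth noting:

* **`unspecified` branching is first-class** because LC-MS cannot
  distinguish iC5 from aiC5; only NMR resolves them.
  `enumerate_isomers()` expands the unresolved space (e.g. the eight
  co-eluting branching isomers of a P-type S3:15).
* The position vocabulary has eight symbols even though the modeled
  chemistry uses four (R2, R3, R4, R3′), so ASAT4-style acetylation and
  future chemistry are expressible. The structural cap of 8 chains is the
  model's hydroxyl count.
* Output is canonical (pyranose R2→R6 then furanose R1p→R6p;
  compositions ascending), so formatted strings double as state keys.
* The classification invariants: F-type ⇔ exactly one furanose chain, at
  R3′, with ≥ 1 pyranose chain; P-type ⇔ ≥ 1 chain, all pyranose. A lone
  R3′ chain is "other", and composition-only objects are
  "unclassifiable".

## Mass arithmetic and CID fragments

All mass computation runs on integer C/H/O element counts. Constants are
C = 12 exactly, H = 1.00782503, O = 15.99491462, electron = 0.00054858;
ion masses include the electron. A chain of *n* carbons adds
C*n*H(2*n*−2)O to sucrose's C12H22O11 (ester bond, water loss). The
formate adduct is implemented as +CHO2 with charge −1, which reproduces
the adduct formulas and the four printed high-resolution masses of the
NMR-characterized compounds:

```{r}
vapply(c("S2:10 (5, 5)", "S3:15 (5, 5, 5)", "S3:22 (5, 5, 12)"),
       function(a) round(adduct_mz(molecular_formula(parse_annotation(a)),
                                   "M+formate"), 4), numeric(1))
```

Negative-mode CID releases one carboxylate anion CnH(2n−1)O2⁻ per
distinct chain length — the number and lengths of chains.
`infer_composition()` inverts this: it enumerates chain multisets over a
bounded space (≤ 4 chains, lengths {2,4,5,10,12} by default, both
configurable), keeps those whose [M+formate]⁻ or [M−H]⁻ ion matches the
precursor within tolerance and whose chain-length set matches the
observed carboxylates in both directions, and ranks by |ppm| with
deterministic tie-breaks (fewer chains, then ascending composition). The
two-way carboxylate constraint is what disambiguates compositions that
are isobaric at the precursor (equal chain count and total carbons, e.g.
4×C4 vs C2+C4+2×C5).

Positive-mode CID cleaves the glycosidic bond, giving glucosyl and
fructosyl oxocarbenium cores (both C6H11O5⁺) plus the chain increments of
each ring — the ring distribution of the chains. The exact fragment
species in the original reports live in cited prior work, so this
fragment model is a decided, documented dialect kept behind
`predict_fragments()` for easy revision. Two numerical consequences are
handled explicitly in `infer_ring_distribution()`:

* the two cores are **isobaric**, so mirror-image splits cannot be
  distinguished by mass. The split space is therefore restricted to at
  most one furanose chain by default (`max_furanose`), matching the
  single-R3′ furanose acylation seen throughout the clade;
* a ring carrying no chains imposes no constraint: its bare core ion is
  routinely below the recorded range, so requiring it would reject
  correct splits.

With no fragments at all the result is `"ambiguous"` with every
admissible split listed. The default mass tolerance everywhere is 10 ppm
(the printed found-vs-calcd discrepancies are ≤ 4 ppm); retention time is
carried through I/O but never scored.

## The pathway engine

Each ASAT activity is an `enzyme_rule()`: occupancy pattern over ring
positions → donor chain added at a product position, with a qualitative
donor set (the study reports no kinetics, so there are no rates). The six
built-ins:

```{r}
for (r in builtin_rules()) print(r)
```

`simulate_pathway()` computes the breadth-first closure from sucrose,
records a provenance edge for every application, classifies terminal
states and flags terminal mono- and di-acylsucroses as degraded dead ends
(monoacyl S1:5 does not accumulate in planta, and stranded diacylsucroses
are hydrolysed). The phenotype call is the set of F/P classes among
non-dead-end terminals. Determinism comes from canonical state keys and
sorted state tables; termination from strict chain-count growth bounded
by free positions (`max_steps` default 6).

The central scientific property is **emergent order reversal**: with the
cultivated-tomato rules the R3 chain is added before R3′ (ASAT2 then
ASAT3); with the *S. pennellii* rules R2 precedes R3 (ASAT3 then ASAT2).
Nothing encodes order — only occupancy patterns — and the P-type diacyl
S2:10 (iC5R2, iC5R4) is inert under every cultivated-tomato rule, exactly
as observed in vitro:

```{r}
simulate_pathway(c("ASAT1", "ASAT3-P", "ASAT2-P"), donors = c("iC5", "nC12"))
```

Choices made where the in-vitro record is silent:

* **ASAT1 donors {iC5, aiC5}**: only iC5 was demonstrated; aiC5 is
  included because aiC5-containing products exist at R4. Configurable.
* **ASAT3-P donors {iC5, aiC5}**: mirrors the F-type enzyme's short-chain
  set minus nC12, because long chains are never reported at R2. An
  assumption, configurable per rule.
* **ASAT3-F acceptor = exactly the {R3, R4} diacyl.** A looser "R3+R4
  occupied" pattern would let ASAT3-F extend P-type triacylsucroses to
  furanose-acylated tetraacyls, collapsing mixed genotypes to pure F
  phenotype — contradicting the observed accumulation of both types in
  *S. habrochaites*. The characterized acceptor is the diacyl, so the
  rule says so.
* **Hybrid profiles contribute both rules.** `phenotype_from_profiles()`
  maps F capability to the F rule and P capability to the P rule, plus
  ASAT1; a hybrid ASAT2 with a P-only ASAT3 then yields {P} with the
  F-pathway diacyl stranded as a dead end — the northern *S. pennellii*
  situation.
* **ASAT4 is not included by default**: whether it acts in P-type
  backgrounds is an open question; it is exposed as a scenario switch
  (`include_asat4`).

## Diagnostic residues and chemotype prediction

All residue coordinates are 1-based positions in the Sl-type reference;
queries are projected onto them by global alignment
(Needleman–Wunsch-style, BLOSUM62, gap open 10 / extension 0.5 — fixed
for reproducibility and recorded in reports). This single coordinate
scheme absorbs the P-type ASAT3 allele's own shifted numbering (its
Val353/Ser380 are reference 354/381, with the adjacent deletion mapping
reference 382 to a gap).

The rules, as pure functions of the mapped residues:

* **ASAT2**: F-activity ⇔ Q135 ∧ Y136; P-activity ⇔ G304. Observed
  alphabets are {Q,H,P} at 135, {Y,C} at 136, {C,G} at 304; anything else
  sets an exception flag rather than silently defaulting.
* **ASAT3**: P-activity ⇔ H161 ∧ S162 ∧ V289 (one or two matches are
  reported as weak evidence but never set the flag, because single-site
  natural and engineered variants show only partial activity); F-activity
  ⇔ L354 ∧ H381 ∧ P382. A user-extensible exception list exists for the
  known nonconforming P-type alleles; it ships empty because those
  sequences are not enumerated in the primary record.

Per plant, allele profiles are combined by union (the contributing loci
are co-dominant: heterozygotes make both product classes), and the
chemotype follows by running the pathway engine on the implied enzyme
complement — so the genotype→chemotype table is derived end to end, not
looked up.

```{r}
fx <- make_reference_fixtures()
pred <- predict_phenotype(c(
  "plant|ASAT2|1" = apply_mutations(as.character(fx[["Sl-ASAT2-like"]]),
                                    "C304G"),
  "plant|ASAT3|1" = as.character(fx[["Sp-ASAT3-like"]])))
pred$plants
```

## What the synthetic data emulate — and what they do not

The sequence generator plants diagnostic letters into deterministic
460-residue BAHD-length stand-ins and adds seeded background
substitutions (default 2–5% per site, capped at 20%) that never hit
diagnostic sites; the P-type ASAT3 indel is realised as a deletion of
reference position 382. The Sl/Sp fixture pairs carry ~18 background
differences so that within-family identity sits near 95% — comfortably
above the 92% reported for the real ortholog pairs and far above the 40%
homolog floor. The peak-list generator perturbs theoretical m/z values
with Gaussian **ppm** noise (ToF mass error scales with m/z, hence ppm
rather than Da; default σ = 2 ppm) and adds uniform decoy peaks over the
observed range.

These fixtures validate the logic, not the biology: real BAHD sequences
share conserved motifs and non-uniform residue composition, real spectra
contain isotopologues, in-source fragments and chimeric peaks, and real
chromatography separates isomers the m/z domain cannot. Passing the
recovery tests therefore demonstrates correctness of the mapping,
classification and annotation machinery under the stated noise model —
not performance on raw instrument data. Plant-level metabolite profiles
(total-ion chromatograms) are deliberately out of scope.

The optional `fetch_genbank_proteins()` helper can pull the real
accessions for the identity check when a network is available; nothing
else depends on it.

## Problem sizes and numerical conventions

The test suite runs the simulator on complements of up to six rules and
three donors (state spaces of a few dozen), recovery experiments over 200
seeded sequence variants and composition inference over the full bounded
candidate space (125 multisets), which keeps the whole suite under a
minute on a laptop while still exercising every rule path. Tolerances:
masses are asserted at the printed 4-decimal precision, formula/mass
additivity at 1e-9 Da, annotation at the stated ppm tolerances. All
generators require an explicit seed and restore the caller's RNG state.

## Known limitations

* No kinetics, donor competition or abundance prediction — the donor
  model is set membership.
* The positive-mode fragment model is a documented dialect (protonated
  oxocarbenium cores; no ketene losses, no sodiated fragments).
* No isotope-pattern fitting, RT modeling or quantification.
* Residue rules cover the residue alphabets observed in nature; novel
  letters are flagged, not classified.
* Stereochemistry and 3-D conformation are outside the structural model.
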