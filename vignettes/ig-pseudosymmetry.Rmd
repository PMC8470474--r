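---
title: "Methods: detecting and quantifying Ig-fold pseudosymmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and quantifying Ig-fold pseudosymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igproto)
```

## The model

`igproto` treats an immunoglobulin (Ig) domain as a covalently linked dimer
of two *protodomains*: the N-terminal AB-CC′ unit and the C-terminal DE-FG
unit, each a pair of β-hairpins, related by an internal rotation close to
180° (a pseudo-C2). Everything else the package computes derives from that
decomposition:

* the **tertiary axis** is the fixed axis of the rigid transform that best
  superposes protodomain 1 onto protodomain 2 under the symmetry
  correspondence of strands (A↔D, B↔E, C↔F, C′↔G);
* the **topology classes** (V-set, C1-set, C2-set, I-set, FN3, cadherin) are
  the ways evolution breaks that symmetry at the edges of the sandwich —
  which lateral strands exist and on which sheet the N-terminal strand lies;
* the **double Ig fold** (CD19-like) is the same grammar one level up: two
  parallel-linked protodomain pairs, joined by a long inverter segment,
  interdigitating into two composite Ig domains — one regular, one *inverse*
  (its DE-FG unit precedes its AB-CC′ unit in sequence);
* **quaternary pseudosymmetry** applies the identical machinery across two
  domains: a label-matched superposition gives the quaternary C2 axis, and in
  idealized homodimers the two tertiary axes and the quaternary axis combine
  into a quasi-D2 arrangement.

The assumptions are deliberately minimal: coordinates of one crystal/EM model
(first NMR model if several), no hydrogens, no sequence profiles. Sequence
enters in exactly one place — the CCW(L) signature used to separate the
C2-set from FN3, whose strand tables are identical.

## Strand detection and Ig labelling

A residue joins a β-ladder *rung* when (mode `ca_only`) its Cα lies within
`ca_ladder_dist` (5.5 Å) of a partner at sequence separation ≥ `min_seq_sep`
(4), or (mode `backbone`) when a geometric N···O hydrogen bond exists
(≤ 3.5 Å, donor angle ≥ 120°). Three geometric gates make this usable without
a full secondary-structure program:

* **extended conformation** — a residue may only join a ladder when the chain
  is locally straight at or next to it (Cα virtual-bond turn angle ≤
  `extended_turn_max`, 40°); this is what keeps turns and loops out of
  strands;
* **lateral geometry** — the two residues' local chain directions must be
  (anti)parallel (|cos| > 0.7) and the connecting vector lateral, not
  along-chain; strand ends qualify through their inward step;
* **ladders** — at least `min_ladder_rungs` (2) consecutive rungs, with a
  one-rung interruption tolerated (`bulge_tolerance`), define a ladder;
  strands are maximal runs of ladder residues, sheets are connected
  components of strand adjacency.

A strand whose residues ladder to two different sheets is split at a hinge —
the first proline, else the midpoint of the longest glycine run, else the
geometric crossover — which realizes the A/A′ split of variable-type domains.
Because the split strand may itself be the only bridge between the two
sheets, the split test groups its partners by the connected components of the
adjacency graph *with the candidate removed*.

Labelling anchors the invariant core first: B, C, E, F are the longest
strand quadruple (N→C order) with B|E laddered in one sheet and C|F in the
other — the intertwined BC/EF straddle shared by all Ig and Ig-like domains.
Remaining labels follow from sequence position and sheet membership.
Two deliberately pragmatic refinements:

* **short-strand rescue** — the I-set's C′ is only 2–3 residues and sits on
  one 2–3-rung ladder; thermal-scale coordinate noise can push it below the
  strict criteria. When the surrounding labels imply such a strand (a split
  A/A′ context with C and D labelled but no C′; or a split context missing
  one of A/A′), the unassigned residues between the flanking strands are
  re-scanned for a plain lateral ladder to the anchor strand with 0.5 Å of
  extra slack and the usual bulge tolerance. The rescue never invents
  evidence — it only relaxes the extended-conformation gate where the label
  grammar already requires a strand — and it cannot fire on C1-set or
  cadherin domains (no split).
* **manual override** — a label → residue-interval map replaces detection
  entirely after validation, for cases where the user knows the register.

## Superposition and axis extraction

The residue correspondence is register-free: each mapped strand pair is
trimmed symmetrically around its center to the shorter strand's length (ties
resolved toward the N side) and paired index-by-index, both strands read
N→C — the C2 acts on the protodomain as a whole, so no antiparallel reversal
is applied. A↔D is mapped only when a strand literally labelled A exists: an
A′ lying alone on the G-side sheet is a symmetry-breaking remnant (CD4-like
V domains, cadherins, CD19) and stays unmatched, which reproduces the
three-strand (B↔E, C↔F, C′↔G) matches seen in those topologies.

The optimal rotation is the closed-form orthogonal-Procrustes solution (SVD
of the covariance matrix, reflection excluded by sign-correcting the smallest
singular direction). The test suite and the acceptance script verify it
against an independent numeric minimizer over unit-quaternion rotations. From
the fitted transform, the rotation angle comes from the trace, the axis from
the antisymmetric part (or, at 180°, from `R + I`), the screw component as
the translation along the axis, and the axis point by solving the singular
point equation restricted to the plane normal to the axis, then sliding to
the point nearest the centroid midpoint. Rotations within `c2_angle_tol`
(30°) of 180° are labelled C2 — generous on purpose, because tilted
pseudosymmetric arrangements are still C2-related in kind; near-identity
transforms (< 1°) give a typed no-axis result.

An optional refinement pass (`refine = TRUE`: drop pairs fitting worse than
3.5 Å, re-fit, at most 3 rounds) emulates trimmed tool-style alignments; it
is off by default so that reported RMSDs are plain all-pair values.

## Classification rules

The decision list is total and ordered; every test is recorded in the rule
trace:

1. C″ present → **V-set** (the only class with a C″ strand).
2. no C″, C′ at most `short_cprime_max` (3) residues, split A/A′ → **I-set**.
3. no C′, A on the ABED sheet → **C1-set**.
4. no C′, the N-terminal strand only on the GFC sheet → **cadherin**.
5. no D → **C2-set** when the CCW(L) signature has ≥ 3 of 4 strict hits, else
   **FN3** (identical strand tables otherwise).
6. otherwise → **not_Ig** (including AB-swapped architectures, which are
   reported with a diagnostic rather than modelled).

Rule order resolves overlaps: a domain with both C″ and a short C′ is V-set
because C″ is the V-set's unique marker. The signature is a *sequence*
pattern (Cys on B, Trp on C, Leu on E with Ile/Val/Met accepted as a flagged
fallback, Cys on F, each strand widened by one flanking residue); an
incomplete signature never reclassifies a domain that already matched a
structural rule — some genuine V domains (CD2-like) miss it.

Double-Ig detection requires all three evidence items: (a) two
protodomain-like pairs each joined by a short linker (≤ `short_linker_max`,
5 residues) leaving their B and E strands parallel (< 90°); (b) an inverter
segment longer than `inverter_min` (10 residues) between the halves; (c)
lateral fusion ladders C′|C′ and D|D with ≥ 2 rungs each. Partial evidence
returns a typed negative with the list of failed items. The thresholds encode
"very short" vs "long" linkers and are configurable. The composite domains
follow the sequential definition: (p1,p4) regular and (p2,p3) inverse, the
latter because its DE-FG member precedes its AB-CC′ member — equivalent to a
circular permutation. Both composite C2 axes and the central axis are
computed with the ordinary protodomain machinery; arbitrary groupings (e.g.
p1+p3 vs p2+p4) remain available through `build_correspondence`'s `pair_map`.

Protodomain-swap detection is label-agnostic by design: domain closure
between an AB-CC′ unit and a DE-FG unit is the total number of cross-ladder
rungs between any strands of the two units (a closed core interleaves them
through B|E and C|F), and a dimer is *swapped* when the cross pairings close
while the sequential pairings fail. Swapped chains cannot be annotated alone
— the core straddle spans both chains — so when single-chain annotation
fails, strands are re-detected on a merged two-chain view where the
cross-chain ladders complete them, and each chain is cut into its two units
at the longest linker.

## Interaction typing

All criteria are geometric, hydrogen-free, and symmetric in the residue pair;
a pair may carry several types at once: van der Waals (any heavy-atom pair
≤ 4.0 Å), hydrogen bond (donor-heavy to acceptor-heavy ≤ 3.8 Å, angle at the
donor ≥ 90° using the donor's nearest intra-residue heavy atom as
antecedent), ionic (Asp/Glu carboxylate oxygens to Lys/Arg/His nitrogens
≤ 6.0 Å), π-stacking (ring centroids ≤ 5.5 Å), π-cation (centroid to cationic
nitrogen ≤ 6.0 Å), disulfide (Sγ-Sγ ≤ 2.5 Å). The thresholds follow common
interactive-viewer defaults and are all configuration keys. Network
comparison is structural-position-based: an edge is conserved iff both mapped
endpoints exist in the other network and share at least one type; nodes are
conserved iff the mapped residue has the same identity.

## The synthetic generator: what it emulates, and what it does not

The generator builds flat two-sheet sandwiches on a grid: strands along x
with `rise` 3.4 Å per residue, lateral spacing 4.8 Å, sheet separation 10 Å,
full strands of 6 residues — textbook β-sheet values, stated here as the
package's chosen study conditions. Strand tables per preset follow the class
definitions exactly (split A/A′ and C″ for the V-set; a 3-residue C′ for the
I-set; no C′ for C1/cadherin; no D for C2/FN3; A′-only N-termini and the
fused (BED)1(DEB)2 / (A′GFCC′)1(C′CFG A′)2 sheets for the double Ig).
Protodomain 2 — and, for dimers, the whole second domain — is generated as
the *exact image* of its partner under a 180° rotation, so noise-free outputs
satisfy every exactness property by construction (RMSD 0, angles exactly
180°, exactly symmetric interface networks). Noise is isotropic Gaussian
displacement of every atom with a stated seed; 0.3 Å is used as the standard
perturbed condition in tests, roughly crystallographic coordinate precision.

Design choices a user should know about:

* **A and A′ are 4 residues** (the I-set C′ stays at 3, its defining
  feature). Two-residue-wide edge strands carry a single interior turn angle,
  which makes them statistically fragile under noise out of proportion to
  anything in real structures, where backbone hydrogen bonds would hold the
  assignment.
* **Loops are deliberately non-extended**: interpolated arcs routed outside
  the sandwich in alternating lateral lanes, with a golden-angle wiggle and
  perpendicular kicks at their first and last residues. Real loops are
  compact for chemical reasons; the generator enforces the same property
  geometrically so that the extended-conformation gate separates strands from
  loops the way it does in real chains. Bond-length and Ramachandran realism
  are *not* modelled — detection operates on distances and local directions,
  not dihedrals.
* **Dimer interfaces**: in `full` atom mode each residue gets idealized N and
  O sites (for backbone-mode detection) and an outward-pointing Cβ; dimer
  presets place the facing GFCC′ sheet planes `interface_gap` = 5.8 Å apart,
  which puts the facing Cβ atoms in van der Waals range while keeping all
  Cα-Cα distances above the ladder cutoff. This is an idealization chosen so
  interface contacts exist at standard cutoffs without side-chain packing.
* **Double-Ig composite symmetry**: the flat idealization cannot make the
  local (p1,p4)/(p2,p3) pseudosymmetry exact at the same time as the fused
  sheet order — the composite superpositions give a clean 180° angle but a
  nonzero RMSD. The *central* C2 relating the two halves is exact. Real
  double Ig domains are not flat, so this is a limitation of the fixture, not
  of the detector.
* The orientation thresholds for dimers (parallel < 60°, inverted > 120°,
  tilted between) leave an explicit intermediate band because real Ig-Ig
  interfaces populate it.

Consequently, passing tests on synthetic fixtures demonstrate that the
algorithms recover designed topology, symmetry, and networks under
thermal-scale coordinate noise; they do not demonstrate robustness to the
full heterogeneity of experimental structures (register shifts, β-bulges
beyond one residue, long insertions, alternate conformations beyond the
highest-occupancy rule, domain flexibility).

## Numerical choices and degenerate inputs

Collinear or < 3-point sets are rejected before the SVD; ties in the
occupancy-based altloc rule go to the first-listed conformer; multi-model
files use model 1; non-standard residues with a Cα (MSE and relatives) are
retained and mapped to their parent amino acid; residues without a Cα are
excluded from traces and never interpolated. Residue intervals are closed
and inclusive in source numbering. The topology map falls back to sequential
packing (flagged) when a strand has no register with a placed neighbor.
Classification is a total function: every annotation, including typed
not-Ig verdicts, yields exactly one label with a non-empty rule trace.

## Problem sizes used by the test suite

Unit and property tests run on single domains of ~60–90 residues and dimers
of ~150 residues; the recovery and axis properties use 20 noise replicates
per preset at σ = 0.3 Å (ten presets), and the superposition oracle check
uses 100 random 20-point sets. These sizes make the whole suite and the
acceptance script each run in about a minute on one core while keeping the
binomial recovery statistics meaningful.
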