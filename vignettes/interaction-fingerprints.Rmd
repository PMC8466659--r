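---
title: "Interaction fingerprints: model, criteria and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction fingerprints: model, criteria and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resifp)
```

## The model

An interaction fingerprint (IFP) encodes, for one frame or pose of a
molecular complex, which predefined noncovalent interactions occur between
a "ligand" side and each residue of a "protein" side (the labels are
conventional: any combination of small molecule, protein, DNA or RNA works,
and passing the same structure on both sides analyses intramolecular
interactions, skipping residue self-pairs).

Each interaction is defined by two **moiety patterns** — substructure
queries over elements, formal charges, aromatic flags and bonds — plus
**geometric constraints** on distances and angles between the matched
atoms. A detector takes two residue fragments and returns a Boolean plus
the parent atom indices responsible, which is what makes per-atom
post-processing (network diagrams, 2D/3D annotation) possible downstream.

Per frame, the presence values over (ligand residue × protein residue ×
interaction) form a bitvector with a fixed, deterministic layout, so
vectors are comparable across frames and runs. Tanimoto similarity between
frame bitvectors (|AND| / |OR|) then quantifies binding-mode drift along a
trajectory; presence fractions across frames give per-interaction and
per-residue contact frequencies.

## Moiety patterns

The built-in registry expresses the standard SMARTS queries as graph
predicates (R has no SMARTS engine; the queries involved are simple enough
that a predicate over the atom table plus bond list is an exact
equivalent, and each predicate is cross-checked in the tests against
hand-derived truth tables and a brute-force enumerator):

* **Anion / Cation** — formal charge ≤ −1 / ≥ +1. The printed charge
  tokens in the reference tables are typographically mangled; the
  documented SMARTS charge-extension semantics (any magnitude of the given
  sign) are implemented, which is unambiguous and testable.
* **Aromatic** — rings of size 6 or 5 among atoms flagged aromatic,
  found by cycle enumeration and deduplicated *as atom sets*, so a ring
  matched by both ring sizes counts once. Fused systems (indole) report
  each constituent ring; a cation or second ring may then satisfy the
  geometry against either ring ("any ring" semantics).
* **HBAcceptor** — N, O, F or any anion, excluding cations. The printed
  pattern mixes element and charge tokens ambiguously; it is read as
  (element ∈ {N,O,F} OR charge ≤ −1) AND NOT cation.
* **HBDonor** — N/O/S heavy atom with an explicit bonded H (arity 2).
* **XBDonor / XBAcceptor** — C/N/Si/F/Cl/Br/I bonded to Cl/Br/I/At;
  N/O/P/S/Se/Te or aromatic atom (not cationic) with its substituent R.
* **Metal / MetalLigand** — the nine common biological metals; O/N or
  anions as coordinating partners.
* **Hydrophobic** — uncharged C, S or halogen.

Custom patterns and custom detectors register under a name and then behave
exactly like built-ins, including appearing as fingerprint columns.

## Geometric conventions that matter

* **All thresholds are inclusive** (≤, closed angle windows). A numerical
  slack of 1e−9 is added to every comparison so that a geometry
  constructed *exactly at* a printed cutoff (D–A = 3.50 Å) is never
  rejected due to floating-point round-trip noise. The slack is ~7 orders
  of magnitude below the scan resolution used anywhere, so it cannot move
  a boundary.
* **The H-bond angle is measured at the hydrogen**, between the H→D and
  H→A vectors: a linear D–H⋯A arrangement scores ≈ 180°. Conventions
  differ between packages; this one is stated prominently because a
  [130, 180] window at H is a [0, 50] window at the donor.
* **Ring normals are least-squares normals** (SVD of centred ring
  coordinates, smallest singular vector; degenerate if the second singular
  value vanishes). Their sign is arbitrary, so every normal-vs-normal and
  normal-vs-direction angle is folded into [0, 90] before window tests.
  Angle windows with upper bounds ≤ 90 are then applied directly.
* **Both halogen-bond angle windows apply together** ([130, 180] at X,
  [80, 140] at A) — they constrain one geometry even though reference
  tables typeset them on separate rows.
* **Tie-breaking**: detectors report the first match pair satisfying all
  constraints under the deterministic moiety match order (ascending atom
  index). An exhaustive `all_pairs` mode records every satisfying pair;
  the ligand-network aggregation uses it for atom frequencies.
* A fragment with no match for a required moiety yields `present = FALSE`,
  never an error.

## Tunable parameters

Every cutoff is an empirical convention, not a law; published H-bond
criteria alone range from H⋯A ≤ 3.0 Å to D–A ≤ 4.1 Å. `configure()`
returns a modified copy of a definition (distance, angle windows, moiety
roles), and a JSON config file applies the same overrides reproducibly
from the CLI. The van der Waals radius set (bundled: Bondi 1964 plus
published supplements for metals) materially affects the VdWContact
criterion and is therefore loadable from a plain two-column file.

Default engine set: Hydrophobic, PiStacking, PiCation, CationPi, Anionic,
Cationic, HBDonor, HBAcceptor. EdgeToFace, FaceToFace, the halogen-bond
and metal pairs, and VdWContact are available but off by default — the
general PiStacking window [0, 90] at ctd ≤ 6.0 already subsumes both
specialised angle windows (though not the tighter FaceToFace distance),
and the specialised variants are mainly useful when the distinction itself
is the question. The three stacking variants are implemented with
independent thresholds rather than as a union, because their printed
cutoffs differ.

## The synthetic-fixture generator

All tests run without external data. The `make_*()` builders emit small
two-residue complexes whose governing geometric parameter is exact by
construction: the H-bond pair solves the D/H/A triangle in closed form so
the requested D–A distance and D–H⋯A angle are reproduced to < 1e−6;
the ring dimer controls plane gap, lateral centroid offset and
inter-plane tilt independently; the ion pair, metal site, halogen pair
and methane pair place their matched atoms at the exact requested
separation. That exactness is what turns threshold scans into *exact*
boundary locations instead of approximate ones.

What the fixtures deliberately are **not**: physically relaxed
conformers. Bond lengths are idealised, hydrogens are placed only where a
criterion needs them, and the "protein" side is a minimal carbonyl or
ammonium probe. A green fixture battery therefore establishes that the
geometric rules are implemented correctly and symmetrically — it says
nothing about force-field realism, protonation assignment or conformational
sampling, which are upstream of this package by design (inputs must arrive
with explicit hydrogens, formal charges and aromaticity).

Seeded Gaussian jitter (`jitter_structure()`) turns the exact probes into
randomized batteries for the property suites (role-swap symmetry,
brute-force oracle equivalence on 200+ cases).

## Input contract and readers

Structures must carry explicit hydrogens, formal charges and aromatic
flags before detection. The readers do what each format allows:

* **PDB** — coordinates, residue metadata, formal charges (columns 79–80)
  and CONECT bonds round-trip through the bundled writer. PDB cannot
  encode aromaticity, so the reader flags planar (≤ 0.1 Å deviation)
  5/6-rings of C/N/O/S atoms as aromatic; this is a reader-layer service
  over *explicit bonds*, not bond perception from distance geometry, which
  remains out of scope.
* **SDF (V2000)** — formal charges from `M  CHG`, aromaticity from bond
  type 4; multi-record files become frame lists, as do multi-MODEL PDBs.
* **MOL2** — elements and aromaticity from SYBYL atom/bond types; the
  partial charges MOL2 carries are ignored, since only formal charges
  drive moiety matching.

The CLI refuses hydrogen/halogen-bond detection when the inputs contain no
explicit hydrogens at all, with a diagnostic naming the cure.

## Numerical and design choices in the analyses

* **Bit space** is the full Cartesian product (residues × interactions),
  not just ever-observed pairs, so bitvectors are comparable across runs;
  tables use observed-only columns for readability, and the two views are
  proven consistent in the tests.
* **Tanimoto of two all-false frames is 1.0** by default (identical
  absence of interactions is similarity, not dissimilarity); configurable
  to 0 for users who prefer the strict set-theoretic convention.
* **The residue-pair distance prefilter** (minimum any-atom distance
  above 6 Å + the largest active cutoff ⇒ skip) is a pure optimisation; a
  property test shows identical results with it disabled.
* **Ligand-network endpoints**: per (residue, interaction) group the most
  frequent ligand atom across frames is shown, ties broken by lowest atom
  index — a deterministic, documented rule.
* **Covalent-neighbour filtering** in residue networks defaults to
  sequence-adjacent residues (|Δnumber| ≤ 1, same chain). Disulfide-style
  covalent links are not recoverable from a fingerprint store, so a
  bond-based variant beyond chain adjacency is not offered; segment-label
  filters cover those cases in practice.
* Graphs are exported as data (GraphML, JSON node-link); interactive
  rendering is intentionally out of scope.

## Known limitations

* Moiety matching is predicate-based over prepared structures; arbitrary
  user SMARTS strings are not parsed — custom patterns are supplied as R
  predicate functions instead.
* No protonation/tautomer assignment, no bond-order inference, no
  periodic-boundary imaging: inputs are assumed prepared and whole.
* Interaction presence is purely geometric; no energies or strengths.
* Trajectory formats beyond multi-model PDB (DCD/XTC) require an external
  conversion step producing per-frame structures.

## What the tests establish

The non-acceptance suite covers each module's contract (fragmentation
conservation, match determinism and permutation invariance, detector
examples and twins, store/table/bitvector consistency, network filters,
reader round-trips, CLI exit behaviour). The acceptance suite then locks
the headline guarantees: threshold scans in 0.01 Å / 0.1° steps flip
exactly at the documented cutoffs; every detector agrees with an
independent brute-force oracle on 200+ randomized jittered fixtures;
role-swapped twins agree under argument exchange; Tanimoto algebra matches
set arithmetic on random bitvectors; network contracts (threshold
monotonicity, filter semantics, state-comparison conservation) hold; and
10-frame frequency counts reproduce hand counts exactly. No empirical
claim beyond what those computations themselves establish is made here.
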