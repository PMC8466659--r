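# resifp

Residue-level interaction fingerprints for molecular complexes, in R.

## What problem this solves

Given 3D structures of a molecular complex — a docked ligand in a binding
site, frames of an MD trajectory, a protein–protein interface — structural
biologists and medicinal chemists routinely ask *which residues interact
with what, through which kind of interaction, and how often*. `resifp`
answers this by:

1. fragmenting each structure into residues (keyed on name, number, chain);
2. matching chemical moieties (anions, cations, aromatic rings, H-bond
   donor–H pairs, halogen-bond donors, metals, hydrophobic atoms) inside
   each residue;
3. testing geometric interaction criteria between moiety pairs — every
   detector returns a Boolean **and the atom indices responsible**;
4. encoding the result per frame as a bitvector over
   (residue × interaction), the classical *interaction fingerprint* (IFP).

On top of the fingerprint it computes interaction **frequencies** across
frames, **Tanimoto similarity** matrices between frames (binding-mode
clustering), and **interaction networks** (ligand–residue diagrams,
residue–residue graphs with state comparison, GraphML/JSON export).

## The geometric criteria

Default thresholds (all distances in Å, angles in degrees, all bounds
inclusive; every value is user-configurable because empirical consensus is
weak):

| Interaction | Criterion |
|---|---|
| Anionic / Cationic | anion⋯cation ≤ 4.5 |
| Hydrophobic | C/S/halogen ⋯ C/S/halogen ≤ 4.5 |
| HBDonor / HBAcceptor | D⋯A ≤ 3.5 and ⟨HD, HA⟩ ∈ [130, 180] (angle at H) |
| XBDonor / XBAcceptor | X⋯A ≤ 3.5, ⟨XD, XA⟩ ∈ [130, 180], ⟨AX, AR⟩ ∈ [80, 140] |
| PiStacking | ctd–ctd ≤ 6.0, ⟨n, n⟩ ∈ [0, 90], min ring distance ≤ 3.8 |
| EdgeToFace | ctd–ctd ≤ 6.0, ⟨n, n⟩ ∈ [50, 90], min ≤ 3.8 |
| FaceToFace | ctd–ctd ≤ 4.5, ⟨n, n⟩ ∈ [0, 40], min ≤ 3.8 |
| CationPi / PiCation | (+)⋯ctd ≤ 4.5 and ⟨n, ctd→(+)⟩ ∈ [0, 30] |
| MetalDonor / MetalAcceptor | metal⋯O/N/anion ≤ 2.8 |
| VdWContact | any pair ≤ r₁ + r₂ + 0.6 (Bondi radii, overridable) |

`ctd` is a ring centroid, `n` a least-squares ring normal (sign-ambiguous,
so normal angles are folded into [0, 90]).

## Worked example

```r
library(resifp)

# two frames of a donor/acceptor pair: one H-bonded, one too far
near <- subset_structure(make_hbond_pair(2.9, 180), chains = "A")
prot <- subset_structure(make_hbond_pair(2.9, 180), chains = "B")
far  <- subset_structure(make_hbond_pair(4.9, 180), chains = "A")
prot2 <- subset_structure(make_hbond_pair(4.9, 180), chains = "B")

res <- fp_run(list(near, far), list(prot, prot2))
to_table(res)
#>   frame HOH1.A|ACE2.B|HBDonor
#> 1     0                  TRUE
#> 2     1                 FALSE

frequencies(res)
#>   lig_res prot_res interaction freq
#> 1  HOH1.A   ACE2.B     HBDonor  0.5

tanimoto_matrix(res)
#>   0 1
#> 0 1 0
#> 1 0 1
```

Frame 0 carries the H-bond bit (D–A = 2.9 ≤ 3.5 Å, angle 180°), frame 1
does not (4.9 Å), so the two frames share no set bit and their Tanimoto
similarity is 0. The frequency table says the H-bond is present in 50% of
frames.

The same pipeline runs from the shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/resifp.R", package="resifp"))') \
  --ligand lig.pdb --protein prot.pdb \
  --out-table ifp.csv --out-similarity sim.csv --out-network net.json
```

## Package layout

- `R/chem-model.R` — structures, residue fragmentation, moiety patterns
- `R/geometry.R` — centroids, ring normals, folded angles, vdW radii
- `R/interactions.R` — the detectors and the interaction registry
- `R/fingerprint.R` — the engine: bitvectors, tables, frequencies, Tanimoto
- `R/network.R` — ligand/residue networks, state comparison, graph export
- `R/fixtures.R` — parametric toy complexes at exact geometries
- `R/io.R`, `R/cli.R` — PDB/SDF/MOL2 readers, PDB writer, config, CLI
- `vignettes/interaction-fingerprints.Rmd` — methods and design notes
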