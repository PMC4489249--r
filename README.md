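# ligprof

Rule-based profiling of non-covalent protein–ligand interactions from 3D
structures in PDB format.

Most of the structures in the Protein Data Bank contain a small-molecule
ligand, and understanding *how* that ligand is held — which hydrogen bonds,
salt bridges, stacking and hydrophobic contacts anchor it — is central to
structural bioinformatics, docking post-processing and inhibitor design.
`ligprof` detects these contacts automatically, at single-atom detail,
without manual structure preparation, and reports seven interaction types:

| type | rule (defaults, configurable) |
|---|---|
| hydrophobic contact | apolar C···C (all heavy neighbors carbon), d ≤ 4.0 Å |
| hydrogen bond | D···A ≤ 4.1 Å and ∠(D–H···A) ≥ 100° |
| water bridge | both water legs 2.5–4.1 Å, water angle ω ∈ [75°, 140°], donor legs θ ≥ 100° |
| salt bridge | opposite formal-charge centroids ≤ 5.5 Å |
| π-stacking | ring centroids ≤ 5.5 Å, plane angle ≤ 30° (P) or 90°±30° (T), offset ≤ 2.0 Å |
| π-cation | cation ≤ 6.0 Å from ring centroid, lateral offset ≤ 2.0 Å |
| halogen bond | C–X···A with X···A ≤ 4.0 Å, ∠(C–X···A) = 165°±30°, ∠(Y–A···X) = 120°±30° |

The pipeline has four stages:

1. **Structure preparation** — fixed-column PDB parsing (altloc resolution by
   occupancy, CONECT + covalent-radius bond perception), rule-based polar
   hydrogen placement at pH 7, blacklist-driven ligand selection, and
   binding-site extraction (7.5 Å envelope).
2. **Functional characterization** — hydrophobic atoms, hydrogen/halogen-bond
   donors and acceptors, aromatic rings (residue templates + planarity-checked
   ligand cycles), formal charge centers.
3. **Rule-based matching** — one geometric detector per interaction type,
   protein side against ligand side only, thresholds from a key–value config.
4. **Refinement** — hydrophobic contacts reduced to nearest-neighbor pairs,
   hydrogen bonds subsumed by salt bridges removed, water bridges duplicating
   direct hydrogen bonds pruned.

Results are written as parsable XML, flat text and a plain-text
molecular-viewer command script. A synthetic-complex generator
(`build_fixture()`, `build_gallery()`) produces minimal PDB files with exact
interaction geometry, so the whole detector stack is testable offline.

## Worked example

```r
library(ligprof)

# an idealized Arg/carboxylate complex, guanidinium-carboxylate centroids 4.0 A apart
pdb <- build_fixture(fixture_spec("saltbridge"))
prof <- profile_complex(paste(pdb, collapse = "\n"))
prof
#> <ligprof_profile> structure | 1 binding site(s)
#>   LG1:L:1 : saltbridge=1

rep <- report_from_profile(prof, created = "2026-01-01T00:00:00")
cat(write_report_text(rep), sep = "\n")
#> # interaction report for structure
#> # created 2026-01-01T00:00:00
#>
#> === Binding site LG1:L:1 ===
#> ** saltbridge (1) **
#> RESIDUE | PROT_ATOMS | LIG_ATOMS | DIST
#> ARG-A-1 | 9,10,11    | 14,15     | 4.00
```

The raw detectors also see the two guanidinium N–H···O⁻ hydrogen bonds inside
this contact; refinement reports only the salt bridge, because both heavy
atoms of each hydrogen bond belong to the salt-bridge atom sets — the
electrostatic contact is the more complete description of the same pairing.
`PROT_ATOMS` / `LIG_ATOMS` are atom serials (here CZ/NH1/NH2 vs. the two
carboxylate oxygens) and `DIST` is the centroid–centroid distance in Å.

Batch use from a shell:

```sh
inst/exec/ligprof -i structures/ -o results/ --threshold hbond_dist_max=3.5 -v
```

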