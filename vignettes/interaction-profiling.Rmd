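---
title: "Geometric rules for non-covalent protein-ligand interaction profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric rules for non-covalent protein-ligand interaction profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligprof)
```

## The model

`ligprof` treats interaction detection as a pure geometry problem on an
annotated molecular graph. A protein–ligand complex is reduced to typed
point sets — apolar carbons, hydrogen-bond donors with explicit hydrogens,
acceptors, carbon-bound halogens, aromatic ring planes, formal charge
centroids, water oxygens — and every interaction type is defined by a small
set of distance and angle inequalities between features on opposite sides
of the interface. This rule-based view has two properties worth making
explicit:

* it is *deterministic and auditable*: every reported record carries the
  measured geometry, and re-checking those measurements against the
  configuration must always succeed (the test suite does exactly that);
* it is *permissive by design*: thresholds are set generously so that
  slightly distorted geometry in lower-resolution structures is still
  matched, and redundancy is handled afterwards by explicit filtering
  rather than by tightening cutoffs.

The pipeline runs in four stages — preparation, characterization, matching,
refinement — and each stage is exposed as ordinary functions so any step
can be inspected or replaced.

## Structure preparation

**Parsing.** Fixed-column PDB records are read via `bio3d`; MODEL blocks
and CONECT records are handled by the package. Alternate locations keep the
highest-occupancy conformer (ties by altloc letter), because a
single-conformer analysis must be deterministic. Only one model of a
multi-model file is analyzed at a time. Covalent bonds come from CONECT
records plus a covalent-radius rule (bonded if $d \le r_1 + r_2 + 0.45$ Å,
capped at 3.4 Å, never H–H): the rule's 0.45 Å slack sits comfortably
between real bond stretch and the shortest non-bonded contacts
(hydrogen-bond heavy-atom pairs start around 2.4 Å).

**Hydrogen placement.** Crystal structures usually lack hydrogens, but the
hydrogen-bond donor angle needs them. The package places *polar* hydrogens
only, by rule, at the pH-7 protonation state: Arg and Lys protonated,
Asp/Glu (and ligand carboxylates, phosphates, sulfonates) deprotonated,
His neutral in the tau tautomer (H on NE2, ND1 an acceptor), backbone N–H
except proline. Ligand chemistry is perceived from connectivity and bond
lengths: a terminal O at < 1.32 Å from its carbon is a carbonyl, longer is
a hydroxyl (one H); non-ring, non-amide amines are protonated. Geometry is
idealized (120° trigonal, 109.5° tetrahedral); one refinement matters in
practice: hydroxyl and thiol hydrogens are rotatable, so their azimuth is
chosen on the tetrahedral cone pointing toward the nearest N/O of another
residue within 4.5 Å. Without this, a hydroxyl donating sideways would
systematically fail the donor-angle test. Waters receive no hydrogens at
all — a lone oxygen gives no orientation information — and the water-bridge
rules below are phrased so that no water hydrogen is ever needed.

**Ligand selection.** HETATM residues are ligand candidates unless they are
water, appear on the blacklist (shipped as an editable text file: waters,
monoatomic ions, cryoprotectants and buffer components), or are covalently
bonded to a polymer residue (modified residues, glycosylation). Both the
code-list and the connectivity mechanism are active because neither alone
covers all cases. Covalently linked HET groups are detected through the
same bond graph used everywhere else.

**Binding sites.** Each ligand (HET residues connected by covalent bonds
are merged into one composite ligand) collects all protein residues and
waters with any atom within 7.5 Å of a ligand heavy atom. The value is
deliberately generous — the largest interaction cutoff is 6.0 Å — so no
detector can miss a partner; it only affects run time, not results, and is
configurable.

## Functional characterization

All perception is a function of the bond graph and residue templates only,
never of coordinates (coordinates enter only through ring planarity), so
feature sets are invariant under rigid motion — a property the tests check
directly.

* *Hydrophobic atoms*: carbons whose bonded heavy neighbors are all carbon.
* *Donors*: N/O/S with at least one hydrogen. *Acceptors*: any oxygen;
  nitrogens with no hydrogen and at most two heavy neighbors (excluding
  backbone amide N); sulfur with at most two heavy neighbors. Positively
  charged nitrogens are excluded automatically because they carry
  hydrogens.
* *Halogen-bond donors*: ligand C–X units (X = F/Cl/Br/I singly bonded to
  carbon). Fluorine is kept but flagged weak. Protein-side halogen donors
  would require halogenated modified residues and are not perceived.
  Acceptors are O/N/S atoms with a bonded heavy neighbor, which defines the
  Y–A axis for the acceptor angle; if several neighbors exist the
  lowest-serial one is used (unique in the common backbone-carbonyl case).
* *Aromatic rings*: Phe/Tyr/Trp/His side-chain templates on the protein
  side; on the ligand side, 5/6-membered cycles of sp2-capable atoms
  (C/N/O/S, heavy degree ≤ 3) whose least-squares-plane RMSD is at most
  0.25 Å. The planarity test is the aromaticity criterion here: it is what
  a geometric method can actually verify, it accepts every genuinely
  aromatic ring (which is planar to within coordinate error) and rejects
  saturated rings — chair cyclohexane puckers by ±0.25–0.3 Å and fails.
* *Charge centers*: protein templates (Arg guanidinium centroid over
  CZ/NH1/NH2, Lys NZ, Asp/Glu carboxylate over both oxygens, His only when
  both ring nitrogens are protonated); ligand patterns for carboxylate,
  phosphate, sulfonate, guanidinium, quaternary and protonated amines.
  Centroids are unweighted atom means, and no atom may contribute to two
  centers of opposite sign.

## Matching rules and default thresholds

All thresholds live in one key–value configuration (`default_thresholds()`,
overridable from a file or per key). Distances are in Å, angles in degrees.
The defaults are literature-standard permissive values; the package treats
them as configuration, never as constants baked into detectors.

| parameter | default | meaning |
|---|---|---|
| `hydrophobic_dist_max` | 4.0 | C···C contact distance |
| `hbond_dist_max`, `hbond_don_angle_min` | 4.1, 100 | donor–acceptor distance; D–H···A angle at the best hydrogen |
| `waterbridge_mindist`, `waterbridge_maxdist` | 2.5, 4.1 | leg distances to the water oxygen |
| `waterbridge_omega_min/max`, `waterbridge_theta_min` | 75–140, 100 | water-centered angle between legs; donor angle of donating legs |
| `saltbridge_dist_max` | 5.5 | charge-centroid distance |
| `pistack_dist_max`, `pistack_ang_dev`, `pistack_offset_max` | 5.5, 30, 2.0 | ring centroid distance; deviation from 0° (P) or 90° (T); lateral offset (either projection) |
| `pication_dist_max` | 6.0 | ring centroid to cation distance (offset shares `pistack_offset_max`) |
| `halogen_dist_max`, `halogen_don_angle`, `halogen_acc_angle`, `halogen_angle_dev` | 4.0, 165, 120, 30 | X···A distance; sigma-hole C–X···A angle; Y–A···X angle; allowed deviation |

Only cross-interface pairs are considered; protein–protein and
ligand–ligand contacts are never reported. Ring–ring and ring–cation
contacts are reported pairwise (a ligand ring stacking with two protein
rings gives two records). Water-bridge legs are directional: a leg whose
non-water partner carries hydrogens must satisfy the donor angle θ; a leg
toward a pure acceptor is read as the water donating, which imposes no
angle because waters have no placed hydrogens. When a partner could play
either role the permissive reading wins.

## Refinement

Detection is deliberately over-complete; refinement makes the report
parsimonious without ever adding records or editing measurements:

1. *Hydrophobic reduction*: keep each ligand atom's nearest protein
   partner, then each surviving protein atom's nearest ligand partner
   (ties by lower serial — first protein-side, then ligand-side). The
   result has at most one contact per atom on either side.
2. *Salt-bridge precedence*: a hydrogen bond whose donor and acceptor heavy
   atoms both lie inside one salt bridge's atom sets restates the same
   contact and is dropped. The analogous (rare) cation-donor-to-ring
   overlap with a π-cation record is also dropped and logged.
3. *Water-bridge deduplication*: a bridge whose ligand/protein atom pairing
   is already reported as a direct hydrogen bond is removed — the direct
   bond is the more parsimonious explanation. One water may still mediate
   several distinct bridges.

Both passes are idempotent, and after refinement no donor/acceptor atom
pair appears under two interaction types. π-stacking and π-cation records
for the same ring pair are both kept: they describe different physics and
the package does not adjudicate between them.

## The synthetic-complex generator

`fixture_spec()` / `build_fixture()` construct minimal PDB files — one
protein fragment with correct residue and atom nomenclature plus a
fictitious `LG1` ligand — in which one interaction's geometry holds
*exactly* (distances to 10^-3 Å, angles to 0.1°), verified by re-measuring
after a parse round trip. Decoys place the same motif at least 0.2 Å or 5°
outside the relevant threshold. `build_gallery()` bundles 15 cases (one
positive and one decoy per type, plus a T-shaped stacking case) with
ground-truth inventories, and `build_combined_fixture()` merges the seven
positives 50 Å apart into one multi-site structure.

The fixtures emulate idealized single-interaction geometry: real residue
nomenclature (so template perception runs on the real code path), realistic
bond lengths, and controlled placement. They do **not** emulate crowding,
coordinate noise, alternate conformers, missing atoms or ambiguous HET
chemistry — passing the gallery shows the rules and their plumbing are
implemented correctly, not that perception is robust to degraded
experimental data. Optional jitter (uniform, seeded, byte-reproducible) is
available for robustness experiments but the shipped conditions use exact
geometry.

Two constructions deserve a note. Stacked rings are placed 4.8 Å apart
(T-shaped: 5.4 Å) rather than at the 3.4 Å of real stacking: both pass the
5.5 Å rule, but the larger separation keeps all ring carbons beyond the
4.0 Å hydrophobic cutoff, so the positive case contains exactly one
interaction — the point of a single-interaction fixture. The hydrogen-bond
decoy fails on the donor angle: the donor's heavy-atom frame is rotated so
that no point on the hydrogen's rotation cone can reach more than ~72°
toward the acceptor, below the 100° floor.

## Numerical choices and degenerate inputs

* Plane fitting is total least squares via SVD; the normal's sign is fixed
  (positive z, ties by y then x) so serialized geometry is bit-stable.
  Collinear point sets and zero-length angle arms raise explicit
  degenerate-geometry errors.
* Angles are degrees everywhere in the interface; reports round all values
  to two decimals, which PDB coordinate precision (10^-3 Å) makes the honest
  limit. XML reports round-trip byte-identically once a timestamp is
  injected.
* Detector loops are exhaustive O(n·m) scans within a binding site; the
  7.5 Å envelope keeps sites small, and the test suite checks equality with
  an independently written brute-force scan on random scenes (100 seeds)
  rather than trusting shared code paths.
* The test and acceptance workloads use ~25-atom feature scenes, 15-case
  galleries and 10–20 rigid motions per fixture — sizes chosen so the whole
  verification cycle runs in seconds while still exercising every rule
  branch.

## Known limitations

* Protonation is rule-based; unusual pKa environments (catalytic His,
  buried Asp) are not modeled, so charge assignment can differ from
  reality in such pockets.
* Water orientation is not modeled; the water-bridge rules compensate but
  cannot distinguish donor from acceptor water.
* Ligand aromaticity is geometric: a genuinely aromatic but badly distorted
  ring (planarity RMSD > 0.25 Å) is missed, and a planar but non-aromatic
  ring (rare in 5/6-cycles of sp2-capable atoms) would be accepted.
* Metal coordination, amide-π and C–H···π contacts are out of scope; the
  taxonomy is the seven types listed above.
* mmCIF input, assembly expansion and partial charges are not supported.
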