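---
title: "Knob-socket packing analysis: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knob-socket packing analysis: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knobsocket)
```

## The model

An α-helix presents a regular lattice of three-residue surfaces. The unit
of that lattice is the 2:1 clique or *socket*: residues X and Y adjacent in
sequence (peptide bond), residue H hydrogen-bonded to X through the helical
*i*→*i*+4 backbone bond, and Y and H sharing side-chain packing (they sit
three apart in sequence). Reading along the sequence the socket occurs in
two orientations, `XY:H` on the pattern (i, i+1, i+4) and `H:YX` on
(i, i+3, i+4); the colon marks the hydrogen-bonded member. Tertiary and
quaternary packing is then a knob residue B from a different helix, coil or
chain inserting into a socket so that B contacts all three members — the
2:1+1 tetrahedral knob-socket. One knob filling two sockets that share an
edge defines a four-residue *pocket*.

Applied to a receptor whose surface groove binds a single α-helical
ligand — the canonical case being a BH3-domain helix in the hydrophobic
groove of a pro-survival BCL-2 family protein — this decomposition turns
the interface into two directed motif lists (ligand knobs into receptor
sockets, receptor knobs into ligand sockets) that can be compared across
complexes: which sockets are filled in every complex of a paralog
(conserved) versus some (specific), and which ligand lattice positions
participate identically everywhere (conserved residues), differ by
receptor (variable), or never touch the receptor (non-essential). The
conserved Gly–Gly core — a ligand glycine packing a glycine-bearing pocket
on the receptor's central groove helix — anchors all ligands to a common
27-position lattice frame with the central glycine at position 20, so
positions are comparable across complexes (offset from the reference + 20
= lattice index, by construction).

## Contacts: Delaunay with a cutoff

Atomic contacts are Delaunay adjacency (equivalently, shared Voronoi
facets) over all heavy atoms, filtered by an inter-atomic distance cutoff.
The tessellation is computed by an internal Bowyer–Watson implementation
(C++); no pre-installed R package provides 3-D Delaunay, and the test
suite validates the implementation against an independent reference
(`scipy.spatial.Delaunay`) and a pure-R empty-circumsphere brute force.

Numerical choices:

* **Cutoff, 6.0 Å (default, configurable).** Raw Delaunay adjacency
  includes arbitrarily long edges near the convex hull; the cutoff removes
  them and doubles as a light proxy for the solvent-occlusion test used in
  the original packing literature, which we deliberately do not implement
  (a documented simplification). 6 Å spans the heavy-atom pair distances
  seen in first-shell side-chain packing.
* **Degeneracy.** Idealised fixtures put atoms in exactly cospherical
  positions, where the tessellation is ill-defined. Every coordinate is
  therefore jittered by at most 1e-6 Å from a fixed-seed deterministic
  generator before tessellating — far below PDB precision (1e-3 Å) and six
  orders below any distance that matters, while making the tessellation
  unique and runs reproducible bit for bit.
* **Classes.** Backbone atoms are N, CA, C, O (and OXT); all other atoms
  are side chain, except that glycine's CA counts as its side chain for
  packing classes. Residue edges record which of main/main, main/side,
  side/side classes their atomic contacts realise; the socket definition
  requires a side/side contact between Y and H.
* **Trivial neighbours.** Intra-residue contacts are dropped; peptide-bond
  neighbour edges are kept (they are the X–Y edge of every socket) but
  flagged, and a same-chain knob is rejected when it is a sequence
  neighbour (±1) of any socket member.

## Hydrogen bonds and helices

The backbone hydrogen-bond criterion is distance-only: carbonyl O to amide
N within 3.5 Å (configurable). The literature names the *i*→*i*+4 bond but
no criterion; a distance-only rule on O···N is the simplest reproducible
choice ("DSSP-lite") and on ideal geometry gives i→i+4 distances near
2.9–3.1 Å, comfortably inside the cutoff. A helix is a maximal run of
consecutive i→i+4 bonds (all five residues backbone-complete), extended to
the final acceptor; the minimum length is 5 residues so that one socket
(span i..i+4) fits inside a helix. Helices are labelled H1..Hn per chain
in sequence order; mapping these labels to a published nomenclature for a
particular fold (H2..H7 of the BCL-2 fold) is per-complex configuration,
not something coordinates alone can decide. A socket may extend one
position beyond an annotated helix terminus ("hybrid" coil/helix sockets),
which reproduces the motifs observed at groove helix N-termini.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `contact_cutoff` | 6.0 | Å | first-shell heavy-atom packing; trims hull edges |
| `hbond_cutoff` | 3.5 | Å | upper bound of helical O···N distances |
| `min_helix_length` | 5 | residues | one socket must fit inside a helix |
| `model_index` | 1 | – | first deposited NMR model, the field's convention |
| altloc policy | highest occupancy, ties → "A" | – | standard single-conformer choice |

All parameters are recorded in outputs (`attr(contacts, "cutoff")`,
`res$params`, CLI log lines) so deviations are auditable.

## The synthetic world

The generator builds geometrically ideal α-helices: CA atoms on a helix of
radius 2.3 Å, rise 1.5 Å/residue, twist 100°/residue (textbook values;
implementation constants, not literature-derived data), with N, C, O and
CB placed at fixed offsets in the co-rotating CA frame derived once from a
standard (φ = −57°, ψ = −47°) internal-coordinate build. Leu/Ile/Val get
schematic compact rotamers whose terminal methyls sit ~3.9 Å from CA — the
reach of a real knob — so Delaunay contacts across an interface are
realistic; other side chains stop at CB.

Two packing fixtures carry frozen ground truth:

* **two-helix** — an antiparallel pair at the canonical 9.5 Å coiled-coil
  separation, chain A carrying Leu knobs on the interface face. Ground
  truth: a Leu-filled pocket (`A:AA:A`) plus two filled sockets on the
  partner helix.
* **groove** — three parallel receptor helices forming a shallow groove
  (central helix with a mid-face glycine) and a ligand helix whose central
  Gly packs the receptor's Gly socket, emulating the BH3-in-groove
  arrangement; variants substitute the central residue (Ala/Ser) or
  translate the ligand away.

The ground-truth motif lists were established once by running the pipeline
on the generated coordinates and hand-checking every motif geometrically
(side chain pointing into the socket triangle, all contacts within the
cutoff); they are the fixtures' declared truth, never regenerated to chase
a test. What a green fixture test establishes: the pipeline recovers known
packing exactly on clean geometry, and all graph/label/alignment machinery
is correct. What it does not establish: robustness to crystallographic
reality — alternate conformations beyond simple occupancy rules, missing
atoms, bent helices, rotamer diversity — or that the unknown contact
parameters of the original packing studies are matched; analyses of real
PDB entries remain subject to the cutoff choices above.

## Consensus conventions

* "Participation" of a ligand position counts both roles: serving as a
  knob and being a member of a ligand socket packed by a receptor knob.
* Consensus residues use strict plurality; any tie (including 1–1) yields
  `X`, matching the convention that a consensus is only reported when one
  residue is observed most frequently outright.
* Duplicated maps count as separate observations (consensus over n copies
  of one complex is that complex's profile, all conserved).
* Ligands longer than the 27-position window are flagged
  `out_of_window`, never silently truncated.
* Point-mutant complexes participate in conservation scoring but are
  omitted from alignment FASTA displays (the `mutant` config flag).
* The receptor's central groove helix (the BCL-2 "H5") is either named
  per complex in the configuration or auto-detected as the receptor helix
  whose Gly-containing sockets are packed by a ligand Gly knob.

## Known limitations

* Voronoi contacts are approximated by Delaunay + cutoff without a
  solvent-occlusion test; buried vs exposed facets are not distinguished.
* β-sheet sockets and non-helical lattices are out of scope.
* The two network-dependent validation paths (re-deriving the printed
  distance table from the MCL-1:Bim co-crystal, and the 19-complex
  conservation counts) require fetching deposited structures; in an
  offline environment those acceptance tests fail by design rather than
  pass vacuously. Chain assignments in the shipped 19-complex table follow
  the usual deposition convention and are user-editable configuration.
* Lattice SVGs are working diagrams, not publication figures.
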