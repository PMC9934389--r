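# knobsocket

Knob-socket packing analysis of α-helical protein–protein interfaces in R,
built for the interface that matters in apoptosis drug design: a BH3-domain
α-helix bound in the hydrophobic groove of a pro-survival BCL-2 family
receptor (MCL-1, BCL-xL, BCL-2, BFL-1/A1, BHRF1, …). The package is for
structural bioinformaticians who want the packing topology of such
helix-in-groove complexes as typed, reproducible tables and lattice maps
rather than hand-drawn figures.

## The model

Packing is organised into four-residue units:

* a **socket** is a 2:1 clique of three residues on one helix — neighbours
  X and Y joined by the peptide bond, plus H joined to X by the helical
  *i*→*i*+4 backbone hydrogen bond, with Y and H in side-chain contact.
  Sockets come in two sequence orientations, `XY:H` (X lowest in sequence)
  and `H:YX` (H lowest); the `:` marks the hydrogen-bonded residue.
* a **knob** is a single residue from another helix (or chain, or coil)
  whose side chain packs against all three socket residues, making the
  2:1+1 tetrahedral knob-socket clique.
* a **pocket** is the diamond surface formed when one knob fills two
  contiguous sockets sharing an edge (e.g. sockets {4,7,8} and {7,8,11}
  merge into the pocket {4,7,8,11}).

Residue contacts are derived from a Delaunay tessellation of heavy-atom
coordinates (atoms in contact iff their Voronoi cells share a facet and
they are within a 6 Å cutoff), lifted to a residue contact graph typed by
main-chain/side-chain atom classes. Cliques of the graph are then
classified into sockets and knob-sockets.

On top of the motifs the package builds the analyses used for BCL-2:BH3
interfaces: interface maps split by knob direction (ligand→receptor vs
receptor→ligand), socket-centroid distance tables (centroid = mean Cβ,
Cα for glycine), conserved-vs-specific groove models across complexes of
one receptor paralog, and ligand consensus models on a 27-position helical
lattice anchored at the central glycine (lattice position 20), the
conserved Gly–Gly packing that orients every BH3 ligand in the groove.

## Worked example

A synthetic three-helix groove with a ligand helix carrying a central Gly
(`groove_spec()` ships frozen ground truth for this geometry):

```r
library(knobsocket)
fx  <- make_packing_fixture(groove_spec())
res <- analyze_complex(fx$structure, receptor_chains = "A", ligand_chain = "B")
res$interface$lig_knobs[, c("type", "label", "helix", "knob_resseq", "knob_aa")]
#>     type label helix knob_resseq knob_aa
#> 1 socket  AG:A  A:H2           9       G
#> 2 socket  G:AA  A:H2          12       A
#> 3 socket  AA:A  A:H1           8       A
```

Three ligand knobs pack receptor sockets: the ligand's Gly9 fills the
`AG:A` socket on the central receptor helix (the socket containing the
receptor's glycine — the Gly–Gly core), and two Ala knobs fill sockets on
helices H2 and H1. The central reference and the groove distance table:

```r
ref <- find_central_reference(res$interface, central_helix = "A:H2")
unlist(ref[c("knob_resseq", "knob_aa", "substituted", "motif_label")])
#> knob_resseq     knob_aa substituted motif_label
#>         "9"         "G"     "FALSE"      "AG:A"

groove_distance_table(res$interface$lig_knobs, fx$structure)
#> Minimum centroid distances (A):
#>      A:H1 A:H2
#> A:H1   NA 6.77
#> A:H2 6.77 3.26
#> Maximum centroid distances (A):
#>      A:H1 A:H2
#> A:H1   NA 8.59
#> A:H2 8.59 3.26
```

The minima say the packed socket surfaces on the two helices sit 3.3–6.8 Å
apart — the scale that makes a groove targetable by one small molecule.
`run_complex()` writes the same information as TSV/JSON plus helical
lattice maps (JSON + SVG); `run_aggregate()`/`run_study()` derive central
references, aligned ligands, consensus lattices and per-paralog groove
conservation across a set of complexes. The shipped
`inst/extdata/bcl2_complexes.tsv` configures the 19 curated BCL-2:BH3
co-structures for `run_study()` (network or a local PDB cache required).
A command-line front end lives at `inst/cli/knobsocket`
(`analyze`, `aggregate`, `simulate`, `fetch`).

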