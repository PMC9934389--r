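# Frozen ground-truth interface motifs of the synthetic packing fixtures at
# their default geometries. Each row names a knob residue and the socket it
# fills on the partner chain. The lists were established once by running the
# pipeline on the generated coordinates and hand-checking every motif
# geometrically (knob side chain pointing into the triangle of socket
# residues, tip-to-centroid distance smaller than CA-to-centroid, all
# knob/member atom contacts under the 6 A cutoff); they are the fixtures'
# declared truth and the pipeline must recover them exactly at default
# parameters. Regenerate deliberately (never to chase a test) if the
# generator geometry changes.

TWO_HELIX_TRUTH <- data.frame(
  direction = rep("receptor_to_ligand", 3),
  type = c("pocket", "socket", "socket"),
  label = c("A:AA:A", "AA:A", "AA:A"),
  helix = c("B:H1", "B:H1", "B:H1"),
  member_resseq = c("3,6,7,10", "9,10,13", "13,14,17"),
  member_aa = c("AAAA", "AAA", "AAA"),
  knob_chain = c("A", "A", "A"),
  knob_resseq = c(10L, 6L, 3L),
  knob_aa = c("L", "A", "L"),
  stringsAsFactors = FALSE
)

GROOVE_TRUTH <- data.frame(
  direction = c(rep("ligand_to_receptor", 3), rep("receptor_to_ligand", 4)),
  type = rep("socket", 7),
  label = c("AG:A", "G:AA", "AA:A",
            "AA:A", "AG:A", "A:AA", "G:AA"),
  helix = c("A:H2", "A:H2", "A:H1",
            "B:H1", "B:H1", "B:H1", "B:H1"),
  member_resseq = c("37,38,41", "38,41,42", "8,9,12",
                    "2,3,6", "8,9,12", "8,11,12", "9,12,13"),
  member_aa = c("AGA", "GAA", "AAA",
                "AAA", "AGA", "AAA", "GAA"),
  knob_chain = c("B", "B", "B", "A", "A", "A", "A"),
  knob_resseq = c(9L, 12L, 8L, 64L, 8L, 12L, 41L),
  knob_aa = c("G", "A", "A", "A", "A", "A", "A"),
  stringsAsFactors = FALSE
)

#' Extract the comparable motif table of an interface map
#'
#' Projects a `ks_interface_map` onto the columns the fixture ground truths
#' declare, sorted deterministically, for exact comparison.
#'
#' @param map a `ks_interface_map`.
#' @return data.frame with the ground-truth columns.
#' @export
interface_motif_table <- function(map) {
  cols <- c("direction", "type", "label", "helix", "member_resseq",
            "member_aa", "knob_chain", "knob_resseq", "knob_aa")
  tab <- rbind(map$lig_knobs[, cols], map$rec_knobs[, cols])
  tab <- tab[order(tab$direction, tab$helix, tab$member_resseq,
                   tab$knob_resseq), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
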