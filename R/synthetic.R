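# Ideal alpha-helix geometry. Atom offsets are expressed in the co-rotating
# frame of each CA (u = radial outward, v = axis x u, w = helix axis) and were
# derived once from a helix built by internal coordinates at phi = -57,
# psi = -47 with standard bond geometry. At the default rise/twist/radius the
# resulting backbone has CA-CA 3.80 A and O...N(i+4) near 3.1 A.
HELIX_ATOM_OFFSETS <- list(
  N  = c(-0.8907, -0.6988, -0.9187),
  CA = c( 0.0000,  0.0000,  0.0000),
  C  = c(-0.7880,  0.7497,  1.0689),
  O  = c(-0.4749,  0.6676,  2.2566),
  CB = c( 0.8981,  0.9683, -0.7661)
)

#' Generate an ideal alpha helix with known geometry
#'
#' Places backbone atoms (N, CA, C, O) and CB on ideal helical paths around a
#' straight axis. Leu, Ile and Val additionally get schematic outward-pointing
#' side-chain heavy atoms (CG/CD level) so that knob packing produces
#' realistic Delaunay contacts; other residue types stop at CB (glycine has
#' none). Fully deterministic: the same spec always yields bit-identical
#' coordinates.
#'
#' @param sequence one-letter amino acid string (length >= 1).
#' @param rise rise per residue along the axis, Angstrom (default 1.5).
#' @param twist rotation per residue, degrees (default 100, right-handed).
#' @param radius CA helix radius, Angstrom (default 2.3).
#' @param origin 3-vector: axis position of the first CA's axial level.
#' @param axis 3-vector: helix axis direction (normalised internally).
#' @param phase rotation of the whole helix about its axis, degrees; controls
#'   which face points where.
#' @param chain chain identifier (single character).
#' @param resseq_start first residue number.
#' @param id structure id.
#' @return a `ks_structure`.
#' @export
#' @examples
#' h <- make_ideal_helix(strrep("A", 12))
#' hb <- detect_backbone_hbonds(h)
#' assign_helices(h, hb)
make_ideal_helix <- function(sequence, rise = 1.5, twist = 100,
                             radius = 2.3, origin = c(0, 0, 0),
                             axis = c(0, 0, 1), phase = 0, chain = "A",
                             resseq_start = 1L, id = "ideal_helix") {
  stopifnot(rise > 0, abs(twist) > 0, abs(twist) < 180, radius > 0)
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (!length(aa)) stop("empty sequence")
  bad <- setdiff(aa, names(AA1TO3))
  if (length(bad)) stop("unknown residue letter(s): ",
                        paste(unique(bad), collapse = ", "))
  w <- axis / sqrt(sum(axis^2))
  # orthonormal frame perpendicular to the axis
  ref <- if (abs(w[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * w) * w; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(w[2] * e1[3] - w[3] * e1[2],
          w[3] * e1[1] - w[1] * e1[3],
          w[1] * e1[2] - w[2] * e1[1])
  rows <- list()
  add <- function(resi, name, el, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resseq = resseq_start + resi - 1L, icode = "",
      resname = unname(AA1TO3[aa[resi]]), atom = name, element = el,
      altloc = "", occ = 1,
      x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
  }
  for (i in seq_along(aa)) {
    th <- (twist * (i - 1) + phase) * pi / 180
    u <- cos(th) * e1 + sin(th) * e2
    v <- c(w[2] * u[3] - w[3] * u[2],
           w[3] * u[1] - w[1] * u[3],
           w[1] * u[2] - w[2] * u[1])
    ca_ax <- origin + rise * (i - 1) * w
    frame <- function(off) ca_ax + (radius + off[1]) * u + off[2] * v + off[3] * w
    pos <- lapply(HELIX_ATOM_OFFSETS, frame)
    add(i, "N", "N", pos$N)
    add(i, "CA", "C", pos$CA)
    add(i, "C", "C", pos$C)
    add(i, "O", "O", pos$O)
    if (aa[i] != "G") {
      add(i, "CB", "C", pos$CB)
      if (aa[i] %in% c("L", "I", "V")) {
        # schematic compact rotamer: the chain bends along the helix axis so
        # terminal methyls sit ~3.9 A from CA, the reach of a real knob
        dir <- pos$CB - pos$CA; dir <- dir / sqrt(sum(dir^2))
        perp <- c(dir[2] * w[3] - dir[3] * w[2],
                  dir[3] * w[1] - dir[1] * w[3],
                  dir[1] * w[2] - dir[2] * w[1])
        perp <- perp / sqrt(sum(perp^2))
        unitize <- function(x) x / sqrt(sum(x^2))
        if (aa[i] == "V") {
          add(i, "CG1", "C", pos$CB + 1.53 * unitize(dir + 0.8 * perp + 0.5 * w))
          add(i, "CG2", "C", pos$CB + 1.53 * unitize(dir - 0.8 * perp + 0.5 * w))
        } else if (aa[i] == "L") {
          cg <- pos$CB + 1.53 * unitize(dir + w)
          add(i, "CG", "C", cg)
          add(i, "CD1", "C", cg + 1.53 * unitize(dir + 0.9 * perp + 0.4 * w))
          add(i, "CD2", "C", cg + 1.53 * unitize(dir - 0.9 * perp + 0.4 * w))
        } else {
          cg1 <- pos$CB + 1.53 * unitize(dir + 0.6 * perp + 0.6 * w)
          add(i, "CG1", "C", cg1)
          add(i, "CG2", "C", pos$CB + 1.53 * unitize(dir - 0.8 * perp))
          add(i, "CD1", "C", cg1 + 1.53 * unitize(dir + 0.5 * w))
        }
      }
    }
  }
  new_structure(do.call(rbind, rows), id = id, model = 1L)
}

#' Generate a fully extended (all-coil) chain fixture
#'
#' Residues on a straight line at 3.8 A CA spacing with locally planar
#' backbone geometry; no i to i+4 hydrogen bonds exist, so helix annotation
#' returns nothing.
#'
#' @param n number of residues (poly-Ala).
#' @param chain chain id.
#' @return a `ks_structure`.
#' @export
make_extended_chain <- function(n, chain = "A") {
  rows <- list()
  for (i in seq_len(n)) {
    x0 <- 3.8 * (i - 1)
    flip <- if (i %% 2 == 0) -1 else 1
    add <- function(name, el, p)
      rows[[length(rows) + 1L]] <<- data.frame(
        chain = chain, resseq = i, icode = "", resname = "ALA", atom = name,
        element = el, altloc = "", occ = 1, x = p[1], y = p[2], z = p[3],
        stringsAsFactors = FALSE)
    add("N", "N", c(x0 - 1.2, flip * 0.4, 0))
    add("CA", "C", c(x0, 0, 0))
    add("C", "C", c(x0 + 1.2, flip * 0.5, 0))
    add("O", "O", c(x0 + 1.2, flip * 1.7, 0))
    add("CB", "C", c(x0, -flip * 0.9, 1.2))
  }
  new_structure(do.call(rbind, rows), id = "extended_chain", model = 1L)
}

#' Specification of the canonical two-helix packing fixture
#'
#' An antiparallel pair of helices at coiled-coil separation. Chain A carries
#' Leu knobs on the face pointing at chain B (poly-Ala otherwise); chain B is
#' poly-Ala with a complementary contact face. The returned spec carries the
#' frozen ground-truth interface motif list (knob residue -> socket members),
#' hand-verified once against the generated geometry.
#'
#' @param separation inter-axial distance in Angstrom (default 9.5, the
#'   canonical antiparallel coiled-coil spacing).
#' @return a list of class `ks_fixture_spec` understood by
#'   [make_packing_fixture()].
#' @export
two_helix_spec <- function(separation = 9.5) {
  spec <- list(
    name = "two_helix",
    helices = list(
      list(sequence = "AALAAAAAALAAAAAAL", chain = "A",
           origin = c(0, 0, 0), axis = c(0, 0, 1), phase = 190),
      list(sequence = "AAAAAAAAAAAAAAAAA", chain = "B",
           origin = c(separation, 0, 23), axis = c(0, 0, -1), phase = 40)
    ),
    # ground truth holds at the default separation only
    ground_truth = if (identical(separation, 9.5)) TWO_HELIX_TRUTH else NULL
  )
  class(spec) <- "ks_fixture_spec"
  spec
}

#' Specification of the three-helix groove fixture
#'
#' A receptor chain (A) of three parallel helices forming a shallow groove,
#' with a glycine mid-face on the central helix, and a ligand helix (chain B)
#' lying in the groove with a central Gly knob packing the receptor glycine
#' pocket, flanked by Leu knobs. Emulates the BH3-in-groove arrangement at
#' desk scale. The central receptor helix is the second helix of chain A
#' (`A:H2`), playing the role the receptor's H5 plays in a BCL-2 groove.
#'
#' @param ligand_offset rigid translation applied to the ligand helix
#'   (3-vector, default none); translating it far away empties the interface.
#' @param central_aa one-letter code at the ligand's central position
#'   (default "G"; use e.g. "A" to emulate a substituted central residue).
#' @return a list of class `ks_fixture_spec`.
#' @export
groove_spec <- function(ligand_offset = c(0, 0, 0), central_aa = "G") {
  stopifnot(central_aa %in% names(AA1TO3))
  lig_seq <- paste0("AAAAAAAA", central_aa, "AAAAAAAA")
  spec <- list(
    name = "groove",
    helices = list(
      list(sequence = "AAAAAAAAAAAAAAAA", chain = "A", resseq_start = 1L,
           origin = c(-7, 3, 0), axis = c(0, 0, 1), phase = 35),
      list(sequence = "AAAAAAAGAAAAAAAA", chain = "A", resseq_start = 31L,
           origin = c(0, 0, 0), axis = c(0, 0, 1), phase = 125),
      list(sequence = "AAAAAAAAAAAAAAAA", chain = "A", resseq_start = 61L,
           origin = c(7, 3, 0), axis = c(0, 0, 1), phase = 145),
      list(sequence = lig_seq, chain = "B", resseq_start = 1L,
           origin = c(0, 8.6, 0) + ligand_offset, axis = c(0, 0, 1),
           phase = 205)
    ),
    central_helix = "A:H2",
    ground_truth = if (identical(ligand_offset, c(0, 0, 0)) &&
                         central_aa == "G") GROOVE_TRUTH else NULL
  )
  class(spec) <- "ks_fixture_spec"
  spec
}

#' Build a multi-helix packing fixture from a spec
#'
#' Generates every helix in the spec with [make_ideal_helix()], assembles
#' them into one structure, and refuses geometries in steric clash (any
#' inter-chain heavy-atom pair closer than 2.5 A).
#'
#' @param spec a `ks_fixture_spec` from [two_helix_spec()], [groove_spec()],
#'   or built by hand (list of helix parameter lists plus optional
#'   `ground_truth`).
#' @return list with `structure` (a `ks_structure`) and `ground_truth` (the
#'   spec's frozen motif list, or NULL for non-default geometries).
#' @export
make_packing_fixture <- function(spec) {
  stopifnot(is.list(spec), length(spec$helices) >= 1L)
  parts <- lapply(spec$helices, function(h) {
    do.call(make_ideal_helix, c(h, list(id = spec$name)))$atoms
  })
  atoms <- do.call(rbind, parts)
  s <- new_structure(atoms, id = if (is.null(spec$name)) "fixture" else spec$name)
  # steric-clash guard between chains
  ch <- s$atoms$chain
  for (c1 in unique(ch)) for (c2 in unique(ch)) {
    if (c1 >= c2) next
    a1 <- s$atoms[ch == c1, c("x", "y", "z")]
    a2 <- s$atoms[ch == c2, c("x", "y", "z")]
    d2 <- outer(a1$x, a2$x, "-")^2 + outer(a1$y, a2$y, "-")^2 +
      outer(a1$z, a2$z, "-")^2
    if (min(d2) < 2.5^2)
      stop(sprintf("steric clash between chains %s and %s (%.2f A)",
                   c1, c2, sqrt(min(d2))))
  }
  list(structure = s, ground_truth = spec$ground_truth,
       central_helix = spec$central_helix)
}
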