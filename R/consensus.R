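#' Locate the central packing reference of a BH3-type interface
#'
#' The core of every receptor:ligand-helix interface studied here is a
#' central glycine-glycine packing: a ligand Gly knob filling the receptor
#' pocket (on the groove's central helix) that contains the receptor's
#' conserved Gly. This function finds the ligand knob packing a
#' Gly-containing socket/pocket on that helix. When no ligand glycine
#' qualifies, the knob packing the same pocket is returned with
#' `substituted = TRUE` (Ser and Ala occupy the central position in known
#' complexes).
#'
#' @param map a `ks_interface_map`.
#' @param central_helix chain-qualified label of the receptor helix bearing
#'   the central glycine (the BCL-2 "H5"), e.g. `"A:H5"` or the fixture's
#'   `"A:H2"`.
#' @return list of class `ks_central_ref`: `knob_ord`, `knob_resseq`,
#'   `knob_aa`, `substituted`, `motif_label`.
#' @export
find_central_reference <- function(map, central_helix) {
  lk <- map$lig_knobs
  if (!nrow(lk)) stop("interface map ", map$id, " is empty")
  on_h5 <- lk[lk$helix == central_helix, , drop = FALSE]
  has_gly <- grepl("G", on_h5$member_aa, fixed = TRUE)
  cand <- on_h5[has_gly, , drop = FALSE]
  if (!nrow(cand))
    stop("no ligand knob packs a Gly-containing socket on ", central_helix,
         " in ", map$id, "; candidate motifs on that helix: ",
         if (nrow(on_h5)) paste(unique(on_h5$label), collapse = ", ") else
           "(none)")
  gly_knob <- cand$knob_aa == "G"
  pick_from <- if (any(gly_knob)) cand[gly_knob, , drop = FALSE] else cand
  # deterministic pick: the knob filling the most qualifying motifs,
  # then the lowest residue number
  counts <- table(pick_from$knob_ord)
  best <- as.integer(names(counts)[counts == max(counts)])
  knob <- min(best)
  row <- pick_from[pick_from$knob_ord == knob, , drop = FALSE][1, ]
  structure(list(knob_ord = row$knob_ord, knob_resseq = row$knob_resseq,
                 knob_aa = row$knob_aa, substituted = row$knob_aa != "G",
                 motif_label = row$label, complex = map$id),
            class = "ks_central_ref")
}

#' Align ligand helices on their central reference
#'
#' Maps each ligand residue to an offset relative to the central reference
#' (reference = 0) and to an index on the 27-position helical lattice with
#' the reference pinned at position 20, so offset + 20 = lattice index.
#' Participation roles are attached per residue: `knob` (serves as a knob
#' into the receptor), `socket` (member of a ligand socket packed by a
#' receptor knob), or `none`. Residues whose lattice index falls outside
#' 1..27 are flagged `out_of_window`, not dropped.
#'
#' @param maps list of `ks_interface_map`.
#' @param refs list of `ks_central_ref`, parallel to `maps`.
#' @return list of class `ks_aligned_ligand` data.frames: one per complex
#'   with columns `complex`, `resseq`, `aa`, `offset`, `lattice`, `role`,
#'   `out_of_window`.
#' @export
align_ligands <- function(maps, refs) {
  stopifnot(length(maps) == length(refs))
  out <- vector("list", length(maps))
  for (k in seq_along(maps)) {
    m <- maps[[k]]; rf <- refs[[k]]
    lig <- m$ligand_residues
    ref_row <- which(lig$res_ord == rf$knob_ord)
    if (!length(ref_row))
      stop("reference residue not on ligand chain of ", m$id)
    offset <- lig$chain_ord - lig$chain_ord[ref_row]
    lattice <- offset + 20L
    knob_ords <- unique(m$lig_knobs$knob_ord)
    sock_ords <- unique(unlist(lapply(m$rec_knobs$member_ords, function(s)
      as.integer(strsplit(s, ",")[[1]]))))
    role <- rep("none", nrow(lig))
    role[lig$res_ord %in% sock_ords] <- "socket"
    role[lig$res_ord %in% knob_ords] <- "knob"  # knob wins if both
    al <- data.frame(complex = m$id, resseq = lig$resseq, aa = lig$aa1,
                     offset = offset, lattice = lattice, role = role,
                     out_of_window = lattice < 1L | lattice > 27L,
                     stringsAsFactors = FALSE)
    class(al) <- c("ks_aligned_ligand", class(al))
    out[[k]] <- al
  }
  out
}

#' Strict-plurality consensus residue of a position
#'
#' @param column character vector of one-letter codes observed at one
#'   lattice position (participating complexes only).
#' @return the single most frequent residue, or "X" when the column is empty
#'   or the top count is tied.
#' @export
consensus_residue <- function(column) {
  if (!length(column)) return("X")
  tab <- sort(table(column), decreasing = TRUE)
  if (length(tab) > 1L && tab[1] == tab[2]) return("X")
  names(tab)[1]
}

#' Classify lattice positions as conserved, variable or non-essential
#'
#' Across the aligned ligands of a scope (all complexes, one receptor
#' paralog, or one ligand family), a lattice position is *conserved* when it
#' participates in binding (as a knob or socket member) with the identical
#' amino acid in every complex, *variable* when it participates somewhere
#' but not identically everywhere, and *non-essential* when it never
#' participates. Position 20 is additionally tagged `central`. A consensus
#' residue (strict plurality, "X" on ties) is attached to participating
#' positions.
#'
#' @param aligned list of `ks_aligned_ligand` frames ([align_ligands()]).
#' @param scope label recorded in the output (e.g. "all", a paralog name).
#' @param positions lattice window (default 1:27).
#' @return data.frame of class `ks_consensus_model`: `scope`, `lattice`,
#'   `class`, `consensus`, `n_participating`, `n_covered`, `residues`.
#' @export
classify_positions <- function(aligned, scope = "all", positions = 1:27) {
  stopifnot(length(aligned) >= 1L)
  out <- lapply(positions, function(p) {
    # per-ligand participation (duplicated maps count separately)
    part_aa <- lapply(aligned, function(a)
      a$aa[a$lattice == p & a$role != "none"])
    covered <- vapply(aligned, function(a) any(a$lattice == p), logical(1))
    participates <- lengths(part_aa) > 0L
    aas <- unlist(part_aa)
    n_par <- sum(participates)
    cls <- if (p == 20L) "central" else if (n_par == 0L) "non-essential"
      else if (n_par == length(aligned) &&
                 length(unique(aas)) == 1L) "conserved" else "variable"
    cons <- if (n_par > 0L) consensus_residue(aas) else ""
    data.frame(scope = scope, lattice = p, class = cls, consensus = cons,
               n_participating = n_par, n_covered = sum(covered),
               residues = paste(sort(aas), collapse = ""),
               stringsAsFactors = FALSE)
  })
  model <- do.call(rbind, out)
  class(model) <- c("ks_consensus_model", class(model))
  model
}

#' Write consensus model and alignment outputs
#'
#' @param model a `ks_consensus_model`.
#' @param aligned the aligned ligands behind it.
#' @param tsv_path,json_path,fasta_path output paths (NULL to skip).
#' @return invisibly, the model.
#' @export
write_consensus <- function(model, aligned, tsv_path = NULL,
                            json_path = NULL, fasta_path = NULL) {
  if (!is.null(tsv_path))
    write.table(model, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(as.data.frame(model), json_path,
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(fasta_path)) {
    lines <- unlist(lapply(aligned, function(a) {
      inw <- a[!a$out_of_window, , drop = FALSE]
      seqv <- rep("-", 27L)
      seqv[inw$lattice] <- inw$aa
      c(paste0(">", a$complex[1]), paste(seqv, collapse = ""))
    }))
    writeLines(lines, fasta_path)
  }
  invisible(model)
}
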