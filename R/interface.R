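#' Restrict knob-socket motifs to a receptor/ligand interface
#'
#' Partitions the detected motifs (filled sockets and pockets) into those
#' whose knob comes from the ligand chain and packs a receptor socket, and
#' those whose knob comes from a receptor chain and packs a ligand socket.
#' Motifs entirely within the receptor or within the ligand are dropped.
#' Each motif row is materialised with residue identities so downstream
#' conservation analyses need no structure object.
#'
#' @param structure the `ks_structure` of the complex.
#' @param receptor_chains character vector of receptor chain ids.
#' @param ligand_chain single ligand chain id.
#' @param motifs output of [merge_pockets()] (list with `pockets`,
#'   `singles`).
#' @param helices output of [assign_helices()].
#' @return An object of class `ks_interface_map`: list with `id`,
#'   `receptor_chains`, `ligand_chain`, `lig_knobs` and `rec_knobs`
#'   (data.frames, one motif per row: `type` socket/pocket, `label`,
#'   `socket_chain`, `helix`, member residue descriptors, knob descriptors),
#'   and `ligand_residues` (the full ligand residue table).
#' @export
map_interface <- function(structure, receptor_chains, ligand_chain, motifs,
                          helices) {
  res <- structure$residues
  if (!ligand_chain %in% res$chain)
    stop("ligand chain '", ligand_chain, "' absent from structure ",
         structure$id)
  seg <- segment_labels(structure, helices)
  desc <- function(ords)
    paste(sprintf("%s/%d%s/%s", res$chain[ords], res$resseq[ords],
                  res$icode[ords], res$aa1[ords]), collapse = "+")

  rows <- list()
  add_motif <- function(member_ords, hmark_ords, knob_ord, helix, type) {
    kc <- res$chain[knob_ord]
    sc <- res$chain[member_ords[1]]
    knob_side <- if (kc == ligand_chain) "ligand" else
      if (kc %in% receptor_chains) "receptor" else NA_character_
    sock_side <- if (sc == ligand_chain) "ligand" else
      if (sc %in% receptor_chains) "receptor" else NA_character_
    if (is.na(knob_side) || is.na(sock_side) || knob_side == sock_side)
      return(invisible())
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type,
      direction = if (knob_side == "ligand") "ligand_to_receptor" else
        "receptor_to_ligand",
      label = motif_label(res$aa1[member_ords], member_ords %in% hmark_ords),
      socket_chain = sc, helix = helix,
      members = desc(member_ords),
      member_ords = paste(member_ords, collapse = ","),
      member_resseq = paste(res$resseq[member_ords], collapse = ","),
      member_aa = paste(res$aa1[member_ords], collapse = ""),
      knob_ord = knob_ord, knob_chain = kc,
      knob_resseq = res$resseq[knob_ord], knob_icode = res$icode[knob_ord],
      knob_aa = res$aa1[knob_ord], knob_segment = seg[knob_ord],
      stringsAsFactors = FALSE)
  }
  sk <- motifs$singles
  for (r in seq_len(nrow(sk)))
    add_motif(c(sk$m1[r], sk$m2[r], sk$m3[r]), sk$h_ord[r], sk$knob_ord[r],
              sk$helix[r], "socket")
  pk <- motifs$pockets
  for (r in seq_len(nrow(pk)))
    add_motif(c(pk$m1[r], pk$m2[r], pk$m3[r], pk$m4[r]),
              c(pk$h1_ord[r], pk$h2_ord[r]), pk$knob_ord[r], pk$helix[r],
              "pocket")
  all_rows <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(type = character(), direction = character(),
               label = character(), socket_chain = character(),
               helix = character(), members = character(),
               member_ords = character(), member_resseq = character(),
               member_aa = character(), knob_ord = integer(),
               knob_chain = character(), knob_resseq = integer(),
               knob_icode = character(), knob_aa = character(),
               knob_segment = character(), stringsAsFactors = FALSE)
  ord <- order(all_rows$socket_chain, all_rows$member_ords, all_rows$knob_ord)
  all_rows <- all_rows[ord, , drop = FALSE]
  rownames(all_rows) <- NULL
  lig <- res[res$chain == ligand_chain, , drop = FALSE]
  structure(list(
    id = structure$id,
    receptor_chains = receptor_chains, ligand_chain = ligand_chain,
    lig_knobs = all_rows[all_rows$direction == "ligand_to_receptor", ,
                         drop = FALSE],
    rec_knobs = all_rows[all_rows$direction == "receptor_to_ligand", ,
                         drop = FALSE],
    ligand_residues = lig), class = "ks_interface_map")
}

#' Socket centroid: mean of member CB coordinates (CA for glycine)
#'
#' @param member_ords residue ordinals of the motif members.
#' @param structure the `ks_structure`.
#' @return numeric 3-vector (Angstrom).
#' @export
socket_centroid <- function(member_ords, structure) {
  a <- structure$atoms
  res <- structure$residues
  pts <- vapply(member_ords, function(o) {
    want <- if (res$aa1[o] == "G") "CA" else "CB"
    row <- which(a$res_ord == o & a$atom == want)
    if (!length(row))
      stop("residue ", res$chain[o], "/", res$resseq[o], " (", res$aa1[o],
           ") lacks a ", want, " atom")
    c(a$x[row[1]], a$y[row[1]], a$z[row[1]])
  }, numeric(3))
  rowMeans(pts)
}

#' Minimum/maximum centroid distances between helix groups of a groove
#'
#' Computes socket centroids (mean CB, CA for Gly) for every motif, groups
#' them by receptor helix, and reports the minimum and maximum Euclidean
#' distance for every helix pair, including within-helix pairs (distinct
#' sockets only). Helix groups with a single socket have no within-pair and
#' are reported as NA; absent groups are omitted.
#'
#' @param motif_table data.frame with columns `helix` and `member_ords`
#'   (comma-separated residue ordinals), e.g. the `lig_knobs` frame of a
#'   [map_interface()] result.
#' @param structure the `ks_structure`.
#' @param helix_names optional explicit group ordering.
#' @return list of class `ks_distance_table` with matrices `min` and `max`
#'   (Angstrom, full precision; print rounds to 2 decimals) and `centroids`.
#' @export
groove_distance_table <- function(motif_table, structure,
                                  helix_names = NULL) {
  mt <- unique(motif_table[, c("helix", "member_ords")])
  if (!nrow(mt)) stop("no motifs to measure")
  cent <- t(vapply(mt$member_ords, function(s)
    socket_centroid(as.integer(strsplit(s, ",")[[1]]), structure),
    numeric(3)))
  groups <- if (is.null(helix_names)) sort(unique(mt$helix)) else helix_names
  k <- length(groups)
  mn <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  mx <- mn
  for (i in seq_len(k)) for (j in i:k) {
    gi <- which(mt$helix == groups[i])
    gj <- which(mt$helix == groups[j])
    if (!length(gi) || !length(gj)) next
    d <- sqrt(outer(cent[gi, 1], cent[gj, 1], "-")^2 +
                outer(cent[gi, 2], cent[gj, 2], "-")^2 +
                outer(cent[gi, 3], cent[gj, 3], "-")^2)
    if (i == j) {
      if (length(gi) < 2L) next
      d <- d[upper.tri(d)]
    }
    mn[i, j] <- mn[j, i] <- min(d)
    mx[i, j] <- mx[j, i] <- max(d)
  }
  structure(list(min = mn, max = mx,
                 centroids = cbind(mt, as.data.frame(cent))),
            class = "ks_distance_table")
}

#' @export
print.ks_distance_table <- function(x, ...) {
  cat("Minimum centroid distances (A):\n")
  print(round(x$min, 2))
  cat("Maximum centroid distances (A):\n")
  print(round(x$max, 2))
  invisible(x)
}

#' Conserved-groove model across complexes of one receptor paralog
#'
#' A receptor socket (identified by its receptor residue numbers and amino
#' acids, chain-independent) is *conserved* when a motif at that position is
#' filled in every interface map supplied; otherwise it is *specific* to the
#' subset of complexes in which it appears. Member chemistry (aliphatic /
#' aromatic / polar / charged) is annotated per socket.
#'
#' @param maps list of `ks_interface_map` objects sharing a receptor paralog.
#' @return data.frame: `socket_key`, `label`, `helix`, `class`
#'   ("conserved"/"specific"), `n_maps`, `maps` (complex ids), `chemistry`.
#' @export
conserved_groove_model <- function(maps) {
  stopifnot(length(maps) >= 1L)
  per_map <- lapply(maps, function(m) {
    lk <- m$lig_knobs
    data.frame(id = m$id,
               socket_key = paste(lk$member_resseq, lk$member_aa, sep = ":"),
               label = lk$label, helix = lk$helix,
               member_aa = lk$member_aa, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_map)
  if (!nrow(tab))
    return(data.frame(socket_key = character(), label = character(),
                      helix = character(), class = character(),
                      n_maps = integer(), maps = character(),
                      chemistry = character(), stringsAsFactors = FALSE))
  agg <- lapply(split(tab, tab$socket_key), function(d) {
    ids <- unique(d$id)
    aa <- strsplit(d$member_aa[1], "")[[1]]
    data.frame(socket_key = d$socket_key[1], label = d$label[1],
               helix = d$helix[1],
               class = if (length(ids) == length(maps)) "conserved" else
                 "specific",
               n_maps = length(ids), maps = paste(sort(ids), collapse = ","),
               chemistry = paste(unique(unname(AA_CHEMISTRY[aa])),
                                 collapse = "/"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$helix, out$socket_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an interface map as JSON and TSV
#' @param map a `ks_interface_map`.
#' @param json_path,tsv_path output paths (NULL to skip either).
#' @return invisibly, the map.
#' @export
write_interface_map <- function(map, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(unclass(map), json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path)) {
    both <- rbind(map$lig_knobs, map$rec_knobs)
    both <- cbind(complex = map$id, both)
    write.table(both, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(map)
}
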