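#' Per-residue segment labels (helix or coil)
#'
#' Labels every residue with its chain-qualified segment: `Hk` inside the
#' k-th helix of its chain, `Ci-j` for the coil between helices Hi and Hj
#' (`C0-1` before the first, `Ck-` after the last).
#'
#' @param structure a `ks_structure`.
#' @param helices output of [assign_helices()].
#' @return character vector indexed by `res_ord`, e.g. `"A:H2"`, `"B:C1-2"`.
#' @export
segment_labels <- function(structure, helices) {
  res <- structure$residues
  lab <- character(nrow(res))
  for (ch in unique(res$chain)) {
    idx <- which(res$chain == ch)
    h <- helices[helices$chain == ch, , drop = FALSE]
    h <- h[order(h$start_ord), , drop = FALSE]
    seg <- rep(sprintf("C%d-", nrow(h)), length(idx))
    prev_end <- 0L
    for (k in seq_len(nrow(h))) {
      co <- res$chain_ord[idx]
      seg[co > prev_end & co < h$start_ord[k]] <-
        if (k == 1L) "C0-1" else sprintf("C%d-%d", k - 1L, k)
      seg[co >= h$start_ord[k] & co <= h$end_ord[k]] <- h$label[k]
      prev_end <- h$end_ord[k]
    }
    if (nrow(h) == 0L) seg[] <- "C0-"
    lab[idx] <- paste(ch, seg, sep = ":")
  }
  lab
}

#' Classify 3-residue cliques into oriented 2:1 sockets
#'
#' A 3-clique is a socket when its residues lie on one chain in the pattern
#' (i, i+1, i+4) or (i, i+3, i+4), the outer pair (i, i+4) is joined by the
#' helical backbone hydrogen bond O(i)...N(i+4), the Y and H residues share a
#' side-chain contact, and the triple sits on (or at most one position
#' beyond) an annotated helix. Pattern (i, i+1, i+4) is the XY:H orientation
#' (X = i); pattern (i, i+3, i+4) is H:YX (H = i).
#'
#' @param cliques3 3-column matrix from [enumerate_cliques()].
#' @param helices output of [assign_helices()].
#' @param hbonds output of [detect_backbone_hbonds()].
#' @param graph the `ks_contact_graph`.
#' @param structure the `ks_structure`.
#' @return data.frame of sockets: `socket_id`, roles `x_ord`, `y_ord`,
#'   `h_ord` (residue ordinals), `orientation` ("XY:H" or "H:YX"), `chain`,
#'   `helix` (chain-qualified host helix label), `m1`,`m2`,`m3` (members in
#'   sequence order).
#' @export
classify_sockets <- function(cliques3, helices, hbonds, graph, structure) {
  res <- structure$residues
  empty <- data.frame(socket_id = integer(), x_ord = integer(),
                      y_ord = integer(), h_ord = integer(),
                      orientation = character(), chain = character(),
                      helix = character(), m1 = integer(), m2 = integer(),
                      m3 = integer(), stringsAsFactors = FALSE)
  if (is.null(cliques3) || nrow(cliques3) == 0L) return(empty)
  hb_key <- paste(hbonds$acceptor, hbonds$donor, sep = "_")
  e <- graph$edges
  ss_key <- paste(e$i[e$ss], e$j[e$ss], sep = "_")
  out <- list()
  for (r in seq_len(nrow(cliques3))) {
    m <- sort(cliques3[r, ])
    ch <- res$chain[m]
    if (length(unique(ch)) != 1L) next
    co <- res$chain_ord[m]
    d <- co - co[1]
    if (identical(d, c(0L, 1L, 4L))) {
      x <- m[1]; y <- m[2]; h <- m[3]; orient <- "XY:H"
    } else if (identical(d, c(0L, 3L, 4L))) {
      h <- m[1]; y <- m[2]; x <- m[3]; orient <- "H:YX"
    } else next
    # helical hydrogen bond between the outer pair: O(lower) -> N(upper)
    if (!(paste(m[1], m[3], sep = "_") %in% hb_key)) next
    # Y and H must share side-chain packing
    if (!(paste(min(y, h), max(y, h), sep = "_") %in% ss_key)) next
    # host helix: all members within span +- 1, at least two strictly inside
    hx <- helices[helices$chain == ch[1], , drop = FALSE]
    host <- NA_character_
    for (k in seq_len(nrow(hx))) {
      inside <- co >= hx$start_ord[k] & co <= hx$end_ord[k]
      near <- co >= hx$start_ord[k] - 1L & co <= hx$end_ord[k] + 1L
      if (all(near) && sum(inside) >= 2L) { host <- hx$label[k]; break }
    }
    if (is.na(host)) next
    out[[length(out) + 1L]] <- data.frame(
      x_ord = x, y_ord = y, h_ord = h, orientation = orient,
      chain = ch[1], helix = paste(ch[1], host, sep = ":"),
      m1 = m[1], m2 = m[2], m3 = m[3], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  sockets <- do.call(rbind, out)
  sockets <- sockets[order(sockets$chain, sockets$m1, sockets$m2, sockets$m3), ,
                     drop = FALSE]
  sockets <- cbind(socket_id = seq_len(nrow(sockets)), sockets)
  rownames(sockets) <- NULL
  sockets
}

#' Detect 2:1+1 knob-socket motifs from 4-residue cliques
#'
#' Every 4-clique that contains a classified socket plus one residue B from
#' outside the socket's helix (a different helix, a coil region, or another
#' chain) yields a knob-socket: B packs against all three socket residues.
#' Same-chain knobs that are peptide-bond neighbours of any socket residue
#' are rejected as trivial contacts. A knob may fill several sockets, and a
#' residue may be a knob in one motif and a socket member in another.
#'
#' @param cliques4 4-column matrix from [enumerate_cliques()].
#' @param sockets output of [classify_sockets()].
#' @param helices output of [assign_helices()].
#' @param structure the `ks_structure`.
#' @return data.frame: socket columns (as in `sockets`) plus `knob_ord`,
#'   `knob_chain`, one row per (socket, knob) pair, ordered by chain then
#'   residue.
#' @export
find_knob_sockets <- function(cliques4, sockets, helices, structure) {
  res <- structure$residues
  empty <- cbind(sockets[0, , drop = FALSE],
                 data.frame(knob_ord = integer(), knob_chain = character()))
  if (is.null(cliques4) || nrow(cliques4) == 0L || nrow(sockets) == 0L)
    return(empty)
  skey <- paste(sockets$m1, sockets$m2, sockets$m3, sep = "_")
  out <- list()
  for (r in seq_len(nrow(cliques4))) {
    q <- sort(cliques4[r, ])
    for (drop in 1:4) {
      trip <- q[-drop]
      b <- q[drop]
      hit <- which(skey == paste(trip, collapse = "_"))
      if (!length(hit)) next
      s <- sockets[hit[1], ]
      if (res$chain[b] == s$chain) {
        # must lie outside the host helix span
        hx <- helices[helices$chain == s$chain &
                        paste(s$chain, helices$label, sep = ":") == s$helix, ]
        bco <- res$chain_ord[b]
        if (nrow(hx) && bco >= hx$start_ord[1] && bco <= hx$end_ord[1]) next
        # reject trivial sequence neighbours of the socket
        if (any(abs(bco - res$chain_ord[trip]) <= 1L)) next
      }
      out[[length(out) + 1L]] <-
        cbind(s, data.frame(knob_ord = b, knob_chain = res$chain[b],
                            stringsAsFactors = FALSE))
    }
  }
  if (!length(out)) return(empty)
  ks <- do.call(rbind, out)
  ks <- unique(ks)
  ks <- ks[order(ks$chain, ks$m1, ks$knob_chain, res$chain_ord[ks$knob_ord]), ,
           drop = FALSE]
  rownames(ks) <- NULL
  ks
}

#' Merge contiguous filled sockets into pockets
#'
#' Two knob-sockets filled by the same knob whose sockets share exactly two
#' residues form a pocket: a four-residue diamond surface packed by one knob.
#' Knob-sockets that do not merge pass through unchanged. A knob filling
#' three pairwise-contiguous sockets yields two pockets sharing the middle
#' socket (reported via a message).
#'
#' @param knob_sockets output of [find_knob_sockets()].
#' @param structure the `ks_structure`.
#' @return list with `pockets` (data.frame: `m1`..`m4` members in sequence
#'   order, `knob_ord`, `knob_chain`, `chain`, `helix`, `socket_ids`,
#'   `h1_ord`, `h2_ord` the hydrogen-bonded members) and `singles` (the rows
#'   of `knob_sockets` not absorbed into any pocket).
#' @export
merge_pockets <- function(knob_sockets, structure) {
  ks <- knob_sockets
  pockets <- list()
  merged <- rep(FALSE, nrow(ks))
  if (nrow(ks)) {
    groups <- split(seq_len(nrow(ks)), ks$knob_ord)
    for (g in groups) {
      if (length(g) < 2L) next
      pair_count <- 0L
      for (ii in seq_along(g)) for (jj in seq_along(g)) {
        if (ii >= jj) next
        a <- g[ii]; b <- g[jj]
        ma <- c(ks$m1[a], ks$m2[a], ks$m3[a])
        mb <- c(ks$m1[b], ks$m2[b], ks$m3[b])
        shared <- intersect(ma, mb)
        if (length(shared) != 2L) next
        u <- sort(union(ma, mb))
        pair_count <- pair_count + 1L
        # canonical order: the socket starting lower in sequence comes first
        if (ks$m1[b] < ks$m1[a] ||
              (ks$m1[b] == ks$m1[a] && ks$m2[b] < ks$m2[a])) {
          tmp <- a; a <- b; b <- tmp
        }
        pockets[[length(pockets) + 1L]] <- data.frame(
          m1 = u[1], m2 = u[2], m3 = u[3], m4 = u[4],
          knob_ord = ks$knob_ord[a], knob_chain = ks$knob_chain[a],
          chain = ks$chain[a], helix = ks$helix[a],
          socket_ids = paste(sort(c(ks$socket_id[a], ks$socket_id[b])),
                             collapse = ","),
          h1_ord = ks$h_ord[a], h2_ord = ks$h_ord[b],
          stringsAsFactors = FALSE)
        merged[c(a, b)] <- TRUE
      }
      if (pair_count > 1L)
        message("knob residue ", ks$knob_ord[g[1]], " fills ", length(g),
                " contiguous sockets; emitting ", pair_count,
                " overlapping pockets")
    }
  }
  pockets <- if (length(pockets)) do.call(rbind, pockets) else
    data.frame(m1 = integer(), m2 = integer(), m3 = integer(),
               m4 = integer(), knob_ord = integer(), knob_chain = character(),
               chain = character(), helix = character(),
               socket_ids = character(), h1_ord = integer(),
               h2_ord = integer(), stringsAsFactors = FALSE)
  if (nrow(pockets)) {
    pockets <- unique(pockets)
    pockets <- pockets[order(pockets$chain, pockets$m1, pockets$m2,
                             pockets$knob_ord), , drop = FALSE]
    rownames(pockets) <- NULL
  }
  list(pockets = pockets, singles = ks[!merged, , drop = FALSE])
}

#' Label a packing motif
#'
#' Builds the field's socket/pocket string: member one-letter codes in
#' sequence order with a ':' marking each residue that is a backbone
#' hydrogen-bond partner within the motif. The colon sits between the marked
#' residue and the motif interior, so an XY:H socket prints as "XY:H", an
#' H:YX socket as e.g. "A:AA", and a pocket whose hydrogen-bonded members
#' flank the middle pair as e.g. "S:RV:H".
#'
#' @param aa character vector of one-letter codes in sequence order.
#' @param hmark logical vector: is this member a hydrogen-bond partner?
#' @return the label string.
#' @export
#' @examples
#' motif_label(c("V", "M", "V"), c(FALSE, FALSE, TRUE))  # "VM:V"
motif_label <- function(aa, hmark) {
  stopifnot(length(aa) == length(hmark), length(aa) >= 2L)
  n <- length(aa)
  sep <- rep("", n - 1L)  # separator after member k
  for (k in which(hmark)) {
    if (k == 1L) sep[1L] <- ":"
    else sep[k - 1L] <- ":"
  }
  paste0(paste0(aa[-n], sep, collapse = ""), aa[n])
}

#' Parse a socket or first/last-marked pocket label
#'
#' Inverse of [motif_label()] for the unambiguous cases: 3-residue sockets
#' (one colon, after the first or before the last member) and pockets whose
#' hydrogen-bonded members are the first and last. Pocket labels with
#' interior marks are ambiguous by construction; the structured motif tables
#' are authoritative there.
#'
#' @param label a motif label string.
#' @return list with `aa` (one-letter codes) and `hmark` (logical).
#' @export
parse_motif_label <- function(label) {
  chars <- strsplit(label, "")[[1]]
  aa <- chars[chars != ":"]
  n <- length(aa)
  hmark <- rep(FALSE, n)
  pos <- 0L
  for (c in chars) {
    if (c == ":") {
      hmark[if (pos == 1L) 1L else pos + 1L] <- TRUE
    } else pos <- pos + 1L
  }
  list(aa = aa, hmark = hmark)
}

#' Label a socket row
#' @param socket one row of [classify_sockets()] output.
#' @param structure the `ks_structure`.
#' @return label string.
#' @export
socket_label <- function(socket, structure) {
  m <- c(socket$m1, socket$m2, socket$m3)
  motif_label(structure$residues$aa1[m], m == socket$h_ord)
}

#' Label a pocket row
#' @param pocket one row of the `pockets` frame from [merge_pockets()].
#' @param structure the `ks_structure`.
#' @return label string.
#' @export
pocket_label <- function(pocket, structure) {
  m <- c(pocket$m1, pocket$m2, pocket$m3, pocket$m4)
  motif_label(structure$residues$aa1[m],
              m %in% c(pocket$h1_ord, pocket$h2_ord))
}

#' Build the helical lattice map of one helix
#'
#' Lays the helix residues on a 2-D helical net (seven residues per row, two
#' turns, successive rows offset by half a period so that residues i and i+4
#' are vertical neighbours and i and i+1 horizontal neighbours), tiles the
#' classified sockets as triangular cells, and overlays the knobs filling
#' them, tagged by the knob's segment of origin.
#'
#' @param helix one row of [assign_helices()] output.
#' @param sockets sockets hosted on this helix ([classify_sockets()] rows).
#' @param knob_sockets filled sockets ([find_knob_sockets()] rows), may be
#'   empty.
#' @param structure the `ks_structure`.
#' @param helices full helix table (for knob origin labels).
#' @return An object of class `ks_lattice_map`: list with `helix`,
#'   `residues` (res_ord, aa, resseq, grid `x`, `y`), `cells` (one per
#'   socket: members, orientation, label), `knobs` (knob residue, target
#'   socket, origin segment).
#' @export
build_lattice_map <- function(helix, sockets, knob_sockets, structure,
                              helices = NULL) {
  res <- structure$residues
  span <- which(res$chain == helix$chain &
                  res$chain_ord >= helix$start_ord &
                  res$chain_ord <= helix$end_ord)
  i0 <- res$chain_ord[span] - helix$start_ord
  grid <- data.frame(res_ord = span, aa = res$aa1[span],
                     resseq = res$resseq[span],
                     x = i0 %% 7 + 3.5 * (i0 %/% 7), y = i0 %/% 7)
  hlabel <- paste(helix$chain, helix$label, sep = ":")
  sk <- sockets[sockets$helix == hlabel, , drop = FALSE]
  cells <- data.frame(
    socket_id = sk$socket_id,
    members = if (nrow(sk)) paste(sk$m1, sk$m2, sk$m3, sep = ",") else character(),
    orientation = sk$orientation,
    label = if (nrow(sk))
      vapply(seq_len(nrow(sk)), function(r) socket_label(sk[r, ], structure),
             character(1)) else character(),
    stringsAsFactors = FALSE)
  ks <- knob_sockets[knob_sockets$helix == hlabel, , drop = FALSE]
  origin <- if (!is.null(helices)) segment_labels(structure, helices) else
    paste(res$chain, "?", sep = ":")
  knobs <- data.frame(
    knob_ord = ks$knob_ord,
    knob_aa = res$aa1[ks$knob_ord],
    knob_chain = ks$knob_chain,
    knob_resseq = res$resseq[ks$knob_ord],
    socket_id = ks$socket_id,
    origin = origin[ks$knob_ord],
    stringsAsFactors = FALSE)
  structure(list(helix = hlabel, residues = grid, cells = cells,
                 knobs = knobs),
            class = "ks_lattice_map")
}

#' Write a lattice map as JSON
#' @param map a `ks_lattice_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lattice_json <- function(map, path) {
  jsonlite::write_json(unclass(map), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Render a lattice map as SVG
#'
#' Schematic helical-net diagram: one circle per residue, a triangle per
#' socket cell, filled sockets carrying the knob's one-letter code and origin
#' tag in the cell centre. Intended as a working visual, not a publication
#' figure.
#'
#' @param map a `ks_lattice_map`.
#' @param path output path.
#' @param scale pixels per lattice unit.
#' @return `path`, invisibly.
#' @export
write_lattice_svg <- function(map, path, scale = 40) {
  g <- map$residues
  px <- function(v) sprintf("%.1f", (v - min(g$x) + 1) * scale)
  py <- function(v) sprintf("%.1f", (max(g$y) - v + 1) * scale)
  w <- (diff(range(g$x)) + 2) * scale
  h <- (diff(range(g$y)) + 2) * scale
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f">',
    w, h),
    sprintf('<text x="5" y="15" font-size="13">%s</text>', map$helix))
  pal <- c("#d95f02", "#7570b3", "#1b9e77", "#e7298a", "#66a61e", "#e6ab02")
  origin_col <- function(o)
    pal[1 + (sum(utf8ToInt(o)) %% length(pal))]
  for (r in seq_len(nrow(map$cells))) {
    m <- as.integer(strsplit(map$cells$members[r], ",")[[1]])
    gi <- match(m, g$res_ord)
    if (anyNA(gi)) next
    pts <- paste(paste(px(g$x[gi]), py(g$y[gi]), sep = ","), collapse = " ")
    out <- c(out, sprintf(
      '<polygon points="%s" fill="#eeeeee" stroke="#999999"/>', pts))
  }
  for (r in seq_len(nrow(map$knobs))) {
    cell <- map$cells[map$cells$socket_id == map$knobs$socket_id[r], ]
    if (!nrow(cell)) next
    m <- as.integer(strsplit(cell$members[1], ",")[[1]])
    gi <- match(m, g$res_ord)
    if (anyNA(gi)) next
    cx <- mean(g$x[gi]); cy <- mean(g$y[gi])
    col <- origin_col(map$knobs$origin[r])
    out <- c(out,
      sprintf('<circle cx="%s" cy="%s" r="%.1f" fill="%s" opacity="0.85"/>',
              px(cx), py(cy), scale * 0.28, col),
      sprintf(paste0('<text x="%s" y="%s" font-size="%.0f" ',
                     'text-anchor="middle" fill="white">%s</text>'),
              px(cx), py(cy), scale * 0.3, map$knobs$knob_aa[r]))
  }
  for (r in seq_len(nrow(g))) {
    out <- c(out,
      sprintf('<circle cx="%s" cy="%s" r="%.1f" fill="white" stroke="black"/>',
              px(g$x[r]), py(g$y[r]), scale * 0.2),
      sprintf(paste0('<text x="%s" y="%s" font-size="%.0f" ',
                     'text-anchor="middle">%s%d</text>'),
              px(g$x[r]), py(as.numeric(g$y[r]) - 0.35), scale * 0.25,
              g$aa[r], g$resseq[r]))
  }
  writeLines(c(out, "</svg>"), path)
  invisible(path)
}
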