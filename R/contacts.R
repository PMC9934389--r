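#' Atomic contacts from a Delaunay tessellation
#'
#' Two heavy atoms are in contact when they are Delaunay neighbours (their
#' Voronoi cells share a facet) and their distance is within `cutoff`. The
#' distance filter removes the spurious long edges a convex-hull tessellation
#' creates at the molecular surface. Coplanar/cospherical degeneracies are
#' broken by a deterministic 1e-6 Angstrom jitter (fixed seed), so results
#' are reproducible run to run.
#'
#' @param structure a `ks_structure`.
#' @param cutoff distance cutoff in Angstrom (default 6.0).
#' @return data.frame of contacts: atom row indices `a1`, `a2` (into
#'   `structure$atoms`, a1 < a2), `dist`, residue ordinals `r1`, `r2`, and
#'   `same_res`. Attribute `cutoff` records the parameter.
#' @export
atomic_contacts <- function(structure, cutoff = 6.0) {
  stopifnot(inherits(structure, "ks_structure"), cutoff > 0)
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  edges <- .delaunay_edges_cpp(xyz)
  if (nrow(edges)) {
    d <- sqrt(rowSums((xyz[edges[, 1], , drop = FALSE] -
                         xyz[edges[, 2], , drop = FALSE])^2))
    keep <- d <= cutoff
    edges <- edges[keep, , drop = FALSE]
    d <- d[keep]
  } else d <- numeric()
  out <- data.frame(a1 = edges[, 1], a2 = edges[, 2], dist = d,
                    r1 = a$res_ord[edges[, 1]], r2 = a$res_ord[edges[, 2]])
  out$same_res <- out$r1 == out$r2
  attr(out, "cutoff") <- cutoff
  out
}

#' Lift atomic contacts to a typed residue contact graph
#'
#' Residues are connected when at least one inter-residue atomic contact
#' joins them. Each edge records which of the three packing classes its
#' supporting atomic contacts fall into: main-chain/main-chain (`mm`),
#' main-chain/side-chain (`ms`), side-chain/side-chain (`ss`). Backbone atoms
#' are N, CA, C, O (and OXT); everything else is side chain, and glycine's CA
#' counts as its side chain for classing. Sequence-adjacent pairs (peptide
#' bond neighbours) are kept but flagged so knob detection can exclude them.
#'
#' @param contacts output of [atomic_contacts()].
#' @param structure the same `ks_structure`.
#' @return An object of class `ks_contact_graph`: list with `edges`
#'   (data.frame `i`, `j` residue ordinals i < j, logical `mm`/`ms`/`ss`,
#'   `n_atomic`, `adjacent`), `n_res`, and `cutoff`.
#' @export
residue_contact_graph <- function(contacts, structure) {
  stopifnot(inherits(structure, "ks_structure"))
  a <- structure$atoms
  res <- structure$residues
  cc <- contacts[!contacts$same_res, , drop = FALSE]
  lo <- pmin(cc$r1, cc$r2)
  hi <- pmax(cc$r1, cc$r2)
  side1 <- a$class_side[cc$a1]
  side2 <- a$class_side[cc$a2]
  cls <- ifelse(!side1 & !side2, "mm", ifelse(side1 & side2, "ss", "ms"))
  key <- paste(lo, hi, sep = "_")
  uk <- unique(key)
  idx <- match(key, uk)
  edges <- data.frame(
    i = lo[!duplicated(key)], j = hi[!duplicated(key)],
    mm = as.logical(tapply(cls == "mm", idx, any)[as.character(seq_along(uk))]),
    ms = as.logical(tapply(cls == "ms", idx, any)[as.character(seq_along(uk))]),
    ss = as.logical(tapply(cls == "ss", idx, any)[as.character(seq_along(uk))]),
    n_atomic = as.integer(tapply(key, idx, length)[as.character(seq_along(uk))])
  )
  if (nrow(edges) == 0L)
    edges <- data.frame(i = integer(), j = integer(), mm = logical(),
                        ms = logical(), ss = logical(), n_atomic = integer(),
                        adjacent = logical())
  else {
    same_chain <- res$chain[edges$i] == res$chain[edges$j]
    edges$adjacent <- same_chain &
      abs(res$chain_ord[edges$i] - res$chain_ord[edges$j]) == 1L
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges, n_res = nrow(res),
                 cutoff = attr(contacts, "cutoff")),
            class = "ks_contact_graph")
}

#' Test whether a residue pair is an edge of the contact graph
#' @param graph a `ks_contact_graph`.
#' @param i,j residue ordinals.
#' @param require_ss if TRUE, only count edges with a side-chain/side-chain
#'   contact class.
#' @return logical
#' @keywords internal
has_edge <- function(graph, i, j, require_ss = FALSE) {
  e <- graph$edges
  lo <- pmin(i, j); hi <- pmax(i, j)
  hit <- e$i == lo & e$j == hi
  if (require_ss) hit <- hit & e$ss
  any(hit)
}

#' Enumerate residue cliques of size 3 or 4
#'
#' Returns every complete subgraph of exactly the requested size in the
#' residue contact graph (embedded cliques included, not only maximal ones),
#' each reported once as a sorted residue set.
#'
#' @param graph a `ks_contact_graph`.
#' @param size 3 or 4.
#' @return integer matrix with `size` columns, one clique per row, rows and
#'   columns sorted ascending.
#' @export
enumerate_cliques <- function(graph, size) {
  stopifnot(inherits(graph, "ks_contact_graph"), size %in% c(3L, 4L))
  e <- graph$edges
  if (nrow(e) == 0L) return(matrix(integer(), 0, size))
  g <- igraph::graph_from_edgelist(cbind(e$i, e$j), directed = FALSE)
  cl <- igraph::cliques(g, min = size, max = size)
  if (!length(cl)) return(matrix(integer(), 0, size))
  m <- t(vapply(cl, function(v) sort(as.integer(v)), integer(size)))
  m <- m[do.call(order, as.data.frame(m)), , drop = FALSE]
  dimnames(m) <- NULL
  m
}

#' Write residue contact edges as TSV
#' @param graph a `ks_contact_graph`.
#' @param structure the `ks_structure` it was built from.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_contact_tsv <- function(graph, structure, path) {
  res <- structure$residues
  e <- graph$edges
  out <- data.frame(
    chain = res$chain[e$i], resseq = res$resseq[e$i], aa = res$aa1[e$i],
    partner_chain = res$chain[e$j], partner_resseq = res$resseq[e$j],
    partner_aa = res$aa1[e$j],
    classes = paste0(ifelse(e$mm, "M", ""), ifelse(e$ms, "X", ""),
                     ifelse(e$ss, "S", "")),
    n_atomic = e$n_atomic, adjacent = e$adjacent)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
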