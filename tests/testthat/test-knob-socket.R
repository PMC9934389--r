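# knob_socket: socket classification, knob detection, pockets, labels, lattice

# brute-force socket oracle: test every (i,i+1,i+4) and (i,i+3,i+4) triple on
# a chain directly against the definitions (O...N distance, ss edge, helix
# span), independently of the clique route
socket_oracle <- function(s, graph, helices, hb_cut = 3.5) {
  res <- s$residues
  a <- s$atoms
  dist_ON <- function(i, j) {
    O <- a[a$res_ord == i & a$atom == "O", c("x", "y", "z")]
    N <- a[a$res_ord == j & a$atom == "N", c("x", "y", "z")]
    if (!nrow(O) || !nrow(N)) return(Inf)
    sqrt(sum((unlist(O) - unlist(N))^2))
  }
  e <- graph$edges
  has <- function(i, j, ss = FALSE) {
    hit <- e$i == min(i, j) & e$j == max(i, j)
    if (ss) hit <- hit & e$ss
    any(hit)
  }
  out <- character()
  for (ch in unique(res$chain)) {
    r <- res[res$chain == ch, ]
    for (k in seq_len(nrow(r))) {
      i <- r$res_ord[k]
      if (k + 4 > nrow(r)) next
      i1 <- r$res_ord[k + 1]; i3 <- r$res_ord[k + 3]; i4 <- r$res_ord[k + 4]
      if (dist_ON(i, i4) > hb_cut) next
      hx <- helices[helices$chain == ch, ]
      hostok <- function(tri) {
        co <- res$chain_ord[tri]
        any(vapply(seq_len(nrow(hx)), function(q)
          all(co >= hx$start_ord[q] - 1 & co <= hx$end_ord[q] + 1) &&
            sum(co >= hx$start_ord[q] & co <= hx$end_ord[q]) >= 2,
          logical(1)))
      }
      # XY:H on (i, i+1, i+4): full clique + ss edge between Y=i1 and H=i4
      if (has(i, i1) && has(i, i4) && has(i1, i4, ss = TRUE) &&
            hostok(c(i, i1, i4)))
        out <- c(out, paste("XY:H", i, i1, i4))
      # H:YX on (i, i+3, i+4): Y=i3, H=i
      if (has(i3, i4) && has(i, i4) && has(i, i3, ss = TRUE) &&
            hostok(c(i, i3, i4)))
        out <- c(out, paste("H:YX", i, i3, i4))
    }
  }
  sort(out)
}

test_that("socket classification matches the brute-force oracle on fixtures", {
  for (world in list(helix12()[c("s", "hb", "hel")],
                     list(s = two_helix()$res$structure,
                          hb = two_helix()$res$hbonds,
                          hel = two_helix()$res$helices))) {
    g <- residue_contact_graph(atomic_contacts(world$s), world$s)
    c3 <- enumerate_cliques(g, 3L)
    got <- classify_sockets(c3, world$hel, world$hb, g, world$s)
    want <- socket_oracle(world$s, g, world$hel)
    expect_setequal(paste(got$orientation, got$m1, got$m2, got$m3), want)
  }
})

test_that("socket roles and orientations follow the sequence patterns", {
  w <- helix12()
  g <- residue_contact_graph(atomic_contacts(w$s), w$s)
  s <- classify_sockets(enumerate_cliques(g, 3L), w$hel, w$hb, g, w$s)
  xyh <- s[s$orientation == "XY:H", ]
  expect_true(all(xyh$y_ord == xyh$x_ord + 1 & xyh$h_ord == xyh$x_ord + 4))
  hyx <- s[s$orientation == "H:YX", ]
  expect_true(all(hyx$y_ord == hyx$h_ord + 3 & hyx$x_ord == hyx$h_ord + 4))
  # lowest-sequence member is X in XY:H, H in H:YX; |seq(Y)-seq(H)| = 3 always
  expect_true(all(abs(s$y_ord - s$h_ord) == 3))
  # an ideal 12-mer tiles completely: i = 1..8 in both orientations
  expect_equal(sort(xyh$x_ord), 1:8)
  expect_equal(sort(hyx$h_ord), 1:8)
})

test_that("three residues from three different helices never form a socket", {
  res <- groove()$res
  s <- res$sockets
  # every socket lies on a single chain and a single host helix
  rr <- res$structure$residues
  expect_true(all(rr$chain[s$m1] == rr$chain[s$m3]))
  expect_true(nrow(s) > 0)
})

test_that("knobs must come from outside the socket's helix", {
  res <- two_helix()$res
  ks <- res$knob_sockets
  rr <- res$structure$residues
  hel <- res$helices
  for (r in seq_len(nrow(ks))) {
    if (ks$knob_chain[r] != ks$chain[r]) next
    hx <- hel[paste(hel$chain, hel$label, sep = ":") == ks$helix[r], ]
    bco <- rr$chain_ord[ks$knob_ord[r]]
    expect_false(bco >= hx$start_ord && bco <= hx$end_ord)
  }
  # every knob-socket's 4 residues form a 4-clique in the graph
  key4 <- apply(enumerate_cliques(res$graph, 4L), 1, paste, collapse = "_")
  quad <- apply(cbind(ks$m1, ks$m2, ks$m3, ks$knob_ord), 1,
                function(v) paste(sort(v), collapse = "_"))
  expect_true(all(quad %in% key4))
})

test_that("pocket merging reproduces the two-contiguous-sockets rule", {
  # synthetic knob-socket table: knob 99 fills sockets {4,7,8} and {7,8,11}
  ks <- data.frame(
    socket_id = c(1L, 2L, 3L),
    x_ord = c(8L, 7L, 30L), y_ord = c(7L, 8L, 31L), h_ord = c(4L, 11L, 34L),
    orientation = c("H:YX", "XY:H", "XY:H"),
    chain = "A", helix = "A:H1",
    m1 = c(4L, 7L, 30L), m2 = c(7L, 8L, 31L), m3 = c(8L, 11L, 34L),
    knob_ord = c(99L, 99L, 77L), knob_chain = "B",
    stringsAsFactors = FALSE)
  out <- merge_pockets(ks, NULL)
  expect_equal(nrow(out$pockets), 1L)
  expect_equal(unlist(out$pockets[1, c("m1", "m2", "m3", "m4")],
                      use.names = FALSE), c(4L, 7L, 8L, 11L))
  expect_equal(out$pockets$knob_ord, 99L)
  expect_equal(sort(unlist(out$pockets[1, c("h1_ord", "h2_ord")],
                           use.names = FALSE)), c(4L, 11L))
  # the unmerged knob-socket passes through unchanged
  expect_equal(out$singles$socket_id, 3L)
  # knobs each filling a single socket produce no pockets
  out2 <- merge_pockets(ks[c(1, 3), ], NULL)
  expect_equal(nrow(out2$pockets), 0L)
  expect_equal(nrow(out2$singles), 2L)
})

test_that("pocket merging is order independent and handles triple fills", {
  res <- two_helix()$res
  base <- merge_pockets(res$knob_sockets, res$structure)
  for (seed in 1:5) {
    set.seed(seed)
    perm <- res$knob_sockets[sample(nrow(res$knob_sockets)), ]
    out <- merge_pockets(perm, res$structure)
    expect_equal(out$pockets, base$pockets)
    expect_setequal(unname(apply(out$singles, 1, paste, collapse = "|")),
                    unname(apply(base$singles, 1, paste, collapse = "|")))
  }
  # a knob filling three contiguous sockets yields two pockets and a message
  ks3 <- data.frame(
    socket_id = 1:3,
    x_ord = c(8L, 7L, 12L), y_ord = c(7L, 8L, 11L), h_ord = c(4L, 11L, 8L),
    orientation = c("H:YX", "XY:H", "H:YX"),
    chain = "A", helix = "A:H1",
    m1 = c(4L, 7L, 8L), m2 = c(7L, 8L, 11L), m3 = c(8L, 11L, 12L),
    knob_ord = 99L, knob_chain = "B", stringsAsFactors = FALSE)
  expect_message(out3 <- merge_pockets(ks3, NULL), "contiguous")
  expect_equal(nrow(out3$pockets), 2L)
})

test_that("motif labels follow the colon notation in both orientations", {
  expect_equal(motif_label(c("V", "M", "V"), c(FALSE, FALSE, TRUE)), "VM:V")
  expect_equal(motif_label(c("A", "A", "A"), c(TRUE, FALSE, FALSE)), "A:AA")
  expect_equal(motif_label(c("S", "R", "V", "H"),
                           c(TRUE, FALSE, FALSE, TRUE)), "S:RV:H")
  expect_equal(motif_label(c("R", "T", "L", "F"),
                           c(TRUE, FALSE, FALSE, TRUE)), "R:TL:F")
})

test_that("socket and pocket labels round-trip through the parser", {
  res <- two_helix()$res
  for (r in seq_len(nrow(res$sockets))) {
    lab <- socket_label(res$sockets[r, ], res$structure)
    p <- parse_motif_label(lab)
    m <- unlist(res$sockets[r, c("m1", "m2", "m3")], use.names = FALSE)
    expect_equal(p$aa, res$structure$residues$aa1[m])
    expect_equal(which(p$hmark),
                 which(m == res$sockets$h_ord[r]))
    expect_equal(motif_label(p$aa, p$hmark), lab)
  }
  pk <- res$motifs$pockets
  for (r in seq_len(nrow(pk))) {
    lab <- pocket_label(pk[r, ], res$structure)
    p <- parse_motif_label(lab)
    expect_equal(motif_label(p$aa, p$hmark), lab)
  }
})

test_that("lattice maps place each helix residue once with adjacent cells", {
  res <- groove()$res
  hel <- res$helices
  for (k in seq_len(nrow(hel))) {
    lm <- build_lattice_map(hel[k, ], res$sockets, res$knob_sockets,
                            res$structure, hel)
    span <- hel$end_ord[k] - hel$start_ord[k] + 1L
    expect_equal(nrow(lm$residues), span)
    expect_equal(anyDuplicated(lm$residues$res_ord), 0L)
    # members of every cell are grid-adjacent under the helical-net layout
    for (cell in lm$cells$members) {
      m <- as.integer(strsplit(cell, ",")[[1]])
      gi <- match(m, lm$residues$res_ord)
      gi <- gi[!is.na(gi)]
      if (length(gi) < 2) next
      dx <- max(lm$residues$x[gi]) - min(lm$residues$x[gi])
      dy <- max(lm$residues$y[gi]) - min(lm$residues$y[gi])
      expect_lte(dx, 4); expect_lte(dy, 1)
    }
  }
})

test_that("lattice map is deterministic and serialises to JSON and SVG", {
  res <- two_helix()$res
  hel <- res$helices[res$helices$chain == "B", ]
  lm1 <- build_lattice_map(hel[1, ], res$sockets, res$knob_sockets,
                           res$structure, res$helices)
  lm2 <- build_lattice_map(hel[1, ], res$sockets, res$knob_sockets,
                           res$structure, res$helices)
  expect_identical(lm1, lm2)
  # knob origin tags name the helix of origin on the partner chain
  expect_true(all(grepl("^A:", lm1$knobs$origin)))
  jf <- withr::local_tempfile(fileext = ".json")
  sf <- withr::local_tempfile(fileext = ".svg")
  write_lattice_json(lm1, jf)
  write_lattice_svg(lm1, sf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(length(parsed$residues), nrow(lm1$residues))
  svg <- readLines(sf)
  expect_true(grepl("<svg", svg[1]))
  expect_equal(sum(grepl("<polygon", svg)), nrow(lm1$cells))
})

test_that("bare lattice of a helix with no motifs has residues only", {
  w <- helix12()
  lm <- build_lattice_map(w$hel[1, ],
                          classify_sockets(matrix(integer(), 0, 3), w$hel,
                                           w$hb, NULL, w$s)[0, ],
                          two_helix()$res$knob_sockets[0, ], w$s, w$hel)
  expect_equal(nrow(lm$cells), 0L)
  expect_equal(nrow(lm$knobs), 0L)
  expect_equal(nrow(lm$residues), 12L)
})
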