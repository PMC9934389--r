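# Shared fixtures (built once per test run) and independent oracles.

.fx_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx_env[[name]])) .fx_env[[name]] <- build()
  .fx_env[[name]]
}

helix12 <- function() fixture("helix12", function() {
  s <- make_ideal_helix(strrep("A", 12))
  hb <- detect_backbone_hbonds(s)
  list(s = s, hb = hb, hel = assign_helices(s, hb))
})

two_helix <- function() fixture("two_helix", function() {
  fx <- make_packing_fixture(two_helix_spec())
  res <- analyze_complex(fx$structure, "A", "B")
  list(fx = fx, res = res)
})

groove <- function() fixture("groove", function() {
  fx <- make_packing_fixture(groove_spec())
  res <- analyze_complex(fx$structure, "A", "B")
  list(fx = fx, res = res)
})

# random rigid-body transform (proper rotation + translation)
random_rigid <- function(seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = runif(3, -50, 50))
}

transform_structure <- function(s, rigid) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(rigid$R)
  s$atoms$x <- xyz[, 1] + rigid$t[1]
  s$atoms$y <- xyz[, 2] + rigid$t[2]
  s$atoms$z <- xyz[, 3] + rigid$t[3]
  s
}

# random single-atom-per-residue point cloud as a structure, for contact tests
cloud_structure <- function(n, seed, box = 20) {
  set.seed(seed)
  atoms <- data.frame(
    chain = "A", resseq = seq_len(n), icode = "", resname = "ALA",
    atom = "CA", element = "C", altloc = "", occ = 1,
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    stringsAsFactors = FALSE)
  knobsocket:::new_structure(atoms, id = sprintf("cloud%d", seed))
}

# O(n^5) pure-R Delaunay oracle: an edge is Delaunay iff some tetrahedron on
# it has an empty circumsphere (checked via explicit circumcentres). Tiny n
# only.
delaunay_edges_bruteforce <- function(xyz) {
  n <- nrow(xyz)
  edges <- matrix(integer(), 0, 2)
  for (tet in utils::combn(n, 4, simplify = FALSE)) {
    p <- xyz[tet, , drop = FALSE]
    A <- 2 * sweep(p[2:4, , drop = FALSE], 2, p[1, ])
    if (abs(det(A)) < 1e-9) next  # degenerate (coplanar) tetra
    b <- rowSums(p[2:4, , drop = FALSE]^2) - sum(p[1, ]^2)
    centre <- solve(A, b)
    r2 <- sum((centre - p[1, ])^2)
    others <- xyz[-tet, , drop = FALSE]
    d2 <- rowSums(sweep(others, 2, centre)^2)
    if (all(d2 >= r2 * (1 - 1e-9)))
      edges <- rbind(edges, t(utils::combn(tet, 2)))
  }
  unique(as.data.frame(edges))
}

# scipy.spatial.Delaunay as independent reference for larger clouds
scipy_delaunay_edges <- function(xyz) {
  fin <- tempfile(fileext = ".txt"); fout <- tempfile(fileext = ".txt")
  utils::write.table(xyz, fin, row.names = FALSE, col.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "from scipy.spatial import Delaunay",
    sprintf("pts = np.loadtxt(%s)", deparse(fin)),
    "tri = Delaunay(pts)",
    "es = set()",
    "for s in tri.simplices:",
    "    for i in range(4):",
    "        for j in range(i+1, 4):",
    "            a, b = sorted((int(s[i])+1, int(s[j])+1))",
    "            es.add((a, b))",
    sprintf("with open(%s, 'w') as f:", deparse(fout)),
    "    for a, b in sorted(es):",
    "        f.write(f'{a} {b}\\n')"), script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("python/scipy oracle unavailable")
  utils::read.table(fout, col.names = c("a", "b"))
}

# canonical sorted edge-string representation for set comparisons
edge_key <- function(a, b) {
  sort(paste(pmin(a, b), pmax(a, b)))
}

sorted_truth <- function(truth) {
  truth <- truth[order(truth$direction, truth$helix, truth$member_resseq,
                       truth$knob_resseq), , drop = FALSE]
  rownames(truth) <- NULL
  truth
}

# local PDB cache for the network-dependent acceptance criteria: tests look
# here first and only then try the network
acceptance_cache <- function() {
  testthat::test_path("pdb_cache")
}
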