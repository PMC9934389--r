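#' Build a structure object from an atom table
#'
#' Internal constructor shared by the PDB reader and the synthetic-structure
#' generators. Filters to heavy protein atoms, resolves alternate locations
#' (highest occupancy wins, ties broken toward altloc "A"), indexes residues,
#' and flags residues with an incomplete backbone (missing any of N, CA, C, O).
#'
#' @param atoms data.frame with columns chain, resseq, icode, resname, atom,
#'   element, altloc, occ, x, y, z (one row per atom).
#' @param id source identifier (PDB ID or fixture name).
#' @param model model index the atoms came from.
#' @return An object of class `ks_structure`: a list with `id`, `model`,
#'   `atoms` (with `res_ord` linking into `residues`) and `residues`
#'   (`res_ord`, `chain`, `resseq`, `icode`, `resname`, `aa1`, `chain_ord`,
#'   `complete`).
#' @keywords internal
new_structure <- function(atoms, id = "structure", model = 1L) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resseq", "icode", "resname", "atom", "element",
            "altloc", "occ", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")

  # drop hydrogens/deuteriums and waters
  el <- toupper(trimws(atoms$element))
  guess <- toupper(substr(gsub("[^A-Za-z].*$", "",
                               sub("^[0-9]*", "", atoms$atom)), 1, 1))
  el[el == ""] <- guess[el == ""]
  atoms <- atoms[!(el %in% c("H", "D")) & !(atoms$resname %in% c("HOH", "DOD", "WAT")), ,
                 drop = FALSE]
  if (nrow(atoms) == 0L) stop("structure '", id, "' has no heavy protein atoms")

  # altloc resolution: per (chain, residue, atom name) keep highest occupancy,
  # ties toward 'A' (blank altloc sorts first and always wins alone)
  orig <- seq_len(nrow(atoms))
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$atom, sep = "\r")
  ord <- order(key, -atoms$occ, atoms$altloc)
  keep <- ord[!duplicated(key[ord])]
  atoms <- atoms[sort(keep), , drop = FALSE]

  # residue order = order of first appearance in the input
  rkey <- paste(atoms$chain, atoms$resseq, atoms$icode, sep = "\r")
  res_rank <- match(rkey, unique(rkey))
  atoms <- atoms[order(res_rank, atoms$atom), , drop = FALSE]
  rownames(atoms) <- NULL

  rkey <- paste(atoms$chain, atoms$resseq, atoms$icode, sep = "\r")
  atoms$res_ord <- match(rkey, unique(rkey))
  idx <- !duplicated(rkey)
  residues <- data.frame(
    res_ord = atoms$res_ord[idx],
    chain   = atoms$chain[idx],
    resseq  = atoms$resseq[idx],
    icode   = atoms$icode[idx],
    resname = atoms$resname[idx],
    stringsAsFactors = FALSE
  )
  residues$aa1 <- unname(AA3TO1[residues$resname])
  residues$aa1[is.na(residues$aa1)] <- "X"
  residues$chain_ord <- stats::ave(seq_len(nrow(residues)), residues$chain,
                                   FUN = seq_along)
  bb <- vapply(split(atoms$atom, atoms$res_ord),
               function(a) all(c("N", "CA", "C", "O") %in% a), logical(1))
  residues$complete <- unname(bb[as.character(residues$res_ord)])

  atoms$is_backbone <- atoms$atom %in% BACKBONE_ATOMS
  # Gly has no side chain; its CA stands in for one when classifying packing
  atoms$class_side <- !atoms$is_backbone |
    (atoms$resname == "GLY" & atoms$atom == "CA")

  structure(list(id = id, model = as.integer(model),
                 atoms = atoms, residues = residues),
            class = "ks_structure")
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (HETATM, waters and hydrogens are ignored), selects one
#' model from multi-model (NMR) entries, and resolves alternate locations by
#' highest occupancy.
#'
#' @param path path to a PDB-format file.
#' @param model_index which MODEL to use (default 1, the first deposited
#'   model). Files without MODEL records are treated as a single model 1.
#' @return A `ks_structure` (see [new_structure()]).
#' @export
#' @examples
#' h <- make_ideal_helix("ALAVALLEU")
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(h, f)
#' s <- read_structure(f)
#' nrow(s$residues)
read_structure <- function(path, model_index = 1L) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts)) {
    model_ids <- suppressWarnings(as.integer(substr(lines[model_starts], 11, 14)))
    model_ids[is.na(model_ids)] <- seq_along(model_starts)
    hit <- which(model_ids == model_index)
    if (!length(hit))
      stop("model ", model_index, " not present in ", path,
           "; available models: ", paste(model_ids, collapse = ", "))
    start <- model_starts[hit[1]]
    ends <- which(rec == "ENDMDL")
    end <- ends[ends > start]
    end <- if (length(end)) end[1] else length(lines)
    lines <- lines[start:end]
    rec <- substr(lines, 1, 6)
  } else if (model_index != 1L) {
    stop("model ", model_index, " not present in ", path,
         "; file has a single unnumbered model")
  }
  at <- lines[rec == "ATOM  "]
  if (!length(at)) stop("no ATOM records in ", path)
  xyz <- suppressWarnings(cbind(as.numeric(substr(at, 31, 38)),
                                as.numeric(substr(at, 39, 46)),
                                as.numeric(substr(at, 47, 54))))
  bad <- which(!stats::complete.cases(xyz))
  if (length(bad))
    stop("unparseable ATOM coordinates in ", path, " at record ", bad[1],
         ": ", at[bad[1]])
  occ <- suppressWarnings(as.numeric(substr(at, 55, 60)))
  occ[is.na(occ)] <- 1
  atoms <- data.frame(
    chain   = substr(at, 22, 22),
    resseq  = suppressWarnings(as.integer(substr(at, 23, 26))),
    icode   = trimws(substr(at, 27, 27)),
    resname = trimws(substr(at, 18, 20)),
    atom    = trimws(substr(at, 13, 16)),
    element = trimws(substr(at, 77, 78)),
    altloc  = trimws(substr(at, 17, 17)),
    occ     = occ,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$resseq)) stop("unparseable residue number in ", path)
  id <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  new_structure(atoms, id = id, model = model_index)
}

#' Write a structure as PDB ATOM records
#'
#' Emits standard fixed-width ATOM records with TER records between chains,
#' so the file round-trips through [read_structure()] at PDB coordinate
#' precision (1e-3 Angstrom).
#'
#' @param structure a `ks_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "ks_structure"))
  a <- structure$atoms
  if (nrow(a) == 0L) stop("refusing to write an empty structure")
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (ch in unique(a$chain)) {
    rows <- which(a$chain == ch)
    for (r in rows) {
      serial <- serial + 1L
      name <- a$atom[r]
      # atom name column rules: element right-justified in cols 13-14
      name_f <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
      writeLines(sprintf(
        "ATOM  %5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, name_f, substr(paste0(a$altloc[r], " "), 1, 1),
        a$resname[r], ch, a$resseq[r] %% 10000L,
        substr(paste0(a$icode[r], " "), 1, 1),
        a$x[r], a$y[r], a$z[r], a$occ[r], 0,
        toupper(a$element[r])), con)
    }
    serial <- serial + 1L
    last <- rows[length(rows)]
    writeLines(sprintf("TER   %5d      %-3s %1s%4d%1s",
                       serial %% 100000L, a$resname[last], ch,
                       a$resseq[last] %% 10000L,
                       substr(paste0(a$icode[last], " "), 1, 1)), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Detect backbone hydrogen bonds by a donor-acceptor distance criterion
#'
#' A bond is recorded between the carbonyl O of an acceptor residue and the
#' amide N of a donor residue whenever the O...N distance is within the
#' cutoff. This distance-only criterion (DSSP-lite) is what the helix
#' annotation consumes; the i to i+4 pattern is not imposed here.
#'
#' @param structure a `ks_structure`.
#' @param max_ON O...N distance cutoff in Angstrom (default 3.5).
#' @return data.frame with `acceptor` and `donor` residue ordinals (`res_ord`)
#'   and `dist` (Angstrom). Self pairs are excluded.
#' @export
detect_backbone_hbonds <- function(structure, max_ON = 3.5) {
  stopifnot(inherits(structure, "ks_structure"), max_ON > 0)
  a <- structure$atoms
  O <- a[a$atom == "O", c("res_ord", "x", "y", "z")]
  N <- a[a$atom == "N", c("res_ord", "x", "y", "z")]
  if (nrow(O) == 0L || nrow(N) == 0L)
    return(data.frame(acceptor = integer(), donor = integer(),
                      dist = numeric()))
  d2 <- outer(O$x, N$x, "-")^2 + outer(O$y, N$y, "-")^2 +
    outer(O$z, N$z, "-")^2
  hit <- which(d2 <= max_ON^2, arr.ind = TRUE)
  out <- data.frame(acceptor = O$res_ord[hit[, 1]],
                    donor    = N$res_ord[hit[, 2]],
                    dist     = sqrt(d2[hit]))
  out <- out[out$acceptor != out$donor, , drop = FALSE]
  out <- out[order(out$acceptor, out$donor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate alpha helices from i to i+4 backbone hydrogen bonds
#'
#' A helix is a maximal run of consecutive residues i whose carbonyl O is
#' hydrogen-bonded to the amide N of residue i+4 on the same chain, extended
#' to include both endpoint residues of every supporting bond. Runs shorter
#' than `min_length` residues are discarded; residues with incomplete
#' backbones never support a helical bond.
#'
#' @param structure a `ks_structure`.
#' @param hbonds output of [detect_backbone_hbonds()] on the same structure.
#' @param min_length minimum helix length in residues (default 5, the span of
#'   one i..i+4 socket).
#' @return data.frame with one row per helix: `chain`, `label` (H1..Hn per
#'   chain in sequence order), `start_ord`/`end_ord` (chain ordinals),
#'   `start_res`/`end_res` (global `res_ord`), `length`.
#' @export
assign_helices <- function(structure, hbonds, min_length = 5L) {
  stopifnot(inherits(structure, "ks_structure"))
  res <- structure$residues
  out <- list()
  for (ch in unique(res$chain)) {
    r <- res[res$chain == ch, , drop = FALSE]
    n <- nrow(r)
    supported <- logical(n)  # indexed by chain_ord of the acceptor
    if (nrow(hbonds)) {
      acc <- match(hbonds$acceptor, res$res_ord)
      don <- match(hbonds$donor, res$res_ord)
      same <- res$chain[acc] == ch & res$chain[don] == ch
      i <- res$chain_ord[acc[same]]
      j <- res$chain_ord[don[same]]
      for (k in seq_along(i)) {
        if (j[k] - i[k] == 4L) {
          span <- i[k]:j[k]
          if (all(r$complete[span])) supported[i[k]] <- TRUE
        }
      }
    }
    runs <- rle(supported)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    hn <- 0L
    for (k in seq_along(runs$values)) {
      if (!runs$values[k]) next
      s <- starts[k]; e <- ends[k] + 4L
      if (e - s + 1L < min_length) next
      hn <- hn + 1L
      out[[length(out) + 1L]] <- data.frame(
        chain = ch, label = paste0("H", hn),
        start_ord = s, end_ord = e,
        start_res = r$res_ord[s], end_res = r$res_ord[e],
        length = e - s + 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chain = character(), label = character(),
                      start_ord = integer(), end_ord = integer(),
                      start_res = integer(), end_res = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Summarise a structure's chains, helices and coil segments
#'
#' @param structure a `ks_structure`.
#' @param helices output of [assign_helices()].
#' @return data.frame with one row per helix or coil segment: `chain`,
#'   `label` (Hi, or Ci-j for the coil between Hi and Hj, C0-1 / Cn- at the
#'   termini), residue spans and the one-letter sequence.
#' @export
structure_summary <- function(structure, helices) {
  res <- structure$residues
  out <- list()
  for (ch in unique(res$chain)) {
    r <- res[res$chain == ch, , drop = FALSE]
    h <- helices[helices$chain == ch, , drop = FALSE]
    h <- h[order(h$start_ord), , drop = FALSE]
    segs <- list()
    pos <- 1L
    for (k in seq_len(nrow(h))) {
      if (h$start_ord[k] > pos) {
        lab <- if (k == 1L) "C0-1" else
          sprintf("C%d-%d", k - 1L, k)
        segs[[length(segs) + 1L]] <- c(lab, pos, h$start_ord[k] - 1L)
      }
      segs[[length(segs) + 1L]] <- c(h$label[k], h$start_ord[k], h$end_ord[k])
      pos <- h$end_ord[k] + 1L
    }
    if (pos <= nrow(r))
      segs[[length(segs) + 1L]] <- c(sprintf("C%d-", nrow(h)), pos, nrow(r))
    for (sg in segs) {
      i <- as.integer(sg[2]); j <- as.integer(sg[3])
      out[[length(out) + 1L]] <- data.frame(
        chain = ch, label = sg[1],
        start_resseq = r$resseq[i], end_resseq = r$resseq[j],
        length = j - i + 1L,
        sequence = paste(r$aa1[i:j], collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chain = character(), label = character(),
                      start_resseq = integer(), end_resseq = integer(),
                      length = integer(), sequence = character()))
  do.call(rbind, out)
}

#' Fetch a PDB entry into a local cache
#'
#' Downloads `<id>.pdb` from RCSB unless already cached. Network access is
#' optional everywhere in the package: all analyses also run on local files
#' or on synthetic fixtures.
#'
#' @param id 4-character PDB ID.
#' @param cache_dir directory for cached files (created if needed).
#' @param quiet passed to [download.file()].
#' @return path to the cached PDB file.
#' @export
fetch_pdb <- function(id, cache_dir = file.path(tempdir(), "pdb_cache"),
                      quiet = TRUE) {
  stopifnot(grepl("^[0-9][a-zA-Z0-9]{3}$", id))
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(cache_dir, paste0(tolower(id), ".pdb"))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
    status <- try(download.file(url, dest, quiet = quiet, mode = "wb"),
                  silent = TRUE)
    if (inherits(status, "try-error") || !file.exists(dest) ||
        file.size(dest) == 0) {
      unlink(dest)
      stop("could not fetch PDB ", id, " (no network?); place ",
           basename(dest), " in ", cache_dir, " manually")
    }
  }
  dest
}
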