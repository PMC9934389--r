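#' Run the full knob-socket analysis of one complex in memory
#'
#' Chains together structure annotation, Delaunay contacts, clique
#' enumeration, socket/knob-socket classification, pocket merging, and
#' interface mapping, with the package defaults for every tunable.
#'
#' @param structure a `ks_structure` (from [read_structure()] or a
#'   generator).
#' @param receptor_chains receptor chain ids.
#' @param ligand_chain ligand chain id.
#' @param contact_cutoff Delaunay contact distance cutoff, Angstrom.
#' @param hbond_cutoff O...N hydrogen-bond cutoff, Angstrom.
#' @param min_helix_length minimum helix length, residues.
#' @return list with every intermediate: `structure`, `hbonds`, `helices`,
#'   `contacts`, `graph`, `cliques3`, `cliques4`, `sockets`,
#'   `knob_sockets`, `motifs`, `interface` (a `ks_interface_map`), and
#'   `params`.
#' @export
analyze_complex <- function(structure, receptor_chains, ligand_chain,
                            contact_cutoff = 6.0, hbond_cutoff = 3.5,
                            min_helix_length = 5L) {
  stopifnot(inherits(structure, "ks_structure"))
  chains <- unique(structure$residues$chain)
  missing <- setdiff(c(receptor_chains, ligand_chain), chains)
  if (length(missing))
    stop("chain assignment mismatch for ", structure$id, ": chain(s) ",
         paste(missing, collapse = ", "), " not in structure (has: ",
         paste(chains, collapse = ", "), ")")
  hbonds <- detect_backbone_hbonds(structure, max_ON = hbond_cutoff)
  helices <- assign_helices(structure, hbonds, min_length = min_helix_length)
  contacts <- atomic_contacts(structure, cutoff = contact_cutoff)
  graph <- residue_contact_graph(contacts, structure)
  cliques3 <- enumerate_cliques(graph, 3L)
  cliques4 <- enumerate_cliques(graph, 4L)
  sockets <- classify_sockets(cliques3, helices, hbonds, graph, structure)
  ks <- find_knob_sockets(cliques4, sockets, helices, structure)
  motifs <- merge_pockets(ks, structure)
  interface <- map_interface(structure, receptor_chains, ligand_chain,
                             motifs, helices)
  list(structure = structure, hbonds = hbonds, helices = helices,
       contacts = contacts, graph = graph, cliques3 = cliques3,
       cliques4 = cliques4, sockets = sockets, knob_sockets = ks,
       motifs = motifs, interface = interface,
       params = list(contact_cutoff = contact_cutoff,
                     hbond_cutoff = hbond_cutoff,
                     min_helix_length = min_helix_length))
}

#' Auto-detect the central (H5-like) receptor helix of an interface
#'
#' Picks the receptor helix whose Gly-containing sockets are packed by a
#' ligand Gly knob; falls back to the helix with the most ligand-packed
#' Gly-containing sockets.
#'
#' @param map a `ks_interface_map`.
#' @return chain-qualified helix label.
#' @export
auto_central_helix <- function(map) {
  lk <- map$lig_knobs
  if (!nrow(lk)) stop("empty interface map ", map$id)
  cand <- lk[grepl("G", lk$member_aa, fixed = TRUE), , drop = FALSE]
  if (!nrow(cand))
    stop("no Gly-containing receptor socket is packed by a ligand knob in ",
         map$id)
  gly <- cand[cand$knob_aa == "G", , drop = FALSE]
  pool <- if (nrow(gly)) gly else cand
  tab <- sort(table(pool$helix), decreasing = TRUE)
  names(tab)[1]
}

#' Run one complex and write its per-complex artifacts
#'
#' Writes, under `outdir/<id>/`: `summary.tsv` (chains/segments),
#' `contacts.tsv`, `motifs.tsv` (one row per interface motif),
#' `interface.json`, and a lattice map (`lattice_<helix>.json` + `.svg`) for
#' every receptor helix that hosts interface sockets. Runs are deterministic:
#' identical inputs give byte-identical outputs.
#'
#' @param structure a `ks_structure` (or a path to a PDB file).
#' @param receptor_chains,ligand_chain chain assignment.
#' @param outdir output directory (created).
#' @param ... parameter overrides passed to [analyze_complex()].
#' @return the [analyze_complex()] result, invisibly extended with
#'   `outputs` (paths written).
#' @export
run_complex <- function(structure, receptor_chains, ligand_chain,
                        outdir, ...) {
  if (is.character(structure)) structure <- read_structure(structure)
  res <- analyze_complex(structure, receptor_chains, ligand_chain, ...)
  dir.create(file.path(outdir, structure$id), showWarnings = FALSE,
             recursive = TRUE)
  base <- file.path(outdir, structure$id)
  paths <- c(summary = file.path(base, "summary.tsv"),
             contacts = file.path(base, "contacts.tsv"),
             motifs = file.path(base, "motifs.tsv"),
             interface = file.path(base, "interface.json"))
  write.table(structure_summary(structure, res$helices), paths["summary"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_contact_tsv(res$graph, structure, paths["contacts"])
  write_interface_map(res$interface, json_path = paths["interface"],
                      tsv_path = paths["motifs"])
  iface_helices <- unique(c(res$interface$lig_knobs$helix))
  for (hl in iface_helices) {
    parts <- strsplit(hl, ":", fixed = TRUE)[[1]]
    hrow <- res$helices[res$helices$chain == parts[1] &
                          res$helices$label == parts[2], , drop = FALSE]
    if (!nrow(hrow)) next
    lm <- build_lattice_map(hrow[1, ], res$sockets, res$knob_sockets,
                            structure, res$helices)
    jp <- file.path(base, sprintf("lattice_%s_%s.json", parts[1], parts[2]))
    sp <- sub("\\.json$", ".svg", jp)
    write_lattice_json(lm, jp)
    write_lattice_svg(lm, sp)
    paths <- c(paths, jp, sp)
  }
  res$outputs <- paths
  invisible(res)
}

#' Aggregate per-complex results into conservation outputs
#'
#' Produces, per receptor paralog, the conserved-groove model and the ligand
#' consensus model, plus an all-complex consensus and per-paralog groove
#' distance tables, and writes them as TSV/JSON/FASTA under `outdir`.
#'
#' @param results named list of [analyze_complex()]/[run_complex()] results
#'   (names = complex ids).
#' @param paralogs character vector, parallel to `results`: receptor paralog
#'   of each complex.
#' @param central_helices chain-qualified central-helix label per complex,
#'   or "auto" to detect (default).
#' @param outdir output directory, or NULL to skip writing.
#' @param mutant logical vector: point mutants are kept in conservation
#'   scoring but dropped from the alignment FASTA displays.
#' @return list with `refs`, `aligned`, `consensus_all`,
#'   `consensus_by_paralog`, `groove_by_paralog`, `distance_by_paralog`.
#' @export
run_aggregate <- function(results, paralogs,
                          central_helices = rep("auto", length(results)),
                          outdir = NULL,
                          mutant = rep(FALSE, length(results))) {
  stopifnot(length(results) >= 1L,
            length(paralogs) == length(results),
            length(central_helices) == length(results))
  maps <- lapply(results, `[[`, "interface")
  refs <- vector("list", length(maps))
  for (k in seq_along(maps)) {
    ch <- central_helices[k]
    if (identical(ch, "auto")) ch <- auto_central_helix(maps[[k]])
    refs[[k]] <- find_central_reference(maps[[k]], ch)
  }
  aligned <- align_ligands(maps, refs)
  consensus_all <- classify_positions(aligned, scope = "all")
  by_par <- split(seq_along(maps), paralogs)
  consensus_by_paralog <- lapply(by_par, function(idx)
    classify_positions(aligned[idx], scope = paralogs[idx[1]]))
  groove_by_paralog <- lapply(by_par, function(idx)
    conserved_groove_model(maps[idx]))
  distance_by_paralog <- lapply(by_par, function(idx) {
    m <- maps[[idx[1]]]
    st <- results[[idx[1]]]$structure
    groove <- groove_by_paralog[[paralogs[idx[1]]]]
    lk <- m$lig_knobs
    key <- paste(lk$member_resseq, lk$member_aa, sep = ":")
    keep <- lk[key %in% groove$socket_key[groove$class == "conserved"], ,
               drop = FALSE]
    if (!nrow(keep)) return(NULL)
    groove_distance_table(keep, st)
  })
  out <- list(refs = refs, aligned = aligned,
              consensus_all = consensus_all,
              consensus_by_paralog = consensus_by_paralog,
              groove_by_paralog = groove_by_paralog,
              distance_by_paralog = distance_by_paralog)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    ref_df <- do.call(rbind, lapply(refs, function(r)
      data.frame(complex = r$complex, resseq = r$knob_resseq,
                 aa = r$knob_aa, substituted = r$substituted,
                 motif = r$motif_label, stringsAsFactors = FALSE)))
    write.table(ref_df, file.path(outdir, "central_references.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_consensus(consensus_all, aligned[!mutant],
                    tsv_path = file.path(outdir, "consensus_all.tsv"),
                    json_path = file.path(outdir, "consensus_all.json"),
                    fasta_path = file.path(outdir, "ligands_all.fasta"))
    for (p in names(consensus_by_paralog)) {
      idx <- by_par[[p]]
      write_consensus(consensus_by_paralog[[p]],
                      aligned[idx][!mutant[idx]],
                      tsv_path = file.path(outdir,
                                           sprintf("consensus_%s.tsv", p)),
                      fasta_path = file.path(outdir,
                                             sprintf("ligands_%s.fasta", p)))
      write.table(groove_by_paralog[[p]],
                  file.path(outdir, sprintf("groove_%s.tsv", p)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      dt <- distance_by_paralog[[p]]
      if (!is.null(dt)) {
        write.table(round(dt$min, 2),
                    file.path(outdir, sprintf("distances_min_%s.tsv", p)),
                    sep = "\t", quote = FALSE, col.names = NA)
        write.table(round(dt$max, 2),
                    file.path(outdir, sprintf("distances_max_%s.tsv", p)),
                    sep = "\t", quote = FALSE, col.names = NA)
      }
    }
  }
  out
}

#' The shipped study configuration: 19 receptor:BH3-ligand co-structures
#'
#' Returns the packaged table of curated complexes (PDB ids, receptor
#' paralog, ligand name, chain assignment, point-mutant flag). Chain
#' assignments follow the usual deposition convention (receptor chain A,
#' ligand peptide chain B) and are user-editable configuration, not data:
#' pass your own table to override.
#'
#' @return data.frame with columns `pdb_id`, `paralog`, `ligand`,
#'   `receptor_chains`, `ligand_chain`, `central_helix`, `mutant`.
#' @export
study_config <- function() {
  path <- system.file("extdata", "bcl2_complexes.tsv",
                      package = "knobsocket")
  cfg <- read.delim(path, stringsAsFactors = FALSE)
  cfg$mutant <- as.logical(cfg$mutant)
  cfg
}

#' Run the whole study pipeline from a configuration table
#'
#' Fetches (or reads from `cache_dir`) every structure in the config, runs
#' [run_complex()] on each, then [run_aggregate()] over the set. Requires the
#' structures to be available locally or the network to reach RCSB.
#'
#' @param config a config table ([study_config()] format).
#' @param cache_dir directory holding `<pdbid>.pdb` files.
#' @param outdir output directory.
#' @param ... parameter overrides for [analyze_complex()].
#' @return the [run_aggregate()] result plus `per_complex`.
#' @export
run_study <- function(config = study_config(),
                      cache_dir = file.path(tempdir(), "pdb_cache"),
                      outdir = tempfile("ks_out"), ...) {
  if (!nrow(config)) stop("empty configuration")
  results <- list()
  for (r in seq_len(nrow(config))) {
    path <- file.path(cache_dir, paste0(tolower(config$pdb_id[r]), ".pdb"))
    if (!file.exists(path)) path <- fetch_pdb(config$pdb_id[r], cache_dir)
    st <- read_structure(path)
    results[[config$pdb_id[r]]] <- run_complex(
      st, strsplit(config$receptor_chains[r], ",")[[1]],
      config$ligand_chain[r], outdir = outdir, ...)
  }
  agg <- run_aggregate(results, config$paralog,
                       central_helices = config$central_helix,
                       outdir = file.path(outdir, "aggregate"),
                       mutant = config$mutant)
  agg$per_complex <- results
  agg
}
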