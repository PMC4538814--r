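# pipeline: run configuration and command-style entry points wiring the
# modules together.  These functions are the package's working surface for
# scripted use; inst/exec/modbp wraps them for the shell.

#' Run configuration
#'
#' Bundles the tunable thresholds of the pipeline.  Serializable to JSON and
#' reloadable (round-trip identity).
#'
#' @param hbond_dist_max,hbond_angle_min H-bond criteria (see
#'   \code{\link{hbond_params}}).
#' @param interplane_max,voffset_max pairing plausibility filters.
#' @param resolution_cutoff structure filter in Angstrom.
#' @param seed integer seed for synthetic generation.
#' @param three_prime 3'-capping rule for fragments.
#' @return a \code{RunConfig} list.
#' @export
run_config <- function(hbond_dist_max = 3.5, hbond_angle_min = 100,
                       interplane_max = 70, voffset_max = 2.5,
                       resolution_cutoff = 3.5, seed = 1,
                       three_prime = "trim") {
  stopifnot(hbond_dist_max > 0, hbond_angle_min > 0, interplane_max > 0,
            voffset_max > 0, resolution_cutoff > 0)
  structure(list(hbond_dist_max = hbond_dist_max,
                 hbond_angle_min = hbond_angle_min,
                 interplane_max = interplane_max, voffset_max = voffset_max,
                 resolution_cutoff = resolution_cutoff, seed = seed,
                 three_prime = three_prime), class = "RunConfig")
}

config_params <- function(config) {
  hbond_params(dist_max = config$hbond_dist_max,
               angle_min = config$hbond_angle_min,
               interplane_max = config$interplane_max,
               voffset_max = config$voffset_max)
}

#' @rdname run_config
#' @param config a \code{RunConfig}.
#' @param path JSON file path.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  save_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Scan one structure file for modified base pairs
#'
#' @param path structure file (PDB or mmCIF).
#' @param out optional TSV output path.
#' @param config a \code{RunConfig}.
#' @return data.frame of per-pair records (invisibly when \code{out} given).
#' @export
cmd_scan <- function(path, out = NULL, config = run_config()) {
  st <- read_structure(path)
  res <- scan_structures(list(st), config_params(config))
  if (!is.null(out)) {
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
    message("wrote ", nrow(res), " pair(s) to ", out, " [config ",
            config_hash(config), "]")
    return(invisible(res))
  }
  res
}

#' Build the atlas from a directory of structure files
#'
#' Applies the resolution filter, annotates every structure, aggregates into
#' atlas entries and computes the census statistics.
#'
#' @param dir directory containing .pdb / .cif files.
#' @param out optional JSON output path.
#' @param config a \code{RunConfig}.
#' @return list(atlas, stats, instances).
#' @export
cmd_atlas <- function(dir, out = NULL, config = run_config()) {
  files <- list.files(dir, pattern = "\\.(pdb|cif)$", full.names = TRUE,
                      ignore.case = TRUE)
  structures <- lapply(files, read_structure)
  structures <- filter_by_resolution(structures, config$resolution_cutoff)
  inst <- scan_structures(structures, config_params(config))
  atlas <- build_atlas(inst)
  res <- list(atlas = atlas, stats = atlas_stats(atlas), instances = inst)
  if (!is.null(out)) {
    jsonlite::write_json(list(atlas = atlas, stats = unclass(res$stats),
                              config_hash = config_hash(config)),
                         out, auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}

#' Build QM model fragments for the pairs of one structure
#'
#' Writes, for every (or one selected) modified pair, the capped fragment and
#' its unmodified counterpart as XYZ files.
#'
#' @param path structure file.
#' @param outdir output directory.
#' @param pair optional 1-based index of the pair to model.
#' @param config a \code{RunConfig}.
#' @return data.frame listing the written files.
#' @export
cmd_model <- function(path, outdir = ".", pair = NULL, config = run_config()) {
  st <- read_structure(path)
  anns <- annotate_structure(st, config_params(config))
  if (!length(anns)) stop("no modified base pairs in ", path)
  idx <- if (is.null(pair)) seq_along(anns) else pair
  rows <- list()
  for (i in idx) {
    frag <- build_pair_model(anns[[i]], st, three_prime = config$three_prime)
    cp <- make_unmodified_counterpart(frag)
    stem <- file.path(outdir, sprintf("pair%02d_%s", i,
                                      gsub("[^A-Za-z0-9]+", "_", anns[[i]]$pair_key)))
    write_xyz(frag, paste0(stem, "_modified.xyz"))
    write_xyz(cp, paste0(stem, "_unmodified.xyz"))
    rows[[length(rows) + 1L]] <- data.frame(
      pair = anns[[i]]$pair_key, modified = paste0(stem, "_modified.xyz"),
      counterpart = paste0(stem, "_unmodified.xyz"), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Interaction/modification-energy report from an energy table
#'
#' The input TSV either carries raw components (columns \code{e_bp},
#' \code{e_b1}, \code{e_b2} and optionally \code{bsse}, in kcal/mol or
#' hartree) or precomputed \code{e_int_modified}/\code{e_int_unmodified}
#' columns; E_int and E_Mod are (re)computed accordingly.
#'
#' @param path TSV file.
#' @param units units of raw components.
#' @return data.frame with the derived energies.
#' @export
cmd_energy <- function(path, units = "kcal/mol") {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("e_bp", "e_b1", "e_b2") %in% names(tb))) {
    bsse <- if ("bsse" %in% names(tb)) tb$bsse else 0
    tb$e_int <- vapply(seq_len(nrow(tb)), function(i)
      interaction_energy(energy_components(tb$e_bp[i], tb$e_b1[i], tb$e_b2[i],
                                           if (length(bsse) > 1) bsse[i] else bsse,
                                           units = units)), 0)
  }
  if (all(c("e_int_modified", "e_int_unmodified") %in% names(tb))) {
    tb$e_mod_recomputed <- modification_energy(tb$e_int_modified, tb$e_int_unmodified)
  }
  tb
}

#' RMSD comparison of two fragment files
#'
#' @param path1,path2 XYZ files with identical atom ordering, or Fragments.
#' @param mode correspondence mode for Fragment inputs.
#' @return RMSD in Angstrom.
#' @export
cmd_compare <- function(path1, path2, mode = "all_heavy") {
  if (inherits(path1, "Fragment")) return(rmsd_pairs(path1, path2, mode))
  f1 <- read_xyz(path1); f2 <- read_xyz(path2)
  h1 <- f1$atoms[f1$atoms$elem != "H", , drop = FALSE]
  h2 <- f2$atoms[f2$atoms$elem != "H", , drop = FALSE]
  if (nrow(h1) != nrow(h2)) {
    stop("fragments differ in heavy-atom count (", nrow(h1), " vs ", nrow(h2),
         "); use Fragment objects for correspondence-based modes")
  }
  best_fit(as.matrix(h1[, c("x", "y", "z")]),
           as.matrix(h2[, c("x", "y", "z")]))$rmsd
}

#' Generate synthetic fixtures
#'
#' @param types named integer vector pair type -> count (default: one of
#'   each atlas type).
#' @param outdir output directory for the PDB files and manifest.
#' @param seed integer seed.
#' @param noise_sigma coordinate noise in Angstrom.
#' @return the manifest data.frame.
#' @export
cmd_synth <- function(types = NULL, outdir = ".", seed = 1, noise_sigma = 0) {
  if (is.null(types)) {
    types <- stats::setNames(rep(1L, length(atlas_recipes())), names(atlas_recipes()))
  }
  gs <- generate_structure_set(types, seed = seed, noise_sigma = noise_sigma)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (st in gs$structures) {
    write_pdb(st, file.path(outdir, paste0(st$id, ".pdb")))
  }
  utils::write.table(gs$manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(gs$manifest)
}

#' Reference tables and recomputed headline statistics
#'
#' Loads the packaged occurrence and energy tables, recomputes the census
#' statistics and the modification energies from the interaction-energy
#' columns, and reports the energy extremes.
#'
#' @return list(atlas, energies, stats, extremes, emod_max_abs_dev).
#' @export
cmd_paper_tables <- function() {
  atlas <- load_paper_atlas()
  en <- load_paper_energies()
  en$e_mod_recomputed <- modification_energy(en$e_int_modified, en$e_int_unmodified)
  dev <- abs(en$e_mod_recomputed - en$e_mod)
  list(atlas = atlas, energies = en, stats = atlas_stats(atlas),
       extremes = energy_extremes(en),
       emod_max_abs_dev = max(dev),
       emod_rows_within_0p01 = sum(dev <= 0.01 + 1e-9))
}
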