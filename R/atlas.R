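# atlas: aggregation of base-pair annotations into unique modified-base-pair
# types with occurrences and best-resolution representatives, plus the
# packaged occurrence (Table-1-style) and energy (Table-2-style) reference
# tables and the census statistics computed from them.

TABLE1_MD5 <- "c32dfeebae75cf27806a2dba57f08171"
TABLE2_MD5 <- "0086f3ed4c70bbfb30b2319cb3043183"

#' Annotate all modified base pairs in one structure
#'
#' Runs H-bond detection, classifies every H-bonded nucleotide pair and keeps
#' the pairs that involve at least one modified base.  Each unordered residue
#' pair is reported once.
#'
#' @param structure a Structure.
#' @param params see \code{\link{hbond_params}}.
#' @param modified_only keep only pairs with a modified base (default TRUE).
#' @return list of \code{BasePairAnnotation}.
#' @export
annotate_structure <- function(structure, params = hbond_params(),
                               modified_only = TRUE) {
  hb <- find_hbonds(structure, params)
  bb <- hb[hb$kind == "base_base", , drop = FALSE]
  if (!nrow(bb)) return(list())
  pairs <- unique(t(apply(cbind(bb$donor_res, bb$acceptor_res), 1, sort)))
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    ann <- classify_pair(structure, pairs[i, 1], pairs[i, 2], hbonds = hb,
                         params = params)
    if (!is_pair(ann)) next
    if (modified_only && !any(ann$modified)) next
    out[[length(out) + 1L]] <- ann
  }
  out
}

#' Scan a list of structures into an instance table
#'
#' @param structures list of Structure objects.
#' @param params see \code{\link{hbond_params}}.
#' @return data.frame with one row per observed modified base pair.
#' @export
scan_structures <- function(structures, params = hbond_params()) {
  rows <- list()
  for (st in structures) {
    for (ann in annotate_structure(st, params)) {
      rows[[length(rows) + 1L]] <- data.frame(
        structure_id = st$id, resolution = st$resolution,
        symbol1 = ann$symbol1, symbol2 = ann$symbol2,
        geometry = ann$geometry, pair_key = ann$pair_key,
        position = paste(sub("^[^|]*\\|", "", sub("\\|$", "", ann$res1)),
                         sub("^[^|]*\\|", "", sub("\\|$", "", ann$res2)), sep = ":"),
        chains = paste(sub("\\|.*", "", ann$res1), sub("\\|.*", "", ann$res2), sep = ":"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(structure_id = character(), resolution = numeric(),
                      symbol1 = character(), symbol2 = character(),
                      geometry = character(), pair_key = character(),
                      position = character(), chains = character()))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

natural_pair <- function(symbol1, symbol2) {
  mapply(function(s1, s2) {
    codes <- c(resolve_code(s1), resolve_code(s2))
    mods <- codes[vapply(codes, is_modified, TRUE)]
    length(mods) > 0 && all(vapply(mods, function(m) residue_spec(m)$natural, TRUE))
  }, symbol1, symbol2, USE.NAMES = FALSE)
}

#' Build the atlas from an instance table
#'
#' Groups instances by (base symbols, geometry), counts occurrences and picks
#' the representative from the best-resolution structure (ties to the
#' lexicographically smallest structure id).
#'
#' @param instances data.frame as produced by \code{\link{scan_structures}}
#'   (or the packaged reference table); must carry \code{resolution}.
#' @return data.frame of atlas entries, one row per unique pair type.
#' @export
build_atlas <- function(instances) {
  if (!nrow(instances)) {
    return(data.frame(key = character(), symbol1 = character(),
                      symbol2 = character(), geometry = character(),
                      natural = logical(), occurrences = integer(),
                      representative = character(), rep_resolution = numeric()))
  }
  key <- paste0(instances$symbol1, ":", instances$symbol2, " ", instances$geometry)
  ord <- order(key, instances$resolution, instances$structure_id)
  inst <- instances[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  entries <- data.frame(
    key = key[first],
    symbol1 = inst$symbol1[first], symbol2 = inst$symbol2[first],
    geometry = inst$geometry[first],
    natural = natural_pair(inst$symbol1[first], inst$symbol2[first]),
    occurrences = as.integer(table(key)[key[first]]),
    representative = inst$structure_id[first],
    rep_resolution = inst$resolution[first],
    stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  entries[order(entries$key), , drop = FALSE]
}

#' Census statistics of an atlas
#'
#' Computes the headline numbers of the reference census: total and natural
#' pair occurrences, the number of (naturally) modified nucleobases involved
#' in pairs (a doubly-modified pair counts twice), per-parent-base pair
#' counts (a doubly-modified pair is attributed to both parents; pseudouridine
#' is kept separate from the other uracil derivatives), and type counts (the
#' trans and strict-cWW counts refer to the natural subset).
#'
#' @param atlas data.frame of atlas entries (see \code{\link{build_atlas}}).
#' @return object of class \code{AtlasStats} (a named list).
#' @export
atlas_stats <- function(atlas) {
  occ <- atlas$occurrences
  nat <- atlas$natural
  parents <- c(A = 0L, G = 0L, C = 0L, U = 0L, Psi = 0L)
  mod_nucleobases <- 0L
  for (i in seq_len(nrow(atlas))) {
    if (!nat[i]) next
    for (s in c(atlas$symbol1[i], atlas$symbol2[i])) {
      code <- resolve_code(s)
      if (!is_modified(code)) next
      mod_nucleobases <- mod_nucleobases + occ[i]
      slot <- if (code == "PSU") "Psi" else parent_of(code)
      parents[slot] <- parents[slot] + occ[i]
    }
  }
  structure(list(
    total_pairs = sum(occ),
    natural_pairs = sum(occ[nat]),
    modified_nucleobases_in_pairs = mod_nucleobases,
    pairs_by_parent = as.list(parents),
    n_types_total = nrow(atlas),
    n_types_natural = sum(nat),
    n_trans_types = sum(nat & startsWith(atlas$geometry, "t")),
    n_cWW_types = sum(nat & atlas$geometry == "cWW")
  ), class = "AtlasStats")
}

#' @export
print.AtlasStats <- function(x, ...) {
  cat("Atlas census:\n",
      sprintf("  %d base-pair occurrences (%d natural)\n",
              x$total_pairs, x$natural_pairs),
      sprintf("  %d naturally modified nucleobases in pairs\n",
              x$modified_nucleobases_in_pairs),
      sprintf("  by parent base: A %d, G %d, C %d, U (non-Psi) %d, Psi %d\n",
              x$pairs_by_parent$A, x$pairs_by_parent$G, x$pairs_by_parent$C,
              x$pairs_by_parent$U, x$pairs_by_parent$Psi),
      sprintf("  %d unique types (%d natural; %d trans, %d strict cWW among natural)\n",
              x$n_types_total, x$n_types_natural, x$n_trans_types, x$n_cWW_types))
  invisible(x)
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "modbp")
}

check_fixture <- function(path, md5) {
  got <- unname(tools::md5sum(path))
  if (!identical(got, md5)) {
    stop("fixture ", basename(path), " is corrupted (checksum mismatch)")
  }
}

#' Load the packaged reference occurrence table
#'
#' The packaged machine-readable copy of the published occurrence atlas:
#' 36 unique modified-base-pair types with geometry strings, occurrence
#' counts, representative structure ids and resolutions.
#'
#' @param as_atlas return atlas entries (default); otherwise the raw table.
#' @return data.frame.
#' @export
load_paper_atlas <- function(as_atlas = TRUE) {
  path <- fixture_path("atlas_table1.tsv")
  check_fixture(path, TABLE1_MD5)
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!as_atlas) return(tb)
  data.frame(
    key = paste0(tb$symbol1, ":", tb$symbol2, " ", tb$geometry),
    symbol1 = tb$symbol1, symbol2 = tb$symbol2, geometry = tb$geometry,
    natural = tb$natural == 1,
    occurrences = as.integer(tb$occurrences),
    representative = tb$pdb_id, rep_resolution = tb$resolution,
    position = tb$position, chains = tb$chains,
    stringsAsFactors = FALSE)
}

#' Load the packaged reference energy table
#'
#' Interaction energies (kcal/mol) of each modified pair type and of its
#' unmodified counterpart, together with the modification energy.  The
#' doubly-modified m1A:m5U pair appears twice, once per single-replacement
#' counterpart, as in the published table.
#'
#' @return data.frame with one row per (pair type, counterpart) combination;
#'   \code{key} is the row's printed orientation, \code{type_key} the
#'   canonical (modified/purine-first) atlas type.
#' @export
load_paper_energies <- function() {
  path <- fixture_path("energy_table2.tsv")
  check_fixture(path, TABLE2_MD5)
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  tb$key <- paste0(tb$symbol1, ":", tb$symbol2, " ", tb$geometry)
  tb$type_key <- vapply(seq_len(nrow(tb)), function(i)
    canonical_pair_key(tb$symbol1[i], tb$symbol2[i], tb$geometry[i]), "")
  tb
}

#' Canonical atlas key of a pair type
#'
#' Puts the modified base first (purine parent first when both or neither are
#' modified), swapping the label's edges and per-base flags accordingly.
#'
#' @param symbol1,symbol2 base symbols.
#' @param geometry geometry string.
#' @return the canonical "sym1:sym2 geometry" key.
#' @export
canonical_pair_key <- function(symbol1, symbol2, geometry) {
  c1 <- resolve_code(symbol1); c2 <- resolve_code(symbol2)
  m1 <- is_modified(c1); m2 <- is_modified(c2)
  p1 <- is_purine_family(c1); p2 <- is_purine_family(c2)
  swap <- if (xor(m1, m2)) !m1 else if (xor(p1, p2)) !p1 else FALSE
  if (!swap) return(paste0(mod_symbol(c1), ":", mod_symbol(c2), " ", geometry))
  lb <- parse_label(geometry)
  sw <- new_lw_label(lb$orientation, lb$edge2, lb$edge1,
                     ribose1 = lb$ribose2, ribose2 = lb$ribose1,
                     water = lb$water, single_hbond = lb$single_hbond,
                     cross1 = lb$cross2, cross2 = lb$cross1)
  paste0(mod_symbol(c2), ":", mod_symbol(c1), " ", label_to_string(sw))
}
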