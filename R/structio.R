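# structio: structure file input/output and residue bookkeeping.
#
# A Structure is a light S3 object: list(id, resolution, atoms) where atoms is
# one data.frame with a row per heavy (or hydrogen) atom and columns
#   record chain resno icode comp name elem x y z altloc occ
# Residues are addressed by the key "chain|resno|icode".

res_key <- function(chain, resno, icode = "") {
  icode[is.na(icode)] <- ""
  paste(chain, resno, icode, sep = "|")
}

new_structure <- function(atoms, id = "structure", resolution = NA_real_) {
  structure(list(id = id, resolution = resolution, atoms = atoms),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("Structure", x$id, "-", nrow(x$atoms), "atoms,",
      sum(rt$kind == "nucleotide"), "nucleotides,",
      sum(rt$kind == "water"), "waters")
  if (!is.na(x$resolution)) cat(", resolution", x$resolution, "A")
  cat("\n")
  invisible(x)
}

WATER_CODES <- c("HOH", "WAT", "H2O")

#' Residue inventory of a structure
#'
#' @param structure a Structure.
#' @return data.frame with key, chain, resno, icode, comp and kind
#'   (nucleotide / water / other).
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  key <- res_key(a$chain, a$resno, a$icode)
  first <- !duplicated(key)
  comp <- a$comp[first]
  kind <- ifelse(toupper(comp) %in% WATER_CODES, "water",
                 ifelse(vapply(comp, is_known_residue, TRUE), "nucleotide", "other"))
  data.frame(key = key[first], chain = a$chain[first], resno = a$resno[first],
             icode = a$icode[first], comp = comp, kind = kind,
             stringsAsFactors = FALSE, row.names = NULL)
}

# atoms of one residue as a data.frame (rows of structure$atoms)
residue_atoms <- function(structure, key) {
  a <- structure$atoms
  a[res_key(a$chain, a$resno, a$icode) == key, , drop = FALSE]
}

# named coordinate matrix of one residue
residue_xyz <- function(structure, key) {
  ra <- residue_atoms(structure, key)
  m <- as.matrix(ra[, c("x", "y", "z")])
  rownames(m) <- ra$name
  m
}

# coordinate of one atom (or NULL)
atom_xyz <- function(structure, key, name) {
  m <- residue_xyz(structure, key)
  nm <- gsub("\\*", "'", name)
  if (!nm %in% rownames(m)) return(NULL)
  m[nm, ]
}

resolve_altloc <- function(atoms) {
  if (all(is.na(atoms$altloc) | atoms$altloc == "")) return(atoms)
  akey <- paste(res_key(atoms$chain, atoms$resno, atoms$icode), atoms$name)
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(akey[duplicated(akey)])) {
    i <- which(akey == k)
    occ <- atoms$occ[i]
    best <- i[order(-occ, ifelse(is.na(atoms$altloc[i]), "", atoms$altloc[i]))][1]
    keep[i] <- FALSE
    keep[best] <- TRUE
  }
  atoms[keep, , drop = FALSE]
}

#' Read a structure file
#'
#' Reads PDB (through bio3d) or mmCIF (minimal \code{_atom_site} reader).
#' RNA residues -- canonical, modified (including HETATM records) -- and
#' waters are retained; other residues (e.g. protein) are dropped.  Alternate
#' locations are resolved to the highest occupancy (ties to altloc "A").
#' Hydrogens present in the file are kept.
#'
#' @param path file path.
#' @param format "pdb", "mmcif" or "auto" (by extension).
#' @return a \code{Structure}.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  atoms <- if (format == "pdb") read_pdb_atoms(path) else read_mmcif_atoms(path)
  resolution <- if (format == "pdb") read_pdb_resolution(path) else read_mmcif_resolution(path)
  atoms$name <- gsub("\\*", "'", atoms$name)
  atoms <- resolve_altloc(atoms)
  known <- vapply(atoms$comp, function(cc)
    toupper(cc) %in% WATER_CODES || is_known_residue(cc), TRUE)
  atoms <- atoms[known, , drop = FALSE]
  if (!any(!toupper(atoms$comp) %in% WATER_CODES)) {
    stop("no RNA residues found in ", path)
  }
  new_structure(atoms, id = sub("\\.(pdb|cif)$", "", basename(path), ignore.case = TRUE),
                resolution = resolution)
}

read_pdb_atoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("cannot parse PDB file ", path, ": ",
                                           conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("cannot parse PDB file ", path, ": no atoms")
  data.frame(record = a$type, chain = ifelse(is.na(a$chain), "A", a$chain),
             resno = a$resno,
             icode = ifelse(is.na(a$insert), "", a$insert),
             comp = toupper(a$resid), name = a$elety,
             elem = ifelse(is.na(a$elesy) | a$elesy == "",
                           toupper(substr(gsub("[0-9']", "", a$elety), 1, 1)),
                           toupper(a$elesy)),
             x = a$x, y = a$y, z = a$z,
             altloc = ifelse(is.na(a$alt), "", a$alt),
             occ = ifelse(is.na(a$o), 1, a$o), stringsAsFactors = FALSE)
}

read_pdb_resolution <- function(path) {
  ln <- grep("^REMARK   2 RESOLUTION", readLines(path), value = TRUE)
  if (!length(ln)) return(NA_real_)
  m <- regmatches(ln[1], gregexpr("[0-9]+\\.[0-9]+", ln[1]))[[1]]
  if (!length(m)) return(NA_real_)
  as.numeric(m[1])
}

read_mmcif_atoms <- function(path) {
  lines <- readLines(path)
  i <- 1L; n <- length(lines)
  fields <- character(); rows <- list(); in_loop <- FALSE; in_atoms <- FALSE
  while (i <= n) {
    ln <- trimws(lines[i])
    if (ln == "loop_") { in_loop <- TRUE; fields <- character(); in_atoms <- FALSE }
    else if (in_loop && grepl("^_atom_site\\.", ln)) {
      fields <- c(fields, sub("^_atom_site\\.", "", strsplit(ln, "\\s+")[[1]][1]))
      in_atoms <- TRUE
    } else if (in_atoms && nzchar(ln) && !startsWith(ln, "_") && !startsWith(ln, "#")) {
      rows[[length(rows) + 1L]] <- strsplit(ln, "\\s+")[[1]]
    } else if (in_atoms && (startsWith(ln, "_") || ln == "loop_" || startsWith(ln, "#"))) {
      in_loop <- ln == "loop_"; in_atoms <- FALSE
    }
    i <- i + 1L
  }
  if (!length(rows)) stop("cannot parse mmCIF file ", path, ": no _atom_site loop")
  tb <- do.call(rbind, rows)
  colnames(tb) <- fields[seq_len(ncol(tb))]
  pick <- function(opts, default = NA_character_) {
    for (o in opts) if (o %in% colnames(tb)) return(tb[, o])
    rep(default, nrow(tb))
  }
  blank <- function(v) ifelse(v %in% c("?", "."), "", v)
  data.frame(
    record = pick("group_PDB", "ATOM"),
    chain = blank(pick(c("auth_asym_id", "label_asym_id"), "A")),
    resno = as.integer(pick(c("auth_seq_id", "label_seq_id"))),
    icode = blank(pick("pdbx_PDB_ins_code", "")),
    comp = toupper(pick(c("auth_comp_id", "label_comp_id"))),
    name = gsub('"', "", pick(c("auth_atom_id", "label_atom_id"))),
    elem = toupper(blank(pick("type_symbol"))),
    x = as.numeric(pick("Cartn_x")), y = as.numeric(pick("Cartn_y")),
    z = as.numeric(pick("Cartn_z")),
    altloc = blank(pick("label_alt_id", "")),
    occ = suppressWarnings(as.numeric(pick("occupancy", "1"))),
    stringsAsFactors = FALSE)
}

read_mmcif_resolution <- function(path) {
  ln <- grep("_refine\\.ls_d_res_high", readLines(path), value = TRUE)
  if (!length(ln)) return(NA_real_)
  v <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  if (length(v) < 2) return(NA_real_)
  suppressWarnings(as.numeric(v[2]))
}

#' Filter structures by crystallographic resolution
#'
#' Keeps structures whose resolution is at or better than (numerically less
#' than or equal to) the cutoff.  Structures without resolution metadata are
#' excluded and reported via a message.
#'
#' @param structures list of Structure objects.
#' @param cutoff resolution cutoff in Angstrom (default 3.5).
#' @return the kept subset (a list).
#' @export
filter_by_resolution <- function(structures, cutoff = 3.5) {
  stopifnot(cutoff > 0)
  keep <- logical(length(structures))
  for (i in seq_along(structures)) {
    r <- structures[[i]]$resolution
    if (is.na(r)) {
      message("excluding ", structures[[i]]$id, ": no resolution metadata")
    } else keep[i] <- r <= cutoff
  }
  structures[keep]
}

fmt_pdb_name <- function(name, elem) {
  # element right-justified in columns 13-14 for standard names
  if (nchar(name) >= 4) return(substr(name, 1, 4))
  if (nchar(elem) == 2) sprintf("%-4s", name) else sprintf(" %-3s", name)
}

#' Write a structure as PDB
#'
#' Emits REMARK 2 resolution metadata (when present) and ATOM/HETATM records.
#'
#' @param structure a Structure.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  out <- character()
  if (!is.na(structure$resolution)) {
    out <- c(out, sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", structure$resolution))
  }
  for (i in seq_len(nrow(a))) {
    rec <- if (identical(a$record[i], "HETATM")) "HETATM" else "ATOM  "
    out <- c(out, sprintf("%s%5d %s%s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                          rec, i, fmt_pdb_name(a$name[i], a$elem[i]),
                          ifelse(is.na(a$altloc[i]) | a$altloc[i] == "", " ", a$altloc[i]),
                          a$comp[i], a$chain[i], a$resno[i],
                          ifelse(is.na(a$icode[i]) | a$icode[i] == "", " ", a$icode[i]),
                          a$x[i], a$y[i], a$z[i], a$occ[i], 0, a$elem[i]))
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_pdb
#' @export
write_mmcif <- function(structure, path) {
  a <- structure$atoms
  out <- c(paste0("data_", gsub("[^A-Za-z0-9_]", "_", structure$id)),
           paste0("_entry.id ", structure$id))
  if (!is.na(structure$resolution)) {
    out <- c(out, sprintf("_refine.ls_d_res_high %.2f", structure$resolution))
  }
  out <- c(out, "loop_",
           paste0("_atom_site.", c("group_PDB", "id", "type_symbol", "label_atom_id",
                                   "label_comp_id", "auth_asym_id", "auth_seq_id",
                                   "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                                   "occupancy", "B_iso_or_equiv", "label_alt_id")))
  for (i in seq_len(nrow(a))) {
    nm <- a$name[i]
    if (grepl("'", nm)) nm <- paste0('"', nm, '"')
    out <- c(out, sprintf("%s %d %s %s %s %s %d %s %.3f %.3f %.3f %.2f %.2f %s",
                          ifelse(is.na(a$record[i]), "ATOM", a$record[i]), i, a$elem[i], nm,
                          a$comp[i], a$chain[i], a$resno[i],
                          ifelse(is.na(a$icode[i]) | a$icode[i] == "", "?", a$icode[i]),
                          a$x[i], a$y[i], a$z[i], a$occ[i], 0,
                          ifelse(is.na(a$altloc[i]) | a$altloc[i] == "", ".", a$altloc[i])))
  }
  writeLines(c(out, "#"), path)
  invisible(path)
}

#' Write a fragment in XYZ format
#'
#' Standard XYZ: atom count, then a comment line carrying the fragment name,
#' net charge and multiplicity, then one "element x y z" line per atom.
#'
#' @param fragment a Fragment (see \code{\link{build_pair_model}}).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_xyz <- function(fragment, path) {
  a <- fragment$atoms
  if (any(is.na(a$elem) | a$elem == "")) stop("fragment has atoms without an element")
  out <- c(as.character(nrow(a)),
           sprintf("%s charge=%d multiplicity=%d", fragment$name,
                   fragment$net_charge, fragment$multiplicity),
           sprintf("%-2s %12.6f %12.6f %12.6f",
                   substr(a$elem, 1, 1 + (nchar(a$elem) > 1)), a$x, a$y, a$z))
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  ln <- readLines(path)
  n <- as.integer(trimws(ln[1]))
  comment <- ln[2]
  rows <- strsplit(trimws(ln[3:(2 + n)]), "\\s+")
  atoms <- data.frame(elem = toupper(vapply(rows, `[`, "", 1)),
                      x = as.numeric(vapply(rows, `[`, "", 2)),
                      y = as.numeric(vapply(rows, `[`, "", 3)),
                      z = as.numeric(vapply(rows, `[`, "", 4)),
                      stringsAsFactors = FALSE)
  charge <- if (grepl("charge=", comment)) {
    as.integer(sub(".*charge=(-?[0-9]+).*", "\\1", comment))
  } else 0L
  list(atoms = atoms, comment = comment, net_charge = charge)
}
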