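# modchem: chemistry of canonical and modified nucleobases.
#
# The dictionary (inst/extdata/nucleobase_dictionary.txt) holds, for each
# residue, idealized heavy-atom coordinates in a standard frame (glycosidic
# base atom at the origin, C1' along -x, base plane = xy), the covalent
# topology, implicit hydrogen counts, H-bond roles and the Leontis-Westhof
# edge each atom belongs to.  Boundary atoms that sit between two H-bonding
# faces (e.g. N6 of adenine between the Watson-Crick and Hoogsteen edges)
# carry a secondary edge; per-contact resolution happens in the classifier.

.modbp <- new.env(parent = emptyenv())

#' Load the nucleobase dictionary
#'
#' Parses the packaged (or a user-supplied) template dictionary and caches it.
#' The dictionary covers the four canonical ribonucleosides, 14 modified
#' nucleosides (11 natural posttranscriptional modifications plus the three
#' halogenated pyrimidines used for crystallographic phasing) and water.
#'
#' @param path optional path to an alternative dictionary file.
#' @param refresh force re-reading even if a cached copy exists.
#' @return invisibly, a named list of residue specifications.
#' @export
load_dictionary <- function(path = NULL, refresh = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "nucleobase_dictionary.txt", package = "modbp")
  }
  key <- normalizePath(path)
  if (!refresh && !is.null(.modbp$dict) && identical(.modbp$dict_path, key)) {
    return(invisible(.modbp$dict))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  dict <- list()
  alias <- character()
  cur <- NULL
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    kind <- tok[1]
    if (kind == "RESIDUE") {
      kv <- strsplit(tok[-(1:2)], "=")
      kv <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
      cur <- list(code = tok[2], symbol = kv[["symbol"]], parent = kv[["parent"]],
                  glyc = kv[["glyc"]], charge = as.integer(kv[["charge"]]),
                  natural = kv[["natural"]] == "1", planar = kv[["planar"]] == "1",
                  affected_edges = character(),
                  atoms = list(), bonds = list())
    } else if (kind == "ALIAS") {
      for (a in tok[-1]) alias[toupper(a)] <- cur$code
    } else if (kind == "EDGEAFF") {
      cur$affected_edges <- strsplit(tok[2], ",")[[1]]
    } else if (kind == "ATOM") {
      cur$atoms[[length(cur$atoms) + 1L]] <- tok[-1]
    } else if (kind == "BOND") {
      cur$bonds[[length(cur$bonds) + 1L]] <- tok[2:3]
    } else if (kind == "END") {
      at <- do.call(rbind, cur$atoms)
      cur$atoms <- data.frame(
        name = at[, 1], elem = at[, 2],
        x = as.numeric(at[, 3]), y = as.numeric(at[, 4]), z = as.numeric(at[, 5]),
        nH = as.integer(at[, 6]), hyb = at[, 7], edge = at[, 8], edge2 = at[, 9],
        role = at[, 10], moiety = at[, 11], stringsAsFactors = FALSE)
      cur$bonds <- if (length(cur$bonds)) {
        bd <- do.call(rbind, cur$bonds)
        data.frame(a1 = bd[, 1], a2 = bd[, 2], stringsAsFactors = FALSE)
      } else data.frame(a1 = character(), a2 = character())
      dict[[cur$code]] <- cur
      cur <- NULL
    }
  }
  .modbp$dict <- dict
  .modbp$alias <- alias
  .modbp$dict_path <- key
  .modbp$pose_cache <- list()
  invisible(dict)
}

dict_get <- function() {
  if (is.null(.modbp$dict)) load_dictionary()
  .modbp$dict
}

#' Resolve a residue component code
#'
#' Accepts PDB chemical-component IDs, package aliases and the conventional
#' modification symbols (e.g. \code{"m1A"}, \code{"Psi"}), case-insensitively.
#'
#' @param code residue code.
#' @return the canonical dictionary code.
#' @export
resolve_code <- function(code) {
  dict <- dict_get()
  up <- toupper(trimws(code))
  if (up %in% names(dict)) return(up)
  if (up %in% names(.modbp$alias)) return(.modbp$alias[[up]])
  sym <- vapply(dict, function(r) toupper(r$symbol), "")
  hit <- names(sym)[sym == up]
  if (length(hit) == 1L) return(hit)
  stop("unsupported residue: ", code)
}

residue_spec <- function(code) dict_get()[[resolve_code(code)]]

#' @rdname resolve_code
#' @export
is_known_residue <- function(code) {
  ok <- try(resolve_code(code), silent = TRUE)
  !inherits(ok, "try-error")
}

#' Is a residue a modified nucleoside?
#' @param code residue code.
#' @export
is_modified <- function(code) {
  r <- residue_spec(code)
  r$code != r$parent && r$code != "HOH"
}

parent_of <- function(code) residue_spec(code)$parent

mod_symbol <- function(code) residue_spec(code)$symbol

is_purine_family <- function(code) parent_of(code) %in% c("A", "G")

base_atom_names <- function(code) {
  a <- residue_spec(code)$atoms
  a$name[a$moiety == "base"]
}

#' Atom correspondence map between a modified base and its parent
#'
#' For substituent modifications the map is the identity on shared atoms
#' (with element replacements such as S4 -> O4 for 4-thiouridine mapped by
#' position).  For pseudouridine the structural ring map is returned, obtained
#' by walking both rings from the glycosidic attachment atom in the same
#' rotational sense, so that superposition compares structurally (not
#' chemically) equivalent positions.
#'
#' @param mod_code modified (or canonical) residue code.
#' @param include_sugar also map the sugar atoms (identity); default TRUE.
#' @return data.frame with columns \code{mod}, \code{parent}.
#' @export
correspondence_map <- function(mod_code, include_sugar = TRUE) {
  r <- residue_spec(mod_code)
  par <- residue_spec(r$parent)
  if (r$code == "PSU") {
    map <- data.frame(
      mod    = c("C5", "C4", "O4", "N3", "C2", "O2", "N1", "C6"),
      parent = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6"),
      stringsAsFactors = FALSE)
  } else {
    shared <- intersect(base_atom_names(r$code), base_atom_names(par$code))
    map <- data.frame(mod = shared, parent = shared, stringsAsFactors = FALSE)
    if (r$code == "4SU") {
      map <- rbind(map, data.frame(mod = "S4", parent = "O4"))
    }
  }
  if (include_sugar) {
    sg <- intersect(residue_spec(r$code)$atoms$name[residue_spec(r$code)$atoms$moiety == "sugar"],
                    par$atoms$name[par$atoms$moiety == "sugar"])
    map <- rbind(map, data.frame(mod = sg, parent = sg))
  }
  stopifnot(!anyDuplicated(map$mod), !anyDuplicated(map$parent))
  map
}

#' Look up a modification specification
#'
#' @param comp_code residue component code (case-insensitive; aliases and
#'   modification symbols accepted).
#' @return an object of class \code{ModificationSpec} with the parent base,
#'   the atom edits relative to the parent template, the net charge, the
#'   H-bonding edges affected by the modification and the atom correspondence
#'   map.  Canonical bases return a degenerate spec with no edits.
#' @export
lookup_modification <- function(comp_code) {
  r <- residue_spec(comp_code)
  if (r$code == "HOH") stop("unsupported residue: water is not a nucleobase")
  par <- residue_spec(r$parent)
  map <- correspondence_map(r$code, include_sugar = FALSE)
  edits <- list()
  mod_base <- base_atom_names(r$code)
  par_base <- base_atom_names(par$code)
  for (nm in setdiff(mod_base, map$mod)) {
    edits[[length(edits) + 1L]] <- list(op = "add", atom = nm)
  }
  for (nm in setdiff(par_base, map$parent)) {
    edits[[length(edits) + 1L]] <- list(op = "remove", atom = nm)
  }
  if (r$code == "4SU") {
    edits[[length(edits) + 1L]] <- list(op = "replace_element", atom = "S4",
                                        parent_atom = "O4")
  }
  if (r$glyc != par$glyc) {
    edits[[length(edits) + 1L]] <- list(op = "reattach_glycosidic",
                                        atom = r$glyc, parent_atom = par$glyc)
  }
  structure(list(
    comp_code = r$code, symbol = r$symbol, parent = r$parent,
    glycosidic_atom = r$glyc, atom_edits = edits, net_charge = r$charge,
    natural = r$natural, affected_edges = r$affected_edges,
    correspondence = map), class = "ModificationSpec")
}

#' @export
print.ModificationSpec <- function(x, ...) {
  cat("ModificationSpec:", x$symbol, "(", x$comp_code, "), parent", x$parent,
      ", charge", x$net_charge,
      if (length(x$affected_edges)) paste(", affects", paste(x$affected_edges, collapse = "/")),
      "\n")
  invisible(x)
}

#' Leontis-Westhof edge of a base atom
#'
#' Returns the primary edge (\code{W}, \code{H} or \code{S}) of a heavy atom.
#' The ribose O2' (and every other sugar atom) maps to the sugar edge.
#' Boundary atoms sitting between two faces report their primary edge here;
#' \code{edge_candidates} exposes both.
#'
#' @param code residue code.
#' @param atom_name heavy-atom name (\code{*} and \code{'} both accepted as
#'   the prime character).
#' @export
edge_of_atom <- function(code, atom_name) {
  edge_candidates(code, atom_name)[1]
}

#' @rdname edge_of_atom
#' @export
edge_candidates <- function(code, atom_name) {
  r <- residue_spec(code)
  nm <- gsub("\\*", "'", trimws(atom_name))
  i <- match(nm, r$atoms$name)
  if (is.na(i)) stop("atom ", atom_name, " not found in residue ", r$code)
  e <- r$atoms$edge[i]
  e2 <- r$atoms$edge2[i]
  if (e2 == "-") e else c(e, e2)
}

# role ("donor"/"acceptor"/"both"/"none") of one atom
atom_role <- function(code, atom_name) {
  r <- residue_spec(code)
  nm <- gsub("\\*", "'", trimws(atom_name))
  i <- match(nm, r$atoms$name)
  if (is.na(i)) return("none")
  r$atoms$role[i]
}

# covalent heavy-atom neighbors of an atom, from the dictionary topology
atom_neighbors <- function(code, atom_name) {
  r <- residue_spec(code)
  nm <- gsub("\\*", "'", trimws(atom_name))
  c(r$bonds$a2[r$bonds$a1 == nm], r$bonds$a1[r$bonds$a2 == nm])
}

#' Idealized template coordinates of a residue
#'
#' @param code residue code.
#' @param atoms optional subset of atom names.
#' @return matrix with rownames = atom names.
#' @export
template_coords <- function(code, atoms = NULL) {
  r <- residue_spec(code)
  m <- as.matrix(r$atoms[, c("x", "y", "z")])
  rownames(m) <- r$atoms$name
  if (!is.null(atoms)) m <- m[atoms, , drop = FALSE]
  m
}

# template bond length between two bonded atoms
template_bond_length <- function(code, a1, a2) {
  m <- template_coords(code)
  vnorm(m[a1, ] - m[a2, ])
}

#' List all modification entries in the dictionary
#' @param natural_only restrict to natural posttranscriptional modifications.
#' @return character vector of component codes.
#' @export
list_modifications <- function(natural_only = FALSE) {
  dict <- dict_get()
  keep <- vapply(dict, function(r) r$code != r$parent && r$code != "HOH", TRUE)
  if (natural_only) keep <- keep & vapply(dict, function(r) r$natural, TRUE)
  names(dict)[keep]
}
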