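# lwclass: extended Leontis-Westhof geometry labels for base pairs.
#
# The label grammar follows the atlas convention:
#   [ct] edge1 [tokens] edge2 [tokens] [1]
# with edge in {W, H, S, Bs}; tokens in brackets: "(r)" marks that the ribose
# 2'-OH of that base is H-bonded to the partner; a lowercase edge letter after
# an edge is a cross-edge note (the partner's ribose binds this base on a
# different edge than the base-base contact); "(w)" after edge2 marks a
# bridging water.  A trailing "1" marks a single-H-bond pair.

new_lw_label <- function(orientation, edge1, edge2, ribose1 = FALSE, ribose2 = FALSE,
                         water = FALSE, single_hbond = FALSE,
                         cross1 = NA_character_, cross2 = NA_character_) {
  structure(list(orientation = orientation, edge1 = edge1, edge2 = edge2,
                 ribose1 = ribose1, ribose2 = ribose2, water = water,
                 single_hbond = single_hbond, cross1 = cross1, cross2 = cross2),
            class = "LWLabel")
}

#' Render an extended Leontis-Westhof label as a string
#'
#' @param label an \code{LWLabel}.
#' @return geometry string such as \code{"tHW(w)"} or \code{"cS(r)W"}.
#' @export
label_to_string <- function(label) {
  s <- if (label$orientation == "cis") "c" else "t"
  s <- paste0(s, label$edge1)
  if (label$ribose1) s <- paste0(s, "(r)")
  if (!is.na(label$cross1)) s <- paste0(s, "(", tolower(label$cross1), ")")
  s <- paste0(s, label$edge2)
  if (label$ribose2) s <- paste0(s, "(r)")
  if (!is.na(label$cross2)) s <- paste0(s, "(", tolower(label$cross2), ")")
  if (label$water) s <- paste0(s, "(w)")
  if (label$single_hbond) s <- paste0(s, "1")
  s
}

#' @export
format.LWLabel <- function(x, ...) label_to_string(x)

#' @export
print.LWLabel <- function(x, ...) {
  cat(label_to_string(x), "\n")
  invisible(x)
}

#' Parse an extended Leontis-Westhof geometry string
#'
#' Inverse of \code{\link{label_to_string}}.  A bracketed \code{(w)} between
#' the two edge symbols is read as a cross-edge Watson-Crick note (the atlas
#' prints it lowercase); after the second edge it is read as a bridging-water
#' flag.  Uppercase edge letters in brackets are accepted as cross-edge notes
#' too.
#'
#' @param text geometry string.
#' @return an \code{LWLabel}.
#' @export
parse_label <- function(text) {
  s <- text
  pos <- 1L
  fail <- function(p) stop("malformed geometry label '", text, "' at position ", p)
  take_edge <- function() {
    if (substr(s, pos, pos + 1) == "Bs") { e <- "Bs"; pos <<- pos + 2L }
    else if (substr(s, pos, pos) %in% c("W", "H", "S")) {
      e <- substr(s, pos, pos); pos <<- pos + 1L
    } else fail(pos)
    e
  }
  take_tokens <- function() {
    toks <- character()
    while (substr(s, pos, pos) == "(") {
      close <- regexpr("\\)", substr(s, pos, nchar(s)))
      if (close < 0) fail(pos)
      toks <- c(toks, substr(s, pos + 1, pos + close - 2))
      pos <<- pos + close
    }
    toks
  }
  ori <- switch(substr(s, 1, 1), c = "cis", t = "trans", fail(1))
  pos <- 2L
  e1 <- take_edge(); t1 <- take_tokens()
  e2 <- take_edge(); t2 <- take_tokens()
  single <- FALSE
  if (pos <= nchar(s)) {
    if (substr(s, pos, nchar(s)) == "1") single <- TRUE else fail(pos)
  }
  lb <- new_lw_label(ori, e1, e2, single_hbond = single)
  for (tk in t1) {
    if (tk == "r") lb$ribose1 <- TRUE
    else if (toupper(tk) %in% c("W", "H", "S")) lb$cross1 <- toupper(tk)
    else fail(pos)
  }
  for (tk in t2) {
    if (tk == "r") lb$ribose2 <- TRUE
    else if (tk == "w") lb$water <- TRUE
    else if (toupper(tk) %in% c("W", "H", "S")) lb$cross2 <- toupper(tk)
    else fail(pos)
  }
  lb
}

# --- geometry helpers on residues -------------------------------------------

base_plane <- function(structure, key, comp) {
  m <- residue_xyz(structure, key)
  bn <- intersect(rownames(m), base_atom_names(comp))
  if (length(bn) < 3) stop("residue ", key, " has too few base atoms")
  fit_plane(m[bn, , drop = FALSE])
}

glyc_atom_of <- function(comp) residue_spec(comp)$glyc

#' Mutual orientation of the glycosidic bonds
#'
#' Computes the pseudo-torsion C1'(1) - glycosidic(1) - glycosidic(2) - C1'(2)
#' and maps it to cis (|torsion| < 90 degrees) or trans (including the
#' boundary at exactly 90 degrees).
#'
#' @param structure a Structure.
#' @param key1,key2 residue keys.
#' @return list(torsion, orientation).
#' @export
glycosidic_orientation <- function(structure, key1, key2) {
  rt <- residue_table(structure)
  comp1 <- rt$comp[rt$key == key1]; comp2 <- rt$comp[rt$key == key2]
  need <- function(key, comp, name) {
    p <- atom_xyz(structure, key, name)
    if (is.null(p)) stop("residue ", key, " (", comp, ") is missing atom ", name)
    p
  }
  c1a <- need(key1, comp1, "C1'"); g1 <- need(key1, comp1, glyc_atom_of(comp1))
  c1b <- need(key2, comp2, "C1'"); g2 <- need(key2, comp2, glyc_atom_of(comp2))
  tor <- dihedral_angle(c1a, g1, g2, c1b)
  list(torsion = tor, orientation = if (abs(tor) < 90) "cis" else "trans")
}

# direction reference vectors (unit, in-plane) for the three edges of a base
edge_directions <- function(structure, key, comp) {
  m <- residue_xyz(structure, key)
  bn <- intersect(rownames(m), base_atom_names(comp))
  ctr <- colMeans(m[bn, , drop = FALSE])
  pl <- fit_plane(m[bn, , drop = FALSE])
  core <- switch(parent_of(comp),
                 A = c(W = "N1", H = "N7"), G = c(W = "N1", H = "N7"),
                 C = c(W = "N3", H = "C5"), U = c(W = "N3", H = "C5"))
  if (resolve_code(comp) == "PSU") core <- c(W = "N3", H = "N1")
  inplane <- function(p) {
    v <- p - ctr
    v <- v - sum(v * pl$normal) * pl$normal
    unitv(v)
  }
  dirs <- list(W = inplane(m[core[["W"]], ]), H = inplane(m[core[["H"]], ]))
  sdir <- if ("C1'" %in% rownames(m)) inplane(m["C1'", ]) else
    inplane(m[glyc_atom_of(comp), ])
  dirs$S <- sdir
  list(center = ctr, normal = pl$normal, dirs = dirs)
}

# resolve the edge of one contact: boundary atoms decided by the direction of
# the partner atom in the base's own frame
contact_edge <- function(ed, comp, atom, partner_xyz) {
  cand <- edge_candidates(comp, atom)
  if (length(cand) == 1) return(cand)
  v <- partner_xyz - ed$center
  v <- v - sum(v * ed$normal) * ed$normal
  v <- unitv(v)
  scores <- vapply(cand, function(e) sum(v * ed$dirs[[e]]), 0)
  cand[which.max(scores)]
}

# is this atom an exocyclic sugar-side keto/amino group (bifurcation anchor)?
is_sugar_side_keto_amino <- function(comp, atom) {
  spec <- residue_spec(comp)
  i <- match(atom, spec$atoms$name)
  if (is.na(i)) return(FALSE)
  if (!spec$atoms$elem[i] %in% c("N", "O", "S")) return(FALSE)
  ring <- atom %in% c("N1", "N3", "N7", "N9")  # ring nitrogens are not exocyclic
  if (ring) return(FALSE)
  "S" %in% edge_candidates(comp, atom)
}

#' Assign the interacting edge of each base
#'
#' Majority vote of the (direction-resolved) edge of every base-base contact
#' atom; ties break to the edge of the shortest H-bond.  When at least two
#' direct H-bonds share one single atom on a base and that atom is a
#' sugar-side keto/amino group, the base's edge is the bifurcated \code{Bs}.
#'
#' @param structure a Structure.
#' @param key1,key2 residue keys.
#' @param hbonds base-base H-bond records between the two residues.
#' @return character vector c(edge1, edge2) following key1, key2 order.
#' @export
assign_edges <- function(structure, key1, key2, hbonds) {
  bb <- hbonds[hbonds$kind == "base_base", , drop = FALSE]
  if (!nrow(bb)) stop("assign_edges needs at least one base-base H-bond")
  rt <- residue_table(structure)
  comp <- stats::setNames(rt$comp, rt$key)
  vapply(c(key1, key2), function(k) {
    other <- if (k == key1) key2 else key1
    mine <- ifelse(bb$donor_res == k, bb$donor_atom, bb$acceptor_atom)
    theirs <- ifelse(bb$donor_res == k, bb$acceptor_atom, bb$donor_atom)
    involved <- bb$donor_res == k | bb$acceptor_res == k
    mine <- mine[involved]; theirs <- theirs[involved]; dist <- bb$distance[involved]
    if (length(mine) >= 2 && length(unique(mine)) == 1 &&
        is_sugar_side_keto_amino(comp[[k]], mine[1])) {
      return("Bs")
    }
    ed <- edge_directions(structure, k, comp[[k]])
    votes <- vapply(seq_along(mine), function(i) {
      pxyz <- atom_xyz(structure, other, theirs[i])
      contact_edge(ed, comp[[k]], mine[i], pxyz)
    }, "")
    tab <- sort(table(votes), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) {
      votes[which.min(dist)]
    } else names(tab)[1]
  }, "")
}

not_a_pair <- function(reason) structure(list(reason = reason), class = "NotAPair")

#' @export
print.NotAPair <- function(x, ...) {
  cat("not a base pair:", x$reason, "\n")
  invisible(x)
}

is_pair <- function(x) inherits(x, "BasePairAnnotation")

#' Classify a candidate base pair
#'
#' Applies pairing plausibility filters (near-coplanarity of the two bases and
#' rejection of stacked geometries by the vertical offset between base
#' centroids), determines the cis/trans orientation from the glycosidic
#' pseudo-torsion, assigns the interacting edges, and sets the extended-label
#' flags: ribose \code{(r)} when a base's 2'-OH H-bonds the partner base,
#' cross-edge notes, bridging water \code{(w)}, and \code{1} when the pair is
#' held by a single direct H-bond.  The modified base is put first (purines
#' first when both or neither base is modified).
#'
#' @param structure a Structure.
#' @param key1,key2 residue keys.
#' @param hbonds optional precomputed H-bonds of the whole structure.
#' @param params see \code{\link{hbond_params}}.
#' @return a \code{BasePairAnnotation}, or a \code{NotAPair} object.
#' @export
classify_pair <- function(structure, key1, key2, hbonds = NULL,
                          params = hbond_params()) {
  if (is.null(hbonds)) hbonds <- find_hbonds(structure, params)
  mine <- (hbonds$donor_res == key1 & hbonds$acceptor_res == key2) |
    (hbonds$donor_res == key2 & hbonds$acceptor_res == key1)
  direct <- hbonds[mine & hbonds$kind %in% c("base_base", "base_ribose"), , drop = FALSE]
  bb <- direct[direct$kind == "base_base", , drop = FALSE]
  if (!nrow(bb)) return(not_a_pair("no direct base-base H-bond"))
  rt <- residue_table(structure)
  comp <- stats::setNames(rt$comp, rt$key)
  pl1 <- base_plane(structure, key1, comp[[key1]])
  pl2 <- base_plane(structure, key2, comp[[key2]])
  ipa <- interplane_angle(pl1$normal, pl2$normal)
  if (ipa > params$interplane_max) {
    return(not_a_pair(sprintf("interplane angle %.0f deg exceeds %.0f",
                              ipa, params$interplane_max)))
  }
  n2 <- if (sum(pl1$normal * pl2$normal) < 0) -pl2$normal else pl2$normal
  nmean <- unitv(pl1$normal + n2)
  voffset <- abs(sum((pl2$center - pl1$center) * nmean))
  # stacking: near-parallel planes displaced along the normal; strongly
  # inclined pairs (e.g. ribose-mediated cW(r)S) legitimately sit off-plane
  if (voffset > params$voffset_max && ipa < 30) {
    return(not_a_pair(sprintf("vertical offset %.1f A suggests stacking", voffset)))
  }
  ori <- glycosidic_orientation(structure, key1, key2)
  edges <- assign_edges(structure, key1, key2, direct)
  bridges <- find_bridging_waters(structure, key1, key2, params)

  ribose_of <- function(k) {
    any(direct$kind == "base_ribose" &
          ((direct$donor_res == k & direct$donor_atom == "O2'") |
             (direct$acceptor_res == k & direct$acceptor_atom == "O2'")))
  }
  cross_of <- function(k, ek) {
    other <- if (k == key1) key2 else key1
    br <- direct[direct$kind == "base_ribose", , drop = FALSE]
    notes <- character()
    for (i in seq_len(nrow(br))) {
      # partner's O2' contacting a base atom of residue k
      if (br$donor_res[i] == other && br$donor_atom[i] == "O2'" &&
          br$acceptor_res[i] == k && br$acceptor_atom[i] != "O2'") {
        notes <- c(notes, edge_of_atom(comp[[k]], br$acceptor_atom[i]))
      }
      if (br$acceptor_res[i] == other && br$acceptor_atom[i] == "O2'" &&
          br$donor_res[i] == k && br$donor_atom[i] != "O2'") {
        notes <- c(notes, edge_of_atom(comp[[k]], br$donor_atom[i]))
      }
    }
    notes <- setdiff(unique(notes), ek)
    if (length(notes)) notes[1] else NA_character_
  }

  k <- c(key1, key2)
  modif <- vapply(comp[k], is_modified, TRUE)
  purine <- vapply(comp[k], is_purine_family, TRUE)
  swap <- if (xor(modif[1], modif[2])) !modif[1] else if (xor(purine[1], purine[2])) !purine[1] else k[1] > k[2]
  if (swap) k <- rev(k)
  e <- if (swap) rev(edges) else edges
  label <- new_lw_label(
    ori$orientation, e[1], e[2],
    ribose1 = ribose_of(k[1]), ribose2 = ribose_of(k[2]),
    water = nrow(bridges) > 0,
    # a water-completed link counts: only a pair held by one H-bond in total
    # (direct plus water-mediated) carries the '1' flag
    single_hbond = nrow(direct) + length(unique(bridges$bridge_water)) == 1,
    # cross-edge notes are reported for the leading (modified) base only,
    # matching the published atlas convention
    cross1 = cross_of(k[1], e[1]), cross2 = NA_character_)
  c1 <- atom_xyz(structure, k[1], "C1'"); c2 <- atom_xyz(structure, k[2], "C1'")
  structure(list(
    res1 = k[1], res2 = k[2], comp1 = comp[[k[1]]], comp2 = comp[[k[2]]],
    symbol1 = mod_symbol(comp[[k[1]]]), symbol2 = mod_symbol(comp[[k[2]]]),
    hbonds = direct, bridges = bridges, label = label,
    geometry = label_to_string(label),
    pair_key = paste0(mod_symbol(comp[[k[1]]]), ":", mod_symbol(comp[[k[2]]]),
                      " ", label_to_string(label)),
    glyc_torsion = ori$torsion, interplane_angle = ipa,
    c1c1_distance = vnorm(c1 - c2),
    modified = c(is_modified(comp[[k[1]]]), is_modified(comp[[k[2]]]))),
    class = "BasePairAnnotation")
}

#' @export
print.BasePairAnnotation <- function(x, ...) {
  cat(sprintf("%s  (%s | %s)  %d H-bond(s), torsion %.0f deg, C1'-C1' %.1f A\n",
              x$pair_key, x$res1, x$res2, nrow(x$hbonds), x$glyc_torsion,
              x$c1c1_distance))
  invisible(x)
}
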