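# qmodel: capped, hydrogen-completed model fragments of base pairs for
# external quantum-chemistry input, and unmodified counterparts that preserve
# the H-bonding pattern of the modified pair.
#
# Base-only residues are truncated at C1' (kept as a methyl carbon); the
# ribose is retained for residues whose 2'-OH takes part in the pairing, in
# which case the 5' side is capped by turning C5' into a methyl and the 3'
# side, by default, by deleting O3' and saturating C3'.  Hydrogens are placed
# at idealized geometry (N-H 1.01, O-H 0.96, C-H 1.09 Angstrom).

H_LENGTH <- c(N = 1.01, O = 0.96, C = 1.09)

new_fragment <- function(atoms, name, net_charge = 0L, provenance = list(),
                         includes_ribose = FALSE, waters = 0L) {
  structure(list(name = name, atoms = atoms, net_charge = as.integer(net_charge),
                 multiplicity = 1L, provenance = provenance,
                 includes_ribose = includes_ribose, waters = waters),
            class = "Fragment")
}

#' @export
print.Fragment <- function(x, ...) {
  cat(sprintf("Fragment %s: %d atoms (%d H), charge %+d\n", x$name,
              nrow(x$atoms), sum(x$atoms$elem == "H"), x$net_charge))
  invisible(x)
}

# --- hydrogen placement -----------------------------------------------------

# deterministic unit vector perpendicular to u
any_perp <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitv(vcross(u, ref))
}

# idealized hydrogens for one heavy atom given its retained neighbors.
# nH counts deleted heavy neighbors as extra hydrogens (each cut bond is
# saturated).
hydrogens_for_atom <- function(xyz, nbr_xyz, nH, hyb, elem) {
  L <- H_LENGTH[[elem]]
  if (nH <= 0) return(NULL)
  k <- nrow(nbr_xyz)
  hs <- list()
  if (k == 0) {
    # isolated atom (water oxygen handled separately upstream)
    u <- c(1, 0, 0); p <- c(0, 1, 0)
    ang <- 104.5 * pi / 180
    hs <- list(xyz + L * u,
               xyz + L * (cos(ang) * u + sin(ang) * p))[seq_len(nH)]
  } else if (k == 1) {
    u <- unitv(xyz - nbr_xyz[1, ])
    p <- any_perp(u)
    q <- vcross(u, p)
    if (hyb == "sp2") {
      w <- p
      a <- 60 * pi / 180  # 120 deg from the single bond
      if (nH == 1) hs <- list(xyz + L * unitv(cos(a) * u + sin(a) * w))
      else hs <- list(xyz + L * unitv(cos(a) * u + sin(a) * w),
                      xyz + L * unitv(cos(a) * u - sin(a) * w))
    } else {
      a <- (180 - 109.47) * pi / 180
      hs <- lapply(seq_len(nH), function(i) {
        phi <- 2 * pi * (i - 1) / 3
        xyz + L * unitv(cos(a) * u + sin(a) * (cos(phi) * p + sin(phi) * q))
      })
    }
  } else if (k == 2) {
    u1 <- unitv(xyz - nbr_xyz[1, ]); u2 <- unitv(xyz - nbr_xyz[2, ])
    bis <- unitv(u1 + u2)
    if (hyb == "sp2" || nH == 1) {
      hs <- list(xyz + L * bis)
      if (nH == 2) {
        perp <- unitv(vcross(u1, u2))
        a <- 54.75 * pi / 180
        hs <- list(xyz + L * unitv(cos(a) * bis + sin(a) * perp),
                   xyz + L * unitv(cos(a) * bis - sin(a) * perp))
      }
    } else {
      perp <- unitv(vcross(u1, u2))
      a <- 54.75 * pi / 180
      hs <- list(xyz + L * unitv(cos(a) * bis + sin(a) * perp),
                 xyz + L * unitv(cos(a) * bis - sin(a) * perp))[seq_len(nH)]
    }
  } else {
    bis <- unitv(unitv(xyz - nbr_xyz[1, ]) + unitv(xyz - nbr_xyz[2, ]) +
                   unitv(xyz - nbr_xyz[3, ]))
    hs <- list(xyz + L * bis)[seq_len(nH)]
  }
  hs
}

h_names <- function(heavy_name, n) {
  if (n == 1) paste0("H", heavy_name) else paste0("H", heavy_name, seq_len(n))
}

# complete one residue's retained heavy atoms with idealized hydrogens.
# m: named coordinate matrix of retained heavy atoms; comp: residue code.
# extra_nH: named additions to the dictionary hydrogen counts.
add_hydrogens <- function(m, comp, extra_nH = integer()) {
  spec <- residue_spec(comp)
  out <- list()
  for (nm in rownames(m)) {
    i <- match(nm, spec$atoms$name)
    if (is.na(i) && nm != "C3M") next
    if (nm == "C3M") {          # 3'-methyl cap: sp3 carbon bonded to C3'
      nbrs <- intersect("C3'", rownames(m))
      nH <- 3L; hyb <- "sp3"; elem <- "C"
    } else {
      nbrs_all <- atom_neighbors(comp, nm)
      nbrs <- intersect(nbrs_all, rownames(m))
      nH <- spec$atoms$nH[i] + length(setdiff(nbrs_all, nbrs)) +
        (if (nm %in% names(extra_nH)) extra_nH[[nm]] else 0L)
      hyb <- spec$atoms$hyb[i]; elem <- spec$atoms$elem[i]
    }
    if (nH <= 0) next
    hs <- hydrogens_for_atom(m[nm, ], m[nbrs, , drop = FALSE], nH, hyb, elem)
    if (is.null(hs)) next
    hn <- h_names(nm, length(hs))
    for (j in seq_along(hs)) {
      out[[length(out) + 1L]] <- data.frame(name = hn[j], elem = "H",
                                            x = hs[[j]][1], y = hs[[j]][2],
                                            z = hs[[j]][3], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# --- capping ----------------------------------------------------------------

PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P")

#' Cap a nucleoside for quantum-chemistry models
#'
#' Removes the phosphate and O5' so that C5' becomes a methyl group, and caps
#' the 3' terminus: by default O3' is deleted and C3' saturated with
#' hydrogens; alternatively (\code{three_prime = "methyl"}) O3' is replaced by
#' a carbon, turning the 3'-OH into a methyl substituent.
#'
#' @param m named coordinate matrix of the residue's heavy atoms.
#' @param comp residue code.
#' @param three_prime "trim" (default) or "methyl".
#' @return list(m = capped heavy-atom matrix, renamed = renames applied).
#' @export
cap_nucleoside <- function(m, comp, three_prime = c("trim", "methyl")) {
  three_prime <- match.arg(three_prime)
  if (!"C5'" %in% rownames(m)) stop("residue lacks ribose atom C5'")
  drop <- intersect(rownames(m), c(PHOSPHATE_ATOMS, "O5'"))
  m <- m[setdiff(rownames(m), drop), , drop = FALSE]
  if (three_prime == "trim") {
    m <- m[setdiff(rownames(m), "O3'"), , drop = FALSE]
  } else if ("O3'" %in% rownames(m)) {
    # O3' -> carbon, rescaled to a C-C bond
    v <- m["O3'", ] - m["C3'", ]
    m["O3'", ] <- m["C3'", ] + unitv(v) * 1.53
    rownames(m)[rownames(m) == "O3'"] <- "C3M"
  }
  m
}

# --- fragment assembly ------------------------------------------------------

residue_fragment_atoms <- function(structure, key, comp, with_ribose,
                                   three_prime = "trim") {
  m <- residue_xyz(structure, key)
  m <- m[intersect(rownames(m), residue_spec(comp)$atoms$name), , drop = FALSE]
  if (!"C1'" %in% rownames(m)) stop("residue ", key, " is missing C1'")
  spec <- residue_spec(comp)
  base <- intersect(rownames(m), base_atom_names(comp))
  extra <- integer()
  if (with_ribose) {
    keep <- c(base, intersect(rownames(m), spec$atoms$name[spec$atoms$moiety == "sugar"]))
    m <- cap_nucleoside(m[keep, , drop = FALSE], comp, three_prime)
    if ("C3M" %in% rownames(m)) extra <- c(extra, C3M = 3L)
  } else {
    m <- m[c(base, "C1'"), , drop = FALSE]
  }
  hs <- add_hydrogens(m, comp, extra)
  at <- data.frame(name = rownames(m),
                   elem = spec$atoms$elem[match(rownames(m), spec$atoms$name)],
                   x = m[, 1], y = m[, 2], z = m[, 3], stringsAsFactors = FALSE)
  at$elem[at$name == "C3M"] <- "C"
  rbind(at, hs)
}

#' Build a QM-ready model fragment of an annotated base pair
#'
#' Truncates base-only residues at C1' (kept as a methyl carbon), retains and
#' caps the ribose of residues whose 2'-OH participates in the pair's
#' H-bonding, includes bridging waters from the annotation, and completes the
#' model with idealized hydrogens.  The fragment's net charge is the sum of
#' the component base charges.
#'
#' @param annotation a \code{BasePairAnnotation}.
#' @param structure the Structure it came from.
#' @param include_ribose_for optional character vector of residue keys whose
#'   ribose should be retained regardless of the H-bond pattern.
#' @param three_prime 3'-capping rule, see \code{\link{cap_nucleoside}}.
#' @return a \code{Fragment}.
#' @export
build_pair_model <- function(annotation, structure, include_ribose_for = NULL,
                             three_prime = "trim") {
  stopifnot(is_pair(annotation))
  keys <- c(annotation$res1, annotation$res2)
  comps <- c(annotation$comp1, annotation$comp2)
  hb <- annotation$hbonds
  rows <- list()
  charge <- 0L
  ribose_any <- FALSE
  for (i in 1:2) {
    ribose <- keys[i] %in% include_ribose_for ||
      any(hb$kind == "base_ribose" &
            ((hb$donor_res == keys[i] & hb$donor_atom == "O2'") |
               (hb$acceptor_res == keys[i] & hb$acceptor_atom == "O2'")))
    ribose_any <- ribose_any || ribose
    at <- residue_fragment_atoms(structure, keys[i], comps[i], ribose, three_prime)
    at$res <- i
    at$comp <- comps[i]
    rows[[i]] <- at
    charge <- charge + residue_spec(comps[i])$charge
  }
  nwat <- 0L
  if (nrow(annotation$bridges)) {
    for (wk in unique(annotation$bridges$bridge_water)) {
      nwat <- nwat + 1L
      o <- atom_xyz(structure, wk, "O")
      anchors <- annotation$bridges[annotation$bridges$bridge_water == wk, , drop = FALSE]
      hpos <- list()
      for (j in seq_len(min(2, nrow(anchors)))) {
        tgt <- atom_xyz(structure, anchors$acceptor_res[j], anchors$acceptor_atom[j])
        hpos[[j]] <- o + 0.96 * unitv(tgt - o)
      }
      wat <- data.frame(name = c("O", paste0("H", seq_along(hpos))),
                        elem = c("O", rep("H", length(hpos))),
                        x = c(o[1], vapply(hpos, `[`, 0, 1)),
                        y = c(o[2], vapply(hpos, `[`, 0, 2)),
                        z = c(o[3], vapply(hpos, `[`, 0, 3)),
                        res = 2L + nwat, comp = "HOH", stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- wat
    }
  }
  atoms <- do.call(rbind, rows)[, c("res", "comp", "name", "elem", "x", "y", "z")]
  rownames(atoms) <- NULL
  new_fragment(atoms, name = annotation$pair_key, net_charge = charge,
               provenance = list(res1 = keys[1], res2 = keys[2],
                                 structure = structure$id,
                                 three_prime = three_prime),
               includes_ribose = ribose_any, waters = nwat)
}

#' Replace modified bases by their unmodified parents
#'
#' Generates the unmodified counterpart of a fragment while preserving the
#' H-bonding pattern: every atom shared between the modified base and its
#' parent keeps the fragment's coordinates through the correspondence map
#' (pseudouridine uses the structural ring map, so the pair orientation is
#' preserved exactly); substituents are removed; element replacements (S4 ->
#' O4) keep the bond direction with the bond length rescaled to the parent
#' template; hydrogens are rebuilt at idealized geometry, restoring e.g. the
#' C5-H of uracil in place of a methyl.  Charges reset to the parental (zero)
#' values.  Fragments without modified residues are returned unchanged.
#'
#' @param fragment a \code{Fragment}.
#' @param which residue slots to replace (default: all modified slots).
#' @return a \code{Fragment}.
#' @export
make_unmodified_counterpart <- function(fragment, which = NULL) {
  a <- fragment$atoms
  slots <- unique(a$res[a$comp != "HOH"])
  mod_slots <- slots[vapply(slots, function(s) is_modified(a$comp[a$res == s][1]), TRUE)]
  if (is.null(which)) which <- mod_slots else which <- intersect(which, mod_slots)
  if (!length(which)) return(fragment)
  out <- list()
  charge <- 0L
  for (s in slots) {
    sa <- a[a$res == s & a$elem != "H", , drop = FALSE]
    comp <- sa$comp[1]
    m <- as.matrix(sa[, c("x", "y", "z")]); rownames(m) <- sa$name
    if (s %in% which) {
      code <- resolve_code(comp)
      par <- parent_of(code)
      map <- correspondence_map(code)
      map <- map[map$mod %in% rownames(m), , drop = FALSE]
      pm <- m[map$mod, , drop = FALSE]
      rownames(pm) <- map$parent
      if (code == "4SU" && "O4" %in% rownames(pm)) {
        v <- pm["O4", ] - pm["C4", ]
        pm["O4", ] <- pm["C4", ] + unitv(v) * template_bond_length("U", "C4", "O4")
      }
      # the 3'-methyl cap, when present, carries over untouched
      if ("C3M" %in% rownames(m)) pm <- rbind(pm, C3M = m["C3M", ])
      m <- pm
      comp <- par
    }
    extra <- integer()
    if ("C3M" %in% rownames(m)) extra <- c(extra, C3M = 3L)
    spec <- residue_spec(comp)
    ord <- order(match(rownames(m), c(spec$atoms$name, "C3M")))
    m <- m[ord, , drop = FALSE]
    hs <- add_hydrogens(m, comp, extra)
    at <- data.frame(name = rownames(m),
                     elem = spec$atoms$elem[match(rownames(m), spec$atoms$name)],
                     x = m[, 1], y = m[, 2], z = m[, 3], stringsAsFactors = FALSE)
    at$elem[at$name == "C3M"] <- "C"
    at <- rbind(at, hs)
    at$res <- s; at$comp <- comp
    out[[length(out) + 1L]] <- at
    charge <- charge + spec$charge
  }
  wat <- a[a$comp == "HOH", , drop = FALSE]
  if (nrow(wat)) out[[length(out) + 1L]] <- wat[, c("name", "elem", "x", "y", "z", "res", "comp")]
  atoms <- do.call(rbind, out)[, c("res", "comp", "name", "elem", "x", "y", "z")]
  rownames(atoms) <- NULL
  slots_syms <- vapply(slots, function(s) mod_symbol(atoms$comp[atoms$res == s][1]), "")
  new_fragment(atoms,
               name = paste0(paste(slots_syms, collapse = ":"), " (counterpart of ",
                             fragment$name, ")"),
               net_charge = charge,
               provenance = c(fragment$provenance, list(counterpart_of = fragment$name)),
               includes_ribose = fragment$includes_ribose, waters = fragment$waters)
}
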