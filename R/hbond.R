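# hbond: hydrogen-bond detection between nucleobases, between bases and the
# ribose 2'-OH, and water-bridged base-base contacts.
#
# X-ray structures typically lack hydrogens, so the criteria work on heavy
# atoms: donor...acceptor distance and the approach angle at the donor
# (covalent neighbor - donor - acceptor).  When hydrogens are present in the
# file they additionally have to satisfy a D-H...A angle cutoff.

#' Hydrogen-bond detection parameters
#'
#' @param dist_max maximum heavy-atom donor-acceptor distance (Angstrom).
#' @param dist_min minimum distance (rejects near-covalent contacts).
#' @param angle_min minimum approach angle (covalent neighbor)-D...A, degrees.
#' @param h_angle_min minimum D-H...A angle when hydrogens are present.
#' @param include_ch include weak C-H donors (off by default).
#' @param water_dist_max maximum water-O to base-atom distance for bridges.
#' @param interplane_max maximum angle between base planes for a pair.
#' @param voffset_max maximum vertical offset between base centroids along the
#'   mean plane normal (rejects stacked geometries).
#' @return a named list of thresholds.
#' @export
hbond_params <- function(dist_max = 3.5, dist_min = 2.4, angle_min = 90,
                         h_angle_min = 120, include_ch = FALSE,
                         water_dist_max = 3.5,
                         interplane_max = 70, voffset_max = 2.5) {
  stopifnot(dist_max > 0, angle_min > 0)
  list(dist_max = dist_max, dist_min = dist_min, angle_min = angle_min,
       h_angle_min = h_angle_min, include_ch = include_ch,
       water_dist_max = water_dist_max,
       interplane_max = interplane_max, voffset_max = voffset_max)
}

# H-bond capable atoms of one residue: data.frame(name, role, moiety, x, y, z)
polar_atoms <- function(structure, key, comp, include_ch = FALSE) {
  ra <- residue_atoms(structure, key)
  spec <- residue_spec(comp)
  i <- match(gsub("\\*", "'", ra$name), spec$atoms$name)
  keep <- !is.na(i)
  ra <- ra[keep, , drop = FALSE]; i <- i[keep]
  role <- spec$atoms$role[i]
  moiety <- spec$atoms$moiety[i]
  sel <- role != "none" & (moiety %in% c("base", "water") | spec$atoms$name[i] == "O2'")
  data.frame(name = gsub("\\*", "'", ra$name[sel]), role = role[sel],
             moiety = moiety[sel], x = ra$x[sel], y = ra$y[sel], z = ra$z[sel],
             stringsAsFactors = FALSE)
}

# angle criterion at the donor: every heavy covalent neighbor must be >= angle_min
donor_angle_ok <- function(structure, key, comp, donor_name, acc_xyz, params) {
  nbrs <- atom_neighbors(comp, donor_name)
  dxyz <- atom_xyz(structure, key, donor_name)
  for (nb in nbrs) {
    nxyz <- atom_xyz(structure, key, nb)
    if (is.null(nxyz)) next
    if (angle_deg(nxyz, dxyz, acc_xyz) < params$angle_min) return(FALSE)
  }
  TRUE
}

hbond_row <- function(donor_key, donor_comp, donor_atom, acc_key, acc_comp,
                      acc_atom, dist, angle, kind, bridge = NA_character_) {
  data.frame(donor_res = donor_key, donor_comp = donor_comp, donor_atom = donor_atom,
             acceptor_res = acc_key, acceptor_comp = acc_comp, acceptor_atom = acc_atom,
             distance = dist, approach_angle = angle, kind = kind,
             bridge_water = bridge, stringsAsFactors = FALSE)
}

empty_hbonds <- function() {
  hbond_row(character(), character(), character(), character(), character(),
            character(), numeric(), numeric(), character(), character())[0, ]
}

#' Detect hydrogen bonds in a structure
#'
#' Finds all donor/acceptor atom pairs between distinct nucleotide residues
#' satisfying the geometric criteria in \code{params}.  Contacts are labeled
#' \code{base_base} when both atoms belong to base moieties and
#' \code{base_ribose} when one partner is a ribose O2'.  The result is
#' deduplicated (one record per atom pair) and deterministically ordered.
#'
#' @param structure a Structure.
#' @param params see \code{\link{hbond_params}}.
#' @return data.frame of H-bonds (possibly empty).
#' @export
find_hbonds <- function(structure, params = hbond_params()) {
  rt <- residue_table(structure)
  nt <- rt[rt$kind == "nucleotide", , drop = FALSE]
  out <- list()
  if (nrow(nt) < 2) return(empty_hbonds())
  pa <- lapply(seq_len(nrow(nt)), function(i)
    polar_atoms(structure, nt$key[i], nt$comp[i], params$include_ch))
  ctr <- lapply(seq_len(nrow(nt)), function(i) {
    m <- residue_xyz(structure, nt$key[i])
    colMeans(m[intersect(rownames(m), base_atom_names(nt$comp[i])), , drop = FALSE])
  })
  for (i in seq_len(nrow(nt) - 1)) {
    for (j in (i + 1):nrow(nt)) {
      if (vnorm(ctr[[i]] - ctr[[j]]) > 15) next
      bonds <- hbonds_between(structure, nt[i, ], pa[[i]], nt[j, ], pa[[j]], params)
      if (nrow(bonds)) out[[length(out) + 1L]] <- bonds
    }
  }
  if (!length(out)) return(empty_hbonds())
  res <- do.call(rbind, out)
  res <- res[order(res$donor_res, res$donor_atom, res$acceptor_res, res$acceptor_atom), ]
  rownames(res) <- NULL
  res
}

# all H-bonds between two specific residues (both directions), deduplicated
hbonds_between <- function(structure, r1, pa1, r2, pa2, params) {
  rows <- list()
  add_dir <- function(rd, pd, ra, pa) {
    don <- pd[pd$role %in% c("donor", "both"), , drop = FALSE]
    acc <- pa[pa$role %in% c("acceptor", "both"), , drop = FALSE]
    for (di in seq_len(nrow(don))) {
      for (ai in seq_len(nrow(acc))) {
        # base-base or base-ribose (O2' on either side); skip sugar-sugar
        d_sugar <- don$moiety[di] == "sugar"; a_sugar <- acc$moiety[ai] == "sugar"
        if (d_sugar && a_sugar) next
        dxyz <- c(don$x[di], don$y[di], don$z[di])
        axyz <- c(acc$x[ai], acc$y[ai], acc$z[ai])
        d <- vnorm(dxyz - axyz)
        if (d > params$dist_max || d < params$dist_min) next
        if (!donor_angle_ok(structure, rd$key, rd$comp, don$name[di], axyz, params)) next
        ang <- approach_angle(structure, rd$key, rd$comp, don$name[di], axyz)
        kind <- if (d_sugar || a_sugar) "base_ribose" else "base_base"
        rows[[length(rows) + 1L]] <<- hbond_row(rd$key, rd$comp, don$name[di],
                                                ra$key, ra$comp, acc$name[ai],
                                                d, ang, kind)
      }
    }
  }
  add_dir(r1, pa1, r2, pa2)
  add_dir(r2, pa2, r1, pa1)
  if (!length(rows)) return(empty_hbonds())
  res <- do.call(rbind, rows)
  # one record per unordered atom pair: keep the shortest interpretation
  res <- res[order(sort_pair_key(res), res$distance), , drop = FALSE]
  res <- res[!duplicated(sort_pair_key(res)), , drop = FALSE]
  # a donor can give at most as many H-bonds as it has hydrogens
  res <- res[order(res$distance), , drop = FALSE]
  dkey <- paste(res$donor_res, res$donor_atom)
  keep <- logical(nrow(res))
  used <- integer()
  for (i in seq_len(nrow(res))) {
    cap <- donor_capacity(res$donor_comp[i], res$donor_atom[i])
    n <- if (dkey[i] %in% names(used)) used[[dkey[i]]] else 0L
    if (n < cap) { keep[i] <- TRUE; used[dkey[i]] <- n + 1L }
  }
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

donor_capacity <- function(comp, atom) {
  spec <- residue_spec(comp)
  i <- match(gsub("\\*", "'", atom), spec$atoms$name)
  if (is.na(i)) return(0L)
  max(1L, spec$atoms$nH[i])
}

sort_pair_key <- function(res) {
  apply(cbind(paste(res$donor_res, res$donor_atom),
              paste(res$acceptor_res, res$acceptor_atom)), 1,
        function(v) paste(sort(v), collapse = "::"))
}

# smallest neighbor-D...A angle (reported in the output record)
approach_angle <- function(structure, key, comp, donor_name, acc_xyz) {
  nbrs <- atom_neighbors(comp, donor_name)
  dxyz <- atom_xyz(structure, key, donor_name)
  angs <- c()
  for (nb in nbrs) {
    nxyz <- atom_xyz(structure, key, nb)
    if (!is.null(nxyz)) angs <- c(angs, angle_deg(nxyz, dxyz, acc_xyz))
  }
  if (!length(angs)) return(NA_real_)
  min(angs)
}

#' Find waters bridging two nucleotides
#'
#' A water qualifies when its oxygen lies within \code{water_dist_max} of at
#' least one base atom of each residue (donor/acceptor capable atoms only).
#'
#' @param structure a Structure.
#' @param key1,key2 residue keys ("chain|resno|icode").
#' @param params see \code{\link{hbond_params}}.
#' @return data.frame of water-bridge records (kind \code{water_bridge}); the
#'   \code{bridge_water} column holds the water residue key.
#' @export
find_bridging_waters <- function(structure, key1, key2, params = hbond_params()) {
  rt <- residue_table(structure)
  waters <- rt[rt$kind == "water", , drop = FALSE]
  if (!nrow(waters)) return(empty_hbonds())
  comp1 <- rt$comp[rt$key == key1]; comp2 <- rt$comp[rt$key == key2]
  pa1 <- polar_atoms(structure, key1, comp1)
  pa1 <- pa1[pa1$moiety == "base", , drop = FALSE]
  pa2 <- polar_atoms(structure, key2, comp2)
  pa2 <- pa2[pa2$moiety == "base", , drop = FALSE]
  out <- list()
  for (w in seq_len(nrow(waters))) {
    oxyz <- atom_xyz(structure, waters$key[w], "O")
    if (is.null(oxyz)) next
    close_atoms <- function(pa) {
      d <- sqrt((pa$x - oxyz[1])^2 + (pa$y - oxyz[2])^2 + (pa$z - oxyz[3])^2)
      pa[d <= params$water_dist_max & d >= params$dist_min, , drop = FALSE]
    }
    c1 <- close_atoms(pa1); c2 <- close_atoms(pa2)
    if (nrow(c1) && nrow(c2)) {
      for (k in seq_len(nrow(c1))) {
        d <- vnorm(c(c1$x[k], c1$y[k], c1$z[k]) - oxyz)
        out[[length(out) + 1L]] <- hbond_row(waters$key[w], "HOH", "O",
                                             key1, comp1, c1$name[k], d, NA_real_,
                                             "water_bridge", waters$key[w])
      }
      for (k in seq_len(nrow(c2))) {
        d <- vnorm(c(c2$x[k], c2$y[k], c2$z[k]) - oxyz)
        out[[length(out) + 1L]] <- hbond_row(waters$key[w], "HOH", "O",
                                             key2, comp2, c2$name[k], d, NA_real_,
                                             "water_bridge", waters$key[w])
      }
    }
  }
  if (!length(out)) return(empty_hbonds())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
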