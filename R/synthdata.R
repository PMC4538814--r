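# synthdata: idealized synthetic base-pair structures for every atlas pair
# type.  Base 1 sits at the origin in its template frame; base 2 is posed by a
# constrained rigid-body fit that satisfies the recipe's donor-acceptor
# distances (soft auxiliary constraints keep the approach angles realistic).
# Every solved pose is self-checked: the generated structure must reproduce
# exactly the recipe's H-bond set and geometry string when run through
# find_hbonds/classify_pair.  Poses are cached per recipe.
#
# Residues are base + C1' models; the full ribose is included for a residue
# whenever its 2'-OH takes part in the pairing.

bond_spec <- function(res_d, atom_d, res_a, atom_a, dist = 2.9, ang = 125,
                      w = 100) {
  data.frame(res_d = res_d, atom_d = atom_d, res_a = res_a, atom_a = atom_a,
             dist = dist, ang = ang, w = w, stringsAsFactors = FALSE)
}

aux_spec <- function(atom1, atom2, dist, w = 20) {
  data.frame(atom1 = atom1, atom2 = atom2, dist = dist, w = w,
             stringsAsFactors = FALSE)
}

recipe <- function(base1, base2, geometry, bonds, water = NULL,
                   ribose1 = FALSE, ribose2 = FALSE, aux = NULL, tilt = FALSE,
                   solver = "optim", key_geometry = geometry) {
  # key_geometry: the atlas type this recipe stands for; `geometry` is the
  # label the generated structure actually classifies to.  They differ for a
  # single contradictory published type (see the vignette).
  key <- paste0(mod_symbol(base1), ":", mod_symbol(base2), " ", key_geometry)
  list(key = key, base1 = base1, base2 = base2, geometry = geometry,
       key_geometry = key_geometry,
       bonds = do.call(rbind, bonds), water = water,
       ribose1 = ribose1, ribose2 = ribose2, aux = aux, tilt = tilt,
       solver = solver)
}

#' The atlas recipe library
#'
#' One synthetic-structure recipe per atlas pair type: base combination,
#' geometry string, donor/acceptor atom pattern with target distances
#' (2.9 Angstrom default; 3.3 for sulfur acceptors), bridging-water anchors
#' and ribose participation.
#'
#' @return named list of recipes keyed by pair type
#'   (e.g. \code{"m1A:U tHW(w)"}).
#' @export
atlas_recipes <- function() {
  if (!is.null(.modbp$recipes)) return(.modbp$recipes)
  r <- list(
    recipe("1MA", "A", "tHW", list(bond_spec(2, "N6", 1, "N7"),
                                   bond_spec(1, "N6", 2, "N1"))),
    recipe("1MA", "U", "tHW(w)", list(bond_spec(2, "N3", 1, "N7")),
           water = list(c(1, "N6"), c(2, "O2")),
           aux = aux_spec("N6", "O2", 4.9)),
    recipe("1MA", "U", "tHW", list(bond_spec(2, "N3", 1, "N7"),
                                   bond_spec(1, "N6", 2, "O2"))),
    recipe("1MA", "5MU", "tHW", list(bond_spec(2, "N3", 1, "N7"),
                                     bond_spec(1, "N6", 2, "O2"))),
    recipe("6MZ", "G", "tS(w)S(r)", list(bond_spec(2, "N2", 1, "N3"),
                                         bond_spec(2, "O2'", 1, "N1")),
           ribose2 = TRUE),
    recipe("1MG", "C", "tHH1", list(bond_spec(2, "N4", 1, "N7"))),
    recipe("2MG", "U", "cWW", list(bond_spec(2, "N3", 1, "O6", 2.85),
                                   bond_spec(1, "N1", 2, "O2", 2.85))),
    recipe("2MG", "C", "cWW", list(bond_spec(2, "N4", 1, "O6", 2.91),
                                   bond_spec(1, "N1", 2, "N3", 2.98),
                                   bond_spec(1, "N2", 2, "O2", 2.9, w = 20))),
    recipe("2MG", "C", "cWW1", list(bond_spec(1, "N1", 2, "O2"))),
    recipe("M2G", "A", "cWW", list(bond_spec(1, "N1", 2, "N1"),
                                   bond_spec(2, "N6", 1, "O6"))),
    recipe("7MG", "C", "cWW", list(bond_spec(2, "N4", 1, "O6", 2.91),
                                   bond_spec(1, "N1", 2, "N3", 2.98),
                                   bond_spec(1, "N2", 2, "O2", 2.86))),
    recipe("7MG", "G", "tWH", list(bond_spec(1, "N1", 2, "N7"),
                                   bond_spec(1, "N2", 2, "O6"))),
    recipe("5MC", "G", "cWW", list(bond_spec(1, "N4", 2, "O6", 2.91),
                                   bond_spec(2, "N1", 1, "N3", 2.98),
                                   bond_spec(2, "N2", 1, "O2", 2.86))),
    recipe("5MC", "G", "tWW", list(bond_spec(2, "N1", 1, "O2"),
                                   bond_spec(2, "N2", 1, "N3"))),
    recipe("5MU", "A", "tWH", list(bond_spec(1, "N3", 2, "N7"),
                                   bond_spec(2, "N6", 1, "O2"))),
    recipe("5MU", "G", "tWH1", list(bond_spec(1, "N3", 2, "N7"))),
    recipe("5MU", "G", "cWW", list(bond_spec(1, "N3", 2, "O6", 2.85),
                                   bond_spec(2, "N1", 1, "O2", 2.85))),
    recipe("4SU", "A", "tWH", list(bond_spec(1, "N3", 2, "N7"),
                                   bond_spec(2, "N6", 1, "O2"))),
    recipe("H2U", "U", "tWW", list(bond_spec(1, "N3", 2, "O4"),
                                   bond_spec(2, "N3", 1, "O4"))),
    recipe("H2U", "G", "cHS1", list(bond_spec(2, "N2", 1, "O4")),
           aux = rbind(aux_spec("C1'", "C1'", 6.3, w = 10),
                       aux_spec("O4", "N3", 3.4, w = 10))),
    recipe("H2U", "G", "tWS", list(bond_spec(1, "N3", 2, "N3", 3.31),
                                   bond_spec(2, "N2", 1, "O2", 2.76)),
           solver = "enum"),
    recipe("PSU", "A", "cWW", list(bond_spec(1, "N3", 2, "N1"),
                                   bond_spec(2, "N6", 1, "O2"))),
    recipe("PSU", "A", "cHW", list(bond_spec(1, "N1", 2, "N1"),
                                   bond_spec(2, "N6", 1, "O2"))),
    recipe("PSU", "U", "tWW", list(bond_spec(1, "N3", 2, "O4"),
                                   bond_spec(2, "N3", 1, "O2"))),
    recipe("PSU", "G", "tBsW", list(bond_spec(2, "N1", 1, "O4", 2.9, ang = 101),
                                    bond_spec(2, "N2", 1, "O4", 3.05, ang = 96))),
    recipe("PSU", "G", "cWW", list(bond_spec(1, "N3", 2, "O6", 2.85),
                                   bond_spec(2, "N1", 1, "O4", 2.85))),
    recipe("PSU", "C", "cS(r)W", list(bond_spec(2, "N4", 1, "O4"),
                                      bond_spec(1, "O2'", 2, "O2")),
           ribose1 = TRUE),
    recipe("CBR", "G", "cWW", list(bond_spec(1, "N4", 2, "O6", 2.91),
                                   bond_spec(2, "N1", 1, "N3", 2.98),
                                   bond_spec(2, "N2", 1, "O2", 2.86))),
    recipe("5BU", "A", "cWW", list(bond_spec(1, "N3", 2, "N1"),
                                   bond_spec(2, "N6", 1, "O4"))),
    recipe("5BU", "G", "cWW", list(bond_spec(1, "N3", 2, "O6", 2.85),
                                   bond_spec(2, "N1", 1, "O2", 2.85))),
    recipe("5BU", "5BU", "cWW", list(bond_spec(1, "N3", 2, "O4"),
                                     bond_spec(2, "N3", 1, "O2"))),
    recipe("5BU", "A", "cWH", list(bond_spec(1, "N3", 2, "N7"),
                                   bond_spec(2, "N6", 1, "O4"))),
    recipe("5BU", "A", "cS(r)H", list(bond_spec(2, "N6", 1, "O2"),
                                      bond_spec(1, "O2'", 2, "N7")),
           ribose1 = TRUE),
    recipe("5BU", "A", "tW(r)S", list(bond_spec(1, "N3", 2, "N3", 2.9),
                                      bond_spec(2, "N6", 1, "O2'", 2.9)),
           ribose1 = TRUE, tilt = TRUE, solver = "enum",
           key_geometry = "cW(r)S"),
    recipe("5IU", "A", "cWW", list(bond_spec(1, "N3", 2, "N1"),
                                   bond_spec(2, "N6", 1, "O4"))),
    recipe("5IU", "G", "cWW", list(bond_spec(1, "N3", 2, "O6", 2.85),
                                   bond_spec(2, "N1", 1, "O2", 2.85)))
  )
  names(r) <- vapply(r, `[[`, "", "key")
  .modbp$recipes <- r
  r
}

# atoms included for a residue of one recipe side
recipe_residue_atoms <- function(code, with_ribose) {
  spec <- residue_spec(code)
  keep <- spec$atoms$moiety == "base" |
    (if (with_ribose) spec$atoms$moiety == "sugar" else spec$atoms$name == "C1'")
  spec$atoms[keep, , drop = FALSE]
}

# rigid pose: optional flip (pi rotation about x), optional small tilts about
# x/y (used only by recipes that need an out-of-plane partner), rotation theta
# about z, then translation (tz nonzero only for tilted recipes)
pose_coords <- function(m, flip, theta, tx, ty, tz = 0, rx = 0, ry = 0) {
  out <- m
  if (flip) { out[, 2] <- -out[, 2]; out[, 3] <- -out[, 3] }
  if (rx != 0 || ry != 0) {
    R <- rotation_about_axis(c(0, 1, 0), ry) %*% rotation_about_axis(c(1, 0, 0), rx)
    out <- out %*% t(R)
  }
  ct <- cos(theta); st <- sin(theta)
  xr <- ct * out[, 1] - st * out[, 2]
  yr <- st * out[, 1] + ct * out[, 2]
  out[, 1] <- xr + tx; out[, 2] <- yr + ty; out[, 3] <- out[, 3] + tz
  out
}

# assemble a Structure from posed coordinate matrices
assemble_structure <- function(rec, m1, m2, water_xyz = NULL, id = "synthetic",
                               resolution = 2.0) {
  mk <- function(m, code, resno) {
    spec <- residue_spec(code)
    nm <- rownames(m)
    i <- match(nm, spec$atoms$name)
    data.frame(record = if (is_modified(code)) "HETATM" else "ATOM",
               chain = "A", resno = resno, icode = "", comp = code,
               name = nm, elem = spec$atoms$elem[i],
               x = m[, 1], y = m[, 2], z = m[, 3],
               altloc = "", occ = 1, stringsAsFactors = FALSE)
  }
  atoms <- rbind(mk(m1, rec$base1, 1L), mk(m2, rec$base2, 2L))
  if (!is.null(water_xyz)) {
    atoms <- rbind(atoms, data.frame(
      record = "HETATM", chain = "A", resno = 3L, icode = "", comp = "HOH",
      name = "O", elem = "O", x = water_xyz[1], y = water_xyz[2], z = water_xyz[3],
      altloc = "", occ = 1, stringsAsFactors = FALSE))
  }
  rownames(atoms) <- NULL
  new_structure(atoms, id = id, resolution = resolution)
}

# in-plane bridging-water placement: circle intersection around both anchors
place_water <- function(rec, m1, m2, r = 2.85) {
  a1 <- rec$water[[1]]; a2 <- rec$water[[2]]
  p1 <- (if (as.integer(a1[1]) == 1) m1 else m2)[a1[2], 1:2]
  p2 <- (if (as.integer(a2[1]) == 1) m1 else m2)[a2[2], 1:2]
  d <- vnorm(p1 - p2)
  if (d >= 2 * r || d < 0.5) return(NULL)
  mid <- (p1 + p2) / 2
  h <- sqrt(r^2 - (d / 2)^2)
  u <- (p2 - p1) / d
  perp <- c(-u[2], u[1])
  cand <- list(c(mid + h * perp, 0), c(mid - h * perp, 0))
  ctr <- c(colMeans(rbind(m1, m2))[1:2], 0)
  cand <- cand[order(-vapply(cand, function(p) vnorm(p - ctr), 0))]
  allxyz <- rbind(m1, m2)
  for (p in cand) {
    dmin <- min(sqrt(rowSums(sweep(allxyz, 2, p)^2)))
    if (dmin >= 2.4) return(p)
  }
  NULL
}

# rotate the sugar moiety about the glycosidic bond (C1'-glyc axis); the
# glycosidic torsion is a genuine conformational degree of freedom used by
# the solver when a recipe involves the ribose 2'-OH
rotate_sugar <- function(m, code, chi) {
  if (chi == 0) return(m)
  spec <- residue_spec(code)
  sug <- setdiff(intersect(rownames(m), spec$atoms$name[spec$atoms$moiety == "sugar"]),
                 "C1'")
  if (!length(sug)) return(m)
  g <- m[glyc_atom_of(code), ]; c1 <- m["C1'", ]
  R <- rotation_about_axis(c1 - g, chi)
  m[sug, ] <- sweep(sweep(m[sug, , drop = FALSE], 2, c1) %*% t(R), 2, -c1)
  m
}

# solve (and cache) the idealized pose for one recipe.
# Parameters: theta/tx/ty (+ optional flip) pose base 2 in the base-1 plane;
# chi1/chi2 rotate the sugars of ribose-involving residues about their
# glycosidic bonds.  Two-stage optimization: a soft stage with approach-angle
# auxiliaries and a steric repulsion escaping overlapped minima, then a
# refinement stage that drives the hard H-bond distances to their targets.
# Every accepted pose must reproduce the recipe's H-bond set and geometry
# string exactly (pose_self_check).
solve_recipe_pose <- function(rec) {
  key <- rec$key
  if (!is.null(.modbp$pose_cache[[key]])) return(.modbp$pose_cache[[key]])
  at1 <- recipe_residue_atoms(rec$base1, rec$ribose1)
  at2 <- recipe_residue_atoms(rec$base2, rec$ribose2)
  m10 <- as.matrix(at1[, c("x", "y", "z")]); rownames(m10) <- at1$name
  m20 <- as.matrix(at2[, c("x", "y", "z")]); rownames(m20) <- at2$name
  bonds <- rec$bonds
  chi1_on <- isTRUE(rec$ribose1); chi2_on <- isTRUE(rec$ribose2)

  aux_target <- function(r_nb, d, ang) {
    sqrt(r_nb^2 + d^2 - 2 * r_nb * d * cos(ang * pi / 180))
  }
  # constraints as (atom on res1, atom on res2, target, weight)
  cons <- list()
  add_con <- function(a1, a2, d, w) {
    cons[[length(cons) + 1L]] <<- data.frame(a1 = a1, a2 = a2, d = d, w = w,
                                             stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(bonds))) {
    d <- bonds$dist[i]; ang <- bonds$ang[i]
    if (bonds$res_d[i] == 1) { a1 <- bonds$atom_d[i]; a2 <- bonds$atom_a[i] }
    else { a1 <- bonds$atom_a[i]; a2 <- bonds$atom_d[i] }
    add_con(a1, a2, d, bonds$w[i])
    for (nb in intersect(atom_neighbors(rec$base1, a1), rownames(m10))) {
      add_con(nb, a2, aux_target(vnorm(m10[nb, ] - m10[a1, ]), d, ang), 1)
    }
    for (nb in intersect(atom_neighbors(rec$base2, a2), rownames(m20))) {
      add_con(a1, nb, aux_target(vnorm(m20[nb, ] - m20[a2, ]), d, ang), 1)
    }
  }
  if (!is.null(rec$aux)) {
    for (i in seq_len(nrow(rec$aux))) {
      add_con(rec$aux$atom1[i], rec$aux$atom2[i], rec$aux$dist[i], rec$aux$w[i])
    }
  }
  cons <- do.call(rbind, cons)
  hard <- cons$w >= 100
  I1 <- match(cons$a1, rownames(m10)); I2 <- match(cons$a2, rownames(m20))

  coords1 <- function(chi1) rotate_sugar(m10, rec$base1, chi1)
  coords2 <- function(flip, theta, tx, ty, tz, rx, ry, chi2) {
    pose_coords(rotate_sugar(m20, rec$base2, chi2), flip, theta, tx, ty, tz, rx, ry)
  }
  decode <- function(par) {
    i <- 4L
    tz <- 0; rx <- 0; ry <- 0
    if (tilt_on) { tz <- par[i]; rx <- par[i + 1]; ry <- par[i + 2]; i <- i + 3L }
    chi1 <- if (chi1_on) { v <- par[i]; i <- i + 1L; v } else 0
    chi2 <- if (chi2_on) par[i] else 0
    list(theta = par[1], tx = par[2], ty = par[3], tz = tz, rx = rx, ry = ry,
         chi1 = chi1, chi2 = chi2)
  }
  eval_pose <- function(par, flip) {
    p <- decode(par)
    m1 <- coords1(p$chi1)
    m2 <- coords2(flip, p$theta, p$tx, p$ty, p$tz, p$rx, p$ry, p$chi2)
    list(m1 = m1, m2 = m2)
  }
  resids <- function(cm) {
    sqrt(rowSums((cm$m1[I1, , drop = FALSE] - cm$m2[I2, , drop = FALSE])^2)) - cons$d
  }
  clash_penalty <- function(cm) {
    dx <- outer(cm$m1[, 1], cm$m2[, 1], "-")
    dy <- outer(cm$m1[, 2], cm$m2[, 2], "-")
    dz <- outer(cm$m1[, 3], cm$m2[, 3], "-")
    dd <- sqrt(dx^2 + dy^2 + dz^2)
    sum(pmax(0, 2.7 - dd)^2) * 50
  }
  objective <- function(par, flip, hard_w = 100, with_clash = TRUE) {
    cm <- eval_pose(par, flip)
    r <- resids(cm)
    w <- ifelse(hard, hard_w, cons$w)
    sum(w * r^2) + if (with_clash) clash_penalty(cm) else 0
  }
  hard_resid <- function(par, flip) {
    max(abs(resids(eval_pose(par, flip))[hard]))
  }

  first <- which(hard)[1]
  aname1 <- cons$a1[first]; aname2 <- cons$a2[first]
  ctr1 <- colMeans(m10[intersect(rownames(m10), base_atom_names(rec$base1)), , drop = FALSE])
  outward <- unitv(c((m10[aname1, ] - ctr1)[1:2], 0))
  if (identical(rec$solver, "enum")) {
    best <- solve_enum_pose(rec, m10, m20)
    .modbp$pose_cache[[key]] <- best
    return(best)
  }
  tilt_on <- isTRUE(rec$tilt)
  chi_grid <- if (chi1_on || chi2_on) {
    seq(0, 2 * pi, length.out = if (tilt_on) 5 else 7)[-(if (tilt_on) 5 else 7)]
  } else 0
  tilt_grid <- if (tilt_on) {
    rbind(c(0, 0), c(0.7, 0), c(-0.7, 0), c(0, 0.7), c(0, -0.7))
  } else matrix(0, 1, 2)
  best <- NULL
  log <- character()
  for (flip in c(FALSE, TRUE)) {
    for (th0 in seq(0, 2 * pi, length.out = 13)[-13]) {
      for (chi0 in chi_grid) {
       for (ti in seq_len(nrow(tilt_grid))) {
        tilt0 <- tilt_grid[ti, ]
        b0 <- pose_coords(m20, flip, th0, 0, 0)[aname2, ]
        t0 <- m10[aname1, ] + cons$d[first] * outward - b0
        par <- c(th0, t0[1], t0[2])
        if (tilt_on) par <- c(par, 0, tilt0[1], tilt0[2])
        if (chi1_on) par <- c(par, chi0)
        if (chi2_on) par <- c(par, chi0)
        opt <- stats::optim(par, objective, flip = flip, method = "Nelder-Mead",
                            control = list(maxit = 1000, reltol = 1e-12))
        opt <- stats::optim(opt$par, objective, flip = flip, hard_w = 1e4,
                            method = "Nelder-Mead",
                            control = list(maxit = 600, reltol = 1e-12))
        if (hard_resid(opt$par, flip) > 0.05) {
          # final polish: hard constraints only (steric acceptability is
          # re-checked below on the polished pose)
          opt <- stats::optim(opt$par, objective, flip = flip, hard_w = 1e4,
                              with_clash = FALSE, method = "Nelder-Mead",
                              control = list(maxit = 400, reltol = 1e-12))
        }
        tag <- sprintf("flip=%d th0=%.2f chi0=%.2f", flip, th0, chi0)
        hr <- hard_resid(opt$par, flip)
        if (hr > 0.05) { log <- c(log, paste(tag, "hard", round(hr, 3))); next }
        cm <- eval_pose(opt$par, flip)
        dmat <- sqrt(outer(cm$m1[, 1], cm$m2[, 1], "-")^2 +
                       outer(cm$m1[, 2], cm$m2[, 2], "-")^2 +
                       outer(cm$m1[, 3], cm$m2[, 3], "-")^2)
        if (min(dmat) < 2.3) { log <- c(log, paste(tag, "clash", round(min(dmat), 2))); next }
        wxyz <- if (!is.null(rec$water)) place_water(rec, cm$m1, cm$m2) else NULL
        if (!is.null(rec$water) && is.null(wxyz)) { log <- c(log, paste(tag, "water")); next }
        st <- assemble_structure(rec, cm$m1, cm$m2, wxyz)
        chk <- pose_self_check(rec, st, verbose = TRUE)
        if (!isTRUE(chk)) { log <- c(log, paste(tag, "selfcheck:", chk)); next }
        best <- list(value = opt$value, m1 = cm$m1, m2 = cm$m2, water = wxyz)
        break
       }
       if (!is.null(best)) break
      }
      if (!is.null(best)) break
    }
    if (!is.null(best)) break
  }
  .modbp$last_solve_log <- log
  if (is.null(best)) stop("unsatisfiable H-bond pattern for pair type ", key)
  .modbp$pose_cache[[key]] <- best
  best
}

# the generated structure must reproduce the recipe exactly
pose_self_check <- function(rec, st, verbose = FALSE) {
  hb <- find_hbonds(st)
  direct <- hb[hb$kind %in% c("base_base", "base_ribose"), , drop = FALSE]
  got <- sort(paste(sub("^A\\|", "", direct$donor_res), direct$donor_atom, "->",
                    sub("^A\\|", "", direct$acceptor_res), direct$acceptor_atom))
  want <- sort(paste(paste0(rec$bonds$res_d, "|"), rec$bonds$atom_d, "->",
                     paste0(rec$bonds$res_a, "|"), rec$bonds$atom_a))
  if (!identical(got, want)) {
    if (verbose) return(paste("bonds", paste(got, collapse = ";"), "!=",
                              paste(want, collapse = ";")))
    return(FALSE)
  }
  ann <- classify_pair(st, "A|1|", "A|2|", hbonds = hb)
  if (!is_pair(ann)) {
    if (verbose) return(paste("notapair:", ann$reason))
    return(FALSE)
  }
  ok <- identical(ann$geometry, rec$geometry) &&
    (is.null(rec$water) == !ann$label$water)
  if (!ok && verbose) return(paste("geom", ann$geometry, "!=", rec$geometry))
  ok
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate an idealized synthetic base pair
#'
#' Poses the two bases so that every target H-bond distance in the recipe is
#' satisfied (within 0.05 Angstrom) with the bases coplanar, optionally
#' applies a propeller twist about the contact axis, places a bridging water
#' when the recipe asks for one, and adds seeded Gaussian coordinate noise to
#' the heavy atoms.
#'
#' @param type pair-type key (see \code{\link{atlas_recipes}}), or a recipe.
#' @param noise_sigma per-coordinate Gaussian noise (Angstrom).
#' @param seed integer seed controlling all randomness.
#' @param resolution declared resolution written to the output header.
#' @param propeller_twist degrees of twist applied to base 2 about the axis
#'   through the two contact atoms of the first H-bond.
#' @return a \code{Structure}.
#' @export
generate_pair <- function(type, noise_sigma = 0, seed = 1, resolution = 2.0,
                          propeller_twist = 0) {
  rec <- if (is.list(type)) type else atlas_recipes()[[type]]
  if (is.null(rec)) stop("unknown pair type: ", type)
  pose <- solve_recipe_pose(rec)
  m1 <- pose$m1; m2 <- pose$m2; wxyz <- pose$water
  if (propeller_twist != 0) {
    b1 <- rec$bonds[1, ]
    p_fix <- (if (b1$res_d == 1) m1[b1$atom_d, ] else m1[b1$atom_a, ])
    p_mov <- (if (b1$res_d == 2) m2[b1$atom_d, ] else m2[b1$atom_a, ])
    R <- rotation_about_axis(p_mov - p_fix, propeller_twist * pi / 180)
    m2 <- sweep(sweep(m2, 2, p_fix) %*% t(R), 2, -p_fix)
  }
  if (noise_sigma > 0) {
    with_seed(seed, {
      m1 <- m1 + matrix(stats::rnorm(length(m1), 0, noise_sigma), ncol = 3)
      m2 <- m2 + matrix(stats::rnorm(length(m2), 0, noise_sigma), ncol = 3)
      if (!is.null(wxyz)) wxyz <- wxyz + stats::rnorm(3, 0, noise_sigma)
    })
  }
  id <- sprintf("synth_%s_s%d", gsub("[^A-Za-z0-9]+", "_", rec$key), seed)
  assemble_structure(rec, m1, m2, wxyz, id = id, resolution = resolution)
}

#' Generate a set of synthetic structures with known ground truth
#'
#' @param type_counts named integer vector: pair-type key -> number of
#'   instances.
#' @param seed integer seed; instance seeds and declared resolutions derive
#'   from it deterministically.
#' @param noise_sigma per-coordinate noise passed to each instance.
#' @return list(structures = list of Structure, manifest = data.frame with
#'   columns id, type, resolution).
#' @export
generate_structure_set <- function(type_counts, seed = 1, noise_sigma = 0) {
  recs <- atlas_recipes()
  unknown <- setdiff(names(type_counts), names(recs))
  if (length(unknown)) stop("unknown pair type: ", paste(unknown, collapse = ", "))
  structures <- list(); manifest <- list()
  res_grid <- c(1.93, 2.2, 2.4, 2.6, 2.85, 3.0, 3.25, 3.35)
  k <- 0L
  for (ty in names(type_counts)) {
    n <- type_counts[[ty]]
    for (i in seq_len(n)) {
      k <- k + 1L
      res <- res_grid[((seed + k - 1L) %% length(res_grid)) + 1L]
      st <- generate_pair(ty, noise_sigma = noise_sigma, seed = seed + k,
                          resolution = res)
      st$id <- sprintf("synth%03d", k)
      structures[[k]] <- st
      manifest[[k]] <- data.frame(id = st$id, type = ty, resolution = res,
                                  stringsAsFactors = FALSE)
    }
  }
  list(structures = structures,
       manifest = if (length(manifest)) do.call(rbind, manifest) else
         data.frame(id = character(), type = character(), resolution = numeric()))
}

# rotation taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  v <- vcross(a, b); s <- vnorm(v); c <- sum(a * b)
  if (s < 1e-12) {
    if (c > 0) return(diag(3))
    return(rotation_about_axis(any_perp(a), pi))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c) / s^2)
}

# Deterministic enumeration solver used by recipes whose pose the smooth
# optimizer cannot reach (a strained trans W/S pair and the non-coplanar
# cW(r)S pair).  The first two hard H-bond distances are satisfied exactly by
# construction: for every sampled orientation of base 2 the translation lies
# on the intersection of two spheres; candidates are filtered by sterics and
# must pass the full self-check.  The first passing pose (fixed scan order)
# is returned.
solve_enum_pose <- function(rec, m10, m20) {
  bonds <- rec$bonds
  hard <- bonds[bonds$w >= 100, , drop = FALSE][1:2, ]
  f_at <- ifelse(hard$res_d == 1, hard$atom_d, hard$atom_a)   # on residue 1
  m_at <- ifelse(hard$res_d == 1, hard$atom_a, hard$atom_d)   # on residue 2
  d1 <- hard$dist[1]; d2 <- hard$dist[2]
  tilt_on <- isTRUE(rec$tilt)
  chi1_grid <- if (isTRUE(rec$ribose1)) seq(0, 2 * pi, length.out = 13)[-13] else 0
  chi2_grid <- if (isTRUE(rec$ribose2)) seq(0, 2 * pi, length.out = 13)[-13] else 0
  th_grid <- seq(0, 2 * pi, length.out = if (tilt_on) 37 else 181)[-1]
  tilt_grid <- if (tilt_on) {
    as.matrix(expand.grid(rx = seq(-0.8, 0.8, by = 0.4),
                          ry = seq(-0.8, 0.8, by = 0.4)))
  } else matrix(0, 1, 2)
  psi_grid <- seq(0, 2 * pi, length.out = 17)[-17]
  soft <- bonds[bonds$w < 100, , drop = FALSE]

  if (tilt_on && length(unique(m_at)) == 2) {
    return(solve_anchored_pose(rec, m10, m20, f_at, m_at, d1, d2, chi1_grid))
  }
  for (chi1 in chi1_grid) {
    m1 <- rotate_sugar(m10, rec$base1, chi1)
    p1 <- m1[f_at[1], ]; p2 <- m1[f_at[2], ]
    for (flip in c(FALSE, TRUE)) for (ti in seq_len(nrow(tilt_grid))) {
      for (th in th_grid) for (chi2 in chi2_grid) {
        m2o <- pose_coords(rotate_sugar(m20, rec$base2, chi2), flip, th,
                           0, 0, 0, tilt_grid[ti, 1], tilt_grid[ti, 2])
        u <- p1 - m2o[m_at[1], ]; v <- p2 - m2o[m_at[2], ]
        w <- v - u; dw <- vnorm(w)
        if (dw >= d1 + d2 || dw <= abs(d1 - d2) || dw < 1e-6) next
        a <- (d1^2 - d2^2 + dw^2) / (2 * dw)
        h <- sqrt(max(0, d1^2 - a^2))
        cw <- u + a * w / dw
        ts <- if (tilt_on) {
          e1 <- any_perp(w / dw); e2 <- vcross(w / dw, e1)
          lapply(psi_grid, function(psi) cw + h * (cos(psi) * e1 + sin(psi) * e2))
        } else {
          # coplanar: translation confined to the base-1 plane (tz = 0)
          dz <- cw[3]
          if (abs(dz) > h) list() else {
            hp <- sqrt(h^2 - dz^2)
            wxy <- c(w[1], w[2], 0)
            if (vnorm(wxy) < 1e-9) list() else {
              e <- unitv(vcross(c(0, 0, 1), wxy))
              list(c(cw[1:2] + hp * e[1:2], 0),
                   c(cw[1:2] - hp * e[1:2], 0))
            }
          }
        }
        for (t in ts) {
          m2 <- sweep(m2o, 2, -t)
          ok_soft <- TRUE
          for (i in seq_len(nrow(soft))) {
            r1a <- if (soft$res_d[i] == 1) soft$atom_d[i] else soft$atom_a[i]
            r2a <- if (soft$res_d[i] == 1) soft$atom_a[i] else soft$atom_d[i]
            dd <- vnorm(m1[r1a, ] - m2[r2a, ])
            if (dd > 3.45 || dd < 2.5) { ok_soft <- FALSE; break }
          }
          if (!ok_soft) next
          dmat <- sqrt(outer(m1[, 1], m2[, 1], "-")^2 +
                         outer(m1[, 2], m2[, 2], "-")^2 +
                         outer(m1[, 3], m2[, 3], "-")^2)
          if (min(dmat) < 2.3) next
          wxyz <- if (!is.null(rec$water)) place_water(rec, m1, m2) else NULL
          if (!is.null(rec$water) && is.null(wxyz)) next
          st <- assemble_structure(rec, m1, m2, wxyz)
          if (!pose_self_check(rec, st)) next
          return(list(value = min(dmat), m1 = m1, m2 = m2, water = wxyz))
        }
      }
    }
  }
  stop("unsatisfiable H-bond pattern for pair type ", rec$key)
}

# Anchored construction for a tilted pair: the two partner atoms bonded to
# residue 1 are placed explicitly (one on a cone around the donor's outward
# bisector so the approach angle is realistic, the second at the rigid
# intra-base separation), the partner base is rotated onto those anchors and
# spun about the anchor axis; candidates must pass the full self-check.
solve_anchored_pose <- function(rec, m10, m20, f_at, m_at, d1, d2, chi1_grid) {
  a2 <- m20[m_at[1], ]; b2 <- m20[m_at[2], ]
  dAB <- vnorm(a2 - b2)
  vAB0 <- unitv(b2 - a2)
  for (chi1 in chi1_grid) {
    m1 <- rotate_sugar(m10, rec$base1, chi1)
    anchor1 <- m1[f_at[1], ]; anchor2 <- m1[f_at[2], ]
    nbrs <- intersect(atom_neighbors(rec$base1, f_at[1]), rownames(m1))
    bis <- -unitv(Reduce(`+`, lapply(nbrs, function(n) unitv(m1[n, ] - anchor1))))
    e1 <- any_perp(bis); e2 <- vcross(bis, e1)
    nbr1 <- lapply(nbrs, function(n) m1[n, ])
    nbr2 <- lapply(intersect(atom_neighbors(rec$base1, f_at[2]), rownames(m1)),
                   function(n) m1[n, ])
    ang_ok <- function(nb, apex, x) {
      all(vapply(nb, function(p) angle_deg(p, apex, x) >= 95, TRUE))
    }
    for (alpha in c(0, 15, 30, 45, 60) * pi / 180) {
      betas <- if (alpha == 0) 0 else seq(0, 2 * pi, length.out = 25)[-25]
      for (beta in betas) {
        dir <- cos(alpha) * bis + sin(alpha) * (cos(beta) * e1 + sin(beta) * e2)
        P <- anchor1 + d1 * dir
        if (!ang_ok(nbr1, anchor1, P)) next
        u <- anchor2 - P
        dw <- vnorm(u)
        if (dw >= d2 + dAB || dw <= abs(d2 - dAB)) next
        aa <- (dAB^2 - d2^2 + dw^2) / (2 * dw)
        h <- sqrt(max(0, dAB^2 - aa^2))
        cw <- P + aa * u / dw
        f1 <- any_perp(u / dw); f2 <- vcross(u / dw, f1)
        for (psi in seq(0, 2 * pi, length.out = 49)[-49]) {
          Q <- cw + h * (cos(psi) * f1 + sin(psi) * f2)
          if (!ang_ok(nbr2, anchor2, Q)) next
          R0 <- rotation_between(vAB0, unitv(Q - P))
          for (gam in seq(0, 2 * pi, length.out = 73)[-73]) {
            R <- rotation_about_axis(unitv(Q - P), gam) %*% R0
            m2 <- sweep(sweep(m20, 2, a2) %*% t(R), 2, -P)
            dmat <- sqrt(outer(m1[, 1], m2[, 1], "-")^2 +
                           outer(m1[, 2], m2[, 2], "-")^2 +
                           outer(m1[, 3], m2[, 3], "-")^2)
            if (min(dmat) < 2.25) next
            st <- assemble_structure(rec, m1, m2, NULL)
            if (!pose_self_check(rec, st)) next
            return(list(value = min(dmat), m1 = m1, m2 = m2, water = NULL))
          }
        }
      }
    }
  }
  stop("unsatisfiable H-bond pattern for pair type ", rec$key)
}
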