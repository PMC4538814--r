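# superpose: least-squares rigid superposition and RMSD with explicit atom
# correspondences.  best_fit() is the Kabsch SVD solution with the reflection
# guard; an independent quaternion implementation (Horn's method) is provided
# for cross-checking.

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing the RMSD of
#' \code{R \%*\% P + t} onto \code{Q}.  Reflections are forbidden: the
#' determinant of the rotation is forced to +1, as required for chiral
#' molecules.
#'
#' @param P,Q n x 3 coordinate matrices in corresponding row order (n >= 3).
#' @return object of class \code{SuperpositionResult}: list(rotation,
#'   translation, rmsd, n_atoms).
#' @export
best_fit <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("coordinate sets differ in length")
  n <- nrow(P)
  if (n < 3) stop("need at least 3 atoms for a superposition")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  if (svd(P0)$d[2] < 1e-8) stop("degenerate (collinear) coordinates")
  H <- t(P0) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q0)^2)))
  structure(list(rotation = R, translation = as.numeric(cq - R %*% cp),
                 rmsd = rmsd, n_atoms = n),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("Superposition of %d atoms: RMSD %.4f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

# apply a SuperpositionResult (or R, t) to coordinates
apply_transform <- function(xyz, rotation, translation) {
  sweep(as.matrix(xyz) %*% t(rotation), 2, -translation)
}

#' Quaternion-based superposition (independent cross-check)
#'
#' Horn's closed-form solution via the largest eigenvalue of the 4x4 key
#' matrix.  Used as an oracle against \code{\link{best_fit}}; not exported for
#' general use.
#'
#' @inheritParams best_fit
#' @return list(rotation, rmsd).
#' @export
quaternion_fit <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
  M <- t(P0) %*% Q0
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  eg <- eigen(K, symmetric = TRUE)
  q <- eg$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2
  ), 3, 3, byrow = TRUE)
  moved <- P0 %*% t(R)
  list(rotation = R, rmsd = sqrt(mean(rowSums((moved - Q0)^2))))
}

#' RMSD between two fragments with atom correspondence
#'
#' Modes: \code{all_heavy} matches heavy atoms by (residue slot, atom name);
#' \code{common_atoms} restricts to atoms shared between a modified base and
#' its parent through the modchem correspondence map (substituents such as
#' methyls are excluded); \code{structural} additionally applies the
#' pseudouridine ring map, comparing structurally (not chemically)
#' corresponding atoms.  Waters are excluded.
#'
#' @param frag1,frag2 fragments (see \code{\link{build_pair_model}}); frag1 may
#'   contain modified residues, frag2 their parent counterparts.
#' @param mode correspondence mode.
#' @param fit superimpose before computing the RMSD (default TRUE); with
#'   \code{fit = FALSE} the RMSD is computed in the current frames.
#' @return RMSD in Angstrom.
#' @export
rmsd_pairs <- function(frag1, frag2, mode = c("all_heavy", "common_atoms", "structural"),
                       fit = TRUE) {
  mode <- match.arg(mode)
  a1 <- frag1$atoms; a2 <- frag2$atoms
  a1 <- a1[a1$elem != "H" & a1$comp != "HOH", , drop = FALSE]
  a2 <- a2[a2$elem != "H" & a2$comp != "HOH", , drop = FALSE]
  pairs <- list()
  for (slot in intersect(unique(a1$res), unique(a2$res))) {
    s1 <- a1[a1$res == slot, , drop = FALSE]
    s2 <- a2[a2$res == slot, , drop = FALSE]
    if (mode == "all_heavy") {
      nm <- intersect(s1$name, s2$name)
      map <- data.frame(mod = nm, parent = nm, stringsAsFactors = FALSE)
    } else {
      c1 <- resolve_code(s1$comp[1]); c2 <- resolve_code(s2$comp[1])
      if (c1 == c2) {
        nm <- intersect(s1$name, s2$name)
        map <- data.frame(mod = nm, parent = nm, stringsAsFactors = FALSE)
      } else if (parent_of(c1) == c2) {
        map <- correspondence_map(c1)
        if (mode == "common_atoms" && c1 == "PSU") {
          # chemical intersection only: identical atom names
          nm <- intersect(s1$name, s2$name)
          map <- data.frame(mod = nm, parent = nm, stringsAsFactors = FALSE)
        }
      } else if (parent_of(c2) == c1) {
        map <- correspondence_map(c2)
        map <- data.frame(mod = map$parent, parent = map$mod, stringsAsFactors = FALSE)
        if (mode == "common_atoms" && c2 == "PSU") {
          nm <- intersect(s1$name, s2$name)
          map <- data.frame(mod = nm, parent = nm, stringsAsFactors = FALSE)
        }
      } else stop("no correspondence between ", c1, " and ", c2)
      map <- map[map$mod %in% s1$name & map$parent %in% s2$name, , drop = FALSE]
      # element replacements (S4 <-> O4) are not "atoms present in both bases"
      e1 <- residue_spec(c1)$atoms
      e2 <- residue_spec(c2)$atoms
      same_elem <- e1$elem[match(map$mod, e1$name)] ==
        e2$elem[match(map$parent, e2$name)]
      map <- map[is.na(same_elem) | same_elem, , drop = FALSE]
    }
    if (!nrow(map)) next
    i1 <- match(map$mod, s1$name); i2 <- match(map$parent, s2$name)
    pairs[[length(pairs) + 1L]] <-
      list(P = as.matrix(s1[i1, c("x", "y", "z")]),
           Q = as.matrix(s2[i2, c("x", "y", "z")]))
  }
  if (!length(pairs)) stop("empty atom correspondence between fragments")
  P <- do.call(rbind, lapply(pairs, `[[`, "P"))
  Q <- do.call(rbind, lapply(pairs, `[[`, "Q"))
  if (fit) best_fit(P, Q)$rmsd else sqrt(mean(rowSums((P - Q)^2)))
}
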