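# energetics: bookkeeping of counterpoise-corrected interaction energies and
# modification energies.
#
#   E_int = E_BP - (E_B1 + E_B2) + BSSE
#   E_Mod = E_int(modified pair) - E_int(unmodified pair)
#
# The quantum-chemistry calculations themselves are delegated to an external
# backend (any function Fragment -> energy); a deliberately simple toy
# backend is included only to exercise the pipeline end to end.

HARTREE_KCAL <- 627.5095

#' Energy components of one base pair
#'
#' @param E_BP electronic energy of the pair.
#' @param E_B1,E_B2 electronic energies of the two isolated bases.
#' @param BSSE counterpoise correction (>= 0 in kcal/mol).
#' @param units "kcal/mol" or "hartree".
#' @return an \code{EnergyComponents} list.
#' @export
energy_components <- function(E_BP, E_B1, E_B2, BSSE = 0, units = c("kcal/mol", "hartree")) {
  units <- match.arg(units)
  stopifnot(is.finite(E_BP), is.finite(E_B1), is.finite(E_B2), is.finite(BSSE))
  structure(list(E_BP = E_BP, E_B1 = E_B1, E_B2 = E_B2, BSSE = BSSE,
                 units = units), class = "EnergyComponents")
}

#' Unit conversion between hartree and kcal/mol
#' @param x energy value(s).
#' @param from,to "hartree" or "kcal/mol".
#' @export
convert_energy <- function(x, from, to) {
  if (from == to) return(x)
  if (from == "hartree" && to == "kcal/mol") return(x * HARTREE_KCAL)
  if (from == "kcal/mol" && to == "hartree") return(x / HARTREE_KCAL)
  stop("unknown units: ", from, " -> ", to)
}

#' Counterpoise-corrected interaction energy
#'
#' \code{E_int = E_BP - (E_B1 + E_B2) + BSSE}, returned in kcal/mol
#' (hartree inputs are converted at 627.5095 kcal/mol per hartree).
#'
#' @param components an \code{EnergyComponents} object.
#' @return E_int in kcal/mol.
#' @export
interaction_energy <- function(components) {
  stopifnot(inherits(components, "EnergyComponents"))
  e <- with(components, E_BP - (E_B1 + E_B2) + BSSE)
  convert_energy(e, components$units, "kcal/mol")
}

#' Modification energy
#'
#' Difference between the interaction energies of the modified and the
#' corresponding unmodified base pair; negative values mean the modification
#' stabilizes the pair.
#'
#' @param E_int_mod,E_int_unmod interaction energies in kcal/mol.
#' @return E_Mod in kcal/mol.
#' @export
modification_energy <- function(E_int_mod, E_int_unmod) {
  E_int_mod - E_int_unmod
}

#' Energy extremes over a set of records
#'
#' @param records data.frame with columns \code{key}, \code{e_int_modified}
#'   and \code{e_mod} (as from \code{\link{load_paper_energies}}).
#' @return list with the weakest pair (E_int closest to zero), the strongest
#'   (most negative E_int), and the E_Mod extremes; values raw and rounded to
#'   one decimal.
#' @export
energy_extremes <- function(records) {
  if (!nrow(records)) stop("empty energy record list")
  iw <- which.max(records$e_int_modified)
  is <- which.min(records$e_int_modified)
  imin <- which.min(records$e_mod)
  imax <- which.max(records$e_mod)
  list(
    weakest = list(key = records$key[iw], E_int = records$e_int_modified[iw],
                   E_int_rounded = round(records$e_int_modified[iw], 1)),
    strongest = list(key = records$key[is], E_int = records$e_int_modified[is],
                     E_int_rounded = round(records$e_int_modified[is], 1)),
    E_Mod_min = list(key = records$key[imin], E_Mod = records$e_mod[imin],
                     E_Mod_rounded = round(records$e_mod[imin], 1)),
    E_Mod_max = list(key = records$key[imax], E_Mod = records$e_mod[imax],
                     E_Mod_rounded = round(records$e_mod[imax], 1)))
}

# --- external-backend contract ---------------------------------------------

#' Toy energy backend (plumbing only, not physical)
#'
#' A fixed-charge Coulomb plus 12-6 repulsion-dispersion score on element
#' types.  It exists solely so that the fragment -> energies -> E_int/E_Mod
#' pipeline can be exercised without an external quantum-chemistry engine;
#' its numbers have no physical meaning.
#'
#' @param fragment a \code{Fragment}.
#' @return a number ("energy" in arbitrary kcal/mol-like units).
#' @export
toy_energy_backend <- function(fragment) {
  q <- c(O = -0.40, N = -0.30, C = 0.15, H = 0.12, S = -0.15, BR = -0.10,
         I = -0.10, P = 0.40)
  a <- fragment$atoms
  qs <- q[a$elem]
  qs[is.na(qs)] <- 0
  # per-residue neutralization so the interaction vanishes at separation
  for (r in unique(a$res)) qs[a$res == r] <- qs[a$res == r] - mean(qs[a$res == r])
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  e <- 0
  eps <- 0.05; sig <- 3.0
  for (i in seq_len(nrow(a) - 1)) {
    for (j in (i + 1):nrow(a)) {
      r <- max(d[i, j], 0.8)
      e <- e + 332 * qs[i] * qs[j] / r
      if (a$res[i] != a$res[j]) {
        e <- e + 4 * eps * ((sig / r)^12 - (sig / r)^6)
      }
    }
  }
  unname(e)
}

#' Interaction energy of a pair fragment through a backend
#'
#' Splits the fragment into its two base monomers (waters kept with the
#' dimer), evaluates the backend on the dimer and both monomers, and applies
#' the interaction-energy bookkeeping.  BSSE is an input (zero by default:
#' the counterpoise logistics beyond emitting monomer geometries are the
#' backend's business).
#'
#' @param fragment a \code{Fragment}.
#' @param backend function Fragment -> energy in kcal/mol.
#' @param BSSE counterpoise correction in kcal/mol.
#' @return E_int in kcal/mol.
#' @export
backend_interaction_energy <- function(fragment, backend = toy_energy_backend,
                                       BSSE = 0) {
  mono <- function(slot) {
    at <- fragment$atoms[fragment$atoms$res == slot, , drop = FALSE]
    ch <- if (at$comp[1] == "HOH") 0L else residue_spec(at$comp[1])$charge
    new_fragment(at, name = paste0(fragment$name, " monomer ", slot),
                 net_charge = ch)
  }
  e_bp <- backend(fragment)
  e_b1 <- backend(mono(1))
  e_b2 <- backend(mono(2))
  interaction_energy(energy_components(e_bp, e_b1, e_b2, BSSE))
}

#' Emit counterpoise monomer geometries
#'
#' Writes the two monomer-in-dimer-basis geometry files (the partner's atoms
#' flagged as ghost centers in the comment) for an external counterpoise
#' calculation.
#'
#' @param fragment a \code{Fragment}.
#' @param dir output directory.
#' @return character vector of the two file paths.
#' @export
write_counterpoise_inputs <- function(fragment, dir = ".") {
  paths <- character(2)
  for (slot in 1:2) {
    at <- fragment$atoms
    ghost <- at$res != slot
    frag <- new_fragment(at, name = sprintf("%s monomer %d (ghosts: %d atoms)",
                                            fragment$name, slot, sum(ghost)),
                         net_charge = if (any(!ghost))
                           residue_spec(at$comp[!ghost][1])$charge else 0L)
    paths[slot] <- file.path(dir, sprintf("monomer%d_in_dimer_basis.xyz", slot))
    write_xyz(frag, paths[slot])
  }
  paths
}
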