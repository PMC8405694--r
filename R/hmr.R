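# Hydrogen mass repartitioning: move mass from heavy atoms onto their bonded
# hydrogens so MD integrators can use longer time steps; total mass must be
# conserved exactly.

H_MASS_U <- 1.008

#' Create an atom mass table
#'
#' @param atoms `data.frame` with columns `id`, `element`, `mass` (unified
#'   atomic mass units, strictly positive).
#' @param bonds `data.frame` with columns `from`, `to` (atom ids); may have
#'   zero rows.
#' @return an object of class `atom_mass_table`.
#' @export
atom_mass_table <- function(atoms, bonds = data.frame(from = integer(), to = integer())) {
  stopifnot(is.data.frame(atoms), all(c("id", "element", "mass") %in% names(atoms)),
            is.data.frame(bonds), all(c("from", "to") %in% names(bonds)))
  if (anyDuplicated(atoms$id)) abort2("duplicate atom ids", "topology_error")
  if (any(atoms$mass <= 0)) abort2("masses must be strictly positive", "invalid_argument")
  bad <- setdiff(c(bonds$from, bonds$to), atoms$id)
  if (length(bad) > 0L)
    abort2("bond references unknown atom id", "topology_error")
  structure(list(atoms = atoms, bonds = bonds), class = "atom_mass_table")
}

#' Repartition hydrogen masses onto bonded heavy atoms
#'
#' Sets every hydrogen mass to `factor * 1.008` u and subtracts the added
#' mass from the single heavy atom it is bonded to, conserving the total
#' system mass exactly. A table without hydrogens is returned unchanged.
#' Hydrogens that already carry >= 4 u are taken as evidence the table has
#' been repartitioned before and the call refuses rather than silently
#' doubling the transform.
#'
#' @param t an [atom_mass_table()].
#' @param factor multiplier on the standard hydrogen mass (default 4, giving
#'   4.0320 u per hydrogen).
#' @return a new `atom_mass_table` with adjusted masses.
#' @export
repartition_hydrogen_mass <- function(t, factor = 4) {
  stopifnot(inherits(t, "atom_mass_table"), is.numeric(factor), factor > 1)
  atoms <- t$atoms
  is_h <- toupper(atoms$element) == "H"
  if (!any(is_h)) return(t)
  if (any(atoms$mass[is_h] >= 4.0))
    abort2("hydrogen masses >= 4 u: table appears already repartitioned",
           "already_repartitioned")

  new_mass <- factor * H_MASS_U
  elem_of <- stats::setNames(atoms$element, atoms$id)
  # heavy partner of each hydrogen
  partners <- lapply(atoms$id[is_h], function(h) {
    nb <- c(t$bonds$to[t$bonds$from == h], t$bonds$from[t$bonds$to == h])
    nb[toupper(elem_of[as.character(nb)]) != "H"]
  })
  n_heavy <- lengths(partners)
  if (any(n_heavy != 1L))
    abort2("every hydrogen must be bonded to exactly one heavy atom",
           "topology_error")

  delta <- new_mass - atoms$mass[is_h]          # mass moved per hydrogen
  heavy_ids <- vapply(partners, `[[`, numeric(1), 1L)
  removed <- tapply(delta, heavy_ids, sum)

  out <- atoms
  out$mass[is_h] <- new_mass
  idx <- match(as.numeric(names(removed)), out$id)
  out$mass[idx] <- out$mass[idx] - as.numeric(removed)
  if (any(out$mass[idx] <= 0))
    abort2("repartitioning would drive a heavy-atom mass to <= 0",
           "infeasible_repartition")
  atom_mass_table(out, t$bonds)
}

#' Total mass of an atom mass table
#' @param t an [atom_mass_table()].
#' @return total mass in u.
#' @export
total_mass <- function(t) {
  stopifnot(inherits(t, "atom_mass_table"))
  sum(t$atoms$mass)
}
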