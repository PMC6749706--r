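#' Default force-field parameter table
#'
#' Per-atom-type Lennard-Jones parameters in the AutoDock4 convention:
#' `epsilon` is the well depth (kcal/mol) and `rmin` the per-atom contribution
#' to the pair equilibrium distance, so that for a pair of atoms
#' `r0 = rmin_i + rmin_j` and `epsilon = sqrt(epsilon_i * epsilon_j)`.
#' `radius` (here equal to `rmin`) is the van der Waals radius used for
#' protein/solvent voxel occupancy.  The `hbond` column marks hydrogen-bond
#' roles ("donor" for polar hydrogens, "acceptor" for N/NA/OA/SA, "none"
#' otherwise); `hb_epsilon`/`hb_r0` hold the 12-10 well parameters of an
#' acceptor paired with a donor hydrogen (5 kcal/mol at 1.9 A for oxygen and
#' nitrogen acceptors, 1 kcal/mol at 2.5 A for sulfur).
#'
#' @param extra optional data.frame with the same columns, appended to (and
#'   overriding) the defaults, keyed by `atom_type`.
#' @return data.frame with columns `atom_type`, `epsilon`, `rmin`, `radius`,
#'   `hbond`, `hb_epsilon`, `hb_r0`.
#' @export
default_forcefield <- function(extra = NULL) {
  ff <- data.frame(
    atom_type = c("C", "A", "N", "NA", "OA", "S", "SA", "H", "HD",
                  "P", "F", "Cl", "Br", "I", "Zn", "Ca", "Mg", "Mn", "Fe"),
    epsilon   = c(0.150, 0.150, 0.160, 0.160, 0.200, 0.200, 0.200, 0.020,
                  0.020, 0.200, 0.080, 0.276, 0.389, 0.550, 0.550, 0.550,
                  0.875, 0.875, 0.010),
    rmin      = c(2.000, 2.000, 1.750, 1.750, 1.600, 2.000, 2.000, 1.000,
                  1.000, 2.100, 1.545, 2.045, 2.165, 2.360, 0.740, 0.990,
                  0.650, 0.650, 0.650),
    hbond     = c("none", "none", "acceptor", "acceptor", "acceptor", "none",
                  "acceptor", "none", "donor", "none", "none", "none",
                  "none", "none", "none", "none", "none", "none", "none"),
    hb_epsilon = NA_real_,
    hb_r0      = NA_real_,
    stringsAsFactors = FALSE
  )
  ff$radius <- ff$rmin
  hb <- list(N = c(5, 1.9), "NA" = c(5, 1.9), OA = c(5, 1.9), SA = c(1, 2.5))
  for (ty in names(hb)) {
    i <- ff$atom_type == ty
    ff$hb_epsilon[i] <- hb[[ty]][1]
    ff$hb_r0[i] <- hb[[ty]][2]
  }
  if (!is.null(extra)) {
    stopifnot(is.data.frame(extra), "atom_type" %in% names(extra))
    ff <- ff[!ff$atom_type %in% extra$atom_type, ]
    ff <- rbind(ff, extra[names(ff)])
  }
  stopifnot(all(ff$epsilon >= 0), all(ff$rmin > 0))
  ff
}

#' Look up force-field rows for a vector of atom types
#'
#' @param ff force-field table from [default_forcefield()].
#' @param types character vector of atom types.
#' @return data.frame of matching rows, one per input type, in input order.
#' @export
ff_lookup <- function(ff, types) {
  i <- match(types, ff$atom_type)
  if (anyNA(i)) {
    bad <- sort(unique(types[is.na(i)]))
    stop("unknown atom type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ff[i, , drop = FALSE]
}

#' Combine per-type parameters into pair coefficients
#'
#' Uses the Amber/AutoDock combination rules: `epsilon = sqrt(e_i * e_j)` and
#' `r0 = rmin_i + rmin_j`, then precomputes the 12-6 coefficients
#' `A = epsilon * r0^12`, `B = 2 * epsilon * r0^6` and the 12-10 coefficients
#' `C = 5 * epsilon * r0^12`, `D = 6 * epsilon * r0^10`.
#'
#' @param p_i,p_j lists or single data.frame rows carrying `epsilon` and
#'   `rmin` for the two atom types.
#' @return object of class `pair_params` with fields `epsilon`, `r0`, `A`,
#'   `B`, `C`, `D`.
#' @export
combine_pair <- function(p_i, p_j) {
  eps <- sqrt(p_i$epsilon * p_j$epsilon)
  r0 <- p_i$rmin + p_j$rmin
  pair_params(eps, r0)
}

#' Pair coefficients from an explicit well
#'
#' @param epsilon well depth, kcal/mol.
#' @param r0 well position, Angstrom.
#' @return `pair_params` object.
#' @export
pair_params <- function(epsilon, r0) {
  stopifnot(epsilon >= 0, r0 > 0)
  structure(list(epsilon = epsilon, r0 = r0,
                 A = epsilon * r0^12, B = 2 * epsilon * r0^6,
                 C = 5 * epsilon * r0^12, D = 6 * epsilon * r0^10),
            class = "pair_params")
}

#' 12-6 Lennard-Jones pair potential
#'
#' `A/r^12 - B/r^6` with the minimum `-epsilon` at distance `r0`; zero beyond the
#' cutoff.
#'
#' @param r distance(s), Angstrom; must be positive.
#' @param p `pair_params` object.
#' @param cutoff interaction cutoff, Angstrom.
#' @return energy in kcal/mol, vectorized over `r`.
#' @export
lj_12_6 <- function(r, p, cutoff = 8) {
  if (any(r <= 0)) stop("distance must be positive", call. = FALSE)
  e <- p$A / r^12 - p$B / r^6
  e[r > cutoff] <- 0
  e
}

#' 12-10 Lennard-Jones hydrogen-bond pair potential
#'
#' `C/r^12 - D/r^10` with the minimum `-epsilon` at distance `r0`; zero beyond the
#' cutoff.
#'
#' @inheritParams lj_12_6
#' @return energy in kcal/mol, vectorized over `r`.
#' @export
lj_12_10 <- function(r, p, cutoff = 8) {
  if (any(r <= 0)) stop("distance must be positive", call. = FALSE)
  e <- p$C / r^12 - p$D / r^10
  e[r > cutoff] <- 0
  e
}

#' Energy-channel parameters
#'
#' @param cutoff pair cutoff in Angstrom beyond which interactions are
#'   ignored (default 8).
#' @param coulomb_k Coulomb constant K in kcal*A/(mol*e^2).
#' @param coulomb_exponent exponent of r in the Coulomb term.  The default 2
#'   uses the squared-distance form `K*q1*q2/r^2`; set 1 for the physical
#'   `1/r` energy.
#' @return list of class `energy_params`.
#' @export
energy_params <- function(cutoff = 8, coulomb_k = 332.0636, coulomb_exponent = 2) {
  stopifnot(cutoff > 0, coulomb_exponent %in% c(1, 2))
  structure(list(cutoff = cutoff, coulomb_k = coulomb_k,
                 coulomb_exponent = coulomb_exponent),
            class = "energy_params")
}
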