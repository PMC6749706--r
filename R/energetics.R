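# Probe-energy channels.  A probe is placed at every voxel center and its
# interaction with the protein is accumulated with an 8 A pair cutoff:
#   vdw     - a united-atom methyl probe (AutoDock type C), 12-6 potential,
#             summed over protein atoms;
#   hbond   - a hydroxyl probe (OA at the voxel center, HD 0.96 A along +x),
#             12-10 potential over donor/acceptor pairs, keeping the single
#             candidate with the largest absolute energy (hydrogen bonds
#             saturate, so energies are not additive);
#   coulomb - a unit positive charge, K*q/r^2 summed over charged atoms.

#' Hydroxyl probe geometry
#'
#' @param oh_bond O-H bond length in Angstrom (default 0.96).
#' @return data.frame of probe atoms with types and offsets from the voxel
#'   center.  The orientation of the O-H bond is fixed along +x; the paper
#'   level of description leaves it free, and any fixed orientation gives a
#'   deterministic channel.
#' @export
hydroxyl_probe <- function(oh_bond = 0.96) {
  data.frame(atom_type = c("OA", "HD"),
             dx = c(0, oh_bond), dy = 0, dz = 0,
             stringsAsFactors = FALSE)
}

#' Van der Waals energy channel
#'
#' Sums the 12-6 potential between a methyl probe at each voxel center and
#' every protein atom within the cutoff, using Amber/AutoDock combination
#' rules per atom type.
#'
#' @param protein a `protein_structure` with resolvable atom types.
#' @param spec a `grid_spec`.
#' @param params an `energy_params` object.
#' @param ff force-field table.
#' @param probe_type AutoDock type of the united-atom probe (default "C").
#' @return a `channel_grid` named "vdw", kcal/mol.
#' @export
vdw_channel <- function(protein, spec, params = energy_params(),
                        ff = default_forcefield(), probe_type = "C") {
  rows <- ff_lookup(ff, protein$atoms$atom_type)
  probe <- ff_lookup(ff, probe_type)
  eps <- sqrt(probe$epsilon * rows$epsilon)
  r0 <- probe$rmin + rows$rmin
  v <- lj_sum_grid_cpp(spec$shape, spec$origin, spec$spacing, coords(protein),
                       eps * r0^12, 2 * eps * r0^6, params$cutoff)
  channel_grid(spec, array(v, spec$shape), "vdw")
}

# 12-10 coefficients for a (probe atom, protein atom) pair, or c(-1, -1) when
# the pair cannot hydrogen-bond.  Wells follow the AutoDock hydrogen-bond
# parameters attached to the acceptor type.
hbond_pair_coeff <- function(probe_row, protein_row) {
  roles <- c(probe_row$hbond, protein_row$hbond)
  if (!(("donor" %in% roles) && ("acceptor" %in% roles))) return(c(-1, -1))
  acc <- if (probe_row$hbond == "acceptor") probe_row else protein_row
  eps <- acc$hb_epsilon
  r0 <- acc$hb_r0
  if (is.na(eps)) return(c(-1, -1))
  c(5 * eps * r0^12, 6 * eps * r0^10)
}

#' Hydrogen-bond energy channel
#'
#' Places a hydroxyl probe at each voxel and evaluates the 12-10 potential
#' for every donor/acceptor pair between probe atoms and hydrogen-bond
#' capable protein atoms within the cutoff.  Because hydrogen bonds saturate,
#' the voxel value is the candidate energy with the maximum absolute value
#' rather than a sum; voxels with no candidate in range are 0.
#'
#' @inheritParams vdw_channel
#' @param probe probe atom table from [hydroxyl_probe()].
#' @return a `channel_grid` named "hbond", kcal/mol.
#' @export
hbond_channel <- function(protein, spec, params = energy_params(),
                          ff = default_forcefield(), probe = hydroxyl_probe()) {
  rows <- ff_lookup(ff, protein$atoms$atom_type)
  capable <- rows$hbond != "none"
  if (!any(capable)) {
    return(channel_grid(spec, array(0, spec$shape), "hbond"))
  }
  sub <- protein$atoms[capable, , drop = FALSE]
  subrows <- rows[capable, , drop = FALSE]
  proberows <- ff_lookup(ff, probe$atom_type)
  n <- nrow(sub)
  m <- nrow(probe)
  CD <- matrix(-1, n, 2 * m)
  for (pa in seq_len(m)) {
    for (ty in unique(sub$atom_type)) {
      i <- sub$atom_type == ty
      cd <- hbond_pair_coeff(proberows[pa, ], subrows[which(i)[1], ])
      CD[i, 2 * pa - 1] <- cd[1]
      CD[i, 2 * pa] <- cd[2]
    }
  }
  v <- hbond_max_grid_cpp(spec$shape, spec$origin, spec$spacing,
                          as.matrix(sub[c("x", "y", "z")]), CD,
                          as.matrix(probe[c("dx", "dy", "dz")]), params$cutoff)
  channel_grid(spec, array(v, spec$shape), "hbond")
}

#' Coulomb energy channel
#'
#' A unit positive probe charge at each voxel center; the voxel value is
#' `sum_j K * q_j / r^2` over protein atoms within the cutoff (squared
#' distance by default, see [energy_params()]).
#'
#' @inheritParams vdw_channel
#' @return a `channel_grid` named "coulomb", kcal/mol.
#' @export
coulomb_channel <- function(protein, spec, params = energy_params(),
                            ff = default_forcefield()) {
  q <- protein$atoms$charge
  if (all(q == 0))
    warning("all partial charges are zero; coulomb channel will be 0",
            call. = FALSE)
  v <- coulomb_grid_cpp(spec$shape, spec$origin, spec$spacing, coords(protein),
                        q, params$coulomb_k, params$cutoff,
                        as.integer(params$coulomb_exponent))
  channel_grid(spec, array(v, spec$shape), "coulomb")
}
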