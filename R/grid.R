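# The voxel lattice.  Grids use 1 A cubic voxels; the center of voxel
# (i,j,k) (1-based) is origin + (i-0.5, j-0.5, k-0.5).  An 8 A buffer around
# the protein bounding box guarantees that energy cutoff spheres and sample
# blocks near the surface stay inside the lattice.

#' Construct a grid specification
#'
#' @param origin lower corner of the grid, Angstrom.
#' @param shape integer vector of voxels per axis.
#' @param spacing voxel edge length; fixed at 1 Angstrom.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(origin, shape, spacing = 1) {
  stopifnot(length(origin) == 3, length(shape) == 3, all(shape >= 1),
            spacing == 1)
  structure(list(origin = as.numeric(origin), shape = as.integer(shape),
                 spacing = spacing), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %dx%dx%d voxels, %.0f A spacing, origin (%.1f, %.1f, %.1f)\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel centers along one axis
#' @param spec a `grid_spec`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of center coordinates, Angstrom.
#' @export
voxel_centers <- function(spec, axis) {
  spec$origin[axis] + (seq_len(spec$shape[axis]) - 0.5) * spec$spacing
}

#' Build the buffered grid around a protein
#'
#' The grid origin is the per-axis coordinate minimum minus the buffer; each
#' axis gets `ceil(extent) + 2 * buffer` voxels, where the extent is the
#' coordinate range of the protein on that axis.
#'
#' @param protein a `protein_structure`.
#' @param buffer buffer width in Angstrom added on every side (default 8).
#' @return a `grid_spec`.
#' @export
make_grid <- function(protein, buffer = 8) {
  xyz <- coords(protein)
  lo <- apply(xyz, 2, min)
  hi <- apply(xyz, 2, max)
  grid_spec(origin = lo - buffer,
            shape = as.integer(ceiling(hi - lo) + 2L * as.integer(buffer)))
}

#' Mark protein-occupied voxels
#'
#' A voxel belongs to the protein when its center lies within the van der
#' Waals radius of any atom; all other voxels are solvent.
#'
#' @param protein a `protein_structure`.
#' @param spec a `grid_spec` covering the protein.
#' @return object of class `occupancy_mask`: the spec plus a logical 3D array.
#' @export
mark_occupancy <- function(protein, spec) {
  flags <- occupancy_cpp(spec$shape, spec$origin, spec$spacing,
                         coords(protein), protein$atoms$vdw_radius)
  structure(list(spec = spec, flags = array(flags, spec$shape)),
            class = "occupancy_mask")
}

#' Protein-solvent-protein cavity scan (shape channel)
#'
#' Scans the occupancy mask along seven directions (the three axes and four
#' cube diagonals) in 1 A steps.  Every maximal solvent run bounded by
#' protein voxels at both ends marks its voxels with one PSP event; a voxel's
#' value is the number of directions (0-7) in which it lies inside such a
#' run.  Runs that reach the grid boundary are open to bulk solvent and do
#' not count; protein voxels keep the value 0.
#'
#' @param mask an `occupancy_mask`.
#' @return a `channel_grid` named "shape" with integer values in 0..7.
#' @export
psp_scan <- function(mask) {
  stopifnot(inherits(mask, "occupancy_mask"))
  v <- psp_scan_cpp(as.logical(mask$flags), mask$spec$shape)
  channel_grid(mask$spec, array(as.numeric(v), mask$spec$shape), "shape")
}

#' Construct a channel grid
#'
#' @param spec a `grid_spec`.
#' @param values numeric 3D array matching `spec$shape`.
#' @param channel_name one of "shape", "vdw", "hbond", "coulomb".
#' @return object of class `channel_grid`.
#' @export
channel_grid <- function(spec, values, channel_name) {
  stopifnot(inherits(spec, "grid_spec"),
            identical(dim(values), as.integer(spec$shape)),
            channel_name %in% c("shape", "vdw", "hbond", "coulomb"))
  if (!all(is.finite(values))) stop("non-finite channel values", call. = FALSE)
  structure(list(spec = spec, values = values, channel_name = channel_name),
            class = "channel_grid")
}
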