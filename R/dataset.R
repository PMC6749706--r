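# Descriptor assembly and 16 A block sampling.  A sample block covers 16^3
# voxels; its center is the mean of its voxel centers, i.e. corner index t
# (0-based) puts the center at origin + t + 8 on each axis.  Positive blocks
# are the 4^3 = 64 blocks whose centers sit at offsets {-2,-1,0,+1} from the
# site center snapped to the block-center lattice (the half-open [-2, 2) A
# reading is the only one that yields 64); negatives come from the stride-4
# scan lattice outside every positive envelope, down-sampled to 64.

BLOCK <- 16L

#' Compute the four-channel descriptor of a protein
#'
#' Builds the buffered grid, the protein-solvent-protein shape channel and
#' the three probe-energy channels.
#'
#' @param protein a `protein_structure`.
#' @param ff force-field table.
#' @param params an `energy_params` object.
#' @param buffer grid buffer, Angstrom.
#' @return object of class `descriptor_grid`: `spec`, a named list
#'   `channels` (shape, vdw, hbond, coulomb; each a numeric 3D array) and a
#'   `normalized` flag.
#' @export
compute_descriptor <- function(protein, ff = default_forcefield(),
                               params = energy_params(), buffer = 8) {
  spec <- make_grid(protein, buffer)
  mask <- mark_occupancy(protein, spec)
  channels <- list(
    shape = psp_scan(mask)$values,
    vdw = vdw_channel(protein, spec, params, ff)$values,
    hbond = hbond_channel(protein, spec, params, ff)$values,
    coulomb = coulomb_channel(protein, spec, params, ff)$values
  )
  structure(list(spec = spec, channels = channels, normalized = FALSE,
                 id = protein$id),
            class = "descriptor_grid")
}

#' @export
print.descriptor_grid <- function(x, ...) {
  cat(sprintf("<descriptor_grid> %s: %dx%dx%d voxels x 4 channels%s\n",
              x$id, x$spec$shape[1], x$spec$shape[2], x$spec$shape[3],
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Arctangent normalization of a descriptor
#'
#' Maps every voxel value v of every channel to `(2/pi) * atan(v)`, so all
#' values lie strictly in (-1, 1) regardless of the raw energy scale.
#' Extremely large energies (clashing voxels inside the protein) would round
#' to exactly +-1 in double precision; those are nudged to the nearest
#' representable value inside the open interval.  Normalizing twice is an
#' error because the mapping is not idempotent.
#'
#' @param grid a `descriptor_grid`.
#' @return the normalized `descriptor_grid`.
#' @export
normalize_descriptor <- function(grid) {
  stopifnot(inherits(grid, "descriptor_grid"))
  if (isTRUE(grid$normalized)) stop("descriptor already normalized", call. = FALSE)
  lim <- 1 - .Machine$double.eps / 2
  grid$channels <- lapply(grid$channels, function(v)
    pmin(pmax((2 / pi) * atan(v), -lim), lim))
  grid$normalized <- TRUE
  grid
}

# 0-based corner offsets of all fully-contained blocks on a stride lattice
block_lattice <- function(spec, step) {
  lapply(1:3, function(ax) seq(0L, spec$shape[ax] - BLOCK, by = step))
}

block_center_from_corner <- function(spec, corner) {
  spec$origin + (corner + BLOCK / 2) * spec$spacing
}

# snap a point to the nearest block-center lattice position (centers live at
# origin + integer + 8); returns the 0-based corner offset
snap_corner <- function(spec, point) {
  t0 <- floor(point - spec$origin - BLOCK / 2 + 0.5)
  as.integer(t0)
}

extract_block <- function(grid, corner) {
  ix <- lapply(1:3, function(ax) (corner[ax] + 1):(corner[ax] + BLOCK))
  vals <- array(0, c(BLOCK, BLOCK, BLOCK, 4))
  for (c in 1:4)
    vals[, , , c] <- grid$channels[[c]][ix[[1]], ix[[2]], ix[[3]]]
  vals
}

new_block <- function(grid, corner, label = NA) {
  structure(list(corner = as.integer(corner),
                 center = block_center_from_corner(grid$spec, corner),
                 values = extract_block(grid, corner),
                 label = label),
            class = "sample_block")
}

corner_inside <- function(spec, corner) {
  all(corner >= 0L) && all(corner + BLOCK <= spec$shape)
}

#' Positive sample blocks around a site center
#'
#' Returns the blocks whose centers lie within 2 A of the site center: the
#' site is snapped to the block-center lattice and the 4 offsets
#' {-2,-1,0,+1} per axis give 64 blocks filling a 20 A cube.  Blocks that
#' would extend past the grid are dropped with a warning.
#'
#' @param grid a `descriptor_grid`.
#' @param site_center actual site center, Angstrom.
#' @return list of `sample_block` objects labelled 1.
#' @export
positive_blocks <- function(grid, site_center) {
  stopifnot(inherits(grid, "descriptor_grid"), length(site_center) == 3)
  c0 <- snap_corner(grid$spec, site_center)
  offs <- expand.grid(dx = -2:1, dy = -2:1, dz = -2:1)
  out <- list()
  for (i in seq_len(nrow(offs))) {
    corner <- c0 + as.integer(offs[i, ])
    if (corner_inside(grid$spec, corner))
      out[[length(out) + 1]] <- new_block(grid, corner, label = 1)
  }
  if (length(out) < 64)
    warning("site too close to the grid boundary: only ", length(out),
            " of 64 positive blocks fit", call. = FALSE)
  out
}

# Is a block center inside the 20 A positive envelope of any site?  The
# envelope is the union of the extents of the 64 positive blocks: a cube of
# side 20 A (16 + 2 + 2) around the snapped site center.  Blocks centered
# inside it overlap the site too much to be clean negatives but are not
# positives either; they are simply not sampled.
in_positive_envelope <- function(spec, center, site_centers) {
  half <- BLOCK / 2 + 2
  for (r in seq_len(nrow(site_centers))) {
    c0 <- snap_corner(spec, site_centers[r, ])
    ref <- block_center_from_corner(spec, c0)
    off <- center - ref
    if (all(off >= -half & off < half)) return(TRUE)
  }
  FALSE
}

#' Negative sample blocks from the stride lattice
#'
#' Scans the grid with 16 A blocks in steps of `step` (default 4 A); blocks
#' whose centers fall outside the positive envelope of every site are
#' negative candidates, down-sampled uniformly without replacement to `n`
#' using the seed.  Fewer than `n` candidates are kept in full with a
#' warning.
#'
#' @param grid a `descriptor_grid`.
#' @param site_centers numeric vector (one site) or matrix with one site
#'   center per row.
#' @param seed integer seed for the down-sampling draw.
#' @param n number of negatives to keep (default 64).
#' @param step scan stride, voxels (default 4).
#' @return list of `sample_block` objects labelled 0.
#' @export
negative_blocks <- function(grid, site_centers, seed, n = 64L, step = 4L) {
  stopifnot(inherits(grid, "descriptor_grid"))
  if (is.null(dim(site_centers))) site_centers <- matrix(site_centers, nrow = 1)
  lat <- block_lattice(grid$spec, step)
  corners <- as.matrix(expand.grid(lat[[1]], lat[[2]], lat[[3]]))
  keep <- vapply(seq_len(nrow(corners)), function(i) {
    ctr <- block_center_from_corner(grid$spec, corners[i, ])
    !in_positive_envelope(grid$spec, ctr, site_centers)
  }, logical(1))
  corners <- corners[keep, , drop = FALSE]
  if (nrow(corners) < n) {
    warning("only ", nrow(corners), " negative candidates available",
            call. = FALSE)
    pick <- seq_len(nrow(corners))
  } else {
    pick <- with_seed(seed, sample.int(nrow(corners), n))
  }
  lapply(pick, function(i) new_block(grid, corners[i, ], label = 0))
}

#' Assemble blocks into a training array
#'
#' @param blocks list of `sample_block` objects.
#' @return list with `x`, an array of dim (16, 16, 16, 4, n), `y` the label
#'   vector and `centers` an n x 3 matrix of block centers.
#' @export
block_array <- function(blocks) {
  n <- length(blocks)
  x <- array(0, c(BLOCK, BLOCK, BLOCK, 4, n))
  for (i in seq_len(n)) x[, , , , i] <- blocks[[i]]$values
  list(x = x,
       y = vapply(blocks, function(b) as.numeric(b$label), numeric(1)),
       centers = do.call(rbind, lapply(blocks, function(b) b$center)))
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
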