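# Deterministic synthetic structures with planted cavities.  A fixture is a
# hollow two-layer atom shell around an empty cavity — the cavity center is
# the planted binding site — optionally decorated with solid surface blobs
# that break the symmetry of the bounding box.  Geometry is chosen so the
# cavity is enclosed in all seven scan directions (shell >= 2 voxels thick,
# atom spacing ~1.6-1.8 A keeps occupancy contiguous) and the default shell
# radius makes the grid at least 33 voxels per axis, which gives the stride-4
# scan lattice 5 positions per axis and leaves >= 64 negative candidates.
# Generation is a pure function of the spec (all draws under the spec seed).

#' Specification of a synthetic shell fixture
#'
#' @param n_atoms number of shell atoms (split between concentric layers
#'   about 1.7 A apart, in proportion to layer areas).  The default `NULL`
#'   places one atom per ~2.56 square Angstrom of layer area, a surface
#'   density at which occupancy spheres overlap into a closed shell.
#' @param cavity_center planted site center, Angstrom.
#' @param cavity_radius radius of the empty cavity (default 5.5, i.e. an
#'   11 A diameter pocket, the scale of a drug binding site; the clustering
#'   defaults MinPts = 7 / Eps = 5 presume site regions spanning at least
#'   three 4 A stride cells).
#' @param shell_radius outer shell layer radius (default 12, which makes
#'   the buffered grid at least 40 voxels per axis so the stride-4 scan
#'   lattice keeps well over 64 negative candidates outside the positive
#'   envelope).
#' @param charge_scheme "zero", "alternating" (+0.2/-0.2) or "random"
#'   (uniform in +-0.3).
#' @param seed integer seed; generation is a pure function of the spec.
#' @param n_decoys number of solid surface blobs attached outside the shell.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_atoms = NULL, cavity_center = c(0, 0, 0),
                         cavity_radius = 5.5, shell_radius = 12,
                         charge_scheme = c("alternating", "zero", "random"),
                         seed = 1L, n_decoys = 2L) {
  charge_scheme <- match.arg(charge_scheme)
  stopifnot(cavity_radius > 0, shell_radius > cavity_radius + 2.5)
  if (is.null(n_atoms)) {
    radii <- shell_layer_radii(cavity_radius, shell_radius)
    n_atoms <- round(sum(4 * pi * radii^2) / 2.56)
  }
  stopifnot(n_atoms >= 50)
  structure(list(n_atoms = as.integer(n_atoms),
                 cavity_center = as.numeric(cavity_center),
                 cavity_radius = cavity_radius, shell_radius = shell_radius,
                 charge_scheme = charge_scheme, seed = as.integer(seed),
                 n_decoys = as.integer(n_decoys)),
            class = "fixture_spec")
}

# concentric layers <= 1.7 A apart: with vdW radii ~1.6-2 A the shell
# occupancy is contiguous and >= 2 voxels thick everywhere
shell_layer_radii <- function(cavity_radius, shell_radius) {
  r_in <- cavity_radius + 1.9
  nlayer <- max(2, ceiling((shell_radius - r_in) / 1.7) + 1)
  seq(r_in, shell_radius, length.out = nlayer)
}

# near-uniform points on a sphere (golden-spiral lattice)
fibonacci_sphere <- function(n, radius, center) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(center[1] + radius * sin(phi) * cos(theta),
        center[2] + radius * sin(phi) * sin(theta),
        center[3] + radius * cos(phi))
}

fixture_types <- function(n) {
  sample(c("C", "N", "OA", "SA", "HD"), n, replace = TRUE,
         prob = c(0.5, 0.15, 0.2, 0.05, 0.1))
}

fixture_charges <- function(n, scheme) {
  switch(scheme,
         zero = rep(0, n),
         alternating = rep_len(c(0.2, -0.2), n),
         random = runif(n, -0.3, 0.3))
}

#' Generate a hollow-shell fixture with a planted cavity
#'
#' @param spec a `fixture_spec`.
#' @param ff force-field table used to assign van der Waals radii.
#' @return list with `protein` (a `protein_structure`), `site_center` (the
#'   planted cavity center) and `spec`.
#' @export
make_hollow_shell <- function(spec, ff = default_forcefield()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    radii <- shell_layer_radii(spec$cavity_radius, spec$shell_radius)
    n_per <- round(spec$n_atoms * radii^2 / sum(radii^2))
    pts <- do.call(rbind, lapply(seq_along(radii), function(l)
      fibonacci_sphere(n_per[l], radii[l], spec$cavity_center)))
    pts <- pts + matrix(runif(3 * nrow(pts), -0.15, 0.15), ncol = 3)
    # solid decoy blobs on the outside break bounding-box symmetry
    if (spec$n_decoys > 0) {
      for (b in seq_len(spec$n_decoys)) {
        dir <- rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        rb <- runif(1, 2.5, 3.5)
        ctr <- spec$cavity_center + dir * (spec$shell_radius + 0.8 * rb)
        g <- seq(-rb, rb, by = 1.7)
        bl <- as.matrix(expand.grid(g, g, g))
        bl <- bl[rowSums(bl^2) <= rb^2, , drop = FALSE]
        bl <- sweep(bl + matrix(runif(3 * nrow(bl), -0.2, 0.2), ncol = 3),
                    2, ctr, "+")
        pts <- rbind(pts, bl)
      }
    }
    n <- nrow(pts)
    types <- fixture_types(n)
    charges <- fixture_charges(n, spec$charge_scheme)
    atoms <- data.frame(serial = seq_len(n), name = types,
                        element = element_from_type(types),
                        x = pts[, 1], y = pts[, 2], z = pts[, 3],
                        charge = charges,
                        vdw_radius = ff_lookup(ff, types)$radius,
                        atom_type = types, stringsAsFactors = FALSE)
    prot <- protein_structure(atoms, id = sprintf("shell_seed%d", spec$seed))
    list(protein = prot, site_center = spec$cavity_center, spec = spec,
         charge_total = sum(charges))
  })
}

#' A small synthetic ligand filling a cavity
#'
#' Atoms on a 1.5 A sphere around the center; its geometric center is the
#' cavity center, and every atom is within 4 A of it by construction.
#'
#' @param center cavity center, Angstrom.
#' @param n number of atoms.
#' @return a `ligand_structure`.
#' @export
fixture_ligand <- function(center, n = 8L) {
  pts <- fibonacci_sphere(n, 1.5, center)
  types <- rep_len(c("C", "OA"), n)
  ligand_structure(data.frame(
    serial = seq_len(n), name = types, element = element_from_type(types),
    x = pts[, 1], y = pts[, 2], z = pts[, 3], charge = 0,
    vdw_radius = ff_lookup(default_forcefield(), types)$radius,
    atom_type = types, stringsAsFactors = FALSE))
}

#' Write a fixture as PDBQT plus JSON ground truth
#'
#' @param fixture result of [make_hollow_shell()].
#' @param dir output directory (created if needed).
#' @return paths of the files written, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, fixture$protein$id)
  write_pdbqt(fixture$protein, paste0(base, ".pdbqt"))
  truth <- list(id = fixture$protein$id,
                site_center = fixture$site_center,
                spec = unclass(fixture$spec))
  jsonlite::write_json(truth, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(base, c(".pdbqt", ".json")))
}

#' Per-protein fixture specs for a corpus
#'
#' Cavity size (radius 5-6 A), shell radius, charge scheme and decoy count
#' vary per protein; every draw is derived from `(n_proteins, seed)`, so the
#' same arguments always give the same specs.
#'
#' @inheritParams make_labeled_corpus
#' @return list of `fixture_spec`s.
#' @export
corpus_specs <- function(n_proteins, seed) {
  with_seed(seed, {
    lapply(seq_len(n_proteins), function(i) {
      cr <- runif(1, 5.0, 6.0)
      fixture_spec(
        cavity_radius = cr,
        shell_radius = cr + runif(1, 6.2, 6.8),
        charge_scheme = c("alternating", "zero", "random")[1 + (i %% 3)],
        seed = seed * 1000L + i,
        n_decoys = sample(1:3, 1))
    })
  })
}

#' Build a labelled block corpus from synthetic fixtures
#'
#' Generates `n_proteins` shell fixtures with varied cavity sizes, charge
#' schemes and decoys, computes and normalizes each descriptor, and samples
#' 64 positive and up to 64 negative blocks per protein.  Proteins (not
#' blocks) are split into training and validation sets, so the two sets
#' never share a structure.
#'
#' @param n_proteins number of fixtures.
#' @param seed master seed; the corpus is a pure function of
#'   `(n_proteins, seed)`.
#' @param val_fraction fraction of proteins assigned to the validation set.
#' @return list with `x` (16,16,16,4,N array), `y` labels, `protein` index
#'   per block, `split` ("train"/"val" per block), `site_centers`
#'   (n_proteins x 3) and `specs`.
#' @export
make_labeled_corpus <- function(n_proteins, seed, val_fraction = 0.2) {
  stopifnot(n_proteins >= 1)
  specs <- corpus_specs(n_proteins, seed)
  xs <- list(); ys <- list(); pid <- list()
  centers <- matrix(0, n_proteins, 3)
  for (i in seq_len(n_proteins)) {
    fx <- make_hollow_shell(specs[[i]])
    # zero-charge fixtures legitimately produce an all-zero coulomb channel
    grid <- withCallingHandlers(
      normalize_descriptor(compute_descriptor(fx$protein)),
      warning = function(w) {
        if (grepl("partial charges are zero", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    blocks <- c(positive_blocks(grid, fx$site_center),
                negative_blocks(grid, fx$site_center,
                                seed = specs[[i]]$seed + 7L))
    ba <- block_array(blocks)
    xs[[i]] <- ba$x; ys[[i]] <- ba$y
    pid[[i]] <- rep(i, length(ba$y))
    centers[i, ] <- fx$site_center
  }
  nb <- vapply(xs, function(a) dim(a)[5], integer(1))
  x <- array(0, c(BLOCK, BLOCK, BLOCK, 4, sum(nb)))
  at <- 0L
  for (i in seq_len(n_proteins)) {
    x[, , , , at + seq_len(nb[i])] <- xs[[i]]
    at <- at + nb[i]
  }
  n_val <- floor(n_proteins * val_fraction)
  val_prot <- if (n_val > 0)
    with_seed(seed + 1L, sample.int(n_proteins, n_val)) else integer(0)
  protein <- unlist(pid)
  list(x = x, y = unlist(ys), protein = protein,
       split = ifelse(protein %in% val_prot, "val", "train"),
       site_centers = centers, specs = specs)
}
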