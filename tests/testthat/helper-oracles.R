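# Independent brute-force oracles used to cross-check the compiled kernels.
# They share no code with the implementation: the PSP oracle enumerates scan
# lines and classifies runs with rle(); the energy oracles loop over every
# voxel/atom pair; the DBSCAN oracle builds the core-point graph in igraph.

PSP_DIRS <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))

# all scan lines of a dims-sized grid for one direction: list of voxel-index
# vectors (1-based linear indices)
psp_lines <- function(dims, dir) {
  inside <- function(p) all(p >= 1) && all(p <= dims)
  lines <- list()
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
    for (i in seq_len(dims[1])) {
      p <- c(i, j, k)
      if (inside(p - dir)) next  # not a line start
      idx <- integer(0)
      while (inside(p)) {
        idx <- c(idx, p[1] + dims[1] * (p[2] - 1 + dims[2] * (p[3] - 1)))
        p <- p + dir
      }
      lines[[length(lines) + 1]] <- idx
    }
  lines
}

psp_lines_cached <- local({
  cache <- list()
  function(dims) {
    key <- paste(dims, collapse = "x")
    if (is.null(cache[[key]]))
      cache[[key]] <<- lapply(seq_len(nrow(PSP_DIRS)), function(d)
        psp_lines(dims, PSP_DIRS[d, ]))
    cache[[key]]
  }
})

# oracle PSP scan: per line, rle of the occupancy; solvent runs that are
# neither the first nor the last run are protein-bounded on both ends
psp_oracle <- function(mask) {
  dims <- dim(mask)
  out <- array(0L, dims)
  for (lines in psp_lines_cached(dims)) {
    for (idx in lines) {
      r <- rle(as.vector(mask[idx]))
      if (length(r$values) < 3) next
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (runi in seq_along(r$values)) {
        if (r$values[runi]) next                      # protein run
        if (runi == 1 || runi == length(r$values)) next  # open to boundary
        v <- idx[starts[runi]:ends[runi]]
        out[v] <- out[v] + 1L
      }
    }
  }
  out
}

voxel_center_grid <- function(spec) {
  as.matrix(expand.grid(voxel_centers(spec, 1), voxel_centers(spec, 2),
                        voxel_centers(spec, 3)))
}

# all-pairs vdW oracle (no spatial indexing): loops over voxels, vectorizes
# over atoms with the scalar pair potential
vdw_oracle <- function(protein, spec, params = energy_params(),
                       ff = default_forcefield(), probe_type = "C") {
  ctrs <- voxel_center_grid(spec)
  xyz <- coords(protein)
  probe <- ff_lookup(ff, probe_type)
  rows <- ff_lookup(ff, protein$atoms$atom_type)
  pairs <- lapply(seq_len(nrow(xyz)), function(a)
    combine_pair(probe, rows[a, ]))
  out <- numeric(nrow(ctrs))
  for (v in seq_len(nrow(ctrs))) {
    r <- sqrt(colSums((t(xyz) - ctrs[v, ])^2))
    e <- 0
    for (a in seq_len(nrow(xyz)))
      if (r[a] <= params$cutoff) e <- e + lj_12_6(r[a], pairs[[a]], params$cutoff)
    out[v] <- e
  }
  array(out, spec$shape)
}

coulomb_oracle <- function(protein, spec, params = energy_params()) {
  ctrs <- voxel_center_grid(spec)
  xyz <- coords(protein)
  q <- protein$atoms$charge
  out <- numeric(nrow(ctrs))
  for (v in seq_len(nrow(ctrs))) {
    r2 <- colSums((t(xyz) - ctrs[v, ])^2)
    keep <- r2 <= params$cutoff^2
    rterm <- if (params$coulomb_exponent == 2) r2 else sqrt(r2)
    out[v] <- sum(params$coulomb_k * q[keep] / rterm[keep])
  }
  array(out, spec$shape)
}

# enumerate every (probe atom, capable protein atom) candidate and keep the
# max-|E| energy per voxel
hbond_oracle <- function(protein, spec, params = energy_params(),
                         ff = default_forcefield(), probe = hydroxyl_probe()) {
  ctrs <- voxel_center_grid(spec)
  rows <- ff_lookup(ff, protein$atoms$atom_type)
  cap <- which(rows$hbond != "none")
  proberows <- ff_lookup(ff, probe$atom_type)
  out <- numeric(nrow(ctrs))
  for (v in seq_len(nrow(ctrs))) {
    best <- 0; bestabs <- 0
    for (pa in seq_len(nrow(probe))) {
      ppos <- ctrs[v, ] + as.numeric(probe[pa, c("dx", "dy", "dz")])
      for (a in cap) {
        roles <- c(proberows$hbond[pa], rows$hbond[a])
        if (!("donor" %in% roles && "acceptor" %in% roles)) next
        acc <- if (proberows$hbond[pa] == "acceptor") proberows[pa, ] else rows[a, ]
        if (is.na(acc$hb_epsilon)) next
        r <- sqrt(sum((as.numeric(protein$atoms[a, c("x", "y", "z")]) - ppos)^2))
        if (r > params$cutoff) next
        e <- lj_12_10(r, pair_params(acc$hb_epsilon, acc$hb_r0), params$cutoff)
        if (abs(e) > bestabs) { bestabs <- abs(e); best <- e }
      }
    }
    out[v] <- best
  }
  array(out, spec$shape)
}

# DBSCAN oracle: connected components of the core-point graph (igraph),
# border points attached to their nearest core
dbscan_oracle <- function(x, eps, min_pts) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(x))
  nb <- d <= eps
  core <- which(rowSums(nb) >= min_pts)
  labels <- integer(n)
  if (length(core)) {
    adj <- nb[core, core, drop = FALSE]
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    labels[core] <- igraph::components(g)$membership
    for (i in setdiff(seq_len(n), core)) {
      cand <- core[nb[i, core]]
      if (length(cand))
        labels[i] <- labels[cand[order(d[i, cand], cand)][1]]
    }
  }
  labels
}

# relabel clusters by order of first appearance so two labelings of the same
# partition compare equal (noise stays 0)
canonical_labels <- function(labels) {
  labels <- as.integer(labels)
  pos <- labels > 0
  labels[pos] <- match(labels[pos], unique(labels[pos]))
  labels
}

# a small random protein for oracle comparisons
random_test_protein <- function(n_atoms, seed, box = 6,
                                types = c("C", "N", "OA", "HD", "SA")) {
  set.seed(seed)
  ty <- sample(types, n_atoms, replace = TRUE)
  protein_structure(data.frame(
    serial = seq_len(n_atoms), name = ty, element = element_from_type(ty),
    x = runif(n_atoms, -box, box), y = runif(n_atoms, -box, box),
    z = runif(n_atoms, -box, box), charge = round(runif(n_atoms, -0.5, 0.5), 3),
    vdw_radius = ff_lookup(default_forcefield(), ty)$radius,
    atom_type = ty, stringsAsFactors = FALSE), id = paste0("rand", seed))
}

# a linearly separable toy block set: positives carry a centered blob in the
# shape channel
sep_blocks <- function(n, seed) {
  set.seed(seed)
  x <- array(rnorm(16^3 * 4 * n, 0, 0.3), c(16, 16, 16, 4, n))
  y <- rep_len(c(0, 1), n)
  for (s in which(y == 1))
    x[6:11, 6:11, 6:11, 1, s] <- x[6:11, 6:11, 6:11, 1, s] + 0.9
  list(x = x, y = y)
}

# a synthetic descriptor grid with smooth random channel values, already
# normalized, for block-sampling and scanning tests
fake_descriptor <- function(shape, seed = 1, normalized = TRUE) {
  set.seed(seed)
  spec <- grid_spec(origin = c(0, 0, 0), shape = shape)
  mk <- function() array(runif(prod(shape), -0.9, 0.9), shape)
  structure(list(spec = spec,
                 channels = list(shape = mk(), vdw = mk(), hbond = mk(),
                                 coulomb = mk()),
                 normalized = normalized, id = "fake"),
            class = "descriptor_grid")
}
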