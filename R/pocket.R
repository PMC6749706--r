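# Sliding-window pocket prediction.  The normalized descriptor is scanned
# with 16 A blocks at a 4 A stride, each block is scored by the classifier,
# blocks with probability >= 0.5 are clustered with DBSCAN on their centers
# (Eps = step + 1 = 5 A so that face-adjacent lattice blocks are neighbors
# while diagonal ones, 4*sqrt(2) ~ 5.66 A apart, are not; MinPts = 7), and
# each cluster becomes one pocket whose center is the unweighted mean of the
# member block centers and whose score is their mean probability.

#' Clustering and scanning parameters
#'
#' @param step scan stride in Angstrom (default 4).
#' @param eps DBSCAN neighborhood radius; defaults to `step + 1`.
#' @param min_pts DBSCAN minimum neighborhood size, counting the point
#'   itself (default 7).
#' @param threshold probability above which a block counts as positive.
#' @return list of class `clustering_params`.
#' @export
clustering_params <- function(step = 4L, eps = step + 1, min_pts = 7L,
                              threshold = 0.5) {
  stopifnot(eps > 0, min_pts >= 1, threshold > 0, threshold < 1, step >= 1)
  structure(list(step = as.integer(step), eps = eps,
                 min_pts = as.integer(min_pts), threshold = threshold),
            class = "clustering_params")
}

#' Score all scan blocks of a descriptor
#'
#' @param grid a normalized `descriptor_grid` at least 16 voxels on each
#'   axis.
#' @param model a trained `gridpocket_model`.
#' @param params a `clustering_params` (only `step` is used here).
#' @return object of class `block_scores`: data.frame `table` with block
#'   centers and probabilities plus the corner lattice.
#' @export
scan_protein <- function(grid, model, params = clustering_params()) {
  stopifnot(inherits(grid, "descriptor_grid"))
  if (!isTRUE(grid$normalized))
    stop("descriptor must be normalized before scanning", call. = FALSE)
  if (any(grid$spec$shape < BLOCK))
    stop("grid smaller than one 16^3 block", call. = FALSE)
  lat <- block_lattice(grid$spec, params$step)
  corners <- as.matrix(expand.grid(lat[[1]], lat[[2]], lat[[3]]))
  n <- nrow(corners)
  x <- array(0, c(BLOCK, BLOCK, BLOCK, 4, n))
  centers <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    x[, , , , i] <- extract_block(grid, corners[i, ])
    centers[i, ] <- block_center_from_corner(grid$spec, corners[i, ])
  }
  prob <- predict_blocks(model, x)
  structure(list(table = data.frame(x = centers[, 1], y = centers[, 2],
                                    z = centers[, 3], prob = prob),
                 corners = corners, spec = grid$spec),
            class = "block_scores")
}

#' Density-based clustering (DBSCAN)
#'
#' Classic DBSCAN on Euclidean distance.  A point is a core point when at
#' least `min_pts` points (itself included) lie within `eps`; clusters are
#' the connected components of core points under the eps-neighbor relation;
#' non-core points within `eps` of a core point join the cluster of their
#' nearest core (ties broken by lowest index); the rest are noise.
#'
#' @param x numeric matrix, one point per row.
#' @param eps neighborhood radius.
#' @param min_pts minimum neighborhood size, counting the point itself.
#' @return integer cluster labels, 0 for noise.
#' @export
dbscan_cluster <- function(x, eps, min_pts) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(x))
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      for (k in which(nb[j, ] & core & labels == 0L)) {
        labels[k] <- cl
        queue <- c(queue, k)
      }
    }
  }
  # border points: nearest core neighbor's cluster
  for (i in which(!core)) {
    cand <- which(nb[i, ] & core)
    if (length(cand)) {
      best <- cand[order(d[i, cand], cand)][1]
      labels[i] <- labels[best]
    }
  }
  labels
}

#' Cluster positive blocks into ranked pockets
#'
#' Thresholds the scored blocks, clusters the survivors with DBSCAN and
#' reports one pocket per cluster: center = unweighted mean of member block
#' centers, score = mean member probability.  Noise blocks are dropped.
#' Pockets are sorted by score (descending), ties broken by cluster size
#' then lexicographic center order, so the ranking is deterministic.
#'
#' @param scored a `block_scores` object from [scan_protein()].
#' @param params a `clustering_params`.
#' @return data.frame of class `pocket_predictions` with columns `x`, `y`,
#'   `z`, `score`, `n_blocks`; member row indices in attribute `members`.
#' @export
cluster_positive_blocks <- function(scored, params = clustering_params()) {
  stopifnot(inherits(scored, "block_scores"))
  tab <- scored$table
  pass <- which(tab$prob >= params$threshold)
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      score = numeric(0), n_blocks = integer(0))
  if (length(pass) == 0) return(structure(empty, class = c("pocket_predictions", "data.frame"),
                                          members = list()))
  pts <- as.matrix(tab[pass, c("x", "y", "z")])
  labels <- dbscan_cluster(pts, params$eps, params$min_pts)
  ids <- setdiff(unique(labels), 0L)
  if (length(ids) == 0) return(structure(empty, class = c("pocket_predictions", "data.frame"),
                                         members = list()))
  rows <- lapply(ids, function(cl) {
    m <- pass[labels == cl]
    ctr <- colMeans(tab[m, c("x", "y", "z")])
    data.frame(x = ctr[1], y = ctr[2], z = ctr[3],
               score = mean(tab$prob[m]), n_blocks = length(m))
  })
  pockets <- do.call(rbind, rows)
  members <- lapply(ids, function(cl) pass[labels == cl])
  ord <- order(-pockets$score, -pockets$n_blocks,
               pockets$x, pockets$y, pockets$z)
  pockets <- pockets[ord, , drop = FALSE]
  rownames(pockets) <- NULL
  structure(pockets, class = c("pocket_predictions", "data.frame"),
            members = members[ord])
}

#' Keep the n highest-scoring pockets
#'
#' The input is already deterministically ranked; this is a stable head.
#'
#' @param pockets a `pocket_predictions` data.frame.
#' @param n number of pockets to keep.
#' @return the first `min(n, nrow)` pockets.
#' @export
top_n <- function(pockets, n) {
  head(pockets, n)
}

#' Full prediction pipeline for one protein
#'
#' Descriptor, normalization, stride scan, thresholding and clustering in
#' one call.
#'
#' @param protein a `protein_structure`.
#' @param model a trained `gridpocket_model`.
#' @param params a `clustering_params`.
#' @param ff force-field table.
#' @param energy an `energy_params` object.
#' @return a `pocket_predictions` data.frame.
#' @export
predict_pockets <- function(protein, model, params = clustering_params(),
                            ff = default_forcefield(),
                            energy = energy_params()) {
  grid <- normalize_descriptor(compute_descriptor(protein, ff, energy))
  scored <- scan_protein(grid, model, params)
  cluster_positive_blocks(scored, params)
}

#' Write pockets as TSV, JSON or pseudo-atom PDB
#'
#' The PDB output holds one HETATM per pocket center (score in the B-factor
#' column) for quick visualization.
#'
#' @param pockets a `pocket_predictions` data.frame.
#' @param path output file; format chosen by extension (.tsv, .json, .pdb).
#' @return `path`, invisibly.
#' @export
write_pockets <- function(pockets, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(pockets), path, digits = NA)
  } else if (grepl("\\.pdb$", path)) {
    lines <- sprintf(
      "HETATM%5d  C   PKT %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(pockets)), "A", seq_len(nrow(pockets)),
      pockets$x, pockets$y, pockets$z, 1, pockets$score)
    writeLines(c(lines, "END"), path)
  } else {
    utils::write.table(as.data.frame(pockets), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
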