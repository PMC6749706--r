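fake_scores <- function(centers, prob) {
  structure(list(table = data.frame(x = centers[, 1], y = centers[, 2],
                                    z = centers[, 3], prob = prob)),
            class = "block_scores")
}

# a 3x3x3 clump of block centers on the stride-4 lattice around a point
lattice_clump <- function(center, k = 3, step = 4) {
  offs <- step * (seq_len(k) - (k + 1) / 2)
  as.matrix(expand.grid(center[1] + offs, center[2] + offs, center[3] + offs))
}

test_that("the stride-4 scan enumerates fully contained blocks", {
  g <- fake_descriptor(c(26, 26, 26), seed = 1)
  m <- build_model(network_config(seed = 2))
  sc <- scan_protein(g, m)
  expect_equal(nrow(sc$table), 27)          # floor((26-16)/4)+1 = 3 per axis
  g16 <- fake_descriptor(c(16, 16, 16), seed = 2)
  expect_equal(nrow(scan_protein(g16, m)$table), 1)
  # deterministic across repeated calls
  sc2 <- scan_protein(g, m)
  expect_identical(sc$table$prob, sc2$table$prob)
  raw <- fake_descriptor(c(26, 26, 26), seed = 1, normalized = FALSE)
  expect_error(scan_protein(raw, m), "normalized")
  tiny <- fake_descriptor(c(12, 16, 16), seed = 3)
  expect_error(scan_protein(tiny, m), "block")
})

test_that("DBSCAN matches the graph-components oracle on random points", {
  set.seed(14)
  for (rep in 1:40) {
    n <- sample(20:80, 1)
    pts <- matrix(runif(3 * n, 0, 12), ncol = 3)
    eps <- runif(1, 1.5, 3)
    mp <- sample(2:6, 1)
    got <- canonical_labels(dbscan_cluster(pts, eps, mp))
    want <- canonical_labels(dbscan_oracle(pts, eps, mp))
    expect_identical(got, want)
  }
})

test_that("Eps = 5 links face-adjacent stride blocks but not diagonal ones", {
  p <- clustering_params()
  expect_equal(p$eps, 5)
  ctr <- c(10, 10, 10)
  faces <- rbind(ctr, ctr + c(4, 0, 0), ctr - c(4, 0, 0), ctr + c(0, 4, 0),
                 ctr - c(0, 4, 0), ctr + c(0, 0, 4), ctr - c(0, 0, 4))
  lab <- dbscan_cluster(faces, p$eps, p$min_pts)
  expect_equal(lab, rep(1L, 7))             # center is a core with 6+self
  offs <- 4 * rbind(c(1, 1, 0), c(-1, 1, 0), c(1, -1, 0),
                    c(-1, -1, 0), c(1, 0, 1), c(-1, 0, 1))
  diag7 <- rbind(ctr, sweep(offs, 2, ctr, "+"))
  lab2 <- dbscan_cluster(diag7, p$eps, p$min_pts)
  expect_equal(lab2, rep(0L, 7))            # 4*sqrt(2) ~ 5.66 > 5: all noise
})

test_that("clusters become pockets with mean centers and mean scores", {
  p <- clustering_params()
  clump <- lattice_clump(c(20, 20, 20))
  probs <- seq(0.6, 0.95, length.out = nrow(clump))
  sc <- fake_scores(rbind(clump, c(80, 80, 80)), c(probs, 0.99))
  pk <- cluster_positive_blocks(sc, p)
  # the lone distant block is noise; in the 3x3x3 clump only the center is
  # core (6 face neighbors + itself = MinPts), so the pocket is the center
  # plus its six face neighbors
  expect_equal(nrow(pk), 1)
  d <- sqrt(rowSums(sweep(clump, 2, c(20, 20, 20))^2))
  mem <- d <= p$eps
  expect_equal(pk$n_blocks, sum(mem))
  expect_equal(c(pk$x, pk$y, pk$z), unname(colMeans(clump[mem, ])))
  expect_equal(pk$score, mean(probs[mem]))
  expect_gte(pk$n_blocks, p$min_pts)
})

test_that("single passing blocks are noise and empty inputs are valid", {
  p <- clustering_params()
  sc <- fake_scores(matrix(c(5, 5, 5), 1), 0.99)
  expect_equal(nrow(cluster_positive_blocks(sc, p)), 0)
  sc0 <- fake_scores(lattice_clump(c(0, 0, 0)), rep(0.2, 27))
  expect_equal(nrow(cluster_positive_blocks(sc0, p)), 0)  # none pass 0.5
})

test_that("two well-separated dense groups give two ranked pockets", {
  p <- clustering_params()
  a <- lattice_clump(c(0, 0, 0))
  b <- lattice_clump(c(40, 0, 0))
  sc <- fake_scores(rbind(a, b), c(rep(0.7, 27), rep(0.9, 27)))
  pk <- cluster_positive_blocks(sc, p)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$score, c(0.9, 0.7))       # sorted by score descending
  expect_equal(pk$x, c(40, 0))
  expect_equal(top_n(pk, 1)$x, 40)
  expect_equal(nrow(top_n(pk, 5)), 2)       # fewer pockets than requested
})

test_that("raising the threshold never feeds more blocks to clustering", {
  set.seed(31)
  pts <- matrix(runif(300, 0, 40), ncol = 3)
  probs <- runif(100)
  sc <- fake_scores(pts, probs)
  sizes <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th) {
    pk <- cluster_positive_blocks(sc, clustering_params(threshold = th))
    sum(pk$n_blocks)
  }, numeric(1))
  passed <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th) sum(probs >= th),
                   numeric(1))
  expect_true(all(diff(passed) <= 0))
  expect_true(all(sizes <= passed))
})

test_that("tied pockets rank deterministically by size then center", {
  a <- lattice_clump(c(0, 0, 0))
  b <- lattice_clump(c(40, 0, 0))
  sc <- fake_scores(rbind(a, b), rep(0.8, 54))
  pk1 <- cluster_positive_blocks(sc, clustering_params())
  pk2 <- cluster_positive_blocks(sc, clustering_params())
  expect_identical(pk1$x, pk2$x)
  expect_equal(pk1$x, c(0, 40))             # equal score and size: by center
})

test_that("pocket output formats round-trip the table", {
  pk <- structure(data.frame(x = c(1.5, 9), y = c(2, 3), z = c(0, -4),
                             score = c(0.9, 0.7), n_blocks = c(9L, 8L)),
                  class = c("pocket_predictions", "data.frame"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_pockets(pk, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(back$score, pk$score)
  js <- withr::local_tempfile(fileext = ".json")
  write_pockets(pk, js)
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE)$x, pk$x)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_pockets(pk, pdb)
  expect_equal(length(readLines(pdb)), 3)
})
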