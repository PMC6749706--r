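mk_pockets <- function(centers, scores) {
  structure(data.frame(x = centers[, 1], y = centers[, 2], z = centers[, 3],
                       score = scores, n_blocks = rep(9L, nrow(centers))),
            class = c("pocket_predictions", "data.frame"))
}

test_that("offset is the Euclidean center distance", {
  expect_equal(offset(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(offset(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(offset(c(1, 1, 1), c(2, 2, 2)), sqrt(3))
})

test_that("topN offset takes the best among the n highest-scoring pockets", {
  # pockets ranked by score with offsets 10, 2, 6, 1 from the origin
  pk <- mk_pockets(rbind(c(10, 0, 0), c(2, 0, 0), c(6, 0, 0), c(1, 0, 0)),
                   scores = c(0.9, 0.8, 0.7, 0.6))
  actual <- c(0, 0, 0)
  expect_equal(topN_offset(pk, actual, 1), 10)
  expect_equal(topN_offset(pk, actual, 3), 2)
  expect_equal(topN_offset(pk, actual, 5), 1)
  # non-increasing in n
  offs <- vapply(1:5, function(n) topN_offset(pk, actual, n), numeric(1))
  expect_true(all(diff(offs) <= 0))
  expect_equal(topN_offset(mk_pockets(matrix(0, 0, 3), numeric(0)), actual, 3),
               Inf)
})

test_that("evaluation records keep top5 <= top3 <= top1", {
  set.seed(20)
  for (rep in 1:25) {
    n <- sample(0:6, 1)
    pk <- mk_pockets(matrix(runif(3 * n, -20, 20), ncol = 3), runif(n))
    rec <- evaluate_protein("p", pk, actual_center = c(0, 0, 0))
    expect_lte(rec$offset_top5, rec$offset_top3)
    expect_lte(rec$offset_top3, rec$offset_top1)
  }
})

test_that("the 4 A hit criterion checks pocket centers against ligand atoms", {
  lig <- fixture_ligand(c(0, 0, 0))          # atoms on a 1.5 A sphere
  mind <- function(p) min(sqrt(colSums((t(coords(lig)) - p)^2)))
  for (p in list(c(0, 0, 5.0), c(0, 0, 5.6), c(3.9, 0, 0), c(6, 1, 1))) {
    expect_equal(hit_within(mk_pockets(rbind(p), 0.9), lig), mind(p) <= 4)
  }
  # both branches of the criterion are exercised
  expect_true(mind(c(0, 0, 5.0)) <= 4)
  expect_gt(mind(c(0, 0, 5.6)), 4)
  # a pocket at the ligand centroid always hits a compact ligand
  expect_true(hit_within(mk_pockets(rbind(c(0, 0, 0)), 1), lig))
  expect_false(hit_within(mk_pockets(matrix(0, 0, 3), numeric(0)), lig))
  expect_error(hit_within(hit, list(atoms = NULL)), "empty")
})

test_that("summaries bin offsets, sum errors and track no-prediction cases", {
  rec <- function(off, n_pockets = 2, hit = NA) {
    r <- list(id = "x", n_pockets = n_pockets, offset_top3 = off,
              offset_top1 = off, offset_top5 = off, hit_4A = hit)
    class(r) <- "evaluation_record"
    r
  }
  s <- summarize_records(list(rec(2), rec(6)), bin_edges = c(0, 5, 10))
  expect_equal(unname(s$proportions), c(0.5, 0.5))
  expect_equal(s$error_sum, 8)
  expect_equal(s$mean_offset, 4)
  expect_equal(summarize_records(list(rec(6)))$mean_offset, 6)
  # proportions over covering bins sum to one
  expect_equal(sum(s$proportions), 1)
  # no-prediction records are reported separately, not averaged in
  s2 <- summarize_records(list(rec(2), rec(Inf, n_pockets = 0)),
                          bin_edges = c(0, 5, 10))
  expect_equal(s2$n_no_prediction, 1)
  expect_equal(s2$error_sum, 2)
  # error sum matches a brute-force total on a large synthetic batch
  set.seed(3)
  offs <- runif(1000, 0, 30)
  s3 <- summarize_records(lapply(offs, rec), bin_edges = c(0, 10, 20, 30))
  expect_equal(s3$error_sum, sum(offs))
  expect_equal(sum(s3$proportions), 1)
  expect_error(summarize_records(list()), "no records")
})
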