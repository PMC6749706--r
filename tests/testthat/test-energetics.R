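test_that("pair combination follows the Amber/AutoDock rules", {
  p <- combine_pair(list(epsilon = 0.15, rmin = 1.75),
                    list(epsilon = 0.15, rmin = 1.75))
  expect_equal(p$epsilon, 0.15)
  expect_equal(p$r0, 3.5)
  expect_equal(p$A, 0.15 * 3.5^12)
  expect_equal(p$B, 2 * 0.15 * 3.5^6)
  p2 <- combine_pair(list(epsilon = 0.25, rmin = 2), list(epsilon = 0.09, rmin = 1.5))
  expect_equal(p2$epsilon, 0.15)
  p0 <- combine_pair(list(epsilon = 0, rmin = 1), list(epsilon = 0.2, rmin = 1))
  expect_equal(c(p0$A, p0$B, p0$C, p0$D), rep(0, 4))
})

test_that("both potentials reach depth -epsilon exactly at r0", {
  for (eps in c(0.02, 0.15, 1, 5)) {
    for (r0 in c(1.9, 3, 3.5, 4.2)) {
      p <- pair_params(eps, r0)
      expect_equal(lj_12_6(r0, p), -eps, tolerance = 1e-12)
      expect_equal(lj_12_10(r0, p), -eps, tolerance = 1e-12)
      # r0 is the minimum: numerical minimization over r agrees
      for (fn in list(lj_12_6, lj_12_10)) {
        opt <- stats::optimize(function(r) fn(r, p, cutoff = Inf),
                               c(0.5 * r0, 2 * r0), tol = 1e-10)
        expect_equal(opt$minimum, r0, tolerance = 1e-5)
        expect_equal(opt$objective, -eps, tolerance = 1e-9)
      }
    }
  }
})

test_that("the 12-6 potential evaluates correctly at twice the well distance", {
  p <- pair_params(0.15, 3.5)
  expect_equal(lj_12_6(7, p), -(127 / 4096) * 0.15, tolerance = 1e-12)
  expect_equal(lj_12_6(9, p), 0)        # beyond the 8 A cutoff
  expect_error(lj_12_6(0, p), "positive")
  expect_error(lj_12_10(-1, p), "positive")
  # oxygen hydrogen-bond well: 5 kcal/mol at 1.9 A
  ph <- pair_params(5, 1.9)
  expect_equal(lj_12_10(1.9, ph), -5)
  expect_equal(lj_12_10(100, ph), 0)
})

test_that("energy grids match the all-pairs oracle", {
  prot <- random_test_protein(20, seed = 31, box = 4)
  spec <- grid_spec(c(-7, -7, -7), c(14, 14, 14))
  pars <- energy_params()
  vd <- vdw_channel(prot, spec, pars)$values
  vo <- vdw_oracle(prot, spec, pars)
  expect_equal(vd, vo, tolerance = 1e-9)
  hb <- hbond_channel(prot, spec, pars)$values
  ho <- hbond_oracle(prot, spec, pars)
  expect_equal(hb, ho, tolerance = 1e-9)
  cl <- coulomb_channel(prot, spec, pars)$values
  co <- coulomb_oracle(prot, spec, pars)
  expect_equal(cl, co, tolerance = 1e-9)
})

test_that("all channels vanish beyond the cutoff", {
  prot <- protein_structure(data.frame(
    serial = 1:2, name = c("OA", "HD"), element = c("O", "H"),
    x = c(0, 1), y = 0, z = 0, charge = c(-0.4, 0.4),
    vdw_radius = c(1.6, 1), atom_type = c("OA", "HD")))
  spec <- grid_spec(c(-2, -2, -2), c(24, 6, 6))
  pars <- energy_params(cutoff = 8)
  vd <- vdw_channel(prot, spec, pars)$values
  hb <- hbond_channel(prot, spec, pars)$values
  cb <- coulomb_channel(prot, spec, pars)$values
  ctrs <- voxel_center_grid(spec)
  far <- apply(ctrs, 1, function(v)
    min(sqrt(sum((v - c(0, 0, 0))^2)), sqrt(sum((v - c(1, 0, 0))^2))))
  expect_true(all(vd[far > 8] == 0))
  expect_true(all(cb[far > 8] == 0))
  # the hydroxyl probe extends 0.96 A from the voxel center
  expect_true(all(hb[far > 8 + 0.96] == 0))
  expect_true(any(vd != 0) && any(hb != 0) && any(cb != 0))
})

test_that("hydrogen-bond channel keeps the max-|E| candidate, not the sum", {
  # one acceptor and one donor H at different distances from a probe: the
  # voxel value must equal one of the candidate energies, the largest in
  # absolute value (which may be negative when a positive one exists)
  prot <- protein_structure(data.frame(
    serial = 1:2, name = c("OA", "HD"), element = c("O", "H"),
    x = c(2.0, -1.2), y = 0, z = 0, charge = 0,
    vdw_radius = c(1.6, 1), atom_type = c("OA", "HD")))
  spec <- grid_spec(c(-0.5, -0.5, -0.5), c(1, 1, 1))  # single voxel at origin
  pars <- energy_params()
  got <- hbond_channel(prot, spec, pars)$values[1, 1, 1]
  # candidates computed by hand from the probe geometry
  probe <- hydroxyl_probe()
  cand <- c(
    lj_12_10(2.0 - 0.96, pair_params(5, 1.9)),  # probe HD (at +0.96) vs OA at 2.0
    lj_12_10(1.2, pair_params(5, 1.9)))         # probe OA (at 0) vs protein HD
  expect_equal(got, cand[which.max(abs(cand))], tolerance = 1e-9)
  expect_true(any(sign(cand) != sign(got)) || length(unique(sign(cand))) == 1)
})

test_that("coulomb channel follows the printed inverse-square form", {
  mk <- function(q, x) protein_structure(data.frame(
    serial = seq_along(q), name = "C", element = "C", x = x, y = 0.5, z = 0.5,
    charge = q, vdw_radius = 2, atom_type = "C"))
  spec <- grid_spec(c(0, 0, 0), c(6, 1, 1))
  K <- energy_params()$coulomb_k
  # single +1 charge 1 A from a voxel center: value K
  v <- coulomb_channel(mk(1, 1.5), spec)$values
  expect_equal(v[1, 1, 1], K, tolerance = 1e-12)
  # -0.5 charge at 2 A: K * (-0.5) / 4
  v2 <- coulomb_channel(mk(-0.5, 2.5), spec)$values
  expect_equal(v2[1, 1, 1], -0.125 * K, tolerance = 1e-12)
  # mirrored +/- charges cancel at the midpoint voxel
  v3 <- coulomb_channel(mk(c(0.3, -0.3), c(0.5, 4.5)), spec)$values
  expect_equal(v3[3, 1, 1], 0, tolerance = 1e-12)
  # inverse-r option
  v4 <- coulomb_channel(mk(1, 2.5), spec, energy_params(coulomb_exponent = 1))$values
  expect_equal(v4[1, 1, 1], K / 2, tolerance = 1e-12)
  expect_warning(coulomb_channel(mk(0, 1.5), spec), "zero")
})

test_that("channels are translation equivariant", {
  prot <- random_test_protein(15, seed = 8, box = 3)
  shift <- c(5.3, -2.7, 1.9)
  atoms2 <- prot$atoms
  atoms2$x <- atoms2$x + shift[1]
  atoms2$y <- atoms2$y + shift[2]
  atoms2$z <- atoms2$z + shift[3]
  prot2 <- protein_structure(atoms2)
  spec1 <- grid_spec(c(-6, -6, -6), c(12, 12, 12))
  spec2 <- grid_spec(c(-6, -6, -6) + shift, c(12, 12, 12))
  for (ch in list(vdw_channel, hbond_channel, coulomb_channel)) {
    a <- ch(prot, spec1)$values
    b <- ch(prot2, spec2)$values
    expect_equal(a, b, tolerance = 1e-9)
  }
})
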