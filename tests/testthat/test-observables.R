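test_that("end-to-end and center-of-mass observables match hand calculations", {
  expect_equal(squared_end_to_end(rbind(c(0, 0, 0), c(3, 4, 0))), 25)
  nearly_closed <- rbind(c(0, 0, 0), c(1, 1, 0), c(0, 0, 1e-12))
  expect_equal(squared_end_to_end(nearly_closed), 1e-24)
  rod <- cbind(seq(0, 7, length.out = 15), 0, 0)
  expect_equal(squared_end_to_end(rod), arclength(rod)^2)

  two <- list(rbind(c(0, 0, 0), c(0, 0, 1e-9)),
              rbind(c(3, 0, 0), c(3, 0, 1e-9)))
  expect_equal(mean_sq_com_distance(two), 9, tolerance = 1e-12)
  expect_equal(mean_sq_com_distance(list(rod, rod)), 0)
  tri <- lapply(list(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                function(c0) rbind(c0 - c(0, 0, 0.1), c0 + c(0, 0, 0.1)))
  expect_equal(mean_sq_com_distance(tri), 1, tolerance = 1e-12)
})

test_that("analytic ACN agrees with the projection-counting oracle", {
  set.seed(6)
  a <- rbind(c(0, 0, 0), c(1, 0, 0))
  b <- rbind(c(0.3, 0.4, 0.5), c(0.9, 1.0, 0.2))
  expect_lt(abs(acn_pair(a, b) - acn_projection(a, b, n_dirs = 2e5)),
            0.005)
  for (i in 1:4) {
    x <- random_polyline(6)
    y <- random_polyline(6)
    inter <- acn_pair(x, y)
    expect_lt(abs(inter - acn_projection(x, y, n_dirs = 1e5)),
              0.01 + 0.015 * inter)
    intra <- acn_pair(x)
    expect_lt(abs(intra - acn_projection(x, n_dirs = 1e5)),
              0.01 + 0.03 * intra)
  }
})

test_that("ACN is Euclidean- and scale-invariant and decays with separation", {
  set.seed(7)
  x <- random_polyline(8)
  y <- random_polyline(8)
  base <- acn_pair(x, y)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(acn_pair(x %*% rot + 2, y %*% rot + 2), base,
               tolerance = 1e-10)
  expect_equal(acn_pair(x * 7.3, y * 7.3), base, tolerance = 1e-10)
  expect_gte(base, 0)
  # Gauss integrand decays as 1/r^2: negligible at 100x separation
  size <- max(dist(rbind(x, y)))
  expect_lt(acn_pair(x, y + 100 * size), 1e-3)
  # simple planar polyline has zero self-crossing number
  zig <- cbind(seq(0, 9), rep(c(0, 1), 5), 0)
  expect_equal(acn_pair(zig), 0)
})

test_that("ensemble mean ACN separates intra and inter contributions", {
  rods <- lapply(1:3, function(i) cbind(seq(0, 10), 0, 2 * i))
  one <- mean_acn(list(rods))
  expect_equal(one$macn_intra, 0)
  dup <- mean_acn(list(rods, rods))
  expect_equal(dup$macn_intra, one$macn_intra)
  expect_equal(dup$macn_inter, one$macn_inter)
  expect_equal(dup$se_intra, 0)
  expect_equal(dup$se_inter, 0)
})

test_that("end-to-end distance histogram is density-normalized", {
  same <- ree_distribution(rep(2.5, 50), breaks = 10)
  expect_equal(sum(same$density * diff(same$breaks)), 1, tolerance = 1e-9)
  expect_equal(sum(same$counts > 0), 1L)
  set.seed(8)
  u <- runif(1e5)
  h <- ree_distribution(u, breaks = seq(0, 1, by = 0.1))
  expect_true(all(abs(h$density - 1) < 0.05))
  expect_equal(sum(h$density * diff(h$breaks)), 1, tolerance = 1e-9)
})

test_that("ensemble_stats aggregates all observables with errors", {
  set.seed(9)
  confs <- lapply(1:12, function(i)
    lapply(1:3, function(j) random_polyline(10) + 3 * j))
  st <- ensemble_stats(confs, resample_n = 10)
  expect_s3_class(st, "ensemble_stats")
  expect_equal(st$n_conformations, 12L)
  expect_gt(st$mean_sq_ree, 0)
  expect_gt(st$mean_sq_dcm, 0)
  expect_gt(st$se_sq_ree, 0)
  expect_gte(st$macn_intra, 0)
  direct <- mean(vapply(confs, function(cf)
    mean(vapply(cf, squared_end_to_end, 0)), 0))
  expect_equal(st$mean_sq_ree, direct)
})
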