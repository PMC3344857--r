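test_that("the WLC generator honors limits, tethering and reproducibility", {
  stiff <- synth_config(n_chains = 1L, l_p_um = 1e6, tether_mode = "free",
                        seed = 1L)
  set.seed(1)
  tr <- sample_wlc_trace(stiff)
  expect_equal(sqrt(squared_end_to_end(tr)) / arclength(tr), 1,
               tolerance = 1e-3)

  teth <- synth_config(n_chains = 2L, seed = 3L)
  ds <- generate_nucleus(teth)
  r <- teth$cavity$diameter_um / 2
  for (t in ds$traces) {
    p <- t$points
    expect_equal(sqrt(sum(p[1L, ]^2)), r, tolerance = 1e-6)
    expect_equal(sqrt(sum(p[nrow(p), ]^2)), r, tolerance = 1e-6)
    # all interior points inside the cavity
    expect_true(all(rowSums(p^2) <= r^2 + 1e-9))
  }
  expect_identical(generate_nucleus(teth)$traces[[1L]]$points,
                   ds$traces[[1L]]$points)
  expect_length(generate_nucleus(synth_config(n_chains = 19L,
                                              n_points = 12L,
                                              seed = 5L))$traces, 19L)
})

test_that("generated contour lengths scatter around the configured mean", {
  cfg <- synth_config(n_chains = 100L, n_points = 13L, l_p_um = 1,
                      tether_mode = "free", seed = 7L)
  ds <- generate_nucleus(cfg)
  contours <- vapply(ds$traces, arclength, 0)
  expect_equal(mean(contours), 12, tolerance = 0.05 * 12)
  expect_true(all(contours >= 12 * 0.8 - 1e-9 &
                    contours <= 12 * 1.2 + 1e-9))
})

test_that("persistence length round-trips through the estimator", {
  for (lp in c(0.5, 2)) {
    cfg <- synth_config(n_chains = 1L, n_points = 61L, l_p_um = lp,
                        tether_mode = "free", seed = 11L)
    set.seed(11)
    traces <- replicate(250, sample_wlc_trace(cfg), simplify = FALSE)
    est <- effective_persistence_length(traces)
    expect_equal(est$l_p, lp, tolerance = 0.15 * lp)
  }
})

test_that("localization noise behaves like an isotropic Gaussian", {
  rod <- sc_trace(cbind(seq(0, 12, length.out = 61), 0, 0), "r", "n")
  expect_identical(add_noise(rod, 0), rod)
  sigma <- 0.05
  set.seed(12)
  disp <- replicate(400, {
    noisy <- add_noise(rod, sigma)
    sqrt(rowSums((noisy$points - rod$points)^2))
  })
  # closed form for the mean norm of a 3D Gaussian: sigma * sqrt(8 / pi)
  expect_equal(mean(disp), sigma * sqrt(8 / pi), tolerance = 0.02)
  # noise strictly lengthens a straight trace in expectation
  set.seed(13)
  lens <- replicate(200, arclength(add_noise(rod, sigma)))
  expect_gt(mean(lens), arclength(rod))
  # tethered endpoints are re-projected onto the cavity boundary
  cav <- list(shape = "sphere", diameter_um = 10)
  sph <- sc_trace(cbind(seq(-5, 5, length.out = 21), 0, 0), "d", "n")
  set.seed(14)
  noisy <- add_noise(sph, 0.1, cavity = cav)
  expect_equal(sqrt(sum(noisy$points[1L, ]^2)), 5, tolerance = 1e-9)
  expect_equal(sqrt(sum(noisy$points[21L, ]^2)), 5, tolerance = 1e-9)
})

test_that("infeasible cavity/persistence combinations are reported", {
  cramped <- synth_config(n_chains = 1L, contour_length_um = 12,
                          l_p_um = 500, n_points = 25L,
                          cavity = list(shape = "sphere", diameter_um = 2),
                          seed = 15L)
  set.seed(15)
  expect_error(sample_wlc_trace(cramped, max_restarts = 50L),
               "infeasible")
})
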