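test_that("autocorrelation matches closed forms and error bounds", {
  expect_equal(autocorrelation(rep(c(1, -1), 50), 1)[2L], -1,
               tolerance = 0.02)  # alternating series
  set.seed(1)
  iid <- rnorm(1e5)
  expect_lt(abs(autocorrelation(iid, 1)[2L]), 0.02)  # ~ 1/sqrt(n)
  set.seed(2)
  ar <- as.numeric(arima.sim(list(ar = 0.5), 1e6))
  rho <- autocorrelation(ar, 5)
  expect_equal(rho[2:6], 0.5^(1:5), tolerance = 0.01)
  expect_error(autocorrelation(rep(3, 10)), "zero variance")
})

test_that("Sokal windowing recovers the AR(1) integrated time", {
  set.seed(3)
  noise <- rnorm(5e4)
  d <- acf_diagnostics(noise)
  expect_equal(d$tau_int, 0.5, tolerance = 0.05)
  for (rho in c(0.5, 0.9)) {
    set.seed(4)
    ar <- as.numeric(arima.sim(list(ar = rho), 1e6))
    d <- acf_diagnostics(ar)
    expect_equal(d$tau_int, (1 + rho) / (2 * (1 - rho)), tolerance = 0.1 *
                   (1 + rho) / (2 * (1 - rho)))
    expect_lte(d$window, max(d$lags))
  }
  # strongly correlated short series admits no self-consistent window
  expect_error(integrated_autocorrelation_time(rep(1, 10)),
               "no self-consistent")
})

test_that("decorrelated extraction spaces and prunes conformations", {
  confs <- as.list(1:100)
  out <- decorrelated_ensemble(confs, sweeps = 1:100, tau_int = 0.5,
                               n_target = 50)
  expect_length(out$conformations, 50L)
  expect_equal(out$spacing, 1L)
  expect_false(out$short)
  expect_true(all(out$sweeps > 5))  # burn-in of 10 * tau
  expect_warning(
    short <- decorrelated_ensemble(confs, 1:100, tau_int = 0.5,
                                   n_target = 200),
    "decorrelated conformations available")
  expect_true(short$short)
  # output subseries of a real run is decorrelated
  cfg <- tiny_config(kappa = 1, seed = 19L)
  pilot <- run_sweeps(init_state(cfg), 30000)
  tau <- acf_diagnostics(rowMeans(pilot$r2ee)[10001:30000])$tau_int
  traj <- run_sweeps(pilot$state, ceiling(2 * tau) * 120,
                     record_conf_every = ceiling(2 * tau))
  sub <- vapply(traj$conformations, function(cf)
    mean(vapply(cf, squared_end_to_end, 0)), 0)
  expect_lt(abs(autocorrelation(sub, 1)[2L]), 0.25)
})

test_that("persistence length estimation handles limits and real chains", {
  rods <- replicate(20, {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    outer(seq(0, 19), u)
  }, simplify = FALSE)
  est <- effective_persistence_length(rods)
  expect_true(est$censored)
  expect_gt(est$l_p, 5)  # only a lower bound, far above the fit range

  # freely jointed BFM chain: effective l_p of about one Kuhn length
  cfg <- sim_config(n_chains = 1L, n_monomers = 30L, box_side = 200L,
                    kappa = 0, tether_mode = "untethered", seed = 23L)
  traj <- run_sweeps(init_state(cfg), 120000, record_conf_every = 400)
  confs <- lapply(traj$conformations[101:300], `[[`, 1L)
  b <- mean(unlist(lapply(confs, function(p) sqrt(rowSums(diff(p)^2)))))
  est0 <- effective_persistence_length(confs)
  expect_equal(est0$l_p / b, 1, tolerance = 0.25)

  # stiffer chains fit longer persistence lengths
  lp_at <- function(kappa, seed) {
    cfg <- sim_config(n_chains = 1L, n_monomers = 30L, box_side = 200L,
                      kappa = kappa, tether_mode = "untethered", seed = seed)
    traj <- run_sweeps(init_state(cfg), 120000, record_conf_every = 400)
    effective_persistence_length(
      lapply(traj$conformations[101:300], `[[`, 1L))$l_p
  }
  expect_gt(lp_at(8, 24L), lp_at(2, 25L))
})
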