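test_that("the BFM bond set has the canonical 108 vectors", {
  bonds <- allowed_bond_set()
  expect_equal(nrow(bonds), 108L)
  # independent enumeration: all integer vectors with the right length and
  # component profile
  grid <- as.matrix(expand.grid(-3:3, -3:3, -3:3))
  profile <- apply(grid, 1L, function(v) paste(sort(abs(v)), collapse = ","))
  expected <- grid[profile %in% c("0,0,2", "0,1,2", "1,1,2", "1,2,2",
                                  "0,0,3", "0,1,3"), ]
  expect_equal(nrow(expected), 108L)
  key <- function(m) sort(apply(m, 1L, paste, collapse = ","))
  expect_equal(key(bonds), key(expected))
  expect_true(is_allowed_bond(c(2, 0, 0)))
  expect_false(is_allowed_bond(c(1, 0, 0)))  # length-1 bonds break excluded volume
  expect_false(is_allowed_bond(c(2, 2, 2)))
})

test_that("initialization satisfies all invariants in both tether modes", {
  cfg <- sim_config(n_chains = 1L, n_monomers = 2L, box_side = 10L,
                    tether_mode = "untethered", seed = 1L)
  st <- init_state(cfg)
  bond <- diff(st$positions[[1L]])
  expect_true(is_allowed_bond(bond))

  cfg2 <- tiny_config(tether_mode = "two_tethers", seed = 3L)
  st2 <- init_state(cfg2)
  expect_true(validate_state(st2, quiet = TRUE))
  L <- cfg2$box_side
  for (p in st2$positions) {
    for (m in c(1L, nrow(p)))
      expect_true(any(p[m, ] == 0L | p[m, ] == L - 2L))
  }
  # determinism of placement
  expect_identical(init_state(cfg2)$positions, st2$positions)
  # box that cannot hold the monomers is rejected up front
  expect_error(sim_config(n_chains = 10L, n_monomers = 60L, box_side = 10L),
               "box_side too small")
})

test_that("bending energy matches the discrete worm-like-chain form", {
  straight <- cbind(seq(0, 20, by = 2), 0, 0)
  expect_equal(bending_energy(straight, kappa = 5), 0)
  elbow <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0))  # 90 degree turn
  expect_equal(bending_energy(elbow, kappa = 2), 2)
  # term-by-term brute-force oracle on a random valid lattice chain
  cfg <- tiny_config(kappa = 1.7, seed = 21L)
  st <- run_sweeps(init_state(cfg), 200)$state
  for (p in st$positions) {
    u <- diff(p) / sqrt(rowSums(diff(p)^2))
    manual <- 0
    for (i in seq_len(nrow(u) - 1L))
      manual <- manual + (1 - sum(u[i, ] * u[i + 1L, ]))
    expect_equal(bending_energy(p, 1.7), 1.7 * manual, tolerance = 1e-12)
  }
  expect_equal(bending_energy(rbind(c(0, 0, 0), c(2, 0, 0)), 3), 0)
})

test_that("incremental energy tracks full recomputation over long runs", {
  cfg <- tiny_config(kappa = 3, seed = 5L)
  st <- init_state(cfg)
  for (chunk in 1:5) {
    traj <- run_sweeps(st, 1000)
    expect_equal(traj$energy_incremental, traj$energy_full,
                 tolerance = 1e-10)
    expect_equal(traj$energy_full,
                 bending_energy(traj$state$positions, cfg$kappa),
                 tolerance = 1e-10)
    st <- traj$state
  }
})

test_that("single-move proposals respect constraints and the athermal limit", {
  # a move pushing a monomer out of the box is constraint-rejected
  cfg <- sim_config(n_chains = 1L, n_monomers = 2L, box_side = 10L,
                    kappa = 0, tether_mode = "untethered", seed = 2L)
  st <- init_state(cfg)
  st$positions[[1L]] <- rbind(c(0L, 0L, 0L), c(2L, 0L, 0L))
  res <- propose_and_apply(st, move = list(chain = 1L, monomer = 1L,
                                           dir = 2L))  # -x leaves the box
  expect_equal(res$result, "constraint_rejected")
  expect_identical(res$state$positions, st$positions)
  # excluded volume: another chain's cube blocks the target sites while the
  # new bond itself stays valid
  cfg2 <- sim_config(n_chains = 2L, n_monomers = 2L, box_side = 10L,
                     kappa = 0, tether_mode = "untethered", seed = 2L)
  st2 <- init_state(cfg2)
  st2$positions[[1L]] <- rbind(c(0L, 0L, 0L), c(2L, 0L, 0L))
  st2$positions[[2L]] <- rbind(c(0L, 2L, 0L), c(2L, 2L, 0L))
  blocked <- propose_and_apply(st2, move = list(chain = 1L, monomer = 1L,
                                                dir = 3L))  # +y into chain 2
  expect_equal(blocked$result, "constraint_rejected")
  expect_identical(blocked$state$positions, st2$positions)
  # at kappa = 0 a constraint-satisfying move is always accepted
  ok <- propose_and_apply(st2, move = list(chain = 1L, monomer = 1L,
                                           dir = 6L))  # -z impossible; +z free
  expect_equal(ok$result, "constraint_rejected")
  ok2 <- propose_and_apply(st2, move = list(chain = 1L, monomer = 1L,
                                            dir = 5L))  # +z is free
  expect_equal(ok2$result, "accepted")

  # acceptance rate equals the constraint-satisfying fraction at kappa = 0
  traj <- run_sweeps(init_state(tiny_config(kappa = 0, seed = 9L)), 500)
  expect_equal(traj$n_accepted, traj$n_satisfying)
  expect_lt(traj$n_accepted, traj$n_proposed)
})

test_that("trajectories preserve invariants, tethering and seed determinism", {
  cfg <- tiny_config(kappa = 1, seed = 13L)
  traj <- run_sweeps(init_state(cfg), 10000, record_conf_every = 500)
  expect_length(traj$conformations, 20L)
  for (conf in traj$conformations[c(1L, 10L, 20L)]) {
    st <- traj$state
    st$positions <- conf
    expect_true(validate_state(st, quiet = TRUE))
  }
  # empty trajectory contract
  empty <- run_sweeps(init_state(cfg), 0)
  expect_equal(nrow(empty$r2ee), 0L)
  expect_length(empty$conformations, 0L)
  # bit-identical reproducibility from the config seed
  t1 <- run_sweeps(init_state(cfg), 300, record_conf_every = 100)
  t2 <- run_sweeps(init_state(cfg), 300, record_conf_every = 100)
  expect_identical(t1$r2ee, t2$r2ee)
  expect_identical(t1$conformations, t2$conformations)
})

test_that("tethered ends diffuse along the envelope", {
  cfg <- tiny_config(kappa = 0, seed = 17L)
  traj <- run_sweeps(init_state(cfg), 20000, record_conf_every = 200)
  ends <- t(vapply(traj$conformations, function(conf) conf[[1L]][1L, ],
                   numeric(3)))
  # the end monomer moves within the boundary layer
  msd <- mean(rowSums(sweep(ends, 2L, ends[1L, ])^2))
  expect_gt(msd, 0)
  L <- cfg$box_side
  on_boundary <- apply(ends, 1L, function(p) any(p == 0L | p == L - 2L))
  expect_true(all(on_boundary))
})

test_that("free-chain statistics show self-avoiding swelling and the stiff limit", {
  ree_at <- function(nm, kappa) {
    cfg <- sim_config(n_chains = 1L, n_monomers = nm, box_side = 200L,
                      kappa = kappa, tether_mode = "untethered", seed = 31L)
    traj <- run_sweeps(init_state(cfg), 60000)
    mean(traj$r2ee[30001:60000, ])
  }
  r16 <- ree_at(16L, 0)
  r32 <- ree_at(32L, 0)
  expect_gt(r32 / r16, 2)  # <R2ee> ~ N^(2*0.588) beats linear growth
  # near-rod behavior at large kappa
  cfg <- sim_config(n_chains = 1L, n_monomers = 16L, box_side = 200L,
                    kappa = 60, tether_mode = "untethered", seed = 32L)
  traj <- run_sweeps(init_state(cfg), 30000)
  p <- traj$state$positions[[1L]]
  contour2 <- sum(sqrt(rowSums(diff(p)^2)))^2
  expect_gt(mean(traj$r2ee[15001:30000, ]) / contour2, 0.85)
})

test_that("lattice states convert to physical traces and back", {
  cfg <- tiny_config(seed = 41L)
  st <- init_state(cfg)
  ds <- state_to_traces(st)
  expect_s3_class(ds, "nucleus_dataset")
  expect_length(ds$traces, cfg$n_chains)
  expect_equal(ds$traces[[1L]]$points,
               `dimnames<-`(st$positions[[1L]] * cfg$lattice_to_micron,
                            list(NULL, c("X", "Y", "Z"))))
  back <- round(ds$traces[[2L]]$points / cfg$lattice_to_micron)
  expect_equal(back, `dimnames<-`(st$positions[[2L]] * 1.0,
                                  list(NULL, c("X", "Y", "Z"))))
  # contour of a straight 10-bond chain of bond length 2 lattice units
  straight <- list(cbind(seq(0L, 20L, by = 2L), 0L, 0L))
  ds2 <- state_to_traces(straight, cfg)
  expect_equal(arclength(ds2$traces[[1L]]), 20 * cfg$lattice_to_micron,
               tolerance = 1e-12)
})
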