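# shared fixtures and independent oracles used across the suite

tiny_config <- function(kappa = 2, tether_mode = "two_tethers", seed = 7L,
                        n_chains = 3L, n_monomers = 12L, box_side = 32L) {
  sim_config(n_chains = n_chains, n_monomers = n_monomers,
             box_side = box_side, kappa = kappa,
             tether_mode = tether_mode, seed = seed)
}

# reduced-scale study geometry preserving the modeled system's ratios:
# contour/box ~ 1.2 (chains span the cavity) and comparable envelope
# grafting density and monomer volume fraction
study_config <- function(kappas = c(1, 4, 12), n_target = 400L,
                         seed = 11L, ...) {
  experiment_config(kappas = kappas,
                    tether_modes = c("two_tethers", "untethered"),
                    n_chains = 4L, n_monomers = 24L, box_side = 53L,
                    pilot_sweeps = 500000L, n_target = n_target,
                    resample_n = 24L, n_bins = 24L, seed = seed, ...)
}

# independent numeric quadrature of the (signed) Gauss integral over one
# segment pair, panel-subdivided so close approaches converge below the
# comparison tolerance; |value| / (2 pi) matches the ordered-pair ACN
gauss_pair_quadrature <- function(p1, p2, p3, p4, n_panels = 4L) {
  e1 <- p2 - p1
  e2 <- p4 - p3
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  f <- function(s, t) {
    dx <- p1[1] + s * e1[1] - p3[1] - t * e2[1]
    dy <- p1[2] + s * e1[2] - p3[2] - t * e2[2]
    dz <- p1[3] + s * e1[3] - p3[3] - t * e2[3]
    (cr[1] * dx + cr[2] * dy + cr[3] * dz) / (dx^2 + dy^2 + dz^2)^1.5
  }
  br <- seq(0, 1, length.out = n_panels + 1L)
  tot <- 0
  for (a in seq_len(n_panels))
    for (b in seq_len(n_panels))
      tot <- tot + pracma::integral2(f, br[a], br[a + 1L], br[b], br[b + 1L],
                                     reltol = 1e-10, abstol = 1e-13)$Q
  abs(tot) / (2 * pi)
}

# brute-force per-sample Gaussian summation (KDE oracle)
kde_brute <- function(samples, queries, h) {
  out <- numeric(nrow(queries))
  for (i in seq_len(nrow(queries))) {
    acc <- 0
    for (j in seq_len(nrow(samples))) {
      d2 <- sum((queries[i, ] - samples[j, ])^2)
      acc <- acc + exp(-d2 / (2 * h^2))
    }
    out[i] <- acc / nrow(samples) * (2 * pi * h^2)^(-3 / 2)
  }
  out
}

random_polyline <- function(n_points, scale = 1) {
  matrix(rnorm(3 * n_points, sd = scale), ncol = 3)
}
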