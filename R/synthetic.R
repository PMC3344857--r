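#' Configuration for synthetic nucleus datasets
#'
#' The generator emulates the statistical shape of reconstructed SC trace
#' data: about 19 polylines per nucleus, mean contour length 12 um,
#' endpoints on the nuclear envelope (sphere of diameter 10 um by
#' default), tunable effective persistence length and optional isotropic
#' localization noise.
#'
#' @param n_chains traces per nucleus.
#' @param contour_length_um mean contour length, um; individual contours
#'   are drawn uniformly within `+/- contour_jitter` of the mean.
#' @param n_points points per trace.
#' @param l_p_um target persistence length, um.
#' @param cavity list: `shape` (`"sphere"` or `"cube"`) plus
#'   `diameter_um` or `side_um`.
#' @param tether_mode `"two_tethers"` or `"untethered"`; `"free"` disables
#'   the cavity entirely (unconfined chains, for calibration tests).
#' @param noise_sigma_um localization noise sd per coordinate, um.
#' @param contour_jitter relative half-width of the contour distribution.
#' @param seed integer seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_chains = 19L, contour_length_um = 12,
                         n_points = 61L, l_p_um = 2,
                         cavity = list(shape = "sphere", diameter_um = 10),
                         tether_mode = c("two_tethers", "untethered",
                                         "free"),
                         noise_sigma_um = 0, contour_jitter = 0.2,
                         seed = 1L) {
  tether_mode <- match.arg(tether_mode)
  stopifnot(n_chains >= 1L, contour_length_um > 0, n_points >= 2L,
            l_p_um > 0, noise_sigma_um >= 0,
            contour_jitter >= 0, contour_jitter < 1)
  if (tether_mode != "free") {
    stopifnot(is.list(cavity), cavity$shape %in% c("sphere", "cube"))
    size <- if (cavity$shape == "sphere") cavity$diameter_um else
      cavity$side_um
    stopifnot(size > 0)
  }
  structure(list(n_chains = as.integer(n_chains),
                 contour_length_um = contour_length_um,
                 n_points = as.integer(n_points), l_p_um = l_p_um,
                 cavity = cavity, tether_mode = tether_mode,
                 noise_sigma_um = noise_sigma_um,
                 contour_jitter = contour_jitter, seed = as.integer(seed)),
            class = "synth_config")
}

# mean single-step tangent correlation of the update
# u' = normalize(u + g * eta), eta ~ N(0, I3).  With u = e3:
# u.u' = (1 + g z) / sqrt((1 + g z)^2 + g^2 s^2), z ~ N(0,1), s Rayleigh.
wlc_step_correlation <- function(g) {
  inner <- function(s) vapply(s, function(si)
    integrate(function(z) (1 + g * z) /
                sqrt((1 + g * z)^2 + g^2 * si^2) * stats::dnorm(z),
              -Inf, Inf, rel.tol = 1e-9)$value, 0)
  integrate(function(s) inner(s) * s * exp(-s^2 / 2), 0, Inf,
            rel.tol = 1e-8)$value
}

.wlc_g_cache <- new.env(parent = emptyenv())

# calibrate g so the single-step correlation equals rho = exp(-ds/l_p)
wlc_gain <- function(rho) {
  stopifnot(rho > 0, rho < 1)
  if (1 - rho < 1e-5) return(sqrt(1 - rho))  # small-g expansion: m ~ 1 - g^2
  key <- sprintf("%.12g", rho)
  if (!is.null(.wlc_g_cache[[key]])) return(.wlc_g_cache[[key]])
  g <- uniroot(function(g) wlc_step_correlation(g) - rho,
               lower = 1e-4, upper = 100, tol = 1e-8)$root
  .wlc_g_cache[[key]] <- g
  g
}

inside_cavity <- function(p, cavity) {
  if (cavity$shape == "sphere") {
    sum(p^2) <= (cavity$diameter_um / 2)^2
  } else {
    all(abs(p) <= cavity$side_um / 2)
  }
}

boundary_distance <- function(p, cavity) {
  if (cavity$shape == "sphere") {
    cavity$diameter_um / 2 - sqrt(sum(p^2))
  } else {
    cavity$side_um / 2 - max(abs(p))
  }
}

project_to_boundary <- function(p, cavity) {
  if (cavity$shape == "sphere") {
    r <- sqrt(sum(p^2))
    if (r == 0) c(cavity$diameter_um / 2, 0, 0) else
      p * (cavity$diameter_um / 2) / r
  } else {
    a <- which.max(abs(p))
    p[a] <- sign(p[a]) * cavity$side_um / 2
    pmin(pmax(p, -cavity$side_um / 2), cavity$side_um / 2)
  }
}

random_boundary_point <- function(cavity) {
  if (cavity$shape == "sphere") {
    u <- rnorm(3)
    u / sqrt(sum(u^2)) * cavity$diameter_um / 2
  } else {
    p <- runif(3, -cavity$side_um / 2, cavity$side_um / 2)
    a <- sample.int(3L, 1L)
    p[a] <- sample(c(-1, 1), 1L) * cavity$side_um / 2
    p
  }
}

random_unit <- function() {
  u <- rnorm(3)
  u / sqrt(sum(u^2))
}

#' Sample one worm-like-chain trace
#'
#' Sequential tangent sampling with single-step correlation
#' `<u_i . u_{i+1}> = exp(-ds / l_p)` (tangent update
#' `normalize(u + g * eta)`, `eta` standard 3D Gaussian, `g` calibrated
#' numerically).  Steps leaving the cavity are re-drawn with bounded
#' retries; in `two_tethers` mode the walk starts on the cavity boundary
#' with an inward tangent and is restarted until its last point lies
#' within one step of the boundary, onto which it is then projected.
#'
#' @param config a [synth_config()].
#' @param contour_um optional contour length overriding the config mean.
#' @param sc_id,nucleus_id labels for the returned trace.
#' @param max_restarts whole-walk restarts before the config is declared
#'   infeasible.
#' @return an [sc_trace()] in um.
#' @export
sample_wlc_trace <- function(config, contour_um = NULL, sc_id = "SC",
                             nucleus_id = "synthetic",
                             max_restarts = 5000L) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(contour_um)) contour_um <- config$contour_length_um
  n <- config$n_points
  ds <- contour_um / (n - 1L)
  g <- wlc_gain(exp(-ds / config$l_p_um))
  tethered <- config$tether_mode == "two_tethers"
  confined <- config$tether_mode != "free"
  cavity <- config$cavity

  for (restart in seq_len(max_restarts)) {
    if (tethered) {
      p0 <- random_boundary_point(cavity)
      # inward-pointing initial tangent
      repeat {
        u <- random_unit()
        if (inside_cavity(p0 + u * min(ds, 1e-3), cavity)) break
      }
    } else if (confined) {
      repeat {
        p0 <- if (cavity$shape == "sphere")
          runif(3, -1, 1) * cavity$diameter_um / 2 else
            runif(3, -1, 1) * cavity$side_um / 2
        if (inside_cavity(p0, cavity)) break
      }
      u <- random_unit()
    } else {
      p0 <- c(0, 0, 0)
      u <- random_unit()
    }

    pts <- matrix(NA_real_, n, 3L)
    pts[1L, ] <- p0
    ok <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      for (try in 1:50) {
        un <- u + g * rnorm(3)
        un <- un / sqrt(sum(un^2))
        cand <- pts[i - 1L, ] + un * ds
        if (!confined || inside_cavity(cand, cavity)) {
          pts[i, ] <- cand
          u <- un
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (!ok) next
    if (tethered) {
      if (boundary_distance(pts[n, ], cavity) > ds) next
      pts[n, ] <- project_to_boundary(pts[n, ], cavity)
    }
    return(sc_trace(pts, sc_id = sc_id, nucleus_id = nucleus_id))
  }
  stop("infeasible config: no admissible walk after ", max_restarts,
       " restarts (l_p too large for the cavity?)")
}

#' Generate a synthetic nucleus dataset
#'
#' Draws `n_chains` worm-like-chain traces with contour lengths uniform
#' within `+/- contour_jitter` of the configured mean, applies
#' localization noise if requested, and packages the result as a
#' [nucleus_dataset()] (source `"synthetic"`).  Traces do not enforce
#' mutual excluded volume: they are analysis fixtures emulating
#' reconstructed trace data, not equilibrium samples of the physical
#' model.
#'
#' @param config a [synth_config()].
#' @param nucleus_id label.
#' @return a [nucleus_dataset()].
#' @export
generate_nucleus <- function(config, nucleus_id = "synthetic") {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  contours <- config$contour_length_um *
    runif(config$n_chains, 1 - config$contour_jitter,
          1 + config$contour_jitter)
  traces <- lapply(seq_len(config$n_chains), function(i)
    sample_wlc_trace(config, contour_um = contours[i],
                     sc_id = sprintf("SC%02d", i), nucleus_id = nucleus_id))
  if (config$noise_sigma_um > 0)
    traces <- lapply(traces, add_noise, sigma = config$noise_sigma_um,
                     cavity = if (config$tether_mode == "two_tethers")
                       config$cavity else NULL)
  nucleus_dataset(traces, nucleus_id = nucleus_id, source = "synthetic",
                  geometry = if (config$tether_mode != "free")
                    config$cavity else NULL)
}

#' Add isotropic localization noise to a trace
#'
#' Displaces every point by iid `N(0, sigma^2)` per coordinate, modeling
#' localization error of reconstructed backbones.  When a cavity is
#' given, the endpoints are re-projected onto its boundary afterwards so
#' tethered data keep their tether exactly.
#'
#' @param trace an `sc_trace` or point matrix.
#' @param sigma noise sd per coordinate, same units as the trace.
#' @param cavity optional cavity list (see [synth_config()]) whose
#'   boundary the endpoints are re-projected onto.
#' @return same type as the input.
#' @export
add_noise <- function(trace, sigma, cavity = NULL) {
  stopifnot(sigma >= 0)
  p <- trace_points(trace)
  if (sigma > 0) {
    p <- p + matrix(rnorm(length(p), sd = sigma), ncol = 3L)
    if (!is.null(cavity)) {
      p[1L, ] <- project_to_boundary(p[1L, ], cavity)
      p[nrow(p), ] <- project_to_boundary(p[nrow(p), ], cavity)
    }
  }
  if (inherits(trace, "sc_trace")) {
    trace$points <- `dimnames<-`(p, list(NULL, c("X", "Y", "Z")))
    trace
  } else p
}
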