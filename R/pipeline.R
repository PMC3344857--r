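#' Configuration of a rigidity sweep experiment
#'
#' Describes the full computational experiment behind the tethered
#' vs. untethered comparison: the bending-rigidity grid for both tether
#' modes, the system size, sampling parameters, and the analysis
#' parameters shared with trace data.
#'
#' @param kappas bending-stiffness grid (kBT units); the defaults target
#'   effective persistence lengths of roughly 1-32 Kuhn lengths.
#' @param tether_modes subset of `c("two_tethers", "untethered")`.
#' @param n_chains,n_monomers,box_side,lattice_to_micron system geometry
#'   (see [sim_config()]).
#' @param pilot_sweeps sweeps used to measure the autocorrelation time.
#' @param n_target decorrelated conformations per parameter point.
#' @param window_factor Sokal window factor.
#' @param spacing_factor,burn_in_factor decorrelation spacing and burn-in
#'   as multiples of `tau_int`.
#' @param resample_n common per-trace site count for ACN and profiles.
#' @param n_bins normalized-position bins of the density profile.
#' @param bandwidth KDE bandwidth; `NULL` = Scott's rule per ensemble.
#' @param seed master seed; each parameter point derives its own stream.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(kappas = c(1, 2, 4, 8, 16, 32),
                              tether_modes = c("two_tethers", "untethered"),
                              n_chains = 19L, n_monomers = 60L,
                              box_side = 135L,
                              lattice_to_micron = 0.2 / 2.7,
                              pilot_sweeps = 100000L, n_target = 200L,
                              window_factor = 6, spacing_factor = 2,
                              burn_in_factor = 10,
                              resample_n = 60L, n_bins = 30L,
                              bandwidth = NULL, seed = 1L) {
  stopifnot(length(kappas) >= 1L, all(kappas >= 0), n_target >= 10L,
            all(tether_modes %in% c("two_tethers", "untethered")))
  structure(list(kappas = sort(unique(kappas)), tether_modes = tether_modes,
                 n_chains = as.integer(n_chains),
                 n_monomers = as.integer(n_monomers),
                 box_side = as.integer(box_side),
                 lattice_to_micron = lattice_to_micron,
                 pilot_sweeps = as.integer(pilot_sweeps),
                 n_target = as.integer(n_target),
                 window_factor = window_factor,
                 spacing_factor = spacing_factor,
                 burn_in_factor = burn_in_factor,
                 resample_n = as.integer(resample_n),
                 n_bins = as.integer(n_bins), bandwidth = bandwidth,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# equilibrate + decorrelate one parameter point; returns stats, profile and
# the decorrelated conformations (lattice units)
run_point <- function(cfg, xc) {
  state <- init_state(cfg)
  pilot <- run_sweeps(state, xc$pilot_sweeps)
  series <- rowMeans(pilot$r2ee)
  tail_half <- series[(length(series) %/% 2 + 1L):length(series)]
  diag <- tryCatch(acf_diagnostics(tail_half, c = xc$window_factor),
                   error = function(e) NULL)
  flagged <- is.null(diag)
  tau <- if (flagged) xc$pilot_sweeps / 20 else diag$tau_int

  extra_burn <- max(0L, ceiling(xc$burn_in_factor * tau) - xc$pilot_sweeps)
  state <- pilot$state
  if (extra_burn > 0L) state <- run_sweeps(state, extra_burn)$state
  spacing <- max(1L, ceiling(xc$spacing_factor * tau))
  prod <- run_sweeps(state, xc$n_target * spacing,
                     record_conf_every = spacing,
                     record_r2ee_every = spacing)
  confs <- prod$conformations
  stats <- ensemble_stats(confs, resample_n = xc$resample_n)
  profile <- backbone_profile(confs, h = xc$bandwidth,
                              resample_n = xc$resample_n,
                              n_bins = xc$n_bins)
  list(stats = stats, profile = profile, conformations = confs,
       tau_int = tau, flagged = flagged, spacing = spacing,
       acceptance = prod$n_accepted / prod$n_proposed)
}

#' Run a rigidity sweep for both tether modes
#'
#' For every (kappa, tether mode) pair: initializes the BFM system,
#' measures the integrated autocorrelation time of the squared end-to-end
#' distance on a pilot run, burns in, records decorrelated conformations,
#' and computes the ensemble observables and backbone-density profile.
#' Points whose series admits no self-consistent Sokal window are flagged
#' rather than silently included.  The whole sweep is a deterministic
#' function of (config, seed).
#'
#' @param config an [experiment_config()].
#' @param keep_conformations retain decorrelated conformations in the
#'   result (needed by [compare_to_traces()]).
#' @param verbose print one line per parameter point.
#' @return object of class `sc_sweep`: `summary` (one data.frame row per
#'   point, lattice and um units with standard errors), `profiles`,
#'   `conformations` and the `config`.
#' @export
run_sweep <- function(config, keep_conformations = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list(); profiles <- list(); confs <- list()
  i <- 0L
  for (mode in config$tether_modes) {
    for (kappa in config$kappas) {
      i <- i + 1L
      cfg <- sim_config(n_chains = config$n_chains,
                        n_monomers = config$n_monomers,
                        box_side = config$box_side, kappa = kappa,
                        tether_mode = mode,
                        seed = config$seed + 7919L * i,
                        lattice_to_micron = config$lattice_to_micron)
      t0 <- proc.time()[["elapsed"]]
      pt <- run_point(cfg, config)
      dt <- proc.time()[["elapsed"]] - t0
      key <- sprintf("%s_kappa%g", mode, kappa)
      st <- pt$stats
      u2 <- config$lattice_to_micron^2
      rows[[key]] <- data.frame(
        tether_mode = mode, kappa = kappa, tau_int = pt$tau_int,
        flagged = pt$flagged, n_conformations = st$n_conformations,
        acceptance = pt$acceptance,
        mean_sq_ree = st$mean_sq_ree, se_sq_ree = st$se_sq_ree,
        mean_sq_dcm = st$mean_sq_dcm, se_sq_dcm = st$se_sq_dcm,
        macn_intra = st$macn_intra, se_macn_intra = st$se_macn_intra,
        macn_inter = st$macn_inter, se_macn_inter = st$se_macn_inter,
        mean_sq_ree_um2 = st$mean_sq_ree * u2,
        se_sq_ree_um2 = st$se_sq_ree * u2,
        mean_sq_dcm_um2 = st$mean_sq_dcm * u2,
        se_sq_dcm_um2 = st$se_sq_dcm * u2,
        wall_seconds = dt)
      profiles[[key]] <- pt$profile
      if (keep_conformations) confs[[key]] <- pt$conformations
      if (verbose)
        message(sprintf("%-28s tau=%.2f acc=%.2f <R2ee>=%.1f (%.1fs)%s",
                        key, pt$tau_int, pt$acceptance, st$mean_sq_ree, dt,
                        if (pt$flagged) " [FLAGGED]" else ""))
    }
  }
  structure(list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
                 profiles = profiles, conformations = confs,
                 config = config),
            class = "sc_sweep")
}

#' @export
print.sc_sweep <- function(x, ...) {
  cat(sprintf("<sc_sweep: %d parameter points>\n", nrow(x$summary)))
  print(x$summary[, c("tether_mode", "kappa", "tau_int", "mean_sq_ree",
                      "mean_sq_dcm", "macn_intra", "macn_inter",
                      "flagged")])
  invisible(x)
}

# z-like effect size for a one-sided comparison a > b
sep_effect <- function(a, b, se_a, se_b) (a - b) / sqrt(se_a^2 + se_b^2)

trend_slope <- function(kappa, y) {
  if (length(unique(kappa)) < 2L) return(NA_real_)
  coef(lm(y ~ kappa))[[2L]]
}

#' Qualitative tethering/rigidity checks on a sweep
#'
#' Evaluates the four signature comparisons between the tethered and the
#' untethered system, each as pass/fail with an effect size in units of
#' the separated standard error:
#' (a) larger mean squared end-to-end distance under tethering at every
#' kappa; (b) stronger center-of-mass segregation under tethering at the
#' lowest kappa; (c) fewer intra- and inter-chain overcrossings under
#' tethering; (d) opposite monotonic trends of intra- vs inter-chain mACN
#' in kappa (entanglement frustration), reported per mode via the signs
#' of the fitted linear trends.
#'
#' @param sweep an `sc_sweep` containing both tether modes.
#' @return list of per-check results (`pass`, effect sizes/details).
#' @export
check_qualitative <- function(sweep) {
  s <- sweep$summary
  stopifnot(all(c("two_tethers", "untethered") %in% s$tether_mode))
  te <- s[s$tether_mode == "two_tethers", ]
  un <- s[s$tether_mode == "untethered", ]
  te <- te[order(te$kappa), ]; un <- un[order(un$kappa), ]
  stopifnot(identical(te$kappa, un$kappa))

  eff_a <- sep_effect(te$mean_sq_ree, un$mean_sq_ree,
                      te$se_sq_ree, un$se_sq_ree)
  low <- 1L  # lowest kappa
  eff_b <- sep_effect(te$mean_sq_dcm[low], un$mean_sq_dcm[low],
                      te$se_sq_dcm[low], un$se_sq_dcm[low])
  eff_c_intra <- sep_effect(un$macn_intra, te$macn_intra,
                            un$se_macn_intra, te$se_macn_intra)
  eff_c_inter <- sep_effect(un$macn_inter, te$macn_inter,
                            un$se_macn_inter, te$se_macn_inter)
  # curve-wise dominance: pooled over the kappa grid the tethered curve
  # lies below, and at no grid point does it lie significantly above
  pooled <- function(a, b, se_a, se_b)
    (mean(b) - mean(a)) / (sqrt(sum(se_a^2 + se_b^2)) / length(a))
  pool_intra <- pooled(te$macn_intra, un$macn_intra,
                       te$se_macn_intra, un$se_macn_intra)
  pool_inter <- pooled(te$macn_inter, un$macn_inter,
                       te$se_macn_inter, un$se_macn_inter)
  slopes <- lapply(list(te = te, un = un), function(d)
    c(intra = trend_slope(d$kappa, d$macn_intra),
      inter = trend_slope(d$kappa, d$macn_inter)))

  list(
    ree_tethered_larger = list(
      pass = all(eff_a > 2), effect = eff_a, kappa = te$kappa),
    dcm_tethered_larger_low_kappa = list(
      pass = eff_b > 2, effect = eff_b, kappa = te$kappa[low]),
    macn_tethered_lower = list(
      pass = pool_intra > 2 && pool_inter > 2 &&
        all(eff_c_intra > -2) && all(eff_c_inter > -2),
      pooled_intra = pool_intra, pooled_inter = pool_inter,
      effect_intra = eff_c_intra, effect_inter = eff_c_inter,
      kappa = te$kappa),
    macn_frustration = list(
      pass = all(vapply(slopes, function(sl)
        is.finite(sl["intra"]) && is.finite(sl["inter"]) &&
          sl["intra"] * sl["inter"] < 0, TRUE)),
      slopes = slopes))
}

bracket_kappa <- function(kappa, value, target) {
  # kappa range over which the simulated curve brackets the target value
  hit <- numeric(0)
  for (i in seq_len(length(kappa) - 1L)) {
    lo <- min(value[i], value[i + 1L]); hi <- max(value[i], value[i + 1L])
    if (target >= lo && target <= hi)
      hit <- c(hit, kappa[i], kappa[i + 1L])
  }
  if (length(hit) == 0L) return(c(NA_real_, NA_real_))
  range(hit)
}

#' Compare a rigidity sweep against trace data
#'
#' Computes the shared observables on (experimental or synthetic) nucleus
#' datasets with the same analysis parameters as the sweep, locates the
#' bending-rigidity range whose simulated mean squared end-to-end and
#' center-of-mass distances bracket the trace values, and reports the
#' ratio of the backbone-density peaks (trace / simulation) at matched
#' bandwidth, as a function of the bandwidth.
#'
#' @param sweep an `sc_sweep` run with `keep_conformations = TRUE`.
#' @param datasets a [nucleus_dataset()] or list of them, coordinates in
#'   um.
#' @param mode simulated curve to compare against (default two_tethers).
#' @param kappa_ref rigidity whose conformations back the density
#'   comparison; default the grid point nearest the midpoint of the
#'   end-to-end bracketing range (falling back to the median kappa).
#' @param h_factors bandwidth grid as multiples of Scott's-rule bandwidth
#'   of the pooled trace points.
#' @return object of class `sc_comparison`.
#' @export
compare_to_traces <- function(sweep, datasets, mode = "two_tethers",
                              kappa_ref = NULL, h_factors = c(0.5, 1, 2)) {
  stopifnot(inherits(sweep, "sc_sweep"))
  if (inherits(datasets, "nucleus_dataset")) datasets <- list(datasets)
  xc <- sweep$config
  trace_stats <- ensemble_stats(datasets, resample_n = xc$resample_n)
  s <- sweep$summary
  s <- s[s$tether_mode == mode, ]
  s <- s[order(s$kappa), ]

  br_ree <- bracket_kappa(s$kappa, s$mean_sq_ree_um2,
                          trace_stats$mean_sq_ree)
  br_dcm <- bracket_kappa(s$kappa, s$mean_sq_dcm_um2,
                          trace_stats$mean_sq_dcm)

  if (is.null(kappa_ref)) {
    kappa_ref <- if (all(is.finite(br_ree)))
      s$kappa[which.min(abs(s$kappa - mean(br_ree)))] else
        s$kappa[(length(s$kappa) + 1L) %/% 2L]
  }
  key <- sprintf("%s_kappa%g", mode, kappa_ref)
  confs <- sweep$conformations[[key]]
  if (is.null(confs))
    stop("sweep has no stored conformations for ", key,
         "; rerun with keep_conformations = TRUE")
  sim_um <- lapply(confs, function(conf)
    lapply(conf, function(p) p * xc$lattice_to_micron))

  trace_pts <- do.call(rbind, unlist(lapply(datasets, function(d)
    lapply(d$traces, function(tr)
      resample_uniform(trace_points(tr), xc$resample_n))),
    recursive = FALSE))
  h0 <- scott_bandwidth(trace_pts)

  density_vs_h <- lapply(h_factors, function(f) {
    h <- f * h0
    ptr <- backbone_profile(datasets, h = h, resample_n = xc$resample_n,
                            n_bins = xc$n_bins)
    psim <- backbone_profile(sim_um, h = h, resample_n = xc$resample_n,
                             n_bins = xc$n_bins)
    list(h = h, peak_trace = max(ptr$mean_density),
         peak_sim = max(psim$mean_density),
         peak_ratio = peak_ratio(ptr, psim),
         trace_profile = ptr, sim_profile = psim)
  })

  structure(list(trace_stats = trace_stats,
                 bracket_ree_kappa = br_ree, bracket_dcm_kappa = br_dcm,
                 kappa_ref = kappa_ref, mode = mode,
                 h_scott = h0,
                 density_vs_h = density_vs_h,
                 n_nuclei = length(datasets)),
            class = "sc_comparison")
}

#' @export
print.sc_comparison <- function(x, ...) {
  cat(sprintf("<sc_comparison over %d nuclei>\n", x$n_nuclei))
  cat(sprintf("  trace <R2ee> = %.3g um2, <d2CM> = %.3g um2\n",
              x$trace_stats$mean_sq_ree, x$trace_stats$mean_sq_dcm))
  cat(sprintf("  mACN intra/inter = %.3g / %.3g\n",
              x$trace_stats$macn_intra, x$trace_stats$macn_inter))
  cat(sprintf("  bracketing kappa: R2ee [%g, %g], d2CM [%g, %g]\n",
              x$bracket_ree_kappa[1L], x$bracket_ree_kappa[2L],
              x$bracket_dcm_kappa[1L], x$bracket_dcm_kappa[2L]))
  for (d in x$density_vs_h)
    cat(sprintf("  h = %.3g um: peak ratio trace/sim = %.3g\n",
                d$h, d$peak_ratio))
  invisible(x)
}

#' Write sweep results as CSV + JSON
#'
#' Emits the per-point summary as CSV (the machine-readable analog of a
#' results table), each density profile as CSV (bin center, mean density,
#' stderr), and a combined JSON report including flags.
#'
#' @param sweep an `sc_sweep`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sweep <- function(sweep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "sweep_summary.csv")
  utils::write.csv(sweep$summary, p, row.names = FALSE)
  paths <- c(paths, p)
  for (key in names(sweep$profiles)) {
    pr <- sweep$profiles[[key]]
    pp <- file.path(dir, paste0("profile_", key, ".csv"))
    utils::write.csv(data.frame(bin_center = pr$bin_centers,
                                mean_density = pr$mean_density,
                                stderr = pr$stderr), pp, row.names = FALSE)
    paths <- c(paths, pp)
  }
  jp <- file.path(dir, "sweep_report.json")
  report <- list(
    config = unclass(sweep$config),
    summary = sweep$summary,
    warnings = sweep$summary$flagged,
    profiles = lapply(sweep$profiles, function(pr)
      list(h = pr$h, n_sites = pr$n_sites,
           self_excluded = pr$self_excluded,
           bin_centers = pr$bin_centers,
           mean_density = pr$mean_density)))
  jsonlite::write_json(report, jp, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(paths, jp))
}
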