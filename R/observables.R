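#' Squared end-to-end distance of a trace
#'
#' @param trace an `sc_trace` or point matrix (>= 2 points).
#' @return squared Euclidean distance between first and last point, in the
#'   trace's length units squared.
#' @export
squared_end_to_end <- function(trace) {
  p <- trace_points(trace)
  stopifnot(nrow(p) >= 2L)
  sum((p[nrow(p), ] - p[1L, ])^2)
}

#' Mean squared center-of-mass distance of a conformation
#'
#' Segregation measure: the mean over all unordered chain pairs (i, j) of
#' the squared distance between their centers of mass, the center of mass
#' being the unweighted mean of a trace's points.  Larger values mean more
#' strongly segregated chains.
#'
#' @param conformation list of `sc_trace` objects or point matrices
#'   (>= 2), or a [nucleus_dataset()].
#' @return mean squared COM distance, length units squared.
#' @export
mean_sq_com_distance <- function(conformation) {
  if (inherits(conformation, "nucleus_dataset"))
    conformation <- conformation$traces
  stopifnot(length(conformation) >= 2L)
  coms <- t(vapply(conformation, function(tr) colMeans(trace_points(tr)),
                   numeric(3)))
  d2 <- as.matrix(stats::dist(coms))^2
  mean(d2[upper.tri(d2)])
}

#' Average crossing number of one polyline or a polyline pair
#'
#' The number of apparent crossings of the projection onto a plane,
#' averaged over all projection directions; computed as the absolute-value
#' Gauss double integral over segment pairs using the analytic closed form
#' for straight segments.  In intrachain mode (one curve) self-pairs and
#' adjacent (vertex-sharing) segment pairs are skipped: their analytic
#' contribution is zero but the closed form is numerically unstable there.
#'
#' @param a first polyline (`sc_trace` or point matrix with >= 2 points).
#' @param b second polyline; omit (or pass `NULL`) for the intrachain ACN
#'   of `a`.
#' @return dimensionless ACN (>= 0).
#' @export
acn_pair <- function(a, b = NULL) {
  pa <- trace_points(a)
  stopifnot(nrow(pa) >= 2L, all(is.finite(pa)))
  if (is.null(b)) return(acn_segments_cpp(pa, pa, TRUE))
  pb <- trace_points(b)
  stopifnot(nrow(pb) >= 2L, all(is.finite(pb)))
  acn_segments_cpp(pa, pb, FALSE)
}

#' Mean average crossing numbers of an ensemble
#'
#' `macn_intra` is the mean over conformations and chains of the
#' single-chain ACN (self-entanglement); `macn_inter` the mean over
#' conformations and unordered chain pairs of the pairwise ACN
#' (entanglement between chains).  Standard errors are taken over
#' conformations.
#'
#' @param ensemble list of conformations, each a list of `sc_trace`
#'   objects or point matrices (or a single [nucleus_dataset()], treated
#'   as one conformation).
#' @return list with `macn_intra`, `macn_inter`, `se_intra`, `se_inter`,
#'   `n_conformations`.
#' @export
mean_acn <- function(ensemble) {
  if (inherits(ensemble, "nucleus_dataset")) ensemble <- list(ensemble)
  stopifnot(length(ensemble) >= 1L)
  per_conf <- vapply(ensemble, function(conf) {
    if (inherits(conf, "nucleus_dataset")) conf <- conf$traces
    mats <- lapply(conf, trace_points)
    nc <- length(mats)
    intra <- mean(vapply(mats, function(m) acn_segments_cpp(m, m, TRUE), 0))
    inter <- if (nc >= 2L) {
      pairs <- utils::combn(nc, 2L)
      mean(vapply(seq_len(ncol(pairs)), function(k)
        acn_segments_cpp(mats[[pairs[1L, k]]], mats[[pairs[2L, k]]], FALSE),
        0))
    } else NA_real_
    c(intra, inter)
  }, numeric(2))
  nconf <- length(ensemble)
  se <- function(v) if (nconf > 1L) sd(v) / sqrt(nconf) else NA_real_
  list(macn_intra = mean(per_conf[1L, ]),
       macn_inter = mean(per_conf[2L, ]),
       se_intra = se(per_conf[1L, ]),
       se_inter = se(per_conf[2L, ]),
       n_conformations = nconf)
}

#' Monte-Carlo projection-counting estimate of the ACN
#'
#' Independent estimator of [acn_pair()] used for cross-checks: draws
#' uniformly random projection directions, projects both curves onto the
#' orthogonal plane and counts transversal crossings of the projected
#' segments, excluding self and adjacent pairs in intrachain mode.
#'
#' @param a,b polylines as in [acn_pair()] (`b = NULL` for intrachain).
#' @param n_dirs number of random projection directions.
#' @return mean crossing count over directions.
#' @export
acn_projection <- function(a, b = NULL, n_dirs = 10000L) {
  pa <- trace_points(a)
  intra <- is.null(b)
  pb <- if (intra) pa else trace_points(b)
  na <- nrow(pa) - 1L
  nb <- nrow(pb) - 1L

  # uniform directions on the sphere + per-direction orthonormal basis
  z <- matrix(rnorm(3L * n_dirs), ncol = 3L)
  z <- z / sqrt(rowSums(z^2))
  ref <- matrix(rep(c(1, 0, 0), each = n_dirs), ncol = 3L)
  flip <- abs(z[, 1L]) > 0.9
  ref[flip, ] <- matrix(rep(c(0, 1, 0), each = sum(flip)), ncol = 3L)
  e1 <- ref - z * rowSums(ref * z)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(z[, 2L] * e1[, 3L] - z[, 3L] * e1[, 2L],
              z[, 3L] * e1[, 1L] - z[, 1L] * e1[, 3L],
              z[, 1L] * e1[, 2L] - z[, 2L] * e1[, 1L])

  proj <- function(p) list(u = tcrossprod(e1, p), v = tcrossprod(e2, p))
  A <- proj(pa); B <- proj(pb)
  orient <- function(ux, uy, vx, vy, wx, wy)
    (vx - ux) * (wy - uy) - (vy - uy) * (wx - ux)

  counts <- numeric(n_dirs)
  for (i in seq_len(na)) {
    jset <- if (intra) seq_len(nb)[seq_len(nb) > i + 1L] else seq_len(nb)
    for (j in jset) {
      o1 <- orient(A$u[, i], A$v[, i], A$u[, i + 1L], A$v[, i + 1L],
                   B$u[, j], B$v[, j])
      o2 <- orient(A$u[, i], A$v[, i], A$u[, i + 1L], A$v[, i + 1L],
                   B$u[, j + 1L], B$v[, j + 1L])
      o3 <- orient(B$u[, j], B$v[, j], B$u[, j + 1L], B$v[, j + 1L],
                   A$u[, i], A$v[, i])
      o4 <- orient(B$u[, j], B$v[, j], B$u[, j + 1L], B$v[, j + 1L],
                   A$u[, i + 1L], A$v[, i + 1L])
      counts <- counts + as.numeric(o1 * o2 < 0 & o3 * o4 < 0)
    }
  }
  mean(counts)
}

#' Probability density function of the end-to-end distance
#'
#' Density-normalized histogram of (unsquared) end-to-end distances of an
#' ensemble.
#'
#' @param x numeric vector of end-to-end distances, or a list of
#'   conformations / traces from which they are computed.
#' @param breaks passed to [graphics::hist()]; default 30 bins.
#' @return list with `mids`, `breaks`, `density`, `counts`; the density
#'   integrates to 1 over the bins.
#' @export
ree_distribution <- function(x, breaks = 30) {
  if (is.list(x))
    x <- vapply(x, function(tr) sqrt(squared_end_to_end(tr)), 0)
  stopifnot(length(x) >= 10L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(mids = h$mids, breaks = h$breaks, density = h$density,
       counts = h$counts)
}

#' Ensemble observables shared by simulation and trace data
#'
#' Computes the per-rigidity summary: mean squared end-to-end distance,
#' its PDF, mean squared center-of-mass distance and intra-/inter-chain
#' mean average crossing numbers, each with a standard error over
#' conformations.
#'
#' @param ensemble list of conformations (each a list of traces/matrices,
#'   or a `nucleus_dataset`).
#' @param resample_n resample every trace to this many points before the
#'   ACN computation so ensembles at different discretizations are
#'   comparable; `NULL` disables.
#' @param ree_breaks histogram specification for the end-to-end PDF.
#' @return object of class `ensemble_stats`.
#' @export
ensemble_stats <- function(ensemble, resample_n = NULL, ree_breaks = 30) {
  if (inherits(ensemble, "nucleus_dataset")) ensemble <- list(ensemble)
  confs <- lapply(ensemble, function(conf) {
    if (inherits(conf, "nucleus_dataset")) conf <- conf$traces
    lapply(conf, trace_points)
  })
  nconf <- length(confs)
  se <- function(v) if (nconf > 1L) sd(v) / sqrt(nconf) else NA_real_

  ree_all <- unlist(lapply(confs, function(cf)
    vapply(cf, squared_end_to_end, 0)))
  ree_per_conf <- vapply(confs, function(cf)
    mean(vapply(cf, squared_end_to_end, 0)), 0)
  dcm_per_conf <- vapply(confs, function(cf)
    if (length(cf) >= 2L) mean_sq_com_distance(cf) else NA_real_, 0)

  acn_confs <- confs
  if (!is.null(resample_n))
    acn_confs <- lapply(confs, function(cf)
      lapply(cf, resample_uniform, n_points = resample_n))
  acn <- mean_acn(acn_confs)

  structure(list(
    mean_sq_ree = mean(ree_per_conf), se_sq_ree = se(ree_per_conf),
    ree_pdf = if (length(ree_all) >= 10L)
      ree_distribution(sqrt(ree_all), ree_breaks) else NULL,
    mean_sq_dcm = mean(dcm_per_conf), se_sq_dcm = se(dcm_per_conf),
    macn_intra = acn$macn_intra, se_macn_intra = acn$se_intra,
    macn_inter = acn$macn_inter, se_macn_inter = acn$se_inter,
    n_conformations = nconf), class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf(paste0("<ensemble_stats over %d conformations>\n",
                     "  <R2ee>   = %.4g +/- %.2g\n",
                     "  <d2CM>   = %.4g +/- %.2g\n",
                     "  mACN in  = %.4g +/- %.2g\n",
                     "  mACN out = %.4g +/- %.2g\n"),
              x$n_conformations, x$mean_sq_ree, x$se_sq_ree,
              x$mean_sq_dcm, x$se_sq_dcm,
              x$macn_intra, x$se_macn_intra,
              x$macn_inter, x$se_macn_inter))
  invisible(x)
}
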