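#' Simulation configuration for the BFM synaptonemal-complex model
#'
#' Defaults reflect the modeled system: 19 autosomal mouse SCs of mean
#' contour length 12 um, coarse-grained at a Kuhn length of 0.2 um (60 Kuhn
#' segments per chain), confined to a cubic cavity of side 50 Kuhn lengths
#' (nucleus diameter 10 um).  On the lattice one Kuhn length maps to the
#' mean BFM bond length (about 2.7 lattice units), giving the default box
#' side of 135 lattice units.
#'
#' @param n_chains number of polymer chains (SCs).
#' @param n_monomers Kuhn segments per chain.
#' @param box_side cubic cavity side, lattice units.
#' @param kappa bending stiffness in units of thermal energy kBT.
#' @param tether_mode `"two_tethers"` (both chain ends attached to, and
#'   diffusing along, the cavity envelope) or `"untethered"` (free chains).
#' @param seed integer seed governing all randomness of a run.
#' @param lattice_to_micron physical length of one lattice unit, um.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_chains = 19L, n_monomers = 60L, box_side = 135L,
                       kappa = 2, tether_mode = c("two_tethers", "untethered"),
                       seed = 1L, lattice_to_micron = 0.2 / 2.7) {
  tether_mode <- match.arg(tether_mode)
  n_chains <- as.integer(n_chains)
  n_monomers <- as.integer(n_monomers)
  box_side <- as.integer(box_side)
  stopifnot(n_chains >= 1L, n_monomers >= 2L, kappa >= 0,
            is.finite(seed), lattice_to_micron > 0)
  if (8 * n_chains * n_monomers >= box_side^3)
    stop("box_side too small: 8 * n_chains * n_monomers lattice sites must be < box_side^3")
  structure(list(n_chains = n_chains, n_monomers = n_monomers,
                 box_side = box_side, kappa = kappa,
                 tether_mode = tether_mode, seed = as.integer(seed),
                 lattice_to_micron = lattice_to_micron),
            class = "sim_config")
}

#' The canonical 3D bond-fluctuation-model bond set
#'
#' All permutations and sign combinations of (2,0,0), (2,1,0), (2,1,1),
#' (2,2,1), (3,0,0), (3,1,0): 108 vectors.  Together with the 2x2x2-cube
#' excluded volume this set guarantees that chains cannot cross.
#'
#' @return integer matrix with 108 rows (one bond vector per row).
#' @export
allowed_bond_set <- function() {
  base <- rbind(c(2,0,0), c(2,1,0), c(2,1,1), c(2,2,1), c(3,0,0), c(3,1,0))
  perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  signs <- as.matrix(expand.grid(c(-1L,1L), c(-1L,1L), c(-1L,1L)))
  out <- do.call(rbind, lapply(seq_len(nrow(base)), function(b)
    do.call(rbind, lapply(seq_len(nrow(perms)), function(p) {
      v <- base[b, perms[p, ]]
      sweep(signs, 2L, v, `*`)
    }))))
  unique(out)
}

#' Test membership of bond vectors in the BFM bond set
#'
#' @param d integer matrix of bond vectors (rows) or a single 3-vector.
#' @return logical vector.
#' @export
is_allowed_bond <- function(d) {
  if (is.null(dim(d))) d <- matrix(as.integer(d), nrow = 1L)
  bfm_bond_ok_cpp(matrix(as.integer(d), ncol = 3L))
}

# hairpin conformation in a canonical frame: columns of vertical (2,0,0)-type
# bonds joined by 1-2 bridge bonds, both ends at height 0.  Returns an
# integer matrix of cube corners with columns (u, v, w); w = 0 is the anchor
# plane.
hairpin_shape <- function(n_monomers) {
  nb <- n_monomers - 1L
  bridges <- if (nb %% 2L == 1L) 1L else 2L
  leg <- (nb - bridges) %/% 2L
  up <- cbind(0L, 0L, 2L * (0:leg))
  top <- if (bridges >= 1L)
    cbind(2L * seq_len(bridges), 0L, 2L * leg) else NULL
  down <- if (leg > 0L)
    cbind(2L * bridges, 0L, 2L * (leg - seq_len(leg))) else NULL
  rbind(up, top, down)[seq_len(n_monomers), , drop = FALSE]
}

# straight spanning conformation along the w axis: nb bonds of length 2 or
# 3 whose lengths sum to span; returns w offsets (0 .. span) per monomer,
# or NULL when the span is not representable
straight_shape <- function(n_monomers, span) {
  nb <- n_monomers - 1L
  k <- span - 2L * nb          # number of length-3 bonds needed
  if (k < 0L || k > nb) return(NULL)
  lens <- rep(2L, nb)
  if (k > 0L) lens[sample.int(nb, k)] <- 3L
  cbind(0L, 0L, c(0L, cumsum(lens)))
}

# map canonical (u, v, w) coordinates onto a cavity face.  face in 1..6:
# (w -> +x from x=0, -x from x=L-2, +y, -y, +z, -z).  offset is the in-plane
# translation (u0, v0) plus the wall offset w0 (0 for tethered anchors).
place_on_face <- function(shape, face, u0, v0, w0, L) {
  u <- shape[, 1L] + u0; v <- shape[, 2L] + v0; w <- shape[, 3L] + w0
  wr <- (L - 2L) - w  # reflected normal coordinate
  switch(face,
         cbind(w,  u,  v),  # from x = 0 inward
         cbind(wr, u,  v),  # from x = L-2 inward
         cbind(u,  w,  v),
         cbind(u,  wr, v),
         cbind(u,  v,  w),
         cbind(u,  v,  wr))
}

cube_site_keys <- function(pos, L) {
  off <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  keys <- vapply(seq_len(nrow(off)), function(i) {
    p <- sweep(pos, 2L, off[i, ], `+`)
    p[, 1L] + as.numeric(L) * (p[, 2L] + as.numeric(L) * p[, 3L])
  }, numeric(nrow(pos)))
  as.numeric(keys)
}

#' Initialize a BFM system state
#'
#' Chains are seeded as straight spanning conformations along a uniformly
#' random axis — in `two_tethers` mode stretching wall-to-wall so both ends
#' touch opposite faces, satisfying the tether constraint exactly — or, when
#' the box geometry cannot host a spanning chain, as hairpin conformations
#' anchored on a random face.  Untethered chains are placed at uniformly
#' random interior positions.  Overlapping placements are rejected with
#' bounded retries; placement is reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param max_tries placement retries per chain before the configuration is
#'   declared infeasible.
#' @return an object of class `bfm_state` with fields `positions` (list of
#'   integer matrices of 0-based lattice cube corners), `config`, `energy`
#'   (thermal-energy units) and `sweep`.
#' @export
init_state <- function(config, max_tries = 500L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$box_side
  nm <- config$n_monomers
  tethered <- config$tether_mode == "two_tethers"
  nb <- nm - 1L
  # straight chains span wall-to-wall (tethered) or lie in the interior
  span_target <- if (tethered) L - 2L else 2L * nb
  can_straight <- if (tethered)
    span_target >= 2L * nb && span_target <= 3L * nb else
      span_target <= L - 2L
  hairpin <- hairpin_shape(nm)
  if (!can_straight &&
      (max(hairpin[, 3L]) > L - 2L || max(hairpin[, 1L]) > L - 2L))
    stop("infeasible config: no initial conformation fits in the box")
  occupied <- numeric(0)
  positions <- vector("list", config$n_chains)
  for (c in seq_len(config$n_chains)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      shape <- if (can_straight) straight_shape(nm, span_target) else hairpin
      span_u <- max(shape[, 1L])
      span_w <- max(shape[, 3L])
      face <- sample.int(6L, 1L)
      u0 <- sample.int(L - 1L - span_u, 1L) - 1L
      v0 <- sample.int(L - 1L, 1L) - 1L
      w0 <- if (tethered) 0L else sample.int(L - 1L - span_w, 1L) - 1L
      pos <- place_on_face(shape, face, u0, v0, w0, L)
      keys <- cube_site_keys(pos, L)
      if (anyDuplicated(keys) == 0L && !any(keys %in% occupied)) {
        positions[[c]] <- pos
        occupied <- c(occupied, keys)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("infeasible config: could not place chain ", c,
           " after ", max_tries, " tries (box too small?)")
  }
  state <- structure(list(positions = positions, config = config,
                          energy = bfm_energy_cpp(positions, config$kappa),
                          sweep = 0L),
                     class = "bfm_state")
  validate_state(state)
  state
}

#' Validate all structural invariants of a BFM state
#'
#' Checks bond-set membership of every bond, 2x2x2-cube excluded volume,
#' confinement to the cavity and (in `two_tethers` mode) that both end
#' monomers of every chain touch the envelope.
#'
#' @param state a `bfm_state`.
#' @param quiet if `TRUE`, return `TRUE`/`FALSE` instead of erroring.
#' @return invisibly `TRUE`, or an error naming the violated invariant.
#' @export
validate_state <- function(state, quiet = FALSE) {
  bad <- bfm_validate_cpp(state$positions, state$config$box_side,
                          state$config$tether_mode == "two_tethers")
  if (length(bad) > 0L) {
    if (quiet) return(FALSE)
    stop("invalid BFM state: ", paste(bad, collapse = "; "))
  }
  if (quiet) TRUE else invisible(TRUE)
}

#' Discrete worm-like-chain bending energy of a chain
#'
#' `E = kappa * sum_i (1 - u_i . u_{i+1})` over consecutive unit bond
#' tangents `u_i`; zero for a straight chain, and by convention zero for
#' chains with fewer than two bonds.  This reference implementation sums the
#' angle terms directly; the Monte Carlo engine tracks the same quantity
#' incrementally.
#'
#' @param positions numeric or integer matrix of monomer positions (rows),
#'   or a list of such matrices (energies are summed).
#' @param kappa bending stiffness, kBT units.
#' @return bending energy in kBT.
#' @export
bending_energy <- function(positions, kappa) {
  stopifnot(kappa >= 0)
  if (is.list(positions) && !is.data.frame(positions))
    return(sum(vapply(positions, bending_energy, 0, kappa = kappa)))
  p <- as.matrix(positions)
  if (nrow(p) < 3L) return(0)
  b <- diff(p)
  u <- b / sqrt(rowSums(b^2))
  n <- nrow(u)
  kappa * sum(1 - rowSums(u[-n, , drop = FALSE] * u[-1L, , drop = FALSE]))
}

#' Propose and apply a single elementary Monte Carlo move
#'
#' Picks a uniformly random monomer and one of the six axis unit
#' displacements, rejects moves that violate the bond set, excluded volume,
#' confinement or the tether constraint, and accepts the remainder with
#' Metropolis probability `min(1, exp(-dE))` on the bending energy.
#'
#' @param state a `bfm_state`.
#' @param move optional list `(chain, monomer, dir)` (1-based chain/monomer,
#'   dir in 1..6 for +x,-x,+y,-y,+z,-z); when omitted the move is drawn
#'   uniformly at random.
#' @return list with the updated `state`, logical `accepted`, and `result`
#'   (`"constraint_rejected"`, `"metropolis_rejected"` or `"accepted"`).
#' @export
propose_and_apply <- function(state, move = NULL) {
  cfg <- state$config
  if (is.null(move)) {
    idx <- sample.int(cfg$n_chains * cfg$n_monomers, 1L) - 1L
    move <- list(chain = idx %/% cfg$n_monomers + 1L,
                 monomer = idx %% cfg$n_monomers + 1L,
                 dir = sample.int(6L, 1L))
  }
  res <- bfm_step_cpp(state$positions, cfg$box_side, cfg$kappa,
                      cfg$tether_mode == "two_tethers",
                      move$chain - 1L, move$monomer - 1L, move$dir - 1L)
  state$positions <- res$positions
  state$energy <- res$energy
  list(state = state,
       accepted = res$result == 2L,
       result = c("constraint_rejected", "metropolis_rejected",
                  "accepted")[res$result + 1L])
}

#' Run Monte Carlo sweeps
#'
#' One sweep is `n_chains * n_monomers` elementary proposals.  The squared
#' end-to-end distance of every chain is recorded every sweep; full
#' conformation snapshots are recorded every `record_conf_every` sweeps.
#' Randomness continues R's RNG stream, so a run is reproducible from the
#' seed set by [init_state()].
#'
#' @param state a `bfm_state`.
#' @param n_sweeps number of sweeps (0 gives an empty trajectory).
#' @param record_conf_every snapshot interval in sweeps; 0 disables
#'   snapshots.
#' @param record_r2ee_every record the end-to-end series every this many
#'   sweeps (thinning for long production runs).
#' @return an object of class `bfm_trajectory`: final `state`, matrix
#'   `r2ee` (sweep x chain, lattice units squared), list `conformations`
#'   with their `conformation_sweeps`, and acceptance counters
#'   `n_proposed`, `n_satisfying` (proposals passing all hard constraints)
#'   and `n_accepted`.
#' @export
run_sweeps <- function(state, n_sweeps, record_conf_every = 0L,
                       record_r2ee_every = 1L) {
  stopifnot(n_sweeps >= 0L)
  cfg <- state$config
  if (n_sweeps == 0L)
    return(structure(list(state = state,
                          r2ee = matrix(numeric(0), 0L, cfg$n_chains),
                          conformations = list(),
                          conformation_sweeps = integer(0),
                          n_proposed = 0, n_satisfying = 0, n_accepted = 0),
                     class = "bfm_trajectory"))
  res <- bfm_run_cpp(state$positions, cfg$box_side, cfg$kappa,
                     cfg$tether_mode == "two_tethers",
                     as.integer(n_sweeps), as.integer(record_conf_every),
                     as.integer(record_r2ee_every))
  state$positions <- res$positions
  state$energy <- res$energy
  state$sweep <- state$sweep + as.integer(n_sweeps)
  structure(list(state = state, r2ee = res$r2ee,
                 conformations = res$conformations,
                 conformation_sweeps = state$sweep - n_sweeps +
                   res$conformation_sweeps,
                 energy_incremental = res$energy,
                 energy_full = res$energy_full,
                 n_proposed = res$n_proposed,
                 n_satisfying = res$n_satisfying,
                 n_accepted = res$n_accepted),
            class = "bfm_trajectory")
}

#' Convert a lattice conformation to physical traces
#'
#' Scales integer lattice coordinates by `config$lattice_to_micron`,
#' preserving monomer order, so simulated conformations flow through the
#' same observable pipeline as reconstructed microscopy traces.
#'
#' @param state a `bfm_state`, or a bare list of integer position matrices.
#' @param config the [sim_config()] (taken from `state` when present).
#' @param nucleus_id label for the resulting dataset.
#' @return a [nucleus_dataset()] with one trace per chain, coordinates
#'   in um.
#' @export
state_to_traces <- function(state, config = NULL, nucleus_id = "sim") {
  if (inherits(state, "bfm_state")) {
    config <- state$config
    positions <- state$positions
  } else positions <- state
  stopifnot(inherits(config, "sim_config"))
  traces <- lapply(seq_along(positions), function(i)
    sc_trace(positions[[i]] * config$lattice_to_micron,
             sc_id = sprintf("SC%02d", i), nucleus_id = nucleus_id))
  nucleus_dataset(traces, nucleus_id = nucleus_id, source = "simulation",
                  geometry = list(shape = "cube",
                                  side_um = config$box_side *
                                    config$lattice_to_micron))
}
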