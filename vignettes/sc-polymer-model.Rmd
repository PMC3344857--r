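---
title: "An entropy-driven polymer model of synaptonemal complex organization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An entropy-driven polymer model of synaptonemal complex organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

At pachytene, the paired homologous chromosomes of a mouse spermatocyte are
held together by 19 autosomal synaptonemal complexes (SCs): ladder-like
protein axes of roughly 12 µm mean contour length whose two ends attach to
the nuclear envelope through their telomeres and diffuse along it.
`scpolymer` asks how much of the observed spatial organization of these
axes follows from nothing but entropy: each SC is modeled as a confined,
self-avoiding, semiflexible polymer, with no attractive interactions of
any kind.  Two variants are compared throughout:

* **two_tethers** — both end monomers of every chain are constrained to
  touch the envelope of the confining cavity and may slide along it; and
* **untethered** — a null model of otherwise identical free chains.

Conformations are sampled with the lattice bond-fluctuation model (BFM):
each monomer occupies a 2×2×2 cube of lattice sites and consecutive
monomers are joined by one of the 108 bond vectors obtained from
(2,0,0), (2,1,0), (2,1,1), (2,2,1), (3,0,0), (3,1,0) by permutation and
sign change.  Together these two rules make excluded volume and chain
uncrossability automatic.  Moves are single-monomer hops by one lattice
unit along an axis, accepted by Metropolis on the bending energy

$$E = \kappa \sum_i \left(1 - \hat u_i \cdot \hat u_{i+1}\right),$$

the standard discretization of the worm-like chain, with
$\hat u_i$ the unit tangent of bond $i$ and $\kappa$ in units of
$k_\mathrm{B}T$.  This discretization reproduces the exponential tangent
decay $\langle \hat u(s)\cdot\hat u(s+\Delta)\rangle = e^{-\Delta/\ell_p}$
with $\ell_p \approx \kappa b$ for $\kappa \gtrsim 1$.  No reptation or
pivot moves are used: nonlocal moves would teleport tethered ends and
break the "diffuses along the envelope" semantics.

### Geometry and units

Published descriptions of this system fix the biology (19 SCs, 12 µm mean
contour, ~10 µm nucleus) but the lattice parameters must be
reconstructed.  The package's defaults coarse-grain at a Kuhn length of
b = 0.2 µm, giving 60 segments per chain, and map one Kuhn length to the
mean BFM bond length (≈2.7 lattice units), so the cubic cavity of side
50 b becomes `box_side = 135`.  All four numbers are `sim_config()`
arguments, not constants.  A cube stands in for the nucleus: at this
level of coarse-graining the difference from a sphere affects only the
envelope geometry, and every observable is computed identically for both
tether modes, so mode comparisons are unaffected.

### Initialization

Chains are seeded as straight spanning conformations along a random axis
(mixing bond lengths 2 and 3 so that a chain lands exactly wall-to-wall,
which satisfies both tether constraints by construction), falling back to
face-anchored hairpins when a spanning chain does not fit.  Random-walk
growth with backtracking was considered and rejected: it struggles to
land the second end on the envelope, whereas spanning initialization is
guaranteed feasible, seed-reproducible, and close to equilibrium for
stiff chains — the regime where equilibration is slowest.  Flexible
chains relax away from the initial state quickly, and the burn-in
protocol below governs equilibration in every case.

## Sampling protocol

The squared end-to-end distance (averaged over chains) is recorded every
sweep (one sweep = one attempted move per monomer).  Its normalized
autocorrelation is computed by FFT — numerically identical to the direct
estimator with 1/n normalization — and the integrated autocorrelation
time $\tau_{\mathrm{int}}$ by Sokal's self-consistent window: the
smallest $W$ with $W \ge c\,\tau_{\mathrm{int}}(W)$, window factor
$c = 6$ (common practice; smaller $c$ truncates, larger ones sum noise).
Production runs then discard a burn-in of $10\,\tau_{\mathrm{int}}$ and
record one conformation every $\lceil 2\,\tau_{\mathrm{int}} \rceil$
sweeps, treating those as independent.  A parameter point whose pilot
series admits no self-consistent window (for example a frozen,
zero-variance series) is flagged in the output rather than silently
included.

The pilot run must be long enough to *see* the slow modes.  For tethered
systems the slowest mode is the rearrangement of anchor points along the
envelope, which is much slower than the intra-anchor breathing of
$R^2_{ee}$; pilots of several hundred thousand sweeps are used at desk
scale so that the measured $\tau_{\mathrm{int}}$ includes this mode.

## Observables

All observables accept both simulated conformations and trace polylines,
after resampling every curve to a common site count (default 60) at
uniform arclength, so simulation and experiment are always compared at
matched discretization.

* **Squared end-to-end distance** and its distribution (the histogram is
  of the unsquared distance, matching how such distributions are usually
  plotted).
* **Center-of-mass segregation**: the mean over unordered chain pairs of
  the squared distance between centers of mass.  Larger values mean the
  chains stake out separate territories.
* **Average crossing number (ACN)**: the number of apparent crossings of
  the projected curves averaged over all projection directions, computed
  as the absolute Gauss double integral with the analytic
  solid-angle closed form per straight segment pair.  The Gauss integral
  runs over ordered segment pairs, so each unordered pair contributes
  $|\Omega|/2\pi$; the package's convention agrees with a direct
  projection-counting estimate (kept in the package as an independent
  cross-check, `acn_projection()`, never as the production path).
  Intrachain mode skips self- and adjacent pairs: their analytic
  contribution is zero but the closed form is numerically unstable there.
  Nearly-degenerate pairs are resolved by a coplanarity analysis
  (coplanar non-crossing pairs contribute zero, properly crossing ones
  the limiting half-sphere value) with recursive bisection for genuinely
  3D contacts.
* **Backbone density profile**: for each backbone site of each chain, a
  3D Gaussian kernel density estimate built from the backbone sites of
  the *other* chains of the same conformation, averaged in 30 bins of
  normalized backbone position.  Self-exclusion is the default because
  the scientific question is "how likely am I to find *another* SC near
  this part of the backbone"; the inclusive variant remains available.
  The bandwidth defaults to Scott's rule on the pooled point set and, in
  comparisons, the *same* h is always applied to both ensembles — the
  peak ratio is meaningless otherwise, and since it varies with h it is
  reported as a function of h over a grid.

## The synthetic trace generator

`generate_nucleus()` emulates the statistical shape of reconstructed SC
backbones: ~19 polylines per nucleus, contour lengths uniform within
±20% of a 12 µm mean, endpoints exactly on the (spherical) envelope,
tunable effective persistence length and optional isotropic Gaussian
localization noise (endpoints re-projected after noising so the tether
is exact).  Tangents follow
$\hat u' = \mathrm{normalize}(\hat u + g\,\eta)$ with standard-normal
$\eta$; the gain g is calibrated by numerical integration so the
single-step correlation equals $e^{-\Delta s/\ell_p}$ exactly, which
makes the persistence-length round-trip through the estimator a genuine
two-sided check.  The generator deliberately does **not** enforce mutual
excluded volume between traces and knows nothing about microscope optics
(anisotropic localization error, tracing artifacts); it feeds the
*analysis* stages.  Tests passing on synthetic data therefore validate
the pipeline's estimators and I/O, not the physics claims — those rest
on the BFM simulator — and say nothing about tracing quality in real
images.

## Persistence-length estimation

`effective_persistence_length()` fits
$\log\langle\hat u(s)\cdot\hat u(s+\Delta)\rangle = -\Delta/\ell_p$ by
least squares through the origin.  Two range guards matter: the fit is
capped at a quarter of the contour, because confinement induces
anticorrelation at large separations that would contaminate the decay
(the result is an effective, "quasi" persistence length — a global
flexibility scale, not local intrinsic stiffness); and lags whose
correlation has fallen below 0.05 are dropped, because equal-weight
fitting of log-correlations deep in the noise floor biases the estimate
low.  Straight-rod ensembles, whose correlation never decays, are
reported as censored lower bounds; ensembles with no positive leading
correlation are reported at the flexible-limit floor of one bond length.

## Desk-scale study conditions

The full-scale system (19 chains × 60 segments, box 135) equilibrates
too slowly for a test suite, so the packaged study runs a reduced system
chosen to preserve the ratios that control the physics rather than any
absolute size: 4 chains of 24 monomers in a box of 53 lattice units.
That keeps contour/box ≈ 1.2 (chains must span the cavity, as the 12 µm
SCs must span the 10 µm nucleus), envelope grafting density within ~15%
of the full system's, and the monomer volume fraction comparable.  The
rigidity grid {1, 4, 12} spans flexible to stiff *relative to the box*:
κ = 12 gives ℓ_p comparable to the cavity size, matching the stiffest
regime of the full-scale sweep.  Ensembles of 400 decorrelated
conformations per point make the directional comparisons resolvable
against their standard errors.  The acceptance script and the
acceptance-level tests state these sizes explicitly and recompute
everything from scratch.

Two desk-scale observations deserve honesty.  First, differences between
tether modes in *intrachain* entanglement are small at the flexible end
of the grid, so the "fewer overcrossings under tethering" comparison is
formalized curve-wise: pooled over the rigidity grid the tethered curve
must lie significantly below, and at no grid point significantly above —
the statistical meaning of one curve lying under another.  Second, small
systems are not the large system: with 4 chains the interchain
statistics rest on 6 pairs, and effects near the noise floor at this
scale may be decisive at full scale.

## Numerical choices

* Bond-set membership by table lookup; incremental bending energy is
  validated against full recomputation (they agree to floating
  precision over arbitrarily long runs).
* The Monte Carlo inner loop uses a xoshiro256++ generator seeded from
  R's RNG, so `set.seed()` fully determines a trajectory while the hot
  path avoids per-call R API overhead.  Identical config + seed gives
  bit-identical trajectories.
* Uniform-arclength resampling keeps endpoints exact; it preserves the
  arclength of smooth curves to ≪0.5%, but shortens jagged curves
  (corner cutting) — trace data should be resampled at or above its
  native resolution.
* Zero-length traces, zero-variance series, non-positive bandwidths,
  single-chain self-excluded profiles and zero-peak denominators all
  raise immediate, named errors instead of propagating NaNs.

## Limitations

* The reconstructed 4Pi trace coordinates are distributed as a journal
  supplement without an accession, so the packaged analyses exercise the
  experimental branch of the pipeline on clearly-labeled synthetic
  stand-ins; the reader layout (`read_sc_stacks()`) accepts the real
  per-nucleus stacks (CSV or xlsx) unchanged.
* No chromatin loops decorate the backbones: the model deliberately
  isolates entropy, and the known consequence is that it overestimates
  entanglement relative to experiment.
* The sex bivalent is not modeled; the reader does not hard-code 19
  chains.
* No knot polynomials or signed linking analysis — ACN is the only
  topological observable.
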