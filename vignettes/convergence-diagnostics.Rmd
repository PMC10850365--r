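---
title: "Convergence diagnostics for MD trajectories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convergence diagnostics for MD trajectories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdequil)
```

# The operational notion of equilibrium

Statistical-mechanical equilibrium — equal time in equal phase-space
volumes — is unattainable and, for most questions, unnecessary in a
molecular simulation. What a practitioner needs is a *per-property*
statement: the running average ⟨A⟩(t) of the observable under study has
stopped moving. `equilibrium_verdict()` implements exactly that: the
property is declared equilibrated when |⟨A⟩(t) − ⟨A⟩(T)| stays below
`fluct_tol` × scale for the entire trailing `tail_frac` of the
trajectory, and t_c is the earliest time from which the condition holds
through to T.

Two caveats are built into the interface rather than hidden:

* **"Small" needs a scale.** The default scale is the sample standard
  deviation of A, so the default tolerance reads "the running mean sits
  within 5% of one typical fluctuation of its final value". For
  observables whose own values are the natural yardstick (e.g. a
  cumulative transition rate), pass `scale =` the final value instead.
  For a strictly constant series the scale degenerates; the verdict then
  falls back to an absolute tolerance and records that it did.
* **The tolerances are configuration, not ground truth.** "A significant
  trailing portion" is irreducibly a judgement call; the defaults
  (`fluct_tol = 0.05`, `tail_frac = 0.5`) are exposed and every verdict
  carries the thresholds it used. Note a quantitative consequence of the
  5% default, used when sizing the tests: for an Ornstein–Uhlenbeck
  property with correlation time τ, the deviation of ⟨A⟩(t) at t = T/2
  has standard deviation σ√(2τ/T), and the extreme over the ~T/(4τ)
  effectively independent tail points inflates this by √(2 log N). The
  verdict therefore reliably converges only for T of order 10³–10⁴ τ, not
  at 100 τ; trajectories in the test suite are sized accordingly.

# Windowed autocorrelation and the decorrelation curve

`normalized_acf()` estimates the autocorrelation of the window [0, t]
about the *window-local* mean, dividing each lag's sum by its own pair
count n − k (the discrete analogue of the 1/(t − Δ) prefactor of the
continuous definition). The window-local mean matters: a trajectory
prefix that has not yet seen a slow oscillation treats that oscillation
as a drifting baseline, which is precisely the effect the decorrelation
curve is designed to expose. Lags are capped at half the window: beyond
that the estimator averages too few pairs to be meaningful.

The estimator is computed by FFT with explicit pair-count correction; a
direct O(nk) summation is kept as an independent oracle and the two are
tested to agree to 10⁻¹⁰.

The characteristic decorrelation time τ_c is read off as the first 1/e
crossing, linearly interpolated between bracketing lags
(`decorrelation_time()`). The 1/e convention is a design decision — no
universal definition exists — validated against closed forms: for an
exponential ACF it returns τ exactly, and for a pure cosine
arccos(1/e)/ω. An integrated-ACF variant is available behind
`method = "integrated"`. When the curve never reaches 1/e within the lag
cap, τ_c is reported as the cap with `crossing_found = FALSE`; this
fallback is what produces the τ_c ∝ t growth of under-sampled prefixes.

`decorrelation_curve()` evaluates τ_c on a log-spaced prefix grid
(10 points per decade from 100·dt to the full span, the full span always
included). The curve is invariant under affine transforms of the values,
so the units of the observable never matter.

## Plateau detection

`dc_convergence_time()` declares the plateau onset at the earliest prefix
satisfying two conditions: every later τ_c stays within ±10% (`band`) of
the final τ_c, **and** the curve is locally flat at entry — the change
from the previous grid point is itself within the band. The flatness
condition is the package's reading of "a clear, flat plateau": a curve
can *enter* the terminal band on a jump (the three-sine composite does,
rising ~30% into it), and calling that point the plateau onset would
label a still-moving curve converged. With flatness required, the
analytic suite lands where closed-form reasoning says it should: each
pure sine of period T plateaus at ≈ 1.5 T (`period_convergence_estimate`),
and the composite converges when its slowest component does. The pure
band-entry rule remains available via `require_flat = FALSE`.

A detected onset is *trusted* (`converged = TRUE`) only when the plateau
spans at least 25% (`min_tail`) of the log-time axis. A slow sine sampled
to 3×10⁵ ps has its onset found near 10⁵ ps but flagged untrusted — the
plateau is only a third of a decade long — which mirrors how a cautious
analyst would read the curve.

`fit_power_law()` fits log τ_c against log t for the self-similar
pre-plateau regime; on synthetic pure power laws it recovers the exponent
to machine precision, and the test suite checks the τ_c ~ t^0.9-style
regime on the analytic signals numerically.

# Mode-space metrics

`anm_modes()` builds the anisotropic network model on one node per
residue at the Cα position: uniform springs γ = 1 between nodes within
12 Å, the standard super-element Hessian, eigendecomposition, and removal
of near-zero modes (threshold 10⁻⁸ × largest eigenvalue). A connected
non-degenerate 3D network yields exactly 6 such modes; collinear
geometries (dimers, straight chains) legitimately carry more because
pairwise springs cannot restrain transverse motion, and the removal
handles both. Only mode shapes and eigenvalue ratios are used downstream,
so γ is a pure gauge.

`pca_modes()` diagonalises the 3N×3N coordinate covariance of a
superposed ensemble (see `iterative_mean_superpose()`, a fixed-point
iteration of Kabsch fits onto the running mean, tolerance 10⁻⁶ Å).
Eigenvector signs follow a deterministic convention (largest-magnitude
component positive) so outputs are reproducible across linear-algebra
backends.

`cumulative_overlap()` uses the root-sum-of-squares form, which is the
quantity bounded by 1 with the clean geometric meaning "fraction of the
target mode inside the span of the first j PCs"; a signed linear sum of
dot products (which is neither bounded nor monotone) is available behind
`mode = "signed"` for debugging. CO is tested for monotonicity in j, for
invariance under sign flips and rotations within the PC subspace, and for
CO = 1 at a complete basis.

Two prefix conventions coexist deliberately: `co_convergence()`
*recomputes* PCA per prefix (the question is whether the subspace itself
has stabilised), whereas `pc_histogram()` projects every prefix onto the
*fixed full-length* PCs (distributions must share an axis to be
comparable).

# States, rates and free-energy surfaces

`region_partition()` divides a periodic angular domain into named
half-open intervals [lo, hi); the wrap point is part of the partition
definition so that no populated region is split (the reference ψ
partition wraps at −100°/260° for exactly that reason). Assignment is
total and idempotent under wrapping; a boundary angle belongs to the
interval it opens.

`transition_stats()` counts an event on every consecutive-frame label
change — raw counting, no debounce — because any dwell filter changes the
measured rate and should be an explicit choice (`min_dwell`, default
off). Combined rates (n_XY + n_YX)/T use total simulated time in the
denominator. Regions under 2% occupancy are reported but flagged: rates
into scarcely visited regions are exactly the slowest-converging
quantities, and the flag marks them as unreliable rather than silently
dropping them.

`pmf()` is plain Boltzmann inversion of a binned histogram, minimum
shifted to zero, empty bins masked as `NA` (an unvisited bin has unknown,
not zero, free energy), with the per-bin shot-noise floor k_BT/√n
reported alongside. The default 5° bin is fine enough to resolve wells of
width ~30° and coarse enough that well bins hold thousands of samples in
the intended regimes. `minima_and_barriers()` finds strict local minima
under periodic adjacency and computes barriers as minimax saddles via
threshold union–find over bins sorted by F; the implementation is tested
for exact agreement with brute-force path enumeration on small grids, and
reports `Inf` when two minima are separated by never-visited bins.

Clustering (`cluster_frames()`) defaults to k-means (seeded, 10 restarts)
on projections onto the top 3 full-length PCs, with average-linkage
hierarchical clustering as the alternative; frames are relabelled so C0
is always the most populated state. These defaults are choices, not
reconstructions — the algorithms are standard but their parameterisation
for this purpose is not canonical. Note one behavioural difference the
tests rely on: asked for k = 2 on a homogeneous blob, k-means bisects it
by construction, while average linkage typically splits off a negligible
satellite, leaving one dominant cluster — the latter is the right probe
for "is there substructure here at all?" (`subcluster()`).

# Synthetic generators and what they do (not) emulate

The generators provide every input the diagnostics need, with known
ground truth; all are reproducible under a fixed seed, which is consumed
locally (the caller's RNG state is restored).

* `composite_function()` — the analytic family
  A − A·e^(−Bt) + sin(Ct) + sin(Dt) + sin(Et); `analytic_suite_params()`
  fixes the six reference parameter sets (A = 10, B = 5×10⁻⁴ ps⁻¹;
  sine frequencies 10⁻², 10⁻³, 10⁻⁴ rad/ps) used throughout the
  validation study.
* `ou_process()` — exact AR(1) update, so the autocovariance
  σ²e^(−Δ/τ) holds without integrator bias at any dt < τ.
* `jump_dihedral()` — Gillespie realisation of a continuous-time Markov
  chain over angular regions. The paper-style observable is the
  *combined* two-way rate per region pair; per-direction intensities are
  derived from it by detailed balance against prescribed stationary
  populations (equal by default): each directional flux is c_XY/2, so
  k_XY = c_XY/(2π_X). Reference rates for a dialanine-like ψ partition
  ship as `dialanine_psi_rates()` (1/0.9, 1/7.5, 1/9.9 events/ns).
  Angles are emitted from truncated Gaussians of width one sixth of the
  region span, so region assignment round-trips the hidden state exactly
  and rate recovery is decoupled from boundary noise.
* `langevin_2d()` — overdamped Euler–Maruyama on a separable periodic
  potential with two Gaussian wells per axis. Defaults emulate a
  dialanine-like landscape: ψ wells offset 1 kcal/mol behind a
  ~3 kcal/mol barrier, φ wells offset 3.5 kcal/mol (nominal midpoint of
  "3–4") behind ~5 kcal/mol. k_B = 0.0019872041 kcal/(mol·K) and T =
  298 K give k_BT = 0.5922 kcal/mol. The friction parameter is expressed
  in kcal·mol⁻¹·ps·deg⁻² so that D = k_BT/friction is an angular
  diffusion coefficient; the default gives D = 100 deg²/ps, which makes
  the ψ barrier crossing a ~nanosecond-scale event — frequent enough to
  sample well offsets at desk scale. The constructor enforces
  dt < 0.5·friction/max V″ (the stiffest-well stability bound), and the
  integrator aborts on non-finite coordinates. Well-to-well occupancy
  ratios are validated against direct quadrature of the Boltzmann
  weights, the independent oracle for the sampler.
* `harmonic_ensemble()` — direct Gaussian sampling in the internal mode
  space of a bead-spring Hessian (the same construction as the ANM), so
  PCA, CO, RMSF and per-atom variances all have closed-form targets.

What these fixtures deliberately do **not** reproduce: anharmonicity
coupled across many degrees of freedom, aging/slow drift without a
stationary distribution, solvent memory effects, and the broad continuum
of overlapping timescales of a real protein. Passing tests demonstrate
that the estimators are correct on processes whose answers are known —
not that any particular protein trajectory is converged.

# Numerical choices and problem sizes

* ACF: FFT with zero-padding to the next power of two; unbiased per-lag
  denominators; window-local mean. Degenerate (zero-variance) windows
  raise an error rather than returning NaN.
* τ_c: linear interpolation at the 1/e crossing; ties on the grid resolve
  to the earliest bracketing pair.
* Plateau: band 10%, flatness required, minimum trusted extent 25% of the
  log axis — all exposed.
* Langevin: 10⁷ steps at dt = 0.05 ps (5×10⁵ ps) for free-energy
  recovery; ~350 independent ψ barrier crossings give ΔF standard error
  ≈ 0.08 kcal/mol at the bin level.
* Jump process: 2×10⁴ ns at 10 ps output stride for rate recovery —
  ~2.7×10⁴ events against mean dwell times of ≥ 0.5 ns, so
  discretisation misses < 1% of events and estimates land well within
  10%.
* Harmonic ensembles: 10⁵ frames for mode recovery (CO ≥ 0.95 against
  the generating modes), 2×10⁴ for variance checks at 5%.
* OU validation: T = 4×10³–10⁴ τ. The 1/e-crossing estimate from a
  single trajectory carries ≈ 5% realization noise (a −0.02 ACF
  fluctuation near the crossing shifts it by ~5%), and that noise is
  persistent across prefixes of the same trajectory, so per-seed bands
  are set at 2–3 of those sigmas rather than at the naive √(2τ/T).

# Known limitations

* τ_c conventions differ across the literature (1/e crossing, integrated
  ACF, exponential fits); curves produced under different conventions are
  not numerically comparable, only qualitatively.
* The plateau detector inspects the curve only on its prefix grid; a
  plateau shorter than two grid points (a fifth of a decade at default
  density) cannot be resolved.
* Barriers are read from binned, sampled surfaces: they are minimax
  saddle *estimates* whose resolution is one bin and whose bias grows in
  poorly sampled regions (the noise floor accompanies every surface).
* The PDB reader targets multi-model Cα trajectories; binary trajectory
  formats are out of scope behind the `trajectory_adapter()` seam.
* The package diagnoses convergence of *properties*, not of the full
  phase-space distribution; a complete set of converged diagnostics is
  strong evidence, never proof, of global convergence.
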