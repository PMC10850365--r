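# mdequil

Convergence and equilibrium diagnostics for molecular-dynamics
trajectories.

## The problem

An MD simulation is only as trustworthy as its sampling. The common
practice — watch the RMSD or the energy until it "looks flat" — answers a
different, weaker question than the one that matters: *has every motion
that contributes to the property I care about decorrelated and been
sampled repeatedly?* Different properties of the same molecule converge at
wildly different times: a dihedral transition rate can be settled after
nanoseconds while the occupancy of a rarely visited rotamer is still
drifting after tens of microseconds. `mdequil` implements a suite of
diagnostics that make those statements quantitative, plus synthetic
trajectory generators with known ground truth so every diagnostic can be
validated before it is pointed at real data.

A property A(t) is called **operationally equilibrated** when its running
average ⟨A⟩(t) stays within a small band of its final value ⟨A⟩(T) for a
significant trailing portion of the trajectory; the earliest such time is
the convergence time t_c.

## The diagnostics

**Windowed autocorrelation and decorrelation curves.** For a property R(t)
observed over a window [0, t], the normalized autocorrelation is

    C(Δ, t) = C′(Δ, t) / C′(0, t),
    C′(Δ, t) = 1/(t − Δ) ∫ δR(t′) δR(t′ + Δ) dt′,   δR = R − ⟨R⟩,

with the mean taken over the window itself. The characteristic
decorrelation time τ_c is the first lag where C falls to 1/e. Recomputing
τ_c on growing prefixes of the trajectory gives the **decorrelation curve
(DC)** τ_c(t): it grows (roughly as a power law τ_c ~ t^0.9 in the
self-similar regime) while the trajectory is still discovering slow
motions, and flattens into a plateau once they are all sampled. The
plateau onset is the convergence time of the property; a useful rule of
thumb, exact for a pure sinusoid, is that a motion of period T needs about
**1.5 T** of trajectory to converge. For two-state hopping observed as a
combined forward-plus-backward rate r, the effective period is 2/r.

**Mode-space convergence.** PCA modes P_j of the trajectory are compared
against the anisotropic-network-model (ANM; Cα nodes, uniform springs,
12 Å cutoff) modes M_i of a single structure through the cumulative
overlap

    CO_i(j_max) = sqrt( Σ_{j ≤ j_max} (P_j · M_i)² )  ∈ [0, 1],

recomputed per trajectory prefix: stabilised CO curves indicate converged
global dynamics. Per-residue RMSF profiles and cluster
population/time-distribution curves (k-means or average-linkage
hierarchical, with sub-cluster analysis) cover local and structural
convergence.

**States, rates and free energy.** Dihedral angles are assigned to named
angular regions; transition events are counted on label changes, giving
combined rates (n_XY + n_YX)/T with sub-2%-occupancy regions flagged, and
cumulative-rate convergence curves. Histogram free-energy surfaces
F = −k_B T ln p (1D/2D, minimum at zero, empty bins masked) come with
minima detection and minimax-saddle barrier readout.

**Synthetic generators** (all seeded, all with closed-form ground truth):
an analytic composite signal A − A·exp(−Bt) + sin(Ct) + sin(Dt) + sin(Et);
an exact-AR(1) Ornstein–Uhlenbeck process; a continuous-time Markov jump
process over angular regions with prescribed combined rates; overdamped
Langevin dynamics on a two-well-per-axis periodic 2D landscape (Rcpp
integrator); and Gaussian harmonic bead ensembles with known normal modes.

## Worked example

The analytic reference suite generates six signals on a 5 ps grid out to
3×10⁵ ps, computes each decorrelation curve and reports plateau onsets:

```r
library(mdequil)
demo_analytic_suite(dt = 5, t_max = 3e5)
#>         system t_conv_ps log10_t_conv converged tau_final_ps slowest_period_ps period_rule_ps
#> 1          Exp     12555        4.099      TRUE       2013.0                NA             NA
#> 2       Sine-L     99760        4.999     FALSE      11929.5           62831.9        94247.8
#> 3       Sine-M      9975        3.999      TRUE       1194.0            6283.2         9424.8
#> 4       Sine-H       995        2.998      TRUE        119.4            628.3          942.5
#> 5     Sine-LMH     62945        4.799     FALSE        261.3           62831.9        94247.8
#> 6 Exp-Sine-LMH     79240        4.899     FALSE        857.1           62831.9        94247.8
```

Each pure sine plateaus close to 1.5 times its period (`period_rule_ps`):
the high-frequency sine near log₁₀ t ≈ 3, the mid one near 4, the slow one
near 5 — and the three-sine composite converges only when its slowest
component does. The slow systems carry `converged = FALSE` because their
plateau, though detected, does not yet span a quarter of the log-time
axis: the detector reports the onset but does not trust a plateau this
short, which is the intended reading of "a plateau that lasts a
significant time".

The same machinery on a stochastic signal with known answer:

```r
s  <- ou_process(tau = 100, sigma = 1, dt = 1, n = 1e5, seed = 42)
dc <- decorrelation_curve(s)
dc_convergence_time(dc)
#> $t_conv   [1] 10000
#> $converged [1] TRUE
#> $tau_final [1] 93.6
```

The Ornstein–Uhlenbeck 1/e time is τ = 100 ps; the curve plateaus there
(within single-trajectory estimator noise) after ~100 τ of observation.

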