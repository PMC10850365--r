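#' Boltzmann constant and thermal energy
#'
#' `k_B` = 0.0019872041 kcal/(mol K); the package default temperature is
#' 298 K, giving `k_B T` = 0.5922 kcal/mol.
#'
#' @param temperature Temperature in K (default 298).
#' @return Thermal energy in kcal/mol.
#' @export
thermal_energy <- function(temperature = 298) {
  0.0019872041 * temperature
}

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Parameters of the analytic composite test signal
#'
#' The composite function
#' \deqn{f(t) = A - A e^{-B t} + \sin(C t) + \sin(D t) + \sin(E t)}
#' combines a saturating exponential with three sinusoids; switching terms
#' on and off produces a family of analytic signals whose decorrelation
#' behaviour is known, used to validate the convergence diagnostics.
#'
#' @param A Amplitude of the exponential part (property units).
#' @param B Exponential rate (1/ps).
#' @param C,D,E Angular frequencies of the three sine terms (rad/ps).
#' @return An object of class `composite_params`.
#' @seealso [composite_function()], [analytic_suite_params()]
#' @export
composite_params <- function(A = 0, B = 0, C = 0, D = 0, E = 0) {
  p <- c(A = A, B = B, C = C, D = D, E = E)
  if (any(p < 0)) stop("composite parameters must be non-negative",
                       call. = FALSE)
  if (all(p[c("B", "C", "D", "E")] == 0)) {
    stop("at least one of B, C, D, E must be positive ",
         "(signal would be constant)", call. = FALSE)
  }
  structure(as.list(p), class = "composite_params")
}

#' Evaluate the analytic composite signal on a time grid
#'
#' @param params A [composite_params()].
#' @param t_grid Uniform, increasing time grid in ps.
#' @return A [property_series()].
#' @examples
#' p <- composite_params(A = 10, B = 5e-4, C = 0.01, D = 0.001, E = 1e-4)
#' s <- composite_function(p, seq(0, 1e5, by = 10))
#' @export
composite_function <- function(params, t_grid) {
  stopifnot(inherits(params, "composite_params"))
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 2) stop("t_grid needs at least 2 points",
                               call. = FALSE)
  steps <- diff(t_grid)
  if (any(steps <= 0) || any(abs(steps - steps[1]) > 1e-6 * steps[1])) {
    stop("t_grid must be uniform and increasing", call. = FALSE)
  }
  v <- with(params,
            A - A * exp(-B * t_grid) +
              sin(C * t_grid) + sin(D * t_grid) + sin(E * t_grid))
  property_series(v, times = t_grid, label = "composite")
}

#' The six reference analytic systems
#'
#' Named parameter sets of the composite signal used throughout the
#' package's validation study: a pure saturating exponential (`Exp`,
#' A = 10, B = 5e-4/ps), three pure sines at angular frequencies 1e-4,
#' 1e-3 and 1e-2 rad/ps (`Sine-L`, `Sine-M`, `Sine-H`; the low-frequency
#' sine has period 2*pi/1e-4 ~ 63,000 ps), their sum (`Sine-LMH`), and the
#' full composite (`Exp-Sine-LMH`).
#'
#' @return Named list of [composite_params()].
#' @export
analytic_suite_params <- function() {
  list(
    "Exp"          = composite_params(A = 10, B = 5e-4),
    "Sine-L"       = composite_params(E = 1e-4),
    "Sine-M"       = composite_params(D = 1e-3),
    "Sine-H"       = composite_params(C = 1e-2),
    "Sine-LMH"     = composite_params(C = 1e-2, D = 1e-3, E = 1e-4),
    "Exp-Sine-LMH" = composite_params(A = 10, B = 5e-4,
                                      C = 1e-2, D = 1e-3, E = 1e-4)
  )
}

#' Ornstein-Uhlenbeck process with known autocorrelation
#'
#' Stationary Gaussian process with autocovariance
#' \eqn{\sigma^2 e^{-\Delta/\tau}}, generated with the exact discrete AR(1)
#' update (no Euler discretisation bias): given `a = exp(-dt/tau)`,
#' `x[i+1] = a x[i] + sigma sqrt(1 - a^2) z`. Serves as the fixture whose
#' decorrelation time is known in closed form (`tau_c = tau` under the 1/e
#' convention).
#'
#' @param tau Correlation time in ps (> 0).
#' @param sigma Stationary standard deviation (>= 0).
#' @param dt Sampling interval in ps; must be < `tau` (an update with
#'   `dt >= tau` under-resolves the process and is refused).
#' @param n Number of samples.
#' @param seed Integer seed; the caller's RNG state is restored afterwards.
#' @param mean Stationary mean (default 0).
#' @return A [property_series()].
#' @export
ou_process <- function(tau, sigma, dt, n, seed = NULL, mean = 0) {
  stopifnot(tau > 0, sigma >= 0, dt > 0, n >= 2)
  if (dt >= tau) {
    stop("dt >= tau: the requested sampling does not resolve the process",
         call. = FALSE)
  }
  a <- exp(-dt / tau)
  with_seed(seed, {
    z <- stats::rnorm(n)
    x <- numeric(n)
    x[1] <- sigma * z[1]
    if (n > 1) {
      innov <- sigma * sqrt(1 - a^2) * z[-1]
      x <- stats::filter(c(x[1], innov), a, method = "recursive")
    }
    property_series(mean + as.numeric(x), dt = dt, label = "OU")
  })
}

#' Parameters for the dihedral jump-process generator
#'
#' Defines a continuous-time Markov jump process between named angular
#' regions, specified through combined two-way rates (events per ns for
#' X->Y and Y->X together, the observable a transition counter measures).
#' Combined rates are converted to per-direction intensities under detailed
#' balance with the prescribed stationary populations: with combined rate
#' `c_XY` and populations `pi`, each directional flux is `c_XY / 2`, so
#' `k_XY = c_XY / (2 pi_X)`.
#'
#' @param partition A [region_partition()] naming the regions.
#' @param rates Named numeric of combined rates in events/ns; names are
#'   unordered pairs `"X:Y"` of region labels. Missing pairs get rate 0.
#' @param total_ns Total simulated time in ns.
#' @param dt_ps Output sampling interval in ps (default 10).
#' @param populations Stationary region populations (default equal); must
#'   sum to 1.
#' @param emission_width Per-region width (degrees) of the truncated
#'   Gaussian emitting angles inside a region; default 1/6 of each region's
#'   span, so emitted angles round-trip to their region exactly.
#' @param seed Integer seed.
#' @return An object of class `jump_params`.
#' @export
jump_params <- function(partition, rates, total_ns, dt_ps = 10,
                        populations = NULL, emission_width = NULL,
                        seed = NULL) {
  stopifnot(inherits(partition, "region_partition"))
  labs <- partition$labels
  m <- length(labs)
  if (is.null(populations)) populations <- rep(1 / m, m)
  stopifnot(length(populations) == m, all(populations > 0),
            abs(sum(populations) - 1) < 1e-8)
  rate_mat <- matrix(0, m, m, dimnames = list(labs, labs))
  if (length(rates)) {
    if (is.null(names(rates))) stop("rates must be named 'X:Y'",
                                    call. = FALSE)
    for (nm in names(rates)) {
      pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
      if (length(pair) != 2 || !all(pair %in% labs)) {
        stop("bad rate name '", nm, "': expected 'X:Y' with region labels",
             call. = FALSE)
      }
      r <- rates[[nm]]
      if (!is.finite(r) || r < 0) stop("rates must be finite and >= 0",
                                       call. = FALSE)
      rate_mat[pair[1], pair[2]] <- r
      rate_mat[pair[2], pair[1]] <- r
    }
  }
  structure(
    list(partition = partition, combined_rates = rate_mat,
         populations = stats::setNames(populations, labs),
         total_ns = total_ns, dt_ps = dt_ps,
         emission_width = emission_width, seed = seed),
    class = "jump_params"
  )
}

#' Simulate a dihedral-angle jump process
#'
#' Gillespie realisation of the continuous-time Markov chain defined by
#' [jump_params()], discretised on the output grid; the emitted observable
#' is a dihedral angle in degrees drawn from a narrow truncated Gaussian
#' centred in the occupied region, so that region assignment recovers the
#' hidden state exactly and rate estimation is decoupled from boundary
#' noise.
#'
#' @param params A [jump_params()].
#' @return A [property_series()] of angles in degrees, with attributes
#'   `region_labels` (the true state at each output sample, a factor) and
#'   `params`.
#' @export
jump_dihedral <- function(params) {
  stopifnot(inherits(params, "jump_params"))
  part <- params$partition
  labs <- part$labels
  m <- length(labs)
  pi_st <- params$populations
  total_ps <- params$total_ns * 1000
  dt <- params$dt_ps
  # per-direction intensities (1/ps) from combined rates (1/ns)
  kmat <- params$combined_rates / (2 * matrix(pi_st, m, m)) / 1000
  diag(kmat) <- 0
  exit <- rowSums(kmat)
  if (m > 1 && all(exit == 0)) {
    warning("all rates zero with >1 region: process never leaves its ",
            "initial region")
  }
  n_out <- 1L + floor(total_ps / dt + 1e-9)
  grid <- dt * (0:(n_out - 1L))
  with_seed(params$seed, {
    state <- sample.int(m, 1, prob = pi_st)
    # Gillespie: jump times and states (preallocated, grown by doubling)
    cap <- max(64L, ceiling(1.5 * total_ps * max(exit, 1e-12)))
    jump_t <- numeric(cap)
    jump_s <- integer(cap)
    nj <- 0L
    t_now <- 0
    s_now <- state
    while (t_now < total_ps && exit[s_now] > 0) {
      t_now <- t_now + stats::rexp(1, exit[s_now])
      if (t_now >= total_ps) break
      s_now <- sample.int(m, 1, prob = kmat[s_now, ])
      nj <- nj + 1L
      if (nj > length(jump_t)) {
        jump_t <- c(jump_t, numeric(length(jump_t)))
        jump_s <- c(jump_s, integer(length(jump_s)))
      }
      jump_t[nj] <- t_now
      jump_s[nj] <- s_now
    }
    jump_t <- jump_t[seq_len(nj)]
    jump_s <- jump_s[seq_len(nj)]
    states <- c(state, jump_s)[1L + findInterval(grid, jump_t)]
    # emission: truncated Gaussian inside each region
    lo <- part$breaks[-length(part$breaks)]
    hi <- part$breaks[-1]
    ctr <- (lo + hi) / 2
    wd <- params$emission_width
    if (is.null(wd)) wd <- (hi - lo) / 6
    wd <- rep_len(wd, m)
    ang <- ctr[states] + wd[states] * stats::rnorm(n_out)
    # reflect the (rare) tail excursions back inside the region
    for (k in seq_len(m)) {
      idx <- which(states == k & (ang <= lo[k] | ang >= hi[k]))
      while (length(idx)) {
        ang[idx] <- ctr[k] + wd[k] * stats::rnorm(length(idx))
        idx <- idx[ang[idx] <= lo[k] | ang[idx] >= hi[k]]
      }
    }
    out <- property_series(ang, dt = dt, label = "dihedral (deg)")
    attr(out, "region_labels") <- factor(labs[states], levels = labs)
    attr(out, "params") <- params
    out
  })
}

#' Dialanine-like psi partition and transition rates
#'
#' Reference three-region partition of the psi dihedral — B (bottom,
#' psi < 32 deg), M (middle), T (top, psi > 112 deg) on the wrap domain
#' (-100, 260] deg — together with the reference combined transition rates
#' between them: T:B 1/0.9, T:M 1/7.5, B:M 1/9.9 events/ns. These serve
#' as ground truth for the jump-process generator and the rate estimator.
#'
#' @return `dialanine_psi_partition()`: a [region_partition()];
#'   `dialanine_psi_rates()`: named numeric of combined rates (events/ns).
#' @export
dialanine_psi_partition <- function() {
  region_partition(breaks = c(-100, 32, 112, 260),
                   labels = c("B", "M", "T"))
}

#' @rdname dialanine_psi_partition
#' @export
dialanine_psi_rates <- function() {
  c("T:B" = 1 / 0.9, "T:M" = 1 / 7.5, "B:M" = 1 / 9.9)
}

#' Parameters of the 2D angular free-energy landscape generator
#'
#' A separable potential `V(psi, phi) = V1(psi) + V2(phi)` on the periodic
#' angular domain, each axis carrying two Gaussian wells: the first centre
#' is the global well, the second sits `offset` kcal/mol higher, and the
#' plateau between them is `barrier` kcal/mol above the global well.
#' Defaults emulate a dialanine-like landscape: psi wells offset by 1
#' kcal/mol behind a ~3 kcal/mol barrier (frequent transitions), phi wells
#' offset by 3.5 kcal/mol behind a ~5 kcal/mol barrier (rare transitions).
#'
#' @param psi_centers,phi_centers Two well centres per axis, degrees.
#' @param psi_barrier,phi_barrier Barrier height above the global well,
#'   kcal/mol; must exceed the corresponding offset.
#' @param psi_offset,phi_offset Free-energy offset of the second well,
#'   kcal/mol (>= 0).
#' @param width Gaussian well width, degrees (default 30).
#' @param kbt Thermal energy, kcal/mol (default [thermal_energy()] at
#'   298 K).
#' @param friction Friction coefficient in kcal mol^-1 ps deg^-2; the
#'   angular diffusion coefficient is `kbt / friction` (default gives
#'   100 deg^2/ps).
#' @param dt Integrator timestep in ps; must satisfy the stability bound
#'   `dt < 0.5 * friction / max(V'')` of the stiffest well.
#' @param n_steps Number of integration steps.
#' @param stride Record every `stride`-th step (default 10).
#' @param start Starting `(psi, phi)` in degrees (default: global well).
#' @param seed Integer seed.
#' @return An object of class `landscape2d_params`.
#' @export
landscape2d_params <- function(psi_centers = c(155, 0), psi_barrier = 3,
                               psi_offset = 1,
                               phi_centers = c(-115, 55), phi_barrier = 5,
                               phi_offset = 3.5,
                               width = 30, kbt = thermal_energy(),
                               friction = thermal_energy() / 100,
                               dt = 0.05, n_steps = 1e6, stride = 10,
                               start = NULL, seed = NULL) {
  stopifnot(psi_barrier >= psi_offset, phi_barrier >= phi_offset,
            psi_offset >= 0, phi_offset >= 0,
            width > 0, kbt > 0, friction > 0, dt > 0, n_steps >= 1,
            stride >= 1)
  # stiffest curvature of a Gaussian well of depth d and width w is d / w^2;
  # zero barriers (flat potential, free diffusion) have no stability bound
  vpp_max <- max(psi_barrier, phi_barrier) / width^2
  if (vpp_max > 0 && dt > 0.5 * friction / vpp_max) {
    stop("timestep ", dt, " ps exceeds the stability bound ",
         signif(0.5 * friction / vpp_max, 4),
         " ps of the stiffest well", call. = FALSE)
  }
  if (is.null(start)) start <- c(psi_centers[1], phi_centers[1])
  structure(
    list(psi_centers = psi_centers, psi_barrier = psi_barrier,
         psi_offset = psi_offset,
         phi_centers = phi_centers, phi_barrier = phi_barrier,
         phi_offset = phi_offset,
         width = width, kbt = kbt, friction = friction, dt = dt,
         n_steps = as.integer(n_steps), stride = as.integer(stride),
         start = start, seed = seed),
    class = "landscape2d_params"
  )
}

# per-axis potential: plateau at `barrier`, wells dug by Gaussian dips
axis_well_params <- function(centers, barrier, offset, width) {
  list(c1 = centers[1], c2 = centers[2],
       d1 = barrier, d2 = barrier - offset, w = width)
}

#' Evaluate the 2D landscape potential
#'
#' @param params A [landscape2d_params()].
#' @param psi,phi Angles in degrees (vectors of equal length, or one of
#'   them length 1).
#' @return Potential energy in kcal/mol, zero at the global well.
#' @export
landscape_potential <- function(params, psi, phi) {
  stopifnot(inherits(params, "landscape2d_params"))
  a1 <- axis_well_params(params$psi_centers, params$psi_barrier,
                         params$psi_offset, params$width)
  a2 <- axis_well_params(params$phi_centers, params$phi_barrier,
                         params$phi_offset, params$width)
  axis_potential_cpp(psi, a1$c1, a1$c2, a1$d1, a1$d2, a1$w) +
    axis_potential_cpp(phi, a2$c1, a2$c2, a2$d1, a2$d2, a2$w)
}

#' Overdamped Langevin sampling of the 2D angular landscape
#'
#' Euler-Maruyama integration of
#' `gamma dtheta = -dV/dtheta dt + sqrt(2 gamma kbt) dW` on the periodic
#' domain, angles wrapped into (-180, 180] internally and reported on each
#' axis's own wrap domain (centred so neither well straddles the wrap
#' point). The long-run angle histogram is Boltzmann-distributed on the
#' potential, which is what the free-energy recovery tests assert.
#'
#' @param params A [landscape2d_params()].
#' @return List with `psi` and `phi`, both [property_series()] (degrees),
#'   and `params`.
#' @export
langevin_2d <- function(params) {
  stopifnot(inherits(params, "landscape2d_params"))
  a1 <- axis_well_params(params$psi_centers, params$psi_barrier,
                         params$psi_offset, params$width)
  a2 <- axis_well_params(params$phi_centers, params$phi_barrier,
                         params$phi_offset, params$width)
  out <- with_seed(params$seed, {
    langevin2d_cpp(params$n_steps, params$stride, params$dt,
                   params$kbt, params$friction,
                   unlist(a1), unlist(a2), params$start)
  })
  if (any(!is.finite(out))) {
    stop("energy divergence detected: non-finite coordinates during ",
         "integration; reduce the timestep", call. = FALSE)
  }
  dt_out <- params$dt * params$stride
  # wrap each axis about its own well midpoint so wells are not split
  wrap_about <- function(x, mid) mid + ((x - mid + 180) %% 360) - 180
  list(
    psi = property_series(wrap_about(out[, 1], mean(params$psi_centers)),
                          dt = dt_out, label = "psi (deg)"),
    phi = property_series(wrap_about(out[, 2], mean(params$phi_centers)),
                          dt = dt_out, label = "phi (deg)"),
    params = params
  )
}

#' Parameters of the harmonic bead-ensemble generator
#'
#' A coarse-grained bead model held together by uniform springs between
#' beads within a cutoff (the same network construction as the anisotropic
#' network model). Frames are drawn directly in mode space from the exact
#' Gaussian ensemble `N(0, kbt H^-1)` restricted to internal modes, so the
#' true covariance, normal modes and RMSF are all known analytically —
#' the validation fixture for PCA, cumulative overlap and RMSF.
#'
#' @param geometry Reference coordinates, an `n x 3` matrix in Angstrom;
#'   default is a 10-bead helical arc (non-degenerate in 3D).
#' @param spring_k Uniform spring constant, kcal/(mol A^2) (default 1).
#' @param cutoff Network cutoff in Angstrom (default 12).
#' @param kbt Thermal energy, kcal/mol.
#' @param n_frames Number of frames to draw.
#' @param seed Integer seed.
#' @return An object of class `harmonic_params`.
#' @export
harmonic_params <- function(geometry = NULL, spring_k = 1, cutoff = 12,
                            kbt = thermal_energy(), n_frames = 1000,
                            seed = NULL) {
  if (is.null(geometry)) geometry <- helix_geometry(10)
  geometry <- as.matrix(geometry)
  stopifnot(ncol(geometry) == 3, nrow(geometry) >= 3,
            all(is.finite(geometry)),
            spring_k > 0, cutoff > 0, kbt >= 0, n_frames >= 1)
  structure(
    list(geometry = geometry, spring_k = spring_k, cutoff = cutoff,
         kbt = kbt, n_frames = as.integer(n_frames), seed = seed),
    class = "harmonic_params"
  )
}

#' Helical bead geometry
#'
#' A simple alpha-helix-like arc (rise 1.5 A, radius 2.3 A, 100 deg turn
#' per bead) used as the default non-degenerate reference geometry.
#'
#' @param n Number of beads.
#' @return `n x 3` coordinate matrix (Angstrom).
#' @export
helix_geometry <- function(n) {
  i <- seq_len(n) - 1
  cbind(2.3 * cos(i * 100 * pi / 180),
        2.3 * sin(i * 100 * pi / 180),
        1.5 * i)
}

#' Sample a harmonic coordinate ensemble with known modes
#'
#' @param params A [harmonic_params()].
#' @return A [coordinate_ensemble()] with attributes `modes` (the
#'   generating internal [mode_set], eigenvalues in stiffness units) and
#'   `params`. With `kbt = 0` every frame equals the reference geometry.
#' @export
harmonic_ensemble <- function(params) {
  stopifnot(inherits(params, "harmonic_params"))
  H <- anm_hessian(params$geometry, cutoff = params$cutoff,
                   gamma = params$spring_k)
  eig <- eigen(H, symmetric = TRUE)
  nzero <- sum(eig$values < 1e-8 * max(eig$values))
  if (nzero != 6) {
    stop("internal Hessian is singular beyond rigid-body motions (",
         nzero, " near-zero modes); geometry degenerate or network ",
         "disconnected", call. = FALSE)
  }
  ord <- order(eig$values)                    # internal modes, ascending
  lam <- eig$values[ord][-seq_len(6)]
  U <- fix_mode_signs(eig$vectors[, ord][, -seq_len(6), drop = FALSE])
  nm <- length(lam)
  frames <- with_seed(params$seed, {
    if (params$kbt == 0) {
      matrix(0, params$n_frames, nm)
    } else {
      matrix(stats::rnorm(params$n_frames * nm), params$n_frames, nm) %*%
        diag(sqrt(params$kbt / lam), nm)
    }
  })
  coords_flat <- frames %*% t(U)
  ref_flat <- as.numeric(t(params$geometry))
  coords <- array(0, c(params$n_frames, nrow(params$geometry), 3))
  for (f in seq_len(params$n_frames)) {
    coords[f, , ] <- matrix(ref_flat + coords_flat[f, ], ncol = 3,
                            byrow = TRUE)
  }
  ens <- coordinate_ensemble(coords,
                             times = seq_len(params$n_frames) - 1,
                             residue_index = seq_len(nrow(params$geometry)))
  attr(ens, "modes") <- mode_set(U, lam, provenance = "ANM",
                                 reference = params$geometry)
  attr(ens, "params") <- params
  ens
}
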