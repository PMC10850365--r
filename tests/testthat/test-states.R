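test_that("region assignment is total, idempotent and matches the reference partition", {
  part <- dialanine_psi_partition()
  expect_identical(as.character(assign_regions(c(150, 0, 32), part)),
                   c("T", "B", "M"))
  # wrapping: -120 is congruent to 240, inside T; 260 wraps onto -100 (B)
  expect_identical(as.character(assign_regions(c(-120, 260), part)),
                   c("T", "B"))
  # total and idempotent under wrap
  set.seed(61)
  ang <- runif(1000, -1000, 1000)
  l1 <- assign_regions(ang, part)
  expect_false(any(is.na(l1)))
  expect_identical(assign_regions(ang + 360, part), l1)

  expect_error(region_partition(c(0, 90, 180), c("a", "b")), "360")
  expect_error(region_partition(c(0, 180, 360), c("a", "a")), "unique")
})

test_that("transition statistics count label changes correctly", {
  # strictly alternating labels: n - 1 events
  n <- 11
  lab <- factor(rep_len(c("A", "B"), n))
  ts <- transition_stats(lab, dt_ps = 1000)  # 1 ns frames
  expect_equal(sum(ts$counts), n - 1)
  expect_equal(ts$combined_rates$rate_per_ns, (n - 1) / (n - 1))
  expect_false(ts$no_events)

  # constant labels: zero rates, flagged
  tc <- transition_stats(factor(rep("A", 10), levels = c("A", "B")),
                         dt_ps = 1)
  expect_true(tc$no_events)
  expect_equal(sum(tc$counts), 0)

  # combined counts invariant under time reversal
  set.seed(62)
  lab2 <- factor(sample(c("A", "B", "C"), 500, replace = TRUE))
  f <- transition_stats(lab2, dt_ps = 10)
  r <- transition_stats(rev(lab2), dt_ps = 10)
  expect_equal(f$combined_rates$events, r$combined_rates$events)

  # occupancy below 2% is flagged
  lab3 <- factor(c(rep("A", 99), "B"), levels = c("A", "B"))
  expect_identical(transition_stats(lab3, dt_ps = 1)$sub_threshold, "B")
  expect_error(transition_stats(factor("A"), dt_ps = 1), "at least 2")
})

test_that("reference dihedral rates are recovered end to end", {
  jp <- jump_params(dialanine_psi_partition(), dialanine_psi_rates(),
                    total_ns = 4000, dt_ps = 10, seed = 71)
  s <- jump_dihedral(jp)
  ts <- transition_stats(assign_regions(s, dialanine_psi_partition()),
                         dt_ps = 10)
  truth <- dialanine_psi_rates()
  for (pair in names(truth)) {
    key <- paste(sort(strsplit(pair, ":")[[1]]), collapse = ":")
    est <- ts$combined_rates$rate_per_ns[
      vapply(ts$combined_rates$pair, function(p) {
        paste(sort(strsplit(p, ":")[[1]]), collapse = ":") == key
      }, logical(1))]
    expect_equal(est, unname(truth[pair]), tolerance = 0.10)
  }
})

test_that("cumulative rate curve ends at the overall rate and decays without events", {
  set.seed(63)
  lab <- factor(sample(c("A", "B"), 2000, replace = TRUE))
  dt <- 100
  cr <- cumulative_rate_curve(lab, dt_ps = dt, pair = "A:B")
  ts <- transition_stats(lab, dt_ps = dt)
  expect_equal(cr$values[length(cr$values)],
               ts$combined_rates$rate_per_ns[1], tolerance = 1e-12)

  # all events in the first half (the last of them on the boundary
  # step): tail decays exactly as n_ev / t
  lab2 <- factor(c(rep_len(c("A", "B"), 100), rep("A", 100)))
  cr2 <- cumulative_rate_curve(lab2, dt_ps = 1000, pair = "A:B")
  tail_t <- cr2$times[cr2$times >= 100 * 1000]
  tail_v <- cr2$values[cr2$times >= 100 * 1000]
  expect_equal(tail_v, 100 / (tail_t / 1000), tolerance = 1e-12)

  # verdict contrast at the same tolerances, measured relative to the
  # final rate: the Poisson-like curve converges, the frozen one cannot
  set.seed(64)
  lab3 <- factor(sample(c("A", "B"), 20000, replace = TRUE))
  cr3 <- cumulative_rate_curve(lab3, 1000, "A:B")
  v_ok <- equilibrium_verdict(cr3, scale = cr3$values[length(cr3$values)])
  v_bad <- equilibrium_verdict(cr2, scale = cr2$values[length(cr2$values)])
  expect_true(v_ok$converged)
  expect_false(v_bad$converged)
})

test_that("clustering separates constructed states and relabels by population", {
  set.seed(65)
  blob <- rbind(matrix(rnorm(300 * 2), ncol = 2),
                matrix(rnorm(700 * 2) + 30, ncol = 2))
  truth <- rep(c("far", "near"), c(300, 700))
  cm <- cluster_frames(blob, k = 2, seed = 1)
  # largest cluster is C0 and the split is exact
  expect_equal(as.integer(cm$sizes), c(700, 300))
  expect_equal(length(unique(cm$labels[truth == "near"])), 1)
  expect_equal(length(unique(cm$labels[truth == "far"])), 1)
  expect_identical(levels(cm$labels)[1], "C0")

  cm1 <- cluster_frames(blob, k = 1)
  expect_equal(as.integer(cm1$sizes), 1000)
  expect_error(cluster_frames(blob[1:3, ], k = 5), "k")

  # hierarchical route agrees on well-separated blobs
  ch <- cluster_frames(blob, k = 2, method = "hierarchical")
  expect_equal(as.integer(ch$sizes), c(700, 300))

  # three-state jump process embedded as separated centroids
  jp <- jump_params(dialanine_psi_partition(), dialanine_psi_rates(),
                    total_ns = 200, dt_ps = 10, seed = 66)
  s <- jump_dihedral(jp)
  feats <- cbind(cos(pi * s$values / 180), sin(pi * s$values / 180))
  cm3 <- cluster_frames(feats * 50, k = 3, seed = 2)
  occ <- as.numeric(cm3$sizes) / length(s$values)
  st <- sort(as.numeric(table(attr(s, "region_labels"))) /
               length(s$values), decreasing = TRUE)
  expect_equal(occ, st, tolerance = 0.02)
})

test_that("population curves track block structure and stationarity", {
  lab <- factor(rep(c("C0", "C1"), c(60, 40)), levels = c("C0", "C1"))
  model <- list(labels = lab, sizes = table(lab), method = "kmeans",
                k = 2, features = matrix(0, 100, 1))
  class(model) <- "cluster_model"
  pc <- cluster_population_curves(model)
  expect_equal(pc$cumulative[, "C0"][1:60], rep(1, 60))
  expect_equal(pc$cumulative[100, ], c(C0 = 0.6, C1 = 0.4))
  # single cluster: constant at 1
  lab1 <- factor(rep("C0", 10))
  m1 <- structure(list(labels = lab1, sizes = table(lab1),
                       method = "kmeans", k = 1,
                       features = matrix(0, 10, 1)),
                  class = "cluster_model")
  expect_equal(unname(cluster_population_curves(m1)$cumulative[, 1]),
               rep(1, 10))
})

test_that("subclustering exposes structure within one cluster", {
  set.seed(67)
  # cluster 0 is itself a 2-mixture; cluster 1 a distant blob
  sub_a <- matrix(rnorm(300 * 2, sd = 0.5), ncol = 2)
  sub_b <- matrix(rnorm(300 * 2, sd = 0.5) + 6, ncol = 2)
  far <- matrix(rnorm(200 * 2, sd = 0.5) + 100, ncol = 2)
  X <- rbind(sub_a, sub_b, far)
  cm <- cluster_frames(X, k = 2, seed = 3)
  sub <- subcluster(cm, "C0", k = 2, seed = 4)
  expect_equal(sort(as.integer(sub$sizes)), c(300, 300))

  # homogeneous restriction: average linkage leaves one dominant
  # subcluster (k-means would bisect the blob by construction)
  subf <- subcluster(cm, "C1", k = 2, method = "hierarchical")
  expect_gt(max(as.integer(subf$sizes)) / 200, 0.9)

  expect_error(subcluster(cm, "C9"), "no cluster")
  expect_error(subcluster(cm, "C1", window = c(1, 10)), "no frames")
})

test_that("free-energy surfaces invert Boltzmann weights exactly", {
  # integer-count fixture: F differences equal -kbt log(count ratio)
  kbt <- 0.5922
  ang <- c(rep(10, 80), rep(100, 20))  # p ratio 4
  fes <- pmf(ang, bin_width = 20, kbt = kbt, domain = c(0, 360))
  occ <- which(!is.na(fes$F))
  expect_equal(length(occ), 2)
  expect_equal(fes$F[occ[2]] - fes$F[occ[1]], -kbt * log(20 / 80))
  expect_equal(min(fes$F, na.rm = TRUE), 0)

  # two-state populations with ratio exp(-1/kbt): delta F = 1 kcal/mol
  p_ratio <- exp(-1 / kbt)
  n_major <- 100000
  n_minor <- round(n_major * p_ratio)
  ang2 <- c(rep(-50, n_major), rep(50, n_minor))
  fes2 <- pmf(ang2, bin_width = 10, kbt = kbt, domain = c(-180, 180))
  occ2 <- which(!is.na(fes2$F))
  expect_equal(abs(diff(fes2$F[occ2])), 1, tolerance = 1e-4)

  # uniform sampling: all occupied bins within noise of 0
  set.seed(68)
  u <- runif(200000, -180, 180)
  fesu <- pmf(u, bin_width = 10, kbt = kbt, domain = c(-180, 180))
  expect_lt(max(fesu$F, na.rm = TRUE), 0.05)
})

test_that("minima and barriers match the brute-force path oracle", {
  kbt <- 0.5922
  # single-well discretised paraboloid: one minimum, no barriers
  x <- seq(-175, 175, by = 10)
  Fwell <- 0.001 * (x - 5)^2   # well centred on a bin: unique minimum
  fes1 <- list(edges = list(seq(-180, 180, by = 10)),
               F = Fwell - min(Fwell), counts = rep(1L, length(x)),
               kbt = kbt, bin_width = 10,
               noise_floor = rep(0, length(x)))
  class(fes1) <- "free_energy_surface"
  mb1 <- minima_and_barriers(fes1, periodic = FALSE)
  expect_equal(nrow(mb1$minima), 1)
  expect_null(mb1$barriers)

  # 1D double well with a known saddle
  # wells centred on bins (+-85) so each minimum is a strict one
  Fdw <- 3 - 3 * exp(-(x + 85)^2 / 800) - 2 * exp(-(x - 85)^2 / 800)
  fes2 <- fes1
  fes2$F <- Fdw - min(Fdw)
  mb2 <- minima_and_barriers(fes2, periodic = TRUE)
  expect_equal(nrow(mb2$minima), 2)
  bf <- brute_force_barrier(fes2$F,
                            c(which.min(abs(x + 85)), 1),
                            c(which.min(abs(x - 85)), 1))
  expect_equal(mb2$barriers$F_saddle, bf)

  # masked gap between minima: unresolved barrier
  Fgap <- fes2$F
  Fgap[x > -40 & x < 40] <- NA
  Fgap[abs(x) > 130] <- NA
  fes3 <- fes2
  fes3$F <- Fgap
  mb3 <- minima_and_barriers(fes3, periodic = FALSE)
  expect_equal(nrow(mb3$minima), 2)
  expect_true(is.infinite(mb3$barriers$F_saddle))

  # randomized 2D grids: union-find equals exhaustive enumeration
  for (seed in 1:3) {
    set.seed(seed)
    Fv <- matrix(runif(30, 0, 5), 6, 5)
    fes4 <- list(edges = list(seq(0, 360, by = 60), seq(0, 360, by = 72)),
                 F = Fv - min(Fv), counts = matrix(1L, 6, 5), kbt = kbt,
                 bin_width = 60, noise_floor = matrix(0, 6, 5))
    class(fes4) <- "free_energy_surface"
    mb4 <- minima_and_barriers(fes4, periodic = TRUE)
    if (nrow(mb4$minima) >= 2) {
      for (r in seq_len(nrow(mb4$barriers))) {
        a <- mb4$minima[mb4$barriers$from[r], ]
        b <- mb4$minima[mb4$barriers$to[r], ]
        bf <- brute_force_barrier(fes4$F, c(a$ix, a$iy), c(b$ix, b$iy))
        expect_equal(mb4$barriers$F_saddle[r], bf)
      }
    }
  }
})
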