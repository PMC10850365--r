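#' Named angular region partition
#'
#' Partition of a periodic angular domain into named half-open intervals
#' `[lo, hi)`. The breaks must span exactly 360 degrees; any finite angle
#' is wrapped into the domain before assignment, so the partition is
#' total. The wrap point should be placed so that no populated region
#' straddles it (e.g. the reference psi partition wraps at -100/260 deg so
#' the top region stays contiguous).
#'
#' @param breaks Increasing numeric vector of interval edges (degrees);
#'   `length(labels) + 1` entries spanning 360.
#' @param labels Region names, one per interval.
#' @return An object of class `region_partition`.
#' @examples
#' dialanine_psi_partition()
#' @export
region_partition <- function(breaks, labels) {
  breaks <- as.numeric(breaks)
  labels <- as.character(labels)
  if (length(breaks) != length(labels) + 1) {
    stop("need length(labels) + 1 breaks", call. = FALSE)
  }
  if (any(diff(breaks) <= 0)) stop("breaks must be increasing",
                                   call. = FALSE)
  span <- breaks[length(breaks)] - breaks[1]
  if (abs(span - 360) > 1e-9) {
    stop("breaks must span exactly 360 degrees (got ", span, ")",
         call. = FALSE)
  }
  if (anyDuplicated(labels)) stop("region labels must be unique",
                                  call. = FALSE)
  structure(list(breaks = breaks, labels = labels),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  n <- length(x$labels)
  cat("<region_partition>\n")
  for (i in seq_len(n)) {
    cat(sprintf("  %s: [%g, %g) deg\n", x$labels[i], x$breaks[i],
                x$breaks[i + 1]))
  }
  invisible(x)
}

#' Assign angles to named regions
#'
#' Wraps each angle into the partition's domain and assigns it to its
#' half-open interval `[lo, hi)`. Total: every finite angle receives
#' exactly one label, and assignment is idempotent under wrapping.
#'
#' @param angles Numeric vector of angles in degrees, or a
#'   [property_series()] of angles.
#' @param partition A [region_partition()].
#' @return Factor of region labels (levels in partition order).
#' @examples
#' p <- dialanine_psi_partition()
#' assign_regions(c(150, 0, 32), p)  # T, B, M
#' @export
assign_regions <- function(angles, partition) {
  stopifnot(inherits(partition, "region_partition"))
  if (inherits(angles, "property_series")) angles <- angles$values
  stopifnot(all(is.finite(angles)))
  lo <- partition$breaks[1]
  wrapped <- lo + (angles - lo) %% 360
  idx <- findInterval(wrapped, partition$breaks, rightmost.closed = FALSE,
                      left.open = FALSE)
  idx[idx > length(partition$labels)] <- length(partition$labels)
  factor(partition$labels[idx], levels = partition$labels)
}

#' Transition statistics between angular regions
#'
#' Counts an event whenever consecutive frames carry different region
#' labels (no dwell filter by default: the raw-counting convention), and
#' reports the combined two-way rate per unordered region pair,
#' `(n_XY + n_YX) / T`, in events per ns. Regions whose occupancy falls
#' below `min_occupancy` (default 2%) are retained but flagged: rates
#' into scarcely-visited regions are exactly the quantities that converge
#' last, and the flag marks them as unreliable.
#'
#' @param labels Factor of region labels per frame (e.g. from
#'   [assign_regions()]).
#' @param dt_ps Frame spacing in ps.
#' @param min_occupancy Occupancy fraction below which a region is flagged
#'   (default 0.02).
#' @param min_dwell Optional minimum dwell, in frames, for a visit to
#'   count (default 0 = off); a configurable debounce for noisy
#'   assignments.
#' @return An object of class `transition_stats`: list with `counts`
#'   (ordered-pair matrix), `combined_rates` (data frame per unordered
#'   pair, events/ns), `occupancy`, `sub_threshold` (flagged labels),
#'   `total_ns`.
#' @export
transition_stats <- function(labels, dt_ps, min_occupancy = 0.02,
                             min_dwell = 0) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (n < 2) stop("need at least 2 frames", call. = FALSE)
  stopifnot(dt_ps > 0)
  labs <- levels(labels)
  if (min_dwell > 0) {
    r <- rle(as.integer(labels))
    keep <- r$lengths >= min_dwell
    if (!any(keep)) stop("min_dwell removes every visit", call. = FALSE)
    seqs <- r$values[keep]
    # merge consecutive repeats after dropping short visits
    seqs <- seqs[c(TRUE, diff(seqs) != 0)]
    trans_from <- seqs[-length(seqs)]
    trans_to <- seqs[-1]
  } else {
    li <- as.integer(labels)
    chg <- which(diff(li) != 0)
    trans_from <- li[chg]
    trans_to <- li[chg + 1]
  }
  m <- length(labs)
  counts <- matrix(0L, m, m, dimnames = list(from = labs, to = labs))
  if (length(trans_from)) {
    tab <- table(factor(trans_from, levels = seq_len(m)),
                 factor(trans_to, levels = seq_len(m)))
    counts[] <- as.integer(tab)
  }
  total_ns <- (n - 1) * dt_ps / 1000
  occ <- as.numeric(table(labels)) / n
  names(occ) <- labs
  pairs <- utils::combn(labs, 2)
  combined <- data.frame(
    pair = apply(pairs, 2, paste, collapse = ":"),
    events = apply(pairs, 2, function(p) {
      counts[p[1], p[2]] + counts[p[2], p[1]]
    }),
    stringsAsFactors = FALSE
  )
  combined$rate_per_ns <- combined$events / total_ns
  structure(
    list(counts = counts, combined_rates = combined, occupancy = occ,
         sub_threshold = labs[occ < min_occupancy], total_ns = total_ns,
         no_events = sum(counts) == 0),
    class = "transition_stats"
  )
}

#' @export
print.transition_stats <- function(x, ...) {
  cat(sprintf("<transition_stats> %g ns, %d events\n", x$total_ns,
              sum(x$counts)))
  df <- x$combined_rates
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %s: %d events, %.4g /ns\n", df$pair[i], df$events[i],
                df$rate_per_ns[i]))
  }
  if (length(x$sub_threshold)) {
    cat("  sub-threshold occupancy:", paste(x$sub_threshold, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Cumulative transition-rate convergence curve
#'
#' The combined rate of one region pair computed on the growing prefix
#' `[0, t]`, for every frame time t. A converging rate flattens with a
#' `1/sqrt(t)` fluctuation envelope; a region pair that stops
#' transitioning decays as `n/t`. Feed the result to
#' [equilibrium_verdict()] for an operational converged/not-converged
#' call.
#'
#' @param labels Factor of region labels per frame.
#' @param dt_ps Frame spacing in ps.
#' @param pair Character vector of 2 region labels, or `"X:Y"`.
#' @return A [property_series()] of combined rates (events/ns) versus time
#'   (ps), starting at the second frame.
#' @export
cumulative_rate_curve <- function(labels, dt_ps, pair) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (n < 2) stop("need at least 2 frames", call. = FALSE)
  if (length(pair) == 1) pair <- strsplit(pair, ":", fixed = TRUE)[[1]]
  stopifnot(length(pair) == 2, all(pair %in% levels(labels)))
  a <- labels[-n]
  b <- labels[-1]
  ev <- (a == pair[1] & b == pair[2]) | (a == pair[2] & b == pair[1])
  t_ns <- (seq_len(n - 1)) * dt_ps / 1000
  property_series(cumsum(ev) / t_ns, dt = dt_ps, t0 = dt_ps,
                  label = paste0("rate ", paste(pair, collapse = ":"),
                                 " (/ns)"))
}

#' Cluster trajectory frames into conformational states
#'
#' Clusters frames either by k-means (seeded, `n_start` restarts) or
#' hierarchical agglomerative clustering with average linkage on Euclidean
#' distance. The default feature representation for a coordinate ensemble
#' is the projection onto its top 3 full-length principal components.
#' Clusters are relabelled by descending population: `C0` is always the
#' most populated state.
#'
#' @param x A [coordinate_ensemble()] or a numeric feature matrix
#'   (frames x features).
#' @param k Number of clusters (>= 1, <= frames).
#' @param method `"kmeans"` (default) or `"hierarchical"`.
#' @param seed Integer seed for k-means initialisation.
#' @param n_pcs Number of PCs used as features for an ensemble input
#'   (default 3).
#' @param n_start k-means restarts (default 10).
#' @return An object of class `cluster_model`: `labels` (factor
#'   `C0, C1, ...` per frame), `sizes`, `method`, `k`, and the `features`
#'   matrix used.
#' @export
cluster_frames <- function(x, k, method = c("kmeans", "hierarchical"),
                           seed = NULL, n_pcs = 3, n_start = 10) {
  method <- match.arg(method)
  if (inherits(x, "coordinate_ensemble")) {
    nf <- dim(x$coords)[1]
    na <- dim(x$coords)[2]
    pcs <- pca_modes(x, n_modes = min(n_pcs, 3 * na, nf - 1))
    X <- t(vapply(seq_len(nf), function(f) as.numeric(t(x$coords[f, , ])),
                  numeric(3 * na)))
    features <- sweep(X, 2, as.numeric(t(pcs$reference))) %*% pcs$vectors
  } else {
    features <- as.matrix(x)
  }
  if (any(!is.finite(features))) stop("features must be finite",
                                      call. = FALSE)
  n <- nrow(features)
  stopifnot(k >= 1, k <= n)
  raw <- if (k == 1) {
    rep(1L, n)
  } else if (method == "kmeans") {
    with_seed(seed, stats::kmeans(features, centers = k,
                                  nstart = n_start)$cluster)
  } else {
    stats::cutree(stats::hclust(stats::dist(features), method = "average"),
                  k = k)
  }
  # relabel by descending population; ties broken by first appearance
  sizes <- table(raw)
  ord <- order(-as.numeric(sizes),
               vapply(names(sizes), function(g) {
                 which(raw == as.integer(g))[1]
               }, numeric(1)))
  map <- integer(length(sizes))
  map[as.integer(names(sizes)[ord])] <- seq_along(sizes) - 1L
  lab <- factor(paste0("C", map[raw]),
                levels = paste0("C", seq_along(sizes) - 1L))
  structure(
    list(labels = lab, sizes = table(lab), method = method, k = k,
         features = features),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %s, k = %d\n", x$method, x$k))
  print(x$sizes)
  invisible(x)
}

#' Cluster cumulative population and time-distribution curves
#'
#' For each cluster, the fraction of frames in `[0, t]` belonging to it,
#' as a function of t, plus the per-frame label raster (the
#' time-distribution). Converged structural sampling shows as the
#' cumulative curves flattening at the stationary occupancies.
#'
#' @param model A [cluster_frames()] result.
#' @param times Frame times in ps (default frame index).
#' @return List of class `cluster_population`: `times`, `cumulative`
#'   (frames x clusters matrix of running fractions), and `labels`.
#' @export
cluster_population_curves <- function(model, times = NULL) {
  stopifnot(inherits(model, "cluster_model"))
  lab <- model$labels
  n <- length(lab)
  if (is.null(times)) times <- as.numeric(seq_len(n) - 1)
  stopifnot(length(times) == n)
  cum <- vapply(levels(lab), function(cl) {
    cumsum(lab == cl) / seq_len(n)
  }, numeric(n))
  structure(list(times = times, cumulative = cum, labels = lab),
            class = "cluster_population")
}

#' Re-cluster the frames of one cluster within a time window
#'
#' Restricts the trajectory to the frames of a given cluster inside a
#' window and re-runs clustering there, exposing sub-states of an
#' apparently homogeneous cluster (slow internal rearrangements invisible
#' to the full-trajectory clustering).
#'
#' @param model A [cluster_frames()] result.
#' @param cluster_id Cluster label (e.g. `"C0"`).
#' @param window Frame-index range `c(first, last)` (default all frames).
#' @param k Number of subclusters.
#' @param ... Passed to [cluster_frames()].
#' @return A `cluster_model` on the restricted frames, with attribute
#'   `frame_index` giving their positions in the original trajectory.
#' @export
subcluster <- function(model, cluster_id, window = NULL, k = 2, ...) {
  stopifnot(inherits(model, "cluster_model"))
  n <- length(model$labels)
  if (is.null(window)) window <- c(1L, n)
  stopifnot(length(window) == 2, window[1] >= 1, window[2] <= n,
            window[1] <= window[2])
  if (!cluster_id %in% levels(model$labels)) {
    stop("no cluster '", cluster_id, "'", call. = FALSE)
  }
  idx <- which(model$labels == cluster_id &
                 seq_len(n) >= window[1] & seq_len(n) <= window[2])
  if (!length(idx)) {
    stop("window contains no frames of ", cluster_id, call. = FALSE)
  }
  sub <- cluster_frames(model$features[idx, , drop = FALSE], k = k, ...)
  attr(sub, "frame_index") <- idx
  sub
}

#' Histogram free-energy surface (potential of mean force)
#'
#' Boltzmann inversion of a binned angle distribution:
#' `F_bin = -kbt * log(p_bin)`, shifted so the minimum occupied bin is
#' zero. Accepts a 1D angle vector or a 2-column matrix (2D surface).
#' Empty bins are masked (`NA`), never reported as zero. The sampling
#' noise floor `kbt / sqrt(count)` per occupied bin is reported alongside.
#'
#' @param angles Numeric vector (1D) or 2-column matrix / data frame (2D)
#'   of angles in degrees; [property_series()] accepted for 1D.
#' @param bin_width Bin width in degrees per axis (default 5).
#' @param kbt Thermal energy in kcal/mol (default [thermal_energy()]).
#' @param domain Optional `c(lo, hi)` (1D) or list of two (2D); default is
#'   the data range padded to whole bins.
#' @return An object of class `free_energy_surface`: `edges` (list per
#'   axis), `F` (vector or matrix, kcal/mol, `NA` = never visited),
#'   `counts`, `kbt`, `noise_floor`.
#' @export
pmf <- function(angles, bin_width = 5, kbt = thermal_energy(),
                domain = NULL) {
  if (inherits(angles, "property_series")) angles <- angles$values
  if (is.data.frame(angles)) angles <- as.matrix(angles)
  stopifnot(bin_width > 0, kbt > 0)
  two_d <- is.matrix(angles) && ncol(angles) == 2
  if (!two_d) angles <- matrix(as.numeric(angles), ncol = 1)
  stopifnot(all(is.finite(angles)), nrow(angles) >= 1)
  make_edges <- function(v, dom) {
    if (is.null(dom)) {
      lo <- bin_width * floor(min(v) / bin_width)
      hi <- bin_width * ceiling(max(v) / bin_width)
      if (hi <= lo) hi <- lo + bin_width
    } else {
      lo <- dom[1]; hi <- dom[2]
    }
    seq(lo, hi, by = bin_width)
  }
  if (two_d) {
    if (is.null(domain)) domain <- list(NULL, NULL)
    ex <- make_edges(angles[, 1], domain[[1]])
    ey <- make_edges(angles[, 2], domain[[2]])
    ix <- findInterval(angles[, 1], ex, rightmost.closed = TRUE)
    iy <- findInterval(angles[, 2], ey, rightmost.closed = TRUE)
    ok <- ix >= 1 & ix <= length(ex) - 1 & iy >= 1 & iy <= length(ey) - 1
    counts <- matrix(0L, length(ex) - 1, length(ey) - 1)
    tb <- table(factor(ix[ok], levels = seq_len(length(ex) - 1)),
                factor(iy[ok], levels = seq_len(length(ey) - 1)))
    counts[] <- as.integer(tb)
    edges <- list(ex, ey)
  } else {
    ex <- make_edges(angles[, 1], domain)
    ix <- findInterval(angles[, 1], ex, rightmost.closed = TRUE)
    counts <- as.integer(table(factor(ix, levels = seq_len(length(ex) - 1))))
    edges <- list(ex)
  }
  p <- counts / sum(counts)
  Fv <- -kbt * log(p)
  Fv[counts == 0L] <- NA_real_
  Fv <- Fv - min(Fv, na.rm = TRUE)
  noise <- kbt / sqrt(pmax(counts, 1))
  noise[counts == 0L] <- NA_real_
  structure(list(edges = edges, F = Fv, counts = counts, kbt = kbt,
                 bin_width = bin_width, noise_floor = noise),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  dims <- if (is.matrix(x$F)) paste(dim(x$F), collapse = " x ") else
    length(x$F)
  cat(sprintf(
    "<free_energy_surface> %s bins of %g deg, kbt = %g kcal/mol, max F = %g\n",
    paste(dims, collapse = ""), x$bin_width, x$kbt,
    round(max(x$F, na.rm = TRUE), 3)))
  invisible(x)
}

#' Minima and barriers of a free-energy surface
#'
#' Local minima are occupied bins lying below all their occupied
#' neighbours (periodic adjacency on the angular grid). The barrier
#' between two minima is the minimax path height: the lowest value F such
#' that the two minima are connected through bins of free energy <= F,
#' found by threshold union-find over bins sorted by F. Pairs separated
#' by never-visited (masked) bins get an infinite barrier: the sampling
#' cannot resolve a saddle it never crossed.
#'
#' @param surface A [pmf()] result.
#' @param periodic Treat each axis as periodic (default TRUE); set FALSE
#'   when the binned domain does not wrap.
#' @return List of class `fes_minima`: `minima` (data frame with bin
#'   indices, centre coordinates in degrees and F) and `barriers` (data
#'   frame per minima pair: saddle height `F_saddle` and `barrier`, the
#'   saddle relative to the higher minimum; `Inf` when unresolved).
#' @export
minima_and_barriers <- function(surface, periodic = TRUE) {
  stopifnot(inherits(surface, "free_energy_surface"))
  Fv <- surface$F
  two_d <- is.matrix(Fv)
  dims <- if (two_d) dim(Fv) else c(length(Fv), 1L)
  if (!two_d) Fv <- matrix(Fv, ncol = 1)
  nx <- dims[1]
  ny <- dims[2]
  wrap_x <- periodic && nx > 2
  wrap_y <- periodic && two_d && ny > 2
  nbrs <- function(i, j) {
    out <- list()
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]
      jj <- j + d[2]
      if (ii < 1 || ii > nx) {
        if (!wrap_x) next
        ii <- ((ii - 1) %% nx) + 1
      }
      if (jj < 1 || jj > ny) {
        if (!wrap_y) next
        jj <- ((jj - 1) %% ny) + 1
      }
      out[[length(out) + 1]] <- c(ii, jj)
    }
    out
  }
  occupied <- which(!is.na(Fv), arr.ind = TRUE)
  is_min <- logical(nrow(occupied))
  for (r in seq_len(nrow(occupied))) {
    i <- occupied[r, 1]
    j <- occupied[r, 2]
    vals <- vapply(nbrs(i, j), function(p) Fv[p[1], p[2]], numeric(1))
    vals <- vals[!is.na(vals)]
    is_min[r] <- !length(vals) || all(Fv[i, j] < vals)
  }
  mins <- occupied[is_min, , drop = FALSE]
  centre <- function(edges, idx) (edges[idx] + edges[idx + 1]) / 2
  minima <- data.frame(
    ix = mins[, 1],
    iy = if (two_d) mins[, 2] else rep(NA_integer_, nrow(mins)),
    x = centre(surface$edges[[1]], mins[, 1]),
    y = if (two_d) centre(surface$edges[[2]], mins[, 2]) else
      rep(NA_real_, nrow(mins)),
    F = Fv[mins]
  )
  minima <- minima[order(minima$F), , drop = FALSE]
  rownames(minima) <- paste0("m", seq_len(nrow(minima)) - 1)
  # minimax saddles by union-find over bins sorted by F
  barriers <- NULL
  nmin <- nrow(minima)
  if (nmin > 1) {
    lin <- function(i, j) (j - 1L) * nx + i
    parent <- seq_len(nx * ny)
    find <- function(a) {
      while (parent[a] != a) {
        parent[a] <<- parent[parent[a]]
        a <- parent[a]
      }
      a
    }
    added <- matrix(FALSE, nx, ny)
    ordbins <- occupied[order(Fv[occupied]), , drop = FALSE]
    min_id <- rep(NA_integer_, nx * ny)
    for (r in seq_len(nmin)) {
      min_id[lin(minima$ix[r], if (two_d) minima$iy[r] else 1L)] <- r
    }
    saddle <- matrix(Inf, nmin, nmin)
    pending <- nmin * (nmin - 1) / 2
    for (r in seq_len(nrow(ordbins))) {
      i <- ordbins[r, 1]
      j <- ordbins[r, 2]
      added[i, j] <- TRUE
      for (p in nbrs(i, j)) {
        if (!added[p[1], p[2]]) next
        ra <- find(lin(i, j))
        rb <- find(lin(p[1], p[2]))
        if (ra == rb) next
        # roots carry the set of minima they contain via min_id groups
        parent[ra] <- rb
        ga <- which(vapply(seq_len(nmin), function(m) {
          find(lin(minima$ix[m], if (two_d) minima$iy[m] else 1L)) == rb
        }, logical(1)))
        # any two minima first united at this F get this saddle height
        if (length(ga) > 1) {
          for (a in ga) for (b in ga) {
            if (a < b && !is.finite(saddle[a, b])) {
              saddle[a, b] <- Fv[i, j]
              pending <- pending - 1
            }
          }
        }
      }
      if (pending == 0) break
    }
    pr <- utils::combn(nmin, 2)
    barriers <- data.frame(
      from = rownames(minima)[pr[1, ]],
      to = rownames(minima)[pr[2, ]],
      F_saddle = saddle[cbind(pr[1, ], pr[2, ])]
    )
    barriers$barrier <- barriers$F_saddle -
      pmax(minima$F[pr[1, ]], minima$F[pr[2, ]])
  }
  structure(list(minima = minima, barriers = barriers),
            class = "fes_minima")
}

#' @export
print.fes_minima <- function(x, ...) {
  cat("<fes_minima>\n")
  print(round(x$minima, 3))
  if (!is.null(x$barriers)) {
    cat("barriers:\n")
    print(transform(x$barriers, F_saddle = round(F_saddle, 3),
                    barrier = round(barrier, 3)))
  }
  invisible(x)
}
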