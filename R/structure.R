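#' Conformational ensemble of coordinates
#'
#' Frames-by-atoms-by-3 coordinate array (Angstrom) with residue metadata
#' and frame times, the carrier for all structural convergence metrics
#' (PCA, cumulative overlap, RMSF, clustering).
#'
#' @param coords Numeric array `frames x atoms x 3`.
#' @param times Frame times in ps (default `0, 1, 2, ...`).
#' @param residue_index Integer residue index per atom (default
#'   `1..atoms`).
#' @param atom_name Atom name per atom (default `"CA"`).
#' @return An object of class `coordinate_ensemble`.
#' @export
coordinate_ensemble <- function(coords, times = NULL, residue_index = NULL,
                                atom_name = NULL) {
  coords <- as.array(coords)
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    stop("coords must be a frames x atoms x 3 array", call. = FALSE)
  }
  if (any(!is.finite(coords))) stop("coordinates must be finite",
                                    call. = FALSE)
  nf <- dim(coords)[1]
  na <- dim(coords)[2]
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1)
  if (length(times) != nf) stop("times must have one entry per frame",
                                call. = FALSE)
  if (is.null(residue_index)) residue_index <- seq_len(na)
  if (is.null(atom_name)) atom_name <- rep("CA", na)
  structure(
    list(coords = coords, times = as.numeric(times),
         residue_index = as.integer(residue_index),
         atom_name = as.character(atom_name)),
    class = "coordinate_ensemble"
  )
}

#' @export
print.coordinate_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<coordinate_ensemble> %d frames x %d atoms\n", d[1], d[2]))
  invisible(x)
}

#' @export
length.coordinate_ensemble <- function(x) dim(x$coords)[1]

#' Subset the frames of an ensemble
#' @param ensemble A [coordinate_ensemble()].
#' @param idx Frame indices to keep.
#' @return A `coordinate_ensemble` with the selected frames.
#' @export
ensemble_frames <- function(ensemble, idx) {
  stopifnot(inherits(ensemble, "coordinate_ensemble"))
  coordinate_ensemble(ensemble$coords[idx, , , drop = FALSE],
                      times = ensemble$times[idx],
                      residue_index = ensemble$residue_index,
                      atom_name = ensemble$atom_name)
}

#' Orthonormal mode set (PCA or ANM)
#'
#' @param vectors `3N x m` matrix of orthonormal mode vectors (columns).
#' @param eigenvalues Length-m eigenvalues: variances (A^2) for PCA
#'   (descending), stiffnesses for ANM (ascending, rigid-body modes
#'   removed).
#' @param provenance `"PCA"` or `"ANM"`.
#' @param reference Reference coordinates (`N x 3`), optional.
#' @return An object of class `mode_set`.
#' @export
mode_set <- function(vectors, eigenvalues, provenance = c("PCA", "ANM"),
                     reference = NULL) {
  provenance <- match.arg(provenance)
  vectors <- as.matrix(vectors)
  if (ncol(vectors) > nrow(vectors)) {
    stop("more modes than degrees of freedom", call. = FALSE)
  }
  gram <- crossprod(vectors)
  if (max(abs(gram - diag(ncol(vectors)))) > 1e-8) {
    stop("mode vectors are not orthonormal to 1e-8", call. = FALSE)
  }
  stopifnot(length(eigenvalues) == ncol(vectors))
  structure(
    list(vectors = vectors, eigenvalues = as.numeric(eigenvalues),
         provenance = provenance, reference = reference),
    class = "mode_set"
  )
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set> %s: %d modes in %d dimensions\n",
              x$provenance, ncol(x$vectors), nrow(x$vectors)))
  invisible(x)
}

# deterministic sign convention: largest-magnitude component positive
fix_mode_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Kabsch rigid-body superposition
#'
#' Optimal least-squares fit of a mobile frame onto a reference over
#' rotations and translations (SVD solution, with the determinant
#' correction that excludes reflections).
#'
#' @param mobile,reference `N x 3` coordinate matrices.
#' @param selection Atom indices used to compute the fit (default all);
#'   the transform is applied to all atoms.
#' @return List with `coords` (fitted mobile), `rmsd` (Angstrom, over the
#'   selection), `rotation` (3x3) and `translation`.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, all(dim(mobile) == dim(reference)))
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3) {
    stop("need at least 3 atoms in the selection", call. = FALSE)
  }
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  # collinearity check: rank of the centred selection must be >= 2
  if (sum(svd(A0)$d > 1e-8 * max(1, max(abs(A0)))) < 2) {
    stop("degenerate (collinear) selection: superposition ill-defined",
         call. = FALSE)
  }
  s <- svd(crossprod(A0, B0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- sweep(sweep(mobile, 2, ca) %*% t(R), 2, cb, `+`)
  rmsd <- sqrt(mean(rowSums((fitted[selection, , drop = FALSE] - B)^2)))
  list(coords = fitted, rmsd = rmsd, rotation = R,
       translation = cb - ca %*% t(R))
}

#' Iterative superposition onto the converged mean structure
#'
#' Fits every frame to the running mean structure and iterates until the
#' mean stops moving (fixed point), the standard preprocessing before PCA
#' and RMSF.
#'
#' @param ensemble A [coordinate_ensemble()].
#' @param tol Convergence tolerance on mean drift, Angstrom (default
#'   1e-6).
#' @param max_iter Iteration cap (default 100).
#' @return List with `ensemble` (superposed), `mean` (`N x 3`), `rmsd`
#'   (per-frame RMSD to the mean) and `iterations`.
#' @export
iterative_mean_superpose <- function(ensemble, tol = 1e-6,
                                     max_iter = 100) {
  stopifnot(inherits(ensemble, "coordinate_ensemble"))
  nf <- dim(ensemble$coords)[1]
  if (nf < 2) stop("need at least 2 frames", call. = FALSE)
  coords <- ensemble$coords
  ref <- coords[1, , ]
  for (it in seq_len(max_iter)) {
    for (f in seq_len(nf)) {
      coords[f, , ] <- kabsch_superpose(coords[f, , ], ref)$coords
    }
    m <- apply(coords, c(2, 3), mean)
    drift <- sqrt(mean((m - ref)^2))
    ref <- m
    if (drift < tol) {
      rmsds <- vapply(seq_len(nf), function(f) {
        sqrt(mean(rowSums((coords[f, , ] - ref)^2)))
      }, numeric(1))
      out <- coordinate_ensemble(coords, times = ensemble$times,
                                 residue_index = ensemble$residue_index,
                                 atom_name = ensemble$atom_name)
      return(list(ensemble = out, mean = ref, rmsd = rmsds,
                  iterations = it))
    }
  }
  stop("iterative superposition did not converge in ", max_iter,
       " iterations (last mean drift ", signif(drift, 4), " A)",
       call. = FALSE)
}

#' Principal component analysis of a superposed ensemble
#'
#' Eigendecomposition of the `3N x 3N` coordinate covariance about the
#' ensemble mean. Eigenvalues are variances (A^2), descending; eigenvector
#' signs follow a deterministic convention (largest-magnitude component
#' positive) so results are reproducible across linear-algebra backends.
#'
#' @param ensemble A superposed [coordinate_ensemble()] (see
#'   [iterative_mean_superpose()]). A warning is issued if frames still
#'   carry net rotation relative to the first frame.
#' @param n_modes Number of modes to keep (default: all with positive
#'   variance, at most `frames - 1`).
#' @return A [mode_set()] with `provenance = "PCA"`; the ensemble mean is
#'   stored as `reference`.
#' @export
pca_modes <- function(ensemble, n_modes = NULL) {
  stopifnot(inherits(ensemble, "coordinate_ensemble"))
  nf <- dim(ensemble$coords)[1]
  na <- dim(ensemble$coords)[2]
  if (nf < 2) stop("need at least 2 frames for PCA", call. = FALSE)
  X <- t(vapply(seq_len(nf), function(f) as.numeric(t(ensemble$coords[f, , ])),
                numeric(3 * na)))
  # net-rotation check against frame 1 (superposition sanity)
  if (na >= 3) {
    fit <- kabsch_superpose(ensemble$coords[nf, , ], ensemble$coords[1, , ])
    raw <- sqrt(mean(rowSums((ensemble$coords[nf, , ] -
                                ensemble$coords[1, , ])^2)))
    if (raw > 1e-6 && fit$rmsd < 0.5 * raw) {
      warning("ensemble does not look superposed (net rigid-body motion ",
              "between frames); run iterative_mean_superpose() first")
    }
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  cv <- crossprod(Xc) / (nf - 1)
  eig <- eigen(cv, symmetric = TRUE)
  keep <- if (is.null(n_modes)) {
    min(sum(eig$values > 1e-12 * max(eig$values, 1e-300)), nf - 1)
  } else {
    min(n_modes, ncol(eig$vectors))
  }
  V <- fix_mode_signs(eig$vectors[, seq_len(keep), drop = FALSE])
  mode_set(V, eig$values[seq_len(keep)], provenance = "PCA",
           reference = matrix(mu, ncol = 3, byrow = TRUE))
}

#' Anisotropic network model Hessian
#'
#' Builds the `3N x 3N` Hessian of the ANM harmonic potential: for every
#' node pair within the cutoff, the standard super-element
#' `-gamma (r r^T) / |r|^2` off-diagonal block, diagonal blocks the
#' negative sum of the row's off-diagonal blocks.
#'
#' @param coords `N x 3` node coordinates (Angstrom), one node per residue
#'   at the C-alpha position.
#' @param cutoff Interaction cutoff in Angstrom (default 12).
#' @param gamma Uniform spring constant (default 1).
#' @return Symmetric positive semidefinite `3N x 3N` matrix.
#' @export
anm_hessian <- function(coords, cutoff = 12, gamma = 1) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(ncol(coords) == 3, n >= 2)
  H <- matrix(0, 3 * n, 3 * n)
  d <- as.matrix(stats::dist(coords))
  # connectivity check: the contact graph must have a single component
  adj <- d <= cutoff & d > 0
  comp <- graph_components(adj)
  if (max(comp) > 1) {
    sizes <- table(comp)
    stop("elastic network is disconnected at cutoff ", cutoff, " A: ",
         length(sizes), " components of sizes ",
         paste(sizes, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!adj[i, j]) next
      r <- coords[j, ] - coords[i, ]
      blk <- -gamma * tcrossprod(r) / sum(r^2)
      ii <- (3 * i - 2):(3 * i)
      jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- blk
      H[jj, ii] <- blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  H
}

# connected components of an adjacency matrix (BFS)
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Anisotropic network model normal modes
#'
#' Normal modes of the elastic network built on the reference coordinates:
#' eigenvectors of the ANM Hessian with the near-zero rigid-body modes
#' removed (threshold `1e-8` times the largest eigenvalue; exactly 6 for a
#' connected non-degenerate 3D network, more for collinear geometries
#' whose transverse motions the pairwise springs cannot restrain), remaining
#' modes in ascending stiffness order — the softest internal modes are the
#' large-scale functional motions the cumulative-overlap diagnostic
#' compares against MD principal components.
#'
#' @param coords `N x 3` reference coordinates (Angstrom).
#' @param cutoff Cutoff distance in Angstrom (default 12).
#' @param gamma Uniform spring constant (default 1; only mode shapes and
#'   eigenvalue ratios are used downstream).
#' @param n_modes Number of internal modes to keep (default all).
#' @return A [mode_set()] with `provenance = "ANM"`.
#' @export
anm_modes <- function(coords, cutoff = 12, gamma = 1, n_modes = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("need at least 2 nodes", call. = FALSE)
  H <- anm_hessian(coords, cutoff = cutoff, gamma = gamma)
  eig <- eigen(H, symmetric = TRUE)
  vals <- rev(eig$values)
  vecs <- eig$vectors[, rev(seq_len(ncol(eig$vectors))), drop = FALSE]
  # a connected 3D network has exactly 6 rigid-body zero modes; degenerate
  # geometries (collinear chains, dimers) carry more unrestrained dofs,
  # which are removed the same way
  nzero <- sum(vals < 1e-8 * max(vals))
  if (nzero < 5) {
    stop("found only ", nzero, " near-zero modes where at least 5 rigid ",
         "motions are expected; Hessian construction inconsistent",
         call. = FALSE)
  }
  vals <- vals[-seq_len(nzero)]
  vecs <- vecs[, -seq_len(nzero), drop = FALSE]
  if (!is.null(n_modes)) {
    keep <- seq_len(min(n_modes, length(vals)))
    vals <- vals[keep]
    vecs <- vecs[, keep, drop = FALSE]
  }
  mode_set(fix_mode_signs(vecs), vals, provenance = "ANM",
           reference = coords)
}

#' Cumulative overlap of a target mode in a basis
#'
#' Measures how much of a target mode (typically an ANM normal mode) is
#' contained in the subspace spanned by the first `j_max` vectors of an
#' orthonormal basis (typically MD principal components):
#' \deqn{CO_i(j_{max}) = \sqrt{\sum_{j \le j_{max}} (P_j \cdot M_i)^2}}
#' clipped to `[0, 1]`. CO = 1 means the basis span fully contains the
#' target. A signed linear sum of dot products (not bounded by 1) is
#' available via `mode = "signed"` for debugging.
#'
#' @param target Numeric vector (length 3N) or a single-column of a
#'   [mode_set()].
#' @param basis A [mode_set()] (or `3N x m` orthonormal matrix).
#' @param j_max Number of basis vectors to accumulate (default all).
#' @param mode `"rss"` (root-sum-of-squares, default) or `"signed"`.
#' @return If `j_max` is scalar, a single CO value; if a vector, the CO
#'   curve at each `j_max`.
#' @export
cumulative_overlap <- function(target, basis, j_max = NULL,
                               mode = c("rss", "signed")) {
  mode <- match.arg(mode)
  if (inherits(target, "mode_set")) target <- target$vectors[, 1]
  target <- as.numeric(target)
  B <- if (inherits(basis, "mode_set")) basis$vectors else as.matrix(basis)
  if (length(target) != nrow(B)) {
    stop("dimension mismatch: target has length ", length(target),
         ", basis rows ", nrow(B), call. = FALSE)
  }
  if (is.null(j_max)) j_max <- ncol(B)
  stopifnot(all(j_max >= 1), all(j_max <= ncol(B)))
  dots <- as.numeric(crossprod(B, target))
  if (mode == "signed") {
    return(cumsum(dots)[j_max])
  }
  co <- sqrt(cumsum(dots^2))
  pmin(co[j_max], 1)
}

#' Cumulative-overlap convergence across trajectory prefixes
#'
#' For each prefix of the trajectory, recomputes the PCA on that prefix
#' and evaluates the cumulative overlap of the first `n_anm_modes`
#' internal ANM modes (from the reference structure) against the prefix's
#' PC basis, as a function of the number of PCs. Convergence of the
#' trajectory shows as these curves stabilising with prefix length.
#'
#' @param ensemble A superposed [coordinate_ensemble()].
#' @param reference Reference `N x 3` coordinates for the ANM (default:
#'   the ensemble mean).
#' @param prefixes Increasing frame counts; prefixes with fewer than 3
#'   frames are skipped with a warning.
#' @param n_anm_modes Number of ANM modes tracked (default 3).
#' @param n_pcs Number of PCs in the CO curves (default 10).
#' @param cutoff,gamma Passed to [anm_modes()].
#' @return List of class `co_convergence`: per prefix, a
#'   `n_pcs x n_anm_modes` CO matrix; plus `prefixes` and the `anm`
#'   mode set.
#' @export
co_convergence <- function(ensemble, reference = NULL, prefixes,
                           n_anm_modes = 3, n_pcs = 10, cutoff = 12,
                           gamma = 1) {
  stopifnot(inherits(ensemble, "coordinate_ensemble"))
  prefixes <- sort(unique(as.integer(prefixes)))
  nf <- dim(ensemble$coords)[1]
  stopifnot(all(prefixes <= nf))
  if (is.null(reference)) reference <- apply(ensemble$coords, c(2, 3), mean)
  anm <- anm_modes(reference, cutoff = cutoff, gamma = gamma,
                   n_modes = n_anm_modes)
  curves <- vector("list", length(prefixes))
  names(curves) <- as.character(prefixes)
  for (i in seq_along(prefixes)) {
    p <- prefixes[i]
    if (p < 3) {
      warning("prefix of ", p, " frame(s) too short for PCA; skipped")
      next
    }
    pcs <- pca_modes(ensemble_frames(ensemble, seq_len(p)))
    jm <- min(n_pcs, ncol(pcs$vectors))
    co <- vapply(seq_len(n_anm_modes), function(k) {
      cumulative_overlap(anm$vectors[, k], pcs, j_max = seq_len(jm))
    }, numeric(jm))
    colnames(co) <- paste0("ANM", seq_len(n_anm_modes))
    curves[[i]] <- co
  }
  structure(list(curves = curves, prefixes = prefixes, anm = anm),
            class = "co_convergence")
}

#' Principal-component projection histograms across prefixes
#'
#' Projects each trajectory prefix onto one fixed principal component of
#' the full-length PCA and histograms the projections on a common grid, so
#' the distributions are directly comparable across prefixes. A still-
#' shifting distribution flags unconverged sampling along that PC even
#' when other metrics look settled.
#'
#' @param ensemble A superposed [coordinate_ensemble()].
#' @param mode_index Which full-length PC to project on (default 1).
#' @param prefixes Increasing frame counts.
#' @param bins Number of histogram bins (default 50).
#' @return List of class `pc_histogram`: `breaks`, `mids` and a `density`
#'   matrix (bins x prefixes), plus the projection series.
#' @export
pc_histogram <- function(ensemble, mode_index = 1, prefixes, bins = 50) {
  stopifnot(inherits(ensemble, "coordinate_ensemble"))
  prefixes <- sort(unique(as.integer(prefixes)))
  nf <- dim(ensemble$coords)[1]
  na <- dim(ensemble$coords)[2]
  stopifnot(all(prefixes >= 1), all(prefixes <= nf))
  pcs <- pca_modes(ensemble)
  stopifnot(mode_index <= ncol(pcs$vectors))
  X <- t(vapply(seq_len(nf), function(f) as.numeric(t(ensemble$coords[f, , ])),
                numeric(3 * na)))
  mu <- as.numeric(t(pcs$reference))
  proj <- as.numeric(sweep(X, 2, mu) %*% pcs$vectors[, mode_index])
  breaks <- seq(min(proj), max(proj), length.out = bins + 1)
  breaks[1] <- breaks[1] - 1e-9
  breaks[length(breaks)] <- breaks[length(breaks)] + 1e-9
  dens <- vapply(prefixes, function(p) {
    h <- graphics::hist(proj[seq_len(p)], breaks = breaks, plot = FALSE)
    h$density
  }, numeric(bins))
  colnames(dens) <- as.character(prefixes)
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-bins - 1]) / 2,
                 density = dens, projection = proj, prefixes = prefixes,
                 mode_index = mode_index),
            class = "pc_histogram")
}

#' Root-mean-square fluctuation profile
#'
#' Per-atom RMSF over a window of frames:
#' \deqn{RMSF_i = \sqrt{ \frac{1}{N} \sum_j | r_i(t_j) -
#'   \langle r_i \rangle |^2 }}
#' with the mean position taken over the same window. The ensemble is
#' expected to be superposed on the window mean.
#'
#' @param ensemble A superposed [coordinate_ensemble()].
#' @param window Frame indices (default all frames).
#' @param selection Atom indices (default all atoms).
#' @return An object of class `rmsf_profile`: data frame with
#'   `residue_index` and `rmsf` (Angstrom), window stored as attribute.
#' @export
rmsf <- function(ensemble, window = NULL, selection = NULL) {
  stopifnot(inherits(ensemble, "coordinate_ensemble"))
  nf <- dim(ensemble$coords)[1]
  if (is.null(window)) window <- seq_len(nf)
  if (length(window) == 0) stop("empty window", call. = FALSE)
  if (is.null(selection)) selection <- seq_len(dim(ensemble$coords)[2])
  sub <- ensemble$coords[window, selection, , drop = FALSE]
  mu <- apply(sub, c(2, 3), mean)
  sq <- sweep(sub, c(2, 3), mu)^2
  msf <- apply(sq, 2, sum) / length(window)   # sums x,y,z and frames
  out <- data.frame(residue_index = ensemble$residue_index[selection],
                    rmsf = sqrt(msf))
  attr(out, "window") <- range(ensemble$times[window])
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' RMSF convergence across trajectory prefixes
#'
#' RMSF profiles on growing prefixes, each superposed on its own mean,
#' with the maximum pairwise deviation between consecutive profiles as the
#' convergence trace.
#'
#' @param ensemble A [coordinate_ensemble()] (superposition is redone per
#'   prefix).
#' @param prefixes Increasing frame counts (each >= 2).
#' @param superpose Re-superpose each prefix on its own mean
#'   (default TRUE).
#' @return List of class `rmsf_convergence`: `profiles` (one
#'   [rmsf()] per prefix), `prefixes`, and `max_deviation` between
#'   consecutive profiles (Angstrom).
#' @export
rmsf_convergence <- function(ensemble, prefixes, superpose = TRUE) {
  stopifnot(inherits(ensemble, "coordinate_ensemble"))
  prefixes <- sort(unique(as.integer(prefixes)))
  stopifnot(all(prefixes >= 2),
            all(prefixes <= dim(ensemble$coords)[1]))
  profiles <- lapply(prefixes, function(p) {
    sub <- ensemble_frames(ensemble, seq_len(p))
    if (superpose) sub <- iterative_mean_superpose(sub)$ensemble
    rmsf(sub)
  })
  names(profiles) <- as.character(prefixes)
  maxdev <- if (length(profiles) > 1) {
    vapply(seq_len(length(profiles) - 1), function(i) {
      max(abs(profiles[[i + 1]]$rmsf - profiles[[i]]$rmsf))
    }, numeric(1))
  } else numeric(0)
  structure(list(profiles = profiles, prefixes = prefixes,
                 max_deviation = maxdev),
            class = "rmsf_convergence")
}
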