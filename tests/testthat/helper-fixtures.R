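# small fixtures shared across test files; everything is built in code

sine_series <- function(omega, dt, t_max, label = "sine") {
  tt <- seq(0, t_max, by = dt)
  property_series(sin(omega * tt), dt = dt, label = label)
}

# regular tetrahedron, edge sqrt(2)
tetrahedron <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(2)
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

# ensemble of n Gaussian-jittered copies of a reference geometry
jitter_ensemble <- function(ref, n, sd, seed = 1) {
  set.seed(seed)
  coords <- array(0, c(n, nrow(ref), 3))
  for (f in seq_len(n)) coords[f, , ] <- ref + matrix(rnorm(length(ref), sd = sd), ncol = 3)
  coordinate_ensemble(coords)
}

# random orthonormal basis of R^d (QR of a Gaussian matrix)
random_orthonormal <- function(d, m = d, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
  q[, seq_len(m), drop = FALSE]
}

# brute-force minimax barrier: enumerate all simple paths between two bins
# on a small grid, track the minimum over paths of the maximum F en route
brute_force_barrier <- function(Fv, from, to, periodic = TRUE) {
  two_d <- is.matrix(Fv)
  if (!two_d) Fv <- matrix(Fv, ncol = 1)
  nx <- nrow(Fv)
  ny <- ncol(Fv)
  best <- Inf
  neighbours <- function(i, j) {
    out <- list()
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1 || ii > nx) {
        if (!periodic || nx <= 2) next
        ii <- ((ii - 1) %% nx) + 1
      }
      if (jj < 1 || jj > ny) {
        if (!periodic || !two_d || ny <= 2) next
        jj <- ((jj - 1) %% ny) + 1
      }
      if (!is.na(Fv[ii, jj])) out[[length(out) + 1]] <- c(ii, jj)
    }
    out
  }
  visited <- matrix(FALSE, nx, ny)
  dfs <- function(i, j, height) {
    height <- max(height, Fv[i, j])
    if (height >= best) return()
    if (i == to[1] && j == to[2]) {
      best <<- min(best, height)
      return()
    }
    visited[i, j] <<- TRUE
    for (p in neighbours(i, j)) {
      if (!visited[p[1], p[2]]) dfs(p[1], p[2], height)
    }
    visited[i, j] <<- FALSE
  }
  if (!is.na(Fv[from[1], from[2]]) && !is.na(Fv[to[1], to[2]])) {
    dfs(from[1], from[2], -Inf)
  }
  best
}
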