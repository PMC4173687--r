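## Independent oracles used by the tests. These deliberately re-derive the
## quantities by the most direct route available (brute force, closed form,
## textbook algorithms) and share no code with the package's fitting paths.

## Poisson log-link GLM by textbook IRLS (working response + weighted LS)
irls_poisson <- function(y, x, tol = 1e-12, maxit = 200) {
  X <- cbind(1, x)
  beta <- c(log(mean(y) + 0.1), 0)
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    beta_new <- solve(crossprod(X, mu * X), crossprod(X, mu * z))
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- as.numeric(beta_new); break
    }
    beta <- as.numeric(beta_new)
  }
  beta
}

## Kendall tau-b by explicit pair enumeration with tie corrections
kendall_tau_brute <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

## profile-RSS grid search for the one-breakpoint model (the stated
## independent oracle for the segmented estimator)
profile_psi_grid <- function(x, y, n_grid = 1000) {
  xs <- sort(unique(x))
  grid <- seq(xs[2], xs[length(xs) - 1], length.out = n_grid)
  rss <- vapply(grid, function(psi) {
    f <- lm(y ~ x + pmax(x - psi, 0))
    sum(resid(f)^2)
  }, numeric(1))
  list(psi = grid[which.min(rss)], step = diff(grid[1:2]),
       rss = min(rss), grid = grid, profile = rss)
}

## Moran's I by the direct double sum over a row-standardized weight list
moran_brute <- function(values, W_dense) {
  n <- length(values)
  z <- values - mean(values)
  s0 <- sum(W_dense)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W_dense[i, j] * z[i] * z[j]
  unname((n / s0) * num / sum(z^2))
}

## ray-casting point-in-polygon (boundary treatment irrelevant: callers use
## strictly interior sample points)
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in 1:n) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

## membership oracle: a cell belongs to a polygon if any point of a k x k
## lattice of interior sample points (10x finer than the cell) is inside
raster_membership <- function(grid, rings_proj, k = 10) {
  hits <- integer(0)
  for (id in seq_len(grid$n_cols * grid$n_rows)) {
    b <- glottorisk:::cell_bounds(grid, id)
    xs <- seq(b["xmin"], b["xmax"], length.out = k + 2)[2:(k + 1)]
    ys <- seq(b["ymin"], b["ymax"], length.out = k + 2)[2:(k + 1)]
    found <- FALSE
    for (ring in rings_proj) {
      for (px in xs) {
        for (py in ys)
          if (point_in_ring(px, py, ring)) { found <- TRUE; break }
        if (found) break
      }
      if (found) break
    }
    if (found) hits <- c(hits, id)
  }
  hits
}

## a small deterministic world for reuse across tests
tiny_world_config <- function(seed = 11, n_languages = 120L, ...) {
  synthetic_config(seed = seed, grid_cols = 12L, grid_rows = 8L,
                   n_languages = n_languages, ...)
}
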