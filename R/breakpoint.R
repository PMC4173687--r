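#' Segmented (one-breakpoint) regression
#'
#' Fits the continuous two-segment linear model
#' `y = b0 + b1 * x + b2 * (x - psi)_+` by least squares, estimating the
#' breakpoint `psi` jointly with the slopes. The primary estimator is
#' iterative linearization: the model is augmented with the hinge term
#' `(x - psi)_+` and its negative indicator, and `psi` is updated by
#' `psi + gamma / b2` until the step falls below `1e-6 * range(x)`
#' (Muggeo-style algorithm). A coarse profile search over candidate
#' breakpoints guards against convergence to a local optimum; ties in
#' profile residual sum of squares are broken toward the smallest `psi`.
#'
#' The 95% confidence interval for `psi` uses the delta method
#' (`Var(psi) = Var(gamma) / b2^2` at convergence) by default, or a
#' nonparametric bootstrap.
#'
#' @param x,y numeric vectors; `length(x) >= 7` with at least 5 distinct
#'   `x` values.
#' @param ci one of `"delta"` or `"boot"`.
#' @param n_boot bootstrap resamples when `ci = "boot"`.
#' @param seed seed for the bootstrap.
#' @return object of class `breakpoint_fit`: `psi`, `psi_ci`, `slope_left`,
#'   `slope_right`, `intercept`, `sigma2` (ML residual variance),
#'   `log_likelihood`, `k` (5 parameters: intercept, two slopes, psi,
#'   variance), `aic`, `degenerate` (no interior optimum), `converged`,
#'   `fitted`, `residuals`.
#' @export
fit_segmented <- function(x, y, ci = c("delta", "boot"), n_boot = 500,
                          seed = 1L) {
  ci <- match.arg(ci)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 7) stop("need at least 7 observations")
  if (length(unique(x)) < 5) stop("need at least 5 distinct x values")
  rng <- range(x)
  span <- diff(rng)

  rss_at <- function(psi) {
    u <- pmax(x - psi, 0)
    f <- stats::lm.fit(cbind(1, x, u), y)
    sum(f$residuals^2)
  }

  ## interior candidate breakpoints: keep >= 2 distinct x on each side
  xs <- sort(unique(x))
  lo <- xs[2]; hi <- xs[length(xs) - 1]

  iterate <- function(psi) {
    for (it in seq_len(100)) {
      u <- pmax(x - psi, 0)
      v <- -(x > psi)
      f <- tryCatch(stats::lm(y ~ x + u + v), error = function(e) NULL)
      if (is.null(f) || anyNA(stats::coef(f))) return(NULL)
      b2 <- stats::coef(f)[["u"]]; gam <- stats::coef(f)[["v"]]
      if (abs(b2) < 1e-12) return(NULL)
      step <- gam / b2
      psi_new <- min(max(psi + step, lo), hi)
      if (abs(psi_new - psi) < 1e-6 * span)
        return(list(psi = psi_new, fit = f, converged = TRUE))
      psi <- psi_new
    }
    list(psi = psi, fit = NULL, converged = FALSE)
  }

  ## profile guard on a coarse grid (always computed; cheap)
  grid <- seq(lo, hi, length.out = 200)
  prof <- vapply(grid, rss_at, numeric(1))
  i_min <- which(prof <= min(prof) + 1e-12)[1]   # smallest-psi tie-break
  degenerate <- i_min == 1L || i_min == length(grid)

  res <- iterate(stats::median(x))
  psi_hat <- if (!is.null(res) && res$converged) res$psi else NA_real_
  if (is.na(psi_hat) || rss_at(psi_hat) > prof[i_min] + 1e-9) {
    res2 <- iterate(grid[i_min])
    if (!is.null(res2) && res2$converged &&
        rss_at(res2$psi) <= prof[i_min] + 1e-9) {
      res <- res2; psi_hat <- res2$psi
    } else {
      ## fall back to a fine local profile refinement around the grid optimum
      g2 <- seq(grid[max(1, i_min - 1)], grid[min(length(grid), i_min + 1)],
                length.out = 200)
      p2 <- vapply(g2, rss_at, numeric(1))
      psi_hat <- g2[which.min(p2)]
      res <- list(psi = psi_hat, fit = NULL, converged = FALSE)
    }
  }
  if (psi_hat <= lo + 1e-9 * span || psi_hat >= hi - 1e-9 * span)
    degenerate <- TRUE

  u <- pmax(x - psi_hat, 0)
  final <- stats::lm(y ~ x + u)
  cf <- stats::coef(final)
  rss <- max(sum(stats::residuals(final)^2), 1e-16 * max(1, sum(y^2)))
  sigma2 <- rss / n
  logL <- -n / 2 * (log(2 * pi * sigma2) + 1)
  k <- 5L

  ## delta-method SE of psi from the augmented model at the optimum
  psi_se <- NA_real_
  if (!is.null(res$fit)) {
    cfa <- stats::coef(res$fit)
    V <- suppressWarnings(stats::vcov(res$fit))  # exact fits: SE ~ 0
    if (!anyNA(cfa) && all(is.finite(V)) && abs(cfa[["u"]]) > 1e-12)
      psi_se <- sqrt(V["v", "v"]) / abs(cfa[["u"]])
  } else {
    v <- -(x > psi_hat)
    fa <- tryCatch(stats::lm(y ~ x + u + v), error = function(e) NULL)
    if (!is.null(fa) && !anyNA(stats::coef(fa)) &&
        abs(stats::coef(fa)[["u"]]) > 1e-12)
      psi_se <- sqrt(suppressWarnings(stats::vcov(fa))["v", "v"]) /
        abs(stats::coef(fa)[["u"]])
  }
  psi_ci <- c(NA_real_, NA_real_)
  if (ci == "delta" && is.finite(psi_se))
    psi_ci <- psi_hat + c(-1, 1) * stats::qnorm(0.975) * psi_se
  if (ci == "boot") {
    set.seed(seed)
    bs <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      f <- tryCatch(fit_segmented_once(x[idx], y[idx], lo, hi),
                    error = function(e) NA_real_)
      f
    })
    bs <- bs[is.finite(bs)]
    if (length(bs) >= 50)
      psi_ci <- unname(stats::quantile(bs, c(0.025, 0.975)))
  }
  if (degenerate) psi_ci <- c(rng[1], rng[2])
  psi_ci <- c(max(psi_ci[1], rng[1], na.rm = TRUE),
              min(psi_ci[2], rng[2], na.rm = TRUE))

  structure(list(psi = psi_hat, psi_ci = psi_ci, psi_se = psi_se,
                 intercept = unname(cf[1]),
                 slope_left = unname(cf[2]),
                 slope_right = unname(cf[2] + cf[3]),
                 sigma2 = sigma2, log_likelihood = logL, k = k,
                 aic = -2 * logL + 2 * k,
                 degenerate = degenerate,
                 converged = isTRUE(res$converged),
                 fitted = stats::fitted(final),
                 residuals = stats::residuals(final)),
            class = "breakpoint_fit")
}

## single bootstrap replicate: coarse profile + local refinement
fit_segmented_once <- function(x, y, lo, hi) {
  lo <- max(lo, sort(unique(x))[2])
  xs <- sort(unique(x))
  if (length(xs) < 5) return(NA_real_)
  hi <- min(hi, xs[length(xs) - 1])
  if (hi <= lo) return(NA_real_)
  g <- seq(lo, hi, length.out = 100)
  rss <- vapply(g, function(psi) {
    f <- stats::lm.fit(cbind(1, x, pmax(x - psi, 0)), y)
    sum(f$residuals^2)
  }, numeric(1))
  g[which.min(rss)]
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf("Segmented fit: psi = %.4f (95%% CI %.4f..%.4f)\n",
              x$psi, x$psi_ci[1], x$psi_ci[2]))
  cat(sprintf("  slopes: left %.5f, right %.5f; AIC %.2f%s\n",
              x$slope_left, x$slope_right, x$aic,
              if (x$degenerate) " [degenerate: no interior breakpoint]" else ""))
  invisible(x)
}

#' Candidate models for a pairwise relationship
#'
#' Fits the four candidate shapes for a bivariate risk-component
#' relationship -- null (intercept only), linear, quadratic, and segmented
#' one-breakpoint regression -- under a Gaussian likelihood, and compares
#' them by AIC. Parameter counts include the error variance: 2, 3, 4 and 5
#' respectively. A degenerate segmented fit (no interior breakpoint) is
#' dropped from the candidate list.
#'
#' @param x,y numeric vectors.
#' @return list with `table` (data.frame: family, k, log_likelihood, aic,
#'   delta_aic), `best` (family name with smallest AIC), and `fits`.
#' @export
fit_candidates <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  ## residual sums below numerical resolution are floored, so families
  ## fitting the data exactly share one likelihood and the parameter
  ## penalty decides (a constant response selects the null family)
  floor_rss <- 1e-16 * max(1, sum(y^2))
  gauss_ll <- function(fit) {
    rss <- max(sum(stats::residuals(fit)^2), floor_rss)
    -n / 2 * (log(2 * pi * rss / n) + 1)
  }
  fits <- list(null = stats::lm(y ~ 1), linear = stats::lm(y ~ x),
               quadratic = stats::lm(y ~ x + I(x^2)))
  ll <- vapply(fits, gauss_ll, numeric(1))
  k <- c(null = 2, linear = 3, quadratic = 4)
  seg <- tryCatch(fit_segmented(x, y), error = function(e) NULL)
  if (!is.null(seg) && !seg$degenerate) {
    fits$segmented <- seg
    ll <- c(ll, segmented = seg$log_likelihood)
    k <- c(k, segmented = 5)
  }
  tab <- data.frame(family = names(ll), k = unname(k),
                    log_likelihood = unname(ll),
                    aic = unname(-2 * ll + 2 * k))
  tab$delta_aic <- tab$aic - min(tab$aic)
  list(table = tab, best = tab$family[which.min(tab$aic)], fits = fits)
}

#' Pairwise threshold analyses among the three risk components
#'
#' Runs the three bivariate analyses: (i) log10 range size as a function of
#' log10 speaker population size, (ii) speaker growth rate as a function of
#' log10 range size, and (iii) speaker growth rate as a function of log10
#' initial population size (the count at the oldest survey year, used
#' instead of the latest estimate to avoid circularity with the fitted
#' growth rate). Predictor and any size response are log10-transformed;
#' growth rate stays on its raw (per-year) scale. Breakpoints estimated on
#' the log10 scale are back-transformed to natural units (speakers, km^2).
#'
#' @param components per-language table from [compute_risk_components()].
#' @return named list of three analyses; each has the `fit_candidates()`
#'   output plus, when the segmented family is present, `psi_natural` and
#'   `psi_ci_natural` (back-transformed breakpoint and CI).
#' @export
pairwise_threshold_analyses <- function(components) {
  d <- components
  ana <- list(
    range_vs_population = list(
      x = ifelse(d$population > 0, log10(d$population), NA),
      y = ifelse(d$area_km2 > 0, log10(d$area_km2), NA),
      log_scale = TRUE),
    growth_vs_range = list(
      x = ifelse(d$area_km2 > 0, log10(d$area_km2), NA),
      y = d$rate, log_scale = TRUE),
    growth_vs_initial_population = list(
      x = ifelse(d$initial_population > 0, log10(d$initial_population), NA),
      y = d$rate, log_scale = TRUE))
  out <- lapply(ana, function(a) {
    ok <- is.finite(a$x) & is.finite(a$y)
    if (!any(ok)) stop("empty join: no language has both variables")
    res <- fit_candidates(a$x[ok], a$y[ok])
    seg <- res$fits$segmented
    if (!is.null(seg)) {
      res$psi <- seg$psi
      res$psi_ci <- seg$psi_ci
      res$psi_natural <- 10^seg$psi
      res$psi_ci_natural <- 10^seg$psi_ci
    }
    res$n <- sum(ok)
    res
  })
  out
}
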