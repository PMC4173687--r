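#' Collinearity screening with tolerance report
#'
#' Greedy pairwise screening: while any pair of candidate variables has
#' absolute Pearson correlation above the threshold, the lower-priority
#' member of the worst pair is dropped. For every retained variable the
#' tolerance `1 - R^2` of that variable regressed on all other retained
#' variables is reported; low tolerance flags residual multicollinearity.
#'
#' @param data data.frame of numeric candidate columns.
#' @param priority character vector ordering the variables from most to
#'   least preferred (defaults to column order).
#' @param threshold absolute correlation above which a pair is screened
#'   (default 0.8).
#' @return list with `retained` (variable names), `excluded` (data.frame:
#'   variable, partner, r), `tolerance` (named vector for retained
#'   variables).
#' @export
collinearity_screen <- function(data, priority = names(data),
                                threshold = 0.8) {
  vars <- priority[priority %in% names(data)]
  stopifnot(length(vars) >= 1)
  d <- data[vars]
  if (any(vapply(d, function(v) stats::sd(v, na.rm = TRUE) == 0, logical(1))))
    stop("constant column in candidate set")
  excluded <- data.frame(variable = character(0), partner = character(0),
                         r = numeric(0))
  repeat {
    if (length(vars) < 2) break
    cm <- stats::cor(data[vars], use = "pairwise.complete.obs")
    diag(cm) <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    if (abs(cm[worst[1], worst[2]]) <= threshold) break
    pair <- vars[c(worst[1], worst[2])]
    drop <- pair[which.max(match(pair, priority))]
    keep <- setdiff(pair, drop)
    excluded <- rbind(excluded,
                      data.frame(variable = drop, partner = keep,
                                 r = cm[worst[1], worst[2]]))
    vars <- setdiff(vars, drop)
  }
  tol <- vapply(vars, function(v) {
    others <- setdiff(vars, v)
    if (!length(others)) return(1)
    f <- stats::lm.fit(cbind(1, as.matrix(data[others])), data[[v]])
    rss <- sum(f$residuals^2)
    tss <- sum((data[[v]] - mean(data[[v]]))^2)
    rss / tss
  }, numeric(1))
  list(retained = vars, excluded = excluded, tolerance = tol)
}

#' All-subsets model specifications
#'
#' @param variables character vector of candidate explanatory variables
#'   (at most 20).
#' @return list of `2^p` character vectors (subsets), the first being the
#'   intercept-only model (empty subset).
#' @export
all_subsets <- function(variables) {
  p <- length(variables)
  if (p > 20) stop("more than 20 variables; restrict the candidate set")
  if (p == 0) return(list(character(0)))
  idx <- 0:(2^p - 1)
  lapply(idx, function(i) variables[bitwAnd(i, 2^(seq_len(p) - 1)) > 0])
}

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AIC_i - min(AIC)`. Non-finite AICs receive weight 0.
#'
#' @param aics numeric vector (at least one finite value).
#' @return numeric weights summing to 1.
#' @export
akaike_weights <- function(aics) {
  if (!any(is.finite(aics))) stop("no finite AIC")
  delta <- aics - min(aics, na.rm = TRUE)
  w <- ifelse(is.finite(delta), exp(-delta / 2), 0)
  w / sum(w)
}

#' 95% confidence set of models
#'
#' The smallest prefix of the weight-sorted model list whose cumulative
#' Akaike weight reaches the level.
#'
#' @param weights numeric Akaike weights.
#' @param level cumulative weight target (default 0.95).
#' @return integer indices (into `weights`) of the confidence set, ordered
#'   by decreasing weight.
#' @export
confidence_set <- function(weights, level = 0.95) {
  o <- order(weights, decreasing = TRUE)
  cum <- cumsum(weights[o])
  m <- which(cum >= level - 1e-12)[1]
  if (is.na(m)) m <- length(weights)
  o[seq_len(m)]
}

#' Model-averaged coefficients across a confidence set
#'
#' Conditional ("natural") averaging: each variable's coefficient is
#' averaged over the models of the confidence set that contain it, with
#' weights renormalized within that subset. The unconditional standard
#' error follows the Burnham-Anderson formula
#' `se = sum_i w'_i * sqrt(se_i^2 + (b_i - b_bar)^2)`, and `z = |coef|/se`.
#' `sum_wi` is the summed (set-renormalized) weight of the models
#' containing the variable, the relative-importance measure.
#'
#' @param coefs list of named coefficient vectors, one per model.
#' @param ses list of named SE vectors matching `coefs`.
#' @param weights Akaike weights of the models (full candidate set scale).
#' @param set indices of the confidence set (default: all models).
#' @return data.frame: `variable`, `coef`, `se`, `z_value`, `sum_wi`,
#'   `important` (`z > 2`), ordered by decreasing `sum_wi`.
#' @export
model_average <- function(coefs, ses, weights, set = seq_along(coefs)) {
  stopifnot(length(coefs) == length(ses), length(coefs) == length(weights))
  w <- weights[set] / sum(weights[set])
  coefs <- coefs[set]; ses <- ses[set]
  vars <- unique(unlist(lapply(coefs, names)))
  vars <- setdiff(vars, "(Intercept)")
  rows <- lapply(vars, function(v) {
    has <- vapply(coefs, function(b) v %in% names(b), logical(1))
    if (!any(has)) return(NULL)
    wv <- w[has] / sum(w[has])
    b <- vapply(coefs[has], `[[`, numeric(1), v)
    s <- vapply(ses[has], `[[`, numeric(1), v)
    bbar <- sum(wv * b)
    se <- sum(wv * sqrt(s^2 + (b - bbar)^2))
    data.frame(variable = v, coef = bbar, se = se,
               z_value = abs(bbar) / se, sum_wi = sum(w[has]))
  })
  out <- do.call(rbind, rows)
  out$important <- out$z_value > 2
  out[order(-out$sum_wi), ]
}

#' SAR multimodel inference for one response
#'
#' The full driver-inference procedure for one per-cell response: all
#' subsets of the candidate variables are fitted as SAR error models (the
#' spatial autoregression parameter re-estimated per model), ranked by
#' delta-AIC with Akaike weights, reduced to the 95% confidence set, and
#' model-averaged.
#'
#' @param y response vector over cells.
#' @param data data.frame of candidate explanatory variables (cells as
#'   rows); columns are standardized internally when `standardize = TRUE`.
#' @param weights `spatial_weights` for the adopted neighbourhood distance.
#' @param variables candidate variable names (default: all columns).
#' @param level confidence-set level (default 0.95).
#' @param standardize center/scale predictors before fitting.
#' @return list with `models` (data.frame: formula, k, aic, delta_aic,
#'   weight, in_set), `averaged` (output of [model_average()]), `best`
#'   (minimum-AIC `sar_fit`), `full` (all-variables `sar_fit`).
#' @export
sar_multimodel <- function(y, data, weights, variables = names(data),
                           level = 0.95, standardize = FALSE) {
  X_all <- as.matrix(data[variables])
  if (standardize) X_all <- scale(X_all)
  subsets <- all_subsets(variables)
  n <- length(y)
  fits <- lapply(subsets, function(vs) {
    X <- cbind("(Intercept)" = rep(1, n),
               X_all[, vs, drop = FALSE])
    fit_sar_error(y, X, weights)
  })
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  w <- akaike_weights(aics)
  set <- confidence_set(w, level)
  models <- data.frame(
    formula = vapply(subsets, function(v)
      if (length(v)) paste(v, collapse = " + ") else "1", character(1)),
    k = vapply(fits, `[[`, integer(1), "k"),
    aic = aics, delta_aic = aics - min(aics), weight = w)
  models$in_set <- seq_along(fits) %in% set
  avg <- model_average(lapply(fits, `[[`, "beta"),
                       lapply(fits, `[[`, "se"), w, set)
  full_idx <- which(vapply(subsets, length, integer(1)) == length(variables))
  list(models = models[order(-models$weight), ], averaged = avg,
       best = fits[[which.min(aics)]], full = fits[[full_idx]],
       set_size = length(set))
}
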