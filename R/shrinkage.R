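#' Raw predictor: each subject's own first-session map
#'
#' Predicts the second-session Fisher-Z connectivity map of every subject by
#' its own first-session map, \eqn{\hat V^{R}_{i2}(v) = V_{i1}(v)}. `NaN`
#' voxels propagate.
#'
#' @param fisher A `fisher_panel` array (I x J x V) with session 1 in the
#'   first session slot.
#' @return An `estimator_result`: list with `method`, `fisher` (I x V matrix
#'   of Fisher-scale predictions) and `correlation` (its `tanh`).
#' @examples
#' sim <- generate_fisher_panel(synth_config(4, n_voxels = 3, rng_seed = 1))
#' raw <- raw_estimator(sim$panel)
#' @export
raw_estimator <- function(fisher) {
  v1 <- session_slice(fisher, 1L)
  new_estimator("raw", v1)
}

#' Group-mean predictor: the average first-session map
#'
#' Predicts every subject's second-session map by the across-subject mean of
#' the first-session Fisher-Z maps, \eqn{\hat V^{M}_{2}(v) = I^{-1} \sum_i
#' V_{i1}(v)}; the prediction is identical for all subjects. `NaN` voxels are
#' excluded from the mean voxelwise; a voxel `NaN` in every subject stays
#' `NaN`.
#'
#' @inheritParams raw_estimator
#' @return An `estimator_result`; its `fisher` matrix carries the same map in
#'   every row, and attribute `n_effective` records the per-voxel count of
#'   subjects contributing to the mean.
#' @export
mean_estimator <- function(fisher) {
  v1 <- session_slice(fisher, 1L)
  n_eff <- colSums(!is.na(v1))
  m <- colMeans(v1, na.rm = TRUE)
  m[n_eff == 0L] <- NaN
  pred <- matrix(m, nrow(v1), ncol(v1), byrow = TRUE,
                 dimnames = dimnames(v1))
  res <- new_estimator("mean", pred)
  attr(res, "n_effective") <- n_eff
  res
}

#' Voxelwise variance components of a two-session Fisher panel
#'
#' Under the classical measurement-error model \eqn{V_{ij}(v) = X_i(v) +
#' U_{ij}(v)}, estimates for every voxel: the measurement-error variance from
#' the session differences \eqn{D_i(v) = V_{i2}(v) - V_{i1}(v)},
#' \deqn{\widehat{Var}\{U\}(v) = \tfrac12 \cdot \tfrac{1}{I-1} \sum_i
#' \{D_i(v) - \bar D(v)\}^2,}
#' the total single-measurement variance as the within-session
#' between-subject sample variance pooled over sessions,
#' \deqn{\widehat{Var}\{V\}(v) = \tfrac1J \sum_j \tfrac{1}{I-1} \sum_i
#' \{V_{ij}(v) - \bar V_{j}(v)\}^2,}
#' and the between-subject variance \eqn{\widehat{Var}\{X\} =
#' \max(\widehat{Var}\{V\} - \widehat{Var}\{U\}, 0)} — a negative moment
#' estimate is a known finite-sample artifact and is clamped to zero, with
#' the affected voxels flagged. Voxels `NaN` in any session of a subject
#' drop that subject for that voxel; a voxel with fewer than 2 complete
#' subjects has `NA` components (downstream [lambda_map()] assigns its
#' fixed fallback weight there).
#'
#' @param fisher A `fisher_panel` with exactly 2 sessions and I >= 2.
#' @return A `variance_components` list with per-voxel numeric vectors
#'   `var_U`, `var_V`, `var_X`, `D_bar`, logical `clamped`, and integer
#'   `n_effective`.
#' @examples
#' sim <- generate_fisher_panel(synth_config(20, n_voxels = 10, rng_seed = 3))
#' vc <- variance_components(sim$panel)
#' @export
variance_components <- function(fisher) {
  stopifnot(length(dim(fisher)) == 3L)
  if (dim(fisher)[2] != 2L)
    stop("variance components require exactly 2 sessions", call. = FALSE)
  if (dim(fisher)[1] < 2L)
    stop("variance components require >=2 subjects", call. = FALSE)
  v1 <- session_slice(fisher, 1L)
  v2 <- session_slice(fisher, 2L)
  ok <- !(is.na(v1) | is.na(v2))
  v1[!ok] <- NA; v2[!ok] <- NA
  n_eff <- colSums(ok)
  D <- v2 - v1
  var_U <- 0.5 * apply(D, 2, stats::var, na.rm = TRUE)
  var_V <- 0.5 * (apply(v1, 2, stats::var, na.rm = TRUE) +
                  apply(v2, 2, stats::var, na.rm = TRUE))
  D_bar <- colMeans(D, na.rm = TRUE)
  deficient <- n_eff < 2L
  var_U[deficient] <- NA_real_
  var_V[deficient] <- NA_real_
  D_bar[deficient] <- NA_real_
  var_X <- var_V - var_U
  clamped <- !is.na(var_X) & var_X < 0
  var_X[clamped] <- 0
  structure(list(var_U = var_U, var_V = var_V, var_X = var_X,
                 D_bar = D_bar, clamped = clamped, n_effective = n_eff),
            class = "variance_components")
}

#' Voxelwise shrinkage weight lambda(v)
#'
#' The weight placed on the group-mean map in the convex-combination
#' predictor: \eqn{\lambda(v) = Var\{U\}(v) / (Var\{X\}(v) + Var\{U\}(v))},
#' i.e. one minus the intraclass correlation coefficient (ICC, the
#' test-retest reliability) of the voxel's connectivity value. `lambda = 0`
#' means the subject's own map is fully reliable and no shrinkage occurs;
#' `lambda = 1` means it is fully unreliable and the prediction collapses to
#' the group mean. When both variance components are zero the weight is 1 by
#' convention (the raw map carries no information beyond the common value).
#' Voxels whose components could not be estimated (fewer than 2 complete
#' subjects) receive `fallback_lambda`.
#'
#' Alternatively a single fixed weight may be imposed on all voxels via
#' `fixed_lambda` (a value of 0.1 has been advocated as close to the average
#' voxel reliability in scan-rescan data).
#'
#' @param comp A [variance_components()] object (ignored when `fixed_lambda`
#'   is given, may be `NULL` in that case).
#' @param fixed_lambda Optional scalar in \[0, 1\]; if supplied, a constant
#'   map is returned.
#' @param fallback_lambda Weight for voxels with inestimable components;
#'   default 0.1.
#' @return A `lambda_map` list with numeric vector `lambda` in \[0, 1\],
#'   `icc = 1 - lambda`, and `source` (`"estimated"` or `"fixed"`).
#' @examples
#' lambda_map(NULL, fixed_lambda = 0.1)$source
#' @export
lambda_map <- function(comp, fixed_lambda = NULL, fallback_lambda = 0.1) {
  if (!is.null(fixed_lambda)) {
    if (!is.numeric(fixed_lambda) || length(fixed_lambda) != 1L ||
        is.na(fixed_lambda) || fixed_lambda < 0 || fixed_lambda > 1)
      stop("fixed_lambda must be a scalar in [0, 1]", call. = FALSE)
    n <- if (inherits(comp, "variance_components")) length(comp$var_U) else 1L
    lam <- rep(fixed_lambda, n)
    return(structure(list(lambda = lam, icc = 1 - lam, source = "fixed"),
                     class = "lambda_map"))
  }
  stopifnot(inherits(comp, "variance_components"))
  tot <- comp$var_X + comp$var_U
  lam <- ifelse(!is.na(tot) & tot == 0, 1, comp$var_U / tot)
  lam[is.na(lam)] <- fallback_lambda
  lam <- pmin(pmax(lam, 0), 1)
  structure(list(lambda = lam, icc = 1 - lam, source = "estimated"),
            class = "lambda_map")
}

#' Shrinkage predictor: convex combination of raw and group-mean maps
#'
#' The best linear unbiased predictor of the true subject-level map under the
#' measurement-error model:
#' \deqn{\hat V^{SH}_{i2}(v) = \lambda(v)\, \hat V^{M}_{2}(v) +
#'   \{1 - \lambda(v)\}\, \hat V^{R}_{i2}(v),}
#' computed on the Fisher-Z scale and back-transformed to the correlation
#' scale with `tanh`. At every voxel the prediction lies between the raw and
#' group-mean values; `lambda = 0` reproduces [raw_estimator()] exactly and
#' `lambda = 1` reproduces [mean_estimator()] exactly.
#'
#' @inheritParams raw_estimator
#' @param lambda A [lambda_map()] defined on the same voxel set.
#' @return An `estimator_result` with `method = "shrinkage"`.
#' @examples
#' sim <- generate_fisher_panel(synth_config(10, n_voxels = 5, rng_seed = 4))
#' lam <- lambda_map(variance_components(sim$panel))
#' sh <- shrink(sim$panel, lam)
#' @export
shrink <- function(fisher, lambda) {
  stopifnot(inherits(lambda, "lambda_map"))
  raw <- raw_estimator(fisher)$fisher
  mn <- mean_estimator(fisher)$fisher
  if (length(lambda$lambda) != ncol(raw))
    stop("lambda map and panel voxel sets differ", call. = FALSE)
  lam <- matrix(lambda$lambda, nrow(raw), ncol(raw), byrow = TRUE)
  pred <- lam * mn + (1 - lam) * raw
  res <- new_estimator("shrinkage", pred)
  attr(res, "lambda_source") <- lambda$source
  res
}

new_estimator <- function(method, fisher_pred) {
  structure(list(method = method, fisher = fisher_pred,
                 correlation = tanh(fisher_pred)),
            class = "estimator_result")
}

#' @export
print.estimator_result <- function(x, ...) {
  cat(sprintf("%s predictor: %d subjects x %d voxels (Fisher + correlation scale)\n",
              x$method, nrow(x$fisher), ncol(x$fisher)))
  invisible(x)
}

session_slice <- function(fisher, j) {
  stopifnot(length(dim(fisher)) == 3L)
  d <- dim(fisher); dn <- dimnames(fisher)
  m <- matrix(fisher[, j, ], d[1], d[3])
  dimnames(m) <- list(subject = dn[[1]], voxel = dn[[3]])
  m
}
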