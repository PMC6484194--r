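#' Seed time course of one scan
#'
#' The seed signal of subject `i`, session `j` is the unweighted mean of the
#' time series over all ROI voxels (each voxel included, with no exclusion of
#' the target voxel), evaluated at every time point.
#'
#' @param panel A `ts_panel` array (I x J x V x T) as produced by
#'   [generate_timeseries_panel()] or [load_panel()].
#' @param i,j Subject and session index (integer position or dimname).
#' @return Numeric vector of length T.
#' @examples
#' sim <- generate_timeseries_panel(synth_config(3, n_voxels = 4,
#'                                               n_timepoints = 20,
#'                                               rng_seed = 1))
#' sc <- seed_timecourse(sim$panel, 1, 1)
#' @export
seed_timecourse <- function(panel, i, j) {
  stopifnot(length(dim(panel)) == 4L)
  colMeans(matrix(panel[i, j, , ], dim(panel)[3], dim(panel)[4]))
}

#' Seed-based correlation map of one scan
#'
#' For every ROI voxel, the Pearson correlation between the voxel's time
#' series and the seed time course of the same scan (centered sums over
#' time). The map does not depend on time. A voxel whose series has zero
#' variance — or a zero-variance seed — yields `NaN` at the affected voxels,
#' with a warning; such voxels are excluded from all downstream voxelwise
#' statistics.
#'
#' @inheritParams seed_timecourse
#' @return Numeric vector of length V with values in \[-1, 1\] or `NaN`.
#' @export
correlation_map <- function(panel, i, j) {
  stopifnot(length(dim(panel)) == 4L)
  T <- dim(panel)[4]
  if (T < 3L) stop("correlation requires T >= 3", call. = FALSE)
  y <- matrix(panel[i, j, , ], dim(panel)[3], T)
  s <- colMeans(y)
  if (stats::sd(s) == 0) {
    warning("zero-variance seed time course; all correlations NaN")
    return(rep(NaN, nrow(y)))
  }
  w <- suppressWarnings(as.vector(stats::cor(t(y), s)))
  if (anyNA(w)) {
    warning(sum(is.na(w)), " zero-variance voxel(s) set to NaN")
    w[is.na(w)] <- NaN
  }
  w
}

#' Fisher Z transform of a correlation
#'
#' `fisher_z()` maps a correlation to the variance-stabilized scale
#' \eqn{V = \tfrac12 \log\{(1+W)/(1-W)\} = \mathrm{artanh}(W)}; its inverse
#' [inverse_fisher_z()] is \eqn{W = \tanh(V)}. Inputs are clipped to
#' `|W| <= 1 - 1e-7` before transforming so the result stays finite;
#' `NaN` propagates.
#'
#' @param w Correlation value(s) in \[-1, 1\].
#' @return Fisher-Z value(s), finite for clipped input.
#' @examples
#' fisher_z(0.5)
#' inverse_fisher_z(fisher_z(0.5))
#' @export
fisher_z <- function(w) {
  bound <- 1 - 1e-7
  atanh(pmin(pmax(w, -bound), bound))
}

#' @rdname fisher_z
#' @param v Fisher-Z value(s).
#' @export
inverse_fisher_z <- function(v) tanh(v)

#' Compute the Fisher-Z connectivity panel of a time-series panel
#'
#' Runs [correlation_map()] for every subject-session scan and applies the
#' Fisher Z transform, giving the observed panel \eqn{V_{ij}(v)} on the
#' analysis scale.
#'
#' @inheritParams seed_timecourse
#' @param keep_correlation Also return the raw correlation panel.
#' @return A `fisher_panel` array (I x J x V); with
#'   `keep_correlation = TRUE`, a list with elements `fisher` and
#'   `correlation`.
#' @examples
#' sim <- generate_timeseries_panel(synth_config(3, n_voxels = 4,
#'                                               n_timepoints = 20,
#'                                               rng_seed = 1))
#' fp <- connectivity_panel(sim$panel)
#' @export
connectivity_panel <- function(panel, keep_correlation = FALSE) {
  stopifnot(length(dim(panel)) == 4L)
  d <- dim(panel)
  W <- array(NA_real_, d[1:3], dimnames = dimnames(panel)[1:3])
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    W[i, j, ] <- correlation_map(panel, i, j)
  V <- fisher_z(W)
  class(V) <- c("fisher_panel", class(V))
  if (keep_correlation) list(fisher = V, correlation = W) else V
}
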