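#' Configuration for the synthetic connectivity generators
#'
#' Bundles and validates the dimensions and variance parameters of the
#' measurement-error model used by [generate_fisher_panel()] and
#' [generate_timeseries_panel()]. The model places a true subject-level
#' Fisher-Z connectivity \eqn{X_i(v) \sim N(\mu_x(v), \sigma^2_x)} at every
#' voxel and adds an independent session-level error
#' \eqn{U_{ij}(v) \sim N(0, \sigma^2_u)}, so an observed single-session value
#' is \eqn{V_{ij}(v) = X_i(v) + U_{ij}(v)}.
#'
#' @param n_subjects Number of subjects I (>= 2).
#' @param n_sessions Number of scanning sessions J (>= 2).
#' @param n_voxels Number of ROI voxels V (>= 1).
#' @param n_timepoints Scan length T (>= 5); used by the time-series
#'   generator only.
#' @param mu_x Per-voxel mean true Fisher-Z connectivity; scalar (recycled)
#'   or a vector of length `n_voxels`.
#' @param sigma2_x Between-subject variance of the true connectivity
#'   (Fisher-Z^2 units), >= 0.
#' @param sigma2_u Measurement-error variance on the Fisher-Z scale
#'   (Fisher-Z^2 units), >= 0. For the time-series generator this is the
#'   session-effect variance, to which finite-length sampling variance of
#'   roughly 1/(T-3) adds.
#' @param ar1 Optional lag-1 autocorrelation of the seed and noise signals in
#'   the time-series generator; default 0 (white noise, which keeps the
#'   Fisher-Z sampling variance at its classical 1/(T-3) value).
#' @param rng_seed Integer master seed; the same config yields bit-identical
#'   output.
#'
#' @return An object of class `synth_config`.
#' @examples
#' cfg <- synth_config(n_subjects = 10, n_voxels = 50, rng_seed = 1)
#' @export
synth_config <- function(n_subjects, n_sessions = 2L, n_voxels,
                         n_timepoints = 74L, mu_x = 0, sigma2_x = 0.04,
                         sigma2_u = 0.01, ar1 = 0, rng_seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  n_sessions <- as.integer(n_sessions)
  n_voxels <- as.integer(n_voxels)
  n_timepoints <- as.integer(n_timepoints)
  if (is.na(n_subjects) || n_subjects < 2L)
    stop("configuration error: n_subjects must be >= 2", call. = FALSE)
  if (is.na(n_sessions) || n_sessions < 2L)
    stop("configuration error: n_sessions must be >= 2", call. = FALSE)
  if (is.na(n_voxels) || n_voxels < 1L)
    stop("configuration error: n_voxels must be >= 1", call. = FALSE)
  if (is.na(n_timepoints) || n_timepoints < 5L)
    stop("configuration error: n_timepoints must be >= 5", call. = FALSE)
  if (!is.numeric(sigma2_x) || length(sigma2_x) != 1L || sigma2_x < 0)
    stop("configuration error: sigma2_x must be a scalar >= 0", call. = FALSE)
  if (!is.numeric(sigma2_u) || length(sigma2_u) != 1L || sigma2_u < 0)
    stop("configuration error: sigma2_u must be a scalar >= 0", call. = FALSE)
  if (!is.numeric(ar1) || length(ar1) != 1L || abs(ar1) >= 1)
    stop("configuration error: ar1 must lie in (-1, 1)", call. = FALSE)
  if (!length(mu_x) %in% c(1L, n_voxels))
    stop("configuration error: mu_x must be scalar or length n_voxels",
         call. = FALSE)
  mu_x <- rep_len(as.numeric(mu_x), n_voxels)
  rng_seed <- as.integer(rng_seed)
  if (is.na(rng_seed)) stop("configuration error: rng_seed must be an integer",
                            call. = FALSE)
  structure(list(n_subjects = n_subjects, n_sessions = n_sessions,
                 n_voxels = n_voxels, n_timepoints = n_timepoints,
                 mu_x = mu_x, sigma2_x = sigma2_x, sigma2_u = sigma2_u,
                 ar1 = ar1, rng_seed = rng_seed),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synthetic connectivity config:",
      sprintf("I=%d subjects, J=%d sessions, V=%d voxels, T=%d time points",
              x$n_subjects, x$n_sessions, x$n_voxels, x$n_timepoints), "\n")
  cat(sprintf("  sigma2_x=%g, sigma2_u=%g, ar1=%g, seed=%d\n",
              x$sigma2_x, x$sigma2_u, x$ar1, x$rng_seed))
  invisible(x)
}

# Deterministic substream seed for unit (i, j): mixes the master seed with the
# cell index so panels are reproducible regardless of generation order.
# Kept strictly below 2^31 - 1.
substream_seed <- function(master, i, j = 0L) {
  h <- (as.double(master) %% 2147483647) * 48271 + i * 69621 + j * 16807 + 1
  as.integer(h %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a Fisher-Z connectivity panel under the measurement-error model
#'
#' Draws \eqn{X_i(v) \sim N(\mu_x(v), \sigma^2_x)} once per subject and
#' \eqn{U_{ij}(v) \sim N(0, \sigma^2_u)} per subject-session, all mutually
#' independent, and returns the observed panel \eqn{V_{ij}(v) = X_i(v) +
#' U_{ij}(v)} together with the ground truth. This generates data directly on
#' the analysis (Fisher-Z) scale; see [generate_timeseries_panel()] for the
#' version that routes through voxel time series and finite-length
#' correlation estimates.
#'
#' @param config A [synth_config()] object.
#' @return A list with components `panel`, a `fisher_panel` (numeric array
#'   I x J x V with dimnames subject/session/voxel), and `truth`, a
#'   `ground_truth` list carrying the matrix `X` (I x V) and the model-implied
#'   constant shrinkage weight `lambda_true`.
#' @examples
#' sim <- generate_fisher_panel(synth_config(5, n_voxels = 3, rng_seed = 7))
#' dim(sim$panel)
#' @export
generate_fisher_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  I <- config$n_subjects; J <- config$n_sessions; V <- config$n_voxels
  X <- with_seed(substream_seed(config$rng_seed, 0L), {
    matrix(rep(config$mu_x, each = I) +
             stats::rnorm(I * V, sd = sqrt(config$sigma2_x)), I, V)
  })
  panel <- array(NA_real_, c(I, J, V),
                 dimnames = panel_dimnames(I, J, V))
  for (i in seq_len(I)) for (j in seq_len(J)) {
    U <- with_seed(substream_seed(config$rng_seed, i, j),
                   stats::rnorm(V, sd = sqrt(config$sigma2_u)))
    panel[i, j, ] <- X[i, ] + U
  }
  class(panel) <- c("fisher_panel", class(panel))
  truth <- structure(list(X = X,
                          lambda_true = lambda_from_variances(
                            config$sigma2_x, config$sigma2_u)),
                     class = "ground_truth")
  list(panel = panel, truth = truth)
}

panel_dimnames <- function(I, J, V) {
  list(subject = sprintf("sub%02d", seq_len(I)),
       session = as.character(seq_len(J)),
       voxel = sprintf("v%04d", seq_len(V)))
}

lambda_from_variances <- function(sigma2_x, sigma2_u) {
  if (sigma2_x == 0 && sigma2_u == 0) return(1)
  min(max(sigma2_u / (sigma2_x + sigma2_u), 0), 1)
}

# AR(1) series with standard-normal marginals (variance 1); phi = 0 gives
# plain white noise.
ar1_series <- function(T, phi) {
  z <- stats::rnorm(T)
  if (phi == 0) return(z)
  x <- numeric(T)
  x[1] <- z[1]
  s <- sqrt(1 - phi^2)
  for (t in 2:T) x[t] <- phi * x[t - 1] + s * z[t]
  x
}

#' Simulate voxel time series with known connectivity ground truth
#'
#' Emulates a scan-rescan resting-state design at the signal level so the
#' whole pipeline (seed time course, correlation map, Fisher transform,
#' variance components) can be exercised end to end. For each subject i and
#' session j a latent standard-normal seed signal \eqn{s(t)} is drawn, and
#' each voxel's series is \eqn{y(v,t) = \rho\, s(t) + \sqrt{1-\rho^2}\,
#' \epsilon(v,t)} with white standard-normal \eqn{\epsilon}, where the
#' session-level true correlation is \eqn{\rho_{ij}(v) = \tanh(X_i(v) +
#' B_{ij}(v))} and \eqn{B_{ij}(v) \sim N(0, \sigma^2_u)} is a session effect
#' added on the Fisher-Z scale (so the measurement-error model stays exactly
#' additive on the analysis scale). The effective measurement-error variance
#' on the Fisher scale is approximately `sigma2_u + 1/(T-3)` because
#' finite-length correlation estimates add classical Fisher-Z sampling noise.
#' True correlations are clipped to |rho| <= 0.999 before signal synthesis.
#'
#' @param config A [synth_config()] object; `sigma2_u` plays the role of the
#'   session-effect variance.
#' @return A list with `panel`, a `ts_panel` (numeric array I x J x V x T),
#'   and `truth`, a `ground_truth` list with `X` (I x V), `rho`
#'   (I x J x V, the session-level true correlations), `seed_signal`
#'   (I x J x T, the latent seed signals), and `lambda_true` computed with
#'   the effective error variance.
#' @examples
#' sim <- generate_timeseries_panel(synth_config(3, n_voxels = 4,
#'                                               n_timepoints = 20,
#'                                               rng_seed = 2))
#' dim(sim$panel)
#' @export
generate_timeseries_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  I <- config$n_subjects; J <- config$n_sessions
  V <- config$n_voxels; T <- config$n_timepoints
  X <- with_seed(substream_seed(config$rng_seed, 0L), {
    matrix(rep(config$mu_x, each = I) +
             stats::rnorm(I * V, sd = sqrt(config$sigma2_x)), I, V)
  })
  panel <- array(NA_real_, c(I, J, V, T),
                 dimnames = c(panel_dimnames(I, J, V),
                              list(time = NULL)))
  rho <- array(NA_real_, c(I, J, V), dimnames = panel_dimnames(I, J, V))
  seed_sig <- array(NA_real_, c(I, J, T))
  for (i in seq_len(I)) for (j in seq_len(J)) {
    cell <- with_seed(substream_seed(config$rng_seed, i, j), {
      B <- stats::rnorm(V, sd = sqrt(config$sigma2_u))
      r <- tanh(X[i, ] + B)
      r <- pmin(pmax(r, -0.999), 0.999)
      s <- ar1_series(T, config$ar1)
      if (config$ar1 == 0) {
        eps <- matrix(stats::rnorm(V * T), V, T)
      } else {
        eps <- matrix(0, V, T)
        for (k in seq_len(V)) eps[k, ] <- ar1_series(T, config$ar1)
      }
      y <- r %o% s + sqrt(1 - r^2) * eps
      list(r = r, s = s, y = y)
    })
    rho[i, j, ] <- cell$r
    seed_sig[i, j, ] <- cell$s
    panel[i, j, , ] <- cell$y
  }
  class(panel) <- c("ts_panel", class(panel))
  sigma2_u_eff <- config$sigma2_u + 1 / (T - 3)
  truth <- structure(list(X = X, rho = rho, seed_signal = seed_sig,
                          lambda_true = lambda_from_variances(
                            config$sigma2_x, sigma2_u_eff)),
                     class = "ground_truth")
  list(panel = panel, truth = truth)
}

#' Model-implied shrinkage weight of a synthetic configuration
#'
#' Returns the constant voxelwise shrinkage weight implied by the generative
#' variances: `lambda = sigma2_u_eff / (sigma2_x + sigma2_u_eff)`, the weight
#' placed on the group-mean map (equal to 1 - ICC). For the time-series
#' generator the effective error variance includes the Fisher-Z sampling
#' variance `1/(T-3)` of a finite-length correlation estimate. When both
#' variances are zero the weight is 1 by convention (the raw map carries no
#' information beyond the common mean).
#'
#' @param config A [synth_config()] object.
#' @param mode `"fisher"` for the model-level generator, `"timeseries"` to
#'   include the finite-T sampling variance.
#' @return A numeric vector of length `n_voxels` (a constant map) with values
#'   in \[0, 1\].
#' @examples
#' true_lambda(synth_config(5, n_voxels = 2, sigma2_x = 0.04, sigma2_u = 0.01))
#' @export
true_lambda <- function(config, mode = c("fisher", "timeseries")) {
  stopifnot(inherits(config, "synth_config"))
  mode <- match.arg(mode)
  s2u <- config$sigma2_u
  if (mode == "timeseries") s2u <- s2u + 1 / (config$n_timepoints - 3)
  rep(lambda_from_variances(config$sigma2_x, s2u), config$n_voxels)
}

#' Read a synthetic configuration from a flat key-value file
#'
#' Parses a plain-text file with one `key = value` (or `key<TAB>value`) pair
#' per line, keys named exactly as the [synth_config()] arguments; `#` starts
#' a comment. Unknown keys are an error.
#'
#' @param path Path to the config file.
#' @return A `synth_config` object.
#' @export
read_synth_config <- function(path) {
  kv <- read_keyvalue(path)
  allowed <- names(formals(synth_config))
  bad <- setdiff(names(kv), allowed)
  if (length(bad))
    stop("configuration error: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  kv <- lapply(kv, function(x) {
    v <- suppressWarnings(as.numeric(strsplit(x, "[,[:space:]]+")[[1]]))
    if (anyNA(v)) stop("configuration error: non-numeric value in config",
                       call. = FALSE)
    v
  })
  do.call(synth_config, kv)
}

read_keyvalue <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)[[:space:]]*[=\t][[:space:]]*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("configuration error: cannot parse line: ", ln, call. = FALSE)
    kv[[m[2]]] <- trimws(m[3])
  }
  kv
}
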