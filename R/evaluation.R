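#' Per-subject mean squared prediction error
#'
#' Scores a predictor against the observed second-session maps: for each
#' subject, the average of the squared voxelwise differences over the voxels
#' that are non-`NaN` in both prediction and observation,
#' \eqn{MSE_i = |S^*|^{-1} \sum_{v \in S^*} (\hat W_{i2}(v) - W_{i2}(v))^2.}
#' The comparison is made on the Fisher-Z scale or the correlation scale; on
#' the correlation scale the Fisher-scale quantities are `tanh`-transformed
#' first.
#'
#' @param pred An `estimator_result` (from [raw_estimator()],
#'   [mean_estimator()] or [shrink()]).
#' @param observed I x V matrix of observed second-session maps on the
#'   Fisher-Z scale (e.g. `session_2_maps(fisher)`), or a `fisher_panel`
#'   from which session 2 is taken.
#' @param scale `"fisher"` (default) or `"correlation"`.
#' @return Named numeric vector of per-subject MSEs (all >= 0).
#' @examples
#' sim <- generate_fisher_panel(synth_config(6, n_voxels = 20, rng_seed = 5))
#' mse_per_subject(raw_estimator(sim$panel), sim$panel)
#' @export
mse_per_subject <- function(pred, observed, scale = c("fisher", "correlation")) {
  scale <- match.arg(scale)
  stopifnot(inherits(pred, "estimator_result"))
  if (length(dim(observed)) == 3L) observed <- session_slice(observed, 2L)
  p <- pred$fisher
  if (!all(dim(p) == dim(observed)))
    stop("prediction and observation must share subjects and voxels",
         call. = FALSE)
  if (scale == "correlation") {
    p <- tanh(p); observed <- tanh(observed)
  }
  se <- (p - observed)^2
  n_ok <- rowSums(!is.na(se))
  if (any(n_ok == 0L))
    stop("no jointly non-NaN voxels for subject(s): ",
         paste(which(n_ok == 0L), collapse = ", "), call. = FALSE)
  rowMeans(se, na.rm = TRUE)
}

#' Percent reduction in MSE relative to the raw predictor
#'
#' `100 * (mse_raw - mse_other) / mse_raw`; positive values mean the other
#' predictor improves on the raw one. Undefined (`NA`) when `mse_raw` is 0.
#' Internal arithmetic is unrounded; round only at report time.
#'
#' @param mse_raw,mse_other Non-negative MSE values (vectorized).
#' @return Percent reduction(s).
#' @examples
#' percent_reduction(0.2, 0.1)
#' @export
percent_reduction <- function(mse_raw, mse_other) {
  ifelse(mse_raw > 0, 100 * (mse_raw - mse_other) / mse_raw, NA_real_)
}

#' Per-subject evaluation table for the three predictors
#'
#' Convenience wrapper producing the standard report: one row per subject
#' with the raw, mean, and shrinkage MSEs and the percent reductions of the
#' latter two relative to raw.
#'
#' @param fisher A two-session `fisher_panel`.
#' @param lambda A [lambda_map()]; default estimates it from the panel's
#'   variance components.
#' @param scale MSE scale, `"fisher"` (default) or `"correlation"`.
#' @return A data.frame with columns `subject`, `mse_raw`, `mse_mean`,
#'   `red_mean_pct`, `mse_shrinkage`, `red_shrink_pct`.
#' @examples
#' sim <- generate_fisher_panel(synth_config(8, n_voxels = 50, rng_seed = 6))
#' evaluation_table(sim$panel)
#' @export
evaluation_table <- function(fisher, lambda = NULL,
                             scale = c("fisher", "correlation")) {
  scale <- match.arg(scale)
  if (is.null(lambda)) lambda <- lambda_map(variance_components(fisher))
  obs <- session_slice(fisher, 2L)
  mse_r <- mse_per_subject(raw_estimator(fisher), obs, scale)
  mse_m <- mse_per_subject(mean_estimator(fisher), obs, scale)
  mse_s <- mse_per_subject(shrink(fisher, lambda), obs, scale)
  data.frame(subject = names(mse_r) %||% seq_along(mse_r),
             mse_raw = unname(mse_r),
             mse_mean = unname(mse_m),
             red_mean_pct = unname(percent_reduction(mse_r, mse_m)),
             mse_shrinkage = unname(mse_s),
             red_shrink_pct = unname(percent_reduction(mse_r, mse_s)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summary block of an evaluation table
#'
#' Per-method mean, median, min, and max of the per-subject MSEs, percent
#' reductions recomputed from the average MSEs, and Tukey boxplot outliers.
#' The median of an even count is the midpoint of the two central values.
#' Quartiles follow the boxplot convention of medians of the lower and upper
#' halves of the sorted data, excluding the overall median itself when the
#' count is odd; outliers are values outside
#' \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\].
#'
#' @param table A data.frame as returned by [evaluation_table()] (columns
#'   `subject`, `mse_raw`, `mse_mean`, `mse_shrinkage`).
#' @return A list with `summary`, a data.frame (rows raw/mean/shrinkage;
#'   columns method, mean, median, min, max, n_outliers), `reductions`, the
#'   mean/shrinkage percent reductions recomputed from the average MSEs, and
#'   `outliers`, a per-method list of the outlying subjects and values.
#' @examples
#' sim <- generate_fisher_panel(synth_config(8, n_voxels = 50, rng_seed = 6))
#' summarize_evaluation(evaluation_table(sim$panel))
#' @export
summarize_evaluation <- function(table) {
  stopifnot(nrow(table) >= 1L,
            all(c("mse_raw", "mse_mean", "mse_shrinkage") %in% names(table)))
  methods <- c(raw = "mse_raw", mean = "mse_mean", shrinkage = "mse_shrinkage")
  rows <- lapply(names(methods), function(m) {
    x <- table[[methods[[m]]]]
    out <- tukey_outliers(x)
    data.frame(method = m, mean = mean(x), median = stats::median(x),
               min = min(x), max = max(x), n_outliers = length(out$index),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  outliers <- lapply(methods, function(col) {
    out <- tukey_outliers(table[[col]])
    data.frame(subject = table$subject[out$index], value = out$value,
               stringsAsFactors = FALSE)
  })
  avg <- summary$mean
  reductions <- c(mean = percent_reduction(avg[1], avg[2]),
                  shrinkage = percent_reduction(avg[1], avg[3]))
  list(summary = summary, reductions = reductions, outliers = outliers)
}

#' Tukey boxplot outliers
#'
#' Values outside \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\], with the quartiles taken
#' as the medians of the lower and upper halves of the sorted sample (the
#' overall median excluded from both halves when n is odd).
#'
#' @param x Numeric vector, length >= 1.
#' @return List with `index` (positions of outliers in `x`), `value`,
#'   `q1`, `q3`, `lower`, `upper` (the fences).
#' @export
tukey_outliers <- function(x) {
  n <- length(x)
  s <- sort(x)
  if (n < 2L) {
    q1 <- q3 <- s[1] %||% NA_real_
  } else {
    half <- floor(n / 2)
    q1 <- stats::median(s[seq_len(half)])
    q3 <- stats::median(s[seq.int(n - half + 1L, n)])
  }
  iqr <- q3 - q1
  lower <- q1 - 1.5 * iqr
  upper <- q3 + 1.5 * iqr
  idx <- which(x < lower | x > upper)
  list(index = idx, value = x[idx], q1 = q1, q3 = q3,
       lower = lower, upper = upper)
}
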