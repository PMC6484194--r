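#' Read a pipeline run configuration from a flat key-value file
#'
#' Plain-text `key = value` lines (`#` comments allowed). Recognized keys:
#' `mode` (simulate | fit | evaluate | run-all), `out_dir`, `manifest`,
#' `mask`, `fit_dir`, `lambda_mode` (estimate | fixed), `fixed_lambda`,
#' `scale` (fisher | correlation), `seed`, `write_nifti` (0/1), and the
#' synthetic-generator block as `synth_`-prefixed [synth_config()] fields
#' (e.g. `synth_n_subjects`). Unrecognized keys are an error.
#'
#' @param path Path to the config file.
#' @return A named list usable as the `config` argument of [run_pipeline()].
#' @export
read_run_config <- function(path) {
  kv <- read_keyvalue(path)
  known <- c("mode", "out_dir", "manifest", "mask", "fit_dir", "lambda_mode",
             "fixed_lambda", "scale", "seed", "write_nifti")
  synth_keys <- paste0("synth_", names(formals(synth_config)))
  bad <- setdiff(names(kv), c(known, synth_keys))
  if (length(bad))
    stop("configuration error: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  num_keys <- c("fixed_lambda", "seed", "write_nifti", synth_keys)
  for (k in intersect(names(kv), num_keys)) {
    v <- suppressWarnings(as.numeric(strsplit(kv[[k]], "[,[:space:]]+")[[1]]))
    if (anyNA(v))
      stop("configuration error: non-numeric value for ", k, call. = FALSE)
    kv[[k]] <- v
  }
  kv
}

resolve_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  stopifnot(is.list(config))
  config$mode <- match.arg(config$mode %||% "run-all",
                           c("simulate", "fit", "evaluate", "run-all"))
  config$lambda_mode <- match.arg(config$lambda_mode %||% "estimate",
                                  c("estimate", "fixed"))
  config$fixed_lambda <- config$fixed_lambda %||% 0.1
  config$scale <- match.arg(config$scale %||% "fisher",
                            c("fisher", "correlation"))
  config$seed <- as.integer(config$seed %||% 1L)
  config$write_nifti <- as.logical(config$write_nifti %||% TRUE)
  if (is.null(config$out_dir))
    stop("configuration error: out_dir is required", call. = FALSE)
  config
}

synth_config_from_run <- function(config) {
  keys <- names(config)[startsWith(names(config), "synth_")]
  if (!length(keys))
    stop("simulate stage: no synth_* keys in config", call. = FALSE)
  args <- config[keys]
  names(args) <- sub("^synth_", "", names(args))
  if (is.null(args$rng_seed)) args$rng_seed <- config$seed
  do.call(synth_config, args)
}

write_resolved_config <- function(config, dir) {
  keys <- sort(names(config))
  lines <- vapply(keys, function(k)
    paste0(k, " = ", paste(format(config[[k]], digits = 15), collapse = " ")),
    character(1))
  writeLines(lines, file.path(dir, "config_resolved.txt"))
}

log_line <- function(log_path, stage, msg) {
  cat(sprintf("[%s] %s\n", stage, msg), file = log_path, append = TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the simulate / fit / evaluate pipeline
#'
#' One entry point wiring the stages into a reproducible run. `simulate`
#' writes a synthetic scan-rescan dataset (4-D NIfTI per scan, mask,
#' manifest, ground truth) from the `synth_*` config block; `fit` loads a
#' manifest + mask, computes seed-based correlation and Fisher-Z maps,
#' variance components, the shrinkage weight map, and the raw / mean /
#' shrinkage predictions; `evaluate` scores the fit-stage predictions
#' against the observed session-2 maps and writes the per-subject MSE table
#' and summary; `run-all` chains the three on one master seed. Every
#' stochastic step derives from that seed, so a repeated run reproduces the
#' tabular outputs byte for byte. The resolved configuration and a log with
#' per-stage record counts are written into the output directory.
#'
#' @param config A named list or the path to a flat key-value config file
#'   (see [read_run_config()] for the keys).
#' @return The output directory path, invisibly.
#' @examples
#' \donttest{
#' out <- file.path(tempdir(), "demo_run")
#' run_pipeline(list(mode = "run-all", out_dir = out, seed = 7,
#'                   synth_n_subjects = 6, synth_n_voxels = 30,
#'                   synth_n_timepoints = 30, write_nifti = FALSE))
#' read.delim(file.path(out, "evaluate", "mse_table.tsv"))
#' }
#' @export
run_pipeline <- function(config) {
  config <- resolve_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  if (file.exists(log_path)) unlink(log_path)
  write_resolved_config(config, config$out_dir)
  switch(config$mode,
    "simulate" = stage_simulate(config, config$out_dir, log_path),
    "fit" = stage_fit(config, config$manifest, config$mask,
                      config$out_dir, log_path),
    "evaluate" = stage_evaluate(config, config$fit_dir, config$out_dir,
                                log_path),
    "run-all" = {
      sim_dir <- file.path(config$out_dir, "simulate")
      fit_dir <- file.path(config$out_dir, "fit")
      eval_dir <- file.path(config$out_dir, "evaluate")
      stage_simulate(config, sim_dir, log_path)
      stage_fit(config, file.path(sim_dir, "manifest.tsv"),
                file.path(sim_dir, "mask.nii.gz"), fit_dir, log_path)
      stage_evaluate(config, fit_dir, eval_dir, log_path)
    })
  invisible(config$out_dir)
}

stage_simulate <- function(config, out_dir, log_path) {
  scfg <- tryCatch(synth_config_from_run(config), error = function(e)
    stop("simulate stage: ", conditionMessage(e), call. = FALSE))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_timeseries_panel(scfg)
  manifest <- export_panel_nifti(sim$panel, out_dir)
  d <- dim(sim$panel)
  truth <- data.frame(
    subject = rep(dimnames(sim$panel)[[1]], times = d[3]),
    voxel = rep(seq_len(d[3]), each = d[1]),
    X = as.vector(sim$truth$X),
    stringsAsFactors = FALSE)
  write_tsv(truth, file.path(out_dir, "ground_truth.tsv"))
  log_line(log_path, "simulate",
           sprintf("subjects=%d sessions=%d voxels=%d timepoints=%d lambda_true=%.6f",
                   d[1], d[2], d[3], d[4], sim$truth$lambda_true))
  invisible(manifest)
}

stage_fit <- function(config, manifest, mask_path, out_dir, log_path) {
  if (is.null(manifest) || !file.exists(manifest))
    stop("fit stage: manifest not found: ", manifest %||% "<missing>",
         call. = FALSE)
  if (is.null(mask_path) || !file.exists(mask_path))
    stop("fit stage: mask not found: ", mask_path %||% "<missing>",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mask <- load_mask(mask_path)
  panel <- load_panel(manifest, mask)
  maps <- connectivity_panel(panel, keep_correlation = TRUE)
  fisher <- maps$fisher
  d <- dim(fisher)
  n_nan <- sum(is.na(fisher))
  comp <- variance_components(fisher)
  lam <- if (config$lambda_mode == "fixed") {
    lambda_map(comp, fixed_lambda = config$fixed_lambda)
  } else lambda_map(comp)
  preds <- list(raw = raw_estimator(fisher),
                mean = mean_estimator(fisher),
                shrinkage = shrink(fisher, lam))

  subjects <- dimnames(fisher)[[1]]
  sessions <- dimnames(fisher)[[2]]
  grid <- expand.grid(voxel = seq_len(d[3]), session = sessions,
                      subject = subjects, stringsAsFactors = FALSE)
  fp <- data.frame(subject = grid$subject, session = grid$session,
                   voxel = grid$voxel,
                   fisher = as.vector(aperm(fisher, c(3, 2, 1))),
                   correlation = as.vector(aperm(maps$correlation, c(3, 2, 1))),
                   stringsAsFactors = FALSE)
  write_tsv(fp, file.path(out_dir, "fisher_panel.tsv"))

  vs <- data.frame(voxel = seq_len(d[3]),
                   x = mask$coords[, 1] - 1L, y = mask$coords[, 2] - 1L,
                   z = mask$coords[, 3] - 1L,
                   var_U = comp$var_U, var_V = comp$var_V, var_X = comp$var_X,
                   D_bar = comp$D_bar, clamped = as.integer(comp$clamped),
                   n_effective = comp$n_effective,
                   lambda = lam$lambda, icc = lam$icc,
                   stringsAsFactors = FALSE)
  write_tsv(vs, file.path(out_dir, "voxel_stats.tsv"))

  pr <- do.call(rbind, lapply(names(preds), function(m) {
    p <- preds[[m]]
    g <- expand.grid(voxel = seq_len(d[3]), subject = subjects,
                     stringsAsFactors = FALSE)
    data.frame(method = m, subject = g$subject, voxel = g$voxel,
               fisher = as.vector(t(p$fisher)),
               correlation = as.vector(t(p$correlation)),
               stringsAsFactors = FALSE)
  }))
  write_tsv(pr, file.path(out_dir, "predictions.tsv"))

  if (isTRUE(config$write_nifti)) {
    map_dir <- file.path(out_dir, "maps")
    dir.create(map_dir, showWarnings = FALSE)
    write_map(lam$lambda, mask, file.path(map_dir, "lambda.nii.gz"))
    write_map(lam$icc, mask, file.path(map_dir, "icc.nii.gz"))
    scale_field <- if (config$scale == "fisher") "fisher" else "correlation"
    for (m in names(preds)) for (i in seq_along(subjects)) {
      write_map(preds[[m]][[scale_field]][i, ], mask,
                file.path(map_dir, sprintf("pred_%s_%s.nii.gz",
                                           m, subjects[i])))
    }
  }
  log_line(log_path, "fit",
           sprintf("subjects=%d sessions=%d voxels=%d nan_fisher=%d lambda_mode=%s lambda_mean=%.6f",
                   d[1], d[2], d[3], n_nan, lam$source, mean(lam$lambda)))
  invisible(out_dir)
}

stage_evaluate <- function(config, fit_dir, out_dir, log_path) {
  if (is.null(fit_dir) || !file.exists(file.path(fit_dir, "predictions.tsv")))
    stop("evaluate stage: fit outputs not found in ", fit_dir %||% "<missing>",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- utils::read.delim(file.path(fit_dir, "fisher_panel.tsv"),
                          colClasses = c(subject = "character",
                                         session = "character"))
  pr <- utils::read.delim(file.path(fit_dir, "predictions.tsv"),
                          colClasses = c(subject = "character"))
  subjects <- unique(fp$subject)
  voxels <- sort(unique(fp$voxel))
  obs2 <- fp[fp$session == sort(unique(fp$session))[2], ]
  obs <- matrix(NA_real_, length(subjects), length(voxels),
                dimnames = list(subject = subjects, voxel = NULL))
  obs[cbind(match(obs2$subject, subjects), match(obs2$voxel, voxels))] <-
    obs2$fisher
  mse <- list()
  for (m in c("raw", "mean", "shrinkage")) {
    pm <- pr[pr$method == m, ]
    pmat <- matrix(NA_real_, length(subjects), length(voxels),
                   dimnames = list(subject = subjects, voxel = NULL))
    pmat[cbind(match(pm$subject, subjects), match(pm$voxel, voxels))] <-
      pm$fisher
    est <- new_estimator(m, pmat)
    mse[[m]] <- mse_per_subject(est, obs, scale = config$scale)
  }
  table <- data.frame(subject = subjects,
                      mse_raw = unname(mse$raw),
                      mse_mean = unname(mse$mean),
                      red_mean_pct = unname(percent_reduction(mse$raw, mse$mean)),
                      mse_shrinkage = unname(mse$shrinkage),
                      red_shrink_pct = unname(percent_reduction(mse$raw, mse$shrinkage)),
                      stringsAsFactors = FALSE)
  summ <- summarize_evaluation(table)
  avg <- data.frame(subject = "Average",
                    mse_raw = mean(table$mse_raw),
                    mse_mean = mean(table$mse_mean),
                    red_mean_pct = summ$reductions[["mean"]],
                    mse_shrinkage = mean(table$mse_shrinkage),
                    red_shrink_pct = summ$reductions[["shrinkage"]],
                    stringsAsFactors = FALSE)
  full <- rbind(table, avg)
  disp <- data.frame(mse_raw_display = sprintf("%.4f", full$mse_raw),
                     mse_mean_display = sprintf("%.4f", full$mse_mean),
                     red_mean_pct_display = sprintf("%.2f", full$red_mean_pct),
                     mse_shrinkage_display = sprintf("%.4f", full$mse_shrinkage),
                     red_shrink_pct_display = sprintf("%.2f", full$red_shrink_pct),
                     stringsAsFactors = FALSE)
  write_tsv(cbind(full, disp), file.path(out_dir, "mse_table.tsv"))
  out_rows <- vapply(summ$outliers, function(o)
    paste(o$subject, collapse = ","), character(1))
  summary_df <- cbind(summ$summary,
                      outlier_subjects = unname(out_rows[summ$summary$method]))
  write_tsv(summary_df, file.path(out_dir, "summary.tsv"))
  log_line(log_path, "evaluate",
           sprintf("subjects=%d voxels=%d scale=%s mse_raw=%.6f mse_mean=%.6f mse_shrinkage=%.6f",
                   length(subjects), length(voxels), config$scale,
                   avg$mse_raw, avg$mse_mean, avg$mse_shrinkage))
  invisible(out_dir)
}
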