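#' Load an ROI mask from a 3-D NIfTI volume
#'
#' Voxels with value strictly greater than 0.5 form the ROI; the threshold
#' accommodates both binary masks and probabilistic/atlas-resampled masks
#' with fractional values. The voxel enumeration is fixed ascending by x,
#' then y, then z, and is used identically by every operation in a run.
#' World/affine coordinates are carried through headers but never used in
#' computation.
#'
#' @param path Path to a 3-D NIfTI (.nii / .nii.gz) volume.
#' @return An `roi_mask`: list with `dim` (grid dimensions), `coords`
#'   (|S| x 3 integer matrix of 1-based voxel indices in enumeration order),
#'   `n` = |S|, and `linear` (column-major linear indices into the grid).
#' @export
load_mask <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("mask must be a 3-D volume, got ", length(d), "-D: ", path,
         call. = FALSE)
  arr <- as.array(img)
  sel <- which(arr > 0.5, arr.ind = TRUE)
  if (nrow(sel) == 0L) stop("empty mask: ", path, call. = FALSE)
  sel <- sel[order(sel[, 1], sel[, 2], sel[, 3]), , drop = FALSE]
  dimnames(sel) <- list(NULL, c("x", "y", "z"))
  structure(list(dim = d, coords = sel, n = nrow(sel),
                 linear = as.integer((sel[, 3] - 1) * d[1] * d[2] +
                                     (sel[, 2] - 1) * d[1] + sel[, 1]),
                 reference = path),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI mask: %d voxels on a %s grid\n", x$n,
              paste(x$dim, collapse = " x ")))
  invisible(x)
}

#' Load a subject-session panel of voxel time series from a manifest
#'
#' Reads a TSV manifest with header columns `subject_id`, `session`, `path`,
#' each path a 4-D NIfTI on the mask's grid, and assembles the masked time
#' series into an I x J x V x T array. Subjects are ordered by first
#' appearance in the manifest; sessions are sorted; the voxel axis follows
#' the mask enumeration. All scans must share the grid and number of time
#' points, and every subject must have the same set of sessions.
#'
#' @param manifest_path Path to the TSV manifest.
#' @param mask An [load_mask()] result.
#' @return A `ts_panel` array (I x J x V x T) with subject/session dimnames.
#' @export
load_panel <- function(manifest_path, mask) {
  stopifnot(inherits(mask, "roi_mask"))
  man <- utils::read.delim(manifest_path, colClasses = "character")
  req <- c("subject_id", "session", "path")
  if (!all(req %in% names(man)))
    stop("manifest must have columns subject_id, session, path", call. = FALSE)
  subjects <- unique(man$subject_id)
  sessions <- sort(unique(man$session))
  for (s in subjects) {
    have <- sort(man$session[man$subject_id == s])
    if (!identical(have, sessions))
      stop("incomplete sessions for subject ", s, call. = FALSE)
  }
  base <- dirname(manifest_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  T <- NA_integer_
  panel <- NULL
  for (ii in seq_along(subjects)) for (jj in seq_along(sessions)) {
    row <- man[man$subject_id == subjects[ii] & man$session == sessions[jj], ]
    f <- resolve(row$path[1])
    img <- RNifti::readNifti(f)
    d <- dim(img)
    if (length(d) != 4L)
      stop("expected 4-D volume: ", f, call. = FALSE)
    if (!identical(as.integer(d[1:3]), as.integer(mask$dim)))
      stop("grid mismatch with mask: ", f, call. = FALSE)
    if (is.na(T)) {
      T <- d[4]
      panel <- array(NA_real_, c(length(subjects), length(sessions), mask$n, T),
                     dimnames = list(subject = subjects, session = sessions,
                                     voxel = NULL, time = NULL))
    } else if (d[4] != T) {
      stop("unequal number of time points: ", f, call. = FALSE)
    }
    vol <- matrix(as.array(img), prod(d[1:3]), d[4])
    vals <- vol[mask$linear, , drop = FALSE]
    if (!all(is.finite(vals)))
      stop("non-finite values in ", f, call. = FALSE)
    panel[ii, jj, , ] <- vals
  }
  class(panel) <- c("ts_panel", class(panel))
  panel
}

#' Write a voxelwise map as a 3-D NIfTI volume
#'
#' Places one value per mask voxel on the mask's grid; voxels outside the
#' mask are written as `NaN` (not 0) so genuine zero correlations remain
#' distinguishable from background. Header geometry is copied from a
#' reference volume when given.
#'
#' @param values Numeric vector of length `mask$n`, in mask enumeration
#'   order.
#' @param mask An [load_mask()] result.
#' @param out_path Output path (.nii or .nii.gz).
#' @param reference_path Optional NIfTI whose header geometry is copied;
#'   defaults to the file the mask was loaded from, when available.
#' @return `out_path`, invisibly.
#' @export
write_map <- function(values, mask, out_path, reference_path = NULL) {
  stopifnot(inherits(mask, "roi_mask"))
  if (length(values) != mask$n)
    stop("expected ", mask$n, " values, got ", length(values), call. = FALSE)
  vol <- array(NaN, mask$dim)
  vol[mask$linear] <- as.numeric(values)
  ref <- reference_path %||% mask$reference
  img <- if (!is.null(ref) && file.exists(ref)) {
    RNifti::asNifti(vol, reference = RNifti::readNifti(ref))
  } else RNifti::asNifti(vol)
  RNifti::writeNifti(img, out_path, datatype = "double")
  invisible(out_path)
}

#' Read a voxelwise map back through a mask
#'
#' Inverse of [write_map()]: extracts the mask voxels of a 3-D volume in
#' enumeration order.
#'
#' @param path Path to a 3-D NIfTI volume on the mask's grid.
#' @param mask An [load_mask()] result.
#' @return Numeric vector of length `mask$n`.
#' @export
read_map <- function(path, mask) {
  stopifnot(inherits(mask, "roi_mask"))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L || !identical(as.integer(d), as.integer(mask$dim)))
    stop("grid mismatch with mask: ", path, call. = FALSE)
  as.array(img)[mask$linear]
}

#' Export a synthetic time-series panel as NIfTI fixtures
#'
#' Writes one 4-D NIfTI per subject-session scan, a 3-D binary mask volume,
#' and a TSV manifest (`subject_id`, `session`, `path` with paths relative to
#' the manifest), so the real-data pipeline runs unchanged on synthetic
#' fixtures. The V mask voxels occupy the first V grid positions in
#' enumeration order on a near-cubic grid.
#'
#' @param panel A `ts_panel` (I x J x V x T).
#' @param dir Output directory (created if needed).
#' @return Path to the written manifest, invisibly.
#' @export
export_panel_nifti <- function(panel, dir) {
  stopifnot(length(dim(panel)) == 4L)
  d <- dim(panel)
  V <- d[3]
  nx <- max(2L, ceiling(V^(1 / 3)))
  ny <- nx
  nz <- ceiling(V / (nx * ny))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- c(nx, ny, nz)
  all_coords <- as.matrix(expand.grid(x = seq_len(nx), y = seq_len(ny),
                                      z = seq_len(nz)))
  all_coords <- all_coords[order(all_coords[, 1], all_coords[, 2],
                                 all_coords[, 3]), , drop = FALSE]
  coords <- all_coords[seq_len(V), , drop = FALSE]
  lin <- (coords[, 3] - 1) * nx * ny + (coords[, 2] - 1) * nx + coords[, 1]
  maskvol <- array(0, grid)
  maskvol[lin] <- 1
  mask_path <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(maskvol), mask_path, datatype = "double")
  subjects <- dimnames(panel)[[1]] %||% sprintf("sub%02d", seq_len(d[1]))
  sessions <- dimnames(panel)[[2]] %||% as.character(seq_len(d[2]))
  rows <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    vol <- array(0, c(grid, d[4]))
    m <- matrix(panel[i, j, , ], V, d[4])
    step <- prod(grid)
    for (t in seq_len(d[4])) vol[lin + (t - 1) * step] <- m[, t]
    fname <- sprintf("%s_ses-%s_bold.nii.gz", subjects[i], sessions[j])
    RNifti::writeNifti(RNifti::asNifti(vol), file.path(dir, fname),
                       datatype = "double")
    rows[[length(rows) + 1L]] <- data.frame(subject_id = subjects[i],
                                            session = sessions[j],
                                            path = fname,
                                            stringsAsFactors = FALSE)
  }
  man <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(man, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest_path)
}
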