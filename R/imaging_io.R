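#' Construct a DCE-MRI time series container
#'
#' Holds the 4D signal volume together with the acquisition metadata the
#' pipeline needs: frame interval, number of pre-contrast frames, voxel
#' spacing and the retained frame times.
#'
#' @param data 4D numeric array `(x, y, z, t)`, non-negative signal units.
#' @param dt Frame interval in seconds.
#' @param n_precontrast Number of pre-contrast frames (>= 2).
#' @param voxel_spacing Voxel spacing in mm, length 3.
#' @param excluded_frames Original indices of frames already removed.
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(data, dt, n_precontrast, voxel_spacing = c(1, 1, 1),
                       excluded_frames = integer(0)) {
  stopifnot(is.array(data), length(dim(data)) == 4, dt > 0,
            n_precontrast >= 2, dim(data)[4] > n_precontrast,
            length(voxel_spacing) == 3)
  if (any(data < 0, na.rm = TRUE)) stop("signal data must be non-negative")
  structure(list(data = data, dt = dt,
                 n_precontrast = as.integer(n_precontrast),
                 voxel_spacing = voxel_spacing,
                 frame_times = (seq_len(dim(data)[4]) - 1) * dt,
                 excluded_frames = as.integer(excluded_frames)),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dce_series> %dx%dx%d voxels, %d frames, dt = %g s, %d pre-contrast\n",
              d[1], d[2], d[3], d[4], x$dt, x$n_precontrast))
  invisible(x)
}

#' Write / read a DCE series as NIfTI plus a JSON sidecar
#'
#' The 4D volume goes to a `.nii.gz` file; timing metadata (`dt`,
#' `n_precontrast`, `excluded_frames`) that NIfTI cannot carry reliably goes
#' to a JSON sidecar. `read_dce_series()` refuses files without the sidecar
#' metadata and non-4D images.
#'
#' @param series A [dce_series()].
#' @param path Path of the NIfTI file (`.nii` or `.nii.gz`).
#' @param sidecar_path Path of the JSON sidecar; defaults to `path` with a
#'   `.json` extension.
#' @return `write_dce_series()` returns the paths invisibly;
#'   `read_dce_series()` returns a [dce_series()].
#' @export
write_dce_series <- function(series, path, sidecar_path = NULL) {
  stopifnot(inherits(series, "dce_series"))
  if (is.null(sidecar_path)) sidecar_path <- .sidecar_of(path)
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_spacing, series$dt)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(dt = series$dt,
                            n_precontrast = series$n_precontrast,
                            voxel_spacing = series$voxel_spacing,
                            excluded_frames = series$excluded_frames),
                       sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar_path))
}

.sidecar_of <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' @rdname write_dce_series
#' @export
read_dce_series <- function(path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) sidecar_path <- .sidecar_of(path)
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(sidecar_path))
    stop("missing JSON sidecar with dt/n_precontrast metadata: ", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$dt) || is.null(meta$n_precontrast))
    stop("sidecar must provide dt and n_precontrast")
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4)
    stop("expected a 4D DCE series, got rank ", length(dim(img)))
  sp <- if (!is.null(meta$voxel_spacing)) meta$voxel_spacing
        else RNifti::pixdim(img)[1:3]
  dce_series(array(as.numeric(img), dim(img)), dt = meta$dt,
             n_precontrast = meta$n_precontrast, voxel_spacing = sp,
             excluded_frames = as.integer(meta$excluded_frames %||% integer(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write 3D maps as NIfTI volumes
#'
#' @param maps Named list of 3D arrays (or a single 3D array).
#' @param dir Output directory (created if needed).
#' @param voxel_spacing Voxel spacing in mm.
#' @return Character vector of written paths, invisibly.
#' @export
write_maps <- function(maps, dir, voxel_spacing = c(1, 1, 1)) {
  if (is.array(maps)) maps <- list(map = maps)
  stopifnot(all(vapply(maps, function(m) length(dim(m)) == 3, TRUE)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(maps)) {
    img <- RNifti::asNifti(maps[[nm]] * 1)  # logical -> numeric
    RNifti::pixdim(img) <- voxel_spacing
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Remove frames from a DCE series
#'
#' Mirrors the manual refinement step in which acquisitions with respiratory
#' artifacts before or after the bolus passage are removed. Retained frames
#' stay contiguous in stored order, the timebase is rebuilt from the retained
#' frames, and the original indices of removed frames are recorded.
#'
#' @param series A [dce_series()].
#' @param indices Frame indices (in current stored order) to remove.
#' @return A [dce_series()] without the given frames.
#' @export
exclude_frames <- function(series, indices) {
  stopifnot(inherits(series, "dce_series"))
  if (length(indices) == 0) return(series)
  nf <- dim(series$data)[4]
  indices <- as.integer(indices)
  if (any(indices < 1 | indices > nf)) stop("frame indices out of range")
  indices <- unique(indices)
  # bolus peak from the global mean enhancement; removing it empties the passage
  mean_sig <- apply(series$data, 4, mean)
  base <- mean(mean_sig[1:2])
  peak_frame <- which.max(mean_sig - base)
  if (peak_frame %in% indices)
    stop("cannot remove the bolus peak frame (frame ", peak_frame, ")")
  keep <- setdiff(seq_len(nf), indices)
  n_pre_kept <- sum(keep <= series$n_precontrast)
  if (n_pre_kept < 2) stop("at least two pre-contrast frames must remain")
  if (sum(keep > series$n_precontrast) < 5)
    stop("at least five post-contrast frames must remain")
  dce_series(series$data[, , , keep, drop = FALSE], dt = series$dt,
             n_precontrast = n_pre_kept, voxel_spacing = series$voxel_spacing,
             excluded_frames = sort(c(series$excluded_frames, indices)))
}

#' Exam- and frame-level quality control
#'
#' Automated surrogate for the visual exam review: an exam fails for
#' insufficient enhancement when the peak mean lung enhancement divided by
#' the baseline noise SD falls below `cnr_threshold`; for bolus mistiming
#' when the enhancement peak lies inside the pre-contrast block or at the
#' final frame; and for breathing artifacts when more than
#' `artifact_fail_fraction` of frames are flagged. The per-frame artifact
#' score is the mean absolute deviation of the lung-edge signal profile from
#' its temporal-neighbor median, normalized by the across-frame median score.
#'
#' @param series A [dce_series()].
#' @param lung_mask 3D logical mask matching the series grid.
#' @param cnr_threshold Minimum acceptable peak-enhancement CNR (default 5).
#' @param artifact_flag_factor Frames whose normalized score exceeds this
#'   factor are flagged (default 3).
#' @param artifact_fail_fraction Exam fails when more than this fraction of
#'   frames is flagged (default 0.25).
#' @return A list of class `qc_report`: `exam_status` ("pass"/"fail"),
#'   `fail_reason`, `peak_enhancement_cnr`, `peak_frame`,
#'   `artifact_score_per_frame`, `flagged_frames`.
#' @export
qc_exam <- function(series, lung_mask, cnr_threshold = 5,
                    artifact_flag_factor = 3, artifact_fail_fraction = 0.25) {
  stopifnot(inherits(series, "dce_series"),
            all(dim(lung_mask) == dim(series$data)[1:3]))
  nf <- dim(series$data)[4]
  flat <- matrix(series$data, ncol = nf)
  lung_idx <- which(lung_mask)
  n_nonfinite <- sum(!is.finite(flat[lung_idx, ]))
  sub <- flat[lung_idx, , drop = FALSE] -
    rowMeans(flat[lung_idx, 1:2, drop = FALSE])
  mean_enh <- colMeans(sub, na.rm = TRUE)
  noise_sd <- sd(as.vector(sub[, seq_len(series$n_precontrast)]), na.rm = TRUE)
  peak_frame <- which.max(mean_enh)
  cnr <- if (noise_sd > 0) mean_enh[peak_frame] / noise_sd else Inf
  if (!is.finite(cnr) || is.na(cnr)) cnr <- 0

  # lung-edge profile: voxels on the mask boundary are most sensitive to
  # displacement; compare each frame against the median of its neighbors
  edge <- lung_mask & !.erode1(lung_mask)
  prof <- flat[which(edge), , drop = FALSE]
  score <- numeric(nf)
  for (f in seq_len(nf)) {
    nb <- setdiff(intersect((f - 2):(f + 2), seq_len(nf)), f)
    ref <- apply(prof[, nb, drop = FALSE], 1, median, na.rm = TRUE)
    score[f] <- mean(abs(prof[, f] - ref), na.rm = TRUE)
  }
  score <- score / median(score)
  flagged <- which(score > artifact_flag_factor)

  status <- "pass"; reason <- "none"
  if (cnr < cnr_threshold) {
    status <- "fail"; reason <- "insufficient_enhancement"
  } else if (peak_frame <= series$n_precontrast || peak_frame == nf) {
    status <- "fail"; reason <- "bolus_mistiming"
  } else if (length(flagged) > artifact_fail_fraction * nf) {
    status <- "fail"; reason <- "breathing_artifacts"
  }
  structure(list(exam_status = status, fail_reason = reason,
                 peak_enhancement_cnr = cnr, peak_frame = peak_frame,
                 artifact_score_per_frame = score, flagged_frames = flagged,
                 n_nonfinite_voxels = n_nonfinite),
            class = "qc_report")
}

# one-voxel 6-connected erosion
.erode1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[ax]
    src <- pmin(pmax(seq_len(n) + by, 1L), n)
    idx[[ax]] <- src
    do.call(`[`, c(list(m), idx))
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out & shift(mask, ax, by)
  out
}

# one-voxel 6-connected dilation
.dilate1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[ax]
    src <- pmin(pmax(seq_len(n) + by, 1L), n)
    idx[[ax]] <- src
    do.call(`[`, c(list(m), idx))
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out | shift(mask, ax, by)
  out
}
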