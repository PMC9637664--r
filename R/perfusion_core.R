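#' Compute the subtraction series
#'
#' Subtracts the mean of the first two pre-contrast frames from every frame,
#' converting signal into enhancement. Negative values are retained: noise
#' is symmetric about zero before contrast arrival.
#'
#' @param series A [dce_series()].
#' @return A list of class `subtraction_series` with `data` (4D enhancement
#'   array), `dt`, `n_precontrast`, `baseline_frames_used`.
#' @export
compute_subtraction <- function(series) {
  stopifnot(inherits(series, "dce_series"))
  if (series$n_precontrast < 2)
    stop("need at least two pre-contrast frames for the baseline")
  nf <- dim(series$data)[4]
  flat <- matrix(series$data, ncol = nf)
  base <- rowMeans(flat[, 1:2, drop = FALSE])
  sub <- flat - base
  structure(list(data = array(sub, dim(series$data)), dt = series$dt,
                 n_precontrast = series$n_precontrast,
                 baseline_frames_used = 2L),
            class = "subtraction_series")
}

#' Automatically detect the arterial input function
#'
#' Ranks voxels of the search region by peak enhancement, restricts the
#' top candidates to those whose peak frame lies within one frame of the
#' candidate-set mode (ties broken toward the earlier frame, preferring the
#' first-pass over late-enhancing populations), and averages the `k` best
#' remaining curves.
#'
#' @param sub A [compute_subtraction()] result.
#' @param search_mask 3D logical array of candidate voxels (e.g. a
#'   pulmonary-artery region, or all extrapulmonary voxels).
#' @param k Number of curves averaged into the AIF (default 10).
#' @param n_candidates Size of the initial top-peak candidate set.
#' @param cnr_threshold Minimum peak / pre-contrast-noise ratio; below it the
#'   exam has insufficient enhancement for an AIF.
#' @return A list of class `aif`: `curve`, `source_voxels` (linear indices),
#'   `peak_value`, `peak_frame`.
#' @export
detect_aif <- function(sub, search_mask, k = 10, n_candidates = 50,
                       cnr_threshold = 5) {
  stopifnot(inherits(sub, "subtraction_series"),
            all(dim(search_mask) == dim(sub$data)[1:3]), any(search_mask))
  nf <- dim(sub$data)[4]
  flat <- matrix(sub$data, ncol = nf)
  idx <- which(search_mask)
  curves <- flat[idx, , drop = FALSE]
  peaks <- apply(curves, 1, max)
  noise_sd <- sd(as.vector(curves[, seq_len(sub$n_precontrast)]))
  if (!is.finite(noise_sd) || noise_sd == 0) noise_sd <- .Machine$double.eps
  if (max(peaks) <= 0 || max(peaks) / noise_sd < cnr_threshold)
    stop("insufficient_enhancement: no usable AIF candidate in search region")
  ord <- order(peaks, decreasing = TRUE)
  cand <- ord[seq_len(min(n_candidates, length(ord)))]
  pf <- apply(curves[cand, , drop = FALSE], 1, which.max)
  tab <- table(pf)
  mode_pf <- as.integer(names(tab)[tab == max(tab)])
  mode_pf <- min(mode_pf)  # earlier population wins ties
  keep <- cand[abs(pf - mode_pf) <= 1]
  keep <- keep[seq_len(min(k, length(keep)))]  # already peak-ordered
  curve <- colMeans(curves[keep, , drop = FALSE])
  structure(list(curve = curve, source_voxels = idx[keep],
                 peak_value = max(curve), peak_frame = which.max(curve)),
            class = "aif")
}

#' Build the discrete convolution operator of an AIF
#'
#' Returns the `n x n` lower-triangular Toeplitz matrix `A` with
#' `A[i, j] = dt * AIF[i - j + 1]` for `i >= j`, which maps a sampled
#' residue function `R` to tissue enhancement `C = A %*% R` under the
#' rectangle-rule discretization of the indicator-dilution convolution.
#' `A` is nonsingular iff `AIF[1] != 0`.
#'
#' @param aif An `aif` object or a numeric AIF curve.
#' @param dt Frame interval in seconds.
#' @return The convolution matrix.
#' @export
build_convolution_matrix <- function(aif, dt) {
  a <- if (inherits(aif, "aif")) aif$curve else aif
  n <- length(a)
  stopifnot(n >= 5, dt > 0)
  i <- matrix(seq_len(n), n, n)
  lag <- i - t(i) + 1L
  A <- matrix(0, n, n)
  low <- lag >= 1L
  A[low] <- dt * a[lag[low]]
  A
}

#' Deconvolve a subtraction series into residue-function maps
#'
#' Per masked voxel solves `C = A %*% R` by truncated singular value
#' decomposition: singular values below `truncation_fraction` of the largest
#' are discarded and the pseudo-inverse applied to the voxel enhancement
#' curve. The scan-level reference frame `tmax_frame` is the frame of
#' maximum mean enhancement over the lung, and the Rmax map is the residue
#' field evaluated there.
#'
#' @param sub A [compute_subtraction()] result.
#' @param aif An `aif` object (or numeric curve).
#' @param lung_mask 3D logical mask of voxels to deconvolve.
#' @param truncation_fraction Relative singular-value cutoff in (0, 1),
#'   default 0.2.
#' @param rmax_mode `"tmax"` (scan-level frame, default) or `"per_voxel"`
#'   (per-voxel maximum of the residue function) for the Rmax map.
#' @return A list of class `residue_maps`: `rt` (4D residue array, 1/s;
#'   zero outside the mask), `rmax` (3D), `tmax_frame`, `dt`,
#'   `truncation_fraction`, `mask`, `n_sv_kept`.
#' @export
tsvd_deconvolve <- function(sub, aif, lung_mask, truncation_fraction = 0.2,
                            rmax_mode = c("tmax", "per_voxel")) {
  rmax_mode <- match.arg(rmax_mode)
  stopifnot(inherits(sub, "subtraction_series"),
            all(dim(lung_mask) == dim(sub$data)[1:3]), any(lung_mask))
  if (truncation_fraction <= 0 || truncation_fraction >= 1)
    stop("truncation_fraction must lie in (0, 1)")
  nf <- dim(sub$data)[4]
  A <- build_convolution_matrix(aif, sub$dt)
  sv <- svd(A)
  keep <- sv$d >= truncation_fraction * sv$d[1]
  Ainv <- sv$v %*% (t(sv$u) * ifelse(keep, 1 / sv$d, 0))

  flat <- matrix(sub$data, ncol = nf)
  idx <- which(lung_mask)
  C <- t(flat[idx, , drop = FALSE])          # frames x voxels
  R <- Ainv %*% C
  rt <- array(0, dim(sub$data))
  rt_flat <- matrix(rt, ncol = nf)
  rt_flat[idx, ] <- t(R)
  rt <- array(rt_flat, dim(sub$data))

  tmax_frame <- which.max(rowMeans(C))
  rmax <- if (rmax_mode == "tmax") rt[, , , tmax_frame]
          else apply(rt, 1:3, max)
  structure(list(rt = rt, rmax = rmax, tmax_frame = tmax_frame, dt = sub$dt,
                 truncation_fraction = truncation_fraction, mask = lung_mask,
                 n_sv_kept = sum(keep)),
            class = "residue_maps")
}

#' Pulmonary blood flow map from residue functions
#'
#' PBF is the maximum height of the residue function in each voxel, floored
#' at zero to keep the map physical, and scaled by 6000 to convert the
#' relative 1/s residue units to ml/100ml/min.
#'
#' @param rt A `residue_maps` object or a 4D residue array.
#' @param scale Unit scale constant (default 6000 = s/min x 100ml/ml).
#' @return 3D PBF map.
#' @export
compute_pbf <- function(rt, scale = 6000) {
  r <- if (inherits(rt, "residue_maps")) rt$rt else rt
  stopifnot(length(dim(r)) == 4)
  d <- dim(r)
  flat <- matrix(r, ncol = d[4])
  pbf <- do.call(pmax, c(lapply(seq_len(d[4]), function(f) flat[, f]), list(0)))
  array(scale * pbf, d[1:3])
}

#' Pulmonary blood volume map from residue functions
#'
#' PBV is the time-integral of the residue function in each voxel,
#' trapezoidal rule over the frame grid; negative residue samples are
#' retained in the integral (preserving unbiasedness under noise) and the
#' final map is floored at zero. The factor 100 converts the relative
#' residue units to ml/100ml.
#'
#' @param rt A `residue_maps` object or a 4D residue array.
#' @param dt Frame interval in seconds (taken from the object if omitted).
#' @param scale Unit scale constant (default 100).
#' @return 3D PBV map.
#' @export
compute_pbv <- function(rt, dt = NULL, scale = 100) {
  if (inherits(rt, "residue_maps")) {
    if (is.null(dt)) dt <- rt$dt
    r <- rt$rt
  } else r <- rt
  stopifnot(length(dim(r)) == 4, !is.null(dt))
  d <- dim(r)
  flat <- matrix(r, ncol = d[4])
  integral <- dt * (rowSums(flat) - (flat[, 1] + flat[, d[4]]) / 2)
  array(pmax(scale * integral, 0), d[1:3])
}

#' Whole-lung summary of a voxel map
#'
#' The whole-lung value of a perfusion map is the median over all voxels
#' within the lung mask; non-finite voxels are excluded and their count
#' reported via the `n_nonfinite` attribute.
#'
#' @param map 3D numeric array.
#' @param mask 3D logical array, non-empty.
#' @return Scalar median with attribute `n_nonfinite`.
#' @export
summarize_whole_lung <- function(map, mask) {
  stopifnot(all(dim(map) == dim(mask)))
  if (!any(mask)) stop("empty mask")
  v <- map[mask]
  bad <- !is.finite(v)
  out <- median(v[!bad])
  attr(out, "n_nonfinite") <- sum(bad)
  out
}
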