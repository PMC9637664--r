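#' Segment the lungs by seeded region growing
#'
#' Grows 6- or 26-connected regions from seed voxels through all voxels whose
#' intensity lies inside `intensity_window`, then applies a radius-1
#' morphological closing to fill single-voxel holes. On T1-weighted
#' gradient-echo morphology the air-filled lungs are dark, so the default
#' seeds are the darkest voxels of the left and right volume halves and the
#' default window upper bound is a single Otsu threshold separating the dark
#' (lung) from the bright (soft-tissue) intensity mode.
#'
#' @param morph 3D numeric array, morphological volume.
#' @param seeds Matrix of voxel indices (rows = seeds, columns = x,y,z), or
#'   `NULL` for automatic seeding.
#' @param intensity_window `c(lo, hi)` intensity window, or `NULL` for
#'   `c(-Inf, otsu)` with a single-threshold Otsu bound.
#' @param connectivity 6 (faces) or 26 (faces+edges+corners).
#' @param voxel_spacing Voxel spacing in mm (for the volume report).
#' @param closing_radius Radius of the morphological closing (0 disables).
#' @return A list of class `lung_mask`: `mask` (3D logical), `volume_ml`,
#'   `n_components`, `seed_points`, `intensity_window`.
#' @export
region_grow <- function(morph, seeds = NULL, intensity_window = NULL,
                        connectivity = 6, voxel_spacing = c(1, 1, 1),
                        closing_radius = 1) {
  stopifnot(length(dim(morph)) == 3, connectivity %in% c(6, 26))
  d <- dim(morph)
  if (is.null(intensity_window)) {
    t1 <- .otsu_single(as.vector(morph))
    intensity_window <- c(-Inf, t1)
  }
  lo <- intensity_window[1]; hi <- intensity_window[2]
  if (!(lo < hi)) stop("intensity window must satisfy lo < hi")
  if (is.null(seeds)) {
    halves <- list(1:floor(d[1] / 2), (floor(d[1] / 2) + 1):d[1])
    seeds <- do.call(rbind, lapply(halves, function(xs) {
      sub <- morph[xs, , , drop = FALSE]
      w <- which.min(sub)
      i <- arrayInd(w, dim(sub))
      c(xs[i[1]], i[2], i[3])
    }))
  }
  seeds <- matrix(as.integer(seeds), ncol = 3)
  for (s in seq_len(nrow(seeds))) {
    v <- morph[seeds[s, 1], seeds[s, 2], seeds[s, 3]]
    if (v < lo || v > hi)
      stop(sprintf("seed (%d,%d,%d) intensity %.3g lies outside window [%g, %g]",
                   seeds[s, 1], seeds[s, 2], seeds[s, 3], v, lo, hi))
  }
  candidate <- morph >= lo & morph <= hi
  mask <- array(FALSE, d)
  n_components <- 0L
  for (s in seq_len(nrow(seeds))) {
    idx <- seeds[s, 1] + (seeds[s, 2] - 1L) * d[1] +
      (seeds[s, 3] - 1L) * d[1] * d[2]
    if (mask[idx]) next
    mask <- mask | .flood_fill(candidate, idx, d, connectivity)
    n_components <- n_components + 1L
  }
  if (closing_radius >= 1) {
    closed <- mask
    for (r in seq_len(closing_radius)) closed <- .dilate1(closed)
    for (r in seq_len(closing_radius)) closed <- .erode1(closed)
    mask <- mask | closed
  }
  structure(list(mask = mask,
                 volume_ml = sum(mask) * prod(voxel_spacing) / 1000,
                 n_components = n_components,
                 seed_points = seeds,
                 intensity_window = c(lo, hi)),
            class = "lung_mask")
}

# vectorized flood fill by iterative constrained dilation from one seed
.flood_fill <- function(candidate, seed_idx, d, connectivity) {
  grown <- array(FALSE, d)
  grown[seed_idx] <- TRUE
  shift <- function(m, dx, dy, dz) {
    out <- array(FALSE, d)
    xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
    sx <- xs - dx; sy <- ys - dy; sz <- zs - dz
    okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]
    okz <- sz >= 1 & sz <= d[3]
    out[xs[okx], ys[oky], zs[okz]] <- m[sx[okx], sy[oky], sz[okz]]
    out
  }
  offs <- if (connectivity == 6) {
    list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
    lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
  }
  repeat {
    nb <- array(FALSE, d)
    for (o in offs) nb <- nb | shift(grown, o[1], o[2], o[3])
    new <- nb & candidate & !grown
    if (!any(new)) break
    grown <- grown | new
  }
  grown
}

# single-threshold Otsu (maximize between-class variance, 2 classes)
.otsu_single <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w <- counts / sum(counts)
  cw <- cumsum(w); cm <- cumsum(w * centers); mu <- cm[n_bins]
  valid <- cw > 0 & cw < 1
  bcv <- (mu * cw - cm)^2 / (cw * (1 - cw))
  bcv[!valid] <- -Inf
  centers[which.max(bcv)]
}

#' Report on a lung mask, optionally against a reference
#'
#' @param mask A [region_grow()] result or a 3D logical array.
#' @param truth_mask Optional reference 3D logical mask.
#' @return A list with `volume_voxels`, `n_components` (when available) and,
#'   if a reference is given, the `dice` overlap coefficient in `[0, 1]`
#'   (1 iff the masks are identical).
#' @export
review_mask <- function(mask, truth_mask = NULL) {
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  out <- list(volume_voxels = sum(m),
              n_components = if (inherits(mask, "lung_mask"))
                mask$n_components else NA_integer_)
  if (!is.null(truth_mask)) {
    stopifnot(all(dim(m) == dim(truth_mask)))
    denom <- sum(m) + sum(truth_mask)
    out$dice <- if (denom == 0) 1 else 2 * sum(m & truth_mask) / denom
  }
  out
}

#' Nearest-neighbour mask resampling
#'
#' Hook for carrying a mask from a morphological grid onto a (coarser or
#' finer) DCE grid when the two are rigidly aligned but sampled differently.
#'
#' @param mask 3D logical array.
#' @param new_dims Target grid dimensions.
#' @return 3D logical array of size `new_dims`.
#' @export
resample_mask_nn <- function(mask, new_dims) {
  stopifnot(length(dim(mask)) == 3, length(new_dims) == 3)
  d <- dim(mask)
  ix <- pmin(pmax(round((seq_len(new_dims[1]) - 0.5) * d[1] / new_dims[1] + 0.5), 1), d[1])
  iy <- pmin(pmax(round((seq_len(new_dims[2]) - 0.5) * d[2] / new_dims[2] + 0.5), 1), d[2])
  iz <- pmin(pmax(round((seq_len(new_dims[3]) - 0.5) * d[3] / new_dims[3] + 0.5), 1), d[3])
  mask[ix, iy, iz]
}
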