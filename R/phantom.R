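#' Arterial input function parameters
#'
#' Parameters of the gamma-variate first-pass bolus model used as the
#' ground-truth arterial input function (AIF) of the digital perfusion
#' phantom, with an optional recirculation bump.
#'
#' @param amplitude Peak first-pass enhancement, signal units (> 0).
#' @param t0 Bolus onset time in seconds (>= 0).
#' @param alpha Gamma-variate shape parameter (> 0, dimensionless).
#' @param beta Gamma-variate scale parameter in seconds (> 0). The first-pass
#'   lobe peaks at `t0 + alpha * beta`.
#' @param recirculation_fraction Amplitude of the recirculation bump relative
#'   to the first pass, in `[0, 1)`.
#' @param recirculation_delay Delay of the recirculation bump in seconds.
#'
#' @return An object of class `aif_params`.
#' @export
aif_params <- function(amplitude = 60, t0 = 4.5, alpha = 2, beta = 2,
                       recirculation_fraction = 0.1,
                       recirculation_delay = 15) {
  stopifnot(amplitude > 0, t0 >= 0, alpha > 0, beta > 0,
            recirculation_fraction >= 0, recirculation_fraction < 1,
            recirculation_delay > 0)
  structure(list(amplitude = amplitude, t0 = t0, alpha = alpha, beta = beta,
                 recirculation_fraction = recirculation_fraction,
                 recirculation_delay = recirculation_delay),
            class = "aif_params")
}

#' Evaluate a gamma-variate arterial input function
#'
#' Evaluates the first-pass bolus curve
#' `A * ((t - t0)^alpha * exp(-(t - t0)/beta)) / max` on a uniform timebase,
#' zero before onset, plus an optional delayed, scaled recirculation copy.
#'
#' @param params An [aif_params()] object.
#' @param timebase Strictly increasing, uniformly spaced time vector (s).
#'
#' @return Numeric vector of enhancement values, one per time point.
#' @export
gamma_variate_aif <- function(params, timebase) {
  stopifnot(inherits(params, "aif_params"), length(timebase) >= 2)
  dts <- diff(timebase)
  if (any(dts <= 0) || max(abs(dts - dts[1])) > 1e-8 * dts[1])
    stop("timebase must be strictly increasing with uniform spacing")
  lobe <- function(tt) {
    y <- numeric(length(tt))
    ok <- tt > 0
    y[ok] <- tt[ok]^params$alpha * exp(-tt[ok] / params$beta)
    y
  }
  # normalize the first-pass lobe by its analytic peak (alpha*beta)^alpha*e^-alpha
  # so `amplitude` is the continuous peak regardless of sampling
  pk <- (params$alpha * params$beta)^params$alpha * exp(-params$alpha)
  y <- lobe(timebase - params$t0) / pk
  if (params$recirculation_fraction > 0) {
    y <- y + params$recirculation_fraction *
      lobe(timebase - params$t0 - params$recirculation_delay) / pk
  }
  params$amplitude * y
}

#' Specification of a synthetic two-visit DCE-MRI phantom
#'
#' Bundles every parameter of the digital thorax phantom: grid geometry,
#' frame timing, the ground-truth AIF, the perfusion model of normal lung,
#' perfusion defects and intrapulmonary vessels, the gravity-direction
#' perfusion gradient, the noise model, frame corruption, and the two
#' scan-level error mechanisms (a global visit-2 gain and a per-visit
#' arterial-signal measurement error).
#'
#' @param dims Grid dimensions `c(nx, ny, nz)` in voxels.
#' @param voxel_spacing Voxel spacing `c(dx, dy, dz)` in mm.
#' @param dt Frame interval in seconds.
#' @param n_frames Number of dynamic frames.
#' @param n_precontrast Number of pre-contrast frames (>= 2; the pipeline
#'   subtracts the mean of the first two).
#' @param aif Ground-truth [aif_params()].
#' @param defect_fraction Fraction of lung voxels inside perfusion defects,
#'   in `[0, 1]`.
#' @param defect_pbf_scale PBF inside defects relative to normal lung,
#'   in `[0, 1)`.
#' @param normal_pbf Normal-lung pulmonary blood flow, ml/100ml/min
#'   (relative calibration, see Details).
#' @param mtt_normal,mtt_defect Mean transit times (s) of normal and defect
#'   tissue.
#' @param vessel_fraction Fraction of lung voxels belonging to the
#'   intrapulmonary vessel compartment.
#' @param vessel_pbf_scale Vessel-compartment PBF relative to normal lung
#'   (> 1; vessels are the bright Rmax cluster).
#' @param gravity_gradient Fractional PBF change per slice along the
#'   slice-stacking (gravity) axis; linear multiplicative gradient.
#' @param cnr Contrast-to-noise ratio: peak noiseless enhancement in normal
#'   lung divided by the noise SD (> 0).
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param artifact_frames Integer frame indices corrupted by a
#'   breathing-artifact surrogate (2-voxel in-plane shift + 1-voxel blur).
#' @param visit_scale_error Global multiplier applied to the visit-2 signal
#'   (scanner gain error).
#' @param aif_scale_error Length-2 multiplier (one per visit) applied to the
#'   arterial and intrapulmonary-vessel signal only. This emulates the
#'   inconsistent underestimation of the measured AIF maximum between scans
#'   (e.g. by temporal undersampling of the bolus peak): the deconvolved
#'   residue functions of the whole scan are then scaled by its inverse.
#' @param n_defect_blobs Number of connected defect regions.
#' @param rng_seed Integer seed; all phantom randomness derives from it.
#'
#' @details The phantom works in relative perfusion units: voxel residue
#' functions are `R(t) = (PBF/6000) * exp(-t/MTT)` in 1/s, so that
#' `PBF` in ml/100ml/min equals `6000 * max(R)` and
#' `PBV = 100 * integral(R)` in ml/100ml, giving the exponential-residue
#' identity `PBV = PBF * MTT / 60`. Absolute calibration (contrast-agent
#' relaxivity, tissue density) is out of scope.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(64, 64, 24), voxel_spacing = c(3, 3, 6),
                         dt = 1.5, n_frames = 40, n_precontrast = 4,
                         aif = aif_params(),
                         defect_fraction = 0.3, defect_pbf_scale = 0.15,
                         normal_pbf = 60, mtt_normal = 5, mtt_defect = 8,
                         vessel_fraction = 0.05, vessel_pbf_scale = 4,
                         gravity_gradient = 0.015,
                         cnr = 20, noise_model = c("gaussian", "rician"),
                         artifact_frames = integer(0),
                         visit_scale_error = 1,
                         aif_scale_error = c(1, 1),
                         n_defect_blobs = 3, rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (length(aif_scale_error) == 1) aif_scale_error <- rep(aif_scale_error, 2)
  stopifnot(length(dims) == 3, all(dims >= 8), dt > 0, n_frames >= 10,
            n_precontrast >= 2, inherits(aif, "aif_params"),
            defect_fraction >= 0, defect_fraction <= 1,
            defect_pbf_scale >= 0, defect_pbf_scale < 1,
            normal_pbf > 0, mtt_normal > 0, mtt_defect > 0,
            vessel_fraction >= 0, defect_fraction + vessel_fraction <= 1,
            vessel_pbf_scale > 1, cnr > 0,
            visit_scale_error > 0, all(aif_scale_error > 0),
            n_defect_blobs >= 1)
  structure(list(dims = as.integer(dims), voxel_spacing = voxel_spacing,
                 dt = dt, n_frames = as.integer(n_frames),
                 n_precontrast = as.integer(n_precontrast), aif = aif,
                 defect_fraction = defect_fraction,
                 defect_pbf_scale = defect_pbf_scale,
                 normal_pbf = normal_pbf, mtt_normal = mtt_normal,
                 mtt_defect = mtt_defect, vessel_fraction = vessel_fraction,
                 vessel_pbf_scale = vessel_pbf_scale,
                 gravity_gradient = gravity_gradient, cnr = cnr,
                 noise_model = noise_model,
                 artifact_frames = as.integer(artifact_frames),
                 visit_scale_error = visit_scale_error,
                 aif_scale_error = aif_scale_error,
                 n_defect_blobs = as.integer(n_defect_blobs),
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# ellipsoid mask helper
.ellipsoid <- function(dims, center, semi) {
  x <- (seq_len(dims[1]) - center[1]) / semi[1]
  y <- (seq_len(dims[2]) - center[2]) / semi[2]
  z <- (seq_len(dims[3]) - center[3]) / semi[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

# 6-neighbour linear-index offsets with boundary guards
.neighbors6 <- function(idx, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  i <- (idx - 1L) %% nx + 1L
  j <- ((idx - 1L) %/% nx) %% ny + 1L
  k <- (idx - 1L) %/% (nx * ny) + 1L
  out <- c(idx[i > 1L] - 1L, idx[i < nx] + 1L,
           idx[j > 1L] - nx, idx[j < ny] + nx,
           idx[k > 1L] - nx * ny, idx[k < nz] + nx * ny)
  unique(out)
}

# Grow n_blobs connected regions inside candidate up to target_n voxels total.
# Seeded region growth with randomized frontier accretion gives compact,
# irregular blobs resembling focal perfusion defects.
.grow_blobs <- function(candidate, target_n, n_blobs, dims) {
  target_n <- as.integer(round(target_n))
  blob <- array(FALSE, dims)
  if (target_n == 0L) return(blob)
  cand_idx <- which(candidate)
  if (length(cand_idx) < target_n)
    stop("cannot realize the requested fraction: only ", length(cand_idx),
         " candidate voxels available for a target of ", target_n)
  seeds <- sample(cand_idx, min(n_blobs, length(cand_idx)))
  blob[seeds] <- TRUE
  n <- sum(blob)
  frontier <- seeds
  while (n < target_n) {
    nb <- .neighbors6(frontier, dims)
    nb <- nb[candidate[nb] & !blob[nb]]
    if (length(nb) == 0L) {
      # blob hit a geometric boundary: restart growth from a fresh seed
      free <- which(candidate & !blob)
      if (length(free) == 0L)
        stop("cannot realize the requested fraction as connected regions ",
             "on this grid (frontier exhausted at ", n, "/", target_n, ")")
      nb <- sample(free, 1L)
    }
    take <- sample(nb, min(length(nb), target_n - n))
    blob[take] <- TRUE
    n <- n + length(take)
    frontier <- take
  }
  blob
}

#' Generate the ground-truth anatomy and perfusion maps of a phantom
#'
#' Builds the lung (two ellipsoids), the extrapulmonary arterial compartment,
#' connected defect blobs, intrapulmonary vessel blobs, the voxelwise
#' PBF/PBV/MTT truth maps (with the linear gravity gradient applied), and a
#' morphological T1-like volume for lung segmentation (dark lungs in bright
#' soft tissue; tight thorax field of view without exterior air).
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_truth` with elements `lung_mask`,
#'   `artery_mask`, `defect_mask`, `vessel_mask`, `pbf_truth`, `pbv_truth`,
#'   `mtt_truth`, `qdp_truth` (percent), `morph`, and `gravity_factor`
#'   (per-slice multiplier).
#' @export
make_phantom_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$rng_seed)
  d <- spec$dims
  left  <- .ellipsoid(d, c(0.30 * d[1], 0.50 * d[2], 0.52 * d[3]),
                      c(0.16 * d[1], 0.32 * d[2], 0.42 * d[3]))
  right <- .ellipsoid(d, c(0.70 * d[1], 0.50 * d[2], 0.52 * d[3]),
                      c(0.16 * d[1], 0.32 * d[2], 0.42 * d[3]))
  lung <- left | right
  # pulmonary-artery surrogate: a small block in the mediastinum
  artery <- array(FALSE, d)
  ax <- seq(round(0.47 * d[1]), round(0.53 * d[1]))
  ay <- seq(round(0.40 * d[2]), round(0.50 * d[2]))
  az <- seq(round(0.40 * d[3]), round(0.60 * d[3]))
  artery[ax, ay, az] <- TRUE
  artery <- artery & !lung

  n_lung <- sum(lung)
  defect <- .grow_blobs(lung, spec$defect_fraction * n_lung,
                        spec$n_defect_blobs, d)
  vessel <- .grow_blobs(lung & !defect, spec$vessel_fraction * n_lung,
                        max(4L, spec$n_defect_blobs), d)

  gz <- pmax(1 + spec$gravity_gradient * (seq_len(d[3]) - (d[3] + 1) / 2), 0.1)
  gvol <- array(rep(gz, each = d[1] * d[2]), d)

  pbf <- array(0, d)
  pbf[lung] <- spec$normal_pbf * gvol[lung]
  pbf[defect] <- pbf[defect] * spec$defect_pbf_scale
  pbf[vessel] <- spec$normal_pbf * spec$vessel_pbf_scale * gvol[vessel]
  mtt <- array(NA_real_, d)
  mtt[lung] <- spec$mtt_normal
  mtt[defect] <- spec$mtt_defect
  pbv <- array(0, d)
  pbv[lung] <- pbf[lung] * mtt[lung] / 60

  morph <- array(120, d)
  morph[lung] <- 30
  morph <- morph + array(rnorm(prod(d), 0, 5), d)

  structure(list(lung_mask = lung, artery_mask = artery, defect_mask = defect,
                 vessel_mask = vessel, pbf_truth = pbf, pbv_truth = pbv,
                 mtt_truth = mtt, qdp_truth = 100 * sum(defect) / n_lung,
                 morph = morph, gravity_factor = gz),
            class = "phantom_truth")
}

# in-plane integer shift (edge replication) + separable Gaussian blur of one
# 3D frame: the breathing-artifact surrogate
.corrupt_frame <- function(vol, shift = 2L, sigma = 1) {
  d <- dim(vol)
  src <- pmin(pmax(seq_len(d[1]) - shift, 1L), d[1])
  vol <- vol[src, , , drop = FALSE]
  half <- 3L
  kx <- exp(-(-half:half)^2 / (2 * sigma^2)); kx <- kx / sum(kx)
  pad_idx <- function(n) pmin(pmax(seq(1 - half, n + half), 1L), n)
  for (ax in 1:2) {
    n <- d[ax]
    padded <- if (ax == 1) vol[pad_idx(n), , , drop = FALSE]
              else vol[, pad_idx(n), , drop = FALSE]
    out <- array(0, d)
    for (o in -half:half) {
      sl <- seq_len(n) + half + o
      out <- out + kx[o + half + 1] *
        (if (ax == 1) padded[sl, , , drop = FALSE]
         else padded[, sl, , drop = FALSE])
    }
    vol <- out
  }
  vol
}

#' Synthesize one DCE-MRI visit of a phantom
#'
#' Forward model: per-voxel enhancement is the discrete convolution
#' `C(t) = dt * sum(AIF(tau) * R(t - tau))` with exponential residue
#' functions `R(t) = (PBF/6000) * exp(-t/MTT)` from the truth maps. The
#' arterial compartment and intrapulmonary vessels carry scaled (and, for
#' vessels, dispersed high-flow) copies of the AIF, multiplied by the
#' per-visit `aif_scale_error`. Baseline signal is 100 inside the lung and
#' 50 outside; noise is added at the requested CNR; listed artifact frames
#' are corrupted by an in-plane shift plus blur; visit 2 reuses the identical
#' noiseless construction times `visit_scale_error` with fresh noise.
#'
#' @param spec A [phantom_spec()].
#' @param truth The matching [make_phantom_truth()] output.
#' @param visit Visit number (1 or 2).
#' @param noise_seed Seed for the noise stream; defaults to
#'   `rng_seed + (visit - 1) * 1000003` so the two visits share truth but not
#'   noise. Pass equal seeds to make the visits identical (when
#'   `visit_scale_error = 1`).
#' @return A [dce_series()] object.
#' @export
synthesize_visit <- function(spec, truth, visit = 1L,
                             noise_seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(truth, "phantom_truth"),
            visit %in% c(1L, 2L))
  d <- spec$dims
  stopifnot(all(dim(truth$lung_mask) == d))
  nf <- spec$n_frames
  t <- (seq_len(nf) - 1) * spec$dt
  aif <- gamma_variate_aif(spec$aif, t)
  A <- build_convolution_matrix(aif, spec$dt)

  lung <- truth$lung_mask
  vessel <- truth$vessel_mask
  tissue <- lung & !vessel
  s_aif <- spec$aif_scale_error[visit]

  # residue basis curves per unique MTT; voxel curves scale linearly with PBF
  vox <- c(which(lung), which(truth$artery_mask))
  mtts <- truth$mtt_truth[lung]
  pbfs <- truth$pbf_truth[lung]
  curves <- matrix(0, nf, sum(lung))
  for (m in unique(mtts)) {
    basis <- as.vector(A %*% exp(-t / m))
    sel <- mtts == m
    curves[, sel] <- outer(basis, pbfs[sel] / 6000)
  }
  # arterial and vessel compartments carry the AIF measurement scale error
  vessel_in_lung <- vessel[lung]
  curves[, vessel_in_lung] <- curves[, vessel_in_lung] * s_aif
  artery_curves <- matrix(rep(s_aif * aif, sum(truth$artery_mask)), nrow = nf)
  enh <- cbind(curves, artery_curves)

  # CNR reference: peak noiseless enhancement over normal (non-defect,
  # non-vessel) lung tissue
  normal_in_lung <- (tissue & !truth$defect_mask)[lung]
  peak_enh <- max(curves[, normal_in_lung])
  noise_sd <- peak_enh / spec$cnr

  baseline <- array(50, d)
  baseline[lung] <- 100
  scl <- if (visit == 2L) spec$visit_scale_error else 1

  data <- array(rep(baseline, nf), c(d, nf))
  flat <- matrix(data, nrow = prod(d))
  flat[vox, ] <- flat[vox, ] + t(enh)
  flat <- flat * scl

  if (is.null(noise_seed))
    noise_seed <- spec$rng_seed + (visit - 1L) * 1000003L
  set.seed(noise_seed)
  if (spec$noise_model == "gaussian") {
    flat <- flat + matrix(rnorm(length(flat), 0, noise_sd), nrow = nrow(flat))
  } else {
    n1 <- matrix(rnorm(length(flat), 0, noise_sd), nrow = nrow(flat))
    n2 <- matrix(rnorm(length(flat), 0, noise_sd), nrow = nrow(flat))
    flat <- sqrt((flat + n1)^2 + n2^2)
  }
  data <- array(pmax(flat, 0), c(d, nf))

  for (f in spec$artifact_frames) {
    stopifnot(f >= 1, f <= nf)
    data[, , , f] <- .corrupt_frame(data[, , , f])
  }

  dce_series(data, dt = spec$dt, n_precontrast = spec$n_precontrast,
             voxel_spacing = spec$voxel_spacing)
}

#' Generate a reproducible two-visit phantom cohort
#'
#' Each subject gets an independent phantom (own defect geometry, defect
#' fraction, per-scan AIF measurement error) and two visits with identical
#' ground truth but fresh noise. Per-subject scalar covariates emulating a
#' visual perfusion score (0-12, increasing with defect extent) and
#' FEV1 percent predicted (decreasing with defect extent) are generated from
#' the ground-truth QDP.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer master seed.
#' @param spec_sampler Optional `function(i)` returning the [phantom_spec()]
#'   for subject `i`; it is called with the subject-specific RNG state
#'   already set. The default samples `defect_fraction ~ U(0.1, 0.5)` and
#'   per-scan `aif_scale_error ~ U(0.8, 1.2)` at otherwise default settings.
#' @return A list of class `phantom_cohort`: per subject a list with
#'   `spec`, `truth`, `visit1`, `visit2`, `score`, `fev1_pct`; plus an
#'   attribute-free `manifest` data frame accessor via `attr(x, "manifest")`.
#' @export
make_cohort <- function(n_subjects, seed = 1L, spec_sampler = NULL) {
  stopifnot(n_subjects >= 1)
  if (is.null(spec_sampler)) {
    spec_sampler <- function(i) {
      phantom_spec(defect_fraction = runif(1, 0.1, 0.5),
                   aif_scale_error = runif(2, 0.8, 1.2),
                   rng_seed = seed + 1000L + i)
    }
  }
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    set.seed(seed + i)
    sp <- spec_sampler(i)
    tr <- make_phantom_truth(sp)
    v1 <- synthesize_visit(sp, tr, 1L)
    v2 <- synthesize_visit(sp, tr, 2L)
    set.seed(seed + 20000L + i)
    score <- min(12, max(0, round(0.25 * tr$qdp_truth + rnorm(1, 0, 1.5))))
    fev1 <- max(15, 95 - 0.9 * tr$qdp_truth + rnorm(1, 0, 8))
    subjects[[i]] <- list(subject_id = sprintf("S%02d", i), spec = sp,
                          truth = tr, visit1 = v1, visit2 = v2,
                          score = score, fev1_pct = fev1)
  }
  manifest <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    qdp_truth = vapply(subjects, function(s) s$truth$qdp_truth, 0),
    score = vapply(subjects, `[[`, 0, "score"),
    fev1_pct = vapply(subjects, `[[`, 0, "fev1_pct"))
  structure(subjects, manifest = manifest, class = "phantom_cohort")
}
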