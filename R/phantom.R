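# Numerical vein/nucleus phantom: geometry, forward simulation of the
# acquired complex image, and the reference map / ROI definitions used for
# quantitative evaluation.

GAMMA_HZ_PER_T <- 42.576e6 # proton gyromagnetic ratio / 2pi

#' Phase scaling between field (ppm) and radians
#'
#' Radians of gradient-echo phase accrued per ppm of fractional field shift:
#' `2 * pi * 42.576e6 * B0 * TE * 1e-6`.
#'
#' @param b0 main field strength in Tesla.
#' @param te echo time in seconds.
#' @return Scalar, radians per ppm.
#' @export
phase_scaling <- function(b0, te) 2 * pi * GAMMA_HZ_PER_T * b0 * te * 1e-6

#' Phantom specification
#'
#' Declarative geometry of the numerical brain phantom: an ellipsoidal brain
#' (susceptibility 0 ppm, magnitude 1), four spherical deep-gray nuclei
#' (0.05/0.1/0.15/0.2 ppm, magnitude 0.7, the 0.2-ppm nucleus largest) and
#' 36 cylindrical veins covering every combination of susceptibility
#' (0.1/0.2/0.3 ppm), diameter (0.25/0.5/0.7 mm) and angle to B0
#' (0/30/60/90 degrees), with magnitude 1. Acquisition constants: B0 = 3 T
#' along z, TE = 20 ms, brain SNR 30, factor-2 complex-image shrink.
#'
#' The default is a scaled phantom on a 128^3 high-resolution grid at
#' 0.25 mm (64^3 working grid at 0.5 mm after shrinking); `full = TRUE`
#' reproduces the 800 x 640 x 640 study dimensions. Nuclei sit in one
#' coronal slab and vein groups on a 3 x 3 in-plane grid in a second slab,
#' one group per (diameter, susceptibility) pair with its four angles
#' stacked along y; all placement scales with the field of view. Vein
#' centres are snapped to high-resolution voxel centres so the thinnest
#' (sub-voxel) veins rasterize to at least one voxel per cross-section.
#'
#' @param n high-resolution grid size (integer triple).
#' @param voxel_size high-resolution voxel size in mm.
#' @param shrink integer shrink factor from model to working grid.
#' @param b0 field strength (T).
#' @param te echo time (s).
#' @param snr signal-to-noise ratio of the complex image in the brain.
#' @param nucleus_chi nucleus susceptibilities in ppm (ascending).
#' @param vein_chi,vein_diam,vein_theta vein susceptibilities (ppm),
#'   diameters (mm) and angles to B0 (degrees); all combinations are built.
#' @param vein_len vein length in mm before geometry scaling (default 7,
#'   the longest the group layout accommodates inside the brain ellipsoid;
#'   veins are much longer than thick, as in real cortical venous anatomy).
#' @param magnitude_nucleus magnitude value inside nuclei.
#' @param artifact_dir_a,artifact_dist_a direction (degrees from B0 in the
#'   x-z plane) and distance (mm from the nucleus surface, before geometry
#'   scaling) of artifact ROI (A), fixed on the magic-angle streak cone of
#'   the largest nucleus where the TKD-only artifact is strongest.
#' @param artifact_dir_b,artifact_dist_b direction and distance of artifact
#'   ROI (B), fixed where the residual artifact is weak and near-identical
#'   across methods.
#' @param full if `TRUE`, use the full-size 800 x 640 x 640 grid.
#' @return A `phantom_spec`: list with grid constants and `brain`, `nuclei`,
#'   `veins` geometry tables.
#' @export
phantom_spec <- function(n = c(128, 128, 128), voxel_size = 0.25, shrink = 2,
                         b0 = 3, te = 0.02, snr = 30,
                         nucleus_chi = c(0.05, 0.1, 0.15, 0.2),
                         vein_chi = c(0.1, 0.2, 0.3),
                         vein_diam = c(0.25, 0.5, 0.7),
                         vein_theta = c(0, 30, 60, 90),
                         vein_len = 7,
                         magnitude_nucleus = 0.7,
                         artifact_dir_a = 54.7, artifact_dist_a = 2.0,
                         artifact_dir_b = 156, artifact_dist_b = 5.7,
                         full = FALSE) {
  if (full) n <- c(800, 640, 640)
  n <- as.integer(n)
  if (length(n) != 3L || any(n < 8L)) stop("n must be three integers >= 8")
  if (shrink < 1 || any(n %% shrink != 0)) {
    stop("shrink must divide every grid dimension")
  }
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (snr <= 0) stop("snr must be positive")
  if (te <= 0) stop("te must be positive")

  fov <- n * voxel_size
  ctr <- fov / 2
  # brain ellipsoid: long axis along the largest grid dimension (y for cubes)
  long <- if (n[1] > n[2]) 1L else 2L
  semi <- 0.4375 * fov
  semi[long] <- 0.469 * fov[long]
  s <- min(fov) / 32 # geometry scale relative to the 32-mm design

  snap <- function(x, v) (floor(x / v) + 0.5) * v # to hi-res voxel centres

  # nuclei: 2 x 2 layout in a coronal (constant-y) slab
  nx <- ctr[1] + c(-4, 4, -4, 4) * s
  nz <- ctr[3] + c(-4, -4, 4, 4) * s
  ny <- rep(ctr[2] - 0.25 * fov[2], 4)
  nucleus_chi <- sort(nucleus_chi)
  nuclei <- data.frame(
    x = snap(nx, voxel_size[1]), y = snap(ny, voxel_size[2]),
    z = snap(nz, voxel_size[3]),
    r = c(2.2, 2.2, 2.2, 3.0) * s,
    chi = nucleus_chi
  )

  # veins: 3 x 3 groups of (diam, chi) in-plane; four angles per group
  # stacked along y. The angle-to-y assignment is rotated per group so that
  # same-angle veins of adjacent groups never share a coronal plane and
  # tip-to-tip overlaps are impossible.
  gpos <- c(-6.4, 0, 6.4) * s
  yoff <- c(-3, -1, 1, 3) * s
  veins <- do.call(rbind, lapply(seq_along(vein_diam), function(i) {
    do.call(rbind, lapply(seq_along(vein_chi), function(j) {
      rot <- (i + j) %% length(vein_theta)
      ord <- ((seq_along(vein_theta) - 1 + rot) %% length(vein_theta)) + 1
      data.frame(
        x = snap(ctr[1] + gpos[i], voxel_size[1]),
        y = snap(ctr[2] + yoff, voxel_size[2]),
        z = snap(ctr[3] + gpos[j], voxel_size[3]),
        theta = vein_theta[ord],
        diam = vein_diam[i],
        chi = vein_chi[j],
        len = vein_len * s
      )
    }))
  }))
  rownames(veins) <- NULL

  spec <- structure(list(
    n = n, voxel_size = voxel_size, shrink = as.integer(shrink),
    b0 = b0, te = te, snr = snr,
    brain = list(center = ctr, semi = semi),
    nuclei = nuclei, veins = veins,
    magnitude_nucleus = magnitude_nucleus,
    artifact_dir_a = artifact_dir_a, artifact_dist_a = artifact_dist_a * s,
    artifact_dir_b = artifact_dir_b, artifact_dist_b = artifact_dist_b * s,
    geom_scale = s
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  inside <- function(p, margin = 0) {
    semi <- pmax(spec$brain$semi - margin, 1e-9)
    sum(((p - spec$brain$center) / semi)^2) <= 1
  }
  for (i in seq_len(nrow(spec$nuclei))) {
    nc <- unlist(spec$nuclei[i, c("x", "y", "z")])
    if (!inside(nc, spec$nuclei$r[i])) {
      stop("nucleus ", i, " extends outside the brain ellipsoid")
    }
  }
  for (i in seq_len(nrow(spec$veins))) {
    v <- spec$veins[i, ]
    u <- c(sin(v$theta * pi / 180), 0, cos(v$theta * pi / 180))
    for (e in c(-1, 1)) {
      p <- c(v$x, v$y, v$z) + e * u * v$len / 2
      if (!inside(p, v$diam / 2)) {
        stop("vein ", i, " extends outside the brain ellipsoid")
      }
    }
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d x %d x %d @ %.2g mm (shrink %d), B0 = %g T, TE = %g ms, SNR = %g\n",
    x$n[1], x$n[2], x$n[3], x$voxel_size[1], x$shrink, x$b0, x$te * 1e3, x$snr
  ))
  cat(sprintf("  %d nuclei, %d veins\n", nrow(x$nuclei), nrow(x$veins)))
  invisible(x)
}

# ellipsoid indicator on the hi-res grid, optional semi-axis shrink (mm)
ellipsoid_mask <- function(n, voxel_size, center, semi, margin = 0) {
  cx <- ((seq_len(n[1]) - 0.5) * voxel_size[1] - center[1]) / (semi[1] - margin)
  cy <- ((seq_len(n[2]) - 0.5) * voxel_size[2] - center[2]) / (semi[2] - margin)
  cz <- ((seq_len(n[3]) - 0.5) * voxel_size[3] - center[3]) / (semi[3] - margin)
  q <- array(cx^2, n)
  q <- q + array(rep(cy^2, each = n[1]), n)
  q <- q + array(rep(cz^2, each = n[1] * n[2]), n)
  q <= 1
}

#' Rasterize the phantom geometry
#'
#' Voxelizes the susceptibility and magnitude models by point-in-primitive
#' tests at voxel centres; later primitives override earlier ones (nuclei
#' override brain, veins override everything). Sub-voxel veins therefore
#' carry rasterization errors of up to one voxel, as in any discrete model.
#'
#' @param spec a [phantom_spec()].
#' @return List with `chi` and `magnitude` volumes (`vol3d`, high-resolution
#'   grid, ppm / dimensionless) and the logical `brain` indicator array.
#' @export
rasterize_phantom <- function(spec) {
  n <- spec$n
  v <- spec$voxel_size
  chi <- array(0, n)
  brain <- ellipsoid_mask(n, v, spec$brain$center, spec$brain$semi)
  mag <- array(0, n)
  mag[brain] <- 1

  xs <- (seq_len(n[1]) - 0.5) * v[1]
  ys <- (seq_len(n[2]) - 0.5) * v[2]
  zs <- (seq_len(n[3]) - 0.5) * v[3]
  clamp_idx <- function(lo, hi, n) {
    lo <- max(1L, lo); hi <- min(n, hi)
    if (lo > hi) integer(0) else lo:hi
  }
  box <- function(c0, half, axis) {
    clamp_idx(floor((c0 - half) / v[axis]) + 1L,
              ceiling((c0 + half) / v[axis]), n[axis])
  }

  for (i in seq_len(nrow(spec$nuclei))) {
    nc <- spec$nuclei[i, ]
    ix <- box(nc$x, nc$r + v[1], 1L)
    iy <- box(nc$y, nc$r + v[2], 2L)
    iz <- box(nc$z, nc$r + v[3], 3L)
    dx2 <- (xs[ix] - nc$x)^2
    dy2 <- (ys[iy] - nc$y)^2
    dz2 <- (zs[iz] - nc$z)^2
    sub <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= nc$r^2
    chi[ix, iy, iz][sub] <- nc$chi
    mag[ix, iy, iz][sub] <- spec$magnitude_nucleus
  }

  for (i in seq_len(nrow(spec$veins))) {
    vn <- spec$veins[i, ]
    u <- c(sin(vn$theta * pi / 180), 0, cos(vn$theta * pi / 180))
    r <- vn$diam / 2
    half <- abs(u) * vn$len / 2 + r + v
    ix <- box(vn$x, half[1], 1L)
    iy <- box(vn$y, half[2], 2L)
    iz <- box(vn$z, half[3], 3L)
    dx <- xs[ix] - vn$x
    dy <- ys[iy] - vn$y
    dz <- zs[iz] - vn$z
    nsub <- c(length(ix), length(iy), length(iz))
    px <- array(dx, nsub)
    py <- array(rep(dy, each = nsub[1]), nsub)
    pz <- array(rep(dz, each = nsub[1] * nsub[2]), nsub)
    t <- px * u[1] + py * u[2] + pz * u[3]
    rad2 <- px^2 + py^2 + pz^2 - t^2
    sub <- abs(t) <= vn$len / 2 & rad2 <= r^2
    chi[ix, iy, iz][sub] <- vn$chi
    mag[ix, iy, iz][sub] <- 1
  }

  list(
    chi = vol3d(chi, v), magnitude = vol3d(mag, v), brain = brain
  )
}

#' Simulate the gradient-echo phase of a susceptibility model
#'
#' Applies the forward dipole model and converts the fractional field shift
#' to phase: `phi(r) = 2 pi gamma B0 TE delta(r)` with `delta` in absolute
#' units (input susceptibility is in ppm). Positive susceptibility along B0
#' gives positive phase (sign convention recorded here once; the inversion
#' routines assume the same).
#'
#' @param chi susceptibility volume in ppm.
#' @param b0 field strength (T).
#' @param te echo time (s).
#' @return Phase volume in radians (same type as input).
#' @export
simulate_phase <- function(chi, b0, te) {
  if (te <= 0) stop("te must be positive")
  delta <- forward_field(chi)
  vol_like(vol_data(delta) * phase_scaling(b0, te), chi)
}

#' Shrink a complex image by Fourier cropping
#'
#' Downsamples the complex image `m * exp(i phi)` by keeping the central
#' k-space block (band-limited acquisition analogue) and re-extracting
#' magnitude and phase. The DC value (and hence any uniform image) is
#' preserved exactly.
#'
#' @param magnitude,phase volumes on the same grid (phase in radians).
#' @param factor integer shrink factor; must divide every dimension.
#' @return List with downsampled `magnitude` and `phase` volumes; voxel
#'   size grows by `factor`.
#' @export
shrink_complex <- function(magnitude, phase, factor) {
  m <- vol_data(magnitude)
  p <- vol_data(phase)
  if (!all(dim(m) == dim(p))) stop("magnitude and phase shapes differ")
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(list(magnitude = magnitude, phase = phase))
  d <- dim(m)
  if (any(d %% factor != 0)) {
    stop("shrink factor must divide every dimension")
  }
  dn <- d %/% factor
  keep <- lapply(seq_len(3L), function(a) {
    c(1:(dn[a] / 2), (d[a] - dn[a] / 2 + 1):d[a])
  })
  cc <- fft3(m * exp(1i * p))
  cc <- cc[keep[[1]], keep[[2]], keep[[3]]] * (prod(dn) / prod(d))
  small <- ifft3(cc)
  vsz <- vox_of(magnitude) * factor
  list(
    magnitude = vol_like(Mod(small), magnitude, vsz),
    phase = vol_like(Arg(small), phase, vsz)
  )
}

#' Add complex Gaussian noise at a target brain SNR
#'
#' Independent Gaussian noise of standard deviation
#' `mean(magnitude in brain) / snr` is added to the real and imaginary
#' channels of the complex image, matching the MRI noise model in which SNR
#' is defined on the complex signal. Magnitude and phase are re-extracted.
#'
#' @param magnitude,phase working-grid volumes.
#' @param snr target signal-to-noise ratio (> 0); `Inf` returns the inputs.
#' @param seed integer seed for reproducibility (`NULL` to leave the RNG
#'   state alone).
#' @param brain_mask logical/0-1 array marking brain voxels for the signal
#'   mean; defaults to `magnitude > 0.5`.
#' @return List with noisy `magnitude` and `phase`.
#' @export
add_noise <- function(magnitude, phase, snr, seed = NULL, brain_mask = NULL) {
  m <- vol_data(magnitude)
  p <- vol_data(phase)
  if (snr <= 0) stop("snr must be positive")
  if (is.infinite(snr)) return(list(magnitude = magnitude, phase = phase))
  if (is.null(brain_mask)) brain_mask <- m > 0.5
  sdev <- mean(m[as.logical(brain_mask)]) / snr
  if (!is.null(seed)) set.seed(as.integer(seed))
  nvox <- length(m)
  cc <- m * exp(1i * p) +
    complex(real = stats::rnorm(nvox, sd = sdev),
            imaginary = stats::rnorm(nvox, sd = sdev))
  dim(cc) <- dim(m)
  list(
    magnitude = vol_like(Mod(cc), magnitude),
    phase = vol_like(Arg(cc), phase)
  )
}

#' Reference susceptibility map
#'
#' Block-average downsampling of the high-resolution susceptibility model.
#' Unlike Fourier cropping this preserves partial volumes without ringing,
#' which is what the evaluation ROIs compare against; the total
#' susceptibility sum is conserved exactly (up to the factor^3 volume
#' ratio).
#'
#' @param chi_model high-resolution susceptibility volume (ppm).
#' @param factor integer shrink factor dividing every dimension.
#' @return Working-grid reference volume (ppm).
#' @export
make_reference <- function(chi_model, factor) {
  arr <- vol_data(chi_model)
  vol_like(block_mean(arr, as.integer(factor)), chi_model,
           vox_of(chi_model) * factor)
}

#' Evaluation ROIs on the working grid
#'
#' Builds the ROI set used for quantitative evaluation:
#' \itemize{
#'   \item 9 vein ROIs, one per (diameter, susceptibility) pair, pooling the
#'     four vein angles; voxels near each vein axis whose reference value
#'     exceeds a threshold, excluding the vein-centre slice and both end
#'     caps. The threshold is half the nominal vein susceptibility, capped
#'     at half the peak reference value within the vein neighbourhood so
#'     that sub-voxel veins (whose partial-volume reference never reaches
#'     `chi_v / 2`) still yield a non-empty ROI.
#'   \item 4 nucleus ROIs (eroded interiors), for the regression slope.
#'   \item 1 brain ROI in coronal slices free of any tissue structure.
#'   \item 2 artifact ROIs of 5 x 5 in-plane voxels near the largest
#'     (0.2 ppm) nucleus, at the direction/distance offsets recorded in the
#'     spec: (A) on the magic-angle streak cone at 54.7 deg from B0 where
#'     the TKD-only streak is strongest, (B) where the residual artifact is
#'     weak and shared by all methods.
#' }
#' An ROI that ends up empty is dropped with a warning.
#'
#' @param reference working-grid reference volume from [make_reference()].
#' @param spec the [phantom_spec()] the reference was built from.
#' @return A `roi_set`: list of integer index vectors (`vein` and `nucleus`
#'   are named lists).
#' @export
make_rois <- function(reference, spec) {
  ref <- vol_data(reference)
  nw <- spec$n %/% spec$shrink
  if (!all(dim(ref) == nw)) stop("reference grid does not match the spec")
  vw <- spec$voxel_size * spec$shrink
  xs <- (seq_len(nw[1]) - 0.5) * vw[1]
  ys <- (seq_len(nw[2]) - 0.5) * vw[2]
  zs <- (seq_len(nw[3]) - 0.5) * vw[3]

  vein_keys <- unique(spec$veins[, c("diam", "chi")])
  vein_rois <- list()
  for (i in seq_len(nrow(vein_keys))) {
    dv <- vein_keys$diam[i]
    cv <- vein_keys$chi[i]
    group <- spec$veins[spec$veins$diam == dv & spec$veins$chi == cv, ]
    cand <- integer(0)
    for (j in seq_len(nrow(group))) {
      vn <- group[j, ]
      u <- c(sin(vn$theta * pi / 180), 0, cos(vn$theta * pi / 180))
      r <- vn$diam / 2
      half <- abs(u) * vn$len / 2 + r + 2 * max(vw)
      ix <- which(abs(xs - vn$x) <= half[1])
      iy <- which(abs(ys - vn$y) <= half[2])
      iz <- which(abs(zs - vn$z) <= half[3])
      if (!length(ix) || !length(iy) || !length(iz)) next
      nsub <- c(length(ix), length(iy), length(iz))
      px <- array(xs[ix] - vn$x, nsub)
      py <- array(rep(ys[iy] - vn$y, each = nsub[1]), nsub)
      pz <- array(rep(zs[iz] - vn$z, each = nsub[1] * nsub[2]), nsub)
      t <- px * u[1] + py * u[2] + pz * u[3]
      rad2 <- px^2 + py^2 + pz^2 - t^2
      ok <- rad2 <= (r + max(vw))^2 &
        abs(t) <= 0.35 * vn$len &        # drop both end caps
        abs(t) >= 0.75 * max(vw)         # drop the centre slice
      if (!any(ok)) next
      gi <- as.matrix(expand.grid(ix, iy, iz))[as.vector(ok), , drop = FALSE]
      cand <- c(cand, gi[, 1] + (gi[, 2] - 1) * nw[1] +
                  (gi[, 3] - 1) * nw[1] * nw[2])
    }
    cand <- unique(cand)
    thr <- min(cv / 2, 0.5 * max(ref[cand], 0))
    roi <- cand[ref[cand] > thr]
    key <- sprintf("d%.2f_chi%.2f", dv, cv)
    if (!length(roi)) {
      warning("vein ROI ", key, " is empty after thresholding")
    } else {
      vein_rois[[key]] <- roi
    }
  }

  nucleus_rois <- list()
  for (i in seq_len(nrow(spec$nuclei))) {
    nc <- spec$nuclei[i, ]
    ix <- which((rep(xs, times = nw[2] * nw[3]) - nc$x)^2 +
                  (rep(rep(ys, each = nw[1]), times = nw[3]) - nc$y)^2 +
                  (rep(zs, each = nw[1] * nw[2]) - nc$z)^2 <= (0.7 * nc$r)^2)
    nucleus_rois[[sprintf("chi%.2f", nc$chi)]] <- ix
  }

  # tissue-free coronal slices, beyond the vein slab, well inside the brain
  tissue_ymax <- max(spec$veins$y + spec$veins$diam / 2,
                     spec$nuclei$y + spec$nuclei$r)
  iy_free <- which(ys > tissue_ymax + 2 * spec$geom_scale)
  brain_w <- ellipsoid_mask(nw, vw, spec$brain$center,
                            0.85 * spec$brain$semi)
  sel <- array(FALSE, nw)
  sel[, iy_free, ] <- TRUE
  brain_roi <- which(brain_w & sel)
  if (!length(brain_roi)) warning("brain ROI is empty")

  big <- spec$nuclei[which.max(spec$nuclei$chi), ]
  patch <- function(center_mm) {
    ci <- pmin(pmax(round(center_mm / vw + 0.5), 3), nw - 2)
    ix <- (ci[1] - 2):(ci[1] + 2)
    iz <- (ci[3] - 2):(ci[3] + 2)
    gi <- as.matrix(expand.grid(ix, ci[2], iz))
    gi[, 1] + (gi[, 2] - 1) * nw[1] + (gi[, 3] - 1) * nw[1] * nw[2]
  }
  ray <- function(deg) c(sin(deg * pi / 180), 0, cos(deg * pi / 180))
  roi_a <- patch(c(big$x, big$y, big$z) +
                   ray(spec$artifact_dir_a) * (big$r + spec$artifact_dist_a))
  roi_b <- patch(c(big$x, big$y, big$z) +
                   ray(spec$artifact_dir_b) * (big$r + spec$artifact_dist_b))

  structure(list(
    vein = vein_rois, nucleus = nucleus_rois, brain = brain_roi,
    artifact = list(A = roi_a, B = roi_b)
  ), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf(
    "<roi_set> %d vein, %d nucleus ROIs; brain ROI %d voxels; artifact ROIs %d/%d voxels\n",
    length(x$vein), length(x$nucleus), length(x$brain),
    length(x$artifact$A), length(x$artifact$B)
  ))
  invisible(x)
}

#' Simulate a complete phantom acquisition
#'
#' Runs the whole synthetic pipeline: rasterize the model, compute the
#' forward dipole field and phase at high resolution, shrink the complex
#' image to the working grid, add complex noise at the target SNR, and
#' derive the local field map (ppm), brain mask, reference map and ROIs.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer noise seed.
#' @return List with working-grid volumes `delta` (local field, ppm),
#'   `magnitude`, `phase`, `brain_mask` (0/1 array), `reference`, the
#'   `roi_set` in `rois`, and the originating `spec`.
#' @export
simulate_acquisition <- function(spec, seed = 1L) {
  ras <- rasterize_phantom(spec)
  ph <- simulate_phase(ras$chi, spec$b0, spec$te)
  sc <- shrink_complex(ras$magnitude, ph, spec$shrink)
  bmask <- (block_mean(ras$brain + 0, spec$shrink) >= 0.5) + 0
  noisy <- add_noise(sc$magnitude, sc$phase, spec$snr, seed = seed,
                     brain_mask = bmask)
  delta <- vol_data(noisy$phase) / phase_scaling(spec$b0, spec$te)
  reference <- make_reference(ras$chi, spec$shrink)
  rois <- make_rois(reference, spec)
  vw <- spec$voxel_size * spec$shrink
  list(
    delta = vol3d(delta, vw), magnitude = noisy$magnitude,
    phase = noisy$phase, brain_mask = bmask, reference = reference,
    rois = rois, spec = spec
  )
}
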