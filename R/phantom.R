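#' Specify a synthetic vascular phantom
#'
#' Defines the geometry, vessel population and noise model of a ground-truthed
#' 3D angiographic phantom. Defaults emulate a 600 x 600 x 400 um patch of
#' mouse somatosensory cortex at 2-um isotropic voxel pitch: a few large
#' (>20 um) vessels weighted toward the surface, medium (15-20 um) arterioles,
#' and a capillary population whose true diameters follow a lognormal law with
#' mean 6.2 um and SD 1.3 um. Voxel values are on the decorrelation scale
#' [0, 1]: a dark extravascular speckle floor, bright tubular lumina, a
#' multiple-scattering "tail" of signal extending axially below each vessel,
#' and a tilted cortical surface.
#'
#' @param domain_um lateral x lateral x depth extent of the tissue block (um).
#' @param voxel_um isotropic voxel pitch (um).
#' @param n_large,n_medium,n_small vessel counts for the >20, 15-20 and <15 um
#'   classes.
#' @param small_diam_mean_um,small_diam_sd_um mean and SD of the (lognormal)
#'   capillary diameter distribution.
#' @param depth_profile per-class depth law: list with entries `large`,
#'   `medium`, `small`, each `c(lo, hi, shape1, shape2)` meaning depth =
#'   lo + (hi - lo) * Beta(shape1, shape2) um below the surface.
#' @param tilt_deg surface tilt about the slow lateral axis (degrees).
#' @param tail_strength initial intensity of the projection tail relative to
#'   the parent vessel, in [0, 1).
#' @param tail_decay_um e-folding depth of the projection tail (um).
#' @param speckle_cv coefficient of variation of the multiplicative speckle.
#' @param bg_level,lumen_level mean decorrelation of extravascular tissue and
#'   of the vessel lumen centerline.
#' @param noise_floor additive (absolute-Gaussian) noise, also present above
#'   the surface.
#' @param air_um axial clearance above the cortical surface (um).
#' @param n_repeats default number of repeated frames per B-scan for
#'   [build_frame_stack()].
#' @param seed RNG seed; identical seeds give byte-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @seealso [build_phantom()], [build_frame_stack()], [build_study()]
#' @export
phantom_spec <- function(domain_um = c(600, 600, 400),
                         voxel_um = 2,
                         n_large = 2, n_medium = 3, n_small = 50,
                         small_diam_mean_um = 6.2,
                         small_diam_sd_um = 1.3,
                         depth_profile = list(
                           large  = c(10, 390, 1.0, 4.0),
                           medium = c(15, 390, 1.2, 2.5),
                           small  = c(20, 390, 1.2, 1.2)),
                         tilt_deg = 2,
                         tail_strength = 0.3,
                         tail_decay_um = 30,
                         speckle_cv = 0.15,
                         bg_level = 0.06,
                         lumen_level = 0.6,
                         noise_floor = 0.002,
                         air_um = 60,
                         n_repeats = 4,
                         seed = 1L) {
  stopifnot(length(domain_um) == 3, all(domain_um > 0), voxel_um > 0)
  counts <- c(n_large, n_medium, n_small)
  if (any(counts < 0)) stop("vessel counts must be >= 0")
  if (tail_strength < 0 || tail_strength >= 1)
    stop("tail_strength must lie in [0, 1)")
  if (small_diam_mean_um < 5)
    stop("small_diam_mean_um must be >= 5 (pipeline inclusion floor)")
  if (speckle_cv < 0) stop("speckle_cv must be >= 0")
  structure(list(
    domain_um = domain_um, voxel_um = voxel_um,
    n_large = n_large, n_medium = n_medium, n_small = n_small,
    small_diam_mean_um = small_diam_mean_um,
    small_diam_sd_um = small_diam_sd_um,
    depth_profile = depth_profile,
    tilt_deg = tilt_deg,
    tail_strength = tail_strength, tail_decay_um = tail_decay_um,
    speckle_cv = speckle_cv, bg_level = bg_level,
    lumen_level = lumen_level, noise_floor = noise_floor,
    air_um = air_um, n_repeats = n_repeats, seed = as.integer(seed)),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %g x %g x %g um @ %g um voxels\n",
              x$domain_um[1], x$domain_um[2], x$domain_um[3], x$voxel_um))
  cat(sprintf("  vessels: %d large / %d medium / %d small (capillary %g +/- %g um)\n",
              x$n_large, x$n_medium, x$n_small,
              x$small_diam_mean_um, x$small_diam_sd_um))
  cat(sprintf("  tilt %g deg, tail %g (decay %g um), speckle CV %g, seed %d\n",
              x$tilt_deg, x$tail_strength, x$tail_decay_um, x$speckle_cv,
              x$seed))
  invisible(x)
}

# deterministic sub-seed derivation; keeps values < 2^31 so set.seed is safe
.derive_seed <- function(root, ...) {
  ix <- c(...)
  s <- (as.double(root) %% 2147483647) + 1
  for (k in seq_along(ix))
    s <- (s * 69621 + (as.double(ix[k]) + 1) * 10007 + k) %% 2147483563
  as.integer(s)
}

.lognorm_pars <- function(m, s) {
  s2 <- log1p((s / m)^2)
  c(mu = log(m) - s2 / 2, sigma = sqrt(s2))
}

# moments of a lognormal truncated to (lo, hi)
.trunc_lnorm_moments <- function(mu, sigma, lo, hi) {
  z <- function(x, k) (log(x) - mu - k * sigma^2) / sigma
  denom <- stats::pnorm(z(hi, 0)) - stats::pnorm(z(lo, 0))
  mk <- function(k) exp(k * mu + k^2 * sigma^2 / 2) *
    (stats::pnorm(z(hi, k)) - stats::pnorm(z(lo, k))) / denom
  m1 <- unname(mk(1)); m2 <- unname(mk(2))
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# lognormal parameters such that the (lo, hi)-truncated distribution has the
# requested mean and SD: the reported capillary statistics describe the
# observed (floor-limited) population, so the truth sampler is calibrated to
# reproduce them within the class limits
.calibrate_lognorm <- function(mean_target, sd_target, lo, hi) {
  start <- .lognorm_pars(mean_target, sd_target)
  obj <- function(p) {
    m <- .trunc_lnorm_moments(p[1], exp(p[2]), lo, hi)
    (m[["mean"]] - mean_target)^2 + (m[["sd"]] - sd_target)^2
  }
  fit <- stats::optim(unname(c(start["mu"], log(start["sigma"]))), obj,
                      control = list(maxit = 500, reltol = 1e-10))
  c(mu = unname(fit$par[1]), sigma = unname(exp(fit$par[2])))
}

# sample vessel geometry for one phantom (flat-frame um coordinates);
# depths are below the (un-tilted) cortical surface
.sample_geometry <- function(spec, seed = spec$seed) {
  set.seed(seed)
  dx <- spec$domain_um[1]; dy <- spec$domain_um[2]; dz <- spec$domain_um[3]
  classes <- rep(c("large", "medium", "small"),
                 c(spec$n_large, spec$n_medium, spec$n_small))
  n <- length(classes)
  if (n == 0) {
    return(data.frame(branch_id = character(), class_group = character(),
                      diameter_um = numeric(), depth_um = numeric(),
                      x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric(),
                      length_um = numeric(), stringsAsFactors = FALSE))
  }
  # truncated lognormal via inverse CDF (no rejection loop)
  rlnorm_trunc <- function(p, lo, hi) {
    u <- runif(1, stats::plnorm(lo, p["mu"], p["sigma"]),
               stats::plnorm(hi, p["mu"], p["sigma"]))
    stats::qlnorm(u, p["mu"], p["sigma"])
  }
  p_large <- .lognorm_pars(30, 9)
  # calibrated so the measurable (>= 5 um) capillary population reproduces
  # the configured mean/SD within the class limits [5, 15)
  p_small <- .calibrate_lognorm(spec$small_diam_mean_um,
                                spec$small_diam_sd_um, 5, 15)
  samp_d <- function(cl) {
    switch(cl,
      large = rlnorm_trunc(p_large, 20, 48),
      medium = runif(1, 15, 20),
      small = rlnorm_trunc(p_small, 5, 15))
  }
  samp_depth <- function(cl) {
    pr <- spec$depth_profile[[cl]]
    d <- pr[1] + (pr[2] - pr[1]) * rbeta(1, pr[3], pr[4])
    min(d, dz - 10)
  }
  samp_len <- function(cl) switch(cl,
    large = 2 * sqrt(dx^2 + dy^2),          # spans the field after clipping
    medium = runif(1, 0.5, 0.9) * max(dx, dy),
    small = runif(1, 80, 200))

  rows <- vector("list", n)
  margin <- 6
  for (i in seq_len(n)) {
    cl <- classes[i]
    d <- samp_d(cl); dep <- samp_depth(cl)
    # place until the in-domain chord is long enough to be measurable
    # (>= 3 diameters), so no vessel is a sub-diameter corner stump
    best <- NULL; best_len <- -1
    for (try in 1:20) {
      len <- samp_len(cl)
      th <- runif(1, 0, pi)
      cx <- runif(1, margin, dx - margin); cy <- runif(1, margin, dy - margin)
      p0 <- c(cx - cos(th) * len / 2, cy - sin(th) * len / 2)
      p1 <- c(cx + cos(th) * len / 2, cy + sin(th) * len / 2)
      seg <- .clip_segment(p0, p1, c(margin, dx - margin),
                           c(margin, dy - margin))
      if (is.null(seg)) next
      seg_len <- sqrt(sum((seg[2, ] - seg[1, ])^2))
      if (seg_len > best_len) { best <- seg; best_len <- seg_len }
      if (seg_len >= max(3 * d, 50)) break
    }
    cl_seg <- best %||% rbind(c(dx / 2, dy / 2), c(dx / 2 + 10, dy / 2))
    rows[[i]] <- data.frame(
      branch_id = sprintf("V%03d", i), class_group = cl,
      diameter_um = d, depth_um = dep,
      x0 = cl_seg[1, 1], y0 = cl_seg[1, 2],
      x1 = cl_seg[2, 1], y1 = cl_seg[2, 2],
      length_um = sqrt(sum((cl_seg[2, ] - cl_seg[1, ])^2)),
      stringsAsFactors = FALSE)
  }
  geom <- do.call(rbind, rows)

  # feasibility: total vessel volume per class vs domain volume
  vol_dom <- dx * dy * dz
  for (cl in unique(geom$class_group)) {
    g <- geom[geom$class_group == cl, ]
    v <- sum(pi * (g$diameter_um / 2)^2 * g$length_um)
    if (v > 0.5 * vol_dom)
      stop(sprintf("vessel count infeasible for domain: class '%s' fills %.0f%% of the volume",
                   cl, 100 * v / vol_dom))
  }
  geom
}

# Liang-Barsky clipping of a 2D segment to [xr] x [yr]; NULL if outside
.clip_segment <- function(p0, p1, xr, yr) {
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (k in 1:2) {
    rng <- if (k == 1) xr else yr
    p <- c(-d[k], d[k]); q <- c(p0[k] - rng[1], rng[2] - p0[k])
    for (j in 1:2) {
      if (abs(p[j]) < 1e-12) { if (q[j] < 0) return(NULL) }
      else {
        t <- q[j] / p[j]
        if (p[j] < 0) { if (t > t1) return(NULL); if (t > t0) t0 <- t }
        else          { if (t < t0) return(NULL); if (t < t1) t1 <- t }
      }
    }
  }
  rbind(p0 + t0 * d, p0 + t1 * d)
}

# ground-truth table (centerlines sampled every ~5 um, flat-frame um coords)
.geometry_truth <- function(geom, diam_factor = 1, drift_um = c(0, 0)) {
  if (nrow(geom) == 0) {
    return(data.frame(branch_id = character(), class_label = character(),
                      true_diameter_um = numeric(), depth_um = numeric(),
                      length_um = numeric(), stringsAsFactors = FALSE))
  }
  f <- rep_len(diam_factor, nrow(geom))
  d <- geom$diameter_um * f
  truth <- data.frame(
    branch_id = geom$branch_id,
    class_label = classify_branch(geom$diameter_um, min_diameter_um = 0),
    true_diameter_um = d,
    depth_um = geom$depth_um,
    length_um = geom$length_um,
    stringsAsFactors = FALSE)
  truth$centerline <- lapply(seq_len(nrow(geom)), function(i) {
    g <- geom[i, ]
    n <- max(2L, ceiling(g$length_um / 5) + 1L)
    t <- seq(0, 1, length.out = n)
    cbind(x_um = g$x0 + t * (g$x1 - g$x0) + drift_um[1],
          y_um = g$y0 + t * (g$y1 - g$y0) + drift_um[2],
          depth_um = rep(g$depth_um, n))
  })
  truth
}

# rasterize the noiseless vessel intensity (flat frame) into a (nz, ny, nx)
# array; Gaussian radial profile whose FWHM equals the true diameter
.render_ideal <- function(geom, spec, diam_factor = 1, drift_um = c(0, 0),
                          bg_level = 0) {
  v <- spec$voxel_um
  nx <- round(spec$domain_um[1] / v); ny <- round(spec$domain_um[2] / v)
  nz <- round((spec$domain_um[3] + spec$air_um) / v)
  f <- rep_len(diam_factor, max(nrow(geom), 1))
  d <- geom$diameter_um * f[seq_len(nrow(geom))]
  seg <- cbind(geom$x0 + drift_um[1], geom$y0 + drift_um[2],
               spec$air_um + geom$depth_um,
               geom$x1 + drift_um[1], geom$y1 + drift_um[2],
               spec$air_um + geom$depth_um,
               d / (2 * sqrt(2 * log(2))),
               rep(spec$lumen_level, nrow(geom)))
  array(.rasterize_tubes_cpp(c(nz, ny, nx), seg, v, bg_level,
                             as.integer(round(spec$air_um / v))),
        c(nz, ny, nx))
}

# multiple-scattering projection tail below each vessel: running maximum of
# tail_strength * intensity above, attenuated by exp(-dz / tail_decay)
.add_tails <- function(vess, spec) {
  if (spec$tail_strength <= 0) return(vess)
  d <- dim(vess)
  decay <- exp(-spec$voxel_um / spec$tail_decay_um)
  array(.add_tails_cpp(vess, d, spec$tail_strength, decay), d)
}

# multiplicative speckle (lognormal, mean 1, given CV); the additive
# detector floor only matters where there is no tissue signal (the air gap)
.apply_noise <- function(ideal, spec) {
  sl <- if (spec$speckle_cv > 0) sqrt(log1p(spec$speckle_cv^2)) else 0
  .apply_noise_cpp(ideal, sl, spec$noise_floor)
}

# shear A-lines axially to impose the surface tilt (about the slow axis;
# shift depends on the fast (x) coordinate only); nearest-voxel shifts
.apply_tilt <- function(vol, spec) {
  if (spec$tilt_deg == 0) return(vol)
  dims <- dim(vol); nz <- dims[1]; nx <- dims[3]
  v <- spec$voxel_um
  xs <- (seq_len(nx) - 0.5) * v
  sh <- round(tan(spec$tilt_deg * pi / 180) * (xs - mean(xs)) / v)
  for (k in unique(sh)) {
    cols <- which(sh == k)
    if (k == 0) next
    if (k > 0) {
      vol[(k + 1):nz, , cols] <- vol[1:(nz - k), , cols]
      vol[1:k, , cols] <- spec$noise_floor *
        abs(rnorm(k * dims[2] * length(cols)))
    } else {
      m <- -k
      vol[1:(nz - m), , cols] <- vol[(m + 1):nz, , cols]
      vol[(nz - m + 1):nz, , cols] <- spec$noise_floor *
        abs(rnorm(m * dims[2] * length(cols)))
    }
  }
  vol
}

# render one angiographic volume from a sampled geometry
.render_volume <- function(geom, spec, diam_factor = 1, drift_um = c(0, 0),
                           noise_seed = spec$seed) {
  ideal <- .render_ideal(geom, spec, diam_factor, drift_um,
                         bg_level = spec$bg_level)
  ideal <- .add_tails(ideal, spec)
  v <- spec$voxel_um
  set.seed(noise_seed)
  vol <- array(.apply_noise(ideal, spec), dim(ideal))
  vol <- .apply_tilt(vol, spec)
  angio_volume(vol, voxel_um = rep(v, 3),
               provenance = list(source = "phantom", seed = noise_seed,
                                 tilt_deg = spec$tilt_deg,
                                 air_um = spec$air_um,
                                 drift_um = drift_um))
}

#' Build a ground-truthed synthetic angiographic volume
#'
#' Samples a vessel population from `spec`, rasterizes it as bright tubes with
#' Gaussian radial profiles (profile FWHM equals the true diameter) over a
#' dark speckled tissue background, adds projection tails below vessels,
#' applies multiplicative speckle and surface tilt, and returns both the
#' volume and the exact ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (an [angio_volume()], decorrelation scale
#'   `[0, 1]`, axes z / slow / fast) and `truth` (data frame: `branch_id`,
#'   `class_label`, `true_diameter_um`, `depth_um`, `length_um`, and a
#'   `centerline` list-column of n x 3 matrices in um, flat-frame
#'   coordinates with depth below the true surface).
#' @examples
#' ph <- build_phantom(phantom_spec(domain_um = c(200, 200, 120),
#'                                  n_large = 1, n_medium = 1, n_small = 6,
#'                                  seed = 7))
#' dim(ph$volume); head(ph$truth[, 1:5])
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- .sample_geometry(spec)
  vol <- .render_volume(geom, spec,
                        noise_seed = .derive_seed(spec$seed, 999))
  list(volume = vol, truth = .geometry_truth(geom))
}

#' Build a repeated-frame B-scan amplitude stack from a phantom
#'
#' Emulates the acquisition of N repeated B-scan frames at one slow-axis
#' position: extravascular voxels keep the same speckle realization across
#' repeats (plus small additive noise) while a fraction `intra_vessel_decorr`
#' of intravascular voxels have their speckle redrawn independently each
#' repeat, which is what amplitude-decorrelation angiography detects.
#' Optionally applies a known subpixel inter-frame drift (recorded in the
#' metadata) to exercise registration.
#'
#' @param spec a [phantom_spec()].
#' @param n_repeats number of repeated frames (>= 2).
#' @param intra_vessel_decorr fraction in [0, 1] of lumen speckle redrawn per
#'   repeat.
#' @param shift_px optional `c(dz, dx)` drift in pixels applied cumulatively
#'   between consecutive repeats (via Fourier phase ramp).
#' @param noise_sd SD of the additive frame noise.
#' @return A [frame_stack()]; `meta$true_shifts` holds the applied per-frame
#'   shifts and `meta$lumen_mask` the intravascular mask of the slice.
#' @export
build_frame_stack <- function(spec, n_repeats = spec$n_repeats,
                              intra_vessel_decorr = 1,
                              shift_px = NULL, noise_sd = 0.01) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_repeats < 2) stop("n_repeats must be >= 2 (decorrelation undefined)")
  if (intra_vessel_decorr < 0 || intra_vessel_decorr > 1)
    stop("intra_vessel_decorr must lie in [0, 1]")
  geom <- .sample_geometry(spec)
  v <- spec$voxel_um
  nx <- round(spec$domain_um[1] / v)
  nz <- round((spec$domain_um[3] + spec$air_um) / v)
  cy <- spec$domain_um[2] / 2
  xs <- (seq_len(nx) - 0.5) * v; zs <- (seq_len(nz) - 0.5) * v
  ideal <- matrix(0, nz, nx)
  for (i in seq_len(nrow(geom))) {
    g <- geom[i, ]
    sig <- g$diameter_um / (2 * sqrt(2 * log(2)))
    p0 <- c(g$x0, g$y0, spec$air_um + g$depth_um)
    p1 <- c(g$x1, g$y1, spec$air_um + g$depth_um)
    w <- p1 - p0; L2 <- sum(w^2)
    X <- rep(xs, each = nz); Z <- rep(zs, times = nx)
    tt <- if (L2 < 1e-9) rep(0, length(X)) else
      pmin(1, pmax(0, ((X - p0[1]) * w[1] + (cy - p0[2]) * w[2] +
                       (Z - p0[3]) * w[3]) / L2))
    dd <- (X - p0[1] - tt * w[1])^2 + (cy - p0[2] - tt * w[2])^2 +
          (Z - p0[3] - tt * w[3])^2
    ideal <- pmax(ideal, matrix(spec$lumen_level * exp(-dd / (2 * sig^2)),
                                nz, nx))
  }
  lumen <- ideal > 0.5 * spec$lumen_level
  z1 <- round(spec$air_um / v) + 1
  ideal[z1:nz, ][ideal[z1:nz, ] < spec$bg_level] <- spec$bg_level
  set.seed(.derive_seed(spec$seed, 7))
  sl <- sqrt(log1p(max(spec$speckle_cv, 1e-6)^2))
  s0 <- matrix(exp(rnorm(nz * nx, -sl^2 / 2, sl)), nz, nx)
  frames <- array(0, c(nz, nx, n_repeats))
  true_shifts <- matrix(0, n_repeats, 2,
                        dimnames = list(NULL, c("dz", "dx")))
  for (k in seq_len(n_repeats)) {
    sk <- s0
    if (k > 1 && intra_vessel_decorr > 0) {
      redraw <- lumen & (matrix(runif(nz * nx), nz, nx) < intra_vessel_decorr)
      nr <- sum(redraw)
      if (nr > 0) sk[redraw] <- exp(rnorm(nr, -sl^2 / 2, sl))
    }
    f <- ideal * sk
    if (noise_sd > 0) f <- f + noise_sd * abs(rnorm(nz * nx))
    if (!is.null(shift_px) && k > 1) {
      true_shifts[k, ] <- (k - 1) * shift_px
      f <- pmax(.fourier_shift(f, true_shifts[k, 1], true_shifts[k, 2]), 0)
    }
    frames[, , k] <- f
  }
  frame_stack(frames, pixel_um = c(v, v), position_index = round(cy / v),
              meta = list(true_shifts = true_shifts, lumen_mask = lumen,
                          intra_vessel_decorr = intra_vessel_decorr))
}

#' Define a multi-timepoint dilation scenario
#'
#' Describes the two-dose sonication timeline (`pre`, `post1_1min`,
#' `post1_10min`, `post2_10min`) as per-class multiplicative diameter factors
#' at each timepoint, a replicate (animal) count, and a between-animal SD of
#' the effect.
#'
#' @param effect_by_class named list mapping `"<15"`, `"15-20"`, `">20"` to a
#'   length-4 numeric vector of diameter factors in timeline order; the `pre`
#'   factor must be exactly 1.
#' @param n_animals number of independent replicate phantoms.
#' @param inter_animal_sd SD of the multiplicative animal-level perturbation
#'   of the post-sonication factors (0 = perfectly reproducible effect).
#' @param drift_max_um maximum rigid lateral drift between timepoints (um).
#' @return An object of class `dilation_scenario`.
#' @export
dilation_scenario <- function(effect_by_class, n_animals = 10,
                              inter_animal_sd = 0, drift_max_um = 5) {
  stopifnot(is.list(effect_by_class),
            all(CLASS_LABELS %in% names(effect_by_class)))
  for (cl in CLASS_LABELS) {
    f <- effect_by_class[[cl]]
    if (length(f) != length(TIMEPOINTS))
      stop("each class needs one factor per timepoint")
    if (any(f <= 0)) stop("diameter factors must be > 0")
    if (f[1] != 1) stop("the 'pre' factor must be exactly 1.0")
  }
  if (n_animals < 1) stop("n_animals must be >= 1")
  structure(list(timepoints = TIMEPOINTS,
                 effect_by_class = effect_by_class[CLASS_LABELS],
                 n_animals = n_animals,
                 inter_animal_sd = inter_animal_sd,
                 drift_max_um = drift_max_um),
            class = "dilation_scenario")
}

#' Preset scenarios for the sonication study
#'
#' `scenario_low_intensity()` reproduces the group trajectories reported for
#' the 1 W/cm2 condition (small vessels dilate 17% at 1 min after the first
#' dose, 23% at 10 min, 27% after the second dose; larger classes are null),
#' with a 3% between-animal SD. `scenario_high_intensity()` is the 10 W/cm2
#' analogue (27%/30%/32%, 8% between-animal SD). `scenario_sham()` applies no
#' effect to any class (3 animals).
#'
#' @param n_animals replicate count.
#' @return A [dilation_scenario()].
#' @export
scenario_low_intensity <- function(n_animals = 10) {
  dilation_scenario(list(
    "<15"   = c(1, 1.17, 1.23, 1.27),
    "15-20" = c(1, 1.00, 1.02, 1.01),
    ">20"   = c(1, 1.00, 0.99, 1.00)),
    n_animals = n_animals, inter_animal_sd = 0.03)
}

#' @rdname scenario_low_intensity
#' @export
scenario_high_intensity <- function(n_animals = 10) {
  dilation_scenario(list(
    "<15"   = c(1, 1.27, 1.30, 1.32),
    "15-20" = c(1, 1.02, 1.01, 1.02),
    ">20"   = c(1, 1.02, 1.01, 1.04)),
    n_animals = n_animals, inter_animal_sd = 0.08)
}

#' @rdname scenario_low_intensity
#' @export
scenario_sham <- function(n_animals = 3) {
  one <- c(1, 1, 1, 1)
  dilation_scenario(list("<15" = one, "15-20" = one, ">20" = one),
                    n_animals = n_animals, inter_animal_sd = 0)
}

#' Plan a longitudinal phantom study
#'
#' Samples one independent vessel geometry per animal and derives, for every
#' animal x timepoint, the per-branch diameter factors (class factor times an
#' animal-level perturbation), the rigid lateral drift, and the noise seed.
#' Geometry is fixed across timepoints so branches remain trackable. Volumes
#' are not rendered here; see [render_timepoint()] and [build_study()].
#'
#' @param spec a [phantom_spec()].
#' @param scenario a [dilation_scenario()].
#' @param seed root seed (defaults to `spec$seed`); per-animal seeds are
#'   derived so adding animals never perturbs earlier ones.
#' @return An object of class `study_plan`.
#' @export
study_plan <- function(spec, scenario, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(scenario, "dilation_scenario"))
  animals <- vector("list", scenario$n_animals)
  for (a in seq_len(scenario$n_animals)) {
    geom <- .sample_geometry(spec, seed = .derive_seed(seed, a, 0))
    cls <- classify_branch(geom$diameter_um, min_diameter_um = 0)
    set.seed(.derive_seed(seed, a, 1))
    tps <- list()
    for (t in seq_along(scenario$timepoints)) {
      tp <- scenario$timepoints[t]
      fac_cls <- vapply(scenario$effect_by_class, `[`, numeric(1), t)
      if (tp != "pre" && scenario$inter_animal_sd > 0) {
        pert <- 1 + rnorm(length(fac_cls), 0, scenario$inter_animal_sd)
        fac_cls <- fac_cls * pmax(pert, 0.05)
      }
      drift <- if (tp == "pre") c(0, 0) else
        runif(2, -scenario$drift_max_um, scenario$drift_max_um)
      tps[[tp]] <- list(factors = fac_cls[as.character(cls)],
                        class_factors = fac_cls, drift_um = drift,
                        noise_seed = .derive_seed(seed, a, 10 + t))
    }
    animals[[a]] <- list(geom = geom, timepoints = tps)
  }
  structure(list(spec = spec, scenario = scenario, seed = seed,
                 animals = animals),
            class = "study_plan")
}

#' Render one animal x timepoint volume of a planned study
#'
#' @param plan a [study_plan()].
#' @param animal animal index.
#' @param timepoint timepoint label (see `plan$scenario$timepoints`).
#' @return list with `volume` ([angio_volume()]) and `truth` (as in
#'   [build_phantom()], diameters scaled by the timepoint factors and
#'   centerlines shifted by the drift).
#' @export
render_timepoint <- function(plan, animal, timepoint) {
  stopifnot(inherits(plan, "study_plan"))
  tp <- plan$animals[[animal]]$timepoints[[timepoint]]
  if (is.null(tp)) stop("unknown timepoint: ", timepoint)
  geom <- plan$animals[[animal]]$geom
  vol <- .render_volume(geom, plan$spec, diam_factor = tp$factors,
                        drift_um = tp$drift_um, noise_seed = tp$noise_seed)
  list(volume = vol,
       truth = .geometry_truth(geom, tp$factors, tp$drift_um))
}

#' Truth table of a planned study
#'
#' Per animal x timepoint x branch true diameters, without rendering volumes.
#'
#' @param plan a [study_plan()].
#' @return data frame: `animal`, `timepoint`, `branch_id`, `class_label`,
#'   `true_diameter_um`, `depth_um`.
#' @export
study_truth <- function(plan) {
  out <- list()
  for (a in seq_along(plan$animals)) {
    geom <- plan$animals[[a]]$geom
    cls <- classify_branch(geom$diameter_um, min_diameter_um = 0)
    for (tp in names(plan$animals[[a]]$timepoints)) {
      f <- plan$animals[[a]]$timepoints[[tp]]$factors
      out[[length(out) + 1]] <- data.frame(
        animal = a, timepoint = tp, branch_id = geom$branch_id,
        class_label = as.character(cls),
        true_diameter_um = geom$diameter_um * f,
        depth_um = geom$depth_um, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Build (and optionally write) a full longitudinal phantom study
#'
#' Convenience wrapper around [study_plan()] + [render_timepoint()]. With
#' `dir = NULL` all volumes are returned in memory (only sensible for small
#' phantoms); otherwise each volume is written as a 16-bit multi-page TIFF
#' under `dir` together with the truth table (CSV) and a manifest, and only
#' file names are returned. See [simulate_study()] for the config-driven
#' front end.
#'
#' @inheritParams study_plan
#' @param dir output directory or `NULL`.
#' @return With `dir = NULL`: list with `plan`, `truth` and `volumes` (nested
#'   `[[animal]][[timepoint]]`). Otherwise the `plan` with a `files` table.
#' @export
build_study <- function(spec, scenario, seed = spec$seed, dir = NULL) {
  plan <- study_plan(spec, scenario, seed)
  truth <- study_truth(plan)
  if (is.null(dir)) {
    vols <- lapply(seq_along(plan$animals), function(a)
      sapply(plan$scenario$timepoints, function(tp)
        render_timepoint(plan, a, tp)$volume, simplify = FALSE))
    return(list(plan = plan, truth = truth, volumes = vols))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (a in seq_along(plan$animals)) {
    for (tp in plan$scenario$timepoints) {
      rt <- render_timepoint(plan, a, tp)
      fn <- file.path(dir, sprintf("animal%02d_%s.tif", a, tp))
      write_angio_tiff(rt$volume, fn)
      files[[length(files) + 1]] <- data.frame(
        animal = a, timepoint = tp, file = basename(fn),
        stringsAsFactors = FALSE)
    }
  }
  files <- do.call(rbind, files)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  plan$files <- files
  plan
}
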