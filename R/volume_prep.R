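#' Detect the cortical surface of an angiographic volume
#'
#' For every (slow, fast) A-line, finds the first axial voxel whose axially
#' smoothed intensity exceeds a threshold. The default rule applies Otsu's
#' method to the log-scaled smoothed intensities, which separates the empty
#' gap above the brain from the tissue speckle floor even when superficial
#' vessels are sparse. Columns with no crossing are filled by 2D median
#' interpolation from their neighbours.
#'
#' @param vol an [angio_volume()].
#' @param threshold absolute intensity threshold; `NULL` (default) uses the
#'   log-Otsu rule.
#' @param smooth_z axial boxcar half-width in voxels used before
#'   thresholding.
#' @return Matrix `(slow, fast)` of surface voxel indices (also stored on the
#'   volume by [detilt()]).
#' @export
detect_surface <- function(vol, threshold = NULL, smooth_z = 1) {
  stopifnot(inherits(vol, "angio_volume"))
  d <- dim(vol)
  nz <- d[1]
  arr <- unclass(vol)
  if (is.null(threshold)) {
    # Otsu on log intensities separates the empty gap above the brain from
    # the tissue speckle floor; a voxel subsample is ample for the threshold
    sub <- arr[seq(1, length(arr), length.out = min(length(arr), 2e5))]
    lv <- log10(sub + 1e-4)
    rng <- range(lv)
    if (diff(rng) < 1e-9) stop("surface undetectable: volume has no contrast")
    q <- (lv - rng[1]) / diff(rng)
    th_q <- EBImage::otsu(matrix(q, 1), range = c(0, 1))
    threshold <- 10^(th_q * diff(rng) + rng[1]) - 1e-4
  }
  # first axial index whose (axially smoothed) intensity exceeds the
  # threshold, per A-line; scanning stops once almost every line has crossed
  seen <- matrix(FALSE, d[2], d[3])
  surf <- matrix(NA_integer_, d[2], d[3])
  for (z in seq_len(nz)) {
    zi <- max(1, z - smooth_z):min(nz, z + smooth_z)
    sl <- arr[zi[1], , ]
    for (zz in zi[-1]) sl <- sl + arr[zz, , ]
    newly <- !seen & (sl / length(zi) > threshold)
    if (any(newly)) {
      surf[newly] <- z
      seen <- seen | newly
    }
    if (z > 2 * smooth_z + 2 && mean(seen) > 0.999) break
  }
  miss <- mean(is.na(surf))
  if (miss > 0.5)
    stop(sprintf("surface undetectable: %.0f%% of A-lines have no crossing",
                 100 * miss))
  if (miss > 0) surf <- .fill_na_median(surf)
  surf
}

# fill NA entries of a matrix with the median of non-NA values in a growing
# square neighbourhood (2D median interpolation)
.fill_na_median <- function(m) {
  na <- which(is.na(m), arr.ind = TRUE)
  nr <- nrow(m); nc <- ncol(m)
  glob <- median(m, na.rm = TRUE)
  for (i in seq_len(nrow(na))) {
    r <- na[i, 1]; c <- na[i, 2]
    val <- NA
    for (w in c(2L, 4L, 8L, 16L)) {
      rr <- max(1, r - w):min(nr, r + w)
      cc <- max(1, c - w):min(nc, c + w)
      v <- m[rr, cc]
      if (any(!is.na(v))) { val <- median(v, na.rm = TRUE); break }
    }
    m[r, c] <- if (is.na(val)) glob else val
  }
  m
}

#' De-tilt and flatten a volume to the cortical surface
#'
#' Fits a least-squares plane to the detected surface map and shifts every
#' A-line axially (nearest-voxel resampling at the 2-um axial pitch) so that
#' the fitted plane maps to a constant depth. Afterwards the axial coordinate
#' means "um below the cortical surface" and `surface_z` is stored on the
#' volume.
#'
#' @param vol an [angio_volume()].
#' @param surface optional precomputed surface map from [detect_surface()].
#' @return The flattened `angio_volume` with attributes `surface_z` (constant
#'   map) and `tilt_fit` (fitted plane coefficients, slopes in voxel/voxel).
#' @export
detilt <- function(vol, surface = NULL) {
  stopifnot(inherits(vol, "angio_volume"))
  if (is.null(surface)) surface <- detect_surface(vol)
  d <- dim(vol)
  if (d[2] < 2 && d[3] < 2) stop("plane fit rank-deficient")
  ys <- rep(seq_len(d[2]), times = d[3])
  xs <- rep(seq_len(d[3]), each = d[2])
  fit <- lm(as.vector(surface) ~ ys + xs)
  if (any(is.na(coef(fit)))) stop("plane fit rank-deficient")
  plane <- matrix(fitted(fit), d[2], d[3])
  z0 <- round(median(plane))
  shift <- round(plane) - z0 # positive: surface deeper, pull up
  out <- unclass(vol)
  nz <- d[1]
  sh <- as.integer(shift)
  # the tilt is a plane, so shifts group into a handful of integer levels;
  # shift whole (z, column) blocks at once. Columns here are A-lines of the
  # flattened (nz x n_lines) view.
  if (any(sh != 0L)) {
    dim(out) <- c(nz, d[2] * d[3])
    src <- out
    for (k in setdiff(unique(sh), 0L)) {
      cols <- which(sh == k)
      if (k > 0) {
        out[1:(nz - k), cols] <- src[(k + 1):nz, cols]
        out[(nz - k + 1):nz, cols] <-
          matrix(rep(src[nz, cols], each = k), k, length(cols))
      } else {
        m <- -k
        out[(m + 1):nz, cols] <- src[1:(nz - m), cols]
        out[1:m, cols] <- matrix(rep(src[1, cols], each = m), m,
                                 length(cols))
      }
    }
    dim(out) <- d
  }
  res <- angio_volume(out, voxel_um = attr(vol, "voxel_um"),
                      surface_z = matrix(z0, d[2], d[3]),
                      provenance = c(attr(vol, "provenance"),
                                     list(detilt = coef(fit), surface_z0 = z0)))
  attr(res, "tilt_fit") <- coef(fit)
  res
}

#' En-face projection over a depth slab
#'
#' Projects a flattened volume onto the lateral plane over the half-open
#' depth slab `[lo_um, hi_um)` below the cortical surface, by per-pixel
#' maximum (default, standard for angiograms) or mean.
#'
#' @param vol a flattened [angio_volume()] (run [detilt()] first).
#' @param lo_um,hi_um slab bounds in um below the surface, `0 <= lo < hi`.
#' @param kind `"max"` or `"mean"`.
#' @return An `enface_image`: matrix `(slow, fast)` with attributes
#'   `depth_range_um`, `projection_kind`, `pixel_um`.
#' @export
project_enface <- function(vol, lo_um = 0, hi_um = 400, kind = c("max", "mean")) {
  stopifnot(inherits(vol, "angio_volume"))
  kind <- match.arg(kind)
  if (!(lo_um >= 0 && lo_um < hi_um)) stop("need 0 <= lo_um < hi_um")
  surf <- attr(vol, "surface_z")
  if (is.null(surf)) stop("volume is not surface-referenced; run detilt()")
  z0 <- surf[1, 1]
  vz <- attr(vol, "voxel_um")[1]
  z_lo <- z0 + floor(lo_um / vz)
  z_hi <- z0 + ceiling(hi_um / vz) - 1L
  z_lo <- max(1L, z_lo); z_hi <- min(dim(vol)[1], z_hi)
  if (z_lo > z_hi) stop("empty depth slab after clipping to the volume")
  d <- dim(vol)
  if (kind == "max") {
    img <- matrix(-Inf, d[2], d[3])
    for (z in z_lo:z_hi) img <- pmax(img, vol[z, , ])
  } else {
    img <- matrix(0, d[2], d[3])
    for (z in z_lo:z_hi) img <- img + vol[z, , ]
    img <- img / (z_hi - z_lo + 1)
  }
  structure(img, class = c("enface_image", "matrix"),
            depth_range_um = c(lo_um, hi_um), projection_kind = kind,
            pixel_um = attr(vol, "voxel_um")[2:3])
}

#' Bin a flattened volume into axial depth slabs
#'
#' Divides the depth axis below the cortical surface into contiguous
#' half-open slabs `[k*bin_um, (k+1)*bin_um)` and returns one en-face
#' projection per slab, for depth-resolved segmentation.
#'
#' @param vol a flattened [angio_volume()].
#' @param bin_um slab thickness in um (default 25).
#' @param max_depth_um analysis depth below the surface (default 400).
#' @param kind projection type passed to [project_enface()].
#' @return list with `bounds` (n x 2 matrix of `[lo, hi)` um) and
#'   `projections` (list of `enface_image`s).
#' @export
bin_axially <- function(vol, bin_um = 25, max_depth_um = 400,
                        kind = "max") {
  if (bin_um <= 0) stop("bin_um must be > 0")
  n <- ceiling(max_depth_um / bin_um)
  bounds <- cbind(lo = (seq_len(n) - 1) * bin_um, hi = seq_len(n) * bin_um)
  projections <- lapply(seq_len(n), function(k)
    project_enface(vol, bounds[k, 1], bounds[k, 2], kind = kind))
  list(bounds = bounds, projections = projections)
}

#' Half-open depth-bin assignment
#'
#' @param depth_um depths in um below the surface.
#' @param bin_um bin width.
#' @return Integer bin index (1-based) such that depth d falls in
#'   `[(k-1)*bin, k*bin)`.
#' @export
depth_bin_index <- function(depth_um, bin_um = 25) {
  if (bin_um <= 0) stop("bin_um must be > 0")
  as.integer(floor(depth_um / bin_um)) + 1L
}
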