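#' Flow-contrast volume container
#'
#' A 3D array of decorrelation values in `[0, 1]`, ordered (z, slow, fast),
#' with voxel pitch, an optional per-(slow, fast) surface depth map (filled by
#' [detect_surface()] / [detilt()]), and a provenance log.
#'
#' @param voxels 3D numeric array `(z, slow, fast)`.
#' @param voxel_um length-3 pitch `(z, slow, fast)` in um.
#' @param surface_z optional matrix `(slow, fast)` of surface voxel indices.
#' @param provenance named list of processing notes.
#' @return An `angio_volume` (the array with attributes).
#' @export
angio_volume <- function(voxels, voxel_um = c(2, 2, 2), surface_z = NULL,
                         provenance = list()) {
  stopifnot(length(dim(voxels)) == 3, length(voxel_um) == 3)
  if (min(voxels) < -1e-9 || max(voxels) > 1 + 1e-9)
    stop("decorrelation values must lie in [0, 1]")
  structure(voxels, class = "angio_volume",
            voxel_um = as.numeric(voxel_um), surface_z = surface_z,
            provenance = provenance)
}

#' @export
print.angio_volume <- function(x, ...) {
  d <- dim(x); v <- attr(x, "voxel_um")
  cat(sprintf("angio_volume %d x %d x %d (z x slow x fast), voxel %g x %g x %g um\n",
              d[1], d[2], d[3], v[1], v[2], v[3]))
  cat(sprintf("  values in [%.3f, %.3f]; surface %s\n", min(x), max(x),
              if (is.null(attr(x, "surface_z"))) "not set" else "set"))
  invisible(x)
}

#' Repeated-frame B-scan amplitude stack
#'
#' N co-located 2D amplitude frames (z x fast) acquired at one slow-axis
#' position, the input of amplitude-decorrelation angiography.
#'
#' @param frames 3D array `(z, x, repeat)`, N >= 2, amplitudes >= 0.
#' @param pixel_um `(axial, lateral)` pitch in um.
#' @param position_index slow-axis B-scan index.
#' @param bands optional 4D array `(z, x, repeat, band)` of band-limited
#'   amplitudes from [split_spectrum()].
#' @param meta named list (e.g. known true shifts of synthetic stacks).
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(frames, pixel_um = c(2, 2), position_index = 1L,
                        bands = NULL, meta = list()) {
  stopifnot(length(dim(frames)) == 3)
  if (dim(frames)[3] < 2) stop("a frame stack needs N >= 2 repeats")
  if (min(frames) < 0) stop("amplitudes must be >= 0")
  structure(list(frames = frames, pixel_um = as.numeric(pixel_um),
                 position_index = as.integer(position_index),
                 bands = bands, meta = meta),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d repeats of %d x %d (z x fast), position %d%s\n",
              d[3], d[1], d[2], x$position_index,
              if (is.null(x$bands)) "" else
                sprintf(", %d spectral bands", dim(x$bands)[4])))
  invisible(x)
}

# --- subpixel phase correlation ---------------------------------------------

# shift image content by (dr, dc) pixels (circular) via a Fourier phase ramp
.fourier_shift <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  fr <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1))
  if (nr == 1) fr <- 0
  fc <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1))
  if (nc == 1) fc <- 0
  ramp <- exp(-2i * pi * (outer(fr, rep(1, nc)) * dr / nr +
                          outer(rep(1, nr), fc) * dc / nc))
  Re(fft(fft(img) * ramp, inverse = TRUE)) / (nr * nc)
}

# local upsampled cross-correlation by matrix-multiply DFT
.dftups <- function(R, nor, noc, usfac, roff, coff) {
  nr <- nrow(R); nc <- ncol(R)
  fr <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1))
  if (nr == 1) fr <- 0
  fc <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1))
  if (nc == 1) fc <- 0
  kr <- exp(2i * pi / (nr * usfac) * outer(seq(0, nor - 1) + roff, fr))
  kc <- exp(2i * pi / (nc * usfac) * outer(fc, seq(0, noc - 1) + coff))
  Re(kr %*% R %*% kc)
}

# estimate translation of `mov` relative to `ref`: returns c(dr, dc) such
# that .fourier_shift(ref, dr, dc) best matches mov, plus peak confidence
.phasecorr <- function(ref, mov, upsample = 20) {
  if (sd(ref) == 0 || sd(mov) == 0) stop("no spectral content in frame")
  nr <- nrow(ref); nc <- ncol(ref)
  Fr <- fft(ref); Fm <- fft(mov)
  R <- Fm * Conj(Fr)
  mag <- Mod(R); mag[mag < .Machine$double.eps] <- 1
  Rn <- R / mag
  cc <- Re(fft(Rn, inverse = TRUE)) / (nr * nc)
  pk <- which.max(cc)
  pr <- (pk - 1) %% nr; pc <- (pk - 1) %/% nr
  conf <- max(cc)
  sh <- c(ifelse(pr > nr / 2, pr - nr, pr), ifelse(pc > nc / 2, pc - nc, pc))
  if (upsample > 1) {
    # refine on a 0.05-px-scale grid around the integer peak
    half <- ceiling(1.5 * upsample)
    cc_up <- .dftups(Rn, 2 * half + 1, 2 * half + 1, upsample,
                     sh[1] * upsample - half, sh[2] * upsample - half)
    pk2 <- which(cc_up == max(cc_up), arr.ind = TRUE)[1, ]
    sh <- sh + (pk2 - 1 - half) / upsample
  }
  list(shift = sh, confidence = conf)
}

#' Register repeated frames by subpixel DFT phase correlation
#'
#' Aligns every frame of a stack to the first by phase-correlation
#' translation with local upsampled-DFT refinement, then resamples each frame
#' onto the reference grid via a Fourier phase ramp.
#'
#' @param stack a [frame_stack()].
#' @param upsample subpixel refinement factor (shift resolution
#'   `1/upsample` px).
#' @return The aligned `frame_stack`; `meta$shifts` holds the estimated
#'   per-frame `(dz, dx)` shifts in pixels.
#' @export
register_frames <- function(stack, upsample = 20) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- dim(stack$frames)[3]
  ref <- stack$frames[, , 1]
  if (sd(ref) == 0) stop("no spectral content in frame 1")
  shifts <- matrix(0, n, 2, dimnames = list(NULL, c("dz", "dx")))
  out <- stack$frames
  for (k in 2:n) {
    pc <- .phasecorr(ref, stack$frames[, , k], upsample)
    shifts[k, ] <- pc$shift
    if (any(pc$shift != 0))
      out[, , k] <- pmax(.fourier_shift(stack$frames[, , k],
                                        -pc$shift[1], -pc$shift[2]), 0)
  }
  stack$frames <- out
  stack$meta$shifts <- shifts
  stack
}

#' Split frames into band-limited axial spectral sub-bands
#'
#' Approximates spectral splitting when only amplitude images are available:
#' each frame's axial Fourier spectrum is multiplied by `m_bands` Gaussian
#' windows whose centers tile the axial frequency axis, giving band-limited
#' amplitude images whose per-band decorrelation is later averaged (the
#' split-spectrum step that trades axial resolution for flow SNR). With
#' `m_bands = 1` the frames pass through unchanged.
#'
#' @param stack a [frame_stack()].
#' @param m_bands number of sub-bands (>= 1).
#' @param overlap fractional band overlap in `[0, 1)`; window FWHM is
#'   `(1 + overlap)` times the band spacing.
#' @return The `frame_stack` with a 4D `bands` array `(z, x, repeat, band)`.
#' @export
split_spectrum <- function(stack, m_bands = 4, overlap = 0.5) {
  stopifnot(inherits(stack, "frame_stack"))
  if (m_bands < 1) stop("m_bands must be >= 1")
  if (overlap >= 1 || overlap < 0) stop("overlap must lie in [0, 1)")
  d <- dim(stack$frames)
  if (m_bands == 1) {
    stack$bands <- array(stack$frames, c(d, 1))
    return(stack)
  }
  nz <- d[1]
  f <- c(0:floor((nz - 1) / 2), -(ceiling((nz - 1) / 2):1)) / nz # cycles/px
  spacing <- 0.5 / m_bands
  fwhm <- spacing * (1 + overlap)
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  centers <- (seq_len(m_bands) - 0.5) * spacing
  bands <- array(0, c(d, m_bands))
  for (m in seq_len(m_bands)) {
    # one-sided (analytic) Gaussian window: the complex band-limited signal
    # is an analytic signal whose modulus is a smooth band amplitude, as in
    # true source-spectrum splitting; a symmetric window would yield a real
    # oscillatory signal whose modulus rectifies rather than envelopes
    g <- exp(-(f - centers[m])^2 / (2 * sig^2))
    w <- ifelse(f > 0, 2 * g, ifelse(f == 0, g, 0))
    for (k in seq_len(d[3])) {
      Fz <- stats::mvfft(stack$frames[, , k]) * w
      bands[, , k, m] <- Mod(stats::mvfft(Fz, inverse = TRUE)) / nz
    }
  }
  stack$bands <- bands
  stack$meta$split <- list(m_bands = m_bands, overlap = overlap,
                           centers = centers, sigma = sig)
  stack
}

#' Compute the amplitude-decorrelation image of a frame stack
#'
#' Split-spectrum amplitude decorrelation: with amplitudes `A[m, n]` for band
#' m and repeat n,
#' \deqn{D = 1 - \frac{1}{N-1}\frac{1}{M} \sum_n \sum_m
#'   \frac{A_{mn} A_{m,n+1}}{(A_{mn}^2 + A_{m,n+1}^2)/2}.}
#' Identical consecutive nonzero amplitudes give D = 0; fully independent
#' speckle gives high D. Pixels whose amplitude is zero in all frames are
#' masked to D = 0 (a zero pair contributes perfect correlation, avoiding
#' 0/0).
#'
#' @param stack a [frame_stack()]; if [split_spectrum()] has been applied the
#'   band set is used (M = number of bands), otherwise the raw frames (M = 1).
#' @return 2D matrix of decorrelation values in `[0, 1]`.
#' @export
decorrelate <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  A <- stack$bands %||% array(stack$frames, c(dim(stack$frames), 1))
  d <- dim(A); n_rep <- d[3]; m_bands <- d[4]
  if (n_rep < 2) stop("decorrelation needs N >= 2 repeats")
  acc <- matrix(0, d[1], d[2])
  for (n in seq_len(n_rep - 1)) {
    for (m in seq_len(m_bands)) {
      a1 <- A[, , n, m]; a2 <- A[, , n + 1, m]
      den <- (a1^2 + a2^2) / 2
      r <- a1 * a2 / den
      r[den == 0] <- 1 # zero-amplitude pair: define as perfectly correlated
      acc <- acc + r
    }
  }
  D <- 1 - acc / ((n_rep - 1) * m_bands)
  D[apply(A == 0, c(1, 2), all)] <- 0
  pmin(pmax(D, 0), 1)
}

#' Assemble per-B-scan decorrelation images into a volume
#'
#' @param images list of 2D decorrelation matrices (z x fast), one per
#'   slow-axis position, all the same shape.
#' @param voxel_um `(z, slow, fast)` pitch in um.
#' @param provenance named list merged into the volume's processing log.
#' @return An [angio_volume()] ordered (z, slow, fast).
#' @export
assemble_volume <- function(images, voxel_um = c(2, 2, 2),
                            provenance = list()) {
  stopifnot(is.list(images), length(images) >= 1)
  d1 <- dim(images[[1]])
  for (i in seq_along(images)) {
    if (!identical(dim(images[[i]]), d1))
      stop(sprintf("inconsistent B-scan shape at index %d: %s vs %s", i,
                   paste(dim(images[[i]]), collapse = "x"),
                   paste(d1, collapse = "x")))
  }
  vol <- array(0, c(d1[1], length(images), d1[2]))
  for (i in seq_along(images)) vol[, i, ] <- images[[i]]
  angio_volume(vol, voxel_um = voxel_um,
               provenance = c(provenance, list(n_bscans = length(images))))
}

# --- TIFF I/O ----------------------------------------------------------------

#' Read and write angiographic volumes as multi-page TIFF
#'
#' Volumes are stored as one 16-bit grayscale page per z-slice; decorrelation
#' values in `[0, 1]` map linearly onto the 16-bit range. A JSON sidecar
#' (`<file>.json`) carries voxel pitch and provenance.
#'
#' @param vol an [angio_volume()].
#' @param path output file (`.tif`).
#' @return `write_angio_tiff` returns `path` invisibly; `read_angio_tiff`
#'   returns an [angio_volume()].
#' @export
write_angio_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "angio_volume"))
  pages <- lapply(seq_len(dim(vol)[1]), function(z) {
    m <- vol[z, , ]
    m[m < 0] <- 0; m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  side <- list(voxel_um = attr(vol, "voxel_um"),
               provenance = attr(vol, "provenance"),
               dim = dim(vol))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_angio_tiff
#' @export
read_angio_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(length(pages), dim(pages[[1]]))
  vol <- array(0, d)
  for (z in seq_len(d[1])) vol[z, , ] <- pages[[z]]
  voxel <- c(2, 2, 2); prov <- list(source = path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    voxel <- side$voxel_um %||% voxel
    prov <- c(side$provenance, prov)
  }
  angio_volume(vol, voxel_um = voxel, provenance = prov)
}
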