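#' Diametry parameters
#'
#' @param spacing_um spacing of cross-section lines along the centerline
#'   (um); ~15 lines result for the shortest measurable branches.
#' @param step_um sampling step along each cross-section line (bilinear
#'   interpolation).
#' @param line_len_factor line length as a multiple of the current diameter
#'   estimate.
#' @param line_len_min_um minimum line length (um).
#' @param min_r2 minimum R-squared of the Gaussian fit for a cross-section to
#'   be accepted.
#' @param min_quality minimum accepted fraction of cross-sections for a
#'   branch to be considered measurable.
#' @param junction_margin_factor cross-sections closer to a junction end of
#'   the branch than this multiple of the diameter estimate sample the
#'   overlapping lumina of the joining vessels and are skipped (set 0 to
#'   keep them).
#' @param avg branch average of the accepted per-line FWHMs: `"median"`
#'   (default; robust, since speckle skews single-line FWHMs to the right)
#'   or `"mean"`.
#' @param smooth_factor matched-filter smoothing of each profile before
#'   fitting: Gaussian kernel of sigma `smooth_factor * diameter estimate`
#'   (um). The kernel width is known exactly, so the fitted width is
#'   deconvolved analytically (`fwhm^2 - fwhm_kernel^2`), leaving the
#'   estimate unbiased for Gaussian profiles while strongly suppressing
#'   speckle-driven line-to-line variance. Set 0 to disable.
#' @return list of class `diam_params`.
#' @export
diam_params <- function(spacing_um = 5, step_um = 1, line_len_factor = 4,
                        line_len_min_um = 20, min_r2 = 0.5,
                        min_quality = 0.5, junction_margin_factor = 1,
                        avg = c("median", "mean"), smooth_factor = 1 / 8) {
  avg <- match.arg(avg)
  structure(list(spacing_um = spacing_um, step_um = step_um,
                 line_len_factor = line_len_factor,
                 line_len_min_um = line_len_min_um,
                 min_r2 = min_r2, min_quality = min_quality,
                 junction_margin_factor = junction_margin_factor,
                 avg = avg, smooth_factor = smooth_factor),
            class = "diam_params")
}

# Gaussian smoothing of a 1D profile (replicated edges); sigma in samples
.smooth_profile <- function(v, sigma) {
  if (sigma <= 0) return(v)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-h:h)^2 / (2 * sigma^2))
  k <- k / sum(k)
  vp <- c(rep(v[1], h), v, rep(v[length(v)], h))
  as.numeric(stats::filter(vp, k, sides = 2))[(h + 1):(h + length(v))]
}

# bilinear interpolation of a matrix at continuous (row, col) positions
.bilinear <- function(img, rc) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(rc[, 1], 1), nr)
  c <- pmin(pmax(rc[, 2], 1), nc)
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# centered moving average; the window shrinks at the ends and the two
# endpoints stay fixed so the smoothed path keeps the branch's full extent
.smooth_path <- function(m, w = 5) {
  n <- nrow(m)
  if (n <= 2 || w <= 1) return(m)
  h <- floor(w / 2)
  out <- m
  cs <- apply(rbind(0, m), 2, cumsum)
  for (i in seq_len(n)) {
    a <- max(1, i - h); b <- min(n, i + h)
    out[i, ] <- (cs[b + 1, ] - cs[a, ]) / (b - a + 1)
  }
  out[1, ] <- m[1, ]
  out[n, ] <- m[n, ]
  out
}

#' Place perpendicular cross-section lines along a branch
#'
#' Lines are perpendicular to the locally smoothed centerline tangent,
#' spaced `spacing_um` apart, with length
#' `max(line_len_factor * d_est, line_len_min_um)`; a branch shorter than one
#' spacing receives a single mid-branch line. Line points are clipped to the
#' image domain when sampled.
#'
#' @param centerline_px k x 2 matrix of (row, col) skeleton coordinates.
#' @param d_est_um current diameter estimate (um), sets the line length.
#' @param pixel_um lateral pixel pitch (um).
#' @param params a [diam_params()].
#' @return list of lines; each has `center_px`, `normal` (unit vector,
#'   row/col), `offsets_um`, and `points_px` (n x 2 sampling positions).
#' @export
place_cross_sections <- function(centerline_px, d_est_um, pixel_um = 2,
                                 params = diam_params()) {
  cl <- .smooth_path(centerline_px, 5)
  seg <- diff(cl) # k-1 x 2
  seg_len <- sqrt(rowSums(seg^2)) * pixel_um
  s <- c(0, cumsum(seg_len))
  L <- s[length(s)]
  pos <- if (L < params$spacing_um) L / 2 else
    seq(params$spacing_um / 2, L - params$spacing_um / 4,
        by = params$spacing_um)
  half <- max(params$line_len_factor * d_est_um, params$line_len_min_um) / 2
  offs <- seq(-half, half, by = params$step_um)
  lines <- lapply(pos, function(p) {
    i <- findInterval(p, s, rightmost.closed = TRUE)
    i <- min(max(i, 1), nrow(cl) - 1)
    f <- if (seg_len[i] > 0) (p - s[i]) / seg_len[i] else 0
    ctr <- cl[i, ] + f * (cl[i + 1, ] - cl[i, ])
    # local tangent over a wider stencil for stability
    a <- max(1, i - 2); b <- min(nrow(cl), i + 3)
    tg <- cl[b, ] - cl[a, ]
    nt <- sqrt(sum(tg^2))
    if (nt < 1e-9) tg <- c(0, 1) else tg <- tg / nt
    nrm <- c(-tg[2], tg[1])
    pts <- cbind(ctr[1] + offs / pixel_um * nrm[1],
                 ctr[2] + offs / pixel_um * nrm[2])
    list(center_px = ctr, normal = nrm, offsets_um = offs, points_px = pts,
         pos_um = p)
  })
  attr(lines, "length_um") <- L
  lines
}

# contiguous profile core around the peak, above the local baseline. The
# en-face background is a *floor* (max-projection composes flow signal and
# background noise by maximum), so the far tails of a cross-section are
# clipped flat at the floor and carry no width information; fitting them
# with an additive offset model biases sigma low. The core above
# baseline + 25% of amplitude contains the half-maximum region and
# determines the FWHM; on exact additive Gaussians any such subset still
# recovers the parameters exactly.
.profile_core <- function(y) {
  n <- length(y)
  # low quantile approximates the background floor even when neighbouring
  # vessels occupy the outer parts of the window
  b <- unname(quantile(y, 0.1))
  pk <- which.max(y)
  amp <- y[pk] - b
  if (amp <= 0) return(seq_len(n))
  th <- b + 0.25 * amp
  lo <- pk; while (lo > 1 && y[lo - 1] > th) lo <- lo - 1
  hi <- pk; while (hi < n && y[hi + 1] > th) hi <- hi + 1
  lo <- max(1, lo - 2); hi <- min(n, hi + 2)
  if (hi - lo + 1 < 5) seq_len(n) else lo:hi
}

# Levenberg-Marquardt Gaussian + offset fit (via minpack.lm's function
# interface, analytic Jacobian)
.fit_gauss <- function(x, y) {
  off0 <- min(y); amp0 <- max(y) - off0
  if (amp0 <= 0) return(NULL)
  w <- pmax(y - off0, 0)
  sw <- sum(w)
  cen0 <- if (sw > 0) sum(w * x) / sw else mean(x)
  # initial width from the direct half-maximum crossing around the peak;
  # second-moment widths are inflated by noise in the baseline
  pk <- which.max(y)
  half <- off0 + 0.5 * amp0
  lo <- pk; while (lo > 1 && y[lo - 1] > half) lo <- lo - 1
  hi <- pk; while (hi < length(y) && y[hi + 1] > half) hi <- hi + 1
  w_hm <- if (hi > lo) (x[hi] - x[lo]) else NA_real_
  sig0 <- if (is.finite(w_hm) && w_hm > 0) w_hm / (2 * sqrt(2 * log(2)))
          else if (sw > 0) sqrt(sum(w * (x - cen0)^2) / sw)
          else diff(range(x)) / 4
  sig0 <- min(max(sig0, 0.5), diff(range(x)) / 2)
  resid <- function(p) {
    e <- exp(-(x - p[3])^2 / (2 * p[4]^2))
    y - (p[1] + p[2] * e)
  }
  jac <- function(p) {
    u <- x - p[3]
    e <- exp(-u^2 / (2 * p[4]^2))
    cbind(-1, -e, -p[2] * e * u / p[4]^2, -p[2] * e * u^2 / p[4]^3)
  }
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = c(off0, amp0, cen0, sig0), fn = resid,
                         jac = jac,
                         lower = c(-Inf, 0, min(x), 0.2),
                         upper = c(Inf, Inf, max(x), diff(range(x))),
                         control = minpack.lm::nls.lm.control(maxiter = 60))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  ss_res <- sum(resid(p)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(offset = p[1], amplitude = p[2], center = p[3], sigma = p[4],
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 0)
}

#' Fit a Gaussian to a cross-section intensity profile
#'
#' Least-squares Gaussian plus constant offset; the full width at half
#' maximum, `FWHM = 2 * sqrt(2 * log(2)) * sigma`, is the operational vessel
#' diameter. A fit is accepted iff its R-squared reaches `min_r2` and the
#' fitted center lies within the middle half of the line (emulating the
#' automatic selection of usable cross-sections); rejected profiles are
#' excluded from the branch mean. The estimate is invariant to amplitude or
#' offset scaling of the profile.
#'
#' @param samples intensity values along the line (>= 5 finite values).
#' @param spacing_um sample spacing (um).
#' @param params a [diam_params()].
#' @return list of class `cross_section_fit`: `fwhm_um`, `accepted`, `r2`,
#'   and the fit parameters (`amplitude`, `center_um`, `sigma_um`,
#'   `offset`).
#' @examples
#' x <- seq(0, 30, by = 1)
#' prof <- 2 + 5 * exp(-(x - 15)^2 / (2 * 2^2))
#' fit_profile(prof, 1)$fwhm_um # 2*sqrt(2*log(2))*2 = 4.71
#' @export
fit_profile <- function(samples, spacing_um = 1, params = diam_params()) {
  if (any(!is.finite(samples))) stop("non-finite samples in profile")
  n <- length(samples)
  if (n < 5)
    return(structure(list(fwhm_um = NA_real_, accepted = FALSE, r2 = NA_real_),
                     class = "cross_section_fit"))
  x <- (seq_len(n) - 1) * spacing_um
  core <- .profile_core(samples)
  f <- .fit_gauss(x[core], samples[core])
  span <- x[n]
  if (is.null(f))
    return(structure(list(fwhm_um = NA_real_, accepted = FALSE, r2 = NA_real_),
                     class = "cross_section_fit"))
  fwhm <- 2 * sqrt(2 * log(2)) * f$sigma
  centered <- f$center >= span / 4 && f$center <= 3 * span / 4
  # dominance: no second structure in the window comparable to the fitted
  # peak (profiles crossing several vessels are rejected, not mis-measured)
  model <- f$offset + f$amplitude * exp(-(x - f$center)^2 / (2 * f$sigma^2))
  resid_sm <- stats::filter(samples - model, rep(1 / 3, 3), sides = 2)
  dominant <- max(resid_sm, na.rm = TRUE) <= 0.4 * f$amplitude
  accepted <- is.finite(fwhm) && f$r2 >= params$min_r2 && centered &&
    f$amplitude > 0 && fwhm <= span && dominant
  structure(list(fwhm_um = fwhm, accepted = accepted, r2 = f$r2,
                 amplitude = f$amplitude, center_um = f$center,
                 sigma_um = f$sigma, offset = f$offset),
            class = "cross_section_fit")
}

#' Branch diameter from accepted cross-section fits
#'
#' Mean FWHM over accepted cross-sections; `quality` is the accepted
#' fraction. Branches whose quality falls below `min_quality` (or with no
#' accepted cross-section at all) are flagged unmeasurable.
#'
#' @param fits list of `cross_section_fit`s for one branch.
#' @param params a [diam_params()].
#' @return list: `mean_diameter_um`, `quality`, `n_accepted`, `n_total`,
#'   `measurable`.
#' @export
branch_diameter <- function(fits, params = diam_params()) {
  fw <- vapply(fits, function(f) f$fwhm_um, numeric(1))
  ok <- vapply(fits, function(f) isTRUE(f$accepted), logical(1))
  n <- length(fits)
  q <- if (n > 0) mean(ok) else 0
  if (!any(ok))
    return(list(mean_diameter_um = NA_real_, quality = q, n_accepted = 0L,
                n_total = n, measurable = FALSE))
  avg <- if (identical(params$avg, "mean")) mean(fw[ok]) else median(fw[ok])
  list(mean_diameter_um = avg, quality = q,
       n_accepted = sum(ok), n_total = n,
       measurable = q >= params$min_quality)
}

#' Measure all branches of a segmented en-face image
#'
#' Runs cross-section placement and Gaussian-FWHM diametry for every branch
#' on the raw en-face intensity image, classifies branches by mean diameter
#' and applies the inclusion floor.
#'
#' @param img the en-face intensity image the profiles are measured on.
#' @param branches branch list from [skeletonize_and_graph()].
#' @param pixel_um lateral pixel pitch (um).
#' @param sparams a [seg_params()] (class edges, inclusion floor).
#' @param dparams a [diam_params()].
#' @return data frame: `branch_id`, `mean_diameter_um`, `class_label`
#'   (`NA` below the inclusion floor), `length_um`, `n_cross_sections`,
#'   `quality`, `measurable`.
#' @export
measure_branches <- function(img, branches, pixel_um = NULL,
                             sparams = seg_params(),
                             dparams = diam_params()) {
  p <- .pixel_um_of(img, pixel_um)
  im <- matrix(unclass(img), nrow(img))
  rows <- lapply(branches, function(b) {
    lines <- place_cross_sections(b$centerline_px, b$d_est_um, p, dparams)
    if (dparams$junction_margin_factor > 0 && length(lines) > 1 &&
        !is.null(b$end_types)) {
      L <- attr(lines, "length_um")
      marg <- dparams$junction_margin_factor * max(b$d_est_um, 5)
      pos <- vapply(lines, `[[`, numeric(1), "pos_um")
      ok <- rep(TRUE, length(lines))
      if (b$end_types[1] == "junction") ok <- ok & pos >= marg
      if (b$end_types[2] == "junction") ok <- ok & pos <= L - marg
      if (!any(ok)) ok[which.min(abs(pos - L / 2))] <- TRUE
      lines <- lines[ok]
    }
    sm_sig_um <- if (dparams$smooth_factor > 0)
      max(dparams$smooth_factor * max(b$d_est_um, 5), 0.5) else 0
    fwhm_kernel <- 2 * sqrt(2 * log(2)) * sm_sig_um
    fits <- lapply(lines, function(ln) {
      v <- .bilinear(im, ln$points_px)
      if (sm_sig_um > 0)
        v <- .smooth_profile(v, sm_sig_um / dparams$step_um)
      f <- fit_profile(v, dparams$step_um, dparams)
      # deconvolve the known matched-filter width
      if (sm_sig_um > 0 && is.finite(f$fwhm_um)) {
        if (f$fwhm_um > 1.05 * fwhm_kernel)
          f$fwhm_um <- sqrt(f$fwhm_um^2 - fwhm_kernel^2)
        else f$accepted <- FALSE
      }
      f
    })
    # line-level plausibility: a FWHM far from the local mask width means
    # the fit latched onto a speckle-split half-lumen or a neighbour
    if (is.finite(b$d_est_um) && b$d_est_um > 0) {
      ref <- max(b$d_est_um, 5)
      fits <- lapply(fits, function(f) {
        if (isTRUE(f$accepted) &&
            (f$fwhm_um < 0.5 * ref || f$fwhm_um > 2 * ref))
          f$accepted <- FALSE
        f
      })
    }
    bd <- branch_diameter(fits, dparams)
    # width-consistency QC: a FWHM wildly inconsistent with the local mask
    # width means the lines sampled a different (overlapping) vessel
    if (bd$measurable && is.finite(b$d_est_um) && b$d_est_um > 0) {
      ratio <- bd$mean_diameter_um / b$d_est_um
      if (ratio < 0.35 || ratio > 3) bd$measurable <- FALSE
    }
    data.frame(branch_id = b$branch_id,
               mean_diameter_um = bd$mean_diameter_um,
               length_um = b$length_um,
               n_cross_sections = bd$n_total,
               quality = bd$quality,
               measurable = bd$measurable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(branch_id = character(), mean_diameter_um = numeric(),
                      class_label = character(), length_um = numeric(),
                      n_cross_sections = integer(), quality = numeric(),
                      measurable = logical(), stringsAsFactors = FALSE))
  }
  out$class_label <- NA_character_
  ok <- out$measurable & !is.na(out$mean_diameter_um)
  if (any(ok))
    out$class_label[ok] <- classify_branch(
      out$mean_diameter_um[ok], sparams$class_edges_um,
      sparams$min_diameter_um)
  out[, c("branch_id", "mean_diameter_um", "class_label", "length_um",
          "n_cross_sections", "quality", "measurable")]
}
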