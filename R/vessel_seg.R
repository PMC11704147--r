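#' Segmentation parameters
#'
#' @param tophat_width_um white top-hat structuring-element width (um);
#'   the default 6.7 um targets capillary-scale structures.
#' @param min_diameter_um minimum inclusion diameter (um); branches measuring
#'   below this are excluded from all analyses.
#' @param prune_len_um skeleton spurs shorter than this are removed.
#' @param class_edges_um increasing diameter class edges; the default
#'   `c(15, 20)` gives the classes `<15`, `15-20` (half-open), `>=20`.
#' @param binarize_rule `"otsu"` (parameter-free, default) or `"fixed"`.
#' @param fixed_threshold threshold used when `binarize_rule = "fixed"`.
#' @param smooth_sigma_px Gaussian pre-smoothing (pixels) applied to the
#'   image before binarization only -- diameters are always measured on the
#'   raw image, so this suppresses speckle in the mask without biasing the
#'   FWHM.
#' @param dual_band if `TRUE` (default) the vessel mask is the union of the
#'   Otsu mask of the top-hat image (captures narrow vessels riding on haze)
#'   and the Otsu mask of the raw en-face (captures vessels wider than the
#'   top-hat element, whose interior the top-hat suppresses).
#' @return list of class `seg_params`.
#' @export
seg_params <- function(tophat_width_um = 6.7, min_diameter_um = 5,
                       prune_len_um = 10, class_edges_um = c(15, 20),
                       binarize_rule = c("otsu", "fixed"),
                       fixed_threshold = 0.3, dual_band = TRUE,
                       smooth_sigma_px = 1) {
  binarize_rule <- match.arg(binarize_rule)
  if (is.unsorted(class_edges_um, strictly = TRUE))
    stop("class_edges_um must be increasing")
  structure(list(tophat_width_um = tophat_width_um,
                 min_diameter_um = min_diameter_um,
                 prune_len_um = prune_len_um,
                 class_edges_um = class_edges_um,
                 binarize_rule = binarize_rule,
                 fixed_threshold = fixed_threshold,
                 dual_band = dual_band,
                 smooth_sigma_px = smooth_sigma_px),
            class = "seg_params")
}

.pixel_um_of <- function(img, pixel_um = NULL) {
  p <- pixel_um %||% attr(img, "pixel_um")
  if (is.null(p)) stop("pixel_um not given and not carried by the image")
  p[1]
}

#' White top-hat vessel enhancement
#'
#' Subtracts the grayscale opening with a disc of the configured width from
#' the image: flat or slowly varying background maps to ~0 while structures
#' narrower than the element are preserved. Structures much wider than the
#' element have their interiors suppressed, which is why the default
#' segmentation combines this band with a direct binarization (see
#' [seg_params()]).
#'
#' @param img 2D image (an `enface_image` or plain matrix).
#' @param params a [seg_params()].
#' @param pixel_um lateral pixel pitch, if `img` does not carry one.
#' @return Enhanced image (same class/attributes as the input).
#' @export
tophat_enhance <- function(img, params = seg_params(), pixel_um = NULL) {
  p <- .pixel_um_of(img, pixel_um)
  w_px <- params$tophat_width_um / p
  if (w_px < 1)
    stop("top-hat element narrower than 1 px; resample the image or widen it")
  size <- max(3L, as.integer(round(w_px)))
  if (size %% 2L == 0L) size <- size + 1L
  kern <- EBImage::makeBrush(size, shape = "disc")
  # EBImage grayscale morphology assumes [0, 1]; rescale around it
  x <- matrix(unclass(img), nrow(img))
  mx <- max(x, 1e-12)
  out <- EBImage::whiteTopHat(x / mx, kern)
  out <- matrix(as.numeric(out) * mx, nrow(img))
  attributes(out) <- attributes(img)
  out
}

#' Binarize a vessel image
#'
#' Thresholds (Otsu by default) and removes connected components smaller
#' than the area of a disc of the minimum inclusion diameter. An image with
#' no foreground yields an empty mask with a warning, not an error.
#'
#' @inheritParams tophat_enhance
#' @return Logical matrix mask.
#' @export
binarize_vessels <- function(img, params = seg_params(), pixel_um = NULL) {
  p <- .pixel_um_of(img, pixel_um)
  x <- unclass(img)
  mx <- max(x)
  if (mx <= 0) {
    warning("empty foreground: no vessels detected")
    return(matrix(FALSE, nrow(x), ncol(x)))
  }
  th <- if (params$binarize_rule == "fixed") params$fixed_threshold else {
    xn <- x / mx
    EBImage::otsu(xn, range = c(0, 1)) * mx
  }
  mask <- x > th
  if (!any(mask)) {
    warning("empty foreground: no vessels detected")
    return(mask)
  }
  min_area_px <- pi * (params$min_diameter_um / 2)^2 / p^2
  lab <- EBImage::bwlabel(mask)
  sz <- tabulate(lab[lab > 0])
  keep <- which(sz >= min_area_px)
  mask <- matrix(lab %in% keep, nrow(x), ncol(x))
  mask
}

#' Segment vessels in an en-face image
#'
#' Default pipeline mask: union of the binarized top-hat band (narrow
#' vessels) and the binarized raw image (wide vessels), followed by
#' small-object removal; set `dual_band = FALSE` in [seg_params()] for the
#' single top-hat pathway.
#'
#' @inheritParams tophat_enhance
#' @return Logical vessel mask.
#' @export
segment_enface <- function(img, params = seg_params(), pixel_um = NULL) {
  p <- .pixel_um_of(img, pixel_um)
  if (params$smooth_sigma_px > 0) {
    sm <- EBImage::gblur(matrix(unclass(img), nrow(img)),
                         sigma = params$smooth_sigma_px)
    sm <- matrix(as.numeric(sm), nrow(img))
    attributes(sm) <- attributes(img)
    img <- sm
  }
  th_img <- tophat_enhance(img, params, pixel_um = p)
  m1 <- suppressWarnings(binarize_vessels(th_img, params, pixel_um = p))
  if (params$dual_band) {
    m2 <- suppressWarnings(binarize_vessels(img, params, pixel_um = p))
    m1 <- m1 | m2
  }
  if (!any(m1)) {
    warning("empty foreground: no vessels detected")
    return(m1)
  }
  min_area_px <- pi * (params$min_diameter_um / 2)^2 / p^2
  lab <- EBImage::bwlabel(m1)
  sz <- tabulate(lab[lab > 0])
  matrix(lab %in% which(sz >= min_area_px), nrow(m1), ncol(m1))
}

#' Skeletonize a vessel mask and extract the branch graph
#'
#' Thins the mask to a 1-px skeleton (Zhang-Suen), identifies junction
#' (>= 3 neighbours) and end (1 neighbour) pixels, and splits the skeleton
#' into junction-to-junction / junction-to-end branches. Terminal spurs
#' shorter than the prune length are removed and the graph re-traced. Every
#' skeleton pixel is claimed by exactly one branch.
#'
#' @param mask logical vessel mask.
#' @param pixel_um lateral pixel pitch (um).
#' @param params a [seg_params()] (prune length, inclusion floor).
#' @return list of branches; each has `branch_id`, `centerline_px` (k x 2
#'   matrix of (row, col)), `pixels` (claimed pixel indices into the mask),
#'   `length_um`, `d_est_um` (2 x distance-map radius, the initial diameter
#'   estimate), `end_types` (2-vector: `"end"`/`"junction"`/`"loop"`).
#' @export
skeletonize_and_graph <- function(mask, pixel_um = 2, params = seg_params()) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!any(mask)) return(list())
  sk <- .thin_zs(matrix(as.integer(mask), nrow(mask))) > 0
  branches <- .trace_branches(sk)
  # prune sub-threshold branches (terminal spurs and crossing fragments),
  # then re-trace so merged paths rejoin
  if (params$prune_len_um > 0 && length(branches)) {
    for (pass in 1:6) {
      drop <- vapply(branches, function(b)
        b$length_px * pixel_um < params$prune_len_um, logical(1))
      if (!any(drop)) break
      for (b in branches[drop]) {
        # remove interior pixels and free (non-junction) endpoints; the
        # junction pixel stays with the surviving branches
        px <- c(b$interior_idx, b$end_idx[b$end_types != "junction"])
        if (length(px)) sk[px] <- FALSE
      }
      branches <- .trace_branches(sk)
    }
    # drop any stragglers the re-trace kept re-creating
    keep <- vapply(branches, function(b)
      b$length_px * pixel_um >= params$prune_len_um, logical(1))
    branches <- branches[keep]
  }
  if (!length(branches)) return(list())
  dm <- EBImage::distmap(mask)
  for (i in seq_along(branches)) {
    b <- branches[[i]]
    b$branch_id <- sprintf("B%03d", i)
    b$length_um <- b$length_px * pixel_um
    b$d_est_um <- 2 * median(dm[b$all_idx]) * pixel_um
    b$pixels <- b$claimed_idx
    branches[[i]] <- b
  }
  .drop_lumen_duplicates(branches, pixel_um)
}

# a centerline running inside the lumen of a clearly wider branch is a
# skeletonization artifact (edge path created at crossings), not a vessel
.drop_lumen_duplicates <- function(branches, pixel_um) {
  n <- length(branches)
  if (n < 2) return(branches)
  bb <- lapply(branches, function(b) {
    cl <- b$centerline_px
    c(min(cl[, 1]), max(cl[, 1]), min(cl[, 2]), max(cl[, 2]))
  })
  d_est <- vapply(branches, `[[`, numeric(1), "d_est_um")
  drop <- logical(n)
  for (i in seq_len(n)) {
    cli <- branches[[i]]$centerline_px
    for (j in seq_len(n)) {
      if (i == j || drop[j]) next
      if (d_est[j] < 1.6 * d_est[i]) next
      r <- d_est[j] / 2 / pixel_um
      if (bb[[j]][1] > bb[[i]][2] + r || bb[[j]][2] < bb[[i]][1] - r ||
          bb[[j]][3] > bb[[i]][4] + r || bb[[j]][4] < bb[[i]][3] - r) next
      clj <- branches[[j]]$centerline_px
      d2 <- outer(cli[, 1], clj[, 1], "-")^2 +
            outer(cli[, 2], clj[, 2], "-")^2
      inside <- mean(sqrt(apply(d2, 1, min)) <= r)
      if (inside > 0.6) { drop[i] <- TRUE; break }
    }
  }
  branches[!drop]
}

# trace junction-to-junction / junction-to-end paths on a 1-px skeleton
.trace_branches <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  # pad to avoid border checks
  P <- matrix(FALSE, nr + 2, nc + 2)
  P[2:(nr + 1), 2:(nc + 1)] <- sk
  npr <- nr + 2
  offs <- c(-1, 1, -npr, npr, -npr - 1, -npr + 1, npr - 1, npr + 1)
  idx <- which(P)
  if (!length(idx)) return(list())
  deg <- integer(length(P))
  for (o in offs) deg[idx] <- deg[idx] + P[idx + o]
  is_node <- P & (deg != 2)
  claimed <- logical(length(P))
  visited_from <- new.env(hash = TRUE) # edge keys "from:first-step"
  branches <- list()

  unpad <- function(ii) cbind(row = (ii - 1) %% npr + 1 - 1,
                              col = (ii - 1) %/% npr + 1 - 1)
  walk <- function(start, step) {
    path <- c(start, step)
    prev <- start; cur <- step
    while (!is_node[cur]) {
      nb <- cur + offs
      nb <- nb[P[nb] & nb != prev]
      if (length(nb) == 0) break          # isolated line end (shouldn't occur)
      if (length(nb) > 1) nb <- nb[1]     # diagonal ambiguity: deterministic
      prev <- cur; cur <- nb
      path <- c(path, cur)
      if (cur == path[1]) break           # closed a pure loop
      if (length(path) > length(idx)) break
    }
    path
  }

  add_branch <- function(path) {
    k <- length(branches) + 1
    inter <- path[!is_node[path]]
    new_claim <- path[!claimed[path]]
    claimed[new_claim] <<- TRUE
    e1 <- path[1]; e2 <- path[length(path)]
    et <- function(e) if (!is_node[e]) "loop" else
      if (deg[e] == 1) "end" else "junction"
    branches[[k]] <<- list(
      centerline_px = unpad(path),
      all_idx_padded = path,
      length_px = sum(sqrt(rowSums(
        (unpad(path)[-1, , drop = FALSE] -
         unpad(path)[-length(path), , drop = FALSE])^2))),
      interior_idx_padded = inter,
      claimed_idx_padded = new_claim,
      end_idx_padded = c(e1, e2),
      end_types = c(et(e1), et(e2)))
  }

  nodes <- which(is_node)
  for (nd in nodes) {
    for (o in offs) {
      nb <- nd + o
      if (!P[nb]) next
      key <- paste(nd, nb)
      if (!is.null(visited_from[[key]])) next
      path <- walk(nd, nb)
      last <- path[length(path)]
      lp <- path[length(path) - 1]
      visited_from[[key]] <- TRUE
      visited_from[[paste(last, lp)]] <- TRUE
      add_branch(path)
    }
  }
  # remaining unvisited deg==2 pixels are pure loops
  loop_px <- which(P & !claimed & !is_node)
  while (length(loop_px)) {
    start <- loop_px[1]
    nb <- start + offs
    nb <- nb[P[nb]][1]
    path <- walk(start, nb)
    path <- c(start, path[-1])
    add_branch(path)
    loop_px <- which(P & !claimed & !is_node)
  }
  # translate padded indices back to original-matrix indices
  to_orig <- function(ii) {
    rc <- cbind((ii - 1) %% npr + 1 - 1, (ii - 1) %/% npr + 1 - 1)
    (rc[, 2] - 1) * nr + rc[, 1]
  }
  lapply(branches, function(b) {
    list(centerline_px = b$centerline_px,
         all_idx = to_orig(b$all_idx_padded),
         interior_idx = to_orig(b$interior_idx_padded),
         claimed_idx = to_orig(b$claimed_idx_padded),
         end_idx = to_orig(b$end_idx_padded),
         length_px = b$length_px,
         end_types = b$end_types)
  })
}

#' Classify branch diameters
#'
#' Assigns the diameter classes `<15`, `15-20`, `>20` (half-open bins:
#' `d < 15`, `15 <= d < 20`, `d >= 20`). Diameters below the inclusion floor
#' return `NA` and are excluded from all analyses.
#'
#' @param d numeric vector of mean branch diameters (um).
#' @param class_edges_um increasing class edges, default `c(15, 20)`.
#' @param min_diameter_um inclusion floor (um); use 0 to classify everything.
#' @return Character vector of class labels (`NA` below the floor).
#' @examples
#' classify_branch(c(6.2, 17.66, 35.25, 4))
#' @export
classify_branch <- function(d, class_edges_um = c(15, 20),
                            min_diameter_um = 5) {
  if (any(is.na(d))) stop("diameter unset (NA) for some branches")
  lab <- ifelse(d < class_edges_um[1], CLASS_LABELS[1],
         ifelse(d < class_edges_um[2], CLASS_LABELS[2], CLASS_LABELS[3]))
  lab[d < min_diameter_um] <- NA_character_
  lab
}

#' Histogram of branch diameters
#'
#' Counts branches in half-open diameter bins `[k*bin, (k+1)*bin)`, the
#' en-face population summary (optionally pooled across animals upstream).
#'
#' @param d vector of branch diameters (um).
#' @param bin_um bin width (um).
#' @param max_um upper edge of the last bin (default: covers `max(d)`).
#' @return data frame with `lo`, `hi`, `count`.
#' @export
diameter_histogram <- function(d, bin_um = 2, max_um = NULL) {
  if (length(d) == 0) {
    max_um <- max_um %||% bin_um
    n <- ceiling(max_um / bin_um)
    return(data.frame(lo = (seq_len(n) - 1) * bin_um,
                      hi = seq_len(n) * bin_um, count = 0L))
  }
  max_um <- max_um %||% (floor(max(d) / bin_um) + 1) * bin_um
  n <- ceiling(max_um / bin_um)
  ix <- pmin(floor(d / bin_um) + 1, n)
  cnt <- tabulate(ix, nbins = n)
  data.frame(lo = (seq_len(n) - 1) * bin_um, hi = seq_len(n) * bin_um,
             count = cnt)
}
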