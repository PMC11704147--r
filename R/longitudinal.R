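#' Co-register en-face images across timepoints
#'
#' Estimates the rigid lateral translation of each later timepoint's en-face
#' image onto the baseline image by subpixel phase correlation. If the
#' correlation peak is below the confidence floor the shift is set to
#' identity with a warning.
#'
#' @param enfaces list of en-face images (matrices), baseline first.
#' @param conf_floor minimum normalized correlation-peak height.
#' @return n x 2 matrix of `(d_slow, d_fast)` shifts in pixels: the content
#'   of timepoint t sits at baseline position + shift.
#' @export
coregister_timepoints <- function(enfaces, conf_floor = 0.1) {
  stopifnot(is.list(enfaces), length(enfaces) >= 2)
  n <- length(enfaces)
  shifts <- matrix(0, n, 2,
                   dimnames = list(names(enfaces), c("d_slow", "d_fast")))
  ref <- matrix(unclass(enfaces[[1]]), nrow(enfaces[[1]]))
  for (k in 2:n) {
    mov <- matrix(unclass(enfaces[[k]]), nrow(enfaces[[k]]))
    pc <- tryCatch(.phasecorr(ref, mov), error = function(e) NULL)
    if (is.null(pc) || pc$confidence < conf_floor) {
      warning(sprintf("timepoint %d: correlation peak below confidence floor; using identity shift", k))
      next
    }
    shifts[k, ] <- pc$shift
  }
  shifts
}

#' Match branches between two timepoints
#'
#' Greedy one-to-one matching by centerline overlap: for each baseline
#' branch, the fraction of its centerline points lying within `tol_um` of a
#' candidate branch's (drift-corrected) centerline. Pairs below
#' `min_overlap` stay unmatched, unless the candidate lies almost entirely
#' (>= 80% of its own points) on the baseline centerline -- the later
#' segmentation may have split the baseline branch into pieces that
#' individually fall below the overlap floor. Ties are broken by higher
#' overlap, then by smaller diameter difference. Matching is
#' geometry-driven, so a uniformly dilated vessel still maps onto itself.
#'
#' @param base_branches,later_branches branch lists from
#'   [skeletonize_and_graph()].
#' @param shift_px `(d_row, d_col)` drift of the later image relative to
#'   baseline (from [coregister_timepoints()]).
#' @param tol_um centerline proximity tolerance (um).
#' @param pixel_um lateral pixel pitch (um).
#' @param min_overlap minimum overlap fraction for a match.
#' @param base_diam,later_diam optional diameters; when given, candidates
#'   whose diameters disagree by more than `max_diam_ratio` are rejected as
#'   identification errors (short junction-bracketed fragments of a wide
#'   vessel are geometrically promiscuous and can otherwise lock onto a
#'   crossing capillary), and ties are broken by diameter difference.
#' @param max_diam_ratio identity gate on the pairwise diameter ratio;
#'   generous against any plausible physiological change (~1.3x).
#' @return data frame `base` (index), `later` (index), `overlap`.
#' @export
match_branches <- function(base_branches, later_branches, shift_px = c(0, 0),
                           tol_um = 5, pixel_um = 2, min_overlap = 0.5,
                           base_diam = NULL, later_diam = NULL,
                           max_diam_ratio = 2) {
  nb <- length(base_branches); nl <- length(later_branches)
  if (nb == 0 || nl == 0)
    return(data.frame(base = integer(), later = integer(),
                      overlap = numeric()))
  tol_px <- tol_um / pixel_um
  # every 2nd centerline point is ample at 1-px path resolution
  thin2 <- function(m) m[seq(1, nrow(m), by = 2), , drop = FALSE]
  later_cl <- lapply(later_branches, function(b)
    sweep(thin2(b$centerline_px), 2, shift_px))
  bbox <- function(m) c(min(m[, 1]), max(m[, 1]), min(m[, 2]), max(m[, 2]))
  bb_b <- lapply(base_branches, function(b) bbox(b$centerline_px))
  bb_l <- lapply(later_cl, bbox)
  cand <- list()
  for (i in seq_len(nb)) {
    cb <- thin2(base_branches[[i]]$centerline_px)
    for (j in seq_len(nl)) {
      bi <- bb_b[[i]]; bj <- bb_l[[j]]
      if (bj[1] > bi[2] + tol_px || bj[2] < bi[1] - tol_px ||
          bj[3] > bi[4] + tol_px || bj[4] < bi[3] - tol_px) next
      cl <- later_cl[[j]]
      if (!is.null(base_diam) && !is.null(later_diam) &&
          is.finite(base_diam[i]) && is.finite(later_diam[j])) {
        r <- later_diam[j] / base_diam[i]
        if (r > max_diam_ratio || r < 1 / max_diam_ratio) next
      }
      d2 <- outer(cb[, 1], cl[, 1], "-")^2 + outer(cb[, 2], cl[, 2], "-")^2
      dmin <- sqrt(apply(d2, 1, min))
      # +0.71 px compensates the thinned later path's sampling gap
      ov <- mean(dmin <= tol_px + 0.71)
      ok <- ov >= min_overlap
      if (!ok && ov >= 0.2) {
        # containment fallback: the later segmentation may have split the
        # baseline branch, leaving each piece below the overlap floor; a
        # candidate lying almost entirely on the baseline centerline is
        # still the same vessel
        ov2 <- mean(sqrt(apply(d2, 2, min)) <= tol_px + 0.71)
        ok <- ov2 >= 0.8
      }
      if (ok)
        cand[[length(cand) + 1]] <- c(i, j, ov)
    }
  }
  if (!length(cand))
    return(data.frame(base = integer(), later = integer(),
                      overlap = numeric()))
  cand <- do.call(rbind, cand)
  dd <- if (!is.null(base_diam) && !is.null(later_diam))
    abs(base_diam[cand[, 1]] - later_diam[cand[, 2]]) else rep(0, nrow(cand))
  ord <- order(-cand[, 3], dd)
  used_b <- logical(nb); used_l <- logical(nl)
  keep <- logical(nrow(cand))
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_b[i] || used_l[j]) next
    used_b[i] <- TRUE; used_l[j] <- TRUE
    keep[k] <- TRUE
  }
  out <- data.frame(base = as.integer(cand[keep, 1]),
                    later = as.integer(cand[keep, 2]),
                    overlap = cand[keep, 3])
  out[order(out$base), , drop = FALSE]
}

#' Track branches of one animal across the study timeline
#'
#' Co-registers the timepoints, matches every later timepoint's branches to
#' the baseline segmentation, and assembles a long-format track table.
#' Branch identity and diameter class are frozen at the pre-sonication
#' timepoint.
#'
#' @param results named list (one entry per timepoint, baseline first);
#'   each entry a list with `enface` (the image), `branches` (from
#'   [skeletonize_and_graph()]) and `table` (from [measure_branches()]).
#' @param animal animal identifier recorded in the table.
#' @param tol_um matching tolerance (um).
#' @param pixel_um lateral pixel pitch (um).
#' @return Long-format data frame: `animal`, `branch_id`, `class_label`
#'   (from the pre diameter), `timepoint`, `diameter_um`, `matched`.
#'   Only baseline branches that are measurable and above the inclusion
#'   floor are tracked.
#' @export
track_timepoints <- function(results, animal = 1L, tol_um = 5,
                             pixel_um = 2) {
  stopifnot(length(results) >= 2, !is.null(names(results)))
  tps <- names(results)
  shifts <- coregister_timepoints(lapply(results, `[[`, "enface"))
  base <- results[[1]]
  keep <- which(base$table$measurable & !is.na(base$table$class_label))
  if (!length(keep))
    return(data.frame(animal = integer(), branch_id = character(),
                      class_label = character(), timepoint = character(),
                      diameter_um = numeric(), matched = logical(),
                      stringsAsFactors = FALSE))
  rows <- list()
  rows[[1]] <- data.frame(
    animal = animal, branch_id = base$table$branch_id[keep],
    class_label = base$table$class_label[keep], timepoint = tps[1],
    diameter_um = base$table$mean_diameter_um[keep], matched = TRUE,
    stringsAsFactors = FALSE)
  for (t in 2:length(tps)) {
    later <- results[[t]]
    mm <- match_branches(base$branches[keep], later$branches,
                         shift_px = shifts[t, ], tol_um = tol_um,
                         pixel_um = pixel_um,
                         base_diam = base$table$mean_diameter_um[keep],
                         later_diam = later$table$mean_diameter_um)
    d <- rep(NA_real_, length(keep))
    matched <- rep(FALSE, length(keep))
    if (nrow(mm)) {
      matched[mm$base] <- TRUE # geometric identity established
      dl <- later$table$mean_diameter_um[mm$later]
      dl[!later$table$measurable[mm$later]] <- NA_real_
      d[mm$base] <- dl # may stay NA if unmeasurable at this timepoint
    }
    rows[[t]] <- data.frame(
      animal = animal, branch_id = base$table$branch_id[keep],
      class_label = base$table$class_label[keep], timepoint = tps[t],
      diameter_um = d, matched = matched, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Normalize tracked diameters to baseline
#'
#' Adds `normalized = diameter / pre-diameter` per branch; the baseline rows
#' are exactly 1. Branches without a positive baseline diameter are dropped
#' with a message.
#'
#' @param tracks long-format track table ([track_timepoints()]), possibly
#'   concatenated across animals.
#' @param pre_label baseline timepoint label.
#' @return The table with a `normalized` column (`NA` where unmatched).
#' @export
normalize_tracks <- function(tracks, pre_label = "pre") {
  key <- paste(tracks$animal, tracks$branch_id)
  pre <- tracks[tracks$timepoint == pre_label, ]
  pre_d <- setNames(pre$diameter_um, paste(pre$animal, pre$branch_id))
  base <- pre_d[key]
  bad <- is.na(base) | base <= 0
  if (any(bad)) {
    nb <- length(unique(key[bad]))
    message(sprintf("dropping %d track(s) without a usable baseline diameter", nb))
    tracks <- tracks[!bad, , drop = FALSE]
    base <- base[!bad]
  }
  tracks$normalized <- tracks$diameter_um / base
  tracks
}

#' Per-animal mean normalized diameters
#'
#' The animal is the unit of analysis: for each animal, diameter class and
#' timepoint, the unweighted mean normalized diameter across that animal's
#' matched tracks of the class. Animals with no branch in a class are
#' omitted for that class.
#'
#' @param tracks normalized track table ([normalize_tracks()]).
#' @param class_label optional single class to restrict to.
#' @return data frame: `animal`, `class_label`, `timepoint`, `mean_norm`,
#'   `n_branches`.
#' @export
per_animal_summary <- function(tracks, class_label = NULL) {
  t2 <- tracks[tracks$matched & !is.na(tracks$normalized), , drop = FALSE]
  if (!is.null(class_label))
    t2 <- t2[t2$class_label == class_label, , drop = FALSE]
  if (nrow(t2) == 0)
    return(data.frame(animal = integer(), class_label = character(),
                      timepoint = character(), mean_norm = numeric(),
                      n_branches = integer(), stringsAsFactors = FALSE))
  ag <- aggregate(normalized ~ animal + class_label + timepoint, data = t2,
                  FUN = mean)
  cnt <- aggregate(normalized ~ animal + class_label + timepoint, data = t2,
                   FUN = length)
  out <- merge(ag, cnt,
               by = c("animal", "class_label", "timepoint"),
               suffixes = c("", "_n"))
  names(out)[names(out) == "normalized"] <- "mean_norm"
  names(out)[names(out) == "normalized_n"] <- "n_branches"
  out$timepoint <- factor(out$timepoint, levels = TIMEPOINTS)
  out[order(out$class_label, out$animal, out$timepoint), , drop = FALSE]
}
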