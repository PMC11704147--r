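# brute-force grayscale opening oracle: erosion then dilation with an
# explicit disc offset set
naive_tophat <- function(img, radius_px) {
  offs <- expand.grid(dr = -radius_px:radius_px, dc = -radius_px:radius_px)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius_px^2 + 1e-9, ]
  nr <- nrow(img); nc <- ncol(img)
  pad <- function(m, fill) {
    out <- matrix(fill, nr + 2 * radius_px, nc + 2 * radius_px)
    out[radius_px + 1:nr, radius_px + 1:nc] <- m
    out
  }
  sweep_ext <- function(m, fill, fun) {
    p <- pad(m, fill)
    acc <- NULL
    for (k in seq_len(nrow(offs))) {
      s <- p[radius_px + offs$dr[k] + 1:nr, radius_px + offs$dc[k] + 1:nc]
      acc <- if (is.null(acc)) s else fun(acc, s)
    }
    acc
  }
  er <- sweep_ext(img, Inf, pmin)
  op <- sweep_ext(er, -Inf, pmax)
  img - op
}

test_that("top-hat matches a brute-force morphology oracle", {
  p <- seg_params(tophat_width_um = 6.7)
  # constant image -> all zeros
  flat <- matrix(5, 30, 30)
  expect_equal(max(abs(tophat_enhance(flat, p, pixel_um = 2))), 0)

  # narrow ridge preserved, wide plateau suppressed
  img <- matrix(0, 40, 60)
  img[, 10:11] <- 1          # ~4-um ridge
  img[, 30:50] <- 0.8        # ~40-um plateau
  th <- tophat_enhance(img, p, pixel_um = 2)
  oracle <- naive_tophat(img, 1) # 6.7 um / 2 um -> 3-px disc, radius 1
  expect_lt(abs(max(th[, 10:11]) - 1), 0.05)
  expect_lt(max(th[, 38:44]), 0.05)
  expect_equal(as.vector(th), as.vector(oracle), tolerance = 1e-6)

  expect_error(tophat_enhance(img, seg_params(tophat_width_um = 1),
                              pixel_um = 2), "resample")
})

test_that("binarization thresholds cleanly and tolerates empty scenes", {
  img <- matrix(0, 50, 50)
  img[20:30, 10:40] <- 100
  m <- binarize_vessels(img, pixel_um = 2)
  expect_equal(unname(m), unname(img > 50))

  expect_warning(e <- binarize_vessels(matrix(0, 20, 20), pixel_um = 2),
                 "empty foreground")
  expect_false(any(e))
})

test_that("phantom segmentation overlaps the true lumen (Dice >= 0.7)", {
  ph <- fixture("default_phantom", build_phantom(phantom_spec(seed = 11)))
  flat <- detilt(ph$volume)
  enf <- project_enface(flat, 0, 400)
  mask <- segment_enface(enf, seg_params())
  # truth lumen mask: pixels within d/2 of any centerline (en-face)
  d <- dim(enf)
  truth_mask <- matrix(FALSE, d[1], d[2])
  px <- attr(enf, "pixel_um")[1]
  for (i in seq_len(nrow(ph$truth))) {
    cl <- ph$truth$centerline[[i]]
    r_px <- ph$truth$true_diameter_um[i] / 2 / px
    for (k in seq_len(nrow(cl))) {
      rr <- round(cl[k, "y_um"] / px); cc <- round(cl[k, "x_um"] / px)
      w <- ceiling(r_px)
      rs <- max(1, rr - w):min(d[1], rr + w)
      cs <- max(1, cc - w):min(d[2], cc + w)
      sub <- outer((rs - rr)^2, (cs - cc)^2, "+") <= r_px^2
      truth_mask[rs, cs] <- truth_mask[rs, cs] | sub
    }
  }
  dice <- 2 * sum(mask & truth_mask) / (sum(mask) + sum(truth_mask))
  expect_gte(dice, 0.7)
})

test_that("skeleton graph extraction resolves simple topologies", {
  # single straight tube -> one branch of the right length
  m <- matrix(FALSE, 40, 60)
  m[18:22, 10:50] <- TRUE
  br <- skeletonize_and_graph(m, pixel_um = 2)
  expect_equal(length(br), 1)
  # thinning erodes a blunt bar's ends by about half its width each side
  expect_lt(abs(br[[1]]$length_px - 40), 6)

  # Y junction -> 3 branches around 1 junction
  y <- matrix(FALSE, 60, 60)
  y[30:32, 5:30] <- TRUE
  for (k in 0:20) { y[30 + k + 0:2, 30 + k] <- TRUE }
  for (k in 0:20) { y[30 - k + 0:2, 30 + k] <- TRUE }
  br_y <- skeletonize_and_graph(y, pixel_um = 2,
                                params = seg_params(prune_len_um = 6))
  expect_equal(length(br_y), 3)
  njunc <- sum(vapply(br_y, function(b)
    sum(b$end_types == "junction"), numeric(1)))
  expect_gte(njunc, 3)

  # a 3-px spur is pruned away
  sp <- m
  sp[23:25, 30] <- TRUE
  br_sp <- skeletonize_and_graph(sp, pixel_um = 2,
                                 params = seg_params(prune_len_um = 10))
  expect_equal(length(br_sp), 1)

  expect_equal(length(skeletonize_and_graph(matrix(FALSE, 5, 5), 2)), 0)
})

test_that("every skeleton pixel is claimed by exactly one branch", {
  set.seed(40)
  m <- matrix(FALSE, 80, 80)
  for (k in 1:6) {
    r0 <- sample(10:70, 1); c0 <- sample(10:70, 1)
    ang <- runif(1, 0, pi); len <- sample(20:40, 1)
    for (t in seq(0, len)) {
      rr <- round(r0 + t * sin(ang)); cc <- round(c0 + t * cos(ang))
      if (rr %in% 2:78 && cc %in% 2:78) m[rr + -1:1, cc + -1:1] <- TRUE
    }
  }
  br <- skeletonize_and_graph(m, pixel_um = 2,
                              params = seg_params(prune_len_um = 0))
  claimed <- unlist(lapply(br, `[[`, "claimed_idx"))
  expect_equal(anyDuplicated(claimed), 0)
  sk <- octava:::.thin_zs(matrix(as.integer(m), nrow(m))) > 0
  expect_setequal(claimed, which(sk))
})

test_that("diameter classes follow the half-open convention", {
  expect_equal(classify_branch(c(6.20, 17.66, 35.25)),
               c("<15", "15-20", ">20"))
  expect_equal(classify_branch(c(14.999, 15, 19.999, 20)),
               c("<15", "15-20", "15-20", ">20"))
  expect_true(is.na(classify_branch(4.9)))
  expect_equal(classify_branch(4.9, min_diameter_um = 0), "<15")
  expect_error(classify_branch(NA_real_), "unset")
})

test_that("diameter histograms count half-open bins", {
  h0 <- diameter_histogram(numeric(0), bin_um = 10, max_um = 40)
  expect_true(all(h0$count == 0))

  h <- diameter_histogram(c(6, 6, 30), bin_um = 10)
  expect_equal(h$count[h$lo == 0], 2)
  expect_equal(h$count[h$lo == 30], 1)
  expect_equal(sum(h$count), 3)
})

test_that("class counts are invariant under intensity rescaling", {
  ph <- fixture("default_phantom", build_phantom(phantom_spec(seed = 11)))
  flat <- detilt(ph$volume)
  enf <- project_enface(flat, 0, 400)
  m1 <- segment_enface(enf, seg_params())
  enf2 <- enf * 0.37
  attributes(enf2) <- attributes(enf)
  m2 <- segment_enface(enf2, seg_params())
  expect_equal(m1, m2)
})

test_that("most true vessels >= 8 um are recovered by segmentation", {
  ph <- fixture("default_phantom", build_phantom(phantom_spec(seed = 11)))
  res <- analyze_volume(ph$volume)
  br <- res$branches
  px <- 2
  truth <- ph$truth[ph$truth$true_diameter_um >= 8, ]
  # pool all segmented centerline points; a vessel counts as recovered when
  # most of its centerline lies within 5 um of the segmented skeleton
  pts <- do.call(rbind, lapply(br, function(b) b$centerline_px * px))
  found <- vapply(seq_len(nrow(truth)), function(i) {
    cl <- truth$centerline[[i]]
    dmin <- sqrt(outer(cl[, "y_um"], pts[, 1], "-")^2 +
                 outer(cl[, "x_um"], pts[, 2], "-")^2)
    mean(apply(dmin, 1, min) <= 5) > 0.5
  }, logical(1))
  expect_gte(mean(found), 0.9)
})
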