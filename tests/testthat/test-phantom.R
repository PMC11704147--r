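test_that("empty phantom yields uniform background and empty truth", {
  spec <- phantom_spec(domain_um = c(120, 120, 80), n_large = 0,
                       n_medium = 0, n_small = 0, speckle_cv = 0,
                       tilt_deg = 0, seed = 1)
  ph <- build_phantom(spec)
  expect_equal(nrow(ph$truth), 0)
  v <- unclass(ph$volume)
  tissue <- v[40:70, , ] # below the surface
  expect_lt(max(tissue) - min(tissue), 0.02) # background + noise floor only
})

test_that("a noiseless tube has half-max width equal to its diameter", {
  ph <- build_phantom(single_tube_spec(10))
  flat <- detilt(ph$volume)
  enf <- project_enface(flat, 0, 200)
  # direct half-max width of the en-face profile across the tube
  mask <- enf > 0.5 * max(enf)
  cl <- ph$truth$centerline[[1]]
  mid <- cl[ceiling(nrow(cl) / 2), ]
  row <- round(mid["y_um"] / 2)
  run <- rle(mask[row, ])
  w_px <- max(run$lengths[run$values])
  # a cut along a row (fixed y) sees the perpendicular width divided by
  # the sine of the angle between the tube and the x axis: sin = |dy|/len
  dirv <- cl[nrow(cl), 1:2] - cl[1, 1:2]
  s <- abs(dirv[2]) / sqrt(sum(dirv^2)) # |dy| / len
  expect_lt(abs(w_px * 2 * s - 10), 2.5) # within ~1 voxel of 10 um
  expect_equal(nrow(ph$truth), 1)
})

test_that("the capillary sampler reproduces the configured population", {
  spec <- phantom_spec(domain_um = c(2000, 2000, 400), n_large = 0,
                       n_medium = 0, n_small = 500, seed = 99)
  geom <- octava:::.sample_geometry(spec)
  d <- geom$diameter_um
  expect_equal(length(d), 500)
  # sample mean within 3 SE of the configured 6.2 um
  expect_lt(abs(mean(d) - 6.2), 3 * 1.3 / sqrt(500))
  # Kolmogorov-Smirnov distance to the sampler's own CDF < 0.1
  p <- octava:::.calibrate_lognorm(6.2, 1.3, 5, 15)
  cdf <- function(q) {
    lo <- plnorm(5, p["mu"], p["sigma"]); hi <- plnorm(15, p["mu"], p["sigma"])
    (plnorm(q, p["mu"], p["sigma"]) - lo) / (hi - lo)
  }
  ks <- suppressWarnings(ks.test(d, cdf))
  expect_lt(unname(ks$statistic), 0.1)
  expect_true(all(d >= 5 & d < 15))
})

test_that("projection tails decay and never exceed the parent vessel", {
  spec <- phantom_spec(domain_um = c(300, 300, 300), n_large = 0,
                       n_medium = 0, n_small = 1, small_diam_mean_um = 10,
                       small_diam_sd_um = 1e-6, speckle_cv = 0,
                       tail_strength = 0.4, tilt_deg = 0, seed = 5,
                       depth_profile = list(small = c(80, 81, 1, 1),
                                            medium = c(0, 1, 1, 1),
                                            large = c(0, 1, 1, 1)))
  ph <- build_phantom(spec)
  v <- unclass(ph$volume)
  cl <- ph$truth$centerline[[1]]
  mid <- cl[ceiling(nrow(cl) / 2), ]
  row <- round(mid["y_um"] / 2); col <- round(mid["x_um"] / 2)
  zc <- round((60 + mid["depth_um"]) / 2) # air offset 60 um
  column <- v[, row, col]
  peak <- max(column)
  below <- column[(zc + 5):length(column)]
  expect_lt(max(below), 0.4 * peak + 1e-6) # tail bounded by strength
  expect_gt(below[1], below[min(40, length(below))]) # decays with depth
})

test_that("same seed reproduces byte-identical phantoms", {
  s <- tiny_spec(seed = 12)
  a <- build_phantom(s); b <- build_phantom(s)
  expect_identical(unclass(a$volume), unclass(b$volume))
  expect_identical(a$truth$true_diameter_um, b$truth$true_diameter_um)
})

test_that("infeasible vessel loads are rejected by class", {
  spec <- phantom_spec(domain_um = c(100, 100, 50), n_large = 80,
                       n_medium = 0, n_small = 0, seed = 2)
  expect_error(build_phantom(spec), "large")
})

test_that("study scenarios scale truth diameters per class and timepoint", {
  spec <- tiny_spec(seed = 3)

  # sham: identical truths at every timepoint
  sham <- study_plan(spec, scenario_sham(n_animals = 2))
  tru <- study_truth(sham)
  pre <- tru[tru$timepoint == "pre", "true_diameter_um"]
  for (tp in c("post1_1min", "post2_10min"))
    expect_identical(tru[tru$timepoint == tp, "true_diameter_um"], pre)

  # configured 17% small-vessel effect shows in the truth ratios
  scen <- scenario_low_intensity(n_animals = 6)
  plan <- study_plan(phantom_spec(domain_um = c(300, 300, 200),
                                  n_large = 1, n_medium = 1, n_small = 10,
                                  seed = 4), scen)
  tru2 <- study_truth(plan)
  rat <- merge(tru2[tru2$timepoint == "post1_1min", ],
               tru2[tru2$timepoint == "pre", ],
               by = c("animal", "branch_id"))
  small <- rat[rat$class_label.x == "<15", ]
  r <- small$true_diameter_um.x / small$true_diameter_um.y
  expect_equal(mean(r), 1.17, tolerance = 3 * 0.03 / sqrt(6))

  # a class with factor 1.0 is exactly unscaled when the scenario carries
  # no animal-level perturbation
  scen0 <- dilation_scenario(list("<15" = c(1, 1.17, 1.17, 1.17),
                                  "15-20" = c(1, 1, 1, 1),
                                  ">20" = c(1, 1, 1, 1)),
                             n_animals = 2, inter_animal_sd = 0)
  plan0 <- study_plan(spec, scen0)
  tru0 <- study_truth(plan0)
  big <- tru0[tru0$class_label != "<15", ]
  for (tp in TIMEPOINTS[-1])
    expect_identical(big$true_diameter_um[big$timepoint == tp],
                     big$true_diameter_um[big$timepoint == "pre"])
})

test_that("scenario validation enforces the timeline contract", {
  expect_error(dilation_scenario(list("<15" = c(1.1, 1, 1, 1),
                                      "15-20" = c(1, 1, 1, 1),
                                      ">20" = c(1, 1, 1, 1))),
               "pre")
  expect_error(dilation_scenario(list("<15" = c(1, -1, 1, 1),
                                      "15-20" = c(1, 1, 1, 1),
                                      ">20" = c(1, 1, 1, 1))),
               "factors")
})
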