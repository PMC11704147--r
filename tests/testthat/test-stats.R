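test_that("paired t matches the textbook formula on seeded data", {
  # oracle: t = mean(d) / (sd(d)/sqrt(n)), p from the t distribution
  set.seed(5)
  for (k in 1:100) {
    n <- sample(4:12, 1)
    pre <- rnorm(n, 1, 0.05)
    post <- pre + rnorm(n, 0.02, 0.04)
    r <- paired_t(pre, post)
    d <- post - pre
    t_hand <- mean(d) / (sd(d) / sqrt(n))
    p_hand <- 2 * pt(-abs(t_hand), n - 1)
    expect_equal(r$t, t_hand, tolerance = 1e-10)
    expect_equal(r$p, p_hand, tolerance = 1e-10)
  }
})

test_that("paired t handles degenerate inputs per contract", {
  x <- c(1, 1.1, 0.9, 1.05)
  r <- paired_t(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  # constant nonzero difference: p undefined
  expect_message(r2 <- paired_t(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_true(is.na(r2$p))

  # hand-checked: diffs {1,2,3,4} vs zero baseline
  r3 <- paired_t(rep(0, 4), c(1, 2, 3, 4))
  expect_equal(r3$t, 2.5 / (sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-10)
})

test_that("two-way ANOVA agrees with hand-computed sums of squares", {
  # balanced 2x2 design; oracle: textbook SS decomposition
  set.seed(9)
  df <- expand.grid(condition = c("a", "b"), timepoint = c("t1", "t2"),
                    rep = 1:6)
  df$value <- rnorm(nrow(df), 1, 0.1) +
    0.3 * (df$condition == "b") + 0.1 * (df$timepoint == "t2")
  res <- anova_lsd(df)
  g <- mean(df$value)
  n <- 6
  mc <- tapply(df$value, df$condition, mean)
  mt <- tapply(df$value, df$timepoint, mean)
  ss_c <- 2 * n * sum((mc - g)^2)
  ss_t <- 2 * n * sum((mt - g)^2)
  an <- res$anova
  expect_equal(an$`Sum Sq`[an$term == "condition"], ss_c, tolerance = 1e-8)
  expect_equal(an$`Sum Sq`[an$term == "timepoint"], ss_t, tolerance = 1e-8)

  # separated conditions with tiny SD -> overwhelming condition effect
  df2 <- df; df2$value <- ifelse(df2$condition == "a", 1, 2) +
    rnorm(nrow(df2), 0, 0.01)
  res2 <- anova_lsd(df2)
  expect_lt(res2$anova$p[res2$anova$term == "condition"], 1e-3)
})

test_that("degenerate and unbalanced ANOVA inputs follow the contract", {
  df <- expand.grid(condition = c("a", "b"), timepoint = c("t1", "t2"),
                    rep = 1:3)
  df$value <- 1
  res <- anova_lsd(df) # all equal: no significance anywhere
  expect_true(all(res$lsd$p > 0.99))
  expect_true(all(res$anova$p[1:3] > 0.99, na.rm = TRUE))

  df2 <- df[!(df$condition == "b" & df$timepoint == "t2"), ]
  expect_error(anova_lsd(df2), "empty cell")

  # LSD on three equal groups (via timepoints) stays non-significant
  df3 <- expand.grid(condition = c("a", "b"),
                     timepoint = c("t1", "t2", "t3"), rep = 1:4)
  df3$value <- rep(c(1.0, 1.0), length.out = nrow(df3))
  res3 <- anova_lsd(df3)
  expect_true(all(res3$lsd$p > 0.99))
})

test_that("Mann-Whitney matches exact enumeration on small samples", {
  # oracle: enumerate all rank assignments
  enum_p <- function(x, y) {
    n1 <- length(x); n <- n1 + length(y)
    r <- rank(c(x, y))
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    cs <- utils::combn(n, n1)
    us <- apply(cs, 2, function(ix) sum(seq_len(n)[ix]) - n1 * (n1 + 1) / 2)
    mu <- n1 * (length(y)) / 2
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  }
  r <- mannwhitney_depth(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p, 0.1, tolerance = 1e-10)
  expect_equal(enum_p(c(1, 2, 3), c(10, 11, 12)), 0.1, tolerance = 1e-10)

  set.seed(21)
  for (k in 1:20) {
    x <- round(rnorm(sample(3:6, 1), 0, 5), 3)
    y <- round(rnorm(sample(3:6, 1), 1, 5), 3)
    r <- mannwhitney_depth(x, y)
    expect_equal(r$p, enum_p(x, y), tolerance = 1e-9)
  }

  # identical samples: no evidence of a shift
  ri <- mannwhitney_depth(1:6, 1:6)
  expect_gt(ri$p, 0.9)

  expect_message(re <- mannwhitney_depth(numeric(0), 1:3), "empty sample")
  expect_true(is.na(re$p))
})

test_that("summary table reflects a sham scenario and omits empty classes", {
  tr <- simulate_track_table(scenario_sham(n_animals = 4), seed = 3)
  tab <- build_table1(list(sham = tr))
  small <- tab[tab$class == "<15" & tab$condition == "sham", ]
  expect_equal(small$norm_post1_1min_mean, 1, tolerance = 0.02)
  expect_equal(small$norm_post2_10min_mean, 1, tolerance = 0.02)

  # a configured low-intensity effect shows up in the post1 column
  tr2 <- simulate_track_table(scenario_low_intensity(n_animals = 8),
                              seed = 4)
  tab2 <- build_table1(list(low = tr2))
  s2 <- tab2[tab2$class == "<15", ]
  expect_equal(s2$norm_post1_1min_mean, 1.17, tolerance = 0.03)
  expect_lt(s2$p_post1_vs_pre, 0.001)

  # class with no branches -> row omitted with a message
  tr3 <- simulate_track_table(scenario_sham(n_animals = 3),
                              n_branches = c("<15" = 10, "15-20" = 0,
                                             ">20" = 0), seed = 5)
  expect_message(tab3 <- build_table1(list(sham = tr3)), "omitted")
  expect_false("15-20" %in% tab3$class)
})

test_that("depth report flags only bins with a real shift", {
  set.seed(8)
  mk <- function(n, depth_lo, d_mean)
    data.frame(mean_diameter_um = rlnorm(n, log(d_mean), 0.15),
               depth_um = runif(n, depth_lo, depth_lo + 50))
  pre <- rbind(mk(40, 100, 6), mk(40, 200, 6), mk(40, 300, 6))
  post <- rbind(mk(40, 100, 6), mk(40, 200, 7.6), mk(40, 300, 6))
  rep <- depth_report(pre, post, bin_um = 50, max_depth_um = 400)
  b <- rep$bins
  expect_lt(b$mannwhitney_p[b$lo == 200], 0.01)
  expect_gt(min(b$mannwhitney_p[b$lo %in% c(100, 300)], na.rm = TRUE), 0.05)
  expect_equal(b$n_pre[b$lo == 100], 40)

  # no post data: all p undefined, counts still reported
  rep2 <- depth_report(pre, pre[0, ], bin_um = 50)
  expect_true(all(is.na(rep2$bins$mannwhitney_p)))
  expect_equal(sum(rep2$bins$n_pre), nrow(pre))
})

test_that("table building is idempotent on the track table", {
  tr <- simulate_track_table(scenario_low_intensity(n_animals = 5), seed = 6)
  t1 <- build_table1(list(low = tr))
  t2 <- build_table1(list(low = tr))
  expect_identical(t1, t2)
})
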