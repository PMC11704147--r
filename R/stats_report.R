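#' Paired two-tailed t test on per-animal values
#'
#' The unit of analysis is the animal: `pre` and `post` are equal-length
#' vectors of per-animal means. Identical vectors give t = 0, p = 1; a
#' nonzero but constant difference (zero variance) is reported as `NA` with
#' a message.
#'
#' @param pre,post paired per-animal values, n >= 2.
#' @return list: `t`, `p` (two-tailed), `df`, `mean_diff`, `n`.
#' @export
paired_t <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  ok <- complete.cases(pre, post)
  pre <- pre[ok]; post <- post[ok]
  n <- length(pre)
  if (n < 2) return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                         mean_diff = mean(post - pre), n = n))
  d <- post - pre
  if (sd(d) < .Machine$double.eps^0.5) {
    if (abs(mean(d)) < .Machine$double.eps^0.5)
      return(list(t = 0, p = 1, df = n - 1, mean_diff = 0, n = n))
    message("paired_t: zero variance of differences; p undefined")
    return(list(t = NA_real_, p = NA_real_, df = n - 1,
                mean_diff = mean(d), n = n))
  }
  tt <- t.test(post, pre, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d), n = n)
}

#' Two-way ANOVA with Fisher's LSD pairwise comparisons
#'
#' Fits `value ~ condition * timepoint` and computes Fisher's Least
#' Significant Difference tests: unadjusted pairwise t statistics between
#' cell means using the pooled ANOVA mean squared error and its residual
#' degrees of freedom (the classical definition; deliberately no
#' multiplicity adjustment).
#'
#' @param df data frame with numeric `value` and factors `condition`,
#'   `timepoint` (>= 2 levels each); every cell must be non-empty.
#' @return list: `anova` (data frame), `lsd` (pairwise table with `p`),
#'   `cell_means`.
#' @export
anova_lsd <- function(df) {
  stopifnot(all(c("value", "condition", "timepoint") %in% names(df)))
  df$condition <- factor(df$condition)
  df$timepoint <- factor(df$timepoint)
  if (nlevels(df$condition) < 2 || nlevels(df$timepoint) < 2)
    stop("need >= 2 levels per factor")
  tab <- table(df$condition, df$timepoint)
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: condition '%s' x timepoint '%s'",
                 rownames(tab)[bad[1]], colnames(tab)[bad[2]]))
  }
  cells <- aggregate(value ~ condition + timepoint, df, mean)
  counts <- aggregate(value ~ condition + timepoint, df, length)
  cells$n <- counts$value
  if (stats::var(df$value) < 1e-24) { # degenerate: all values identical
    an <- data.frame(term = c("condition", "timepoint",
                              "condition:timepoint", "Residuals"),
                     F = c(0, 0, 0, NA), p = c(1, 1, 1, NA))
    lsd <- .lsd_pairs(cells, mse = 0, dfres = nrow(df) - nrow(cells),
                      degenerate = TRUE)
    return(list(anova = an, lsd = lsd, cell_means = cells))
  }
  fit <- aov(value ~ condition * timepoint, data = df)
  an <- as.data.frame(anova(fit))
  an$term <- rownames(an)
  mse <- an["Residuals", "Mean Sq"]
  dfres <- an["Residuals", "Df"]
  lsd <- .lsd_pairs(cells, mse, dfres)
  list(anova = data.frame(term = an$term, Df = an$Df, `Sum Sq` = an$`Sum Sq`,
                          `Mean Sq` = an$`Mean Sq`, F = an$`F value`,
                          p = an$`Pr(>F)`, check.names = FALSE),
       lsd = lsd, cell_means = cells)
}

.lsd_pairs <- function(cells, mse, dfres, degenerate = FALSE) {
  lab <- paste(cells$condition, cells$timepoint, sep = ":")
  k <- nrow(cells)
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (degenerate || mse <= 0 || dfres <= 0) {
      tstat <- 0; p <- 1
    } else {
      se <- sqrt(mse * (1 / cells$n[i] + 1 / cells$n[j]))
      tstat <- (cells$value[i] - cells$value[j]) / se
      p <- 2 * stats::pt(-abs(tstat), dfres)
    }
    out[[length(out) + 1]] <- data.frame(
      a = lab[i], b = lab[j], diff = cells$value[i] - cells$value[j],
      t = tstat, p = p, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Mann-Whitney-Wilcoxon test for depth-resolved distributions
#'
#' Exact test when the combined sample size is at most 20 and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction. U counts pairs where the first sample exceeds the second.
#'
#' @param pre,post the two diameter distributions (branches as units).
#' @return list: `U`, `p` (two-tailed), `n_pre`, `n_post` (`p = NA` with a
#'   message when a sample is empty).
#' @export
mannwhitney_depth <- function(pre, post) {
  pre <- pre[is.finite(pre)]; post <- post[is.finite(post)]
  n1 <- length(pre); n2 <- length(post)
  if (n1 == 0 || n2 == 0) {
    message("mannwhitney_depth: empty sample; p undefined")
    return(list(U = NA_real_, p = NA_real_, n_pre = n1, n_post = n2))
  }
  ties <- anyDuplicated(c(pre, post)) > 0
  exact <- (n1 + n2) <= 20 && !ties
  wt <- suppressWarnings(wilcox.test(pre, post, exact = exact,
                                     correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, n_pre = n1, n_post = n2)
}

#' Build the study summary table (class x condition)
#'
#' Mirrors the headline group table of a two-dose sonication study: one row
#' per diameter class (plus "All vessels") and condition, with the
#' pre-sonication diameter summarized across branches (mean +/- SD), the
#' normalized diameters at the three post timepoints summarized across
#' animals (mean +/- SD of per-animal means), and the paired two-tailed t
#' test of the first post timepoint against baseline (animals as units).
#' Classes with no measurable branch are omitted with a message.
#'
#' @param track_list named list of normalized track tables (one per
#'   condition, e.g. `sham`, `low`, `high`); see [normalize_tracks()].
#' @return data frame, one row per class x condition.
#' @export
build_table1 <- function(track_list) {
  stopifnot(is.list(track_list), !is.null(names(track_list)))
  post_tps <- TIMEPOINTS[-1]
  rows <- list()
  for (cond in names(track_list)) {
    tr <- track_list[[cond]]
    for (cl in c("All vessels", CLASS_LABELS)) {
      sub <- if (cl == "All vessels") tr else
        tr[tr$class_label == cl, , drop = FALSE]
      pre <- sub[sub$timepoint == "pre" & sub$matched, , drop = FALSE]
      if (nrow(pre) == 0) {
        message(sprintf("build_table1: no branches for class '%s' (%s); row omitted",
                        cl, cond))
        next
      }
      pa <- per_animal_summary(if (cl == "All vessels") {
        tr2 <- sub; tr2$class_label <- "All vessels"; tr2
      } else sub)
      row <- data.frame(class = cl, condition = cond,
                        n_animals = length(unique(pre$animal)),
                        n_branches = nrow(pre),
                        pre_diam_mean = mean(pre$diameter_um),
                        pre_diam_sd = sd(pre$diameter_um),
                        stringsAsFactors = FALSE)
      post1 <- NULL
      for (tp in post_tps) {
        v <- pa$mean_norm[pa$timepoint == tp]
        row[[paste0("norm_", tp, "_mean")]] <-
          if (length(v)) mean(v) else NA_real_
        row[[paste0("norm_", tp, "_sd")]] <-
          if (length(v) > 1) sd(v) else NA_real_
        if (tp == post_tps[1]) post1 <- v
      }
      row$p_post1_vs_pre <- if (length(post1) >= 2)
        paired_t(rep(1, length(post1)), post1)$p else NA_real_
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Depth-resolved pre/post diameter report
#'
#' Bins depth-attributed branches into half-open depth bins and compares the
#' pre and post diameter distributions per bin (branches as units): counts,
#' medians and quartiles, and a Mann-Whitney test. Bins with fewer than 3
#' branches on either side report `p = NA` but keep their counts.
#'
#' @param pre_branches,post_branches data frames with `mean_diameter_um` and
#'   `depth_um` columns (e.g. from depth-resolved segmentation).
#' @param bin_um reporting bin width (um, default 50).
#' @param max_depth_um analysis depth (default 400).
#' @return list: `bins` (per-bin summary data frame) and `distributions`
#'   (long-format values for violin plotting: `lo`, `hi`, `phase`,
#'   `diameter_um`).
#' @export
depth_report <- function(pre_branches, post_branches, bin_um = 50,
                         max_depth_um = 400) {
  n <- ceiling(max_depth_um / bin_um)
  bins <- data.frame(lo = (seq_len(n) - 1) * bin_um, hi = seq_len(n) * bin_um)
  take <- function(df, lo, hi)
    df$mean_diameter_um[!is.na(df$depth_um) & df$depth_um >= lo &
                          df$depth_um < hi & !is.na(df$mean_diameter_um)]
  res <- list(); dist <- list()
  for (k in seq_len(n)) {
    dpre <- take(pre_branches, bins$lo[k], bins$hi[k])
    dpost <- take(post_branches, bins$lo[k], bins$hi[k])
    p <- NA_real_; U <- NA_real_
    if (length(dpre) >= 3 && length(dpost) >= 3) {
      mw <- mannwhitney_depth(dpre, dpost)
      p <- mw$p; U <- mw$U
    }
    qn <- function(v) if (length(v)) quantile(v, c(0.25, 0.5, 0.75)) else
      rep(NA_real_, 3)
    q1 <- qn(dpre); q2 <- qn(dpost)
    res[[k]] <- data.frame(
      lo = bins$lo[k], hi = bins$hi[k],
      n_pre = length(dpre), n_post = length(dpost),
      median_pre = q1[2], q25_pre = q1[1], q75_pre = q1[3],
      median_post = q2[2], q25_post = q2[1], q75_post = q2[3],
      U = U, mannwhitney_p = p, row.names = NULL)
    if (length(dpre))
      dist[[length(dist) + 1]] <- data.frame(
        lo = bins$lo[k], hi = bins$hi[k], phase = "pre",
        diameter_um = dpre, stringsAsFactors = FALSE)
    if (length(dpost))
      dist[[length(dist) + 1]] <- data.frame(
        lo = bins$lo[k], hi = bins$hi[k], phase = "post",
        diameter_um = dpost, stringsAsFactors = FALSE)
  }
  list(bins = do.call(rbind, res),
       distributions = if (length(dist)) do.call(rbind, dist) else
         data.frame(lo = numeric(), hi = numeric(), phase = character(),
                    diameter_um = numeric(), stringsAsFactors = FALSE))
}

#' Fast branch-table simulation of a study (no imaging)
#'
#' Simulates normalized track tables directly at the branch-table level:
#' per-animal baseline diameters are drawn per class, timepoint diameters
#' follow the scenario's class factors and animal-level perturbations, and
#' each measured diameter carries independent multiplicative measurement
#' noise (`meas_cv`, emulating the residual uncertainty of a branch mean
#' after cross-section averaging). Used for calibration experiments (e.g.
#' type-I error of the paired t under a sham scenario) where rendering
#' volumes would add nothing.
#'
#' @param scenario a [dilation_scenario()].
#' @param n_branches named per-class branch count per animal.
#' @param meas_cv per-branch measurement CV of a measured diameter.
#' @param seed RNG seed.
#' @return Normalized long-format track table (as [normalize_tracks()]).
#' @export
simulate_track_table <- function(scenario,
                                 n_branches = c("<15" = 50, "15-20" = 6,
                                                ">20" = 4),
                                 meas_cv = 0.02, seed = 1L) {
  set.seed(seed)
  base_mean <- c("<15" = 6.2, "15-20" = 17.5, ">20" = 30)
  base_sd <- c("<15" = 1.3, "15-20" = 1.4, ">20" = 8)
  rows <- list()
  for (a in seq_len(scenario$n_animals)) {
    for (cl in CLASS_LABELS) {
      nb <- n_branches[[cl]]
      if (nb == 0) next
      p <- .lognorm_pars(base_mean[[cl]], base_sd[[cl]])
      d0 <- rlnorm(nb, p["mu"], p["sigma"])
      for (t in seq_along(scenario$timepoints)) {
        tp <- scenario$timepoints[t]
        f <- scenario$effect_by_class[[cl]][t]
        if (tp != "pre" && scenario$inter_animal_sd > 0)
          f <- f * max(1 + rnorm(1, 0, scenario$inter_animal_sd), 0.05)
        d <- d0 * f * exp(rnorm(nb, -meas_cv^2 / 2,
                                sqrt(log1p(meas_cv^2))))
        rows[[length(rows) + 1]] <- data.frame(
          animal = a, branch_id = sprintf("%s_%03d", cl, seq_len(nb)),
          class_label = cl, timepoint = tp, diameter_um = d,
          matched = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  tracks <- do.call(rbind, rows)
  normalize_tracks(tracks)
}
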