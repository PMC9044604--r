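# scaffolding: build window_values / sexdiff objects from raw matrices
mk_wv <- function(mat, grid, samples, label = "unfiltered") {
  v <- list(); v[[label]] <- mat
  structure(list(grid = grid, values = v, samples = samples,
                 unbounded = label, masked = grid$short,
                 mask_reason = "", normalized = TRUE),
            class = "window_values")
}

mk_sheet <- function(n_f, n_m) {
  data.frame(id = c(paste0("F", seq_len(n_f)), paste0("M", seq_len(n_m))),
             sex = c(rep("female", n_f), rep("male", n_m)), bam = "x",
             stringsAsFactors = FALSE)
}

test_that("role means average within roles and pass single samples through", {
  idx <- genome_index("c", 20000)
  g <- make_window_grid(idx, 5000)
  sheet <- validate_sample_sheet(mk_sheet(1, 2), "XY", check_files = FALSE)
  m <- cbind(F1 = c(1, 1, 1, 1), M1 = c(0.4, 1, 1, 0), M2 = c(0.6, 1, 1, 0.2))
  wv <- mk_wv(m, g, sheet)
  gm <- sex_group_means(wv, sheet)$unfiltered
  expect_equal(gm[, "heterogametic"], c(0.5, 1, 1, 0.1))
  expect_equal(gm[, "homogametic"], m[, "F1"])
  # random data: equals brute-force averaging
  set.seed(3)
  sheet2 <- validate_sample_sheet(mk_sheet(3, 2), "XY", check_files = FALSE)
  m2 <- matrix(runif(4 * 5), 4, 5, dimnames = list(NULL, sheet2$id))
  gm2 <- sex_group_means(mk_wv(m2, g, sheet2), sheet2)$unfiltered
  expect_equal(gm2[, "heterogametic"],
               apply(m2[, sheet2$role == "heterogametic"], 1, mean))
  expect_equal(gm2[, "homogametic"],
               apply(m2[, sheet2$role == "homogametic"], 1, mean))
})

test_that("the sign convention is heterogametic minus homogametic", {
  means <- cbind(heterogametic = c(0.5, 1, 0.004),
                 homogametic = c(1.0, 1, 0.001))
  d <- sex_difference(means)
  expect_equal(d, c(-0.5, 0, 0.003))
  # antisymmetry under role swap
  swapped <- means[, c(2, 1)]
  colnames(swapped) <- colnames(means)
  expect_equal(sex_difference(swapped), -d)
})

# one scaffold, 2 Mb, 400 unit windows of 5 kb
sd_fixture <- function(diff_cov = NULL, seed = 13, n_f = 1, n_m = 1) {
  set.seed(seed)
  idx <- genome_index("chr1", 2e6)
  g <- make_window_grid(idx, 5000)
  sheet <- validate_sample_sheet(mk_sheet(n_f, n_m), "XY",
                                 check_files = FALSE)
  n <- nrow(g)
  cov <- matrix(rnorm(n * nrow(sheet), 1, 0.05), n, nrow(sheet),
                dimnames = list(NULL, sheet$id))
  if (!is.null(diff_cov)) cov[, sheet$role == "heterogametic"] <-
    cov[, sheet$role == "heterogametic"] + diff_cov
  het <- matrix(rpois(n * nrow(sheet), 5) / 5000, n, nrow(sheet),
                dimnames = list(NULL, sheet$id))
  cov_wv <- mk_wv(cov, g, sheet)
  het_wv <- mk_wv(het, g, sheet, label = "het")
  sexdiff_table(cov_wv, het_wv, sheet)
}

test_that("aggregation averages unmasked unit windows by midpoint", {
  sd <- sd_fixture()
  # constant unit values aggregate to the constant with full counts
  sd$metrics$coverage_unfiltered$diff[] <- 1
  agg <- aggregate_windows(sd, 1e6)
  expect_equal(agg$metrics$coverage_unfiltered$diff, c(1, 1))
  expect_equal(agg$metrics$coverage_unfiltered$n, c(200, 200))
  # all unit windows masked -> missing
  sd2 <- sd_fixture()
  sd2$masked[] <- TRUE
  expect_error(agg2 <- aggregate_windows(sd2, 1e6), NA)
  expect_true(all(is.na(agg2$metrics$coverage_unfiltered$diff)))
  # non-multiple report window is a configuration error
  expect_error(aggregate_windows(sd, 7777), "integer multiple")
})

test_that("aggregation equals brute-force midpoint binning on random masks", {
  set.seed(17)
  sd <- sd_fixture()
  sd$masked <- runif(length(sd$masked)) < 0.2
  agg <- aggregate_windows(sd, 1e5, min_n = 5)
  mid <- (sd$grid$start + sd$grid$end) / 2
  bin <- floor(mid / 1e5) + 1
  for (k in names(sd$metrics)) {
    d <- sd$metrics[[k]]$diff
    brute <- vapply(1:20, function(b) {
      sel <- bin == b & !sd$masked
      if (sum(sel) < 5) return(NA_real_)
      mean(d[sel])
    }, 0)
    expect_equal(agg$metrics[[k]]$diff, brute, info = k)
  }
})

test_that("aggregated means reproduce the n-weighted genome-wide mean", {
  set.seed(19)
  sd <- sd_fixture()
  sd$masked <- runif(length(sd$masked)) < 0.1
  agg <- aggregate_windows(sd, 1e5, min_n = 1)
  k <- "coverage_unfiltered"
  w_mean <- sum(agg$metrics[[k]]$diff * agg$metrics[[k]]$n) /
    sum(agg$metrics[[k]]$n)
  expect_equal(w_mean, mean(sd$metrics[[k]]$diff[!sd$masked]))
})

test_that("the 95% band matches normal quantiles on simulated diffs", {
  set.seed(23)
  sd <- sd_fixture()
  n <- length(sd$metrics$coverage_unfiltered$diff)
  agg <- aggregate_windows(sd, 1e4, min_n = 1)
  m <- length(agg$metrics$coverage_unfiltered$diff)
  agg$metrics$coverage_unfiltered$diff <- rnorm(m)
  band <- confidence_band(agg)
  b <- band[band$metric == "coverage_unfiltered", ]
  # Monte-Carlo tolerance at m = 200 windows
  expect_lt(abs(b$low - qnorm(0.025)), 0.35)
  expect_lt(abs(b$high - qnorm(0.975)), 0.35)
  # constant diffs give a degenerate band and no outliers
  agg$metrics$coverage_unfiltered$diff[] <- 0.7
  band2 <- confidence_band(agg)
  b2 <- band2[band2$metric == "coverage_unfiltered", ]
  expect_equal(c(b2$low, b2$high), c(0.7, 0.7))
  flagged <- flag_outlier_windows(agg, band2)
  expect_true(all(flagged$metrics$coverage_unfiltered$outlier == "none"))
  # the mean +/- 1.96 SD variant
  agg$metrics$coverage_unfiltered$diff <- rnorm(m)
  b3 <- confidence_band(agg, method = "meansd")
  d <- agg$metrics$coverage_unfiltered$diff
  expect_equal(b3$low[b3$metric == "coverage_unfiltered"],
               mean(d) - qnorm(0.975) * sd(d))
})

test_that("too few report windows omits the band with a warning", {
  sd <- sd_fixture()
  agg <- aggregate_windows(sd, 1e6)  # only 2 report windows
  w <- capture_warnings(band <- confidence_band(agg))
  expect_true(all(grepl("omitted", w)))
  expect_equal(length(w), length(agg$metrics))  # one per metric
  expect_true(all(is.na(band$low)))
})

test_that("outlier flagging marks exactly the windows outside the band", {
  set.seed(29)
  sd <- sd_fixture()
  agg <- aggregate_windows(sd, 1e4, min_n = 1)
  m <- length(agg$metrics$coverage_unfiltered$diff)
  d <- rnorm(m)
  # injected differentiated block, kept below 2.5% of windows so the
  # empirical band threshold stays in the null noise
  d[11:13] <- -8
  agg$metrics$coverage_unfiltered$diff <- d
  flagged <- flag_outlier_windows(agg, confidence_band(agg))
  o <- flagged$metrics$coverage_unfiltered$outlier
  expect_true(all(o[11:13] == "low"))
  b <- flagged$band[flagged$band$metric == "coverage_unfiltered", ]
  expect_equal(which(o == "high"), which(d > b$high))
  expect_equal(which(o == "low"), which(d < b$low))
  ot <- outlier_table(flagged)
  expect_true(all(ot$outlier %in% c("high", "low")))
  expect_equal(sum(ot$metric == "coverage_unfiltered"),
               sum(o != "none"))
})

test_that("about 5% of null windows are flagged, and role permutation preserves this", {
  set.seed(37)
  frac <- replicate(10, {
    sd <- sd_fixture(seed = sample.int(1e6, 1))
    agg <- aggregate_windows(sd, 1e4, min_n = 1)
    agg$metrics$coverage_unfiltered$diff <-
      rnorm(length(agg$metrics$coverage_unfiltered$diff))
    flagged <- flag_outlier_windows(agg, confidence_band(agg))
    mean(flagged$metrics$coverage_unfiltered$outlier != "none")
  })
  expect_lt(abs(mean(frac) - 0.05), 0.02)
})

test_that("per-scaffold summaries equal group-by brute force", {
  set.seed(41)
  idx <- genome_index(c("a", "b", "c"), c(5e5, 3e5, 2e5))
  g <- make_window_grid(idx, 5000)
  sheet <- validate_sample_sheet(mk_sheet(1, 1), "XY", check_files = FALSE)
  n <- nrow(g)
  cov <- matrix(rnorm(2 * n, 1, 0.1), n, 2, dimnames = list(NULL, sheet$id))
  het <- matrix(rpois(2 * n, 5) / 5000, n, 2,
                dimnames = list(NULL, sheet$id))
  sd <- sexdiff_table(mk_wv(cov, g, sheet), mk_wv(het, g, sheet, "het"),
                      sheet)
  sd$masked <- runif(n) < 0.3
  ps <- per_scaffold_summary(sd)
  for (sc in idx$name) {
    sel <- g$scaffold == sc & !sd$masked
    row <- ps[ps$scaffold == sc & ps$setting == "unfiltered", ]
    expect_equal(row$cov_diff,
                 mean(sd$metrics$coverage_unfiltered$diff[sel]))
    expect_equal(row$het_diff, mean(sd$metrics$heterozygosity$diff[sel]))
    expect_equal(row$n_windows, sum(sel))
  }
  # single-scaffold genome: summary equals the genome-wide mean
  idx1 <- genome_index("solo", 5e5)
  g1 <- make_window_grid(idx1, 5000)
  sd1 <- sexdiff_table(mk_wv(cov[1:100, , drop = FALSE], g1, sheet),
                       mk_wv(het[1:100, , drop = FALSE], g1, sheet, "het"),
                       sheet)
  ps1 <- per_scaffold_summary(sd1)
  expect_equal(ps1$cov_diff[1],
               mean(sd1$metrics$coverage_unfiltered$diff[!sd1$masked]))
  # fully masked scaffold is excluded with a note
  sd$masked[g$scaffold == "c"] <- TRUE
  ps2 <- per_scaffold_summary(sd)
  expect_false("c" %in% ps2$scaffold)
  expect_equal(attr(ps2, "excluded"), "c")
})

test_that("per-chromosome summaries report mean, SD and degenerate cases", {
  set.seed(43)
  sd <- sd_fixture()
  agg <- aggregate_windows(sd, 1e5, min_n = 1)
  k <- "coverage_unfiltered"
  # constant diffs on the single scaffold -> SD 0
  agg$metrics[[k]]$diff[] <- 0.3
  cs <- per_chromosome_summary(agg)
  row <- cs[cs$metric == k, ]
  expect_equal(row$mean, 0.3)
  expect_equal(row$sd, 0)
  # one non-missing window -> SD reported as 0 with n = 1
  agg$metrics[[k]]$diff[] <- NA
  agg$metrics[[k]]$diff[1] <- 0.9
  cs2 <- per_chromosome_summary(agg)
  row2 <- cs2[cs2$metric == k, ]
  expect_equal(c(row2$mean, row2$sd, row2$n), c(0.9, 0, 1))
  # random data matches brute-force mean/SD and the medians attribute
  d <- rnorm(20)
  agg$metrics[[k]]$diff <- d
  cs3 <- per_chromosome_summary(agg)
  row3 <- cs3[cs3$metric == k, ]
  expect_equal(row3$mean, mean(d))
  expect_equal(row3$sd, sd(d))
  expect_equal(attr(cs3, "medians")[[k]], median(d))
})

test_that("per-sample profiles collapse to role means for single-sample roles", {
  set.seed(47)
  idx <- genome_index("c", 1e6)
  g <- make_window_grid(idx, 5000)
  sheet <- validate_sample_sheet(mk_sheet(1, 1), "XY", check_files = FALSE)
  cov <- matrix(rnorm(2 * nrow(g), 1, 0.1), nrow(g), 2,
                dimnames = list(NULL, sheet$id))
  het <- matrix(rpois(2 * nrow(g), 5) / 5000, nrow(g), 2,
                dimnames = list(NULL, sheet$id))
  cov_wv <- mk_wv(cov, g, sheet); het_wv <- mk_wv(het, g, sheet, "het")
  pr <- per_sample_profiles(cov_wv, het_wv, 1e5)
  sd <- sexdiff_table(cov_wv, het_wv, sheet)
  agg <- aggregate_windows(sd, 1e5)
  expect_equal(pr$tracks$coverage_unfiltered[, "M1"],
               agg$metrics$coverage_unfiltered$het_mean)
  expect_equal(pr$tracks$coverage_unfiltered[, "F1"],
               agg$metrics$coverage_unfiltered$hom_mean)
  # identical samples give identical tracks
  cov2 <- cov; cov2[, 2] <- cov2[, 1]
  pr2 <- per_sample_profiles(mk_wv(cov2, g, sheet), het_wv, 1e5)
  expect_equal(pr2$tracks$coverage_unfiltered[, 1],
               pr2$tracks$coverage_unfiltered[, 2])
})
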