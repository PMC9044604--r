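strict <- list(label = "0mm", max_mismatches = 0)
inter <- list(label = "2mm", max_mismatches = 2)
unbounded <- list(label = "unfiltered", max_mismatches = Inf)
three <- list(strict, inter, unbounded)

test_that("the alignment filter gates on mapping quality and NM", {
  aln <- list(mapq = c(60L, 60L, 10L, 60L, 60L),
              nm = c(0L, 3L, 0L, NA, 2L))
  expect_equal(as.logical(suppressWarnings(passes_alignment_filter(aln, strict))),
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(as.logical(suppressWarnings(passes_alignment_filter(aln, inter))),
               c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # unbounded ignores NM (and missing NM) but keeps the MAPQ floor
  expect_equal(as.logical(passes_alignment_filter(aln, unbounded)),
               c(TRUE, TRUE, FALSE, TRUE, TRUE))
})

test_that("kept counts match an exhaustive NM-tag scan on simulated records", {
  set.seed(11)
  n <- 1000
  aln <- list(mapq = sample(c(0L, 20L, 60L), n, replace = TRUE,
                            prob = c(0.05, 0.15, 0.8)),
              nm = sample(c(0:6, NA), n, replace = TRUE))
  for (s in three) {
    keep <- suppressWarnings(passes_alignment_filter(aln, s))
    brute <- sum(vapply(seq_len(n), function(i) {
      if (aln$mapq[i] < 20) return(FALSE)
      if (!is.finite(s$max_mismatches)) return(TRUE)
      !is.na(aln$nm[i]) && aln$nm[i] <= s$max_mismatches
    }, TRUE))
    expect_equal(sum(keep), brute, info = s$label)
  }
})

test_that("a warning fires when >1% of records lack NM under a bounded setting", {
  aln <- list(mapq = rep(60L, 100), nm = c(rep(NA, 5), rep(0L, 95)))
  expect_warning(passes_alignment_filter(aln, strict), "NM tag")
})

test_that("window coverage equals simple closed-form cases", {
  idx <- genome_index("chrA", 10000)
  g <- make_window_grid(idx, 5000)
  dir <- tempfile()
  bam <- write_fixture_bam(dir, "one", idx, "r1", 0L, "chrA", 101L, 60L,
                           "100M", 0L)
  sheet <- data.frame(id = "S1", sex = "female", bam = bam,
                      stringsAsFactors = FALSE)
  wv <- window_coverage(sheet, g, list(unbounded))
  expect_equal(wv$values$unfiltered[, 1], c(100 / 5000, 0))
  # a read straddling the window boundary splits proportionally
  bam2 <- write_fixture_bam(dir, "strad", idx, "r1", 0L, "chrA", 4951L,
                            60L, "100M", 0L)
  sheet$bam <- bam2
  wv2 <- window_coverage(sheet, g, list(unbounded))
  expect_equal(wv2$values$unfiltered[, 1], c(50 / 5000, 50 / 5000))
})

test_that("empty alignment files give zero coverage everywhere", {
  idx <- genome_index(c("cA", "cB"), c(4000, 3000))
  g <- make_window_grid(idx, 2000)
  bam <- write_fixture_bam(tempfile(), "empty", idx, character(),
                           integer(), character(), integer(), integer(),
                           character(), integer())
  sheet <- data.frame(id = "S1", sex = "female", bam = bam,
                      stringsAsFactors = FALSE)
  wv <- window_coverage(sheet, g, list(unbounded))
  expect_true(all(wv$values$unfiltered == 0))
})

test_that("window coverage equals the per-base pileup oracle on random fixtures", {
  for (seed in 1:5) {
    fx <- random_bam_fixture(seed)
    g <- make_window_grid(fx$index, 500)
    sheet <- data.frame(id = "S1", sex = "female", bam = fx$bam,
                        stringsAsFactors = FALSE)
    wv <- window_coverage(sheet, g, list(unbounded))
    oracle <- oracle_pileup_coverage(fx$rname, fx$pos, fx$cigar, g)
    expect_equal(wv$values$unfiltered[, 1], oracle, info = seed)
  }
})

test_that("records on scaffolds absent from the index are an error", {
  idx_big <- genome_index(c("cA", "cB"), c(2000, 2000))
  bam <- write_fixture_bam(tempfile(), "mis", idx_big, "r1", 0L, "cB",
                           10L, 60L, "50M", 0L)
  idx_small <- genome_index("cA", 2000)
  g <- make_window_grid(idx_small, 1000)
  sheet <- data.frame(id = "S1", sex = "female", bam = bam,
                      stringsAsFactors = FALSE)
  expect_error(window_coverage(sheet, g, list(unbounded)), "absent")
})

test_that("total raw coverage mass equals total kept aligned bases", {
  fx <- random_bam_fixture(99)
  g <- make_window_grid(fx$index, 500)
  sheet <- data.frame(id = "S1", sex = "female", bam = fx$bam,
                      stringsAsFactors = FALSE)
  wv <- window_coverage(sheet, g, list(unbounded))
  aligned <- sum(vapply(seq_along(fx$pos), function(i) {
    b <- oracle_ref_blocks(fx$pos[i], fx$cigar[i])
    sum(b[, 2] - b[, 1] + 1)
  }, 0))
  expect_equal(sum(wv$values$unfiltered[, 1] * g$length), aligned)
})

make_cov <- function(mat_list, grid, samples) {
  # assemble a window_values object from raw matrices (test scaffolding)
  structure(list(grid = grid, values = mat_list, samples = samples,
                 unbounded = "unfiltered", masked = grid$short,
                 mask_reason = ifelse(grid$short, "short_window", ""),
                 normalized = FALSE),
            class = "window_values")
}

test_that("outlier masking applies the 10x-median rule per sample", {
  idx <- genome_index("c", 50000)
  g <- make_window_grid(idx, 5000)
  m <- matrix(10, 10, 2, dimnames = list(NULL, c("a", "b")))
  wv <- make_cov(list(unfiltered = m), g,
                 data.frame(id = c("a", "b"), sex = c("female", "male")))
  expect_false(any(mask_outlier_windows(wv)$masked))
  m2 <- m; m2[4, 1] <- 200  # 200 > 10 * median 10
  wv2 <- make_cov(list(unfiltered = m2), g, wv$samples)
  expect_equal(which(mask_outlier_windows(wv2)$masked), 4L)
})

test_that("masked set equals a brute-force threshold scan on noisy data", {
  set.seed(5)
  idx <- genome_index("c", 5e5)
  g <- make_window_grid(idx, 5000)
  n <- nrow(g)
  base <- matrix(rpois(2 * n, 10), n, 2, dimnames = list(NULL, c("a", "b")))
  hot <- sample(n, round(0.01 * n))
  base[hot, 1] <- 50 * 10
  wv <- make_cov(list(unfiltered = base), g,
                 data.frame(id = c("a", "b"), sex = c("female", "male")))
  masked <- mask_outlier_windows(wv, 10)$masked
  meds <- apply(base, 2, median)
  brute <- (base[, 1] > 10 * meds[1]) | (base[, 2] > 10 * meds[2])
  expect_equal(masked, brute | g$short)
})

test_that("fully masked input is a hard error", {
  idx <- genome_index("c", 30000)
  g <- make_window_grid(idx, 5000)
  # each sample has two extreme windows; jointly every window is masked
  m <- matrix(1, 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  m[1:2, 1] <- 1e6; m[3:4, 2] <- 1e6; m[5:6, 3] <- 1e6
  wv <- make_cov(list(unfiltered = m), g,
                 data.frame(id = c("a", "b", "c"),
                            sex = c("female", "male", "female")))
  expect_error(mask_outlier_windows(wv), "degenerate")
})

test_that("normalization scales each sample-setting to unit mean", {
  idx <- genome_index("c", 50000)
  g <- make_window_grid(idx, 5000)
  m <- matrix(c(rep(10, 10), rep(20, 10)), 10, 2,
              dimnames = list(NULL, c("a", "b")))
  wv <- make_cov(list(unfiltered = m), g,
                 data.frame(id = c("a", "b"), sex = c("female", "male")))
  wv <- normalize_coverage(mask_outlier_windows(wv))
  expect_true(all(wv$values$unfiltered == 1))
  # depth-invariance: samples at uniform 10 and 20 become identical
  expect_equal(wv$values$unfiltered[, "a"], wv$values$unfiltered[, "b"])
})

test_that("normalization is invariant to per-sample rescaling and exact in the mean", {
  set.seed(21)
  idx <- genome_index("c", 5e5)
  g <- make_window_grid(idx, 5000)
  n <- nrow(g)
  m <- matrix(rgamma(2 * n, 10), n, 2, dimnames = list(NULL, c("a", "b")))
  wv <- make_cov(list(unfiltered = m), g,
                 data.frame(id = c("a", "b"), sex = c("female", "male")))
  wv <- normalize_coverage(mask_outlier_windows(wv))
  for (j in 1:2)
    expect_lt(abs(mean(wv$values$unfiltered[!wv$masked, j]) - 1), 1e-9)
  # multiply one sample's raw depths by 7: identical normalized values
  m2 <- m; m2[, 2] <- m2[, 2] * 7
  wv2 <- make_cov(list(unfiltered = m2), g, wv$samples)
  wv2 <- normalize_coverage(mask_outlier_windows(wv2))
  expect_equal(wv2$values$unfiltered, wv$values$unfiltered)
})

test_that("a sample with zero coverage is reported by name", {
  idx <- genome_index("c", 20000)
  g <- make_window_grid(idx, 5000)
  m <- matrix(c(rep(10, 4), rep(0, 4)), 4, 2,
              dimnames = list(NULL, c("ok", "empty")))
  wv <- make_cov(list(unfiltered = m), g,
                 data.frame(id = c("ok", "empty"), sex = c("female", "male")))
  expect_error(normalize_coverage(mask_outlier_windows(wv)), "empty")
})

test_that("kept-read sets are nested across settings on simulated data", {
  fx <- preset_dataset("fig1b")
  g <- make_window_grid(read_genome_index(fx$ds$reference), 5000)
  sheet <- validate_sample_sheet(fx$ds$samples, "XY")
  wv <- window_coverage(sheet, g, three)
  for (j in seq_len(ncol(wv$values[[1]]))) {
    expect_true(all(wv$values[["0mm"]][, j] <= wv$values[["2mm"]][, j] + 1e-12))
    expect_true(all(wv$values[["2mm"]][, j] <=
                      wv$values[["unfiltered"]][, j] + 1e-12))
  }
})
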