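# Metric keys used throughout: "heterozygosity" for the het branch and
# "coverage_<setting label>" for each mismatch setting of the coverage
# branch. The sign convention is heterogametic minus homogametic in both
# systems: differentiated sex-linked regions give negative coverage diffs,
# low-differentiation regions give positive heterozygosity diffs.

.metric_keys <- function(cov_wv) {
  c("heterozygosity", paste0("coverage_", names(cov_wv$values)))
}

#' Per-window sex-group means for one value table
#'
#' Unweighted mean across the samples of each heterogamety role, for every
#' setting in the table. Single-sample roles pass the sample values
#' through.
#'
#' @param wv A `window_values` table (coverage or heterozygosity).
#' @param samples Validated sample sheet with a `role` column.
#' @return Named list (per setting label) of two-column matrices
#'   `heterogametic`, `homogametic`.
#' @export
sex_group_means <- function(wv, samples) {
  samples <- samples[match(colnames(wv$values[[1]]), samples$id), ]
  het_cols <- samples$role == "heterogametic"
  lapply(wv$values, function(m)
    cbind(heterogametic = rowMeans(m[, het_cols, drop = FALSE]),
          homogametic = rowMeans(m[, !het_cols, drop = FALSE])))
}

#' Sex difference from role means
#'
#' @param means A two-column matrix (`heterogametic`, `homogametic`) as
#'   produced by [sex_group_means()].
#' @return Numeric vector: heterogametic mean minus homogametic mean.
#' @export
sex_difference <- function(means) {
  means[, "heterogametic"] - means[, "homogametic"]
}

#' Combine coverage and heterozygosity into a unit-window sex-difference table
#'
#' @param cov_wv Normalized coverage `window_values`.
#' @param het_wv Heterozygosity `window_values`.
#' @param samples Validated sample sheet.
#' @return A `sexdiff_unit` object: list with `grid`, `masked` (union of the
#'   coverage mask and short-window flags, applied to both metrics),
#'   `samples`, and `metrics` — per metric key a list of `het_mean`,
#'   `hom_mean`, `diff` vectors over unit windows.
#' @export
sexdiff_table <- function(cov_wv, het_wv, samples) {
  stopifnot(nrow(cov_wv$grid) == nrow(het_wv$grid))
  metrics <- list()
  hm <- sex_group_means(het_wv, samples)[["het"]]
  metrics[["heterozygosity"]] <- list(het_mean = hm[, 1], hom_mean = hm[, 2],
                                      diff = sex_difference(hm))
  for (l in names(cov_wv$values)) {
    cm <- sex_group_means(cov_wv, samples)[[l]]
    metrics[[paste0("coverage_", l)]] <-
      list(het_mean = cm[, 1], hom_mean = cm[, 2], diff = sex_difference(cm))
  }
  structure(list(grid = cov_wv$grid, masked = cov_wv$masked | het_wv$masked,
                 mask_reason = cov_wv$mask_reason, samples = samples,
                 metrics = metrics),
            class = "sexdiff_unit")
}

# Assign each (scaffold, midpoint) to a report-grid window id (NA outside).
.bin_by_midpoint <- function(scaffold, mid, report_grid) {
  bin <- rep(NA_integer_, length(mid))
  for (sc in unique(scaffold)) {
    if (!sc %in% report_grid$scaffold) next
    sel <- scaffold == sc
    win <- .grid_ranges(report_grid, sc)
    offset <- match(sc, report_grid$scaffold) - 1L
    h <- IRanges::findOverlaps(
      IRanges::IRanges(as.integer(floor(mid[sel])) + 1L, width = 1L), win)
    b <- rep(NA_integer_, sum(sel))
    b[S4Vectors::queryHits(h)] <- offset + S4Vectors::subjectHits(h)
    bin[sel] <- b
  }
  bin
}

# Mean per report bin of unmasked rows of a matrix (or vector); bins with
# fewer than min_n contributing unit windows are set missing.
.aggregate_values <- function(x, bin, masked, n_bins, min_n) {
  x <- as.matrix(x)
  keep <- !masked & !is.na(bin)
  out <- matrix(NA_real_, n_bins, ncol(x), dimnames = list(NULL, colnames(x)))
  n <- integer(n_bins)
  if (any(keep)) {
    tn <- table(factor(bin[keep], levels = seq_len(n_bins)))
    n <- as.integer(tn)
    s <- rowsum(x[keep, , drop = FALSE], bin[keep])
    rows <- as.integer(rownames(s))
    out[rows, ] <- s / n[rows]
  }
  out[n < min_n, ] <- NA_real_
  list(values = out, n = n)
}

#' Aggregate unit-window sex differences to report windows
#'
#' Bins unit windows by midpoint into a coarser window grid and averages
#' unmasked values. Report windows with fewer than `min_n` contributing
#' unit windows are set missing (suppresses noise where few unit windows
#' anchor, e.g. after liftover).
#'
#' @param sd `sexdiff_unit` from [sexdiff_table()].
#' @param report_window Report window size in bp; must be an integer
#'   multiple >= 2 of the unit window.
#' @param min_n Minimum contributing unit windows (default 5).
#' @return A `sexdiff_agg` object: `report_grid`, per-metric `het_mean`,
#'   `hom_mean`, `diff`, and `n` (contributing unit windows per report
#'   window).
#' @export
aggregate_windows <- function(sd, report_window, min_n = 5) {
  unit <- attr(sd$grid, "window")
  if (report_window %% unit != 0 || report_window < 2 * unit)
    stop("report window (", report_window, ") must be an integer multiple ",
         ">= 2 of the unit window (", unit, ")", call. = FALSE)
  index <- attr(sd$grid, "index")
  rgrid <- make_window_grid(index, report_window)
  mid <- (sd$grid$start + sd$grid$end) / 2
  bin <- .bin_by_midpoint(sd$grid$scaffold, mid, rgrid)
  metrics <- lapply(sd$metrics, function(m) {
    a <- .aggregate_values(cbind(het_mean = m$het_mean, hom_mean = m$hom_mean,
                                 diff = m$diff),
                           bin, sd$masked, nrow(rgrid), min_n)
    list(het_mean = a$values[, "het_mean"], hom_mean = a$values[, "hom_mean"],
         diff = a$values[, "diff"], n = a$n)
  })
  structure(list(report_grid = rgrid, report_window = report_window,
                 metrics = metrics, samples = sd$samples),
            class = "sexdiff_agg")
}

#' Genome-wide 95% band per metric
#'
#' The outlier band for the genome scan: by default the empirical 2.5th and
#' 97.5th percentiles of the genome-wide report-window difference
#' distribution per metric (`"quantile"`), optionally mean +/- 1.96 SD
#' (`"meansd"`). The band is an outlier threshold for the scan, not a
#' standard error of the mean. Requires at least `min_windows` non-missing
#' report windows, otherwise the band is omitted with a warning.
#'
#' @param agg `sexdiff_agg` from [aggregate_windows()].
#' @param level Band mass (fixed at 0.95 for the standard analysis).
#' @param method `"quantile"` or `"meansd"`.
#' @param min_windows Minimum non-missing report windows (default 20).
#' @return data.frame with `metric`, `low`, `high`, `method`; `NA` bounds
#'   where the band was omitted.
#' @export
confidence_band <- function(agg, level = 0.95,
                            method = c("quantile", "meansd"),
                            min_windows = 20) {
  method <- match.arg(method)
  alpha <- (1 - level) / 2
  rows <- lapply(names(agg$metrics), function(k) {
    d <- agg$metrics[[k]]$diff
    d <- d[!is.na(d)]
    if (length(d) < min_windows) {
      warning("band omitted for ", k, ": only ", length(d),
              " non-missing report windows (need ", min_windows, ")",
              call. = FALSE)
      return(data.frame(metric = k, low = NA_real_, high = NA_real_,
                        method = method, stringsAsFactors = FALSE))
    }
    if (method == "quantile") {
      q <- stats::quantile(d, c(alpha, 1 - alpha), names = FALSE)
    } else {
      z <- stats::qnorm(1 - alpha)
      q <- mean(d) + c(-z, z) * stats::sd(d)
    }
    data.frame(metric = k, low = q[1], high = q[2], method = method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag report windows outside the band
#'
#' @param agg `sexdiff_agg`.
#' @param band Band table from [confidence_band()].
#' @return `agg` with an added per-metric `outlier` vector
#'   (`"none"`/`"high"`/`"low"`, `NA` for missing windows).
#' @export
flag_outlier_windows <- function(agg, band) {
  for (k in names(agg$metrics)) {
    d <- agg$metrics[[k]]$diff
    b <- band[band$metric == k, ]
    o <- rep(NA_character_, length(d))
    ok <- !is.na(d)
    if (nrow(b) == 1 && !is.na(b$low)) {
      o[ok] <- "none"
      o[ok & d > b$high] <- "high"
      o[ok & d < b$low] <- "low"
    }
    agg$metrics[[k]]$outlier <- o
  }
  agg$band <- band
  agg
}

#' Outlier windows as a long table
#'
#' One row per (metric, report window) flagged outside the 95% band, with
#' 1-based inclusive coordinates — the "outlier tables" used to read off
#' candidate sex-linked ranges and pseudoautosomal boundaries.
#'
#' @param agg Flagged `sexdiff_agg` from [flag_outlier_windows()].
#' @return data.frame `metric`, `scaffold`, `start`, `end`, `diff`,
#'   `outlier`.
#' @export
outlier_table <- function(agg) {
  rows <- lapply(names(agg$metrics), function(k) {
    m <- agg$metrics[[k]]
    sel <- which(!is.na(m$outlier) & m$outlier != "none")
    if (length(sel) == 0) return(NULL)
    data.frame(metric = k,
               scaffold = agg$report_grid$scaffold[sel],
               start = agg$report_grid$start[sel] + 1,
               end = agg$report_grid$end[sel],
               diff = m$diff[sel], outlier = m$outlier[sel],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(metric = character(), scaffold = character(),
                      start = numeric(), end = numeric(), diff = numeric(),
                      outlier = character(), stringsAsFactors = FALSE)
  out
}

#' Per-scaffold sex-difference summary
#'
#' Mean coverage and heterozygosity differences over unmasked unit windows
#' for every scaffold and setting, with scaffold length — the data behind
#' the per-scaffold scatter (useful for fragmented assemblies). Fully
#' masked scaffolds are excluded and listed in the `excluded` attribute.
#'
#' @param sd `sexdiff_unit`.
#' @return data.frame `scaffold`, `setting`, `length`, `cov_diff`,
#'   `het_diff`, `n_windows`.
#' @export
per_scaffold_summary <- function(sd) {
  index <- attr(sd$grid, "index")
  keep <- !sd$masked
  cov_keys <- grep("^coverage_", names(sd$metrics), value = TRUE)
  rows <- list()
  excluded <- character()
  for (sc in index$name) {
    sel <- sd$grid$scaffold == sc & keep
    if (!any(sel)) { excluded <- c(excluded, sc); next }
    hd <- mean(sd$metrics[["heterozygosity"]]$diff[sel])
    for (ck in cov_keys) {
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = sc, setting = sub("^coverage_", "", ck),
        length = index$length[index$name == sc],
        cov_diff = mean(sd$metrics[[ck]]$diff[sel]),
        het_diff = hd, n_windows = sum(sel), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}

#' Per-chromosome mean and SD of sex differences
#'
#' Mean and standard deviation of report-window differences per scaffold,
#' metric and setting (the data behind the mean +/- SD chromosome plot),
#' plus genome-wide medians per metric for the dashed reference lines.
#' Scaffolds with a single non-missing report window get SD 0 and `n = 1`.
#'
#' @param agg `sexdiff_agg`.
#' @return data.frame `scaffold`, `metric`, `mean`, `sd`, `n`, `length`,
#'   with attribute `medians` (named per-metric genome-wide medians).
#' @export
per_chromosome_summary <- function(agg) {
  index <- attr(agg$report_grid, "index")
  rows <- list()
  medians <- stats::setNames(numeric(length(agg$metrics)),
                             names(agg$metrics))
  for (k in names(agg$metrics)) {
    d <- agg$metrics[[k]]$diff
    medians[k] <- stats::median(d, na.rm = TRUE)
    for (sc in index$name) {
      sel <- agg$report_grid$scaffold == sc & !is.na(d)
      n <- sum(sel)
      if (n == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = sc, metric = k, mean = mean(d[sel]),
        sd = if (n > 1) stats::sd(d[sel]) else 0, n = n,
        length = index$length[index$name == sc], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "medians") <- medians
  out
}

#' Per-sample value tracks at report-window resolution
#'
#' Normalized coverage per setting and heterozygosity per sample, averaged
#' over unmasked unit windows in each report window — the data behind the
#' per-sample profile plot used to confirm sample sexing.
#'
#' @param cov_wv Normalized coverage `window_values`.
#' @param het_wv Heterozygosity `window_values`.
#' @param report_window Report window size in bp.
#' @param min_n Minimum contributing unit windows (default 5).
#' @return List with `report_grid` and `tracks`: per metric key a report
#'   windows x samples matrix.
#' @export
per_sample_profiles <- function(cov_wv, het_wv, report_window, min_n = 5) {
  index <- attr(cov_wv$grid, "index")
  rgrid <- make_window_grid(index, report_window)
  mid <- (cov_wv$grid$start + cov_wv$grid$end) / 2
  bin <- .bin_by_midpoint(cov_wv$grid$scaffold, mid, rgrid)
  masked <- cov_wv$masked | het_wv$masked
  tracks <- list()
  for (l in names(cov_wv$values))
    tracks[[paste0("coverage_", l)]] <-
      .aggregate_values(cov_wv$values[[l]], bin, masked, nrow(rgrid),
                        min_n)$values
  tracks[["heterozygosity"]] <-
    .aggregate_values(het_wv$values[["het"]], bin, masked, nrow(rgrid),
                      min_n)$values
  list(report_grid = rgrid, tracks = tracks)
}
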