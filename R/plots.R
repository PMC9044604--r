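# Five diagnostic plot types, rendered as multi-page PDFs with base
# graphics. Colour semantics are fixed throughout: red = above the 95%
# band, blue = below, grey band = the 95% interval itself. The final page
# of every PDF lists the output tables the plot was drawn from.

# cumulative x-coordinates for genome-wide scans; returns per-row x plus
# scaffold boundaries for axis annotation
.genome_coords <- function(scaffold, start, end, index) {
  offsets <- c(0, cumsum(as.numeric(index$length)))[seq_len(nrow(index))]
  names(offsets) <- index$name
  x <- offsets[scaffold] + (start + end) / 2
  list(x = x, offsets = offsets,
       total = sum(as.numeric(index$length)))
}

.subset_index <- function(index, chromosomes) {
  if (is.null(chromosomes)) return(index)
  keep <- index$name %in% chromosomes
  if (!any(keep))
    stop("chromosome subset matches no scaffold; available: ",
         paste(utils::head(index$name, 20), collapse = ", "), call. = FALSE)
  genome_index(index$name[keep], index$length[keep])
}

.metric_label <- function(k) {
  if (k == "heterozygosity") "Heterozygosity diff (het per bp)"
  else paste0("Coverage diff (", sub("^coverage_", "", k), ")")
}

# order: heterozygosity first, then coverage settings as configured
.scan_metric_order <- function(metrics) {
  c("heterozygosity", grep("^coverage_", names(metrics), value = TRUE))
}

.table_path_page <- function(paths) {
  graphics::plot.new()
  graphics::title(main = "Source data tables")
  if (length(paths) == 0) paths <- "(none recorded)"
  graphics::text(0, seq(0.95, by = -0.05, length.out = length(paths)),
                 paths, adj = 0, cex = 0.7, family = "mono")
}

#' Plot type 1: genome-wide sex-difference scan
#'
#' One row per metric (heterozygosity, then coverage under each mismatch
#' setting, strictest first): sex difference (heterogametic minus
#' homogametic) per report window along the genome, the 95% band in grey,
#' high outliers red, low outliers blue.
#'
#' @param agg Flagged `sexdiff_agg` (with band, from
#'   [flag_outlier_windows()]).
#' @param file Output PDF path.
#' @param chromosomes Optional scaffold subset.
#' @param table_paths Character vector of source-table paths listed on the
#'   final page.
#' @return `file`, invisibly.
#' @export
render_genome_scan <- function(agg, file, chromosomes = NULL,
                               table_paths = character()) {
  index <- .subset_index(attr(agg$report_grid, "index"), chromosomes)
  g <- agg$report_grid
  sel <- g$scaffold %in% index$name
  co <- .genome_coords(g$scaffold[sel], g$start[sel], g$end[sel], index)
  keys <- .scan_metric_order(agg$metrics)
  grDevices::pdf(file, width = 10, height = 2.2 * length(keys))
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(length(keys), 1), mar = c(2.5, 4.5, 1.5, 1))
  for (k in keys) {
    d <- agg$metrics[[k]]$diff[sel]
    o <- agg$metrics[[k]]$outlier[sel]
    b <- agg$band[agg$band$metric == k, ]
    ylim <- range(c(d, b$low, b$high), na.rm = TRUE, finite = TRUE)
    graphics::plot(NA, xlim = c(0, co$total), ylim = ylim,
                   xlab = "", ylab = .metric_label(k), xaxt = "n")
    graphics::axis(1, at = co$offsets + index$length / 2,
                   labels = index$name, tick = FALSE, cex.axis = 0.8)
    graphics::abline(v = co$offsets[-1], col = "grey80", lty = 3)
    if (nrow(b) == 1 && !is.na(b$low))
      graphics::rect(0, b$low, co$total, b$high, col = "grey90",
                     border = NA)
    col <- rep("black", length(d))
    col[!is.na(o) & o == "high"] <- "red"
    col[!is.na(o) & o == "low"] <- "blue"
    graphics::points(co$x, d, pch = 16, cex = 0.5, col = col)
    graphics::abline(h = 0, col = "grey40")
  }
  .table_path_page(table_paths)
  invisible(file)
}

#' Plot type 2: per-sex genome scan
#'
#' Same layout as plot type 1, but the two role means (heterogametic,
#' homogametic) are drawn as separate series per row, to show which sex
#' drives a signal.
#'
#' @inheritParams render_genome_scan
#' @return `file`, invisibly.
#' @export
render_per_sex_scan <- function(agg, file, chromosomes = NULL,
                                table_paths = character()) {
  index <- .subset_index(attr(agg$report_grid, "index"), chromosomes)
  g <- agg$report_grid
  sel <- g$scaffold %in% index$name
  co <- .genome_coords(g$scaffold[sel], g$start[sel], g$end[sel], index)
  keys <- .scan_metric_order(agg$metrics)
  roles <- c(heterogametic = "firebrick", homogametic = "steelblue")
  grDevices::pdf(file, width = 10, height = 2.2 * length(keys))
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(length(keys), 1), mar = c(2.5, 4.5, 1.5, 1))
  for (k in keys) {
    hm <- agg$metrics[[k]]$het_mean[sel]
    om <- agg$metrics[[k]]$hom_mean[sel]
    ylim <- range(c(hm, om), na.rm = TRUE, finite = TRUE)
    graphics::plot(NA, xlim = c(0, co$total), ylim = ylim, xlab = "",
                   ylab = sub(" diff", "", .metric_label(k)), xaxt = "n")
    graphics::axis(1, at = co$offsets + index$length / 2,
                   labels = index$name, tick = FALSE, cex.axis = 0.8)
    graphics::abline(v = co$offsets[-1], col = "grey80", lty = 3)
    graphics::points(co$x, hm, pch = 16, cex = 0.5, col = roles[1])
    graphics::points(co$x, om, pch = 16, cex = 0.5, col = roles[2])
    graphics::legend("topright", legend = names(roles), col = roles,
                     pch = 16, cex = 0.7, bty = "n")
  }
  .table_path_page(table_paths)
  invisible(file)
}

#' Plot type 3: per-scaffold scatter
#'
#' One column per mismatch setting. Top row: heterozygosity difference
#' against coverage difference per scaffold, symbol size scaled by
#' scaffold length. Bottom row: scaffold length against coverage
#' difference. An optional colour list marks scaffold groups (e.g.
#' candidate sex-linked scaffolds).
#'
#' @param scaffold_summary Table from [per_scaffold_summary()].
#' @param file Output PDF path.
#' @param colour_groups Optional named list: group label -> scaffold
#'   names; listed groups are coloured, other scaffolds grey.
#' @param table_paths Source-table paths for the final page.
#' @return `file`, invisibly.
#' @export
render_scaffold_scatter <- function(scaffold_summary, file,
                                    colour_groups = NULL,
                                    table_paths = character()) {
  settings <- unique(scaffold_summary$setting)
  grDevices::pdf(file, width = 3.4 * length(settings), height = 7)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, length(settings)), mar = c(4, 4, 2, 1))
  pal <- c("firebrick", "steelblue", "darkorange", "forestgreen", "purple")
  col_of <- function(sc) {
    col <- rep("grey50", length(sc))
    if (!is.null(colour_groups))
      for (i in seq_along(colour_groups))
        col[sc %in% colour_groups[[i]]] <- pal[(i - 1) %% length(pal) + 1]
    col
  }
  for (s in settings) {
    d <- scaffold_summary[scaffold_summary$setting == s, ]
    cex <- 0.5 + 1.5 * sqrt(d$length / max(d$length))
    graphics::plot(d$cov_diff, d$het_diff, pch = 16, cex = cex,
                   col = col_of(d$scaffold),
                   xlab = paste0("Coverage diff (", s, ")"),
                   ylab = "Heterozygosity diff", main = s)
    graphics::abline(h = 0, v = 0, col = "grey80")
  }
  for (s in settings) {
    d <- scaffold_summary[scaffold_summary$setting == s, ]
    graphics::plot(d$cov_diff, d$length, pch = 16, cex = 0.8, log = "y",
                   col = col_of(d$scaffold),
                   xlab = paste0("Coverage diff (", s, ")"),
                   ylab = "Scaffold length (bp)")
    graphics::abline(v = 0, col = "grey80")
  }
  if (!is.null(colour_groups))
    graphics::legend("topleft", legend = names(colour_groups),
                     col = pal[seq_along(colour_groups)], pch = 16,
                     cex = 0.7, bty = "n")
  .table_path_page(table_paths)
  invisible(file)
}

#' Plot type 4: per-chromosome mean +/- SD
#'
#' Two rows (heterozygosity, coverage) by one column per mismatch
#' setting: per-chromosome mean sex difference with SD error bars, symbol
#' size proportional to chromosome length, dashed lines at the genome-wide
#' median, highlighted chromosomes coloured and all others grey.
#'
#' @param chrom_summary Table from [per_chromosome_summary()] (with its
#'   `medians` attribute).
#' @param file Output PDF path.
#' @param highlight Optional chromosome names to colour; unknown names are
#'   an error listing the valid ones.
#' @param table_paths Source-table paths for the final page.
#' @return `file`, invisibly.
#' @export
render_chromosome_scatter <- function(chrom_summary, file, highlight = NULL,
                                      table_paths = character()) {
  scaffolds <- unique(chrom_summary$scaffold)
  if (!is.null(highlight)) {
    bad <- setdiff(highlight, scaffolds)
    if (length(bad) > 0)
      stop("unknown highlight name(s): ", paste(bad, collapse = ", "),
           "; valid names: ", paste(scaffolds, collapse = ", "),
           call. = FALSE)
  }
  medians <- attr(chrom_summary, "medians")
  cov_keys <- grep("^coverage_", unique(chrom_summary$metric), value = TRUE)
  grDevices::pdf(file, width = 3.4 * length(cov_keys), height = 7)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, length(cov_keys)), mar = c(6, 4, 2, 1))
  pal <- c("firebrick", "steelblue", "darkorange", "forestgreen", "purple")
  panel <- function(metric, main) {
    d <- chrom_summary[chrom_summary$metric == metric, ]
    xi <- match(d$scaffold, scaffolds)
    col <- rep("grey60", nrow(d))
    if (!is.null(highlight))
      col[d$scaffold %in% highlight] <-
        pal[match(d$scaffold[d$scaffold %in% highlight], highlight) %%
              length(pal) + 1]
    cex <- 0.5 + 1.5 * sqrt(d$length / max(d$length))
    ylim <- range(c(d$mean - d$sd, d$mean + d$sd, medians[metric]),
                  finite = TRUE)
    graphics::plot(xi, d$mean, pch = 16, cex = cex, col = col, xaxt = "n",
                   xlab = "", ylab = "diff (het - hom)", main = main,
                   xlim = c(0.5, length(scaffolds) + 0.5), ylim = ylim)
    graphics::arrows(xi, d$mean - d$sd, xi, d$mean + d$sd, angle = 90,
                     code = 3, length = 0.02, col = col)
    graphics::abline(h = medians[metric], lty = 2, col = "grey30")
    graphics::axis(1, at = seq_along(scaffolds), labels = scaffolds,
                   las = 2, cex.axis = 0.7)
  }
  for (ck in cov_keys) panel("heterozygosity", "Heterozygosity")
  for (ck in cov_keys)
    panel(ck, paste0("Coverage (", sub("^coverage_", "", ck), ")"))
  .table_path_page(table_paths)
  invisible(file)
}

#' Plot type 5: per-sample profiles
#'
#' One page per sample and mismatch setting, with the sample's normalized
#' coverage track (top) and heterozygosity track (bottom) along the
#' genome. The page caption carries the sample's sex, heterogamety role
#' and raw genome-wide mean depth, for confirming sample sexing and
#' sequencing depth.
#'
#' @param profiles List from [per_sample_profiles()].
#' @param samples Validated sample sheet.
#' @param mean_depth Named per-sample raw mean depths (from
#'   [window_coverage()]).
#' @param file Output PDF path.
#' @param table_paths Source-table paths for the final page.
#' @return `file`, invisibly.
#' @export
render_sample_profiles <- function(profiles, samples, mean_depth, file,
                                   table_paths = character()) {
  g <- profiles$report_grid
  index <- attr(g, "index")
  co <- .genome_coords(g$scaffold, g$start, g$end, index)
  cov_keys <- grep("^coverage_", names(profiles$tracks), value = TRUE)
  grDevices::pdf(file, width = 10, height = 5)
  on.exit(grDevices::dev.off())
  for (i in seq_len(nrow(samples))) {
    id <- samples$id[i]
    for (ck in cov_keys) {
      graphics::par(mfrow = c(2, 1), mar = c(2.5, 4.5, 2.5, 1))
      cv <- profiles$tracks[[ck]][, id]
      graphics::plot(co$x, cv, pch = 16, cex = 0.5,
                     xlab = "", ylab = "Normalized coverage", xaxt = "n",
                     main = sprintf(
                       "%s (%s, %s) - %s - mean depth %.2fx", id,
                       samples$sex[i], samples$role[i],
                       sub("^coverage_", "", ck), mean_depth[[id]]))
      graphics::axis(1, at = co$offsets + index$length / 2,
                     labels = index$name, tick = FALSE, cex.axis = 0.8)
      graphics::abline(v = co$offsets[-1], col = "grey80", lty = 3)
      graphics::abline(h = 1, col = "grey40")
      hv <- profiles$tracks[["heterozygosity"]][, id]
      graphics::plot(co$x, hv, pch = 16, cex = 0.5,
                     xlab = "", ylab = "Het (per bp)", xaxt = "n")
      graphics::axis(1, at = co$offsets + index$length / 2,
                     labels = index$name, tick = FALSE, cex.axis = 0.8)
      graphics::abline(v = co$offsets[-1], col = "grey80", lty = 3)
    }
  }
  .table_path_page(table_paths)
  invisible(file)
}
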