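# Output tables (tab-separated, 1-based inclusive coordinates, README
# describing every column) and the static HTML report.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# long per-window table for a window_values object (per-sample columns)
.values_table <- function(wv, label) {
  g <- wv$grid
  data.frame(scaffold = g$scaffold, start = g$start + 1, end = g$end,
             wv$values[[label]], masked = wv$masked,
             check.names = FALSE, stringsAsFactors = FALSE)
}

.sexdiff_unit_table <- function(sd) {
  g <- sd$grid
  rows <- lapply(names(sd$metrics), function(k) {
    m <- sd$metrics[[k]]
    data.frame(metric = k, scaffold = g$scaffold, start = g$start + 1,
               end = g$end, heterogametic = m$het_mean,
               homogametic = m$hom_mean, diff = m$diff,
               masked = sd$masked, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.sexdiff_agg_table <- function(agg) {
  g <- agg$report_grid
  rows <- lapply(names(agg$metrics), function(k) {
    m <- agg$metrics[[k]]
    data.frame(metric = k, scaffold = g$scaffold, start = g$start + 1,
               end = g$end, heterogametic = m$het_mean,
               homogametic = m$hom_mean, diff = m$diff, n_windows = m$n,
               outlier = if (is.null(m$outlier)) NA_character_
                         else m$outlier,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.tables_readme <- function() {
  c("sexscan output tables",
    "=====================",
    "All coordinates are 1-based inclusive; windows are reported even when",
    "masked (masked = TRUE rows are excluded from normalization means,",
    "interval estimation and aggregation).",
    "",
    "coverage_<setting>.tsv: scaffold, start, end, one column of",
    "  normalized relative depth per sample, masked flag.",
    "heterozygosity.tsv: scaffold, start, end, heterozygous sites per bp",
    "  per sample (full window length denominator), masked flag.",
    "sexdiff_unit.tsv: per metric and unit window, heterogametic and",
    "  homogametic role means, diff = heterogametic - homogametic, masked.",
    "  With this sign convention, differentiated sex-linked regions give",
    "  negative coverage diffs; low-differentiation regions give positive",
    "  heterozygosity diffs, in both XY and ZW systems.",
    "sexdiff_<window>.tsv: the same aggregated over report windows by",
    "  unit-window midpoint; n_windows = contributing unmasked unit",
    "  windows (fewer than the configured minimum leaves the row missing);",
    "  outlier = none/high/low against the 95% band.",
    "band_<window>.tsv: the 95% band per metric (low, high, method).",
    "outliers_<window>.tsv: report windows outside the band, per metric.",
    "per_scaffold.tsv: per scaffold and setting, mean coverage and",
    "  heterozygosity diffs over unmasked unit windows, scaffold length.",
    "per_chromosome_<window>.tsv: per scaffold and metric, mean and SD of",
    "  report-window diffs, n windows, scaffold length.",
    "sample_profiles_<window>.tsv: per-sample normalized coverage and",
    "  heterozygosity per report window and setting.",
    "synteny_*.tsv: the same aggregated tables in synteny-species",
    "  coordinates (anchored unit windows only).",
    "genomewide_heterozygosity.tsv: per-sample genome-wide heterozygosity",
    "  percentage (unbounded-setting variant calls).",
    "anchoring.tsv: liftover anchoring rate (anchored / total unit",
    "  windows), when a synteny map was supplied.")
}

#' Write all result tables of a run
#'
#' @param result A `sexscan` result from [run_pipeline()].
#' @param dir Table directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_result_tables <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (l in names(result$coverage$values))
    paths[paste0("coverage_", l)] <-
      .write_tsv(.values_table(result$coverage, l),
                 file.path(dir, paste0("coverage_", l, ".tsv")))
  paths["heterozygosity"] <-
    .write_tsv(.values_table(result$het, "het"),
               file.path(dir, "heterozygosity.tsv"))
  paths["sexdiff_unit"] <- .write_tsv(.sexdiff_unit_table(result$sexdiff),
                                      file.path(dir, "sexdiff_unit.tsv"))
  for (w in names(result$aggregated)) {
    agg <- result$aggregated[[w]]
    paths[paste0("sexdiff_", w)] <-
      .write_tsv(.sexdiff_agg_table(agg),
                 file.path(dir, paste0("sexdiff_", w, ".tsv")))
    paths[paste0("band_", w)] <-
      .write_tsv(agg$band, file.path(dir, paste0("band_", w, ".tsv")))
    paths[paste0("outliers_", w)] <-
      .write_tsv(outlier_table(agg),
                 file.path(dir, paste0("outliers_", w, ".tsv")))
    paths[paste0("per_chromosome_", w)] <-
      .write_tsv(per_chromosome_summary(agg),
                 file.path(dir, paste0("per_chromosome_", w, ".tsv")))
  }
  paths["per_scaffold"] <- .write_tsv(per_scaffold_summary(result$sexdiff),
                                      file.path(dir, "per_scaffold.tsv"))
  pr <- result$profiles
  ptab <- data.frame(scaffold = pr$report_grid$scaffold,
                     start = pr$report_grid$start + 1,
                     end = pr$report_grid$end, stringsAsFactors = FALSE)
  for (k in names(pr$tracks)) {
    m <- pr$tracks[[k]]
    colnames(m) <- paste0(k, ".", colnames(m))
    ptab <- cbind(ptab, m)
  }
  paths["sample_profiles"] <-
    .write_tsv(ptab, file.path(dir, "sample_profiles.tsv"))
  paths["genomewide_heterozygosity"] <- .write_tsv(
    data.frame(sample = names(result$genomewide_het),
               heterozygosity_pct = as.numeric(result$genomewide_het),
               stringsAsFactors = FALSE),
    file.path(dir, "genomewide_heterozygosity.tsv"))
  if (!is.null(result$synteny)) {
    for (w in names(result$synteny$aggregated)) {
      agg <- result$synteny$aggregated[[w]]
      paths[paste0("synteny_sexdiff_", w)] <-
        .write_tsv(.sexdiff_agg_table(agg),
                   file.path(dir, paste0("synteny_sexdiff_", w, ".tsv")))
      paths[paste0("synteny_outliers_", w)] <-
        .write_tsv(outlier_table(agg),
                   file.path(dir, paste0("synteny_outliers_", w, ".tsv")))
    }
    paths["anchoring"] <- .write_tsv(
      data.frame(anchored = sum(result$synteny$lifted$anchor$anchored),
                 total = nrow(result$synteny$lifted$anchor),
                 anchoring_rate = result$synteny$lifted$anchoring_rate),
      file.path(dir, "anchoring.tsv"))
  }
  writeLines(.tables_readme(), file.path(dir, "README"))
  paths["README"] <- file.path(dir, "README")
  invisible(paths)
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.html_table <- function(df, max_rows = 100) {
  if (is.null(df) || nrow(df) == 0)
    return("<p><em>No rows.</em></p>")
  truncated <- nrow(df) > max_rows
  d <- utils::head(df, max_rows)
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], function(x) signif(x, 5))
  head_row <- paste0("<tr>", paste0("<th>", .html_escape(names(d)),
                                    "</th>", collapse = ""), "</tr>")
  body <- apply(d, 1, function(r)
    paste0("<tr>", paste0("<td>", .html_escape(as.character(r)), "</td>",
                          collapse = ""), "</tr>"))
  c("<table border='1' cellspacing='0' cellpadding='3'>", head_row, body,
    "</table>",
    if (truncated) sprintf("<p><em>First %d rows shown.</em></p>", max_rows))
}

#' Assemble the static HTML report
#'
#' One self-contained page summarizing a run: assembly statistics
#' (scaffold count, total length, N50), per-sample mean depth and
#' genome-wide heterozygosity (with a caution when it reaches 1%), the
#' outlier tables, links to the five plot PDFs, run warnings, and the
#' liftover anchoring rate when a synteny map was used. Sections whose
#' artifact is missing render an explanatory placeholder.
#'
#' @param result A `sexscan` result.
#' @param file Output HTML path.
#' @return `file`, invisibly.
#' @export
build_html_report <- function(result, file) {
  idx <- result$index
  st <- assembly_stats(idx)
  h <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
         "<title>sexscan report</title>",
         "<style>body{font-family:sans-serif;margin:2em;max-width:60em}",
         "h2{border-bottom:1px solid #ccc}</style></head><body>",
         "<h1>sexscan run report</h1>",
         sprintf("<p>System: %s &mdash; %d samples &mdash; unit window %d bp, report window(s) %s bp.</p>",
                 result$config$system, nrow(result$samples),
                 result$config$unit_window,
                 paste(result$config$report_windows, collapse = ", ")))
  h <- c(h, "<h2>Assembly</h2>",
         sprintf("<p>%d scaffolds, total length %s bp, N50 %s bp.</p>",
                 st$n_scaffolds, format(st$total_length, big.mark = ","),
                 format(st$n50, big.mark = ",")))
  h <- c(h, "<h2>Samples</h2>",
         .html_table(data.frame(
           id = result$samples$id, sex = result$samples$sex,
           role = result$samples$role,
           mean_depth = round(result$coverage$mean_depth[result$samples$id], 3),
           genomewide_het_pct =
             round(result$genomewide_het[result$samples$id], 4),
           stringsAsFactors = FALSE)))
  if (any(result$genomewide_het >= 1))
    h <- c(h, "<p><strong>Warning:</strong> genome-wide heterozygosity of",
           " 1% or more in at least one sample; very high heterozygosity",
           " can obscure the sex-linked signature.</p>")
  h <- c(h, "<h2>Outlier windows (study coordinates)</h2>")
  main_w <- names(result$aggregated)[1]
  ot <- tryCatch(outlier_table(result$aggregated[[main_w]]),
                 error = function(e) NULL)
  h <- c(h, if (is.null(ot))
    "<p><em>Outlier table unavailable for this run.</em></p>"
    else .html_table(ot))
  if (!is.null(result$synteny)) {
    h <- c(h, "<h2>Synteny liftover</h2>",
           sprintf("<p>Anchoring rate: %.1f%% of unit windows (%d of %d) anchored to the synteny assembly.</p>",
                   100 * result$synteny$lifted$anchoring_rate,
                   sum(result$synteny$lifted$anchor$anchored),
                   nrow(result$synteny$lifted$anchor)))
    sot <- tryCatch(outlier_table(result$synteny$aggregated[[1]]),
                    error = function(e) NULL)
    h <- c(h, "<h3>Outlier windows (synteny coordinates)</h3>",
           if (is.null(sot))
             "<p><em>Synteny outlier table unavailable.</em></p>"
           else .html_table(sot))
  }
  h <- c(h, "<h2>Plots</h2>", "<ul>")
  plot_desc <- c(
    genome_scan = "Plot type 1: genome-wide sex differences with the 95% band; red above, blue below.",
    per_sex_scan = "Plot type 2: the same values per sex, to see which sex drives a signal.",
    scaffold_scatter = "Plot type 3: per-scaffold differences and scaffold length.",
    chromosome_scatter = "Plot type 4: per-chromosome mean &plusmn; SD differences.",
    sample_profiles = "Plot type 5: per-sample coverage and heterozygosity profiles (sexing check).")
  for (p in names(plot_desc)) {
    path <- result$plot_paths[[p]]
    h <- c(h, if (!is.null(path) && file.exists(path))
      sprintf("<li><a href='%s'>%s</a> &mdash; %s</li>",
              file.path("plots", basename(path)), p, plot_desc[[p]])
      else sprintf("<li>%s &mdash; <em>not rendered in this run.</em></li>",
                   p))
  }
  h <- c(h, "</ul>")
  if (length(result$warnings) > 0)
    h <- c(h, "<h2>Warnings</h2>",
           paste0("<p>", .html_escape(result$warnings), "</p>"))
  h <- c(h, "</body></html>")
  writeLines(h, file)
  invisible(file)
}
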