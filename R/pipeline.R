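# Orchestration: runs the stages in dependency order with content-digest
# caching, so re-renders (new chromosome subsets or highlight lists) never
# recompute upstream tables.

# md5 of a string, via base tools (files are digested directly)
.digest_string <- function(...) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(unlist(list(...)), collapse = "|"), f)
  unname(tools::md5sum(f))
}

.digest_files <- function(paths) paste(unname(tools::md5sum(paths)),
                                       collapse = "+")

.stage_cached <- function(cache_dir, stage, key) {
  rds <- file.path(cache_dir, paste0(stage, ".rds"))
  keyf <- file.path(cache_dir, paste0(stage, ".key"))
  if (file.exists(rds) && file.exists(keyf) &&
      identical(readLines(keyf, warn = FALSE)[1], key))
    return(readRDS(rds))
  NULL
}

.stage_store <- function(cache_dir, stage, key, value) {
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(value, file.path(cache_dir, paste0(stage, ".rds")))
  writeLines(key, file.path(cache_dir, paste0(stage, ".key")))
  value
}

#' Run the full sex-chromosome scan
#'
#' Executes coverage, heterozygosity, sex-difference statistics, the
#' optional synteny liftover branch, table writing, plotting and the HTML
#' report, in dependency order. Stages are cached under
#' `output_dir/cache` keyed by content digests of their inputs, so a
#' re-run with only plotting options changed re-executes only the
#' rendering.
#'
#' @param config A `run_config` from [make_run_config()] or
#'   [load_config()].
#' @return A `sexscan` result object (see [print.sexscan()]), invisibly
#'   containing all tables, the band, outliers, summaries, per-sample
#'   profiles and the synteny branch when a map was supplied.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  cache_dir <- file.path(out_dir, "cache")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  warnings_log <- character()
  note <- function(msg) {
    warnings_log <<- c(warnings_log, msg)
    message("sexscan: ", msg)
  }
  samples <- validate_sample_sheet(config$samples, config$system)
  if (is.null(config$reference))
    stop("config must name the reference FASTA (or its .fai)", call. = FALSE)
  index <- read_genome_index(config$reference)
  grid <- make_window_grid(index, config$unit_window)

  cov_key <- .digest_string(.digest_files(samples$bam),
                            yaml::as.yaml(config$mismatch_settings),
                            config$mapq_floor, config$mask_factor,
                            config$unit_window)
  cov <- .stage_cached(cache_dir, "coverage", cov_key)
  if (is.null(cov)) {
    message("sexscan: computing window coverage for ", nrow(samples),
            " sample(s)")
    cov <- window_coverage(samples, grid, config$mismatch_settings,
                           config$mapq_floor)
    cov <- mask_outlier_windows(cov, config$mask_factor)
    cov <- normalize_coverage(cov)
    .stage_store(cache_dir, "coverage", cov_key, cov)
  }

  if (is.null(config$vcf))
    stop("config must name the multi-sample VCF", call. = FALSE)
  het_key <- .digest_string(.digest_files(config$vcf), config$qual_min,
                            config$gq_min, config$dp_min,
                            config$unit_window)
  hetst <- .stage_cached(cache_dir, "heterozygosity", het_key)
  if (is.null(hetst)) {
    message("sexscan: filtering variants and computing heterozygosity")
    fv <- filter_variants(config$vcf, samples$id, config$qual_min,
                          config$gq_min, config$dp_min)
    hetst <- list(het = window_heterozygosity(fv, grid),
                  genomewide = genomewide_heterozygosity(fv, index),
                  dropped = fv$dropped)
    .stage_store(cache_dir, "heterozygosity", het_key, hetst)
  }
  het_wv <- hetst$het
  # share the coverage mask with the heterozygosity branch
  het_wv$masked <- het_wv$masked | cov$masked
  if (any(hetst$genomewide >= 1))
    note(paste0("genome-wide heterozygosity >= 1% in sample(s): ",
                paste(names(hetst$genomewide)[hetst$genomewide >= 1],
                      collapse = ", "),
                "; the sex-linked signature may be obscured"))

  stats_key <- .digest_string(cov_key, het_key, config$band_method,
                              paste(config$report_windows, collapse = ","),
                              config$min_windows_per_bin)
  stats <- .stage_cached(cache_dir, "stats", stats_key)
  if (is.null(stats)) {
    sd <- sexdiff_table(cov, het_wv, samples)
    aggregated <- list()
    for (w in config$report_windows) {
      agg <- aggregate_windows(sd, w, config$min_windows_per_bin)
      band <- confidence_band(agg, method = config$band_method)
      aggregated[[format(w, scientific = FALSE)]] <-
        flag_outlier_windows(agg, band)
    }
    stats <- list(sexdiff = sd, aggregated = aggregated)
    .stage_store(cache_dir, "stats", stats_key, stats)
  }

  synteny <- NULL
  if (!is.null(config$synteny_map)) {
    syn_key <- .digest_string(stats_key, .digest_files(config$synteny_map),
                              config$synteny_dialect,
                              config$anchor_min_overlap)
    synteny <- .stage_cached(cache_dir, "synteny", syn_key)
    if (is.null(synteny)) {
      message("sexscan: lifting windows over the synteny map")
      map <- parse_alignment_map(config$synteny_map,
                                 config$synteny_dialect)
      lifted <- liftover_table(stats$sexdiff, map,
                               min_overlap = config$anchor_min_overlap)
      aggregated <- list()
      for (w in config$report_windows) {
        agg <- aggregate_lifted(lifted, w, config$min_windows_per_bin)
        band <- confidence_band(agg, method = config$band_method)
        aggregated[[format(w, scientific = FALSE)]] <-
          flag_outlier_windows(agg, band)
      }
      synteny <- list(lifted = lifted, aggregated = aggregated)
      .stage_store(cache_dir, "synteny", syn_key, synteny)
    }
  }

  profiles <- per_sample_profiles(cov, het_wv, config$report_windows[1],
                                  config$min_windows_per_bin)
  result <- structure(
    list(config = config, index = index, samples = samples, coverage = cov,
         het = het_wv, genomewide_het = hetst$genomewide,
         dropped_variants = hetst$dropped, sexdiff = stats$sexdiff,
         aggregated = stats$aggregated, profiles = profiles,
         synteny = synteny, warnings = warnings_log,
         plot_paths = list()),
    class = "sexscan")

  tables_dir <- file.path(out_dir, "tables")
  result$table_paths <- write_result_tables(result, tables_dir)
  result <- .render_all(result, out_dir)
  saveRDS(result, file.path(cache_dir, "result.rds"))
  invisible(result)
}

.render_all <- function(result, out_dir) {
  plots_dir <- file.path(out_dir, "plots")
  dir.create(plots_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  main_w <- names(result$aggregated)[1]
  tp <- unname(result$table_paths)
  agg <- if (!is.null(result$synteny)) result$synteny$aggregated[[main_w]]
         else result$aggregated[[main_w]]
  pp <- list()
  pp$genome_scan <- render_genome_scan(
    agg, file.path(plots_dir, "plot1_genome_scan.pdf"),
    chromosomes = cfg$chromosomes, table_paths = tp)
  pp$per_sex_scan <- render_per_sex_scan(
    agg, file.path(plots_dir, "plot2_per_sex.pdf"),
    chromosomes = cfg$chromosomes, table_paths = tp)
  pp$scaffold_scatter <- render_scaffold_scatter(
    per_scaffold_summary(result$sexdiff),
    file.path(plots_dir, "plot3_per_scaffold.pdf"),
    colour_groups = if (!is.null(cfg$highlight))
      list(highlighted = cfg$highlight),
    table_paths = tp)
  pp$chromosome_scatter <- render_chromosome_scatter(
    per_chromosome_summary(agg),
    file.path(plots_dir, "plot4_per_chromosome.pdf"),
    highlight = cfg$highlight, table_paths = tp)
  pp$sample_profiles <- render_sample_profiles(
    result$profiles, result$samples, result$coverage$mean_depth,
    file.path(plots_dir, "plot5_sample_profiles.pdf"), table_paths = tp)
  result$plot_paths <- pp
  build_html_report(result, file.path(out_dir, "report.html"))
  .write_manifest(result, out_dir)
  result
}

.write_manifest <- function(result, out_dir) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("sexscan")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = result$config$seed,
    tables = as.list(unname(tools::md5sum(
      sort(unname(result$table_paths))))))
  names(manifest$tables) <- basename(sort(unname(result$table_paths)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Re-render plots and report from cached tables
#'
#' Rebuilds the five plots and the HTML report from a prior run's cached
#' result, leaving every table untouched. Plotting options (`chromosomes`,
#' `highlight`) may differ from the original run.
#'
#' @param config A `run_config` whose `output_dir` holds a prior run.
#' @return The updated `sexscan` result, invisibly.
#' @export
render_only <- function(config) {
  cache <- file.path(config$output_dir, "cache", "result.rds")
  if (!file.exists(cache))
    stop("no cached run found under ", config$output_dir,
         "; run run_pipeline() first", call. = FALSE)
  result <- readRDS(cache)
  result$config$chromosomes <- config$chromosomes
  result$config$highlight <- config$highlight
  result <- .render_all(result, config$output_dir)
  invisible(result)
}

#' @export
print.sexscan <- function(x, ...) {
  st <- assembly_stats(x$index)
  cat("sexscan run (", x$config$system, " system)\n", sep = "")
  cat(sprintf("  genome: %d scaffolds, %s bp (N50 %s)\n", st$n_scaffolds,
              format(st$total_length, big.mark = ","),
              format(st$n50, big.mark = ",")))
  cat(sprintf("  samples: %d heterogametic, %d homogametic\n",
              sum(x$samples$role == "heterogametic"),
              sum(x$samples$role == "homogametic")))
  cat(sprintf("  windows: %d unit (%d bp), report %s bp\n",
              nrow(x$sexdiff$grid), x$config$unit_window,
              paste(x$config$report_windows, collapse = "/")))
  main_w <- names(x$aggregated)[1]
  ot <- outlier_table(x$aggregated[[main_w]])
  cat(sprintf("  outlier report windows (%s bp): %d\n", main_w, nrow(ot)))
  if (!is.null(x$synteny))
    cat(sprintf("  synteny anchoring rate: %.1f%%\n",
                100 * x$synteny$lifted$anchoring_rate))
  invisible(x)
}

#' @export
summary.sexscan <- function(object, ...) {
  print(object)
  main_w <- names(object$aggregated)[1]
  agg <- object$aggregated[[main_w]]
  cat("\n95% band per metric:\n")
  print(agg$band, row.names = FALSE)
  cat("\nGenome-wide heterozygosity (%):\n")
  print(round(object$genomewide_het, 4))
  ot <- outlier_table(agg)
  if (nrow(ot) > 0) {
    cat("\nOutlier windows:\n")
    print(utils::head(ot, 20), row.names = FALSE)
    if (nrow(ot) > 20) cat("  ...", nrow(ot) - 20, "more\n")
  }
  invisible(object)
}

#' Plot method for a scan result
#'
#' Draws one of the five diagnostic plot types to the active device (or a
#' PDF when `file` is given).
#'
#' @param x A `sexscan` result.
#' @param type Plot type 1-5.
#' @param file Optional output PDF path; default draws to a temporary PDF
#'   and returns its path invisibly.
#' @param ... Passed to the underlying renderer (`chromosomes`,
#'   `highlight`, `colour_groups`).
#' @return The PDF path, invisibly.
#' @export
plot.sexscan <- function(x, type = 1, file = NULL, ...) {
  if (is.null(file)) file <- tempfile(fileext = ".pdf")
  main_w <- names(x$aggregated)[1]
  agg <- x$aggregated[[main_w]]
  tp <- unname(x$table_paths)
  switch(as.character(type),
         "1" = render_genome_scan(agg, file, table_paths = tp, ...),
         "2" = render_per_sex_scan(agg, file, table_paths = tp, ...),
         "3" = render_scaffold_scatter(per_scaffold_summary(x$sexdiff),
                                       file, table_paths = tp, ...),
         "4" = render_chromosome_scatter(per_chromosome_summary(agg),
                                         file, table_paths = tp, ...),
         "5" = render_sample_profiles(x$profiles, x$samples,
                                      x$coverage$mean_depth, file,
                                      table_paths = tp, ...),
         stop("plot type must be 1-5", call. = FALSE))
  invisible(file)
}
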