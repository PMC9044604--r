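#' Default mismatch filtering settings
#'
#' Three alignment filtering stringencies applied to the coverage branch:
#' strict (0 mismatches allowed), intermediate (at most 2 mismatches), and
#' unfiltered (no mismatch bound). The heterozygosity branch always uses the
#' unbounded setting; the optimal threshold for the coverage contrast may
#' differ between species, so arbitrary extra thresholds are accepted by
#' [make_run_config()].
#'
#' @return A named list of settings, each a list with `label` and
#'   `max_mismatches` (`Inf` for the unbounded setting).
#' @export
default_mismatch_settings <- function() {
  list(
    list(label = "0mm", max_mismatches = 0),
    list(label = "2mm", max_mismatches = 2),
    list(label = "unfiltered", max_mismatches = Inf)
  )
}

.setting_labels <- function(settings) vapply(settings, `[[`, "", "label")

.unbounded_label <- function(settings) {
  ub <- .setting_labels(settings)[
    vapply(settings, function(s) is.infinite(s$max_mismatches), TRUE)]
  if (length(ub) == 0L)
    stop("mismatch settings must include an unbounded setting ",
         "(the heterozygosity branch and outlier masking depend on it)",
         call. = FALSE)
  ub[1]
}

#' Build a run configuration
#'
#' Collects all tunable parameters of a scan. Defaults follow the standard
#' analysis: 5 kb unit windows, 1 Mb report windows, the three canonical
#' mismatch settings, a mapping-quality floor of 20, masking of windows
#' whose unfiltered depth exceeds 10 times the per-sample genome-wide
#' median, and an empirical-quantile 95% band.
#'
#' @param samples data.frame with columns `id`, `sex` (`male`/`female`) and
#'   `bam` (path to a coordinate-sorted, indexed alignment file).
#' @param system Heterogamety system, `"XY"` or `"ZW"`.
#' @param reference Path to the study-species reference FASTA (or its
#'   `.fai`); used for the genome index and consensus construction.
#' @param vcf Path to the multi-sample VCF called against the reference.
#' @param unit_window Unit window size in bp (>= 1000; default 5000).
#' @param report_windows Aggregation window sizes in bp; each must be an
#'   integer multiple >= 2 of `unit_window` (default 1e6).
#' @param mismatch_settings List of settings as in
#'   [default_mismatch_settings()]; labels must be unique and one setting
#'   must be unbounded.
#' @param mapq_floor Minimum mapping quality in every setting (default 20).
#' @param mask_factor Coverage-outlier masking factor (default 10).
#' @param qual_min,gq_min,dp_min Variant hard filters: minimum site QUAL,
#'   genotype GQ and genotype DP (defaults 30, 20, 3).
#' @param band_method `"quantile"` (empirical 2.5/97.5 percentiles, default)
#'   or `"meansd"` (mean +/- 1.96 SD).
#' @param min_windows_per_bin Minimum contributing unit windows for a report
#'   window to be non-missing (default 5).
#' @param synteny_map Optional path to a whole-genome-alignment block map.
#' @param synteny_dialect `"tsv"` or `"psl"`.
#' @param anchor_min_overlap Minimum fraction of a unit window covered by
#'   blocks to the majority target scaffold for anchoring (default 0.5).
#' @param chromosomes Optional scaffold subset for plotting.
#' @param highlight Optional scaffold names highlighted in the
#'   per-chromosome plot.
#' @param seed Integer seed fixing all randomness.
#' @param output_dir Output directory for tables, plots and the report.
#' @return A `run_config` object (a validated list).
#' @export
make_run_config <- function(samples, system = c("XY", "ZW"),
                            reference = NULL, vcf = NULL,
                            unit_window = 5000,
                            report_windows = 1e6,
                            mismatch_settings = default_mismatch_settings(),
                            mapq_floor = 20, mask_factor = 10,
                            qual_min = 30, gq_min = 20, dp_min = 3,
                            band_method = c("quantile", "meansd"),
                            min_windows_per_bin = 5,
                            synteny_map = NULL,
                            synteny_dialect = c("tsv", "psl"),
                            anchor_min_overlap = 0.5,
                            chromosomes = NULL, highlight = NULL,
                            seed = 1L, output_dir = "sexscan_out") {
  system <- match.arg(system)
  band_method <- match.arg(band_method)
  synteny_dialect <- match.arg(synteny_dialect)
  if (unit_window < 1000)
    stop("unit_window must be >= 1000 bp", call. = FALSE)
  report_windows <- as.numeric(report_windows)
  bad <- report_windows %% unit_window != 0 | report_windows < 2 * unit_window
  if (any(bad))
    stop("every report window must be an integer multiple >= 2 of the unit ",
         "window; offending: ", paste(report_windows[bad], collapse = ", "),
         call. = FALSE)
  if (length(mismatch_settings) == 0L)
    stop("mismatch_settings must be non-empty", call. = FALSE)
  labs <- .setting_labels(mismatch_settings)
  if (anyDuplicated(labs))
    stop("mismatch setting labels must be unique", call. = FALSE)
  .unbounded_label(mismatch_settings)  # errors if absent
  cfg <- list(samples = samples, system = system, reference = reference,
              vcf = vcf, unit_window = unit_window,
              report_windows = report_windows,
              mismatch_settings = mismatch_settings,
              mapq_floor = mapq_floor, mask_factor = mask_factor,
              qual_min = qual_min, gq_min = gq_min, dp_min = dp_min,
              band_method = band_method,
              min_windows_per_bin = min_windows_per_bin,
              synteny_map = synteny_map, synteny_dialect = synteny_dialect,
              anchor_min_overlap = anchor_min_overlap,
              chromosomes = chromosomes, highlight = highlight,
              seed = as.integer(seed), output_dir = output_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' The file mirrors the arguments of [make_run_config()]; samples are given
#' as a list of `{id, sex, bam}` mappings under `samples`. Relative paths
#' are resolved against the config file's directory.
#'
#' @param path Path to the YAML configuration.
#' @param ... Overrides passed on to [make_run_config()] (e.g. from CLI
#'   flags).
#' @return A `run_config` object.
#' @export
load_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  samples <- do.call(rbind, lapply(y$samples, function(s)
    data.frame(id = s$id, sex = s$sex, bam = rel(s$bam),
               stringsAsFactors = FALSE)))
  if (!is.null(y$mismatch_settings)) {
    y$mismatch_settings <- lapply(y$mismatch_settings, function(s) {
      m <- s$max_mismatches
      if (is.null(m) || (is.character(m) && m %in% c("Inf", "unbounded")))
        m <- Inf
      list(label = s$label, max_mismatches = as.numeric(m))
    })
  }
  args <- y[setdiff(names(y), c("samples", "reference", "vcf",
                                "synteny_map", "output_dir"))]
  args$samples <- samples
  args$reference <- rel(y$reference)
  args$vcf <- rel(y$vcf)
  args$synteny_map <- rel(y$synteny_map)
  if (!is.null(y$output_dir)) args$output_dir <- rel(y$output_dir)
  over <- list(...)
  args[names(over)] <- over
  do.call(make_run_config, args)
}

#' Validate the sample sheet and assign heterogamety roles
#'
#' The heterogametic role is a pure function of the system and the sex
#' label: XY males and ZW females are heterogametic; the other sex is
#' homogametic. At least one sample per role is required; alignment files
#' must exist and be indexed.
#'
#' @param samples data.frame with columns `id`, `sex`, `bam`.
#' @param system `"XY"` or `"ZW"`.
#' @param check_files Verify that BAM files and their indices exist
#'   (default TRUE).
#' @return The sample sheet with an added `role` column
#'   (`heterogametic`/`homogametic`).
#' @export
validate_sample_sheet <- function(samples, system = c("XY", "ZW"),
                                  check_files = TRUE) {
  system <- match.arg(system)
  req <- c("id", "sex", "bam")
  if (!all(req %in% names(samples)))
    stop("sample sheet needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(samples$id))
    stop("duplicate sample ids: ",
         paste(unique(samples$id[duplicated(samples$id)]), collapse = ", "),
         call. = FALSE)
  sex <- as.character(samples$sex)
  if (!all(sex %in% c("male", "female")))
    stop("unknown sex label(s): ",
         paste(unique(sex[!sex %in% c("male", "female")]), collapse = ", "),
         "; expected 'male' or 'female'", call. = FALSE)
  het_sex <- if (system == "XY") "male" else "female"
  samples$role <- ifelse(sex == het_sex, "heterogametic", "homogametic")
  for (role in c("heterogametic", "homogametic")) {
    if (!any(samples$role == role)) {
      miss_sex <- if (role == "heterogametic") het_sex
                  else setdiff(c("male", "female"), het_sex)
      stop("no ", role, " sample in sheet: system ", system,
           " requires at least one ", miss_sex, " sample", call. = FALSE)
    }
  }
  if (check_files) {
    missing <- !file.exists(samples$bam)
    if (any(missing))
      stop("alignment file(s) not found: ",
           paste(samples$bam[missing], collapse = ", "), call. = FALSE)
    noidx <- !file.exists(paste0(samples$bam, ".bai")) &
      !file.exists(sub("\\.bam$", ".bai", samples$bam))
    if (any(noidx))
      stop("alignment file(s) not indexed (.bai missing): ",
           paste(samples$bam[noidx], collapse = ", "), call. = FALSE)
  }
  samples
}
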