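#' Read alignment records needed for coverage computation
#'
#' Pulls flag, position, mapping quality, CIGAR and the NM (edit distance)
#' tag from a coordinate-sorted indexed BAM. Unmapped, secondary,
#' supplementary and duplicate-flagged records are dropped here, as they
#' are excluded under every filtering setting.
#'
#' @param bam Path to an indexed BAM file.
#' @return A list with vectors `rname`, `pos` (1-based leftmost), `mapq`,
#'   `cigar`, `nm` (NA where the tag is absent).
#' @export
read_alignments <- function(bam) {
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flags,
                               what = c("rname", "pos", "mapq", "cigar"),
                               tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  nm <- x$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(x$pos))
  list(rname = as.character(x$rname), pos = x$pos, mapq = x$mapq,
       cigar = x$cigar, nm = nm)
}

#' Mismatch-stratified alignment filter
#'
#' Decides which records survive a filtering setting. A record fails if its
#' mapping quality is below the floor, or, for a bounded setting, if its NM
#' (edit distance) tag exceeds the allowed mismatches. Records lacking an NM
#' tag are excluded under bounded settings and counted; the unbounded
#' setting ignores NM entirely. (Unmapped/secondary/supplementary/duplicate
#' records are already removed by [read_alignments()].)
#'
#' @param aln Record list from [read_alignments()].
#' @param setting One mismatch setting (list with `label`,
#'   `max_mismatches`).
#' @param mapq_floor Minimum mapping quality (applied in all settings).
#' @return Logical vector of kept records, with attribute `n_missing_nm`
#'   (records dropped for a missing NM tag under a bounded setting).
#' @export
passes_alignment_filter <- function(aln, setting, mapq_floor = 20) {
  keep <- !is.na(aln$mapq) & aln$mapq >= mapq_floor
  n_missing_nm <- 0L
  if (is.finite(setting$max_mismatches)) {
    missing_nm <- is.na(aln$nm)
    n_missing_nm <- sum(missing_nm & keep)
    keep <- keep & !missing_nm & aln$nm <= setting$max_mismatches
    if (n_missing_nm > 0.01 * length(keep))
      warning(sprintf(
        "setting '%s': %d records (>1%%) lack an NM tag and were excluded",
        setting$label, n_missing_nm), call. = FALSE)
  }
  attr(keep, "n_missing_nm") <- n_missing_nm
  keep
}

# Sum, per window, the reference bases covered by the given records.
# Blocks are the CIGAR aligned spans (M/=/X; deletions and skips contribute
# no depth). A read overlapping two windows contributes to both
# proportionally to overlap, which makes the result exactly equal to a
# per-base pileup averaged over the window.
.window_covered_bases <- function(rname, pos, cigar, grid) {
  idx <- attr(grid, "index")
  bad <- !(rname %in% idx$name)
  if (any(bad))
    stop("alignment record(s) on scaffold(s) absent from the genome index: ",
         paste(unique(rname[bad]), collapse = ", "),
         " (BAM/index mismatch)", call. = FALSE)
  acc <- numeric(nrow(grid))
  if (length(pos) == 0L) return(acc)
  blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = c("M", "=", "X"))
  nb <- lengths(blocks)
  flat <- unlist(blocks, use.names = FALSE)
  brname <- rep(rname, nb)
  for (sc in unique(brname)) {
    sel <- brname == sc
    win <- .grid_ranges(grid, sc)
    offset <- match(sc, grid$scaffold) - 1L  # first window_id on sc, minus 1
    hits <- IRanges::findOverlaps(flat[sel], win)
    if (length(hits) == 0L) next
    ov <- IRanges::width(IRanges::pintersect(
      flat[sel][S4Vectors::queryHits(hits)],
      win[S4Vectors::subjectHits(hits)]))
    s <- rowsum(ov, S4Vectors::subjectHits(hits))
    acc[offset + as.integer(rownames(s))] <- acc[offset + as.integer(rownames(s))] + s[, 1]
  }
  acc
}

#' Per-window, per-sample, per-setting genome coverage
#'
#' Computes mean per-base depth in every unit window for every sample under
#' every mismatch setting: the sum of reference bases covered by kept reads
#' inside the window (CIGAR aligned spans; deletions contribute nothing),
#' divided by window length. Reads spanning a window boundary contribute to
#' each window proportionally, so values equal a per-base pileup average.
#'
#' @param samples Validated sample sheet (see [validate_sample_sheet()]).
#' @param grid Unit [make_window_grid()] grid.
#' @param settings Mismatch settings list.
#' @param mapq_floor Minimum mapping quality.
#' @return A `window_values` object: list with `grid`, `values` (named list,
#'   one windows x samples matrix per setting label), `masked` (all FALSE
#'   until [mask_outlier_windows()]), `normalized = FALSE`, and
#'   `mean_depth` (per sample raw genome-wide mean depth, unbounded
#'   setting).
#' @export
window_coverage <- function(samples, grid, settings = default_mismatch_settings(),
                            mapq_floor = 20) {
  labs <- .setting_labels(settings)
  n <- nrow(grid)
  values <- lapply(labs, function(l)
    matrix(0, n, nrow(samples), dimnames = list(NULL, samples$id)))
  names(values) <- labs
  mean_depth <- stats::setNames(numeric(nrow(samples)), samples$id)
  ub <- .unbounded_label(settings)
  for (i in seq_len(nrow(samples))) {
    aln <- read_alignments(samples$bam[i])
    for (j in seq_along(settings)) {
      keep <- passes_alignment_filter(aln, settings[[j]], mapq_floor)
      cov <- .window_covered_bases(aln$rname[keep], aln$pos[keep],
                                   aln$cigar[keep], grid)
      values[[j]][, i] <- cov / grid$length
    }
    mean_depth[i] <- sum(values[[ub]][, i] * grid$length) /
      sum(grid$length)
  }
  structure(list(grid = grid, values = values, samples = samples,
                 unbounded = ub,
                 masked = grid$short, mask_reason = ifelse(
                   grid$short, "short_window", ""),
                 normalized = FALSE, mean_depth = mean_depth),
            class = "window_values")
}

#' Mask extreme genome-coverage outlier windows
#'
#' A window is masked when, for any sample, its depth under the unbounded
#' ("unfiltered") setting exceeds `mask_factor` times that sample's
#' genome-wide median unbounded depth (collapsed repeats and other
#' pathological regions). The mask applies to all settings of the window:
#' masked windows are excluded from normalization means, interval
#' estimation and aggregation, but are still written to output tables with
#' a mask flag. Trailing short windows remain flagged for the same
#' treatment.
#'
#' @param wv `window_values` from [window_coverage()].
#' @param mask_factor Multiplier on the per-sample median (default 10).
#' @return `wv` with updated `masked` and `mask_reason`.
#' @export
mask_outlier_windows <- function(wv, mask_factor = 10) {
  ub <- wv$values[[.unbounded_label_from(wv)]]
  if (is.null(ub)) stop("unbounded setting not found in window values",
                        call. = FALSE)
  med <- apply(ub[!wv$grid$short, , drop = FALSE], 2, stats::median)
  extreme <- ub > rep(mask_factor * med, each = nrow(ub))
  out <- rowSums(extreme) > 0
  wv$masked <- wv$masked | out
  wv$mask_reason[out] <- "coverage_outlier"
  if (all(wv$masked))
    stop("all windows masked as coverage outliers: degenerate input",
         call. = FALSE)
  wv
}

.unbounded_label_from <- function(wv) {
  if (!is.null(wv$unbounded)) return(wv$unbounded)
  labs <- names(wv$values)
  if ("unfiltered" %in% labs) return("unfiltered")
  labs[length(labs)]
}

#' Normalize coverage between samples
#'
#' Per sample and setting, every window value is divided by the mean of
#' that sample-setting's unmasked window values, so the genome-wide mean
#' relative depth over unmasked windows is exactly 1 for every sample. This
#' makes coverage comparable between samples of different sequencing depth.
#'
#' @param wv Masked `window_values` from [mask_outlier_windows()].
#' @return `wv` with relative-depth values and `normalized = TRUE`.
#' @export
normalize_coverage <- function(wv) {
  keep <- !wv$masked
  for (l in names(wv$values)) {
    m <- colMeans(wv$values[[l]][keep, , drop = FALSE])
    if (any(m == 0))
      stop("sample(s) with zero mean coverage under setting '", l, "': ",
           paste(colnames(wv$values[[l]])[m == 0], collapse = ", "),
           call. = FALSE)
    wv$values[[l]] <- sweep(wv$values[[l]], 2, m, "/")
  }
  wv$normalized <- TRUE
  wv
}
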