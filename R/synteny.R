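#' Parse a whole-genome-alignment block map
#'
#' Reads co-linear alignment blocks between the study assembly (query) and
#' a synteny-species assembly (target) from either a 7-column TSV
#' (`qname qstart qend tname tstart tend strand`, 0-based half-open) or
#' standard 21-column PSL. Gapped PSL alignments are split into their exact
#' co-linear blocks (no interpolation across gaps); minus-strand PSL query
#' coordinates are converted to forward-strand coordinates. Malformed lines
#' are counted and reported; more than 10% malformed is an error.
#'
#' @param path Path to the map file.
#' @param dialect `"tsv"` or `"psl"`.
#' @return A `synteny_map` object: data.frame of blocks with columns
#'   `qname`, `qstart`, `qend`, `tname`, `tstart`, `tend`, `strand`, each
#'   block satisfying query length == target length.
#' @export
parse_alignment_map <- function(path, dialect = c("tsv", "psl")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "psl") {
    # skip the optional psLayout header: data lines start with a digit
    first_data <- which(grepl("^[0-9]", lines))
    if (length(first_data) > 0) lines <- lines[first_data[1]:length(lines)]
  }
  parts <- strsplit(lines, "\t| +")
  n_total <- length(parts)
  blocks <- list()
  n_bad <- 0L
  for (p in parts) {
    b <- if (dialect == "tsv") .parse_tsv_block(p) else .parse_psl_blocks(p)
    if (is.null(b)) n_bad <- n_bad + 1L else blocks[[length(blocks) + 1L]] <- b
  }
  if (n_total > 0 && n_bad > 0.1 * n_total)
    stop(sprintf("%d of %d lines malformed in %s (>10%%)", n_bad, n_total,
                 path), call. = FALSE)
  if (n_bad > 0)
    warning(n_bad, " malformed line(s) skipped in ", path, call. = FALSE)
  map <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(qname = character(), qstart = numeric(), qend = numeric(),
               tname = character(), tstart = numeric(), tend = numeric(),
               strand = character(), stringsAsFactors = FALSE)
  attr(map, "n_malformed") <- n_bad
  class(map) <- c("synteny_map", "data.frame")
  map
}

.parse_tsv_block <- function(p) {
  if (length(p) < 7) return(NULL)
  qs <- suppressWarnings(as.numeric(p[2])); qe <- suppressWarnings(as.numeric(p[3]))
  ts <- suppressWarnings(as.numeric(p[5])); te <- suppressWarnings(as.numeric(p[6]))
  if (anyNA(c(qs, qe, ts, te)) || !(p[7] %in% c("+", "-"))) return(NULL)
  if (qe <= qs || te <= ts || (qe - qs) != (te - ts)) return(NULL)
  data.frame(qname = p[1], qstart = qs, qend = qe, tname = p[4],
             tstart = ts, tend = te, strand = p[7],
             stringsAsFactors = FALSE)
}

.parse_psl_blocks <- function(p) {
  if (length(p) < 21) return(NULL)
  strand <- p[9]
  if (!strand %in% c("+", "-")) return(NULL)
  qname <- p[10]; qsize <- suppressWarnings(as.numeric(p[11]))
  tname <- p[14]
  nblk <- suppressWarnings(as.integer(p[18]))
  sizes <- suppressWarnings(as.numeric(strsplit(p[19], ",")[[1]]))
  qstarts <- suppressWarnings(as.numeric(strsplit(p[20], ",")[[1]]))
  tstarts <- suppressWarnings(as.numeric(strsplit(p[21], ",")[[1]]))
  if (anyNA(c(qsize, nblk)) || anyNA(sizes) || anyNA(qstarts) ||
      anyNA(tstarts) || length(sizes) != nblk ||
      length(qstarts) != nblk || length(tstarts) != nblk) return(NULL)
  # PSL minus strand: qStarts are on the reversed query; convert to forward
  qs_fwd <- if (strand == "-") qsize - qstarts - sizes else qstarts
  data.frame(qname = qname, qstart = qs_fwd, qend = qs_fwd + sizes,
             tname = tname, tstart = tstarts, tend = tstarts + sizes,
             strand = strand, stringsAsFactors = FALSE)
}

# Project 0-based query positions through one block.
# Plus strand: base q maps to tstart + (q - qstart).
# Minus strand: order reverses within the block: tend - 1 - (q - qstart).
.project_position <- function(pos, block) {
  off <- pos - block$qstart
  ifelse(block$strand == "+", block$tstart + off, block$tend - 1 - off)
}

#' Anchor unit windows onto the synteny-species assembly
#'
#' For each window, collects overlapping alignment blocks and sums overlap
#' per target scaffold. The window is anchored iff the total overlap with
#' blocks pointing to the majority target scaffold is at least
#' `min_overlap` of the window length; its target position is the
#' projection of the window midpoint through the best-overlapping block to
#' that scaffold (ties broken by larger block, then lexicographic target
#' name). Unanchored is a valid outcome.
#'
#' @param grid Unit window grid.
#' @param map `synteny_map` from [parse_alignment_map()].
#' @param min_overlap Minimum anchored fraction of the window (default
#'   0.5).
#' @return data.frame, one row per window: `window_id`, `anchored`,
#'   `tname`, `tpos` (0-based), `overlap_frac`.
#' @export
anchor_windows <- function(grid, map, min_overlap = 0.5) {
  n <- nrow(grid)
  out <- data.frame(window_id = grid$window_id, anchored = FALSE,
                    tname = NA_character_, tpos = NA_real_,
                    overlap_frac = 0, stringsAsFactors = FALSE)
  for (sc in unique(grid$scaffold)) {
    wsel <- which(grid$scaffold == sc)
    bsel <- which(map$qname == sc)
    if (length(bsel) == 0) next
    win <- IRanges::IRanges(grid$start[wsel] + 1L, grid$end[wsel])
    blk <- IRanges::IRanges(map$qstart[bsel] + 1L, map$qend[bsel])
    h <- IRanges::findOverlaps(win, blk)
    if (length(h) == 0) next
    qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
    ov <- IRanges::width(IRanges::pintersect(win[qh], blk[sh]))
    tname <- map$tname[bsel][sh]
    bw <- map$qend[bsel][sh] - map$qstart[bsel][sh]
    for (w in unique(qh)) {
      rows <- which(qh == w)
      per_t <- rowsum(ov[rows], tname[rows])
      best_t <- rownames(per_t)[order(-per_t[, 1], rownames(per_t))][1]
      total <- per_t[best_t, 1]
      wl <- grid$length[wsel[w]]
      out$overlap_frac[wsel[w]] <- total / wl
      if (total < min_overlap * wl) next
      cand <- rows[tname[rows] == best_t]
      # best block: largest overlap, then larger block, then first
      cand <- cand[order(-ov[cand], -bw[cand])]
      b <- map[bsel[sh[cand[1]]], ]
      mid <- floor((grid$start[wsel[w]] + grid$end[wsel[w]]) / 2)
      out$anchored[wsel[w]] <- TRUE
      out$tname[wsel[w]] <- best_t
      out$tpos[wsel[w]] <- .project_position(mid, b)
    }
  }
  out
}

#' Lift a unit-window sex-difference table onto synteny coordinates
#'
#' Re-keys anchored unit windows to target coordinates (values unchanged);
#' unanchored windows are dropped from the synteny branch (they remain in
#' the study-species outputs). The anchoring rate — anchored windows over
#' all unit windows — is the liftover success statistic reported per run.
#'
#' @param sd `sexdiff_unit` from [sexdiff_table()].
#' @param map `synteny_map`.
#' @param target_index Optional [genome_index()] of the synteny species;
#'   inferred from the map's maximal target coordinates when omitted.
#' @param min_overlap Anchoring threshold (default 0.5).
#' @return A `sexdiff_lifted` object: `sd` plus `anchor` (per-window
#'   anchoring table), `target_index`, `anchoring_rate` (fraction in
#'   [0, 1]).
#' @export
liftover_table <- function(sd, map, target_index = NULL, min_overlap = 0.5) {
  anchor <- anchor_windows(sd$grid, map, min_overlap)
  if (is.null(target_index)) {
    if (nrow(map) == 0) {
      target_index <- NULL
    } else {
      tmax <- tapply(map$tend, map$tname, max)
      # preserve order of first appearance in the map
      ord <- unique(map$tname)
      target_index <- genome_index(ord, as.numeric(tmax[ord]))
    }
  }
  structure(list(sd = sd, anchor = anchor, target_index = target_index,
                 map = map,
                 anchoring_rate = mean(anchor$anchored)),
            class = "sexdiff_lifted")
}

#' Aggregate a lifted table over synteny-coordinate report windows
#'
#' Identical semantics to [aggregate_windows()], but unit windows are
#' binned on the target assembly by their projected midpoints. Small query
#' scaffolds mapping into the same target window are averaged together,
#' which is what rescues fragmented study assemblies. Downstream band,
#' outlier and summary operations apply unchanged to the result.
#'
#' @param lifted `sexdiff_lifted` from [liftover_table()].
#' @param report_window Report window size in bp on the target assembly.
#' @param min_n Minimum contributing unit windows (default 5).
#' @return A `sexdiff_agg` in target coordinates.
#' @export
aggregate_lifted <- function(lifted, report_window, min_n = 5) {
  sd <- lifted$sd
  if (is.null(lifted$target_index))
    stop("empty synteny map: no target coordinate space to aggregate over",
         call. = FALSE)
  rgrid <- make_window_grid(lifted$target_index, report_window)
  anc <- lifted$anchor$anchored
  bin <- rep(NA_integer_, nrow(sd$grid))
  bin[anc] <- .bin_by_midpoint(lifted$anchor$tname[anc],
                               lifted$anchor$tpos[anc], rgrid)
  metrics <- lapply(sd$metrics, function(m) {
    a <- .aggregate_values(cbind(het_mean = m$het_mean,
                                 hom_mean = m$hom_mean, diff = m$diff),
                           bin, sd$masked, nrow(rgrid), min_n)
    list(het_mean = a$values[, "het_mean"], hom_mean = a$values[, "hom_mean"],
         diff = a$values[, "diff"], n = a$n)
  })
  structure(list(report_grid = rgrid, report_window = report_window,
                 metrics = metrics, samples = sd$samples,
                 anchoring_rate = lifted$anchoring_rate),
            class = "sexdiff_agg")
}

#' Write a synteny map in the 7-column TSV dialect
#'
#' @param map `synteny_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synteny_map <- function(map, path) {
  utils::write.table(
    data.frame(map$qname, map$qstart, map$qend, map$tname, map$tstart,
               map$tend, map$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
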