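#' Genome index
#'
#' An ordered table of scaffold names and lengths defining the coordinate
#' space of a run. Normally read from a samtools FASTA index (`.fai`), whose
#' first two columns are the scaffold name and length; scaffold order is
#' preserved as the plotting/output order.
#'
#' @param names Character vector of scaffold names (unique).
#' @param lengths Integer vector of scaffold lengths in bp (all >= 1).
#' @return A `genome_index` object: a data.frame with columns `name` and
#'   `length`, ordered as supplied.
#' @export
genome_index <- function(names, lengths) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) == 0L)
    stop("empty genome index: no scaffolds", call. = FALSE)
  if (length(names) != length(lengths))
    stop("scaffold names and lengths differ in length", call. = FALSE)
  if (anyDuplicated(names))
    stop("duplicate scaffold names in genome index: ",
         paste(unique(names[duplicated(names)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(lengths)) || any(lengths < 1))
    stop("scaffold lengths must be >= 1", call. = FALSE)
  idx <- data.frame(name = names, length = lengths,
                    stringsAsFactors = FALSE)
  class(idx) <- c("genome_index", "data.frame")
  idx
}

#' Read a genome index from a FASTA index file
#'
#' Accepts a `.fai` file (or any tab-separated file whose first two columns
#' are scaffold name and length). If given a FASTA file, an index is created
#' next to it when missing.
#'
#' @param path Path to a `.fai` index or a FASTA file.
#' @return A [genome_index()].
#' @export
read_genome_index <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!grepl("\\.fai$", path)) {
    fai <- paste0(path, ".fai")
    if (!file.exists(fai)) Rsamtools::indexFa(path)
    path <- fai
  }
  lines <- readLines(path)
  parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  if (any(lengths(parts) < 2))
    stop("malformed index line(s) in ", path, call. = FALSE)
  genome_index(vapply(parts, `[[`, "", 1L),
               as.numeric(vapply(parts, `[[`, "", 2L)))
}

#' Assembly summary statistics
#'
#' Scaffold count, total length and N50 (the length such that scaffolds of
#' that length or longer cover at least half the assembly), computed from the
#' genome index by largest-first cumulative summing.
#'
#' @param index A [genome_index()].
#' @return A list with `n_scaffolds`, `total_length`, `n50`.
#' @export
assembly_stats <- function(index) {
  len <- sort(index$length, decreasing = TRUE)
  tot <- sum(len)
  n50 <- len[which(cumsum(len) >= tot / 2)[1]]
  list(n_scaffolds = nrow(index), total_length = tot, n50 = n50)
}

#' Tile a genome into analysis windows
#'
#' Produces the unit-window grid over which coverage and heterozygosity are
#' computed. Windows use 0-based half-open coordinates internally; output
#' tables print 1-based inclusive coordinates. Every scaffold is tiled
#' gaplessly from position 0; the last window of a scaffold may be shorter
#' than `window`. Trailing windows shorter than half the window size are
#' flagged (`short = TRUE`) and excluded from normalization means and
#' interval estimation downstream (their statistics are length-normalized,
#' so they remain in the output tables).
#'
#' @param index A [genome_index()].
#' @param window Window size in bp (>= 1; default 5000, the unit scan
#'   resolution).
#' @return A `window_grid` data.frame with columns `window_id`, `scaffold`,
#'   `start`, `end`, `length`, `short`.
#' @export
make_window_grid <- function(index, window = 5000) {
  if (!inherits(index, "genome_index")) index <- genome_index(index$name, index$length)
  window <- as.numeric(window)
  if (length(window) != 1L || !is.finite(window) || window < 1)
    stop("window size must be a single value >= 1", call. = FALSE)
  starts <- lapply(index$length, function(L) seq(0, L - 1, by = window))
  n_per <- lengths(starts)
  scaffold <- rep(index$name, n_per)
  start <- unlist(starts, use.names = FALSE)
  end <- pmin(start + window, rep(index$length, n_per))
  grid <- data.frame(window_id = seq_along(start),
                     scaffold = scaffold, start = start, end = end,
                     length = end - start,
                     short = (end - start) < window / 2,
                     stringsAsFactors = FALSE)
  attr(grid, "window") <- window
  attr(grid, "index") <- index
  class(grid) <- c("window_grid", "data.frame")
  grid
}

# windows of one scaffold as an IRanges (1-based closed, for overlap queries)
.grid_ranges <- function(grid, scaffold) {
  g <- grid[grid$scaffold == scaffold, , drop = FALSE]
  IRanges::IRanges(start = g$start + 1L, end = g$end)
}
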