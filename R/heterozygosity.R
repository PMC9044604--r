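#' Hard-filter a multi-sample VCF
#'
#' Keeps only biallelic single-nucleotide variants with site quality at
#' least `qual_min`. Genotypes with genotype quality below `gq_min` or
#' depth below `dp_min` are set to missing. Indel and multiallelic records
#' are dropped; drop counts are recorded by reason.
#'
#' @param vcf Path to a VCF file (plain or bgzipped; standard GT/GQ/DP
#'   genotype fields).
#' @param sample_ids Sample ids that must be present in the VCF header;
#'   genotypes are returned in this column order.
#' @param qual_min,gq_min,dp_min Hard-filter thresholds (defaults 30, 20,
#'   3).
#' @return A `variant_set` object: list with `sites` (data.frame `scaffold`,
#'   `pos` 1-based, `ref`, `alt`), `geno` (integer matrix sites x samples;
#'   0 hom-ref, 1 het, 2 hom-alt, NA missing) and `dropped` (named counts).
#' @export
filter_variants <- function(vcf, sample_ids, qual_min = 30, gq_min = 20,
                            dp_min = 3) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  have <- colnames(v@gt)[-1]
  missing <- setdiff(sample_ids, have)
  if (length(missing) > 0)
    stop("sample(s) absent from VCF header: ",
         paste(missing, collapse = ", "), call. = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  multi <- grepl(",", alt, fixed = TRUE) | is.na(alt) | alt == "."
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  lowq <- !multi & !indel & (is.na(qual) | qual < qual_min)
  keep <- !multi & !indel & !lowq
  dropped <- c(multiallelic = sum(multi), indel = sum(indel),
               low_qual = sum(lowq))
  gt <- vcfR::extract.gt(v, element = "GT")[keep, sample_ids, drop = FALSE]
  gq <- suppressWarnings(
    vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)[keep, sample_ids,
                                                           drop = FALSE])
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[keep, sample_ids,
                                                           drop = FALSE])
  code <- matrix(NA_integer_, nrow = sum(keep), ncol = length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  a <- sub("[/|].*", "", gt); b <- sub(".*[/|]", "", gt)
  ok <- !is.na(gt) & a %in% c("0", "1") & b %in% c("0", "1")
  code[ok] <- as.integer(a[ok]) + as.integer(b[ok])
  low <- (!is.na(gq) & gq < gq_min) | (!is.na(dp) & dp < dp_min)
  code[low] <- NA_integer_
  sites <- data.frame(scaffold = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      ref = ref[keep], alt = alt[keep],
                      stringsAsFactors = FALSE)
  structure(list(sites = sites, geno = code, dropped = dropped),
            class = "variant_set")
}

#' Per-window, per-sample heterozygosity
#'
#' Counts heterozygous genotypes at kept sites inside each unit window and
#' divides by the full window length (the same denominator for every
#' sample, so between-sex contrasts are unbiased even where callability
#' varies). Missing genotypes contribute nothing.
#'
#' @param fv `variant_set` from [filter_variants()].
#' @param grid Unit window grid.
#' @return A `window_values` object with a single `"het"` value matrix
#'   (heterozygous sites per bp).
#' @export
window_heterozygosity <- function(fv, grid) {
  n <- nrow(grid)
  ids <- colnames(fv$geno)
  counts <- matrix(0, n, length(ids), dimnames = list(NULL, ids))
  if (nrow(fv$sites) > 0) {
    idx <- attr(grid, "index")
    bad <- !(fv$sites$scaffold %in% idx$name)
    if (any(bad))
      stop("variant(s) on scaffold(s) absent from the genome index: ",
           paste(unique(fv$sites$scaffold[bad]), collapse = ", "),
           call. = FALSE)
    win_of <- integer(nrow(fv$sites))
    for (sc in unique(fv$sites$scaffold)) {
      sel <- fv$sites$scaffold == sc
      win <- .grid_ranges(grid, sc)
      offset <- match(sc, grid$scaffold) - 1L
      h <- IRanges::findOverlaps(
        IRanges::IRanges(fv$sites$pos[sel], width = 1L), win)
      w <- integer(sum(sel))
      w[S4Vectors::queryHits(h)] <- offset + S4Vectors::subjectHits(h)
      win_of[sel] <- w
    }
    inside <- win_of > 0L
    het <- fv$geno == 1L
    het[is.na(het)] <- FALSE
    for (j in seq_along(ids)) {
      t <- rowsum(as.numeric(het[inside, j]), win_of[inside])
      counts[as.integer(rownames(t)), j] <- t[, 1]
    }
  }
  structure(list(grid = grid,
                 values = list(het = counts / grid$length),
                 het_counts = counts,
                 masked = grid$short,
                 mask_reason = ifelse(grid$short, "short_window", ""),
                 normalized = FALSE),
            class = "window_values")
}

#' Genome-wide heterozygosity percentage per sample
#'
#' 100 times the number of heterozygous genotypes divided by the total
#' genome length. Reported per sample; values of 1% or more are flagged in
#' the run log and report, as very high genome-wide heterozygosity can
#' obscure the sex-linked signature.
#'
#' @param fv `variant_set` from [filter_variants()].
#' @param index Genome index.
#' @return Named numeric vector of percentages.
#' @export
genomewide_heterozygosity <- function(fv, index) {
  total <- sum(index$length)
  het <- colSums(fv$geno == 1L, na.rm = TRUE)
  100 * het / total
}

#' Build a consensus genome from called variants
#'
#' Writes the majority allele into the reference at every kept site: if the
#' alternate-allele count summed over all provided genotypes exceeds the
#' reference-allele count, the alternate base is substituted; ties and all
#' other positions keep the reference base. Scaffold names, order and
#' lengths are unchanged. Used to equalize autosome-wide mapping success
#' between samples before a second pipeline pass when the reference was
#' assembled from one of the samples.
#'
#' @param reference Path to the reference FASTA.
#' @param fv `variant_set` from [filter_variants()].
#' @param out Path for the consensus FASTA (written 60 columns wide).
#' @return Invisibly, the number of substituted sites.
#' @export
build_consensus_genome <- function(reference, fv, out) {
  seqs <- Biostrings::readDNAStringSet(reference)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  n_sub <- 0L
  if (nrow(fv$sites) > 0) {
    ref_n <- rowSums(2L * (fv$geno == 0L) + (fv$geno == 1L), na.rm = TRUE)
    alt_n <- rowSums(2L * (fv$geno == 2L) + (fv$geno == 1L), na.rm = TRUE)
    swap <- alt_n > ref_n
    for (sc in unique(fv$sites$scaffold)) {
      sel <- fv$sites$scaffold == sc
      if (!sc %in% names(seqs))
        stop("variant scaffold absent from reference FASTA: ", sc,
             call. = FALSE)
      pos <- fv$sites$pos[sel]
      have <- as.character(Biostrings::extractAt(
        seqs[[sc]], IRanges::IRanges(pos, width = 1L)))
      bad <- have != fv$sites$ref[sel]
      if (any(bad))
        stop("REF allele disagrees with FASTA base at ", sc, ":",
             paste(utils::head(pos[bad], 3), collapse = ","),
             " (coordinate mismatch)", call. = FALSE)
      do <- swap[sel]
      if (any(do)) {
        seqs[[sc]] <- Biostrings::replaceLetterAt(
          seqs[[sc]], pos[do], fv$sites$alt[sel][do])
        n_sub <- n_sub + sum(do)
      }
    }
  }
  Biostrings::writeXStringSet(seqs, out, width = 60L)
  invisible(n_sub)
}
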