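# Synthetic-data generator. Produces reference FASTA, per-sample aligned
# BAMs (written as SAM text with synthetic NM tags and converted in place;
# no aligner involved, so the exact filter path is exercised), a
# multi-sample VCF and synteny maps, realizing the canonical sex-chromosome
# differentiation scenarios: autosomal background, low-differentiation
# sex-linked regions (excess heterozygosity in the heterogametic sex;
# coverage loss only under strict mismatch filtering), high-differentiation
# regions (coverage loss that deepens with filtering), and fully
# degenerated regions (half coverage in the heterogametic sex at every
# setting).

# deterministic 31-adic string hash, kept below 2^31 for seed arithmetic
.stable_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  h
}

.sample_seed <- function(scenario, id) {
  as.integer((scenario$seed * 7919 + .stable_hash(id)) %% 2147483647)
}

#' Define a simulation scenario
#'
#' @param scaffold_lengths Named numeric vector: scaffold name -> length in
#'   bp.
#' @param regions data.frame with columns `scaffold`, `start`, `end`
#'   (0-based half-open), `klass`
#'   (`autosomal`/`low_diff`/`high_diff`/`PAR`), `divergence` (expected
#'   mismatches per 100 read bp for reads from the sex-limited gametolog),
#'   `degeneration` (fraction of the sex-limited copy absent, in [0, 1]),
#'   `het_rate` (excess heterozygous sites per bp per heterogametic sample).
#'   May be empty (pure autosomal genome).
#' @param samples data.frame with columns `id`, `sex`.
#' @param system `"XY"` or `"ZW"`.
#' @param depth Nominal diploid depth per sample (default 10).
#' @param read_length Read length in bp (default 100).
#' @param het_rate Background heterozygosity per bp per sample (default
#'   0.001).
#' @param seed Integer seed; fixes all randomness, with per-sample
#'   substreams derived by stable hashing of the sample id.
#' @return A `sim_scenario` object.
#' @export
sim_scenario <- function(scaffold_lengths, regions = NULL, samples,
                         system = c("XY", "ZW"), depth = 10,
                         read_length = 100, het_rate = 0.001, seed = 1L) {
  system <- match.arg(system)
  if (is.null(regions) || nrow(regions) == 0)
    regions <- data.frame(scaffold = character(), start = numeric(),
                          end = numeric(), klass = character(),
                          divergence = numeric(), degeneration = numeric(),
                          het_rate = numeric(), stringsAsFactors = FALSE)
  stopifnot(depth > 0, read_length >= 20,
            all(regions$degeneration >= 0 & regions$degeneration <= 1),
            all(regions$divergence >= 0))
  # regions must not overlap within a scaffold
  for (sc in unique(regions$scaffold)) {
    r <- regions[regions$scaffold == sc, ]
    r <- r[order(r$start), ]
    if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)]))
      stop("overlapping regions on scaffold ", sc, call. = FALSE)
  }
  structure(list(scaffold_lengths = scaffold_lengths, regions = regions,
                 samples = samples, system = system, depth = depth,
                 read_length = read_length, het_rate = het_rate,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Canonical scenario presets
#'
#' Desk-scale presets mirroring the standard differentiation scenarios on a
#' 5 Mb genome (read length 100, depth 10, one sample per sex, XY system):
#' * `fig1d` — fully degenerated sex-linked region (100 kb on `s1`):
#'   half coverage in the heterogametic sex at every mismatch setting,
#'   heterozygosity at or below background.
#' * `fig1c` — highly differentiated but incompletely degenerated region:
#'   diverged reads align only without mismatch filtering; elevated
#'   heterozygosity.
#' * `fig1b` — low-differentiation sex-linked scaffolds (`s5`, `s6`):
#'   excess heterozygosity in the heterogametic sex; coverage loss only
#'   under strict filtering.
#' * `null` — no sex-linked regions (band calibration).
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @return A `sim_scenario`.
#' @export
scenario_preset <- function(name = c("fig1d", "fig1c", "fig1b", "null"),
                            seed = 1L) {
  name <- match.arg(name)
  samples <- data.frame(id = c("F1", "M1"), sex = c("female", "male"),
                        stringsAsFactors = FALSE)
  if (name == "fig1b") {
    lens <- stats::setNames(c(rep(1e6, 4), 5e5, 5e5), paste0("s", 1:6))
    regions <- data.frame(
      scaffold = c("s5", "s6"), start = 0, end = 5e5, klass = "low_diff",
      divergence = 3, degeneration = 0, het_rate = 0.002,
      stringsAsFactors = FALSE)
  } else {
    lens <- stats::setNames(rep(1e6, 5), paste0("s", 1:5))
    regions <- switch(name,
      fig1d = data.frame(scaffold = "s1", start = 1e5, end = 2e5,
                         klass = "high_diff", divergence = 10,
                         degeneration = 1, het_rate = 0,
                         stringsAsFactors = FALSE),
      fig1c = data.frame(scaffold = "s1", start = 1e5, end = 2e5,
                         klass = "high_diff", divergence = 6,
                         degeneration = 0.3, het_rate = 0.004,
                         stringsAsFactors = FALSE),
      null = NULL)
  }
  sim_scenario(lens, regions, samples, system = "XY", depth = 10,
               read_length = 100, het_rate = 0.001, seed = seed)
}

#' Simulate the reference genome
#'
#' Uniform-random-base scaffolds of the configured lengths, written as
#' FASTA with a samtools-style index. Deterministic under the scenario
#' seed.
#'
#' @param scenario A `sim_scenario`.
#' @param dir Output directory.
#' @return Path to the FASTA (its `.fai` sits alongside).
#' @export
simulate_reference <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(scenario$seed)
  seqs <- Biostrings::DNAStringSet(vapply(
    scenario$scaffold_lengths,
    function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                      collapse = ""),
    ""))
  names(seqs) <- names(scenario$scaffold_lengths)
  fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(seqs, fasta, width = 60L)
  Rsamtools::indexFa(fasta)
  fasta
}

# Segments of one scaffold: the regions plus autosomal gaps between them.
.scaffold_segments <- function(scenario, sc) {
  L <- scenario$scaffold_lengths[[sc]]
  r <- scenario$regions[scenario$regions$scaffold == sc, , drop = FALSE]
  r <- r[order(r$start), , drop = FALSE]
  segs <- list()
  cur <- 0
  for (i in seq_len(nrow(r))) {
    if (r$start[i] > cur)
      segs[[length(segs) + 1L]] <- list(start = cur, end = r$start[i],
                                        klass = "autosomal")
    segs[[length(segs) + 1L]] <- as.list(r[i, ])
    cur <- r$end[i]
  }
  if (cur < L)
    segs[[length(segs) + 1L]] <- list(start = cur, end = L,
                                      klass = "autosomal")
  segs
}

.background_nm <- function(n) {
  sample(0:2, n, replace = TRUE, prob = c(0.7, 0.25, 0.05))
}

#' Simulate aligned reads for one sample
#'
#' Writes a coordinate-sorted, indexed BAM of single-end alignment records
#' with NM (edit distance) tags. Homogametic samples receive
#' Poisson-distributed reads with a small background NM everywhere.
#' Heterogametic samples follow the region class: in `high_diff` regions
#' half the diploid depth (the X/Z-derived half) carries background NM
#' while a `(1 - degeneration)/2` share carries NM around
#' `divergence x read_length / 100`; with full degeneration that share is
#' simply absent. In `low_diff` regions the sex-limited half carries NM in
#' 2-4, so it survives unbounded filtering but fails strict filtering.
#' `autosomal` and `PAR` regions are symmetric between sexes. A small
#' fraction of duplicate-flagged and MAPQ-0 records is included to
#' exercise the alignment filter gates.
#'
#' @param scenario A `sim_scenario`.
#' @param sample_id Sample id from the scenario sample sheet.
#' @param dir Output directory (must already contain the reference from
#'   [simulate_reference()] or any directory for the BAM).
#' @return Path to the indexed BAM.
#' @export
simulate_alignments <- function(scenario, sample_id, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- scenario$samples[scenario$samples$id == sample_id, ]
  if (nrow(s) != 1) stop("unknown sample id: ", sample_id, call. = FALSE)
  het_sex <- if (scenario$system == "XY") "male" else "female"
  is_het <- s$sex == het_sex
  rl <- scenario$read_length
  set.seed(.sample_seed(scenario, sample_id))
  rname <- character(0); pos <- integer(0); nm <- integer(0)
  flag <- integer(0); mapq <- integer(0)
  emit <- function(sc, n, seg_start, seg_end, nm_fun) {
    if (n <= 0) return()
    p <- as.integer(floor(stats::runif(n, seg_start,
                                       max(seg_start + 1, seg_end - rl))))
    rname <<- c(rname, rep(sc, n)); pos <<- c(pos, p + 1L)
    nm <<- c(nm, nm_fun(n))
    flag <<- c(flag, sample(c(0L, 16L), n, replace = TRUE))
    mapq <<- c(mapq, rep(60L, n))
  }
  for (sc in names(scenario$scaffold_lengths)) {
    for (seg in .scaffold_segments(scenario, sc)) {
      L <- seg$end - seg$start
      lam <- scenario$depth * L / rl
      if (!is_het || seg$klass %in% c("autosomal", "PAR")) {
        emit(sc, stats::rpois(1, lam), seg$start, seg$end, .background_nm)
      } else if (seg$klass == "high_diff") {
        emit(sc, stats::rpois(1, lam / 2), seg$start, seg$end,
             .background_nm)
        lam_y <- lam / 2 * (1 - seg$degeneration)
        div_nm <- seg$divergence * rl / 100
        emit(sc, stats::rpois(1, lam_y), seg$start, seg$end,
             function(n) stats::rpois(n, div_nm))
      } else if (seg$klass == "low_diff") {
        emit(sc, stats::rpois(1, lam / 2), seg$start, seg$end,
             .background_nm)
        emit(sc, stats::rpois(1, lam / 2), seg$start, seg$end,
             function(n) sample(2:4, n, replace = TRUE))
      } else stop("unknown region class: ", seg$klass, call. = FALSE)
    }
    # filter-exercising artifacts: duplicates and multi-mappers (~1%)
    L <- scenario$scaffold_lengths[[sc]]
    n_art <- stats::rpois(1, 0.01 * scenario$depth * L / rl)
    if (n_art > 0) {
      p <- as.integer(floor(stats::runif(n_art, 0, L - rl))) + 1L
      dup <- stats::runif(n_art) < 0.5
      rname <- c(rname, rep(sc, n_art)); pos <- c(pos, p)
      nm <- c(nm, .background_nm(n_art))
      flag <- c(flag, ifelse(dup, 1024L, 0L))
      mapq <- c(mapq, ifelse(dup, 60L, 0L))
    }
  }
  ord <- order(match(rname, names(scenario$scaffold_lengths)), pos)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d",
                      names(scenario$scaffold_lengths),
                      as.integer(scenario$scaffold_lengths)))
  recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tNM:i:%d",
                  paste0(sample_id, "_r", seq_along(ord)),
                  flag[ord], rname[ord], pos[ord], mapq[ord], rl, nm[ord])
  sam <- file.path(dir, paste0(sample_id, ".sam"))
  writeLines(c(header, recs), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, sample_id),
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  bam
}

#' Simulate a multi-sample VCF
#'
#' Shared candidate sites arise at twice the background heterozygosity
#' rate; each sample is heterozygous at a candidate with probability 1/2
#' (so the per-sample heterozygosity equals `het_rate`), otherwise
#' hom-ref (90%) or hom-alt. In `low_diff` and non-degenerate `high_diff`
#' regions, heterogametic samples gain private heterozygous sites at the
#' region's excess rate (gametolog divergence read as heterozygosity); in
#' fully degenerated regions heterogametic samples are hemizygous and
#' their genotypes are written hom-ref. Passing sites carry QUAL, GQ and
#' DP that survive the default filters; a small set of junk records (low
#' QUAL, indels, multiallelic, low-GQ genotypes) on top exercises the
#' filter gates without biasing the advertised rates.
#'
#' @param scenario A `sim_scenario`.
#' @param dir Output directory.
#' @param reference Optional reference FASTA path; when given, REF alleles
#'   are taken from the sequence (required for consensus-genome round
#'   trips).
#' @return Path to the VCF (plain text).
#' @export
simulate_variants <- function(scenario, dir, reference = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer((scenario$seed * 104729 + 13) %% 2147483647))
  ids <- scenario$samples$id
  het_sex <- if (scenario$system == "XY") "male" else "female"
  is_het <- scenario$samples$sex == het_sex
  seqs <- if (!is.null(reference)) {
    x <- Biostrings::readDNAStringSet(reference)
    names(x) <- sub("\\s.*", "", names(x)); x
  } else NULL
  bases <- c("A", "C", "G", "T")
  lines <- character(0)
  rows <- list()
  for (sc in names(scenario$scaffold_lengths)) {
    L <- scenario$scaffold_lengths[[sc]]
    # shared background candidates
    n_cand <- stats::rpois(1, 2 * scenario$het_rate * L)
    cand <- sort(sample.int(L, min(n_cand, L)))
    geno <- matrix("0/0", length(cand), length(ids),
                   dimnames = list(NULL, ids))
    for (j in seq_along(ids)) {
      u <- stats::runif(length(cand))
      geno[u < 0.5, j] <- "0/1"
      geno[u >= 0.95, j] <- "1/1"
    }
    # region adjustments
    for (seg in .scaffold_segments(scenario, sc)) {
      if (seg$klass == "autosomal" || seg$klass == "PAR") next
      inside <- cand > seg$start & cand <= seg$end
      if (seg$klass == "high_diff" && seg$degeneration >= 1) {
        # hemizygous: heterogametic genotypes collapse to hom-ref
        geno[inside, is_het] <- "0/0"
      }
      excess <- seg$het_rate
      if (excess > 0) {
        for (j in which(is_het)) {
          n_x <- stats::rpois(1, excess * (seg$end - seg$start))
          px <- seg$start + sort(sample.int(seg$end - seg$start,
                                            min(n_x, seg$end - seg$start)))
          px <- setdiff(px, cand)
          if (length(px) == 0) next
          g2 <- matrix("0/0", length(px), length(ids),
                       dimnames = list(NULL, ids))
          g2[, j] <- "0/1"
          cand <- c(cand, px)
          geno <- rbind(geno, g2)
        }
      }
    }
    ord <- order(cand)
    cand <- cand[ord]; geno <- geno[ord, , drop = FALSE]
    dup <- duplicated(cand)
    cand <- cand[!dup]; geno <- geno[!dup, , drop = FALSE]
    if (length(cand) == 0) next
    ref <- if (!is.null(seqs))
      as.character(Biostrings::extractAt(
        seqs[[sc]], IRanges::IRanges(cand, width = 1L)))
    else sample(bases, length(cand), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    qual <- round(stats::runif(length(cand), 60, 200))
    dp <- matrix(stats::rpois(length(cand) * length(ids),
                              scenario$depth) + 3L,
                 length(cand), length(ids))
    gq <- matrix(sample(40:99, length(cand) * length(ids), replace = TRUE),
                 length(cand), length(ids))
    rows[[sc]] <- list(sc = sc, pos = cand, ref = ref, alt = alt,
                       qual = qual, geno = geno, gq = gq, dp = dp)
  }
  # junk records exercising the filter gates (~5% of background site count)
  junk <- list()
  for (sc in names(scenario$scaffold_lengths)) {
    L <- scenario$scaffold_lengths[[sc]]
    n_j <- stats::rpois(1, 0.1 * scenario$het_rate * L)
    if (n_j == 0) next
    pj <- sort(sample.int(L, n_j))
    kind <- sample(c("lowqual", "indel", "multi", "lowgq"), n_j,
                   replace = TRUE)
    junk[[sc]] <- list(sc = sc, pos = pj, kind = kind)
  }
  vcf <- file.path(dir, "variants.vcf")
  con <- file(vcf, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>",
                       names(scenario$scaffold_lengths),
                       as.integer(scenario$scaffold_lengths)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids), collapse = "\t")),
             con)
  for (sc in names(scenario$scaffold_lengths)) {
    r <- rows[[sc]]
    recs <- character(0)
    p_all <- numeric(0)
    if (!is.null(r)) {
      fmt <- vapply(seq_along(r$pos), function(i)
        paste(sprintf("%s:%d:%d", r$geno[i, ], r$gq[i, ], r$dp[i, ]),
              collapse = "\t"), "")
      recs <- sprintf("%s\t%d\t.\t%s\t%s\t%d\tPASS\t.\tGT:GQ:DP\t%s",
                      sc, r$pos, r$ref, r$alt, r$qual, fmt)
      p_all <- r$pos
    }
    j <- junk[[sc]]
    if (!is.null(j)) {
      keepj <- !(j$pos %in% p_all)
      jp <- j$pos[keepj]; jk <- j$kind[keepj]
      if (length(jp) > 0) {
        jfmt <- vapply(seq_along(jp), function(i) {
          gq <- if (jk[i] == "lowgq") 5L else 90L
          paste(sprintf("0/1:%d:%d", rep(gq, length(ids)),
                        scenario$depth + 3L), collapse = "\t")
        }, "")
        jref <- if (!is.null(seqs))
          as.character(Biostrings::extractAt(
            seqs[[sc]], IRanges::IRanges(jp, width = 1L)))
        else sample(bases, length(jp), replace = TRUE)
        jalt <- vapply(seq_along(jp), function(i) {
          switch(jk[i],
                 indel = paste0(jref[i], "A"),
                 multi = paste(sample(setdiff(bases, jref[i]), 2),
                               collapse = ","),
                 sample(setdiff(bases, jref[i]), 1))
        }, "")
        jqual <- ifelse(jk == "lowqual", 10L, 80L)
        jrecs <- sprintf("%s\t%d\t.\t%s\t%s\t%d\tPASS\t.\tGT:GQ:DP\t%s",
                         sc, jp, jref, jalt, jqual, jfmt)
        recs <- c(recs, jrecs)
        p_all <- c(p_all, jp)
      }
    }
    if (length(recs)) writeLines(recs[order(p_all)], con)
  }
  vcf
}

#' Simulate a synteny map
#'
#' Three modes: `identity` writes one forward block per scaffold onto an
#' identically named and sized target; `shuffled` cuts the genome into
#' blocks, permutes them onto two longer target scaffolds with random
#' strands (a fragmented-to-contiguous liftover); `partial` keeps a random
#' fraction `p` of identity blocks of size `block`.
#'
#' @param scenario A `sim_scenario`.
#' @param mode `"identity"`, `"shuffled"` or `"partial"`.
#' @param dir Output directory.
#' @param p Retained block fraction for `partial` (default 0.5).
#' @param block Block size in bp for `shuffled`/`partial` (default 5e4 and
#'   5e3 respectively; pass explicitly to override).
#' @return Path to the TSV map.
#' @export
simulate_synteny_map <- function(scenario,
                                 mode = c("identity", "shuffled", "partial"),
                                 dir, p = 0.5, block = NULL) {
  mode <- match.arg(mode)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer((scenario$seed * 15485863 + 7) %% 2147483647))
  lens <- scenario$scaffold_lengths
  if (mode == "identity") {
    map <- data.frame(qname = names(lens), qstart = 0, qend = as.numeric(lens),
                      tname = names(lens), tstart = 0,
                      tend = as.numeric(lens), strand = "+",
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(block)) block <- if (mode == "shuffled") 5e4 else 5e3
    qname <- character(0); qstart <- numeric(0); qend <- numeric(0)
    for (sc in names(lens)) {
      st <- seq(0, lens[[sc]] - 1, by = block)
      en <- pmin(st + block, lens[[sc]])
      qname <- c(qname, rep(sc, length(st)))
      qstart <- c(qstart, st); qend <- c(qend, en)
    }
    if (mode == "partial") {
      keep <- stats::runif(length(qname)) < p
      map <- data.frame(qname = qname[keep], qstart = qstart[keep],
                        qend = qend[keep], tname = qname[keep],
                        tstart = qstart[keep], tend = qend[keep],
                        strand = "+", stringsAsFactors = FALSE)
    } else {
      ord <- sample(length(qname))
      tname <- rep(c("T1", "T2"), length.out = length(ord))
      w <- qend[ord] - qstart[ord]
      tstart <- numeric(length(ord))
      for (tn in c("T1", "T2")) {
        sel <- tname == tn
        tstart[sel] <- cumsum(c(0, w[sel][-sum(sel)]))
      }
      map <- data.frame(qname = qname[ord], qstart = qstart[ord],
                        qend = qend[ord], tname = tname, tstart = tstart,
                        tend = tstart + w,
                        strand = sample(c("+", "-"), length(ord),
                                        replace = TRUE),
                        stringsAsFactors = FALSE)
    }
  }
  path <- file.path(dir, paste0("synteny_", mode, ".tsv"))
  class(map) <- c("synteny_map", "data.frame")
  write_synteny_map(map, path)
  path
}

#' Simulate a complete ready-to-run dataset
#'
#' Writes reference FASTA (+index), one indexed BAM per sample, the
#' multi-sample VCF, optionally a synteny map, and a YAML config, so a full
#' scan can be run with no external data.
#'
#' @param scenario A `sim_scenario`.
#' @param dir Output directory.
#' @param synteny Optional synteny-map mode passed to
#'   [simulate_synteny_map()] (`NULL` for none).
#' @param report_windows Report window sizes written into the config
#'   (default 5e4, suited to the desk-scale presets).
#' @param p Retained fraction for `synteny = "partial"`.
#' @return List of paths: `reference`, `bams` (named), `vcf`,
#'   `synteny_map` (or `NULL`), `config`, plus the `samples` sheet.
#' @export
simulate_dataset <- function(scenario, dir, synteny = NULL,
                             report_windows = 5e4, p = 0.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reference <- simulate_reference(scenario, dir)
  bams <- vapply(scenario$samples$id, function(id)
    simulate_alignments(scenario, id, dir), "")
  vcf <- simulate_variants(scenario, dir, reference = reference)
  map <- if (!is.null(synteny))
    simulate_synteny_map(scenario, synteny, dir, p = p) else NULL
  samples <- data.frame(scenario$samples, bam = unname(bams),
                        stringsAsFactors = FALSE)
  cfg <- list(
    samples = lapply(seq_len(nrow(samples)), function(i)
      list(id = samples$id[i], sex = samples$sex[i],
           bam = basename(samples$bam[i]))),
    system = scenario$system,
    reference = basename(reference),
    vcf = basename(vcf),
    unit_window = 5000,
    report_windows = as.list(report_windows),
    seed = scenario$seed,
    output_dir = "out")
  if (!is.null(map)) {
    cfg$synteny_map <- basename(map)
    cfg$synteny_dialect <- "tsv"
  }
  config <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, config)
  list(reference = reference, bams = bams, vcf = vcf, synteny_map = map,
       config = config, samples = samples)
}
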