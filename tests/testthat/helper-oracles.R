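# Independent oracles and fixture builders. Everything here is written
# against the raw file formats / definitions, not against the package
# internals, so tests compare two independent routes.

# --- independent CIGAR walker: reference-consuming blocks -------------

# 1-based inclusive reference blocks covered by the read (M/=/X only;
# D and N consume reference but add no depth)
oracle_ref_blocks <- function(pos, cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  cur <- pos
  out <- NULL
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X")) {
      out <- rbind(out, c(cur, cur + n[i] - 1L))
      cur <- cur + n[i]
    } else if (op[i] %in% c("D", "N")) {
      cur <- cur + n[i]
    } # I, S, H, P consume no reference
  }
  out
}

# --- per-base pileup oracle for window coverage -----------------------

oracle_pileup_coverage <- function(rname, pos, cigar, grid) {
  index <- attr(grid, "index")
  vals <- numeric(nrow(grid))
  for (sc in index$name) {
    L <- index$length[index$name == sc]
    depth <- integer(L)
    for (i in which(rname == sc)) {
      b <- oracle_ref_blocks(pos[i], cigar[i])
      for (j in seq_len(nrow(b))) {
        lo <- max(1L, b[j, 1]); hi <- min(L, b[j, 2])
        if (lo <= hi) depth[lo:hi] <- depth[lo:hi] + 1L
      }
    }
    rows <- which(grid$scaffold == sc)
    for (r in rows)
      vals[r] <- sum(depth[(grid$start[r] + 1):grid$end[r]]) / grid$length[r]
  }
  vals
}

# --- SAM/BAM fixture writer -------------------------------------------

write_fixture_bam <- function(dir, name, index, qname, flag, rname, pos,
                              mapq, cigar, nm = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", index$name,
                      as.integer(index$length)))
  ord <- order(match(rname, index$name), pos)
  recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                  qname[ord], flag[ord], rname[ord], pos[ord], mapq[ord],
                  cigar[ord])
  if (!is.null(nm)) {
    tag <- ifelse(is.na(nm[ord]), "", sprintf("\tNM:i:%d", nm[ord]))
    recs <- paste0(recs, tag)
  }
  sam <- file.path(dir, paste0(name, ".sam"))
  writeLines(c(header, recs), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, name), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

# random small alignment fixture with varied CIGARs
random_bam_fixture <- function(seed, dir = tempfile("bamfix")) {
  set.seed(seed)
  index <- genome_index(c("cA", "cB"), c(2000, 1500))
  n <- 150
  rname <- sample(index$name, n, replace = TRUE)
  maxlen <- index$length[match(rname, index$name)]
  cigar <- character(n); pos <- integer(n)
  for (i in seq_len(n)) {
    shape <- sample(1:4, 1)
    cigar[i] <- switch(shape,
      "50M",
      sprintf("%dM%dD%dM", sample(10:30, 1), sample(1:5, 1),
              sample(10:30, 1)),
      sprintf("%dS%dM%dI%dM", sample(2:8, 1), sample(10:25, 1),
              sample(1:4, 1), sample(10:25, 1)),
      sprintf("%dM%dN%dM", sample(8:20, 1), sample(5:20, 1),
              sample(8:20, 1)))
    span <- sum(as.integer(
      sub("[A-Z=]$", "",
          regmatches(cigar[i],
                     gregexpr("[0-9]+[MDN=X]", cigar[i]))[[1]])))
    pos[i] <- sample(seq_len(maxlen[i] - span), 1)
  }
  nm <- sample(0:5, n, replace = TRUE)
  bam <- write_fixture_bam(dir, "fix", index, paste0("r", seq_len(n)),
                           sample(c(0L, 16L), n, replace = TRUE), rname,
                           pos, rep(60L, n), cigar, nm)
  list(bam = bam, index = index, rname = rname, pos = pos, cigar = cigar,
       nm = nm)
}

# --- synteny per-base projection oracle -------------------------------

# project a 0-based query position through a block row by explicit
# base-by-base enumeration
oracle_project <- function(qpos, block) {
  qs <- seq(block$qstart, block$qend - 1)
  ts <- if (block$strand == "+") seq(block$tstart, block$tend - 1)
        else seq(block$tend - 1, block$tstart)
  ts[match(qpos, qs)]
}

# --- tiny VCF writer --------------------------------------------------

write_fixture_vcf <- function(path, index, records, sample_ids) {
  # records: data.frame(scaffold, pos, ref, alt, qual, gt..., gq..., dp...)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", index$name,
                      as.integer(index$length)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
              "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", sample_ids),
                    collapse = "\t"))
  recs <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    fmt <- paste(vapply(sample_ids, function(s)
      sprintf("%s:%d:%d", r[[paste0("gt_", s)]],
              as.integer(r[[paste0("gq_", s)]]),
              as.integer(r[[paste0("dp_", s)]])), ""), collapse = "\t")
    sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t.\tGT:GQ:DP\t%s", r$scaffold,
            as.integer(r$pos), r$ref, r$alt, as.character(r$qual), fmt)
  }, "")
  writeLines(c(header, recs), path)
  path
}

# --- shared simulated datasets (memoized per test session) ------------

.sx_fixtures <- new.env(parent = emptyenv())

preset_dataset <- function(preset, seed = 101) {
  key <- paste0(preset, "_", seed)
  if (is.null(.sx_fixtures[[key]])) {
    dir <- file.path(tempdir(), paste0("sxds_", key))
    sc <- scenario_preset(preset, seed = seed)
    ds <- simulate_dataset(sc, dir)
    .sx_fixtures[[key]] <- list(scenario = sc, ds = ds, dir = dir)
  }
  .sx_fixtures[[key]]
}

preset_result <- function(preset, seed = 101) {
  key <- paste0("res_", preset, "_", seed)
  if (is.null(.sx_fixtures[[key]])) {
    fx <- preset_dataset(preset, seed)
    cfg <- load_config(fx$ds$config)
    .sx_fixtures[[key]] <- suppressMessages(run_pipeline(cfg))
  }
  .sx_fixtures[[key]]
}

# shared fixture: two-scaffold sexdiff table with random values plus an
# identity synteny map over both scaffolds
sd_synteny_fixture <- function() {
  if (!is.null(.sx_fixtures[["sd_syn"]])) return(.sx_fixtures[["sd_syn"]])
  set.seed(71)
  idx <- genome_index(c("sA", "sB"), c(5e5, 2.5e5))
  g <- make_window_grid(idx, 5000)
  sheet <- data.frame(id = c("F1", "M1"), sex = c("female", "male"),
                      bam = "x", stringsAsFactors = FALSE)
  sheet <- validate_sample_sheet(sheet, "XY", check_files = FALSE)
  cov <- matrix(rnorm(2 * nrow(g), 1, 0.05), nrow(g), 2,
                dimnames = list(NULL, sheet$id))
  het <- matrix(rpois(2 * nrow(g), 5) / 5000, nrow(g), 2,
                dimnames = list(NULL, sheet$id))
  mkv <- function(m, lab) {
    v <- list(); v[[lab]] <- m
    structure(list(grid = g, values = v, samples = sheet,
                   unbounded = lab, masked = g$short, mask_reason = "",
                   normalized = TRUE), class = "window_values")
  }
  sd <- sexdiff_table(mkv(cov, "unfiltered"), mkv(het, "het"), sheet)
  mp <- tempfile(fileext = ".tsv")
  writeLines(c("sA\t0\t500000\tsA\t0\t500000\t+",
               "sB\t0\t250000\tsB\t0\t250000\t+"), mp)
  identity_map <- parse_alignment_map(mp, "tsv")
  .sx_fixtures[["sd_syn"]] <- list(sd = sd, identity_map = identity_map)
  .sx_fixtures[["sd_syn"]]
}

count_pdf_pages <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  length(grepRaw("/Type /Page", raw, all = TRUE, fixed = TRUE)) -
    length(grepRaw("/Type /Pages", raw, all = TRUE, fixed = TRUE))
}
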