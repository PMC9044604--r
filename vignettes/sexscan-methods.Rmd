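---
title: "Detecting sex-linked regions with sexscan: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-linked regions with sexscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the signal model

Sex chromosomes arise when recombination stops between a chromosome pair,
after which the sex-limited copy (Y in XY systems, W in ZW systems)
diverges from and eventually loses sequence relative to its gametolog
(X/Z). When whole-genome sequencing reads from both sexes are aligned to
a reference assembled from the homogametic sex, the non-recombining
region leaves two windowed footprints that `sexscan` measures and
contrasts between sexes:

* **Coverage.** Let $c_{w,s}$ be the mean per-base depth of sample $s$ in
  window $w$ (computed from CIGAR-aligned reference spans; deletions add
  no depth; boundary-spanning reads contribute proportionally, which
  makes the value identical to a per-base pileup average). After masking
  and normalization (below), the per-window statistic is
  $\Delta_{\mathrm{cov}}(w) = \bar c_w^{\mathrm{het}} - \bar
  c_w^{\mathrm{hom}}$, the difference of the role means. A fully
  degenerated sex-limited copy halves heterogametic depth
  ($\Delta_{\mathrm{cov}} \approx -0.5$) at every mismatch stringency; a
  weakly differentiated region only loses heterogametic coverage when
  mismatching reads are excluded, because reads from the diverged copy
  still align — with mismatches.
* **Heterozygosity.** Reads from a moderately diverged sex-limited copy
  that do align create apparent heterozygous sites in the heterogametic
  sex only. With $h_{w,s}$ the count of heterozygous genotypes in window
  $w$ divided by window length,
  $\Delta_{\mathrm{het}}(w) = \bar h_w^{\mathrm{het}} - \bar
  h_w^{\mathrm{hom}}$ is positive in low-differentiation regions and at
  or below zero where the sex-limited copy is gone (hemizygosity).

The two statistics are deliberately signed as heterogametic minus
homogametic regardless of the XY/ZW system, so one interpretation table
serves both: differentiated sex linkage pushes
$\Delta_{\mathrm{cov}}$ down, low-differentiation sex linkage pushes
$\Delta_{\mathrm{het}}$ up. Axis labels and the table README state the
convention.

Autosomes show neither signal, so the genome-wide distribution of each
statistic is the null against which outliers are called. There is no
formal test: the scan flags report windows outside an empirical 95% band,
exactly as genome scans of this kind are read in practice.

## Stage by stage

1. **Alignment filtering.** Records that are unmapped, secondary,
   supplementary, duplicate-flagged, or below a mapping-quality floor of
   20 are removed in *every* stringency; the stringencies then bound the
   `NM` (edit distance) tag: 0 allowed (`0mm`), ≤ 2 allowed (`2mm`), and
   unbounded (`unfiltered`). The kept-read sets are therefore nested, and
   per-window depths are monotone across settings — a property the tests
   assert exactly. Records lacking `NM` under a bounded setting are
   excluded and counted, with a run-level warning above 1%.
2. **Masking.** A window is masked when any sample's unbounded depth
   exceeds 10× that sample's genome-wide median (collapsed repeats).
   Masked windows are excluded from normalization means, band estimation
   and aggregation, but still written to tables flagged `masked`. The
   factor is exposed (`mask_factor`); 10 is conservative enough that
   Poisson depth noise never triggers it at realistic depths.
3. **Normalization.** Each sample-setting's values are divided by their
   mean over unmasked windows, making the genome-wide mean exactly 1 and
   removing library-size differences. The mean (not the median) is used
   so that the band is centred on the genome-wide mean value; a median
   variant would change the centring of every diff.
4. **Variant filtering and heterozygosity.** Biallelic SNVs with site
   QUAL ≥ 30; genotypes with GQ < 20 or DP < 3 become missing. These are
   conventional hard filters; all three thresholds are config-exposed
   because no single choice suits every caller. The heterozygosity
   denominator is the full window length for every sample, not callable
   sites: callability varies between samples, but using one denominator
   for all samples keeps the between-sex *difference* unbiased, which is
   the quantity the scan uses. A callable-site correction is listed as
   future work.
5. **Aggregation.** Unit windows (default 5 kb, the scan resolution) are
   averaged into report windows (default 1 Mb) by midpoint membership;
   report windows with fewer than 5 contributing unmasked unit windows
   are set missing, which suppresses noise where liftover anchoring is
   sparse. Trailing unit windows shorter than half the unit size are
   length-normalized but excluded like masked windows, avoiding
   edge-noise in the band.
6. **Band and outliers.** The 95% band per metric is the empirical
   2.5th/97.5th percentile of the report-window diffs. A mean ± 1.96 SD
   variant is available (`band_method = "meansd"`). The quantile form is
   the default because the band is used as a genome-scan outlier
   threshold: a standard-error-of-the-mean band would shrink with window
   count and flag nearly everything. A consequence worth knowing: the
   band flags ~5% of windows *by construction*, and a sex-linked region
   larger than ~2.5% of the genome absorbs the lower percentile itself,
   reducing sensitivity — at that size the per-scaffold and per-sex
   plots, not the outlier table, carry the signal. The band needs at
   least 20 non-missing report windows, else it is omitted with a
   warning.
7. **Liftover (optional).** Whole-genome-alignment blocks (7-column TSV,
   or PSL expanded block-by-block; gapped alignments are split, never
   interpolated) are interval-indexed per query scaffold. A unit window
   anchors when blocks pointing to its majority target scaffold cover at
   least half of it (`anchor_min_overlap = 0.5`); its midpoint projects
   linearly through the best-overlapping block (reversed on `-` strand;
   ties broken by larger block, then lexicographic target name, for
   determinism). Anchored windows re-bin on the target assembly;
   unanchored windows stay in the study-species outputs only. The
   anchoring criterion is a design choice — the anchoring *rule* of the
   original tooling is not published — validated by the property that an
   identity map reproduces the study-coordinate branch byte-for-byte.
8. **Consensus genome (optional).** For the one-sample-per-sex case with
   a reference built from one of the samples, kept variants can be
   written back majority-allele-wise (alternate count > reference count
   across all genotypes; ties keep the reference). Majority, not IUPAC,
   so downstream aligners and the coverage branch stay unambiguous.
   Scaffold names and lengths are preserved; an empty variant set
   reproduces the input byte-for-byte.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `unit_window` | 5000 | bp | scan resolution; small enough to localize PAR boundaries, large enough for stable depth |
| `report_windows` | 1e6 | bp | aggregation scale for plots/outliers; must be a multiple ≥ 2 of the unit window |
| `mismatch_settings` | 0 / ≤2 / unbounded | edit distance | the three canonical stringencies; extra thresholds accepted since the optimal one varies by species |
| `mapq_floor` | 20 | MAPQ | excludes multi-mappers that would flatten the X/Z coverage signal; applied in all settings (the unbounded setting is unbounded in *mismatches* only) |
| `mask_factor` | 10 | × median | collapsed-repeat guard |
| `qual_min`/`gq_min`/`dp_min` | 30/20/3 | phred/phred/reads | conventional VCF hard filters |
| `band_method` | quantile | — | see stage 6 |
| `min_windows_per_bin` | 5 | windows | report-window missingness rule |
| `anchor_min_overlap` | 0.5 | fraction | anchoring rule |

## What the simulator emulates — and what it does not

The bundled generator writes already-aligned records with synthetic `NM`
tags directly (plus ~1% duplicate-flagged and MAPQ-0 records so the
filter gates are exercised), rather than running an aligner. This removes
every external-tool dependency while driving the exact code paths; it
also means the simulation does *not* model alignment artefacts
(mapping-position errors, soft-clip structure), sequencing error beyond
the `NM` burden, indels, GC bias, or structural variants other than the
modelled degeneration. Passing tests therefore demonstrate the
statistical machinery and its calibration, not robustness to every
real-data artefact.

Region classes map to the canonical differentiation scenarios:
heterogametic samples receive, per region, an X/Z-derived half at
background `NM`, plus a sex-limited half that is present at
$(1-\mathrm{degeneration})$ of its share with `NM` centred on
$\mathrm{divergence} \times \mathrm{read\ length}/100$ (`high_diff`), or
present in full with `NM` in 2–4 so it survives unbounded but fails
strict filtering (`low_diff`). Variants arise as shared candidate sites
at twice the background rate (each sample heterozygous with probability
one half, so per-sample heterozygosity equals the advertised rate), with
region-specific excess heterozygosity for the heterogametic sex and
hemizygous collapse (hom-ref) in fully degenerated regions. A small
junk-record stream (low QUAL, indels, multiallelics, low-GQ genotypes)
rides on top without biasing the advertised rates. All randomness flows
from one seed; per-sample substreams are derived by a stable string hash
of the sample id, so adding a sample never reshuffles another's reads.

**Problem sizes.** The presets are desk-scale by design: 5 Mb genomes
over 5–6 scaffolds, read length 100, depth 10, one sample per sex, and a
50 kb report window standing in for the 1 Mb window used on full-size
genomes (the 200:1 unit-to-report ratio is not preserved; what matters
for the band is the report-window count, ≥ 100 here). The fully
degenerated preset's sex-linked region is 100 kb — 2% of the genome —
deliberately below the ~2.5% ceiling discussed in stage 6 so the
quantile band can flag essentially all truly sex-linked windows. These
scales keep a full simulate-plus-scan cycle under half a minute on one
CPU without changing any statistical property being checked.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; VCF input (1-based) is
  converted on read; all output tables print 1-based inclusive
  coordinates, stated in the table README.
* Normalization means are exact (machine epsilon), asserted at 1e-9.
* Quantiles use R's default type-7 interpolation.
* SD over a single report window is reported as 0 with `n = 1` rather
  than NA, so plot error bars degrade gracefully.
* Degenerate inputs fail loudly: an empty genome index, a sample sheet
  missing a role, a sample absent from the VCF header, a REF allele
  disagreeing with the FASTA (coordinate mismatch), all windows masked,
  or a zero-coverage sample are hard errors naming the offender.
* Caching is keyed by content digests of stage inputs, never timestamps,
  so identical inputs re-use results and `render` mode can never produce
  tables inconsistent with plots.

## Known limitations

* Ploidy-aware genotyping of the sex chromosomes themselves is out of
  scope; hemizygous regions are read through their coverage/het
  signatures, not through genotype models.
* Heterozygosity uses a fixed-length denominator (stage 4).
* The outlier logic is descriptive (the 95% band), with no
  multiple-testing control; very small fully sex-linked regions (below
  the report-window scale) will not stand out.
* Genome-wide heterozygosity at or above 1% is flagged in the log and
  report, as the sex-linked signature may drown in background
  heterozygosity at that level.
* An autosomal inversion segregating with sex morphs produces the same
  signature as a sex chromosome; independent validation of candidate
  regions is advised.
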