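---
title: "Calling recurrent differential methylation and integrating it with expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling recurrent differential methylation and integrating it with expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrpipe)
```

## The analysis model

`dmrpipe` implements a tumor-versus-control-panel differential methylation
analysis for WGBS-style per-CpG count data, together with the downstream
steps that turn per-tumor calls into cross-tumor biology: genomic-element
annotation, recurrence signatures, a simplified differential expression test,
and promoter-methylation x expression integration.

The core procedure, per tumor:

1. **Coverage filter.** Only CpGs sequenced to at least `min_depth` reads
   (default 5x, inclusive) enter the analysis.
2. **Control profile.** The control panel is reduced to the CpGs covered in
   *all* controls; at each site the unweighted mean methylation fraction is
   the reference. The per-control fractions are retained because the region
   test needs them.
3. **DMCs.** A differentially methylated cytosine is a shared CpG whose
   tumor-minus-control-mean change is at least `dmc_min_delta` percentage
   points in absolute value (default 10, inclusive); the sign gives the
   direction (hypo/hyper).
4. **Segmentation.** Maximal runs of same-direction DMCs with consecutive
   gaps of at most `dmr_max_gap` bp (default 100) and at least `dmr_min_cpgs`
   members (default 3) become candidate regions; a direction flip, a larger
   gap, or a chromosome change terminates a run. The region spans the first
   to the last member CpG (0-based, half-open, end = last CpG + 1 — the
   extent is otherwise under-determined).
5. **Region test.** A two-sided Mann-Whitney U test compares the tumor's
   per-CpG fractions over the region (one value per member CpG) against the
   pooled controls' per-CpG fractions (one value per control per CpG).
   Candidates with p below `alpha` (default 0.05) are reported, raw by
   default; a Benjamini-Hochberg option exists but is off for fidelity to
   the raw-p convention of this analysis style.

The rank test is exact (dynamic-programming enumeration of the U null
distribution, two-sided by doubling the smaller tail, capped at 1) when both
groups have at most 8 tie-free observations; otherwise a mid-rank normal
approximation with tie-corrected variance and continuity correction is used.
The exact path refuses ties and falls back to the approximation.

**Why one tumor versus pooled controls, per region?** A single tumor value
against five control values can never reach p < 0.05 per CpG (the smallest
exact two-sided p of a 1-vs-5 rank test is 1/3), so a per-DMC significance
reading is unattainable; the region-level reading — the only construction
under which the published thresholds are jointly satisfiable — is adopted and
flagged here.

**Gap boundary.** Two statements of the gap rule circulate for this analysis
style: "at most 100 bp" and "strictly under 100 bp". This package uses the
inclusive rule (a gap of exactly 100 bp keeps a run alive) and exposes
`dmr_max_gap` so the strict reading is one configuration away.

## Downstream stages

* **Annotation.** Regions are matched against promoter / enhancer / exon /
  intron / repeat intervals with 1-bp minimum overlap, half-open arithmetic
  (abutting intervals do not overlap). A region counts toward *every*
  category it touches, once per category — matching per-element bar charts
  computed independently per feature class. An exclusive priority scheme
  (promoter > exon > intron > enhancer > repeat > unannotated) is provided
  for composition/donut-style summaries where shares must sum to 1.
* **Recurrence.** Tumors never share exact DMR boundaries, so the
  cross-tumor "core" signature is defined at base-pair resolution: a core
  region is a maximal interval where same-direction DMR coverage depth
  reaches `n_required` tumors (default: all of them). This is the natural
  merge-by-depth formalization when "the same DMR in two tumors" is otherwise
  undefined; reciprocal-overlap matching is deliberately out of scope.
* **Differential expression.** A defined, simplified stand-in for a full NB
  GLM suited to the 1-tumor-vs-panel design: median-of-ratios size factors
  (controls as reference), per-gene control means, a genome-wide
  mean-dispersion trend `alpha(mu) = a0 + a1/mu` fitted through binned
  medians of method-of-moments dispersions (raw per-gene values with 4
  controls are far too noisy to use directly), and a doubled NB tail
  probability for the normalized tumor count. Fold changes are ratios of
  FPKM means with a pseudo-FPKM (default 0.1) stabilizing zeros;
  significance requires both the fold-change threshold (default 1.5, either
  direction) and p < alpha. Because this is not the shrinkage-based
  reference implementation of NB differential expression, gene lists will
  differ from that tool's in borderline cases — by design, and documented.
* **Integration.** Per gene and direction, the number of tumors with at
  least one promoter-overlapping DMR is tabulated (a tumor contributes at
  most 1 per direction). The hypo-up list requires a hypomethylated promoter
  DMR in at least `integration_min_tumors` tumors (default 6 of 7) and
  expression up (FC >= 2, p < alpha) in at least a majority-plus-one of the
  expression tumors (6 of 10 by default); hyper-down mirrors it. The
  expression fold threshold is 2 by default (the figure-legend convention);
  the alternative 1.5 reading is one configuration away, and the
  tumor quorum on the expression side is exposed because no printed value
  pins it down.

## The simulated world

The simulator is first-class, tested code: it generates the world the
analysis assumes, plus a machine-readable truth table for recovery scoring.

* **Genome.** CpG sites with geometric spacing (mean 60 bp, minimum 2);
  genes in evenly sized slots with random strand and exon/intron structure;
  promoters are strand-oriented −1,500/+500 bp windows around the TSS;
  enhancers sit between gene slots and repeats avoid promoter windows.
* **Methylation.** Latent fractions come from a three-compartment mixture
  assigned in *blocks* of consecutive CpGs (mean ~20 sites), reflecting
  regional methylation coherence: high (Beta around 0.85, 70% of sites), low
  (around 0.08, 20%), intermediate (block mean uniform in 0.25–0.75, 10%).
  Promoter CpGs follow their gene's promoter state instead (12% low, 15%
  intermediate, the rest high). This composition was chosen once so that
  (a) most CpGs are methylated above 75%, as in normal T-cell methylomes,
  and (b) control replicates meet the stated near-identity contract —
  pairwise per-CpG Pearson r >= 0.95 at 30x — with margin (measured
  0.957–0.960 across seeds). Blocks (rather than i.i.d. site draws) are also
  what makes hypermethylatable low-methylation runs exist reliably.
* **Counts.** Depth is Poisson(30) truncated at 1 (every simulated site is
  observed, so the 5x filter is exercised); methylated counts are binomial
  around the latent fraction. Controls share latents up to a 0.01-sd
  perturbation; tumors get independent 0.02-sd baseline noise (heterogeneity,
  not copies of controls) and carrier tumors are shifted by ±effect inside
  planted regions, clamped to [0.001, 0.999]. Neither noise value is a claim
  about tumor biology; both are exposed in the configuration.
* **Planted truth.** Default 16 hypo + 8 hyper regions (hypo-skewed, as in
  the tumors this emulates), width 6 CpGs, effect 0.4, placed on runs with
  gaps under 100 bp so that recovery failures indict the caller, not the
  placement. Hypo regions require highly methylated runs (no clamping), hyper
  regions lowly methylated ones. Carrier schedules default to a deterministic
  mix of all-tumors / all-but-one / small random subsets; the first coupled
  hypo gene always gets the "6 of 7 methylation carriers, 9 of 10 expression
  carriers" configuration so the flagship integration case exists in every
  default run.
* **Expression.** Baseline mean FPKM follows the inverse coupling
  `0.5 * 2^(6 * (1 − promoter methylation))` with lognormal gene noise
  (sd 0.5); expected counts scale with summed-exon length and a
  ~20-million-read library (matching the sequencing depths this emulates —
  at 10x shallower libraries, silenced genes would sit at 1–3 reads and a
  10-fold change would be undetectable by any test); counts are negative
  binomial with dispersion 0.2. Coupled genes are multiplied (hypo) or
  divided (hyper) by a 10-fold change in carrier tumors.

### What the simulator does not emulate

Read-level artifacts (bisulfite conversion errors, mapping bias), CpH
methylation, copy-number effects, and long-range coverage waves are absent.
A green recovery test therefore establishes that the caller implements its
rules correctly on idealized count data — not that those rules are optimal
on real bisulfite libraries.

### Known behavior of the select-then-test design, honestly measured

At 30x, a 10-percentage-point DMC threshold is only ~1.4 binomial standard
deviations, so even a tumor statistically exchangeable with the controls
yields ~15% DMCs and a steady supply of 3-CpG same-direction runs. Because
those candidates are selected for extremeness against the very control panel
the region MWU then compares them to, the conditional rejection rate of the
region test is ~0.5–0.6 — not alpha. Consequences, measured at fixed seeds
and reported in the acceptance suite rather than hidden:

* the null false-region rate is ~8x `alpha x candidates`, so the
  "within 2x nominal" calibration criterion is red;
* planted-region recovery at effect 0.3 / width 5 achieves recall 0.993 but
  precision 0.895–0.898 against a 0.9 bound (the false calls are 3-CpG noise
  runs; the pooled measurement straddles the bound within its own Poisson
  uncertainty).

These are properties of the published rule set itself (threshold
segmentation followed by a rank test on the selected region), not of this
implementation; the optional BH-FDR flag mitigates but is off by default for
fidelity. Both measurements are re-run, not asserted, by
`scripts/acceptance.R` and `tests/testthat/test-acceptance.R`.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; coverage-file
  columns are converted from the 1-based inclusive dialect on read and back
  on write. Chromosome names are taken verbatim.
* Readers reject inconsistent rows (count/percent disagreement beyond 0.5
  points, malformed lines, duplicate positions) with line numbers; they never
  silently repair.
* Methylation bins: the first bin is closed (`[0,25]`), later bins half-open
  (`(25,50]` ...), so 0 and 100 are both housed and totals are conserved;
  integer-labeled bin names do not define real boundaries, so this choice is
  explicit and configurable.
* Promoter means are unweighted by coverage (the averaging convention is
  "percentages were averaged", taken literally); genes with no covered
  promoter CpG are flagged missing and excluded from bin counts.
* Welch's t-test is used for the methylation-expression strata ("Student"
  without a variance statement; unequal variances are the safe default).
  Strata with fewer than 2 genes are flagged and skipped.
* Zero-variance columns yield `NA` (undefined) correlations, never 0.
* `alpha = 0` produces empty DMR sets (p-values are strictly positive on
  both test paths).

## Limitations

* The region test's anti-conservatism under selection (above) is inherited
  from the published procedure; users wanting calibrated discovery should
  enable the FDR flag or raise `dmr_min_cpgs`.
* The NB exceedance test has no dispersion shrinkage and a plug-in trend;
  its null rate is within 2x nominal in the tested worlds but it is not a
  replacement for a full NB GLM when replicated tumors are available.
* Recurrence-by-depth can fragment a biological region into several core
  intervals when tumor boundaries are ragged; counts of core regions are
  therefore convention-dependent (covered bases are the stable quantity, and
  the monotonicity tests use them).
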