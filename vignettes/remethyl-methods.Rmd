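---
title: "Modelling methylation loss and recovery after transient DNMT1 suppression"
author: "remethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling methylation loss and recovery after transient DNMT1 suppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remethyl)
```

## The biological problem

Genome-wide DNA methylation is propagated through cell division by the
maintenance methyltransferase DNMT1, which copies methylation from the
parental to the daughter strand at replication, assisted by the de novo
methyltransferases DNMT3a/3b. Imprinted germline differentially
methylated domains (gDMDs) are special: one parental allele is fully
methylated, the other fully unmethylated, and the unmethylated allele is
*immune* to de novo remethylation. If DNMT1 is removed transiently,
methylation is passively diluted by replication; when DNMT1 returns,
most of the genome is remethylated by the combined maintenance/de novo
machinery — but sequences whose methylation depends *solely* on
continuous maintenance (imprinted gDMDs, and a class of "gDMD-like"
single-copy loci) never recover. `remethyl` simulates this experiment
at RRBS (reduced representation bisulfite sequencing) resolution and
reimplements the downstream tile-based analysis: differential
methylation, trajectory classification, candidate discovery and
genomic-context statistics.

## The inheritance model

Per CpG region, methylation is a fraction $m \in [0,1]$ updated once
per cell division by a strand-averaged semiconservative recurrence
(`step_methylation()`):

$$ m' = \tfrac{1}{2}\left[\, m + m\{\rho + (1-\rho)\delta\} +
   (1-m)\,\delta\, I \,\right] $$

* $\rho$ — maintenance efficiency: the probability that the daughter
  site of a methylated dyad is methylated at replication (0 while
  DNMT1 is absent, `rho_on` during recovery);
* $\delta$ — de novo methylation probability per division;
* $I$ — the *de novo gate*: 1 only while the current regional
  methylation is at least $\theta$, making fully unmethylated regions
  immune to remethylation.

This is the simplest form with the three required behaviours: pure
passive dilution ($\rho=\delta=0$ halves $m$ each division), a stable
retention plateau with maintenance off (for $\rho=0$, gate open:
$m_t = \delta + (m_0-\delta)2^{-t}$, so retention at the end of
suppression approaches $\delta$), and a fixed point at full
methylation under perfect maintenance. The model gives no equation
special status to hemimethylation: both strands are averaged, which is
also how RRBS reports methylation.

An important *emergent* property is gate hysteresis: a locus whose
off-phase trajectory falls below $\theta$ before reaching its plateau
loses de novo activity permanently, and with maintenance restored it
is locked near zero. With the defaults ($\theta=0.05$) this is exactly
what happens to the gDMD-like class ($\delta = 0.02$): its nominal de
novo rate would permit slow remethylation, but the gate closes during
suppression, so no recovery occurs — the defining gDMD-like phenotype.

### Timeline

The timeline maps sampled timepoints (control, d0 = end of
suppression, d3…d21 of recovery) to division counts. DNMT1 protein is
gone after about 3 of 6 treatment days and ES cells divide roughly
twice a day, so the default suppression phase is 8 maintenance-off
divisions (dilution to $2^{-8}$) and recovery adds 2 divisions per
day. Division counts are not measured quantities; both are exposed in
`timeline()`.

### Class parameters

`default_dynamics_params()` gives each sequence class its own
$(m_0, \rho_{on}, \delta, \theta)$:

```{r}
default_dynamics_params()[, 1:7]
```

Rationale, class by class:

* **IMPRINTED_GDMD** — two alleles ($m_0$ = 1 and 0), $\delta = 0$ on
  both: read-level methylation starts at 50%, dilutes to ~0 at d0, and
  the immunity of the unmethylated state plus the gate keep it there.
* **GDMD_LIKE** — highly methylated, tiny $\delta$; gate hysteresis
  (above) prevents recovery.
* **RE_SINE / RE_IAP / RE_SATELLITE** — $\delta$ in 0.25–0.33 puts the
  d0 retention plateau in the observed 22–35% band, and the same de
  novo activity restores the original level during recovery.
* **RE_LINE** — LINE-1-like repeats lose almost all methylation at d0
  but are efficiently remethylated afterwards; that needs a small
  off-phase $\delta$ with strong recovery-phase de novo targeting, so
  this class (alone among defaults, with the hyper-prone loci) uses a
  distinct `delta_recovery`, and $\theta = 0$ because repeat de novo
  targeting is sequence/chromatin driven rather than dependent on
  pre-existing methylation.
* **GENIC_BODY / INTERGENIC** — intermediate retention at d0 and full
  recovery; these form the stable background against which the
  gDMD-like signal is detected.
* **CGI_PROMOTER_UNMETH** — $m_0 = 0$, $\delta = 0$: unmethylated CpG
  island promoters stay unmethylated throughout, keeping the TSS
  metaprofile dip.
* A small **hyper-prone** subclass (`hyper_prone_params()`: a few
  low-methylation intergenic loci with recovery-only elevated
  $\delta$) exercises the hypermethylation branch of the pipeline.
  The phenomenon of methylation gain after transient maintenance loss
  has no established mechanism; this subclass is a modelling
  placeholder, not a claim.

## The synthetic genome and count noise

`build_genome()` lays non-overlapping loci of the nine classes on
abstract chromosomes (2 × 5 Mb by default, ~4,000 loci, ~37,000 CpGs
— small enough to simulate in seconds, large enough for stable
fractions) with a 200 bp minimum inter-locus gap so annotation windows
rarely bleed across unrelated loci. No nucleotide sequence is
generated: nothing downstream of methylation calling needs it. CpGs
are placed in RRBS-like clusters of ~4 per 100 bp patch (~7 in
CGI-like loci), matching the typical 3.5 CpGs per non-CGI tile and 7
per CGI tile of real RRBS data; this matters because the 20×-per-tile
filter acts on the tile mean coverage. Promoter-centred classes carry
a single-exon gene anchored at the locus midpoint; gene bodies carry a
5'UTR/exon/intron/3'UTR model, strand-flipped for minus-strand genes.

`simulate_experiment()` draws, per CpG and sample, a read coverage
from a negative binomial (mean 30, size 5 — most tiles clear the 20×
filter, some fail, so the filter is genuinely exercised) and a
methylated count from a binomial around the class trajectory. Site
heterogeneity is a mean-preserving Beta draw (SD 0.05 at $m=0.5$)
rather than clamped Gaussian noise, because clamping would bias pooled
means near 0 and 1 and break the unbiasedness that the
simulation/closed-form agreement checks rely on. Features of real
RRBS data deliberately *not* modelled: bisulfite conversion failure,
strand- and fragment-level correlation, PCR duplicates, CpG-density
dependent coverage bias, hemimethylation, hydroxymethylation. Passing
tests therefore validate the analysis logic, not robustness to those
artefacts.

## Parameter estimation

`fit_dynamics()` recovers $(m_0, \delta, \rho)$ from a pooled
trajectory by least squares, treating the suppression phase as
$\rho = 0$ (that is the experimental manipulation, not an estimate)
and the gate as open — appropriate for loci staying above $\theta$.
Because the off-phase has the closed form above, $\delta$ inverts
exactly from the control and d0 values; $\rho$ is then solved on the
recovery points by 1-D minimisation, and a box-constrained
quasi-Newton pass polishes the triple jointly from several starts.
On noise-free model output the generating parameters are recovered to
$10^{-6}$; on default-noise simulations of ~5,000 CpGs, $\delta$ and
$\rho$ come back within a few $10^{-3}$. A constant-zero trajectory
is degenerate: $\delta = 0$ is reported and $\rho$ flagged
unidentifiable. The fit returns a classed object with the usual
`coef`/`predict`/`residuals`/`plot`/`simulate` methods:

```{r}
tl <- timeline()
obs <- expected_trajectory(list(m0 = 0.9, rho_on = 0.9, delta = 0.3,
                                delta_recovery = 0.3, theta = 0,
                                alleles = 1L), tl)
fit <- fit_dynamics(obs, tl)
summary(fit)
```

## Tiling and filters

Tiles are non-overlapping 100 bp windows aligned to the genome grid
("step-wise" tiling with step = width; overlapping windows would
double-count CpGs). Tile methylation is the **unweighted** mean of the
per-CpG methylated fractions — not coverage-weighted — and a tile is
kept only if *every* sample gives it ≥ 1 covered CpG and ≥ 20× mean
CpG coverage. Whether the original filter meant the tile-mean or every
single CpG is ambiguous; both are implemented
(`cov_mode = "mean"`/`"each"`, default mean). Minus-strand calls are
collapsed onto the plus-strand C before tiling (standard symmetric-CpG
treatment). Group (timepoint) methylation is the arithmetic mean of
replicate values.

## Differential calls, retention, trajectories

Two significance recipes are provided, mirroring the two used in the
original analysis:

* `test_tile_ttest()` — Welch t test on replicate values, significant
  at $p < 0.05$;
* `test_tile_counts()` — Fisher's exact test on replicate-pooled
  methylated/unmethylated counts with Benjamini–Hochberg correction at
  $q < 0.01$. The exact test replaces the logistic regression of
  MethylKit; in the two-group, no-covariate case they test the same
  null, and exactness removes small-count approximation worries.

In **both** recipes a call additionally requires an absolute
group-mean difference of ≥ 20 percentage points — the effect-size gate
is mandatory, so a tiny p-value with an 19-point difference stays
"stable". Methylation states partition [0,1] into low (< 20%),
intermediate (20–80%, boundaries inclusive so the partition is exact)
and high (> 80%). Retention analysis at d0 uses the two-stage rule:
absolute loss ≥ 20 points, then the *fraction of original methylation
retained* ($m_{d0}/m_{control}$ > 20% / > 40%); the absolute reading
(40–74% methylation retained) is reported alongside, since both
readings appear in the source analyses.

Trajectory classification re-expresses the four RLGS spot patterns as
threshold rules on (control, d0, d21) tile fractions, with `low` =
0.20 (the < 20% convention), `partial_hi` = 0.75 (the "between 20% and
75%" pattern-2 definition) and `recover_tol` = 0.20 (the ± 20-point
significance convention; RLGS itself states no numeric recovery
tolerance, so it is exposed in the configuration). One deliberate
ordering choice: the HYPER rule ($m_{d21} \ge m_{control} + 0.20$) is
tested *before* the stability rule, because a locus that starts low
and gains methylation satisfies the no-loss condition trivially and
would otherwise be absorbed into STABLE. Loci losing ≥ 20 points at d0
from a control level above 75% that then recover fall into no pattern
and are labelled UNCLASSIFIED — the pattern definitions genuinely do
not partition that corner. Candidate genes are ranked by the per-gene
mean of per-tile percentage loss at d21 (the "average of methylation
averages" convention), binned with a top bin of [85,100]% loss.
Hypomethylated tiles are merged into consecutive regions when
separated by at most 500 bp (inclusive).

## Annotation

Each tile gets exactly one feature by an any-overlap priority scheme —
promoter-TSS > TTS > 5UTR > 3UTR > exon > intron > noncoding >
intergenic — with promoter/TTS windows of TSS/TTS ± 1 kb (common
annotation defaults; the original tool's windows are not stated, so
they are configurable). Ties within a class break by longest overlap,
then by distance to the anchoring TSS/TTS, which resolves the case of
a tile inside two overlapping promoter windows in favour of the
nearest gene. CGI membership is any overlap ≥ 1 bp. Repeat context
reports the overlapping class (longest overlap on ties), the bp
distance to the nearest repeat (0 iff overlapping) and a ≤ 1 kb
proximity flag. Composition shifts are tested by Pearson chi-square
without continuity correction (empty classes dropped with a warning);
per-feature methylation shifts by a two-sided Wilcoxon rank-sum test,
exact when both groups have ≤ 10 untied values. The chi-square on
proportions is also used where the original enrichment method is
unnamed.

## Reporting conventions

Fractions are used internally everywhere; percentages appear only in
reports. Printed percentages are rounded half away from zero
(`pct()`), the rule consistent with every verifiable printed ratio
(68%, 26%, 74%, 37.3%); each (count, total, percentage) triple in the
summary report is re-derived and checked at build time. The pipeline
(`run_pipeline()`) is deterministic given the configuration seed, and
its log records in/out counts for every filter.

## Problem sizes and known limitations

The default genome (2 × 5 Mb, ~4,000 loci, ~37,000 CpGs, 10 samples)
runs the full pipeline in well under a minute; the
simulation-agreement and parameter-recovery analyses use 5,000–10,000
CpGs. These sizes were chosen as the smallest giving stable class
fractions and tight pooled standard errors. Headline tile counts from
the real experiment (~150,000 changed tiles, 7,423 intermediate,
9,884 reduced, and the RLGS pattern counts) scale with the real
mouse genome and library depth and are not reproduced at these sizes;
the package reproduces the *rules*, *ratios* and *qualitative
dynamics*, which is what the test suite asserts. Other limitations:
no covariate adjustment or overdispersion correction in the
differential tests, no allele-resolved calling, no motif or
pathway analysis, and the hyper-prone mechanism is a placeholder.
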