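---
title: "Methods: quantifying chemically induced demethylation from WGBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying chemically induced demethylation from WGBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylDose)
```

# The problem

Cytosine analogs such as 5-azacytidine (AZA) and zebularine (ZEB) cannot be
methylated once incorporated into replicating DNA, so seedlings grown on
increasing concentrations lose methylation passively and, in plants,
largely indiscriminately across the CG, CHG and CHH sequence contexts.
Quantifying that loss from whole-genome bisulfite sequencing raises a set
of small statistical questions — how to summarize methylation over a
region, how to compare a treated sample to its control, how to decide
whether a gene is methylated at all — and this vignette documents how
`methylDose` answers each of them, which choices are forced by the data and
which are genuinely open, and what the bundled synthetic generator does and
does not emulate.

# Weighted methylation and its degenerate cases

Every regional statistic is the weighted methylation level
$m_w = \sum_i mc_i \big/ \sum_i t_i$ over covered cytosines
($t_i > 0$) of one context, i.e. reads are pooled before dividing. This
estimator weights each site by its coverage and is robust to shallow sites,
unlike the mean of per-site levels.

Degenerate inputs follow two rules throughout the package:

* Sites with `total_count == 0` are excluded from every statistic. No
  further minimum-coverage filter is applied by default (covered means
  one read or more), though callers can pre-filter.
* An empty denominator — a window with no covered sites, a treated/control
  ratio whose control level is 0 or undefined — propagates as `NA`, never
  as 0 or infinity. `NA` ("no evidence") and 0 ("evidence of none") are
  deliberately distinct.

"Completely methylated" means `mc_count == total_count` exactly (per-site
level 1.0); the fraction of methylated sites that are completely methylated
is the headline summary of the per-site level distribution, because
treatment shifts mass away from 1.0 even where the regional mean moves
modestly.

# Windows, profiles and the pericentromere

Chromosomes are tiled into half-open windows $[0,w), [w,2w), \dots$ with
the final partial window retained, so window widths always sum to the
chromosome length. A site belongs to the window containing `pos - 1`
(coordinates are 0-based half-open everywhere inside the package;
conversion to and from GFF3's 1-based inclusive convention happens only at
I/O boundaries). Chromosome-scale views use 50 kb windows; the pairwise
treated-versus-control comparison of highly methylated windows uses 100 bp
windows, retaining windows whose **control** level is defined and at least
a threshold — 0.5 for CG and 0.3 for CHH by default. (Narrative
descriptions of such analyses sometimes quote >25 % for CHH; both are
exposed through `min_control_level`, and 0.30 is the default.)

A window is assigned to the pericentromere if and only if its midpoint
falls inside the user-supplied pericentromere interval; midpoint assignment
makes the partition total and unambiguous for boundary-straddling windows.
Pericentromere intervals are an input (e.g. a 7.5 Mb block on chromosome
1 of *A. thaliana*); the package does not infer them.

Both an untreated control and a solvent (DMSO) mock control are ordinary
samples: every relative statistic takes an explicit control argument
rather than assuming which control is meant.

# Gene methylation classification

A cytosine is *called* methylated when its methylated read count is
inconsistent with the error floor: call = 1 iff the one-sided binomial
tail $P(X \ge mc \mid n = t, p = \epsilon) \le \alpha$, with defaults
$\epsilon = 0.005$ (a typical bisulfite non-conversion magnitude) and
$\alpha = 0.01$. Calls may also be taken as given from the input table;
both routes are supported because production pipelines usually inherit
calls from the upstream caller.

Per gene and context, the classification counts covered coding-sequence
sites $n$ and called sites $k$ and computes the one-sided enrichment
p-value $P(X \ge k \mid n, \pi_{ctx})$ against the background rate
$\pi_{ctx}$ — the called fraction over the coding sequences of all genes
(configurable to genome-wide; the background scope is a documented
parameter, not a claim). p-values are Benjamini–Hochberg adjusted within
each context across genes, and a context is enriched at $q \le 0.05$ by
default. Class precedence is total and deterministic: CHH-enriched ⇒
`mCHH` (these genes typically carry mCG and mCHG as well), else
CHG-enriched ⇒ `mCHG` (may carry mCG), else CG-enriched ⇒ `gbM`, else
`unmethylated`. A gene with no covered sites in some context is treated as
not enriched there and flagged. Coding-sequence intervals default to the
annotated gene body; if CDS sub-features are available the caller can pass
them as the gene intervals directly.

# Metagene profiles

Each feature's body is divided into 20 proportional bins and each 1500 bp
flank into 15 fixed 100 bp bins (bin counts are conventions, not
measurements; the flank span is the meaningful parameter). Minus-strand
features are mirrored so bin 1 is always the outermost 5′ bin. Within a
feature, reads are pooled per bin; across features, the profile takes the
**unweighted mean of per-feature levels** over features with a defined
value. Averaging per feature rather than pooling reads across features is
the genuinely open choice here; it was taken to match common metagene
practice and to stop long or deeply covered genes dominating the profile.
Bin membership is computed with exact integer floor division
(`(offset * bins) %/% span`), so sites on rational bin seams are assigned
deterministically with no floating-point dependence. Flank bins are not
masked for overlap with neighboring genes. Features shorter than the body
bin count are skipped with a message.

# Dose–response and expression

The dose–response fit is ordinary least squares of the weighted level on
concentration, one genome-wide (or per-context) point per concentration —
the designed n is 4 (0, 25, 50, 100 µM), so the slope p-value is reported
but low-powered, and $r^2$ is the quantity of interest. A flat response
reports $r^2 = 0$ (not `NaN`).

Differential expression applies the strict filter: a pseudocount of 0.1 is
added to both FPKM values before the fold change, and a gene is
upregulated iff $q < 0.05$ **and** $\log_2\!\mathrm{FC} > 2.0$ — both
inequalities strict, so a fold change of exactly 2.0 is excluded.
Enrichment of a category among upregulated genes uses the two-sided
Fisher's exact test on the 2×2 table of category membership
(category vs the rest of its background) against upregulation status;
methylation classes are tested against all classified protein-coding genes
and TE families against all TE genes. Composition summaries include an
explicit `other/unclassified` bucket so percentages always refer to a
complete partition of the background.

# The synthetic generator

The generator exists so that every downstream statistic can be checked
against planted truth. It emulates:

* **Geometry** — chromosomes with an optional pericentromeric interval;
  genes placed without same-strand overlap (protein-coding classes on the
  arms, TE genes preferentially in the pericentromere).
* **Site placement** — unique cytosine positions drawn uniformly at
  per-context densities of 30 (CG), 25 (CHG) and 120 (CHH) sites per kb,
  with consistent trinucleotides; no genome FASTA is needed.
* **Baseline methylation** — per-read probabilities by compartment and
  class: gbM genes 0.85/0.02/0.02 (CG/CHG/CHH), mCHH genes 0.8/0.5/0.3,
  pericentromeric intergenic 0.9/0.7/0.25, arm intergenic 0.05/0.02/0.02.
  mCHG genes, for which no convention was dictated, use 0.80/0.50/0.02 —
  mCHG genes commonly carry mCG alongside mCHG but lack CHH methylation,
  which is what distinguishes them from mCHH genes. TE genes use the
  pericentromeric heterochromatin profile (0.9/0.7/0.25).
* **Treatment** — a per-context demethylation fraction $d$ per
  concentration ($d(0) = 0$, non-decreasing in dose); a site with baseline
  $p$ is sequenced at $p(1-d)$.
* **Sequencing** — coverage Poisson with mean 25 (within the 23–28×
  range typical of deeply sequenced WGBS), methylated reads binomial;
  uncovered sites are written with zero counts and excluded by consumers.
  One deeply sequenced replicate per condition, matching the paired
  design the analysis assumes.
* **Expression** — a differential-expression caller's *output* is
  simulated, not its input: planted upregulated genes get a pseudocounted
  log2 fold change uniform in (2.2, 5) with $q < 0.05$; all other genes
  get $|\mathrm{log_2FC}| \le 1.5$. The planted truth is therefore exactly
  recoverable by the strict filter, which is the property the enrichment
  tests need.

Everything is deterministic given its seed (site placement from the genome
spec's seed, read sampling and expression from per-call seeds), to the
point of byte-identical output files; a treated sample with $d \equiv 0$
is byte-identical to its control under the same seed.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: linkage between neighboring sites (sites are
independent), bisulfite conversion failure and mapping artifacts, CG-pair
strand symmetry, copy-number and repeat-mappability structure, biological
replicate variance, any relationship between a gene's methylation and its
simulated expression, and recovery dynamics over time (the generator
models concentration only, not treatment duration).

# Problem sizes used by the test suite

The suite validates parameter recovery on 1 Mb single-chromosome genomes
(~175,000 sites) across 5 seeds and 4 concentrations with planted
$d = \{0, 0.2, 0.4, 0.6\}$; class recovery on 800 genes (200 per class,
3.5 Mb genome, mean coverage 25, ≥50 covered sites per gene per sparse
context); enrichment detection on 1000 TE genes (100 CACTA at 30 %
planted upregulation vs 5 % elsewhere) with 200 null simulations for
type-I control; and oracle equivalence of weighted methylation, window
profiles, metagene bins, BH adjustment and Fisher p-values against
brute-force reimplementations on 100 randomized instances each. These
sizes give stable recovery (sampling error well inside the tolerances
checked) while keeping the whole suite fast.

# Known limitations

* No DMR calling and no smoothing: the package quantifies planned
  contrasts, it does not discover regions.
* The classification background defaults assume genes collectively are a
  sensible null; on a genome where nearly all genes are methylated in a
  context, enrichment against that background loses meaning (if every
  site is called, $\pi = 1$ and enrichment is impossible by
  construction).
* Fisher's test is conditional on the margins; with very small categories
  the discrete null makes it conservative, which the type-I simulations
  in the test suite reflect.
* The dose–response model is a straight line by design; saturating
  contexts (CHH at high doses) simply yield a lower $r^2$ rather than a
  better-fitting curve.
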