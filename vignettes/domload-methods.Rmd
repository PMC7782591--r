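---
title: "Methods: deleterious-mutation load and domestication sweeps in a selfing crop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deleterious-mutation load and domestication sweeps in a selfing crop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domload)
```

## Scope

`domload` implements the computational chain used to study what happens to
deleterious mutations when a predominantly selfing crop is domesticated:
quality control of a multi-sample variant panel, windowed diversity
statistics, polarization of alleles into ancestral and derived states
against two outgroup genomes, rejected-substitution constraint scoring
from a multi-species alignment, per-accession derived-deleterious burden
with group comparisons, and a cross-population composite-likelihood scan
for domestication-selective sweeps. A synthetic-cohort generator with
known ground truth makes every stage testable without access to a real
resequencing panel. This vignette records the models, the defaults, and
the design decisions that were genuinely open.

## The synthetic cohort generator

`simulate_populations()` draws, per segregating site:

* a wild derived-allele frequency $p_1$ from a neutral-SFS-like prior with
  density proportional to $1/i$ on derived-allele counts
  $i = 1, \dots, 2n_w - 1$;
* a domesticated frequency $p_2$ from the one-step drift kernel
  $\mathcal{N}(p_1,\, \omega\, p_1 (1 - p_1))$ with the out-of-range mass
  absorbed at the 0/1 boundaries — the same kernel the sweep scan assumes
  under neutrality;
* inside planted sweep intervals, a hitchhiking transform
  $q = c\,p_2 + (1 - c)B$ with escape probability
  $c = 1 - e^{-d/\tilde{s}}$ ($d$ the genetic distance to the sweep
  center) and $B \sim \mathrm{Bernoulli}(p_1)$ the allele carried by the
  sweeping haplotype;
* genotypes with the inbreeding-adjusted Hardy–Weinberg probabilities
  (homozygous-derived with probability $p^2 + F p(1-p)$); selfing is
  modeled through $F$ (default 0.98) rather than an explicit pedigree,
  which is sufficient for every statistic tested here;
* outgroup alleles equal to the true ancestral base, flipped with
  probability $e_k$ (defaults 0.05 and 0.10) to a uniformly random other
  base. Divergence mutations do not know about the ingroup's derived
  allele, so two-thirds of flips produce third-state alleles that the
  polarizer correctly treats as missing; the fitted mismatch rates are
  therefore conditional on the outgroup carrying an ingroup allele.

Deleterious sites (default 600 of 20,000, the few-percent share seen in
large crop panels) are confined to CDS, flagged nonsynonymous, and given
constraint scores above 2; the domesticated deleterious frequencies are
rescaled multiplicatively so that the expected per-accession burden ratio
equals the planted value exactly (0.929 for landraces, an additional
1.4% for improved lines). The rescaling freezes any frequency that
saturates at 1 and redistributes the deficit, so the planted expectation
is exact even under saturation.

### One kernel cannot produce both headline conditions

A finding worth recording: under the absorbed-normal kernel with a $1/i$
SFS, rare sites *gain* expected heterozygosity (absorption at 0 removes
mass but the surviving upward tail lands at much more heterozygous
frequencies), so halving total diversity in one step requires a variance
scale near $\omega \approx 80$. At that scale the neutral background's
frequency differentiation exceeds the planted sweeps' differentiation,
and no scan could (or should) find them. The package therefore separates
the two regimes: the default `drift_omega = 0.1` keeps the background in
the regime where planted sweeps stand out, and `bottleneck_omega()`
(calibrated once by simulation, value 80) reproduces the published ~48%
wild-to-domesticated diversity reduction when the bottleneck itself is
the object of study. A multi-generation Wright–Fisher bottleneck would
produce both at once, but coalescent-exact simulation is out of scope by
design.

What the generator does **not** emulate: linkage between neutral sites
(drift is drawn independently per site, so background LD is flat),
indels and structural variants, gene conversion, and ascertainment of
sites through a variant caller. Passing tests therefore show estimator
correctness under the stated model, not robustness to caller artifacts.

## Quality control

`filter_samples()` reproduces the two published sample rules: flag
samples whose heterozygous to homozygous-non-reference call ratio
exceeds 2/3 (among samples with enough heterozygous calls — 0.5 million
at full genome scale, 5% of sites at toy scale), and samples with
per-individual inbreeding coefficient below 0.8, where
$F = (E - O)/E$, $O$ the heterozygous call count and $E = \sum 2\hat p
(1 - \hat p)$ the Hardy–Weinberg expectation over the sample's
non-missing, cohort-polymorphic sites. The union of both flag sets is
removed. `filter_sites()` applies per-genotype masks first (depth above
4x the sample mean; heterozygous calls with allele balance below 30%),
then drops sites in a fixed, contract-level order: non-biallelic,
monomorphic after masking, missing rate > 20%, heterozygosity rate >
10%, minor allele frequency < 1%. Attrition is reported per rule in that
order; the filter is idempotent.

## Windowed diversity statistics

Per-site pairwise diversity uses the unbiased genotype-based estimator
$\pi_s = 2j(n-j)/(n(n-1))$ with $j$ the alternate-allele count and $n$
the non-missing allele count; windows (0-based half-open, 100 kb by
default) report the per-bp sum. Tajima's D uses the standard constants
with $n$ taken as the maximum non-missing allele count in the window —
per-site variation in $n$ is ignored, matching common windowed tools,
and windows without segregating sites return `NA` rather than zero. LD
decay is genotype-based ($r^2$ of dosage vectors), appropriate for a
near-homozygous selfing cohort where genotypes are effectively haploid;
the half-decay distance is read off the binned curve (100-bp bins below
5 kb, 1-kb bins above) with linear interpolation between bin midpoints.

## Polarization against two outgroups

The expectation–maximization estimator treats the ancestral allele as a
latent two-state variable (major or minor ingroup allele). Each
non-missing outgroup matches the ancestral state with probability
$1 - e_k$; third-state outgroup alleles are uninformative and treated as
missing. The prior weight $P(\text{major ancestral})$ is fitted per
minor-allele-frequency bin (5 bins). The frequency stratification is a
deliberate deviation from a single global mixture weight: a global prior
fitted near 0.88 overrides the weak outgroup evidence exactly at
intermediate frequencies, flips about 1% of hard calls, and measurably
attenuates downstream group contrasts; the binned prior is also closer
to the frequency-coupled prior of full unfolded-SFS estimators. EM
monotonicity and parameter recovery (planted $e_1, e_2$, prior recovered
within ±0.02 at $10^4$ sites) are tested.

Hard calls use the 0.5 posterior threshold, with ties resolved
conservatively to "major allele ancestral". For burden estimation,
`mutation_burden()` additionally excludes sites whose posterior
certainty $\max(p, 1-p)$ is below 0.8 (its `min_certainty` argument):
ambiguously polarized sites carry no directional information, and
including them only dilutes between-group contrasts. This is the
package's resolution of the genuinely open question of what posterior
cutoff defines a "derived" call; setting `min_certainty = 0.5` restores
the keep-everything behavior.

## Constraint scoring

For each alignment column the neutral tree is projected onto the species
actually aligned, with the reference species removed to avoid reference
bias; suppressed degree-2 nodes have their branch lengths summed, and the
projected span $T_{proj}$ (substitutions/site) is the expected number of
substitutions under neutrality. The column's maximum-likelihood rate
multiplier $\hat r \in [0, 3]$ is found by golden-section search
(tolerance $10^{-4}$, endpoints checked exactly so fully conserved
columns return $\hat r = 0$) of the Felsenstein pruning likelihood under
Jukes–Cantor. The rejected-substitution score is
$RS = T_{proj}(1 - \hat r)$; positions with fewer than two non-reference
species aligned, or an undetermined reference base, are filled with 0 and
classed `unscored`. Jukes–Cantor replaces the HKY-style model of the
original scorer: the downstream use is threshold classification at
$RS > 0/2/4$, validated by simulation (mean RS of neutral columns within
$0.05\,T$ at $10^4$ columns) rather than bit-parity. The rate MLE has a
small depth-dependent bias (boundary truncation at 0 versus saturation
above), and is well calibrated near the span ~1 substitutions/site
typical of the plant alignments this mirrors.

## Mutation burden

Effects are classified by codon translation with the standard nuclear
code (reverse-strand CDS complemented; stop gain/loss folded into
nonsynonymous). The default deleterious set is nonsynonymous with
$RS > 2$; the 2-vs-4 and synonymous strata, and a SIFT-flag criterion,
are available. Burden counts derived-allele *copies* (heterozygous = 1,
homozygous-derived = 2) — the literal reading of a per-accession count
in a near-homozygous cohort — with missing genotypes contributing 0, no
imputation, and per-accession missingness reported. Normalization is per
100 kb of CDS; with a sweep BED the genome partitions into sweep and
control classes, each normalized by its own CDS length, and burden is
additive across the partition.

The reference-bias correction reweights deleterious sites at which the
reference genome carries the derived allele by
$f = P(\text{del}\mid\text{ref ancestral}) / P(\text{del}\mid\text{ref
derived})$ within each of 10 equal-width derived-frequency bins (an
interpretation choice; the functional form of the published correction is
not restated in its source). It defaults off for constraint-score sets —
the scores are computed with the reference projected out, so they carry
no reference bias — and is intended for SIFT-style sets.

Group comparisons report $100(1 - \bar x_{focal}/\bar x_{ref})$ with the
wild group as the reference denominator, two-sided Welch t-tests, Tukey
HSD when three or more groups are present, and a paired within-group
sweep-versus-control contrast.

## Sweep scan

The scan follows the cross-population composite-likelihood design:
object-population frequencies drift from reference frequencies by the
absorbed truncated-normal kernel (variance scale $\omega$ estimated from
genome-wide mid-frequency SNPs); under a sweep at genetic distance $d$, a
lineage escapes with probability $c = 1 - e^{-d/\tilde s}$ and otherwise
carries the swept haplotype's allele. Observed derived counts are
binomial in the latent frequency, integrated by 64-point Gauss–Legendre
quadrature plus the boundary masses. Per grid point, up to 200 SNPs
within a 0.05-cM genetic window (nearest first) enter the composite
log-likelihood ratio; SNPs correlated above $r = 0.7$ (single-linkage
clusters on genotype correlation, `r` rather than `r²` — a documented
reading of an ambiguous flag) are down-weighted by 1/cluster-size. The
score is twice the maximum over a 15-point logarithmic grid of
$\tilde s$, clipped at zero.

Numerical choices worth recording:

* **Emission regularization.** At $d \to 0$ the sweep emission is
  degenerate — it predicts exact fixation, so one imperfectly fixed SNP
  at the grid point contributes $\log 0$ and erases the whole window. A
  small genotype-error probability (`obs_error`, default 0.005) is
  absorbed into both emissions, $q \mapsto \varepsilon + (1 -
  2\varepsilon)q$. With `obs_error = 0` the pure model is recovered, and
  the exported `snp_loglik_ratio()` defaults to the pure model so its
  limit identities hold exactly.
* **Drift-scale estimator.** The central-90% trimmed mean of
  $(p_2 - p_1)^2 / (p_1(1-p_1))$ is divided by the matching trimmed mean
  of a $\chi^2_1$ (the squared deviates are chi-square under the kernel;
  trimming alone discards ~27% of a $\chi^2_1$'s mass and would bias the
  scale down by ~20%). Only SNPs with reference frequency in $[0.2,
  0.8]$ are used: for mid-frequency SNPs the 0/1 boundary lies beyond
  the trimmed tail, so absorption cannot leak into the kept mass.
* **Threshold and merging.** Grid scores are aggregated to sliding
  100-kb/10-kb windows by the mean (the aggregator is unstated in the
  source design; the mean is the obvious unbiased choice). The threshold
  is the smallest windowed score whose strictly-above windows span at
  most 5% of the genome — span, not window count, since windows overlap.
  Regions are maximal runs of flagged windows tolerating at most one
  sub-threshold window; each region's candidate gene is the gene nearest
  its maximum-score window.

Because the calling rule fixes both the window size (100 kb) and the
genome fraction (5%), a 10-Mb toy genome has a 500-kb flagging budget and
each detected sweep consumes its own span plus up to ~100 kb of window
smear. The default generator therefore plants three 60-kb sweeps —
small enough that all three fit inside the budget, which is what the
planted-recovery tests require. Recovery was verified on seeds 1–6:
all three truth intervals overlapped and no false region, per seed.

## Pseudodiploids

`build_pseudodiploid()` merges two haploid genomes for diploid coalescent
inference in selfers: IUPAC ambiguity codes are first resolved to a
concrete base (seeded, uniform over the code), agreeing positions emit
the base, disagreeing positions emit the IUPAC code of the pair, and `N`
propagates. `enumerate_pseudodiploid_pairs()` lists all
$\binom{n}{2}$ unordered pairs in lexicographic order. Pseudodiploid QC
beyond construction (the identification of spurious demographic
profiles) is intentionally not implemented — no stated rule exists for
it.

## Orchestration and reproducibility

`run_pipeline()` executes simulate → QC → window statistics → polarize →
constraint scores (falling back to a supplied per-site score track when
no alignment is given) → sweep scan → burden, writing every tabular
intermediate as TSV plus a JSON manifest with md5 hashes, row counts and
the fitted stage parameters. All randomness flows from one master seed
through named per-stream sub-seeds, so adding a stream never perturbs
existing ones and identical seeds give byte-identical outputs; the test
suite asserts hash equality across reruns. The package's R functions are
the interface; the pipeline function plays the role a shell entry point
would for a standalone tool.

## Problem sizes used by the tests

The default test suite simulates cohorts of 100 wild / 100 landrace / 25
improved accessions at 20,000 sites on a 10-Mb chromosome for scan and
diversity checks, 1,500-site cohorts for pipeline-level checks, $10^4$
alignment columns for the neutral-score calibration, and ten seeds of
the 6,000-site / 5,000-deleterious-site configuration for the burden
recovery; the whole suite runs in a few minutes on one core. These sizes
were chosen so every stochastic check has comfortable Monte-Carlo margin
at desk scale.

## Known limitations

* The drift kernel is one-step Gaussian with absorption; it reproduces
  either the published diversity loss or a scan-appropriate background,
  not both at once (see above).
* The polarizer is strictly two-outgroup and two-state; topology-aware
  multi-outgroup models and indel polarization are out of scope.
* The constraint scorer assumes Jukes–Cantor and a single rate scale per
  column; no constrained-element segmentation is provided.
* The scan's selection scale $\tilde s$ is an effective parameter
  absorbing the usual $\ln(2Ns)$-type corrections; its absolute value is
  not interpretable, only the rank ordering of scores.
* LD-based statistics ignore phase; this is appropriate for selfers and
  increasingly wrong as outcrossing rates grow.
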