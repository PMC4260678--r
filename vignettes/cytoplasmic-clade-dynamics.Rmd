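---
title: "Tracking cytoplasmic clades under drift and selection"
author: "cytodrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking cytoplasmic clades under drift and selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytodrift)
set.seed(1)
```

## The problem

*Wolbachia* is a maternally transmitted intracellular bacterium of
arthropods. Because it is co-inherited with the mitochondrion, each
*Wolbachia* strain rides on a fixed mtDNA haplotype background: a
*cytoplasmic lineage*. In an evolve-and-resequence experiment, replicate
fly populations founded from one polymorphic base population are kept for
tens of generations in contrasting environments and sequenced as pools at
several time points. The analytical questions this package addresses are:

1. How frequent is each cytoplasmic clade in a pooled sample, given only
   read counts at clade-diagnostic SNPs?
2. Is an observed frequency change across replicates larger than neutral
   genetic drift can plausibly produce?
3. If so, what per-generation selection coefficient does the change imply?
4. Which individually sequenced hosts are infected at all, and at what
   relative titer?

The raw reads of such an experiment are not needed here: the package works
from pooled allele counts (PoPoolation2 "sync" format), a diagnostic SNP
table, and per-sample coverage summaries, and ships a forward simulator
that generates all of these with known ground truth.

## Clade frequencies from pooled counts

A *clade-diagnostic SNP* is an alignment column where every haplotype of
one clade group carries an allele found in no other group.
`identify_diagnostic_snps()` requires the private allele to be *fixed
within* its group, not merely private: the pooled frequency of the allele
is used directly as an estimate of the clade's frequency, which is only an
unbiased reading if every member of the clade carries the allele. Columns
containing N, ambiguity codes or gaps are discarded rather than
interpreted. Closely related clades that share most variation can be
pooled into one group (e.g. a combined `I_II_III` group) before scanning;
this trades resolution for estimation confidence. A single column may be
diagnostic for more than one group (with two groups every strict
difference is), so the table is keyed by (contig, position, clade).

Per replicate, `estimate_clade_frequencies()` downsamples each diagnostic
site to a fixed target coverage and reports the **median** of the per-SNP
diagnostic-allele frequencies. Choices worth stating explicitly:

* **Downsampling without replacement** (multivariate hypergeometric),
  so that a site's evidence is never overweighted; drawing with
  replacement is available (`with_replacement = TRUE`) but not the
  default. Fixed targets of 50x for an endosymbiont genome and 100x for
  mtDNA make estimates comparable across libraries of unequal depth.
* **Sites below the target are excluded**, not up-sampled: up-sampling
  would fabricate precision that the data do not contain. The package
  warns and drops such sites; a clade left with no usable site is reported
  as missing (`NA`), never as frequency zero.
* **N and del reads count toward the coverage** that the downsampling draw
  is taken from, but they can never contribute to the diagnostic
  numerator; frequencies are diagnostic count / target coverage.
* **The median, not the mean**, is the estimator: it is invariant to SNP
  order, robust to misassigned or misaligned SNPs up to a minority of the
  panel, and for an even panel size is the mean of the two central values.

The per-replicate sum of clade medians is a built-in quality control
(`cumulative_frequency_check()`): if the panel captures every major
lineage, the sum should be near one. The default acceptance band
[0.9, 1.1] is deliberately wide — binomial noise at 50x on three clades
routinely moves the sum by a few points — and a sum well below 0.9 is a
red flag that a major lineage is missing from the panel.

## The drift null

Whether a frequency change needs a selective explanation is judged against
a neutral Wright–Fisher null with `N` transmitting cytoplasmic lineages.
The chain on copy numbers 0..N has transition probabilities
P(i -> j) = C(N, j) (i/N)^j (1 - i/N)^(N-j); `wf_transition_matrix()`
builds the dense (N+1) x (N+1) matrix and `end_distribution()` raises it
to the t-th power (repeated squaring; dense matrices keep this exact and
fast for the N <= a few thousand regime this package targets — the 76 x 76
matrix of the default N = 75 takes milliseconds).

The observed start frequency is mapped to the nearest copy number (ties
away from zero), and the p-value is **twice the tail mass at least as
extreme as the observed end count, in the observed direction of change**,
capped at 1. Two remarks on this construction:

* Doubling a directional tail is conservative; the neutral calibration
  test in the suite confirms the rejection rate at alpha = 0.05 stays at
  or below nominal.
* Absorbing states (loss and fixation) are part of the tails; the test is
  unconditional on segregation.

Replicates are combined as the **product** of their p-values: the
probability, under drift acting independently in every replicate, of
seeing a change at least as extreme in all of them. A product of p-values
is *not* itself uniformly distributed under the null, so it should be read
as that joint probability and not as a calibrated combined p-value;
`combine_replicates(..., method = "fisher")` provides Fisher's
chi-squared combination when a calibrated value is wanted, and
`drift_test()` always reports both.

## Selection coefficients

Under haploid selection with constant advantage `s`, the favoured type's
frequency follows p' = p(1+s) / (1 + p s), equivalently its odds
p/(1-p) grow by a factor (1+s) per generation. `estimate_selection()`
inverts this exactly ("discrete" model):

    s = [odds(p_t) / odds(p_0)]^(1/t) - 1

and also offers the logit-linear form s = [logit(p_t) - logit(p_0)] / t,
the continuous-time analogue; the two agree to first order
(s_logit = log(1 + s_discrete)) and both are always computed, since either
parameterisation is common in the experimental-evolution literature and
the data rarely distinguish them. Frequencies of exactly 0 or 1 have
undefined odds; the error message suggests a pseudo-frequency (e.g.
1/(2N)) because silently clamping would hide a qualitatively different
regime (a lost or fixed clade).

`drift_test()` packages all of the above as a single fit: per-replicate
p-values, the product and Fisher combinations, and both `s` estimates per
replicate, with `print()`, `summary()` and `coef()` methods.

## Infection calls and titer

For individually sequenced hosts, infection is called from two strict
coverage criteria: reads must cover more than 95% of the endosymbiont
genome, and the ratio of mean endosymbiont depth to mean nuclear depth
must exceed one. Both thresholds are strict inequalities — uninfected
hosts show residual endosymbiont-mapping signal (conserved regions,
index hopping) of a few percent breadth and a ratio around 0.1, so the
boundary cases belong to the uninfected side. Relative titer is the
depth ratio itself (endosymbiont/nuclear or mtDNA/nuclear), which cancels
library size. `group_coverage_stats()` summarises depths per group with
the mean and the n-1 standard deviation; a single-sample group reports a
missing SD rather than 0. The package ships a 12-individual coverage
table (`cytodrift_example("bp_individuals_coverage.tsv")`) whose depth
columns are published values; its breadth and mtDNA columns are synthetic
placeholders, marked as such in the file, because per-sample values for
those quantities were never published. No statistical test for titer
differences between environments is provided — the choice of test is not
determined by the data this package handles, and group summaries are the
honest stopping point.

## The forward simulator

`simulate_trajectory()` is the package's ground-truth generator and also a
study-design tool. Its model, per generation (non-overlapping, as in the
experiment it emulates):

1. Every cytotype — (mtDNA clade, infection status) — receives weight
   frequency x fitness. Fitness multipliers (1 + s) attach to infection
   status and strain: uninfected lineages share the `"uninfected"`
   multiplier regardless of mtDNA clade, since the phenotype travels with
   the bacterium, not the mitochondrion.
2. With cytoplasmic incompatibility enabled (`ci_intensity > 0`),
   offspring of uninfected mothers are additionally down-weighted by
   `ci_intensity` x (current infected frequency) — the standard
   hatch-rate penalty of unidirectional CI. This layer is an extension
   beyond the experiment's analysis, off by default; bidirectional CI
   between strains is deliberately not modelled (it has not been shown in
   *D. melanogaster*).
3. The next generation is one multinomial draw of `n_lineages` offspring
   from the weights (exact Wright–Fisher resampling with selection).
4. Offspring of infected mothers lose the infection independently with
   probability 1 - `transmission_fidelity`, joining the uninfected pool
   *while keeping their mtDNA clade* — complete cytoplasmic linkage is
   assumed, so infection loss is the only way mtDNA and endosymbiont
   clade frequencies diverge.

Generation 0 is deterministic: initial frequencies are apportioned to
counts by largest-remainder rounding, so counts sum exactly to
`n_lineages` and the realised start composition is reproducible.

Defaults mirror the emulated experiment: N = 75 transmitting lineages
(the drift-scale estimate for these populations, treated here as the count
of transmitting females; roughly a quarter of the ~300 estimated
chromosomes), 15 generations (the cold-environment span), three clades at
relative frequencies 55/25/20%, an uninfected fraction of 47% where
infection dynamics are of interest, and a fitness multiplier of 1.18 on
the focal clade where selection is simulated (the mid-range of the
inferred coefficients). Pool-Seq observation
(`sample_poolseq_counts()`) draws per-site depth as Poisson around the
mean coverage — the natural model for shotgun sampling; overdispersed
alternatives are out of scope — and the diagnostic-allele count
binomially with success probability equal to the owning clade's frequency
perturbed by a per-base error rate (default 0.002, a typical post-filter
Illumina value); all non-diagnostic reads are booked to the reference
base. Diagnostic panels in the simulator-driven tests carry 150 SNPs per
clade: diverged endosymbiont strains differ at hundreds to thousands of
sites genome-wide, so a panel in the hundreds is the realistic scale, and
at any size beyond a few dozen SNPs the Pool-Seq contribution to
estimator noise is negligible next to drift.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: mapping and alignment artefacts
(paralogous reads, indel shadows), overdispersed or GC-biased coverage,
contamination between pools, library-kit effects on mtDNA recovery,
changes in the effective number of transmitting lineages over time, and
host-genotype effects on symbiont fitness. Tests passing on simulated
data validate the inference machinery, not these upstream steps.

## Numerical and design notes

* Frequencies map to copy numbers by rounding half away from zero; with
  N = 75 a start of 0.25 becomes 19/75 and an end of 0.80 becomes 60/75.
* Matrix powers use repeated squaring on dense matrices; row-stochasticity
  is preserved to ~1e-12 at N = 75.
* Reported tables round for display with half-away-from-zero at 2
  decimals (`round_half_up()`); internal computation is never rounded.
* All randomness flows from explicit seeds; the pipeline derives
  per-stage seeds from one global seed, and the estimation stage reuses
  one stage seed for every time point so that identical input counts give
  identical estimates.
* The sync format is headerless by convention and is read/written
  byte-stably; all other tables carry headers that readers validate.

## Worked example

A compact end-to-end run at the default study conditions (three
replicates, N = 75, 15 generations, selection 1.18 on clade V):

```{r example}
params <- sim_params(
  n_lineages = 75, generations = 15,
  clades = c("V", "VI", "I_II_III"),
  initial_frequencies = c(V = 0.25, VI = 0.55, I_II_III = 0.20,
                          uninfected = 0),
  selection = c(V = 1.18, VI = 1, I_II_III = 1, uninfected = 1),
  n_replicates = 3, seed = 19
)
sim <- simulate_trajectory(params)
panel <- data.frame(contig = "wolb", position = 1:90,
                    allele = rep(c("A", "C", "G"), each = 30),
                    clade = rep(c("V", "VI", "I_II_III"), each = 30))
counts0 <- sample_poolseq_counts(clade_frequencies(sim, 0), panel, 80,
                                 seed = 1)
counts15 <- sample_poolseq_counts(clade_frequencies(sim, 15), panel, 80,
                                  seed = 2)
est0 <- suppressWarnings(estimate_clade_frequencies(counts0, panel, 50))
est15 <- suppressWarnings(estimate_clade_frequencies(counts15, panel, 50))
v <- data.frame(
  start_frequency = est0$median_frequency[est0$clade == "V"],
  end_frequency = est15$median_frequency[est15$clade == "V"])
fit <- drift_test(v, N = 75, generations = 15)
fit
```

The test-suite problem sizes follow the same design: 2000 replicate
trajectories for the neutral calibration, 200 seeded end-to-end runs for
parameter recovery, and N = 4, t = 2 where exact path enumeration serves
as the oracle.

## Known limitations

* The drift test ignores the rise in infection rate over the experiment;
  when the infected fraction grows, the effective number of transmitting
  lineages for the endosymbiont is smaller early on than the constant-N
  null assumes, making the null slightly liberal in that direction. No
  correction is attempted, matching the analysis this package reproduces.
* The product-of-p-values combination is a joint probability, not a
  calibrated p-value (see above).
* `N` is an input, not an estimate; nothing in the package estimates the
  effective number of transmitting lineages.
* Selection inference assumes one constant coefficient shared against all
  competitor clades; frequency-dependent or fluctuating selection will be
  mis-summarised by a single `s`.
* At N = 75 the sampling noise of drift itself dominates the uncertainty
  of `s` recovered from a 15-generation experiment: across three
  replicates the standard deviation of the recovered coefficient is about
  0.05 even with error-free frequency estimates. Single-experiment `s`
  values should be read with that width in mind.
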