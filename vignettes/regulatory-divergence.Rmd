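---
title: "Methods: screening and dissecting regulatory-region divergence"
author: "regdiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening and dissecting regulatory-region divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regdiverge)
```

# Overview

`regdiverge` implements a pipeline for asking, across four closely related
*Saccharomyces* species, whether a noncoding (promoter) region has evolved
at an unusual rate on particular lineages, and then for dissecting what an
implicated gene's divergence does: which gene regions carry the phenotypic
difference, whether they interact epistatically, and how coding versus
noncoding divergence propagates into genome-wide expression changes.  Every
stage can be exercised on synthetic data whose statistical structure matches
what the corresponding analysis assumes, so the whole pipeline is testable
without any external download.

The worked system is the yeast transcription factor FZF1, a five-zinc-finger
activator of the sulfite efflux pump SSU1; the phenotype is sulfite
resistance measured as a growth delay.  The package, however, is written
against the general data types (alignments, scaled trees, growth curves,
chimera phenotype tables, expression matrices), not against that one gene.

# The substitution-rate heterogeneity screen

## Model

Let a noncoding locus alignment have the known unrooted topology
((cerevisiae, paradoxus), mikatae, bayanus).  Branch lengths $b_e$ of the
`ScaledTree` are genome-wide substitutions/site at fourfold-degenerate third
codon positions — the conventional neutral yardstick.  The locus evolves
under HKY85 (transition/transversion ratio $\kappa$, stationary frequencies
$\pi$) with effective branch lengths $b_e \cdot r_e$, where $r_e \ge 0$ is
the ratio of the locus's substitution rate to the silent rate (written
dNC/dS).  Two nested models are fitted by maximum likelihood with the
Felsenstein pruning algorithm:

* **constrained**: one shared ratio $r$ for all branches;
* **unconstrained**: one ratio $r_e$ per branch (five on the unrooted
  4-taxon tree).

The likelihood ratio statistic $2(\ln L_u - \ln L_c)$ is referred to a
chi-square with $5 - 1 = 4$ degrees of freedom.  A genome-wide screen
Bonferroni-corrects at $\alpha / n_\text{tested}$, where $n_\text{tested}$
counts loci that survive the insertion/deletion filter (a locus is dropped
when strictly more than 15% of its columns contain a gap; the filter is
column-based so "indel length" is always commensurate with alignment
length).  An explicit allowlist can retain a named locus despite the filter
— an auditable override rather than a silent exception.

## Numerical choices

* Base frequencies are empirical counts over the locus (gaps excluded), not
  free parameters; this is the common default of likelihood engines and
  removes three parameters per locus.
* $\kappa$ is ML-estimated once per locus in the constrained fit and then
  held fixed in the unconstrained fit, so the LRT isolates rate
  heterogeneity rather than model differences.  (Whether $\kappa$ should be
  per-locus or global is genuinely open; per-locus is the default because
  base composition and transition bias vary along yeast chromosomes, and a
  global value would require a prior pass over all loci.)
* Ratios are optimized on the log scale by bounded L-BFGS-B within
  $[10^{-6}, 100]$ — rate-ratio likelihoods flatten near zero — from starts
  0.1, 1 and 10; the unconstrained fit additionally starts from the
  constrained optimum, which guarantees the nesting inequality
  $\ln L_u \ge \ln L_c$ by construction.  Convergence tolerance is $10^{-8}$
  in log-likelihood (`factr = 1e7`); optimizer failures are retried from
  perturbed starts and flagged, never silent.
* Gap and N characters are missing data in the pruning likelihood (a
  partial-likelihood vector of ones at the tip), not deleted columns, so an
  all-gap column contributes exactly zero log-likelihood and locus length
  is preserved for the indel filter.
* Transition probabilities come from an eigendecomposition of the
  symmetrized reversible generator, which is numerically stable and makes
  one decomposition serve every branch within an optimizer step.

## Degenerate and adversarial inputs

A locus in which some base never occurs has no valid HKY85 stationary
distribution under empirical frequencies; the fit raises an explicit
unsupported-input error rather than pseudo-counting silently.  Identical
sequences drive all branch lengths to the lower bound.  Re-aligning the
same sequences with different aligners can flip the test decision — the
screen therefore only aggregates per-alignment decisions and never averages
them; robustness is a property of the ensemble of alignments.

# Sliding-window dN/dS with Monte-Carlo intervals

Pairwise dN and dS use the Nei–Gojobori (1986) counting method: expected
synonymous/nonsynonymous site counts averaged over the two sequences
(mutations to stop codons count as nonsynonymous, so $S + N = 3 \times$
codons exactly), observed differences averaged with equal weight over all
orderings of single-base steps for multi-difference codons (paths through
stop codons excluded; if every path is blocked the unrestricted average is
used), and the Jukes–Cantor correction $d = -\tfrac{3}{4}\ln(1 -
\tfrac{4}{3}p)$.  $p \ge 3/4$ is reported as *saturated*; a window with
$d_S = 0$ carries an undefined (NA) ratio, never an infinity.  The window
scan defaults to 150 codons sliding by 25 — the upstream literature the
scan imitates does not state its geometry, so both are configurable and the
whole-gene estimate is always reported alongside (it pools sites and
differences, which is not the mean of window ratios).

Confidence intervals are a parametric bootstrap in the style of the
K-estimator program: simulate codon pairs at the estimated $(d_S, d_N)$,
re-estimate each, and take empirical 2.5/97.5 percentiles.  The bootstrap is
deterministic given its seed.  The counting scheme is documented as
approximate to, not bit-identical with, K-estimator.

# The growth-delay phenotype

Sulfite resistance is quantified as the delay between the time of maximum
growth rate under sulfite and under a water control from the same strain
and day.  The time of maximum growth rate is located on the smoothed
derivative of log OD: a centered moving average (default window 5 points)
of log OD, central differences, and a second moving-average pass on the
derivative, with ties broken to the earliest time.  The second smoothing
pass is deliberate: differentiation amplifies plate-reader noise roughly by
the sampling rate, and with a single-stage smoother the max-rate time is
localized within 0.5 h in only ~80% of noisy replicates at realistic noise
(OD sd 0.01, 10-minute sampling), versus ~97% with the two-stage smoother —
while noiseless curves and translation equivariance remain exact.  A curve
whose smoothed log OD never gains one doubling is flagged a *non-grower*
and the delay becomes a missing value with a reason code (some strains grow
in water but not in sulfite; a missing control is `"control_failed"`).

Delays from different days are standardized by a per-day Z-score (sample
standard deviation); a zero-variance day is an error naming the day.  Group
comparisons use the Kruskal–Wallis test and pairwise Wilcoxon rank-sum
tests with Bonferroni correction, both invariant to monotone transforms of
the phenotype.

# Chimeric-allele decomposition

The 22-construct panel comprises the two full-length parents, the ten
reciprocal single-region chimeras over five gene regions, and five of the
ten region pairs in both orientations.  Which five pairs were built is not
derivable from the construct count alone; the package uses the balanced
cycle (1,2), (2,3), (3,4), (4,5), (1,5), under which every region enters
exactly two pairwise chimeras and — importantly — all ten pairwise
interaction coefficients of the epistatic model remain estimable (the
fixed-effect design has full rank 16; several other five-pair choices do
not).

Phenotypes are modelled with linear mixed models estimated by **ML, not
REML**, because the additive/epistatic comparison is a fixed-effect LRT:

* additive: `delay ~ region1 + ... + region5 + (1 | batch)`;
* epistatic: all ten pairwise region products added.

Parameters are counted as fixed effects plus the two variance components:
8 versus 18, so the LRT has 10 degrees of freedom.  "Batch" is the 96-well
plate random intercept (repeated measurement of a construct); day-to-day
level shifts are handled by the prior Z-scoring, not by the model.
Variance explained is computed from the LRT against the batch-only
intercept null as $R^2 = 1 - \exp(-LR/n)$, and per-region percent
contributions are $100\,|\hat\beta_i| / |\Delta|$ with the parent
difference $\Delta$ supplied explicitly — the sum of additive effects and
the observed parent difference need not coincide (epistasis absorbs the
remainder), so the package does not silently substitute one for the other.

Two small-sample caveats are documented rather than hidden.  First, ML
fixed-effect LRTs with 10 numerator degrees of freedom are anti-conservative
at the experiment's own size (22 constructs × 3 replicates, $n = 66$:
empirical type-I error ≈ 0.15 at nominal 0.05 in simulation), approaching
the nominal level as the panel is replicated more (≈ 0.07 at $n = 660$).
This is precisely why the package ships `permutationPvalues()`: construct
labels are permuted within day, the parametric p-value is recomputed, and
its permutation distribution is compared to Uniform(0,1) by a
Kolmogorov–Smirnov distance, exposing any miscalibration on the actual
data.  Second, Wald standard errors from ML are biased downward by a factor
of about $\sqrt{n/(n-k)}$; effect-size tables report them as z-based
p-values, and the recovery tests judge coverage at replication levels where
they are close to honest.

# Expression analysis

Expression values are treated as gene-level log2 quantities (for two-color
arrays against a common reference, after per-array median normalization,
which fixes each array's median at zero and preserves within-array ranks).
The first-level per-gene ANOVA is `expression = allele*time + technical
replicate + error`, with a single error term from the full model; it yields
the allele main-effect, allele-by-time and treatment (time) p-values.  All
genes share one design, so the package computes every per-gene F statistic
from shared QR projections rather than looping over `lm()` fits; genes with
missing values are flagged, never silently dropped.

For genes with a significant allele effect the allele factor is decomposed
as `expression = noncoding*coding + error` on the sample values; for genes
whose allele effect varies by time the same decomposition is fitted to the
per-culture sulfite response (the time-point difference averaged over
technical replicates), which is the contrast that "time-dependent allele
effect" actually tests.  A gene's source class (coding / noncoding /
interaction) is the smallest significant source p-value; classification is
invariant to which species is called the reference.

The permutation FDR permutes biological samples (technical replicates
travel together): within time point for the allele test — preserving the
tested null exactly — and across all units for the interaction test.  FDR
is the mean permuted significant-gene count over the observed count,
reported even when above 1 and undefined (with a note) when nothing is
observed.  qPCR relative expression is $2^{-\Delta C_t}$ against ACT1 with
a per-plate allele-primer correction factor estimated from heterozygous
genomic DNA, whose true allelic ratio is 1:1 — after correction the
heterozygote ratio is exactly 1 and residual amplification-efficiency
deviations are assumed absorbed by the factor.

# What the generators emulate — and what they do not

Each generator is a pure function of its seed (one user seed fans out to
substreams by a fixed splitting rule) and none imports from the analysis
code, so they remain independent oracles:

* `simulateAlignment()` evolves sites i.i.d. by exact continuous-time jump
  simulation of HKY85 along the tree (its own rate matrix, no matrix
  exponentials), with optional geometric gap runs (mean 5 columns) placed
  until a target gap-column fraction is reached.  It does not emulate
  alignment error, context-dependent mutation, or selection on specific
  sites — so passing screens on synthetic data says the *statistics* are
  right, not that real alignments are trustworthy (the multi-aligner
  sensitivity of real screens is exactly why the robustness report exists).
* `simulateCodonPair()` applies Poisson numbers of synonymous and
  nonsynonymous single-base changes at random eligible positions; multiple
  hits arise naturally.  It does not model codon usage bias or
  transition/transversion asymmetry within the coding sequence.
* `simulateGrowthPair()` produces shifted-logistic growth on the log OD
  scale (so the max specific growth rate falls exactly at the nominal
  inflection time), with i.i.d. Gaussian OD noise.  Defaults — baseline OD
  0.05, saturation 1.5, steepness 1.2/h (max specific growth rate ≈ 1/h,
  a fast-growing yeast in rich medium), 10-minute sampling over 20 h —
  are fixed once as realistic plate-reader conditions.  Real curves have
  autocorrelated noise, evaporation drift and diauxic shoulders; none are
  emulated.
* `simulateChimeraTable()` draws the 22-construct panel with specified
  additive effects, pairwise interactions, per-plate random intercepts and
  residual noise; each replicate of the panel is one plate and one day.
* `simulateExpressionMatrix()` spikes genes with coding, noncoding,
  pure-interaction (chimeras shifted against both parents), treatment, or
  allele-by-time patterns over Gaussian background noise, and returns the
  ground-truth labels.  Array spatial artifacts and intensity-dependent
  variance are out of scope.

# Problem sizes used by the shipped tests

The test-suite and acceptance-script simulation sizes are the package's
own choices: 500 one-kilobase null loci for LRT calibration, 200
two-kilobase loci for the 5× branch-multiplier recovery, 200 random ≤6
column instances for the enumeration oracle, 2,000-gene matrices (with 200
spiked genes and 100 label permutations) for the expression stage, the
22-construct × 3-replicate panel (with a 30-plate variant for variance
recovery) for the chimera stage, and 10-minute-resolution 20-hour growth
curves.  All are reproducible from a single integer seed.

# Known limitations

* The screen tests *rate heterogeneity*, not its cause; positive selection
  versus loss of constraint is deliberately not adjudicated.
* NG86 counting is approximate to codon-model ML and to K-estimator's exact
  implementation; windows with low synonymous-site counts are noisy, which
  is why per-window Monte-Carlo intervals and the whole-gene estimate are
  always available together.
* The chimera decomposition stops at five regions; mapping effects to
  individual substitutions is out of scope.
* The expression ANOVA assumes homoscedastic per-gene noise and treats the
  technical replicate as a simple blocking factor; empirical-Bayes variance
  moderation is intentionally not layered on top, to keep the per-gene test
  exactly the stated linear model.
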