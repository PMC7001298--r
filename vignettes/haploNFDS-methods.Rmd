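---
title: "Quantifying negative frequency-dependent selection on mtDNA haplotypes"
author: "haploNFDS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying negative frequency-dependent selection on mtDNA haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploNFDS)
```

## The scientific problem

Many *Drosophila subobscura* populations worldwide segregate two major
mitochondrial haplotype groups, HI and HII, at intermediate frequencies — a
pattern suggestive of balancing selection on what is effectively a haploid,
maternally inherited life-history supergene.  The decisive experimental test
of negative frequency-dependent selection (NFDS) is to found replicated
laboratory populations at contrasting starting frequencies and ask whether
each haplotype gains when rare and loses when common.  `haploNFDS`
implements the quantitative machinery for that test: a forward model of
frequency-dependent haplotype dynamics, a closed-form estimator of the
selection strength, pool-seq frequency estimation from diagnostic-SNP read
counts, and the replicated-line inference layer.

## The model

Let $p_I$ and $p_{II} = 1 - p_I$ be the frequencies of HI and HII, with
fitnesses $W_I$ and $W_{II}$.  One generation of haploid selection changes
$p_I$ by

$$\Delta p_I = \frac{p_I\, p_{II}\,(W_I - W_{II})}{\bar W}, \qquad
  \bar W = p_I W_I + p_{II} W_{II}.$$

Three assumptions — an internal equilibrium at $p_I = p_{II} = 0.5$, fitness
linear in frequency, and symmetric selection on the two haplotypes — give
the one-parameter fitness map

$$W_I = 1 - p_I s_I, \qquad W_{II} = 1 - p_{II} s_I,$$

so $\bar W = 1 - s_I(p_I^2 + p_{II}^2)$ and
$\Delta p_I = p_I p_{II} s_I (p_{II} - p_I)/\bar W$.  Positive $s_I$
penalises the common haplotype: the dynamics are attracted to 0.5, which is
NFDS.  Inverting the recursion for $s_I$ given an observed change yields the
closed form implemented in `estimateS()`:

$$s_I = \frac{-\Delta p_I\, p_I - \Delta p_I\, p_{II}}
  {-\Delta p_I\, p_{II}^2 - p_I p_{II}^2 + p_I^2 p_{II} - \Delta p_I\, p_I^2}
  \;=\; \frac{\Delta p_I}{\Delta p_I (p_I^2 + p_{II}^2) +
  p_I p_{II}(p_{II} - p_I)}.$$

`estimateS()` and `forwardDeltaP()` are exact algebraic inverses (the suite
verifies the round trip to $10^{-10}$ over a grid).  The estimator is
positive when the observed change points toward 0.5, negative when it points
away, and is undefined at fixation and in the $0/0$ case
($p_I = 0.5$, $\Delta p_I = 0$, where any $s_I$ is consistent with no
change); undefined cases are flagged `NA`, never silently numeric.  The
coefficient lives on an arbitrary scale; it is exact when the true
equilibrium is at 0.5 and approximate otherwise, and no correction for a
shifted equilibrium is attempted.

### Which frequency enters the estimator

Lines are sequenced at generations 5 and 10, so each line yields two
repeated per-generation changes, $\Delta f_{0\text{–}5} = (f_5 - f_0)/5$ and
$\Delta f_{5\text{–}10} = (f_{10} - f_5)/5$.  The estimator needs a single
reference frequency per interval; `lineSelectionEstimates()` uses the
frequency observed at the *start* of the interval, the only frequency
actually observed when the interval opens.  Because $p$ drifts over the five
generations, this discretises the continuous recursion and biases the
estimate slightly toward zero (at $s_I = 0.2$ from $p_0 = 0.2$ or $0.8$, the
deterministic recursion plus this reduction recovers about $0.18$).  The
bias is a property of the measurement design, not of sampling noise; the
acceptance computations quantify it by running the estimator on noise-free
deterministic trajectories and using that value as the recovery oracle.
Interval midpoints or means would be alternative choices; they are not
observable in the real design and are not implemented.

## The synthetic-data generator

`simulateExperiment()` emulates the statistical structure of the 12-line
experiment:

* **Design**: 2 starting frequencies of HI (0.2, 0.8) × 2 resource
  environments (homogeneous, heterogeneous) × 3 replicate lines, 10
  discrete generations, pools sequenced at generations 5 and 10.
* **Drift**: each generation the expected frequency moves by
  `forwardDeltaP()` and the realised count of HI carriers is a binomial
  draw with the generation's census size as trials — an unstructured
  haploid Wright–Fisher step.  mtDNA is maternally transmitted, so the
  biologically relevant size is the number of transmitting females; the
  census parameter is therefore an *effective* size, not a literal adult
  count.
* **Census trajectory**: 100 founders, growing linearly to 773 adults (the
  mean adult census of the motivating experiment) over the first five
  generations, then constant — cage populations grow quickly after founding
  and then saturate.  A constant or user-supplied trajectory is
  configurable.
* **Pooling**: 105 flies are drawn without replacement from the census
  (hypergeometric), with the census composition rounded to whole flies.
* **Sequencing**: each diagnostic SNP (`nad5`, `rrnS`) receives
  binomially distributed reads around the pool's HI fraction,
  conditionally independent given the pool.  The default depth of 10,000
  reads per SNP reflects the very deep effective mtDNA coverage of
  whole-fly pool-seq (mtDNA is present at high copy number); at that depth
  read-sampling noise is negligible next to the 105-fly pool.
* **True selection**: the default generating coefficient is
  $s_I = 0.2$, a moderate NFDS regime of the magnitude the estimator and
  12-line design are powered to detect.  `trueS` may instead be one value
  per environment — the hook used to create a non-null
  starting-frequency-by-environment interaction, since no mechanistic model
  of the environmental effect is assumed.
* **Seeding**: each line's random stream is derived from the global seed
  and the line's identity (start-frequency level, environment, replicate),
  so enlarging a design never perturbs existing lines, and equal seeds give
  byte-identical fixture files.

The generator deliberately omits sequencing error, reads mapping to neither
allele (inputs are strictly biallelic counts; the real pipeline's
unique/zero-mismatch mapping filter is upstream of this package), nuclear
variation and mitonuclear epistasis, within-generation viability stages,
and overlapping generations.  Passing tests therefore demonstrate that the
inference layer behaves correctly when its own distributional assumptions
hold — they do not validate those assumptions against real fly data.

## The inference layer

Each line is the observational unit.  For each response ($\Delta f$ or
$s_I$), the two interval measures per line form a split-plot
(within-subjects) layout: starting frequency (coded rare/common of HI) and
environment are between-line factors tested against the line-within-cell
residual (df 8 for 12 lines), and generation interval plus its interactions
are within-line effects tested against the interval-by-line residual
(df 8).  Drift contributes to the residual strata, which is what makes the
replicated design informative despite strong drift in mtDNA.  Sums of
squares come from base R's `aov()` with an `Error(line)` stratum; the test
suite verifies the F statistics against an independent general-linear-model
oracle (cell means for the between stratum, difference scores for the
within stratum) to $10^{-8}$.

Between-line F tests are validated by permutation: the (SF, E) label pairs
are permuted across lines as a unit — preserving each line's two repeated
measures and the factors' joint distribution — and the term's F is
recomputed each time with a closed-form balanced-contrast engine that the
suite checks against `aov()` exactly.  The permutation p-value uses the
add-one convention $(b+1)/(B+1)$ with $B = 9999$ by default, upper tail of
F (F is inherently one-tailed; all other tests are two-sided).  Permuting
raw responses or desynchronising the terms would be alternative schemes;
synchronized label-pair permutation is the one implemented because it
preserves the within-line structure exactly.

Group means of $s_I$ are summarised with percentile bootstrap intervals
(9999 replicates by default) over per-line values, where each line's scalar
is the arithmetic mean of its two interval estimates — the reduction that
makes a 12-line experiment yield the global one-sample $t_{11}$ test of
$H_0: s_I = 0$.  The percentile method is the simplest standard choice; it
is known to undercover slightly at $n = 12$ (the acceptance computations
measure its realised coverage directly), and BCa would be the natural
refinement if calibrated small-sample intervals were required.

## Numerical choices and degenerate inputs

* Frequencies are clamped to $[0,1]$ after floating arithmetic; values more
  than $10^{-12}$ outside raise an error rather than being clamped.
* Admissibility requires $\bar W > 0$, i.e. $s_I < 1/(p_I^2 + p_{II}^2)$;
  the forward model errors outside it and the simulator refuses designs
  with $s_I \ge 1$ (the bound's infimum over frequencies).
* Estimator degeneracies (fixation, vanishing denominator at tolerance
  $10^{-12}$) are flagged and propagate as named flags through
  `lineSelectionEstimates()` into `estimates.csv`.
* A response with no variation yields an ANOVA with zero sums of squares
  and flagged (`NaN`) F ratios; the permutation p-value is then the maximal
  1, and the zero-variance t statistic is flagged with a warning.
* All resampling (permutation, bootstrap, simulation) is bit-reproducible
  under a fixed seed.

## Validation problem sizes

The suite validates the stack at sizes chosen to give tight Monte-Carlo
error while keeping a default test run to a couple of minutes: a 200-point
round-trip grid; 50 random datasets for the ANOVA/oracle comparison; 500
null experiments (499 permutations each) for type-I calibration; 1000
Gaussian repeats for bootstrap coverage; 2000 replicate lines for the
neutral-drift martingale; and a census-10,000, depth-100,000 recovery run
compared to the deterministic-recursion oracle within $\pm 0.03$.

## Limitations

The model is strictly biallelic and haploid with a linear fitness map and a
0.5 equilibrium; estimates under a shifted equilibrium are systematically
approximate.  The interval-start discretisation biases $|s_I|$ downward
over 5-generation intervals.  The 105-fly pool is the dominant noise source
at realistic depths, and per-line estimates become heavy-tailed when a
line's frequency approaches 0.5, where the estimator's denominator is
small.  The generator's environment labels carry no mechanism: an
environmental effect exists in the synthetic data only through the
per-environment `trueS` hook.
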