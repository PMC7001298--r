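# haploNFDS

Detecting and quantifying **negative frequency-dependent selection (NFDS)**
on a biallelic haplotype system from replicated experimental evolution with
pool-seq, modelled on the two major mitochondrial haplotype groups (HI/HII)
that co-segregate within natural populations of *Drosophila subobscura*.

The package is for population geneticists running (or simulating)
manipulated-starting-frequency evolution experiments: lines founded with a
haplotype rare (e.g. 20%) or common (80%), evolved for 10 generations in
contrasting resource environments, and pool-sequenced at generations 5 and
10 at diagnostic SNPs.  NFDS predicts each haplotype gains when rare and
loses when common.

## The model at the core

With HI at frequency $p_I$ ($p_{II} = 1 - p_I$) and fitnesses
$W_I = 1 - p_I s_I$, $W_{II} = 1 - p_{II} s_I$, one generation of haploid
selection gives

$$\Delta p_I = \frac{p_I p_{II}(W_I - W_{II})}{\bar W},
\qquad \bar W = 1 - s_I\,(p_I^2 + p_{II}^2).$$

Positive $s_I$ penalises the common haplotype, so $p_I = 0.5$ is a stable
attractor.  Inverting the recursion gives the closed-form estimator

$$s_I = \frac{-\Delta p_I p_I - \Delta p_I p_{II}}
{-\Delta p_I p_{II}^2 - p_I p_{II}^2 + p_I^2 p_{II} - \Delta p_I p_I^2},$$

positive when the observed change points toward 0.5.  Around this core the
package provides:

* `forwardDeltaP()`, `estimateS()`, `fitnessPair()`, `deltaF()`,
  `lineSelectionEstimates()` — the model and its exact inverse;
* `experimentDesign()`, `simulateExperiment()` — a fully seeded generator
  of the 12-line 2 × 2 design with Wright–Fisher drift, 105-fly pools and
  per-SNP read counts;
* `PoolSeqCounts()`, `sampleFrequencies()`, `buildLineRecords()`,
  `snpConcordance()` — haplotype-frequency estimation from diagnostic-SNP
  counts (mean proportion across SNPs);
* `rmAnova()`, `permutationTestBetween()`, `bootstrapMeanCI()`,
  `globalTTest()`, `groupMeans()` — split-plot repeated-measures ANOVA with
  9999-permutation validation of between-line effects, percentile bootstrap
  CIs and the global one-sample t-test;
* `runSimulate()` / `runAnalyze()` — the end-to-end CSV pipeline
  (`counts.csv`, `design.csv`, `truth.csv` → `freqs.csv`, `estimates.csv`,
  `anova.csv`, `summary.csv`), also exposed as a command line in
  `inst/scripts/nfds-pipeline.R`.

## Worked example

Simulate the default 12-line experiment under a true coefficient of
$s_I = 0.2$ and run the full analysis:

```r
library(haploNFDS)

des <- experimentDesign()
des
#> ExperimentDesign: 12 lines ( 2 start freqs x 2 environments x 3 replicates )
#>   generations: 10 ; sampled at: 5, 10
#>   census: 100 founders -> 235..773
#>   pool size: 105 ; read depth: 10000 per SNP x 2 SNPs
#>   true s_I: 0.2

sim <- simulateExperiment(des, seed = 42)
res <- runAnalyze(sim$counts, sim$design, nPerm = 9999, nBoot = 9999,
                  seed = 42, verbose = FALSE)

head(res$lines, 3)
#>   line_id start_freq environment  f0      f5     f10
#> 1     L01        0.2 homogeneous 0.2 0.25195 0.26330
#> 2     L02        0.2 homogeneous 0.2 0.34920 0.36740
#> 3     L03        0.2 homogeneous 0.2 0.45325 0.47205

res$t_test
#> $t
#> [1] 5.926399
#> $df
#> [1] 11
#> $p
#> [1] 9.92499e-05

res$overall
#>    estimate     lower     upper  n n_boot
#> 1 0.1629549 0.1112624 0.2139385 12   9999
```

The lines founded at $f_0 = 0.2$ climb toward 0.5, and the mean selection
coefficient across the 12 lines (each line reduced to the mean of its two
interval estimates) is positive — $\bar s_I = 0.163$, 95% bootstrap CI
$[0.111,\ 0.214]$, $t_{11} = 5.93$, $p = 9.9\times10^{-5}$ — detecting the
NFDS regime the data were generated under (the recovered value sits below
the generating 0.2 because the estimator references each interval's
starting frequency; see the methods vignette).  `res$anova` holds the two
split-plot ANOVA tables ($\Delta f$ and $s_I$ responses) with permutation
p-values for the between-line terms, `res$groups` the per-cell bootstrap
intervals, and `res$concordance` the cross-SNP correlation of the HI read
proportions (here $r = 0.9996$).

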