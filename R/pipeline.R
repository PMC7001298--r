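## End-to-end pipeline: simulate fixtures, analyse counts into estimates,
## ANOVA tables and summary statistics.

.log <- function(verbose, ...) {
  if (verbose) message(...)
}

#' Simulate an experiment and write its fixture files
#'
#' Runs [simulateExperiment()] and writes `counts.csv`, `design.csv` and
#' `truth.csv` to `outDir`.  Output is byte-identical across runs with the
#' same design and seed.
#'
#' @param design An [ExperimentDesign-class] (default: the 12-line design).
#' @param seed Integer seed (mandatory).
#' @param outDir Output directory, created if needed.
#' @param verbose Log parameters and seed to standard error.
#' @return Invisibly, the list returned by [simulateExperiment()].
#' @export
runSimulate <- function(design = experimentDesign(), seed, outDir,
                        verbose = TRUE) {
  sim <- simulateExperiment(design, seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  .log(verbose, "simulate: ", nLines(design), " lines, seed ", seed,
       ", true s_I ", paste(signif(design@trueS, 4), collapse = "/"))
  writeTableCsv(sim$counts, file.path(outDir, "counts.csv"))
  writeTableCsv(sim$design, file.path(outDir, "design.csv"))
  writeTableCsv(sim$truth, file.path(outDir, "truth.csv"))
  invisible(sim)
}

#' Analyse a pooled-count experiment
#'
#' The full inferential pipeline: per-sample haplotype frequencies from the
#' diagnostic-SNP counts, per-interval frequency changes and selection
#' coefficients per line, split-plot repeated-measures ANOVAs (one per
#' response: `delta_f` and `s_I`) with permutation p-values for the
#' between-line terms, the global one-sample t-test of mean `s_I`, and
#' bootstrap intervals for the overall and per-group means.
#'
#' Writes `freqs.csv`, `estimates.csv`, `anova.csv` and `summary.csv` to
#' `outDir` when it is given; always returns the results.
#'
#' @param counts A counts `data.frame`/[PoolSeqCounts-class], or a path to
#'   `counts.csv`.
#' @param design A design `data.frame` or a path to `design.csv`.
#' @param outDir Optional output directory.
#' @param nPerm Permutations for the between-line tests (default 9999).
#' @param nBoot Bootstrap replicates for the CIs (default 9999).
#' @param seed Seed for the permutation and bootstrap draws (mandatory).
#' @param sampleGenerations The two sequenced generations.
#' @param verbose Log progress to standard error.
#' @return A list: `freqs`, `lines`, `estimates`, `anova` (both responses,
#'   stacked, with a `response` column), `concordance`, `t_test`,
#'   `overall`, `groups`.
#' @export
#' @examples
#' sim <- simulateExperiment(experimentDesign(), seed = 1)
#' res <- runAnalyze(sim$counts, sim$design, nPerm = 199, nBoot = 199,
#'                   seed = 1, verbose = FALSE)
#' res$t_test$t
runAnalyze <- function(counts, design, outDir = NULL, nPerm = 9999L,
                       nBoot = 9999L, seed, sampleGenerations = c(5, 10),
                       verbose = TRUE) {
  if (missing(seed) || is.null(seed)) {
    .validationError("a seed is mandatory for runAnalyze")
  }
  if (nPerm < 1L || nBoot < 1L) {
    .validationError("nPerm and nBoot must be positive")
  }
  if (is.character(counts)) counts <- readCountsCsv(counts)
  if (is.character(design)) design <- readDesignCsv(design)
  if (!is(counts, "PoolSeqCounts")) counts <- PoolSeqCounts(counts)
  design <- .validateDesignDf(design)

  .log(verbose, "analyze: ", ncol(counts), " samples, seed ", seed,
       ", nPerm ", nPerm, ", nBoot ", nBoot)
  freqs <- sampleFrequencies(counts)
  lines <- buildLineRecords(freqs, design, sampleGenerations)
  estimates <- lineSelectionEstimates(lines, sampleGenerations)
  concordance <- if (nrow(counts) >= 2L) snpConcordance(counts) else NA_real_

  anova <- do.call(rbind, lapply(c("delta_f", "s_I"), function(rsp) {
    rm <- responseMatrix(lines, rsp, sampleGenerations)
    tab <- rmAnova(rm, nPerm = nPerm, seed = seed)
    cbind(response = rsp, tab)
  }))

  respS <- responseMatrix(lines, "s_I", sampleGenerations)
  perLine <- perLineMeans(respS)
  tt <- globalTTest(perLine)
  overall <- bootstrapMeanCI(perLine, nBoot = nBoot, seed = seed)
  groups <- groupMeans(respS, nBoot = nBoot, seed = seed)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTableCsv(freqs[, .schemas$freqs], file.path(outDir, "freqs.csv"))
    writeTableCsv(estimates, file.path(outDir, "estimates.csv"))
    writeTableCsv(anova, file.path(outDir, "anova.csv"))
    summaryTab <- rbind(
      data.frame(statistic = "snp_concordance_r", group = "all",
                 value = concordance, lower = NA_real_, upper = NA_real_),
      data.frame(statistic = "global_t", group = "all", value = tt$t,
                 lower = NA_real_, upper = NA_real_),
      data.frame(statistic = "global_t_p", group = "all", value = tt$p,
                 lower = NA_real_, upper = NA_real_),
      data.frame(statistic = "mean_s_I", group = "all",
                 value = overall$estimate, lower = overall$lower,
                 upper = overall$upper),
      data.frame(statistic = "mean_s_I",
                 group = paste(groups$sf, groups$environment, sep = "/"),
                 value = groups$estimate, lower = groups$lower,
                 upper = groups$upper))
    writeTableCsv(summaryTab, file.path(outDir, "summary.csv"))
  }
  list(freqs = freqs, lines = lines, estimates = estimates, anova = anova,
       concordance = concordance, t_test = tt, overall = overall,
       groups = groups)
}
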