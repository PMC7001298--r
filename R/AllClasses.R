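#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats anova aov cor lm pf quantile rbinom rhyper rnorm sd
#'   setNames t.test var
#' @importFrom utils read.csv write.csv
NULL

#' ExperimentDesign: parameters of a replicated NFDS evolution experiment
#'
#' Describes a 2 x 2 crossed experimental-evolution design: lines founded at
#' contrasting HI starting frequencies, evolving in one of two resource
#' environments, with replicate lines per cell.  Carries the demographic and
#' sequencing parameters the synthetic-data generator needs: a per-generation
#' census trajectory, the number of flies pooled per sample, per-SNP read
#' depth and the true frequency-dependent selection coefficient.
#'
#' The default parameterisation mirrors the fly experiment the package is
#' modelled on: 12 lines (2 starting frequencies x 2 environments x 3
#' replicates), 100 founders growing to 773 adults by generation 5, pools of
#' 105 flies sequenced at generations 5 and 10 at two diagnostic SNPs
#' (`nad5`, `rrnS`).
#'
#' @slot startFreqs Numeric, the HI founding frequencies (default
#'   `c(0.2, 0.8)`).
#' @slot environments Character, environment labels (default
#'   `c("homogeneous", "heterogeneous")`).
#' @slot replicates Integer, lines per design cell (default 3).
#' @slot nGenerations Integer, generations of evolution (default 10).
#' @slot sampleGenerations Integer, generations at which pools are sequenced
#'   (default `c(5, 10)`).
#' @slot founders Integer, census at generation 0 (default 100).
#' @slot census Integer vector of length `nGenerations`: census size at
#'   generations `1..nGenerations`.  Default ramps linearly from the founder
#'   count to 773 adults over the first five generations, then stays at 773.
#' @slot poolSize Integer, flies pooled per sequenced sample (default 105).
#' @slot readDepth Integer, reads per diagnostic SNP per sample
#'   (default 10000).
#' @slot snpIds Character, diagnostic SNP labels (default
#'   `c("nad5", "rrnS")`).
#' @slot trueS Numeric, the generating selection coefficient: either a single
#'   value or one named value per environment (the environment hook used to
#'   create a non-null starting-frequency-by-environment interaction).
#' @slot deterministic Logical; if `TRUE` the generator runs the infinite
#'   census limit: no drift, pool fraction equal to the true frequency, and
#'   read counts rounded from exact proportions.
#'
#' @seealso [experimentDesign()], [simulateExperiment()]
#' @export
setClass("ExperimentDesign",
  representation(
    startFreqs = "numeric",
    environments = "character",
    replicates = "integer",
    nGenerations = "integer",
    sampleGenerations = "integer",
    founders = "integer",
    census = "integer",
    poolSize = "integer",
    readDepth = "integer",
    snpIds = "character",
    trueS = "numeric",
    deterministic = "logical"
  )
)

setValidity("ExperimentDesign", function(object) {
  msg <- character()
  if (any(object@startFreqs < 0 | object@startFreqs > 1))
    msg <- c(msg, "startFreqs must lie in [0, 1]")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (object@nGenerations < 1L) msg <- c(msg, "nGenerations must be >= 1")
  if (length(object@census) != object@nGenerations)
    msg <- c(msg, "census must have one entry per generation 1..nGenerations")
  if (any(object@census < 1L)) msg <- c(msg, "census sizes must be >= 1")
  if (object@founders < 1L) msg <- c(msg, "founders must be >= 1")
  if (!all(object@sampleGenerations %in% seq_len(object@nGenerations)))
    msg <- c(msg, "sampleGenerations must lie in 1..nGenerations")
  if (length(object@sampleGenerations) != 2L)
    msg <- c(msg, "exactly two sample generations are required")
  if (object@poolSize < 1L) msg <- c(msg, "poolSize must be >= 1")
  if (!object@deterministic &&
      any(object@poolSize > object@census[object@sampleGenerations]))
    msg <- c(msg, "poolSize exceeds the census at a sampled generation")
  if (object@readDepth < 1L) msg <- c(msg, "readDepth must be >= 1")
  if (length(object@snpIds) < 1L) msg <- c(msg, "need at least one SNP id")
  if (anyDuplicated(object@snpIds)) msg <- c(msg, "snpIds must be unique")
  if (!(length(object@trueS) == 1L ||
        (length(object@trueS) == length(object@environments) &&
         !is.null(names(object@trueS)) &&
         setequal(names(object@trueS), object@environments))))
    msg <- c(msg, paste("trueS must be a single value or one value named per",
                        "environment"))
  if (any(object@trueS >= 1))
    msg <- c(msg, "trueS must be < 1 so mean fitness stays positive")
  if (length(msg)) msg else TRUE
})

#' Construct an ExperimentDesign
#'
#' @param startFreqs Numeric HI founding frequencies, one per
#'   starting-frequency level.
#' @param environments Character environment labels.
#' @param replicates Lines per design cell.
#' @param nGenerations Number of discrete generations.
#' @param sampleGenerations The two generations at which pools are sequenced.
#' @param founders Census size at generation 0.
#' @param census Optional integer vector of census sizes at generations
#'   `1..nGenerations`.  A single value is recycled (constant census).  The
#'   default ramps from `founders` to `adultCensus` over the first five
#'   generations and holds there.
#' @param adultCensus Plateau census used by the default ramp (default 773).
#' @param poolSize Flies pooled per sequenced sample.
#' @param readDepth Reads per diagnostic SNP per sample.
#' @param snpIds Diagnostic SNP labels.
#' @param trueS Generating selection coefficient; a single value, or one
#'   value named per environment.
#' @param deterministic Run the infinite-census, noise-free limit.
#' @return A validated [ExperimentDesign-class] object.
#' @export
#' @examples
#' experimentDesign()                      # the 12-line default
#' experimentDesign(replicates = 1L)       # 4 lines
#' experimentDesign(trueS = c(homogeneous = 0.25, heterogeneous = 0))
experimentDesign <- function(startFreqs = c(0.2, 0.8),
                             environments = c("homogeneous", "heterogeneous"),
                             replicates = 3L,
                             nGenerations = 10L,
                             sampleGenerations = c(5L, 10L),
                             founders = 100L,
                             census = NULL,
                             adultCensus = 773L,
                             poolSize = 105L,
                             readDepth = 10000L,
                             snpIds = c("nad5", "rrnS"),
                             trueS = 0.2,
                             deterministic = FALSE) {
  nGenerations <- as.integer(nGenerations)
  if (is.null(census)) {
    ramp <- round(founders + (adultCensus - founders) *
                    pmin(seq_len(nGenerations), 5L) / 5)
    census <- as.integer(ramp)
  } else {
    census <- as.integer(rep_len(census, nGenerations))
  }
  new("ExperimentDesign",
      startFreqs = as.numeric(startFreqs),
      environments = as.character(environments),
      replicates = as.integer(replicates),
      nGenerations = nGenerations,
      sampleGenerations = sort(as.integer(sampleGenerations)),
      founders = as.integer(founders),
      census = census,
      poolSize = as.integer(poolSize),
      readDepth = as.integer(readDepth),
      snpIds = as.character(snpIds),
      trueS = trueS,
      deterministic = deterministic)
}

#' Number of lines implied by a design
#'
#' @param design An [ExperimentDesign-class].
#' @return Integer: starting frequencies x environments x replicates.
#' @export
nLines <- function(design) {
  stopifnot(is(design, "ExperimentDesign"))
  length(design@startFreqs) * length(design@environments) * design@replicates
}

#' Design table for a replicated experiment
#'
#' Expands an [ExperimentDesign-class] into its per-line table, in the fixed
#' order: starting frequency, then environment, then replicate.
#'
#' @param design An [ExperimentDesign-class].
#' @return A `data.frame` with columns `line_id`, `start_freq`,
#'   `environment`, `replicate`.
#' @export
#' @examples
#' designTable(experimentDesign(replicates = 1L))
designTable <- function(design) {
  stopifnot(is(design, "ExperimentDesign"))
  grid <- expand.grid(replicate = seq_len(design@replicates),
                      environment = design@environments,
                      start_freq = design@startFreqs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("start_freq", "environment", "replicate")]
  grid$line_id <- sprintf("L%02d", seq_len(nrow(grid)))
  grid[, c("line_id", "start_freq", "environment", "replicate")]
}

setMethod("show", "ExperimentDesign", function(object) {
  cat("ExperimentDesign:", nLines(object), "lines (",
      length(object@startFreqs), "start freqs x",
      length(object@environments), "environments x",
      object@replicates, "replicates )\n")
  cat("  generations:", object@nGenerations,
      "; sampled at:", paste(object@sampleGenerations, collapse = ", "), "\n")
  cat("  census:", object@founders, "founders ->",
      paste(range(object@census), collapse = ".."), "\n")
  cat("  pool size:", object@poolSize, "; read depth:", object@readDepth,
      "per SNP x", length(object@snpIds), "SNPs\n")
  cat("  true s_I:", paste(signif(object@trueS, 4), collapse = "/"),
      if (object@deterministic) " [deterministic]" else "", "\n")
})

#' PoolSeqCounts: diagnostic-SNP read counts from pooled samples
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] holding the read
#' counts supporting each haplotype at each diagnostic SNP (rows) in each
#' pooled sample (columns).  Two assays, `countHI` and `countHII`, hold the
#' reads supporting haplotypes HI and HII; `colData` carries `sample_id`,
#' `line_id` and `generation`.  Missing SNP-by-sample measurements may be
#' `NA` in both assays.
#'
#' @seealso [PoolSeqCounts()], [sampleFrequencies()], [snpConcordance()]
#' @export
setClass("PoolSeqCounts", contains = "SummarizedExperiment")

setValidity("PoolSeqCounts", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("countHI", "countHII") %in% an))
    return("assays 'countHI' and 'countHII' are required")
  for (a in c("countHI", "countHII")) {
    m <- SummarizedExperiment::assay(object, a)
    ok <- is.na(m) | (m >= 0 & m == round(m))
    if (!all(ok)) msg <- c(msg, paste(a, "must be non-negative integers"))
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "line_id", "generation")
  if (!all(need %in% names(cd)))
    msg <- c(msg, paste("colData must contain",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Build a PoolSeqCounts object from a long count table
#'
#' @param counts A `data.frame` with columns `sample_id`, `line_id`,
#'   `generation`, `snp_id`, `count_HI`, `count_HII` (one row per SNP per
#'   pooled sample), as written by [runSimulate()] or read by
#'   [readCountsCsv()].
#' @return A [PoolSeqCounts-class] with one row per SNP and one column per
#'   sample; SNP-by-sample combinations absent from `counts` become `NA`.
#' @export
#' @examples
#' sim <- simulateExperiment(experimentDesign(replicates = 1L), seed = 1)
#' PoolSeqCounts(sim$counts)
PoolSeqCounts <- function(counts) {
  .validateCountsDf(counts)
  counts$sample_id <- as.character(counts$sample_id)
  snps <- unique(as.character(counts$snp_id))
  smp <- unique(counts$sample_id)
  hi <- matrix(NA_real_, length(snps), length(smp),
               dimnames = list(snps, smp))
  hii <- hi
  hi[cbind(match(counts$snp_id, snps), match(counts$sample_id, smp))] <-
    counts$count_HI
  hii[cbind(match(counts$snp_id, snps), match(counts$sample_id, smp))] <-
    counts$count_HII
  meta <- unique(counts[, c("sample_id", "line_id", "generation")])
  if (anyDuplicated(meta$sample_id))
    stop("sample_id maps to more than one line/generation", call. = FALSE)
  meta <- meta[match(smp, meta$sample_id), ]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(countHI = hi, countHII = hii),
    colData = S4Vectors::DataFrame(meta, row.names = smp))
  new("PoolSeqCounts", se)
}

setMethod("show", "PoolSeqCounts", function(object) {
  cat("PoolSeqCounts:", nrow(object), "diagnostic SNP(s) x",
      ncol(object), "pooled sample(s)\n")
  cat("  SNPs:", paste(rownames(object), collapse = ", "), "\n")
  gen <- SummarizedExperiment::colData(object)$generation
  cat("  generations:", paste(sort(unique(gen)), collapse = ", "), "\n")
})
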