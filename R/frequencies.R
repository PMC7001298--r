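## Haplotype-frequency estimation from diagnostic-SNP read counts.

#' Per-SNP HI read proportion
#'
#' @param countHI,countHII Non-negative integer read counts supporting each
#'   haplotype at one SNP in one pooled sample (vectorised).
#' @return `countHI / (countHI + countHII)`; errors on a zero total.
#' @export
#' @examples
#' snpProportion(300, 700)  # 0.3
snpProportion <- function(countHI, countHII) {
  if (any(countHI < 0 | countHII < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  tot <- countHI + countHII
  if (any(tot < 1)) {
    stop("zero total read count at ", sum(tot < 1), " record(s)",
         call. = FALSE)
  }
  countHI / tot
}

#' Combine per-SNP proportions into one sample's frequency estimate
#'
#' The HI frequency of a pooled sample is the unweighted mean of the HI read
#' proportions across the diagnostic SNPs.  When only one usable SNP is
#' supplied the single proportion is returned with a warning.  Optional
#' depth weighting (total reads per SNP as weights) is available but is not
#' the default.
#'
#' @param countHI,countHII Integer vectors, one entry per diagnostic SNP of
#'   the same sample; `NA` entries mark missing SNPs.
#' @param depthWeighted Weight SNPs by their total read depth instead of
#'   averaging proportions unweighted.
#' @return A single HI frequency in `[0, 1]`.
#' @export
#' @examples
#' combineSnps(c(300, 320), c(700, 680))  # 0.31
combineSnps <- function(countHI, countHII, depthWeighted = FALSE) {
  stopifnot(length(countHI) == length(countHII))
  use <- !is.na(countHI) & !is.na(countHII)
  if (!any(use)) stop("no usable SNP records for sample", call. = FALSE)
  if (sum(use) < length(countHI)) {
    warning("sample has ", sum(!use), " missing SNP record(s); ",
            "using the ", sum(use), " available", call. = FALSE)
  }
  prop <- snpProportion(countHI[use], countHII[use])
  if (depthWeighted) {
    w <- countHI[use] + countHII[use]
    sum(prop * w) / sum(w)
  } else {
    mean(prop)
  }
}

#' Per-sample haplotype-frequency estimates
#'
#' Applies [combineSnps()] to every pooled sample of a
#' [PoolSeqCounts-class] object.
#'
#' @param counts A [PoolSeqCounts-class].
#' @param depthWeighted Passed to [combineSnps()].
#' @return A `data.frame` with columns `sample_id`, `line_id`, `generation`,
#'   `f_HI`.
#' @export
sampleFrequencies <- function(counts, depthWeighted = FALSE) {
  stopifnot(is(counts, "PoolSeqCounts"))
  hi <- SummarizedExperiment::assay(counts, "countHI")
  hii <- SummarizedExperiment::assay(counts, "countHII")
  cd <- as.data.frame(SummarizedExperiment::colData(counts))
  f <- vapply(seq_len(ncol(hi)), function(j) {
    combineSnps(hi[, j], hii[, j], depthWeighted = depthWeighted)
  }, numeric(1))
  data.frame(sample_id = cd$sample_id, line_id = cd$line_id,
             generation = cd$generation, f_HI = f,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble line records from pooled counts and the design table
#'
#' Combines the known generation-0 frequencies (set by the design: the lines
#' were founded at those frequencies, not sequenced) with the pool-seq
#' estimates at the sampled generations into one record per line.  Missing
#' samples and counts for lines absent from the design fail loudly, naming
#' the offending line/generation.
#'
#' @param counts A [PoolSeqCounts-class], or a frequency `data.frame` as
#'   returned by [sampleFrequencies()].
#' @param design The per-line design `data.frame` (`line_id`, `start_freq`,
#'   `environment`, `replicate`).
#' @param sampleGenerations The two sequenced generations (default
#'   `c(5, 10)`).
#' @param depthWeighted Passed on to [sampleFrequencies()].
#' @return A `data.frame` with columns `line_id`, `start_freq`,
#'   `environment`, `f0`, and `f<g>` for each sampled generation.
#' @export
buildLineRecords <- function(counts, design, sampleGenerations = c(5, 10),
                             depthWeighted = FALSE) {
  freqs <- if (is(counts, "PoolSeqCounts")) {
    sampleFrequencies(counts, depthWeighted = depthWeighted)
  } else {
    stopifnot(is.data.frame(counts),
              all(c("line_id", "generation", "f_HI") %in% names(counts)))
    counts
  }
  stopifnot(is.data.frame(design),
            all(c("line_id", "start_freq", "environment") %in% names(design)))
  unknown <- setdiff(unique(freqs$line_id), design$line_id)
  if (length(unknown)) {
    stop("counts contain line(s) absent from the design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sampleGenerations <- sort(as.integer(sampleGenerations))
  out <- design[, c("line_id", "start_freq", "environment")]
  out$f0 <- out$start_freq
  for (g in sampleGenerations) {
    idx <- match(paste(out$line_id, g),
                 paste(freqs$line_id, freqs$generation))
    if (anyNA(idx)) {
      miss <- out$line_id[is.na(idx)]
      stop("missing sample(s) for generation ", g, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    out[[paste0("f", g)]] <- freqs$f_HI[idx]
  }
  rownames(out) <- NULL
  out
}

#' Concordance of the two diagnostic SNPs
#'
#' Pearson correlation of the per-sample HI read proportions at the first
#' two SNPs — the diagnostic check that both markers estimate the same pool
#' fraction.  A diagnostic to report, not a quantity to assert on.
#'
#' @param counts A [PoolSeqCounts-class] with at least two SNP rows and at
#'   least three samples carrying both.
#' @return The correlation coefficient, or `NA` (with a warning) when either
#'   SNP's proportions are constant across samples.
#' @export
snpConcordance <- function(counts) {
  stopifnot(is(counts, "PoolSeqCounts"))
  if (nrow(counts) < 2L) {
    stop("snpConcordance needs two diagnostic SNPs", call. = FALSE)
  }
  hi <- SummarizedExperiment::assay(counts, "countHI")
  hii <- SummarizedExperiment::assay(counts, "countHII")
  ok <- !is.na(hi[1, ]) & !is.na(hi[2, ])
  if (sum(ok) < 3L) {
    stop("need at least 3 samples with both SNPs present", call. = FALSE)
  }
  p1 <- snpProportion(hi[1, ok], hii[1, ok])
  p2 <- snpProportion(hi[2, ok], hii[2, ok])
  if (sd(p1) == 0 || sd(p2) == 0) {
    warning("a SNP's proportions are constant across samples; ",
            "correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(p1, p2)
}
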