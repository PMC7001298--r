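## Synthetic-data generator: Wright-Fisher drift around the deterministic
## NFDS recursion, pooled-fly sampling, and diagnostic-SNP read counts.

## Per-line seed derived from the line's identity (start-frequency level,
## environment level, replicate), never from its position in the table, so
## enlarging a design leaves existing lines' streams untouched.
.lineSeed <- function(seed, startIdx, envIdx, rep) {
  as.integer((abs(as.numeric(seed)) + 100003 * startIdx + 10007 * envIdx +
                101 * rep) %% 2147483629)
}

.trueSFor <- function(design, environment) {
  s <- design@trueS
  if (length(s) == 1L) unname(s) else unname(s[[environment]])
}

#' Simulate one line's haplotype-frequency trajectory
#'
#' Runs the haploid Wright-Fisher process with NFDS: each generation the
#' expected frequency moves by [forwardDeltaP()] under the true coefficient,
#' then the realised count of HI carriers is drawn from a binomial with the
#' generation's census size as the number of trials.  With
#' `deterministic = TRUE` the binomial step is skipped (infinite-census
#' limit).  Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param startP HI frequency at generation 0.
#' @param trueS Generating frequency-dependent selection coefficient.
#' @param census Integer vector of census sizes at generations
#'   `1..nGenerations`.
#' @param deterministic Logical; skip drift.
#' @return Numeric vector of length `length(census) + 1`: the true HI
#'   frequency at generations `0..nGenerations`.
#' @export
#' @examples
#' simulateLineTrajectory(0.2, 5 / 13, census = rep(500L, 1),
#'                        deterministic = TRUE)  # c(0.2, 0.25)
simulateLineTrajectory <- function(startP, trueS, census,
                                   deterministic = FALSE) {
  p <- numeric(length(census) + 1L)
  p[1] <- .clampFreq(startP, "startP")
  for (g in seq_along(census)) {
    pExp <- p[g] + forwardDeltaP(p[g], trueS)
    if (pExp < -1e-12 || pExp > 1 + 1e-12) {
      stop("expected frequency left [0, 1] at generation ", g,
           ": trueS inadmissible", call. = FALSE)
    }
    pExp <- min(max(pExp, 0), 1)
    p[g + 1L] <- if (deterministic) pExp else
      rbinom(1L, census[g], pExp) / census[g]
  }
  p
}

#' Draw a pooled sample of flies from a census
#'
#' Pools are modelled as sampling `poolSize` flies without replacement from a
#' census whose HI-carrier count is the census size times the true frequency,
#' rounded to the nearest fly (a hypergeometric draw).
#'
#' @param trueP True HI frequency in the census.
#' @param census Census size the pool is drawn from.
#' @param poolSize Number of flies pooled.
#' @return Integer vector `c(HI, HII)` summing to `poolSize`.
#' @export
samplePool <- function(trueP, census, poolSize) {
  trueP <- .clampFreq(trueP, "trueP")
  if (poolSize > census) {
    stop("poolSize (", poolSize, ") exceeds census (", census, ")",
         call. = FALSE)
  }
  m <- round(census * trueP)
  hi <- rhyper(1L, m, census - m, poolSize)
  c(HI = hi, HII = poolSize - hi)
}

#' Draw diagnostic-SNP read counts for a pooled sample
#'
#' Each SNP's HI read count is binomial with the sequencing depth as trials
#' and the pool's HI fraction as success probability; SNPs are conditionally
#' independent given the pool.
#'
#' @param poolHI Number of HI flies in the pool.
#' @param poolSize Pool size.
#' @param depth Reads per SNP.
#' @param nSnps Number of diagnostic SNPs.
#' @return Integer matrix with `nSnps` rows and columns `count_HI`,
#'   `count_HII`; rows sum to `depth`.
#' @export
sampleReads <- function(poolHI, poolSize, depth, nSnps) {
  stopifnot(depth >= 1, nSnps >= 1, poolHI >= 0, poolHI <= poolSize)
  hi <- rbinom(nSnps, depth, poolHI / poolSize)
  cbind(count_HI = hi, count_HII = depth - hi)
}

#' Generate a complete synthetic pool-seq evolution experiment
#'
#' Simulates every line of the design (trajectory, pooled samples at the
#' sampled generations, per-SNP read counts) under independent per-line
#' random streams derived from `seed`.  In deterministic designs the pool
#' fraction equals the true frequency and read counts are
#' `round(p * depth)`, so estimates recover the deterministic recursion to
#' rounding error.
#'
#' @param design An [ExperimentDesign-class].
#' @param seed Integer seed governing all randomness.
#' @return A list with elements
#'   \describe{
#'     \item{design}{the per-line design table ([designTable()]),}
#'     \item{truth}{`data.frame` `line_id`, `generation`, `true_p`, `census`
#'       — the latent trajectories,}
#'     \item{counts}{`data.frame` in the `counts.csv` schema: `sample_id`,
#'       `line_id`, `generation`, `snp_id`, `count_HI`, `count_HII`.}
#'   }
#' @export
#' @examples
#' sim <- simulateExperiment(experimentDesign(), seed = 1)
#' nrow(sim$counts)  # 12 lines x 2 generations x 2 SNPs = 48
simulateExperiment <- function(design, seed) {
  stopifnot(is(design, "ExperimentDesign"))
  validObject(design)
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for simulateExperiment", call. = FALSE)
  }
  dt <- designTable(design)
  censusAll <- c(design@founders, design@census)
  truth <- vector("list", nrow(dt))
  counts <- vector("list", nrow(dt))
  for (i in seq_len(nrow(dt))) {
    row <- dt[i, ]
    si <- match(row$start_freq, design@startFreqs)
    ei <- match(row$environment, design@environments)
    set.seed(.lineSeed(seed, si, ei, row$replicate))
    s <- .trueSFor(design, row$environment)
    traj <- simulateLineTrajectory(row$start_freq, s, design@census,
                                   deterministic = design@deterministic)
    truth[[i]] <- data.frame(line_id = row$line_id,
                             generation = 0:design@nGenerations,
                             true_p = traj, census = censusAll,
                             stringsAsFactors = FALSE)
    cl <- lapply(design@sampleGenerations, function(g) {
      p <- traj[g + 1L]
      if (design@deterministic) {
        hi <- rep(round(p * design@readDepth), length(design@snpIds))
        reads <- cbind(count_HI = hi, count_HII = design@readDepth - hi)
      } else {
        pool <- samplePool(p, censusAll[g + 1L], design@poolSize)
        reads <- sampleReads(pool[["HI"]], design@poolSize,
                             design@readDepth, length(design@snpIds))
      }
      data.frame(sample_id = sprintf("%s_g%02d", row$line_id, g),
                 line_id = row$line_id, generation = g,
                 snp_id = design@snpIds,
                 count_HI = as.integer(reads[, "count_HI"]),
                 count_HII = as.integer(reads[, "count_HII"]),
                 stringsAsFactors = FALSE)
    })
    counts[[i]] <- do.call(rbind, cl)
  }
  list(design = dt,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       counts = do.call(rbind, c(counts, list(make.row.names = FALSE))))
}
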