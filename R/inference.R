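## Replicated-line inference: split-plot repeated-measures ANOVA,
## permutation tests of between-line effects, bootstrap CIs, global t-test.

#' Response matrix for the repeated-measures analyses
#'
#' Reduces per-line, per-interval estimates to the wide layout the
#' split-plot ANOVA expects: one row per line with the two repeated measures
#' (intervals 0–5 and 5–10) as columns, plus the two between-line factors.
#' Starting frequency is coded as rare/common of haplotype HI (0.2 = rare,
#' 0.8 = common).
#'
#' @param lines Line records ([buildLineRecords()]) with design columns.
#' @param response `"s_I"` for the selection coefficient or `"delta_f"` for
#'   the per-generation frequency change.
#' @param sampleGenerations The two sampled generations (default `c(5, 10)`).
#' @return A `data.frame` with columns `line_id`, `sf` (factor rare/common),
#'   `environment` (factor), `y1`, `y2` (the interval 0–5 and 5–10
#'   responses), with the response kind in attribute `"response"`.
#' @export
responseMatrix <- function(lines, response = c("s_I", "delta_f"),
                           sampleGenerations = c(5, 10)) {
  response <- match.arg(response)
  est <- lineSelectionEstimates(lines, sampleGenerations)
  if (response == "s_I" && any(est$flag != "ok")) {
    stop("selection estimator undefined for line(s) ",
         paste(unique(est$line_id[est$flag != "ok"]), collapse = ", "),
         call. = FALSE)
  }
  val <- est[[response]]
  ivs <- sort(unique(est$interval))
  wide <- data.frame(
    line_id = lines$line_id,
    sf = factor(ifelse(lines$start_freq < 0.5, "rare", "common"),
                levels = c("rare", "common")),
    environment = factor(lines$environment),
    y1 = val[match(paste(lines$line_id, ivs[1]),
                   paste(est$line_id, est$interval))],
    y2 = val[match(paste(lines$line_id, ivs[2]),
                   paste(est$line_id, est$interval))],
    stringsAsFactors = FALSE)
  .checkBalance(wide)
  attr(wide, "response") <- response
  attr(wide, "intervals") <- ivs
  wide
}

.checkBalance <- function(resp) {
  need <- c("line_id", "sf", "environment", "y1", "y2")
  if (!all(need %in% names(resp))) {
    stop("response matrix must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nlevels(factor(resp$sf)) != 2L ||
      nlevels(factor(resp$environment)) != 2L) {
    stop("both between-line factors must have two levels", call. = FALSE)
  }
  tab <- table(resp$sf, resp$environment)
  if (length(unique(as.vector(tab))) != 1L || any(tab < 1L)) {
    stop("unbalanced design: unequal lines per factor cell", call. = FALSE)
  }
  if (anyNA(resp$y1) || anyNA(resp$y2)) {
    stop("response matrix contains missing repeated measures", call. = FALSE)
  }
  invisible(resp)
}

## Between-line F statistics computed from line means of a balanced 2x2
## design via orthogonal +/-1 contrasts.  `m` may be a matrix with one
## column per (permuted) dataset.  Identical to the between stratum of the
## split-plot ANOVA; used by the permutation engine where refitting aov
## thousands of times would be wasteful.
.betweenF <- function(m, a, b) {
  m <- as.matrix(m)
  n <- length(a)
  ab <- a * b
  ssA <- colSums(m * a)^2 / n
  ssB <- colSums(m * b)^2 / n
  ssAB <- colSums(m * ab)^2 / n
  ssT <- colSums(scale(m, scale = FALSE)^2)
  ssE <- pmax(ssT - ssA - ssB - ssAB, 0)
  msE <- ssE / (n - 4L)
  rbind(SF = ssA / msE, E = ssB / msE, `SF:E` = ssAB / msE)
}

.codes <- function(resp) {
  list(a = ifelse(resp$sf == levels(resp$sf)[1], -1, 1),
       b = ifelse(resp$environment == levels(resp$environment)[1], -1, 1))
}

#' Split-plot repeated-measures ANOVA for the 2 x 2 replicated-line design
#'
#' Fits the classical within-subjects ANOVA with each line as the subject:
#' starting frequency (SF) and environment (E) are between-line factors
#' tested against the line-within-cell residual, and generation interval (G:
#' 0–5 vs 5–10) and its interactions are within-line effects tested against
#' the G-by-line residual.  Sums of squares come from base R's
#' `aov(y ~ SF * E * G + Error(line))`.  Optionally appends permutation
#' p-values for the three between-line terms
#' ([permutationTestBetween()]).
#'
#' @param resp A response matrix from [responseMatrix()] (or any
#'   `data.frame` with columns `line_id`, `sf`, `environment`, `y1`, `y2`
#'   describing a balanced 2 x 2 design with two repeated measures).
#' @param nPerm Number of permutations for the between-line terms; `0`
#'   (default) skips the permutation column.
#' @param seed Seed for the permutation draw (required when `nPerm > 0`).
#' @return A `data.frame` with columns `stratum` (`between`/`within`),
#'   `term`, `df`, `SS`, `MS`, `F`, `p`, and `p_perm` when requested.  A
#'   response with no variation yields zero sums of squares and `NaN` F
#'   ratios.
#' @export
#' @examples
#' sim <- simulateExperiment(experimentDesign(), seed = 1)
#' lines <- buildLineRecords(PoolSeqCounts(sim$counts), sim$design)
#' rmAnova(responseMatrix(lines, "delta_f"))
rmAnova <- function(resp, nPerm = 0L, seed = NULL) {
  .checkBalance(resp)
  long <- data.frame(
    y = c(resp$y1, resp$y2),
    SF = factor(rep(resp$sf, 2L)),
    E = factor(rep(resp$environment, 2L)),
    G = factor(rep(c("g1", "g2"), each = nrow(resp))),
    line = factor(rep(resp$line_id, 2L)))
  fit <- aov(y ~ SF * E * G + Error(line), data = long)
  sm <- summary(fit)
  pick <- function(stratum, labels, rename) {
    tab <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    idx <- match(labels, rn)
    data.frame(stratum = if (stratum == "Error: line") "between" else
                 "within",
               term = rename,
               df = tab$Df[idx],
               SS = tab$`Sum Sq`[idx],
               MS = tab$`Mean Sq`[idx],
               F = if ("F value" %in% colnames(tab)) tab$`F value`[idx]
                   else NA_real_,
               p = if ("Pr(>F)" %in% colnames(tab)) tab$`Pr(>F)`[idx]
                   else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    pick("Error: line", c("SF", "E", "SF:E", "Residuals"),
         c("SF", "E", "SF:E", "Residual")),
    pick("Error: Within", c("G", "SF:G", "E:G", "SF:E:G", "Residuals"),
         c("G", "G:SF", "G:E", "G:SF:E", "Residual")))
  rownames(out) <- NULL
  term <- out$term != "Residual"
  out$F[term & !is.finite(out$F)] <- NaN
  ## a response with no variation at all: report exact zeros and flagged F
  ## rather than the ~1e-31 rounding residue the linear-model fit leaves
  if (all(long$y == long$y[1])) {
    out$SS <- 0
    out$MS <- 0
    out$F[term] <- NaN
    out$p <- NA_real_
  }
  if (nPerm > 0L) {
    out$p_perm <- NA_real_
    for (term in c("SF", "E", "SF:E")) {
      out$p_perm[out$stratum == "between" & out$term == term] <-
        permutationTestBetween(resp, term, nPerm = nPerm, seed = seed)
    }
  }
  out
}

#' Permutation test of a between-line effect
#'
#' Randomly permutes the (SF, E) factor-label pairs across lines — keeping
#' each line's two repeated measures together — and recomputes the term's
#' between-stratum F each time.  The p-value uses the add-one convention
#' `(b + 1) / (nPerm + 1)` on the upper tail of F.  When the observed F is
#' undefined (no variation), the maximal p-value 1 is returned.
#'
#' @param resp A response matrix (see [rmAnova()]).
#' @param term One of `"SF"`, `"E"`, `"SF:E"`.
#' @param nPerm Number of random permutations (default 9999).
#' @param seed Seed for the permutation draw.
#' @return The permutation p-value.
#' @export
permutationTestBetween <- function(resp, term = c("SF", "E", "SF:E"),
                                   nPerm = 9999L, seed = NULL) {
  term <- match.arg(term)
  .checkBalance(resp)
  if (!is.null(seed)) set.seed(seed)
  m <- (resp$y1 + resp$y2) / 2
  cd <- .codes(resp)
  fObs <- .betweenF(m, cd$a, cd$b)[term, 1]
  if (!is.finite(fObs)) return(1)
  n <- length(m)
  perms <- vapply(seq_len(nPerm), function(i) m[sample.int(n)], numeric(n))
  fPerm <- .betweenF(perms, cd$a, cd$b)[term, ]
  (sum(fPerm >= fObs, na.rm = TRUE) + 1) / (nPerm + 1)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the per-line values with replacement and returns the sample
#' mean with a percentile interval over the bootstrap means.
#'
#' @param values Numeric vector of per-line responses (length >= 1).
#' @param nBoot Number of bootstrap replicates (default 9999).
#' @param level Confidence level (default 0.95).
#' @param seed Seed for the resampling.
#' @return A `data.frame` row: `estimate`, `lower`, `upper`, `n`, `n_boot`.
#'   A single value yields a degenerate zero-width interval with a warning.
#' @export
#' @examples
#' bootstrapMeanCI(rnorm(12, 0.2, 0.05), nBoot = 999, seed = 1)
bootstrapMeanCI <- function(values, nBoot = 9999L, level = 0.95,
                            seed = NULL) {
  if (length(values) == 0L) stop("no values to bootstrap", call. = FALSE)
  if (anyNA(values)) stop("values contain NA", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  if (n == 1L) {
    warning("single value: degenerate zero-width interval", call. = FALSE)
    return(data.frame(estimate = values, lower = values, upper = values,
                      n = 1L, n_boot = nBoot))
  }
  idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), nrow = nBoot)
  means <- rowMeans(matrix(values[idx], nrow = nBoot))
  alpha <- (1 - level) / 2
  q <- unname(quantile(means, c(alpha, 1 - alpha)))
  data.frame(estimate = mean(values), lower = q[1], upper = q[2],
             n = n, n_boot = nBoot)
}

#' Global one-sample t-test of the mean selection coefficient
#'
#' Tests whether the mean per-line selection coefficient differs from zero.
#' Each line contributes one value: the arithmetic mean of its two interval
#' estimates (so 12 lines give 11 degrees of freedom).
#'
#' @param perLineS Numeric vector, one `s_I` value per line; flagged
#'   (missing) estimates are an error.
#' @return A list with `t`, `df`, `p` and `mean`.  A zero-variance input is
#'   flagged: `t` is `NaN` with a warning.
#' @export
#' @examples
#' globalTTest(c(1, 2, 3))  # t = 3.4641, df = 2
globalTTest <- function(perLineS) {
  if (anyNA(perLineS)) {
    stop("per-line selection estimates contain undefined values",
         call. = FALSE)
  }
  if (length(perLineS) < 2L) stop("need at least two lines", call. = FALSE)
  if (sd(perLineS) == 0) {
    warning("zero variance across lines: t statistic undefined",
            call. = FALSE)
    return(list(t = NaN, df = length(perLineS) - 1L, p = NA_real_,
                mean = mean(perLineS)))
  }
  tt <- t.test(perLineS, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(perLineS))
}

#' Per-line mean selection coefficients
#'
#' @param resp A response matrix of `s_I` responses ([responseMatrix()]).
#' @return Numeric vector: `(y1 + y2) / 2` per line, named by `line_id`.
#' @export
perLineMeans <- function(resp) {
  .checkBalance(resp)
  setNames((resp$y1 + resp$y2) / 2, resp$line_id)
}

#' Group mean selection coefficients with bootstrap intervals
#'
#' For each cell of the 2 x 2 design (starting frequency x environment),
#' bootstraps the mean of that cell's per-line mean responses.
#'
#' @param resp A response matrix ([responseMatrix()]).
#' @param nBoot,level,seed Passed to [bootstrapMeanCI()]; each cell uses an
#'   independent seed derived from `seed`.
#' @return A `data.frame` with one row per cell: `sf`, `environment`,
#'   `estimate`, `lower`, `upper`, `n`, `n_boot`.
#' @export
groupMeans <- function(resp, nBoot = 9999L, level = 0.95, seed = NULL) {
  .checkBalance(resp)
  m <- perLineMeans(resp)
  cells <- expand.grid(sf = levels(factor(resp$sf)),
                       environment = levels(factor(resp$environment)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- resp$sf == cells$sf[i] & resp$environment == cells$environment[i]
    ci <- bootstrapMeanCI(m[sel], nBoot = nBoot, level = level,
                          seed = if (is.null(seed)) NULL else seed + i)
    cbind(cells[i, , drop = FALSE], ci)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
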