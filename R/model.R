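## Core NFDS model: linear frequency-dependent fitness with a 0.5 attractor,
## the one-generation forward recursion, and its closed-form inverse.

# Frequencies are clamped to [0,1] after floating arithmetic; values outside
# [-tol, 1+tol] are an error, not silently clamped.
.clampFreq <- function(p, what = "frequency", tol = 1e-12) {
  if (any(!is.finite(p))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  if (any(p < -tol | p > 1 + tol)) {
    stop(what, " outside [0, 1]: ", paste(signif(p[p < -tol | p > 1 + tol], 6),
         collapse = ", "), call. = FALSE)
  }
  pmin(pmax(p, 0), 1)
}

#' Largest admissible frequency-dependent selection coefficient
#'
#' The fitness map \eqn{W_I = 1 - p_I s_I}, \eqn{W_{II} = 1 - p_{II} s_I}
#' yields mean fitness \eqn{\bar W = 1 - s_I (p_I^2 + p_{II}^2)}, which must
#' stay positive for the forward recursion to be defined.  This returns the
#' supremum of admissible `s` at a given frequency, \eqn{1/(p_I^2+p_{II}^2)}.
#'
#' @param pI Numeric vector of HI frequencies in `[0, 1]`.
#' @return Numeric vector of upper bounds on `s`.
#' @export
#' @examples
#' admissibleSMax(0.5)  # 2: the most permissive point
#' admissibleSMax(0)    # 1
admissibleSMax <- function(pI) {
  pI <- .clampFreq(pI, "pI")
  1 / (pI^2 + (1 - pI)^2)
}

#' Haplotype fitnesses under the linear NFDS map
#'
#' Evaluates \eqn{W_I = 1 - p_I s_I}, \eqn{W_{II} = 1 - p_{II} s_I} and the
#' mean fitness \eqn{\bar W = p_I W_I + p_{II} W_{II}} at a given HI frequency.
#' Positive `sI` penalises whichever haplotype is common, so the model has a
#' stable internal equilibrium at \eqn{p_I = 0.5}.
#'
#' @param pI Numeric vector of HI frequencies in `[0, 1]`.
#' @param sI Numeric vector (recycled) of frequency-dependent selection
#'   coefficients.
#' @return A `data.frame` with columns `W_I`, `W_II`, `W_bar` and a logical
#'   `admissible` flag (`W_bar > 0`).
#' @export
#' @examples
#' fitnessPair(0.2, 0.5)  # W_I = 0.9, W_II = 0.6, W_bar = 0.66
fitnessPair <- function(pI, sI) {
  pI <- .clampFreq(pI, "pI")
  n <- max(length(pI), length(sI))
  pI <- rep_len(pI, n); sI <- rep_len(sI, n)
  pII <- 1 - pI
  WI <- 1 - pI * sI
  WII <- 1 - pII * sI
  Wbar <- pI * WI + pII * WII
  data.frame(W_I = WI, W_II = WII, W_bar = Wbar, admissible = Wbar > 0)
}

#' Expected one-generation change in HI frequency
#'
#' The deterministic forward recursion
#' \deqn{\Delta p_I = p_I p_{II} (W_I - W_{II}) / \bar W}
#' of the NFDS model.  Zero at the boundaries and at the 0.5 equilibrium;
#' for admissible `sI > 0` the change always points toward 0.5.
#'
#' @inheritParams fitnessPair
#' @return Numeric vector of expected per-generation changes in `pI`.
#'   Errors when `W_bar <= 0` (inadmissible `sI` at that frequency).
#' @export
#' @examples
#' forwardDeltaP(0.5, 0.3)        # 0 at the attractor
#' forwardDeltaP(0.2, 5 / 13)     # 0.05
forwardDeltaP <- function(pI, sI) {
  fp <- fitnessPair(pI, sI)
  if (any(!fp$admissible)) {
    stop("mean fitness W_bar <= 0: s_I inadmissible at this frequency ",
         "(need s_I < 1/(p_I^2 + p_II^2))", call. = FALSE)
  }
  pI <- .clampFreq(pI, "pI")
  pI <- rep_len(pI, nrow(fp))
  pI * (1 - pI) * (fp$W_I - fp$W_II) / fp$W_bar
}

## Detailed estimator: returns the coefficient and a flag describing
## degenerate inputs.  Flags: "ok", "boundary_p" (p in {0,1}),
## "zero_denominator" (includes the 0/0 case at p = 0.5 with no change).
.estimateSDetail <- function(pI, deltaP, tol = 1e-12) {
  pI <- .clampFreq(pI, "pI")
  n <- max(length(pI), length(deltaP))
  pI <- rep_len(pI, n); deltaP <- rep_len(deltaP, n)
  pII <- 1 - pI
  num <- -deltaP * pI - deltaP * pII
  den <- -deltaP * pII^2 - pI * pII^2 + pI^2 * pII - deltaP * pI^2
  s <- num / den
  flag <- rep("ok", n)
  flag[abs(den) < tol] <- "zero_denominator"
  flag[pI <= 0 | pI >= 1] <- "boundary_p"
  s[flag != "ok"] <- NA_real_
  list(s = s, flag = flag)
}

#' Closed-form frequency-dependent selection-coefficient estimator
#'
#' Inverts the forward NFDS recursion: given the HI frequency `pI` at the
#' start of a generation and the observed per-generation change `deltaP`,
#' returns the coefficient
#' \deqn{s_I = \frac{-\Delta p\, p_I - \Delta p\, p_{II}}
#'   {-\Delta p\, p_{II}^2 - p_I p_{II}^2 + p_I^2 p_{II} - \Delta p\, p_I^2}}
#' which is the exact algebraic inverse of [forwardDeltaP()].  Positive values
#' mean the observed change points toward the 0.5 attractor (negative
#' frequency dependence), negative values away from it.
#'
#' The estimator is undefined at fixation (`pI` of 0 or 1) and when the
#' denominator vanishes — notably the 0/0 case `pI = 0.5`, `deltaP = 0`,
#' where any `s` is consistent with no change.  Undefined cases are returned
#' as `NA` with a warning, never as a silent number.
#'
#' @param pI Numeric vector of HI frequencies at the start of the interval,
#'   strictly inside `(0, 1)` for a defined estimate.
#' @param deltaP Numeric vector (recycled) of observed per-generation changes.
#' @return Numeric vector of `s_I` estimates (`NA` where undefined).
#' @seealso [lineSelectionEstimates()] for the per-line, per-interval wrapper.
#' @export
#' @examples
#' estimateS(0.2, 0.05)   # 5/13 = 0.3846...
#' estimateS(0.8, -0.05)  # same, by symmetry
estimateS <- function(pI, deltaP) {
  d <- .estimateSDetail(pI, deltaP)
  if (any(d$flag != "ok")) {
    warning("estimateS undefined for ", sum(d$flag != "ok"), " input(s): ",
            paste(unique(d$flag[d$flag != "ok"]), collapse = ", "),
            call. = FALSE)
  }
  d$s
}

#' Per-generation haplotype frequency change over an interval
#'
#' \eqn{\Delta f = (f_{end} - f_{start}) / (g_{end} - g_{start})}, the
#' per-generation rate of change used as the response in the replicated-line
#' analyses (e.g. \eqn{\Delta f_{0-5} = (f_5 - f_0)/5}).
#'
#' @param fStart,fEnd HI frequencies at the interval endpoints, in `[0, 1]`.
#' @param genStart,genEnd Integer generations; `genEnd > genStart`.
#' @return Numeric vector of per-generation frequency changes.
#' @export
#' @examples
#' deltaF(0.8, 0.7, 0, 5)  # -0.02
deltaF <- function(fStart, fEnd, genStart, genEnd) {
  fStart <- .clampFreq(fStart, "fStart")
  fEnd <- .clampFreq(fEnd, "fEnd")
  if (any(genEnd <= genStart)) {
    stop("genEnd must be greater than genStart", call. = FALSE)
  }
  (fEnd - fStart) / (genEnd - genStart)
}

#' Interval selection-coefficient estimates for replicated lines
#'
#' For each line, computes the per-generation frequency change and the
#' frequency-dependent selection coefficient for the two repeated measures:
#' generations 0–5 and 5–10 (or the two intervals defined by
#' `sampleGenerations`).  Following the repeated-measures design, the
#' frequency entering the estimator is the one observed at the *start* of
#' each interval, paired with that interval's per-generation \eqn{\Delta f}.
#'
#' @param lines A `data.frame` of line records with columns `line_id`, `f0`,
#'   and one `f<g>` column per sampled generation (e.g. `f5`, `f10`), as
#'   produced by [buildLineRecords()].
#' @param sampleGenerations Integer vector of the two sampled generations
#'   (default `c(5, 10)`).
#' @return A `data.frame` with one row per line and interval: `line_id`,
#'   `interval` (e.g. `"0-5"`), `p_start`, `delta_f`, `s_I`, and a `flag`
#'   column (`"ok"`, `"boundary_p"` or `"zero_denominator"`).
#' @export
#' @examples
#' lines <- data.frame(line_id = "L01", f0 = 0.2, f5 = 0.45, f10 = 0.45)
#' lineSelectionEstimates(lines)
lineSelectionEstimates <- function(lines, sampleGenerations = c(5, 10)) {
  stopifnot(is.data.frame(lines), length(sampleGenerations) == 2)
  gens <- c(0, sort(as.integer(sampleGenerations)))
  cols <- paste0("f", gens)
  missing <- setdiff(cols, names(lines))
  if (length(missing)) {
    stop("line records lack frequency column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(2), function(k) {
    g0 <- gens[k]; g1 <- gens[k + 1]
    f0 <- lines[[paste0("f", g0)]]
    f1 <- lines[[paste0("f", g1)]]
    df <- deltaF(f0, f1, g0, g1)
    est <- .estimateSDetail(f0, df)
    data.frame(line_id = lines$line_id,
               interval = sprintf("%d-%d", g0, g1),
               p_start = f0, delta_f = df,
               s_I = est$s, flag = est$flag,
               stringsAsFactors = FALSE)
  }))
  out[order(out$line_id, out$interval), , drop = FALSE]
}
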