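# Shared fixtures and independent oracles used across the suite.

# Balanced 2 x 2 response matrix with `reps` lines per cell and Gaussian
# responses (null unless shifted afterwards).
makeRespMatrix <- function(seed, reps = 3L, mean = 0, sd = 1) {
  set.seed(seed)
  n <- 4L * reps
  data.frame(
    line_id = sprintf("L%02d", seq_len(n)),
    sf = factor(rep(c("rare", "common"), each = n / 2L),
                levels = c("rare", "common")),
    environment = factor(rep(rep(c("homogeneous", "heterogeneous"),
                                 each = reps), 2L)),
    y1 = rnorm(n, mean, sd),
    y2 = rnorm(n, mean, sd),
    stringsAsFactors = FALSE)
}

# Independent split-plot oracle: between-stratum F from a GLM on line
# means, within-stratum F from a GLM on per-line difference scores.
oracleSplitPlotF <- function(resp) {
  m <- (resp$y1 + resp$y2) / 2
  d <- resp$y2 - resp$y1
  n <- nrow(resp)
  bet <- anova(lm(m ~ sf * environment, data = resp))
  wit <- anova(lm(d ~ sf * environment, data = resp))
  msRes <- wit["Residuals", "Mean Sq"]
  c(SF = bet$`F value`[1], E = bet$`F value`[2], `SF:E` = bet$`F value`[3],
    G = (sum(d)^2 / n) / msRes,
    `G:SF` = wit$`F value`[1], `G:E` = wit$`F value`[2],
    `G:SF:E` = wit$`F value`[3])
}

# Root-finding oracle for the selection-coefficient estimator: invert the
# forward recursion numerically instead of using the closed form.
bisectionS <- function(p, dp, tol = 1e-12) {
  f <- function(s) forwardDeltaP(p, s) - dp
  lo <- -0.999
  hi <- 1 / (p^2 + (1 - p)^2) - 1e-9
  stopifnot(sign(f(lo)) != sign(f(hi)))
  uniroot(f, c(lo, hi), tol = tol)$root
}

# aov-free F for one between term on line means, used by the exhaustive
# permutation oracle (kept lm-based, independent of the package engine).
lmBetweenF <- function(m, resp, term) {
  d <- resp
  d$m <- m
  a <- anova(lm(m ~ sf * environment, data = d))
  rn <- c(SF = "sf", E = "environment", `SF:E` = "sf:environment")[term]
  a[rn, "F value"]
}
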