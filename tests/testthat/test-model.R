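test_that("fitness pairs follow the linear NFDS map", {
  eq <- fitnessPair(0.5, 0.2)
  expect_equal(eq$W_I, 0.9)
  expect_equal(eq$W_II, 0.9)
  expect_equal(eq$W_bar, 0.9)

  neutral <- fitnessPair(0.2, 0)
  expect_equal(unlist(neutral[, c("W_I", "W_II", "W_bar")]),
               c(W_I = 1, W_II = 1, W_bar = 1))

  fp <- fitnessPair(0.2, 0.5)
  expect_equal(fp$W_I, 0.9)
  expect_equal(fp$W_II, 0.6)
  expect_equal(fp$W_bar, 0.2 * 0.9 + 0.8 * 0.6)

  # W_bar identity and the closed form 1 - s (p^2 + q^2)
  p <- seq(0, 1, by = 0.1); s <- 0.37
  fp <- fitnessPair(p, s)
  expect_equal(fp$W_bar, p * fp$W_I + (1 - p) * fp$W_II)
  expect_equal(fp$W_bar, 1 - s * (p^2 + (1 - p)^2))

  # inadmissible regime flagged
  expect_false(fitnessPair(0.1, 1.5)$admissible)
  expect_error(fitnessPair(-0.2, 0.1), "outside")
})

test_that("forward recursion is zero at equilibrium and boundaries", {
  for (s in c(-0.5, 0, 0.3, 0.9)) {
    expect_equal(forwardDeltaP(c(0, 0.5, 1), s), c(0, 0, 0))
  }
  expect_equal(forwardDeltaP(0.2, 0), 0)
  expect_equal(forwardDeltaP(0.2, 5 / 13), 0.05)
  expect_error(forwardDeltaP(0.1, 1.5), "W_bar")
})

test_that("closed-form estimator matches the root-finding oracle", {
  # frozen from the bisection oracle: s solving forwardDeltaP(0.2, s) = 0.05
  expect_equal(estimateS(0.2, 0.05), 0.3846153846153846, tolerance = 1e-12)
  expect_equal(estimateS(0.8, -0.05), 0.3846153846153846, tolerance = 1e-12)
  for (case in list(c(0.2, 0.05), c(0.8, -0.05), c(0.35, -0.02),
                    c(0.6, 0.013))) {
    expect_equal(estimateS(case[1], case[2]),
                 bisectionS(case[1], case[2]), tolerance = 1e-8)
  }
  # no change, no selection (except at the attractor)
  expect_equal(estimateS(c(0.2, 0.4, 0.9), 0), c(0, 0, 0))
})

test_that("estimator flags undefined inputs instead of returning numbers", {
  expect_warning(s <- estimateS(0.5, 0), "zero_denominator")
  expect_true(is.na(s))
  expect_warning(s <- estimateS(c(0, 1), 0.01), "boundary_p")
  expect_true(all(is.na(s)))
})

test_that("estimator and forward recursion are exact inverses", {
  ps <- setdiff(seq(0.05, 0.95, by = 0.05), 0.5)
  ss <- seq(-0.8, 0.95, by = 0.07)
  for (p in ps) {
    admissible <- ss[ss < admissibleSMax(p) - 1e-6]
    dp <- forwardDeltaP(p, admissible)
    expect_equal(estimateS(p, dp), admissible, tolerance = 1e-10)
  }
})

test_that("estimator sign follows the attractor convention and symmetry", {
  for (p in c(0.1, 0.25, 0.4)) {
    q <- 1 - p
    scaleDp <- p * q * (q - p) / (p^2 + q^2)
    for (frac in c(0.25, 0.75)) {
      toward <- frac * scaleDp    # p < 0.5, change toward 0.5
      away <- -frac * scaleDp
      expect_gt(estimateS(p, toward), 0)
      expect_lt(estimateS(p, away), 0)
      # mirrored above the attractor
      expect_gt(estimateS(1 - p, -toward), 0)
      expect_lt(estimateS(1 - p, -away), 0)
      # exact symmetry p -> 1 - p, dp -> -dp
      expect_equal(estimateS(p, toward), estimateS(1 - p, -toward),
                   tolerance = 1e-12)
    }
  }
})

test_that("deterministic iteration converges monotonically to 0.5", {
  for (p0 in c(0.05, 0.3, 0.95)) {
    p <- p0
    traj <- numeric(300)
    for (i in seq_along(traj)) {
      p <- p + forwardDeltaP(p, 0.3)
      traj[i] <- p
    }
    dirs <- diff(c(p0, traj))
    expect_true(all(dirs >= 0) || all(dirs <= 0))  # flat once converged
    expect_true(all(diff(abs(c(p0, traj) - 0.5)) <= 0))
    expect_equal(traj[300], 0.5, tolerance = 1e-6)
  }
})

test_that("per-generation frequency change is endpoint arithmetic", {
  expect_equal(deltaF(0.8, 0.7, 0, 5), -0.02)
  expect_equal(deltaF(0.7, 0.8, 5, 10), 0.02)
  expect_equal(deltaF(0.2, 0.3, 0, 10), 0.01)
  expect_error(deltaF(0.2, 0.3, 5, 5), "greater")
  expect_error(deltaF(1.2, 0.3, 0, 5), "outside")
})

test_that("line estimates pair interval-start frequency with interval delta", {
  flat <- data.frame(line_id = "L01", f0 = 0.2, f5 = 0.2, f10 = 0.2)
  est <- lineSelectionEstimates(flat)
  expect_equal(est$s_I, c(0, 0))
  expect_equal(est$interval, c("0-5", "5-10"))

  line <- data.frame(line_id = "L01", f0 = 0.2, f5 = 0.45, f10 = 0.45)
  est <- lineSelectionEstimates(line)
  expect_equal(est$s_I[est$interval == "0-5"], estimateS(0.2, 0.05))
  expect_equal(est$s_I[est$interval == "5-10"], 0)

  down <- data.frame(line_id = "L01", f0 = 0.8, f5 = 0.55, f10 = 0.55)
  est <- lineSelectionEstimates(down)
  expect_equal(est$s_I[est$interval == "0-5"], estimateS(0.8, -0.05))

  # undefined flags propagate
  fixed <- data.frame(line_id = "L01", f0 = 1, f5 = 1, f10 = 1)
  est <- lineSelectionEstimates(fixed)
  expect_true(all(est$flag == "boundary_p"))
  expect_true(all(is.na(est$s_I)))

  expect_error(lineSelectionEstimates(data.frame(line_id = "L01", f0 = 0.2)),
               "f5")
})
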