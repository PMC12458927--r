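# Two-state relaxation model: identities, fitting, bootstrap.

test_that("equilibrium fraction and residence time follow the rates", {
  expect_equal(aEq(1, 1), 0.5)
  expect_equal(aEq(0, 2), 0)
  expect_equal(round(aEq(0.052, 0.2385), 3), 0.179)
  expect_error(aEq(0, 0), "> 0")
  expect_error(aEq(-0.1, 0.2), ">= 0")

  expect_equal(signif(meanResidenceTime(0.052), 3), 19.2)
  expect_equal(meanResidenceTime(1), 1)
  expect_equal(meanResidenceTime(0.1), 10)
  expect_error(meanResidenceTime(0), "> 0")
})

test_that("the relaxation solution obeys its boundary behaviour", {
  expect_equal(relaxFraction(0, 0, a0 = 0.45, aEq = 0.2, lambda = 0.3),
               0.45)
  expect_equal(relaxFraction(1e6, 0, a0 = 0.45, aEq = 0.2, lambda = 0.3),
               0.2)
  expect_equal(relaxFraction(4, 0, a0 = 0.06, aEq = 0.20, lambda = 0.2905),
               0.20 - 0.14 * exp(-1.162))
  # monotone and confined between a0 and aEq
  t <- seq(0, 30, by = 0.25)
  a <- relaxFraction(t, 0, a0 = 0.06, aEq = 0.179, lambda = 0.2905)
  expect_true(all(diff(a) > 0))
  expect_true(all(a >= 0.06 & a <= 0.179))
  expect_error(relaxFraction(-1, 0, a0 = 0.5, aEq = 0.5, lambda = 1),
               "t0")
})

test_that("the closed form solves the two-state ODE", {
  # dA/dt = kon - (kon + koff) A, checked algebraically and numerically
  set.seed(2)
  for (rep in 1:10) {
    kon <- runif(1, 0.01, 1)
    koff <- runif(1, 0.01, 1)
    lambda <- kon + koff
    aEqVal <- aEq(kon, koff)
    a0 <- runif(1)
    t <- runif(1, 0, 50)
    a <- relaxFraction(t, 0, a0, aEqVal, lambda)
    dAdt <- -lambda * (a - aEqVal)            # derivative of the closed form
    expect_lt(abs(dAdt - (kon - lambda * a)), 1e-12)
  }
  skip_if_not_installed("deSolve")
  for (rep in 1:5) {
    kon <- runif(1, 0.02, 0.5)
    koff <- runif(1, 0.02, 0.5)
    a0 <- runif(1)
    tt <- seq(0, 50, by = 1)
    num <- deSolve::ode(
      y = c(A = a0), times = tt,
      func = function(t, y, p) list(kon - (kon + koff) * y[1]),
      parms = NULL, rtol = 1e-12, atol = 1e-12
    )
    ana <- relaxFraction(tt, 0, a0, aEq(kon, koff), kon + koff)
    expect_lt(max(abs(num[, "A"] - ana)), 1e-8)
  }
})

test_that("time to equilibrium inverts the exponential decay", {
  expect_equal(timeToEquilibrium(0.2, 0.2, 0.3, 0.005), 0)
  expect_equal(timeToEquilibrium(0.25, 0.2, 0.3, 0.1), 0)
  expect_equal(timeToEquilibrium(0.06, 0.179, 0.2905, 0.005),
               log(0.119 / 0.005) / 0.2905)
  expect_equal(round(timeToEquilibrium(0.06, 0.179, 0.2905, 0.005), 1),
               10.9)
})

test_that("noiseless joint fits recover the generating parameters", {
  kon <- 0.052; koff <- 0.2385
  for (seed in c(1, 5, 9)) {
    traj <- simulatePopulationTrajectories(
      kon, koff, c(high = 0.45, low = 0.06), c(1, 4, 6, 10), 500, 1,
      seed = seed
    )
    traj$fraction_transcribing <- traj$true_fraction
    fit <- fitRelaxation(traj, "fitted_equilibrium", seed = seed)
    expect_lt(abs(relaxationRate(fit) - (kon + koff)) / (kon + koff), 1e-4)
    expect_lt(abs(equilibriumFraction(fit) - aEq(kon, koff)) /
                aEq(kon, koff), 1e-4)
    expect_lt(abs(initialFractions(fit)[["high"]] - 0.45) / 0.45, 1e-3)
    expect_lt(abs(initialFractions(fit)[["low"]] - 0.06) / 0.06, 1e-3)
    # derived identities hold by construction
    expect_equal(konRate(fit) + koffRate(fit), relaxationRate(fit))
    expect_equal(konRate(fit) / relaxationRate(fit),
                 equilibriumFraction(fit))
  }
})

test_that("fixed-equilibrium mode pins kon to aEq * lambda", {
  traj <- simulatePopulationTrajectories(
    0.052, 0.2385, c(high = 0.45, low = 0.06), c(1, 4, 6, 10), 500, 3,
    seed = 42
  )
  fit <- fitRelaxation(traj, "fixed_equilibrium", aEqFixed = 0.20)
  expect_equal(equilibriumFraction(fit), 0.20)
  expect_equal(konRate(fit), 0.20 * relaxationRate(fit))
  pred <- predictRelaxation(fit, c(0, 21))
  expect_identical(nrow(pred), 4L)
  expect_equal(pred$fraction_transcribing[pred$day == 0],
               unname(initialFractions(fit)[pred$population[pred$day == 0]]))
})

test_that("unidentifiable designs are refused", {
  flat <- data.frame(
    population = rep(c("a", "b"), each = 4),
    day = rep(c(1, 4), 4), fraction_transcribing = 0.2,
    n_cells = 100L, replicate = rep(1:2, each = 2)
  )
  expect_error(fitRelaxation(flat), "unidentifiable")
  oneDay <- data.frame(
    population = c("a", "a", "b", "b"), day = c(1, 1, 1, 4),
    fraction_transcribing = c(0.1, 0.2, 0.3, 0.4),
    n_cells = 100L, replicate = 1L
  )
  expect_error(fitRelaxation(oneDay), "distinct days")
  onePop <- data.frame(
    population = "a", day = c(1, 4, 6), fraction_transcribing = 0.1 * 1:3,
    n_cells = 100L, replicate = 1L
  )
  expect_error(fitRelaxation(onePop), "2 populations")
})

test_that("the bootstrap is deterministic and collapses without noise", {
  traj <- simulatePopulationTrajectories(
    0.052, 0.2385, c(high = 0.45, low = 0.06), c(1, 4, 6, 10), 500, 3,
    seed = 42
  )
  b1 <- bootstrapRelaxationCI(traj, "fitted_equilibrium", nBoot = 100,
                              seed = 5)
  b2 <- bootstrapRelaxationCI(traj, "fitted_equilibrium", nBoot = 100,
                              seed = 5)
  expect_identical(b1@ci, b2@ci)
  expect_lt(b1@ci$lambda[1], relaxationRate(b1))
  expect_gt(b1@ci$lambda[2], relaxationRate(b1))

  # identical replicates carry no resampling variability
  ident <- traj[traj$replicate == 1, ]
  ident <- do.call(rbind, lapply(1:3, function(r) {
    d <- ident; d$replicate <- r; d
  }))
  b0 <- bootstrapRelaxationCI(ident, "fitted_equilibrium", nBoot = 100,
                              seed = 6)
  expect_lt(diff(b0@ci$lambda), 1e-4)
  expect_lt(diff(b0@ci$aEq), 1e-4)

  expect_error(bootstrapRelaxationCI(traj, nBoot = 50), ">= 100")
})
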