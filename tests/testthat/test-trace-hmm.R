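# Two-state HMM segmentation and dwell-time summaries.

twoLevelTraceSet <- function(states, lo = 0, hi = 200, noise = 0,
                             dt = 100, seed = 1) {
  set.seed(seed)
  tr <- data.frame(
    allele_id = "a1", frame = seq_along(states) - 1L,
    intensity = ifelse(states == 1, hi, lo) + rnorm(length(states), 0, noise)
  )
  new("TraceSet", traces = tr, frameInterval = dt)
}

test_that("a noiseless two-level trace is fit and decoded exactly", {
  states <- rep(c(0L, 1L, 0L, 1L, 0L, 1L), c(30, 20, 25, 15, 35, 25))
  ts <- twoLevelTraceSet(states, lo = 10, hi = 210)
  hmm <- fitTelegraphHMM(ts)
  expect_equal(emissionMeans(hmm), c(10, 210), tolerance = 1e-6)
  dec <- decodeStates(ts, hmm)
  expect_identical(dec$state, states)
  expect_true(all(dec$posterior_active >= 0 & dec$posterior_active <= 1))
  # posterior of the active state is near 1 exactly on active frames
  expect_true(all(abs(dec$posterior_active - states) < 1e-6))
})

test_that("the active label always goes to the higher-mean state", {
  # mostly-active trace: the threshold init sees an inverted split
  states <- rep(c(1L, 0L, 1L), c(200, 30, 200))
  ts <- twoLevelTraceSet(states, lo = 5, hi = 100, noise = 8, seed = 3)
  hmm <- fitTelegraphHMM(ts)
  expect_gt(emissionMeans(hmm)[2], emissionMeans(hmm)[1])
  dec <- decodeStates(ts, hmm)
  expect_gt(mean(dec$state == states), 0.99)
})

test_that("degenerate inputs are refused", {
  flat <- new("TraceSet", traces = data.frame(
    allele_id = "a", frame = 0:19, intensity = rep(7, 20)
  ), frameInterval = 100)
  expect_error(fitTelegraphHMM(flat), "variance")
  short <- new("TraceSet", traces = data.frame(
    allele_id = "a", frame = 0:3, intensity = rnorm(4)
  ), frameInterval = 100)
  expect_error(fitTelegraphHMM(short), "10 frames")
})

test_that("Viterbi agrees with exhaustive path enumeration", {
  hmm <- new("TelegraphHMM",
    transition = matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE),
    means = c(0, 100), sds = c(30, 30), initProb = c(0.5, 0.5),
    logLik = 0, nIter = 0L, converged = TRUE
  )
  set.seed(11)
  for (rep in 1:5) {
    y <- rnorm(8, sample(c(0, 100), 8, replace = TRUE), 40)
    ts <- new("TraceSet",
              traces = data.frame(allele_id = "a", frame = 0:7,
                                  intensity = y),
              frameInterval = 100)
    dec <- decodeStates(ts, hmm)
    expect_identical(dec$state, oracleViterbi(y, hmm))
  }
  # alternating means with near-zero noise decode to the alternating path
  y <- rep(c(0, 100), 4) + rnorm(8, 0, 1e-3)
  ts <- new("TraceSet",
            traces = data.frame(allele_id = "a", frame = 0:7, intensity = y),
            frameInterval = 100)
  expect_identical(decodeStates(ts, hmm)$state, rep(c(0L, 1L), 4))
})

test_that("dwell extraction censors boundary runs and converts units", {
  d <- data.frame(allele_id = "a", frame = 0:5,
                  state = c(0L, 1L, 1L, 1L, 1L, 0L))
  dw <- extractDwells(d, dt = 100)
  expect_identical(nrow(dw$dwells), 3L)
  act <- dw$dwells[dw$dwells$state == 1L, ]
  expect_false(act$censored)
  expect_equal(act$minutes, 400 / 60)          # 4 frames at 100 s
  expect_equal(round(act$minutes, 2), 6.67)
  expect_equal(dw$median_active, 400 / 60)
  expect_true(is.na(dw$median_inactive))       # both OFF runs touch edges
  expect_identical(dw$n_censored_excluded, 2L)

  d2 <- data.frame(allele_id = "a", frame = 0:5,
                   state = c(1L, 1L, 0L, 0L, 1L, 1L))
  dw2 <- extractDwells(d2, dt = 100)
  expect_true(all(dw2$dwells$censored[dw2$dwells$state == 1L]))
  expect_equal(dw2$median_inactive, 200 / 60)
  # a 26-frame run reports 43.33 minutes
  d3 <- data.frame(allele_id = "a", frame = 0:27,
                   state = c(0L, rep(1L, 26), 0L))
  expect_equal(round(extractDwells(d3, 100)$median_active, 2), 43.33)
  # run lengths are conserved frame for frame
  expect_equal(sum(dw$dwells$frames), 6)
  # a trace with no change contributes only a censored run
  d4 <- data.frame(allele_id = "a", frame = 0:9, state = rep(1L, 10))
  dw4 <- extractDwells(d4, 100)
  expect_true(all(dw4$dwells$censored))
  expect_true(is.na(dw4$median_active))
})

test_that("the dwell CDF is the empirical distribution", {
  one <- dwellCDF(5)
  expect_equal(one$cdf, 1)
  cdf <- dwellCDF(c(2, 4, 4, 8))
  expect_equal(cdf$cdf[cdf$minutes == 4], 0.75)
  expect_error(dwellCDF(numeric(0)), "no dwells")
  # exponential sample: ECDF within 0.02 of the closed form
  set.seed(13)
  x <- rexp(1e4, 1 / 6.67)
  tab <- dwellCDF(x)
  expect_lt(max(abs(tab$cdf - pexp(tab$minutes, 1 / 6.67))), 0.02)
})

test_that("telegraph kinetics are recovered from noisy traces", {
  # mean ON 6.67 min (kOff = 0.15/min), mean OFF 43.3 min, SNR 5
  sim <- simulateTelegraphTraces(30, kOn = 1 / 43.3, kOff = 0.15,
                                 intensityPerRNA = 100, meanNascent = 2,
                                 noiseSd = 40, seed = 31)
  hmm <- fitTelegraphHMM(sim$traces)
  dec <- decodeStates(sim$traces, hmm)
  expect_gt(mean(dec$state == sim$states$state), 0.97)
  est <- extractDwells(dec, 100)
  truth <- extractDwells(sim$states, 100)
  expect_lt(abs(est$median_active - truth$median_active) /
              truth$median_active, 0.15)
  expect_lt(abs(est$median_inactive - truth$median_inactive) /
              truth$median_inactive, 0.15)
  # transition-probability dwell means agree with the generating rates
  dm <- hmmDwellMeans(hmm, 100)
  expect_lt(abs(dm[["active"]] - 6.67) / 6.67, 0.2)
  expect_lt(abs(dm[["inactive"]] - 43.3) / 43.3, 0.2)
})

test_that("decoding is invariant to affine rescaling when refit", {
  sim <- simulateTelegraphTraces(10, kOn = 0.05, kOff = 0.1,
                                 noiseSd = 30, seed = 8)
  dec1 <- decodeStates(sim$traces, fitTelegraphHMM(sim$traces))
  tr2 <- traces(sim$traces)
  tr2$intensity <- 3.7 * tr2$intensity + 250
  ts2 <- new("TraceSet", traces = tr2, frameInterval = 100)
  dec2 <- decodeStates(ts2, fitTelegraphHMM(ts2))
  expect_identical(dec1$state, dec2$state)
})
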