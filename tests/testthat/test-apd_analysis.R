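test_that("detector recovers trapezoid APDs to interpolation accuracy", {
  for (plateau in c(150, 300)) {
    fx <- makeFixtureTrace("trapezoid", nBeats = 4, plateau = plateau,
                           dt = 0.05)
    ser <- detectApds(fx$t, fx$V, fx$stimTimes)
    expect_true(all(ser$captured))
    expect_false(any(ser$capped))
    expect_lt(max(abs(ser$apd40 - fx$truth$apd40)), 0.05)
    expect_lt(max(abs(ser$apd90 - fx$truth$apd90)), 0.05)
  }
})

test_that("detector matches the closed-form exponential repolarization", {
  fx <- makeFixtureTrace("exponential", nBeats = 3, cl = 1000, tau = 70,
                         dt = 0.02)
  ser <- detectApds(fx$t, fx$V, fx$stimTimes)
  expect_lt(max(abs(ser$apd40 - fx$truth$apd40)), 0.02)
  expect_lt(max(abs(ser$apd90 - fx$truth$apd90)), 0.02)
})

test_that("alternans fixture yields a period-2 series and EAD-free flags", {
  fx <- makeFixtureTrace("alternans", nBeats = 6, plateau = c(150, 350),
                         cl = 500)
  ser <- detectApds(fx$t, fx$V, fx$stimTimes)
  expect_lt(max(abs(ser$apd40 - fx$truth$apd40)), 0.05)
  expect_equal(eadsim:::countDistinct(ser$apd40, 0.5), 2L)
  expect_false(any(ser$ead))
})

test_that("beats that never recross the threshold are capped at CL and flagged", {
  fx <- makeFixtureTrace("trapezoid", nBeats = 3, cl = 300, plateau = 400)
  ser <- detectApds(fx$t, fx$V, fx$stimTimes)
  expect_true(ser$capped[1])
  expect_equal(ser$apd40[1], 300)
})

test_that("a stimulus without an upstroke is a no-capture record, not an error", {
  t <- seq(0, 1000, by = 0.1)
  V <- rep(-80, length(t))
  ser <- detectApds(t, V, c(0, 500))
  expect_false(any(ser$captured))
  expect_true(all(is.na(ser$apd40)))
})

test_that("both APD conventions stretch linearly under uniform time dilation", {
  fx <- makeFixtureTrace("trapezoid", nBeats = 1, cl = 800, plateau = 200,
                         ramp = 60)
  ser1 <- detectApds(fx$t, fx$V, fx$stimTimes)
  ser2 <- detectApds(fx$t * 1.5, fx$V, fx$stimTimes * 1.5)
  expect_equal(ser2$apd40, 1.5 * ser1$apd40, tolerance = 1e-6)
  expect_equal(ser2$apd90, 1.5 * ser1$apd90, tolerance = 1e-6)
})

test_that("statistics discard the transient and normalize the histogram to max 1", {
  x <- c(500, 500, rep(c(200, 300), 50))
  st <- apdStatistics(x, discard = 2)
  expect_equal(st$mean, 250)
  expect_equal(st$sd, sd(rep(c(200, 300), 50)))
  expect_equal(st$cv, st$sd / 250)
  expect_equal(max(st$histogram$density), 1)
  expect_error(apdStatistics(c(1, 2), discard = 5), "discard")
  # constant series: zero spread
  st0 <- apdStatistics(rep(250, 20))
  expect_equal(st0$sd, 0)
  expect_equal(st0$cv, 0)
})

test_that("the detector flags a secondary plateau depolarization as an EAD", {
  # hand-built AP with a 12 mV bump during the plateau decay
  t <- seq(0, 600, by = 0.1)
  base <- -80 + ifelse(t > 5 & t <= 500, 100 * exp(-pmax(t - 10, 0) / 250), 0)
  V <- base
  bump <- t > 120 & t <= 220
  V[bump] <- V[bump] + 12 * sin(pi * (t[bump] - 120) / 100)
  ser <- detectApds(t, V, 0)
  expect_true(ser$ead[1])
  # same AP without the bump is clean
  expect_false(detectApds(t, base, 0)$ead[1])
})

test_that("online per-beat records agree with the trace-based detector", {
  run <- cachedRun("normal", beats = 6, traceDt = 0.1)
  ser <- detectApds(run$trace$t, run$trace$V,
                    stimTimes = run$beats$tStim)
  ok <- ser$captured & run$beats$capped %in% FALSE
  expect_gt(sum(ok), 3)
  expect_lt(max(abs(ser$apd40[ok] - run$beats$apd40[ok])), 0.25)
  # the 90% level depends weakly on the rest/peak sampling convention and
  # the final-phase slope is shallow, so allow a slightly wider margin
  expect_lt(max(abs(ser$apd90[ok] - run$beats$apd90[ok])), 1.5)
})
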