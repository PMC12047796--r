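test_that("the resting cell is stable without stimulation", {
  p <- defaultParams()
  pv <- eadsim:::asParamVector(p)
  s0 <- initCellState(p)
  out <- .engine_run(pv, matrix(as.numeric(s0), ncol = 1), 1L, 1L,
                     numeric(0), numeric(0), 1, FALSE, 1, 0L, 1,
                     numeric(0), 2000, FALSE)
  V <- out$trace$V
  expect_lt(diff(range(V[out$trace$t > 1000])), 0.5)
  expect_gt(min(V), -100); expect_lt(max(V), -70)
})

test_that("a suprathreshold pulse elicits an upstroke within 10 ms", {
  run <- cachedRun("normal", beats = 2, traceDt = 0.1)
  b <- run$beats[1, ]
  expect_true(is.finite(b$tUp))
  expect_lt(b$tUp - b$tStim, 10)
  expect_gt(b$peak, 0)
})

test_that("deterministic runs are bitwise reproducible; stochastic runs reproduce under a seed", {
  p <- defaultParams()
  r1 <- runPaced(p, pacingProtocol(400, 3), mode = "deterministic")
  r2 <- runPaced(p, pacingProtocol(400, 3), mode = "deterministic")
  expect_identical(r1$beats$apd40, r2$beats$apd40)
  expect_identical(r1$finalState, r2$finalState)
  s1 <- runPaced(p, pacingProtocol(400, 4), mode = "stochastic", seed = 77)
  s2 <- runPaced(p, pacingProtocol(400, 4), mode = "stochastic", seed = 77)
  s3 <- runPaced(p, pacingProtocol(400, 4), mode = "stochastic", seed = 78)
  expect_identical(s1$beats$apd40, s2$beats$apd40)
  expect_false(identical(s1$beats$apd40, s3$beats$apd40))
})

test_that("operator-split update is consistent under step halving", {
  p <- defaultParams()
  run <- function(dtF, dtS) {
    pp <- defaultParams(dtFast = dtF, dtSlow = dtS)
    runPaced(pp, pacingProtocol(450, 3), mode = "deterministic")$beats$apd40[3]
  }
  a1 <- run(0.01, 0.1)
  a2 <- run(0.005, 0.05)
  expect_lt(abs(a1 - a2), 1.5)
})

test_that("an integration blow-up names the failing component", {
  p <- defaultParams(gna = 90, dtFast = 1, dtSlow = 1, stimAmp = 500,
                     DV = 0)
  expect_error(runPaced(p, pacingProtocol(300, 2), mode = "deterministic"),
               "cell|step|negative|exit")
})

test_that("single-cell stochastic and deterministic modes agree in the large-Nb limit", {
  p <- defaultParams(Nb = 1e5)
  det <- runPaced(defaultParams(), pacingProtocol(420, 25),
                  mode = "deterministic")
  sto <- runPaced(p, pacingProtocol(420, 25), mode = "stochastic", seed = 5)
  expect_lt(abs(mean(tail(det$beats$apd40, 5)) -
                mean(tail(sto$beats$apd40, 5))), 1)
})

test_that("the normal preset stays period-1 across the studied pacing range", {
  p <- defaultParams("normal")
  for (cl in c(440, 552)) {
    r <- runPaced(p, pacingProtocol(cl, 60), mode = "deterministic")
    last <- tail(r$beats$apd40, 8)
    expect_lt(diff(range(last)), 1)
    expect_false(any(tail(r$beats$ead, 8)))
  }
})

test_that("reduced Ca-induced inactivation produces EAD alternans at slow pacing", {
  p <- defaultParams("ead")
  r <- runPaced(p, pacingProtocol(545, 80), mode = "deterministic")
  last <- tail(r$beats$apd40, 12)
  expect_gt(diff(range(last)), 80)       # large beat-to-beat alternation
  expect_true(any(tail(r$beats$ead, 12)))  # with EADs on a subset of beats
  expect_false(all(tail(r$beats$ead, 12)))
})

test_that("S1S2 restitution is monotone in DI, consistent at S2 = S1, and steep near EAD onset", {
  p <- defaultParams("ead")
  tab <- s1s2Restitution(p, s1 = 500, s2List = seq(300, 580, 40),
                         s1Beats = 30)
  expect_false(any(duplicated(round(tab$di, 6))))
  expect_false(is.unsorted(tab$di))
  # the S2 = S1 point reproduces the steady state
  base <- runPaced(p, pacingProtocol(500, 31), mode = "deterministic")
  iS1 <- which.min(abs(tab$s2 - 500))  # closest sample to S2 = S1
  expect_equal(tab$apd[iS1], tail(base$beats$apd40, 1), tolerance = 2)
  # an abrupt APD rise exists within the sampled DI range
  expect_gt(max(diff(tab$apd) / diff(tab$di)), 2)
})
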