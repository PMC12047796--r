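test_that("stability bound and geometry are validated up front", {
  p <- defaultParams(dtSlow = 0.1)
  expect_error(tissueGrid(defaultParams(DV = 8e-4), 10, 10), "stability|dx")
  g <- tissueGrid(p, 4, 2)
  expect_equal(dim(g$state), c(26L, 8L))
  expect_error(runPlanar(tissueGrid(p, 5, 2), pacingProtocol(400, 1),
                         stripWidth = 7), "strip")
})

test_that("a quiescent grid stays at rest and diffusion conserves mean voltage", {
  p <- defaultParams()
  g <- tissueGrid(p, 6, 4, mode = "deterministic")
  out <- eadsim:::runTissueEngine(g, numeric(0), numeric(0),
                                  rep(0, 24), 1, 1L, 500)
  expect_lt(diff(range(out$grid$state["V", ])), 1e-6)
  expect_lt(abs(out$grid$state["V", 1] - g$state["V", 1]), 3)
  # passive membrane (all conductances off): pure diffusion preserves the
  # spatial mean of a random voltage field
  p0 <- defaultParams(gna = 0, gkr = 0, gks = 0, gk1 = 0, gtos = 0,
                      gtof = 0, gnak = 0, gnaca = 0, gca = 0, gcab = 0)
  g0 <- tissueGrid(p0, 8, 3, mode = "deterministic")
  set.seed(3)
  g0$state["V", ] <- runif(24, -90, 20)
  m0 <- mean(g0$state["V", ])
  out0 <- eadsim:::runTissueEngine(g0, numeric(0), numeric(0),
                                   rep(0, 24), 1, 1L, 200)
  expect_equal(mean(out0$grid$state["V", ]), m0, tolerance = 1e-10)
  # and relaxes the field toward uniformity
  expect_lt(sd(out0$grid$state["V", ]), sd(g0$state["V", ]))
})

test_that("a uniformly stimulated uniform grid reproduces the single cell", {
  p <- defaultParams()
  g <- tissueGrid(p, 3, 3, mode = "deterministic")
  u <- runUniform(g, pacingProtocol(500, 2))
  single <- runPaced(p, pacingProtocol(500, 2), mode = "deterministic")
  expect_equal(u$beats$apd40, single$beats$apd40, tolerance = 1e-6)
  # diffusion term vanishes: every cell identical to 1e-6 mV
  expect_lt(diff(range(u$grid$state["V", ])), 1e-6)
})

test_that("a 1x1 grid reduces exactly to the stochastic single cell", {
  p <- defaultParams()
  g <- tissueGrid(p, 1, 1, mode = "stochastic")
  u <- runUniform(g, pacingProtocol(480, 4), seed = 123)
  s <- runPaced(p, pacingProtocol(480, 4), mode = "stochastic", seed = 123)
  expect_identical(u$beats$apd40, s$beats$apd40)
})

test_that("a full-width paced strip is equivalent to uniform pacing", {
  p <- defaultParams()
  gA <- tissueGrid(p, 4, 3, mode = "deterministic")
  a <- runPlanar(gA, pacingProtocol(450, 2), stripWidth = 4)
  gB <- tissueGrid(p, 4, 3, mode = "deterministic")
  b <- runUniform(gB, pacingProtocol(450, 2))
  expect_equal(a$beats$apd40, b$beats$apd40, tolerance = 1e-9)
})

test_that("plane waves propagate at about the reference conduction velocity", {
  p <- defaultParams()
  res <- conductionVelocity(p, nCells = 80, sites = c(25, 60))
  expect_gt(res$cv, 7); expect_lt(res$cv, 14)
  # activation times increase monotonically along the cable interior
  act <- res$activation[10:70]
  expect_true(all(diff(act) > 0))
})

test_that("halving the grid spacing changes conduction velocity by < 5%", {
  # the reference spacing (0.015 cm) only marginally resolves the upstroke
  # front at this slow conduction velocity, so grid convergence is assessed
  # from a spacing that resolves it; the paced source is scaled to a fixed
  # physical size
  cvAt <- function(dx, dtS) {
    p <- defaultParams(dx = dx, dtSlow = dtS, dtFast = 0.0025)
    n <- round(0.6 / dx)
    conductionVelocity(p, nCells = n, pacedCells = round(0.045 / dx),
                       sites = round(c(0.35, 0.75) * n))$cv
  }
  cv1 <- cvAt(0.003, 0.01)
  cv2 <- cvAt(0.0015, 0.005)
  expect_lt(abs(cv2 - cv1) / cv1, 0.05)
})

test_that("a premature stimulus into refractory tissue does not propagate", {
  p <- defaultParams("ead")
  blk <- blockThreshold(p, nx = 30, ny = 1, stimCols = 5, s1 = 500,
                        s1Beats = 4, s2List = c(400, 190))
  expect_true(blk$table$propagated[blk$table$s2 == 400])
  expect_false(blk$table$propagated[blk$table$s2 == 190])
  expect_true(is.finite(blk$diBlock))
})

test_that("the wavebreak detector counts excited components", {
  f <- matrix(-80, 10, 10)
  expect_false(detectWavebreak(f))
  f[1:10, 1:3] <- 0                      # one intact band
  expect_false(detectWavebreak(f))
  f[1:4, 7:9] <- 0                       # a detached excited island
  expect_true(detectWavebreak(f))
})
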