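test_that("diffusive fluxes vanish at equal concentrations and carry the right sign", {
  p <- defaultParams()
  ca <- caState(0.5, 0.5, 600, 600, p)
  f <- caFluxes(ca, pb = 0, V = -86, p)
  expect_equal(unname(f[["Jdc"]]), 0)
  expect_equal(unname(f[["Jdsr"]]), 0)
  ca2 <- caState(1.0, 0.2, 700, 500, p)
  f2 <- caFluxes(ca2, pb = 0, V = -86, p)
  expect_gt(f2[["Jdc"]], 0)    # J -> NJ when cb > ci
  expect_gt(f2[["Jdsr"]], 0)
  expect_error(caFluxes(c(-1, 0.1, 500, 500), 0, -86, p), "corruption")
})

test_that("release and uptake fluxes have the documented structure", {
  p <- defaultParams()
  ca <- caState(0.3, 0.3, 800, 800, p)
  f0 <- caFluxes(ca, pb = 0, V = -86, p)
  expect_equal(unname(f0[["Jrb"]]), 0)
  f1 <- caFluxes(ca, pb = 0.2, V = -86, p)
  expect_equal(unname(f1[["Jrb"]]), p[["gb"]] * 800 * 0.2)
  expect_gte(f1[["Jupb"]], 0)
  expect_gte(f1[["Jupi"]], 0)
})

test_that("zero fluxes leave the state unchanged and dt<=0 errors", {
  p <- defaultParams()
  ca <- caState(0.2, 0.2, 700, 700, p)
  zero <- setNames(rep(0, 10),
                   c("Jrb", "Jri", "Jupb", "Jupi", "Jdsr", "Jdc", "JCa",
                     "JNaCa", "Jleakb", "Jleaki"))
  expect_equal(as.numeric(caStep(ca, zero, 0.1, p)), as.numeric(ca))
  expect_error(caStep(ca, zero, 0, p), "dt")
})

test_that("a closed cell conserves volume-weighted total Ca", {
  # membrane fluxes disabled: total (free + buffered) Ca is invariant
  p <- defaultParams()
  ca <- caState(0.4, 0.15, 820, 640, p)
  tot0 <- totalCa(ca, p)
  pb <- 0.15
  for (i in 1:20000) {
    f <- caFluxes(ca, pb = pb, V = -86, p)
    f[["JCa"]] <- 0; f[["JNaCa"]] <- 0
    ca <- caStep(ca, f, 0.05, p)
    pb <- pb * 0.999
  }
  expect_equal(totalCa(ca, p), tot0, tolerance = 1e-8)
})

test_that("pure SR diffusion relaxes the gradient at the analytic rate", {
  # only Jdsr active: d(csrb - csri)/dt = -gdsr*betaSR*(1/vsrb + 1/vsri)*(csrb - csri)
  p <- defaultParams(gdc = 0, gsrleak = 0, vup = 0, gb = 0, gcab = 0)
  ca <- caState(0, 0, 900, 500, p)
  rate <- p[["gdsr"]] * p[["betaSR"]] * (1 / p[["vsrb"]] + 1 / p[["vsri"]])
  dt <- 0.05; n <- 4000
  d0 <- 400
  for (i in seq_len(n)) {
    f <- caFluxes(ca, pb = 0, V = -86, p)
    f[["JCa"]] <- 0; f[["JNaCa"]] <- 0
    ca <- caStep(ca, f, dt, p)
  }
  dEnd <- ca[["csrb"]] - ca[["csri"]]
  expect_equal(dEnd, d0 * exp(-rate * n * dt), tolerance = 1e-2)
  # diffusion in isolation never amplifies the gradient
  expect_lt(abs(dEnd), d0)
})

test_that("a spark episode depletes junctional SR and raises cb when uptake is off", {
  p <- defaultParams(vup = 0)
  ca <- caState(0.1, 0.1, 800, 800, p)
  for (i in 1:200) {
    f <- caFluxes(ca, pb = 0.3, V = -86, p)
    f[["JCa"]] <- 0; f[["JNaCa"]] <- 0
    ca <- caStep(ca, f, 0.05, p)
  }
  expect_lt(ca[["csrb"]], 800)
  expect_gt(ca[["cb"]], 0.1)
})

test_that("a step that would go negative raises a step-size error", {
  p <- defaultParams()
  ca <- caState(0.001, 0.001, 500, 500, p)
  f <- caFluxes(ca, pb = 0, V = -86, p)
  f[["Jupb"]] <- 1e3  # absurd uptake drains cb below zero in one step
  expect_error(caStep(ca, f, 1, p), "negative")
})

test_that("the unstimulated cell sits near a stationary resting balance", {
  p <- defaultParams()
  rest <- caRestingState(p, tMax = 8000)
  # advance the full cell a further second: drift must be tiny
  pv <- eadsim:::asParamVector(p)
  s0 <- initCellState(p, ca = as.list(rest))
  out <- .engine_run(pv, matrix(as.numeric(s0), ncol = 1), 1L, 1L,
                     numeric(0), numeric(0), 1, FALSE, 1, 0L, 0,
                     numeric(0), 1000, FALSE)
  fs <- out$finalState[, 1]
  expect_lt(abs(fs[12] - rest[["cb"]]), 0.02 * max(rest[["cb"]], 0.05))
  expect_lt(abs(fs[14] - rest[["csrb"]]) / rest[["csrb"]], 0.02)
})
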