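test_that("spline fit reproduces polynomial data and guards its domain", {
  di <- seq(50, 400, by = 25)
  apd <- 0.5 * di + 100
  map <- fitRestitution(di, apd)
  xs <- c(di, di[-length(di)] + 12.5)
  expect_lt(max(abs(map$fun(xs) - (0.5 * xs + 100))), 1e-9)
  expect_error(evalMapDomain <- eadsim:::evalMap(map, 401), "extrapolate")
  expect_error(fitRestitution(di[1:3], apd[1:3]), "4")
  expect_error(fitRestitution(c(1, 2, 2, 3), c(1, 2, 3, 4)), "increasing")
})

test_that("iteration preserves the pacing identity DI + APD = T", {
  di <- seq(50, 400, by = 25)
  map <- fitRestitution(di, 150 + 100 * tanh((di - 200) / 60))
  it <- iterateMap(map, T = 450, di0 = 200, nIter = 60)
  tr <- it$trajectory
  expect_equal(tr$di[-1] + tr$apd[-1], rep(450, nrow(tr) - 1),
               tolerance = 1e-12)
})

test_that("a constant map reaches its fixed point immediately", {
  di <- seq(50, 400, by = 50)
  map <- fitRestitution(di, rep(180, length(di)) + 1e-9 * di)
  it <- iterateMap(map, T = 400, di0 = 100, nIter = 50)
  expect_identical(it$classification, "period-1")
  expect_equal(tail(it$trajectory$di, 1), 220, tolerance = 1e-6)
})

test_that("linear-map stability matches the closed form", {
  # F(DI) = s*DI + c: fixed point DI* = (T-c)/(1+s), stable iff |s| < 1
  mk <- function(s, c) fitRestitution(seq(20, 600, 20), s * seq(20, 600, 20) + c)
  for (s in c(0.4, 0.9)) {
    map <- mk(s, 100)
    T <- 400
    fp <- fixedPointAnalysis(map, T)
    expect_equal(fp$period1$di, (T - 100) / (1 + s), tolerance = 1e-6)
    expect_true(fp$period1$stable)
    it <- iterateMap(map, T, di0 = fp$period1$di + 30, nIter = 200)
    expect_identical(it$classification, "period-1")
  }
  mapU <- mk(1.4, 60)
  fpU <- fixedPointAnalysis(mapU, 500)
  expect_false(fpU$period1$stable)
  expect_equal(fpU$period1$slope, 1.4, tolerance = 1e-6)
})

test_that("fixed points and stability agree with brute-force iteration on random maps", {
  set.seed(9)
  for (rep in 1:6) {
    di <- seq(40, 500, by = 20)
    a <- runif(1, 120, 180); b <- runif(1, 40, 140)
    mid <- runif(1, 150, 350); width <- runif(1, 40, 90)
    apd <- a + b * (1 + tanh((di - mid) / width)) / 2
    map <- fitRestitution(di, apd)
    T <- runif(1, 350, 620)
    fp <- fixedPointAnalysis(map, T)
    stableP1 <- fp$period1[fp$period1$stable, , drop = FALSE]
    outcomes <- vapply(seq(41, 499, length.out = 200), function(d0) {
      it <- iterateMap(map, T, d0, nIter = 300)
      if (it$classification %in% c("period-1"))
        tail(it$trajectory$di, 1) else NA_real_
    }, numeric(1))
    conv <- outcomes[is.finite(outcomes)]
    if (nrow(stableP1)) {
      # every converged orbit lands on a stable period-1 point
      expect_true(all(vapply(conv, function(x)
        min(abs(x - stableP1$di)) < 0.5, logical(1))))
    } else {
      # no stable fixed point: nothing converges to period-1
      expect_equal(length(conv), 0L)
    }
  }
})

test_that("period-2 structure of G2 is detected with paired orbit points", {
  di <- seq(40, 500, by = 10)
  apd <- 150 + 120 * (1 + tanh((di - 250) / 30)) / 2
  map <- fitRestitution(di, apd)
  # choose T where the period-1 point sits on the steep segment
  fp1 <- NULL
  for (T in seq(380, 620, 5)) {
    f <- fixedPointAnalysis(map, T)
    if (nrow(f$period1) && all(!f$period1$stable)) { fp1 <- f; break }
  }
  expect_false(is.null(fp1))
  p2 <- fp1$period2[!fp1$period2$onPeriod1, , drop = FALSE]
  expect_gte(nrow(p2), 2)
  # orbit points map to each other under G
  G <- function(x) fp1$T - map$fun(x)
  for (i in seq_len(nrow(p2)))
    expect_true(min(abs(G(p2$di[i]) - p2$di)) < 1e-4)
})

test_that("onset classification distinguishes sub- and supercritical families", {
  # steep sigmoid with a long flat approach: subcritical structure with
  # off-diagonal unstable G2 points below onset
  di <- seq(40, 640, by = 10)
  apdSub <- 150 + 230 * (1 + tanh((di - 330) / 3)) / 2
  mapSub <- fitRestitution(di, apdSub)
  onSub <- findAlternansOnset(mapSub, c(350, 700), dT = 2)
  expect_identical(onSub$type, "subcritical")
  expect_gt(onSub$jump, 20)  # discontinuous jump to alternans
  # unimodal logistic-family map: supercritical period doubling
  apdSup <- 7.5 * di * exp(-di / 200)
  mapSup <- fitRestitution(di, apdSup)
  onSup <- findAlternansOnset(mapSup, c(200, 900), dT = 2)
  expect_identical(onSup$type, "supercritical")
  # linear map: degenerate, no pitchfork structure
  mapLin <- fitRestitution(di, 1.2 * di + 30)
  onLin <- findAlternansOnset(mapLin, c(100, 900), dT = 2)
  expect_identical(onLin$type, "degenerate")
})

test_that("the phase diagram applies the block rule before the domain check", {
  di <- seq(30, 500, by = 10)
  apd <- 150 + 200 * (1 + tanh((di - 300) / 25)) / 2
  map <- fitRestitution(di, apd, diBlock = 25)
  # first iterate below 25 ms => block regardless of later escape
  itB <- iterateMap(map, T = 360, di0 = 480, nIter = 100)
  expect_identical(itB$classification, "block")
  pd <- phaseDiagram(map, tGrid = seq(350, 600, by = 50),
                     di0Grid = seq(40, 480, by = 40))
  expect_true(all(pd$classification %in%
    c("period-1", "period-2", "period-n", "block", "out-of-domain")))
  # a flat map is period-1 everywhere
  flat <- fitRestitution(di, rep(150, length(di)) + 1e-9 * di, diBlock = 25)
  pdF <- phaseDiagram(flat, seq(400, 500, 50), seq(40, 480, 80))
  expect_true(all(pdF$classification == "period-1"))
})
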