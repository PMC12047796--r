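#' Fit a restitution map
#'
#' Fits a natural cubic spline `F(DI)` through (DI, APD) samples.  The
#' spline is valid only on the sampled DI range: evaluation outside the
#' domain is an explicit error, never silent extrapolation.
#'
#' @param di diastolic intervals (ms), strictly increasing after sorting;
#'   duplicated or non-finite DIs are an error.
#' @param apd action potential durations (ms).
#' @param diBlock conduction-block threshold (ms); iterates falling below
#'   it are classified as block.  `NA` disables the block rule (single-cell
#'   maps); tissue maps default to 25 ms.
#' @return object of class `restitutionMap` with elements `fun` (the
#'   spline), `deriv`, `domain`, `samples`, `residuals`, `diBlock`.
#' @export
fitRestitution <- function(di, apd, diBlock = NA) {
  if (is.data.frame(di)) { apd <- di$apd; di <- di$di }
  keep <- is.finite(di) & is.finite(apd)
  di <- di[keep]; apd <- apd[keep]
  o <- order(di); di <- di[o]; apd <- apd[o]
  if (length(di) < 4) stop("at least 4 (DI, APD) samples are required")
  if (any(diff(di) <= 0)) stop("DI values must be strictly increasing")
  f <- splinefun(di, apd, method = "natural")
  structure(list(fun = f,
                 deriv = function(x) f(x, deriv = 1),
                 domain = range(di),
                 samples = data.frame(di = di, apd = apd),
                 residuals = apd - f(di),
                 diBlock = diBlock),
            class = "restitutionMap")
}

#' @export
print.restitutionMap <- function(x, ...) {
  cat(sprintf("<restitutionMap> %d samples, DI in [%.1f, %.1f] ms, block threshold %s\n",
              nrow(x$samples), x$domain[1], x$domain[2],
              if (is.na(x$diBlock)) "none" else paste0(x$diBlock, " ms")))
  invisible(x)
}

evalMap <- function(map, di) {
  if (any(di < map$domain[1] - 1e-9 | di > map$domain[2] + 1e-9))
    stop(sprintf("DI = %.3f outside the fitted domain [%.1f, %.1f]; refusing to extrapolate",
                 di[which.max(di < map$domain[1] | di > map$domain[2])],
                 map$domain[1], map$domain[2]))
  map$fun(di)
}

#' Iterate the restitution map at a fixed pacing period
#'
#' Iterates `A_{n+1} = F(DI_n)`, `DI_{n+1} = T - A_{n+1}`, so that
#' `DI_n + A_n = T` at every iterate.  The block rule (`DI < diBlock`) is
#' evaluated before the domain check at each step; leaving the spline
#' domain without crossing the block threshold is classified
#' out-of-domain.  The orbit period is classified from the last quarter of
#' the trajectory with a 0.5 ms tolerance on APD values.
#'
#' @param map a `restitutionMap`.
#' @param T pacing period (ms).
#' @param di0 initial diastolic interval (ms), inside the domain.
#' @param nIter number of iterations.
#' @param tol APD tolerance (ms) for the period classification.
#' @return list with `trajectory` (data.frame `n`, `di`, `apd`) and
#'   `classification` in `{"period-1", "period-2", "period-n", "block",
#'   "out-of-domain"}`.
#' @export
iterateMap <- function(map, T, di0, nIter = 100, tol = 0.5) {
  di <- numeric(nIter + 1)
  apd <- numeric(nIter + 1)
  di[1] <- di0; apd[1] <- NA
  cls <- NULL
  n <- 1
  for (k in seq_len(nIter)) {
    d <- di[k]
    if (!is.na(map$diBlock) && d < map$diBlock) { cls <- "block"; break }
    if (d < map$domain[1] || d > map$domain[2]) { cls <- "out-of-domain"; break }
    a <- map$fun(d)
    apd[k + 1] <- a
    di[k + 1] <- T - a
    n <- k + 1
  }
  traj <- data.frame(n = seq_len(n) - 1, di = di[seq_len(n)],
                     apd = apd[seq_len(n)])
  if (is.null(cls)) {
    lastQ <- apd[max(2, floor(3 * n / 4)):n]
    k <- countDistinct(lastQ, tol)
    cls <- if (k == 1) "period-1" else if (k == 2) "period-2" else "period-n"
  }
  list(trajectory = traj, classification = cls)
}

countDistinct <- function(x, tol) {
  x <- sort(x)
  if (!length(x)) return(0L)
  sum(c(TRUE, diff(x) > tol))
}

#' Fixed points of the map and of its second iterate
#'
#' Writes the map as `DI_{n+1} = G(DI_n)` with `G(DI) = T - F(DI)`, then
#' locates all roots of `G(DI) - DI` (period-1) and `G2(DI) - DI`
#' (period-2 candidates) by dense sign-change bracketing plus bisection
#' over the restricted domain where `G` stays inside the spline domain.
#' Stability is read from the spline's analytic derivative: a period-1
#' point is stable iff `|F'(DI*)| < 1`; a `G2` fixed point iff
#' `|dG2/dDI| < 1`.  Period-2 orbit points are paired by mutual mapping.
#'
#' @param map a `restitutionMap`.
#' @param T pacing period (ms).
#' @param nGrid bracketing grid size.
#' @return list with data.frames `period1` (`di`, `apd`, `slope`,
#'   `stable`) and `period2` (`di`, `slope2`, `stable`, `partner`,
#'   `onPeriod1`); empty data.frames when no fixed point lies in the
#'   domain.
#' @export
fixedPointAnalysis <- function(map, T, nGrid = 2000) {
  lo <- map$domain[1]; hi <- map$domain[2]
  G <- function(x) T - map$fun(x)
  inDom <- function(x) x >= lo & x <= hi
  roots <- function(h, restrict = NULL) {
    xs <- seq(lo, hi, length.out = nGrid)
    if (!is.null(restrict)) xs <- xs[restrict(xs)]
    if (length(xs) < 2) return(numeric(0))
    hx <- h(xs)
    ok <- is.finite(hx)
    xs <- xs[ok]; hx <- hx[ok]
    idx <- which(hx[-1] * hx[-length(hx)] <= 0 & hx[-1] != hx[-length(hx)])
    unique(vapply(idx, function(i)
      uniroot(h, c(xs[i], xs[i + 1]), tol = 1e-8)$root, numeric(1)))
  }
  p1 <- roots(function(x) G(x) - x)
  period1 <- data.frame(di = numeric(0), apd = numeric(0),
                        slope = numeric(0), stable = logical(0))
  if (length(p1)) {
    sl <- map$deriv(p1)
    period1 <- data.frame(di = p1, apd = map$fun(p1), slope = sl,
                          stable = abs(sl) < 1)
  }
  # G2 defined only where the first iterate stays in the domain
  g2 <- function(x) G(G(x))
  p2 <- roots(function(x) g2(x) - x, restrict = function(x) inDom(G(x)))
  period2 <- data.frame(di = numeric(0), slope2 = numeric(0),
                        stable = logical(0), partner = numeric(0),
                        onPeriod1 = logical(0))
  if (length(p2)) {
    sl2 <- map$deriv(p2) * map$deriv(G(p2))  # chain rule for dG2/dDI
    partner <- G(p2)
    onP1 <- vapply(p2, function(x)
      length(p1) > 0 && min(abs(x - p1)) < 1e-3, logical(1))
    period2 <- data.frame(di = p2, slope2 = sl2, stable = abs(sl2) < 1,
                          partner = partner, onPeriod1 = onP1)
  }
  list(period1 = period1, period2 = period2, T = T)
}

#' Locate the alternans onset of the iterated map
#'
#' Scans pacing periods for the smallest `T` at which the period-1 fixed
#' point loses stability (`|F'(DI*)| >= 1`).  The transition is classified
#' subcritical if, just below onset, the second iterate already has
#' off-diagonal unstable fixed points (the hallmark of a subcritical
#' pitchfork: unstable period-2 points collide with the stable point at
#' onset, giving a discontinuous jump and bistability below threshold);
#' otherwise supercritical.  A linear map (constant `F'`) has no pitchfork
#' structure and is reported as `"degenerate"`.
#'
#' @param map a `restitutionMap`.
#' @param tRange range of pacing periods to scan (ms).
#' @param dT scan step (ms).
#' @return list with `Tc`, `type` (`"subcritical"`, `"supercritical"`,
#'   `"degenerate"`, or `"not-found"`), and `jump` (period-2 APD amplitude
#'   just above onset, `NA` if unavailable).
#' @export
findAlternansOnset <- function(map, tRange, dT = 1) {
  slopes <- map$deriv(seq(map$domain[1], map$domain[2], length.out = 200))
  linear <- diff(range(slopes)) < 1e-8
  Ts <- seq(tRange[1], tRange[2], by = dT)
  Tc <- NA
  for (T in Ts) {
    fp <- fixedPointAnalysis(map, T)
    if (!nrow(fp$period1)) next
    # track the fixed point continuing the stable branch: smallest |slope|
    i <- which.min(abs(fp$period1$slope))
    if (abs(fp$period1$slope[i]) >= 1) { Tc <- T; break }
  }
  if (is.na(Tc)) return(list(Tc = NA, type = "not-found", jump = NA))
  if (linear) return(list(Tc = Tc, type = "degenerate", jump = NA))
  below <- fixedPointAnalysis(map, Tc - dT)
  sub <- nrow(below$period2) > 0 &&
    any(!below$period2$onPeriod1 & !below$period2$stable)
  jump <- NA_real_
  aboveT <- Tc + dT
  fpA <- fixedPointAnalysis(map, aboveT)
  start <- if (nrow(fpA$period1)) fpA$period1$di[1] + 1 else mean(map$domain)
  start <- min(max(start, map$domain[1]), map$domain[2])
  it <- iterateMap(map, aboveT, start, nIter = 200)
  if (it$classification %in% c("period-2", "period-n")) {
    tailA <- it$trajectory$apd[floor(3 * nrow(it$trajectory) / 4):nrow(it$trajectory)]
    jump <- diff(range(tailA, na.rm = TRUE))
  }
  list(Tc = Tc, type = if (sub) "subcritical" else "supercritical",
       jump = jump)
}

#' Phase diagram of the iterated map
#'
#' Classifies the long-term behavior (`period-1`, `period-2`, `period-n`,
#' `block`, `out-of-domain`) over a grid of pacing periods and initial
#' diastolic intervals, with the conduction-block rule `DI < diBlock`
#' applied at every iterate.
#'
#' @param map a `restitutionMap` (its `diBlock`, default 25 ms for tissue
#'   maps, is used unless overridden).
#' @param tGrid pacing periods (ms).
#' @param di0Grid initial diastolic intervals (ms).
#' @param nIter iterations per cell (100 as in the reference protocol).
#' @param diBlock optional override of the block threshold (ms).
#' @return data.frame with `T`, `di0`, `classification`.
#' @export
phaseDiagram <- function(map, tGrid, di0Grid, nIter = 100, diBlock = NULL) {
  if (!is.null(diBlock)) map$diBlock <- diBlock
  if (is.na(map$diBlock)) map$diBlock <- 25
  grid <- expand.grid(T = tGrid, di0 = di0Grid)
  grid$classification <- vapply(seq_len(nrow(grid)), function(i) {
    iterateMap(map, grid$T[i], grid$di0[i], nIter = nIter)$classification
  }, character(1))
  grid
}

#' Cobweb trajectory data
#'
#' Returns the segments for a cobweb plot of the iterated map at period
#' `T` from `di0`: alternating vertical moves to the map and horizontal
#' moves to the diagonal.
#'
#' @inheritParams iterateMap
#' @return data.frame of segment endpoints `x0, y0, x1, y1`.
#' @export
cobwebData <- function(map, T, di0, nIter = 30) {
  it <- iterateMap(map, T, di0, nIter = nIter)
  di <- it$trajectory$di
  if (length(di) < 2) return(data.frame())
  segs <- NULL
  y <- di[1]
  for (k in seq_len(length(di) - 1)) {
    segs <- rbind(segs,
                  c(di[k], y, di[k], di[k + 1]),
                  c(di[k], di[k + 1], di[k + 1], di[k + 1]))
    y <- di[k + 1]
  }
  setNames(as.data.frame(segs), c("x0", "y0", "x1", "y1"))
}
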