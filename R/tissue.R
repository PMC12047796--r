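#' Tissue grid constructor
#'
#' A homogeneous 2D monodomain grid of `nx * ny` coupled cells sharing a
#' single parameter bundle.  Cells are indexed row-major: cell `(ix, iy)`
#' (1-based) is column `(iy-1)*nx + ix` of the state matrix.
#'
#' @param params parameter bundle.
#' @param nx,ny grid dimensions.
#' @param mode spark dynamics mode for the cells.
#' @return object of class `tissueGrid`.
#' @export
tissueGrid <- function(params, nx, ny = 1,
                       mode = c("stochastic", "deterministic")) {
  mode <- match.arg(mode)
  validateParams(params)
  if (params[["DV"]] > 0) {
    ndim <- (nx > 1) + (ny > 1)
    bound <- params[["dx"]]^2 / (2 * max(1, ndim) * params[["DV"]])
    if (nx * ny > 1 && params[["dtSlow"]] > bound + 1e-12)
      stop(sprintf("diffusion stability bound violated: dtSlow = %g > %g",
                   params[["dtSlow"]], bound))
  }
  s0 <- initCellState(params, stochastic = mode == "stochastic")
  structure(list(params = params, nx = as.integer(nx), ny = as.integer(ny),
                 mode = mode,
                 state = matrix(s0, nrow = length(s0), ncol = nx * ny,
                                dimnames = list(names(s0), NULL))),
            class = "tissueGrid")
}

#' @export
print.tissueGrid <- function(x, ...) {
  cat(sprintf("<tissueGrid> %d x %d cells, %s sparks, V in [%.1f, %.1f] mV\n",
              x$nx, x$ny, x$mode, min(x$state["V", ]), max(x$state["V", ])))
  invisible(x)
}

cellIndex <- function(grid, ix, iy) (iy - 1L) * grid$nx + ix

runTissueEngine <- function(grid, stimTimes, cls, stimMask, seed,
                            recordCells, tEnd, snapshotTimes = numeric(0),
                            recordMaps = TRUE, traceDt = 0) {
  pv <- asParamVector(grid$params)
  out <- .engine_run(pv, grid$state, grid$nx, grid$ny,
                     stimTimes, cls, as.numeric(stimMask),
                     grid$mode == "stochastic", seed,
                     as.integer(recordCells - 1L), traceDt,
                     snapshotTimes, tEnd, recordMaps)
  out$grid <- grid
  out$grid$state <- out$finalState
  dimnames(out$grid$state) <- list(stateNames(), NULL)
  out
}

#' Uniformly paced tissue
#'
#' Stimulates every cell simultaneously with a 2 ms current pulse each
#' beat and records the per-beat APDs at the approximate tissue center,
#' cell `(floor(nx/2), floor(ny/2))` (clamped to 1 for small grids).
#'
#' @param grid a [tissueGrid()].
#' @param protocol a [pacingProtocol()].
#' @param seed run seed for the per-cell spark streams.
#' @param recordSite optional `(ix, iy)` overriding the center cell.
#' @return list with `beats` (data.frame at the recorded site),
#'   `activation`/`repolarization` matrices (beat x cell, -40 mV crossing
#'   times), and the advanced `grid`.
#' @export
runUniform <- function(grid, protocol, seed = 1, recordSite = NULL) {
  sch <- protocolSchedule(protocol, grid$params[["stimDur"]])
  if (is.null(recordSite))
    recordSite <- c(max(1L, grid$nx %/% 2L), max(1L, grid$ny %/% 2L))
  rec <- cellIndex(grid, recordSite[1], recordSite[2])
  out <- runTissueEngine(grid, sch$times, sch$cls,
                         rep(1, grid$nx * grid$ny), seed, rec, sch$tEnd)
  list(beats = out$beats[[1]], activation = out$activation,
       repolarization = out$repolarization, grid = out$grid)
}

#' Planar-wave pacing of a tissue sheet
#'
#' Stimulates a strip of cells on the left edge each beat, producing
#' planar wavefronts; exports voltage snapshots at a configurable stride
#' and per-beat activation/repolarization maps, plus a per-beat wavebreak
#' flag from connected-component analysis of the excited region.
#'
#' @param grid a [tissueGrid()].
#' @param protocol a [pacingProtocol()].
#' @param stripWidth width (cells) of the paced strip on the left edge.
#' @param seed run seed.
#' @param snapshotDt stride (ms) between exported voltage frames; 0
#'   disables snapshots.
#' @param recordSite `(ix, iy)` cell whose per-beat APDs are recorded.
#' @return list with `beats`, `activation`, `repolarization`, `snapshots`
#'   (cells x frames matrix), `snapshotTimes`, `wavebreak` (per-frame
#'   logical), and the advanced `grid`.
#' @export
runPlanar <- function(grid, protocol, stripWidth = 10, seed = 1,
                      snapshotDt = 0, recordSite = NULL) {
  if (stripWidth >= grid$nx + 1) stop("strip width must not exceed nx")
  sch <- protocolSchedule(protocol, grid$params[["stimDur"]])
  ix <- ((seq_len(grid$nx * grid$ny) - 1L) %% grid$nx) + 1L
  mask <- as.numeric(ix <= stripWidth)
  snaps <- if (snapshotDt > 0) seq(0, sch$tEnd, by = snapshotDt) else numeric(0)
  if (is.null(recordSite))
    recordSite <- c(max(1L, grid$nx %/% 2L), max(1L, grid$ny %/% 2L))
  rec <- cellIndex(grid, recordSite[1], recordSite[2])
  out <- runTissueEngine(grid, sch$times, sch$cls, mask, seed, rec, sch$tEnd,
                         snapshotTimes = snaps)
  wb <- if (length(snaps)) {
    apply(out$snapshots, 2, function(v)
      detectWavebreak(matrix(v, grid$nx, grid$ny)))
  } else logical(0)
  list(beats = out$beats[[1]], activation = out$activation,
       repolarization = out$repolarization,
       snapshots = out$snapshots, snapshotTimes = out$snapshotTimes,
       wavebreak = wb, grid = out$grid)
}

#' Wavebreak detector
#'
#' Flags a voltage frame whose excited region (`V > threshold`) is
#' non-simply-connected in the propagation sense: more than one connected
#' component of excited tissue (4-neighborhood flood fill), the
#' operational signature of a broken wavefront and incipient reentry.
#'
#' @param Vframe matrix of voltages (nx x ny).
#' @param threshold excitation threshold (mV).
#' @return logical: `TRUE` when the excited region has more than one
#'   connected component.
#' @export
detectWavebreak <- function(Vframe, threshold = -40) {
  exc <- Vframe > threshold
  if (!any(exc)) return(FALSE)
  lab <- matrix(0L, nrow(exc), ncol(exc))
  comp <- 0L
  for (j in seq_len(ncol(exc))) for (i in seq_len(nrow(exc))) {
    if (exc[i, j] && lab[i, j] == 0L) {
      comp <- comp + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[1] > nrow(exc) || p[2] < 1 || p[2] > ncol(exc))
          next
        if (!exc[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- comp
        stack <- c(stack, list(c(p[1] - 1, p[2]), c(p[1] + 1, p[2]),
                               c(p[1], p[2] - 1), c(p[1], p[2] + 1)))
      }
    }
  }
  comp > 1L
}

#' Conduction velocity on a 1D cable
#'
#' Paces one end of a cable and measures the plane-wave speed from the
#' activation times (first -40 mV upward crossings) of two interior
#' sites, away from boundary and stimulus artifacts.
#'
#' @param params parameter bundle.
#' @param nCells cable length in cells.
#' @param pacedCells number of cells stimulated at the left end.
#' @param cl conditioning cycle length (ms).
#' @param beats number of paced beats; the last beat is measured.
#' @param sites two interior cell indices used for the speed estimate.
#' @param mode spark dynamics mode (deterministic for a clean estimate).
#' @param seed run seed.
#' @return list with `cv` (cm/s), `activation` (activation times of the
#'   measured beat, ms), and `sites`.
#' @export
conductionVelocity <- function(params, nCells = 100, pacedCells = 5,
                               cl = 600, beats = 2,
                               sites = round(c(0.3, 0.7) * nCells),
                               mode = "deterministic", seed = 1) {
  grid <- tissueGrid(params, nx = nCells, ny = 1, mode = mode)
  mask <- as.numeric(seq_len(nCells) <= pacedCells)
  st <- seq(0, by = cl, length.out = beats)
  out <- runTissueEngine(grid, st, rep(cl, beats), mask, seed,
                         recordCells = sites[1], tEnd = cl * beats)
  act <- out$activation[beats, ]
  dtAct <- act[sites[2]] - act[sites[1]]
  if (!is.finite(dtAct) || dtAct <= 0)
    stop("wave did not traverse both measurement sites")
  cv <- (sites[2] - sites[1]) * params[["dx"]] / dtAct * 1000
  list(cv = cv, activation = act, sites = sites)
}

#' Conduction-block threshold on a tissue strip
#'
#' S1S2 protocol on an `nx x ny` strip: a region at the left end is paced
#' at the S1 cycle length to steady state, then single S2 beats at
#' decreasing coupling intervals are delivered from the stored state.  A
#' beat is propagated when the distal-end cell activates.  Returns the
#' largest diastolic interval (measured at a paced-edge cell with the
#' -40 mV convention) at which propagation fails, bracketing the block
#' threshold.
#'
#' @param params parameter bundle (the reduced-inactivation preset for the
#'   reference protocol).
#' @param nx,ny strip dimensions.
#' @param stimCols number of paced columns at the left end.
#' @param s1 S1 cycle length (ms).
#' @param s1Beats conditioning beats.
#' @param s2List S2 coupling intervals to test (ms), descending.
#' @param mode spark dynamics mode.
#' @param seed run seed.
#' @return list with `diBlock` (ms), and the scan `table`
#'   (`s2`, `di`, `propagated`, `apdDistal`).
#' @export
blockThreshold <- function(params, nx = 60, ny = 3, stimCols = 10,
                           s1 = 500, s1Beats = 10,
                           s2List = seq(320, 180, by = -10),
                           mode = "deterministic", seed = 1) {
  grid <- tissueGrid(params, nx = nx, ny = ny, mode = mode)
  ix <- ((seq_len(nx * ny) - 1L) %% nx) + 1L
  mask <- as.numeric(ix <= stimCols)
  edge <- cellIndex(grid, 1L, max(1L, ny %/% 2L + 1L))
  distal <- cellIndex(grid, nx, max(1L, ny %/% 2L + 1L))
  st <- seq(0, by = s1, length.out = s1Beats)
  base <- runTissueEngine(grid, st, rep(s1, s1Beats), mask, seed,
                          recordCells = c(edge, distal), tEnd = s1 * s1Beats)
  rows <- lapply(s2List, function(s2) {
    g2 <- base$grid
    o2 <- runTissueEngine(g2, c(0, s2), c(s1, s2), mask, seed + 1,
                          recordCells = c(edge, distal), tEnd = s2 + 700)
    eb <- o2$beats[[1]]; db <- o2$beats[[2]]
    data.frame(s2 = s2, di = eb$di40[2], diDistal = db$di40[2],
               propagated = is.finite(db$tUp[2]),
               apdDistal = db$apd40[2])
  })
  tab <- do.call(rbind, rows)
  failed <- tab$di[!tab$propagated & is.finite(tab$di)]
  list(diBlock = if (length(failed)) max(failed) else NA_real_, table = tab)
}

#' S1S2 restitution measured on a tissue strip
#'
#' Same S1S2 protocol as [blockThreshold()] but returning the (DI, APD)
#' table measured at the distal end for propagated beats, the input for
#' a tissue-level restitution map with a conduction-block region.
#'
#' @inheritParams blockThreshold
#' @return data.frame `s2`, `di`, `apd` for propagated beats, with the
#'   failed S2 values in attribute `blocked`.
#' @export
s1s2Strip <- function(params, nx = 60, ny = 3, stimCols = 10, s1 = 500,
                      s1Beats = 10, s2List = seq(250, 900, by = 25),
                      mode = "deterministic", seed = 1) {
  scan <- blockThreshold(params, nx, ny, stimCols, s1, s1Beats,
                         s2List = sort(s2List, decreasing = TRUE),
                         mode = mode, seed = seed)
  tab <- scan$table
  ok <- tab$propagated
  out <- data.frame(s2 = tab$s2[ok], di = tab$di[ok], apd = tab$apdDistal[ok])
  out <- out[order(out$di), ]
  rownames(out) <- NULL
  attr(out, "blocked") <- tab$s2[!ok]
  out
}
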