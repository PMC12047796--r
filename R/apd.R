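#' Detect action potentials and their durations in a voltage trace
#'
#' For each stimulus, the upstroke is the first upward crossing of -40 mV
#' after the stimulus; APD-40mV is the time to the next downward -40 mV
#' crossing; APD90 is the time to the downward crossing of
#' `rest + 0.1*(peak - rest)`, where rest is the pre-stimulus voltage and
#' peak the per-beat maximum.  Crossings are located by linear
#' interpolation between samples.  Beats without a downward crossing
#' before the next stimulus are capped at the cycle length and flagged;
#' stimuli without an upstroke are recorded as no-capture.
#'
#' @param t sample times (ms), strictly increasing, stride <= 0.1 ms
#'   recommended for interpolation accuracy.
#' @param V voltages (mV).
#' @param stimTimes stimulus onset times (ms).
#' @param convention `"apd40"` or `"apd90"` selects which duration fills
#'   the `apd` column; both are always computed.
#' @param eadDelay blanking period after the upstroke before the EAD
#'   detector arms (ms).
#' @param eadJump secondary-rise amplitude (mV) flagging an EAD.
#' @return data.frame of class `apdSeries` with one row per stimulus:
#'   `beat`, `tStim`, `cl`, `tUp`, `apd90`, `apd40`, `apd`, `di40`,
#'   `peak`, `rest`, `capped`, `ead`, `captured`.
#' @export
detectApds <- function(t, V, stimTimes, convention = c("apd40", "apd90"),
                       eadDelay = 80, eadJump = 2) {
  convention <- match.arg(convention)
  stopifnot(length(t) == length(V), !is.unsorted(t))
  n <- length(stimTimes)
  cls <- diff(c(stimTimes, t[length(t)]))
  interp <- function(i, lvl) {
    t[i - 1] + (lvl - V[i - 1]) * (t[i] - t[i - 1]) / (V[i] - V[i - 1])
  }
  rows <- vector("list", n)
  lastDown40 <- NA_real_
  for (b in seq_len(n)) {
    t0 <- stimTimes[b]
    t1 <- if (b < n) stimTimes[b + 1] else t[length(t)] + 1e-9
    win <- which(t >= t0 & t < t1)
    rec <- list(beat = b, tStim = t0, cl = cls[b], tUp = NA_real_,
                apd90 = NA_real_, apd40 = NA_real_, di40 = NA_real_,
                peak = NA_real_, rest = NA_real_, capped = FALSE,
                ead = FALSE, captured = FALSE)
    if (length(win) > 1) {
      iPre <- win[1]
      rest <- if (iPre > 1) V[iPre - 1] else V[iPre]
      up <- win[-1][V[win[-1]] >= -40 & V[win[-length(win)]] < -40]
      if (length(up)) {
        iUp <- up[1]
        tUp <- interp(iUp, -40)
        seg <- win[t[win] > tUp]
        peak <- max(V[seg])
        rec$captured <- TRUE
        rec$tUp <- tUp
        rec$rest <- rest
        rec$peak <- peak
        if (!is.na(lastDown40)) rec$di40 <- tUp - lastDown40
        dn <- seg[-1][V[seg[-1]] < -40 & V[seg[-length(seg)]] >= -40]
        if (length(dn)) {
          tD40 <- interp(dn[1], -40)
          rec$apd40 <- tD40 - tUp
          lastDown40 <- tD40
        } else {
          rec$apd40 <- rec$cl
          rec$capped <- TRUE
          lastDown40 <- tUp + rec$cl
        }
        lvl90 <- rest + 0.1 * (peak - rest)
        iPk <- seg[which.max(V[seg])]
        post <- seg[seg > iPk]
        dn90 <- post[V[post] < lvl90 & V[pmax(post - 1, 1)] >= lvl90]
        if (length(dn90)) rec$apd90 <- interp(dn90[1], lvl90) - tUp
        else { rec$apd90 <- rec$cl; rec$capped <- TRUE }
        # EAD: local min then a rise >= eadJump, both above -40 mV,
        # during repolarization
        arm <- seg[t[seg] > tUp + eadDelay & V[seg] > -40 &
                   t[seg] < tUp + ifelse(is.na(rec$apd40), rec$cl, rec$apd40)]
        if (length(arm) > 2) {
          vmin <- cummin(V[arm])
          rec$ead <- any(V[arm] > vmin + eadJump)
        }
      }
    }
    rows[[b]] <- rec
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out$apd <- if (convention == "apd40") out$apd40 else out$apd90
  attr(out, "convention") <- convention
  class(out) <- c("apdSeries", "data.frame")
  out
}

#' APD statistics
#'
#' Discards an initial transient, then reports the mean, standard
#' deviation, coefficient of variation (sigma over mean), and a histogram
#' normalized so its maximum bin equals 1.
#'
#' @param apd numeric vector of APDs (ms), or an `apdSeries` (its `apd`
#'   column is used, no-capture beats dropped).
#' @param discard number of leading beats to discard.
#' @param breaks histogram breaks (passed to [graphics::hist()] logic via
#'   [base::cut()]); default 30 equal bins.
#' @return list with `mean`, `sd`, `cv` (fraction, not percent), `n`, and
#'   `histogram` (data.frame `mid`, `density` with max 1).
#' @export
apdStatistics <- function(apd, discard = 0, breaks = 30) {
  if (inherits(apd, "apdSeries")) apd <- apd$apd[apd$captured]
  apd <- apd[!is.na(apd)]
  if (length(apd) <= discard) stop("no beats left after discarding the transient")
  x <- apd[(discard + 1):length(apd)]
  m <- mean(x); s <- sd(x)
  if (length(x) > 1 && diff(range(x)) > 0) {
    h <- hist(x, breaks = breaks, plot = FALSE)
    hd <- data.frame(mid = h$mids, density = h$counts / max(h$counts))
  } else {
    hd <- data.frame(mid = m, density = 1)
  }
  list(mean = m, sd = s, cv = if (m > 0) s / m else 0, n = length(x),
       histogram = hd)
}

#' Bifurcation diagram table
#'
#' Collects the last `keepLast` APDs at each cycle length of a sweep,
#' tagged with the sweep direction so up- and down-sweeps can be overlaid
#' to expose hysteresis.
#'
#' @param sweep data.frame from [dynamicSweep()].
#' @param keepLast beats kept per cycle length.
#' @param direction label stored with the table (e.g. `"up"`, `"down"`).
#' @return data.frame with `cl`, `apd`, `ead`, `direction`.
#' @export
bifurcationDiagram <- function(sweep, keepLast = 50, direction = "up") {
  keep <- sweep[sweep$beatInSegment > max(sweep$beatInSegment) - keepLast, ]
  data.frame(cl = keep$cl, apd = keep$apd40, ead = keep$ead,
             direction = direction)
}

#' Synthetic voltage waveforms with analytically known APDs
#'
#' Fixture generator for the APD detector: `"trapezoid"` (linear upstroke,
#' flat plateau, linear repolarization ramp -- every threshold crossing is
#' in closed form), `"exponential"` (square upstroke to `vPeak`, then
#' exponential relaxation toward rest with time constant `tau` -- crossing
#' times by analytic inversion), and `"alternans"` (trapezoids of
#' alternating plateau durations).
#'
#' @param kind waveform family.
#' @param nBeats number of beats.
#' @param cl cycle length (ms).
#' @param dt sample stride (ms).
#' @param vRest,vPeak rest and plateau/peak voltages (mV).
#' @param plateau plateau duration (ms) for trapezoids; for `"alternans"`
#'   a vector of two alternating durations.
#' @param ramp repolarization ramp duration (ms) for trapezoids.
#' @param riseTime upstroke duration (ms).
#' @param tau repolarization time constant (ms) for `"exponential"`.
#' @return list with `t`, `V`, `stimTimes`, and `truth` -- a data.frame of
#'   ground-truth `apd40` and `apd90` per beat (as measured from the -40
#'   crossing of the upstroke, matching the detector's convention).
#' @export
makeFixtureTrace <- function(kind = c("trapezoid", "exponential", "alternans"),
                             nBeats = 5, cl = 500, dt = 0.05,
                             vRest = -80, vPeak = 20, plateau = 200,
                             ramp = 40, riseTime = 1, tau = 60) {
  kind <- match.arg(kind)
  tEnd <- nBeats * cl
  t <- seq(0, tEnd, by = dt)
  V <- rep(vRest, length(t))
  stimTimes <- (seq_len(nBeats) - 1) * cl
  plateaus <- switch(kind,
    trapezoid = rep(plateau[1], nBeats),
    exponential = rep(NA_real_, nBeats),
    alternans = rep(rep_len(plateau, 2), length.out = nBeats))
  truth <- data.frame(beat = seq_len(nBeats), apd40 = NA_real_,
                      apd90 = NA_real_)
  for (b in seq_len(nBeats)) {
    t0 <- stimTimes[b]
    tl <- t - t0
    inBeat <- tl >= 0 & tl < cl
    if (kind == "exponential") {
      shape <- ifelse(tl < riseTime, vRest + (vPeak - vRest) * tl / riseTime,
                      vRest + (vPeak - vRest) * exp(-(tl - riseTime) / tau))
      V[inBeat] <- shape[inBeat]
      # upstroke crossing of -40 on the linear rise, decay crossing by inversion
      tUp <- riseTime * (-40 - vRest) / (vPeak - vRest)
      cross <- function(lvl) riseTime + tau * log((vPeak - vRest) / (lvl - vRest))
      lvl90 <- vRest + 0.1 * (vPeak - vRest)
      truth$apd40[b] <- cross(-40) - tUp
      truth$apd90[b] <- cross(lvl90) - tUp
    } else {
      pl <- plateaus[b]
      shape <- ifelse(tl < riseTime, vRest + (vPeak - vRest) * tl / riseTime,
               ifelse(tl < riseTime + pl, vPeak,
               ifelse(tl < riseTime + pl + ramp,
                      vPeak - (vPeak - vRest) * (tl - riseTime - pl) / ramp,
                      vRest)))
      V[inBeat] <- shape[inBeat]
      tUp <- riseTime * (-40 - vRest) / (vPeak - vRest)
      downAt <- function(lvl)
        riseTime + pl + ramp * (vPeak - lvl) / (vPeak - vRest)
      lvl90 <- vRest + 0.1 * (vPeak - vRest)
      truth$apd40[b] <- downAt(-40) - tUp
      truth$apd90[b] <- downAt(lvl90) - tUp
    }
  }
  list(t = t, V = V, stimTimes = stimTimes, truth = truth)
}
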