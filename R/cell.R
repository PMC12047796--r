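#' Initial single-cell state
#'
#' Builds the 26-component state vector at the resting membrane potential:
#' voltage, the ten Hodgkin-Huxley gates at their steady state for `V`,
#' the four compartment Ca concentrations, the spark state (count `nb` in
#' stochastic mode, fraction `pb` in the deterministic limit), and the ten
#' L-type channel occupancies (all channels in the deep closed state C1).
#'
#' @param params parameter bundle from [defaultParams()].
#' @param V resting voltage (mV).
#' @param ca named numeric overrides for `cb`, `ci`, `csrb`, `csri` (uM).
#' @param stochastic logical; spark slot holds a count if `TRUE`.
#' @return named numeric state vector.
#' @export
initCellState <- function(params, V = -86, ca = NULL, stochastic = FALSE) {
  g <- .gate_steady_cpp(V)
  s <- c(V = V, g,
         cb = 0.1, ci = 0.1, csrb = 750, csri = 750,
         spark = 0,
         C1 = 1, C2 = 0, O = 0, I1 = 0, I2 = 0,
         CS1 = 0, CS2 = 0, OS = 0, IS1 = 0, IS2 = 0)
  if (!is.null(ca)) for (nm in names(ca)) s[[nm]] <- ca[[nm]]
  s
}

stateNames <- function() {
  c("V", "m", "h", "j", "xkr", "xs1", "xs2", "xtos", "ytos", "xtof", "ytof",
    "cb", "ci", "csrb", "csri", "spark",
    "C1", "C2", "O", "I1", "I2", "CS1", "CS2", "OS", "IS1", "IS2")
}

#' Advance a single cell one reaction step
#'
#' One operator-split reaction step of the full cell: Hodgkin-Huxley gates
#' (Rush-Larsen), L-type channel Markov occupancies (explicit Euler with a
#' guarded exit-probability check), spark recruitment (binomial draws in
#' stochastic mode, the mean-field ODE in deterministic mode), compartment
#' Ca balances, and the voltage update \eqn{dV/dt = -(I_{ion} - I_{stim})/C_m}.
#' All subsystems read beginning-of-step values in a fixed order
#' (gates, LCC, sparks, Ca, currents, voltage).
#'
#' @param state state vector from [initCellState()].
#' @param params parameter bundle.
#' @param dt time step (ms).
#' @param istim stimulus amplitude (uA/uF, depolarizing positive).
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param seed RNG seed for the stochastic spark draws.
#' @return list with the advanced `state` and `dvdt` (mV/ms).
#' @export
stepCell <- function(state, params, dt, istim = 0,
                     mode = c("deterministic", "stochastic"), seed = 1) {
  mode <- match.arg(mode)
  out <- .cell_step_cpp(as.numeric(state), asParamVector(params), dt, istim,
                        mode == "stochastic", seed)
  names(out$state) <- stateNames()
  out
}

asParamVector <- function(params) {
  if (inherits(params, "eadsimParams")) validateParams(params)
  v <- as.numeric(params)
  names(v) <- names(params)
  v
}

# Build a stimulus schedule from (cl, beats) segments.
stimSchedule <- function(segments) {
  ts <- numeric(0); cl <- numeric(0); t0 <- 0
  for (seg in segments) {
    stopifnot(seg$beats >= 1)
    ts <- c(ts, t0 + seg$cl * (seq_len(seg$beats) - 1))
    cl <- c(cl, rep(seg$cl, seg$beats))
    t0 <- t0 + seg$cl * seg$beats
  }
  list(times = ts, cls = cl, tEnd = t0)
}

#' Pacing protocol
#'
#' An ordered list of (cycle length, beats) segments with an optional extra
#' S2 interval appended after the last segment.
#'
#' @param cl cycle length(s), ms; recycled against `beats`.
#' @param beats number of beats per segment.
#' @param s2 optional S2 coupling interval (ms) appended as one extra beat.
#' @return object of class `pacingProtocol`.
#' @export
pacingProtocol <- function(cl, beats, s2 = NULL) {
  stopifnot(length(cl) == length(beats), all(beats >= 1), all(cl > 0))
  segs <- Map(function(c1, b) list(cl = c1, beats = b), cl, beats)
  structure(list(segments = segs, s2 = s2), class = "pacingProtocol")
}

protocolSchedule <- function(protocol, stimDur) {
  sch <- stimSchedule(protocol$segments)
  if (!is.null(protocol$s2)) {
    if (protocol$s2 <= stimDur) stop("S2 interval must exceed the stimulus duration")
    lastCl <- tail(sch$cls, 1)
    tS2 <- sch$tEnd - lastCl + protocol$s2
    sch$times <- c(sch$times, tS2)
    sch$cls <- c(sch$cls, protocol$s2)
    sch$tEnd <- tS2 + max(protocol$s2, 600)
  }
  sch
}

#' Pace a single cell
#'
#' Integrates the cell under a pacing protocol and returns the (decimated)
#' voltage trace plus a per-beat table of APD90 and APD-40mV as located by
#' the online crossing detector (linear interpolation; beats that never
#' recross the threshold before the next stimulus are capped at the cycle
#' length and flagged).
#'
#' @param params parameter bundle.
#' @param protocol a [pacingProtocol()].
#' @param mode `"stochastic"` or `"deterministic"` spark dynamics.
#' @param seed run seed (stochastic mode).
#' @param state0 optional initial state (defaults to [initCellState()]).
#' @param traceDt output stride for the trace (ms); `0` disables the trace.
#' @param tailMs extra quiescent time integrated after the last beat (ms).
#' @return list with elements `beats` (data.frame), `trace` (data.frame or
#'   `NULL`) and `finalState`.
#' @export
runPaced <- function(params, protocol, mode = c("stochastic", "deterministic"),
                     seed = 1, state0 = NULL, traceDt = 0, tailMs = 0) {
  mode <- match.arg(mode)
  pv <- asParamVector(params)
  sch <- protocolSchedule(protocol, pv[["stimDur"]])
  if (is.null(state0))
    state0 <- initCellState(params, stochastic = mode == "stochastic")
  out <- .engine_run(pv, matrix(as.numeric(state0), ncol = 1), 1L, 1L,
                     sch$times, sch$cls, 1, mode == "stochastic", seed,
                     0L, traceDt, numeric(0), sch$tEnd + tailMs, FALSE)
  fs <- out$finalState[, 1]
  names(fs) <- stateNames()
  list(beats = out$beats[[1]],
       trace = if (traceDt > 0) out$trace else NULL,
       finalState = fs)
}

#' Dynamic cycle-length sweep
#'
#' Paces the cell for `beatsPerCl` beats at each cycle length in `cls`
#' (in the order given), carrying the state across segments -- the
#' up-sweep/down-sweep protocol used to expose hysteresis and the
#' bistable alternans window.
#'
#' @param params parameter bundle.
#' @param cls cycle lengths in sweep order (ms).
#' @param beatsPerCl beats paced at each cycle length.
#' @param mode spark dynamics mode.
#' @param seed run seed.
#' @param keepLast per-beat records kept per cycle length (from the end).
#' @return data.frame of the kept beats with their cycle length and sweep
#'   position.
#' @export
dynamicSweep <- function(params, cls, beatsPerCl = 200,
                         mode = c("deterministic", "stochastic"), seed = 1,
                         keepLast = 50) {
  mode <- match.arg(mode)
  protocol <- pacingProtocol(cls, rep(beatsPerCl, length(cls)))
  run <- runPaced(params, protocol, mode = mode, seed = seed)
  b <- run$beats
  b$segment <- rep(seq_along(cls), each = beatsPerCl)
  b$beatInSegment <- rep(seq_len(beatsPerCl), length(cls))
  b[b$beatInSegment > beatsPerCl - keepLast, , drop = FALSE]
}

#' S1S2 restitution protocol
#'
#' Paces at the S1 cycle length to steady state, then delivers a single S2
#' beat at each coupling interval from the stored steady state, recording
#' the final APD and the preceding diastolic interval (both at the -40 mV
#' convention).  S2 beats that fail to elicit an action potential are
#' recorded as no-capture and excluded from the table.
#'
#' @param params parameter bundle.
#' @param s1 S1 cycle length (ms).
#' @param s2List S2 coupling intervals (ms).
#' @param s1Beats conditioning beats at S1.
#' @param mode spark dynamics mode.
#' @param seed run seed.
#' @return data.frame with columns `s2`, `di`, `apd` (ms) plus a
#'   `noCapture` attribute listing excluded S2 values.
#' @export
s1s2Restitution <- function(params, s1 = 500, s2List = seq(250, 700, by = 25),
                            s1Beats = 50, mode = c("deterministic", "stochastic"),
                            seed = 1) {
  mode <- match.arg(mode)
  base <- runPaced(params, pacingProtocol(s1, s1Beats), mode = mode, seed = seed)
  lastBeat <- base$beats[s1Beats, ]
  rows <- lapply(s2List, function(s2) {
    pr <- pacingProtocol(s1, 1, s2 = s2)
    run <- runPaced(params, pr, mode = mode, seed = seed + 1,
                    state0 = base$finalState, tailMs = 600)
    s2beat <- run$beats[2, ]
    data.frame(s2 = s2, di = s2beat$di40, apd = s2beat$apd40,
               captured = is.finite(s2beat$tUp) && !s2beat$capped)
  })
  tab <- do.call(rbind, rows)
  nc <- tab$s2[!tab$captured]
  if (length(nc))
    message("no capture at S2 = ", paste(nc, collapse = ", "), " ms (excluded)")
  out <- tab[tab$captured, c("s2", "di", "apd")]
  out <- out[order(out$di), ]
  rownames(out) <- NULL
  attr(out, "noCapture") <- nc
  out
}

#' Alternans / bistability window from up- and down-sweeps
#'
#' Runs the dynamic pacing protocol up and then down across `cls`
#' (carrying the state between cycle lengths), classifies each cycle
#' length in each direction as period-1 or alternans (last `keepLast`
#' APD-40mV range above `ampThreshold`), and reports the window over
#' which the two sweeps settle on different regimes.  When the window is
#' narrower than the sweep increment (both sweeps switch at the same
#' grid point) the window is degenerate and its upper end is reported as
#' that common transition cycle length, with zero width.
#'
#' @param params parameter bundle (the reduced-inactivation preset for
#'   the reference protocol).
#' @param cls cycle lengths of the sweep, ascending (ms).
#' @param beatsPerCl beats paced per cycle length.
#' @param keepLast beats summarized per cycle length.
#' @param ampThreshold APD range (ms) classifying alternans.
#' @param mode spark dynamics mode.
#' @param seed run seed.
#' @return list with `upper`, `lower` (ms), `width`, `window` (the
#'   disagreeing cycle lengths), `jump` (alternans amplitude at onset,
#'   ms), and the per-CL summary `table`.
#' @export
alternansWindow <- function(params, cls = seq(475, 550, by = 2),
                            beatsPerCl = 200, keepLast = 50,
                            ampThreshold = 40,
                            mode = "deterministic", seed = 1) {
  cls <- sort(cls)
  sweep <- function(order, startCl) {
    r <- runPaced(params, pacingProtocol(startCl, beatsPerCl),
                  mode = mode, seed = seed)
    t(vapply(order, function(cl) {
      r <<- runPaced(params, pacingProtocol(cl, beatsPerCl), mode = mode,
                     seed = seed, state0 = r$finalState)
      a <- tail(r$beats$apd40, keepLast)
      c(cl = cl, amp = diff(range(a, na.rm = TRUE)),
        mean = mean(a, na.rm = TRUE))
    }, numeric(3)))
  }
  up <- sweep(cls, min(cls) - 5)
  dn <- sweep(rev(cls), max(cls) + 5)
  dn <- dn[order(dn[, "cl"]), , drop = FALSE]
  altUp <- up[, "amp"] > ampThreshold
  altDn <- dn[, "amp"] > ampThreshold
  differs <- xor(altUp, altDn)
  tab <- data.frame(cl = cls, ampUp = up[, "amp"], ampDown = dn[, "amp"],
                    alternansUp = altUp, alternansDown = altDn,
                    differs = differs)
  alt <- cls[altUp & altDn]
  onset <- if (length(alt)) min(alt) else NA_real_
  jump <- if (is.finite(onset))
    max(tab$ampUp[tab$cl == onset], tab$ampDown[tab$cl == onset])
  else NA_real_
  if (any(differs)) {
    upper <- max(cls[differs]); lower <- min(cls[differs])
    width <- upper - lower
  } else {
    upper <- onset; lower <- onset; width <- 0
  }
  list(upper = upper, lower = lower, width = width,
       window = cls[differs], jump = jump, table = tab)
}
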