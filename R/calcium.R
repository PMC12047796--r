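#' Ca state constructor
#'
#' Free Ca concentrations of the four cell compartments: cytosol near
#' junctional clusters (`cb`), cytosol near non-junctional clusters (`ci`),
#' and the corresponding SR volumes (`csrb`, `csri`), all in uM.
#'
#' @param cb,ci,csrb,csri concentrations (uM).
#' @param params parameter bundle (used for the SR capacity bound).
#' @return named numeric vector of class `caState`.
#' @export
caState <- function(cb = 0.1, ci = 0.1, csrb = 750, csri = 750,
                    params = defaultParams()) {
  v <- c(cb = cb, ci = ci, csrb = csrb, csri = csri)
  if (any(v < 0)) stop("state corruption: concentrations must be >= 0")
  if (csrb > params[["csrMax"]] || csri > params[["csrMax"]])
    stop("SR concentration exceeds the capacity bound csrMax")
  structure(v, class = "caState")
}

#' Compartment Ca fluxes
#'
#' Evaluates the eight fluxes of the compartment topology (all whole-cell
#' uM/ms): spark release `Jrb = gb*csrb*pb`; threshold-gated NJ release
#' `Jri` (zero by default); saturating SERCA uptake `Jupb`/`Jupi`;
#' diffusive exchange `Jdc` (cytosol, positive J -> NJ, proportional to
#' `cb - ci`) and `Jdsr` (SR, proportional to `csrb - csri`); the membrane
#' fluxes `JCa` (L-type Ca entry) and `JNaCa` (exchanger, signed into the
#' junctional cytosol); plus the two small SR leak terms.
#'
#' @param ca a `caState` (or the four concentrations in order).
#' @param pb active spark fraction.
#' @param V membrane voltage (mV), drives the exchanger.
#' @param params parameter bundle.
#' @param jca optional externally computed LCC Ca entry (uM/ms); if `NULL`
#'   it is 0 (the cell integrator supplies it from the LCC state).
#' @return named numeric vector of fluxes.
#' @export
caFluxes <- function(ca, pb, V, params, jca = NULL) {
  v <- as.numeric(ca)
  if (any(!is.finite(v)) || any(v < 0))
    stop("state corruption: non-finite or negative concentration")
  s <- initCellState(params, V = V)
  s[c("cb", "ci", "csrb", "csri")] <- v
  cur <- .membrane_currents_cpp(as.numeric(s), asParamVector(params))
  if (is.null(jca)) jca <- 0
  .ca_fluxes_cpp(as.numeric(s), pb, jca, unname(cur[["jnaca"]]),
                 asParamVector(params))
}

#' Advance the compartment concentrations one step
#'
#' Each compartment is updated by its net flux divided by its volume
#' fraction, with the rapid-buffering factor applied to the cytosolic
#' compartments and the constant SR buffering factor to the SR.  A step
#' that would drive any concentration negative raises a step-size error
#' rather than clamping.
#'
#' @param ca a `caState`.
#' @param fluxes named flux vector from [caFluxes()].
#' @param dt time step (ms).
#' @param params parameter bundle.
#' @return the advanced `caState`.
#' @export
caStep <- function(ca, fluxes, dt, params) {
  if (dt <= 0) stop("dt must be > 0")
  f <- as.list(fluxes)
  vb <- params[["vb"]]; vi <- params[["vi"]]
  vsrb <- params[["vsrb"]]; vsri <- params[["vsri"]]
  bSR <- params[["betaSR"]]
  B <- params[["Bcyt"]]; K <- params[["Kbuf"]]
  # conservative update: advance the buffered total, invert the isotherm
  wTot <- function(c1) c1 + B * c1 / (K + c1)
  wInv <- function(w) {
    b <- K + B - w
    0.5 * (-b + sqrt(b^2 + 4 * K * w))
  }
  v <- as.numeric(ca)
  dcb <- (f$Jrb + f$JCa + f$JNaCa + f$Jleakb - f$Jupb - f$Jdc) / vb
  dci <- (f$Jri + f$Jdc + f$Jleaki - f$Jupi) / vi
  dcsrb <- (f$Jupb - f$Jrb - f$Jleakb - f$Jdsr) / vsrb
  dcsri <- (f$Jupi + f$Jdsr - f$Jri - f$Jleaki) / vsri
  out <- c(wInv(wTot(v[1]) + dt * dcb), wInv(wTot(v[2]) + dt * dci),
           v[3] + dt * bSR * dcsrb, v[4] + dt * bSR * dcsri)
  if (any(out < 0))
    stop("step-size error: a concentration would become negative at this dt")
  caState(out[1], out[2], out[3], out[4], params = params)
}

#' Total cell Ca content
#'
#' Volume-weighted total Ca (free + buffered) across the four
#' compartments; invariant when the membrane fluxes are disabled.
#'
#' @param ca a `caState`.
#' @param params parameter bundle.
#' @return total Ca in uM referred to the whole-cell volume.
#' @export
totalCa <- function(ca, params) {
  v <- as.numeric(ca)
  bound <- function(c1)
    params[["Bcyt"]] * c1 / (params[["Kbuf"]] + c1)  # equilibrium-bound buffer
  cyt <- params[["vb"]] * (v[1] + bound(v[1])) +
         params[["vi"]] * (v[2] + bound(v[2]))
  # constant-factor SR buffering: bound SR Ca = free * (1/betaSR - 1)
  sr <- (params[["vsrb"]] * v[3] + params[["vsri"]] * v[4]) / params[["betaSR"]]
  cyt + sr
}

#' Resting Ca state
#'
#' Locates the quiescent balance of the Ca subsystem at the resting
#' voltage by integrating the unstimulated cell to near-stationarity.
#'
#' @param params parameter bundle.
#' @param tMax integration horizon (ms).
#' @return a `caState` at the calibrated resting point.
#' @export
caRestingState <- function(params, tMax = 20000) {
  pv <- asParamVector(params)
  s0 <- matrix(initCellState(params), ncol = 1)
  out <- .engine_run(pv, s0, 1L, 1L, numeric(0), numeric(0), 1,
                     FALSE, 1, 0L, 0, numeric(0), tMax, FALSE)
  fs <- out$finalState[, 1]
  names(fs) <- stateNames()
  caState(fs[["cb"]], fs[["ci"]], fs[["csrb"]], fs[["csri"]], params = params)
}
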