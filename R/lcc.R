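#' Ca-dependent inactivation gate
#'
#' \eqn{F_{Ca}(c_b) = 1 / (1 + (c_{th}/c_b)^2)}: the fraction of maximal
#' Ca-induced inactivation at junctional Ca concentration `cb`.  Returns 0
#' at `cb = 0` (limit), is monotone increasing, and tends to 1 as
#' `cb -> Inf`.
#'
#' @param cb junctional Ca concentration (uM).
#' @param cth inactivation threshold (uM), > 0.
#' @return fraction in `[0, 1]`; vectorized over `cb`.
#' @export
fcaGate <- function(cb, cth) {
  if (cth <= 0) stop("cth must be > 0")
  if (any(cb < 0)) stop("cb must be >= 0")
  vapply(cb, function(c1) .fca_cpp(c1, cth), numeric(1))
}

#' Ca-dependent inactivation rates of the L-type channel
#'
#' `a24 = a24o + ACa * FCa(cb)` and `a34 = a34o + ACa * FCa(cb)` for
#' channels away from an active spark; channels in a spark's junctional
#' space face the high local spark Ca (100 uM by default), for which
#' `FCa` is effectively 1.
#'
#' @param cb junctional Ca (uM), sensed by spark-off channels.
#' @param params parameter bundle.
#' @param sparkOn logical; use the spark-local Ca instead of `cb`.
#' @return named vector `c(a24, a34)` in 1/ms.
#' @export
lccInactivationRates <- function(cb, params, sparkOn = FALSE) {
  .lcc_inact_rates_cpp(cb, asParamVector(params), sparkOn)
}

#' LCC state constructor
#'
#' Occupancies of the ten Markov states: C1, C2, O, I1, I2 for the
#' spark-off population and CS1, CS2, OS, IS1, IS2 for channels facing an
#' active spark.  Occupancies are population fractions summing to 1.
#'
#' @param occupancy named numeric vector; missing states are 0.  Defaults
#'   to all channels in C1.
#' @return named numeric vector of class `lccState`.
#' @export
lccState <- function(occupancy = c(C1 = 1)) {
  st <- setNames(numeric(10), lccStateNames())
  bad <- setdiff(names(occupancy), names(st))
  if (length(bad)) stop("unknown LCC state(s): ", paste(bad, collapse = ", "))
  st[names(occupancy)] <- occupancy
  if (any(st < 0)) stop("occupancies must be >= 0")
  if (abs(sum(st) - 1) > 1e-9) stop("occupancies must sum to 1")
  structure(st, class = "lccState")
}

lccStateNames <- function()
  c("C1", "C2", "O", "I1", "I2", "CS1", "CS2", "OS", "IS1", "IS2")

#' LCC transition-rate generator
#'
#' Builds the 10x10 generator matrix (entry `[i, j]` is the rate i -> j)
#' at membrane voltage `V` and junctional Ca `cb`.  Voltage acts on the
#' C1 <-> C2 activation step and on the recovery rates; Ca acts on the
#' inactivation rates (spark-on states sense the fixed spark-local Ca).
#' Open channels exchange between the populations: O -> OS at the spark
#' recruitment rate, OS -> O at the extinction rate.
#'
#' @param V membrane voltage (mV).
#' @param cb junctional Ca (uM).
#' @param alphaB spark recruitment rate (1/ms).
#' @param betaB spark extinction rate (1/ms).
#' @param params parameter bundle.
#' @return 10x10 matrix with state dimnames.
#' @export
lccGenerator <- function(V, cb, alphaB, betaB, params) {
  .lcc_generator_cpp(V, cb, alphaB, betaB, asParamVector(params))
}

#' Advance the LCC occupancies one step
#'
#' Deterministic population-fraction update (explicit Euler on the
#' generator).  The per-state exit probability must stay below 1 in one
#' step, otherwise a step-size error is raised; the sum of occupancies is
#' preserved to numerical accuracy and verified to 1e-9 (not forcibly
#' renormalized, so rate errors are not masked).
#'
#' @param state an `lccState`.
#' @inheritParams lccGenerator
#' @param dt time step (ms).
#' @return the advanced `lccState`.
#' @export
lccStep <- function(state, V, cb, alphaB, betaB, dt, params) {
  Q <- lccGenerator(V, cb, alphaB, betaB, params)
  y <- as.numeric(state)
  out <- rowSums(Q)
  if (any(out * dt >= 1))
    stop(sprintf("LCC step too large: exit probability %.3f >= 1; reduce dt",
                 max(out * dt)))
  dy <- as.numeric(t(Q) %*% y) - out * y
  y2 <- y + dt * dy
  if (abs(sum(y2) - 1) > 1e-9)
    stop("LCC occupancy conservation violated beyond tolerance 1e-9")
  structure(setNames(y2, lccStateNames()), class = "lccState")
}

#' LCC Ca flux and ionic current
#'
#' The whole-cell L-type current is the total open fraction (O + OS) times
#' a Goldman-Hodgkin-Katz-style driving term; the matching Ca flux into
#' the junctional cytosol is the same quantity expressed in uM/ms via the
#' fixed current-to-flux conversion `wca`.
#'
#' @param state an `lccState` (or full cell state vector).
#' @param V membrane voltage (mV).
#' @param cb junctional Ca (uM).
#' @param params parameter bundle.
#' @return named vector `c(ICa, JCa)`: current (uA/uF, inward negative)
#'   and flux (uM/ms, entry positive).
#' @export
lccFluxes <- function(state, V, cb, params) {
  s <- initCellState(params, V = V)
  s[["cb"]] <- cb
  s[lccStateNames()] <- as.numeric(state)
  cur <- .membrane_currents_cpp(as.numeric(s), asParamVector(params))
  c(ICa = unname(cur[["ica"]]), JCa = unname(cur[["jca"]]))
}

#' Membrane currents of the full cell state
#'
#' Evaluates all membrane currents (outward positive) and the two membrane
#' Ca fluxes for a full 26-component state vector.
#'
#' @param state full cell state vector ([initCellState()]).
#' @param params parameter bundle.
#' @return named numeric vector with `ina, ikr, iks, ik1, itos, itof,
#'   inak, inaca, ica, itot, jca, jnaca`.
#' @export
membraneCurrents <- function(state, params) {
  .membrane_currents_cpp(as.numeric(state), asParamVector(params))
}
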