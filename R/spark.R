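#' Spark state constructor
#'
#' The population of junctional (J) ryanodine-receptor clusters is described
#' by the number of clusters currently firing a Ca spark: an integer count
#' `nb` out of `Nb` clusters in stochastic mode, or the continuous fraction
#' `pb` in the deterministic (mean-field) limit.
#'
#' @param Nb total number of J clusters.
#' @param nb active spark count (stochastic mode).
#' @param pb active fraction (deterministic mode).
#' @param mode `"stochastic"` or `"deterministic"`.
#' @return object of class `sparkState`.
#' @export
sparkState <- function(Nb, nb = 0, pb = nb / Nb,
                       mode = c("stochastic", "deterministic")) {
  mode <- match.arg(mode)
  if (Nb < 1) stop("invariant violated: Nb >= 1")
  if (mode == "stochastic") {
    if (nb < 0 || nb > Nb) stop("invariant violated: 0 <= nb <= Nb")
    pb <- nb / Nb
  } else {
    if (pb < 0 || pb > 1) stop("invariant violated: 0 <= pb <= 1")
    nb <- pb * Nb
  }
  structure(list(Nb = Nb, nb = nb, pb = pb, mode = mode),
            class = "sparkState")
}

#' @export
print.sparkState <- function(x, ...) {
  cat(sprintf("<sparkState %s> Nb=%g nb=%g pb=%.4f\n",
              x$mode, x$Nb, x$nb, x$pb))
  invisible(x)
}

#' One stochastic spark-recruitment step
#'
#' Advances the active spark count by binomial recruitment and extinction:
#' the number of newly recruited sparks is Binomial(`alphaB dt`, `Nb - nb`)
#' and the number extinguished is Binomial(`betaB dt`, `nb`), so the count
#' stays in `[0, Nb]` by construction.  Probabilities above 1 are an error
#' (the step must be shrunk), never silently clipped.
#'
#' @param state a `sparkState` in stochastic mode.
#' @param alphaB recruitment rate (1/ms).
#' @param betaB extinction rate (1/ms).
#' @param dt time step (ms).
#' @return the advanced `sparkState`.
#' @export
stochasticSparkStep <- function(state, alphaB, betaB, dt) {
  stopifnot(inherits(state, "sparkState"))
  if (state$mode != "stochastic") stop("state is not in stochastic mode")
  if (alphaB < 0 || betaB < 0) stop("rates must be >= 0")
  pUp <- alphaB * dt
  pDn <- betaB * dt
  if (pUp > 1 || pDn > 1)
    stop(sprintf("rate overflow: alphaB*dt = %g, betaB*dt = %g; both must be <= 1 (reduce dt)",
                 pUp, pDn))
  up <- rbinom(1, state$Nb - state$nb, pUp)
  dn <- rbinom(1, state$nb, pDn)
  sparkState(state$Nb, nb = state$nb + up - dn, mode = "stochastic")
}

#' One deterministic (mean-field) spark step
#'
#' Explicit-Euler step of the mean-field limit
#' \eqn{dp_b/dt = \alpha_b (1 - p_b) - \beta_b p_b}, the `Nb -> Inf` limit
#' of the binomial scheme.
#'
#' @inheritParams stochasticSparkStep
#' @export
deterministicSparkStep <- function(state, alphaB, betaB, dt) {
  stopifnot(inherits(state, "sparkState"))
  if (state$mode != "deterministic") stop("state is not in deterministic mode")
  if (alphaB < 0 || betaB < 0) stop("rates must be >= 0")
  pb <- state$pb + dt * (alphaB * (1 - state$pb) - betaB * state$pb)
  sparkState(state$Nb, pb = min(1, max(0, pb)), mode = "deterministic")
}

#' Spark-mediated SR release flux
#'
#' `Jrb = gb * csrb * pb`: the whole-cell release flux from junctional SR is
#' proportional to the junctional SR load and the fraction of clusters with
#' an active spark.
#'
#' @param pb active spark fraction (or a `sparkState`).
#' @param csrb junctional SR Ca concentration (uM).
#' @param gb release conductance (1/ms).
#' @return flux in uM/ms.
#' @export
sparkReleaseFlux <- function(pb, csrb, gb) {
  if (inherits(pb, "sparkState")) pb <- pb$pb
  if (csrb < 0) stop("csrb must be >= 0")
  gb * csrb * pb
}

#' Spark recruitment rate
#'
#' The recruitment rate at J clusters is driven by local L-type channel
#' openings and gated by the junctional SR load:
#' `alphaB = gAlpha * openFraction * load`, with
#' `load = (csrb/Ksr)^nSr / (1 + (csrb/Ksr)^nSr)`.
#'
#' @param openFraction spark-off open occupancy of the L-type channel.
#' @param csrb junctional SR Ca (uM).
#' @param params parameter bundle.
#' @return recruitment rate (1/ms).
#' @export
sparkRecruitmentRate <- function(openFraction, csrb, params) {
  lr <- (csrb / params[["Ksr"]])^params[["nSr"]]
  params[["gAlpha"]] * openFraction * lr / (1 + lr)
}
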