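# Shared fixtures: small, fast parameter bundles and cached runs.

fastParams <- function(preset = "normal", ...) {
  defaultParams(preset, ...)
}

# a short deterministic paced run reused across tests
cachedRun <- local({
  cache <- new.env()
  function(preset = "normal", cl = 500, beats = 12, traceDt = 0.1) {
    key <- paste(preset, cl, beats, traceDt, sep = "_")
    if (is.null(cache[[key]])) {
      cache[[key]] <- runPaced(defaultParams(preset),
                               pacingProtocol(cl, beats),
                               mode = "deterministic", traceDt = traceDt)
    }
    cache[[key]]
  }
})

# analytic two-state relaxation for the LCC sub-chain oracle
twoStateRelax <- function(p0, kOpen, kClose, t) {
  pInf <- kOpen / (kOpen + kClose)
  pInf + (p0 - pInf) * exp(-(kOpen + kClose) * t)
}
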