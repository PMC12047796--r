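#' @useDynLib eadsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats splinefun sd uniroot approx rbinom setNames
#' @importFrom utils modifyList write.table read.table head tail packageVersion
#' @importFrom graphics hist
NULL

# Master registry: one row per model constant.  Units convention is fixed
# globally: ms, mV, uM, cm, uA/uF; fluxes are whole-cell uM/ms.
paramRegistry <- function() {
  reg <- rbind(
    # section, name, default, min, max, description
    c("physics", "frt",    0.03767, 0.001, 1,   "F/RT at 308 K (1/mV)"),
    c("physics", "Cm",     1,       1e-6,  10,  "membrane capacitance (uF/cm^2)"),
    c("physics", "Ko",     5.4,     0.1,   50,  "external K (mM)"),
    c("physics", "Nao",    136,     1,     500, "external Na (mM)"),
    c("physics", "Cao",    1.8,     0.1,   20,  "external Ca (mM)"),
    c("physics", "Nai",    14,      1,     50,  "internal Na, fixed (mM)"),
    c("physics", "Ki",     140,     10,    300, "internal K, fixed (mM)"),
    c("ionic",   "gna",    8,      0,     100, "INa conductance (mS/uF)"),
    c("ionic",   "gkr",    0.02,  0,     1,   "IKr conductance (mS/uF)"),
    c("ionic",   "gks",    0.3,    0,     2,   "IKs conductance (mS/uF)"),
    c("ionic",   "gk1",    0.3,     0,     2,   "IK1 conductance (mS/uF)"),
    c("ionic",   "gtos",   0.04,    0,     1,   "slow Ito conductance (mS/uF)"),
    c("ionic",   "gtof",   0.11,    0,     1,   "fast Ito conductance (mS/uF)"),
    c("ionic",   "jSpeed", 1,       0.01,  100, "INa j-gate kinetics scale factor"),
    c("ionic",   "xs2TauScale", 4,   0.01,  100, "tau(xs2) as a multiple of tau(xs1)"),
    c("ionic",   "gnak",   1.5,     0,     10,  "NaK pump scale (uA/uF)"),
    c("ionic",   "gnaca",  800,     0,     1e5, "NCX flux scale (uM/ms)"),
    c("ionic",   "ksat",   0.27,    0,     1,   "NCX saturation factor"),
    c("ionic",   "eta",    0.35,    0,     1,   "NCX energy partition"),
    c("ionic",   "xkmna",  87.5,    1,     500, "NCX Km for Na (mM)"),
    c("ionic",   "xkmca",  1.38,    0.01,  20,  "NCX Km for Ca (mM)"),
    c("lcc",     "gca",    23.5,      0,     500, "LCC current scale (uA/uF per mM)"),
    c("lcc",     "cth",    5,       1e-3,  100, "Ca inactivation threshold (uM)"),
    c("lcc",     "ACa",    0.15,    0,     10,  "Ca-induced inactivation strength (1/ms)"),
    c("lcc",     "a24o",   0.001,   0,     10,  "baseline C2->I1 inactivation (1/ms)"),
    c("lcc",     "a34o",   0.002,   0,     10,  "baseline O->I1 inactivation (1/ms)"),
    c("lcc",     "tauD",   2,       0.01,  1e9, "activation time constant (ms)"),
    c("lcc",     "vAct",   -10,     -80,   40,  "activation half-voltage (mV)"),
    c("lcc",     "sAct",   5,    0.1,   40,  "activation slope (mV)"),
    c("lcc",     "kOpen",  1,       0,     50,  "C2->O rate (1/ms)"),
    c("lcc",     "kClose", 0.5,     0,     50,  "O->C2 rate (1/ms)"),
    c("lcc",     "r42",    0.015,    0,     10,  "I1->C2 recovery amplitude (1/ms)"),
    c("lcc",     "v42",    -15,     -100,  40,  "I1->C2 recovery half-voltage (mV)"),
    c("lcc",     "s42",    6,       0.1,   40,  "I1->C2 recovery slope (mV)"),
    c("lcc",     "a45",    0.0028,   0,     10,  "I1->I2 deep inactivation (1/ms)"),
    c("lcc",     "r54",    0.0045,   0,     10,  "I2->I1 recovery amplitude (1/ms)"),
    c("lcc",     "v54",    -70,     -120,  40,  "I2->I1 recovery half-voltage (mV)"),
    c("lcc",     "s54",    6,       0.1,   40,  "I2->I1 recovery slope (mV)"),
    c("lcc",     "caSparkLocal", 100, 0.1, 1e4, "local Ca at spark-on LCCs (uM)"),
    c("spark",   "Nb",     4000,    1,     1e9, "number of junctional RyR clusters"),
    c("spark",   "betaB",  0.05,    0,     10,  "spark extinction rate (1/ms)"),
    c("spark",   "gAlpha", 0.3,    0,     100, "spark recruitment gain (1/ms)"),
    c("spark",   "Ksr",    650,     1,     1e4, "SR-load sensitivity of recruitment (uM)"),
    c("spark",   "nSr",    2,       0.5,   12,  "SR-load Hill exponent of recruitment"),
    c("ca",      "gb",     0.005,   0,     10,  "RyR release conductance (1/ms)"),
    c("ca",      "gri",    0,       0,     10,  "NJ release conductance (1/ms), off by default"),
    c("ca",      "criTh",  2,       0,     100, "NJ release activation threshold (uM)"),
    c("ca",      "vb",     0.2,     1e-4,  1,   "cytosolic volume fraction near J clusters"),
    c("ca",      "vi",     0.7,     1e-4,  1,   "cytosolic volume fraction near NJ clusters"),
    c("ca",      "vsrb",   0.03,    1e-4,  1,   "SR volume fraction near J clusters"),
    c("ca",      "vsri",   0.07,    1e-4,  1,   "SR volume fraction near NJ clusters"),
    c("ca",      "vup",    0.23,     0,     100, "maximal SERCA uptake (uM/ms)"),
    c("ca",      "cup",    0.5,     1e-3,  100, "SERCA half-activation (uM)"),
    c("ca",      "gdc",    0.01,    0,     10,  "cytosolic J<->NJ exchange (1/ms)"),
    c("ca",      "gdsr",   0.001,   0,     10,  "SR J<->NJ exchange (1/ms)"),
    c("ca",      "gsrleak", 1e-5,   0,     1,   "SR leak (1/ms)"),
    c("ca",      "gcab",   0,       0,     1,   "background Ca current (mS/uF)"),
    c("ca",      "wca",    0.03,    1e-6,  100, "flux per unit current (uM/ms per uA/uF)"),
    c("ca",      "Bcyt",   46,      0,     1e4, "cytosolic buffer concentration (uM)"),
    c("ca",      "Kbuf",   0.6,     1e-3,  100, "cytosolic buffer Kd (uM)"),
    c("ca",      "betaSR", 0.1,     1e-4,  1,   "SR instantaneous-buffering factor"),
    c("ca",      "csrMax", 5000,    1,     1e5, "SR capacity bound (uM)"),
    c("tissue",  "DV",     1e-4,    0,     1,   "voltage diffusion coefficient (cm^2/ms)"),
    c("tissue",  "dx",     0.015,   1e-4,  1,   "grid spacing (cm)"),
    c("tissue",  "dtFast", 0.01,    1e-5,  1,   "fast time step (ms)"),
    c("tissue",  "dtSlow", 0.1,     1e-5,  1,   "slow time step (ms)"),
    c("tissue",  "dvdtFast", 1,     0,     100, "dV/dt switching to the fast step (mV/ms)"),
    c("tissue",  "postStimFast", 5, 0,     100, "fast-step window after a stimulus (ms)"),
    c("protocol", "stimAmp", 40,    0,     500, "stimulus amplitude (uA/uF)"),
    c("protocol", "stimDur", 2,     0,     50,  "stimulus duration (ms)"),
    c("analysis", "eadDelay", 80,   0,     1e3, "blanking after upstroke before EAD detection (ms)"),
    c("analysis", "eadJump", 2,     0,     100, "secondary-rise amplitude flagging an EAD (mV)")
  )
  data.frame(section = reg[, 1], name = reg[, 2],
             default = as.numeric(reg[, 3]), min = as.numeric(reg[, 4]),
             max = as.numeric(reg[, 5]), description = reg[, 6],
             stringsAsFactors = FALSE)
}

#' Model parameter bundle
#'
#' Returns the validated parameter bundle for the ventricular cell / tissue
#' model.  Two named presets are provided: `"normal"` (full Ca-induced
#' inactivation of the L-type channel, `ACa = 0.15`) and `"ead"` (reduced
#' Ca-induced inactivation, `ACa = 0.09`, which promotes early
#' afterdepolarizations at slow pacing).  Any constant can be overridden;
#' the bundle records per-parameter provenance (default, preset, or user).
#'
#' @param preset `"normal"` or `"ead"`.
#' @param ... named numeric overrides, e.g. `Nb = 1000`.
#' @return a named numeric vector of class `eadsimParams` with attributes
#'   `provenance` (character, per parameter) and `preset`.
#' @examples
#' p <- defaultParams("ead", Nb = 2000)
#' p[["ACa"]]
#' @export
defaultParams <- function(preset = c("normal", "ead"), ...) {
  preset <- match.arg(preset)
  reg <- paramRegistry()
  p <- setNames(reg$default, reg$name)
  prov <- setNames(rep("default", nrow(reg)), reg$name)
  if (preset == "ead") {
    p[["ACa"]] <- 0.09
    prov[["ACa"]] <- "preset:ead"
  }
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("overrides must be named")
    unknown <- setdiff(names(over), reg$name)
    if (length(unknown))
      warning("unknown parameter(s) ignored: ", paste(unknown, collapse = ", "))
    for (nm in intersect(names(over), reg$name)) {
      p[[nm]] <- as.numeric(over[[nm]])
      prov[[nm]] <- "user"
    }
  }
  structure(p, provenance = prov, preset = preset, class = "eadsimParams")
}

#' @export
print.eadsimParams <- function(x, ...) {
  reg <- paramRegistry()
  prov <- attr(x, "provenance")
  cat("<eadsimParams> preset:", attr(x, "preset"), "\n")
  for (sec in unique(reg$section)) {
    cat("--", sec, "--\n")
    for (nm in reg$name[reg$section == sec]) {
      tag <- if (prov[[nm]] == "default") "" else paste0("  [", prov[[nm]], "]")
      cat(sprintf("  %-12s %12g%s\n", nm, x[[nm]], tag))
    }
  }
  invisible(x)
}

#' Validate a parameter bundle
#'
#' Checks every constant against its documented admissible range plus the
#' cross-parameter invariants (positive volumes, `Nb >= 1`, `cth > 0`, and
#' the explicit-diffusion stability bound `dtSlow <= dx^2/(4 DV)`).
#'
#' @param p an `eadsimParams` bundle (or named numeric vector).
#' @return `p`, invisibly; errors name the violated invariant.
#' @export
validateParams <- function(p) {
  reg <- paramRegistry()
  miss <- setdiff(reg$name, names(p))
  if (length(miss))
    stop("missing required parameter(s): ", paste(miss, collapse = ", "))
  for (i in seq_len(nrow(reg))) {
    v <- p[[reg$name[i]]]
    if (!is.finite(v) || v < reg$min[i] || v > reg$max[i])
      stop(sprintf("parameter '%s' = %g violates its range [%g, %g]",
                   reg$name[i], v, reg$min[i], reg$max[i]))
  }
  if (p[["Nb"]] < 1) stop("invariant violated: Nb >= 1")
  if (p[["cth"]] <= 0) stop("invariant violated: cth > 0")
  if (any(p[c("vb", "vi", "vsrb", "vsri")] <= 0))
    stop("invariant violated: all volumes > 0")
  if (p[["DV"]] > 0 && p[["dtSlow"]] > p[["dx"]]^2 / (4 * p[["DV"]]) + 1e-12)
    stop(sprintf("invariant violated: dtSlow (%g) > dx^2/(4 DV) (%g)",
                 p[["dtSlow"]], p[["dx"]]^2 / (4 * p[["DV"]])))
  invisible(p)
}

#' Read a parameter file
#'
#' The on-disk format is a flat, human-readable YAML document of
#' `name: value` pairs (sections are optional nesting and are flattened on
#' read).  Keys absent from the file take their preset defaults; unknown
#' keys raise a warning; out-of-range values raise a validation error.
#'
#' @param path file to read.
#' @param preset base preset applied before the file's overrides.
#' @return a validated `eadsimParams` bundle with provenance `"file"` for
#'   every key the document set.
#' @export
loadParams <- function(path, preset = "normal") {
  doc <- yaml::read_yaml(path)
  flat <- list()
  if (length(doc)) {
    for (k in names(doc)) {
      v <- doc[[k]]
      if (is.list(v)) flat <- c(flat, v) else flat[[k]] <- v
    }
  }
  p <- do.call(defaultParams, c(list(preset = preset), flat))
  prov <- attr(p, "provenance")
  prov[names(prov) %in% names(flat)] <- "file"
  attr(p, "provenance") <- prov
  validateParams(p)
  p
}

#' Write a parameter bundle
#'
#' Serializes the full resolved bundle (sectioned, one key per line) so that
#' `loadParams()` on the result reproduces the bundle field-by-field.
#'
#' @param p an `eadsimParams` bundle.
#' @param path output file.
#' @export
writeParams <- function(p, path) {
  validateParams(p)
  reg <- paramRegistry()
  doc <- list()
  for (sec in unique(reg$section)) {
    nms <- reg$name[reg$section == sec]
    doc[[sec]] <- as.list(setNames(as.numeric(p[nms]), nms))
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}
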