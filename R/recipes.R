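#' Named experiment recipes
#'
#' Each recipe encodes one of the study's pacing protocols as data:
#' preset, mode, protocol constants, and grid geometry.  `scale` reduces
#' beat counts and grid sizes proportionally for desk-scale runs while
#' recording the full settings in the manifest.
#'
#' @param name one of `"fig2"` (single-cell APD fluctuations, CL 500 ms),
#'   `"fig3"` (dynamic cycle-length sweep 440-552 ms, both presets),
#'   `"fig4"` (uniformly paced N x N tissue), `"fig5"` (deterministic
#'   up/down sweep hysteresis), `"fig6"` (3 x 100 paced strip),
#'   `"fig7"` (100 x 100 planar-wave pacing with a 10-cell strip),
#'   `"fig8"` (S1S2 restitution and map analysis), `"fig9"` (tissue-strip
#'   S1S2, block threshold and phase diagram).
#' @param scale factor in (0, 1] shrinking beat counts / grid sizes.
#' @param seed run seed stored in the recipe.
#' @return object of class `runRecipe`.
#' @export
figureRecipe <- function(name = c("fig2", "fig3", "fig4", "fig5", "fig6",
                                  "fig7", "fig8", "fig9"),
                         scale = 1, seed = 1) {
  name <- match.arg(name)
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  sc <- function(n, min = 10) max(min, round(n * scale))
  spec <- switch(name,
    fig2 = list(preset = "normal", mode = "stochastic",
                cl = 500, beats = sc(15000, 200), discard = 50),
    fig3 = list(preset = "ead", mode = "stochastic",
                cls = seq(440, 552, by = 8), beatsPerCl = sc(200, 50),
                keepLast = 50),
    fig4 = list(preset = "ead", mode = "stochastic", cl = 420,
                sizes = c(1, 5, 10), beats = sc(5000, 100), discard = 50),
    fig5 = list(preset = "ead", mode = "deterministic",
                clUp = seq(475, 550, by = 5), beatsPerCl = sc(200, 50)),
    fig6 = list(preset = "ead", mode = "stochastic", nx = 100, ny = 3,
                cl1 = 400, beats1 = sc(30, 10), cl2 = 420,
                beats2 = sc(270, 30)),
    fig7 = list(preset = "ead", mode = "stochastic",
                nx = sc(100, 30), ny = sc(100, 30), strip = 10,
                cl1 = 420, beats1 = sc(20, 5), cl2 = 530, beats2 = sc(25, 5)),
    fig8 = list(preset = "ead", mode = "deterministic", s1 = 500,
                s2 = seq(260, 900, by = 20), s1Beats = 50,
                tRange = c(420, 760)),
    fig9 = list(preset = "ead", mode = "deterministic", nx = 60, ny = 3,
                stimCols = 10, s1 = 500, diBlock = 25,
                tGrid = seq(300, 700, by = 10), nIter = 100))
  structure(list(name = name, scale = scale, seed = seed, spec = spec),
            class = "runRecipe")
}

#' Run a recipe
#'
#' Executes the recipe end-to-end and writes its outputs (delimited-text
#' tables) plus a manifest capturing the resolved parameter bundle, seed,
#' protocol, and package version, so that rerunning from the manifest
#' reproduces the run bit-for-bit.
#'
#' @param recipe a [figureRecipe()].
#' @param outDir output directory (created if missing).
#' @param params optional parameter bundle overriding the recipe preset.
#' @return invisibly, a list of the in-memory results.
#' @export
runRecipe <- function(recipe, outDir = tempfile("eadsim-run-"), params = NULL) {
  if (!inherits(recipe, "runRecipe")) stop("not a runRecipe")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sp <- recipe$spec
  if (is.null(params)) params <- defaultParams(sp$preset)
  res <- switch(recipe$name,
    fig2 = {
      run <- runPaced(params, pacingProtocol(sp$cl, sp$beats),
                      mode = sp$mode, seed = recipe$seed)
      st <- apdStatistics(run$beats$apd90, discard = sp$discard)
      list(beats = run$beats, stats = st)
    },
    fig3 = {
      sw <- dynamicSweep(params, sp$cls, sp$beatsPerCl, mode = sp$mode,
                         seed = recipe$seed, keepLast = sp$keepLast)
      list(sweep = sw)
    },
    fig4 = {
      lapply(sp$sizes, function(N) {
        g <- tissueGrid(params, N, N, mode = sp$mode)
        u <- runUniform(g, pacingProtocol(sp$cl, sp$beats),
                        seed = recipe$seed)
        apd <- u$beats$apd40[-seq_len(min(sp$discard, sp$beats - 1))]
        list(N = N, apd = apd, sd = sd(apd, na.rm = TRUE))
      })
    },
    fig5 = {
      up <- dynamicSweep(params, sp$clUp, sp$beatsPerCl,
                         mode = sp$mode, seed = recipe$seed)
      dn <- dynamicSweep(params, rev(sp$clUp), sp$beatsPerCl,
                         mode = sp$mode, seed = recipe$seed)
      list(up = up, down = dn)
    },
    fig6 = {
      g <- tissueGrid(params, sp$nx, sp$ny, mode = sp$mode)
      u <- runUniform(g, pacingProtocol(c(sp$cl1, sp$cl2),
                                        c(sp$beats1, sp$beats2)),
                      seed = recipe$seed,
                      recordSite = c(sp$nx %/% 2L, max(1L, sp$ny %/% 2L)))
      list(beats = u$beats, repolarization = u$repolarization,
           activation = u$activation)
    },
    fig7 = {
      g <- tissueGrid(params, sp$nx, sp$ny, mode = sp$mode)
      runPlanar(g, pacingProtocol(c(sp$cl1, sp$cl2),
                                  c(sp$beats1, sp$beats2)),
                stripWidth = sp$strip, seed = recipe$seed,
                snapshotDt = 50)
    },
    fig8 = {
      tab <- s1s2Restitution(params, s1 = sp$s1, s2List = sp$s2,
                             s1Beats = sp$s1Beats, mode = sp$mode,
                             seed = recipe$seed)
      map <- fitRestitution(tab$di, tab$apd)
      onset <- findAlternansOnset(map, sp$tRange, dT = 2)
      list(table = tab, map = map, onset = onset)
    },
    fig9 = {
      tab <- s1s2Strip(params, nx = sp$nx, ny = sp$ny,
                       stimCols = sp$stimCols, s1 = sp$s1,
                       mode = sp$mode, seed = recipe$seed)
      blk <- blockThreshold(params, nx = sp$nx, ny = sp$ny,
                            stimCols = sp$stimCols, s1 = sp$s1,
                            mode = sp$mode, seed = recipe$seed)
      map <- fitRestitution(tab$di, tab$apd, diBlock = sp$diBlock)
      pd <- phaseDiagram(map, sp$tGrid,
                         seq(ceiling(map$domain[1]), floor(map$domain[2]),
                             by = 10),
                         nIter = sp$nIter)
      list(table = tab, block = blk, map = map, phase = pd)
    })
  writeManifest(recipe, params, outDir)
  saveTables(res, outDir)
  invisible(res)
}

writeManifest <- function(recipe, params, outDir) {
  man <- list(
    experiment = recipe$name,
    scale = recipe$scale,
    seed = recipe$seed,
    package = as.character(utils::packageVersion("eadsim")),
    preset = attr(params, "preset"),
    protocol = recipe$spec,
    parameters = as.list(setNames(as.numeric(params), names(params))),
    provenance = as.list(attr(params, "provenance")))
  yaml::write_yaml(man, file.path(outDir, "manifest.yml"))
}

saveTables <- function(res, outDir, prefix = "") {
  for (nm in names(res)) {
    x <- res[[nm]]
    if (is.data.frame(x))
      write.table(x, file.path(outDir, paste0(prefix, nm, ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    else if (is.list(x) && !is.function(x) && !inherits(x, "restitutionMap"))
      saveTables(Filter(is.data.frame, x), outDir,
                 prefix = paste0(prefix, nm, "-"))
  }
  invisible(NULL)
}
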