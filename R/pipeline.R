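# End-to-end pipeline: phantom -> segmentation -> geometry -> hemodynamics.

#' Default pipeline configuration
#'
#' A fully serializable nested list of every stage's settings. The single
#' `seed` drives all randomness (phantom noise, contour jitter, synthetic
#' Doppler noise). Any element can be overridden via `...` using the same
#' nesting, e.g. `pipelineConfig(segmentation = list(mode = "global"))`
#' merges into the defaults.
#'
#' @param ... named stage lists (`phantom`, `cast`, `segmentation`,
#'   `geometry`, `hemodynamics`) or `seed`, merged over the defaults.
#' @return A named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    phantom = list(gridShape = c(160L, 160L, 300L), voxelSize = 40,
                   lumenHuNoncast = 339, lumenHuCast = 257,
                   backgroundHu = 53, castHu = -97, noiseSd = 30,
                   fluctuationAmplitude = 0.1, fluctuationPeriod = 1.5,
                   supersample = 3L, wallThicknessInCast = 13.5,
                   vesselRadiusNoncast = 250, transitionLength = 0.3,
                   curvatureAmplitude = 200, curvaturePeriod = 8),
    cast = list(proximalDiameter = 400, distalDiameter = 200,
                castLength = 1.5, outerDiameter = 1000, castStart = 6),
    segmentation = list(mode = "local", shrink = 0.8, expand = c(1.2, 1.4),
                        passes = 4L, K = 72L, spacing = 10, harmonics = 8L,
                        rMax = 600, sliceSpacing = 0.04, margin = 0.3,
                        seedPointSpacing = 0.5, radiusEstimate = 250,
                        jitter = 0, jitterSeed = NULL),
    geometry = list(smoothingPasses = 20L, lambda = 0.5, mu = -0.53,
                    extensionFactor = 5),
    hemodynamics = list(nCycles = 5L, harmonics = 8L, phasePoints = 100L,
                        profile = "parabolic", viscosity = 3.5e-3,
                        density = 1060, waveformCsv = NULL))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

.stageLog <- function(logPath, fmt, ...) {
  line <- sprintf(fmt, ...)
  message(line)
  cat(line, "\n", file = logPath, append = TRUE)
}

#' Run the reconstruction pipeline
#'
#' Executes the requested stages in order on a synthetic phantom: volume
#' generation, local/global midway-threshold segmentation, geometry
#' profiling and surface building, and quasi-1D hemodynamics. All outputs
#' (NIfTI volume, ground truth, stats/contour/profile CSVs, STL surface, WSS
#' summaries) are written under `outDir` together with the resolved
#' configuration and a JSON manifest of files, MD5 digests, seed and package
#' version. Identical config and seed reproduce identical CSV outputs.
#'
#' @param config a [pipelineConfig()] list.
#' @param outDir output directory (created if needed).
#' @param stages subset of `c("phantom", "segment", "geometry", "hemo")`,
#'   in order.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir,
                        stages = c("phantom", "segment", "geometry",
                                   "hemo")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  cat("", file = logPath)
  jsonlite::write_json(config, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- c("config.json")
  ranStages <- character()
  state <- new.env(parent = emptyenv())

  runStage <- function(name, fun) {
    t0 <- Sys.time()
    fun()
    .stageLog(logPath, "stage %s finished in %.1f s", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
    ranStages <<- c(ranStages, name)
  }

  if ("phantom" %in% stages) runStage("phantom", function() {
    pc <- do.call(phantomConfig, c(config$phantom, list(seed = config$seed)))
    cast <- do.call(castSpec, config$cast)
    ph <- generatePhantom(pc, cast)
    state$volume <- ph$volume
    state$truth <- ph$truth
    state$cast <- cast
    writeImageVolume(ph$volume, file.path(outDir, "volume.nii.gz"))
    writeGroundTruth(ph$truth, file.path(outDir, "truth.json"),
                     file.path(outDir, "truth.csv"))
    files <<- c(files, "volume.nii.gz", "truth.json", "truth.csv")
  })

  if ("segment" %in% stages) runStage("segment", function() {
    if (is.null(state$volume)) stop("segment stage requires the phantom stage")
    sg <- config$segmentation
    seedIdx <- unique(c(seq(1, nrow(state$truth@centerline),
                            by = max(1L, round(sg$seedPointSpacing /
                                               diff(state$truth@arcLength[1:2])))),
                        nrow(state$truth@centerline)))
    cl <- fitCenterline(state$truth@centerline[seedIdx, ],
                        sampleSpacing = sg$sliceSpacing)
    sMax <- max(arcLength(cl))
    sPos <- seq(sg$margin, sMax - sg$margin, by = sg$sliceSpacing)
    init <- initialContours(state$volume, cl, sPos,
                            radiusEstimate = sg$radiusEstimate, K = sg$K,
                            spacing = sg$spacing, rMax = sg$rMax,
                            harmonics = sg$harmonics)
    if (sg$jitter > 0)
      init <- jitterContours(init, sg$jitter,
                             if (is.null(sg$jitterSeed)) config$seed + 1L
                             else sg$jitterSeed)
    seg <- segmentVessel(state$volume, cl, init, mode = sg$mode,
                         shrink = sg$shrink, expand = sg$expand,
                         passes = sg$passes, spacing = sg$spacing,
                         harmonics = sg$harmonics, rMax = sg$rMax)
    state$centerline <- cl
    state$stack <- seg
    writeContours(seg, file.path(outDir, "contours.csv"))
    writeRegionStats(seg@metadata$stats, seg@metadata$thresholds,
                     file.path(outDir, "stats.csv"))
    files <<- c(files, "contours.csv", "stats.csv", "stats.csv.global.json")
    if (length(seg@metadata$dropped))
      .stageLog(logPath, "WARN dropped %d slices at the volume boundary",
                length(seg@metadata$dropped))
  })

  if ("geometry" %in% stages) runStage("geometry", function() {
    if (is.null(state$stack)) stop("geometry stage requires the segment stage")
    gm <- config$geometry
    dp <- diameterProfile(state$stack)
    cast <- state$cast
    wt <- wallThickness(dp, cast)
    if (any(wt$overshoot))
      .stageLog(logPath, "WARN negative wall thickness on %d slices",
                sum(wt$overshoot))
    castD <- rep(NA_real_, length(dp@s))
    inC <- dp@s >= cast@castStart & dp@s <= cast@castStart + cast@castLength
    castD[inC] <- castInnerDiameter(cast, dp@s[inC])
    prof <- data.frame(s_mm = dp@s, D_um = dp@diameter, A_um2 = dp@area,
                       cast_D_um = castD,
                       w_um = ifelse(inC, (castD - dp@diameter) / 2, NA))
    utils::write.csv(prof, file.path(outDir, "profiles.csv"),
                     row.names = FALSE)
    cmp <- compareToCast(dp, cast)
    .stageLog(logPath, "cast-region diameter undershoot %.1f +/- %.1f %%",
              cmp$meanPct, cmp$sdPct)
    ext <- addFlowExtensions(state$stack, state$centerline,
                             factor = gm$extensionFactor)
    surf <- loftSurface(ext$stack, ext$centerline)
    surf <- smoothSurface(surf, passes = gm$smoothingPasses,
                          lambda = gm$lambda, mu = gm$mu)
    state$profile <- dp
    state$surface <- surf
    writeSurfaceSTL(surf, file.path(outDir, "surface.stl"))
    files <<- c(files, "profiles.csv", "surface.stl")
  })

  if ("hemo" %in% stages) runStage("hemo", function() {
    if (is.null(state$profile)) stop("hemo stage requires the geometry stage")
    hm <- config$hemodynamics
    trace <- if (!is.null(hm$waveformCsv)) {
      df <- utils::read.csv(hm$waveformCsv)
      names(df)[1:2] <- c("time", "velocity")
      df
    } else syntheticDopplerTrace(nCycles = hm$nCycles + 1L,
                                 seed = config$seed)
    wf <- averageCycles(trace$time, trace$velocity, nCycles = hm$nCycles,
                        phasePoints = hm$phasePoints)
    wf <- lowpassFilter(wf, hm$harmonics)
    blood <- bloodModel(hm$viscosity, hm$density)
    dp <- state$profile
    inletR <- dp@diameter[1] / 2
    q <- flowRate(wf, inletR, profile = hm$profile)
    field <- poiseuilleWSS(q, data.frame(s = dp@s, r = dp@diameter / 2),
                           blood)
    writeWSSField(field, file.path(outDir, "wss_field.csv"),
                  file.path(outDir, "wss_summary.csv"))
    qMean <- mean(q@value[-length(q@value)])
    re <- reynoldsNumber(qMean, dp@diameter[1], blood)
    utils::write.csv(data.frame(mean_flow_mm3_s = qMean,
                                inlet_tawss_pa = tawss(field)[1],
                                reynolds = re),
                     file.path(outDir, "hemo_summary.csv"),
                     row.names = FALSE)
    files <<- c(files, "wss_field.csv", "wss_summary.csv",
                "hemo_summary.csv")
  })

  paths <- file.path(outDir, files)
  manifest <- list(package = "castseg",
                   version = as.character(utils::packageVersion("castseg")),
                   seed = config$seed, stages = ranStages,
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(paths)), files)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Compare local- and global-threshold segmentations of the same volume
#'
#' Generates (or reuses) the phantom, segments it once per mode from the
#' same initial contours, and reports per-slice diameter differences, the
#' cast-region percent underestimation of each mode, both wall-thickness
#' profiles and a two-sample t test on them.
#'
#' @param config a [pipelineConfig()] list.
#' @param phantom optional precomputed result of [generatePhantom()]
#'   matching `config` (to avoid regenerating the volume).
#' @return A list with `perSlice` (s, D_local, D_global, relDiffPct),
#'   `castPct` (per-mode mean/sd percent underestimation), `wall` (both
#'   wall-thickness profiles) and `tTest` (the [stats::t.test()] result on
#'   cast-region wall thickness).
#' @export
compareModes <- function(config = pipelineConfig(), phantom = NULL) {
  pc <- do.call(phantomConfig, c(config$phantom, list(seed = config$seed)))
  cast <- do.call(castSpec, config$cast)
  if (is.null(phantom)) phantom <- generatePhantom(pc, cast)
  sg <- config$segmentation
  ds0 <- diff(phantom$truth@arcLength[1:2])
  seedIdx <- unique(c(seq(1, nrow(phantom$truth@centerline),
                          by = max(1L, round(sg$seedPointSpacing / ds0))),
                      nrow(phantom$truth@centerline)))
  cl <- fitCenterline(phantom$truth@centerline[seedIdx, ],
                      sampleSpacing = sg$sliceSpacing)
  sPos <- seq(sg$margin, max(arcLength(cl)) - sg$margin,
              by = sg$sliceSpacing)
  init <- initialContours(phantom$volume, cl, sPos,
                          radiusEstimate = sg$radiusEstimate, K = sg$K,
                          spacing = sg$spacing, rMax = sg$rMax,
                          harmonics = sg$harmonics)
  run <- function(mode)
    segmentVessel(phantom$volume, cl, init, mode = mode,
                  shrink = sg$shrink, expand = sg$expand,
                  passes = sg$passes, spacing = sg$spacing,
                  harmonics = sg$harmonics, rMax = sg$rMax)
  segL <- run("local")
  segG <- run("global")
  sCommon <- intersect(segL@s, segG@s)
  dL <- diameterProfile(segL)
  dG <- diameterProfile(segG)
  iL <- match(sCommon, dL@s)
  iG <- match(sCommon, dG@s)
  perSlice <- data.frame(
    s = sCommon, D_local = dL@diameter[iL], D_global = dG@diameter[iG],
    relDiffPct = 100 * abs(dL@diameter[iL] - dG@diameter[iG]) /
      ((dL@diameter[iL] + dG@diameter[iG]) / 2))
  cmpL <- compareToCast(dL, cast)
  cmpG <- compareToCast(dG, cast)
  wL <- wallThickness(dL, cast)
  wG <- wallThickness(dG, cast)
  list(perSlice = perSlice,
       castPct = data.frame(row.names = c("local", "global"),
                            meanPct = c(cmpL$meanPct, cmpG$meanPct),
                            sdPct = c(cmpL$sdPct, cmpG$sdPct)),
       wall = list(local = wL, global = wG),
       tTest = stats::t.test(wL$thickness, wG$thickness))
}
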