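# File I/O: NIfTI volumes, CSV tables, STL/PLY surfaces.

#' Write / read an image volume as NIfTI
#'
#' Volumes are stored with their isotropic voxel spacing in the NIfTI
#' `pixdim`; the world origin is taken as voxel (0,0,0) on read.
#'
#' @param volume an [ImageVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `writeImageVolume` returns `path` invisibly; `readImageVolume`
#'   returns an [ImageVolume-class].
#' @export
writeImageVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@hu)
  RNifti::pixdim(img) <- rep(volume@voxelSize, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeImageVolume
#' @export
readImageVolume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  new("ImageVolume", hu = arr, voxelSize = RNifti::pixdim(img)[1],
      origin = c(0, 0, 0))
}

#' Read ordered centerline seed points from CSV
#'
#' Expects columns `x`, `y`, `z` in mm, one row per point, ordered proximal
#' to distal.
#'
#' @param path CSV path.
#' @return An n x 3 matrix, mm.
#' @export
readCenterlinePoints <- function(path) {
  df <- utils::read.csv(path)
  as.matrix(df[, c("x", "y", "z")])
}

#' Write / read a contour stack as CSV
#'
#' Long format with columns `s` (mm), `theta` (radians) and `r` (um).
#'
#' @param stack a [ContourStack-class].
#' @param path CSV path.
#' @return `writeContours` returns `path` invisibly; `readContours` a
#'   [ContourStack-class].
#' @export
writeContours <- function(stack, path) {
  rows <- do.call(rbind, lapply(stack@contours, function(ct)
    data.frame(s = ct@s, theta = ct@theta, r = ct@radius)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeContours
#' @export
readContours <- function(path) {
  df <- utils::read.csv(path)
  sv <- sort(unique(df$s))
  cts <- lapply(sv, function(si) {
    d <- df[df$s == si, ]
    d <- d[order(d$theta), ]
    new("Contour", theta = d$theta, radius = d$r, s = si)
  })
  new("ContourStack", contours = cts, s = sv, metadata = list())
}

#' Write per-slice region statistics and thresholds
#'
#' CSV columns: `s_mm`, `L_hu`, `L_sd`, `B_hu`, `B_sd`, `C_hu`,
#' `T_local_hu`, `n_lumen`, `n_bg`. The global threshold goes to a JSON
#' sidecar `<path>.global.json`.
#'
#' @param stats a [RegionStats-class].
#' @param thresholds a [ThresholdProfile-class].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeRegionStats <- function(stats, thresholds, path) {
  df <- data.frame(s_mm = stats@s, L_hu = stats@lumenMean,
                   L_sd = stats@lumenSD, B_hu = stats@bgMean,
                   B_sd = stats@bgSD, C_hu = stats@contrast,
                   T_local_hu = thresholds@local, n_lumen = stats@nLumen,
                   n_bg = stats@nBg)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(T_global_hu = thresholds@global),
                       paste0(path, ".global.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a Doppler / flow waveform trace from CSV
#'
#' Expects columns `t_s` and `value` (or the first two columns).
#'
#' @param path CSV path.
#' @param kind `"velocity"` (m/s) or `"flow"` (mm^3/s).
#' @return A [FlowWaveform-class] (if the trace covers one period) -- the
#'   raw samples are returned as-is; use [averageCycles()] for multi-cycle
#'   traces.
#' @export
readWaveform <- function(path, kind = c("velocity", "flow")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path)
  if (!all(c("t_s", "value") %in% names(df))) names(df)[1:2] <- c("t_s", "value")
  new("FlowWaveform", time = df$t_s, value = df$value, kind = kind)
}

#' Write a vessel surface as ASCII STL or PLY
#'
#' @param surface a [VesselSurface-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSurfaceSTL <- function(surface, path) {
  v <- surface@vertices
  f <- surface@faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nn <- sqrt(rowSums(nrm^2))
  nn[nn == 0] <- 1
  nrm <- nrm / nn
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid vessel", con)
  chunk <- sprintf(
    "facet normal %g %g %g\nouter loop\nvertex %g %g %g\nvertex %g %g %g\nvertex %g %g %g\nendloop\nendfacet",
    nrm[, 1], nrm[, 2], nrm[, 3], p1[, 1], p1[, 2], p1[, 3],
    p2[, 1], p2[, 2], p2[, 3], p3[, 1], p3[, 2], p3[, 3])
  writeLines(chunk, con)
  writeLines("endsolid vessel", con)
  invisible(path)
}

#' @rdname writeSurfaceSTL
#' @export
writeSurfacePLY <- function(surface, path) {
  v <- surface@vertices
  f <- surface@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%g %g %g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
  invisible(path)
}

#' Read an externally computed wall shear stress field
#'
#' Long-format CSV with columns `s_mm`, `t_s`, `tau_pa`, so that TAWSS/OSI
#' post-processing stays solver-agnostic.
#'
#' @param path CSV path.
#' @return A [WSSField-class].
#' @export
readWSSField <- function(path) {
  df <- utils::read.csv(path)
  sv <- sort(unique(df$s_mm))
  tv <- sort(unique(df$t_s))
  tau <- matrix(NA_real_, length(sv), length(tv))
  tau[cbind(match(df$s_mm, sv), match(df$t_s, tv))] <- df$tau_pa
  if (any(is.na(tau))) stop("incomplete (s, t) grid in WSS table")
  new("WSSField", s = sv, time = tv, tau = tau)
}

#' Write WSS field and summaries as CSV
#'
#' The field goes to `<path>` in long format (`s_mm`, `t_s`, `tau_pa`); the
#' per-position TAWSS/OSI summary to `<summaryPath>` (`s_mm`, `tawss_pa`,
#' `osi`).
#'
#' @param field a [WSSField-class].
#' @param path field CSV path.
#' @param summaryPath summary CSV path.
#' @return `path`, invisibly.
#' @export
writeWSSField <- function(field, path, summaryPath = NULL) {
  df <- data.frame(s_mm = rep(field@s, times = length(field@time)),
                   t_s = rep(field@time, each = length(field@s)),
                   tau_pa = as.vector(field@tau))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(summaryPath))
    utils::write.csv(data.frame(s_mm = field@s, tawss_pa = tawss(field),
                                osi = osi(field)),
                     summaryPath, row.names = FALSE)
  invisible(path)
}

#' Write phantom ground truth
#'
#' Cast geometry and HU parameters as JSON; the centerline and true radius
#' profile as CSV (`s_mm`, `r_um`, `x_mm`, `y_mm`, `z_mm`).
#'
#' @param truth a [GroundTruth-class].
#' @param jsonPath,csvPath output paths.
#' @return `csvPath`, invisibly.
#' @export
writeGroundTruth <- function(truth, jsonPath, csvPath) {
  cast <- truth@cast
  jsonlite::write_json(list(
    cast = list(proximalDiameter = cast@proximalDiameter,
                distalDiameter = cast@distalDiameter,
                castLength = cast@castLength,
                outerDiameter = cast@outerDiameter,
                castStart = cast@castStart),
    huParams = truth@huParams), jsonPath, auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(s_mm = truth@arcLength,
                              r_um = truth@trueRadius,
                              x_mm = truth@centerline[, 1],
                              y_mm = truth@centerline[, 2],
                              z_mm = truth@centerline[, 3]),
                   csvPath, row.names = FALSE)
  invisible(csvPath)
}
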