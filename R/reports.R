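# Contrast-parameter summaries in the published table layout.

#' Per-region contrast summary of one vessel
#'
#' Summarises the per-slice lumen mean, background mean and contrast
#' difference separately over the non-cast and cast portions of the vessel,
#' as mean +/- SD across slices (the per-animal row of the published
#' contrast table).
#'
#' @param stats a [RegionStats-class].
#' @param cast a [CastSpec-class], or a numeric `c(start, end)` arc-length
#'   extent in mm; must lie within the profiled range.
#' @return A data frame with rows `noncast` and `cast` and columns
#'   `lumenMean`, `lumenSD`, `bgMean`, `bgSD`, `contrastMean`, `contrastSD`,
#'   `nSlices`.
#' @export
table1Report <- function(stats, cast) {
  ext <- if (is(cast, "CastSpec"))
    c(cast@castStart, cast@castStart + cast@castLength) else cast[1:2]
  if (ext[1] < min(stats@s) - 1e-9 || ext[2] > max(stats@s) + 1e-9)
    stop("cast extent outside the profiled arc-length range")
  inC <- stats@s >= ext[1] & stats@s <= ext[2]
  mk <- function(sel) {
    if (!any(sel)) stop("empty region: no slices fall in it")
    sd0 <- function(x) if (sum(sel) > 1) stats::sd(x[sel]) else 0
    data.frame(lumenMean = mean(stats@lumenMean[sel]), lumenSD = sd0(stats@lumenMean),
               bgMean = mean(stats@bgMean[sel]), bgSD = sd0(stats@bgMean),
               contrastMean = mean(stats@contrast[sel]),
               contrastSD = sd0(stats@contrast), nSlices = sum(sel))
  }
  out <- rbind(mk(!inC), mk(inC))
  rownames(out) <- c("noncast", "cast")
  out
}

#' Cross-animal average of per-animal contrast parameters
#'
#' Given per-animal region means (one row per animal), returns the Average
#' row: the mean and SD across animals of each column.
#'
#' @param perAnimal data frame or matrix, one row per animal, columns being
#'   per-animal region means (e.g. non-cast lumen, background, contrast
#'   difference, and the cast-region equivalents), HU.
#' @return A data frame with rows `mean` and `sd`.
#' @examples
#' table1Average(data.frame(lumenNoncast = c(428, 372, 286, 328,
#'                                           330, 281, 306, 383)))
#' @export
table1Average <- function(perAnimal) {
  m <- as.matrix(perAnimal)
  out <- rbind(mean = colMeans(m),
               sd = apply(m, 2, function(x) if (length(x) > 1) stats::sd(x) else 0))
  as.data.frame(out)
}
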