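#' Construct a per-batch peak table
#'
#' A peak table is the pipeline's atomic input: the integrated peaks detected
#' in one batch's chromatogram, with retention times in minutes and areas in
#' arbitrary detector units.
#'
#' @param batch_id Single character string identifying the batch (e.g. "S1").
#' @param rt_min Numeric vector of retention times in minutes, strictly
#'   positive.
#' @param area Numeric vector of non-negative peak areas, same length as
#'   `rt_min`.
#' @param peak_id Optional character vector of within-batch peak labels;
#'   defaults to `"p1", "p2", ...` in input order. Must be unique.
#' @return A `data.frame` of class `peak_table` with columns `batch_id`,
#'   `peak_id`, `rt_min`, `area`.
#' @examples
#' peak_table("S1", rt_min = c(5, 10), area = c(120, 80))
#' @export
peak_table <- function(batch_id, rt_min, area, peak_id = NULL) {
  stopifnot(is.character(batch_id), length(batch_id) == 1L, nzchar(batch_id))
  rt_min <- as.numeric(rt_min)
  area <- as.numeric(area)
  if (length(rt_min) < 1L)
    stop("a peak table needs at least one peak", call. = FALSE)
  if (length(area) != length(rt_min))
    stop("`rt_min` and `area` must have the same length", call. = FALSE)
  if (any(!is.finite(rt_min)) || any(rt_min <= 0))
    stop("retention times must be finite and strictly positive", call. = FALSE)
  if (any(!is.finite(area)) || any(area < 0))
    stop("areas must be finite and non-negative", call. = FALSE)
  if (is.null(peak_id)) peak_id <- paste0("p", seq_along(rt_min))
  peak_id <- as.character(peak_id)
  if (anyDuplicated(peak_id))
    stop("`peak_id` must be unique within a batch", call. = FALSE)
  out <- data.frame(batch_id = batch_id, peak_id = peak_id,
                    rt_min = rt_min, area = area,
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Construct a chromatogram
#'
#' Holds one batch's raw detector trace. Only resampling and similarity
#' scoring operate on chromatograms; peak detection is out of scope and peak
#' tables are the primary input.
#'
#' @param batch_id Single character string.
#' @param times Strictly increasing numeric vector of times in minutes.
#' @param intensities Finite numeric vector, same length as `times`
#'   (length >= 2).
#' @param wavelength_nm Detection wavelength metadata; default 330.
#' @return An object of class `chromatogram`.
#' @export
chromatogram <- function(batch_id, times, intensities, wavelength_nm = 330) {
  stopifnot(is.character(batch_id), length(batch_id) == 1L)
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) < 2L || length(times) != length(intensities))
    stop("`times` and `intensities` must have equal length >= 2", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("intensities must be finite", call. = FALSE)
  structure(list(batch_id = batch_id, times = times,
                 intensities = intensities, wavelength_nm = wavelength_nm),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram %s: %d points, %.2f-%.2f min, %g nm>\n",
              x$batch_id, length(x$times), min(x$times), max(x$times),
              x$wavelength_nm))
  invisible(x)
}

# piecewise-linear map through (xs, ys), linearly extrapolated at both ends
piecewise_linear <- function(x, xs, ys) {
  y <- stats::approx(xs, ys, xout = x, rule = 2)$y
  n <- length(xs)
  lo <- x < xs[1L]
  hi <- x > xs[n]
  if (any(lo)) {
    s <- (ys[2L] - ys[1L]) / (xs[2L] - xs[1L])
    y[lo] <- ys[1L] + s * (x[lo] - xs[1L])
  }
  if (any(hi)) {
    s <- (ys[n] - ys[n - 1L]) / (xs[n] - xs[n - 1L])
    y[hi] <- ys[n] + s * (x[hi] - xs[n])
  }
  y
}

#' Multipoint retention-time correction
#'
#' Remaps a batch's retention times through the piecewise-linear function
#' defined by anchor pairs (observed, reference), with linear extrapolation
#' beyond the outermost anchors. Used to align batches to a reference
#' fingerprint before common-peak matching; peak areas are unchanged.
#'
#' @param table A [peak_table()].
#' @param anchors A two-column matrix or data frame of anchor points,
#'   `(observed_rt, reference_rt)`, at least two rows, strictly increasing in
#'   both columns.
#' @return A `peak_table` with corrected `rt_min`.
#' @examples
#' tab <- peak_table("S1", rt_min = 1.5, area = 10)
#' multipoint_rt_correction(tab, anchors = cbind(c(1, 2), c(2, 4)))$rt_min # 3
#' @export
multipoint_rt_correction <- function(table, anchors) {
  anchors <- as.matrix(anchors)
  if (nrow(anchors) < 2L || ncol(anchors) != 2L)
    stop("need at least two (observed, reference) anchor pairs", call. = FALSE)
  if (any(diff(anchors[, 1L]) <= 0) || any(diff(anchors[, 2L]) <= 0))
    stop("anchors must be strictly increasing in both coordinates",
         call. = FALSE)
  out <- table
  out$rt_min <- piecewise_linear(table$rt_min, anchors[, 1L], anchors[, 2L])
  out
}

#' Resample chromatograms onto a shared time grid
#'
#' Linear interpolation onto the union time range sampled at the finest step
#' present in any input; points outside a chromatogram's own range are held at
#' its boundary values.
#'
#' @param chroms List of [chromatogram()] objects.
#' @return A matrix (batches x grid points) with batch ids as row names and
#'   the grid as `attr(, "times")`.
#' @export
resample_chromatograms <- function(chroms) {
  stopifnot(length(chroms) >= 1L)
  step <- min(vapply(chroms, function(ch) min(diff(ch$times)), numeric(1)))
  lo <- min(vapply(chroms, function(ch) min(ch$times), numeric(1)))
  hi <- max(vapply(chroms, function(ch) max(ch$times), numeric(1)))
  grid <- seq(lo, hi, by = step)
  out <- t(vapply(chroms, function(ch)
    stats::approx(ch$times, ch$intensities, xout = grid, rule = 2)$y,
    numeric(length(grid))))
  rownames(out) <- vapply(chroms, `[[`, character(1), "batch_id")
  attr(out, "times") <- grid
  out
}
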