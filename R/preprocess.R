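## Preprocessing: NDVI arithmetic, the regular 16-day grid, gap infilling,
## LOESS-based seasonal-trend decomposition and remainder filtering.

#' Compute NDVI from red and near-infrared reflectance
#'
#' `(nir - red) / (nir + red)` elementwise. Entries where the denominator is
#' zero (both bands zero) are undefined and returned as `NA`.
#'
#' @param red,nir numeric vectors/matrices of surface reflectance, same shape.
#' @return numeric object of the same shape with NDVI in `[-1, 1]` (or `NA`).
#' @examples
#' computeNDVI(0.05, 0.30)  # 0.714286
#' @export
computeNDVI <- function(red, nir) {
    if (!identical(dim(red), dim(nir)) || length(red) != length(nir))
        stop("red and NIR bands must have identical shape")
    den <- nir + red
    out <- (nir - red) / den
    out[!is.na(den) & den == 0] <- NA_real_
    out
}

#' Build a regular acquisition date grid
#'
#' Inclusive arithmetic sequence of dates from `start_date` stepping by
#' `step_days`; the last element never exceeds `end_date` and equals it when
#' the span is divisible by the step. The 16-day Landsat TM grid from
#' 1984-05-21 to 2011-11-08 has exactly 628 steps.
#'
#' @param start_date,end_date coercible to `Date`.
#' @param step_days integer step, >= 1.
#' @return `Date` vector.
#' @examples
#' length(buildTimeGrid("1984-05-21", "2011-11-08", 16))  # 628
#' @export
buildTimeGrid <- function(start_date, end_date, step_days = 16) {
    start_date <- as.Date(start_date); end_date <- as.Date(end_date)
    if (end_date < start_date) stop("end_date must be >= start_date")
    if (step_days < 1) stop("step_days must be >= 1")
    seq(start_date, end_date, by = as.integer(step_days))
}

#' Infill missing observations by linear interpolation in time
#'
#' Observed values are never altered; interior gaps are linear in time between
#' the flanking observations; leading/trailing gaps are constant-extended from
#' the nearest observation (linear extrapolation could exit the physical
#' NDVI range). The result is clamped to `[-1, 1]`.
#'
#' @param values numeric series with `NA` at missing steps.
#' @param dates time coordinates (Date or numeric), same length; defaults to
#'   the step index.
#' @return complete numeric series.
#' @export
infillSeries <- function(values, dates = seq_along(values)) {
    obs <- !is.na(values)
    if (!any(obs)) stop("series is entirely missing")
    if (all(obs)) return(values)
    t <- as.numeric(dates)
    out <- approx(t[obs], values[obs], xout = t, method = "linear",
                  rule = 2)$y
    out[obs] <- values[obs]
    pmin(1, pmax(-1, out))
}

#' Seasonal-trend decomposition of a complete series
#'
#' LOESS-based additive decomposition (`stl`) into trend, seasonal and
#' remainder. The seasonal extraction is periodic (seasonal sub-series
#' smoothed across years) and the trend window spans about 1.5 cycles. The
#' seasonal component is centred so its mean over each full cycle is zero
#' (the cycle mean is moved into the trend), and the remainder is recomputed
#' as `input - trend - seasonal` so additivity is exact to machine precision.
#'
#' @param series complete numeric series (no `NA`), length >= 2 periods.
#' @param period integer steps per seasonal cycle (23 for a 16-day grid).
#' @return a [SeasonalDecomposition-class].
#' @export
decomposeSeries <- function(series, period = 23L) {
    period <- as.integer(period)
    if (anyNA(series)) stop("series must be complete; infill first")
    if (length(series) < 2L * period)
        stop("series must span at least two full periods")
    tw <- as.integer(ceiling(1.5 * period))
    if (tw %% 2L == 0L) tw <- tw + 1L
    fit <- stl(ts(series, frequency = period), s.window = "periodic",
               t.window = tw)
    seas <- as.numeric(fit$time.series[, "seasonal"])
    trend <- as.numeric(fit$time.series[, "trend"])
    ctr <- mean(seas[seq_len(period)])  # periodic, so one cycle suffices
    seas <- seas - ctr
    trend <- trend + ctr
    new("SeasonalDecomposition", trend = trend, seasonal = seas,
        remainder = series - trend - seas, period = period)
}

#' Recombine trend and seasonal components, discarding the remainder
#'
#' The filtered series keeps the low-frequency and periodic structure of the
#' input and drops the residual, raising the signal-to-noise ratio for
#' classification.
#'
#' @param decomp a [SeasonalDecomposition-class].
#' @return numeric filtered series (`trend + seasonal`).
#' @export
filterSeries <- function(decomp) {
    stopifnot(is(decomp, "SeasonalDecomposition"))
    decomp@trend + decomp@seasonal
}

#' Infill, decompose and filter every pixel of a stack
#'
#' Runs [infillSeries()], [decomposeSeries()] and [filterSeries()] on each
#' pixel time series. Pixel order, dates and geo-metadata are preserved; the
#' output mask is all-`FALSE`. An entirely missing pixel aborts with its
#' 0-based raster coordinates.
#'
#' @param stack an [NDVIStack-class] on a regular date grid.
#' @param period integer seasonal period in steps (default 23, i.e. one year
#'   of 16-day steps).
#' @return a filtered [NDVIStack-class].
#' @export
preprocessStack <- function(stack, period = 23L) {
    v <- ndviValues(stack)
    m <- missingMask(stack)
    d <- sceneDates(stack)
    if (length(d) > 2 && length(unique(diff(as.numeric(d)))) != 1L)
        stop("stack dates must form a regular grid")
    gd <- gridDims(stack)
    t_num <- as.numeric(d)
    out <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
    for (i in seq_len(nrow(v))) {
        x <- v[i, ]
        x[m[i, ]] <- NA_real_
        if (all(is.na(x))) {
            r0 <- (i - 1L) %/% gd[2]; c0 <- (i - 1L) %% gd[2]
            stop(sprintf("pixel (row %d, col %d) has no valid observations",
                         r0, c0))
        }
        x <- infillSeries(x, t_num)
        f <- filterSeries(decomposeSeries(x, period))
        out[i, ] <- pmin(1, pmax(-1, f))
    }
    NDVIStack(out, dates = d, mask = matrix(FALSE, nrow(v), ncol(v)),
              gridDims = gd, geo = geoInfo(stack))
}
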