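## Synthetic-scene generator: precipitation records and NDVI raster time
## series whose seasonal amplitude is modulated jointly by site class (soil),
## ecological-state code (degradation) and antecedent precipitation.

.validateClimate <- function(climate) {
    stopifnot(is.data.frame(climate),
              all(c("date", "precip_mm") %in% names(climate)))
    d <- as.Date(climate$date)
    if (anyDuplicated(d) || any(diff(as.numeric(d)) <= 0))
        stop("climate record must have strictly increasing, unique dates")
    if (any(climate$precip_mm < 0)) stop("precipitation must be non-negative")
    invisible(climate)
}

#' Simulate a daily precipitation record
#'
#' Semi-arid monsoonal rainfall: per-day occurrence is Bernoulli with a higher
#' probability inside the summer monsoon window (1 July - 1 October), and wet
#' day amounts are gamma distributed, giving the zero-inflated, right-skewed
#' daily record that SPI estimation must handle. Multi-year wet/dry/normal
#' regimes are imposed through a schedule of multipliers applied to the
#' amounts, so expected monthly totals scale with the multiplier. Defaults
#' give roughly 250 mm/yr with ~80% of it in the monsoon window.
#'
#' @param start_date,end_date span of the record (coercible to `Date`).
#' @param regime_schedule `NULL` (multiplier 1 throughout) or a data.frame
#'   with columns `start`, `end`, `multiplier`; intervals must tile the span
#'   with no gaps or overlaps.
#' @param seed integer RNG seed.
#' @param monsoon_doy day-of-year window `c(first, last)` of concentrated
#'   rainfall.
#' @param p_wet occurrence probability `c(monsoon, off)` per day.
#' @param shape gamma shape of wet-day amounts.
#' @param mean_mm mean wet-day amount `c(monsoon, off)` in mm.
#' @return data.frame with columns `date`, `precip_mm`.
#' @export
simulatePrecipitation <- function(start_date, end_date,
                                  regime_schedule = NULL, seed = 1L,
                                  monsoon_doy = c(182L, 274L),
                                  p_wet = c(monsoon = 0.45, off = 0.08),
                                  shape = 0.7,
                                  mean_mm = c(monsoon = 4.8, off = 2.3)) {
    start_date <- as.Date(start_date); end_date <- as.Date(end_date)
    if (end_date <= start_date) stop("end_date must be after start_date")
    dates <- seq(start_date, end_date, by = 1L)

    mult <- rep(1, length(dates))
    if (!is.null(regime_schedule)) {
        rs <- as.data.frame(regime_schedule)
        if (nrow(rs) == 0L) stop("regime_schedule must not be empty")
        rs$start <- as.Date(rs$start); rs$end <- as.Date(rs$end)
        rs <- rs[order(rs$start), , drop = FALSE]
        if (rs$start[1] > start_date || rs$end[nrow(rs)] < end_date)
            stop("regime_schedule does not cover the full record span")
        if (nrow(rs) > 1 &&
            any(as.numeric(rs$start[-1] - rs$end[-nrow(rs)]) != 1))
            stop("regime intervals must tile the span (no gaps or overlaps)")
        idx <- findInterval(as.numeric(dates), as.numeric(rs$start))
        mult <- rs$multiplier[idx]
    }

    doy <- as.integer(format(dates, "%j"))
    in_mon <- doy >= monsoon_doy[1] & doy < monsoon_doy[2]
    p <- ifelse(in_mon, p_wet[[1]], p_wet[[2]])
    mu <- ifelse(in_mon, mean_mm[[1]], mean_mm[[2]])

    set.seed(as.integer(seed))
    wet <- rbinom(length(dates), 1L, p)
    amt <- rgamma(length(dates), shape = shape, scale = mu / shape)
    data.frame(date = dates, precip_mm = wet * amt * mult)
}

## Default per-class phenology parameters, qualitatively ordered like the
## field system: four grassland-reference classes whose seasonal amplitude
## shrinks with degradation, and one savanna-reference class (Deep sand)
## whose amplitude grows as woody plants take over. Values are chosen as a
## realistic semi-arid NDVI range (winter baseline ~0.13-0.17, peak-season
## amplitude up to ~0.38), not taken from any measured table.
.presetClassTable <- function() {
    data.frame(
        class = c("Clayey", "Loamy", "Sandy", "Shallow sandy", "Deep sand"),
        reference = c("grassland", "grassland", "grassland", "grassland",
                      "savanna"),
        base = c(0.14, 0.16, 0.15, 0.13, 0.17),
        amplitude = c(0.30, 0.38, 0.25, 0.18, 0.15),
        lag_days = c(15, 30, 45, 25, 60),
        half_sat = c(0.8, 1.0, 1.2, 1.0, 1.5),
        lambda = c(0.9, 0.8, 0.7, 0.6, 0.5),
        stringsAsFactors = FALSE)
}

.presetStateMultipliers <- function() {
    list(grassland = c(1.00, 0.92, 0.85, 0.70, 0.55, 0.40, 0.28),
         savanna   = c(0.60, 0.60, 0.55, 0.75, 0.95, 1.00, 1.00))
}

#' Scene generator configuration
#'
#' Bundles the pixel grid, per-class phenology parameters, per-state
#' amplitude multipliers, the class/state patch layout and the observation
#' model into a validated configuration list.
#'
#' Per class `c` and state `s`, pixel NDVI at time `t` is
#' \deqn{b_c + A_c m_{c,s} S(doy_t) [(1-\lambda_c) + \lambda_c g(\bar P_{\tau_c}(t))] + \epsilon}
#' where `S` is a truncated-cosine seasonal bump peaking on day-of-year 260
#' (mid/late September), `g(x) = x/(x+h_c)` is a saturating response to the
#' mean daily precipitation over the preceding `tau_c` days, `lambda_c` in
#' `[0,1]` is the moisture sensitivity (0 = climate-invariant phenology), and
#' `eps` is Gaussian observation noise clipped so NDVI stays in `[-1, 1]`.
#'
#' @param class_raster character matrix of class labels (one per pixel).
#' @param state_raster integer matrix of state codes 1-7, same shape.
#' @param classes data.frame with columns `class`, `reference`, `base`,
#'   `amplitude`, `lag_days`, `half_sat`, `lambda`.
#' @param state_mult named list of length-7 multiplier vectors per reference
#'   group (`grassland`, `savanna`).
#' @param noise_sd per-observation Gaussian noise SD.
#' @param missing_rate fraction of observations masked out, in `[0, 1)`.
#' @param seed integer seed for noise and masking.
#' @return a list of class `SceneConfig`.
#' @export
sceneConfig <- function(class_raster, state_raster,
                        classes = .presetClassTable(),
                        state_mult = .presetStateMultipliers(),
                        noise_sd = 0.02, missing_rate = 0, seed = 1L) {
    if (!identical(dim(class_raster), dim(state_raster)))
        stop("class and state rasters must have identical shape")
    if (missing_rate < 0 || missing_rate >= 1)
        stop("missing_rate must be in [0, 1)")
    bad <- setdiff(unique(as.vector(class_raster)), classes$class)
    if (length(bad))
        stop("unknown class label(s) in layout: ", paste(bad, collapse = ", "))
    if (!all(as.vector(state_raster) %in% 1:7))
        stop("state codes in layout must be integers in 1..7")
    if (!all(classes$reference %in% names(state_mult)))
        stop("state_mult must cover every reference group used by classes")
    structure(list(n_rows = nrow(class_raster), n_cols = ncol(class_raster),
                   classes = classes, state_mult = state_mult,
                   class_raster = class_raster, state_raster = state_raster,
                   noise_sd = noise_sd, missing_rate = missing_rate,
                   seed = as.integer(seed)),
              class = "SceneConfig")
}

#' A study-system-like scene preset
#'
#' Five-class scene (Clayey, Loamy, Sandy, Shallow sandy, Deep sand) laid out
#' in vertical class bands. With `states = "reference"` every grassland-class
#' pixel is in state 1 and Deep sand in state 3 (maximal between-class
#' separability); with `states = "mixed"` each class band is split into
#' horizontal state blocks over its plausible degradation sequence
#' (grassland: 1,2,4,6,7; savanna: 3,5,6), which makes degraded states of
#' different classes spectrally convergent.
#'
#' @param n_rows,n_cols pixel grid size.
#' @param states `"reference"` or `"mixed"`.
#' @param noise_sd,missing_rate,seed passed to [sceneConfig()]; the default
#'   noise SD of 0.05 is typical single-scene NDVI observation noise.
#' @return a `SceneConfig`.
#' @export
semiAridScenePreset <- function(n_rows = 64L, n_cols = 64L,
                                states = c("reference", "mixed"),
                                noise_sd = 0.05, missing_rate = 0,
                                seed = 1L) {
    states <- match.arg(states)
    cls <- .presetClassTable()
    band <- rep(seq_len(nrow(cls)), length.out = n_cols,
                each = ceiling(n_cols / nrow(cls)))[seq_len(n_cols)]
    class_raster <- matrix(cls$class[band], n_rows, n_cols, byrow = TRUE)
    state_raster <- matrix(1L, n_rows, n_cols)
    if (states == "reference") {
        state_raster[class_raster == "Deep sand"] <- 3L
    } else {
        seqs <- list(grassland = c(1L, 2L, 4L, 6L, 7L),
                     savanna = c(3L, 5L, 6L))
        for (j in seq_len(n_cols)) {
            ref <- cls$reference[match(class_raster[1, j], cls$class)]
            sq <- seqs[[ref]]
            blk <- rep(sq, length.out = n_rows,
                       each = ceiling(n_rows / length(sq)))[seq_len(n_rows)]
            state_raster[, j] <- blk
        }
    }
    sceneConfig(class_raster, state_raster, noise_sd = noise_sd,
                missing_rate = missing_rate, seed = seed)
}

## Truncated-cosine seasonal bump: 1 at the peak day-of-year, 0 outside
## +/- width days (circular distance), matching a mid/late-September biomass
## peak and winter dormancy.
.seasonalCurve <- function(doy, peak = 260, width = 110) {
    d <- abs(doy - peak)
    d <- pmin(d, 365 - d)
    ifelse(d < width, cos(0.5 * pi * d / width), 0)
}

## Mean daily precipitation over the `lag` days ending at each target date.
.antecedentMean <- function(climate, target_dates, lag) {
    d <- as.numeric(as.Date(climate$date))
    cum <- c(0, cumsum(climate$precip_mm))
    t <- as.numeric(target_dates)
    lo <- findInterval(t - lag, d)       # last day <= t - lag (excluded)
    hi <- findInterval(t, d)             # last day <= t (included)
    if (any(t - lag < d[1] - 1) || any(hi == 0) || any(t > d[length(d)]))
        stop("climate record does not cover the antecedent window")
    (cum[hi + 1] - cum[lo + 1]) / lag
}

#' Simulate an NDVI scene from a configuration and climate record
#'
#' Generates the full pixel-by-scene NDVI matrix of the model described in
#' [sceneConfig()]: identical (class, state) pixels share the same expected
#' series, wetter antecedent conditions raise peak-season NDVI for any class
#' with positive moisture sensitivity, and degraded states compress (grassland
#' reference) or inflate (savanna reference) the seasonal amplitude.
#'
#' @param config a `SceneConfig`.
#' @param climate daily precipitation data.frame (`date`, `precip_mm`); must
#'   cover every acquisition date plus the longest antecedent lag.
#' @param time_grid `Date` vector of acquisition dates (regular grid).
#' @return list with elements `stack` ([NDVIStack-class]) and `truth`
#'   ([SceneTruth-class]).
#' @export
simulateScene <- function(config, climate, time_grid) {
    stopifnot(inherits(config, "SceneConfig"))
    .validateClimate(climate)
    time_grid <- as.Date(time_grid)
    if (length(time_grid) > 2 &&
        length(unique(diff(as.numeric(time_grid)))) != 1L)
        stop("time_grid must be regular")
    cls <- config$classes
    doy <- as.integer(format(time_grid, "%j"))
    S <- .seasonalCurve(doy)

    combos <- unique(data.frame(class = as.vector(config$class_raster),
                                state = as.vector(config$state_raster),
                                stringsAsFactors = FALSE))
    npx <- config$n_rows * config$n_cols
    nt <- length(time_grid)
    vals <- matrix(NA_real_, npx, nt)

    pbar_cache <- list()
    ## pixel (r, c) 0-based -> matrix row r * n_cols + c + 1 (row-major)
    px_class <- as.vector(t(config$class_raster))
    px_state <- as.vector(t(config$state_raster))

    for (k in seq_len(nrow(combos))) {
        ci <- match(combos$class[k], cls$class)
        key <- as.character(cls$lag_days[ci])
        if (is.null(pbar_cache[[key]]))
            pbar_cache[[key]] <- .antecedentMean(climate, time_grid,
                                                 cls$lag_days[ci])
        pbar <- pbar_cache[[key]]
        g <- pbar / (pbar + cls$half_sat[ci])
        m <- config$state_mult[[cls$reference[ci]]][combos$state[k]]
        lam <- cls$lambda[ci]
        mu <- cls$base[ci] + cls$amplitude[ci] * m * S *
            ((1 - lam) + lam * g)
        rows <- which(px_class == combos$class[k] &
                      px_state == combos$state[k])
        vals[rows, ] <- matrix(mu, length(rows), nt, byrow = TRUE)
    }

    if (config$noise_sd > 0) {
        set.seed(config$seed)
        vals <- vals + matrix(rnorm(npx * nt, sd = config$noise_sd), npx, nt)
    }
    vals <- pmin(pmax(vals, -1), 1)  # pmax(vals, ...) keeps the dim attribute

    stack <- NDVIStack(vals, dates = time_grid,
                       mask = matrix(FALSE, npx, nt),
                       gridDims = c(config$n_rows, config$n_cols))
    if (config$missing_rate > 0)
        stack <- injectGaps(stack, config$missing_rate,
                            seed = config$seed + 1L)
    truth <- new("SceneTruth", classRaster = config$class_raster,
                 stateRaster = matrix(as.integer(config$state_raster),
                                      config$n_rows, config$n_cols),
                 params = unclass(config))
    list(stack = stack, truth = truth)
}

#' Mask out a random fraction of observations
#'
#' Emulates cloud/QA masking: each observation is independently flagged
#' missing with probability `missing_rate`; flagged values are set `NA`,
#' everything else is untouched. Deterministic given the seed.
#'
#' @param stack an [NDVIStack-class].
#' @param missing_rate fraction in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return the gapped [NDVIStack-class].
#' @export
injectGaps <- function(stack, missing_rate, seed = 1L) {
    if (missing_rate < 0 || missing_rate >= 1)
        stop("missing_rate must be in [0, 1)")
    if (missing_rate == 0) return(stack)
    v <- ndviValues(stack)
    m <- missingMask(stack)
    set.seed(as.integer(seed))
    hit <- matrix(runif(length(v)) < missing_rate, nrow(v), ncol(v))
    m <- m | hit
    v[m] <- NA_real_
    NDVIStack(v, dates = sceneDates(stack), mask = m,
              gridDims = gridDims(stack), geo = geoInfo(stack))
}

#' Draw labelled sample points from a simulated scene
#'
#' Samples pixels per class from a [SceneTruth-class] (without replacement)
#' and returns them in the field-point schema used by [extractCovariates()]:
#' 0-based pixel indices plus map coordinates at pixel centres.
#'
#' @param truth a [SceneTruth-class].
#' @param n_per_class samples per class (capped at class pixel count).
#' @param seed integer RNG seed.
#' @param geo georeferencing list as in [NDVIStack()].
#' @return data.frame with `id`, `x`, `y`, `row`, `col`, `es_class`,
#'   `state_code`, `dataset`.
#' @export
sampleScenePoints <- function(truth, n_per_class = 50L, seed = 1L,
                              geo = list(x0 = 0, y0 = 0, px = 30,
                                         crs = "local")) {
    cr <- classRaster(truth); sr <- stateRaster(truth)
    set.seed(as.integer(seed))
    picks <- integer(0)
    for (cl in sort(unique(as.vector(cr)))) {
        idx <- which(cr == cl)  # column-major raster indices
        picks <- c(picks, sample(idx, min(n_per_class, length(idx))))
    }
    r0 <- (picks - 1L) %% nrow(cr)        # 0-based raster row
    c0 <- (picks - 1L) %/% nrow(cr)       # 0-based raster col
    data.frame(id = sprintf("pt%04d", seq_along(picks)),
               x = geo$x0 + (c0 + 0.5) * geo$px,
               y = geo$y0 - (r0 + 0.5) * geo$px,
               row = r0, col = c0,
               es_class = cr[picks], state_code = as.integer(sr[picks]),
               dataset = "synthetic", stringsAsFactors = FALSE)
}
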