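## Climate context: monthly aggregation, the standardized precipitation index
## (SPI) at 1-36 month accumulation scales, climatic-state categorization and
## transition detection, NDVI variability series, and the alignment of
## classifier covariate importance with climatic transitions.

#' Aggregate a daily precipitation record to calendar-month totals
#'
#' Partial months at either end of the record are dropped (with a message) so
#' every total covers a complete month.
#'
#' @param climate data.frame with `date`, `precip_mm`.
#' @return data.frame with `month` (Date, first of month) and `total_mm`.
#' @export
aggregateMonthly <- function(climate) {
    .validateClimate(climate)
    if (nrow(climate) == 0L) stop("climate record is empty")
    d <- as.Date(climate$date)
    first_full <- as.Date(format(d[1], "%Y-%m-01"))
    if (d[1] != first_full)
        first_full <- seq(first_full, by = "month", length.out = 2)[2]
    last_day <- d[length(d)]
    nxt <- seq(as.Date(format(last_day, "%Y-%m-01")), by = "month",
               length.out = 2)[2]
    last_full <- if (last_day == nxt - 1) as.Date(format(last_day, "%Y-%m-01"))
                 else seq(as.Date(format(last_day, "%Y-%m-01")), by = "-1 month",
                          length.out = 2)[2]
    keep <- d >= first_full & d < seq(last_full, by = "month",
                                      length.out = 2)[2]
    if (!any(keep)) stop("record does not cover a complete calendar month")
    if (!all(keep))
        message(sprintf("dropped %d day(s) in partial boundary months",
                        sum(!keep)))
    dd <- d[keep]
    key <- format(dd, "%Y-%m")
    tot <- tapply(climate$precip_mm[keep], key, sum)
    data.frame(month = as.Date(paste0(names(tot), "-01")),
               total_mm = as.numeric(tot), row.names = NULL)
}

## Thom's closed-form approximation to the gamma MLE; also the starting point
## (and fallback) for the full MLE via MASS::fitdistr.
.gammaFit <- function(x) {
    A <- log(mean(x)) - mean(log(x))
    if (!is.finite(A) || A <= 0) return(NULL)
    shape <- (1 + sqrt(1 + 4 * A / 3)) / (4 * A)
    rate <- shape / mean(x)
    fit <- tryCatch(
        suppressWarnings(MASS::fitdistr(x, "gamma",
                                        start = list(shape = shape,
                                                     rate = rate),
                                        lower = c(1e-8, 1e-8))),
        error = function(e) NULL)
    if (!is.null(fit)) c(shape = unname(fit$estimate["shape"]),
                         rate = unname(fit$estimate["rate"]))
    else c(shape = shape, rate = rate)
}

#' Standardized precipitation index
#'
#' Rolling `scale_months`-month accumulations are fitted, separately per
#' calendar month, with a zero-inflated gamma distribution
#' `H(x) = q + (1 - q) G(x)` (`q` = probability of a zero accumulation, `G`
#' = gamma CDF fitted to the positive accumulations by maximum likelihood,
#' Thom's approximation as starting point and fallback), then mapped through
#' the standard-normal quantile function. An index of 0 is the median
#' accumulation for that calendar month; values at or below -2 are
#' exceptionally dry, at or above +2 exceptionally wet.
#'
#' @param monthly data.frame from [aggregateMonthly()].
#' @param scale_months accumulation window in months (1-36).
#' @param thresholds category band edges passed to [spiCategory()].
#' @return data.frame with `month`, `scale`, `spi`, `category`; the first
#'   `scale_months - 1` months are undefined (`NA`), as are calendar months
#'   whose accumulations are all zero.
#' @export
spi <- function(monthly, scale_months = 1L, thresholds = c(dry = -1, wet = 1,
                                                           exceptional = 2)) {
    scale_months <- as.integer(scale_months)
    stopifnot(scale_months >= 1L)
    x <- monthly$total_mm
    n <- length(x)
    if (n - scale_months + 1L < 30L)
        stop("fewer than 30 accumulation windows; SPI fit would be unreliable")
    acc <- as.numeric(stats::filter(x, rep(1, scale_months), sides = 1))
    cal <- as.integer(format(monthly$month, "%m"))
    out <- rep(NA_real_, n)
    for (m in sort(unique(cal))) {
        i <- which(cal == m & !is.na(acc))
        if (!length(i)) next
        v <- acc[i]
        q <- mean(v == 0)
        if (q == 1) next                      # all-zero month: undefined
        pos <- v[v > 0]
        if (length(pos) < 3L || sd(pos) == 0) {
            ## point mass: every observed accumulation sits at the median
            H <- ifelse(v == 0, q, q + (1 - q) * 0.5)
        } else {
            fit <- .gammaFit(pos)
            if (is.null(fit)) next
            H <- q + (1 - q) * pgamma(v, shape = fit["shape"],
                                      rate = fit["rate"])
            H[v == 0] <- q
        }
        H <- pmin(1 - 1e-9, pmax(1e-9, H))
        out[i] <- qnorm(H)
    }
    data.frame(month = monthly$month, scale = scale_months, spi = out,
               category = spiCategory(out, thresholds))
}

#' Categorize SPI values into climatic states
#'
#' Bands: `<= -exceptional` exceptionally dry, `<= -dry` dry, `>= exceptional`
#' exceptionally wet, `>= wet` wet, otherwise normal.
#'
#' @param spi numeric SPI values (NA allowed).
#' @param thresholds named vector `c(dry, wet, exceptional)`; `dry` is the
#'   (negative) dry edge, `wet` the wet edge, `exceptional` the magnitude of
#'   the exceptional band.
#' @return character vector of category labels.
#' @export
spiCategory <- function(spi, thresholds = c(dry = -1, wet = 1,
                                            exceptional = 2)) {
    ex <- abs(thresholds[["exceptional"]])
    out <- rep(NA_character_, length(spi))
    ok <- !is.na(spi)
    out[ok] <- "normal"
    out[ok & spi <= thresholds[["dry"]]] <- "dry"
    out[ok & spi <= -ex] <- "exceptionally dry"
    out[ok & spi >= thresholds[["wet"]]] <- "wet"
    out[ok & spi >= ex] <- "exceptionally wet"
    out
}

#' Detect transitions between climatic states
#'
#' Collapses SPI into three bands (dry `<= -threshold`, wet `>= threshold`,
#' else normal) and reports every month whose band differs from the previous
#' defined month's band.
#'
#' @param spi_series data.frame from [spi()].
#' @param threshold band edge (default 1, the conventional moderate-anomaly
#'   edge).
#' @return `Date` vector of transition months (possibly empty).
#' @export
detectTransitions <- function(spi_series, threshold = 1) {
    s <- spi_series$spi
    band <- ifelse(s <= -threshold, "dry",
                   ifelse(s >= threshold, "wet", "normal"))
    idx <- which(!is.na(band))
    if (length(idx) < 2L) return(as.Date(character(0)))
    ch <- idx[-1][band[idx[-1]] != band[idx[-length(idx)]]]
    sort(as.Date(spi_series$month[ch]))
}

#' Per-scene standard deviation of NDVI over sample pixels
#'
#' One population SD (divide by n) per scene across the sampled pixels; peaks
#' track the seasonal biomass maximum when classes differ mainly in seasonal
#' amplitude.
#'
#' @param stack an [NDVIStack-class].
#' @param samples data.frame with `row`, `col` (0-based), >= 2 rows.
#' @return data.frame with `date` and `sd`.
#' @export
ndviSdSeries <- function(stack, samples) {
    if (nrow(samples) < 2L) stop("at least two sample pixels are required")
    gd <- gridDims(stack)
    idx <- samples$row * gd[2] + samples$col + 1L
    v <- ndviValues(stack)[idx, , drop = FALSE]
    sds <- apply(v, 2, function(col) {
        col <- col[!is.na(col)]
        sqrt(mean((col - mean(col))^2))
    })
    data.frame(date = sceneDates(stack), sd = as.numeric(sds))
}

#' Alignment of covariate importance with climatic transitions
#'
#' Tests whether scenes shortly after a climatic-state transition carry more
#' classifier importance. The statistic is the mean importance rank of scenes
#' within `window_steps` scenes at/after a transition minus the mean rank of
#' all other scenes (ranks are 1 = most important, so negative values mean
#' post-transition scenes matter more). Significance by label permutation.
#'
#' @param importance data.frame with `date` and `rank` (a permutation of
#'   1..n scenes).
#' @param transitions `Date` vector from [detectTransitions()] (>= 1).
#' @param window_steps window length in scenes (>= 1).
#' @param n_perm number of permutations (>= 999 recommended).
#' @param seed integer RNG seed.
#' @return list with `statistic`, `p_value` (one-sided, small = ranks
#'   concentrate after transitions), `n_in`, `n_out`.
#' @export
importanceTransitionAlignment <- function(importance, transitions,
                                          window_steps, n_perm = 999L,
                                          seed = 1L) {
    if (length(transitions) < 1L) stop("at least one transition is required")
    if (window_steps < 1L) stop("window_steps must be >= 1")
    dates <- as.Date(importance$date)
    ord <- order(dates)
    dates <- dates[ord]
    rk <- importance$rank[ord]
    n <- length(rk)
    inwin <- rep(FALSE, n)
    for (tr in as.list(sort(as.Date(transitions)))) {
        i0 <- which(dates >= tr)[1]
        if (is.na(i0)) next
        inwin[i0:min(n, i0 + window_steps - 1L)] <- TRUE
    }
    stat_fun <- function(r) {
        if (!any(inwin) || all(inwin)) return(0)
        mean(r[inwin]) - mean(r[!inwin])
    }
    obs <- stat_fun(rk)
    set.seed(as.integer(seed))
    perm <- replicate(n_perm, stat_fun(sample(rk)))
    list(statistic = obs,
         p_value = (1 + sum(perm <= obs)) / (n_perm + 1),
         n_in = sum(inwin), n_out = sum(!inwin))
}
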