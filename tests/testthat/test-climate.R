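# Monthly aggregation, SPI, transitions, NDVI variability, importance
# alignment.

test_that("monthly aggregation drops partial months and matches a groupby oracle", {
    clim <- data.frame(date = seq(as.Date("2000-01-01"), as.Date("2000-01-31"),
                                  by = 1),
                       precip_mm = 1)
    m <- aggregateMonthly(clim)
    expect_equal(nrow(m), 1)
    expect_equal(m$total_mm, 31)

    # trailing partial month dropped
    clim2 <- data.frame(date = seq(as.Date("2000-01-01"),
                                   as.Date("2000-03-10"), by = 1),
                        precip_mm = 1)
    expect_message(m2 <- aggregateMonthly(clim2), "partial")
    expect_equal(nrow(m2), 2)

    # randomized record vs brute-force groupby
    set.seed(3)
    d <- seq(as.Date("1991-01-01"), as.Date("1994-12-31"), by = 1)
    p <- rgamma(length(d), 0.5) * rbinom(length(d), 1, 0.3)
    m3 <- aggregateMonthly(data.frame(date = d, precip_mm = p))
    oracle <- tapply(p, format(d, "%Y-%m"), sum)
    expect_equal(m3$total_mm, as.numeric(oracle[format(m3$month, "%Y-%m")]),
                 tolerance = 1e-12)
})

test_that("SPI maps a point-mass record to zero and categorizes thresholds", {
    mo <- data.frame(month = seq(as.Date("1980-01-01"), by = "month",
                                 length.out = 12 * 10),
                     total_mm = 40)
    for (sc in c(1L, 3L, 12L)) {
        s <- spi(mo, sc)
        expect_true(all(is.na(s$spi[seq_len(sc - 1)])))
        expect_equal(s$spi[sc:nrow(mo)], rep(0, nrow(mo) - sc + 1))
    }
    expect_equal(spiCategory(c(-2.3, -1.2, 0, 1.4, 2.5)),
                 c("exceptionally dry", "dry", "normal", "wet",
                   "exceptionally wet"))
    expect_error(spi(mo[1:20, ], 1), "30")
})

test_that("SPI is standardized and scale-invariant on gamma records", {
    set.seed(14)
    mo <- data.frame(month = seq(as.Date("1970-01-01"), by = "month",
                                 length.out = 480),
                     total_mm = rgamma(480, shape = 2, scale = 20))
    s <- spi(mo, 3L)
    v <- s$spi[!is.na(s$spi)]
    expect_equal(mean(v), 0, tolerance = 0.1)
    expect_equal(sd(v), 1, tolerance = 0.1)

    # probability-integral-transform property: rescaling precipitation by a
    # positive constant leaves SPI unchanged
    mo10 <- mo; mo10$total_mm <- mo$total_mm * 10
    s10 <- spi(mo10, 3L)
    expect_equal(s10$spi, s$spi, tolerance = 1e-6)
})

test_that("zero-inflated records keep SPI defined and all-zero months flagged", {
    set.seed(8)
    mo <- data.frame(month = seq(as.Date("1970-01-01"), by = "month",
                                 length.out = 480),
                     total_mm = rgamma(480, 1, scale = 15) *
                         rbinom(480, 1, 0.7))
    jan <- format(mo$month, "%m") == "01"
    mo$total_mm[jan] <- 0   # a month that never rains
    s <- spi(mo, 1L)
    expect_true(all(is.na(s$spi[jan])))
    expect_true(all(is.finite(s$spi[!jan])))
})

test_that("transition detection finds band changes", {
    mo <- seq(as.Date("2000-01-01"), by = "month", length.out = 48)
    s <- data.frame(month = mo, scale = 1, spi = rep(0, 48),
                    category = "normal")
    expect_length(detectTransitions(s), 0)

    s$spi <- c(rep(-1.5, 24), rep(1.5, 24))
    tr <- detectTransitions(s)
    expect_equal(tr, mo[25])

    # regime-switch precipitation: detected transition near the true switch
    sched <- data.frame(start = c("1970-01-01", "1980-01-01"),
                        end = c("1979-12-31", "1991-12-31"),
                        multiplier = c(2.0, 0.4))
    clim <- simulatePrecipitation("1970-01-01", "1991-12-31",
                                  regime_schedule = sched, seed = 6)
    sp <- spi(aggregateMonthly(clim), 12L)
    tr2 <- detectTransitions(sp, threshold = 1)
    gap <- min(abs(as.numeric(tr2 - as.Date("1980-01-01")))) / 30.44
    # the 12-month window smears the switch; it must register within the
    # accumulation scale
    expect_lte(gap, 12)
})

test_that("NDVI dispersion across samples peaks in the growing season", {
    filt <- tinyFilteredScene()
    # identical pixels -> zero dispersion
    v <- ndviValues(filt)
    same <- NDVIStack(rbind(v[1, ], v[1, ], v[1, ]),
                      sceneDates(filt), gridDims = c(1L, 3L))
    s0 <- ndviSdSeries(same, data.frame(row = 0L, col = 0:2))
    expect_equal(s0$sd, rep(0, ncol(v)), tolerance = 1e-12)

    # two constant pixels differing by d -> population SD d/2
    two <- NDVIStack(rbind(rep(0.2, 10), rep(0.4, 10)),
                     seq(as.Date("2000-01-01"), by = 16, length.out = 10),
                     gridDims = c(1L, 2L))
    s2 <- ndviSdSeries(two, data.frame(row = c(0L, 0L), col = c(0L, 1L)))
    expect_equal(s2$sd, rep(0.1, 10))

    expect_error(ndviSdSeries(two, data.frame(row = 0L, col = 0L)), "two")

    # dispersion peaks within the seasonal-peak window in most years
    truth <- tinyScene()$truth
    pts <- sampleScenePoints(truth, 8, seed = 2)
    ss <- ndviSdSeries(filt, pts)
    doy <- as.integer(format(ss$date, "%j"))
    yr <- as.integer(format(ss$date, "%Y"))
    full <- names(which(table(yr) >= 20))  # only fully observed years
    hits <- vapply(full, function(y) {
        i <- which(yr == as.integer(y))
        d <- doy[i[which.max(ss$sd[i])]]
        d >= 230 && d <= 290
    }, logical(1))
    expect_gte(mean(hits), 0.8)
})

test_that("importance-transition alignment statistic and p-value behave", {
    dates <- seq(as.Date("2000-01-01"), by = 16, length.out = 100)
    tr <- dates[c(20, 60)]

    # best ranks planted exactly in the post-transition windows
    rk <- rep(NA_integer_, 100)
    win <- c(20:25, 60:65)
    rk[win] <- seq_along(win)
    rk[-win] <- length(win) + seq_len(100 - length(win))
    res <- importanceTransitionAlignment(
        data.frame(date = dates, rank = rk), tr, window_steps = 6,
        n_perm = 999, seed = 1)
    expect_lt(res$statistic, 0)
    expect_lte(res$p_value, 0.001)

    # a window covering the whole series has nothing to compare against
    res0 <- importanceTransitionAlignment(
        data.frame(date = dates, rank = rk), dates[1], window_steps = 200,
        n_perm = 99, seed = 1)
    expect_equal(res0$statistic, 0)

    expect_error(importanceTransitionAlignment(
        data.frame(date = dates, rank = rk), as.Date(character(0)), 5),
        "transition")

    # null calibration: random ranks rarely give small p-values
    ps <- vapply(1:40, function(s) {
        set.seed(s)
        importanceTransitionAlignment(
            data.frame(date = dates, rank = sample(100)), tr,
            window_steps = 6, n_perm = 199, seed = s)$p_value
    }, numeric(1))
    expect_lte(mean(ps <= 0.1), 0.3)
    expect_gt(mean(ps), 0.3)
})
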