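# Covariate extraction, SVM tuning/fitting, RFE, LGOCV, scene prediction.

test_that("covariate rows equal the sampled pixel series exactly", {
    filt <- tinyFilteredScene()
    s <- data.frame(id = c("a", "b", "c"), row = c(0L, 3L, 0L),
                    col = c(0L, 7L, 0L))
    x <- extractCovariates(filt, s)
    expect_equal(unname(x["a", ]), unname(ndviValues(filt)[1, ]))
    idx <- 3L * gridDims(filt)[2] + 7L + 1L
    expect_equal(unname(x["b", ]), unname(ndviValues(filt)[idx, ]))
    # two samples sharing a pixel get identical rows
    expect_equal(x["a", ], x["c", ], ignore_attr = TRUE)
    expect_identical(colnames(x), format(sceneDates(filt)))

    s_bad <- data.frame(id = "oob", row = 99L, col = 0L)
    expect_error(extractCovariates(filt, s_bad), "oob")
})

test_that("SVM grid tuning picks the best point with the stated tie rule", {
    gc <- gaussianClouds(100L, sep = 4)
    one <- tuneSvm(gc$x, gc$y, cost_grid = 2, gamma_grid = 0.5,
                   cv_folds = 5, seed = 1)
    expect_equal(one$cost, 2)
    expect_equal(one$gamma, 0.5)

    tuned <- tuneSvm(gc$x, gc$y, cost_grid = 2^(0:4), gamma_grid = 2^(-4:0),
                     cv_folds = 5, seed = 1)
    expect_gte(tuned$accuracy, 0.95)

    # a fully separable problem ties across the grid -> smallest (C, gamma)
    sep <- gaussianClouds(30L, sep = 30)
    t2 <- tuneSvm(sep$x, sep$y, cost_grid = c(8, 2), gamma_grid = c(1, 0.25),
                  cv_folds = 3, seed = 2)
    expect_equal(t2$accuracy, 1)
    expect_equal(t2$cost, 2)
    expect_equal(t2$gamma, 0.25)

    expect_error(tuneSvm(gc$x, rep("A", nrow(gc$x))), "two classes")
})

test_that("weighted SVM fits are deterministic and protect the minority class", {
    gc <- gaussianClouds(50L, sep = 6)
    fit <- fitSvm(gc$x, gc$y, cost = 4, gamma = 0.5)
    expect_equal(mean(predict(fit, gc$x) == gc$y), 1)  # separable toy
    fit2 <- fitSvm(gc$x, gc$y, cost = 4, gamma = 0.5)
    expect_identical(as.character(predict(fit, gc$x)),
                     as.character(predict(fit2, gc$x)))

    # 9:1 overlapping clouds: inverse-frequency weights raise minority PA
    wins <- 0L
    for (s in 1:20) {
        set.seed(s)
        x <- rbind(matrix(rnorm(2 * 180), ncol = 2),
                   matrix(rnorm(2 * 20, mean = 1.5), ncol = 2))
        y <- rep(c("maj", "min"), c(180, 20))
        w <- inverseFrequencyWeights(y)
        pa <- function(weights) {
            f <- fitSvm(x, y, cost = 1, gamma = 0.5, class_weights = weights)
            m <- errorMatrix(as.character(predict(f, x)), y)
            usersProducers(m)$pa[classLabels(m) == "min"]
        }
        wins <- wins + (pa(w) > pa(NULL))
    }
    expect_gte(wins, 11)  # strict majority of paired runs

    xx <- gc$x; xx[1, 1] <- NA
    expect_error(fitSvm(xx, gc$y), "missing")
})

test_that("inverse-frequency weights are normalized and ordered", {
    w <- inverseFrequencyWeights(rep(c("A", "B"), c(90, 10)))
    expect_equal(mean(w), 1)
    expect_gt(w[["B"]], w[["A"]])
})

test_that("RFE follows the size schedule and ranks by class separation", {
    set.seed(21)
    n <- 80L
    y <- rep(c("u", "v"), each = n / 2)
    x <- matrix(rnorm(n * 60), n, 60,
                dimnames = list(NULL, sprintf("cov%02d", 1:60)))
    inf <- c("cov05", "cov23", "cov41")
    x[y == "v", inf] <- x[y == "v", inf] + 2.5  # effect >= 2 SD
    x[, "cov60"] <- 0                           # zero variance

    r <- rfe(x, y, step = 10L, cost = 4, gamma = 1 / 60, seed = 1)
    expect_equal(r$sizes, seq(60L, 10L, by = -10L))
    expect_setequal(sort(unname(r$ranking)), 1:60)
    # informative covariates outrank the constant one
    expect_true(all(r$ranking[inf] < r$ranking["cov60"]))
    expect_true(all(inf %in% r$selected))
    expect_equal(r$best_size, length(r$selected))

    expect_error(rfe(x, y, step = 100L), "exceeds")
})

test_that("LGOCV pools the expected number of predictions and is seeded", {
    gc <- gaussianClouds(40L, sep = 4)
    one <- lgocv(gc$x, gc$y, reps = 1, test_frac = 0.3, cost = 4,
                 gamma = 0.5, seed = 3)
    expect_equal(sum(counts(one$matrix)), round(0.3 * 80))

    cv <- lgocv(gc$x, gc$y, reps = 10, test_frac = 0.3, cost = 4,
                gamma = 0.5, seed = 3)
    expect_equal(sum(counts(cv$matrix)), 10 * round(0.3 * 80))
    expect_equal(nrow(cv$records), 10 * 24)
    # the stated protocol arithmetic: n = 176, 30% holdout, 100 reps
    expect_equal(100 * round(0.3 * 176), 5300)

    cv2 <- lgocv(gc$x, gc$y, reps = 10, test_frac = 0.3, cost = 4,
                 gamma = 0.5, seed = 3)
    expect_identical(counts(cv$matrix), counts(cv2$matrix))
    expect_identical(cv$pcc_reps, cv2$pcc_reps)

    expect_error(lgocv(gc$x[1:41, ], rep(c("A", "B"), c(40, 1))), "2 members")
})

test_that("LGOCV reference marginals track class frequencies", {
    set.seed(5)
    y <- rep(c("A", "B", "C"), c(30, 15, 15))
    x <- matrix(rnorm(60 * 2), 60, 2)
    x[y == "B", ] <- x[y == "B", ] + 3
    x[y == "C", 1] <- x[y == "C", 1] - 3
    cv <- lgocv(x, y, reps = 100, test_frac = 0.3, cost = 4, gamma = 0.5,
                seed = 11)
    obs <- colSums(counts(cv$matrix))
    p <- c(30, 15, 15) / 60
    chi <- suppressWarnings(stats::chisq.test(obs, p = p))
    expect_gt(chi$p.value, 0.01)
})

test_that("scene prediction is pixelwise and order-consistent", {
    filt <- tinyFilteredScene()
    truth <- tinyScene()$truth
    pts <- sampleScenePoints(truth, 8, seed = 5)
    x <- extractCovariates(filt, pts)
    tuned <- tuneSvm(x, pts$es_class, cost_grid = 2^c(2, 5, 8),
                     gamma_grid = 2^c(-2, 0, 2), cv_folds = 4, seed = 1)
    model <- fitSvm(x, pts$es_class, cost = tuned$cost, gamma = tuned$gamma,
                    class_weights = inverseFrequencyWeights(pts$es_class))
    map <- predictMap(model, filt)
    expect_equal(dim(map), dim(classRaster(truth)))
    expect_gte(mean(map == classRaster(truth)), 0.95)

    # the map is exactly the per-pixel prediction of the value matrix
    v <- ndviValues(filt)
    colnames(v) <- format(sceneDates(filt))
    direct <- as.character(predict(model, v))
    expect_identical(as.vector(t(map)), direct)

    # a spatially constant stack yields a single-class map
    const <- NDVIStack(matrix(rep(v[1, ], each = nrow(v)), nrow(v)),
                       sceneDates(filt), gridDims = gridDims(filt))
    expect_length(unique(as.vector(predictMap(model, const))), 1)

    # mismatched date grid errors
    short <- NDVIStack(v[, -1], sceneDates(filt)[-1],
                       gridDims = gridDims(filt))
    expect_error(predictMap(model, short), "grid")
})
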