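# Shared fixtures built in code. The tiny scene is cached per test run; most
# tests only need a handful of pixels and a few seasons.

.fixtureCache <- new.env(parent = emptyenv())

tinyClimate <- function(seed = 2) {
    key <- paste0("clim", seed)
    if (is.null(.fixtureCache[[key]]))
        .fixtureCache[[key]] <- simulatePrecipitation(
            "1983-01-01", "1992-12-31", seed = seed)
    .fixtureCache[[key]]
}

tinyGrid <- function() buildTimeGrid("1984-05-21", "1992-11-01", 16)

# 8 x 10 reference-state scene, 5 classes in vertical bands, low noise
tinyScene <- function(noise_sd = 0.02, states = "reference", seed = 3) {
    key <- paste("scene", noise_sd, states, seed, sep = "_")
    if (is.null(.fixtureCache[[key]])) {
        cfg <- semiAridScenePreset(8L, 10L, states = states,
                                   noise_sd = noise_sd, seed = seed)
        .fixtureCache[[key]] <- simulateScene(cfg, tinyClimate(), tinyGrid())
    }
    .fixtureCache[[key]]
}

tinyFilteredScene <- function() {
    if (is.null(.fixtureCache$filt)) {
        sim <- tinyScene()
        .fixtureCache$filt <- preprocessStack(sim$stack)
    }
    .fixtureCache$filt
}

# two well-separated 2-D Gaussian clouds for classifier unit tests
gaussianClouds <- function(n_per_class = 100L, sep = 4, seed = 1) {
    set.seed(seed)
    x <- rbind(matrix(rnorm(2 * n_per_class), ncol = 2),
               matrix(rnorm(2 * n_per_class, mean = sep), ncol = 2))
    colnames(x) <- c("f1", "f2")
    list(x = x, y = rep(c("A", "B"), each = n_per_class))
}

table3Matrix <- function(which = c("svm", "expert", "gssurgo")) {
    which <- match.arg(which)
    readErrorMatrixCsv(system.file("extdata",
                                   sprintf("table3_%s.csv", which),
                                   package = "EcoSiteRS"))
}
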