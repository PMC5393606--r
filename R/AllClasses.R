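#' @import methods
#' @importFrom stats approx median optim pgamma qnorm quantile rbinom rgamma
#'   rnorm runif sd setNames stl ts var predict filter complete.cases aggregate
#' @importFrom utils read.csv write.csv head tail
NULL

#' NDVIStack: a pixel-by-scene vegetation-index time series
#'
#' An `NDVIStack` holds a dense vegetation-index (NDVI) time series for every
#' pixel of a rectangular raster, on a strictly increasing date grid, together
#' with a per-observation missing-data mask and minimal georeferencing.
#' It extends [SummarizedExperiment::SummarizedExperiment] with rows = pixels
#' (in row-major raster order) and columns = scenes.
#'
#' Assays:
#' \describe{
#'   \item{ndvi}{numeric matrix of NDVI values in `[-1, 1]`; entries flagged
#'     missing in the mask are `NA`.}
#'   \item{mask}{logical matrix, `TRUE` where the observation is missing
#'     (cloud/QA masked or never acquired).}
#' }
#'
#' Metadata carries `gridDims` (raster rows, cols) and `geo`, a list with the
#' affine georeferencing (`x0`, `y0` = outer corner of the top-left pixel,
#' `px` = pixel size in map units, `crs` = free-text CRS tag). Pixel `(r, c)`
#' (0-based) maps to matrix row `r * ncols + c + 1`.
#'
#' @aliases NDVIStack-class
#' @export
setClass("NDVIStack", contains = "SummarizedExperiment")

.validNDVIStack <- function(object) {
    msg <- NULL
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("ndvi", "mask") %in% an))
        msg <- c(msg, "assays must include 'ndvi' and 'mask'")
    else {
        v <- SummarizedExperiment::assay(object, "ndvi")
        m <- SummarizedExperiment::assay(object, "mask")
        if (!is.logical(m))
            msg <- c(msg, "'mask' assay must be logical")
        obs <- v[!m]
        obs <- obs[!is.na(obs)]
        if (length(obs) && (min(obs) < -1 - 1e-9 || max(obs) > 1 + 1e-9))
            msg <- c(msg, "unmasked NDVI values must lie in [-1, 1]")
    }
    d <- sceneDates(object)
    if (length(d) != ncol(object))
        msg <- c(msg, "one date per scene is required")
    if (length(d) > 1 && any(diff(as.numeric(d)) <= 0))
        msg <- c(msg, "scene dates must be strictly increasing")
    gd <- S4Vectors::metadata(object)$gridDims
    if (is.null(gd) || length(gd) != 2L || prod(gd) != nrow(object))
        msg <- c(msg, "metadata$gridDims must multiply to the pixel count")
    if (is.null(msg)) TRUE else msg
}
setValidity("NDVIStack", .validNDVIStack)

#' Construct an NDVIStack
#'
#' @param values numeric matrix, pixels (row-major raster order) by scenes.
#' @param dates `Date` vector, one per scene, strictly increasing.
#' @param mask logical matrix congruent with `values` (`TRUE` = missing);
#'   defaults to `is.na(values)`.
#' @param gridDims integer vector `c(nrow, ncol)` of the raster grid.
#' @param geo list with `x0`, `y0`, `px`, `crs` (see class docs).
#' @return an [NDVIStack-class] object.
#' @examples
#' v <- matrix(runif(4 * 6, 0, 0.5), 4, 6)
#' stk <- NDVIStack(v, dates = seq(as.Date("2000-01-01"), by = 16, length.out = 6),
#'                  gridDims = c(2L, 2L))
#' @export
NDVIStack <- function(values, dates, mask = NULL, gridDims,
                      geo = list(x0 = 0, y0 = 0, px = 30, crs = "local")) {
    values <- as.matrix(values)
    if (is.null(mask)) mask <- is.na(values)
    storage.mode(mask) <- "logical"
    dates <- as.Date(dates)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(ndvi = values, mask = mask),
        colData = S4Vectors::DataFrame(date = dates),
        metadata = list(gridDims = as.integer(gridDims), geo = geo))
    new("NDVIStack", se)
}

#' @describeIn NDVIStack scene dates of a stack.
#' @param x an `NDVIStack`.
#' @export
sceneDates <- function(x) as.Date(SummarizedExperiment::colData(x)$date)

#' @describeIn NDVIStack NDVI value matrix (pixels x scenes).
#' @export
ndviValues <- function(x) SummarizedExperiment::assay(x, "ndvi")

#' @describeIn NDVIStack logical missing-data mask (TRUE = missing).
#' @export
missingMask <- function(x) SummarizedExperiment::assay(x, "mask")

#' @describeIn NDVIStack raster grid dimensions `c(nrow, ncol)`.
#' @export
gridDims <- function(x) S4Vectors::metadata(x)$gridDims

#' @describeIn NDVIStack georeferencing list (`x0`, `y0`, `px`, `crs`).
#' @export
geoInfo <- function(x) S4Vectors::metadata(x)$geo

setMethod("show", "NDVIStack", function(object) {
    gd <- gridDims(object)
    d <- sceneDates(object)
    cat(sprintf("NDVIStack: %d x %d pixels, %d scenes (%s .. %s)\n",
                gd[1], gd[2], length(d), format(min(d)), format(max(d))))
    cat(sprintf("  missing: %.1f%% of observations\n",
                100 * mean(missingMask(object))))
})

#' SceneTruth: ground truth for a simulated scene
#'
#' Per-pixel ecological-site class and ecological-state code used to generate
#' a synthetic scene, plus the generator configuration, retained so that
#' recovery experiments can score predictions against truth.
#'
#' @slot classRaster character matrix of site-class labels (raster layout).
#' @slot stateRaster integer matrix of state codes 1-7 (raster layout).
#' @slot params list, the `SceneConfig` used by the generator.
#' @aliases SceneTruth-class
#' @export
setClass("SceneTruth",
         representation(classRaster = "matrix", stateRaster = "matrix",
                        params = "list"))

setValidity("SceneTruth", function(object) {
    msg <- NULL
    if (!identical(dim(object@classRaster), dim(object@stateRaster)))
        msg <- c(msg, "class and state rasters must have identical shape")
    st <- object@stateRaster
    if (!all(st %in% 1:7))
        msg <- c(msg, "state codes must be integers in 1..7")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn SceneTruth site-class raster.
#' @param x a `SceneTruth`.
#' @export
classRaster <- function(x) x@classRaster

#' @describeIn SceneTruth state-code raster.
#' @export
stateRaster <- function(x) x@stateRaster

#' @describeIn SceneTruth generator configuration.
#' @export
truthParams <- function(x) x@params

setMethod("show", "SceneTruth", function(object) {
    cat(sprintf("SceneTruth: %d x %d pixels, %d classes, states {%s}\n",
                nrow(object@classRaster), ncol(object@classRaster),
                length(unique(as.vector(object@classRaster))),
                paste(sort(unique(as.vector(object@stateRaster))),
                      collapse = ",")))
})

#' ErrorMatrix: a prediction-by-reference confusion matrix
#'
#' Square count matrix with rows = predicted class, columns = reference class,
#' both ordered by the same class list. All accuracy metrics (percent
#' correctly classified, user's/producer's accuracy, quantity and allocation
#' disagreement) derive from it.
#'
#' @slot counts non-negative numeric matrix with identical row/column labels.
#' @aliases ErrorMatrix-class
#' @export
setClass("ErrorMatrix", representation(counts = "matrix"))

setValidity("ErrorMatrix", function(object) {
    m <- object@counts
    msg <- NULL
    if (nrow(m) != ncol(m)) msg <- c(msg, "counts must be square")
    if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
    dn <- dimnames(m)
    if (is.null(dn) || !identical(dn[[1]], dn[[2]]))
        msg <- c(msg, "row and column class labels must be identical")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn ErrorMatrix class labels, in matrix order.
#' @param x an `ErrorMatrix`.
#' @export
classLabels <- function(x) rownames(x@counts)

#' @importMethodsFrom BiocGenerics counts
#' @describeIn ErrorMatrix raw count matrix (rows = prediction,
#'   columns = reference).
#' @param object an `ErrorMatrix`.
#' @export
setMethod("counts", "ErrorMatrix", function(object) object@counts)

setMethod("show", "ErrorMatrix", function(object) {
    cat(sprintf("ErrorMatrix: %d classes, %d observations\n",
                nrow(object@counts), sum(object@counts)))
    print(object@counts)
})

#' SeasonalDecomposition: additive trend/seasonal/remainder split
#'
#' Result of the LOESS-based seasonal-trend decomposition of a complete,
#' regularly sampled series. The three components reconstruct the input
#' exactly: `input = trend + seasonal + remainder`.
#'
#' @slot trend numeric, low-frequency component.
#' @slot seasonal numeric, periodic component with zero mean over each cycle.
#' @slot remainder numeric, residual.
#' @slot period integer, steps per seasonal cycle.
#' @aliases SeasonalDecomposition-class
#' @export
setClass("SeasonalDecomposition",
         representation(trend = "numeric", seasonal = "numeric",
                        remainder = "numeric", period = "integer"))

setValidity("SeasonalDecomposition", function(object) {
    n <- length(object@trend)
    if (length(object@seasonal) != n || length(object@remainder) != n)
        return("components must have equal length")
    if (object@period < 2L) return("period must be >= 2")
    TRUE
})

setMethod("show", "SeasonalDecomposition", function(object) {
    cat(sprintf(
        "SeasonalDecomposition: n = %d, period = %d, remainder RMS = %.4g\n",
        length(object@trend), object@period,
        sqrt(mean(object@remainder^2))))
})
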