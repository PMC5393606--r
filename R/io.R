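## File formats. Stacks travel as multi-directory 32-bit TIFF (one band per
## scene, band order = date ascending) plus two plain-text sidecars: a CSV
## date index (band, date) and a JSON geo sidecar (geotransform, CRS, nodata).
## NDVI v is stored scaled to s = (v + 1) / 2 in [0, 1]; missing observations
## are stored as the declared nodata value 0, and real data are kept >= 1e-6
## in scaled space (i.e. NDVI exactly -1 is nudged by ~2e-6, far below sensor
## noise).

.SCALED_NODATA <- 0
.SCALED_FLOOR <- 1e-6

.sidecarPath <- function(tiff_path) paste0(tiff_path, ".json")

#' Write an NDVI stack to TIFF + sidecars
#'
#' @param stack an [NDVIStack-class].
#' @param tiff_path output TIFF path; the geo sidecar goes to
#'   `<tiff_path>.json`.
#' @param date_index_csv output CSV path for the (band, date) index.
#' @return `tiff_path`, invisibly.
#' @export
writeStack <- function(stack, tiff_path, date_index_csv) {
    v <- ndviValues(stack)
    m <- missingMask(stack)
    gd <- gridDims(stack)
    d <- sceneDates(stack)
    bands <- lapply(seq_len(ncol(v)), function(j) {
        s <- (v[, j] + 1) / 2
        s <- pmin(1, pmax(.SCALED_FLOOR, s))
        s[m[, j] | is.na(s)] <- .SCALED_NODATA
        ## pixel rows are row-major; fill the raster grid by row
        matrix(s, gd[1], gd[2], byrow = TRUE)
    })
    tiff::writeTIFF(bands, tiff_path, bits.per.sample = 32L)
    write.csv(data.frame(band = seq_along(d), date = format(d)),
              date_index_csv, row.names = FALSE)
    jsonlite::write_json(c(geoInfo(stack),
                           list(grid_dims = gd, nodata = .SCALED_NODATA,
                                scaling = "ndvi = 2*stored - 1")),
                         .sidecarPath(tiff_path), auto_unbox = TRUE,
                         digits = NA)
    invisible(tiff_path)
}

#' Read an NDVI stack from TIFF + sidecars
#'
#' The missing-data mask is derived from the nodata value declared in the geo
#' sidecar. Errors on a band/date-count mismatch or non-monotone dates.
#'
#' @param tiff_path TIFF written by [writeStack()].
#' @param date_index_csv the matching date index CSV.
#' @return an [NDVIStack-class].
#' @export
readStack <- function(tiff_path, date_index_csv) {
    bands <- tiff::readTIFF(tiff_path, all = TRUE)
    di <- read.csv(date_index_csv)
    if (!all(c("band", "date") %in% names(di)) || anyNA(di$date))
        stop("date index must provide a date for every band")
    if (length(bands) != nrow(di))
        stop(sprintf("band count (%d) does not match date index rows (%d)",
                     length(bands), nrow(di)))
    d <- as.Date(di$date[order(di$band)])
    if (any(diff(as.numeric(d)) <= 0)) stop("dates must be strictly increasing")
    side <- jsonlite::read_json(.sidecarPath(tiff_path), simplifyVector = TRUE)
    gd <- as.integer(side$grid_dims)
    v <- vapply(bands, function(b) as.vector(t(b)), numeric(prod(gd)))
    m <- v == side$nodata
    v <- 2 * v - 1
    v[m] <- NA_real_
    NDVIStack(v, dates = d, mask = m, gridDims = gd,
              geo = side[c("x0", "y0", "px", "crs")])
}

#' Write a class raster to TIFF + JSON legend
#'
#' Classes are coded as small integers (8-bit) with the label mapping in a
#' JSON legend at `<path>.legend.json`.
#'
#' @param class_raster character matrix of class labels.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeClassRaster <- function(class_raster, path) {
    classes <- sort(unique(as.vector(class_raster)))
    if (length(classes) > 255L) stop("more than 255 classes")
    code <- matrix(match(class_raster, classes), nrow(class_raster),
                   ncol(class_raster))
    tiff::writeTIFF(code / 255, path, bits.per.sample = 8L)
    jsonlite::write_json(list(codes = setNames(as.list(seq_along(classes)),
                                               classes)),
                         paste0(path, ".legend.json"), auto_unbox = TRUE)
    invisible(path)
}

#' Read a class raster written by [writeClassRaster()]
#'
#' @param path TIFF path.
#' @return character matrix of class labels.
#' @export
readClassRaster <- function(path) {
    img <- tiff::readTIFF(path)
    leg <- jsonlite::read_json(paste0(path, ".legend.json"),
                               simplifyVector = TRUE)
    classes <- names(sort(unlist(leg$codes)))
    matrix(classes[round(img * 255)], nrow(img), ncol(img))
}

#' Write / read a daily climate record CSV
#'
#' @param climate data.frame with `date`, `precip_mm`.
#' @param path CSV path.
#' @return `path` (write) or the validated data.frame (read).
#' @export
writeClimateCsv <- function(climate, path) {
    .validateClimate(climate)
    write.csv(data.frame(date = format(as.Date(climate$date)),
                         precip_mm = climate$precip_mm),
              path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeClimateCsv
#' @export
readClimateCsv <- function(path) {
    df <- read.csv(path)
    df$date <- as.Date(df$date)
    .validateClimate(df)
    df
}

#' Read field sample points and bind them to stack pixels
#'
#' Required columns: `id`, `x`, `y`, `es_class`, `state_code` (an optional
#' `dataset` tag is carried through). Map coordinates are converted to
#' 0-based (row, col) pixel indices through the stack's geotransform, with
#' pixel centres at half-pixel offsets; points outside the raster extent are
#' dropped with their ids in a message.
#'
#' @param csv_path sample CSV path.
#' @param stack the [NDVIStack-class] the points are bound to.
#' @return data.frame with added `row`, `col` columns.
#' @export
readSamples <- function(csv_path, stack) {
    df <- read.csv(csv_path, stringsAsFactors = FALSE)
    need <- c("id", "x", "y", "es_class", "state_code")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("missing required column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$id))
        stop("duplicate sample ids: ",
             paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
    if (!all(df$state_code %in% 1:7)) stop("state_code must be in 1..7")
    geo <- geoInfo(stack)
    gd <- gridDims(stack)
    col <- floor((df$x - geo$x0) / geo$px)
    row <- floor((geo$y0 - df$y) / geo$px)
    out <- col < 0 | col >= gd[2] | row < 0 | row >= gd[1]
    if (any(out))
        message("dropped out-of-extent sample(s): ",
                paste(df$id[out], collapse = ", "))
    df$row <- as.integer(row)
    df$col <- as.integer(col)
    if (!"dataset" %in% names(df)) df$dataset <- "field"
    df[!out, , drop = FALSE]
}
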