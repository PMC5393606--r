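## Ecological-state misclassification diagnostics: state codes are carried as
## data (never as model covariates) and used post hoc to stratify errors,
## plus class/correctness-conditioned spectral signatures and per-class map
## area summaries.

#' Assemble classification records
#'
#' Joins truth, prediction and state code per sample and flags correctness.
#'
#' @param ids sample identifiers.
#' @param true_class,predicted_class label vectors.
#' @param state_code integer codes 1-7.
#' @return data.frame with a logical `correct` column.
#' @export
classificationRecords <- function(ids, true_class, predicted_class,
                                  state_code) {
    state_code <- as.integer(state_code)
    if (!all(state_code %in% 1:7)) stop("state codes must be in 1..7")
    data.frame(id = as.character(ids),
               true_class = as.character(true_class),
               predicted_class = as.character(predicted_class),
               state_code = state_code,
               correct = as.character(true_class) ==
                   as.character(predicted_class),
               stringsAsFactors = FALSE)
}

#' Misclassification rate per ecological state
#'
#' States absent from the records are omitted.
#'
#' @param records data.frame from [classificationRecords()].
#' @return data.frame with `state_code`, `n_total`, `n_misclassified`, `pct`
#'   (raw percent) and `pct_rounded` (integer percent for report parity).
#' @export
misclassificationByState <- function(records) {
    sc <- sort(unique(records$state_code))
    n_tot <- vapply(sc, function(s) sum(records$state_code == s), integer(1))
    n_mis <- vapply(sc, function(s)
        sum(records$state_code == s & !records$correct), integer(1))
    pct <- 100 * n_mis / n_tot
    data.frame(state_code = sc, n_total = n_tot, n_misclassified = n_mis,
               pct = pct, pct_rounded = roundHalfUp(pct))
}

#' Breakdown of a class's misclassifications by assigned class
#'
#' Partitions the misclassified records of one true class by the class they
#' were assigned to, each with its state-code frequency table. The partition
#' is disjoint and exhaustive over that class's misclassifications.
#'
#' @param records data.frame from [classificationRecords()].
#' @param site_class the true class to break down.
#' @return named list (one element per wrongly assigned class) of lists with
#'   `n` and `states` (named integer table); empty list if the class was never
#'   misclassified.
#' @export
misclassifiedAsBreakdown <- function(records, site_class) {
    if (!site_class %in% records$true_class)
        stop("unknown site class: ", site_class)
    mis <- records[records$true_class == site_class & !records$correct, ,
                   drop = FALSE]
    if (nrow(mis) == 0L) return(list())
    out <- lapply(split(mis, mis$predicted_class), function(g) {
        tab <- table(g$state_code)
        list(n = nrow(g),
             states = setNames(as.integer(tab), names(tab)))
    })
    out[order(-vapply(out, `[[`, numeric(1), "n"))]
}

#' Spectral signature of a pixel subset
#'
#' Per-scene mean and population SD of NDVI over a set of pixels (e.g., all
#' correctly classified points of one class).
#'
#' @param stack an [NDVIStack-class].
#' @param pixels data.frame with `row`, `col` (0-based), non-empty.
#' @return data.frame with `date`, `mean`, `sd`, `n`.
#' @export
spectralSignature <- function(stack, pixels) {
    if (nrow(pixels) == 0L) stop("pixel subset is empty")
    gd <- gridDims(stack)
    idx <- pixels$row * gd[2] + pixels$col + 1L
    v <- ndviValues(stack)[idx, , drop = FALSE]
    mu <- colMeans(v)
    sds <- sqrt(colMeans(sweep(v, 2, mu)^2))
    data.frame(date = sceneDates(stack), mean = as.numeric(mu),
               sd = as.numeric(sds), n = nrow(pixels))
}

#' Per-class area summary of a class raster
#'
#' @param class_raster character matrix of class labels.
#' @param pixel_area area per pixel in map units squared (900 m^2 for a 30 m
#'   pixel).
#' @return data.frame with `class`, `n_pixels`, `area`, `percent` (percents
#'   sum to 100).
#' @export
classAreaSummary <- function(class_raster, pixel_area = 900) {
    if (length(class_raster) == 0L) stop("class raster is empty")
    tab <- table(as.vector(class_raster))
    data.frame(class = names(tab), n_pixels = as.integer(tab),
               area = as.numeric(tab) * pixel_area,
               percent = 100 * as.numeric(tab) / sum(tab),
               row.names = NULL, stringsAsFactors = FALSE)
}
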