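## Accuracy assessment: error matrices, percent correctly classified, user's
## and producer's accuracy, and the decomposition of total disagreement into
## quantity disagreement (mismatched class proportions) and allocation
## disagreement (mislocated assignments at fixed proportions).

#' Round half away from zero
#'
#' Plain commercial rounding (R's `round()` rounds half to even). All
#' reported percentages and disagreement values use this convention.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build an error matrix from prediction/reference label vectors
#'
#' Counts with rows = prediction, columns = reference, ordered by
#' `class_list`.
#'
#' @param predictions,references equal-length label vectors.
#' @param class_list class labels fixing the matrix order; defaults to the
#'   sorted union of observed labels.
#' @return an [ErrorMatrix-class].
#' @export
errorMatrix <- function(predictions, references, class_list = NULL) {
    predictions <- as.character(predictions)
    references <- as.character(references)
    if (length(predictions) != length(references))
        stop("prediction and reference vectors must have equal length")
    if (is.null(class_list))
        class_list <- sort(unique(c(predictions, references)))
    bad <- setdiff(unique(c(predictions, references)), class_list)
    if (length(bad))
        stop("unknown class label(s): ", paste(bad, collapse = ", "))
    counts <- table(factor(predictions, levels = class_list),
                    factor(references, levels = class_list))
    m <- matrix(as.numeric(counts), length(class_list), length(class_list),
                dimnames = list(class_list, class_list))
    new("ErrorMatrix", counts = m)
}

.emProportions <- function(m) {
    cm <- counts(m)
    total <- sum(cm)
    if (total <= 0) stop("error matrix is empty")
    cm / total
}

#' Percent correctly classified
#'
#' `100 * trace / total` of the error matrix.
#'
#' @param m an [ErrorMatrix-class].
#' @return numeric percentage (unrounded).
#' @export
pcc <- function(m) {
    p <- .emProportions(m)
    100 * sum(diag(p))
}

#' Overall agreement (proportion correct)
#'
#' @param m an [ErrorMatrix-class].
#' @return proportion in `[0, 1]`.
#' @export
overallAgreement <- function(m) sum(diag(.emProportions(m)))

#' Per-class user's and producer's accuracy
#'
#' `UA_i = 100 * diag_i / rowsum_i` (reliability of predictions),
#' `PA_i = 100 * diag_i / colsum_i` (detectability of reference points).
#' A zero marginal makes the corresponding accuracy undefined: it is returned
#' as `NA` (never silently 0).
#'
#' @param m an [ErrorMatrix-class].
#' @return data.frame with columns `class`, `ua`, `pa` (percent, unrounded).
#' @export
usersProducers <- function(m) {
    cm <- counts(m)
    if (sum(cm) <= 0) stop("error matrix is empty")
    rs <- rowSums(cm); cs <- colSums(cm); dg <- diag(cm)
    data.frame(class = classLabels(m),
               ua = ifelse(rs > 0, 100 * dg / rs, NA_real_),
               pa = ifelse(cs > 0, 100 * dg / cs, NA_real_),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Quantity disagreement
#'
#' Half the L1 distance between the prediction and reference marginal
#' proportions: the share of total disagreement caused by mismatched class
#' proportions alone.
#'
#' @param m an [ErrorMatrix-class].
#' @return proportion in `[0, 1]` (unrounded).
#' @export
quantityDisagreement <- function(m) {
    p <- .emProportions(m)
    0.5 * sum(abs(rowSums(p) - colSums(p)))
}

#' Allocation disagreement
#'
#' `sum_i min(p_i+, p_+i) - C`, where `C` is the overall agreement: the share
#' of total disagreement caused by mislocated assignments at fixed class
#' proportions. For every matrix, `QD + AD = 1 - C` exactly.
#'
#' @param m an [ErrorMatrix-class].
#' @return proportion in `[0, 1]` (unrounded).
#' @export
allocationDisagreement <- function(m) {
    p <- .emProportions(m)
    sum(pmin(rowSums(p), colSums(p))) - sum(diag(p))
}

#' Percentile confidence interval for repeated-split PCC
#'
#' Two-sided percentile interval over the per-repetition percent-correct
#' values of a repeated holdout validation.
#'
#' @param per_rep_pcc numeric vector of per-repetition PCC values (>= 2).
#' @param level confidence level (default 0.95).
#' @return numeric `c(lo, hi)` (unrounded).
#' @export
confidenceInterval <- function(per_rep_pcc, level = 0.95) {
    if (length(per_rep_pcc) < 2L) stop("at least two repetitions required")
    a <- (1 - level) / 2
    unname(quantile(per_rep_pcc, c(a, 1 - a), type = 7))
}

#' Full accuracy report for an error matrix
#'
#' Bundles PCC, per-class user's/producer's accuracy, overall agreement and
#' the quantity/allocation decomposition, both raw and under the reporting
#' rounding convention (accuracies to integer percent, QD/AD to two decimals,
#' half away from zero).
#'
#' @param m an [ErrorMatrix-class].
#' @param pcc_reps optional per-repetition PCC values for a 95% CI.
#' @param level CI level.
#' @return list suitable for JSON serialization.
#' @export
accuracyReport <- function(m, pcc_reps = NULL, level = 0.95) {
    up <- usersProducers(m)
    C <- overallAgreement(m)
    qd <- quantityDisagreement(m)
    ad <- allocationDisagreement(m)
    rep <- list(
        n = sum(counts(m)),
        classes = classLabels(m),
        pcc = pcc(m), overall_agreement = C, qd = qd, ad = ad,
        users_accuracy = setNames(up$ua, up$class),
        producers_accuracy = setNames(up$pa, up$class),
        rounded = list(pcc = roundHalfUp(pcc(m)),
                       qd = roundHalfUp(qd, 2), ad = roundHalfUp(ad, 2),
                       users_accuracy = setNames(roundHalfUp(up$ua), up$class),
                       producers_accuracy = setNames(roundHalfUp(up$pa),
                                                     up$class)))
    if (!is.null(pcc_reps)) {
        ci <- confidenceInterval(pcc_reps, level)
        rep$pcc_ci <- ci
        rep$rounded$pcc_ci <- roundHalfUp(ci)
    }
    rep
}

#' Read an error matrix from CSV
#'
#' Expects a header row and a first column of class labels, rows =
#' prediction, columns = reference (the layout the report tables print).
#'
#' @param path CSV file path.
#' @return an [ErrorMatrix-class].
#' @export
readErrorMatrixCsv <- function(path) {
    df <- read.csv(path, check.names = FALSE, row.names = 1)
    m <- as.matrix(df)
    if (!identical(rownames(m), colnames(m)))
        stop("row and column class labels must match: ", path)
    new("ErrorMatrix", counts = m)
}

#' Write an error matrix to CSV
#'
#' @param m an [ErrorMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeErrorMatrixCsv <- function(m, path) {
    write.csv(as.data.frame(counts(m)), path)
    invisible(path)
}
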