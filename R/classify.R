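## Classification: covariate extraction at sample pixels, grid-tuned weighted
## RBF-kernel SVM, recursive feature elimination with a deterministic
## class-separation filter score, leave-group-out cross-validation, and
## whole-scene prediction.

#' Extract per-sample covariate rows from a stack
#'
#' Row `i` of the result is the (filtered) NDVI time series at sample `i`'s
#' pixel; columns are the scene dates. The stack must be complete at the
#' sampled pixels (run [preprocessStack()] first).
#'
#' @param stack an [NDVIStack-class].
#' @param samples data.frame with at least `id`, `row`, `col` (0-based pixel
#'   indices).
#' @return numeric matrix, samples x scenes, with sample ids as rownames and
#'   ISO dates as colnames.
#' @export
extractCovariates <- function(stack, samples) {
    gd <- gridDims(stack)
    bad <- samples$row < 0 | samples$row >= gd[1] |
           samples$col < 0 | samples$col >= gd[2]
    if (any(bad))
        stop("sample pixel out of bounds: ",
             paste(samples$id[bad], collapse = ", "))
    idx <- samples$row * gd[2] + samples$col + 1L
    out <- ndviValues(stack)[idx, , drop = FALSE]
    if (anyNA(out))
        stop("covariate table contains missing values; preprocess the stack")
    dimnames(out) <- list(as.character(samples$id),
                          format(sceneDates(stack)))
    out
}

#' Inverse-frequency class weights
#'
#' Weights proportional to `1 / class frequency`, normalized to mean 1, so
#' underrepresented classes get more emphasis in the SVM fit.
#'
#' @param labels factor or character class labels.
#' @return named numeric vector of weights.
#' @export
inverseFrequencyWeights <- function(labels) {
    f <- table(labels)
    w <- 1 / as.numeric(f)
    w <- w * length(w) / sum(w)
    setNames(w, names(f))
}

.makeFolds <- function(labels, k, seed) {
    set.seed(as.integer(seed))
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
        i <- which(labels == cl)
        fold[i] <- sample(rep_len(seq_len(k), length(i)))
    }
    fold
}

.svmFit <- function(x, y, cost, gamma, class_weights) {
    e1071::svm(x = x, y = y, type = "C-classification", kernel = "radial",
               cost = cost, gamma = gamma, class.weights = class_weights,
               scale = FALSE)
}

.cvAccuracy <- function(x, y, fold, cost, gamma, class_weights) {
    k <- max(fold)
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (f in seq_len(k)) {
        te <- fold == f
        fit <- .svmFit(x[!te, , drop = FALSE], droplevels(y[!te]),
                       cost, gamma,
                       class_weights[levels(droplevels(y[!te]))])
        pred[te] <- predict(fit, x[te, , drop = FALSE])
    }
    mean(pred == y)
}

## Draw `reps` random holdout index sets of size round(test_frac * n),
## redrawing (up to max_redraws per rep) any split that leaves a class absent
## from training. Returns list(splits = list of test-index vectors, redraws).
.drawSplits <- function(y, reps, test_frac, seed, max_redraws = 10L) {
    n <- length(y)
    n_test <- round(test_frac * n)
    if (n_test < 1L || n_test >= n) stop("test_frac leaves no usable split")
    set.seed(as.integer(seed))
    splits <- vector("list", reps)
    redraws <- 0L
    for (r in seq_len(reps)) {
        tries <- 0L
        repeat {
            te <- sample.int(n, n_test)
            if (nlevels(droplevels(y[-te])) == nlevels(y)) break
            tries <- tries + 1L; redraws <- redraws + 1L
            if (tries > max_redraws)
                stop("could not draw a split with all classes in training")
        }
        splits[[r]] <- te
    }
    list(splits = splits, redraws = redraws)
}

## Mean holdout accuracy over a fixed list of test-index splits.
.splitAccuracy <- function(x, y, splits, cost, gamma, class_weights) {
    acc <- vapply(splits$splits, function(te) {
        fit <- .svmFit(x[-te, , drop = FALSE], y[-te], cost, gamma,
                       class_weights)
        mean(predict(fit, x[te, , drop = FALSE]) == y[te])
    }, numeric(1))
    mean(acc)
}

#' Grid search for RBF-SVM hyper-parameters
#'
#' Evaluates every `(cost, gamma)` combination by cross-validated percent
#' correctly classified and returns the best point. Ties are broken toward
#' the smallest cost, then the smallest gamma.
#'
#' Two evaluation schemes are available. `method = "kfold"` (default) scores
#' each grid point by stratified k-fold cross-validation. `method = "lgocv"`
#' scores it by repeated random 70/30-style holdout splits -- the same split
#' style the validation protocol uses -- which is the more faithful choice
#' when the selected point will be frozen and reused inside [lgocv()]:
#' stratified folds can saturate at perfect accuracy across the whole grid on
#' easy problems, and the smallest-(cost, gamma) tie rule may then pick a
#' point that underfits on unstratified splits.
#'
#' @param x covariate matrix (samples x covariates).
#' @param labels class labels (>= 2 classes, each with >= `cv_folds` members).
#' @param cost_grid,gamma_grid numeric grids (powers of 2 by default).
#' @param class_weights named weights as from [inverseFrequencyWeights()], or
#'   `NULL`.
#' @param cv_folds number of folds (`method = "kfold"`).
#' @param seed integer seed controlling the fold/split assignment.
#' @param method `"kfold"` or `"lgocv"`.
#' @param tune_reps,test_frac repetitions and holdout fraction for
#'   `method = "lgocv"`; the same splits are reused for every grid point.
#' @return list with `cost`, `gamma`, `accuracy` and the full `grid`
#'   data.frame.
#' @export
tuneSvm <- function(x, labels, cost_grid = 2^(-2:8), gamma_grid = 2^(-8:2),
                    class_weights = NULL, cv_folds = 5L, seed = 1L,
                    method = c("kfold", "lgocv"), tune_reps = 10L,
                    test_frac = 0.30) {
    method <- match.arg(method)
    y <- factor(labels)
    if (nlevels(y) < 2L) stop("at least two classes are required")
    if (min(table(y)) < cv_folds)
        stop("every class needs at least cv_folds members")
    grid <- expand.grid(cost = sort(cost_grid), gamma = sort(gamma_grid))
    if (method == "kfold") {
        fold <- .makeFolds(y, cv_folds, seed)
        grid$accuracy <- vapply(seq_len(nrow(grid)), function(i)
            .cvAccuracy(x, y, fold, grid$cost[i], grid$gamma[i],
                        class_weights),
            numeric(1))
    } else {
        splits <- .drawSplits(y, tune_reps, test_frac, seed)
        grid$accuracy <- vapply(seq_len(nrow(grid)), function(i)
            .splitAccuracy(x, y, splits, grid$cost[i], grid$gamma[i],
                           class_weights),
            numeric(1))
    }
    ## ties -> smallest cost, then smallest gamma
    ord <- order(-grid$accuracy, grid$cost, grid$gamma)
    best <- grid[ord[1L], ]
    list(cost = best$cost, gamma = best$gamma, accuracy = best$accuracy,
         grid = grid)
}

#' Fit a weighted RBF-kernel SVM
#'
#' One-vs-one multiclass C-classification with a radial basis kernel
#' (libsvm via e1071). Covariates are not rescaled: NDVI covariates already
#' share a physical scale.
#'
#' @param x covariate matrix without missing values.
#' @param labels class labels.
#' @param cost,gamma hyper-parameters.
#' @param class_weights optional named class weights.
#' @param seed integer seed (the fit itself is deterministic; the seed is
#'   recorded for provenance).
#' @return a `SiteModel` list: `fit`, `classes`, `cost`, `gamma`,
#'   `class_weights`, `covariates` (column names used), `seed`.
#' @export
fitSvm <- function(x, labels, cost = 1, gamma = 1 / ncol(x),
                   class_weights = NULL, seed = 1L) {
    if (anyNA(x) || any(!is.finite(x)))
        stop("covariates contain missing or non-finite values")
    y <- factor(labels)
    if (nlevels(y) < 2L) stop("at least two classes are required")
    set.seed(as.integer(seed))
    fit <- .svmFit(x, y, cost, gamma, class_weights)
    structure(list(fit = fit, classes = levels(y), cost = cost, gamma = gamma,
                   class_weights = class_weights, covariates = colnames(x),
                   seed = as.integer(seed)),
              class = "SiteModel")
}

#' Predict classes for new covariate rows
#'
#' @param object a `SiteModel` from [fitSvm()].
#' @param newdata covariate matrix whose columns include the model's
#'   covariates (matched by name when named).
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.SiteModel <- function(object, newdata, ...) {
    if (!is.null(object$covariates) && !is.null(colnames(newdata)))
        newdata <- newdata[, object$covariates, drop = FALSE]
    predict(object$fit, newdata)
}

## Deterministic per-covariate class-separation score: one-way F ratio of
## between-class to within-class variance. Zero-variance covariates score 0.
.fRatio <- function(x, y) {
    n <- length(y)
    cls <- levels(y)
    gm <- colMeans(x)
    between <- numeric(ncol(x))
    within <- numeric(ncol(x))
    for (cl in cls) {
        xi <- x[y == cl, , drop = FALSE]
        ni <- nrow(xi)
        mi <- colMeans(xi)
        between <- between + ni * (mi - gm)^2
        if (ni > 1)
            within <- within + (ni - 1) * apply(xi, 2, var)
    }
    between <- between / (length(cls) - 1)
    within <- within / (n - length(cls))
    between / (within + 1e-12)
}

#' Recursive feature elimination with a class-separation filter
#'
#' Backward selection: starting from all covariates, each iteration drops the
#' `step` covariates with the lowest importance, where importance is the
#' one-way F ratio (between-class over within-class variance) recomputed on
#' the surviving set. Each iteration's subset is scored by stratified k-fold
#' cross-validated SVM accuracy; the best-scoring subset is selected (ties
#' broken toward the smaller subset). Every covariate receives a rank
#' 1..n (1 = most important): survivors of the final iteration are ranked by
#' final importance, and eliminated covariates rank behind all survivors in
#' reverse order of elimination.
#'
#' @param x covariate matrix.
#' @param labels class labels.
#' @param step covariates removed per iteration (default 10).
#' @param cost,gamma SVM hyper-parameters used for scoring.
#' @param class_weights optional named class weights.
#' @param cv_folds folds for the accuracy score.
#' @param seed integer seed (fold assignment).
#' @return list with `ranking` (named integer permutation of 1..n),
#'   `selected` (covariate names of the best iteration), `sizes`,
#'   `accuracies`, `best_size`.
#' @export
rfe <- function(x, labels, step = 10L, cost = 1, gamma = 1 / ncol(x),
                class_weights = NULL, cv_folds = 5L, seed = 1L) {
    step <- as.integer(step)
    n <- ncol(x)
    if (step < 1L) stop("step must be >= 1")
    if (step > n) stop("step exceeds the covariate count")
    if (is.null(colnames(x))) colnames(x) <- sprintf("cov%04d", seq_len(n))
    y <- factor(labels)
    fold <- .makeFolds(y, cv_folds, seed)

    sizes <- seq.int(n, 1L, by = -step)
    current <- colnames(x)
    subsets <- vector("list", length(sizes))
    acc <- numeric(length(sizes))
    rank_rev <- character(0)  # worst-first accumulation of eliminated names

    for (k in seq_along(sizes)) {
        if (length(current) > sizes[k]) {
            imp <- .fRatio(x[, current, drop = FALSE], y)
            drop_n <- length(current) - sizes[k]
            dropped <- current[order(imp)][seq_len(drop_n)]
            ## worst score eliminated first -> worst overall rank
            rank_rev <- c(rank_rev, dropped)
            current <- setdiff(current, dropped)
        }
        subsets[[k]] <- current
        acc[k] <- .cvAccuracy(x[, current, drop = FALSE], y, fold,
                              cost, gamma, class_weights)
    }

    ## survivors ranked 1.. by final importance, then eliminated (reverse order)
    imp_fin <- .fRatio(x[, current, drop = FALSE], y)
    ordered <- c(current[order(-imp_fin)], rev(rank_rev))
    ranking <- setNames(seq_len(n), ordered)[colnames(x)]
    names(ranking) <- colnames(x)

    best <- order(-acc, sizes)[1L]  # ties -> smaller subset
    list(ranking = ranking, selected = subsets[[best]], sizes = sizes,
         accuracies = acc, best_size = sizes[best])
}

#' Leave-group-out cross-validation
#'
#' Repeated random 70/30-style train/test splits: each repetition holds out
#' `round(test_frac * n)` observations, fits the SVM on the remainder with
#' fixed hyper-parameters, and predicts the held-out set. All (prediction,
#' reference) pairs are pooled into a single [ErrorMatrix-class]. A split
#' leaving any class absent from training is redrawn (at most `max_redraws`
#' times per repetition, then an error).
#'
#' @param x covariate matrix.
#' @param labels class labels (every class needs >= 2 members).
#' @param reps number of repetitions (100 in the standard protocol).
#' @param test_frac held-out fraction (0.30 in the standard protocol).
#' @param cost,gamma fixed hyper-parameters (tune once beforehand).
#' @param class_weights optional named class weights.
#' @param seed integer RNG seed.
#' @param max_redraws redraw budget per repetition.
#' @return list with `matrix` ([ErrorMatrix-class]), `pcc_reps` (per-rep
#'   percent correct), `records` (pooled per-prediction data.frame with `id`,
#'   `rep`, `reference`, `prediction` for post-hoc stratification), and
#'   `redraws` (total redraw count).
#' @export
lgocv <- function(x, labels, reps = 100L, test_frac = 0.30, cost = 1,
                  gamma = 1 / ncol(x), class_weights = NULL, seed = 1L,
                  max_redraws = 10L) {
    y <- factor(labels)
    if (min(table(y)) < 2L) stop("every class needs at least 2 members")
    n <- length(y)
    ids <- if (!is.null(rownames(x))) rownames(x) else as.character(seq_len(n))
    drawn <- .drawSplits(y, reps, test_frac, seed, max_redraws)
    preds <- refs <- pids <- character(0)
    prep <- integer(0)
    pcc_reps <- numeric(reps)
    for (r in seq_len(reps)) {
        te <- drawn$splits[[r]]
        fit <- .svmFit(x[-te, , drop = FALSE], y[-te], cost, gamma,
                       class_weights)
        p <- as.character(predict(fit, x[te, , drop = FALSE]))
        preds <- c(preds, p)
        refs <- c(refs, as.character(y[te]))
        pids <- c(pids, ids[te])
        prep <- c(prep, rep.int(r, length(te)))
        pcc_reps[r] <- 100 * mean(p == as.character(y[te]))
    }
    list(matrix = errorMatrix(preds, refs, levels(y)), pcc_reps = pcc_reps,
         records = data.frame(id = pids, rep = prep, reference = refs,
                              prediction = preds, stringsAsFactors = FALSE),
         redraws = drawn$redraws)
}

#' Predict a class raster for a whole scene
#'
#' Applies a fitted model to every pixel of a (filtered) stack, optionally on
#' a covariate subset selected by [rfe()]. The stack's date grid must contain
#' the model's training covariate dates.
#'
#' @param model a `SiteModel`.
#' @param stack a complete [NDVIStack-class] (no missing values).
#' @param selected optional character vector of covariate (date) names to use.
#' @return character matrix of class labels in raster layout.
#' @export
predictMap <- function(model, stack, selected = NULL) {
    v <- ndviValues(stack)
    colnames(v) <- format(sceneDates(stack))
    want <- if (is.null(selected)) model$covariates else selected
    if (!all(want %in% colnames(v)))
        stop("stack date grid does not match the model's training grid")
    if (anyNA(v)) stop("stack contains missing values; preprocess first")
    p <- as.character(predict(model, v[, want, drop = FALSE]))
    gd <- gridDims(stack)
    ## pixel rows are row-major: fill the raster by row
    matrix(p, gd[1], gd[2], byrow = TRUE)
}
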