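#' @include AllClasses.R
NULL

.popSd <- function(m) {
    mu <- colMeans(m)
    sqrt(colMeans(sweep(m, 2L, mu)^2))
}

#' Standardize feature matrices
#'
#' Centers and scales each column to mean 0 and (population) standard
#' deviation 1. In `"joint"` mode the parameters are fitted on the
#' row-stacked `[train; test]` matrix — the transductive normalization in
#' which simulated training features are standardized together with the
#' candidate features they will be compared against; note that this leaks
#' test statistics into training and `"train_only"` (fit on train, apply
#' to both) is the conventional alternative. Zero-variance columns get
#' spread 1 (so a constant column scales to all zeros).
#'
#' @param train numeric training matrix.
#' @param test optional test matrix with the same columns.
#' @param mode `"joint"` (default) or `"train_only"`.
#' @return a list with `train`, `test` (NULL if absent), `center`,
#'   `spread`.
#' @export
scaleFeatures <- function(train, test = NULL, mode = c("joint",
                                                       "train_only")) {
    mode <- match.arg(mode)
    train <- as.matrix(train)
    if (nrow(train) == 0L || ncol(train) == 0L)
        stop("empty feature matrix")
    if (!is.null(test)) {
        test <- as.matrix(test)
        if (ncol(test) != ncol(train))
            stop("train and test must have the same number of columns")
    }
    fitOn <- if (mode == "joint" && !is.null(test))
        rbind(train, test) else train
    center <- colMeans(fitOn)
    spread <- .popSd(fitOn)
    spread[spread == 0 | !is.finite(spread)] <- 1
    sc <- function(m)
        sweep(sweep(m, 2L, center), 2L, spread, "/")
    list(train = sc(train), test = if (is.null(test)) NULL else sc(test),
         center = center, spread = spread)
}

#' Train the inversion SVM
#'
#' Fits a support vector machine on standardized breakpoint-window
#' features. The default specification is a linear kernel with penalty
#' factor C = 0.1 and gamma = 20 (gamma is inert for the linear kernel
#' but kept as part of the model specification); the radial kernel is
#' available for exploring the C/gamma grid. The raw training matrix is
#' stored in the model so the transductive `"joint"` scaling mode can
#' re-standardize training and candidate features together at prediction
#' time.
#'
#' @param X numeric matrix of raw (unscaled) features; either 15 columns
#'   `f1..f15` or exactly the `selectedIds` columns.
#' @param y 0/1 labels (1 = inversion), both classes present.
#' @param selectedIds feature IDs the model uses (default the reference
#'   ten-feature set, [defaultFeatureIds()]).
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param C penalty factor (default 0.1).
#' @param gamma kernel coefficient (default 20).
#' @param scalingMode `"joint"` (default) or `"train_only"`; see
#'   [scaleFeatures()].
#' @param seed RNG seed recorded in the model (training itself is
#'   deterministic).
#' @return an [InversionClassifier-class].
#' @examples
#' set.seed(1)
#' X <- matrix(abs(rnorm(40, rep(c(1, 8), each = 20))), ncol = 1)
#' X <- X[, rep(1, 15)]; colnames(X) <- paste0("f", 1:15)
#' y <- rep(c(0, 1), each = 20)
#' fit <- trainInversionClassifier(X, y, selectedIds = 1:15)
#' all(predictInversions(fit, X) == y)
#' @export
trainInversionClassifier <- function(X, y,
                                     selectedIds = defaultFeatureIds(),
                                     kernel = c("linear", "radial"),
                                     C = 0.1, gamma = 20,
                                     scalingMode = c("joint",
                                                     "train_only"),
                                     seed = 1L) {
    kernel <- match.arg(kernel)
    scalingMode <- match.arg(scalingMode)
    X <- .selectColumns(as.matrix(X), selectedIds)
    y <- as.integer(y)
    if (length(unique(y)) < 2L)
        stop("degenerate labels: both classes must be present")
    sc <- scaleFeatures(X, mode = "train_only")
    set.seed(seed)
    fit <- e1071::svm(x = sc$train, y = factor(y, levels = c(0L, 1L)),
                      kernel = kernel, cost = C, gamma = gamma,
                      scale = FALSE)
    new("InversionClassifier", selectedIds = as.integer(selectedIds),
        kernel = kernel, cost = C, gamma = gamma,
        scalingMode = scalingMode, trainX = X, y = y, center = sc$center, spread = sc$spread,
        fit = fit, seed = as.integer(seed))
}

.selectColumns <- function(X, ids) {
    if (ncol(X) == 15L)
        return(X[, ids, drop = FALSE])
    if (ncol(X) == length(ids))
        return(X)
    stop("feature matrix must have 15 columns or exactly the ",
         length(ids), " selected columns")
}

#' Predict inversion labels for candidate windows
#'
#' Scores raw candidate feature vectors with a trained model and returns
#' 1 (inversion) or 0 (wild-type) per row. Under the model's `"joint"`
#' scaling mode, the stored raw training matrix is re-standardized
#' together with the candidates and the SVM is refitted on the jointly
#' scaled training rows (the transductive procedure); under
#' `"train_only"` the stored scaler and fit are applied directly. Either
#' way the result is deterministic and invariant under row permutation of
#' `X`.
#'
#' @param model an [InversionClassifier-class].
#' @param X raw feature matrix (15 columns or the model's selected
#'   columns).
#' @return integer vector of 0/1 labels.
#' @export
predictInversions <- function(model, X) {
    X <- .selectColumns(as.matrix(X), model@selectedIds)
    if (nrow(X) == 0L)
        return(integer(0))
    if (model@scalingMode == "joint") {
        sc <- scaleFeatures(model@trainX, X, mode = "joint")
        set.seed(model@seed)
        fit <- e1071::svm(x = sc$train,
                          y = factor(model@y, levels = c(0L, 1L)),
                          kernel = model@kernel, cost = model@cost,
                          gamma = model@gamma, scale = FALSE)
        pred <- stats::predict(fit, sc$test)
    } else {
        scX <- sweep(sweep(X, 2L, model@center), 2L, model@spread, "/")
        pred <- stats::predict(model@fit, scX)
    }
    as.integer(as.character(pred))
}

#' Serialize / restore a trained classifier
#'
#' Writes the full model object (selected IDs, scaler, SVM parameters and
#' support data, raw training matrix, seed) to a single file, and reads
#' it back.
#'
#' @param model an [InversionClassifier-class].
#' @param path file path.
#' @return `path` invisibly (write) or an [InversionClassifier-class]
#'   (read).
#' @export
writeInversionModel <- function(model, path) {
    saveRDS(model, path)
    invisible(path)
}

#' @rdname writeInversionModel
#' @export
readInversionModel <- function(path) {
    model <- readRDS(path)
    if (!is(model, "InversionClassifier"))
        stop("file does not contain an InversionClassifier")
    model
}
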