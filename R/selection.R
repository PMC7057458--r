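#' @include AllClasses.R
NULL

#' Chi-square scores of count features against a binary label
#'
#' For each feature column j, the observed class totals are
#' \eqn{O_c = \sum_{i: y_i = c} X_{ij}} and the expected totals under
#' label independence are \eqn{E_c = p_c \sum_i X_{ij}}, with `p_c` the
#' class proportion; the score is
#' \eqn{x^2_j = \sum_c (O_c - E_c)^2 / E_c}. This is the standard
#' count-data chi-square used for scoring non-negative features against a
#' target: the larger the score, the stronger the association between the
#' feature and the inversion/wild-type label. A feature with zero total
#' sum scores 0.
#'
#' The score is invariant under row permutation and scales linearly with
#' a positive rescaling of a column.
#'
#' @param X numeric matrix of non-negative feature values (columns =
#'   features).
#' @param y binary labels (0/1), both classes present.
#' @return a named numeric vector of chi-square values (one per column;
#'   names from `colnames(X)` or `"1".."k"`).
#' @examples
#' X <- cbind(a = c(10, 0, 10, 0), b = c(10, 10, 0, 0))
#' chiSquareScores(X, c(1, 1, 0, 0))  # a: 0, b: 20
#' @export
chiSquareScores <- function(X, y) {
    X <- as.matrix(X)
    if (any(X < 0))
        stop("feature values must be non-negative")
    y <- as.integer(y)
    if (length(y) != nrow(X))
        stop("length(y) must equal nrow(X)")
    if (length(unique(y)) < 2L)
        stop("degenerate labels: both classes must be present")
    p1 <- mean(y == 1L)
    tot <- colSums(X)
    O1 <- colSums(X[y == 1L, , drop = FALSE])
    O0 <- tot - O1
    E1 <- p1 * tot
    E0 <- (1 - p1) * tot
    x2 <- ifelse(tot == 0, 0,
                 (O1 - E1)^2 / E1 + (O0 - E0)^2 / E0)
    names(x2) <- if (!is.null(colnames(X))) colnames(X) else
        as.character(seq_len(ncol(X)))
    x2
}

#' Select features by chi-square rank plus curated additions
#'
#' Keeps the `k` features with the highest chi-square scores (ties broken
#' by ascending feature ID for determinism) and unions in the curated IDs
#' that domain experience marks as informative regardless of rank — by
#' default 3 (read pairs with one end unmapped) and 9 (summed mapping
#' quality). The final set is returned in ascending ID order.
#'
#' @param scores numeric vector of chi-square values for feature IDs
#'   1..15 (order = ID).
#' @param k number of top-ranked features to keep (default 8).
#' @param curated integer IDs always included (default `c(3, 9)`).
#' @return a [SelectionResult-class].
#' @examples
#' sc <- numeric(15)
#' sc[c(2, 4, 6, 8, 11, 13, 14, 15)] <- 10:3
#' selectedIds(selectFeatures(sc))  # 2 3 4 6 8 9 11 13 14 15
#' @export
selectFeatures <- function(scores, k = 8L, curated = c(3L, 9L)) {
    n <- length(scores)
    if (k > n)
        stop("k cannot exceed the number of features (", n, ")")
    if (length(curated) && !all(curated %in% seq_len(n)))
        stop("curated IDs must lie in 1..", n)
    ranked <- order(-scores, seq_len(n))
    top <- ranked[seq_len(k)]
    sel <- sort(unique(c(top, as.integer(curated))))
    new("SelectionResult",
        chi2 = stats::setNames(as.numeric(scores),
                               as.character(seq_len(n))),
        rankedIds = as.integer(ranked), selectedIds = as.integer(sel),
        curatedIds = as.integer(sort(unique(curated))), k = as.integer(k))
}

#' The reference ten-feature set
#'
#' The feature IDs used by default when classifying candidates: the eight
#' top chi-square features plus the two curated additions.
#'
#' @return `c(2, 3, 4, 6, 8, 9, 11, 13, 14, 15)`.
#' @export
defaultFeatureIds <- function() c(2L, 3L, 4L, 6L, 8L, 9L, 11L, 13L, 14L, 15L)
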