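## Eigen-scaled correlation PCA.
##
## Columns are standardised to zero mean / unit variance, so the PCA is
## an eigendecomposition of the variable correlation matrix, computed
## through the sample-side Gram matrix (cheaper when variables outnumber
## samples, and exact): for standardised X = U D V',
##   eigenvalues  lambda_k = d_k^2 / (n - 1)
##   scores       U D                  (subject coordinates)
##   scaled loadings V sqrt(lambda) = X' U / sqrt(n - 1)
## i.e. each eigenvector is scaled by the square root of its eigenvalue,
## so the first component carries the largest scale and components
## shrink as their explained variability decreases.

.topEigen <- function(G, k) {
    out <- .Call(C_top_eigen, G, as.integer(k))
    out$values <- pmax(out$values, 0)
    out
}

#' Fit an eigen-scaled correlation PCA
#'
#' @param lbf an \linkS4class{LBFMatrix} or a plain samples-x-variables
#'   numeric matrix.
#' @param K number of components to retain (default 5).  If K exceeds the
#'   matrix rank it is reduced with a warning.
#' @param labels optional case/control labels; when given, each component
#'   is oriented so the case-mean score is >= the control-mean score
#'   (deterministic output).  Otherwise the largest-magnitude loading of
#'   each component is made positive.
#' @return a \linkS4class{PCAModel}.  Constant variables are excluded
#'   from the fit (recorded in the \code{dropped} slot) and carry zero
#'   loadings.
#' @export
fitScaledPCA <- function(lbf, K = 5L, labels = NULL) {
    X0 <- if (is(lbf, "LBFMatrix")) lbfValues(lbf, samplesAsRows = TRUE)
          else as.matrix(lbf)
    n <- nrow(X0); m <- ncol(X0)
    if (is.null(colnames(X0)))
        colnames(X0) <- paste0("V", seq_len(m))
    if (is.null(rownames(X0)))
        rownames(X0) <- paste0("S", seq_len(n))
    mu <- colMeans(X0)
    sd <- sqrt(colSums(X0^2) / n - mu^2) * sqrt(n / (n - 1))
    const <- sd <= 1e-12 * (abs(mu) + 1)
    inv <- ifelse(const, 0, 1 / sd)
    X <- (X0 - matrix(mu, n, m, byrow = TRUE)) *
        matrix(inv, n, m, byrow = TRUE)
    if (any(const))
        .msg("dropping ", sum(const), " constant variable(s) before PCA")
    rank <- min(n - 1L, sum(!const))
    if (K > rank) {
        warning("K = ", K, " exceeds the matrix rank; reduced to ", rank)
        K <- rank
    }
    if (K < 1) stop("n_samples must be at least K + 1")
    G <- tcrossprod(X)
    eig <- .topEigen(G, K)
    d <- sqrt(eig$values)
    U <- eig$vectors
    eigenvalues <- eig$values / (n - 1)
    scores <- U * matrix(d, n, K, byrow = TRUE)
    loadings <- crossprod(X, U) / sqrt(n - 1)
    loadings[const, ] <- 0
    ## deterministic per-component sign
    for (k in seq_len(K)) {
        flip <- if (!is.null(labels)) {
            cs <- mean(scores[labels == "case", k]) -
                  mean(scores[labels == "control", k])
            cs < 0
        } else {
            loadings[which.max(abs(loadings[, k])), k] < 0
        }
        if (isTRUE(flip)) {
            scores[, k] <- -scores[, k]
            U[, k] <- -U[, k]
            loadings[, k] <- -loadings[, k]
        }
    }
    dimnames(scores) <- list(rownames(X0), paste0("PC", seq_len(K)))
    dimnames(loadings) <- list(colnames(X0), paste0("PC", seq_len(K)))
    new("PCAModel", scores = scores, loadings = loadings,
        eigenvalues = eigenvalues, center = stats::setNames(mu, colnames(X0)),
        scale = stats::setNames(sd, colnames(X0)),
        dropped = colnames(X0)[const])
}

#' Observed case/control direction in component space
#'
#' The difference of class-mean score vectors over the retained
#' components, normalised to unit length and oriented so that cases
#' project positively.
#'
#' @param model a \linkS4class{PCAModel}.
#' @param labels case/control label per sample (aligned with the scores).
#' @return unit-length numeric vector of length K with attribute
#'   \code{"separation"} (the unnormalised class-mean distance).
#' @export
caseControlDirection <- function(model, labels) {
    stopifnot(is(model, "PCAModel"))
    s <- model@scores
    if (length(labels) != nrow(s))
        stop("labels must align with the score rows")
    caseM <- colMeans(s[labels == "case", , drop = FALSE])
    ctrlM <- colMeans(s[labels == "control", , drop = FALSE])
    d <- caseM - ctrlM
    nrm <- sqrt(sum(d^2))
    if (nrm < 1e-12 * (max(abs(s)) + 1))
        stop("no case/control separation: identical class means")
    w <- d / nrm
    attr(w, "separation") <- nrm
    w
}

#' Project variable loadings onto the case/control direction
#'
#' Scalar per variable: the dot product of its K-dimensional
#' eigen-scaled loading vector with the unit case/control direction.
#' Variables orthogonal to the direction contribute 0; risk variables
#' project positively by the direction's orientation.
#'
#' @param model a \linkS4class{PCAModel}.
#' @param direction unit vector from \code{\link{caseControlDirection}}.
#' @return named numeric vector, one value per variable.
#' @export
projectedLoadings <- function(model, direction) {
    stopifnot(is(model, "PCAModel"))
    if (length(direction) != ncol(model@loadings))
        stop("direction length must equal the number of components")
    p <- as.vector(model@loadings %*% as.numeric(direction))
    names(p) <- rownames(model@loadings)
    p
}

#' Project new samples into a fitted component space
#'
#' Supplementary projection: rows are standardised with the training
#' means/SDs and multiplied by the training eigenvectors, so appended
#' samples cannot alter the fit (used for the "unknown subjects" of the
#' reference-panel co-analysis).
#'
#' @param model a \linkS4class{PCAModel}.
#' @param lbf an \linkS4class{LBFMatrix} or samples-x-variables matrix
#'   over the same variables the model was fitted on.
#' @return score matrix (samples x K).
#' @export
projectSamples <- function(model, lbf) {
    stopifnot(is(model, "PCAModel"))
    X0 <- if (is(lbf, "LBFMatrix")) lbfValues(lbf, samplesAsRows = TRUE)
          else as.matrix(lbf)
    if (ncol(X0) != nrow(model@loadings))
        stop("variable count disagrees with the fitted model")
    n <- nrow(X0); m <- ncol(X0)
    inv <- ifelse(model@scale <= 0, 0, 1 / model@scale)
    X <- (X0 - matrix(model@center, n, m, byrow = TRUE)) *
        matrix(inv, n, m, byrow = TRUE)
    lam <- model@eigenvalues
    V <- model@loadings * matrix(ifelse(lam > 0, 1 / sqrt(lam), 0),
                                 m, length(lam), byrow = TRUE)
    sc <- X %*% V
    dimnames(sc) <- list(rownames(X0), colnames(model@scores))
    sc
}

#' Scree-based automatic component count
#'
#' Retains the components whose eigenvalue exceeds the mean eigenvalue
#' of the full spectrum (Kaiser-style rule on the correlation scale,
#' where the mean eigenvalue is 1 in expectation), as an automatic
#' alternative to visual scree inspection.
#'
#' @param lbf an \linkS4class{LBFMatrix} or samples-x-variables matrix.
#' @param maxK cap on the returned count (default 20).
#' @return integer component count (at least 1).
#' @export
chooseK <- function(lbf, maxK = 20L) {
    X0 <- if (is(lbf, "LBFMatrix")) lbfValues(lbf, samplesAsRows = TRUE)
          else as.matrix(lbf)
    n <- nrow(X0); m <- ncol(X0)
    mu <- colMeans(X0)
    sd <- sqrt(colSums(X0^2) / n - mu^2) * sqrt(n / (n - 1))
    keep <- sd > 1e-12 * (abs(mu) + 1)
    X <- (X0[, keep, drop = FALSE] -
          matrix(mu[keep], n, sum(keep), byrow = TRUE)) *
        matrix(1 / sd[keep], n, sum(keep), byrow = TRUE)
    ev <- pmax(eigen(tcrossprod(X), symmetric = TRUE,
                     only.values = TRUE)$values, 0) / (n - 1)
    meanEv <- sum(ev) / sum(keep)
    max(1L, min(as.integer(maxK), sum(ev > meanEv)))
}
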