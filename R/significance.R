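## Permutation significance.
##
## The null distribution of projected loadings is obtained by shuffling
## case/control labels and re-running the FULL pipeline per permutation:
## model re-estimation, LBF transform, PCA refit, case/control direction,
## projection.  Per-variable p-values are parametric upper-tail
## probabilities of a 1-3 component Gaussian mixture fitted to each
## variable's permuted projected loadings (BIC-selected), giving p-value
## resolution well below 1/n_perm.

## one full pipeline pass for a given 0/1 case vector; returns the
## m-vector of projected loadings
.pipelineProjected <- function(prep, caseVec, ctrlVec, cntLabTot, K, pc) {
    cntCase <- .lbfCountClass(prep, caseVec)
    mod <- .lbfModel(prep, cntCase, cntLabTot, pc)
    L <- .lbfL(mod)
    std <- .lbfStandardized(prep, L)
    X <- std$X
    n <- prep$n
    Keff <- min(K, n - 1L, sum(!std$constant))
    G <- tcrossprod(X)
    eig <- .topEigen(G, Keff)
    d <- sqrt(eig$values)
    U <- eig$vectors
    scores <- U * matrix(d, n, Keff, byrow = TRUE)
    n1 <- sum(caseVec); n0 <- sum(ctrlVec)
    dirRaw <- as.vector(crossprod(scores, caseVec)) / n1 -
        as.vector(crossprod(scores, ctrlVec)) / n0
    nrm <- sqrt(sum(dirRaw^2))
    if (nrm == 0) return(numeric(prep$m))
    w <- dirRaw / nrm
    as.vector(crossprod(X, U %*% w)) / sqrt(n - 1)
}

#' Permutation null of projected loadings
#'
#' For each permutation the case/control labels are shuffled and the
#' complete analysis is re-run: class models re-estimated, LBFs
#' recomputed, PCA refitted, the case/control direction recomputed, and
#' all variable loadings projected onto it.
#'
#' @param dataset a \linkS4class{GenotypeDataset} (post-QC).
#' @param K retained components (default 5).
#' @param nPerm number of permutations (the reference analysis setting is
#'   10,000; at least 100 for any inferential use).
#' @param seed integer seed (one deterministic stream per stage).
#' @param pseudocount LBF smoothing constant.
#' @param labels case/control labels (defaults to the dataset phenotype).
#' @return numeric matrix nPerm x n_variables with variant-id columns.
#' @export
permutationNull <- function(dataset, K = 5L, nPerm = 10000L,
                            seed = 1L, pseudocount = 0.5,
                            labels = phenotype(dataset)) {
    stopifnot(is(dataset, "GenotypeDataset"))
    if (nPerm < 1) stop("nPerm must be >= 1")
    if (nPerm < 100)
        warning("fewer than 100 permutations is below any inferential use")
    prep <- .lbfPrep(dataset)
    isCase <- labels == "case" & !is.na(labels)
    isCtrl <- labels == "control" & !is.na(labels)
    if (!sum(isCase) || !sum(isCtrl))
        stop("both classes must be non-empty")
    lab <- which(isCase | isCtrl)
    nCase <- sum(isCase)
    cntLabTot <- .lbfCountClass(prep, as.numeric(isCase | isCtrl))
    null <- matrix(NA_real_, nPerm, prep$m,
                   dimnames = list(NULL, prep$variantIds))
    set.seed(deriveSeed(seed, "permutation"))
    n <- prep$n
    for (b in seq_len(nPerm)) {
        permCase <- sample(lab, nCase)
        cv <- numeric(n); cv[permCase] <- 1
        ctrl <- numeric(n); ctrl[setdiff(lab, permCase)] <- 1
        null[b, ] <- .pipelineProjected(prep, cv, ctrl, cntLabTot,
                                        K, pseudocount)
    }
    null
}

## ---- 1-D Gaussian mixtures, vectorised across variables ----------------

## fit a G-component mixture to every column of Y (R x m); deterministic
## quantile initialisation, EM with a variance floor; returns parameter
## matrices (G x m) and the per-column log-likelihood
## maxIter caps the EM where the likelihood ridge is nearly flat
## (overparameterised fits on effectively one-component data); early
## stopping there only lowers the multi-component log-likelihood, so
## BIC selection errs toward fewer components
.gmmFitG <- function(Y, G, maxIter = 60L, tol = 1e-8) {
    R <- nrow(Y); m <- ncol(Y)
    muAll <- colMeans(Y)
    sdAll <- sqrt(pmax(colMeans(Y^2) - muAll^2, 0))      # MLE scale
    floorSd <- pmax(sdAll * 1e-4, 1e-300)
    if (G == 1L) {
        ## closed-form maximum likelihood: no EM needed
        sg1 <- pmax(sdAll, floorSd)
        ll <- -R / 2 * log(2 * pi) - R * log(sg1) - R / 2
        return(list(w = matrix(1, 1, m), mu = matrix(muAll, 1, m),
                    sigma = matrix(sg1, 1, m), loglik = ll))
    }
    Ys <- apply(Y, 2L, sort)
    bounds <- round(seq(0, R, length.out = G + 1))
    mu <- matrix(0, G, m); sg <- matrix(0, G, m); w <- matrix(1 / G, G, m)
    for (g in seq_len(G)) {
        blk <- Ys[(bounds[g] + 1):bounds[g + 1], , drop = FALSE]
        mu[g, ] <- colMeans(blk)
        sg[g, ] <- pmax(sqrt(pmax(colMeans(blk^2) - colMeans(blk)^2, 0)),
                        floorSd)
    }
    ll <- rep(-Inf, m)
    act <- seq_len(m)          # columns whose EM has not converged yet
    for (it in seq_len(maxIter)) {
        a <- length(act)
        Ya <- Y[, act, drop = FALSE]
        dens <- vector("list", G)
        tot <- matrix(0, R, a)
        for (g in seq_len(G)) {
            dens[[g]] <- matrix(w[g, act], R, a, byrow = TRUE) *
                stats::dnorm(Ya, matrix(mu[g, act], R, a, byrow = TRUE),
                             matrix(sg[g, act], R, a, byrow = TRUE))
            tot <- tot + dens[[g]]
        }
        tot[tot < 1e-300] <- 1e-300
        llNew <- colSums(log(tot))
        for (g in seq_len(G)) {
            r <- dens[[g]] / tot
            Ng <- colSums(r)
            Ng[Ng < 1e-12] <- 1e-12
            w[g, act] <- Ng / R
            mug <- colSums(r * Ya) / Ng
            mu[g, act] <- mug
            v <- colSums(r * (Ya - matrix(mug, R, a, byrow = TRUE))^2) / Ng
            sg[g, act] <- pmax(sqrt(v), floorSd[act])
        }
        conv <- llNew - ll[act] <= tol * (abs(llNew) + 1)
        ll[act] <- llNew
        act <- act[!conv]
        if (!length(act)) break
    }
    list(w = w, mu = mu, sigma = sg, loglik = ll)
}

#' Fit BIC-selected Gaussian mixtures to permutation nulls
#'
#' For every variable, 1- to 3-component Gaussian mixtures are fitted to
#' its permuted projected loadings and the component count is selected by
#' BIC (ties favour fewer components).
#'
#' @param null matrix nPerm x n_variables from
#'   \code{\link{permutationNull}}.
#' @param maxComponents maximum mixture size (default 3).
#' @return list with per-variable parameter matrices \code{w}, \code{mu},
#'   \code{sigma} (maxComponents x m, zero-weight rows unused), selected
#'   component counts \code{G}, and \code{loglik}/\code{bic} per size.
#' @export
gmmFitNull <- function(null, maxComponents = 3L) {
    R <- nrow(null); m <- ncol(null)
    if (R < 100)
        warning("fewer than 100 null values per variable")
    fits <- lapply(seq_len(maxComponents), function(G) .gmmFitG(null, G))
    bic <- vapply(seq_len(maxComponents), function(G)
        2 * fits[[G]]$loglik - (3 * G - 1) * log(R), numeric(m))
    bic <- matrix(bic, nrow = m)
    best <- apply(bic, 1L, function(b) which(b >= max(b) - 1e-9)[1])
    w <- mu <- sg <- matrix(0, maxComponents, m)
    for (G in seq_len(maxComponents)) {
        j <- which(best == G)
        if (!length(j)) next
        w[seq_len(G), j] <- fits[[G]]$w[, j]
        mu[seq_len(G), j] <- fits[[G]]$mu[, j]
        sg[seq_len(G), j] <- fits[[G]]$sigma[, j]
    }
    list(w = w, mu = mu, sigma = sg, G = best,
         bic = bic, variantIds = colnames(null))
}

#' Gaussian-mixture tail p-values for observed projected loadings
#'
#' One-sided upper-tail probability of each variable's fitted null
#' mixture beyond its observed projected loading (the case-positive
#' orientation); optionally two-sided.  p-values are floored at the
#' smallest representable positive double.  A degenerate
#' (zero-variance) null yields p = 1 when the observation equals the
#' constant and the floor value otherwise, with a warning.
#'
#' @param observed named numeric vector of observed projected loadings.
#' @param null permutation matrix from \code{\link{permutationNull}}, or
#'   a fitted mixture from \code{\link{gmmFitNull}}.
#' @param twoSided use a two-sided tail (default FALSE).
#' @return data.frame with columns \code{variant_id},
#'   \code{projected_loading}, \code{p_value}, \code{gmm_g}; the full
#'   mixture parameters are attached as attribute \code{"gmm"}.
#' @export
gmmPValues <- function(observed, null, twoSided = FALSE) {
    fit <- if (is.matrix(null)) gmmFitNull(null) else null
    m <- length(fit$G)
    if (length(observed) != m)
        stop("observed and null cover different variable counts")
    degenerate <- colSums(fit$w * fit$sigma) <= 1e-300
    p <- numeric(m)
    for (g in seq_len(nrow(fit$w))) {
        act <- fit$w[g, ] > 0
        z <- (observed - fit$mu[g, ]) / pmax(fit$sigma[g, ], 1e-300)
        p <- p + ifelse(act, fit$w[g, ] * stats::pnorm(z, lower.tail = FALSE), 0)
    }
    if (twoSided) p <- 2 * pmin(p, 1 - p)
    if (any(degenerate)) {
        const <- fit$mu[1, ]
        pd <- ifelse(abs(observed - const) <= 1e-12 * (abs(const) + 1),
                     1, .Machine$double.xmin)
        p[degenerate] <- pd[degenerate]
        warning(sum(degenerate), " variable(s) had a degenerate ",
                "(zero-variance) permutation null")
    }
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    out <- data.frame(variant_id = if (!is.null(fit$variantIds))
                          fit$variantIds else names(observed),
                      projected_loading = as.numeric(observed),
                      p_value = p, gmm_g = fit$G,
                      stringsAsFactors = FALSE)
    attr(out, "gmm") <- fit
    out
}

#' Sidak family-wise threshold
#'
#' Per-test p-value threshold \code{1 - (1 - alpha)^(1/m)} controlling
#' the family-wise error rate over the exact number of tests carried out.
#'
#' @param alpha family-wise error level in (0, 1).
#' @param m number of tests (>= 1).
#' @return the per-test p-value threshold.
#' @examples
#' sidakThreshold(0.05, 1)  # = 0.05
#' sidakThreshold(0.05, 2)  # = 1 - sqrt(0.95)
#' @export
sidakThreshold <- function(alpha, m) {
    stopifnot(alpha > 0, alpha < 1, m >= 1)
    -expm1(log1p(-alpha) / m)
}

#' Benjamini-Hochberg selection
#'
#' Standard FDR step-up procedure at level \code{alpha}.
#'
#' @param pvalues numeric vector in (0, 1].
#' @param alpha FDR level.
#' @return logical pass flags.
#' @export
bhSelect <- function(pvalues, alpha = 0.05) {
    stats::p.adjust(pvalues, method = "BH") <= alpha
}

#' Full case/control analysis of a cohort
#'
#' Runs the complete pipeline on a (QC'd) dataset: LBF transform with
#' models estimated from the observed labels, eigen-scaled correlation
#' PCA, projection of variable loadings onto the case/control direction,
#' label-permutation null, Gaussian-mixture p-values, and Sidak/BH flags
#' (Sidak over the exact number of non-constant variables tested).
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param config a \code{\link{runConfig}} list.
#' @param nPerm,K,seed optional overrides of the config fields.
#' @param verbose print progress messages.
#' @return list with elements \code{lbf} (\linkS4class{LBFMatrix}),
#'   \code{pca} (\linkS4class{PCAModel}), \code{direction},
#'   \code{null} (permutation matrix), \code{table} (the significance
#'   table: variant_id, chrom, pos, projected_loading, p_value, gmm_g,
#'   sidak_pass, bh_pass), \code{sidak_threshold}, and \code{m_tests}.
#' @export
analyzeCohort <- function(dataset, config = runConfig(),
                          nPerm = config$n_permutations,
                          K = config$n_components,
                          seed = config$seed, verbose = FALSE) {
    stopifnot(is(dataset, "GenotypeDataset"))
    labels <- phenotype(dataset)
    .msg("estimating LBF models and transform", verbose = verbose)
    model <- estimateModels(dataset, labels,
                            pseudocount = config$pseudocount)
    lbf <- lbfTransform(dataset, model)
    pca <- fitScaledPCA(lbf, K = K, labels = labels)
    dir <- caseControlDirection(pca, labels)
    obs <- projectedLoadings(pca, dir)
    .msg("running ", nPerm, " label permutations", verbose = verbose)
    null <- permutationNull(dataset, K = K, nPerm = nPerm, seed = seed,
                            pseudocount = config$pseudocount,
                            labels = labels)
    .msg("fitting Gaussian mixtures to the permutation null",
         verbose = verbose)
    tab <- gmmPValues(obs, null, twoSided = isTRUE(config$two_sided))
    tested <- !names(obs) %in% pca@dropped
    mTests <- sum(tested)
    thr <- sidakThreshold(config$fwer_alpha, mTests)
    tab$sidak_pass <- tested & tab$p_value <= thr
    tab$bh_pass <- FALSE
    tab$bh_pass[tested] <- bhSelect(tab$p_value[tested], config$fwer_alpha)
    rd <- as.data.frame(rowData(dataset))
    ord <- match(tab$variant_id, rd$variant_id)
    tab <- cbind(tab[, "variant_id", drop = FALSE],
                 chrom = rd$chrom[ord], pos = rd$pos[ord],
                 tab[, setdiff(colnames(tab), "variant_id")])
    list(lbf = lbf, pca = pca, direction = dir, null = null,
         table = tab, sidak_threshold = thr, m_tests = mTests)
}

#' Export biplot and Manhattan tables
#'
#' Writes two deterministic TSVs: a biplot table holding subject scores,
#' eigen-scaled variable coordinates and the case/control dummy arrow
#' (one row per sample, per variable, plus one dummy row), and a
#' Manhattan table of -log10 p per variant sorted by (chrom, pos).
#'
#' @param result the list returned by \code{\link{analyzeCohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
exportPlots <- function(result, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pca <- result$pca
    sc <- pca@scores; ld <- pca@loadings
    w <- as.numeric(result$direction)
    dummy <- w * sqrt(pca@eigenvalues)
    bi <- rbind(
        data.frame(id = rownames(sc), type = "sample",
                   x = sc[, 1], y = sc[, 2], stringsAsFactors = FALSE),
        data.frame(id = rownames(ld), type = "variable",
                   x = ld[, 1], y = ld[, 2], stringsAsFactors = FALSE),
        data.frame(id = "case_control_dummy", type = "dummy",
                   x = dummy[1], y = dummy[2], stringsAsFactors = FALSE))
    rownames(bi) <- NULL
    bpPath <- file.path(dir, "biplot.tsv")
    writeTable(bi, bpPath)
    tab <- result$table
    man <- data.frame(variant_id = tab$variant_id, chrom = tab$chrom,
                      pos = tab$pos, p_value = tab$p_value,
                      neg_log10_p = -log10(tab$p_value),
                      stringsAsFactors = FALSE)
    man <- man[order(man$chrom, man$pos, man$variant_id), ]
    rownames(man) <- NULL
    mhPath <- file.path(dir, "manhattan.tsv")
    writeTable(man, mhPath)
    invisible(c(bpPath, mhPath))
}
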