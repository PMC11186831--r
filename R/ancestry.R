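## Genetic ancestry homogenisation: study subjects are co-analysed with
## labelled reference panels in the LBF-PCA space (reference vs contrast
## populations define the models; study subjects are projected
## passively), an ancestrally homogeneous subject set is selected by a
## Mahalanobis ellipse around the k-means centre of the reference
## cluster, and the cohort is sex-balanced to a case/control sex odds
## ratio of 1.

.bindSamples <- function(datasets, sharedIds) {
    mats <- lapply(datasets, function(d) {
        g <- genotypes(d)
        g[match(sharedIds, rownames(g)), , drop = FALSE]
    })
    do.call(cbind, mats)
}

#' Co-analyse study subjects with labelled reference panels
#'
#' Variants shared by every dataset, non-monomorphic and with a total
#' missing rate below \code{missingMax} across all datasets, are
#' analysed.  LBF models are estimated from the reference-vs-contrast
#' labels only; all subjects (including the unknowns) are transformed
#' and scored in the same component space, so the study subjects cannot
#' distort the contrast.
#'
#' @param reference reference-population panel
#'   (\linkS4class{GenotypeDataset}); its cluster defines the target
#'   ancestry.
#' @param contrast one panel or a list of panels providing the opposing
#'   populations.
#' @param unknowns the study subjects to be positioned.
#' @param K retained components (default 2 for a one-contrast analysis;
#'   use more for multi-population panels).
#' @param pseudocount LBF smoothing constant.
#' @param missingMax maximum combined missing rate per variant.
#' @return list: \code{scores} (all subjects x K), \code{roles}
#'   (\code{"reference"}, \code{"contrast"}, \code{"unknown"} per row),
#'   \code{pca}, \code{model}, \code{variants} (shared ids used).
#' @export
coanalyze <- function(reference, contrast, unknowns, K = 2L,
                      pseudocount = 0.5, missingMax = 0.05) {
    if (is(contrast, "GenotypeDataset")) contrast <- list(contrast)
    panels <- c(list(reference), contrast, list(unknowns))
    shared <- Reduce(intersect, lapply(panels, variantIds))
    if (length(shared) == 0)
        stop("no variants shared by all datasets")
    if (length(shared) < 1000)
        warning("only ", length(shared),
                " variants shared by all datasets")
    g <- .bindSamples(panels, shared)
    obsRate <- rowMeans(is.na(g))
    altCount <- rowSums(g, na.rm = TRUE)
    nObs <- rowSums(!is.na(g))
    mono <- nObs == 0 | altCount == 0 | altCount == 2 * nObs
    keep <- shared[!mono & obsRate < missingMax]
    if (length(keep) == 0)
        stop("no shared variants survive the monomorphic/missingness filter")

    nRef <- ncol(reference)
    nCon <- sum(vapply(contrast, ncol, integer(1)))
    labelled <- c(list(reference), contrast)
    lm <- lapply(labelled, function(d) subsetDataset(d, variants = keep))
    ## one labelled dataset: reference scored as "case" (positive side)
    gl <- .bindSamples(lm, keep)
    cdl <- do.call(rbind, lapply(lm, function(d)
        as.data.frame(colData(d))[, c("sample_id", "sex_reported")]))
    cdl$phenotype <- rep(c("case", "control"), c(nRef, nCon))
    rdl <- as.data.frame(rowData(lm[[1]]))
    train <- GenotypeDataset(gl, rdl, cdl)
    model <- estimateModels(train, pseudocount = pseudocount)
    lbfTrain <- lbfTransform(train, model)
    pca <- fitScaledPCA(lbfTrain, K = K, labels = phenotype(train))

    unk <- subsetDataset(unknowns, variants = keep)
    lbfUnk <- lbfTransform(unk, model)
    scUnk <- projectSamples(pca, lbfUnk)
    scores <- rbind(pca@scores, scUnk)
    roles <- rep(c("reference", "contrast", "unknown"),
                 c(nRef, nCon, ncol(unknowns)))
    list(scores = scores, roles = roles, pca = pca, model = model,
         variants = keep)
}

#' Select an ancestrally homogeneous subject set
#'
#' k-means clustering of the reference subjects' scores determines the
#' cluster centres; around the chosen centre (the largest reference
#' cluster), the covariance of its reference members defines a
#' Mahalanobis ellipse.  A subject is kept iff its squared Mahalanobis
#' distance is at most the chi-square quantile at \code{1 - alpha}
#' (df = K): the alpha tail of the reference distribution is excluded.
#'
#' @param scores subject score matrix (all subjects x K, row names =
#'   subject ids).
#' @param referenceMask logical vector marking the reference rows.
#' @param alpha excluded tail percentile (default 0.2).
#' @param k number of k-means clusters for the reference (default 1).
#' @param seed seed for the k-means restarts.
#' @return an \linkS4class{AncestrySelection}.
#' @export
selectHomogeneous <- function(scores, referenceMask, alpha = 0.2,
                              k = 1L, seed = 1L) {
    scores <- as.matrix(scores)
    if (is.null(rownames(scores)))
        rownames(scores) <- paste0("S", seq_len(nrow(scores)))
    ref <- scores[referenceMask, , drop = FALSE]
    if (nrow(ref) < 10 * k)
        stop("at least 10 reference subjects per cluster are required")
    if (k == 1L) {
        centre <- colMeans(ref)
        members <- rep(TRUE, nrow(ref))
    } else {
        set.seed(deriveSeed(seed, "ancestry-kmeans"))
        km <- stats::kmeans(ref, centers = k, nstart = 10)
        main <- which.max(tabulate(km$cluster, k))
        centre <- km$centers[main, ]
        members <- km$cluster == main
    }
    S <- stats::cov(ref[members, , drop = FALSE])
    d2 <- tryCatch(stats::mahalanobis(scores, centre, S),
                   error = function(e) NULL)
    if (is.null(d2)) {
        warning("singular reference covariance; applying a ridge")
        S <- S + diag(1e-6 * sum(diag(S)), ncol(S))
        d2 <- stats::mahalanobis(scores, centre, S)
    }
    thr <- stats::qchisq(1 - alpha, df = ncol(scores))
    kept <- rownames(scores)[d2 <= thr]
    new("AncestrySelection", scores = scores, center = centre,
        covariance = S, alpha = alpha, threshold = thr,
        mahalanobisSq = stats::setNames(d2, rownames(scores)),
        kept = kept, excluded = setdiff(rownames(scores), kept))
}

#' Balance the cohort to a case/control sex odds ratio of 1
#'
#' Randomly subsamples one stratum of the more sex-imbalanced class
#' (ties favour reducing cases, matching the convention that only the
#' case cohort shrinks) until the case/control sex odds ratio is 1, to
#' the nearest achievable integer composition.  Only one class is
#' reduced.  Samples of unknown sex are left untouched.
#'
#' @param samples data.frame with columns \code{sample_id},
#'   \code{sex_reported}, \code{phenotype}, or a
#'   \linkS4class{GenotypeDataset}.
#' @param seed integer seed (subsampling is deterministic under it).
#' @return an object of the same kind as \code{samples}, reduced.
#' @export
balanceSex <- function(samples, seed = 1L) {
    dataset <- NULL
    if (is(samples, "GenotypeDataset")) {
        dataset <- samples
        samples <- as.data.frame(colData(samples))
    }
    sex <- samples$sex_reported
    ph <- samples$phenotype
    cnt <- function(p, s) sum(ph == p & sex == s, na.rm = TRUE)
    caM <- cnt("case", "male"); caF <- cnt("case", "female")
    coM <- cnt("control", "male"); coF <- cnt("control", "female")
    if (min(caM, caF, coM, coF) == 0)
        stop("both sexes must be present in both classes")
    orNow <- (caM / caF) / (coM / coF)
    removed <- character(0)
    if (abs(log(orNow)) > 1e-12) {
        imbCase <- abs(log(caM / caF))
        imbCtrl <- abs(log(coM / coF))
        reduceClass <- if (imbCase >= imbCtrl) "case" else "control"
        if (reduceClass == "case") {
            tgt <- coM / coF; M <- caM; F <- caF
        } else {
            tgt <- caM / caF; M <- coM; F <- coF
        }
        ## reduce the over-represented stratum of that class
        if (M / F > tgt) {
            cand <- seq_len(M)
            dev <- abs(log((cand / F) / tgt))
            mNew <- max(cand[dev == min(dev)])
            stratum <- "male"; keepN <- mNew
        } else {
            cand <- seq_len(F)
            dev <- abs(log((M / cand) / tgt))
            fNew <- max(cand[dev == min(dev)])
            stratum <- "female"; keepN <- fNew
        }
        if (min(dev) > 1e-12)
            warning("a sex odds ratio of exactly 1 is not achievable; ",
                    "using the closest integer composition")
        pool <- samples$sample_id[ph == reduceClass & sex == stratum &
                                  !is.na(ph)]
        set.seed(deriveSeed(seed, "balance-sex"))
        removed <- sample(pool, length(pool) - keepN)
    }
    keepIds <- setdiff(samples$sample_id, removed)
    if (!is.null(dataset))
        return(subsetDataset(dataset, samples = keepIds))
    samples[samples$sample_id %in% keepIds, , drop = FALSE]
}
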