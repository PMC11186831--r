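## Log-Bayes-factor transform.
##
## Each variable is modelled per class (case/control) by smoothed
## category frequencies; each observed category is replaced by
## ln P(category | case model) - ln P(category | control model).
## X-linked SNPs are modelled per sex stratum (3 genotype levels in
## females, 2 hemizygous levels in males); categorical variables carry k
## levels.  Missing cells contribute LBF 0 (no evidence).
##
## Internally every (sample, variable) cell maps to a "value slot":
##   1..maxK        category codes 0..k-1, autosomal / female stratum
##   maxK+1, maxK+2 male X codes 0 and 2
##   S = maxK+3     missing (also invalid cells: male X heterozygote,
##                  unknown-sex sample at an X variant)
## so the transform is one table lookup, and per-permutation model
## refitting reduces to a handful of indicator crossproducts.

.lbfPrep <- function(dataset) {
    g <- genotypes(dataset)              # variants x samples
    codes <- t(g)                        # samples x variants
    n <- nrow(codes); m <- ncol(codes)
    rd <- as.data.frame(rowData(dataset))
    xcol <- isXLinked(dataset)
    isCat <- rd$is_categorical
    kvec <- ifelse(isCat, rd$n_categories, 3L)
    maxK <- max(3L, kvec)
    S <- maxK + 3L
    sex <- reportedSex(dataset)
    male <- sex == "male"
    unknownSex <- sex == "unknown"

    slot <- codes + 1L
    slot[is.na(slot)] <- S
    if (any(xcol)) {
        xc <- which(xcol)
        sub <- slot[, xc, drop = FALSE]
        cm <- codes[, xc, drop = FALSE]
        maleRows <- matrix(male, n, length(xc))
        sub[maleRows & !is.na(cm) & cm == 0L] <- maxK + 1L
        sub[maleRows & !is.na(cm) & cm == 2L] <- maxK + 2L
        sub[maleRows & !is.na(cm) & cm == 1L] <- S
        sub[matrix(unknownSex, n, length(xc))] <- S
        slot[, xc] <- sub
    }
    idx <- as.integer(slot + S * rep(0:(m - 1L), each = n))

    E <- lapply(1:3, function(r) {
        e <- as.double(slot == r)
        dim(e) <- c(n, m)
        e
    })
    EX <- NULL
    if (any(xcol)) {
        xc <- which(xcol)
        slx <- slot[, xc, drop = FALSE]
        EX <- lapply(1:2, function(r) {
            e <- as.double(slx == maxK + r)
            dim(e) <- dim(slx)
            e
        })
    }
    highCat <- which(isCat & kvec > 3L)

    prep <- list(n = n, m = m, S = S, maxK = maxK, idx = idx,
                 slot = slot, E = E, EX = EX,
                 xCols = which(xcol), autoCols = which(!xcol & !isCat),
                 catCols = which(isCat), highCat = highCat,
                 kvec = kvec,
                 variantIds = rd$variant_id,
                 sampleIds = colnames(g))
    prep$totAll <- .lbfCountClass(prep, rep(1, n))
    prep
}

## class-conditional slot counts: S x m, w is a 0/1 sample weight vector
.lbfCountClass <- function(prep, w) {
    cnt <- matrix(0, prep$S, prep$m)
    for (r in 1:3)
        cnt[r, ] <- as.vector(crossprod(prep$E[[r]], w))
    if (length(prep$xCols))
        for (r in 1:2)
            cnt[prep$maxK + r, prep$xCols] <-
                as.vector(crossprod(prep$EX[[r]], w))
    for (j in prep$highCat) {
        k <- prep$kvec[j]
        sl <- prep$slot[, j]
        sel <- w > 0 & sl >= 4L & sl <= k
        if (any(sel))
            cnt[4:k, j] <- tabulate(sl[sel] - 3L, nbins = k - 3L)
    }
    cnt
}

## smoothed per-class probabilities for one row-block/column-set
.blockProb <- function(cnt, tot, rows, cols, k, pc) {
    cc <- cnt[rows, cols, drop = FALSE]
    obs <- colSums(cc)
    p <- sweep(cc + pc, 2L, obs + k * pc, "/")
    fallback <- obs == 0
    if (any(fallback)) {
        tt <- tot[rows, cols, drop = FALSE][, fallback, drop = FALSE]
        p[, fallback] <- sweep(tt + pc, 2L, colSums(tt) + k * pc, "/")
    }
    list(p = p, fallback = fallback)
}

## full model: case/control probability tables (S x m) from case counts
.lbfModel <- function(prep, cntCase, cntLabTot, pc) {
    cntCtrl <- cntLabTot - cntCase
    S <- prep$S; m <- prep$m; maxK <- prep$maxK
    pcase <- matrix(NA_real_, S, m)
    pctrl <- matrix(NA_real_, S, m)
    fb <- logical(m)
    fill <- function(rows, cols, k) {
        if (!length(cols)) return()
        a <- .blockProb(cntCase, cntLabTot, rows, cols, k, pc)
        b <- .blockProb(cntCtrl, cntLabTot, rows, cols, k, pc)
        pcase[rows, cols] <<- a$p
        pctrl[rows, cols] <<- b$p
        fb[cols[a$fallback | b$fallback]] <<- TRUE
    }
    fill(1:3, c(prep$autoCols, prep$xCols), 3L)
    fill(maxK + 1:2, prep$xCols, 2L)
    for (k in unique(prep$kvec[prep$catCols]))
        fill(seq_len(k), prep$catCols[prep$kvec[prep$catCols] == k], k)
    list(pcase = pcase, pctrl = pctrl, fallback = fb)
}

## per-slot LBF values (missing slot and unused slots are 0)
.lbfL <- function(model) {
    L <- log(model$pcase) - log(model$pctrl)
    L[is.na(L)] <- 0
    L
}

## standardised sample x variable matrix from per-slot values; exact
## column moments come from the total slot counts, not a data pass
.lbfStandardized <- function(prep, L) {
    n <- prep$n
    mu <- colSums(prep$totAll * L) / n
    m2 <- colSums(prep$totAll * L * L) / n
    v <- (m2 - mu^2) * n / (n - 1)
    sd <- sqrt(pmax(v, 0))
    const <- sd <= 1e-12 * (abs(mu) + 1)
    inv <- ifelse(const, 0, 1 / sd)
    V <- (L - matrix(mu, prep$S, prep$m, byrow = TRUE)) *
        matrix(inv, prep$S, prep$m, byrow = TRUE)
    V[, const] <- 0
    X <- .Call(C_slot_gather, V, prep$idx, n)
    list(X = X, constant = const, center = mu, scale = sd)
}

#' Estimate per-class genotype models
#'
#' Category probabilities are \code{(count + pseudocount) /
#' (class total + k * pseudocount)} per class, computed from observed
#' (non-missing) genotypes; X-linked variables are estimated separately
#' per sex stratum.  A class with zero observations for a variable falls
#' back to the pooled distribution (with a warning naming the variables).
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param labels phenotype per sample (\code{"case"}/\code{"control"});
#'   defaults to the dataset's phenotype column.
#' @param pseudocount additive smoothing constant (default 0.5,
#'   Jeffreys-style; guarantees finite LBFs).
#' @return a \linkS4class{GenotypeModel}.
#' @export
estimateModels <- function(dataset, labels = phenotype(dataset),
                           pseudocount = 0.5) {
    stopifnot(is(dataset, "GenotypeDataset"))
    if (length(labels) != ncol(dataset))
        stop("labels must align with samples")
    caseVec <- as.numeric(labels == "case" & !is.na(labels))
    ctrlVec <- as.numeric(labels == "control" & !is.na(labels))
    if (sum(caseVec) == 0 || sum(ctrlVec) == 0)
        stop("both classes must be non-empty")
    prep <- .lbfPrep(dataset)
    cntCase <- .lbfCountClass(prep, caseVec)
    cntLabTot <- cntCase + .lbfCountClass(prep, ctrlVec)
    mod <- .lbfModel(prep, cntCase, cntLabTot, pseudocount)
    fbIds <- prep$variantIds[mod$fallback]
    if (length(fbIds))
        warning("pooled-distribution fallback for ", length(fbIds),
                " variable(s) with an unobserved class: ",
                paste(utils::head(fbIds, 5), collapse = ", "),
                if (length(fbIds) > 5) ", ..." else "")
    new("GenotypeModel",
        caseProb = mod$pcase, controlProb = mod$pctrl,
        slotMap = list(S = prep$S, maxK = prep$maxK, kvec = prep$kvec),
        variantIds = as.character(prep$variantIds),
        pseudocount = pseudocount,
        pooledFallback = as.character(fbIds))
}

#' Transform genotypes into log Bayes factors
#'
#' Cell (i, j) becomes \code{ln P(g_ij | case model) -
#' ln P(g_ij | control model)} (natural log); missing genotypes become 0.
#' The result has the same dimensions as the source genotype matrix.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param model a \linkS4class{GenotypeModel} covering every variable of
#'   \code{dataset} (from \code{\link{estimateModels}}).
#' @return an \linkS4class{LBFMatrix}.
#' @export
lbfTransform <- function(dataset, model) {
    stopifnot(is(dataset, "GenotypeDataset"), is(model, "GenotypeModel"))
    if (!identical(as.character(variantIds(dataset)), model@variantIds))
        stop("model does not cover the dataset's variables ",
             "(variant ids disagree)")
    prep <- .lbfPrep(dataset)
    if (prep$S != model@slotMap$S)
        stop("internal error: slot layout mismatch between dataset and model")
    L <- .lbfL(list(pcase = model@caseProb, pctrl = model@controlProb))
    X <- .Call(C_slot_gather, L, prep$idx, prep$n)
    vals <- t(X)
    dimnames(vals) <- list(model@variantIds, prep$sampleIds)
    new("LBFMatrix", values = vals, model = model)
}
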