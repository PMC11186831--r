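# Shared fixture builders for the test suite.

suppressPackageStartupMessages(library(SummarizedExperiment))

# Build a GenotypeDataset directly from a variants x samples matrix.
makeDs <- function(g, chrom = rep("1", nrow(g)),
                   sex = rep(c("female", "male"), length.out = ncol(g)),
                   phen = rep(c("case", "control"), length.out = ncol(g)),
                   isCat = rep(FALSE, nrow(g)),
                   nCat = rep(3L, nrow(g)),
                   callProb = NULL) {
    m <- nrow(g); n <- ncol(g)
    variants <- data.frame(
        variant_id = paste0("v", seq_len(m)), chrom = chrom,
        pos = seq_len(m) * 1000L, ref = "A", alt = "G",
        is_categorical = isCat, n_categories = nCat,
        stringsAsFactors = FALSE)
    samples <- data.frame(
        sample_id = paste0("s", seq_len(n)), sex_reported = sex,
        phenotype = phen, stringsAsFactors = FALSE)
    GenotypeDataset(g, variants, samples, callProb = callProb)
}

# HWE genotype matrix at given allele frequencies (variants x samples).
rHweMatrix <- function(m, n, p) {
    matrix(stats::rbinom(m * n, 2L, rep_len(p, m)), m, n)
}

# Independent brute-force HWE exact test: enumerate all heterozygote
# counts compatible with the allele counts, using exact conditional
# probabilities computed with full-precision factorials via lchoose.
bruteHwe <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    if (n == 0) return(1)
    nA <- 2 * nAA + nAa
    hs <- seq.int(nA %% 2, min(nA, 2 * n - nA), by = 2)
    pr <- vapply(hs, function(h) {
        aa <- (nA - h) / 2
        bb <- (2 * n - nA - h) / 2
        exp(lchoose(n, aa) + lchoose(n - aa, h) + h * log(2) -
            (lchoose(2 * n, nA)))
    }, numeric(1))
    pr <- pr / sum(pr)
    pObs <- pr[match(nAa, hs)]
    min(1, sum(pr[pr <= pObs * (1 + 1e-7)]))
}

# Independent classical TOPSIS: weight the matrix, Euclidean distance
# to the weighted ideal/anti-ideal, closeness coefficient.
oracleTopsis <- function(X, w) {
    V <- sweep(X, 2, w, "*")
    best <- w; worst <- rep(0, length(w))
    dPlus <- sqrt(rowSums(sweep(V, 2, best, "-")^2))
    dMinus <- sqrt(rowSums(sweep(V, 2, worst, "-")^2))
    ifelse(dPlus + dMinus == 0, 0, dMinus / (dPlus + dMinus))
}
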