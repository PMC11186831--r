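## Univariate cohort quality control: sex inference from X-chromosome
## heterozygosity, sample missingness, a relatedness scan on
## high-MAF SNPs, and variant filters (monomorphic, missingness, exact
## Hardy-Weinberg departure in controls).  No MAF floor is applied
## anywhere outside the relatedness scan: the LBF method retains rare
## variants by design.

#' Infer sex from X-chromosome heterozygosity
#'
#' Per-sample heterozygosity rate over observed X-linked genotypes;
#' inferred male when the rate is below \code{maleMax}, female above
#' \code{femaleMin}, otherwise unknown.  A mismatch is flagged when the
#' inferred sex is known and differs from the recorded sex.
#'
#' @param dataset a \linkS4class{GenotypeDataset} with X-linked variants.
#' @param maleMax,femaleMin heterozygosity cutoffs (defaults 0.02 / 0.20).
#' @return data.frame: sample_id, x_het_rate, sex_inferred, sex_reported,
#'   mismatch.
#' @export
inferSex <- function(dataset, maleMax = 0.02, femaleMin = 0.20) {
    stopifnot(is(dataset, "GenotypeDataset"))
    xv <- isXLinked(dataset)
    if (!any(xv))
        stop("no X-linked variants present: sex inference is not possible")
    if (sum(xv) < 20)
        warning("fewer than 20 X-linked variants; sex inference is unreliable")
    g <- genotypes(dataset)[xv, , drop = FALSE]
    het <- colSums(g == 1L, na.rm = TRUE)
    obs <- colSums(!is.na(g))
    rate <- ifelse(obs > 0, het / obs, NA_real_)
    inf <- ifelse(is.na(rate), "unknown",
                  ifelse(rate < maleMax, "male",
                         ifelse(rate > femaleMin, "female", "unknown")))
    rep <- reportedSex(dataset)
    data.frame(sample_id = sampleIds(dataset), x_het_rate = rate,
               sex_inferred = inf, sex_reported = rep,
               mismatch = inf != "unknown" & inf != rep,
               stringsAsFactors = FALSE)
}

#' Filter samples by missing-value rate
#'
#' Samples with a missing fraction strictly above \code{maxRate} are
#' removed.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param maxRate maximum tolerated missing fraction (default 0.05).
#' @return list with \code{kept} and \code{removed} sample ids and the
#'   per-sample \code{missing_rate}.
#' @export
filterSampleMissingness <- function(dataset, maxRate = 0.05) {
    g <- genotypes(dataset)
    rate <- colMeans(is.na(g))
    ids <- sampleIds(dataset)
    list(kept = ids[rate <= maxRate], removed = ids[rate > maxRate],
         missing_rate = stats::setNames(rate, ids))
}

#' Relatedness scan on high-MAF SNPs
#'
#' Selects up to \code{nSnps} autosomal SNPs with minor allele frequency
#' strictly above \code{mafMin} (the most variable sites, where
#' unrelated pairs share genotypes least often) and computes, for every
#' sample pair, the fraction of co-observed selected variants with equal
#' genotype codes.  Pairs above \code{identityMin} are flagged; the
#' higher-missingness member of each flagged pair (ties: the
#' later-indexed sample) is marked for removal.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param mafMin MAF threshold (default 0.48).
#' @param nSnps number of SNPs to use (all passing SNPs if fewer, with a
#'   warning).
#' @param identityMin identity fraction above which a pair is flagged.
#' @return list: \code{pairs} (data.frame sample_a, sample_b, identity for
#'   flagged pairs), \code{remove} (sample ids), \code{identity} (full
#'   symmetric matrix), \code{n_snps_used}.
#' @export
relatednessScan <- function(dataset, mafMin = 0.48, nSnps = 20000L,
                            identityMin = 0.8) {
    stopifnot(is(dataset, "GenotypeDataset"))
    rd <- rowData(dataset)
    snp <- !rd$is_categorical & !isXLinked(dataset)
    g <- genotypes(dataset)[snp, , drop = FALSE]
    obs <- !is.na(g)
    p <- rowSums(g, na.rm = TRUE) / (2 * rowSums(obs))
    maf <- pmin(p, 1 - p)
    pass <- which(!is.na(maf) & maf > mafMin)
    if (length(pass) < 100)
        stop("fewer than 100 variants pass the MAF filter (",
             length(pass), ")")
    if (length(pass) > nSnps)
        pass <- pass[order(maf[pass], decreasing = TRUE)[seq_len(nSnps)]]
    else if (length(pass) < nSnps)
        .msg("only ", length(pass), " SNPs pass MAF > ", mafMin,
             "; using all of them")
    gs <- g[pass, , drop = FALSE]
    os <- matrix(as.numeric(!is.na(gs)), nrow(gs), ncol(gs))
    match <- matrix(0, ncol(gs), ncol(gs))
    for (code in 0:2) {
        ind <- matrix(as.numeric(!is.na(gs) & gs == code),
                      nrow(gs), ncol(gs))
        match <- match + crossprod(ind)
    }
    coObs <- crossprod(os)
    identity <- ifelse(coObs > 0, match / coObs, NA_real_)
    ids <- sampleIds(dataset)
    dimnames(identity) <- list(ids, ids)
    flag <- which(upper.tri(identity) & !is.na(identity) &
                  identity > identityMin, arr.ind = TRUE)
    missRate <- colMeans(is.na(genotypes(dataset)))
    pairs <- data.frame(sample_a = ids[flag[, 1]],
                        sample_b = ids[flag[, 2]],
                        identity = identity[flag],
                        stringsAsFactors = FALSE)
    remove <- character(0)
    if (nrow(pairs)) {
        worse <- ifelse(missRate[flag[, 1]] > missRate[flag[, 2]],
                        flag[, 1], flag[, 2])
        remove <- unique(ids[worse])
    }
    list(pairs = pairs, remove = remove, identity = identity,
         n_snps_used = length(pass))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional on the observed allele counts, sums the probabilities of
#' all heterozygote counts no more probable than the observed one
#' (two-sided exact test).
#'
#' @param nAA,nAa,naa genotype counts (non-negative; total > 0 expected;
#'   an all-zero triple returns 1 with a warning).
#' @return exact two-sided p-value.
#' @examples
#' hweExactTest(25, 50, 25)  # HWE-consistent: p close to 1
#' hweExactTest(50, 0, 50)   # total heterozygote deficit: p << 1e-8
#' @export
hweExactTest <- function(nAA, nAa, naa) {
    stopifnot(length(nAA) == 1, nAA >= 0, nAa >= 0, naa >= 0)
    n <- nAA + nAa + naa
    if (n == 0) {
        warning("all genotype counts are zero; HWE test undefined")
        return(1)
    }
    nA <- 2 * nAA + nAa
    hMax <- min(nA, 2 * n - nA)
    h <- seq.int(nA %% 2, hMax, by = 2)
    lp <- lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
        lfactorial((2 * n - nA - h) / 2) + h * log(2) +
        lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    pObs <- pr[match(nAa, h)]
    min(1, sum(pr[pr <= pObs * (1 + 1e-7)]))
}

#' Variant quality-control filters
#'
#' Applies the three variant rules: monomorphic in the whole population
#' (a single observed allele, or a single observed category for
#' categorical variables), missing fraction strictly above
#' \code{config$variant_missing_max}, and exact Hardy-Weinberg departure
#' in the control group below \code{config$hwe_p_min} (X-linked variants
#' are tested in control females only; categorical variables are exempt).
#' A variant may be counted under several reasons but is removed once.
#'
#' @param dataset a \linkS4class{GenotypeDataset} with phenotype labels.
#' @param config a \code{\link{runConfig}} list.
#' @return list: \code{dataset} (filtered), \code{report}
#'   (\linkS4class{QCReport} covering the variant reasons).
#' @export
filterVariants <- function(dataset, config = runConfig()) {
    stopifnot(is(dataset, "GenotypeDataset"))
    g <- genotypes(dataset)
    rd <- rowData(dataset)
    ids <- variantIds(dataset)
    obs <- !is.na(g)
    nObs <- rowSums(obs)

    ## monomorphic: single observed allele / category
    mono <- logical(nrow(g))
    isCat <- rd$is_categorical
    nLevels <- vapply(seq_len(nrow(g)), function(i) {
        v <- g[i, obs[i, ]]
        length(unique(v))
    }, integer(1))
    mono[isCat] <- nObs[isCat] > 0 & nLevels[isCat] <= 1L
    snp <- !isCat
    altCount <- rowSums(g, na.rm = TRUE)
    mono[snp] <- nObs[snp] > 0 &
        (altCount[snp] == 0 | altCount[snp] == 2 * nObs[snp])

    highMiss <- rowMeans(!obs) > config$variant_missing_max

    ## HWE in controls (control females for X-linked variants)
    ctrl <- phenotype(dataset) == "control" & !is.na(phenotype(dataset))
    fem <- reportedSex(dataset) == "female"
    xv <- isXLinked(dataset)
    hweFail <- logical(nrow(g))
    testable <- which(snp)
    for (i in testable) {
        cols <- if (xv[i]) ctrl & fem else ctrl
        v <- g[i, cols]
        v <- v[!is.na(v)]
        if (!length(v)) next
        p <- hweExactTest(sum(v == 0L), sum(v == 1L), sum(v == 2L))
        hweFail[i] <- p < config$hwe_p_min
    }

    rv <- rbind(
        data.frame(variant_id = ids[mono],
                   reason = rep("monomorphic", sum(mono)),
                   stringsAsFactors = FALSE),
        data.frame(variant_id = ids[highMiss],
                   reason = rep("variant_missingness", sum(highMiss)),
                   stringsAsFactors = FALSE),
        data.frame(variant_id = ids[hweFail],
                   reason = rep("hwe", sum(hweFail)),
                   stringsAsFactors = FALSE))
    counts <- c(monomorphic = sum(mono),
                variant_missingness = sum(highMiss),
                hwe = sum(hweFail))
    keep <- !(mono | highMiss | hweFail)
    report <- new("QCReport",
                  removedSamples = data.frame(sample_id = character(0),
                                              reason = character(0)),
                  removedVariants = rv,
                  counts = as.integer(counts) |>
                      stats::setNames(names(counts)),
                  thresholds = list(
                      variant_missing_max = config$variant_missing_max,
                      hwe_p_min = config$hwe_p_min))
    list(dataset = dataset[keep, ], report = report)
}

#' Run the complete univariate QC pipeline
#'
#' Order of operations: sex-mismatch removal, sample missingness,
#' relatedness scan (one member of each related pair removed), then the
#' variant filters of \code{\link{filterVariants}} on the remaining
#' samples.
#'
#' @param dataset a \linkS4class{GenotypeDataset}.
#' @param config a \code{\link{runConfig}} list.
#' @param verbose print progress.
#' @return list: \code{dataset} (filtered), \code{report}
#'   (\linkS4class{QCReport}), \code{sex} (the inferSex table),
#'   \code{relatedness} (flagged pairs).
#' @export
runQC <- function(dataset, config = runConfig(), verbose = FALSE) {
    sex <- inferSex(dataset, maleMax = config$sex_het_male_max,
                    femaleMin = config$sex_het_female_min)
    sexBad <- sex$sample_id[sex$mismatch]
    .msg("sex mismatches: ", length(sexBad), verbose = verbose)
    keep1 <- setdiff(sampleIds(dataset), sexBad)
    d1 <- subsetDataset(dataset, samples = keep1)

    sm <- filterSampleMissingness(d1, maxRate = config$sample_missing_max)
    .msg("high-missingness samples: ", length(sm$removed),
         verbose = verbose)
    d2 <- subsetDataset(d1, samples = sm$kept)

    rel <- relatednessScan(d2, mafMin = config$relatedness_maf_min,
                           nSnps = config$relatedness_n_snps,
                           identityMin = config$relatedness_identity_min)
    .msg("related samples removed: ", length(rel$remove),
         verbose = verbose)
    d3 <- subsetDataset(d2, samples = setdiff(sampleIds(d2), rel$remove))

    vf <- filterVariants(d3, config)
    rs <- rbind(
        data.frame(sample_id = sexBad,
                   reason = rep("sex_mismatch", length(sexBad)),
                   stringsAsFactors = FALSE),
        data.frame(sample_id = sm$removed,
                   reason = rep("sample_missingness", length(sm$removed)),
                   stringsAsFactors = FALSE),
        data.frame(sample_id = rel$remove,
                   reason = rep("related", length(rel$remove)),
                   stringsAsFactors = FALSE))
    counts <- c(sex_mismatch = length(sexBad),
                sample_missingness = length(sm$removed),
                related = length(rel$remove),
                qcCounts(vf$report))
    report <- new("QCReport",
                  removedSamples = rs,
                  removedVariants = removedVariants(vf$report),
                  counts = stats::setNames(as.integer(counts),
                                           names(counts)),
                  thresholds = list(
                      sample_missing_max = config$sample_missing_max,
                      variant_missing_max = config$variant_missing_max,
                      hwe_p_min = config$hwe_p_min,
                      relatedness_maf_min = config$relatedness_maf_min,
                      relatedness_identity_min =
                          config$relatedness_identity_min,
                      sex_het_male_max = config$sex_het_male_max,
                      sex_het_female_min = config$sex_het_female_min))
    list(dataset = vf$dataset, report = report, sex = sex,
         relatedness = rel$pairs)
}

#' Write a QCReport as TSV tables plus a JSON summary
#'
#' @param report a \linkS4class{QCReport}.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
writeQCReport <- function(report, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(dir, "removed_samples.tsv")
    p2 <- file.path(dir, "removed_variants.tsv")
    p3 <- file.path(dir, "qc_summary.json")
    writeTable(removedSamples(report), p1)
    writeTable(removedVariants(report), p2)
    jsonlite::write_json(list(counts = as.list(qcCounts(report)),
                              thresholds = report@thresholds),
                         p3, auto_unbox = TRUE, digits = NA)
    invisible(c(p1, p2, p3))
}
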