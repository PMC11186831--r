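## Synthetic case/control cohorts with the statistical structure the
## pipeline assumes: HWE control genotypes at uniform MAFs, case
## genotypes tilted at planted risk loci under a multiplicative allelic
## odds ratio, and planted QC defects (monomorphic variants,
## high-missingness variants, Hardy-Weinberg violators, related pairs,
## sex mismatches, ancestry outliers drawn from Balding-Nichols
## perturbed allele frequencies).  All randomness flows from one root
## seed through named per-purpose streams.

#' Specification of a simulated cohort
#'
#' @param n_case,n_control sample sizes.
#' @param n_variants autosomal variant count.
#' @param n_x_variants X-linked variant count (needed for sex checks).
#' @param maf_range range the per-variant alt-allele frequencies are
#'   drawn from (uniform).
#' @param risk_loci data.frame with columns \code{index} (autosomal
#'   variant index) and \code{or} (allelic odds ratio > 0), or NULL.
#' @param missing_rate background genotype missingness.
#' @param n_monomorphic,n_hwe_violators,n_high_missing planted defective
#'   variant counts (allocated from the top autosomal indices, disjoint
#'   from the risk loci).
#' @param high_missing_rate missingness given to planted high-missing
#'   variants (default 0.10).
#' @param hwe_inbreeding inbreeding coefficient used for planted HWE
#'   violators in controls (default 0.8: strong homozygote excess).
#' @param n_related_pairs planted related pairs (duplicate-with-noise:
#'   5\% of sites re-randomised).
#' @param n_sex_mismatches samples whose reported sex is flipped (their
#'   X genotypes follow the true sex).
#' @param n_outlier_ancestry samples redrawn from a Balding-Nichols
#'   perturbed population at \code{fst_outlier}.
#' @param sex_case_fraction_female,sex_control_fraction_female expected
#'   female fractions per class.
#' @param fst_outlier Wright's Fst of the outlier population.
#' @param seed root seed.
#' @return a validated list of class \code{"SimSpec"}.
#' @export
simSpec <- function(n_case, n_control, n_variants,
                    n_x_variants = 100L,
                    maf_range = c(0.05, 0.5),
                    risk_loci = NULL,
                    missing_rate = 0.002,
                    n_monomorphic = 0L, n_hwe_violators = 0L,
                    n_high_missing = 0L, high_missing_rate = 0.10,
                    hwe_inbreeding = 0.8,
                    n_related_pairs = 0L, n_sex_mismatches = 0L,
                    n_outlier_ancestry = 0L,
                    sex_case_fraction_female = 0.5,
                    sex_control_fraction_female = 0.5,
                    fst_outlier = 0.15, seed = 1L) {
    spec <- as.list(environment())
    n <- n_case + n_control
    if (!is.null(risk_loci)) {
        risk_loci <- as.data.frame(risk_loci)
        stopifnot(all(c("index", "or") %in% colnames(risk_loci)))
        if (any(risk_loci$or <= 0)) stop("odds ratios must be > 0")
        if (any(risk_loci$index < 1 | risk_loci$index > n_variants))
            stop("risk locus index out of range")
        spec$risk_loci <- risk_loci
    }
    if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2])
        stop("maf_range must lie in (0, 0.5]")
    if (missing_rate < 0 || missing_rate >= 1)
        stop("missing_rate must lie in [0, 1)")
    if (fst_outlier < 0 || fst_outlier >= 1)
        stop("fst_outlier must lie in [0, 1)")
    nPlanted <- n_monomorphic + n_hwe_violators + n_high_missing
    if (nPlanted + NROW(risk_loci) > n_variants)
        stop("planted variant counts exceed n_variants")
    if (!is.null(risk_loci) &&
        any(risk_loci$index > n_variants - nPlanted))
        stop("risk loci collide with the planted defective block")
    if (2 * n_related_pairs + n_sex_mismatches + n_outlier_ancestry > n)
        stop("planted sample counts exceed the cohort size")
    class(spec) <- "SimSpec"
    spec
}

## multiplicative allelic risk: case allele frequency under odds ratio
.tiltFreq <- function(p, or) or * p / (1 - p + or * p)

#' Simulate a case/control cohort
#'
#' Control genotypes are drawn from Hardy-Weinberg proportions at the
#' per-variant allele frequency; case genotypes at planted risk loci are
#' drawn from HWE at the tilted frequency \code{OR p / (1 - p + OR p)}
#' (the multiplicative allelic risk model).  See \code{\link{simSpec}}
#' for the planted-defect machinery.
#'
#' @param spec a \code{\link{simSpec}}.
#' @return a \linkS4class{GenotypeDataset}; the planted truth (risk
#'   indices, defective variant ids, related pairs, mismatch/outlier
#'   ids, allele frequencies) is stored in \code{metadata(x)$truth}.
#' @export
simulateCohort <- function(spec) {
    stopifnot(inherits(spec, "SimSpec"))
    set.seed(deriveSeed(spec$seed, "cohort"))
    nCa <- spec$n_case; nCo <- spec$n_control; n <- nCa + nCo
    mA <- spec$n_variants; mX <- spec$n_x_variants; m <- mA + mX

    ## variant frame: autosomes spread over chr1-22, then X
    chromA <- as.character(rep_len(1:22, mA))
    posA <- 5000L * (((seq_len(mA) - 1L) %/% 22L) + 1L)
    variants <- data.frame(
        variant_id = paste0("var", seq_len(m)),
        chrom = c(chromA, rep("X", mX)),
        pos = c(posA, 5000L * seq_len(mX)),
        ref = "A", alt = "G", stringsAsFactors = FALSE)

    ## samples: cases then controls; sex by class-specific fractions
    phen <- rep(c("case", "control"), c(nCa, nCo))
    sexTrue <- ifelse(stats::runif(n) <
                      ifelse(phen == "case", spec$sex_case_fraction_female,
                             spec$sex_control_fraction_female),
                      "female", "male")
    samples <- data.frame(sample_id = sprintf("subj%04d", seq_len(n)),
                          sex_reported = sexTrue, phenotype = phen,
                          stringsAsFactors = FALSE)

    p <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
    pCase <- p
    if (!is.null(spec$risk_loci))
        pCase[spec$risk_loci$index] <-
            .tiltFreq(p[spec$risk_loci$index], spec$risk_loci$or)

    isCase <- phen == "case"
    G <- matrix(NA_integer_, m, n)
    G[, isCase] <- stats::rbinom(m * nCa, 2L, pCase)
    G[, !isCase] <- stats::rbinom(m * nCo, 2L, p)
    ## X-linked: males hemizygous (codes 0/2); redrawn by true sex
    if (mX > 0) {
        xr <- mA + seq_len(mX)
        male <- sexTrue == "male"
        if (any(male))
            G[xr, male] <- 2L * stats::rbinom(mX * sum(male), 1L, p[xr])
    }

    truth <- list(maf = p, case_maf = pCase,
                  risk_index = spec$risk_loci$index,
                  risk_or = spec$risk_loci$or)

    ## planted defective variants from the top autosomal indices
    cursor <- mA
    take <- function(k) {
        idx <- if (k > 0) (cursor - k + 1L):cursor else integer(0)
        cursor <<- cursor - k
        idx
    }
    monoIdx <- take(spec$n_monomorphic)
    hweIdx <- take(spec$n_hwe_violators)
    hmIdx <- take(spec$n_high_missing)
    truth$monomorphic_ids <- variants$variant_id[monoIdx]
    truth$hwe_ids <- variants$variant_id[hweIdx]
    truth$high_missing_ids <- variants$variant_id[hmIdx]

    ## planted samples, allocated disjointly from the end of the cohort
    scursor <- n
    stake <- function(k) {
        idx <- if (k > 0) (scursor - k + 1L):scursor else integer(0)
        scursor <<- scursor - k
        idx
    }
    outIdx <- stake(spec$n_outlier_ancestry)
    relIdx <- stake(2L * spec$n_related_pairs)
    mmIdx <- stake(spec$n_sex_mismatches)

    if (length(outIdx)) {
        fst <- spec$fst_outlier
        pOut <- if (fst == 0) p[seq_len(mA)] else
            stats::rbeta(mA, p[seq_len(mA)] * (1 - fst) / fst,
                         (1 - p[seq_len(mA)]) * (1 - fst) / fst)
        G[seq_len(mA), outIdx] <-
            stats::rbinom(mA * length(outIdx), 2L, pOut)
        truth$outlier_maf <- pOut
    }
    truth$outlier_ids <- samples$sample_id[outIdx]

    if (length(relIdx)) {
        a <- relIdx[seq_len(spec$n_related_pairs)]
        b <- relIdx[spec$n_related_pairs + seq_len(spec$n_related_pairs)]
        for (t in seq_along(a)) {
            samples$sex_reported[b[t]] <- samples$sex_reported[a[t]]
            sexTrue[b[t]] <- sexTrue[a[t]]
            G[, b[t]] <- G[, a[t]]
            redo <- which(stats::runif(m) < 0.05)
            if (length(redo)) {
                pv <- if (isCase[b[t]]) pCase[redo] else p[redo]
                G[redo, b[t]] <- stats::rbinom(length(redo), 2L, pv)
                xredo <- redo[redo > mA]
                if (length(xredo) && sexTrue[b[t]] == "male")
                    G[xredo, b[t]] <- 2L *
                        stats::rbinom(length(xredo), 1L, p[xredo])
            }
        }
        truth$related_pairs <- data.frame(
            sample_a = samples$sample_id[a],
            sample_b = samples$sample_id[b], stringsAsFactors = FALSE)
    }

    if (length(mmIdx))
        samples$sex_reported[mmIdx] <-
            ifelse(sexTrue[mmIdx] == "male", "female", "male")
    truth$sex_mismatch_ids <- samples$sample_id[mmIdx]

    ## variant-level planting last, so the sample-level redraws above
    ## (outliers, related-pair noise) cannot dilute it
    if (length(monoIdx)) G[monoIdx, ] <- 0L
    if (length(hweIdx)) {
        ## homozygote excess in controls via inbreeding coefficient F
        f <- spec$hwe_inbreeding
        for (i in hweIdx) {
            pr <- c((1 - p[i])^2 + f * p[i] * (1 - p[i]),
                    2 * p[i] * (1 - p[i]) * (1 - f),
                    p[i]^2 + f * p[i] * (1 - p[i]))
            G[i, !isCase] <- sample(0:2, nCo, replace = TRUE, prob = pr)
        }
    }

    if (spec$missing_rate > 0)
        G[stats::runif(length(G)) < spec$missing_rate] <- NA_integer_
    if (length(hmIdx)) {
        extra <- matrix(stats::runif(length(hmIdx) * n) <
                        spec$high_missing_rate, length(hmIdx), n)
        G[hmIdx, ][extra] <- NA_integer_
    }

    ds <- GenotypeDataset(G, variants, samples)
    metadata(ds)$truth <- truth
    ds
}

#' Simulate reference population panels
#'
#' Each population's allele frequencies are drawn from a Balding-Nichols
#' distribution around shared base frequencies (Beta with mean p and
#' variance Fst p (1-p)); genotypes are HWE draws.  All panels share the
#' variant frame.
#'
#' @param populations data.frame with columns \code{label}, \code{n},
#'   \code{fst} (Fst from the shared base; 0 = the base itself).
#' @param n_variants variant count (autosomal).
#' @param seed root seed.
#' @param maf_range base allele-frequency range.
#' @return named list of \linkS4class{GenotypeDataset}, one per
#'   population (phenotype NA, \code{population} column set);
#'   \code{metadata(x)$base_maf} holds the shared base frequencies and
#'   \code{metadata(x)$pop_maf} the population's own.
#' @export
simulateReferencePanels <- function(populations, n_variants, seed = 1L,
                                    maf_range = c(0.05, 0.5)) {
    populations <- as.data.frame(populations)
    stopifnot(all(c("label", "n", "fst") %in% colnames(populations)))
    if (any(populations$fst < 0 | populations$fst >= 1))
        stop("fst values must lie in [0, 1)")
    set.seed(deriveSeed(seed, "panels-base"))
    m <- n_variants
    base <- stats::runif(m, maf_range[1], maf_range[2])
    chrom <- as.character(rep_len(1:22, m))
    pos <- 5000L * (((seq_len(m) - 1L) %/% 22L) + 1L)
    variants <- data.frame(variant_id = paste0("var", seq_len(m)),
                           chrom = chrom, pos = pos, ref = "A", alt = "G",
                           stringsAsFactors = FALSE)
    out <- list()
    for (r in seq_len(nrow(populations))) {
        lab <- as.character(populations$label[r])
        n <- populations$n[r]
        fst <- populations$fst[r]
        set.seed(deriveSeed(seed, paste0("panel-", lab)))
        pp <- if (fst == 0) base else
            stats::rbeta(m, base * (1 - fst) / fst,
                         (1 - base) * (1 - fst) / fst)
        G <- matrix(stats::rbinom(m * n, 2L, pp), m, n)
        samples <- data.frame(
            sample_id = sprintf("%s%04d", lab, seq_len(n)),
            sex_reported = "unknown", phenotype = NA_character_,
            population = lab, stringsAsFactors = FALSE)
        ds <- GenotypeDataset(G, variants, samples)
        metadata(ds)$base_maf <- base
        metadata(ds)$pop_maf <- pp
        out[[lab]] <- ds
    }
    out
}

#' Simulate SNP-to-gene evidence tables
#'
#' Builds toy evidence tables in the exact schemas the gene-mapping
#' stage consumes, with a known planted best gene per seed SNP: the
#' planted gene receives strong QTL evidence, a coding consequence half
#' of the time and chromatin contact evidence, while other nearby genes
#' receive weak or no evidence.
#'
#' @param genes data.frame: gene_id, chrom, start, end, strand.
#' @param snps data.frame: variant_id, chrom, pos (seed SNPs).
#' @param seed root seed.
#' @param windowBp distance window used to find candidate genes.
#' @return list of data.frames \code{vep} (variant_id, gene_id,
#'   consequence), \code{qtl} (variant_id, gene_id, score),
#'   \code{chromatin} (variant_id, gene_id, score), \code{ppi} (gene_a,
#'   gene_b, confidence), \code{tractability} (gene_id, term), and
#'   \code{truth} (variant_id, gene_id planted assignments).
#' @export
simulateEvidence <- function(genes, snps, seed = 1L, windowBp = 40000L) {
    genes <- as.data.frame(genes)
    snps <- as.data.frame(snps)
    set.seed(deriveSeed(seed, "evidence"))
    vep <- qtl <- chrom <- NULL
    truth <- NULL
    for (i in seq_len(nrow(snps))) {
        cand <- genes[genes$chrom == snps$chrom[i] &
                      genes$start - windowBp <= snps$pos[i] &
                      genes$end + windowBp >= snps$pos[i], , drop = FALSE]
        if (!nrow(cand)) next
        d <- pmax(cand$start - snps$pos[i], snps$pos[i] - cand$end, 0)
        best <- which.min(d)
        for (j in seq_len(nrow(cand))) {
            gid <- cand$gene_id[j]
            vid <- snps$variant_id[i]
            if (j == best) {
                qtl <- rbind(qtl, data.frame(
                    variant_id = vid, gene_id = gid,
                    score = stats::runif(1, 0.8, 0.95)))
                if (stats::runif(1) < 0.5)
                    vep <- rbind(vep, data.frame(
                        variant_id = vid, gene_id = gid,
                        consequence = "missense_variant"))
                chrom <- rbind(chrom, data.frame(
                    variant_id = vid, gene_id = gid,
                    score = stats::runif(1, 0.5, 0.9)))
                truth <- rbind(truth, data.frame(
                    variant_id = vid, gene_id = gid,
                    stringsAsFactors = FALSE))
            } else if (stats::runif(1) < 0.3) {
                qtl <- rbind(qtl, data.frame(
                    variant_id = vid, gene_id = gid,
                    score = stats::runif(1, 0.05, 0.3)))
            }
        }
    }
    gid <- genes$gene_id
    ppi <- NULL
    if (length(gid) >= 2) {
        pairs <- utils::combn(gid, 2)
        pick <- stats::runif(ncol(pairs)) < 0.3
        if (any(pick))
            ppi <- data.frame(gene_a = pairs[1, pick],
                              gene_b = pairs[2, pick],
                              confidence = stats::runif(sum(pick), 0.2, 1),
                              stringsAsFactors = FALSE)
    }
    terms <- names(tractabilityTerms())
    tract <- do.call(rbind, lapply(gid, function(g) {
        k <- stats::rbinom(1, 3, 0.4)
        if (k == 0) return(NULL)
        data.frame(gene_id = g, term = sample(terms, k),
                   stringsAsFactors = FALSE)
    }))
    empty <- function(...) {
        d <- data.frame(...)
        d[0, , drop = FALSE]
    }
    list(vep = if (is.null(vep)) empty(variant_id = "", gene_id = "",
                                       consequence = "") else vep,
         qtl = if (is.null(qtl)) empty(variant_id = "", gene_id = "",
                                       score = 0) else qtl,
         chromatin = if (is.null(chrom)) empty(variant_id = "",
                                               gene_id = "", score = 0)
                     else chrom,
         ppi = if (is.null(ppi)) empty(gene_a = "", gene_b = "",
                                       confidence = 0) else ppi,
         tractability = if (is.null(tract)) empty(gene_id = "", term = "")
                        else tract,
         truth = if (is.null(truth)) empty(variant_id = "", gene_id = "")
                 else truth)
}
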