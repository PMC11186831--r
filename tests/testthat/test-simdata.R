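test_that("simSpec validates its arguments", {
    expect_s3_class(simSpec(10, 10, 50), "SimSpec")
    expect_error(simSpec(10, 10, 50, maf_range = c(0, 0.5)), "maf_range")
    expect_error(simSpec(10, 10, 50, maf_range = c(0.6, 0.7)), "maf_range")
    expect_error(simSpec(10, 10, 50, missing_rate = 1), "missing_rate")
    expect_error(simSpec(10, 10, 50,
                         risk_loci = data.frame(index = 60, or = 2)),
                 "out of range")
    expect_error(simSpec(10, 10, 50,
                         risk_loci = data.frame(index = 1, or = -2)),
                 "odds ratios")
    expect_error(simSpec(10, 10, 50, n_monomorphic = 30,
                         n_hwe_violators = 30), "exceed")
    expect_error(simSpec(4, 4, 50, n_related_pairs = 3,
                         n_sex_mismatches = 3), "exceed")
    expect_error(simSpec(10, 10, 50, n_monomorphic = 5,
                         risk_loci = data.frame(index = 48, or = 2)),
                 "collide")
})

test_that("control genotypes follow Hardy-Weinberg at the drawn MAF", {
    spec <- simSpec(10, 2000, 400, n_x_variants = 0, missing_rate = 0,
                    seed = 41)
    ds <- simulateCohort(spec)
    p <- metadata(ds)$truth$maf
    g <- genotypes(ds)[, phenotype(ds) == "control"]
    nCo <- ncol(g)
    ## chi-square GOF against HWE proportions at the true p, per variant
    stat <- vapply(seq_len(nrow(g)), function(i) {
        e <- nCo * c((1 - p[i])^2, 2 * p[i] * (1 - p[i]), p[i]^2)
        o <- tabulate(g[i, ] + 1L, 3)
        sum((o - e)^2 / e)
    }, numeric(1))
    pv <- pchisq(stat, df = 2, lower.tail = FALSE)
    ## under the null the GOF p-values are uniform: few tiny ones
    expect_lt(mean(pv < 0.01), 0.03)
    expect_gt(mean(pv > 0.5), 0.40)
})

test_that("case genotypes at risk loci follow the tilted frequency", {
    or <- 3
    spec <- simSpec(3000, 10, 60, n_x_variants = 0, missing_rate = 0,
                    risk_loci = data.frame(index = 1:3, or = or),
                    maf_range = c(0.2, 0.4), seed = 42)
    ds <- simulateCohort(spec)
    tr <- metadata(ds)$truth
    p <- tr$maf[1:3]
    expected <- or * p / (1 - p + or * p)
    expect_equal(tr$case_maf[1:3], expected)
    g <- genotypes(ds)[1:3, phenotype(ds) == "case"]
    pHat <- rowMeans(g) / 2
    se <- sqrt(expected * (1 - expected) / (2 * ncol(g)))
    expect_true(all(abs(pHat - expected) < 4 * se))
    ## non-risk loci stay at the base frequency
    expect_equal(tr$case_maf[4:60], tr$maf[4:60])
})

test_that("male X genotypes are hemizygous codes", {
    spec <- simSpec(50, 50, 50, n_x_variants = 40, missing_rate = 0,
                    seed = 43)
    ds <- simulateCohort(spec)
    male <- reportedSex(ds) == "male"
    gx <- genotypes(ds)[as.character(rowData(ds)$chrom) == "X", male]
    expect_true(all(gx %in% c(0L, 2L)))
})

test_that("planted defects are recorded in the truth and detectable", {
    spec <- simSpec(80, 80, 500, n_x_variants = 60, missing_rate = 0,
                    n_monomorphic = 5, n_hwe_violators = 3,
                    n_high_missing = 4, n_related_pairs = 2,
                    n_sex_mismatches = 3, n_outlier_ancestry = 2,
                    seed = 44)
    ds <- simulateCohort(spec)
    tr <- metadata(ds)$truth
    expect_length(tr$monomorphic_ids, 5)
    expect_length(tr$hwe_ids, 3)
    expect_length(tr$high_missing_ids, 4)
    expect_length(tr$sex_mismatch_ids, 3)
    expect_length(tr$outlier_ids, 2)
    expect_equal(nrow(tr$related_pairs), 2)
    g <- genotypes(ds)
    ## monomorphic rows really are constant
    mono <- match(tr$monomorphic_ids, variantIds(ds))
    expect_true(all(g[mono, ] == 0L))
    ## high-missing rows have elevated missingness vs the background 0
    hm <- match(tr$high_missing_ids, variantIds(ds))
    hmRate <- rowMeans(is.na(g[hm, , drop = FALSE]))
    expect_true(all(hmRate > 0))
    expect_gt(mean(hmRate), 0.05)   # Bernoulli(0.10) per entry
    expect_equal(sum(is.na(g[-c(hm), ])), 0)
    ## related pairs are near-identical (95% duplicated sites)
    ra <- match(tr$related_pairs$sample_a, sampleIds(ds))
    rb <- match(tr$related_pairs$sample_b, sampleIds(ds))
    for (t in seq_along(ra)) {
        same <- mean(g[, ra[t]] == g[, rb[t]], na.rm = TRUE)
        expect_gt(same, 0.9)
    }
    ## HWE violators show a heterozygote deficit in controls
    hw <- match(tr$hwe_ids, variantIds(ds))
    co <- phenotype(ds) == "control"
    for (i in hw) {
        cnt <- tabulate(g[i, co] + 1L, 3)
        expect_lt(hweExactTest(cnt[1], cnt[2], cnt[3]), 1e-4)
    }
    ## all planted groups are disjoint
    ids <- c(tr$monomorphic_ids, tr$hwe_ids, tr$high_missing_ids)
    expect_false(any(duplicated(ids)))
})

test_that("simulateCohort is deterministic in the seed", {
    spec <- simSpec(20, 20, 80, seed = 45)
    d1 <- simulateCohort(spec)
    d2 <- simulateCohort(spec)
    expect_identical(genotypes(d1), genotypes(d2))
    spec2 <- simSpec(20, 20, 80, seed = 46)
    expect_false(identical(genotypes(d1),
                           genotypes(simulateCohort(spec2))))
})

test_that("reference panels share the variant frame and separate by Fst", {
    pops <- data.frame(label = c("base", "far"), n = c(50, 50),
                       fst = c(0, 0.2))
    panels <- simulateReferencePanels(pops, 800, seed = 47)
    expect_named(panels, c("base", "far"))
    expect_identical(variantIds(panels$base), variantIds(panels$far))
    expect_identical(as.data.frame(rowData(panels$base)),
                     as.data.frame(rowData(panels$far)))
    ## the fst = 0 panel sits at the base frequencies
    expect_identical(metadata(panels$base)$pop_maf,
                     metadata(panels$base)$base_maf)
    ## the perturbed panel's frequencies have roughly Fst p (1-p) spread
    b <- metadata(panels$far)$base_maf
    d <- metadata(panels$far)$pop_maf - b
    ## the ratio estimate over 800 variants has sd about 0.01
    expect_lt(abs(mean(d^2 / (b * (1 - b))) - 0.2), 0.04)
    expect_error(simulateReferencePanels(
        data.frame(label = "x", n = 5, fst = 1), 100), "fst")
})

test_that("simulateEvidence emits the expected schemas and truth", {
    genes <- data.frame(gene_id = c("g1", "g2"), chrom = "1",
                        start = c(1e5, 3e5), end = c(1.2e5, 3.2e5),
                        strand = c("+", "-"), stringsAsFactors = FALSE)
    snps <- data.frame(variant_id = c("sA", "sB"), chrom = "1",
                       pos = c(1.1e5, 9e6))
    sim <- simulateEvidence(genes, snps, seed = 48)
    expect_named(sim, c("vep", "qtl", "chromatin", "ppi",
                        "tractability", "truth"))
    ## sA lands inside g1; sB is nowhere near a gene
    expect_identical(sim$truth$variant_id, "sA")
    expect_identical(sim$truth$gene_id, "g1")
    expect_true(all(sim$qtl$score >= 0 & sim$qtl$score <= 1))
    expect_true("sA" %in% sim$qtl$variant_id)
    expect_false("sB" %in% sim$qtl$variant_id)
    expect_true(all(sim$tractability$term %in%
                    names(tractabilityTerms())))
})
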