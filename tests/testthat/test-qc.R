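test_that("inferSex classifies X heterozygosity correctly", {
    set.seed(51)
    nX <- 60
    gF <- matrix(rbinom(nX * 3, 2L, 0.4), nX, 3)       # het rate ~ 0.48
    gM <- 2L * matrix(rbinom(nX * 3, 1L, 0.4), nX, 3)  # no heterozygotes
    g <- cbind(gF, gM)
    ds <- makeDs(g, chrom = rep("X", nX),
                 sex = c("female", "female", "male",   # s3 mismatched
                         "male", "male", "female"))    # s6 mismatched
    tab <- inferSex(ds)
    expect_identical(tab$sex_inferred,
                     c("female", "female", "female", "male", "male", "male"))
    expect_identical(tab$mismatch, c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
    dsAuto <- makeDs(matrix(0:2, 3, 4), chrom = rep("1", 3))
    expect_error(inferSex(dsAuto), "X-linked")
})

test_that("sample missingness uses a strict 5% threshold", {
    g <- matrix(0L, 100, 3)
    g[1:5, 2] <- NA    # exactly 5%: kept
    g[1:6, 3] <- NA    # 6%: removed
    ds <- makeDs(g)
    res <- filterSampleMissingness(ds, maxRate = 0.05)
    expect_identical(res$kept, c("s1", "s2"))
    expect_identical(res$removed, "s3")
})

test_that("relatednessScan flags duplicates and spares unrelated pairs", {
    set.seed(52)
    m <- 400
    g <- rHweMatrix(m, 8, 0.5)
    g[, 2] <- g[, 1]                    # s2 duplicates s1
    g[3, 2] <- NA                       # s2 has higher missingness
    ds <- makeDs(g)
    res <- relatednessScan(ds, mafMin = 0.3, nSnps = m, identityMin = 0.8)
    expect_identical(res$pairs$sample_a, "s1")
    expect_identical(res$pairs$sample_b, "s2")
    expect_identical(res$remove, "s2")  # higher-missingness member
    offDiag <- res$identity[upper.tri(res$identity)]
    others <- offDiag[offDiag < 0.8]
    expect_true(all(others < 0.6))      # unrelated pairs sit near 0.375
    tiny <- makeDs(rHweMatrix(50, 4, 0.5))
    expect_error(relatednessScan(tiny, mafMin = 0.3), "100 variants")
})

test_that("hweExactTest matches the brute-force oracle on spot checks", {
    cases <- list(c(25, 50, 25), c(50, 0, 50), c(3, 5, 2), c(0, 10, 0),
                  c(7, 0, 0), c(1, 1, 1), c(12, 2, 9))
    for (cc in cases)
        expect_equal(hweExactTest(cc[1], cc[2], cc[3]),
                     bruteHwe(cc[1], cc[2], cc[3]), tolerance = 1e-10,
                     info = paste(cc, collapse = ","))
    expect_gt(hweExactTest(25, 50, 25), 0.5)   # HWE-consistent
    expect_lt(hweExactTest(50, 0, 50), 1e-25)  # total het deficit
    expect_warning(p0 <- hweExactTest(0, 0, 0), "zero")
    expect_equal(p0, 1)
})

test_that("variant filters flag monomorphic, missing and HWE failures", {
    set.seed(53)
    n <- 120
    g <- rHweMatrix(12, n, 0.3)
    g[1, ] <- 0L                         # monomorphic (all reference)
    g[2, ] <- 2L                         # monomorphic (all alternate)
    g[3, sample(n, 10)] <- NA            # 8.3% missing
    g[4, ] <- 1L                         # cases: all heterozygous
    g[4, seq(2, n, 2)] <- rep(c(0L, 2L), n / 4)  # controls: no hets
    ds <- makeDs(g, phen = rep(c("case", "control"), n / 2))
    out <- filterVariants(ds, runConfig())
    rv <- removedVariants(out$report)
    expect_identical(sort(rv$variant_id[rv$reason == "monomorphic"]),
                     c("v1", "v2"))
    expect_identical(rv$variant_id[rv$reason == "variant_missingness"], "v3")
    expect_identical(rv$variant_id[rv$reason == "hwe"], "v4")
    expect_equal(nrow(out$dataset), 8L)
    expect_false(any(c("v1", "v2", "v3", "v4") %in%
                     variantIds(out$dataset)))
})

test_that("X-linked HWE is tested in control females only", {
    set.seed(54)
    n <- 160
    sex <- rep(c("female", "male"), n / 2)
    phen <- rep(c("case", "case", "control", "control"), n / 4)
    # X variant: control females have zero heterozygotes; case females HWE
    g <- matrix(0L, 2, n)
    fem <- sex == "female"
    g[1, fem & phen == "case"] <- rbinom(sum(fem & phen == "case"), 2, 0.5)
    g[1, fem & phen == "control"] <-
        2L * rbinom(sum(fem & phen == "control"), 1, 0.5)
    g[1, !fem] <- 2L * rbinom(sum(!fem), 1, 0.5)
    g[2, ] <- rbinom(n, 2, 0.4)   # row 2: ordinary autosomal HWE variant
    ds <- makeDs(g, chrom = c("X", "1"), sex = sex, phen = phen)
    out <- filterVariants(ds, runConfig())
    rv <- removedVariants(out$report)
    expect_true("v1" %in% rv$variant_id[rv$reason == "hwe"])
})

test_that("runQC composes the filters and reports per-reason counts", {
    spec <- simSpec(60, 60, 600, n_x_variants = 60,
                    maf_range = c(0.2, 0.5),
                    n_monomorphic = 4, n_hwe_violators = 2,
                    n_high_missing = 3, high_missing_rate = 0.2,
                    n_related_pairs = 1,
                    n_sex_mismatches = 2, missing_rate = 0.001, seed = 77)
    ds <- simulateCohort(spec)
    cfg <- runConfig(relatedness_maf_min = 0.3, relatedness_n_snps = 1000L)
    res <- runQC(ds, cfg)
    cnt <- qcCounts(res$report)
    expect_equal(unname(cnt["sex_mismatch"]), 2L)
    expect_equal(unname(cnt["related"]), 1L)
    expect_equal(unname(cnt["monomorphic"]), 4L)
    expect_equal(unname(cnt["variant_missingness"]), 3L)
    # report tables are consistent with the counts
    expect_equal(nrow(removedSamples(res$report)),
                 sum(cnt[c("sex_mismatch", "sample_missingness", "related")]))
    # each removed variant appears once per reason, removed once
    expect_false(any(duplicated(
        removedVariants(res$report)[c("variant_id", "reason")])))
    dir <- tempfile(); on.exit(unlink(dir, recursive = TRUE))
    writeQCReport(res$report, dir)
    expect_true(file.exists(file.path(dir, "qc_summary.json")))
    js <- jsonlite::read_json(file.path(dir, "qc_summary.json"))
    expect_equal(js$counts$monomorphic, 4L)
})
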