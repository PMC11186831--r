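test_that("coanalyze scores reference, contrast and unknown subjects", {
    pops <- data.frame(label = c("refA", "conB"), n = c(40, 40),
                       fst = c(0, 0.2))
    panels <- simulateReferencePanels(pops, 1500, seed = 61)
    spec <- simSpec(25, 25, 1500, n_x_variants = 0, missing_rate = 0,
                    maf_range = c(0.05, 0.5), seed = 62)
    study <- simulateCohort(spec)
    # shared variant ids by construction (var1..var1500)
    co <- suppressWarnings(coanalyze(panels$refA, panels$conB, study, K = 2))
    expect_equal(nrow(co$scores), 40 + 40 + 50)
    expect_identical(unique(co$roles),
                     c("reference", "contrast", "unknown"))
    # the two panels separate along the leading component
    pc1 <- co$scores[, 1]
    expect_gt(mean(pc1[co$roles == "reference"]),
              mean(pc1[co$roles == "contrast"]))
    expect_error(coanalyze(panels$refA, panels$conB,
                           subsetDataset(study, variants = character(0))))
})

test_that("selectHomogeneous keeps the chi-square ellipse", {
    set.seed(63)
    ref <- matrix(rnorm(400 * 2), 400, 2)
    out <- matrix(rnorm(20 * 2, mean = 8), 20, 2)
    scores <- rbind(ref, out)
    rownames(scores) <- paste0("p", seq_len(nrow(scores)))
    mask <- c(rep(TRUE, 400), rep(FALSE, 20))
    sel <- selectHomogeneous(scores, mask, alpha = 0.2)
    expect_equal(sel@threshold, qchisq(0.8, df = 2))
    keptRef <- mean(rownames(scores)[mask] %in% keptSubjects(sel))
    expect_gt(keptRef, 0.72); expect_lt(keptRef, 0.88)
    expect_true(all(paste0("p", 401:420) %in% excludedSubjects(sel)))
    # kept/excluded partition the subjects
    expect_setequal(c(keptSubjects(sel), excludedSubjects(sel)),
                    rownames(scores))
})

test_that("smaller alpha keeps a superset (nested ellipses)", {
    set.seed(64)
    scores <- matrix(rnorm(300 * 3), 300, 3)
    rownames(scores) <- paste0("q", 1:300)
    mask <- rep(TRUE, 300)
    k10 <- keptSubjects(selectHomogeneous(scores, mask, alpha = 0.10))
    k30 <- keptSubjects(selectHomogeneous(scores, mask, alpha = 0.30))
    expect_true(all(k30 %in% k10))
    expect_gt(length(k10), length(k30))
})

test_that("k-means path selects the dominant reference cluster", {
    set.seed(65)
    main <- matrix(rnorm(120 * 2, 0, 0.5), 120, 2)
    minor <- matrix(rnorm(30 * 2, 6, 0.5), 30, 2)
    scores <- rbind(main, minor)
    rownames(scores) <- paste0("r", 1:150)
    sel <- selectHomogeneous(scores, rep(TRUE, 150), alpha = 0.2, k = 2)
    expect_lt(sqrt(sum(sel@center^2)), 1)       # centred on the main cluster
    expect_true(all(paste0("r", 121:150) %in% excludedSubjects(sel)))
    expect_error(selectHomogeneous(scores[1:15, ], rep(TRUE, 15), k = 2),
                 "reference subjects")
})

test_that("balanceSex reaches a sex odds ratio of 1 by reducing one class", {
    samples <- data.frame(
        sample_id = sprintf("b%03d", 1:60),
        sex_reported = c(rep("male", 30), rep("female", 10),
                         rep("male", 10), rep("female", 10)),
        phenotype = rep(c("case", "control"), c(40, 20)),
        stringsAsFactors = FALSE)
    bal <- balanceSex(samples, seed = 2)
    cnt <- table(bal$phenotype, bal$sex_reported)
    orAfter <- (cnt["case", "male"] / cnt["case", "female"]) /
        (cnt["control", "male"] / cnt["control", "female"])
    expect_equal(orAfter, 1)
    # only case males were reduced (controls untouched)
    expect_equal(unname(cnt["control", "male"]), 10)
    expect_equal(unname(cnt["control", "female"]), 10)
    expect_equal(unname(cnt["case", "female"]), 10)
    expect_equal(unname(cnt["case", "male"]), 10)
})

test_that("balanceSex is deterministic under a seed and warns when OR=1 is unreachable", {
    samples <- data.frame(
        sample_id = sprintf("c%03d", 1:23),
        sex_reported = c(rep("male", 7), rep("female", 3),
                         rep("male", 6), rep("female", 7)),
        phenotype = rep(c("case", "control"), c(10, 13)),
        stringsAsFactors = FALSE)
    expect_warning(b1 <- balanceSex(samples, seed = 5), "closest integer")
    b2 <- suppressWarnings(balanceSex(samples, seed = 5))
    expect_identical(b1$sample_id, b2$sample_id)
    bad <- samples; bad$sex_reported[bad$phenotype == "control"] <- "male"
    expect_error(balanceSex(bad), "both sexes")
})
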