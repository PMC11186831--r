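test_that("ldExpand finds proxies by squared dosage correlation", {
    set.seed(71)
    n <- 300
    seed <- rbinom(n, 2, 0.4)
    dup <- seed                               # identical copy: r2 = 1
    flip <- seed
    swap <- sample(n, 60)                     # ~20% perturbed copy
    flip[swap] <- rbinom(60, 2, 0.4)
    indep <- rbinom(n, 2, 0.4)                # independent variant
    far <- seed                               # perfect LD but 2 Mb away
    g <- rbind(seed, dup, flip, indep, far)
    ds <- makeDs(g)
    rowData(ds)$pos <- c(1e5, 1.1e5, 1.2e5, 1.3e5, 2.1e6)
    out <- ldExpand(ds, "v1", r2Min = 0.6, windowBp = 1e6)
    expect_true(all(c("v1", "v2") %in% out$proxy_id))
    expect_equal(out$r2[out$proxy_id == "v1"], 1)
    expect_equal(out$r2[out$proxy_id == "v2"], 1)
    expect_false("v4" %in% out$proxy_id)      # independent: r2 near 0
    expect_false("v5" %in% out$proxy_id)      # outside the 1 Mb window
    # the flipped copy's r2 equals the direct correlation computation
    r2flip <- cor(seed, flip)^2
    if (r2flip >= 0.6)
        expect_equal(out$r2[out$proxy_id == "v3"], r2flip)
    expect_warning(ldExpand(ds, c("v1", "ghost")), "absent")
})

test_that("LD proxy relation is symmetric", {
    set.seed(72)
    g <- rHweMatrix(6, 200, 0.3)
    g[2, ] <- g[1, ]; g[2, sample(200, 20)] <- rbinom(20, 2, 0.3)
    ds <- makeDs(g)
    a <- ldExpand(ds, "v1", r2Min = 0.3)
    b <- ldExpand(ds, "v2", r2Min = 0.3)
    expect_equal("v2" %in% a$proxy_id, "v1" %in% b$proxy_id)
})

test_that("collectEvidence applies the strict window and promoter rules", {
    genes <- data.frame(
        gene_id = c("IN", "NEAR", "FAR", "PROM_P", "PROM_M"),
        chrom = "1",
        start = c(1000, 60000, 200000, 500000, 600000),
        end = c(5000, 70000, 210000, 510000, 610000),
        strand = c("+", "+", "+", "+", "-"), stringsAsFactors = FALSE)
    px <- function(pos) data.frame(seed_id = "s", proxy_id = paste0("p", pos),
                                   r2 = 1, chrom = "1", pos = pos)
    # inside the gene body: distance 0, proximity 1
    ev <- collectEvidence(px(2000), genes)
    expect_equal(ev$distance[ev$gene_id == "IN"], 1)
    # 39,999 bp away: present; 40,001 bp away: absent (strict <)
    evNear <- collectEvidence(px(60000 - 39999), genes)
    expect_true("NEAR" %in% evNear$gene_id)
    evOut <- collectEvidence(px(200000 - 40001), genes)
    expect_false("FAR" %in% evOut$gene_id)
    expect_true("FAR" %in% collectEvidence(px(200000 - 39999), genes)$gene_id)
    # promoter (windowBp shrunk so only the promoter rule can apply):
    # 500 bp upstream of a plus-strand TSS is in the promoter ...
    evP <- collectEvidence(px(500000 - 500), genes, windowBp = 100)
    expect_true("PROM_P" %in% evP$gene_id)
    # ... but 500 bp beyond the 3' end of the same gene is not
    evQ <- collectEvidence(px(510000 + 500), genes, windowBp = 100)
    expect_false("PROM_P" %in% evQ$gene_id)
    # minus-strand promoter sits beyond the higher genomic coordinate
    evM <- collectEvidence(px(610000 + 500), genes, windowBp = 100)
    expect_true("PROM_M" %in% evM$gene_id)
    expect_false("PROM_M" %in%
                 collectEvidence(px(600000 - 500), genes,
                                 windowBp = 100)$gene_id)
    # unknown strand: promoter on both sides, with a warning
    gU <- genes; gU$strand[4] <- NA
    expect_warning(evU <- collectEvidence(px(510000 + 500), gU,
                                          windowBp = 100), "strand")
    expect_true("PROM_P" %in% evU$gene_id)
})

test_that("evidence records create rows and fill the axes", {
    genes <- data.frame(gene_id = "G", chrom = "2", start = 5e6,
                        end = 5.01e6, strand = "+")
    px <- data.frame(seed_id = "s", proxy_id = "v", r2 = 1,
                     chrom = "2", pos = 1000)   # ~5 Mb away
    qtl <- data.frame(variant_id = "v", gene_id = "G", score = 0.8)
    vep <- data.frame(variant_id = "v", gene_id = "G",
                      consequence = "missense_variant")
    ev <- collectEvidence(px, genes, vep = vep, qtl = qtl)
    expect_equal(nrow(ev), 1)
    expect_equal(ev$qtl, 0.8)
    expect_equal(ev$functional, 0.7)            # missense severity
    expect_equal(ev$distance, 0)                # beyond the window
    expect_equal(ev$chromatin, 0)               # absent evidence
    # no evidence and no proximity: no row at all
    expect_equal(nrow(collectEvidence(px, genes)), 0)
})

test_that("topsisScore matches the fixed-anchor hand computation", {
    rows <- data.frame(
        seed_id = "s", variant_id = paste0("v", 1:3),
        gene_id = c("A", "A", "B"),
        functional = c(1, 0, 0), qtl = c(1, 1, 0),
        distance = c(1, 1, 0), chromatin = c(1, 0, 0))
    ts <- topsisScore(rows)
    sc <- ts$pairs$score[match(paste0("v", 1:3), ts$pairs$variant_id)]
    expect_equal(sc[1], 1)                      # ideal row
    expect_equal(sc[3], 0)                      # anti-ideal row
    # row (0,1,1,0): d- = sqrt(.35^2+.2^2), d+ = sqrt(.35^2+.1^2)
    dm <- sqrt(0.35^2 + 0.2^2); dp <- sqrt(0.35^2 + 0.1^2)
    expect_equal(sc[2], dm / (dp + dm), tolerance = 1e-12)
    expect_equal(round(sc[2], 4), 0.5255)
    # per-gene max aggregation and the 0.4 pass rule
    genes <- ts$genes
    expect_equal(genes$score[genes$gene_id == "A"], 1)
    expect_identical(genes$pass, c(TRUE, FALSE))
    expect_error(topsisScore(rows, weights = c(functional = 1, qtl = 1,
                                               distance = 0, chromatin = 0)),
                 "sum to 1")
})

test_that("TOPSIS is monotone and matches the independent oracle", {
    set.seed(73)
    X <- matrix(runif(400 * 4), 400, 4,
                dimnames = list(NULL, c("functional", "qtl",
                                        "distance", "chromatin")))
    rows <- data.frame(seed_id = "s", variant_id = paste0("v", 1:400),
                       gene_id = paste0("g", 1:400), X)
    w <- c(functional = 0.35, qtl = 0.35, distance = 0.2, chromatin = 0.1)
    sc <- topsisScore(rows)$pairs
    sc <- sc$score[match(rows$variant_id, sc$variant_id)]
    expect_equal(sc, oracleTopsis(X, w), tolerance = 1e-10)
    # monotonicity on random increase pairs
    for (i in 1:200) {
        j <- sample(400, 1); ax <- sample(4, 1)
        X2 <- X[j, , drop = FALSE]
        X2[1, ax] <- min(1, X2[1, ax] + runif(1, 0, 1 - X2[1, ax] + 1e-12))
        r2 <- rows[j, ]; r2[1, c("functional", "qtl", "distance",
                                 "chromatin")] <- X2
        s2 <- topsisScore(r2)$pairs$score
        expect_gte(s2 + 1e-12, sc[j])
    }
})

test_that("tractability takes the max term score and rejects unknowns", {
    tab <- tractabilityTerms()
    expect_equal(unname(tab["Approved Drug"]), 1)
    expect_equal(unname(tab["Druggable Family"]), 0.1)
    ann <- data.frame(gene_id = c("g1", "g1", "g2"),
                      term = c("Approved Drug", "Med-Quality Pocket",
                               "Druggable Family"))
    ts <- tractabilityScore(ann, geneIds = c("g1", "g2", "g3"))
    expect_equal(ts$tractability, c(1, 0.1, 0))
    expect_identical(ts$best_term[1], "Approved Drug")
    expect_true(is.na(ts$best_term[3]))
    bad <- data.frame(gene_id = "g", term = "Magic Beans")
    err <- tryCatch(tractabilityScore(bad), error = conditionMessage)
    expect_match(err, "Magic Beans")
    expect_match(err, "Approved Drug")          # lists the valid terms
})

test_that("simulated evidence recovers the planted gene", {
    set.seed(74)
    genes <- data.frame(
        gene_id = paste0("G", 1:6), chrom = "1",
        start = seq(1e5, 6e5, by = 1e5),
        end = seq(1e5, 6e5, by = 1e5) + 2e4,
        strand = rep(c("+", "-"), 3), stringsAsFactors = FALSE)
    hits <- 0; tries <- 20
    for (s in seq_len(tries)) {
        snps <- data.frame(variant_id = "lead", chrom = "1",
                           pos = sample(seq(1e5, 6.2e5, by = 1), 1))
        sim <- simulateEvidence(genes, snps, seed = s)
        if (!nrow(sim$truth)) next
        prox <- data.frame(seed_id = "lead", proxy_id = "lead", r2 = 1,
                           chrom = "1", pos = snps$pos)
        ev <- collectEvidence(prox, genes, vep = sim$vep, qtl = sim$qtl,
                              chromatin = sim$chromatin)
        top <- topsisScore(ev)$genes$gene_id[1]
        hits <- hits + (top == sim$truth$gene_id[1])
    }
    expect_gte(hits / tries, 0.95)
})
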