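## SNP-to-gene mapping and prioritisation.  Seed SNPs are expanded with
## their LD proxies, candidate genes collected from positional and
## functional evidence, and each SNP-gene pair ranked by TOPSIS against
## a fixed ideal: the closer a pair sits to an (impossible) pair with
## full marks on every evidence axis, and the further from one with
## none, the higher its score.

#' Expand seed SNPs with linkage-disequilibrium proxies
#'
#' For each seed SNP, every variant within \code{windowBp} on the same
#' chromosome whose squared Pearson correlation of genotype dosages with
#' the seed (pairwise-complete observations) is at least \code{r2Min}
#' is returned as a proxy.  The seed is its own proxy with r2 = 1.
#'
#' @param dataset a \linkS4class{GenotypeDataset} providing the dosages.
#' @param seedIds character vector of seed variant ids.
#' @param r2Min LD threshold (default 0.6).
#' @param windowBp physical window around the seed (default 1e6).
#' @return data.frame: \code{seed_id}, \code{proxy_id}, \code{r2},
#'   \code{chrom}, \code{pos} (proxy coordinates).
#' @export
ldExpand <- function(dataset, seedIds, r2Min = 0.6, windowBp = 1e6) {
    stopifnot(is(dataset, "GenotypeDataset"))
    rd <- as.data.frame(rowData(dataset))
    g <- genotypes(dataset)
    missing <- setdiff(seedIds, rd$variant_id)
    if (length(missing))
        warning("seed variant(s) absent from the dataset: ",
                paste(missing, collapse = ", "))
    out <- NULL
    for (sid in intersect(seedIds, rd$variant_id)) {
        i <- match(sid, rd$variant_id)
        near <- which(rd$chrom == rd$chrom[i] &
                      abs(rd$pos - rd$pos[i]) <= windowBp)
        r2 <- vapply(near, function(j) {
            if (j == i) return(1)
            r <- suppressWarnings(
                stats::cor(g[i, ], g[j, ], use = "pairwise.complete.obs"))
            if (is.na(r)) 0 else r^2
        }, numeric(1))
        keep <- near[r2 >= r2Min | near == i]
        out <- rbind(out, data.frame(
            seed_id = sid, proxy_id = rd$variant_id[keep],
            r2 = r2[match(keep, near)], chrom = rd$chrom[keep],
            pos = rd$pos[keep], stringsAsFactors = FALSE))
    }
    if (is.null(out))
        out <- data.frame(seed_id = character(0), proxy_id = character(0),
                          r2 = numeric(0), chrom = character(0),
                          pos = numeric(0))
    rownames(out) <- NULL
    out
}

#' Variant consequence severity scale
#'
#' Fixed map from sequence-ontology consequence terms to a functional
#' severity in [0, 1], used as the functional axis of the TOPSIS
#' decision matrix.  Unknown terms score 0.
#'
#' @return named numeric vector.
#' @export
consequenceSeverity <- function() {
    c(stop_gained = 0.95, stop_lost = 0.9, frameshift_variant = 0.95,
      splice_acceptor_variant = 0.9, splice_donor_variant = 0.9,
      start_lost = 0.9, missense_variant = 0.7,
      inframe_insertion = 0.6, inframe_deletion = 0.6,
      splice_region_variant = 0.5, synonymous_variant = 0.2,
      `5_prime_UTR_variant` = 0.3, `3_prime_UTR_variant` = 0.3,
      upstream_gene_variant = 0.15, downstream_gene_variant = 0.15,
      intron_variant = 0.1, intergenic_variant = 0.05,
      regulatory_region_variant = 0.3, non_coding_transcript_variant = 0.1)
}

#' Collect per-pair evidence for candidate SNP-gene assignments
#'
#' Candidate genes for a (proxy) SNP are those whose body lies strictly
#' within \code{windowBp} of the SNP, or whose strand-aware promoter
#' (\code{promoterBp} upstream of the transcription start) contains it.
#' A functional, QTL or chromatin record linking the SNP to a gene also
#' creates a row regardless of distance (the distance axis is then 0
#' beyond the window).  Genes with an unknown strand get a promoter on
#' both sides (with a warning).  Four evidence axes in [0, 1] are returned per pair:
#' \describe{
#'   \item{functional}{consequence severity of the most severe VEP
#'     annotation of the SNP in the gene (see
#'     \code{\link{consequenceSeverity}}).}
#'   \item{qtl}{the strongest molecular-QTL colocalisation score linking
#'     the SNP to the gene.}
#'   \item{distance}{linear proximity \code{max(0, 1 - d / windowBp)}
#'     where d is the distance to the gene body (0 inside the gene).}
#'   \item{chromatin}{the strongest chromatin-interaction score linking
#'     the SNP to the gene's region.}
#' }
#'
#' @param proxies data.frame from \code{\link{ldExpand}} (or any frame
#'   with \code{seed_id}, \code{proxy_id}, \code{chrom}, \code{pos}).
#' @param genes data.frame: \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand} (\code{"+"}/\code{"-"}).
#' @param vep data.frame \code{variant_id}, \code{gene_id},
#'   \code{consequence}, or NULL.
#' @param qtl data.frame \code{variant_id}, \code{gene_id},
#'   \code{score}, or NULL.
#' @param chromatin data.frame \code{variant_id}, \code{gene_id},
#'   \code{score}, or NULL.
#' @param windowBp gene window (default 40000).
#' @param promoterBp promoter extension upstream of the TSS (default
#'   1000).
#' @return data.frame: \code{seed_id}, \code{variant_id},
#'   \code{gene_id}, \code{functional}, \code{qtl}, \code{distance},
#'   \code{chromatin}.
#' @export
collectEvidence <- function(proxies, genes, vep = NULL, qtl = NULL,
                            chromatin = NULL, windowBp = 40000,
                            promoterBp = 1000) {
    proxies <- as.data.frame(proxies)
    genes <- as.data.frame(genes)
    if (is.null(genes$strand)) genes$strand <- NA_character_
    sev <- consequenceSeverity()
    if (any(is.na(genes$strand) |
            !genes$strand %in% c("+", "-")))
        warning("gene(s) with unknown strand: promoter applied on both ",
                "sides")
    out <- NULL
    evGenes <- function(vid) unique(c(
        if (!is.null(vep)) vep$gene_id[vep$variant_id == vid],
        if (!is.null(qtl)) qtl$gene_id[qtl$variant_id == vid],
        if (!is.null(chromatin))
            chromatin$gene_id[chromatin$variant_id == vid]))
    for (r in seq_len(nrow(proxies))) {
        vid <- proxies$proxy_id[r]
        pos <- proxies$pos[r]
        d <- ifelse(genes$chrom == proxies$chrom[r],
                    pmax(genes$start - pos, pos - genes$end, 0), Inf)
        inProm <- genes$chrom == proxies$chrom[r] & mapply(
            function(s, e, st) {
                if (identical(st, "+")) pos >= s - promoterBp && pos < s
                else if (identical(st, "-")) pos > e && pos <= e + promoterBp
                else (pos >= s - promoterBp && pos < s) ||
                     (pos > e && pos <= e + promoterBp)
            }, genes$start, genes$end, genes$strand)
        ## positional rule OR any evidence record linking variant and gene
        keep <- d < windowBp | inProm | genes$gene_id %in% evGenes(vid)
        if (!any(keep)) next
        cand <- genes[keep, , drop = FALSE]
        dk <- d[keep]
        lookup <- function(tab, val = "score") {
            if (is.null(tab) || !nrow(tab)) return(rep(0, nrow(cand)))
            vapply(cand$gene_id, function(g) {
                rows <- tab$variant_id == vid & tab$gene_id == g
                if (!any(rows)) return(0)
                if (val == "consequence")
                    max(sev[match(tab$consequence[rows], names(sev))],
                        0, na.rm = TRUE)
                else max(tab$score[rows])
            }, numeric(1), USE.NAMES = FALSE)
        }
        out <- rbind(out, data.frame(
            seed_id = proxies$seed_id[r], variant_id = vid,
            gene_id = cand$gene_id,
            functional = lookup(vep, "consequence"),
            qtl = pmin(pmax(lookup(qtl), 0), 1),
            distance = pmax(0, 1 - dk / windowBp),
            chromatin = pmin(pmax(lookup(chromatin), 0), 1),
            stringsAsFactors = FALSE))
    }
    if (is.null(out))
        out <- data.frame(seed_id = character(0), variant_id = character(0),
                          gene_id = character(0), functional = numeric(0),
                          qtl = numeric(0), distance = numeric(0),
                          chromatin = numeric(0))
    rownames(out) <- NULL
    out
}

#' TOPSIS prioritisation of SNP-gene pairs
#'
#' Each evidence row is scored by similarity to a fixed ideal
#' alternative with value 1 on every axis and a fixed anti-ideal with
#' value 0 (the axes are already on a common [0, 1] scale, so no
#' data-dependent normalisation is applied and scores are comparable
#' across analyses).  The axes are multiplied by their weights (the
#' classical TOPSIS weighted matrix) and plain Euclidean distances to
#' the weighted ideal and anti-ideal are taken,
#' \eqn{d^+ = \sqrt{\sum_j w_j^2 (1 - x_j)^2}} and
#' \eqn{d^- = \sqrt{\sum_j w_j^2 x_j^2}}; the closeness score is
#' \eqn{d^- / (d^+ + d^-)}: 1 at the ideal, 0 at the anti-ideal, and
#' strictly increasing in every axis.  An all-zero row scores 0.
#' Per-gene scores are the maximum over that gene's pairs.
#'
#' @param evidence data.frame from \code{\link{collectEvidence}}.
#' @param weights named axis weights (must sum to 1); default
#'   functional 0.35, qtl 0.35, distance 0.2, chromatin 0.1.
#' @param passMin per-gene score threshold for the \code{pass} flag
#'   (default 0.4).
#' @return list: \code{pairs} (the evidence with a \code{score} column,
#'   sorted decreasing), \code{genes} (\code{gene_id}, \code{score},
#'   \code{best_variant}, \code{pass}, sorted decreasing).
#' @export
topsisScore <- function(evidence,
                        weights = c(functional = 0.35, qtl = 0.35,
                                    distance = 0.2, chromatin = 0.1),
                        passMin = 0.4) {
    evidence <- as.data.frame(evidence)
    axes <- names(weights)
    if (!all(axes %in% colnames(evidence)))
        stop("evidence must contain the axis columns: ",
             paste(axes, collapse = ", "))
    if (abs(sum(weights) - 1) > 1e-8)
        stop("weights must sum to 1")
    X <- as.matrix(evidence[, axes, drop = FALSE])
    if (any(!is.finite(X)) || any(X < 0 | X > 1))
        stop("evidence axes must lie in [0, 1]")
    W <- matrix(weights, nrow(X), length(axes), byrow = TRUE)
    dPlus <- sqrt(rowSums((W * (1 - X))^2))
    dMinus <- sqrt(rowSums((W * X)^2))
    score <- ifelse(dPlus + dMinus == 0, 0, dMinus / (dPlus + dMinus))
    pairs <- evidence
    pairs$score <- score
    pairs <- pairs[order(-pairs$score), , drop = FALSE]
    rownames(pairs) <- NULL
    genes <- if (nrow(pairs)) {
        byGene <- split(seq_len(nrow(pairs)), pairs$gene_id)
        g <- do.call(rbind, lapply(byGene, function(ii) {
            top <- ii[which.max(pairs$score[ii])]
            data.frame(gene_id = pairs$gene_id[top],
                       score = pairs$score[top],
                       best_variant = pairs$variant_id[top],
                       stringsAsFactors = FALSE)
        }))
        g$pass <- g$score >= passMin
        g <- g[order(-g$score), , drop = FALSE]
        rownames(g) <- NULL
        g
    } else data.frame(gene_id = character(0), score = numeric(0),
                      best_variant = character(0), pass = logical(0))
    list(pairs = pairs, genes = genes)
}

#' Target tractability term scores
#'
#' Fixed map from tractability evidence terms to scores in [0, 1]; a
#' gene's tractability is the maximum score over its terms
#' (\code{\link{tractabilityScore}}).
#'
#' @return named numeric vector.
#' @export
tractabilityTerms <- function() {
    c("Approved Drug" = 1,
      "Advanced Clinical" = 0.9,
      "Phase 1 Clinical" = 0.8,
      "Structure with Ligand" = 0.5,
      "UniProt loc high conf" = 0.5,
      "Literature" = 0.5,
      "GO CC high conf" = 0.45,
      "High-Quality Ligand" = 0.4,
      "UniProt loc med conf" = 0.4,
      "UniProt Ubiquitination" = 0.4,
      "High-Quality Pocket" = 0.3,
      "UniProt SigP or TMHMM" = 0.3,
      "Database Ubiquitination" = 0.3,
      "Med-Quality Pocket" = 0.2,
      "GO CC med conf" = 0.2,
      "Half-life Data" = 0.2,
      "Druggable Family" = 0.1,
      "Human Protein Atlas loc" = 0.1,
      "Small Molecule Binder" = 0.1)
}

#' Score gene tractability
#'
#' @param annotations data.frame with columns \code{gene_id} and
#'   \code{term}; terms must come from \code{\link{tractabilityTerms}}.
#' @param geneIds genes to score (default: those annotated); genes with
#'   no annotation score 0.
#' @return data.frame \code{gene_id}, \code{tractability},
#'   \code{best_term} (NA when unannotated).
#' @export
tractabilityScore <- function(annotations, geneIds = NULL) {
    annotations <- as.data.frame(annotations)
    tab <- tractabilityTerms()
    bad <- setdiff(unique(annotations$term), names(tab))
    if (length(bad))
        stop("unknown tractability term(s): ",
             paste(bad, collapse = ", "), "; valid terms are: ",
             paste(names(tab), collapse = ", "))
    if (is.null(geneIds)) geneIds <- unique(annotations$gene_id)
    res <- data.frame(gene_id = geneIds, tractability = 0,
                      best_term = NA_character_, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(res))) {
        terms <- annotations$term[annotations$gene_id == res$gene_id[r]]
        if (length(terms)) {
            sc <- tab[terms]
            res$tractability[r] <- max(sc)
            res$best_term[r] <- terms[which.max(sc)]
        }
    }
    res
}
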