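#' Construct a GenotypeDataset
#'
#' @param genotypes integer/numeric matrix of genotype codes, variants in
#'   rows and samples in columns (alt-allele dosage 0/1/2 for SNPs, category
#'   index for categorical variables, \code{NA} missing).
#' @param variants data.frame (or DataFrame) with columns \code{variant_id},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}; optional
#'   \code{is_categorical} and \code{n_categories} (defaulted for SNPs).
#' @param samples data.frame with columns \code{sample_id},
#'   \code{sex_reported}, \code{phenotype}; further columns (e.g.
#'   \code{centre}, \code{population}) are kept.
#' @param callProb optional same-shape matrix of call probabilities; when
#'   supplied together with \code{callProbMin}, genotypes below the minimum
#'   are set to missing.
#' @param callProbMin minimum acceptable call probability (default
#'   \code{NULL}: no masking at construction).
#' @return a \linkS4class{GenotypeDataset}.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L), nrow = 2, byrow = TRUE)
#' v <- data.frame(variant_id = c("v1", "v2"), chrom = "1",
#'                 pos = c(100L, 200L), ref = "A", alt = "G")
#' s <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                 sex_reported = "female",
#'                 phenotype = c("case", "control", "control"))
#' gd <- GenotypeDataset(g, v, s)
#' dim(gd)
#' @export
GenotypeDataset <- function(genotypes, variants, samples,
                            callProb = NULL, callProbMin = NULL) {
    variants <- as.data.frame(variants)
    samples <- as.data.frame(samples)
    if (is.null(variants$is_categorical))
        variants$is_categorical <- FALSE
    if (is.null(variants$n_categories))
        variants$n_categories <- 3L
    variants$n_categories <- ifelse(variants$is_categorical,
                                    variants$n_categories, 3L)
    genotypes <- as.matrix(genotypes)
    storage.mode(genotypes) <- "integer"
    if (nrow(genotypes) != nrow(variants) ||
        ncol(genotypes) != nrow(samples))
        stop("genotype matrix dimensions do not match variant/sample frames")
    dimnames(genotypes) <- list(variants$variant_id, samples$sample_id)
    assays <- list(genotype = genotypes)
    if (!is.null(callProb)) {
        callProb <- as.matrix(callProb)
        if (!all(dim(callProb) == dim(genotypes)))
            stop("callProb dimensions do not match the genotype matrix")
        dimnames(callProb) <- dimnames(genotypes)
        if (!is.null(callProbMin)) {
            mask <- !is.na(callProb) & callProb < callProbMin
            genotypes[mask] <- NA_integer_
            assays$genotype <- genotypes
        }
        assays$callProb <- callProb
    }
    se <- SummarizedExperiment(assays = assays,
                               rowData = DataFrame(variants),
                               colData = DataFrame(samples))
    new("GenotypeDataset", se)
}

#' @describeIn GenotypeDataset genotype code matrix (variants x samples).
#' @param x a GenotypeDataset.
#' @export
genotypes <- function(x) assay(x, "genotype")

#' @describeIn GenotypeDataset call-probability matrix or NULL.
#' @export
callProb <- function(x) {
    if ("callProb" %in% assayNames(x)) assay(x, "callProb") else NULL
}

#' @describeIn GenotypeDataset per-sample phenotype ("case"/"control"/NA).
#' @export
phenotype <- function(x) as.character(colData(x)$phenotype)

#' @describeIn GenotypeDataset per-sample reported sex.
#' @export
reportedSex <- function(x) as.character(colData(x)$sex_reported)

#' @describeIn GenotypeDataset sample identifiers.
#' @export
sampleIds <- function(x) as.character(colData(x)$sample_id)

#' @describeIn GenotypeDataset variant identifiers.
#' @export
variantIds <- function(x) as.character(rowData(x)$variant_id)

#' @describeIn GenotypeDataset logical: is the row an X-linked variant?
#' @export
isXLinked <- function(x) {
    rd <- rowData(x)
    !rd$is_categorical & as.character(rd$chrom) %in% c("X", "23", "chrX")
}

setMethod("show", "GenotypeDataset", function(object) {
    cd <- colData(object)
    ph <- table(factor(cd$phenotype, levels = c("case", "control")),
                useNA = "no")
    cat("GenotypeDataset:", nrow(object), "variants x",
        ncol(object), "samples\n")
    cat("  cases:", ph[["case"]], " controls:", ph[["control"]],
        " unlabelled:", sum(is.na(cd$phenotype)), "\n")
    cat("  categorical variables:", sum(rowData(object)$is_categorical),
        " X-linked:", sum(isXLinked(object)), "\n")
    if ("callProb" %in% assayNames(object))
        cat("  call probabilities present\n")
})

setMethod("show", "LBFMatrix", function(object) {
    v <- object@values
    cat("LBFMatrix:", nrow(v), "variables x", ncol(v), "samples",
        sprintf("(range %.3g .. %.3g)\n", min(v), max(v)))
})

setMethod("show", "PCAModel", function(object) {
    cat("PCAModel:", nrow(object@scores), "samples,",
        nrow(object@loadings), "variables, K =",
        length(object@eigenvalues), "\n")
    cat("  eigenvalues:",
        paste(sprintf("%.3f", object@eigenvalues), collapse = ", "), "\n")
    if (length(object@dropped))
        cat("  dropped constant variables:", length(object@dropped), "\n")
})

setMethod("show", "QCReport", function(object) {
    cat("QCReport\n  removed samples:", nrow(object@removedSamples),
        " removed variants:", nrow(object@removedVariants), "\n")
    for (nm in names(object@counts))
        cat(sprintf("    %-12s %d\n", nm, object@counts[[nm]]))
})

setMethod("show", "AncestrySelection", function(object) {
    cat("AncestrySelection: kept", length(object@kept), "of",
        nrow(object@scores), "subjects (alpha =", object@alpha, ")\n")
})

setMethod("show", "PPINetwork", function(object) {
    cat("PPINetwork:", sum(object@nodes$is_seed), "seed genes,",
        sum(!object@nodes$is_seed), "interactors,",
        nrow(object@edges), "edges\n")
})

#' Extract the LBF value matrix
#'
#' @param x an \linkS4class{LBFMatrix}.
#' @param samplesAsRows return samples x variables (analysis orientation)
#'   instead of the container's variants x samples orientation.
#' @return numeric matrix.
#' @export
lbfValues <- function(x, samplesAsRows = FALSE) {
    stopifnot(is(x, "LBFMatrix"))
    if (samplesAsRows) t(x@values) else x@values
}

#' Accessors for PCAModel components
#'
#' \code{pcaScores} returns subject coordinates (samples x K),
#' \code{pcaLoadings} the eigen-scaled variable coordinates
#' (variables x K), \code{pcaEigenvalues} the component eigenvalues.
#'
#' @param x a \linkS4class{PCAModel}.
#' @return matrix or numeric vector.
#' @export
pcaScores <- function(x) { stopifnot(is(x, "PCAModel")); x@scores }

#' @rdname pcaScores
#' @export
pcaLoadings <- function(x) { stopifnot(is(x, "PCAModel")); x@loadings }

#' @rdname pcaScores
#' @export
pcaEigenvalues <- function(x) { stopifnot(is(x, "PCAModel")); x@eigenvalues }

#' Accessors for QCReport
#'
#' @param x a \linkS4class{QCReport}.
#' @return data.frame of removals, or named integer counts.
#' @export
removedSamples <- function(x) { stopifnot(is(x, "QCReport")); x@removedSamples }

#' @rdname removedSamples
#' @export
removedVariants <- function(x) { stopifnot(is(x, "QCReport")); x@removedVariants }

#' @rdname removedSamples
#' @export
qcCounts <- function(x) { stopifnot(is(x, "QCReport")); x@counts }

#' Accessors for AncestrySelection
#'
#' @param x an \linkS4class{AncestrySelection}.
#' @return character vector of subject ids, or the score matrix.
#' @export
keptSubjects <- function(x) { stopifnot(is(x, "AncestrySelection")); x@kept }

#' @rdname keptSubjects
#' @export
excludedSubjects <- function(x) {
    stopifnot(is(x, "AncestrySelection")); x@excluded
}

#' @rdname keptSubjects
#' @export
ancestryScores <- function(x) {
    stopifnot(is(x, "AncestrySelection")); x@scores
}

#' Accessors for PPINetwork
#'
#' @param x a \linkS4class{PPINetwork}.
#' @return data.frame of nodes or edges.
#' @export
networkNodes <- function(x) { stopifnot(is(x, "PPINetwork")); x@nodes }

#' @rdname networkNodes
#' @export
networkEdges <- function(x) { stopifnot(is(x, "PPINetwork")); x@edges }

#' Convert a PPINetwork to an igraph graph
#'
#' @param x a \linkS4class{PPINetwork}.
#' @return an \code{igraph} undirected graph with a logical \code{is_seed}
#'   vertex attribute and a \code{confidence} edge attribute.
#' @export
asIgraph <- function(x) {
    stopifnot(is(x, "PPINetwork"))
    if (!requireNamespace("igraph", quietly = TRUE))
        stop("the igraph package is required for asIgraph()")
    g <- igraph::graph_from_data_frame(
        x@edges, directed = FALSE,
        vertices = data.frame(name = x@nodes$gene_id,
                              is_seed = x@nodes$role == "seed"))
    g
}

#' Subset a GenotypeDataset by sample or variant identifiers
#'
#' @param x a GenotypeDataset.
#' @param samples,variants character vectors of ids to keep (NULL = all).
#' @return a GenotypeDataset.
#' @export
subsetDataset <- function(x, samples = NULL, variants = NULL) {
    stopifnot(is(x, "GenotypeDataset"))
    ri <- if (is.null(variants)) seq_len(nrow(x)) else
        match(variants, variantIds(x))
    ci <- if (is.null(samples)) seq_len(ncol(x)) else
        match(samples, sampleIds(x))
    if (any(is.na(ri))) stop("unknown variant ids in subset")
    if (any(is.na(ci))) stop("unknown sample ids in subset")
    x[ri, ci]
}
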