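#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' GenotypeDataset: a sample-by-variant genotype container
#'
#' Extends \linkS4class{SummarizedExperiment}: rows are variants (or
#' categorical variables such as imputed HLA alleles or collection centres),
#' columns are samples.  The \code{"genotype"} assay holds integer codes:
#' alt-allele dosage 0/1/2 for SNPs (X-linked males take 0/2), or a category
#' index \code{0..k-1} for categorical variables; \code{NA} is missing.  An
#' optional \code{"callProb"} assay holds per-genotype call probabilities in
#' [0, 1].
#'
#' Required \code{rowData} columns: \code{variant_id}, \code{chrom},
#' \code{pos}, \code{ref}, \code{alt}, \code{is_categorical},
#' \code{n_categories}.  Required \code{colData} columns: \code{sample_id},
#' \code{sex_reported} (\code{"male"}, \code{"female"} or \code{"unknown"}),
#' \code{phenotype} (\code{"case"}, \code{"control"} or \code{NA} for
#' reference-panel samples, which may instead carry a \code{population}
#' column).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @aliases GenotypeDataset-class
#' @exportClass GenotypeDataset
setClass("GenotypeDataset", contains = "SummarizedExperiment")

.validGenotypeDataset <- function(object) {
    msg <- NULL
    rd <- rowData(object)
    cd <- colData(object)
    need_rd <- c("variant_id", "chrom", "pos", "ref", "alt",
                 "is_categorical", "n_categories")
    need_cd <- c("sample_id", "sex_reported", "phenotype")
    miss <- setdiff(need_rd, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste("missing rowData columns:",
                            paste(miss, collapse = ", ")))
    miss <- setdiff(need_cd, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste("missing colData columns:",
                            paste(miss, collapse = ", ")))
    if (!"genotype" %in% assayNames(object))
        msg <- c(msg, "assay 'genotype' is required")
    if (is.null(msg)) {
        if (anyDuplicated(rd$variant_id))
            msg <- c(msg, "variant_id values must be unique")
        if (anyDuplicated(cd$sample_id))
            msg <- c(msg, "sample_id values must be unique")
        pos <- rd$pos[!rd$is_categorical]
        if (length(pos) && any(!is.na(pos) & pos < 1))
            msg <- c(msg, "positions of positional variants must be >= 1")
        bad_sex <- !cd$sex_reported %in% c("male", "female", "unknown")
        if (any(bad_sex))
            msg <- c(msg, "sex_reported must be male/female/unknown")
        ph <- cd$phenotype
        if (any(!is.na(ph) & !ph %in% c("case", "control")))
            msg <- c(msg, "phenotype must be case/control or NA")
        g <- assay(object, "genotype")
        k <- ifelse(rd$is_categorical, rd$n_categories, 3L)
        rng <- suppressWarnings(apply(g, 1L, max, na.rm = TRUE))
        rng[!is.finite(rng)] <- 0
        if (any(rng > k - 1L))
            msg <- c(msg, "genotype codes exceed the per-variant category count")
        if ("callProb" %in% assayNames(object)) {
            cp <- assay(object, "callProb")
            if (any(!is.na(cp) & (cp < 0 | cp > 1)))
                msg <- c(msg, "callProb values must lie in [0, 1]")
        }
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("GenotypeDataset", .validGenotypeDataset)

#' LBFMatrix: per-subject, per-variable log Bayes factors
#'
#' Same shape as the source genotype matrix (variants in rows, samples in
#' columns, matching \linkS4class{GenotypeDataset} orientation).  Each cell
#' is the natural-log Bayes factor of that subject's observed category under
#' the case model versus the control model; missing genotypes contribute 0.
#'
#' @slot values numeric matrix, variants x samples, finite everywhere.
#' @slot model the \linkS4class{GenotypeModel} that produced it.
#' @exportClass LBFMatrix
setClass("LBFMatrix",
    representation(values = "matrix", model = "ANY"))

setValidity("LBFMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be numeric")
    if (any(!is.finite(v))) return("LBF values must be finite")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        return("values must carry variant (row) and sample (column) names")
    TRUE
})

#' GenotypeModel: class-conditional category probabilities
#'
#' Per variable and per class (case/control), smoothed category probability
#' vectors: 3 genotype levels for autosomal SNPs, stratified 3-level
#' (female) and 2-level (male) tables for X-linked SNPs, k levels for
#' categorical variables.  Stored slot-wise as matrices (slots x variants)
#' so the LBF transform is a single table lookup.
#'
#' @slot caseProb,controlProb numeric matrices (value slots x variants).
#' @slot slotMap description of the slot layout (list).
#' @slot variantIds character.
#' @slot pseudocount smoothing pseudocount used.
#' @slot pooledFallback variant ids for which a class had zero observations
#'   and the pooled distribution was substituted.
#' @exportClass GenotypeModel
setClass("GenotypeModel",
    representation(caseProb = "matrix", controlProb = "matrix",
                   slotMap = "list", variantIds = "character",
                   pseudocount = "numeric", pooledFallback = "character"))

#' PCAModel: eigen-scaled correlation PCA of an LBF matrix
#'
#' @slot scores numeric matrix, samples x K subject coordinates (U D).
#' @slot loadings numeric matrix, variables x K eigen-scaled variable
#'   coordinates (eigenvector times sqrt(eigenvalue)).
#' @slot eigenvalues length-K, non-increasing, non-negative.
#' @slot center,scale per-variable standardisation constants.
#' @slot dropped ids of constant variables excluded from the fit.
#' @exportClass PCAModel
setClass("PCAModel",
    representation(scores = "matrix", loadings = "matrix",
                   eigenvalues = "numeric", center = "numeric",
                   scale = "numeric", dropped = "character"))

setValidity("PCAModel", function(object) {
    ev <- object@eigenvalues
    if (any(ev < -1e-8)) return("eigenvalues must be non-negative")
    if (is.unsorted(rev(ev), strictly = FALSE) && any(diff(ev) > 1e-8))
        return("eigenvalues must be non-increasing")
    if (ncol(object@scores) != length(ev) ||
        ncol(object@loadings) != length(ev))
        return("scores/loadings/eigenvalues disagree on K")
    TRUE
})

#' AncestrySelection: Mahalanobis-ellipse subject selection
#'
#' @slot scores co-analysis score matrix for all subjects (samples x K).
#' @slot center reference cluster centre (length K).
#' @slot covariance reference cluster covariance (K x K).
#' @slot alpha excluded tail percentile.
#' @slot threshold chi-square cutoff applied to squared distances.
#' @slot mahalanobisSq per-subject squared Mahalanobis distance.
#' @slot kept,excluded subject ids.
#' @exportClass AncestrySelection
setClass("AncestrySelection",
    representation(scores = "matrix", center = "numeric",
                   covariance = "matrix", alpha = "numeric",
                   threshold = "numeric", mahalanobisSq = "numeric",
                   kept = "character", excluded = "character"))

setValidity("AncestrySelection", function(object) {
    ids <- rownames(object@scores)
    if (!setequal(c(object@kept, object@excluded), ids))
        return("kept + excluded must partition the scored subjects")
    if (length(intersect(object@kept, object@excluded)))
        return("kept and excluded overlap")
    TRUE
})

#' PPINetwork: seed genes plus filtered interactors
#'
#' @slot nodes data.frame with columns \code{gene_id}, \code{is_seed}.
#' @slot edges data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{confidence}.
#' @exportClass PPINetwork
setClass("PPINetwork",
    representation(nodes = "data.frame", edges = "data.frame"))

#' QCReport: audit record of univariate quality control
#'
#' @slot removedSamples data.frame (sample_id, reason).
#' @slot removedVariants data.frame (variant_id, reason).
#' @slot counts named integer vector, one entry per reason.
#' @slot thresholds named list of thresholds applied.
#' @exportClass QCReport
setClass("QCReport",
    representation(removedSamples = "data.frame",
                   removedVariants = "data.frame",
                   counts = "integer", thresholds = "list"))

setValidity("QCReport", function(object) {
    rs <- object@removedSamples
    rv <- object@removedVariants
    if (anyDuplicated(paste(rs$sample_id, rs$reason)))
        return("a sample may appear once per reason")
    if (anyDuplicated(paste(rv$variant_id, rv$reason)))
        return("a variant may appear once per reason")
    tab <- c(table(rs$reason), table(rv$reason))
    for (nm in names(tab))
        if (object@counts[[nm]] != tab[[nm]])
            return("counts must equal list lengths")
    TRUE
})
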