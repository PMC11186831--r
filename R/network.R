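## Protein-protein interaction expansion of a prioritised gene set.

#' Expand a seed gene set over a PPI network
#'
#' Keeps interaction edges with confidence at least \code{scoreMin}.
#' Edges between two seed genes are retained unconditionally (after the
#' confidence filter).  A non-seed interactor joins the network only if
#' it has qualifying edges to at least \code{minLinks} distinct seed
#' genes; its edges to those seeds are retained.  Edges between two
#' non-seed genes are never used to admit nodes.
#'
#' @param seeds character vector of seed gene ids.
#' @param edges data.frame: \code{gene_a}, \code{gene_b},
#'   \code{confidence} in [0, 1].
#' @param scoreMin confidence threshold (default 0.5).
#' @param minLinks minimum distinct seed partners for a non-seed
#'   interactor (default 2).
#' @return a \linkS4class{PPINetwork}; nodes carry a \code{role}
#'   (\code{"seed"}/\code{"interactor"}) and \code{degree} column.
#' @export
expandPPI <- function(seeds, edges, scoreMin = 0.5, minLinks = 2L) {
    seeds <- unique(as.character(seeds))
    edges <- as.data.frame(edges)
    stopifnot(all(c("gene_a", "gene_b", "confidence") %in%
                  colnames(edges)))
    e <- edges[edges$confidence >= scoreMin &
               edges$gene_a != edges$gene_b, , drop = FALSE]
    aSeed <- e$gene_a %in% seeds
    bSeed <- e$gene_b %in% seeds
    seedSeed <- e[aSeed & bSeed, , drop = FALSE]
    ## one seed endpoint: candidate interactor on the other side
    half <- rbind(
        data.frame(seed = e$gene_a[aSeed & !bSeed],
                   other = e$gene_b[aSeed & !bSeed],
                   confidence = e$confidence[aSeed & !bSeed],
                   stringsAsFactors = FALSE),
        data.frame(seed = e$gene_b[bSeed & !aSeed],
                   other = e$gene_a[bSeed & !aSeed],
                   confidence = e$confidence[bSeed & !aSeed],
                   stringsAsFactors = FALSE))
    nSeedPartners <- vapply(split(half$seed, half$other),
                            function(s) length(unique(s)), integer(1))
    admitted <- names(nSeedPartners)[nSeedPartners >= minLinks]
    halfKept <- half[half$other %in% admitted, , drop = FALSE]
    keptEdges <- rbind(
        seedSeed[, c("gene_a", "gene_b", "confidence"), drop = FALSE],
        if (nrow(halfKept))
            data.frame(gene_a = halfKept$seed, gene_b = halfKept$other,
                       confidence = halfKept$confidence,
                       stringsAsFactors = FALSE)
        else NULL)
    if (is.null(keptEdges) || !nrow(keptEdges))
        keptEdges <- data.frame(gene_a = character(0),
                                gene_b = character(0),
                                confidence = numeric(0))
    rownames(keptEdges) <- NULL
    nodeIds <- unique(c(seeds, admitted))
    deg <- vapply(nodeIds, function(g)
        sum(keptEdges$gene_a == g | keptEdges$gene_b == g), integer(1))
    nodes <- data.frame(
        gene_id = nodeIds,
        role = ifelse(nodeIds %in% seeds, "seed", "interactor"),
        degree = as.integer(deg), stringsAsFactors = FALSE)
    rownames(nodes) <- NULL
    new("PPINetwork", nodes = nodes, edges = keptEdges)
}
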