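#' Run configuration
#'
#' Bundles every numeric threshold of the pipeline with its default.
#' Defaults follow the published analysis settings: genotypes below a 90%
#' call probability are discarded; samples/variants with more than 5%
#' missingness are removed; Hardy-Weinberg departures in controls below
#' p = 1e-8 are removed; the relatedness scan uses SNPs with MAF above 48%;
#' the ancestry ellipse excludes the alpha = 0.2 tail; 5 principal
#' components are retained; 10,000 label permutations; family-wise alpha
#' 0.05; LD proxies at r^2 >= 0.6; gene mapping within 40 kb of the gene
#' boundary plus a 1 kb promoter; evidence weights 0.35 (functional),
#' 0.35 (QTL), 0.2 (distance), 0.1 (chromatin); TOPSIS pass at >= 0.4;
#' PPI edges at confidence >= 0.5 with interactors linked to >= 2 seed
#' genes.
#'
#' @param ... named overrides of any default listed above.
#' @return a named list of class \code{"RunConfig"}.
#' @examples
#' cfg <- runConfig(n_permutations = 200, seed = 7)
#' cfg$hwe_p_min
#' @export
runConfig <- function(...) {
    cfg <- list(
        call_prob_min = 0.90,
        sample_missing_max = 0.05,
        variant_missing_max = 0.05,
        hwe_p_min = 1e-8,
        relatedness_maf_min = 0.48,
        relatedness_n_snps = 20000L,
        relatedness_identity_min = 0.8,
        sex_het_male_max = 0.02,
        sex_het_female_min = 0.20,
        ancestry_alpha = 0.20,
        ancestry_k = 1L,
        n_components = 5L,
        n_permutations = 10000L,
        fwer_alpha = 0.05,
        pseudocount = 0.5,
        two_sided = FALSE,
        ld_r2_min = 0.6,
        ld_window_bp = 1e6,
        gene_window_bp = 40000L,
        promoter_bp = 1000L,
        evidence_weights = c(functional = 0.35, qtl = 0.35,
                             distance = 0.2, chromatin = 0.1),
        topsis_min = 0.4,
        ppi_score_min = 0.5,
        ppi_min_links = 2L,
        seed = 1L)
    dots <- list(...)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
        stop("unknown configuration fields: ",
             paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
    probs <- c(cfg$call_prob_min, cfg$sample_missing_max,
               cfg$variant_missing_max, cfg$hwe_p_min,
               cfg$relatedness_maf_min, cfg$ancestry_alpha,
               cfg$fwer_alpha, cfg$ld_r2_min, cfg$topsis_min,
               cfg$ppi_score_min)
    if (any(probs < 0 | probs > 1))
        stop("all probability-scale thresholds must lie in [0, 1]")
    if (abs(sum(cfg$evidence_weights) - 1) > 1e-9)
        stop("evidence_weights must sum to 1")
    if (cfg$n_permutations < 1)
        stop("n_permutations must be >= 1")
    class(cfg) <- "RunConfig"
    cfg
}

#' Read a flat key/value configuration file
#'
#' Parses a flat TOML-dialect file: one \code{key = value} assignment per
#' line, \code{#} comments, quoted strings, numbers, \code{true}/\code{false},
#' and arrays like \code{[0.35, 0.35, 0.2, 0.1]} (used for
#' \code{evidence_weights}, in the order functional, qtl, distance,
#' chromatin).  Unknown keys are an error.
#'
#' @param path file path.
#' @param base configuration to override (default \code{runConfig()}).
#' @return a \code{"RunConfig"} list.
#' @export
readRunConfig <- function(path, base = runConfig()) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    vals <- list()
    for (ln in lines) {
        if (!grepl("=", ln, fixed = TRUE))
            stop("malformed config line: ", ln)
        key <- trimws(sub("=.*$", "", ln))
        raw <- trimws(sub("^[^=]*=", "", ln))
        vals[[key]] <- .parseTomlValue(raw, key)
    }
    if (!is.null(vals$evidence_weights))
        names(vals$evidence_weights) <-
            c("functional", "qtl", "distance", "chromatin")
    do.call(runConfig, utils::modifyList(unclass(base), vals))
}

.parseTomlValue <- function(raw, key) {
    if (grepl("^\\[", raw)) {
        inner <- sub("^\\[", "", sub("\\]$", "", raw))
        parts <- trimws(strsplit(inner, ",")[[1]])
        return(vapply(parts, function(p) .parseTomlValue(p, key),
                      numeric(1), USE.NAMES = FALSE))
    }
    if (grepl('^".*"$', raw)) return(gsub('^"|"$', "", raw))
    if (raw %in% c("true", "false")) return(raw == "true")
    num <- suppressWarnings(as.numeric(raw))
    if (is.na(num)) stop("cannot parse config value for ", key, ": ", raw)
    num
}

#' Derive a reproducible sub-seed for a named purpose
#'
#' All randomness in a run flows from one root seed; each stage draws from
#' its own deterministic stream so stages can be regenerated independently.
#'
#' @param seed integer root seed.
#' @param purpose character stream label.
#' @return an integer below 2^31.
#' @export
deriveSeed <- function(seed, purpose) {
    h <- 0
    for (ch in utf8ToInt(purpose)) h <- (h * 131 + ch) %% 2147483647
    as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

.msg <- function(..., verbose = TRUE) {
    if (isTRUE(verbose)) message("[divergene] ", ...)
}

#' Write a result table as TSV
#'
#' Tab-separated UTF-8, one header row, stable column order; numeric
#' columns keep 15 significant digits so a read-back reproduces them.
#'
#' @param table a data.frame (may have zero rows; must have columns).
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeTable <- function(table, path) {
    table <- as.data.frame(table)
    if (ncol(table) == 0)
        stop("refusing to write a table without columns")
    for (j in seq_along(table))
        if (is.numeric(table[[j]]) && !is.integer(table[[j]]))
            table[[j]] <- sprintf("%.15g", table[[j]])
    utils::write.table(table, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE,
                       fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a TSV written by writeTable
#'
#' @param path file path.
#' @return a data.frame.
#' @export
readTable <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "")
}
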