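#' Read genotypes from PLINK, VCF or TSV
#'
#' Genotype codes are alt-allele dosages 0/1/2 (\code{NA} missing).  For
#' PLINK input the A1 allele of the \code{.bim} file is taken as the
#' alternate allele, so homozygous-A1 reads as dosage 2 (the standard
#' PLINK convention).  When a call-probability matrix is available (the GP
#' FORMAT field of a VCF, or the \code{callProb} table of the TSV layout),
#' genotypes whose called-genotype probability falls below
#' \code{callProbMin} are set to missing.
#'
#' @param path file path: a PLINK prefix (or any of the three
#'   \code{.bed/.bim/.fam} paths), a \code{.vcf} file, or a TSV prefix
#'   written by \code{\link{writeGenotypes}}.
#' @param format one of \code{"plink"}, \code{"vcf"}, \code{"tsv"}.
#' @param samples optional data.frame of sample metadata
#'   (\code{sample_id}, \code{sex_reported}, \code{phenotype}, ...) for
#'   formats that do not carry it (VCF); matched by sample id.
#' @param callProbMin genotypes with call probability strictly below this
#'   are set missing (default 0.90; \code{NULL} disables masking).
#' @return a \linkS4class{GenotypeDataset}.
#' @export
readGenotypes <- function(path, format = c("plink", "vcf", "tsv"),
                          samples = NULL, callProbMin = 0.90) {
    format <- match.arg(format)
    switch(format,
           plink = .readPlink(path, callProbMin),
           vcf = .readVcf(path, samples, callProbMin),
           tsv = .readTsv(path, callProbMin))
}

#' Write a GenotypeDataset to PLINK, VCF or TSV
#'
#' @param x a \linkS4class{GenotypeDataset}.
#' @param path output prefix (PLINK/TSV) or \code{.vcf} path.
#' @param format one of \code{"plink"}, \code{"vcf"}, \code{"tsv"}.
#'   Categorical variables can only be represented by the TSV layout.
#' @return invisibly, the path(s) written.
#' @export
writeGenotypes <- function(x, path, format = c("plink", "vcf", "tsv")) {
    format <- match.arg(format)
    if (format != "tsv" && any(rowData(x)$is_categorical))
        stop("categorical variables require format = 'tsv'")
    switch(format,
           plink = .writePlink(x, path),
           vcf = .writeVcf(x, path),
           tsv = .writeTsv(x, path))
}

## ---- PLINK bed/bim/fam -------------------------------------------------

.plinkPrefix <- function(path) sub("\\.(bed|bim|fam)$", "", path)

.readPlink <- function(path, callProbMin) {
    prefix <- .plinkPrefix(path)
    bed <- paste0(prefix, ".bed")
    bim <- paste0(prefix, ".bim")
    fam <- paste0(prefix, ".fam")
    for (f in c(bed, bim, fam))
        if (!file.exists(f)) stop("PLINK file not found: ", f)
    bimTab <- utils::read.table(bim, header = FALSE,
                                stringsAsFactors = FALSE,
        col.names = c("chrom", "variant_id", "cm", "pos", "a1", "a2"))
    if (anyDuplicated(bimTab$variant_id))
        stop("duplicated variant ids in ", bim)
    famTab <- utils::read.table(fam, header = FALSE,
                                stringsAsFactors = FALSE,
        col.names = c("fid", "sample_id", "pat", "mat", "sex", "phen"))
    if (anyDuplicated(famTab$sample_id))
        stop("duplicated sample ids in ", fam)
    n <- nrow(famTab); m <- nrow(bimTab)
    raw <- readBin(bed, "raw", n = file.size(bed))
    if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
        stop("malformed PLINK bed magic in ", bed)
    if (raw[3] != as.raw(0x01))
        stop("only SNP-major PLINK bed files are supported: ", bed)
    bpv <- ceiling(n / 4)
    if (length(raw) - 3 != bpv * m)
        stop("PLINK bed size inconsistent with bim/fam in ", bed)
    body <- matrix(as.integer(raw[-(1:3)]), nrow = bpv, ncol = m)
    ## unpack 2-bit fields (variant-major; samples packed 4 per byte, LSB
    ## first): 00 = hom A1, 01 = missing, 10 = het, 11 = hom A2
    codes <- matrix(NA_integer_, nrow = m, ncol = n)
    lut <- c(2L, NA_integer_, 1L, 0L)
    shift <- c(1L, 4L, 16L, 64L)
    for (i in seq_len(n)) {
        b <- (i - 1L) %/% 4L + 1L
        s <- (i - 1L) %% 4L + 1L
        two <- (body[b, ] %/% shift[s]) %% 4L
        codes[, i] <- lut[two + 1L]
    }
    variants <- data.frame(variant_id = bimTab$variant_id,
                           chrom = as.character(bimTab$chrom),
                           pos = bimTab$pos,
                           ref = bimTab$a2, alt = bimTab$a1,
                           stringsAsFactors = FALSE)
    sexMap <- c("unknown", "male", "female")
    phenMap <- c(NA, "control", "case")
    samples <- data.frame(sample_id = famTab$sample_id,
                          sex_reported = sexMap[
                              ifelse(famTab$sex %in% 1:2, famTab$sex + 1L, 1L)],
                          phenotype = phenMap[
                              ifelse(famTab$phen %in% 1:2, famTab$phen + 1L, 1L)],
                          stringsAsFactors = FALSE)
    GenotypeDataset(codes, variants, samples)
}

.writePlink <- function(x, prefix) {
    g <- genotypes(x)
    rd <- as.data.frame(rowData(x))
    cd <- as.data.frame(colData(x))
    n <- ncol(g); m <- nrow(g)
    bim <- data.frame(rd$chrom, rd$variant_id, 0L, rd$pos, rd$alt, rd$ref)
    utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    sexCode <- c(male = 1L, female = 2L, unknown = 0L)[cd$sex_reported]
    phenCode <- ifelse(is.na(cd$phenotype), -9L,
                       ifelse(cd$phenotype == "case", 2L, 1L))
    fam <- data.frame(cd$sample_id, cd$sample_id, 0L, 0L, sexCode, phenCode)
    utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    bpv <- ceiling(n / 4)
    two <- matrix(1L, nrow = m, ncol = bpv * 4)  # pad = missing (01)
    enc <- c(3L, 2L, 0L)                          # dosage 0,1,2 -> 2-bit
    gi <- g
    two[, seq_len(n)] <- ifelse(is.na(gi), 1L, enc[gi + 1L])
    shift <- c(1L, 4L, 16L, 64L)
    bytes <- matrix(0L, nrow = m, ncol = bpv)
    for (s in 1:4)
        bytes <- bytes + two[, seq.int(s, by = 4, length.out = bpv),
                             drop = FALSE] * shift[s]
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    writeBin(as.raw(t(bytes)), con)
    invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

## ---- VCF ---------------------------------------------------------------

.readVcf <- function(path, samples, callProbMin) {
    if (!file.exists(path)) stop("VCF file not found: ", path)
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (anyDuplicated(fix[, "ID"]))
        stop("duplicated variant ids in ", path)
    gt <- vcfR::extract.gt(v, element = "GT")
    alleles <- gsub("\\|", "/", gt)
    dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt))
    dose[alleles == "0/0"] <- 0L
    dose[alleles %in% c("0/1", "1/0")] <- 1L
    dose[alleles == "1/1"] <- 2L
    ## haploid male X calls
    dose[alleles == "0"] <- 0L
    dose[alleles == "1"] <- 2L
    unknown <- !is.na(gt) & is.na(dose) &
        !alleles %in% c("./.", ".", ".|.")
    if (any(unknown))
        stop("unsupported GT value at record ",
             which(rowSums(unknown) > 0)[1], " of ", path)
    cp <- NULL
    if ("GP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
        gp <- vcfR::extract.gt(v, element = "GP")
        if (!all(is.na(gp))) {
            idx <- ifelse(is.na(dose), NA_integer_,
                          ifelse(dose == 2L, 3L, dose + 1L))
            cp <- matrix(NA_real_, nrow(gp), ncol(gp), dimnames = dimnames(gp))
            parts <- strsplit(gp, ",", fixed = TRUE)
            flat <- vapply(seq_along(parts), function(i) {
                j <- idx[i]
                if (is.na(j) || length(parts[[i]]) < j) NA_real_
                else as.numeric(parts[[i]][j])
            }, numeric(1))
            cp[] <- flat
        }
    }
    ids <- colnames(gt)
    if (is.null(samples)) {
        samples <- data.frame(sample_id = ids, sex_reported = "unknown",
                              phenotype = NA_character_,
                              stringsAsFactors = FALSE)
    } else {
        samples <- as.data.frame(samples)
        ord <- match(ids, samples$sample_id)
        if (any(is.na(ord)))
            stop("sample table is missing ids present in the VCF")
        samples <- samples[ord, , drop = FALSE]
    }
    variants <- data.frame(variant_id = fix[, "ID"],
                           chrom = fix[, "CHROM"],
                           pos = as.integer(fix[, "POS"]),
                           ref = fix[, "REF"], alt = fix[, "ALT"],
                           stringsAsFactors = FALSE)
    GenotypeDataset(dose, variants, samples, callProb = cp,
                    callProbMin = if (is.null(cp)) NULL else callProbMin)
}

.writeVcf <- function(x, path) {
    g <- genotypes(x)
    rd <- as.data.frame(rowData(x))
    cp <- callProb(x)
    gtMap <- c("0/0", "0/1", "1/1")
    lines <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
    fmt <- "GT"
    if (!is.null(cp)) {
        lines <- c(lines,
            "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype posterior\">")
        fmt <- "GT:GP"
    }
    lines <- c(lines, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", sampleIds(x)),
                            collapse = "\t"))
    body <- vapply(seq_len(nrow(g)), function(i) {
        gt <- ifelse(is.na(g[i, ]), "./.", gtMap[g[i, ] + 1L])
        if (!is.null(cp)) {
            gp <- vapply(seq_len(ncol(g)), function(j) {
                p <- cp[i, j]
                if (is.na(p)) return(".")
                v <- c(0, 0, 0)
                k <- if (is.na(g[i, j])) NA else g[i, j] + 1L
                if (is.na(k)) return(".")
                v[k] <- p
                v[-k] <- (1 - p) / 2
                paste(sprintf("%.4g", v), collapse = ",")
            }, character(1))
            gt <- paste(gt, gp, sep = ":")
        }
        paste(c(rd$chrom[i], rd$pos[i], rd$variant_id[i], rd$ref[i],
                rd$alt[i], ".", "PASS", ".", fmt, gt), collapse = "\t")
    }, character(1))
    writeLines(c(lines, body), path)
    invisible(path)
}

## ---- TSV layout --------------------------------------------------------

.tsvPaths <- function(prefix)
    list(geno = paste0(prefix, ".geno.tsv"),
         callprob = paste0(prefix, ".callprob.tsv"),
         variants = paste0(prefix, ".variants.tsv"),
         samples = paste0(prefix, ".samples.tsv"))

.readTsv <- function(prefix, callProbMin) {
    p <- .tsvPaths(prefix)
    for (f in c(p$geno, p$variants, p$samples))
        if (!file.exists(f)) stop("TSV layout file not found: ", f)
    variants <- readTable(p$variants)
    samples <- readTable(p$samples)
    if (anyDuplicated(variants$variant_id))
        stop("duplicated variant ids in ", p$variants)
    if (anyDuplicated(samples$sample_id))
        stop("duplicated sample ids in ", p$samples)
    gtab <- readTable(p$geno)
    g <- as.matrix(gtab[, -1, drop = FALSE])
    rownames(g) <- gtab[[1]]
    if (!identical(rownames(g), as.character(variants$variant_id)) ||
        !identical(colnames(g), as.character(samples$sample_id)))
        stop("genotype matrix ids disagree with variant/sample tables at ",
             prefix)
    cp <- NULL
    if (file.exists(p$callprob)) {
        ctab <- readTable(p$callprob)
        cp <- as.matrix(ctab[, -1, drop = FALSE])
        rownames(cp) <- ctab[[1]]
    }
    GenotypeDataset(g, variants, samples, callProb = cp,
                    callProbMin = if (is.null(cp)) NULL else callProbMin)
}

.writeTsv <- function(x, prefix) {
    p <- .tsvPaths(prefix)
    g <- genotypes(x)
    writeTable(data.frame(variant_id = rownames(g), g,
                          check.names = FALSE), p$geno)
    cp <- callProb(x)
    if (!is.null(cp))
        writeTable(data.frame(variant_id = rownames(cp), cp,
                              check.names = FALSE), p$callprob)
    writeTable(as.data.frame(rowData(x)), p$variants)
    writeTable(as.data.frame(colData(x)), p$samples)
    invisible(unlist(p))
}
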