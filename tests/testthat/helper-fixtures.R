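# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

# Full in-memory analysis path from a scenario: generate, encode/impute,
# winsorize, covariate + stratification adjustment, residualize, map, and
# build membership. Mirrors what the file-based pipeline stages do.
processScenario <- function(spec, covariates = TRUE, stratPCs = 0) {
    g <- generateGenotypes(spec)
    ann <- generateAnnotationAndSets(spec)
    e <- generateExpression(spec, g$genotypes, g$truth)
    X0 <- encodeAndImpute(g$genotypes)
    E0 <- t(exprsValues(winsorizeExpression(e$expression)))
    C <- NULL
    if (covariates) C <- buildCovariateMatrix(e$covariates, rownames(X0))
    if (stratPCs > 0) C <- cbind(C, stratificationPCs(X0, stratPCs))
    Xadj <- residualize(X0, C)
    Eadj <- residualize(E0, C)
    mem <- buildMembership(
        mapSnpsToGenes(snpInfo(g$genotypes), ann$annotation),
        mapProbesToGenes(ann$probeMap, ann$annotation),
        ann$geneSets)
    list(Xadj = Xadj, Eadj = Eadj, membership = mem,
         nCovariates = if (is.null(C)) 0L else ncol(C),
         genotypes = g, annotation = ann, expression = e)
}

# Minimal hand-written VCF with GT-only genotype columns.
writeTinyVcf <- function(path, records, samples) {
    header <- c("##fileformat=VCFv4.2",
        paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
               "Description=\"Genotype\">"),
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", samples), collapse = "\t"))
    writeLines(c(header, records), path)
    path
}

# GenotypeExperiment straight from a dosage matrix (SNPs x samples).
makeGenotypes <- function(dosage, chrom = "chr1",
                          pos = seq_len(nrow(dosage))) {
    if (is.null(rownames(dosage)))
        rownames(dosage) <- paste0("snp", seq_len(nrow(dosage)))
    if (is.null(colnames(dosage)))
        colnames(dosage) <- paste0("s", seq_len(ncol(dosage)))
    snps <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(pos, width = 1L))
    names(snps) <- rownames(dosage)
    S4Vectors::mcols(snps)$ref <- "A"
    S4Vectors::mcols(snps)$alt <- "B"
    GenotypeExperiment(dosage, snps)
}

# Independent closed-form HWE chi-square (different parametrization than
# the implementation, which works from expected counts).
hweOracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    a1 <- 2 * nAA + nAa
    a2 <- 2 * naa + nAa
    if (a1 == 0 || a2 == 0) return(1)
    chisq <- n * (4 * nAA * naa - nAa^2)^2 / (a1^2 * a2^2)
    pchisq(chisq, df = 1, lower.tail = FALSE)
}
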