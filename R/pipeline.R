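# End-to-end orchestration from a single config. Each stage reads the
# previous stage's persisted outputs from the output directory, so the
# chained stages and the single-shot runPipeline() produce identical
# files.

.configDefaults <- list(
    genotype_format = "vcf", annotation_dialect = "bed",
    covariates = NULL, exclude_genes = NULL,
    call_rate = 0.95, maf_min = 0.05, hwe_alpha = 0.001,
    winsor_k = 4, flank_bp = 20000, var_threshold = 0.80,
    fdr_cut = 0.05, n_permutations = 10000, n_strat_pcs = 2,
    seed = 1)

#' Read and validate a pipeline run configuration
#'
#' YAML key-value file; every threshold is a named key whose default equals
#' the method's standard value (call rate 0.95, MAF 0.05, HWE alpha 0.001,
#' winsorization 4 SD, 20 kb flank, 80\% variance, FDR cutoff 0.05, 10,000
#' permutations). Validation is fail-fast: an invalid value stops before
#' any computation.
#'
#' @param path path to the YAML config (or a named list to validate).
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
    cfg <- if (is.list(path)) path else yaml::read_yaml(path)
    for (k in names(.configDefaults))
        if (is.null(cfg[[k]])) cfg[[k]] <- .configDefaults[[k]]
    required <- c("genotypes", "expression", "probe_map", "annotation",
                  "gene_sets", "output_dir")
    miss <- setdiff(required, names(cfg))
    if (length(miss))
        stop("config lacks required key(s): ", paste(miss,
             collapse = ", "))
    if (cfg$n_permutations < 1)
        stop("n_permutations must be at least 1")
    if (cfg$call_rate <= 0 || cfg$call_rate > 1 ||
        cfg$maf_min <= 0 || cfg$maf_min >= 1 ||
        cfg$hwe_alpha <= 0 || cfg$hwe_alpha >= 1 ||
        cfg$var_threshold <= 0 || cfg$var_threshold > 1)
        stop("threshold out of range")
    if (cfg$flank_bp < 0 || cfg$winsor_k <= 0 || cfg$n_strat_pcs < 0)
        stop("threshold out of range")
    cfg
}

.log <- function(cfg, ...) {
    cat(format(Sys.time(), "%H:%M:%S"), paste0(...), "\n",
        file = file.path(cfg$output_dir, "log.txt"), append = TRUE)
}

#' Pipeline stages
#'
#' Each stage is runnable standalone on the previous stage's persisted
#' outputs in \code{output_dir}: \code{stagePreprocess} (QC, imputation,
#' winsorization, stratification eigenvectors, residualization),
#' \code{stageMap} (SNP/probe/gene-set membership, overlap distances,
#' collection summary), \code{stageTest} (all pair tests),
#' \code{stageFdr} (permutation null and empirical FDR) and
#' \code{stageReport} (cis/trans enrichment and run summary). Chained
#' execution is output-identical to [runPipeline()].
#'
#' @param cfg a validated config from [readRunConfig()].
#' @return each stage returns its main product invisibly.
#' @name stages
NULL

#' @rdname stages
#' @export
stagePreprocess <- function(cfg) {
    cfg <- readRunConfig(cfg)
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    g <- readGenotypes(cfg$genotypes, cfg$genotype_format)
    e <- readExpression(cfg$expression)
    common <- intersect(colnames(dosages(g)), colnames(exprsValues(e)))
    if (!length(common)) stop("no samples shared between genotypes and ",
                              "expression")
    g <- g[, common]
    e <- ExpressionExperiment(exprsValues(e)[, common, drop = FALSE])
    sf <- filterSamplesByCallRate(g, cfg$call_rate)
    g <- sf$genotypes
    kept <- colnames(dosages(g))
    e <- ExpressionExperiment(exprsValues(e)[, kept, drop = FALSE])
    qc <- snpQCFilter(g, cfg$call_rate, cfg$maf_min, cfg$hwe_alpha)
    g <- qc$genotypes
    X0 <- encodeAndImpute(g)
    ew <- winsorizeExpression(e, cfg$winsor_k)
    E0 <- t(exprsValues(ew))
    C <- NULL
    if (!is.null(cfg$covariates))
        C <- buildCovariateMatrix(readCovariates(cfg$covariates), kept)
    if (cfg$n_strat_pcs > 0) {
        ev <- stratificationPCs(X0, cfg$n_strat_pcs)
        C <- if (is.null(C)) ev else cbind(C, ev)
    }
    Xadj <- residualize(X0, C)
    Eadj <- residualize(E0, C)
    nCov <- if (is.null(C)) 0L else ncol(C)
    qcOut <- rbind(
        data.frame(id = sf$report$id,
                   kind = rep("sample", nrow(sf$report)),
                   reason = sf$report$reason),
        data.frame(id = qc$report$removed$id,
                   kind = rep("snp", nrow(qc$report$removed)),
                   reason = qc$report$removed$reason))
    write.table(qcOut, file.path(cfg$output_dir, "qc_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    saveRDS(list(Xadj = Xadj, Eadj = Eadj, snps = snpInfo(g),
                 samples = kept, nCovariates = nCov,
                 snpStats = qc$report$stats),
            file.path(cfg$output_dir, "adjusted.rds"))
    .log(cfg, "preprocess: kept ", length(kept), " samples, ",
         ncol(Xadj), " SNPs, ", ncol(Eadj), " probes",
         " (call_rate<", cfg$call_rate, ", maf<", cfg$maf_min,
         ", hwe_p<", cfg$hwe_alpha, ", winsor ", cfg$winsor_k, " SD, ",
         cfg$n_strat_pcs, " stratification EVs)")
    invisible(file.path(cfg$output_dir, "adjusted.rds"))
}

#' @rdname stages
#' @export
stageMap <- function(cfg) {
    cfg <- readRunConfig(cfg)
    adj <- readRDS(file.path(cfg$output_dir, "adjusted.rds"))
    genes <- readGeneAnnotation(cfg$annotation, cfg$annotation_dialect)
    gsc <- readGMT(cfg$gene_sets)
    pm <- readProbeMap(cfg$probe_map)
    excl <- character()
    if (!is.null(cfg$exclude_genes))
        excl <- if (length(cfg$exclude_genes) == 1 &&
                    file.exists(cfg$exclude_genes))
            readLines(cfg$exclude_genes) else cfg$exclude_genes
    snpMap <- mapSnpsToGenes(adj$snps, genes, cfg$flank_bp)
    pm <- pm[pm$probe_id %in% colnames(adj$Eadj), , drop = FALSE]
    probeMap <- mapProbesToGenes(pm, genes)
    mem <- buildMembership(snpMap, probeMap, gsc, excl)
    D <- gsDistanceMatrix(gsc)
    write.table(D, file.path(cfg$output_dir, "distance_matrix.tsv"),
                sep = "\t", quote = FALSE)
    write.table(summarizeCollection(mem, gsc),
                file.path(cfg$output_dir, "collection_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(clusterOrder(D),
               file.path(cfg$output_dir, "cluster_order.txt"))
    saveRDS(mem, file.path(cfg$output_dir, "membership.rds"))
    cnt <- membershipCounts(mem)
    .log(cfg, "map: ", sum(cnt$testable), "/", nrow(cnt),
         " sets testable (flank ", cfg$flank_bp, " bp; excluded ",
         length(excl), " gene(s))")
    for (s in cnt$set[!cnt$testable])
        .log(cfg, "map: set '", s, "' untestable (no SNPs or probes)")
    invisible(mem)
}

#' @rdname stages
#' @export
stageTest <- function(cfg) {
    cfg <- readRunConfig(cfg)
    adj <- readRDS(file.path(cfg$output_dir, "adjusted.rds"))
    mem <- readRDS(file.path(cfg$output_dir, "membership.rds"))
    res <- runAllPairs(mem, adj$Xadj, adj$Eadj, cfg$var_threshold,
                       nCovariates = adj$nCovariates)
    skipped <- attr(res, "skipped")
    for (i in seq_len(nrow(skipped)))
        .log(cfg, "test: set '", skipped$set[i], "' skipped (",
             skipped$reason[i], ")")
    if (any(res$capped))
        .log(cfg, "test: component cap applied to ", sum(res$capped),
             " pair(s)")
    saveRDS(list(results = res, setup = attr(res, "setup")),
            file.path(cfg$output_dir, "results.rds"))
    writeResults(res, file.path(cfg$output_dir, "results_nominal.tsv"))
    .log(cfg, "test: ", nrow(res), " pair tests (",
         sum(res$type == "cis"), " cis, ", sum(res$type == "trans"),
         " trans)")
    invisible(res)
}

#' @rdname stages
#' @export
stageFdr <- function(cfg) {
    cfg <- readRunConfig(cfg)
    adj <- readRDS(file.path(cfg$output_dir, "adjusted.rds"))
    mem <- readRDS(file.path(cfg$output_dir, "membership.rds"))
    st <- readRDS(file.path(cfg$output_dir, "results.rds"))
    null <- permutationNull(mem, adj$Xadj, adj$Eadj,
                            B = cfg$n_permutations, seed = cfg$seed,
                            varThreshold = cfg$var_threshold,
                            .setup = st$setup)
    res <- st$results
    res$fdr <- empiricalFdr(res$p_value, null)
    saveRDS(null, file.path(cfg$output_dir, "null.rds"))
    saveRDS(list(results = res, setup = st$setup),
            file.path(cfg$output_dir, "results.rds"))
    writeResults(res, file.path(cfg$output_dir, "results.tsv"))
    .log(cfg, "fdr: B = ", cfg$n_permutations, ", seed = ", cfg$seed,
         "; ", sum(res$fdr < cfg$fdr_cut), " pairs at FDR < ",
         cfg$fdr_cut)
    invisible(res)
}

#' @rdname stages
#' @export
stageReport <- function(cfg) {
    cfg <- readRunConfig(cfg)
    st <- readRDS(file.path(cfg$output_dir, "results.rds"))
    null <- readRDS(file.path(cfg$output_dir, "null.rds"))
    res <- st$results
    pFisher <- cisTransEnrichment(res, cfg$fdr_cut, method = "fisher")
    pPerm <- cisTransEnrichment(res, cfg$fdr_cut, null = null,
                                method = "permutation")
    enr <- data.frame(
        n_cis = sum(res$type == "cis"),
        n_cis_significant = sum(res$type == "cis" &
                                res$fdr < cfg$fdr_cut),
        n_trans = sum(res$type == "trans"),
        n_trans_significant = sum(res$type == "trans" &
                                  res$fdr < cfg$fdr_cut),
        fdr_cut = cfg$fdr_cut, p_fisher = pFisher,
        p_permutation = pPerm)
    write.table(enr, file.path(cfg$output_dir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .log(cfg, "report: cis/trans enrichment p (Fisher) = ",
         signif(pFisher, 4), ", p (permutation) = ", signif(pPerm, 4))
    invisible(enr)
}

#' Run the whole gene-set eQTL pipeline
#'
#' Executes preprocess, mapping, all pair tests, permutation FDR and the
#' cis/trans enrichment report, writing every product (results TSV, QC
#' report, distance matrix, collection summary, enrichment table, log and
#' a verbatim config echo) into \code{output_dir}. Every random draw
#' derives from the config seed, so the same config produces identical
#' output files.
#'
#' @param config path to a YAML config or a named list (see
#'   [readRunConfig()]).
#' @return list with \code{results} (data.frame incl. \code{fdr}),
#'   \code{enrichment} (one-row data.frame) and \code{dir}.
#' @export
runPipeline <- function(config) {
    cfg <- readRunConfig(config)
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    echo <- cfg
    echo$covariates <- echo$covariates %||% "none"
    echo$exclude_genes <- echo$exclude_genes %||% "none"
    yaml::write_yaml(echo, file.path(cfg$output_dir, "config.yml"))
    stagePreprocess(cfg)
    stageMap(cfg)
    stageTest(cfg)
    res <- stageFdr(cfg)
    enr <- stageReport(cfg)
    list(results = res, enrichment = enr, dir = cfg$output_dir)
}
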