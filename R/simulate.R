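# Synthetic-data generator: genotypes in Hardy-Weinberg equilibrium with
# configurable MAF and optional two-population allele-frequency divergence
# (Balding-Nichols), non-overlapping gene loci with configurable gene-set
# overlap, and expression built from gene baselines, batch/sex/population
# covariate effects, planted linear SNP effects confined to chosen sets,
# and Gaussian noise. Every draw is determined by the scenario seed.

#' Define a simulation scenario
#'
#' Defaults describe a small but realistic study: 60 samples, 6 disjoint
#' sets of 5 genes, 3 SNPs and 2 probes per gene, allele frequencies
#' uniform on \code{[0.1, 0.4]}, one homogeneous population, modest batch
#' and sex effects on expression (0.5 on the log2 scale), unit residual
#' noise, and no planted genetic effects.
#'
#' @param nSamples,nGenes,nSets,genesPerSet,snpsPerGene,probesPerGene
#'   scenario sizes (all >= 1).
#' @param geneOverlap genes shared between consecutive sets (sliding
#'   window); 0 gives disjoint sets.
#' @param mafRange range the per-SNP minor allele frequency is drawn from.
#' @param nPopulations 1 (homogeneous) or 2 (Balding-Nichols divergence).
#' @param fst divergence parameter for the two-population model.
#' @param missingRate genotype missingness rate (for exercising QC).
#' @param batchEffect,sexEffect,popEffect additive covariate effect sizes
#'   on the log2 expression scale.
#' @param plantedEffects list of planted effects, each a list with
#'   \code{source} (SNP set name or index), \code{target} (expression set),
#'   \code{beta} (effect per minor allele), \code{nCausal} (causal SNP
#'   count), and optionally \code{snps} (explicit causal SNP ids, which
#'   must belong to the source set).
#' @param noiseSd residual SD of expression.
#' @param baselineMean,baselineSd distribution of per-gene baseline
#'   expression (log2 scale).
#' @param seed integer; fully determines the generated data.
#' @return validated scenario list of class \code{"ScenarioSpec"}.
#' @export
scenarioSpec <- function(nSamples = 60, nGenes = 30, nSets = 6,
                         genesPerSet = 5, geneOverlap = 0,
                         snpsPerGene = 3, probesPerGene = 2,
                         mafRange = c(0.1, 0.4), nPopulations = 1,
                         fst = 0.1, missingRate = 0,
                         batchEffect = 0.5, sexEffect = 0.5,
                         popEffect = 0, plantedEffects = list(),
                         noiseSd = 1, baselineMean = 8, baselineSd = 1,
                         seed = 1) {
    spec <- as.list(environment())
    stopifnot(nSamples >= 2, nGenes >= 1, nSets >= 1, genesPerSet >= 1,
              snpsPerGene >= 1, probesPerGene >= 1,
              geneOverlap >= 0, geneOverlap < genesPerSet,
              noiseSd >= 0, missingRate >= 0, missingRate < 1,
              nPopulations %in% c(1, 2))
    if (mafRange[1] <= 0 || mafRange[2] > 0.5 ||
        mafRange[1] > mafRange[2])
        stop("infeasible MAF range: must lie within (0, 0.5]")
    need <- nSets * (genesPerSet - geneOverlap) + geneOverlap
    if (nGenes < need)
        stop("nGenes must be at least ", need,
             " for the requested sets and overlap")
    for (ef in plantedEffects) {
        if (!all(c("source", "target", "beta") %in% names(ef)))
            stop("planted effect needs source, target and beta")
    }
    structure(spec, class = "ScenarioSpec")
}

# Deterministic layout: genes on chr1, 10 kb bodies, 100 kb spacing, so
# 20 kb flanking windows of neighbouring genes never touch. SNPs sit
# evenly spaced inside the gene body.
.geneLoci <- function(spec) {
    ids <- sprintf("g%03d", seq_len(spec$nGenes))
    start <- (seq_len(spec$nGenes) - 1L) * 100000L + 50001L
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start, width = 10000L), strand = "+")
    names(gr) <- ids
    gr
}

.setDefinitions <- function(spec) {
    stride <- spec$genesPerSet - spec$geneOverlap
    ids <- names(.geneLoci(spec))
    sets <- lapply(seq_len(spec$nSets), function(i)
        ids[(i - 1L) * stride + seq_len(spec$genesPerSet)])
    names(sets) <- sprintf("GS%02d", seq_len(spec$nSets))
    sets
}

.snpLayout <- function(spec) {
    genes <- .geneLoci(spec)
    gene <- rep(names(genes), each = spec$snpsPerGene)
    off <- round(seq(1, 10000, length.out = spec$snpsPerGene + 2L))
    off <- off[-c(1L, spec$snpsPerGene + 2L)]
    pos <- rep(GenomicRanges::start(genes), each = spec$snpsPerGene) +
        rep(off, times = length(genes)) - 1L
    id <- paste0(gene, "_s", rep(seq_len(spec$snpsPerGene),
                                 times = length(genes)))
    data.frame(id = id, gene = gene, pos = pos)
}

#' Generate genotypes for a scenario
#'
#' Biallelic SNPs sampled under Hardy-Weinberg equilibrium at each SNP's
#' allele frequency; with two populations, per-population frequencies
#' diverge around the ancestral MAF following the Balding-Nichols model
#' with parameter \code{fst}, and the sample is split evenly between the
#' populations. Optional missingness is applied uniformly at random.
#'
#' @param spec a [scenarioSpec()].
#' @return list with \code{genotypes} (a
#'   \linkS4class{GenotypeExperiment}) and \code{truth} (per-SNP ancestral
#'   and per-population frequencies, sample population labels).
#' @export
generateGenotypes <- function(spec) {
    set.seed(spec$seed)
    lay <- .snpLayout(spec)
    m <- nrow(lay)
    n <- spec$nSamples
    maf <- runif(m, spec$mafRange[1], spec$mafRange[2])
    pop <- rep(1L, n)
    popFreq <- cbind(maf, maf)
    if (spec$nPopulations == 2) {
        pop <- rep(c(1L, 2L), length.out = n)
        a <- maf * (1 - spec$fst) / spec$fst
        b <- (1 - maf) * (1 - spec$fst) / spec$fst
        popFreq <- cbind(rbeta(m, a, b), rbeta(m, a, b))
        popFreq <- pmin(pmax(popFreq, 1e-4), 1 - 1e-4)
    }
    dosage <- matrix(NA_real_, m, n,
                     dimnames = list(lay$id,
                                     sprintf("sample%03d", seq_len(n))))
    for (k in 1:2) {
        idx <- which(pop == k)
        if (length(idx))
            dosage[, idx] <- rbinom(m * length(idx), 2,
                                    rep(popFreq[, k], length(idx)))
    }
    if (spec$missingRate > 0)
        dosage[runif(m * n) < spec$missingRate] <- NA_real_
    snps <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(lay$pos, width = 1L))
    names(snps) <- lay$id
    S4Vectors::mcols(snps)$ref <- "A"
    S4Vectors::mcols(snps)$alt <- "B"
    list(genotypes = GenotypeExperiment(dosage, snps),
         truth = list(maf = setNames(maf, lay$id), popFreq = popFreq,
                      population = setNames(pop, colnames(dosage)),
                      snpGene = setNames(lay$gene, lay$id)))
}

#' Generate the annotation, gene sets and probe map for a scenario
#'
#' Gene loci are non-overlapping by construction; sets are sliding windows
#' over the gene list with the configured overlap, so the overlap distance
#' and collection summaries are exercised. No randomness is involved.
#'
#' @param spec a [scenarioSpec()].
#' @return list with \code{annotation} (named
#'   \link[GenomicRanges]{GRanges}), \code{geneSets}
#'   (\linkS4class{GeneSetCollection}) and \code{probeMap} (data.frame).
#' @export
generateAnnotationAndSets <- function(spec) {
    genes <- .geneLoci(spec)
    sets <- .setDefinitions(spec)
    probeMap <- data.frame(
        probe_id = paste0(rep(names(genes), each = spec$probesPerGene),
                          "_p", seq_len(spec$probesPerGene)),
        gene_id = rep(names(genes), each = spec$probesPerGene))
    list(annotation = genes,
         geneSets = GeneSetCollection(sets,
             category = setNames(rep("synthetic", length(sets)),
                                 names(sets))),
         probeMap = probeMap)
}

#' Generate expression with planted effects
#'
#' Probe value = gene baseline + planted SNP effects + batch + sex +
#' population shift + N(0, noiseSd). Each planted effect adds
#' \code{beta * dosage} of every causal SNP (drawn from the source set, or
#' given explicitly) to every probe of the target set's genes; the truth
#' record lists every nonzero (SNP, probe, beta) triple. A causal SNP
#' outside its declared source set is an error.
#'
#' @param spec a [scenarioSpec()].
#' @param genotypes the \linkS4class{GenotypeExperiment} from
#'   [generateGenotypes()].
#' @param truth the matching truth record.
#' @return list with \code{expression} (an
#'   \linkS4class{ExpressionExperiment}), \code{covariates} (data.frame,
#'   rownames = samples) and \code{truth} (data.frame of planted
#'   (snp, probe, beta) triples).
#' @export
generateExpression <- function(spec, genotypes, truth) {
    set.seed(spec$seed + 1L)
    ann <- generateAnnotationAndSets(spec)
    sets <- geneSets(ann$geneSets)
    pm <- ann$probeMap
    n <- spec$nSamples
    samples <- colnames(dosages(genotypes))
    baseline <- setNames(rnorm(spec$nGenes, spec$baselineMean,
                               spec$baselineSd), names(.geneLoci(spec)))
    batch <- factor(sample(c("b1", "b2"), n, replace = TRUE))
    sex <- factor(sample(c("F", "M"), n, replace = TRUE))
    pop <- factor(paste0("pop", truth$population))
    vals <- matrix(rnorm(nrow(pm) * n, 0, spec$noiseSd), nrow(pm), n,
                   dimnames = list(pm$probe_id, samples))
    vals <- vals + baseline[pm$gene_id] +
        rep(spec$batchEffect * (batch == "b2") +
            spec$sexEffect * (sex == "M") +
            spec$popEffect * (truth$population == 2L),
            each = nrow(pm))
    d <- dosages(genotypes)
    if (anyNA(d)) {   # planted effects act through the true genotypes
        mu <- rowMeans(d, na.rm = TRUE)
        idx <- which(is.na(d), arr.ind = TRUE)
        d[idx] <- mu[idx[, 1]]
    }
    planted <- list()
    for (ef in spec$plantedEffects) {
        src <- if (is.numeric(ef$source)) names(sets)[ef$source] else
            ef$source
        tgt <- if (is.numeric(ef$target)) names(sets)[ef$target] else
            ef$target
        srcSnps <- rownames(d)[truth$snpGene[rownames(d)] %in%
                               sets[[src]]]
        causal <- if (!is.null(ef$snps)) ef$snps else
            srcSnps[seq_len(min(ef$nCausal %||% 1L, length(srcSnps)))]
        if (!all(causal %in% srcSnps))
            stop("causal SNP outside declared source set '", src, "'")
        tgtProbes <- pm$probe_id[pm$gene_id %in% sets[[tgt]]]
        for (s in causal) {
            vals[tgtProbes, ] <- vals[tgtProbes, , drop = FALSE] +
                rep(ef$beta * d[s, ], each = length(tgtProbes))
        }
        planted[[length(planted) + 1L]] <- data.frame(
            snp = rep(causal, each = length(tgtProbes)),
            probe = rep(tgtProbes, times = length(causal)),
            beta = ef$beta, source = src, target = tgt)
    }
    covariates <- data.frame(batch = batch, sex = sex,
                             row.names = samples)
    if (spec$nPopulations == 2) covariates$population <- pop
    list(expression = ExpressionExperiment(vals),
         covariates = covariates,
         truth = if (length(planted)) do.call(rbind, planted) else
             data.frame(snp = character(), probe = character(),
                        beta = numeric(), source = character(),
                        target = character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a complete scenario, optionally writing it to disk
#'
#' Composes [generateGenotypes()], [generateAnnotationAndSets()] and
#' [generateExpression()]. When \code{dir} is given, writes the fixture
#' files in the formats the readers consume: \code{genotypes.vcf},
#' \code{expression.tsv}, \code{annotation.bed}, \code{sets.gmt},
#' \code{probe_map.tsv}, \code{covariates.tsv} and \code{truth.json}.
#' Identical spec and seed produce bitwise-identical files.
#'
#' @param spec a [scenarioSpec()].
#' @param dir output directory, or \code{NULL} for in-memory only.
#' @return list with all generated objects (and \code{dir} if written).
#' @export
simulateScenario <- function(spec, dir = NULL) {
    g <- generateGenotypes(spec)
    ann <- generateAnnotationAndSets(spec)
    e <- generateExpression(spec, g$genotypes, g$truth)
    out <- list(genotypes = g$genotypes, genotypeTruth = g$truth,
                annotation = ann$annotation, geneSets = ann$geneSets,
                probeMap = ann$probeMap, expression = e$expression,
                covariates = e$covariates, effectTruth = e$truth)
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        writeGenotypes(g$genotypes, file.path(dir, "genotypes.vcf"),
                       "vcf")
        writeExpression(e$expression, file.path(dir, "expression.tsv"))
        writeGeneAnnotation(ann$annotation,
                            file.path(dir, "annotation.bed"), "bed")
        writeGMT(ann$geneSets, file.path(dir, "sets.gmt"))
        write.table(ann$probeMap, file.path(dir, "probe_map.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        cov <- cbind(sample = rownames(e$covariates), e$covariates)
        write.table(cov, file.path(dir, "covariates.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        jsonlite::write_json(list(
            planted = e$truth,
            maf = as.list(g$truth$maf),
            population = as.list(g$truth$population)),
            file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
        out$dir <- dir
    }
    out
}
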