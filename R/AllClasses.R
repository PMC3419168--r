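#' @import methods
#' @importFrom stats cor cummax fisher.test pchisq pf pt qr.coef qr.resid
#'   rbeta rbinom rnorm runif sd setNames var ks.test p.adjust hclust as.dist
#'   model.matrix
#' @importFrom utils read.delim write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#'   RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges
#' @importFrom S4Vectors mcols queryHits subjectHits elementNROWS
#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end width
#'   strand
#' @importFrom IRanges IRanges
NULL

#' GenotypeExperiment: SNP dosages with genomic positions
#'
#' Container for biallelic SNP genotypes coded additively as the count of the
#' minor allele (0, 1, 2), stored as a
#' \linkS4class{RangedSummarizedExperiment} with one assay \code{"dosage"}
#' (SNPs as rows, samples as columns; \code{NA} marks a missing genotype).
#' Row ranges carry the SNP id (names), \code{ref}, \code{alt} and
#' \code{counted} (which allele the dosage counts) in their metadata columns.
#'
#' @slot .Data inherited SummarizedExperiment internals.
#' @seealso [readGenotypes()], [dosages()], [snpInfo()]
#' @export
setClass("GenotypeExperiment", contains = "RangedSummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        return("assay 'dosage' is required")
    d <- SummarizedExperiment::assay(object, "dosage")
    v <- d[!is.na(d)]
    if (length(v) && (min(v) < 0 || max(v) > 2))
        return("dosages must lie in [0, 2] or be NA")
    ids <- rownames(object)
    if (is.null(ids) || anyDuplicated(ids))
        return("SNP ids (rownames) must be present and unique")
    mc <- names(S4Vectors::mcols(SummarizedExperiment::rowRanges(object)))
    if (!all(c("ref", "alt") %in% mc))
        return("rowRanges must carry 'ref' and 'alt' metadata columns")
    TRUE
})

#' Construct a GenotypeExperiment
#'
#' @param dosage numeric matrix, SNPs x samples, entries in \code{[0, 2]} or
#'   \code{NA} for missing genotypes.
#' @param snps a \link[GenomicRanges]{GRanges} of SNP positions (width 1),
#'   named by SNP id, with metadata columns \code{ref} and \code{alt}.
#' @return A \linkS4class{GenotypeExperiment}.
#' @export
GenotypeExperiment <- function(dosage, snps) {
    if (is.null(rownames(dosage))) rownames(dosage) <- names(snps)
    if (!"counted" %in% names(S4Vectors::mcols(snps)))
        S4Vectors::mcols(snps)$counted <- S4Vectors::mcols(snps)$alt
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage), rowRanges = snps)
    new("GenotypeExperiment", se)
}

#' ExpressionExperiment: normalized expression values
#'
#' Log2-scale normalized expression, probes as rows and samples as columns in
#' the single assay \code{"exprs"}. Values must be finite: the upstream
#' normalization is expected to leave no missing data, and loading fails
#' otherwise.
#'
#' @seealso [readExpression()], [exprsValues()]
#' @export
setClass("ExpressionExperiment", contains = "SummarizedExperiment")

setValidity("ExpressionExperiment", function(object) {
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        return("assay 'exprs' is required")
    v <- SummarizedExperiment::assay(object, "exprs")
    if (anyNA(v) || any(!is.finite(v)))
        return("expression values must be finite with no missing entries")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        return("probe ids (rownames) must be present and unique")
    TRUE
})

#' Construct an ExpressionExperiment
#'
#' @param values numeric matrix, probes x samples, finite, no \code{NA}.
#' @return An \linkS4class{ExpressionExperiment}.
#' @export
ExpressionExperiment <- function(values) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values))
    new("ExpressionExperiment", se)
}

#' GeneSetCollection: named gene sets with optional categories
#'
#' @slot sets named list; each element a character vector of gene ids
#'   (deduplicated within a set). Empty sets are permitted.
#' @slot category named character vector of category labels (may be empty).
#' @seealso [readGMT()], [geneSets()]
#' @export
setClass("GeneSetCollection",
    representation(sets = "list", category = "character"))

setValidity("GeneSetCollection", function(object) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
        return("set names must be present and unique")
    if (any(vapply(object@sets, anyDuplicated, 0L) > 0))
        return("genes must be unique within a set")
    TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene ids.
#' @param category optional named character vector of category labels.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, category = character()) {
    sets <- lapply(sets, function(g) unique(as.character(g)))
    new("GeneSetCollection", sets = sets, category = category)
}

#' PCBlock: per-gene-set principal component scores
#'
#' Result of [pcaReduce()]: centered-data SVD scores for the smallest number
#' of components whose cumulative variance fraction reaches the threshold.
#'
#' @slot scores samples x k score matrix (component j = j-th left singular
#'   vector times its singular value, sign-fixed).
#' @slot rotation features x k loadings.
#' @slot center per-feature column means removed before the SVD.
#' @slot explained variance fractions of all positive-variance components
#'   (not just the k retained), so cumulative coverage can be inspected.
#' @slot k number of retained components.
#' @slot varThreshold the threshold that determined k.
#' @export
setClass("PCBlock",
    representation(scores = "matrix", rotation = "matrix",
                   center = "numeric", explained = "numeric",
                   k = "integer", varThreshold = "numeric"))

setValidity("PCBlock", function(object) {
    if (object@k != ncol(object@scores))
        return("k must equal ncol(scores)")
    if (object@k < 1L) return("at least one component must be retained")
    TRUE
})

#' GSMembership: SNP and probe membership of each gene set
#'
#' For every gene set, the SNP columns and expression probe columns mapped to
#' it through its member genes, after dropping excluded genes. A set with no
#' SNPs or no probes is flagged untestable.
#'
#' @slot snpIds named list of character vectors.
#' @slot probeIds named list of character vectors.
#' @slot genes named list of character vectors (member genes contributing at
#'   least one SNP or probe are a subset of these).
#' @slot counts data.frame with one row per set: \code{set}, \code{n_genes},
#'   \code{n_snps}, \code{n_probes}, \code{testable}.
#' @seealso [buildMembership()]
#' @export
setClass("GSMembership",
    representation(snpIds = "list", probeIds = "list",
                   genes = "list", counts = "data.frame"))

setValidity("GSMembership", function(object) {
    nm <- names(object@snpIds)
    if (!identical(nm, names(object@probeIds)) ||
        !identical(nm, names(object@genes)) ||
        !identical(nm, object@counts$set))
        return("set names must agree across slots")
    if (any(lengths(object@snpIds) != object@counts$n_snps) ||
        any(lengths(object@probeIds) != object@counts$n_probes))
        return("counts must match id-list lengths")
    TRUE
})

#' MultivariateFit: least-squares fit of a multivariate linear model
#'
#' Fit of \code{Y = B0 + B1 X + E} by ordinary least squares with an
#' intercept, with the error (E) and hypothesis (H) sums-of-squares and
#' cross-products matrices used by [wilksTest()].
#'
#' @slot coefficients (1 + pH) x q coefficient matrix, intercept row first.
#' @slot residuals n x q residual matrix.
#' @slot E q x q residual SSCP.
#' @slot H q x q hypothesis SSCP (fitted minus grand mean).
#' @slot n,pH,q sample size, predictor count, response count.
#' @export
setClass("MultivariateFit",
    representation(coefficients = "matrix", residuals = "matrix",
                   E = "matrix", H = "matrix",
                   n = "integer", pH = "integer", q = "integer"))

#' PermutationNull: permutation replicates of all gene-set pair p-values
#'
#' @slot pvalues B x T matrix; row b holds the p-values of all testable
#'   gene-set pairs after applying permutation b to the expression samples.
#' @slot B replicate count.
#' @slot seed the seed the permutations were drawn from.
#' @slot pairs data.frame (\code{gs_snp}, \code{gs_expr}, \code{type}) giving
#'   the column ordering of \code{pvalues}, identical to the observed run.
#' @seealso [permutationNull()], [empiricalFdr()]
#' @export
setClass("PermutationNull",
    representation(pvalues = "matrix", B = "integer",
                   seed = "integer", pairs = "data.frame"))

setValidity("PermutationNull", function(object) {
    if (nrow(object@pvalues) != object@B)
        return("pvalues must have B rows")
    if (ncol(object@pvalues) != nrow(object@pairs))
        return("pvalues must have one column per pair")
    TRUE
})
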