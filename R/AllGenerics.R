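#' Accessors for GSeQTL containers
#'
#' \code{dosages()} returns the SNPs x samples dosage matrix (NA = missing);
#' \code{snpInfo()} the SNP \link[GenomicRanges]{GRanges}; \code{exprsValues()}
#' the probes x samples expression matrix; \code{geneSets()} the named list of
#' gene sets; \code{setCategories()} their category labels; \code{pcScores()}
#' the retained PC score matrix; \code{varExplained()} the per-component
#' variance fractions; \code{membershipCounts()} the per-set count table;
#' \code{nullPValues()} the B x T permutation p-value matrix.
#'
#' @param x an object of the documented class.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases dosages snpInfo exprsValues geneSets setCategories pcScores
#'   varExplained membershipCounts nullPValues
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname accessors
#' @export
setGeneric("exprsValues", function(x) standardGeneric("exprsValues"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("setCategories", function(x) standardGeneric("setCategories"))
#' @rdname accessors
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))
#' @rdname accessors
#' @export
setGeneric("varExplained", function(x) standardGeneric("varExplained"))
#' @rdname accessors
#' @export
setGeneric("membershipCounts", function(x) standardGeneric("membershipCounts"))
#' @rdname accessors
#' @export
setGeneric("nullPValues", function(x) standardGeneric("nullPValues"))

#' @rdname accessors
setMethod("dosages", "GenotypeExperiment", function(x)
    SummarizedExperiment::assay(x, "dosage"))

#' @rdname accessors
setMethod("snpInfo", "GenotypeExperiment", function(x)
    SummarizedExperiment::rowRanges(x))

#' @rdname accessors
setMethod("exprsValues", "ExpressionExperiment", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' @rdname accessors
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname accessors
setMethod("setCategories", "GeneSetCollection", function(x) x@category)

#' @rdname accessors
setMethod("pcScores", "PCBlock", function(x) x@scores)

#' @rdname accessors
setMethod("varExplained", "PCBlock", function(x) x@explained)

#' @rdname accessors
setMethod("membershipCounts", "GSMembership", function(x) x@counts)

#' @rdname accessors
setMethod("nullPValues", "PermutationNull", function(x) x@pvalues)

setMethod("show", "GeneSetCollection", function(object) {
    ns <- lengths(object@sets)
    cat("GeneSetCollection with", length(ns), "sets;",
        "gene counts:", if (length(ns)) paste0(min(ns), "-", max(ns)) else "-",
        "\n")
    if (length(object@category))
        cat("  categories:", length(unique(object@category)), "\n")
})

setMethod("show", "PCBlock", function(object) {
    cat("PCBlock:", nrow(object@scores), "samples x", object@k,
        "components (threshold", object@varThreshold, ")\n")
    cat("  cumulative variance of retained components:",
        round(sum(object@explained[seq_len(object@k)]), 4), "\n")
})

setMethod("show", "GSMembership", function(object) {
    cat("GSMembership for", nrow(object@counts), "sets;",
        sum(object@counts$testable), "testable\n")
})

setMethod("show", "PermutationNull", function(object) {
    cat("PermutationNull:", object@B, "replicates x",
        ncol(object@pvalues), "pair tests (seed", object@seed, ")\n")
})

setMethod("show", "MultivariateFit", function(object) {
    cat("MultivariateFit: n =", object@n, ", predictors =", object@pH,
        ", responses =", object@q, "\n")
})
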