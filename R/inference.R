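# Driver for all (GS_SNP, GS_expression) pair tests, the permutation null,
# the pooled empirical FDR, and the cis-vs-trans enrichment test.
#
# Permutation optimization: shuffling expression sample labels permutes the
# rows of the expression matrix, and a row permutation of a matrix permutes
# its centered-PCA scores identically (same singular values and loadings),
# so each replicate permutes the per-set score blocks directly instead of
# re-running the PCA. Equality with full recomputation is covered by a
# dedicated oracle test.

# Degrees of freedom: when the matrices were residualized on c covariate
# columns upstream, the effective sample size entering the error df is
# n - c (nCovariates), keeping the test calibrated after adjustment.
#
# Precompute everything reusable across pairs and permutation replicates:
# per-set PC blocks, per-(set, kx) QR bases of [1, X scores], per-(set, ky)
# uncentered cross-products and log-determinants of the centered total
# SSCP, and per-pair Rao constants.
.pairSetup <- function(membership, Xadj, Eadj, varThreshold = 0.8,
                       nCovariates = 0) {
    cnt <- membershipCounts(membership)
    skipped <- data.frame(set = character(), reason = character())
    if (any(!cnt$testable))
        skipped <- data.frame(set = cnt$set[!cnt$testable],
                              reason = "no mapped SNPs or probes")
    sets <- cnt$set[cnt$testable]
    n <- nrow(Xadj)
    nEff <- n - nCovariates
    xb <- list(); yb <- list()
    for (s in sets) {
        px <- tryCatch(pcaReduce(Xadj[, membership@snpIds[[s]],
                                      drop = FALSE], varThreshold),
                       error = function(e) NULL)
        py <- tryCatch(pcaReduce(Eadj[, membership@probeIds[[s]],
                                      drop = FALSE], varThreshold),
                       error = function(e) NULL)
        xb[[s]] <- px; yb[[s]] <- py
    }
    noVar <- sets[vapply(sets, function(s)
        is.null(xb[[s]]) || is.null(yb[[s]]), TRUE)]
    if (length(noVar))
        skipped <- rbind(skipped,
            data.frame(set = noVar, reason = "no variance"))
    sets <- setdiff(sets, noVar)
    if (!length(sets)) stop("zero testable gene sets")

    # per-pair bookkeeping (SNP-set major, deterministic order)
    pairs <- expand.grid(gs_expr = sets, gs_snp = sets,
                         stringsAsFactors = FALSE)[, c("gs_snp", "gs_expr")]
    pairs <- pairs[order(match(pairs$gs_snp, sets),
                         match(pairs$gs_expr, sets)), ]
    rownames(pairs) <- NULL
    pairs$type <- ifelse(pairs$gs_snp == pairs$gs_expr, "cis", "trans")
    kx0 <- vapply(xb[pairs$gs_snp], function(b) b@k, 0L)
    ky0 <- vapply(yb[pairs$gs_expr], function(b) b@k, 0L)
    caps <- mapply(function(kx, ky) unlist(.capComponents(kx, ky, nEff)),
                   kx0, ky0)
    pairs$kx <- as.integer(caps["kx", ])
    pairs$ky <- as.integer(caps["ky", ])
    pairs$capped <- as.logical(caps["capped", ])

    Qcache <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(pairs))) {
        key <- paste(pairs$gs_snp[i], pairs$kx[i])
        if (is.null(Qcache[[key]])) {
            Xs <- pcScores(xb[[pairs$gs_snp[i]]])[,
                seq_len(pairs$kx[i]), drop = FALSE]
            Qcache[[key]] <- qr.Q(qr(cbind(1, Xs)))
        }
    }
    Ycache <- new.env(parent = emptyenv())   # per (set, ky): YtY and ldT
    for (i in seq_len(nrow(pairs))) {
        key <- paste(pairs$gs_expr[i], pairs$ky[i])
        if (is.null(Ycache[[key]])) {
            Y <- pcScores(yb[[pairs$gs_expr[i]]])[,
                seq_len(pairs$ky[i]), drop = FALSE]
            YtY <- crossprod(Y)
            Tc <- YtY - n * tcrossprod(colMeans(Y))
            Ycache[[key]] <- list(YtY = YtY,
                ldT = as.numeric(determinant(Tc, TRUE)$modulus))
        }
    }
    list(n = n, nEff = nEff, sets = sets, xb = xb, yb = yb, pairs = pairs,
         Qcache = Qcache, Ycache = Ycache, skipped = skipped,
         counts = cnt)
}

# p-values (and lambdas) of every pair for one arrangement of the
# expression rows. perm = NULL means the observed data.
#
# Observed tests use the covariate-corrected effective sample size: after
# residualization the X and Y blocks are co-aligned inside the
# covariate-orthogonal subspace, which costs nCovariates error df. A
# row-permuted Y block sits in generic position relative to that subspace,
# exactly as in a from-scratch re-analysis of shuffled adjusted data, so
# replicate p-values use the full n.
.allPairP <- function(setup, perm = NULL, withLambda = FALSE) {
    pairs <- setup$pairs
    nDf <- if (is.null(perm)) setup$nEff else setup$n
    P <- numeric(nrow(pairs))
    L <- if (withLambda) numeric(nrow(pairs)) else NULL
    for (i in seq_len(nrow(pairs))) {
        Q <- setup$Qcache[[paste(pairs$gs_snp[i], pairs$kx[i])]]
        yc <- setup$Ycache[[paste(pairs$gs_expr[i], pairs$ky[i])]]
        Y <- pcScores(setup$yb[[pairs$gs_expr[i]]])[,
            seq_len(pairs$ky[i]), drop = FALSE]
        if (!is.null(perm)) Y <- Y[perm, , drop = FALSE]
        A <- crossprod(Q, Y)
        E <- yc$YtY - crossprod(A)
        ldE <- determinant(E, logarithm = TRUE)
        lambda <- if (ldE$sign <= 0) .Machine$double.xmin else
            min(1, exp(as.numeric(ldE$modulus) - yc$ldT))
        P[i] <- .raoF(lambda, nDf, pairs$kx[i], pairs$ky[i])$p
        if (withLambda) L[i] <- lambda
    }
    if (withLambda) list(p = P, lambda = L) else P
}

#' Test all ordered gene-set pairs
#'
#' One Wilks-lambda test per ordered (GS_SNP, GS_expression) pair over the
#' testable sets: G cis plus G(G-1) trans results for G testable sets, in a
#' deterministic (SNP-set major) order. Untestable sets (no SNPs, no
#' probes, or no variance) are excluded and recorded in
#' \code{attr(, "skipped")}.
#'
#' @param membership a \linkS4class{GSMembership}.
#' @param Xadj,Eadj covariate-adjusted samples x SNPs and samples x probes
#'   matrices (same row order).
#' @param varThreshold PCA variance threshold; default 0.8.
#' @param nCovariates covariate columns absorbed upstream by
#'   [residualize()]; subtracted from the effective sample size used for
#'   the error degrees of freedom.
#' @return data.frame with one row per pair: set names, \code{type},
#'   per-side gene/SNP/probe/PC counts, \code{lambda}, \code{p_value}.
#' @export
runAllPairs <- function(membership, Xadj, Eadj, varThreshold = 0.8,
                        nCovariates = 0) {
    setup <- .pairSetup(membership, Xadj, Eadj, varThreshold, nCovariates)
    res <- .resultsFromSetup(setup)
    attr(res, "skipped") <- setup$skipped
    attr(res, "setup") <- setup
    res
}

.resultsFromSetup <- function(setup) {
    obs <- .allPairP(setup, withLambda = TRUE)
    pairs <- setup$pairs
    cnt <- setup$counts
    idxS <- match(pairs$gs_snp, cnt$set)
    idxE <- match(pairs$gs_expr, cnt$set)
    data.frame(gs_snp = pairs$gs_snp, gs_expression = pairs$gs_expr,
        type = pairs$type,
        n_genes_snp = cnt$n_genes[idxS], n_snps = cnt$n_snps[idxS],
        n_pcs_snp = pairs$kx,
        n_genes_expr = cnt$n_genes[idxE], n_probes = cnt$n_probes[idxE],
        n_pcs_expr = pairs$ky, capped = pairs$capped,
        lambda = obs$lambda, p_value = obs$p)
}

#' Build the permutation null for all pair tests
#'
#' For each replicate, one uniform random permutation of the expression
#' sample labels is applied to the whole expression side (a single shared
#' permutation across all pairs within a replicate, preserving the
#' between-test correlation), the SNP side is held fixed, and every pair
#' test is recomputed. Pairs untestable in the observed analysis are
#' excluded from every replicate. All B permutations are drawn up front
#' from \code{seed}, so the null is reproducible and chunk-safe.
#'
#' @param membership a \linkS4class{GSMembership}.
#' @param Xadj,Eadj adjusted matrices as in [runAllPairs()].
#' @param B replicate count (>= 1).
#' @param seed integer seed for the permutation draws.
#' @param varThreshold PCA variance threshold; default 0.8.
#' @param nCovariates covariate columns absorbed upstream (see
#'   [runAllPairs()]).
#' @param .setup internal: a prebuilt pair setup (as attached by
#'   [runAllPairs()] in \code{attr(, "setup")}) to avoid recomputation.
#' @return A \linkS4class{PermutationNull}.
#' @export
permutationNull <- function(membership, Xadj, Eadj, B, seed,
                            varThreshold = 0.8, nCovariates = 0,
                            .setup = NULL) {
    if (B < 1) stop("B must be at least 1")
    setup <- .setup
    if (is.null(setup))
        setup <- .pairSetup(membership, Xadj, Eadj, varThreshold,
                            nCovariates)
    n <- setup$n
    set.seed(seed)
    perms <- replicate(B, sample.int(n))
    pv <- matrix(NA_real_, B, nrow(setup$pairs))
    for (b in seq_len(B))
        pv[b, ] <- .allPairP(setup, perm = perms[, b])
    new("PermutationNull", pvalues = pv, B = as.integer(B),
        seed = as.integer(seed),
        pairs = setup$pairs[, c("gs_snp", "gs_expr", "type")])
}

#' Pooled permutation-based empirical FDR
#'
#' For each observed p-value, the estimated FDR is the mean over replicates
#' of the number of null p-values at or below it, divided by the number of
#' observed p-values at or below it, pooling across all tests. Values are
#' clipped to \code{[0, 1]} and made monotone non-decreasing in p by a
#' cumulative minimum from the largest p downward. Pooling across the B x T
#' null draws lets the smallest attainable nonzero FDR be about 1/(B*T),
#' i.e. below 1/B.
#'
#' @param observedP observed p-values, in the pair order of \code{null}.
#' @param null a \linkS4class{PermutationNull} built on the same test set.
#' @return numeric vector of FDR values aligned with \code{observedP}.
#' @export
empiricalFdr <- function(observedP, null) {
    np <- nullPValues(null)
    if (length(observedP) != ncol(np))
        stop("observed p-values and null have mismatched lengths (",
             length(observedP), " vs ", ncol(np), ")")
    pooled <- sort(as.vector(np))
    cntNull <- findInterval(observedP, pooled)
    cntObs <- rank(observedP, ties.method = "max")
    fdr <- pmin(1, pmax(0, (cntNull / null@B) / cntObs))
    ord <- order(observedP)
    fdr[ord] <- rev(cummin(rev(fdr[ord])))
    fdr
}

#' Test for disproportionate cis vs trans significance
#'
#' Given per-pair FDR values, tests whether significant findings
#' (\code{fdr < fdrCut}) are distributed disproportionately between cis and
#' trans pairs. \code{method = "fisher"} runs a two-sided Fisher exact test
#' on the 2x2 (cis/trans x significant/not) table; \code{"permutation"}
#' compares the observed cis-minus-trans significant-proportion difference
#' with the same difference recomputed on each permutation replicate.
#'
#' @param results data.frame from [runAllPairs()] carrying an \code{fdr}
#'   column.
#' @param fdrCut significance cutoff; default 0.05.
#' @param null a \linkS4class{PermutationNull}; required for
#'   \code{method = "permutation"}.
#' @param method \code{"fisher"} or \code{"permutation"}.
#' @return the p-value (1, with a warning, when a table margin is empty).
#' @export
cisTransEnrichment <- function(results, fdrCut = 0.05, null = NULL,
                               method = c("fisher", "permutation")) {
    method <- match.arg(method)
    if (!"fdr" %in% names(results)) stop("results lack an fdr column")
    sig <- factor(results$fdr < fdrCut, levels = c(TRUE, FALSE))
    type <- factor(results$type, levels = c("cis", "trans"))
    tab <- table(type, sig)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        warning("empty margin in the cis/trans significance table")
        return(1)
    }
    if (method == "fisher")
        return(fisher.test(tab)$p.value)
    if (is.null(null)) stop("method 'permutation' needs the null object")
    obsDiff <- mean(results$fdr[results$type == "cis"] < fdrCut) -
        mean(results$fdr[results$type == "trans"] < fdrCut)
    np <- nullPValues(null)
    ptype <- null@pairs$type
    diffs <- vapply(seq_len(null@B), function(b) {
        f <- empiricalFdr(np[b, ], null)
        mean(f[ptype == "cis"] < fdrCut) -
            mean(f[ptype == "trans"] < fdrCut)
    }, 0)
    (1 + sum(abs(diffs) >= abs(obsDiff))) / (null@B + 1)
}
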