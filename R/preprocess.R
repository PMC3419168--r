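# Sample/SNP quality control, additive encoding with mean-dosage
# imputation, expression winsorization, stratification eigenvectors, and
# covariate residualization. Pipeline order: sample filter -> SNP filters ->
# encode/impute -> residualize.

#' Remove samples with low genotype call rate
#'
#' A sample is removed when its fraction of observed (non-missing) genotypes
#' is strictly below \code{threshold}; a sample at exactly the threshold is
#' kept.
#'
#' @param g a \linkS4class{GenotypeExperiment}.
#' @param threshold call-rate cutoff in (0, 1]; default 0.95.
#' @return list with elements \code{genotypes} (filtered) and \code{report}
#'   (data.frame \code{id}, \code{reason}, \code{call_rate} of removals).
#' @export
filterSamplesByCallRate <- function(g, threshold = 0.95) {
    stopifnot(threshold > 0, threshold <= 1)
    d <- dosages(g)
    cr <- colMeans(!is.na(d))
    drop <- cr < threshold
    if (all(drop)) stop("all samples fail the call-rate filter")
    report <- data.frame(id = colnames(d)[drop],
                         reason = rep("call_rate", sum(drop)),
                         call_rate = unname(cr[drop]))
    list(genotypes = g[, !drop], report = report)
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of the genotype counts against the
#' Hardy-Weinberg expectations \eqn{np^2, 2npq, nq^2} with the allele
#' frequency estimated from the same counts. No continuity correction. A
#' monomorphic triple (an expected cell of zero) returns p = 1 by
#' convention.
#'
#' @param nAA,nAa,naa genotype counts (homozygous, heterozygous,
#'   homozygous).
#' @return the p-value.
#' @examples
#' hweTest(25, 50, 25)  # exact HWE proportions: p = 1
#' hweTest(30, 40, 30)  # chi-square 4, p ~= 0.0455
#' @export
hweTest <- function(nAA, nAa, naa) {
    cnt <- c(nAA, nAa, naa)
    if (any(cnt < 0)) stop("negative genotype count")
    n <- sum(cnt)
    if (n == 0) stop("no genotypes")
    p <- (2 * nAA + nAa) / (2 * n)
    expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    if (any(expd == 0)) return(1)
    chisq <- sum((cnt - expd)^2 / expd)
    pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' SNP quality-control filter
#'
#' Removes SNPs with call rate strictly below \code{callRate}, minor allele
#' frequency strictly below \code{mafMin}, or Hardy-Weinberg p-value
#' strictly below \code{hweAlpha}. Statistics are computed on the observed
#' (non-missing) genotypes, after any sample filtering. Each removed SNP is
#' recorded with its first failing criterion (call rate, then MAF, then
#' HWE).
#'
#' @param g a \linkS4class{GenotypeExperiment}.
#' @param callRate,mafMin,hweAlpha thresholds; defaults 0.95, 0.05, 0.001.
#' @return list with \code{genotypes} (filtered) and \code{report} (list of
#'   \code{removed} and per-SNP \code{stats}).
#' @export
snpQCFilter <- function(g, callRate = 0.95, mafMin = 0.05,
                        hweAlpha = 0.001) {
    d <- dosages(g)
    cr <- rowMeans(!is.na(d))
    f <- rowMeans(d, na.rm = TRUE) / 2
    maf <- pmin(f, 1 - f)
    hwe <- vapply(seq_len(nrow(d)), function(i) {
        x <- round(d[i, !is.na(d[i, ])])
        hweTest(sum(x == 2), sum(x == 1), sum(x == 0))
    }, 0)
    reason <- rep(NA_character_, nrow(d))
    reason[is.na(reason) & cr < callRate] <- "call_rate"
    reason[is.na(reason) & maf < mafMin] <- "maf"
    reason[is.na(reason) & hwe < hweAlpha] <- "hwe"
    keep <- is.na(reason)
    if (!any(keep)) stop("no SNPs survive quality control")
    stats <- data.frame(id = rownames(d), call_rate = unname(cr),
                        maf = unname(maf), hwe_p = unname(hwe))
    removed <- data.frame(id = rownames(d)[!keep],
                          reason = reason[!keep])
    list(genotypes = g[keep, ], report = list(removed = removed,
                                              stats = stats))
}

#' Encode genotypes with mean-dosage imputation
#'
#' Replaces each missing genotype with the mean observed dosage of that SNP,
#' and returns the analysis-oriented samples x SNPs matrix with no missing
#' entries.
#'
#' @param g a QC-filtered \linkS4class{GenotypeExperiment}.
#' @return numeric matrix, samples x SNPs.
#' @export
encodeAndImpute <- function(g) {
    d <- dosages(g)
    if (anyNA(d)) {
        mu <- rowMeans(d, na.rm = TRUE)
        if (anyNA(mu)) stop("SNP with no observed genotypes: ",
                            rownames(d)[which(is.na(mu))[1]])
        idx <- which(is.na(d), arr.ind = TRUE)
        d[idx] <- mu[idx[, 1]]
    }
    t(d)
}

#' Winsorize expression values at mean +/- k standard deviations
#'
#' Per probe, the mean and sample SD are computed once on the raw values
#' (outliers included, single pass); values beyond mean + k SD or below
#' mean - k SD are clamped to that bound. Interior values and constant
#' probes (SD zero) are untouched.
#'
#' @param e an \linkS4class{ExpressionExperiment}.
#' @param kSD clamp width in SD units; default 4.
#' @return a winsorized \linkS4class{ExpressionExperiment}.
#' @export
winsorizeExpression <- function(e, kSD = 4) {
    v <- exprsValues(e)
    mu <- rowMeans(v)
    s <- apply(v, 1, sd)
    pos <- s > 0
    hi <- mu + kSD * s
    lo <- mu - kSD * s
    v[pos, ] <- pmin(pmax(v[pos, , drop = FALSE], lo[pos]), hi[pos])
    ExpressionExperiment(v)
}

#' Population-stratification eigenvectors from genotype data
#'
#' Standardizes each SNP column as \eqn{(x - 2\hat p)/\sqrt{\hat p (1-\hat
#' p)}} with \eqn{\hat p} the observed allele frequency, and returns the
#' top-k eigenvectors of the sample-by-sample covariance (left singular
#' vectors of the standardized matrix). Signs are fixed so the
#' largest-magnitude entry of each eigenvector is positive. Monomorphic
#' columns are dropped before standardization.
#'
#' @param X samples x SNPs encoded (imputed) dosage matrix.
#' @param k number of eigenvectors; must satisfy \code{k < nrow(X)}.
#' @return samples x k matrix of eigenvectors.
#' @export
stratificationPCs <- function(X, k) {
    n <- nrow(X)
    if (k >= n) stop("k must be smaller than the number of samples")
    p <- colMeans(X) / 2
    ok <- p > 0 & p < 1
    G <- sweep(X[, ok, drop = FALSE], 2, 2 * p[ok])
    G <- sweep(G, 2, sqrt(p[ok] * (1 - p[ok])), "/")
    s <- svd(G, nu = k, nv = 0)
    U <- s$u
    for (j in seq_len(k)) {
        i <- which.max(abs(U[, j]))
        if (U[i, j] < 0) U[, j] <- -U[, j]
    }
    rownames(U) <- rownames(X)
    colnames(U) <- paste0("EV", seq_len(k))
    U
}

#' Expand covariates to a full-rank numeric design block
#'
#' Categorical columns become indicator contrasts dropping one level;
#' numeric columns pass through. The block excludes the intercept (added by
#' [residualize()]), and rank deficiency after adding the intercept is an
#' error naming the collinear columns.
#'
#' @param covariates data.frame as returned by [readCovariates()].
#' @param samples sample ids giving the required row order.
#' @return samples x covariates numeric matrix.
#' @export
buildCovariateMatrix <- function(covariates, samples) {
    if (!all(samples %in% rownames(covariates)))
        stop("covariates missing for sample(s): ",
             paste(head(setdiff(samples, rownames(covariates))),
                   collapse = ", "))
    df <- covariates[samples, , drop = FALSE]
    C <- model.matrix(~ ., data = df)[, -1, drop = FALSE]
    rownames(C) <- samples
    qrD <- qr(cbind(1, C))
    if (qrD$rank < ncol(C) + 1L) {
        bad <- c("(intercept)", colnames(C))[-qrD$pivot[seq_len(qrD$rank)]]
        stop("collinear covariate column(s): ",
             paste(bad, collapse = ", "))
    }
    C
}

#' Residualize a matrix on covariates
#'
#' Replaces each column of \code{M} by its least-squares residual on an
#' intercept plus the covariate block, so the output columns are mean-zero
#' and orthogonal to every covariate. With an empty covariate block this is
#' plain column mean-centering.
#'
#' @param M samples x features numeric matrix.
#' @param C samples x covariates numeric matrix, or \code{NULL}.
#' @return residual matrix, same shape as \code{M}.
#' @export
residualize <- function(M, C = NULL) {
    if (is.null(C) || ncol(as.matrix(C)) == 0)
        return(sweep(M, 2, colMeans(M)))
    C <- as.matrix(C)
    D <- cbind(`(Intercept)` = 1, C)
    qrD <- qr(D)
    if (qrD$rank < ncol(D)) {
        bad <- colnames(D)[-qrD$pivot[seq_len(qrD$rank)]]
        stop("rank-deficient covariate design; collinear column(s): ",
             paste(bad, collapse = ", "))
    }
    R <- qr.resid(qrD, M)
    dimnames(R) <- dimnames(M)
    R
}
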