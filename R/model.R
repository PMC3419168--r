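# Per-set PCA reduction and the multivariate association test.
#
# The model is Y = B0 + B1 X + E with X the PC scores of the adjusted SNP
# dosages of one set and Y the PC scores of the adjusted expression values
# of one set, each side keeping the smallest number of components whose
# cumulative variance fraction reaches the threshold (default 80%). The
# null B1 = 0 is assessed with Wilks' lambda and Rao's F approximation.

#' PCA reduction retaining a cumulative variance fraction
#'
#' SVD-based PCA on the covariance (columns are centered, not rescaled: the
#' inputs are covariate-adjusted residuals on comparable scales). Keeps the
#' smallest k whose cumulative variance fraction reaches \code{varThreshold}
#' (a component landing exactly on the threshold terminates). Component
#' signs are fixed so the largest-magnitude loading of each component is
#' positive, making scores deterministic across platforms and invariant to
#' column reordering up to that convention.
#'
#' @param M samples x features numeric matrix (at least 2 rows).
#' @param varThreshold cumulative variance fraction in (0, 1]; default 0.8.
#' @param scale. if \code{TRUE}, use correlation-based PCA (columns
#'   rescaled to unit variance) instead of the covariance default.
#' @return A \linkS4class{PCBlock}; \code{k <= min(n - 1, ncol(M))}.
#' @export
pcaReduce <- function(M, varThreshold = 0.8, scale. = FALSE) {
    M <- as.matrix(M)
    if (nrow(M) < 2) stop("need at least 2 samples")
    stopifnot(varThreshold > 0, varThreshold <= 1)
    ctr <- colMeans(M)
    Mc <- sweep(M, 2, ctr)
    if (scale.) {
        s0 <- apply(Mc, 2, sd)
        s0[s0 == 0] <- 1
        Mc <- sweep(Mc, 2, s0, "/")
    }
    sv <- svd(Mc)
    tol <- max(dim(Mc)) * .Machine$double.eps * max(sv$d)
    pos <- sv$d > tol
    if (!any(pos)) stop("no variance: all columns are constant")
    d <- sv$d[pos]
    U <- sv$u[, pos, drop = FALSE]
    V <- sv$v[, pos, drop = FALSE]
    explained <- d^2 / sum(d^2)
    k <- which(cumsum(explained) >= varThreshold - 1e-9)[1]
    for (j in seq_len(k)) {
        i <- which.max(abs(V[, j]))
        if (V[i, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
    }
    scores <- U[, seq_len(k), drop = FALSE] %*%
        diag(d[seq_len(k)], k, k)
    rownames(scores) <- rownames(M)
    colnames(scores) <- paste0("PC", seq_len(k))
    new("PCBlock", scores = scores,
        rotation = V[, seq_len(k), drop = FALSE], center = ctr,
        explained = explained, k = as.integer(k),
        varThreshold = varThreshold)
}

#' Fit the multivariate linear model Y = B0 + B1 X + E
#'
#' Ordinary least squares with an intercept via QR. The error SSCP is
#' \code{E = crossprod(residuals)}; the hypothesis SSCP is the SSCP of the
#' fitted values about the grand mean, \code{H = T - E} with \code{T} the
#' centered total SSCP.
#'
#' @param Y n x q response matrix (expression PC scores).
#' @param X n x p predictor matrix (SNP PC scores).
#' @return A \linkS4class{MultivariateFit}.
#' @export
fitMultivariate <- function(Y, X) {
    Y <- as.matrix(Y); X <- as.matrix(X)
    n <- nrow(Y)
    if (nrow(X) != n) stop("Y and X must have the same number of rows")
    if (n <= ncol(X) + 1) stop("need n > p + 1 for the fit")
    D <- cbind(`(Intercept)` = 1, X)
    qrD <- qr(D)
    if (qrD$rank < ncol(D))
        stop("singular design matrix (collinear predictor scores)")
    coefs <- qr.coef(qrD, Y)
    res <- qr.resid(qrD, Y)
    E <- crossprod(res)
    Yc <- sweep(Y, 2, colMeans(Y))
    H <- crossprod(Yc) - E
    new("MultivariateFit", coefficients = coefs, residuals = res,
        E = E, H = H, n = as.integer(n), pH = as.integer(ncol(X)),
        q = as.integer(ncol(Y)))
}

# Rao's F approximation to the null distribution of Wilks' lambda.
# Exact when min(pH, q) <= 2.
.raoF <- function(lambda, n, pH, q) {
    ve <- n - pH - 1
    den <- pH^2 + q^2 - 5
    tt <- if (den > 0) sqrt((pH^2 * q^2 - 4) / den) else 1
    w <- ve + pH - (q + pH + 1) / 2
    df1 <- pH * q
    df2 <- w * tt - (pH * q - 2) / 2
    if (df2 <= 0) stop("non-positive error degrees of freedom")
    lr <- lambda^(1 / tt)
    Fs <- (1 - lr) / lr * (df2 / df1)
    list(F = Fs, df1 = df1, df2 = df2,
         p = pf(Fs, df1, df2, lower.tail = FALSE))
}

#' Wilks' lambda test of B1 = 0
#'
#' \eqn{\Lambda = \det(E)/\det(E + H)}, with the p-value from Rao's F
#' approximation (exact when \code{min(pH, q) <= 2}; for \code{q = 1} it
#' reduces to the univariate overall-regression F test). Requires error
#' degrees of freedom \code{n - pH - 1 >= q}, otherwise E is singular and
#' the test is refused (the association driver caps component counts so
#' this cannot occur there).
#'
#' @param fit a \linkS4class{MultivariateFit}.
#' @param n,pH,q sample size, predictor and response counts; default from
#'   the fit.
#' @return list with \code{lambda}, \code{F}, \code{df1}, \code{df2},
#'   \code{p_value}.
#' @export
wilksTest <- function(fit, n = fit@n, pH = fit@pH, q = fit@q) {
    if (n - pH - 1 < q)
        stop("error df ", n - pH - 1, " < q = ", q,
             ": E is singular; reduce component counts")
    lambda <- .wilksLambda(fit@E, fit@H)
    r <- .raoF(lambda, n, pH, q)
    list(lambda = lambda, F = r$F, df1 = r$df1, df2 = r$df2,
         p_value = r$p)
}

.wilksLambda <- function(E, H) {
    ldT <- determinant(E + H, logarithm = TRUE)
    if (ldT$sign <= 0) stop("total SSCP is singular (zero variance)")
    ldE <- determinant(E, logarithm = TRUE)
    if (ldE$sign <= 0) return(.Machine$double.xmin)
    min(1, exp(as.numeric(ldE$modulus) - as.numeric(ldT$modulus)))
}

# Reduce retained components until the error df can support the test:
# drop smallest-variance SNP components first, then expression components.
.capComponents <- function(kx, ky, n) {
    capped <- FALSE
    while (n - kx - 1 < ky && kx > 1) { kx <- kx - 1; capped <- TRUE }
    while (n - kx - 1 < ky && ky > 1) { ky <- ky - 1; capped <- TRUE }
    if (n - kx - 1 < ky)
        stop("too few samples for any multivariate test (n = ", n, ")")
    list(kx = kx, ky = ky, capped = capped)
}

#' Gene-set eQTL association test for one pair of sets
#'
#' Composes [pcaReduce()] on the adjusted SNP dosages and expression values
#' of the two sets, caps the component counts if needed to keep the error
#' degrees of freedom at least the response count, fits the multivariate
#' model and applies [wilksTest()]. The pair is labeled \code{cis} when the
#' two set names are equal and \code{trans} otherwise.
#'
#' @param snpCols,exprCols SNP / probe column ids of the two sets.
#' @param Xadj,Eadj covariate-adjusted samples x SNPs and samples x probes
#'   matrices.
#' @param varThreshold PCA variance threshold; default 0.8.
#' @param nCovariates number of covariate columns (intercept excluded)
#'   absorbed upstream by [residualize()]; subtracted from the effective
#'   sample size so the error degrees of freedom reflect the adjustment.
#' @param gsSnp,gsExpr set names (used for the cis/trans label).
#' @return one-row data.frame with set names, type, size metadata
#'   (\code{n_snps}, \code{n_probes}, \code{n_pcs_snp}, \code{n_pcs_expr}),
#'   \code{lambda}, \code{F}, \code{df1}, \code{df2}, \code{p_value}.
#' @export
gsEqtlTest <- function(snpCols, exprCols, Xadj, Eadj, varThreshold = 0.8,
                       nCovariates = 0,
                       gsSnp = "GS_SNP", gsExpr = "GS_expression") {
    if (!length(snpCols) || !length(exprCols))
        stop("untestable pair: empty membership on one side")
    px <- pcaReduce(Xadj[, snpCols, drop = FALSE], varThreshold)
    py <- pcaReduce(Eadj[, exprCols, drop = FALSE], varThreshold)
    n <- nrow(Xadj) - nCovariates
    cap <- .capComponents(px@k, py@k, n)
    Xs <- pcScores(px)[, seq_len(cap$kx), drop = FALSE]
    Ys <- pcScores(py)[, seq_len(cap$ky), drop = FALSE]
    fit <- fitMultivariate(Ys, Xs)
    w <- wilksTest(fit, n = n)
    data.frame(gs_snp = gsSnp, gs_expression = gsExpr,
        type = if (identical(gsSnp, gsExpr)) "cis" else "trans",
        n_snps = length(snpCols), n_probes = length(exprCols),
        n_pcs_snp = cap$kx, n_pcs_expr = cap$ky, capped = cap$capped,
        lambda = w$lambda, F = w$F, df1 = w$df1, df2 = w$df2,
        p_value = w$p_value)
}

#' First canonical correlation between two score blocks
#'
#' Largest singular value of the whitened cross-covariance, computed from
#' the QR decompositions of the centered blocks (so it is invariant under
#' separate invertible linear maps of X and Y).
#'
#' @param X,Y samples x k score matrices.
#' @return the first canonical correlation in \code{[0, 1]}.
#' @export
firstCanonicalCorrelation <- function(X, Y) {
    X <- as.matrix(X); Y <- as.matrix(Y)
    Xc <- sweep(X, 2, colMeans(X))
    Yc <- sweep(Y, 2, colMeans(Y))
    qx <- qr(Xc); qy <- qr(Yc)
    if (qx$rank == 0 || qy$rank == 0)
        stop("zero-variance input block")
    Qx <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    Qy <- qr.Q(qy)[, seq_len(qy$rank), drop = FALSE]
    min(1, max(0, svd(crossprod(Qx, Qy))$d[1]))
}

#' All pairwise SNP-by-probe regressions within a set pair
#'
#' Simple linear regression of each probe on each SNP dosage, with the
#' nominal p-value from the t test on the slope and a Bonferroni-adjusted
#' p-value using the number of performed pairs as the factor. Pairs with a
#' constant SNP or probe column are skipped with a reason.
#'
#' @param snpCols,exprCols SNP / probe column ids.
#' @param Xadj,Eadj adjusted samples x SNPs and samples x probes matrices.
#' @return data.frame with \code{snp}, \code{probe}, \code{beta},
#'   \code{t}, \code{p_value}, \code{p_bonferroni} (one row per tested
#'   pair), with skipped pairs in \code{attr(,"skipped")}.
#' @export
pairwiseEqtl <- function(snpCols, exprCols, Xadj, Eadj) {
    if (!length(snpCols) || !length(exprCols))
        stop("empty membership")
    X <- Xadj[, snpCols, drop = FALSE]
    Y <- Eadj[, exprCols, drop = FALSE]
    n <- nrow(X)
    sdx <- apply(X, 2, sd); sdy <- apply(Y, 2, sd)
    okx <- sdx > 0; oky <- sdy > 0
    skipped <- expand.grid(snp = snpCols[!okx], probe = exprCols,
                           stringsAsFactors = FALSE)
    if (any(!oky))
        skipped <- rbind(skipped,
            expand.grid(snp = snpCols[okx], probe = exprCols[!oky],
                        stringsAsFactors = FALSE))
    if (nrow(skipped)) skipped$reason <- "constant column"
    X <- X[, okx, drop = FALSE]; Y <- Y[, oky, drop = FALSE]
    R <- cor(X, Y)
    R2 <- pmin(R^2, 1 - 1e-15)
    tstat <- R * sqrt((n - 2) / (1 - R2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    beta <- R * outer(1 / sdx[okx], sdy[oky], function(a, b) a * b)
    out <- data.frame(
        snp = rep(colnames(X), times = ncol(Y)),
        probe = rep(colnames(Y), each = ncol(X)),
        beta = as.vector(beta), t = as.vector(tstat),
        p_value = as.vector(p))
    out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
    attr(out, "skipped") <- skipped
    out
}
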