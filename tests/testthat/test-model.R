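test_that("pcaReduce keeps the minimal components reaching the threshold", {
    # orthogonal mean-zero columns with sample variances 8, 1, 1:
    # variance fractions 0.8, 0.1, 0.1, so the first component lands
    # exactly on the threshold and terminates the count
    H <- stats::contr.helmert(4)
    H <- scale(H, center = FALSE, scale = sqrt(colSums(H^2)))
    M <- H %*% diag(sqrt(c(8, 1, 1) * 3))
    pb <- pcaReduce(M, 0.8)
    expect_equal(pb@k, 1L)
    expect_equal(varExplained(pb)[1], 0.8, tolerance = 1e-12)
    # checked against the SVD of the known diagonal covariance
    expect_equal(sort(varExplained(pb), decreasing = TRUE),
                 c(8, 1, 1) / 10, tolerance = 1e-12)
})

test_that("pcaReduce handles rank-1, full-threshold and degenerate input", {
    u <- 1:6
    M <- outer(u, c(1, -2, 0.5))
    pb <- pcaReduce(M, 0.8)
    expect_equal(pb@k, 1L)
    expect_equal(varExplained(pb)[1], 1.0)
    set.seed(91)
    M2 <- matrix(rnorm(8 * 5), 8, 5)
    pb2 <- pcaReduce(M2, 1.0)
    expect_equal(pb2@k, qr(sweep(M2, 2, colMeans(M2)))$rank)
    # scores reproduce the centered data when everything is kept
    rec <- pcScores(pb2) %*% t(pb2@rotation)
    rec <- sweep(rec, 2, pb2@center, "+")
    expect_equal(rec, M2, tolerance = 1e-10, ignore_attr = TRUE)
    expect_error(pcaReduce(matrix(1, 4, 3)), "no variance")
})

test_that("pcaReduce scores are invariant to feature reordering", {
    set.seed(92)
    M <- matrix(rnorm(30 * 6), 30, 6)
    p1 <- pcScores(pcaReduce(M, 0.9))
    p2 <- pcScores(pcaReduce(M[, sample(6)], 0.9))
    expect_equal(p1, p2, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("multivariate fit matches the normal-equations oracle", {
    set.seed(101)
    n <- 25
    X <- matrix(rnorm(n * 3), n)
    Y <- matrix(rnorm(n * 2), n)
    fit <- fitMultivariate(Y, X)
    D <- cbind(1, X)
    oracle <- solve(crossprod(D), crossprod(D, Y))
    expect_equal(unname(fit@coefficients), unname(oracle),
                 tolerance = 1e-8)
    expect_equal(fit@E, crossprod(Y - D %*% oracle), tolerance = 1e-8)
    # perfect fit: Y identical to X
    x <- matrix(rnorm(10))
    pf <- fitMultivariate(x, x)
    expect_lt(max(abs(pf@residuals)), 1e-12)
    expect_lt(max(abs(pf@E)), 1e-12)
    # independent X at large n: slopes shrink to ~0 (4.5 SE bound)
    set.seed(102)
    n2 <- 2000
    f0 <- fitMultivariate(matrix(rnorm(n2)), matrix(rnorm(n2)))
    expect_lt(abs(f0@coefficients[2, 1]), 0.1)
})

test_that("Wilks' lambda matches the independent MANOVA oracle", {
    set.seed(111)
    for (shape in list(c(2, 3), c(3, 2), c(1, 4), c(2, 2), c(4, 2))) {
        p <- shape[1]; q <- shape[2]; n <- 15
        X <- matrix(rnorm(n * p), n)
        Y <- matrix(rnorm(n * q), n)
        w <- wilksTest(fitMultivariate(Y, X))
        a <- stats::anova(lm(Y ~ X), test = "Wilks")
        expect_equal(w$lambda, a$Wilks[2], tolerance = 1e-10)
        expect_equal(w$F, a$`approx F`[2], tolerance = 1e-10)
        expect_equal(w$p_value, a$`Pr(>F)`[2], tolerance = 1e-10)
    }
})

test_that("with one response the Wilks test is the overall F test", {
    set.seed(112)
    for (p in c(1, 2, 3)) {
        X <- matrix(rnorm(10 * p), 10)
        y <- rnorm(10)
        w <- wilksTest(fitMultivariate(matrix(y), X))
        sf <- summary(lm(y ~ X))$fstatistic
        expect_equal(unname(w$F), unname(sf[1]), tolerance = 1e-10)
        expect_equal(w$df1, unname(sf[2]))
        expect_equal(w$df2, unname(sf[3]))
        expect_equal(w$p_value,
                     pf(sf[1], sf[2], sf[3], lower.tail = FALSE),
                     tolerance = 1e-12, ignore_attr = TRUE)
    }
})

test_that("a null hypothesis SSCP gives lambda 1, F 0, p 1", {
    set.seed(113)
    X <- matrix(rnorm(12 * 2), 12)
    # make Y orthogonal to the design in-sample
    Y <- qr.resid(qr(cbind(1, X)), matrix(rnorm(12 * 2), 12))
    w <- wilksTest(fitMultivariate(Y, X))
    expect_equal(w$lambda, 1, tolerance = 1e-10)
    expect_equal(w$F, 0, tolerance = 1e-8)
    expect_equal(w$p_value, 1, tolerance = 1e-8)
    # too few error degrees of freedom for the response count
    expect_error(wilksTest(fitMultivariate(matrix(rnorm(10 * 8), 10),
                                           X[1:10, ])),
                 "singular")
})

test_that("adding a predictor component never increases lambda", {
    set.seed(114)
    n <- 30
    X <- matrix(rnorm(n * 4), n)
    Y <- matrix(rnorm(n * 2), n)
    lam <- vapply(1:4, function(k)
        wilksTest(fitMultivariate(Y, X[, 1:k, drop = FALSE]))$lambda, 0)
    expect_true(all(diff(lam) <= 1e-12))
})

test_that("gsEqtlTest labels cis/trans and is invariant to column order", {
    set.seed(121)
    n <- 40
    Xadj <- matrix(rnorm(n * 6), n,
                   dimnames = list(NULL, paste0("s", 1:6)))
    Eadj <- matrix(rnorm(n * 4), n,
                   dimnames = list(NULL, paste0("p", 1:4)))
    r1 <- gsEqtlTest(paste0("s", 1:6), paste0("p", 1:4), Xadj, Eadj,
                     gsSnp = "A", gsExpr = "A")
    expect_equal(r1$type, "cis")
    r2 <- gsEqtlTest(paste0("s", 1:6), paste0("p", 1:4), Xadj, Eadj,
                     gsSnp = "A", gsExpr = "B")
    expect_equal(r2$type, "trans")
    # relabeling/reordering columns within a set leaves the test unchanged
    r3 <- gsEqtlTest(paste0("s", c(4, 2, 6, 1, 3, 5)),
                     paste0("p", c(3, 1, 4, 2)), Xadj, Eadj,
                     gsSnp = "A", gsExpr = "A")
    expect_equal(r3$p_value, r1$p_value, tolerance = 1e-10)
    expect_equal(r3$lambda, r1$lambda, tolerance = 1e-10)
    expect_error(gsEqtlTest(character(), "p1", Xadj, Eadj),
                 "untestable")
})

test_that("first canonical correlation matches cancor and its invariances", {
    set.seed(131)
    n <- 50
    X <- matrix(rnorm(n * 3), n)
    Y <- matrix(rnorm(n * 2), n)
    r <- firstCanonicalCorrelation(X, Y)
    expect_equal(r, stats::cancor(X, Y)$cor[1], tolerance = 1e-8)
    # invariance under separate invertible linear maps
    A <- matrix(rnorm(9), 3) + diag(3)
    B <- matrix(rnorm(4), 2) + diag(2)
    expect_equal(firstCanonicalCorrelation(X %*% A, Y %*% B), r,
                 tolerance = 1e-8)
    # shared column: perfect correlation
    expect_equal(firstCanonicalCorrelation(X, X[, 1, drop = FALSE]), 1,
                 tolerance = 1e-10)
    expect_error(firstCanonicalCorrelation(matrix(0, 10, 2), Y[1:10, ]),
                 "zero-variance")
    # independent blocks stay below the permutation 99th percentile
    set.seed(132)
    n2 <- 200
    X2 <- matrix(rnorm(n2 * 3), n2)
    Y2 <- matrix(rnorm(n2 * 3), n2)
    robs <- firstCanonicalCorrelation(X2, Y2)
    rperm <- vapply(1:200, function(i)
        firstCanonicalCorrelation(X2[sample(n2), ], Y2), 0)
    expect_lt(robs, quantile(rperm, 0.99) + 0.05)
})

test_that("pairwise eQTL regressions match the t-test-on-slope oracle", {
    set.seed(141)
    n <- 20
    Xadj <- matrix(sample(0:2, n * 3, TRUE), n,
                   dimnames = list(NULL, paste0("s", 1:3)))
    Eadj <- matrix(rnorm(n * 2), n,
                   dimnames = list(NULL, paste0("p", 1:2)))
    out <- pairwiseEqtl(paste0("s", 1:3), paste0("p", 1:2), Xadj, Eadj)
    expect_equal(nrow(out), 6L)   # 3 SNPs x 2 probes
    expect_equal(out$p_bonferroni, pmin(1, out$p_value * 6))
    for (i in seq_len(nrow(out))) {
        sm <- summary(lm(Eadj[, out$probe[i]] ~ Xadj[, out$snp[i]]))
        expect_equal(out$p_value[i], sm$coefficients[2, 4],
                     tolerance = 1e-10)
        expect_equal(out$beta[i], sm$coefficients[2, 1],
                     tolerance = 1e-10)
    }
    # a probe identical to a dosage column: essentially zero p
    Eadj2 <- cbind(Eadj, px = Xadj[, 1])
    out2 <- pairwiseEqtl("s1", "px", Xadj, Eadj2)
    expect_lt(out2$p_value, 1e-10)
    # constant column skipped with a reason
    Xadj3 <- cbind(Xadj, sc = 1)
    out3 <- pairwiseEqtl(c("s1", "sc"), "p1", Xadj3, Eadj)
    expect_equal(nrow(out3), 1L)
    expect_equal(attr(out3, "skipped")$reason, "constant column")
})
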