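test_that("sample call-rate filter removes below 95% with a strict boundary", {
    d <- matrix(1, 100, 3, dimnames = list(NULL, c("low", "edge", "full")))
    d[1:6, "low"] <- NA    # 94% observed -> removed
    d[1:5, "edge"] <- NA   # exactly 95% -> kept
    g <- makeGenotypes(d)
    out <- filterSamplesByCallRate(g, 0.95)
    expect_equal(colnames(dosages(out$genotypes)), c("edge", "full"))
    expect_equal(out$report$id, "low")
    expect_equal(out$report$reason, "call_rate")
    # no missing data -> identity
    full <- filterSamplesByCallRate(makeGenotypes(matrix(1, 5, 4)))
    expect_equal(ncol(dosages(full$genotypes)), 4L)
    expect_equal(nrow(full$report), 0L)
})

test_that("SNP QC applies strict MAF, HWE and call-rate rules", {
    n <- 500
    hets <- function(k) c(rep(1, k), rep(0, n - k))
    d <- rbind(
        maf049 = hets(49),              # MAF 0.049 -> removed
        maf050 = hets(50),              # MAF exactly 0.05 -> kept
        mono = rep(0, n),               # monomorphic -> removed via MAF
        hwe_bad = c(rep(2, 250), rep(0, 250)),  # no hets: HWE p ~ 0
        good = rep(c(0, 1, 1, 2), n / 4))
    g <- makeGenotypes(d)
    out <- snpQCFilter(g, 0.95, 0.05, 0.001)
    expect_setequal(rownames(dosages(out$genotypes)),
                    c("maf050", "good"))
    rem <- out$report$removed
    expect_equal(rem$reason[rem$id == "maf049"], "maf")
    expect_equal(rem$reason[rem$id == "mono"], "maf")
    expect_equal(rem$reason[rem$id == "hwe_bad"], "hwe")
    d2 <- rbind(cr = c(rep(NA, 26), rep(1, 474)),
                ok = rep(c(0, 1, 1, 2), 125))
    out2 <- snpQCFilter(makeGenotypes(d2), 0.95, 0.01, 1e-12)
    expect_equal(out2$report$removed$id, "cr")
    expect_equal(out2$report$removed$reason, "call_rate")
})

test_that("HWE test matches hand arithmetic and the closed-form oracle", {
    expect_equal(hweTest(25, 50, 25), 1)
    # (30,40,30): expected 25/50/25, chi-square 1 + 2 + 1 = 4
    expect_equal(hweTest(30, 40, 30),
                 pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
    expect_equal(hweTest(30, 40, 30), 0.04550026, tolerance = 1e-7)
    expect_equal(hweTest(100, 0, 0), 1)   # monomorphic convention
    expect_error(hweTest(0, 0, 0), "no genotypes")
    # exhaustive agreement with an independent parametrization, n <= 20
    for (n in 1:20) for (a in 0:n) for (h in 0:(n - a)) {
        expect_equal(hweTest(a, h, n - a - h), hweOracle(a, h, n - a - h),
                     tolerance = 1e-12)
    }
})

test_that("mean-dosage imputation fills missing genotypes", {
    d <- rbind(a = c(0, 1, 2, NA), b = c(0, 0, 2, NA),
               c = c(1, 1, 1, 1))
    X <- encodeAndImpute(makeGenotypes(d))
    expect_equal(dim(X), c(4L, 3L))       # samples x SNPs
    expect_equal(unname(X[4, "a"]), 1.0)
    expect_equal(unname(X[4, "b"]), 2 / 3)
    expect_false(anyNA(X))
    # no missing -> identity
    expect_equal(unname(encodeAndImpute(makeGenotypes(d[3, , drop = FALSE]))),
                 matrix(1, 4, 1))
})

test_that("winsorization clamps at mean +/- 4 SD and leaves the rest alone", {
    set.seed(21)
    n <- 200
    x <- rnorm(n)
    mu0 <- mean(x); s0 <- sd(x)
    x[1] <- mu0 + 6 * s0   # plant a 6 SD outlier
    v <- rbind(outlier = x, flat = rep(3, n), inner = rnorm(n, 0, 0.1))
    colnames(v) <- paste0("s", 1:n)
    e <- winsorizeExpression(ExpressionExperiment(v), 4)
    w <- exprsValues(e)
    # oracle: single-pass bound recomputed independently
    bound <- mean(v["outlier", ]) + 4 * sd(v["outlier", ])
    expect_equal(unname(w["outlier", 1]), bound, tolerance = 1e-10)
    expect_equal(w["flat", ], v["flat", ])      # SD 0 untouched
    expect_equal(w["inner", ], v["inner", ])    # interior untouched
    lo <- mean(v["outlier", ]) - 4 * sd(v["outlier", ])
    expect_true(all(w["outlier", ] >= lo - 1e-12 &
                    w["outlier", ] <= bound + 1e-12))
})

test_that("stratification eigenvectors separate diverged populations", {
    spec <- scenarioSpec(nSamples = 100, nGenes = 50, nSets = 10,
                         snpsPerGene = 3, nPopulations = 2, fst = 0.2,
                         seed = 31)
    g <- generateGenotypes(spec)
    X <- encodeAndImpute(g$genotypes)
    ev <- stratificationPCs(X, 2)
    pop <- g$truth$population
    # best 1-D threshold on PC1 classifies populations > 90%
    cut <- mean(tapply(ev[, 1], pop, mean))
    acc <- mean((ev[, 1] > cut) + 1 == pop)
    expect_gt(max(acc, 1 - acc), 0.9)
    # homogeneous population: leading eigenvalue does not dominate
    spec0 <- scenarioSpec(nSamples = 100, nGenes = 50, nSets = 10,
                          snpsPerGene = 3, seed = 32)
    X0 <- encodeAndImpute(generateGenotypes(spec0)$genotypes)
    share <- function(M) {
        p <- colMeans(M) / 2; ok <- p > 0 & p < 1
        G <- sweep(sweep(M[, ok], 2, 2 * p[ok]), 2,
                   sqrt(p[ok] * (1 - p[ok])), "/")
        ev <- svd(G, nu = 0, nv = 0)$d^2
        ev[1] / mean(ev)
    }
    expect_gt(share(X), 3 * share(X0))
    expect_error(stratificationPCs(X, 100), "smaller")
})

test_that("a full eigenbasis reconstructs the standardized data", {
    set.seed(41)
    X <- matrix(sample(0:2, 8 * 20, TRUE), 8, 20)
    ev <- stratificationPCs(X, 7)
    expect_equal(dim(ev), c(8L, 7L))
    expect_equal(crossprod(ev), diag(7), tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("residualization matches the normal-equations oracle", {
    set.seed(51)
    n <- 40
    C <- cbind(a = rnorm(n), b = rnorm(n))
    M <- matrix(rnorm(n * 6), n)
    R <- residualize(M, C)
    D <- cbind(1, C)
    oracle <- M - D %*% solve(crossprod(D), crossprod(D, M))
    expect_equal(R, oracle, tolerance = 1e-8, ignore_attr = TRUE)
    expect_lt(max(abs(colMeans(R))), 1e-10)
    expect_lt(max(abs(crossprod(C, R))), 1e-8 * max(abs(M)))
    # intercept-only: plain centering
    expect_equal(residualize(M), sweep(M, 2, colMeans(M)))
    # fixed point: already orthogonal, mean-zero column is unchanged
    z <- qr.resid(qr(D), rnorm(n))
    expect_equal(residualize(cbind(z), C), cbind(z), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_error(residualize(M, cbind(C, dup = C[, 1] * 2)),
                 "collinear")
})

test_that("preprocessing is idempotent on its own output", {
    set.seed(61)
    n <- 60
    C <- cbind(rnorm(n), rbinom(n, 1, 0.5))
    M <- matrix(rnorm(n * 5), n)
    R1 <- residualize(M, C)
    expect_equal(residualize(R1, C), R1, tolerance = 1e-10)
    # winsorization is a single-pass rule; with no value beyond the
    # bounds it is the identity
    v <- matrix(rnorm(10 * n), 10, n,
                dimnames = list(paste0("p", 1:10), paste0("s", 1:n)))
    v <- pmin(pmax(v, -3), 3)
    w1 <- winsorizeExpression(ExpressionExperiment(v), 4)
    expect_equal(exprsValues(w1), v, tolerance = 1e-12)
    g <- makeGenotypes(rbind(a = rep(c(0, 1, 2, 1), 15)))
    qc1 <- snpQCFilter(g)
    expect_equal(nrow(qc1$report$removed), 0L)
})
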