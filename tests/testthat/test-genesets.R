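test_that("SNP-to-gene mapping honors the inclusive 20 kb flank", {
    genes <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(100000L, 110000L))
    names(genes) <- "geneA"
    pos <- c(at_edge = 80000L, beyond = 79999L, inside = 105000L,
             right_edge = 130000L, right_beyond = 130001L)
    snps <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1L))
    names(snps) <- names(pos)
    m <- mapSnpsToGenes(snps, genes, 20000)
    expect_setequal(m$snp_id, c("at_edge", "inside", "right_edge"))
    expect_true(all(m$gene_id == "geneA"))
})

test_that("mapped SNPs always lie within the flank window (brute force)", {
    set.seed(71)
    genes <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(sort(sample(1:500000, 8)) * 2L, width = 5000L))
    names(genes) <- paste0("g", 1:8)
    snps <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(sample(1:1100000, 300), width = 1L))
    names(snps) <- paste0("s", 1:300)
    flank <- 20000
    m <- mapSnpsToGenes(snps, genes, flank)
    # brute-force interval oracle over every (SNP, gene) combination
    oracle <- do.call(rbind, lapply(seq_along(snps), function(i) {
        p <- GenomicRanges::start(snps)[i]
        hit <- GenomicRanges::start(genes) - flank <= p &
            p <= GenomicRanges::end(genes) + flank
        if (any(hit)) data.frame(snp_id = names(snps)[i],
                                 gene_id = names(genes)[hit])
    }))
    key <- function(d) sort(paste(d$snp_id, d$gene_id))
    expect_equal(key(m), key(oracle))
})

test_that("probe mapping drops unannotated genes with a warning", {
    genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
    names(genes) <- "gA"
    pm <- data.frame(probe_id = c("p1", "p2", "p3"),
                     gene_id = c("gA", "gX", "gA"))
    expect_warning(out <- mapProbesToGenes(pm, genes), "unannotated")
    expect_equal(out$probe_id, c("p1", "p3"))
    # a probe mapped to two annotated genes keeps both entries
    names(genes) <- "gA"
    genes2 <- c(genes, genes)
    names(genes2) <- c("gA", "gB")
    pm2 <- data.frame(probe_id = "p1", gene_id = c("gA", "gB"))
    expect_equal(nrow(mapProbesToGenes(pm2, genes2)), 2L)
})

test_that("membership takes per-set unions with dedup and exclusions", {
    snpMap <- data.frame(
        snp_id = c("s1", "s2", "s3", "s4", "s1"),
        gene_id = c("gA", "gA", "gA", "gB", "gB"))  # s1 via both genes
    probeMap <- data.frame(probe_id = c("p1", "p2", "p3"),
                           gene_id = c("gA", "gA", "gB"))
    gsc <- GeneSetCollection(list(S = c("gA", "gB")))
    m <- buildMembership(snpMap, probeMap, gsc)
    cnt <- membershipCounts(m)
    expect_equal(cnt$n_snps, 4L)   # shared SNP counted once
    expect_equal(cnt$n_probes, 3L)
    expect_true(cnt$testable)
    m2 <- buildMembership(snpMap, probeMap, gsc, excludeGenes = "gB")
    expect_equal(membershipCounts(m2)$n_snps, 3L)
    expect_equal(membershipCounts(m2)$n_probes, 2L)
    # counts are monotone non-increasing under any extra exclusion
    for (ex in list("gA", c("gA", "gB"))) {
        mx <- buildMembership(snpMap, probeMap, gsc, excludeGenes = ex)
        expect_true(all(membershipCounts(mx)$n_snps <= cnt$n_snps))
        expect_true(all(membershipCounts(mx)$n_probes <= cnt$n_probes))
    }
    # a set with no probes is flagged untestable
    m3 <- buildMembership(snpMap, probeMap[0, ], gsc)
    expect_false(membershipCounts(m3)$testable)
})

test_that("the 1 - tau distance averages the directed overlap proportions", {
    expect_equal(gsDistance(c("a", "b"), c("a", "b")), 0)
    expect_equal(gsDistance(c("a", "b"), c("x", "y")), 1)
    # |A|=4, |B|=2, overlap 2: tau = (0.5 + 1)/2 = 0.75
    expect_equal(gsDistance(paste0("g", 1:4), c("g1", "g2")), 0.25)
    expect_equal(gsDistance(c("g1", "g2"), paste0("g", 1:4)), 0.25)
    expect_equal(gsDistance(character(), "a"), 1)
    expect_error(gsDistance(character(), character()), "empty")
    D <- gsDistanceMatrix(GeneSetCollection(
        list(A = c("a", "b"), B = c("b", "c"), C = "z")))
    expect_equal(D, t(D))
    expect_equal(diag(D), c(A = 0, B = 0, C = 0))
    expect_true(all(D >= 0 & D <= 1))
})

test_that("cluster ordering puts identical sets adjacent and respects ties", {
    gsc <- GeneSetCollection(list(A = c("a", "b", "c"), C = c("x", "y"),
                                  B = c("a", "b", "c"), D = c("p", "q")))
    ord <- clusterOrder(gsDistanceMatrix(gsc))
    expect_equal(abs(diff(match(c("A", "B"), ord))), 1)
    Deq <- matrix(1, 4, 4) - diag(4)
    dimnames(Deq) <- list(letters[1:4], letters[1:4])
    expect_equal(clusterOrder(Deq), letters[1:4])  # tie: input order
    D1 <- matrix(0, 1, 1, dimnames = list("only", "only"))
    expect_equal(clusterOrder(D1), "only")
})

test_that("collection summaries match brute-force overlap arithmetic", {
    snpMap <- data.frame(snp_id = paste0("s", 1:6),
                         gene_id = paste0("g", 1:6))
    probeMap <- data.frame(probe_id = paste0("p", 1:6),
                           gene_id = paste0("g", 1:6))
    gsc <- GeneSetCollection(list(S1 = c("g1", "g2"),
                                  S2 = c("g1", "g3", "g4", "g5")))
    sm <- summarizeCollection(buildMembership(snpMap, probeMap, gsc), gsc)
    expect_equal(sm$genes_per_set_avg, 3)
    expect_equal(sm$genes_per_set_max, 4)
    expect_equal(sm$genes_per_set_min, 2)
    expect_equal(sm$gene_overlap_avg, 1)
    expect_equal(sm$total_genes_mapped, 5)
    expect_equal(sm$snps_mapped_max, 4)
    # single set: overlap degenerates to 0
    sm1 <- summarizeCollection(
        buildMembership(snpMap, probeMap,
                        GeneSetCollection(list(S = c("g1", "g2")))),
        GeneSetCollection(list(S = c("g1", "g2"))))
    expect_equal(sm1$gene_overlap_avg, 0)
    # random fixture against a double-loop oracle
    set.seed(81)
    sets <- lapply(1:5, function(i) sample(paste0("g", 1:6),
                                           sample(2:5, 1)))
    names(sets) <- paste0("R", 1:5)
    gscR <- GeneSetCollection(sets)
    smR <- summarizeCollection(buildMembership(snpMap, probeMap, gscR),
                               gscR)
    ov <- c()
    for (i in 1:4) for (j in (i + 1):5)
        ov <- c(ov, length(intersect(geneSets(gscR)[[i]],
                                     geneSets(gscR)[[j]])))
    expect_equal(smR$gene_overlap_avg, mean(ov))
    expect_equal(smR$gene_overlap_max, max(ov))
    expect_equal(smR$gene_overlap_min, min(ov))
})
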