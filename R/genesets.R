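# Gene-set membership construction: SNP -> gene by genomic proximity,
# probe -> gene by the platform map, gene -> set from the collection;
# plus the 1 - tau overlap distance and reporting summaries.

#' Map SNPs to genes within a flanking window
#'
#' A SNP maps to a gene when its position lies within
#' \code{[start - flankBp, end + flankBp]} on the same chromosome, both ends
#' inclusive ("within 20 kb" is read as <= 20,000 bp). All qualifying genes
#' are retained (multiple SNP-to-gene mappings allowed).
#'
#' @param snps named \link[GenomicRanges]{GRanges} of SNP positions (e.g.
#'   \code{snpInfo(g)}).
#' @param genes named \link[GenomicRanges]{GRanges} of gene bodies.
#' @param flankBp flank in bp; default 20000.
#' @return data.frame with columns \code{snp_id}, \code{gene_id}.
#' @export
mapSnpsToGenes <- function(snps, genes, flankBp = 20000) {
    shared <- intersect(as.character(GenomeInfoDb::seqnames(snps)),
                        as.character(GenomeInfoDb::seqnames(genes)))
    if (!length(shared))
        warning("no shared chromosome names between SNPs (",
                length(unique(GenomeInfoDb::seqnames(snps))),
                " levels) and genes (",
                length(unique(GenomeInfoDb::seqnames(genes))), " levels)")
    ext <- genes
    GenomicRanges::start(ext) <-
        pmax(1L, GenomicRanges::start(genes) - flankBp)
    GenomicRanges::end(ext) <- GenomicRanges::end(genes) + flankBp
    hits <- GenomicRanges::findOverlaps(snps, ext, ignore.strand = TRUE)
    data.frame(snp_id = names(snps)[S4Vectors::queryHits(hits)],
               gene_id = names(genes)[S4Vectors::subjectHits(hits)])
}

#' Map expression probes to annotated genes
#'
#' Probes whose gene is absent from the annotation are dropped with a
#' warning; a probe mapped to several annotated genes yields one entry per
#' gene.
#'
#' @param probeMap data.frame (\code{probe_id}, \code{gene_id}) from
#'   [readProbeMap()].
#' @param genes named \link[GenomicRanges]{GRanges} of gene bodies.
#' @return the filtered probe map data.frame.
#' @export
mapProbesToGenes <- function(probeMap, genes) {
    known <- probeMap$gene_id %in% names(genes)
    if (any(!known))
        warning(sum(!known), " probe mapping(s) to unannotated gene(s) ",
                "dropped")
    probeMap[known, , drop = FALSE]
}

#' Build per-set SNP and probe membership
#'
#' For every gene set, the union of the SNP ids and probe ids of its member
#' genes (each id at most once per set), after removing \code{excludeGenes}
#' from every set. Sets left with zero SNPs or zero probes are flagged
#' untestable; they stay in the table but are skipped, with a logged reason,
#' by the association driver.
#'
#' @param snpMap data.frame from [mapSnpsToGenes()].
#' @param probeMap data.frame from [mapProbesToGenes()].
#' @param gsc a \linkS4class{GeneSetCollection}.
#' @param excludeGenes gene ids removed from every set (the HLA-type
#'   exclusion is one instance).
#' @return A \linkS4class{GSMembership}.
#' @export
buildMembership <- function(snpMap, probeMap, gsc,
                            excludeGenes = character()) {
    sets <- geneSets(gsc)
    snpBy <- split(snpMap$snp_id, snpMap$gene_id)
    prbBy <- split(probeMap$probe_id, probeMap$gene_id)
    genes <- lapply(sets, function(g) setdiff(g, excludeGenes))
    snpIds <- lapply(genes, function(g)
        unique(unlist(snpBy[intersect(g, names(snpBy))],
                      use.names = FALSE)))
    probeIds <- lapply(genes, function(g)
        unique(unlist(prbBy[intersect(g, names(prbBy))],
                      use.names = FALSE)))
    snpIds <- lapply(snpIds, function(x) if (is.null(x)) character() else x)
    probeIds <- lapply(probeIds, function(x)
        if (is.null(x)) character() else x)
    counts <- data.frame(set = names(sets),
        n_genes = lengths(genes),
        n_snps = lengths(snpIds),
        n_probes = lengths(probeIds), row.names = NULL)
    counts$testable <- counts$n_snps > 0 & counts$n_probes > 0
    new("GSMembership", snpIds = snpIds, probeIds = probeIds,
        genes = genes, counts = counts)
}

#' Overlap distance between two gene sets
#'
#' \eqn{1 - \tau} where \eqn{\tau} is the average proportion of shared
#' genes: the mean of the two directed overlap proportions,
#' \eqn{\tau = (|A \cap B|/|A| + |A \cap B|/|B|)/2}. An empty set against a
#' non-empty one has distance 1; symmetric; zero iff the sets are equal.
#' Not a metric (the triangle inequality can fail), so it is used only for
#' clustering and reporting.
#'
#' @param a,b character vectors of gene ids.
#' @return distance in \code{[0, 1]}.
#' @export
gsDistance <- function(a, b) {
    a <- unique(a); b <- unique(b)
    if (!length(a) && !length(b)) stop("both gene sets are empty")
    if (!length(a) || !length(b)) return(1)
    ov <- length(intersect(a, b))
    1 - (ov / length(a) + ov / length(b)) / 2
}

#' Pairwise gene-set distance matrix
#' @param gsc a \linkS4class{GeneSetCollection} (empty sets get distance 1
#'   to everything; two empty sets get 1 as well, so the matrix is always
#'   defined).
#' @return symmetric matrix of \code{1 - tau} distances with zero diagonal.
#' @export
gsDistanceMatrix <- function(gsc) {
    sets <- geneSets(gsc)
    G <- length(sets)
    D <- matrix(0, G, G, dimnames = list(names(sets), names(sets)))
    if (G < 2) return(D)
    for (i in seq_len(G - 1)) for (j in (i + 1):G) {
        d <- if (!length(sets[[i]]) && !length(sets[[j]])) 1
             else gsDistance(sets[[i]], sets[[j]])
        D[i, j] <- D[j, i] <- d
    }
    D
}

#' Order gene sets by hierarchical clustering
#'
#' Leaf order of complete-linkage agglomerative clustering
#' (\code{\link[stats]{hclust}}) of the distance matrix; used to arrange
#' sets so that overlapping ones sit next to each other in reports. With
#' all pairwise distances equal the input order is preserved.
#'
#' @param D symmetric distance matrix from [gsDistanceMatrix()].
#' @return character vector of set names in leaf order.
#' @export
clusterOrder <- function(D) {
    if (nrow(D) <= 1L) return(rownames(D))
    if (nrow(D) == 2L) return(rownames(D))
    hc <- hclust(as.dist(D), method = "complete")
    if (length(unique(D[lower.tri(D)])) == 1L) return(rownames(D))
    rownames(D)[hc$order]
}

#' Summarize a mapped gene-set collection
#'
#' The same statistics reported for a gene-set resource: total genes
#' mapped, genes per set (mean/max/min), pairwise gene overlap
#' (mean/max/min over distinct set pairs), and per-set SNP and probe counts
#' (max/min). With a single set the overlap statistics are reported as 0.
#'
#' @param m a \linkS4class{GSMembership}.
#' @param gsc the matching \linkS4class{GeneSetCollection}.
#' @return one-row data.frame.
#' @export
summarizeCollection <- function(m, gsc) {
    cnt <- membershipCounts(m)
    genes <- m@genes
    G <- length(genes)
    ov <- if (G >= 2) {
        combn2 <- utils::combn(G, 2)
        apply(combn2, 2, function(ij)
            length(intersect(genes[[ij[1]]], genes[[ij[2]]])))
    } else 0
    data.frame(
        n_sets = G,
        total_genes_mapped = length(unique(unlist(genes))),
        genes_per_set_avg = mean(cnt$n_genes),
        genes_per_set_max = max(cnt$n_genes),
        genes_per_set_min = min(cnt$n_genes),
        gene_overlap_avg = mean(ov),
        gene_overlap_max = max(ov),
        gene_overlap_min = min(ov),
        snps_mapped_max = max(cnt$n_snps),
        snps_mapped_min = min(cnt$n_snps),
        probes_mapped_max = max(cnt$n_probes),
        probes_mapped_min = min(cnt$n_probes))
}
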