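# Readers and writers for every external format the pipeline touches.
# Internal coordinate convention: 1-based inclusive (VCF); BED converted
# on read, so a BED record "chr1 99 200" becomes start=100, end=200.

.gtCodes <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
              "./." = NA, "." = NA, "0/." = NA, "./0" = NA,
              "1/." = NA, "./1" = NA)

#' Read genotypes from VCF or dosage TSV
#'
#' Loads biallelic genotypes and orients them to the minor allele: at sites
#' where the counted-allele frequency exceeds 0.5, dosages are recoded as
#' \code{2 - dosage} so that every column counts the rarer allele (a tie at
#' exactly 0.5 keeps the alt allele as the counted allele). Missing genotypes
#' are masked as \code{NA}, not imputed.
#'
#' The dosage TSV dialect defined by this package has one SNP per row with
#' columns \code{id}, \code{chrom}, \code{pos} (1-based), \code{ref},
#' \code{alt}, followed by one numeric column per sample (\code{NA} allowed).
#' Lines starting with \code{#} are comments.
#'
#' @param path path to the file.
#' @param format \code{"vcf"} (VCF 4.x with GT field) or \code{"dosage_tsv"}.
#' @return A \linkS4class{GenotypeExperiment}. Multi-allelic VCF records are
#'   skipped with a warning; a malformed dosage row is a hard error naming
#'   its line.
#' @export
readGenotypes <- function(path, format = c("vcf", "dosage_tsv")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "vcf") .readGenotypesVcf(path) else .readGenotypesTsv(path)
}

.readGenotypesVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    alt <- VariantAnnotation::alt(vcf)
    multi <- S4Vectors::elementNROWS(alt) != 1L
    if (any(multi)) {
        warning(sum(multi), " multi-allelic VCF record(s) skipped")
        vcf <- vcf[!multi]
        alt <- VariantAnnotation::alt(vcf)
    }
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) stop("VCF has no GT field")
    gtn <- gsub("|", "/", gt, fixed = TRUE)
    bad <- !(gtn %in% names(.gtCodes))
    if (any(bad))
        stop("unrecognized GT value(s): ",
             paste(unique(gt[bad]), collapse = ", "))
    dosage <- matrix(.gtCodes[gtn], nrow = nrow(gt),
                     dimnames = dimnames(gt))
    gr <- SummarizedExperiment::rowRanges(vcf)
    snps <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(gr), IRanges::ranges(gr))
    names(snps) <- rownames(gt)
    S4Vectors::mcols(snps)$ref <-
        as.character(VariantAnnotation::ref(vcf))
    S4Vectors::mcols(snps)$alt <- as.character(unlist(alt))
    .orientToMinor(GenotypeExperiment(dosage, snps))
}

.readGenotypesTsv <- function(path) {
    df <- read.delim(path, comment.char = "#", check.names = FALSE,
                     colClasses = "character")
    meta <- c("id", "chrom", "pos", "ref", "alt")
    if (!all(meta %in% names(df)[seq_len(5)]))
        stop("dosage TSV must start with columns: ",
             paste(meta, collapse = ", "))
    sampleCols <- setdiff(names(df), meta)
    if (!length(sampleCols)) stop("dosage TSV has no sample columns")
    dosage <- matrix(NA_real_, nrow(df), length(sampleCols),
                     dimnames = list(df$id, sampleCols))
    for (j in seq_along(sampleCols)) {
        raw <- df[[sampleCols[j]]]
        val <- suppressWarnings(as.numeric(raw))
        malformed <- is.na(val) & !(is.na(raw) | raw %in% c("NA", ""))
        if (any(malformed))
            stop("malformed dosage at line ", which(malformed)[1] + 1L,
                 " (sample ", sampleCols[j], "): '",
                 raw[which(malformed)[1]], "'")
        dosage[, j] <- val
    }
    if (any(dosage < 0 | dosage > 2, na.rm = TRUE))
        stop("dosage values outside [0, 2]")
    snps <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(as.integer(df$pos), width = 1L))
    names(snps) <- df$id
    S4Vectors::mcols(snps)$ref <- df$ref
    S4Vectors::mcols(snps)$alt <- df$alt
    .orientToMinor(GenotypeExperiment(dosage, snps))
}

# Recode columns whose counted-allele frequency exceeds 0.5; ties at 0.5
# keep the current (alt) orientation.
.orientToMinor <- function(g) {
    d <- dosages(g)
    f <- rowMeans(d, na.rm = TRUE) / 2
    flip <- !is.na(f) & f > 0.5
    if (any(flip)) {
        d[flip, ] <- 2 - d[flip, ]
        gr <- snpInfo(g)
        cnt <- S4Vectors::mcols(gr)$counted
        S4Vectors::mcols(gr)$counted <-
            ifelse(flip, S4Vectors::mcols(gr)$ref, cnt)
        g <- GenotypeExperiment(d, gr)
    }
    g
}

#' Write genotypes as a minimal VCF or as dosage TSV
#'
#' The VCF writer emits a minimal VCF 4.2 with GT-only genotype columns
#' (dosage 0/1/2 on the counted allele becomes 0/0, 0/1, 1/1 on the alt
#' allele; missing becomes ./.). Round-trips through [readGenotypes()].
#'
#' @param g a \linkS4class{GenotypeExperiment}.
#' @param path output file.
#' @param format \code{"vcf"} or \code{"dosage_tsv"}.
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(g, path, format = c("vcf", "dosage_tsv")) {
    format <- match.arg(format)
    d <- dosages(g)
    gr <- snpInfo(g)
    ref <- S4Vectors::mcols(gr)$ref
    alt <- S4Vectors::mcols(gr)$alt
    cnt <- S4Vectors::mcols(gr)$counted
    if (is.null(cnt)) cnt <- alt
    # express dosages on the alt allele for serialization
    dAlt <- d
    onRef <- cnt == ref
    dAlt[onRef, ] <- 2 - dAlt[onRef, ]
    if (format == "vcf") {
        gtmap <- c("0/0", "0/1", "1/1")
        gt <- matrix("./.", nrow(d), ncol(d))
        ok <- !is.na(dAlt)
        gt[ok] <- gtmap[round(dAlt[ok]) + 1L]
        lines <- c("##fileformat=VCFv4.2",
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
            paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", colnames(d)), collapse = "\t"),
            paste(as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr), names(gr), ref, alt,
                  ".", ".", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t"))
        writeLines(lines, path)
    } else {
        df <- data.frame(id = names(gr),
            chrom = as.character(GenomicRanges::seqnames(gr)),
            pos = GenomicRanges::start(gr), ref = ref, alt = alt,
            check.names = FALSE)
        df <- cbind(df, as.data.frame(dAlt, check.names = FALSE))
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Read a normalized expression matrix
#'
#' Expects a TSV whose rows are samples (first column \code{sample}) and
#' whose remaining columns are probes. Any missing or non-numeric cell is a
#' hard error naming the row and column; duplicate probe ids are an error.
#'
#' @param path path to the TSV.
#' @return An \linkS4class{ExpressionExperiment} (probes x samples).
#' @export
readExpression <- function(path) {
    df <- read.delim(path, comment.char = "#", check.names = FALSE,
                     colClasses = "character")
    if (names(df)[1] != "sample")
        stop("expression TSV must have first column 'sample'")
    probes <- names(df)[-1]
    if (anyDuplicated(probes))
        stop("duplicate probe id: ",
             probes[duplicated(probes)][1])
    samples <- df$sample
    vals <- matrix(NA_real_, length(probes), length(samples),
                   dimnames = list(probes, samples))
    for (j in seq_along(probes)) {
        raw <- df[[probes[j]]]
        v <- suppressWarnings(as.numeric(raw))
        if (anyNA(v)) {
            i <- which(is.na(v))[1]
            stop("missing or non-numeric expression value at sample '",
                 samples[i], "', probe '", probes[j], "'")
        }
        vals[j, ] <- v
    }
    ExpressionExperiment(vals)
}

#' Write an expression matrix in the samples-by-probes TSV layout
#'
#' Values are serialized at full double precision so a write/read round trip
#' is bitwise exact.
#'
#' @param e an \linkS4class{ExpressionExperiment}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(e, path) {
    v <- exprsValues(e)
    m <- matrix(sprintf("%.17g", t(v)), ncol(v), nrow(v),
                dimnames = list(NULL, rownames(v)))
    df <- cbind(data.frame(sample = colnames(v)), as.data.frame(m,
        check.names = FALSE))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, \code{name TAB description TAB gene ...}.
#' Genes duplicated within one set are deduplicated with a warning; empty
#' sets are retained (they are skipped, with a logged reason, at test time).
#' A duplicated set name is an error. The description field is kept as the
#' set's category label.
#'
#' @param path path to the GMT file.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nms <- vapply(parts, `[`, "", 1L)
    if (anyDuplicated(nms))
        stop("duplicate gene set name: ", nms[duplicated(nms)][1])
    cats <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", "")
    sets <- lapply(parts, function(p) {
        g <- p[-(1:2)]
        g <- g[nzchar(g)]
        if (anyDuplicated(g)) {
            warning("duplicate gene(s) within set '", p[1],
                    "' deduplicated")
            g <- unique(g)
        }
        g
    })
    names(sets) <- nms
    GeneSetCollection(sets, category = setNames(cats, nms))
}

#' Write a GeneSetCollection as GMT
#' @param gsc a \linkS4class{GeneSetCollection}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(gsc, path) {
    sets <- geneSets(gsc)
    cats <- setCategories(gsc)
    lines <- vapply(names(sets), function(nm) {
        desc <- if (nm %in% names(cats)) cats[[nm]] else "na"
        paste(c(nm, desc, sets[[nm]]), collapse = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Read gene annotation (BED or 1-based TSV)
#'
#' BED input (0-based half-open) is converted so that all internal
#' coordinates are 1-based inclusive; the \code{tsv_1based} dialect
#' (columns \code{gene_id}, \code{chrom}, \code{start}, \code{end}, optional
#' \code{strand}) is taken as-is. Both encodings of the same interval yield
#' identical internal records.
#'
#' @param path path to the file.
#' @param dialect \code{"bed"} or \code{"tsv_1based"}.
#' @return A named \link[GenomicRanges]{GRanges}, one range per gene.
#' @export
readGeneAnnotation <- function(path, dialect = c("bed", "tsv_1based")) {
    dialect <- match.arg(dialect)
    if (dialect == "bed") {
        gr <- rtracklayer::import(path, format = "BED")
        names(gr) <- S4Vectors::mcols(gr)$name
        S4Vectors::mcols(gr) <- NULL
    } else {
        df <- read.delim(path, comment.char = "#")
        need <- c("gene_id", "chrom", "start", "end")
        if (!all(need %in% names(df)))
            stop("tsv_1based annotation needs columns: ",
                 paste(need, collapse = ", "))
        if (any(df$start > df$end))
            stop("gene annotation with start > end: ",
                 df$gene_id[df$start > df$end][1])
        strand <- if ("strand" %in% names(df)) df$strand else "*"
        gr <- GenomicRanges::GRanges(df$chrom,
            IRanges::IRanges(df$start, df$end), strand = strand)
        names(gr) <- df$gene_id
    }
    if (anyDuplicated(names(gr)))
        stop("duplicate gene_id in annotation")
    if (any(GenomicRanges::width(gr) < 1))
        stop("gene annotation with start > end")
    gr
}

#' Write gene annotation
#' @param genes named \link[GenomicRanges]{GRanges}.
#' @param path output file.
#' @param dialect \code{"bed"} (0-based half-open on disk) or
#'   \code{"tsv_1based"}.
#' @return \code{path}, invisibly.
#' @export
writeGeneAnnotation <- function(genes, path,
                                dialect = c("bed", "tsv_1based")) {
    dialect <- match.arg(dialect)
    if (dialect == "bed") {
        gr <- genes
        S4Vectors::mcols(gr)$name <- names(gr)
        rtracklayer::export(gr, path, format = "BED")
    } else {
        df <- data.frame(gene_id = names(genes),
            chrom = as.character(GenomicRanges::seqnames(genes)),
            start = GenomicRanges::start(genes),
            end = GenomicRanges::end(genes),
            strand = as.character(GenomicRanges::strand(genes)))
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Read a probe-to-gene map
#'
#' TSV with columns \code{probe_id} and \code{gene_id}; many-to-one and
#' one-to-many mappings are both permitted.
#'
#' @param path path to the TSV.
#' @return data.frame with columns \code{probe_id}, \code{gene_id}.
#' @export
readProbeMap <- function(path) {
    df <- read.delim(path, comment.char = "#",
                     colClasses = "character")
    if (!all(c("probe_id", "gene_id") %in% names(df)))
        stop("probe map needs columns probe_id, gene_id")
    unique(df[, c("probe_id", "gene_id")])
}

#' Read a covariate table
#'
#' TSV with first column \code{sample}; remaining columns are covariates.
#' Columns that parse as numbers are kept numeric, everything else becomes a
#' factor (expanded to indicator contrasts by [buildCovariateMatrix()]).
#'
#' @param path path to the TSV.
#' @return data.frame with rownames = sample ids.
#' @export
readCovariates <- function(path) {
    df <- read.delim(path, comment.char = "#", colClasses = "character")
    if (names(df)[1] != "sample")
        stop("covariate TSV must have first column 'sample'")
    out <- df[, -1, drop = FALSE]
    for (j in seq_along(out)) {
        v <- suppressWarnings(as.numeric(out[[j]]))
        out[[j]] <- if (anyNA(v)) factor(out[[j]]) else v
    }
    rownames(out) <- df$sample
    out
}

.resultCols <- c("type", "gs_expression", "n_genes_expr", "n_probes",
                 "n_pcs_expr", "gs_snp", "n_genes_snp", "n_snps",
                 "n_pcs_snp", "p_value", "fdr")

#' Write the gene-set association result table
#'
#' TSV with columns \code{type, gs_expression, n_genes_expr, n_probes,
#' n_pcs_expr, gs_snp, n_genes_snp, n_snps, n_pcs_snp, p_value, fdr}, sorted
#' by ascending p-value with a stable secondary sort on
#' (\code{gs_expression}, \code{gs_snp}). Numeric columns are written at
#' full double precision so a round trip is exact.
#'
#' @param results data.frame of results from [runAllPairs()] (the \code{fdr}
#'   column may be absent and is written as NA).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(results, path) {
    if (!"fdr" %in% names(results)) results$fdr <- NA_real_
    missing <- setdiff(.resultCols, names(results))
    if (length(missing))
        stop("results lack column(s): ", paste(missing, collapse = ", "))
    out <- results[order(results$p_value, results$gs_expression,
                         results$gs_snp), .resultCols]
    out$p_value <- sprintf("%.17g", out$p_value)
    out$fdr <- ifelse(is.na(out$fdr), "NA", sprintf("%.17g",
        as.numeric(out$fdr)))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read back a result table written by [writeResults()]
#' @param path path to the TSV.
#' @return data.frame with the documented columns.
#' @export
readResults <- function(path) {
    df <- read.delim(path, colClasses = "character")
    for (col in c("n_genes_expr", "n_probes", "n_pcs_expr", "n_genes_snp",
                  "n_snps", "n_pcs_snp"))
        df[[col]] <- as.integer(df[[col]])
    df$p_value <- as.numeric(df$p_value)
    df$fdr <- as.numeric(df$fdr)
    df
}
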