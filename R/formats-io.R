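#' Read TFBS clusters from an ENCODE-style BED file
#'
#' Parses the dialect of the ENCODE TFBS cluster (v3) track
#' (\code{wgEncodeRegTfbsClusteredV3}): tab-separated BED with at least
#' chrom, start, end and name (the regulator), an optional integer score
#' (0-1000) in column 5, and further experiment-list columns that are
#' tolerated and ignored. BED half-open 0-based coordinates are converted
#' to the 1-based closed convention of \linkS4class{GRanges} at parse time.
#' Rows are never merged or reordered; de-duplication, if wanted, is a
#' downstream concern.
#'
#' @param path path to a BED(-like) file; plain text or gzip.
#' @param minScore optional integer; rows with score strictly below it are
#'   dropped. Requires a score column.
#' @param chromAliases optional named character vector mapping input
#'   chromosome names to canonical names (e.g. \code{c("1" = "chr1")}).
#'   Off by default: chromosome matching elsewhere is exact, so silent
#'   renaming would hide input errors.
#' @return A \linkS4class{GRanges} with metadata columns \code{regulator}
#'   and (when present) \code{score}.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tMYC\t900", bed)
#' readTfbsClusters(bed)
#' @export
readTfbsClusters <- function(path, minScore = NULL, chromAliases = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
    if (!length(lines))
        return(GRanges(regulator = character(0)))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ncol <- lengths(fields)
    if (any(ncol < 4L))
        stop("BED format error: line(s) ",
             paste(head(which(ncol < 4L), 5L), collapse = ", "),
             " have fewer than 4 columns (name column required)")
    chrom <- vapply(fields, `[[`, "", 1L)
    start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    bad <- which(is.na(start0) | is.na(end0) | start0 >= end0 | start0 < 0L)
    if (length(bad))
        stop("malformed coordinates on line(s): ",
             paste(head(bad, 5L), collapse = ", "))
    regulator <- vapply(fields, `[[`, "", 4L)
    if (any(!nzchar(regulator)))
        stop("empty regulator name on line(s): ",
             paste(head(which(!nzchar(regulator)), 5L), collapse = ", "))
    if (!is.null(chromAliases)) {
        hit <- chrom %in% names(chromAliases)
        chrom[hit] <- unname(chromAliases[chrom[hit]])
    }
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
    mcols(gr)$regulator <- regulator
    if (all(ncol >= 5L)) {
        score <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
        if (!anyNA(score) && all(score >= 0L & score <= 1000L))
            mcols(gr)$score <- score
    }
    if (!is.null(minScore)) {
        if (is.null(mcols(gr)$score))
            stop("minScore given but the file carries no usable score column")
        gr <- gr[mcols(gr)$score >= minScore]
    }
    gr
}

#' Write TFBS clusters as BED
#'
#' Inverse of [readTfbsClusters()]: emits 4 or 5 tab-separated columns,
#' converting back to 0-based half-open coordinates.
#'
#' @param clusters a \linkS4class{GRanges} with a \code{regulator} column.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTfbsClusters <- function(clusters, path) {
    df <- data.frame(chrom = as.character(seqnames(clusters)),
                     start = start(clusters) - 1L,
                     end = end(clusters),
                     name = mcols(clusters)$regulator)
    if (!is.null(mcols(clusters)$score))
        df$score <- mcols(clusters)$score
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

.readVariantsTsv <- function(path, sample) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character")
    need <- c("chrom", "pos", "ref", "alt", "ref_reads", "alt_reads")
    missing <- setdiff(need, colnames(df))
    if (length(missing))
        stop("variant TSV is missing column(s): ",
             paste(missing, collapse = ", "))
    if (nrow(df) == 0L)
        return(VariantCalls(sample = sample))
    VariantCalls(df$chrom, as.integer(df$pos), df$ref, df$alt,
                 as.integer(df$ref_reads), as.integer(df$alt_reads),
                 sample = sample)
}

.readVariantsVcf <- function(path, sample) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop("reading VCF requires the VariantAnnotation package; ",
             "use the TSV dialect otherwise")
    vcf <- VariantAnnotation::readVcf(path)
    if (!"AD" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf))))
        stop("VCF lacks the AD (allele depth) FORMAT field: ", path)
    # expand() splits multi-allelic records into one row per alt and
    # subsets AD accordingly (ref depth + the matching alt depth)
    vcf <- VariantAnnotation::expand(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    ad <- VariantAnnotation::geno(vcf)$AD
    # post-expand() AD is records x samples x 2 (ref, matching alt), or a
    # matrix of length-2 vectors depending on header Number
    if (length(dim(ad)) == 3L) {
        if (dim(ad)[2L] != 1L)
            stop("expected a single-sample VCF: ", path)
        refd <- ad[, 1L, 1L]
        altd <- ad[, 1L, 2L]
    } else {
        if (ncol(ad) != 1L)
            stop("expected a single-sample VCF: ", path)
        admat <- matrix(unlist(ad[, 1L]), ncol = 2L, byrow = TRUE)
        refd <- admat[, 1L]
        altd <- admat[, 2L]
    }
    alt <- as.character(rr$ALT)
    keep <- grepl("^[ACGT]+$", alt)   # drop symbolic/spanning alleles
    VariantCalls(as.character(seqnames(rr))[keep], start(rr)[keep],
                 as.character(rr$REF)[keep], alt[keep],
                 refd[keep], altd[keep], sample = sample)
}

#' Read variant calls from TSV or VCF
#'
#' The TSV dialect has a single header line and columns
#' \code{chrom, pos, ref, alt, ref_reads, alt_reads} (\code{pos} 1-based,
#' first reference base). VCF input (extension \code{.vcf}/\code{.vcf.gz})
#' requires per-record AD allele depths; multi-allelic records are split
#' into one call per alternate allele.
#'
#' @param path input file.
#' @param sample sample label attached to every call: \code{"germline"},
#'   \code{"diagnosis"} or \code{"relapse"}.
#' @return A \linkS4class{VariantCalls} object.
#' @export
readVariants <- function(path, sample = c("diagnosis", "relapse", "germline")) {
    sample <- match.arg(sample)
    if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path))
        .readVariantsVcf(path, sample)
    else
        .readVariantsTsv(path, sample)
}

#' Write variant calls as TSV
#'
#' Inverse of the TSV branch of [readVariants()].
#'
#' @param calls a \linkS4class{VariantCalls} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVariants <- function(calls, path) {
    df <- data.frame(chrom = as.character(seqnames(calls)),
                     pos = start(calls),
                     ref = mcols(calls)$ref, alt = mcols(calls)$alt,
                     ref_reads = mcols(calls)$refReads,
                     alt_reads = mcols(calls)$altReads)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A \linkS4class{DNAStringSet}, sequences uppercased, names
#'   truncated at the first whitespace.
#' @export
readGenome <- function(path) {
    dna <- Biostrings::readDNAStringSet(path)
    names(dna) <- sub("\\s.*$", "", names(dna))
    # uppercase so soft-masked references compare equal to allele strings
    Biostrings::DNAStringSet(toupper(dna))
}

#' Extract genome sequence for intervals
#'
#' @param genome a \linkS4class{DNAStringSet} as returned by [readGenome()].
#' @param gr a \linkS4class{GRanges}; strand is honoured (minus-strand
#'   ranges return the reverse complement).
#' @return A \linkS4class{DNAStringSet}, one sequence per range.
#' @export
genomeSeq <- function(genome, gr) {
    missing <- setdiff(as.character(unique(seqnames(gr))), names(genome))
    if (length(missing))
        stop("chromosome(s) absent from genome: ",
             paste(missing, collapse = ", "))
    res <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
        s <- as.character(Biostrings::subseq(genome[[as.character(seqnames(gr)[i])]],
                                             start(gr)[i], end(gr)[i]))
        s
    }, character(1)))
    neg <- as.logical(strand(gr) == "-")
    if (any(neg))
        res[neg] <- Biostrings::reverseComplement(res[neg])
    res
}

# GFF3 attribute helper: value of key in a ;-separated attribute string
.gffAttr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[[2L]] else NA_character_, "")
}

.gtfAttr <- function(attrs, key) {
    m <- regmatches(attrs,
                    regexec(paste0(key, ' "([^"]+)"'), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[[2L]] else NA_character_, "")
}

#' Read gene models from GFF3 or GTF
#'
#' Parses gene/mRNA/CDS features (GFF3 \code{ID}/\code{Parent} linkage, or
#' GTF \code{gene_id}/\code{transcript_id} attributes) and keeps one
#' protein-coding transcript per gene: the transcript with the longest
#' total CDS, ties broken lexicographically by transcript id. 1-based
#' inclusive GFF coordinates map directly onto \linkS4class{GRanges}.
#' Transcripts whose CDS length is not divisible by 3 are flagged
#' non-codable with a warning and excluded from consequence calls.
#'
#' @param path GFF3 or GTF file (extension decides the attribute dialect;
#'   \code{.gtf} means GTF, anything else GFF3).
#' @return A \linkS4class{GeneModels} object.
#' @export
readGeneModels <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    gtf <- grepl("\\.gtf(\\.gz)?$", path)
    if (!length(lines))
        return(new("GeneModels", genes = GRanges(gene_id = character(0),
                   gene_name = character(0), tx_id = character(0),
                   codable = logical(0)), cds = GRangesList()))
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 9L))
        stop("malformed GFF/GTF: fewer than 9 columns")
    col <- function(i) vapply(f, `[[`, "", i)
    type <- col(3L)
    attrs <- col(9L)
    df <- data.frame(chrom = col(1L), type = type,
                     start = as.integer(col(4L)), end = as.integer(col(5L)),
                     strand = col(7L), attrs = attrs)
    if (gtf) {
        df$tx_id <- .gtfAttr(attrs, "transcript_id")
        df$gene_id <- .gtfAttr(attrs, "gene_id")
        df$gene_name <- .gtfAttr(attrs, "gene_name")
        mrna <- df[df$type %in% c("transcript", "mRNA"), ]
        tx2gene <- stats::setNames(mrna$gene_id, mrna$tx_id)
        tx2name <- stats::setNames(
            ifelse(is.na(mrna$gene_name), mrna$gene_id, mrna$gene_name),
            mrna$tx_id)
    } else {
        id <- .gffAttr(attrs, "ID")
        parent <- .gffAttr(attrs, "Parent")
        name <- .gffAttr(attrs, "Name")
        genes <- df$type == "gene"
        gene2name <- stats::setNames(ifelse(is.na(name[genes]),
                                            id[genes], name[genes]), id[genes])
        mrna <- df$type %in% c("mRNA", "transcript")
        tx2gene <- stats::setNames(parent[mrna], id[mrna])
        tx2name <- stats::setNames(unname(gene2name[parent[mrna]]), id[mrna])
        df$tx_id <- parent      # for CDS rows, Parent is the transcript
        mrna <- df[mrna, ]
    }
    cdsdf <- df[df$type == "CDS", ]
    if (nrow(cdsdf) == 0L)
        stop("no CDS features found in ", path)
    cdsdf$gene_id <- unname(tx2gene[cdsdf$tx_id])
    if (anyNA(cdsdf$gene_id))
        stop("CDS feature(s) with unknown transcript parent in ", path)
    # pick the transcript with the longest CDS per gene; ties by tx id
    lens <- tapply(cdsdf$end - cdsdf$start + 1L,
                   cdsdf$tx_id, sum)
    txTab <- data.frame(tx_id = names(lens), len = as.integer(lens))
    txTab$gene_id <- unname(tx2gene[txTab$tx_id])
    txTab <- txTab[order(txTab$gene_id, -txTab$len, txTab$tx_id), ]
    chosen <- txTab[!duplicated(txTab$gene_id), ]
    cdsdf <- cdsdf[cdsdf$tx_id %in% chosen$tx_id, ]
    cdsdf <- cdsdf[order(cdsdf$gene_id, cdsdf$start), ]
    cdsGrl <- GRangesList(lapply(split(cdsdf, cdsdf$gene_id), function(d)
        GRanges(d$chrom, IRanges(d$start, d$end), strand = d$strand[1L])))
    geneIds <- names(cdsGrl)
    spans <- unlist(range(cdsGrl))
    txOfGene <- stats::setNames(chosen$tx_id, chosen$gene_id)[geneIds]
    codable <- vapply(cdsGrl, function(g) sum(width(g)) %% 3L == 0L, TRUE)
    if (any(!codable))
        warning("gene model(s) with CDS length not divisible by 3 flagged ",
                "non-codable: ", paste(geneIds[!codable], collapse = ", "))
    gname <- unname(tx2name[txOfGene])
    gname[is.na(gname)] <- geneIds[is.na(gname)]
    mcols(spans) <- DataFrame(gene_id = geneIds, gene_name = gname,
                              tx_id = unname(txOfGene), codable = codable)
    names(spans) <- NULL
    new("GeneModels", genes = spans, cds = cdsGrl)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and CDS features with ID/Parent linkage, 1-based
#' inclusive coordinates. Inverse of the GFF3 branch of
#' [readGeneModels()] for models this package produces.
#'
#' @param models a \linkS4class{GeneModels} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(models, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    g <- geneRanges(models)
    cds <- cdsByGene(models)
    for (i in seq_along(g)) {
        gid <- mcols(g)$gene_id[i]
        tid <- mcols(g)$tx_id[i]
        chrom <- as.character(seqnames(g)[i])
        std <- as.character(strand(g)[i])
        writeLines(c(
            paste(chrom, "TRAscan", "gene", start(g)[i], end(g)[i], ".",
                  std, ".", paste0("ID=", gid, ";Name=",
                                   mcols(g)$gene_name[i]), sep = "\t"),
            paste(chrom, "TRAscan", "mRNA", start(g)[i], end(g)[i], ".",
                  std, ".", paste0("ID=", tid, ";Parent=", gid), sep = "\t")),
            con)
        segs <- cds[[gid]]
        # phase in transcript order: minus strand reads right-to-left
        ord <- if (std == "-") rev(seq_along(segs)) else seq_along(segs)
        phase <- integer(length(segs))
        acc <- 0L
        for (j in ord) {
            phase[j] <- (3L - acc %% 3L) %% 3L
            acc <- acc + width(segs)[j]
        }
        writeLines(paste(chrom, "TRAscan", "CDS", start(segs), end(segs),
                         ".", std, phase,
                         paste0("ID=cds-", tid, ";Parent=", tid), sep = "\t"),
                   con)
    }
    invisible(path)
}

#' Write TRA regions as BED(+)
#'
#' BED 0-based half-open coordinates, name \code{TRA_<n>}, score
#' \code{maxDepth}, plus a sixth column with the semicolon-joined
#' regulator union.
#'
#' @param tras a \linkS4class{TRARegions} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTraRegions <- function(tras, path) {
    df <- data.frame(chrom = as.character(seqnames(tras)),
                     start = start(tras) - 1L, end = end(tras),
                     name = paste0("TRA_", seq_along(tras)),
                     score = mcols(tras)$maxDepth,
                     regulators = vapply(mcols(tras)$regulators,
                                         paste, "", collapse = ";"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

# single-header TSV writer used by all report outputs (UTF-8, LF)
.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, eol = "\n",
                       fileEncoding = "UTF-8")
    invisible(path)
}
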