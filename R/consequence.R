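# --- coding-consequence annotation -----------------------------------------
#
# SNVs inside a CDS segment are classified by translating the affected codon
# on the coding strand; indels overlapping any CDS base are frameshift or
# in-frame by the mod-3 rule on the length difference. Everything else is
# non_CDS (no splice/UTR sub-classes: the analysis only distinguishes CDS
# from non-CDS).

# CDS (transcript) coordinate of genomic base gpos, or NA if not in CDS.
# segs: CDS segments in genomic order; minus-strand transcripts read
# right-to-left.
.cdsPos <- function(segs, std, gpos) {
    hit <- which(gpos >= start(segs) & gpos <= end(segs))
    if (!length(hit))
        return(NA_integer_)
    w <- width(segs)
    if (std == "+") {
        before <- if (hit > 1L) sum(w[seq_len(hit - 1L)]) else 0L
        before + (gpos - start(segs)[hit] + 1L)
    } else {
        after <- if (hit < length(segs)) sum(w[seq(hit + 1L, length(segs))]) else 0L
        after + (end(segs)[hit] - gpos + 1L)
    }
}

# spliced CDS on the coding strand
.splicedCds <- function(genome, chrom, segs, std) {
    s <- paste(vapply(seq_along(segs), function(j)
        as.character(Biostrings::subseq(genome[[chrom]],
                                        start(segs)[j], end(segs)[j])),
        character(1)), collapse = "")
    if (std == "-")
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.aa1 <- function(codon) {
    aa <- Biostrings::GENETIC_CODE[[codon]]
    if (is.null(aa)) stop("bad codon: ", codon)
    aa
}

#' Annotate coding consequence of variant calls
#'
#' Classifies each call against one-transcript-per-gene models
#' (\linkS4class{GeneModels}) and the genome sequence. SNVs falling in a
#' CDS segment of a codable model are classified by codon translation on
#' the coding strand (\code{synonymous}, \code{missense}, \code{nonsense},
#' \code{stop_lost}, \code{start_lost}); indels overlapping CDS are
#' \code{frameshift} when the ref/alt length difference is not a multiple
#' of 3, else \code{inframe_indel}; calls without CDS overlap (including
#' those only touching non-codable models) are \code{non_CDS}. An
#' HGVS-flavoured label such as \code{"c.3340G>T (p.E1114*)"} or
#' \code{"c.504delG (p.L168fs)"} is rendered for coding calls.
#'
#' Indels spanning a CDS boundary are classed by their CDS-overlapping
#' portion; a call overlapping several genes' CDS is attributed to the
#' left-most gene (ties by gene id) for determinism.
#'
#' @param calls a \linkS4class{VariantCalls} object.
#' @param models a \linkS4class{GeneModels} object.
#' @param genome a \linkS4class{DNAStringSet} (see [readGenome()]).
#' @return \code{calls} with metadata columns added: \code{variantClass}
#'   (\code{SNV}/\code{indel}), \code{consequence}, \code{geneId},
#'   \code{hgvsLike}.
#' @export
annotateConsequence <- function(calls, models, genome) {
    g <- geneRanges(models)
    keep <- mcols(g)$codable
    g <- g[keep]
    cds <- cdsByGene(models)[as.character(mcols(g)$gene_id)]
    flat <- unlist(cds, use.names = FALSE)
    geneOfSeg <- rep(seq_along(cds), lengths(cds))

    n <- length(calls)
    variantClass <- ifelse(nchar(mcols(calls)$ref) == 1L &
                           nchar(mcols(calls)$alt) == 1L, "SNV", "indel")
    consequence <- rep("non_CDS", n)
    geneId <- rep(NA_character_, n)
    hgvs <- rep(NA_character_, n)

    if (n == 0L || length(flat) == 0L) {
        mcols(calls)$variantClass <- variantClass
        mcols(calls)$consequence <- consequence
        mcols(calls)$geneId <- geneId
        mcols(calls)$hgvsLike <- hgvs
        return(calls)
    }

    # reference check for every call on a chromosome we have sequence for
    for (i in seq_len(n)) {
        chrom <- as.character(seqnames(calls)[i])
        if (!chrom %in% names(genome)) next
        obs <- as.character(Biostrings::subseq(genome[[chrom]],
                                               start(calls)[i], end(calls)[i]))
        if (obs != mcols(calls)$ref[i])
            stop("reference mismatch at ", chrom, ":", start(calls)[i],
                 " (expected ", mcols(calls)$ref[i], ", genome has ", obs, ")")
    }

    hits <- findOverlaps(granges(calls), flat, ignore.strand = TRUE)
    if (length(hits)) {
        # deterministic gene choice: left-most gene span, then gene id
        hdf <- data.frame(q = queryHits(hits), gene = geneOfSeg[subjectHits(hits)])
        hdf <- unique(hdf)
        ord <- order(hdf$q, start(g)[hdf$gene],
                     as.character(mcols(g)$gene_id)[hdf$gene])
        hdf <- hdf[ord, ]
        hdf <- hdf[!duplicated(hdf$q), ]

        for (k in seq_len(nrow(hdf))) {
            i <- hdf$q[k]; gi <- hdf$gene[k]
            segs <- cds[[gi]]
            std <- as.character(strand(g)[gi])
            chrom <- as.character(seqnames(g)[gi])
            gid <- as.character(mcols(g)$gene_id)[gi]
            geneId[i] <- gid
            ref <- mcols(calls)$ref[i]; alt <- mcols(calls)$alt[i]
            if (variantClass[i] == "indel") {
                # boundary-spanning indels are classed by their
                # CDS-overlapping portion: for a canonical deletion only
                # the deleted bases inside CDS count
                if (nchar(alt) == 1L && nchar(ref) > 1L) {
                    delPos <- seq(start(calls)[i] + 1L, end(calls)[i])
                    diffLen <- sum(vapply(delPos, function(p)
                        any(p >= start(segs) & p <= end(segs)), TRUE))
                } else {
                    diffLen <- abs(nchar(ref) - nchar(alt))
                }
                if (diffLen == 0L) {   # shared anchor base only; CDS intact
                    geneId[i] <- NA_character_
                    next
                }
                consequence[i] <- if (diffLen %% 3L != 0L) "frameshift"
                                  else "inframe_indel"
                hgvs[i] <- .indelHgvs(calls[i], segs, std, genome, chrom,
                                      consequence[i])
                next
            }
            gpos <- start(calls)[i]
            cpos <- .cdsPos(segs, std, gpos)
            if (is.na(cpos)) next  # defensive; hit implies containment for SNV
            cdsSeq <- .splicedCds(genome, chrom, segs, std)
            refT <- if (std == "+") ref else unname(.COMPLEMENT[ref])
            altT <- if (std == "+") alt else unname(.COMPLEMENT[alt])
            codonIdx <- (cpos - 1L) %/% 3L            # 0-based codon index
            within <- (cpos - 1L) %% 3L + 1L
            codon <- substr(cdsSeq, codonIdx * 3L + 1L, codonIdx * 3L + 3L)
            if (substr(codon, within, within) != refT)
                stop("internal CDS mapping error at ", chrom, ":", gpos)
            mut <- codon
            substr(mut, within, within) <- altT
            aaWt <- .aa1(codon); aaMut <- .aa1(mut)
            consequence[i] <-
                if (aaWt == aaMut) "synonymous"
                else if (aaMut == "*") "nonsense"
                else if (aaWt == "*") "stop_lost"
                else if (codonIdx == 0L && codon == "ATG") "start_lost"
                else "missense"
            hgvs[i] <- sprintf("c.%d%s>%s (p.%s%d%s)", cpos, refT, altT,
                               aaWt, codonIdx + 1L, aaMut)
        }
    }
    mcols(calls)$variantClass <- variantClass
    mcols(calls)$consequence <- consequence
    mcols(calls)$geneId <- geneId
    mcols(calls)$hgvsLike <- hgvs
    calls
}

# HGVS-flavoured label for a CDS-overlapping indel; uses the first
# affected base that maps into the CDS (in transcript order)
.indelHgvs <- function(call, segs, std, genome, chrom, consequence) {
    ref <- mcols(call)$ref; alt <- mcols(call)$alt
    deletion <- nchar(ref) > nchar(alt)
    # affected genomic bases: for a VCF-style indel the first base is shared
    affected <- if (nchar(ref) > 1L)
        seq(start(call) + 1L, end(call)) else start(call)
    cpositions <- vapply(affected, function(p) .cdsPos(segs, std, p),
                         integer(1))
    cpositions <- cpositions[!is.na(cpositions)]
    if (!length(cpositions))
        cpositions <- .cdsPos(segs, std, start(call))
    cpos <- suppressWarnings(min(cpositions, na.rm = TRUE))
    if (!is.finite(cpos))
        return(NA_character_)
    aaIdx <- (cpos - 1L) %/% 3L + 1L
    cdsSeq <- .splicedCds(genome, chrom, segs, std)
    codon <- substr(cdsSeq, (aaIdx - 1L) * 3L + 1L, aaIdx * 3L)
    aaWt <- if (nchar(codon) == 3L) .aa1(codon) else "X"
    changed <- if (deletion) substr(ref, 2L, nchar(ref))
               else substr(alt, 2L, nchar(alt))
    if (std == "-")
        changed <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(changed)))
    op <- if (deletion) paste0("del", changed) else paste0("ins", changed)
    paa <- if (consequence == "frameshift") sprintf("p.%s%dfs", aaWt, aaIdx)
           else sprintf("p.%s%d%s", aaWt, aaIdx,
                        if (deletion) "del" else "ins")
    sprintf("c.%d%s (%s)", cpos, op, paa)
}

#' Translate the coding sequence of gene models
#'
#' Utility used by the simulator audits and tests: returns the protein
#' translation of each codable model's spliced CDS.
#'
#' @param models a \linkS4class{GeneModels} object.
#' @param genome a \linkS4class{DNAStringSet}.
#' @return A named character vector of protein sequences (with trailing
#'   \code{*}), one per codable gene.
#' @export
translateModels <- function(models, genome) {
    g <- geneRanges(models)
    g <- g[mcols(g)$codable]
    cds <- cdsByGene(models)[as.character(mcols(g)$gene_id)]
    out <- vapply(seq_along(cds), function(i) {
        s <- .splicedCds(genome, as.character(seqnames(g)[i]), cds[[i]],
                         as.character(strand(g)[i]))
        as.character(Biostrings::translate(Biostrings::DNAString(s)))
    }, character(1))
    names(out) <- as.character(mcols(g)$gene_id)
    out
}
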