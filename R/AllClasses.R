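#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @importFrom GenomeInfoDb seqnames seqlevels sortSeqlevels
#' @import GenomicRanges
NULL

.VALID_SAMPLES <- c("germline", "diagnosis", "relapse")
.VALID_STATUS <- c("common", "additional", "lost")
.CODING_CONSEQUENCES <- c("synonymous", "missense", "nonsense", "stop_lost",
                          "start_lost", "frameshift", "inframe_indel")
.ALL_CONSEQUENCES <- c(.CODING_CONSEQUENCES, "non_CDS")

#' VariantCalls: somatic/germline variant calls with read support
#'
#' A \linkS4class{GRanges}-backed container for variant calls. Each range
#' spans the reference allele (1-based, closed, as in VCF); metadata columns
#' carry the \code{ref} and \code{alt} allele strings, the supporting read
#' counts \code{refReads} and \code{altReads}, and the \code{sample} label
#' (one of \code{germline}, \code{diagnosis}, \code{relapse}).
#'
#' The variant allele frequency (VAF) is defined as
#' \code{altReads / (refReads + altReads)}; depth carried by other alleles is
#' deliberately excluded, matching AD-style two-allele accounting.
#'
#' @seealso [readVariants()], [filterCalls()], [subtractGermline()]
#' @export
setClass("VariantCalls", contains = "GRanges")

setValidity("VariantCalls", function(object) {
    msg <- NULL
    mc <- mcols(object)
    need <- c("ref", "alt", "refReads", "altReads", "sample")
    missing <- setdiff(need, colnames(mc))
    if (length(missing))
        return(paste("missing metadata column(s):",
                     paste(missing, collapse = ", ")))
    if (length(object)) {
        if (!all(grepl("^[ACGT]+$", mc$ref)) || !all(grepl("^[ACGT]+$", mc$alt)))
            msg <- c(msg, "ref/alt alleles must be non-empty strings over A,C,G,T")
        if (any(mc$ref == mc$alt))
            msg <- c(msg, "ref and alt must differ")
        if (any(mc$refReads < 0) || any(mc$altReads < 0))
            msg <- c(msg, "read counts must be non-negative")
        if (!all(mc$sample %in% .VALID_SAMPLES))
            msg <- c(msg, paste("sample must be one of:",
                                paste(.VALID_SAMPLES, collapse = ", ")))
        if (any(width(object) != nchar(mc$ref)))
            msg <- c(msg, "range width must equal reference allele length")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a VariantCalls object
#'
#' @param chrom chromosome names.
#' @param pos 1-based position of the first reference base (VCF convention).
#' @param ref,alt reference and alternate allele strings (A/C/G/T).
#' @param refReads,altReads supporting read counts for ref and alt.
#' @param sample sample label, recycled: \code{"germline"}, \code{"diagnosis"}
#'   or \code{"relapse"}.
#' @return A \linkS4class{VariantCalls} object.
#' @examples
#' VariantCalls("chr2", 501, "G", "T", refReads = 14, altReads = 6,
#'              sample = "diagnosis")
#' @export
VariantCalls <- function(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         refReads = integer(), altReads = integer(),
                         sample = "diagnosis") {
    gr <- GRanges(chrom, IRanges(as.integer(pos), width = nchar(ref)))
    mcols(gr) <- DataFrame(ref = as.character(ref), alt = as.character(alt),
                           refReads = as.integer(refReads),
                           altReads = as.integer(altReads),
                           sample = rep_len(as.character(sample), length(gr)))
    new("VariantCalls", gr)
}

#' TRARegions: transcription regulatory areas
#'
#' A \linkS4class{GRanges}-backed container for transcription regulatory
#' areas (TRAs): maximal genomic intervals on which at least
#' \code{minRegulators} distinct transcription regulators have overlapping
#' binding-site clusters. Metadata columns: \code{regulators}, a
#' \linkS4class{CharacterList} with the union of regulator names whose
#' clusters overlap the region, and \code{maxDepth}, the maximum number of
#' distinct regulators simultaneously bound at any base of the region.
#'
#' @seealso [buildTraRegions()]
#' @export
setClass("TRARegions", contains = "GRanges")

setValidity("TRARegions", function(object) {
    mc <- mcols(object)
    if (!all(c("regulators", "maxDepth") %in% colnames(mc)))
        return("metadata columns 'regulators' and 'maxDepth' are required")
    if (length(object)) {
        if (!is(mc$regulators, "CharacterList"))
            return("'regulators' must be a CharacterList")
        if (any(mc$maxDepth < 1L))
            return("maxDepth must be >= 1")
        if (any(lengths(mc$regulators) < mc$maxDepth))
            return("|regulators| must be >= maxDepth")
    }
    TRUE
})

#' TRAAlterations: classified variants joined to their TRA
#'
#' A \linkS4class{GRanges}-backed container holding, for each filtered and
#' classified variant whose anchor base falls inside a TRA, the anchor
#' position (width-1 range), the variant alleles and timepoint
#' \code{status} (\code{common}/\code{additional}/\code{lost}), the index
#' of the containing TRA (\code{traIndex}) and the set of regulators whose
#' clusters overlap the mutated base (\code{involved},
#' a \linkS4class{CharacterList}).
#'
#' @seealso [intersectVariantsTras()], [involvementTable()]
#' @export
setClass("TRAAlterations", contains = "GRanges")

setValidity("TRAAlterations", function(object) {
    mc <- mcols(object)
    need <- c("ref", "alt", "status", "traIndex", "involved")
    missing <- setdiff(need, colnames(mc))
    if (length(missing))
        return(paste("missing metadata column(s):",
                     paste(missing, collapse = ", ")))
    if (length(object)) {
        if (!all(mc$status %in% .VALID_STATUS))
            return("status must be common/additional/lost")
        if (!is(mc$involved, "CharacterList"))
            return("'involved' must be a CharacterList")
        if (any(width(object) != 1L))
            return("anchors must be width-1 ranges")
    }
    TRUE
})

#' GeneModels: one protein-coding transcript model per gene
#'
#' Holds gene spans and CDS structures for consequence annotation. The
#' \code{genes} slot is a \linkS4class{GRanges} of transcript extents
#' (one per gene; strand set) with metadata columns \code{gene_id},
#' \code{gene_name}, \code{tx_id} and \code{codable} (CDS length divisible
#' by 3). The \code{cds} slot is a \linkS4class{GRangesList}, named by
#' \code{gene_id}, of CDS segments in genomic order.
#'
#' @seealso [readGeneModels()], [annotateConsequence()]
#' @export
setClass("GeneModels",
         representation(genes = "GRanges", cds = "GRangesList"))

setValidity("GeneModels", function(object) {
    g <- object@genes
    need <- c("gene_id", "gene_name", "tx_id", "codable")
    if (!all(need %in% colnames(mcols(g))))
        return(paste("genes slot needs metadata columns:",
                     paste(need, collapse = ", ")))
    cdsNames <- names(object@cds)
    if (is.null(cdsNames)) cdsNames <- character(0)
    if (!identical(cdsNames, as.character(mcols(g)$gene_id)))
        return("cds list names must equal genes gene_id, in order")
    for (i in seq_along(object@cds)) {
        segs <- object@cds[[i]]
        if (length(segs) == 0L)
            return("every gene model must have at least one CDS segment")
        if (is.unsorted(start(segs)))
            return("CDS segments must be in genomic order")
        if (length(segs) > 1L &&
            any(start(segs)[-1L] <= end(segs)[-length(segs)]))
            return("CDS segments must be pairwise non-overlapping")
        if (any(start(segs) < start(g)[i]) || any(end(segs) > end(g)[i]))
            return("CDS segments must lie within the gene span")
    }
    TRUE
})

#' @describeIn GeneModels-class number of gene models
#' @param x,object a \code{GeneModels} object
#' @export
setMethod("length", "GeneModels", function(x) length(x@genes))

#' Accessors for TRAscan classes
#'
#' \code{vaf} returns the variant allele frequency
#' \code{altReads/(refReads+altReads)} (NaN at zero depth);
#' \code{variantKeys} the identity key \code{chrom:pos:ref>alt} used for
#' germline subtraction and timepoint matching; \code{regulators} the
#' per-region regulator sets of a \linkS4class{TRARegions};
#' \code{involvedRegulators} the per-alteration regulator sets of a
#' \linkS4class{TRAAlterations}; \code{geneRanges} and \code{cdsByGene} the
#' slots of a \linkS4class{GeneModels}.
#'
#' @param x an object of the documented class
#' @return See the description for each accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vaf", function(x) standardGeneric("vaf"))
#' @rdname accessors
#' @export
setMethod("vaf", "VariantCalls", function(x) {
    depth <- mcols(x)$refReads + mcols(x)$altReads
    ifelse(depth == 0L, NaN, mcols(x)$altReads / depth)
})

#' @rdname accessors
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))
#' @rdname accessors
#' @export
.keyOf <- function(x) {
    if (length(x) == 0L)  # paste0 would recycle the separators to "::>"
        return(character(0))
    paste0(seqnames(x), ":", start(x), ":", mcols(x)$ref, ">", mcols(x)$alt)
}
#' @rdname accessors
#' @export
setMethod("variantKeys", "VariantCalls", .keyOf)
#' @rdname accessors
#' @export
setMethod("variantKeys", "TRAAlterations", .keyOf)

#' @rdname accessors
#' @export
setGeneric("regulators", function(x) standardGeneric("regulators"))
#' @rdname accessors
#' @export
setMethod("regulators", "TRARegions", function(x) mcols(x)$regulators)

#' @rdname accessors
#' @export
setGeneric("maxDepth", function(x) standardGeneric("maxDepth"))
#' @rdname accessors
#' @export
setMethod("maxDepth", "TRARegions", function(x) mcols(x)$maxDepth)

#' @rdname accessors
#' @export
setGeneric("involvedRegulators", function(x) standardGeneric("involvedRegulators"))
#' @rdname accessors
#' @export
setMethod("involvedRegulators", "TRAAlterations", function(x) mcols(x)$involved)

#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname accessors
#' @export
setMethod("geneRanges", "GeneModels", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("cdsByGene", function(x) standardGeneric("cdsByGene"))
#' @rdname accessors
#' @export
setMethod("cdsByGene", "GeneModels", function(x) x@cds)

setMethod("show", "GeneModels", function(object) {
    n <- length(object)
    cat("GeneModels with", n, "gene model(s);",
        sum(mcols(object@genes)$codable), "codable\n")
    if (n)
        show(object@genes)
})

setMethod("show", "TRARegions", function(object) {
    cat("TRARegions with", length(object), "region(s), ",
        sum(width(object)), "bp total coverage\n")
    callNextMethod()
})
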