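#' Filter variant calls on allele frequency and read support
#'
#' Implements the variant identification condition "more than 20\% of at
#' least five reads": a call is retained iff its VAF is strictly greater
#' than \code{minVaf} AND its supporting reads meet \code{minAltReads}
#' (inclusive). By default the read criterion counts alt-supporting reads;
#' \code{depthRule = "total"} applies it to total depth instead (the other
#' natural reading). Calls with zero depth are rejected with reason
#' \code{"zero_depth"}, never a division error. Relative order is
#' preserved; a filter log counting rejects by reason is attached as the
#' \code{"filterLog"} attribute.
#'
#' @param calls a \linkS4class{VariantCalls} object.
#' @param minVaf strict lower bound on VAF (default 0.20).
#' @param minAltReads inclusive lower bound on supporting reads (default 5).
#' @param depthRule \code{"alt"} (default) or \code{"total"}: which depth
#'   the read criterion applies to.
#' @return The retained \linkS4class{VariantCalls}, with attribute
#'   \code{filterLog}: a named integer vector of reject counts
#'   (\code{zero_depth}, \code{low_vaf}, \code{low_reads}) plus
#'   \code{retained}.
#' @examples
#' x <- VariantCalls("chr1", c(10, 20, 30), "G", "T",
#'                   refReads = c(20L, 6L, 14L), altReads = c(5L, 4L, 6L))
#' filterCalls(x)   # only the 6/20 call (VAF 0.30, 6 reads) survives
#' @export
filterCalls <- function(calls, minVaf = 0.20, minAltReads = 5L,
                        depthRule = c("alt", "total")) {
    depthRule <- match.arg(depthRule)
    stopifnot(minVaf >= 0, minVaf < 1, minAltReads >= 0)
    depth <- mcols(calls)$refReads + mcols(calls)$altReads
    v <- vaf(calls)
    reads <- if (depthRule == "alt") mcols(calls)$altReads else depth
    zero <- depth == 0L
    lowVaf <- !zero & !(v > minVaf)
    lowReads <- !zero & (v > minVaf) & reads < minAltReads
    keep <- !zero & v > minVaf & reads >= minAltReads
    out <- calls[keep]
    attr(out, "filterLog") <- c(retained = sum(keep),
                                zero_depth = sum(zero),
                                low_vaf = sum(lowVaf),
                                low_reads = sum(lowReads))
    out
}

#' Subtract germline calls from a tumor call set
#'
#' Removes tumor calls whose identity key \code{(chrom, pos, ref, alt)}
#' occurs in the germline set; germline read counts are irrelevant to the
#' match. Keys are compared as-is: indels are assumed left-normalised
#' upstream (see [leftAlignCalls()] for an optional pass).
#'
#' @param tumor,germline \linkS4class{VariantCalls} objects.
#' @return The tumor calls whose key is absent from the germline set.
#' @export
subtractGermline <- function(tumor, germline) {
    tumor[!(variantKeys(tumor) %in% variantKeys(germline))]
}

#' Left-align indels against the reference (optional pass)
#'
#' Shifts insertion/deletion records left while the flanking reference
#' base allows it, the standard VCF normalisation. Off by default in the
#' pipeline: silent re-normalisation can merge records that the caller
#' emitted as distinct.
#'
#' @param calls a \linkS4class{VariantCalls} object.
#' @param genome a \linkS4class{DNAStringSet}.
#' @return A \linkS4class{VariantCalls} object with indels left-aligned.
#' @export
leftAlignCalls <- function(calls, genome) {
    mc <- mcols(calls)
    chrom <- as.character(seqnames(calls))
    pos <- start(calls)
    ref <- mc$ref; alt <- mc$alt
    for (i in seq_along(calls)) {
        r <- ref[i]; a <- alt[i]; p <- pos[i]
        if (nchar(r) == nchar(a)) next
        repeat {
            # trim identical trailing base, prepend preceding reference base
            if (nchar(r) > 1L && nchar(a) > 1L &&
                substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
                r <- substr(r, 1L, nchar(r) - 1L)
                a <- substr(a, 1L, nchar(a) - 1L)
                next
            }
            last_r <- substr(r, nchar(r), nchar(r))
            last_a <- substr(a, nchar(a), nchar(a))
            if (p > 1L && last_r == last_a) {
                prev <- as.character(Biostrings::subseq(
                    genome[[chrom[i]]], p - 1L, p - 1L))
                r <- paste0(prev, substr(r, 1L, nchar(r) - 1L))
                a <- paste0(prev, substr(a, 1L, nchar(a) - 1L))
                p <- p - 1L
                next
            }
            break
        }
        ref[i] <- r; alt[i] <- a; pos[i] <- p
    }
    VariantCalls(chrom, pos, ref, alt, mc$refReads, mc$altReads, mc$sample)
}

# collapse duplicate keys within one sample, keeping the record with the
# most alt-supporting reads (deterministic; ties keep the first)
.dedupCalls <- function(calls, label = "sample") {
    keys <- variantKeys(calls)
    if (!anyDuplicated(keys))
        return(calls)
    warning("duplicate variant key(s) in ", label,
            " collapsed keeping max alt_reads: ",
            paste(unique(keys[duplicated(keys)]), collapse = ", "))
    ord <- order(match(keys, unique(keys)), -mcols(calls)$altReads)
    calls <- calls[ord]
    calls[!duplicated(variantKeys(calls))]
}

#' Classify variants between diagnosis and relapse
#'
#' Partitions the union of the two (already germline-subtracted and
#' filtered) call sets by identity key: present in both timepoints =
#' \code{common}; only in relapse = \code{additional}; only in diagnosis =
#' \code{lost}. Duplicate keys within one sample are collapsed with a
#' warning (keeping max alt reads).
#'
#' @param diagnosis,relapse \linkS4class{VariantCalls} objects.
#' @return A named list of \linkS4class{VariantCalls}:
#'   \code{common} (the relapse record is kept for common keys),
#'   \code{additional}, \code{lost}.
#' @export
classifyTimepoints <- function(diagnosis, relapse) {
    diagnosis <- .dedupCalls(diagnosis, "diagnosis")
    relapse <- .dedupCalls(relapse, "relapse")
    kd <- variantKeys(diagnosis)
    kr <- variantKeys(relapse)
    list(common = relapse[kr %in% kd],
         additional = relapse[!(kr %in% kd)],
         lost = diagnosis[!(kd %in% kr)])
}
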