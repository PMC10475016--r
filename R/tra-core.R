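.emptyTraRegions <- function() {
    gr <- GRanges()
    mcols(gr) <- DataFrame(regulators = CharacterList(),
                           maxDepth = integer(0))
    new("TRARegions", gr)
}

#' Build transcription regulatory areas (TRAs) from TFBS clusters
#'
#' A TRA is a maximal genomic interval on which at least
#' \code{minRegulators} DISTINCT transcription regulators have overlapping
#' binding-site clusters. Per chromosome, the distinct-regulator depth at
#' each base is obtained by first merging each regulator's clusters
#' (so duplicates and within-regulator overlaps never double-count) and
#' then summing coverage across regulators; TRAs are the maximal runs
#' where that depth reaches the threshold. Adjacent qualifying runs are
#' merged by construction. Each TRA carries the union of regulators whose
#' clusters overlap it and the maximum distinct depth it attains.
#'
#' @param clusters a \linkS4class{GRanges} with a \code{regulator}
#'   metadata column (see [readTfbsClusters()]).
#' @param minRegulators minimum number of distinct regulators (default 5,
#'   the "five or more transcription regulators" definition).
#' @return A \linkS4class{TRARegions} object, sorted by (chrom, start).
#' @examples
#' gr <- GRanges("chr1", IRanges(c(101, 111, 121, 101, 141),
#'                               c(200, 190, 180, 150, 200)))
#' gr$regulator <- c("A", "B", "C", "D", "E")
#' buildTraRegions(gr, minRegulators = 5)   # the [141,150] core
#' @export
buildTraRegions <- function(clusters, minRegulators = 5L) {
    stopifnot(minRegulators >= 1L)
    if (length(clusters) == 0L)
        return(.emptyTraRegions())
    gr <- granges(clusters)
    strand(gr) <- "*"
    perReg <- reduce(split(gr, mcols(clusters)$regulator))
    flat <- unlist(perReg, use.names = FALSE)
    cvg <- coverage(flat)
    out <- list()
    for (ch in names(cvg)) {
        v <- slice(cvg[[ch]], lower = minRegulators)
        if (!length(v)) next
        out[[ch]] <- GRanges(ch, as(v, "IRanges"),
                             maxDepth = as.integer(viewMaxs(v)))
    }
    if (!length(out))
        return(.emptyTraRegions())
    tras <- suppressWarnings(do.call(c, unname(out)))
    tras <- sort(sortSeqlevels(tras), ignore.strand = TRUE)
    hits <- findOverlaps(tras, clusters, ignore.strand = TRUE)
    regs <- splitAsList(mcols(clusters)$regulator[subjectHits(hits)],
                        factor(queryHits(hits), levels = seq_along(tras)))
    md <- mcols(tras)$maxDepth
    mcols(tras) <- DataFrame(regulators = unname(sort(unique(regs))),
                             maxDepth = md)
    new("TRARegions", tras)
}

#' Regulators bound at given bases
#'
#' Returns, for each query position, the distinct regulator names whose
#' cluster interval contains that base.
#'
#' @param pos a \linkS4class{GRanges} of width-1 positions (wider ranges
#'   are allowed; any overlap counts).
#' @param clusters TFBS clusters (\linkS4class{GRanges} with
#'   \code{regulator}).
#' @return A \linkS4class{CharacterList}, one sorted unique set per
#'   position.
#' @export
regulatorsAt <- function(pos, clusters) {
    hits <- findOverlaps(pos, clusters, ignore.strand = TRUE)
    unname(sort(unique(splitAsList(
        mcols(clusters)$regulator[subjectHits(hits)],
        factor(queryHits(hits), levels = seq_along(pos))))))
}

# width-1 anchor: the leftmost reference base (VCF convention for indels)
.anchorsOf <- function(x) {
    GRanges(seqnames(x), IRanges(start(x), width = 1L))
}

#' Stack timepoint classes into one call set with a status column
#'
#' @param classes the list returned by [classifyTimepoints()].
#' @param include which classes to keep (default common and additional;
#'   the lost class is not analysed downstream).
#' @return A \linkS4class{VariantCalls} with a \code{status} metadata
#'   column.
#' @export
stackTimepointClasses <- function(classes,
                                  include = c("common", "additional")) {
    parts <- lapply(include, function(st) {
        x <- classes[[st]]
        mcols(x)$status <- rep(st, length(x))
        x
    })
    out <- suppressWarnings(
        do.call(c, lapply(parts, function(p) as(p, "GRanges"))))
    new("VariantCalls", out)
}

#' Intersect classified variants with TRAs
#'
#' A variant joins a TRA iff its anchor base (the SNV base; the leftmost
#' reference base for an indel) lies inside the TRA interval. Regulator
#' involvement is attributed per variant position by default (the
#' regulators whose clusters overlap the mutated base); with
#' \code{attribution = "region"} each alteration instead inherits the full
#' regulator union of its TRA.
#'
#' @param variants a \linkS4class{VariantCalls} with a \code{status}
#'   metadata column (see [stackTimepointClasses()]).
#' @param tras a \linkS4class{TRARegions} built from \code{clusters}.
#' @param clusters the TFBS clusters the TRAs were built from.
#' @param attribution \code{"position"} (default) or \code{"region"}.
#' @return A \linkS4class{TRAAlterations} object.
#' @export
intersectVariantsTras <- function(variants, tras, clusters,
                                  attribution = c("position", "region")) {
    attribution <- match.arg(attribution)
    stopifnot(!is.null(mcols(variants)$status))
    anchors <- .anchorsOf(variants)
    hits <- findOverlaps(anchors, tras, ignore.strand = TRUE)
    qi <- queryHits(hits); ti <- subjectHits(hits)
    out <- anchors[qi]
    involved <- if (attribution == "position")
        regulatorsAt(out, clusters)
    else
        regulators(tras)[ti]
    mcols(out) <- DataFrame(ref = mcols(variants)$ref[qi],
                            alt = mcols(variants)$alt[qi],
                            status = mcols(variants)$status[qi],
                            traIndex = ti,
                            involved = involved)
    new("TRAAlterations", out)
}

#' Genes within a flanking window of TRA alterations
#'
#' A gene is collected for an alteration iff the gap between the anchor
#' base and the gene span is at most \code{window} bp (gap 0 when the
#' anchor lies inside the span); the bound is inclusive at exactly
#' \code{window}. Distance is measured to the transcript extent by
#' default, or to the TSS (strand-aware span start) with
#' \code{useTss = TRUE}.
#'
#' @param alterations a \linkS4class{TRAAlterations} object.
#' @param genes a \linkS4class{GeneModels} object or a
#'   \linkS4class{GRanges} with a \code{gene_id} column.
#' @param window window size in bp (default 20000, the 20-kb rule).
#' @param useTss measure distance to the TSS point instead of the span.
#' @return A list: \code{perAlteration}, a \linkS4class{CharacterList} of
#'   gene ids per alteration; \code{byStatus}, the sorted union gene set
#'   for each status present.
#' @export
genesWithinWindow <- function(alterations, genes, window = 20000L,
                              useTss = FALSE) {
    stopifnot(window >= 0L)
    g <- if (is(genes, "GeneModels")) geneRanges(genes) else genes
    target <- if (useTss) resize(g, width = 1L, fix = "start") else g
    hits <- findOverlaps(granges(alterations), target, maxgap = window,
                         ignore.strand = TRUE)
    ids <- as.character(mcols(g)$gene_id)
    perAlteration <- unname(sort(unique(splitAsList(
        ids[subjectHits(hits)],
        factor(queryHits(hits), levels = seq_along(alterations))))))
    statuses <- unique(mcols(alterations)$status)
    byStatus <- lapply(stats::setNames(statuses, statuses), function(st)
        sort(unique(unlist(perAlteration[mcols(alterations)$status == st]))))
    list(perAlteration = perAlteration, byStatus = byStatus)
}
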