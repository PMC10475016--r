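#' Compute fold change (and optionally p-values) from FPKM columns
#'
#' Fold change is \code{(mean condition FPKM + pseudocount) /
#' (mean control FPKM + pseudocount)}. When both groups have at least two
#' replicates, a Welch two-sample t-test on \code{log2(FPKM + pseudocount)}
#' supplies a p-value; otherwise a \code{p_value} column must already be
#' present in the input (the differential-expression engine itself is out
#' of scope here, so externally computed p-values are first-class input).
#'
#' @param records a data.frame with one row per gene (or transcript) and
#'   named FPKM sample columns.
#' @param controlSamples,conditionSamples character vectors of column
#'   names.
#' @param pseudocount added to both means before the ratio (default 0.1).
#' @return \code{records} with \code{fold_change} (and, when computed,
#'   \code{p_value}) columns.
#' @export
computeFoldChange <- function(records, controlSamples, conditionSamples,
                              pseudocount = 0.1) {
    missing <- setdiff(c(controlSamples, conditionSamples), colnames(records))
    if (length(missing))
        stop("sample column(s) missing from expression table: ",
             paste(missing, collapse = ", "))
    ctrl <- as.matrix(records[, controlSamples, drop = FALSE])
    cond <- as.matrix(records[, conditionSamples, drop = FALSE])
    records$fold_change <- (rowMeans(cond) + pseudocount) /
        (rowMeans(ctrl) + pseudocount)
    if (length(controlSamples) >= 2L && length(conditionSamples) >= 2L) {
        lc <- log2(ctrl + pseudocount)
        ld <- log2(cond + pseudocount)
        records$p_value <- vapply(seq_len(nrow(records)), function(i) {
            a <- ld[i, ]; b <- lc[i, ]
            if (!all(is.finite(a)) || !all(is.finite(b)))
                return(NA_real_)   # zero FPKM with zero pseudocount
            if (stats::sd(a) == 0 && stats::sd(b) == 0) {
                if (all(a == b)) 1 else 0
            } else {
                stats::t.test(a, b)$p.value
            }
        }, numeric(1))
    }
    records
}

#' Differential-expression gene sets at fold-change and p thresholds
#'
#' Applies the volcano thresholds |FC| >= \code{fcThreshold} (on the
#' ratio scale: FC >= threshold or FC <= 1/threshold, i.e.
#' |log2 FC| >= log2 threshold) and p < \code{pThreshold} (strict).
#' The FC bound is inclusive; the p bound is strict.
#'
#' @param records a data.frame with \code{gene_id}, \code{fold_change}
#'   and \code{p_value} columns.
#' @param fcThreshold fold-change threshold (default 2).
#' @param pThreshold p-value cutoff (default 0.01).
#' @return A list of character vectors: \code{up} and \code{down} gene
#'   ids (sorted, unique).
#' @export
deFilter <- function(records, fcThreshold = 2, pThreshold = 0.01) {
    need <- c("gene_id", "fold_change", "p_value")
    missing <- setdiff(need, colnames(records))
    if (length(missing))
        stop("expression table missing column(s): ",
             paste(missing, collapse = ", "))
    if (anyNA(records$p_value))
        stop("missing p_value for gene(s): ",
             paste(utils::head(records$gene_id[is.na(records$p_value)], 10L),
                   collapse = ", "))
    sig <- records$p_value < pThreshold
    list(up = sort(unique(records$gene_id[sig &
                       records$fold_change >= fcThreshold])),
         down = sort(unique(records$gene_id[sig &
                       records$fold_change <= 1 / fcThreshold])))
}

#' Genes with shifted transcript variants
#'
#' A gene is included iff at least one of its transcripts both passes the
#' FC/p thresholds of [deFilter()] and carries an accepted structure
#' class. Structure classes are consumed as labels from the transcript
#' assembler (gffcompare-style codes); the defaults are \code{"c"}
#' (containment of reference) and \code{"j"} (at least one junction
#' match).
#'
#' @param transcriptRecords data.frame with \code{gene_id},
#'   \code{transcript_id}, \code{fold_change}, \code{p_value} and
#'   \code{structure_class} columns.
#' @param fcThreshold,pThreshold as in [deFilter()].
#' @param acceptedClasses structure labels that qualify.
#' @return Sorted character vector of gene ids.
#' @export
transcriptShiftGenes <- function(transcriptRecords, fcThreshold = 2,
                                 pThreshold = 0.01,
                                 acceptedClasses = c("c", "j")) {
    r <- transcriptRecords
    pass <- (r$fold_change >= fcThreshold | r$fold_change <= 1 / fcThreshold) &
        r$p_value < pThreshold & r$structure_class %in% acceptedClasses
    sort(unique(r$gene_id[pass]))
}

# region label for a membership combination, e.g. "A&B" or "A_only"
.regionLabel <- function(member, setNames) {
    inset <- setNames[member]
    if (length(inset) == 1L) paste0(inset, "_only")
    else paste(inset, collapse = "&")
}

#' Exact Venn partition of 2-4 named gene sets
#'
#' Partitions the union of the sets into the disjoint membership regions
#' of a Venn diagram; region counts always sum to the union size. The
#' intersection of all sets (the headline overlap) is reported
#' explicitly.
#'
#' @param namedSets a named list of 2-4 character vectors.
#' @return A list: \code{set_names}; \code{region_counts}, a named
#'   integer vector keyed by region label (\code{"A_only"},
#'   \code{"A&B"}, ...); \code{region_members}, the gene sets per region;
#'   \code{intersection_all}, the genes in every set.
#' @export
overlapSets <- function(namedSets) {
    if (length(namedSets) < 2L || length(namedSets) > 4L)
        stop("overlapSets supports 2 to 4 sets, got ", length(namedSets))
    if (is.null(names(namedSets)) || any(!nzchar(names(namedSets))))
        stop("all sets must be named")
    sets <- lapply(namedSets, function(x) sort(unique(x)))
    nm <- names(sets)
    universe <- sort(unique(unlist(sets)))
    member <- vapply(sets, function(s) universe %in% s,
                     logical(length(universe)))
    if (length(universe) == 1L)
        member <- matrix(member, nrow = 1L, dimnames = list(NULL, nm))
    labels <- apply(member, 1L, function(row) .regionLabel(row, nm))
    regions <- split(universe, labels)
    counts <- vapply(regions, length, integer(1))
    allLabel <- paste(nm, collapse = "&")
    list(set_names = nm,
         region_counts = counts,
         region_members = regions,
         intersection_all = if (allLabel %in% names(regions))
             regions[[allLabel]] else character(0))
}

#' Write an overlap report
#'
#' One row per Venn region: label, count, comma-joined members.
#'
#' @param overlap result of [overlapSets()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeOverlapReport <- function(overlap, path) {
    df <- data.frame(region = names(overlap$region_counts),
                     count = as.integer(overlap$region_counts),
                     members = vapply(overlap$region_members, paste, "",
                                      collapse = ","))
    .writeTsv(df, path)
}
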