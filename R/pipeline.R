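#' Pipeline configuration
#'
#' Builds the single source of truth for [runPipeline()]: input paths,
#' thresholds and switches, all echoed into the run manifest. Defaults
#' are the documented analysis defaults (VAF strictly > 0.20, at least 5
#' alt-supporting reads, >= 5 distinct regulators per TRA, 20-kb
#' proximity window, |FC| >= 2 and p < 0.01).
#'
#' @param tfbs,germline,diagnosis,relapse,genome,geneModels input paths
#'   (TFBS BED; variant TSV/VCF per sample; FASTA; GFF3/GTF).
#' @param expressionGene,expressionTranscript optional expression table
#'   paths; when NULL the integration stage is skipped.
#' @param outDir output directory.
#' @param minVaf,minAltReads,depthRule variant filter settings
#'   (see [filterCalls()]).
#' @param leftAlign left-align indels against the genome before keying
#'   (off by default; see [leftAlignCalls()]).
#' @param minRegulators TRA threshold (see [buildTraRegions()]).
#' @param window proximity window in bp (see [genesWithinWindow()]).
#' @param attribution involvement attribution mode
#'   (see [intersectVariantsTras()]).
#' @param fcThreshold,pThreshold expression thresholds (see [deFilter()]).
#' @param acceptedClasses transcript structure classes that count as a
#'   shift (see [transcriptShiftGenes()]).
#' @return A named list of class \code{tra_pipeline_config}.
#' @export
pipelineConfig <- function(tfbs, germline, diagnosis, relapse, genome,
                           geneModels, expressionGene = NULL,
                           expressionTranscript = NULL,
                           outDir = tempfile("tra_run_"),
                           minVaf = 0.20, minAltReads = 5L,
                           depthRule = "alt", leftAlign = FALSE,
                           minRegulators = 5L, window = 20000L,
                           attribution = "position",
                           fcThreshold = 2, pThreshold = 0.01,
                           acceptedClasses = c("c", "j")) {
    cfg <- list(tfbs = tfbs, germline = germline, diagnosis = diagnosis,
                relapse = relapse, genome = genome, geneModels = geneModels,
                expressionGene = expressionGene,
                expressionTranscript = expressionTranscript,
                outDir = outDir, minVaf = minVaf,
                minAltReads = as.integer(minAltReads),
                depthRule = depthRule, leftAlign = leftAlign,
                minRegulators = as.integer(minRegulators),
                window = as.integer(window), attribution = attribution,
                fcThreshold = fcThreshold, pThreshold = pThreshold,
                acceptedClasses = acceptedClasses)
    inputs <- c("tfbs", "germline", "diagnosis", "relapse", "genome",
                "geneModels")
    for (p in inputs)
        if (!file.exists(cfg[[p]]))
            stop("input path for '", p, "' does not exist: ", cfg[[p]])
    stopifnot(cfg$minVaf >= 0, cfg$minVaf < 1, cfg$minAltReads >= 0,
              cfg$minRegulators >= 1, cfg$window >= 0)
    class(cfg) <- "tra_pipeline_config"
    cfg
}

.stageMsg <- function(stage, ...) {
    message("[", stage, "] ", ...)
}

#' Run the end-to-end TRA alteration pipeline
#'
#' Fixed stage order: filter -> germline subtraction -> timepoint
#' classification -> consequence annotation -> TRA construction ->
#' TRA intersection -> proximal gene collection -> involvement table ->
#' expression integration (when expression inputs are configured).
#' Writes, under \code{config$outDir}: \code{classified_variants.tsv},
#' \code{tra_regions.bed}, \code{tra_alterations.tsv},
#' \code{proximal_genes_common.txt} / \code{_additional.txt},
#' \code{involvement.tsv}, \code{overlap_report.tsv} (integration only)
#' and \code{manifest.json}. There is no randomness anywhere in the
#' analysis path, so reruns on identical inputs are byte-identical.
#'
#' @param config a configuration from [pipelineConfig()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   \code{manifest}.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "tra_pipeline_config"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)

    .stageMsg("read", "loading inputs")
    clusters <- readTfbsClusters(config$tfbs)
    genome <- readGenome(config$genome)
    models <- readGeneModels(config$geneModels)
    germ <- readVariants(config$germline, "germline")
    diag <- readVariants(config$diagnosis, "diagnosis")
    rel <- readVariants(config$relapse, "relapse")
    nRead <- c(germline = length(germ), diagnosis = length(diag),
               relapse = length(rel))

    if (config$leftAlign) {
        .stageMsg("left-align", "normalising indels")
        germ <- leftAlignCalls(germ, genome)
        diag <- leftAlignCalls(diag, genome)
        rel <- leftAlignCalls(rel, genome)
    }

    .stageMsg("filter", "VAF > ", config$minVaf, ", reads >= ",
              config$minAltReads, " (", config$depthRule, ")")
    germF <- filterCalls(germ, config$minVaf, config$minAltReads,
                         config$depthRule)
    diagF <- filterCalls(diag, config$minVaf, config$minAltReads,
                         config$depthRule)
    relF <- filterCalls(rel, config$minVaf, config$minAltReads,
                        config$depthRule)
    nFiltered <- c(germline = length(germF), diagnosis = length(diagF),
                   relapse = length(relF))

    .stageMsg("subtract", "removing germline keys")
    diagS <- subtractGermline(diagF, germF)
    relS <- subtractGermline(relF, germF)

    .stageMsg("classify", "common/additional/lost")
    classes <- classifyTimepoints(diagS, relS)
    nClass <- vapply(classes, length, 0L)

    .stageMsg("consequence", "annotating coding consequence")
    stacked <- stackTimepointClasses(classes,
                                     include = c("common", "additional",
                                                 "lost"))
    stacked <- annotateConsequence(stacked, models, genome)
    classTab <- data.frame(
        chrom = as.character(seqnames(stacked)), pos = start(stacked),
        ref = mcols(stacked)$ref, alt = mcols(stacked)$alt,
        vaf = round(vaf(stacked), 4),
        alt_reads = mcols(stacked)$altReads,
        status = mcols(stacked)$status,
        variant_class = mcols(stacked)$variantClass,
        consequence = mcols(stacked)$consequence,
        gene_id = mcols(stacked)$geneId,
        hgvs_like = mcols(stacked)$hgvsLike)
    classTab <- classTab[order(classTab$chrom, classTab$pos, classTab$ref,
                               classTab$alt), ]
    .writeTsv(classTab, file.path(config$outDir, "classified_variants.tsv"))

    .stageMsg("build-tra", "min distinct regulators = ", config$minRegulators)
    tras <- buildTraRegions(clusters, config$minRegulators)
    writeTraRegions(tras, file.path(config$outDir, "tra_regions.bed"))

    .stageMsg("scan", "intersecting variants with TRAs")
    ca <- stackTimepointClasses(classes)   # common + additional only
    ca <- annotateConsequence(ca, models, genome)
    alts <- intersectVariantsTras(ca, tras, clusters, config$attribution)
    nAlts <- c(common = sum(mcols(alts)$status == "common"),
               additional = sum(mcols(alts)$status == "additional"))
    altTab <- data.frame(
        chrom = as.character(seqnames(alts)), pos = start(alts),
        ref = mcols(alts)$ref, alt = mcols(alts)$alt,
        status = mcols(alts)$status, tra_index = mcols(alts)$traIndex,
        involved = vapply(mcols(alts)$involved, paste, "", collapse = ";"))
    altTab <- altTab[order(altTab$chrom, altTab$pos, altTab$ref,
                           altTab$alt), ]
    .writeTsv(altTab, file.path(config$outDir, "tra_alterations.tsv"))

    .stageMsg("proximity", "genes within ", config$window, " bp")
    prox <- genesWithinWindow(alts, models, config$window)
    for (st in c("common", "additional")) {
        genes <- if (!is.null(prox$byStatus[[st]])) prox$byStatus[[st]]
                 else character(0)
        writeLines(genes, file.path(config$outDir,
                                    paste0("proximal_genes_", st, ".txt")))
    }
    nProx <- vapply(c(common = "common", additional = "additional"),
                    function(st) length(prox$byStatus[[st]]), 0L)

    .stageMsg("involvement", "per-regulator rates and ratio")
    invTab <- involvementTable(alts[mcols(alts)$status == "common"],
                               alts[mcols(alts)$status == "additional"])
    writeInvolvementTable(invTab, file.path(config$outDir,
                                            "involvement.tsv"))

    deSets <- NULL; shiftGenes <- NULL; overlap <- NULL
    if (!is.null(config$expressionGene)) {
        .stageMsg("integrate", "expression-derived gene sets")
        ge <- utils::read.delim(config$expressionGene)
        deSets <- deFilter(ge, config$fcThreshold, config$pThreshold)
        if (!is.null(config$expressionTranscript)) {
            tx <- utils::read.delim(config$expressionTranscript,
                                    colClasses = list(structure_class =
                                                      "character"))
            shiftGenes <- transcriptShiftGenes(tx, config$fcThreshold,
                                               config$pThreshold,
                                               config$acceptedClasses)
        }
        sets <- list(
            proximal_additional = prox$byStatus[["additional"]],
            de = union(deSets$up, deSets$down))
        if (!is.null(shiftGenes))
            sets$transcript_shift <- shiftGenes
        sets <- lapply(sets, function(s) if (is.null(s)) character(0) else s)
        overlap <- overlapSets(sets)
        writeOverlapReport(overlap, file.path(config$outDir,
                                              "overlap_report.tsv"))
    }

    manifest <- list(
        tool = "TRAscan",
        version = as.character(utils::packageVersion("TRAscan")),
        config = config[setdiff(names(config), "acceptedClasses")],
        accepted_classes = config$acceptedClasses,
        counts = list(
            variants_read = as.list(nRead),
            variants_filtered = as.list(nFiltered),
            classified = as.list(nClass),
            tras_built = length(tras),
            tra_coverage_bp = sum(width(tras)),
            tra_alterations = as.list(nAlts),
            proximal_genes = as.list(nProx),
            de = if (!is.null(deSets))
                list(up = length(deSets$up), down = length(deSets$down))
                else NULL,
            transcript_shift_genes = if (!is.null(shiftGenes))
                length(shiftGenes) else NULL,
            overlap_regions = if (!is.null(overlap))
                as.list(overlap$region_counts) else NULL))
    # internal consistency: filtered <= read; the classes partition the
    # post-subtraction key union
    stopifnot(all(nFiltered <= nRead),
              sum(nClass) == length(unique(c(variantKeys(diagS),
                                             variantKeys(relS)))))
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(list(classes = classes, tras = tras, alterations = alts,
                   proximal = prox, involvement = invTab, de = deSets,
                   shiftGenes = shiftGenes, overlap = overlap,
                   manifest = manifest))
}
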