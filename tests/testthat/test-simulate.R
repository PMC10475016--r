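smallCounts <- list(nGermline = 5L, nCommon = 12L, nAdditional = 15L,
                    nLost = 4L, nCommonInTra = 8L, nAdditionalInTra = 10L)

smallPlanted <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                           start = c(5000L, 20000L, 8000L),
                           end = c(6999L, 21999L, 9999L),
                           k = c(5L, 6L, 4L))

test_that("generators are pure functions of their seed", {
    r1 <- simulateReference(nChrom = 1L, chromLength = 50000L, nGenes = 4L,
                            seed = 5L)
    r2 <- simulateReference(nChrom = 1L, chromLength = 50000L, nGenes = 4L,
                            seed = 5L)
    expect_identical(as.character(r1$genome), as.character(r2$genome))
    expect_identical(translateModels(r1$models, r1$genome),
                     translateModels(r2$models, r2$genome))
    r3 <- simulateReference(nChrom = 1L, chromLength = 50000L, nGenes = 4L,
                            seed = 6L)
    expect_false(identical(as.character(r1$genome), as.character(r3$genome)))
})

test_that("every simulated CDS is codable and translates cleanly", {
    ref <- simulateReference(nChrom = 2L, chromLength = 80000L, nGenes = 10L,
                             cdsExonsPerGene = 3L, seed = 21L)
    prot <- translateModels(ref$models, ref$genome)
    expect_length(prot, 10L)
    expect_true(all(grepl("^M", prot)))
    expect_true(all(grepl("[*]$", prot)))
    expect_false(any(grepl("[*].", prot)))     # no internal stops
    expect_setequal(unique(as.character(strand(geneRanges(ref$models)))),
                    c("+", "-"))
    # zero genes: genome only
    bare <- simulateReference(nChrom = 1L, chromLength = 10000L, nGenes = 0L,
                              seed = 1L)
    expect_length(bare$models, 0L)
})

test_that("planted TRAs are recovered exactly; sub-threshold ones are not", {
    chromLens <- c(chr1 = 40000L, chr2 = 20000L)
    tf <- simulateTfbs(chromLens, smallPlanted, nBackground = 60L, seed = 2L)
    built <- buildTraRegions(tf$clusters, 5L)
    expectGr <- GRanges(c("chr1", "chr1"), IRanges(c(5000L, 20000L),
                                                   c(6999L, 21999L)))
    expect_identical(as.character(granges(built)), as.character(expectGr))
    # the k=4 region never qualifies at threshold 5
    expect_false(any(suppressWarnings(
        overlapsAny(GRanges("chr2", IRanges(8000, 9999)), built))))
    # zero planted, sparse background: empty TRA set
    none <- simulateTfbs(chromLens, smallPlanted[0, ], nBackground = 30L,
                         seed = 3L)
    expect_length(buildTraRegions(none$clusters, 5L), 0L)
})

test_that("variant simulator plants exact class and in-TRA counts", {
    ref <- simulateReference(nChrom = 2L, chromLength = 40000L, nGenes = 6L,
                             seed = 4L)
    chromLens <- setNames(Biostrings::width(ref$genome), names(ref$genome))
    tf <- simulateTfbs(chromLens, smallPlanted, nBackground = 40L, seed = 5L)
    qualifying <- tf$plantedTras[mcols(tf$plantedTras)$k >= 5L]
    vs <- simulateVariantSets(ref$genome, qualifying, tf$clusters,
                              counts = smallCounts, seed = 6L)
    run <- function(calls) filterCalls(calls)
    dS <- subtractGermline(run(vs$diagnosis), run(vs$germline))
    rS <- subtractGermline(run(vs$relapse), run(vs$germline))
    cl <- classifyTimepoints(dS, rS)
    expect_length(cl$common, smallCounts$nCommon)
    expect_length(cl$additional, smallCounts$nAdditional)
    expect_length(cl$lost, smallCounts$nLost)
    tras <- buildTraRegions(vs$clusters, 5L)
    alts <- intersectVariantsTras(stackTimepointClasses(cl), tras,
                                  vs$clusters)
    expect_equal(sum(mcols(alts)$status == "common"),
                 smallCounts$nCommonInTra)
    expect_equal(sum(mcols(alts)$status == "additional"),
                 smallCounts$nAdditionalInTra)
})

test_that("sub-threshold decoys all fail the filter, at both boundaries", {
    ref <- simulateReference(nChrom = 1L, chromLength = 40000L, nGenes = 0L,
                             seed = 8L)
    planted <- data.frame(chrom = "chr1", start = 5000L, end = 6999L, k = 5L)
    tf <- simulateTfbs(c(chr1 = 40000L), planted, nBackground = 20L,
                       seed = 9L)
    vs <- simulateVariantSets(ref$genome, tf$plantedTras, tf$clusters,
                              counts = list(nGermline = 0L, nCommon = 6L,
                                            nAdditional = 6L, nLost = 0L,
                                            nCommonInTra = 4L,
                                            nAdditionalInTra = 4L),
                              subthresholdFraction = 1.0, seed = 10L)
    expect_equal(vs$truth$nDecoys, 12L)
    # decoys appear in the raw tables but never after filtering
    expect_gt(length(vs$relapse), 12L)
    relF <- filterCalls(vs$relapse)
    diaF <- filterCalls(vs$diagnosis)
    log <- attr(relF, "filterLog")
    expect_gt(log[["low_vaf"]] + log[["low_reads"]], 0L)
    cl <- classifyTimepoints(diaF, relF)
    expect_length(cl$common, 6L)
    expect_length(cl$additional, 6L)
})

test_that("planted Bernoulli involvement is realised exactly in geometry", {
    ref <- simulateReference(nChrom = 1L, chromLength = 60000L, nGenes = 0L,
                             seed = 11L)
    planted <- data.frame(chrom = "chr1", start = c(5000L, 30000L),
                          end = c(8999L, 33999L), k = c(5L, 6L))
    tf <- simulateTfbs(c(chr1 = 60000L), planted,
                       excludeRegulators = "MYC", nBackground = 30L,
                       seed = 12L)
    vs <- simulateVariantSets(ref$genome, tf$plantedTras, tf$clusters,
                              counts = list(nGermline = 0L, nCommon = 40L,
                                            nAdditional = 40L, nLost = 0L,
                                            nCommonInTra = 40L,
                                            nAdditionalInTra = 40L),
                              regulatorProbs = list(MYC = c(0.3, 0.6)),
                              seed = 13L)
    cl <- classifyTimepoints(filterCalls(vs$diagnosis),
                             filterCalls(vs$relapse))
    tras <- buildTraRegions(vs$clusters, 5L)
    alts <- intersectVariantsTras(stackTimepointClasses(cl), tras,
                                  vs$clusters)
    tab <- involvementTable(alts[mcols(alts)$status == "common"],
                            alts[mcols(alts)$status == "additional"])
    myc <- tab[tab$regulator == "MYC", ]
    expect_equal(myc$n_common_involved,
                 vs$truth$realizedInvolvement$MYC$nCommonInvolved)
    expect_equal(myc$n_additional_involved,
                 vs$truth$realizedInvolvement$MYC$nAdditionalInvolved)
})

test_that("expression tables are reproducible and carry planted truth", {
    s1 <- simulateExpression(nGenes = 200L, nUp = 10L, nDown = 15L,
                             nShiftGenes = 12L, seed = 14L)
    s2 <- simulateExpression(nGenes = 200L, nUp = 10L, nDown = 15L,
                             nShiftGenes = 12L, seed = 14L)
    expect_identical(s1$geneTable, s2$geneTable)
    expect_identical(s1$transcriptTable, s2$transcriptTable)
    # flat effect with null p: empty DE sets at default thresholds
    flat <- simulateExpression(nGenes = 100L, nUp = 0L, nDown = 0L,
                               nShiftGenes = 0L, seed = 15L)
    sets <- deFilter(flat$geneTable)
    expect_length(sets$up, 0L)
    expect_length(sets$down, 0L)
})

test_that("requesting more in-TRA variants than TRA bases is fatal", {
    ref <- simulateReference(nChrom = 1L, chromLength = 20000L, nGenes = 0L,
                             seed = 16L)
    planted <- data.frame(chrom = "chr1", start = 5000L, end = 5019L, k = 5L)
    tf <- simulateTfbs(c(chr1 = 20000L), planted, nBackground = 0L,
                       seed = 17L)
    expect_error(
        simulateVariantSets(ref$genome, tf$plantedTras, tf$clusters,
                            counts = list(nGermline = 0L, nCommon = 30L,
                                          nAdditional = 0L, nLost = 0L,
                                          nCommonInTra = 30L,
                                          nAdditionalInTra = 0L),
                            seed = 18L),
        "TRA capacity")
})
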