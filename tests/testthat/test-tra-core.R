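mkClusters <- function(chrom, start, end, regulator) {
    gr <- GRanges(chrom, IRanges(start, end))
    mcols(gr)$regulator <- regulator
    gr
}

test_that("TRA construction finds the depth-5 core of stacked clusters", {
    # 1-based versions of A[100,200) B[110,190) C[120,180) D[100,150)
    # E[140,200): all five overlap only on [140,150)
    cl <- mkClusters("chr1", c(101, 111, 121, 101, 141),
                     c(200, 190, 180, 150, 200), c("A", "B", "C", "D", "E"))
    tras <- buildTraRegions(cl, 5)
    expect_length(tras, 1L)
    expect_equal(start(tras), 141L)
    expect_equal(end(tras), 150L)
    expect_equal(as.character(regulators(tras)[[1]]), c("A", "B", "C", "D", "E"))
    expect_equal(maxDepth(tras), 5L)
    expect_length(buildTraRegions(mkClusters(character(0), integer(0),
                                             integer(0), character(0)), 5),
                  0L)
})

test_that("duplicate clusters of one regulator never double-count", {
    cl <- mkClusters("chr1", rep(1, 5), rep(10, 5),
                     c("A", "A", "B", "C", "D"))   # 4 distinct regulators
    expect_length(buildTraRegions(cl, 5), 0L)
    expect_length(buildTraRegions(cl, 4), 1L)
})

test_that("regulatorsAt returns exactly the covering regulator sets", {
    cl <- mkClusters("chr1", c(101, 111, 121, 101, 141),
                     c(200, 190, 180, 150, 200), c("A", "B", "C", "D", "E"))
    at <- regulatorsAt(GRanges("chr1", IRanges(c(146, 126, 50), width = 1)),
                       cl)
    expect_equal(as.character(at[[1]]), c("A", "B", "C", "D", "E"))
    expect_equal(as.character(at[[2]]), c("A", "B", "C", "D"))
    expect_length(at[[3]], 0L)
})

test_that("sweep equals the per-base oracle on random instances", {
    for (seed in 1:20) {
        cl <- randomClusterInstance(seed)
        k <- sample(2:6, 1)
        got <- granges(buildTraRegions(cl, k))
        mcols(got) <- NULL
        expect_identical(as.character(got),
                         as.character(bruteTraOracle(cl, k)),
                         info = paste("seed", seed, "k", k))
    }
})

test_that("TRAs are disjoint, sorted, and merging is idempotent", {
    for (seed in c(3, 14)) {
        cl <- randomClusterInstance(seed)
        tras <- buildTraRegions(cl, 3)
        expect_false(is.unsorted(order(as.character(seqnames(tras)),
                                       start(tras))))
        expect_true(all(lengths(findOverlaps(tras, tras)) == 1L))
        # reinterpret each TRA as a single-factor cluster: rebuilding at
        # threshold 1 must not split intervals
        single <- granges(tras)
        mcols(single)$regulator <- "X"
        rebuilt <- buildTraRegions(single, 1)
        expect_identical(as.character(granges(rebuilt)),
                         as.character(reduce(granges(tras))))
    }
})

test_that("raising the threshold never enlarges TRA coverage", {
    cl <- randomClusterInstance(8)
    cov <- vapply(c(1, 3, 5, 8), function(k)
        sum(width(buildTraRegions(cl, k))), numeric(1))
    expect_true(all(diff(cov) <= 0))
    # and coverage is nested, not merely smaller
    t5 <- buildTraRegions(cl, 5); t3 <- buildTraRegions(cl, 3)
    if (length(t5))
        expect_equal(sum(width(intersect(granges(t5), granges(t3)))),
                     sum(width(t5)))
})

test_that("variants join TRAs by anchor base; involvement is per position", {
    cl <- mkClusters("chr1", c(101, 111, 121, 101, 141),
                     c(200, 190, 180, 150, 200), c("A", "B", "C", "D", "E"))
    tras <- buildTraRegions(cl, 5)
    v <- VariantCalls("chr1", c(146, 139, 149), c("A", "A", "AGT"),
                      c("T", "T", "A"), refReads = 10L, altReads = 10L)
    mcols(v)$status <- c("common", "additional", "additional")
    alts <- intersectVariantsTras(v, tras, cl)
    # base 146 in the TRA; base 139 (depth 4) outside; the deletion's
    # anchor 149 inside even though its span leaves the TRA
    expect_equal(start(alts), c(146L, 149L))
    expect_equal(as.character(involvedRegulators(alts)[[1]]),
                 c("A", "B", "C", "D", "E"))
    expect_equal(mcols(alts)$status, c("common", "additional"))
    expect_true(all(overlapsAny(alts, tras)))
    # region attribution inherits the TRA's regulator union
    reg <- intersectVariantsTras(v, tras, cl, attribution = "region")
    expect_equal(as.character(involvedRegulators(reg)[[2]]),
                 as.character(regulators(tras)[[1]]))
})

test_that("the 20-kb window is inclusive at exactly 20,000 bp", {
    genes <- GRanges("chr1", IRanges(c(30002, 30003), width = 500))
    mcols(genes)$gene_id <- c("near", "far")
    alt <- plantedAlterations(1, list(character(0)), "additional")
    # anchor at base 10001: gap to gene starting 30002 is 20,000 (in);
    # to 30003 it is 20,001 (out)
    alt <- GenomicRanges::shift(alt, 10001L - start(alt))
    res <- genesWithinWindow(alt, genes, window = 20000L)
    expect_equal(as.character(res$perAlteration[[1]]), "near")
    expect_equal(res$byStatus$additional, "near")
})

test_that("window inclusion matches the quadratic oracle on random instances", {
    for (seed in 1:15) {
        set.seed(seed)
        nA <- sample(3:20, 1); nG <- sample(3:30, 1)
        anchors <- GRanges(sample(c("chr1", "chr2"), nA, TRUE),
                           IRanges(sample(2e5, nA), width = 1))
        genes <- GRanges(sample(c("chr1", "chr2"), nG, TRUE),
                         IRanges(sample(2e5, nG),
                                 width = sample(100:5000, nG, TRUE)))
        mcols(genes)$gene_id <- sprintf("g%02d", seq_len(nG))
        alt <- plantedAlterations(nA, rep(list(character(0)), nA), "common")
        alt <- GRanges(seqnames(anchors), ranges(anchors),
                       ref = mcols(alt)$ref, alt = mcols(alt)$alt,
                       status = mcols(alt)$status,
                       traIndex = mcols(alt)$traIndex,
                       involved = mcols(alt)$involved)
        alt <- new("TRAAlterations", alt)
        w <- sample(c(0L, 500L, 20000L), 1)
        res <- genesWithinWindow(alt, genes, window = w)
        oracle <- bruteProximityOracle(anchors, genes, w)
        for (i in seq_len(nA))
            expect_equal(as.character(res$perAlteration[[i]]),
                         sort(mcols(genes)$gene_id[oracle[i, ]]),
                         info = paste("seed", seed, "anchor", i))
    }
})

test_that("anchors inside a gene span count at distance zero", {
    genes <- GRanges("chr1", IRanges(100, 500))
    mcols(genes)$gene_id <- "g"
    alt <- plantedAlterations(1, list(character(0)), "common")
    alt <- GenomicRanges::shift(alt, 250L - start(alt))
    expect_equal(genesWithinWindow(alt, genes, 0L)$byStatus$common, "g")
    # empty gene set gives empty mapping values
    empty <- GRanges()
    mcols(empty)$gene_id <- character(0)
    expect_length(genesWithinWindow(alt, empty, 20000L)$perAlteration[[1]],
                  0L)
})
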