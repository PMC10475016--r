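# builds a single-exon model from an explicit CDS string at genomic
# positions 101..(100+nchar), on either strand
explicitToy <- function(cdsSeq, std) {
    L <- max(400L, 200L + nchar(cdsSeq))
    set.seed(99)
    s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    towrite <- if (std == "-")
        as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(cdsSeq)))
    else cdsSeq
    substr(s, 101, 100 + nchar(cdsSeq)) <- towrite
    genome <- Biostrings::DNAStringSet(s)
    names(genome) <- "chrT"
    genes <- GRanges("chrT", IRanges(101, 100 + nchar(cdsSeq)), strand = std)
    mcols(genes) <- S4Vectors::DataFrame(gene_id = "toy", gene_name = "TOY",
                                         tx_id = "toy.t1", codable = TRUE)
    models <- new("GeneModels", genes = genes,
                  cds = GRangesList(toy = granges(genes)))
    list(genome = genome, models = models)
}

test_that("a GAG>TAG change is nonsense with a p.E..* label on both strands", {
    cds <- "ATGGAGTAA"
    plus <- explicitToy(cds, "+")
    v <- VariantCalls("chrT", 104, "G", "T", 20L, 10L)
    ann <- annotateConsequence(v, plus$models, plus$genome)
    expect_equal(mcols(ann)$consequence, "nonsense")
    expect_equal(mcols(ann)$hgvsLike, "c.4G>T (p.E2*)")
    # same transcript change on the minus strand: genomic C>A at the
    # mirrored position gives the identical consequence and label
    minus <- explicitToy(cds, "-")
    v2 <- VariantCalls("chrT", 106, "C", "A", 20L, 10L)
    ann2 <- annotateConsequence(v2, minus$models, minus$genome)
    expect_equal(mcols(ann2)$consequence, "nonsense")
    expect_equal(mcols(ann2)$hgvsLike, "c.4G>T (p.E2*)")
})

test_that("third-position wobble is synonymous; start and stop losses called", {
    toy <- explicitToy("ATGGCTTAA", "+")
    wob <- annotateConsequence(VariantCalls("chrT", 106, "T", "C", 9L, 9L),
                               toy$models, toy$genome)
    expect_equal(mcols(wob)$consequence, "synonymous")   # GCT -> GCC
    startl <- annotateConsequence(VariantCalls("chrT", 101, "A", "G", 9L, 9L),
                                  toy$models, toy$genome)
    expect_equal(mcols(startl)$consequence, "start_lost")
    stopl <- annotateConsequence(VariantCalls("chrT", 107, "T", "C", 9L, 9L),
                                 toy$models, toy$genome)
    expect_equal(mcols(stopl)$consequence, "stop_lost")  # TAA -> CAA
})

test_that("a single-base CDS deletion is frameshift with a c.504delG-style label", {
    sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
    set.seed(7)
    codons <- c("ATG", sample(setdiff(sense, "CTG"), 168, replace = TRUE))
    codons[168] <- "CTG"                         # Leu at aa 168, G at c.504
    cds <- paste0(paste(codons, collapse = ""), "TAA")
    toy <- explicitToy(cds, "+")
    # VCF-style deletion of the G at coding position 504 (genomic 604)
    v <- VariantCalls("chrT", 603, "TG", "T", 20L, 10L)
    ann <- annotateConsequence(v, toy$models, toy$genome)
    expect_equal(mcols(ann)$variantClass, "indel")
    expect_equal(mcols(ann)$consequence, "frameshift")
    expect_equal(mcols(ann)$hgvsLike, "c.504delG (p.L168fs)")
})

test_that("in-frame and boundary-spanning indels follow the mod-3 rule", {
    toy <- explicitToy("ATGGCTGCTGCTTAA", "+")
    base <- function(p) as.character(Biostrings::subseq(toy$genome[[1]], p, p))
    del3 <- VariantCalls("chrT", 103,
                         as.character(Biostrings::subseq(toy$genome[[1]],
                                                         103, 106)),
                         base(103), 20L, 10L)
    ann <- annotateConsequence(del3, toy$models, toy$genome)
    expect_equal(mcols(ann)$consequence, "inframe_indel")
    # deletion anchored before the CDS but overlapping it is classed by
    # its CDS-overlapping portion
    spanning <- VariantCalls("chrT", 99,
                             as.character(Biostrings::subseq(toy$genome[[1]],
                                                             99, 102)),
                             base(99), 20L, 10L)
    ann2 <- annotateConsequence(spanning, toy$models, toy$genome)
    expect_equal(mcols(ann2)$consequence, "frameshift")
    expect_equal(mcols(ann2)$geneId, "toy")
})

test_that("variants outside any CDS are non_CDS and carry no gene", {
    toy <- explicitToy("ATGGCTTAA", "+")
    b <- as.character(Biostrings::subseq(toy$genome[[1]], 50, 50))
    v <- VariantCalls("chrT", 50, b, setdiff(c("A", "C", "G", "T"), b)[1],
                      9L, 9L)
    ann <- annotateConsequence(v, toy$models, toy$genome)
    expect_equal(mcols(ann)$consequence, "non_CDS")
    expect_true(is.na(mcols(ann)$geneId))
})

test_that("a reference allele disagreeing with the genome is fatal", {
    toy <- explicitToy("ATGGCTTAA", "+")
    b <- as.character(Biostrings::subseq(toy$genome[[1]], 104, 104))
    wrong <- setdiff(c("A", "C", "G", "T"), b)[1]
    v <- VariantCalls("chrT", 104, wrong, setdiff(c("A", "C", "G", "T"),
                                                  c(b, wrong))[1], 9L, 9L)
    expect_error(annotateConsequence(v, toy$models, toy$genome),
                 "reference mismatch at chrT:104")
})

test_that("codon-local classification agrees with the full-protein oracle", {
    set.seed(123)
    checked <- 0L
    for (seed in 1:12) {
        toy <- randomToyGene(seed)
        for (k in 1:10) {
            pos <- sample(seq(80L, max(toy$segEnd) + 40L), 1L)
            refb <- as.character(Biostrings::subseq(toy$genome[[1]],
                                                    pos, pos))
            altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
            got <- mcols(annotateConsequence(
                VariantCalls("chrT", pos, refb, altb, 20L, 10L),
                toy$models, toy$genome))$consequence
            expect_equal(got, bruteConsequenceOracle(toy, pos, altb),
                         info = sprintf("seed %d pos %d %s>%s strand %s",
                                        seed, pos, refb, altb, toy$strand))
            checked <- checked + 1L
        }
    }
    expect_gte(checked, 100L)
})
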