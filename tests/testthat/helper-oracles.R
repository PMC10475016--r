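# Independent brute-force oracles and toy-instance builders. These stay
# deliberately naive (per-base loops, full-protein translation diffs,
# quadratic distance scans) so they check the optimized implementations
# from a different direction.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
})

# per-base distinct-regulator count -> maximal runs >= minReg, per chrom
bruteTraOracle <- function(clusters, minReg) {
    out <- list()
    for (ch in sort(unique(as.character(seqnames(clusters))))) {
        cl <- clusters[seqnames(clusters) == ch]
        L <- max(end(cl))
        count <- integer(L)
        for (reg in unique(mcols(cl)$regulator)) {
            covered <- logical(L)
            r <- cl[mcols(cl)$regulator == reg]
            for (i in seq_along(r))
                covered[start(r)[i]:end(r)[i]] <- TRUE
            count <- count + covered
        }
        runs <- rle(count >= minReg)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1L
        keep <- runs$values
        if (any(keep))
            out[[ch]] <- GRanges(ch, IRanges(starts[keep], ends[keep]))
    }
    if (!length(out)) return(GRanges())
    sort(sortSeqlevels(suppressWarnings(do.call(c, unname(out)))),
         ignore.strand = TRUE)
}

# random TRA-builder instance: genome <= 100 kb, <= 20 regulators,
# <= 300 clusters
randomClusterInstance <- function(seed) {
    set.seed(seed)
    nChrom <- sample(1:2, 1)
    genomeLen <- sample(2e4:1e5, 1)
    nReg <- sample(3:20, 1)
    nClust <- sample(20:300, 1)
    chrom <- paste0("chr", sample(nChrom, nClust, replace = TRUE))
    w <- sample(50:2000, nClust, replace = TRUE)
    start <- vapply(w, function(wi) sample(genomeLen - wi, 1), 1L)
    gr <- GRanges(chrom, IRanges(start, width = w))
    mcols(gr)$regulator <- paste0("R", sample(nReg, nClust, replace = TRUE))
    gr
}

# quadratic anchor-to-gene-span gap scan
bruteProximityOracle <- function(anchors, genes, window) {
    hits <- matrix(FALSE, length(anchors), length(genes))
    for (i in seq_along(anchors)) {
        for (j in seq_along(genes)) {
            if (as.character(seqnames(anchors)[i]) !=
                as.character(seqnames(genes)[j])) next
            p <- start(anchors)[i]
            gap <- if (p < start(genes)[j]) start(genes)[j] - p - 1L
                   else if (p > end(genes)[j]) p - end(genes)[j] - 1L
                   else 0L
            hits[i, j] <- gap <= window
        }
    }
    hits
}

# toy gene model: random genome, one multi-exon gene, either strand
randomToyGene <- function(seed, nExons = sample(1:3, 1)) {
    set.seed(seed)
    L <- 5000L
    genome <- Biostrings::DNAStringSet(paste(sample(c("A", "C", "G", "T"), L,
                                        replace = TRUE), collapse = ""))
    names(genome) <- "chrT"
    nCodons <- sample(20:80, 1)
    sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
    cdsSeq <- paste0("ATG", paste(sample(sense, nCodons - 2, replace = TRUE),
                                  collapse = ""),
                     sample(c("TAA", "TAG", "TGA"), 1))
    std <- sample(c("+", "-"), 1)
    Lc <- nchar(cdsSeq)
    if (nExons > 1) {
        cuts <- sort(sample(Lc - 1, nExons - 1))
        exLens <- diff(c(0L, cuts, Lc))
    } else exLens <- Lc
    towrite <- if (std == "-")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(cdsSeq))) else cdsSeq
    gstart <- 100L
    segStart <- integer(nExons); segEnd <- integer(nExons)
    s <- as.character(genome[[1]])
    p <- gstart; off <- 0L
    for (e in seq_len(nExons)) {
        segStart[e] <- p; segEnd[e] <- p + exLens[e] - 1L
        substr(s, segStart[e], segEnd[e]) <-
            substr(towrite, off + 1L, off + exLens[e])
        off <- off + exLens[e]
        p <- segEnd[e] + 1L + sample(50:200, 1)
    }
    genome <- Biostrings::DNAStringSet(s); names(genome) <- "chrT"
    genes <- GRanges("chrT", IRanges(gstart, segEnd[nExons]), strand = std)
    mcols(genes) <- S4Vectors::DataFrame(gene_id = "toy", gene_name = "TOY",
                                         tx_id = "toy.t1", codable = TRUE)
    models <- new("GeneModels", genes = genes,
                  cds = GRangesList(toy = GRanges("chrT",
                      IRanges(segStart, segEnd), strand = std)))
    list(genome = genome, models = models, cdsSeq = cdsSeq, strand = std,
         segStart = segStart, segEnd = segEnd)
}

# full-protein translation-diff consequence oracle for an SNV
bruteConsequenceOracle <- function(toy, pos, alt) {
    s <- as.character(toy$genome[[1]])
    stopifnot(substr(s, pos, pos) != alt)
    mut <- s
    substr(mut, pos, pos) <- alt
    splice <- function(seqchar) {
        parts <- vapply(seq_along(toy$segStart), function(e)
            substr(seqchar, toy$segStart[e], toy$segEnd[e]), "")
        cds <- paste(parts, collapse = "")
        if (toy$strand == "-")
            cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
        cds
    }
    inCds <- any(pos >= toy$segStart & pos <= toy$segEnd)
    if (!inCds) return("non_CDS")
    wt <- as.character(Biostrings::translate(Biostrings::DNAString(splice(s))))
    mu <- as.character(Biostrings::translate(Biostrings::DNAString(splice(mut))))
    if (wt == mu) return("synonymous")
    i <- which(strsplit(wt, "")[[1]] != strsplit(mu, "")[[1]])[1]
    wtAA <- substr(wt, i, i); muAA <- substr(mu, i, i)
    if (muAA == "*") "nonsense"
    else if (wtAA == "*") "stop_lost"
    else if (i == 1 && wtAA == "M") "start_lost"
    else "missense"
}

# random paired diagnosis/relapse call sets over a shared key pool
randomPairedCalls <- function(seed) {
    set.seed(seed)
    nKeys <- sample(5:60, 1)
    pos <- sample(1e5, nKeys)
    ref <- sample(c("A", "C", "G", "T"), nKeys, replace = TRUE)
    alt <- vapply(ref, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    pick <- function() {
        idx <- which(runif(nKeys) < 0.6)
        if (!length(idx)) idx <- sample(nKeys, 1)
        VariantCalls("chr1", pos[idx], ref[idx], alt[idx],
                     refReads = rep(10L, length(idx)),
                     altReads = rep(10L, length(idx)))
    }
    list(diagnosis = pick(), relapse = pick())
}

# TRAAlterations with directly planted involvement sets
plantedAlterations <- function(n, involvedList, status) {
    gr <- GRanges(rep("chr1", n), IRanges(seq_len(n) * 10L, width = 1L))
    mcols(gr) <- S4Vectors::DataFrame(
        ref = rep("A", n), alt = rep("T", n),
        status = rep(status, n), traIndex = rep(1L, n),
        involved = IRanges::CharacterList(involvedList))
    new("TRAAlterations", gr)
}
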