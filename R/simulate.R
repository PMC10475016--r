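# --- synthetic data with planted truth -------------------------------------
#
# Every generator is a pure function of (parameters, seed): identical calls
# give byte-identical output. Planted truth is returned as a plain list and
# can be serialized as a JSON sidecar, so tests read truth instead of
# re-deriving it.

.SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                         c("TAA", "TAG", "TGA"))
.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Default transcription regulator name pool
#'
#' Twenty regulator names drawn from the ENCODE TFBS cluster vocabulary,
#' used by the simulators.
#' @return A character vector of length 20.
#' @export
defaultRegulators <- function() {
    c("POLR2A", "EP300", "CTCF", "MYC", "RCOR1", "CHD2", "PHF8", "STAT1",
      "GATA1", "HDAC1", "RXRA", "KDM5B", "MAX", "JUN", "FOS", "SPI1",
      "TAF1", "YY1", "REST", "SIN3A")
}

#' Simulate a reference genome and codable gene models
#'
#' Generates a random A/C/G/T genome and non-overlapping protein-coding
#' gene models on both strands. Every CDS starts with ATG, ends with a
#' stop codon, has length divisible by 3 and no internal stop codon (the
#' coding sequence is written into the genome, reverse-complemented for
#' minus-strand genes).
#'
#' @param nChrom number of chromosomes (default 2).
#' @param chromLength length of each chromosome in bp (default 300000).
#' @param nGenes total number of genes (default 24); 0 gives a genome
#'   with no models.
#' @param cdsExonsPerGene CDS segments per gene (default 2).
#' @param seed integer seed.
#' @return A list: \code{genome} (\linkS4class{DNAStringSet}, chromosomes
#'   named \code{chr1}, ...), \code{models} (\linkS4class{GeneModels}).
#' @export
simulateReference <- function(nChrom = 2L, chromLength = 300000L,
                              nGenes = 24L, cdsExonsPerGene = 2L,
                              seed = 1L) {
    set.seed(seed)
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(nChrom), function(i)
        paste(sample(bases, chromLength, replace = TRUE), collapse = ""),
        character(1))
    names(seqs) <- paste0("chr", seq_len(nChrom))

    geneRows <- list()
    cdsList <- list()
    if (nGenes > 0L) {
        cursor <- stats::setNames(rep(1L, nChrom), names(seqs))
        for (gi in seq_len(nGenes)) {
            chrom <- names(seqs)[(gi - 1L) %% nChrom + 1L]
            nCodons <- sample(60:160, 1L)
            L <- 3L * nCodons
            nEx <- max(1L, cdsExonsPerGene)
            # split L into nEx positive parts
            if (nEx > 1L) {
                cuts <- sort(sample(seq_len(L - 1L), nEx - 1L))
                exLens <- diff(c(0L, cuts, L))
            } else exLens <- L
            introns <- if (nEx > 1L) sample(100:800, nEx - 1L, replace = TRUE)
                       else integer(0)
            gap <- sample(2000:6000, 1L)
            startPos <- cursor[[chrom]] + gap
            geneLen <- sum(exLens) + sum(introns)
            if (startPos + geneLen > chromLength - 1000L)
                stop("infeasible packing: reduce nGenes or gene sizes, ",
                     "or increase chromLength")
            std <- sample(c("+", "-"), 1L)
            cds <- paste0("ATG",
                          paste(sample(.SENSE_CODONS, nCodons - 2L,
                                       replace = TRUE), collapse = ""),
                          sample(.STOP_CODONS, 1L))
            towrite <- if (std == "-")
                as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(cds)))
            else cds
            segStart <- integer(nEx); segEnd <- integer(nEx)
            p <- startPos; off <- 0L
            for (e in seq_len(nEx)) {
                segStart[e] <- p
                segEnd[e] <- p + exLens[e] - 1L
                substr(seqs[[chrom]], segStart[e], segEnd[e]) <-
                    substr(towrite, off + 1L, off + exLens[e])
                off <- off + exLens[e]
                p <- segEnd[e] + 1L + if (e < nEx) introns[e] else 0L
            }
            gid <- sprintf("gene%03d", gi)
            geneRows[[gi]] <- data.frame(
                chrom = chrom, start = startPos,
                end = segEnd[nEx], strand = std, gene_id = gid,
                gene_name = toupper(gid), tx_id = sprintf("tx%03d", gi))
            cdsList[[gid]] <- GRanges(chrom, IRanges(segStart, segEnd),
                                      strand = std)
            cursor[[chrom]] <- segEnd[nEx]
        }
    }
    genome <- Biostrings::DNAStringSet(seqs)
    if (length(geneRows)) {
        gdf <- do.call(rbind, geneRows)
        ord <- order(gdf$gene_id)
        gdf <- gdf[ord, ]
        genes <- GRanges(gdf$chrom, IRanges(gdf$start, gdf$end),
                         strand = gdf$strand)
        mcols(genes) <- DataFrame(gene_id = gdf$gene_id,
                                  gene_name = gdf$gene_name,
                                  tx_id = gdf$tx_id,
                                  codable = TRUE)
        models <- new("GeneModels", genes = genes,
                      cds = GRangesList(cdsList[gdf$gene_id]))
    } else {
        genes <- GRanges()
        mcols(genes) <- DataFrame(gene_id = character(0),
                                  gene_name = character(0),
                                  tx_id = character(0), codable = logical(0))
        models <- new("GeneModels", genes = genes, cds = GRangesList())
    }
    list(genome = genome, models = models)
}

#' Simulate TFBS clusters with planted TRAs
#'
#' Each planted region receives clusters from \code{k} distinct
#' regulators covering it exactly, so the TRA builder recovers exactly
#' the planted intervals with \code{k >= minRegulators} and nothing else.
#' Background clusters are sprinkled across the genome and the guarantee
#' is audited by running [buildTraRegions()] on the generated set; on an
#' accidental threshold-reaching background region the background is
#' re-jittered, up to \code{maxRetries} times.
#'
#' @param chromLengths named integer vector of chromosome lengths.
#' @param planted data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (1-based closed), \code{k} (distinct regulators to
#'   plant); intervals must be pairwise disjoint with >= 1 kb spacing.
#' @param regulators regulator name pool (default [defaultRegulators()]).
#' @param nBackground number of background clusters (default 100).
#' @param excludeRegulators regulators never used for planting or
#'   background (reserved, e.g., for per-variant involvement planting).
#' @param minRegulators audit threshold (default 5).
#' @param maxRetries background re-jitter attempts (default 20).
#' @param seed integer seed.
#' @return A list: \code{clusters} (\linkS4class{GRanges} with
#'   \code{regulator} and \code{score}), \code{plantedTras}
#'   (\linkS4class{GRanges} of the planted intervals with \code{k}).
#' @export
simulateTfbs <- function(chromLengths, planted,
                         regulators = defaultRegulators(),
                         nBackground = 100L, excludeRegulators = character(0),
                         minRegulators = 5L, maxRetries = 20L, seed = 1L) {
    stopifnot(all(c("chrom", "start", "end", "k") %in% colnames(planted)))
    pool <- setdiff(regulators, excludeRegulators)
    if (nrow(planted) && max(planted$k) > length(pool))
        stop("k exceeds the available regulator pool")
    set.seed(seed)
    plantedClusters <- list()
    for (i in seq_len(nrow(planted))) {
        regs <- sample(pool, planted$k[i])
        gr <- GRanges(planted$chrom[i],
                      IRanges(rep(planted$start[i], planted$k[i]),
                              rep(planted$end[i], planted$k[i])))
        mcols(gr)$regulator <- regs
        plantedClusters[[i]] <- gr
    }
    plantedGr <- if (length(plantedClusters))
        suppressWarnings(do.call(c, plantedClusters))
    else GRanges(regulator = character(0))
    expect <- planted[planted$k >= minRegulators, , drop = FALSE]
    expectGr <- GRanges(expect$chrom, IRanges(expect$start, expect$end))
    expectGr <- sort(sortSeqlevels(expectGr))

    allPlanted <- GRanges(planted$chrom, IRanges(planted$start, planted$end))
    makeBackground <- function() {
        if (nBackground == 0L)
            return(GRanges(regulator = character(0)))
        # keep background off the planted intervals so sub-threshold
        # regions can never be upgraded by an accidental extra regulator
        out <- GRanges()
        guard <- 0L
        while (length(out) < nBackground) {
            guard <- guard + 1L
            if (guard > 200L)
                stop("cannot place background clusters off the planted ",
                     "intervals; reduce nBackground")
            chrom <- sample(names(chromLengths), nBackground, replace = TRUE)
            w <- sample(100:1000, nBackground, replace = TRUE)
            start <- vapply(seq_len(nBackground), function(j)
                sample.int(chromLengths[[chrom[j]]] - w[j], 1L), integer(1))
            gr <- GRanges(chrom, IRanges(start, width = w))
            out <- suppressWarnings(
                c(out, gr[!overlapsAny(gr, allPlanted)]))
        }
        out <- out[seq_len(nBackground)]
        mcols(out)$regulator <- sample(pool, nBackground, replace = TRUE)
        out
    }
    for (try in seq_len(maxRetries)) {
        bg <- makeBackground()
        clusters <- suppressWarnings(c(plantedGr, bg))
        built <- buildTraRegions(clusters, minRegulators)
        got <- granges(built)
        mcols(got) <- NULL
        if (length(got) == length(expectGr) && all(got == expectGr)) {
            mcols(clusters)$score <- sample(200:1000, length(clusters),
                                            replace = TRUE)
            plantedOut <- GRanges(planted$chrom,
                                  IRanges(planted$start, planted$end),
                                  k = planted$k)
            return(list(clusters = clusters, plantedTras = plantedOut))
        }
    }
    stop("could not place background clusters without breaking the planted ",
         "TRA guarantee after ", maxRetries, " attempts")
}

# read-count draw guaranteed to pass VAF > 0.2 and alt >= 5
.passingReads <- function(n) {
    depth <- sample(30:100, n, replace = TRUE)
    v <- pmin(pmax(stats::rnorm(n, 0.35, 0.05), 0.25), 0.9)
    alt <- pmax(ceiling(v * depth), 8L)
    data.frame(ref_reads = depth - alt, alt_reads = alt)
}

.randomAlt <- function(ref) {
    vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
           "", USE.NAMES = FALSE)
}

#' Simulate germline/diagnosis/relapse variant call tables
#'
#' Plants exact post-filter truth: germline variants appear in all three
#' samples (exercising subtraction), common variants in both tumor
#' samples, additional only in relapse, lost only in diagnosis. A
#' configurable number of each somatic class is placed inside the planted
#' TRAs; a fraction of sub-threshold decoys (VAF exactly 0.20, or exactly
#' 4 supporting reads) is added to exercise the filter boundaries, and
#' these fail filtering wherever they occur.
#'
#' Per-regulator involvement probabilities are realised geometrically:
#' for each regulator in \code{regulatorProbs}, each in-TRA variant draws
#' a Bernoulli with the class probability, and on success a width-1
#' cluster of that regulator is emitted over the variant base (inside an
#' existing TRA, so TRA intervals are unchanged); [regulatorsAt()] then
#' recovers exactly the drawn involvement. Such regulators must be
#' reserved via \code{excludeRegulators} when building the clusters.
#'
#' @param genome a \linkS4class{DNAStringSet}.
#' @param plantedTras \linkS4class{GRanges} of TRA intervals (those with
#'   \code{k >=} the build threshold).
#' @param clusters the TFBS clusters (\linkS4class{GRanges}); returned
#'   augmented with involvement clusters.
#' @param counts list with \code{nGermline}, \code{nCommon},
#'   \code{nAdditional}, \code{nLost}, \code{nCommonInTra},
#'   \code{nAdditionalInTra} (in-TRA counts are subsets of the class
#'   totals).
#' @param regulatorProbs named list: regulator -> c(pCommon, pAdditional).
#' @param indelFraction fraction of somatic calls simulated as 1-3 bp
#'   deletions (default 0.1; in-TRA calls stay SNVs so regulator planting
#'   is base-exact).
#' @param subthresholdFraction decoy calls added as a fraction of the
#'   somatic total (default 0.1).
#' @param seed integer seed.
#' @return A list: \code{germline}, \code{diagnosis}, \code{relapse}
#'   (\linkS4class{VariantCalls}), \code{clusters} (augmented),
#'   \code{truth} (planted counts, realised involvement draws, seed).
#' @export
simulateVariantSets <- function(genome, plantedTras, clusters,
                                counts = list(nGermline = 20L, nCommon = 40L,
                                              nAdditional = 70L, nLost = 15L,
                                              nCommonInTra = 32L,
                                              nAdditionalInTra = 54L),
                                regulatorProbs = NULL,
                                indelFraction = 0.1,
                                subthresholdFraction = 0.1, seed = 1L) {
    stopifnot(counts$nCommon >= counts$nCommonInTra,
              counts$nAdditional >= counts$nAdditionalInTra)
    set.seed(seed)
    chromLengths <- stats::setNames(Biostrings::width(genome), names(genome))

    traBases <- data.frame(chrom = rep(as.character(seqnames(plantedTras)),
                                       width(plantedTras)),
                           pos = unlist(lapply(seq_along(plantedTras),
                               function(i) seq(start(plantedTras)[i],
                                               end(plantedTras)[i]))))
    nInTra <- counts$nCommonInTra + counts$nAdditionalInTra
    if (nInTra > nrow(traBases))
        stop("requested in-TRA variant count exceeds TRA capacity (",
             nrow(traBases), " bases)")
    inTraIdx <- sample.int(nrow(traBases), nInTra)

    nOutside <- (counts$nCommon - counts$nCommonInTra) +
        (counts$nAdditional - counts$nAdditionalInTra) +
        counts$nLost + counts$nGermline
    nDecoy <- ceiling(subthresholdFraction *
                      (counts$nCommon + counts$nAdditional + counts$nLost))
    drawOutside <- function(n) {
        out <- data.frame(chrom = character(0), pos = integer(0))
        guard <- 0L
        while (nrow(out) < n) {
            guard <- guard + 1L
            if (guard > 1000L) stop("cannot place variants outside TRAs")
            chrom <- sample(names(chromLengths), n, replace = TRUE)
            pos <- vapply(chrom, function(ch)
                sample.int(chromLengths[[ch]] - 10L, 1L), integer(1),
                USE.NAMES = FALSE)
            cand <- GRanges(chrom, IRanges(pos, width = 1L))
            ok <- !overlapsAny(cand, plantedTras)
            out <- unique(rbind(out, data.frame(chrom = chrom[ok],
                                                pos = pos[ok])))
        }
        out[seq_len(n), ]
    }
    outside <- drawOutside(nOutside + nDecoy)

    mkCalls <- function(posDf, allowIndel) {
        n <- nrow(posDf)
        ref <- vapply(seq_len(n), function(i)
            as.character(Biostrings::subseq(genome[[posDf$chrom[i]]],
                                            posDf$pos[i], posDf$pos[i])),
            character(1))
        alt <- .randomAlt(ref)
        isIndel <- allowIndel & stats::runif(n) < indelFraction
        for (i in which(isIndel)) {
            dl <- sample(1:3, 1L)
            ref[i] <- as.character(Biostrings::subseq(
                genome[[posDf$chrom[i]]], posDf$pos[i], posDf$pos[i] + dl))
            alt[i] <- substr(ref[i], 1L, 1L)
        }
        data.frame(chrom = posDf$chrom, pos = posDf$pos,
                   ref = ref, alt = alt)
    }

    inTraCalls <- mkCalls(traBases[inTraIdx, ], allowIndel = FALSE)
    outCalls <- mkCalls(outside[seq_len(nOutside), , drop = FALSE],
                        allowIndel = TRUE)
    split1 <- counts$nCommonInTra
    commonInTra <- inTraCalls[seq_len(split1), , drop = FALSE]
    additionalInTra <- inTraCalls[-seq_len(split1), , drop = FALSE]
    idx <- 0L
    take <- function(n) {
        r <- outCalls[idx + seq_len(n), , drop = FALSE]; idx <<- idx + n; r
    }
    commonOut <- take(counts$nCommon - counts$nCommonInTra)
    additionalOut <- take(counts$nAdditional - counts$nAdditionalInTra)
    lostCalls <- take(counts$nLost)
    germCalls <- take(counts$nGermline)
    commonCalls <- rbind(commonInTra, commonOut)
    additionalCalls <- rbind(additionalInTra, additionalOut)

    # Bernoulli involvement realised as width-1 clusters over variant bases
    extraClusters <- GRanges(regulator = character(0))
    realized <- list()
    if (!is.null(regulatorProbs)) {
        present <- mcols(clusters)$regulator
        for (reg in names(regulatorProbs)) {
            if (reg %in% present)
                stop("regulator ", reg, " must be excluded from cluster ",
                     "simulation to plant involvement probabilities")
            p <- regulatorProbs[[reg]]
            drawC <- stats::runif(nrow(commonInTra)) < p[[1L]]
            drawA <- stats::runif(nrow(additionalInTra)) < p[[2L]]
            hitC <- commonInTra[drawC, , drop = FALSE]
            hitA <- additionalInTra[drawA, , drop = FALSE]
            hits <- rbind(hitC, hitA)
            if (nrow(hits)) {
                gr <- GRanges(hits$chrom, IRanges(hits$pos, width = 1L))
                mcols(gr)$regulator <- reg
                mcols(gr)$score <- rep(1000L, length(gr))
                extraClusters <- suppressWarnings(c(extraClusters, gr))
            }
            realized[[reg]] <- list(nCommonInvolved = sum(drawC),
                                    nAdditionalInvolved = sum(drawA))
        }
    }
    if (is.null(mcols(clusters)$score))
        mcols(clusters)$score <- rep(1000L, length(clusters))
    clustersOut <- suppressWarnings(c(clusters, extraClusters))

    asCalls <- function(df, sample) {
        if (nrow(df) == 0L) return(VariantCalls(sample = sample))
        reads <- .passingReads(nrow(df))
        VariantCalls(df$chrom, df$pos, df$ref, df$alt,
                     reads$ref_reads, reads$alt_reads, sample = sample)
    }
    germG <- asCalls(germCalls, "germline")
    # germline variants re-drawn per tumor sample but same keys
    germInDiag <- asCalls(germCalls, "diagnosis")
    germInRel <- asCalls(germCalls, "relapse")
    commonDiag <- asCalls(commonCalls, "diagnosis")
    commonRel <- asCalls(commonCalls, "relapse")
    additionalRel <- asCalls(additionalCalls, "relapse")
    lostDiag <- asCalls(lostCalls, "diagnosis")

    decoys <- outside[nOutside + seq_len(nDecoy), , drop = FALSE]
    mkDecoys <- function(df, sample) {
        if (nrow(df) == 0L) return(VariantCalls(sample = sample))
        n <- nrow(df)
        ref <- vapply(seq_len(n), function(i)
            as.character(Biostrings::subseq(genome[[df$chrom[i]]],
                                            df$pos[i], df$pos[i])),
            character(1))
        alt <- .randomAlt(ref)
        # alternate the two boundary cases: VAF exactly 0.20 / exactly 4 reads
        even <- seq_len(n) %% 2L == 0L
        refReads <- ifelse(even, 24L, 6L)
        altReads <- ifelse(even, 6L, 4L)
        VariantCalls(df$chrom, df$pos, ref, alt, refReads, altReads,
                     sample = sample)
    }
    third <- rep_len(c("both", "relapse", "diagnosis"), nDecoy)
    decoyDiag <- mkDecoys(decoys[third != "relapse", , drop = FALSE],
                          "diagnosis")
    decoyRel <- mkDecoys(decoys[third != "diagnosis", , drop = FALSE],
                         "relapse")

    comb <- function(...) {
        parts <- list(...)
        parts <- parts[vapply(parts, length, 0L) > 0L]
        if (!length(parts)) return(VariantCalls())
        new("VariantCalls",
            suppressWarnings(do.call(c, lapply(parts, as, "GRanges"))))
    }
    diagnosis <- comb(germInDiag, commonDiag, lostDiag, decoyDiag)
    relapse <- comb(germInRel, commonRel, additionalRel, decoyRel)

    truth <- list(
        counts = counts,
        nDecoys = nDecoy,
        regulatorProbs = lapply(regulatorProbs, as.numeric),
        realizedInvolvement = realized,
        plantedTras = data.frame(chrom = as.character(seqnames(plantedTras)),
                                 start = start(plantedTras),
                                 end = end(plantedTras)),
        seed = seed)
    list(germline = germG, diagnosis = diagnosis, relapse = relapse,
         clusters = clustersOut, truth = truth)
}

#' Simulate gene- and transcript-level expression tables
#'
#' Gene-level: FPKM columns for control and condition replicates; planted
#' up/down genes carry a log2 effect of \code{effectLog2fc} (clear of the
#' default |FC| >= 2 threshold), null genes only noise. p-values are
#' planted (below the cutoff for planted genes, above it for nulls),
#' mirroring the pipeline's stance that p-value provenance is external;
#' fold change is computed from the FPKM columns via
#' [computeFoldChange()]. Transcript-level: each planted shift gene gets
#' one transcript passing the thresholds with an accepted structure class
#' (\code{"c"}/\code{"j"}); distractor transcripts pass the thresholds
#' with a non-accepted class, or carry an accepted class but fail them.
#'
#' @param nGenes total genes (default 2000).
#' @param nUp,nDown planted differential genes (defaults 74 and 320, the
#'   headline fixture sizes).
#' @param nShiftGenes planted transcript-shift genes (default 150).
#' @param effectLog2fc planted |log2 FC| (default 2).
#' @param replicates per-group replicates (default 3).
#' @param noiseSd sd of log2 FPKM noise (default 0.2).
#' @param geneIds optional gene id vector of length \code{nGenes}.
#' @param seed integer seed.
#' @return A list: \code{geneTable}, \code{transcriptTable} (data.frames)
#'   and \code{truth} (\code{up}, \code{down}, \code{shift} id vectors).
#' @export
simulateExpression <- function(nGenes = 2000L, nUp = 74L, nDown = 320L,
                               nShiftGenes = 150L, effectLog2fc = 2,
                               replicates = 3L, noiseSd = 0.2,
                               geneIds = NULL, seed = 1L) {
    stopifnot(nUp + nDown + nShiftGenes <= nGenes)
    set.seed(seed)
    if (is.null(geneIds))
        geneIds <- sprintf("g%05d", seq_len(nGenes))
    stopifnot(length(geneIds) == nGenes)
    planted <- sample(geneIds, nUp + nDown + nShiftGenes)
    up <- planted[seq_len(nUp)]
    down <- planted[nUp + seq_len(nDown)]
    shift <- planted[nUp + nDown + seq_len(nShiftGenes)]

    base <- stats::rlnorm(nGenes, meanlog = 3, sdlog = 1)
    eff <- numeric(nGenes)
    eff[geneIds %in% up] <- effectLog2fc
    eff[geneIds %in% down] <- -effectLog2fc
    tab <- data.frame(gene_id = geneIds)
    for (r in seq_len(replicates))
        tab[[paste0("ctrl_", r)]] <-
            base * 2^stats::rnorm(nGenes, 0, noiseSd)
    for (r in seq_len(replicates))
        tab[[paste0("cond_", r)]] <-
            base * 2^(eff + stats::rnorm(nGenes, 0, noiseSd))
    tab <- computeFoldChange(tab, paste0("ctrl_", seq_len(replicates)),
                             paste0("cond_", seq_len(replicates)))
    isPlanted <- geneIds %in% c(up, down)
    tab$p_value <- ifelse(isPlanted,
                          stats::runif(nGenes, 1e-6, 0.005),
                          stats::runif(nGenes, 0.02, 1))

    # transcript table: one passing accepted-class transcript per shift gene
    shiftRows <- if (length(shift) == 0L)
        data.frame(gene_id = character(0), transcript_id = character(0),
                   fold_change = numeric(0), p_value = numeric(0),
                   structure_class = character(0))
    else data.frame(
        gene_id = shift,
        transcript_id = paste0(shift, ".t1"),
        fold_change = 2^(sample(c(-1, 1), length(shift), replace = TRUE) *
                         effectLog2fc),
        p_value = stats::runif(length(shift), 1e-6, 0.005),
        structure_class = sample(c("c", "j"), length(shift), replace = TRUE))
    nonShift <- setdiff(geneIds, shift)
    nDistract <- min(length(nonShift), max(20L, nShiftGenes %/% 2L))
    dg <- sample(nonShift, nDistract)
    half <- nDistract %/% 2L
    distract <- data.frame(
        gene_id = dg,
        transcript_id = paste0(dg, ".t1"),
        # first half: pass thresholds, wrong class; rest: right class, fail p
        fold_change = c(rep(2^effectLog2fc, half),
                        rep(1.1, nDistract - half)),
        p_value = c(stats::runif(half, 1e-6, 0.005),
                    stats::runif(nDistract - half, 0.5, 1)),
        structure_class = c(rep("=", half),
                            sample(c("c", "j"), nDistract - half,
                                   replace = TRUE)))
    txTab <- rbind(shiftRows, distract)
    txTab <- txTab[order(txTab$gene_id, txTab$transcript_id), ]
    rownames(txTab) <- NULL
    list(geneTable = tab, transcriptTable = txTab,
         truth = list(up = sort(up), down = sort(down),
                      shift = sort(shift)))
}

#' Write the paper-like end-to-end fixture
#'
#' Generates and serializes every pipeline input with planted truth, at
#' the headline scale of the motivating study: 32 common and 54
#' additional in-TRA alterations, 74 up- and 320 down-regulated genes,
#' and a MYC-like regulator with involvement probabilities 0.28 (common)
#' and 0.47 (additional). Those sizes are an homage to the study's
#' counts, not a reproduction of them. All files are plain text; the
#' truth sidecar is JSON.
#'
#' @param dir output directory (created if needed).
#' @param seed integer master seed (default 7); sub-seeds for each
#'   generator are derived deterministically from it.
#' @param counts planted variant counts (see [simulateVariantSets()]).
#' @param regulatorProbs planted involvement probabilities (default
#'   \code{list(MYC = c(0.28, 0.47))}).
#' @param expression list of overrides for [simulateExpression()]
#'   parameters.
#' @return Invisibly, a list with the file \code{paths} and the
#'   \code{truth} list.
#' @export
paperLikeFixture <- function(dir, seed = 7L,
                             counts = list(nGermline = 20L, nCommon = 40L,
                                           nAdditional = 70L, nLost = 15L,
                                           nCommonInTra = 32L,
                                           nAdditionalInTra = 54L),
                             regulatorProbs = list(MYC = c(0.28, 0.47)),
                             expression = list()) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    set.seed(seed)
    subSeeds <- sample.int(.Machine$integer.max - 1L, 4L)

    ref <- simulateReference(nChrom = 2L, chromLength = 300000L,
                             nGenes = 24L, cdsExonsPerGene = 2L,
                             seed = subSeeds[1L])
    chromLengths <- stats::setNames(Biostrings::width(ref$genome),
                                    names(ref$genome))
    # 10 qualifying TRAs (k 5-8) + 2 sub-threshold decoy regions (k 4)
    plantedDf <- data.frame(
        chrom = rep(names(chromLengths), each = 6L),
        start = rep(20000L + (0:5) * 45000L, 2L),
        end = rep(20000L + (0:5) * 45000L, 2L) + 2499L,
        k = c(5L, 6L, 7L, 8L, 5L, 4L, 6L, 5L, 7L, 5L, 6L, 4L))
    tf <- simulateTfbs(chromLengths, plantedDf,
                       excludeRegulators = names(regulatorProbs),
                       nBackground = 120L, seed = subSeeds[2L])
    qualifying <- tf$plantedTras[mcols(tf$plantedTras)$k >= 5L]
    vs <- simulateVariantSets(ref$genome, qualifying, tf$clusters,
                              counts = counts,
                              regulatorProbs = regulatorProbs,
                              seed = subSeeds[3L])
    exArgs <- utils::modifyList(
        list(nGenes = 2000L, nUp = 74L, nDown = 320L, nShiftGenes = 1321L,
             seed = subSeeds[4L]),
        expression)
    # expression ids share the reference gene namespace so WGS/expression
    # gene sets can genuinely overlap
    modelIds <- as.character(mcols(geneRanges(ref$models))$gene_id)
    exArgs$geneIds <- c(modelIds,
                        sprintf("g%05d", seq_len(exArgs$nGenes -
                                                 length(modelIds))))
    ex <- do.call(simulateExpression, exArgs)

    paths <- list(
        genome = file.path(dir, "genome.fa"),
        geneModels = file.path(dir, "genes.gff3"),
        tfbs = file.path(dir, "tfbs_clusters.bed"),
        germline = file.path(dir, "germline.tsv"),
        diagnosis = file.path(dir, "diagnosis.tsv"),
        relapse = file.path(dir, "relapse.tsv"),
        expressionGene = file.path(dir, "expression_genes.tsv"),
        expressionTranscript = file.path(dir, "expression_transcripts.tsv"),
        truth = file.path(dir, "truth.json"))
    Biostrings::writeXStringSet(ref$genome, paths$genome)
    writeGeneModels(ref$models, paths$geneModels)
    writeTfbsClusters(vs$clusters, paths$tfbs)
    writeVariants(vs$germline, paths$germline)
    writeVariants(vs$diagnosis, paths$diagnosis)
    writeVariants(vs$relapse, paths$relapse)
    .writeTsv(ex$geneTable, paths$expressionGene)
    .writeTsv(ex$transcriptTable, paths$expressionTranscript)
    truth <- c(vs$truth,
               list(deTruth = ex$truth, masterSeed = seed,
                    nQualifyingTras = length(qualifying)))
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(list(paths = paths, truth = truth))
}
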