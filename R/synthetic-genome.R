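## Synthetic plasmid generator: plants promoters, terminators and regulon
## motifs with a recorded ground truth so recovery can be scored exactly.

PROMOTER_M35 <- "TTGACA"
PROMOTER_M10 <- "TATAAT"

#' The 34 bp regulon motif consensus
#'
#' Degenerate IUPAC consensus of the conserved 34 bp regulatory motif that
#' overlaps the -10 promoter element of plasmid regulon genes
#' (`W` = A/T, `Y` = C/T); positions 9-14 are the -10 hexamer.
#'
#' @return a single IUPAC character string of length 34.
#' @examples
#' nchar(regulonMotif())
#' @export
regulonMotif <- function() "AWAYATGYTATACTGAATATGTCCACATAAAAWA"

#' Construct generator parameters for a synthetic plasmid
#'
#' Bundles and validates all tunables of [simulatePlasmid()]. Defaults
#' emulate a 20 kb fragment of a high-GC (60%) plasmid with 20 genes across
#' four transcription tiers, canonical TTGACA-n17-TATAAT promoters whose
#' degeneracy grows as the tier drops, tier-dependent spacer-length
#' distributions (mode 17 nt for high-tier, 16 nt for medium-tier
#' promoters), a mix of rho-independent, stem-loop and convergent
#' terminators, and six planted copies of the 34 bp regulon motif.
#'
#' @param genomeLength genome size in nt.
#' @param gcContent background GC fraction.
#' @param nGenes number of genes.
#' @param tierProportions named fractions over
#'   `c(high, medium, low, silent)`, summing to 1.
#' @param promoterFidelity named integer vector `c(high, medium, low)`:
#'   maximum mismatches to the promoter consensus per tier.
#' @param spacerDist 3 x 5 matrix of spacer-length probabilities
#'   (rows `high`, `medium`, `low`; columns 15-19 nt), rows summing to 1.
#' @param terminatorMix named fractions over
#'   `c(rho_independent, stem_loop, convergent)`, summing to 1.
#' @param motifCount number of 34 bp regulon motifs planted over -10
#'   elements of distinct high-tier genes (requires `promoterFidelity["high"]
#'   >= 1`, since the motif -10 is TATACT).
#' @param seed integer RNG seed.
#' @return a validated [GenParams-class] object.
#' @examples
#' genParams(seed = 1)
#' @export
genParams <- function(genomeLength = 20000L,
                      gcContent = 0.60,
                      nGenes = 20L,
                      tierProportions = c(high = 0.3, medium = 0.3,
                                          low = 0.2, silent = 0.2),
                      promoterFidelity = c(high = 1L, medium = 2L, low = 3L),
                      spacerDist = rbind(
                          high   = c(0.02, 0.10, 0.76, 0.10, 0.02),
                          medium = c(0.10, 0.40, 0.25, 0.15, 0.10),
                          low    = c(0.20, 0.25, 0.20, 0.20, 0.15)),
                      terminatorMix = c(rho_independent = 0.5,
                                        stem_loop = 0.2, convergent = 0.3),
                      motifCount = 6L,
                      seed = 1L) {
    colnames(spacerDist) <- as.character(SPACER_RANGE)
    new("GenParams",
        genomeLength = as.integer(genomeLength),
        gcContent = gcContent,
        nGenes = as.integer(nGenes),
        tierProportions = tierProportions,
        promoterFidelity = vapply(promoterFidelity, as.integer, integer(1)),
        spacerDist = spacerDist,
        terminatorMix = terminatorMix,
        motifCount = as.integer(motifCount),
        seed = as.integer(seed))
}

## resolve IUPAC ambiguity codes to concrete bases, randomly
resolveIupac <- function(pattern) {
    chars <- strsplit(pattern, "")[[1]]
    vapply(chars, function(ch) {
        switch(ch,
            W = sample(c("A", "T"), 1L),
            Y = sample(c("C", "T"), 1L),
            N = sample(DNA_BASES_CHR, 1L),
            ch)
    }, character(1), USE.NAMES = FALSE) |> paste(collapse = "")
}

## random in-frame CDS: ATG + nCodons sense codons + stop
randomCDS <- function(nCodons, gc) {
    stops <- c("TAA", "TAG", "TGA")
    body <- character(nCodons)
    i <- 1L
    while (i <= nCodons) {
        cod <- randomDNA(3L, gc)
        if (!cod %in% stops) {
            body[i] <- cod
            i <- i + 1L
        }
    }
    paste0("ATG", paste(body, collapse = ""), sample(stops, 1L))
}

## hairpin used for terminator planting: GC-only stem, loop avoiding
## accidental stem extension, optional poly-T tail
plantHairpin <- function(polyT) {
    stem <- paste(sample(c("G", "C"), 8L, replace = TRUE), collapse = "")
    loop <- paste(sample(c("A", "T"), 4L, replace = TRUE), collapse = "")
    tail <- if (polyT) strrep("T", 7L)
            else paste(sample(c("A", "C", "G"), 8L, replace = TRUE),
                       collapse = "")
    paste0(stem, loop, revcompChr(stem), tail)
}

## one gene cassette in reading orientation; local 1-based coordinates
buildCassette <- function(tier, termClass, withMotif, params) {
    pad <- 12L
    cdsLen <- 3L * sample(100:220, 1L) + 6L   # ATG + body + stop
    if (tier == "silent") {
        seq <- paste0(randomDNA(pad, params@gcContent),
                      randomCDS((cdsLen - 6L) / 3L, params@gcContent),
                      randomDNA(6L, params@gcContent))
        return(list(seq = seq, tier = tier,
                    cds = c(pad + 1L, pad + cdsLen),
                    tss = NA_integer_, tts = NA_integer_,
                    minus35 = NA_character_, spacer = NA_integer_,
                    minus10 = NA_character_, minus10End = NA_integer_,
                    termClass = "none", motif = NULL))
    }
    s <- sample(SPACER_RANGE, 1L, prob = params@spacerDist[tier, ])
    utr5 <- switch(tier,
        high = sample(28:38, 1L),
        medium = sample(20:32, 1L),
        low = sample(20:32, 1L))
    utr3 <- sample(15:40, 1L)

    ## promoter with tier-limited degeneracy (total mismatches over both
    ## hexamers); motif genes carry the motif's own -10 (TATACT, one
    ## mismatch) and an exact -35
    prom12 <- paste0(PROMOTER_M35, PROMOTER_M10)
    if (withMotif) {
        nmm <- 1L
    } else {
        nmm <- sample(0:params@promoterFidelity[[tier]], 1L)
        if (nmm > 0L)
            prom12 <- mutateBases(prom12, sample(12L, nmm))
    }
    m35 <- substr(prom12, 1L, 6L)
    m10 <- substr(prom12, 7L, 12L)

    term <- switch(termClass,
        rho_independent = paste0(randomDNA(3L, params@gcContent),
                                 plantHairpin(polyT = TRUE),
                                 randomDNA(5L, params@gcContent)),
        stem_loop = paste0(randomDNA(3L, params@gcContent),
                           plantHairpin(polyT = FALSE),
                           randomDNA(5L, params@gcContent)),
        randomDNA(4L, params@gcContent))

    parts <- c(randomDNA(pad, params@gcContent), m35,
               randomDNA(s, params@gcContent), m10,
               randomDNA(6L, params@gcContent),
               randomDNA(utr5, params@gcContent),
               randomCDS((cdsLen - 6L) / 3L, params@gcContent),
               randomDNA(utr3, params@gcContent), term)
    seq <- paste(parts, collapse = "")

    m35Start <- pad + 1L                       # 13
    m10Start <- m35Start + 6L + s              # 19 + s
    m10End <- m10Start + 5L                    # 24 + s
    tss <- m10End + 7L                         # 31 + s
    cdsStart <- tss + utr5
    cdsEnd <- cdsStart + cdsLen - 1L
    tts <- cdsEnd + utr3

    motif <- NULL
    if (withMotif) {
        inst <- resolveIupac(regulonMotif())
        mStart <- m10Start - 8L
        substr(seq, mStart, mStart + 33L) <- inst
        m10 <- substr(seq, m10Start, m10End)   # TATACT by construction
        motif <- list(start = mStart, end = mStart + 33L, sequence = inst)
    }

    list(seq = seq, tier = tier,
         cds = c(cdsStart, cdsEnd), tss = tss, tts = tts,
         minus35 = m35, spacer = s, minus10 = m10, minus10End = m10End,
         termClass = termClass, motif = motif)
}

#' Simulate a plasmid genome with planted regulatory ground truth
#'
#' Generates a single-contig genome in which every non-silent gene is
#' preceded by a planted TTGACA-n(15-19)-TATAAT promoter (mismatch count
#' bounded by its tier's fidelity, spacer drawn from its tier's
#' distribution, transcription start site 7 nt downstream of the -10
#' hexamer's 3' end), carries a 5'/3' UTR and a terminator of the drawn
#' class, and may carry one planted 34 bp regulon motif overlapping its -10
#' element. Convergent terminators are planted as adjacent opposite-strand
#' gene pairs whose 3' ends lie within 50 nt, without a hairpin. Output is
#' a pure function of the parameters (including the seed).
#'
#' @param params a [GenParams-class] object from [genParams()].
#' @return a list with elements `bundle` (a [GenomeBundle-class]) and
#'   `truth` (a [TruthSet-class] recording every planted feature).
#' @examples
#' sim <- simulatePlasmid(genParams(seed = 1))
#' sim$bundle
#' head(truthGenes(sim$truth))
#' @export
simulatePlasmid <- function(params) {
    stopifnot(is(params, "GenParams"))
    validObject(params)
    withSeed(params@seed, {
        n <- params@nGenes
        ## deterministic tier counts, shuffled over gene positions
        counts <- round(params@tierProportions[TIER_LEVELS] * n)
        counts[1L] <- counts[1L] + (n - sum(counts))
        tiers <- sample(rep(TIER_LEVELS, times = counts))

        highIdx <- which(tiers == "high")
        if (params@motifCount > length(highIdx))
            stop("motifCount exceeds the number of high-tier genes")
        if (params@motifCount > 0L && params@promoterFidelity[["high"]] < 1L)
            stop("planting the regulon motif needs high-tier fidelity >= 1")
        motifGenes <- sort(sample(highIdx, params@motifCount))

        ## terminator classes; convergent genes must come in adjacent pairs
        classes <- rep("none", n)
        i <- 1L
        while (i <= n) {
            if (tiers[i] == "silent") { i <- i + 1L; next }
            cls <- sample(names(params@terminatorMix), 1L,
                          prob = params@terminatorMix)
            if (cls == "convergent" && i < n && tiers[i + 1L] != "silent") {
                classes[i] <- classes[i + 1L] <- "convergent"
                i <- i + 2L
            } else {
                if (cls == "convergent")
                    cls <- "rho_independent"
                classes[i] <- cls
                i <- i + 1L
            }
        }

        pieces <- character(0)
        pos <- 0L   # genomic end of assembled sequence so far
        geneRows <- vector("list", n)
        motifRows <- list()
        i <- 1L
        while (i <= n) {
            gap <- randomDNA(sample(20:60, 1L), params@gcContent)
            pieces <- c(pieces, gap)
            pos <- pos + nchar(gap)
            convPair <- classes[i] == "convergent" && i < n &&
                classes[i + 1L] == "convergent"
            idx <- if (convPair) c(i, i + 1L) else i
            strands <- if (convPair) c("+", "-") else "+"
            for (k in seq_along(idx)) {
                g <- idx[k]
                cas <- buildCassette(tiers[g], classes[g],
                                     g %in% motifGenes, params)
                Lc <- nchar(cas$seq)
                if (strands[k] == "+") {
                    toGenomic <- function(p) pos + p
                    pieces <- c(pieces, cas$seq)
                } else {
                    toGenomic <- function(p) pos + Lc - p + 1L
                    pieces <- c(pieces, revcompChr(cas$seq))
                }
                cdsG <- sort(toGenomic(cas$cds))
                geneRows[[g]] <- data.frame(
                    gene_id = sprintf("gene_%03d", g),
                    tier = cas$tier, strand = strands[k],
                    start = cdsG[1L], end = cdsG[2L],
                    tss = if (is.na(cas$tss)) NA_integer_ else
                        toGenomic(cas$tss),
                    tts = if (is.na(cas$tts)) NA_integer_ else
                        toGenomic(cas$tts),
                    minus35 = cas$minus35, spacer_len = cas$spacer,
                    minus10 = cas$minus10,
                    minus10_end = if (is.na(cas$minus10End)) NA_integer_ else
                        toGenomic(cas$minus10End),
                    terminator_class = cas$termClass,
                    stringsAsFactors = FALSE)
                if (!is.null(cas$motif)) {
                    mg <- sort(toGenomic(c(cas$motif$start, cas$motif$end)))
                    motifRows[[length(motifRows) + 1L]] <- data.frame(
                        gene_id = sprintf("gene_%03d", g),
                        start = mg[1L], end = mg[2L], strand = strands[k],
                        sequence = cas$motif$sequence,
                        stringsAsFactors = FALSE)
                }
                pos <- pos + Lc
                if (convPair && k == 1L) {
                    gap2 <- randomDNA(20L, params@gcContent)
                    pieces <- c(pieces, gap2)
                    pos <- pos + 20L
                }
            }
            i <- i + length(idx)
        }
        if (pos > params@genomeLength)
            stop(sprintf(
                "genome too small: %d nt of features exceed genomeLength %d",
                pos, params@genomeLength))
        pieces <- c(pieces,
                    randomDNA(params@genomeLength - pos, params@gcContent))
        genome <- paste(pieces, collapse = "")

        genesDf <- do.call(rbind, geneRows)
        motifsDf <- if (length(motifRows)) do.call(rbind, motifRows) else
            data.frame(gene_id = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       sequence = character(0), stringsAsFactors = FALSE)
        ## UTR lengths implied by the planted boundaries
        genesDf$utr5_len <- ifelse(is.na(genesDf$tss), NA_integer_,
            ifelse(genesDf$strand == "+", genesDf$start - genesDf$tss,
                   genesDf$tss - genesDf$end))
        genesDf$utr3_len <- ifelse(is.na(genesDf$tts), NA_integer_,
            ifelse(genesDf$strand == "+", genesDf$tts - genesDf$end,
                   genesDf$start - genesDf$tts))

        seqs <- Biostrings::DNAStringSet(genome)
        names(seqs) <- "synthetic_plasmid"
        gr <- GenomicRanges::GRanges(
            seqnames = "synthetic_plasmid",
            ranges = IRanges::IRanges(genesDf$start, genesDf$end),
            strand = genesDf$strand)
        gr$gene_id <- genesDf$gene_id
        gr$tier <- genesDf$tier
        bundle <- new("GenomeBundle", seq = seqs, genes = gr,
                      circular = FALSE)
        truth <- new("TruthSet",
                     genes = S4Vectors::DataFrame(genesDf),
                     motifs = S4Vectors::DataFrame(motifsDf),
                     degs = S4Vectors::DataFrame(
                         gene_id = character(0), log2fc = numeric(0),
                         direction = character(0)),
                     params = list(seed = params@seed,
                                   genomeLength = params@genomeLength,
                                   gcContent = params@gcContent))
        list(bundle = bundle, truth = truth)
    })
}
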