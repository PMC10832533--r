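test_that("plasmid generation is deterministic and byte-stable on disk", {
    s1 <- simulatePlasmid(genParams(seed = 1))
    s2 <- simulatePlasmid(genParams(seed = 1))
    expect_identical(as.character(genomeSeq(s1$bundle)),
                     as.character(genomeSeq(s2$bundle)))
    expect_identical(as.data.frame(truthGenes(s1$truth)),
                     as.data.frame(truthGenes(s2$truth)))
    d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
    dir.create(d1, showWarnings = FALSE)
    dir.create(d2, showWarnings = FALSE)
    for (d in c(d1, d2)) {
        s <- simulatePlasmid(genParams(seed = 1))
        writeGenomeBundle(s$bundle, file.path(d, "g.fasta"),
                          file.path(d, "g.gff3"))
        writeTruth(s$truth, file.path(d, "truth.json"))
        cv <- simulateCoverage(s$bundle, s$truth, seed = 5)
        writeCoverage(cv$track, file.path(d, "p.bedgraph"),
                      file.path(d, "m.bedgraph"))
    }
    for (f in c("g.fasta", "g.gff3", "truth.json", "p.bedgraph",
                "m.bedgraph"))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    ## a different seed gives a different genome
    s3 <- simulatePlasmid(genParams(seed = 2))
    expect_false(identical(as.character(genomeSeq(s1$bundle)),
                           as.character(genomeSeq(s3$bundle))))
})

test_that("promoter planting respects tier fidelity and spacer law", {
    ## zero-mismatch case: every high-tier promoter is the exact consensus
    p0 <- genParams(promoterFidelity = c(high = 0L, medium = 2L,
                                         low = 3L),
                    motifCount = 0L, seed = 11)
    tg <- as.data.frame(truthGenes(simulatePlasmid(p0)$truth))
    hi <- tg[tg$tier == "high", ]
    expect_true(all(hi$minus35 == "TTGACA"))
    expect_true(all(hi$minus10 == "TATAAT"))
    ## degenerate spacer distribution: point mass at 17
    sd17 <- rbind(high = c(0, 0, 1, 0, 0),
                  medium = c(0.1, 0.4, 0.25, 0.15, 0.1),
                  low = c(0.2, 0.25, 0.2, 0.2, 0.15))
    tg2 <- as.data.frame(truthGenes(
        simulatePlasmid(genParams(spacerDist = sd17, seed = 12))$truth))
    expect_true(all(tg2$spacer_len[tg2$tier == "high"] == 17L))
    ## general case: mismatch count bounded by the tier budget
    tg3 <- as.data.frame(truthGenes(
        simulatePlasmid(genParams(seed = 13))$truth))
    mm <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    for (i in which(tg3$tier == "high"))
        expect_lte(mm(tg3$minus35[i], "TTGACA") +
                   mm(tg3$minus10[i], "TATAAT"), 1L)
    for (i in which(tg3$tier == "medium"))
        expect_lte(mm(tg3$minus35[i], "TTGACA") +
                   mm(tg3$minus10[i], "TATAAT"), 2L)
})

test_that("planted features round-trip: truth matches the sequence", {
    sim <- simulatePlasmid(genParams(seed = 3))
    genome <- genomeSeq(sim$bundle)[[1L]]
    tg <- as.data.frame(truthGenes(sim$truth))
    fetch <- function(lo, hi, strand) {
        s <- as.character(Biostrings::subseq(genome, lo, hi))
        if (strand == "-")
            s <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(s)))
        s
    }
    for (i in which(tg$tier != "silent")) {
        m10 <- if (tg$strand[i] == "+")
            fetch(tg$minus10_end[i] - 5L, tg$minus10_end[i], "+")
        else fetch(tg$minus10_end[i], tg$minus10_end[i] + 5L, "-")
        expect_identical(m10, tg$minus10[i])
        ## TSS sits 7 nt downstream of the -10 3' end
        expect_identical(abs(tg$tss[i] - tg$minus10_end[i]), 7L)
        ## every gene starts with a start codon in reading orientation
        cds <- fetch(tg$start[i], tg$end[i], tg$strand[i])
        expect_identical(substr(cds, 1L, 3L), "ATG")
    }
    ## planted motif instances are present verbatim
    tm <- as.data.frame(truthMotifs(sim$truth))
    expect_identical(nrow(tm), 6L)
    for (i in seq_len(nrow(tm)))
        expect_identical(fetch(tm$start[i], tm$end[i], tm$strand[i]),
                         tm$sequence[i])
    ## truth json round-trips
    f <- tempfile(fileext = ".json")
    writeTruth(sim$truth, f)
    back <- readTruth(f)
    expect_equal(as.data.frame(truthGenes(back)), tg)
})

test_that("generator rejects impossible requests", {
    expect_error(simulatePlasmid(genParams(genomeLength = 2500L,
                                           nGenes = 20L, seed = 1)),
                 "too small")
    expect_error(genParams(tierProportions = c(high = 0.5, medium = 0.5,
                                               low = 0.5, silent = 0.5)),
                 "sum to 1")
    expect_error(simulatePlasmid(
        genParams(promoterFidelity = c(high = 0L, medium = 2L, low = 3L),
                  motifCount = 6L, seed = 1)),
        "fidelity")
})

test_that("simulated coverage hits tier depth, stays quiet on silent genes
           and conserves fragment mass", {
    sim <- simulatePlasmid(genParams(seed = 4))
    tg <- as.data.frame(truthGenes(sim$truth))
    depths <- c(high = 200, medium = 100, low = 50)
    cov <- simulateCoverage(sim$bundle, sim$truth, depths,
                            fragLen = 30L, seed = 7)
    plus <- as.numeric(strandCoverage(cov$track, "+"))
    minus <- as.numeric(strandCoverage(cov$track, "-"))
    for (i in seq_len(nrow(tg))) {
        v <- if (tg$strand[i] == "+") plus else minus
        if (tg$tier[i] == "silent") {
            expect_lte(max(v[tg$start[i]:tg$end[i]]), 6)
        } else {
            span <- min(tg$tss[i], tg$tts[i]):max(tg$tss[i], tg$tts[i])
            expect_lt(abs(mean(v[span]) - depths[[tg$tier[i]]]),
                      0.1 * depths[[tg$tier[i]]] + 0.5)
        }
    }
    ## mass conservation without noise: planted depth equals
    ## n_fragments x fragLen minus the logged truncation
    cov0 <- simulateCoverage(sim$bundle, sim$truth, depths,
                             fragLen = 30L, noiseLambda = 0, seed = 7)
    total <- sum(as.numeric(strandCoverage(cov0$track, "+"))) +
        sum(as.numeric(strandCoverage(cov0$track, "-")))
    expect_identical(total,
                     sum(cov0$fragments$n_fragments) * 30 -
                         cov0$truncatedBases)
    expect_error(simulateCoverage(sim$bundle, sim$truth,
                                  c(high = 50, medium = 100, low = 10)),
                 "decreasing")
    expect_error(simulateCoverage(sim$bundle, sim$truth, fragLen = 10),
                 "fragLen")
})

test_that("count simulation plants the designed DEG structure", {
    sim <- simulateCounts(countDesign(seed = 21))
    tr <- as.data.frame(truthDEGs(sim$truth))
    expect_identical(sum(tr$direction == "up"), 127L)
    expect_identical(sum(tr$direction == "down"), 30L)
    expect_identical(dim(sim$counts), c(1864L, 6L))
    ## no effect -> no planted labels
    tr0 <- as.data.frame(truthDEGs(simulateCounts(
        countDesign(effectLog2fc = 0, seed = 21))$truth))
    expect_true(all(tr0$direction == "null"))
    ## NB mean identity: at many replicates the condition-2 mean of an
    ## up gene approaches 2^lfc times its condition-1 mean
    big <- simulateCounts(countDesign(nGenes = 40L, replicates = 1000L,
                                      nUp = 20L, nDown = 0L, seed = 22))
    trb <- as.data.frame(truthDEGs(big$truth))
    up <- trb$gene_id[trb$direction == "up"]
    mA <- rowMeans(big$counts[up, big$condition == "condA"])
    mB <- rowMeans(big$counts[up, big$condition == "condB"])
    keep <- mA > 20   # sampling error negligible only at decent baselines
    expect_true(all(abs(mB[keep] / mA[keep] - 4) < 0.4))
    ## determinism
    expect_identical(simulateCounts(countDesign(seed = 5))$counts,
                     simulateCounts(countDesign(seed = 5))$counts)
})
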