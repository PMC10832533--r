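test_that("step detection finds clean edges exactly and ignores flat or
           ramped tracks", {
    tr <- coverageTrack(c(rep(0, 999), rep(50, 1001), rep(0, 500)))
    expect_identical(detectTSS(tr, "+"), 1000L)
    expect_identical(detectTTS(tr, "+"), 2000L)
    expect_length(detectTSS(coverageTrack(rep(100, 400)), "+"), 0L)
    ramp <- coverageTrack(seq(0, 100, length.out = 2000))
    expect_length(detectTTS(ramp, "+"), 0L)
    ## minus strand mirrors: same signal on the minus track swaps roles
    trm <- coverageTrack(rep(0, 2500), c(rep(0, 999), rep(50, 1001),
                                         rep(0, 500)))
    expect_identical(detectTSS(trm, "-"), 2000L)
    expect_identical(detectTTS(trm, "-"), 1000L)
})

test_that("strand symmetry: reversing the genome maps TSS to TTS", {
    set.seed(9)
    v <- c(rpois(300, 0.2), rep(80, 500), rpois(400, 0.2),
           rep(30, 250), rpois(300, 0.2))
    n <- length(v)
    tr <- coverageTrack(v)
    rev_tr <- coverageTrack(rep(0, n), rev(v))
    expect_identical(sort(n - detectTSS(tr, "+") + 1L),
                     detectTSS(rev_tr, "-"))
    expect_identical(sort(n - detectTTS(tr, "+") + 1L),
                     detectTTS(rev_tr, "-"))
})

test_that("planted TSS/TTS are recovered from simulated coverage", {
    sim <- simulatePlasmid(genParams(seed = 1))
    cov <- simulateCoverage(sim$bundle, sim$truth, seed = 2)
    tss <- list(`+` = detectTSS(cov$track, "+"),
                `-` = detectTSS(cov$track, "-"))
    tts <- list(`+` = detectTTS(cov$track, "+"),
                `-` = detectTTS(cov$track, "-"))
    tg <- as.data.frame(truthGenes(sim$truth))
    ns <- tg[tg$tier != "silent", ]
    near <- function(x, set, tol)
        length(set) > 0 && min(abs(set - x)) <= tol
    tssHit <- mapply(function(t, s) near(t, tss[[s]], 5),
                     ns$tss, ns$strand)
    ttsHit <- mapply(function(t, s) near(t, tts[[s]], 10),
                     ns$tts, ns$strand)
    expect_gte(mean(tssHit), 0.9)
    expect_gte(mean(ttsHit), 0.85)
})

test_that("TU assembly joins covered gene runs and splits at gaps", {
    gr <- GenomicRanges::GRanges("ctg",
        IRanges::IRanges(c(101, 211), c(200, 310)), strand = "+")
    gr$gene_id <- c("gA", "gB")
    cont <- numeric(400)
    cont[95:315] <- 50
    track <- coverageTrack(cont, seqname = "ctg")
    tus <- assembleTUs(gr, list(`+` = 95L, `-` = integer(0)),
                       list(`+` = 315L, `-` = integer(0)), track)
    expect_length(tus, 1L)
    expect_identical(tus$gene_ids, "gA,gB")
    expect_identical(tus$tss, 95L)
    expect_identical(tus$tts, 315L)
    expect_identical(tus$utr5_len, 6L)
    ## a coverage gap splits the pair into two units
    gap <- cont
    gap[201:210] <- 0
    track2 <- coverageTrack(gap, seqname = "ctg")
    tus2 <- assembleTUs(gr, list(`+` = 95L, `-` = integer(0)),
                        list(`+` = 315L, `-` = integer(0)), track2)
    expect_length(tus2, 2L)
    ## an internal TSS also splits
    tus3 <- assembleTUs(gr, list(`+` = c(95L, 205L), `-` = integer(0)),
                        list(`+` = 315L, `-` = integer(0)), track)
    expect_length(tus3, 2L)
    ## three-gene operonic fixture comes back as one unit
    gr3 <- GenomicRanges::GRanges("ctg",
        IRanges::IRanges(c(101, 211, 321), c(200, 310, 420)),
        strand = "+")
    gr3$gene_id <- c("g1", "g2", "g3")
    op <- numeric(520)
    op[95:430] <- 60
    tus4 <- assembleTUs(gr3, list(`+` = 95L, `-` = integer(0)),
                        list(`+` = 430L, `-` = integer(0)),
                        coverageTrack(op, seqname = "ctg"))
    expect_length(tus4, 1L)
    expect_identical(tus4$n_genes, 3L)
    ## unassignable boundaries are flagged, not dropped
    tus5 <- assembleTUs(gr, list(`+` = integer(0), `-` = integer(0)),
                        list(`+` = integer(0), `-` = integer(0)), track)
    expect_true(all(tus5$flagged))
    expect_true(all(is.na(tus5$tss)))
})

test_that("promoter-anchored refinement recomputes the 5' boundary", {
    tus <- GenomicRanges::GRanges("ctg", IRanges::IRanges(1000, 1500),
                                  strand = "+")
    tus$tu_id <- "TU_001"
    tus$gene_ids <- "g1"
    tus$tss <- 1000L       # coverage TSS; start codon at 1020
    tus$utr5_len <- 20L
    tus$tts <- 1500L
    tus$utr3_len <- 0L
    tus$flagged <- FALSE
    calls <- data.frame(tu_id = "TU_001", minus10_end = 980L)
    ref <- refineUTRs(tus, calls)
    expect_identical(ref$tss, 987L)
    expect_identical(ref$utr5_len, 33L)
    expect_true(ref$refined)
    ## no promoter call: unit unchanged
    ref0 <- refineUTRs(tus, data.frame(tu_id = character(0),
                                       minus10_end = integer(0)))
    expect_identical(ref0$tss, 1000L)
    expect_false(ref0$refined)
    ## refined TSS at/after the start codon: keep coverage TSS, flag
    bad <- data.frame(tu_id = "TU_001", minus10_end = 1015L)
    refb <- refineUTRs(tus, bad)
    expect_identical(refb$tss, 1000L)
    expect_true(refb$flagged)
})

test_that("refinement beats a 5'-truncated coverage TSS on planted data", {
    sim <- simulatePlasmid(genParams(seed = 6))
    tg <- as.data.frame(truthGenes(sim$truth))
    ns <- tg[tg$tier != "silent" & tg$strand == "+", ]
    ## emulate the ~20 nt 5' truncation of coverage-derived TSS calls
    shift <- 20L
    tus <- GenomicRanges::GRanges("synthetic_plasmid",
        IRanges::IRanges(ns$tss + shift, ns$tts), strand = "+")
    tus$tu_id <- sprintf("TU_%03d", seq_len(nrow(ns)))
    tus$gene_ids <- ns$gene_id
    tus$tss <- ns$tss + shift
    tus$utr5_len <- ns$start - (ns$tss + shift)
    tus$tts <- ns$tts
    tus$utr3_len <- ns$utr3_len
    tus$flagged <- FALSE
    calls <- data.frame(tu_id = tus$tu_id, minus10_end = ns$minus10_end)
    ref <- refineUTRs(tus, calls)
    errBefore <- mean(abs((ns$tss + shift) - ns$tss))
    errAfter <- mean(abs(ref$tss - ns$tss))
    expect_lt(errAfter, errBefore)
    expect_equal(errAfter, 0)   # generator plants TSS at -10 end + 7
    expect_true(all(ref$utr5_len >= 0))
})
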