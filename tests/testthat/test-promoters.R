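## build upstream windows of width 62 with a planted promoter whose -10
## hexamer ends 6 nt before the window end (TSS convention of the
## generator)
plantWindows <- function(n, spacers, nMismatch = 0, seed = 1,
                         width = 62L) {
    set.seed(seed)
    bases <- c("A", "C", "G", "T")
    vapply(seq_len(n), function(i) {
        s <- spacers[(i - 1L) %% length(spacers) + 1L]
        prom <- strsplit(paste0("TTGACA",
                                paste(sample(bases, s, TRUE),
                                      collapse = ""),
                                "TATAAT"), "")[[1]]
        if (nMismatch > 0) {
            fixed <- c(1:6, (6 + s + 1):(6 + s + 6))
            pos <- sample(fixed, nMismatch)
            for (p in pos)
                prom[p] <- sample(setdiff(bases, prom[p]), 1)
        }
        pad <- width - length(prom) - 6L
        paste0(paste(sample(bases, pad, TRUE), collapse = ""),
               paste(prom, collapse = ""),
               paste(sample(bases, 6L, TRUE), collapse = ""))
    }, character(1))
}

test_that("upstream windows are strand-aware, edge-flagged and circular
           when asked", {
    g <- paste(rep(c("A", "C", "G", "T"), 50), collapse = "")
    seqs <- Biostrings::DNAStringSet(g)
    names(seqs) <- "ctg"
    gr <- GenomicRanges::GRanges("ctg", IRanges::IRanges(1, 10),
                                 strand = "+")
    gr$gene_id <- "g1"
    lin <- new("GenomeBundle", seq = seqs, genes = gr, circular = FALSE)
    circ <- new("GenomeBundle", seq = seqs, genes = gr, circular = TRUE)
    w <- extractUpstream(lin, 100L, "+", 62L)
    expect_identical(as.character(w[[1L]]), substr(g, 38L, 99L))
    ## minus strand: reverse complement of the downstream flank
    wm <- extractUpstream(lin, 100L, "-", 10L)
    expect_identical(
        as.character(wm[[1L]]),
        as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(substr(g, 101L, 110L)))))
    ## linear: truncated and flagged near the origin
    wt <- extractUpstream(lin, 10L, "+", 62L)
    expect_identical(nchar(as.character(wt[[1L]])), 9L)
    expect_true(S4Vectors::mcols(wt)$truncated[1L])
    ## circular: wraps the origin; equals a manual splice
    wc <- extractUpstream(circ, 10L, "+", 62L)
    expect_identical(as.character(wc[[1L]]),
                     paste0(substr(g, 200L - 52L, 200L),
                            substr(g, 1L, 9L)))
    expect_error(extractUpstream(lin, 500L, "+"), "outside")
})

test_that("EM recovers planted consensus, spacer law and placement", {
    wins <- plantWindows(30, spacers = c(rep(17, 24), 16, 16, 16,
                                         18, 18, 15),
                         nMismatch = 1, seed = 42)
    model <- fitPromoterModel(wins)
    expect_true(model@converged)
    expect_identical(plasmidtx:::pwmConsensus(model@pwm35), "TTGACA")
    expect_identical(plasmidtx:::pwmConsensus(model@pwm10), "TATAAT")
    expect_identical(names(which.max(model@spacerPrior)), "17")
    ## objective is non-decreasing across EM iterations
    expect_true(all(diff(model@objective) > -1e-9))
    ## -10 placement: the planted -10 ends 6 nt before the window end
    hits <- lapply(wins, scanPromoter, model = model)
    pos10end <- vapply(hits, function(h) h$pos10 + 5L, integer(1))
    expect_gte(mean(abs(pos10end - 56L) <= 1L), 0.9)
})

test_that("EM degenerates gracefully: identical input gives point masses,
           random input is flagged uninformative", {
    ## 30 copies + pseudocount 0.5: max column probability 30.5/32
    same <- rep(plantWindows(1, 17, seed = 5), 30)
    m <- fitPromoterModel(same)
    expect_true(all(apply(m@pwm35, 2, max) > 0.9))
    expect_true(all(apply(m@pwm10, 2, max) > 0.9))
    expect_gt(max(m@spacerPrior), 0.9)
    set.seed(6)
    rnd <- vapply(1:50, function(i)
        paste(sample(c("A", "C", "G", "T"), 62, TRUE), collapse = ""),
        character(1))
    mr <- fitPromoterModel(rnd)
    expect_false(mr@informative)
    expect_error(fitPromoterModel(rnd[1:5]), "at least 10")
})

test_that("scanPromoter maximises the planted placement and breaks ties
           leftmost", {
    wins <- plantWindows(30, 17, seed = 7)
    model <- fitPromoterModel(wins)
    exact <- paste0(strrep("G", 10), "TTGACA", strrep("C", 17), "TATAAT",
                    strrep("G", 10))
    hit <- scanPromoter(exact, model)
    expect_identical(hit$spacer_len, 17L)
    expect_identical(hit$minus35, "TTGACA")
    expect_identical(hit$minus10, "TATAAT")
    expect_identical(hit$pos35, 11L)
    ## two identical placements: the leftmost is reported
    double <- paste0("GG", "TTGACA", strrep("C", 17), "TATAAT",
                     strrep("G", 4), "TTGACA", strrep("C", 17), "TATAAT",
                     "GG")
    hit2 <- scanPromoter(double, model)
    expect_identical(hit2$pos35, 3L)
    ## below-threshold or too-short input gives no call
    expect_null(scanPromoter(strrep("A", 62), model))
    expect_null(scanPromoter("ACGT", model))
    ## degenerate promoters (2 mismatches) are still placed within 1 nt
    deg <- plantWindows(50, 17, nMismatch = 2, seed = 8)
    hits <- lapply(deg, scanPromoter, model = model, threshold = 0)
    ok <- vapply(hits, function(h)
        !is.null(h) && abs(h$pos10 + 5L - 56L) <= 1L, logical(1))
    expect_gte(mean(ok), 0.8)
})

test_that("spacer histograms and sequence-logo arithmetic are exact", {
    calls <- data.frame(
        tier = c(rep("high", 5), rep("medium", 4)),
        spacer_len = c(17, 17, 17, 16, 18, 16, 16, 17, 15))
    st <- spacerStats(calls)
    expect_identical(unname(st$mode["high"]), 17L)
    expect_identical(unname(st$mode["medium"]), 16L)
    expect_identical(unname(st$counts["high", "17"]), 3L)
    expect_error(spacerStats(calls[0, ]), "no promoter calls")
    lg <- logoMatrix(c("AAC", "AGC", "ATC"))
    expect_equal(lg$ic[1L], 2)
    expect_equal(lg$ic[3L], 2)
    expect_equal(logoMatrix(c("AA", "CA", "GA", "TA"))$ic[1L], 0)
    expect_equal(logoMatrix(c("AT", "CT"))$ic[1L], 1)
    expect_error(logoMatrix(c("AAA", "AA")), "equal length")
})
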