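test_that("codon counting validates frame, start and internal stops", {
    x <- codonCounts("ATGGCCTAA")
    expect_identical(unname(x["ATG"]), 1L)
    expect_identical(unname(x["GCC"]), 1L)
    expect_identical(sum(x), 2L)   # terminal stop excluded
    expect_error(codonCounts("ATGGCCT"), "divisible by 3")
    expect_error(codonCounts("CCCGCCTAA"), "start codon")
    expect_error(codonCounts("ATGTAAGCCTAA"), "internal stop")
    ## concatenation additivity for in-frame fragments
    a <- "ATGGCCGTT"; b <- "ATGCTGCTG"
    expect_identical(codonCounts(a) + codonCounts(b),
                     codonCounts(paste0(a, b)))
})

test_that("RSCU spans its endpoints: 0 absent, 1 unbiased, |F| exclusive", {
    ## alanine family (GCT/GCC/GCA/GCG): all counts on GCC
    only <- codonCounts(paste0("ATG", strrep("GCC", 8), "TAA"))
    r <- rscu(only)
    expect_equal(unname(r["GCC"]), 4)
    expect_equal(unname(r["GCT"]), 0)
    ## uniform usage: all 1
    unif <- codonCounts(paste0("ATG", "GCT", "GCC", "GCA", "GCG", "TAA"))
    expect_equal(unname(rscu(unif)[c("GCT", "GCC", "GCA", "GCG")]),
                 rep(1, 4))
    ## six-codon family used exclusively: RSCU 6
    leu <- codonCounts(paste0("ATG", strrep("CTG", 6), "TAA"))
    expect_equal(unname(rscu(leu)["CTG"]), 6)
    ## family-sum invariant on random seeded profiles
    set.seed(13)
    fams <- split(names(Biostrings::GENETIC_CODE),
                  Biostrings::GENETIC_CODE)
    fams <- fams[names(fams) != "*" & lengths(fams) > 1]
    for (rep in 1:10) {
        cds <- randomCdsFixture(300, gc = runif(1, 0.3, 0.7))
        r <- rscu(codonCounts(cds))
        for (fam in fams) {
            if (all(is.na(r[fam]))) next
            expect_equal(unname(sum(r[fam])), length(fam))
        }
    }
})

test_that("reference weights: family maxima get 1, ties share it, absent
           codons are floored", {
    counts <- codonCounts(paste0("ATG", strrep("GCC", 3), "GCA", "TAA"))
    w <- referenceWeights(counts)
    expect_equal(unname(w["GCC"]), 1)
    expect_equal(unname(w["GCA"]), 1 / 3)
    expect_equal(unname(w["GCT"]), 0.01)
    tie <- codonCounts(paste0("ATG", "GGC", "GGC", "GGA", "GGA", "TAA"))
    wt <- referenceWeights(tie)
    expect_equal(unname(wt["GGC"]), 1)
    expect_equal(unname(wt["GGA"]), 1)
})

test_that("CAI is a geometric mean with the documented endpoints", {
    set.seed(14)
    ref <- vapply(1:20, function(i) randomCdsFixture(150, 0.6),
                  character(1))
    w <- referenceWeights(ref)
    fams <- plasmidtx:::MULTI_FAMILIES
    optimal <- vapply(fams, function(f) f[which.max(w[f])], character(1))
    gene <- paste0("ATG", paste(rep(optimal, 3), collapse = ""), "TAA")
    expect_equal(cai(gene, w), 1.0)
    expect_equal(cbi(gene, optimal), 1.0)
    ## two-codon arithmetic: sqrt(1 * 0.25) = 0.5
    w2 <- w; w2[] <- 1; w2["GCC"] <- 1; w2["TTC"] <- 0.25
    expect_equal(cai(codonCounts("ATGGCCTTCTAA"), w2), 0.5)
    ## all weights 0.5 -> CAI 0.5
    w3 <- w; w3[] <- 0.5
    expect_equal(cai(codonCounts(randomCdsFixture(50)), w3), 0.5)
    ## length invariance under repeat concatenation
    cds <- randomCdsFixture(60, 0.5)
    core <- substr(cds, 1, nchar(cds) - 3)   # drop the stop
    rep3 <- paste0(core, substr(core, 4, nchar(core)),
                   substr(core, 4, nchar(core)), "TAA")
    expect_equal(cai(cds, w), cai(rep3, w), tolerance = 1e-12)
})

test_that("CBI hits 0 for uniform and balanced-optimal usage", {
    unif <- codonCounts(paste0("ATG", "GCT", "GCC", "GCA", "GCG", "TAA"))
    expect_equal(cbi(unif, "GCC"), 0)
    ## two-codon family, half optimal: N_opt == N_rand
    half <- codonCounts(paste0("ATG", "GAA", "GAG", "TAA"))
    expect_equal(cbi(half, "GAG"), 0)
})

test_that("base composition matches a direct tally and GC3 = C3 + G3", {
    bc <- baseComposition("ATGGCCTAA")
    expect_equal(unname(bc["gc3"]), 1.0)   # ATG, GCC -> G, C
    low <- baseComposition(paste0("ATG", strrep("ATT", 10), "TAA"))
    expect_lt(unname(low["gc3"]), 0.1)
    set.seed(15)
    for (rep in 1:5) {
        cds <- randomCdsFixture(120, runif(1, 0.3, 0.7))
        bc <- baseComposition(cds)
        expect_equal(unname(bc["gc3"]), unname(bc["c3"] + bc["g3"]))
        ## brute-force third-position tally (stop codon excluded)
        body <- substr(cds, 1, nchar(cds) - 3)
        thirds <- substr(strsplit(body, "(?<=...)", perl = TRUE)[[1]],
                         3, 3)
        expect_equal(unname(bc["g3"]), mean(thirds == "G"))
        chars <- strsplit(body, "")[[1]]
        expect_equal(unname(bc["gc"]), mean(chars %in% c("G", "C")))
    }
})

test_that("hydropathy and aromaticity follow the residue tables", {
    expect_equal(unname(gravyAromo("A")["gravy"]), 1.8)
    expect_equal(unname(gravyAromo("FYW")["aromo"]), 1.0)
    expect_equal(unname(gravyAromo("AIV")["aromo"]), 0)
    expect_equal(unname(gravyAromo("AI")["gravy"]), (1.8 + 4.5) / 2)
    expect_error(gravyAromo(""), "empty")
    expect_error(gravyAromo("ABZ"), "non-standard")
})

test_that("anticodon decoding is strict reverse complement", {
    expect_identical(trnaToCodons("UGC"), "GCA")
    expect_identical(trnaToCodons("CAU"), "ATG")
    expect_identical(trnaToCodons(c("UGC", "UGC")), "GCA")
    expect_identical(sort(trnaToCodons(c("UCU", "CCU"))),
                     sort(c("AGA", "AGG")))
    expect_error(trnaToCodons("UG"), "triplets")
})

test_that("rare codons are the <10% family fraction set", {
    counts <- codonCounts(paste0("ATG", strrep("GAA", 19), "GAG", "TAA"))
    expect_identical(rareCodons(counts), "GAG")
    unif <- codonCounts(paste0("ATG", "GCT", "GCC", "GCA", "GCG", "TAA"))
    expect_length(rareCodons(unif), 0L)
    expect_length(rareCodons(counts, threshold = 0), 0L)
})

test_that("codon chi-squared equals the direct-formula oracle", {
    same <- codonCounts(randomCdsFixture(200, 0.5))
    res <- rscuChisq(same, same)
    expect_equal(res$statistic, 0)
    expect_equal(res$p.value, 1)
    ## constructed 2x2: (10,0 / 0,10) -> chi2 = 20
    a <- stats::setNames(c(10, 0), c("GCT", "GCC"))
    b <- stats::setNames(c(0, 10), c("GCT", "GCC"))
    expect_equal(rscuChisq(a, b)$statistic, 20)
    ## 100 random seeded profile pairs match the oracle
    set.seed(16)
    for (rep in 1:100) {
        x <- codonCounts(randomCdsFixture(sample(50:200, 1),
                                          runif(1, 0.3, 0.7)))
        y <- codonCounts(randomCdsFixture(sample(50:200, 1),
                                          runif(1, 0.3, 0.7)))
        got <- rscuChisq(x, y)
        want <- chisqOracle(x, y)
        expect_equal(got$statistic, want$statistic)
        expect_equal(got$df, want$df)
        expect_equal(got$p.value, want$p.value)
    }
})

test_that("tRNA-pool compatibility separates enriched from depleted
           gene sets", {
    r <- c(GCA = 2, GGA = 1)
    prof <- stats::setNames(rep(NA_real_,
                                length(plasmidtx:::FAMILY_CODONS)),
                            plasmidtx:::FAMILY_CODONS)
    prof[names(r)] <- r
    tc <- trnaCompatibility(list(set1 = prof), c("GCA", "GGA"))
    expect_equal(unname(tc$mean["set1"]), 1.5)
    expect_error(trnaCompatibility(list(s = prof), character(0)),
                 "empty")
    ## constructed sequences: a set enriched for the tRNA codons scores
    ## higher than one avoiding them
    trna <- c("GCA", "GGA")
    rich <- codonCounts(paste0("ATG", strrep("GCAGGA", 10), "TAA"))
    poor <- codonCounts(paste0("ATG", strrep("GCCGGC", 10), "TAA"))
    tc2 <- trnaCompatibility(list(rich = rich, poor = poor), trna)
    expect_gt(tc2$mean["rich"], tc2$mean["poor"])
})
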