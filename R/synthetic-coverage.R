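## Strand-specific coverage simulation over planted transcripts.

#' Simulate strand-specific per-base coverage
#'
#' Places sequencing fragments uniformly over each planted transcript
#' (`[TSS, TTS]` from the truth set) at a mean depth set by the gene's
#' expression tier, clipping fragments at transcript boundaries so that
#' coverage is uniform across the transcript with sharp steps at both ends
#' (the profile from which transcript boundaries are read). A Poisson
#' background (`noiseLambda` per base, both strands) models stray reads
#' outside transcripts. Output is a pure function of the inputs and seed.
#'
#' @param bundle a [GenomeBundle-class].
#' @param truth the matching [TruthSet-class].
#' @param depthPerTier named mean depths `c(high, medium, low)`; must be
#'   strictly decreasing.
#' @param fragLen fragment length in nt (>= 20).
#' @param noiseLambda Poisson mean of the per-base background depth;
#'   `0` disables noise.
#' @param seed integer RNG seed.
#' @return a list: `track` (a [CoverageTrack-class]), `fragments`
#'   (a `DataFrame` of fragment counts per gene, the per-gene read counts
#'   implied by the simulation) and `truncatedBases` (total fragment bases
#'   clipped at transcript boundaries, for the coverage-mass ledger).
#' @examples
#' sim <- simulatePlasmid(genParams(seed = 1))
#' cov <- simulateCoverage(sim$bundle, sim$truth, seed = 1)
#' cov$track
#' @export
simulateCoverage <- function(bundle, truth,
                             depthPerTier = c(high = 200, medium = 100,
                                              low = 50),
                             fragLen = 30L, noiseLambda = 0.2, seed = 1L) {
    stopifnot(is(bundle, "GenomeBundle"), is(truth, "TruthSet"))
    if (!all(diff(depthPerTier[c("high", "medium", "low")]) < 0))
        stop("depthPerTier must be strictly decreasing high -> low")
    if (fragLen < 20L)
        stop("fragLen must be >= 20 nt")
    L <- as.integer(fragLen)
    glen <- Biostrings::width(genomeSeq(bundle))[1L]
    tg <- as.data.frame(truthGenes(truth))

    withSeed(seed, {
        frags <- list(`+` = list(), `-` = list())
        nFrag <- integer(nrow(tg))
        truncated <- 0L
        shortWarned <- FALSE
        for (i in seq_len(nrow(tg))) {
            if (tg$tier[i] == "silent" || is.na(tg$tss[i])) next
            left <- min(tg$tss[i], tg$tts[i])
            right <- max(tg$tss[i], tg$tts[i])
            txlen <- right - left + 1L
            if (txlen < L && !shortWarned) {
                warning("transcript(s) shorter than fragLen: ",
                        "fragments truncated to the transcript")
                shortWarned <- TRUE
            }
            depth <- depthPerTier[[tg$tier[i]]]
            n <- as.integer(round(depth * (txlen + L - 1) / L))
            nFrag[i] <- n
            if (n == 0L) next
            starts <- sample.int(txlen + L - 1L, n, replace = TRUE) +
                left - L
            ends <- pmin(starts + L - 1L, right)
            starts <- pmax(starts, left)
            truncated <- truncated + n * L - sum(ends - starts + 1L)
            frags[[tg$strand[i]]][[length(frags[[tg$strand[i]]]) + 1L]] <-
                IRanges::IRanges(starts, ends)
        }
        covOf <- function(irl) {
            ir <- if (length(irl)) do.call(c, irl) else IRanges::IRanges()
            as.numeric(IRanges::coverage(ir, width = glen))
        }
        plus <- covOf(frags[["+"]])
        minus <- covOf(frags[["-"]])
        if (noiseLambda > 0) {
            plus <- plus + stats::rpois(glen, noiseLambda)
            minus <- minus + stats::rpois(glen, noiseLambda)
        }
        track <- new("CoverageTrack",
                     plus = S4Vectors::Rle(plus),
                     minus = S4Vectors::Rle(minus),
                     seqname = names(genomeSeq(bundle))[1L])
        list(track = track,
             fragments = S4Vectors::DataFrame(gene_id = tg$gene_id,
                                              n_fragments = nFrag),
             truncatedBases = truncated)
    })
}

#' Construct a CoverageTrack from plain vectors
#'
#' @param plus,minus numeric per-base depth vectors of equal length.
#' @param seqname contig name.
#' @return a [CoverageTrack-class].
#' @examples
#' coverageTrack(c(0, 0, 5, 5), c(0, 0, 0, 0))
#' @export
coverageTrack <- function(plus, minus = numeric(length(plus)),
                          seqname = "contig") {
    new("CoverageTrack", plus = S4Vectors::Rle(as.numeric(plus)),
        minus = S4Vectors::Rle(as.numeric(minus)), seqname = seqname)
}
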