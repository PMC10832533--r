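## Bipartite -35/spacer/-10 promoter model: constrained EM fit anchored on
## the canonical bifidobacterial consensus, scanning, and conservation
## statistics.

BASE_IDX <- stats::setNames(1:4, DNA_BASES_CHR)

#' Extract strand-aware upstream windows
#'
#' Returns the `width` nt ending 1 nt before each anchor (a TSS or start
#' codon), reverse-complemented for minus-strand anchors. Windows are
#' truncated at contig edges (and flagged) unless the bundle is circular,
#' in which case they wrap the origin.
#'
#' @param bundle a [GenomeBundle-class].
#' @param anchors integer genomic positions (1-based).
#' @param strand character vector of `"+"`/`"-"`, recycled to
#'   `length(anchors)`.
#' @param width window width in nt (> 0).
#' @return a [Biostrings::DNAStringSet] with mcols `anchor`, `strand`,
#'   `win_start`, `win_end` (genomic span of the window) and `truncated`.
#' @examples
#' sim <- simulatePlasmid(genParams(seed = 1))
#' extractUpstream(sim$bundle, anchors = 500L, strand = "+", width = 62)
#' @export
extractUpstream <- function(bundle, anchors, strand = "+", width = 62L) {
    stopifnot(is(bundle, "GenomeBundle"), width > 0)
    genome <- genomeSeq(bundle)[[1L]]
    glen <- length(genome)
    strand <- rep_len(strand, length(anchors))
    if (any(anchors < 1L | anchors > glen))
        stop("anchor outside genome")
    seqs <- character(length(anchors))
    winStart <- winEnd <- integer(length(anchors))
    trunc <- logical(length(anchors))
    for (i in seq_along(anchors)) {
        a <- anchors[i]
        if (strand[i] == "+") {
            lo <- a - width; hi <- a - 1L
            if (lo < 1L && bundle@circular) {
                s <- paste0(as.character(
                        Biostrings::subseq(genome, glen + lo, glen)),
                    as.character(Biostrings::subseq(genome, 1L,
                                                    max(hi, 0L))))
                winStart[i] <- glen + lo
            } else {
                if (lo < 1L) { trunc[i] <- TRUE; lo <- 1L }
                s <- if (hi >= lo)
                    as.character(Biostrings::subseq(genome, lo, hi)) else ""
                winStart[i] <- lo
            }
            winEnd[i] <- hi
            seqs[i] <- s
        } else {
            lo <- a + 1L; hi <- a + width
            if (hi > glen && bundle@circular) {
                s <- paste0(as.character(
                        Biostrings::subseq(genome, lo, glen)),
                    as.character(Biostrings::subseq(genome, 1L,
                                                    hi - glen)))
                winEnd[i] <- hi - glen
            } else {
                if (hi > glen) { trunc[i] <- TRUE; hi <- glen }
                s <- if (hi >= lo)
                    as.character(Biostrings::subseq(genome, lo, hi)) else ""
                winEnd[i] <- hi
            }
            winStart[i] <- lo
            seqs[i] <- revcompChr(s)
        }
    }
    out <- Biostrings::DNAStringSet(seqs)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        anchor = anchors, strand = strand,
        win_start = winStart, win_end = winEnd, truncated = trunc)
    out
}

## PWM from a consensus string: `conc` probability on the consensus base
consensusPwm <- function(consensus, conc = 0.7) {
    chars <- strsplit(consensus, "")[[1]]
    m <- matrix((1 - conc) / 3, nrow = 4L, ncol = length(chars),
                dimnames = list(DNA_BASES_CHR, NULL))
    for (j in seq_along(chars)) m[chars[j], j] <- conc
    m
}

## best (pos35, spacer) placement of the bipartite model on one encoded
## sequence; returns c(pos35, spacer, score) or NULL if nothing fits
bestPlacement <- function(enc, lw35, lw10, logPrior) {
    L <- length(enc)
    best <- NULL
    for (s in SPACER_RANGE) {
        maxPos <- L - (12L + s) + 1L
        if (maxPos < 1L) next
        for (pos in seq_len(maxPos)) {
            i35 <- pos:(pos + 5L)
            i10 <- (pos + 6L + s):(pos + 11L + s)
            sc <- sum(lw35[cbind(enc[i35], 1:6)]) +
                sum(lw10[cbind(enc[i10], 1:6)]) +
                logPrior[as.character(s)]
            if (is.null(best) || sc > best[3L] + 1e-12)
                best <- c(pos, s, sc)
        }
    }
    best
}

#' Fit the bipartite promoter model by constrained EM
#'
#' Two-block expectation-maximisation over a -35 hexamer, a 15-19 nt
#' spacer and a -10 hexamer, seeded from the canonical consensus
#' (TTGACA / TATAAT). The E step takes, for every sequence, the
#' best-scoring placement (log-odds against the background plus the log
#' spacer prior; ties resolved to the most upstream position, then the
#' shorter spacer); the M step rebuilds both position-weight matrices
#' (pseudocount 0.5) and the spacer prior from the placements. Iteration
#' stops when no PWM entry moves by more than `tol`, or at `maxIter`
#' (the model is then returned with `converged = FALSE`). Deterministic
#' given its inputs.
#'
#' @param seqs upstream windows, a [Biostrings::DNAStringSet] or
#'   character vector; at least 10 sequences of at least 27 nt.
#' @param initConsensus length-2 character vector, the -35 and -10
#'   seeding consensus hexamers.
#' @param maxIter,tol EM iteration cap and PWM convergence tolerance.
#' @param pseudocount added per PWM cell and spacer class in the M step.
#' @return a [PromoterModel-class]; `informative` is `FALSE` when the
#'   mean per-column information content of the fitted PWMs is below
#'   0.5 bits (e.g. on random sequence).
#' @examples
#' sim <- simulatePlasmid(genParams(seed = 1))
#' tg <- truthGenes(sim$truth)
#' up <- extractUpstream(sim$bundle, tg$tss[tg$tier == "high"],
#'                       tg$strand[tg$tier == "high"])
#' fitPromoterModel(up)
#' @export
fitPromoterModel <- function(seqs, initConsensus = c("TTGACA", "TATAAT"),
                             maxIter = 100L, tol = 1e-4,
                             pseudocount = 0.5) {
    seqs <- as.character(seqs)
    if (length(seqs) < 10L)
        stop("need at least 10 sequences to fit the promoter model")
    if (any(nchar(seqs) < 6L + 15L + 6L))
        stop("every sequence must be at least 27 nt")
    encs <- lapply(strsplit(seqs, ""), function(ch) BASE_IDX[ch])
    allBases <- unlist(encs)
    background <- (tabulate(allBases, 4L) + 1) / (length(allBases) + 4)
    names(background) <- DNA_BASES_CHR

    pwm35 <- consensusPwm(initConsensus[1L])
    pwm10 <- consensusPwm(initConsensus[2L])
    prior <- stats::setNames(rep(1 / 5, 5L), as.character(SPACER_RANGE))
    objective <- numeric(0)
    converged <- FALSE
    iter <- 0L
    placements <- NULL
    while (iter < maxIter) {
        iter <- iter + 1L
        lw35 <- log2(pwm35 / background)
        lw10 <- log2(pwm10 / background)
        logPrior <- log2(prior)
        placements <- lapply(encs, bestPlacement, lw35 = lw35,
                             lw10 = lw10, logPrior = logPrior)
        objective <- c(objective,
                       sum(vapply(placements, `[`, numeric(1), 3L)))
        c35 <- matrix(pseudocount, 4L, 6L,
                      dimnames = list(DNA_BASES_CHR, NULL))
        c10 <- c35
        sCount <- stats::setNames(rep(pseudocount, 5L),
                                  as.character(SPACER_RANGE))
        for (k in seq_along(encs)) {
            pl <- placements[[k]]
            enc <- encs[[k]]
            pos <- pl[1L]; s <- pl[2L]
            for (j in 1:6) {
                c35[enc[pos + j - 1L], j] <- c35[enc[pos + j - 1L], j] + 1
                c10[enc[pos + 5L + s + j], j] <-
                    c10[enc[pos + 5L + s + j], j] + 1
            }
            sCount[as.character(s)] <- sCount[as.character(s)] + 1
        }
        new35 <- sweep(c35, 2L, colSums(c35), "/")
        new10 <- sweep(c10, 2L, colSums(c10), "/")
        newPrior <- sCount / sum(sCount)
        delta <- max(abs(new35 - pwm35), abs(new10 - pwm10))
        pwm35 <- new35; pwm10 <- new10; prior <- newPrior
        if (delta < tol) { converged <- TRUE; break }
    }
    ic <- function(pwm) mean(2 + colSums(ifelse(pwm > 0,
                                                pwm * log2(pwm), 0)))
    informative <- mean(c(ic(pwm35), ic(pwm10))) >= 0.5
    if (!converged)
        warning("promoter EM did not converge in ", maxIter,
                " iterations; returning the last model")
    new("PromoterModel", pwm35 = pwm35, pwm10 = pwm10,
        spacerPrior = prior, background = background,
        converged = converged, iterations = iter,
        objective = objective, informative = informative)
}

#' Scan one sequence with a fitted promoter model
#'
#' Reports the placement maximising the summed hexamer log-odds plus the
#' log spacer prior; ties go to the most upstream (leftmost) placement.
#' Returns `NULL` when the best score falls below `threshold` or the
#' sequence is shorter than the minimal -35/spacer/-10 layout.
#'
#' @param seq a single character string or `DNAString` (an upstream
#'   window, 5' to 3').
#' @param model a fitted [PromoterModel-class].
#' @param threshold minimum score in bits.
#' @return `NULL`, or a one-row `data.frame` with `pos35`, `minus35`,
#'   `spacer_len`, `pos10`, `minus10`, `score` (positions 1-based within
#'   `seq`).
#' @export
scanPromoter <- function(seq, model, threshold = 4) {
    stopifnot(is(model, "PromoterModel"))
    seq <- as.character(seq)
    if (nchar(seq) < 27L) return(NULL)
    enc <- BASE_IDX[strsplit(seq, "")[[1]]]
    pl <- bestPlacement(enc, log2(model@pwm35 / model@background),
                        log2(model@pwm10 / model@background),
                        log2(model@spacerPrior))
    if (is.null(pl) || pl[3L] < threshold) return(NULL)
    pos <- as.integer(pl[1L]); s <- as.integer(pl[2L])
    data.frame(pos35 = pos, minus35 = substr(seq, pos, pos + 5L),
               spacer_len = s, pos10 = pos + 6L + s,
               minus10 = substr(seq, pos + 6L + s, pos + 11L + s),
               score = pl[3L])
}

#' Call promoters for transcriptional units
#'
#' Extracts the `width` nt upstream of each unit's TSS, scans it with the
#' model and maps the placement back to genomic coordinates.
#'
#' @param bundle a [GenomeBundle-class].
#' @param tus TU `GRanges` from [assembleTUs()] (needs mcols `tu_id`,
#'   `tss`; `tier` is carried through when present).
#' @param model a fitted [PromoterModel-class].
#' @param width upstream window width in nt.
#' @param threshold minimum promoter score in bits.
#' @return a [S4Vectors::DataFrame] with one row per called promoter:
#'   `tu_id`, `tier`, `minus35`, `spacer_len`, `minus10`, `score`,
#'   `minus10_end` (genomic 3' end of the -10 in reading orientation).
#' @export
callPromoters <- function(bundle, tus, model, width = 62L, threshold = 4) {
    rows <- list()
    for (i in seq_along(tus)) {
        if (is.na(tus$tss[i])) next
        st <- as.character(BiocGenerics::strand(tus))[i]
        win <- extractUpstream(bundle, tus$tss[i], st, width)
        hit <- scanPromoter(win[[1L]], model, threshold)
        if (is.null(hit)) next
        m10EndLocal <- hit$pos10 + 5L
        minus10End <- if (st == "+")
            S4Vectors::mcols(win)$win_start[1L] + m10EndLocal - 1L
        else S4Vectors::mcols(win)$win_end[1L] - m10EndLocal + 1L
        rows[[length(rows) + 1L]] <- data.frame(
            tu_id = tus$tu_id[i],
            tier = if (!is.null(tus$tier)) tus$tier[i] else NA_character_,
            minus35 = hit$minus35, spacer_len = hit$spacer_len,
            minus10 = hit$minus10, score = hit$score,
            minus10_end = minus10End, stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(S4Vectors::DataFrame(tu_id = character(0),
                                    tier = character(0),
                                    minus35 = character(0),
                                    spacer_len = integer(0),
                                    minus10 = character(0),
                                    score = numeric(0),
                                    minus10_end = integer(0)))
    S4Vectors::DataFrame(do.call(rbind, rows))
}

#' Spacer-length histogram by expression tier
#'
#' @param calls promoter calls (from [callPromoters()] or any table with
#'   `spacer_len` and `tier` columns).
#' @return a list: `counts` (tiers x spacer lengths 15-19) and `mode`
#'   (named modal spacer per tier; ties -> shorter spacer).
#' @export
spacerStats <- function(calls) {
    calls <- as.data.frame(calls)
    if (!nrow(calls))
        stop("no promoter calls to summarise")
    tiers <- unique(as.character(calls$tier))
    counts <- matrix(0L, nrow = length(tiers), ncol = 5L,
                     dimnames = list(tiers, as.character(SPACER_RANGE)))
    for (t in tiers) {
        tab <- table(factor(calls$spacer_len[calls$tier == t],
                            levels = SPACER_RANGE))
        counts[t, ] <- as.integer(tab)
    }
    mode <- apply(counts, 1L, function(x) SPACER_RANGE[which.max(x)])
    list(counts = counts, mode = mode)
}

#' Per-column information content of aligned sequences
#'
#' `IC_j = 2 + sum_b f_bj log2 f_bj` bits (0 log 0 taken as 0), without
#' small-sample correction, plus the base-frequency matrix (the numbers
#' behind a sequence logo).
#'
#' @param seqs equal-length aligned sequences (character or
#'   `DNAStringSet`).
#' @return a list: `freq` (4 x L base-frequency matrix, rows A,C,G,T) and
#'   `ic` (numeric length L, bits).
#' @examples
#' logoMatrix(c("TATAAT", "TATACT", "TATAAT"))$ic
#' @export
logoMatrix <- function(seqs) {
    seqs <- as.character(seqs)
    L <- unique(nchar(seqs))
    if (length(L) != 1L)
        stop("sequences must be of equal length")
    chars <- do.call(rbind, strsplit(seqs, ""))
    freq <- vapply(seq_len(L), function(j) {
        tabulate(BASE_IDX[chars[, j]], 4L) / nrow(chars)
    }, numeric(4L))
    rownames(freq) <- DNA_BASES_CHR
    ic <- 2 + colSums(ifelse(freq > 0, freq * log2(freq), 0))
    list(freq = freq, ic = ic)
}
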