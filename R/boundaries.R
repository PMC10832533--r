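## Transcript boundary mapping from strand-specific coverage: step
## detection for TSS/TTS, transcriptional-unit assembly, UTR refinement.

#' Step-detection parameters
#'
#' @param minDepth minimum windowed median depth for a step call.
#' @param ratio required fold change of the windowed median over the local
#'   flank median (> 1).
#' @param window median window in nt (>= 1).
#' @param flank flank length in nt for the local background median.
#' @return a named list of validated parameters.
#' @examples
#' stepParams(minDepth = 20)
#' @export
stepParams <- function(minDepth = 10, ratio = 3.0, window = 5L,
                       flank = 50L) {
    if (ratio <= 1) stop("ratio must be > 1")
    if (window < 1L) stop("window must be >= 1")
    list(minDepth = minDepth, ratio = ratio, window = as.integer(window),
         flank = as.integer(flank))
}

## Rising-edge detector on a numeric vector, scanning left to right.
## A candidate is a position i whose windowed median over [i, i+window)
## reaches max(minDepth, ratio * median over the upstream flank). Runs of
## candidates closer than `window` are merged; within a run the reported
## position is the first base whose own depth clears the threshold (the
## step onset), falling back to the highest-step candidate.
risingEdges <- function(cov, p) {
    n <- length(cov)
    w <- p$window
    if (n < w + 1L) return(integer(0))
    medIn <- vapply(seq_len(n - w + 1L),
                    function(i) stats::median(cov[i:(i + w - 1L)]),
                    numeric(1))
    if (n < p$flank + w + 1L) return(integer(0))
    cand <- integer(0); thr <- numeric(0); step <- numeric(0)
    ## positions without a full upstream flank are not callable
    for (i in (p$flank + 1L):(n - w + 1L)) {
        lo <- i - p$flank
        medOut <- stats::median(cov[lo:(i - 1L)])
        t <- max(p$minDepth, p$ratio * medOut)
        if (medIn[i] >= t) {
            cand <- c(cand, i)
            thr <- c(thr, t)
            step <- c(step, medIn[i] / max(medOut, 0.5))
        }
    }
    if (!length(cand)) return(integer(0))
    runs <- cumsum(c(TRUE, diff(cand) > w))
    out <- integer(max(runs))
    for (r in seq_len(max(runs))) {
        idx <- which(runs == r)
        onset <- idx[which(cov[cand[idx]] >= thr[idx])]
        out[r] <- if (length(onset)) cand[onset[1L]] else
            cand[idx[which.max(step[idx])]]
    }
    out
}

#' Detect transcription start / termination sites from coverage
#'
#' A TSS is the first transcribed base, read as a coverage rise in the
#' strand's reading direction; a TTS is the last transcribed base, read as
#' the matching drop. On the minus strand the scan runs right to left, so
#' the two calls are exact mirror images (reverse-complement symmetry).
#'
#' @param track a [CoverageTrack-class].
#' @param strand `"+"` or `"-"`.
#' @param p step-detection parameters from [stepParams()].
#' @return sorted integer vector of 1-based genomic positions (possibly
#'   empty).
#' @examples
#' tr <- coverageTrack(c(rep(0, 99), rep(50, 101)))
#' detectTSS(tr, "+")
#' detectTTS(tr, "+")
#' @export
detectTSS <- function(track, strand = c("+", "-"), p = stepParams()) {
    strand <- match.arg(strand)
    cov <- as.numeric(strandCoverage(track, strand))
    if (strand == "+") {
        sort(risingEdges(cov, p))
    } else {
        n <- length(cov)
        sort(n - risingEdges(rev(cov), p) + 1L)
    }
}

#' @rdname detectTSS
#' @export
detectTTS <- function(track, strand = c("+", "-"), p = stepParams()) {
    strand <- match.arg(strand)
    cov <- as.numeric(strandCoverage(track, strand))
    n <- length(cov)
    if (strand == "+") {
        sort(n - risingEdges(rev(cov), p) + 1L)
    } else {
        sort(risingEdges(cov, p))
    }
}

#' Assemble transcriptional units from genes, boundaries and coverage
#'
#' Joins consecutive same-strand genes into one transcriptional unit when
#' the inter-gene coverage never falls below `joinRatio` times the smaller
#' of the two flanking genes' mean depths and no detected TSS lies between
#' them. Each unit is then assigned the nearest upstream TSS (within
#' `maxUpstream` nt of its first start codon) and the nearest downstream
#' TTS (within `maxDownstream` nt of its last stop codon); units whose
#' boundaries cannot be assigned are emitted with `NA` boundaries and
#' `flagged = TRUE`.
#'
#' @param genes a [GenomicRanges::GRanges] of (expressed) genes with mcols
#'   `gene_id` and optionally `tier`.
#' @param tssList,ttsList positions from [detectTSS()] / [detectTTS()]
#'   for both strands (named list `list("+" = ..., "-" = ...)`).
#' @param track the [CoverageTrack-class] the boundaries came from.
#' @param joinRatio inter-gene depth floor as a fraction of the flanking
#'   gene means.
#' @param maxUpstream,maxDownstream search limits in nt for boundary
#'   assignment.
#' @return a [GenomicRanges::GRanges], one range per unit spanning TSS to
#'   TTS where assigned (gene span otherwise), with mcols `tu_id`,
#'   `gene_ids` (comma-separated, in reading order), `n_genes`, `tss`,
#'   `tts`, `utr5_len`, `utr3_len`, `tier` (highest member tier) and
#'   `flagged`.
#' @export
assembleTUs <- function(genes, tssList, ttsList, track,
                        joinRatio = 0.25, maxUpstream = 300L,
                        maxDownstream = 300L) {
    stopifnot(is(genes, "GRanges"), is(track, "CoverageTrack"))
    if (any(BiocGenerics::strand(genes) == "*"))
        stop("genes must be strand-annotated")
    tus <- list()
    for (st in c("+", "-")) {
        g <- genes[BiocGenerics::strand(genes) == st]
        if (!length(g)) next
        g <- g[order(BiocGenerics::start(g))]
        cov <- as.numeric(strandCoverage(track, st))
        tss <- tssList[[st]]
        if (length(g) > 1L) {
            joined <- logical(length(g) - 1L)
            for (i in seq_len(length(g) - 1L)) {
                lo <- BiocGenerics::end(g)[i] + 1L
                hi <- BiocGenerics::start(g)[i + 1L] - 1L
                if (lo > hi) { joined[i] <- TRUE; next }
                m1 <- mean(cov[BiocGenerics::start(g)[i]:
                               BiocGenerics::end(g)[i]])
                m2 <- mean(cov[BiocGenerics::start(g)[i + 1L]:
                               BiocGenerics::end(g)[i + 1L]])
                ok <- all(cov[lo:hi] >= joinRatio * min(m1, m2))
                noTss <- !any(tss >= lo & tss <= hi)
                joined[i] <- ok && noTss
            }
            grp <- cumsum(c(1L, !joined))
        } else grp <- 1L
        for (k in unique(grp)) {
            members <- g[grp == k]
            tus[[length(tus) + 1L]] <- list(strand = st, members = members)
        }
    }
    rows <- lapply(seq_along(tus), function(i) {
        m <- tus[[i]]$members
        st <- tus[[i]]$strand
        first <- min(BiocGenerics::start(m))
        last <- max(BiocGenerics::end(m))
        if (st == "+") {
            ts <- tssList[["+"]]
            ts <- ts[ts <= first & ts >= first - maxUpstream]
            tssPos <- if (length(ts)) max(ts) else NA_integer_
            tt <- ttsList[["+"]]
            tt <- tt[tt >= last & tt <= last + maxDownstream]
            ttsPos <- if (length(tt)) min(tt) else NA_integer_
            utr5 <- if (is.na(tssPos)) NA_integer_ else first - tssPos
            utr3 <- if (is.na(ttsPos)) NA_integer_ else ttsPos - last
        } else {
            ts <- tssList[["-"]]
            ts <- ts[ts >= last & ts <= last + maxUpstream]
            tssPos <- if (length(ts)) min(ts) else NA_integer_
            tt <- ttsList[["-"]]
            tt <- tt[tt <= first & tt >= first - maxDownstream]
            ttsPos <- if (length(tt)) max(tt) else NA_integer_
            utr5 <- if (is.na(tssPos)) NA_integer_ else tssPos - last
            utr3 <- if (is.na(ttsPos)) NA_integer_ else first - ttsPos
        }
        ids <- if (st == "+") m$gene_id else rev(m$gene_id)
        tier <- if (!is.null(m$tier))
            TIER_LEVELS[max(match(as.character(m$tier), TIER_LEVELS))]
        else NA_character_
        data.frame(
            seqname = as.character(GenomicRanges::seqnames(m))[1L],
            start = min(first, tssPos, ttsPos, na.rm = TRUE),
            end = max(last, tssPos, ttsPos, na.rm = TRUE),
            strand = st, gene_ids = paste(ids, collapse = ","),
            n_genes = length(m), tss = tssPos, tts = ttsPos,
            utr5_len = utr5, utr3_len = utr3, tier = tier,
            flagged = is.na(tssPos) || is.na(ttsPos),
            stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df <- df[order(df$start), , drop = FALSE]
    out <- GenomicRanges::GRanges(df$seqname,
                                  IRanges::IRanges(df$start, df$end),
                                  strand = df$strand)
    out$tu_id <- sprintf("TU_%03d", seq_len(nrow(df)))
    for (cl in c("gene_ids", "n_genes", "tss", "tts", "utr5_len",
                 "utr3_len", "tier", "flagged"))
        S4Vectors::mcols(out)[[cl]] <- df[[cl]]
    out
}

#' Refine TU 5' boundaries from promoter placements
#'
#' Coverage-derived TSS calls tend to under-estimate the 5' UTR by roughly
#' 20 nt, so when a promoter has been placed for a unit the TSS is
#' re-anchored to 7 nt downstream of the -10 hexamer's 3' end and the UTR
#' lengths recomputed. Units without a promoter call, or whose refined TSS
#' would fall at or beyond the first start codon, keep their coverage TSS
#' (the latter are flagged).
#'
#' @param tus a `GRanges` of transcriptional units from [assembleTUs()].
#' @param promoterCalls a `DataFrame`/data.frame with columns `tu_id` and
#'   `minus10_end` (genomic position of the -10 hexamer's 3' end in
#'   reading orientation), e.g. from [callPromoters()].
#' @param offset nt from the -10 3' end to the transcription start
#'   (prokaryotic spacing, default 7).
#' @return the input `GRanges` with `tss`, `utr5_len`, `flagged` updated
#'   and a new logical mcol `refined`.
#' @export
refineUTRs <- function(tus, promoterCalls, offset = 7L) {
    stopifnot(is(tus, "GRanges"))
    pc <- as.data.frame(promoterCalls)
    tus$refined <- FALSE
    if (!nrow(pc)) return(tus)
    for (i in seq_along(tus)) {
        j <- match(tus$tu_id[i], pc$tu_id)
        if (is.na(j) || is.na(pc$minus10_end[j])) next
        st <- as.character(BiocGenerics::strand(tus))[i]
        geneIds <- strsplit(tus$gene_ids[i], ",")[[1]]
        if (st == "+") {
            newTss <- pc$minus10_end[j] + offset
            ## first start codon position: recover from current tss/utr5
            firstStart <- if (!is.na(tus$tss[i]))
                tus$tss[i] + tus$utr5_len[i] else
                BiocGenerics::start(tus)[i]
            if (newTss >= firstStart) { tus$flagged[i] <- TRUE; next }
            tus$tss[i] <- newTss
            tus$utr5_len[i] <- firstStart - newTss
            BiocGenerics::start(tus)[i] <-
                min(BiocGenerics::start(tus)[i], newTss)
        } else {
            newTss <- pc$minus10_end[j] - offset
            firstStart <- if (!is.na(tus$tss[i]))
                tus$tss[i] - tus$utr5_len[i] else
                BiocGenerics::end(tus)[i]
            if (newTss <= firstStart) { tus$flagged[i] <- TRUE; next }
            tus$tss[i] <- newTss
            tus$utr5_len[i] <- newTss - firstStart
            BiocGenerics::end(tus)[i] <-
                max(BiocGenerics::end(tus)[i], newTss)
        }
        tus$refined[i] <- TRUE
    }
    tus
}
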