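## Hairpin detection (perfect inverted repeats) and terminator
## classification: rho-independent, bare stem-loop, convergent.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Find perfect hairpins (inverted repeats) in a sequence
#'
#' Enumerates perfect Watson-Crick inverted repeats with stem length
#' within `stemRange` and loop length within `loopRange`. Each candidate
#' is scored as the sum of its base-pair scores (G:C = 3, A:T = 2);
#' overlapping candidates are pruned greedily to the best score (ties:
#' earlier start, then longer stem).
#'
#' @param seq a character string or `DNAString`.
#' @param stemRange allowed stem lengths in nt.
#' @param loopRange allowed loop lengths in nt.
#' @return a `data.frame`, one row per retained hairpin: `start`, `end`
#'   (1-based span of the full hairpin), `stem_len`, `loop_len`,
#'   `gc_frac` (GC fraction of the stem), `score`, `stem` (5' arm).
#' @examples
#' findHairpins("GGGGGGTTTTCCCCCC")
#' @export
findHairpins <- function(seq, stemRange = 5:15, loopRange = 3:10) {
    seq <- toupper(as.character(seq))
    n <- nchar(seq)
    chars <- strsplit(seq, "")[[1]]
    cand <- list()
    for (i in seq_len(n)) {
        for (s in rev(stemRange)) {
            for (l in loopRange) {
                end <- i + 2L * s + l - 1L
                if (end > n) next
                arm1 <- chars[i:(i + s - 1L)]
                arm2 <- chars[(i + s + l):end]
                comp <- COMPLEMENT[rev(arm2)]
                if (anyNA(comp) || any(arm1 != comp)) next
                gc <- mean(arm1 %in% c("G", "C"))
                score <- sum(ifelse(arm1 %in% c("G", "C"), 3L, 2L))
                cand[[length(cand) + 1L]] <- data.frame(
                    start = i, end = end, stem_len = s, loop_len = l,
                    gc_frac = gc, score = score,
                    stem = paste(arm1, collapse = ""),
                    stringsAsFactors = FALSE)
            }
        }
    }
    empty <- data.frame(start = integer(0), end = integer(0),
                        stem_len = integer(0), loop_len = integer(0),
                        gc_frac = numeric(0), score = integer(0),
                        stem = character(0))
    if (!length(cand)) return(empty)
    df <- do.call(rbind, cand)
    df <- df[order(-df$score, df$start, -df$stem_len), , drop = FALSE]
    keep <- logical(nrow(df))
    occupied <- rep(FALSE, n)
    for (r in seq_len(nrow(df))) {
        span <- df$start[r]:df$end[r]
        if (!any(occupied[span])) {
            keep[r] <- TRUE
            occupied[span] <- TRUE
        }
    }
    out <- df[keep, , drop = FALSE]
    out[order(out$start), , drop = FALSE]
}

## >= minT T's in the `width` nt after position `hairpinEnd` of `chars`
hasPolyT <- function(chars, hairpinEnd, width = 8L, minT = 4L) {
    lo <- hairpinEnd + 1L
    hi <- min(hairpinEnd + width, length(chars))
    if (lo > hi) return(FALSE)
    sum(chars[lo:hi] == "T") >= minT
}

#' Classify transcriptional terminators
#'
#' For each transcriptional unit, hairpins are sought in the region from
#' 20 nt before to 150 nt after its TTS (reading orientation) and the
#' class is assigned by precedence: (1) a hairpin with stem GC fraction
#' >= 0.5 followed by a poly-T tract (>= 4 T within the 8 nt downstream
#' of the stem) is `rho_independent`; (2) a hairpin without the poly-T
#' tract is `stem_loop`; (3) no hairpin, but an opposite-strand unit
#' whose 3' end lies within `convergentDist` nt (or overlaps) is
#' `convergent`; otherwise `none`. Every unit receives exactly one class.
#'
#' Only hairpins with stability score >= `minScore` count as terminator
#' candidates: in GC-rich sequence, short perfect inverted repeats occur
#' frequently by chance, and a score floor (20 = e.g. a 7 bp all-GC stem)
#' keeps such background hairpins from masking the convergent class.
#'
#' @param tus TU `GRanges` from [assembleTUs()] (mcols `tu_id`, `tts`).
#' @param bundle a [GenomeBundle-class].
#' @param upstream,downstream search region around the TTS in nt.
#' @param convergentDist maximum 3'-end distance for convergent calls.
#' @param minScore minimum hairpin stability score.
#' @return a [S4Vectors::DataFrame], one row per unit: `tu_id`, `class`,
#'   `hairpin_start`/`hairpin_end` (genomic), `stem_len`, `loop_len`,
#'   `gc_frac`, `polyT`, `score`.
#' @export
classifyTerminators <- function(tus, bundle, upstream = 20L,
                                downstream = 150L, convergentDist = 100L,
                                minScore = 20L) {
    stopifnot(is(tus, "GRanges"), is(bundle, "GenomeBundle"))
    genome <- genomeSeq(bundle)[[1L]]
    glen <- length(genome)
    strands <- as.character(BiocGenerics::strand(tus))
    ## 3' end of each unit in genomic coordinates (TTS when known)
    end3 <- ifelse(!is.na(tus$tts), tus$tts,
                   ifelse(strands == "+", BiocGenerics::end(tus),
                          BiocGenerics::start(tus)))
    rows <- lapply(seq_along(tus), function(i) {
        st <- strands[i]
        na <- data.frame(tu_id = tus$tu_id[i], class = "none",
                         hairpin_start = NA_integer_,
                         hairpin_end = NA_integer_,
                         stem_len = NA_integer_, loop_len = NA_integer_,
                         gc_frac = NA_real_, polyT = NA, score = NA_integer_,
                         stringsAsFactors = FALSE)
        hp <- NULL
        if (!is.na(tus$tts[i])) {
            if (st == "+") {
                lo <- max(1L, tus$tts[i] - upstream)
                hi <- min(glen, tus$tts[i] + downstream)
                region <- as.character(Biostrings::subseq(genome, lo, hi))
            } else {
                lo <- max(1L, tus$tts[i] - downstream)
                hi <- min(glen, tus$tts[i] + upstream)
                region <- revcompChr(as.character(
                    Biostrings::subseq(genome, lo, hi)))
            }
            hps <- findHairpins(region)
            hps <- hps[hps$score >= minScore, , drop = FALSE]
            if (nrow(hps)) {
                chars <- strsplit(region, "")[[1]]
                ## poly-T immediately after the stem's 3' arm
                hps$polyT <- vapply(seq_len(nrow(hps)), function(r)
                    hasPolyT(chars, hps$end[r]), logical(1))
                rho <- hps[hps$gc_frac >= 0.5 & hps$polyT, , drop = FALSE]
                if (nrow(rho)) {
                    hp <- rho[which.max(rho$score), ]
                    cls <- "rho_independent"
                } else {
                    noT <- hps[!hps$polyT, , drop = FALSE]
                    if (nrow(noT)) {
                        hp <- noT[which.max(noT$score), ]
                        cls <- "stem_loop"
                    }
                }
                if (!is.null(hp)) {
                    gStart <- if (st == "+") lo + hp$start - 1L
                              else hi - hp$end + 1L
                    gEnd <- if (st == "+") lo + hp$end - 1L
                            else hi - hp$start + 1L
                    return(data.frame(tu_id = tus$tu_id[i], class = cls,
                        hairpin_start = gStart, hairpin_end = gEnd,
                        stem_len = hp$stem_len, loop_len = hp$loop_len,
                        gc_frac = hp$gc_frac, polyT = hp$polyT,
                        score = hp$score, stringsAsFactors = FALSE))
                }
            }
        }
        ## no hairpin: convergent if an opposite-strand unit's 3' end is
        ## near or the units overlap
        opp <- which(strands != st)
        if (length(opp)) {
            near <- abs(end3[opp] - end3[i]) <= convergentDist
            ovl <- BiocGenerics::start(tus)[opp] <=
                BiocGenerics::end(tus)[i] &
                BiocGenerics::end(tus)[opp] >=
                BiocGenerics::start(tus)[i]
            if (any(near | ovl)) {
                na$class <- "convergent"
                return(na)
            }
        }
        na
    })
    S4Vectors::DataFrame(do.call(rbind, rows))
}
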