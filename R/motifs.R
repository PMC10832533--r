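## Degenerate IUPAC motif scanning over upstream windows.

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   W = c("A", "T"), Y = c("C", "T"),
                   N = c("A", "C", "G", "T"))

checkIupac <- function(pattern) {
    chars <- strsplit(pattern, "")[[1]]
    bad <- setdiff(unique(chars), names(IUPAC_SETS))
    if (length(bad))
        stop("invalid IUPAC code(s) in pattern: ",
             paste(bad, collapse = ", "))
    chars
}

#' Count mismatches of a degenerate pattern at one position
#'
#' Position-by-position comparison under IUPAC semantics (`W` = A/T,
#' `Y` = C/T, `N` = any): a text base matches when it belongs to the
#' pattern symbol's set.
#'
#' @param pattern IUPAC pattern (codes A,C,G,T,W,Y,N).
#' @param text concrete sequence of the same length.
#' @return integer mismatch count.
#' @examples
#' iupacMismatches("AWA", "ATA")   # 0
#' iupacMismatches("AWA", "AGA")   # 1
#' @export
iupacMismatches <- function(pattern, text) {
    pc <- checkIupac(pattern)
    tc <- strsplit(toupper(text), "")[[1]]
    if (length(pc) != length(tc))
        stop("pattern and text must have equal length")
    sum(vapply(seq_along(pc),
               function(i) !(tc[i] %in% IUPAC_SETS[[pc[i]]]),
               logical(1)))
}

#' Scan a sequence with a degenerate IUPAC pattern
#'
#' Reports every placement with at most `maxMismatch` mismatches under
#' IUPAC semantics.
#'
#' @param seq a character string or `DNAString`.
#' @param pattern IUPAC pattern (codes A,C,G,T,W,Y,N).
#' @param maxMismatch mismatch budget.
#' @return a `data.frame` with `start`, `end` (1-based in `seq`),
#'   `mismatches` and `match` (the matched subsequence).
#' @examples
#' scanIupacSeq("CCATACC", "AWA")
#' @export
scanIupacSeq <- function(seq, pattern, maxMismatch = 0L) {
    checkIupac(pattern)
    subject <- Biostrings::DNAString(as.character(seq))
    if (length(subject) < nchar(pattern))
        return(data.frame(start = integer(0), end = integer(0),
                          mismatches = integer(0), match = character(0)))
    hits <- Biostrings::matchPattern(pattern, subject,
                                     max.mismatch = maxMismatch,
                                     fixed = "subject")
    st <- BiocGenerics::start(hits)
    ## with a mismatch budget, matchPattern can report placements
    ## overhanging the subject; only fully contained ones count
    st <- st[st >= 1L & st + nchar(pattern) - 1L <= length(subject)]
    mm <- vapply(st, function(s)
        iupacMismatches(pattern,
                        as.character(Biostrings::subseq(
                            subject, s, s + nchar(pattern) - 1L))),
        integer(1))
    data.frame(start = st, end = st + nchar(pattern) - 1L,
               mismatches = mm,
               match = vapply(st, function(s)
                   as.character(Biostrings::subseq(
                       subject, s, s + nchar(pattern) - 1L)),
                   character(1)))
}

#' Scan upstream gene windows for a degenerate regulon motif
#'
#' For every gene, the `window` nt upstream of its translation start
#' (gene-strand orientation) are scanned for `pattern` with at most
#' `maxMismatch` mismatches (IUPAC semantics). The bundled default
#' pattern is the 34 bp regulon consensus ([regulonMotif()]).
#'
#' @param bundle a [GenomeBundle-class].
#' @param pattern IUPAC pattern string.
#' @param maxMismatch mismatch budget.
#' @param window upstream window width in nt.
#' @return a [S4Vectors::DataFrame] of hits: `gene_id`, `strand`,
#'   `start`/`end` (genomic, 1-based inclusive), `offset` (nt between
#'   motif end and the start codon), `mismatches`, `match`.
#' @examples
#' sim <- simulatePlasmid(genParams(seed = 1))
#' hits <- scanIupacMotif(sim$bundle)
#' nrow(as.data.frame(hits))
#' @export
scanIupacMotif <- function(bundle, pattern = regulonMotif(),
                           maxMismatch = 0L, window = 60L) {
    stopifnot(is(bundle, "GenomeBundle"))
    checkIupac(pattern)
    genes <- geneRanges(bundle)
    rows <- list()
    for (i in seq_along(genes)) {
        st <- as.character(BiocGenerics::strand(genes))[i]
        anchor <- if (st == "+") BiocGenerics::start(genes)[i]
                  else BiocGenerics::end(genes)[i]
        win <- extractUpstream(bundle, anchor, st, window)
        hits <- scanIupacSeq(win[[1L]], pattern, maxMismatch)
        if (!nrow(hits)) next
        wlen <- nchar(as.character(win[[1L]]))
        for (h in seq_len(nrow(hits))) {
            if (st == "+") {
                gStart <- S4Vectors::mcols(win)$win_start[1L] +
                    hits$start[h] - 1L
                gEnd <- gStart + nchar(pattern) - 1L
            } else {
                gEnd <- S4Vectors::mcols(win)$win_end[1L] -
                    hits$start[h] + 1L
                gStart <- gEnd - nchar(pattern) + 1L
            }
            rows[[length(rows) + 1L]] <- data.frame(
                gene_id = genes$gene_id[i], strand = st,
                start = gStart, end = gEnd,
                offset = wlen - hits$end[h],
                mismatches = hits$mismatches[h], match = hits$match[h],
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(S4Vectors::DataFrame(gene_id = character(0),
                                    strand = character(0),
                                    start = integer(0), end = integer(0),
                                    offset = integer(0),
                                    mismatches = integer(0),
                                    match = character(0)))
    S4Vectors::DataFrame(do.call(rbind, rows))
}
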