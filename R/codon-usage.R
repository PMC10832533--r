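## Codon-usage indices: RSCU, CAI (Sharp-Li), CBI (Bennetzen-Hall), base
## composition at the wobble position, hydropathy/aromaticity, tRNA
## decoding and pool-compatibility summaries.

GENETIC_CODE_TAB <- Biostrings::GENETIC_CODE
STOP_CODONS <- names(GENETIC_CODE_TAB)[GENETIC_CODE_TAB == "*"]
SENSE_CODONS <- setdiff(names(GENETIC_CODE_TAB), STOP_CODONS)
## synonymous families (amino acid -> codons); single-codon families
## (Met, Trp) are excluded from RSCU/CAI/CBI
CODON_FAMILIES <- split(SENSE_CODONS, GENETIC_CODE_TAB[SENSE_CODONS])
MULTI_FAMILIES <- CODON_FAMILIES[lengths(CODON_FAMILIES) > 1L]
FAMILY_CODONS <- unlist(MULTI_FAMILIES, use.names = FALSE)

KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Count sense codons in a CDS
#'
#' Validates frame (length divisible by 3), start codon and absence of
#' internal stops, then counts the 61 sense codons; a terminal stop codon
#' is excluded from the counts.
#'
#' @param cds a character string or `DNAString`, the coding sequence.
#' @param startCodons accepted start codons.
#' @return named integer vector over the 61 sense codons.
#' @examples
#' codonCounts("ATGGCCTAA")[c("ATG", "GCC")]
#' @export
codonCounts <- function(cds, startCodons = c("ATG", "GTG", "TTG")) {
    cds <- toupper(as.character(cds))
    if (nchar(cds) %% 3L != 0L)
        stop("CDS length ", nchar(cds), " is not divisible by 3")
    cods <- substring(cds, seq(1L, nchar(cds) - 2L, by = 3L),
                      seq(3L, nchar(cds), by = 3L))
    if (!cods[1L] %in% startCodons)
        stop("CDS does not begin with an accepted start codon (",
             cods[1L], ")")
    if (cods[length(cods)] %in% STOP_CODONS)
        cods <- cods[-length(cods)]
    internal <- which(cods %in% STOP_CODONS)
    if (length(internal))
        stop("internal stop codon at codon position ", internal[1L])
    bad <- which(!cods %in% SENSE_CODONS)
    if (length(bad))
        stop("non-ACGT codon at codon position ", bad[1L])
    counts <- table(factor(cods, levels = SENSE_CODONS))
    stats::setNames(as.integer(counts), SENSE_CODONS)
}

#' Relative synonymous codon usage
#'
#' For a codon `c` in a synonymous family `F`,
#' `RSCU_c = count_c / (sum(counts over F) / |F|)`: 0 for an absent codon,
#' 1 under no bias, up to `|F|` when a single codon carries the whole
#' family. Computed for multi-codon families only (Met and Trp are
#' excluded); families with zero total get `NA`.
#'
#' @param counts named codon counts from [codonCounts()] (or a pooled
#'   sum of such vectors).
#' @return named numeric vector of RSCU values over the 59 codons in
#'   multi-codon families.
#' @examples
#' x <- codonCounts(paste0("ATG", strrep("GCC", 4), "TAA"))
#' rscu(x)[c("GCT", "GCC", "GCA", "GCG")]
#' @export
rscu <- function(counts) {
    out <- stats::setNames(rep(NA_real_, length(FAMILY_CODONS)),
                           FAMILY_CODONS)
    for (fam in MULTI_FAMILIES) {
        tot <- sum(counts[fam])
        if (tot > 0)
            out[fam] <- counts[fam] / (tot / length(fam))
    }
    out
}

#' Relative adaptiveness weights from a reference gene set
#'
#' `w_c = RSCU_c / max(RSCU over the family)` computed on the pooled
#' codon counts of the reference set; codons unused in the reference get
#' the conventional floor of 0.01.
#'
#' @param ref reference CDSs (character vector / `DNAStringSet`) or a
#'   pre-pooled named codon-count vector.
#' @param floor weight assigned to reference-absent codons.
#' @return named numeric weights over the 59 multi-family codons.
#' @export
referenceWeights <- function(ref, floor = 0.01) {
    counts <- if (is.numeric(ref)) ref
              else Reduce(`+`, lapply(as.character(ref), codonCounts))
    if (all(counts == 0))
        stop("reference set is empty")
    w <- stats::setNames(rep(floor, length(FAMILY_CODONS)), FAMILY_CODONS)
    for (fam in MULTI_FAMILIES) {
        tot <- sum(counts[fam])
        if (tot == 0) next
        r <- counts[fam] / (tot / length(fam))
        w[fam] <- pmax(r / max(r), 0)
    }
    w[w == 0] <- floor
    w
}

#' Codon adaptation index
#'
#' Geometric mean of the reference relative-adaptiveness weights over the
#' gene's codons, excluding Met, Trp and stop codons (Sharp-Li
#' convention); ranges 0 to 1.
#'
#' @param cds coding sequence (string) or a named codon-count vector.
#' @param weights reference weights from [referenceWeights()].
#' @return CAI in `[0, 1]`.
#' @export
cai <- function(cds, weights) {
    counts <- if (is.numeric(cds)) cds else codonCounts(cds)
    n <- counts[FAMILY_CODONS]
    if (sum(n) == 0)
        stop("no family codons in CDS: CAI undefined")
    exp(sum(n * log(weights[FAMILY_CODONS])) / sum(n))
}

#' Codon bias index
#'
#' Bennetzen-Hall `CBI = (N_opt - N_rand) / (N_tot - N_rand)` with
#' `N_rand = sum over families of n_fam / |F|`, computed over multi-codon
#' families: 1 for exclusive use of optimal codons, 0 for uniform usage.
#'
#' @param cds coding sequence (string) or a named codon-count vector.
#' @param optimalSet character vector of optimal codons, one per family
#'   (e.g. the weight-1 codons of [referenceWeights()]).
#' @return CBI value (<= 1; negative when optimal codons are avoided).
#' @export
cbi <- function(cds, optimalSet) {
    counts <- if (is.numeric(cds)) cds else codonCounts(cds)
    nTot <- nRand <- nOpt <- 0
    for (fam in MULTI_FAMILIES) {
        nf <- sum(counts[fam])
        nTot <- nTot + nf
        nRand <- nRand + nf / length(fam)
        nOpt <- nOpt + sum(counts[intersect(fam, optimalSet)])
    }
    if (nTot == nRand)
        stop("CBI undefined: no codons in multi-codon families")
    (nOpt - nRand) / (nTot - nRand)
}

#' Base composition of a CDS
#'
#' Third-position (wobble) base fractions over the sense codons plus the
#' overall GC fraction; `gc3 = c3 + g3` by construction.
#'
#' @param cds coding sequence string.
#' @return named numeric: `a3`, `t3`, `c3`, `g3`, `gc3`, `gc`.
#' @examples
#' baseComposition("ATGGCCTAA")
#' @export
baseComposition <- function(cds) {
    counts <- codonCounts(cds)
    third <- substr(names(counts), 3L, 3L)
    tot <- sum(counts)
    frac <- vapply(c("A", "T", "C", "G"),
                   function(b) sum(counts[third == b]) / tot, numeric(1))
    chars <- unlist(strsplit(names(counts), ""))
    gcAll <- sum(rep(counts, each = 3L) *
                 (chars %in% c("G", "C"))) / (3L * tot)
    c(a3 = frac[["A"]], t3 = frac[["T"]], c3 = frac[["C"]],
      g3 = frac[["G"]], gc3 = frac[["C"]] + frac[["G"]], gc = gcAll)
}

#' Hydropathy and aromaticity of a protein
#'
#' `gravy` is the mean Kyte-Doolittle hydropathy over residues; `aromo`
#' the fraction of aromatic residues (F, Y, W).
#'
#' @param protein amino-acid string (standard one-letter codes; a
#'   trailing `*` is ignored).
#' @return named numeric: `gravy`, `aromo`.
#' @examples
#' gravyAromo("A")
#' @export
gravyAromo <- function(protein) {
    aa <- strsplit(toupper(as.character(protein)), "")[[1]]
    aa <- aa[aa != "*"]
    if (!length(aa))
        stop("empty protein")
    bad <- setdiff(unique(aa), names(KYTE_DOOLITTLE))
    if (length(bad))
        stop("non-standard amino acid(s): ", paste(bad, collapse = ", "))
    c(gravy = mean(KYTE_DOOLITTLE[aa]),
      aromo = mean(aa %in% c("F", "Y", "W")))
}

#' Decode tRNA anticodons to the codons they read
#'
#' Strict Watson-Crick decoding: the codon is the reverse complement of
#' the 5'->3' anticodon (RNA or DNA alphabet accepted); duplicates are
#' collapsed.
#'
#' @param anticodons character vector of anticodon triplets, 5' to 3'.
#' @return character vector of unique DNA codons.
#' @examples
#' trnaToCodons(c("UGC", "CAU"))   # GCA, ATG
#' @export
trnaToCodons <- function(anticodons) {
    ac <- toupper(gsub("U", "T", anticodons))
    if (any(nchar(ac) != 3L) || any(grepl("[^ACGT]", ac)))
        stop("anticodons must be triplets over A,C,G,T/U")
    unique(vapply(ac, revcompChr, character(1), USE.NAMES = FALSE))
}

#' Rare (low-usage) codons of a profile
#'
#' Codons whose within-family usage fraction falls below `threshold`
#' (default 10%), over multi-codon families with non-zero counts.
#'
#' @param counts named codon counts (pooled genome or gene-set profile).
#' @param threshold usage fraction below which a codon is rare.
#' @return character vector of rare codons.
#' @export
rareCodons <- function(counts, threshold = 0.10) {
    out <- character(0)
    for (fam in MULTI_FAMILIES) {
        tot <- sum(counts[fam])
        if (tot == 0) next
        out <- c(out, fam[counts[fam] / tot < threshold])
    }
    out
}

#' Chi-squared comparison of two codon-usage profiles
#'
#' Pearson chi-squared test on the 2 x k table of raw codon counts.
#' Codons whose expected count under independence falls below 1 in either
#' group are pooled into a single column before testing; the test is run
#' without continuity correction, df = k - 1 after pooling.
#'
#' @param countsA,countsB named codon-count vectors on the same codons.
#' @return a list: `statistic`, `df`, `p.value`, `pooled` (codons merged
#'   into the pooled column).
#' @export
rscuChisq <- function(countsA, countsB) {
    stopifnot(identical(names(countsA), names(countsB)))
    keep <- countsA + countsB > 0
    a <- countsA[keep]; b <- countsB[keep]
    tab <- rbind(a, b)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    low <- apply(expected, 2L, min) < 1
    pooled <- colnames(tab)[low]
    if (any(low)) {
        tab <- cbind(tab[, !low, drop = FALSE],
                     pooled = rowSums(tab[, low, drop = FALSE]))
    }
    if (ncol(tab) < 2L)
        stop("fewer than 2 codon classes after pooling")
    res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(res$statistic), df = unname(res$parameter),
         p.value = res$p.value, pooled = pooled)
}

#' Mean RSCU of gene sets over a codon subset
#'
#' For each gene-set codon profile, the arithmetic mean of its RSCU
#' values restricted to `trnaCodons` (typically the codons decoded by
#' plasmid-expressed tRNAs) -- a summary of how compatible each set is
#' with the tRNA pool.
#'
#' @param profiles a named list of RSCU vectors (from [rscu()]) or codon
#'   count vectors (converted with [rscu()] automatically).
#' @param trnaCodons non-empty character vector of codons.
#' @return a list: `mean` (named numeric per gene set) and `values`
#'   (matrix of the restricted RSCU values, sets x codons).
#' @export
trnaCompatibility <- function(profiles, trnaCodons) {
    if (!length(trnaCodons))
        stop("empty codon subset")
    bad <- setdiff(trnaCodons, FAMILY_CODONS)
    if (length(bad))
        stop("codons outside multi-codon families: ",
             paste(bad, collapse = ", "))
    vals <- t(vapply(profiles, function(p) {
        ## integer vectors are taken as codon counts, doubles as RSCU
        r <- if (is.integer(p)) rscu(p) else p
        r[trnaCodons]
    }, numeric(length(trnaCodons))))
    colnames(vals) <- trnaCodons
    list(mean = rowMeans(vals, na.rm = TRUE), values = vals)
}

#' Full codon-usage profile of one CDS
#'
#' Convenience wrapper computing counts, RSCU, base composition, gravy
#' and aromaticity (and CAI/CBI when reference weights are supplied).
#'
#' @param cds coding sequence string.
#' @param weights optional reference weights from [referenceWeights()].
#' @return a list with elements `counts`, `rscu`, `composition`,
#'   `gravy`, `aromo` and, when weights are given, `cai` and `cbi`.
#' @export
codonProfile <- function(cds, weights = NULL) {
    counts <- codonCounts(cds)
    prot <- as.character(Biostrings::translate(
        Biostrings::DNAString(toupper(as.character(cds))),
        if.fuzzy.codon = "X"))
    ga <- gravyAromo(sub("\\*$", "", prot))
    out <- list(counts = counts, rscu = rscu(counts),
                composition = baseComposition(cds),
                gravy = ga[["gravy"]], aromo = ga[["aromo"]])
    if (!is.null(weights)) {
        out$cai <- cai(counts, weights)
        opt <- unlist(lapply(MULTI_FAMILIES, function(fam)
            fam[which.max(weights[fam])]), use.names = FALSE)
        out$cbi <- cbi(counts, opt)
    }
    out
}
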