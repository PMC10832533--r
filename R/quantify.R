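## Expression quantification: RPKM, TPM and floor-plus-quartile tiering.

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = numReads / ((geneLength / 1e3) * (totalNumReads / 1e6))`, where
#' `numReads` is the number of fragments mapped to the gene, `geneLength`
#' the gene length in nt and `totalNumReads` the sample's total mapped
#' reads. Vectorised over genes.
#'
#' @param numReads fragment count(s) mapped to the gene(s).
#' @param geneLength gene length(s) in nt (> 0).
#' @param totalNumReads total mapped reads in the sample (> 0).
#' @return numeric RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6)   # 10
#' @export
rpkm <- function(numReads, geneLength, totalNumReads) {
    if (any(geneLength <= 0))
        stop("geneLength must be > 0")
    stopifnotScalarNum(totalNumReads, "totalNumReads")
    if (totalNumReads <= 0)
        stop("totalNumReads must be > 0")
    numReads / ((geneLength / 1e3) * (totalNumReads / 1e6))
}

#' Transcripts per million
#'
#' Per-gene length-normalised rate `count/length`, rescaled so the sample
#' sums to one million: `TPM = 1e6 * rate / sum(rate)`.
#'
#' @param counts fragment counts per gene (one sample).
#' @param lengths gene lengths in nt (> 0), parallel to `counts`.
#' @return numeric TPM vector summing to 1e6.
#' @examples
#' tpm(c(10, 10), c(1000, 2000))
#' @export
tpm <- function(counts, lengths) {
    if (length(counts) != length(lengths))
        stop("counts and lengths must have equal length")
    if (any(lengths <= 0))
        stop("lengths must be > 0")
    if (all(counts == 0))
        stop("TPM undefined for an all-zero sample")
    rate <- counts / lengths
    1e6 * rate / sum(rate)
}

#' Assign expression tiers by the floor-plus-quartile rule
#'
#' Genes below the expression floor (default 1.5 RPKM) are `silent`.
#' Quartiles Q1/Q2/Q3 are computed on the expressed genes only
#' (linear-interpolation, type-7 quantiles); a gene is `high` if its RPKM
#' exceeds Q3, `low` if at or below Q1, `medium` otherwise.
#'
#' @param rpkmValues numeric RPKM per gene.
#' @param floor expression floor in RPKM (> 0).
#' @return a list: `thresholds` (named `floor`, `Q1`, `Q2`, `Q3`) and
#'   `tier` (factor with levels silent < low < medium < high, parallel to
#'   `rpkmValues`).
#' @examples
#' assignTiers(c(0.1, 2, 4, 6, 8))
#' @export
assignTiers <- function(rpkmValues, floor = 1.5) {
    stopifnotScalarNum(floor, "floor")
    if (floor <= 0)
        stop("floor must be > 0")
    expressed <- rpkmValues >= floor
    if (sum(expressed, na.rm = TRUE) < 4L)
        stop("fewer than 4 expressed genes: tier thresholds undefined")
    q <- stats::quantile(rpkmValues[expressed], c(0.25, 0.5, 0.75),
                         type = 7, names = FALSE)
    tier <- ifelse(!expressed, "silent",
            ifelse(rpkmValues > q[3L], "high",
            ifelse(rpkmValues <= q[1L], "low", "medium")))
    list(thresholds = c(floor = floor, Q1 = q[1L], Q2 = q[2L], Q3 = q[3L]),
         tier = factor(tier, levels = TIER_LEVELS, ordered = TRUE))
}

#' Quantify expression from a count matrix
#'
#' Computes per-sample RPKM and TPM and a single tier per gene from the
#' mean RPKM across samples (floor-plus-quartile rule, [assignTiers()]).
#'
#' @param counts integer matrix, genes x samples, rownames = gene ids.
#' @param lengths named gene lengths in nt covering all rows of `counts`.
#' @param floor expression floor in RPKM.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assays
#'   `counts`, `rpkm`, `tpm`; rowData columns `gene_length`, `mean_rpkm`,
#'   `tier`; and the tier thresholds in `metadata()$thresholds`.
#' @examples
#' sim <- simulateCounts(countDesign(nGenes = 50, nUp = 0, nDown = 0,
#'                                   seed = 2))
#' se <- quantifyExpression(sim$counts, sim$lengths)
#' table(SummarizedExperiment::rowData(se)$tier)
#' @export
quantifyExpression <- function(counts, lengths, floor = 1.5) {
    if (is.null(rownames(counts)))
        stop("counts must have gene ids as rownames")
    if (!all(rownames(counts) %in% names(lengths)))
        stop("lengths must cover every gene in counts")
    len <- lengths[rownames(counts)]
    totals <- colSums(counts)
    rpkmMat <- vapply(seq_len(ncol(counts)),
                      function(j) rpkm(counts[, j], len, totals[j]),
                      numeric(nrow(counts)))
    tpmMat <- vapply(seq_len(ncol(counts)),
                     function(j) tpm(counts[, j], len),
                     numeric(nrow(counts)))
    dimnames(rpkmMat) <- dimnames(tpmMat) <- dimnames(counts)
    meanRpkm <- rowMeans(rpkmMat)
    tiers <- assignTiers(meanRpkm, floor)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts, rpkm = rpkmMat, tpm = tpmMat),
        rowData = S4Vectors::DataFrame(gene_length = unname(len),
                                       mean_rpkm = meanRpkm,
                                       tier = tiers$tier),
        metadata = list(thresholds = tiers$thresholds))
}
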