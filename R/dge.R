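## Plasmid-carriage differential expression: TPM matrix, SSE-based k
## selection for k-means clustering, per-gene testing, fold-change /
## p / FDR filtering, and functional-class-scoring enrichment.

#' Per-sample TPM matrix
#'
#' Applies [tpm()] column-wise; every column sums to one million.
#'
#' @param counts integer matrix, genes x samples.
#' @param lengths named gene lengths in nt covering all rows.
#' @return numeric matrix of TPM values with the dimnames of `counts`.
#' @export
tpmMatrix <- function(counts, lengths) {
    if (is.null(rownames(counts)))
        stop("counts must have gene ids as rownames")
    len <- lengths[rownames(counts)]
    out <- matrix(0, nrow(counts), ncol(counts),
                  dimnames = dimnames(counts))
    for (j in seq_len(ncol(counts)))
        out[, j] <- tpm(counts[, j], len)
    out
}

#' Choose the number of k-means clusters by the SSE elbow
#'
#' Rows are z-scored over `log2(TPM + 1)` and clustered with k-means
#' (`nstart` restarts, seeded) for each k in `kRange`; the within-cluster
#' sum of squared errors (SSE) is recorded and the selected k maximises
#' the second difference of the SSE curve (the elbow), ties going to the
#' smaller k. Degenerate input (all rows identical after z-scoring)
#' selects k = 1.
#'
#' @param tpmMat numeric TPM matrix, genes x samples.
#' @param kRange candidate cluster numbers.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart k-means restarts per k.
#' @return a list: `k` (chosen), `sse` (named by k), `assignments`
#'   (cluster id per gene for the chosen k) and `seed`.
#' @export
selectK <- function(tpmMat, kRange = 1:8, seed = 20240111L,
                    nstart = 10L) {
    if (nrow(tpmMat) < 2L)
        stop("need at least 2 genes to cluster")
    z <- t(apply(log2(tpmMat + 1), 1L, function(x) {
        s <- stats::sd(x)
        if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
    }))
    if (all(abs(z) < 1e-12)) {
        return(list(k = 1L,
                    sse = stats::setNames(0, "1"),
                    assignments = stats::setNames(rep(1L, nrow(tpmMat)),
                                                  rownames(tpmMat)),
                    seed = seed))
    }
    kRange <- sort(unique(pmin(kRange, nrow(z))))
    withSeed(seed, {
        fits <- list()
        sse <- stats::setNames(numeric(length(kRange)),
                               as.character(kRange))
        for (i in seq_along(kRange)) {
            k <- kRange[i]
            if (k == 1L) {
                sse[i] <- sum(scale(z, scale = FALSE)^2)
                fits[[i]] <- rep(1L, nrow(z))
            } else {
                fit <- stats::kmeans(z, centers = k, nstart = nstart,
                                     iter.max = 50L)
                sse[i] <- fit$tot.withinss
                fits[[i]] <- fit$cluster
            }
        }
        ## elbow: maximal second difference sse[k-1] - 2 sse[k] + sse[k+1]
        if (length(kRange) >= 3L) {
            inner <- 2:(length(kRange) - 1L)
            d2 <- sse[inner - 1L] - 2 * sse[inner] + sse[inner + 1L]
            kIdx <- inner[which.max(d2)]
        } else kIdx <- length(kRange)
        k <- kRange[kIdx]
        list(k = k, sse = sse,
             assignments = stats::setNames(fits[[kIdx]], rownames(z)),
             seed = seed)
    })
}

#' Per-gene two-group test
#'
#' `log2fc = log2(mean_B / mean_A)` on condition means floored at
#' `meanFloor` TPM; the p-value is a Welch t-test on `log2(TPM + 1)` with
#' each group variance floored at `varFloor` (so identical groups give
#' p = 1 rather than an undefined statistic).
#'
#' @param tpmA,tpmB TPM replicate vectors for the two conditions
#'   (>= 2 each).
#' @param meanFloor TPM floor applied to the condition means.
#' @param varFloor variance floor on the log scale.
#' @return named numeric: `log2fc`, `p`.
#' @examples
#' geneTest(c(4, 4, 4), c(16, 16, 16))
#' @export
geneTest <- function(tpmA, tpmB, meanFloor = 0.5, varFloor = 1e-3) {
    if (length(tpmA) < 2L || length(tpmB) < 2L)
        stop("need at least 2 replicates per group")
    log2fc <- log2(max(mean(tpmB), meanFloor) /
                   max(mean(tpmA), meanFloor))
    a <- log2(tpmA + 1); b <- log2(tpmB + 1)
    v1 <- max(stats::var(a), varFloor)
    v2 <- max(stats::var(b), varFloor)
    n1 <- length(a); n2 <- length(b)
    se2 <- v1 / n1 + v2 / n2
    t <- (mean(b) - mean(a)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
    p <- 2 * stats::pt(-abs(t), df)
    c(log2fc = log2fc, p = p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `p.adjust(method = "BH")`).
#'
#' @param p p-values in `[0, 1]`.
#' @return monotone q-values, same length and order as `p`.
#' @export
bhFdr <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' The procedure: genes below `meanTpmFloor` mean TPM are excluded from
#' testing. Per-gene p-values come from a moderated t-test on
#' TMM-normalised, precision-weighted log-counts (limma-voom): with few
#' replicates, empirical-Bayes variance pooling across genes is what
#' keeps the false-discovery rate controlled, where an unmoderated
#' per-gene test is not calibrated. Fold changes are
#' `log2(mean_B / mean_A)` on TPM columns rescaled by median-of-ratios
#' size factors (raw TPM is composition-biased when differential
#' expression is asymmetric) with condition means floored at 0.5 TPM.
#' q-values are Benjamini-Hochberg over the tested genes; a gene is
#' called `up` when `log2fc >= log2(fc)`, `p < pMax` and `q < qMax`
#' (mirrored for `down`). Cluster assignments from [selectK()] on the
#' full TPM matrix are attached.
#'
#' @param counts integer matrix, genes x samples.
#' @param lengths named gene lengths in nt.
#' @param condition factor/character of length `ncol(counts)` with two
#'   levels; the first level is the reference (condition A).
#' @param fc fold-change threshold (calls need `|log2fc| >= log2(fc)`).
#' @param pMax p-value threshold.
#' @param qMax FDR (q-value) threshold.
#' @param meanTpmFloor mean-expression pre-filter in TPM.
#' @param clusterSeed seed forwarded to [selectK()].
#' @return a list: `records` (a `DataFrame`: `gene_id`, `mean_tpm_A`,
#'   `mean_tpm_B`, `log2fc`, `p_value`, `q_value`, `cluster`, `call`),
#'   `summary` (named counts `n_tested`, `n_up`, `n_down`) and
#'   `cluster` (the [selectK()] result).
#' @export
callDEGs <- function(counts, lengths, condition, fc = 2, pMax = 0.05,
                     qMax = 0.1, meanTpmFloor = 1,
                     clusterSeed = 20240111L) {
    condition <- as.factor(condition)
    if (nlevels(condition) != 2L)
        stop("condition must have exactly two levels")
    tpmMat <- tpmMatrix(counts, lengths)
    idxA <- condition == levels(condition)[1L]
    idxB <- condition == levels(condition)[2L]
    km <- selectK(tpmMat, seed = clusterSeed)
    meanTpm <- rowMeans(tpmMat)
    tested <- meanTpm >= meanTpmFloor
    ids <- rownames(counts)

    ## composition-corrected TPM for fold changes
    ref <- exp(rowMeans(log(tpmMat + 0.5)))
    sizeFac <- apply(tpmMat, 2L, function(x)
        stats::median((x + 0.5) / ref))
    tpmScaled <- sweep(tpmMat, 2L, sizeFac, "/")
    mA <- rowMeans(tpmScaled[, idxA, drop = FALSE])
    mB <- rowMeans(tpmScaled[, idxB, drop = FALSE])
    lfc <- log2(pmax(mB, 0.5) / pmax(mA, 0.5))

    ## moderated t on TMM-normalised, precision-weighted log-counts
    p <- rep(NA_real_, nrow(counts))
    sub <- counts[tested, , drop = FALSE]
    design <- stats::model.matrix(~condition)
    dgel <- edgeR::calcNormFactors(edgeR::DGEList(sub), method = "TMM")
    v <- limma::voom(dgel, design)
    fit <- limma::eBayes(limma::lmFit(v, design))
    p[tested] <- fit$p.value[, 2L]

    q <- rep(NA_real_, nrow(counts))
    q[tested] <- bhFdr(p[tested])
    lfcMin <- log2(fc)
    call <- rep("not_de", nrow(counts))
    call[tested & lfc >= lfcMin & p < pMax & q < qMax] <- "up"
    call[tested & lfc <= -lfcMin & p < pMax & q < qMax] <- "down"
    records <- S4Vectors::DataFrame(
        gene_id = ids,
        mean_tpm_A = rowMeans(tpmMat[, idxA, drop = FALSE]),
        mean_tpm_B = rowMeans(tpmMat[, idxB, drop = FALSE]),
        log2fc = lfc, p_value = p, q_value = q,
        cluster = unname(km$assignments[ids]), call = call)
    list(records = records,
         summary = c(n_tested = sum(tested), n_up = sum(call == "up"),
                     n_down = sum(call == "down")),
         cluster = km)
}

#' Functional-class-scoring enrichment of a gene set
#'
#' Two-sample Wilcoxon rank test of the gene set's log2 fold changes
#' against the complement: exact enumeration when the set has at most 8
#' genes in a background of at most 25, otherwise the normal
#' approximation with tie correction.
#'
#' @param log2fcAll named numeric log2 fold changes for the full
#'   background.
#' @param geneSet character vector of gene ids, a proper non-empty
#'   subset of `names(log2fcAll)`.
#' @param alternative `"two.sided"` (default), `"greater"` (set shifted
#'   up) or `"less"`.
#' @return a list: `statistic` (rank-sum U of the set), `p.value`,
#'   `exact` (whether enumeration was used), `n_set`, `n_background`.
#' @export
fcsEnrichment <- function(log2fcAll, geneSet,
                          alternative = c("two.sided", "greater",
                                          "less")) {
    alternative <- match.arg(alternative)
    if (is.null(names(log2fcAll)))
        stop("log2fcAll must be named by gene id")
    if (!length(geneSet) || !all(geneSet %in% names(log2fcAll)))
        stop("geneSet must be a non-empty subset of the background")
    if (length(geneSet) >= length(log2fcAll))
        stop("geneSet must be a proper subset of the background")
    x <- log2fcAll[geneSet]
    y <- log2fcAll[setdiff(names(log2fcAll), geneSet)]
    exact <- length(x) <= 8L && length(log2fcAll) <= 25L &&
        !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(
        x, y, alternative = alternative, exact = exact,
        correct = !exact))
    list(statistic = unname(wt$statistic), p.value = wt$p.value,
         exact = exact, n_set = length(x),
         n_background = length(log2fcAll))
}
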