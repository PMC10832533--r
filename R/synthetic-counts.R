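## Negative-binomial count simulation with planted differential expression.

#' Design a planted two-condition count experiment
#'
#' Defaults describe a chromosome-scale plasmid-carriage comparison:
#' 1864 genes, three biological replicates per condition, 127 planted
#' up-regulated and 30 planted down-regulated genes at |log2 fold change|
#' of 2, negative-binomial dispersion 0.1.
#'
#' @param nGenes number of genes.
#' @param replicates replicates per condition (>= 2).
#' @param nbDispersion NB dispersion; counts use `size = 1/nbDispersion`.
#' @param nUp,nDown numbers of planted up-/down-regulated genes.
#' @param effectLog2fc planted |log2 fold change|.
#' @param seed integer RNG seed.
#' @return a validated [CountDesign-class] object.
#' @examples
#' countDesign(seed = 7)
#' @export
countDesign <- function(nGenes = 1864L, replicates = 3L,
                        nbDispersion = 0.1, nUp = 127L, nDown = 30L,
                        effectLog2fc = 2.0, seed = 1L) {
    new("CountDesign", nGenes = as.integer(nGenes),
        replicates = as.integer(replicates), nbDispersion = nbDispersion,
        nUp = as.integer(nUp), nDown = as.integer(nDown),
        effectLog2fc = effectLog2fc, seed = as.integer(seed))
}

#' Simulate a two-condition count matrix with planted DEGs
#'
#' Per-gene baseline means are log-normal (meanlog = log 50, sdlog = 1);
#' condition-2 means are the baseline multiplied by `2^log2fc` for planted
#' genes; counts are negative-binomial with `size = 1/nbDispersion`. Which
#' genes carry an effect is drawn uniformly at random (seeded). Gene
#' lengths (for TPM) are drawn uniformly on 200-3000 nt.
#'
#' @param design a [CountDesign-class] from [countDesign()].
#' @return a list: `counts` (integer matrix, genes x samples, columns
#'   `condA_rep*` / `condB_rep*`), `lengths` (named gene lengths in nt),
#'   `condition` (factor of column conditions) and `truth`
#'   (a [TruthSet-class] whose `degs` table records the planted
#'   `log2fc` and `direction`; genes with planted log2fc = 0 are `null`).
#' @examples
#' sim <- simulateCounts(countDesign(nGenes = 100, nUp = 5, nDown = 2,
#'                                   seed = 3))
#' table(truthDEGs(sim$truth)$direction)
#' @export
simulateCounts <- function(design) {
    stopifnot(is(design, "CountDesign"))
    validObject(design)
    withSeed(design@seed, {
        n <- design@nGenes
        reps <- design@replicates
        ids <- sprintf("g%04d", seq_len(n))
        lengths <- sample(200:3000, n, replace = TRUE)
        names(lengths) <- ids
        mu <- stats::rlnorm(n, meanlog = log(50), sdlog = 1)
        lfc <- numeric(n)
        affected <- sample.int(n, design@nUp + design@nDown)
        lfc[affected[seq_len(design@nUp)]] <- design@effectLog2fc
        if (design@nDown > 0L)
            lfc[affected[design@nUp + seq_len(design@nDown)]] <-
                -design@effectLog2fc
        size <- 1 / design@nbDispersion
        muMat <- cbind(matrix(mu, n, reps),
                       matrix(mu * 2^lfc, n, reps))
        counts <- matrix(stats::rnbinom(n * 2L * reps, mu = muMat,
                                        size = size),
                         nrow = n, ncol = 2L * reps)
        dimnames(counts) <- list(ids,
            c(sprintf("condA_rep%d", seq_len(reps)),
              sprintf("condB_rep%d", seq_len(reps))))
        direction <- ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "null"))
        truth <- new("TruthSet",
            genes = S4Vectors::DataFrame(),
            motifs = S4Vectors::DataFrame(),
            degs = S4Vectors::DataFrame(gene_id = ids, log2fc = lfc,
                                        direction = direction),
            params = list(seed = design@seed, nGenes = n,
                          replicates = reps,
                          nbDispersion = design@nbDispersion,
                          effectLog2fc = design@effectLog2fc))
        list(counts = counts, lengths = lengths,
             condition = factor(rep(c("condA", "condB"), each = reps)),
             truth = truth)
    })
}
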