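## End-to-end orchestration: simulate -> quantify -> boundaries ->
## promoters/terminators/motifs -> codon usage -> differential expression,
## with a deterministic TSV report.

#' Run the full synthetic-demo pipeline
#'
#' Simulates a plasmid genome with planted regulatory truth and a
#' two-condition chromosomal count experiment, then runs every analysis
#' stage: expression tiering from coverage-derived counts, TSS/TTS
#' mapping, transcriptional-unit assembly, promoter-model fitting and
#' calling with UTR refinement, spacer statistics, regulon-motif
#' scanning, terminator classification, codon-usage profiling by tier,
#' and differential-expression calling. All intermediates are written to
#' `outdir` in standard formats (FASTA, GFF3, bedGraph, TSV, JSON)
#' together with a `report.tsv` of headline summaries. Given the same
#' seed and parameters the report is byte-identical across runs.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed; stage seeds are derived from it.
#' @param params a [GenParams-class] for the plasmid (defaults to
#'   `genParams(seed = seed)`).
#' @param design a [CountDesign-class] for the carriage comparison
#'   (defaults to `countDesign(seed = seed + 1)`).
#' @param depthPerTier,fragLen forwarded to [simulateCoverage()].
#' @return invisibly, a list with every stage result: `bundle`, `truth`,
#'   `coverage`, `expression`, `tus`, `model`, `promoters`,
#'   `spacers`, `motifHits`, `terminators`, `codon`, `dge`, `report`.
#' @examples
#' \donttest{
#' res <- runPipeline(file.path(tempdir(), "demo"), seed = 1)
#' res$report
#' }
#' @export
runPipeline <- function(outdir, seed = 1L,
                        params = genParams(seed = seed),
                        design = countDesign(seed = seed + 1L),
                        depthPerTier = c(high = 200, medium = 100,
                                         low = 50),
                        fragLen = 30L) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    version <- as.character(utils::packageVersion("plasmidtx"))

    ## --- simulate -------------------------------------------------------
    sim <- simulatePlasmid(params)
    bundle <- sim$bundle
    truth <- sim$truth
    cov <- simulateCoverage(bundle, truth, depthPerTier, fragLen,
                            seed = seed + 2L)
    writeGenomeBundle(bundle, file.path(outdir, "genome.fasta"),
                      file.path(outdir, "genes.gff3"))
    writeCoverage(cov$track, file.path(outdir, "coverage.plus.bedgraph"),
                  file.path(outdir, "coverage.minus.bedgraph"))
    writeTruth(truth, file.path(outdir, "truth.json"))

    ## --- quantify: per-gene fragment counts from the coverage run ------
    counts <- matrix(cov$fragments$n_fragments, ncol = 1L,
                     dimnames = list(cov$fragments$gene_id, "sample1"))
    lengths <- stats::setNames(
        BiocGenerics::width(geneRanges(bundle)),
        geneRanges(bundle)$gene_id)
    writeCounts(counts, file.path(outdir, "counts.tsv"))
    se <- quantifyExpression(counts, lengths)
    tiers <- stats::setNames(
        as.character(SummarizedExperiment::rowData(se)$tier),
        rownames(se))
    exprDf <- data.frame(
        gene_id = rownames(se),
        numReads = counts[, 1L],
        rpkm = SummarizedExperiment::assay(se, "rpkm")[, 1L],
        tpm = SummarizedExperiment::assay(se, "tpm")[, 1L],
        tier = tiers)
    utils::write.table(exprDf, file.path(outdir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    ## --- boundaries -----------------------------------------------------
    tssList <- list(`+` = detectTSS(cov$track, "+"),
                    `-` = detectTSS(cov$track, "-"))
    ttsList <- list(`+` = detectTTS(cov$track, "+"),
                    `-` = detectTTS(cov$track, "-"))
    genes <- geneRanges(bundle)
    genes$tier <- unname(tiers[genes$gene_id])
    expressed <- genes[genes$tier != "silent"]
    tus <- assembleTUs(expressed, tssList, ttsList, cov$track)

    ## --- promoters ------------------------------------------------------
    hm <- tus[!is.na(tus$tss) & tus$tier %in% c("high", "medium")]
    model <- NULL
    proms <- S4Vectors::DataFrame()
    spacers <- NULL
    if (length(hm) >= 10L) {
        wins <- extractUpstream(bundle, hm$tss,
                                as.character(BiocGenerics::strand(hm)))
        model <- fitPromoterModel(wins)
        proms <- callPromoters(bundle, tus, model)
        tus <- refineUTRs(tus, proms)
        if (nrow(proms))
            spacers <- spacerStats(proms[!is.na(proms$tier), ,
                                         drop = FALSE])
        utils::write.table(as.data.frame(proms),
                           file.path(outdir, "promoters.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(as.data.frame(tus),
                       file.path(outdir, "tus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    ## --- motifs & terminators ------------------------------------------
    motifHits <- scanIupacMotif(bundle)
    utils::write.table(as.data.frame(motifHits),
                       file.path(outdir, "motif_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    terms <- classifyTerminators(tus, bundle)
    utils::write.table(as.data.frame(terms),
                       file.path(outdir, "terminators.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    ## --- codon usage by tier -------------------------------------------
    cdsOf <- function(gr) {
        s <- as.character(Biostrings::subseq(
            genomeSeq(bundle)[[1L]], BiocGenerics::start(gr),
            BiocGenerics::end(gr)))
        if (as.character(BiocGenerics::strand(gr)) == "-")
            revcompChr(s) else s
    }
    gc3ByTier <- sapply(c("high", "medium", "low", "silent"),
        function(t) {
            idx <- which(genes$tier == t)
            if (!length(idx)) return(NA_real_)
            mean(vapply(idx, function(i)
                baseComposition(cdsOf(genes[i]))[["gc3"]], numeric(1)))
        })
    pooledCounts <- function(t) {
        idx <- which(genes$tier == t)
        if (!length(idx)) return(NULL)
        Reduce(`+`, lapply(idx, function(i) codonCounts(cdsOf(genes[i]))))
    }
    highCounts <- pooledCounts("high")
    lowCounts <- pooledCounts(if (any(genes$tier == "low")) "low"
                              else "silent")
    chisq <- if (!is.null(highCounts) && !is.null(lowCounts))
        rscuChisq(highCounts, lowCounts) else NULL

    ## --- carriage differential expression ------------------------------
    csim <- simulateCounts(design)
    dge <- callDEGs(csim$counts, csim$lengths, csim$condition)
    utils::write.table(as.data.frame(dge$records),
                       file.path(outdir, "dge.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    ## --- report ---------------------------------------------------------
    tierTab <- table(factor(tiers, levels = TIER_LEVELS))
    termTab <- table(factor(terms$class, levels = TERMINATOR_CLASSES))
    utr5ByTier <- sapply(c("high", "medium"), function(t) {
        v <- tus$utr5_len[tus$tier == t & !is.na(tus$utr5_len)]
        if (length(v)) mean(v) else NA_real_
    })
    kv <- c(
        stats::setNames(as.integer(tierTab),
                        paste0("n_genes_", names(tierTab))),
        n_tus = length(tus),
        if (!is.null(spacers))
            stats::setNames(spacers$mode,
                            paste0("spacer_mode_", names(spacers$mode))),
        stats::setNames(round(as.integer(termTab) / max(1L, length(tus)),
                              4),
                        paste0("frac_term_", names(termTab))),
        stats::setNames(round(utr5ByTier, 2),
                        paste0("mean_utr5_", names(utr5ByTier))),
        n_regulon_motif_hits = nrow(as.data.frame(motifHits)),
        n_regulon_genes = length(unique(as.data.frame(motifHits)$gene_id)),
        gc3_high = round(gc3ByTier[["high"]], 4),
        gc3_low = round(gc3ByTier[["low"]], 4),
        chisq_p_high_vs_low = if (!is.null(chisq))
            signif(chisq$p.value, 4) else NA,
        n_deg_up = unname(dge$summary["n_up"]),
        n_deg_down = unname(dge$summary["n_down"]))
    reportPath <- file.path(outdir, "report.tsv")
    header <- c(sprintf("# plasmidtx %s", version),
                sprintf("# seed %d", as.integer(seed)),
                sprintf("# genomeLength %d nGenes %d designGenes %d",
                        params@genomeLength, params@nGenes,
                        design@nGenes))
    writeLines(c(header, "key\tvalue",
                 sprintf("%s\t%s", names(kv), unlist(kv))), reportPath)

    invisible(list(bundle = bundle, truth = truth, coverage = cov,
                   expression = se, tus = tus, model = model,
                   promoters = proms, spacers = spacers,
                   motifHits = motifHits, terminators = terms,
                   codon = list(gc3_by_tier = gc3ByTier, chisq = chisq),
                   dge = dge, report = kv))
}

#' Validate pipeline input files
#'
#' Conformance checks for the on-disk formats the pipeline consumes:
#' FASTA (readable, non-empty), GFF3 (9 columns, end >= start, strand
#' `+`/`-`), bedGraph (4 columns, non-negative scores, no overlapping
#' intervals) and counts TSV (gene_id column plus non-negative numeric
#' sample columns). Files given as `NULL` are skipped.
#'
#' @param fasta,gff,bedgraphPlus,bedgraphMinus,counts file paths (or
#'   `NULL`).
#' @return character vector of human-readable violations; empty when all
#'   supplied files conform.
#' @export
validateInputs <- function(fasta = NULL, gff = NULL, bedgraphPlus = NULL,
                           bedgraphMinus = NULL, counts = NULL) {
    bad <- character(0)
    note <- function(...) bad <<- c(bad, sprintf(...))
    if (!is.null(fasta)) {
        seqs <- tryCatch(Biostrings::readDNAStringSet(fasta),
                         error = function(e) NULL)
        if (is.null(seqs) || !length(seqs))
            note("fasta: %s unreadable or empty", fasta)
    }
    if (!is.null(gff)) {
        df <- tryCatch(
            utils::read.delim(gff, header = FALSE, comment.char = "#"),
            error = function(e) NULL)
        if (is.null(df) || ncol(df) < 9L) {
            note("gff3: %s unreadable or not 9 columns", gff)
        } else {
            if (any(df[[5L]] < df[[4L]]))
                note("gff3: end < start in %d record(s)",
                     sum(df[[5L]] < df[[4L]]))
            if (any(!df[[7L]] %in% c("+", "-")))
                note("gff3: invalid strand symbol in %d record(s)",
                     sum(!df[[7L]] %in% c("+", "-")))
        }
    }
    for (bg in c(bedgraphPlus, bedgraphMinus)) {
        lines <- tryCatch(readLines(bg), error = function(e) NULL)
        if (!is.null(lines))
            lines <- lines[!grepl("^(track|#)", lines) &
                           nzchar(lines)]
        df <- if (is.null(lines) || !length(lines)) NULL else
            tryCatch(utils::read.table(text = lines, header = FALSE),
                     error = function(e) NULL)
        if (is.null(df) || ncol(df) < 4L) {
            note("bedGraph: %s unreadable or not 4 columns", bg)
            next
        }
        st <- as.integer(df[[2L]]); en <- as.integer(df[[3L]])
        if (any(en <= st))
            note("bedGraph: %s has %d empty/inverted interval(s)",
                 bg, sum(en <= st))
        if (any(as.numeric(df[[4L]]) < 0))
            note("bedGraph: %s has negative score(s)", bg)
        for (ctg in unique(df[[1L]])) {
            i <- df[[1L]] == ctg
            o <- order(st[i])
            if (any(st[i][o][-1L] < en[i][o][-sum(i)]))
                note("bedGraph: %s has overlapping intervals on %s",
                     bg, ctg)
        }
    }
    if (!is.null(counts)) {
        m <- tryCatch(readCounts(counts), error = function(e) NULL)
        if (is.null(m))
            note("counts: %s unreadable", counts)
        else if (any(m < 0, na.rm = TRUE))
            note("counts: %s has negative values", counts)
    }
    bad
}
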