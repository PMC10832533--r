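#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

DNA_BASES_CHR <- c("A", "C", "G", "T")
TIER_LEVELS <- c("silent", "low", "medium", "high")
SPACER_RANGE <- 15:19
TERMINATOR_CLASSES <- c("rho_independent", "stem_loop", "convergent", "none")

#' Parameters for the synthetic plasmid generator
#'
#' Container for all tunables of [simulatePlasmid()]. Construct with
#' [genParams()], which supplies field-level defaults and validation.
#'
#' @slot genomeLength single integer, genome size in nt.
#' @slot gcContent background GC fraction of intergenic sequence.
#' @slot nGenes number of genes to place.
#' @slot tierProportions named fractions over
#'   `c("high","medium","low","silent")`; must sum to 1.
#' @slot promoterFidelity named integer vector, maximum number of mismatches
#'   to the TTGACA/TATAAT consensus allowed per expression tier.
#' @slot spacerDist 3 x 5 matrix (rows `high`, `medium`, `low`; columns
#'   spacer lengths 15--19 nt) of spacer-length probabilities; rows sum to 1.
#' @slot terminatorMix named fractions over terminator classes
#'   `c("rho_independent","stem_loop","convergent")`.
#' @slot motifCount number of 34 bp regulon motif instances to plant over
#'   the -10 elements of distinct high-tier genes.
#' @slot seed integer RNG seed.
#' @seealso [simulatePlasmid()]
#' @exportClass GenParams
setClass("GenParams",
    representation(
        genomeLength = "integer",
        gcContent = "numeric",
        nGenes = "integer",
        tierProportions = "numeric",
        promoterFidelity = "integer",
        spacerDist = "matrix",
        terminatorMix = "numeric",
        motifCount = "integer",
        seed = "integer"
    )
)

setValidity("GenParams", function(object) {
    msg <- NULL
    if (object@genomeLength < 2000L)
        msg <- c(msg, "genomeLength must be >= 2000 nt")
    if (object@gcContent <= 0 || object@gcContent >= 1)
        msg <- c(msg, "gcContent must be in (0, 1)")
    tp <- object@tierProportions
    if (!identical(sort(names(tp)), sort(TIER_LEVELS)))
        msg <- c(msg, "tierProportions must be named over silent/low/medium/high")
    else if (abs(sum(tp) - 1) > 1e-9)
        msg <- c(msg, "tierProportions must sum to 1")
    sd <- object@spacerDist
    if (!identical(dim(sd), c(3L, 5L)))
        msg <- c(msg, "spacerDist must be a 3 x 5 matrix (tiers x spacer 15..19)")
    else if (any(abs(rowSums(sd) - 1) > 1e-9))
        msg <- c(msg, "spacerDist rows must sum to 1")
    tm <- object@terminatorMix
    if (abs(sum(tm) - 1) > 1e-9)
        msg <- c(msg, "terminatorMix must sum to 1")
    if (is.null(msg)) TRUE else msg
})

#' Design of a planted two-condition count experiment
#'
#' Construct with [countDesign()]. Defaults mirror a chromosome-scale
#' plasmid-carriage comparison: 1864 genes, three biological replicates per
#' condition, 127 genes planted up-regulated and 30 down-regulated at
#' |log2 fold change| = 2, with negative-binomial dispersion 0.1.
#'
#' @slot nGenes number of genes.
#' @slot replicates biological replicates per condition (>= 2).
#' @slot nbDispersion negative-binomial dispersion (size = 1/dispersion).
#' @slot nUp,nDown numbers of planted up-/down-regulated genes.
#' @slot effectLog2fc planted |log2 fold change| of affected genes.
#' @slot seed integer RNG seed.
#' @seealso [simulateCounts()]
#' @exportClass CountDesign
setClass("CountDesign",
    representation(
        nGenes = "integer",
        replicates = "integer",
        nbDispersion = "numeric",
        nUp = "integer",
        nDown = "integer",
        effectLog2fc = "numeric",
        seed = "integer"
    )
)

setValidity("CountDesign", function(object) {
    msg <- NULL
    if (object@replicates < 2L)
        msg <- c(msg, "replicates must be >= 2")
    if (object@nUp + object@nDown > object@nGenes)
        msg <- c(msg, "nUp + nDown must be <= nGenes")
    if (object@nbDispersion <= 0)
        msg <- c(msg, "nbDispersion must be > 0")
    if (is.null(msg)) TRUE else msg
})

#' Genome sequence plus stranded gene annotation
#'
#' Lightweight container pairing a single-contig genome with its gene
#' features, the unit consumed by quantification, boundary mapping and
#' regulatory-element scanning.
#'
#' @slot seq a [Biostrings::DNAStringSet] of length 1 (the contig).
#' @slot genes a [GenomicRanges::GRanges] with mcols `gene_id` (character);
#'   1-based inclusive coordinates, strand `+`/`-`.
#' @slot circular logical; if `TRUE`, windows may wrap the origin.
#' @seealso [genomeBundle()], [simulatePlasmid()], [readGenomeBundle()]
#' @exportClass GenomeBundle
setClass("GenomeBundle",
    representation(
        seq = "DNAStringSet",
        genes = "GRanges",
        circular = "logical"
    )
)

setValidity("GenomeBundle", function(object) {
    msg <- NULL
    if (length(object@seq) != 1L)
        msg <- c(msg, "seq must contain exactly one contig")
    if (!"gene_id" %in% names(S4Vectors::mcols(object@genes)))
        msg <- c(msg, "genes must carry an mcols column 'gene_id'")
    else if (anyDuplicated(object@genes$gene_id))
        msg <- c(msg, "gene_id values must be unique")
    if (length(object@genes) &&
        max(BiocGenerics::end(object@genes)) > Biostrings::width(object@seq)[1L])
        msg <- c(msg, "gene coordinates exceed genome length")
    if (length(object@genes) && any(BiocGenerics::strand(object@genes) == "*"))
        msg <- c(msg, "all genes must be stranded (+/-)")
    if (is.null(msg)) TRUE else msg
})

#' Strand-specific per-base sequencing depth
#'
#' Per-base coverage over a single contig, one run-length-encoded vector per
#' strand, as imported from a pair of bedGraph files or produced by
#' [simulateCoverage()].
#'
#' @slot plus,minus [S4Vectors::Rle] numeric vectors of identical length
#'   (the genome length), depth at each base.
#' @slot seqname contig name.
#' @seealso [simulateCoverage()], [readCoverage()], [detectTSS()]
#' @exportClass CoverageTrack
setClass("CoverageTrack",
    representation(plus = "Rle", minus = "Rle", seqname = "character")
)

setValidity("CoverageTrack", function(object) {
    msg <- NULL
    if (length(object@plus) != length(object@minus))
        msg <- c(msg, "plus and minus tracks must have equal length")
    if (any(S4Vectors::runValue(object@plus) < 0) ||
        any(S4Vectors::runValue(object@minus) < 0))
        msg <- c(msg, "coverage must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' Bipartite -35/spacer/-10 promoter model
#'
#' Position-weight matrices for the two hexamers plus a prior over the
#' 15--19 nt spacer, fitted by constrained expectation-maximisation
#' ([fitPromoterModel()]) and used for scanning ([scanPromoter()]).
#'
#' @slot pwm35,pwm10 4 x 6 column-stochastic matrices (rows A,C,G,T).
#' @slot spacerPrior probabilities over spacer lengths 15--19.
#' @slot background genome base frequencies (A,C,G,T).
#' @slot converged logical, EM convergence flag.
#' @slot iterations EM iterations run.
#' @slot objective trace of the EM objective (sum of best placement
#'   log-odds), non-decreasing.
#' @slot informative `FALSE` when the fitted PWMs carry little information
#'   (mean column information content < 0.5 bits), e.g. on random input.
#' @exportClass PromoterModel
setClass("PromoterModel",
    representation(
        pwm35 = "matrix",
        pwm10 = "matrix",
        spacerPrior = "numeric",
        background = "numeric",
        converged = "logical",
        iterations = "integer",
        objective = "numeric",
        informative = "logical"
    )
)

setValidity("PromoterModel", function(object) {
    msg <- NULL
    for (nm in c("pwm35", "pwm10")) {
        m <- slot(object, nm)
        if (!identical(dim(m), c(4L, 6L)))
            msg <- c(msg, sprintf("%s must be 4 x 6", nm))
        else if (any(abs(colSums(m) - 1) > 1e-6))
            msg <- c(msg, sprintf("%s columns must sum to 1", nm))
    }
    if (abs(sum(object@spacerPrior) - 1) > 1e-6)
        msg <- c(msg, "spacerPrior must sum to 1")
    if (is.null(msg)) TRUE else msg
})

#' Ground truth of a synthetic genome and count experiment
#'
#' Records every planted feature so that recovery can be scored exactly:
#' per-gene tier, transcript boundaries, promoter architecture and
#' terminator class; planted regulon-motif instances; and, for simulated
#' count experiments, per-gene planted log2 fold changes and direction.
#'
#' @slot genes [S4Vectors::DataFrame], one row per gene: `gene_id`,
#'   `tier`, `strand`, `start`, `end`, `tss`, `tts`, `minus35`,
#'   `spacer_len`, `minus10`, `minus10_end` (genomic 3' end of the -10
#'   hexamer in reading orientation), `terminator_class`.
#' @slot motifs [S4Vectors::DataFrame]: `gene_id`, `start`, `end`, `strand`,
#'   `sequence` of each planted 34 bp motif instance.
#' @slot degs [S4Vectors::DataFrame]: `gene_id`, `log2fc`, `direction`
#'   (`up`/`down`/`null`) for simulated count experiments.
#' @slot params list of generator parameters (including the seed).
#' @exportClass TruthSet
setClass("TruthSet",
    representation(
        genes = "DataFrame",
        motifs = "DataFrame",
        degs = "DataFrame",
        params = "list"
    )
)

setMethod("show", "GenParams", function(object) {
    cat("GenParams\n")
    cat("  genome:", object@genomeLength, "nt, GC",
        format(object@gcContent), "\n")
    cat("  genes:", object@nGenes, "| tiers:",
        paste(sprintf("%s=%.2f", names(object@tierProportions),
                      object@tierProportions), collapse = " "), "\n")
    cat("  motifs planted:", object@motifCount, "| seed:", object@seed, "\n")
})

setMethod("show", "GenomeBundle", function(object) {
    cat("GenomeBundle:", names(object@seq)[1L], "\n")
    cat("  length:", Biostrings::width(object@seq)[1L], "nt",
        if (object@circular) "(circular)" else "(linear)", "\n")
    cat("  genes:", length(object@genes), "\n")
})

setMethod("show", "CoverageTrack", function(object) {
    cat("CoverageTrack:", object@seqname, "(", length(object@plus), "nt )\n")
    cat("  mean depth +:", round(mean(object@plus), 2),
        " -:", round(mean(object@minus), 2), "\n")
})

setMethod("show", "PromoterModel", function(object) {
    cat("PromoterModel (", if (object@converged) "converged" else
        "not converged", "after", object@iterations, "iterations )\n")
    cat("  consensus:", pwmConsensus(object@pwm35), "- n(15..19) -",
        pwmConsensus(object@pwm10), "\n")
    cat("  spacer prior:",
        paste(sprintf("%d:%.2f", SPACER_RANGE, object@spacerPrior),
              collapse = " "), "\n")
})

setMethod("show", "TruthSet", function(object) {
    cat("TruthSet\n")
    cat("  genes:", nrow(object@genes), "| planted motifs:",
        nrow(object@motifs), "| DEG labels:", nrow(object@degs), "\n")
})
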