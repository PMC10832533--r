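#' Accessors for plasmidtx containers
#'
#' Slot accessors for [GenomeBundle-class], [CoverageTrack-class] and
#' [TruthSet-class] objects; user code should use these rather than `@`.
#'
#' @param x a plasmidtx container object.
#' @param strand `"+"` or `"-"` for [strandCoverage()].
#' @return the requested component: a `DNAStringSet` / `GRanges` / `Rle` /
#'   `DataFrame` depending on the accessor.
#' @examples
#' sim <- simulatePlasmid(genParams(seed = 1))
#' genomeSeq(sim$bundle)
#' head(geneRanges(sim$bundle))
#' head(truthGenes(sim$truth))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setMethod("genomeSeq", "GenomeBundle", function(x) x@seq)

#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname accessors
#' @export
setMethod("geneRanges", "GenomeBundle", function(x) x@genes)

#' @rdname accessors
#' @export
isCircularGenome <- function(x) {
    stopifnot(is(x, "GenomeBundle"))
    x@circular
}

#' @rdname accessors
#' @export
setGeneric("strandCoverage", function(x, strand) {
    standardGeneric("strandCoverage")
})
#' @rdname accessors
#' @export
setMethod("strandCoverage", "CoverageTrack", function(x, strand) {
    strand <- match.arg(strand, c("+", "-"))
    if (strand == "+") x@plus else x@minus
})

#' @rdname accessors
#' @export
setGeneric("truthGenes", function(x) standardGeneric("truthGenes"))
#' @rdname accessors
#' @export
setMethod("truthGenes", "TruthSet", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("truthMotifs", function(x) standardGeneric("truthMotifs"))
#' @rdname accessors
#' @export
setMethod("truthMotifs", "TruthSet", function(x) x@motifs)

#' @rdname accessors
#' @export
setGeneric("truthDEGs", function(x) standardGeneric("truthDEGs"))
#' @rdname accessors
#' @export
setMethod("truthDEGs", "TruthSet", function(x) x@degs)

## majority-rule consensus string of a column-stochastic PWM (rows A,C,G,T)
pwmConsensus <- function(pwm) {
    paste(rownames(pwm)[apply(pwm, 2L, which.max)], collapse = "")
}
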