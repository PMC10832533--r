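## Readers and writers for the standard on-disk formats: FASTA + GFF3 for
## the genome bundle, one bedGraph per strand for coverage, TSV for counts,
## JSON for the ground truth.

#' Write / read a genome bundle as FASTA + GFF3
#'
#' The genome is written 70 columns wide; genes are written as GFF3
#' `gene` features (1-based inclusive, strand `+`/`-`) with `ID` and any
#' further mcols as attributes.
#'
#' @param bundle a [GenomeBundle-class].
#' @param fasta,gff file paths.
#' @param circular logical passed to the reconstructed bundle.
#' @return `writeGenomeBundle()` returns the paths invisibly;
#'   `readGenomeBundle()` returns a [GenomeBundle-class].
#' @examples
#' sim <- simulatePlasmid(genParams(seed = 1))
#' fa <- tempfile(fileext = ".fasta"); gf <- tempfile(fileext = ".gff3")
#' writeGenomeBundle(sim$bundle, fa, gf)
#' readGenomeBundle(fa, gf)
#' @export
writeGenomeBundle <- function(bundle, fasta, gff) {
    stopifnot(is(bundle, "GenomeBundle"))
    Biostrings::writeXStringSet(genomeSeq(bundle), fasta, width = 70L)
    gr <- geneRanges(bundle)
    gr$type <- "gene"
    gr$ID <- gr$gene_id
    rtracklayer::export(gr, gff, format = "gff3")
    invisible(c(fasta = fasta, gff = gff))
}

#' @rdname writeGenomeBundle
#' @export
readGenomeBundle <- function(fasta, gff, circular = FALSE) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    gr <- rtracklayer::import(gff, format = "gff3")
    gr <- gr[gr$type == "gene"]
    if (is.null(gr$gene_id))
        gr$gene_id <- gr$ID
    S4Vectors::mcols(gr) <-
        S4Vectors::mcols(gr)[, intersect(c("gene_id", "tier"),
                                         names(S4Vectors::mcols(gr))),
                             drop = FALSE]
    new("GenomeBundle", seq = seqs, genes = gr, circular = circular)
}

#' Write / read strand-specific coverage as bedGraph
#'
#' One bedGraph file per strand (0-based half-open on disk, as usual for
#' the format); zero-depth runs are omitted on write and restored as zeros
#' on read.
#'
#' @param track a [CoverageTrack-class].
#' @param plusFile,minusFile bedGraph paths for the two strands.
#' @param genomeLength genome length in nt (read side).
#' @param seqname contig name (read side; defaults to the name found in
#'   the plus-strand file).
#' @return `writeCoverage()` returns the paths invisibly;
#'   `readCoverage()` returns a [CoverageTrack-class].
#' @examples
#' tr <- coverageTrack(c(0, 3, 3, 0), c(1, 1, 0, 0), "ctg")
#' fp <- tempfile(); fm <- tempfile()
#' writeCoverage(tr, fp, fm)
#' readCoverage(fp, fm, genomeLength = 4)
#' @export
writeCoverage <- function(track, plusFile, minusFile) {
    stopifnot(is(track, "CoverageTrack"))
    writeOne <- function(rle, path) {
        gr <- GenomicRanges::GRanges(track@seqname,
            IRanges::IRanges(start = cumsum(c(1L,
                utils::head(S4Vectors::runLength(rle), -1L))),
                width = S4Vectors::runLength(rle)),
            score = S4Vectors::runValue(rle))
        gr <- gr[gr$score > 0]
        rtracklayer::export(gr, path, format = "bedGraph")
    }
    writeOne(track@plus, plusFile)
    writeOne(track@minus, minusFile)
    invisible(c(plus = plusFile, minus = minusFile))
}

#' @rdname writeCoverage
#' @export
readCoverage <- function(plusFile, minusFile, genomeLength,
                         seqname = NULL) {
    readOne <- function(path) {
        gr <- rtracklayer::import(path, format = "bedGraph")
        v <- numeric(genomeLength)
        if (length(gr)) {
            for (i in seq_along(gr))
                v[BiocGenerics::start(gr)[i]:BiocGenerics::end(gr)[i]] <-
                    gr$score[i]
        }
        list(v = v, seqname = if (length(gr))
            as.character(GenomicRanges::seqnames(gr))[1L] else "contig")
    }
    p <- readOne(plusFile)
    m <- readOne(minusFile)
    new("CoverageTrack", plus = S4Vectors::Rle(p$v),
        minus = S4Vectors::Rle(m$v),
        seqname = if (is.null(seqname)) p$seqname else seqname)
}

#' Write / read a gene-level count table
#'
#' Plain TSV with a `gene_id` column followed by one column per sample.
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param path TSV path.
#' @return `writeCounts()` returns `path` invisibly; `readCounts()`
#'   returns an integer matrix with gene ids as rownames.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' f <- tempfile(fileext = ".tsv")
#' writeCounts(m, f)
#' readCounts(f)
#' @export
writeCounts <- function(counts, path) {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCounts
#' @export
readCounts <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$gene_id
    storage.mode(m) <- "integer"
    m
}

#' Write / read a TruthSet as JSON
#'
#' @param truth a [TruthSet-class].
#' @param path JSON path.
#' @return `writeTruth()` returns `path` invisibly; `readTruth()` returns
#'   a [TruthSet-class].
#' @examples
#' sim <- simulateCounts(countDesign(nGenes = 10, nUp = 2, nDown = 1))
#' f <- tempfile(fileext = ".json")
#' writeTruth(sim$truth, f)
#' readTruth(f)
#' @export
writeTruth <- function(truth, path) {
    stopifnot(is(truth, "TruthSet"))
    obj <- list(genes = as.data.frame(truthGenes(truth)),
                motifs = as.data.frame(truthMotifs(truth)),
                degs = as.data.frame(truthDEGs(truth)),
                params = truth@params)
    jsonlite::write_json(obj, path, digits = NA, na = "null",
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    asDF <- function(x) {
        if (is.null(x) || (is.data.frame(x) && nrow(x) == 0) ||
            length(x) == 0)
            S4Vectors::DataFrame()
        else S4Vectors::DataFrame(x)
    }
    new("TruthSet", genes = asDF(obj$genes), motifs = asDF(obj$motifs),
        degs = asDF(obj$degs),
        params = if (is.null(obj$params)) list() else obj$params)
}
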