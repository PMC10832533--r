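## Internal helpers shared across modules.

## Run `code` under a fixed RNG state, restoring the caller's state after.
## All user-facing simulators funnel their `seed` argument through here so
## generation is a pure function of (parameters, seed).
withSeed <- function(seed, code) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

## i.i.d. background sequence at a given GC content
randomDNA <- function(n, gc) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(DNA_BASES_CHR, n, replace = TRUE, prob = p), collapse = "")
}

revcompChr <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## single-base substitution away from the current base
mutateBases <- function(seq, positions) {
    chars <- strsplit(seq, "")[[1]]
    for (i in positions) {
        chars[i] <- sample(setdiff(DNA_BASES_CHR, chars[i]), 1L)
    }
    paste(chars, collapse = "")
}

stopifnotScalarNum <- function(x, name, min = -Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
        stop(sprintf("'%s' must be a single number >= %s", name, min))
    invisible(x)
}
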