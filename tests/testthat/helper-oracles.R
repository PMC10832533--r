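## Independent oracles used by the test suite. These deliberately avoid
## the package's own code paths.

## Benjamini-Hochberg step-up, written directly from the definition
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    q[o[m]] <- p[o[m]]
    for (i in (m - 1):1) {
        if (i == 0) break
        q[o[i]] <- min(p[o[i]] * m / i, q[o[i + 1]])
    }
    pmin(q, 1)
}

## Pearson chi-squared on a 2 x k table with the same <1-expected pooling
## rule as the implementation, computed from the textbook formula
chisqOracle <- function(a, b) {
    keep <- a + b > 0
    tab <- rbind(a[keep], b[keep])
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    low <- apply(expected, 2, min) < 1
    if (any(low))
        tab <- cbind(tab[, !low, drop = FALSE],
                     rowSums(tab[, low, drop = FALSE]))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - expected)^2 / expected)
    df <- ncol(tab) - 1
    list(statistic = stat, df = df,
         p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

## brute-force IUPAC scan: position-by-position set comparison
iupacScanOracle <- function(seq, pattern, maxMismatch) {
    sets <- list(A = "A", C = "C", G = "G", T = "T",
                 W = c("A", "T"), Y = c("C", "T"),
                 N = c("A", "C", "G", "T"))
    pc <- strsplit(pattern, "")[[1]]
    tc <- strsplit(seq, "")[[1]]
    L <- length(pc)
    hits <- integer(0)
    mms <- integer(0)
    if (length(tc) >= L) {
        for (i in 1:(length(tc) - L + 1)) {
            mm <- 0L
            for (j in 1:L)
                if (!(tc[i + j - 1] %in% sets[[pc[j]]])) mm <- mm + 1L
            if (mm <= maxMismatch) {
                hits <- c(hits, i)
                mms <- c(mms, mm)
            }
        }
    }
    data.frame(start = hits, mismatches = mms)
}

## Nussinov maximum base-pairing (Watson-Crick only, min loop 3)
nussinovOracle <- function(seq) {
    pairs <- c(A = "T", T = "A", G = "C", C = "G")
    s <- strsplit(seq, "")[[1]]
    n <- length(s)
    if (n < 5) return(0)
    M <- matrix(0L, n, n)
    for (len in 5:n) {
        for (i in 1:(n - len + 1)) {
            j <- i + len - 1
            best <- M[i, j - 1]
            for (k in i:(j - 4)) {
                if (pairs[s[k]] == s[j]) {
                    left <- if (k > i) M[i, k - 1] else 0L
                    inner <- if (k + 1 <= j - 1) M[k + 1, j - 1] else 0L
                    best <- max(best, left + inner + 1L)
                }
            }
            M[i, j] <- best
        }
    }
    M[1, n]
}

## random valid CDS (start codon, no internal stop, terminal stop)
randomCdsFixture <- function(nCodons, gc = 0.5) {
    stops <- c("TAA", "TAG", "TGA")
    sense <- setdiff(names(Biostrings::GENETIC_CODE), stops)
    p <- vapply(sense, function(cod) {
        prod(ifelse(strsplit(cod, "")[[1]] %in% c("G", "C"),
                    gc / 2, (1 - gc) / 2))
    }, numeric(1))
    body <- sample(sense, nCodons, replace = TRUE, prob = p)
    paste0("ATG", paste(body, collapse = ""), sample(stops, 1))
}
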