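# Independent plain-R dynamic-programming oracle for the affine-gap
# Smith-Waterman score. Written against the scoring definition only (gap of
# length L costs go + (L - 1) * ge, opening charged on the first gap
# residue); shares no code with the production aligner.
oracle_sw_score <- function(q, t, scheme = scoringScheme()) {
    S <- scheme@matrix
    go <- scheme@gapOpen; ge <- scheme@gapExtend
    qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
    n <- length(qc); m <- length(tc)
    NEG <- -1e9
    H <- matrix(0, n + 1, m + 1)
    E <- matrix(NEG, n + 1, m + 1)  # gap in query (consumes target)
    F <- matrix(NEG, n + 1, m + 1)  # gap in target (consumes query)
    best <- 0
    for (i in 2:(n + 1)) {
        for (j in 2:(m + 1)) {
            E[i, j] <- max(H[i, j - 1] - go, E[i, j - 1] - ge)
            F[i, j] <- max(H[i - 1, j] - go, F[i - 1, j] - ge)
            H[i, j] <- max(0,
                           H[i - 1, j - 1] + S[qc[i - 1], tc[j - 1]],
                           E[i, j], F[i, j])
            if (H[i, j] > best) best <- H[i, j]
        }
    }
    best
}

# Naive sliding-window canonical k-mer counter (independent of
# contigFeatures' Biostrings-based path).
naive_canonical_kmer_freq <- function(seq, k) {
    L <- nchar(seq)
    if (L < k) return(numeric(0))
    kmers <- substring(seq, seq_len(L - k + 1), seq_len(L - k + 1) + k - 1)
    kmers <- kmers[!grepl("N", kmers)]
    rc <- vapply(kmers, function(x)
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
        character(1), USE.NAMES = FALSE)
    canon <- ifelse(kmers <= rc, kmers, rc)
    tab <- table(canon)
    as.numeric(tab) / sum(tab) -> fr
    names(fr) <- names(tab)
    fr
}
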