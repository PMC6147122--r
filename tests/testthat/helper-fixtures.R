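# Shared fixtures, built in code. All randomness is seeded.

test_scheme <- function() scoringScheme()

test_root <- function() rootProtein()

# Deterministic random protein over the 20 standard residues.
rand_prot <- function(n, seed) randomProtein(n, seed = seed)

# A reverse-translated copy of the packaged root protein (1,650 nt).
test_gene <- function(seed = 3) {
    reverseTranslate(as.character(test_root()[[1]]), seed = seed)
}

aa_set <- function(x) {
    s <- Biostrings::AAStringSet(x)
    if (is.null(names(x))) names(s) <- sprintf("s%03d", seq_along(x))
    s
}

dna_set <- function(x) {
    s <- Biostrings::DNAStringSet(x)
    if (is.null(names(x))) names(s) <- sprintf("r%03d", seq_along(x))
    s
}

rand_dna <- function(n, seed) {
    withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = ""))
}

revcomp <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Identity of a consensus against its planted gene: local alignment, either
# orientation (the assembler is strand-agnostic).
consensus_identity <- function(cons, gene) {
    sc <- dnaScoringScheme()
    max(localAlign(cons, gene, sc)@identityFraction,
        localAlign(revcomp(cons), gene, sc)@identityFraction)
}
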