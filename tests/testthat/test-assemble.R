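test_that("two overlapping reads merge; non-overlapping reads stay apart", {
    withr::with_seed(41, {
        g <- paste(sample(c("A", "C", "G", "T"), 250, replace = TRUE),
                   collapse = "")
    })
    reads <- dna_set(c(r1 = substr(g, 1, 150), r2 = substr(g, 101, 250)))
    ctgs <- assembleGeneReads(reads)
    expect_length(ctgs, 1)
    expect_identical(as.character(consensus(ctgs[[1]])), g)
    expect_length(filterContigs(ctgs), 0)  # 250 nt < 1,000 nt gate

    far <- dna_set(c(a = rand_dna(150, 42), b = rand_dna(150, 43)))
    ctgs2 <- assembleGeneReads(far)
    expect_length(ctgs2, 2)
})

test_that("error-free tiled reads reassemble the gene exactly", {
    for (glen in c(450L, 900L)) {
        g <- substr(test_gene(), 1, glen)
        starts <- unique(c(seq(1L, glen - 150L + 1L, by = 60L),
                           glen - 150L + 1L))
        reads <- dna_set(vapply(starts, function(s)
            substr(g, s, s + 149L), character(1)))
        ctgs <- assembleGeneReads(reads)
        expect_length(ctgs, 1)
        cons <- as.character(consensus(ctgs[[1]]))
        expect_true(cons == g || revcomp(cons) == g)
        expect_identical(max(ctgs[[1]]@depth) >= 2L, TRUE)
    }
})

test_that("read order changes ids at most, not consensus sequences", {
    g <- substr(test_gene(), 1, 600)
    starts <- seq(1L, 451L, by = 90L)
    reads <- dna_set(vapply(starts, function(s)
        substr(g, s, s + 149L), character(1)))
    c1 <- assembleGeneReads(reads)
    c2 <- assembleGeneReads(rev(reads))
    canon <- function(ctgs) sort(vapply(ctgs, function(x) {
        s <- as.character(consensus(x)); min(s, revcomp(s))
    }, character(1)))
    expect_identical(canon(c1), canon(c2))
})

test_that("every placement re-verifies at the overlap identity", {
    gene <- Biostrings::DNAStringSet(test_gene())
    names(gene) <- "g"
    rr <- simulateReads(gene, coverage = 8, readLen = 150,
                        errorRate = 0.005, seed = 44)
    ctgs <- assembleGeneReads(rr$reads)
    g <- ctgs[[1]]
    cons <- as.character(consensus(g))
    expect_identical(length(g@depth), nchar(cons))
    for (k in seq_len(nrow(g@members))) {
        m <- g@members[k, ]
        rs <- as.character(rr$reads[[m$read_id]])
        if (m$strand == "-") rs <- revcomp(rs)
        placed <- substr(cons, m$start + 1L, m$end)
        mm <- mean(strsplit(rs, "")[[1]] != strsplit(placed, "")[[1]])
        expect_lte(mm, 1 - 0.95)
    }
})

test_that("a noisy 10x read set reconstructs the planted gene", {
    gene <- Biostrings::DNAStringSet(test_gene())
    names(gene) <- "g"
    rr <- simulateReads(gene, coverage = 10, readLen = 150,
                        errorRate = 0.005, seed = 45)
    ctgs <- assembleGeneReads(rr$reads)
    expect_gt(length(consensus(ctgs[[1]])), 1000)
    expect_gte(consensus_identity(as.character(consensus(ctgs[[1]])),
                                  as.character(gene[[1]])), 0.99)
})

test_that("contig features match enumeration and a naive counter", {
    fe <- contigFeatures(dna_set(c(c1 = "GGCC")), k = 1)
    expect_equal(fe$table$gc, 1)
    expect_identical(fe$table$length, 4L)

    fe2 <- contigFeatures(dna_set(c(c1 = "ATAT")), k = 2)
    # windows AT, TA, AT; canonical classes AT (2) and TA (1)
    expect_equal(unname(fe2$kmerFreq[1, "AT"]), 2 / 3)
    expect_equal(unname(fe2$kmerFreq[1, "TA"]), 1 / 3)

    big <- rand_dna(10000, 46)
    fe3 <- contigFeatures(dna_set(c(c1 = big)), k = 4)
    expect_equal(sum(fe3$kmerFreq[1, ]), 1, tolerance = 1e-9)
    ref <- naive_canonical_kmer_freq(big, 4)
    expect_equal(fe3$kmerFreq[1, names(ref)], ref, tolerance = 1e-12)

    short <- contigFeatures(dna_set(c(s = "ACG")), k = 4)
    expect_true(short$table$short)
    expect_equal(sum(short$kmerFreq[1, ]), 0)
})

test_that("contig outputs land on disk with both FASTA tiers", {
    g <- substr(test_gene(), 1, 400)
    starts <- seq(1L, 251L, by = 50L)
    reads <- dna_set(vapply(starts, function(s)
        substr(g, s, s + 149L), character(1)))
    ctgs <- assembleGeneReads(reads, datasetId = "dsX")
    d <- tempfile()
    writeContigs(ctgs, d, minContigLen = 300L)
    expect_true(file.exists(file.path(d, "contigs.fasta")))
    allc <- readSequences(file.path(d, "contigs_all.fasta"))
    expect_gte(length(allc), 1)
})
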