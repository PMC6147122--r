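test_that("exact reads from a centroid's gene screen at identity 1", {
    root <- test_root()
    gene <- test_gene()
    withr::with_seed(12, {
        starts <- sample(seq_len(nchar(gene) - 150L), 10)
    })
    reads <- dna_set(vapply(starts, function(s)
        substr(gene, s, s + 149L), character(1)))
    h <- screenReads(reads, root)
    expect_identical(nrow(h), 10L)
    expect_true(all(h$identity == 1))
    expect_identical(attr(h, "screened"), 10L)
})

test_that("outgroup BSR arithmetic retains and removes as specified", {
    # marker 70 vs outgroup 100 at theta 0.8: bsr 0.7, removed
    root <- test_root()
    gene <- test_gene()
    reads <- dna_set(c(q1 = substr(gene, 100, 249)))
    hits <- screenReads(reads, root)
    # outgroup contains the marker itself: bsr = 1, retained at any theta
    fl <- outgroupBsrFilter(hits, reads, outgroupDb = root, theta = 1)
    expect_identical(names(fl$retained), "q1")
    expect_equal(fl$bsr$bsr, 1)
    # outgroup with no homolog at all: no outgroup hit, retained
    masked <- aa_set(c(none = strrep("X", 300)))
    fl2 <- outgroupBsrFilter(hits, reads, outgroupDb = masked, theta = 0.8)
    expect_identical(names(fl2$retained), "q1")
    expect_true(is.na(fl2$bsr$bsr))
    # synthetic score pair via a doctored hit table
    h3 <- hits; h3$raw_score <- 70L
    og <- root  # outgroup score will be the true full score (>70/0.8)
    fl3 <- outgroupBsrFilter(h3, reads, outgroupDb = og, theta = 0.8)
    expect_length(fl3$retained, 0)
    expect_lt(fl3$bsr$bsr, 0.8)
})

test_that("raising theta never grows the retained set", {
    bm <- spikeInBenchmark(seed = 9, nTargetReads = 40, nDecoyReads = 40,
                          nBackgroundReads = 150)
    hits <- screenReads(bm$reads, bm$markerDb)
    kept <- lapply(c(0.5, 0.8, 0.95), function(th)
        names(outgroupBsrFilter(hits, bm$reads, bm$outgroupDb,
                                theta = th)$retained))
    expect_true(all(kept[[2]] %in% kept[[1]]))
    expect_true(all(kept[[3]] %in% kept[[2]]))
})

test_that("the dataset gate is strict and coverage is arithmetic", {
    g <- datasetGate(21)
    expect_true(g$gatePassed)
    expect_equal(g$approxCoverage, 2.1)
    expect_false(datasetGate(20)$gatePassed)
    g0 <- datasetGate(0)
    expect_false(g0$gatePassed)
    expect_equal(g0$approxCoverage, 0)
})

test_that("screening a file equals screening the in-memory set, chunked", {
    root <- test_root()
    gene <- test_gene()
    withr::with_seed(13, {
        starts <- sample(seq_len(nchar(gene) - 150L), 12)
    })
    reads <- dna_set(vapply(starts, function(s)
        substr(gene, s, s + 149L), character(1)))
    f1 <- tempfile(fileext = ".fasta")
    writeSequences(reads, f1)
    h_mem <- screenReads(reads, root)
    h_file <- screenReads(f1, root, chunkSize = 5L)  # forces 3 chunks
    expect_identical(attr(h_file, "screened"), 12L)
    expect_equal(h_file[, colnames(h_mem)], h_mem, ignore_attr = TRUE)
    # concatenation of two files == union of the parts
    f2 <- tempfile(fileext = ".fasta")
    writeSequences(dna_set(setNames(as.character(reads), paste0("x_",
        names(reads)))), f2)
    fc <- tempfile(fileext = ".fasta")
    writeLines(c(readLines(f1), readLines(f2)), fc)
    h_cat <- screenReads(fc, root)
    expect_identical(nrow(h_cat), 2L * nrow(h_mem))
})

test_that("mineDataset assembles the counts and gate consistently", {
    bm <- spikeInBenchmark(seed = 14, nTargetReads = 30, nDecoyReads = 30,
                          nBackgroundReads = 100)
    ms <- mineDataset(bm$reads, bm$markerDb, bm$outgroupDb,
                      datasetId = "toy")
    cn <- ms@counts
    expect_identical(unname(cn["screened"]), 160L)
    expect_lte(cn["retained"], cn["hit"])
    expect_identical(ms@gatePassed, unname(cn["retained"]) > 20L)
    expect_true(all(names(retainedReads(ms)) %in% ms@hits$query_id))
    d <- tempfile()
    writeMinedReadSet(ms, d)
    expect_true(file.exists(file.path(d, "toy_retained.fasta")))
    expect_true(file.exists(file.path(d, "toy_summary.tsv")))
})
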