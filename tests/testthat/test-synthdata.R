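test_that("family simulation hits its nominal divergence", {
    root <- test_root()
    fam0 <- simulateFamily(root, 3, 0, seed = 201, topology = "star")
    expect_true(all(as.character(fam0$members) ==
                        as.character(root[[1]])))

    p <- rand_prot(500, seed = 202)
    fam <- simulateFamily(p, 5, 0.2, seed = 203, topology = "star")
    for (m in as.character(fam$members)) {
        d <- mean(strsplit(m, "")[[1]] != strsplit(p, "")[[1]])
        expect_gte(d, 0.16)  # binomial concentration around 0.2
        expect_lte(d, 0.24)
    }

    fam_a <- simulateFamily(p, 5, 0.2, seed = 204, topology = "star")
    fam_b <- simulateFamily(p, 5, 0.2, seed = 205, topology = "star")
    expect_false(identical(as.character(fam_a$members),
                           as.character(fam_b$members)))
    fam_a2 <- simulateFamily(p, 5, 0.2, seed = 204, topology = "star")
    expect_identical(as.character(fam_a$members),
                     as.character(fam_a2$members))  # per-seed determinism
})

test_that("tree families stay inside the divergence envelope", {
    root <- test_root()
    fam <- simulateFamily(root, 30, c(0.2, 0.6), seed = 206,
                          topology = "tree")
    expect_true(all(fam$rootDivergence <= 0.6 + 1e-9))
    expect_true(all(fam$rootDivergence >= 0.1))
    pw <- fam$pairwiseDivergence
    expect_true(isSymmetric(pw))
    expect_true(all(diag(pw) == 0))
})

test_that("reverse translation is a left inverse of translation", {
    expect_identical(reverseTranslate("M"), "ATG")
    expect_identical(reverseTranslate("W"), "TGG")
    p <- rand_prot(300, seed = 207)
    g <- reverseTranslate(p, seed = 208)
    expect_identical(translateSeq(g, 1), p)
    expect_identical(reverseTranslate("O"), "TAG")
    expect_error(reverseTranslate("MK*V"))
})

test_that("read simulation respects counts, intervals and error rate", {
    gene <- Biostrings::DNAStringSet(substr(test_gene(), 1, 1500))
    names(gene) <- "g"
    rr <- simulateReads(gene, coverage = 10, readLen = 150,
                        errorRate = 0, seed = 209)
    expect_identical(length(rr$reads), 100L)  # round(10 * 1500 / 150)
    expect_identical(nrow(rr$truth), 100L)
    gs <- as.character(gene[[1]])
    for (k in seq_len(nrow(rr$truth))) {
        t <- rr$truth[k, ]
        frag <- substr(gs, t$start + 1L, t$end)
        got <- as.character(rr$reads[[t$read_id]])
        expect_identical(if (t$strand == "-") revcomp(got) else got, frag)
    }

    rr2 <- simulateReads(gene, coverage = 20, readLen = 150,
                         errorRate = 0.005, seed = 210)
    mm <- vapply(seq_len(nrow(rr2$truth)), function(k) {
        t <- rr2$truth[k, ]
        frag <- substr(gs, t$start + 1L, t$end)
        got <- as.character(rr2$reads[[t$read_id]])
        if (t$strand == "-") got <- revcomp(got)
        sum(strsplit(got, "")[[1]] != strsplit(frag, "")[[1]])
    }, numeric(1))
    pooled <- sum(mm) / (length(mm) * 150)
    expect_gte(pooled, 0.003)
    expect_lte(pooled, 0.007)

    # a gene shorter than the read length yields flagged whole-gene reads
    tiny <- Biostrings::DNAStringSet(c(t1 = substr(test_gene(), 1, 90)))
    rr3 <- simulateReads(tiny, coverage = 10, readLen = 150,
                         errorRate = 0, seed = 211)
    expect_true(all(rr3$truth$short))
    expect_true(all(width(rr3$reads) == 90L))
})

test_that("truth-table scoring gives exact precision and recall", {
    truth <- data.frame(
        read_id = sprintf("r%02d", 1:10),
        origin = rep(c("target", "decoy"), each = 5),
        stringsAsFactors = FALSE)
    ev <- evaluateAgainstTruth(sprintf("r%02d", 1:5), truth)
    expect_equal(ev$precision, 1)
    expect_equal(ev$recall, 1)
    ev2 <- evaluateAgainstTruth(character(0), truth)
    expect_true(is.na(ev2$precision))
    expect_equal(ev2$recall, 0)
    ev3 <- evaluateAgainstTruth(c("r01", "r06"), truth)
    expect_equal(ev3$precision, 0.5)
    expect_equal(ev3$recall, 0.2)
    expect_error(evaluateAgainstTruth("nope", truth), "not in truth")
})

test_that("SimConfig validates and survives the JSON round trip", {
    cfg <- simConfig(7, nFamily = 10L, errorRate = 0.01)
    expect_s3_class(cfg, "SimConfig")
    expect_error(simConfig(7, errorRate = 1.2))
    tf <- tempfile(fileext = ".json")
    writeSimConfig(cfg, tf)
    back <- readSimConfig(tf)
    expect_equal(back$errorRate, 0.01)
    expect_identical(back$nFamily, 10L)
})

test_that("the spike-in benchmark is deterministic per seed", {
    b1 <- spikeInBenchmark(seed = 212, nTargetReads = 10, nDecoyReads = 10,
                           nBackgroundReads = 20, nBackgroundGenes = 5)
    b2 <- spikeInBenchmark(seed = 212, nTargetReads = 10, nDecoyReads = 10,
                           nBackgroundReads = 20, nBackgroundGenes = 5)
    expect_identical(as.character(b1$reads), as.character(b2$reads))
    expect_identical(b1$truth, b2$truth)
})
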