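test_that("local alignment handles the elementary cases", {
    a <- localAlign("MKV", "MKV")
    expect_identical(rawScore(a), 14L)  # 5 + 5 + 4 on BLOSUM62
    expect_equal(identityFraction(a), 1)
    expect_identical(a@columns, 3L)
    expect_equal(a@bitScore, (0.267 * 14 - log(0.041)) / log(2))

    b <- localAlign("AAAA", "CCCC")  # A-C scores 0: empty alignment
    expect_identical(rawScore(b), 0L)
    expect_identical(b@columns, 0L)
    expect_equal(identityFraction(b), 0)

    expect_error(localAlign("MKB", "MKV"), "alphabet")
    expect_error(localAlign("", "MKV"))
})

test_that("global identity uses alignment columns as denominator", {
    expect_equal(percentIdentity("MKVMKV", "MKV"), 0.5)
    expect_equal(percentIdentity("MKV", "MKV"), 1)
    p <- rand_prot(200, seed = 4)
    expect_equal(percentIdentity(p, p), 1)
})

test_that("production scores equal the independent DP oracle", {
    sch <- test_scheme()
    withr::with_seed(101, {
        for (i in 1:60) {
            q <- rand_prot(sample(10:60, 1), seed = NULL)
            t <- rand_prot(sample(10:60, 1), seed = NULL)
            expect_identical(localAlign(q, t, sch)@rawScore,
                             as.integer(oracle_sw_score(q, t, sch)))
        }
    })
})

test_that("scores agree with Biostrings pairwiseAlignment", {
    # independent cross-check against an established implementation; the
    # gap conventions differ (Biostrings charges opening + extension on the
    # first gap residue), so gapOpening = gapOpen - gapExtend
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    withr::with_seed(77, {
        for (i in 1:25) {
            q <- rand_prot(sample(20:80, 1), seed = NULL)
            t <- rand_prot(sample(20:80, 1), seed = NULL)
            pa <- Biostrings::pairwiseAlignment(
                q, t, type = "local", substitutionMatrix = e$BLOSUM62,
                gapOpening = 10, gapExtension = 1)
            expect_equal(localAlign(q, t)@rawScore,
                         as.integer(Biostrings::score(pa)))
            pg <- Biostrings::pairwiseAlignment(
                q, t, type = "global", substitutionMatrix = e$BLOSUM62,
                gapOpening = 10, gapExtension = 1)
            expect_equal(globalAlign(q, t)@rawScore,
                         as.integer(Biostrings::score(pg)))
        }
    })
})

test_that("score symmetry and self-maximality hold", {
    withr::with_seed(55, {
        for (i in 1:40) {
            a <- rand_prot(sample(10:70, 1), seed = NULL)
            b <- rand_prot(sample(10:70, 1), seed = NULL)
            sab <- localAlign(a, b)@rawScore
            expect_identical(sab, localAlign(b, a)@rawScore)
            expect_lte(sab, min(localAlign(a, a)@rawScore,
                                localAlign(b, b)@rawScore))
        }
    })
})

test_that("translated search recovers planted windows with frame", {
    root <- test_root()
    gene <- test_gene()
    # forward windows at offsets 0, 1, 2 map to frames 1, 3, 2
    for (p in 0:2) {
        read <- substr(gene, 241 + p, 390 + p)
        h <- translatedSearch(read, root)
        expect_equal(h$identity, 1)
        expect_identical(h$frame, c(1L, 3L, 2L)[p + 1])
    }
    # reverse-strand read
    h <- translatedSearch(revcomp(substr(gene, 241, 390)), root)
    expect_true(h$frame %in% c(-1L, -2L, -3L))
    expect_equal(h$identity, 1)
})

test_that("random reads rarely clear the default score threshold", {
    root <- test_root()
    withr::with_seed(31, {
        reads <- dna_set(vapply(1:200, function(i)
            paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                  collapse = ""), character(1)))
    })
    h <- screenReads(reads, root)
    expect_lte(nrow(h), 4)  # <= 2% of 200
})

test_that("the k-mer prefilter only drops noise the BSR filter removes", {
    bm <- spikeInBenchmark(seed = 5, nTargetReads = 40, nDecoyReads = 40,
                          nBackgroundReads = 150)
    h1 <- screenReads(bm$reads, bm$markerDb, prefilter = TRUE)
    h2 <- screenReads(bm$reads, bm$markerDb, prefilter = FALSE)
    # prefiltered hits are a subset and can never outscore the full search
    expect_true(all(h1$query_id %in% h2$query_id))
    m <- match(h1$query_id, h2$query_id)
    expect_true(all(h1$raw_score <= h2$raw_score[m]))
    # target-origin hits are found identically: 0.5% error reads always
    # share exact 4-mers with their source family, so the prefilter is
    # lossless where it matters
    tgt <- bm$truth$read_id[bm$truth$origin == "target"]
    expect_equal(h1[h1$query_id %in% tgt, ],
                 h2[h2$query_id %in% tgt, ], ignore_attr = TRUE)
    # after outgroup-BSR filtering the retained sets coincide: what the
    # prefilter drops is exactly what the outgroup comparison rejects
    r1 <- outgroupBsrFilter(h1, bm$reads, bm$outgroupDb, theta = 0.8)
    r2 <- outgroupBsrFilter(h2, bm$reads, bm$outgroupDb, theta = 0.8)
    expect_identical(sort(names(r1$retained)), sort(names(r2$retained)))
})

test_that("hit tables are written with 1-based inclusive coordinates", {
    root <- test_root()
    gene <- test_gene()
    h <- translatedSearch(substr(gene, 301, 450), root)
    expect_identical(h$t_start, 101L)
    expect_identical(h$t_end, 150L)
    expect_identical(h$q_start, 1L)
    tf <- tempfile(fileext = ".tsv")
    writeHitTable(h, tf)
    back <- read.delim(tf)
    expect_identical(back$t_start, 101L)
})
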