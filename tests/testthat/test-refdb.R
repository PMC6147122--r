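test_that("self-hit BSR is exactly 1 for a candidate present in the seeds", {
    root <- test_root()
    cand <- aa_set(c(same = as.character(root[[1]])))
    res <- curateBySelfBsr(cand, root)
    expect_equal(res$bsr$bsr, 1)
    expect_true(res$bsr$retained)
    expect_identical(names(res$kept), "same")
})

test_that("candidates without a positive family hit get no BsrRecord", {
    root <- test_root()
    cand <- aa_set(c(masked = strrep("X", 500)))  # X scores 0 everywhere
    res <- curateBySelfBsr(cand, root)
    expect_identical(nrow(res$bsr), 0L)
    expect_length(res$kept, 0)
    # empty candidate set is fine too
    res2 <- curateBySelfBsr(Biostrings::AAStringSet(), root)
    expect_length(res2$kept, 0)
})

test_that("the full-length gate rejects short high-identity candidates", {
    root <- test_root()
    frag <- aa_set(c(frag = substr(as.character(root[[1]]), 1, 200)))
    res <- curateBySelfBsr(frag, root)  # bsr = 1 but 200 < 0.8 * 550
    expect_equal(res$bsr$bsr, 1)
    expect_false(res$bsr$retained)
})

test_that("curation separates a radiating family from unrelated decoys", {
    cb <- curationBenchmark(21, nSeed = 8L, nCandidates = 15L,
                            nDecoys = 30L)
    res <- curateBySelfBsr(c(cb$candidates, cb$decoys), cb$seedDb)
    kept <- names(res$kept)
    expect_gte(mean(names(cb$candidates) %in% kept), 0.95)
    expect_lte(mean(names(cb$decoys) %in% kept), 0.05)
    # diagnostics cover rejected candidates too
    expect_true(all(c(names(cb$candidates)) %in% res$bsr$query_id))
})

test_that("greedy clustering groups duplicates and splits distant pairs", {
    a <- rand_prot(300, seed = 61)
    c_ <- rand_prot(280, seed = 62)
    db <- clusterGreedy(aa_set(c(A = a, A2 = a, C = c_)), 0.9)
    expect_identical(sort(names(centroids(db))), c("A", "C"))
    mem <- membership(db)
    expect_identical(mem$centroid_id[mem$member_id == "A2"], "A")

    far <- mutateProtein(a, 0.5, seed = 63)
    db2 <- clusterGreedy(aa_set(c(x = a, y = far)), 0.9)
    expect_length(centroids(db2), 2)
})

test_that("cluster membership and centroid separation verify directly", {
    root <- test_root()
    fam <- simulateFamily(root, 30, seq(0.02, 0.2, length.out = 30),
                          seed = 71, topology = "star")
    db <- clusterGreedy(fam$members, 0.90)
    mem <- membership(db)
    seqs <- fam$members
    for (i in seq_len(nrow(mem))) {
        pid <- percentIdentity(as.character(seqs[[mem$member_id[i]]]),
                               as.character(seqs[[mem$centroid_id[i]]]))
        expect_gte(pid, 0.90)
    }
    cen <- centroids(db)
    expect_gt(length(cen), 1)  # divergence range straddles the threshold
    expect_lt(length(cen), 30)
    for (i in seq_len(length(cen) - 1)) for (j in seq(i + 1, length(cen)))
        expect_lt(percentIdentity(as.character(cen[[i]]),
                                  as.character(cen[[j]])), 0.90)
})

test_that("clustering the centroids again is the identity (idempotence)", {
    root <- test_root()
    fam <- simulateFamily(root, 12, c(0.05, 0.25), seed = 81,
                          topology = "star")
    db <- clusterGreedy(fam$members, 0.90)
    db2 <- clusterGreedy(centroids(db), 0.90)
    expect_identical(names(centroids(db2)), names(centroids(db)))
    expect_identical(as.character(centroids(db2)),
                     as.character(centroids(db)))
})

test_that("a reference database survives the disk round trip", {
    root <- test_root()
    fam <- simulateFamily(root, 6, c(0.05, 0.3), seed = 91,
                          topology = "star")
    db <- clusterGreedy(fam$members, 0.90)
    d <- tempfile()
    writeReferenceDb(db, d)
    back <- readReferenceDb(d)
    expect_identical(as.character(centroids(back)),
                     as.character(centroids(db)))
    expect_equal(identityThreshold(back), 0.90)
    expect_identical(membership(back)$centroid_id,
                     membership(db)$centroid_id)
})
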