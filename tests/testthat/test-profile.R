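test_that("clade BSR assignment is strict at the cutoff", {
    # engineered exact ratio: poly-A query, clade rep covers 3/4 of it
    q <- aa_set(c(q = strrep("A", 300)))
    cladeRep <- strrep("A", 225)
    fullRep <- strrep("A", 300)
    full <- aa_set(c(full = fullRep, clade = cladeRep))
    res <- suppressWarnings(
        assignClade(q, aa_set(c(clade = cladeRep)), full))
    expect_equal(res$bsr, 0.75)
    expect_false(res$assigned)  # strictly 'over 0.75'
    # identical to a clade representative: bsr 1, assigned
    res2 <- assignClade(aa_set(c(q = cladeRep)),
                        aa_set(c(clade = cladeRep)), full)
    expect_equal(res2$bsr, 1)
    expect_true(res2$assigned)
    # no full-database hit at all
    res3 <- assignClade(aa_set(c(q = strrep("X", 100))),
                        aa_set(c(clade = cladeRep)), full)
    expect_true(res3$no_hit)
    expect_false(res3$assigned)
})

test_that("two simulated clades separate cleanly at BSR 0.75", {
    repA <- as.character(test_root()[[1]])
    repB <- mutateProtein(repA, 0.5, seed = 110)
    withr::with_seed(111, {
        qa <- aa_set(vapply(1:15, function(i)
            mutateProtein(repA, runif(1, 0.1, 0.2)), character(1)))
        qb <- aa_set(vapply(1:15, function(i)
            mutateProtein(repB, runif(1, 0.1, 0.2)), character(1)))
    })
    names(qa) <- paste0("a", 1:15); names(qb) <- paste0("b", 1:15)
    full <- aa_set(c(cladeA = repA, cladeB = repB))
    clade <- aa_set(c(cladeA = repA))
    inres <- assignClade(qa, clade, full)
    outres <- assignClade(qb, clade, full)
    expect_gte(mean(inres$assigned), 0.95)
    expect_identical(sum(outres$assigned), 0L)
})

test_that("clade_db == full centroids assigns every query with a hit", {
    root <- test_root()
    fam <- simulateFamily(root, 8, c(0.05, 0.3), seed = 112,
                          topology = "star")
    db <- clusterGreedy(fam$members, 0.9)
    res <- assignClade(fam$members, centroids(db), db)
    expect_true(all(res$assigned[!res$no_hit]))
    expect_true(all(res$bsr[!res$no_hit] == 1))
})

test_that("recruitment counts verbatim copies and flags divergent sets", {
    root <- test_root()
    fam <- simulateFamily(root, 5, c(0.02, 0.25), seed = 113,
                          topology = "star")
    db <- clusterGreedy(fam$members, 0.9)
    cen <- centroids(db)
    copies <- rep(cen, times = c(3, rep(1, length(cen) - 1)))
    names(copies) <- sprintf("q%02d", seq_along(copies))
    pr <- recruit(copies, db)
    expect_identical(pr@belowFloorCount, 0L)
    expect_identical(unname(recruitCounts(pr)[1]), 3L)
    expect_identical(sum(pr@histogram$count), pr@nWithHit)

    withr::with_seed(114, {
        div <- aa_set(vapply(1:20, function(i)
            mutateProtein(as.character(root[[1]]), 0.15), character(1)))
    })
    pr2 <- recruit(div, root)
    expect_gte(belowFloorFraction(pr2), 0.9)

    pr0 <- recruit(Biostrings::AAStringSet(), db)
    expect_identical(pr0@nQueries, 0L)
    expect_identical(sum(pr0@histogram$count), 0L)
})

test_that("recruitment totals ignore query order", {
    root <- test_root()
    withr::with_seed(115, {
        q <- aa_set(vapply(1:12, function(i)
            mutateProtein(as.character(root[[1]]), runif(1, 0.02, 0.2)),
            character(1)))
    })
    p1 <- recruit(q, root)
    p2 <- recruit(rev(q), root)
    expect_identical(recruitCounts(p1), recruitCounts(p2))
    expect_identical(p1@histogram$count, p2@histogram$count)
})

test_that("adding centroids never lowers a query's best identity", {
    root <- as.character(test_root()[[1]])
    withr::with_seed(116, {
        q <- aa_set(vapply(1:10, function(i)
            mutateProtein(root, runif(1, 0.05, 0.3)), character(1)))
    })
    before <- aa_set(c(c1 = mutateProtein(root, 0.25, seed = 117)))
    after <- c(before, aa_set(c(c2 = root)))
    best_id <- function(db) vapply(seq_along(q), function(i)
        localAlign(as.character(q[[i]]),
                   as.character(db[[which.max(vapply(seq_along(db),
                       function(j) localAlign(as.character(q[[i]]),
                           as.character(db[[j]]))@rawScore, numeric(1)))]])
                   )@identityFraction, numeric(1))
    expect_true(all(best_id(after) >= best_id(before) - 1e-12))
    ns <- noveltyShift(q, before, after)
    expect_lte(ns$afterFraction, ns$beforeFraction)
    same <- noveltyShift(q, after, after)
    expect_identical(same$before@histogram$count,
                     same$after@histogram$count)
    # a database holding the exact sources recruits everything
    srcdb <- q
    names(srcdb) <- paste0("src", seq_along(q))
    expect_equal(recruit(q, srcdb)@belowFloorFraction, 0)
})
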