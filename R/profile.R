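#' Assign sequences to a clade by BLAST score ratio
#'
#' Each query is scored against the clade-representative subset and against
#' the full reference database; the ratio of the two best raw scores is the
#' clade BSR. Queries with bsr strictly above \code{cutoff} are assigned.
#' Queries with no full-database hit are unassigned and flagged
#' \code{no_hit}.
#'
#' @param queries [Biostrings::AAStringSet].
#' @param cladeDb [Biostrings::AAStringSet] clade representatives
#'   (recommended to be a subset of the full database's centroids; a
#'   warning is emitted otherwise).
#' @param fullDb [ReferenceDb-class] or [Biostrings::AAStringSet].
#' @param cutoff strict assignment cutoff (default 0.75).
#' @param scheme protein [ScoringScheme-class].
#' @return data.frame: \code{query_id, clade_score, full_score, bsr,
#'   assigned, no_hit}.
#' @export
assignClade <- function(queries, cladeDb, fullDb, cutoff = 0.75,
                        scheme = scoringScheme()) {
    full <- .db_seqs(fullDb)
    if (!all(as.character(cladeDb) %in% as.character(full)))
        warning("cladeDb is not a subset of the full database centroids")
    cs <- .cpp_best_scores(as.character(queries), as.character(cladeDb),
                           scheme@matrix, scheme@alphabet, scheme@gapOpen,
                           scheme@gapExtend, FALSE, 4L)
    fs <- .cpp_best_scores(as.character(queries), as.character(full),
                           scheme@matrix, scheme@alphabet, scheme@gapOpen,
                           scheme@gapExtend, FALSE, 4L)
    no_hit <- fs$score <= 0
    bsr <- ifelse(no_hit, NA_real_, cs$score / fs$score)
    data.frame(query_id = names(queries),
               clade_score = cs$score, full_score = fs$score, bsr = bsr,
               assigned = !no_hit & !is.na(bsr) & bsr > cutoff,
               no_hit = no_hit, stringsAsFactors = FALSE)
}

#' Recruitment of queries to reference centroids at an identity floor
#'
#' Nucleotide queries are routed through translated search, amino-acid
#' queries through best local alignment; the best hit's identity fraction
#' is binned (width 0.01) and compared with the floor. Identity equal to
#' the floor counts as recruited, so the recruited and below-floor sets
#' partition the queries with a hit.
#'
#' @param queries [Biostrings::DNAStringSet] (reads) or
#'   [Biostrings::AAStringSet] (proteins).
#' @param db [ReferenceDb-class] or [Biostrings::AAStringSet].
#' @param identityFloor the floor (default 0.90).
#' @param minScore minimum raw score for nucleotide queries (default 40);
#'   amino-acid queries count as hits whenever any positive-scoring
#'   alignment exists.
#' @inheritParams screenReads
#' @return a [RecruitmentProfile-class].
#' @export
recruit <- function(queries, db, identityFloor = 0.90,
                    scheme = scoringScheme(), minScore = 40L,
                    prefilter = TRUE, code = "11") {
    dbs <- .db_seqs(db)
    if (length(queries) == 0) {
        ident <- numeric(0); centroid <- character(0)
    } else if (is(queries, "DNAStringSet")) {
        h <- screenReads(queries, dbs, scheme = scheme,
                         minScore = minScore, prefilter = prefilter,
                         code = code)
        ident <- h$identity
        centroid <- h$db_id
    } else {
        bs <- .cpp_best_scores(as.character(queries), as.character(dbs),
                               scheme@matrix, scheme@alphabet,
                               scheme@gapOpen, scheme@gapExtend,
                               FALSE, 4L)
        ok <- which(bs$score > 0)
        ident <- numeric(0); centroid <- character(0)
        if (length(ok) > 0) {
            ident <- vapply(ok, function(i) {
                al <- .cpp_sw_align(as.character(queries[[i]]),
                                    as.character(dbs[[bs$db[i]]]),
                                    scheme@matrix, scheme@alphabet,
                                    scheme@gapOpen, scheme@gapExtend)
                if (al$columns > 0) al$identities / al$columns else 0
            }, numeric(1))
            centroid <- names(dbs)[bs$db[ok]]
        }
    }
    bins <- seq(0, 1, by = 0.01)
    binned <- findInterval(ident, bins, rightmost.closed = TRUE)
    binned[binned > 100L] <- 100L
    hist_count <- tabulate(binned, nbins = 100L)
    recruited <- ident >= identityFloor
    counts <- setNames(integer(length(dbs)), names(dbs))
    if (any(recruited)) {
        tb <- table(centroid[recruited])
        counts[names(tb)] <- as.integer(tb)
    }
    new("RecruitmentProfile",
        counts = counts,
        histogram = data.frame(bin_low = bins[-101L],
                               bin_high = bins[-1L],
                               count = hist_count),
        belowFloorCount = sum(!recruited),
        belowFloorFraction = if (length(ident) > 0)
            sum(!recruited) / length(ident) else 0,
        identityFloor = identityFloor, boundary = ">=",
        nQueries = length(queries), nWithHit = length(ident))
}

setMethod("show", "RecruitmentProfile", function(object) {
    cat(sprintf(
        "RecruitmentProfile: %d/%d queries with a hit; %d (%.1f%%) below the %.2f identity floor\n",
        object@nWithHit, object@nQueries, object@belowFloorCount,
        100 * object@belowFloorFraction, object@identityFloor))
})

#' @describeIn recruit below-floor (novelty) fraction accessor
#' @param x a \code{RecruitmentProfile}.
#' @export
belowFloorFraction <- function(x) x@belowFloorFraction

#' @describeIn recruit per-centroid recruited counts accessor
#' @export
recruitCounts <- function(x) x@counts

#' Novelty shift between two reference databases
#'
#' Profiles the same queries against a database before and after expansion
#' and reports both identity histograms with their below-floor fractions.
#' When the expanded database contains every centroid of the original one,
#' no query's best-hit identity can decrease, so the after fraction is at
#' most the before fraction.
#'
#' @param queries as in [recruit()].
#' @param dbBefore,dbAfter [ReferenceDb-class] or
#'   [Biostrings::AAStringSet]; a warning is emitted when \code{dbAfter}
#'   does not contain all \code{dbBefore} centroids.
#' @inheritParams recruit
#' @return list(before, after, beforeFraction, afterFraction).
#' @export
noveltyShift <- function(queries, dbBefore, dbAfter, identityFloor = 0.90,
                         scheme = scoringScheme(), minScore = 40L,
                         prefilter = TRUE, code = "11") {
    b <- .db_seqs(dbBefore); a <- .db_seqs(dbAfter)
    if (!all(as.character(b) %in% as.character(a)))
        warning("dbAfter does not contain every dbBefore centroid")
    pb <- recruit(queries, b, identityFloor, scheme, minScore, prefilter,
                  code)
    pa <- recruit(queries, a, identityFloor, scheme, minScore, prefilter,
                  code)
    list(before = pb, after = pa,
         beforeFraction = pb@belowFloorFraction,
         afterFraction = pa@belowFloorFraction)
}

#' Write profiling outputs as TSV
#'
#' @param profile a [RecruitmentProfile-class].
#' @param countsPath,histPath output paths (either may be NULL).
#' @export
writeRecruitment <- function(profile, countsPath = NULL, histPath = NULL) {
    if (!is.null(countsPath))
        write.table(data.frame(centroid_id = names(profile@counts),
                               recruited = profile@counts),
                    countsPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    if (!is.null(histPath)) {
        h <- profile@histogram
        attr(h, "boundary") <- profile@boundary
        write.table(h, histPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(NULL)
}
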