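#' Curate candidates against a seed family by self-hit BSR
#'
#' For every candidate with a positive local-alignment score against at
#' least one seed sequence, the BLAST score ratio is formed between its best
#' single-seed raw score and its maximum possible score (the self-hit). A
#' candidate is kept when bsr >= \code{bsrCutoff} and its length reaches
#' \code{minLenFraction} of the median seed length (the full-length gate).
#' All BsrRecords are returned for diagnostics, including those of rejected
#' candidates.
#'
#' @param candidates [Biostrings::AAStringSet] candidate pool.
#' @param seedDb [Biostrings::AAStringSet] seed family.
#' @param bsrCutoff retention cutoff in (0, 1); default 0.5.
#' @param minLenFraction minimum candidate length as a fraction of the
#'   median seed length; default 0.8.
#' @param scheme protein [ScoringScheme-class].
#' @param prefilter shared-4-mer prefilter (default FALSE here: curation is
#'   a one-off where completeness trumps speed).
#' @return list with \code{kept} (AAStringSet) and \code{bsr} (data.frame:
#'   query_id, target_score, reference_score, bsr, mode = "self",
#'   retained).
#' @export
curateBySelfBsr <- function(candidates, seedDb, bsrCutoff = 0.5,
                            minLenFraction = 0.8,
                            scheme = scoringScheme(), prefilter = FALSE) {
    stopifnot(bsrCutoff > 0, bsrCutoff < 1)
    if (length(seedDb) == 0) stop("seed database is empty")
    empty <- list(kept = AAStringSet(),
                  bsr = data.frame(query_id = character(),
                                   target_score = integer(),
                                   reference_score = integer(),
                                   bsr = numeric(), mode = character(),
                                   retained = logical()))
    if (length(candidates) == 0) return(empty)
    if (is.null(names(candidates)) || anyDuplicated(names(candidates)))
        stop("candidates must carry unique names")
    fam <- .cpp_best_scores(as.character(candidates), as.character(seedDb),
                            scheme@matrix, scheme@alphabet, scheme@gapOpen,
                            scheme@gapExtend, prefilter, 4L)
    has_hit <- fam$score > 0
    if (!any(has_hit)) return(empty)
    idx <- which(has_hit)
    self <- vapply(idx, function(i)
        .cpp_sw_score(as.character(candidates[[i]]),
                      as.character(candidates[[i]]), scheme@matrix,
                      scheme@alphabet, scheme@gapOpen, scheme@gapExtend),
        integer(1))
    bsr <- fam$score[idx] / self
    min_len <- minLenFraction * median(width(seedDb))
    long_enough <- width(candidates)[idx] >= min_len
    keep <- bsr >= bsrCutoff & long_enough
    rec <- data.frame(query_id = names(candidates)[idx],
                      target_score = fam$score[idx],
                      reference_score = self, bsr = bsr, mode = "self",
                      retained = keep, stringsAsFactors = FALSE)
    list(kept = candidates[idx][keep], bsr = rec)
}

#' Greedy length-sorted centroid clustering
#'
#' Sequences are visited in length-descending order (ties keep input
#' order). Each sequence joins the first existing centroid it matches at or
#' above the global-alignment identity threshold, else founds a new
#' centroid. Deterministic for a fixed input.
#'
#' @param seqs [Biostrings::AAStringSet] with unique names.
#' @param threshold identity threshold in (0, 1]; default 0.90.
#' @param scheme protein [ScoringScheme-class].
#' @return a [ReferenceDb-class].
#' @export
clusterGreedy <- function(seqs, threshold = 0.90,
                          scheme = scoringScheme()) {
    stopifnot(threshold > 0, threshold <= 1)
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
        stop("sequences must carry unique names")
    ord <- order(-width(seqs), seq_along(seqs))
    cent_idx <- integer(0)
    member <- character(length(seqs))
    ident <- numeric(length(seqs))
    for (i in ord) {
        s <- as.character(seqs[[i]])
        placed <- FALSE
        for (ci in cent_idx) {
            pid <- percentIdentity(s, as.character(seqs[[ci]]), scheme)
            if (pid >= threshold) {
                member[i] <- names(seqs)[ci]; ident[i] <- pid
                placed <- TRUE
                break
            }
        }
        if (!placed) {
            cent_idx <- c(cent_idx, i)
            member[i] <- names(seqs)[i]; ident[i] <- 1
        }
    }
    new("ReferenceDb",
        centroids = seqs[cent_idx],
        membership = data.frame(member_id = names(seqs),
                                centroid_id = member, identity = ident,
                                stringsAsFactors = FALSE),
        identityThreshold = threshold,
        provenance = list(n_input = length(seqs),
                          n_centroids = length(cent_idx),
                          threshold = threshold,
                          scheme = scheme@name,
                          created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
}

#' @describeIn clusterGreedy centroid sequences
#' @param db a \code{ReferenceDb}.
#' @export
centroids <- function(db) db@centroids

#' @describeIn clusterGreedy membership table
#' @export
membership <- function(db) db@membership

#' @describeIn clusterGreedy identity threshold used at construction
#' @export
identityThreshold <- function(db) db@identityThreshold

setMethod("show", "ReferenceDb", function(object) {
    cat(sprintf(
        "ReferenceDb: %d centroids from %d sequences at >= %.2f identity\n",
        length(object@centroids), nrow(object@membership),
        object@identityThreshold))
})

setMethod("length", "ReferenceDb", function(x) length(x@centroids))

#' Persist / load a reference database
#'
#' The database is written as centroid FASTA, membership TSV, and a JSON
#' provenance file in \code{dir}.
#'
#' @param db a [ReferenceDb-class].
#' @param dir directory.
#' @export
writeReferenceDb <- function(db, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeSequences(db@centroids, file.path(dir, "centroids.faa"))
    write.table(db@membership, file.path(dir, "membership.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    prov <- db@provenance
    prov$identity_threshold <- db@identityThreshold
    write_json(prov, file.path(dir, "provenance.json"), auto_unbox = TRUE)
    invisible(dir)
}

#' @rdname writeReferenceDb
#' @export
readReferenceDb <- function(dir) {
    cen <- readSequences(file.path(dir, "centroids.faa"), alphabet = "aa")
    mem <- read.delim(file.path(dir, "membership.tsv"),
                      stringsAsFactors = FALSE)
    prov <- read_json(file.path(dir, "provenance.json"),
                      simplifyVector = TRUE)
    new("ReferenceDb", centroids = cen, membership = mem,
        identityThreshold = as.numeric(prov$identity_threshold),
        provenance = prov[setdiff(names(prov), "identity_threshold")])
}
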