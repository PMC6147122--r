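.scheme_env <- new.env(parent = emptyenv())

# BLOSUM62 over the internal alphabet. X is forced to score 0 against
# everything (neutral mask residue); O (pyrrolysine readthrough) is scored
# like X; '*' keeps its BLOSUM62 values.
.AA_ALPHA <- "ARNDCQEGHILKMFPSTWYVX*O"

.blosum62 <- function() {
    if (!is.null(.scheme_env$blosum62)) return(.scheme_env$blosum62)
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    B <- e$BLOSUM62
    letters20 <- strsplit(substr(.AA_ALPHA, 1, 20), "")[[1]]
    al <- c(letters20, "X", "*", "O")
    M <- matrix(0L, 23, 23, dimnames = list(al, al))
    M[letters20, letters20] <- as.integer(B[letters20, letters20])
    M["*", c(letters20, "*")] <- as.integer(B["*", c(letters20, "*")])
    M[c(letters20, "*"), "*"] <- as.integer(B[c(letters20, "*"), "*"])
    # X and O rows/cols stay 0, including vs '*'? keep '*' penalty there too
    M["*", c("X", "O")] <- 0L
    M[c("X", "O"), "*"] <- 0L
    storage.mode(M) <- "integer"
    .scheme_env$blosum62 <- M
    M
}

#' Protein scoring scheme (BLOSUM62 with affine gaps)
#'
#' The default scheme for all protein and translated-read alignments:
#' BLOSUM62 with gap open 11, gap extend 1, and Karlin-Altschul parameters
#' lambda = 0.267, K = 0.041 for bit scores. The matrix is extended with X
#' (scores 0 against everything), O (pyrrolysine readthrough, scored like X)
#' and the stop character \code{*}.
#'
#' @param gapOpen,gapExtend affine gap penalties; a gap of length L costs
#'   \code{gapOpen + (L - 1) * gapExtend}.
#' @param lambda,K bit-score parameters.
#' @return a [ScoringScheme-class].
#' @examples
#' scoringScheme()
#' @export
scoringScheme <- function(gapOpen = 11L, gapExtend = 1L,
                          lambda = 0.267, K = 0.041) {
    new("ScoringScheme", name = "BLOSUM62", matrix = .blosum62(),
        alphabet = .AA_ALPHA, gapOpen = as.integer(gapOpen),
        gapExtend = as.integer(gapExtend), lambda = lambda, K = K,
        type = "aa")
}

#' Nucleotide scoring scheme
#'
#' Simple match/mismatch scheme used when aligning reconstructed nucleotide
#' consensus sequences: match +2, mismatch -2, N neutral (0), gap open 5,
#' gap extend 2.
#'
#' @inheritParams scoringScheme
#' @param match,mismatch match reward and mismatch penalty (penalty given as
#'   a negative score).
#' @return a [ScoringScheme-class].
#' @export
dnaScoringScheme <- function(match = 2L, mismatch = -2L, gapOpen = 5L,
                             gapExtend = 2L, lambda = 0.625, K = 0.41) {
    al <- c("A", "C", "G", "T", "N")
    M <- matrix(as.integer(mismatch), 5, 5, dimnames = list(al, al))
    diag(M) <- as.integer(match)
    M["N", ] <- 0L; M[, "N"] <- 0L
    new("ScoringScheme", name = "DNA", matrix = M, alphabet = "ACGTN",
        gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend),
        lambda = lambda, K = K, type = "dna")
}

setMethod("show", "ScoringScheme", function(object) {
    cat(sprintf(
        "ScoringScheme '%s' (%s): gap %d/%d, lambda %.3f, K %.3f\n",
        object@name, object@type, object@gapOpen, object@gapExtend,
        object@lambda, object@K))
})

.bit_score <- function(raw, scheme)
    (scheme@lambda * raw - log(scheme@K)) / log(2)

.chr1 <- function(x) {
    if (is(x, "XStringSet")) { stopifnot(length(x) == 1L); x <- x[[1L]] }
    toupper(as.character(x))
}

.mk_alignment <- function(res, scheme, frame = 0L) {
    cols <- res$columns
    new("LocalAlignment",
        rawScore = as.integer(res$score),
        bitScore = .bit_score(res$score, scheme),
        identityFraction = if (cols > 0) res$identities / cols else 0,
        identities = as.integer(res$identities),
        columns = as.integer(cols),
        queryInterval = as.integer(c(res$q_start, res$q_end)),
        targetInterval = as.integer(c(res$t_start, res$t_end)),
        frame = as.integer(frame),
        alignedQuery = res$aligned_query,
        alignedTarget = res$aligned_target)
}

#' Optimal local alignment with affine gaps
#'
#' Smith-Waterman over the scheme's substitution matrix. The traceback is
#' deterministic (diagonal preferred over up over left on ties). When no
#' residue pair scores positively the empty alignment is returned (raw score
#' 0, zero columns).
#'
#' @param query,target sequences (character, XString or length-1
#'   XStringSet) over the scheme's alphabet.
#' @param scheme a [ScoringScheme-class]; default [scoringScheme()].
#' @param frame frame annotation carried into the result (0 for
#'   protein-vs-protein).
#' @return a [LocalAlignment-class].
#' @examples
#' localAlign("MKV", "MKV")            # raw score 14
#' localAlign("AAAA", "CCCC")          # empty alignment, score 0
#' @export
localAlign <- function(query, target, scheme = scoringScheme(),
                       frame = 0L) {
    q <- .chr1(query); t <- .chr1(target)
    if (nchar(q) == 0 || nchar(t) == 0) stop("sequences must be non-empty")
    res <- .cpp_sw_align(q, t, scheme@matrix, scheme@alphabet,
                         scheme@gapOpen, scheme@gapExtend)
    .mk_alignment(res, scheme, frame)
}

#' Global alignment percent identity
#'
#' Identity fraction of the optimal Needleman-Wunsch global alignment under
#' the scheme (end gaps penalized): identical residue pairs divided by
#' alignment columns, gap columns included in the denominator.
#'
#' @inheritParams localAlign
#' @return a number in [0, 1].
#' @examples
#' percentIdentity("MKVMKV", "MKV")  # 0.5
#' @export
percentIdentity <- function(query, target, scheme = scoringScheme()) {
    q <- .chr1(query); t <- .chr1(target)
    if (nchar(q) == 0 || nchar(t) == 0) stop("sequences must be non-empty")
    res <- .cpp_nw_align(q, t, scheme@matrix, scheme@alphabet,
                         scheme@gapOpen, scheme@gapExtend)
    if (res$columns == 0) return(0)
    res$identities / res$columns
}

#' Global alignment (Needleman-Wunsch, end gaps penalized)
#'
#' @inheritParams localAlign
#' @return a [LocalAlignment-class] (rawScore may be negative conceptually;
#'   it is reported as computed).
#' @export
globalAlign <- function(query, target, scheme = scoringScheme()) {
    q <- .chr1(query); t <- .chr1(target)
    if (nchar(q) == 0 || nchar(t) == 0) stop("sequences must be non-empty")
    res <- .cpp_nw_align(q, t, scheme@matrix, scheme@alphabet,
                         scheme@gapOpen, scheme@gapExtend)
    .mk_alignment(res, scheme, 0L)
}

setMethod("show", "LocalAlignment", function(object) {
    cat(sprintf(
        "LocalAlignment: raw %d (%.1f bits), identity %.3f over %d cols, q[%d,%d) t[%d,%d) frame %+d\n",
        object@rawScore, object@bitScore, object@identityFraction,
        object@columns, object@queryInterval[1], object@queryInterval[2],
        object@targetInterval[1], object@targetInterval[2], object@frame))
})

#' @describeIn localAlign raw score accessor
#' @param x a \code{LocalAlignment}.
#' @export
rawScore <- function(x) x@rawScore

#' @describeIn localAlign identity-fraction accessor
#' @export
identityFraction <- function(x) x@identityFraction

.db_seqs <- function(db) {
    if (is(db, "ReferenceDb")) db@centroids
    else if (is(db, "AAStringSet")) db
    else AAStringSet(db)
}

#' Best translated hit of one read against a protein database
#'
#' All six reading frames of the read are aligned locally against every
#' database entry; the single best raw score wins (ties broken by lower
#' database index, then lower frame in the order +1,+2,+3,-1,-2,-3).
#'
#' @param read nucleotide sequence (character, DNAString, or length-1
#'   DNAStringSet).
#' @param db protein database: [Biostrings::AAStringSet] or
#'   [ReferenceDb-class].
#' @param scheme protein [ScoringScheme-class].
#' @param minScore minimum raw score to report a hit (default 40).
#' @param prefilter use the shared-4-mer prefilter before full dynamic
#'   programming (default TRUE; score-lossless for anything clearing
#'   \code{minScore} in practice, and verifiable by setting FALSE).
#' @param code genetic-code table id.
#' @return a one-row hit data.frame (see [screenReads()]) or NULL when no
#'   alignment reaches \code{minScore}.
#' @export
translatedSearch <- function(read, db, scheme = scoringScheme(),
                             minScore = 40L, prefilter = TRUE,
                             code = "11") {
    reads <- DNAStringSet(.as_dna_string(read))
    names(reads) <- "query"
    h <- screenReads(reads, db, scheme = scheme, minScore = minScore,
                     prefilter = prefilter, code = code)
    if (nrow(h) == 0) NULL else h
}

#' Write a hit table as TSV
#'
#' Columns: query_id, db_id, raw_score, bit_score, identity, columns,
#' q_start, q_end, t_start, t_end, frame, with 1-based inclusive
#' coordinates.
#'
#' @param hits hit data.frame from [screenReads()].
#' @param path output path.
#' @export
writeHitTable <- function(hits, path) {
    write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
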