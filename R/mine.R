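#' Screen reads against a marker protein database
#'
#' Each read is translated in all six frames and locally aligned against
#' every database entry; the best hit per read clearing \code{minScore} is
#' reported. File input is processed in chunks so memory stays constant in
#' the number of reads, mirroring a download-screen-discard loop.
#'
#' @param reads a [Biostrings::DNAStringSet] with unique names, or a path to
#'   a FASTA/FASTQ file (plain or gzip).
#' @param db marker database ([ReferenceDb-class] or
#'   [Biostrings::AAStringSet]).
#' @param scheme protein [ScoringScheme-class].
#' @param minScore minimum raw score for a hit (default 40).
#' @param prefilter shared-4-mer prefilter before full dynamic programming.
#' @param code genetic-code table id.
#' @param chunkSize reads per chunk for file input.
#' @return data.frame with one row per hit read: \code{query_id, db_id,
#'   raw_score, bit_score, identity, columns, q_start, q_end, t_start,
#'   t_end, frame}. Coordinates are 1-based inclusive; query coordinates are
#'   amino-acid positions on the translated frame. The attribute
#'   \code{screened} carries the total number of reads examined.
#' @export
screenReads <- function(reads, db, scheme = scoringScheme(),
                        minScore = 40L, prefilter = TRUE, code = "11",
                        chunkSize = 5000L) {
    dbs <- .db_seqs(db)
    if (length(dbs) == 0) stop("marker database is empty")
    if (is.character(reads) && length(reads) == 1L) {
        fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", reads, ignore.case = TRUE))
            "fastq" else "fasta"
        out <- list(); screened <- 0L; skip <- 0L
        repeat {
            chunk <- readBStringSet(reads, format = fmt, nrec = chunkSize,
                                    skip = skip)
            if (length(chunk) == 0) break
            dna <- DNAStringSet(chartr("U", "T", toupper(
                as.character(chunk))))
            names(dna) <- sub("\\s.*$", "", names(chunk))
            h <- .screen_chunk(dna, dbs, scheme, minScore, prefilter, code)
            h$sequence <- as.character(dna)[match(h$query_id, names(dna))]
            out[[length(out) + 1L]] <- h
            screened <- screened + length(chunk)
            skip <- skip + length(chunk)
            if (length(chunk) < chunkSize) break
        }
        res <- do.call(rbind, out)
        if (is.null(res)) res <- .empty_hits(sequence = TRUE)
        if (anyDuplicated(res$query_id))
            stop("duplicated read ids across ", reads)
    } else {
        if (!is(reads, "DNAStringSet")) reads <- DNAStringSet(reads)
        if (is.null(names(reads)) || anyDuplicated(names(reads)))
            stop("reads must carry unique names")
        res <- .screen_chunk(reads, dbs, scheme, minScore, prefilter, code)
        screened <- length(reads)
    }
    attr(res, "screened") <- screened
    res
}

.empty_hits <- function(sequence = FALSE) {
    d <- data.frame(query_id = character(), db_id = character(),
                    raw_score = integer(), bit_score = numeric(),
                    identity = numeric(), columns = integer(),
                    q_start = integer(), q_end = integer(),
                    t_start = integer(), t_end = integer(),
                    frame = integer(), stringsAsFactors = FALSE)
    if (sequence) d$sequence <- character()
    d
}

.screen_chunk <- function(reads, dbs, scheme, minScore, prefilter, code) {
    stopifnot(minScore >= 1L)
    hv <- .cpp_screen_reads(as.character(reads), as.character(dbs),
                            .codonTable(code), scheme@matrix,
                            scheme@alphabet, scheme@gapOpen,
                            scheme@gapExtend, as.integer(minScore),
                            prefilter, 4L)
    if (nrow(hv) == 0) return(.empty_hits())
    n <- nrow(hv)
    out <- .empty_hits()[seq_len(0), ]
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        r <- hv$read[i]; d <- hv$db[i]; fr <- hv$frame[i]
        aa <- .cpp_six_frames(as.character(reads[[r]]),
                              .codonTable(code))[[as.character(fr)]]
        al <- .cpp_sw_align(aa, as.character(dbs[[d]]), scheme@matrix,
                            scheme@alphabet, scheme@gapOpen,
                            scheme@gapExtend)
        rows[[i]] <- data.frame(
            query_id = names(reads)[r], db_id = names(dbs)[d],
            raw_score = al$score,
            bit_score = .bit_score(al$score, scheme),
            identity = if (al$columns > 0) al$identities / al$columns else 0,
            columns = al$columns,
            q_start = al$q_start + 1L, q_end = al$q_end,
            t_start = al$t_start + 1L, t_end = al$t_end,
            frame = fr, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}

#' Outgroup BSR false-positive filter
#'
#' Re-scores every marker-hit read against an outgroup database and forms
#' the BLAST score ratio bsr = marker score / best outgroup score. A read is
#' retained when it has no outgroup hit at all (absence of a better
#' non-marker homolog is the point of the ratio, and divergent true
#' positives must survive) or when bsr >= theta.
#'
#' @param hits hit table from [screenReads()].
#' @param reads the screened reads (DNAStringSet with names matching
#'   \code{hits$query_id}); may be omitted when \code{hits} carries a
#'   \code{sequence} column (file-streamed screening).
#' @param outgroupDb [Biostrings::AAStringSet] outgroup proteins.
#' @param theta BSR retention threshold in (0, 1]; default 0.8.
#' @inheritParams screenReads
#' @return list with \code{retained} (DNAStringSet) and \code{bsr}
#'   (data.frame: query_id, target_score, reference_score, bsr, mode,
#'   retained; reference_score and bsr are NA for reads without an outgroup
#'   hit).
#' @export
outgroupBsrFilter <- function(hits, reads = NULL, outgroupDb, theta = 0.8,
                              scheme = scoringScheme(), prefilter = TRUE,
                              code = "11") {
    stopifnot(theta > 0, theta <= 1)
    if (is.null(reads)) {
        if (is.null(hits$sequence))
            stop("either 'reads' or a hits$sequence column is required")
        reads <- DNAStringSet(hits$sequence)
        names(reads) <- hits$query_id
    }
    if (nrow(hits) == 0)
        return(list(retained = DNAStringSet(),
                    bsr = data.frame(query_id = character(),
                                     target_score = integer(),
                                     reference_score = integer(),
                                     bsr = numeric(), mode = character(),
                                     retained = logical())))
    hr <- reads[hits$query_id]
    og <- .cpp_screen_reads(as.character(hr), as.character(outgroupDb),
                            .codonTable(code), scheme@matrix,
                            scheme@alphabet, scheme@gapOpen,
                            scheme@gapExtend, 1L, prefilter, 4L)
    ref <- rep(NA_integer_, nrow(hits))
    ref[og$read] <- og$score
    bsr <- hits$raw_score / ref
    keep <- is.na(ref) | bsr >= theta
    rec <- data.frame(query_id = hits$query_id,
                      target_score = hits$raw_score,
                      reference_score = ref, bsr = bsr,
                      mode = "outgroup", retained = keep,
                      stringsAsFactors = FALSE)
    list(retained = hr[keep], bsr = rec)
}

#' Per-dataset hit gate and approximate gene coverage
#'
#' A dataset is worth assembling when it yields strictly more than
#' \code{minHits} retained reads (default 20, i.e. roughly two-fold coverage
#' of a 1,500 nt gene with 150 nt reads).
#'
#' @param retainedCount retained reads after outgroup BSR.
#' @param minHits gate threshold (strict inequality).
#' @param readLen read length in nt.
#' @param geneLen expected gene length in nt.
#' @return list(gatePassed, approxCoverage).
#' @examples
#' datasetGate(21)  # passed, 2.1x
#' datasetGate(20)  # not passed
#' @export
datasetGate <- function(retainedCount, minHits = 20L, readLen = 150L,
                        geneLen = 1500L) {
    stopifnot(minHits >= 0, retainedCount >= 0)
    list(gatePassed = retainedCount > minHits,
         approxCoverage = retainedCount * readLen / geneLen)
}

#' Mine one read set: screen, outgroup-filter, gate
#'
#' Convenience wrapper running [screenReads()], [outgroupBsrFilter()] and
#' [datasetGate()] for a single dataset.
#'
#' @inheritParams screenReads
#' @inheritParams outgroupBsrFilter
#' @inheritParams datasetGate
#' @param datasetId dataset label recorded in the result.
#' @return a [MinedReadSet-class].
#' @export
mineDataset <- function(reads, db, outgroupDb, datasetId = "dataset",
                        scheme = scoringScheme(), minScore = 40L,
                        theta = 0.8, minHits = 20L, geneLen = 1500L,
                        prefilter = TRUE, code = "11",
                        chunkSize = 5000L) {
    hits <- screenReads(reads, db, scheme = scheme, minScore = minScore,
                        prefilter = prefilter, code = code,
                        chunkSize = chunkSize)
    fl <- outgroupBsrFilter(hits,
                            reads = if (is.character(reads)) NULL else reads,
                            outgroupDb = outgroupDb, theta = theta,
                            scheme = scheme, prefilter = prefilter,
                            code = code)
    ret <- fl$retained
    readLen <- if (length(ret) > 0) round(median(width(ret))) else 150L
    gate <- datasetGate(length(ret), minHits = minHits, readLen = readLen,
                        geneLen = geneLen)
    hits$sequence <- NULL
    new("MinedReadSet", datasetId = datasetId, hits = hits,
        retained = ret, bsr = fl$bsr,
        counts = c(screened = as.integer(attr(hits, "screened")),
                   hit = as.integer(nrow(hits)),
                   retained = length(ret)),
        gatePassed = gate$gatePassed, approxCoverage = gate$approxCoverage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "MinedReadSet", function(object) {
    cn <- object@counts
    cat(sprintf(
        "MinedReadSet '%s': %d screened, %d hit, %d retained; gate %s (%.1fx)\n",
        object@datasetId, cn["screened"], cn["hit"], cn["retained"],
        if (object@gatePassed) "passed" else "not passed",
        object@approxCoverage))
})

#' @describeIn mineDataset retained reads accessor
#' @param x a \code{MinedReadSet}.
#' @export
retainedReads <- function(x) x@retained

#' Write mining outputs for one dataset
#'
#' Writes retained reads as FASTA, the outgroup BsrRecord table as TSV, and
#' a one-line summary TSV (screened/hit/retained/gate) into \code{dir}.
#'
#' @param x a [MinedReadSet-class].
#' @param dir output directory (created if needed).
#' @export
writeMinedReadSet <- function(x, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeSequences(x@retained,
                   file.path(dir, paste0(x@datasetId, "_retained.fasta")))
    write.table(x@bsr, file.path(dir, paste0(x@datasetId, "_bsr.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cn <- x@counts
    write.table(data.frame(dataset_id = x@datasetId,
                           screened = cn["screened"], hit = cn["hit"],
                           retained = cn["retained"],
                           gate_passed = x@gatePassed,
                           approx_coverage = x@approxCoverage),
                file.path(dir, paste0(x@datasetId, "_summary.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}
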