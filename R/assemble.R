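#' Greedy overlap-consensus assembly of marker-gene reads
#'
#' A deterministic overlap-layout-consensus assembler aimed at
#' reconstructing a single short gene from a bag of screened reads at low
#' coverage. Both strands are considered (a read or its reverse complement
#' is placed). At every step the best ungapped overlap between any two
#' current contigs is merged: longest overlap first, then fewest
#' mismatches, then lexicographically smallest contig-id pair, preferring
#' the same-strand placement on full ties. Merging stops when no overlap of
#' at least \code{minOverlap} nt at \code{minOverlapIdentity} identity
#' remains. The consensus is the per-column majority base, ties resolved in
#' favour of the earliest-placed read.
#'
#' All contigs are returned, sorted by decreasing length; use
#' [filterContigs()] to apply the primary-output length gate (default
#' 1,000 nt, strict).
#'
#' @param reads [Biostrings::DNAStringSet] with unique names.
#' @param minOverlap minimum overlap length in nt (default 30).
#' @param minOverlapIdentity minimum overlap identity (default 0.95).
#' @param datasetId dataset label carried into the contigs.
#' @return list of [GeneContig-class], longest first.
#' @export
assembleGeneReads <- function(reads, minOverlap = 30L,
                              minOverlapIdentity = 0.95,
                              datasetId = NA_character_) {
    if (length(reads) == 0) stop("no reads to assemble")
    if (is.null(names(reads)) || anyDuplicated(names(reads)))
        stop("reads must carry unique names")
    n <- length(reads)
    # working contigs: seq (character), reads (data.frame read_id, offset,
    # strand, seq, rank), id (lexicographic tie-break key)
    ctg <- vector("list", n)
    for (i in seq_len(n)) {
        s <- as.character(reads[[i]])
        ctg[[i]] <- list(id = names(reads)[i], seq = s,
                         reads = data.frame(read_id = names(reads)[i],
                                            offset = 0L, strand = "+",
                                            seq = s, rank = i,
                                            stringsAsFactors = FALSE))
    }
    alive <- rep(TRUE, n)
    # pairwise best overlaps in upper-triangular matrices; the row/column of
    # a merged contig is recomputed in one batched C call
    OV <- matrix(-1L, n, n); MM <- matrix(0L, n, n)
    FLIP <- matrix(0L, n, n); OFF <- matrix(0L, n, n)
    refresh <- function(i) {
        others <- which(alive); others <- others[others != i]
        if (length(others) == 0) return(invisible())
        m <- .cpp_overlap_vs_many(ctg[[i]]$seq,
                                  vapply(ctg[others], `[[`, character(1),
                                         "seq"),
                                  minOverlap, minOverlapIdentity)
        for (z in seq_along(others)) {
            j <- others[z]
            a <- min(i, j); b <- max(i, j)
            if (m[z, 1] == 1) {
                # store relative to the pair (a, b): overlap of a vs b
                if (a == i) {
                    OV[a, b] <<- m[z, 4]; MM[a, b] <<- m[z, 5]
                    FLIP[a, b] <<- m[z, 2]; OFF[a, b] <<- m[z, 3]
                } else {
                    # re-express from j's perspective: same orientation
                    # negates the offset; flipped reflects it
                    OV[a, b] <<- m[z, 4]; MM[a, b] <<- m[z, 5]
                    FLIP[a, b] <<- m[z, 2]
                    OFF[a, b] <<- if (m[z, 2] == 0) -m[z, 3] else
                        m[z, 3] + nchar(ctg[[j]]$seq) -
                            nchar(ctg[[i]]$seq)
                }
            } else OV[a, b] <<- -1L
        }
        invisible()
    }
    for (i in seq_len(n)) {
        others <- if (i < n) seq(i + 1L, n) else integer(0)
        if (length(others) == 0) next
        m <- .cpp_overlap_vs_many(ctg[[i]]$seq,
                                  vapply(ctg[others], `[[`, character(1),
                                         "seq"),
                                  minOverlap, minOverlapIdentity)
        ok <- m[, 1] == 1
        OV[i, others[ok]] <- m[ok, 4]; MM[i, others[ok]] <- m[ok, 5]
        FLIP[i, others[ok]] <- m[ok, 2]; OFF[i, others[ok]] <- m[ok, 3]
    }

    repeat {
        mx <- max(OV)
        if (mx < minOverlap) break
        cand_idx <- which(OV == mx, arr.ind = TRUE)
        mms <- MM[cand_idx]
        cand_idx <- cand_idx[mms == min(mms), , drop = FALSE]
        if (nrow(cand_idx) > 1L) {
            keys <- apply(cand_idx, 1L, function(p) {
                ids <- sort(c(ctg[[p[1]]]$id, ctg[[p[2]]]$id))
                paste(ids, collapse = "\r")
            })
            cand_idx <- cand_idx[order(keys)[1L], , drop = FALSE]
        }
        i <- cand_idx[1, 1]; j <- cand_idx[1, 2]
        A <- ctg[[i]]; B <- ctg[[j]]
        if (FLIP[i, j] == 1) B <- .flip_contig(B)
        d <- OFF[i, j]
        shift <- max(0L, -d)
        A$reads$offset <- A$reads$offset + shift
        B$reads$offset <- B$reads$offset + d + shift
        la <- nchar(A$seq); lb <- nchar(B$seq)
        # patchwork sequence (A's bases win in the overlap); true majority
        # consensus is computed once at the end from the placements
        left <- if (d < 0) substr(B$seq, 1L, -d) else ""
        right <- if (d + lb > la) substr(B$seq, la - d + 1L, lb) else ""
        A$seq <- paste0(left, A$seq, right)
        A$reads <- rbind(A$reads, B$reads)
        A$id <- min(A$id, B$id)
        ctg[[i]] <- A
        alive[j] <- FALSE
        OV[j, ] <- -1L; OV[, j] <- -1L
        refresh(i)
    }

    out <- lapply(which(alive), function(i) .finalize_contig(ctg[[i]]))
    lens <- vapply(out, function(g) length(g@consensus), integer(1))
    out <- out[order(-lens)]
    for (k in seq_along(out)) {
        out[[k]]@contigId <- sprintf("ctg_%04d", k)
        out[[k]]@datasetId <- datasetId
    }
    out
}

.flip_contig <- function(B) {
    lb <- nchar(B$seq)
    w <- nchar(B$reads$seq)
    B$reads$offset <- lb - (B$reads$offset + w)
    B$reads$strand <- ifelse(B$reads$strand == "+", "-", "+")
    B$reads$seq <- vapply(B$reads$seq, .revcomp_chr, character(1),
                          USE.NAMES = FALSE)
    B$seq <- .revcomp_chr(B$seq)
    B
}

.BASES <- c("A", "C", "G", "T", "N")

# Per-column majority consensus with earliest-placed-read tie-break.
.finalize_contig <- function(C) {
    rd <- C$reads[order(C$reads$rank), , drop = FALSE]
    L <- nchar(C$seq)
    counts <- matrix(0L, nrow = 5L, ncol = L)
    chs <- strsplit(rd$seq, "", fixed = TRUE)
    for (r in seq_len(nrow(rd))) {
        pos <- rd$offset[r] + seq_len(nchar(rd$seq[r]))
        bi <- match(chs[[r]], .BASES)
        counts[cbind(bi, pos)] <- counts[cbind(bi, pos)] + 1L
    }
    depth <- as.integer(colSums(counts))
    cons <- character(L)
    maxc <- apply(counts, 2L, max)
    for (jj in seq_len(L)) {
        tied <- which(counts[, jj] == maxc[jj])
        if (length(tied) == 1L) { cons[jj] <- .BASES[tied]; next }
        # earliest-placed read covering this column whose base is tied
        for (r in seq_len(nrow(rd))) {
            o <- rd$offset[r]
            if (o < jj && jj <= o + nchar(rd$seq[r])) {
                b <- match(chs[[r]][jj - o], .BASES)
                if (b %in% tied) { cons[jj] <- .BASES[b]; break }
            }
        }
        if (cons[jj] == "") cons[jj] <- .BASES[tied[1]]
    }
    w <- nchar(rd$seq)
    new("GeneContig", contigId = "ctg", datasetId = NA_character_,
        consensus = DNAString(paste(cons, collapse = "")),
        depth = depth,
        members = data.frame(read_id = rd$read_id, start = rd$offset,
                             end = rd$offset + w, strand = rd$strand,
                             placed_rank = rd$rank,
                             stringsAsFactors = FALSE))
}

#' Apply the primary-output contig length gate
#'
#' @param contigs list of [GeneContig-class].
#' @param minLen strict lower bound on contig length (default 1,000 nt:
#'   only contigs longer than this are kept).
#' @return the filtered list.
#' @export
filterContigs <- function(contigs, minLen = 1000L) {
    Filter(function(g) length(g@consensus) > minLen, contigs)
}

setMethod("show", "GeneContig", function(object) {
    cat(sprintf("GeneContig %s (%s): %d nt, %d reads, mean depth %.1f\n",
                object@contigId, object@datasetId,
                length(object@consensus), nrow(object@members),
                mean(object@depth)))
})

#' @describeIn assembleGeneReads consensus sequence accessor
#' @param x a \code{GeneContig}.
#' @export
consensus <- function(x) x@consensus

#' Contig feature table: length, GC, canonical k-mer frequencies
#'
#' GC is computed over unambiguous bases only. K-mer frequencies pool each
#' k-mer with its reverse complement (canonical k-mers) and are normalized
#' to sum to one; windows containing N are dropped. Contigs shorter than k
#' get a zero vector and are flagged.
#'
#' @param contigs list of [GeneContig-class] or a
#'   [Biostrings::DNAStringSet].
#' @param k k-mer size (default 4).
#' @return list with \code{table} (data.frame: contig_id, length, gc,
#'   short) and \code{kmerFreq} (matrix, one row per contig, columns the
#'   canonical k-mers).
#' @export
contigFeatures <- function(contigs, k = 4L) {
    stopifnot(k >= 1L)
    if (is.list(contigs)) {
        ids <- vapply(contigs, function(g) g@contigId, character(1))
        ds <- DNAStringSet(lapply(contigs, function(g) g@consensus))
        names(ds) <- ids
    } else {
        ds <- contigs
        ids <- names(ds)
    }
    len <- width(ds)
    acgt <- letterFrequency(ds, c("A", "C", "G", "T"))
    unamb <- rowSums(acgt)
    gc <- ifelse(unamb > 0, rowSums(acgt[, c("C", "G"), drop = FALSE]) /
                     unamb, NA_real_)
    raw <- oligonucleotideFrequency(ds, width = k)
    kms <- colnames(raw)
    canon <- as.character(reverseComplement(DNAStringSet(kms)))
    canon <- ifelse(kms <= canon, kms, canon)
    pooled <- t(rowsum(t(raw), group = canon))
    tot <- rowSums(pooled)
    freq <- pooled
    ok <- tot > 0
    freq[ok, ] <- pooled[ok, , drop = FALSE] / tot[ok]
    freq[!ok, ] <- 0
    rownames(freq) <- ids
    list(table = data.frame(contig_id = ids, length = len, gc = gc,
                            short = len < k, stringsAsFactors = FALSE),
         kmerFreq = freq)
}

#' Write contig FASTA, features and read placements
#'
#' Writes \code{contigs.fasta} (contigs passing the length gate),
#' \code{contigs_all.fasta}, \code{features.tsv} and \code{placements.tsv}
#' (1-based inclusive coordinates) into \code{dir}.
#'
#' @param contigs list of [GeneContig-class].
#' @param dir output directory.
#' @param minContigLen strict length gate for the primary FASTA.
#' @param k k-mer size for features.
#' @export
writeContigs <- function(contigs, dir, minContigLen = 1000L, k = 4L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    all_ds <- DNAStringSet(lapply(contigs, function(g) g@consensus))
    names(all_ds) <- vapply(contigs, function(g) g@contigId, character(1))
    writeXStringSet(all_ds, file.path(dir, "contigs_all.fasta"), width = 60)
    primary <- filterContigs(contigs, minContigLen)
    pds <- DNAStringSet(lapply(primary, function(g) g@consensus))
    names(pds) <- vapply(primary, function(g) g@contigId, character(1))
    writeXStringSet(pds, file.path(dir, "contigs.fasta"), width = 60)
    fe <- contigFeatures(contigs, k = k)
    write.table(cbind(fe$table, fe$kmerFreq),
                file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    pl <- do.call(rbind, lapply(contigs, function(g) {
        m <- g@members
        data.frame(contig_id = g@contigId, read_id = m$read_id,
                   start = m$start + 1L, end = m$end, strand = m$strand,
                   stringsAsFactors = FALSE)
    }))
    write.table(pl, file.path(dir, "placements.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}
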