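.START_CODONS <- c("ATG", "GTG", "TTG")

#' Predict (possibly edge-open) reading frames on a contig
#'
#' In each of the six frames, maximal stop-free codon stretches are
#' enumerated. A stretch anchored at a contig edge is reported even without
#' a start or stop codon, with the corresponding open flag set
#' (\code{open5}: no start codon, runs off the 5' edge of the oriented
#' contig; \code{open3}: no stop codon, runs off the 3' edge). Interior
#' stretches must begin at a prokaryotic start codon (ATG/GTG/TTG) and are
#' trimmed to the first one. Only predictions strictly longer than
#' \code{minAa} residues are returned, longest first.
#'
#' With \code{amberReadthrough = TRUE}, TAG is treated as coding for the
#' readthrough residue \code{"O"} (scored like X in alignments) and only
#' TAA/TGA terminate; this matters for pyrrolysine-utilizing methylamine
#' methyltransferase genes, where a hard TAG stop truncates the product.
#'
#' @param x a [GeneContig-class], [Biostrings::DNAString] or nucleotide
#'   string.
#' @param minAa strict minimum protein length (default 300: "over 300").
#' @param code genetic-code table id.
#' @param amberReadthrough treat TAG as coding (default FALSE).
#' @return data.frame with one row per prediction: \code{contig_id,
#'   protein, nt_start, nt_end} (0-based half-open on the forward contig
#'   strand; the interval includes the stop codon when \code{open3} is
#'   FALSE), \code{strand, frame, open5, open3, length_aa}.
#' @export
predictOrfs <- function(x, minAa = 300L, code = "11",
                        amberReadthrough = FALSE) {
    if (is(x, "GeneContig")) {
        cid <- x@contigId
        s <- as.character(x@consensus)
    } else {
        cid <- "contig"
        s <- .as_dna_string(x)
    }
    L <- nchar(s)
    rows <- list()
    for (strand in c("+", "-")) {
        oriented <- if (strand == "+") s else .revcomp_chr(s)
        for (off in 0:2) {
            ncod <- (L - off) %/% 3L
            if (ncod < 1L) next
            starts_nt <- off + 3L * (seq_len(ncod) - 1L)  # 0-based
            cod <- substring(oriented, starts_nt + 1L, starts_nt + 3L)
            aa <- .translate_codons(cod, code, amberReadthrough)
            is_stop <- aa == "*"
            # maximal stop-free stretches of codon indices
            bounds <- c(0L, which(is_stop), ncod + 1L)
            for (b in seq_len(length(bounds) - 1L)) {
                from <- bounds[b] + 1L
                to <- bounds[b + 1L] - 1L
                if (to < from) next
                edge5 <- from == 1L
                open3 <- to == ncod  # ran off the end without a stop
                if (!edge5) {
                    hit <- which(cod[from:to] %in% .START_CODONS)
                    if (length(hit) == 0) next
                    from <- from + hit[1L] - 1L
                    open5 <- FALSE
                } else {
                    open5 <- !(cod[from] %in% .START_CODONS)
                }
                naa <- to - from + 1L
                if (naa <= minAa) next
                prot <- paste(aa[from:to], collapse = "")
                nt_from <- starts_nt[from]
                nt_to <- starts_nt[to] + 3L + (if (!open3) 3L else 0L)
                if (strand == "-") {
                    tmp <- L - nt_to
                    nt_to <- L - nt_from
                    nt_from <- tmp
                }
                rows[[length(rows) + 1L]] <- data.frame(
                    contig_id = cid, protein = prot,
                    nt_start = nt_from, nt_end = nt_to,
                    strand = strand,
                    frame = if (strand == "+") off + 1L else -(off + 1L),
                    open5 = open5, open3 = open3, length_aa = naa,
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (length(rows) == 0) return(data.frame(
        contig_id = character(), protein = character(),
        nt_start = integer(), nt_end = integer(), strand = character(),
        frame = integer(), open5 = logical(), open3 = logical(),
        length_aa = integer(), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    out[order(-out$length_aa, out$nt_start), , drop = FALSE]
}

.translate_codons <- function(cod, code, amberReadthrough) {
    tab <- .codonTable(code)
    idx <- .codon_index(cod)
    aa <- ifelse(is.na(idx), "X", substring(tab, idx, idx))
    if (amberReadthrough) aa[cod == "TAG"] <- "O"
    aa
}

.codon_index <- function(cod) {
    b <- c(A = 0L, C = 1L, G = 2L, T = 3L)
    i1 <- b[substring(cod, 1, 1)]
    i2 <- b[substring(cod, 2, 2)]
    i3 <- b[substring(cod, 3, 3)]
    unname(16L * i1 + 4L * i2 + i3 + 1L)
}

#' Write predicted proteins as FASTA plus a TSV summary
#'
#' FASTA headers carry contig id, 1-based inclusive nucleotide interval,
#' strand and the open flags.
#'
#' @param orfs data.frame from [predictOrfs()].
#' @param fastaPath,tsvPath output paths.
#' @export
writeOrfs <- function(orfs, fastaPath, tsvPath = NULL) {
    if (nrow(orfs) > 0) {
        prot <- AAStringSet(orfs$protein)
        names(prot) <- sprintf("%s_orf%02d %d-%d(%s) open5=%s open3=%s",
                               orfs$contig_id, seq_len(nrow(orfs)),
                               orfs$nt_start + 1L, orfs$nt_end,
                               orfs$strand, orfs$open5, orfs$open3)
        writeXStringSet(prot, fastaPath, width = 60)
    } else {
        writeXStringSet(AAStringSet(), fastaPath)
    }
    if (!is.null(tsvPath)) {
        tab <- orfs[, setdiff(colnames(orfs), "protein"), drop = FALSE]
        tab$nt_start <- tab$nt_start + 1L  # 1-based inclusive in reports
        write.table(tab, tsvPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(fastaPath)
}
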