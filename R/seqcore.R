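#' Read sequences from FASTA or FASTQ
#'
#' Records are returned in file order as a [Biostrings::DNAStringSet] or
#' [Biostrings::AAStringSet]. Nucleotide input is normalized to upper case
#' with U converted to T. FASTQ qualities are parsed and discarded: the
#' downstream screening workflow is quality-agnostic. Gzip-compressed files
#' are accepted. An empty file yields an empty set; duplicated ids are an
#' error.
#'
#' The record id is the first whitespace-delimited token of the header; the
#' remainder is kept as the element metadata column \code{description}.
#'
#' @param path file path (plain or gzip).
#' @param format \code{"fasta"} or \code{"fastq"}; default guessed from the
#'   file extension.
#' @param alphabet \code{"auto"} (guess from residue content),
#'   \code{"dna"} or \code{"aa"}.
#' @return a \code{DNAStringSet} or \code{AAStringSet} with unique names.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a one", "ACGT", ">b", "MKV"), tf)  # mixed file: forced dna
#' readSequences(tf, alphabet = "dna")
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq"),
                          alphabet = c("auto", "dna", "aa")) {
    format <- match.arg(format)
    alphabet <- match.arg(alphabet)
    if (format == "auto") {
        base <- sub("\\.(gz|bgz)$", "", path)
        format <- if (grepl("\\.(fastq|fq)$", base, ignore.case = TRUE))
            "fastq" else "fasta"
    }
    if (!file.exists(path)) stop("no such file: ", path)
    raw <- tryCatch(
        readBStringSet(path, format = format),
        error = function(e) stop("parse error in ", path, " (", format,
                                 "): ", conditionMessage(e), call. = FALSE))
    if (length(raw) == 0) {
        out <- if (alphabet == "aa") AAStringSet() else DNAStringSet()
        return(out)
    }
    hdr <- names(raw)
    ids <- sub("\\s.*$", "", hdr)
    desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
    if (anyDuplicated(ids))
        stop("duplicated sequence id(s) in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    s <- toupper(as.character(raw))
    if (alphabet == "auto") {
        nt_frac <- mean(unlist(strsplit(paste(s, collapse = ""), "")) %in%
                        c("A", "C", "G", "T", "U", "N"))
        alphabet <- if (nt_frac >= 0.95) "dna" else "aa"
    }
    out <- if (alphabet == "dna") {
        DNAStringSet(chartr("U", "T", s))
    } else {
        bad <- grepl(sprintf("[^%s]", .AA_ALPHABET_RE), s)
        if (any(bad))
            stop("non-amino-acid residues in record(s): ",
                 paste(ids[bad], collapse = ", "))
        AAStringSet(s)
    }
    names(out) <- ids
    mcols(out)$description <- desc
    out
}

.AA_ALPHABET_RE <- "ACDEFGHIKLMNPQRSTVWYX*O"

#' Write sequences as 60-column wrapped FASTA
#'
#' @param x an XStringSet (names become headers; a \code{description}
#'   metadata column, if present, is appended after the id).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSequences <- function(x, path) {
    y <- x
    d <- mcols(x)$description
    if (!is.null(d) && any(nzchar(d)))
        names(y) <- ifelse(nzchar(d), paste(names(x), d), names(x))
    writeXStringSet(y, path, width = 60L)
    invisible(path)
}

.codon_env <- new.env(parent = emptyenv())

# 64-character codon -> amino acid string, indexed 16*b1 + 4*b2 + b3 with
# A=0, C=1, G=2, T=3; used by both the R and C translation paths.
.codonTable <- function(code = "11") {
    key <- paste0("tab", code)
    if (!is.null(.codon_env[[key]])) return(.codon_env[[key]])
    gc <- getGeneticCode(code)
    bases <- c("A", "C", "G", "T")
    codons <- character(64)
    k <- 1L
    for (a in bases) for (b in bases) for (c in bases) {
        codons[k] <- paste0(a, b, c); k <- k + 1L
    }
    .codon_env[[key]] <- paste(unname(gc[codons]), collapse = "")
    .codon_env[[key]]
}

#' Translate a nucleotide sequence in a given frame
#'
#' Translation starts at offset \code{abs(frame) - 1}; negative frames
#' translate the reverse complement. The trailing partial codon is dropped,
#' stop codons are rendered \code{"*"} and codons containing an ambiguous
#' base render \code{"X"}.
#'
#' @param x a [Biostrings::DNAString], one-element \code{DNAStringSet}, or
#'   nucleotide string.
#' @param frame integer in \{+1,+2,+3,-1,-2,-3\}.
#' @param code genetic-code table id (default \code{"11"},
#'   bacterial/archaeal).
#' @return the amino-acid translation as a character string (possibly
#'   empty).
#' @examples
#' translateSeq("ATGAAAGTG", 1)    # "MKV"
#' translateSeq("CACTTTCAT", -1)   # "MKV"
#' @export
translateSeq <- function(x, frame, code = "11") {
    frame <- as.integer(frame)
    if (!frame %in% c(1:3, -1:-3))
        stop("frame must be one of +1,+2,+3,-1,-2,-3")
    s <- .as_dna_string(x)
    tr <- .cpp_six_frames(s, .codonTable(code))
    unname(tr[[as.character(frame)]])
}

#' All six translation frames
#'
#' @inheritParams translateSeq
#' @return named character vector of six translations, names
#'   \code{"1","2","3","-1","-2","-3"}.
#' @export
sixFrames <- function(x, code = "11") {
    .cpp_six_frames(.as_dna_string(x), .codonTable(code))
}

.as_dna_string <- function(x) {
    if (is(x, "XStringSet")) {
        stopifnot(length(x) == 1L)
        x <- x[[1L]]
    }
    s <- toupper(chartr("U", "T", as.character(x)))
    if (grepl("[^ACGTN]", s)) stop("non-ACGTN base in nucleotide sequence")
    s
}

.revcomp_chr <- function(s)
    as.character(reverseComplement(DNAString(s)))
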