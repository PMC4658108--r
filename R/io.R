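#' Reverse complement of a DNA string
#'
#' @param x character vector of A/C/G/T/N sequences.
#' @return character vector of reverse complements.
#' @export
dna_revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a 4-line FASTQ file
#'
#' Parses a plain (uncompressed) FASTQ file into a data frame of raw reads.
#' Malformed records — a truncated final record, a missing `@`/`+` marker, or
#' a quality string whose length differs from the sequence — raise an error
#' naming the offending record index.
#'
#' @param path FASTQ file path.
#' @return data.frame with columns `id`, `seq`, `qual` (quality as the raw
#'   ASCII string; decode with [phred_scores()]).
#' @export
read_fastq <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L)
        stop("malformed FASTQ (truncated record ", length(lines) %/% 4L + 1L,
             "): line count not a multiple of 4 in ", path)
    n <- length(lines) %/% 4L
    if (n == 0L)
        return(data.frame(id = character(), seq = character(),
                          qual = character(), stringsAsFactors = FALSE))
    idx <- seq_len(n)
    hdr <- lines[4L * idx - 3L]
    seqs <- lines[4L * idx - 2L]
    plus <- lines[4L * idx - 1L]
    qual <- lines[4L * idx]
    bad <- which(!startsWith(hdr, "@"))
    if (length(bad)) stop("malformed FASTQ record ", bad[1L], ": header lacks '@'")
    bad <- which(!startsWith(plus, "+"))
    if (length(bad)) stop("malformed FASTQ record ", bad[1L], ": separator lacks '+'")
    bad <- which(nchar(seqs) != nchar(qual))
    if (length(bad))
        stop("malformed FASTQ record ", bad[1L],
             ": quality length differs from sequence length")
    data.frame(id = sub("^@", "", hdr), seq = seqs, qual = qual,
               stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with `id`, `seq`, `qual` columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
    stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
    if (any(nchar(reads$seq) != nchar(reads$qual)))
        stop("sequence and quality lengths differ")
    out <- character(4L * nrow(reads))
    idx <- seq_len(nrow(reads))
    out[4L * idx - 3L] <- paste0("@", reads$id)
    out[4L * idx - 2L] <- reads$seq
    out[4L * idx - 1L] <- "+"
    out[4L * idx] <- reads$qual
    writeLines(out, path)
    invisible(path)
}

#' Decode a quality string to Phred scores
#'
#' @param qual character vector of ASCII quality strings.
#' @param offset ASCII offset (33 for modern Illumina).
#' @return list of integer vectors, one per read.
#' @export
phred_scores <- function(qual, offset = 33L) {
    lapply(qual, function(q) utf8ToInt(q) - as.integer(offset))
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of sequences (names are full headers).
#' @export
read_fasta <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    out <- as.character(x)
    names(out) <- names(x)
    out
}

#' Write named sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- names(seqs)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Write a tabular stage report
#'
#' Tab-separated, header row, input row order preserved.
#'
#' @param records data.frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path) {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a tabular stage report written by [write_report()]
#'
#' @param path input file path.
#' @return data.frame.
#' @export
read_report <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE)
}
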