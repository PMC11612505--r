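#' Read a reference genome from FASTA
#'
#' @param path Path to a (optionally indexed) FASTA file.
#' @return A named character vector of uppercase contig sequences. This is the
#'   reference representation used throughout the package.
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  seqs
}

#' Write a reference genome to FASTA
#' @param reference Named character vector of contig sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  ss <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read paired-end alignments into a tibble
#'
#' Reads a coordinate-sorted BAM (or plain-text SAM, converted on the fly via
#' Rsamtools) into the alignment tibble used by the caller: one row per primary
#' record with 0-based coordinates.
#'
#' @param path BAM or SAM file.
#' @return A tibble with columns `name`, `chrom`, `pos` (0-based leftmost),
#'   `mapq`, `cigar`, `seq`, `is_reverse`, `is_read1`, `mate_chrom`,
#'   `mate_pos` (0-based), `mate_reverse`, `insert_size`.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                              overwrite = TRUE, indexDestination = FALSE))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
             "strand", "mrnm", "mpos", "isize"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  fl <- b$flag
  tibble::tibble(
    name = b$qname,
    chrom = as.character(b$rname),
    pos = as.integer(b$pos) - 1L,
    mapq = as.integer(b$mapq),
    cigar = as.character(b$cigar),
    seq = as.character(b$seq),
    is_reverse = bitwAnd(fl, 16L) != 0L,
    is_read1 = bitwAnd(fl, 64L) != 0L,
    mate_chrom = as.character(b$mrnm),
    mate_pos = as.integer(b$mpos) - 1L,
    mate_reverse = bitwAnd(fl, 32L) != 0L,
    insert_size = as.integer(b$isize))
}

#' Write an alignment tibble as SAM
#'
#' Emits a coordinate-sorted plain-text SAM file with a proper header, suitable
#' for conversion to BAM with Rsamtools or samtools.
#'
#' @param alignments Alignment tibble (see [read_alignments()]).
#' @param reference Named character vector of contig sequences (for `@SQ`).
#' @param path Output path (conventionally ending in `.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)))
  a <- dplyr::arrange(alignments, .data$chrom, .data$pos)
  flag <- 1L + 2L +
    ifelse(a$is_reverse, 16L, 0L) + ifelse(a$mate_reverse, 32L, 0L) +
    ifelse(a$is_read1, 64L, 128L)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
                 a$name, flag, a$chrom, a$pos + 1L, a$mapq, a$cigar,
                 ifelse(a$mate_chrom == a$chrom, "=", a$mate_chrom),
                 a$mate_pos + 1L, a$insert_size, a$seq)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read or write a tandem-repeat annotation track
#'
#' The repeat track is a BED-like, 0-based half-open, tab-separated table with
#' columns `chrom`, `start`, `end`, `unit_length` (the length of the repeat
#' unit of each annotated tandem repeat).
#'
#' @param path File path.
#' @return `read_repeat_track()` returns a tibble; `write_repeat_track()`
#'   returns `path` invisibly.
#' @export
read_repeat_track <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "start", "end", "unit_length"),
                  colClasses = c("character", "integer", "integer", "integer"))
  tibble::as_tibble(d)
}

#' @rdname read_repeat_track
#' @param repeats Repeat track tibble.
#' @export
write_repeat_track <- function(repeats, path) {
  write.table(repeats[, c("chrom", "start", "end", "unit_length")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
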