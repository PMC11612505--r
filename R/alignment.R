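#' Alignment scoring scheme
#'
#' The caller uses a single affine-gap scoring scheme throughout: hidden split
#' read detection, junction realignment, expected-support computation and
#' duplication-versus-insertion matching. The default values are match +1,
#' mismatch -4, gap opening -6, gap extension -1; the first base of a gap costs
#' `gap_open + gap_extend`.
#'
#' @param match Positive score for a matching base.
#' @param mismatch Negative score for a mismatching base. `N` never matches.
#' @param gap_open Negative gap-opening penalty.
#' @param gap_extend Negative per-base gap-extension penalty.
#' @return An object of class `alignment_scheme`.
#' @examples
#' alignment_scheme()
#' @export
alignment_scheme <- function(match = 1L, mismatch = -4L, gap_open = -6L,
                             gap_extend = -1L) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "alignment_scheme")
}

#' @export
print.alignment_scheme <- function(x, ...) {
  cat(sprintf("<alignment_scheme> match %+d, mismatch %+d, gap open %+d, gap extend %+d\n",
              x$match, x$mismatch, x$gap_open, x$gap_extend))
  invisible(x)
}

#' Optimal affine-gap local alignment
#'
#' Smith-Waterman local alignment of `query` against `target`. Score ties are
#' broken towards the smallest reference start, then the smallest query start.
#' A score of 0 denotes the empty alignment (all coordinates 0).
#'
#' @param query,target Non-empty DNA strings over `A`, `C`, `G`, `T`, `N`.
#' @param scheme An [alignment_scheme()].
#' @return A one-row tibble with columns `score`, `query_start`, `query_end`,
#'   `ref_start`, `ref_end` (0-based half-open).
#' @examples
#' local_align("ACGT", "TTACGTTT")
#' @export
local_align <- function(query, target, scheme = alignment_scheme()) {
  if (!nzchar(query) || !nzchar(target)) {
    rlang::abort("local_align() requires non-empty query and target sequences")
  }
  v <- cpp_local_align(query, target, scheme$match, scheme$mismatch,
                       scheme$gap_open, scheme$gap_extend)
  tibble::tibble(score = v[1], query_start = v[2], query_end = v[3],
                 ref_start = v[4], ref_end = v[5])
}

# Best local alignment score only (scalar).
local_align_score <- function(query, target, scheme = alignment_scheme()) {
  if (!nzchar(query) || !nzchar(target)) return(0L)
  utils::tail(cpp_prefix_best(query, target, scheme$match, scheme$mismatch,
                              scheme$gap_open, scheme$gap_extend), 1L)
}

# Best local score of every query prefix (forward pass) / suffix (reverse pass).
prefix_scores <- function(query, target, scheme = alignment_scheme()) {
  cpp_prefix_best(query, target, scheme$match, scheme$mismatch,
                  scheme$gap_open, scheme$gap_extend)
}

suffix_scores <- function(query, target, scheme = alignment_scheme()) {
  rev(cpp_prefix_best(revcomp(query), revcomp(target), scheme$match,
                      scheme$mismatch, scheme$gap_open, scheme$gap_extend))
}

#' Count differences between aligned reads and the reference
#'
#' The number of differences of an aligned read is the count of mismatched
#' aligned bases plus the number of indel events, where an indel of any length
#' counts as one difference. Soft/hard-clipped bases are ignored.
#'
#' @param alignments Alignment tibble (see [read_alignments()]) with columns
#'   `pos` (0-based), `cigar` and `seq`.
#' @param reference Named character vector of contig sequences.
#' @return `alignments` with an added integer column `n_diff`.
#' @export
count_differences <- function(alignments, reference) {
  if (nrow(alignments) == 0) {
    return(dplyr::mutate(alignments, n_diff = integer(0)))
  }
  out <- alignments
  out$n_diff <- NA_integer_
  for (ct in unique(alignments$chrom)) {
    idx <- which(alignments$chrom == ct)
    if (is.na(reference[ct])) {
      rlang::abort(sprintf("contig '%s' present in alignments but not in the reference", ct))
    }
    d <- cpp_count_differences(alignments$pos[idx], alignments$cigar[idx],
                               alignments$seq[idx], reference[[ct]])
    if (any(d < 0)) {
      rlang::abort("cigar/reference inconsistency: a read walks outside its contig")
    }
    out$n_diff[idx] <- d
  }
  out
}

#' Reverse complement
#' @param x A DNA string.
#' @return The reverse complement string.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# substr wrapper for 0-based half-open coordinates
subseq0 <- function(x, start, end) substr(x, start + 1L, end)
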