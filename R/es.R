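#' Build the reference/CNV allele pair for a CNV
#'
#' Extracts the reference window spanning the event plus `flank` bp on each
#' side (`r_ref`), and constructs the alternative allele `r_cnv` by applying
#' the event (removing the deleted span, or tandem-duplicating the duplicated
#' span). `b1`/`b2` are the breakpoint offsets on `r_cnv`: for a deletion the
#' single junction (b1 = b2), for a duplication the two boundaries of the
#' second copy.
#'
#' @param cnv One-row callset tibble (`chrom`, `start`, `end`, `svtype`).
#' @param reference Named character vector of contig sequences.
#' @param flank Flank length (default 2000 bp; truncated and flagged at
#'   contig edges).
#' @return An `allele_pair` list: `r_ref`, `r_cnv`, `b1`, `b2`, `svtype`,
#'   `flank_left`, `flank_right`, `truncated`.
#' @export
build_allele_pair <- function(cnv, reference, flank = 2000L) {
  contig <- reference[[cnv$chrom]]
  clen <- nchar(contig)
  if (cnv$start < 0 || cnv$end > clen || cnv$end <= cnv$start) {
    rlang::abort("cnv outside contig bounds")
  }
  fl <- min(flank, cnv$start)
  fr <- min(flank, clen - cnv$end)
  r_ref <- subseq0(contig, cnv$start - fl, cnv$end + fr)
  d <- cnv$end - cnv$start
  event <- subseq0(contig, cnv$start, cnv$end)
  left <- subseq0(contig, cnv$start - fl, cnv$start)
  right <- subseq0(contig, cnv$end, cnv$end + fr)
  if (cnv$svtype == "DEL") {
    r_cnv <- paste0(left, right)
    b1 <- b2 <- fl
  } else {
    r_cnv <- paste0(left, event, event, right)
    b1 <- fl + d
    b2 <- fl + 2L * d
  }
  structure(list(r_ref = r_ref, r_cnv = r_cnv, b1 = as.integer(b1),
                 b2 = as.integer(b2), svtype = cnv$svtype,
                 flank_left = fl, flank_right = fr,
                 truncated = fl < flank || fr < flank),
            class = "allele_pair")
}

#' Enumerate all breakpoint-containing reads of length l
#'
#' All positioned reads `r_cnv[i, i + l)` that strictly straddle a breakpoint
#' (`i < b < i + l` for b in {b1, b2}). Reads are positioned: identical
#' sequences at different offsets count separately.
#'
#' @param allele An [build_allele_pair()] object.
#' @param l Read length (must be shorter than `r_cnv`).
#' @return Tibble with `offset` (0-based) and `seq`.
#' @export
enumerate_breakpoint_reads <- function(allele, l) {
  n <- nchar(allele$r_cnv)
  if (l >= n) rlang::abort("read length must be shorter than the CNV allele")
  offs <- sort(unique(c(outer(c(allele$b1, allele$b2), seq_len(l - 1),
                              function(b, k) b - k))))
  offs <- offs[offs >= 0 & offs + l <= n]
  tibble::tibble(offset = as.integer(offs),
                 seq = substring(allele$r_cnv, offs + 1L, offs + l))
}

#' Expected support (ES) score of a CNV
#'
#' The fraction of all breakpoint-containing reads of length `l` from the CNV
#' allele that align strictly better (local alignment score) to the CNV
#' allele than to the reference window. An ES of 0 means no read drawn across
#' a breakpoint can reveal the event (e.g. full-unit events in perfect tandem
#' repeats); an ES of 1 means every breakpoint read supports it.
#'
#' @inheritParams enumerate_breakpoint_reads
#' @param scheme [alignment_scheme()].
#' @return An `es_result` list: `es`, `n_total`, `n_support`, plus the
#'   per-read table.
#' @export
expected_support <- function(allele, l, scheme = alignment_scheme()) {
  reads <- enumerate_breakpoint_reads(allele, l)
  s_cnv <- vapply(reads$seq, local_align_score, integer(1),
                  target = allele$r_cnv, scheme = scheme, USE.NAMES = FALSE)
  s_ref <- vapply(reads$seq, local_align_score, integer(1),
                  target = allele$r_ref, scheme = scheme, USE.NAMES = FALSE)
  supp <- s_cnv > s_ref
  structure(list(es = mean(supp), n_total = nrow(reads), n_support = sum(supp),
                 reads = dplyr::mutate(reads, score_cnv = s_cnv,
                                       score_ref = s_ref, supports = supp)),
            class = "es_result")
}

#' @export
print.es_result <- function(x, ...) {
  cat(sprintf("<es_result> ES = %.3f (%d of %d breakpoint reads)\n",
              x$es, x$n_support, x$n_total))
  invisible(x)
}

#' Classify a single read's support for a CNV
#'
#' `SPLIT` when the read is clipped (>= `min_clip` unaligned terminal bases)
#' against the reference allele but unclipped against the CNV allele; `HSR`
#' when it is unclipped against the reference but aligns strictly better to
#' the CNV allele; `NONE` otherwise.
#'
#' @param read Read sequence (drawn from the CNV allele).
#' @param allele An [build_allele_pair()] object.
#' @param scheme [alignment_scheme()].
#' @param min_clip Minimum unaligned terminus to count as clipped (default 5).
#' @return `"SPLIT"`, `"HSR"` or `"NONE"`.
#' @export
classify_read_support <- function(read, allele, scheme = alignment_scheme(),
                                  min_clip = 5L) {
  l <- nchar(read)
  clipped <- function(al) al$query_start >= min_clip || (l - al$query_end) >= min_clip
  a_ref <- local_align(read, allele$r_ref, scheme)
  a_cnv <- local_align(read, allele$r_cnv, scheme)
  if (clipped(a_ref) && !clipped(a_cnv)) return("SPLIT")
  if (!clipped(a_ref) && a_cnv$score > a_ref$score) return("HSR")
  "NONE"
}

#' Call potential CNVs by realigning individual hidden split reads
#'
#' For each read, splits it at every position, aligns the two halves locally
#' and independently to the region, and takes the split with the highest
#' summed score. With the left half ending at `e_l` and the right half
#' starting at `s_r`: `s_r > e_l` yields a deletion `[e_l, s_r)` and
#' `s_r < e_l` a duplication `[s_r, e_l)`. Events of at least `min_size` bp
#' are retained.
#'
#' @param reads Character vector of read sequences (reads that do not align
#'   perfectly to the region).
#' @param region_sequence The region's reference sequence.
#' @param scheme [alignment_scheme()].
#' @param min_size Minimum event size (default 50).
#' @param min_half Minimum half length considered for a split (default 1).
#' @return Tibble: `read`, `svtype`, `start`, `end` (region-relative),
#'   `split_score`.
#' @export
hsr_scan_region <- function(reads, region_sequence,
                            scheme = alignment_scheme(), min_size = 50L,
                            min_half = 1L) {
  out <- purrr::map(seq_along(reads), function(k) {
    seq <- reads[k]
    n <- nchar(seq)
    if (n < 2L * min_half) return(NULL)
    pre <- prefix_scores(seq, region_sequence, scheme)
    if (pre[n] == n * scheme$match) return(NULL) # aligns perfectly: excluded
    suf <- suffix_scores(seq, region_sequence, scheme)
    idx <- seq.int(min_half, n - min_half)
    gain <- pre[idx] + suf[idx + 1L]
    i <- idx[which.max(gain)]
    lh <- local_align(substr(seq, 1L, i), region_sequence, scheme)
    rh <- local_align(substr(seq, i + 1L, n), region_sequence, scheme)
    e_l <- lh$ref_end; s_r <- rh$ref_start
    if (s_r == e_l) return(NULL)
    svtype <- if (s_r > e_l) "DEL" else "DUP"
    start <- min(e_l, s_r); end <- max(e_l, s_r)
    if (end - start < min_size) return(NULL)
    tibble::tibble(read = k, svtype = svtype, start = start, end = end,
                   split_score = lh$score + rh$score)
  })
  dplyr::bind_rows(out)
}
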