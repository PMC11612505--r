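#' Classify read pairs as concordant or discordant
#'
#' A pair is deletion-type discordant when its insert size strictly exceeds
#' `stats$max_is` (= mu + 3 sigma), and duplication-type discordant when it has
#' outward orientation, i.e. the forward-facing read maps downstream of the
#' reverse-facing read. Pairs with an unmapped mate or mates on different
#' contigs are neutral.
#'
#' @param alignments Alignment tibble.
#' @param stats A [library_stats()] object.
#' @return One row per pair: `name`, `chrom`, `kind` (one of `DISCORDANT_DEL`,
#'   `DISCORDANT_DUP`, `CONCORDANT`, `NEUTRAL`), `insert_size`,
#'   `left_read_start`, `left_read_end`, `right_read_start`,
#'   `right_read_end` (left = the upstream read), and `mapq` (minimum of the
#'   two mates).
#' @export
classify_pairs <- function(alignments, stats) {
  cs <- cpp_cigar_stats(alignments$cigar)
  a <- dplyr::mutate(alignments, ref_span = cs[, 1])
  fw <- dplyr::filter(a, !.data$is_reverse)
  rv <- dplyr::filter(a, .data$is_reverse)
  pairs <- dplyr::inner_join(
    dplyr::select(fw, "name", "chrom", fwd_pos = "pos", fwd_span = "ref_span",
                  fwd_mapq = "mapq"),
    dplyr::select(rv, "name", rev_chrom = "chrom", rev_pos = "pos",
                  rev_span = "ref_span", rev_mapq = "mapq"),
    by = "name")
  # half-pairs (unmapped or missing mates) are neutral and simply absent here
  dplyr::mutate(
    pairs,
    same_chrom = .data$chrom == .data$rev_chrom,
    insert_size = ifelse(.data$same_chrom,
                         pmax(.data$fwd_pos + .data$fwd_span,
                              .data$rev_pos + .data$rev_span) -
                           pmin(.data$fwd_pos, .data$rev_pos),
                         NA_integer_),
    kind = dplyr::case_when(
      !.data$same_chrom ~ "NEUTRAL",
      .data$fwd_pos > .data$rev_pos ~ "DISCORDANT_DUP",
      .data$insert_size > stats$max_is ~ "DISCORDANT_DEL",
      TRUE ~ "CONCORDANT"),
    left_read_start = pmin(.data$fwd_pos, .data$rev_pos),
    left_read_end = dplyr::if_else(.data$fwd_pos <= .data$rev_pos,
                                   .data$fwd_pos + .data$fwd_span,
                                   .data$rev_pos + .data$rev_span),
    right_read_start = pmax(.data$fwd_pos, .data$rev_pos),
    right_read_end = pmax(.data$fwd_pos + .data$fwd_span,
                          .data$rev_pos + .data$rev_span),
    mapq = pmin(.data$fwd_mapq, .data$rev_mapq)) |>
    dplyr::select("name", "chrom", "kind", "insert_size", "left_read_start",
                  "left_read_end", "right_read_start", "right_read_end",
                  "mapq")
}

#' Annotate clip status and hidden-split-read candidacy
#'
#' A read counts as clipped when it carries a soft or hard clip of at least
#' `min_clip` bases on a side (smaller clips are alignment-trimming noise). A
#' read is a candidate hidden split read when it is unclipped and has at least
#' `min_diff` differences (mismatches plus indel events) with the reference.
#'
#' @param alignments Alignment tibble.
#' @param reference Named character vector of contig sequences.
#' @param min_clip Minimum clip length, default 5.
#' @param min_diff Minimum differences for HSR candidacy, default 3 (a "strong"
#'   hidden split read).
#' @return `alignments` with added columns `ref_span`, `left_clip`,
#'   `right_clip`, `is_clipped`, `n_diff`, `hsr_candidate`.
#' @export
annotate_reads <- function(alignments, reference, min_clip = 5L, min_diff = 3L) {
  cs <- cpp_cigar_stats(alignments$cigar)
  a <- dplyr::mutate(alignments,
                     ref_span = cs[, 1],
                     left_clip = ifelse(cs[, 3] >= min_clip, cs[, 3], 0L),
                     right_clip = ifelse(cs[, 4] >= min_clip, cs[, 4], 0L),
                     is_clipped = .data$left_clip > 0L | .data$right_clip > 0L)
  a <- count_differences(a, reference)
  dplyr::mutate(a, hsr_candidate = !.data$is_clipped & .data$n_diff >= min_diff)
}

#' Is a read a candidate hidden split read?
#'
#' @inheritParams annotate_reads
#' @return Logical vector: unclipped and at least `min_diff` differences.
#' @export
is_candidate_hsr <- function(alignments, reference, min_clip = 5L, min_diff = 3L) {
  annotate_reads(alignments, reference, min_clip, min_diff)$hsr_candidate
}

#' Optimal free split of a hidden split read
#'
#' Finds the split index `i` maximising `score(r[1..i]) + score(r[i+1..n])`,
#' where each half is locally aligned, independently, to the reference window
#' around the read. The HSR-score is that maximum minus `score(r)`; it is
#' always non-negative. A split is reported only when the HSR-score reaches
#' `hsr_min_score`, and is converted to a virtual clip: the half that anchors
#' at the read's original mapping position determines the side (left half
#' anchored = virtual right clip at its alignment end, and vice versa).
#'
#' Both passes of the exhaustive split search use prefix/suffix dynamic
#' programming tables, so all `n - 1` splits cost two alignments.
#'
#' @param segment A one-row alignment tibble (or list) with `chrom`, `pos`,
#'   `cigar`, `seq`, `name`.
#' @param reference Named character vector of contig sequences.
#' @param stats [library_stats()]; the window spans the read +/- `max_is`.
#' @param scheme [alignment_scheme()].
#' @param hsr_min_score Minimum HSR-score to emit a split (default 8: the split
#'   explanation must beat the linear one by two mismatches' worth).
#' @param min_half Minimum half length considered for a split (default 1: every
#'   split position is examined).
#' @return A one-row tibble (`name`, `split_index`, `virtual_side`,
#'   `virtual_breakpoint`, `hsr_score`) or `NULL`.
#' @export
compute_hsr_split <- function(segment, reference, stats,
                              scheme = alignment_scheme(),
                              hsr_min_score = 8L, min_half = 1L) {
  seq <- segment$seq
  n <- nchar(seq)
  contig <- reference[[segment$chrom]]
  span <- cpp_cigar_stats(segment$cigar)[1, 1]
  w0 <- max(0L, as.integer(segment$pos - stats$max_is - stats$read_len))
  w1 <- min(nchar(contig), as.integer(segment$pos + span + stats$max_is + stats$read_len))
  if (w1 - w0 < n) {
    rlang::abort("reference window shorter than the read")
  }
  window <- subseq0(contig, w0, w1)
  pre <- prefix_scores(seq, window, scheme)
  suf <- suffix_scores(seq, window, scheme)
  total <- pre[n]
  if (n < 2L * min_half) return(NULL)
  idx <- seq.int(min_half, n - min_half)
  gain <- pre[idx] + suf[idx + 1L] - total
  best <- which.max(gain)
  if (gain[best] < hsr_min_score) return(NULL)
  i <- idx[best]
  lh <- local_align(substr(seq, 1L, i), window, scheme)
  rh <- local_align(substr(seq, i + 1L, n), window, scheme)
  d_left <- abs((w0 + lh$ref_start) - segment$pos)
  d_right <- abs((w0 + rh$ref_end) - (segment$pos + span))
  if (d_left <= d_right) {
    side <- "RIGHT_CLIP"; bp <- w0 + lh$ref_end
  } else {
    side <- "LEFT_CLIP"; bp <- w0 + rh$ref_start
  }
  tibble::tibble(name = segment$name, chrom = segment$chrom,
                 split_index = i, virtual_side = side,
                 virtual_breakpoint = as.integer(bp),
                 hsr_score = as.integer(gain[best]))
}

# Evidence scan used by the pipeline: annotates reads, classifies pairs and
# computes hidden-split candidates for one chromosome's alignments.
scan_evidence <- function(alignments, reference, stats,
                          scheme = alignment_scheme(), use_hsr = TRUE,
                          hsr_min_score = 8L, min_clip = 5L, min_diff = 3L) {
  reads <- annotate_reads(alignments, reference, min_clip, min_diff)
  pairs <- classify_pairs(alignments, stats)
  hsr <- tibble::tibble(name = character(), chrom = character(),
                        split_index = integer(), virtual_side = character(),
                        virtual_breakpoint = integer(), hsr_score = integer())
  if (use_hsr) {
    cand <- dplyr::filter(reads, .data$hsr_candidate)
    if (nrow(cand) > 0) {
      # mates share a name, so each split carries its own read's fields
      splits <- purrr::map(seq_len(nrow(cand)), function(k) {
        hs <- compute_hsr_split(cand[k, ], reference, stats, scheme,
                                hsr_min_score)
        if (is.null(hs)) return(NULL)
        dplyr::bind_cols(hs, cand[k, c("seq", "mapq", "mate_chrom",
                                       "mate_pos")])
      })
      hsr <- dplyr::bind_rows(splits)
    }
  }
  list(reads = reads, pairs = pairs, hsr = hsr)
}
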