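#' Pile clipped reads and hidden split reads into breakpoint consensuses
#'
#' Clip records (real soft clips and virtual clips from hidden split reads)
#' sharing a side are clustered by clip position: records within `cluster_tol`
#' bp of their neighbour join the same cluster, and clusters with at least
#' `min_support` members (at least one with mapping quality above 0, so that
#' multi-mapping reads never seed a consensus) emit a consensus. The consensus
#' sequence is the per-column plurality base over the aligned members; its
#' breakpoint is the median clip position.
#'
#' @param clips Tibble of clip records with columns `name`, `chrom`,
#'   `breakpoint` (reference position of the (virtual) clip), `side`
#'   (`LEFT_CLIP`/`RIGHT_CLIP`), `seq`, `pre_bp` (number of read bases
#'   preceding the breakpoint), `source` (`SR`/`HSR`), `mapq`, `mate_chrom`,
#'   `mate_pos`.
#' @param stats [library_stats()].
#' @param cluster_tol Maximum gap between neighbouring clip positions within a
#'   cluster (default 5 bp).
#' @param min_support Minimum reads per consensus (default 3).
#' @return Tibble of consensuses: `chrom`, `side`, `breakpoint`, `sequence`,
#'   `junction_offset` (bases of `sequence` preceding the breakpoint),
#'   `support`, `support_sr`, `support_hsr`, `mean_mapq`, `opp_lo`, `opp_hi`
#'   (opposite breakpoint range), `degraded_range`.
#' @export
pile_consensuses <- function(clips, stats, cluster_tol = 5L, min_support = 3L) {
  empty <- tibble::tibble(chrom = character(), side = character(),
                          breakpoint = integer(), sequence = character(),
                          junction_offset = integer(), support = integer(),
                          support_sr = integer(), support_hsr = integer(),
                          mean_mapq = double(), opp_lo = integer(),
                          opp_hi = integer(), degraded_range = logical())
  if (nrow(clips) == 0) return(empty)
  out <- list()
  for (grp in split(clips, paste(clips$chrom, clips$side))) {
    grp <- dplyr::arrange(grp, .data$breakpoint)
    cl_id <- cumsum(c(1L, diff(grp$breakpoint) > cluster_tol))
    for (cl in split(grp, cl_id)) {
      if (nrow(cl) < min_support || all(cl$mapq == 0L)) next
      bp <- as.integer(round(median(cl$breakpoint)))
      # place member sequences in breakpoint coordinates (clip boundary at 0)
      offs <- as.integer(-cl$pre_bp + (cl$breakpoint - bp))
      cons <- cpp_pileup_consensus(cl$seq, offs)
      if (nchar(cons$seq) < stats$read_len / 2) next
      rng <- opposite_breakpoint_range(cl, bp, cl$side[1], stats)
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = cl$chrom[1], side = cl$side[1], breakpoint = bp,
        sequence = cons$seq, junction_offset = -cons$start,
        support = nrow(cl),
        support_sr = sum(cl$source == "SR"),
        support_hsr = sum(cl$source == "HSR"),
        mean_mapq = mean(cl$mapq),
        opp_lo = rng[1], opp_hi = rng[2],
        degraded_range = attr(rng, "degraded"))
    }
  }
  if (length(out) == 0) return(empty)
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$breakpoint)
}

#' Opposite breakpoint range of a consensus
#'
#' The interval, inferred from the clustered reads' mates, within which the
#' second breakpoint of the consensus's CNV must lie. For a right-clipped
#' consensus it is `[min mate start, max mate end + max_is)`, mirrored for a
#' left-clipped one. With no usable mates, the fallback is
#' `[breakpoint, breakpoint + max_is)` (right side; mirrored), flagged
#' degraded.
#'
#' @param members Tibble of clustered reads with `mate_chrom`, `mate_pos`,
#'   `chrom`.
#' @param breakpoint Consensus breakpoint.
#' @param side `"LEFT_CLIP"` or `"RIGHT_CLIP"`.
#' @param stats [library_stats()].
#' @return Integer vector `c(lo, hi)` with attribute `degraded`.
#' @export
opposite_breakpoint_range <- function(members, breakpoint, side, stats) {
  ok <- !is.na(members$mate_pos) & members$mate_chrom == members$chrom
  max_is <- as.integer(ceiling(stats$max_is))
  if (!any(ok)) {
    rng <- if (side == "RIGHT_CLIP") c(breakpoint, breakpoint + max_is)
           else c(breakpoint - max_is, breakpoint)
    rng <- as.integer(pmax(rng, 0L))
    attr(rng, "degraded") <- TRUE
    return(rng)
  }
  ms <- members$mate_pos[ok]
  me <- members$mate_pos[ok] + stats$read_len
  rng <- if (side == "RIGHT_CLIP") c(min(ms), max(me) + max_is)
         else c(min(ms) - max_is, max(me))
  rng <- as.integer(pmax(rng, 0L))
  if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1L
  attr(rng, "degraded") <- FALSE
  rng
}

#' Pair right-clipped with left-clipped consensuses
#'
#' A pair is valid when each consensus's breakpoint lies within the other's
#' opposite breakpoint range. Valid pairs are matched greedily by descending
#' combined support (ties towards smaller breakpoints); each consensus is used
#' at most once.
#'
#' @param consensuses Output of [pile_consensuses()] (both sides together).
#' @return List with `pairs` (tibble of index pairs `right_idx`, `left_idx`
#'   into `consensuses`) and `unpaired` (integer indices).
#' @export
pair_consensuses <- function(consensuses) {
  rights <- which(consensuses$side == "RIGHT_CLIP")
  lefts <- which(consensuses$side == "LEFT_CLIP")
  cand <- list()
  for (r in rights) {
    for (l in lefts) {
      if (consensuses$chrom[r] != consensuses$chrom[l]) next
      bl <- consensuses$breakpoint[l]; br <- consensuses$breakpoint[r]
      if (bl >= consensuses$opp_lo[r] && bl <= consensuses$opp_hi[r] &&
          br >= consensuses$opp_lo[l] && br <= consensuses$opp_hi[l]) {
        cand[[length(cand) + 1L]] <- tibble::tibble(
          right_idx = r, left_idx = l,
          combined = consensuses$support[r] + consensuses$support[l])
      }
    }
  }
  if (length(cand) == 0) {
    return(list(pairs = tibble::tibble(right_idx = integer(),
                                       left_idx = integer()),
                unpaired = seq_len(nrow(consensuses))))
  }
  cand <- dplyr::bind_rows(cand)
  cand <- cand[order(-cand$combined, consensuses$breakpoint[cand$right_idx],
                     consensuses$breakpoint[cand$left_idx]), ]
  used <- logical(nrow(consensuses))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    r <- cand$right_idx[k]; l <- cand$left_idx[k]
    if (!used[r] && !used[l]) {
      keep[k] <- TRUE; used[r] <- TRUE; used[l] <- TRUE
    }
  }
  list(pairs = cand[keep, c("right_idx", "left_idx")],
       unpaired = which(!used))
}

#' Assemble a junction sequence from a consensus pair
#'
#' Overlaps the suffix of the right-clipped consensus with the prefix of the
#' left-clipped consensus (minimum overlap 20 bp, minimum identity 90%). The
#' junction offset is the clip position of the right-clipped consensus within
#' the merged sequence.
#'
#' @param right,left One-row consensus tibbles (right-clipped, left-clipped).
#' @param min_overlap Minimum overlap length (default 20).
#' @param min_identity Minimum overlap identity (default 0.9).
#' @return A junction list (`sequence`, `junction_offset`, `provenance`,
#'   support fields) or `NULL` when no acceptable overlap exists.
#' @export
assemble_junction_from_pair <- function(right, left, min_overlap = 20L,
                                        min_identity = 0.9) {
  ov <- cpp_best_overlap(right$sequence, left$sequence, min_overlap, min_identity)
  if (ov[1] == 0L) return(NULL)
  merged <- paste0(right$sequence,
                   substr(left$sequence, ov[1] + 1L, nchar(left$sequence)))
  list(sequence = merged, junction_offset = right$junction_offset,
       provenance = "PAIRED",
       chrom = right$chrom,
       support_sr = right$support_sr + left$support_sr,
       support_hsr = right$support_hsr + left$support_hsr,
       mean_mapq = mean(c(right$mean_mapq, left$mean_mapq)),
       win_lo = min(right$opp_lo, left$opp_lo, right$breakpoint, left$breakpoint),
       win_hi = max(right$opp_hi, left$opp_hi, right$breakpoint, left$breakpoint))
}

#' Extend an unpaired consensus into a junction sequence
#'
#' Greedy overlap-layout-consensus: repeatedly appends the local read with the
#' best suffix-prefix overlap (>= `min_overlap` bp, >= `min_identity`) that
#' extends the sequence past the clip, up to `2 * read_len` of novel sequence.
#' Returns `NULL` when the clipped tail cannot be grown to at least
#' `1.5 * read_len`.
#'
#' @param consensus One-row consensus tibble.
#' @param local_seqs Character vector of read sequences mapped close to or
#'   overlapping the consensus (reference orientation).
#' @param stats [library_stats()].
#' @inheritParams assemble_junction_from_pair
#' @return A junction list as in [assemble_junction_from_pair()] (provenance
#'   `"EXTENDED"`) or `NULL`.
#' @export
extend_unpaired <- function(consensus, local_seqs, stats, min_overlap = 20L,
                            min_identity = 0.9) {
  rl <- stats$read_len
  rightwards <- consensus$side == "RIGHT_CLIP"
  jseq <- consensus$sequence
  if (!rightwards) jseq <- strrev(jseq)
  seqs <- if (rightwards) local_seqs else vapply(local_seqs, strrev, character(1))
  novel <- 0L
  repeat {
    best <- NULL; best_score <- -Inf
    for (s in seqs) {
      ov <- cpp_best_overlap(jseq, s, min_overlap, min_identity)
      ext <- nchar(s) - ov[1]
      if (ov[1] == 0L || ext <= 0L) next
      score <- (ov[1] - ov[2]) - 5L * ov[2]
      if (score > best_score || (score == best_score && !is.null(best) &&
                                 ext > (nchar(best) - attr(best, "ov")))) {
        best <- s; attr(best, "ov") <- ov[1]; best_score <- score
      }
    }
    if (is.null(best)) break
    add <- substr(best, attr(best, "ov") + 1L, nchar(best))
    if (novel + nchar(add) > 2L * rl) {
      add <- substr(add, 1L, 2L * rl - novel)
    }
    if (!nzchar(add)) break
    jseq <- paste0(jseq, add)
    novel <- novel + nchar(add)
    if (novel >= 2L * rl) break
  }
  offset <- consensus$junction_offset
  tail_len <- nchar(jseq) - (if (rightwards) offset
                             else nchar(consensus$sequence) - offset)
  if (tail_len < 1.5 * rl) return(NULL)
  if (!rightwards) {
    jseq <- strrev(jseq)
    offset <- nchar(jseq) - (nchar(consensus$sequence) - consensus$junction_offset)
  }
  list(sequence = jseq, junction_offset = offset, provenance = "EXTENDED",
       chrom = consensus$chrom,
       support_sr = consensus$support_sr, support_hsr = consensus$support_hsr,
       mean_mapq = consensus$mean_mapq,
       win_lo = min(consensus$opp_lo, consensus$breakpoint),
       win_hi = max(consensus$opp_hi, consensus$breakpoint))
}

strrev <- function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")

#' Realign a junction sequence to the reference to call a precise CNV
#'
#' Splits the junction sequence at every position, aligns both halves locally
#' and independently to the reference window, and keeps the split maximising
#' the score sum subject to both halves anchoring with at least 90% of their
#' length aligned. With the left half ending at `e_l` and the right half
#' starting at `s_r`, `s_r > e_l` calls a deletion `[e_l, s_r)` and
#' `s_r < e_l` a tandem duplication `[s_r, e_l)`; events shorter than
#' `min_size` (or with `s_r == e_l`) are discarded. Emitted calls are precise
#' and left-aligned to their leftmost equivalent position.
#'
#' @param junction A junction list (see [assemble_junction_from_pair()]).
#' @param reference Named character vector of contig sequences.
#' @param stats [library_stats()].
#' @param scheme [alignment_scheme()].
#' @param min_size Minimum event size (default 50; use 30 for small-indel
#'   mode).
#' @param min_half_cov Minimum aligned fraction of each half (default 0.9).
#' @param min_half Minimum half length considered (default 10).
#' @return A one-row candidate tibble or `NULL`.
#' @export
realign_junction <- function(junction, reference, stats,
                             scheme = alignment_scheme(), min_size = 50L,
                             min_half_cov = 0.9, min_half = 10L) {
  contig <- reference[[junction$chrom]]
  max_is <- as.integer(ceiling(stats$max_is))
  w0 <- max(0L, as.integer(junction$win_lo) - max_is)
  w1 <- min(nchar(contig), as.integer(junction$win_hi) + max_is)
  window <- subseq0(contig, w0, w1)
  jseq <- junction$sequence
  n <- nchar(jseq)
  if (n < 2L * min_half || !nzchar(window)) return(NULL)
  pre <- prefix_scores(jseq, window, scheme)
  suf <- suffix_scores(jseq, window, scheme)
  idx <- seq.int(min_half, n - min_half)
  gain <- pre[idx] + suf[idx + 1L]
  ord <- idx[order(-gain, idx)]
  for (i in utils::head(ord, 8L)) {
    lh <- local_align(substr(jseq, 1L, i), window, scheme)
    rh <- local_align(substr(jseq, i + 1L, n), window, scheme)
    if ((lh$query_end - lh$query_start) < min_half_cov * i) next
    if ((rh$query_end - rh$query_start) < min_half_cov * (n - i)) next
    e_l <- w0 + lh$ref_end
    s_r <- w0 + rh$ref_start
    if (s_r == e_l) return(NULL)
    svtype <- if (s_r > e_l) "DEL" else "DUP"
    start <- min(e_l, s_r); end <- max(e_l, s_r)
    if (end - start < min_size) return(NULL)
    la <- left_align_interval(contig, start, end)
    jscore <- lh$score + rh$score
    return(tibble::tibble(
      chrom = junction$chrom, start = la[1], end = la[2], svtype = svtype,
      precise = TRUE, source = "SPLIT",
      support_sr = junction$support_sr, support_hsr = junction$support_hsr,
      support_disc = 0L, mean_mapq = junction$mean_mapq,
      junction_score = jscore,
      junction_score_ratio = jscore / (scheme$match * n)))
  }
  NULL
}

# Shift an interval to its leftmost equivalent position within a tandem
# context: while the base preceding start equals the base preceding end,
# shift left by one.
left_align_interval <- function(contig, start, end) {
  while (start > 0L &&
         substr(contig, start, start) == substr(contig, end, end)) {
    start <- start - 1L; end <- end - 1L
  }
  c(as.integer(start), as.integer(end))
}

#' @rdname realign_junction
#' @param calls Callset tibble with `chrom`, `start`, `end`.
#' @export
left_align_calls <- function(calls, reference) {
  if (nrow(calls) == 0) return(calls)
  for (k in seq_len(nrow(calls))) {
    la <- left_align_interval(reference[[calls$chrom[k]]],
                              calls$start[k], calls$end[k])
    calls$start[k] <- la[1]; calls$end[k] <- la[2]
  }
  calls
}

# Full split module for one chromosome: evidence -> clip records -> consensus
# -> pairing -> junctions -> realignment.
split_call_cnvs <- function(evidence, reference, stats,
                            scheme = alignment_scheme(), min_size = 50L,
                            min_support = 3L, cluster_tol = 5L) {
  reads <- evidence$reads
  qlen <- nchar(reads$seq)
  rclips <- dplyr::filter(reads, .data$right_clip > 0L) |>
    dplyr::mutate(side = "RIGHT_CLIP",
                  breakpoint = .data$pos + .data$ref_span,
                  pre_bp = nchar(.data$seq) - .data$right_clip,
                  source = "SR")
  lclips <- dplyr::filter(reads, .data$left_clip > 0L) |>
    dplyr::mutate(side = "LEFT_CLIP", breakpoint = .data$pos,
                  pre_bp = .data$left_clip, source = "SR")
  cols <- c("name", "chrom", "breakpoint", "side", "seq", "pre_bp", "source",
            "mapq", "mate_chrom", "mate_pos")
  clips <- dplyr::bind_rows(rclips[, cols], lclips[, cols])
  if (nrow(evidence$hsr) > 0) {
    hs <- dplyr::mutate(evidence$hsr, side = .data$virtual_side,
                        breakpoint = .data$virtual_breakpoint,
                        pre_bp = .data$split_index, source = "HSR")
    clips <- dplyr::bind_rows(clips, hs[, cols])
  }
  cons <- pile_consensuses(clips, stats, cluster_tol, min_support)
  if (nrow(cons) == 0) return(empty_callset())
  pr <- pair_consensuses(cons)
  junctions <- list()
  for (k in seq_len(nrow(pr$pairs))) {
    j <- assemble_junction_from_pair(cons[pr$pairs$right_idx[k], ],
                                     cons[pr$pairs$left_idx[k], ])
    if (!is.null(j)) junctions[[length(junctions) + 1L]] <- j
    else {
      # pair rejected for lack of overlap: fall back to extending each side
      pr$unpaired <- c(pr$unpaired, pr$pairs$right_idx[k], pr$pairs$left_idx[k])
    }
  }
  max_is <- as.integer(ceiling(stats$max_is))
  for (u in pr$unpaired) {
    cu <- cons[u, ]
    local <- dplyr::filter(reads, .data$chrom == cu$chrom,
                           .data$pos >= cu$breakpoint - max_is - stats$read_len,
                           .data$pos <= cu$breakpoint + max_is)
    j <- extend_unpaired(cu, local$seq, stats)
    if (!is.null(j)) junctions[[length(junctions) + 1L]] <- j
  }
  calls <- purrr::map(junctions, realign_junction, reference = reference,
                      stats = stats, scheme = scheme, min_size = min_size)
  calls <- dplyr::bind_rows(calls)
  if (nrow(calls) == 0) return(empty_callset())
  # collapse duplicates that realigned to the same event
  dplyr::arrange(calls, .data$chrom, .data$start, .data$end,
                 -(.data$support_sr + .data$support_hsr)) |>
    dplyr::distinct(.data$chrom, .data$start, .data$end, .data$svtype,
                    .keep_all = TRUE)
}

empty_callset <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 svtype = character(), precise = logical(), source = character(),
                 support_sr = integer(), support_hsr = integer(),
                 support_disc = integer(), mean_mapq = double(),
                 junction_score = integer(), junction_score_ratio = double())
}
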