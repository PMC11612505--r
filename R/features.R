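#' Collect the insert sizes of read pairs spanning a candidate CNV
#'
#' For a deletion, the insert sizes of inward (forward-reverse) pairs whose
#' forward read ends at or before the event start and whose reverse read
#' starts at or after the event end. For a duplication, outward pairs
#' bracketing the interval contribute a virtual insert size
#' `mu + (right read start - left read end)`, so the same shift machinery
#' applies to both types (the outward span is 0-expected under the null).
#'
#' @param cnv One-row callset tibble.
#' @param pairs Pair classification tibble from [classify_pairs()].
#' @param stats [library_stats()].
#' @return Numeric vector of (virtual) insert sizes (possibly empty).
#' @export
collect_spanning_insert_sizes <- function(cnv, pairs, stats) {
  p <- dplyr::filter(pairs, .data$chrom == cnv$chrom)
  if (cnv$svtype == "DEL") {
    p <- dplyr::filter(p, .data$kind %in% c("CONCORDANT", "DISCORDANT_DEL"),
                       .data$left_read_end <= cnv$start,
                       .data$right_read_start >= cnv$end)
    p$insert_size
  } else {
    p <- dplyr::filter(p, .data$kind == "DISCORDANT_DUP",
                       .data$right_read_start >= cnv$start - stats$max_is,
                       .data$left_read_end <= cnv$end + stats$max_is,
                       .data$left_read_end >= cnv$start - stats$max_is,
                       .data$right_read_start <= cnv$end + stats$max_is)
    stats$mu + (p$right_read_start - p$left_read_end)
  }
}

#' Insert-size shift test and size confidence interval
#'
#' Under the null (no CNV), spanning insert sizes are modelled i.i.d.
#' Normal(mu, sigma). The estimated shift is `mean(sizes) - mu`; the size
#' point estimate is the shift for deletions and `shift + mu` for
#' duplications (outward spans measure `size - fragment`). The 95% interval
#' is `point +/- 1.96 sigma / sqrt(n)` and the p-value the upper-tail
#' probability of the observed mean under the null. With no spanning pairs
#' the p-value is 1 and the interval undefined-wide.
#'
#' @param sizes Numeric vector from [collect_spanning_insert_sizes()].
#' @param stats [library_stats()].
#' @param svtype `"DEL"` or `"DUP"`.
#' @return One-row tibble: `size_point`, `ci_lo`, `ci_hi`, `p_value`,
#'   `n_pairs`.
#' @export
insert_size_test <- function(sizes, stats, svtype = "DEL") {
  n <- length(sizes)
  if (n == 0) {
    return(tibble::tibble(size_point = NA_real_, ci_lo = -Inf, ci_hi = Inf,
                          p_value = 1, n_pairs = 0L))
  }
  shift <- mean(sizes) - stats$mu
  point <- if (svtype == "DUP") shift + stats$mu else shift
  se <- if (stats$sigma > 0) stats$sigma / sqrt(n) else 0
  z <- if (se > 0) shift / se else ifelse(shift > 0, Inf, ifelse(shift < 0, -Inf, 0))
  tibble::tibble(size_point = point,
                 ci_lo = point - 1.96 * se, ci_hi = point + 1.96 * se,
                 p_value = pnorm(z, lower.tail = FALSE),
                 n_pairs = n)
}

#' Per-contig coverage from high-quality primary alignments
#'
#' @param alignments Alignment tibble.
#' @param reference Named character vector of contig sequences.
#' @param min_mapq Minimum mapping quality (default 20).
#' @return Named list of [IRanges][IRanges::coverage] Rle coverage vectors.
#' @export
coverage_track <- function(alignments, reference, min_mapq = 20L) {
  cs <- cpp_cigar_stats(alignments$cigar)
  a <- dplyr::mutate(alignments, ref_span = cs[, 1]) |>
    dplyr::filter(.data$mapq >= min_mapq)
  lapply(setNames(names(reference), names(reference)), function(ct) {
    ai <- a[a$chrom == ct, ]
    IRanges::coverage(IRanges::IRanges(start = ai$pos + 1L,
                                       width = ai$ref_span),
                      width = nchar(reference[[ct]]))
  })
}

#' Read-depth features of a candidate CNV
#'
#' Mean per-base depth over the event and over flanking windows of
#' `max(2 * read_len, 300)` bp each side (truncated and flagged at contig
#' edges).
#'
#' @param cnv One-row callset tibble.
#' @param coverage Output of [coverage_track()].
#' @param stats [library_stats()].
#' @return One-row tibble: `depth_event`, `depth_left_flank`,
#'   `depth_right_flank`, `flank_degraded`.
#' @export
depth_features <- function(cnv, coverage, stats) {
  cov <- coverage[[cnv$chrom]]
  clen <- length(cov)
  fw <- max(2L * stats$read_len, 300L)
  mean_depth <- function(lo, hi) { # 0-based half-open
    lo <- max(lo, 0L); hi <- min(hi, clen)
    if (hi <= lo) return(NA_real_)
    mean(S4Vectors::window(cov, start = lo + 1L, end = hi))
  }
  lf_lo <- cnv$start - fw
  rf_hi <- cnv$end + fw
  tibble::tibble(
    depth_event = mean_depth(cnv$start, cnv$end),
    depth_left_flank = mean_depth(lf_lo, cnv$start),
    depth_right_flank = mean_depth(cnv$end, rf_hi),
    flank_degraded = lf_lo < 0L || rf_hi > clen)
}

#' Hard filters for candidate CNVs
#'
#' A candidate passes when all of the following hold: (1) split plus hidden
#' split support of at least `min_support` reads, or at least `min_support`
#' discordant pairs; (2) insert-size p-value at most `alpha`, or a precise
#' call whose junction realigns with score ratio at least 0.9; (3) for events
#' of at least 300 bp, depth consistency (deletion: event depth at most 0.75
#' of the mean flank depth; duplication: at least 1.25 of it). Failures are
#' reported as ordered reasons.
#'
#' @param call One-row callset tibble with feature columns (`support_sr`,
#'   `support_hsr`, `support_disc`, `p_value`, `precise`,
#'   `junction_score_ratio`, `depth_event`, `depth_left_flank`,
#'   `depth_right_flank`).
#' @param min_support Minimum supporting reads/pairs (default 3).
#' @param alpha Significance level for the insert-size test (default 0.05).
#' @param min_depth_len Event length from which the depth clause applies
#'   (default 300).
#' @return `"PASS"` or a `;`-separated string of failure reasons
#'   (`support`, `p_value`, `depth`).
#' @export
hard_filter <- function(call, min_support = 3L, alpha = 0.05,
                        min_depth_len = 300L) {
  reasons <- character()
  if (!((call$support_sr + call$support_hsr) >= min_support ||
        call$support_disc >= min_support)) {
    reasons <- c(reasons, "support")
  }
  stat_ok <- (!is.na(call$p_value) && call$p_value <= alpha) ||
    (isTRUE(call$precise) && !is.na(call$junction_score_ratio) &&
       call$junction_score_ratio >= 0.9)
  if (!stat_ok) reasons <- c(reasons, "p_value")
  if ((call$end - call$start) >= min_depth_len) {
    flank <- mean(c(call$depth_left_flank, call$depth_right_flank), na.rm = TRUE)
    depth_ok <- if (is.na(flank) || is.na(call$depth_event)) TRUE
    else if (call$svtype == "DEL") call$depth_event <= 0.75 * flank
    else call$depth_event >= 1.25 * flank
    if (!depth_ok) reasons <- c(reasons, "depth")
  }
  if (length(reasons) == 0) "PASS" else paste(reasons, collapse = ";")
}

#' Annotate candidate calls with features and filter them
#'
#' Computes the insert-size statistics, depth features and the filter verdict
#' for every candidate, using the random-forest model when supplied and the
#' hard filters otherwise.
#'
#' @param candidates Candidate callset tibble.
#' @param pairs Pair classification tibble.
#' @param coverage Output of [coverage_track()].
#' @param stats [library_stats()].
#' @param model Optional [rf_train()] model.
#' @param min_support,alpha Passed to [hard_filter()].
#' @return The candidates with feature columns and a `filter` column.
#' @export
annotate_and_filter <- function(candidates, pairs, coverage, stats,
                                model = NULL, min_support = 3L, alpha = 0.05) {
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates, size_point = double(), ci_lo = double(),
                         ci_hi = double(), p_value = double(),
                         n_pairs = integer(), depth_event = double(),
                         depth_left_flank = double(),
                         depth_right_flank = double(),
                         flank_degraded = logical(), filter = character()))
  }
  feats <- purrr::map(seq_len(nrow(candidates)), function(k) {
    cnv <- candidates[k, ]
    sz <- collect_spanning_insert_sizes(cnv, pairs, stats)
    dplyr::bind_cols(insert_size_test(sz, stats, cnv$svtype),
                     depth_features(cnv, coverage, stats))
  })
  out <- dplyr::bind_cols(candidates, dplyr::bind_rows(feats))
  if (is.null(model)) {
    out$filter <- vapply(seq_len(nrow(out)), function(k) {
      hard_filter(out[k, ], min_support, alpha)
    }, character(1))
  } else {
    prob <- rf_apply(model, out)
    out$filter <- ifelse(prob >= 0.5, "PASS", "rf")
  }
  out
}
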