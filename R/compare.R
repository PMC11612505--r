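#' Comparison parameter presets
#'
#' Two CNVs match when (1) the distance between their start coordinates and
#' between their end coordinates are each at most `max_distance`; (2) the
#' fraction of the shorter event overlapped by the longer is at least
#' `min_overlap`; and (3) the difference between the two lengths is at most
#' `max_len_diff`. The precise preset is (100 bp, 0.8, 100 bp) and the
#' imprecise preset (500 bp, 0.5, 500 bp); the imprecise preset applies
#' whenever either record is imprecise.
#'
#' @param preset `"precise"` or `"imprecise"`, or use the individual
#'   arguments.
#' @param max_distance,min_overlap,max_len_diff Override individual
#'   thresholds.
#' @return A `match_params` object.
#' @export
match_params <- function(preset = c("precise", "imprecise"),
                         max_distance = NULL, min_overlap = NULL,
                         max_len_diff = NULL) {
  preset <- match.arg(preset)
  p <- if (preset == "precise") list(max_distance = 100, min_overlap = 0.8,
                                     max_len_diff = 100)
       else list(max_distance = 500, min_overlap = 0.5, max_len_diff = 500)
  if (!is.null(max_distance)) p$max_distance <- max_distance
  if (!is.null(min_overlap)) p$min_overlap <- min_overlap
  if (!is.null(max_len_diff)) p$max_len_diff <- max_len_diff
  structure(p, class = "match_params")
}

params_for <- function(a, b, params) {
  if (!is.null(params)) return(params)
  imprec <- isFALSE(a[["precise"]] %||% TRUE) || isFALSE(b[["precise"]] %||% TRUE)
  match_params(if (imprec) "imprecise" else "precise")
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0 || is.na(x[1])) y else x

#' Do two CNVs match?
#'
#' @param a,b One-row callset tibbles (or lists) with `chrom`, `start`, `end`,
#'   `svtype` and optionally `precise`.
#' @param params A [match_params()] object, or `NULL` to choose the preset
#'   from the records' precision flags (imprecise when either is imprecise).
#' @return `TRUE`/`FALSE`; records of different types never match.
#' @export
cnv_match <- function(a, b, params = NULL) {
  if (a$svtype != b$svtype || a$chrom != b$chrom) return(FALSE)
  p <- params_for(a, b, params)
  la <- a$end - a$start; lb <- b$end - b$start
  if (abs(a$start - b$start) > p$max_distance) return(FALSE)
  if (abs(a$end - b$end) > p$max_distance) return(FALSE)
  if (abs(la - lb) > p$max_len_diff) return(FALSE)
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
  ov / min(la, lb) >= p$min_overlap
}

#' Repeat-aware CNV matching
#'
#' When both events fall within the same annotated tandem repeat (each with at
#' least 90% of its span covered by that repeat interval), the same deletion
#' or duplication may legitimately be reported at disjoint coordinates, so
#' only the length criterion is checked. Otherwise matching delegates to
#' [cnv_match()].
#'
#' @inheritParams cnv_match
#' @param repeats Repeat track tibble (see [read_repeat_track()]), or `NULL`.
#' @export
cnv_match_repeat_aware <- function(a, b, params = NULL, repeats = NULL) {
  if (a$svtype != b$svtype || a$chrom != b$chrom) return(FALSE)
  p <- params_for(a, b, params)
  if (!is.null(repeats)) {
    ra <- containing_repeat(a, repeats)
    rb <- containing_repeat(b, repeats)
    if (!is.na(ra) && !is.na(rb) && ra == rb) {
      return(abs((a$end - a$start) - (b$end - b$start)) <= p$max_len_diff)
    }
  }
  cnv_match(a, b, p)
}

# Index (in repeats) of a repeat interval covering >= 90% of the cnv, NA if
# none; ties towards the shortest repeat unit.
containing_repeat <- function(cnv, repeats, min_cov = 0.9) {
  r <- repeats[repeats$chrom == cnv$chrom, , drop = FALSE]
  if (nrow(r) == 0) return(NA_integer_)
  len <- cnv$end - cnv$start
  cov <- pmax(0, pmin(r$end, cnv$end) - pmax(r$start, cnv$start)) / len
  ok <- which(cov >= min_cov)
  if (length(ok) == 0) return(NA_integer_)
  ok[order(r$unit_length[ok])][1] |>
    (\(i) which(repeats$chrom == cnv$chrom)[i])()
}

#' Is a CNV inside a tandem repeat?
#'
#' @inheritParams cnv_match_repeat_aware
#' @param cnv One-row callset tibble.
#' @return `TRUE` iff at least 90% of the CNV is covered by a single repeat
#'   interval.
#' @export
in_tandem_repeat <- function(cnv, repeats) {
  !is.na(containing_repeat(cnv, repeats))
}

#' Number of repeat units spanned by a CNV
#'
#' The length of the event divided by the repeat unit length; when several
#' annotated repeats contain the event, callers should pick the one with the
#' shortest unit (the convention used by [cnv_match_repeat_aware()]).
#'
#' @param cnv One-row callset tibble (or list with `start`, `end`).
#' @param unit_length Repeat unit length in bp.
#' @param tol Tolerance (in copies) for the integer-multiple predicate
#'   (default 0.05).
#' @return A list with `units` (real) and `is_integer_multiple`.
#' @export
repeat_units <- function(cnv, unit_length, tol = 0.05) {
  if (unit_length <= 0) rlang::abort("unit_length must be positive")
  u <- (cnv$end - cnv$start) / unit_length
  list(units = u, is_integer_multiple = abs(u - round(u)) <= tol)
}

#' Match a tandem duplication against an insertion record
#'
#' Benchmark catalogues represent tandem duplications as insertions (site +
#' inserted sequence), while a duplication call reports only the duplicated
#' reference span. The two match when the insertion site is within
#' `max_distance` of either duplication boundary and the local alignment of
#' the inserted sequence I against D' (the duplicated reference sequence D
#' concatenated `ceiling(len(I)/len(D))` times) covers at least 80% of I.
#'
#' @param dup One-row duplication callset tibble.
#' @param ins A list/row with `site` (position) and `inserted_seq`.
#' @param reference Named character vector of contig sequences (for D).
#' @param params [match_params()] or `NULL` (chosen from `dup$precise`).
#' @param scheme [alignment_scheme()].
#' @param min_cov Minimum covered fraction of I (default 0.8).
#' @return `TRUE`/`FALSE`.
#' @export
dup_ins_match <- function(dup, ins, reference, params = NULL,
                          scheme = alignment_scheme(), min_cov = 0.8) {
  stopifnot(dup$svtype == "DUP")
  p <- params_for(dup, list(precise = TRUE), params)
  if (min(abs(ins$site - dup$start), abs(ins$site - dup$end)) > p$max_distance) {
    return(FALSE)
  }
  D <- subseq0(reference[[dup$chrom]], dup$start, dup$end)
  i_len <- nchar(ins$inserted_seq)
  d_len <- nchar(D)
  if (i_len < 1 || d_len < 1) return(FALSE)
  n <- ceiling(i_len / d_len)
  dprime <- strrep(D, n)
  al <- local_align(ins$inserted_seq, dprime, scheme)
  (al$query_end - al$query_start) / i_len >= min_cov
}

#' Cluster a multi-sample CNV catalogue by clique cover
#'
#' Builds the compatibility graph ([cnv_match()], non-repeat-aware) and covers
#' it heuristically with cliques: events are scanned in start order and added
#' to the first open clique whose members they all match, otherwise they open
#' a new clique. Every cluster is a clique by construction, and every event
#' belongs to exactly one cluster. The cluster representative takes the
#' member-wise median start and end.
#'
#' @param cnvs Callset tibble (possibly multi-sample; extra columns kept).
#' @param params [match_params()] or `NULL` for per-pair presets.
#' @return List with `members` (the input plus a `cluster` id column) and
#'   `clusters` (one row per cluster: representative coordinates and size).
#' @export
cluster_catalogue <- function(cnvs, params = NULL) {
  cnvs <- dplyr::arrange(cnvs, .data$svtype, .data$chrom, .data$start, .data$end)
  n <- nrow(cnvs)
  cluster <- integer(n)
  current <- integer(0) # member row indices of the clique being grown
  next_id <- 0L
  for (k in seq_len(n)) {
    grows <- length(current) > 0 &&
      all(vapply(current, function(m) cnv_match(cnvs[k, ], cnvs[m, ], params),
                 logical(1)))
    if (grows) {
      current <- c(current, k)
    } else {
      next_id <- next_id + 1L
      current <- k
    }
    cluster[k] <- next_id
  }
  cnvs$cluster <- cluster
  reps <- dplyr::group_by(cnvs, .data$cluster) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     svtype = dplyr::first(.data$svtype),
                     start = as.integer(round(median(.data$start))),
                     end = as.integer(round(median(.data$end))),
                     n_members = dplyr::n(), .groups = "drop")
  list(members = cnvs, clusters = reps)
}

#' Sensitivity and precision of a callset against a truth set
#'
#' Matching is repeat-aware when a repeat track is supplied. Truth
#' duplications may be represented as insertion records (rows with `svtype ==
#' "INS"`, `site` and `inserted_seq` columns) and are then matched against
#' called duplications via [dup_ins_match()]. Sensitivity is the fraction of
#' truth events matched by any call; precision the fraction of calls matching
#' any truth event (NA when the respective set is empty).
#'
#' @param calls,truth Callset tibbles.
#' @param reference Reference sequences (needed for insertion matching).
#' @param params [match_params()] or `NULL`.
#' @param repeats Repeat track or `NULL`.
#' @return A `cnv_evaluation` object (list with `sensitivity`, `precision`,
#'   `n_truth`, `n_calls`, and the matched flags).
#' @export
evaluate_calls <- function(calls, truth, reference = NULL, params = NULL,
                           repeats = NULL) {
  one_match <- function(cl, tr) {
    if (tr$svtype == "INS") {
      cl$svtype == "DUP" && !is.null(reference) &&
        dup_ins_match(cl, list(site = tr$site, inserted_seq = tr$inserted_seq),
                      reference, params)
    } else {
      cnv_match_repeat_aware(cl, tr, params, repeats)
    }
  }
  truth_matched <- rep(FALSE, nrow(truth))
  calls_matched <- rep(FALSE, nrow(calls))
  for (t in seq_len(nrow(truth))) {
    for (c in seq_len(nrow(calls))) {
      if (one_match(calls[c, ], truth[t, ])) {
        truth_matched[t] <- TRUE
        calls_matched[c] <- TRUE
      }
    }
  }
  structure(list(
    sensitivity = if (nrow(truth) > 0) mean(truth_matched) else NA_real_,
    precision = if (nrow(calls) > 0) mean(calls_matched) else NA_real_,
    n_truth = nrow(truth), n_calls = nrow(calls),
    truth_matched = truth_matched, calls_matched = calls_matched),
    class = "cnv_evaluation")
}

#' @export
print.cnv_evaluation <- function(x, ...) {
  cat(sprintf("<cnv_evaluation> sensitivity %.3f (%d truth), precision %.3f (%d calls)\n",
              x$sensitivity, x$n_truth, x$precision, x$n_calls))
  invisible(x)
}
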