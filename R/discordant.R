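#' Cluster discordant pairs into imprecise candidate CNVs
#'
#' Same-kind discordant pairs are compatible when their left read ends are
#' within `max_is` of each other and their right read starts are within
#' `max_is`. Maximal compatible groups are formed by single linkage; groups
#' with at least `min_disc_support` pairs emit an imprecise candidate:
#' deletion `[max left_read_end, min right_read_start)`, duplication
#' `[min right_read_start, max left_read_end)`.
#'
#' @param pairs Pair classification tibble from [classify_pairs()].
#' @param stats [library_stats()].
#' @param min_disc_support Minimum supporting pairs (default 3).
#' @param min_size Minimum event size (default 50).
#' @return Candidate callset tibble (`precise = FALSE`, `source =
#'   "DISCORDANT"`).
#' @export
cluster_discordant <- function(pairs, stats, min_disc_support = 3L,
                               min_size = 50L) {
  max_is <- stats$max_is
  out <- list()
  disc <- dplyr::filter(pairs, .data$kind %in% c("DISCORDANT_DEL", "DISCORDANT_DUP"))
  for (grp in split(disc, paste(disc$chrom, disc$kind))) {
    grp <- dplyr::arrange(grp, .data$left_read_end)
    n <- nrow(grp)
    if (n < min_disc_support) next
    # single-linkage union-find on the compatibility graph
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (grp$left_read_end[j] - grp$left_read_end[i] > max_is) break
        if (abs(grp$right_read_start[j] - grp$right_read_start[i]) <= max_is) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    root <- vapply(seq_len(n), find, integer(1))
    for (cl in split(grp, root)) {
      if (nrow(cl) < min_disc_support) next
      kind <- cl$kind[1]
      if (kind == "DISCORDANT_DEL") {
        start <- max(cl$left_read_end); end <- min(cl$right_read_start)
      } else {
        start <- min(cl$left_read_start); end <- max(cl$right_read_end)
      }
      if (end - start < min_size) next
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = cl$chrom[1], start = as.integer(start), end = as.integer(end),
        svtype = if (kind == "DISCORDANT_DEL") "DEL" else "DUP",
        precise = FALSE, source = "DISCORDANT",
        support_sr = 0L, support_hsr = 0L, support_disc = nrow(cl),
        mean_mapq = mean(cl$mapq), junction_score = NA_integer_,
        junction_score_ratio = NA_real_)
    }
  }
  if (length(out) == 0) return(empty_callset())
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

#' Merge split-module and discordant-module candidates
#'
#' When a discordant call matches a split call under the imprecise comparison
#' parameters, only the split call (with its precise coordinates) survives.
#' Unmatched calls from both sources are retained.
#'
#' @param split_calls,discordant_calls Candidate callset tibbles.
#' @param params [match_params()] used for the redundancy check (default the
#'   imprecise preset).
#' @return Merged candidate callset tibble, sorted.
#' @export
merge_candidates <- function(split_calls, discordant_calls,
                             params = match_params("imprecise")) {
  keep <- rep(TRUE, nrow(discordant_calls))
  for (d in seq_len(nrow(discordant_calls))) {
    for (s in seq_len(nrow(split_calls))) {
      if (cnv_match(discordant_calls[d, ], split_calls[s, ], params)) {
        keep[d] <- FALSE
        break
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(split_calls, discordant_calls[keep, ]),
                 .data$chrom, .data$start, .data$end)
}
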