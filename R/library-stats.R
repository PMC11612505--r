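#' Estimate sequencing-library statistics
#'
#' Computes the insert-size distribution (mean `mu`, standard deviation
#' `sigma`) and the modal read length from concordant forward-reverse pairs.
#' The discordance threshold is `max_is = mu + 3 * sigma`: a pair with insert
#' size above `max_is` is deletion-type discordant.
#'
#' @param alignments Alignment tibble. Only primary records of
#'   forward-reverse pairs mapped to the same contig are used; insert size is
#'   the absolute template length.
#' @param sample_size Number of pairs to sample (the first `sample_size`
#'   concordant pairs in file order). Default 100,000.
#' @param min_pairs Minimum usable pairs for a valid estimate (default 1000).
#'   Set lower only for controlled experiments.
#' @return A `library_stats` object: `read_len`, `mu`, `sigma`, `max_is`,
#'   `n_sampled`.
#' @export
estimate_library_stats <- function(alignments, sample_size = 1e5,
                                   min_pairs = 1000L) {
  a <- dplyr::filter(alignments,
                     .data$chrom == .data$mate_chrom,
                     .data$is_reverse != .data$mate_reverse,
                     !is.na(.data$insert_size), .data$insert_size != 0L)
  # one record per pair: keep the forward-strand mate of inward-facing pairs
  fw <- dplyr::filter(a, !.data$is_reverse, .data$insert_size > 0L)
  fw <- utils::head(fw, sample_size)
  if (nrow(fw) < min_pairs) {
    rlang::abort(sprintf(
      "library statistics require at least %d usable pairs; got %d",
      min_pairs, nrow(fw)))
  }
  isz <- abs(fw$insert_size)
  rl_tab <- table(nchar(fw$seq))
  library_stats(read_len = as.integer(names(rl_tab)[which.max(rl_tab)]),
                mu = mean(isz),
                sigma = stats::sd(isz) * sqrt((length(isz) - 1) / length(isz)),
                n_sampled = length(isz))
}

#' @rdname estimate_library_stats
#' @param read_len,mu,sigma,n_sampled Components of a `library_stats` object,
#'   for constructing one directly (e.g. for simulations).
#' @export
library_stats <- function(read_len, mu, sigma, n_sampled = 1L) {
  stopifnot(sigma >= 0, read_len > 0)
  if (is.na(sigma)) sigma <- 0
  structure(list(read_len = as.integer(read_len), mu = mu, sigma = sigma,
                 max_is = mu + 3 * sigma, n_sampled = as.integer(n_sampled)),
            class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf(
    "<library_stats> read_len %d, mu %.1f, sigma %.1f, max_is %.1f (n = %d pairs)\n",
    x$read_len, x$mu, x$sigma, x$max_is, x$n_sampled))
  invisible(x)
}
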