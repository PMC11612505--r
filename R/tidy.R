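#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for callsets, evaluations and ES results
#'
#' `tidy()` returns one row per record (calls, matched flags, breakpoint
#' reads); `glance()` a one-row summary.
#'
#' @param x A `cnv_callset`, `cnv_evaluation` or `es_result`.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.cnv_callset <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cnv_callset")
  tibble::as_tibble(out)
}

#' @rdname tidiers
#' @export
glance.cnv_callset <- function(x, ...) {
  tibble::tibble(
    n_calls = nrow(x),
    n_del = sum(x$svtype == "DEL"),
    n_dup = sum(x$svtype == "DUP"),
    n_pass = sum(x$filter == "PASS"),
    n_precise = sum(x$precise),
    median_size = if (nrow(x)) median(x$end - x$start) else NA_real_)
}

#' @rdname tidiers
#' @export
tidy.cnv_evaluation <- function(x, ...) {
  tibble::tibble(metric = c("sensitivity", "precision"),
                 value = c(x$sensitivity, x$precision),
                 n = c(x$n_truth, x$n_calls))
}

#' @rdname tidiers
#' @export
glance.cnv_evaluation <- function(x, ...) {
  tibble::tibble(sensitivity = x$sensitivity, precision = x$precision,
                 n_truth = x$n_truth, n_calls = x$n_calls)
}

#' @rdname tidiers
#' @export
tidy.es_result <- function(x, ...) x$reads

#' @rdname tidiers
#' @export
glance.es_result <- function(x, ...) {
  tibble::tibble(es = x$es, n_total = x$n_total, n_support = x$n_support)
}

#' Plot methods
#'
#' `autoplot()` on a callset shows the size distribution per SV type and
#' filter status; on an evaluation, a sensitivity/precision bar chart; on an
#' ES result, per-read support along the CNV allele.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name plots
NULL

#' @rdname plots
#' @export
autoplot.cnv_callset <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$end - .data$start,
                                  fill = .data$filter == "PASS")) +
    ggplot2::geom_histogram(bins = 30, position = "stack") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~svtype) +
    ggplot2::labs(x = "event size (bp)", y = "calls", fill = "PASS") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.cnv_evaluation <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(width = 0.5, fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.es_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$offset, y = as.integer(.data$supports))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "read offset on the CNV allele",
                  y = "supports the CNV (0/1)") +
    ggplot2::theme_minimal()
}
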