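rf_feature_cols <- c("support_sr", "support_hsr", "support_disc", "mean_mapq",
                     "junction_score_ratio", "p_value", "n_pairs",
                     "depth_event", "depth_left_flank", "depth_right_flank")

rf_feature_frame <- function(calls) {
  x <- calls[, intersect(rf_feature_cols, names(calls)), drop = FALSE]
  for (m in setdiff(rf_feature_cols, names(x))) x[[m]] <- 0
  x <- as.data.frame(x[, rf_feature_cols])
  x[is.na(x)] <- 0
  x
}

#' Train / apply the random-forest call filter
#'
#' A class-balanced probability forest (200 trees by default) over the
#' per-call features; labels typically come from matching raw calls against a
#' long-read truth set with [evaluate_calls()]. `rf_apply()` returns the PASS
#' probability; a call passes at probability 0.5. When no model is available,
#' the caller falls back to the hard filters.
#'
#' @param calls Feature-annotated callset tibble (see [annotate_and_filter()]).
#' @param labels Logical vector (`TRUE` = true call), same length as
#'   `nrow(calls)`.
#' @param seed Integer seed for the forest.
#' @param num_trees Number of trees (default 200).
#' @return `rf_train()`: a `cnv_filter_model`; `rf_apply()`: numeric PASS
#'   probabilities.
#' @export
rf_train <- function(calls, labels, seed = 1L, num_trees = 200L) {
  if (nrow(calls) != length(labels)) {
    rlang::abort("feature/label length mismatch")
  }
  x <- rf_feature_frame(calls)
  y <- factor(ifelse(labels, "pass", "fail"), levels = c("fail", "pass"))
  w <- ifelse(labels, 0.5 / max(sum(labels), 1L),
              0.5 / max(sum(!labels), 1L))
  fit <- ranger::ranger(x = x, y = y, probability = TRUE,
                        num.trees = num_trees, seed = seed,
                        case.weights = w, num.threads = 1L)
  structure(list(fit = fit, features = rf_feature_cols), class = "cnv_filter_model")
}

#' @rdname rf_train
#' @param model A `cnv_filter_model`.
#' @export
rf_apply <- function(model, calls) {
  x <- rf_feature_frame(calls)
  p <- predict(model$fit, data = x, num.threads = 1L)$predictions
  unname(p[, "pass"])
}

#' @export
print.cnv_filter_model <- function(x, ...) {
  cat(sprintf("<cnv_filter_model> ranger forest, %d trees, %d features\n",
              x$fit$num.trees, length(x$features)))
  invisible(x)
}
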