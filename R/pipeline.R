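#' Call CNVs (deletions and tandem duplications) from paired-end alignments
#'
#' The full calling pipeline: evidence scan (split reads, hidden split reads,
#' discordant pairs), split-module consensus piling / junction assembly /
#' realignment, discordant-module clustering, candidate merging, feature
#' computation (insert-size test, read depth, junction score) and filtering
#' (random forest when a model is given, hard filters otherwise).
#'
#' @param alignments Alignment tibble ([read_alignments()]) or a BAM/SAM path.
#' @param reference Named character vector ([read_reference()]) or FASTA path.
#' @param stats [library_stats()], estimated from the alignments when `NULL`.
#' @param scheme [alignment_scheme()].
#' @param min_size Minimum event size (default 50 bp; 30 for small-indel
#'   mode).
#' @param min_support Minimum same-side supporting reads / discordant pairs
#'   (default 3).
#' @param hsr_min_score Minimum HSR-score (default 8).
#' @param alpha Insert-size test significance level (default 0.05).
#' @param use_hsr Use hidden split reads (set `FALSE` for a split-read-only
#'   caller).
#' @param model Optional [rf_train()] filter model.
#' @return A `cnv_callset` tibble (one row per candidate, with features and a
#'   `filter` column), sorted by position, left-aligned coordinates.
#' @export
cnv_call <- function(alignments, reference, stats = NULL,
                     scheme = alignment_scheme(), min_size = 50L,
                     min_support = 3L, hsr_min_score = 8L, alpha = 0.05,
                     use_hsr = TRUE, model = NULL) {
  if (is.character(alignments) && length(alignments) == 1) {
    alignments <- read_alignments(alignments)
  }
  if (is.character(reference) && length(reference) == 1 && is.null(names(reference))) {
    reference <- read_reference(reference)
  }
  missing_ct <- setdiff(unique(alignments$chrom), names(reference))
  if (length(missing_ct) > 0) {
    rlang::abort(sprintf(
      "alignment contigs missing from the reference: %s",
      paste(missing_ct, collapse = ", ")))
  }
  if (nrow(alignments) == 0) {
    out <- annotate_and_filter(empty_callset(), NULL, NULL, NULL)
    return(as_cnv_callset(out, stats))
  }
  if (is.null(stats)) stats <- estimate_library_stats(alignments)
  ev <- scan_evidence(alignments, reference, stats, scheme, use_hsr,
                      hsr_min_score)
  split_calls <- split_call_cnvs(ev, reference, stats, scheme, min_size,
                                 min_support)
  disc_calls <- cluster_discordant(ev$pairs, stats, min_support, min_size)
  cand <- merge_candidates(split_calls, disc_calls)
  cand <- left_align_calls(cand, reference)
  cov <- coverage_track(alignments, reference)
  out <- annotate_and_filter(cand, ev$pairs, cov, stats, model,
                             min_support, alpha)
  message(sprintf(
    "hiddensplit: %d split + %d discordant candidates -> %d merged, %d PASS",
    nrow(split_calls), nrow(disc_calls), nrow(out),
    sum(out$filter == "PASS")))
  as_cnv_callset(dplyr::arrange(out, .data$chrom, .data$start, .data$end),
                 stats)
}

as_cnv_callset <- function(x, stats = NULL) {
  class(x) <- unique(c("cnv_callset", class(tibble::as_tibble(x))))
  attr(x, "library_stats") <- stats
  x
}

#' Run the calling pipeline on files (CLI backend)
#'
#' @param config Named list: `bam`, `ref`, `out` (VCF path), and optionally
#'   `repeats`, `model` (RDS path), `min_size`, `min_support`,
#'   `hsr_min_score`, `alpha`, `features_out`, `no_hsr`.
#' @return The output VCF path, invisibly.
#' @export
run_call <- function(config) {
  reference <- read_reference(config$ref)
  alignments <- read_alignments(config$bam)
  model <- if (!is.null(config$model)) readRDS(config$model) else NULL
  calls <- cnv_call(alignments, reference,
                    min_size = config$min_size %||% 50L,
                    min_support = config$min_support %||% 3L,
                    hsr_min_score = config$hsr_min_score %||% 8L,
                    alpha = config$alpha %||% 0.05,
                    use_hsr = !isTRUE(config$no_hsr), model = model)
  write_vcf(calls, reference, config$out, attr(calls, "library_stats"))
  if (!is.null(config$features_out)) {
    write.table(as.data.frame(calls), config$features_out, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(config$out)
}

#' Compare a callset against a truth callset (CLI backend)
#'
#' @param config Named list: `calls`, `truth` (VCF paths), optionally
#'   `ref`, `repeats` (BED), `out` (metrics TSV).
#' @return A `cnv_evaluation`, invisibly.
#' @export
run_compare <- function(config) {
  calls <- read_vcf(config$calls)
  truth <- read_vcf(config$truth)
  reference <- if (!is.null(config$ref)) read_reference(config$ref) else NULL
  repeats <- if (!is.null(config$repeats)) read_repeat_track(config$repeats) else NULL
  ev <- evaluate_calls(calls, truth, reference, repeats = repeats)
  print(ev)
  if (!is.null(config$out)) {
    write.table(data.frame(sensitivity = ev$sensitivity,
                           precision = ev$precision,
                           n_truth = ev$n_truth, n_calls = ev$n_calls),
                config$out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(ev)
}

#' Cluster one or more callsets across samples (CLI backend)
#'
#' @param config Named list: `calls` (character vector of VCF paths), `out`
#'   (clusters TSV).
#' @return The cluster table, invisibly.
#' @export
run_cluster <- function(config) {
  cnvs <- dplyr::bind_rows(lapply(seq_along(config$calls), function(i) {
    dplyr::mutate(read_vcf(config$calls[i]), sample = i)
  }))
  cl <- cluster_catalogue(cnvs)
  if (!is.null(config$out)) {
    write.table(as.data.frame(cl$clusters), config$out, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(cl)
}

#' Expected-support scores for a callset (CLI backend)
#'
#' @param config Named list: `calls` (VCF), `ref` (FASTA), `read_len`
#'   (default 150), `out` (TSV).
#' @return Tibble of per-call ES scores, invisibly.
#' @export
run_es <- function(config) {
  calls <- read_vcf(config$calls)
  reference <- read_reference(config$ref)
  l <- config$read_len %||% 150L
  es <- purrr::map_dbl(seq_len(nrow(calls)), function(k) {
    expected_support(build_allele_pair(calls[k, ], reference), l)$es
  })
  out <- dplyr::mutate(calls, es = es)
  for (k in seq_len(nrow(out))) {
    message(sprintf("%s:%d-%d %s ES = %.3f", out$chrom[k], out$start[k],
                    out$end[k], out$svtype[k], out$es[k]))
  }
  if (!is.null(config$out)) {
    write.table(as.data.frame(out), config$out, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(out)
}

#' Simulate a dataset to files (CLI backend)
#'
#' @param config A [sim_config()] plus an `out_dir` element.
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config) {
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(seed = config$seed %||% 1L,
                    contig_length = config$contig_length %||% 1e6L,
                    repeat_specs = config$repeat_specs,
                    planted_cnvs = config$planted_cnvs,
                    coverage = config$coverage %||% 30,
                    read_len = config$read_len %||% 150L,
                    mu = config$mu %||% 400, sigma = config$sigma %||% 50,
                    subst_error = config$subst_error %||% 0.001)
  sim <- simulate_dataset(cfg)
  write_reference(sim$reference, file.path(out_dir, "reference.fa"))
  write_sam(sim$alignments, sim$reference, file.path(out_dir, "reads.sam"))
  write_repeat_track(sim$repeats, file.path(out_dir, "repeats.bed"))
  write.table(as.data.frame(sim$truth), file.path(out_dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth_calls <- dplyr::mutate(sim$truth, precise = TRUE, source = "SPLIT",
                               filter = "PASS")
  write_vcf(truth_calls, sim$reference, file.path(out_dir, "truth.vcf"))
  invisible(out_dir)
}

#' Train the random-forest filter from a features table (CLI backend)
#'
#' @param config Named list: `features` (TSV from `run_call`'s
#'   `features_out`), `truth` (VCF), optionally `ref`, `repeats`, `seed`,
#'   `out` (RDS model path).
#' @return The trained model, invisibly.
#' @export
run_train <- function(config) {
  feats <- tibble::as_tibble(read.table(config$features, sep = "\t",
                                        header = TRUE,
                                        stringsAsFactors = FALSE))
  truth <- read_vcf(config$truth)
  reference <- if (!is.null(config$ref)) read_reference(config$ref) else NULL
  repeats <- if (!is.null(config$repeats)) read_repeat_track(config$repeats) else NULL
  ev <- evaluate_calls(feats, truth, reference, repeats = repeats)
  model <- rf_train(feats, ev$calls_matched, seed = config$seed %||% 1L)
  if (!is.null(config$out)) saveRDS(model, config$out)
  invisible(model)
}
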