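#' Write a callset as VCF 4.2
#'
#' Calls use symbolic alleles: POS is the 1-based position of the base
#' immediately preceding the event (REF is that base, or `N` without a
#' reference), ALT is `<DEL>` or `<DUP>`. INFO carries END, SVTYPE, SVLEN
#' (negative for deletions), evidence counts, the insert-size p-value, depth
#' features, and IMPRECISE with CIPOS/CIEND (`+/- (max_is - read_len)`) for
#' discordant-only calls.
#'
#' @param calls Callset tibble, sorted by `chrom`, `start`.
#' @param reference Named character vector of contig sequences (or a named
#'   integer vector of contig lengths; REF bases are then `N`).
#' @param path Output path.
#' @param stats Optional [library_stats()] (for CIPOS/CIEND width).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, reference, path, stats = NULL) {
  contig_len <- if (is.character(reference)) nchar(reference) else reference
  if (is.unsorted(order(match(calls$chrom, names(contig_len)), calls$start))) {
    calls <- calls[order(match(calls$chrom, names(contig_len)), calls$start,
                         calls$end), ]
  }
  ci <- if (!is.null(stats)) as.integer(round(stats$max_is - stats$read_len)) else 0L
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=hiddensplit",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_len), contig_len),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Tandem duplication\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the event (1-based inclusive)\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Event length (negative for deletions)\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise breakpoints\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Confidence interval around POS\">",
    "##INFO=<ID=CIEND,Number=2,Type=Integer,Description=\"Confidence interval around END\">",
    "##INFO=<ID=SOURCE,Number=1,Type=String,Description=\"Evidence module (SPLIT or DISCORDANT)\">",
    "##INFO=<ID=SUPPORT_SR,Number=1,Type=Integer,Description=\"Supporting split reads\">",
    "##INFO=<ID=SUPPORT_HSR,Number=1,Type=Integer,Description=\"Supporting hidden split reads\">",
    "##INFO=<ID=SUPPORT_DISC,Number=1,Type=Integer,Description=\"Supporting discordant pairs\">",
    "##INFO=<ID=PVAL,Number=1,Type=Float,Description=\"Insert-size shift p-value\">",
    "##INFO=<ID=DEPTH_EVENT,Number=1,Type=Float,Description=\"Mean depth inside the event\">",
    "##INFO=<ID=DEPTH_LF,Number=1,Type=Float,Description=\"Mean depth of the left flank\">",
    "##INFO=<ID=DEPTH_RF,Number=1,Type=Float,Description=\"Mean depth of the right flank\">",
    "##FILTER=<ID=support,Description=\"Insufficient read support\">",
    "##FILTER=<ID=p_value,Description=\"Insert sizes consistent with no event\">",
    "##FILTER=<ID=depth,Description=\"Read depth inconsistent with the event\">",
    "##FILTER=<ID=rf,Description=\"Rejected by the random-forest filter\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE")
  fmt_num <- function(x) ifelse(is.na(x), ".", sprintf("%.6g", x))
  rec <- character(nrow(calls))
  for (k in seq_len(nrow(calls))) {
    cl <- calls[k, ]
    pos1 <- cl$start # 1-based position of the base preceding the event
    refbase <- if (is.character(reference)) {
      substr(reference[[cl$chrom]], pos1, pos1)
    } else "N"
    if (!nzchar(refbase)) refbase <- "N"
    len <- cl$end - cl$start
    info <- c(
      sprintf("SVTYPE=%s", cl$svtype),
      sprintf("END=%d", cl$end),
      sprintf("SVLEN=%d", if (cl$svtype == "DEL") -len else len),
      if (!isTRUE(cl$precise)) "IMPRECISE",
      if (!isTRUE(cl$precise)) sprintf("CIPOS=-%d,%d;CIEND=-%d,%d", ci, ci, ci, ci),
      sprintf("SOURCE=%s", cl[["source"]] %||% "SPLIT"),
      sprintf("SUPPORT_SR=%d", cl[["support_sr"]] %||% 0L),
      sprintf("SUPPORT_HSR=%d", cl[["support_hsr"]] %||% 0L),
      sprintf("SUPPORT_DISC=%d", cl[["support_disc"]] %||% 0L),
      if (!is.null(cl[["p_value"]])) sprintf("PVAL=%s", fmt_num(cl[["p_value"]])),
      if (!is.null(cl[["depth_event"]])) sprintf("DEPTH_EVENT=%s", fmt_num(cl[["depth_event"]])),
      if (!is.null(cl[["depth_left_flank"]])) sprintf("DEPTH_LF=%s", fmt_num(cl[["depth_left_flank"]])),
      if (!is.null(cl[["depth_right_flank"]])) sprintf("DEPTH_RF=%s", fmt_num(cl[["depth_right_flank"]])))
    rec[k] <- paste(cl$chrom, pos1, sprintf("hs_%s_%d", cl$svtype, k), refbase,
                    sprintf("<%s>", cl$svtype), ".",
                    cl[["filter"]] %||% "PASS",
                    paste(info, collapse = ";"), "GT", "./.",
                    sep = "\t")
  }
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a CNV callset from VCF
#'
#' Parses a VCF (via vcfR) into the package's callset tibble, inverting
#' [write_vcf()]: 0-based half-open `start`/`end`, `svtype`, `precise`,
#' evidence counts and feature fields when present.
#'
#' @param path VCF path.
#' @return Callset tibble.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_callset())
  info1 <- function(key, type = "integer") {
    val <- vcfR::extract.info(v, element = key)
    if (type == "integer") suppressWarnings(as.integer(val))
    else if (type == "numeric") suppressWarnings(as.numeric(val))
    else val
  }
  svtype <- info1("SVTYPE", "character")
  tibble::tibble(
    chrom = fix$CHROM,
    start = as.integer(fix$POS), # POS is the base preceding the event
    end = info1("END"),
    svtype = svtype,
    precise = !grepl("(^|;)IMPRECISE(;|$)", fix$INFO),
    source = info1("SOURCE", "character"),
    support_sr = info1("SUPPORT_SR"),
    support_hsr = info1("SUPPORT_HSR"),
    support_disc = info1("SUPPORT_DISC"),
    p_value = info1("PVAL", "numeric"),
    depth_event = info1("DEPTH_EVENT", "numeric"),
    depth_left_flank = info1("DEPTH_LF", "numeric"),
    depth_right_flank = info1("DEPTH_RF", "numeric"),
    filter = fix$FILTER)
}
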