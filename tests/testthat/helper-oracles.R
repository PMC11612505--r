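# Independent oracles and small fixture builders used across the test files.

# Biostrings Smith-Waterman as an independent oracle for local alignment
# scores (same gap convention: first gap base costs opening + extension).
# Biostrings forces at least one aligned pair, so the empty alignment maps to
# a score floor of 0.
bs_local_score <- function(query, target, scheme = alignment_scheme()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scheme$match, mismatch = scheme$mismatch, baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = query, subject = target, type = "local",
    substitutionMatrix = mat,
    gapOpening = -scheme$gap_open, gapExtension = -scheme$gap_extend)
  max(0, Biostrings::score(pa))
}

# Exhaustive HSR score via independent per-half alignments (Biostrings):
# max over every split i of score(r[1..i]) + score(r[i+1..n]) - score(r).
brute_hsr_score <- function(seq, window, scheme = alignment_scheme()) {
  n <- nchar(seq)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scheme$match, mismatch = scheme$mismatch, baseOnly = TRUE)
  halves <- c(substring(seq, 1, 1:(n - 1)), substring(seq, 2:n, n))
  sc <- pmax(0, Biostrings::score(Biostrings::pairwiseAlignment(
    pattern = halves, subject = window, type = "local",
    substitutionMatrix = mat,
    gapOpening = -scheme$gap_open, gapExtension = -scheme$gap_extend)))
  pre <- sc[1:(n - 1)]
  suf <- sc[n:(2 * n - 2)]
  max(pre + suf) - bs_local_score(seq, window, scheme)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Minimal alignment-tibble row builder.
mk_aln <- function(name = "r1", chrom = "c1", pos = 0L, mapq = 60L,
                   cigar = "150M", seq = strrep("A", 150), is_reverse = FALSE,
                   is_read1 = TRUE, mate_chrom = chrom, mate_pos = pos,
                   mate_reverse = !is_reverse, insert_size = 400L) {
  tibble::tibble(name = name, chrom = chrom, pos = as.integer(pos),
                 mapq = as.integer(mapq), cigar = cigar, seq = seq,
                 is_reverse = is_reverse, is_read1 = is_read1,
                 mate_chrom = mate_chrom, mate_pos = as.integer(mate_pos),
                 mate_reverse = mate_reverse,
                 insert_size = as.integer(insert_size))
}

# A forward/reverse pair with the given positions and read length.
mk_pair <- function(name, chrom, fwd_pos, rev_pos, read_len = 100L,
                    seq = strrep("A", read_len), mapq = 60L) {
  cigar <- paste0(read_len, "M")
  tl <- max(fwd_pos, rev_pos) + read_len - min(fwd_pos, rev_pos)
  dplyr::bind_rows(
    mk_aln(name, chrom, fwd_pos, mapq, cigar, seq, FALSE, TRUE,
           chrom, rev_pos, TRUE, if (fwd_pos <= rev_pos) tl else -tl),
    mk_aln(name, chrom, rev_pos, mapq, cigar, seq, TRUE, FALSE,
           chrom, fwd_pos, FALSE, if (fwd_pos <= rev_pos) -tl else tl))
}

# Substitute exactly n random positions.
mutate_seq_n <- function(seq, n) {
  if (n == 0) return(seq)
  subst_at(seq, sample(nchar(seq), n))
}

# Substitute bases at given 1-based positions with a fixed different base.
subst_at <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) ch[p] <- chartr("ACGT", "CGTA", ch[p])
  paste(ch, collapse = "")
}

# Simulated-dataset builders shared by pipeline and acceptance tests.
hsr_regime_config <- function(seed, n_arrays, contig_length) {
  set.seed(seed + 500000L)
  specs <- tibble::tibble(
    unit_length = sample(60:120, n_arrays, replace = TRUE),
    copies = sample(5:7, n_arrays, replace = TRUE),
    divergence = runif(n_arrays, 0.02, 0.05))
  sim_config(seed = seed, contig_length = contig_length,
             repeat_specs = specs,
             planted_cnvs = function(ref, reps)
               plan_repeat_cnvs(ref, reps, specs$copies, seed = seed))
}

unique_regime_config <- function(seed, n_del, n_dup, contig_length,
                                 size_range = c(60L, 2000L)) {
  sim_config(seed = seed, contig_length = contig_length,
             planted_cnvs = function(ref, reps)
               plan_unique_cnvs(ref, reps, n_del = n_del, n_dup = n_dup,
                                size_range = size_range, seed = seed))
}
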