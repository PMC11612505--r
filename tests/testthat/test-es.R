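test_that("allele pairs do the length bookkeeping and flag truncation", {
  set.seed(71)
  ref <- c(c1 = random_seq(9000))
  del <- tibble::tibble(chrom = "c1", start = 4000L, end = 4100L, svtype = "DEL")
  ap <- build_allele_pair(del, ref)
  expect_equal(nchar(ap$r_cnv), nchar(ap$r_ref) - 100L)
  expect_equal(ap$b1, 2000L)
  expect_equal(ap$b2, 2000L)
  expect_false(ap$truncated)

  dup <- tibble::tibble(chrom = "c1", start = 4000L, end = 4080L, svtype = "DUP")
  apd <- build_allele_pair(dup, ref)
  expect_equal(nchar(apd$r_cnv), nchar(apd$r_ref) + 80L)
  expect_equal(apd$b2 - apd$b1, 80L)

  # event near the contig edge: flank truncated and flagged
  edge <- tibble::tibble(chrom = "c1", start = 500L, end = 600L, svtype = "DEL")
  ape <- build_allele_pair(edge, ref)
  expect_true(ape$truncated)
  expect_equal(ape$flank_left, 500L)

  out <- tibble::tibble(chrom = "c1", start = 8950L, end = 9100L, svtype = "DEL")
  expect_error(build_allele_pair(out, ref), "contig")
})

test_that("breakpoint-read enumeration counts positioned reads", {
  set.seed(72)
  ref <- c(c1 = random_seq(9000))
  del <- tibble::tibble(chrom = "c1", start = 4000L, end = 4100L, svtype = "DEL")
  ap <- build_allele_pair(del, ref)
  expect_equal(nrow(enumerate_breakpoint_reads(ap, 100L)), 99L)
  expect_equal(nrow(enumerate_breakpoint_reads(ap, 2L)), 1L)

  dup <- tibble::tibble(chrom = "c1", start = 4000L, end = 4150L, svtype = "DUP")
  apd <- build_allele_pair(dup, ref)
  # the two copy boundaries are 150 >= l apart: two disjoint windows
  expect_equal(nrow(enumerate_breakpoint_reads(apd, 60L)), 2L * 59L)

  expect_error(enumerate_breakpoint_reads(ap, 10000L), "shorter")
})

test_that("ES is 0 for full-unit events in perfect repeats and ~1 for unique junctions", {
  set.seed(73)
  # the analytic zero requires the read not to outspan the remaining copies
  # (unit length >= read length here)
  unit <- random_seq(120)
  contig <- paste0(random_seq(700), unit, unit, random_seq(700))
  ref <- c(c1 = contig)
  # delete one full copy of the perfect 2-copy repeat
  del <- tibble::tibble(chrom = "c1", start = 700L, end = 820L, svtype = "DEL")
  es0 <- expected_support(build_allele_pair(del, ref, flank = 400L), 100L)
  expect_equal(es0$es, 0)

  # duplicating one copy of a perfect repeat is equally invisible
  dup <- tibble::tibble(chrom = "c1", start = 700L, end = 820L, svtype = "DUP")
  esd <- expected_support(build_allele_pair(dup, ref, flank = 400L), 100L)
  expect_equal(esd$es, 0)

  # unique random junction: essentially every breakpoint read supports the
  # deletion (the rare exceptions are coincidental micro-homologies that let
  # a junction-grazing read tie on the reference allele)
  es_all <- vapply(1:5, function(k) {
    contig2 <- random_seq(2200)
    ref2 <- c(c1 = contig2)
    del2 <- tibble::tibble(chrom = "c1", start = 1000L, end = 1150L,
                           svtype = "DEL")
    expected_support(build_allele_pair(del2, ref2, flank = 400L), 60L)$es
  }, double(1))
  expect_true(all(es_all >= 0.9))
  expect_gte(mean(es_all), 0.95)
})

test_that("ES on a diverged repeat is fractional and matches the per-read oracle", {
  set.seed(74)
  unit <- random_seq(60)
  c2 <- subst_at(unit, 30) # single diverged base between the copies
  contig <- paste0(random_seq(500), unit, c2, random_seq(500))
  ref <- c(c1 = contig)
  del <- tibble::tibble(chrom = "c1", start = 500L, end = 560L, svtype = "DEL")
  ap <- build_allele_pair(del, ref, flank = 300L)
  res <- expected_support(ap, 50L)
  expect_gt(res$es, 0)
  expect_lt(res$es, 1)
  # independent per-read oracle through Biostrings scores
  reads <- enumerate_breakpoint_reads(ap, 50L)
  oracle <- vapply(reads$seq, function(r) {
    bs_local_score(r, ap$r_cnv) > bs_local_score(r, ap$r_ref)
  }, logical(1))
  expect_equal(res$es, mean(oracle))
})

test_that("ES is invariant under reverse complement of the alleles", {
  set.seed(75)
  unit <- random_seq(50)
  contig <- paste0(random_seq(400), unit, subst_at(unit, c(10, 25)),
                   random_seq(400))
  ref <- c(c1 = contig)
  del <- tibble::tibble(chrom = "c1", start = 400L, end = 450L, svtype = "DEL")
  ap <- build_allele_pair(del, ref, flank = 250L)
  res <- expected_support(ap, 40L)
  ap_rc <- ap
  ap_rc$r_ref <- revcomp(ap$r_ref)
  ap_rc$r_cnv <- revcomp(ap$r_cnv)
  n <- nchar(ap$r_cnv)
  ap_rc$b1 <- n - ap$b2
  ap_rc$b2 <- n - ap$b1
  res_rc <- expected_support(ap_rc, 40L)
  expect_equal(res$es, res_rc$es)
})

test_that("read-support classification agrees with the ES definition", {
  set.seed(76)
  for (k in 1:20) {
    unit <- random_seq(sample(40:70, 1))
    c2 <- mutate_seq_n(unit, sample(0:4, 1))
    contig <- paste0(random_seq(300), unit, c2, random_seq(300))
    ref <- c(c1 = contig)
    u <- nchar(unit)
    del <- tibble::tibble(chrom = "c1", start = 300L, end = 300L + u,
                          svtype = "DEL")
    ap <- build_allele_pair(del, ref, flank = 200L)
    res <- expected_support(ap, 40L)
    cls <- vapply(res$reads$seq, classify_read_support, character(1),
                  allele = ap)
    expect_equal(res$es, mean(cls %in% c("SPLIT", "HSR")))
  }
})

test_that("single-read classification distinguishes split, hidden and none", {
  set.seed(77)
  contig <- random_seq(3000)
  ref <- c(c1 = contig)
  del <- tibble::tibble(chrom = "c1", start = 1400L, end = 1600L, svtype = "DEL")
  ap <- build_allele_pair(del, ref, flank = 500L)
  # a junction read with unique flanks is a split read
  junction_read <- substr(ap$r_cnv, ap$b1 - 24, ap$b1 + 25)
  expect_equal(classify_read_support(junction_read, ap), "SPLIT")
  # a read entirely within a shared flank supports nothing
  flank_read <- substr(ap$r_cnv, 10, 59)
  expect_equal(classify_read_support(flank_read, ap), "NONE")
  # a junction read in a diverged repeat aligns fully with mismatches: hidden
  unit <- random_seq(80)
  c2 <- subst_at(unit, c(20, 40, 60))
  contig2 <- paste0(random_seq(400), unit, c2, random_seq(400))
  ref2 <- c(c1 = contig2)
  del2 <- tibble::tibble(chrom = "c1", start = 400L, end = 480L, svtype = "DEL")
  ap2 <- build_allele_pair(del2, ref2, flank = 300L)
  hsr_read <- substr(ap2$r_cnv, ap2$b1 - 29, ap2$b1 + 30)
  expect_equal(classify_read_support(hsr_read, ap2), "HSR")
})

test_that("single-read realignment scanning recovers planted full-unit events", {
  set.seed(78)
  unit <- random_seq(60)
  c2 <- subst_at(unit, c(15, 35, 55))
  region <- paste0(random_seq(300), unit, c2, random_seq(300))
  # sample deletes the first copy: read across the junction
  donor <- paste0(substr(region, 1, 300), c2, substr(region, 421, 720))
  reads <- vapply(seq(230, 280, by = 10), function(s) substr(donor, s, s + 99),
                  character(1))
  calls <- hsr_scan_region(reads, region, min_size = 50L)
  expect_gt(nrow(calls), 0)
  expect_true(all(calls$svtype == "DEL"))
  expect_true(all(calls$end - calls$start == 60L))
  expect_true(all(calls$start == 300L))

  # a perfectly aligning read yields nothing
  expect_equal(nrow(hsr_scan_region(substr(region, 101, 200), region)), 0L)
})
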