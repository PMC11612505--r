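stats100 <- library_stats(read_len = 100L, mu = 400, sigma = 50)

mk_clip <- function(name, bp, side, seq, pre_bp, source = "SR", mapq = 60L,
                    mate_pos = bp + 200L, chrom = "c1") {
  tibble::tibble(name = name, chrom = chrom, breakpoint = as.integer(bp),
                 side = side, seq = seq, pre_bp = as.integer(pre_bp),
                 source = source, mapq = as.integer(mapq),
                 mate_chrom = chrom, mate_pos = as.integer(mate_pos))
}

test_that("consensus piling needs three reads and uses the plurality base", {
  set.seed(9)
  anchor <- random_seq(60)
  tail <- random_seq(60)
  seq <- paste0(anchor, tail)
  five <- dplyr::bind_rows(lapply(1:5, function(i) {
    mk_clip(paste0("r", i), 1000L, "RIGHT_CLIP", seq, 60L)
  }))
  cons <- pile_consensuses(five, stats100)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$support, 5L)
  expect_equal(cons$sequence, seq)
  expect_equal(cons$breakpoint, 1000L)
  expect_equal(cons$junction_offset, 60L)

  # two reads are not enough
  expect_equal(nrow(pile_consensuses(five[1:2, ], stats100)), 0L)

  # 2-vs-1 column: plurality wins
  seq_var <- subst_at(seq, 70)
  three <- dplyr::bind_rows(
    mk_clip("a", 1000L, "RIGHT_CLIP", seq, 60L),
    mk_clip("b", 1000L, "RIGHT_CLIP", seq, 60L),
    mk_clip("c", 1000L, "RIGHT_CLIP", seq_var, 60L))
  expect_equal(pile_consensuses(three, stats100)$sequence, seq)
})

test_that("mapq-0 reads never seed a consensus", {
  seq <- paste0(random_seq(60), random_seq(60))
  all0 <- dplyr::bind_rows(lapply(1:4, function(i) {
    mk_clip(paste0("r", i), 500L, "LEFT_CLIP", seq, 60L, mapq = 0L)
  }))
  expect_equal(nrow(pile_consensuses(all0, stats100)), 0L)
  seeded <- dplyr::bind_rows(all0, mk_clip("r5", 500L, "LEFT_CLIP", seq, 60L))
  expect_equal(pile_consensuses(seeded, stats100)$support, 5L)
})

test_that("opposite breakpoint range follows the mate-extent rule", {
  members <- tibble::tibble(chrom = "c1", mate_chrom = "c1",
                            mate_pos = c(12000L, 12100L, 12200L))
  # mates span 12,000-12,300 (mate end = start + read_len), max_is 550
  rng <- opposite_breakpoint_range(members, 11500L, "RIGHT_CLIP", stats100)
  expect_equal(as.integer(rng), c(12000L, 12850L))
  expect_false(attr(rng, "degraded"))

  # mirrored for a left clip
  rng_l <- opposite_breakpoint_range(members, 12500L, "LEFT_CLIP", stats100)
  expect_equal(as.integer(rng_l), c(11450L, 12300L))

  # no mates: degraded fallback [bp, bp + max_is]
  none <- tibble::tibble(chrom = "c1", mate_chrom = NA_character_,
                         mate_pos = NA_integer_)
  rngd <- opposite_breakpoint_range(none, 700L, "RIGHT_CLIP", stats100)
  expect_equal(as.integer(rngd), c(700L, 1250L))
  expect_true(attr(rngd, "degraded"))

  # single mate exactly at the breakpoint still yields an interval covering it
  one <- tibble::tibble(chrom = "c1", mate_chrom = "c1", mate_pos = 900L)
  rng1 <- opposite_breakpoint_range(one, 900L, "RIGHT_CLIP", stats100)
  expect_true(rng1[1] <= 900L && rng1[2] >= 900L)
})

test_that("consensus pairing is mutual-range gated and greedy by support", {
  cons <- tibble::tibble(
    chrom = "c1",
    side = c("RIGHT_CLIP", "RIGHT_CLIP", "LEFT_CLIP"),
    breakpoint = c(1000L, 1010L, 1500L),
    sequence = "X", junction_offset = 1L,
    support = c(8L, 4L, 5L), support_sr = c(8L, 4L, 5L),
    support_hsr = 0L, mean_mapq = 60,
    opp_lo = c(1400L, 1400L, 900L), opp_hi = c(1600L, 1600L, 1100L),
    degraded_range = FALSE)
  pr <- pair_consensuses(cons)
  # two rights compete for one left: the higher combined support wins
  expect_equal(nrow(pr$pairs), 1L)
  expect_equal(pr$pairs$right_idx, 1L)
  expect_equal(sort(pr$unpaired), 2L)

  # non-overlapping ranges: nothing pairs
  cons2 <- cons[c(1, 3), ]
  cons2$opp_lo <- c(5000L, 4000L); cons2$opp_hi <- c(5100L, 4100L)
  pr2 <- pair_consensuses(cons2)
  expect_equal(nrow(pr2$pairs), 0L)
  expect_equal(length(pr2$unpaired), 2L)
})

test_that("pairing is symmetric in input order", {
  set.seed(21)
  cons <- dplyr::bind_rows(lapply(1:6, function(i) {
    right <- i <= 3
    tibble::tibble(chrom = "c1", side = if (right) "RIGHT_CLIP" else "LEFT_CLIP",
                   breakpoint = if (right) 1000L * i else 1000L * (i - 3L) + 400L,
                   sequence = "X", junction_offset = 1L,
                   support = sample(3:9, 1), support_sr = 3L, support_hsr = 0L,
                   mean_mapq = 60,
                   opp_lo = if (right) 1000L * i else 1000L * (i - 3L) - 200L,
                   opp_hi = if (right) 1000L * i + 600L else 1000L * (i - 3L) + 200L,
                   degraded_range = FALSE)
  }))
  pr_a <- pair_consensuses(cons)
  shuf <- c(4, 1, 5, 2, 6, 3)
  pr_b <- pair_consensuses(cons[shuf, ])
  pairs_a <- with(pr_a$pairs, paste(cons$breakpoint[right_idx],
                                    cons$breakpoint[left_idx]))
  cons_b <- cons[shuf, ]
  pairs_b <- with(pr_b$pairs, paste(cons_b$breakpoint[right_idx],
                                    cons_b$breakpoint[left_idx]))
  expect_setequal(pairs_a, pairs_b)
})

test_that("junction assembly accepts only long, high-identity overlaps", {
  set.seed(10)
  a <- random_seq(80)
  b <- random_seq(80)
  shared <- random_seq(30)
  right <- tibble::tibble(chrom = "c1", side = "RIGHT_CLIP", breakpoint = 500L,
                          sequence = paste0(a, shared), junction_offset = 40L,
                          support = 5L, support_sr = 5L, support_hsr = 0L,
                          mean_mapq = 60, opp_lo = 600L, opp_hi = 900L,
                          degraded_range = FALSE)
  left <- tibble::tibble(chrom = "c1", side = "LEFT_CLIP", breakpoint = 700L,
                         sequence = paste0(shared, b), junction_offset = 50L,
                         support = 4L, support_sr = 4L, support_hsr = 0L,
                         mean_mapq = 60, opp_lo = 400L, opp_hi = 600L,
                         degraded_range = FALSE)
  j <- assemble_junction_from_pair(right, left)
  expect_equal(nchar(j$sequence), 80 + 30 + 80)
  expect_equal(j$sequence, paste0(a, shared, b))
  expect_equal(j$junction_offset, 40L)

  # 25 bp with one mismatch (96% identity) is accepted
  shared25 <- random_seq(25)
  right$sequence <- paste0(a, shared25)
  left$sequence <- paste0(subst_at(shared25, 3), b)
  expect_false(is.null(assemble_junction_from_pair(right, left)))

  # a 10 bp overlap is below the length floor
  shared10 <- random_seq(10)
  right$sequence <- paste0(a, shared10)
  left$sequence <- paste0(shared10, b)
  expect_null(assemble_junction_from_pair(right, left))
})

test_that("unpaired consensuses extend through local reads into a junction", {
  set.seed(12)
  # donor junction sequence: anchor (150) + novel tail (300)
  anchor <- random_seq(150)
  tail <- random_seq(300)
  donor <- paste0(anchor, tail)
  cons <- tibble::tibble(chrom = "c1", side = "RIGHT_CLIP", breakpoint = 5000L,
                         sequence = substr(donor, 1, 190),
                         junction_offset = 150L, support = 4L, support_sr = 4L,
                         support_hsr = 0L, mean_mapq = 60, opp_lo = 5000L,
                         opp_hi = 5550L, degraded_range = FALSE)
  # overlapping 100-mers tiled across the junction region
  local <- vapply(seq(1, 340, by = 30), function(s) substr(donor, s, s + 99),
                  character(1))
  st <- library_stats(read_len = 100L, mu = 400, sigma = 50)
  j <- extend_unpaired(cons, local, st)
  expect_false(is.null(j))
  expect_equal(j$provenance, "EXTENDED")
  # the extension reproduces the true junction sequence
  expect_equal(j$sequence, substr(donor, 1, nchar(j$sequence)))
  expect_gte(nchar(j$sequence) - j$junction_offset, 1.5 * 100)

  # no overlapping reads: nothing to extend
  expect_null(extend_unpaired(cons, character(0), st))
})

test_that("junction realignment reconstructs planted events exactly", {
  set.seed(14)
  st <- library_stats(read_len = 100L, mu = 400, sigma = 50)
  for (k in 1:60) {
    contig <- random_seq(4000)
    ref <- c(c1 = contig)
    size <- sample(50:500, 1)
    start <- sample(1200:1800, 1)
    end <- start + size
    svtype <- sample(c("DEL", "DUP"), 1)
    jseq <- if (svtype == "DEL") {
      paste0(substr(contig, start - 149, start), substr(contig, end + 1, end + 150))
    } else {
      paste0(substr(contig, end - 149, end), substr(contig, start + 1, start + 150))
    }
    junction <- list(sequence = jseq, junction_offset = 150L, chrom = "c1",
                     provenance = "PAIRED", support_sr = 5L, support_hsr = 0L,
                     mean_mapq = 60, win_lo = start - 200L, win_hi = end + 200L)
    call <- realign_junction(junction, ref, st)
    expect_false(is.null(call), info = paste(svtype, start, end))
    # compare after left-aligning the planted interval the same way
    la <- hiddensplit:::left_align_interval(contig, start, end)
    expect_equal(c(call$svtype, call$start, call$end),
                 c(svtype, la[1], la[2]), info = paste(svtype, start, end))
    expect_true(call$precise)
  }
})

test_that("a junction with no novel adjacency yields no call", {
  set.seed(15)
  contig <- random_seq(2000)
  ref <- c(c1 = contig)
  st <- library_stats(read_len = 100L, mu = 400, sigma = 50)
  junction <- list(sequence = substr(contig, 801, 1100), junction_offset = 150L,
                   chrom = "c1", provenance = "PAIRED", support_sr = 5L,
                   support_hsr = 0L, mean_mapq = 60, win_lo = 700L,
                   win_hi = 1200L)
  expect_null(realign_junction(junction, ref, st))
})

test_that("the ABBBC duplication junction realigns to the duplicated unit", {
  # reference A B C, sample A B B B C: junction reads join the end of B to the
  # start of B; realignment reports the duplication of B only
  set.seed(16)
  A <- random_seq(400)
  B <- random_seq(120)
  C <- random_seq(400)
  contig <- paste0(A, B, C)
  ref <- c(c1 = contig)
  st <- library_stats(read_len = 100L, mu = 400, sigma = 50)
  jseq <- paste0(substr(B, 21, 120), substr(B, 1, 100)) # B-suffix | B-prefix
  junction <- list(sequence = jseq, junction_offset = 100L, chrom = "c1",
                   provenance = "PAIRED", support_sr = 5L, support_hsr = 0L,
                   mean_mapq = 60, win_lo = 380L, win_hi = 560L)
  call <- realign_junction(junction, ref, st)
  expect_equal(call$svtype, "DUP")
  la <- hiddensplit:::left_align_interval(contig, 400L, 520L)
  expect_equal(c(call$start, call$end), la)
  expect_equal(call$end - call$start, 120L)
})
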