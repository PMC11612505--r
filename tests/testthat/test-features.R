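stats_f <- library_stats(read_len = 100L, mu = 400, sigma = 50)

test_that("spanning pairs are collected by the bracketing condition", {
  cnv <- tibble::tibble(chrom = "c1", start = 5000L, end = 5300L, svtype = "DEL")
  a <- dplyr::bind_rows(
    mk_pair("spans", "c1", 4800L, 5350L),   # fwd ends 4900 <= 5000, rev starts 5350 >= 5300
    mk_pair("inside", "c1", 5050L, 5150L),  # wholly inside the event
    mk_pair("left_only", "c1", 4800L, 5100L))
  pairs <- classify_pairs(a, stats_f)
  sz <- collect_spanning_insert_sizes(cnv, pairs, stats_f)
  expect_equal(sz, 650L) # 5350 + 100 - 4800
  # no pairs span
  cnv2 <- tibble::tibble(chrom = "c1", start = 9000L, end = 9300L, svtype = "DEL")
  expect_length(collect_spanning_insert_sizes(cnv2, pairs, stats_f), 0L)
})

test_that("spanning insert sizes of a homozygous deletion centre on mu + size", {
  set.seed(41)
  cfg <- sim_config(seed = 61, contig_length = 60000L, coverage = 30,
                    planted_cnvs = tibble::tibble(
                      chrom = "sim1", start = 30000L, end = 30300L,
                      svtype = "DEL", zygosity = "HOM"))
  sim <- simulate_dataset(cfg)
  pairs <- classify_pairs(sim$alignments,
                          library_stats(150L, cfg$mu, cfg$sigma))
  sz <- collect_spanning_insert_sizes(sim$truth[1, ], pairs,
                                      library_stats(150L, cfg$mu, cfg$sigma))
  expect_gt(length(sz), 5)
  expect_lt(abs(mean(sz) - (400 + 300)), 3 * 50 / sqrt(length(sz)) + 5)
})

test_that("the insert-size test follows the closed-form normal tail", {
  # all sizes at mu: no shift, p = 0.5
  t0 <- insert_size_test(rep(400, 20), stats_f, "DEL")
  expect_equal(t0$size_point, 0)
  expect_equal(t0$p_value, 0.5)
  expect_lte(t0$ci_lo, 0); expect_gte(t0$ci_hi, 0)

  # n = 25 with mean mu + 1.645 * sigma / sqrt(25): p ~ 0.05
  m <- 400 + 1.645 * 50 / 5
  t1 <- insert_size_test(rep(m, 25), stats_f, "DEL")
  expect_equal(t1$p_value, 1 - pnorm(1.645), tolerance = 1e-6)

  # empty input: p-value 1, undefined-wide interval
  te <- insert_size_test(numeric(0), stats_f, "DEL")
  expect_equal(te$p_value, 1)
  expect_equal(c(te$ci_lo, te$ci_hi), c(-Inf, Inf))
  expect_equal(te$n_pairs, 0L)
})

test_that("the null p-value distribution is uniform and the CI covers", {
  set.seed(43)
  # type-I error at alpha = 0.05 over 1000 null replicates
  p <- replicate(1000, {
    insert_size_test(rnorm(25, 400, 50), stats_f, "DEL")$p_value
  })
  expect_lt(abs(mean(p <= 0.05) - 0.05), 0.02)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)

  # 95% CI coverage over 500 deletions with n >= 20 spanning pairs
  cover <- replicate(500, {
    truth <- runif(1, 100, 900)
    est <- insert_size_test(rnorm(30, 400 + truth, 50), stats_f, "DEL")
    est$ci_lo <= truth && truth <= est$ci_hi
  })
  expect_lt(abs(mean(cover) - 0.95), 0.03)
})

test_that("depth features read the coverage track with flank windows", {
  ref <- c(c1 = strrep("A", 20000))
  # uniform 30x: 30 overlapping 100-mers starting every ~3.33 bp
  a <- dplyr::bind_rows(lapply(seq(0, 19900, by = 10), function(p) {
    dplyr::bind_rows(lapply(1:3, function(j) {
      mk_aln(sprintf("r%d_%d", p, j), pos = p, cigar = "100M",
             seq = strrep("A", 100))
    }))
  }))
  cov <- coverage_track(a, ref)
  cnv <- tibble::tibble(chrom = "c1", start = 10000L, end = 10400L, svtype = "DEL")
  d <- depth_features(cnv, cov, stats_f)
  expect_equal(d$depth_event, 30, tolerance = 0.05)
  expect_equal(d$depth_left_flank, 30, tolerance = 0.05)
  expect_equal(d$depth_right_flank, 30, tolerance = 0.05)
  expect_false(d$flank_degraded)

  # event at the contig edge: flank degraded
  edge <- tibble::tibble(chrom = "c1", start = 50L, end = 500L, svtype = "DEL")
  expect_true(depth_features(edge, cov, stats_f)$flank_degraded)
})

test_that("simulated deletions and duplications shift depth as expected", {
  cfg <- sim_config(seed = 71, contig_length = 80000L, coverage = 30,
                    planted_cnvs = tibble::tibble(
                      chrom = "sim1", start = c(20000L, 50000L),
                      end = c(20600L, 50600L), svtype = c("DEL", "DUP"),
                      zygosity = c("HOM", "HET")))
  sim <- simulate_dataset(cfg)
  st <- library_stats(150L, cfg$mu, cfg$sigma)
  cov <- coverage_track(sim$alignments, sim$reference)
  d_del <- depth_features(sim$truth[1, ], cov, st)
  d_dup <- depth_features(sim$truth[2, ], cov, st)
  flanks_del <- mean(c(d_del$depth_left_flank, d_del$depth_right_flank))
  flanks_dup <- mean(c(d_dup$depth_left_flank, d_dup$depth_right_flank))
  expect_lt(d_del$depth_event, 0.15 * flanks_del)  # homozygous: ~0
  expect_equal(d_dup$depth_event / flanks_dup, 1.5, tolerance = 0.2)
})

test_that("hard filters apply the support, statistics and depth clauses in order", {
  base <- tibble::tibble(chrom = "c1", start = 1000L, end = 1500L,
                         svtype = "DEL", precise = TRUE, support_sr = 10L,
                         support_hsr = 0L, support_disc = 0L,
                         junction_score_ratio = 0.95, p_value = 0.5,
                         depth_event = 12, depth_left_flank = 30,
                         depth_right_flank = 30)
  expect_equal(hard_filter(base), "PASS")

  imprecise <- dplyr::mutate(base, precise = FALSE, support_sr = 0L,
                             support_disc = 3L, p_value = 0.3,
                             junction_score_ratio = NA_real_)
  expect_equal(hard_filter(imprecise), "p_value")

  weak <- dplyr::mutate(base, support_sr = 2L)
  expect_equal(hard_filter(weak), "support")

  # depth clause only for events >= 300 bp
  dup_bad_depth <- dplyr::mutate(base, svtype = "DUP", depth_event = 30,
                                 p_value = 0.001)
  expect_equal(hard_filter(dup_bad_depth), "depth")
  small <- dplyr::mutate(dup_bad_depth, end = 1200L)
  expect_equal(hard_filter(small), "PASS")

  # multiple failures are reported in order
  bad <- dplyr::mutate(base, support_sr = 1L, p_value = 0.9,
                       junction_score_ratio = 0.5, depth_event = 31,
                       svtype = "DUP")
  expect_equal(hard_filter(bad), "support;p_value;depth")
})

test_that("the random-forest filter separates, degenerates and falls back", {
  set.seed(51)
  n <- 200
  feats <- tibble::tibble(
    chrom = "c1", start = 1L, end = 100L, svtype = "DEL", precise = TRUE,
    support_sr = c(rpois(n / 2, 20), rpois(n / 2, 0)),
    support_hsr = 0L, support_disc = 0L, mean_mapq = 60,
    junction_score_ratio = c(runif(n / 2, 0.9, 1), runif(n / 2, 0.2, 0.6)),
    p_value = c(runif(n / 2, 0, 0.05), runif(n / 2, 0.2, 1)),
    n_pairs = 10L, depth_event = 15, depth_left_flank = 30,
    depth_right_flank = 30)
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  idx <- sample(n, 150)
  model <- rf_train(feats[idx, ], labels[idx], seed = 9)
  prob <- rf_apply(model, feats[-idx, ])
  acc <- mean((prob >= 0.5) == labels[-idx])
  expect_gte(acc, 0.95)

  # degenerate all-positive training labels: everything passes
  m1 <- suppressWarnings(rf_train(feats, rep(TRUE, n), seed = 9)) # one-class forest

  expect_true(all(rf_apply(m1, feats) >= 0.5))

  # mismatched labels error
  expect_error(rf_train(feats, labels[-1]), "mismatch")

  # no model: annotate_and_filter takes the hard-filter path
  ref <- c(c1 = strrep("A", 5000))
  cand <- tibble::tibble(chrom = "c1", start = 2000L, end = 2100L,
                         svtype = "DEL", precise = TRUE, source = "SPLIT",
                         support_sr = 10L, support_hsr = 0L, support_disc = 0L,
                         mean_mapq = 60, junction_score = 280L,
                         junction_score_ratio = 0.95)
  pairs <- classify_pairs(mk_pair("p", "c1", 100L, 400L), stats_f)
  cov <- coverage_track(mk_aln(pos = 0L, cigar = "100M", seq = strrep("A", 100)),
                        ref)
  out <- annotate_and_filter(cand, pairs, cov, stats_f, model = NULL)
  expect_equal(out$filter, "PASS") # precise with ratio >= 0.9
})

test_that("VCF writing and reading round-trip a random callset", {
  set.seed(52)
  ref <- c(c1 = random_seq(40000), c2 = random_seq(40000))
  n <- 50
  calls <- tibble::tibble(
    chrom = sample(c("c1", "c2"), n, replace = TRUE),
    start = sample(1000:30000, n),
    svtype = sample(c("DEL", "DUP"), n, replace = TRUE),
    precise = sample(c(TRUE, FALSE), n, replace = TRUE),
    source = NA_character_,
    support_sr = sample(0:30, n, replace = TRUE),
    support_hsr = sample(0:30, n, replace = TRUE),
    support_disc = sample(0:10, n, replace = TRUE),
    p_value = signif(runif(n), 6),
    depth_event = signif(runif(n, 0, 60), 6),
    depth_left_flank = signif(runif(n, 10, 40), 6),
    depth_right_flank = signif(runif(n, 10, 40), 6),
    filter = sample(c("PASS", "support", "p_value"), n, replace = TRUE))
  calls$end <- calls$start + sample(50:5000, n)
  calls$source <- ifelse(calls$precise, "SPLIT", "DISCORDANT")
  calls <- dplyr::arrange(calls, .data$chrom, .data$start, .data$end)
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, ref, path, stats_f)
  back <- read_vcf(path)
  for (col in c("chrom", "start", "end", "svtype", "precise", "source",
                "support_sr", "support_hsr", "support_disc", "p_value",
                "depth_event", "depth_left_flank", "depth_right_flank",
                "filter")) {
    expect_equal(back[[col]], calls[[col]], info = col)
  }
})

test_that("an empty callset writes a valid header-only VCF", {
  ref <- c(c1 = strrep("A", 1000))
  path <- tempfile(fileext = ".vcf")
  write_vcf(hiddensplit:::empty_callset(), ref, path)
  lines <- readLines(path)
  expect_true(all(grepl("^#", lines)))
  expect_equal(nrow(read_vcf(path)), 0L)
})
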