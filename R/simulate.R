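#' Simulation configuration
#'
#' Describes a fully self-contained synthetic dataset: a random reference with
#' embedded tandem repeats, planted CNVs, and paired-end reads with
#' Normal(mu, sigma) insert sizes and substitution errors. All outputs are
#' deterministic functions of the configuration (including `seed`).
#'
#' @param seed Integer seed.
#' @param contig_length Contig length in bp (default 1e6).
#' @param repeat_specs Tibble/data frame with columns `unit_length`, `copies`,
#'   `divergence` (one row per tandem-repeat array). `divergence` is the
#'   per-copy substitution rate relative to the array's unit consensus, so two
#'   copies differ at roughly `2 * divergence` of their positions.
#' @param planted_cnvs Either a truth tibble (`chrom`, `start`, `end`,
#'   `svtype`, `zygosity`) or a function `f(reference, repeats)` returning
#'   one (see [plan_unique_cnvs()] / [plan_repeat_cnvs()]), or `NULL`.
#' @param coverage Total fold coverage across both haplotypes (default 30).
#' @param read_len Read length (default 150).
#' @param mu,sigma Insert-size mean and standard deviation (default 400, 50).
#' @param subst_error Per-base substitution error rate (default 0.001).
#' @param clip_margin A clipped placement must beat the best full-length
#'   placement by more than this score margin to be emitted clipped
#'   (default 8, matching the caller's minimum HSR-score, so the emulated
#'   aligner and the caller agree on when a full mismatched alignment is
#'   preferred over clipping).
#' @param contig_name Contig name (default `"sim1"`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, contig_length = 1e6L,
                       repeat_specs = NULL, planted_cnvs = NULL,
                       coverage = 30, read_len = 150L, mu = 400, sigma = 50,
                       subst_error = 0.001, clip_margin = 8L,
                       contig_name = "sim1") {
  stopifnot(coverage > 0, mu > read_len, subst_error >= 0, subst_error <= 1)
  structure(list(seed = as.integer(seed) %% .Machine$integer.max,
                 contig_length = as.integer(contig_length),
                 repeat_specs = repeat_specs, planted_cnvs = planted_cnvs,
                 coverage = coverage, read_len = as.integer(read_len),
                 mu = mu, sigma = sigma, subst_error = subst_error,
                 clip_margin = clip_margin, contig_name = contig_name),
            class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate a random reference with embedded tandem repeats
#'
#' The contig is random sequence with the configured tandem-repeat arrays
#' placed at evenly spaced, jittered positions (at least ~3 kb apart so that
#' flank-based analyses never straddle two arrays). Each array is a random
#' unit repeated `copies` times, with every copy independently mutated at the
#' `divergence` rate.
#'
#' @param config A [sim_config()].
#' @return List with `reference` (named character vector) and `repeats`
#'   (repeat track tibble).
#' @export
make_reference <- function(config) {
  set.seed(config$seed)
  L <- config$contig_length
  contig <- random_dna(L)
  specs <- config$repeat_specs
  track <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), unit_length = integer())
  if (!is.null(specs) && nrow(specs) > 0) {
    k <- nrow(specs)
    arr_len <- specs$unit_length * specs$copies
    slot <- L / (k + 1)
    if (any(arr_len + 6000 > slot)) {
      rlang::abort("repeat arrays overflow the contig: increase contig_length")
    }
    pos <- as.integer(round(seq_len(k) * slot + runif(k, -slot / 8, slot / 8)))
    for (i in seq_len(k)) {
      unit <- random_dna(specs$unit_length[i])
      copies <- vapply(seq_len(specs$copies[i]), function(j) {
        mutate_seq(unit, specs$divergence[i])
      }, character(1))
      arr <- paste(copies, collapse = "")
      substr(contig, pos[i] + 1L, pos[i] + nchar(arr)) <- arr
      track <- dplyr::bind_rows(track, tibble::tibble(
        chrom = config$contig_name, start = pos[i],
        end = pos[i] + nchar(arr), unit_length = specs$unit_length[i]))
    }
  }
  list(reference = setNames(contig, config$contig_name), repeats = track)
}

#' Plan planted CNVs with unique junction sequences
#'
#' Samples non-overlapping deletion/duplication intervals in non-repetitive
#' sequence, at least `margin` bp from each other, from any repeat array and
#' from the contig edges. Sizes are drawn log-uniformly from `size_range`.
#'
#' @param reference,repeats Output of [make_reference()].
#' @param n_del,n_dup Number of deletions / tandem duplications.
#' @param size_range Event size range in bp (default c(60, 2000)).
#' @param zygosity `"HOM"` or `"HET"` (default `"HOM"`).
#' @param margin Minimum separation (default 4000 bp).
#' @param seed Integer seed.
#' @return A truth tibble (`chrom`, `start`, `end`, `svtype`, `zygosity`).
#' @export
plan_unique_cnvs <- function(reference, repeats, n_del = 30L, n_dup = 30L,
                             size_range = c(60L, 2000L), zygosity = "HOM",
                             margin = 4000L, seed = 1L) {
  set.seed(seed)
  ct <- names(reference)[1]
  L <- nchar(reference[[1]])
  taken <- repeats[, c("start", "end")]
  svtypes <- sample(c(rep("DEL", n_del), rep("DUP", n_dup)))
  out <- list()
  tries <- 0L
  while (length(out) < length(svtypes) && tries < 50000L) {
    tries <- tries + 1L
    size <- as.integer(round(exp(runif(1, log(size_range[1]), log(size_range[2])))))
    start <- as.integer(floor(runif(1, margin, L - margin - size)))
    end <- start + size
    if (nrow(taken) > 0 &&
        any(pmin(taken$end + margin, end) > pmax(taken$start - margin, start))) next
    taken <- dplyr::bind_rows(taken, tibble::tibble(start = start, end = end))
    out[[length(out) + 1L]] <- tibble::tibble(
      chrom = ct, start = start, end = end,
      svtype = svtypes[length(out) + 1L], zygosity = zygosity)
  }
  if (length(out) < length(svtypes)) {
    rlang::abort("could not place all requested events; enlarge the contig")
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start)
}

#' Plan full-unit CNVs on interior repeat copies
#'
#' For each tandem-repeat array, plants one full-unit event (alternating
#' deletion / duplication) on an interior copy, so that the junction's
#' homologous continuation inside the array exceeds a read length and the
#' event can only be recovered through hidden split reads.
#'
#' @inheritParams plan_unique_cnvs
#' @param copies_per_array Integer vector of copy counts per array (taken
#'   from the sim config's repeat specs).
#' @return A truth tibble.
#' @export
plan_repeat_cnvs <- function(reference, repeats, copies_per_array,
                             zygosity = "HOM", seed = 1L) {
  set.seed(seed)
  stopifnot(nrow(repeats) == length(copies_per_array))
  out <- purrr::map(seq_len(nrow(repeats)), function(i) {
    u <- repeats$unit_length[i]
    copies <- copies_per_array[i]
    if (copies < 4) rlang::abort("interior-copy events need >= 4 copies")
    k <- sample(2:(copies - 2), 1L) # interior copy index (1-based)
    start <- repeats$start[i] + (k - 1L) * u
    tibble::tibble(chrom = repeats$chrom[i], start = start, end = start + u,
                   svtype = if (i %% 2L == 1L) "DEL" else "DUP",
                   zygosity = zygosity)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$start)
}

#' Apply planted CNVs to the reference, producing donor haplotypes
#'
#' Heterozygous events are applied to haplotype 1 only, homozygous events to
#' both. Each haplotype carries a donor-to-reference block map (maximal
#' collinear segments) used for placing simulated reads.
#'
#' @param reference Named character vector (single contig).
#' @param truth Truth tibble (`start`, `end`, `svtype`, `zygosity`), sorted,
#'   non-overlapping.
#' @return List of two haplotypes, each `list(seq, blocks)` with `blocks`
#'   columns `donor_start`, `donor_end`, `ref_start`.
#' @export
plant_cnvs <- function(reference, truth) {
  contig <- reference[[1]]
  if (nrow(truth) > 1) {
    truth <- dplyr::arrange(truth, .data$start)
    if (any(truth$start[-1] < truth$end[-nrow(truth)])) {
      rlang::abort("planted events must not overlap")
    }
  }
  if (nrow(truth) > 0 && (min(truth$start) < 0 || max(truth$end) > nchar(contig))) {
    rlang::abort("planted events must lie within the contig")
  }
  apply_events <- function(events) {
    L <- nchar(contig)
    pieces <- character(0)
    blocks <- list()
    donor_pos <- 0L
    add <- function(ref_start, len) {
      if (len <= 0L) return(invisible())
      pieces[[length(pieces) + 1L]] <<- subseq0(contig, ref_start, ref_start + len)
      blocks[[length(blocks) + 1L]] <<- c(donor_pos, donor_pos + len, ref_start)
      donor_pos <<- donor_pos + len
    }
    cursor <- 0L
    if (nrow(events) > 0) {
      for (k in seq_len(nrow(events))) {
        ev <- events[k, ]
        add(cursor, ev$start - cursor)
        if (ev$svtype == "DEL") {
          cursor <- ev$end
        } else {
          add(ev$start, ev$end - ev$start) # first copy
          add(ev$start, ev$end - ev$start) # duplicated copy
          cursor <- ev$end
        }
      }
    }
    add(cursor, L - cursor)
    b <- do.call(rbind, blocks)
    bl <- tibble::tibble(donor_start = b[, 1], donor_end = b[, 2],
                         ref_start = b[, 3])
    # merge reference-collinear neighbours
    keep <- rep(TRUE, nrow(bl))
    for (k in seq_len(nrow(bl))[-1]) {
      prev <- max(which(keep[1:(k - 1)]))
      if (bl$ref_start[k] == bl$ref_start[prev] +
          (bl$donor_start[k] - bl$donor_start[prev])) {
        bl$donor_end[prev] <- bl$donor_end[k]
        keep[k] <- FALSE
      }
    }
    bl <- bl[keep, ]
    list(seq = paste(pieces, collapse = ""), blocks = bl)
  }
  list(apply_events(truth),
       apply_events(truth[truth$zygosity == "HOM", , drop = FALSE]))
}

# Emulated aligner for a read spanning donor block boundaries: choose between
# the best full-length ungapped placement at any donor-implied anchor and the
# best per-segment clipped placement (clipping wins only by > clip_margin).
place_read <- function(seq, segs, contig, scheme, clip_margin, reflen) {
  rl <- nchar(seq)
  best_full <- -Inf; best_full_pos <- NA_integer_
  best_clip <- -Inf; best_clip_seg <- NULL
  for (s in seq_len(nrow(segs))) {
    qs <- segs$qs[s]; qe <- segs$qe[s]; rp <- segs$rp[s]
    p <- rp - qs
    if (p >= 0 && p + rl <= reflen) {
      mm <- cpp_hamming(seq, substr(contig, p + 1L, p + rl))
      sc <- (rl - mm) * scheme$match + mm * scheme$mismatch
      if (sc > best_full) { best_full <- sc; best_full_pos <- p }
    }
    seglen <- qe - qs
    if (seglen > 0 && rp >= 0 && rp + seglen <= reflen) {
      mm <- cpp_hamming(substr(seq, qs + 1L, qe),
                        substr(contig, rp + 1L, rp + seglen))
      sc <- (seglen - mm) * scheme$match + mm * scheme$mismatch
      if (sc > best_clip) { best_clip <- sc; best_clip_seg <- c(qs, qe, rp) }
    }
  }
  if (is.finite(best_clip) && best_clip > best_full + clip_margin) {
    qs <- best_clip_seg[1]; qe <- best_clip_seg[2]; rp <- best_clip_seg[3]
    cig <- paste0(if (qs > 0) paste0(qs, "S"), qe - qs, "M",
                  if (rl - qe > 0) paste0(rl - qe, "S"))
    list(pos = rp, cigar = cig, span = qe - qs)
  } else if (is.finite(best_full)) {
    list(pos = best_full_pos, cigar = paste0(rl, "M"), span = rl)
  } else {
    NULL
  }
}

#' Simulate paired-end alignments from donor haplotypes
#'
#' Fragments are drawn uniformly along each haplotype with Normal(mu, sigma)
#' lengths until the target coverage is reached; substitution errors are
#' injected at the configured rate. Reads falling entirely within a collinear
#' donor block map directly to the reference; reads spanning a block boundary
#' (i.e. a CNV junction) go through the aligner emulation: the full-length
#' mismatched placement is preferred unless a clipped placement beats it by
#' more than `clip_margin` (mirroring how real aligners hide full-unit repeat
#' events, producing hidden split reads instead of clips).
#'
#' @param haplotypes Output of [plant_cnvs()].
#' @param reference Named character vector (the reference contig).
#' @param config A [sim_config()].
#' @return Alignment tibble (see [read_alignments()]), coordinate-sorted.
#' @export
simulate_alignments <- function(haplotypes, reference, config) {
  set.seed(config$seed + 1L)
  contig <- reference[[1]]
  ct <- names(reference)[1]
  reflen <- nchar(contig)
  rl <- config$read_len
  scheme <- alignment_scheme()
  hap_out <- list()
  for (h in seq_along(haplotypes)) {
    hap <- haplotypes[[h]]
    dlen <- nchar(hap$seq)
    nfrag <- ceiling(config$coverage / length(haplotypes) * dlen / (2 * rl))
    f <- pmax(rl, as.integer(round(rnorm(nfrag, config$mu, config$sigma))))
    s <- as.integer(floor(runif(nfrag, 0, dlen - f)))
    starts <- c(s, s + f - rl) # read1 fwd, read2 rev
    seqs <- substring(hap$seq, starts + 1L, starts + rl)
    nerr <- rbinom(length(seqs), rl, config$subst_error)
    for (k in which(nerr > 0)) seqs[k] <- mutate_seq2(seqs[k], nerr[k])
    bl <- hap$blocks
    ib <- findInterval(starts, bl$donor_start)
    jb <- findInterval(starts + rl - 1L, bl$donor_start)
    pos <- integer(length(starts)); cig <- character(length(starts))
    span <- integer(length(starts)); ok <- rep(TRUE, length(starts))
    simple <- ib == jb
    pos[simple] <- bl$ref_start[ib[simple]] +
      (starts[simple] - bl$donor_start[ib[simple]])
    cig[simple] <- paste0(rl, "M")
    span[simple] <- rl
    for (k in which(!simple)) {
      a <- starts[k]
      segs <- purrr::map(ib[k]:jb[k], function(bi) {
        qs <- max(a, bl$donor_start[bi]) - a
        qe <- min(a + rl, bl$donor_end[bi]) - a
        rp <- bl$ref_start[bi] + (max(a, bl$donor_start[bi]) - bl$donor_start[bi])
        tibble::tibble(qs = qs, qe = qe, rp = rp)
      }) |> dplyr::bind_rows()
      # merge reference-collinear consecutive segments
      keep <- rep(TRUE, nrow(segs))
      for (m in seq_len(nrow(segs))[-1]) {
        prev <- max(which(keep[1:(m - 1)]))
        if (segs$rp[m] == segs$rp[prev] + (segs$qs[m] - segs$qs[prev])) {
          segs$qe[prev] <- segs$qe[m]; keep[m] <- FALSE
        }
      }
      pl <- place_read(seqs[k], segs[keep, ], contig, scheme,
                       config$clip_margin, reflen)
      if (is.null(pl)) { ok[k] <- FALSE; next }
      pos[k] <- pl$pos; cig[k] <- pl$cigar; span[k] <- pl$span
    }
    n <- length(s)
    tb <- tibble::tibble(
      name = rep(sprintf("h%d_frag%07d", h, seq_len(n)), 2L),
      chrom = ct, pos = pos, mapq = 60L, cigar = cig, seq = seqs,
      is_reverse = rep(c(FALSE, TRUE), each = n),
      is_read1 = rep(c(TRUE, FALSE), each = n),
      span = span, ok = ok)
    tb <- tb[tb$ok, ]
    # pair bookkeeping: mate fields and TLEN from the mate's placement
    m1 <- tb[tb$is_read1, ]; m2 <- tb[!tb$is_read1, ]
    common <- intersect(m1$name, m2$name)
    m1 <- m1[match(common, m1$name), ]; m2 <- m2[match(common, m2$name), ]
    fill <- function(x, y) {
      lo <- pmin(x$pos, y$pos)
      hi <- pmax(x$pos + x$span, y$pos + y$span)
      tl <- ifelse(x$pos < y$pos | (x$pos == y$pos & x$is_read1),
                   hi - lo, -(hi - lo))
      dplyr::mutate(x, mate_chrom = y$chrom, mate_pos = y$pos,
                    mate_reverse = y$is_reverse, insert_size = as.integer(tl))
    }
    hap_out[[h]] <- dplyr::bind_rows(fill(m1, m2), fill(m2, m1)) |>
      dplyr::select(-"span", -"ok")
  }
  dplyr::bind_rows(hap_out) |> dplyr::arrange(.data$pos, .data$name)
}

# substitute exactly k random positions of a read
mutate_seq2 <- function(seq, k) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in sample.int(length(ch), k)) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Simulate a complete dataset
#'
#' Runs [make_reference()], resolves the planted-CNV plan, applies it with
#' [plant_cnvs()] and simulates reads with [simulate_alignments()].
#'
#' @param config A [sim_config()].
#' @return List: `reference`, `repeats`, `truth`, `haplotypes`, `alignments`,
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  mk <- make_reference(config)
  truth <- config$planted_cnvs
  if (is.function(truth)) truth <- truth(mk$reference, mk$repeats)
  if (is.null(truth)) {
    truth <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), svtype = character(),
                            zygosity = character())
  }
  haps <- plant_cnvs(mk$reference, truth)
  aln <- simulate_alignments(haps, mk$reference, config)
  list(reference = mk$reference, repeats = mk$repeats, truth = truth,
       haplotypes = haps, alignments = aln, config = config)
}
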