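test_that("exact scan finds all occurrences and honours the length floor", {
  lib <- motif_library(exact_sites = data.frame(factor = "eve", site = "TTCGAA"))
  tr <- patch_scan("GGTTCGAAGG", lib)
  expect_equal(tr$intervals$start, 2L)
  expect_equal(tr$intervals$end, 8L)

  short <- motif_library(exact_sites = data.frame(factor = "x", site = "ACGT"))
  expect_equal(nrow(patch_scan(paste(rep("ACGT", 10L), collapse = ""), short)$intervals),
               0L)                                 # below the 5 bp floor

  # overlapping occurrences are all reported
  lib2 <- motif_library(exact_sites = data.frame(factor = "p", site = "ATATA"))
  tr2 <- patch_scan("CATATATAC", lib2)
  expect_equal(tr2$intervals$start, c(1L, 3L))

  expect_equal(nrow(patch_scan("", lib)$intervals), 0L)
})

test_that("exact scan equals the brute-force substring oracle on random input", {
  set.seed(13)
  seq <- rand_seq(1000)
  tr <- patch_scan(seq, toy_lib)
  chars <- strsplit(seq, "")[[1L]]
  oracle <- list()
  for (k in seq_len(nrow(toy_lib$exact_sites))) {
    site <- toy_lib$exact_sites$site[k]
    w <- nchar(site)
    if (w < 5L) next
    for (s0 in 0:(1000 - w))
      if (substr(seq, s0 + 1L, s0 + w) == site)
        oracle[[length(oracle) + 1L]] <- c(s0, s0 + w)
  }
  om <- if (length(oracle)) do.call(rbind, oracle) else matrix(0L, 0L, 2L)
  om <- om[order(om[, 1L], om[, 2L]), , drop = FALSE]
  expect_equal(cbind(tr$intervals$start, tr$intervals$end), unname(om))

  # hit count never increases with min_len
  counts <- vapply(5:9, function(ml) nrow(patch_scan(seq, toy_lib, min_len = ml)$intervals), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("PWM scan: consensus scores 1, core mismatches veto, flank arithmetic", {
  p <- toy_lib$pwms[[1L]]                          # zld, width 6, core 0..4
  consensus <- paste(c("A", "G", "A", "T", "C", "A")[1:6], collapse = "")
  # consensus of counts: pos maxima A G A T C A(3)
  tr <- match_scan(consensus, toy_lib)
  hit <- tr$intervals[tr$intervals$factor == "zld", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$overall, 1)
  expect_equal(hit$core, 1)

  # mismatch at a core position kills the hit regardless of overall score
  core_mm <- "AGATGA"                              # pos 5 C -> G (core position)
  tr2 <- match_scan(core_mm, toy_lib)
  expect_equal(nrow(tr2$intervals[tr2$intervals$factor == "zld", ]), 0L)

  # single flank mismatch at the least informative position: score equals
  # the hand-computed information-weighted similarity
  flank_mm <- "AGATCC"                             # pos 6 A -> C (flank)
  tr3 <- match_scan(flank_mm, toy_lib, overall_cut = 0)
  hit3 <- tr3$intervals[tr3$intervals$factor == "zld", ]
  f <- p$counts / rep(colSums(p$counts), each = 4L)
  info <- apply(f, 2L, function(x) sum(ifelse(x > 0, x * log(4 * x), 0)))
  seq_idx <- c(1L, 3L, 1L, 4L, 2L, 2L)             # A G A T C C
  cur <- sum(info * f[cbind(seq_idx, 1:6)])
  mn <- sum(info * apply(f, 2L, min)); mx <- sum(info * apply(f, 2L, max))
  expect_equal(hit3$overall, (cur - mn) / (mx - mn), tolerance = 1e-12)

  degenerate <- motif_library(pwms = list(list(factor = "flat",
    counts = matrix(1, 4L, 6L), core_start = 0L)))
  expect_error(match_scan("ACGTACGTAC", degenerate), "matrix error")
})

test_that("PWM scan at overall_cut = 1 equals the exact scan of consensi", {
  # tie-free matrices: a unique maximum base at every position
  mk_pwm <- function(factor, cons) {
    counts <- matrix(1, 4L, nchar(cons), dimnames = list(c("A","C","G","T"), NULL))
    idx <- match(strsplit(cons, "")[[1L]], c("A", "C", "G", "T"))
    counts[cbind(idx, seq_along(idx))] <- 7
    list(factor = factor, counts = counts, core_start = 0L)
  }
  lib <- motif_library(pwms = list(mk_pwm("m1", "ACGTGA"), mk_pwm("m2", "TTGACC")))
  set.seed(19)
  seq <- rand_seq(600)
  strict <- match_scan(seq, lib, overall_cut = 1)
  exact <- patch_scan(seq, motif_library(exact_sites = data.frame(
    factor = c("m1", "m2"), site = c("ACGTGA", "TTGACC"))))
  expect_equal(strict$intervals[c("start", "end", "factor")],
               exact$intervals[c("start", "end", "factor")])
})

test_that("core-only track restriction and containment", {
  tr <- annotation_track(data.frame(start = 10L, end = 20L, factor = "f",
                                    strand = "+", overall = 0.9, core = 1,
                                    core_start = 12L, core_end = 17L),
                         "MATCH", 50L, "ungapped")
  core <- core_only_track(tr)
  expect_equal(core$intervals$start, 12L)
  expect_equal(core$intervals$end, 17L)
  expect_equal(core$method, "MATCH_CORE")

  empty <- annotation_track(NULL, "MATCH", 50L, "ungapped")
  expect_equal(nrow(core_only_track(empty)$intervals), 0L)

  set.seed(29)
  seq <- rand_seq(800)
  full <- match_scan(seq, toy_lib, overall_cut = 0.5)
  if (nrow(full$intervals)) {
    expect_true(all(track_mask(core_only_track(full)) <= track_mask(full)))
  }
})

test_that("phylogenetic footprint partition follows the window rule", {
  # outgroup identical to an ingroup row: everything well aligned
  set.seed(31)
  s <- rand_seq(60)
  pf2 <- phylo_footprint(haplotype_alignment(c(s, s), c("in1", "og"),
                                             c("a", "ps")), "og")
  expect_equal(pf2$fraction_well, 1)

  # constructed 12-column case: matches at columns 1-5, mismatches at 6-12
  og <- "AAAAAAAAAAAA"; ing <- "AAAAACCCCCCC"
  a3 <- haplotype_alignment(c(ing, og), c("in1", "og"), c("a", "ps"))
  pf3 <- phylo_footprint(a3, "og")
  expect_equal(which(pf3$well_mask) - 1L, 0:5)     # first 6-window has 5 matches
  expect_equal(pf3$fraction_well, 6 / 12)

  # alternating match/mismatch: no 6-window reaches 5 matches
  og4 <- paste(rep("A", 12L), collapse = "")
  in4 <- paste(rep(c("A", "C"), 6L), collapse = "")
  a4 <- haplotype_alignment(c(in4, og4), c("in1", "og"), c("a", "ps"))
  expect_equal(phylo_footprint(a4, "og")$fraction_well, 0)

  # exhaustive window-enumeration oracle on random data
  set.seed(37)
  for (rep in 1:5) {
    a5 <- rand_alignment(4, 80, p_mut = 0.3, species = c("a", "b", "c", "ps"))
    a5$mat[4L, sample(80, 10L)] <- "-"
    og_row <- rownames(a5$mat)[4L]
    pf5 <- phylo_footprint(a5, og_row)
    bc <- which(a5$mat[4L, ] %in% c("A", "C", "G", "T"))
    m <- vapply(bc, function(j) a5$mat[4L, j] %in% a5$mat[1:3, j], TRUE)
    well <- logical(length(bc))
    if (length(bc) >= 6L)
      for (st in 1:(length(bc) - 5L))
        if (sum(m[st:(st + 5L)]) >= 5L) well[st:(st + 5L)] <- TRUE
    expect_equal(which(pf5$well_mask), bc[well])
    expect_equal(pf5$fraction_well, mean(well))
    # raising min_matches never increases the well fraction
    expect_lte(phylo_footprint(a5, og_row, min_matches = 6L)$fraction_well,
               pf5$fraction_well)
  }

  gaps <- haplotype_alignment(c("ACGT", "----"), c("a", "og"), c("a", "ps"))
  expect_error(phylo_footprint(gaps, "og"), "undefined partition")
})

test_that("track combination is union at the mask level", {
  t1 <- annotation_track(data.frame(start = 0L, end = 5L, factor = "a"),
                         "PATCH", 30L, "alignment_columns")
  t2 <- annotation_track(data.frame(start = 10L, end = 15L, factor = "b"),
                         "MATCH", 30L, "alignment_columns")
  comb <- combine_tracks(t1, t2)
  expect_equal(nrow(comb$intervals), 2L)
  expect_equal(track_mask(comb), track_mask(t1) | track_mask(t2))
  expect_equal(track_mask(combine_tracks(t1, t1)), track_mask(t1))  # idempotent

  set.seed(41)
  for (rep in 1:5) {
    mk <- function() {
      st <- sort(sample(0:25, 3L))
      annotation_track(data.frame(start = st, end = st + sample(1:5, 3L, TRUE),
                                  factor = "x"), "PATCH", 30L, "alignment_columns")
    }
    a <- mk(); b <- mk()
    expect_equal(track_mask(combine_tracks(a, b)), track_mask(a) | track_mask(b))
    # combined coverage is at least each component's coverage
    expect_gte(mean(track_mask(combine_tracks(a, b))), mean(track_mask(a)))
  }

  t3 <- annotation_track(data.frame(start = 0L, end = 5L, factor = "a"),
                         "PATCH", 40L, "alignment_columns")
  expect_error(combine_tracks(t1, t3), "frame")
})
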