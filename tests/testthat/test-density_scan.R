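test_that("pileup counts forced examples correctly", {
  ref <- strrep("A", 100)
  mk <- function(pos, cigar, seq) data.frame(
    qname = "r", flag = 0L, rname = "c", pos = pos, mapq = 60L,
    cigar = cigar, seq = seq, stringsAsFactors = FALSE)
  # ten perfect reads: u = 0 everywhere
  aln <- do.call(rbind, lapply(1:10, function(i) mk(1L, "50M", strrep("A", 50))))
  pu <- build_pileup(aln, ref)
  expect_true(all(pu$u[1:50] == 0))
  expect_true(all(pu$d[1:50] == 10))
  # one read with a single mismatch at site 25 among ten covering reads
  aln2 <- aln
  aln2$seq[1] <- paste0(strrep("A", 24), "G", strrep("A", 25))
  pu2 <- build_pileup(aln2, ref)
  expect_equal(pu2$u[25], 1)
  expect_equal(pu2$d[25], 10)
  expect_true(all(pu2$u[-25] == 0))
  # deletion-spanned sites and insertion anchors count as unmatched
  pu3 <- build_pileup(mk(1L, "10M5D10M", strrep("A", 20)), ref)
  expect_true(all(pu3$u[11:15] == 1))
  expect_equal(pu3$d[15], 1)      # deletion span still covered
  pu4 <- build_pileup(mk(1L, "10M3I10M", strrep("A", 23)), ref)
  expect_equal(pu4$u[10], 1)
  expect_true(all(pu4$u[-10] == 0))
  # soft clip: one unmatched site adjacent to the clip, none under it
  pu5 <- build_pileup(mk(11L, "10S10M", strrep("A", 20)), ref)
  expect_equal(pu5$u[11], 1)
  expect_true(all(pu5$u[-11] == 0))
  expect_true(all(pu5$d[1:10] == 0))
})

test_that("pileup equals the brute-force CIGAR-walk oracle on noisy data", {
  sm <- cached("mini_noisy", make_sim(seed = 31, ref_length = 20000,
                                      n_delins = 1, depth = 10,
                                      read_len_mean = 3000, read_len_sd = 300,
                                      delins_len_range = c(500, 600)))
  pu <- build_pileup(sm$aln, sm$ref)
  orc <- oracle_pileup(sm$aln, sm$ref)
  expect_equal(pu$d, orc$d)
  expect_equal(pu$u, orc$u)
})

test_that("unmatched proportion handles zero depth", {
  expect_equal(unmatched_proportion(list(u = 0, d = 10)), 0)
  expect_equal(unmatched_proportion(list(u = 3, d = 20)), 0.15)
  expect_equal(unmatched_proportion(list(u = 0, d = 0)), 0)
})

test_that("weight vector is normalized, symmetric and peaked at the center", {
  for (wl in c(1, 5, 50, 137)) {
    w <- weight_vector(wl)
    expect_equal(sum(w$weights), 1, tolerance = 1e-12)
    expect_equal(w$weights, rev(w$weights))
    expect_equal(which.max(w$weights), wl + 1)
    expect_true(all(diff(w$weights[1:(wl + 1)]) >= 0))
  }
  expect_error(weight_vector(0), ">= 1")
})

test_that("raw weight sum approximates the normal mass on [-3, 3]", {
  w <- weight_vector(50, renormalize = FALSE)
  expect_equal(sum(w$weights), w$raw_sum)
  # trapezoid quadrature oracle of the standard normal density
  x <- seq(-3, 3, length.out = 6001)
  fx <- exp(-x^2 / 2) / sqrt(2 * pi)
  quad <- sum((fx[-1] + fx[-length(fx)]) / 2 * diff(x))
  expect_equal(w$raw_sum, quad, tolerance = 2e-3)
  expect_equal(round(quad, 4), 0.9973)
})

test_that("score track hits the exact 0 and 1 limits and matches the oracle", {
  w <- weight_vector(10)
  pu0 <- data.frame(pos = 1:200, d = 20, u = 0)
  expect_true(all(score_track(pu0, w)$scores == 0))
  pu1 <- data.frame(pos = 1:200, d = 20, u = 20)
  expect_equal(score_track(pu1, w)$scores, rep(1, 200), tolerance = 1e-12)
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(30:300, 1)
    pu <- data.frame(pos = 1:n, d = 30, u = sample(0:30, n, replace = TRUE))
    tr <- score_track(pu, w)
    expect_equal(tr$scores, oracle_score(pu$u / pu$d, w$weights),
                 tolerance = 1e-12)
    expect_true(all(tr$scores >= 0 & tr$scores <= 1))
  }
})

test_that("score is local and monotone in p", {
  w <- weight_vector(10)
  pu <- data.frame(pos = 1:100, d = 10, u = 2)
  base <- score_track(pu, w)$scores
  pu2 <- pu; pu2$u[50] <- 9
  bumped <- score_track(pu2, w)$scores
  expect_true(all(bumped >= base - 1e-12))          # monotonicity
  far <- abs(seq_len(100) - 50) > 10
  expect_equal(bumped[far], base[far])              # locality
  expect_true(all(bumped[!far] > base[!far]))
})

test_that("smoothing matches the moving-average oracle and its identities", {
  tr <- structure(list(contig = "c", start = 1L, scores = rep(0.4, 50),
                       smooth_scores = NULL, win = NULL),
                  class = "score_track")
  expect_equal(smooth_track(tr, 5)$smooth_scores, rep(0.4, 50))
  spike <- tr; spike$scores <- c(rep(0, 24), 1, rep(0, 25))
  expect_equal(smooth_track(spike, 5)$smooth_scores[25], 1 / 11)
  set.seed(202)
  for (rep in 1:5) {
    n <- sample(20:200, 1); win <- sample(0:15, 1)
    tr$scores <- runif(n)
    expect_equal(smooth_track(tr, win)$smooth_scores,
                 oracle_smooth(tr$scores, win), tolerance = 1e-12)
  }
})

test_that("candidate region calling matches a linear-scan oracle", {
  mk_track <- function(s) structure(
    list(contig = "c", start = 1L, scores = s, smooth_scores = s, win = 0L),
    class = "score_track")
  # all below threshold -> empty
  expect_equal(nrow(call_candidate_regions(mk_track(rep(0.1, 100)), 0.35)), 0)
  # one plateau -> exactly its bounds
  s <- rep(0.1, 100); s[40:60] <- 0.8
  rg <- call_candidate_regions(mk_track(s), 0.35, merge_gap = 1)
  expect_equal(nrow(rg), 1)
  expect_equal(c(rg$l, rg$r), c(40, 60))
  expect_equal(rg$peak_score, 0.8)
  # ties at exactly T break runs
  s2 <- rep(0.5, 10); s2[5] <- 0.35
  rg2 <- call_candidate_regions(mk_track(s2), 0.35, merge_gap = 1)
  expect_equal(nrow(rg2), 2)
  # random tracks against the oracle (no merging)
  set.seed(303)
  for (rep in 1:20) {
    s <- runif(sample(50:400, 1))
    rg <- call_candidate_regions(mk_track(s), 0.5, merge_gap = 1)
    orc <- oracle_regions(s, 0.5)
    expect_equal(nrow(rg), NROW(orc))
    if (NROW(orc)) {
      expect_equal(rg$l, orc[, 1])
      expect_equal(rg$r, orc[, 2])
    }
  }
  # merging: two plateaus separated by less than merge_gap fuse
  s3 <- rep(0.1, 300); s3[100:120] <- 0.8; s3[150:170] <- 0.8
  expect_equal(nrow(call_candidate_regions(mk_track(s3), 0.35, merge_gap = 50)), 1)
  expect_equal(nrow(call_candidate_regions(mk_track(s3), 0.35, merge_gap = 10)), 2)
  expect_error(call_candidate_regions(mk_track(s3), 1.5), "threshold")
})

test_that("a noise-free planted delins yields exactly one overlapping region", {
  sm <- fix_clean()
  pu <- build_pileup(sm$aln, sm$ref)
  tr <- smooth_track(score_track(pu, weight_vector(50)), 50)
  regs <- call_candidate_regions(tr, 0.35, 100)
  expect_equal(nrow(regs), nrow(sm$truth_sv))
  for (i in seq_len(nrow(sm$truth_sv)))
    expect_true(any(regs$l <= sm$truth_sv$end[i] &
                    regs$r >= sm$truth_sv$start[i]))
})

test_that("every planted delins is recovered at 15% error and depth 25", {
  sm <- fix_noisy()
  pu <- build_pileup(sm$aln, sm$ref)
  tr <- smooth_track(score_track(pu, weight_vector(50)), 50)
  regs <- call_candidate_regions(tr, 0.35, 100)
  for (i in seq_len(nrow(sm$truth_sv)))
    expect_true(any(regs$l <= sm$truth_sv$end[i] &
                    regs$r >= sm$truth_sv$start[i]))
})
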