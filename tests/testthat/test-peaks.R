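test_that("candidates_at groups adjacent confident bins, no gap merging", {
  pep <- list(chrT = c(0.01, 0.2, 0.01))
  strict <- candidates_at(pep, 0.05)
  expect_equal(nrow(strict$candidates), 2L)
  expect_equal(strict$candidates$start_bin, c(0L, 2L))
  loose <- candidates_at(pep, 0.3)  # merge on relaxation
  expect_equal(nrow(loose$candidates), 1L)
  expect_equal(loose$candidates$end_bin, 3L)
  none <- candidates_at(list(chrT = rep(1, 10)), 0.5)
  expect_equal(nrow(none$candidates), 0L)
})

test_that("scan_thresholds matches per-threshold recounting", {
  pep <- random_pep_track(300, seed = 2)
  scan <- scan_thresholds(pep, grid_size = 40)
  expect_length(scan$thresholds, 40L)
  expect_true(all(diff(scan$thresholds) > 0))
  expect_equal(scan$thresholds[1], 1e-10, tolerance = 1e-15)
  expect_equal(scan$thresholds[40], 0.5, tolerance = 1e-12)
  for (i in c(1, 15, 30, 40)) {
    cs <- candidates_at(pep, scan$thresholds[i])
    expect_equal(scan$counts[i], nrow(cs$candidates))
    if (nrow(cs$candidates) > 0)
      expect_equal(scan$mean_lengths[i],
                   mean(cs$candidates$end_bin - cs$candidates$start_bin))
  }
})

test_that("bimodal PEPs plateau between the two modes", {
  pep <- list(chrT = rep(c(1e-6, 0.9), 100))
  scan <- scan_thresholds(pep)
  on_plateau <- scan$thresholds > 1e-5 & scan$thresholds < 0.5
  expect_true(all(scan$counts[on_plateau] == 100L))
  expect_true(all(scan$counts[scan$thresholds < 1e-7] == 0L))
})

test_that("select_threshold lands on the plateau before the blow-up", {
  # step-function scan: rise to a 100-candidate plateau, then noise blow-up
  counts <- c(0, 0, rep(100, 35), 5000, 5200, 5300)
  mlen <- c(0, 0, rep(5, 35), 1.2, 1.1, 1.1)  # noise candidates are short
  scan <- structure(list(thresholds = exp(seq(log(1e-10), log(0.5),
                                              length.out = 40)),
                         counts = counts, mean_lengths = mlen),
                    class = "ThresholdScan")
  sel <- select_threshold(scan)
  expect_equal(counts[sel$index], 100)
  expect_lt(sel$index, 38)          # strictly before the blow-up
  expect_equal(sel$pivotal[1], 3)
  expect_equal(sel$pivotal[2], 37)
})

test_that("strictly linear counts fall back to the pivotal midpoint", {
  scan <- structure(list(thresholds = exp(seq(log(1e-10), log(0.5),
                                              length.out = 40)),
                         counts = 1:40 * 10,
                         mean_lengths = rep(4, 40)),
                    class = "ThresholdScan")
  sel <- select_threshold(scan)
  expect_equal(sel$index, floor((1 + 40) / 2))
  expect_error(select_threshold(structure(
    list(thresholds = scan$thresholds, counts = rep(0L, 40),
         mean_lengths = rep(0, 40)), class = "ThresholdScan")),
    "no enrichment")
})

test_that("block scoring matches direct Poisson tail sums", {
  m <- toy_hmm()
  m$constraints <- constraints()
  # single-bin candidate, observed 10, lambda 2
  track <- binned_track(list(chrT = c(0, 10, 0)), 200, 10)
  ctl <- binned_track(list(chrT = c(2, 2, 2)), 200, 10)
  cands <- structure(list(threshold = 0.05, candidates = data.frame(
    chrom = "chrT", start_bin = 1L, end_bin = 2L)), class = "CandidateSet")
  pep <- list(chrT = c(1, 0.01, 1))
  sc <- score_candidates(cands, track, m, pep, control = ctl)
  oracle <- log10(1 - sum(dpois(0:9, 2)))  # direct tail sum P(X >= 10)
  expect_equal(sc$log10_p, oracle, tolerance = 1e-9)

  # controlless: lambda from the noise state mean over the block
  sc2 <- score_candidates(cands, track, m, pep)
  oracle2 <- ppois(9, m$noise$mean, lower.tail = FALSE, log.p = TRUE) /
    log(10)
  expect_equal(sc2$log10_p, oracle2, tolerance = 1e-9)
})

test_that("tied PEPs keep the leftmost bins and score symmetrically", {
  m <- toy_hmm()
  m$constraints <- constraints()
  track <- binned_track(list(chrT = rep(8, 4)), 200, 32)
  cands <- structure(list(threshold = 0.05, candidates = data.frame(
    chrom = "chrT", start_bin = 0L, end_bin = 4L)), class = "CandidateSet")
  pep <- list(chrT = rep(0.01, 4))
  sc <- score_candidates(cands, track, m, pep)
  # top ceil(4/2) = 2 bins, ties -> leftmost: bins 1-2 form one block;
  # equal counts make the score equal a single-block score
  lambda <- m$noise$mean * 2
  oracle <- ppois(15, lambda, lower.tail = FALSE, log.p = TRUE) / log(10)
  expect_equal(sc$log10_p, oracle, tolerance = 1e-9)
})

test_that("unenriched candidates score near p = 1", {
  m <- toy_hmm()
  m$constraints <- constraints()
  track <- binned_track(list(chrT = c(1, 1)), 200, 2)
  ctl <- binned_track(list(chrT = c(10, 10)), 200, 20)
  cands <- structure(list(threshold = 0.5, candidates = data.frame(
    chrom = "chrT", start_bin = 0L, end_bin = 2L)), class = "CandidateSet")
  sc <- score_candidates(cands, track, m, list(chrT = c(0.4, 0.3)),
                         control = ctl)
  expect_gte(10^sc$log10_p, 0.5)
})

test_that("p-value adjustment closed forms", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bh"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(rep(0.01, 1), "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(c(0.01, 0.5), "bonferroni"), c(0.02, 1))
  p <- c(0.04)
  expect_equal(adjust_pvalues(p, "bh"), p)
  expect_equal(adjust_pvalues(p, "bonferroni"), p)
  set.seed(9)
  pr <- runif(50)
  expect_true(all(adjust_pvalues(pr, "bh") >= pr))
  expect_true(all(adjust_pvalues(pr, "bonferroni") >= pr))
})

test_that("boundary refinement clips weak edges within the budget", {
  counts <- c(0, 5, 9, 5, 0)
  expect_equal(refine_boundaries(1:5, counts), 2:4)
  flat <- rep(4, 6)
  expect_equal(refine_boundaries(1:6, flat), 1:6)
  skew <- c(1, 1, 1, 1, 100)
  expect_equal(refine_boundaries(1:5, skew), 2:5)  # cap: floor(0.25*5) = 1
  # properties: never outward, never more than max_clip per side, never empty
  set.seed(17)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    v <- rpois(n, 5)
    bins <- seq_len(n) + 100L
    out <- refine_boundaries(bins, c(rep(0, 100), v))
    expect_true(length(out) >= 1)
    expect_true(all(out %in% bins))
    expect_lte(out[1] - bins[1], floor(0.25 * n))
    expect_lte(bins[n] - out[length(out)], floor(0.25 * n))
  }
})

test_that("summit detection finds separated maxima deterministically", {
  s1 <- find_summits(11:15, c(rep(0, 10), 1, 3, 8, 3, 1))
  expect_equal(s1, 13L)
  two <- c(1, 8, 1, 1, 1, 1, 1, 1, 1, 1, 1, 8, 1)
  s2 <- find_summits(1:13, two, min_separation = 5)
  expect_equal(s2, c(2L, 12L))
  close2 <- c(1, 8, 1, 8, 1)
  s3 <- find_summits(1:5, close2, min_separation = 5)
  expect_length(s3, 1L)
  # oracle: enumerate moving-average maxima, then greedy thinning
  set.seed(23)
  v <- rpois(40, 6)
  bins <- 1:40
  vp <- c(0, v, 0)
  ma <- vapply(bins, function(i) sum(vp[i:(i + 2)]) / 3, numeric(1))
  cand <- which(vapply(bins, function(i) {
    l <- if (i > 1) ma[i - 1] else -Inf
    r <- if (i < 40) ma[i + 1] else -Inf
    ma[i] >= l && ma[i] >= r
  }, logical(1)) & ma >= 0.5 * max(ma))
  ord <- cand[order(-ma[cand], -v[cand], cand)]
  kept <- integer()
  for (i in ord) if (all(abs(i - kept) >= 5)) kept <- c(kept, i)
  expect_equal(find_summits(bins, v), sort(kept))
})

test_that("candidate sets nest or merge under threshold relaxation", {
  pep <- random_pep_track(400, seed = 31)
  scan_ths <- c(1e-4, 1e-2, 0.1, 0.4)
  sets <- lapply(scan_ths, function(t) candidates_at(pep, t)$candidates)
  for (k in seq_len(length(sets) - 1)) {
    strict <- sets[[k]]
    loose <- sets[[k + 1]]
    if (nrow(strict) == 0) next
    for (i in seq_len(nrow(strict))) {
      container <- loose$start_bin <= strict$start_bin[i] &
        loose$end_bin >= strict$end_bin[i]
      expect_equal(sum(container), 1L)
    }
  }
})

test_that("full pipeline recovers truth peaks on a quality-1.0 simulation", {
  exp1 <- small_experiment(quality = 1.0, seed = 1, n_peaks = 50,
                           n_reads = 1e6, genome = 1e7)
  model <- fit_constrained(exp1$track)
  fb <- forward_backward(exp1$track, model)
  peaks <- call_peaks(fb, exp1$track, model, exp1$layout)
  expect_gte(jaccard_intervals(peaks, exp1$truth), 0.7)
  expect_lte(abs(nrow(peaks) - 50), 5)
  # fdr = 1.0 emits every scored candidate surviving thresholding
  all_peaks <- call_peaks(fb, exp1$track, model, exp1$layout, fdr = 1.0)
  sel <- select_threshold(scan_thresholds(fb, bin_size = 200))
  n_cand <- nrow(candidates_at(fb, sel$threshold)$candidates)
  expect_equal(nrow(all_peaks), n_cand)
  # peak count is non-increasing in stricter fdr; q >= p per record
  stricter <- call_peaks(fb, exp1$track, model, exp1$layout, fdr = 1e-4)
  expect_lte(nrow(stricter), nrow(all_peaks))
  expect_true(all(peaks$neg_log10_q <= peaks$neg_log10_p + 1e-9))
  expect_true(all(peaks$score == pmin(1000, round(10 * peaks$neg_log10_q))))
})

test_that("pure background yields no peaks", {
  set.seed(41)
  spec <- simulation_spec(layout = genome_layout("chrS", 2e6), n_peaks = 0,
                          n_reads = 5e4, quality = 0.5, seed = 41)
  tags <- generate_reads(sample_ground_truth(spec), spec)
  layout <- set_bin_size(spec$layout, 200)
  track <- shift_and_bin(tags, fixed_fragment(150), layout)
  model <- fit_constrained(track)
  fb <- forward_backward(track, model)
  res <- tryCatch(call_peaks(fb, track, model, layout),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "no enrichment")
  } else {
    expect_lte(nrow(res), 5)
  }
})

test_that("mixed simulations yield both narrow and broad called peaks", {
  exp1 <- small_experiment(quality = 1.0, seed = 1, n_peaks = 500,
                           n_reads = 1e6, genome = 1e7,
                           peak_length_model = "mixed")
  model <- fit_constrained(exp1$track)
  fb <- forward_backward(exp1$track, model)
  peaks <- call_peaks(fb, exp1$track, model, exp1$layout)
  len_bins <- (peaks$end - peaks$start) / 200
  expect_gte(sum(len_bins < 5), 1)
  expect_gte(sum(len_bins > 100), 1)
})

test_that("jaccard_intervals handles merging and disjoint sets", {
  a <- data.frame(chrom = "c", start = c(0, 50), end = c(60, 100))
  b <- data.frame(chrom = "c", start = 0, end = 100)
  expect_equal(jaccard_intervals(a, b), 1)  # a merges to [0,100)
  d <- data.frame(chrom = "c", start = 200, end = 300)
  expect_equal(jaccard_intervals(a, d), 0)
  expect_equal(jaccard_intervals(a[0, ], d[0, ]), 0)
})
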