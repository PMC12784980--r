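test_that("emission model: zero point mass and NB closed forms", {
  m <- toy_hmm()
  expect_equal(emission_logprob("zero", 0, m), 0)
  expect_equal(emission_logprob("zero", 3, m), -Inf)
  # noise NB(mean 2, r 1) is geometric with success prob 1/3
  ks <- 0:8
  expect_equal(emission_logprob("noise", ks, m),
               log((1 / 3) * (2 / 3)^ks), tolerance = 1e-12)
  expect_error(emission_logprob("noise", -1, m), "non-negative")
})

test_that("initialization recovers two-population moments within 25%", {
  set.seed(7)
  x <- c(rpois(9000, 2), rpois(1000, 30))  # 90% noise / 10% signal
  tr <- binned_track(list(chrT = as.numeric(x)), 200, sum(x))
  m0 <- initialize_model(tr)
  expect_lte(abs(m0$noise$mean - 2) / 2, 0.25)
  expect_lte(abs(m0$signal$mean - 30) / 30, 0.25)
  expect_equal(sum(m0$initial), 1, tolerance = 1e-9)
  expect_equal(rowSums(m0$transitions), rep(1, 3), tolerance = 1e-9)
})

test_that("initialization guards: under-dispersion, rare counts, all-zero", {
  # v <= m in a class -> Poisson-like r = 1e6, no error
  tr <- binned_track(list(chrT = c(rep(0, 50), rep(3, 300), rep(50, 20))),
                     200, 1900)
  m0 <- initialize_model(tr)
  expect_equal(m0$noise$failures, 1e6)
  # rare low counts: projection enforces the SNR bound at init
  cs <- constraints(snr_min = 3)
  tr2 <- binned_track(list(chrT = c(rep(0, 990), rep(1, 10))), 200, 10)
  m2 <- initialize_model(tr2, cs)
  expect_gte(m2$signal$mean / m2$noise$mean, 3 - 1e-9)
  expect_error(initialize_model(binned_track(list(chrT = rep(0, 10)),
                                             200, 0)),
               "empty signal")
})

test_that("forward-backward equals exhaustive path enumeration", {
  m <- toy_hmm()
  set.seed(13)
  for (n in c(3L, 5L, 8L)) {
    counts <- as.numeric(rnbinom(n, size = 2, mu = 4))
    fb <- forward_backward(binned_track(list(chrT = counts), 200,
                                        sum(counts)), m)
    oracle <- enum_posterior(counts, m)
    expect_lt(max(abs(fb$posterior$chrT - oracle$posterior)), 1e-10)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
    expect_equal(rowSums(fb$posterior$chrT), rep(1, n), tolerance = 1e-9)
    # PEP equals 1 - brute-force posterior(signal)
    expect_lt(max(abs(fb$pep$chrT - (1 - oracle$posterior[, 3]))), 1e-10)
  }
})

test_that("all-zero track decodes to the zero state", {
  m <- toy_hmm()
  fb <- forward_backward(binned_track(list(chrT = rep(0, 50)), 200, 0), m)
  expect_true(all(fb$posterior$chrT[, 1] > 0.6))
  expect_true(all(fb$pep$chrT > 0.99))
})

test_that("compute_pep is posterior(zero) + posterior(noise)", {
  m <- toy_hmm()
  counts <- c(0, 4, 12)
  fb <- forward_backward(binned_track(list(chrT = counts), 200, 16), m)
  fb2 <- compute_pep(fb)
  expect_equal(fb2$pep$chrT,
               fb$posterior$chrT[, 1] + fb$posterior$chrT[, 2])
  expect_equal(fb2$pep$chrT, 1 - fb$posterior$chrT[, 3], tolerance = 1e-12)
})

test_that("constrained fit recovers generating parameters on 50k bins", {
  sim <- simulate_hmm_track(recovery_hmm(), 50000, seed = 1)
  fit <- fit_constrained(sim$track)
  expect_lt(abs(fit$noise$mean - 2) / 2, 0.1)
  expect_lt(abs(fit$signal$mean - 40) / 40, 0.1)
  expect_lte(attr(fit, "iterations"), 20)
  expect_lte(length(fit$log_likelihood_trace), 20)
})

test_that("SNR projection forces the bound when data violate it", {
  # generating SNR 1.5 with snr_min 3: fitted ratio must be exactly >= 3
  sim <- simulate_hmm_track(recovery_hmm(noise_mean = 10, signal_mean = 15),
                            20000, seed = 2)
  cs <- constraints(snr_min = 3)
  fit <- fit_constrained(sim$track, cs)
  expect_gte(fit$signal$mean / fit$noise$mean, 3 - 1e-9)
  expect_gte(fit$noise$mean, cs$noise_min)
})

test_that("EM likelihood trace is non-decreasing on well-separated data", {
  sim <- simulate_hmm_track(recovery_hmm(), 20000, seed = 3)
  fit <- fit_constrained(sim$track)
  tr <- fit$log_likelihood_trace
  expect_true(all(diff(tr) >= -1e-6 * abs(tr[-length(tr)])))
})

test_that("parameter recovery: median relative error < 10% over 20 seeds", {
  errs <- t(vapply(1:20, function(s) {
    sim <- simulate_hmm_track(recovery_hmm(), 5000, seed = s)
    fit <- fit_constrained(sim$track)
    c(noise = abs(fit$noise$mean - 2) / 2,
      signal = abs(fit$signal$mean - 40) / 40)
  }, numeric(2)))
  expect_lt(median(errs[, "noise"]), 0.1)
  expect_lt(median(errs[, "signal"]), 0.1)
})

test_that("fits satisfy constraints and agree with near-unconstrained EM", {
  sim <- simulate_hmm_track(recovery_hmm(), 20000, seed = 4)
  fit_def <- fit_constrained(sim$track)
  loose <- constraints(snr_min = 1 + 1e-9, noise_min = 1e-9)
  fit_loose <- fit_constrained(sim$track, loose)
  # on well-separated data the constraints must not bind: < 1% difference
  expect_lt(abs(fit_def$noise$mean - fit_loose$noise$mean) /
              fit_loose$noise$mean, 0.01)
  expect_lt(abs(fit_def$signal$mean - fit_loose$signal$mean) /
              fit_loose$signal$mean, 0.01)
  cs <- fit_def$constraints
  expect_gte(fit_def$signal$mean / fit_def$noise$mean, cs$snr_min - 1e-9)
  expect_gte(fit_def$noise$mean, cs$noise_min - 1e-12)
})

test_that("model persistence round-trips PEPs bit-identically", {
  sim <- simulate_hmm_track(recovery_hmm(), 5000, seed = 5)
  fit <- fit_constrained(sim$track)
  f <- withr::local_tempfile()
  write_model(fit, f)
  back <- read_model(f)
  expect_identical(back$initial, fit$initial)
  expect_identical(back$transitions, fit$transitions)
  pep1 <- forward_backward(sim$track, fit)$pep$chrS
  pep2 <- forward_backward(sim$track, back)$pep$chrS
  expect_identical(pep1, pep2)
})

test_that("chromosomes are independent sequences sharing one model", {
  m <- toy_hmm()
  c1 <- c(0, 5, 9)
  c2 <- c(2, 0, 0, 7)
  fb_joint <- forward_backward(binned_track(list(a = c1, b = c2), 200, 23), m)
  fb_a <- forward_backward(binned_track(list(a = c1), 200, 14), m)
  fb_b <- forward_backward(binned_track(list(b = c2), 200, 9), m)
  expect_equal(fb_joint$posterior$a, fb_a$posterior$a)
  expect_equal(fb_joint$posterior$b, fb_b$posterior$b)
  expect_equal(fb_joint$loglik, fb_a$loglik + fb_b$loglik)
})
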