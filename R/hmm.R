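#' Negative-binomial emission parameters
#'
#' The noise and signal states emit counts from a negative binomial
#' parameterized by its mean and the number of failures `r` (dispersion), so
#' that `variance = mean + mean^2 / r`. Large `r` (up to `1e6`) approaches a
#' Poisson.
#'
#' @param mean expected count per bin (> 0).
#' @param failures dispersion parameter `r` (> 0).
#' @export
nb_params <- function(mean, failures) {
  stopifnot(mean > 0, failures > 0)
  structure(list(mean = as.numeric(mean), failures = as.numeric(failures)),
            class = "NegBinParams")
}

#' Fitting constraints for the three-state model
#'
#' The constrained Baum-Welch projects the model back into the feasible
#' region after every iteration: the noise mean is kept at or above
#' `noise_min` (guards against calling the whole genome a peak) and the
#' signal-to-noise ratio `signal$mean / noise$mean` at or above `snr_min`
#' (keeps the signal state meaningfully enriched; mostly matters for narrow
#' marks). Defaults were chosen on synthetic tracks and are fully
#' configurable.
#'
#' @param snr_min minimal signal-to-noise ratio (> 1).
#' @param noise_min minimal noise mean, counts per bin (> 0).
#' @param noise_max maximal noise mean, counts per bin; the data-dependent
#'   upper boundary of the noise level. `NA` (the default) means "compute
#'   from the track": the genome-wide average count per bin, which the true
#'   background level can never exceed because peaks only add reads on top
#'   of it. Keeps the noise state from climbing into the peaks on
#'   low-background tracks.
#' @param max_iterations EM iteration cap.
#' @param tolerance relative log-likelihood change below which EM stops.
#' @export
constraints <- function(snr_min = 2, noise_min = 0.01, noise_max = NA,
                        max_iterations = 20, tolerance = 1e-3) {
  stopifnot(snr_min > 1, noise_min > 0, max_iterations >= 1, tolerance > 0,
            is.na(noise_max) || noise_max >= noise_min)
  structure(list(snr_min = snr_min, noise_min = noise_min,
                 noise_max = as.numeric(noise_max),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance),
            class = "Constraints")
}

#' Three-state hidden Markov model (zero / noise / signal)
#'
#' State 1 ("zero") is a point mass at count 0; states 2 ("noise") and
#' 3 ("signal") are negative binomials. One global model is shared by all
#' chromosomes, each treated as an independent observation sequence.
#'
#' @param initial probability 3-vector (zero, noise, signal).
#' @param transitions 3x3 row-stochastic matrix.
#' @param noise,signal [nb_params()] for the two emitting states.
#' @param constraints a [constraints()] object.
#' @param trace numeric vector of per-iteration log-likelihoods.
#' @export
hmm_model <- function(initial, transitions, noise, signal,
                      constraints = hmmpeaks::constraints(),
                      trace = numeric()) {
  initial <- as.numeric(initial)
  transitions <- as.matrix(transitions)
  stopifnot(length(initial) == 3, all(dim(transitions) == c(3, 3)))
  if (abs(sum(initial) - 1) > 1e-9) stop("initial must sum to 1")
  if (any(abs(rowSums(transitions) - 1) > 1e-9))
    stop("transition rows must sum to 1")
  structure(list(initial = initial, transitions = transitions,
                 noise = noise, signal = signal,
                 constraints = constraints,
                 log_likelihood_trace = trace),
            class = "HmmModel")
}

#' @export
print.HmmModel <- function(x, ...) {
  cat(sprintf(paste0(
    "HmmModel: noise NB(mean %.4g, r %.4g), signal NB(mean %.4g, r %.4g)\n",
    "  SNR %.3g, initial (%.3g, %.3g, %.3g), %d EM iteration(s)\n"),
    x$noise$mean, x$noise$failures, x$signal$mean, x$signal$failures,
    x$signal$mean / x$noise$mean, x$initial[1], x$initial[2], x$initial[3],
    length(x$log_likelihood_trace)))
  invisible(x)
}

#' Log emission probability of a count under one state
#'
#' The zero state emits only count 0 (log-probability 0 there, `-Inf`
#' elsewhere); noise and signal use the negative-binomial pmf with the
#' state's (mean, failures).
#'
#' @param state `"zero"`, `"noise"` or `"signal"`.
#' @param count non-negative integer count(s); vectorized.
#' @param model an [hmm_model()].
#' @return numeric vector of log probabilities.
#' @export
emission_logprob <- function(state, count, model) {
  state <- match.arg(state, c("zero", "noise", "signal"))
  if (any(count < 0)) stop("counts must be non-negative")
  if (state == "zero") return(ifelse(count == 0, 0, -Inf))
  p <- if (state == "noise") model$noise else model$signal
  stats::dnbinom(count, size = p$failures, mu = p$mean, log = TRUE)
}

# n x 3 log emission matrix for a count vector
emission_matrix <- function(counts, model) {
  cbind(ifelse(counts == 0, 0, -Inf),
        stats::dnbinom(counts, size = model$noise$failures,
                       mu = model$noise$mean, log = TRUE),
        stats::dnbinom(counts, size = model$signal$failures,
                       mu = model$signal$mean, log = TRUE))
}

# method-of-moments NB fit from (weighted) mean and variance
moments_to_nb <- function(m, v, r_max = 1e6) {
  if (m <= 0) m <- 1e-6
  r <- if (is.finite(v) && v > m) m^2 / (v - m) else r_max
  nb_params(m, min(max(r, 1e-3), r_max))
}

# weighted profile-likelihood estimate of the NB dispersion r for a fixed
# mean; x are unique count values with total posterior weights w
nb_mle_r <- function(x, w, m, r_min = 1e-3, r_max = 1e6) {
  obj <- function(lr) -sum(w * stats::dnbinom(x, size = exp(lr), mu = m,
                                              log = TRUE))
  opt <- stats::optimize(obj, interval = log(c(r_min, r_max)), tol = 1e-6)
  # a Poisson-like fit may be flat near r_max; prefer the boundary if equal
  if (obj(log(r_max)) <= opt$objective + 1e-9) return(r_max)
  exp(opt$minimum)
}

# Otsu threshold on log1p of the nonzero counts: the split value
# maximizing the between-class variance, computed in O(unique values) from
# the count histogram. Splits a bimodal noise/signal mixture at the valley
# instead of at a fixed percentile, so the signal population does not leak
# into the noise moments.
otsu_split <- function(nz) {
  v <- sort(unique(nz))
  if (length(v) < 2L) return(v[1])
  w <- as.numeric(table(factor(nz, levels = v)))
  l <- log1p(v)
  cw <- cumsum(w)
  cs <- cumsum(w * l)
  n <- cw[length(cw)]
  tot <- cs[length(cs)]
  k <- seq_len(length(v) - 1L)
  w0 <- cw[k] / n
  m0 <- cs[k] / cw[k]
  m1 <- (tot - cs[k]) / (n - cw[k])
  bv <- w0 * (1 - w0) * (m1 - m0)^2
  v[which.max(bv)]
}

#' Initialize the three-state model by the method of moments
#'
#' Nonzero counts are split into a low (noise) and a high (signal) class at
#' the between-class-variance maximizing threshold in log-count space
#' (Otsu's rule); each class seeds its state by matching mean and variance
#' (`r = m^2 / (v - m)`, or `1e6` when the class is under-dispersed).
#' Transitions start diagonally dominant (0.98 self); the initial
#' distribution is the observed occupancy of the three count classes.
#' Constraints are projected once before EM. Deterministic: no randomness
#' is involved.
#'
#' @param track a [binned_track()].
#' @param constraints a [constraints()] object.
#' @return an [hmm_model()].
#' @export
initialize_model <- function(track, constraints = hmmpeaks::constraints()) {
  counts <- flatten_counts(track)
  nz <- counts[counts > 0]
  if (length(nz) == 0L) stop("empty signal: all bin counts are zero")
  q95 <- otsu_split(nz)
  lower <- nz[nz <= q95]
  upper <- nz[nz > q95]
  noise <- moments_to_nb(mean(lower), stats::var(lower))
  # Empty-background guard: when the observed zero fraction is far above
  # what the moment-based noise state could produce, the genome background
  # is essentially empty (e.g. a maximal-quality synthetic track) and the
  # low nonzero bins are peak shoulders, not noise. Anchoring the noise
  # state near zero keeps it on the background; EM can always raise it.
  p0_obs <- mean(counts == 0)
  p0_pred <- stats::dnbinom(0, size = noise$failures, mu = noise$mean)
  empty_background <- p0_obs > 10 * max(p0_pred, 0.01)
  if (empty_background)
    noise <- nb_params(max(constraints$noise_min, min(1, mean(counts))), 1)
  signal <- if (empty_background) {
    # the top-5% moments are truncation-biased and too narrow here; a
    # geometric-tailed init covers the whole enriched count range so the
    # signal state, not the noise state, captures the peaks
    nb_params(if (length(upper) > 0) mean(upper)
              else max(q95, noise$mean * constraints$snr_min), 1)
  } else if (length(upper) >= 2) {
    moments_to_nb(mean(upper), stats::var(upper))
  } else {
    nb_params(max(mean(lower) * constraints$snr_min, q95), noise$failures)
  }
  p_zero <- mean(counts == 0)
  p_noise <- length(lower) / length(counts)
  p_signal <- length(upper) / length(counts)
  initial <- pmax(c(p_zero, p_noise, p_signal), 1e-6)
  initial <- initial / sum(initial)
  transitions <- matrix(0.01, 3, 3)
  diag(transitions) <- 0.98
  model <- hmm_model(initial, transitions, noise, signal, constraints)
  project_constraints(model)$model
}

# enforce noise floor, state-swap guard and SNR bound; returns the projected
# model and whether any projection fired
project_constraints <- function(model) {
  cs <- model$constraints
  fired <- FALSE
  if (model$noise$mean < cs$noise_min) {
    model$noise$mean <- cs$noise_min
    fired <- TRUE
  }
  if (!is.na(cs$noise_max) && model$noise$mean > cs$noise_max) {
    model$noise$mean <- cs$noise_max
    fired <- TRUE
  }
  if (model$signal$mean < model$noise$mean) {
    # EM may drift the states into swapped roles; swap parameters together
    # with the corresponding transition rows/columns and initial entries
    tmp <- model$noise; model$noise <- model$signal; model$signal <- tmp
    perm <- c(1, 3, 2)
    model$transitions <- model$transitions[perm, perm]
    model$initial <- model$initial[perm]
    fired <- TRUE
  }
  if (model$signal$mean / model$noise$mean < cs$snr_min) {
    model$signal$mean <- cs$snr_min * model$noise$mean
    fired <- TRUE
  }
  list(model = model, fired = fired)
}

#' Forward-backward posterior decoding
#'
#' Runs the log-space forward-backward recursions independently per
#' chromosome (each restarts from the initial distribution) and returns
#' per-bin state posteriors, summed pairwise transition posteriors (for the
#' Baum-Welch M-step) and the total log-likelihood. The posterior error
#' probability (PEP) of a bin is the posterior probability of "no signal":
#' `posterior(zero) + posterior(noise) = 1 - posterior(signal)`.
#'
#' @param track a [binned_track()].
#' @param model an [hmm_model()].
#' @return object of class `PosteriorTrack`: list with `pep` (named list of
#'   per-chromosome vectors), `posterior` (named list of n x 3 matrices),
#'   `xi_sum`, `first_gamma` and `loglik`.
#' @export
forward_backward <- function(track, model) {
  log_pi <- log(model$initial)
  log_A <- log(model$transitions)
  pep <- list()
  posterior <- list()
  xi_sum <- matrix(0, 3, 3)
  ll <- 0
  fg <- matrix(0, 0, 3)
  for (cn in names(track$counts)) {
    counts <- track$counts[[cn]]
    if (length(counts) == 0L) next
    le <- emission_matrix(counts, model)
    res <- forward_backward_cpp(le, log_pi, log_A)
    posterior[[cn]] <- res$gamma
    pep[[cn]] <- 1 - res$gamma[, 3]
    xi_sum <- xi_sum + res$xi_sum
    fg <- rbind(fg, res$gamma[1, ])
    ll <- ll + res$loglik
  }
  if (length(pep) == 0L) stop("track has no bins")
  structure(list(pep = pep, posterior = posterior, xi_sum = xi_sum,
                 first_gamma = fg, loglik = ll),
            class = "PosteriorTrack")
}

#' Posterior error probabilities from state posteriors
#'
#' @param posteriors a `PosteriorTrack` from [forward_backward()].
#' @return the same object with `pep` recomputed as
#'   `posterior(zero) + posterior(noise)`.
#' @export
compute_pep <- function(posteriors) {
  stopifnot(inherits(posteriors, "PosteriorTrack"))
  posteriors$pep <- lapply(posteriors$posterior,
                           function(g) g[, 1] + g[, 2])
  posteriors
}

#' Fit the constrained three-state model by Baum-Welch EM
#'
#' Standard Baum-Welch E-steps (via [forward_backward()]) alternate with
#' M-steps updating the initial distribution, transition matrix and the two
#' negative-binomial emission laws (means from posterior-weighted counts;
#' dispersions by a weighted method of moments). After every M-step the
#' constraints are projected: noise mean floored at `noise_min`, states
#' swapped if the signal mean dropped below the noise mean, and the signal
#' mean raised to `snr_min * noise_mean` if the SNR bound is violated. EM
#' stops when the relative log-likelihood improvement falls below
#' `tolerance` or after `max_iterations`. A log-likelihood decrease beyond
#' numerical noise following a projection-free iteration is an error (EM
#' monotonicity violated); decreases caused by a constraint projection are
#' expected and allowed.
#'
#' @param track a [binned_track()].
#' @param constraints a [constraints()] object.
#' @param model optional starting [hmm_model()]; defaults to
#'   [initialize_model()].
#' @return the fitted `HmmModel` with `log_likelihood_trace` filled in and
#'   an `iterations` attribute (iteration index at which the stopping rule
#'   fired).
#' @export
fit_constrained <- function(track, constraints = hmmpeaks::constraints(),
                            model = NULL) {
  if (is.na(constraints$noise_max)) {
    cts <- flatten_counts(track)
    constraints$noise_max <- max(constraints$noise_min, mean(cts))
  }
  if (is.null(model)) model <- initialize_model(track, constraints)
  model$constraints <- constraints
  trace <- numeric()
  prev_ll <- -Inf
  prev_fired <- TRUE  # initialization counts as a projection
  iterations <- constraints$max_iterations
  for (it in seq_len(constraints$max_iterations)) {
    fb <- forward_backward(track, model)
    ll <- fb$loglik
    trace <- c(trace, ll)
    if (is.finite(prev_ll)) {
      if (!prev_fired && ll < prev_ll - 1e-6 * max(1, abs(prev_ll)))
        stop(sprintf(
          "EM monotonicity violated: log-likelihood fell from %.6f to %.6f",
          prev_ll, ll))
      if (abs(ll - prev_ll) / abs(prev_ll) < constraints$tolerance) {
        iterations <- it
        break
      }
    }
    prev_ll <- ll
    model <- m_step(track, model, fb)
    proj <- project_constraints(model)
    model <- proj$model
    prev_fired <- proj$fired
  }
  model$log_likelihood_trace <- trace
  attr(model, "iterations") <- iterations
  stopifnot(model$signal$mean / model$noise$mean >=
              constraints$snr_min - 1e-9,
            model$noise$mean >= constraints$noise_min - 1e-12)
  model
}

m_step <- function(track, model, fb) {
  # initial distribution: average first-bin posterior across chromosomes
  initial <- colMeans(fb$first_gamma)
  initial <- pmax(initial, 1e-12)
  initial <- initial / sum(initial)
  # transitions: normalized expected transition counts
  A <- fb$xi_sum
  rs <- rowSums(A)
  trans <- model$transitions
  for (i in 1:3) if (rs[i] > 0) trans[i, ] <- A[i, ] / rs[i]
  trans <- trans / rowSums(trans)
  # NB emissions: mean from posterior-weighted counts (exact M-step for the
  # mean); dispersion r by profile maximum likelihood on weights aggregated
  # over unique count values, so the M-step maximizes the expected complete
  # log-likelihood and EM monotonicity holds
  upd <- list(noise = model$noise, signal = model$signal)
  for (s in c(2L, 3L)) {
    wsum <- 0; xsum <- 0
    vals <- list()
    for (cn in names(track$counts)) {
      g <- fb$posterior[[cn]][, s]
      x <- track$counts[[cn]]
      wsum <- wsum + sum(g)
      xsum <- xsum + sum(g * x)
      dt <- data.table::data.table(x = x, g = g)
      vals[[cn]] <- dt[, list(w = sum(g)), by = x]
    }
    if (wsum <= 1e-9) next
    m <- xsum / wsum
    tab <- data.table::rbindlist(vals)[, list(w = sum(w)), by = x]
    upd[[s - 1L]] <- nb_params(max(m, 1e-6),
                               nb_mle_r(tab$x, tab$w, max(m, 1e-6)))
  }
  hmm_model(initial, trans, upd$noise, upd$signal, model$constraints,
            model$log_likelihood_trace)
}

#' Save / load a fitted model as a tab-delimited text dump
#'
#' The dump stores the initial vector, transition matrix, negative-binomial
#' parameters, constraints and the log-likelihood trace at full double
#' precision (`%.17g`), so a reloaded model reproduces PEPs bit-identically
#' on the same track.
#'
#' @param model an [hmm_model()].
#' @param path output (input) file path.
#' @export
write_model <- function(model, path) {
  g <- function(x) sprintf("%.17g", x)
  lines <- c(
    paste(c("initial", g(model$initial)), collapse = "\t"),
    paste(c("transitions", g(as.vector(t(model$transitions)))),
          collapse = "\t"),
    paste(c("noise", g(model$noise$mean), g(model$noise$failures)),
          collapse = "\t"),
    paste(c("signal", g(model$signal$mean), g(model$signal$failures)),
          collapse = "\t"),
    paste(c("constraints", g(model$constraints$snr_min),
            g(model$constraints$noise_min),
            g(model$constraints$noise_max),
            model$constraints$max_iterations,
            g(model$constraints$tolerance)), collapse = "\t"),
    paste(c("trace", g(model$log_likelihood_trace)), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  named <- stats::setNames(lapply(fields, function(f) as.numeric(f[-1])),
                           vapply(fields, `[[`, character(1), 1L))
  cs <- constraints(snr_min = named$constraints[1],
                    noise_min = named$constraints[2],
                    noise_max = named$constraints[3],
                    max_iterations = named$constraints[4],
                    tolerance = named$constraints[5])
  hmm_model(named$initial,
            matrix(named$transitions, 3, 3, byrow = TRUE),
            nb_params(named$noise[1], named$noise[2]),
            nb_params(named$signal[1], named$signal[2]),
            cs, trace = named$trace)
}
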