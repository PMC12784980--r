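# Shared fixtures and independent oracles. Everything is generated in code;
# no binary files.

STATE_NAMES <- c("zero", "noise", "signal")

# Brute-force posterior decoding by enumerating all 3^n state paths.
# Independent of the forward-backward implementation: works directly from
# initial/transition probabilities and emission_logprob.
enum_posterior <- function(counts, model) {
  n <- length(counts)
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  logp <- apply(paths, 1, function(s) {
    lp <- log(model$initial[s[1]]) +
      emission_logprob(STATE_NAMES[s[1]], counts[1], model)
    if (n > 1) for (t in 2:n)
      lp <- lp + log(model$transitions[s[t - 1], s[t]]) +
        emission_logprob(STATE_NAMES[s[t]], counts[t], model)
    lp
  })
  m <- max(logp[is.finite(logp)])
  w <- exp(logp - m)
  loglik <- m + log(sum(w))
  w <- w / sum(w)
  post <- t(sapply(seq_len(n), function(t)
    sapply(1:3, function(k) sum(w[paths[, t] == k]))))
  list(posterior = post, loglik = loglik)
}

toy_hmm <- function() {
  hmm_model(c(0.5, 0.3, 0.2),
            matrix(c(0.8, 0.15, 0.05,
                     0.2, 0.60, 0.20,
                     0.1, 0.30, 0.60), 3, 3, byrow = TRUE),
            nb_params(2, 1), nb_params(10, 5))
}

# a known generating model for parameter-recovery runs
recovery_hmm <- function(noise_mean = 2, signal_mean = 40) {
  hmm_model(c(0.5, 0.3, 0.2),
            matrix(c(0.99, 0.008, 0.002,
                     0.02, 0.95, 0.03,
                     0.01, 0.04, 0.95), 3, 3, byrow = TRUE),
            nb_params(noise_mean, 5), nb_params(signal_mean, 5))
}

# small end-to-end synthetic experiment (2 Mbp, 50 peaks, 100k reads)
small_experiment <- function(quality = 1.0, seed = 1, n_peaks = 50,
                             n_reads = 1e5, genome = 2e6,
                             peak_length_model = "narrow", bin = 200) {
  spec <- simulation_spec(layout = genome_layout("chrS", genome),
                          n_peaks = n_peaks, n_reads = n_reads,
                          quality = quality, seed = seed,
                          peak_length_model = peak_length_model)
  truth <- sample_ground_truth(spec)
  tags <- generate_reads(truth, spec)
  layout <- set_bin_size(spec$layout, bin)
  track <- shift_and_bin(remove_duplicates(tags), fixed_fragment(150),
                         layout)
  list(spec = spec, truth = truth, tags = tags, layout = layout,
       track = track)
}

random_pep_track <- function(n = 500, seed = 1) {
  set.seed(seed)
  list(chrT = stats::rbeta(n, 0.3, 0.3))
}
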