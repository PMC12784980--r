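#' Specification of a synthetic ChIP-seq experiment
#'
#' A lightweight surrogate of model-based read simulators: a ground-truth
#' peak set with a minimal inter-peak gap, reads drawn either from inside
#' the peaks (with probability `quality`) or uniformly from the background,
#' and a matched uniform control. Defaults follow the benchmark design used
#' throughout this package: 500 ground-truth peaks and 1 million reads on a
#' single 10 Mbp toy chromosome, with peaks at least 5 kbp apart and a
#' quality grid of 100/70/50/20/10%.
#'
#' Peak lengths are log-normal with `sdlog = 0.5`, parameterized so the
#' expectation equals the regime mean: ~1 kbp for `"narrow"`, ~20 kbp for
#' `"broad"`; `"mixed"` draws 400 narrow plus 100 broad peaks (scaled to
#' `n_peaks`).
#'
#' @param layout `GenomeLayout`; default one 10 Mbp chromosome `"chrS"`.
#' @param n_peaks number of ground-truth peaks.
#' @param peak_length_model `"narrow"`, `"broad"` or `"mixed"`.
#' @param min_gap minimal gap between neighbouring peaks, bp.
#' @param n_reads number of reads to simulate.
#' @param quality fraction of reads emitted from peaks, in (0, 1].
#' @param fragment fragment length, bp.
#' @param seed integer seed; every simulation is bit-reproducible from it.
#' @return object of class `SimulationSpec`.
#' @export
simulation_spec <- function(layout = NULL, n_peaks = 500,
                            peak_length_model = c("narrow", "broad",
                                                  "mixed"),
                            min_gap = 5000, n_reads = 1e6, quality = 1.0,
                            fragment = 150, seed = 1) {
  if (is.null(layout)) layout <- genome_layout("chrS", 1e7)
  peak_length_model <- match.arg(peak_length_model)
  stopifnot(quality > 0, quality <= 1, n_peaks >= 0, n_reads >= 0,
            min_gap >= 0, fragment >= 0)
  structure(list(layout = layout, n_peaks = as.integer(n_peaks),
                 peak_length_model = peak_length_model,
                 min_gap = as.numeric(min_gap),
                 n_reads = as.integer(n_reads), quality = quality,
                 fragment = as.numeric(fragment), seed = as.integer(seed)),
            class = "SimulationSpec")
}

regime_lengths <- function(spec) {
  n <- spec$n_peaks
  means <- switch(spec$peak_length_model,
                  narrow = rep(1000, n),
                  broad = rep(20000, n),
                  mixed = {
                    n_broad <- round(n * 100 / 500)
                    c(rep(1000, n - n_broad), rep(20000, n_broad))
                  })
  sdlog <- 0.5
  # meanlog set so E[length] equals the regime mean
  list(lengths = pmax(1, round(stats::rlnorm(
         n, meanlog = log(means) - sdlog^2 / 2, sdlog = sdlog))),
       regime = ifelse(means >= 20000, "broad", "narrow"))
}

#' Sample a ground-truth peak set
#'
#' Draws `n_peaks` lengths from the spec's length model and places the peaks
#' left to right across the genome with random gaps of at least `min_gap`
#' bp. Deterministic given the spec seed. Infeasible packing (peaks plus
#' mandatory gaps exceed the genome) is an error before any sampling output
#' is produced.
#'
#' @param spec a [simulation_spec()].
#' @return data.frame of intervals (chrom, start, end), 0-based half-open,
#'   sorted, with all inter-peak gaps >= `min_gap`.
#' @export
sample_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  if (spec$n_peaks == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  set.seed(spec$seed)
  rl <- regime_lengths(spec)
  lens <- rl$lengths
  genome_len <- sum(spec$layout$lengths)
  required <- sum(lens) + (spec$n_peaks - 1) * spec$min_gap
  if (required > genome_len)
    stop(sprintf("infeasible packing: %d peaks need %.0f bp, genome has %.0f",
                 spec$n_peaks, required, genome_len))
  slack <- genome_len - required
  u <- stats::runif(spec$n_peaks + 1)
  extra <- floor(slack * u / sum(u))
  gaps <- c(extra[1], spec$min_gap + extra[-1][-spec$n_peaks])
  starts <- cumsum(gaps) + cumsum(c(0, lens[-spec$n_peaks]))
  ends <- starts + lens
  # map linear genome coordinates back onto chromosomes
  offs <- c(0, cumsum(spec$layout$lengths))
  chrom <- spec$layout$chroms[findInterval(starts, offs,
                                           rightmost.closed = TRUE)]
  start_local <- starts - offs[match(chrom, spec$layout$chroms)]
  end_local <- pmin(start_local + lens,
                    spec$layout$lengths[chrom])
  data.frame(chrom = chrom, start = start_local, end = end_local,
             regime = rl$regime)
}

#' Generate a synthetic treatment tag track
#'
#' Each of `n_reads` reads comes from a ground-truth peak with probability
#' `quality` (peak chosen proportional to its length, fragment midpoint from
#' a symmetric triangular distribution over the peak so coverage is peaked
#' at the center) and from the uniform background otherwise. A single-end
#' tag is emitted at a uniformly chosen fragment end with the corresponding
#' strand (plus at the fragment start, minus at `end - 1`), clamped to the
#' chromosome.
#'
#' @param truth intervals from [sample_ground_truth()].
#' @param spec a [simulation_spec()].
#' @return a [tag_collection()] with exactly `n_reads` tags.
#' @export
generate_reads <- function(truth, spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed + 500009L)
  n <- spec$n_reads
  if (n == 0L)
    return(tag_collection(data.frame(chrom = character(), pos = numeric(),
                                     strand = character())))
  layout <- spec$layout
  genome_len <- sum(layout$lengths)
  offs <- c(0, cumsum(layout$lengths))
  from_peak <- nrow(truth) > 0 & stats::runif(n) < spec$quality
  mid <- numeric(n)
  chrom <- character(n)
  if (any(from_peak)) {
    k <- sum(from_peak)
    lens <- truth$end - truth$start
    pk <- sample.int(nrow(truth), k, replace = TRUE, prob = lens)
    # narrow point sources pile fragments up at the center (symmetric
    # triangular midpoint = mean of two uniforms); broad domains carry
    # near-uniform coverage across their whole span
    broad <- if ("regime" %in% names(truth)) truth$regime[pk] == "broad"
             else rep(FALSE, k)
    u1 <- stats::runif(k); u2 <- stats::runif(k)
    frac <- ifelse(broad, u1, (u1 + u2) / 2)
    mid[from_peak] <- truth$start[pk] + frac * lens[pk]
    chrom[from_peak] <- truth$chrom[pk]
  }
  if (any(!from_peak)) {
    k <- sum(!from_peak)
    g <- stats::runif(k) * genome_len
    ci <- findInterval(g, offs, rightmost.closed = TRUE)
    chrom[!from_peak] <- layout$chroms[ci]
    mid[!from_peak] <- g - offs[ci]
  }
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  half <- floor(spec$fragment / 2)
  pos <- ifelse(strand == "+", mid - half, mid + half - 1)
  pos <- floor(pmin(pmax(pos, 0), layout$lengths[chrom] - 1))
  tag_collection(data.frame(chrom = chrom, pos = pos, strand = strand))
}

#' Generate a matched uniform control track
#'
#' Pure background: the same read model as [generate_reads()] with
#' `quality` effectively 0, drawn from an independent seed stream.
#'
#' @param spec a [simulation_spec()].
#' @param n_reads number of control reads; defaults to the spec's
#'   `n_reads`.
#' @return a [tag_collection()].
#' @export
generate_control <- function(spec, n_reads = spec$n_reads) {
  stopifnot(inherits(spec, "SimulationSpec"))
  ctl_spec <- spec
  ctl_spec$seed <- spec$seed + 1000003L
  ctl_spec$n_reads <- as.integer(n_reads)
  ctl_spec$quality <- 1e-12  # uniform background only
  empty_truth <- data.frame(chrom = character(), start = numeric(),
                            end = numeric())
  generate_reads(empty_truth, ctl_spec)
}

#' Simulate a binned track directly from a known three-state model
#'
#' Draws a hidden state path from the model's initial distribution and
#' transition matrix, then emits per-bin counts (0 for the zero state,
#' negative-binomial draws for noise and signal). Used for parameter
#' recovery and EM convergence benchmarks where the generating truth must
#' be known exactly.
#'
#' @param model an [hmm_model()].
#' @param n_bins number of bins to simulate.
#' @param seed integer seed.
#' @param chrom chromosome name for the resulting track.
#' @param bin_size bin width recorded on the track, bp.
#' @return list with `track` (a [binned_track()]) and `states` (integer
#'   vector, 1 = zero, 2 = noise, 3 = signal).
#' @export
simulate_hmm_track <- function(model, n_bins, seed = 1, chrom = "chrS",
                               bin_size = 200) {
  set.seed(seed)
  A <- model$transitions
  states <- integer(n_bins)
  states[1] <- sample.int(3, 1, prob = model$initial)
  u <- stats::runif(n_bins)
  cA <- t(apply(A, 1, cumsum))
  for (t in 2:n_bins)
    states[t] <- findInterval(u[t], cA[states[t - 1], ]) + 1L
  counts <- integer(n_bins)
  idx_n <- states == 2L
  idx_s <- states == 3L
  counts[idx_n] <- stats::rnbinom(sum(idx_n), size = model$noise$failures,
                                  mu = model$noise$mean)
  counts[idx_s] <- stats::rnbinom(sum(idx_s), size = model$signal$failures,
                                  mu = model$signal$mean)
  track <- binned_track(stats::setNames(list(as.numeric(counts)), chrom),
                        bin_size, library_size = sum(counts))
  list(track = track, states = states)
}

#' Run a full synthetic experiment to files
#'
#' Writes `truth.bed`, `treatment.bed`, `control.bed` and `spec.json` into
#' `dir`.
#'
#' @param spec a [simulation_spec()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named list of file paths.
#' @export
simulate_experiment <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- sample_ground_truth(spec)
  treat <- generate_reads(truth, spec)
  ctl <- generate_control(spec)
  paths <- list(truth = file.path(dir, "truth.bed"),
                treatment = file.path(dir, "treatment.bed"),
                control = file.path(dir, "control.bed"),
                spec = file.path(dir, "spec.json"))
  write_bed(truth, paths$truth)
  write_tags_bed(treat, paths$treatment, read_length = 50)
  write_tags_bed(ctl, paths$control, read_length = 50)
  meta <- spec[setdiff(names(spec), "layout")]
  meta$chromosomes <- as.list(spec$layout$lengths)
  jsonlite::write_json(meta, paths$spec, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Write a tag collection as a BED6 file of fixed-length reads
#' @param tags a `TagCollection`.
#' @param path output file.
#' @param read_length reported read length, bp.
#' @keywords internal
#' @export
write_tags_bed <- function(tags, path, read_length = 50) {
  dt <- tags$tags
  if (nrow(dt) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  # clamp only the non-5' side so the 5' position round-trips exactly
  start <- ifelse(dt$strand == "+", dt$pos,
                  pmax(0, dt$pos + 1 - read_length))
  end <- ifelse(dt$strand == "+", dt$pos + read_length, dt$pos + 1)
  lines <- sprintf("%s\t%d\t%d\t.\t0\t%s", dt$chrom, as.integer(start),
                   as.integer(end), dt$strand)
  writeLines(lines, path)
  invisible(path)
}
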