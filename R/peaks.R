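#' Candidate peaks at a fixed PEP cutoff
#'
#' Groups maximal runs of consecutive bins whose PEP is at or below the
#' cutoff (small PEP = confident signal) into candidate intervals. Strict
#' adjacency: no gap merging.
#'
#' @param pep a `PosteriorTrack` (or a named list of per-chromosome PEP
#'   vectors).
#' @param threshold PEP cutoff in (0, 1).
#' @return object of class `CandidateSet`: list with `threshold` and
#'   `candidates`, a data.frame of (chrom, start_bin, end_bin), 0-based with
#'   exclusive end, sorted and disjoint.
#' @export
candidates_at <- function(pep, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  peps <- pep_list(pep)
  out <- lapply(names(peps), function(cn) {
    r <- rle(peps[[cn]] <= threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(chrom = cn, start_bin = starts[keep], end_bin = ends[keep])
  })
  cands <- do.call(rbind, out)
  if (is.null(cands))
    cands <- data.frame(chrom = character(), start_bin = integer(),
                        end_bin = integer())
  structure(list(threshold = threshold, candidates = cands),
            class = "CandidateSet")
}

pep_list <- function(pep) {
  if (inherits(pep, "PosteriorTrack")) pep$pep else pep
}

#' Candidate count and mean length across a log-spaced PEP threshold grid
#'
#' Evaluates [candidates_at()] on a log-spaced grid of cutoffs covering
#' `[1e-10, 0.5]` (strict to relaxed) and records the number of candidates
#' and their mean length in bp per threshold. The count is not monotone in
#' the threshold because neighbouring candidates merge as the cutoff
#' relaxes.
#'
#' @param pep a `PosteriorTrack`.
#' @param grid_size number of thresholds.
#' @param bin_size bin width in bp used to express mean lengths (default 1:
#'   lengths in bins).
#' @return object of class `ThresholdScan`: data.frame-backed list with
#'   `thresholds` (increasing PEP), `counts`, `mean_lengths`.
#' @export
scan_thresholds <- function(pep, grid_size = 40, bin_size = 1) {
  thresholds <- exp(seq(log(1e-10), log(0.5), length.out = grid_size))
  counts <- integer(grid_size)
  mean_lengths <- numeric(grid_size)
  for (i in seq_along(thresholds)) {
    cs <- candidates_at(pep, thresholds[i])
    counts[i] <- nrow(cs$candidates)
    mean_lengths[i] <- if (counts[i] > 0)
      mean((cs$candidates$end_bin - cs$candidates$start_bin) * bin_size)
    else 0
  }
  structure(list(thresholds = thresholds, counts = counts,
                 mean_lengths = mean_lengths),
            class = "ThresholdScan")
}

#' Select the saturation PEP threshold between pivotal points
#'
#' Walks the candidate count/mean-length trajectory along the log-threshold
#' axis. The first pivotal point is the first threshold producing any
#' candidate. The last pivotal point sits just before the noise blow-up,
#' detected as the first grid step whose count gain exceeds twice the
#' largest gain seen so far while the mean candidate length drops (a flood
#' of new small noise candidates). Between the pivotal points the per-step
#' gain `count(i) - count(i-1)` is examined: the selected threshold is the
#' first grid point after the gain maximum where the gain falls to at most
#' `saturation_fraction` of the maximal gain (newly added candidates have
#' saturated), extended to the end of the saturated stretch: the threshold
#' keeps relaxing while essentially no new candidates appear (existing ones
#' only lengthen or merge), and stops at the first re-acceleration or at the
#' last pivotal point. Stopping at the start of the stretch would truncate
#' peaks to their cores; the end of the stretch is where candidate lengths
#' stabilize. When the gain never saturates inside the interval (e.g.
#' strictly linear growth), the midpoint of the pivotal interval is the
#' deterministic fallback.
#'
#' @param scan a [scan_thresholds()] result.
#' @param saturation_fraction gain fraction that counts as saturated.
#' @return list with `threshold`, `index` into the grid, and
#'   `pivotal` (the two grid indices bracketing the search interval).
#' @export
select_threshold <- function(scan, saturation_fraction = 0.05) {
  counts <- scan$counts
  mlen <- scan$mean_lengths
  G <- length(counts)
  if (max(counts) < 1) stop("no enrichment detected")
  first_pivot <- which(counts > 0)[1]
  gain <- c(counts[1], diff(counts))  # gain at the first nonzero point is
                                      # its own count
  last_pivot <- G
  if (first_pivot < G) {
    for (j in seq(first_pivot + 1L, G)) {
      prior_max <- max(gain[first_pivot:(j - 1L)])
      if (prior_max > 0 && gain[j] > 2 * prior_max &&
          mlen[j] < mlen[j - 1L]) {
        last_pivot <- j - 1L
        break
      }
    }
  }
  if (last_pivot < first_pivot) last_pivot <- first_pivot
  gi <- seq(first_pivot, last_pivot)
  g <- gain[gi]
  sel <- NA_integer_
  gmax <- max(g)
  if (gmax > 0) {
    imax <- which.max(g)
    sat <- seq_along(gi) > imax & g <= saturation_fraction * gmax
    if (any(sat)) {
      s <- which(sat)[1]
      # extend through the saturated stretch: stop at the first grid point
      # where candidates start being added again
      e <- s
      while (e < length(gi) && sat[e + 1L]) e <- e + 1L
      sel <- gi[e]
    }
  }
  if (is.na(sel)) sel <- floor((first_pivot + last_pivot) / 2)
  sel <- min(max(sel, first_pivot), last_pivot)
  list(threshold = scan$thresholds[sel], index = sel,
       pivotal = c(first_pivot, last_pivot))
}

#' Score candidates with a block-wise local Poisson model
#'
#' For each candidate, bins are ranked by PEP (ascending, ties broken by
#' leftmost bin) and the `ceiling(n/2)` most confident bins are kept and
#' partitioned into maximal consecutive runs ("blocks"). Each block is
#' tested against an upper-tail Poisson null: observed = sum of treatment
#' counts over the block; expected lambda = scaled control counts over the
#' block if a control is given, otherwise `noise_mean * block_length`,
#' floored at `noise_min * block_length`. The candidate log10 p-value is the
#' block-length-weighted average of the block log10 p-values.
#'
#' @param cands a [candidates_at()] result.
#' @param track treatment `BinnedTrack` (the one the model was fitted to).
#' @param model the fitted [hmm_model()].
#' @param pep the `PosteriorTrack` used to form candidates.
#' @param control optional control `BinnedTrack`, already scaled to the
#'   treatment library size (bin values may be fractional).
#' @return data.frame: candidates plus `log10_p` and `fold` (observed /
#'   expected over the whole candidate).
#' @export
score_candidates <- function(cands, track, model, pep, control = NULL) {
  cc <- cands$candidates
  if (nrow(cc) == 0L) stop("no candidates to score")
  peps <- pep_list(pep)
  noise_mean <- model$noise$mean
  noise_min <- model$constraints$noise_min
  log10_p <- numeric(nrow(cc))
  fold <- numeric(nrow(cc))
  for (i in seq_len(nrow(cc))) {
    cn <- cc$chrom[i]
    bins <- seq(cc$start_bin[i] + 1L, cc$end_bin[i])  # 1-based indices
    p_bins <- peps[[cn]][bins]
    n <- length(bins)
    keep_n <- ceiling(n / 2)
    ord <- order(p_bins, seq_len(n))  # ties -> leftmost
    kept <- sort(bins[ord[seq_len(keep_n)]])
    runs <- split(kept, cumsum(c(1L, diff(kept) != 1L)))
    x <- track$counts[[cn]]
    ctl <- if (!is.null(control)) control$counts[[cn]] else NULL
    wsum <- 0; lsum <- 0
    for (blk in runs) {
      len <- length(blk)
      obs <- sum(x[blk])
      lambda <- if (!is.null(ctl)) sum(ctl[blk]) else noise_mean * len
      lambda <- max(lambda, noise_min * len)
      lp <- stats::ppois(obs - 1, lambda, lower.tail = FALSE,
                         log.p = TRUE) / log(10)
      wsum <- wsum + len * lp
      lsum <- lsum + len
    }
    log10_p[i] <- wsum / lsum
    all_obs <- sum(x[bins])
    all_exp <- if (!is.null(ctl)) sum(ctl[bins]) else noise_mean * n
    fold[i] <- all_obs / max(all_exp, noise_min * n)
  }
  cbind(cc, log10_p = log10_p, fold = fold)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (with monotonicity enforcement) or Bonferroni
#' `min(1, m * p)`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param method `"bh"` or `"bonferroni"`.
#' @return vector of adjusted q-values.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Refine peak boundaries using local coverage
#'
#' From each edge inward, bins whose count is below
#' `clip_fraction * max(count within the peak)` are dropped, removing at
#' most `max_clip` of the original length per side; the peak is never
#' emptied and boundaries never move outward.
#'
#' @param bins integer vector of 1-based bin indices (consecutive).
#' @param counts per-bin counts for the whole chromosome.
#' @param clip_fraction fraction of the in-peak maximum below which edge
#'   bins are clipped.
#' @param max_clip maximal fraction of the original length removable per
#'   side.
#' @return integer vector of retained bin indices.
#' @export
refine_boundaries <- function(bins, counts, clip_fraction = 0.25,
                              max_clip = 0.25) {
  n <- length(bins)
  stopifnot(n >= 1)
  v <- counts[bins]
  cut <- clip_fraction * max(v)
  budget <- floor(max_clip * n)
  lo <- 1L; hi <- n
  nl <- 0L
  while (nl < budget && lo < hi && v[lo] < cut) {
    lo <- lo + 1L; nl <- nl + 1L
  }
  nr <- 0L
  while (nr < budget && hi > lo && v[hi] < cut) {
    hi <- hi - 1L; nr <- nr + 1L
  }
  bins[lo:hi]
}

#' Find independent summits inside a peak
#'
#' Local maxima of the 3-bin moving-average coverage inside the peak with
#' height at least `height_fraction` of the in-peak maximum, greedily
#' thinned (highest first, ties to the leftmost) so that retained summits
#' are at least `min_separation` bins apart.
#'
#' @param bins integer vector of 1-based bin indices of the refined peak.
#' @param counts per-bin counts for the whole chromosome.
#' @param min_separation minimal distance between summits, bins.
#' @param height_fraction minimal summit height relative to the peak max.
#' @return integer vector of summit bin indices (subset of `bins`).
#' @export
find_summits <- function(bins, counts, min_separation = 5,
                         height_fraction = 0.5) {
  v <- counts[bins]
  n <- length(v)
  if (n == 1L) return(bins)
  # zero-padded 3-bin average: truncated windows would inflate edge bins
  vp <- c(0, v, 0)
  ma <- (vp[seq_len(n)] + vp[seq_len(n) + 1L] + vp[seq_len(n) + 2L]) / 3
  peak_max <- max(ma)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) ma[i - 1] else -Inf
    right <- if (i < n) ma[i + 1] else -Inf
    ma[i] >= left && ma[i] >= right
  }, logical(1))
  cand <- which(is_max & ma >= height_fraction * peak_max)
  if (length(cand) == 0L) cand <- which.max(ma)
  # smoothing plateaus tie several bins; prefer the higher raw count, then
  # the leftmost
  ord <- cand[order(-ma[cand], -v[cand], cand)]
  kept <- integer()
  for (i in ord)
    if (all(abs(i - kept) >= min_separation)) kept <- c(kept, i)
  bins[sort(kept)]
}

#' Full model-to-peaks pipeline
#'
#' Selects the saturation PEP threshold, forms candidates, scores them by
#' the block-wise local Poisson model, adjusts p-values, keeps candidates
#' with `q <= fdr`, refines boundaries, optionally finds summits, and
#' returns BED 6+3-ready peak records in bp coordinates.
#'
#' @param pep `PosteriorTrack` from the fitted model.
#' @param track treatment `BinnedTrack`.
#' @param model fitted [hmm_model()].
#' @param layout `GenomeLayout` with `bin_size` set.
#' @param control optional scaled control `BinnedTrack` (see
#'   [score_candidates()]).
#' @param fdr false discovery rate; the single user-facing parameter.
#' @param method multiple-testing adjustment, `"bh"` or `"bonferroni"`.
#' @param summits logical; also report summits within each peak.
#' @param clip_fraction,max_clip boundary refinement parameters, see
#'   [refine_boundaries()].
#' @return object of class `PeakSet`: a data.frame with columns chrom,
#'   start, end, name, score, strand, value, neg_log10_p, neg_log10_q (and a
#'   `summits` list-column of bp offsets when `summits = TRUE`), plus
#'   attributes `threshold` and `scan`.
#' @export
call_peaks <- function(pep, track, model, layout, control = NULL,
                       fdr = 0.05, method = c("bh", "bonferroni"),
                       summits = FALSE, clip_fraction = 0.25,
                       max_clip = 0.25) {
  method <- match.arg(method)
  stopifnot(fdr > 0, fdr <= 1)
  bs <- layout$bin_size
  scan <- scan_thresholds(pep, bin_size = bs)
  sel <- select_threshold(scan)
  cands <- candidates_at(pep, sel$threshold)
  scored <- score_candidates(cands, track, model, pep, control = control)
  pvals <- 10^scored$log10_p
  qvals <- adjust_pvalues(pvals, method)
  keep <- which(qvals <= fdr)
  if (length(keep) == 0L)
    return(empty_peakset(sel$threshold, scan))
  recs <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    cn <- scored$chrom[i]
    bins <- seq(scored$start_bin[i] + 1L, scored$end_bin[i])
    bins <- refine_boundaries(bins, track$counts[[cn]], clip_fraction,
                              max_clip)
    start_bp <- (bins[1] - 1L) * bs
    end_bp <- min(bins[length(bins)] * bs, layout$lengths[[cn]])
    nl10p <- -scored$log10_p[i]
    nl10q <- -log10(max(qvals[i], 1e-300))
    rec <- data.frame(chrom = cn, start = start_bp, end = end_bp,
                      name = "", score = min(1000, round(10 * nl10q)),
                      strand = ".", value = scored$fold[i],
                      neg_log10_p = nl10p, neg_log10_q = nl10q)
    if (summits) {
      sb <- find_summits(bins, track$counts[[cn]])
      rec$summits <- I(list((sb - 1L) * bs + floor(bs / 2) - start_bp))
    }
    recs[[k]] <- rec
  }
  peaks <- do.call(rbind, recs)
  ord <- order(match(peaks$chrom, layout$chroms), peaks$start)
  peaks <- peaks[ord, , drop = FALSE]
  peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  rownames(peaks) <- NULL
  attr(peaks, "threshold") <- sel$threshold
  attr(peaks, "scan") <- scan
  class(peaks) <- c("PeakSet", "data.frame")
  peaks
}

empty_peakset <- function(threshold, scan) {
  peaks <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = integer(),
                      strand = character(), value = numeric(),
                      neg_log10_p = numeric(), neg_log10_q = numeric())
  attr(peaks, "threshold") <- threshold
  attr(peaks, "scan") <- scan
  class(peaks) <- c("PeakSet", "data.frame")
  peaks
}

#' Length-based Jaccard index of two interval sets
#'
#' Total intersection length divided by total union length, the standard
#' consistency metric for peak sets. Intervals are 0-based half-open; each
#' set is flattened (self-overlaps merged) first.
#'
#' @param a,b data.frames with columns chrom, start, end.
#' @return a number in `[0, 1]` (0 when both sets are empty).
#' @export
jaccard_intervals <- function(a, b) {
  merge_set <- function(df) {
    if (nrow(df) == 0L) return(df)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    out <- list()
    for (cn in unique(df$chrom)) {
      s <- df[df$chrom == cn, , drop = FALSE]
      starts <- s$start; ends <- s$end
      m_starts <- starts[1]; m_ends <- ends[1]
      if (nrow(s) > 1) for (i in 2:nrow(s)) {
        last <- length(m_ends)
        if (starts[i] <= m_ends[last]) {
          m_ends[last] <- max(m_ends[last], ends[i])
        } else {
          m_starts <- c(m_starts, starts[i]); m_ends <- c(m_ends, ends[i])
        }
      }
      out[[cn]] <- data.frame(chrom = cn, start = m_starts, end = m_ends)
    }
    do.call(rbind, out)
  }
  a <- merge_set(a[, c("chrom", "start", "end")])
  b <- merge_set(b[, c("chrom", "start", "end")])
  len <- function(df) if (nrow(df) == 0L) 0 else sum(df$end - df$start)
  inter <- 0
  for (cn in intersect(unique(a$chrom), unique(b$chrom))) {
    sa <- a[a$chrom == cn, ]; sb <- b[b$chrom == cn, ]
    for (i in seq_len(nrow(sa))) {
      lo <- pmax(sa$start[i], sb$start); hi <- pmin(sa$end[i], sb$end)
      inter <- inter + sum(pmax(0, hi - lo))
    }
  }
  un <- len(a) + len(b) - inter
  if (un == 0) return(0)
  inter / un
}
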