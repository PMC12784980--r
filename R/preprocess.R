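#' Binned coverage track
#'
#' Per-chromosome vectors of non-negative counts on a fixed bin grid.
#' Before control correction the counts are integers and sum to the number
#' of shifted tags; after correction they remain non-negative integers.
#'
#' @param counts named list (one element per chromosome) of numeric vectors.
#' @param bin_size bin width in bp.
#' @param library_size total number of tags the track was built from.
#' @return object of class `BinnedTrack`.
#' @export
binned_track <- function(counts, bin_size, library_size) {
  stopifnot(is.list(counts), !is.null(names(counts)), bin_size > 0)
  if (any(vapply(counts, function(x) any(x < 0), logical(1))))
    stop("bin counts must be non-negative")
  structure(list(counts = counts, bin_size = as.numeric(bin_size),
                 library_size = as.numeric(library_size)),
            class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf(
    "BinnedTrack: %d chromosome(s), %d bins of %d bp, library size %s\n",
    length(x$counts), sum(lengths(x$counts)), as.integer(x$bin_size),
    format(x$library_size, big.mark = ",")))
  invisible(x)
}

#' Concatenate per-chromosome bin counts into one genome-wide vector
#' @param track a `BinnedTrack`.
#' @keywords internal
#' @export
flatten_counts <- function(track) unlist(track$counts, use.names = FALSE)

#' Remove PCR-duplicate tags
#'
#' Keeps at most one tag per (chromosome, position, strand) for single-end
#' libraries, and per (chromosome, position, strand, insert size) for
#' paired-end ones. Idempotent.
#'
#' @param tags a [tag_collection()].
#' @return deduplicated `TagCollection`.
#' @export
remove_duplicates <- function(tags) {
  stopifnot(inherits(tags, "TagCollection"))
  key <- if (tags$paired) c("chrom", "pos", "strand", "insert")
         else c("chrom", "pos", "strand")
  dt <- unique(tags$tags, by = key)
  tag_collection(dt, paired = tags$paired)
}

#' Estimate library fragment size
#'
#' For paired-end libraries the fragment size is the median insert size. For
#' single-end libraries it is estimated by strand cross-correlation: plus-
#' and minus-strand 5'-position coverage is accumulated in small micro-bins
#' (default 5 bp) and the Pearson correlation between the plus profile and
#' the minus profile shifted by d is evaluated for every shift d in
#' `[0, max_shift]` (in micro-bin steps); the fragment size is the argmax,
#' excluding a +-10 bp "phantom" window around the read length. With too few
#' tags (< 1000 per strand) or a flat profile the estimate falls back to a
#' fixed 150 bp with a warning.
#'
#' @param tags a `TagCollection` (deduplicated).
#' @param layout a `GenomeLayout`.
#' @param max_shift largest shift tried, bp.
#' @param read_length read length in bp, used to mask the phantom
#'   autocorrelation peak; `NA` disables masking.
#' @param micro_bin micro-bin width for the correlation profile, bp.
#' @return list of class `FragmentEstimate` with `fragment_size`, `method`
#'   (`"cross_correlation"`, `"paired_end"` or `"user_fixed"`), and
#'   `profile` (data.frame shift/correlation, single-end only).
#' @export
estimate_fragment_size <- function(tags, layout, max_shift = 500,
                                   read_length = NA, micro_bin = 5) {
  stopifnot(inherits(tags, "TagCollection"))
  if (tags$paired) {
    ins <- tags$tags$insert
    ins <- ins[!is.na(ins) & ins > 0]
    if (length(ins) == 0L)
      return(fragment_fallback("no usable insert sizes"))
    return(structure(list(fragment_size = stats::median(ins),
                          method = "paired_end", profile = NULL),
                     class = "FragmentEstimate"))
  }
  dt <- tags$tags
  n_plus <- sum(dt$strand == "+")
  n_minus <- sum(dt$strand == "-")
  if (n_plus < 1000 || n_minus < 1000)
    return(fragment_fallback(sprintf(
      "too few tags per strand (+%d/-%d)", n_plus, n_minus)))
  shifts <- seq(0, max_shift, by = micro_bin)
  corr <- numeric(length(shifts))
  wts <- numeric(length(shifts))
  for (cn in intersect(layout$chroms, unique(dt$chrom))) {
    sub <- dt[dt$chrom == cn]
    nb <- as.integer(ceiling(layout$lengths[[cn]] / micro_bin))
    if (nb < max_shift / micro_bin + 2) next
    cp <- tabulate(sub$pos[sub$strand == "+"] %/% micro_bin + 1L, nbins = nb)
    cm <- tabulate(sub$pos[sub$strand == "-"] %/% micro_bin + 1L, nbins = nb)
    for (i in seq_along(shifts)) {
      k <- shifts[i] %/% micro_bin
      a <- cp[seq_len(nb - k)]
      b <- cm[seq_len(nb - k) + k]
      r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0
           else stats::cor(a, b)
      corr[i] <- corr[i] + r * (nb - k)
      wts[i] <- wts[i] + (nb - k)
    }
  }
  if (all(wts == 0)) return(fragment_fallback("chromosomes too short"))
  corr <- corr / pmax(wts, 1)
  if (max(corr) - min(corr) < 1e-12)
    return(fragment_fallback("flat cross-correlation profile"))
  usable <- rep(TRUE, length(shifts))
  if (!is.na(read_length))
    usable <- shifts < read_length - 10 | shifts > read_length + 10
  if (!any(usable)) usable <- rep(TRUE, length(shifts))
  best <- which(usable)[which.max(corr[usable])]
  structure(list(fragment_size = shifts[best], method = "cross_correlation",
                 profile = data.frame(shift = shifts, correlation = corr)),
            class = "FragmentEstimate")
}

fragment_fallback <- function(why) {
  warning("fragment size estimation failed (", why,
          "); falling back to 150 bp", call. = FALSE)
  structure(list(fragment_size = 150, method = "user_fixed", profile = NULL),
            class = "FragmentEstimate")
}

#' Fixed (user-supplied) fragment size
#' @param fragment_size fragment size in bp; 0 disables tag shifting
#'   (recommended for ATAC-seq).
#' @export
fixed_fragment <- function(fragment_size) {
  stopifnot(fragment_size >= 0)
  structure(list(fragment_size = as.numeric(fragment_size),
                 method = "user_fixed", profile = NULL),
            class = "FragmentEstimate")
}

#' Shift tags toward fragment centers and accumulate per-bin counts
#'
#' Plus-strand tags move to `pos + floor(fragment / 2)`, minus-strand tags
#' to `pos - floor(fragment / 2)`; shifted positions are clamped to the
#' chromosome. Tag count is conserved exactly: the bin counts sum to the
#' number of tags.
#'
#' @param tags a `TagCollection`.
#' @param fragment a `FragmentEstimate` (or the result of
#'   [fixed_fragment()]).
#' @param layout a `GenomeLayout` with `bin_size` set.
#' @return a [binned_track()].
#' @export
shift_and_bin <- function(tags, fragment, layout) {
  stopifnot(inherits(tags, "TagCollection"),
            inherits(fragment, "FragmentEstimate"),
            inherits(layout, "GenomeLayout"))
  if (is.na(layout$bin_size)) stop("bin_size not set on layout")
  half <- floor(fragment$fragment_size / 2)
  bs <- layout$bin_size
  nb <- n_bins(layout)
  counts <- lapply(layout$chroms, function(cn) numeric(nb[[cn]]))
  names(counts) <- layout$chroms
  dt <- tags$tags
  for (cn in intersect(layout$chroms, unique(dt$chrom))) {
    sub <- dt[dt$chrom == cn]
    shifted <- ifelse(sub$strand == "+", sub$pos + half, sub$pos - half)
    shifted <- pmin(pmax(shifted, 0), layout$lengths[[cn]] - 1)
    counts[[cn]] <- tabulate(shifted %/% bs + 1L, nbins = nb[[cn]])
  }
  binned_track(counts, bs, library_size = nrow(dt))
}

#' Beta-based control correction
#'
#' Scales the control track by the library-size ratio, then chooses beta on
#' the grid `{0, 0.01, ..., 1}` minimizing the absolute Pearson correlation
#' between `signal - beta * scaled_control` and the scaled control over all
#' genome bins (a zero-variance correlation counts as 0). Corrected counts
#' are `max(0, round(signal - beta * scaled_control))`.
#'
#' @param signal treatment `BinnedTrack`.
#' @param control control `BinnedTrack` on the same layout and bin grid.
#' @param beta_grid candidate beta values.
#' @return list of class `ControlCorrection` with `beta`, `control_scale`,
#'   `objective` (per-grid-point |correlation|) and `corrected`
#'   (`BinnedTrack`).
#' @export
correct_with_control <- function(signal, control,
                                 beta_grid = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(signal, "BinnedTrack"), inherits(control, "BinnedTrack"))
  if (signal$bin_size != control$bin_size)
    stop("signal and control bin sizes differ")
  if (!identical(lengths(signal$counts), lengths(control$counts)))
    stop("signal and control bin grids differ")
  if (control$library_size <= 0) stop("control track has library size 0")
  scale <- signal$library_size / control$library_size
  x <- flatten_counts(signal)
  c_raw <- flatten_counts(control)
  cs <- c_raw * scale
  obj <- vapply(beta_grid, function(b) {
    resid <- x - b * cs
    if (stats::sd(resid) == 0 || stats::sd(cs) == 0) 0
    else abs(stats::cor(resid, cs))
  }, numeric(1))
  beta <- beta_grid[which.min(obj)]
  corr_counts <- lapply(signal$counts, function(v) numeric(0))
  offset <- 0L
  for (cn in names(signal$counts)) {
    n <- length(signal$counts[[cn]])
    seg <- x[(offset + 1):(offset + n)] - beta * cs[(offset + 1):(offset + n)]
    corr_counts[[cn]] <- pmax(0, round(seg))
    offset <- offset + n
  }
  corrected <- binned_track(corr_counts, signal$bin_size,
                            library_size = signal$library_size)
  structure(list(beta = beta, control_scale = scale,
                 objective = data.frame(beta = beta_grid, objective = obj),
                 corrected = corrected),
            class = "ControlCorrection")
}
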