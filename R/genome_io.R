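#' Genome layout: chromosome sizes and the bin grid
#'
#' A `GenomeLayout` holds the ordered chromosome names and lengths plus the
#' bin width used to discretise coverage. All coordinates in this package are
#' 0-based, half-open (BED convention); bin `b` on a chromosome of length `L`
#' covers `[b * bin_size, min((b + 1) * bin_size, L))`.
#'
#' @param chroms character vector of chromosome names (unique, ordered).
#' @param lengths integer vector of chromosome lengths in bp (all > 0).
#' @param bin_size bin width in bp (> 0); may be set later with
#'   [set_bin_size()].
#' @return An object of class `GenomeLayout`: a list with elements `chroms`,
#'   `lengths` (named), and `bin_size` (may be `NA` until set).
#' @export
genome_layout <- function(chroms, lengths, bin_size = NA_integer_) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) == 0L) stop("no chromosomes")
  if (length(chroms) != length(lengths))
    stop("chroms and lengths differ in length")
  if (anyDuplicated(chroms))
    stop("duplicate chromosome name: ",
         paste(unique(chroms[duplicated(chroms)]), collapse = ", "))
  if (any(!is.finite(lengths)) || any(lengths <= 0) ||
      any(lengths != floor(lengths)))
    stop("chromosome lengths must be positive integers")
  if (!is.na(bin_size) && bin_size <= 0) stop("bin_size must be > 0")
  names(lengths) <- chroms
  structure(list(chroms = chroms, lengths = lengths,
                 bin_size = as.numeric(bin_size)),
            class = "GenomeLayout")
}

#' @rdname genome_layout
#' @param layout a `GenomeLayout`.
#' @export
set_bin_size <- function(layout, bin_size) {
  stopifnot(inherits(layout, "GenomeLayout"))
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stop("bin_size must be a single positive number")
  layout$bin_size <- as.numeric(bin_size)
  layout
}

#' Number of bins per chromosome
#' @param layout a `GenomeLayout` with `bin_size` set.
#' @return named integer vector, `ceiling(length / bin_size)` per chromosome.
#' @export
n_bins <- function(layout) {
  stopifnot(inherits(layout, "GenomeLayout"))
  if (is.na(layout$bin_size)) stop("bin_size not set")
  setNames(as.integer(ceiling(layout$lengths / layout$bin_size)),
           layout$chroms)
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat(sprintf("GenomeLayout: %d chromosome(s), %s bp total, bin_size = %s\n",
              length(x$chroms), format(sum(x$lengths), big.mark = ","),
              ifelse(is.na(x$bin_size), "<unset>", x$bin_size)))
  invisible(x)
}

#' Read a chromosome-sizes file
#'
#' Parses the standard two-column `chrom.sizes` format (`name<TAB>length`,
#' one chromosome per line). The only genome annotation the peak caller
#' needs; any assembly works.
#'
#' @param path path to a tab-separated chrom.sizes file.
#' @return a [genome_layout()] without a bin grid (`bin_size = NA`).
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no chromosomes in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 2L, logical(1))
  if (any(bad)) stop("malformed chrom.sizes line: ", lines[which(bad)[1]])
  chroms <- vapply(parts, `[[`, character(1), 1L)
  lens <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (any(is.na(lens)) || any(lens <= 0) || any(lens != floor(lens)))
    stop("chromosome lengths must be positive integers in ", path)
  genome_layout(chroms, lens)
}

#' Tag collection: deduplicatable strand-aware read 5' positions
#'
#' Internal container for aligned tags. `tags` is a `data.table` with columns
#' `chrom` (character), `pos` (0-based 5' position of the read), `strand`
#' (`"+"`/`"-"`), and `insert` (template length for paired-end, `NA`
#' otherwise), sorted by `(chrom, pos)`.
#'
#' @param tags data.frame/data.table with columns chrom, pos, strand and
#'   optionally insert.
#' @param paired logical; whether the library is paired-end.
#' @return object of class `TagCollection`.
#' @keywords internal
#' @export
tag_collection <- function(tags, paired = FALSE) {
  dt <- data.table::as.data.table(tags)
  if (!"insert" %in% names(dt)) dt[, insert := NA_real_]
  dt <- dt[, c("chrom", "pos", "strand", "insert")]
  stopifnot(all(dt$strand %in% c("+", "-")))
  data.table::setorder(dt, chrom, pos)
  structure(list(tags = dt, paired = isTRUE(paired)),
            class = "TagCollection")
}

#' @export
print.TagCollection <- function(x, ...) {
  cat(sprintf("TagCollection: %d tag(s) on %d chromosome(s)%s\n",
              nrow(x$tags), data.table::uniqueN(x$tags$chrom),
              if (x$paired) ", paired-end" else ""))
  invisible(x)
}

#' Total number of tags
#' @param tags a `TagCollection`.
#' @export
n_tags <- function(tags) nrow(tags$tags)

format_from_extension <- function(path) {
  p <- tolower(path)
  if (grepl("\\.bed\\.gz$", p)) return("bed.gz")
  switch(tolower(tools::file_ext(p)),
         bam = "bam", sam = "sam", cram = "cram", bed = "bed",
         bw = "bigwig", bigwig = "bigwig",
         stop("cannot infer format from extension of ", path))
}

#' Load aligned tags or pre-binned coverage
#'
#' Reads aligned tags from BAM/SAM/CRAM/BED/BED.gz, or pre-binned coverage
#' from BigWig. Alignment formats yield a [tag_collection()] of 5' positions
#' (minus-strand 5' end is `end - 1`, 0-based); unmapped, secondary and
#' supplementary alignments are skipped. BigWig bypasses tag preprocessing
#' entirely and yields a [binned_track()] whose per-bin values are the sums
#' of per-bp coverage, rounded to integers (`layout` must have `bin_size`
#' set). Reads on chromosomes absent from `layout` are dropped with a
#' message.
#'
#' @param path input file.
#' @param layout a [genome_layout()].
#' @param format one of `"bam"`, `"sam"`, `"cram"`, `"bed"`, `"bed.gz"`,
#'   `"bigwig"`; inferred from the extension when `NULL`.
#' @return a `TagCollection`, or a `BinnedTrack` for BigWig input.
#' @export
load_tags <- function(path, layout, format = NULL) {
  stopifnot(inherits(layout, "GenomeLayout"))
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(format)) format <- format_from_extension(path)
  format <- match.arg(format, c("bam", "sam", "cram", "bed", "bed.gz",
                                "bigwig"))
  out <- switch(format,
                bed = , bed.gz = load_tags_bed(path, layout),
                bam = , sam = , cram = load_tags_bam(path, layout, format),
                bigwig = load_bigwig(path, layout))
  out
}

load_tags_bed <- function(path, layout) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  df <- tryCatch(
    utils::read.table(con, sep = "\t", header = FALSE,
                      colClasses = c("character", "numeric", "numeric",
                                     "NULL", "NULL", "character"),
                      col.names = c("chrom", "start", "end", "name", "score",
                                    "strand"),
                      fill = TRUE, comment.char = "#"),
    error = function(e) stop("cannot read BED file ", path, ": ",
                             conditionMessage(e)))
  if (nrow(df) == 0L) stop("empty track: no usable reads in ", path)
  if (anyNA(df$strand) || any(!df$strand %in% c("+", "-", "")))
    df$strand[!df$strand %in% c("+", "-")] <- "+"
  df$strand[df$strand == ""] <- "+"
  keep <- df$chrom %in% layout$chroms
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " read(s) on chromosomes absent from layout dropped")
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty track: no reads on layout chromosomes")
  pos <- ifelse(df$strand == "+", df$start, df$end - 1)
  bad <- pos < 0 | pos >= layout$lengths[df$chrom]
  if (any(bad)) {
    message(sum(bad), " read(s) outside chromosome bounds dropped")
    df <- df[!bad, , drop = FALSE]
    pos <- pos[!bad]
  }
  if (nrow(df) == 0L) stop("empty track: no usable reads in ", path)
  tag_collection(data.frame(chrom = df$chrom, pos = pos,
                            strand = df$strand))
}

load_tags_bam <- function(path, layout, format) {
  for (pkg in c("Rsamtools", "GenomicAlignments"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop(pkg, " is required to read ", format, " files")
  if (format == "sam") {
    # htslib readers want BAM; convert to a session-temporary BAM first
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, what = c("flag", "isize"))
  ga <- GenomicAlignments::readGAlignments(path, param = param)
  if (length(ga) == 0L) stop("empty track: no usable reads in ", path)
  chrom <- as.character(GenomicAlignments::seqnames(ga))
  strand <- as.character(GenomicAlignments::strand(ga))
  strand[!strand %in% c("+", "-")] <- "+"
  # readGAlignments coordinates are 1-based closed; 5' end 0-based:
  pos <- ifelse(strand == "+",
                GenomicAlignments::start(ga) - 1L,
                GenomicAlignments::end(ga) - 1L)
  fl <- S4Vectors::mcols(ga)$flag
  isize <- S4Vectors::mcols(ga)$isize
  paired <- any(bitwAnd(fl, 1L) > 0L)
  insert <- if (paired) abs(as.numeric(isize)) else NA_real_
  keep <- chrom %in% layout$chroms
  if (any(!keep))
    message(sum(!keep), " read(s) on chromosomes absent from layout dropped")
  if (!any(keep)) stop("empty track: no reads on layout chromosomes")
  df <- data.frame(chrom = chrom[keep], pos = pos[keep],
                   strand = strand[keep],
                   insert = if (paired) insert[keep] else NA_real_)
  bad <- df$pos < 0 | df$pos >= layout$lengths[df$chrom]
  if (any(bad)) df <- df[!bad, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty track: no usable reads in ", path)
  tag_collection(df, paired = paired)
}

load_bigwig <- function(path, layout) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read BigWig files")
  if (is.na(layout$bin_size))
    stop("bin_size must be set on the layout before loading BigWig coverage")
  gr <- rtracklayer::import(path, format = "BigWig")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  keep <- chrom %in% layout$chroms
  if (any(!keep))
    message(sum(!keep), " interval(s) on chromosomes absent from layout dropped")
  gr <- gr[keep]
  chrom <- chrom[keep]
  if (length(gr) == 0L) stop("empty track: no coverage on layout chromosomes")
  bs <- layout$bin_size
  nb <- n_bins(layout)
  counts <- lapply(layout$chroms, function(cn) numeric(nb[[cn]]))
  names(counts) <- layout$chroms
  start0 <- GenomicRanges::start(gr) - 1  # to 0-based half-open
  end0 <- GenomicRanges::end(gr)
  val <- as.numeric(gr$score)
  for (i in seq_along(gr)) {
    cn <- chrom[i]
    s <- max(0, start0[i]); e <- min(end0[i], layout$lengths[[cn]])
    if (e <= s) next
    b0 <- floor(s / bs); b1 <- floor((e - 1) / bs)
    for (b in b0:b1) {
      lo <- max(s, b * bs); hi <- min(e, (b + 1) * bs)
      counts[[cn]][b + 1] <- counts[[cn]][b + 1] + val[i] * (hi - lo)
    }
  }
  counts <- lapply(counts, round)
  binned_track(counts, bs, library_size = sum(unlist(counts)))
}

#' Write peaks in BED 6+3 format
#'
#' Nine tab-separated columns, no header: chrom, start, end, name, score,
#' strand, signal value, -log10(p), -log10(q). Floats are printed with five
#' decimal places. Peaks must already be sorted by layout chromosome order
#' and start.
#'
#' @param peaks a `PeakSet` data.frame as produced by [call_peaks()]
#'   (columns chrom, start, end, name, score, strand, value, neg_log10_p,
#'   neg_log10_q).
#' @param path output file path.
#' @export
write_peaks_bed <- function(peaks, path) {
  if (is.null(peaks) || nrow(peaks) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  stopifnot(all(c("chrom", "start", "end", "name", "score", "strand",
                  "value", "neg_log10_p", "neg_log10_q") %in% names(peaks)))
  stopifnot(all(peaks$start < peaks$end))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%.5f\t%.5f\t%.5f",
                   peaks$chrom, as.integer(peaks$start),
                   as.integer(peaks$end), peaks$name,
                   as.integer(peaks$score), peaks$strand, peaks$value,
                   peaks$neg_log10_p, peaks$neg_log10_q)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED 6+3 peaks file written by [write_peaks_bed()]
#' @param path input file.
#' @return data.frame with the nine peak columns (zero rows for empty file).
#' @export
read_peaks_bed <- function(path) {
  if (!file.exists(path)) stop("peaks file not found: ", path)
  cols <- c("chrom", "start", "end", "name", "score", "strand", "value",
            "neg_log10_p", "neg_log10_q")
  if (file.size(path) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = integer(),
                      strand = character(), value = numeric(),
                      neg_log10_p = numeric(), neg_log10_q = numeric())
    return(out)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = cols,
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer", "character",
                                         "numeric", "numeric", "numeric"))
  df
}

#' Write intervals as a minimal BED file (3 or 6 columns)
#' @param intervals data.frame with chrom, start, end and optionally
#'   name/score/strand.
#' @param path output file.
#' @keywords internal
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (all(c("name", "score", "strand") %in% names(intervals))) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", intervals$chrom,
                     as.integer(intervals$start), as.integer(intervals$end),
                     intervals$name, as.integer(intervals$score),
                     intervals$strand)
  } else {
    lines <- sprintf("%s\t%d\t%d", intervals$chrom,
                     as.integer(intervals$start), as.integer(intervals$end))
  }
  writeLines(lines, path)
  invisible(path)
}
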