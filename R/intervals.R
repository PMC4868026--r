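#' Genomic interval utilities
#'
#' All coordinates inside the package are 1-based and inclusive (the PennCNV
#' convention); conversions from BED's 0-based half-open convention happen
#' only at file boundaries in [read_bed()] / [write_bed()]. Chromosome labels
#' are bare ("1".."22", "X"); a leading "chr" is stripped on input.
#'
#' @name intervals
#' @keywords internal
NULL

#' Normalize chromosome labels
#'
#' Strips any leading "chr" prefix and returns a character vector.
#'
#' @param chrom character or factor vector of chromosome labels.
#' @return character vector without "chr" prefixes.
#' @export
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

#' Width of 1-based inclusive intervals
#'
#' @param start,end integer vectors, `start <= end`.
#' @return integer vector `end - start + 1`.
#' @export
interval_span <- function(start, end) {
  stopifnot(all(start <= end))
  end - start + 1
}

#' Reported length of an interval in kb
#'
#' The kb length printed in result tables, computed as `(end - start) / 1000`
#' rounded to the nearest integer. Note this differs by one bp from the
#' inclusive span used in the QC filters ([interval_span()]); the reporting
#' convention follows the kb columns of PennCNV-style result tables.
#'
#' @param start_bp,end_bp positions, 1-based inclusive, `start_bp <= end_bp`.
#' @return numeric vector of kb lengths.
#' @export
call_span_kb <- function(start_bp, end_bp) {
  stopifnot(all(start_bp <= end_bp))
  round((end_bp - start_bp) / 1000)
}

#' Overlap widths of one query interval against a set of intervals
#'
#' @param qstart,qend scalar query interval (1-based inclusive).
#' @param starts,ends vectors of subject intervals on the same chromosome.
#' @return integer vector of per-subject intersection widths (0 when disjoint).
#' @keywords internal
overlap_width <- function(qstart, qend, starts, ends) {
  pmax(0L, pmin(qend, ends) - pmax(qstart, starts) + 1L)
}

#' Merge overlapping/adjacent intervals within chromosomes
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`.
#' @return data.frame of disjoint intervals sorted by (chrom, start).
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) {
    return(intervals[, c("chrom", "start", "end")])
  }
  pieces <- lapply(split(intervals, intervals$chrom), function(df) {
    ir <- IRanges::reduce(IRanges::IRanges(df$start, df$end))
    data.frame(chrom = df$chrom[1], start = IRanges::start(ir),
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of a query interval covered by a union of intervals
#'
#' Used for the exclusion-region QC filter: the union of the subject set is
#' intersected with the query and the covered fraction of the query span is
#' returned.
#'
#' @param chrom,start,end scalar query interval.
#' @param regions data.frame of intervals (`chrom`, `start`, `end`).
#' @return fraction in \[0, 1\].
#' @export
covered_fraction <- function(chrom, start, end, regions) {
  regions <- regions[normalize_chrom(regions$chrom) == normalize_chrom(chrom), ,
                     drop = FALSE]
  if (nrow(regions) == 0) return(0)
  merged <- merge_intervals(regions)
  w <- overlap_width(start, end, merged$start, merged$end)
  sum(as.numeric(w)) / interval_span(start, end)
}

#' Indices of probes falling inside an interval
#'
#' @param probes data.frame with `chrom` and `pos`, sorted by (chrom, pos).
#' @param chrom,start,end query interval.
#' @return integer vector of row indices of `probes` inside the interval.
#' @export
probes_in_interval <- function(probes, chrom, start, end) {
  idx <- which(normalize_chrom(probes$chrom) == normalize_chrom(chrom))
  if (length(idx) == 0) return(integer(0))
  pos <- probes$pos[idx]
  lo <- findInterval(start - 1, pos) + 1
  hi <- findInterval(end, pos)
  if (hi < lo) return(integer(0))
  idx[lo:hi]
}

#' Find interval overlaps between two interval sets
#'
#' Thin chromosome-aware wrapper around [IRanges::findOverlaps()] returning a
#' two-column data.frame of (query row, subject row) index pairs.
#'
#' @param query,subject data.frames with `chrom`, `start`, `end`.
#' @return data.frame with integer columns `query` and `subject`.
#' @export
find_interval_overlaps <- function(query, subject) {
  qc <- normalize_chrom(query$chrom)
  sc <- normalize_chrom(subject$chrom)
  out <- list()
  for (ch in unique(qc)) {
    qi <- which(qc == ch)
    si <- which(sc == ch)
    if (length(si) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(query$start[qi], query$end[qi]),
      IRanges::IRanges(subject$start[si], subject$end[si]))
    if (length(hits) == 0) next
    out[[ch]] <- data.frame(query = qi[S4Vectors::queryHits(hits)],
                            subject = si[S4Vectors::subjectHits(hits)])
  }
  if (length(out) == 0) {
    return(data.frame(query = integer(0), subject = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reciprocal overlap test for two intervals
#'
#' Two intervals overlap reciprocally at fraction `f` when their intersection
#' covers at least `f` of each interval's span. Used to decide whether two
#' samples carry "the same" CNV.
#'
#' @param s1,e1,s2,e2 interval coordinates (same chromosome assumed).
#' @param frac required fraction (default 0.5).
#' @return logical.
#' @export
reciprocal_overlap <- function(s1, e1, s2, e2, frac = 0.5) {
  w <- overlap_width(s1, e1, s2, e2)
  w >= frac * interval_span(s1, e1) & w >= frac * interval_span(s2, e2)
}
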