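#' Read CNV calls in PennCNV-style text format
#'
#' Each line looks like
#' `chr3:2663757-2675189 numsnp=13 length=11,433 state2,cn=1 sampleA conf=15.1`
#' (whitespace separated; `length=` and any `startsnp=`/`endsnp=` fields are
#' ignored on input, coordinates are authoritative). Coordinates are 1-based
#' inclusive on disk and in memory.
#'
#' @param path file path.
#' @return data.frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `cn`, `n_snps`, `conf`.
#' @export
read_penncnv_calls <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_calls())
  parse_one <- function(i) {
    ln <- lines[i]
    fields <- strsplit(trimws(ln), "\\s+")[[1]]
    m <- regmatches(fields[1],
                    regexec("^(chr)?([0-9XY]+):([0-9,]+)-([0-9,]+)$", fields[1]))[[1]]
    if (length(m) == 0) {
      stop(sprintf("line %d: cannot parse coordinates from '%s'", i, fields[1]))
    }
    grab <- function(key) {
      hit <- grep(paste0("^", key, "="), fields, value = TRUE)
      if (length(hit) == 0) return(NA_character_)
      sub(paste0("^", key, "="), "", hit[1])
    }
    cn_field <- grep("cn=", fields, value = TRUE)
    if (length(cn_field) == 0) {
      stop(sprintf("line %d: missing cn= field", i))
    }
    cn <- as.integer(sub(".*cn=([0-9]+).*", "\\1", cn_field[1]))
    keyed <- grepl("=", fields) | grepl("^chr|:", fields)
    sample_field <- fields[!keyed]
    if (length(sample_field) == 0) {
      stop(sprintf("line %d: missing sample identifier", i))
    }
    data.frame(
      sample_id = sample_field[1],
      chrom = m[3],
      start = as.integer(gsub(",", "", m[4])),
      end = as.integer(gsub(",", "", m[5])),
      cn = cn,
      n_snps = as.integer(grab("numsnp")),
      conf = as.numeric(grab("conf")),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(lines), parse_one))
  rownames(out) <- NULL
  out
}

#' Write CNV calls in PennCNV-style text format
#'
#' @param calls data.frame as returned by [read_penncnv_calls()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_penncnv_calls <- function(calls, path) {
  lines <- sprintf("chr%s:%d-%d numsnp=%d length=%d state%d,cn=%d %s conf=%s",
                   calls$chrom, calls$start, calls$end, calls$n_snps,
                   calls$end - calls$start + 1L,
                   pmin(calls$cn + 1L, 6L), calls$cn, calls$sample_id,
                   format(calls$conf, trim = TRUE, digits = 10))
  writeLines(lines, path)
  invisible(path)
}

empty_calls <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), cn = integer(0),
             n_snps = integer(0), conf = numeric(0), stringsAsFactors = FALSE)
}

#' Read a BED file as 1-based inclusive intervals
#'
#' BED is 0-based half-open on disk; in memory the package uses 1-based
#' inclusive coordinates, so `start` becomes `start + 1`. Column 4 (name) and
#' column 5 (score) are kept when present.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score")[1:max(3, count_bed_cols(path))],
                          fill = TRUE)
  if (any(df$end <= df$start)) {
    stop("BED intervals must satisfy end > start (0-based half-open)")
  }
  df$chrom <- normalize_chrom(df$chrom)
  df$start <- as.integer(df$start + 1L)
  df$end <- as.integer(df$end)
  df
}

count_bed_cols <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) return(3L)
  length(strsplit(first, "\t")[[1]])
}

#' Write 1-based inclusive intervals as BED
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optional
#'   `name`, `score` columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- list(paste0(intervals$chrom), intervals$start - 1L, intervals$end)
  if (!is.null(intervals$name)) {
    cols <- c(cols, list(intervals$name))
    if (!is.null(intervals$score)) cols <- c(cols, list(intervals$score))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT-like gene-set file
#'
#' Tab-separated lines: set name, description, then member gene symbols.
#'
#' @param path file path.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) < 3) character(0) else unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(ln) strsplit(ln, "\t")[[1]][1], "")
  sets
}

#' Write a table with an audit-trail header
#'
#' Writes a TSV preceded by `#`-prefixed comment lines naming the parameter
#' values used to produce it, so every output records its own thresholds.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params named list of parameter values recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv_audited <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(params) > 0) {
    writeLines(sprintf("# %s=%s", names(params),
                       vapply(params, function(x) paste(format(x, digits = 10),
                                                        collapse = ","), "")),
               con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_audited()]
#'
#' @param path file path.
#' @return data.frame (header comment lines skipped).
#' @export
read_tsv_audited <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
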