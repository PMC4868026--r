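#' Filter CNV calls by confidence, span, probe count and exclusion overlap
#'
#' A call is retained iff confidence >= `min_conf`, inclusive span
#' (`end - start + 1`) >= `min_span_bp`, probe count >= `min_snps`, and the
#' fraction of its span covered by the union of exclusion regions (Ig
#' regions, pseudo-autosomal regions, centromeres, large gaps) is strictly
#' below `max_excl_frac`. All thresholds on the call's own measures are
#' inclusive; the exclusion-overlap rule is strict.
#'
#' @param calls calls data.frame (`sample_id`, `chrom`, `start`, `end`, `cn`,
#'   `n_snps`, `conf`).
#' @param exclusion_regions data.frame of intervals, or NULL for none.
#' @param min_conf,min_span_bp,min_snps,max_excl_frac thresholds.
#' @return the retained subset of `calls`.
#' @export
filter_calls <- function(calls, exclusion_regions = NULL, min_conf = 10,
                         min_span_bp = 20000, min_snps = 10,
                         max_excl_frac = 0.5) {
  if (nrow(calls) == 0) return(calls)
  keep <- calls$conf >= min_conf &
    interval_span(calls$start, calls$end) >= min_span_bp &
    calls$n_snps >= min_snps
  if (!is.null(exclusion_regions) && nrow(exclusion_regions) > 0) {
    idx <- which(keep)
    if (length(idx) > 0) {
      frac <- vapply(idx, function(i) {
        covered_fraction(calls$chrom[i], calls$start[i], calls$end[i],
                         exclusion_regions)
      }, numeric(1))
      keep[idx] <- frac < max_excl_frac
    }
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Join adjacent same-state CNV calls
#'
#' Within each (sample, chromosome, copy number) group, two consecutive calls
#' A (left) and B (right) are merged into `[A.start, B.end]` when the gap
#' between them is at most `max_gap_frac` of the total length of the region
#' they would cover: `gap / (B.end - A.start + 1) <= max_gap_frac`, with
#' `gap = B.start - A.end - 1` (overlapping calls always merge). Applied
#' left-to-right until a fixed point. The merged call's probe count is the
#' sum and its confidence the maximum of the members.
#'
#' @param calls calls data.frame.
#' @param max_gap_frac gap fraction threshold (inclusive).
#' @return calls data.frame with joined records.
#' @export
join_adjacent_calls <- function(calls, max_gap_frac = 0.2) {
  if (nrow(calls) <= 1) return(calls)
  key <- paste(calls$sample_id, calls$chrom, calls$cn, sep = "\r")
  pieces <- lapply(split(calls, key), function(df) {
    df <- df[order(df$start, df$end), , drop = FALSE]
    repeat {
      if (nrow(df) <= 1) break
      merged_any <- FALSE
      i <- 1
      while (i < nrow(df)) {
        a <- df[i, ]
        b <- df[i + 1, ]
        gap <- b$start - a$end - 1
        total <- max(a$end, b$end) - a$start + 1
        if (gap <= 0 || gap / total <= max_gap_frac) {
          df$end[i] <- max(a$end, b$end)
          df$n_snps[i] <- a$n_snps + b$n_snps
          df$conf[i] <- max(a$conf, b$conf)
          if ("is_causal" %in% names(df)) {
            df$is_causal[i] <- a$is_causal || b$is_causal
          }
          df <- df[-(i + 1), , drop = FALSE]
          merged_any <- TRUE
        } else {
          i <- i + 1
        }
      }
      if (!merged_any) break
    }
    df
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$sample_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter whole samples on call count and LRR noise
#'
#' A sample is dropped (with all its calls) iff it has strictly more than
#' `max_autosomal_calls` autosomal calls or an LRR standard deviation
#' strictly above `max_lrr_sd`. X-chromosome calls do not count toward the
#' call-count rule.
#'
#' @param calls calls data.frame.
#' @param lrr_sd named numeric of per-sample LRR SDs (names = sample ids).
#' @param max_autosomal_calls,max_lrr_sd thresholds (strict).
#' @return list with `samples_kept` (character), `samples_dropped`, and
#'   `calls` (calls of kept samples).
#' @export
filter_samples <- function(calls, lrr_sd, max_autosomal_calls = 100,
                           max_lrr_sd = 0.35) {
  sids <- unique(calls$sample_id)
  missing <- setdiff(sids, names(lrr_sd))
  if (length(missing) > 0) {
    stop("missing LRR SD for samples with calls: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  autosomal <- normalize_chrom(calls$chrom) != "X"
  n_auto <- table(factor(calls$sample_id[autosomal], levels = sids))
  drop <- union(sids[as.vector(n_auto) > max_autosomal_calls],
                names(lrr_sd)[lrr_sd > max_lrr_sd])
  keep_all <- setdiff(names(lrr_sd), drop)
  out <- calls[!calls$sample_id %in% drop, , drop = FALSE]
  rownames(out) <- NULL
  list(samples_kept = keep_all, samples_dropped = drop, calls = out)
}

#' Annotate calls to genes and exons
#'
#' A call is annotated to every gene whose span, extended by `flank_bp` on
#' both sides (to include nearby regulatory territory), intersects the call.
#' `exonic` is TRUE iff any exon interval intersects the call (no flank).
#'
#' @param calls calls data.frame.
#' @param genes gene models (`gene`, `chrom`, `start`, `end`).
#' @param exons exon intervals (`gene`, `chrom`, `start`, `end`).
#' @param flank_bp gene flank in bp (default 50 kb).
#' @return `calls` with added columns `genes` (comma-separated symbols, ""
#'   when none) and `exonic` (logical).
#' @export
annotate_genes <- function(calls, genes, exons = NULL, flank_bp = 50000) {
  calls$genes <- ""
  calls$exonic <- FALSE
  if (nrow(calls) == 0 || nrow(genes) == 0) return(calls)
  flanked <- genes
  flanked$start <- pmax(1L, genes$start - as.integer(flank_bp))
  flanked$end <- genes$end + as.integer(flank_bp)
  hits <- find_interval_overlaps(calls, flanked)
  if (nrow(hits) > 0) {
    gl <- split(genes$gene[hits$subject], hits$query)
    calls$genes[as.integer(names(gl))] <-
      vapply(gl, function(g) paste(sort(unique(g)), collapse = ","), "")
  }
  if (!is.null(exons) && nrow(exons) > 0) {
    ehits <- find_interval_overlaps(calls, exons)
    calls$exonic[unique(ehits$query)] <- TRUE
  }
  calls
}

#' Classify call rarity against a reference CNV event set
#'
#' For each call, reference events whose intersection with the call covers at
#' least `min_cover_frac` of the call's span are counted as substantial
#' overlaps; the call is rare iff the count is strictly below `max_common`.
#' The fraction is anchored on the call (not reciprocal).
#'
#' @param calls calls data.frame.
#' @param reference_cnvs data.frame of reference events (one row per event).
#' @param min_cover_frac required covered fraction of the call (default 0.5).
#' @param max_common events needed to be "common" (default 5: >= 5 common,
#'   < 5 rare).
#' @return `calls` with added columns `ref_overlaps` (count) and `rare`.
#' @export
classify_rarity <- function(calls, reference_cnvs, min_cover_frac = 0.5,
                            max_common = 5) {
  calls$ref_overlaps <- 0L
  if (nrow(calls) > 0 && !is.null(reference_cnvs) &&
      nrow(reference_cnvs) > 0) {
    hits <- find_interval_overlaps(calls, reference_cnvs)
    if (nrow(hits) > 0) {
      w <- overlap_width(calls$start[hits$query], calls$end[hits$query],
                         reference_cnvs$start[hits$subject],
                         reference_cnvs$end[hits$subject])
      span <- interval_span(calls$start[hits$query], calls$end[hits$query])
      qual <- hits$query[w >= min_cover_frac * span]
      if (length(qual) > 0) {
        tab <- table(qual)
        calls$ref_overlaps[as.integer(names(tab))] <- as.integer(tab)
      }
    }
  }
  calls$rare <- calls$ref_overlaps < max_common
  calls
}

#' Run the complete call-level and sample-level QC chain
#'
#' filter -> join -> sample QC -> gene/exon annotation -> rarity, in that
#' order, returning the final annotated call set plus per-stage counts for
#' the audit log.
#'
#' @param calls raw calls.
#' @param genome list with `genes`, `exons`, `exclusion_regions`,
#'   `reference_cnvs` (see [generate_genome()]).
#' @param lrr_sd per-sample LRR SD named vector.
#' @param thresholds named list overriding any of the QC defaults
#'   (`min_conf`, `min_span_bp`, `min_snps`, `max_excl_frac`, `max_gap_frac`,
#'   `max_autosomal_calls`, `max_lrr_sd`, `flank_bp`, `rare_max_common`).
#' @return list with `calls` (annotated, QC-passing), `samples_kept`,
#'   `counts` (named integer vector of per-stage call counts).
#' @export
qc_pipeline <- function(calls, genome, lrr_sd, thresholds = list()) {
  th <- utils::modifyList(list(min_conf = 10, min_span_bp = 20000,
                               min_snps = 10, max_excl_frac = 0.5,
                               max_gap_frac = 0.2, max_autosomal_calls = 100,
                               max_lrr_sd = 0.35, flank_bp = 50000,
                               rare_max_common = 5), thresholds)
  counts <- c(input = nrow(calls))
  f <- filter_calls(calls, genome$exclusion_regions, th$min_conf,
                    th$min_span_bp, th$min_snps, th$max_excl_frac)
  counts["after_call_filter"] <- nrow(f)
  j <- join_adjacent_calls(f, th$max_gap_frac)
  counts["after_join"] <- nrow(j)
  s <- filter_samples(j, lrr_sd, th$max_autosomal_calls, th$max_lrr_sd)
  counts["after_sample_filter"] <- nrow(s$calls)
  a <- annotate_genes(s$calls, genome$genes, genome$exons, th$flank_bp)
  a <- classify_rarity(a, genome$reference_cnvs, 0.5, th$rare_max_common)
  counts["annotated_to_genes"] <- sum(a$genes != "")
  counts["exonic"] <- sum(a$exonic)
  counts["rare"] <- sum(a$rare)
  list(calls = a, samples_kept = s$samples_kept, counts = counts,
       thresholds = th)
}
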