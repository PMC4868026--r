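#' Large CNVs in case samples
#'
#' Calls of case-labeled samples with inclusive span strictly greater than
#' `min_kb`, reported with their annotation and the carrier's composite
#' phenotype scores.
#'
#' @param calls annotated calls.
#' @param pheno phenotype table with `sample_id`, `PC1`, `IQadjPC1`,
#'   `IBGdiscr`, `label`.
#' @param samples samples table (`sample_id`, `family_id`).
#' @param min_kb span threshold in kb (strict >; default 500).
#' @return report data.frame (one row per qualifying call).
#' @export
find_large_case_cnvs <- function(calls, pheno, samples, min_kb = 500) {
  lab <- pheno$label[match(calls$sample_id, pheno$sample_id)]
  span <- interval_span(calls$start, calls$end)
  keep <- !is.na(lab) & lab == "case" & span > min_kb * 1000
  sub <- calls[keep, , drop = FALSE]
  report_calls(sub, pheno, samples)
}

report_calls <- function(sub, pheno, samples) {
  m <- match(sub$sample_id, pheno$sample_id)
  freq <- if (is.null(sub$rare)) rep(NA_character_, nrow(sub)) else
    ifelse(sub$rare, "Rare", "Common")
  out <- data.frame(
    sample_id = sub$sample_id,
    family_id = samples$family_id[match(sub$sample_id, samples$sample_id)],
    chrom = sub$chrom, start = sub$start, end = sub$end,
    n_snps = sub$n_snps, length_kb = call_span_kb(sub$start, sub$end),
    cn = sub$cn,
    frequency = freq,
    genes = if (is.null(sub$genes)) rep("", nrow(sub)) else sub$genes,
    PC1 = pheno$PC1[m], IQadjPC1 = pheno$IQadjPC1[m],
    IBGdiscr = pheno$IBGdiscr[m],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# direction of a call relative to the carrier's baseline: "loss" or "gain"
call_direction <- function(calls, samples) {
  sex <- samples$sex[match(calls$sample_id, samples$sample_id)]
  base <- baseline_cn(calls$chrom, sex)
  ifelse(calls$cn < base, "loss", "gain")
}

# single-linkage clusters of calls under reciprocal overlap >= frac and
# equal direction; returns an integer cluster id per row of `calls`
cluster_calls <- function(calls, samples, frac = 0.5) {
  n <- nrow(calls)
  if (n == 0) return(integer(0))
  dir <- call_direction(calls, samples)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  hits <- find_interval_overlaps(calls, calls)
  hits <- hits[hits$query < hits$subject, , drop = FALSE]
  for (r in seq_len(nrow(hits))) {
    i <- hits$query[r]
    j <- hits$subject[r]
    if (dir[i] != dir[j]) next
    if (!reciprocal_overlap(calls$start[i], calls$end[i],
                            calls$start[j], calls$end[j], frac)) next
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  vapply(seq_len(n), find, integer(1))
}

#' CNVs shared by affected co-siblings and absent in unaffected participants
#'
#' Within every family with two or more cases, calls are clustered across
#' individuals by reciprocal overlap (>= `frac`) and same direction (loss vs
#' gain); clusters carried by at least two affected co-siblings of the
#' family are candidate co-segregating CNVs. A candidate is reported only if
#' no unaffected participant carries a matching call — in `scope = "cohort"`
#' (default, strict) "unaffected" means any non-case sample in the whole
#' dataset; in `scope = "family"` only unaffected members of that family are
#' checked.
#'
#' @param calls annotated calls.
#' @param pheno phenotype table with `label`.
#' @param samples samples table.
#' @param frac reciprocal overlap fraction (default 0.5).
#' @param scope "cohort" (strict) or "family".
#' @return report data.frame (one row per qualifying call, i.e. per carrier).
#' @export
find_shared_case_cnvs <- function(calls, pheno, samples, frac = 0.5,
                                  scope = c("cohort", "family")) {
  scope <- match.arg(scope)
  calls$.row <- seq_len(nrow(calls))
  lab <- pheno$label[match(samples$sample_id, pheno$sample_id)]
  case_ids <- samples$sample_id[!is.na(lab) & lab == "case"]
  fam_of <- stats::setNames(samples$family_id, samples$sample_id)
  multi_case_fams <- names(which(table(fam_of[case_ids]) >= 2))
  if (length(multi_case_fams) == 0) {
    return(report_calls(calls[0, , drop = FALSE], pheno, samples))
  }
  call_lab <- pheno$label[match(calls$sample_id, pheno$sample_id)]
  call_fam <- fam_of[calls$sample_id]
  unaffected_calls <- calls[is.na(call_lab) | call_lab != "case", ,
                            drop = FALSE]
  rows <- integer(0)
  for (f in multi_case_fams) {
    fam_case_calls <- calls[call_fam == f & !is.na(call_lab) &
                              call_lab == "case", , drop = FALSE]
    if (nrow(fam_case_calls) < 2) next
    cl <- cluster_calls(fam_case_calls, samples, frac)
    for (cid in unique(cl)) {
      members <- which(cl == cid)
      if (length(unique(fam_case_calls$sample_id[members])) < 2) next
      # absent in unaffected participants?
      checks <- if (scope == "cohort") {
        unaffected_calls
      } else {
        unaffected_calls[fam_of[unaffected_calls$sample_id] == f, ,
                         drop = FALSE]
      }
      hit <- FALSE
      dirs <- call_direction(fam_case_calls[members, , drop = FALSE], samples)
      if (nrow(checks) > 0) {
        cdirs <- call_direction(checks, samples)
        for (m in members) {
          same_chr <- checks$chrom == fam_case_calls$chrom[m] &
            cdirs == dirs[which(members == m)]
          if (any(same_chr & reciprocal_overlap(
            fam_case_calls$start[m], fam_case_calls$end[m],
            checks$start, checks$end, frac))) {
            hit <- TRUE
            break
          }
        }
      }
      if (!hit) {
        rows <- c(rows, fam_case_calls$.row[members])
      }
    }
  }
  calls$.row <- NULL
  report_calls(calls[rows, , drop = FALSE], pheno, samples)
}

#' CNV overlaps with candidate genes/regions, with co-segregation verdicts
#'
#' Every call intersecting a candidate interval is reported. Candidates
#' tagged as genes (`type == "gene"`, or all when no `type` column) are
#' extended by `flank_bp` before intersection, matching the gene annotation
#' convention. Per family, a co-segregation verdict is attached:
#' "co-segregates" when every carrier in the family is a case and at least
#' one case carries it, otherwise "no co-segregation".
#'
#' A default editable candidate list (reading/language candidate genes and
#' neuropsychiatric CNV hotspot regions, approximate hg19 spans) ships at
#' `system.file("extdata", "candidate_regions_hg19.tsv", package =
#' "cnvtrait")`; coordinates are data, not code — edit them to your build.
#'
#' @param calls annotated calls.
#' @param candidates data.frame with `name`, `chrom`, `start`, `end` and
#'   optional `type` ("gene" or "region").
#' @param pheno phenotype table with `label`.
#' @param samples samples table.
#' @param flank_bp gene flank (default 50 kb).
#' @return report data.frame with `candidate` and `verdict` columns added.
#' @export
candidate_overlap <- function(calls, candidates, pheno, samples,
                              flank_bp = 50000) {
  cand <- candidates
  is_gene <- if (is.null(cand$type)) rep(TRUE, nrow(cand)) else
    cand$type == "gene"
  cand$start <- ifelse(is_gene, pmax(1, cand$start - flank_bp), cand$start)
  cand$end <- ifelse(is_gene, cand$end + flank_bp, cand$end)
  hits <- find_interval_overlaps(calls, cand)
  if (nrow(hits) == 0) {
    out <- report_calls(calls[0, , drop = FALSE], pheno, samples)
    out$candidate <- character(0)
    out$verdict <- character(0)
    return(out)
  }
  sub <- calls[hits$query, , drop = FALSE]
  out <- report_calls(sub, pheno, samples)
  out$candidate <- candidates$name[hits$subject]
  lab <- pheno$label[match(sub$sample_id, pheno$sample_id)]
  verdict <- character(nrow(out))
  for (r in seq_len(nrow(out))) {
    fam <- out$family_id[r]
    carriers_here <- unique(sub$sample_id[out$family_id == fam &
                                            out$candidate == out$candidate[r]])
    carrier_lab <- pheno$label[match(carriers_here, pheno$sample_id)]
    verdict[r] <- if (length(carriers_here) > 0 &&
                      all(carrier_lab == "case", na.rm = FALSE) &&
                      !anyNA(carrier_lab)) {
      "co-segregates"
    } else {
      "no co-segregation"
    }
  }
  out$verdict <- verdict
  out
}
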