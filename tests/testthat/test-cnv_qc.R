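test_that("call filters apply inclusive thresholds and the strict
           exclusion-overlap rule", {
  # single-rule failure: confidence just under 10
  expect_equal(nrow(filter_calls(make_call(conf = 9.99, start = 1e5,
                                           end = 1.3e5, n_snps = 15))), 0)
  # boundary call retained: conf 10, span exactly 20,000 bp, 10 SNPs
  boundary <- make_call(conf = 10, start = 100000, end = 119999, n_snps = 10)
  expect_equal(nrow(filter_calls(boundary)), 1)
  # overlap fraction exactly 0.50 -> rejected (< 0.50 required)
  call <- make_call(start = 100001, end = 200000)   # span 100,000
  excl <- data.frame(chrom = "1", start = 150001, end = 250000)
  expect_equal(covered_fraction("1", call$start, call$end, excl), 0.5)
  expect_equal(nrow(filter_calls(call, excl)), 0)
  excl2 <- data.frame(chrom = "1", start = 150002, end = 250000)
  expect_equal(nrow(filter_calls(call, excl2)), 1)
})

test_that("retained calls equal a per-rule brute-force checker on random
           fixtures", {
  set.seed(77)
  n <- 200
  start <- sample.int(5e6, n)
  calls <- data.frame(
    sample_id = sample(sprintf("S%d", 1:20), n, replace = TRUE),
    chrom = sample(c("1", "2"), n, replace = TRUE),
    start = start, end = start + sample(c(5000, 19999, 20000, 50000), n,
                                        replace = TRUE) - 1L,
    cn = sample(c(1L, 3L), n, replace = TRUE),
    n_snps = sample(5:20, n, replace = TRUE),
    conf = runif(n, 5, 30), stringsAsFactors = FALSE)
  excl <- data.frame(chrom = sample(c("1", "2"), 10, replace = TRUE),
                     start = sample.int(5e6, 10))
  excl$end <- excl$start + sample.int(3e5, 10)
  got <- filter_calls(calls, excl)
  # independent per-rule checker
  keep <- logical(n)
  for (i in 1:n) {
    span <- calls$end[i] - calls$start[i] + 1
    ov <- 0
    sub <- excl[excl$chrom == calls$chrom[i], ]
    if (nrow(sub) > 0) {
      covered <- logical(span)
      for (j in seq_len(nrow(sub))) {
        lo <- max(calls$start[i], sub$start[j])
        hi <- min(calls$end[i], sub$end[j])
        if (lo <= hi) covered[(lo:hi) - calls$start[i] + 1] <- TRUE
      }
      ov <- sum(covered)
    }
    keep[i] <- calls$conf[i] >= 10 && span >= 20000 &&
      calls$n_snps[i] >= 10 && ov / span < 0.5
  }
  expect_identical(got, {
    x <- calls[keep, ]
    rownames(x) <- NULL
    x
  })
})

test_that("adjacent same-state calls join by the 20% gap rule, iteratively", {
  # worked example: gap 10,000 over total 100,001 -> ratio 0.0999.. joins
  two <- rbind(make_call(start = 100000, end = 150000),
               make_call(start = 160001, end = 200000))
  j <- join_adjacent_calls(two)
  expect_equal(nrow(j), 1)
  expect_equal(j$start, 100000L)
  expect_equal(j$end, 200000L)
  expect_equal(j$n_snps, 30L)
  # gap ratio exactly 0.20 -> joined (inclusive): gap 200 / total 1000
  pair <- rbind(make_call(start = 1, end = 799),
                make_call(start = 1000, end = 1000))
  jj <- join_adjacent_calls(pair)
  expect_equal(nrow(jj), 1)   # 200/1000 = 0.2 exactly, inclusive
  # just over: gap 201 / total 1000
  pair2 <- rbind(make_call(start = 1, end = 798),
                 make_call(start = 1000, end = 1000))
  expect_equal(nrow(join_adjacent_calls(pair2)), 2)
  # single call unchanged; different copy numbers never join
  one <- make_call()
  expect_identical(join_adjacent_calls(one), one)
  mixed <- rbind(make_call(start = 100, end = 200, cn = 1),
                 make_call(start = 150, end = 250, cn = 3))
  expect_equal(nrow(join_adjacent_calls(mixed)), 2)
  # overlapping same-state calls merge unconditionally
  overl <- rbind(make_call(start = 100, end = 2000),
                 make_call(start = 150, end = 5000))
  expect_equal(nrow(join_adjacent_calls(overl)), 1)
})

test_that("joining is idempotent and leaves no joinable pair", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 15
    start <- sort(sample.int(1e6, n))
    calls <- data.frame(sample_id = "S1", chrom = "1", start = start,
                        end = start + sample.int(30000, n),
                        cn = sample(c(1L, 3L), n, replace = TRUE),
                        n_snps = sample(10:20, n, replace = TRUE),
                        conf = runif(n, 10, 30), stringsAsFactors = FALSE)
    j1 <- join_adjacent_calls(calls)
    expect_identical(join_adjacent_calls(j1), j1)
    for (cn in unique(j1$cn)) {
      sub <- j1[j1$cn == cn, ]
      sub <- sub[order(sub$start), ]
      if (nrow(sub) > 1) {
        gap <- sub$start[-1] - sub$end[-nrow(sub)] - 1
        total <- sub$end[-1] - sub$start[-nrow(sub)] + 1
        expect_true(all(gap / total > 0.2))
      }
    }
  }
})

test_that("sample QC drops on strict call-count and LRR-SD thresholds,
           counting autosomal calls only", {
  calls <- do.call(rbind, c(
    lapply(1:100, function(i) make_call("A", "1", i * 1e4, i * 1e4 + 100)),
    lapply(1:101, function(i) make_call("B", "2", i * 1e4, i * 1e4 + 100)),
    lapply(1:5, function(i) make_call("C", "1", i * 1e4, i * 1e4 + 100)),
    lapply(1:200, function(i) make_call("C", "X", i * 1e4, i * 1e4 + 100))))
  lrr_sd <- c(A = 0.35, B = 0.1, C = 0.2, D = 0.36)
  res <- filter_samples(calls, lrr_sd)
  # A: exactly 100 autosomal and SD exactly 0.35 -> kept (strict >)
  expect_true("A" %in% res$samples_kept)
  # B: 101 autosomal -> dropped
  expect_true("B" %in% res$samples_dropped)
  # C: 5 autosomal + 200 X -> kept
  expect_true("C" %in% res$samples_kept)
  # D: no calls but SD 0.36 -> dropped from the sample list
  expect_true("D" %in% res$samples_dropped)
  expect_true(all(res$calls$sample_id != "B"))
  expect_error(filter_samples(make_call("Z"), lrr_sd), "missing LRR SD")
})

test_that("gene annotation uses the 50-kb flank and exact exon overlap", {
  genes <- data.frame(gene = "G1", chrom = "1", start = 500000L,
                      end = 600000L, stringsAsFactors = FALSE)
  exons <- data.frame(gene = "G1", chrom = "1", start = c(500000L, 590000L),
                      end = c(500500L, 590500L), stringsAsFactors = FALSE)
  # call 10 kb upstream -> annotated
  near <- annotate_genes(make_call(start = 480000, end = 490001), genes,
                         exons)
  expect_equal(near$genes, "G1")
  expect_false(near$exonic)
  # call ending 50,001 bp before the gene -> not annotated
  far <- annotate_genes(make_call(start = 400000, end = 449999), genes, exons)
  expect_equal(far$genes, "")
  # boundary: exactly 50 kb away -> annotated
  at <- annotate_genes(make_call(start = 400000, end = 450000), genes, exons)
  expect_equal(at$genes, "G1")
  # intron-only call: genes nonempty, exonic FALSE (exon-scan oracle)
  intron <- annotate_genes(make_call(start = 501000, end = 589000), genes,
                           exons)
  expect_equal(intron$genes, "G1")
  expect_false(intron$exonic)
  ex <- annotate_genes(make_call(start = 501000, end = 590200), genes, exons)
  expect_true(ex$exonic)
})

test_that("rarity counts reference events covering >= 50% of the call", {
  call <- make_call(start = 100001, end = 200000)   # span 100,000
  # zero overlaps -> rare
  expect_true(classify_rarity(call, NULL)$rare)
  # exactly 5 qualifying events -> common
  five <- data.frame(chrom = "1", start = rep(100001L, 5),
                     end = rep(200000L, 5))
  r5 <- classify_rarity(call, five)
  expect_equal(r5$ref_overlaps, 5)
  expect_false(r5$rare)
  # six events each covering only 40% -> rare (none qualifies)
  six40 <- data.frame(chrom = "1", start = rep(100001L, 6),
                      end = rep(100001L + 39999L, 6))
  r6 <- classify_rarity(call, six40)
  expect_equal(r6$ref_overlaps, 0)
  expect_true(r6$rare)
  # annotation/classification are pure and order-independent
  calls <- rbind(call, make_call(start = 300000, end = 360000))
  a <- classify_rarity(calls, five)
  b <- classify_rarity(calls[2:1, ], five)
  expect_equal(a$rare, rev(b$rare))
})
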