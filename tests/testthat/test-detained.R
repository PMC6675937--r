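test_that("effective lengths and weights follow the alignability formula", {
  introns <- data.frame(gene_id = "g", chrom = "c",
                        start = c(0L, 2000L), end = c(1000L, 2700L))
  ef <- effective_lengths(introns, read_len = 50L,
                          mask = c(30L, 0L))
  expect_equal(ef$L_eff[1L], 1000L)    # 1000 + 50 - 20 - 30
  expect_equal(ef$L_eff[2L], 730L)
  expect_equal(ef$weight, c(1000, 730) / 1730)
  # weight-0 exclusion when the mask swallows the intron
  ef2 <- effective_lengths(data.frame(gene_id = "g", chrom = "c",
                                      start = 0L, end = 100L),
                           read_len = 50L, mask = 200L)
  expect_true(ef2$excluded)
  expect_equal(ef2$weight, 0)
  # interval mask is counted as masked positions inside the intron
  mask_iv <- data.frame(chrom = "c", start = c(10L, 2600L),
                        end = c(40L, 2900L))
  ef3 <- effective_lengths(introns, 50L, mask_iv)
  expect_equal(ef3$M, c(30L, 100L))
})

test_that("weights keep their ordering under uniform mask inflation", {
  introns <- data.frame(gene_id = "g", chrom = "c",
                        start = c(0L, 2000L, 5000L),
                        end = c(1500L, 2700L, 5400L))
  w0 <- effective_lengths(introns, 50L, c(0L, 0L, 0L))$weight
  w1 <- effective_lengths(introns, 50L, c(100L, 100L, 100L))$weight
  expect_identical(order(w0), order(w1))
})

test_that("median-of-ratios size factors match the textbook oracle and DESeq2", {
  m <- matrix(rpois(300, 50) + 1, ncol = 3)
  expect_equal(size_factors(cbind(m[, 1], m[, 1])), c(1, 1))
  expect_equal(size_factors(cbind(m[, 1], 2 * m[, 1]))[2] /
                 size_factors(cbind(m[, 1], 2 * m[, 1]))[1], 2)
  # textbook oracle
  set.seed(131)
  cnt <- matrix(rnbinom(900, mu = 100, size = 10), ncol = 3)
  ref <- exp(rowMeans(log(cnt)))
  ok <- is.finite(log(ref)) & ref > 0
  want <- apply(cnt, 2, function(x) exp(median(log(x / ref)[ok])))
  expect_equal(size_factors(cnt), want, tolerance = 1e-12)
  # cross-check against DESeq2's estimator
  skip_if_not_installed("DESeq2")
  expect_equal(unname(size_factors(cnt)),
               unname(DESeq2::estimateSizeFactorsForMatrix(cnt)),
               tolerance = 1e-8)
  expect_error(size_factors(cnt[, 1, drop = FALSE]), "2 replicates")
})

test_that("null replicates redistribute gene totals by weight, conserving sums", {
  C <- matrix(c(60, 40, 80, 20), nrow = 2)   # 2 introns x 2 reps
  N <- null_replicates(C, weights = c(0.3, 0.7), gene_id = c("g", "g"))
  expect_equal(N[, 1L], c(30, 70))
  expect_equal(N[, 2L], c(30, 70))
  # single-intron gene: null equals observed
  N1 <- null_replicates(matrix(c(5, 9), 1), 1, "g")
  expect_equal(as.numeric(N1), c(5, 9))
  expect_error(null_replicates(C, c(0.3, 0.7), "g"), "align")
  # random matrices: per-gene per-replicate conservation to machine precision
  set.seed(137)
  for (rep in 1:10) {
    ng <- 8L; npg <- sample(2:6, ng, replace = TRUE)
    gid <- rep(sprintf("g%d", seq_len(ng)), npg)
    C <- matrix(rnbinom(length(gid) * 3L, mu = 50, size = 5), ncol = 3L)
    lens <- runif(length(gid), 100, 5000)
    w <- unlist(lapply(split(lens, gid)[unique(gid)], function(x) x / sum(x)))
    N <- null_replicates(C, w, gid)
    for (g in unique(gid)) {
      expect_equal(colSums(N[gid == g, , drop = FALSE]),
                   colSums(C[gid == g, , drop = FALSE]), tolerance = 1e-12)
    }
  }
})

test_that("detained-intron calling separates planted signal from the null", {
  # observed == null -> nothing called
  set.seed(139)
  C <- matrix(rnbinom(3000, mu = 80, size = 20), ncol = 3)
  res0 <- call_detained(C, C)
  expect_false(any(res0$detained))
  # a clear 8x intron is called; a 3.5x intron fails the fold filter
  null <- matrix(rep(c(100, 100, 100), each = 50), ncol = 3)
  obs <- null
  obs[1L, ] <- 800
  obs[2L, ] <- 350
  res <- call_detained(obs + matrix(rpois(150, 3), ncol = 3), null)
  expect_true(res$detained[1L])
  expect_false(res$detained[2L])   # q can be small but fold < 4
  expect_lt(res$qvalue[2L], 0.01)
})

test_that("increasing observed counts never removes a detained call", {
  set.seed(149)
  null <- matrix(rep(rnbinom(100, mu = 100, size = 10), 3), ncol = 3)
  obs <- null
  obs[5L, ] <- null[5L, ] * 10
  r1 <- call_detained(obs, null)
  obs2 <- obs
  obs2[5L, ] <- obs[5L, ] * 2
  r2 <- call_detained(obs2, null)
  expect_true(r1$detained[5L])
  expect_true(r2$detained[5L])
  expect_lte(r2$qvalue[5L], r1$qvalue[5L] + 1e-12)
})

test_that("intronic read counting enforces overlap and multimapper rules", {
  chunks <- data.frame(chunk_id = c("i1", "i2"), chrom = "chr1",
                       start = c(1000L, 3000L), end = c(2000L, 3500L))
  recs <- rbind(
    data.frame(qname = "ok10", chrom = "chr1", strand = "+", pos0 = 990L,
               cigar = "20M", nh = 1L),   # exactly 10 nt inside i1
    data.frame(qname = "no9", chrom = "chr1", strand = "+", pos0 = 989L,
               cigar = "20M", nh = 1L),   # only 9 nt inside
    data.frame(qname = "multi", chrom = "chr1", strand = "+", pos0 = 1200L,
               cigar = "20M", nh = 3L),   # multimapper
    data.frame(qname = "spliced", chrom = "chr1", strand = "+", pos0 = 1980L,
               cigar = "20M980N20M", nh = 1L))  # 20 nt in i1, gap over rest
  sam <- write_sam(recs, tempfile(fileext = ".sam"))
  cnt <- count_intronic_reads(read_alignments(sam), chunks)
  expect_equal(unname(cnt["i1"]), 2L)    # ok10 + spliced
  expect_equal(unname(cnt["i2"]), 0L)    # gap skips i2... spliced lands at 3000
})

test_that("binding-density bins are thirds of the density range", {
  chunks <- data.frame(chunk_id = c("a", "b", "c", "d", "tiny"),
                       start = c(0L, 0L, 0L, 0L, 0L),
                       end = c(1024L, 1024L, 1024L, 1024L, 5L))
  tags <- c(1024, 64, 4096, 0, 100)
  expect_message(db <- density_bins(chunks, tags), "Low bin")
  expect_false("tiny" %in% db$chunk_id)          # < 10 bp excluded
  expect_equal(db$density[db$chunk_id == "a"], 0)
  expect_identical(db$bin[db$chunk_id == "b"], "Low")
  expect_identical(db$bin[db$chunk_id == "c"], "High")
  expect_identical(db$bin[db$chunk_id == "d"], "Low")   # zero tags
  # equal densities: single deterministic bin
  db2 <- density_bins(chunks[1:3, ], c(100, 100, 100))
  expect_true(all(db2$bin == "Low"))
  # random chunks against a direct binning oracle
  set.seed(151)
  n <- 50L
  ch <- data.frame(chunk_id = sprintf("c%d", 1:n), start = 0L,
                   end = sample(10:2000, n))
  tg <- rpois(n, 200) + 1
  db3 <- density_bins(ch, tg)
  d <- log2(tg / (ch$end - ch$start))
  edges <- min(d) + diff(range(d)) * c(1, 2) / 3
  want <- ifelse(d <= edges[1], "Low", ifelse(d <= edges[2], "Medium", "High"))
  expect_identical(db3$bin, want)
})
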