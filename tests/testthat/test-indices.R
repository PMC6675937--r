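test_that("splicing index arithmetic and error paths", {
  expect_equal(splicing_index(data.frame(S = 8, EI = 2, IE = 2)), 2.0)
  # balance point: sum(S) = sum(EI+IE)/2
  expect_equal(splicing_index(data.frame(S = 2, EI = 2, IE = 2)), 0.0)
  expect_error(splicing_index(data.frame(S = 5, EI = 0, IE = 0)), "undefined")
  expect_warning(si <- splicing_index(data.frame(S = 0, EI = 1, IE = 1)),
                 "-Inf")
  expect_identical(si, -Inf)
  # first-junction restriction
  jc <- data.frame(S = c(8, 100), EI = c(2, 1), IE = c(2, 1),
                   rank = c("first", "internal"))
  expect_equal(splicing_index(jc, "first_only"), 2.0)
  expect_length(splicing_index(jc, per_junction = TRUE), 2L)
})

test_that("SI is monotone in the read classes", {
  base <- data.frame(S = 10, EI = 4, IE = 3)
  s0 <- splicing_index(base)
  expect_gt(splicing_index(transform(base, S = S + 5)), s0)
  expect_lt(splicing_index(transform(base, EI = EI + 5)), s0)
})

test_that("junction ranks follow the transcript strand", {
  m <- gene_models(data.frame(
    gene_id = "g", transcript_id = "t", chrom = "c", strand = "-",
    start = c(0L, 200L, 400L, 600L), end = c(100L, 300L, 500L, 700L)))
  j <- transcript_junctions(m)
  # minus strand: the first junction is the highest-coordinate intron
  expect_identical(j$rank[j$start == 500L], "first")
  expect_identical(j$rank[j$start == 100L], "last")
  expect_identical(j$rank[j$start == 300L], "internal")
})

test_that("junction reads are classified by splice coordinates and anchors", {
  m <- gene_models(data.frame(
    gene_id = "g", transcript_id = "t", chrom = "chr1", strand = "+",
    start = c(1000L, 2000L), end = c(1500L, 2500L)))
  j <- transcript_junctions(m)  # intron [1500,2000)
  recs <- rbind(
    # spliced at exact coordinates
    data.frame(qname = "s1", chrom = "chr1", strand = "+", pos0 = 1490L,
               cigar = "10M500N10M"),
    # spliced at wrong coordinates (gap ends 1 nt early)
    data.frame(qname = "s2", chrom = "chr1", strand = "+", pos0 = 1490L,
               cigar = "10M499N10M"),
    # exon-intron read, 10 nt each side
    data.frame(qname = "e1", chrom = "chr1", strand = "+", pos0 = 1490L,
               cigar = "20M"),
    # only 2 nt in the intron: fails the 3-nt anchor
    data.frame(qname = "e2", chrom = "chr1", strand = "+", pos0 = 1482L,
               cigar = "20M"),
    # intron-exon read
    data.frame(qname = "i1", chrom = "chr1", strand = "+", pos0 = 1990L,
               cigar = "20M"),
    # fully intronic
    data.frame(qname = "o1", chrom = "chr1", strand = "+", pos0 = 1600L,
               cigar = "20M"),
    # antisense read: ignored under same-strand counting
    data.frame(qname = "a1", chrom = "chr1", strand = "-", pos0 = 1600L,
               cigar = "20M"))
  sam <- write_sam(recs, tempfile(fileext = ".sam"))
  got <- classify_junction_reads(read_alignments(sam), j)
  expect_equal(got$S, 1L)
  expect_equal(got$EI, 1L)
  expect_equal(got$IE, 1L)
  expect_equal(got$other, 3L)   # s2, e2, o1
})

test_that("classification matches a per-read rule oracle on simulated reads", {
  cfg <- sim_config(seed = 11L, n_genes = 8L)
  ann <- simulate_annotation(cfg)
  sim <- simulate_junction_reads(cfg, ann, tempfile(fileext = ".sam"))
  aln <- read_alignments(sim$path)
  j <- transcript_junctions(ann$models)
  got <- classify_junction_reads(aln, j)
  expect_equal(sum(got$S), sim$truth$n[sim$truth$class == "S"])
  expect_equal(sum(got$EI), sim$truth$n[sim$truth$class == "EI"])
  expect_equal(sum(got$IE), sim$truth$n[sim$truth$class == "IE"])
  expect_equal(sum(got$other), sim$truth$n[sim$truth$class == "other"])
  # configured 2:1:1 S:EI:IE gives SI = log2(2*2/2) = 1
  expect_equal(splicing_index(got), 1.0)
})

test_that("terminal poly(A) site selection is strand-aware", {
  m <- gene_models(rbind(
    data.frame(gene_id = "gp", transcript_id = "tp", chrom = "c",
               strand = "+", start = 0L, end = 1000L),
    data.frame(gene_id = "gm", transcript_id = "tm", chrom = "c",
               strand = "-", start = 2000L, end = 3000L)))
  pa_sites <- data.frame(chrom = "c",
                         start = c(400L, 800L, 2100L, 2600L),
                         end = c(420L, 820L, 2120L, 2620L))
  sel <- select_terminal_pa(pa_sites, m)
  expect_equal(sel$pa_pos[sel$gene_id == "gp"], 820L)   # highest end
  expect_equal(sel$pa_pos[sel$gene_id == "gm"], 2100L)  # lowest start
  # no overlapping site: gene omitted
  far <- data.frame(chrom = "c", start = 5000L, end = 5020L)
  expect_message(sel2 <- select_terminal_pa(far, m), "omitted")
  expect_identical(nrow(sel2), 0L)
})

test_that("poly(A) windows split at the site and feed the processing index", {
  # plus strand gene, pa boundary at 500: upstream [450,500), downstream [500,550)
  pa <- data.frame(gene_id = "g", chrom = "c", strand = "+", pa_pos = 500L)
  tr <- clip_track(rep("c", 4L), c(450L, 499L, 500L, 549L), rep("+", 4L))
  cnt <- pa_window_counts(tr, pa)
  expect_equal(cnt$u, 2L)
  expect_equal(cnt$d, 2L)
  # minus strand: upstream is the high side including the boundary base
  pam <- data.frame(gene_id = "g", chrom = "c", strand = "-", pa_pos = 500L)
  trm <- clip_track(rep("c", 3L), c(500L, 549L, 499L), rep("-", 3L))
  cntm <- pa_window_counts(trm, pam)
  expect_equal(cntm$u, 2L)
  expect_equal(cntm$d, 1L)
})

test_that("processing index arithmetic, clamping and sentinels", {
  expect_equal(processing_index(data.frame(u = 10, d = 2)), -2.0)
  expect_equal(processing_index(data.frame(u = 12, d = 4)), -1.0)
  expect_warning(pi0 <- processing_index(data.frame(u = 10, d = 0)), "-Inf")
  expect_identical(pi0, -Inf)
  expect_error(processing_index(data.frame(u = 2, d = 2)), "undefined")
  # genes with d > u are clamped, not allowed to cancel signal
  expect_message(
    val <- processing_index(data.frame(u = c(10, 1), d = c(2, 5))),
    "clamped")
  expect_equal(val, log2(7 / 8))
})

test_that("uncleaved-only binding gives PI near 0; upstream-only strongly negative", {
  set.seed(23)
  # equal parts unprocessed (uniform across the site) and processed
  # (upstream only): u ~ 2d, so PI = log2(d/(u-d)) ~ 0
  pa <- data.frame(gene_id = sprintf("g%d", 1:40), chrom = "c",
                   strand = "+", pa_pos = seq(1000L, 40000L, 1000L))
  pos <- unlist(lapply(pa$pa_pos, function(b) {
    c(b - 50L + sample.int(100L, 30L, replace = TRUE) - 1L,  # unprocessed
      b - 50L + sample.int(50L, 15L, replace = TRUE) - 1L)   # processed
  }))
  tr <- clip_track(rep("c", length(pos)), pos, rep("+", length(pos)))
  cnt <- pa_window_counts(tr, pa)
  expect_lt(abs(processing_index(cnt)), 0.35)
  # all tags upstream: fully processed sentinel
  pos_up <- unlist(lapply(pa$pa_pos, function(b)
    b - 50L + sample.int(49L, 30L, replace = TRUE) - 1L))
  tru <- clip_track(rep("c", length(pos_up)), pos_up, rep("+", length(pos_up)))
  cu <- pa_window_counts(tru, pa)
  expect_warning(piu <- processing_index(cu), "-Inf")
  expect_identical(piu, -Inf)
})
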