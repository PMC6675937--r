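test_that("expressed-set filter keeps transcripts above threshold and drops MT genes", {
  exons <- rbind(
    data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
               strand = "+", start = 0L, end = 100L),
    data.frame(gene_id = "g1", transcript_id = "t2", chrom = "chr1",
               strand = "+", start = 0L, end = 100L),
    data.frame(gene_id = "gm", transcript_id = "tm", chrom = "MT",
               strand = "+", start = 0L, end = 100L)
  )
  m <- gene_models(exons)
  out <- filter_expressed(m, c(t1 = 5.0, t2 = 0.2, tm = 10))
  expect_identical(unique(out$exons$transcript_id), "t1")

  # TPM exactly at the threshold is not expressed (strict >)
  out2 <- filter_expressed(m, c(t1 = 1.0, t2 = 0, tm = 0))
  expect_identical(nrow(out2$exons), 0L)

  # all zero -> empty set
  expect_identical(nrow(filter_expressed(m, c(t1 = 0, t2 = 0, tm = 0))$exons), 0L)

  # missing entry names the transcript
  expect_error(filter_expressed(m, c(t1 = 5)), "t2")

  # multi-sample table is averaged
  tab <- data.frame(transcript_id = c("t1", "t2", "tm"),
                    s1 = c(0.5, 3, 0), s2 = c(2.0, 0, 0))
  out3 <- filter_expressed(m, tab)  # means 1.25, 1.5, 0
  expect_setequal(unique(out3$exons$transcript_id), c("t1", "t2"))
})

test_that("chunks tile the gene span with boundaries at every exon edge", {
  m1 <- gene_models(data.frame(
    gene_id = "g", transcript_id = "t", chrom = "c", strand = "+",
    start = c(0L, 200L), end = c(100L, 300L)))
  ch <- build_chunks(m1)
  expect_equal(ch$start, c(0L, 100L, 200L))
  expect_equal(ch$end, c(100L, 200L, 300L))

  # two isoforms with an extra boundary at 150
  m2 <- gene_models(rbind(
    data.frame(gene_id = "g", transcript_id = "a", chrom = "c", strand = "+",
               start = c(0L, 200L), end = c(100L, 300L)),
    data.frame(gene_id = "g", transcript_id = "b", chrom = "c", strand = "+",
               start = c(0L, 200L), end = c(150L, 300L))))
  ch2 <- build_chunks(m2)
  expect_equal(sort(unique(c(ch2$start, ch2$end))), c(0L, 100L, 150L, 200L, 300L))
  expect_identical(nrow(ch2), 4L)

  # identical isoforms give the single-isoform chunking
  m3 <- gene_models(rbind(
    data.frame(gene_id = "g", transcript_id = "a", chrom = "c", strand = "+",
               start = c(0L, 200L), end = c(100L, 300L)),
    data.frame(gene_id = "g", transcript_id = "b", chrom = "c", strand = "+",
               start = c(0L, 200L), end = c(100L, 300L))))
  expect_equal(build_chunks(m3)[, c("start", "end")], ch[, c("start", "end")])
})

test_that("chunk boundaries match a brute-force union oracle on random models", {
  set.seed(42)
  for (rep in 1:20) {
    m <- random_models()
    ch <- build_chunks(m)
    for (g in unique(m$exons$gene_id)) {
      e <- m$exons[m$exons$gene_id == g, ]
      cg <- ch[ch$gene_id == g, ]
      # oracle: all exon edges, sorted
      edges <- sort(unique(c(e$start, e$end)))
      expect_equal(sort(unique(c(cg$start, cg$end))), edges)
      # tiling: chunks abut exactly and cover the span
      o <- order(cg$start)
      expect_equal(cg$start[o][-1L], cg$end[o][-nrow(cg)])
      expect_equal(min(cg$start), min(e$start))
      expect_equal(max(cg$end), max(e$end))
      # reconstruction: every isoform's exons are unions of whole chunks
      for (t in unique(e$transcript_id)) {
        et <- e[e$transcript_id == t, ]
        for (k in seq_len(nrow(et))) {
          inside <- cg$start >= et$start[k] & cg$end <= et$end[k]
          expect_equal(min(cg$start[inside]), et$start[k])
          expect_equal(max(cg$end[inside]), et$end[k])
          expect_equal(sum(cg$end[inside] - cg$start[inside]),
                       et$end[k] - et$start[k])
        }
      }
    }
  }
})

test_that("chunk classification follows the expressed/reference overlap rules", {
  # t1 splices intron [100,200); t2 retains it
  ref <- toy_models()
  ch <- build_chunks(ref)
  # expressed set = only t1 -> [100,200) overlaps t1's intron but also t2's exon
  exp1 <- gene_models(ref$exons[ref$exons$transcript_id == "t1", ])
  cl <- classify_chunks(ch, ref, exp1)
  k <- cl$kind[cl$start == 100 & cl$end == 200]
  expect_identical(k, "ambiguous")
  # pure intron of every isoform: [300,400)
  expect_identical(cl$kind[cl$start == 300], "intron")
  # shared exon [0,100) is exonic
  expect_identical(cl$kind[cl$start == 0], "exon")
})

test_that("chunks overlapping two genes are removed", {
  exons <- rbind(
    data.frame(gene_id = "gA", transcript_id = "tA", chrom = "c",
               strand = "+", start = 0L, end = 300L),
    data.frame(gene_id = "gB", transcript_id = "tB", chrom = "c",
               strand = "+", start = 250L, end = 500L))
  m <- gene_models(exons)
  cl <- classify_chunks(build_chunks(m), m, m)
  # every surviving chunk overlaps at most one gene span
  expect_true(all(!(cl$start < 300 & cl$end > 250)))
})

test_that("exon position labels respect the transcript strand", {
  lab <- label_exon_positions(toy_models("-"))
  t1 <- lab[lab$transcript_id == "t1", ]
  expect_identical(t1$exon_position[which.max(t1$start)], "first")
  expect_identical(t1$exon_position[which.min(t1$start)], "last")

  lab5 <- label_exon_positions(gene_models(data.frame(
    gene_id = "g", transcript_id = "t", chrom = "c", strand = "+",
    start = seq(0L, 800L, 200L), end = seq(0L, 800L, 200L) + 100L)))
  expect_identical(sum(lab5$exon_position == "middle"), 3L)

  lab1 <- label_exon_positions(gene_models(data.frame(
    gene_id = "g", transcript_id = "t", chrom = "c", strand = "+",
    start = 0L, end = 100L)))
  expect_true(is.na(lab1$exon_position))
})

test_that("retained introns are found for the canonical isoform pair", {
  # A single-exon [0,500); B has intron [100,200)
  m <- gene_models(rbind(
    data.frame(gene_id = "g", transcript_id = "A", chrom = "c", strand = "+",
               start = 0L, end = 500L),
    data.frame(gene_id = "g", transcript_id = "B", chrom = "c", strand = "+",
               start = c(0L, 200L), end = c(100L, 500L))))
  ri <- find_retained_introns(m)
  expect_equal(ri[, c("start", "end")],
               data.frame(start = 100L, end = 200L))

  # disjoint intron sets (neither a subset): nothing reported
  m2 <- gene_models(rbind(
    data.frame(gene_id = "g", transcript_id = "A", chrom = "c", strand = "+",
               start = c(0L, 150L), end = c(100L, 500L)),
    data.frame(gene_id = "g", transcript_id = "B", chrom = "c", strand = "+",
               start = c(0L, 300L), end = c(200L, 500L))))
  expect_identical(nrow(find_retained_introns(m2)), 0L)

  # single isoform: empty
  expect_identical(nrow(find_retained_introns(gene_models(
    data.frame(gene_id = "g", transcript_id = "t", chrom = "c",
               strand = "+", start = 0L, end = 100L)))), 0L)
})

test_that("retained introns equal an exhaustive pairwise oracle on random genes", {
  # independent oracle: literal pairwise subset scan over intron string sets
  oracle_ri <- function(m) {
    intr <- transcript_introns(m)
    ex <- m$exons
    found <- character(0)
    for (g in unique(ex$gene_id)) {
      txs <- unique(ex$transcript_id[ex$gene_id == g])
      for (a in txs) for (b in txs) {
        if (a == b) next
        ia <- intr[intr$transcript_id == a, ]
        ib <- intr[intr$transcript_id == b, ]
        ka <- paste(ia$start, ia$end); kb <- paste(ib$start, ib$end)
        if (!all(ka %in% kb)) next
        ea <- ex[ex$transcript_id == a, ]
        lo <- min(ea$start); hi <- max(ea$end)
        for (j in seq_len(nrow(ib))) {
          kj <- paste(ib$start[j], ib$end[j])
          if (!(kj %in% ka) && ib$start[j] >= lo && ib$end[j] <= hi) {
            found <- c(found, paste(g, kj))
          }
        }
      }
    }
    sort(unique(found))
  }
  set.seed(7)
  for (rep in 1:20) {
    m <- random_models(n_genes = 4L, max_iso = 3L)
    got <- find_retained_introns(m)
    expect_identical(sort(paste(got$gene_id, got$start, got$end)), oracle_ri(m))
    # order of isoforms must not matter
    perm <- m$exons[sample(nrow(m$exons)), ]
    got2 <- find_retained_introns(gene_models(perm))
    expect_identical(sort(paste(got2$gene_id, got2$start, got2$end)),
                     oracle_ri(m))
  }
})

test_that("GTF round-trip preserves gene models and coordinates", {
  sim <- simulate_annotation(sim_config(seed = 3L, n_genes = 4L))
  path <- tempfile(fileext = ".gtf")
  write_gtf(sim$models, path)
  back <- read_gtf(path)
  a <- sim$models$exons[order(sim$models$exons$transcript_id,
                              sim$models$exons$start), ]
  b <- back$exons[order(back$exons$transcript_id, back$exons$start), ]
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
  expect_equal(a$transcript_id, b$transcript_id)
  expect_equal(a$strand, b$strand)
  expect_false(is.null(back$cds))
})

test_that("classify_chunks never labels an interval both exon and intron", {
  set.seed(11)
  for (rep in 1:10) {
    m <- random_models()
    cl <- classify_chunks(build_chunks(m), m, m)
    expect_true(all(table(cl$chunk_id) == 1L))
    expect_true(all(cl$kind %in% c("exon", "intron", "ambiguous")))
  }
})
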