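# Shared in-code fixtures: tiny gene models, random tracks and brute-force
# reference implementations used as independent oracles.

# a two-isoform gene: t1 three exons, t2 retains the first intron
toy_models <- function(strand = "+") {
  exons <- rbind(
    data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
               strand = strand, start = c(0L, 200L, 400L),
               end = c(100L, 300L, 500L)),
    data.frame(gene_id = "g1", transcript_id = "t2", chrom = "chr1",
               strand = strand, start = c(0L, 400L), end = c(300L, 500L))
  )
  gene_models(exons)
}

# random multi-isoform models on one chromosome for property tests
random_models <- function(n_genes = 5L, max_iso = 3L) {
  cursor <- 100L
  exons <- NULL
  for (g in seq_len(n_genes)) {
    ne <- sample(2:5, 1L)
    elen <- sample(20:80, ne, replace = TRUE)
    ilen <- sample(30:120, ne - 1L, replace = TRUE)
    starts <- cursor + cumsum(c(0L, elen[-ne] + ilen))
    ends <- starts + elen
    strand <- sample(c("+", "-"), 1L)
    gid <- paste0("rg", g)
    for (t in seq_len(sample(seq_len(max_iso), 1L))) {
      keep <- sort(sample(seq_len(ne), sample(2:ne, 1L)))
      # drop random exons so isoforms differ but share exon boundaries
      exons <- rbind(exons, data.frame(
        gene_id = gid, transcript_id = paste0(gid, ".t", t), chrom = "chrR",
        strand = strand, start = starts[keep], end = ends[keep]))
    }
    cursor <- max(ends) + 500L
  }
  gene_models(exons)
}

# random sparse track over [0, len) on both strands
random_track <- function(n = 50L, len = 1000L, chrom = "chr1") {
  clip_track(rep(chrom, n),
             sample.int(len, n, replace = TRUE) - 1L,
             sample(c("+", "-"), n, replace = TRUE))
}

# brute-force per-position tag counting over intervals
brute_count_tags <- function(track, intervals, same_strand = TRUE) {
  vapply(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    keep <- track$chrom == iv$chrom & track$pos >= iv$start &
      track$pos < iv$end
    if (same_strand) keep <- keep & track$strand == iv$strand
    as.integer(sum(track$count[keep]))
  }, integer(1L))
}

# brute-force windowed heights from a per-base count vector
brute_heights <- function(x, w = 15L) {
  L <- length(x)
  vapply(seq_len(L), function(i) {
    sum(x[max(1L, i - w):min(L, i + w)])
  }, numeric(1L))
}

# write a minimal SAM file from a record data.frame
write_sam <- function(records, path, chrom_len = 100000L) {
  chroms <- unique(records$chrom)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", chroms, chrom_len))
  flag <- ifelse(records$strand == "-", 16L, 0L)
  if (!is.null(records$flag_extra)) flag <- flag + records$flag_extra
  nh <- if (is.null(records$nh)) rep(1L, nrow(records)) else records$nh
  recs <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*\tNH:i:%d",
                  records$qname, flag, records$chrom, records$pos0 + 1L,
                  records$cigar, nh)
  writeLines(c(hdr, recs), path)
  path
}

# independent oracle: scan every position with substring comparison
brute_kmer_f <- function(seqs, tags, s, w = 15L) {
  total <- 0
  k <- nchar(s)
  for (i in seq_along(seqs)) {
    h <- brute_heights(tags[[i]], w)
    L <- nchar(seqs[i])
    if (L < k) next
    for (p in seq_len(L - k + 1L)) {
      if (substr(seqs[i], p, p + k - 1L) == s) total <- total + h[p]
    }
  }
  total
}
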