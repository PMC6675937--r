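# Synthetic-data generators.  Every pipeline stage has a generator that
# plants known structure (peaks at fixed junction offsets, retained-intron
# isoform pairs, detained introns at a controlled fold over the null,
# isoform-usage shifts) and returns the matching truth table, so recovery
# can be tested without external sequencing data.

#' Simulation configuration
#'
#' Collects all generator parameters with defaults emulating a compact
#' mammalian-like transcriptome at desk scale: exons around 150 nt, short
#' introns, Poisson background crosslinking with EJC-like peaks 24 nt
#' upstream of exon-exon junctions.
#'
#' @param seed integer RNG seed; all generators are deterministic given it.
#' @param n_genes number of genes for annotation-driven simulations.
#' @param n_exons_range integer range of exons per transcript.
#' @param exon_meanlog,exon_sdlog,min_exon,max_exon log-normal exon length
#'   parameters (nt) and clamps.
#' @param intron_meanlog,intron_sdlog,min_intron,max_intron same for
#'   introns.
#' @param fraction_ri fraction of genes given a retained-intron isoform
#'   pair.
#' @param bg_rate background crosslink rate (tags/nt, Poisson).
#' @param peak_offset junction offset of planted peaks (transcript
#'   coordinates; -24 mirrors the EJC deposition site).
#' @param peak_fold peak rate as a fold over `bg_rate`.
#' @param peak_width peak width in nt (1 = single-base peak).
#' @param half_window height window half-width used to size peak tag
#'   numbers.
#' @param read_len read length (nt) for junction reads and DI counting.
#' @param n_junction_reads reads emitted per junction.
#' @param junction_props relative proportions of S/EI/IE/other junction
#'   reads.
#' @param di_n_genes,di_introns_per_gene,di_gene_fraction,di_fold,
#'   nb_dispersion,n_reps,mask_fraction,intron_mean_count,lib_scales
#'   detained-intron simulation: genes, introns per gene, fraction of genes
#'   with one planted DI at `di_fold` times its expected (null) count,
#'   negative-binomial dispersion, replicates, masked (multimappable)
#'   fraction per intron, mean count per unit weight, and per-replicate
#'   library scale factors.
#' @param apa_n_genes,apa_shift,samples_per_cond APA simulation: genes, the
#'   usage fraction moved from the long to the short isoform in condition
#'   B, samples per condition.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 50L,
                       n_exons_range = c(4L, 8L),
                       exon_meanlog = log(150), exon_sdlog = 0.35,
                       min_exon = 30L, max_exon = 1500L,
                       intron_meanlog = log(300), intron_sdlog = 0.4,
                       min_intron = 120L, max_intron = 3000L,
                       fraction_ri = 0.3,
                       bg_rate = 0.02,
                       peak_offset = -24L, peak_fold = 20, peak_width = 1L,
                       half_window = 15L,
                       read_len = 50L,
                       n_junction_reads = 24L,
                       junction_props = c(S = 2, EI = 1, IE = 1, other = 1),
                       di_n_genes = 500L, di_introns_per_gene = 10L,
                       di_gene_fraction = 0.5, di_fold = 8,
                       nb_dispersion = 0.05, n_reps = 3L,
                       mask_fraction = 0.1, intron_mean_count = 300,
                       lib_scales = c(1, 1.25, 0.8),
                       apa_n_genes = 100L, apa_shift = 0.5,
                       samples_per_cond = 3L) {
  cfg <- as.list(environment())
  stopifnot(cfg$bg_rate >= 0, cfg$peak_fold >= 0, cfg$min_intron >= 1,
            cfg$min_exon >= 1, cfg$di_fold > 0, cfg$nb_dispersion >= 0)
  structure(cfg, class = "sim_config")
}

.rlen <- function(n, meanlog, sdlog, lo, hi) {
  as.integer(pmin(pmax(round(stats::rlnorm(n, meanlog, sdlog)), lo), hi))
}

#' Simulate multi-isoform gene models with retained-intron pairs
#'
#' Builds `n_genes` genes laid head-to-tail (5 kb apart) on one chromosome,
#' each with one full-length transcript; a configured fraction also get a
#' second isoform in which one internal intron has been retained (the two
#' flanking exons merged), which satisfies the retained-intron rule by
#' construction.  Every transcript gets a CDS (15%/50%/35% split of the
#' spliced length into 5'UTR/CDS/3'UTR) so UTR-aware profiling can run.
#'
#' @param config a [sim_config()].
#' @return list with `models` (a [gene_models()]), `tpm` (named vector, all
#'   transcripts expressed at 10), and `truth_ri` (data.frame of planted
#'   retained introns: `gene_id`, `chrom`, `strand`, `start`, `end`).
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed + 101L)
  chrom <- "chrS"
  cursor <- 1000L
  exons <- NULL; cds <- NULL; truth <- NULL
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("G%03d", g)
    ne <- sample(seq(config$n_exons_range[1L], config$n_exons_range[2L]), 1L)
    elen <- .rlen(ne, config$exon_meanlog, config$exon_sdlog,
                  config$min_exon, config$max_exon)
    ilen <- .rlen(ne - 1L, config$intron_meanlog, config$intron_sdlog,
                  config$min_intron, config$max_intron)
    starts <- cursor + cumsum(c(0L, elen[-ne] + ilen))
    ends <- starts + elen
    strand <- sample(c("+", "-"), 1L)
    tid <- paste0(gid, ".t1")
    exons <- rbind(exons, data.frame(
      gene_id = gid, transcript_id = tid, chrom = chrom, strand = strand,
      start = starts, end = ends, biotype = "protein_coding",
      stringsAsFactors = FALSE))
    cds <- rbind(cds, .simulate_cds(tid, chrom, strand, starts, ends))
    if (stats::runif(1L) < config$fraction_ri && ne >= 3L) {
      k <- if (ne == 3L) 1L else sample(seq_len(ne - 2L), 1L) + 1L
      # isoform retaining intron k: merge exons k and k+1
      s2 <- starts[-(k + 1L)]; e2 <- ends[-k]
      tid2 <- paste0(gid, ".t2")
      exons <- rbind(exons, data.frame(
        gene_id = gid, transcript_id = tid2, chrom = chrom, strand = strand,
        start = s2, end = e2, biotype = "protein_coding",
        stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        gene_id = gid, chrom = chrom, strand = strand,
        start = ends[k], end = starts[k + 1L], stringsAsFactors = FALSE))
    }
    cursor <- max(ends) + 5000L
  }
  if (is.null(truth)) {
    truth <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), start = integer(),
                        end = integer())
  }
  list(models = gene_models(exons, cds), tpm = .all_expressed(exons),
       truth_ri = truth)
}

.all_expressed <- function(exons) {
  stats::setNames(rep(10, length(unique(exons$transcript_id))),
                  unique(exons$transcript_id))
}

# genomic intervals of transcript-coordinate range [from, to) (internal)
.tx_slice <- function(starts, ends, strand, from, to) {
  ord <- order(starts)
  if (strand == "-") ord <- rev(ord)
  s <- starts[ord]; e <- ends[ord]
  lens <- e - s
  offs <- cumsum(c(0L, lens))
  out <- NULL
  for (k in seq_along(s)) {
    lo <- max(from, offs[k]); hi <- min(to, offs[k + 1L])
    if (hi <= lo) next
    if (strand == "+") {
      out <- rbind(out, c(s[k] + (lo - offs[k]), s[k] + (hi - offs[k])))
    } else {
      out <- rbind(out, c(e[k] - (hi - offs[k]), e[k] - (lo - offs[k])))
    }
  }
  out
}

.simulate_cds <- function(tid, chrom, strand, starts, ends) {
  L <- sum(ends - starts)
  u5 <- max(1L, round(0.15 * L)); u3 <- max(1L, round(0.35 * L))
  iv <- .tx_slice(starts, ends, strand, u5, L - u3)
  data.frame(transcript_id = tid, chrom = chrom, strand = strand,
             start = iv[, 1L], end = iv[, 2L], stringsAsFactors = FALSE)
}

# genomic position of one transcript coordinate (internal)
.tx_pos <- function(starts, ends, strand, p) {
  iv <- .tx_slice(starts, ends, strand, p, p + 1L)
  if (is.null(iv)) NA_integer_ else
    if (strand == "+") iv[1L, 1L] else iv[1L, 2L] - 1L
}

#' Simulate iCLIP crosslink tracks with planted junction peaks
#'
#' Lays Poisson background (rate `bg_rate` tags/nt) over each gene's span
#' and plants single-base peaks at `peak_offset` relative to every
#' exon-exon junction of the gene's first transcript whose upstream exon is
#' long enough.  Peak tag numbers are Poisson with mean
#' `peak_fold * bg_rate * (2*half_window + 1)` (at least 2), i.e. the
#' planted height is `peak_fold` times the expected background height.  A
#' matched control track carries background only.
#'
#' @param config a [sim_config()].
#' @param annotation result of [simulate_annotation()].
#' @return list with `test` and `control` [clip_track()]s and `truth_peaks`
#'   (data.frame `gene_id`, `chrom`, `strand`, `pos`, `offset`).
#' @export
simulate_iclip <- function(config, annotation) {
  set.seed(config$seed + 202L)
  ex <- annotation$models$exons
  chroms <- character(); poss <- integer(); strands <- character()
  c_chroms <- character(); c_poss <- integer(); c_strands <- character()
  truth <- NULL
  for (i in split(seq_len(nrow(ex)), ex$gene_id)) {
    e <- ex[i, , drop = FALSE]
    gs <- min(e$start); ge <- max(e$end)
    strand <- e$strand[1L]; chrom <- e$chrom[1L]
    for (tgt in c("test", "control")) {
      nbg <- stats::rpois(1L, (ge - gs) * config$bg_rate)
      p <- if (nbg > 0) gs + sample.int(ge - gs, nbg, replace = TRUE) - 1L
           else integer(0)
      if (tgt == "test") {
        chroms <- c(chroms, rep(chrom, nbg)); poss <- c(poss, p)
        strands <- c(strands, rep(strand, nbg))
      } else {
        c_chroms <- c(c_chroms, rep(chrom, nbg)); c_poss <- c(c_poss, p)
        c_strands <- c(c_strands, rep(strand, nbg))
      }
    }
    # peaks at junctions of the first transcript
    t1 <- e[e$transcript_id == paste0(e$gene_id[1L], ".t1"), , drop = FALSE]
    t1 <- t1[order(t1$start), , drop = FALSE]
    ne <- nrow(t1)
    if (ne < 2L) next
    ord <- if (strand == "-") rev(seq_len(ne)) else seq_len(ne)
    need <- abs(config$peak_offset) + config$peak_width - 1L
    for (j in seq_len(ne - 1L)) {
      up <- t1[ord[j], ]
      if (up$end - up$start < need) next
      base0 <- if (strand == "+") up$end + config$peak_offset
               else up$start - 1L - config$peak_offset
      npk <- max(2L, stats::rpois(1L, config$peak_fold * config$bg_rate *
                                    (2L * config$half_window + 1L)))
      w <- config$peak_width
      pk <- rep(base0, npk) +
        if (w > 1L) sample.int(w, npk, replace = TRUE) - 1L else 0L
      chroms <- c(chroms, rep(chrom, npk)); poss <- c(poss, pk)
      strands <- c(strands, rep(strand, npk))
      truth <- rbind(truth, data.frame(
        gene_id = e$gene_id[1L], chrom = chrom, strand = strand,
        pos = base0, offset = config$peak_offset, stringsAsFactors = FALSE))
    }
  }
  list(test = clip_track(chroms, poss, strands),
       control = clip_track(c_chroms, c_poss, c_strands),
       truth_peaks = truth)
}

#' Simulate merged-exon gene sequences with a kmer planted under peaks
#'
#' Generates random sequences (uniform A/C/G/T) per gene in spliced
#' coordinates, uniform background tags, and peak tags at random positions;
#' the configured kmer is written into the sequence starting at every peak
#' position.  A control tag set carries background only over the same
#' sequences.
#'
#' @param config a [sim_config()].
#' @param kmer the planted kmer (default "TGTCGA").
#' @param n_genes number of genes (default 50).
#' @param gene_length sequence length per gene (default 1000).
#' @param peaks_per_gene planted peaks per gene (default 3).
#' @return list `seqs` (character), `tags_test`, `tags_control` (lists of
#'   per-base counts), `kmer`.
#' @export
simulate_kmer_data <- function(config, kmer = "TGTCGA", n_genes = 50L,
                               gene_length = 1000L, peaks_per_gene = 3L) {
  set.seed(config$seed + 303L)
  k <- nchar(kmer)
  seqs <- character(n_genes)
  tags_test <- tags_control <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    chars <- sample(c("A", "C", "G", "T"), gene_length, replace = TRUE)
    x <- tabulate(sample.int(gene_length,
                             stats::rpois(1L, gene_length * config$bg_rate),
                             replace = TRUE), gene_length)
    xc <- tabulate(sample.int(gene_length,
                              stats::rpois(1L, gene_length * config$bg_rate),
                              replace = TRUE), gene_length)
    at <- sample.int(gene_length - k, peaks_per_gene)
    for (p in at) {
      chars[p:(p + k - 1L)] <- strsplit(kmer, "")[[1L]]
      npk <- max(2L, stats::rpois(1L, config$peak_fold * config$bg_rate *
                                    (2L * config$half_window + 1L)))
      x[p] <- x[p] + npk
    }
    seqs[g] <- paste(chars, collapse = "")
    tags_test[[g]] <- x
    tags_control[[g]] <- xc
  }
  list(seqs = seqs, tags_test = tags_test, tags_control = tags_control,
       kmer = kmer)
}

#' Simulate junction-spanning reads as a SAM file
#'
#' Emits, for every junction of each gene's first transcript, spliced (S),
#' exon-intron (EI), intron-exon (IE) and intron-internal (other) reads at
#' the configured proportions, with 15-nt anchors so the 3-nt anchor rule
#' is satisfied cleanly.  Reads are written as minimal SAM so the standard
#' readers are exercised.
#'
#' @param config a [sim_config()].
#' @param annotation result of [simulate_annotation()].
#' @param path output SAM path.
#' @return list with `path` and `truth` (expected per-class totals,
#'   data.frame `class`, `n`).
#' @export
simulate_junction_reads <- function(config, annotation, path) {
  set.seed(config$seed + 404L)
  ex <- annotation$models$exons
  chrom_len <- max(ex$end) + 10000L
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", unique(ex$chrom), chrom_len))
  props <- config$junction_props / sum(config$junction_props)
  n_per <- round(config$n_junction_reads * props)
  anchor <- 15L
  recs <- character(0)
  tot <- c(S = 0L, EI = 0L, IE = 0L, other = 0L)
  rid <- 0L
  for (i in split(seq_len(nrow(ex)), ex$gene_id)) {
    e <- ex[i, , drop = FALSE]
    t1 <- e[e$transcript_id == paste0(e$gene_id[1L], ".t1"), , drop = FALSE]
    t1 <- t1[order(t1$start), , drop = FALSE]
    if (nrow(t1) < 2L) next
    strand <- t1$strand[1L]
    flag <- if (strand == "-") 16L else 0L
    for (j in seq_len(nrow(t1) - 1L)) {
      s <- t1$end[j]; en <- t1$start[j + 1L]      # the intron, 0-based
      ilen <- en - s
      if (ilen < 2L * anchor + 10L) next
      if (t1$end[j] - t1$start[j] < anchor ||
          t1$end[j + 1L] - t1$start[j + 1L] < anchor) next
      emit <- function(pos0, cigar, n) {
        if (n <= 0L) return(invisible())
        for (q in seq_len(n)) {
          rid <<- rid + 1L
          recs <<- c(recs, sprintf(
            "r%06d\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*\tNH:i:1",
            rid, flag, t1$chrom[1L], pos0 + 1L, cigar))
        }
      }
      emit(s - anchor, sprintf("%dM%dN%dM", anchor, ilen, anchor), n_per["S"])
      # boundary at the 5' exon end: genomic s on +, genomic en on -
      if (strand == "+") {
        emit(s - anchor, sprintf("%dM", 2L * anchor), n_per["EI"])
        emit(en - anchor, sprintf("%dM", 2L * anchor), n_per["IE"])
      } else {
        emit(en - anchor, sprintf("%dM", 2L * anchor), n_per["EI"])
        emit(s - anchor, sprintf("%dM", 2L * anchor), n_per["IE"])
      }
      emit(s + 5L, sprintf("%dM", 2L * anchor), n_per["other"])
      tot <- tot + n_per[c("S", "EI", "IE", "other")]
    }
  }
  writeLines(c(hdr, recs), path)
  list(path = path,
       truth = data.frame(class = names(tot), n = as.integer(tot)))
}

#' Simulate intronic count matrices with planted detained introns
#'
#' Builds genes of `di_introns_per_gene` introns with log-normal lengths
#' and a partial multimappability mask, assigns per-intron expected counts
#' proportional to their effective-length weights, and in a configured
#' fraction of genes inflates one intron so that its expected observed mean
#' is exactly `di_fold` times the null mean that the weighted
#' redistribution will assign to it (solving the fixed point; the intron is
#' only planted when its weight allows the target fold).  Counts are
#' negative binomial with the configured dispersion and per-replicate
#' library scale factors.
#'
#' @param config a [sim_config()].
#' @return list with `introns` (data.frame `chunk_id`, `gene_id`, `chrom`,
#'   `start`, `end`), `mask` (data.frame of multimappable intervals),
#'   `counts` (raw matrix, introns x replicates), `truth_di` (character
#'   vector of planted chunk ids).
#' @export
simulate_intron_counts <- function(config) {
  set.seed(config$seed + 505L)
  npg <- config$di_introns_per_gene
  ng <- config$di_n_genes
  introns <- NULL; mask <- NULL
  cursor <- 1000L
  for (g in seq_len(ng)) {
    gid <- sprintf("D%04d", g)
    lens <- .rlen(npg, config$intron_meanlog, config$intron_sdlog,
                  config$min_intron, config$max_intron)
    starts <- cursor + cumsum(c(0L, lens[-npg] + 200L))
    ends <- starts + lens
    introns <- rbind(introns, data.frame(
      chunk_id = sprintf("%s.i%02d", gid, seq_len(npg)), gene_id = gid,
      chrom = "chrD", start = starts, end = ends, stringsAsFactors = FALSE))
    mlen <- as.integer(round(config$mask_fraction * lens))
    keep <- mlen > 0L
    if (any(keep)) {
      mask <- rbind(mask, data.frame(chrom = "chrD", start = starts[keep],
                                     end = starts[keep] + mlen[keep],
                                     stringsAsFactors = FALSE))
    }
    cursor <- max(ends) + 2000L
  }
  ef <- effective_lengths(introns, config$read_len, mask)
  mu <- numeric(nrow(ef))
  planted <- character(0)
  for (i in split(seq_len(nrow(ef)), ef$gene_id)) {
    w <- ef$weight[i]
    gene_total <- config$intron_mean_count * length(i)
    m <- w * gene_total
    if (stats::runif(1L) < config$di_gene_fraction) {
      ok <- which(w > 0 & w < 1 / config$di_fold)
      if (length(ok)) {
        pick <- ok[which.min(abs(w[ok] - stats::median(w[ok])))]
        wp <- w[pick]
        rest <- gene_total * (1 - wp)
        # expected observed = di_fold x the null mean it will receive
        m[pick] <- config$di_fold * wp * rest / (1 - config$di_fold * wp)
        planted <- c(planted, ef$chunk_id[i[pick]])
      }
    }
    mu[i] <- m
  }
  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  counts <- sapply(seq_len(config$n_reps), function(r) {
    m <- mu * config$lib_scales[(r - 1L) %% length(config$lib_scales) + 1L]
    if (is.finite(size)) stats::rnbinom(length(m), mu = m, size = size)
    else stats::rpois(length(m), m)
  })
  rownames(counts) <- ef$chunk_id
  colnames(counts) <- paste0("rep", seq_len(config$n_reps))
  list(introns = introns, mask = mask, counts = counts, truth_di = planted)
}

#' Simulate two-condition transcript expression with usage shifts
#'
#' Each gene has a long and a short (half-length) isoform; condition A uses
#' them 80/20 and condition B moves `apa_shift` of the long isoform's usage
#' onto the short one, producing a known negative weighted-length change.
#' TPM values are exact (no sampling noise) so the expected log2 ratio is
#' closed-form.
#'
#' @param config a [sim_config()].
#' @return list with `expr` (long data.frame for [weighted_length()]) and
#'   `truth` (data.frame `gene_id`, `expected_log2_ratio`).
#' @export
simulate_expression <- function(config) {
  set.seed(config$seed + 606L)
  rows <- NULL; truth <- NULL
  for (g in seq_len(config$apa_n_genes)) {
    gid <- sprintf("A%04d", g)
    Llong <- .rlen(1L, log(2000), 0.3, 500L, 8000L)
    Lshort <- as.integer(round(Llong / 2))
    ua <- c(0.8, 0.2)
    shift <- config$apa_shift * ua[1L]
    ub <- c(ua[1L] - shift, ua[2L] + shift)
    tot <- stats::runif(1L, 5, 50)
    for (cond in c("A", "B")) {
      u <- if (cond == "A") ua else ub
      for (s in seq_len(config$samples_per_cond)) {
        rows <- rbind(rows, data.frame(
          gene_id = gid, transcript_id = paste0(gid, c(".L", ".S")),
          length = c(Llong, Lshort), sample = sprintf("%s%d", cond, s),
          tpm = tot * u, condition = cond, stringsAsFactors = FALSE))
      }
    }
    wa <- sum(ua * c(Llong, Lshort)); wb <- sum(ub * c(Llong, Lshort))
    truth <- rbind(truth, data.frame(gene_id = gid,
                                     expected_log2_ratio = log2(wb / wa),
                                     stringsAsFactors = FALSE))
  }
  list(expr = rows, truth = truth)
}
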