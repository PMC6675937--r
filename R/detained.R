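# Detained-intron identification: intronic RNA-seq counts are compared to an
# in-silico null that redistributes each gene's intronic signal between its
# introns according to alignability-corrected effective lengths, followed by
# a negative-binomial test.  Also: binding-density binning of chunks.

#' Count intronic RNA-seq reads
#'
#' Counts primary, non-duplicate, uniquely mapping reads (NH tag 1 or
#' absent) per intron chunk, requiring at least `min_overlap` aligned nt
#' inside the chunk (splice gaps do not count as overlap).
#'
#' @param alignments data.frame from [read_alignments()].
#' @param intron_chunks data.frame of constitutive-intron chunks (`chrom`,
#'   `start`, `end`, and an id column `chunk_id`).
#' @param min_overlap minimum aligned overlap in nt (default 10).
#' @return integer vector of counts named by `chunk_id`.
#' @export
count_intronic_reads <- function(alignments, intron_chunks,
                                 min_overlap = 10L) {
  keep <- !alignments$secondary & !alignments$duplicate &
    (is.na(alignments$nh) | alignments$nh == 1L)
  aln <- alignments[keep, , drop = FALSE]
  counts <- stats::setNames(integer(nrow(intron_chunks)),
                            intron_chunks$chunk_id)
  if (nrow(aln) == 0L || nrow(intron_chunks) == 0L) return(counts)
  blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    aln$cigar, pos = aln$start + 1L, ops = c("M", "=", "X"))
  hits <- GenomicRanges::findOverlaps(
    .as_granges(intron_chunks, stranded = FALSE),
    GenomicRanges::GRanges(aln$chrom,
                           IRanges::IRanges(aln$start + 1L, aln$end)))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (h in seq_along(qh)) {
    ck <- intron_chunks[qh[h], ]
    bl <- blocks[[sh[h]]]
    ov <- sum(pmax(0L, pmin(IRanges::end(bl), ck$end) -
                     pmax(IRanges::start(bl) - 1L, ck$start)))
    if (ov >= min_overlap) counts[qh[h]] <- counts[qh[h]] + 1L
  }
  counts
}

#' Median-of-ratios library size factors
#'
#' The classic size-factor estimator: per intron, the geometric mean over
#' replicates is the reference; each replicate's factor is the median over
#' introns of count/reference (introns with a zero geometric mean are
#' skipped).
#'
#' @param counts integer matrix, introns x replicates.
#' @return numeric vector of per-replicate factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("size factors need at least 2 replicates")
  logg <- rowMeans(log(counts))
  ok <- is.finite(logg)
  if (!any(ok)) stop("no intron with all-positive counts")
  apply(counts, 2L, function(x) exp(stats::median(log(x[ok]) - logg[ok])))
}

#' Alignability-corrected effective lengths and within-gene weights
#'
#' The effective length of an intron is the number of positions a valid
#' counted read could start from: L_eff = L_genomic + L_read - 20 - M,
#' where 20 is twice the 10-nt overlap required for counting and M is the
#' number of intron positions yielding a multimapping read.  Weights divide
#' each intron's effective length by the gene total; introns with weight 0
#' (L_eff <= 0) are flagged excluded.
#'
#' @param introns data.frame with `gene_id`, `chrom`, `start`, `end` (and
#'   optionally `chunk_id`).
#' @param read_len RNA-seq read length in nt.
#' @param mask either a data.frame of multimappable-position intervals
#'   (`chrom`, `start`, `end`; 0-based half-open) or a numeric vector M per
#'   intron.  NULL means no masked positions.
#' @return `introns` with added columns `L_genomic`, `M`, `L_eff`, `weight`,
#'   `excluded`; weights of included introns sum to 1 within each gene.
#' @export
effective_lengths <- function(introns, read_len, mask = NULL) {
  introns$L_genomic <- introns$end - introns$start
  if (is.null(mask)) {
    M <- rep(0L, nrow(introns))
  } else if (is.data.frame(mask)) {
    gr_i <- .as_granges(introns, stranded = FALSE)
    gr_m <- GenomicRanges::reduce(.as_granges(mask, stranded = FALSE))
    ov <- GenomicRanges::findOverlaps(gr_i, gr_m)
    M <- integer(nrow(introns))
    if (length(ov)) {
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(gr_i)[S4Vectors::queryHits(ov)],
        IRanges::ranges(gr_m)[S4Vectors::subjectHits(ov)]))
      acc <- rowsum(w, S4Vectors::queryHits(ov))
      M[as.integer(rownames(acc))] <- acc[, 1L]
    }
  } else {
    M <- mask
  }
  introns$M <- M
  introns$L_eff <- introns$L_genomic + read_len - 20L - M
  introns$excluded <- introns$L_eff <= 0
  introns$L_eff[introns$excluded] <- 0L
  w <- numeric(nrow(introns))
  for (i in split(seq_len(nrow(introns)), introns$gene_id)) {
    tot <- sum(introns$L_eff[i])
    if (tot > 0) w[i] <- introns$L_eff[i] / tot
  }
  introns$weight <- w
  introns
}

#' In-silico null replicates from effective-length weights
#'
#' For each gene and replicate, the sum of the gene's normalized intronic
#' counts is redistributed between its introns according to the weights:
#' N[i, r] = w_i * sum_j C[j, r].  Per gene and replicate the null column
#' totals equal the observed totals exactly.
#'
#' @param norm_counts numeric matrix of normalized counts, introns x
#'   replicates.
#' @param weights numeric vector of within-gene weights, parallel to rows.
#' @param gene_id character vector of gene ids, parallel to rows.
#' @return numeric matrix of null counts, same dimensions as `norm_counts`.
#' @export
null_replicates <- function(norm_counts, weights, gene_id) {
  norm_counts <- as.matrix(norm_counts)
  if (length(weights) != nrow(norm_counts) ||
      length(gene_id) != nrow(norm_counts)) {
    stop("weights/gene_id must align with the count matrix rows")
  }
  N <- matrix(0, nrow(norm_counts), ncol(norm_counts),
              dimnames = dimnames(norm_counts))
  for (i in split(seq_len(nrow(norm_counts)), gene_id)) {
    tot <- colSums(norm_counts[i, , drop = FALSE])
    N[i, ] <- outer(weights[i], tot)
  }
  N
}

#' Call detained introns against the weighted null
#'
#' Compares each intron's observed replicates to its null replicates under
#' a negative-binomial model.  Per-intron dispersions are estimated by the
#' method of moments from within-group variability and shrunk halfway
#' toward a mean-dependent trend (a0 + a1/mean, fitted across introns); the
#' Wald statistic uses Var(log mean) ~ (1/mean + alpha)/n per group.
#' P-values are Benjamini-Hochberg adjusted and an intron is detained when
#' q < `fdr` and its observed mean is at least `min_fold` times its null
#' mean.
#'
#' @param observed,null numeric matrices (introns x replicates) of
#'   normalized observed counts and null counts.
#' @param fdr BH FDR threshold (default 0.01).
#' @param min_fold minimum observed/expected fold change (default 4).
#' @return data.frame `mean_obs`, `mean_null`, `dispersion`, `log2_fold`,
#'   `pvalue`, `qvalue`, `detained`; all-zero introns get NA statistics and
#'   `detained = FALSE`.  Row names follow `observed`.
#' @export
call_detained <- function(observed, null, fdr = 0.01, min_fold = 4) {
  observed <- as.matrix(observed); null <- as.matrix(null)
  stopifnot(dim(observed) == dim(null))
  mo <- rowMeans(observed); mn <- rowMeans(null)
  vo <- apply(observed, 1L, stats::var)
  vn <- apply(null, 1L, stats::var)
  testable <- mo + mn > 0
  mom <- function(m, v) ifelse(m > 0, (v - m) / m^2, NA_real_)
  a_raw <- rowMeans(cbind(mom(mo, vo), mom(mn, vn)), na.rm = TRUE)
  base_mean <- (mo + mn) / 2
  fit_ok <- is.finite(a_raw) & a_raw > 0 & base_mean > 0
  if (sum(fit_ok) >= 10L) {
    tf <- stats::lm(a_raw[fit_ok] ~ I(1 / base_mean[fit_ok]))
    trend <- pmax(stats::coef(tf)[1L] + stats::coef(tf)[2L] / base_mean,
                  1e-8)
  } else {
    trend <- rep(max(mean(a_raw[fit_ok], na.rm = TRUE), 0.01), length(mo))
    trend[!is.finite(trend)] <- 0.01
  }
  alpha <- ifelse(is.finite(a_raw) & a_raw > 0,
                  (a_raw + trend) / 2, trend)
  alpha <- pmax(alpha, 1e-8)
  n_o <- ncol(observed); n_n <- ncol(null)
  p <- rep(NA_real_, length(mo))
  both <- testable & mo > 0 & mn > 0
  se <- sqrt((1 / mo[both] + alpha[both]) / n_o +
               (1 / mn[both] + alpha[both]) / n_n)
  z <- (log(mo[both]) - log(mn[both])) / se
  p[both] <- 2 * stats::pnorm(-abs(z))
  p[testable & mo > 0 & mn == 0] <- 0   # signal where the null expects none
  p[testable & mo == 0] <- 1
  q <- rep(NA_real_, length(p))
  q[testable] <- stats::p.adjust(p[testable], method = "BH")
  out <- data.frame(
    mean_obs = mo, mean_null = mn, dispersion = alpha,
    log2_fold = ifelse(mn > 0, log2(mo / mn), ifelse(mo > 0, Inf, NA)),
    pvalue = p, qvalue = q,
    detained = !is.na(q) & q < fdr & mo >= min_fold * mn & mo > 0
  )
  rownames(out) <- rownames(observed)
  out
}

#' Bin chunks by crosslink binding density
#'
#' Density is log2(tags / genomic size).  Chunks shorter than 10 bp are
#' excluded; chunks with zero tags have undefined density and are assigned
#' the Low bin (their number is reported via a message).  The range of
#' finite densities is split into three equal-width bins Low/Medium/High
#' (right-closed; a degenerate range puts everything in Low).
#'
#' @param chunks data.frame with `chunk_id`, `start`, `end`.
#' @param tag_counts numeric per-chunk tag counts (union of replicates),
#'   parallel to `chunks` rows.
#' @return data.frame `chunk_id`, `size`, `tags`, `density`, `bin`.
#' @export
density_bins <- function(chunks, tag_counts) {
  size <- chunks$end - chunks$start
  keep <- size >= 10L
  chunks <- chunks[keep, , drop = FALSE]
  size <- size[keep]
  tags <- tag_counts[keep]
  density <- log2(tags / size)
  fin <- is.finite(density)
  if (any(!fin)) message(sum(!fin), " zero-tag chunk(s) assigned to the Low bin")
  bin <- rep("Low", length(density))
  if (any(fin) && diff(range(density[fin])) > 0) {
    edges <- seq(min(density[fin]), max(density[fin]), length.out = 4L)
    idx <- 1L + (density[fin] > edges[2L]) + (density[fin] > edges[3L])
    bin[fin] <- c("Low", "Medium", "High")[idx]
  }
  data.frame(chunk_id = chunks$chunk_id, size = size, tags = tags,
             density = density, bin = bin, stringsAsFactors = FALSE)
}
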