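# Kmer enrichment under crosslink signal, scored by within-gene
# randomization z-scores and corrected against a control pulldown.
#
# Genes enter as merged-exon (spliced) sequences with a parallel per-base tag
# count vector; heights use the same 15-nt window as significance calling.

.KMER_ALPHA <- c("A", "C", "G", "T")

# all 4^k kmers in encoding order (first character most significant)
.all_kmers <- function(k) {
  idx <- 0:(4^k - 1)
  out <- character(length(idx))
  for (j in seq_len(k)) {
    digit <- (idx %/% 4^(k - j)) %% 4
    out <- paste0(out, .KMER_ALPHA[digit + 1L])
  }
  out
}

#' All kmers of length k over A/C/G/T
#' @param k kmer length.
#' @return character vector of the 4^k kmers in lexicographic order.
#' @export
all_kmers <- function(k) .all_kmers(k)

# integer kmer id (1..4^k) at each start position; NA under ambiguous bases
.kmer_ids <- function(seq, k) {
  chars <- strsplit(chartr("acgtuU", "ACGTTT", seq), "", fixed = TRUE)[[1L]]
  v <- match(chars, .KMER_ALPHA) - 1L
  L <- length(v)
  if (L < k) return(integer(0))
  n <- L - k + 1L
  ids <- rep(1, n)
  for (j in 0:(k - 1L)) ids <- ids + v[(1L + j):(n + j)] * 4^(k - 1L - j)
  as.integer(ids)
}

# accumulate height-weighted kmer frequencies into f (length 4^k)
.accumulate_f <- function(f, heights, ids) {
  ok <- !is.na(ids)
  if (!any(ok)) return(f)
  acc <- rowsum(as.numeric(heights[seq_along(ids)][ok]), ids[ok])
  at <- as.integer(rownames(acc))
  f[at] <- f[at] + acc[, 1L]
  f
}

#' Height-weighted frequency of one kmer
#'
#' Sums the crosslink height at every position where a match to the kmer
#' begins, across all supplied gene sequences.  T and U are equivalent;
#' ambiguous bases never match.
#'
#' @param seqs character vector (or list) of merged-exon gene sequences.
#' @param tags list of integer per-base tag count vectors, parallel to
#'   `seqs` (same lengths).
#' @param s the kmer (string over A/C/G/T/U).
#' @param half_window half-width of the height window (default 15).
#' @return numeric scalar f_s.
#' @export
kmer_frequency <- function(seqs, tags, s, half_window = 15L) {
  seqs <- as.character(seqs)
  stopifnot(length(seqs) == length(tags))
  k <- nchar(s)
  target <- match(chartr("acgtuU", "ACGTTT", s), .all_kmers(k))
  total <- 0
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) != length(tags[[i]])) {
      stop("sequence/tag length mismatch for entry ", i)
    }
    ids <- .kmer_ids(seqs[i], k)
    if (!length(ids)) next
    h <- .window_heights(tags[[i]], half_window)
    total <- total + sum(h[seq_along(ids)][!is.na(ids) & ids == target])
  }
  total
}

#' Randomization z-scores for all kmers of length k
#'
#' Scores every kmer by its height-weighted match frequency f_s and
#' standardizes it against `n_rand` randomizations in which each gene's tags
#' are repositioned uniformly within that gene (heights are recomputed per
#' randomization): z_s = (f_s - mu_s) / sigma_s.
#'
#' @inheritParams kmer_frequency
#' @param k kmer length (1..8; the analyses of interest use 6 and 7).
#' @param n_rand number of randomizations (default 100).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return data.frame `kmer`, `f`, `mu`, `sigma`, `z` (z is NA where
#'   sigma = 0), ordered by decreasing z.
#' @export
kmer_zscores <- function(seqs, tags, k = 6L, n_rand = 100L,
                         half_window = 15L,
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!k %in% 1:8) stop("k must be between 1 and 8")
  seqs <- as.character(seqs)
  stopifnot(length(seqs) == length(tags))
  ids_by_gene <- lapply(seqs, .kmer_ids, k = k)
  n_tags <- vapply(tags, function(x) as.integer(sum(x)), integer(1L))
  lens <- vapply(tags, length, integer(1L))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) != lens[i]) {
      stop("sequence/tag length mismatch for entry ", i)
    }
  }
  nk <- as.integer(4^k)
  f_obs <- numeric(nk)
  for (i in seq_along(seqs)) {
    if (!length(ids_by_gene[[i]])) next
    f_obs <- .accumulate_f(f_obs, .window_heights(tags[[i]], half_window),
                           ids_by_gene[[i]])
  }
  fsum <- numeric(nk)
  fsq <- numeric(nk)
  for (r in seq_len(n_rand)) {
    f_r <- numeric(nk)
    for (i in seq_along(seqs)) {
      if (!length(ids_by_gene[[i]]) || n_tags[i] == 0L) next
      xr <- tabulate(randomize_positions(n_tags[i], lens[i]), nbins = lens[i])
      f_r <- .accumulate_f(f_r, .window_heights(xr, half_window),
                           ids_by_gene[[i]])
    }
    fsum <- fsum + f_r
    fsq <- fsq + f_r^2
  }
  mu <- fsum / n_rand
  sigma <- sqrt(pmax(fsq / n_rand - mu^2, 0))
  if (sd_type == "sample") sigma <- sigma * sqrt(n_rand / (n_rand - 1))
  z <- ifelse(sigma > 0, (f_obs - mu) / sigma, NA_real_)
  out <- data.frame(kmer = .all_kmers(k), f = f_obs, mu = mu, sigma = sigma,
                    z = z, stringsAsFactors = FALSE)
  out[order(-out$z, out$kmer, na.last = TRUE), , drop = FALSE]
}

#' Correct test-protein kmer z-scores against a control pulldown
#'
#' Crosslinking preference (e.g. uridine bias) inflates z-scores in both the
#' test and the control library.  The corrected score of a kmer is its
#' residual from the ordinary least-squares regression of test z on control
#' z over all kmers with defined z in both.
#'
#' @param test_scores,control_scores data.frames from [kmer_zscores()] over
#'   the same kmer universe.
#' @return `test_scores` with added columns `z_control` and `residual`
#'   (NA where either z is undefined), ordered by decreasing residual.
#' @export
control_correct <- function(test_scores, control_scores) {
  m <- match(test_scores$kmer, control_scores$kmer)
  if (anyNA(m)) stop("test and control must share the same kmer universe")
  zc <- control_scores$z[m]
  zt <- test_scores$z
  ok <- is.finite(zt) & is.finite(zc)
  if (sum(ok) < 3L) stop("need at least 3 kmers with defined z in both sets")
  fit <- stats::lm(zt[ok] ~ zc[ok])
  resid <- rep(NA_real_, length(zt))
  resid[ok] <- zt[ok] - (stats::coef(fit)[1L] + stats::coef(fit)[2L] * zc[ok])
  out <- test_scores
  out$z_control <- zc
  out$residual <- resid
  out[order(-out$residual, na.last = TRUE), , drop = FALSE]
}

#' Per-gene merged-exon tag vectors from a track
#'
#' Maps a genomic crosslink track onto each gene's merged-exon (spliced)
#' coordinates, for use with the kmer scoring functions.  Exons are
#' concatenated in genomic order; for minus-strand genes the vector is
#' reversed so position 1 is the transcript 5' end.
#'
#' @param track a [clip_track()].
#' @param models a [gene_models()] object.
#' @return named list (by gene) of integer per-base tag count vectors.
#' @export
gene_tag_vectors <- function(track, models) {
  regs <- gene_regions(models)
  regs <- regs[regs$type == "exonic", , drop = FALSE]
  out <- lapply(split(seq_len(nrow(regs)), regs$gene_id), function(i) {
    reg <- regs[i, , drop = FALSE]
    x <- .region_counts(track, reg)$counts
    if (reg$strand[1L] == "-") x <- rev(x)
    x
  })
  out
}
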