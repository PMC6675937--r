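# Significantly crosslinked bases by within-region randomization.
#
# A region is one exonic union or one intron of a gene (see gene_regions());
# multi-interval regions are concatenated in genomic order so windows do not
# leak across introns.

# per-base tag counts of a region in concatenated coordinates (internal)
.region_counts <- function(track, region) {
  region <- region[order(region$start), , drop = FALSE]
  sub <- track_slice(track, region$chrom[1L], region$strand[1L])
  pos <- integer(0)
  cnt <- integer(0)
  offs <- cumsum(c(0L, region$end - region$start))
  for (k in seq_len(nrow(region))) {
    keep <- sub$pos >= region$start[k] & sub$pos < region$end[k]
    pos <- c(pos, sub$pos[keep] - region$start[k] + offs[k] + 1L)  # 1-based
    cnt <- c(cnt, sub$count[keep])
  }
  L <- offs[length(offs)]
  x <- integer(L)
  x[pos] <- x[pos] + cnt   # positions unique within track
  list(counts = x, genomic = unlist(lapply(seq_len(nrow(region)), function(k)
    seq.int(region$start[k], region$end[k] - 1L)), use.names = FALSE))
}

# running-window sum of a per-base count vector (internal)
.window_heights <- function(x, half_window) {
  L <- length(x)
  if (L == 0L) return(integer(0))
  cs <- c(0, cumsum(as.numeric(x)))
  i <- seq_len(L)
  as.integer(cs[pmin(i + half_window, L) + 1L] - cs[pmax(i - half_window - 1L, 0L) + 1L])
}

#' Per-base crosslink heights within a region
#'
#' The height of a base is the number of crosslink tags within
#' `half_window` nt of it (the base itself included), counting only tags
#' inside the region.  Multi-interval regions (a gene's merged exons) are
#' concatenated so the window runs in spliced coordinates.
#'
#' @param track a [clip_track()].
#' @param region data.frame with columns `chrom`, `strand`, `start`, `end`
#'   (one or more rows of a single region).
#' @param half_window window half-width in nt (default 15).
#' @return data.frame with one row per region base: `chrom`, `strand`,
#'   `pos` (genomic), `count` (tags at the base), `height`.
#' @export
base_heights <- function(track, region, half_window = 15L) {
  if (nrow(region) == 0L || sum(region$end - region$start) == 0L) {
    stop("empty region")
  }
  rc <- .region_counts(track, region)
  data.frame(chrom = region$chrom[1L], strand = region$strand[1L],
             pos = rc$genomic, count = rc$counts,
             height = .window_heights(rc$counts, half_window),
             stringsAsFactors = FALSE)
}

#' Uniformly randomize tag positions within a region
#'
#' Each tag is independently reassigned a uniform position in `1..length`
#' (sampling with replacement, so randomized tags may collide).  Uses the
#' session RNG; call `set.seed()` for reproducibility.
#'
#' @param n_tags number of tags to place.
#' @param length region length in nt.
#' @return integer vector of `n_tags` positions in `1..length`.
#' @export
randomize_positions <- function(n_tags, length) {
  if (length < 1L) stop("region length must be >= 1")
  sample.int(length, n_tags, replace = TRUE)
}

#' Height-FDR curve for one region
#'
#' For heights h = 1..max observed, computes the observed fraction of bases
#' with height >= h, the mean and standard deviation of that fraction over
#' `n_rand` within-region randomizations of the tag positions, and
#' FDR(h) = (mu_h + sigma_h) / P_obs(h).
#'
#' @inheritParams base_heights
#' @param n_rand number of randomizations (default 100; must be >= 2).
#' @param strict use a strict inequality (height > h) for the height
#'   fractions instead of the default >=.
#' @param sd_type `"population"` (n divisor, default) or `"sample"` for the
#'   randomization standard deviation.
#' @return data.frame `h`, `p_obs`, `mu`, `sigma`, `fdr`; zero rows when the
#'   region holds no tags.
#' @export
fdr_curve <- function(track, region, n_rand = 100L, half_window = 15L,
                      strict = FALSE, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (n_rand < 2L) stop("n_rand must be >= 2 (sigma undefined otherwise)")
  rc <- .region_counts(track, region)
  x <- rc$counts
  L <- length(x)
  N <- sum(x)
  empty <- data.frame(h = integer(), p_obs = numeric(), mu = numeric(),
                      sigma = numeric(), fdr = numeric())
  if (N == 0L) return(empty)
  p_of <- function(hh, hmax) {
    tab <- tabulate(pmin(hh[hh > 0L], hmax), nbins = hmax)
    p_ge <- rev(cumsum(rev(tab))) / L
    if (strict) c(p_ge[-1L], 0) else p_ge
  }
  h_obs <- .window_heights(x, half_window)
  hmax <- max(h_obs)
  p_obs <- p_of(h_obs, hmax)
  P <- matrix(0, n_rand, hmax)
  for (r in seq_len(n_rand)) {
    xr <- tabulate(randomize_positions(N, L), nbins = L)
    P[r, ] <- p_of(.window_heights(xr, half_window), hmax)
  }
  mu <- colMeans(P)
  sigma <- if (sd_type == "population") {
    sqrt(pmax(colMeans(P^2) - mu^2, 0))
  } else {
    apply(P, 2L, stats::sd)
  }
  fdr <- ifelse(p_obs > 0, (mu + sigma) / p_obs, 0)
  data.frame(h = seq_len(hmax), p_obs = p_obs, mu = mu, sigma = sigma,
             fdr = fdr)
}

#' Call significantly crosslinked bases
#'
#' Runs [fdr_curve()] per region and reports every base whose height h has
#' FDR(h) below the threshold.
#'
#' @param track a [clip_track()].
#' @param regions data.frame as from [gene_regions()]: columns `region_id`,
#'   `chrom`, `strand`, `start`, `end` (regions may span several rows).
#' @param fdr_threshold report bases with FDR strictly below this (default
#'   0.1).
#' @param tagged_only if TRUE, report only bases that themselves carry at
#'   least one tag (default FALSE: any base whose windowed height qualifies).
#' @inheritParams fdr_curve
#' @return data.frame `region_id`, `chrom`, `strand`, `pos`, `height`,
#'   `fdr`, sorted by region and position.
#' @export
call_significant <- function(track, regions, fdr_threshold = 0.1,
                             half_window = 15L, n_rand = 100L,
                             strict = FALSE, tagged_only = FALSE) {
  out <- lapply(split(seq_len(nrow(regions)), regions$region_id), function(i) {
    reg <- regions[i, , drop = FALSE]
    curve <- fdr_curve(track, reg, n_rand = n_rand,
                       half_window = half_window, strict = strict)
    if (nrow(curve) == 0L) return(NULL)
    bh <- base_heights(track, reg, half_window = half_window)
    fdr <- rep(NA_real_, nrow(bh))
    nz <- bh$height > 0L
    fdr[nz] <- curve$fdr[bh$height[nz]]
    keep <- nz & fdr < fdr_threshold
    if (tagged_only) keep <- keep & bh$count > 0L
    if (!any(keep)) return(NULL)
    data.frame(region_id = reg$region_id[1L], bh[keep, , drop = FALSE],
               fdr = fdr[keep], row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(region_id = character(), chrom = character(),
                      strand = character(), pos = integer(),
                      count = integer(), height = integer(), fdr = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Merge significant bases into clusters
#'
#' Bases on the same chromosome and strand whose pairwise gaps are at most
#' `max_gap` nt chain into one cluster interval.
#'
#' @param calls data.frame with columns `chrom`, `strand`, `pos` (e.g. from
#'   [call_significant()]).
#' @param max_gap maximum distance (nt) between consecutive bases of a
#'   cluster (default 15).
#' @return data.frame `chrom`, `strand`, `start`, `end` (half-open),
#'   `n_bases`.
#' @examples
#' calls <- data.frame(chrom = "c", strand = "+", pos = c(10L, 20L, 40L))
#' merge_clusters(calls)[, c("start", "end")]  # [10,21) and [40,41)
#' @export
merge_clusters <- function(calls, max_gap = 15L) {
  empty <- data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(), n_bases = integer())
  if (nrow(calls) == 0L) return(empty)
  key <- paste(calls$chrom, calls$strand)
  out <- lapply(split(seq_len(nrow(calls)), key), function(i) {
    p <- sort(unique(calls$pos[i]))
    grp <- cumsum(c(1L, diff(p) > max_gap))
    data.frame(chrom = calls$chrom[i[1L]], strand = calls$strand[i[1L]],
               start = as.integer(tapply(p, grp, min)),
               end = as.integer(tapply(p, grp, max)) + 1L,
               n_bases = as.integer(table(grp)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
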