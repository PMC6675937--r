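# log2 enrichment of a pulldown over the control iCLIP per category
# (biotype, exon position, intron class, exon-length bin) with percentile
# bootstrap confidence intervals.

#' Per-category log2 enrichment over control
#'
#' For each category, tag counts of its units (genes or exons/chunks) are
#' summed in the test and control libraries and the enrichment is
#' log2(sum test / sum control).  No pseudo-counts are added: categories
#' with a zero control sum are reported as NA with a warning.
#'
#' @param test_counts,control_counts numeric vectors of per-unit tag counts
#'   over the same unit universe (matched by names when named, else by
#'   position).
#' @param categories character/factor vector of category labels, parallel
#'   to the unit universe.
#' @return data.frame `category`, `log2_ratio`, `n_units`.
#' @export
enrichment <- function(test_counts, control_counts, categories) {
  if (!is.null(names(test_counts)) && !is.null(names(control_counts))) {
    control_counts <- control_counts[names(test_counts)]
  }
  stopifnot(length(test_counts) == length(control_counts),
            length(categories) == length(test_counts))
  cats <- unique(as.character(categories))
  res <- lapply(cats, function(cc) {
    i <- which(categories == cc)
    st <- sum(test_counts[i]); sc <- sum(control_counts[i])
    data.frame(category = cc,
               log2_ratio = if (sc > 0) log2(st / sc) else NA_real_,
               n_units = length(i), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (anyNA(out$log2_ratio)) {
    warning(sum(is.na(out$log2_ratio)),
            " categor(ies) with zero control tags reported as NA")
  }
  out
}

#' Bootstrap confidence intervals for category enrichment
#'
#' Units (genes, or exons when the categories are exon classes) are
#' resampled with replacement within each category; for each of `n_boot`
#' draws the test/control ratio of summed counts is recomputed and the CI
#' is the central `level` percentile interval of those draws.  Draws with a
#' zero control sum are excluded (their number is reported via a message).
#' Uses the session RNG; call `set.seed()` for reproducibility.
#'
#' @inheritParams enrichment
#' @param n_boot number of bootstrap draws (default 1000; at least 100).
#' @param level CI level as a fraction (default 0.95).
#' @return the [enrichment()] table with added `ci_low` and `ci_high`
#'   columns (log2 scale).
#' @export
bootstrap_ci <- function(test_counts, control_counts, categories,
                         n_boot = 1000L, level = 0.95) {
  if (n_boot < 100L) stop("n_boot must be >= 100")
  if (!is.null(names(test_counts)) && !is.null(names(control_counts))) {
    control_counts <- control_counts[names(test_counts)]
  }
  out <- suppressWarnings(enrichment(test_counts, control_counts, categories))
  out$ci_low <- out$ci_high <- NA_real_
  dropped <- 0L
  for (r in seq_len(nrow(out))) {
    i <- which(categories == out$category[r])
    n <- length(i)
    draws <- matrix(sample(i, n * n_boot, replace = TRUE), nrow = n)
    st <- colSums(matrix(test_counts[draws], nrow = n))
    sc <- colSums(matrix(control_counts[draws], nrow = n))
    ok <- sc > 0
    dropped <- dropped + sum(!ok)
    if (!any(ok)) next
    q <- stats::quantile(log2(st[ok] / sc[ok]),
                         c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE, na.rm = TRUE)
    out$ci_low[r] <- q[1L]
    out$ci_high[r] <- q[2L]
  }
  if (dropped) message(dropped, " bootstrap draw(s) with zero control sum excluded")
  out
}

#' Enrichment as a function of exon length
#'
#' Exons are grouped into length bins and per-bin enrichment over control is
#' computed with bootstrap CIs over exons.
#'
#' @param lengths numeric vector of exon lengths (nt).
#' @param test_counts,control_counts per-exon tag counts, parallel to
#'   `lengths`.
#' @param breaks increasing numeric vector of bin edges (passed to `cut`;
#'   values outside the edges are dropped).
#' @param n_boot bootstrap draws per bin (default 1000).
#' @param level CI level (default 0.95).
#' @return data.frame `category` (the length bin), `log2_ratio`, `n_units`,
#'   `ci_low`, `ci_high`, ordered by bin; empty bins are absent.
#' @export
exon_length_bins <- function(lengths, test_counts, control_counts, breaks,
                             n_boot = 1000L, level = 0.95) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("bin edges must be strictly increasing")
  }
  bin <- cut(lengths, breaks = breaks, right = FALSE, dig.lab = 8L)
  keep <- !is.na(bin)
  res <- bootstrap_ci(test_counts[keep], control_counts[keep],
                      as.character(bin[keep]), n_boot = n_boot, level = level)
  res[order(match(res$category, levels(bin))), , drop = FALSE]
}
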