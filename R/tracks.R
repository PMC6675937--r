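#' Stranded single-nucleotide crosslink track
#'
#' A `clip_track` is the universal iCLIP signal object: a sparse map from
#' (chromosome, strand, position) to a positive tag count.  Positions use the
#' package-wide 0-based, half-open convention, so a tag at `pos = p` occupies
#' the single base `[p, p + 1)`.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based positions.
#' @param strand character vector of strands, `"+"` or `"-"`.
#' @param count integer vector of tag counts (default 1 per entry).  Entries
#'   at the same (chrom, strand, pos) are summed.
#'
#' @return A data.frame of class `clip_track` with columns `chrom`, `strand`,
#'   `pos` and `count`, sorted by chromosome, strand and position, holding
#'   only strictly positive counts.
#' @examples
#' tr <- clip_track(c("chr1", "chr1"), c(100L, 100L), c("+", "+"))
#' track_total(tr)  # 2 tags collapsed onto one base
#' @export
clip_track <- function(chrom = character(), pos = integer(),
                       strand = character(), count = NULL) {
  if (is.null(count)) count <- rep(1L, length(pos))
  stopifnot(length(chrom) == length(pos), length(strand) == length(pos),
            length(count) == length(pos))
  if (any(pos < 0)) stop("crosslink positions must be >= 0")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  key <- paste(chrom, strand, pos, sep = "\r")
  agg <- rowsum(as.numeric(count), key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  df <- data.frame(
    chrom  = vapply(parts, `[`, "", 1L),
    strand = vapply(parts, `[`, "", 2L),
    pos    = as.integer(vapply(parts, `[`, "", 3L)),
    count  = as.integer(agg[, 1L]),
    stringsAsFactors = FALSE
  )
  df <- df[df$count > 0L, , drop = FALSE]
  df <- df[order(df$chrom, df$strand, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("clip_track", "data.frame")
  df
}

#' @export
print.clip_track <- function(x, ...) {
  cat(sprintf("clip_track: %d tags at %d bases on %d chromosome/strand pair(s)\n",
              track_total(x), nrow(x),
              nrow(unique(as.data.frame(x)[, c("chrom", "strand")]))))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Total number of tags in a track
#' @param track a [clip_track()].
#' @return integer total tag count.
#' @export
track_total <- function(track) {
  as.integer(sum(track$count))
}

#' Subset a track to one chromosome/strand
#' @keywords internal
track_slice <- function(track, chrom, strand = NULL) {
  keep <- track$chrom == chrom
  if (!is.null(strand)) keep <- keep & track$strand == strand
  track[keep, , drop = FALSE]
}

#' Count crosslink tags over intervals
#'
#' Counts tags whose position lies inside each half-open interval
#' `[start, end)`, optionally requiring the tag strand to match the interval
#' strand (the default; iCLIP signal is sense-stranded).
#'
#' @param track a [clip_track()].
#' @param intervals data.frame with columns `chrom`, `start`, `end` and, when
#'   `same_strand = TRUE`, `strand`.
#' @param same_strand count only tags on the interval's strand (default TRUE).
#' @return integer vector of per-interval tag counts, parallel to
#'   `intervals` rows.
#' @examples
#' tr <- clip_track("chr1", 100L, "+")
#' iv <- data.frame(chrom = "chr1", strand = "+", start = 100L, end = 101L)
#' count_tags(tr, iv)  # 1: boundary base included
#' @export
count_tags <- function(track, intervals, same_strand = TRUE) {
  n <- nrow(intervals)
  out <- integer(n)
  if (n == 0L || nrow(track) == 0L) return(out)
  grp_key <- if (same_strand) paste(intervals$chrom, intervals$strand)
             else intervals$chrom
  for (g in unique(grp_key)) {
    idx <- which(grp_key == g)
    iv1 <- intervals[idx, , drop = FALSE]
    sub <- if (same_strand)
      track_slice(track, iv1$chrom[1L], iv1$strand[1L])
    else
      track_slice(track, iv1$chrom[1L])
    if (nrow(sub) == 0L) next
    sub <- sub[order(sub$pos), , drop = FALSE]
    cs <- cumsum(as.numeric(sub$count))
    hi <- findInterval(iv1$end - 1L, sub$pos)    # tags with pos <= end - 1
    lo <- findInterval(iv1$start - 1L, sub$pos)  # tags with pos <= start - 1
    cnt <- ifelse(hi > 0L, cs[pmax(hi, 1L)], 0) - ifelse(lo > 0L, cs[pmax(lo, 1L)], 0)
    out[idx] <- as.integer(cnt)
  }
  out
}

#' Write a track as one bedGraph file per strand
#'
#' @param track a [clip_track()].
#' @param prefix output path prefix; files `<prefix>_plus.bedgraph` and
#'   `<prefix>_minus.bedgraph` are written (0-based, half-open).
#' @return invisibly, the two file paths.
#' @export
write_track_bedgraph <- function(track, prefix) {
  paths <- c(paste0(prefix, "_plus.bedgraph"), paste0(prefix, "_minus.bedgraph"))
  for (i in 1:2) {
    s <- c("+", "-")[i]
    sub <- track[track$strand == s, , drop = FALSE]
    df <- data.frame(sub$chrom, sub$pos, sub$pos + 1L, sub$count)
    utils::write.table(df, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Write single-base tags as BED6 with the tag count in the score column
#' @param track a [clip_track()].
#' @param path output BED path.
#' @return invisibly, `path`.
#' @export
write_track_bed <- function(track, path) {
  df <- data.frame(track$chrom, track$pos, track$pos + 1L,
                   name = ".", score = track$count, strand = track$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file of single-base tags back into a track
#' @param path BED path written by [write_track_bed()].
#' @return a [clip_track()].
#' @export
read_track_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  clip_track(bed[[1L]], as.integer(bed[[2L]]), bed[[6L]], as.integer(bed[[5L]]))
}
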