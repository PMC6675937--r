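#' Read deduplicated iCLIP/RNA-seq alignments from SAM or BAM
#'
#' Thin wrapper around Rsamtools that returns alignments as a plain
#' data.frame in the package's 0-based, half-open coordinates.  SAM input is
#' converted to BAM on the fly so the standard readers are always exercised.
#' Unmapped records are dropped (with a message); secondary and duplicate
#' flags are kept as columns so downstream steps can honour them.
#'
#' @param file path to a SAM or BAM file.
#' @return data.frame with columns `qname`, `flag`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open reference span including splice gaps),
#'   `cigar`, `mapq`, `nh` (NH tag, NA when absent), `secondary`,
#'   `duplicate`.
#' @export
read_alignments <- function(file) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    file <- Rsamtools::asBam(file, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    file,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "strand", "pos", "cigar", "mapq"),
      tag = "NH"
    )
  )[[1L]]
  mapped <- !is.na(res$pos)
  if (any(!mapped)) {
    message(sum(!mapped), " unmapped record(s) skipped")
  }
  nh <- res$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(res$pos))
  df <- data.frame(
    qname  = res$qname[mapped],
    flag   = res$flag[mapped],
    chrom  = as.character(res$rname)[mapped],
    strand = as.character(res$strand)[mapped],
    start  = res$pos[mapped] - 1L,
    cigar  = res$cigar[mapped],
    mapq   = res$mapq[mapped],
    nh     = nh[mapped],
    stringsAsFactors = FALSE
  )
  df$end <- df$start +
    GenomicAlignments::cigarWidthAlongReferenceSpace(df$cigar)
  df$secondary <- bitwAnd(df$flag, 256L) > 0L
  df$duplicate <- bitwAnd(df$flag, 1024L) > 0L
  df[, c("qname", "flag", "chrom", "strand", "start", "end",
         "cigar", "mapq", "nh", "secondary", "duplicate")]
}

#' Infer the crosslinked base of each alignment
#'
#' In iCLIP the crosslinked nucleotide is inferred from the read: if the
#' alignment contains a deletion from the reference, the deleted base closest
#' to the read's 5' end marks the crosslink; otherwise, in `"truncation"`
#' mode the base immediately 5' of the read start is used (cDNAs truncate at
#' the crosslink), while in `"center"` mode (appropriate for e.g. eIF4A3-style
#' libraries) the central aligned base is used.
#'
#' Insertions and soft-clips never count as deletions.  Sites that would fall
#' before position 0 are returned as NA (and counted in a message by
#' [build_track()]).
#'
#' @param alignments data.frame from [read_alignments()].
#' @param mode `"truncation"` or `"center"`.
#' @return data.frame with columns `chrom`, `strand`, `pos` (0-based; NA for
#'   skipped sites).
#' @examples
#' aln <- data.frame(chrom = "chr1", strand = "+", start = 1000L, end = 1030L,
#'                   cigar = "30M")
#' call_crosslink_site(aln, "truncation")$pos  # 999
#' @export
call_crosslink_site <- function(alignments, mode = c("truncation", "center")) {
  mode <- match.arg(mode)
  n <- nrow(alignments)
  pos <- rep(NA_integer_, n)
  if (n == 0L) {
    return(data.frame(chrom = character(), strand = character(),
                      pos = integer()))
  }
  minus <- alignments$strand == "-"
  dels <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    alignments$cigar, pos = alignments$start + 1L, ops = "D"
  )
  ndel <- lengths(dels)
  has_del <- ndel > 0L
  if (any(has_del)) {
    idx <- which(has_del)
    first_del <- vapply(idx, function(i) {
      r <- dels[[i]]
      if (minus[i]) max(IRanges::end(r)) - 1L   # 5'-most in read order
      else min(IRanges::start(r)) - 1L
    }, integer(1L))
    pos[idx] <- first_del
  }
  nod <- which(!has_del)
  if (length(nod)) {
    if (mode == "truncation") {
      pos[nod] <- ifelse(minus[nod],
                         alignments$end[nod],
                         alignments$start[nod] - 1L)
    } else {
      blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        alignments$cigar[nod], pos = alignments$start[nod] + 1L,
        ops = c("M", "=", "X")
      )
      pos[nod] <- vapply(seq_along(nod), function(k) {
        bl <- blocks[[k]]
        p <- unlist(Map(seq.int, IRanges::start(bl), IRanges::end(bl)),
                    use.names = FALSE)
        if (minus[nod[k]]) p <- rev(p)   # read 5' -> 3'
        as.integer(p[(length(p) + 1L) %/% 2L] - 1L)
      }, integer(1L))
    }
  }
  pos[!is.na(pos) & pos < 0L] <- NA_integer_
  data.frame(chrom = alignments$chrom, strand = alignments$strand, pos = pos,
             stringsAsFactors = FALSE)
}

#' Build a crosslink track from alignments
#'
#' Filters to mapped, primary, non-duplicate alignments, infers one
#' crosslink site per retained alignment via [call_crosslink_site()] and
#' accumulates them into a [clip_track()].
#'
#' @inheritParams call_crosslink_site
#' @return a [clip_track()]; its [track_total()] equals the number of
#'   retained alignments whose site was on-chromosome.
#' @export
build_track <- function(alignments, mode = c("truncation", "center")) {
  mode <- match.arg(mode)
  keep <- !alignments$secondary & !alignments$duplicate
  aln <- alignments[keep, , drop = FALSE]
  sites <- call_crosslink_site(aln, mode)
  bad <- is.na(sites$pos)
  if (any(bad)) message(sum(bad), " site(s) fell before position 0; skipped")
  sites <- sites[!bad, , drop = FALSE]
  clip_track(sites$chrom, sites$pos, sites$strand)
}
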