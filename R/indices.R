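# Splicing index (SI) from junction-spanning read classes and processing
# index (PI) from tag counts around terminal poly(A) sites.

#' Annotated exon-exon junctions of each gene
#'
#' One row per unique (gene, intron) junction, with its rank on the
#' transcript strand: `first` if it is the 5'-most junction of any
#' transcript, else `last` if the 3'-most, else `internal`.
#'
#' @param models a [gene_models()] object.
#' @return data.frame `gene_id`, `chrom`, `strand`, `start`, `end` (the
#'   intron, 0-based half-open), `rank`.
#' @export
transcript_junctions <- function(models) {
  intr <- transcript_introns(models)
  if (nrow(intr) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), rank = character()))
  }
  intr$rank <- "internal"
  for (i in split(seq_len(nrow(intr)), intr$transcript_id)) {
    o <- i[order(intr$start[i])]
    if (intr$strand[o[1L]] == "-") o <- rev(o)
    intr$rank[o[1L]] <- "first"
    if (length(o) > 1L) intr$rank[o[length(o)]] <- "last"
  }
  key <- paste(intr$gene_id, intr$start, intr$end)
  pick <- unlist(lapply(split(seq_len(nrow(intr)), key), function(i) {
    r <- intr$rank[i]
    i[order(match(r, c("first", "internal", "last")))][1L]
  }), use.names = FALSE)
  out <- intr[sort(pick), c("gene_id", "chrom", "strand", "start", "end",
                            "rank"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify reads at annotated junctions
#'
#' Reads overlapping an intron are assigned to one of four classes:
#' Spliced (S) reads splice at exactly the annotated intron coordinates and
#' overlap both flanking exons; Exon-Intron (EI) reads align contiguously
#' across the 5' exon/intron boundary with at least `min_anchor` nt on each
#' side; Intron-Exon (IE) reads do the same at the intron/3' exon boundary;
#' anything else overlapping the intron is `other`.  Boundaries are strand
#' oriented (for a minus-strand gene the 5' exon is on the high-coordinate
#' side).  A read satisfying both EI and IE (an unspliced read spanning the
#' whole intron) is counted once, as EI.
#'
#' @param alignments data.frame from [read_alignments()]; secondary and
#'   duplicate records are ignored.
#' @param junctions data.frame from [transcript_junctions()].
#' @param min_anchor minimum aligned nt on each side of a boundary
#'   (default 3).
#' @param same_strand require read strand to match the gene strand
#'   (default TRUE).
#' @return `junctions` with added integer columns `S`, `EI`, `IE`, `other`.
#' @export
classify_junction_reads <- function(alignments, junctions, min_anchor = 3L,
                                    same_strand = TRUE) {
  aln <- alignments[!alignments$secondary & !alignments$duplicate, ,
                    drop = FALSE]
  out <- junctions
  out$S <- out$EI <- out$IE <- out$other <- 0L
  if (nrow(aln) == 0L || nrow(junctions) == 0L) return(out)
  gaps <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    aln$cigar, pos = aln$start + 1L, ops = "N")
  blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    aln$cigar, pos = aln$start + 1L, ops = c("M", "=", "X"))
  hits <- GenomicRanges::findOverlaps(
    .as_granges(junctions, stranded = FALSE),
    GenomicRanges::GRanges(aln$chrom, IRanges::IRanges(aln$start + 1L,
                                                       aln$end)))
  covers <- function(bl, lo, hi) {           # contiguous aligned [lo,hi)?
    any(IRanges::start(bl) - 1L <= lo & IRanges::end(bl) >= hi)
  }
  for (h in seq_along(hits)) {
    j <- S4Vectors::queryHits(hits)[h]
    i <- S4Vectors::subjectHits(hits)[h]
    if (same_strand && aln$strand[i] != junctions$strand[j]) next
    s <- junctions$start[j]; e <- junctions$end[j]
    g <- gaps[[i]]
    spliced_here <- length(g) &&
      any(IRanges::start(g) - 1L == s & IRanges::end(g) == e)
    if (spliced_here) { out$S[j] <- out$S[j] + 1L; next }
    bl <- blocks[[i]]
    a <- min_anchor
    if (junctions$strand[j] == "+") {
      ei <- covers(bl, s - a, s + a)
      ie <- covers(bl, e - a, e + a)
    } else {
      ei <- covers(bl, e - a, e + a)
      ie <- covers(bl, s - a, s + a)
    }
    if (ei) out$EI[j] <- out$EI[j] + 1L
    else if (ie) out$IE[j] <- out$IE[j] + 1L
    else out$other[j] <- out$other[j] + 1L
  }
  out
}

#' Splicing index
#'
#' SI = log2( 2 * sum(S) / sum(EI + IE) ) over the chosen junction subset
#' (a ratio of sums, robust to zero-count junctions).  SI > 0 indicates a
#' binding preference for spliced RNA.
#'
#' @param counts data.frame with columns `S`, `EI`, `IE` and, for
#'   `junction_subset = "first_only"`, `rank` (see
#'   [classify_junction_reads()]).
#' @param junction_subset `"all"` or `"first_only"` (restrict to each
#'   transcript's first junction).
#' @param per_junction if TRUE, return the per-junction SI distribution
#'   instead of the pooled value.
#' @return numeric SI (or a vector when `per_junction`); -Inf with a warning
#'   when no spliced reads are present; error when sum(EI + IE) is 0.
#' @examples
#' splicing_index(data.frame(S = 8, EI = 2, IE = 2))  # 2
#' @export
splicing_index <- function(counts, junction_subset = c("all", "first_only"),
                           per_junction = FALSE) {
  junction_subset <- match.arg(junction_subset)
  if (junction_subset == "first_only") {
    counts <- counts[counts$rank == "first", , drop = FALSE]
  }
  if (per_junction) {
    return(log2(2 * counts$S / (counts$EI + counts$IE)))
  }
  den <- sum(counts$EI) + sum(counts$IE)
  num <- 2 * sum(counts$S)
  if (den == 0) stop("no exon-intron/intron-exon reads: SI undefined")
  if (num == 0) {
    warning("no spliced reads: SI is -Inf")
    return(-Inf)
  }
  log2(num / den)
}

#' Select the terminal poly(A) site of each gene
#'
#' Picks, per gene, the 3'-most (strand-aware) poly(A) site that overlaps
#' any of the gene's expressed transcripts.  Genes without an overlapping
#' site are omitted (with a message).
#'
#' @param pa_sites data.frame of site intervals: `chrom`, `start`, `end`
#'   and optionally `strand` (matched to the gene strand when present).
#' @param models expressed-set [gene_models()].
#' @return data.frame `gene_id`, `chrom`, `strand`, `pa_pos`, where
#'   `pa_pos` is the 0-based boundary immediately 3' of the last transcribed
#'   base (the site interval's strand-aware 3' edge).
#' @export
select_terminal_pa <- function(pa_sites, models) {
  ex <- models$exons
  spans <- do.call(rbind, lapply(split(ex, ex$gene_id), function(e) {
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               strand = e$strand[1L], start = min(e$start),
               end = max(e$end), stringsAsFactors = FALSE)
  }))
  out <- NULL
  dropped <- 0L
  for (g in seq_len(nrow(spans))) {
    sp <- spans[g, ]
    cand <- pa_sites[pa_sites$chrom == sp$chrom &
                       pa_sites$end > sp$start & pa_sites$start < sp$end, ,
                     drop = FALSE]
    if ("strand" %in% names(cand) && nrow(cand)) {
      cand <- cand[cand$strand == sp$strand, , drop = FALSE]
    }
    if (!nrow(cand)) { dropped <- dropped + 1L; next }
    pa_pos <- if (sp$strand == "+") max(cand$end) else min(cand$start)
    out <- rbind(out, data.frame(gene_id = sp$gene_id, chrom = sp$chrom,
                                 strand = sp$strand, pa_pos = pa_pos,
                                 stringsAsFactors = FALSE))
  }
  if (dropped) message(dropped, " gene(s) without an overlapping poly(A) site omitted")
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), pa_pos = integer())
  }
  rownames(out) <- NULL
  out
}

#' Tag counts in windows around terminal poly(A) sites
#'
#' For each gene, counts tags in the strand-oriented `window`-nt windows
#' upstream (u, including the last transcribed base) and downstream (d) of
#' the poly(A) boundary.
#'
#' @param track a [clip_track()].
#' @param pa data.frame from [select_terminal_pa()].
#' @param window window size in nt (default 50).
#' @return `pa` with added integer columns `u` and `d`.
#' @export
pa_window_counts <- function(track, pa, window = 50L) {
  plus <- pa$strand == "+"
  up <- data.frame(chrom = pa$chrom, strand = pa$strand,
                   start = ifelse(plus, pa$pa_pos - window, pa$pa_pos),
                   end = ifelse(plus, pa$pa_pos, pa$pa_pos + window))
  dn <- data.frame(chrom = pa$chrom, strand = pa$strand,
                   start = ifelse(plus, pa$pa_pos, pa$pa_pos - window),
                   end = ifelse(plus, pa$pa_pos + window, pa$pa_pos))
  pa$u <- count_tags(track, up)
  pa$d <- count_tags(track, dn)
  pa
}

#' Processing index
#'
#' Signal upstream of the terminal poly(A) site comes from both processed
#' and unprocessed transcripts while downstream signal is unprocessed only,
#' so u - d estimates the processed contribution and
#' PI = log2( sum(d) / sum(u - d) ).  High PI indicates binding before 3'
#' end cleavage.  Per-gene processed estimates below zero are clamped to 0
#' (their count is reported via a message).
#'
#' @param counts data.frame with per-gene columns `u` and `d` (see
#'   [pa_window_counts()]).
#' @return numeric PI; -Inf with a warning when sum(d) = 0; error when the
#'   summed processed estimate is not positive.
#' @examples
#' processing_index(data.frame(u = 10, d = 2))  # -2
#' @export
processing_index <- function(counts) {
  proc <- counts$u - counts$d
  n_clamped <- sum(proc < 0)
  if (n_clamped) {
    message(n_clamped, " gene(s) with d > u clamped to processed estimate 0")
    proc <- pmax(proc, 0)
  }
  den <- sum(proc)
  num <- sum(counts$d)
  if (den <= 0) stop("summed processed estimate is not positive: PI undefined")
  if (num == 0) {
    warning("no downstream tags: PI is -Inf (fully processed)")
    return(-Inf)
  }
  log2(num / den)
}
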