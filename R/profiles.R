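# Metagene profiles: whole genes with scaled flanks, 5'UTR/CDS/3'UTR with
# RNA-seq normalization, and exon-exon junction windows.

# bin totals of a per-base vector into nb equal bins (internal)
.bin_vector <- function(x, nb) {
  L <- length(x)
  idx <- pmin(floor(seq_len(L) * nb / L - 1e-9), nb - 1L) + 1L
  out <- numeric(nb)
  acc <- rowsum(as.numeric(x), idx)
  out[as.integer(rownames(acc))] <- acc[, 1L]
  out
}

#' Whole-gene metagene profile with scaled flanks
#'
#' Each gene's merged exons are divided into `n_bins` bins; flanking regions
#' are covered by `n_flank_bins` bins whose width equals the gene's exonic
#' bin width, so flanks scale with the gene.  Per-gene profiles are
#' normalized to their total over all three regions (genes with zero tags
#' are excluded) and summed across genes.
#'
#' @param track a [clip_track()].
#' @param models expressed [gene_models()] (protein-coding transcripts).
#' @param n_bins number of exonic bins (default 100).
#' @param n_flank_bins number of bins per flank (default 25).
#' @param area_normalize divide the final profile by its sum (default
#'   FALSE: the raw across-gene sum is returned).
#' @return data.frame `bin` (1..2*n_flank_bins+n_bins, 5' to 3'), `region`
#'   (`upstream`/`exons`/`downstream`), `value`; attribute `n_genes` gives
#'   the number of contributing genes.
#' @export
gene_profile <- function(track, models, n_bins = 100L, n_flank_bins = 25L,
                         area_normalize = FALSE) {
  if (n_bins < 1L) stop("n_bins must be >= 1")
  regs <- gene_regions(models)
  regs <- regs[regs$type == "exonic", , drop = FALSE]
  total <- numeric(2L * n_flank_bins + n_bins)
  n_genes <- 0L
  for (i in split(seq_len(nrow(regs)), regs$gene_id)) {
    reg <- regs[i, , drop = FALSE]
    minus <- reg$strand[1L] == "-"
    x <- .region_counts(track, reg)$counts
    if (minus) x <- rev(x)
    Lg <- length(x)
    w <- Lg / n_bins
    exonic <- .bin_vector(x, n_bins)
    gstart <- min(reg$start); gend <- max(reg$end)
    flank_len <- ceiling(n_flank_bins * w)
    flank_bins <- function(lo, hi, toward_gene) {
      sub <- track_slice(track, reg$chrom[1L], reg$strand[1L])
      sub <- sub[sub$pos >= lo & sub$pos < hi, , drop = FALSE]
      v <- numeric(n_flank_bins)
      if (!nrow(sub)) return(v)
      dist <- if (toward_gene == "right") (hi - 1L) - sub$pos
              else sub$pos - lo    # distance from the gene edge
      b <- floor(dist / w)
      keep <- b < n_flank_bins
      if (any(keep)) {
        acc <- rowsum(as.numeric(sub$count[keep]), b[keep] + 1L)
        v[as.integer(rownames(acc))] <- acc[, 1L]
      }
      v
    }
    if (!minus) {
      up <- flank_bins(gstart - flank_len, gstart, "right")
      dn <- flank_bins(gend, gend + flank_len, "left")
    } else {
      up <- flank_bins(gend, gend + flank_len, "left")
      dn <- flank_bins(gstart - flank_len, gstart, "right")
    }
    # flank_bins indexes by distance from the gene edge; flip the upstream
    # flank so the display runs 5' -> 3'
    prof <- c(rev(up), exonic, dn)
    tot <- sum(prof)
    if (tot == 0) next
    total <- total + prof / tot
    n_genes <- n_genes + 1L
  }
  if (area_normalize && sum(total) > 0) total <- total / sum(total)
  out <- data.frame(
    bin = seq_along(total),
    region = rep(c("upstream", "exons", "downstream"),
                 c(n_flank_bins, n_bins, n_flank_bins)),
    value = total
  )
  attr(out, "n_genes") <- n_genes
  out
}

#' Split transcripts into 5'UTR, CDS and 3'UTR intervals
#'
#' @param models a [gene_models()] object whose `cds` table is set.
#' @return data.frame `gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `start`, `end`, `region` (`utr5`/`cds`/`utr3`); transcripts without CDS
#'   are omitted.
#' @export
utr_cds_regions <- function(models) {
  if (is.null(models$cds)) stop("gene models carry no CDS annotation")
  ex <- models$exons
  cds <- models$cds
  out <- lapply(split(seq_len(nrow(ex)), ex$transcript_id), function(i) {
    e <- ex[i, , drop = FALSE]
    cc <- cds[cds$transcript_id == e$transcript_id[1L], , drop = FALSE]
    if (!nrow(cc)) return(NULL)
    cmin <- min(cc$start); cmax <- max(cc$end)
    minus <- e$strand[1L] == "-"
    pieces <- NULL
    add <- function(s, en, lab) {
      if (en > s) rbind(pieces, data.frame(
        gene_id = e$gene_id[1L], transcript_id = e$transcript_id[1L],
        chrom = e$chrom[1L], strand = e$strand[1L], start = s, end = en,
        region = lab, stringsAsFactors = FALSE)) else pieces
    }
    for (k in seq_len(nrow(e))) {
      s <- e$start[k]; en <- e$end[k]
      pieces <- add(s, min(en, cmin), if (minus) "utr3" else "utr5")
      pieces <- add(max(s, cmin), min(en, cmax), "cds")
      pieces <- add(max(s, cmax), en, if (minus) "utr5" else "utr3")
    }
    pieces
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# per-transcript normalized region profile of one track (internal)
.region_profile_track <- function(track, regions, bins) {
  nb_tot <- sum(bins)
  total <- numeric(nb_tot)
  n_tx <- 0L
  skipped <- 0L
  for (i in split(seq_len(nrow(regions)), regions$transcript_id)) {
    rr <- regions[i, , drop = FALSE]
    if (!all(names(bins) %in% rr$region)) { skipped <- skipped + 1L; next }
    prof <- numeric(0)
    for (nm in names(bins)) {
      reg <- rr[rr$region == nm, , drop = FALSE]
      x <- .region_counts(track, reg)$counts
      if (reg$strand[1L] == "-") x <- rev(x)
      v <- .bin_vector(x, bins[[nm]])
      prof <- c(prof, v / (length(x) / bins[[nm]]))  # per-nt bin density
    }
    tot <- sum(prof)
    if (tot == 0) next
    total <- total + prof / tot
    n_tx <- n_tx + 1L
  }
  if (skipped) message(skipped, " transcript(s) lacking a region skipped")
  list(profile = total, n = n_tx)
}

#' UTR/CDS/UTR metagene profile normalized by RNA-seq
#'
#' Each transcript's 5'UTR, CDS and 3'UTR are binned (default 20/100/70
#' bins), bin counts are divided by the bin's genomic size, the transcript
#' profile is normalized to sum 1 and profiles are summed over transcripts.
#' The identical procedure is applied to an RNA-seq track and the final
#' profile is the elementwise iCLIP/RNA-seq ratio, which controls for UTR
#' mis-annotation.
#'
#' @param track iCLIP [clip_track()].
#' @param rnaseq_track RNA-seq signal as a [clip_track()] (e.g. read 5'
#'   ends or per-base coverage collapsed to counts).
#' @param regions data.frame from [utr_cds_regions()].
#' @param bins named integer vector of bin counts for `utr5`, `cds`, `utr3`.
#' @return data.frame `bin`, `region`, `iclip`, `rnaseq`, `value` (the
#'   ratio; NA with a warning where the RNA-seq bin is empty).
#' @export
region_profile <- function(track, rnaseq_track, regions,
                           bins = c(utr5 = 20L, cds = 100L, utr3 = 70L)) {
  icl <- .region_profile_track(track, regions, bins)
  rna <- .region_profile_track(rnaseq_track, regions, bins)
  ratio <- rep(NA_real_, length(icl$profile))
  ok <- rna$profile > 0
  ratio[ok] <- icl$profile[ok] / rna$profile[ok]
  if (any(!ok & icl$profile > 0)) {
    warning(sum(!ok & icl$profile > 0),
            " bin(s) with iCLIP signal but empty RNA-seq set to NA")
  }
  data.frame(
    bin = seq_along(ratio),
    region = rep(names(bins), bins),
    iclip = icl$profile, rnaseq = rna$profile, value = ratio
  )
}

#' Crosslink profile around internal exon-exon junctions
#'
#' For every internal junction (first and last junctions of each transcript
#' excluded) whose flanking exons are both at least `flank` nt long, tags
#' within `flank` nt of the junction are counted in transcript coordinates.
#' Offset 0 is the first base of the downstream exon and offset -1 the last
#' base of the upstream exon, so an EJC-like peak 24 nt into the upstream
#' exon appears at offset -24.  Each junction is normalized to its window
#' total (zero-tag junctions are skipped), summed, and the profile
#' normalized to sum 1.
#'
#' @param track a [clip_track()].
#' @param models a [gene_models()] object.
#' @param flank window half-width and minimum flanking-exon length
#'   (default 100).
#' @return data.frame `offset` (-flank .. flank-1), `value`; attribute
#'   `n_junctions` gives the number of contributing junctions.
#' @export
junction_profile <- function(track, models, flank = 100L) {
  ex <- models$exons
  juncs <- NULL
  for (i in split(seq_len(nrow(ex)), ex$transcript_id)) {
    e <- ex[i, , drop = FALSE]
    ne <- nrow(e)
    if (ne < 4L) next                      # no internal junction otherwise
    e <- e[order(e$start), , drop = FALSE]
    ord <- if (e$strand[1L] == "-") rev(seq_len(ne)) else seq_len(ne)
    jj <- seq_len(ne - 1L)[-c(1L, ne - 1L)]  # internal junction indices
    for (j in jj) {
      up <- e[ord[j], ]; dn <- e[ord[j + 1L], ]
      if (up$end - up$start < flank || dn$end - dn$start < flank) next
      juncs <- rbind(juncs, data.frame(
        chrom = up$chrom, strand = up$strand,
        up_start = up$start, up_end = up$end,
        dn_start = dn$start, dn_end = dn$end, stringsAsFactors = FALSE))
    }
  }
  prof <- numeric(2L * flank)
  n_junc <- 0L
  if (!is.null(juncs)) {
    juncs <- unique(juncs)
    for (j in seq_len(nrow(juncs))) {
      jc <- juncs[j, ]
      sub <- track_slice(track, jc$chrom, jc$strand)
      if (jc$strand == "+") {
        upk <- sub$pos >= jc$up_end - flank & sub$pos < jc$up_end
        dnk <- sub$pos >= jc$dn_start & sub$pos < jc$dn_start + flank
        off <- c(sub$pos[upk] - jc$up_end, sub$pos[dnk] - jc$dn_start)
      } else {
        upk <- sub$pos >= jc$up_start & sub$pos < jc$up_start + flank
        dnk <- sub$pos >= jc$dn_end - flank & sub$pos < jc$dn_end
        off <- c(jc$up_start - 1L - sub$pos[upk],
                 jc$dn_end - 1L - sub$pos[dnk])
      }
      cnt <- c(sub$count[upk], sub$count[dnk])
      if (!length(cnt) || sum(cnt) == 0) next
      v <- numeric(2L * flank)
      acc <- rowsum(as.numeric(cnt), off + flank + 1L)
      v[as.integer(rownames(acc))] <- acc[, 1L]
      prof <- prof + v / sum(v)
      n_junc <- n_junc + 1L
    }
  }
  if (sum(prof) > 0) prof <- prof / sum(prof)
  out <- data.frame(offset = seq(-flank, flank - 1L), value = prof)
  attr(out, "n_junctions") <- n_junc
  out
}
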