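#' Gene model container
#'
#' Multi-isoform gene models are held as plain exon (and optionally CDS)
#' tables in 0-based, half-open coordinates.  This is the input to chunking,
#' junction and profile machinery.
#'
#' @param exons data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` and optionally `biotype`.
#' @param cds optional data.frame with columns `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` (per-transcript coding intervals).
#' @return list of class `gene_models` with elements `exons` and `cds`.
#' @export
gene_models <- function(exons, cds = NULL) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(exons))) {
    stop("exons must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(exons$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(exons$end <= exons$start)) stop("empty or reversed exon intervals")
  if (!"biotype" %in% names(exons)) exons$biotype <- "protein_coding"
  exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  # within a transcript exons must not overlap
  ok <- tapply(seq_len(nrow(exons)), exons$transcript_id, function(i) {
    e <- exons[i, , drop = FALSE]
    all(e$start[-1L] >= e$end[-length(i)]) || length(i) == 1L
  })
  if (!all(unlist(ok))) stop("overlapping exons within a transcript")
  structure(list(exons = exons, cds = cds), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d gene(s), %d transcript(s), %d exon row(s)\n",
              length(unique(x$exons$gene_id)),
              length(unique(x$exons$transcript_id)), nrow(x$exons)))
  invisible(x)
}

# GRanges view of a 0-based interval data.frame (internal)
.as_granges <- function(df, stranded = TRUE) {
  GenomicRanges::GRanges(
    df$chrom,
    IRanges::IRanges(df$start + 1L, df$end),
    strand = if (stranded && "strand" %in% names(df)) df$strand
             else rep("*", nrow(df))
  )
}

#' Read gene models from a GTF file (Ensembl attribute dialect)
#'
#' Uses rtracklayer; `exon` and `CDS` features are retained and converted to
#' the package's 0-based, half-open coordinates.
#'
#' @param path GTF file path.
#' @return a [gene_models()] object.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  biotype <- if ("gene_biotype" %in% names(md)) md$gene_biotype
             else rep("protein_coding", length(gr))
  df <- data.frame(
    gene_id = md$gene_id,
    transcript_id = md$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    biotype = biotype,
    type = md$type,
    stringsAsFactors = FALSE
  )
  exons <- df[df$type == "exon", names(df) != "type", drop = FALSE]
  cds <- df[df$type == "CDS", !names(df) %in% c("type", "biotype", "gene_id"),
            drop = FALSE]
  gene_models(exons, if (nrow(cds)) cds else NULL)
}

#' Write gene models as GTF (1-based, inclusive; Ensembl attributes)
#' @param models a [gene_models()] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gtf <- function(models, path) {
  fmt_row <- function(chrom, src, type, start, end, strand, attr) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, src, type, start + 1L, end, strand, attr)
  }
  e <- models$exons
  lines <- fmt_row(e$chrom, "iclipr", "exon", e$start, e$end, e$strand,
                   sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                           e$gene_id, e$transcript_id, e$biotype))
  if (!is.null(models$cds) && nrow(models$cds)) {
    cc <- models$cds
    gid <- e$gene_id[match(cc$transcript_id, e$transcript_id)]
    lines <- c(lines, fmt_row(cc$chrom, "iclipr", "CDS", cc$start, cc$end,
                              cc$strand,
                              sprintf('gene_id "%s"; transcript_id "%s";',
                                      gid, cc$transcript_id)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Restrict gene models to expressed transcripts
#'
#' Keeps transcripts whose mean TPM strictly exceeds `tpm_threshold`, drops
#' genes left with no transcript, and drops genes on the mitochondrial
#' chromosome.
#'
#' @param models a [gene_models()] object.
#' @param tpm either a named numeric vector of per-transcript mean TPM, or a
#'   data.frame with a `transcript_id` column and one or more numeric sample
#'   columns (averaged).
#' @param tpm_threshold expression cutoff (default 1).
#' @param mito_chroms chromosome names treated as mitochondrial.
#' @return a filtered [gene_models()] object.
#' @export
filter_expressed <- function(models, tpm, tpm_threshold = 1,
                             mito_chroms = c("MT", "chrM", "M")) {
  ex <- models$exons
  if (is.data.frame(tpm)) {
    vals <- tpm[, setdiff(names(tpm), "transcript_id"), drop = FALSE]
    tpm <- stats::setNames(rowMeans(as.matrix(vals)), tpm$transcript_id)
  }
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  txs <- unique(ex$transcript_id)
  miss <- setdiff(txs, names(tpm))
  if (length(miss)) {
    stop("no expression entry for transcript(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  keep_tx <- names(tpm)[tpm > tpm_threshold]
  ex <- ex[ex$transcript_id %in% keep_tx & !ex$chrom %in% mito_chroms, ,
           drop = FALSE]
  cds <- models$cds
  if (!is.null(cds)) {
    cds <- cds[cds$transcript_id %in% ex$transcript_id, , drop = FALSE]
    if (!nrow(cds)) cds <- NULL
  }
  gene_models(ex, cds)
}

#' Introns of every transcript
#' @param models a [gene_models()] object.
#' @return data.frame `gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open intron intervals).
#' @export
transcript_introns <- function(models) {
  ex <- models$exons
  out <- lapply(split(seq_len(nrow(ex)), ex$transcript_id), function(i) {
    e <- ex[i, , drop = FALSE]
    if (nrow(e) < 2L) return(NULL)
    e <- e[order(e$start), , drop = FALSE]
    data.frame(gene_id = e$gene_id[1L], transcript_id = e$transcript_id[1L],
               chrom = e$chrom[1L], strand = e$strand[1L],
               start = e$end[-nrow(e)], end = e$start[-1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), transcript_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer())
  }
  rownames(out) <- NULL
  out
}

#' Flatten each gene into its minimal set of non-overlapping chunks
#'
#' Chunk boundaries are the union of all exon start/end coordinates across a
#' gene's isoforms, so every isoform's exon set equals a union of whole
#' chunks and the chunks tile the gene span.
#'
#' @param models a [gene_models()] object.
#' @return data.frame `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `chunk_id`, sorted by gene then coordinate.
#' @examples
#' m <- gene_models(data.frame(gene_id = "g", transcript_id = "t",
#'                             chrom = "chr1", strand = "+",
#'                             start = c(0L, 200L), end = c(100L, 300L)))
#' build_chunks(m)$start  # 0 100 200
#' @export
build_chunks <- function(models) {
  ex <- models$exons
  out <- lapply(split(seq_len(nrow(ex)), ex$gene_id), function(i) {
    e <- ex[i, , drop = FALSE]
    b <- sort(unique(c(e$start, e$end)))
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               strand = e$strand[1L],
               start = b[-length(b)], end = b[-1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$chunk_id <- sprintf("%s:%d-%d", out$gene_id, out$start, out$end)
  rownames(out) <- NULL
  out
}

#' Classify chunks as exonic, intronic or ambiguous
#'
#' A chunk is an intron if it overlaps at least one intron of the expressed
#' transcript set but no exon of any isoform in the reference set; an exon if
#' it overlaps at least one expressed exon but no reference-set intron;
#' otherwise it is ambiguous.  Chunks overlapping more than one gene span are
#' removed.  Overlap means at least one shared base, on either strand (the
#' classification mirrors unstranded interval intersection).
#'
#' @param chunks data.frame from [build_chunks()].
#' @param reference_models full-annotation [gene_models()].
#' @param expressed_models expressed-set [gene_models()] (see
#'   [filter_expressed()]).
#' @return `chunks` with a `kind` column (`exon`/`intron`/`ambiguous`),
#'   multi-gene chunks dropped.
#' @export
classify_chunks <- function(chunks, reference_models, expressed_models) {
  ref_ex <- reference_models$exons
  spans <- do.call(rbind, lapply(split(ref_ex, ref_ex$gene_id), function(e) {
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               start = min(e$start), end = max(e$end),
               stringsAsFactors = FALSE)
  }))
  qgr <- .as_granges(chunks, stranded = FALSE)
  ngenes <- GenomicRanges::countOverlaps(qgr, .as_granges(spans, FALSE))
  chunks <- chunks[ngenes <= 1L, , drop = FALSE]
  qgr <- .as_granges(chunks, stranded = FALSE)

  n_ov <- function(subject) {
    if (is.null(subject) || nrow(subject) == 0L) return(integer(nrow(chunks)))
    GenomicRanges::countOverlaps(qgr, .as_granges(subject, FALSE))
  }
  ref_in <- transcript_introns(reference_models)
  exp_ex <- expressed_models$exons
  exp_in <- transcript_introns(expressed_models)

  hits_ref_exon <- n_ov(ref_ex) > 0L
  hits_ref_intron <- n_ov(ref_in) > 0L
  hits_exp_exon <- n_ov(exp_ex) > 0L
  hits_exp_intron <- n_ov(exp_in) > 0L

  kind <- rep("ambiguous", nrow(chunks))
  kind[hits_exp_intron & !hits_ref_exon] <- "intron"
  kind[hits_exp_exon & !hits_ref_intron] <- "exon"
  chunks$kind <- kind
  rownames(chunks) <- NULL
  chunks
}

#' Label exons of each transcript as first, middle or last
#'
#' Positions are on the transcript strand: the 5'-most exon is `first`.
#' Single-exon transcripts are labelled NA.
#'
#' @param models a [gene_models()] object.
#' @return the exon table with an added `exon_position` column.
#' @export
label_exon_positions <- function(models) {
  ex <- models$exons
  ex$exon_position <- NA_character_
  for (i in split(seq_len(nrow(ex)), ex$transcript_id)) {
    if (length(i) < 2L) next
    o <- i[order(ex$start[i])]
    if (ex$strand[o[1L]] == "-") o <- rev(o)
    ex$exon_position[o] <- c("first", rep("middle", length(o) - 2L), "last")
  }
  ex
}

#' Identify retained introns from isoform pairs
#'
#' For every ordered isoform pair (A, B) of a gene where every intron of A is
#' present with identical coordinates in B, any intron of B absent from A and
#' lying fully within A's span is a retained intron: sequence spliced out in
#' B but exonic in A.
#'
#' @param models a [gene_models()] object (may hold many genes).
#' @return data.frame `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   deduplicated and sorted; empty for genes with fewer than two isoforms.
#' @export
find_retained_introns <- function(models) {
  ex <- models$exons
  introns <- transcript_introns(models)
  empty <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer())
  res <- lapply(split(seq_len(nrow(ex)), ex$gene_id), function(i) {
    e <- ex[i, , drop = FALSE]
    txs <- unique(e$transcript_id)
    if (length(txs) < 2L) return(NULL)
    ikey <- lapply(txs, function(t) {
      ii <- introns[introns$transcript_id == t, , drop = FALSE]
      paste(ii$start, ii$end, sep = "-")
    })
    names(ikey) <- txs
    span <- lapply(txs, function(t) {
      range(c(e$start[e$transcript_id == t], e$end[e$transcript_id == t]))
    })
    names(span) <- txs
    hits <- character()
    for (a in txs) for (b in txs) {
      if (a == b) next
      if (!all(ikey[[a]] %in% ikey[[b]])) next
      extra <- setdiff(ikey[[b]], ikey[[a]])
      if (!length(extra)) next
      se <- do.call(rbind, strsplit(extra, "-", fixed = TRUE))
      s <- as.integer(se[, 1L]); en <- as.integer(se[, 2L])
      inside <- s >= span[[a]][1L] & en <= span[[a]][2L]
      hits <- c(hits, extra[inside])
    }
    if (!length(hits)) return(NULL)
    se <- do.call(rbind, strsplit(unique(hits), "-", fixed = TRUE))
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               strand = e$strand[1L],
               start = as.integer(se[, 1L]), end = as.integer(se[, 2L]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty)
  res <- res[order(res$gene_id, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write classified chunks as BED6 plus kind and exon-position columns
#'
#' @param chunks classified chunk table (see [classify_chunks()]); an
#'   `exon_position` column is included when present, `.` otherwise.
#' @param path output path (0-based BED).
#' @return invisibly, `path`.
#' @export
write_chunks_bed <- function(chunks, path) {
  pos <- if ("exon_position" %in% names(chunks)) {
    ifelse(is.na(chunks$exon_position), ".", chunks$exon_position)
  } else "."
  df <- data.frame(chunks$chrom, chunks$start, chunks$end, chunks$chunk_id,
                   0L, chunks$strand, chunks$kind, pos)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-gene regions for significance calling
#'
#' Each gene contributes one exonic region (its merged exons, concatenated)
#' and one region per intron of the merged-exon structure.
#'
#' @param models a [gene_models()] object.
#' @return data.frame `region_id`, `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `type` (`exonic`/`intron`); exonic regions may span several rows
#'   (one per merged exon), concatenated in genomic order.
#' @export
gene_regions <- function(models) {
  ex <- models$exons
  out <- lapply(split(seq_len(nrow(ex)), ex$gene_id), function(i) {
    e <- ex[i, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(e$start + 1L, e$end))
    ms <- IRanges::start(ir) - 1L; me <- IRanges::end(ir)
    g <- e$gene_id[1L]
    exonic <- data.frame(region_id = paste0(g, ":exonic"), gene_id = g,
                         chrom = e$chrom[1L], strand = e$strand[1L],
                         start = ms, end = me, type = "exonic",
                         stringsAsFactors = FALSE)
    if (length(ms) > 1L) {
      istart <- me[-length(me)]; iend <- ms[-1L]
      intr <- data.frame(
        region_id = sprintf("%s:intron%d", g, seq_along(istart)),
        gene_id = g, chrom = e$chrom[1L], strand = e$strand[1L],
        start = istart, end = iend, type = "intron",
        stringsAsFactors = FALSE)
      rbind(exonic, intr)
    } else exonic
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
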