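# Alternative polyadenylation summarised as expression-weighted transcript
# lengths per gene and their change between conditions.

#' Expression-weighted transcript length per gene and sample
#'
#' The weighted length of a gene in a sample is the average of its
#' transcript lengths weighted by transcript usage (TPM):
#' sum(TPM_t * L_t) / sum(TPM_t).  Genes with zero total abundance in a
#' sample get NA.
#'
#' @param expr long-format data.frame with columns `gene_id`,
#'   `transcript_id`, `length` (nt), `sample`, `tpm` and optionally
#'   `condition`.
#' @return data.frame `gene_id`, `sample`, `weighted_length` (nt; NA when
#'   the gene is unexpressed in the sample).
#' @examples
#' e <- data.frame(gene_id = "g", transcript_id = c("a", "b"),
#'                 length = c(1000, 2000), sample = "s1", tpm = c(9, 1))
#' weighted_length(e)$weighted_length  # 1100
#' @export
weighted_length <- function(expr) {
  stopifnot(all(c("gene_id", "transcript_id", "length", "sample", "tpm")
                %in% names(expr)))
  if (any(expr$tpm < 0)) stop("TPM values must be non-negative")
  if (any(expr$length <= 0)) stop("transcript lengths must be positive")
  key <- interaction(expr$gene_id, expr$sample, drop = TRUE)
  res <- lapply(split(seq_len(nrow(expr)), key), function(i) {
    tot <- sum(expr$tpm[i])
    data.frame(gene_id = expr$gene_id[i[1L]], sample = expr$sample[i[1L]],
               weighted_length = if (tot > 0)
                 sum(expr$tpm[i] * expr$length[i]) / tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-gene change in weighted transcript length between conditions
#'
#' log2( mean weighted length over condition-B samples / mean over
#' condition-A samples ).  Genes without a defined weighted length in
#' either condition are omitted.
#'
#' @param expr as in [weighted_length()], with a `condition` column.
#' @param cond_a,cond_b condition labels (A is the reference/denominator).
#' @return data.frame `gene_id`, `mean_length_a`, `mean_length_b`,
#'   `log2_ratio`.
#' @export
length_change <- function(expr, cond_a, cond_b) {
  stopifnot("condition" %in% names(expr))
  wl <- weighted_length(expr)
  cond <- expr$condition[match(wl$sample, expr$sample)]
  mean_by <- function(cc) {
    sub <- wl[cond == cc & !is.na(wl$weighted_length), , drop = FALSE]
    tapply(sub$weighted_length, sub$gene_id, mean)
  }
  ma <- mean_by(cond_a); mb <- mean_by(cond_b)
  genes <- intersect(names(ma), names(mb))
  data.frame(gene_id = genes,
             mean_length_a = as.numeric(ma[genes]),
             mean_length_b = as.numeric(mb[genes]),
             log2_ratio = log2(as.numeric(mb[genes]) / as.numeric(ma[genes])),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tally genes shortening or lengthening beyond a cutoff
#'
#' Reporting helper over [length_change()] output.
#'
#' @param changes data.frame from [length_change()].
#' @param cutoff absolute log2 change cutoff (default 0.1).
#' @return named integer vector with elements `shorter`, `unchanged`,
#'   `longer`.
#' @export
length_change_summary <- function(changes, cutoff = 0.1) {
  c(shorter = sum(changes$log2_ratio < -cutoff, na.rm = TRUE),
    unchanged = sum(abs(changes$log2_ratio) <= cutoff, na.rm = TRUE),
    longer = sum(changes$log2_ratio > cutoff, na.rm = TRUE))
}
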