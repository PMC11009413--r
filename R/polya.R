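## Poly(A) tail-length summarization and stratification by binding-site
## load. Only PASS-flagged tail estimates enter any summary.

#' Per-gene poly(A) summary: reads, RPM, mean and median tail length
#'
#' Only records with `qc == "PASS"` are used; `RPM = 1e6 * gene reads /
#' total PASS reads`. Genes with zero PASS reads are omitted, so RPM sums
#' to 1e6 over the reported genes.
#'
#' @param records a `polya_records` table.
#' @return data.frame `gene_id`, `n_reads`, `rpm`, `mean_tail`,
#'   `median_tail`.
#' @export
summarize_tails <- function(records) {
  ok <- records$qc == "PASS"
  rec <- records[ok, , drop = FALSE]
  if (!nrow(rec))
    return(data.frame(gene_id = character(), n_reads = integer(),
                      rpm = numeric(), mean_tail = numeric(),
                      median_tail = numeric(), stringsAsFactors = FALSE))
  n <- tapply(rec$tail_length, rec$gene_id, length)
  out <- data.frame(
    gene_id = names(n),
    n_reads = as.integer(n),
    rpm = 1e6 * as.numeric(n) / nrow(rec),
    mean_tail = as.numeric(tapply(rec$tail_length, rec$gene_id, mean)),
    median_tail = as.numeric(tapply(rec$tail_length, rec$gene_id,
                                    stats::median)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Bin genes by their number of binding sites
#'
#' Bins are the closed integer ranges 0, 1-2, 3-10, 11-30, and 31 or more
#' sites.
#'
#' @param summary per-gene summary (any data.frame with `gene_id`).
#' @param site_counts named integer vector of binding sites per gene
#'   (missing genes count 0).
#' @return `summary` with `n_sites` and an ordered `bs_bin` factor.
#' @export
bin_by_binding_sites <- function(summary, site_counts) {
  n <- site_counts[summary$gene_id]
  n[is.na(n)] <- 0L
  labels <- c("No BS", "1-2 BS", "3-10 BS", "11-30 BS", "31 or more BS")
  bin <- cut(as.integer(n), breaks = c(-1L, 0L, 2L, 10L, 30L, Inf),
             labels = labels)
  summary$n_sites <- as.integer(n)
  summary$bs_bin <- factor(bin, levels = labels, ordered = TRUE)
  summary
}

#' Spearman rank correlation of two summary columns
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `p` (two-sided), `n`.
#' @export
correlate <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  ct <- suppressWarnings(stats::cor.test(x[keep], y[keep],
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}
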