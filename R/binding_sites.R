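## Post-processing of called binding sites: canonical 9-nt expansion,
## crosslink maxima, the 20-event filter, feature hierarchy, gene
## assignment, binding-strength classification, and peak-peak overlap.

#' Expand raw called sites to the canonical 9-nt window
#'
#' Each raw site is replaced by a 9-nt interval centred on its crosslink
#' coordinate (the centre of a wider raw interval), clipped at the
#' transcript ends. Clipped sites narrower than 5 nt are dropped.
#'
#' @param sites `binding_sites` (raw caller output; any width).
#' @param models `transcript_models` giving transcript lengths.
#' @return a `binding_sites` table of expanded sites.
#' @export
expand_sites <- function(sites, models) {
  len <- transcript_length(models)
  unknown <- setdiff(sites$transcript_id, names(len))
  if (length(unknown)) fail("site on unknown transcript %s", unknown[1L])
  L <- len[sites$transcript_id]
  if (any(sites$start < 0L | sites$end > L))
    fail("raw site outside transcript %s",
         sites$transcript_id[which(sites$start < 0L | sites$end > L)[1L]])
  centre <- ifelse(sites$end - sites$start == 1L, sites$start,
                   as.integer(floor((sites$start + sites$end) / 2)))
  st <- pmax(centre - 4L, 0L)
  en <- pmin(centre + 5L, L)
  keep <- (en - st) >= 5L
  out <- sites[keep, , drop = FALSE]
  out$start <- as.integer(st[keep])
  out$end <- as.integer(en[keep])
  out$max_pos <- rep(NA_integer_, nrow(out))
  rownames(out) <- NULL
  out
}

#' Position of the crosslink maximum within one site
#'
#' The nucleotide with the highest crosslink-event count in
#' `[start, end)`; the leftmost is taken when several tie.
#'
#' @param start,end 0-based half-open site interval.
#' @param counts the transcript's full counts vector.
#' @return 0-based position of the maximum. All-zero sites are an error
#'   (sites must carry events).
#' @export
site_maximum <- function(start, end, counts) {
  win <- counts[(start + 1L):end]
  if (all(win == 0L)) fail("all-zero counts in site [%d, %d)", start, end)
  start + which.max(win) - 1L
}

#' Annotate sites with their maxima and total events from tracks
#'
#' @param sites `binding_sites`.
#' @param tracks `crosslink_tracks` (pooled over replicates).
#' @param models `transcript_models`.
#' @return `sites` with `max_pos` and `total_events` recomputed.
#' @export
annotate_sites <- function(sites, tracks, models) {
  pooled <- pool_tracks(tracks, models)
  n <- nrow(sites)
  mp <- integer(n); te <- integer(n)
  for (i in seq_len(n)) {
    cnt <- pooled[[sites$transcript_id[i]]]
    if (is.null(cnt)) fail("no track for transcript %s",
                           sites$transcript_id[i])
    mp[i] <- site_maximum(sites$start[i], sites$end[i], cnt)
    te[i] <- sum(cnt[(sites$start[i] + 1L):sites$end[i]])
  }
  sites$max_pos <- mp
  sites$total_events <- te
  sites
}

#' Drop sites carrying fewer than the minimum crosslink events
#'
#' The total for each site is the (re)computed sum of pooled track counts
#' over its interval; sites with fewer than `min_events` are removed.
#'
#' @param sites `binding_sites`.
#' @param tracks `crosslink_tracks` (pooled over replicates).
#' @param models `transcript_models`.
#' @param min_events minimum events per peak (default 20).
#' @return the filtered, annotated `binding_sites`.
#' @export
filter_min_events <- function(sites, tracks, models, min_events = 20L) {
  sites <- annotate_sites(sites, tracks, models)
  out <- sites[sites$total_events >= min_events, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlapping feature labels by the annotation hierarchy
#'
#' Priority: ncRNA > CDS > 3'UTR > 5'UTR > intron > other; a position with
#' no overlapping annotation is `intergenic`.
#'
#' @param labels character vector of feature labels overlapping one
#'   position (any of `"ncRNA"`, `"CDS"`, `"utr3"`, `"utr5"`, `"intron"`,
#'   `"other"`).
#' @return the single winning label.
#' @export
assign_feature <- function(labels) {
  hierarchy <- c("ncRNA", "CDS", "utr3", "utr5", "intron", "other")
  labels <- labels[labels %in% hierarchy]
  if (!length(labels)) return("intergenic")
  hierarchy[min(match(labels, hierarchy))]
}

#' Feature label of a transcript position
#'
#' @param model one-row `transcript_models` slice.
#' @param pos 0-based position on the transcript.
#' @return `"ncRNA"` for non-coding transcripts, else `"utr5"`, `"CDS"` or
#'   `"utr3"`.
#' @export
feature_of_position <- function(model, pos) {
  if (model$biotype == "ncRNA") return("ncRNA")
  b <- segment_bounds(model)
  hit <- which(pos >= b$start & pos < b$end)
  if (!length(hit)) fail("position %d outside transcript %s", pos,
                         model$transcript_id)
  c(utr5 = "utr5", cds = "CDS", utr3 = "utr3")[[b$segment[hit[1L]]]]
}

#' Assign sites to genes and collapse isoform duplicates
#'
#' Each site inherits the gene of its transcript; sites reported on
#' several isoforms of one gene with the identical interval are collapsed
#' to a single gene-level site (the one with the most events kept).
#'
#' @param sites `binding_sites`.
#' @param models `transcript_models` (transcript -> gene map).
#' @return `binding_sites` with `gene_id` filled and duplicates collapsed.
#' @export
assign_sites_to_genes <- function(sites, models) {
  g <- stats::setNames(models$gene_id, models$transcript_id)
  unknown <- setdiff(sites$transcript_id, names(g))
  if (length(unknown)) fail("site on unknown transcript %s", unknown[1L])
  sites$gene_id <- unname(g[sites$transcript_id])
  key <- paste(sites$gene_id, sites$start, sites$end, sites$condition,
               sep = "\r")
  ord <- order(key, -ifelse(is.na(sites$total_events), 0L,
                            sites$total_events))
  sites <- sites[ord, , drop = FALSE]
  out <- sites[!duplicated(key[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize binding per gene
#'
#' @param sites annotated, gene-assigned `binding_sites`.
#' @param genes universe of gene ids (genes without sites get zero rows).
#' @return data.frame `gene_id`, `n_sites`, `total_tags`,
#'   `max_peak_height`.
#' @export
summarize_gene_binding <- function(sites, genes) {
  tt <- tapply(sites$total_events, sites$gene_id, sum)
  mh <- tapply(sites$total_events, sites$gene_id, max)
  ns <- table(sites$gene_id)
  out <- data.frame(
    gene_id = genes,
    n_sites = as.integer(ifelse(genes %in% names(ns), ns[genes], 0L)),
    total_tags = as.integer(ifelse(genes %in% names(tt), tt[genes], 0L)),
    max_peak_height = as.integer(ifelse(genes %in% names(mh), mh[genes], 0L)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Classify gene binding strength by quartile ranks
#'
#' Among genes with at least one site: `high` if the gene is in the top 25%
#' by total tag count OR top 25% by maximal peak height; `low` if it is in
#' the bottom 25% of BOTH; `moderate` otherwise. Genes with no sites are
#' `low`. Quartiles are empirical; a value equal to the quantile falls in
#' the outer group.
#'
#' @param summaries output of [summarize_gene_binding()].
#' @return `summaries` with a `strength_class` column. Fewer than 4 genes
#'   with sites is an error (quartiles undefined).
#' @export
classify_gene_binding <- function(summaries) {
  with_sites <- summaries$n_sites > 0L
  if (sum(with_sites) < 4L)
    fail("need >= 4 genes with sites to define quartiles (got %d)",
         sum(with_sites))
  tags <- summaries$total_tags[with_sites]
  hts <- summaries$max_peak_height[with_sites]
  q_tags <- stats::quantile(tags, c(0.25, 0.75), names = FALSE)
  q_hts <- stats::quantile(hts, c(0.25, 0.75), names = FALSE)
  cls <- rep("moderate", sum(with_sites))
  cls[tags >= q_tags[2L] | hts >= q_hts[2L]] <- "high"
  cls[tags <= q_tags[1L] & hts <= q_hts[1L] &
        !(tags >= q_tags[2L] | hts >= q_hts[2L])] <- "low"
  summaries$strength_class <- "low"
  summaries$strength_class[with_sites] <- cls
  summaries
}

sites_granges <- function(sites, seqnames_universe = NULL) {
  lev <- unique(c(seqnames_universe, sites$transcript_id))
  GenomicRanges::GRanges(factor(sites$transcript_id, levels = lev),
                         IRanges::IRanges(sites$start + 1L, sites$end),
                         strand = "+")
}

#' Count overlaps of slopped sites with a second site set
#'
#' Each a-site is extended (`slop` nt both ways, clipped at transcript
#' bounds); a b-site counts as overlapping iff the intersection with the
#' extended interval is at least `min_overlap` nt (default: strictly more
#' than 1 nt).
#'
#' @param sites_a,sites_b `binding_sites` tables.
#' @param models `transcript_models` for clipping.
#' @param slop extension in nt on each side (default 20).
#' @param min_overlap minimum intersection in nt (default 2).
#' @return `sites_a` with `n_overlap` and `overlapping` columns.
#' @export
slop_and_overlap <- function(sites_a, sites_b, models, slop = 20L,
                             min_overlap = 2L) {
  len <- transcript_length(models)
  a <- sites_a
  a$start <- pmax(a$start - slop, 0L)
  a$end <- as.integer(pmin(a$end + slop, len[a$transcript_id]))
  uni <- unique(c(a$transcript_id, sites_b$transcript_id))
  hits <- GenomicRanges::countOverlaps(sites_granges(a, uni),
                                       sites_granges(sites_b, uni),
                                       minoverlap = min_overlap)
  sites_a$n_overlap <- as.integer(hits)
  sites_a$overlapping <- hits > 0L
  sites_a
}

#' Sites of one condition with no qualifying overlap in another
#'
#' An a-site is a-specific iff no b-site intersects it by at least
#' `min_overlap` nt (no slop applied).
#'
#' @param sites_a,sites_b `binding_sites` tables.
#' @param min_overlap minimum intersection in nt (default 2).
#' @return the a-specific subset of `sites_a`.
#' @export
condition_specific_sites <- function(sites_a, sites_b, min_overlap = 2L) {
  if (!nrow(sites_a)) return(sites_a)
  if (!nrow(sites_b)) return(sites_a)
  uni <- unique(c(sites_a$transcript_id, sites_b$transcript_id))
  hits <- GenomicRanges::countOverlaps(sites_granges(sites_a, uni),
                                       sites_granges(sites_b, uni),
                                       minoverlap = min_overlap)
  out <- sites_a[hits == 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}
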