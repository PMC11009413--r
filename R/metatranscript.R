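## Proportional metatranscript profiling: crosslink-event mass over 100
## percent-bins per mRNA segment (5'UTR, CDS, 3'UTR; 300 bins total), with
## the UAG trimer's positional background, and per-segment rank-sum
## comparisons between conditions.

segment_names <- c("utr5", "cds", "utr3")

# 0-based bin index (0..299) for every position of one transcript; NA for
# positions of empty segments (cannot occur: every position lies in some
# segment).
position_bins <- function(model) {
  b <- segment_bounds(model)
  L <- sum(b$end - b$start)
  bins <- integer(L)
  for (k in seq_len(3L)) {
    if (b$end[k] == b$start[k]) next
    p <- b$start[k]:(b$end[k] - 1L)
    rel <- pmin(floor(100 * (p - b$start[k]) / (b$end[k] - b$start[k])), 99)
    bins[p + 1L] <- (k - 1L) * 100L + as.integer(rel)
  }
  bins
}

#' Proportional metatranscript profile of crosslink events
#'
#' Every crosslink event at position `p` in segment `S` of length `L` maps
#' to percent-bin `floor(100 (p - segment_start) / L)` (clipped to 99) of
#' that segment. Each sample's track is first scaled to events-per-million
#' (equal weight per sample, not per read), bins are summed over
#' transcripts and samples, and the 300-bin vector is divided by its grand
#' total so it sums to 1. Empty segments contribute nothing.
#'
#' @param tracks `crosslink_tracks` (typically one condition).
#' @param models `transcript_models`.
#' @return object of class `metatranscript_profile`: list with `bins`
#'   (numeric 300), `condition`, `n_events` (raw events seen).
#' @export
metatranscript_profile <- function(tracks, models) {
  unknown <- setdiff(tracks$transcript_id, models$transcript_id)
  if (length(unknown))
    fail("track transcript %s absent from models", unknown[1L])
  binmap <- lapply(seq_len(nrow(models)), function(i)
    position_bins(models[i, , drop = FALSE]))
  names(binmap) <- models$transcript_id
  bins <- numeric(300L)
  n_events <- 0
  for (sid in unique(tracks$sample_id)) {
    sub <- tracks[tracks$sample_id == sid, , drop = FALSE]
    tot <- sum(vapply(sub$counts, sum, numeric(1L)))
    n_events <- n_events + tot
    if (tot == 0) next
    for (i in seq_len(nrow(sub))) {
      cnt <- sub$counts[[i]]
      nz <- which(cnt > 0L)
      if (!length(nz)) next
      bm <- binmap[[sub$transcript_id[i]]]
      contrib <- tapply(cnt[nz] * 1e6 / tot, bm[nz], sum)
      idx <- as.integer(names(contrib)) + 1L
      bins[idx] <- bins[idx] + as.numeric(contrib)
    }
  }
  if (sum(bins) > 0) bins <- bins / sum(bins)
  structure(list(bins = bins,
                 condition = paste(unique(tracks$condition), collapse = "+"),
                 n_events = n_events),
            class = "metatranscript_profile")
}

#' Positional UAG background over the metatranscript bins
#'
#' Counts TAG occurrences (by the trimer's first nucleotide) per
#' percent-bin across all transcript models, unnormalized.
#'
#' @param models `transcript_models`.
#' @return numeric vector of 300 total counts.
#' @export
uag_background <- function(models) {
  bins <- numeric(300L)
  for (i in seq_len(nrow(models))) {
    h <- gregexpr("TAG", models$sequence[i], fixed = TRUE)[[1L]]
    if (h[1L] == -1L) next
    bm <- position_bins(models[i, , drop = FALSE])
    idx <- bm[h] + 1L # h is 1-based start -> 0-based start = h - 1; bm[h-1+1]
    tb <- table(idx)
    bins[as.integer(names(tb))] <- bins[as.integer(names(tb))] + as.numeric(tb)
  }
  bins
}

#' Compare two conditions' metatranscript mass within one segment
#'
#' Two-sided Wilcoxon rank-sum test with continuity correction on the 100
#' per-percent normalized values of the named segment, one sample of 100
#' values per condition.
#'
#' @param tracks_a,tracks_b `crosslink_tracks` of the two conditions.
#' @param models shared `transcript_models`.
#' @param segment `"utr5"`, `"cds"` or `"utr3"`.
#' @return list with `p`, `segment`, and the two 100-bin vectors.
#' @export
compare_segment_distributions <- function(tracks_a, tracks_b, models,
                                          segment = c("cds", "utr5", "utr3")) {
  segment <- match.arg(segment)
  k <- match(segment, segment_names)
  idx <- ((k - 1L) * 100L + 1L):(k * 100L)
  a <- metatranscript_profile(tracks_a, models)$bins[idx]
  b <- metatranscript_profile(tracks_b, models)$bins[idx]
  p <- if (identical(a, b)) 1 else
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                        correct = TRUE))$p.value
  list(p = p, segment = segment, bins_a = a, bins_b = b)
}
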