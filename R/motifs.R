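## Positional trimer enrichment around binding-site maxima, hierarchical
## clustering of trimer profiles into the three spatial sets (UAG, U/A-rich,
## other), summarized set profiles, paired profile comparison, and
## UAG-upstream prevalence.

#' The 64 trimers over A/C/G/T in lexicographic order
#' @return character vector of length 64.
#' @export
all_trimers <- function() {
  b <- c("A", "C", "G", "T")
  apply(expand.grid(b, b, b)[, 3:1], 1L, paste, collapse = "")
}

#' Extract aligned sequence windows around site maxima
#'
#' Each window spans offsets `-flank .. +flank` around the site maximum
#' (plus two extra downstream nucleotides so the trimer starting at offset
#' `+flank` is countable); positions outside the transcript are padded with
#' `N` and contribute no trimer counts.
#'
#' @param sites `binding_sites` with `max_pos` filled.
#' @param models `transcript_models` providing the sequences.
#' @param flank half-width of the window in nt (default 51).
#' @return object of class `site_windows`: list with `windows` (character
#'   vector, each of length `2*flank + 3`), `flank`, `n`.
#' @export
extract_windows <- function(sites, models, flank = 51L) {
  if (any(is.na(sites$max_pos))) fail("site maxima must be computed first")
  seqs <- stats::setNames(models$sequence, models$transcript_id)
  len <- transcript_length(models)
  w <- 2L * flank + 3L
  out <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    tx <- sites$transcript_id[i]
    s <- seqs[[tx]]
    if (is.null(s)) fail("no model for transcript %s", tx)
    m <- sites$max_pos[i]
    from <- m - flank       # 0-based inclusive
    to <- m + flank + 2L    # 0-based inclusive
    lo <- max(from, 0L)
    hi <- min(to, len[[tx]] - 1L)
    body <- if (hi >= lo) substr(s, lo + 1L, hi + 1L) else ""
    out[i] <- paste0(strrep("N", lo - from), body, strrep("N", to - hi))
  }
  structure(list(windows = out, flank = as.integer(flank),
                 n = length(out)), class = "site_windows")
}

#' Positional trimer counts around site maxima
#'
#' `counts[t, p]` is the number of windows whose trimer starting at offset
#' `p` (offset of the trimer's first nucleotide from the site maximum,
#' `-flank .. +flank`) equals trimer `t`. Offsets whose trimer touches a
#' padded nucleotide are skipped for that window.
#'
#' @param windows a `site_windows` object.
#' @return object of class `trimer_matrix`: list with `counts` (64 x
#'   2*flank+1 integer matrix), `coverage` (windows contributing per
#'   offset), `positions`, `trimers`, `n_sites`.
#' @export
trimer_positional_counts <- function(windows) {
  if (windows$n < 1L) fail("need at least one window")
  flank <- windows$flank
  trimers <- all_trimers()
  npos <- 2L * flank + 1L
  counts <- matrix(0L, nrow = 64L, ncol = npos,
                   dimnames = list(trimers, as.character(-flank:flank)))
  coverage <- integer(npos)
  for (j in seq_len(npos)) {
    tri <- substr(windows$windows, j, j + 2L)
    ok <- !grepl("N", tri, fixed = TRUE)
    coverage[j] <- sum(ok)
    if (any(ok))
      counts[, j] <- as.integer(table(factor(tri[ok], levels = trimers)))
  }
  structure(list(counts = counts, coverage = coverage,
                 positions = -flank:flank, trimers = trimers,
                 n_sites = windows$n, enrichment = NULL),
            class = "trimer_matrix")
}

#' Median-normalize trimer frequency profiles into enrichment scores
#'
#' Each trimer's positional frequency profile is divided by its median
#' frequency across the window, yielding enrichment scores. Medians are
#' taken over fully covered offsets only (every window contributes), so
#' clipped-edge columns cannot distort them; rows whose raw median is 0 use
#' the median of (counts + 0.5) instead, keeping the statistic defined for
#' rare trimers without touching rows where the plain formula works.
#'
#' @param tm a `trimer_matrix` with counts filled.
#' @return `tm` with `enrichment` filled.
#' @export
normalize_to_median <- function(tm) {
  full <- tm$coverage == tm$n_sites
  if (!any(full)) full <- rep(TRUE, length(tm$coverage))
  enr <- matrix(0, nrow = nrow(tm$counts), ncol = ncol(tm$counts),
                dimnames = dimnames(tm$counts))
  for (t in seq_len(nrow(tm$counts))) {
    med <- stats::median(tm$counts[t, full])
    if (med == 0) med <- stats::median(tm$counts[t, full] + 0.5)
    enr[t, ] <- tm$counts[t, ] / med
  }
  tm$enrichment <- enr
  tm
}

#' Cluster trimer profiles into the three spatial sets
#'
#' Agglomerative hierarchical clustering (Euclidean distance, Ward linkage)
#' of the 64 enrichment profiles restricted to a window centred on the site
#' maximum; the dendrogram is cut into `k` subtrees. The subtree containing
#' `TAG` is labelled `uag`; among the remaining subtrees the one with the
#' largest mean enrichment over downstream offsets `+1 .. +(window-1)/2` is
#' `ua_rich`; everything else is `other`.
#'
#' @param tm a `trimer_matrix` with enrichment filled.
#' @param window width in nt of the clustering window (odd; default 31).
#' @param k number of subtrees to cut (default 3).
#' @return object of class `trimer_sets`: list with character vectors
#'   `uag`, `ua_rich`, `other` partitioning the 64 trimers. Identical rows
#'   throughout are an error (degenerate clustering).
#' @export
cluster_trimer_profiles <- function(tm, window = 31L, k = 3L) {
  if (is.null(tm$enrichment)) fail("run normalize_to_median() first")
  half <- (window - 1L) %/% 2L
  cols <- which(tm$positions >= -half & tm$positions <= half)
  m <- tm$enrichment[, cols, drop = FALSE]
  if (all(stats::dist(m) == 0))
    fail("all trimer profiles identical; clustering is degenerate")
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  grp <- stats::cutree(hc, k = k)
  down <- which(tm$positions[cols] >= 1L)
  uag_grp <- grp[["TAG"]]
  rest <- setdiff(unique(grp), uag_grp)
  down_mean <- vapply(rest, function(g)
    mean(m[grp == g, down, drop = FALSE]), numeric(1L))
  ua_grp <- if (length(rest)) rest[which.max(down_mean)] else integer(0)
  structure(list(
    uag = names(grp)[grp == uag_grp],
    ua_rich = names(grp)[grp %in% ua_grp],
    other = names(grp)[!grp %in% c(uag_grp, ua_grp)]
  ), class = "trimer_sets")
}

#' Mean enrichment profile of each trimer set
#'
#' @param tm a `trimer_matrix` with enrichment filled.
#' @param sets a `trimer_sets` partition.
#' @return numeric matrix with rows `uag`, `ua_rich`, `other` and one
#'   column per position: the arithmetic mean of the member trimers'
#'   enrichment at that position.
#' @export
summarize_sets <- function(tm, sets) {
  if (is.null(tm$enrichment)) fail("run normalize_to_median() first")
  out <- rbind(
    uag = colMeans(tm$enrichment[sets$uag, , drop = FALSE]),
    ua_rich = colMeans(tm$enrichment[sets$ua_rich, , drop = FALSE]),
    other = colMeans(tm$enrichment[sets$other, , drop = FALSE])
  )
  colnames(out) <- as.character(tm$positions)
  out
}

# Exact two-sided signed-rank p-value with midranks, by sign-flip DP over
# doubled ranks (exact even under ties, unlike the base exact method).
signed_rank_exact_p <- function(d) {
  r <- rank(abs(d)) # midranks; doubling makes them integers
  w <- as.integer(round(2 * r))
  v <- as.integer(round(sum(w[d > 0])))
  tot <- sum(w)
  # distribution of V2 = sum of doubled ranks of "positive" signs under
  # uniform sign flips
  probs <- numeric(tot + 1L); probs[1L] <- 1
  for (wi in w) {
    shifted <- c(rep(0, wi), probs[seq_len(tot + 1L - wi)])
    probs <- (probs + shifted) / 2
  }
  lower <- sum(probs[seq_len(v + 1L)])
  upper <- sum(probs[(v + 1L):(tot + 1L)])
  min(1, 2 * min(lower, upper))
}

#' Compare two positional set profiles (paired Wilcoxon signed-rank)
#'
#' Two-sided signed-rank test over positions, pairing the two profiles
#' position by position. Zero differences are dropped; for 25 or fewer
#' remaining pairs the exact sign-flip distribution (with midranks) is
#' used, above that the normal approximation with continuity correction.
#' All-zero differences give p = 1 with a warning.
#'
#' @param profile_a,profile_b numeric vectors of equal length.
#' @return list with `p`, `n` (pairs after zero removal), `method`.
#' @export
compare_set_profiles <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b))
    fail("profiles must have equal length")
  d <- profile_b - profile_a
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; p reported as 1")
    return(list(p = 1, n = 0L, method = "degenerate"))
  }
  if (length(d) <= 25L) {
    list(p = signed_rank_exact_p(d), n = length(d), method = "exact")
  } else {
    p <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                             correct = TRUE))$p.value
    list(p = p, n = length(d), method = "normal approximation")
  }
}

#' Fraction of sites with UAG just upstream of the maximum
#'
#' A site counts iff a `TAG` trimer starts within `[m - upstream, m - 1]`
#' for site maximum `m` (the trimer may extend past `m`).
#'
#' @param sites `binding_sites` with `max_pos` filled.
#' @param models `transcript_models` providing sequences.
#' @param upstream window size in nt (default 15).
#' @return fraction in `[0, 1]` of sites carrying an upstream UAG.
#' @export
uag_upstream_prevalence <- function(sites, models, upstream = 15L) {
  if (!nrow(sites)) return(NaN)
  seqs <- stats::setNames(models$sequence, models$transcript_id)
  hit <- vapply(seq_len(nrow(sites)), function(i) {
    m <- sites$max_pos[i]
    s <- seqs[[sites$transcript_id[i]]]
    lo <- max(m - upstream, 0L)           # first candidate start, 0-based
    if (m - 1L < lo) return(FALSE)
    win <- substr(s, lo + 1L, min(m + 1L, nchar(s) - 1L) + 1L)
    h <- gregexpr("TAG", win, fixed = TRUE)[[1L]]
    if (h[1L] == -1L) return(FALSE)
    any((lo + h - 1L) <= (m - 1L))
  }, logical(1L))
  mean(hit)
}
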