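## Reference-gene-normalized differential RNA abundance and ribosome
## occupancy. Because the RBP binds most expressed transcripts, global
## size-factor normalization is invalid; counts are instead scaled so that
## a fixed set of highly expressed, unbound reference genes sums to an
## arbitrary constant (40,000) in every sample. Testing is a self-contained
## negative-binomial Wald test on the normalized counts.

#' Gene-by-sample RPKM
#'
#' `RPKM = 1e9 * count / (sample total count * gene length)`; the gene
#' length is its longest isoform's mature transcript length.
#'
#' @param cm a `count_matrix`.
#' @param models `transcript_models` supplying isoform lengths.
#' @return numeric matrix parallel to `cm$counts`.
#' @export
compute_rpkm <- function(cm, models) {
  iso_len <- transcript_length(models)
  glen <- tapply(iso_len, models$gene_id, max)
  genes <- rownames(cm$counts)
  missing <- setdiff(genes, names(glen))
  if (length(missing)) fail("no transcript model for gene %s", missing[1L])
  libs <- colSums(cm$counts)
  sweep(sweep(cm$counts * 1e9, 2L, libs, "/"), 1L, glen[genes], "/")
}

#' Select reference genes for normalization
#'
#' Highly expressed genes (mean uninduced RPKM strictly above the
#' threshold) that carry no binding site in any condition.
#'
#' @param rpkm RPKM matrix restricted to uninduced samples.
#' @param bound_gene_ids gene ids bound in at least one condition.
#' @param rpkm_threshold expression cutoff (default 10, strict `>`).
#' @return character vector of reference gene ids; empty result is an
#'   error (relax the threshold or the simulation).
#' @export
select_reference_genes <- function(rpkm, bound_gene_ids,
                                   rpkm_threshold = 10) {
  mean_rpkm <- rowMeans(rpkm)
  ref <- rownames(rpkm)[mean_rpkm > rpkm_threshold &
                          !rownames(rpkm) %in% bound_gene_ids]
  if (!length(ref))
    fail(paste("no reference genes found; relax rpkm_threshold or the",
               "simulation's expression settings"))
  ref
}

#' Reference-gene normalization factors
#'
#' @param cm a `count_matrix`.
#' @param reference_genes non-empty set of reference gene ids present in
#'   `cm`.
#' @param scale the arbitrary scaling constant (default 40000).
#' @return object of class `normalization_factors`: list with
#'   `reference_genes`, `N` (per-sample raw reference total, all > 0),
#'   `scale`.
#' @export
normalization_factors <- function(cm, reference_genes, scale = 40000) {
  if (!length(reference_genes)) fail("reference set must be non-empty")
  missing <- setdiff(reference_genes, rownames(cm$counts))
  if (length(missing))
    fail("reference gene %s absent from count matrix", missing[1L])
  N <- colSums(cm$counts[reference_genes, , drop = FALSE])
  if (any(N <= 0)) fail("reference total is zero in sample %s",
                        names(N)[which(N <= 0)[1L]])
  structure(list(reference_genes = reference_genes, N = N, scale = scale),
            class = "normalization_factors")
}

#' Normalize counts to the reference-gene total
#'
#' `normalized = scale * R / N` with `R` the raw count of one gene in one
#' sample and `N` that sample's raw total over the reference genes; the
#' reference genes therefore sum exactly to `scale` in every sample.
#'
#' @param cm a `count_matrix`.
#' @param factors a `normalization_factors` object.
#' @return numeric matrix of normalized counts.
#' @export
normalize_counts <- function(cm, factors) {
  sweep(cm$counts * factors$scale, 2L, factors$N, "/")
}

#' Method-of-moments NB dispersion with median shrinkage
#'
#' Per gene, `alpha_hat = max((s^2 - mu) / mu^2, 1e-8)` where `s^2` is the
#' within-condition (residual) variance pooled across conditions and `mu`
#' the overall mean of normalized counts; the final estimate shrinks
#' halfway to the across-gene median:
#' `alpha = 0.5 alpha_hat + 0.5 median(alpha_hat)`.
#'
#' @param norm normalized count matrix.
#' @param design design data.frame with `condition` per column of `norm`.
#' @return named numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(norm, design) {
  cond <- design$condition
  if (any(table(cond) < 2L)) fail("need >= 2 replicates per condition")
  centred <- norm
  for (cn in unique(cond)) {
    j <- cond == cn
    centred[, j] <- norm[, j] - rowMeans(norm[, j, drop = FALSE])
  }
  df <- ncol(norm) - length(unique(cond))
  s2 <- rowSums(centred^2) / df
  mu <- rowMeans(norm)
  alpha_hat <- pmax((s2 - mu) / mu^2, 1e-8)
  alpha_hat[!is.finite(alpha_hat)] <- 1e-8
  0.5 * alpha_hat + 0.5 * stats::median(alpha_hat)
}

#' Negative-binomial Wald test between two conditions
#'
#' Per gene: `log2fc = log2((mean_b + 0.5) / (mean_a + 0.5))` on normalized
#' counts; the standard error comes from the delta method with NB variance
#' `mu + alpha mu^2` per observation; `wald_z = log2fc / se`; two-sided
#' normal p; Benjamini-Hochberg adjustment across tested genes.
#' Significance follows the assay convention: RNA requires `padj` below the
#' threshold and fold change above `fc_threshold`; RPF uses the unadjusted
#' `p`.
#'
#' @param norm normalized count matrix.
#' @param design design data.frame (`sample_id`, `condition`).
#' @param dispersion per-gene dispersion vector (e.g. from
#'   [estimate_dispersion()]).
#' @param condition_a,condition_b the two condition labels (fold change is
#'   b over a).
#' @param assay `"RNA"` or `"RPF"` (selects the significance rule).
#' @param alpha_threshold p/padj threshold (default 0.05; the stricter 0.01
#'   preset of some displays can be passed here).
#' @param fc_threshold minimum fold change (default 2).
#' @return data.frame of class `differential_results` with columns
#'   `gene_id`, `base_mean`, `log2fc`, `se`, `wald_z`, `p`, `padj`,
#'   `significant`.
#' @export
wald_test <- function(norm, design, dispersion, condition_a, condition_b,
                      assay = c("RNA", "RPF"), alpha_threshold = 0.05,
                      fc_threshold = 2) {
  assay <- match.arg(assay)
  ja <- design$condition == condition_a
  jb <- design$condition == condition_b
  if (sum(ja) < 2L || sum(jb) < 2L)
    fail("each condition needs >= 2 replicates")
  na <- sum(ja); nb <- sum(jb)
  ma <- rowMeans(norm[, ja, drop = FALSE])
  mb <- rowMeans(norm[, jb, drop = FALSE])
  c0 <- 0.5
  log2fc <- log2((mb + c0) / (ma + c0))
  va <- (ma + dispersion * ma^2) / na
  vb <- (mb + dispersion * mb^2) / nb
  se <- sqrt(va / ((ma + c0) * log(2))^2 + vb / ((mb + c0) * log(2))^2)
  se[se == 0] <- NA_real_
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))
  p[is.na(p)] <- 1
  padj <- stats::p.adjust(p, method = "BH")
  sig_p <- if (assay == "RNA") padj < alpha_threshold else p < alpha_threshold
  out <- data.frame(
    gene_id = rownames(norm),
    base_mean = (ma + mb) / 2,
    log2fc = log2fc, se = se, wald_z = z, p = p, padj = padj,
    significant = sig_p & abs(log2fc) > log2(fc_threshold),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "assay") <- assay
  attr(out, "alpha_threshold") <- alpha_threshold
  class(out) <- c("differential_results", "data.frame")
  out
}

#' Bin tested genes into regulation groups by strength and sense
#'
#' Genes passing the assay's p-value criterion (adjusted p for RNA, raw p
#' for RPF) are split by sense of regulation and |log2fc| strength:
#' RNA cuts at (0.5, 1, 2) giving g1-g4 (down, strongest to weakest) and
#' g5-g8 (up, weakest to strongest); RPF cuts at (1, 2) giving g1-g6. The
#' `twofold` column flags |log2fc| >= 1 (changes of two-fold or larger).
#'
#' @param results a `differential_results` table.
#' @param assay `"RNA"` or `"RPF"`; defaults to the table's assay.
#' @return `results` with `group` (NA for untested/non-passing genes) and
#'   `twofold` columns.
#' @export
bin_regulation_groups <- function(results, assay = attr(results, "assay")) {
  thr <- attr(results, "alpha_threshold") %||% 0.05
  pass <- if (assay == "RNA") results$padj < thr else results$p < thr
  cuts <- if (assay == "RNA") c(0.5, 1, 2) else c(1, 2)
  nbin <- length(cuts) + 1L
  strength <- findInterval(abs(results$log2fc), cuts) + 1L # 1..nbin, weak->strong
  group <- ifelse(results$log2fc < 0,
                  nbin + 1L - strength,        # g1 strongest down
                  nbin + strength)             # last group strongest up
  results$group <- ifelse(pass, sprintf("g%d", group), NA_character_)
  results$twofold <- pass & abs(results$log2fc) >= 1
  results
}

#' Translational efficiency ratios per gene
#'
#' The primary TER is the RPF fold change (ribosome occupancy ratio,
#' condition over baseline); an RNA-adjusted ratio (RPF fc / RNA fc) is
#' also emitted, together with a flag for genes with no significant RNA
#' change (the restriction used to separate translation from abundance
#' effects).
#'
#' @param rpf_results,rna_results `differential_results` tables for the
#'   same contrast.
#' @return data.frame `gene_id`, `rpf_fc`, `rna_fc`, `ter`,
#'   `ter_rna_adjusted`, `rna_stable`.
#' @export
ter <- function(rpf_results, rna_results) {
  i <- match(rpf_results$gene_id, rna_results$gene_id)
  rpf_fc <- 2^rpf_results$log2fc
  rna_fc <- 2^rna_results$log2fc[i]
  data.frame(
    gene_id = rpf_results$gene_id,
    rpf_fc = rpf_fc, rna_fc = rna_fc,
    ter = rpf_fc,
    ter_rna_adjusted = rpf_fc / rna_fc,
    rna_stable = !rna_results$significant[i] %in% TRUE,
    stringsAsFactors = FALSE
  )
}

#' Compare mature transcript lengths between two gene groups
#'
#' Two-sided two-sample Student t-test (pooled variance) on mature
#' transcript lengths (longest isoform per gene), with per-group n, mean,
#' and box-plot statistics (median, quartiles, whiskers at 1.5 IQR,
#' outliers omitted).
#'
#' @param genes_a,genes_b character vectors of gene ids.
#' @param models `transcript_models`.
#' @return list with `p`, `t`, `df`, and a `summary` data.frame (one row
#'   per group) with n, mean, and box-plot statistics.
#' @export
compare_group_lengths <- function(genes_a, genes_b, models) {
  iso_len <- transcript_length(models)
  glen <- tapply(iso_len, models$gene_id, max)
  la <- glen[intersect(genes_a, names(glen))]
  lb <- glen[intersect(genes_b, names(glen))]
  tt <- stats::t.test(la, lb, var.equal = TRUE)
  box <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    lw <- min(x[x >= q[1L] - 1.5 * iqr])
    uw <- max(x[x <= q[3L] + 1.5 * iqr])
    c(q1 = q[1L], median = q[2L], q3 = q[3L], whisker_lo = lw,
      whisker_hi = uw)
  }
  summary <- rbind(
    data.frame(group = "a", n = length(la), mean = mean(la),
               t(box(la))),
    data.frame(group = "b", n = length(lb), mean = mean(lb),
               t(box(lb)))
  )
  list(p = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter), summary = summary)
}
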