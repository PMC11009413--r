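# RPKM, reference-gene selection, 40000*R/N normalization, dispersion
# estimation, the NB Wald test, regulation groups, TER, and group-length
# comparison.

make_cm <- function(m, conds, assay = "RNA") {
  design <- data.frame(sample_id = colnames(m), condition = conds,
                       replicate = ave(seq_along(conds), conds,
                                       FUN = seq_along))
  count_matrix(m, design, assay = assay)
}

test_that("RPKM follows its defining formula", {
  models <- transcript_models(c("t1", "t2"), c("g1", "g2"), 0L,
                              c(999L, 300L), c(1L, 0L),
                              c(strrep("A", 1000), strrep("A", 300)))
  m <- matrix(c(100L, 999900L, 0L, 10000L), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cm <- make_cm(m, c("uninduced", "uninduced"))
  rpkm <- compute_rpkm(cm, models)
  expect_equal(rpkm["g1", "s1"], 1e9 * 100 / (1e6 * 1000))  # = 100
  expect_equal(rpkm["g1", "s1"], 100)
  expect_equal(rpkm["g1", "s2"], 0)
  # random oracle
  set.seed(81)
  models2 <- random_models(8, seed = 81)
  m2 <- matrix(rpois(16, 500), nrow = 8,
               dimnames = list(models2$gene_id, c("a", "b")))
  cm2 <- make_cm(m2, c("uninduced", "uninduced"))
  rpkm2 <- compute_rpkm(cm2, models2)
  glen <- setNames(transcript_length(models2), models2$gene_id)
  for (g in models2$gene_id) for (s in c("a", "b"))
    expect_equal(rpkm2[g, s], 1e9 * m2[g, s] / (sum(m2[, s]) * glen[[g]]))
})

test_that("reference genes are highly expressed and unbound, strictly", {
  rpkm <- matrix(c(10, 10, 50, 50, 10.01, 10.01, 3, 3), nrow = 4,
                 byrow = TRUE, dimnames = list(paste0("g", 1:4), NULL))
  ref <- select_reference_genes(rpkm, bound_gene_ids = character())
  expect_setequal(ref, c("g2", "g3"))      # 10.0 exactly is excluded
  ref2 <- select_reference_genes(rpkm, bound_gene_ids = "g2")
  expect_equal(ref2, "g3")                 # bound in any condition: excluded
  expect_error(select_reference_genes(rpkm, paste0("g", 1:4)), "reference")
  # random fixture vs brute-force set logic
  set.seed(82)
  rp <- matrix(runif(300, 0, 30), nrow = 100,
               dimnames = list(sprintf("g%03d", 1:100), NULL))
  bound <- sample(rownames(rp), 40)
  ref3 <- select_reference_genes(rp, bound)
  brute <- setdiff(rownames(rp)[rowMeans(rp) > 10], bound)
  expect_setequal(ref3, brute)
})

test_that("normalization satisfies 40000*R/N and its exact identities", {
  set.seed(83)
  m <- matrix(rpois(60, 200), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  m["g01", 1] <- 10L
  cm <- make_cm(m, rep(c("uninduced", "WT"), each = 3), "RPF")
  ref <- c("g02", "g03", "g04")
  fac <- normalization_factors(cm, ref)
  nm <- normalize_counts(cm, fac)
  # direct arithmetic: R=10, N as computed
  expect_equal(nm["g01", 1], 40000 * 10 / sum(m[ref, 1]))
  # reference genes sum to exactly 40000 in every sample
  expect_equal(unname(colSums(nm[ref, ])), rep(40000, 6))
  # brute-force application
  expect_equal(nm, sweep(m * 40000, 2, colSums(m[ref, ]), "/"))
  # scaling one sample leaves its normalized counts unchanged
  m2 <- m; m2[, 2] <- m2[, 2] * 5L
  nm2 <- normalize_counts(make_cm(m2, rep(c("uninduced", "WT"), each = 3),
                                  "RPF"),
                          normalization_factors(make_cm(m2,
                                                        rep(c("uninduced",
                                                              "WT"),
                                                            each = 3),
                                                        "RPF"), ref))
  expect_equal(nm2[, 2], nm[, 2])
  expect_error(normalization_factors(cm, c("g02", "nope")), "absent")
})

test_that("dispersion estimation hits its simulation oracles", {
  cfg_p <- synthetic_config(seed = 84, nb_dispersion = 1e-6,
                            libsize_sdlog = 1e-9)
  genes <- sprintf("g%04d", 1:1000)
  cls <- setNames(rep("low", 1000), genes)
  cm <- simulate_counts(genes, cls, cfg_p, c("uninduced", "WT"), 3L,
                        seed = 84)$rna
  disp <- estimate_dispersion(cm$counts, cm$design)
  expect_lte(median(disp), 0.01)           # Poisson-like data
  cfg_nb <- synthetic_config(seed = 85, nb_dispersion = 0.1,
                             libsize_sdlog = 1e-9)
  cm2 <- simulate_counts(genes, cls, cfg_nb, c("uninduced", "WT"), 3L,
                         seed = 85)$rna
  disp2 <- estimate_dispersion(cm2$counts, cm2$design)
  expect_gte(mean(disp2), 0.05)
  expect_lte(mean(disp2), 0.2)
  # constant replicates floor at 1e-8
  m <- matrix(50L, nrow = 3, ncol = 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  cmc <- make_cm(m, rep(c("a", "b"), each = 2))
  expect_equal(unname(estimate_dispersion(m, cmc$design)),
               rep(1e-8, 3))
  expect_error(estimate_dispersion(m, data.frame(condition = c("a", "a",
                                                               "a", "b"))),
               "replicates")
})

test_that("the Wald test handles identical means and demands replicates", {
  m <- matrix(rep(c(100L, 200L, 300L), 4), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  cm <- make_cm(m, rep(c("uninduced", "WT"), each = 2))
  disp <- setNames(rep(0.05, 3), paste0("g", 1:3))
  res <- wald_test(m, cm$design, disp, "uninduced", "WT", "RNA")
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
  expect_false(any(res$significant))
  expect_error(wald_test(m[, 1:3], cm$design[1:3, ], disp, "uninduced",
                         "WT", "RNA"),
               "replicates")
})

test_that("estimated fold changes agree with DESeq2 on shared data", {
  skip_if_not_installed("DESeq2")
  cfg <- synthetic_config(seed = 86, libsize_sdlog = 1e-9)
  genes <- sprintf("g%03d", 1:400)
  cls <- setNames(rep("low", 400), genes)
  pl <- setNames(runif(400, -2, 2), genes)
  cm <- simulate_counts(genes, cls, cfg, c("uninduced", "WT"), 3L,
                        seed = 86, log2fc_rna = pl)$rna
  disp <- estimate_dispersion(cm$counts, cm$design)
  ours <- wald_test(cm$counts, cm$design, disp, "uninduced", "WT", "RNA")
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      cm$counts, S4Vectors::DataFrame(condition = factor(cm$design$condition,
                                                         c("uninduced",
                                                           "WT"))),
      ~condition)
    DESeq2::sizeFactors(dds) <- rep(1, 6)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds)
  })
  keep <- !is.na(ref$log2FoldChange)
  expect_gt(cor(ours$log2fc[keep], ref$log2FoldChange[keep]), 0.98)
  agree <- sign(ours$log2fc[keep]) == sign(ref$log2FoldChange[keep])
  expect_gt(mean(agree[abs(pl[keep]) > 0.5]), 0.95)
})

test_that("regulation groups bin by sense and strength", {
  res <- data.frame(
    gene_id = paste0("g", 1:8),
    log2fc = c(-3, -1.5, -0.7, -0.2, 0.2, 0.7, 1.5, 3),
    p = rep(0.001, 8), padj = rep(0.004, 8),
    significant = rep(TRUE, 8)
  )
  attr(res, "assay") <- "RNA"; attr(res, "alpha_threshold") <- 0.05
  class(res) <- c("differential_results", "data.frame")
  out <- bin_regulation_groups(res)
  expect_equal(out$group, paste0("g", 1:8))
  expect_equal(out$twofold, abs(res$log2fc) >= 1)
  # RPF: six groups
  attr(res, "assay") <- "RPF"
  out2 <- bin_regulation_groups(res, assay = "RPF")
  expect_equal(out2$group, c("g1", "g2", "g3", "g3", "g4", "g4", "g5", "g6"))
  # non-passing genes get no group
  res$padj[1L] <- 0.9
  out3 <- bin_regulation_groups(res, assay = "RNA")
  expect_true(is.na(out3$group[1L]))
  # random results vs brute-force binning
  set.seed(87)
  rr <- data.frame(gene_id = sprintf("g%03d", 1:200),
                   log2fc = rnorm(200, 0, 1.5),
                   p = runif(200), padj = runif(200),
                   significant = NA)
  attr(rr, "assay") <- "RNA"; attr(rr, "alpha_threshold") <- 0.05
  class(rr) <- c("differential_results", "data.frame")
  out4 <- bin_regulation_groups(rr)
  cuts <- c(0.5, 1, 2)
  for (i in seq_len(200)) {
    if (rr$padj[i] >= 0.05) { expect_true(is.na(out4$group[i])); next }
    k <- findInterval(abs(rr$log2fc[i]), cuts) + 1L
    expected <- if (rr$log2fc[i] < 0) paste0("g", 5L - k) else
      paste0("g", 4L + k)
    expect_equal(out4$group[i], expected)
  }
})

test_that("TER reports occupancy and RNA-adjusted ratios", {
  rpf <- data.frame(gene_id = c("a", "b"), log2fc = c(-1, -1),
                    significant = c(TRUE, TRUE))
  rna <- data.frame(gene_id = c("a", "b"), log2fc = c(0, -1),
                    significant = c(FALSE, TRUE))
  out <- ter(rpf, rna)
  expect_equal(out$ter, c(0.5, 0.5))
  expect_equal(out$ter_rna_adjusted, c(0.5, 1.0))
  expect_equal(out$rna_stable, c(TRUE, FALSE))
})

test_that("group length comparison matches the textbook t-test", {
  models <- random_models(60, seed = 88)
  ga <- models$gene_id[1:30]; gb <- models$gene_id[31:60]
  res <- compare_group_lengths(ga, gb, models)
  oracle <- t.test(transcript_length(models)[1:30],
                   transcript_length(models)[31:60], var.equal = TRUE)
  expect_equal(res$p, oracle$p.value)
  expect_equal(res$t, unname(oracle$statistic))
  # identical groups -> p = 1
  expect_equal(compare_group_lengths(ga, ga, models)$p, 1)
  # strongly separated length distributions
  set.seed(89)
  lens <- 3L * as.integer(round(rnorm(100, 2000, 30) / 3))
  long <- transcript_models(sprintf("L%03d", 1:100), sprintf("GL%03d", 1:100),
                            0L, lens, 0L, strrep("A", lens))
  expect_lt(compare_group_lengths(models$gene_id[1:30],
                                  long$gene_id,
                                  rbind(models, long))$p, 1e-10)
})
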