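# Site expansion, maxima, event filtering, feature hierarchy, gene
# assignment, strength classification, and overlap rules — each against a
# brute-force oracle on randomized fixtures.

test_that("expansion centres a 9-nt window and clips at transcript ends", {
  models <- transcript_models("t1", "g1", 100L, 600L, 300L,
                              strrep("A", 1000))
  s <- binding_sites("t1", 100L, 101L)
  e <- expand_sites(s, models)
  expect_equal(c(e$start, e$end), c(96L, 105L))
  # near the 5' end: clipped but retained at width >= 5
  e2 <- expand_sites(binding_sites("t1", 1L, 2L), models)
  expect_equal(c(e2$start, e2$end), c(0L, 6L))
  # clipped below 5 nt (only possible on very short transcripts): dropped
  tiny <- transcript_models("s1", "g1", 0L, 3L, 1L, "ACGT")
  e3 <- expand_sites(binding_sites("s1", 0L, 1L), tiny)
  expect_equal(nrow(e3), 0L)
  expect_error(expand_sites(binding_sites("t1", 995L, 1001L), models),
               "outside")
})

test_that("expansion of random raw sites keeps widths 5..9 and centres", {
  models <- transcript_models("t1", "g1", 0L, 300L, 0L, strrep("A", 300))
  set.seed(41)
  st <- sample(0:298, 50, TRUE)
  wd <- sample(1:5, 50, TRUE)
  en <- pmin(st + wd, 300L)
  e <- expand_sites(binding_sites("t1", st, en), models)
  expect_true(all(e$end - e$start >= 5L & e$end - e$start <= 9L))
  centre <- ifelse(en - st == 1L, st, floor((st + en) / 2))
  unclipped <- centre - 4 >= 0 & centre + 5 <= 300
  kept <- which(pmin(centre + 5, 300) - pmax(centre - 4, 0) >= 5)
  expect_equal(nrow(e), length(kept))
  full <- kept[unclipped[kept]]
  expect_true(all(e$start[match(full, kept)] == centre[full] - 4L))
})

test_that("site maxima take the leftmost of tied crosslink peaks", {
  cnt <- integer(20)
  cnt[11:15] <- c(0L, 5L, 9L, 9L, 2L)
  expect_equal(site_maximum(10L, 15L, cnt), 12L)
  cnt2 <- rep(3L, 10)
  expect_equal(site_maximum(2L, 5L, cnt2), 2L)
  expect_error(site_maximum(0L, 5L, integer(10)), "all-zero")
})

test_that("site maxima agree with a brute-force scan on random tracks", {
  set.seed(42)
  for (i in 1:200) {
    L <- sample(30:100, 1)
    cnt <- as.integer(rpois(L, 2))
    st <- sample(0:(L - 9), 1); en <- st + 9L
    if (all(cnt[(st + 1):en] == 0)) next
    brute <- st + (which(cnt[(st + 1):en] ==
                           max(cnt[(st + 1):en]))[1L] - 1L)
    expect_equal(site_maximum(st, en, cnt), brute)
  }
})

test_that("the 20-event filter keeps exactly sites at or above threshold", {
  models <- transcript_models("t1", "g1", 0L, 300L, 0L, strrep("A", 300))
  cnt <- integer(300)
  cnt[51:59] <- 2L              # sums to 18 < 20 -> removed
  cnt[101:109] <- c(2L, 2L, 2L, 3L, 2L, 2L, 2L, 2L, 2L)  # 19 -> removed
  cnt[151:159] <- c(2L, 2L, 2L, 4L, 2L, 2L, 2L, 2L, 2L)  # 20 -> retained
  tr <- track_of(models, list(t1 = cnt))
  s <- binding_sites("t1", c(50L, 100L, 150L), c(59L, 109L, 159L))
  f <- filter_min_events(s, tr, models)
  expect_equal(f$start, 150L)
  expect_equal(f$total_events, 20L)
  expect_equal(f$max_pos, 153L)
})

test_that("filtering random site sets equals a brute-force recount", {
  models <- random_models(6, seed = 43)
  set.seed(44)
  cnt <- lapply(transcript_length(models), function(L) as.integer(rpois(L, 3)))
  tr <- track_of(models, cnt)
  len <- transcript_length(models)
  tx <- sample(models$transcript_id, 80, TRUE)
  st <- vapply(tx, function(t) sample(0:(len[[t]] - 9L), 1L), integer(1))
  s <- binding_sites(tx, st, st + 9L)
  f <- filter_min_events(s, tr, models, min_events = 25L)
  brute <- sum(vapply(seq_len(nrow(s)), function(i)
    sum(cnt[[s$transcript_id[i]]][(s$start[i] + 1):s$end[i]]) >= 25L,
    logical(1)))
  expect_equal(nrow(f), brute)
})

test_that("feature assignment follows the annotation hierarchy", {
  expect_equal(assign_feature(c("CDS", "utr3")), "CDS")
  expect_equal(assign_feature(c("CDS", "ncRNA")), "ncRNA")
  expect_equal(assign_feature(c("utr5", "intron", "utr3")), "utr3")
  expect_equal(assign_feature(c("other", "intron")), "intron")
  expect_equal(assign_feature(character()), "intergenic")
  m <- tiny_models()
  expect_equal(feature_of_position(m[1, ], 10L), "utr5")
  expect_equal(feature_of_position(m[1, ], 60L), "CDS")
  expect_equal(feature_of_position(m[1, ], 250L), "utr3")
  expect_equal(feature_of_position(m[4, ], 50L), "ncRNA")
})

test_that("sites on several isoforms of one gene collapse to one site", {
  m <- tiny_models()  # tx1, tx2 are isoforms of gA
  s <- binding_sites(c("tx1", "tx2", "tx3"), c(60L, 60L, 20L),
                     c(69L, 69L, 29L), total_events = c(30L, 25L, 40L))
  g <- assign_sites_to_genes(s, m)
  expect_equal(nrow(g), 2L)
  expect_setequal(g$gene_id, c("gA", "gB"))
  expect_equal(g$total_events[g$gene_id == "gA"], 30L)  # best-supported kept
  # different intervals on isoforms stay separate
  s2 <- binding_sites(c("tx1", "tx2"), c(60L, 80L), c(69L, 89L))
  expect_equal(nrow(assign_sites_to_genes(s2, m)), 2L)
})

test_that("random multi-isoform fixtures dedup to the brute-force count", {
  set.seed(45)
  n <- 60L
  iso <- sprintf("i%02d", 1:10)
  gene <- setNames(sprintf("g%d", rep(1:5, each = 2)), iso)
  models <- transcript_models(iso, gene[iso], 0L, 90L, 0L,
                              replicate(10, paste(sample(c("A", "C", "G", "T"),
                                                         90, TRUE),
                                                  collapse = "")))
  tx <- sample(iso, n, TRUE)
  st <- sample(seq(0L, 80L, by = 10L), n, TRUE)
  s <- binding_sites(tx, st, st + 9L, total_events = sample(20:99, n, TRUE))
  g <- assign_sites_to_genes(s, models)
  brute <- nrow(unique(data.frame(gene[tx], st)))
  expect_equal(nrow(g), brute)
})

test_that("binding-strength classes follow the top/bottom quartile rules", {
  # construct summaries with controlled ranks
  set.seed(46)
  n <- 100L
  summ <- data.frame(gene_id = sprintf("g%03d", 1:n),
                     n_sites = rep(2L, n),
                     total_tags = sample(1000:9999, n),
                     max_peak_height = sample(100:999, n))
  cl <- classify_gene_binding(summ)
  # brute-force reimplementation of the stated rule
  qt <- quantile(summ$total_tags, c(0.25, 0.75), names = FALSE)
  qh <- quantile(summ$max_peak_height, c(0.25, 0.75), names = FALSE)
  brute <- ifelse(summ$total_tags >= qt[2] | summ$max_peak_height >= qh[2],
                  "high",
                  ifelse(summ$total_tags <= qt[1] &
                           summ$max_peak_height <= qh[1], "low", "moderate"))
  expect_equal(cl$strength_class, brute)
  # OR rule: top by tags alone is high
  top_tag <- which.max(summ$total_tags)
  expect_equal(cl$strength_class[top_tag], "high")
  # AND rule: bottom tags but mid height stays moderate
  mid <- which(summ$total_tags <= qt[1] & summ$max_peak_height > qh[1] &
                 summ$max_peak_height < qh[2])
  expect_true(all(cl$strength_class[mid] == "moderate"))
})

test_that("classes partition genes, are rank-invariant, and need >= 4 genes", {
  set.seed(47)
  summ <- summarize_gene_binding(
    binding_sites(sprintf("t%02d", 1:20), 0L, 9L,
                  total_events = sample(20:500, 20),
                  gene_id = sprintf("g%02d", sample(12, 20, TRUE))),
    genes = sprintf("g%02d", 1:15))
  cl <- classify_gene_binding(summ)
  expect_true(all(cl$strength_class %in% c("high", "moderate", "low")))
  expect_true(all(cl$strength_class[cl$n_sites == 0L] == "low"))
  summ2 <- summ
  summ2$total_tags <- summ2$total_tags * 7L
  summ2$max_peak_height <- summ2$max_peak_height * 7L
  expect_equal(classify_gene_binding(summ2)$strength_class,
               cl$strength_class)
  expect_error(classify_gene_binding(summ[summ$n_sites == 0, ]), ">= 4")
})

test_that("slopped overlap requires an intersection of more than 1 nt", {
  models <- transcript_models("t1", "g1", 0L, 600L, 0L, strrep("A", 600))
  a <- binding_sites("t1", 100L, 109L)
  b2 <- binding_sites("t1", 127L, 136L)   # slopped a = [80,129): 2 nt
  b1 <- binding_sites("t1", 128L, 137L)   # 1 nt only
  expect_true(slop_and_overlap(a, b2, models)$overlapping)
  expect_false(slop_and_overlap(a, b1, models)$overlapping)
})

test_that("overlap counts equal brute-force interval intersection", {
  models <- random_models(4, seed = 48)
  len <- transcript_length(models)
  set.seed(49)
  mk <- function(n) {
    tx <- sample(models$transcript_id, n, TRUE)
    st <- vapply(tx, function(t) sample(0:(len[[t]] - 9L), 1L), integer(1))
    binding_sites(tx, st, st + 9L)
  }
  a <- mk(40); b <- mk(60)
  ov <- slop_and_overlap(a, b, models, slop = 20L, min_overlap = 2L)
  brute <- vapply(seq_len(nrow(a)), function(i) {
    s <- max(a$start[i] - 20L, 0L)
    e <- min(a$end[i] + 20L, len[[a$transcript_id[i]]])
    sum(b$transcript_id == a$transcript_id[i] &
          pmin(e, b$end) - pmax(s, b$start) >= 2L)
  }, numeric(1))
  expect_equal(ov$n_overlap, as.integer(brute))
  # condition-specific sites: brute-force set difference, no slop
  spec <- condition_specific_sites(a, b)
  brute2 <- vapply(seq_len(nrow(a)), function(i)
    sum(b$transcript_id == a$transcript_id[i] &
          pmin(a$end[i], b$end) - pmax(a$start[i], b$start) >= 2L) == 0,
    logical(1))
  expect_equal(nrow(spec), sum(brute2))
  expect_equal(nrow(condition_specific_sites(a, a)), 0L)
  disjoint <- mk(10); disjoint$transcript_id <- models$transcript_id[1L]
  other <- mk(5); other$transcript_id <- models$transcript_id[2L]
  expect_equal(nrow(condition_specific_sites(disjoint, other)), nrow(disjoint))
})
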