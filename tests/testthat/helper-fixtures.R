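# Shared fixture builders. Everything is generated in code; random fixtures
# always run under a locally fixed seed via withr-free set.seed in tests.

# a tiny deterministic transcriptome: 3 protein-coding + 1 ncRNA
tiny_models <- function() {
  set.seed(401)
  mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  transcript_models(
    transcript_id = c("tx1", "tx2", "tx3", "nc1"),
    gene_id = c("gA", "gA", "gB", "gN"),
    len5utr = c(50L, 40L, 10L, 120L),
    lencds = c(150L, 150L, 90L, 0L),
    len3utr = c(100L, 110L, 60L, 0L),
    sequence = c(mk(300), mk(300), mk(160), mk(120)),
    biotype = c("protein_coding", "protein_coding", "protein_coding", "ncRNA")
  )
}

# random models with given count and length range
random_models <- function(n, min_len = 120L, max_len = 600L, seed = 11) {
  set.seed(seed)
  l5 <- sample(5:60, n, TRUE)
  lc <- 3L * sample(20:120, n, TRUE)
  l3 <- sample(10:200, n, TRUE)
  seqs <- vapply(l5 + lc + l3, function(L)
    paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
    character(1L))
  transcript_models(sprintf("t%03d", seq_len(n)),
                    sprintf("g%03d", seq_len(n)),
                    l5, lc, l3, seqs)
}

# a single-sample track table with the given counts vectors (named by tx)
track_of <- function(models, counts, sample_id = "S1", condition = "custom",
                     replicate = 1L) {
  crosslink_tracks(names(counts), sample_id, condition, replicate,
                   counts, models)
}

# all-zero counts list for models
zero_counts <- function(models) {
  lapply(transcript_length(models), function(L) integer(L))
}

# memoized default-config datasets so expensive acceptance blocks can share
.dataset_cache <- new.env(parent = emptyenv())
cached_dataset <- function(seed) {
  key <- as.character(seed)
  if (is.null(.dataset_cache[[key]]))
    .dataset_cache[[key]] <- simulate_dataset(synthetic_config(seed = seed))
  .dataset_cache[[key]]
}

# filtered, annotated, gene-assigned sites for one condition of a dataset
processed_sites <- function(ds, condition, min_events = 20L) {
  tr <- ds$tracks[ds$tracks$condition == condition, ]
  s <- filter_min_events(ds$truth[ds$truth$condition == condition, ],
                         tr, ds$models, min_events)
  assign_sites_to_genes(s, ds$models)
}
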