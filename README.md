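# clipscape

Downstream analysis of iCLIP binding sites for an RNA-binding protein
(RBP) that recognizes a UAG-anchored motif and represses translation of
its targets — positional trimer enrichment and motif-set clustering,
proportional metatranscript profiling, reference-gene-normalized
differential RNA abundance and ribosome occupancy, poly(A) tail
stratification by binding-site load, and peak-overlap analysis — together
with a fully deterministic synthetic-data generator that emulates every
sequencing input, so the complete pipeline runs and is tested without any
download.

It is written for computational biologists who have upstream outputs in
hand (called crosslink peaks, per-nucleotide crosslink tracks, count
matrices, per-read poly(A) tail estimates) and need the bespoke
*downstream* statistics of an RBP-effector study as reusable, tested
functions rather than one-off scripts.

## The statistics at the core

All positions are 0-based, half-open, in transcript coordinates; UAG is
written `TAG` (DNA alphabet).

* **Binding sites.** Called peaks are expanded to 9-nt windows centred on
  the crosslink coordinate, must carry ≥ 20 crosslink events, and get a
  maximum position (leftmost on ties). Genes are classified *high* /
  *moderate* / *low* by quartile ranks of total tag count and maximal
  peak height (top quartile in either ⇒ high; bottom quartile in both ⇒
  low).
* **Motifs.** For the 103-nt window around each site maximum, the
  frequency of all 64 trimers is counted per position and divided by the
  trimer's median frequency across the window (enrichment score
  `E[t, p] = f[t, p] / median_p f[t, ·]`). Profiles in a 31-nt window are
  clustered (Euclidean, Ward) and cut into three sets: UAG, U/A-rich, and
  the rest. UAG-upstream prevalence is the fraction of sites with a `TAG`
  start within 15 nt upstream of the maximum.
* **Metatranscript.** Crosslink events map to 100 percent-bins per mRNA
  segment (5'UTR, CDS, 3'UTR); samples are scaled to events-per-million
  and the 300-bin profile is normalized to sum to 1.
* **Differential occupancy.** Counts are normalized by
  `40000 · R / N`, where `N` is the sample's total over highly expressed
  (RPKM > 10), never-bound reference genes; a negative-binomial Wald test
  (method-of-moments dispersion with median shrinkage, delta-method
  standard errors) compares conditions, with BH adjustment and the
  fold-change > 2 convention.
* **Poly(A).** PASS-flagged tail estimates give per-gene RPM and mean
  tail length, stratified by binding-site bins 0 / 1–2 / 3–10 / 11–30 /
  ≥ 31.

## Worked example

Simulate a wild-type dataset, process its sites, and run the motif and
occupancy analyses:

```r
library(clipscape)

ds <- simulate_dataset(synthetic_config(seed = 42))
tr <- ds$tracks[ds$tracks$condition == "WT", ]
sites <- filter_min_events(ds$truth[ds$truth$condition == "WT", ], tr, ds$models)
sites <- assign_sites_to_genes(sites, ds$models)
nrow(sites)
#> [1] 456

tm <- normalize_to_median(trimer_positional_counts(extract_windows(sites, ds$models)))
cluster_trimer_profiles(tm)
#> $uag:     "TAG"
#> $ua_rich: "AAA" "AAT" "ATA" "ATT" "TAA" "TAT" "TTA" "TTT"
#> $other:   55 remaining trimers
uag_upstream_prevalence(sites, ds$models)
#> [1] 0.846

summ <- classify_gene_binding(summarize_gene_binding(sites, unique(ds$models$gene_id)))
table(summ$strength_class)
#>     high      low moderate
#>       57      101       92

rpkm <- compute_rpkm(ds$counts$rna, ds$models)
uni <- ds$counts$rna$design$condition == "uninduced"
ref <- select_reference_genes(rpkm[, uni, drop = FALSE], unique(ds$truth$gene_id))
cm <- ds$counts$rpf
nm <- normalize_counts(cm, normalization_factors(cm, ref))   # ref genes sum to 40000
res <- wald_test(nm, cm$design, estimate_dispersion(nm, cm$design),
                 "uninduced", "WT", "RPF")
sig <- res[res$significant, ]
c(significant = nrow(sig), repressed = sum(sig$log2fc < 0))
#> significant   repressed
#>          58          58
```

The clustering isolates `TAG` as its own set and recovers the U/A-rich
trimers downstream of the maxima; 84.6% of wild-type sites carry an
upstream UAG; and every significant ribosome-occupancy change in this run
is a repression, concentrated in highly bound genes — the planted
phenotypes of the generator, which mirror the study's contrasts.

The same run, end to end with files and a checksum manifest:

```r
run_pipeline(list(seed = 42), "out/")   # or: inst/scripts/clipscape.R run --config cfg.yaml --outdir out/
```

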