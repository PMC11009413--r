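## End-to-end orchestration: simulate -> sites -> motifs -> metatx -> diff
## -> polya, one config, one output directory, a manifest with checksums.
## Re-running with the same config reproduces byte-identical TSVs.

default_pipeline_config <- function() {
  list(
    schema_version = 1L,
    seed = 1L,
    simulate = list(),          # overrides for synthetic_config()
    sites = list(min_events = 20L),
    motifs = list(flank = 51L, cluster_window = 31L, upstream = 15L),
    overlap = list(slop = 20L, min_overlap = 2L),
    diff = list(rpkm_threshold = 10, scale = 40000,
                alpha_threshold = 0.05, fc_threshold = 2),
    polya = list()
  )
}

read_pipeline_config <- function(config) {
  cfg <- default_pipeline_config()
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  for (nm in names(user)) {
    if (!nm %in% names(cfg)) fail("unknown config key: %s", nm)
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    } else cfg[[nm]] <- user[[nm]]
  }
  if (is.null(cfg$seed) || is.na(suppressWarnings(as.integer(cfg$seed))))
    fail("config must provide an integer seed")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on a synthetic dataset
#'
#' Stages: `sim` (synthetic dataset + on-disk FASTA/BED/TSV emulations of
#' the sequencing inputs), `sites` (expansion, 20-event filter, gene
#' assignment, strength classes, condition-specific sets, slop overlap),
#' `motifs` (positional trimer counts/enrichment, set clustering, set
#' profiles, UAG prevalence), `metatx` (300-bin profiles per condition,
#' UAG background, per-segment tests), `diff` (reference genes,
#' normalization, NB Wald tests, regulation groups, TER), `polya` (tail
#' summaries by binding-site bin). A `manifest.json` records the config,
#' seed, package version and the MD5 checksum of every written file.
#'
#' @param config path to a YAML config or an equivalent list; see
#'   `clipscape:::default_pipeline_config()` for keys and defaults.
#' @param outdir output directory (created).
#' @param stages subset of stages to run (dependencies are computed in
#'   memory regardless; only writing is restricted).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("sim", "sites", "motifs", "metatx",
                                    "diff", "polya")) {
  cfg <- read_pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(path) files[[length(files) + 1L]] <<- path
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      fail("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  scfg <- do.call(synthetic_config,
                  c(list(seed = cfg$seed), cfg$simulate))
  ds <- run_stage("sim", simulate_dataset(scfg))
  conds <- scfg$iclip_conditions
  if ("sim" %in% stages) {
    emit(write_tsv(data.frame(key = "seed", value = cfg$seed),
                   file.path(outdir, "seed.tsv")))
    yaml::write_yaml(cfg, file.path(outdir, "config_resolved.yaml"))
    emit(file.path(outdir, "config_resolved.yaml"))
    write_transcript_models(ds$models, file.path(outdir, "models.bed"),
                            file.path(outdir, "transcripts.fa"))
    emit(file.path(outdir, "models.bed")); emit(file.path(outdir, "transcripts.fa"))
    for (sid in unique(ds$tracks$sample_id)) {
      p <- file.path(outdir, paste0("track_", sid, ".bed"))
      write_crosslink_tracks(ds$tracks[ds$tracks$sample_id == sid, ], p)
      emit(p)
    }
    for (cond in conds) {
      p <- file.path(outdir, paste0("truth_sites_", cond, ".bed"))
      write_binding_sites(ds$truth[ds$truth$condition == cond, ], p)
      emit(p)
    }
    emit(write_tsv(ds$true_sites, file.path(outdir, "truth_descriptors.tsv")))
    write_counts(ds$counts$rna, file.path(outdir, "counts_rna.tsv"),
                 file.path(outdir, "design_rna.tsv"))
    write_counts(ds$counts$rpf, file.path(outdir, "counts_rpf.tsv"),
                 file.path(outdir, "design_rpf.tsv"))
    emit(file.path(outdir, "counts_rna.tsv")); emit(file.path(outdir, "design_rna.tsv"))
    emit(file.path(outdir, "counts_rpf.tsv")); emit(file.path(outdir, "design_rpf.tsv"))
    emit(write_polya(ds$polya, file.path(outdir, "polya.tsv")))
  }

  ## sites: per condition, annotate/filter the truth peaks against the tracks
  site_res <- run_stage("sites", {
    per_cond <- list()
    for (cond in conds) {
      tr <- ds$tracks[ds$tracks$condition == cond, ]
      s <- ds$truth[ds$truth$condition == cond, ]
      s <- filter_min_events(s, tr, ds$models, cfg$sites$min_events)
      s <- assign_sites_to_genes(s, ds$models)
      per_cond[[cond]] <- s
    }
    summaries <- classify_gene_binding(
      summarize_gene_binding(per_cond[[conds[1L]]], unique(ds$models$gene_id)))
    specific <- list()
    if (length(conds) >= 2L) {
      specific[[paste0(conds[1L], "_specific")]] <-
        condition_specific_sites(per_cond[[conds[1L]]], per_cond[[conds[2L]]],
                                 cfg$overlap$min_overlap)
      specific[[paste0(conds[2L], "_specific")]] <-
        condition_specific_sites(per_cond[[conds[2L]]], per_cond[[conds[1L]]],
                                 cfg$overlap$min_overlap)
    }
    list(per_cond = per_cond, summaries = summaries, specific = specific)
  })
  if ("sites" %in% stages) {
    for (cond in conds) {
      p <- file.path(outdir, paste0("sites_filtered_", cond, ".bed"))
      write_binding_sites(site_res$per_cond[[cond]], p); emit(p)
    }
    emit(write_tsv(site_res$summaries,
                   file.path(outdir, "gene_binding_summary.tsv")))
    for (nm in names(site_res$specific))
      emit(write_tsv(as.data.frame(site_res$specific[[nm]]),
                     file.path(outdir, paste0("sites_", nm, ".tsv"))))
  }

  motif_res <- run_stage("motifs", {
    per_cond <- list()
    for (cond in conds) {
      s <- site_res$per_cond[[cond]]
      tm <- normalize_to_median(trimer_positional_counts(
        extract_windows(s, ds$models, cfg$motifs$flank)))
      sets <- cluster_trimer_profiles(tm, cfg$motifs$cluster_window)
      per_cond[[cond]] <- list(
        tm = tm, sets = sets, profiles = summarize_sets(tm, sets),
        prevalence = uag_upstream_prevalence(s, ds$models,
                                             cfg$motifs$upstream)
      )
    }
    prev_specific <- vapply(site_res$specific, function(s)
      uag_upstream_prevalence(s, ds$models, cfg$motifs$upstream), numeric(1L))
    list(per_cond = per_cond, prev_specific = prev_specific)
  })
  if ("motifs" %in% stages) {
    for (cond in conds) {
      mr <- motif_res$per_cond[[cond]]
      emit(write_tsv(data.frame(trimer = mr$tm$trimers, mr$tm$counts,
                                check.names = FALSE),
                     file.path(outdir, paste0("trimer_counts_", cond, ".tsv"))))
      emit(write_tsv(data.frame(trimer = mr$tm$trimers, mr$tm$enrichment,
                                check.names = FALSE),
                     file.path(outdir, paste0("trimer_enrichment_", cond, ".tsv"))))
      memb <- data.frame(trimer = mr$tm$trimers,
                         set = ifelse(mr$tm$trimers %in% mr$sets$uag, "uag",
                                      ifelse(mr$tm$trimers %in% mr$sets$ua_rich,
                                             "ua_rich", "other")))
      emit(write_tsv(memb,
                     file.path(outdir, paste0("trimer_sets_", cond, ".tsv"))))
      emit(write_tsv(data.frame(set = rownames(mr$profiles), mr$profiles,
                                check.names = FALSE),
                     file.path(outdir, paste0("set_profiles_", cond, ".tsv"))))
    }
    prev <- data.frame(
      set = c(conds, names(motif_res$prev_specific)),
      prevalence = c(vapply(conds, function(cd)
        motif_res$per_cond[[cd]]$prevalence, numeric(1L)),
        unname(motif_res$prev_specific))
    )
    emit(write_tsv(prev, file.path(outdir, "uag_prevalence.tsv")))
  }

  metatx_res <- run_stage("metatx", {
    profiles <- lapply(conds, function(cond)
      metatranscript_profile(ds$tracks[ds$tracks$condition == cond, ],
                             ds$models))
    names(profiles) <- conds
    bg <- uag_background(ds$models)
    tests <- list()
    if (length(conds) >= 2L) {
      for (seg in c("utr5", "cds", "utr3"))
        tests[[seg]] <- compare_segment_distributions(
          ds$tracks[ds$tracks$condition == conds[1L], ],
          ds$tracks[ds$tracks$condition == conds[2L], ], ds$models, seg)$p
    }
    list(profiles = profiles, bg = bg, tests = tests)
  })
  if ("metatx" %in% stages) {
    tab <- data.frame(bin = 0:299,
                      segment = rep(c("utr5", "cds", "utr3"), each = 100L))
    for (cond in conds) tab[[cond]] <- metatx_res$profiles[[cond]]$bins
    tab$uag_background <- metatx_res$bg
    emit(write_tsv(tab, file.path(outdir, "metatranscript.tsv")))
    if (length(metatx_res$tests))
      emit(write_tsv(data.frame(segment = names(metatx_res$tests),
                                p = unlist(metatx_res$tests)),
                     file.path(outdir, "metatranscript_tests.tsv")))
  }

  diff_res <- run_stage("diff", {
    bound <- unique(ds$truth$gene_id)
    uni <- ds$counts$rna$design$condition == "uninduced"
    rpkm <- compute_rpkm(ds$counts$rna, ds$models)
    ref <- select_reference_genes(rpkm[, uni, drop = FALSE], bound,
                                  cfg$diff$rpkm_threshold)
    res <- list(reference_genes = ref)
    for (assay in c("rna", "rpf")) {
      cm <- ds$counts[[assay]]
      fac <- normalization_factors(cm, ref, cfg$diff$scale)
      norm <- normalize_counts(cm, fac)
      disp <- estimate_dispersion(norm, cm$design)
      wt <- wald_test(norm, cm$design, disp, "uninduced", "WT",
                      assay = toupper(assay),
                      alpha_threshold = cfg$diff$alpha_threshold,
                      fc_threshold = cfg$diff$fc_threshold)
      res[[assay]] <- bin_regulation_groups(wt)
      res[[paste0(assay, "_norm")]] <- norm
    }
    res$ter <- ter(res$rpf, res$rna)
    res
  })
  if ("diff" %in% stages) {
    emit(write_tsv(data.frame(gene_id = diff_res$reference_genes),
                   file.path(outdir, "reference_genes.tsv")))
    for (assay in c("rna", "rpf")) {
      emit(write_tsv(as.data.frame(diff_res[[assay]]),
                     file.path(outdir, paste0("diff_", assay, ".tsv"))))
      emit(write_tsv(data.frame(gene_id = rownames(diff_res[[paste0(assay, "_norm")]]),
                                diff_res[[paste0(assay, "_norm")]],
                                check.names = FALSE),
                     file.path(outdir, paste0("normalized_", assay, ".tsv"))))
    }
    emit(write_tsv(diff_res$ter, file.path(outdir, "ter.tsv")))
  }

  polya_res <- run_stage("polya", {
    tails <- summarize_tails(ds$polya)
    site_counts <- table(site_res$per_cond[[conds[1L]]]$gene_id)
    sc <- stats::setNames(as.integer(site_counts), names(site_counts))
    bin_by_binding_sites(tails, sc)
  })
  if ("polya" %in% stages)
    emit(write_tsv(polya_res, file.path(outdir, "polya_summary.tsv")))

  manifest <- list(
    package_version = as.character(utils::packageVersion("clipscape")),
    seed = cfg$seed,
    config = cfg,
    files = lapply(stats::setNames(files, basename(files)), function(p)
      unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(config = cfg, dataset = ds, sites = site_res,
                 motifs = motif_res, metatx = metatx_res, diff = diff_res,
                 polya = polya_res, manifest = manifest))
}
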