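## Synthetic-data generator. Emulates the sequencing inputs the downstream
## analyses assume: a transcriptome with planted binding motifs,
## condition-dependent crosslink tracks, negative-binomial RNA/RPF count
## matrices with binding-coupled translational repression, and per-read
## poly(A) tail estimates. Everything is a pure function of the config's
## master seed; each (task, condition, replicate) draws from its own
## substream so adding replicates never perturbs existing ones.

#' Build a validated synthetic-data configuration
#'
#' Defaults describe the study conditions the package is exercised under:
#' mRNA-like segment lengths (log-normal; ~150/1100/900 nt for
#' 5'UTR/CDS/3'UTR), a mildly U-rich background base composition, about two
#' binding sites per transcript and condition, wild-type sites planted at a
#' consensus (UAG just upstream of a U/A-rich trimer) with probability 0.85
#' and in the 3'UTR with probability 0.6, effector-interface mutants at
#' (0.5, 0.35) with consensus intensity halved, site intensities log-normal
#' around 80 events per replicate, a short two-sided geometric crosslink
#' smearing kernel, NB dispersion 0.05 for count matrices, and RPF
#' repression coupled to the gene's binding class (strongest for highly
#' bound genes). Override any field by name.
#'
#' @param seed master seed (integer).
#' @param ... overrides for any default field; unknown names are an error.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_transcripts = 250L,
    # segment lengths, log-normal per segment
    utr5_meanlog = log(150), utr5_sdlog = 0.45,
    cds_meanlog = log(1100), cds_sdlog = 0.40,
    utr3_meanlog = log(900), utr3_sdlog = 0.50,
    base_composition = c(A = 0.27, C = 0.22, G = 0.21, T = 0.30),
    # binding sites
    site_rate = 2.4,          # mean sites per transcript per condition
    min_site_spacing = 20L,   # min distance between planted maxima
    # U/A-biased sequence context just downstream of every site maximum,
    # emulating the uridine-rich crosslinking environment of real sites
    context_len = 15L,
    extra_uag_prob = 0.5,     # chance of a second upstream UAG per consensus site
    context_composition = c(A = 0.45, C = 0.05, G = 0.05, T = 0.45),
    site_meanlog = log(80), site_sdlog = 0.6, # events per site per replicate
    kernel_width = 3,         # geometric smearing scale (nt); 0 = point mass
    background_rate = 0.01,   # background events / nt / replicate
    n_replicates_iclip = 2L,
    condition_params = list(
      WT = list(consensus_fraction = 0.85, utr3_fraction = 0.60,
                intensity_scale = 1.0),
      dPAM2 = list(consensus_fraction = 0.50, utr3_fraction = 0.35,
                   intensity_scale = 0.5),
      M3 = list(consensus_fraction = 0.50, utr3_fraction = 0.35,
                intensity_scale = 0.5)
    ),
    iclip_conditions = c("WT", "dPAM2"),
    # count matrices
    baseline_meanlog = log(300), baseline_sdlog = 1.2,
    libsize_sdlog = 0.1,      # per-sample size-factor spread
    nb_dispersion = 0.05,
    n_replicates_counts = 3L,
    repression_log2fc = c(high = -1.8, moderate = -0.6, low = 0),
    mutant_effect_scale = 0.3,
    rna_effect_scale = 0.25,
    n_reference_genes = 50L,  # unbound, guaranteed highly expressed
    reference_meanlog = log(2000), reference_sdlog = 0.3,
    # poly(A) tails
    tail_shape = 8, tail_scale = 12,   # gamma; mean 96 nt
    polya_reads_per_gene = 50,
    polya_fail_fraction = 0.15
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    fail("unknown synthetic_config field(s): %s",
         paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  probs <- c(cfg$polya_fail_fraction,
             unlist(lapply(cfg$condition_params, function(p)
               c(p$consensus_fraction, p$utr3_fraction))))
  if (any(probs < 0 | probs > 1)) fail("probabilities must lie in [0, 1]")
  for (comp in list(cfg$base_composition, cfg$context_composition)) {
    if (abs(sum(comp) - 1) > 1e-8)
      fail("base compositions must sum to 1")
    if (!setequal(names(comp), c("A", "C", "G", "T")))
      fail("base compositions must name A, C, G, T")
  }
  pos <- c(cfg$utr5_sdlog, cfg$cds_sdlog, cfg$utr3_sdlog, cfg$site_sdlog,
           cfg$site_rate, cfg$nb_dispersion, cfg$tail_shape, cfg$tail_scale)
  if (any(!is.finite(pos)) || any(pos <= 0))
    fail("distribution parameters must be finite and positive")
  if (cfg$kernel_width < 0 || cfg$background_rate < 0)
    fail("kernel_width and background_rate must be >= 0")
  structure(cfg, class = "synthetic_config")
}

random_sequence <- function(n, composition) {
  paste(sample(names(composition), n, replace = TRUE, prob = composition),
        collapse = "")
}

#' Generate a synthetic transcriptome backbone
#'
#' Draws segment lengths from the configured log-normal distributions (CDS
#' rounded up to a multiple of 3, all segments at least 3 nt) and fills
#' sequences i.i.d. from the background base composition. Motifs are planted
#' afterwards by [plant_sites()] (or the composite [simulate_dataset()]).
#'
#' @param config a `synthetic_config`.
#' @return a `transcript_models` table of `config$n_transcripts` rows.
#' @export
generate_transcriptome <- function(config) {
  n <- config$n_transcripts
  if (is.na(n) || n < 0L) fail("n_transcripts must be >= 0")
  if (n == 0L)
    return(transcript_models(character(), character(), integer(), integer(),
                             integer(), character()))
  with_substream(config$seed, "transcriptome", {
    len5 <- pmax(3L, as.integer(round(stats::rlnorm(n, config$utr5_meanlog,
                                                    config$utr5_sdlog))))
    lenc <- pmax(30L, as.integer(round(stats::rlnorm(n, config$cds_meanlog,
                                                     config$cds_sdlog))))
    lenc <- lenc + (3L - lenc %% 3L) %% 3L
    len3 <- pmax(3L, as.integer(round(stats::rlnorm(n, config$utr3_meanlog,
                                                    config$utr3_sdlog))))
    seqs <- vapply(len5 + lenc + len3, random_sequence, character(1L),
                   composition = config$base_composition)
    transcript_models(sprintf("tx%04d", seq_len(n)),
                      sprintf("gene%04d", seq_len(n)),
                      len5, lenc, len3, seqs)
  })
}

#' The twelve U/A-rich trimers of the binding consensus (DNA alphabet)
#' @return character vector of 12 trimers.
#' @export
ua_rich_reference <- function() {
  c("TTT", "ATT", "TTA", "CTT", "TTC", "TTG", "AAT", "AAA", "GTT", "TAA",
    "TAT", "ATA")
}

# Replace characters of `seq` (0-based positions pos0) with `letters`.
edit_sequence <- function(seq, pos0, letters) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  v[pos0 + 1L] <- letters
  paste(v, collapse = "")
}

#' Plant binding sites into one transcript's sequence
#'
#' Consensus sites get `TAG` at positions `[m - 3, m)` relative to the
#' designated maximum `m` and a U/A-rich trimer (uniform over the 12-member
#' reference set) at `[m + 1, m + 4)`. Satellite sites are placed so that no
#' `TAG` trimer starts within the 15 nt upstream of `m` (pre-existing TAGs
#' there are scrubbed by mutating their G, which cannot create new TAGs).
#' The segment (3'UTR vs CDS) is chosen by `utr3_fraction`; maxima keep a
#' configurable minimum spacing from already-occupied maxima.
#'
#' Call inside an RNG substream (e.g. via [simulate_dataset()]); the
#' function draws from the current RNG state.
#'
#' @param model one-row `transcript_models` slice.
#' @param config a `synthetic_config`.
#' @param condition_params list with `consensus_fraction`, `utr3_fraction`,
#'   `intensity_scale` (see `synthetic_config()$condition_params`).
#' @param n_sites number of sites to plant.
#' @param occupied integer vector of maxima already planted on this
#'   transcript (any condition).
#' @param condition label recorded in the descriptors.
#' @return list with `model` (edited sequence) and `sites`, a data.frame of
#'   descriptors (`max_pos`, `class`, `segment`, `intensity`, `condition`).
#'   Errors if the requested sites cannot be placed without overlap after
#'   bounded retries.
#' @export
plant_sites <- function(model, config, condition_params, n_sites = 1L,
                        occupied = integer(), condition = "WT") {
  L <- transcript_length(model)[[1L]]
  seg <- segment_bounds(model)
  seq <- model$sequence
  margin <- max(16L, config$context_len + 4L)
  desc <- list()
  for (k in seq_len(n_sites)) {
    is_cons <- stats::runif(1) < condition_params$consensus_fraction
    want3 <- stats::runif(1) < condition_params$utr3_fraction
    placed <- FALSE
    for (try in 1:100) {
      segname <- if (want3) "utr3" else "cds"
      if (try > 50) segname <- if (want3) "cds" else "utr3" # fallback
      s <- seg[seg$segment == segname, ]
      lo <- max(s$start, margin)
      hi <- min(s$end, L - margin) - 1L
      if (hi < lo) next
      m <- as.integer(lo + floor(stats::runif(1) * (hi - lo + 1L)))
      if (length(occupied) &&
          min(abs(occupied - m)) < config$min_site_spacing) next
      occupied <- c(occupied, m)
      if (config$context_len > 0L) {
        ctx <- sample(names(config$context_composition), config$context_len,
                      replace = TRUE, prob = config$context_composition)
        seq <- edit_sequence(seq, (m + 1L):(m + config$context_len), ctx)
      }
      if (is_cons) {
        ua <- sample(ua_rich_reference(), 1L)
        seq <- edit_sequence(seq, c((m - 3L):(m - 1L), (m + 1L):(m + 3L)),
                             c("T", "A", "G", strsplit(ua, "")[[1L]]))
        if (stats::runif(1) < config$extra_uag_prob) {
          # motif multiplicity: a further UAG in the upstream window
          p2 <- m - 6L - sample.int(10L, 1L) # start in [m-16, m-7]
          seq <- edit_sequence(seq, p2:(p2 + 2L), c("T", "A", "G"))
        }
      } else {
        # scrub any TAG starting in [m-15, m-1]
        win <- substr(seq, m - 14L, m + 2L) # 0-based chars m-15..m+1
        hits <- gregexpr("TAG", win, fixed = TRUE)[[1L]]
        if (hits[1L] != -1L) {
          g_pos <- (m - 15L) + (hits - 1L) + 2L # 0-based position of the G
          seq <- edit_sequence(seq, g_pos, rep("C", length(g_pos)))
        }
      }
      intensity <- stats::rlnorm(1, config$site_meanlog, config$site_sdlog)
      if (is_cons) intensity <- intensity * condition_params$intensity_scale
      desc[[length(desc) + 1L]] <- data.frame(
        transcript_id = model$transcript_id, gene_id = model$gene_id,
        max_pos = m, class = if (is_cons) "consensus" else "satellite",
        segment = segname, intensity = intensity, condition = condition,
        stringsAsFactors = FALSE
      )
      placed <- TRUE
      break
    }
    if (!placed)
      fail("cannot place %d non-overlapping sites on transcript %s",
           n_sites, model$transcript_id)
  }
  model$sequence <- seq
  list(model = model,
       sites = if (length(desc)) do.call(rbind, desc) else
         data.frame(transcript_id = character(), gene_id = character(),
                    max_pos = integer(), class = character(),
                    segment = character(), intensity = numeric(),
                    condition = character(), stringsAsFactors = FALSE))
}

# Discretized two-sided geometric smearing kernel; mode at offset 0.
kernel_offsets <- function(width, span = 10L) {
  if (width == 0) return(list(d = 0L, p = 1))
  rho <- exp(-1 / width)
  d <- (-span):span
  p <- rho^abs(d)
  list(d = d, p = p / sum(p))
}

#' Simulate replicate crosslink tracks around planted sites
#'
#' Per replicate, each site emits `Poisson(intensity)` events displaced from
#' its maximum by the discretized geometric smearing kernel (mode at the
#' maximum; width 0 collapses to a point mass), on top of uniform Poisson
#' background. Truth binding sites use the 9-nt window centred on each
#' planted maximum, with `total_events` the realized pooled event count in
#' that window.
#'
#' @param models `transcript_models` (already planted).
#' @param true_sites descriptor table from [plant_sites()], one condition.
#' @param config a `synthetic_config`.
#' @param condition condition label for the emitted tracks.
#' @param n_replicates number of independent replicate tracks.
#' @param seed master seed (replicates draw from substreams of it).
#' @return list with `tracks` (`crosslink_tracks`) and `truth`
#'   (`binding_sites`).
#' @export
simulate_crosslinks <- function(models, true_sites, config,
                                condition = "WT",
                                n_replicates = config$n_replicates_iclip,
                                seed = config$seed) {
  len <- transcript_length(models)
  ker <- kernel_offsets(config$kernel_width)
  all_tracks <- list()
  for (r in seq_len(n_replicates)) {
    lab <- sprintf("iclip/%s/rep%d", condition, r)
    cnts <- with_substream(seed, lab, {
      cv <- lapply(len, function(L)
        stats::rpois(L, config$background_rate))
      if (nrow(true_sites)) for (i in seq_len(nrow(true_sites))) {
        tx <- true_sites$transcript_id[i]
        L <- len[[tx]]
        n_ev <- stats::rpois(1L, true_sites$intensity[i])
        if (n_ev == 0L) next
        d <- sample(ker$d, n_ev, replace = TRUE, prob = ker$p)
        pos <- pmin(pmax(true_sites$max_pos[i] + d, 0L), L - 1L)
        tb <- tabulate(pos + 1L, nbins = L)
        cv[[tx]] <- cv[[tx]] + tb
      }
      cv
    })
    all_tracks[[r]] <- crosslink_tracks(
      names(len), sprintf("iclip_%s_rep%d", condition, r), condition, r,
      cnts, models
    )
  }
  tracks <- do.call(rbind, all_tracks)
  class(tracks) <- c("crosslink_tracks", "data.frame")
  pooled <- pool_tracks(tracks, models)
  if (nrow(true_sites)) {
    m <- true_sites$max_pos
    st <- pmax(m - 4L, 0L)
    en <- pmin(m + 5L, len[true_sites$transcript_id])
    tot <- vapply(seq_along(m), function(i)
      sum(pooled[[true_sites$transcript_id[i]]][(st[i] + 1L):en[i]]),
      numeric(1L))
    truth <- binding_sites(true_sites$transcript_id, st, en, m,
                           as.integer(tot), condition,
                           true_sites$gene_id)
  } else {
    truth <- binding_sites(character(), integer(), integer(),
                           condition = character())
  }
  list(tracks = tracks, truth = truth)
}

#' Simulate RNA and RPF count matrices with binding-coupled repression
#'
#' Counts are negative binomial with mean `size_factor * baseline *
#' 2^effect` and the configured dispersion. The RPF effect in induced
#' conditions is the configured repression log2 fold-change for the gene's
#' binding class (negative for highly bound genes, scaled down for mutant
#' conditions); the RNA effect is `rna_effect_scale` times the RPF effect;
#' the `uninduced` condition has zero effect. A configured number of
#' unbound genes (`unbound_genes`) is guaranteed high baseline expression so
#' reference-gene selection always has candidates.
#'
#' @param models `transcript_models` or a character vector of gene ids.
#' @param classes named character vector (`high`/`moderate`/`low`) per gene.
#' @param config a `synthetic_config`.
#' @param conditions condition labels; the first is treated as baseline if
#'   it is `"uninduced"`.
#' @param n_replicates replicates per condition (>= 2 expected; fewer warns).
#' @param seed master seed.
#' @param unbound_genes genes forced to the high-expression unbound baseline.
#' @param log2fc_rpf,log2fc_rna optional named numeric overrides of the
#'   per-gene effect (applied to every non-uninduced condition; used for
#'   calibration studies).
#' @param baseline optional named numeric vector of per-gene baseline
#'   means, overriding the log-normal draw (calibration studies).
#' @return list with elements `rna` and `rpf`, both `count_matrix`.
#' @export
simulate_counts <- function(models, classes, config,
                            conditions = c("uninduced", "WT"),
                            n_replicates = config$n_replicates_counts,
                            seed = config$seed,
                            unbound_genes = character(),
                            log2fc_rpf = NULL, log2fc_rna = NULL,
                            baseline = NULL) {
  genes <- if (is.character(models)) models else unique(models$gene_id)
  if (n_replicates < 2L)
    warning("fewer than 2 replicates per condition; downstream tests need >= 2")
  classes <- classes[genes]
  classes[is.na(classes)] <- "low"
  drawn <- with_substream(seed, "counts/baseline", {
    b <- stats::rlnorm(length(genes), config$baseline_meanlog,
                       config$baseline_sdlog)
    names(b) <- genes
    ref <- intersect(unbound_genes, genes)
    b[ref] <- stats::rlnorm(length(ref), config$reference_meanlog,
                            config$reference_sdlog)
    b
  })
  if (!is.null(baseline)) drawn[names(baseline)] <- baseline
  baseline <- drawn
  effect_for <- function(assay, cond) {
    if (cond == "uninduced") return(stats::setNames(rep(0, length(genes)),
                                                    genes))
    scale <- if (cond %in% c("dPAM2", "M3")) config$mutant_effect_scale else 1
    e <- config$repression_log2fc[classes] * scale
    names(e) <- genes
    if (assay == "RPF" && !is.null(log2fc_rpf))
      e[names(log2fc_rpf)] <- log2fc_rpf
    if (assay == "RNA") {
      e <- e * config$rna_effect_scale
      if (!is.null(log2fc_rna)) e[names(log2fc_rna)] <- log2fc_rna
    }
    e
  }
  one_assay <- function(assay) {
    cols <- list(); design <- list()
    for (cond in conditions) for (r in seq_len(n_replicates)) {
      lab <- sprintf("counts/%s/%s/rep%d", assay, cond, r)
      cols[[lab]] <- with_substream(seed, lab, {
        sf <- stats::rlnorm(1, 0, config$libsize_sdlog)
        mu <- sf * baseline * 2^effect_for(assay, cond)
        stats::rnbinom(length(genes), mu = mu, size = 1 / config$nb_dispersion)
      })
      design[[lab]] <- data.frame(
        sample_id = sprintf("%s_%s_rep%d", tolower(assay), cond, r),
        condition = cond, replicate = r, stringsAsFactors = FALSE
      )
    }
    m <- do.call(cbind, cols)
    rownames(m) <- genes
    design <- do.call(rbind, design)
    colnames(m) <- design$sample_id
    count_matrix(m, design, assay = assay)
  }
  list(rna = one_assay("RNA"), rpf = one_assay("RPF"))
}

#' Simulate per-read poly(A) tail-length records
#'
#' Per gene, the read count is Poisson and tail lengths are gamma with the
#' configured shape/scale — independent of binding by construction (the
#' generator's null). A configured fraction of reads is flagged FAIL.
#'
#' @param models `transcript_models` or character vector of gene ids.
#' @param config a `synthetic_config`.
#' @param seed master seed.
#' @return a `polya_records` table.
#' @export
simulate_polya <- function(models, config, seed = config$seed) {
  genes <- if (is.character(models)) models else unique(models$gene_id)
  with_substream(seed, "polya", {
    n_reads <- stats::rpois(length(genes), config$polya_reads_per_gene)
    gene <- rep(genes, n_reads)
    n <- length(gene)
    tails <- stats::rgamma(n, shape = config$tail_shape,
                           scale = config$tail_scale)
    qc <- ifelse(stats::runif(n) < config$polya_fail_fraction, "FAIL", "PASS")
    polya_records(sprintf("read%06d", seq_len(n)), gene, tails, qc)
  })
}

#' Assign truth binding classes from planted site intensities
#'
#' Quartile rule on the per-gene total planted intensity (pooled over the
#' given conditions): top quartile `high`, bottom quartile `low`, rest
#' `moderate`; genes without sites are `low`.
#'
#' @param genes character vector of all gene ids.
#' @param true_sites descriptor table(s) from [plant_sites()].
#' @return named character vector over `genes`.
#' @export
truth_binding_classes <- function(genes, true_sites) {
  tot <- tapply(true_sites$intensity, true_sites$gene_id, sum)
  cls <- stats::setNames(rep("low", length(genes)), genes)
  if (length(tot) >= 4L) {
    qs <- stats::quantile(tot, c(0.25, 0.75), names = FALSE)
    cls[names(tot)[tot >= qs[2L]]] <- "high"
    cls[names(tot)[tot > qs[1L] & tot < qs[2L]]] <- "moderate"
  }
  cls
}

#' Generate one complete synthetic dataset
#'
#' The composite generator: transcriptome backbone, per-condition planted
#' sites (maxima of different conditions kept `min_site_spacing` apart, so
#' sequence edits never collide), replicate crosslink tracks with truth
#' sites, truth binding classes, RNA/RPF count matrices (with guaranteed
#' unbound high-expression genes for reference selection), and poly(A)
#' records. Deterministic: the result is a pure function of the config.
#'
#' @param config a `synthetic_config`.
#' @return list with `config`, `models`, `true_sites` (descriptors),
#'   `tracks`, `truth` (binding_sites, all conditions), `classes`,
#'   `unbound_genes`, `counts` (list rna/rpf), `polya`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  models <- generate_transcriptome(config)
  n <- nrow(models)
  conds <- config$iclip_conditions
  # reserve unbound genes up-front so reference-gene selection has candidates
  unbound <- with_substream(config$seed, "unbound", {
    sample(models$gene_id, min(config$n_reference_genes, n))
  })
  desc <- list()
  models2 <- models
  with_substream(config$seed, "plant", {
    occupied <- stats::setNames(vector("list", n), models$transcript_id)
    for (i in seq_len(n)) {
      if (models$gene_id[i] %in% unbound) next
      for (cond in conds) {
        k <- stats::rpois(1L, config$site_rate)
        if (k == 0L) next
        res <- tryCatch(
          plant_sites(models2[i, , drop = FALSE], config,
                      config$condition_params[[cond]], k,
                      occupied[[models$transcript_id[i]]], cond),
          error = function(e) NULL
        )
        if (is.null(res)) next # transcript saturated; skip remaining sites
        models2$sequence[i] <- res$model$sequence
        occupied[[models$transcript_id[i]]] <-
          c(occupied[[models$transcript_id[i]]], res$sites$max_pos)
        desc[[length(desc) + 1L]] <- res$sites
      }
    }
  })
  true_sites <- if (length(desc)) do.call(rbind, desc) else
    data.frame(transcript_id = character(), gene_id = character(),
               max_pos = integer(), class = character(), segment = character(),
               intensity = numeric(), condition = character())
  tracks <- list(); truth <- list()
  for (cond in conds) {
    sim <- simulate_crosslinks(models2,
                               true_sites[true_sites$condition == cond, ],
                               config, cond,
                               config$n_replicates_iclip, config$seed)
    tracks[[cond]] <- sim$tracks
    truth[[cond]] <- sim$truth
  }
  tracks <- do.call(rbind, tracks)
  truth <- do.call(rbind, truth)
  class(tracks) <- c("crosslink_tracks", "data.frame")
  class(truth) <- c("binding_sites", "data.frame")
  rownames(tracks) <- rownames(truth) <- NULL
  wt_sites <- true_sites[true_sites$condition ==
                           (if ("WT" %in% conds) "WT" else conds[1L]), ]
  classes <- truth_binding_classes(models$gene_id, wt_sites)
  counts <- simulate_counts(models2, classes, config,
                            conditions = c("uninduced", "WT"),
                            n_replicates = config$n_replicates_counts,
                            seed = config$seed, unbound_genes = unbound)
  polya <- simulate_polya(models2, config, config$seed)
  list(config = config, models = models2, true_sites = true_sites,
       tracks = tracks, truth = truth, classes = classes,
       unbound_genes = unbound, counts = counts, polya = polya)
}
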