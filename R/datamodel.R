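## Shared domain containers. All coordinates in this package are 0-based,
## half-open, in transcript (mature mRNA) space; segment order along a
## transcript is 5'UTR, CDS, 3'UTR. Sequences use DNA letters (UAG == "TAG").

#' Construct a table of transcript models
#'
#' A transcript model is one mRNA with its 5'UTR/CDS/3'UTR extents and
#' sequence; it is the coordinate frame for every positional analysis in the
#' package. Degenerate transcripts (a segment of length 0) are allowed and
#' simply contribute nothing to segment-specific analyses.
#'
#' @param transcript_id,gene_id character vectors.
#' @param len5utr,lencds,len3utr non-negative integer segment lengths;
#'   `lencds` must be a multiple of 3 for protein-coding transcripts.
#' @param sequence character vector over A/C/G/T whose lengths equal the
#'   segment sums.
#' @param biotype `"protein_coding"` or `"ncRNA"`.
#' @return a `data.frame` of class `transcript_models`.
#' @export
transcript_models <- function(transcript_id, gene_id, len5utr, lencds,
                              len3utr, sequence,
                              biotype = "protein_coding") {
  df <- data.frame(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    len5utr = as.integer(len5utr),
    lencds = as.integer(lencds),
    len3utr = as.integer(len3utr),
    sequence = as.character(sequence),
    biotype = rep_len(as.character(biotype), length(transcript_id)),
    stringsAsFactors = FALSE
  )
  validate_transcript_models(df)
  class(df) <- c("transcript_models", "data.frame")
  df
}

#' Validate transcript-model invariants
#'
#' Checks non-negative segment lengths, sequence length equal to the segment
#' sum, CDS length divisible by 3 for protein-coding transcripts, the
#' A/C/G/T alphabet, and unique transcript ids.
#'
#' @param df a data.frame with transcript-model columns.
#' @return `df`, invisibly; errors name the first offending transcript.
#' @export
validate_transcript_models <- function(df) {
  needed <- c("transcript_id", "gene_id", "len5utr", "lencds", "len3utr",
              "sequence", "biotype")
  missing <- setdiff(needed, names(df))
  if (length(missing)) fail("transcript models lack columns: %s",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(df$transcript_id))
    fail("duplicated transcript_id: %s",
         df$transcript_id[duplicated(df$transcript_id)][1L])
  seg <- df$len5utr + df$lencds + df$len3utr
  if (any(df$len5utr < 0 | df$lencds < 0 | df$len3utr < 0))
    fail("negative segment length for transcript %s",
         df$transcript_id[which(df$len5utr < 0 | df$lencds < 0 |
                                  df$len3utr < 0)[1L]])
  bad <- which(nchar(df$sequence) != seg)
  if (length(bad))
    fail("sequence length %d != segment sum %d for transcript %s",
         nchar(df$sequence[bad[1L]]), seg[bad[1L]], df$transcript_id[bad[1L]])
  bad <- which(df$biotype == "protein_coding" & df$lencds > 0 &
                 df$lencds %% 3L != 0L)
  if (length(bad))
    fail("CDS length not a multiple of 3 for transcript %s",
         df$transcript_id[bad[1L]])
  bad <- grepl("[^ACGT]", df$sequence)
  if (any(bad))
    fail("non-ACGT letters in sequence of transcript %s",
         df$transcript_id[which(bad)[1L]])
  invisible(df)
}

#' Total mature length of each transcript
#' @param models a `transcript_models` table.
#' @return named integer vector of lengths.
#' @export
transcript_length <- function(models) {
  stats::setNames(models$len5utr + models$lencds + models$len3utr,
                  models$transcript_id)
}

#' Segment boundaries of one transcript
#'
#' @param model a one-row slice of a `transcript_models` table.
#' @return a data.frame with one row per segment (`utr5`, `cds`, `utr3`) and
#'   0-based half-open `start`/`end` columns; empty segments have
#'   `start == end`.
#' @export
segment_bounds <- function(model) {
  stopifnot(nrow(model) == 1L)
  s <- cumsum(c(0L, model$len5utr, model$lencds))
  data.frame(
    segment = c("utr5", "cds", "utr3"),
    start = s,
    end = s + c(model$len5utr, model$lencds, model$len3utr)
  )
}

#' Construct a table of crosslink tracks
#'
#' One track is the per-nucleotide crosslink-event counts of one sample on
#' one transcript; a collection is stored long-form with a list-column of
#' count vectors, one element per (transcript, sample).
#'
#' @param transcript_id,sample_id character vectors (one entry per track).
#' @param condition condition label per track (e.g. `"WT"`, `"dPAM2"`,
#'   `"M3"`, `"PABPC1"`, `"uninduced"`, or any custom label).
#' @param replicate integer replicate index (>= 1).
#' @param counts list of non-negative integer vectors, each as long as its
#'   transcript.
#' @param models `transcript_models` used to check count-vector lengths.
#' @return a `data.frame` of class `crosslink_tracks` with a `counts`
#'   list-column.
#' @export
crosslink_tracks <- function(transcript_id, sample_id, condition, replicate,
                             counts, models = NULL) {
  df <- data.frame(
    transcript_id = as.character(transcript_id),
    sample_id = as.character(sample_id),
    condition = as.character(condition),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  df$counts <- lapply(counts, as.integer)
  if (any(vapply(df$counts, function(x) any(x < 0), logical(1L))))
    fail("negative crosslink counts")
  if (any(df$replicate < 1L)) fail("replicate indices must be >= 1")
  if (!is.null(models)) {
    len <- transcript_length(models)
    unknown <- setdiff(df$transcript_id, names(len))
    if (length(unknown))
      fail("track references unknown transcript %s", unknown[1L])
    bad <- which(lengths(df$counts) != len[df$transcript_id])
    if (length(bad))
      fail("counts length %d != transcript length %d for %s",
           lengths(df$counts)[bad[1L]], len[df$transcript_id[bad[1L]]],
           df$transcript_id[bad[1L]])
  }
  class(df) <- c("crosslink_tracks", "data.frame")
  df
}

#' Pool crosslink tracks into one counts vector per transcript
#'
#' @param tracks a `crosslink_tracks` table.
#' @param models `transcript_models` (defines lengths; transcripts with no
#'   tracks get all-zero vectors).
#' @return named list of integer vectors, one per transcript in `models`.
#' @export
pool_tracks <- function(tracks, models) {
  len <- transcript_length(models)
  pooled <- lapply(len, function(L) integer(L))
  for (i in seq_len(nrow(tracks))) {
    id <- tracks$transcript_id[i]
    if (!id %in% names(pooled)) fail("track on unknown transcript %s", id)
    pooled[[id]] <- pooled[[id]] + tracks$counts[[i]]
  }
  pooled
}

#' Construct a table of binding sites
#'
#' A binding site is a called peak: after canonical expansion it is a 9-nt
#' interval (possibly clipped at transcript ends, never below 5 nt) with the
#' position of its crosslink maximum and the total crosslink events it
#' carries.
#'
#' @param transcript_id character vector.
#' @param start,end 0-based half-open interval in transcript coordinates.
#' @param max_pos coordinate of the site maximum (`start <= max_pos < end`),
#'   or `NA` when not yet computed.
#' @param total_events total crosslink events in the interval (`NA` when not
#'   yet computed).
#' @param condition condition label.
#' @param gene_id gene assignment (`NA` when not yet assigned).
#' @return a `data.frame` of class `binding_sites`.
#' @export
binding_sites <- function(transcript_id, start, end, max_pos = NA_integer_,
                          total_events = NA_integer_, condition = "custom",
                          gene_id = NA_character_) {
  n <- length(transcript_id)
  df <- data.frame(
    transcript_id = as.character(transcript_id),
    start = as.integer(start),
    end = as.integer(end),
    max_pos = rep_len(as.integer(max_pos), n),
    total_events = rep_len(as.integer(total_events), n),
    condition = rep_len(as.character(condition), n),
    gene_id = rep_len(as.character(gene_id), n),
    stringsAsFactors = FALSE
  )
  if (any(df$end <= df$start)) fail("binding site with end <= start")
  ok <- is.na(df$max_pos) | (df$max_pos >= df$start & df$max_pos < df$end)
  if (!all(ok)) fail("max_pos outside [start, end) for site %d", which(!ok)[1L])
  class(df) <- c("binding_sites", "data.frame")
  df
}

#' Construct a gene-by-sample count matrix with its design
#'
#' @param counts integer matrix, rows = genes (unique rownames), columns =
#'   samples; no negative entries.
#' @param design data.frame with columns `sample_id`, `condition`,
#'   `replicate`, one row per column of `counts` (matched by `sample_id` to
#'   colnames).
#' @param assay `"RNA"` or `"RPF"`.
#' @return an object of class `count_matrix`: a list with elements `counts`,
#'   `design`, `assay`.
#' @export
count_matrix <- function(counts, design, assay = c("RNA", "RPF")) {
  assay <- match.arg(assay)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) fail("count matrix needs gene rownames")
  if (anyDuplicated(rownames(counts)))
    fail("duplicated gene id in count table: %s",
         rownames(counts)[duplicated(rownames(counts))][1L])
  if (any(counts < 0)) fail("negative counts")
  needed <- c("sample_id", "condition", "replicate")
  if (!all(needed %in% names(design)))
    fail("design lacks columns: %s",
         paste(setdiff(needed, names(design)), collapse = ", "))
  if (is.null(colnames(counts))) colnames(counts) <- design$sample_id
  if (!setequal(colnames(counts), design$sample_id) ||
      ncol(counts) != nrow(design))
    fail("design sample_ids do not match count columns")
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(counts = counts, design = design, assay = assay),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d genes x %d samples (%s)\n", x$assay,
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$design$condition), collapse = ", ")))
  invisible(x)
}

#' Construct a table of per-read poly(A) tail-length records
#'
#' Emulates a nanopore tail-length estimate table: one row per read with a
#' QC flag; only `PASS` records enter downstream analysis.
#'
#' @param read_id,gene_id character vectors.
#' @param tail_length finite non-negative tail lengths in nucleotides.
#' @param qc `"PASS"` or `"FAIL"` per read.
#' @return a `data.frame` of class `polya_records`.
#' @export
polya_records <- function(read_id, gene_id, tail_length, qc = "PASS") {
  df <- data.frame(
    read_id = as.character(read_id),
    gene_id = as.character(gene_id),
    tail_length = as.numeric(tail_length),
    qc = rep_len(as.character(qc), length(read_id)),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(df$tail_length)) || any(df$tail_length < 0))
    fail("tail lengths must be finite and >= 0")
  if (!all(df$qc %in% c("PASS", "FAIL"))) fail("qc must be PASS or FAIL")
  class(df) <- c("polya_records", "data.frame")
  df
}
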