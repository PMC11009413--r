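## File dialects (all text, UTF-8, tab-delimited, "." for missing):
##  - transcript models: BED12 in transcript space (chrom = transcript_id,
##    chromStart = 0, chromEnd = length, name = gene_id, thick = CDS, one
##    block) + FASTA with matching ids. biotype is protein_coding iff the
##    thick interval is non-empty.
##  - crosslink tracks: BED6, one file per sample; per-nucleotide rows with
##    score = crosslink events, strand "+" (transcript space).
##  - binding sites: BED12, one file per condition; name = gene_id, score =
##    total_events, thick = [max_pos, max_pos + 1).
##  - count matrices: TSV "gene_id<TAB>sample..." plus a sidecar design TSV
##    (sample_id, condition, replicate, assay).
##  - poly(A) records: TSV read_id, gene_id, tail_length, qc.

#' Read transcript models from BED12 + FASTA
#'
#' @param annotation_path BED12 file in the transcript-space dialect above.
#' @param fasta_path FASTA whose ids match the BED `chrom` (= transcript id)
#'   field.
#' @return a `transcript_models` table. A transcript annotated in the BED but
#'   missing from the FASTA is a hard error naming the id; transcripts whose
#'   parsed fields violate the model invariants are reported via warning and
#'   skipped.
#' @export
read_transcript_models <- function(annotation_path, fasta_path) {
  gr <- rtracklayer::import(annotation_path, format = "bed")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  tx <- as.character(GenomicRanges::seqnames(gr))
  absent <- setdiff(tx, names(seqs))
  if (length(absent))
    fail("no FASTA sequence for annotated transcript %s", absent[1L])
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  if (any(start0 != 0L))
    fail("transcript-space BED12 must have chromStart 0 (transcript %s)",
         tx[which(start0 != 0L)[1L]])
  thick <- gr$thick
  t_start <- IRanges::start(thick) - 1L
  t_end <- IRanges::end(thick)
  lencds <- pmax(t_end - t_start, 0L)
  # an empty thick interval is conventionally written as a zero-width
  # interval at the transcript start
  lencds[IRanges::width(thick) == 0L] <- 0L
  len5 <- ifelse(lencds > 0L, t_start, end0)
  len3 <- end0 - len5 - lencds
  biotype <- ifelse(lencds > 0L, "protein_coding", "ncRNA")
  # ncRNA convention: whole transcript recorded as a single exonic extent
  len5[biotype == "ncRNA"] <- end0[biotype == "ncRNA"]
  len3[biotype == "ncRNA"] <- 0L
  seq <- as.character(seqs[tx])
  keep <- rep(TRUE, length(tx))
  for (i in seq_along(tx)) {
    res <- tryCatch({
      transcript_models(tx[i], gr$name[i], len5[i], lencds[i], len3[i],
                        seq[i], biotype[i])
      TRUE
    }, error = function(e) {
      warning(sprintf("skipping transcript %s: %s", tx[i], conditionMessage(e)),
              call. = FALSE)
      FALSE
    })
    keep[i] <- res
  }
  transcript_models(tx[keep], gr$name[keep], len5[keep], lencds[keep],
                    len3[keep], seq[keep], biotype[keep])
}

#' Write transcript models to BED12 + FASTA
#'
#' Inverse of [read_transcript_models()].
#'
#' @param models a `transcript_models` table.
#' @param annotation_path,fasta_path output paths.
#' @return invisibly, the input `models`.
#' @export
write_transcript_models <- function(models, annotation_path, fasta_path) {
  validate_transcript_models(models)
  len <- unname(transcript_length(models))
  gr <- GenomicRanges::GRanges(models$transcript_id,
                               IRanges::IRanges(1L, len), strand = "+")
  gr$name <- models$gene_id
  gr$score <- 0L
  cds <- models$biotype == "protein_coding" & models$lencds > 0L
  gr$thick <- IRanges::IRanges(
    start = ifelse(cds, models$len5utr + 1L, 1L),
    width = ifelse(cds, models$lencds, 0L)
  )
  gr$blocks <- IRanges::IRangesList(lapply(len, function(L)
    IRanges::IRanges(1L, L)))
  rtracklayer::export(gr, annotation_path, format = "bed")
  seqs <- Biostrings::DNAStringSet(models$sequence)
  names(seqs) <- models$transcript_id
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70L)
  invisible(models)
}

#' Read one sample's crosslink track from BED6
#'
#' Positions absent from the BED are 0. The strand field must be "+"
#' (transcript space).
#'
#' @param bed_path BED6 path (per-nucleotide rows, score = events).
#' @param models `transcript_models` giving transcript lengths.
#' @param sample_id,condition,replicate metadata for the sample the file
#'   holds (one sample per file).
#' @return a `crosslink_tracks` table with one row per transcript in
#'   `models`.
#' @export
read_crosslink_tracks <- function(bed_path, models, sample_id = "S1",
                                  condition = "custom", replicate = 1L) {
  len <- transcript_length(models)
  counts <- lapply(len, function(L) integer(L))
  info <- file.info(bed_path)
  if (!is.na(info$size) && info$size > 0) {
    gr <- rtracklayer::import(bed_path, format = "bed")
    if (length(gr)) {
      if (any(as.character(GenomicRanges::strand(gr)) != "+"))
        fail("crosslink track strand must be '+' in transcript space")
      tx <- as.character(GenomicRanges::seqnames(gr))
      unknown <- setdiff(tx, names(len))
      if (length(unknown))
        fail("track references unknown transcript %s", unknown[1L])
      sc <- gr$score %||% rep(NA_real_, length(gr))
      if (any(is.na(sc))) fail("crosslink BED rows need a score column")
      if (any(sc < 0)) fail("negative crosslink score in %s", bed_path)
      p0 <- GenomicRanges::start(gr) - 1L
      p1 <- GenomicRanges::end(gr)
      if (any(p1 > len[tx]))
        fail("coordinate %d beyond transcript %s length %d",
             p1[which(p1 > len[tx])[1L]], tx[which(p1 > len[tx])[1L]],
             len[tx[which(p1 > len[tx])[1L]]])
      for (i in seq_along(gr)) {
        idx <- (p0[i] + 1L):p1[i]
        counts[[tx[i]]][idx] <- counts[[tx[i]]][idx] + as.integer(sc[i])
      }
    }
  }
  crosslink_tracks(names(len), sample_id, condition, replicate,
                   counts, models)
}

#' Write one sample's crosslink track to BED6
#'
#' Only non-zero positions are written. Inverse of
#' [read_crosslink_tracks()] for a single-sample table.
#'
#' @param tracks a `crosslink_tracks` table holding exactly one sample.
#' @param bed_path output path.
#' @return invisibly, `bed_path`.
#' @export
write_crosslink_tracks <- function(tracks, bed_path) {
  if (length(unique(tracks$sample_id)) > 1L)
    fail("one BED6 file holds one sample; split by sample_id first")
  rows <- list()
  for (i in seq_len(nrow(tracks))) {
    cnt <- tracks$counts[[i]]
    nz <- which(cnt > 0L)
    if (!length(nz)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = tracks$transcript_id[i], start = nz - 1L, end = nz,
      name = tracks$sample_id[i], score = cnt[nz], strand = "+"
    )
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), score = integer(), strand = character())
  utils::write.table(df, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed_path)
}

#' Read one condition's binding sites from BED12
#'
#' @param bed_path BED12 path in the site dialect (name = gene_id, score =
#'   total_events, thick = max position).
#' @param condition condition label to attach (one condition per file).
#' @return a `binding_sites` table.
#' @export
read_binding_sites <- function(bed_path, condition = "custom") {
  info <- file.info(bed_path)
  if (is.na(info$size) || info$size == 0)
    return(binding_sites(character(), integer(), integer(),
                         condition = character()))
  gr <- rtracklayer::import(bed_path, format = "bed")
  if (!length(gr))
    return(binding_sites(character(), integer(), integer(),
                         condition = character()))
  max_pos <- if (!is.null(gr$thick)) IRanges::start(gr$thick) - 1L else
    NA_integer_
  binding_sites(
    transcript_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    max_pos = max_pos,
    total_events = as.integer(gr$score %||% NA_integer_),
    condition = condition,
    gene_id = as.character(gr$name %||% NA_character_)
  )
}

#' Write one condition's binding sites to BED12
#'
#' Inverse of [read_binding_sites()].
#'
#' @param sites a `binding_sites` table holding one condition.
#' @param bed_path output path.
#' @return invisibly, `bed_path`.
#' @export
write_binding_sites <- function(sites, bed_path) {
  if (length(unique(sites$condition)) > 1L)
    fail("one site BED holds one condition; split by condition first")
  if (!nrow(sites)) {
    file.create(bed_path)
    return(invisible(bed_path))
  }
  gr <- GenomicRanges::GRanges(sites$transcript_id,
                               IRanges::IRanges(sites$start + 1L, sites$end),
                               strand = "+")
  gr$name <- ifelse(is.na(sites$gene_id), ".", sites$gene_id)
  gr$score <- ifelse(is.na(sites$total_events), 0L, sites$total_events)
  mp <- ifelse(is.na(sites$max_pos), sites$start, sites$max_pos)
  gr$thick <- IRanges::IRanges(mp + 1L, width = 1L)
  gr$blocks <- IRanges::IRangesList(lapply(sites$end - sites$start,
                                           function(w) IRanges::IRanges(1L, w)))
  rtracklayer::export(gr, bed_path, format = "bed")
  invisible(bed_path)
}

#' Read a count matrix and its design table
#'
#' @param tsv_path TSV with header `gene_id` then one column per sample.
#' @param design_path sidecar design TSV (`sample_id`, `condition`,
#'   `replicate`, `assay`).
#' @param assay which assay the matrix holds; defaults to the design's
#'   `assay` value when unique.
#' @return a `count_matrix`. Duplicated gene ids are an error.
#' @export
read_counts <- function(tsv_path, design_path, assay = NULL) {
  tab <- utils::read.delim(tsv_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1L] != "gene_id") fail("first count column must be gene_id")
  if (anyDuplicated(tab$gene_id))
    fail("duplicated gene id in count table: %s",
         tab$gene_id[duplicated(tab$gene_id)][1L])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$gene_id
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  if (is.null(assay)) {
    assay <- unique(design$assay %||% "RNA")
    if (length(assay) != 1L) fail("design holds several assays; pass `assay`")
  }
  if (!is.null(design$assay)) design <- design[design$assay == assay, ]
  count_matrix(m, design, assay = assay)
}

#' Write a count matrix and its design table
#'
#' Inverse of [read_counts()].
#'
#' @param cm a `count_matrix`.
#' @param tsv_path,design_path output paths.
#' @return invisibly, `tsv_path`.
#' @export
write_counts <- function(cm, tsv_path, design_path) {
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  design <- cm$design
  design$assay <- cm$assay
  utils::write.table(design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tsv_path)
}

#' Read per-read poly(A) tail-length records
#'
#' Rows with `qc == "FAIL"` are parsed and kept, flagged FAIL; downstream
#' summaries use only PASS records.
#'
#' @param tsv_path TSV with columns read_id, gene_id, tail_length, qc.
#' @return a `polya_records` table.
#' @export
read_polya <- function(tsv_path) {
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  polya_records(tab$read_id, tab$gene_id, tab$tail_length, tab$qc)
}

#' Write per-read poly(A) tail-length records
#' @param records a `polya_records` table.
#' @param tsv_path output path.
#' @return invisibly, `tsv_path`.
#' @export
write_polya <- function(records, tsv_path) {
  utils::write.table(as.data.frame(records), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(tsv_path)
}
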