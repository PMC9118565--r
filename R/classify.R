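# lncRNA identification and lincRNA/lncNAT classification.
#
# A transcript is retained as a lncRNA candidate when (I) its spliced length
# exceeds 200 nt, (II) both coding-potential predictors call it noncoding,
# (III) it has no protein/domain/RNA-family database homolog, and (IV) its
# FPKM exceeds 0.5 (single-exon) or 0.1 (multi-exon). Survivors are then
# placed by strand-aware exon overlap against the coding annotation:
# antisense exon overlap makes a lncNAT, no gene contact makes a lincRNA,
# same-strand exon overlap is excluded, and intron-only containment is
# reported as intronic.

#' Apply the four lncRNA identification criteria
#'
#' Each transcript is checked against all four criteria and every failed
#' criterion is recorded, not just the first. Thresholds are strict
#' inequalities, so a 200-bp transcript or one at FPKM exactly 0.1/0.5
#' fails.
#'
#' @param txs transcript set.
#' @param flags `data.frame` with one row per transcript: `transcript_id`,
#'   `coding_by_cpc`, `coding_by_plek`, `has_swissprot_hit`, `has_pfam_hit`,
#'   `has_rfam_hit` (logical). These summarize external coding-potential and
#'   homology searches, which are consumed, not run.
#' @param expr expression matrix (rows = transcripts, columns = tissues).
#' @param length_min minimum spliced length, exclusive (default 200 nt).
#' @param fpkm_single,fpkm_multi FPKM thresholds (exclusive) for single- and
#'   multi-exon transcripts.
#' @param expr_rule `"max"` compares the maximum FPKM across tissues against
#'   the threshold (default); `"any"` is equivalent and kept for symmetry
#'   with per-tissue variants.
#' @return `data.frame`: `transcript_id`, `length`, `n_exons`, `max_fpkm`,
#'   `pass` (logical), `fail_reasons` (comma-joined subset of
#'   `length`, `coding_potential`, `homology`, `expression`; `""` if none).
#' @export
apply_identification_filters <- function(txs, flags, expr,
                                         length_min = 200,
                                         fpkm_single = 0.5,
                                         fpkm_multi = 0.1,
                                         expr_rule = c("max", "any")) {
  expr_rule <- match.arg(expr_rule)
  ids <- names(txs)
  miss_f <- setdiff(ids, flags$transcript_id)
  if (length(miss_f))
    stop("no coding/homology flags for transcript(s): ",
         paste(head(miss_f, 5), collapse = ", "))
  miss_e <- setdiff(ids, rownames(expr))
  if (length(miss_e))
    stop("no expression row for transcript(s): ",
         paste(head(miss_e, 5), collapse = ", "))
  fl <- flags[match(ids, flags$transcript_id), , drop = FALSE]
  len <- tx_lengths(txs)
  n_exons <- lengths(txs)
  max_fpkm <- apply(expr[ids, , drop = FALSE], 1, max)
  thr <- ifelse(n_exons == 1, fpkm_single, fpkm_multi)

  fail_len <- !(len > length_min)
  fail_cod <- fl$coding_by_cpc | fl$coding_by_plek
  fail_hom <- fl$has_swissprot_hit | fl$has_pfam_hit | fl$has_rfam_hit
  fail_exp <- !(max_fpkm > thr)

  reasons <- mapply(function(a, b, c, d)
    paste(c("length", "coding_potential", "homology", "expression")[c(a, b, c, d)],
          collapse = ","),
    fail_len, fail_cod, fail_hom, fail_exp)
  data.frame(transcript_id = ids,
             length = unname(len),
             n_exons = unname(n_exons),
             max_fpkm = unname(max_fpkm),
             pass = !(fail_len | fail_cod | fail_hom | fail_exp),
             fail_reasons = unname(reasons),
             stringsAsFactors = FALSE)
}

#' Antisense exon overlap of transcripts with coding genes
#'
#' Total bases of each transcript's exons overlapping coding-gene exons on
#' the opposite strand, with shared bases counted once (interval union
#' before summation), plus the partner genes contributing overlap.
#'
#' @param txs transcript set; every transcript must be stranded (`+`/`-`).
#' @param gene_exons stranded `GRanges` of coding exons with `gene_id`.
#' @return `data.frame`: `transcript_id`, `antisense_bp`,
#'   `partner_genes` (comma-joined gene ids, `""` if none).
#' @export
antisense_exon_overlap <- function(txs, gene_exons) {
  std <- tx_strands(txs)
  if (any(std == "*"))
    stop("unstranded transcript(s): ",
         paste(head(names(txs)[std == "*"], 5), collapse = ", "),
         " (classification is strand-specific)")
  flipped <- invertStrand(granges(gene_exons))
  mcols(flipped)$gene_id <- gene_exons$gene_id
  bp <- overlap_bp_by_tx(txs, flipped, ignore.strand = FALSE)
  ov <- findOverlaps(txs, flipped, ignore.strand = FALSE)
  partners <- rep("", length(txs))
  if (length(ov)) {
    pl <- tapply(flipped$gene_id[subjectHits(ov)], queryHits(ov),
                 function(g) paste(sort(unique(g)), collapse = ","))
    partners[as.integer(names(pl))] <- unname(pl)
  }
  data.frame(transcript_id = names(txs),
             antisense_bp = unname(bp),
             partner_genes = partners,
             stringsAsFactors = FALSE)
}

#' Classify filter-passing transcripts into lincRNA / lncNAT
#'
#' Decision order per transcript: at least `min_antisense_bp` bases of
#' exon-exon overlap with a coding gene on the opposite strand makes a
#' `lncNAT`; otherwise any exon-exon overlap with a same-strand coding exon
#' excludes the transcript (`sense_overlap_excluded`); otherwise a transcript
#' whose span still touches a gene span lies wholly within introns and is
#' reported `intronic`; everything else is `lincRNA`. A configurable buffer
#' widens the gene spans for the lincRNA test (default 0: no buffer).
#'
#' @param txs transcript set (the filter survivors).
#' @param genes `gene_set` from [read_gff3_genes()], or a list with `genes`
#'   (GRanges spans) and `exons` (GRangesList by gene).
#' @param min_antisense_bp minimum antisense exon overlap to call lncNAT.
#' @param gene_buffer bp added to each side of gene spans before the
#'   intergenic test.
#' @return `data.frame`: `transcript_id`, `class` in
#'   `{lincRNA, lncNAT, sense_overlap_excluded, intronic}`, `antisense_bp`,
#'   `sense_bp`, `partner_genes` (non-empty only for lncNAT).
#' @export
classify_transcripts <- function(txs, genes, min_antisense_bp = 1,
                                 gene_buffer = 0) {
  std <- tx_strands(txs)
  if (any(std == "*"))
    stop("unstranded transcript(s): ",
         paste(head(names(txs)[std == "*"], 5), collapse = ", "))
  gene_exons <- unlist(genes$exons, use.names = FALSE)
  mcols(gene_exons)$gene_id <- rep(names(genes$exons), lengths(genes$exons))
  anti <- antisense_exon_overlap(txs, gene_exons)
  sense_bp <- overlap_bp_by_tx(txs, gene_exons, ignore.strand = FALSE)
  spans <- tx_spans(txs)
  gspan <- granges(genes$genes)
  if (gene_buffer > 0) gspan <- suppressWarnings(
    trim(resize(gspan, width(gspan) + 2 * gene_buffer, fix = "center")))
  touches_gene <- overlapsAny(spans, gspan, ignore.strand = TRUE)

  cls <- ifelse(anti$antisense_bp >= min_antisense_bp, "lncNAT",
         ifelse(sense_bp >= 1, "sense_overlap_excluded",
         ifelse(touches_gene, "intronic", "lincRNA")))
  data.frame(transcript_id = names(txs),
             class = cls,
             antisense_bp = anti$antisense_bp,
             sense_bp = unname(sense_bp),
             partner_genes = ifelse(cls == "lncNAT", anti$partner_genes, ""),
             stringsAsFactors = FALSE)
}

#' Identify and classify lncRNAs end to end
#'
#' Runs [apply_identification_filters()] then [classify_transcripts()] on the
#' survivors, returning one row per input transcript so the classes partition
#' the input.
#'
#' @inheritParams apply_identification_filters
#' @inheritParams classify_transcripts
#' @return `data.frame`: `transcript_id`, `class` in `{lincRNA, lncNAT,
#'   sense_overlap_excluded, intronic, filtered_out}`, `fail_reasons`,
#'   `antisense_bp`, `sense_bp`, `partner_genes`.
#' @export
classify_lncrnas <- function(txs, flags, expr, genes,
                             length_min = 200, fpkm_single = 0.5,
                             fpkm_multi = 0.1, min_antisense_bp = 1,
                             gene_buffer = 0) {
  filt <- apply_identification_filters(txs, flags, expr,
                                       length_min = length_min,
                                       fpkm_single = fpkm_single,
                                       fpkm_multi = fpkm_multi)
  out <- data.frame(transcript_id = filt$transcript_id,
                    class = "filtered_out",
                    fail_reasons = filt$fail_reasons,
                    antisense_bp = 0L, sense_bp = 0L, partner_genes = "",
                    stringsAsFactors = FALSE)
  keep <- filt$pass
  if (any(keep)) {
    cl <- classify_transcripts(txs[filt$transcript_id[keep]], genes,
                               min_antisense_bp = min_antisense_bp,
                               gene_buffer = gene_buffer)
    i <- match(cl$transcript_id, out$transcript_id)
    out$class[i] <- cl$class
    out$antisense_bp[i] <- cl$antisense_bp
    out$sense_bp[i] <- cl$sense_bp
    out$partner_genes[i] <- cl$partner_genes
  }
  stopifnot(sum(out$class == "filtered_out") == sum(!keep))
  out
}

#' Split a transcript set by classification
#'
#' @param txs transcript set.
#' @param classification result of [classify_lncrnas()] or
#'   [classify_transcripts()].
#' @param classes which classes to return.
#' @return named list of transcript sets, one per requested class that is
#'   non-empty.
#' @export
split_by_class <- function(txs, classification,
                           classes = c("lincRNA", "lncNAT")) {
  out <- lapply(classes, function(cl) {
    ids <- classification$transcript_id[classification$class == cl]
    txs[intersect(names(txs), ids)]
  })
  names(out) <- classes
  out[vapply(out, length, integer(1)) > 0]
}
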