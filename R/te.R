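# Transposable-element origination analyses: gene-body and exonic TE
# overlap, Class I/II composition per region set, TE-derived promoters, and
# transcription-factor binding sites supplied by TEs.

#' TE overlap per transcript and per class
#'
#' Gene-body overlap uses the transcript span; exonic overlap uses the exon
#' union. A transcript is a TE-lncRNA when its exons share at least
#' `min_bp` bases with TE sequence. For the coding class pass the CDS
#' intervals per gene as the "exons" (the coding-gene exonic variant is
#' CDS-based).
#'
#' @param txs_by_class named list of transcript sets (or `GRangesList`s of
#'   CDS per gene for the coding class).
#' @param tes `GRanges` of TE records.
#' @param min_bp minimum exonic overlap (default 5 bp).
#' @return list: `report` (`data.frame` with `transcript_id`, `class`,
#'   `gene_body_te_bp`, `exonic_te_bp`, `is_te_lnc`) and `ratios`
#'   (`data.frame` per class: fraction of members with gene-body overlap >=
#'   `min_bp` and fraction with `is_te_lnc`).
#' @export
te_overlap <- function(txs_by_class, tes, min_bp = 5) {
  stopifnot(min_bp >= 1)
  te_red <- reduce(granges(tes), ignore.strand = TRUE)
  rows <- lapply(names(txs_by_class), function(cl) {
    txs <- txs_by_class[[cl]]
    spans <- unlist(range(txs), use.names = TRUE)
    body <- overlap_bp_by_range(spans, te_red)
    exonic <- overlap_bp_by_tx(txs, te_red)
    data.frame(transcript_id = names(txs), class = cl,
               gene_body_te_bp = unname(body),
               exonic_te_bp = unname(exonic),
               is_te_lnc = unname(exonic) >= min_bp,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  ratios <- do.call(rbind, lapply(names(txs_by_class), function(cl) {
    r <- report[report$class == cl, , drop = FALSE]
    data.frame(class = cl,
               n = nrow(r),
               gene_body_ratio = mean(r$gene_body_te_bp >= min_bp),
               exonic_ratio = mean(r$is_te_lnc),
               stringsAsFactors = FALSE)
  }))
  list(report = report, ratios = ratios)
}

#' Class I vs Class II TE base composition per region set
#'
#' For each region set (e.g. whole genome, lincRNA loci, lncNAT loci, coding
#' genes), the fraction of TE bases inside the region that belong to Class I
#' (retrotransposons) vs Class II (DNA transposons). `other` repeats are
#' excluded from the two-class fractions and reported separately.
#'
#' @param tes `GRanges` with a `te_class` column in `{I, II, other}`.
#' @param region_sets named list of `GRanges` region unions.
#' @return `data.frame` per region: `region`, `bp_I`, `bp_II`, `bp_other`,
#'   `frac_I`, `frac_II` (NA when the region holds no Class I/II TE base).
#' @export
te_class_distribution <- function(tes, region_sets) {
  by_cls <- lapply(c(I = "I", II = "II", other = "other"), function(k)
    reduce(granges(tes[tes$te_class == k]), ignore.strand = TRUE))
  rows <- lapply(names(region_sets), function(rn) {
    reg <- reduce(granges(region_sets[[rn]]), ignore.strand = TRUE)
    bp <- vapply(by_cls, function(g)
      if (length(reg) == 0) 0 else
        sum(width(GenomicRanges::intersect(g, reg, ignore.strand = TRUE))),
      numeric(1))
    tot <- bp[["I"]] + bp[["II"]]
    data.frame(region = rn, bp_I = bp[["I"]], bp_II = bp[["II"]],
               bp_other = bp[["other"]],
               frac_I = if (tot > 0) bp[["I"]] / tot else NA_real_,
               frac_II = if (tot > 0) bp[["II"]] / tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Promoter windows upstream of transcription start sites
#'
#' The promoter is the fixed-size window immediately upstream of the TSS on
#' the transcript's strand, clipped at chromosome bounds.
#'
#' @param txs transcript set, or `GRanges` of stranded spans.
#' @param size window size in bp (default 1000, the common plant
#'   convention).
#' @param chrom_sizes named integer vector; needed to clip on the 3' side of
#'   minus-strand promoters.
#' @return `GRanges` named by transcript.
#' @export
promoter_window <- function(txs, size = 1000, chrom_sizes = NULL) {
  spans <- if (is(txs, "GRangesList")) unlist(range(txs), use.names = TRUE)
           else txs
  if (any(strand(spans) == "*"))
    stop("unstranded transcript(s); promoters are strand-specific")
  if (!is.null(chrom_sizes)) {
    seqlevels(spans) <- union(seqlevels(spans), names(chrom_sizes))
    seqlengths(spans)[names(chrom_sizes)] <- unname(chrom_sizes)
  }
  prom <- suppressWarnings(trim(promoters(spans, upstream = size,
                                          downstream = 0)))
  if (any(width(prom) == 0))
    stop("promoter of zero length after clipping for: ",
         paste(head(names(prom)[width(prom) == 0], 5), collapse = ", "))
  prom
}

#' Call TE-derived promoters
#'
#' A promoter originates from a TE when a TE covers the TSS base itself, or
#' when TEs cover at least `cover_frac` of the promoter window. Both clauses
#' are configurable.
#'
#' @param txs_by_class named list of transcript sets.
#' @param tes `GRanges` of TE records.
#' @param size promoter size (bp).
#' @param cover_frac minimum TE coverage fraction of the window.
#' @param tss_rule if `TRUE` (default) a TE over the TSS base alone
#'   suffices.
#' @param chrom_sizes named integer vector for clipping.
#' @return list: `calls` (`data.frame` with `transcript_id`, `class`,
#'   promoter coordinates, `te_bp`, `te_cover`, `tss_in_te`, `te_derived`)
#'   with the promoter `GRanges` as attribute `promoters`, and `fractions`
#'   (per-class fraction of TE-derived promoters).
#' @export
te_derived_promoters <- function(txs_by_class, tes, size = 1000,
                                 cover_frac = 0.5, tss_rule = TRUE,
                                 chrom_sizes = NULL) {
  stopifnot(cover_frac > 0, cover_frac <= 1)
  te_red <- reduce(granges(tes), ignore.strand = TRUE)
  all_prom <- GRanges()
  rows <- lapply(names(txs_by_class), function(cl) {
    txs <- txs_by_class[[cl]]
    spans <- unlist(range(txs), use.names = TRUE)
    prom <- promoter_window(txs, size = size, chrom_sizes = chrom_sizes)
    tss <- resize(spans, 1, fix = "start")
    te_bp <- overlap_bp_by_range(prom, te_red)
    cover <- unname(te_bp) / width(prom)
    tss_in <- overlapsAny(tss, te_red, ignore.strand = TRUE)
    derived <- (tss_rule & tss_in) | cover >= cover_frac
    df <- data.frame(transcript_id = names(txs), class = cl,
                     chrom = as.character(seqnames(prom)),
                     prom_start = start(prom), prom_end = end(prom),
                     strand = as.character(strand(prom)),
                     te_bp = unname(te_bp), te_cover = cover,
                     tss_in_te = unname(tss_in), te_derived = unname(derived),
                     stringsAsFactors = FALSE)
    list(df = df, prom = prom)
  })
  calls <- do.call(rbind, lapply(rows, `[[`, "df"))
  proms <- do.call(c, lapply(rows, `[[`, "prom"))
  fractions <- do.call(rbind, lapply(names(txs_by_class), function(cl) {
    d <- calls[calls$class == cl, , drop = FALSE]
    data.frame(class = cl, n = nrow(d), te_derived_frac = mean(d$te_derived),
               stringsAsFactors = FALSE)
  }))
  structure(list(calls = calls, fractions = fractions), promoters = proms)
}

#' TF binding sites inside TE-derived promoter segments
#'
#' A transcript counts when a ChIP-seq peak summit falls inside the
#' intersection of its promoter with a TE. Also reports, per class, the
#' fraction of transcripts with any peak summit in the promoter at all
#' (TF binding frequency).
#'
#' @param promoter_calls result of [te_derived_promoters()].
#' @param peaks `GRanges` from [read_peaks()] (needs `tf_name`, `summit`).
#' @param tes `GRanges` of TE records.
#' @return list: `report` (`data.frame` per transcript: `tf_hit`,
#'   `tf_hit_in_te`, `tfs` comma-joined TF names with a summit in the
#'   promoter), `n_tf_in_te` (transcripts with a TF site inside a TE
#'   segment), `binding_frequency` (per class).
#' @export
tf_sites_in_te_promoters <- function(promoter_calls, peaks, tes) {
  calls <- promoter_calls$calls
  proms <- attr(promoter_calls, "promoters")
  te_red <- reduce(granges(tes), ignore.strand = TRUE)
  summits <- GRanges(seqnames(peaks), IRanges(peaks$summit, peaks$summit))
  mcols(summits)$tf_name <- peaks$tf_name
  ov <- findOverlaps(summits, proms, ignore.strand = TRUE)
  tf_hit <- logical(length(proms))
  tf_in_te <- logical(length(proms))
  tfs <- character(length(proms))
  if (length(ov)) {
    in_te <- overlapsAny(summits[queryHits(ov)], te_red, ignore.strand = TRUE)
    for (j in unique(subjectHits(ov))) {
      sel <- subjectHits(ov) == j
      tf_hit[j] <- TRUE
      tfs[j] <- paste(sort(unique(summits$tf_name[queryHits(ov)[sel]])),
                      collapse = ",")
      tf_in_te[j] <- any(in_te[sel])
    }
  }
  report <- data.frame(transcript_id = calls$transcript_id,
                       class = calls$class,
                       tf_hit = tf_hit, tf_hit_in_te = tf_in_te, tfs = tfs,
                       stringsAsFactors = FALSE)
  bf <- do.call(rbind, lapply(unique(calls$class), function(cl) {
    d <- report[report$class == cl, , drop = FALSE]
    data.frame(class = cl, n = nrow(d), binding_frequency = mean(d$tf_hit),
               stringsAsFactors = FALSE)
  }))
  list(report = report,
       n_tf_in_te = sum(report$tf_hit_in_te),
       binding_frequency = bf)
}

#' Correlation of TE-promoter fraction with genomic TE content
#'
#' Pearson correlation, across species, between the genome-wide TE content
#' and the fraction of a class's transcripts with TE-derived promoters.
#'
#' @param per_species `data.frame` with columns `genome_te_frac` and
#'   `te_promoter_frac` (one row per species; at least 3 rows).
#' @return Pearson r, or `NA` with a message if either column has zero
#'   variance.
#' @export
te_promoter_genome_correlation <- function(per_species) {
  stopifnot(all(c("genome_te_frac", "te_promoter_frac") %in%
                  names(per_species)))
  if (nrow(per_species) < 3)
    stop("need at least 3 species rows")
  if (stats::sd(per_species$genome_te_frac) == 0 ||
      stats::sd(per_species$te_promoter_frac) == 0) {
    message("zero variance; correlation undefined")
    return(NA_real_)
  }
  cor(per_species$genome_te_frac, per_species$te_promoter_frac,
      method = "pearson")
}
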