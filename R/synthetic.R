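# Deterministic, seeded generation of every pipeline input with planted
# ground truth: genome FASTA, coding-gene GFF3, candidate GTF, a
# RepeatMasker-style TE table, a conservation bedGraph, a VCF, an expression
# TSV, coding/homology flag table, ChIP-seq peaks, and cross-species
# alignment hit tables. The emitted truth is computed by generator-side
# per-base bookkeeping (logical masks over the genome), an arithmetic path
# independent of the interval machinery the pipeline itself uses, so every
# module's output can be scored exactly.

# sample() that never falls into the length-1 "convenience" trap
resample <- function(x, k, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), k, replace = replace, prob = prob)]
}

# per-component substream: adding a generated component never perturbs the
# streams of existing ones
component_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 7919) %% (2^31 - 1))
}

rand_bases <- function(n, gc) {
  resample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the statistical structure of a plant lncRNA landscape at
#' desk scale: five tissues (root, stem, leaf, flower, seed), single-exon
#' fractions of 65% for lincRNA, 82% for lncNAT and 22% for mRNA, a
#' conservation gradient CDS > UTR > lncNAT > lincRNA > intergenic, higher
#' SNP density in lncRNAs than in CDS, and a TE landscape mixing
#' retrotransposons (Class I) and DNA transposons (Class II).
#'
#' @param seed integer seed; identical seeds give byte-identical bundles.
#' @param genome_length chromosome length (single chromosome `chr1`).
#' @param n_genes,n_lincRNA,n_lncNAT locus counts (`n_lncNAT <= n_genes`).
#' @param n_sense_decoys,n_intronic_decoys planted same-strand-overlap and
#'   intron-contained transcripts, surfaced as their own classes.
#' @param tissues tissue names.
#' @param single_exon_frac named fractions of single-exon transcripts per
#'   class.
#' @param n_te_lnc lincRNAs with a TE planted inside an exon (>= 5 bp).
#' @param n_te_promoter_linc,n_te_promoter_nat transcripts whose TSS is
#'   covered by a planted TE.
#' @param n_patch lincRNAs with a planted 12-bp conserved patch.
#' @param n_tf_in_te transcripts with a TF peak summit planted inside the
#'   TE-derived part of their promoter.
#' @param ts_frac,two_tissue_frac fractions of lncRNAs with single-tissue
#'   and exact two-tissue expression profiles (the rest are uniform).
#' @param snp_per_kb named planted SNP densities (per kb of exon union).
#' @param cons_level named background conservation levels per feature class.
#' @param species species labels for the homology tables (first = this
#'   genome).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             genome_length = 300000L,
                             n_genes = 25L, n_lincRNA = 20L, n_lncNAT = 12L,
                             n_sense_decoys = 2L, n_intronic_decoys = 2L,
                             tissues = c("root", "stem", "leaf", "flower", "seed"),
                             single_exon_frac = c(lincRNA = 0.65,
                                                  lncNAT = 0.82,
                                                  mRNA = 0.22),
                             n_te_lnc = 8L,
                             n_te_promoter_linc = 6L, n_te_promoter_nat = 3L,
                             n_patch = 6L, n_tf_in_te = 4L,
                             ts_frac = 0.3, two_tissue_frac = 0.2,
                             snp_per_kb = c(lincRNA = 8, lncNAT = 7, cds = 3),
                             cons_level = c(intergenic = 0.03, lincRNA = 0.08,
                                            intron = 0.15, lncNAT = 0.45,
                                            utr = 0.40, cds = 0.75,
                                            patch = 0.9),
                             species = c("SpA", "SpB", "SpC", "SpD")) {
  stopifnot(n_lncNAT <= n_genes, length(tissues) >= 2)
  # planted-feature counts never exceed the class they are planted in
  n_te_lnc <- min(n_te_lnc, n_lincRNA)
  n_te_promoter_linc <- min(n_te_promoter_linc, n_lincRNA)
  n_te_promoter_nat <- min(n_te_promoter_nat, n_lncNAT)
  n_patch <- min(n_patch, n_lincRNA)
  n_intronic_decoys <- min(n_intronic_decoys, n_genes)
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a complete synthetic input bundle with planted truth
#'
#' Lays out non-overlapping loci (coding genes, lincRNAs at least 1 kb from
#' any gene, plus boundary-class decoys), plants lncNATs antisense over
#' coding exons, TEs in exons/promoters/intergenic space, 12-bp conserved
#' patches on a low-conservation background, tissue-specific expression
#' profiles, class-specific SNP densities, TF peak summits inside TE-derived
#' promoter segments, and cross-species alignment hits; then writes every
#' pipeline input format plus the truth tables.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory (created).
#' @return (invisibly) list: `paths` (named file paths), `truth`
#'   (per-transcript truth `data.frame` plus `nat_pairs`, `snp_counts`,
#'   `homology`, `tf_in_te_ids` components), `chrom_sizes`, `config`, and
#'   the in-memory objects (`transcripts`, `genes`, `tes`, `expr`, `flags`).
#' @export
generate_dataset <- function(config = generator_config(),
                             out_dir = tempfile("lnc_bundle_")) {
  stopifnot(is(config, "generator_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cf <- config
  chrom <- "chr1"
  L <- cf$genome_length
  margin <- 1500L

  ## ---- layout ------------------------------------------------------------
  set.seed(component_seed(cf$seed, 1))
  n_filter_decoys <- 6L  # 2 short, 2 flagged, 2 low-expression
  slot_types <- c(rep("gene", cf$n_genes),
                  rep("linc", cf$n_lincRNA),
                  rep("decoy", n_filter_decoys))
  slot_types <- resample(slot_types, length(slot_types))
  gene_exons <- GRanges(); gene_rows <- list()
  cds_gr <- GRanges(); utr5_gr <- GRanges(); utr3_gr <- GRanges()
  cand_exons <- GRanges()   # candidate transcripts (the GTF)
  truth_rows <- list()
  gene_spans <- list()
  cursor <- 2000L
  gi <- 0L; li <- 0L; di <- 0L
  decoy_plan <- c("short199", "short200", "flag_cpc", "flag_pfam",
                  "lowexpr_single", "lowexpr_multi")
  add_cand <- function(id, gid, exon_starts, exon_ends, strand, planted) {
    gr <- GRanges(chrom, IRanges(exon_starts, exon_ends), strand = strand)
    mcols(gr)$transcript_id <- id
    mcols(gr)$gene_id <- gid
    cand_exons <<- c(cand_exons, gr)
    truth_rows[[id]] <<- data.frame(transcript_id = id,
                                    planted_class = planted,
                                    stringsAsFactors = FALSE)
  }
  intronic_gene_ids <- character(0)

  for (st in slot_types) {
    if (st == "gene") {
      gi <- gi + 1L
      gid <- sprintf("gene%03d", gi)
      std <- resample(c("+", "-"), 1)
      force_long_intron <- gi <= cf$n_intronic_decoys
      single <- !force_long_intron && runif(1) < cf$single_exon_frac[["mRNA"]]
      if (single) {
        ex_w <- resample(700:1400, 1)
        intr_w <- integer(0)
      } else {
        n_ex <- resample(3:6, 1)
        ex_w <- resample(150:400, n_ex, replace = TRUE)
        intr_w <- resample(80:250, n_ex - 1, replace = TRUE)
        if (force_long_intron) intr_w[1] <- 600L
      }
      starts <- integer(length(ex_w)); ends <- integer(length(ex_w))
      p <- cursor
      for (k in seq_along(ex_w)) {
        starts[k] <- p; ends[k] <- p + ex_w[k] - 1L
        p <- ends[k] + 1L + if (k < length(ex_w)) intr_w[k] else 0L
      }
      ex <- GRanges(chrom, IRanges(starts, ends), strand = std)
      splen <- sum(width(ex))
      u5 <- min(150L, splen %/% 5); u3 <- min(200L, splen %/% 4)
      cds <- spliced_to_genomic(ex, u5 + 1, splen - u3)
      utr5 <- spliced_to_genomic(ex, 1, u5)
      utr3 <- spliced_to_genomic(ex, splen - u3 + 1, splen)
      mcols(ex)$gene_id <- gid
      gene_exons <- c(gene_exons, ex)
      mcols(cds)$gene_id <- gid; mcols(utr5)$gene_id <- gid
      mcols(utr3)$gene_id <- gid
      cds_gr <- c(cds_gr, cds); utr5_gr <- c(utr5_gr, utr5)
      utr3_gr <- c(utr3_gr, utr3)
      gene_spans[[gid]] <- GRanges(chrom, IRanges(cursor, max(ends)),
                                   strand = std)
      if (force_long_intron) intronic_gene_ids <- c(intronic_gene_ids, gid)
      cursor <- max(ends) + margin
    } else if (st == "linc") {
      li <- li + 1L
      id <- sprintf("linc%03d", li)
      std <- resample(c("+", "-"), 1)
      if (runif(1) < cf$single_exon_frac[["lincRNA"]]) {
        ex_w <- resample(250:1500, 1); intr_w <- integer(0)
      } else {
        n_ex <- resample(2:3, 1)
        ex_w <- resample(150:500, n_ex, replace = TRUE)
        intr_w <- resample(90:200, n_ex - 1, replace = TRUE)
      }
      starts <- integer(length(ex_w)); ends <- integer(length(ex_w))
      p <- cursor
      for (k in seq_along(ex_w)) {
        starts[k] <- p; ends[k] <- p + ex_w[k] - 1L
        p <- ends[k] + 1L + if (k < length(ex_w)) intr_w[k] else 0L
      }
      add_cand(id, paste0("g_", id), starts, ends, std, "lincRNA")
      cursor <- max(ends) + margin
    } else {
      di <- di + 1L
      kind <- decoy_plan[di]
      id <- sprintf("decoy_%s", kind)
      std <- resample(c("+", "-"), 1)
      if (kind == "short199") {
        add_cand(id, paste0("g_", id), cursor, cursor + 198L, std,
                 "filtered_out")
        cursor <- cursor + 199L + margin
      } else if (kind == "short200") {
        add_cand(id, paste0("g_", id), cursor, cursor + 199L, std,
                 "filtered_out")
        cursor <- cursor + 200L + margin
      } else if (kind == "lowexpr_multi") {
        add_cand(id, paste0("g_", id), c(cursor, cursor + 400L),
                 c(cursor + 249L, cursor + 649L), std, "filtered_out")
        cursor <- cursor + 650L + margin
      } else {
        w <- resample(350:700, 1)
        add_cand(id, paste0("g_", id), cursor, cursor + w - 1L, std,
                 "filtered_out")
        cursor <- cursor + w + margin
      }
    }
  }
  if (cursor > L - 2000L)
    stop("genome_length too small for requested features; deficit ",
         cursor - (L - 2000L), " bp")
  trailing_start <- cursor

  ## ---- lncNATs antisense over coding exons -------------------------------
  set.seed(component_seed(cf$seed, 2))
  gene_ids <- sprintf("gene%03d", seq_len(cf$n_genes))
  nat_hosts <- resample(gene_ids, cf$n_lncNAT)
  nat_pairs <- data.frame(lnc_id = character(0), gene_id = character(0))
  for (i in seq_len(cf$n_lncNAT)) {
    gid <- nat_hosts[i]
    id <- sprintf("nat%03d", i)
    hex <- gene_exons[gene_exons$gene_id == gid]
    hx <- hex[which.max(width(hex))]
    g_std <- as.character(strand(hx))
    n_std <- if (g_std == "+") "-" else "+"
    two_exon <- runif(1) > cf$single_exon_frac[["lncNAT"]] && width(hx) >= 420
    if (two_exon) {
      # both exons and the intron inside the host exon interior, so planted
      # splice dinucleotides never collide with the host gene's own
      e1s <- start(hx) + 10L
      e1e <- e1s + resample(120:160, 1)
      e2s <- e1e + 101L
      e2e <- min(end(hx) - 10L, e2s + resample(120:200, 1))
      add_cand(id, paste0("g_", id), c(e1s, e2s), c(e1e, e2e), n_std,
               "lncNAT")
    } else {
      len <- resample(250:600, 1)
      s <- max(start(hx) - resample(0:80, 1), start(hx) - 80L)
      add_cand(id, paste0("g_", id), s, s + len - 1L, n_std, "lncNAT")
    }
    nat_pairs <- rbind(nat_pairs,
                       data.frame(lnc_id = id, gene_id = gid,
                                  stringsAsFactors = FALSE))
  }

  ## ---- sense-overlap and intronic decoys ---------------------------------
  set.seed(component_seed(cf$seed, 3))
  free_genes <- setdiff(gene_ids, nat_hosts)
  sense_hosts <- resample(free_genes, min(cf$n_sense_decoys,
                                          length(free_genes)))
  for (i in seq_along(sense_hosts)) {
    gid <- sense_hosts[i]
    hex <- gene_exons[gene_exons$gene_id == gid]
    hx <- hex[which.max(width(hex))]
    id <- sprintf("sense%03d", i)
    s <- start(hx) + 20L
    add_cand(id, paste0("g_", id), s, s + resample(300:500, 1),
             as.character(strand(hx)), "sense_overlap_excluded")
  }
  for (i in seq_len(cf$n_intronic_decoys)) {
    gid <- intronic_gene_ids[i]
    hex <- sort(gene_exons[gene_exons$gene_id == gid])
    intr_s <- end(hex)[1] + 1L; intr_e <- start(hex)[2] - 1L
    id <- sprintf("intronic%03d", i)
    s <- intr_s + 50L
    e <- min(intr_e - 50L, s + 299L)
    add_cand(id, paste0("g_", id), s, e, resample(c("+", "-"), 1),
             "intronic")
  }

  ## ---- assemble transcript/gene objects ----------------------------------
  txs <- make_transcript_set(cand_exons)
  genes <- local({
    ex_by_gene <- split(granges(gene_exons), gene_exons$gene_id)
    ex_by_gene <- endoapply(ex_by_gene, sort)
    spans <- unlist(range(ex_by_gene), use.names = TRUE)
    g <- granges(spans)
    mcols(g)$gene_id <- names(spans)
    names(g) <- names(spans)
    intr_l <- psetdiff(spans, ex_by_gene)
    intr <- unlist(intr_l, use.names = FALSE)
    mcols(intr)$gene_id <- rep(names(ex_by_gene), lengths(intr_l))
    structure(list(genes = g, exons = ex_by_gene, cds = cds_gr,
                   utr5 = utr5_gr, utr3 = utr3_gr, introns = intr),
              class = "gene_set")
  })
  linc_ids <- sprintf("linc%03d", seq_len(cf$n_lincRNA))
  nat_ids <- if (cf$n_lncNAT > 0) sprintf("nat%03d", seq_len(cf$n_lncNAT))
             else character(0)

  ## ---- transposable elements ---------------------------------------------
  set.seed(component_seed(cf$seed, 4))
  fam_I <- c("LTR/Gypsy", "LTR/Copia", "LINE/L1", "SINE/tRNA")
  fam_II <- c("DNA/MuDR", "DNA/hAT", "DNA/CMC-EnSpm", "RC/Helitron")
  fam_other <- c("Simple_repeat", "Low_complexity")
  te_list <- list()
  add_te <- function(s, e, fam) {
    te_list[[length(te_list) + 1]] <<- data.frame(s = s, e = e, fam = fam,
                                                  stringsAsFactors = FALSE)
  }
  te_lnc_ids <- resample(linc_ids, cf$n_te_lnc)
  for (id in te_lnc_ids) {
    ex1 <- sort(txs[[id]])[1]
    bp <- resample(20:120, 1)
    s <- start(ex1) + resample(5:30, 1)
    add_te(s, min(s + bp - 1L, end(ex1)),
           resample(c(fam_I, fam_II), 1))
  }
  te_prom_linc <- resample(setdiff(linc_ids, character(0)),
                           cf$n_te_promoter_linc)
  te_prom_nat <- resample(nat_ids, min(cf$n_te_promoter_nat,
                                       length(nat_ids)))
  te_prom_ids <- c(te_prom_linc, te_prom_nat)
  spans_all <- tx_spans(txs)
  for (id in te_prom_ids) {
    sp <- spans_all[id]
    tss <- if (as.character(strand(sp)) == "+") start(sp) else end(sp)
    if (as.character(strand(sp)) == "+")
      add_te(tss - 300L, tss, resample(fam_I, 1))
    else
      add_te(tss, tss + 300L, resample(fam_I, 1))
  }
  # background TEs in the trailing region only, clear of every promoter
  p <- trailing_start + 1200L
  while (p < L - 600L) {
    w <- resample(100:400, 1)
    cls <- resample(c("I", "II", "other"), 1, prob = c(0.55, 0.35, 0.10))
    fam <- switch(cls, I = resample(fam_I, 1), II = resample(fam_II, 1),
                  other = resample(fam_other, 1))
    add_te(p, p + w - 1L, fam)
    p <- p + w + resample(80:400, 1)
  }
  te_df <- do.call(rbind, te_list)
  tes <- GRanges(chrom, IRanges(te_df$s, te_df$e),
                 strand = resample(c("+", "-"), nrow(te_df), replace = TRUE))
  mcols(tes)$repeat_name <- sprintf("RPT%04d", seq_along(tes))
  mcols(tes)$repeat_family <- te_df$fam
  mcols(tes)$te_class <- te_class_of(te_df$fam)
  seqlengths(tes) <- c(chr1 = L)

  ## ---- conservation track -------------------------------------------------
  set.seed(component_seed(cf$seed, 5))
  lvl <- cf$cons_level
  cons <- numeric(L)
  block <- 25L
  nb <- ceiling(L / block)
  bg_vals <- round(pmax(0, lvl[["intergenic"]] +
                          runif(nb, -0.02, 0.03)), 3)
  cons <- rep(bg_vals, each = block)[1:L]
  paint <- function(gr, level, jitter = 0.03) {
    s <- start(gr); e <- end(gr)
    for (i in seq_along(s)) {
      v <- round(min(0.99, max(0, level + runif(1, -jitter, jitter))), 3)
      cons[s[i]:e[i]] <<- v
    }
  }
  paint(genes$introns, lvl[["intron"]])
  paint(genes$utr5, lvl[["utr"]]); paint(genes$utr3, lvl[["utr"]])
  paint(cds_gr, lvl[["cds"]])
  for (id in linc_ids) paint(txs[[id]], lvl[["lincRNA"]], 0.02)
  for (id in nat_ids) paint(txs[[id]], lvl[["lncNAT"]], 0.02)
  for (id in setdiff(names(txs), c(linc_ids, nat_ids)))
    if (grepl("^(decoy|sense|intronic)", id))
      paint(txs[[id]], lvl[["lincRNA"]], 0.02)
  patch_ids <- resample(linc_ids, cf$n_patch)
  patch_pos <- list()
  for (id in patch_ids) {
    ex1 <- sort(txs[[id]])[1]
    s <- start(ex1) + resample(20:(width(ex1) - 40), 1)
    cons[s:(s + 11L)] <- lvl[["patch"]]
    patch_pos[[id]] <- s
  }

  ## ---- genome sequence ----------------------------------------------------
  set.seed(component_seed(cf$seed, 6))
  seq_chars <- rand_bases(L, 0.32)
  repaint_seq <- function(gr, gc) {
    s <- start(gr); e <- end(gr)
    for (i in seq_along(s)) {
      idx <- s[i]:e[i]
      seq_chars[idx] <<- rand_bases(length(idx), gc)
    }
  }
  repaint_seq(unlist(txs, use.names = FALSE), 0.38)
  repaint_seq(utr5_gr, 0.42); repaint_seq(utr3_gr, 0.42)
  repaint_seq(cds_gr, 0.55)
  # canonical splice dinucleotides for every planted intron
  all_introns <- tx_introns(txs)
  intr_all <- c(unlist(all_introns, use.names = FALSE), granges(genes$introns))
  intr_std <- c(rep(tx_strands(txs), lengths(all_introns)),
                as.character(strand(genes$introns)))
  intr_starts <- start(intr_all); intr_ends <- end(intr_all)
  for (i in seq_along(intr_all)) {
    s <- intr_starts[i]; e <- intr_ends[i]
    if (intr_std[i] == "+") {
      seq_chars[s] <- "G"; seq_chars[s + 1] <- "T"
      seq_chars[e - 1] <- "A"; seq_chars[e] <- "G"
    } else {
      seq_chars[s] <- "C"; seq_chars[s + 1] <- "T"
      seq_chars[e - 1] <- "A"; seq_chars[e] <- "C"
    }
  }
  genome <- DNAStringSet(setNames(paste(seq_chars, collapse = ""), chrom))

  ## ---- expression and flags ----------------------------------------------
  set.seed(component_seed(cf$seed, 7))
  tissues <- cf$tissues; nt <- length(tissues)
  cand_ids <- names(txs)
  lnc_all <- c(linc_ids, nat_ids)
  n_ts <- round(cf$ts_frac * length(lnc_all))
  n_two <- round(cf$two_tissue_frac * length(lnc_all))
  prof <- rep("uniform", length(lnc_all))
  pick <- resample(seq_along(lnc_all), n_ts + n_two)
  prof[pick[seq_len(n_ts)]] <- "single"
  prof[pick[seq_len(n_two) + n_ts]] <- "two"
  names(prof) <- lnc_all
  expr <- matrix(0, nrow = length(cand_ids) + cf$n_genes, ncol = nt,
                 dimnames = list(c(cand_ids, gene_ids), tissues))
  ts_tissue <- setNames(rep(NA_character_, length(lnc_all)), lnc_all)
  for (id in lnc_all) {
    v <- switch(prof[[id]],
      single = { t1 <- resample(seq_len(nt), 1)
                 ts_tissue[[id]] <- tissues[t1]
                 x <- numeric(nt); x[t1] <- round(runif(1, 2, 20), 4); x },
      two = { tt <- resample(seq_len(nt), 2)
              x <- numeric(nt); x[tt] <- round(runif(1, 2, 20), 4); x },
      uniform = rep(round(runif(1, 0.6, 5), 4), nt))
    expr[id, ] <- v
  }
  for (id in c("decoy_short199", "decoy_short200", "decoy_flag_cpc",
               "decoy_flag_pfam"))
    if (id %in% cand_ids) expr[id, ] <- rep(2, nt)
  if ("decoy_lowexpr_single" %in% cand_ids)
    expr["decoy_lowexpr_single", ] <- rep(0.3, nt)
  if ("decoy_lowexpr_multi" %in% cand_ids)
    expr["decoy_lowexpr_multi", ] <- rep(0.05, nt)
  for (id in names(txs)[grepl("^(sense|intronic)", names(txs))])
    expr[id, ] <- rep(round(runif(1, 1, 8), 4), nt)
  for (gid in gene_ids)
    expr[gid, ] <- round(runif(nt, 1, 100), 4)
  flags <- data.frame(transcript_id = cand_ids,
                      coding_by_cpc = cand_ids == "decoy_flag_cpc",
                      coding_by_plek = FALSE,
                      has_swissprot_hit = FALSE,
                      has_pfam_hit = cand_ids == "decoy_flag_pfam",
                      has_rfam_hit = FALSE,
                      stringsAsFactors = FALSE)

  ## ---- SNPs ---------------------------------------------------------------
  set.seed(component_seed(cf$seed, 8))
  mask_of <- function(gr) {
    m <- logical(L)
    s <- start(gr); e <- end(gr)
    for (i in seq_along(s)) m[s[i]:e[i]] <- TRUE
    m
  }
  linc_mask <- mask_of(unlist(txs[linc_ids], use.names = FALSE))
  nat_mask <- if (length(nat_ids)) mask_of(unlist(txs[nat_ids],
                                                  use.names = FALSE))
              else logical(L)
  cds_mask <- mask_of(cds_gr)
  place_snps <- function(m, rate_kb) {
    pos <- which(m)
    k <- round(length(pos) / 1000 * rate_kb)
    sort(resample(pos, min(k, length(pos))))
  }
  snp_pos <- unique(c(place_snps(linc_mask, cf$snp_per_kb[["lincRNA"]]),
                      place_snps(nat_mask, cf$snp_per_kb[["lncNAT"]]),
                      place_snps(cds_mask, cf$snp_per_kb[["cds"]])))
  snp_pos <- sort(snp_pos)
  bases <- c("A", "C", "G", "T")
  snp_ref <- seq_chars[snp_pos]
  snp_alt <- vapply(snp_ref, function(b) resample(setdiff(bases, b), 1), "")
  snp_qual <- round(runif(length(snp_pos), 20, 60), 1)
  snp_dp <- resample(6:50, length(snp_pos), replace = TRUE)
  # sub-threshold and non-SNP records exercising the retention rule:
  # low qual, low depth, an indel, and the exact thresholds (strict, so both
  # boundary records must be dropped)
  bad_pos <- trailing_start + c(10L, 20L, 30L, 40L, 50L)
  bad_ref <- seq_chars[bad_pos]
  bad <- data.frame(pos = bad_pos,
                    ref = bad_ref,
                    alt = ifelse(bad_ref == "A", "G", "A"),
                    qual = c(8, 30, 30, 10, 30),
                    dp = c(20L, 4L, 20L, 20L, 5L),
                    stringsAsFactors = FALSE)
  bad$alt[3] <- paste0(bad$ref[3], "T")
  truth_snp_counts <- c(
    lincRNA = sum(linc_mask[snp_pos]),
    lncNAT = sum(nat_mask[snp_pos]),
    cds = sum(cds_mask[snp_pos]))

  ## ---- ChIP-seq peaks -----------------------------------------------------
  set.seed(component_seed(cf$seed, 9))
  tf_names <- c("MADS29", "LFY", "AP1", "WUS", "NLP7", "P1", "MYC2",
                "HSF1b", "ARF5")
  peak_rows <- list()
  add_peak <- function(summit, tf) {
    peak_rows[[length(peak_rows) + 1]] <<-
      data.frame(s = summit - 75L, e = summit + 75L, tf = tf,
                 off = 75L, stringsAsFactors = FALSE)
  }
  tf_in_te_ids <- resample(te_prom_ids, min(cf$n_tf_in_te,
                                            length(te_prom_ids)))
  for (id in tf_in_te_ids) {
    sp <- spans_all[id]
    tss <- if (as.character(strand(sp)) == "+") start(sp) else end(sp)
    # planted TE covers the 300 bases promoter-proximal to the TSS
    summit <- if (as.character(strand(sp)) == "+") tss - 100L else tss + 100L
    add_peak(summit, resample(tf_names, 1))
  }
  # promoter peaks outside any TE for transcripts without promoter TEs
  non_te_pool <- setdiff(linc_ids, te_prom_ids)
  non_te_prom <- resample(non_te_pool, min(3, length(non_te_pool)))
  for (id in non_te_prom) {
    sp <- spans_all[id]
    tss <- if (as.character(strand(sp)) == "+") start(sp) else end(sp)
    summit <- if (as.character(strand(sp)) == "+") tss - 500L else tss + 500L
    add_peak(summit, resample(tf_names, 1))
  }
  # background peaks in the trailing region
  for (k in 1:5)
    add_peak(trailing_start + 5000L + k * 700L, resample(tf_names, 1))
  pk <- do.call(rbind, peak_rows)

  ## ---- cross-species homology hits ---------------------------------------
  set.seed(component_seed(cf$seed, 10))
  sp_names <- cf$species
  tx_per_species <- c(list(linc_ids),
                      lapply(seq_along(sp_names)[-1], function(i)
                        sprintf("%s_lnc%03d", sp_names[i], 1:40)))
  names(tx_per_species) <- sp_names
  frac_target <- matrix(0, length(sp_names), length(sp_names),
                        dimnames = list(sp_names, sp_names))
  fr <- c(0.30, 0.10, 0.05)
  for (i in seq_along(sp_names)) {
    others <- setdiff(seq_along(sp_names), i)
    for (k in seq_along(others))
      frac_target[i, others[k]] <- fr[((i + k) %% 3) + 1]
  }
  hit_rows <- list(); truth_hom <- frac_target * 0
  diag(truth_hom) <- 1
  for (a in sp_names) for (b in setdiff(sp_names, a)) {
    q <- tx_per_species[[a]]
    n_pass <- round(frac_target[a, b] * length(q))
    passq <- resample(q, n_pass)
    for (qq in passq)
      hit_rows[[length(hit_rows) + 1]] <- data.frame(
        q = qq, s = sprintf("%s_scaf%d", b, resample(1:9, 1)),
        pid = round(runif(1, 80, 99), 1), len = resample(120:400, 1),
        ev = 1e-30, qa = a, sb = b, stringsAsFactors = FALSE)
    failq <- resample(setdiff(q, passq), min(3, length(setdiff(q, passq))))
    for (qq in failq)
      hit_rows[[length(hit_rows) + 1]] <- data.frame(
        q = qq, s = sprintf("%s_scaf%d", b, resample(1:9, 1)),
        pid = round(runif(1, 70, 85), 1), len = resample(20:40, 1),
        ev = 1e-3, qa = a, sb = b, stringsAsFactors = FALSE)
    truth_hom[a, b] <- n_pass / length(q)
  }
  hits_df <- do.call(rbind, hit_rows)

  ## ---- per-base truth bookkeeping ----------------------------------------
  te_mask <- mask_of(tes)
  truth <- do.call(rbind, truth_rows)
  truth$te_exonic_bp <- vapply(truth$transcript_id, function(id) {
    ex <- txs[[id]]
    sum(te_mask[unlist(mapply(seq, start(ex), end(ex),
                              SIMPLIFY = FALSE))])
  }, numeric(1))
  truth$te_body_bp <- vapply(truth$transcript_id, function(id) {
    sp <- range(txs[[id]])
    sum(te_mask[start(sp):end(sp)])
  }, numeric(1))
  truth$is_te_lnc <- truth$te_exonic_bp >= 5
  truth$te_promoter <- vapply(truth$transcript_id, function(id) {
    sp <- spans_all[id]
    plus <- as.character(strand(sp)) == "+"
    tss <- if (plus) start(sp) else end(sp)
    win <- if (plus) max(1, tss - 1000):(tss - 1) else
      (tss + 1):min(L, tss + 1000)
    te_mask[tss] || mean(te_mask[win]) >= 0.5
  }, logical(1))
  truth$has_patch <- truth$transcript_id %in% patch_ids
  truth$expr_profile <- prof[truth$transcript_id]
  truth$expr_profile[is.na(truth$expr_profile)] <- "other"
  truth$is_ts <- truth$expr_profile == "single"
  truth$ts_tissue <- ts_tissue[truth$transcript_id]

  ## ---- write the bundle ---------------------------------------------------
  paths <- c(genome = "genome.fa", genes = "genes.gff3",
             transcripts = "transcripts.gtf", repeats = "repeats.out",
             conservation = "conservation.bedGraph", variants = "variants.vcf",
             expression = "expression.tsv", flags = "flags.tsv",
             peaks = "peaks.narrowPeak", hits = "blast_hits.tsv",
             truth = "truth_transcripts.tsv",
             truth_homology = "truth_homology.tsv",
             nat_pairs = "nat_pairs.tsv")
  paths <- setNames(file.path(out_dir, paths), names(paths))
  writeXStringSet(genome, paths[["genome"]])
  write_gene_gff3(genes, paths[["genes"]])
  write_gtf(txs, paths[["transcripts"]])
  write_repeatmasker_out(tes, paths[["repeats"]])
  write_bedgraph_runs(cons, chrom, paths[["conservation"]])
  write_vcf(data.frame(
    chrom = chrom,
    pos = c(snp_pos, bad$pos), ref = c(snp_ref, bad$ref),
    alt = c(snp_alt, bad$alt), qual = c(snp_qual, bad$qual),
    dp = c(snp_dp, bad$dp))[order(c(snp_pos, bad$pos)), ],
    paths[["variants"]])
  write_expression_tsv(expr, paths[["expression"]])
  write.table(flags, paths[["flags"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.\t%.2f\t%.2f\t%.2f\t%d",
                     chrom, pk$s - 1L, pk$e, pk$tf, 500L, 10.0, 8.0, 6.0,
                     pk$off),
             paths[["peaks"]])
  write.table(data.frame(hits_df$q, hits_df$s, hits_df$pid, hits_df$len,
                         0L, 0L, 1L, hits_df$len, 1L, hits_df$len,
                         format(hits_df$ev, scientific = TRUE), 100,
                         hits_df$qa, hits_df$sb),
              paths[["hits"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(species = rownames(truth_hom), truth_hom),
              paths[["truth_homology"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(nat_pairs, paths[["nat_pairs"]], sep = "\t", quote = FALSE,
              row.names = FALSE)

  invisible(list(paths = paths,
                 truth = list(transcripts = truth, nat_pairs = nat_pairs,
                              snp_counts = truth_snp_counts,
                              homology = truth_hom,
                              tf_in_te_ids = tf_in_te_ids,
                              patch_ids = patch_ids,
                              te_lnc_ids = te_lnc_ids,
                              te_prom_ids = te_prom_ids),
                 transcripts = txs, genes = genes, tes = tes,
                 expr = expr, flags = flags,
                 hits = data.frame(query_id = hits_df$q,
                                   query_species = hits_df$qa,
                                   subject_species = hits_df$sb,
                                   identity_pct = hits_df$pid,
                                   align_len = hits_df$len,
                                   evalue = hits_df$ev,
                                   stringsAsFactors = FALSE),
                 tx_per_species = tx_per_species,
                 chrom_sizes = c(chr1 = L),
                 config = cf))
}

# GFF3 writer for a gene_set (gene/mRNA/exon/CDS/UTR rows, one mRNA per gene)
write_gene_gff3 <- function(genes, path) {
  out <- "##gff-version 3"
  g <- genes$genes
  for (i in seq_along(g)) {
    gid <- g$gene_id[i]
    tid <- paste0(gid, ".t1")
    chr <- as.character(seqnames(g[i])); std <- as.character(strand(g[i]))
    line <- function(type, s, e, attrs)
      sprintf("%s\tlncscape\t%s\t%d\t%d\t.\t%s\t.\t%s", chr, type, s, e,
              std, attrs)
    out <- c(out,
             line("gene", start(g[i]), end(g[i]), paste0("ID=", gid)),
             line("mRNA", start(g[i]), end(g[i]),
                  paste0("ID=", tid, ";Parent=", gid)))
    for (feat in c("exons", "cds", "utr5", "utr3")) {
      fg <- if (feat == "exons") genes$exons[[gid]] else {
        x <- genes[[feat]]; x[x$gene_id == gid]
      }
      type <- c(exons = "exon", cds = "CDS", utr5 = "five_prime_UTR",
                utr3 = "three_prime_UTR")[[feat]]
      for (j in seq_along(fg))
        out <- c(out, line(type, start(fg[j]), end(fg[j]),
                           paste0("Parent=", tid)))
    }
  }
  writeLines(out, path)
  invisible(path)
}

# run-length encode a per-base score vector into bedGraph lines
write_bedgraph_runs <- function(v, chrom, path) {
  r <- rle(v)
  e <- cumsum(r$lengths)
  s <- c(0L, e[-length(e)])
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom, s, e,
                     formatC(r$values, format = "f", digits = 3)), path)
  invisible(path)
}

# minimal single-sample VCF writer
write_vcf <- function(df, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\tDP=%d",
                  df$chrom, df$pos, df$ref, df$alt,
                  formatC(df$qual, format = "f", digits = 1), df$dp)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Generate a boundary-case bundle
#'
#' Plants transcripts straddling every printed threshold: spliced lengths
#' 199/200/201 around the strict "longer than 200 bp" rule; FPKM exactly at
#' and just above 0.5 (single-exon) and 0.1 (multi-exon); TE exon overlap of
#' 4 vs 5 bp; 12-bp windows with means 0.55/0.60/0.65 around the strict
#' "more than 0.6" patch rule; and JS scores just below, at, and above the
#' inclusive 0.9 tissue-specificity threshold. Truth records the expected
#' outcome of every case under the strict/inclusive conventions.
#'
#' @param out_dir output directory.
#' @param eps margin used for the "just above" FPKM cases.
#' @param seed integer seed for the genome sequence.
#' @return (invisibly) list: `paths`, `truth` (`data.frame` with one row per
#'   case), plus in-memory `transcripts`, `genes`, `tes`, `expr`, `flags`.
#' @export
plant_boundary_cases <- function(out_dir = tempfile("lnc_boundary_"),
                                 eps = 1e-3, seed = 1L) {
  stopifnot(eps > 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(component_seed(seed, 99))
  chrom <- "chrB"; L <- 40000L
  tissues <- c("root", "stem", "leaf", "flower", "seed")
  ex <- list(); expr_rows <- list(); truth <- list(); cursor <- 1500L
  add <- function(id, widths, gaps = integer(0), fpkm,
                  expect_pass = TRUE, expect_te_lnc = NA,
                  expect_patch = NA, expect_ts = NA) {
    s <- integer(length(widths)); e <- integer(length(widths)); p <- cursor
    for (k in seq_along(widths)) {
      s[k] <- p; e[k] <- p + widths[k] - 1L
      p <- e[k] + 1L + if (k < length(widths)) gaps[k] else 0L
    }
    g <- GRanges(chrom, IRanges(s, e), strand = "+")
    mcols(g)$transcript_id <- id; mcols(g)$gene_id <- paste0("g_", id)
    ex[[id]] <<- g
    expr_rows[[id]] <<- fpkm
    truth[[id]] <<- data.frame(transcript_id = id,
                               expect_pass = expect_pass,
                               expect_te_lnc = expect_te_lnc,
                               expect_patch = expect_patch,
                               expect_ts = expect_ts,
                               stringsAsFactors = FALSE)
    cursor <<- max(e) + 1200L
  }
  flat <- function(v) rep(v, length(tissues))
  one <- function(v) c(v, numeric(length(tissues) - 1))
  # length boundary (strict >200)
  add("len199", 199L, fpkm = flat(2), expect_pass = FALSE)
  add("len200", 200L, fpkm = flat(2), expect_pass = FALSE)
  add("len201", 201L, fpkm = flat(2), expect_pass = TRUE)
  # FPKM boundaries (strict)
  add("fpkm_single_at", 300L, fpkm = one(0.5), expect_pass = FALSE)
  add("fpkm_single_above", 300L, fpkm = one(0.5 + eps), expect_pass = TRUE)
  add("fpkm_multi_at", c(150L, 150L), gaps = 120L, fpkm = one(0.1),
      expect_pass = FALSE)
  add("fpkm_multi_above", c(150L, 150L), gaps = 120L, fpkm = one(0.1 + eps),
      expect_pass = TRUE)
  # TE exon overlap boundary (>= 5 bp)
  add("te4", 400L, fpkm = flat(2), expect_te_lnc = FALSE)
  add("te5", 400L, fpkm = flat(2), expect_te_lnc = TRUE)
  te4_ex <- ex[["te4"]]; te5_ex <- ex[["te5"]]
  tes <- GRanges(chrom,
                 IRanges(c(start(te4_ex) - 50L, start(te5_ex) - 50L),
                         c(start(te4_ex) + 3L, start(te5_ex) + 4L)),
                 strand = "+")
  mcols(tes)$repeat_name <- c("RPT1", "RPT2")
  mcols(tes)$repeat_family <- c("LTR/Gypsy", "DNA/MuDR")
  mcols(tes)$te_class <- te_class_of(tes$repeat_family)
  seqlengths(tes) <- setNames(L, chrom)
  # conserved-patch boundary (window mean strictly > 0.6)
  add("patch055", 300L, fpkm = flat(2), expect_patch = FALSE)
  add("patch060", 300L, fpkm = flat(2), expect_patch = FALSE)
  add("patch065", 300L, fpkm = flat(2), expect_patch = TRUE)
  # JS threshold (inclusive >= 0.9): two-tissue mixtures bracketing it
  js_two <- function(a) {
    p <- c(a, 1 - a); m1 <- c((a + 1) / 2, (1 - a) / 2)
    1 - sqrt(entropy2(m1) - entropy2(p) / 2)
  }
  a_at <- uniroot(function(a) js_two(a) - 0.9, c(0.7, 0.999999),
                  tol = 1e-14)$root + 1e-9
  two_vec <- function(a) c(a, 1 - a, numeric(length(tissues) - 2))
  add("js_below", 300L, fpkm = two_vec(a_at - 0.02) * 10,
      expect_ts = FALSE)
  add("js_at", 300L, fpkm = two_vec(a_at) * 10, expect_ts = TRUE)
  add("js_above", 300L, fpkm = one(5), expect_ts = TRUE)

  exons <- unlist(GRangesList(ex), use.names = FALSE)
  txs <- make_transcript_set(exons)
  expr <- do.call(rbind, expr_rows)
  colnames(expr) <- tissues
  flags <- data.frame(transcript_id = names(ex), coding_by_cpc = FALSE,
                      coding_by_plek = FALSE, has_swissprot_hit = FALSE,
                      has_pfam_hit = FALSE, has_rfam_hit = FALSE)
  # conservation: background 0.05 over all exons, planted 12-base runs
  cons <- rep(0.05, L)
  for (cse in list(c("patch055", 0.55), c("patch060", 0.60),
                   c("patch065", 0.65))) {
    s <- start(ex[[cse[[1]]]]) + 20L
    cons[s:(s + 11L)] <- as.numeric(cse[[2]])
  }
  genome <- DNAStringSet(setNames(
    paste(rand_bases(L, 0.38), collapse = ""), chrom))
  paths <- setNames(file.path(out_dir,
                              c("genome.fa", "genes.gff3", "transcripts.gtf",
                                "repeats.out", "conservation.bedGraph",
                                "expression.tsv", "flags.tsv", "truth.tsv")),
                    c("genome", "genes", "transcripts", "repeats",
                      "conservation", "expression", "flags", "truth"))
  writeXStringSet(genome, paths[["genome"]])
  writeLines("##gff-version 3", paths[["genes"]])
  write_gtf(txs, paths[["transcripts"]])
  write_repeatmasker_out(tes, paths[["repeats"]])
  write_bedgraph_runs(cons, chrom, paths[["conservation"]])
  write_expression_tsv(expr, paths[["expression"]])
  write.table(flags, paths[["flags"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- do.call(rbind, truth)
  write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  empty_genes <- structure(list(
    genes = GRanges(gene_id = character(0)),
    exons = GRangesList(), cds = GRanges(gene_id = character(0)),
    utr5 = GRanges(gene_id = character(0)),
    utr3 = GRanges(gene_id = character(0)),
    introns = GRanges(gene_id = character(0))), class = "gene_set")
  invisible(list(paths = paths, truth = truth, transcripts = txs,
                 genes = empty_genes, tes = tes, expr = expr, flags = flags,
                 chrom_sizes = setNames(L, chrom)))
}
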