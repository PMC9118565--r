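# Independent oracles: per-base brute-force interval arithmetic and a
# Kullback-Leibler-based Jensen-Shannon evaluation, deliberately written on
# different code paths than the package (logical masks and KL sums instead
# of interval trees and entropy differences).

library(GenomicRanges)
library(IRanges)

# logical per-base mask of a GRanges over [1, L]
mask_of_gr <- function(gr, L) {
  m <- logical(L)
  for (i in seq_along(gr)) m[start(gr)[i]:end(gr)[i]] <- TRUE
  m
}

# per-base overlap bp between two interval sets
brute_overlap_bp <- function(a, b, L) {
  sum(mask_of_gr(a, L) & mask_of_gr(b, L))
}

# per-base classifier mirroring the documented decision order:
# antisense exon overlap >= min_bp -> lncNAT; same-strand exon overlap >= 1
# -> sense_overlap_excluded; span touching a gene span -> intronic; else
# lincRNA
brute_classify <- function(txs, gene_exons, gene_spans, L, min_bp = 1) {
  exon_plus <- mask_of_gr(gene_exons[strand(gene_exons) == "+"], L)
  exon_minus <- mask_of_gr(gene_exons[strand(gene_exons) == "-"], L)
  span_any <- mask_of_gr(gene_spans, L)
  u <- unlist(txs, use.names = FALSE)
  grp <- rep(seq_along(txs), lengths(txs))
  us <- start(u); ue <- end(u)
  ustd <- as.character(strand(u))
  vapply(seq_along(txs), function(i) {
    k <- which(grp == i)
    pos <- unlist(mapply(seq, us[k], ue[k], SIMPLIFY = FALSE))
    std <- ustd[k[1]]
    anti <- if (std == "+") sum(exon_minus[pos]) else sum(exon_plus[pos])
    sense <- if (std == "+") sum(exon_plus[pos]) else sum(exon_minus[pos])
    span_pos <- min(us[k]):max(ue[k])
    if (anti >= min_bp) "lncNAT"
    else if (sense >= 1) "sense_overlap_excluded"
    else if (any(span_any[span_pos])) "intronic"
    else "lincRNA"
  }, character(1))
}

# random annotation on a short chromosome: genes (possibly overlapping each
# other) and candidate transcripts with 1-2 non-overlapping exons each
random_annotation <- function(seed, L = 50000L, n_genes = 15L, n_tx = 25L) {
  set.seed(seed)
  # exon coordinate table for n units with 1-2 exons each
  mk_tbl <- function(n_units, prefix) {
    rows <- lapply(seq_len(n_units), function(i) {
      n_ex <- sample(1:2, 1)
      std <- sample(c("+", "-"), 1)
      s1 <- sample.int(L - 3000L, 1)
      w <- sample(100:600, n_ex, replace = TRUE)
      s <- if (n_ex == 1) s1 else c(s1, s1 + w[1] + sample(50:400, 1))
      data.frame(start = s, end = s + w - 1, strand = std,
                 id = sprintf("%s%02d", prefix, i))
    })
    do.call(rbind, rows)
  }
  gt <- mk_tbl(n_genes, "g")
  gene_exons <- GRanges("chr1", IRanges(gt$start, gt$end),
                        strand = gt$strand)
  mcols(gene_exons)$gene_id <- gt$id
  gene_spans <- unlist(range(split(gene_exons, gene_exons$gene_id)))
  tt <- mk_tbl(n_tx, "t")
  tx_exons <- GRanges("chr1", IRanges(tt$start, tt$end), strand = tt$strand)
  mcols(tx_exons)$transcript_id <- tt$id
  mcols(tx_exons)$gene_id <- paste0("gx_", tt$id)
  # exons are generated in sorted order within each gene
  ex_by_gene <- split(granges(gene_exons), gene_exons$gene_id)
  list(txs = make_transcript_set(tx_exons),
       genes = structure(list(genes = gene_spans, exons = ex_by_gene),
                         class = "gene_set"),
       gene_exons = gene_exons, gene_spans = gene_spans, L = L)
}

# Jensen-Shannon tissue-specificity via Kullback-Leibler sums (bits)
oracle_js <- function(x) {
  p <- x / sum(x)
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  scores <- vapply(seq_along(p), function(t) {
    e <- numeric(length(p)); e[t] <- 1
    m <- (p + e) / 2
    1 - sqrt(0.5 * kl(p, m) + 0.5 * kl(e, m))
  }, numeric(1))
  max(scores)
}

# small toy track builder: per-base numeric vector -> cons_track
toy_track <- function(values, chrom = "chr1") {
  structure(setNames(list(S4Vectors::Rle(values)), chrom),
            class = "cons_track")
}

# brute-force sliding-window means (loop, not cumsum)
brute_window_means <- function(v, w) {
  n <- length(v) - w + 1
  if (n < 1) return(numeric(0))
  vapply(seq_len(n), function(i) mean(v[i:(i + w - 1)]), numeric(1))
}

# one-transcript helper
single_tx <- function(start, end, strand = "+", id = "t1", chrom = "chr1") {
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(gr)$transcript_id <- id
  mcols(gr)$gene_id <- paste0("g_", id)
  make_transcript_set(gr)
}
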