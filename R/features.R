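# Molecular-feature panel per transcript class: length, exon number,
# splicing ratio, GC content, SNP density, splice-site base composition,
# plus length-matched intergenic control intervals.

#' GC content of a set of intervals
#'
#' (G+C) / (A+C+G+T) over the union of the intervals; ambiguous bases (N)
#' are excluded from the denominator. Strand is irrelevant since G+C is
#' strand-symmetric.
#'
#' @param intervals `GRanges`.
#' @param genome `DNAStringSet`.
#' @return fraction in [0, 1]; `NaN` if the union contains no unambiguous
#'   base.
#' @export
gc_content <- function(intervals, genome) {
  if (length(intervals) == 0) return(NaN)
  u <- reduce(granges(intervals), ignore.strand = TRUE)
  chr <- as.character(seqnames(u))
  if (!all(chr %in% names(genome)))
    stop("interval on sequence absent from genome: ",
         paste(setdiff(chr, names(genome)), collapse = ", "))
  if (any(end(u) > BiocGenerics::width(genome)[match(chr, names(genome))]))
    stop("interval beyond sequence end")
  seqs <- DNAStringSet(lapply(seq_along(u), function(i)
    subseq(genome[[chr[i]]], start(u[i]), end(u[i]))))
  counts <- colSums(letterFrequency(seqs, c("A", "C", "G", "T")))
  unname((counts["G"] + counts["C"]) / sum(counts))
}

#' Per-class molecular feature summary
#'
#' For each class: transcript count, median spliced length, mean exon
#' number, splicing ratio (fraction of transcripts with two or more exons),
#' GC content over exonic sequence, and SNP density per kb of the class's
#' exon union (so overlapping transcripts are not double counted).
#'
#' @param txs_by_class named list of transcript sets.
#' @param genome `DNAStringSet`, or `NULL` to skip GC.
#' @param variants SNP `data.frame` from [read_vcf_filtered()], or `NULL`
#'   to skip SNP density.
#' @return `data.frame` with one row per non-empty class: `class`, `n`,
#'   `length_median`, `exon_mean`, `splicing_ratio`, `gc`, `snp_per_kb`.
#'   Empty classes are dropped with a warning.
#' @export
feature_summary <- function(txs_by_class, genome = NULL, variants = NULL) {
  empty <- vapply(txs_by_class, length, integer(1)) == 0
  if (any(empty)) {
    warning("empty class(es) omitted: ",
            paste(names(txs_by_class)[empty], collapse = ", "))
    txs_by_class <- txs_by_class[!empty]
  }
  snp_gr <- if (!is.null(variants) && nrow(variants) > 0)
    GRanges(variants$chrom, IRanges(variants$pos, variants$pos)) else NULL
  rows <- lapply(names(txs_by_class), function(cl) {
    txs <- txs_by_class[[cl]]
    union <- reduce(unlist(txs, use.names = FALSE), ignore.strand = TRUE)
    ukb <- sum(width(union)) / 1000
    snp <- if (is.null(snp_gr)) NA_real_ else
      sum(overlapsAny(snp_gr, union, ignore.strand = TRUE)) / ukb
    data.frame(class = cl,
               n = length(txs),
               length_median = median(tx_lengths(txs)),
               exon_mean = mean(lengths(txs)),
               splicing_ratio = mean(lengths(txs) >= 2),
               gc = if (is.null(genome)) NA_real_ else gc_content(union, genome),
               snp_per_kb = snp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sample length-matched intergenic control intervals
#'
#' Draws intervals uniformly from the complement of gene spans, with lengths
#' resampled from `lengths` (typically the lincRNA length distribution) so
#' that GC/conservation comparisons against transcribed classes are fair.
#' Reproducible under `seed`.
#'
#' @param genes `GRanges` of gene spans (or a `gene_set`).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param n number of intervals.
#' @param lengths pool of lengths to resample.
#' @param seed integer seed.
#' @param max_tries placement attempts before giving up.
#' @return `GRanges` of `n` intervals, none intersecting a gene span.
#' @export
sample_intergenic_controls <- function(genes, chrom_sizes, n, lengths,
                                       seed = 1L, max_tries = 100 * n) {
  if (is(genes, "gene_set") || (is.list(genes) && !is(genes, "GRanges")))
    genes <- genes$genes
  gspan <- granges(genes)
  strand(gspan) <- "*"
  si <- Seqinfo(names(chrom_sizes), unname(chrom_sizes))
  seqlevels(gspan) <- names(chrom_sizes)
  seqinfo(gspan) <- si
  free <- gaps(reduce(gspan))
  free <- free[strand(free) == "*"]
  if (sum(width(free)) == 0)
    stop("no intergenic space: gene spans cover the genome")
  set.seed(seed)
  out <- GRanges()
  tries <- 0L
  while (length(out) < n && tries < max_tries) {
    tries <- tries + 1L
    len <- sample(lengths, 1)
    cand <- free[width(free) >= len]
    if (length(cand) == 0) next
    # gap chosen proportionally to the number of valid start positions
    slots <- width(cand) - len + 1
    g <- cand[sample.int(length(cand), 1, prob = slots)]
    s <- start(g) + sample.int(width(g) - len + 1, 1) - 1L
    out <- c(out, GRanges(seqnames(g), IRanges(s, s + len - 1L)))
  }
  if (length(out) < n)
    stop("could only place ", length(out), " of ", n,
         " intergenic controls (deficit ", n - length(out), ")")
  seqlevels(out) <- names(chrom_sizes)
  seqinfo(out) <- si
  out
}

#' Splice-site base composition profile
#'
#' Tabulates base counts around splice donor and acceptor sites of
#' multi-exon transcripts. The donor window covers the last `flank` exonic
#' bases and the first `flank` intronic bases of each intron's 5' end (the
#' canonical GT occupies intronic positions +1/+2); the acceptor window
#' covers the last `flank` intronic bases (canonical AG at -2/-1) and the
#' first `flank` exonic bases at the 3' end. Minus-strand junctions are
#' reverse-complemented so all junctions read 5' to 3'.
#'
#' @param txs transcript set.
#' @param genome `DNAStringSet`.
#' @param flank bases on each side of the junction (default 10).
#' @return list of class `splice_profile`: `donor` and `acceptor`
#'   (4 x 2*flank count matrices, rows A/C/G/T, columns labelled by position
#'   relative to the exon/intron boundary), `n_junctions`, `n_skipped`
#'   (junctions whose window exceeded the chromosome).
#' @export
splice_site_profile <- function(txs, genome, flank = 10) {
  introns <- tx_introns(txs)
  ints <- unlist(introns, use.names = FALSE)
  std <- rep(tx_strands(txs), lengths(introns))
  chr <- as.character(seqnames(ints))
  chrlen <- setNames(BiocGenerics::width(genome), names(genome))[chr]
  # genomic windows: for + strand the donor sits at the intron start, for -
  # strand at the intron end (then reverse-complemented)
  don_s <- ifelse(std == "+", start(ints) - flank, end(ints) - flank + 1)
  don_e <- don_s + 2L * flank - 1L
  acc_s <- ifelse(std == "+", end(ints) - flank + 1, start(ints) - flank)
  acc_e <- acc_s + 2L * flank - 1L
  ok <- don_s >= 1 & acc_s >= 1 & don_e <= chrlen & acc_e <= chrlen
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    message(n_skipped, " junction(s) skipped: window beyond chromosome end")
  fetch <- function(s, e, keep) {
    seqs <- DNAStringSet(lapply(which(keep), function(i)
      subseq(genome[[chr[i]]], s[i], e[i])))
    neg <- std[keep] == "-"
    if (any(neg)) seqs[neg] <- reverseComplement(seqs[neg])
    seqs
  }
  poscols <- c(-flank:-1, 1:flank)
  tab <- function(seqs) {
    if (length(seqs) == 0)
      return(matrix(0L, 4, 2 * flank,
                    dimnames = list(c("A", "C", "G", "T"), poscols)))
    m <- consensusMatrix(seqs)[c("A", "C", "G", "T"), , drop = FALSE]
    colnames(m) <- poscols
    m
  }
  structure(list(donor = tab(fetch(don_s, don_e, ok)),
                 acceptor = tab(fetch(acc_s, acc_e, ok)),
                 n_junctions = sum(ok), n_skipped = n_skipped),
            class = "splice_profile")
}
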