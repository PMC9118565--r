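# Shared interval helpers. Transcript sets are GRangesList objects: one
# element per transcript (its exons, sorted, single chrom/strand), names are
# transcript ids, mcols carry gene_id. This mirrors GenomicFeatures::exonsBy.

#' Build a transcript set from per-exon coordinates
#'
#' A transcript set is a named `GRangesList` (exons grouped by transcript,
#' sorted by start) with a `gene_id` metadata column, the unit every
#' classification and scoring function operates on.
#'
#' @param exons `GRanges` of exons with metadata columns `transcript_id`
#'   and `gene_id`.
#' @return Named `GRangesList`, one element per transcript.
#' @export
make_transcript_set <- function(exons) {
  stopifnot(is(exons, "GRanges"),
            all(c("transcript_id", "gene_id") %in% names(mcols(exons))))
  if (length(exons) == 0) {
    txs <- GRangesList()
    mcols(txs)$gene_id <- character(0)
    return(txs)
  }
  if (anyNA(exons$transcript_id))
    stop("exon without transcript_id attribute")
  exons <- exons[order(exons$transcript_id, start(exons))]
  txs <- split(granges(exons), exons$transcript_id)
  gid <- exons$gene_id[!duplicated(exons$transcript_id)]
  names(gid) <- exons$transcript_id[!duplicated(exons$transcript_id)]
  mcols(txs)$gene_id <- unname(gid[names(txs)])
  validate_transcript_set(txs)
  txs
}

#' Validate a transcript set
#'
#' Checks the structural invariants: at least one exon per transcript, all
#' exons of a transcript on one chromosome and strand, exons sorted and
#' non-overlapping.
#'
#' @param txs transcript set (`GRangesList`).
#' @return `txs` invisibly; stops on violation.
#' @export
validate_transcript_set <- function(txs) {
  if (length(txs) == 0) return(invisible(txs))
  n_ex <- lengths(txs)
  if (any(n_ex < 1)) stop("transcript with zero exons")
  u <- unlist(txs, use.names = FALSE)
  f <- rep(seq_along(txs), n_ex)
  firsts <- cumsum(n_ex) - n_ex + 1L
  chr <- as.character(seqnames(u))
  if (!all(chr == rep(chr[firsts], n_ex)))
    stop("transcript with exons on multiple chromosomes")
  std <- as.character(strand(u))
  if (!all(std == rep(std[firsts], n_ex)))
    stop("transcript with exons on multiple strands")
  # within each transcript (sorted by start) exons must not touch/overlap
  same <- f[-1] == f[-length(f)]
  if (any(same)) {
    s <- start(u); e <- end(u)
    if (any(s[-1][same] <= s[-length(s)][same]))
      stop("transcript with unsorted exons")
    if (any(s[-1][same] <= e[-length(e)][same]))
      stop("transcript with overlapping exons")
  }
  invisible(txs)
}

#' Transcript spans
#'
#' @param txs transcript set.
#' @return `GRanges` of one span per transcript (5' end of the first exon to
#'   3' end of the last), names and `gene_id` carried over.
#' @export
tx_spans <- function(txs) {
  sp <- unlist(range(txs), use.names = TRUE)
  mcols(sp)$transcript_id <- names(sp)
  mcols(sp)$gene_id <- mcols(txs)$gene_id
  sp
}

#' Spliced (exonic) transcript lengths
#'
#' @param txs transcript set.
#' @return Named integer vector of summed exon widths.
#' @export
tx_lengths <- function(txs) {
  setNames(as.integer(sum(width(txs))), names(txs))
}

#' Strand of each transcript
#' @param txs transcript set.
#' @return Named character vector in `{+, -, *}`.
#' @export
tx_strands <- function(txs) {
  n_ex <- lengths(txs)
  firsts <- cumsum(n_ex) - n_ex + 1L
  u <- unlist(txs, use.names = FALSE)
  setNames(as.character(strand(u))[firsts], names(txs))
}

#' Introns of each transcript
#' @param txs transcript set.
#' @return `GRangesList` of gaps between consecutive exons (empty element for
#'   single-exon transcripts).
#' @export
tx_introns <- function(txs) {
  psetdiff(unlist(range(txs), use.names = TRUE), txs)
}

# Total bases of overlap between the exon union of each list element and a
# subject GRanges. Both sides reduced first so shared bases are never counted
# twice.
overlap_bp_by_tx <- function(txs, subject, ignore.strand = TRUE) {
  bp <- integer(length(txs))
  names(bp) <- names(txs)
  if (length(txs) == 0 || length(subject) == 0) return(bp)
  subject <- reduce(granges(subject), ignore.strand = ignore.strand)
  uq <- unlist(txs, use.names = FALSE)
  grp_of_exon <- rep(seq_along(txs), lengths(txs))
  ov <- findOverlaps(uq, subject, ignore.strand = ignore.strand)
  if (length(ov) == 0) return(bp)
  # intersection pieces, unioned per transcript before summing so no base
  # is ever counted twice (exons of one transcript share a chromosome)
  ps <- pmax(start(uq)[queryHits(ov)], start(subject)[subjectHits(ov)])
  pe <- pmin(end(uq)[queryHits(ov)], end(subject)[subjectHits(ov)])
  pieces <- S4Vectors::split(IRanges(ps, pe),
                             factor(grp_of_exon[queryHits(ov)],
                                    levels = seq_along(txs)))
  bp[] <- as.integer(sum(width(reduce(pieces))))
  bp
}

# Per-range overlap bp of a GRanges with a subject; subject reduced first so
# pieces are disjoint and their widths sum cleanly.
overlap_bp_by_range <- function(gr, subject, ignore.strand = TRUE) {
  bp <- integer(length(gr))
  names(bp) <- names(gr)
  if (length(gr) == 0 || length(subject) == 0) return(bp)
  subject <- reduce(granges(subject), ignore.strand = ignore.strand)
  ov <- findOverlaps(gr, subject, ignore.strand = ignore.strand)
  if (length(ov) == 0) return(bp)
  w <- pmin(end(gr)[queryHits(ov)], end(subject)[subjectHits(ov)]) -
    pmax(start(gr)[queryHits(ov)], start(subject)[subjectHits(ov)]) + 1L
  agg <- tapply(w, queryHits(ov), sum)
  bp[as.integer(names(agg))] <- as.integer(agg)
  bp
}

# Map an interval on the spliced transcript (1-based, 5'->3') back to genomic
# intervals. Used by the generator to derive CDS/UTR genomic coordinates.
spliced_to_genomic <- function(exons, from, to) {
  stopifnot(from >= 1, to >= from, to <= sum(width(exons)))
  std <- as.character(strand(exons)[1])
  ex <- if (std == "-") rev(sort(exons)) else sort(exons)
  w <- width(ex)
  off <- cumsum(c(0, w[-length(w)]))
  out <- GRanges()
  for (i in seq_along(ex)) {
    lo <- max(from, off[i] + 1); hi <- min(to, off[i] + w[i])
    if (lo > hi) next
    if (std == "-") {
      gs <- end(ex[i]) - (hi - off[i]) + 1
      ge <- end(ex[i]) - (lo - off[i]) + 1
    } else {
      gs <- start(ex[i]) + (lo - off[i]) - 1
      ge <- start(ex[i]) + (hi - off[i]) - 1
    }
    out <- c(out, GRanges(seqnames(ex[i]), IRanges(gs, ge), strand = std))
  }
  sort(out)
}
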