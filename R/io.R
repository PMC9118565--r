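# Readers and writers for every format the pipeline touches. All coordinates
# are 1-based closed internally (the GRanges convention); rtracklayer performs
# the conversions for 0-based formats (BED, bedGraph, narrowPeak).

#' Read transcript models from a GTF file
#'
#' Parses `exon` features and groups them per transcript. Coordinates come
#' back on the internal 1-based closed convention.
#'
#' @param path GTF file.
#' @return Transcript set (`GRangesList`, see [make_transcript_set()]).
#'   An empty or header-only file yields an empty set.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) return(make_transcript_set(
    GRanges(transcript_id = character(0), gene_id = character(0))))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("GTF parse error in ", path, ": ",
                             conditionMessage(e)))
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) return(make_transcript_set(
    GRanges(transcript_id = character(0), gene_id = character(0))))
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id)) {
    bad <- grep("transcript_id", body, invert = TRUE)
    stop("exon feature without transcript_id (first offending data line ",
         if (length(bad)) bad[1] else NA, ")")
  }
  if (is.null(gr$gene_id)) gr$gene_id <- gr$transcript_id
  ex <- granges(gr)
  mcols(ex)$transcript_id <- gr$transcript_id
  mcols(ex)$gene_id <- gr$gene_id
  make_transcript_set(ex)
}

#' Write a transcript set to GTF
#'
#' @param txs transcript set.
#' @param path output file.
#' @param source source tag for column 2.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(txs, path, source = "lncscape") {
  ex <- unlist(txs, use.names = FALSE)
  n_ex <- lengths(txs)
  df <- data.frame(
    seqnames = as.character(seqnames(ex)),
    source = source, feature = "exon",
    start = start(ex), end = end(ex), score = ".",
    strand = as.character(strand(ex)), frame = ".",
    attr = sprintf('transcript_id "%s"; gene_id "%s";',
                   rep(names(txs), n_ex),
                   rep(mcols(txs)$gene_id, n_ex)),
    stringsAsFactors = FALSE)
  writeLines(do.call(paste, c(df, sep = "\t")), path)
  invisible(path)
}

#' Write a transcript set to GFF3
#'
#' Emits one `transcript` feature per transcript plus its `exon` children.
#' An optional per-transcript class label is written as a `class=` attribute,
#' mirroring the classified-lncRNA annotation the pipeline publishes.
#'
#' @param txs transcript set.
#' @param path output file.
#' @param class optional named character vector (names = transcript ids).
#' @param source source tag for column 2.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(txs, path, class = NULL, source = "lncscape") {
  sp <- tx_spans(txs)
  cls_attr <- if (is.null(class)) "" else {
    stopifnot(all(names(txs) %in% names(class)))
    paste0(";class=", class[names(txs)])
  }
  tx_lines <- sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s%s",
                      as.character(seqnames(sp)), source, start(sp), end(sp),
                      as.character(strand(sp)), names(txs),
                      mcols(txs)$gene_id, cls_attr)
  ex <- unlist(txs, use.names = FALSE)
  parent <- rep(names(txs), lengths(txs))
  ex_lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                      as.character(seqnames(ex)), source, start(ex), end(ex),
                      as.character(strand(ex)), parent)
  out <- character(0)
  for (i in seq_along(txs)) {
    out <- c(out, tx_lines[i], ex_lines[parent == names(txs)[i]])
  }
  writeLines(c("##gff-version 3", out), path)
  invisible(path)
}

#' Read transcript models from a GFF3 file
#'
#' Reads `transcript`/`exon` (or `mRNA`/`exon`) features written by
#' [write_gff3()] or any GFF3 using `Parent` linkage.
#'
#' @param path GFF3 file.
#' @return Transcript set; any `class=` attribute is returned in
#'   `mcols()$class`.
#' @export
read_gff3_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tx <- gr[gr$type %in% c("transcript", "mRNA")]
  ex <- gr[gr$type == "exon"]
  parent <- as.character(unlist(ex$Parent))
  gid <- if (!is.null(tx$gene_id)) tx$gene_id else as.character(tx$ID)
  names(gid) <- as.character(tx$ID)
  exg <- granges(ex)
  mcols(exg)$transcript_id <- parent
  mcols(exg)$gene_id <- unname(gid[parent])
  txs <- make_transcript_set(exg)
  if (!is.null(tx$class)) {
    cl <- setNames(tx$class, as.character(tx$ID))
    mcols(txs)$class <- unname(cl[names(txs)])
  }
  txs
}

#' Read a coding-gene annotation from GFF3
#'
#' Builds a gene set: gene spans, exons per gene, and the CDS/5'UTR/3'UTR
#' sub-features used as comparison classes, plus introns derived as the gaps
#' between consecutive exons.
#'
#' @param path GFF3 with `gene`, `mRNA`, `exon`, `CDS`,
#'   `five_prime_UTR`/`three_prime_UTR` features linked by `Parent`/`ID`.
#' @return A list of class `gene_set`: `genes` (GRanges with `gene_id`),
#'   `exons` (GRangesList by gene), `cds`, `utr5`, `utr3`, `introns`
#'   (GRanges with `gene_id`).
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  mcols(genes) <- DataFrame(gene_id = as.character(genes$ID))
  names(genes) <- genes$gene_id
  mrna <- gr[gr$type == "mRNA"]
  gene_of_tx <- setNames(as.character(unlist(mrna$Parent)),
                         as.character(mrna$ID))
  child_gene <- function(feat) {
    p <- as.character(unlist(feat$Parent))
    g <- ifelse(p %in% names(gene_of_tx), gene_of_tx[p], p)
    out <- granges(feat)
    mcols(out)$gene_id <- unname(g)
    out
  }
  ex <- child_gene(gr[gr$type == "exon"])
  exons <- split(granges(ex), ex$gene_id)
  exons <- endoapply(exons, sort)
  spans <- unlist(range(exons), use.names = TRUE)
  intron_l <- psetdiff(spans, exons)
  introns <- unlist(intron_l, use.names = FALSE)
  mcols(introns)$gene_id <- rep(names(exons), lengths(intron_l))
  gs <- list(genes = genes,
             exons = exons,
             cds = child_gene(gr[gr$type == "CDS"]),
             utr5 = child_gene(gr[gr$type == "five_prime_UTR"]),
             utr3 = child_gene(gr[gr$type == "three_prime_UTR"]),
             introns = introns)
  class(gs) <- "gene_set"
  gs
}

#' Map a RepeatMasker class/family string to TE class
#'
#' Class I (retrotransposons, copy-and-paste via an RNA intermediate) vs
#' Class II (DNA transposons, cut-and-paste); everything else, including
#' simple/low-complexity repeats, is `other`.
#'
#' @param family character vector of RepeatMasker `class/family` strings.
#' @param class1_prefixes,class2_prefixes prefixes (before any `/`) mapped to
#'   Class I and Class II.
#' @return character vector in `{"I","II","other"}`.
#' @export
te_class_of <- function(family,
                        class1_prefixes = c("LINE", "SINE", "LTR", "Retroposon"),
                        class2_prefixes = c("DNA", "RC", "Helitron", "TIR", "MITE")) {
  pre <- sub("/.*$", "", family)
  pre <- sub("\\?$", "", pre)
  ifelse(pre %in% class1_prefixes, "I",
         ifelse(pre %in% class2_prefixes, "II", "other"))
}

#' Read a RepeatMasker .out annotation
#'
#' Standard layout: three header lines, whitespace-separated columns,
#' 1-based inclusive query coordinates, strand `C` meaning minus.
#'
#' @param path RepeatMasker `.out` file.
#' @return `GRanges` with `repeat_name`, `repeat_family`, `te_class`
#'   metadata. Unknown families map to `te_class = "other"` with a warning
#'   naming how many.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 3) lines <- lines[-(1:3)] else lines <- character(0)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(GRanges(repeat_name = character(0), repeat_family = character(0),
                   te_class = character(0)))
  f <- strsplit(trimws(lines), "\\s+")
  get <- function(i) vapply(f, `[[`, character(1), i)
  gr <- GRanges(get(5),
                IRanges(as.integer(get(6)), as.integer(get(7))),
                strand = ifelse(get(9) == "C", "-", "+"))
  mcols(gr)$repeat_name <- get(10)
  mcols(gr)$repeat_family <- get(11)
  mcols(gr)$te_class <- te_class_of(gr$repeat_family)
  known <- c("LINE", "SINE", "LTR", "Retroposon", "DNA", "RC", "Helitron",
             "TIR", "MITE", "Simple_repeat", "Low_complexity", "Satellite",
             "rRNA", "tRNA", "snRNA", "Unknown")
  unk <- !(sub("\\?$", "", sub("/.*$", "", gr$repeat_family)) %in% known)
  if (any(unk))
    warning(sum(unk), " repeat record(s) with unrecognized class/family ",
            "assigned te_class 'other'")
  gr
}

#' Write TE records as a RepeatMasker-style .out table
#'
#' @param tes `GRanges` with `repeat_name` and `repeat_family` metadata.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(tes, path) {
  hdr <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "")
  left <- if (!is.null(seqlengths(tes)) && !anyNA(seqlengths(tes)))
    seqlengths(tes)[as.character(seqnames(tes))] - end(tes) else 0L
  rows <- sprintf("%5d %5.1f %4.1f %4.1f  %-10s %8d %8d (%d) %s %-14s %-18s %6d %5d (0) %5d",
                  1000L, 10.0, 0.5, 0.5,
                  as.character(seqnames(tes)), start(tes), end(tes),
                  as.integer(left),
                  ifelse(as.character(strand(tes)) == "-", "C", "+"),
                  tes$repeat_name, tes$repeat_family,
                  1L, width(tes), seq_along(tes))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read and filter SNPs from a VCF file
#'
#' Applies the variant retention rule: quality strictly greater than
#' `min_qual`, read depth strictly greater than `min_depth`, single-base
#' reference and alternate alleles only. Records from multiple
#' libraries/tissues are merged by position (highest quality kept). Depth is
#' taken from INFO `DP`, falling back to the first sample's `DP`; records
#' with no depth are dropped and counted.
#'
#' @param path VCF 4.x file (plain text).
#' @param min_qual quality threshold (exclusive). Quality is the record QUAL
#'   column (configurable source of "quality").
#' @param min_depth depth threshold (exclusive).
#' @return `data.frame` with `chrom`, `pos` (1-based), `ref`, `alt`, `qual`,
#'   `depth`, sorted by position. Attribute `n_dropped_no_depth` counts
#'   records dropped for missing depth.
#' @export
read_vcf_filtered <- function(path, min_qual = 10, min_depth = 5) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(structure(data.frame(chrom = character(0), pos = integer(0),
                                ref = character(0), alt = character(0),
                                qual = numeric(0), depth = integer(0)),
                     n_dropped_no_depth = 0L))
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  if (all(is.na(dp)) && ncol(v@gt) >= 2) {
    gdp <- vcfR::extract.gt(v, "DP")
    dp <- suppressWarnings(as.integer(gdp[, 1]))
  }
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  no_depth <- is.na(dp)
  n_dropped <- sum(no_depth)
  if (n_dropped > 0)
    message(n_dropped, " VCF record(s) without DP dropped")
  is_snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE)
  keep <- !no_depth & !is.na(qual) & qual > min_qual & dp > min_depth & is_snp
  out <- data.frame(chrom = fix$CHROM[keep],
                    pos = as.integer(fix$POS[keep]),
                    ref = fix$REF[keep], alt = fix$ALT[keep],
                    qual = qual[keep], depth = dp[keep],
                    stringsAsFactors = FALSE)
  # merge multi-library records at the same site, keeping the best-supported
  out <- out[order(out$chrom, out$pos, -out$qual), , drop = FALSE]
  out <- out[!duplicated(out[c("chrom", "pos")]), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_dropped_no_depth = n_dropped)
}

#' Read a per-base conservation track from bedGraph
#'
#' Expands interval scores to per-base values. Scores must lie in [0, 1]
#' (the PhastCons contract); overlapping intervals are an error; bases not
#' covered by any interval are missing (`NA`).
#'
#' @param path bedGraph file (0-based half-open intervals, converted on read).
#' @return A `cons_track`: named list of per-chromosome `Rle` vectors with
#'   `NA` for missing bases.
#' @export
read_conservation_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(gr$score < 0 | gr$score > 1))
    stop("conservation score outside [0,1] in ", path)
  red <- reduce(gr, ignore.strand = TRUE)
  if (sum(width(red)) != sum(width(gr)))
    stop("overlapping intervals in bedGraph ", path)
  track <- lapply(split(gr, seqnames(gr), drop = TRUE), function(g) {
    n <- max(end(g))
    v <- rep(NA_real_, n)
    s <- start(g); e <- end(g); sc <- g$score
    for (i in seq_along(s)) v[s[i]:e[i]] <- sc[i]
    S4Vectors::Rle(v)
  })
  structure(as.list(track), class = "cons_track")
}

#' Per-base scores of a conservation track over exons
#'
#' Returns the spliced 5' to 3' vector of per-base scores for one transcript
#' (exons concatenated; reversed for minus-strand transcripts). Bases beyond
#' the stored track are missing.
#'
#' @param track `cons_track`.
#' @param exons `GRanges` of one transcript's exons.
#' @return numeric vector, `NA` where the track is missing.
#' @export
track_values <- function(track, exons) {
  std <- as.character(strand(exons)[1])
  ex <- sort(exons)
  out <- unlist(lapply(seq_along(ex), function(i) {
    chr <- as.character(seqnames(ex[i]))
    v <- track[[chr]]
    idx <- start(ex[i]):end(ex[i])
    if (is.null(v)) return(rep(NA_real_, length(idx)))
    vals <- rep(NA_real_, length(idx))
    ok <- idx <= length(v)
    vals[ok] <- as.numeric(v[idx[ok]])
    vals
  }), use.names = FALSE)
  if (std == "-") rev(out) else out
}

#' Read an expression matrix from TSV
#'
#' @param path TSV; first column transcript ids, header row tissue names.
#' @return numeric matrix (transcripts x tissues), FPKM units.
#' @export
read_expression_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  m <- as.matrix(df)
  if (any(m < 0)) stop("negative FPKM in ", path)
  if (anyDuplicated(rownames(m))) stop("duplicate transcript ids in ", path)
  m
}

#' Write an expression matrix to TSV
#' @param m matrix; @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(transcript_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read ChIP-seq peaks (BED6 or narrowPeak)
#'
#' The `name` column carries the transcription-factor name. For narrowPeak
#' input the summit is `start + peak offset`; for BED6, or narrowPeak rows
#' with offset -1, the midpoint is used and a message reports how many.
#'
#' @param path BED6 or narrowPeak file.
#' @return `GRanges` with `tf_name`, `score`, `summit` (1-based position).
#' @export
read_peaks <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  fmt <- if (length(first) >= 10) "narrowPeak" else "BED"
  gr <- rtracklayer::import(path, format = fmt)
  tf <- if (!is.null(gr$name)) gr$name else rep(NA_character_, length(gr))
  summit <- rep(NA_integer_, length(gr))
  if (fmt == "narrowPeak") {
    off <- gr$peak
    has <- !is.na(off) & off >= 0
    summit[has] <- start(gr)[has] + off[has]
  }
  mid <- is.na(summit)
  if (any(mid)) {
    summit[mid] <- as.integer(floor((start(gr)[mid] + end(gr)[mid]) / 2))
    if (fmt == "narrowPeak")
      message(sum(mid), " peak(s) without summit; midpoint used")
  }
  out <- granges(gr)
  mcols(out) <- DataFrame(tf_name = tf,
                          score = if (!is.null(gr$score)) gr$score else NA,
                          summit = summit)
  out
}

#' Read cross-species alignment hits (BLAST outfmt 6)
#'
#' @param path tabular BLAST output (12 columns, no header).
#' @param query_species,subject_species species labels attached to every row.
#' @return `data.frame` with `query_id`, `query_species`, `subject_species`,
#'   `identity_pct`, `align_len`, `evalue`.
#' @export
read_blast_hits <- function(path, query_species = NA_character_,
                            subject_species = NA_character_) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(df)[seq_len(min(ncol(df), 12))] <- cols[seq_len(min(ncol(df), 12))]
  data.frame(query_id = df$qseqid,
             query_species = query_species,
             subject_species = subject_species,
             identity_pct = df$pident,
             align_len = as.integer(df$length),
             evalue = as.numeric(df$evalue),
             stringsAsFactors = FALSE)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return `DNAStringSet`, names truncated at the first whitespace.
#' @export
read_genome <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
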