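# Identification filters and lincRNA/lncNAT classification.

mk_flags <- function(ids, ...) {
  df <- data.frame(transcript_id = ids, coding_by_cpc = FALSE,
                   coding_by_plek = FALSE, has_swissprot_hit = FALSE,
                   has_pfam_hit = FALSE, has_rfam_hit = FALSE)
  over <- list(...)
  for (k in names(over)) df[[k]] <- over[[k]]
  df
}

mk_expr <- function(ids, maxes, n_tissues = 3) {
  m <- matrix(0, length(ids), n_tissues,
              dimnames = list(ids, paste0("t", seq_len(n_tissues))))
  m[, 1] <- maxes
  m
}

test_that("all four identification criteria apply with strict thresholds", {
  ex <- c(single_tx(101, 400, id = "a300"),          # length 300, single exon
          single_tx(101, 300, id = "a200"),          # length exactly 200
          make_transcript_set(local({                # 2-exon, length 500
            g <- GRanges("chr1", IRanges(c(1001, 1501), c(1250, 1750)),
                         strand = "+")
            mcols(g)$transcript_id <- "m500"; mcols(g)$gene_id <- "gm"
            g
          })))
  flags <- mk_flags(names(ex))
  expr <- mk_expr(names(ex), c(0.6, 5, 0.1))
  r <- apply_identification_filters(ex, flags, expr)
  r <- r[match(c("a300", "a200", "m500"), r$transcript_id), ]
  expect_identical(r$pass, c(TRUE, FALSE, FALSE))
  expect_identical(r$fail_reasons, c("", "length", "expression"))

  # all failed criteria are recorded, not just the first
  flags2 <- mk_flags(names(ex), coding_by_plek = c(TRUE, TRUE, FALSE),
                     has_rfam_hit = c(TRUE, FALSE, FALSE))
  r2 <- apply_identification_filters(ex, flags2, mk_expr(names(ex),
                                                         c(0.4, 5, 5)))
  expect_identical(r2$fail_reasons[r2$transcript_id == "a300"],
                   "coding_potential,homology,expression")

  # missing rows are an error naming the transcript
  expect_error(apply_identification_filters(ex, flags[-1, ], expr), "a300")
  expect_error(apply_identification_filters(ex, flags, expr[-1, ]), "a300")
})

test_that("single vs multi-exon transcripts use their own FPKM thresholds", {
  single <- single_tx(101, 400, id = "s")
  multi <- make_transcript_set(local({
    g <- GRanges("chr1", IRanges(c(101, 501), c(250, 650)), strand = "+")
    mcols(g)$transcript_id <- "m"; mcols(g)$gene_id <- "gm"
    g
  }))
  txs <- c(single, multi)
  flags <- mk_flags(names(txs))
  for (cse in list(c(0.5, FALSE), c(0.51, TRUE))) {
    r <- apply_identification_filters(txs, flags,
                                      mk_expr(names(txs), c(cse[[1]], 1)))
    expect_identical(r$pass[r$transcript_id == "s"], as.logical(cse[[2]]))
  }
  for (cse in list(c(0.1, FALSE), c(0.11, TRUE))) {
    r <- apply_identification_filters(txs, flags,
                                      mk_expr(names(txs), c(1, cse[[1]])))
    expect_identical(r$pass[r$transcript_id == "m"], as.logical(cse[[2]]))
  }
})

test_that("antisense exon overlap counts opposite-strand bases once", {
  g1 <- GRanges("chr1", IRanges(151, 250), strand = "+", gene_id = "gA")
  t_min <- single_tx(101, 200, strand = "-")
  expect_identical(antisense_exon_overlap(t_min, g1)$antisense_bp, 50L)
  t_pls <- single_tx(101, 200, strand = "+")
  expect_identical(antisense_exon_overlap(t_pls, g1)$antisense_bp, 0L)

  # two exons against one antisense gene exon, checked per base
  ex <- GRanges("chr1", IRanges(c(1, 201), c(100, 300)), strand = "+")
  mcols(ex)$transcript_id <- "t2"; mcols(ex)$gene_id <- "gt2"
  txs <- make_transcript_set(ex)
  gx <- GRanges("chr1", IRanges(51, 250), strand = "-", gene_id = "gB")
  got <- antisense_exon_overlap(txs, gx)
  expect_identical(got$antisense_bp, brute_overlap_bp(ex, gx, 1000L))
  expect_identical(got$antisense_bp, 100L)
  expect_identical(got$partner_genes, "gB")

  expect_error(antisense_exon_overlap(single_tx(1, 100, strand = "*"), g1),
               "strand")
})

test_that("classification assigns lincRNA, lncNAT, sense and intronic", {
  # one gene on + with exons 1001-1200 and 1501-1700
  gex <- GRanges("chr1", IRanges(c(1001, 1501), c(1200, 1700)), strand = "+")
  genes <- structure(list(
    genes = GRanges("chr1", IRanges(1001, 1700), strand = "+",
                    gene_id = "gA"),
    exons = GRangesList(gA = gex)), class = "gene_set")
  txs <- c(
    single_tx(20001, 21000, "+", id = "far"),          # intergenic
    single_tx(1051, 1150, "-", id = "anti"),           # antisense in exon
    single_tx(1171, 1400, "+", id = "sense"),          # 30 bp sense overlap
    single_tx(1251, 1450, "-", id = "inside"))         # intron only
  cl <- classify_transcripts(txs, genes)
  got <- setNames(cl$class, cl$transcript_id)
  expect_identical(unname(got[c("far", "anti", "sense", "inside")]),
                   c("lincRNA", "lncNAT", "sense_overlap_excluded",
                     "intronic"))
  expect_identical(cl$sense_bp[cl$transcript_id == "sense"], 30L)
  expect_identical(cl$antisense_bp[cl$transcript_id == "anti"], 100L)
  expect_identical(cl$partner_genes[cl$transcript_id == "anti"], "gA")
  expect_error(classify_transcripts(single_tx(1, 300, "*"), genes), "strand")
})

test_that("every transcript receives exactly one class (partition)", {
  b <- generate_dataset(generator_config(seed = 11))
  cl <- classify_lncrnas(b$transcripts, b$flags, b$expr, b$genes)
  expect_identical(nrow(cl), length(b$transcripts))
  expect_identical(anyDuplicated(cl$transcript_id), 0L)
  expect_true(all(cl$class %in% c("lincRNA", "lncNAT",
                                  "sense_overlap_excluded", "intronic",
                                  "filtered_out")))
  expect_identical(sum(table(cl$class)), length(b$transcripts))
})

test_that("raising FPKM thresholds never increases the survivor count", {
  b <- generate_dataset(generator_config(seed = 5))
  n_pass <- vapply(c(0.1, 0.5, 2, 10, 50), function(thr)
    sum(apply_identification_filters(b$transcripts, b$flags, b$expr,
                                     fpkm_single = thr,
                                     fpkm_multi = thr / 5)$pass),
    integer(1))
  expect_true(all(diff(n_pass) <= 0))
  n_len <- vapply(c(100, 200, 400, 800), function(thr)
    sum(apply_identification_filters(b$transcripts, b$flags, b$expr,
                                     length_min = thr)$pass), integer(1))
  expect_true(all(diff(n_len) <= 0))
})

test_that("interval classification matches the per-base oracle", {
  for (seed in 1:12) {
    ann <- random_annotation(seed)
    got <- classify_transcripts(ann$txs, ann$genes)
    want <- brute_classify(ann$txs, ann$gene_exons, ann$gene_spans, ann$L)
    expect_identical(got$class, unname(want),
                     info = paste("seed", seed))
  }
})
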