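# TE origination analyses.

mk_te <- function(starts, ends, fam = "LTR/Gypsy") {
  gr <- GRanges("chr1", IRanges(starts, ends), strand = "+")
  mcols(gr)$repeat_name <- paste0("r", seq_along(gr))
  mcols(gr)$repeat_family <- rep(fam, length.out = length(gr))
  mcols(gr)$te_class <- te_class_of(gr$repeat_family)
  gr
}

test_that("TE-lncRNA calls use the 5-bp exonic overlap rule", {
  tx <- single_tx(101, 200)
  at5 <- mk_te(196, 210)   # overlap 196-200 = 5 bp
  at4 <- mk_te(197, 210)   # 4 bp
  r5 <- te_overlap(list(lincRNA = tx), at5)$report
  expect_identical(r5$exonic_te_bp, 5L)
  expect_true(r5$is_te_lnc)
  r4 <- te_overlap(list(lincRNA = tx), at4)$report
  expect_identical(r4$exonic_te_bp, 4L)
  expect_false(r4$is_te_lnc)
})

test_that("gene-body overlap uses the span, exonic overlap the exon union", {
  ex <- GRanges("chr1", IRanges(c(1, 901), c(100, 1000)), strand = "+")
  mcols(ex)$transcript_id <- "t"; mcols(ex)$gene_id <- "g"
  txs <- make_transcript_set(ex)
  te <- mk_te(401, 500)    # intronic
  r <- te_overlap(list(x = txs), te)$report
  expect_identical(r$gene_body_te_bp, 100L)
  expect_identical(r$exonic_te_bp, 0L)
  expect_false(r$is_te_lnc)
  # per-base cross-check on a random overlap layout
  set.seed(2)
  s <- sort(sample(1:900, 5))
  tes <- mk_te(s, s + 120)
  r2 <- te_overlap(list(x = txs), tes)$report
  expect_identical(r2$exonic_te_bp,
                   brute_overlap_bp(ex, reduce(tes, ignore.strand = TRUE),
                                    2000L))
})

test_that("TE-lncRNA count is monotone non-increasing in min_bp", {
  b <- generate_dataset(generator_config(seed = 21))
  cls <- split(b$truth$transcripts$transcript_id,
               b$truth$transcripts$planted_class)
  by_class <- list(lincRNA = b$transcripts[cls$lincRNA])
  n <- vapply(c(1, 5, 20, 60, 200), function(mb)
    sum(te_overlap(by_class, b$tes, min_bp = mb)$report$is_te_lnc),
    integer(1))
  expect_true(all(diff(n) <= 0))
})

test_that("Class I/II base fractions per region match the per-base tally", {
  tes <- c(mk_te(1, 100, "LTR/Gypsy"), mk_te(201, 250, "DNA/MuDR"))
  reg <- GRanges("chr1", IRanges(1, 300))
  d <- te_class_distribution(tes, list(r = reg))
  expect_equal(d$frac_I, 2 / 3)
  expect_equal(d$frac_II, 1 / 3)
  # region cutting the Class I TE in half: only Class I bases inside
  reg2 <- GRanges("chr1", IRanges(1, 50))
  d2 <- te_class_distribution(tes, list(r = reg2))
  expect_equal(d2$frac_I, 1.0)
  expect_equal(d2$bp_I, 50)
  # empty region -> undefined fractions
  d3 <- te_class_distribution(tes, list(r = GRanges()))
  expect_true(is.na(d3$frac_I))
  # random landscape vs brute force
  set.seed(4)
  tes_r <- mk_te(seq(1, 2000, by = 150), seq(1, 2000, by = 150) + 99,
                 c("LTR/Gypsy", "DNA/hAT", "Simple_repeat"))
  reg_r <- GRanges("chr1", IRanges(c(50, 1200), c(700, 1800)))
  d4 <- te_class_distribution(tes_r, list(r = reg_r))
  bpI <- brute_overlap_bp(tes_r[tes_r$te_class == "I"], reg_r, 3000L)
  bpII <- brute_overlap_bp(tes_r[tes_r$te_class == "II"], reg_r, 3000L)
  expect_equal(d4$bp_I, bpI)
  expect_equal(d4$frac_I, bpI / (bpI + bpII))
})

test_that("promoter windows sit upstream of the TSS, strand-aware, clipped", {
  cs <- c(chr1 = 100000L)
  p <- promoter_window(GRanges("chr1", IRanges(5001, 6000), strand = "+"),
                       1000, cs)
  expect_identical(c(start(p), end(p)), c(4001L, 5000L))
  m <- promoter_window(GRanges("chr1", IRanges(2001, 3000), strand = "-"),
                       1000, cs)
  expect_identical(c(start(m), end(m)), c(3001L, 4000L))
  clip <- promoter_window(GRanges("chr1", IRanges(401, 900), strand = "+"),
                          1000, cs)
  expect_identical(c(start(clip), end(clip)), c(1L, 400L))
  expect_error(promoter_window(GRanges("chr1", IRanges(1, 900),
                                       strand = "+"), 1000, cs),
               "zero length")
  expect_error(promoter_window(GRanges("chr1", IRanges(1, 900),
                                       strand = "*"), 1000, cs),
               "strand")
})

test_that("TE-derived promoters: TSS clause and coverage clause", {
  cs <- c(chr1 = 100000L)
  tx <- single_tx(5001, 6000)
  # TE right over the TSS base
  r1 <- te_derived_promoters(list(x = tx), mk_te(4950, 5010),
                             chrom_sizes = cs)
  expect_true(r1$calls$te_derived)
  expect_true(r1$calls$tss_in_te)
  # 600/1000 coverage, TSS untouched
  r2 <- te_derived_promoters(list(x = tx), mk_te(4101, 4700),
                             chrom_sizes = cs)
  expect_false(r2$calls$tss_in_te)
  expect_equal(r2$calls$te_cover, 0.6)
  expect_true(r2$calls$te_derived)
  # 100/1000 coverage
  r3 <- te_derived_promoters(list(x = tx), mk_te(4101, 4200),
                             chrom_sizes = cs)
  expect_false(r3$calls$te_derived)
  # coverage fraction monotonicity with the TSS clause disabled
  b <- generate_dataset(generator_config(seed = 31))
  cls <- split(b$truth$transcripts$transcript_id,
               b$truth$transcripts$planted_class)
  by_class <- list(lincRNA = b$transcripts[cls$lincRNA])
  fr <- vapply(c(0.05, 0.2, 0.5, 0.9), function(cv)
    sum(te_derived_promoters(by_class, b$tes, cover_frac = cv,
                             tss_rule = FALSE,
                             chrom_sizes = b$chrom_sizes)$calls$te_derived),
    integer(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("TF summits are localized to TE-derived promoter segments", {
  cs <- c(chr1 = 100000L)
  tx <- c(single_tx(5001, 6000, id = "in_te"),
          single_tx(20001, 21000, id = "out_te"))
  tes <- mk_te(4500, 5010)
  prom <- te_derived_promoters(list(x = tx), tes, chrom_sizes = cs)
  peaks <- GRanges("chr1", IRanges(c(4701, 19501), c(4901, 19701)))
  mcols(peaks)$tf_name <- c("TFa", "TFb")
  mcols(peaks)$score <- 1
  mcols(peaks)$summit <- c(4800L, 19600L)  # both inside their promoters
  r <- tf_sites_in_te_promoters(prom, peaks, tes)
  rep <- r$report[match(c("in_te", "out_te"), r$report$transcript_id), ]
  expect_identical(rep$tf_hit, c(TRUE, TRUE))
  expect_identical(rep$tf_hit_in_te, c(TRUE, FALSE))
  expect_identical(r$n_tf_in_te, 1L)
  expect_equal(r$binding_frequency$binding_frequency, 1.0)
})

test_that("TE-promoter/genome correlation matches the closed formula", {
  lin <- data.frame(genome_te_frac = 1:5 / 10,
                    te_promoter_frac = (1:5) / 5)
  expect_equal(te_promoter_genome_correlation(lin), 1.0)
  lin$te_promoter_frac <- rev(lin$te_promoter_frac)
  expect_equal(te_promoter_genome_correlation(lin), -1.0)
  set.seed(8)
  tb <- data.frame(genome_te_frac = runif(8), te_promoter_frac = runif(8))
  x <- tb$genome_te_frac; y <- tb$te_promoter_frac
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(te_promoter_genome_correlation(tb), r_manual,
               tolerance = 1e-12)
  expect_error(te_promoter_genome_correlation(lin[1:2, ]), "3 species")
  flat <- data.frame(genome_te_frac = c(.1, .1, .1),
                     te_promoter_frac = runif(3))
  expect_message(expect_true(is.na(te_promoter_genome_correlation(flat))),
                 "zero variance")
})
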