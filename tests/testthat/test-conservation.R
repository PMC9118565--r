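# Conservation statistics: transcript means, the 12-bp patch scan, class
# profiles, and the homology matrix.

test_that("transcript mean scores ignore introns and missing bases", {
  v <- rep(NA_real_, 300)
  v[1:100] <- c(rep(1, 50), rep(0, 50))
  tr <- toy_track(v)
  tx <- single_tx(1, 100)
  expect_equal(transcript_mean_score(tx, tr)$mean_score, 0.5)
  # all-zero exon
  v2 <- rep(0, 100)
  expect_equal(transcript_mean_score(tx, toy_track(v2))$mean_score, 0)
  # two exons vs brute-force average over exonic bases only
  set.seed(3)
  v3 <- runif(1000)
  ex <- GRanges("chr1", IRanges(c(101, 501), c(200, 700)), strand = "-")
  mcols(ex)$transcript_id <- "t"; mcols(ex)$gene_id <- "g"
  txs <- make_transcript_set(ex)
  expect_equal(transcript_mean_score(txs, toy_track(v3))$mean_score,
               mean(v3[c(101:200, 501:700)]))
  # everything missing -> NA and flagged via n_scored
  far <- single_tx(900, 950)
  r <- transcript_mean_score(far, toy_track(c(0.5, NA)))
  expect_true(is.na(r$mean_score))
  expect_identical(r$n_scored, 0L)
})

test_that("the worked patch case: 50-base transcript, 12-base 0.9 run", {
  v <- rep(0, 60)
  v[11 + (0:11)] <- 0.9   # 12-base run inside a 50-base transcript at 1..50
  tr <- toy_track(v)
  tx <- single_tx(1, 50)
  r <- conserved_patch_scan(tx, tr)
  expect_equal(r$whole_mean, 0.216)
  expect_equal(r$best_window_mean, 0.9)
  expect_true(r$has_conserved_patch)
})

test_that("patch thresholds are strict on both clauses", {
  # uniform 0.6: best window not > 0.6 -> no patch
  tx <- single_tx(1, 50)
  r1 <- conserved_patch_scan(tx, toy_track(rep(0.6, 50)))
  expect_equal(r1$best_window_mean, 0.6)
  expect_false(r1$has_conserved_patch)
  # uniform 0.9: whole mean not < 0.3 -> conserved overall, not a patch
  r2 <- conserved_patch_scan(tx, toy_track(rep(0.9, 50)))
  expect_false(r2$has_conserved_patch)
  # transcripts shorter than the window are never patch-positive
  short <- single_tx(1, 8)
  r3 <- conserved_patch_scan(short, toy_track(rep(0.9, 10)))
  expect_true(r3$too_short)
  expect_false(r3$has_conserved_patch)
})

test_that("windows slide over spliced coordinates and drop missing bases", {
  # two exons: patch straddles the junction in spliced coordinates
  ex <- GRanges("chr1", IRanges(c(1, 101), c(30, 130)), strand = "+")
  mcols(ex)$transcript_id <- "t"; mcols(ex)$gene_id <- "g"
  txs <- make_transcript_set(ex)
  v <- rep(0, 200)
  v[25:30] <- 0.9; v[101:106] <- 0.9   # 6 + 6 spliced-contiguous bases
  r <- conserved_patch_scan(txs, toy_track(v))
  expect_equal(r$best_window_mean, 0.9)
  expect_true(r$has_conserved_patch)
  # a missing base disqualifies windows containing it
  v2 <- rep(0.9, 60); v2[20] <- NA
  r2 <- conserved_patch_scan(single_tx(1, 50), toy_track(v2))
  wm <- window_means_oracle_check <- brute_window_means(v2[1:50], 12)
  expect_equal(r2$best_window_mean, max(wm, na.rm = TRUE))

  # min window mean <= whole mean <= max window mean on full-coverage tracks
  set.seed(6)
  for (i in 1:5) {
    v3 <- runif(80)
    r3 <- conserved_patch_scan(single_tx(1, 80), toy_track(v3))
    wm3 <- brute_window_means(v3[1:80], 12)
    expect_equal(r3$best_window_mean, max(wm3))
    expect_gte(r3$whole_mean, min(wm3) - 1e-12)
    expect_lte(r3$whole_mean, max(wm3) + 1e-12)
  }
})

test_that("class profiles recover the planted conservation gradient", {
  b <- generate_dataset(generator_config(seed = 17))
  track <- read_conservation_bedgraph(b$paths[["conservation"]])
  cls <- split(b$truth$transcripts$transcript_id,
               b$truth$transcripts$planted_class)
  cds_set <- as(b$genes$cds, "GRangesList")
  intergenic <- sample_intergenic_controls(
    b$genes, b$chrom_sizes, 30,
    lengths = width(unlist(b$transcripts[cls$lincRNA])), seed = 2)
  prof <- class_conservation_profiles(
    list(cds = cds_set, lincRNA = b$transcripts[cls$lincRNA],
         intergenic = as(intergenic, "GRangesList")), track)
  m <- vapply(prof$means, function(x) mean(x, na.rm = TRUE), numeric(1))
  expect_gt(m[["cds"]], m[["lincRNA"]])
  expect_gt(m[["lincRNA"]], m[["intergenic"]])
  # cumulative curves are non-decreasing and end at 1
  for (cl in unique(prof$cumulative$class)) {
    cf <- prof$cumulative$cumfreq[prof$cumulative$class == cl]
    expect_true(all(diff(cf) >= 0))
    expect_equal(cf[length(cf)], 1)
  }
  # all-zero class
  z <- toy_track(rep(0, 1000))
  p0 <- class_conservation_profiles(list(a = single_tx(1, 500)), z)
  expect_equal(p0$summary$frac_gt_0.6, 0)
  expect_equal(p0$summary$frac_zero, 1)
})

test_that("homology matrix counts queries with passing hits", {
  per_sp <- list(A = sprintf("a%02d", 1:100), B = sprintf("b%02d", 1:10))
  none <- data.frame(query_id = character(0), query_species = character(0),
                     subject_species = character(0),
                     identity_pct = numeric(0), align_len = integer(0),
                     evalue = numeric(0))
  m0 <- homology_conservation_matrix(none, per_sp)
  expect_equal(unname(m0["A", "B"]), 0)
  expect_equal(unname(diag(m0)), c(1, 1))
  # 5 of 100 queries pass
  hits <- data.frame(query_id = sprintf("a%02d", 1:5), query_species = "A",
                     subject_species = "B", identity_pct = 90,
                     align_len = 200L, evalue = 1e-20)
  m5 <- homology_conservation_matrix(hits, per_sp)
  expect_equal(unname(m5["A", "B"]), 0.05)
  # every B query passing to A
  hitsb <- data.frame(query_id = per_sp$B, query_species = "B",
                      subject_species = "A", identity_pct = 90,
                      align_len = 200L, evalue = 1e-20)
  expect_equal(unname(homology_conservation_matrix(hitsb, per_sp)["B", "A"]),
               1)
  expect_error(homology_conservation_matrix(
    data.frame(query_id = "zz", query_species = "A", subject_species = "B",
               identity_pct = 90, align_len = 200L, evalue = 1e-20), per_sp),
    "unknown query")
})

test_that("matrix entries are monotone in the hit thresholds", {
  b <- generate_dataset(generator_config(seed = 23))
  offdiag <- function(m) { diag(m) <- NA; sum(m, na.rm = TRUE) }
  tot_len <- vapply(c(10, 50, 150, 500), function(ml)
    offdiag(homology_conservation_matrix(b$hits, b$tx_per_species,
                                         min_len = ml)), numeric(1))
  expect_true(all(diff(tot_len) <= 0))
  tot_ev <- vapply(c(1e-40, 1e-20, 1e-5, 1e-2), function(ev)
    offdiag(homology_conservation_matrix(b$hits, b$tx_per_species,
                                         evalue_max = ev)), numeric(1))
  expect_true(all(diff(tot_ev) >= 0))
})
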