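# Jensen-Shannon specificity, TS calling, summaries, antisense-pair
# correlation, and network candidate selection.

test_that("JS specificity matches the divergence definition", {
  # single expressed tissue: score exactly 1, argmax is that tissue
  s <- js_specificity(c(a = 0, b = 0, c = 7, d = 0, e = 0))
  expect_identical(s$js_score, 1)
  expect_identical(s$argmax_tissue, "c")
  # uniform 2-tissue vector: 1 - sqrt(JSD) with JSD ~ 0.3113 bits,
  # cross-checked against the Kullback-Leibler formulation to 1e-9
  s2 <- js_specificity(c(1, 1))
  expect_equal(s2$js_score, oracle_js(c(1, 1)), tolerance = 1e-9)
  expect_equal(s2$js_score, 1 - sqrt(0.31127812445913283), tolerance = 1e-9)
  # scale invariance
  set.seed(1)
  for (i in 1:10) {
    x <- runif(5)
    expect_equal(js_specificity(x)$js_score,
                 js_specificity(x * runif(1, 0.01, 100))$js_score)
  }
  # permutation equivariance and the [0,1] range
  for (i in 1:10) {
    x <- runif(6) * rbinom(6, 1, 0.7)
    if (all(x == 0)) x[1] <- 1
    p <- sample(6)
    expect_equal(js_specificity(x[p])$js_score, js_specificity(x)$js_score)
    expect_gte(js_specificity(x)$js_score, 0)
    expect_lte(js_specificity(x)$js_score, 1)
  }
  expect_error(js_specificity(c(0, 0, 0)), "undefined")
  expect_error(js_specificity(7), "2 tissues")
})

test_that("random vectors agree with the independent KL oracle", {
  set.seed(12)
  for (i in 1:25) {
    x <- runif(sample(2:8, 1)) * rbinom(8, 1, 0.8)[1]
    x <- abs(x) + ifelse(sum(x) == 0, 1, 0)
    expect_equal(js_specificity(x)$js_score, oracle_js(x),
                 tolerance = 1e-9)
  }
})

test_that("TS calling uses the inclusive 0.9 threshold", {
  # build a two-tissue mixture scoring exactly at the threshold
  js_two <- function(a) js_specificity(c(a, 1 - a, 0, 0, 0))$js_score
  a_at <- uniroot(function(a) js_two(a) - 0.9, c(0.7, 0.9999),
                  tol = 1e-14)$root
  m <- rbind(at = c(a_at + 1e-9, 1 - a_at - 1e-9, 0, 0, 0),
             uniform = rep(2, 5),
             single = c(0, 0, 5, 0, 0))
  colnames(m) <- paste0("t", 1:5)
  ts <- call_ts(m)
  expect_identical(setNames(ts$is_ts, ts$transcript_id),
                   c(at = TRUE, uniform = FALSE, single = TRUE))
  # uniform five-tissue expression scores ~0.404, far from TS
  expect_equal(js_specificity(rep(2, 5))$js_score, oracle_js(rep(1, 5)),
               tolerance = 1e-9)
  expect_lt(js_specificity(rep(2, 5))$js_score, 0.41)
  # TS count is monotone non-increasing in the threshold
  set.seed(5)
  big <- matrix(runif(600) * rbinom(600, 1, 0.5), nrow = 100,
                dimnames = list(sprintf("t%03d", 1:100), paste0("ts", 1:6)))
  big[rowSums(big) == 0, 1] <- 1
  n_ts <- vapply(c(0.2, 0.5, 0.9, 0.95, 1), function(th)
    sum(call_ts(big, ts_threshold = th)$is_ts), integer(1))
  expect_true(all(diff(n_ts) <= 0))
  # all-zero rows are flagged, never TS
  z <- matrix(0, 1, 5, dimnames = list("z", paste0("t", 1:5)))
  tz <- call_ts(z)
  expect_true(tz$flagged)
  expect_false(tz$is_ts)
})

test_that("tissue summaries use log10(FPKM+1)", {
  m <- matrix(c(9, 0, 99, 0), 2, 2,
              dimnames = list(c("a", "b"), c("t1", "t2")))
  s <- tissue_summary(m, list(x = c("a", "b")))
  expect_equal(unname(s$by_tissue["x", "t1"]), mean(log10(c(9, 0) + 1)))
  expect_equal(unname(s$by_tissue["x", "t2"]), mean(log10(c(99, 0) + 1)))
  expect_equal(s$pooled$mean_fpkm, 27)
  expect_error(tissue_summary(m, list(x = "nope")), "absent")
})

test_that("antisense-pair correlations behave at the degenerate ends", {
  m <- rbind(n1 = c(1, 2, 3, 4), g1 = c(2, 4, 6, 8),
             n2 = c(1, 2, 3, 4), g2 = c(5, 5, 5, 5))
  colnames(m) <- paste0("t", 1:4)
  pr <- nat_pair_correlation(m, data.frame(lnc_id = c("n1", "n2"),
                                           gene_id = c("g1", "g2")))
  expect_equal(pr$pairs$r[1], 1.0)
  expect_true(pr$pairs$zero_variance[2])
  expect_true(is.na(pr$pairs$r[2]))
  expect_error(nat_pair_correlation(m, data.frame(lnc_id = "qq",
                                                  gene_id = "g1")), "unknown")
  # planted independent pairs: mean |r| stays small
  set.seed(77)
  n <- 200
  mm <- matrix(runif(2 * n * 30), 2 * n, 30)
  rownames(mm) <- c(sprintf("L%03d", 1:n), sprintf("G%03d", 1:n))
  pairs <- data.frame(lnc_id = sprintf("L%03d", 1:n),
                      gene_id = sprintf("G%03d", 1:n))
  pr2 <- nat_pair_correlation(mm, pairs)
  expect_lt(mean(abs(pr2$pairs$r)), 0.2)
})

test_that("network candidate selection implements the three rules", {
  m <- rbind(
    nat_hi = c(50, 40, 0, 0, 0),   # 2 tissues, top of the lncNAT maxima
    nat_lo = c(2, 0, 0, 0, 0),     # 1 tissue, low max
    nat_many = c(9, 9, 9, 0, 0),   # 3 tissues: fails the count clause
    linc_ok = c(1.5, 0.8, 0, 0, 0),# 2 tissues, max > 1
    linc_many = c(5, 5, 5, 0, 0),  # 3 tissues
    linc_low = c(0.9, 0, 0, 0, 0), # max below 1
    mrna_hi = c(2, 2, 2, 2, 2),
    mrna_at = c(1, 1, 1, 1, 1))    # max exactly 1: strict, excluded
  colnames(m) <- paste0("t", 1:5)
  classes <- list(lncNAT = c("nat_hi", "nat_lo", "nat_many"),
                  lincRNA = c("linc_ok", "linc_many", "linc_low"),
                  mRNA = c("mrna_hi", "mrna_at"))
  sel <- wgcna_candidate_selection(m, classes)
  expect_identical(sel$lncNAT, "nat_hi")
  expect_identical(sel$lincRNA, "linc_ok")
  expect_identical(sel$mRNA, "mrna_hi")
  # empty class -> empty selection
  sel0 <- wgcna_candidate_selection(m, list(lncNAT = character(0),
                                            lincRNA = character(0),
                                            mRNA = "mrna_hi"))
  expect_length(sel0$lncNAT, 0)
  # selections are disjoint across classes
  expect_length(intersect(sel$lncNAT, c(sel$lincRNA, sel$mRNA)), 0)
})
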