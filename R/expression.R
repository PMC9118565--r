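# Expression analyses: Jensen-Shannon tissue specificity, tissue-specific
# transcript calling, per-tissue summaries, lncNAT/antisense-gene
# correlation, and candidate selection for co-expression network input.

# Base-2 Shannon entropy with the 0*log(0) := 0 convention.
entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Jensen-Shannon divergence (bits) between two distributions.
jsd2 <- function(p, q) {
  m <- (p + q) / 2
  entropy2(m) - (entropy2(p) + entropy2(q)) / 2
}

#' Jensen-Shannon tissue-specificity score
#'
#' The expression vector is normalized to a distribution p; for each tissue
#' t the score against the single-tissue indicator distribution e_t is
#' 1 - sqrt(JSD(p, e_t)) with the divergence in bits, and the JS score is
#' the maximum over tissues. A transcript expressed in exactly one tissue
#' scores 1; the score is invariant to scaling of the vector. Note that a
#' perfectly uniform vector does not score 0 (e.g. about 0.404 over five
#' tissues): 0 is approached, not attained, as expression spreads over many
#' tissues.
#'
#' @param x non-negative expression vector over at least 2 tissues (names
#'   used as tissue labels if present), or a matrix (rows = transcripts).
#' @param log_transform if `TRUE`, scores are computed on log10(FPKM + 1)
#'   rather than raw FPKM.
#' @return For a vector: list with `js_score`, `argmax_tissue` (ties broken
#'   by tissue order), `per_tissue` scores. For a matrix: `data.frame` with
#'   `transcript_id`, `js_score`, `argmax_tissue`, `flagged` (`TRUE` for
#'   all-zero rows, whose score is undefined/`NA`, not 0).
#' @export
js_specificity <- function(x, log_transform = FALSE) {
  if (is.matrix(x)) {
    rows <- lapply(seq_len(nrow(x)), function(i) {
      xi <- x[i, ]
      if (all(xi == 0))
        return(data.frame(transcript_id = rownames(x)[i],
                          js_score = NA_real_,
                          argmax_tissue = NA_character_, flagged = TRUE,
                          stringsAsFactors = FALSE))
      s <- js_specificity(xi, log_transform = log_transform)
      data.frame(transcript_id = rownames(x)[i], js_score = s$js_score,
                 argmax_tissue = s$argmax_tissue, flagged = FALSE,
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  if (length(x) < 2) stop("need at least 2 tissues")
  if (any(x < 0)) stop("negative expression value")
  if (all(x == 0)) stop("all-zero expression vector: JS score undefined")
  if (log_transform) x <- log10(x + 1)
  p <- x / sum(x)
  tn <- if (!is.null(names(x))) names(x) else as.character(seq_along(x))
  per <- vapply(seq_along(p), function(t) {
    e <- numeric(length(p)); e[t] <- 1
    1 - sqrt(jsd2(p, e))
  }, numeric(1))
  names(per) <- tn
  best <- which.max(per)  # first maximum: ties break by tissue order
  list(js_score = unname(per[best]), argmax_tissue = tn[best],
       per_tissue = per)
}

#' Call tissue-specific (TS) transcripts
#'
#' A transcript is TS when its JS score is at least `ts_threshold`
#' (inclusive, default 0.9). Its TS tissue is the argmax tissue.
#'
#' @param expr expression matrix (transcripts x tissues).
#' @param ts_threshold inclusive JS threshold.
#' @param log_transform passed to [js_specificity()].
#' @return `data.frame`: `transcript_id`, `js_score`, `argmax_tissue`,
#'   `is_ts`, `flagged` (all-zero rows; never TS).
#' @export
call_ts <- function(expr, ts_threshold = 0.9, log_transform = FALSE) {
  sc <- js_specificity(expr, log_transform = log_transform)
  sc$is_ts <- !sc$flagged & sc$js_score >= ts_threshold
  sc[c("transcript_id", "js_score", "argmax_tissue", "is_ts", "flagged")]
}

#' Per-class, per-tissue expression summary
#'
#' Mean of log10(FPKM + 1) per class and tissue, plus pooled per-class raw
#' FPKM means.
#'
#' @param expr expression matrix.
#' @param classes named list of transcript id vectors (or transcript sets).
#' @return list: `by_tissue` (classes x tissues matrix of mean
#'   log10(FPKM+1)), `pooled` (`data.frame` of per-class mean FPKM).
#' @export
tissue_summary <- function(expr, classes) {
  ids <- lapply(classes, function(x) if (is.character(x)) x else names(x))
  miss <- setdiff(unlist(ids), rownames(expr))
  if (length(miss))
    stop("class member(s) absent from expression matrix: ",
         paste(head(miss, 5), collapse = ", "))
  by_tissue <- t(vapply(ids, function(i)
    colMeans(log10(expr[i, , drop = FALSE] + 1)),
    numeric(ncol(expr))))
  pooled <- data.frame(class = names(ids),
                       mean_fpkm = vapply(ids, function(i)
                         mean(expr[i, , drop = FALSE]), numeric(1)),
                       stringsAsFactors = FALSE)
  list(by_tissue = by_tissue, pooled = pooled)
}

#' lncNAT / antisense-gene expression relationship
#'
#' Pearson correlation across tissues for each (lncNAT, antisense gene)
#' pair, plus the pooled expression vectors of genes with vs without an
#' antisense lncNAT for distributional comparison (test statistics are left
#' to the caller).
#'
#' @param expr expression matrix containing both transcripts and genes.
#' @param nat_pairs `data.frame` with columns `lnc_id`, `gene_id`.
#' @param all_gene_ids optional character vector of every coding gene id in
#'   `expr`; enables the with/without-lncNAT comparison.
#' @return list: `pairs` (`data.frame` with `lnc_id`, `gene_id`, `r`,
#'   `zero_variance` flag), `genes_with_nat`, `genes_without_nat`
#'   (mean-FPKM vectors, `NULL` when `all_gene_ids` is missing).
#' @export
nat_pair_correlation <- function(expr, nat_pairs, all_gene_ids = NULL) {
  if (ncol(expr) < 3) stop("need at least 3 tissues for correlation")
  miss <- setdiff(c(nat_pairs$lnc_id, nat_pairs$gene_id), rownames(expr))
  if (length(miss))
    stop("unknown id(s) in nat_pairs: ", paste(head(miss, 5), collapse = ", "))
  pairs <- do.call(rbind, lapply(seq_len(nrow(nat_pairs)), function(i) {
    a <- expr[nat_pairs$lnc_id[i], ]
    b <- expr[nat_pairs$gene_id[i], ]
    zv <- stats::sd(a) == 0 || stats::sd(b) == 0
    data.frame(lnc_id = nat_pairs$lnc_id[i], gene_id = nat_pairs$gene_id[i],
               r = if (zv) NA_real_ else cor(a, b),
               zero_variance = zv, stringsAsFactors = FALSE)
  }))
  gw <- gwo <- NULL
  if (!is.null(all_gene_ids)) {
    with_nat <- intersect(all_gene_ids, nat_pairs$gene_id)
    without <- setdiff(all_gene_ids, nat_pairs$gene_id)
    gw <- rowMeans(expr[with_nat, , drop = FALSE])
    gwo <- rowMeans(expr[without, , drop = FALSE])
  }
  list(pairs = pairs, genes_with_nat = gw, genes_without_nat = gwo)
}

#' Select candidates for co-expression network construction
#'
#' Selection rules: (1) lncNATs expressed in one or two tissues whose
#' maximum FPKM lies in the top `top_frac` of maxima among lncNATs passing
#' the tissue-count clause; (2) lincRNAs expressed in one or two tissues
#' with maximum FPKM strictly greater than `fpkm_min`; (3) mRNAs with
#' maximum FPKM strictly greater than `fpkm_min`. "Expressed in a tissue"
#' means FPKM at least `expressed_min`.
#'
#' @param expr expression matrix.
#' @param classes named list with elements `lncNAT`, `lincRNA`, `mRNA`
#'   (id vectors or transcript sets).
#' @param expressed_min FPKM call threshold for "expressed" (inclusive).
#' @param top_frac top fraction for the lncNAT rule.
#' @param fpkm_min FPKM threshold (exclusive) for rules 2 and 3.
#' @param top_scope `"eligible"` ranks lncNAT maxima among tissue-clause
#'   passers (default); `"class"` ranks within the whole class.
#' @return list of class `selection_report`: `lncNAT`, `lincRNA`, `mRNA`
#'   (selected id vectors) and `params`.
#' @export
wgcna_candidate_selection <- function(expr, classes, expressed_min = 0.1,
                                      top_frac = 0.10, fpkm_min = 1.0,
                                      top_scope = c("eligible", "class")) {
  top_scope <- match.arg(top_scope)
  ids <- lapply(classes, function(x) if (is.character(x)) x else names(x))
  get <- function(nm) intersect(ids[[nm]], rownames(expr))
  sel <- list()

  nat <- get("lncNAT")
  if (length(nat)) {
    sub <- expr[nat, , drop = FALSE]
    n_expr <- rowSums(sub >= expressed_min)
    maxf <- apply(sub, 1, max)
    elig <- n_expr %in% c(1, 2)
    pool <- if (top_scope == "eligible") maxf[elig] else maxf
    if (any(elig) && length(pool)) {
      cut <- quantile(pool, probs = 1 - top_frac, names = FALSE)
      sel$lncNAT <- nat[elig & maxf >= cut]
    } else sel$lncNAT <- character(0)
  } else sel$lncNAT <- character(0)

  linc <- get("lincRNA")
  if (length(linc)) {
    sub <- expr[linc, , drop = FALSE]
    n_expr <- rowSums(sub >= expressed_min)
    maxf <- apply(sub, 1, max)
    sel$lincRNA <- linc[n_expr %in% c(1, 2) & maxf > fpkm_min]
  } else sel$lincRNA <- character(0)

  mrna <- get("mRNA")
  sel$mRNA <- if (length(mrna)) {
    maxf <- apply(expr[mrna, , drop = FALSE], 1, max)
    mrna[maxf > fpkm_min]
  } else character(0)

  structure(c(sel, list(params = list(expressed_min = expressed_min,
                                      top_frac = top_frac,
                                      fpkm_min = fpkm_min,
                                      top_scope = top_scope))),
            class = "selection_report")
}
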