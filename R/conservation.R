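# PhastCons-based conservation statistics: per-transcript means over the
# spliced sequence, the 12-bp conserved-patch scan, per-class profiles, and
# the cross-species homology matrix from precomputed blastn hit tables.

#' Mean conservation score per transcript
#'
#' Mean of per-base PhastCons scores over the spliced (exon-union) sequence;
#' bases missing from the track are excluded from numerator and denominator.
#' Introns never contribute: the statistic describes the transcript.
#'
#' @param txs transcript set.
#' @param track `cons_track` from [read_conservation_bedgraph()].
#' @return `data.frame`: `transcript_id`, `mean_score` (`NA` when every base
#'   is missing), `n_scored` bases.
#' @export
transcript_mean_score <- function(txs, track) {
  ids <- names(txs)
  if (is.null(ids)) ids <- sprintf("iv%04d", seq_along(txs))
  rows <- lapply(seq_along(txs), function(i) {
    v <- track_values(track, txs[[i]])
    n <- sum(!is.na(v))
    data.frame(transcript_id = ids[i],
               mean_score = if (n > 0) mean(v, na.rm = TRUE) else NA_real_,
               n_scored = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Sliding-window means over a numeric vector, step 1; any window containing a
# missing base is disqualified (NA) rather than imputed.
window_means <- function(v, window) {
  n <- length(v)
  if (n < window) return(numeric(0))
  vv <- v; vv[is.na(v)] <- 0
  cs <- c(0, cumsum(vv))
  cn <- c(0, cumsum(is.na(v)))
  i <- seq_len(n - window + 1)
  means <- (cs[i + window] - cs[i]) / window
  means[(cn[i + window] - cn[i]) > 0] <- NA_real_
  means
}

#' Scan transcripts for short conserved patches
#'
#' A conserved patch is a `window`-bp stretch (default 12) of the spliced
#' transcript with mean PhastCons strictly greater than `patch_min`
#' (default 0.6) inside a transcript whose overall spliced mean is strictly
#' less than `whole_max` (default 0.3): a locally conserved island in an
#' otherwise non-conserved transcript. Windows slide by one base over the
#' concatenated exons, 5' to 3'; windows containing missing bases are
#' disqualified.
#'
#' @param txs transcript set.
#' @param track `cons_track`.
#' @param window patch width in bp.
#' @param patch_min window-mean threshold (exclusive).
#' @param whole_max whole-transcript mean ceiling (exclusive).
#' @return `data.frame`: `transcript_id`, `whole_mean`, `best_window_mean`
#'   (max over windows; the score a sliding-window summary assigns the
#'   transcript), `n_patches`, `has_conserved_patch`, `too_short` (spliced
#'   length < `window`; such transcripts are never patch-positive). The
#'   per-transcript patch offsets (1-based, spliced coordinates) are in
#'   attribute `patches`.
#' @export
conserved_patch_scan <- function(txs, track, window = 12, patch_min = 0.6,
                                 whole_max = 0.3) {
  ids <- names(txs)
  if (is.null(ids)) ids <- sprintf("iv%04d", seq_along(txs))
  patches <- list()
  rows <- lapply(seq_along(txs), function(i) {
    id <- ids[i]
    v <- track_values(track, txs[[i]])
    n_ok <- sum(!is.na(v))
    whole <- if (n_ok > 0) mean(v, na.rm = TRUE) else NA_real_
    wm <- window_means(v, window)
    too_short <- length(v) < window
    best <- if (length(wm) && any(!is.na(wm))) max(wm, na.rm = TRUE)
            else NA_real_
    hit <- which(!is.na(wm) & wm > patch_min)
    has <- !too_short && !is.na(whole) && whole < whole_max && length(hit) > 0
    patches[[id]] <<- if (has)
      data.frame(offset = hit, window_mean = wm[hit]) else
      data.frame(offset = integer(0), window_mean = numeric(0))
    data.frame(transcript_id = id, whole_mean = whole,
               best_window_mean = best, n_patches = length(hit),
               has_conserved_patch = has, too_short = too_short,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), patches = patches)
}

#' Per-class conservation profiles
#'
#' Pools per-transcript mean scores by class and summarizes them: fraction
#' of the class with mean above each cutoff, fraction scoring exactly zero,
#' and the cumulative frequency curve of the means.
#'
#' @param txs_by_class named list of transcript sets (interval classes such
#'   as CDS/UTR/intergenic controls can be passed as single-interval
#'   transcript sets or `GRangesList`s).
#' @param track `cons_track`.
#' @param cutoffs score cutoffs for the exceedance fractions.
#' @return list: `means` (named list of per-transcript mean vectors),
#'   `summary` (`data.frame` per class: `n`, `frac_gt_<cutoff>` columns,
#'   `frac_zero`), `cumulative` (`data.frame` `class`, `score`, `cumfreq`,
#'   non-decreasing and ending at 1).
#' @export
class_conservation_profiles <- function(txs_by_class, track,
                                        cutoffs = c(0, 0.6)) {
  means <- lapply(txs_by_class, function(txs) {
    sc <- transcript_mean_score(txs, track)
    setNames(sc$mean_score, sc$transcript_id)
  })
  summary <- do.call(rbind, lapply(names(means), function(cl) {
    m <- means[[cl]][!is.na(means[[cl]])]
    row <- data.frame(class = cl, n = length(m))
    for (ct in cutoffs) row[[paste0("frac_gt_", ct)]] <- mean(m > ct)
    row$frac_zero <- mean(m == 0)
    row
  }))
  cumulative <- do.call(rbind, lapply(names(means), function(cl) {
    m <- sort(means[[cl]][!is.na(means[[cl]])])
    data.frame(class = cl, score = m,
               cumfreq = seq_along(m) / length(m),
               stringsAsFactors = FALSE)
  }))
  list(means = means, summary = summary, cumulative = cumulative)
}

#' Cross-species homology-conservation matrix
#'
#' Entry (a, b) is the fraction of species a's lincRNAs with at least one
#' alignment hit in species b passing the e-value and alignment-length
#' thresholds. The diagonal is 1 by convention.
#'
#' @param hits `data.frame` from [read_blast_hits()] (rows may be pooled
#'   over species pairs).
#' @param transcripts_per_species named list: lincRNA ids per species.
#' @param evalue_max maximum e-value (inclusive; default 1e-5).
#' @param min_len minimum alignment length (inclusive; default 50 bp).
#' @return numeric matrix species x species with entries in [0, 1];
#'   thresholds recorded in attribute `params`.
#' @export
homology_conservation_matrix <- function(hits, transcripts_per_species,
                                         evalue_max = 1e-5, min_len = 50) {
  sp <- names(transcripts_per_species)
  unknown <- setdiff(unique(hits$query_id),
                     unlist(transcripts_per_species, use.names = FALSE))
  if (length(unknown))
    stop("hit(s) for unknown query id: ",
         paste(head(unknown, 5), collapse = ", "))
  pass <- hits[hits$evalue <= evalue_max & hits$align_len >= min_len, ,
               drop = FALSE]
  m <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  diag(m) <- 1
  for (a in sp) for (b in setdiff(sp, a)) {
    q <- transcripts_per_species[[a]]
    ok <- unique(pass$query_id[pass$query_species == a &
                                 pass$subject_species == b])
    m[a, b] <- length(intersect(ok, q)) / length(q)
  }
  structure(m, params = list(evalue_max = evalue_max, min_len = min_len))
}
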