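# End-to-end orchestration: read every input, run classification, features,
# TE, conservation and expression stages in dependency order, and write a
# report bundle with a checksummed manifest.

#' Pipeline run configuration
#'
#' Collects input paths and every analysis threshold. Defaults are the
#' printed values of the identification and characterization rules: length
#' > 200 nt, FPKM > 0.5 / > 0.1 (single/multi-exon), TE overlap >= 5 bp,
#' 12-bp patch window with mean > 0.6 inside transcripts with whole mean
#' < 0.3, JS >= 0.9 for tissue specificity, 1 kb promoters, variant
#' quality > 10 and depth > 5. All thresholds are echoed into the output
#' manifest.
#'
#' @param inputs named list/vector of input paths (`genome`, `genes`,
#'   `transcripts`, `flags`, `expression`; optional `repeats`,
#'   `conservation`, `variants`, `peaks`). A bundle from
#'   [generate_dataset()] can be passed directly via its `paths` element.
#' @param out_dir report directory.
#' @param length_min,fpkm_single,fpkm_multi,min_antisense_bp identification
#'   and classification thresholds.
#' @param te_min_bp,promoter_size,cover_frac TE-analysis parameters.
#' @param patch_window,patch_min,whole_max conserved-patch parameters.
#' @param ts_threshold JS threshold for TS calling (inclusive).
#' @param vcf_qual,vcf_depth variant retention thresholds (exclusive).
#' @param evalue_max,min_len homology-hit thresholds.
#' @param expressed_min,top_frac,fpkm_min network candidate-selection
#'   parameters.
#' @param seed seed for the intergenic control sampler.
#' @return list of class `run_config`.
#' @export
run_config <- function(inputs, out_dir = tempfile("lnc_run_"),
                       length_min = 200, fpkm_single = 0.5, fpkm_multi = 0.1,
                       min_antisense_bp = 1, te_min_bp = 5,
                       promoter_size = 1000, cover_frac = 0.5,
                       patch_window = 12, patch_min = 0.6, whole_max = 0.3,
                       ts_threshold = 0.9, vcf_qual = 10, vcf_depth = 5,
                       evalue_max = 1e-5, min_len = 50,
                       expressed_min = 0.1, top_frac = 0.10, fpkm_min = 1.0,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

log_msg <- function(...) message("[lncscape] ", ...)

#' Run the full characterization pipeline
#'
#' Stages: identification + classification (always), molecular features
#' (needs genome; SNP density added when a VCF is present), TE analyses
#' (need a repeat annotation; TF sites need peaks), conservation (needs a
#' bedGraph track), and expression (always). Optional stages whose inputs
#' are missing are skipped with an explicit `skipped` status; any stage
#' failure aborts naming the stage. Outputs are written under
#' `config$out_dir` with an md5-checksummed manifest that also echoes every
#' threshold.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with per-stage results (`classification`,
#'   `features`, `te`, `conservation`, `expression`), `status` per stage,
#'   and `manifest` (`data.frame` file/md5).
#' @export
run_pipeline <- function(config) {
  stopifnot(is(config, "run_config"))
  cfg <- config
  inp <- as.list(cfg$inputs)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  has <- function(k) k %in% names(inp) && !is.null(inp[[k]]) &&
    file.exists(inp[[k]])
  need <- c("genome", "genes", "transcripts", "flags", "expression")
  missing_req <- need[!vapply(need, has, logical(1))]
  if (length(missing_req))
    stop("missing required input(s): ", paste(missing_req, collapse = ", "))
  status <- list()
  outputs <- character(0)
  stage <- function(name, expr) {
    log_msg("stage ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  emit <- function(obj, file, writer = function(o, p)
    write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE)) {
    p <- file.path(cfg$out_dir, file)
    writer(obj, p)
    outputs <<- c(outputs, p)
    p
  }

  ## inputs
  genome <- stage("read", {
    g <- read_genome(inp[["genome"]])
    log_msg("genome: ", length(g), " sequence(s)")
    g
  })
  chrom_sizes <- setNames(BiocGenerics::width(genome), names(genome))
  txs <- read_gtf(inp[["transcripts"]])
  genes <- read_gff3_genes(inp[["genes"]])
  flags <- read.table(inp[["flags"]], header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  expr <- read_expression_tsv(inp[["expression"]])
  log_msg(length(txs), " candidate transcripts, ",
          length(genes$genes), " coding genes")

  ## classification
  classification <- stage("classify", classify_lncrnas(
    txs, flags, expr, genes,
    length_min = cfg$length_min, fpkm_single = cfg$fpkm_single,
    fpkm_multi = cfg$fpkm_multi, min_antisense_bp = cfg$min_antisense_bp))
  status$classify <- "ok"
  log_msg("classes: ", paste(names(table(classification$class)),
                             table(classification$class),
                             sep = "=", collapse = ", "))
  by_class <- split_by_class(txs, classification)
  lnc <- classification[classification$class %in% c("lincRNA", "lncNAT"), ]
  emit(classification, "classification.tsv")
  emit(NULL, "lncRNA.gff3", function(o, p)
    write_gff3(txs[lnc$transcript_id], p,
               class = setNames(lnc$class, lnc$transcript_id)))

  ## features
  features <- stage("features", {
    variants <- NULL
    if (has("variants")) {
      variants <- read_vcf_filtered(inp[["variants"]], cfg$vcf_qual,
                                    cfg$vcf_depth)
      status$snp <- "ok"
    } else {
      status$snp <- "skipped"
      log_msg("no VCF: SNP densities skipped")
    }
    fs <- feature_summary(by_class, genome, variants)
    status$features <- "ok"
    fs
  })
  emit(features, "feature_summary.tsv")

  ## TE analyses
  te <- NULL
  if (has("repeats")) {
    te <- stage("te", {
      tes <- read_repeatmasker_out(inp[["repeats"]])
      ov <- te_overlap(by_class, tes, min_bp = cfg$te_min_bp)
      prom <- te_derived_promoters(by_class, tes, size = cfg$promoter_size,
                                   cover_frac = cfg$cover_frac,
                                   chrom_sizes = chrom_sizes)
      tf <- if (has("peaks"))
        tf_sites_in_te_promoters(prom, read_peaks(inp[["peaks"]]), tes)
      else NULL
      genome_gr <- GRanges(names(chrom_sizes),
                           IRanges(1, unname(chrom_sizes)))
      dist <- te_class_distribution(tes, c(
        list(genome = genome_gr),
        lapply(by_class, function(t) unlist(range(t), use.names = FALSE))))
      list(overlap = ov, promoters = prom, tf = tf, class_distribution = dist)
    })
    status$te <- "ok"
    status$tf <- if (has("peaks")) "ok" else "skipped"
    emit(te$overlap$report, "te_overlap.tsv")
    emit(te$promoters$calls, "te_promoters.tsv")
    emit(te$class_distribution, "te_class_distribution.tsv")
    if (!is.null(te$tf)) emit(te$tf$report, "tf_in_te_promoters.tsv")
  } else {
    status$te <- "skipped"
    log_msg("no repeat annotation: TE stage skipped")
  }

  ## conservation
  conservation <- NULL
  if (has("conservation")) {
    conservation <- stage("conserve", {
      track <- read_conservation_bedgraph(inp[["conservation"]])
      patches <- conserved_patch_scan(do.call(c, unname(by_class)), track,
                                      window = cfg$patch_window,
                                      patch_min = cfg$patch_min,
                                      whole_max = cfg$whole_max)
      profiles <- class_conservation_profiles(by_class, track)
      list(patches = patches, profiles = profiles)
    })
    status$conserve <- "ok"
    emit(as.data.frame(conservation$patches), "conserved_patches.tsv")
    emit(conservation$profiles$summary, "conservation_summary.tsv")
  } else {
    status$conserve <- "skipped"
    log_msg("no conservation track: conservation stage skipped")
  }

  ## expression
  expression <- stage("express", {
    ts <- call_ts(expr[intersect(rownames(expr), names(txs)), , drop = FALSE],
                  ts_threshold = cfg$ts_threshold)
    classes <- lapply(by_class, names)
    classes$mRNA <- setdiff(rownames(expr),
                            c(names(txs), unlist(classes)))
    sel <- wgcna_candidate_selection(expr, classes,
                                     expressed_min = cfg$expressed_min,
                                     top_frac = cfg$top_frac,
                                     fpkm_min = cfg$fpkm_min)
    summ <- tissue_summary(expr, classes)
    list(ts = ts, selection = sel, summary = summ)
  })
  status$express <- "ok"
  emit(expression$ts, "tissue_specificity.tsv")
  emit(data.frame(class = rep(c("lncNAT", "lincRNA", "mRNA"),
                              times = c(length(expression$selection$lncNAT),
                                        length(expression$selection$lincRNA),
                                        length(expression$selection$mRNA))),
                  transcript_id = c(expression$selection$lncNAT,
                                    expression$selection$lincRNA,
                                    expression$selection$mRNA)),
       "network_candidates.tsv")

  ## manifest
  params <- cfg[setdiff(names(cfg), c("inputs", "out_dir"))]
  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(cfg$out_dir, "manifest.tsv")
  write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(paste0(names(params), "=", vapply(params, function(x)
    paste(format(x), collapse = ","), character(1))),
    file.path(cfg$out_dir, "params.txt"))
  log_msg("done: ", length(outputs), " outputs in ", cfg$out_dir)
  invisible(list(classification = classification, features = features,
                 te = te, conservation = conservation,
                 expression = expression, status = status,
                 manifest = manifest))
}
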