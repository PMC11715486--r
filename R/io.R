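#' Read SpliceAI annotations from a VCF file
#'
#' Parses the standard 10-field SpliceAI `INFO` annotation
#' (`ALLELE|SYMBOL|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL`) into
#' [spliceai_record()] objects. Multi-allelic annotations (comma-separated
#' entries) are split into one record per allele. Variants without a
#' SpliceAI annotation, or with a `.` placeholder, are skipped with a
#' warning.
#'
#' @param path VCF path (plain or bgzipped).
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `max_delta` and a list-column `record` of `spliceai_record`.
#' @export
read_spliceai_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
  info <- vcfR::extract.info(vcf, element = "SpliceAI")
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    ann <- info[i]
    if (is.na(ann) || ann == ".") { skipped <- skipped + 1L; next }
    for (entry in strsplit(ann, ",", fixed = TRUE)[[1]]) {
      f <- strsplit(entry, "|", fixed = TRUE)[[1]]
      if (length(f) != 10L)
        stop(sprintf("malformed SpliceAI annotation at %s:%s ('%s')",
                     fix[i, "CHROM"], fix[i, "POS"], entry), call. = FALSE)
      num <- suppressWarnings(as.numeric(f[3:6]))
      pos <- suppressWarnings(as.integer(f[7:10]))
      if (any(is.na(num))) { skipped <- skipped + 1L; next }
      rec <- spliceai_record(ds_ag = num[1], ds_al = num[2], ds_dg = num[3], ds_dl = num[4],
                             dp_ag = pos[1], dp_al = pos[2], dp_dg = pos[3], dp_dl = pos[4])
      rows <- c(rows, list(list(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
                                ref = fix[i, "REF"], alt = f[1], gene = f[2],
                                max_delta = rec$max_delta, record = rec)))
    }
  }
  if (skipped > 0L)
    warning(sprintf("%d VCF record(s) without a usable SpliceAI annotation were skipped", skipped))
  out <- data.frame(
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    pos = vapply(rows, `[[`, integer(1), "pos"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt"),
    gene = vapply(rows, `[[`, character(1), "gene"),
    max_delta = vapply(rows, `[[`, numeric(1), "max_delta"),
    stringsAsFactors = FALSE
  )
  out$record <- lapply(rows, `[[`, "record")
  out
}

#' Run the full splicing-assay interpretation pipeline
#'
#' One call from a long assay dataset to the full result set: per-variant
#' analysis, group summaries, predictor cross-tabulations,
#' score/expression correlation, score-bin expression tests and (when
#' evidence codes are supplied) points-based classifications.
#'
#' @param dataset An `assay_dataset` (defaults to the shipped fixture).
#' @param model A `gene_model`.
#' @param tiers A `region_tiers` map.
#' @param codes Named list of non-RNA evidence codes per variant, or NULL
#'   to skip classification.
#' @param gate_threshold_pct Expression gate for the applied RNA code.
#' @param total_tolerance See [analyze_variants()].
#' @return List of class `tp53_splice_report`.
#' @export
run_splice_analysis <- function(dataset = tp53_assay_fixture(),
                                model = tp53_gene_model(),
                                tiers = tp53_region_tiers(),
                                codes = NULL,
                                gate_threshold_pct = 80,
                                total_tolerance = 3) {
  analysis <- analyze_variants(dataset, model, tiers,
                               gate_threshold_pct = gate_threshold_pct,
                               total_tolerance = total_tolerance)
  classification <- if (!is.null(codes)) classify_dataset(analysis, codes) else NULL
  structure(list(
    variants = analysis,
    group_summary = summarize_groups(analysis),
    crosstabs = predictor_crosstab(analysis),
    correlation = score_expression_correlation(analysis),
    bin_tests = bin_comparison_tests(analysis),
    classification = classification,
    config = list(gate_threshold_pct = gate_threshold_pct,
                  total_tolerance = total_tolerance,
                  n_variants = nrow(analysis))
  ), class = "tp53_splice_report")
}

#' @export
print.tp53_splice_report <- function(x, ...) {
  a <- x$variants
  tst <- a[is_test_group(a$group), ]
  cat(sprintf("<tp53_splice_report> %d variants (%d test)\n", nrow(a), nrow(tst)))
  cat(sprintf("  PVS1-weighted expression: any %d | >50%% %d | >80%% %d\n",
              sum(tst$pvs1_total_pct > 0), sum(tst$pvs1_total_pct > 50),
              sum(tst$pvs1_total_pct > 80)))
  cat(sprintf("  score/expression Pearson r = %.3f (n = %d)\n",
              x$correlation$r, x$correlation$n))
  if (!is.null(x$classification)) {
    s <- attr(x$classification, "summary")
    cat(sprintf("  classified: %d/%d reclassified (%d P/LP, %d LB/B)\n",
                s$reclassified, s$n_test, s$p_lp, s$lb_b))
  }
  invisible(x)
}

#' @export
summary.tp53_splice_report <- function(object, ...) {
  print(object)
  cat("\nGroup summary (test variants):\n")
  print(object$group_summary, row.names = FALSE)
  cat(sprintf("\nKruskal-Wallis across score bins: chi-sq = %.2f, p = %.3g\n",
              unname(object$bin_tests$kruskal$statistic),
              object$bin_tests$kruskal$p.value))
  invisible(object)
}

#' @export
plot.tp53_splice_report <- function(x, ...) {
  a <- x$variants[is_test_group(x$variants$group), ]
  graphics::plot(a$spliceai_max, a$pvs1_total_pct,
                 xlab = "SpliceAI max delta", ylab = "PVS1-weighted expression (%)",
                 pch = 19, col = grDevices::adjustcolor("steelblue", 0.7),
                 main = sprintf("Score vs aberrant expression (r = %.2f)", x$correlation$r), ...)
  graphics::abline(h = c(50, 80), lty = 3, col = "grey40")
  graphics::abline(v = c(0.1, 0.2, 0.5), lty = 3, col = "grey70")
  invisible(x)
}

#' Write a report to text files
#'
#' Writes the per-variant table, group summary, predictor cross-tabs,
#' classifications and a JSON manifest (inputs, thresholds, package
#' version) under `dir`.
#'
#' @param report A `tp53_splice_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_assay_report <- function(report, dir) {
  stopifnot(inherits(report, "tp53_splice_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wtsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wtsv(report$variants, "variants.tsv")
  wtsv(report$group_summary, "group_summary.tsv")
  if (!is.null(report$classification)) wtsv(report$classification, "classification.tsv")

  xt <- lapply(report$crosstabs, function(ct) {
    list(counts = as.data.frame.matrix(ct$counts),
         pct = as.data.frame.matrix(ct$pct),
         n = ct$n)
  })
  manifest <- list(
    package = "tp53splice",
    version = as.character(utils::packageVersion("tp53splice")),
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = report$config,
    correlation = list(r = report$correlation$r, n = report$correlation$n),
    kruskal_p = report$bin_tests$kruskal$p.value,
    crosstabs = xt
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, mp)
  invisible(paths)
}
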