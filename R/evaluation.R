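## Predictor performance evaluation: group summaries, predictor-vs-assay
## cross-tabulations, score/expression correlation, score-bin expression
## tests and concordance of predicted vs observed aberrations.

#' Per-group summary of assay outcomes
#'
#' For each variant group: number of variants, number with full-length-only
#' expression, number with at least one characterised aberrant transcript,
#' number carrying any PVS1-weighted (non-NA) expression, and numbers whose
#' PVS1-weighted total exceeds 50% and 80% (strict).
#'
#' @param analysis A `variant_analysis` from [analyze_variants()].
#' @param include_controls Include control groups (default FALSE: test
#'   variants only).
#' @return data.frame, one row per group plus a `total` row.
#' @export
summarize_groups <- function(analysis, include_controls = FALSE) {
  a <- analysis
  if (!include_controls) a <- a[is_test_group(a$group), ]
  one <- function(rows) {
    data.frame(
      n = nrow(rows),
      fl100 = sum(vapply(rows$fl_pct, function(f) isTRUE(all.equal(f, 100)), logical(1))),
      aberrant = sum(rows$characterised_aberrant_pct > 0),
      pvs1_any = sum(rows$pvs1_total_pct > 0),
      gt50 = sum(rows$pvs1_total_pct > 50),
      gt80 = sum(rows$pvs1_total_pct > 80)
    )
  }
  parts <- lapply(split(a, a$group), one)
  out <- do.call(rbind, parts)
  out <- cbind(group = rownames(out), out)
  out <- rbind(out, cbind(group = "total", one(a)))
  rownames(out) <- NULL
  out
}

#' Splicing-predictor definitions for cross-tabulation
#'
#' Three predictors over the same variants:
#' * `SPLICEAI_BINARY`: SpliceAI max delta >= 0.2 positive, <= 0.1 negative;
#'   intermediate scores (0.1, 0.2) excluded.
#' * `SPLICEAI_VCEP`: same calls, but evaluated only on the variants the
#'   VCEP-style score bands cover (identical exclusions here).
#' * `MES`: MaxEntScan-style category, HIGH positive, LOW negative,
#'   MODERATE excluded.
#'
#' @param analysis A `variant_analysis` row set.
#' @param predictor One of `"SPLICEAI_BINARY"`, `"SPLICEAI_VCEP"`, `"MES"`.
#' @return Character vector parallel to rows: `"positive"`, `"negative"`
#'   or NA (excluded).
#' @export
predictor_call <- function(analysis, predictor = c("SPLICEAI_BINARY", "SPLICEAI_VCEP", "MES")) {
  predictor <- match.arg(predictor)
  if (predictor == "MES") {
    ifelse(analysis$mes_category == "HIGH", "positive",
           ifelse(analysis$mes_category == "LOW", "negative", NA_character_))
  } else {
    s <- analysis$spliceai_max
    ifelse(s >= 0.2, "positive", ifelse(s <= 0.1, "negative", NA_character_))
  }
}

#' Predictor vs assay-impact cross-tabulation
#'
#' Cross-tabulates each predictor's call against the assay impact category
#' (no impact / PVS1-weighted total under 50% / 50-80% / over 80%).
#' Variants whose only aberrant products carry no PVS1 weight (entirely
#' uncharacterised, or weighted PVS1_NA) are excluded throughout: the
#' impact scale is undefined for them. Counts and column percentages
#' (1 decimal) are reported.
#'
#' @param analysis A `variant_analysis`; controls are dropped.
#' @param predictors Predictor names (see [predictor_call()]).
#' @return Named list per predictor with `counts` and `pct` matrices
#'   (rows = impact categories, columns = negative/positive) and `n`.
#' @export
predictor_crosstab <- function(analysis,
                               predictors = c("SPLICEAI_BINARY", "SPLICEAI_VCEP", "MES")) {
  a <- analysis[is_test_group(analysis$group), ]
  # impact scale undefined: aberrant expression present but none of it carries
  # a PVS1 weight
  undefined <- a$characterised_aberrant_pct + a$uncharacterised_pct > 0 & a$pvs1_total_pct == 0
  a <- a[!undefined, ]
  impact <- factor(a$impact_category, levels = IMPACT_LEVELS)
  out <- lapply(predictors, function(p) {
    call <- factor(predictor_call(a, p), levels = c("negative", "positive"))
    keep <- !is.na(call)
    tab <- table(impact[keep], call[keep])
    pct <- round(100 * sweep(tab, 2, pmax(colSums(tab), 1L), "/"), 1)
    list(counts = unclass(tab), pct = unclass(pct), n = sum(keep))
  })
  stats::setNames(out, predictors)
}

#' Correlation of SpliceAI score with PVS1-weighted aberrant expression
#'
#' Pearson correlation between the SpliceAI max delta score and the
#' variant's PVS1-weighted aberrant expression total over the test
#' variants (controls excluded; variants without PVS1-weighted products
#' contribute 0%).
#'
#' @param analysis A `variant_analysis`.
#' @return List with `r`, `n`, and the two vectors used.
#' @export
score_expression_correlation <- function(analysis) {
  a <- analysis[is_test_group(analysis$group), ]
  r <- stats::cor(a$spliceai_max, a$pvs1_total_pct, method = "pearson")
  list(r = r, n = nrow(a), score = a$spliceai_max, expression = a$pvs1_total_pct)
}

SCORE_BINS <- c(0, 0.2, 0.5, 0.8, 1)

score_bin <- function(score) {
  cut(score, breaks = SCORE_BINS, include.lowest = TRUE, right = FALSE,
      labels = c("[0,0.2)", "[0.2,0.5)", "[0.5,0.8)", "[0.8,1]"))
}
# right=FALSE makes bins half-open on the right except the last, which
# include.lowest closes at 1.

#' Nonparametric tests of aberrant expression across score bins
#'
#' Kruskal-Wallis omnibus test of PVS1-weighted aberrant expression across
#' SpliceAI score bins, followed by pairwise Wilcoxon rank-sum tests with
#' Holm adjustment. Empty bins are dropped with a warning.
#'
#' @param analysis A `variant_analysis`.
#' @return List with `bins` (factor), `kruskal` (htest) and `pairwise`
#'   (pairwise.htest).
#' @export
bin_comparison_tests <- function(analysis) {
  a <- analysis[is_test_group(analysis$group), ]
  bins <- score_bin(a$spliceai_max)
  empty <- setdiff(levels(bins), unique(as.character(bins)))
  if (length(empty) > 0) {
    warning(sprintf("empty score bins dropped: %s", paste(empty, collapse = ", ")))
    bins <- droplevels(bins)
  }
  expr <- a$pvs1_total_pct
  list(bins = bins,
       kruskal = stats::kruskal.test(expr, bins),
       pairwise = stats::pairwise.wilcox.test(expr, bins, p.adjust.method = "holm",
                                              exact = FALSE))
}

#' Concordance of predicted aberrations with observed transcripts
#'
#' A variant is scored at expression level L (percent) when its total
#' characterised aberrant expression exceeds L; among those, the predicted
#' aberration set is concordant when at least one observed aberrant
#' transcript matches a prediction (see [match_concordance()]). Reported
#' per level and stratified by position relative to the splice region.
#'
#' @param analysis A `variant_analysis` (needs `in_splice_region`).
#' @param predictions Named list: variant -> list of `predicted_aberration`
#'   (from [predict_aberrations()]).
#' @param dataset The long `assay_dataset` holding observed transcripts.
#' @param model A `gene_model`.
#' @param levels Expression levels (percent) at which to score.
#' @param min_expr_pct Minimum observed expression for a transcript to be
#'   matchable.
#' @return data.frame with `level`, `stratum`, `n`, `concordant`, `pct`.
#' @export
concordance_by_level <- function(analysis, predictions, dataset,
                                 model = tp53_gene_model(),
                                 levels = c(5, 50, 80), min_expr_pct = 3) {
  a <- analysis[is_test_group(analysis$group) & !is.na(analysis$in_splice_region), ]
  conc <- vapply(a$variant, function(v) {
    obs <- dataset[dataset$variant_hgvs_c == v, c("transcript_token", "mean_pct")]
    names(obs) <- c("token", "mean_pct")
    match_concordance(predictions[[v]] %||% list(), obs, model, min_expr_pct = min_expr_pct)
  }, logical(1))
  grid <- expand.grid(level = levels, stratum = c("inside", "outside"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    L <- grid$level[i]
    inside <- grid$stratum[i] == "inside"
    sel <- a$characterised_aberrant_pct > L & a$in_splice_region == inside
    n <- sum(sel)
    k <- sum(conc[sel])
    data.frame(level = L, stratum = grid$stratum[i], n = n, concordant = k,
               pct = if (n > 0) round(100 * k / n, 1) else NA_real_)
  })
  do.call(rbind, rows)
}
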