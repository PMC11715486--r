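#' Load an assay-results table (fixture TSV schema)
#'
#' One row per transcript observation: `variant_hgvs_c`, `protein_hgvs_p`,
#' `group`, `mes_mode`, `mes_category`, `spliceai_max`, `transcript_token`,
#' `mean_pct`, `sd_pct`, `frame_column`, `assigned_weight`.
#'
#' @param path TSV path.
#' @param expect_variants Optional expected variant count (load error when
#'   it does not match, guarding against truncation).
#' @return data.frame of class `assay_dataset`.
#' @export
load_assay_fixture <- function(path, expect_variants = NULL) {
  req <- c("variant_hgvs_c", "protein_hgvs_p", "group", "mes_mode", "mes_category",
           "spliceai_max", "transcript_token", "mean_pct", "sd_pct",
           "frame_column", "assigned_weight")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  if (!all(req %in% names(df)))
    stop(sprintf("assay table misses columns: %s", paste(setdiff(req, names(df)), collapse = ", ")),
         call. = FALSE)
  if (!is.null(expect_variants) && length(unique(df$variant_hgvs_c)) != expect_variants)
    stop(sprintf("expected %d variants, found %d (truncated or corrupt table?)",
                 expect_variants, length(unique(df$variant_hgvs_c))), call. = FALSE)
  class(df) <- c("assay_dataset", "data.frame")
  df
}

#' Shipped assay-results fixture (59 test variants + 8 positive + 1 negative control)
#' @return `assay_dataset` data.frame.
#' @export
tp53_assay_fixture <- function() {
  load_assay_fixture(system.file("extdata", "tp53_assay_results.tsv",
                                 package = "tp53splice", mustWork = TRUE),
                     expect_variants = 68)
}

consequence_of_group <- function(group) {
  switch(group,
         synonymous_outside = "synonymous",
         missense_outside = , missense_inside = "missense",
         positive_control = "intronic",
         negative_control = "none",
         "unknown")
}

in_splice_region_of_group <- function(group) {
  switch(group,
         missense_inside = , positive_control = TRUE,
         missense_outside = , synonymous_outside = FALSE,
         NA)
}

#' Per-variant analysis: recompute frames, weights, totals, codes, routes
#'
#' The pipeline core. Every transcript token is parsed against the gene
#' model; frame and PVS1 (RNA) weight are recomputed from the model and
#' region-tier annotations (the table's own frame/weight columns are kept
#' only as a cross-check oracle); expression is aggregated into variant
#' totals, the gated RNA code, the BP7 (RNA) call and the classification
#' route.
#'
#' @param dataset An `assay_dataset` (long, one row per transcript).
#' @param model A `gene_model`.
#' @param tiers A `region_tiers` annotation table.
#' @param gate_threshold_pct Expression gate for applying a PVS1-type code
#'   at variant level (default 80).
#' @param total_tolerance Permitted deviation of per-variant expression
#'   totals from 100 (default 0.5; the shipped fixture is loaded with 3 to
#'   admit two rows whose printed components round inconsistently).
#' @return data.frame of class `variant_analysis`, one row per variant.
#' @export
analyze_variants <- function(dataset, model = tp53_gene_model(),
                             tiers = tp53_region_tiers(),
                             gate_threshold_pct = 80, total_tolerance = 3) {
  stopifnot(is.data.frame(dataset))
  out <- lapply(split(seq_len(nrow(dataset)), dataset$variant_hgvs_c), function(idx) {
    rows <- dataset[idx, ]
    n <- nrow(rows)
    kind_class <- character(n); weight <- rep(NA_character_, n); frame <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      evs <- parse_events(rows$transcript_token[i], model)
      k1 <- evs[[1]]$kind
      if (k1 == "FULL_LENGTH") { kind_class[i] <- "FL"; next }
      if (k1 == "UNCHARACTERISED") { kind_class[i] <- "uncharacterised"; next }
      kind_class[i] <- "characterised"
      fc <- classify_frame(evs, model)
      frame[i] <- fc$frame
      weight[i] <- assign_pvs1_weight(evs, fc, tiers, model)
    }
    obs <- data.frame(mean_pct = rows$mean_pct, kind_class = kind_class)
    totals <- variant_totals(obs, weight, tolerance = total_tolerance)
    applied <- applied_variant_code(totals, threshold_pct = gate_threshold_pct)
    consequence <- consequence_of_group(rows$group[1])
    bp7 <- bp7_rna(consequence, totals$fl_pct)
    data.frame(
      variant = rows$variant_hgvs_c[1],
      protein = rows$protein_hgvs_p[1],
      group = rows$group[1],
      consequence = consequence,
      in_splice_region = in_splice_region_of_group(rows$group[1]),
      mes_mode = rows$mes_mode[1],
      mes_category = rows$mes_category[1],
      spliceai_max = rows$spliceai_max[1],
      fl_pct = totals$fl_pct,
      pvs1_total_pct = totals$pvs1_total_pct,
      pvs1_full_pct = unname(totals$pvs1_weighted_pct["PVS1"]),
      na_pct = totals$na_pct,
      uncharacterised_pct = totals$uncharacterised_pct,
      characterised_aberrant_pct = totals$pvs1_total_pct + totals$na_pct,
      impact_category = totals$impact_category,
      applied_code = applied$code,
      applied_pct = applied$supporting_expression_pct,
      bp7_code = bp7,
      route = route_gate(totals, applied),
      n_transcripts = n,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  # keep the dataset's variant order
  res <- res[match(unique(dataset$variant_hgvs_c), res$variant), ]
  rownames(res) <- NULL
  class(res) <- c("variant_analysis", "data.frame")
  res
}

is_test_group <- function(group) !group %in% c("negative_control", "positive_control")

#' Per-transcript recomputed frames and weights (long form)
#'
#' Companion to [analyze_variants()] exposing, per characterised
#' transcript, the recomputed frame call and PVS1 weight next to the
#' table's printed columns; used to validate the engine against the
#' published assignments.
#'
#' @inheritParams analyze_variants
#' @return data.frame with `variant`, `token`, `frame`, `weight`,
#'   `printed_frame`, `printed_weight`.
#' @export
transcript_calls <- function(dataset, model = tp53_gene_model(),
                             tiers = tp53_region_tiers()) {
  rows <- lapply(seq_len(nrow(dataset)), function(i) {
    evs <- parse_events(dataset$transcript_token[i], model)
    k1 <- evs[[1]]$kind
    if (k1 %in% c("FULL_LENGTH", "UNCHARACTERISED")) return(NULL)
    fc <- classify_frame(evs, model)
    data.frame(variant = dataset$variant_hgvs_c[i],
               token = dataset$transcript_token[i],
               frame = fc$frame,
               weight = assign_pvs1_weight(evs, fc, tiers, model),
               printed_frame = dataset$frame_column[i],
               printed_weight = dataset$assigned_weight[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
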