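#' PVS1 (RNA) variable weights, strongest first
#' @export
PVS1_WEIGHTS <- c("PVS1", "PVS1_Strong", "PVS1_Moderate", "PVS1_Supporting", "PVS1_NA")

TIER_TO_WEIGHT <- c(PATHOGENIC_MISSENSE = "PVS1",
                    FUNCTIONAL_DAMAGING = "PVS1_Strong",
                    BIOINFORMATIC_DAMAGING = "PVS1_Supporting",
                    BENIGN_PREDICTED = "PVS1_NA")

weight_rank <- function(w) match(w, PVS1_WEIGHTS)

#' Load a codon-level region-tier annotation config
#'
#' @param path JSON file with a `tiers` array of
#'   `{codon_start, codon_end, tier, source_note}` records.
#' @return data.frame of class `region_tiers`.
#' @export
load_region_tiers <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  tiers <- as.data.frame(cfg$tiers)
  stopifnot(all(c("codon_start", "codon_end", "tier") %in% names(tiers)),
            all(tiers$tier %in% names(TIER_TO_WEIGHT)),
            all(tiers$codon_end >= tiers$codon_start))
  class(tiers) <- c("region_tiers", "data.frame")
  tiers
}

#' Shipped (synthetic) p53 region-tier map
#'
#' Curated codon intervals carrying the evidence tier used to weight
#' in-frame deletions/insertions; reconstructed from the assay's reported
#' weight assignments rather than from live database queries.
#' @return `region_tiers` data.frame.
#' @export
tp53_region_tiers <- function() {
  load_region_tiers(system.file("extdata", "tp53_region_tiers_synthetic.json",
                                package = "tp53splice", mustWork = TRUE))
}

#' Assign a PVS1 (RNA) variable weight to one transcript
#'
#' PTC transcripts receive the configured PTC weight (full PVS1 by
#' default: every PTC product of this minigene truncates within the
#' functionally essential region). In-frame events are weighted by the
#' strongest evidence tier overlapping their affected codon interval:
#' pathogenic-missense evidence -> PVS1, damaging functional data ->
#' PVS1_Strong, damaging bioinformatics only -> PVS1_Supporting, benign
#' prediction -> PVS1_NA. An in-frame event overlapping no annotated
#' region is an error, never a silent default.
#'
#' @param event A `splice_event` or list of them (one transcript).
#' @param frame A `frame_call` for the event(s).
#' @param annotations A `region_tiers` data.frame.
#' @param model A `gene_model` (needed to locate affected codons).
#' @param ptc_weight Weight for PTC transcripts (rule-table default "PVS1").
#' @return One of [PVS1_WEIGHTS].
#' @export
assign_pvs1_weight <- function(event, frame, annotations, model,
                               ptc_weight = "PVS1") {
  stopifnot(inherits(frame, "frame_call"), ptc_weight %in% PVS1_WEIGHTS)
  if (frame$frame == "PTC") return(ptc_weight)
  iv <- affected_codons(event, model)
  hit <- vapply(seq_len(nrow(annotations)), function(i) {
    any(annotations$codon_start[i] <= iv$codon_end & annotations$codon_end[i] >= iv$codon_start)
  }, logical(1))
  if (!any(hit))
    stop(structure(class = c("unannotated_region", "error", "condition"),
                   list(message = sprintf("in-frame event %s (codons %d-%d) overlaps no annotated region",
                                          event_token(event), min(iv$codon_start), max(iv$codon_end)),
                        call = sys.call(-1))))
  w <- TIER_TO_WEIGHT[annotations$tier[hit]]
  PVS1_WEIGHTS[min(weight_rank(w))]
}

#' Variant-level applied PVS1 (RNA) code
#'
#' The code is applied conservatively: the strongest weight W such that
#' the summed expression of transcripts weighted at W or stronger exceeds
#' the threshold (80% of total expression by default). Below the
#' threshold no RNA code is applied.
#'
#' @param totals A `variant_totals`.
#' @param threshold_pct Gate on cumulative expression (strict >), default 80.
#' @return List of class `applied_rna_code` with `code` (a PVS1 weight or
#'   NA) and `supporting_expression_pct`.
#' @export
applied_variant_code <- function(totals, threshold_pct = 80) {
  cum <- cumsum(totals$pvs1_weighted_pct)  # ordered strongest -> weakest
  i <- which(cum > threshold_pct)
  if (length(i) == 0L)
    return(structure(list(code = NA_character_, supporting_expression_pct = NA_real_),
                     class = "applied_rna_code"))
  i <- min(i)
  structure(list(code = names(cum)[i], supporting_expression_pct = unname(cum[i])),
            class = "applied_rna_code")
}

#' BP7 (RNA)_Strong for synonymous variants with no splicing impact
#'
#' Applied iff the variant is synonymous and full-length expression is
#' 100% (complete experimental exclusion of a splicing effect).
#'
#' @param consequence `"synonymous"` or `"missense"` (or other).
#' @param fl_pct Full-length expression percentage.
#' @return `"BP7_Strong"` or NA.
#' @export
bp7_rna <- function(consequence, fl_pct) {
  if (identical(consequence, "synonymous") && isTRUE(all.equal(fl_pct, 100)))
    "BP7_Strong" else NA_character_
}

#' Classification-route gate from the assay result
#'
#' SPLICING_ROUTE when a PVS1-type RNA code is applied (aberrant
#' PVS1-weighted expression above the gate); PROTEIN_ROUTE when no
#' PVS1-weighted transcript was observed at all (full-length 100%, or only
#' uncharacterised / PVS1_NA products), so protein-level functional and
#' computational codes may be used; otherwise INDETERMINATE (real but
#' sub-threshold splicing impact blocks both code families).
#'
#' @param totals A `variant_totals`.
#' @param applied An `applied_rna_code` for the same variant.
#' @return `"SPLICING_ROUTE"`, `"PROTEIN_ROUTE"` or `"INDETERMINATE"`.
#' @export
route_gate <- function(totals, applied = applied_variant_code(totals)) {
  if (!is.na(applied$code)) return("SPLICING_ROUTE")
  if (totals$pvs1_total_pct == 0) return("PROTEIN_ROUTE")
  "INDETERMINATE"
}
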