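#' Construct a SpliceAI record
#'
#' Delta scores (acceptor/donor gain/loss) in \[0,1\] with their positions
#' in nt relative to the variant (negative = upstream/5'), plus optional
#' reference/alternate site-score maps used for splice-site competition.
#'
#' @param ds_ag,ds_al,ds_dg,ds_dl Delta scores.
#' @param dp_ag,dp_al,dp_dg,dp_dl Delta positions (signed nt offsets).
#' @param ref_scores,alt_scores Optional named numeric vectors mapping a
#'   position offset (as character) to a site score.
#' @return List of class `spliceai_record`, with `max_delta` computed.
#' @export
spliceai_record <- function(ds_ag = 0, ds_al = 0, ds_dg = 0, ds_dl = 0,
                            dp_ag = NA_integer_, dp_al = NA_integer_,
                            dp_dg = NA_integer_, dp_dl = NA_integer_,
                            ref_scores = NULL, alt_scores = NULL) {
  ds <- c(ds_ag = ds_ag, ds_al = ds_al, ds_dg = ds_dg, ds_dl = ds_dl)
  if (any(is.na(ds)) || any(ds < 0 | ds > 1))
    stop("delta scores must lie in [0, 1]", call. = FALSE)
  structure(list(ds_ag = ds_ag, ds_al = ds_al, ds_dg = ds_dg, ds_dl = ds_dl,
                 dp_ag = dp_ag, dp_al = dp_al, dp_dg = dp_dg, dp_dl = dp_dl,
                 ref_scores = ref_scores, alt_scores = alt_scores,
                 max_delta = max(ds)),
            class = "spliceai_record")
}

#' Bin a SpliceAI maximum delta score at the evaluation cutoffs
#'
#' Bins reflect the cutoffs used to evaluate the predictor: the
#' VCEP-specified `<= 0.1` and `>= 0.2` thresholds and the developers'
#' `>= 0.5` cryptic-site cutoff (both boundary scores inclusive, matching
#' the published notation).
#'
#' @param score Max delta score in \[0,1\] (vectorised).
#' @return Factor with levels `LE_0_1`, `BETWEEN_0_1_0_2`, `GE_0_2_LT_0_5`, `GE_0_5`.
#' @export
bin_spliceai <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 1))
    stop("SpliceAI score out of [0, 1]", call. = FALSE)
  lev <- c("LE_0_1", "BETWEEN_0_1_0_2", "GE_0_2_LT_0_5", "GE_0_5")
  out <- ifelse(score <= 0.1, "LE_0_1",
         ifelse(score < 0.2, "BETWEEN_0_1_0_2",
         ifelse(score < 0.5, "GE_0_2_LT_0_5", "GE_0_5")))
  factor(out, levels = lev)
}

# resolve a position offset relative to an exonic variant into
# (context = "exonic"/"intron_down"/"intron_up", exon, pos-or-offset)
resolve_site <- function(variant_cdna_pos, offset, model) {
  ex <- model$exons
  i <- which(ex$cdna_start <= variant_cdna_pos & ex$cdna_end >= variant_cdna_pos)
  if (length(i) != 1L)
    stop(sprintf("variant position c.%d not inside a modeled exon", variant_cdna_pos), call. = FALSE)
  p <- variant_cdna_pos + offset
  e <- ex[i, ]
  if (p >= e$cdna_start && p <= e$cdna_end)
    list(context = "exonic", exon = e$exon_id, pos = p)
  else if (p > e$cdna_end)
    list(context = "intron_down", exon = e$exon_id, offset = p - e$cdna_end)
  else
    list(context = "intron_up", exon = e$exon_id, offset = e$cdna_start - p)
}

nearest_exon <- function(model, pos, boundary = c("end", "start")) {
  boundary <- match.arg(boundary)
  b <- if (boundary == "end") model$exons$cdna_end else model$exons$cdna_start
  model$exons$exon_id[which.min(abs(b - pos))]
}

new_predicted_aberration <- function(kind, target_id, length_nt = NA_integer_,
                                     competition_flagged = NA, source = NA_character_) {
  structure(list(kind = kind, target_id = target_id, length_nt = as.integer(length_nt),
                 competition_flagged = competition_flagged, source = source),
            class = "predicted_aberration")
}

#' @export
print.predicted_aberration <- function(x, ...) {
  cat(sprintf("<predicted_aberration> %s target %s (%s nt)%s\n", x$kind, x$target_id,
              ifelse(is.na(x$length_nt), "?", x$length_nt),
              ifelse(isTRUE(x$competition_flagged), " [competition-flagged]", "")))
  invisible(x)
}

#' Predict splicing-aberration types from a SpliceAI record
#'
#' Interprets the four delta scores jointly, in the style of the
#' SpliceAI-10k calculator defaults: paired loss of an exon's donor and
#' acceptor predicts skipping of that exon; an unpaired donor (acceptor)
#' loss predicts retention of the downstream (upstream) intron; a donor
#' gain inside an exon predicts deletion of the exonic segment between the
#' new and the native donor; a donor gain in the downstream intron
#' predicts partial retention of that many intronic nt (mirrored rules for
#' acceptor gains). Deltas below `threshold` are ignored. When the record
#' carries alternate site scores, gains are annotated (never suppressed)
#' with a native-vs-new competition flag.
#'
#' @param rec A `spliceai_record`.
#' @param variant_cdna_pos 1-based coding position of the variant.
#' @param model A `gene_model`.
#' @param threshold Delta-score threshold, default 0.2.
#' @param competition_margin Margin for [competition_flag()], default 0.2.
#' @return List of `predicted_aberration` (empty = no predicted impact).
#' @export
predict_aberrations <- function(rec, variant_cdna_pos, model, threshold = 0.2,
                                competition_margin = 0.2) {
  stopifnot(inherits(rec, "spliceai_record"))
  out <- list()

  loss_exon <- function(ds, dp, boundary) {
    if (ds < threshold || is.na(dp)) return(NA_integer_)
    r <- resolve_site(variant_cdna_pos, dp, model)
    pos <- if (r$context == "exonic") r$pos
           else if (r$context == "intron_down") exon_row(model, r$exon)$cdna_end
           else exon_row(model, r$exon)$cdna_start
    nearest_exon(model, pos, boundary)
  }
  dl_exon <- loss_exon(rec$ds_dl, rec$dp_dl, "end")
  al_exon <- loss_exon(rec$ds_al, rec$dp_al, "start")

  if (!is.na(dl_exon) && !is.na(al_exon) && dl_exon == al_exon) {
    out <- c(out, list(new_predicted_aberration("EXON_SKIP", dl_exon,
                                                exon_length(model, dl_exon), source = "DL+AL")))
  } else {
    if (!is.na(dl_exon))
      out <- c(out, list(new_predicted_aberration("INTRON_RETENTION",
                                                  downstream_intron_id(model, dl_exon), source = "DL")))
    if (!is.na(al_exon))
      out <- c(out, list(new_predicted_aberration("INTRON_RETENTION",
                                                  upstream_intron_id(model, al_exon), source = "AL")))
  }

  gain_flag <- function(dp, native_offset) {
    if (is.null(rec$alt_scores)) return(NA)
    new_alt <- rec$alt_scores[as.character(dp)]
    native_alt <- rec$alt_scores[as.character(native_offset)]
    if (length(new_alt) != 1L || is.na(new_alt)) return(NA)
    competition_flag(unname(new_alt),
                     if (length(native_alt) == 1L) unname(native_alt) else NA_real_,
                     margin = competition_margin)
  }

  if (rec$ds_dg >= threshold && !is.na(rec$dp_dg)) {
    r <- resolve_site(variant_cdna_pos, rec$dp_dg, model)
    d <- exon_row(model, r$exon)$cdna_end
    if (r$context == "exonic" && r$pos < d) {
      out <- c(out, list(new_predicted_aberration(
        "PARTIAL_EXON_DEL_DONOR_SIDE", r$exon, d - r$pos,
        competition_flagged = gain_flag(rec$dp_dg, d - variant_cdna_pos), source = "DG")))
    } else if (r$context == "intron_down") {
      out <- c(out, list(new_predicted_aberration(
        "PARTIAL_INTRON_RETENTION_DONOR_SIDE", r$exon, r$offset,
        competition_flagged = gain_flag(rec$dp_dg, d - variant_cdna_pos), source = "DG")))
    }
  }
  if (rec$ds_ag >= threshold && !is.na(rec$dp_ag)) {
    r <- resolve_site(variant_cdna_pos, rec$dp_ag, model)
    a <- exon_row(model, r$exon)$cdna_start
    if (r$context == "exonic" && r$pos > a) {
      out <- c(out, list(new_predicted_aberration(
        "PARTIAL_EXON_DEL_ACCEPTOR_SIDE", r$exon, r$pos - a + 1L,
        competition_flagged = gain_flag(rec$dp_ag, a - variant_cdna_pos), source = "AG")))
    } else if (r$context == "intron_up") {
      out <- c(out, list(new_predicted_aberration(
        "PARTIAL_INTRON_RETENTION_ACCEPTOR_SIDE", r$exon, r$offset,
        competition_flagged = gain_flag(rec$dp_ag, a - variant_cdna_pos), source = "AG")))
    }
  }
  out
}

#' Native-vs-new splice-site competition flag
#'
#' TRUE when the alternate (post-variant) score of the native site exceeds
#' the new site's alternate score by more than `margin`: the native site
#' may out-compete the predicted cryptic site. The flag annotates a
#' prediction and never suppresses it (the assay shows out-competed sites
#' can still be used).
#'
#' @param new_site_alt_score Alternate score of the gained site.
#' @param native_site_alt_score Alternate score of the native site (NA when
#'   the lookup does not report it, giving flag NA = unknown).
#' @param margin Score margin, default 0.2.
#' @return TRUE / FALSE / NA.
#' @export
competition_flag <- function(new_site_alt_score, native_site_alt_score, margin = 0.2) {
  if (is.na(native_site_alt_score) || is.na(new_site_alt_score)) return(NA)
  (native_site_alt_score - new_site_alt_score) > margin
}

#' Do predicted aberrations match the observed transcript profile?
#'
#' TRUE iff at least one predicted aberration coincides (same kind, same
#' exon/intron target and, for partial events, identical length) with an
#' observed event expressed at or above `min_expr_pct` of total expression.
#'
#' @param predicted List of `predicted_aberration`.
#' @param observed data.frame with columns `token` and `mean_pct` (one row
#'   per observed transcript), or a list of `list(events=, mean_pct=)`.
#' @param model A `gene_model`.
#' @param min_expr_pct Observation floor, default 3 (the calculator
#'   resolves transcripts down to about 3% expression).
#' @return Logical scalar.
#' @export
match_concordance <- function(predicted, observed, model, min_expr_pct = 3) {
  if (length(predicted) == 0L) return(FALSE)
  obs_events <- list()
  if (is.data.frame(observed)) {
    for (i in seq_len(nrow(observed))) {
      if (observed$mean_pct[i] < min_expr_pct) next
      evs <- tryCatch(parse_events(observed$token[i], model), error = function(e) NULL)
      if (is.null(evs)) next
      for (e in evs) if (!e$kind %in% c("FULL_LENGTH", "UNCHARACTERISED"))
        obs_events <- c(obs_events, list(e))
    }
  } else {
    for (o in observed) if (o$mean_pct >= min_expr_pct)
      obs_events <- c(obs_events, o$events)
  }
  same <- function(p, o) {
    if (p$kind != o$kind) return(FALSE)
    if (as.character(p$target_id) != as.character(o$target_id)) return(FALSE)
    if (p$kind %in% c("EXON_SKIP", "INTRON_RETENTION")) return(TRUE)
    isTRUE(p$length_nt == o$length_nt)
  }
  for (p in predicted) for (o in obs_events) if (same(p, o)) return(TRUE)
  FALSE
}

#' Build a SpliceAI record that exactly encodes observed events
#'
#' Inverse of [predict_aberrations()]: given one characterised event (the
#' dominant product of a synthetic variant), constructs the delta scores
#' and positions from which the prediction rules recover that event. Used
#' as the self-consistency oracle for the prediction module.
#'
#' @param event A `splice_event` (characterised, non-FL).
#' @param variant_cdna_pos Exonic coding position of the variant; must lie
#'   in the exon the event refers to (for intron retention: the upstream
#'   exon).
#' @param model A `gene_model`.
#' @param delta Delta score given to the encoding components, default 0.9.
#' @return A `spliceai_record`.
#' @export
perfect_spliceai_record <- function(event, variant_cdna_pos, model, delta = 0.9) {
  k <- event$kind
  ex_of <- function(id) exon_row(model, id)
  if (k == "EXON_SKIP") {
    e <- ex_of(event$target_id)
    return(spliceai_record(ds_dl = delta, dp_dl = e$cdna_end - variant_cdna_pos,
                           ds_al = delta, dp_al = e$cdna_start - variant_cdna_pos))
  }
  if (k == "INTRON_RETENTION") {
    # donor loss of the exon upstream of the retained intron
    up_exon <- as.integer(sub("-mg$", "", event$target_id))
    e <- ex_of(up_exon)
    return(spliceai_record(ds_dl = delta, dp_dl = e$cdna_end - variant_cdna_pos))
  }
  e <- ex_of(event$target_id)
  switch(k,
    PARTIAL_EXON_DEL_DONOR_SIDE =
      spliceai_record(ds_dg = delta, dp_dg = (e$cdna_end - event$length_nt) - variant_cdna_pos),
    PARTIAL_EXON_DEL_ACCEPTOR_SIDE =
      spliceai_record(ds_ag = delta, dp_ag = (e$cdna_start + event$length_nt - 1L) - variant_cdna_pos),
    PARTIAL_INTRON_RETENTION_DONOR_SIDE =
      spliceai_record(ds_dg = delta, dp_dg = (e$cdna_end + event$length_nt) - variant_cdna_pos),
    PARTIAL_INTRON_RETENTION_ACCEPTOR_SIDE =
      spliceai_record(ds_ag = delta, dp_ag = (e$cdna_start - event$length_nt) - variant_cdna_pos),
    stop("cannot encode event kind ", k)
  )
}
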