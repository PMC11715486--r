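## Transcript-event nomenclature
##
## The assay reports each aberrant product with a compact token:
##   Δ(E5)      exon 5 skipped
##   Δ(E5q46)   last 46 nt of exon 5 deleted (cryptic donor inside the exon)
##   Δ(E5p21)   first 21 nt of exon 5 deleted (cryptic acceptor inside the exon)
##   ▼(I7)      intron 7 fully retained
##   ▼(E6q5)    5 intronic nt retained immediately downstream of exon 6
##   ▼(E8p3)    3 intronic nt retained immediately upstream of exon 8
##   "955-nt"   uncharacterised product, known only by its size
## Δ and △ are interchangeable in print; an ASCII dialect (del(...)/ins(...))
## is used in data files.

EVENT_KINDS <- c("FULL_LENGTH", "EXON_SKIP",
                 "PARTIAL_EXON_DEL_ACCEPTOR_SIDE", "PARTIAL_EXON_DEL_DONOR_SIDE",
                 "INTRON_RETENTION",
                 "PARTIAL_INTRON_RETENTION_DONOR_SIDE",
                 "PARTIAL_INTRON_RETENTION_ACCEPTOR_SIDE",
                 "UNCHARACTERISED")

new_splice_event <- function(kind, target_id = NA, length_nt = NA_integer_,
                             raw_token = NA_character_, product_size_nt = NA_integer_) {
  stopifnot(kind %in% EVENT_KINDS)
  structure(list(kind = kind, target_id = target_id,
                 length_nt = as.integer(length_nt), raw_token = raw_token,
                 product_size_nt = as.integer(product_size_nt)),
            class = "splice_event")
}

#' @export
print.splice_event <- function(x, ...) {
  cat(sprintf("<splice_event> %s %s\n", x$kind, event_token(x)))
  invisible(x)
}

normalize_token <- function(token) {
  token <- trimws(token)
  # unicode triangle dialects -> ASCII dialect
  token <- gsub("Δ|△", "del", token)  # Δ, △
  token <- gsub("▼", "ins", token)         # ▼
  token
}

#' Parse one transcript-event token
#'
#' Accepts the published Unicode notation and its ASCII dialect. A bare
#' size label (e.g. `"955-nt"`) yields an `UNCHARACTERISED` event; the
#' full-length sentinel (`"FL"`) yields `FULL_LENGTH`.
#'
#' @param token Event token text.
#' @param model A `gene_model`; every parsed event is validated against it.
#' @return A `splice_event`.
#' @export
parse_event <- function(token, model) {
  raw <- token
  tok <- normalize_token(token)
  if (toupper(tok) %in% c("FL", "FULL-LENGTH", "FULL_LENGTH"))
    return(new_splice_event("FULL_LENGTH", raw_token = raw))
  if (grepl("^[0-9]+[- ]?nt$", tok))
    return(new_splice_event("UNCHARACTERISED", raw_token = raw,
                            product_size_nt = as.integer(sub("[- ]?nt$", "", tok))))

  m <- regmatches(tok, regexec("^(del|ins)\\(([EI])([0-9]+(?:-mg)?)(?:([pq])([0-9]+))?\\)$", tok))[[1]]
  if (length(m) == 0L)
    stop(sprintf("malformed event token: '%s'", raw), call. = FALSE)
  op <- m[2]; unit <- m[3]; id <- m[4]; side <- m[5]; k <- m[6]

  if (unit == "I") {
    if (op != "ins") stop(sprintf("malformed event token: '%s' (introns can only be retained)", raw), call. = FALSE)
    if (nzchar(side)) stop(sprintf("malformed event token: '%s'", raw), call. = FALSE)
    intron_row(model, id)  # errors if unknown
    return(new_splice_event("INTRON_RETENTION", target_id = id, raw_token = raw))
  }

  exon_id <- as.integer(sub("-mg$", "", id))
  ex <- exon_row(model, exon_id)
  exlen <- ex$cdna_end - ex$cdna_start + 1L

  if (!nzchar(side)) {
    if (op == "del") return(new_splice_event("EXON_SKIP", target_id = exon_id,
                                             length_nt = exlen, raw_token = raw))
    stop(sprintf("malformed event token: '%s' (whole-exon insertion is not an event)", raw), call. = FALSE)
  }

  k <- as.integer(k)
  if (k < 1L) stop(sprintf("malformed event token: '%s'", raw), call. = FALSE)
  if (op == "del") {
    if (k > exlen)
      stop(sprintf("event '%s' deletes %d nt but exon %d is only %d nt", raw, k, exon_id, exlen), call. = FALSE)
    kind <- if (side == "p") "PARTIAL_EXON_DEL_ACCEPTOR_SIDE" else "PARTIAL_EXON_DEL_DONOR_SIDE"
    return(new_splice_event(kind, target_id = exon_id, length_nt = k, raw_token = raw))
  }
  # ins(Enq k): k intronic nt retained just downstream of exon n's donor;
  # ins(Enp k): k intronic nt retained just upstream of exon n's acceptor.
  iid <- if (side == "q") downstream_intron_id(model, exon_id) else upstream_intron_id(model, exon_id)
  ilen <- intron_row(model, iid)$length_nt
  if (!is.na(ilen) && k > ilen)
    stop(sprintf("event '%s' retains %d nt but intron %s is only %d nt", raw, k, iid, ilen), call. = FALSE)
  kind <- if (side == "q") "PARTIAL_INTRON_RETENTION_DONOR_SIDE" else "PARTIAL_INTRON_RETENTION_ACCEPTOR_SIDE"
  new_splice_event(kind, target_id = exon_id, length_nt = k, raw_token = raw)
}

#' Parse a (possibly compound) transcript token into a list of events
#'
#' A few assay products combine aberrations (e.g. a partial exon-4 deletion
#' together with an exon-5 skip, printed as juxtaposed tokens); frame is
#' then classified on the summed length change.
#'
#' @inheritParams parse_event
#' @return List of `splice_event`.
#' @export
parse_events <- function(token, model) {
  tok <- normalize_token(token)
  pieces <- regmatches(tok, gregexpr("(del|ins)\\([^)]*\\)", tok))[[1]]
  if (length(pieces) <= 1L) return(list(parse_event(token, model)))
  leftover <- gsub("(del|ins)\\([^)]*\\)", "", tok)
  if (grepl("[^[:space:]]", leftover))
    stop(sprintf("malformed compound token: '%s'", token), call. = FALSE)
  lapply(pieces, parse_event, model = model)
}

#' Canonical (Unicode) serialization of a splice event
#'
#' @param event A `splice_event` (or list of them, serialized juxtaposed).
#' @return Character scalar token.
#' @export
event_token <- function(event) {
  if (is.list(event) && !inherits(event, "splice_event"))
    return(paste(vapply(event, event_token, character(1)), collapse = ""))
  switch(event$kind,
    FULL_LENGTH = "FL",
    UNCHARACTERISED = sprintf("%d-nt", event$product_size_nt),
    EXON_SKIP = sprintf("Δ(E%s)", event$target_id),
    PARTIAL_EXON_DEL_ACCEPTOR_SIDE = sprintf("Δ(E%sp%d)", event$target_id, event$length_nt),
    PARTIAL_EXON_DEL_DONOR_SIDE = sprintf("Δ(E%sq%d)", event$target_id, event$length_nt),
    INTRON_RETENTION = sprintf("▼(I%s)", event$target_id),
    PARTIAL_INTRON_RETENTION_DONOR_SIDE = sprintf("▼(E%sq%d)", event$target_id, event$length_nt),
    PARTIAL_INTRON_RETENTION_ACCEPTOR_SIDE = sprintf("▼(E%sp%d)", event$target_id, event$length_nt)
  )
}

#' Signed transcript length change of an event (nt)
#'
#' Deletions are negative, retentions positive. Full intron retention
#' requires the intron length to be annotated in the model; the minigene
#' intron lengths are not published, so that case signals an
#' `unknown_length` condition instead of guessing.
#'
#' @param event A `splice_event` or list of them (summed).
#' @param model A `gene_model`.
#' @return Signed integer.
#' @export
length_change <- function(event, model) {
  if (is.list(event) && !inherits(event, "splice_event"))
    return(sum(vapply(event, length_change, numeric(1), model = model)))
  switch(event$kind,
    FULL_LENGTH = 0L,
    UNCHARACTERISED = stop("length change undefined for an uncharacterised product", call. = FALSE),
    EXON_SKIP = -exon_length(model, event$target_id),
    PARTIAL_EXON_DEL_ACCEPTOR_SIDE = -event$length_nt,
    PARTIAL_EXON_DEL_DONOR_SIDE = -event$length_nt,
    PARTIAL_INTRON_RETENTION_DONOR_SIDE = event$length_nt,
    PARTIAL_INTRON_RETENTION_ACCEPTOR_SIDE = event$length_nt,
    INTRON_RETENTION = {
      len <- intron_row(model, event$target_id)$length_nt
      if (is.na(len))
        stop(structure(class = c("unknown_length", "error", "condition"),
                       list(message = sprintf("length of intron %s is not annotated", event$target_id),
                            call = sys.call(-1))))
      len
    }
  )
}

#' Classify the reading-frame consequence of an event (or event set)
#'
#' Frameshifts (net length change not divisible by 3) are PTC; in-frame
#' exonic deletions are IN_FRAME; full intron retention is PTC when the
#' model annotates an in-frame stop in the retained intron (or when its
#' length is known and frameshifting). With no usable annotation the frame
#' is explicitly undetermined, never silently defaulted.
#'
#' @param event A `splice_event` or list of them.
#' @param model A `gene_model`.
#' @return A `frame_call`: list with `frame` ("PTC"/"IN_FRAME") and
#'   `length_change_nt` (NA when an intron length is unknown).
#' @export
classify_frame <- function(event, model) {
  events <- if (is.list(event) && !inherits(event, "splice_event")) event else list(event)
  kinds <- vapply(events, function(e) e$kind, character(1))
  if (any(kinds %in% c("UNCHARACTERISED", "FULL_LENGTH")))
    stop("frame classification applies to characterised aberrant events only", call. = FALSE)

  retained_stop <- FALSE
  unknown <- FALSE
  total <- 0L
  for (e in events) {
    if (e$kind == "INTRON_RETENTION") {
      ir <- intron_row(model, e$target_id)
      if (isTRUE(ir$contains_in_frame_stop)) retained_stop <- TRUE
      if (is.na(ir$length_nt)) { unknown <- TRUE; next }
    }
    total <- total + length_change(e, model)
  }
  if (retained_stop)
    return(structure(list(frame = "PTC", length_change_nt = if (unknown) NA_integer_ else as.integer(total)),
                     class = "frame_call"))
  if (unknown)
    stop(structure(class = c("frame_undetermined", "error", "condition"),
                   list(message = "retained intron has unknown length and no stop-codon annotation; frame undetermined",
                        call = sys.call(-1))))
  frame <- if (total %% 3L != 0L) "PTC" else "IN_FRAME"
  structure(list(frame = frame, length_change_nt = as.integer(total)), class = "frame_call")
}

#' @export
print.frame_call <- function(x, ...) {
  cat(sprintf("<frame_call> %s (net %+d nt)\n", x$frame,
              ifelse(is.na(x$length_change_nt), 0L, x$length_change_nt)))
  invisible(x)
}

# cDNA span removed by a deletion-type event (NULL for insertions)
deleted_span <- function(event, model) {
  ex <- if (event$kind %in% c("EXON_SKIP", "PARTIAL_EXON_DEL_ACCEPTOR_SIDE",
                              "PARTIAL_EXON_DEL_DONOR_SIDE"))
    exon_row(model, event$target_id) else return(NULL)
  switch(event$kind,
    EXON_SKIP = c(ex$cdna_start, ex$cdna_end),
    PARTIAL_EXON_DEL_ACCEPTOR_SIDE = c(ex$cdna_start, ex$cdna_start + event$length_nt - 1L),
    PARTIAL_EXON_DEL_DONOR_SIDE = c(ex$cdna_end - event$length_nt + 1L, ex$cdna_end)
  )
}

# codon interval affected by an event: codons touched by a deletion, or the
# codon(s) flanking/containing an insertion point
affected_codons <- function(event, model) {
  if (is.list(event) && !inherits(event, "splice_event")) {
    ivs <- lapply(event, affected_codons, model = model)
    return(do.call(rbind, ivs))
  }
  span <- deleted_span(event, model)
  if (!is.null(span))
    return(data.frame(codon_start = codon_of(span[1]), codon_end = codon_of(span[2])))
  # intronic retention: insertion at an exon boundary
  ex <- exon_row(model, event$target_id)
  at <- switch(event$kind,
    PARTIAL_INTRON_RETENTION_DONOR_SIDE = ex$cdna_end,
    PARTIAL_INTRON_RETENTION_ACCEPTOR_SIDE = ex$cdna_start - 1L,
    INTRON_RETENTION = ex$cdna_end,
    stop("no codon footprint for event kind ", event$kind))
  data.frame(codon_start = codon_of(max(at, 1L)), codon_end = codon_of(at + 1L))
}

#' Protein-level consequence of an in-frame event
#'
#' Codon-aligned deletions are named `p.Xaa<i>_Xaa<j>del` directly from
#' codon arithmetic and the model's residue annotation. Events whose
#' boundary codons merge (non-aligned deletions, intronic insertions)
#' produce a delins/ins whose replacement residues cannot be derived
#' without nucleotide sequence; those are looked up in the model's
#' junction-notation annotation and are otherwise reported with the codon
#' range and `notation = NA`.
#'
#' @param event A single `splice_event` with an IN_FRAME frame call.
#' @param model A `gene_model`.
#' @return List of class `protein_consequence` with `notation`,
#'   `codon_start`, `codon_end` and `kind` ("del", "delins" or "ins").
#' @export
protein_consequence <- function(event, model) {
  fc <- classify_frame(event, model)
  if (fc$frame != "IN_FRAME")
    stop("protein consequence is defined for in-frame events only", call. = FALSE)

  override <- model$junction_notation[[event_token(event)]]
  span <- deleted_span(event, model)
  if (!is.null(span)) {
    a <- span[1]; b <- span[2]
    cs <- codon_of(a); ce <- codon_of(b)
    aligned <- (a - 1L) %% 3L == 0L && b %% 3L == 0L
    kind <- if (aligned) "del" else "delins"
    notation <- if (aligned) {
      if (cs == ce) sprintf("p.%s%ddel", residue3(model, cs), cs)
      else sprintf("p.%s%d_%s%ddel", residue3(model, cs), cs, residue3(model, ce), ce)
    } else if (!is.null(override)) override else NA_character_
  } else {
    iv <- affected_codons(event, model)
    cs <- iv$codon_start; ce <- iv$codon_end
    kind <- "ins"
    notation <- if (!is.null(override)) override else NA_character_
  }
  structure(list(notation = notation, codon_start = cs, codon_end = ce, kind = kind),
            class = "protein_consequence")
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat(sprintf("<protein_consequence> %s (codons %d-%d, %s)\n",
              ifelse(is.na(x$notation), "<unnamed>", x$notation),
              x$codon_start, x$codon_end, x$kind))
  invisible(x)
}
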