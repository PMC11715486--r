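## ACMG/AMP points-based classification (TP53 VCEP-style specifications).
## Code ids are "<base><number>[_<strength>]": the base prefix fixes the
## direction and default strength (PVS 8, PS 4, PM 2, PP 1; BS -4, BP -1,
## BA -8), an explicit strength suffix overrides the magnitude.

STRENGTH_POINTS <- c(Supporting = 1L, Moderate = 2L, Strong = 4L, VeryStrong = 8L)

DEFAULT_STRENGTH <- c(PVS = "VeryStrong", PS = "Strong", PM = "Moderate", PP = "Supporting",
                      BA = "VeryStrong", BS = "Strong", BP = "Supporting")

#' Points value of an evidence-code id
#'
#' @param code_id e.g. `"PVS1"`, `"PM2_Supporting"`, `"BP7_Strong"`,
#'   `"PS3_Moderate"`. Vectorised.
#' @return Signed integer points (+ pathogenic, - benign).
#' @export
points_for <- function(code_id) {
  vapply(code_id, function(id) {
    m <- regmatches(id, regexec("^(PVS|PS|PM|PP|BA|BS|BP)([0-9]+)(?:_(Supporting|Moderate|Strong|VeryStrong))?$", id))[[1]]
    if (length(m) == 0L) stop(sprintf("unknown evidence code: '%s'", id), call. = FALSE)
    base <- m[2]
    strength <- if (nzchar(m[4])) m[4] else DEFAULT_STRENGTH[[base]]
    pts <- STRENGTH_POINTS[[strength]]
    if (substr(base, 1, 1) == "B") -pts else pts
  }, integer(1), USE.NAMES = FALSE)
}

#' Five-tier classification thresholds on total points
#'
#' The standard points scale: Pathogenic >= 10, Likely pathogenic 6..9,
#' VUS 0..5, Likely benign -6..-1, Benign <= -7.
#' @export
CLASS_THRESHOLDS <- list(P = 10L, LP = 6L, VUS = 0L, LB = -6L)

points_to_class <- function(points, thresholds = CLASS_THRESHOLDS) {
  if (points >= thresholds$P) "P"
  else if (points >= thresholds$LP) "LP"
  else if (points >= thresholds$VUS) "VUS"
  else if (points >= thresholds$LB) "LB"
  else "B"
}

#' Combine evidence codes into a classification
#'
#' Points are summed (order-invariant, additive); the class is a pure
#' function of the total. An empty code list is VUS with 0 points.
#'
#' @param codes Character vector of evidence-code ids.
#' @param thresholds Class thresholds (see [CLASS_THRESHOLDS]).
#' @return List of class `acmg_classification` with `total_points`,
#'   `klass`, `codes`.
#' @export
classify_codes <- function(codes, thresholds = CLASS_THRESHOLDS) {
  codes <- codes[!is.na(codes) & nzchar(codes)]
  total <- if (length(codes) == 0L) 0L else sum(points_for(codes))
  structure(list(total_points = total, klass = points_to_class(total, thresholds),
                 codes = codes),
            class = "acmg_classification")
}

#' @export
print.acmg_classification <- function(x, ...) {
  cat(sprintf("<acmg_classification> %s (%+d points) [%s]\n", x$klass, x$total_points,
              paste(x$codes, collapse = ", ")))
  invisible(x)
}

#' Load a variant -> evidence-code fixture
#'
#' @param path TSV with columns `variant_hgvs_c` and semicolon-separated `codes`.
#' @return Named list of character vectors.
#' @export
load_evidence_codes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variant_hgvs_c", "codes") %in% names(df)))
  stats::setNames(strsplit(df$codes, ";", fixed = TRUE), df$variant_hgvs_c)
}

#' Shipped TP53 evidence-code fixture (non-RNA codes)
#'
#' Pre-resolved population/clinical/functional codes per variant; the
#' RNA-derived codes (PVS1 (RNA) at the applied weight, BP7 (RNA)_Strong)
#' are computed from the assay results and merged at classification time.
#' @return Named list of character vectors.
#' @export
tp53_evidence_codes <- function() {
  load_evidence_codes(system.file("extdata", "tp53_evidence_codes.tsv",
                                  package = "tp53splice", mustWork = TRUE))
}

PROTEIN_ONLY_CODES <- "^(PS3|BS3|PP3|BP4|BP7)"

#' Classify a dataset of variants with route gating
#'
#' For each variant the applied RNA code (PVS1 (RNA) at its gated weight,
#' or BP7 (RNA)_Strong for synonymous variants with 100% full-length
#' expression) is merged with the variant's pre-resolved codes and
#' classified under the points system. Route gating is enforced: protein
#' functional / computational codes (PS3, BS3, PP3, BP4, BP7) are
#' inconsistent with an applied splicing-route code, and sub-threshold
#' splicing impact (INDETERMINATE route) blocks them too.
#'
#' @param analysis Per-variant analysis table from [analyze_variants()].
#' @param codes Named list: variant -> character vector of non-RNA codes.
#' @param thresholds Points thresholds.
#' @return data.frame with per-variant `codes_applied`, `total_points`,
#'   `klass`, plus attribute `summary` (counts of P/LP, LB/B, VUS and
#'   reclassified by route).
#' @export
classify_dataset <- function(analysis, codes = tp53_evidence_codes(),
                             thresholds = CLASS_THRESHOLDS) {
  rows <- lapply(seq_len(nrow(analysis)), function(i) {
    v <- analysis[i, ]
    rna_code <- if (!is.na(v$applied_code)) v$applied_code else v$bp7_code
    other <- codes[[v$variant]] %||% character(0)
    if (v$route %in% c("SPLICING_ROUTE", "INDETERMINATE") &&
        any(grepl(PROTEIN_ONLY_CODES, other)))
      stop(sprintf("variant %s: protein-level codes applied on the %s route", v$variant, v$route),
           call. = FALSE)
    cl <- classify_codes(c(rna_code[!is.na(rna_code)], other), thresholds)
    data.frame(variant = v$variant, group = v$group, route = v$route,
               codes_applied = paste(cl$codes, collapse = ";"),
               total_points = cl$total_points, klass = cl$klass,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  is_test <- !out$group %in% c("negative_control", "positive_control")
  tst <- out[is_test, ]
  attr(out, "summary") <- list(
    n_test = nrow(tst),
    reclassified = sum(tst$klass != "VUS"),
    p_lp = sum(tst$klass %in% c("P", "LP")),
    lb_b = sum(tst$klass %in% c("LB", "B")),
    vus = sum(tst$klass == "VUS"),
    splicing_route_p_lp = sum(tst$klass %in% c("P", "LP") & tst$route == "SPLICING_ROUTE"),
    protein_route_classified = sum(tst$klass != "VUS" & tst$route == "PROTEIN_ROUTE")
  )
  out
}
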