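#' Quantification settings for fragment-analysis peak data
#'
#' @param rfu_min Minimum peak height (relative fluorescence units) for a
#'   peak to be counted, default 100.
#' @param replicate_count Expected number of semi-quantitative RT-PCR
#'   replicates (triplicates in the assay).
#' @param uncharacterised_negligible_pct Expression level below which
#'   uncharacterised products are regarded as negligible background.
#' @return List of class `quant_config`.
#' @export
quant_config <- function(rfu_min = 100, replicate_count = 3,
                         uncharacterised_negligible_pct = 3.3) {
  stopifnot(rfu_min > 0, replicate_count >= 1)
  structure(list(rfu_min = rfu_min, replicate_count = replicate_count,
                 uncharacterised_negligible_pct = uncharacterised_negligible_pct),
            class = "quant_config")
}

#' Transcript proportions from replicate fragment-analysis peaks
#'
#' Per replicate, peaks whose height is below `rfu_min` are dropped and the
#' remaining peak areas are converted to proportions of the replicate
#' total; the mean and sample (n-1) standard deviation across replicates
#' give each transcript's expression estimate.
#'
#' @param replicates List of replicates; each replicate is a named list (or
#'   data.frame with columns `transcript`, `area`, `height`) mapping a
#'   transcript label to `c(area, height)`.
#' @param cfg A `quant_config`.
#' @return data.frame with `transcript`, `mean_pct`, `sd_pct`.
#' @export
proportions_from_peaks <- function(replicates, cfg = quant_config()) {
  stopifnot(length(replicates) >= 1)
  per_rep <- lapply(replicates, function(rep) {
    if (is.data.frame(rep)) {
      lab <- rep$transcript; area <- rep$area; height <- rep$height
    } else {
      lab <- names(rep)
      area <- vapply(rep, function(p) p[[1]], numeric(1))
      height <- vapply(rep, function(p) p[[2]], numeric(1))
    }
    if (any(area < 0)) stop("negative peak area", call. = FALSE)
    keep <- height >= cfg$rfu_min
    lab <- lab[keep]; area <- area[keep]
    if (length(area) == 0L || sum(area) == 0)
      stop("all peaks filtered out: empty transcript profile", call. = FALSE)
    stats::setNames(100 * area / sum(area), lab)
  })
  labels <- unique(unlist(lapply(per_rep, names)))
  mat <- vapply(per_rep, function(p) {
    v <- stats::setNames(numeric(length(labels)), labels)
    v[names(p)] <- p
    v
  }, numeric(length(labels)))
  mat <- matrix(mat, nrow = length(labels), dimnames = list(labels, NULL))
  data.frame(transcript = labels,
             mean_pct = rowMeans(mat),
             sd_pct = apply(mat, 1, function(x) if (length(x) > 1) stats::sd(x) else 0),
             row.names = NULL)
}

IMPACT_LEVELS <- c("NO_IMPACT", "LT50", "BETWEEN_50_80", "GT80")

impact_category <- function(fl_pct, pvs1_total_pct) {
  if (isTRUE(all.equal(fl_pct, 100))) return("NO_IMPACT")
  if (pvs1_total_pct > 80) return("GT80")
  if (pvs1_total_pct > 50) return("BETWEEN_50_80")
  "LT50"
}

#' Per-variant expression totals and impact category
#'
#' Sums transcript expression by PVS1 (RNA) weight class. Uncharacterised
#' products never count toward the PVS1 total (the assay treats them as
#' irrelevant to function at any level), and neither do transcripts
#' weighted `PVS1_NA`. The impact category uses strict thresholds: totals
#' over 50% / over 80%.
#'
#' @param observations data.frame with one row per transcript: columns
#'   `mean_pct` and `kind_class` in `c("FL","characterised","uncharacterised")`
#'   (see [analyze_variants()] which builds it from parsed tokens).
#' @param weights Character vector parallel to `observations` rows: PVS1
#'   weight per transcript (`"PVS1"`, `"PVS1_Strong"`, `"PVS1_Moderate"`,
#'   `"PVS1_Supporting"`, `"PVS1_NA"`) or NA for FL/uncharacterised rows.
#' @param tolerance Permitted deviation of the expression total from 100
#'   (printed tables round to one decimal).
#' @return List of class `variant_totals`: `fl_pct`, `pvs1_weighted_pct`
#'   (named vector by weight), `pvs1_total_pct`, `na_pct`,
#'   `uncharacterised_pct`, `impact_category`.
#' @export
variant_totals <- function(observations, weights, tolerance = 0.5) {
  stopifnot(nrow(observations) == length(weights))
  total <- sum(observations$mean_pct)
  if (abs(total - 100) > tolerance)
    stop(sprintf("transcript expression sums to %.1f%%, outside 100 +/- %.1f", total, tolerance),
         call. = FALSE)
  kc <- observations$kind_class
  fl <- sum(observations$mean_pct[kc == "FL"])
  unchar <- sum(observations$mean_pct[kc == "uncharacterised"])
  chr <- which(kc == "characterised")
  if (any(is.na(weights[chr])))
    stop("every characterised aberrant transcript needs a PVS1 weight (possibly PVS1_NA)", call. = FALSE)
  w <- weights[chr]
  expr <- observations$mean_pct[chr]
  na_pct <- sum(expr[w == "PVS1_NA"])
  lev <- setdiff(PVS1_WEIGHTS, "PVS1_NA")
  weighted <- vapply(lev, function(L) sum(expr[w == L]), numeric(1))
  pvs1_total <- sum(weighted)
  structure(list(fl_pct = fl,
                 pvs1_weighted_pct = weighted,
                 pvs1_total_pct = pvs1_total,
                 na_pct = na_pct,
                 uncharacterised_pct = unchar,
                 impact_category = impact_category(fl, pvs1_total)),
            class = "variant_totals")
}

#' @export
print.variant_totals <- function(x, ...) {
  cat(sprintf("<variant_totals> FL %.1f%% | PVS1-weighted %.1f%% | NA %.1f%% | uncharacterised %.1f%% -> %s\n",
              x$fl_pct, x$pvs1_total_pct, x$na_pct, x$uncharacterised_pct, x$impact_category))
  invisible(x)
}
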