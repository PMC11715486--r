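## Synthetic minigene-assay data generator.
##
## Variants are simulated with a Gaussian copula coupling the in-silico
## splice score to the aberrant expression fraction; marginals are a
## stitched Beta-mixture quantile (score: mass piled at both extremes, as
## for real splice predictors) and a zero-inflated Beta (aberrant
## fraction: a point mass of splice-neutral variants plus a right-skewed
## aberrant bulk). The latent correlation is calibrated by Monte Carlo so
## that the *output* Pearson correlation between score and PVS1-weighted
## expression matches the requested target: the event grammar, weight
## tiers, uncharacterised products and replicate noise all attenuate the
## latent association, so using the target as latent rho directly would
## systematically undershoot.

#' Configuration for the synthetic assay-data generator
#'
#' @param n_variants Number of test variants to simulate.
#' @param seed RNG seed (required for a reproducible dataset).
#' @param group_mix Named proportions over the three test-variant groups;
#'   defaults mirror a 9/24/26 split of synonymous-outside /
#'   missense-outside / missense-inside variants.
#' @param target_correlation Target Pearson correlation between the splice
#'   score and PVS1-weighted aberrant expression; |target| > 0.99 is not
#'   calibratable and errors here.
#' @param noise_sd_range Range of the per-variant replicate noise standard
#'   deviation, in percentage points (defaults span the spread seen in
#'   triplicate fragment analysis).
#' @param dirichlet_concentration Concentration of the Dirichlet partition
#'   of aberrant expression across a variant's events.
#' @param prob_uncharacterised Probability that an aberrant variant also
#'   expresses one uncharacterised (size-only) product.
#' @param prob_aberrant Probability that a variant expresses any aberrant
#'   transcript at all (zero-inflation complement).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_variants = 59, seed = 1,
                              group_mix = c(synonymous_outside = 9/59,
                                            missense_outside = 24/59,
                                            missense_inside = 26/59),
                              target_correlation = 0.5,
                              noise_sd_range = c(0.1, 8.5),
                              dirichlet_concentration = 1.5,
                              prob_uncharacterised = 0.15,
                              prob_aberrant = 0.73) {
  stopifnot(n_variants >= 0, length(seed) == 1L, is.finite(seed),
            length(group_mix) == 3L,
            all(names(group_mix) %in% c("synonymous_outside", "missense_outside", "missense_inside")),
            abs(sum(group_mix) - 1) < 1e-8,
            length(noise_sd_range) == 2L, noise_sd_range[1] >= 0,
            noise_sd_range[2] >= noise_sd_range[1],
            dirichlet_concentration > 0,
            prob_uncharacterised >= 0, prob_uncharacterised <= 1,
            prob_aberrant > 0, prob_aberrant <= 1)
  if (abs(target_correlation) > 0.99)
    stop("|target_correlation| > 0.99 cannot be calibrated through the generative noise",
         call. = FALSE)
  structure(list(n_variants = as.integer(n_variants), seed = as.integer(seed),
                 group_mix = group_mix, target_correlation = target_correlation,
                 noise_sd_range = noise_sd_range,
                 dirichlet_concentration = dirichlet_concentration,
                 prob_uncharacterised = prob_uncharacterised,
                 prob_aberrant = prob_aberrant),
            class = "simulation_config")
}

#' Full-coverage synthetic region-tier map
#'
#' Tier bands covering every p53 codon, so any in-frame synthetic event is
#' weightable (the curated map shipped for the real assay intentionally
#' covers only regions evidenced there).
#' @return `region_tiers` data.frame.
#' @export
synthetic_region_tiers <- function() {
  tiers <- data.frame(
    codon_start = c(1L, 51L, 181L, 221L, 261L, 301L),
    codon_end   = c(50L, 180L, 220L, 260L, 300L, 393L),
    tier = c("FUNCTIONAL_DAMAGING", "PATHOGENIC_MISSENSE", "BIOINFORMATIC_DAMAGING",
             "PATHOGENIC_MISSENSE", "BENIGN_PREDICTED", "FUNCTIONAL_DAMAGING"),
    stringsAsFactors = FALSE
  )
  class(tiers) <- c("region_tiers", "data.frame")
  tiers
}

## ---- marginals ------------------------------------------------------------

# stitched Beta-mixture quantile for the splice score: three Beta segments
# over [0,0.2), [0.2,0.5), [0.5,1] carrying 55% / 20% / 25% of the mass
score_quantile <- function(u) {
  breaks <- c(0, 0.55, 0.75, 1)
  lo <- c(0, 0.2, 0.5); hi <- c(0.2, 0.5, 1)
  a <- c(1.3, 1.0, 0.8); b <- c(2.5, 1.0, 0.8)
  seg <- findInterval(u, breaks, rightmost.closed = TRUE)
  v <- (u - breaks[seg]) / (breaks[seg + 1] - breaks[seg])
  lo[seg] + (hi[seg] - lo[seg]) * stats::qbeta(v, a[seg], b[seg])
}

# zero-inflated Beta quantile for the aberrant expression fraction
aberrant_fraction_quantile <- function(u, prob_aberrant) {
  p0 <- 1 - prob_aberrant
  ifelse(u <= p0, 0, stats::qbeta((u - p0) / (1 - p0), 0.9, 0.5))
}

## ---- event grammar --------------------------------------------------------

# sample one characterised event consistent with the gene model; returns a
# splice_event; acceptor-side partial exon deletions use K >= 2 so a
# perfect record never collides with the native acceptor
sample_event <- function(model) {
  kind <- sample(c("EXON_SKIP", "PARTIAL_EXON_DEL_DONOR_SIDE",
                   "PARTIAL_EXON_DEL_ACCEPTOR_SIDE", "INTRON_RETENTION",
                   "PARTIAL_INTRON_RETENTION_DONOR_SIDE",
                   "PARTIAL_INTRON_RETENTION_ACCEPTOR_SIDE"),
                 1, prob = c(0.35, 0.2, 0.1, 0.1, 0.15, 0.1))
  if (kind == "INTRON_RETENTION") {
    # only introns annotated with an in-frame stop are frame-resolvable
    iid <- sample(c("5", "6", "7"), 1)
    return(new_splice_event("INTRON_RETENTION", target_id = iid))
  }
  exon <- sample(3:8, 1)
  exlen <- exon_length(model, exon)
  switch(kind,
    EXON_SKIP = new_splice_event("EXON_SKIP", target_id = exon, length_nt = exlen),
    PARTIAL_EXON_DEL_DONOR_SIDE =
      new_splice_event(kind, target_id = exon, length_nt = sample(seq_len(exlen - 1L), 1)),
    PARTIAL_EXON_DEL_ACCEPTOR_SIDE =
      new_splice_event(kind, target_id = exon, length_nt = sample(2:(exlen - 1L), 1)),
    PARTIAL_INTRON_RETENTION_DONOR_SIDE =
      new_splice_event(kind, target_id = exon, length_nt = sample(1:80, 1)),
    PARTIAL_INTRON_RETENTION_ACCEPTOR_SIDE =
      new_splice_event(kind, target_id = exon, length_nt = sample(1:80, 1))
  )
}

# exonic cDNA position from which a perfect SpliceAI record can encode the
# event (mid-exon of the event's exon; upstream exon for intron retention)
anchor_position <- function(event, model) {
  ex_id <- if (event$kind == "INTRON_RETENTION")
    as.integer(sub("-mg$", "", event$target_id)) else event$target_id
  e <- exon_row(model, ex_id)
  as.integer(floor((e$cdna_start + e$cdna_end) / 2))
}

## ---- generative core ------------------------------------------------------

rdirichlet1 <- function(m, conc) {
  g <- stats::rgamma(m, shape = conc)
  if (sum(g) == 0) g <- rep(1, m)
  g / sum(g)
}

# simulate n variants at latent correlation rho; returns the long dataset
# rows plus per-variant truth (score, pvs1_total, events)
synth_core <- function(n, rho, cfg, model, tiers, sidecar = TRUE) {
  groups <- rep(names(cfg$group_mix), diff(round(cumsum(c(0, cfg$group_mix)) * n)))
  if (length(groups) < n) groups <- c(groups, rep(names(cfg$group_mix)[which.max(cfg$group_mix)],
                                                  n - length(groups)))
  rows <- vector("list", n)
  truth <- vector("list", n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    z1 <- stats::rnorm(1)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
    score <- round(score_quantile(stats::pnorm(z1)), 2)
    frac <- aberrant_fraction_quantile(stats::pnorm(z2), cfg$prob_aberrant)

    events <- list(); weights <- character(0); frames <- character(0)
    unchar_pct <- 0
    if (frac > 0) {
      m <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
      shares <- rdirichlet1(m, cfg$dirichlet_concentration) * frac * 100
      for (j in seq_len(m)) {
        repeat {
          ev <- sample_event(model)
          if (!any(vapply(events, function(e) identical(event_token(e), event_token(ev)),
                          logical(1)))) break
        }
        events <- c(events, list(ev))
        fc <- classify_frame(ev, model)
        frames <- c(frames, fc$frame)
        weights <- c(weights, assign_pvs1_weight(ev, fc, tiers, model))
      }
      if (stats::runif(1) < cfg$prob_uncharacterised) {
        cut <- stats::runif(1, 0.05, 0.4)
        unchar_pct <- sum(shares) * cut
        shares <- shares * (1 - cut)
      }
    } else shares <- numeric(0)

    props <- c(100 * (1 - (if (frac > 0) frac else 0)), shares, if (unchar_pct > 0) unchar_pct)
    labels <- c("FL", vapply(events, event_token, character(1)),
                if (unchar_pct > 0) sprintf("%d-nt", sample(300:1100, 1)))

    # triplicate replicate noise, truncated at zero, renormalized to 100
    sd_i <- stats::runif(1, cfg$noise_sd_range[1], cfg$noise_sd_range[2])
    reps <- vapply(1:3, function(r) {
      x <- pmax(props + stats::rnorm(length(props), 0, sd_i), 0)
      if (sum(x) == 0) x <- props
      100 * x / sum(x)
    }, numeric(length(props)))
    reps <- matrix(reps, nrow = length(props))
    mean_pct <- rowMeans(reps)
    sd_pct <- apply(reps, 1, stats::sd)

    vid <- sprintf("SYN-%04d", i)
    is_ab <- labels != "FL" & !grepl("-nt$", labels)
    rows[[i]] <- data.frame(
      variant_hgvs_c = vid, protein_hgvs_p = NA_character_, group = groups[i],
      mes_mode = "native_loss",
      mes_category = if (score >= 0.5) "HIGH" else if (score >= 0.2) "MODERATE" else "LOW",
      spliceai_max = score, transcript_token = labels,
      mean_pct = mean_pct, sd_pct = sd_pct,
      frame_column = c(NA_character_, frames, if (unchar_pct > 0) NA_character_)[seq_along(labels)],
      assigned_weight = c(NA_character_, weights, if (unchar_pct > 0) NA_character_)[seq_along(labels)],
      stringsAsFactors = FALSE
    )
    pvs1_total <- sum(mean_pct[is_ab][weights != "PVS1_NA"])
    truth[[i]] <- list(variant = vid, score = score, aberrant_fraction = frac,
                       events = events, weights = weights, frames = frames,
                       pvs1_total_pct = pvs1_total, noise_sd = sd_i)
    if (sidecar && length(events) > 0) {
      dom <- which.max(mean_pct[is_ab])
      ev <- events[[dom]]
      pos <- anchor_position(ev, model)
      records[[i]] <- list(variant = vid, cdna_pos = pos, event = ev,
                           record = perfect_spliceai_record(ev, pos, model,
                                                            delta = min(max(score, 0.25), 1)))
    }
  }
  list(rows = do.call(rbind, rows), truth = truth,
       records = Filter(Negate(is.null), records))
}

## ---- latent-rho calibration ----------------------------------------------

.calib_cache <- new.env(parent = emptyenv())

# run fn with an isolated, fixed-seed RNG stream; the caller's stream is
# untouched so memoization cannot change downstream draws
with_isolated_rng <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

output_correlation_at <- function(rho, cfg, model, tiers, n_mc = 3000L) {
  with_isolated_rng(990017L, function() {
    sim <- synth_core(n_mc, rho, cfg, model, tiers, sidecar = FALSE)
    scores <- vapply(sim$truth, `[[`, numeric(1), "score")
    totals <- vapply(sim$truth, `[[`, numeric(1), "pvs1_total_pct")
    stats::cor(scores, totals)
  })
}

#' Calibrate the latent copula correlation for a target output correlation
#'
#' Monte Carlo inversion: the generative pipeline (event grammar, weight
#' tiers, uncharacterised products, replicate noise) attenuates the latent
#' Gaussian-copula correlation, so the latent value solving
#' `cor(score, pvs1_total) = target` is found by root search over a fixed
#' internal simulation stream. Results are memoized per configuration.
#'
#' @param cfg A `simulation_config`.
#' @param model,tiers Gene model and tier map used by the generator.
#' @param n_mc Monte Carlo size per root-search evaluation.
#' @return Latent correlation in (-1, 1).
#' @export
calibrate_latent_rho <- function(cfg, model = tp53_gene_model(),
                                 tiers = synthetic_region_tiers(), n_mc = 3000L) {
  target <- cfg$target_correlation
  if (abs(target) < 1e-9) return(0)
  key <- paste(target, cfg$dirichlet_concentration, cfg$prob_uncharacterised,
               cfg$prob_aberrant, paste(cfg$noise_sd_range, collapse = ","), n_mc, sep = "|")
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  s <- sign(target)
  f <- function(r) output_correlation_at(s * r, cfg, model, tiers, n_mc) - s * target
  hi <- 0.995
  if (f(hi) < 0)
    stop(sprintf("target correlation %.3f exceeds what the generative noise allows", target),
         call. = FALSE)
  rho <- s * stats::uniroot(f, c(1e-4, hi), tol = 5e-3)$root
  .calib_cache[[key]] <- rho
  rho
}

#' Generate a synthetic minigene assay dataset
#'
#' Deterministic given the config seed. The returned long table has the
#' assay-fixture schema (one row per transcript) and can be fed directly
#' to [analyze_variants()]. Attributes carry the config, the per-variant
#' generative truth and a sidecar of "perfect" SpliceAI records that
#' exactly encode each variant's dominant event (a self-consistency oracle
#' for [predict_aberrations()]).
#'
#' @param cfg A `simulation_config`.
#' @param model A `gene_model`.
#' @param tiers A full-coverage `region_tiers` map.
#' @return `assay_dataset` data.frame with attributes `config`, `truth`,
#'   `spliceai_sidecar`.
#' @export
generate_dataset <- function(cfg = simulation_config(), model = tp53_gene_model(),
                             tiers = synthetic_region_tiers()) {
  stopifnot(inherits(cfg, "simulation_config"))
  rho <- calibrate_latent_rho(cfg, model, tiers)
  empty <- data.frame(variant_hgvs_c = character(0), protein_hgvs_p = character(0),
                      group = character(0), mes_mode = character(0),
                      mes_category = character(0), spliceai_max = numeric(0),
                      transcript_token = character(0), mean_pct = numeric(0),
                      sd_pct = numeric(0), frame_column = character(0),
                      assigned_weight = character(0), stringsAsFactors = FALSE)
  if (cfg$n_variants == 0L) {
    out <- empty
  } else {
    set.seed(cfg$seed)
    sim <- synth_core(cfg$n_variants, rho, cfg, model, tiers, sidecar = TRUE)
    out <- sim$rows
  }
  attr(out, "config") <- cfg
  attr(out, "latent_rho") <- rho
  attr(out, "truth") <- if (cfg$n_variants > 0L) sim$truth else list()
  attr(out, "spliceai_sidecar") <- if (cfg$n_variants > 0L) sim$records else list()
  class(out) <- c("assay_dataset", "data.frame")
  out
}
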