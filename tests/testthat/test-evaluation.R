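test_that("the group summary reproduces the published per-group outcome counts", {
  gs <- summarize_groups(ANALYSIS)
  syn <- gs[gs$group == "synonymous_outside", ]
  expect_equal(unlist(syn[, c("n", "fl100", "aberrant", "pvs1_any", "gt50", "gt80")],
                      use.names = FALSE), c(9, 4, 5, 5, 1, 0))
  tot <- gs[gs$group == "total", ]
  expect_equal(unlist(tot[, c("n", "pvs1_any", "gt50", "gt80")], use.names = FALSE),
               c(59, 42, 26, 15))

  # For the splice-dinucleotide controls, one variant (c.783-1G>A) expresses
  # half its aberrant product as a PVS1_NA junction insertion, leaving 49.8%
  # of PVS1-weighted expression, so it misses the strict >50/>80 thresholds.
  gs_all <- summarize_groups(ANALYSIS, include_controls = TRUE)
  pc <- gs_all[gs_all$group == "positive_control", ]
  expect_equal(unlist(pc[, c("n", "aberrant", "pvs1_any", "gt50", "gt80")],
                      use.names = FALSE), c(8, 8, 8, 7, 7))
})

test_that("the predictor cross-tab reproduces the published cells after the stated exclusions", {
  ct <- predictor_crosstab(ANALYSIS)
  sai <- ct$SPLICEAI_VCEP
  # 5 variants with aberrant but PVS1-unweightable products are excluded,
  # 3 intermediate scores (0.1, 0.2) are excluded from the score columns
  expect_equal(sai$n, 51)
  expect_equal(unname(sai$counts["NO_IMPACT", "negative"]), 4)
  expect_equal(unname(sai$pct["NO_IMPACT", "negative"]), 80)
  expect_equal(unname(sai$counts["GT80", "positive"]), 15)
  expect_equal(unname(sai$pct["GT80", "positive"]), 32.6)
  expect_equal(sum(sai$counts[, "positive"]), 46)
  # MES: the single MODERATE variant is excluded
  expect_equal(ct$MES$n, 53)
  expect_equal(unname(ct$MES$counts["GT80", "positive"]), 11)
})

test_that("the score/expression Pearson correlation matches a brute-force oracle and the published value", {
  co <- score_expression_correlation(ANALYSIS)
  expect_equal(co$n, 59)
  expect_equal(co$r, 0.50, tolerance = 0.02 / 0.50)
  x <- co$score; y <- co$expression
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(co$r, brute, tolerance = 1e-12)
})

test_that("aberrant expression differs across score bins (omnibus and pairwise)", {
  bt <- bin_comparison_tests(ANALYSIS)
  expect_equal(nlevels(bt$bins), 4)
  expect_lt(bt$kruskal$p.value, 0.001)
  # the lowest bin differs from every higher bin after Holm adjustment
  pw <- bt$pairwise$p.value
  expect_true(all(pw[, "[0,0.2)"] < 0.05, na.rm = TRUE))
})

test_that("empty score bins are dropped with a warning, not an error", {
  sub <- ANALYSIS[ANALYSIS$spliceai_max < 0.5, ]
  expect_warning(bt <- bin_comparison_tests(sub), "empty score bins")
  expect_lt(nlevels(bt$bins), 4)
})

test_that("concordance is scored per expression level and splice-region stratum", {
  # one variant inside the splice region with a matching intron-retention
  # prediction, one outside with no prediction at all
  a <- ANALYSIS[ANALYSIS$variant %in% c("c.782G>C", "c.879G>T"), ]
  preds <- list(
    `c.782G>C` = predict_aberrations(
      perfect_spliceai_record(ev1("ins(I7)"), 700, MODEL), 700, MODEL),
    `c.879G>T` = list()
  )
  cb <- concordance_by_level(a, preds, FIXTURE, MODEL, levels = 5)
  inside <- cb[cb$stratum == "inside", ]
  outside <- cb[cb$stratum == "outside", ]
  expect_equal(inside$n, 1)
  expect_equal(inside$concordant, 1)
  expect_equal(outside$n, 1)
  expect_equal(outside$concordant, 0)
})
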