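test_that("score bins respect the inclusive 0.1 / 0.2 / 0.5 cutoffs", {
  expect_equal(as.character(bin_spliceai(c(0, 0.1, 0.15, 0.2, 0.49, 0.5, 1))),
               c("LE_0_1", "LE_0_1", "BETWEEN_0_1_0_2", "GE_0_2_LT_0_5",
                 "GE_0_2_LT_0_5", "GE_0_5", "GE_0_5"))
  expect_error(bin_spliceai(1.2), "out of")
  expect_error(bin_spliceai(NA), "out of")
})

test_that("paired donor+acceptor loss predicts skipping of the shared exon", {
  # variant inside exon 5 (c.376-559): both native sites of exon 5 lost
  rec <- spliceai_record(ds_dl = 0.9, dp_dl = 559 - 500, ds_al = 0.8, dp_al = 376 - 500)
  pred <- predict_aberrations(rec, 500, MODEL)
  expect_length(pred, 1)
  expect_equal(pred[[1]]$kind, "EXON_SKIP")
  expect_equal(pred[[1]]$target_id, 5)
  expect_equal(pred[[1]]$length_nt, 184L)
})

test_that("an unpaired donor (acceptor) loss predicts retention of the adjacent intron", {
  rec <- spliceai_record(ds_dl = 0.7, dp_dl = 672 - 600)   # exon 6 donor lost
  pred <- predict_aberrations(rec, 600, MODEL)
  expect_equal(pred[[1]]$kind, "INTRON_RETENTION")
  expect_equal(pred[[1]]$target_id, "6")
  rec2 <- spliceai_record(ds_al = 0.7, dp_al = 560 - 600)  # exon 6 acceptor lost
  pred2 <- predict_aberrations(rec2, 600, MODEL)
  expect_equal(pred2[[1]]$kind, "INTRON_RETENTION")
  expect_equal(pred2[[1]]$target_id, "5")
})

test_that("gain positions split partial-exon deletions from partial-intron retentions", {
  # donor gain 46 nt inside exon 5 from c.513
  rec <- spliceai_record(ds_dg = 0.9, dp_dg = 0)
  pred <- predict_aberrations(rec, 513, MODEL)
  expect_equal(pred[[1]]$kind, "PARTIAL_EXON_DEL_DONOR_SIDE")
  expect_equal(pred[[1]]$target_id, 5)
  expect_equal(pred[[1]]$length_nt, 559L - 513L)
  # donor gain 5 nt into the intron downstream of exon 6
  rec2 <- spliceai_record(ds_dg = 0.9, dp_dg = (672 + 5) - 650)
  pred2 <- predict_aberrations(rec2, 650, MODEL)
  expect_equal(pred2[[1]]$kind, "PARTIAL_INTRON_RETENTION_DONOR_SIDE")
  expect_equal(pred2[[1]]$length_nt, 5L)
  # acceptor gain inside exon 8: acceptor-side partial deletion
  rec3 <- spliceai_record(ds_ag = 0.9, dp_ag = (783 + 23) - 850)
  pred3 <- predict_aberrations(rec3, 850, MODEL)
  expect_equal(pred3[[1]]$kind, "PARTIAL_EXON_DEL_ACCEPTOR_SIDE")
  expect_equal(pred3[[1]]$length_nt, 24L)
  # sub-threshold deltas predict nothing
  expect_length(predict_aberrations(spliceai_record(ds_dg = 0.19, dp_dg = 0), 513, MODEL), 0)
})

test_that("competition flags annotate but never suppress a gain prediction", {
  expect_true(competition_flag(0.3, 0.6))
  expect_false(competition_flag(0.5, 0.6))
  expect_true(is.na(competition_flag(0.5, NA)))
  # native donor of exon 5 out-competes the cryptic site by > 0.2
  rec <- spliceai_record(ds_dg = 0.9, dp_dg = 0,
                         alt_scores = c(`0` = 0.3, `46` = 0.8))  # native at 559, offset 46 from c.513
  pred <- predict_aberrations(rec, 513, MODEL)
  expect_length(pred, 1)
  expect_true(pred[[1]]$competition_flagged)
})

test_that("concordance matching requires kind, target and (for partial events) exact length", {
  pred <- list(structure(list(kind = "EXON_SKIP", target_id = 5, length_nt = 184L,
                              competition_flagged = NA, source = "DL+AL"),
                         class = "predicted_aberration"))
  obs <- data.frame(token = c("FL", "del(E5)"), mean_pct = c(40, 60))
  expect_true(match_concordance(pred, obs, MODEL))
  # below the expression floor the observation does not count
  obs_low <- data.frame(token = c("FL", "del(E5)"), mean_pct = c(98, 2))
  expect_false(match_concordance(pred, obs_low, MODEL))
  # wrong exon, wrong kind, or wrong partial length all fail
  expect_false(match_concordance(pred, data.frame(token = "del(E6)", mean_pct = 100), MODEL))
  pp <- list(structure(list(kind = "PARTIAL_EXON_DEL_DONOR_SIDE", target_id = 5, length_nt = 46L,
                            competition_flagged = NA, source = "DG"),
                       class = "predicted_aberration"))
  expect_true(match_concordance(pp, data.frame(token = "del(E5q46)", mean_pct = 100), MODEL))
  expect_false(match_concordance(pp, data.frame(token = "del(E5q45)", mean_pct = 100), MODEL))
  expect_false(match_concordance(list(), obs, MODEL))
})

test_that("perfect records round-trip through the prediction rules for every encodable event kind", {
  cases <- list(list("del(E5)", 450), list("ins(I6)", 600), list("del(E5q46)", 400),
                list("del(E8p24)", 850), list("ins(E6q5)", 600), list("ins(E8p3)", 850))
  for (cs in cases) {
    ev <- ev1(cs[[1]])
    rec <- perfect_spliceai_record(ev, cs[[2]], MODEL)
    pred <- predict_aberrations(rec, cs[[2]], MODEL)
    expect_true(match_concordance(pred, list(list(events = list(ev), mean_pct = 100)), MODEL),
                info = cs[[1]])
  }
})
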