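test_that("PTC transcripts take the full PVS1 weight; in-frame events take the strongest overlapping tier", {
  w <- function(token) {
    evs <- parse_events(token, MODEL)
    assign_pvs1_weight(evs, classify_frame(evs, MODEL), TIERS, MODEL)
  }
  expect_equal(w("del(E5)"), "PVS1")              # frameshift
  expect_equal(w("ins(I7)"), "PVS1")              # retained in-frame stop
  expect_equal(w("del(E4)"), "PVS1")              # in-frame, pathogenic-missense region
  expect_equal(w("del(E4q171)"), "PVS1_Strong")   # in-frame, functional-damaging region
  expect_equal(w("del(E5q9)"), "PVS1_Supporting") # in-frame, bioinformatic-only region
  expect_equal(w("ins(E8p3)"), "PVS1_NA")         # benign-predicted junction
  expect_equal(w("del(E9p3)"), "PVS1_NA")
  expect_equal(w("del(E8p24)"), "PVS1_Strong")
  expect_equal(w("del(E8p54)"), "PVS1")

  # a configurable rule table can down-weight PTC products
  evs <- parse_events("del(E5)", MODEL)
  expect_equal(assign_pvs1_weight(evs, classify_frame(evs, MODEL), TIERS, MODEL,
                                  ptc_weight = "PVS1_Strong"), "PVS1_Strong")
})

test_that("an in-frame event outside every annotated region is an error, never a default", {
  empty <- TIERS[0, ]
  evs <- parse_events("del(E4)", MODEL)
  expect_error(assign_pvs1_weight(evs, classify_frame(evs, MODEL), empty, MODEL),
               class = "unannotated_region")
})

test_that("recomputed frames and weights agree with the published assignment for every fixture transcript", {
  tc <- transcript_calls(FIXTURE)
  expect_gt(nrow(tc), 70)
  expect_equal(unname(c(IN_FRAME = "inframe", PTC = "PTC")[tc$frame]), tc$printed_frame)
  expect_equal(tc$weight, tc$printed_weight)
})

test_that("the applied variant code is gated at cumulative expression strictly above 80%", {
  mk <- function(w, e) {
    obs <- data.frame(mean_pct = c(100 - sum(e), e),
                      kind_class = c("FL", rep("characterised", length(e))))
    applied_variant_code(variant_totals(obs, c(NA, w)))
  }
  expect_equal(mk("PVS1", 81)$code, "PVS1")
  expect_true(is.na(mk("PVS1", 80)$code))                    # boundary is strict
  expect_true(is.na(mk("PVS1", 79.9)$code))
  # weights accumulate from strongest: 45% PVS1 + 40% Strong crosses at Strong
  a <- mk(c("PVS1", "PVS1_Strong"), c(45, 40))
  expect_equal(a$code, "PVS1_Strong")
  expect_equal(a$supporting_expression_pct, 85)
  # PVS1_NA expression never contributes
  expect_true(is.na(mk(c("PVS1", "PVS1_NA"), c(45, 45))$code))
})

test_that("exactly the fifteen >80% test variants carry an applied PVS1-type code", {
  gated <- TEST_ROWS$variant[!is.na(TEST_ROWS$applied_code)]
  expect_length(gated, 15)
  expect_setequal(gated, TEST_ROWS$variant[TEST_ROWS$pvs1_total_pct > 80])
})

test_that("BP7 (RNA)_Strong applies only to synonymous variants with 100% full-length expression", {
  expect_equal(bp7_rna("synonymous", 100), "BP7_Strong")
  expect_true(is.na(bp7_rna("synonymous", 99.9)))
  expect_true(is.na(bp7_rna("missense", 100)))
  syn_bp7 <- TEST_ROWS[TEST_ROWS$group == "synonymous_outside" & !is.na(TEST_ROWS$bp7_code), ]
  expect_equal(nrow(syn_bp7), 4)
  expect_true(all(syn_bp7$fl_pct == 100))
})

test_that("the route gate separates splicing, protein and indeterminate variants", {
  mk_tot <- function(w, e) {
    obs <- data.frame(mean_pct = c(100 - sum(e), e),
                      kind_class = c("FL", rep("characterised", length(e))))
    variant_totals(obs, c(NA, w))
  }
  expect_equal(route_gate(mk_tot("PVS1", 90)), "SPLICING_ROUTE")
  expect_equal(route_gate(mk_tot("PVS1_NA", 90)), "PROTEIN_ROUTE")
  expect_equal(route_gate(mk_tot("PVS1", 40)), "INDETERMINATE")
  fl_only <- variant_totals(data.frame(mean_pct = 100, kind_class = "FL"), NA_character_)
  expect_equal(route_gate(fl_only), "PROTEIN_ROUTE")
})
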