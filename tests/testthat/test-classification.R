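test_that("evidence-code points honour base prefixes and strength suffixes", {
  expect_equal(points_for(c("PVS1", "PS3", "PM2", "PP4")), c(8L, 4L, 2L, 1L))
  expect_equal(points_for(c("BS3", "BP4", "BA1")), c(-4L, -1L, -8L))
  expect_equal(points_for("PVS1_Strong"), 4L)
  expect_equal(points_for("PM2_Supporting"), 1L)
  expect_equal(points_for("PP3_Moderate"), 2L)
  expect_equal(points_for("BP7_Strong"), -4L)
  expect_equal(points_for("BP4_Moderate"), -2L)
  expect_error(points_for("XYZ"), "unknown evidence code")
})

test_that("points map to classes at the published boundaries", {
  cases <- c(`5` = "VUS", `6` = "LP", `9` = "LP", `10` = "P",
             `-1` = "LB", `-6` = "LB", `-7` = "B", `0` = "VUS")
  for (p in names(cases))
    expect_equal(points_to_class(as.integer(p)), unname(cases[p]), info = p)
  expect_equal(classify_codes(character(0))$klass, "VUS")
  expect_equal(classify_codes(character(0))$total_points, 0L)
})

test_that("code combination is additive and order-invariant", {
  a <- classify_codes(c("PVS1_Strong", "PM2_Supporting"))
  b <- classify_codes(c("PM2_Supporting", "PVS1_Strong"))
  expect_equal(a$total_points, 5L)
  expect_equal(a$klass, "VUS")
  expect_equal(a$total_points, b$total_points)
})

test_that("the full classification run reproduces every published code-set -> class pair", {
  cl <- classify_dataset(ANALYSIS)
  got <- stats::setNames(cl$klass, cl$variant)
  lp <- c("c.782G>C", "c.782G>T", "c.672G>C", "c.672G>T", "c.671A>C", "c.671A>T",
          "c.559G>A", "c.559G>C", "c.410T>A", "c.318C>G", "c.178C>A", "c.50A>T",
          "c.811G>A", "c.797G>T", "c.374C>G", "c.325T>A")
  p <- c("c.356C>G", "c.182A>G", "c.817C>A")
  lb <- c("c.919G>T", "c.781A>C", "c.781A>G", "c.673G>C",
          "c.837G>C", "c.837G>T", "c.816G>A", "c.114A>G")
  for (v in lp) expect_equal(unname(got[v]), "LP", info = v)
  for (v in p) expect_equal(unname(got[v]), "P", info = v)
  for (v in lb) expect_equal(unname(got[v]), "LB", info = v)
  expect_equal(unname(got["c.314G>T"]), "VUS")
  expect_equal(cl$total_points[cl$variant == "c.314G>T"], 5L)
  expect_equal(cl$codes_applied[cl$variant == "c.314G>T"], "PVS1_Strong;PM2_Supporting")
})

test_that("dataset-level classification counts match the published totals", {
  cl <- classify_dataset(ANALYSIS)
  s <- attr(cl, "summary")
  expect_equal(s$n_test, 59L)
  expect_equal(s$reclassified, 27L)
  expect_gte(s$splicing_route_p_lp, 14L)
  expect_equal(s$protein_route_classified, 13L)
  expect_equal(s$p_lp + s$lb_b, s$reclassified)
})

test_that("protein-level codes are rejected on splicing or indeterminate routes", {
  a <- ANALYSIS[ANALYSIS$variant == "c.782G>C", ]  # splicing route
  expect_error(classify_dataset(a, codes = list(`c.782G>C` = c("PS3", "PM2_Supporting"))),
               "protein-level codes")
  ind <- ANALYSIS[ANALYSIS$route == "INDETERMINATE", ][1, ]
  bad <- stats::setNames(list("BP4"), ind$variant)
  expect_error(classify_dataset(ind, codes = bad), "protein-level codes")
})

test_that("classification with no evidence codes leaves every variant a VUS", {
  cl <- classify_dataset(ANALYSIS[ANALYSIS$route == "PROTEIN_ROUTE" &
                                    ANALYSIS$group == "missense_outside", ][1:3, ],
                         codes = list())
  expect_true(all(cl$klass == "VUS"))
})
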