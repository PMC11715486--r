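test_that("event tokens parse across both dialects and round-trip", {
  for (pair in list(c("Δ(E5)", "del(E5)"),
                    c("△(E4q171)", "del(E4q171)"),
                    c("▼(I7)", "ins(I7)"),
                    c("▼(E6q5)", "ins(E6q5)"),
                    c("▼(E8p3)", "ins(E8p3)"),
                    c("Δ(E5p21)", "del(E5p21)"))) {
    a <- parse_event(pair[1], MODEL)
    b <- parse_event(pair[2], MODEL)
    expect_equal(a$kind, b$kind)
    expect_equal(a$target_id, b$target_id)
    expect_equal(a$length_nt, b$length_nt)
    # canonical serialization re-parses to the same event
    expect_equal(parse_event(event_token(a), MODEL)$kind, a$kind)
  }
  expect_equal(parse_event("FL", MODEL)$kind, "FULL_LENGTH")
  un <- parse_event("955-nt", MODEL)
  expect_equal(un$kind, "UNCHARACTERISED")
  expect_equal(un$product_size_nt, 955L)
})

test_that("malformed or model-inconsistent tokens are rejected", {
  expect_error(parse_event("del(X5)", MODEL), "malformed")
  expect_error(parse_event("del(I5)", MODEL), "retained")
  expect_error(parse_event("ins(E5)", MODEL), "malformed")
  expect_error(parse_event("del(E5q999)", MODEL), "only")
  expect_error(parse_event("del(E12)", MODEL), "not in gene model")
  expect_error(parse_events("del(E4)garbage", MODEL), "malformed")
  expect_error(parse_events("del(E4q16)xdel(E5)", MODEL), "malformed compound")
})

test_that("compound tokens split into their component events", {
  evs <- parse_events("del(E4q16)del(E5)", MODEL)
  expect_length(evs, 2)
  expect_equal(evs[[1]]$kind, "PARTIAL_EXON_DEL_DONOR_SIDE")
  expect_equal(evs[[2]]$kind, "EXON_SKIP")
  # net change -16 - 184 = -200, not divisible by 3 -> PTC
  expect_equal(length_change(evs, MODEL), -200)
  expect_equal(classify_frame(evs, MODEL)$frame, "PTC")
})

test_that("length change signs and magnitudes follow the gene model", {
  expect_equal(length_change(ev1("del(E5)"), MODEL), -184)
  expect_equal(length_change(ev1("del(E4q171)"), MODEL), -171)
  expect_equal(length_change(ev1("ins(E6q5)"), MODEL), 5)
  expect_equal(length_change(ev1("ins(E8p3)"), MODEL), 3)
  # unannotated intron length is an explicit condition, not a guess
  expect_error(length_change(ev1("ins(I7)"), MODEL), class = "unknown_length")
})

test_that("frame classification: mod-3 arithmetic and retained-stop annotation", {
  expect_equal(classify_frame(ev1("del(E5)"), MODEL)$frame, "PTC")       # 184 nt
  expect_equal(classify_frame(ev1("del(E6)"), MODEL)$frame, "PTC")       # 113 nt
  expect_equal(classify_frame(ev1("del(E4)"), MODEL)$frame, "IN_FRAME")  # 279 nt
  expect_equal(classify_frame(ev1("del(E4q171)"), MODEL)$frame, "IN_FRAME")
  expect_equal(classify_frame(ev1("ins(E8p3)"), MODEL)$frame, "IN_FRAME")
  # intron 7 retention: length unknown but an in-frame stop is annotated
  expect_equal(classify_frame(ev1("ins(I7)"), MODEL)$frame, "PTC")
  # intron without stop annotation and without length: undetermined
  expect_error(classify_frame(ev1("ins(I3)"), MODEL), class = "frame_undetermined")
  expect_error(classify_frame(ev1("FL"), MODEL), "characterised")
})

test_that("in-frame protein consequences name codon-aligned deletions from the model", {
  pc <- protein_consequence(ev1("del(E4)"), MODEL)  # c.97-375 = codons 33-125
  expect_equal(pc$notation, "p.Ser33_Thr125del")
  expect_equal(pc$kind, "del")
  pc2 <- protein_consequence(ev1("del(E4q171)"), MODEL)  # c.205-375 = codons 69-125
  expect_equal(pc2$notation, "p.Ala69_Thr125del")
  # junction events fall back to the model's annotated notation
  pc3 <- protein_consequence(ev1("ins(E8p3)"), MODEL)
  expect_equal(pc3$notation, "p.Ser261_Gly262insSer")
  pc4 <- protein_consequence(ev1("del(E9p3)"), MODEL)
  expect_equal(pc4$notation, "p.Ala307_Leu308delinsVal")
  expect_error(protein_consequence(ev1("del(E5)"), MODEL), "in-frame")
})
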