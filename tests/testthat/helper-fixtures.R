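# Shared fixtures, built once per test session
MODEL <- tp53_gene_model()
TIERS <- tp53_region_tiers()
FIXTURE <- tp53_assay_fixture()
ANALYSIS <- analyze_variants(FIXTURE)
TEST_ROWS <- ANALYSIS[!ANALYSIS$group %in% c("negative_control", "positive_control"), ]

ev1 <- function(token) parse_events(token, MODEL)[[1]]
arow <- function(v) ANALYSIS[ANALYSIS$variant == v, ]
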