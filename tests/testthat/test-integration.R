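pos_interp <- function() classify_fish(fish_observation(c(R1G1F1 = 62), 200))
del3_interp <- function() classify_fish(fish_observation(c(R1F1 = 104), 200))
norm_interp <- function() classify_fish(fish_observation(integer(), 200))

test_that("concordance applies the RT-PCR sensitivity equivalence rule", {
  expect_equal(concordance(pos_interp(), rtpcr_result(FALSE)),
               "discordant_fish_pos")
  expect_equal(concordance(pos_interp(), rtpcr_result(TRUE, 150)), "concordant")
  expect_equal(concordance(norm_interp(), rtpcr_result(TRUE, 100)),
               "discordant_pcr_pos")
  # a PCR positive below the FISH limit of detection is concordant with
  # a negative FISH
  expect_equal(concordance(norm_interp(), rtpcr_result(TRUE, 1.0)), "concordant")
  expect_equal(concordance(norm_interp(), rtpcr_result(FALSE)), "concordant")
  # atypical FISH with positive PCR: both assays flag CBFB
  expect_equal(concordance(del3_interp(), rtpcr_result(TRUE, 50)), "concordant")
  expect_equal(concordance(NULL, rtpcr_result(TRUE, 50)), "not_evaluable")
  expect_equal(concordance(pos_interp(), NULL), "not_evaluable")
})

test_that("confirmation requires positive FISH or confirmatory RT-PCR", {
  expect_true(confirm_rearrangement(del3_interp(), rtpcr_result(TRUE, 80)))
  expect_false(confirm_rearrangement(del3_interp(), rtpcr_result(FALSE)))
  expect_false(confirm_rearrangement(norm_interp(), NULL))
  expect_true(confirm_rearrangement(pos_interp(), NULL))
  # detected screen result without a ratio counts as detected
  expect_true(confirm_rearrangement(norm_interp(), rtpcr_result(TRUE)))
  # but a quantified ratio below the equivalence threshold does not confirm
  expect_false(confirm_rearrangement(norm_interp(), rtpcr_result(TRUE, 1.0)))
  expect_error(confirm_rearrangement(NULL, NULL), class = "cbfb_rule_error")
})

test_that("RT-PCR turning positive never unconfirms a case", {
  interps <- list(pos_interp(), del3_interp(), norm_interp())
  for (fish in interps) {
    before <- confirm_rearrangement(fish, rtpcr_result(FALSE))
    after <- confirm_rearrangement(fish, rtpcr_result(TRUE, 120))
    expect_false(before && !after)
    expect_true(after >= before)
  }
})

test_that("discordance causes follow the karyotype-aware decision tree", {
  k_t1619 <- parse_iscn("46,XX,t(16;19)(q22;q13.3)[17]/46,XX[3]")
  k_inv16 <- parse_iscn("46,XX,inv(16)(p13.1q22)[10]/46,XX[10]")
  k_norm <- parse_iscn("46,XY,inv(9)(p12q13)[20]")
  expect_equal(annotate_discordance_cause(pos_interp(), rtpcr_result(FALSE), k_t1619),
               "novel_partner")
  expect_equal(annotate_discordance_cause(pos_interp(), rtpcr_result(FALSE), k_inv16),
               "rare_transcript_variant")
  expect_equal(annotate_discordance_cause(norm_interp(), rtpcr_result(TRUE, 100), k_norm),
               "cryptic_insertion")
  expect_equal(annotate_discordance_cause(del3_interp(), rtpcr_result(TRUE, 50), k_inv16),
               "unbalanced_fusion_3del")
  expect_equal(annotate_discordance_cause(del3_interp(), rtpcr_result(FALSE), NULL),
               "non_MYH11_chr16_event")
  del5 <- classify_fish(fish_observation(c(G1F1 = 178), 200))
  expect_equal(annotate_discordance_cause(del5, rtpcr_result(FALSE), NULL),
               "non_MYH11_chr16_event")
  # no karyotype context: cause of a FISH-pos/PCR-neg discordance is unknown
  expect_equal(annotate_discordance_cause(pos_interp(), rtpcr_result(FALSE), NULL),
               "none")
  expect_equal(annotate_discordance_cause(pos_interp(), rtpcr_result(TRUE, 90), k_inv16),
               "none")
})

test_that("AC16A detection distinguishes apparent from cryptic aberrations", {
  k_app <- parse_iscn(
    "47,XY,der(16)inv(16)(p13.1q22)del(16)(q22q34),+mar[2]/46,XY[18]")
  expect_equal(detect_ac16a(k_app, confirmed = TRUE, balance = "unbalanced"),
               "apparent")
  # deletion seen only by FISH: karyotype clean, unbalanced pattern
  k_cry <- parse_iscn("47,XY,inv(16)(p13.1q22),+22[20]")
  expect_equal(detect_ac16a(k_cry, confirmed = TRUE, balance = "unbalanced"),
               "cryptic")
  expect_equal(detect_ac16a(k_cry, confirmed = TRUE, balance = "balanced"),
               "none")
  expect_equal(detect_ac16a(parse_iscn("46,XY[20]"), FALSE, "not_applicable"),
               "none")
  # cryptic calls require confirmation
  expect_equal(detect_ac16a(k_cry, confirmed = FALSE, balance = "unbalanced"),
               "none")
})

test_that("complex karyotype rules: standard vs re-defined", {
  # inv(16) + two trisomies: complex by the standard rule only
  k11 <- parse_iscn("46,XX,inv(16)(p13.1q22),+8,+22[3]")
  expect_true(complex_karyotype(k11, "standard"))
  expect_false(complex_karyotype(k11, "redefined"))

  # a structural ACA beside the primary event qualifies under both rules
  k2 <- parse_iscn(
    "50,XY,t(2;16)(q37;q22),t(3;16)(p21;p13),+8,+21,+22,+mar[5]/46,XY[13]")
  expect_true(complex_karyotype(k2, "standard"))
  expect_true(complex_karyotype(k2, "redefined"))
  expect_true(complex_karyotype(k2, "redefined", redefined_strict = TRUE))

  # strict reading additionally demands a numerical ACA
  k_strict <- parse_iscn("46,XX,inv(16)(p13.1q22),del(7)(q22),t(9;22)(q34;q11.2)[10]")
  expect_true(complex_karyotype(k_strict, "redefined"))
  expect_false(complex_karyotype(k_strict, "redefined", redefined_strict = TRUE))

  expect_false(complex_karyotype(parse_iscn("46,XY[20]"), "standard"))
  expect_false(complex_karyotype(parse_iscn("46,XY[20]"), "redefined"))
  expect_true(is.na(complex_karyotype(NULL, "standard")))
})

test_that("re-defined complex implies standard complex on every packaged case", {
  for (txt in example_cases()$karyotype) {
    k <- parse_iscn(txt, lenient = TRUE)
    if (isTRUE(complex_karyotype(k, "redefined"))) {
      expect_true(complex_karyotype(k, "standard"), label = txt)
    }
  }
})

test_that("NGS detectability predictions follow the published parameters", {
  # confirmed inv(16): fusion by all three, structure only by WGS
  p <- predict_ngs_detectability(TRUE, "inv16", ac16a = "none")
  expect_equal(p$fusion, rep("yes", 3))
  expect_equal(p$structure[p$method == "WGS"], "yes")
  expect_equal(p$structure[p$method != "WGS"], rep("no", 2))

  # cryptic AC16As escape WGS; apparent ones do not
  pc <- predict_ngs_detectability(TRUE, "inv16", ac16a = "cryptic")
  expect_equal(pc$ac16a[pc$method == "WGS"], "no")
  pa <- predict_ngs_detectability(TRUE, "inv16", ac16a = "apparent")
  expect_equal(pa$ac16a[pa$method == "WGS"], "yes")

  # other ACAs: WGS depends on clone size
  po <- predict_ngs_detectability(TRUE, "inv16", has_other_acas = TRUE)
  expect_equal(po$other_acas[po$method == "WGS"], "uncertain")
  expect_equal(po$other_acas[po$method != "WGS"], rep("no", 2))

  # unconfirmed case: no fusion call anywhere
  pu <- predict_ngs_detectability(FALSE)
  expect_equal(pu$fusion, rep("no", 3))
})

test_that("case tables can supply FISH as per-pattern count columns", {
  cases <- tibble::tibble(
    case_id = c("a", "b"),
    karyotype = c("46,XX,inv(16)(p13.1q22)[20]", "46,XY[20]"),
    R1G1F1 = c(120L, 0L), R1F1 = c(0L, 0L), total_scored = c(200L, 200L),
    rtpcr_detected = c("Pos", "Neg"), rtpcr_ratio_percent = c(85, NA)
  )
  calls <- call_cases(cases)
  expect_equal(calls$fish_category, c("positive", "normal"))
  expect_equal(calls$confirmed_rearrangement, c(TRUE, FALSE))
  expect_equal(calls$balance, c("balanced", "not_applicable"))
})

test_that("strict parsing produces per-row error records, not a failed run", {
  ex <- example_cases()
  calls <- call_cases(ex, pipeline_config(lenient = FALSE))
  expect_equal(nrow(calls), 17L)
  expect_equal(sum(!is.na(calls$error)), 2L)  # damaged nuc ish + missing count
  expect_true(all(is.na(calls$error) | is.na(calls$confirmed_rearrangement)))
})

test_that("empty input yields an empty verdict table", {
  calls <- call_cases(example_cases()[0, ])
  expect_equal(nrow(calls), 0L)
  expect_true(all(c("confirmed_rearrangement", "concordance", "ac16a") %in%
                    names(calls)))
})
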