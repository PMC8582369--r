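#' Seventeen representative cases with discordant or atypical findings
#'
#' A bundled worked-example cohort of 17 clinical AML cases illustrating
#' every diagnostic challenge the rule engine handles: FISH-positive /
#' RT-PCR-negative discordances caused by novel partner genes or rare
#' transcript variants, a FISH-normal / RT-PCR-positive cryptic insertion,
#' unbalanced rearrangements with a 3'CBFB deletion pattern, and
#' RT-PCR-negative 3'/5' deletion patterns in which a non-MYH11 CBFB
#' rearrangement cannot be excluded.
#'
#' Karyotype and `nuc ish` strings are transcribed verbatim from the source
#' clinical reports, including their typographical artifacts (a bracketed
#' count printed `[1 2]`, a damaged bracket printed `l200}`, a sub-band
#' printed `p13,1`, one clone with a missing cell count): parse them with
#' the default lenient [pipeline_config()]. The `feature` column holds the
#' reported result label (ASCII primes) and `evidence` the confirmatory
#' follow-up assays (dual-fusion FISH, whole chromosome 16 painting, aCGH)
#' as advisory flags.
#'
#' @return A tibble with columns `case_id`, `karyotype`, `fish`,
#'   `rtpcr_detected`, `rtpcr_ratio_percent`, `evidence`, `feature`.
#' @examples
#' calls <- call_cases(example_cases())
#' sum(calls$confirmed_rearrangement)
#' @export
example_cases <- function() {
  tibble::tribble(
    ~case_id, ~karyotype, ~fish, ~rtpcr_detected, ~rtpcr_ratio_percent, ~evidence, ~feature,
    "1", "46,XY,t(1;16)(q21;q22)[8]/46,XY[1 2]",
    "ish t(1;16)(q21;q22)(3′CBFB+;5′CBFB+)[2].nuc ish(CBFBx2)(5′CBFB sep 3′CBFBx1)[62/200]",
    FALSE, NA, NA, "t(1;16)Discordant",
    "2", "50,XY,t(2;16)(q37;q22),t(3;16)(p21;p13),+8,+21,+22,+mar[5]/51,idem[cp2]/46,XY[13]",
    "nuc ish(CBFBx2)(5′CBFB sep 3′CBFBx1)[40/200]",
    FALSE, NA, NA, "t(2;16)Discordant",
    "3", "46,XX,inv(3)(q21q26.2),del(6)(q21q27),t(16;19)(q22;q13.3),del(17)(p12)[17]/46,XX,inv(3)(q21q26.2),t(11;15)(q14;q26.3)[1]//46,XY[2]",
    "nuc ish(CBFBx2)(5′CBFB sep 3′CBFBx1)[139/200]",
    FALSE, NA, NA, "t(16;19)Discordant",
    "4", "46,XX,inv(16)(p13.1q22)[10]/46,XX[10]",
    "nuc ish(CBFBx2)(5′CBFB sep 3′CBFBx1)[134/200]",
    FALSE, NA, "df_fish_fusion_positive;acgh_note:normal", "Discordant",
    "5", "46,XY,inv(9)(p12q13)[20]",
    "nuc ish(CBFBx2)l200}. Negative",
    TRUE, 100, "df_fish_insertion;acgh_note:loss 16p13.11 ~140 kb including part of MYH11", "Discordant",
    "6", "47,XY,der(16)inv(16)(p13.1q22)del(16)(q22q34),+mar[2]/46,XY[18]",
    "nuc ish (5′CBFBx2,3′CBFBx1)(5′CBFB con 3′CBFBx1)[104/200]",
    TRUE, NA, NA, "3'CBFB del",
    "7", "47,XY,inv(16)(p13.1q22),+22[20]",
    "nuc ish(5′CBFBx2,3′CBFBx1)(5′CBFB con 3′CBFBx1)[20/200]",
    TRUE, NA, NA, "3'CBFB del",
    "8", "46,XX,der(16)inv(16)(p13.1q22)del(16)(q22)[19]/47,sl,+8[1]",
    "nuc ish(5′CBFBx2,3′CBFBx1)(5′CBFB con 3′CBFBx1)[180/200]",
    TRUE, NA, NA, "3'CBFB del",
    "9", "46,XY,der(16)inv(16)(p13.1q22)del(16)(q22)[19]/46,XY[1]",
    "ish der(16)inv(16)(p13.1)(5′CBFB+)q22(3′CBFB-)del(16)(q22)[2]nuc ish(5′CBFBx2,3′CBFBx1)(5′CBFB con 3′CBFBx1)[182/200]",
    TRUE, NA, "acgh_note:aCGH performed", "3'CBFB del",
    "10", "46,XY,inv(16)(p13.1q22)[13]/46,XY",
    "nuc ish(5′CBFBx2,3′CBFBx1)(5′CBFB con 3′CBFBx1)[146/200]",
    TRUE, NA, NA, "3'CBFB del",
    "11", "46,XX,inv(16)(p13.1q22)[9]/46,idem,+8,+22[3]/46,idem[cp2]/46,XX,t(2;22)(p13;q11.2),del(18)(q21.1q23),−22[1]/46,XX[5]",
    "nuc ish(5′CBFBx2,3′CBFBx1)(5′CBFB con 3′CBFBx1)[189/200]",
    TRUE, NA, NA, "3'CBFB del",
    "12", "46,XY,der(16)del(16)(p13,1)inv(16)(p13.1q22)[20]",
    "nuc ish(5′CBFBx2,3′CBFBx1)(5′CBFB con 3′CBFBx1)[175/200]",
    TRUE, NA, "df_fish_fusion_positive;wcp16_no_translocation", "3'CBFB del",
    "13", "46,XX,der(11)t(11;16)(p15;p13.1)inv(16)(p13.1q22),der(16)t(11;16)inv(16)del(16)(q22)[18]/46,XX[2]",
    "nuc ish(5′CBFBx2,3′CBFBx1)(5′CBFB con 3′CBFBx1)[200]",
    TRUE, NA, NA, "3'CBFB del",
    "14", "46,XX,del(16)(q22)[15]/46,XX[4]",
    "nuc ish(5′CBFBx2,3′CBFBx1)(5′CBFB con 3′CBFBx1)[190/200]",
    FALSE, NA, NA, "3'CBFB del",
    "15", "47,XY,+8[5]/47,idem,der(16)inv(16)(p13.3q13)del(16)(q22q22)[15]",
    "nuc ish(5′CBFBx2,3′CBFBx1)(5′CBFB con 3′CBFBx1)[154/200]",
    FALSE, NA, "df_fish_fusion_negative", "3'CBFB del",
    "16", "43~45,XY,add(1)(q21),−5,+6,−7,−8,add(11)(p15),add(16)(q22),add(18)(q21.1),del(20)(q11.2q13.3),+1~2mar[cp16]/46,XY[4]",
    "nuc ish(5′CBFBx2,3′CBFBx1)(5′CBFB con 3′CBFBx1)[138/200]",
    FALSE, NA, NA, "3'CBFB del",
    "17", "43–46,XY,-2,del(3)(p21p25),del(5)(q13q33),add(7)(q36),+8,add(11)(p15),add(12)(p12),del(12)(p13),−15,der(16)del(16)(q11.2q22)add(16)(q22),−17,−19,+2mar[cp20]",
    "nuc ish(5′CBFBx1,3′CBFBx2)(5′CBFB con 3′CBFBx1)[178/200]",
    FALSE, NA, "acgh_note:aCGH performed", "5'CBFB del"
  )
}
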