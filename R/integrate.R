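#' Construct an RT-PCR result
#'
#' @param detected Logical: was the CBFB-MYH11 fusion transcript detected?
#' @param transcript_ratio_percent Quantitative transcript level as a
#'   percentage of the control transcript, or `NA` when only a qualitative
#'   screen result is available. A non-detected result is treated as 0.
#' @param assay `"screen"` or `"quantitative"`.
#' @return An object of class `cbfb_rtpcr`.
#' @export
rtpcr_result <- function(detected, transcript_ratio_percent = NA_real_,
                         assay = c("quantitative", "screen")) {
  assay <- match.arg(assay)
  detected <- isTRUE(detected)
  ratio <- as.numeric(transcript_ratio_percent)
  if (!detected) ratio <- 0
  if (!is.na(ratio) && ratio < 0) {
    rlang::abort("transcript ratio must be non-negative",
                 class = "cbfb_config_error")
  }
  structure(list(detected = detected, transcript_ratio_percent = ratio,
                 assay = assay), class = "cbfb_rtpcr")
}

# RT-PCR counts as confirmatory when detected with a ratio at/above the
# FISH-equivalence threshold, or detected with no ratio reported
rtpcr_confirmatory <- function(rtpcr, threshold) {
  if (is.null(rtpcr)) return(FALSE)
  isTRUE(rtpcr$detected) &&
    (is.na(rtpcr$transcript_ratio_percent) ||
       rtpcr$transcript_ratio_percent >= threshold)
}

#' FISH vs RT-PCR concordance
#'
#' Because RT-PCR is far more sensitive than FISH, a positive RT-PCR result
#' with a transcript percentage below the FISH limit of detection (4.2% for
#' the typical pattern) is intentionally considered concordant with a
#' negative FISH result. A positive RT-PCR against a *normal* FISH is
#' discordant; against an *abnormal* (atypical CBFB) FISH both assays
#' flag the gene and the case is concordant at this level — the atypical
#' configuration is explained by [annotate_discordance_cause()].
#'
#' @param fish A `cbfb_fish_interp` (or `NULL` when FISH was not performed).
#' @param rtpcr A `cbfb_rtpcr` (or `NULL` when RT-PCR was not performed).
#' @param equivalence_threshold Percent transcript ratio treated as
#'   FISH-equivalent (default 4.2).
#' @return One of `"concordant"`, `"discordant_fish_pos"`,
#'   `"discordant_pcr_pos"`, `"not_evaluable"`.
#' @export
concordance <- function(fish, rtpcr, equivalence_threshold = 4.2) {
  if (is.null(fish) || is.null(rtpcr)) return("not_evaluable")
  stopifnot(inherits(fish, "cbfb_fish_interp"), inherits(rtpcr, "cbfb_rtpcr"))
  pcr_pos <- rtpcr_confirmatory(rtpcr, equivalence_threshold)
  if (fish$category == "positive") {
    return(if (isTRUE(rtpcr$detected)) "concordant" else "discordant_fish_pos")
  }
  if (fish$category == "normal" && pcr_pos) return("discordant_pcr_pos")
  "concordant"
}

#' Confirm a CBFB rearrangement from FISH and/or RT-PCR
#'
#' A rearrangement is confirmed when FISH is positive (typical pattern at
#' or above its cutoff) or when RT-PCR detects the fusion transcript at a
#' level at/above the FISH-equivalence threshold (a detected screen result
#' without a quantitative ratio also counts).
#'
#' @inheritParams concordance
#' @return Logical flag.
#' @export
confirm_rearrangement <- function(fish, rtpcr, equivalence_threshold = 4.2) {
  if (is.null(fish) && is.null(rtpcr)) {
    rlang::abort("cannot confirm a rearrangement with neither FISH nor RT-PCR",
                 class = "cbfb_rule_error")
  }
  fish_pos <- !is.null(fish) && fish$category == "positive"
  fish_pos || rtpcr_confirmatory(rtpcr, equivalence_threshold)
}

#' Annotate the cause of a discordant or atypical result
#'
#' Decision tree over FISH category/subtype, RT-PCR outcome and karyotype
#' context: a FISH-positive/PCR-negative case with a t(16q22;v) karyotype
#' points to a novel (non-MYH11) partner gene; with inv(16)/t(16;16) to a
#' rare or novel CBFB-MYH11 transcript variant; a FISH-normal/PCR-positive
#' case to a cryptic insertion; a 3' deletion pattern with positive PCR to
#' an unbalanced CBFB-MYH11 rearrangement; and a 3'/5' deletion pattern
#' with negative PCR to a chromosome 16 event in which a CBFB rearrangement
#' with a partner other than MYH11 cannot be excluded.
#'
#' @inheritParams concordance
#' @param karyotype A `cbfb_karyotype`, or `NULL` when unavailable (causes
#'   that require karyotype context then fall back to `"none"`).
#' @return One of `"novel_partner"`, `"rare_transcript_variant"`,
#'   `"cryptic_insertion"`, `"unbalanced_fusion_3del"`,
#'   `"non_MYH11_chr16_event"`, `"none"`.
#' @export
annotate_discordance_cause <- function(fish, rtpcr, karyotype = NULL,
                                       equivalence_threshold = 4.2) {
  if (is.null(fish) || is.null(rtpcr)) return("none")
  pcr_pos <- rtpcr_confirmatory(rtpcr, equivalence_threshold)
  if (fish$category == "positive" && !isTRUE(rtpcr$detected)) {
    cls <- chr16_class(karyotype)
    if (is.na(cls)) return("none")
    if (cls == "t16q22v") return("novel_partner")
    if (cls %in% c("inv16", "t1616")) return("rare_transcript_variant")
    return("none")
  }
  if (fish$category == "normal" && pcr_pos) return("cryptic_insertion")
  subtype <- fish$abnormal_subtype
  if (!is.na(subtype)) {
    if (subtype == "del_3prime" && pcr_pos) return("unbalanced_fusion_3del")
    if (subtype %in% c("del_3prime", "del_5prime") && !pcr_pos) {
      return("non_MYH11_chr16_event")
    }
  }
  "none"
}

#' Detect additional chromosome 16 aberrations (AC16As)
#'
#' An AC16A is *apparent* when the karyotype itself shows chromosome 16
#' events beyond the CBFB-rearranging one (see [chr16_events()]); it is
#' *cryptic* when the karyotype shows none but a confirmed rearrangement
#' presents an unbalanced FISH signal pattern, implying simultaneous gain
#' or loss of all or part of CBFB.
#'
#' @param karyotype A `cbfb_karyotype` or `NULL`.
#' @param confirmed Logical confirmation flag.
#' @param balance Balance label from [balanced_state()].
#' @return One of `"apparent"`, `"cryptic"`, `"none"`.
#' @export
detect_ac16a <- function(karyotype, confirmed, balance) {
  if (!is.null(karyotype) && inherits(karyotype, "cbfb_karyotype")) {
    ev <- chr16_events(karyotype)
    if (length(ev$additional) > 0L) return("apparent")
  }
  if (isTRUE(confirmed) && identical(balance, "unbalanced")) return("cryptic")
  "none"
}

# top-level token carrying the CBFB-rearranging event (directly or embedded)
is_primary_top <- function(a) {
  is_primary_cbfb(a) ||
    (a$category == "derivative" &&
       any(vapply(a$embedded, is_primary_cbfb, logical(1))))
}

#' Complex-karyotype call under the standard or re-defined rule
#'
#' Standard rule: >= 3 chromosomal abnormalities with at least one
#' structural (the CBFB-rearranging inv(16)/t(16;16) counts as
#' structural). Re-defined rule: the CBFB-rearranging event — usually a
#' simple balanced aberration — is treated as equivalent to a numerical
#' abnormality, so >= 3 abnormalities are required with at least one
#' structural abnormality among the *non-primary* events. Under
#' `redefined_strict = TRUE` the additional-abnormality requirement is
#' read tightly: at least one structural and at least one numerical
#' additional abnormality. The case-level flag is the OR over clones.
#'
#' @param karyotype A `cbfb_karyotype` (idem references resolved
#'   automatically).
#' @param rule `"standard"` or `"redefined"`.
#' @param policy A [counting_policy()].
#' @param redefined_strict Logical; see above.
#' @return Logical flag.
#' @export
complex_karyotype <- function(karyotype, rule = c("standard", "redefined"),
                              policy = counting_policy(),
                              redefined_strict = FALSE) {
  rule <- match.arg(rule)
  if (is.null(karyotype) || !inherits(karyotype, "cbfb_karyotype")) return(NA)
  karyotype <- resolve_idem(karyotype)
  excl <- normalize_token(policy$exclude)
  clone_flag <- function(cl) {
    if (cl$chimeric_donor) return(FALSE)
    cnt <- count_abnormalities(cl, policy)
    if (rule == "standard") {
      return(cnt[["n_total"]] >= 3L && cnt[["n_structural"]] >= 1L)
    }
    kept <- Filter(function(a) !(normalize_token(a$raw) %in% excl),
                   cl$abnormalities)
    n_primary <- sum(vapply(kept, is_primary_top, logical(1)))
    if (n_primary == 0L) {
      return(cnt[["n_total"]] >= 3L && cnt[["n_structural"]] >= 1L)
    }
    structural_acas <- cnt[["n_structural"]] - n_primary
    ok <- cnt[["n_total"]] >= 3L && structural_acas >= 1L
    if (redefined_strict) ok <- ok && cnt[["n_numerical"]] >= 1L
    ok
  }
  any(vapply(karyotype$clones, clone_flag, logical(1)))
}

#' Predict detectability by NGS-based methods
#'
#' Following published analytical parameters of whole genome sequencing
#' (WGS), whole transcriptome sequencing (WTS), and partner-agnostic
#' targeted RNA-Seq: a confirmed CBFB rearrangement/fusion is detectable by
#' all three; the underlying structural configuration (inv(16), t(16;16),
#' insertion, t(16q22;v)) only by WGS; apparent AC16As by WGS but cryptic
#' AC16As (below the structural-variant size/clone-level parameters) by
#' none; other ACAs by WGS depending on clone size (uncertain), and by
#' neither transcriptome method.
#'
#' @param confirmed Logical confirmation flag.
#' @param karyotype_class One of `"inv16"`, `"t1616"`, `"t16q22v"`,
#'   `"normal_chr16"` or `NA`.
#' @param ac16a AC16A status (`"apparent"`, `"cryptic"`, `"none"`).
#' @param insertion Logical: is the rearrangement a cryptic insertion?
#' @param has_other_acas Logical: are there ACAs not involving chromosome 16?
#' @return A tibble with one row per method (`WGS`, `WTS`,
#'   `targeted_RNASeq`) and columns `fusion`, `structure`, `ac16a`,
#'   `other_acas` with values `"yes"`, `"no"`, `"uncertain"`, or `NA` when
#'   the feature is absent.
#' @export
predict_ngs_detectability <- function(confirmed, karyotype_class = NA,
                                      ac16a = "none", insertion = FALSE,
                                      has_other_acas = FALSE) {
  fusion <- if (isTRUE(confirmed)) "yes" else "no"
  structure_wgs <- if (!isTRUE(confirmed)) {
    NA_character_
  } else if (isTRUE(insertion) ||
             (!is.na(karyotype_class) &&
              karyotype_class %in% c("inv16", "t1616", "t16q22v"))) {
    "yes"
  } else {
    "uncertain"
  }
  structure_rna <- if (isTRUE(confirmed)) "no" else NA_character_
  ac16a_col <- function(method) {
    if (identical(ac16a, "none")) return(NA_character_)
    if (method != "WGS") return("no")
    if (identical(ac16a, "apparent")) "yes" else "no"
  }
  other_col <- function(method) {
    if (!isTRUE(has_other_acas)) return(NA_character_)
    if (method == "WGS") "uncertain" else "no"
  }
  tibble::tibble(
    method = c("WGS", "WTS", "targeted_RNASeq"),
    fusion = fusion,
    structure = c(structure_wgs, structure_rna, structure_rna),
    ac16a = vapply(c("WGS", "WTS", "targeted_RNASeq"), ac16a_col, character(1),
                   USE.NAMES = FALSE),
    other_acas = vapply(c("WGS", "WTS", "targeted_RNASeq"), other_col,
                        character(1), USE.NAMES = FALSE)
  )
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the rule engine. The defaults are the
#' validated laboratory values; no override is needed to reproduce the
#' packaged worked examples.
#'
#' @param cutoffs A [fish_cutoffs()] configuration.
#' @param policy A [counting_policy()].
#' @param equivalence_threshold Percent RT-PCR transcript ratio treated as
#'   FISH-equivalent (default 4.2).
#' @param redefined_strict Strict reading of the re-defined complex rule
#'   (see [complex_karyotype()]).
#' @param lenient Tolerate typographical artifacts in ISCN/nuc-ish strings
#'   (default `TRUE`; published tables contain such artifacts). Set to
#'   `FALSE` for strict parsing with per-row error records.
#' @return A list of class `cbfb_config`.
#' @export
pipeline_config <- function(cutoffs = fish_cutoffs(),
                            policy = counting_policy(),
                            equivalence_threshold = 4.2,
                            redefined_strict = FALSE,
                            lenient = TRUE) {
  structure(list(cutoffs = cutoffs, policy = policy,
                 equivalence_threshold = equivalence_threshold,
                 redefined_strict = redefined_strict, lenient = lenient),
            class = "cbfb_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may set `cutoffs` (named list), `counting_policy`
#' (`exclude`, `mar_structural`), `equivalence_threshold`,
#' `redefined_strict` and `lenient`; unset fields keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `cbfb_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cutoffs <- do.call(fish_cutoffs, as.list(raw$cutoffs %||% list()))
  policy <- do.call(counting_policy, as.list(raw$counting_policy %||% list()))
  pipeline_config(
    cutoffs = cutoffs, policy = policy,
    equivalence_threshold = raw$equivalence_threshold %||% 4.2,
    redefined_strict = isTRUE(raw$redefined_strict),
    lenient = raw$lenient %||% TRUE
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# printed feature label, e.g. "3'CBFB del" or "t(16;19)Discordant"
feature_label <- function(fish, concord, karyotype) {
  if (!is.null(fish) && !is.na(fish$abnormal_subtype)) {
    return(switch(fish$abnormal_subtype,
                  del_3prime = "3'CBFB del",
                  del_5prime = "5'CBFB del",
                  loss_one_copy = "Loss of one copy",
                  extra_copies = "Extra copy(ies)",
                  gain_plus_loss = "Gain + loss",
                  gain_5prime = "5'CBFB gain"))
  }
  if (concord %in% c("discordant_fish_pos", "discordant_pcr_pos")) {
    if (!is.null(karyotype) && identical(chr16_class(karyotype), "t16q22v")) {
      ev <- chr16_events(karyotype)
      tr <- ev$primary[[1]]
      return(paste0("t(", paste(tr$chromosomes, collapse = ";"), ")Discordant"))
    }
    return("Discordant")
  }
  if (!is.null(fish) && fish$category == "positive") return("Positive")
  "Normal"
}

normalize_detected <- function(x) {
  if (is.logical(x)) return(x)
  xl <- tolower(as.character(x))
  dplyr::case_when(
    xl %in% c("pos", "positive", "true", "yes", "1", "detected") ~ TRUE,
    xl %in% c("neg", "negative", "false", "no", "0", "not detected") ~ FALSE,
    .default = NA
  )
}

# build the per-case inputs (karyotype model, FISH observation, RT-PCR)
# from one row of a case table
assemble_case <- function(row, config) {
  k <- NULL
  k_status <- row$karyotype_status %||% NA_character_
  if (!is.na(k_status) && k_status %in% c("insufficient", "failed", "missing")) {
    k <- NULL
  } else if (!is.null(row$karyotype) && !is.na(row$karyotype) &&
             nzchar(stringr::str_trim(row$karyotype))) {
    k <- parse_iscn(row$karyotype, lenient = config$lenient)
  }
  obs <- NULL
  if (!is.null(row$fish) && !is.na(row$fish) && nzchar(row$fish)) {
    obs <- parse_nuc_ish(row$fish, lenient = config$lenient)
  } else {
    pat_cols <- intersect(PATTERN_CODES, names(row))
    if (length(pat_cols) > 0L) {
      counts <- unlist(row[pat_cols])
      counts <- counts[!is.na(counts)]
      obs <- fish_observation(counts,
                              total_scored = row$total_scored %||% 200L)
    }
  }
  rtpcr <- NULL
  det <- normalize_detected(row$rtpcr_detected %||% NA)
  if (!is.na(det)) {
    rtpcr <- rtpcr_result(det, row$rtpcr_ratio_percent %||% NA_real_)
  }
  list(karyotype = k, fish_obs = obs, rtpcr = rtpcr)
}

call_one_case <- function(row, config) {
  inputs <- assemble_case(row, config)
  k <- inputs$karyotype
  fish <- if (!is.null(inputs$fish_obs)) {
    classify_fish(inputs$fish_obs, config$cutoffs)
  } else {
    NULL
  }
  rtpcr <- inputs$rtpcr
  thr <- config$equivalence_threshold
  confirmed <- if (is.null(fish) && is.null(rtpcr)) NA else
    confirm_rearrangement(fish, rtpcr, thr)
  concord <- concordance(fish, rtpcr, thr)
  balance <- if (!is.null(fish)) balanced_state(fish, confirmed) else "not_applicable"
  cause <- annotate_discordance_cause(fish, rtpcr, k, thr)
  ac16a <- detect_ac16a(k, confirmed, balance)
  cls <- chr16_class(k)
  has_other_acas <- FALSE
  if (!is.null(k)) {
    kr <- resolve_idem(k)
    excl <- normalize_token(config$policy$exclude)
    for (cl in kr$clones) {
      if (cl$chimeric_donor) next
      for (a in cl$abnormalities) {
        if (normalize_token(a$raw) %in% excl) next
        if (!involves_chr16(a)) has_other_acas <- TRUE
      }
    }
  }
  ngs <- predict_ngs_detectability(
    confirmed = isTRUE(confirmed), karyotype_class = cls, ac16a = ac16a,
    insertion = identical(cause, "cryptic_insertion"),
    has_other_acas = has_other_acas
  )
  tibble::tibble(
    case_id = as.character(row$case_id %||% NA_character_),
    fish_category = if (is.null(fish)) NA_character_ else fish$category,
    fish_subtype = if (is.null(fish)) NA_character_ else fish$abnormal_subtype,
    rtpcr_detected = if (is.null(rtpcr)) NA else rtpcr$detected,
    rtpcr_positive = if (is.null(rtpcr)) NA else rtpcr_confirmatory(rtpcr, thr),
    confirmed_rearrangement = confirmed,
    concordance = concord,
    discordance_cause = cause,
    balance = balance,
    ac16a = ac16a,
    karyotype_class = cls,
    has_other_acas = has_other_acas,
    complex_standard = complex_karyotype(k, "standard", config$policy),
    complex_redefined = complex_karyotype(k, "redefined", config$policy,
                                          config$redefined_strict),
    feature = feature_label(fish, concord, k),
    error = NA_character_,
    ngs_prediction = list(ngs)
  )
}

error_row <- function(case_id, msg) {
  tibble::tibble(
    case_id = as.character(case_id), fish_category = NA_character_,
    fish_subtype = NA_character_, rtpcr_detected = NA, rtpcr_positive = NA,
    confirmed_rearrangement = NA, concordance = NA_character_,
    discordance_cause = NA_character_, balance = NA_character_,
    ac16a = NA_character_, karyotype_class = NA_character_,
    has_other_acas = NA, complex_standard = NA, complex_redefined = NA,
    feature = NA_character_, error = msg, ngs_prediction = list(NULL)
  )
}

#' Integrate karyotype, FISH and RT-PCR calls for a cohort of cases
#'
#' The central pipeline verb: takes a case table, runs ISCN and nuc-ish
#' parsing, FISH classification, RT-PCR integration, AC16A detection,
#' complex-karyotype rules and NGS-detectability prediction, and returns
#' one verdict row per case.
#'
#' @param cases A data frame with columns `case_id`, `karyotype` (ISCN
#'   string; may be `NA`), `fish` (a `nuc ish` string) *or* per-pattern
#'   count columns named by [PATTERN_CODES] plus `total_scored`,
#'   `rtpcr_detected` (logical or `"Pos"`/`"Neg"`), and optionally
#'   `rtpcr_ratio_percent`, `karyotype_status`
#'   (`insufficient`/`failed`/`missing`) and `evidence`.
#' @param config A [pipeline_config()].
#' @return A tibble with one row per case: FISH category and subtype,
#'   `confirmed_rearrangement`, `concordance`, `discordance_cause`,
#'   `balance`, `ac16a`, `karyotype_class`, complex-karyotype flags,
#'   a printed-style `feature` label, an `error` column (`NA` unless a
#'   strict-mode parse failed for that row) and a list-column
#'   `ngs_prediction` of per-method detectability tibbles.
#' @examples
#' call_cases(example_cases())
#' @export
call_cases <- function(cases, config = pipeline_config()) {
  stopifnot(is.data.frame(cases))
  if (nrow(cases) == 0L) return(error_row("x", "x")[0, ])
  rows <- lapply(seq_len(nrow(cases)), function(i) {
    row <- as.list(cases[i, , drop = FALSE])
    tryCatch(call_one_case(row, config), error = function(e) {
      error_row(row$case_id %||% i, conditionMessage(e))
    })
  })
  dplyr::bind_rows(rows)
}
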