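#' Default background signal-noise rates for the generator
#'
#' Background (false-signal) rates per abnormal pattern, in percent of
#' nuclei, used by [simulate_cohort()] for patterns other than the true
#' one. Defaults are one quarter of each pattern's cutoff, except for the
#' two deletion patterns (R1F1, G1F1): their 0.4% cutoff is below the
#' one-nucleus resolution of a 200-cell score — any background nucleus
#' would be reportable — so their background rate is 0.
#'
#' @param cutoffs A [fish_cutoffs()] configuration.
#' @return Named numeric vector of percent rates.
#' @export
default_background_noise <- function(cutoffs = fish_cutoffs()) {
  noise <- unclass(cutoffs) / 4
  noise[c("R1F1", "G1F1")] <- 0
  noise
}

CATEGORY_PATTERNS <- list(
  positive = "R1G1F1", normal = character(), extra_copies = "F3plus",
  loss_one_copy = "F1", gain_plus_loss = c("F1", "F3plus"),
  del_3prime = "R1F1", del_5prime = "G1F1", gain_5prime = "G1F2"
)

#' Synthetic-cohort generator configuration
#'
#' The defaults emulate the composition of a large single-institution
#' break-apart FISH cohort: result-category prevalences from the reported
#' 1629-patient breakdown (positive 262, normal 1234, extra copies 34,
#' loss of one copy 84, gain+loss 2, 3' deletion 11, 5' deletion 1, 5'
#' gain 1), a karyotype mix among rearranged cases of inv(16) 240,
#' t(16;16) 17, t(16q22;v) 3 and cryptic-normal 3 (of 263), trisomy 22/8
#' rates of 21%/20.2% among confirmed cases, and the observed discordance
#' rates (FISH-pos/PCR-neg 4/262, FISH-normal/PCR-pos 1/645, 3'-del
#' PCR-pos 8/11).
#'
#' @param category_prevalences Named probabilities over the result
#'   categories (must sum to 1).
#' @param nuclei_per_test Nuclei scored per test (default 200).
#' @param true_fraction_range Percent interval from which the abnormal-
#'   pattern nucleus fraction of an abnormal case is drawn (default 10-95,
#'   comfortably above every cutoff; each component of a gain+loss mixture
#'   is drawn from 10-45 so the two subclones fit in one test).
#' @param background_noise Named percent rates of false signals for
#'   non-true patterns; see [default_background_noise()].
#' @param karyotype_mix Named probabilities over
#'   `inv16`/`t1616`/`t16q22v`/`normal_cryptic` for rearranged cases.
#' @param aca_rates Named rates: `tri22`, `tri8`, `other_structural`
#'   (probability that a confirmed case carries the corresponding
#'   additional chromosomal abnormality).
#' @param discordance_rates Named rates `fish_pos_pcr_neg`,
#'   `fish_norm_pcr_pos`, `del3_pcr_pos`.
#' @param apparent_del_rate Probability that a PCR-positive 3'-deletion
#'   case shows the deletion in its karyotype (apparent AC16A) rather than
#'   only by FISH (cryptic).
#' @param cutoffs Cutoffs used to sanity-check the noise rates.
#' @return A list of class `cbfb_cohort_config`.
#' @export
cohort_config <- function(
    category_prevalences = c(positive = 262, normal = 1234, extra_copies = 34,
                             loss_one_copy = 84, gain_plus_loss = 2,
                             del_3prime = 11, del_5prime = 1,
                             gain_5prime = 1) / 1629,
    nuclei_per_test = 200L,
    true_fraction_range = c(10, 95),
    background_noise = default_background_noise(),
    karyotype_mix = c(inv16 = 240, t1616 = 17, t16q22v = 3,
                      normal_cryptic = 3) / 263,
    aca_rates = c(tri22 = 0.21, tri8 = 0.202, other_structural = 0.1),
    discordance_rates = c(fish_pos_pcr_neg = 4 / 262,
                          fish_norm_pcr_pos = 1 / 645,
                          del3_pcr_pos = 8 / 11),
    apparent_del_rate = 5 / 8,
    cutoffs = fish_cutoffs()) {
  if (abs(sum(category_prevalences) - 1) > 1e-8) {
    rlang::abort("category prevalences must sum to 1",
                 class = "cbfb_config_error")
  }
  if (!setequal(names(category_prevalences), names(CATEGORY_PATTERNS))) {
    rlang::abort("category prevalences must cover exactly the result categories",
                 class = "cbfb_config_error")
  }
  if (any(background_noise[names(cutoffs)] >= unclass(cutoffs))) {
    rlang::abort("background noise rates must lie strictly below the cutoffs",
                 class = "cbfb_config_error")
  }
  structure(list(
    category_prevalences = category_prevalences,
    nuclei_per_test = as.integer(nuclei_per_test),
    true_fraction_range = true_fraction_range,
    background_noise = background_noise,
    karyotype_mix = karyotype_mix / sum(karyotype_mix),
    aca_rates = aca_rates,
    discordance_rates = discordance_rates,
    apparent_del_rate = apparent_del_rate
  ), class = "cbfb_cohort_config")
}

#' Draw nucleus-level FISH counts for a test
#'
#' Nuclei are assigned multinomially: the true pattern(s) at the given
#' fraction(s), background patterns at their noise rates, and the
#' remainder as normal two-fusion nuclei.
#'
#' @param true_patterns Character vector of abnormal pattern codes truly
#'   present (may be empty for a normal case).
#' @param fractions Percent of nuclei carrying each true pattern.
#' @param n_nuclei Number of nuclei scored.
#' @param noise Named percent background rates (see
#'   [default_background_noise()]); applied to patterns not in
#'   `true_patterns`.
#' @return A `cbfb_fish_obs`. Uses the current RNG stream.
#' @export
generate_fish_counts <- function(true_patterns, fractions, n_nuclei = 200L,
                                 noise = default_background_noise()) {
  stopifnot(length(true_patterns) == length(fractions),
            all(fractions >= 0), all(fractions <= 100))
  probs <- stats::setNames(numeric(length(PATTERN_CODES)), PATTERN_CODES)
  for (i in seq_along(true_patterns)) {
    probs[true_patterns[[i]]] <- fractions[[i]] / 100
  }
  for (code in names(noise)) {
    if (!code %in% true_patterns) probs[code] <- noise[[code]] / 100
  }
  if (sum(probs[setdiff(PATTERN_CODES, "F2")]) > 1) {
    rlang::abort("pattern fractions exceed 100% of nuclei",
                 class = "cbfb_config_error")
  }
  probs["F2"] <- 1 - sum(probs[setdiff(PATTERN_CODES, "F2")])
  draw <- stats::rmultinom(1, size = n_nuclei, prob = probs)[, 1]
  counts <- draw[setdiff(PATTERN_CODES, "F2")]
  fish_observation(counts[counts > 0], total_scored = n_nuclei)
}

#' Instantiate an ISCN karyotype string from a template
#'
#' Templates are modelled on the clone structures seen in clinical reports
#' of this disease; every emitted string round-trips through
#' [parse_iscn()] and classifies as the requested chromosome 16 category.
#'
#' @param class One of `"inv16"`, `"t1616"`, `"t16q22v"`,
#'   `"normal_cryptic"`, `"del3_apparent"` (unbalanced rearrangement with
#'   the deletion visible in the karyotype), `"del16q22"` (isolated 16q22
#'   deletion), `"monosomy16"`, `"trisomy16"`, `"normal"`.
#' @param sex `"XX"` or `"XY"`.
#' @param tri22,tri8 Add trisomy 22 / trisomy 8 to the abnormal clone.
#' @param other_aca Add a structural non-chromosome-16 ACA
#'   (`del(7)(q22)`).
#' @param t16q22v_partner Partner specification for `t(16q22;v)` as
#'   `c(chrom, band)` (default chromosome 1 at q21).
#' @param cells Metaphases in the abnormal clone; a normal sideline with
#'   `20 - cells` metaphases is appended when `cells < 20`.
#' @return A list: `karyotype` (the ISCN string), `n_abnormalities`
#'   (ground-truth top-level abnormality count of the abnormal clone),
#'   `class` and `sex`.
#' @examples
#' generate_karyotype_string("inv16", tri22 = TRUE)$karyotype
#' @export
generate_karyotype_string <- function(class, sex = "XX", tri22 = FALSE,
                                      tri8 = FALSE, other_aca = FALSE,
                                      t16q22v_partner = c("1", "q21"),
                                      cells = 20L) {
  core <- switch(class,
    inv16 = "inv(16)(p13.1q22)",
    t1616 = "t(16;16)(p13.1;q22)",
    t16q22v = sprintf("t(%s;16)(%s;q22)", t16q22v_partner[[1]],
                      t16q22v_partner[[2]]),
    del3_apparent = "der(16)inv(16)(p13.1q22)del(16)(q22)",
    del16q22 = "del(16)(q22)",
    monosomy16 = "-16",
    trisomy16 = "+16",
    normal_cryptic = NULL,
    normal = NULL,
    rlang::abort(paste0("unknown karyotype template class: ", class),
                 class = "cbfb_config_error")
  )
  abns <- core
  gains <- 0L
  if (tri22) { abns <- c(abns, "+22"); gains <- gains + 1L }
  if (tri8)  { abns <- c(abns, "+8");  gains <- gains + 1L }
  if (other_aca) abns <- c(abns, "del(7)(q22)")
  modal <- 46L + gains +
    (class == "trisomy16") - (class == "monosomy16")
  if (length(abns) == 0L) {
    return(list(karyotype = sprintf("46,%s[20]", sex), n_abnormalities = 0L,
                class = class, sex = sex))
  }
  clone <- sprintf("%d,%s,%s[%d]", modal, sex, paste(abns, collapse = ","),
                   cells)
  if (cells < 20L) {
    clone <- sprintf("%s/46,%s[%d]", clone, sex, 20L - cells)
  }
  list(karyotype = clone, n_abnormalities = length(abns), class = class,
       sex = sex)
}

draw_category <- function(prev) {
  sample(names(prev), 1L, prob = prev)
}

#' Generate a synthetic break-apart FISH cohort
#'
#' Draws per-case result categories, nucleus-level FISH counts, ISCN
#' karyotype strings and RT-PCR outcomes from a [cohort_config()], with
#' per-case ground-truth labels, so the whole pipeline can be exercised
#' and validated in a closed loop. Every generated string parses with the
#' package's own parsers.
#'
#' @param n_patients Number of cases to generate.
#' @param config A [cohort_config()].
#' @param seed Optional integer seed; when given, the cohort is
#'   bit-reproducible.
#' @return A tibble in the case-table format consumed by [call_cases()]
#'   (`case_id`, `karyotype`, `fish`, `rtpcr_detected`,
#'   `rtpcr_ratio_percent`) plus ground-truth columns prefixed `truth_`
#'   (`truth_category`, `truth_karyotype_class`, `truth_ac16a`,
#'   `truth_n_abnormalities`, `truth_discordance_cause`).
#' @examples
#' cohort <- simulate_cohort(50, seed = 1)
#' table(cohort$truth_category)
#' @export
simulate_cohort <- function(n_patients, config = cohort_config(),
                            seed = NULL) {
  stopifnot(inherits(config, "cbfb_cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  if (n_patients == 0L) {
    return(tibble::tibble(
      case_id = character(), karyotype = character(), fish = character(),
      rtpcr_detected = logical(), rtpcr_ratio_percent = numeric(),
      truth_category = character(), truth_karyotype_class = character(),
      truth_ac16a = character(), truth_n_abnormalities = integer(),
      truth_discordance_cause = character()
    ))
  }
  rows <- vector("list", n_patients)
  fr <- config$true_fraction_range
  for (i in seq_len(n_patients)) {
    cat_i <- draw_category(config$category_prevalences)
    sex <- sample(c("XX", "XY"), 1L)
    patterns <- CATEGORY_PATTERNS[[cat_i]]
    fractions <- if (cat_i == "gain_plus_loss") {
      stats::runif(2, 10, 45)
    } else if (length(patterns) > 0L) {
      stats::runif(1, fr[[1]], fr[[2]])
    } else {
      numeric()
    }
    obs <- generate_fish_counts(patterns, fractions,
                                n_nuclei = config$nuclei_per_test,
                                noise = config$background_noise)
    detected <- FALSE
    ratio <- NA_real_
    ac16a <- "none"
    cause <- "none"
    if (cat_i == "positive") {
      kclass <- draw_category(config$karyotype_mix)
      tri22 <- stats::runif(1) < config$aca_rates[["tri22"]]
      tri8 <- stats::runif(1) < config$aca_rates[["tri8"]]
      oaca <- stats::runif(1) < config$aca_rates[["other_structural"]]
      kt <- generate_karyotype_string(kclass, sex, tri22 = tri22, tri8 = tri8,
                                      other_aca = oaca,
                                      cells = sample(c(20L, 15L, 10L), 1L))
      pcr_neg <- stats::runif(1) < config$discordance_rates[["fish_pos_pcr_neg"]]
      detected <- !pcr_neg
      if (detected) ratio <- stats::runif(1, 10, 200)
      if (pcr_neg) {
        cause <- switch(kclass, t16q22v = "novel_partner",
                        inv16 = , t1616 = "rare_transcript_variant", "none")
      }
    } else if (cat_i == "normal") {
      kt <- generate_karyotype_string("normal", sex)
      kclass <- "normal_chr16"
      detected <- stats::runif(1) < config$discordance_rates[["fish_norm_pcr_pos"]]
      if (detected) {
        ratio <- stats::runif(1, 50, 150)
        cause <- "cryptic_insertion"
      }
    } else if (cat_i == "del_3prime") {
      detected <- stats::runif(1) < config$discordance_rates[["del3_pcr_pos"]]
      if (detected) {
        ratio <- stats::runif(1, 10, 200)
        apparent <- stats::runif(1) < config$apparent_del_rate
        tri22 <- stats::runif(1) < config$aca_rates[["tri22"]]
        kt <- generate_karyotype_string(
          if (apparent) "del3_apparent" else "inv16", sex, tri22 = tri22,
          cells = sample(c(20L, 15L), 1L))
        kclass <- "inv16"
        ac16a <- if (apparent) "apparent" else "cryptic"
        cause <- "unbalanced_fusion_3del"
      } else {
        kt <- generate_karyotype_string("del16q22", sex, cells = 15L)
        kclass <- "normal_chr16"
        ac16a <- "apparent"
        cause <- "non_MYH11_chr16_event"
      }
    } else if (cat_i == "loss_one_copy") {
      kt <- generate_karyotype_string("monosomy16", sex, cells = 15L)
      kclass <- "normal_chr16"
      ac16a <- "apparent"
    } else if (cat_i == "extra_copies") {
      kt <- generate_karyotype_string("trisomy16", sex, cells = 15L)
      kclass <- "normal_chr16"
      ac16a <- "apparent"
    } else {
      # gain_plus_loss, del_5prime, gain_5prime: subclonal / cryptic events
      kt <- generate_karyotype_string("normal", sex)
      kclass <- "normal_chr16"
      if (cat_i == "del_5prime") cause <- "non_MYH11_chr16_event"
    }
    rows[[i]] <- tibble::tibble(
      case_id = sprintf("S%04d", i),
      karyotype = kt$karyotype,
      fish = serialize_nuc_ish(obs),
      rtpcr_detected = detected,
      rtpcr_ratio_percent = ratio,
      truth_category = cat_i,
      truth_karyotype_class = kclass,
      truth_ac16a = ac16a,
      truth_n_abnormalities = kt$n_abnormalities,
      truth_discordance_cause = cause
    )
  }
  dplyr::bind_rows(rows)
}
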