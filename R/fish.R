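#' Validated cutoffs for break-apart FISH signal patterns
#'
#' Thresholds are percentages of scored nuclei at or above which a pattern
#' is reported (the validated normal ranges are stated as strict `<`, so
#' the abnormal comparison is `>=`). The laboratory-validated values are
#' 4.2% for the typical rearrangement pattern (R1G1F1), 0.4% for the 3' and
#' 5' deletion patterns (R1F1, G1F1), and 5% for loss of one CBFB copy
#' (F1). No validated cutoff is published for the extra-copy (F3plus) and
#' 5'-gain (G1F2) patterns; 5% is used by symmetry with the loss cutoff and
#' can be overridden.
#'
#' @param R1G1F1,R1F1,G1F1,F1,F3plus,G1F2 Per-pattern thresholds in percent,
#'   each in (0, 100).
#' @return A named numeric vector of class `cbfb_cutoffs`.
#' @export
fish_cutoffs <- function(R1G1F1 = 4.2, R1F1 = 0.4, G1F1 = 0.4,
                         F1 = 5, F3plus = 5, G1F2 = 5) {
  x <- c(R1G1F1 = R1G1F1, R1F1 = R1F1, G1F1 = G1F1,
         F1 = F1, F3plus = F3plus, G1F2 = G1F2)
  if (any(x <= 0 | x >= 100)) {
    rlang::abort("cutoffs must lie strictly between 0 and 100 percent",
                 class = "cbfb_config_error")
  }
  structure(x, class = c("cbfb_cutoffs", "numeric"))
}

ABNORMAL_SUBTYPES <- c(
  R1F1 = "del_3prime", G1F1 = "del_5prime", F1 = "loss_one_copy",
  F3plus = "extra_copies", G1F2 = "gain_5prime"
)

#' Classify a break-apart FISH observation
#'
#' Converts per-pattern nucleus counts into the reported result category.
#' A pattern is "exceeded" when its percentage of scored nuclei is at or
#' above its cutoff. Category precedence is positive (typical R1G1F1
#' pattern exceeded) over abnormal over normal; the abnormal subtype is
#' taken from the exceeded atypical pattern, with simultaneous loss (F1)
#' and gain (F3plus) subclones reported as `gain_plus_loss`.
#'
#' @param obs A `cbfb_fish_obs` (or a `nuc ish` string, parsed strictly).
#' @param cutoffs A [fish_cutoffs()] configuration.
#' @return An object of class `cbfb_fish_interp`: list with `category`
#'   (`positive`/`normal`/`abnormal`), `abnormal_subtype` (one of
#'   `extra_copies`, `loss_one_copy`, `gain_plus_loss`, `del_3prime`,
#'   `del_5prime`, `gain_5prime`, or `NA`), `fractions` (percent per
#'   pattern), `exceeded` (pattern codes at/above cutoff) and `balance`
#'   (filled in by [balanced_state()], initially `"not_applicable"`).
#' @examples
#' classify_fish(fish_observation(c(R1G1F1 = 62), 200))
#' @export
classify_fish <- function(obs, cutoffs = fish_cutoffs()) {
  if (is.character(obs)) obs <- parse_nuc_ish(obs)
  stopifnot(inherits(obs, "cbfb_fish_obs"))
  if (obs$total_scored <= 0L) {
    rlang::abort("total_scored must be positive", class = "cbfb_fish_error")
  }
  fractions <- stats::setNames(numeric(length(PATTERN_CODES)), PATTERN_CODES)
  for (code in names(obs$counts)) {
    fractions[code] <- 100 * obs$counts[[code]] / obs$total_scored
  }
  exceeded <- character()
  for (code in names(cutoffs)) {
    if (fractions[code] >= cutoffs[[code]]) exceeded <- c(exceeded, code)
  }
  atypical <- intersect(names(ABNORMAL_SUBTYPES), exceeded)
  category <- if ("R1G1F1" %in% exceeded) {
    "positive"
  } else if (length(atypical) > 0L) {
    "abnormal"
  } else {
    "normal"
  }
  subtype <- NA_character_
  if (category == "abnormal") {
    if (all(c("F1", "F3plus") %in% atypical)) {
      subtype <- "gain_plus_loss"
    } else {
      # deletion patterns take precedence over copy-number patterns
      order <- c("R1F1", "G1F1", "F1", "F3plus", "G1F2")
      subtype <- ABNORMAL_SUBTYPES[[intersect(order, atypical)[1]]]
    }
  }
  structure(list(category = category, abnormal_subtype = subtype,
                 fractions = fractions, exceeded = exceeded,
                 balance = "not_applicable"),
            class = "cbfb_fish_interp")
}

#' Balanced vs unbalanced CBFB rearrangement by FISH
#'
#' A confirmed rearrangement whose only exceeded pattern is the typical
#' R1G1F1 is "balanced"; a confirmed rearrangement with any other exceeded
#' pattern implies simultaneous gain or loss of all or part of CBFB and is
#' "unbalanced". Unconfirmed cases, and confirmed cases in which FISH shows
#' no exceeded pattern at all (e.g. a cryptic insertion detected only by
#' RT-PCR), are `"not_applicable"`.
#'
#' @param interp A `cbfb_fish_interp`.
#' @param confirmed Logical: is the CBFB rearrangement confirmed (by FISH
#'   and/or RT-PCR)?
#' @return One of `"balanced"`, `"unbalanced"`, `"not_applicable"`.
#' @export
balanced_state <- function(interp, confirmed) {
  stopifnot(inherits(interp, "cbfb_fish_interp"))
  if (!isTRUE(confirmed)) return("not_applicable")
  others <- setdiff(interp$exceeded, "R1G1F1")
  if (length(others) > 0L) return("unbalanced")
  if ("R1G1F1" %in% interp$exceeded) return("balanced")
  "not_applicable"
}

#' @export
print.cbfb_fish_interp <- function(x, ...) {
  cat("<cbfb_fish_interp>", x$category)
  if (!is.na(x$abnormal_subtype)) cat(" (", x$abnormal_subtype, ")", sep = "")
  cat("\n  exceeded:",
      if (length(x$exceeded)) paste(x$exceeded, collapse = ", ") else "none",
      "\n  balance:", x$balance, "\n")
  invisible(x)
}

#' Tidy a FISH interpretation into one row per signal pattern
#'
#' @param x A `cbfb_fish_interp`.
#' @param ... Unused.
#' @return A tibble with pattern code, percent of nuclei, and whether the
#'   pattern is at/above its cutoff.
#' @method tidy cbfb_fish_interp
#' @export
tidy.cbfb_fish_interp <- function(x, ...) {
  tibble::tibble(
    pattern = names(x$fractions),
    percent = unname(x$fractions),
    exceeded = names(x$fractions) %in% x$exceeded
  )
}

#' One-row summary of a FISH interpretation
#'
#' @param x A `cbfb_fish_interp`.
#' @param ... Unused.
#' @return A one-row tibble: category, abnormal subtype, balance label and
#'   the percentage of the dominant abnormal pattern.
#' @method glance cbfb_fish_interp
#' @export
glance.cbfb_fish_interp <- function(x, ...) {
  abn <- x$fractions[setdiff(names(x$fractions), "F2")]
  tibble::tibble(
    category = x$category,
    abnormal_subtype = x$abnormal_subtype,
    balance = x$balance,
    max_abnormal_percent = if (length(abn)) max(abn) else 0
  )
}

#' Patient-level aggregation of repeated FISH tests
#'
#' A patient is reported positive if any test is positive; otherwise
#' abnormal if any test is abnormal; otherwise normal.
#'
#' @param categories Character vector of per-test categories
#'   (`positive`/`abnormal`/`normal`).
#' @return A single patient-level category.
#' @export
aggregate_patient_category <- function(categories) {
  if ("positive" %in% categories) return("positive")
  if ("abnormal" %in% categories) return("abnormal")
  "normal"
}
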