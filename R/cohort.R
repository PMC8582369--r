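#' Rounded percentage
#'
#' Computes `100 * numerator / denominator` rounded half-away-from-zero to
#' the requested number of decimals (the rounding convention used in
#' clinical cytogenetics reporting; note base R's `round()` rounds half to
#' even instead).
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @param decimals Number of decimals (default 1).
#' @return The rounded percentage.
#' @examples
#' proportion(262, 1629) # 16.1
#' @export
proportion <- function(numerator, denominator, decimals = 1L) {
  if (any(denominator <= 0)) {
    rlang::abort("proportion is undefined for a non-positive denominator",
                 class = "cbfb_stat_error")
  }
  x <- 100 * numerator / denominator
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction) with one
#' degree of freedom; the two-sided p-value is the upper tail of the
#' chi-square distribution. Equivalent to the closed form
#' `N * (a*d - b*c)^2 / (r1 * r2 * c1 * c2)`.
#'
#' @param a,b,c,d Cell counts, row-wise (`a`,`b` top row).
#' @return A list with `statistic` and `p_value`.
#' @examples
#' chi_square_2x2(7, 2, 132, 122) # p ~ 0.127
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    rlang::abort("degenerate 2x2 table: a row or column margin is zero",
                 class = "cbfb_stat_error")
  }
  # small expected counts trigger chisq.test's approximation warning; the
  # uncorrected Pearson statistic is the intended quantity regardless
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

# the reported result category of one case: positive / normal / abnormal
# subtype, as used for the cohort result table rows
category_label <- function(fish_category, fish_subtype) {
  dplyr::case_when(
    is.na(fish_category) ~ NA_character_,
    fish_category == "positive" ~ "positive",
    fish_category == "normal" ~ "normal",
    .default = fish_subtype
  )
}

CATEGORY_LEVELS <- c("positive", "normal", "extra_copies", "loss_one_copy",
                     "gain_plus_loss", "del_3prime", "del_5prime",
                     "gain_5prime")

#' Tabulate a called cohort
#'
#' Produces the standard cohort summaries of CBFB break-apart FISH testing:
#' result-category counts with rounded percentages, the FISH x RT-PCR
#' cross-tabulation (restricted to cases with both assays, with the
#' FISH-equivalence rule applied to the RT-PCR outcome), the karyotype x
#' FISH correlation (restricted to confirmed cases with an analyzable
#' karyotype), and 2x2 chi-square comparisons of ACA and complex-karyotype
#' prevalence between cases with and without apparent additional chromosome
#' 16 aberrations.
#'
#' @param calls Output of [call_cases()] (optionally with a `patient_id`
#'   column).
#' @param level `"test"` (default; one row per record) or `"patient"`
#'   (requires `patient_id`; a patient is positive if any test is
#'   positive).
#' @return An object of class `cbfb_cohort_summary`: list with tibbles
#'   `result_table` (category, n, percent), `fish_rtpcr_table`,
#'   `karyotype_fish_table`, `comparisons`, and `n_cases`.
#' @export
summarize_cohort <- function(calls, level = c("test", "patient")) {
  level <- match.arg(level)
  stopifnot(is.data.frame(calls))
  df <- dplyr::mutate(
    calls, .category = category_label(.data$fish_category, .data$fish_subtype)
  )
  if (level == "patient") {
    if (!"patient_id" %in% names(df)) {
      rlang::abort("patient-level tabulation requires a patient_id column",
                   class = "cbfb_stat_error")
    }
    df <- df |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        .category = aggregate_patient_level(.data$.category),
        rtpcr_positive = any_or_na(.data$rtpcr_positive),
        rtpcr_detected = any_or_na(.data$rtpcr_detected),
        confirmed_rearrangement = any_or_na(.data$confirmed_rearrangement),
        karyotype_class = first_non_na(.data$karyotype_class),
        ac16a = if (any(.data$ac16a == "apparent", na.rm = TRUE)) "apparent"
                else if (any(.data$ac16a == "cryptic", na.rm = TRUE)) "cryptic"
                else "none",
        has_other_acas = any_or_na(.data$has_other_acas),
        complex_standard = any_or_na(.data$complex_standard),
        .groups = "drop"
      )
  }
  n_cases <- sum(!is.na(df$.category))

  result_table <- df |>
    dplyr::filter(!is.na(.data$.category)) |>
    dplyr::count(category = factor(.data$.category, levels = CATEGORY_LEVELS),
                 .drop = FALSE) |>
    dplyr::mutate(category = as.character(.data$category),
                  percent = if (n_cases > 0) proportion(.data$n, n_cases, 1L)
                            else NA_real_)

  both <- dplyr::filter(df, !is.na(.data$.category), !is.na(.data$rtpcr_positive))
  fish_rtpcr_table <- both |>
    dplyr::count(category = factor(.data$.category, levels = CATEGORY_LEVELS),
                 .drop = FALSE, name = "tests") |>
    dplyr::mutate(category = as.character(.data$category)) |>
    dplyr::left_join(
      both |>
        dplyr::group_by(category = .data$.category) |>
        dplyr::summarise(pcr_positive = sum(.data$rtpcr_positive),
                         pcr_negative = sum(!.data$rtpcr_positive),
                         .groups = "drop"),
      by = "category"
    ) |>
    dplyr::mutate(
      pcr_positive = dplyr::coalesce(.data$pcr_positive, 0L),
      pcr_negative = dplyr::coalesce(.data$pcr_negative, 0L),
      pct_pcr_positive = dplyr::if_else(
        .data$tests > 0,
        proportion(.data$pcr_positive, pmax(.data$tests, 1L), 1L),
        NA_real_)
    )

  kf <- dplyr::filter(df, isTRUE_vec(.data$confirmed_rearrangement),
                      !is.na(.data$karyotype_class))
  karyotype_fish_table <- tibble::as_tibble(table(
    category = factor(kf$.category, levels = CATEGORY_LEVELS),
    karyotype_class = factor(kf$karyotype_class,
                             levels = c("normal_chr16", "inv16",
                                        "t1616", "t16q22v"))
  ))

  comparisons <- cohort_comparisons(kf)

  structure(list(result_table = result_table,
                 fish_rtpcr_table = fish_rtpcr_table,
                 karyotype_fish_table = karyotype_fish_table,
                 comparisons = comparisons,
                 n_cases = n_cases),
            class = "cbfb_cohort_summary")
}

isTRUE_vec <- function(x) !is.na(x) & x
any_or_na <- function(x) if (all(is.na(x))) NA else any(x, na.rm = TRUE)
first_non_na <- function(x) {
  y <- x[!is.na(x)]
  if (length(y)) y[[1]] else NA_character_
}
aggregate_patient_level <- function(cats) {
  cats <- cats[!is.na(cats)]
  if (length(cats) == 0L) return(NA_character_)
  if ("positive" %in% cats) return("positive")
  abn <- setdiff(cats, c("positive", "normal"))
  if (length(abn) > 0L) return(abn[[1]])
  "normal"
}

# AC16A vs non-AC16A 2x2 comparisons among confirmed cases with karyotype
cohort_comparisons <- function(kf) {
  empty <- tibble::tibble(label = character(), a = integer(), b = integer(),
                          c = integer(), d = integer(), statistic = numeric(),
                          p_value = numeric())
  if (nrow(kf) == 0L) return(empty)
  grp <- isTRUE_vec(kf$ac16a == "apparent")
  rows <- list()
  for (spec in list(
    list(label = "ACA prevalence, AC16A vs no AC16A",
         outcome = isTRUE_vec(kf$has_other_acas)),
    list(label = "Complex karyotype (standard), AC16A vs no AC16A",
         outcome = isTRUE_vec(kf$complex_standard))
  )) {
    a <- sum(grp & spec$outcome); b <- sum(grp & !spec$outcome)
    c_ <- sum(!grp & spec$outcome); d <- sum(!grp & !spec$outcome)
    test <- tryCatch(chi_square_2x2(a, b, c_, d), error = function(e) NULL)
    if (is.null(test)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      label = spec$label, a = a, b = b, c = c_, d = d,
      statistic = test$statistic, p_value = test$p_value
    )
  }
  if (length(rows) == 0L) return(empty)
  dplyr::bind_rows(rows)
}

#' @export
print.cbfb_cohort_summary <- function(x, ...) {
  cat("<cbfb_cohort_summary>", x$n_cases, "cases\n\n")
  cat("Reported FISH results:\n")
  rt <- x$result_table
  for (i in seq_len(nrow(rt))) {
    cat(sprintf("  %-15s %5d (%s%%)\n", rt$category[i], rt$n[i],
                format(rt$percent[i])))
  }
  ft <- dplyr::filter(x$fish_rtpcr_table, .data$tests > 0)
  if (nrow(ft) > 0) {
    cat("\nFISH x RT-PCR (cases with both assays):\n")
    for (i in seq_len(nrow(ft))) {
      cat(sprintf("  %-15s %5d tests: %d PCR-positive (%s%%), %d negative\n",
                  ft$category[i], ft$tests[i], ft$pcr_positive[i],
                  format(ft$pct_pcr_positive[i]), ft$pcr_negative[i]))
    }
  }
  if (nrow(x$comparisons) > 0) {
    cat("\nComparisons:\n")
    for (i in seq_len(nrow(x$comparisons))) {
      cm <- x$comparisons[i, ]
      cat(sprintf("  %s: %d/%d vs %d/%d, chi2 = %.3f, p = %.3f\n",
                  cm$label, cm$a, cm$a + cm$b, cm$c, cm$c + cm$d,
                  cm$statistic, cm$p_value))
    }
  }
  invisible(x)
}

#' Tidy a cohort summary into a long table
#'
#' @param x A `cbfb_cohort_summary`.
#' @param ... Unused.
#' @return The result-category tibble (category, n, percent).
#' @method tidy cbfb_cohort_summary
#' @export
tidy.cbfb_cohort_summary <- function(x, ...) x$result_table

#' One-row overview of a cohort summary
#'
#' @param x A `cbfb_cohort_summary`.
#' @param ... Unused.
#' @return A one-row tibble with cohort size and headline percentages.
#' @method glance cbfb_cohort_summary
#' @export
glance.cbfb_cohort_summary <- function(x, ...) {
  g <- function(cat) {
    row <- dplyr::filter(x$result_table, .data$category == cat)
    if (nrow(row) == 0L) 0 else row$percent[[1]]
  }
  abnormal_n <- sum(dplyr::filter(
    x$result_table, !.data$category %in% c("positive", "normal"))$n)
  tibble::tibble(
    n_cases = x$n_cases,
    pct_positive = g("positive"),
    pct_normal = g("normal"),
    pct_abnormal = if (x$n_cases > 0) proportion(abnormal_n, x$n_cases, 1L)
                   else NA_real_
  )
}
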