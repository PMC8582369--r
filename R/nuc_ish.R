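#' Break-apart FISH signal pattern codes
#'
#' Per-nucleus signal configurations of the CBFB break-apart probe
#' (red = 5' probe, green = 3' probe, fusion = co-localised):
#' `F2` two fusions (normal), `R1G1F1` one red/one green/one fusion
#' (typical rearrangement), `R1F1` 3' deletion, `G1F1` 5' deletion,
#' `F1` loss of one CBFB copy, `F3plus` extra copies, `G1F2` 5' gain.
#'
#' @format Character vector of the seven recognised codes.
#' @export
PATTERN_CODES <- c("F2", "R1G1F1", "R1F1", "G1F1", "F1", "F3plus", "G1F2")

#' Construct an interphase FISH observation
#'
#' @param counts Named numeric vector of nucleus counts per signal pattern
#'   (names from [PATTERN_CODES]). Patterns not listed are taken as zero.
#' @param total_scored Number of nuclei scored (default 200, the routine
#'   scoring denominator).
#' @param metaphase_note Optional verbatim metaphase `ish` text accompanying
#'   the interphase result.
#' @return An object of class `cbfb_fish_obs`.
#' @examples
#' fish_observation(c(R1G1F1 = 62), total_scored = 200)
#' @export
fish_observation <- function(counts = integer(), total_scored = 200L,
                             metaphase_note = NA_character_) {
  counts <- counts[counts != 0]
  if (length(counts) > 0L) {
    bad <- setdiff(names(counts), PATTERN_CODES)
    if (length(bad) > 0L) {
      rlang::abort(paste0("unknown signal pattern code(s): ",
                          paste(bad, collapse = ", ")),
                   class = "cbfb_fish_error")
    }
    if (any(counts < 0)) {
      rlang::abort("signal pattern counts must be non-negative",
                   class = "cbfb_fish_error")
    }
  }
  total_scored <- as.integer(total_scored)
  if (is.na(total_scored) || total_scored <= 0L) {
    rlang::abort("total_scored must be a positive integer",
                 class = "cbfb_fish_error")
  }
  if (sum(counts) > total_scored) {
    rlang::abort("pattern counts exceed the number of scored nuclei",
                 class = "cbfb_fish_error")
  }
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, total_scored = total_scored,
                 metaphase_note = metaphase_note),
            class = "cbfb_fish_obs")
}

abort_nucish <- function(msg, token, offset) {
  rlang::abort(
    sprintf("nuc ish parse error: %s (near \"%s\" at offset %d)", msg, token, offset),
    class = "cbfb_parse_error", token = token, offset = offset
  )
}

# accept both the Unicode prime and the ASCII apostrophe
normalize_primes <- function(x) stringr::str_replace_all(x, "′", "'")

copy_counts <- function(clause) {
  cl <- normalize_primes(clause)
  five <- stringr::str_match(cl, "5'CBFBx([0-9]+)")[1, 2]
  three <- stringr::str_match(cl, "3'CBFBx([0-9]+)")[1, 2]
  if (is.na(five) && is.na(three)) {
    both <- stringr::str_match(cl, "^\\s*CBFBx([0-9]+)\\s*$")[1, 2]
    if (!is.na(both)) {
      five <- both
      three <- both
    }
  }
  c(five = as.integer(five), three = as.integer(three))
}

# map one clause-group segment to a signal pattern code
segment_pattern <- function(clauses, lenient, full) {
  norm <- normalize_primes(clauses)
  has_sep <- any(stringr::str_detect(norm, "\\bsep\\b"))
  has_con <- any(stringr::str_detect(norm, "\\bcon\\b"))
  if (has_sep) return("R1G1F1")
  copy_clause <- clauses[!stringr::str_detect(norm, "\\b(sep|con)\\b")]
  cc <- if (length(copy_clause) > 0L) copy_counts(copy_clause[[1]]) else
    c(five = NA_integer_, three = NA_integer_)
  if (has_con) {
    if (!is.na(cc[["five"]]) && !is.na(cc[["three"]])) {
      key <- paste(cc[["five"]], cc[["three"]], sep = "/")
      out <- switch(key, "2/1" = "R1F1", "1/2" = "G1F1",
                    "3/2" = "G1F2", "2/3" = "F3plus", NA_character_)
      if (!is.na(out)) return(out)
    }
    if (lenient) return(NA_character_)
    abort_nucish("cannot resolve the signal pattern of a 'con' clause",
                 token = paste(clauses, collapse = ""), offset = 1L)
  }
  if (!is.na(cc[["five"]]) || !is.na(cc[["three"]])) {
    n <- max(cc, na.rm = TRUE)
    n_min <- min(cc, na.rm = TRUE)
    if (n == 2L && n_min == 2L) return("F2")
    if (n == 1L) return("F1")
    if (n >= 3L) return("F3plus")
    return("F2")
  }
  if (lenient) return(NA_character_)
  abort_nucish("unrecognised probe clause", token = paste(clauses, collapse = ""),
               offset = 1L)
}

#' Parse ISCN "nuc ish" nomenclature into a FISH observation
#'
#' Understands the interphase result strings of CBFB break-apart testing,
#' e.g. `"nuc ish(CBFBx2)(5'CBFB sep 3'CBFBx1)[62/200]"`. `sep` clauses map
#' to the typical rearrangement pattern (R1G1F1); `con` clauses map to the
#' atypical patterns according to the probe copy numbers (5'x2/3'x1 is a 3'
#' deletion, 5'x1/3'x2 a 5' deletion). A bracket `[a/b]` records `a`
#' abnormal nuclei of `b` scored; a bare `[n]` records the clause pattern in
#' all `n` scored nuclei. A leading metaphase `ish ...` section is stored
#' verbatim as `metaphase_note`. Unicode primes and ASCII apostrophes are
#' both accepted.
#'
#' @param text A `nuc ish` string (optionally preceded by a metaphase `ish`
#'   section).
#' @param lenient Logical; when `TRUE`, typographically damaged strings are
#'   recovered by token salvage (unmatched text is skipped and a stray
#'   number standing where a bracket should be is read as the scored total).
#'   The default strict mode raises a parse error with the offending text
#'   and offset.
#' @return A `cbfb_fish_obs` (see [fish_observation()]).
#' @examples
#' parse_nuc_ish("nuc ish(CBFBx2)(5'CBFB sep 3'CBFBx1)[62/200]")
#' @export
parse_nuc_ish <- function(text, lenient = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- text
  note <- NA_character_
  loc <- stringr::str_locate(raw, stringr::fixed("nuc ish"))
  if (is.na(loc[1, 1])) {
    if (stringr::str_detect(stringr::str_trim(raw), "^ish")) {
      # metaphase-only record
      return(fish_observation(total_scored = 200L,
                              metaphase_note = stringr::str_trim(raw)))
    }
    abort_nucish("input does not contain 'nuc ish' (or start with 'ish')",
                 token = stringr::str_trunc(raw, 30), offset = 1L)
  }
  if (loc[1, 1] > 1L) note <- stringr::str_sub(raw, 1L, loc[1, 1] - 1L)
  rest <- stringr::str_sub(raw, loc[1, 2] + 1L)

  item_pat <- "\\(([^()]*)\\)|\\[([^\\]]*)\\]"
  m <- stringr::str_locate_all(rest, item_pat)[[1]]
  items <- stringr::str_sub(rest, m[, 1], m[, 2])
  # strict mode: everything outside clause groups and brackets must be blank
  covered <- rep(FALSE, nchar(rest))
  if (nrow(m) > 0L) {
    for (i in seq_len(nrow(m))) covered[seq(m[i, 1], m[i, 2])] <- TRUE
  }
  leftover_chars <- stringr::str_split(rest, "")[[1]][!covered]
  leftover <- paste(leftover_chars, collapse = "")
  if (!lenient && stringr::str_detect(leftover, "\\S")) {
    bad <- stringr::str_trim(leftover)
    abort_nucish("unrecognised text outside clauses/brackets", token = bad,
                 offset = token_offset(raw, stringr::str_sub(bad, 1L, 5L)))
  }

  counts <- integer()
  total <- NA_integer_
  clauses <- character()
  close_segment <- function(bracket_content) {
    bc <- stringr::str_remove_all(bracket_content, "\\s+")
    bm <- stringr::str_match(bc, "^([0-9]+)(?:/([0-9]+))?$")
    if (is.na(bm[1, 1])) {
      if (!lenient) {
        abort_nucish("malformed bracketed nucleus count", token = bracket_content,
                     offset = token_offset(raw, bracket_content))
      }
      return(invisible(NULL))
    }
    count <- as.integer(bm[1, 2])
    denom <- if (is.na(bm[1, 3])) count else as.integer(bm[1, 3])
    pat <- segment_pattern(clauses, lenient, raw)
    if (!is.na(pat)) {
      counts[pat] <<- sum(counts[pat], count, na.rm = TRUE)
    }
    total <<- max(total, denom, na.rm = TRUE)
    clauses <<- character()
  }
  for (it in items) {
    if (stringr::str_starts(it, stringr::fixed("("))) {
      clauses <- c(clauses, stringr::str_sub(it, 2L, -2L))
    } else {
      inner <- stringr::str_sub(it, 2L, -2L)
      if (length(clauses) == 0L) next  # metaphase-style bracket, already in note
      close_segment(inner)
    }
  }
  if (length(clauses) > 0L) {
    # clause group with no closing bracket: salvage a total in lenient mode
    if (lenient) {
      num <- stringr::str_match(leftover, "([0-9]+)")[1, 2]
      if (!is.na(num)) close_segment(num)
    } else {
      abort_nucish("clause group has no bracketed nucleus count",
                   token = clauses[[length(clauses)]], offset = nchar(raw))
    }
  }
  if (is.na(total)) total <- 200L
  # a pure normal observation records its F2 nuclei; drop implicit zeros
  fish_observation(counts = counts, total_scored = total, metaphase_note = note)
}

#' Serialize a FISH observation to "nuc ish" nomenclature
#'
#' Canonical clause forms are emitted per pattern (with Unicode primes), so
#' that parsing the output reproduces the observation.
#'
#' @param obs A `cbfb_fish_obs`.
#' @return A single `nuc ish` string.
#' @export
serialize_nuc_ish <- function(obs) {
  stopifnot(inherits(obs, "cbfb_fish_obs"))
  p <- "′"
  forms <- c(
    F2 = "(CBFBx2)",
    R1G1F1 = paste0("(CBFBx2)(5", p, "CBFB sep 3", p, "CBFBx1)"),
    R1F1 = paste0("(5", p, "CBFBx2,3", p, "CBFBx1)(5", p, "CBFB con 3", p, "CBFBx1)"),
    G1F1 = paste0("(5", p, "CBFBx1,3", p, "CBFBx2)(5", p, "CBFB con 3", p, "CBFBx1)"),
    F1 = "(CBFBx1)",
    F3plus = "(CBFBx3)",
    G1F2 = paste0("(5", p, "CBFBx3,3", p, "CBFBx2)(5", p, "CBFB con 3", p, "CBFBx2)")
  )
  segs <- character()
  for (code in PATTERN_CODES) {
    n <- obs$counts[code]
    if (!is.na(n) && n > 0L) {
      segs <- c(segs, paste0(forms[[code]], "[", n, "/", obs$total_scored, "]"))
    }
  }
  if (length(segs) == 0L) {
    segs <- paste0(forms[["F2"]], "[", obs$total_scored, "]")
  }
  prefix <- if (!is.na(obs$metaphase_note)) obs$metaphase_note else ""
  paste0(prefix, "nuc ish", paste(segs, collapse = ""))
}

#' @export
print.cbfb_fish_obs <- function(x, ...) {
  cat("<cbfb_fish_obs>", x$total_scored, "nuclei scored\n")
  if (length(x$counts) == 0L) {
    cat("  no abnormal signal patterns recorded\n")
  } else {
    for (nm in names(x$counts)) {
      cat(sprintf("  %-7s %4d (%.1f%%)\n", nm, x$counts[[nm]],
                  100 * x$counts[[nm]] / x$total_scored))
    }
  }
  if (!is.na(x$metaphase_note)) cat("  metaphase:", x$metaphase_note, "\n")
  invisible(x)
}
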