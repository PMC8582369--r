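#' Parse an ISCN 2020 karyotype string
#'
#' Parses the karyotype dialect used in routine G-banded reporting of
#' inv(16)/t(16;16) AML into a typed clone/abnormality model. Supported
#' constructs are those seen in clinical reports of this disease: modal
#' numbers (including ranges such as `43~45` or `43-46`), sex designations,
#' whole-chromosome gains/losses (`+8`, `-7`, Unicode minus accepted),
#' markers (`+mar`, `+1~2mar`), `inv`, `t`, `del`, `add`, compound `der`
#' chromosomes with embedded events, `idem`/`sl` stemline references,
#' composite `[cp..]` clones, and chimeric donor clones after `//`.
#'
#' @param text A single ISCN karyotype string, e.g.
#'   `"47,XY,inv(16)(p13.1q22),+22[20]"`.
#' @param lenient Logical. In lenient mode the parser tolerates two
#'   typographical artifacts seen in published reports: whitespace inside
#'   bracketed cell counts (`[1 2]` read as `[12]`, always accepted) and a
#'   trailing clone with a missing bracketed count (recorded with
#'   `cell_count = NA`). In strict mode (default) a missing count is an error.
#' @return An object of class `cbfb_karyotype`: a list with elements `raw`
#'   (the input string), `clones` (list of clones, each with `modal_raw`,
#'   `modal` (integer range), `sex`, `idem_ref`, `abnormalities`,
#'   `cell_count`, `composite`, `chimeric_donor`, `resolved`) and `status`
#'   (`"normal"` or `"parsed"`).
#' @seealso [resolve_idem()], [count_abnormalities()], [chr16_events()],
#'   [serialize_iscn()]
#' @examples
#' k <- parse_iscn("47,XY,inv(16)(p13.1q22),+22[20]")
#' tidy(k)
#' @export
parse_iscn <- function(text, lenient = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- stringr::str_trim(text)
  if (!nzchar(raw)) {
    abort_parse("empty karyotype string", token = "", offset = 1L)
  }
  segments <- stringr::str_split(raw, stringr::fixed("//"))[[1]]
  clones <- list()
  for (seg_i in seq_along(segments)) {
    donor <- seg_i > 1L
    clone_strings <- stringr::str_split(segments[[seg_i]], stringr::fixed("/"))[[1]]
    for (cs in clone_strings) {
      clones[[length(clones) + 1L]] <-
        parse_clone(cs, donor = donor, lenient = lenient, full = raw)
    }
  }
  status <- if (all(vapply(clones, function(cl) {
    length(cl$abnormalities) == 0L && is.na(cl$idem_ref)
  }, logical(1)))) "normal" else "parsed"
  structure(list(raw = raw, clones = clones, status = status),
            class = "cbfb_karyotype")
}

abort_parse <- function(msg, token, offset) {
  rlang::abort(
    sprintf("ISCN parse error: %s (token \"%s\" at offset %d)", msg, token, offset),
    class = "cbfb_parse_error", token = token, offset = offset
  )
}

token_offset <- function(full, token) {
  loc <- stringr::str_locate(full, stringr::fixed(token))[1, 1]
  if (is.na(loc)) 1L else as.integer(loc)
}

parse_clone <- function(clone_string, donor, lenient, full) {
  cs <- stringr::str_trim(clone_string)
  bracket <- stringr::str_match(cs, "\\[([^\\]]*)\\]\\s*$")
  composite <- FALSE
  cell_count <- NA_integer_
  if (!is.na(bracket[1, 1])) {
    inside <- stringr::str_trim(bracket[1, 2])
    composite <- stringr::str_detect(inside, "^cp")
    digits <- stringr::str_remove_all(stringr::str_remove(inside, "^cp"), "\\s+")
    if (!stringr::str_detect(digits, "^[0-9]+$")) {
      abort_parse("malformed bracketed cell count", token = bracket[1, 1],
                  offset = token_offset(full, bracket[1, 1]))
    }
    cell_count <- as.integer(digits)
    if (cell_count < 1L) {
      abort_parse("cell count must be >= 1", token = bracket[1, 1],
                  offset = token_offset(full, bracket[1, 1]))
    }
    cs <- stringr::str_trim(stringr::str_remove(cs, "\\[[^\\]]*\\]\\s*$"))
  } else if (!lenient) {
    abort_parse("clone is missing its bracketed cell count", token = cs,
                offset = token_offset(full, cs))
  }
  if (stringr::str_count(cs, "\\(") != stringr::str_count(cs, "\\)")) {
    abort_parse("unbalanced parentheses", token = cs,
                offset = token_offset(full, cs))
  }
  tokens <- split_top_level(cs)
  if (length(tokens) == 0L) {
    abort_parse("empty clone", token = clone_string,
                offset = token_offset(full, clone_string))
  }
  modal_raw <- tokens[[1]]
  modal <- parse_modal(modal_raw, full)
  tokens <- tokens[-1]
  sex <- NA_character_
  idem_ref <- NA_character_
  if (length(tokens) > 0L && stringr::str_detect(tokens[[1]], "^[XY?]+$")) {
    sex <- tokens[[1]]
    tokens <- tokens[-1]
  }
  if (length(tokens) > 0L && tokens[[1]] %in% c("idem", "sl", "sdl1", "sdl2")) {
    idem_ref <- tokens[[1]]
    tokens <- tokens[-1]
  }
  abnormalities <- lapply(tokens, parse_abnormality, full = full)
  list(
    modal_raw = modal_raw, modal = modal, sex = sex, idem_ref = idem_ref,
    abnormalities = abnormalities, cell_count = cell_count,
    composite = composite, chimeric_donor = donor,
    resolved = is.na(idem_ref)
  )
}

# split on commas at parenthesis depth 0 ("p13,1" inside parens stays intact)
split_top_level <- function(x) {
  chars <- stringr::str_split(x, "")[[1]]
  depth <- 0L
  out <- character()
  buf <- character()
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) {
      out <- c(out, paste(buf, collapse = ""))
      buf <- character()
    } else {
      buf <- c(buf, ch)
    }
  }
  out <- c(out, paste(buf, collapse = ""))
  out <- stringr::str_trim(out)
  out[nzchar(out)]
}

parse_modal <- function(tok, full) {
  m <- stringr::str_match(tok, "^\\??([0-9]+)(?:\\s*[~–—-]\\s*([0-9]+))?$")
  if (is.na(m[1, 1])) {
    abort_parse("expected a modal chromosome number", token = tok,
                offset = token_offset(full, tok))
  }
  lo <- as.integer(m[1, 2])
  hi <- if (is.na(m[1, 3])) lo else as.integer(m[1, 3])
  c(lo, hi)
}

STRUCTURAL_TYPES <- c(
  t = "translocation", inv = "inversion", del = "deletion", add = "addition",
  der = "derivative", dup = "other_structural", ins = "other_structural",
  i = "other_structural", dic = "other_structural", trp = "other_structural"
)

new_abnormality <- function(raw, category, chromosomes = character(),
                            breakpoints = empty_breakpoints(),
                            embedded = list(), uncertain = FALSE) {
  list(raw = raw, category = category, chromosomes = chromosomes,
       breakpoints = breakpoints, embedded = embedded, uncertain = uncertain)
}

empty_breakpoints <- function() {
  tibble::tibble(chrom = character(), band = character())
}

parse_abnormality <- function(tok, full = tok) {
  tok <- stringr::str_trim(tok)
  uncertain <- stringr::str_detect(tok, stringr::fixed("?"))
  clean <- stringr::str_remove_all(tok, stringr::fixed("?"))
  # whole-chromosome gains, markers
  if (stringr::str_detect(clean, "^\\+")) {
    body <- stringr::str_remove(clean, "^\\+")
    if (stringr::str_detect(body, "mar$")) {
      return(new_abnormality(tok, "marker", chromosomes = "mar",
                             uncertain = uncertain))
    }
    if (stringr::str_detect(body, "^([0-9]+|[XY])$")) {
      return(new_abnormality(tok, "numerical_gain", chromosomes = body,
                             uncertain = uncertain))
    }
  }
  # whole-chromosome losses (ASCII hyphen, Unicode minus or en dash)
  if (stringr::str_detect(clean, "^[-−–]")) {
    body <- stringr::str_remove(clean, "^[-−–]")
    if (stringr::str_detect(body, "^([0-9]+|[XY])$")) {
      return(new_abnormality(tok, "numerical_loss", chromosomes = body,
                             uncertain = uncertain))
    }
  }
  units <- match_structural_units(clean)
  if (is.null(units)) {
    abort_parse("unknown abnormality token", token = tok,
                offset = token_offset(full, tok))
  }
  build_structural(tok, units, uncertain, full)
}

# decompose e.g. "der(16)inv(16)(p13.1q22)del(16)(q22q34)" into typed units;
# returns NULL when the token is not a recognised unit sequence
match_structural_units <- function(x) {
  pattern <- "([a-z]+)\\(([^()]+)\\)(\\(([^()]+)\\))?"
  m <- stringr::str_match_all(x, pattern)[[1]]
  if (nrow(m) == 0L) return(NULL)
  consumed <- sum(nchar(m[, 1]))
  if (consumed != nchar(x)) return(NULL)
  if (!all(m[, 2] %in% names(STRUCTURAL_TYPES))) return(NULL)
  m
}

build_structural <- function(raw, units, uncertain, full) {
  first_type <- units[1, 2]
  if (first_type == "der" && nrow(units) > 1L) {
    der_chroms <- split_semis(units[1, 3])
    embedded <- lapply(seq(2, nrow(units)), function(i) {
      build_structural(units[i, 1], units[i, , drop = FALSE], FALSE, full)
    })
    bps <- unit_breakpoints(der_chroms, units[1, 5])
    return(new_abnormality(raw, "derivative", chromosomes = der_chroms,
                           breakpoints = bps, embedded = embedded,
                           uncertain = uncertain))
  }
  if (nrow(units) > 1L) {
    abort_parse("unknown abnormality token", token = raw,
                offset = token_offset(full, raw))
  }
  type <- STRUCTURAL_TYPES[[units[1, 2]]]
  chroms <- split_semis(units[1, 3])
  bps <- unit_breakpoints(chroms, units[1, 5])
  if (type == "derivative") {
    return(new_abnormality(raw, "derivative", chromosomes = chroms,
                           breakpoints = bps, uncertain = uncertain))
  }
  new_abnormality(raw, type, chromosomes = chroms, breakpoints = bps,
                  uncertain = uncertain)
}

split_semis <- function(x) {
  if (is.na(x)) return(character())
  stringr::str_trim(stringr::str_split(x, stringr::fixed(";"))[[1]])
}

# pair printed bands with their chromosome: "(q21;q22)" against t(1;16),
# "(p13.1q22)" against inv(16)
unit_breakpoints <- function(chroms, band_group) {
  if (is.na(band_group) || length(chroms) == 0L) return(empty_breakpoints())
  parts <- split_semis(band_group)
  rows <- list()
  for (i in seq_along(parts)) {
    chrom <- chroms[min(i, length(chroms))]
    bands <- stringr::str_extract_all(parts[[i]], "[pq][0-9][0-9.,]*|cen|ter")[[1]]
    for (b in bands) {
      rows[[length(rows) + 1L]] <- tibble::tibble(chrom = chrom, band = b)
    }
  }
  if (length(rows) == 0L) return(empty_breakpoints())
  dplyr::bind_rows(rows)
}

#' Serialize a karyotype model back to an ISCN string
#'
#' Emits a canonical ISCN string from a parsed model. Verbatim abnormality
#' tokens are preserved; bracket whitespace artifacts are normalised (a
#' parsed `[1 2]` serializes as `[12]`), so serialization followed by
#' re-parsing is the identity on the model.
#'
#' @param karyotype A `cbfb_karyotype`.
#' @return A single ISCN string.
#' @export
serialize_iscn <- function(karyotype) {
  stopifnot(inherits(karyotype, "cbfb_karyotype"))
  fmt_clone <- function(cl) {
    parts <- cl$modal_raw
    if (!is.na(cl$sex)) parts <- c(parts, cl$sex)
    if (!is.na(cl$idem_ref)) parts <- c(parts, cl$idem_ref)
    own <- if (!is.null(cl$own_abnormalities)) cl$own_abnormalities else cl$abnormalities
    parts <- c(parts, vapply(own, function(a) a$raw, character(1)))
    out <- paste(parts, collapse = ",")
    if (!is.na(cl$cell_count)) {
      out <- paste0(out, "[", if (cl$composite) "cp" else "", cl$cell_count, "]")
    }
    out
  }
  host <- vapply(Filter(function(cl) !cl$chimeric_donor, karyotype$clones),
                 fmt_clone, character(1))
  donor <- vapply(Filter(function(cl) cl$chimeric_donor, karyotype$clones),
                  fmt_clone, character(1))
  out <- paste(host, collapse = "/")
  if (length(donor) > 0L) out <- paste0(out, "//", paste(donor, collapse = "/"))
  out
}

#' Expand idem/sl stemline references
#'
#' Clones written as `46,idem,+8,+22[3]` inherit the abnormalities of the
#' stem clone (the first listed abnormal clone in the same specimen).
#' Expansion prepends the stem abnormalities to the clone's own and is
#' idempotent. The verbatim clone-specific tokens are retained so that
#' [serialize_iscn()] still emits the original `idem` form.
#'
#' @param karyotype A `cbfb_karyotype`.
#' @return The karyotype with every `idem`/`sl` clone carrying its full
#'   expanded abnormality list (`resolved = TRUE`).
#' @export
resolve_idem <- function(karyotype) {
  stopifnot(inherits(karyotype, "cbfb_karyotype"))
  needs <- vapply(karyotype$clones,
                  function(cl) !is.na(cl$idem_ref) && !isTRUE(cl$resolved),
                  logical(1))
  if (!any(needs)) return(karyotype)
  stem <- NULL
  for (cl in karyotype$clones) {
    if (!cl$chimeric_donor && is.na(cl$idem_ref) && length(cl$abnormalities) > 0L) {
      stem <- cl
      break
    }
  }
  if (is.null(stem)) {
    rlang::abort("idem/sl reference with no stem clone to expand from",
                 class = "cbfb_resolve_error")
  }
  karyotype$clones <- lapply(karyotype$clones, function(cl) {
    if (!is.na(cl$idem_ref) && !isTRUE(cl$resolved)) {
      cl$own_abnormalities <- cl$abnormalities
      cl$abnormalities <- c(stem$abnormalities, cl$abnormalities)
      cl$resolved <- TRUE
    }
    cl
  })
  karyotype
}

#' Abnormality-counting policy
#'
#' @param exclude Character vector of verbatim constitutional-polymorphism
#'   tokens excluded from abnormality counts. The default, `inv(9)(p12q13)`,
#'   is a polymorphism present in healthy individuals.
#' @param mar_structural Should marker chromosomes (`+mar`) satisfy the
#'   "at least one structural abnormality" requirement of the complex-
#'   karyotype rule? Markers always count toward the total; their origin is
#'   unknown, so by default they do not count as structural.
#' @return A list of class `cbfb_counting_policy`.
#' @export
counting_policy <- function(exclude = "inv(9)(p12q13)", mar_structural = FALSE) {
  structure(list(exclude = exclude, mar_structural = mar_structural),
            class = "cbfb_counting_policy")
}

normalize_token <- function(x) stringr::str_remove_all(x, "\\s+")

STRUCTURAL_CATEGORIES <- c("inversion", "translocation", "deletion",
                           "addition", "derivative", "other_structural")

#' Count clonal abnormalities in one clone
#'
#' Counts each top-level listed abnormality once: a compound derivative such
#' as `der(16)inv(16)(p13.1q22)del(16)(q22q34)` is a single abnormality.
#' Constitutional polymorphisms on the policy exclusion list are skipped,
#' and chimeric donor clones contribute nothing.
#'
#' @param clone A clone from a resolved `cbfb_karyotype`.
#' @param policy A [counting_policy()].
#' @return Named integer vector `c(n_total, n_structural, n_numerical)`.
#' @export
count_abnormalities <- function(clone, policy = counting_policy()) {
  if (!is.na(clone$idem_ref) && !isTRUE(clone$resolved)) {
    rlang::abort("clone has an unexpanded idem/sl reference; call resolve_idem() first",
                 class = "cbfb_resolve_error")
  }
  zero <- c(n_total = 0L, n_structural = 0L, n_numerical = 0L)
  if (isTRUE(clone$chimeric_donor)) return(zero)
  excl <- normalize_token(policy$exclude)
  n_total <- 0L; n_structural <- 0L; n_numerical <- 0L
  for (a in clone$abnormalities) {
    if (normalize_token(a$raw) %in% excl) next
    n_total <- n_total + 1L
    if (a$category %in% STRUCTURAL_CATEGORIES) {
      n_structural <- n_structural + 1L
    } else if (a$category == "marker") {
      if (isTRUE(policy$mar_structural)) n_structural <- n_structural + 1L
      else n_numerical <- n_numerical + 1L
    } else {
      n_numerical <- n_numerical + 1L
    }
  }
  c(n_total = n_total, n_structural = n_structural, n_numerical = n_numerical)
}

# prefix band matching at sub-band resolution: p13 matches p13.1/p13.3,
# q13 does not match q22
band_match <- function(band, family) {
  if (is.na(band) || !nzchar(band)) return(FALSE)
  if (band == family) return(TRUE)
  if (stringr::str_starts(band, family)) {
    nxt <- stringr::str_sub(band, nchar(family) + 1L, nchar(family) + 1L)
    return(nxt %in% c(".", ","))
  }
  FALSE
}

involves_chr16 <- function(a) {
  "16" %in% a$chromosomes || any(a$breakpoints$chrom == "16") ||
    any(vapply(a$embedded, involves_chr16, logical(1)))
}

# CBFB-compatible primary signature: inv(16) with breakpoints in the p13
# family and at q22; or any translocation with a 16q22 breakpoint
# (covers t(16;16)(p13;q22) and t(16q22;v))
is_primary_cbfb <- function(a) {
  if (a$category == "inversion" && "16" %in% a$chromosomes) {
    bands <- a$breakpoints$band
    return(any(vapply(bands, band_match, logical(1), family = "p13")) &&
             any(vapply(bands, band_match, logical(1), family = "q22")))
  }
  if (a$category == "translocation") {
    hit <- a$breakpoints$chrom == "16" &
      vapply(a$breakpoints$band, band_match, logical(1), family = "q22")
    return(any(hit))
  }
  FALSE
}

#' Partition chromosome 16 events into primary and additional
#'
#' The primary events are those with a CBFB-compatible signature:
#' `inv(16)` with one breakpoint in the p13 band family and the other at
#' q22, `t(16;16)(p13;q22)`, or any translocation with a 16q22 breakpoint
#' (`t(16q22;v)`). Every other chromosome 16 involvement — `del(16)`,
#' `add(16)`, whole-chromosome 16 gains/losses, and non-q22 translocations —
#' is an additional chromosome 16 aberration (AC16A). Compound derivatives
#' are decomposed: an embedded event matching the primary signature is
#' reported as primary and the remaining embedded chromosome 16 events
#' (e.g. an accompanying `del(16)(q22q34)`) as additional; a derivative with
#' no primary-signature component is reported whole as one additional event.
#'
#' @param karyotype A `cbfb_karyotype` (idem references are resolved
#'   automatically). Chimeric donor clones are ignored.
#' @return A list with elements `primary` and `additional`, each a list of
#'   abnormality records (deduplicated across clones by verbatim token).
#' @export
chr16_events <- function(karyotype) {
  stopifnot(inherits(karyotype, "cbfb_karyotype"))
  karyotype <- resolve_idem(karyotype)
  primary <- list(); additional <- list()
  seen_primary <- character(); seen_additional <- character()
  add_primary <- function(a) {
    key <- normalize_token(a$raw)
    if (!key %in% seen_primary) {
      seen_primary <<- c(seen_primary, key)
      primary[[length(primary) + 1L]] <<- a
    }
  }
  add_additional <- function(a) {
    key <- normalize_token(a$raw)
    if (!key %in% seen_additional) {
      seen_additional <<- c(seen_additional, key)
      additional[[length(additional) + 1L]] <<- a
    }
  }
  for (cl in karyotype$clones) {
    if (cl$chimeric_donor) next
    for (a in cl$abnormalities) {
      if (a$category == "derivative" && length(a$embedded) > 0L) {
        prim_idx <- vapply(a$embedded, is_primary_cbfb, logical(1))
        if (any(prim_idx)) {
          for (e in a$embedded[prim_idx]) add_primary(e)
          for (e in a$embedded[!prim_idx]) if (involves_chr16(e)) add_additional(e)
        } else if (involves_chr16(a)) {
          add_additional(a)
        }
      } else if (is_primary_cbfb(a)) {
        add_primary(a)
      } else if (involves_chr16(a)) {
        add_additional(a)
      }
    }
  }
  list(primary = primary, additional = additional)
}

#' Classify the chromosome 16 configuration of a karyotype
#'
#' @param karyotype A `cbfb_karyotype`, or `NULL`/missing.
#' @return One of `"inv16"`, `"t1616"`, `"t16q22v"`, `"normal_chr16"`, or
#'   `NA` when the karyotype is unavailable.
#' @export
chr16_class <- function(karyotype) {
  if (is.null(karyotype) || !inherits(karyotype, "cbfb_karyotype")) {
    return(NA_character_)
  }
  ev <- chr16_events(karyotype)
  cats <- vapply(ev$primary, function(a) a$category, character(1))
  if (any(cats == "inversion")) return("inv16")
  if (length(ev$primary) > 0L) {
    both16 <- vapply(ev$primary, function(a) {
      a$category == "translocation" && sum(a$chromosomes == "16") >= 2L
    }, logical(1))
    if (any(both16)) return("t1616")
    return("t16q22v")
  }
  "normal_chr16"
}

#' @export
print.cbfb_karyotype <- function(x, ...) {
  cat("<cbfb_karyotype> status:", x$status, "\n")
  cat(" ", serialize_iscn(x), "\n")
  cat("  clones:", length(x$clones),
      " cells:", sum(vapply(x$clones, function(cl) {
        if (is.na(cl$cell_count)) 0L else cl$cell_count
      }, integer(1))), "\n")
  invisible(x)
}

#' Tidy a parsed karyotype into one row per abnormality
#'
#' @param x A `cbfb_karyotype`.
#' @param ... Unused.
#' @return A tibble with one row per clone-level abnormality: clone index,
#'   cell count, verbatim token, category, chromosomes, and flags.
#' @method tidy cbfb_karyotype
#' @export
tidy.cbfb_karyotype <- function(x, ...) {
  rows <- list()
  for (i in seq_along(x$clones)) {
    cl <- x$clones[[i]]
    if (length(cl$abnormalities) == 0L) next
    for (a in cl$abnormalities) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        clone = i,
        cell_count = cl$cell_count,
        abnormality = a$raw,
        category = a$category,
        chromosomes = paste(a$chromosomes, collapse = ";"),
        n_embedded = length(a$embedded),
        uncertain = a$uncertain,
        chimeric_donor = cl$chimeric_donor
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      clone = integer(), cell_count = integer(), abnormality = character(),
      category = character(), chromosomes = character(),
      n_embedded = integer(), uncertain = logical(), chimeric_donor = logical()
    ))
  }
  dplyr::bind_rows(rows)
}

#' One-row summary of a parsed karyotype
#'
#' @param x A `cbfb_karyotype`.
#' @param ... Unused.
#' @return A one-row tibble: status, clone count, total cells, abnormality
#'   counts of the stem clone, and chromosome 16 class.
#' @method glance cbfb_karyotype
#' @export
glance.cbfb_karyotype <- function(x, ...) {
  xr <- resolve_idem(x)
  counts <- lapply(xr$clones, count_abnormalities)
  n_tot <- vapply(counts, function(v) v[["n_total"]], integer(1))
  tibble::tibble(
    status = x$status,
    n_clones = length(x$clones),
    total_cells = sum(vapply(x$clones, function(cl) {
      if (is.na(cl$cell_count)) 0L else cl$cell_count
    }, integer(1))),
    max_abnormalities = if (length(n_tot)) max(n_tot) else 0L,
    chr16_class = chr16_class(x)
  )
}
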