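test_that("simple karyotypes parse into typed clones and abnormalities", {
  k <- parse_iscn("47,XY,inv(16)(p13.1q22),+22[20]")
  expect_s3_class(k, "cbfb_karyotype")
  expect_length(k$clones, 1L)
  expect_equal(k$clones[[1]]$cell_count, 20L)
  abns <- k$clones[[1]]$abnormalities
  expect_length(abns, 2L)
  expect_equal(abns[[1]]$category, "inversion")
  expect_equal(abns[[1]]$chromosomes, "16")
  expect_equal(abns[[1]]$breakpoints$band, c("p13.1", "q22"))
  expect_equal(abns[[2]]$category, "numerical_gain")
  expect_equal(abns[[2]]$chromosomes, "22")

  norm <- parse_iscn("46,XX[20]")
  expect_equal(norm$status, "normal")
  expect_length(norm$clones[[1]]$abnormalities, 0L)
  expect_equal(norm$clones[[1]]$cell_count, 20L)
})

test_that("compound derivatives carry embedded events; markers are typed", {
  k <- parse_iscn(
    "47,XY,der(16)inv(16)(p13.1q22)del(16)(q22q34),+mar[2]/46,XY[18]")
  stem <- k$clones[[1]]$abnormalities
  expect_length(stem, 2L)
  expect_equal(stem[[1]]$category, "derivative")
  expect_equal(vapply(stem[[1]]$embedded, function(a) a$category, character(1)),
               c("inversion", "deletion"))
  expect_equal(stem[[2]]$category, "marker")
  expect_length(k$clones[[2]]$abnormalities, 0L)
})

test_that("bracket whitespace and modal ranges in both dialects are accepted", {
  k <- parse_iscn("46,XY,t(1;16)(q21;q22)[8]/46,XY[1 2]")
  expect_equal(vapply(k$clones, function(cl) cl$cell_count, integer(1)),
               c(8L, 12L))
  tr <- k$clones[[1]]$abnormalities[[1]]
  expect_equal(tr$category, "translocation")
  expect_equal(tr$breakpoints$chrom, c("1", "16"))
  expect_equal(tr$breakpoints$band, c("q21", "q22"))

  expect_equal(parse_iscn("43~45,XY,+8[cp16]")$clones[[1]]$modal, c(43L, 45L))
  expect_equal(parse_iscn("43–46,XY,+8[cp20]")$clones[[1]]$modal,
               c(43L, 46L))
  expect_true(parse_iscn("51,XY,+8[cp2]")$clones[[1]]$composite)
})

test_that("malformed input raises parse errors naming the offending token", {
  expect_error(parse_iscn("46,XY,inv(16)(p13.1q22)"),
               class = "cbfb_parse_error")
  expect_error(parse_iscn("46,XY,inv(16)(p13.1q22[20]"),
               class = "cbfb_parse_error")
  expect_error(parse_iscn("46,XY,frob(16)[20]"), regexp = "frob",
               class = "cbfb_parse_error")
  expect_error(parse_iscn("46,XY[2x]"), class = "cbfb_parse_error")
  err <- tryCatch(parse_iscn("46,XY,frob(16)[20]"), error = identity)
  expect_true(is.numeric(err$offset) && err$offset > 1)
})

test_that("lenient mode tolerates a trailing clone without a cell count", {
  expect_error(parse_iscn("46,XY,inv(16)(p13.1q22)[13]/46,XY"),
               class = "cbfb_parse_error")
  k <- parse_iscn("46,XY,inv(16)(p13.1q22)[13]/46,XY", lenient = TRUE)
  expect_length(k$clones, 2L)
  expect_true(is.na(k$clones[[2]]$cell_count))
})

test_that("idem and sl stemline references expand to the stem abnormalities", {
  k <- resolve_idem(parse_iscn(
    "46,XX,inv(16)(p13.1q22)[9]/46,idem,+8,+22[3]/46,idem[cp2]/46,XX,t(2;22)(p13;q11.2),del(18)(q21.1q23),−22[1]/46,XX[5]"))
  sub <- k$clones[[2]]
  expect_equal(vapply(sub$abnormalities, function(a) a$raw, character(1)),
               c("inv(16)(p13.1q22)", "+8", "+22"))
  expect_true(sub$resolved)
  # idempotent
  k2 <- resolve_idem(k)
  expect_identical(k, k2)
  # unrelated clone untouched
  expect_length(k$clones[[4]]$abnormalities, 3L)

  ksl <- resolve_idem(parse_iscn(
    "46,XX,der(16)inv(16)(p13.1q22)del(16)(q22)[19]/47,sl,+8[1]"))
  expect_equal(vapply(ksl$clones[[2]]$abnormalities, function(a) a$raw,
                      character(1)),
               c("der(16)inv(16)(p13.1q22)del(16)(q22)", "+8"))

  k15 <- resolve_idem(parse_iscn(
    "47,XY,+8[5]/47,idem,der(16)inv(16)(p13.3q13)del(16)(q22q22)[15]"))
  expect_equal(vapply(k15$clones[[2]]$abnormalities, function(a) a$raw,
                      character(1)),
               c("+8", "der(16)inv(16)(p13.3q13)del(16)(q22q22)"))

  expect_error(resolve_idem(parse_iscn("46,idem,+8[5]")),
               class = "cbfb_resolve_error")
  expect_identical(resolve_idem(parse_iscn("46,XY[20]")),
                   parse_iscn("46,XY[20]"))
})

test_that("abnormality counting follows top-level token and polymorphism rules", {
  k2 <- parse_iscn(
    "50,XY,t(2;16)(q37;q22),t(3;16)(p21;p13),+8,+21,+22,+mar[5]/51,idem[cp2]/46,XY[13]")
  cnt <- count_abnormalities(k2$clones[[1]])
  expect_equal(cnt[["n_total"]], 6L)
  expect_equal(cnt[["n_structural"]], 2L)
  expect_equal(cnt[["n_numerical"]], 4L)

  # a compound derivative counts once
  k6 <- parse_iscn(
    "47,XY,der(16)inv(16)(p13.1q22)del(16)(q22q34),+mar[2]/46,XY[18]")
  expect_equal(count_abnormalities(k6$clones[[1]])[["n_total"]], 2L)

  # constitutional polymorphism excluded by default, countable on request
  k5 <- parse_iscn("46,XY,inv(9)(p12q13)[20]")
  expect_equal(count_abnormalities(k5$clones[[1]])[["n_total"]], 0L)
  expect_equal(count_abnormalities(
    k5$clones[[1]], counting_policy(exclude = character()))[["n_total"]], 1L)

  # marker structural status is a policy flag
  km <- parse_iscn("47,XY,+mar[10]")
  expect_equal(count_abnormalities(km$clones[[1]])[["n_structural"]], 0L)
  expect_equal(count_abnormalities(
    km$clones[[1]], counting_policy(mar_structural = TRUE))[["n_structural"]], 1L)

  expect_equal(unname(count_abnormalities(parse_iscn("46,XX[20]")$clones[[1]])),
               c(0L, 0L, 0L))
  expect_error(count_abnormalities(parse_iscn("46,idem,+8[5]")$clones[[1]]),
               class = "cbfb_resolve_error")
})

test_that("adding a token never decreases the abnormality count", {
  base <- "46,XY,inv(16)(p13.1q22)"
  extras <- c("+8", "+22", "del(7)(q22)", "+mar", "t(9;22)(q34;q11.2)", "-5")
  prev <- count_abnormalities(
    parse_iscn(paste0(base, "[20]"))$clones[[1]])[["n_total"]]
  acc <- base
  for (e in extras) {
    acc <- paste0(acc, ",", e)
    cur <- count_abnormalities(
      parse_iscn(paste0(acc, "[20]"))$clones[[1]])[["n_total"]]
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("chromosome 16 events split into primary signature and AC16As", {
  # clean inversion: primary only
  ev <- chr16_events(parse_iscn("47,XY,inv(16)(p13.1q22),+22[20]"))
  expect_length(ev$primary, 1L)
  expect_length(ev$additional, 0L)

  # derivative with embedded matching inversion plus deletion: both reported
  ev6 <- chr16_events(parse_iscn(
    "47,XY,der(16)inv(16)(p13.1q22)del(16)(q22q34),+mar[2]/46,XY[18]"))
  expect_equal(ev6$primary[[1]]$raw, "inv(16)(p13.1q22)")
  expect_equal(ev6$additional[[1]]$raw, "del(16)(q22q34)")

  # inversion at non-matching bands fails the signature: whole der is an AC16A
  ev15 <- chr16_events(parse_iscn(
    "47,XY,+8[5]/47,idem,der(16)inv(16)(p13.3q13)del(16)(q22q22)[15]"))
  expect_length(ev15$primary, 0L)
  expect_length(ev15$additional, 1L)
  expect_equal(ev15$additional[[1]]$category, "derivative")

  # t(16q22;v) is primary; a 16p translocation is an AC16A
  ev2 <- chr16_events(parse_iscn(
    "50,XY,t(2;16)(q37;q22),t(3;16)(p21;p13),+8,+21,+22,+mar[5]/46,XY[13]"))
  expect_equal(ev2$primary[[1]]$raw, "t(2;16)(q37;q22)")
  expect_equal(ev2$additional[[1]]$raw, "t(3;16)(p21;p13)")

  expect_equal(chr16_class(parse_iscn("46,XY,t(16;16)(p13.1;q22)[20]")), "t1616")
  expect_equal(chr16_class(parse_iscn("46,XX,t(16;19)(q22;q13.3)[17]")), "t16q22v")
  expect_equal(chr16_class(parse_iscn("46,XY[20]")), "normal_chr16")
})

test_that("chimeric donor clones are excluded from counting and chr16 queries", {
  k3 <- parse_iscn(paste0(
    "46,XX,inv(3)(q21q26.2),del(6)(q21q27),t(16;19)(q22;q13.3),del(17)(p12)[17]",
    "/46,XX,inv(3)(q21q26.2),t(11;15)(q14;q26.3)[1]//46,XY[2]"))
  donor <- k3$clones[[3]]
  expect_true(donor$chimeric_donor)
  expect_equal(unname(count_abnormalities(donor)), c(0L, 0L, 0L))
  # a donor clone's events never reach chr16_events
  kd <- parse_iscn("46,XX[18]//46,XY,inv(16)(p13.1q22)[2]")
  ev <- chr16_events(kd)
  expect_length(ev$primary, 0L)
})

test_that("parse -> serialize -> parse is the identity on the packaged cases", {
  for (txt in example_cases()$karyotype) {
    k <- parse_iscn(txt, lenient = TRUE)
    k2 <- parse_iscn(serialize_iscn(k), lenient = TRUE)
    expect_identical(strip_raw(k), strip_raw(k2), label = txt)
    # serialization is a fixed point
    expect_identical(serialize_iscn(k), serialize_iscn(k2))
  }
})

test_that("clone cell counts sum to the bracketed counts in the raw string", {
  for (txt in example_cases()$karyotype) {
    k <- parse_iscn(txt, lenient = TRUE)
    brackets <- stringr::str_match_all(txt, "\\[(?:cp)?([0-9 ]+)\\]")[[1]][, 2]
    expected <- sum(as.integer(stringr::str_remove_all(brackets, " ")))
    got <- sum(vapply(k$clones, function(cl) {
      if (is.na(cl$cell_count)) 0L else cl$cell_count
    }, integer(1)))
    expect_equal(got, expected, label = txt)
  }
})

test_that("tidy and glance summarise a karyotype model", {
  k <- parse_iscn("47,XY,inv(16)(p13.1q22),+22[18]/46,XY[2]")
  td <- tidy(k)
  expect_equal(nrow(td), 2L)
  expect_setequal(td$category, c("inversion", "numerical_gain"))
  g <- glance(k)
  expect_equal(g$n_clones, 2L)
  expect_equal(g$total_cells, 20L)
  expect_equal(g$max_abnormalities, 2L)
  expect_equal(g$chr16_class, "inv16")
})
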