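test_that("nuc ish strings parse into per-pattern nucleus counts", {
  o <- parse_nuc_ish("nuc ish(CBFBx2)(5′CBFB sep 3′CBFBx1)[62/200]")
  expect_equal(o$counts[["R1G1F1"]], 62L)
  expect_equal(o$total_scored, 200L)

  # ASCII apostrophes are equivalent to Unicode primes
  o2 <- parse_nuc_ish("nuc ish(CBFBx2)(5'CBFB sep 3'CBFBx1)[62/200]")
  expect_equal(o2$counts, o$counts)

  del5 <- parse_nuc_ish("nuc ish(5′CBFBx1,3′CBFBx2)(5′CBFB con 3′CBFBx1)[178/200]")
  expect_equal(del5$counts[["G1F1"]], 178L)

  del3 <- parse_nuc_ish("nuc ish(5′CBFBx2,3′CBFBx1)(5′CBFB con 3′CBFBx1)[104/200]")
  expect_equal(del3$counts[["R1F1"]], 104L)

  # a bare [n] bracket: the clause pattern was seen in all n scored nuclei
  all200 <- parse_nuc_ish("nuc ish(5′CBFBx2,3′CBFBx1)(5′CBFB con 3′CBFBx1)[200]")
  expect_equal(all200$counts[["R1F1"]], 200L)
  expect_equal(all200$total_scored, 200L)
})

test_that("metaphase ish prefixes are preserved as a note", {
  txt <- paste0("ish der(16)inv(16)(p13.1)(5′CBFB+)q22(3′CBFB-)del(16)(q22)[2]",
                "nuc ish(5′CBFBx2,3′CBFBx1)(5′CBFB con 3′CBFBx1)[182/200]")
  o <- parse_nuc_ish(txt)
  expect_match(o$metaphase_note, "^ish der\\(16\\)")
  expect_equal(o$counts[["R1F1"]], 182L)
})

test_that("damaged strings are salvaged in lenient mode and rejected in strict", {
  damaged <- "nuc ish(CBFBx2)l200}. Negative"
  expect_error(parse_nuc_ish(damaged), class = "cbfb_parse_error")
  o <- parse_nuc_ish(damaged, lenient = TRUE)
  expect_equal(o$total_scored, 200L)
  expect_equal(classify_fish(o)$category, "normal")
})

test_that("parse errors carry the offending text", {
  expect_error(parse_nuc_ish("nuc ish(XYZZYx2)[200]"), class = "cbfb_parse_error")
  expect_error(parse_nuc_ish("no fish here"), class = "cbfb_parse_error")
  expect_error(parse_nuc_ish("nuc ish(CBFBx2)[20O]"), class = "cbfb_parse_error")
})

test_that("classification applies the validated cutoffs with >= semantics", {
  expect_equal(classify_fish(fish_observation(c(R1G1F1 = 62), 200))$category,
               "positive")
  del3 <- classify_fish(fish_observation(c(R1F1 = 104), 200))
  expect_equal(del3$category, "abnormal")
  expect_equal(del3$abnormal_subtype, "del_3prime")
  expect_equal(classify_fish(fish_observation(integer(), 200))$category,
               "normal")

  # boundary: 8/200 = 4.0% < 4.2% is normal; 9/200 = 4.5% is positive
  expect_equal(classify_fish(fish_observation(c(R1G1F1 = 8), 200))$category,
               "normal")
  expect_equal(classify_fish(fish_observation(c(R1G1F1 = 9), 200))$category,
               "positive")
})

test_that("every pattern's cutoff is inclusive at the boundary", {
  cut <- fish_cutoffs()
  for (code in names(cut)) {
    n_at <- ceiling(cut[[code]] / 100 * 1000)
    at <- classify_fish(fish_observation(stats::setNames(n_at, code), 1000))
    expect_true(code %in% at$exceeded, label = paste(code, "at cutoff"))
    below <- classify_fish(fish_observation(stats::setNames(n_at - 1L, code), 1000))
    expect_false(code %in% below$exceeded, label = paste(code, "below cutoff"))
  }
})

test_that("classification is invariant under common scaling of counts and total", {
  base <- c(R1G1F1 = 10, F1 = 12)
  ref <- classify_fish(fish_observation(base, 200))
  for (f in c(2L, 5L, 10L)) {
    scaled <- classify_fish(fish_observation(base * f, 200L * f))
    expect_equal(scaled$category, ref$category)
    expect_equal(scaled$exceeded, ref$exceeded)
    expect_equal(scaled$fractions, ref$fractions)
  }
})

test_that("abnormal subtypes cover gains, losses and their combination", {
  expect_equal(classify_fish(fish_observation(c(F1 = 40), 200))$abnormal_subtype,
               "loss_one_copy")
  expect_equal(classify_fish(fish_observation(c(F3plus = 40), 200))$abnormal_subtype,
               "extra_copies")
  expect_equal(classify_fish(
    fish_observation(c(F1 = 40, F3plus = 30), 200))$abnormal_subtype,
    "gain_plus_loss")
  expect_equal(classify_fish(fish_observation(c(G1F2 = 18), 200))$abnormal_subtype,
               "gain_5prime")
  # category=abnormal always pairs with a subtype
  interp <- classify_fish(fish_observation(c(G1F1 = 30), 200))
  expect_equal(interp$category, "abnormal")
  expect_false(is.na(interp$abnormal_subtype))
})

test_that("balance labelling distinguishes balanced and unbalanced rearrangements", {
  pos <- classify_fish(fish_observation(c(R1G1F1 = 62), 200))
  expect_equal(balanced_state(pos, confirmed = TRUE), "balanced")
  del3 <- classify_fish(fish_observation(c(R1F1 = 104), 200))
  expect_equal(balanced_state(del3, confirmed = TRUE), "unbalanced")
  expect_equal(balanced_state(del3, confirmed = FALSE), "not_applicable")
  norm <- classify_fish(fish_observation(integer(), 200))
  expect_equal(balanced_state(norm, confirmed = TRUE), "not_applicable")
})

test_that("nuc ish serialization round-trips the packaged strings", {
  for (txt in example_cases()$fish) {
    o <- parse_nuc_ish(txt, lenient = TRUE)
    o2 <- parse_nuc_ish(serialize_nuc_ish(o), lenient = TRUE)
    expect_identical(o, o2, label = txt)
  }
})

test_that("the packaged cases reproduce the reported feature labels", {
  ex <- example_cases()
  interp <- lapply(ex$fish, function(s) classify_fish(parse_nuc_ish(s, lenient = TRUE)))
  cats <- vapply(interp, function(x) x$category, character(1))
  subs <- vapply(interp, function(x) x$abnormal_subtype, character(1))
  expect_equal(cats[1:4], rep("positive", 4))
  expect_equal(cats[5], "normal")
  expect_equal(sum(subs == "del_3prime", na.rm = TRUE), 11L)
  expect_equal(sum(subs == "del_5prime", na.rm = TRUE), 1L)
})

test_that("patient-level aggregation reports the most significant test", {
  expect_equal(aggregate_patient_category(c("normal", "positive")), "positive")
  expect_equal(aggregate_patient_category(c("normal", "abnormal")), "abnormal")
  expect_equal(aggregate_patient_category(c("normal", "normal")), "normal")
})
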