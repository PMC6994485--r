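cat_ <- builtin_catalog()

test_that("every rule-table row is reproduced exactly by its construction", {
  for (case in conformance_cases()) {
    rec <- recommend(case$proto, case$target, cat_)
    expect_true(rec$precise, info = case$row)
    expect_identical(rec$bes, case$bes, info = case$row)
  }
})

test_that("the YCC-15 context is a recognised gap (no precise editor)", {
  proto <- mk_proto(c(`-17` = "T", `-16` = "C", `-15` = "C"))
  rec <- recommend(proto, -15L, cat_)
  expect_false(rec$precise)
  expect_length(rec$bes, 0L)
  expect_match(rec$warnings, "no discriminating editor", all = FALSE)
  # Y covers C as well
  rec2 <- recommend(mk_proto(c(`-17` = "C", `-16` = "C", `-15` = "C")),
                    -15L, cat_)
  expect_false(rec2$precise)
})

test_that("context classification buckets and bystanders are right", {
  ctx <- classify_context(mk_proto(c(`-18` = "C")), -18L, cat_)
  expect_identical(ctx$bucket, "-18")
  expect_true(all(lengths(ctx$bystanders) == 0L))
  ctx2 <- classify_context(mk_proto(c(`-20` = "C", `-19` = "C")), -19L,
                           cat_)
  expect_identical(ctx2$bucket, "-19")
  expect_identical(classify_context(mk_proto(c(`-20` = "C")), -20L,
                                    cat_)$bucket, "<-19")
  expect_identical(classify_context(mk_proto(c(`-5` = "C")), -5L,
                                    cat_)$bucket, ">-14")
  # polyC: bystander count inside the full-length CDA1 window (-20..-14)
  ctx3 <- classify_context(strrep("C", 20), -18L, cat_)
  expect_identical(length(ctx3$bystanders[["nCDA1-BE3"]]), 6L)
  # errors name the offending base / range
  expect_error(classify_context(mk_proto(c(`-18` = "C")), -17L, cat_),
               "is A, not C")
  expect_error(classify_context(mk_proto(c(`-18` = "C")), -21L, cat_),
               "-20")
})

test_that("recommendation ordering is specificity-first and deterministic", {
  # TCC also satisfies DDDCC (T is a D); the more specific DDDCC row ranks
  # first but the merged, deduplicated list equals the TCC row's
  proto <- mk_proto(c(`-17` = "T", `-16` = "C", `-15` = "C"))
  rec <- recommend(proto, -16L, cat_)
  expect_identical(rec$matched_rules$pattern[1], "DDDCC")
  expect_identical(rec$bes, c("cCDA1-BE3", "YEE-BE3", "BE-PAPAPAP"))
  # deterministic for fixed input
  rec2 <- recommend(proto, -16L, cat_)
  expect_identical(rec, rec2)
})

test_that("eA3A warns at non-TCR contexts when recommended", {
  # make eA3A recommendable via a custom catalog rule is overkill; check
  # the helper predicate through a context where eA3A appears: none of the
  # built-in rows recommend it, so assert the warning machinery on a
  # profile clone instead
  cat2 <- cat_
  cat2$rules[[length(cat2$rules) + 1L]] <-
    precisebe:::.context_rule("-16", "NCD", 1L, "eA3A-BE3")
  rec <- recommend(mk_proto(c(`-17` = "C", `-16` = "C")), -16L, cat2)
  expect_true("eA3A-BE3" %in% rec$bes)
  expect_match(rec$warnings, "non-TCR", all = FALSE)
  # at a TCR context (TCA around the target) no warning fires
  rec2 <- recommend(mk_proto(c(`-18` = "C", `-17` = "T", `-16` = "C")),
                    -16L, cat2)
  expect_false(any(grepl("non-TCR", rec2$warnings)))
})

test_that("bystander reports tier preferred positions as high risk", {
  # A3Ad182: target -15 with a C at -16 (its top preferred position)
  rep1 <- bystander_report(mk_proto(c(`-16` = "C", `-15` = "C")), -15L,
                           "A3Ad182-BE3", cat_)
  expect_identical(rep1$position, -16L)
  expect_identical(rep1$tier, "high")
  # no other C in window -> empty report
  rep2 <- bystander_report(mk_proto(c(`-15` = "C")), -15L, "A3Ad182-BE3",
                           cat_)
  expect_identical(nrow(rep2), 0L)
  # polyC: every window C of the full-length editor is listed
  rep3 <- bystander_report(strrep("C", 20), -18L, "nCDA1-BE3", cat_)
  expect_setequal(rep3$position, setdiff(-20:-14, -18L))
  expect_identical(rep3$tier[rep3$position == -17L], "high")
  # editors without window profiles refuse
  expect_error(bystander_report(strrep("C", 20), -18L, "YEE-BE3", cat_),
               "no window profile")
})
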