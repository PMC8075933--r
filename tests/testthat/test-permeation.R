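test_that("censored permeation rates resolve by the half-detection-limit rule", {
  # one parameterised sweep over the four censoring forms
  cases <- list(
    list(input = "<0.1", expected = 0.05),
    list(input = "< 0.2", expected = 0.1),
    list(input = ">34", expected = 34),
    list(input = "94", expected = 94),
    list(input = 94, expected = 94),
    list(input = "nd", expected = NA_real_),
    list(input = "Not detected", expected = NA_real_)
  )
  for (cs in cases) {
    expect_equal(resolve_censored_rate(cs$input), cs$expected,
                 info = paste("input:", cs$input))
  }
  # face-value handling of ">x" is validated by the reference dataset:
  # the ">34" nitrile record's published Kp (0.0020) back-calculates to 34
  expect_equal(report_signif(kp_from_rate(34, 1030)), 0.0020)
})

test_that("invalid rates and bounds are rejected", {
  expect_error(resolve_censored_rate("<0"), "> 0")
  expect_error(resolve_censored_rate("-3"), "> 0")
  expect_error(resolve_censored_rate("abc"), "unparseable")
  expect_error(kp_from_rate(1, 0), "positive")
  expect_error(kp_from_rate(1, -5), "positive")
  expect_error(kp_from_rate(-1, 100), "non-negative")
})

test_that("permeability coefficients follow Kp = PR/C x 0.06", {
  cases <- list(
    list(rate = 94, conc = 773, printed = 0.0073),
    list(rate = 1.6, conc = 464, printed = 0.00021),
    list(rate = 0.05, conc = 1030, printed = 0.0000029)
  )
  for (cs in cases) {
    expect_equal(report_signif(kp_from_rate(cs$rate, cs$conc)), cs$printed)
  }
  expect_identical(kp_from_rate(0, 500), 0)
  # full precision internally: no intermediate rounding
  expect_equal(kp_from_rate(94, 773), 94 / 773 * 0.06, tolerance = 1e-15)
})

test_that("gloves classify into protection categories by permeation rate", {
  expect_identical(classify_glove(94), "minimal")
  expect_identical(classify_glove(2.0001), "minimal")
  expect_identical(classify_glove(2), "moderate")
  expect_identical(classify_glove(1.6), "moderate")
  expect_identical(classify_glove(1), "moderate")
  expect_identical(classify_glove(0.3), "maximal")
  expect_identical(classify_glove(0.05), "maximal")
  # the uncovered gap goes to the less-protective neighbour, with a flag
  expect_warning(out <- classify_glove(0.5), "gap")
  expect_identical(out, "moderate")
})

test_that("series-barrier composition matches the resistance-domain oracle", {
  set.seed(42)
  a <- 10^runif(200, -6, 0)
  b <- 10^runif(200, -6, 0)
  # oracle: add resistances in the reciprocal domain
  oracle <- 1 / (1 / a + 1 / b)
  expect_equal(kp_net(a, b), oracle, tolerance = 1e-12)
  # symmetry
  expect_equal(kp_net(a, b), kp_net(b, a), tolerance = 1e-15)
  # strict monotonicity in each argument
  expect_true(all(kp_net(a * 1.01, b) > kp_net(a, b)))
  expect_true(all(kp_net(a, b * 1.01) > kp_net(a, b)))
  # net permeability is below either layer alone
  expect_true(all(kp_net(a, b) < pmin(a, b)))
})

test_that("series-barrier limits: no glove, equal layers, impermeable layer", {
  expect_identical(kp_net(0.00205, Inf), 0.00205)  # exact, not approximate
  expect_equal(kp_net(0.004, 0.004), 0.002)
  expect_identical(kp_net(0.01, 0), 0)
  expect_identical(kp_net(0, 0.01), 0)
  expect_error(kp_net(-1, 0.01), "non-negative")
  # scalar skin against a named vector of glove values keeps names/shape
  g <- c(mean = 1e-3, min = 1e-5, max = 1e-2)
  out <- kp_net(0.000478, g)
  expect_named(out, c("mean", "min", "max"))
  expect_true(out[["min"]] < out[["mean"]] && out[["mean"]] < out[["max"]])
})

test_that("record tables compute effective rates, Kp and categories", {
  recs <- make_records(c("5", "<0.1", ">30", "nd"), c(500, 1000, 1000, NA))
  expect_s3_class(recs, "permeation_records")
  expect_equal(recs$effective_rate, c(5, 0.05, 30, NA))
  expect_equal(recs$kp_cm_per_h,
               c(5 / 500, 0.05 / 1000, 30 / 1000, NA) * 0.06)
  expect_equal(recs$category, c("minimal", "maximal", "minimal", NA))
  # category hints take precedence over the rate rule
  hinted <- make_records(c("0.19", "5"), c(371, 500),
                         hints = c("minimal", ""))
  expect_equal(hinted$category, c("minimal", "minimal"))
  expect_error(make_records("5", 500, hints = "super"), "unknown glove category")
  expect_error(permeation_records(data.frame(material = "x")), "missing column")
})

test_that("category summaries aggregate then compose", {
  recs <- make_records(c("10", "20", "1.5"), c(1000, 1000, 1000))
  s <- category_summary(recs, "minimal", kp_skin = 0.001)
  kp <- c(10, 20) / 1000 * 0.06
  expect_equal(s$n, 2)
  expect_equal(s$mean_kp_glove, mean(kp))
  # composition applied once, to the aggregated statistic
  expect_equal(s$mean_kp_net, 1 / (1 / 0.001 + 1 / mean(kp)), tolerance = 1e-15)
  expect_true(s$min_kp_net <= s$mean_kp_net && s$mean_kp_net <= s$max_kp_net)
  # single-record category: mean = min = max
  s1 <- category_summary(recs, "moderate", kp_skin = 0.001)
  expect_equal(s1$mean_kp_net, s1$min_kp_net)
  expect_equal(s1$mean_kp_net, s1$max_kp_net)
  expect_error(category_summary(recs, "maximal", 0.001), "no quantifiable")
  expect_error(category_summary(recs, "minimal", 0), "positive")
})

test_that("delimited round trip preserves the dataset", {
  recs <- reference_permeation_data()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_permeation(recs, tmp)
  back <- read_permeation(tmp)
  expect_equal(nrow(back), nrow(recs))
  expect_equal(back$effective_rate, recs$effective_rate)
  expect_equal(back$category, recs$category)
  # unrounded Kp recomputes identically from the raw columns
  expect_equal(back$kp_cm_per_h, recs$kp_cm_per_h, tolerance = 1e-12)
  # tab-separated input is also accepted
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_permeation(recs, tmp2, sep = "\t")
  expect_equal(read_permeation(tmp2)$effective_rate, recs$effective_rate)
  expect_error(read_permeation(withr::local_tempfile()), "not found|empty")
})
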