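test_that("summed and pooled ranges reproduce the published totals", {
  known <- known_counts(mors_table1())
  s <- summed_range(known)
  expect_equal(c(s$lower, s$upper), c(33, 243))

  canada <- summed_range(known_counts(mors_table1(), "canada"))
  expect_equal(c(canada$lower, canada$upper), c(18, 133))

  expect_equal(c(summed_range(numeric(0))$lower, summed_range(numeric(0))$upper), c(0, 0))
  one_zero <- summed_range(c(z = 0))
  expect_equal(c(one_zero$lower, one_zero$upper), c(0, 0))

  p <- pooled_range(299)
  expect_equal(c(p$lower, p$upper), c(30, 239))
  praw <- pooled_range(299, rounding = "none")
  expect_equal(c(praw$lower, praw$upper), c(29.9, 239.2))
  p0 <- pooled_range(0)
  expect_equal(c(p0$lower, p0$upper), c(0, 0))
})

test_that("per-service ceiling dominates the pooled range", {
  # ceiling per addend can only raise the sum; raw pooled can only be lower
  set.seed(31)
  for (i in 1:20) {
    counts <- stats::setNames(sample(0:120, 6, replace = TRUE), letters[1:6])
    s <- summed_range(counts)
    p <- pooled_range(sum(counts), rounding = "none")
    expect_gte(s$lower, p$lower)
    expect_gte(s$upper, p$upper)
  }
})

test_that("non-fatal:fatal ratios reproduce the published values", {
  expect_equal(nonfatal_fatal_ratio(299, 135), 1.21)
  expect_equal(nonfatal_fatal_ratio(299, 30), 8.97)
  expect_equal(nonfatal_fatal_ratio(299, 239), 0.25)

  rr <- ratio_report(299, 135)
  expect_equal(rr$averted_at_floor, 30)
  expect_equal(rr$averted_at_ceiling, 239)
  expect_equal(rr$ratio_at_floor, 8.97)
  expect_equal(rr$ratio_at_mc, 1.21)
  expect_equal(rr$ratio_at_ceiling, 0.25)
  expect_true(rr$ratio_at_floor >= rr$ratio_at_mc)
  expect_true(rr$ratio_at_mc >= rr$ratio_at_ceiling)
})

test_that("ratio is strictly decreasing in averted deaths and errors on bad input", {
  vals <- vapply(1:299, function(a) nonfatal_fatal_ratio(299, a, decimals = 6),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(nonfatal_fatal_ratio(299, 0), class = "mors_domain_error")
  expect_error(nonfatal_fatal_ratio(299, 300), class = "mors_domain_error")
})

test_that("cost savings are exact to the cent under the derived constant", {
  cm <- cost_model()
  cs <- cost_savings(new_range(18, 133, "ceiling"), cm)
  # the constant is defined as 3,487,836,040/18 cents per death, so the
  # Canadian lower bound is exact by construction
  expect_identical(cs$lower_cents, 3487836040)
  expect_identical(cs$lower_formatted, "34,878,360.40")
  # independent check of the upper bound: long division of 133 * num by 18
  num <- 133 * 3487836040
  expected_cents <- (num - num %% 18) / 18 + ((num %% 18) * 2 >= 18)
  expect_identical(cs$upper_cents, expected_cents)
  expect_identical(cs$upper_formatted, "257,712,329.62")

  zero <- cost_savings(new_range(0, 0, "ceiling"), cm)
  expect_equal(c(zero$lower, zero$upper), c(0, 0))
  unit <- cost_savings(new_range(1, 1, "ceiling"), cost_model(250000))
  expect_equal(c(unit$lower, unit$upper), c(250000, 250000))
})

test_that("cost savings are exactly linear in the averted counts", {
  cm <- cost_model(1234567.89)
  a <- cost_savings(new_range(7, 31, "ceiling"), cm)
  b <- cost_savings(new_range(14, 62, "ceiling"), cm)
  expect_identical(b$lower_cents, 2 * a$lower_cents)
  expect_identical(b$upper_cents, 2 * a$upper_cents)
})

test_that("the full report mirrors the published table row by row", {
  report <- build_report()
  rows <- report_rows_for_test(report)
  nors <- rows[rows$service == "NORS", ]
  expect_equal(nors$events, "77")
  expect_equal(nors$averted_range, "8–62")
  expect_equal(nors$averted_mc, "35 [9, 60]")
  up <- rows[rows$service == "UnityPhilly", ]
  expect_equal(up$averted_range, "8–60")
  expect_equal(up$averted_mc, "33 [9, 58]")
  tot <- rows[rows$service == "TOTAL", ]
  expect_equal(tot$events, "299")
  expect_equal(tot$averted_range, "33–243")
  expect_equal(tot$averted_mc, "135 [35, 234]")
  # unknown-count services stay in the report, marked
  expect_equal(rows$averted_mc[rows$service == "iKeepr"], "unknown")
  expect_equal(rows$averted_mc[rows$service == "The Canary"], "unknown")

  expect_equal(report$canada$summed_range$lower, 18)
  expect_equal(report$canada$cost$lower_formatted, "34,878,360.40")
})

test_that("report files embed the configuration needed to re-derive them", {
  outdir <- withr::local_tempdir()
  report <- build_report()
  files <- write_report(report, outdir)
  expect_length(files, 4)
  expect_true(all(file.exists(files)))

  json <- jsonlite::fromJSON(file.path(outdir, "mors_report.json"))
  expect_equal(json$provenance$n_draws, 10000)
  expect_equal(json$provenance$seed, 2023)
  expect_equal(json$provenance$rate_lower, 0.1)
  expect_equal(json$provenance$rate_upper, 0.8)
  expect_equal(json$total$point, 135)

  csv <- utils::read.csv(file.path(outdir, "mors_report.csv"), comment.char = "#")
  expect_equal(nrow(csv), 12)
  header <- grep("^#", readLines(file.path(outdir, "mors_report.csv")), value = TRUE)
  expect_true(any(grepl("^# n_draws: 10000", header)))

  md <- readLines(file.path(outdir, "mors_report.md"))
  expect_true(any(grepl("135 \\[35, 234\\]", md)))
})
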