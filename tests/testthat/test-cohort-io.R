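test_that("admission revenue attribution applies the 24h/12h fraction", {
  # long stay: 24/48 of the stay's revenue
  expect_equal(attribute_admission_revenue(10000, 48), 5000)
  # short stay: 12/20
  expect_equal(attribute_admission_revenue(8000, 20), 4800)
  # very short stay: fraction 12/6 = 2 is capped at 1
  expect_equal(attribute_admission_revenue(5000, 6), 5000)
  # zero revenue stays zero
  expect_equal(attribute_admission_revenue(0, 30), 0)
  # boundary: exactly 24 h takes the long-stay branch, fraction 1
  expect_equal(attribute_admission_revenue(1000, 24), 1000)
  expect_error(attribute_admission_revenue(1000, 0), "hospital_los")
  expect_error(attribute_admission_revenue(1000, -3), "hospital_los")
  expect_error(attribute_admission_revenue(-1, 10), "stay_revenue")
})

test_that("attribution fraction lies in (0, 1] and decays within each branch", {
  los <- seq(1, 200, by = 0.5)
  frac <- attribute_admission_revenue(rep(1, length(los)), los)
  expect_true(all(frac > 0 & frac <= 1))
  # the 12h/24h rule is discontinuous at the 24 h boundary (12/24 vs
  # 24/24), so monotone decay holds within each branch, not across it
  expect_true(all(diff(frac[los > 12 & los < 24]) <= 1e-12))
  expect_true(all(diff(frac[los >= 24]) <= 1e-12))
  # attributed revenue never exceeds the stay's revenue
  rev <- runif(length(los), 0, 1e5)
  expect_true(all(attribute_admission_revenue(rev, los) <= rev + 1e-9))
})

test_that("attribute_revenue passes discharges through and transforms admits", {
  v <- make_visits(
    disposition = c("discharge", "admit", "admit", "discharge"),
    hospital_los = c(NA, 48, 20, NA),
    stay_revenue = c(1200, 10000, 8000, NA))
  out <- attribute_revenue(v)
  expect_equal(out$attributed_revenue, c(1200, 5000, 4800, NA))
  # admit without hospital LOS is a validation error naming the row
  bad <- make_visits(disposition = "admit", hospital_los = NA_real_,
                     stay_revenue = 100)
  expect_error(attribute_revenue(bad), "rows: 1")
})

test_that("capping matches a linear-interpolation percentile oracle", {
  v <- make_visits(stay_revenue = as.numeric(1:100))
  v <- attribute_revenue(v)
  res <- cap_revenue(v, percentile = 0.95)
  expect_equal(res$cap_value, lin_percentile_oracle(1:100, 0.95))
  expect_equal(res$cap_value, 95.05)
  expect_equal(sum(res$visits$capped_revenue == 95.05), 5)
  expect_equal(res$visits$capped_revenue[1:95], as.numeric(1:95))
})

test_that("capping handles degenerate and identity cases and never raises values", {
  # all equal: cap equals the common value, nothing changes
  v <- attribute_revenue(make_visits(n = 10, stay_revenue = 42))
  res <- cap_revenue(v)
  expect_equal(res$cap_value, 42)
  expect_equal(res$visits$capped_revenue, rep(42, 10))
  # percentile 1 -> cap at the maximum, identity
  v2 <- attribute_revenue(make_visits(stay_revenue = c(5, 1, 9, 3)))
  res2 <- cap_revenue(v2, percentile = 1)
  expect_equal(res2$cap_value, 9)
  expect_equal(res2$visits$capped_revenue, res2$visits$attributed_revenue)
  # property: capping never increases and leaves values <= cap untouched
  set.seed(11)
  for (i in 1:5) {
    x <- rlnorm(200, 7, 1)
    vv <- attribute_revenue(make_visits(stay_revenue = x))
    rr <- cap_revenue(vv, percentile = 0.9)
    expect_true(all(rr$visits$capped_revenue <= rr$visits$attributed_revenue))
    under <- x <= rr$cap_value
    expect_equal(rr$visits$capped_revenue[under], x[under])
    expect_lte(sum(rr$visits$capped_revenue), sum(x))
  }
  # missing revenue stays missing through capping
  vm <- attribute_revenue(make_visits(stay_revenue = c(1, NA, 3)))
  expect_true(is.na(cap_revenue(vm)$visits$capped_revenue[2]))
  expect_error(cap_revenue(vm, percentile = 0), "percentile")
  expect_error(cap_revenue(vm, percentile = 1.2), "percentile")
  all_na <- attribute_revenue(make_visits(stay_revenue = c(NA_real_, NA_real_)))
  expect_error(cap_revenue(all_na), "missing")
})

test_that("imputation fills stratum means and matches hand arithmetic", {
  # simple stratum mean
  v <- make_visits(disposition = "admit", payer = "medicare",
                   hospital_los = 24,
                   stay_revenue = c(1000, 3000, NA))
  out <- impute_missing_revenue(cap_revenue(attribute_revenue(v), 1)$visits)
  expect_equal(out$final_revenue[3], 2000)
  expect_equal(out$imputed, c(FALSE, FALSE, TRUE))

  # 8-record toy table, 2 strata, 2 missing; hand-computed expectations:
  # admit x medicare observed {1000, 3000} -> stratum mean 2000
  # discharge x private observed {500, 700, 900, 400} -> stratum mean 625
  # overall mean of final revenue = 9125 / 8 = 1140.625
  v8 <- make_visits(
    disposition = c(rep("admit", 3), rep("discharge", 5)),
    payer = c(rep("medicare", 3), rep("private", 5)),
    hospital_los = c(24, 24, 24, NA, NA, NA, NA, NA),
    stay_revenue = c(1000, 3000, NA, 500, 700, 900, 400, NA))
  out8 <- impute_missing_revenue(cap_revenue(attribute_revenue(v8), 1)$visits)
  expect_equal(out8$final_revenue[3], 2000)
  expect_equal(out8$final_revenue[8], 625)
  expect_equal(mean(out8$final_revenue), 1140.625)
  # observed values pass through unchanged and nothing stays missing
  expect_equal(out8$final_revenue[!out8$imputed],
               v8$stay_revenue[!is.na(v8$stay_revenue)])
  expect_false(anyNA(out8$final_revenue))
})

test_that("imputation identity, empty-stratum fallback, and degenerate errors", {
  v <- cap_revenue(attribute_revenue(make_visits(stay_revenue = c(1, 2, 3))), 1)$visits
  out <- impute_missing_revenue(v)
  expect_equal(out$final_revenue, c(1, 2, 3))
  expect_false(any(out$imputed))

  # a stratum with only missing values falls back to the overall mean
  v2 <- make_visits(
    disposition = "discharge",
    payer = c("medicare", "medicare", "self_pay"),
    stay_revenue = c(100, 300, NA))
  v2 <- cap_revenue(attribute_revenue(v2), 1)$visits
  expect_warning(out2 <- impute_missing_revenue(v2), "overall mean")
  expect_equal(out2$final_revenue[3], 200)

  all_na <- cap_revenue(attribute_revenue(
    make_visits(stay_revenue = c(NA, 1))), 1)$visits
  all_na$capped_revenue <- NA_real_
  expect_error(impute_missing_revenue(all_na), "no observed revenue")
})

test_that("summarize_period aggregates count, sum, and median", {
  v <- make_visits(stay_revenue = c(100, 200, 300), ed_los = c(10, 20, 30))
  v <- impute_missing_revenue(cap_revenue(attribute_revenue(v), 1)$visits)
  s <- summarize_period(v, "pre")
  expect_equal(s$n_visits, 3)
  expect_equal(s$total_revenue, 600)
  expect_equal(s$median_ed_los, 20)
  expect_equal(s$revenue_per_visit, 200)
  # single record: summary equals that record
  v1 <- impute_missing_revenue(cap_revenue(attribute_revenue(
    make_visits(n = 1, stay_revenue = 777, ed_los = 45)), 1)$visits)
  s1 <- summarize_period(v1, "pre")
  expect_equal(c(s1$n_visits, s1$total_revenue, s1$median_ed_los),
               c(1, 777, 45))
  expect_error(summarize_period(v, "post"), "no records")
  # total revenue is the exact sum of final revenue
  expect_identical(s$total_revenue, sum(v$final_revenue))
})

test_that("pipeline is the identity on clean discharge-only revenue", {
  set.seed(5)
  x <- runif(50, 100, 2000)
  v <- make_visits(stay_revenue = x)
  res <- process_visits(v, percentile = 1)
  expect_equal(res$visits$final_revenue, x)
  expect_equal(res$n_imputed, 0)
  expect_equal(res$summaries$pre$total_revenue, sum(x))
})

test_that("visit CSV round-trips and validation reports row numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  v <- make_visits(
    period = c("pre", "pre", "post"),
    disposition = c("discharge", "admit", "discharge"),
    payer = c("private", "medicaid", "self_pay"),
    ed_los = c(120, 600, 85),
    hospital_los = c(NA, 36, NA),
    stay_revenue = c(850, 12000, NA))
  write_visits(v, path)
  back <- read_visits(path)
  expect_equal(as.data.frame(back), as.data.frame(v))

  # unknown payer: rejected with the row number in strict mode,
  # mapped to "other" in lenient mode
  raw <- readr::read_csv(path, show_col_types = FALSE)
  raw$payer[2] <- "tricare"
  readr::write_csv(raw, path, na = "")
  expect_error(read_visits(path), "rows: 2")
  lenient <- read_visits(path, strict = FALSE)
  expect_equal(lenient$payer[2], "other")

  raw$payer[2] <- "medicaid"
  raw$ed_los_min[3] <- -5
  readr::write_csv(raw, path, na = "")
  expect_error(read_visits(path), "ed_los_min.*rows: 3")
})
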