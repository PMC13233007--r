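# In-code fixtures shared across test files.

# Minimal visit tibble builder with sensible defaults.
make_visits <- function(n = NULL, visit_id = NULL, period = "pre",
                        disposition = "discharge", payer = "medicare",
                        ed_los = 300, hospital_los = NA_real_,
                        stay_revenue = 1000) {
  if (is.null(n)) {
    n <- max(lengths(list(visit_id, period, disposition, payer, ed_los,
                          hospital_los, stay_revenue)))
  }
  if (is.null(visit_id)) visit_id <- sprintf("v%03d", seq_len(n))
  tibble::tibble(
    visit_id = rep_len(visit_id, n),
    period = rep_len(period, n),
    disposition = rep_len(disposition, n),
    payer = rep_len(payer, n),
    ed_los = rep_len(ed_los, n),
    hospital_los = rep_len(hospital_los, n),
    stay_revenue = rep_len(stay_revenue, n)
  )
}

# Independent linear-interpolation percentile oracle (order-statistic
# interpolation written from the definition, not via quantile()).
lin_percentile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Reference aggregate inputs used as desk-scale model inputs.
study_pre <- function() period_summary(81464, 138309296, 311)
study_post <- function() period_summary(89259, 153747123, 292)
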