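#' Configuration for the synthetic visit-cohort generator
#'
#' Defines the statistical structure of a two-period ED visit cohort:
#' sample sizes, admission rate, payer mix, per-stratum log-normal
#' attributed-revenue distributions, log-normal ED and hospital
#' length-of-stay distributions, post-period shift multipliers, and a
#' missing-completely-at-random revenue missingness rate.
#'
#' Revenue distributions are specified on the *ED-attributed* scale (what a
#' visit contributes to ED revenue after admission attribution); the
#' generator back-constructs whole-stay revenue for admitted visits by
#' dividing by the attribution fraction implied by the drawn hospital LOS,
#' so the processing pipeline recovers exactly the configured attributed
#' distribution.
#'
#' @param n_visits_pre,n_visits_post Visit counts per period (positive
#'   integers).
#' @param admit_rate Fraction of visits admitted, in `[0, 1]`.
#' @param payer_mix Named fractions over
#'   `c("medicare", "medicaid", "private", "self_pay")`, summing to 1.
#' @param revenue_params Data frame with columns `disposition`, `payer`,
#'   `meanlog`, `sdlog`: one log-normal per disposition x payer stratum for
#'   attributed revenue (US $).
#' @param ed_los_meanlog,ed_los_sdlog Log-normal parameters of ED length of
#'   stay in minutes (pre period).
#' @param hospital_los_meanlog,hospital_los_sdlog Log-normal parameters of
#'   hospital length of stay in hours (admitted visits).
#' @param post_los_multiplier Multiplicative shift of ED LOS in the post
#'   period (e.g. 292/311 for a 19-minute median reduction).
#' @param post_revenue_multiplier Multiplicative shift of attributed revenue
#'   in the post period.
#' @param missingness_rate Probability that a visit's revenue is missing
#'   (MCAR), in `[0, 1]`.
#' @param seed Master integer seed; per-period, per-field substreams are
#'   derived from it deterministically.
#' @return An object of class `cohort_config`.
#' @seealso [study_like_config()] for calibrated defaults,
#'   [generate_cohort()].
#' @export
cohort_config <- function(n_visits_pre, n_visits_post,
                          admit_rate,
                          payer_mix,
                          revenue_params,
                          ed_los_meanlog, ed_los_sdlog,
                          hospital_los_meanlog, hospital_los_sdlog,
                          post_los_multiplier = 1,
                          post_revenue_multiplier = 1,
                          missingness_rate = 0,
                          seed = 1L) {
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 ||
        x != round(x)) {
      stop("`", nm, "` must be a positive whole number", call. = FALSE)
    }
  }
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop("`", nm, "` must be a fraction in [0, 1]", call. = FALSE)
    }
  }
  chk_count(n_visits_pre, "n_visits_pre")
  chk_count(n_visits_post, "n_visits_post")
  chk_frac(admit_rate, "admit_rate")
  chk_frac(missingness_rate, "missingness_rate")
  if (!is.numeric(payer_mix) || !setequal(names(payer_mix), PAYER_LEVELS)) {
    stop("`payer_mix` must be named fractions over: ",
         paste(PAYER_LEVELS, collapse = ", "), call. = FALSE)
  }
  payer_mix <- payer_mix[PAYER_LEVELS]
  if (any(payer_mix < 0) || abs(sum(payer_mix) - 1) > 1e-9) {
    stop("`payer_mix` must be non-negative and sum to 1", call. = FALSE)
  }
  stopifnot(is.data.frame(revenue_params),
            all(c("disposition", "payer", "meanlog", "sdlog") %in%
                  names(revenue_params)))
  if (nrow(revenue_params) != 8L ||
      nrow(unique(revenue_params[, c("disposition", "payer")])) != 8L) {
    stop("`revenue_params` needs one row per disposition x payer stratum (8)",
         call. = FALSE)
  }
  if (any(revenue_params$sdlog <= 0)) {
    stop("`revenue_params$sdlog` must be > 0", call. = FALSE)
  }
  for (nm in c("ed_los_sdlog", "hospital_los_sdlog", "post_los_multiplier",
               "post_revenue_multiplier")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || is.na(val) || val <= 0) {
      stop("`", nm, "` must be a positive number", call. = FALSE)
    }
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed)) {
    stop("`seed` must be an integer", call. = FALSE)
  }
  structure(
    list(n_visits_pre = as.integer(n_visits_pre),
         n_visits_post = as.integer(n_visits_post),
         admit_rate = admit_rate,
         payer_mix = payer_mix,
         revenue_params = tibble::as_tibble(revenue_params),
         ed_los_meanlog = ed_los_meanlog, ed_los_sdlog = ed_los_sdlog,
         hospital_los_meanlog = hospital_los_meanlog,
         hospital_los_sdlog = hospital_los_sdlog,
         post_los_multiplier = post_los_multiplier,
         post_revenue_multiplier = post_revenue_multiplier,
         missingness_rate = missingness_rate,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  visits: %s pre / %s post; admit rate %.1f%%\n",
              format(x$n_visits_pre, big.mark = ","),
              format(x$n_visits_post, big.mark = ","), 100 * x$admit_rate))
  cat(sprintf("  payer mix: %s\n",
              paste(sprintf("%s %.0f%%", names(x$payer_mix),
                            100 * x$payer_mix), collapse = ", ")))
  cat(sprintf("  ED LOS: lognormal(meanlog %.3f, sdlog %.3f); post x%.3f\n",
              x$ed_los_meanlog, x$ed_los_sdlog, x$post_los_multiplier))
  cat(sprintf("  missingness: %.2f%%; seed %d\n",
              100 * x$missingness_rate, x$seed))
  invisible(x)
}

# Deterministic substream seed from the master seed and a text tag.
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 10007 + h * 97) %% 2147483647)
}

# Mixture-of-lognormals helpers used for calibration: CDF at x, and the
# mean of min(X, cap) (closed form per component).
mix_lnorm_cdf <- function(x, meanlogs, sdlog, w) {
  sum(w * pnorm((log(x) - meanlogs) / sdlog))
}

mix_lnorm_capped_mean <- function(cap, meanlogs, sdlog, w) {
  z <- (log(cap) - meanlogs) / sdlog
  sum(w * (exp(meanlogs + sdlog^2 / 2) * pnorm(z - sdlog) +
             cap * pnorm(z, lower.tail = FALSE)))
}

#' Cohort configuration emulating a large multisite ED cohort
#'
#' Returns a [cohort_config()] calibrated so that the *processed* cohort
#' reproduces, within Monte-Carlo error, its reference aggregate targets:
#' pre-period revenue per visit (default US $1698) after capping at the
#' 95th percentile (default cap US $7241), pre-period median ED LOS
#' (default 311 min with IQR near 182-554), and the revenue missingness
#' rate (default 3.19%).
#'
#' Per-stratum attributed-revenue distributions share a common log scale
#' `sdlog` with fixed relative log-location offsets (admissions above
#' discharges; private above Medicare above Medicaid above self-pay). The
#' base location and common `sdlog` are solved numerically so that the
#' stratum mixture has its `cap_percentile` quantile at `revenue_cap` and a
#' post-cap mean of `revenue_per_visit`. Matching the cohort's reported
#' revenue SD as well is not attempted: with the mean and cap pinned the
#' achieved SD is a model output, not an input.
#'
#' @param n_visits_pre,n_visits_post Period sizes; defaults
#'   81,464 and 89,259.
#' @param admit_rate Admission fraction (default 0.25).
#' @param payer_mix Payer fractions (defaults: Medicare 0.35, Medicaid 0.25,
#'   private 0.30, self-pay 0.10).
#' @param revenue_per_visit Target mean attributed revenue per visit after
#'   capping, US $ (pre period).
#' @param revenue_cap Target value of the capping percentile, US $.
#' @param cap_percentile Capping percentile (default 0.95).
#' @param median_ed_los Target pre-period median ED LOS, minutes.
#' @param ed_los_iqr Target pre-period ED LOS interquartile range, minutes
#'   (length 2); sets the LOS log-scale via the IQR ratio.
#' @param post_los_multiplier Post-period LOS shift (default 292/311).
#' @param post_revenue_multiplier Post-period revenue shift (default
#'   1722/1698).
#' @param missingness_rate Revenue missingness rate (default 0.0319).
#' @param seed Master seed.
#' @return A calibrated [cohort_config()].
#' @examples
#' cfg <- study_like_config(n_visits_pre = 1000, n_visits_post = 1000)
#' cohort <- generate_cohort(cfg)
#' @export
study_like_config <- function(n_visits_pre = 81464L,
                              n_visits_post = 89259L,
                              admit_rate = 0.25,
                              payer_mix = c(medicare = 0.35, medicaid = 0.25,
                                            private = 0.30, self_pay = 0.10),
                              revenue_per_visit = 1698,
                              revenue_cap = 7241,
                              cap_percentile = 0.95,
                              median_ed_los = 311,
                              ed_los_iqr = c(182, 554),
                              post_los_multiplier = 292 / 311,
                              post_revenue_multiplier = 1722 / 1698,
                              missingness_rate = 0.0319,
                              seed = 1L) {
  stopifnot(revenue_per_visit > 0, revenue_cap > revenue_per_visit,
            cap_percentile > 0, cap_percentile < 1,
            median_ed_los > 0, length(ed_los_iqr) == 2L,
            ed_los_iqr[1] > 0, ed_los_iqr[2] > ed_los_iqr[1])
  # validate the mixture inputs before they feed the calibration solve
  if (!is.numeric(payer_mix) || !setequal(names(payer_mix), PAYER_LEVELS)) {
    stop("`payer_mix` must be named fractions over: ",
         paste(PAYER_LEVELS, collapse = ", "), call. = FALSE)
  }
  payer_mix <- payer_mix[PAYER_LEVELS]
  if (any(payer_mix < 0) || abs(sum(payer_mix) - 1) > 1e-9) {
    stop("`payer_mix` must be non-negative and sum to 1", call. = FALSE)
  }
  if (!is.numeric(admit_rate) || admit_rate < 0 || admit_rate > 1) {
    stop("`admit_rate` must be a fraction in [0, 1]", call. = FALSE)
  }

  # relative log-location offsets by stratum (admissions attribute more
  # revenue per visit; commercial payers reimburse above public payers)
  disp_off <- c(admit = 0.9, discharge = 0)
  payer_off <- c(medicare = 0, medicaid = -0.15, private = 0.25,
                 self_pay = -0.35)
  grid <- expand.grid(disposition = names(disp_off),
                      payer = names(payer_off),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  delta <- disp_off[grid$disposition] + payer_off[grid$payer]
  w <- ifelse(grid$disposition == "admit", admit_rate, 1 - admit_rate) *
    payer_mix[grid$payer]

  solve_base <- function(sdlog) {
    uniroot(function(m0) {
      mix_lnorm_cdf(revenue_cap, m0 + delta, sdlog, w) - cap_percentile
    }, c(-5, 15))$root
  }
  sdlog <- uniroot(function(s) {
    mix_lnorm_capped_mean(revenue_cap, solve_base(s) + delta, s, w) -
      revenue_per_visit
  }, c(0.2, 3))$root
  base_meanlog <- solve_base(sdlog)

  revenue_params <- tibble::tibble(
    disposition = grid$disposition,
    payer = grid$payer,
    meanlog = base_meanlog + as.numeric(delta),
    sdlog = sdlog
  )

  # LOS log-scale from the IQR ratio; with median fixed, a two-parameter
  # log-normal cannot match both quartiles exactly, so the ratio is used
  ed_sdlog <- log(ed_los_iqr[2] / ed_los_iqr[1]) / (2 * qnorm(0.75))

  cohort_config(
    n_visits_pre = n_visits_pre, n_visits_post = n_visits_post,
    admit_rate = admit_rate, payer_mix = payer_mix,
    revenue_params = revenue_params,
    ed_los_meanlog = log(median_ed_los), ed_los_sdlog = ed_sdlog,
    hospital_los_meanlog = log(72), hospital_los_sdlog = 0.7,
    post_los_multiplier = post_los_multiplier,
    post_revenue_multiplier = post_revenue_multiplier,
    missingness_rate = missingness_rate,
    seed = seed
  )
}

#' Generate a synthetic visit cohort
#'
#' Draws a two-period visit table from a [cohort_config()]. Generation is a
#' pure function of the configuration (including its seed): the same config
#' yields byte-identical output. Randomness is consumed through substreams
#' derived from the master seed per period and per field, so changing e.g.
#' the missingness rate does not perturb the LOS draws.
#'
#' Whole-stay revenue for admitted visits is constructed as the drawn
#' attributed revenue divided by the admission attribution fraction implied
#' by the drawn hospital LOS, so that [attribute_revenue()] recovers the
#' configured attributed-revenue distribution exactly.
#'
#' @param config A [cohort_config()].
#' @return A raw visit tibble with columns `visit_id`, `period`,
#'   `disposition`, `payer`, `ed_los` (min), `hospital_los` (hr, `NA` for
#'   discharges), `stay_revenue` (US $, `NA` where missing).
#' @examples
#' cohort <- generate_cohort(study_like_config(n_visits_pre = 200,
#'                                             n_visits_post = 200))
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  parts <- lapply(c("pre", "post"), function(period) {
    n <- if (period == "pre") config$n_visits_pre else config$n_visits_post
    draw <- function(field, expr) {
      set.seed(sub_seed(config$seed, paste0(period, ".", field)))
      eval(expr)
    }
    disposition <- draw("disposition", quote(
      ifelse(runif(n) < config$admit_rate, "admit", "discharge")))
    payer <- draw("payer", quote(
      sample(PAYER_LEVELS, n, replace = TRUE, prob = config$payer_mix)))
    los_mult <- if (period == "post") config$post_los_multiplier else 1
    ed_los <- draw("ed_los", quote(
      rlnorm(n, config$ed_los_meanlog + log(los_mult), config$ed_los_sdlog)))
    hospital_los <- draw("hospital_los", quote(
      rlnorm(n, config$hospital_los_meanlog, config$hospital_los_sdlog)))
    hospital_los[disposition != "admit"] <- NA_real_

    key <- paste(disposition, payer, sep = ".")
    pkey <- paste(config$revenue_params$disposition,
                  config$revenue_params$payer, sep = ".")
    idx <- match(key, pkey)
    rev_mult <- if (period == "post") config$post_revenue_multiplier else 1
    attributed <- draw("revenue", quote(
      rlnorm(n, config$revenue_params$meanlog[idx] + log(rev_mult),
             config$revenue_params$sdlog[idx])))

    stay_revenue <- attributed
    admit <- disposition == "admit"
    if (any(admit)) {
      frac <- ifelse(hospital_los[admit] >= 24, 24 / hospital_los[admit],
                     pmin(1, 12 / hospital_los[admit]))
      stay_revenue[admit] <- attributed[admit] / frac
    }
    missing <- draw("missing", quote(runif(n) < config$missingness_rate))
    stay_revenue[missing] <- NA_real_

    tibble::tibble(
      visit_id = sprintf("%s-%07d", period, seq_len(n)),
      period = period,
      disposition = disposition,
      payer = payer,
      ed_los = ed_los,
      hospital_los = hospital_los,
      stay_revenue = stay_revenue
    )
  })
  dplyr::bind_rows(parts)
}
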