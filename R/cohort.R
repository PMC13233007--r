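#' Attribute a fraction of whole-stay revenue to the ED
#'
#' Revenue for ED-discharged patients belongs wholly to the ED. For admitted
#' patients only a fraction of the revenue of the entire hospital stay is
#' credited to the ED: `24 / hospital_los` for stays of 24 hours or longer,
#' and `min(1, 12 / hospital_los)` for shorter stays. The fraction is capped
#' at 1 (a visit cannot be credited more than the whole stay's revenue, which
#' would otherwise occur for stays under 12 hours); a stay of exactly 24
#' hours takes the long-stay branch so the fraction is continuous at 1 there.
#'
#' @param stay_revenue Revenue of the entire hospital stay, US $ (>= 0).
#'   Vectorised; `NA` passes through as `NA`.
#' @param hospital_los Total hospital length of stay in hours (> 0).
#' @param long_stay_hours Threshold (hours) above which the 24-hour
#'   numerator applies; default 24.
#' @return Attributed ED revenue, US $, between 0 and `stay_revenue`.
#' @examples
#' attribute_admission_revenue(10000, 48) # 24/48 -> 5000
#' attribute_admission_revenue(8000, 20)  # 12/20 -> 4800
#' attribute_admission_revenue(5000, 6)   # fraction capped at 1 -> 5000
#' @export
attribute_admission_revenue <- function(stay_revenue, hospital_los,
                                        long_stay_hours = 24) {
  stopifnot(is.numeric(hospital_los))
  bad <- which(is.na(hospital_los) | hospital_los <= 0)
  if (length(bad)) {
    stop("`hospital_los` must be > 0 (offending record index: ",
         paste(head(bad, 5), collapse = ", "), ")", call. = FALSE)
  }
  if (any(stay_revenue < 0, na.rm = TRUE)) {
    stop("`stay_revenue` must be >= 0", call. = FALSE)
  }
  frac <- ifelse(hospital_los >= long_stay_hours,
                 long_stay_hours / hospital_los,
                 pmin(1, long_stay_hours / 2 / hospital_los))
  stay_revenue * frac
}

#' Add attributed revenue to a visit table
#'
#' Discharged visits keep their revenue unchanged; admitted visits receive
#' the [attribute_admission_revenue()] fraction of the whole-stay revenue.
#' Missing revenue stays missing.
#'
#' @param visits A visit tibble (see [read_visits()] for the columns).
#' @return `visits` with an `attributed_revenue` column.
#' @export
attribute_revenue <- function(visits) {
  check_visit_columns(visits, c("disposition", "stay_revenue"))
  admit <- visits$disposition == "admit"
  if (any(admit & (is.na(visits$hospital_los) | visits$hospital_los <= 0))) {
    bad <- which(admit & (is.na(visits$hospital_los) | visits$hospital_los <= 0))
    stop("admitted visits must carry hospital_los > 0 (rows: ",
         paste(head(bad, 5), collapse = ", "), ")", call. = FALSE)
  }
  out <- visits
  out$attributed_revenue <- visits$stay_revenue
  if (any(admit)) {
    out$attributed_revenue[admit] <- attribute_admission_revenue(
      visits$stay_revenue[admit], visits$hospital_los[admit])
  }
  out
}

#' Cap attributed revenue at a percentile of the pooled distribution
#'
#' Caps revenue per visit at the given percentile (default the 95th) of the
#' non-missing attributed revenue, pooled over both study periods, to limit
#' the influence of high-revenue outliers. Missing values stay missing.
#'
#' @param visits A visit tibble with `attributed_revenue`.
#' @param percentile Capping percentile as a fraction in `(0, 1]`.
#' @param method Percentile convention: `"linear"` (interpolation between
#'   order statistics, default) or `"nearest_rank"`.
#' @return A list with `visits` (gaining a `capped_revenue` column) and
#'   `cap_value` (US $).
#' @export
cap_revenue <- function(visits, percentile = 0.95,
                        method = c("linear", "nearest_rank")) {
  method <- match.arg(method)
  check_visit_columns(visits, "attributed_revenue")
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      is.na(percentile) || percentile <= 0 || percentile > 1) {
    stop("`percentile` must be a fraction in (0, 1]", call. = FALSE)
  }
  obs <- visits$attributed_revenue[!is.na(visits$attributed_revenue)]
  if (!length(obs)) {
    stop("cannot cap: all attributed revenue is missing", call. = FALSE)
  }
  cap <- unname(quantile(obs, percentile,
                         type = if (method == "linear") 7L else 1L))
  out <- visits
  out$capped_revenue <- pmin(visits$attributed_revenue, cap)
  list(visits = out, cap_value = cap)
}

#' Impute missing revenue by stratum mean
#'
#' Missing revenue is replaced by the mean capped revenue within strata
#' defined by disposition (admit/discharge) crossed with primary payer,
#' computed from non-missing records pooled over both periods. A stratum
#' with missing values but no observed records falls back to the overall
#' mean (with a warning). Observed values pass through unchanged.
#'
#' @param visits A visit tibble with `capped_revenue` (run [cap_revenue()]
#'   first).
#' @return `visits` with `final_revenue` (complete) and a logical `imputed`
#'   column marking records whose revenue was missing on input.
#' @export
impute_missing_revenue <- function(visits) {
  check_visit_columns(visits, c("disposition", "payer", "capped_revenue"))
  miss <- is.na(visits$capped_revenue)
  if (all(miss)) {
    stop("cannot impute: no observed revenue in any stratum", call. = FALSE)
  }
  out <- visits
  out$imputed <- miss
  out$final_revenue <- visits$capped_revenue
  if (!any(miss)) {
    return(out)
  }
  obs <- visits[!miss, ]
  stratum_means <- dplyr::summarise(
    dplyr::group_by(obs, .data$disposition, .data$payer),
    stratum_mean = mean(.data$capped_revenue), .groups = "drop")
  overall_mean <- mean(obs$capped_revenue)

  need <- dplyr::distinct(visits[miss, c("disposition", "payer")])
  need <- dplyr::left_join(need, stratum_means,
                           by = c("disposition", "payer"))
  if (anyNA(need$stratum_mean)) {
    empty <- need[is.na(need$stratum_mean), ]
    warning("no observed revenue in stratum ",
            paste(paste(empty$disposition, empty$payer, sep = " x "),
                  collapse = "; "),
            "; falling back to the overall mean", call. = FALSE)
    need$stratum_mean[is.na(need$stratum_mean)] <- overall_mean
  }
  fill <- dplyr::left_join(visits[miss, c("disposition", "payer")], need,
                           by = c("disposition", "payer"))
  out$final_revenue[miss] <- fill$stratum_mean
  out
}

#' Summarise one study period
#'
#' @param visits A fully processed visit tibble (every record of the period
#'   must carry `final_revenue`).
#' @param period `"pre"` or `"post"`.
#' @return A [period_summary()]: visit count, total revenue (exact sum of
#'   final revenue), median ED LOS, revenue per visit.
#' @export
summarize_period <- function(visits, period = c("pre", "post")) {
  period <- match.arg(period)
  check_visit_columns(visits, c("period", "ed_los", "final_revenue"))
  sub <- visits[visits$period == period, ]
  if (!nrow(sub)) {
    stop("no records for period \"", period, "\"", call. = FALSE)
  }
  if (anyNA(sub$final_revenue)) {
    stop("period \"", period, "\" has records without final_revenue; ",
         "run impute_missing_revenue() first", call. = FALSE)
  }
  period_summary(
    n_visits = nrow(sub),
    total_revenue = sum(sub$final_revenue),
    median_ed_los = median(sub$ed_los)
  )
}

#' Run the full visit-processing pipeline
#'
#' Applies, in order: ED revenue attribution for admitted visits
#' ([attribute_revenue()]), percentile capping over both periods pooled
#' ([cap_revenue()]), and stratified mean imputation of missing revenue
#' ([impute_missing_revenue()]); then summarises each period present.
#' Imputation operates on capped values, so imputed revenue never exceeds
#' the cap.
#'
#' @param visits A visit tibble (see [read_visits()]).
#' @param percentile Capping percentile, passed to [cap_revenue()].
#' @param cap_method Percentile convention, passed to [cap_revenue()].
#' @return A list with `visits` (processed tibble), `cap_value`,
#'   `n_imputed`, `imputation_by_stratum` (tibble of imputed counts), and
#'   `summaries` (named list of [period_summary()] per period present).
#' @examples
#' cfg <- study_like_config(n_visits_pre = 500, n_visits_post = 500, seed = 7)
#' out <- process_visits(generate_cohort(cfg))
#' out$summaries$pre
#' @export
process_visits <- function(visits, percentile = 0.95,
                           cap_method = c("linear", "nearest_rank")) {
  cap_method <- match.arg(cap_method)
  v <- attribute_revenue(visits)
  capped <- cap_revenue(v, percentile = percentile, method = cap_method)
  v <- impute_missing_revenue(capped$visits)

  by_stratum <- dplyr::summarise(
    dplyr::group_by(v, .data$disposition, .data$payer),
    n_imputed = sum(.data$imputed), .groups = "drop")

  periods <- intersect(c("pre", "post"), unique(v$period))
  summaries <- lapply(periods, function(p) summarize_period(v, p))
  names(summaries) <- periods

  list(visits = v, cap_value = capped$cap_value,
       n_imputed = sum(v$imputed),
       imputation_by_stratum = by_stratum,
       summaries = summaries)
}

PAYER_LEVELS <- c("medicare", "medicaid", "private", "self_pay")

check_visit_columns <- function(visits, cols) {
  if (!is.data.frame(visits)) {
    stop("`visits` must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(cols, names(visits))
  if (length(missing_cols)) {
    stop("`visits` is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  invisible(visits)
}

#' Read a visit-level CSV
#'
#' Expects a UTF-8 comma-separated file with header columns `visit_id`,
#' `period` (pre/post), `disposition` (admit/discharge), `payer`
#' (medicare/medicaid/private/self_pay), `ed_los_min`, `hospital_los_hr`
#' (may be empty for discharges), and `revenue_usd` (empty cell = missing).
#'
#' @param path Path to the CSV file.
#' @param strict If `TRUE` (default) unknown payer codes are rejected with
#'   their row numbers; if `FALSE` they are mapped to an `"other"` stratum.
#' @return A visit tibble with columns `visit_id`, `period`, `disposition`,
#'   `payer`, `ed_los` (minutes), `hospital_los` (hours), `stay_revenue`
#'   (US $, `NA` = missing).
#' @export
read_visits <- function(path, strict = TRUE) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    visit_id = readr::col_character(),
    period = readr::col_character(),
    disposition = readr::col_character(),
    payer = readr::col_character(),
    ed_los_min = readr::col_double(),
    hospital_los_hr = readr::col_double(),
    revenue_usd = readr::col_double()
  ), progress = FALSE)

  fail_rows <- function(bad, what) {
    stop(what, " (rows: ", paste(head(which(bad), 5), collapse = ", "),
         if (sum(bad) > 5) ", ..." else "", ")", call. = FALSE)
  }
  bad <- !(raw$period %in% c("pre", "post"))
  if (any(bad)) fail_rows(bad, "period must be 'pre' or 'post'")
  bad <- !(raw$disposition %in% c("admit", "discharge"))
  if (any(bad)) fail_rows(bad, "disposition must be 'admit' or 'discharge'")
  bad <- !(raw$payer %in% PAYER_LEVELS)
  if (any(bad)) {
    if (strict) {
      fail_rows(bad, "unknown payer code")
    } else {
      raw$payer[bad] <- "other"
    }
  }
  bad <- is.na(raw$ed_los_min) | raw$ed_los_min <= 0
  if (any(bad)) fail_rows(bad, "ed_los_min must be > 0")
  bad <- raw$disposition == "admit" &
    (is.na(raw$hospital_los_hr) | raw$hospital_los_hr <= 0)
  if (any(bad)) fail_rows(bad, "admitted visits need hospital_los_hr > 0")
  bad <- !is.na(raw$revenue_usd) & raw$revenue_usd < 0
  if (any(bad)) fail_rows(bad, "revenue_usd must be >= 0 or empty")

  tibble::tibble(
    visit_id = raw$visit_id,
    period = raw$period,
    disposition = raw$disposition,
    payer = raw$payer,
    ed_los = raw$ed_los_min,
    hospital_los = raw$hospital_los_hr,
    stay_revenue = raw$revenue_usd
  )
}

#' Write a visit tibble as CSV
#'
#' Emits the same dialect [read_visits()] consumes; processed tibbles gain
#' `attributed_revenue_usd`, `capped_revenue_usd`, `final_revenue_usd`, and
#' `imputed` columns when present.
#'
#' @param visits A visit tibble (raw or processed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path) {
  check_visit_columns(visits, c("visit_id", "period", "disposition", "payer",
                                "ed_los", "stay_revenue"))
  out <- tibble::tibble(
    visit_id = visits$visit_id,
    period = visits$period,
    disposition = visits$disposition,
    payer = visits$payer,
    ed_los_min = visits$ed_los,
    hospital_los_hr = visits$hospital_los,
    revenue_usd = visits$stay_revenue
  )
  extras <- c(attributed_revenue_usd = "attributed_revenue",
              capped_revenue_usd = "capped_revenue",
              final_revenue_usd = "final_revenue",
              imputed = "imputed")
  for (nm in names(extras)) {
    if (extras[[nm]] %in% names(visits)) out[[nm]] <- visits[[extras[[nm]]]]
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
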