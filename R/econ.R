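#' Derive the baseline cost structure from observed revenue
#'
#' Baseline (pre-intervention) total cost is presumed to leave the expected
#' operating margin rate `m` on observed revenue: `total = revenue * (1 - m)`.
#' The total is then partitioned into fixed, variable, and modifiable
#' components according to the configured shares.
#'
#' @param revenue Total baseline revenue, US $ (non-negative).
#' @param params A [model_params()] object.
#' @return A [cost_structure()].
#' @examples
#' baseline_cost(138309296, model_params())
#' @export
baseline_cost <- function(revenue, params = model_params()) {
  stopifnot(inherits(params, "model_params"), is.numeric(revenue),
            length(revenue) == 1L)
  if (revenue < 0) stop("`revenue` must be >= 0", call. = FALSE)
  total <- revenue * (1 - params$margin_rate)
  cost_structure(
    total = total,
    fixed = params$shares[["fixed"]] * total,
    variable = params$shares[["variable"]] * total,
    modifiable = params$shares[["modifiable"]] * total
  )
}

#' Hospital-management cost at changed throughput
#'
#' Projects cost from a baseline partition when patient volume and care
#' hours change: the fixed component is unchanged, the variable component
#' scales with the volume ratio, and the modifiable labor component scales
#' with the care-hours ratio (care hours = volume x ED length of stay).
#'
#' @param baseline A baseline [cost_structure()].
#' @param volume_ratio Post/pre visit-volume ratio (> 0).
#' @param care_hours_ratio Post/pre care-hours ratio,
#'   `(V_post * L_post) / (V_pre * L_pre)` with `L` the median ED LOS (> 0).
#' @return Projected total cost, US $.
#' @examples
#' bc <- baseline_cost(138309296)
#' hm_cost(bc, 89259 / 81464, (89259 * 292) / (81464 * 311))
#' @export
hm_cost <- function(baseline, volume_ratio, care_hours_ratio) {
  stopifnot(inherits(baseline, "cost_structure"))
  if (!is.numeric(volume_ratio) || volume_ratio <= 0) {
    stop("`volume_ratio` must be > 0", call. = FALSE)
  }
  if (!is.numeric(care_hours_ratio) || care_hours_ratio <= 0) {
    stop("`care_hours_ratio` must be > 0", call. = FALSE)
  }
  baseline$fixed + baseline$variable * volume_ratio +
    baseline$modifiable * care_hours_ratio
}

#' Public-policy cost
#'
#' The policy-level framework estimates cost from charges through a
#' cost-to-charge ratio, making cost proportional to revenue at the baseline
#' cost-to-revenue ratio `(1 - m)` (the default, `mode = "proportional"`;
#' this is the framework's operative form and keeps the margin rate fixed at
#' `m` for any revenue). A literal constant cost-per-visit variant is
#' available as `mode = "per_visit"`, which requires the baseline cost per
#' visit and the projected visit count; the two modes differ whenever
#' revenue per visit changes.
#'
#' @param revenue Revenue, US $ (non-negative). Ignored for
#'   `mode = "per_visit"`.
#' @param params A [model_params()] object.
#' @param mode `"proportional"` (default) or `"per_visit"`.
#' @param cost_per_visit Baseline cost per visit, US $ (required for
#'   `mode = "per_visit"`).
#' @param n_visits Projected visit count (required for `mode = "per_visit"`).
#' @return Cost, US $.
#' @examples
#' policy_cost(153747123, model_params())
#' @export
policy_cost <- function(revenue, params = model_params(),
                        mode = c("proportional", "per_visit"),
                        cost_per_visit = NULL, n_visits = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "model_params"))
  if (mode == "proportional") {
    if (!is.numeric(revenue) || revenue < 0) {
      stop("`revenue` must be >= 0", call. = FALSE)
    }
    return(revenue * (1 - params$margin_rate))
  }
  if (is.null(cost_per_visit) || is.null(n_visits)) {
    stop("`cost_per_visit` and `n_visits` are required for mode = \"per_visit\"",
         call. = FALSE)
  }
  stopifnot(cost_per_visit >= 0, n_visits > 0)
  cost_per_visit * n_visits
}

#' Compare pre- and post-intervention financials under both frameworks
#'
#' Anchors the baseline cost structure to the pre period (cost =
#' pre revenue x (1 - m)), then evaluates post-period cost and operating
#' margin under both costing frameworks:
#'
#' * hospital management: [hm_cost()] with volume ratio `V_post / V_pre` and
#'   care-hours ratio `(V_post * L_post) / (V_pre * L_pre)`;
#' * public policy: [policy_cost()] on post revenue.
#'
#' Both frameworks coincide at the pre period by construction.
#'
#' @param pre,post [period_summary()] objects for the two periods.
#' @param params A [model_params()] object.
#' @return An object of class `period_comparison`: a list with the inputs,
#'   the baseline [cost_structure()], a tibble `results` (one row per
#'   framework x period with revenue, cost, margin, margin rate), a tibble
#'   `differences` (post minus pre per framework), and an `operations`
#'   tibble (visit volume and median LOS by period).
#' @examples
#' pre <- period_summary(81464, 138309296, 311)
#' post <- period_summary(89259, 153747123, 292)
#' compare_periods(pre, post)
#' @export
compare_periods <- function(pre, post, params = model_params()) {
  stopifnot(inherits(pre, "period_summary"), inherits(post, "period_summary"),
            inherits(params, "model_params"))
  base <- baseline_cost(pre$total_revenue, params)
  volume_ratio <- post$n_visits / pre$n_visits
  care_hours_ratio <- (post$n_visits * post$median_ed_los) /
    (pre$n_visits * pre$median_ed_los)

  res <- list(
    hm_pre = framework_result("hospital_management", pre$total_revenue, base$total),
    hm_post = framework_result("hospital_management", post$total_revenue,
                               hm_cost(base, volume_ratio, care_hours_ratio)),
    policy_pre = framework_result("public_policy", pre$total_revenue, base$total),
    policy_post = framework_result("public_policy", post$total_revenue,
                                   policy_cost(post$total_revenue, params))
  )

  results <- tibble::tibble(
    framework = rep(c("hospital_management", "public_policy"), each = 2L),
    period = rep(c("pre", "post"), 2L),
    revenue = unname(vapply(res, `[[`, numeric(1), "revenue")),
    cost = unname(vapply(res, `[[`, numeric(1), "cost")),
    margin = unname(vapply(res, `[[`, numeric(1), "margin")),
    margin_rate = unname(vapply(res, `[[`, numeric(1), "margin_rate"))
  )

  post_rows <- results[results$period == "post", ]
  pre_rows <- results[results$period == "pre", ]
  differences <- tibble::tibble(
    framework = post_rows$framework,
    revenue = post_rows$revenue - pre_rows$revenue,
    cost = post_rows$cost - pre_rows$cost,
    margin = post_rows$margin - pre_rows$margin,
    margin_rate = post_rows$margin_rate - pre_rows$margin_rate
  )

  ops_pre <- c(pre$n_visits, pre$median_ed_los)
  ops_post <- c(post$n_visits, post$median_ed_los)
  operations <- tibble::tibble(
    metric = c("n_visits", "median_ed_los"),
    pre = ops_pre,
    post = ops_post,
    difference = ops_post - ops_pre
  )

  structure(
    list(params = params, pre = pre, post = post, baseline = base,
         volume_ratio = volume_ratio, care_hours_ratio = care_hours_ratio,
         operations = operations, results = results, differences = differences),
    class = "period_comparison"
  )
}

fmt_usd <- function(x) format(round(x), big.mark = ",", scientific = FALSE)

#' @export
print.period_comparison <- function(x, ...) {
  row <- function(metric, pre, post, diff) {
    cat(sprintf("  %-28s %15s %15s %15s\n", metric, pre, post, diff))
  }
  cat("Pre- vs post-intervention financial metrics\n")
  cat(sprintf("  %-28s %15s %15s %15s\n", "", "Pre", "Post", "Difference"))
  cat("ED operations\n")
  row("Patient volume, n", fmt_usd(x$pre$n_visits), fmt_usd(x$post$n_visits),
      fmt_usd(x$post$n_visits - x$pre$n_visits))
  row("ED LOS (min), median", sprintf("%.0f", x$pre$median_ed_los),
      sprintf("%.0f", x$post$median_ed_los),
      sprintf("%.0f", x$pre$median_ed_los - x$post$median_ed_los))
  for (fw in c("hospital_management", "public_policy")) {
    lab <- if (fw == "hospital_management") "Hospital management level" else
      "Public policy level"
    cat(lab, "\n")
    r <- x$results[x$results$framework == fw, ]
    d <- x$differences[x$differences$framework == fw, ]
    pre <- r[r$period == "pre", ]; post <- r[r$period == "post", ]
    row("Revenue (US $)", fmt_usd(pre$revenue), fmt_usd(post$revenue),
        fmt_usd(d$revenue))
    row("Costs (US $)", fmt_usd(pre$cost), fmt_usd(post$cost), fmt_usd(d$cost))
    row("Operating margin (US $), %",
        sprintf("%s (%.1f)", fmt_usd(pre$margin), 100 * pre$margin_rate),
        sprintf("%s (%.1f)", fmt_usd(post$margin), 100 * post$margin_rate),
        fmt_usd(d$margin))
  }
  invisible(x)
}
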