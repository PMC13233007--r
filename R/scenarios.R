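#' Efficiency scenario specification
#'
#' An efficiency change `e` multiplies the median ED length of stay by
#' `(1 - e)` (so `e = +0.05` is a 5% throughput gain). Two operating
#' scenarios translate that change into financials:
#'
#' * `"capacity_constrained"` (scenario 1): demand exceeds supply, so the
#'   LOS change is accompanied by an equal and inverse volume change,
#'   `V' = V (1 + e)` at constant revenue per visit.
#' * `"volume_stable"` (scenario 2): demand is met; volume and revenue are
#'   unchanged and the care-hours reduction can be converted into
#'   modifiable-labor savings.
#'
#' @param kind `"capacity_constrained"` or `"volume_stable"`.
#' @param e Signed efficiency change, `|e| <= 0.5` (sanity bound; the
#'   standard sweep spans -0.10 to +0.10).
#' @param modifiable_capture Fraction of the care-hours reduction converted
#'   into modifiable-cost savings in the volume-stable scenario, in
#'   `[0, 1]`; the default 1 treats the reduction as fully commensurate.
#' @return An object of class `efficiency_scenario`.
#' @export
efficiency_scenario <- function(kind = c("capacity_constrained", "volume_stable"),
                                e, modifiable_capture = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(e) || length(e) != 1L || is.na(e) || abs(e) > 0.5) {
    stop("`e` must be a number with |e| <= 0.5", call. = FALSE)
  }
  if (!is.numeric(modifiable_capture) || modifiable_capture < 0 ||
      modifiable_capture > 1) {
    stop("`modifiable_capture` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(kind = kind, e = e, modifiable_capture = modifiable_capture),
            class = "efficiency_scenario")
}

#' Project period financials under an efficiency scenario
#'
#' Starting from a baseline [period_summary()] (volume `V`, revenue `R`,
#' median LOS `L`) and its [baseline_cost()] partition:
#'
#' * **capacity-constrained**: `V' = V (1 + e)`, `L' = L (1 - e)`,
#'   `R' = R (1 + e)` (constant revenue per visit). Hospital-management cost
#'   is `fixed + variable (1 + e) + modifiable (1 + e)(1 - e)` — the
#'   modifiable component follows the care-hours ratio
#'   `(1 + e)(1 - e) = 1 - e^2`. Policy cost is `R' (1 - m)`.
#' * **volume-stable**: `V' = V`, `L' = L (1 - e)`, `R' = R`.
#'   Hospital-management cost is
#'   `fixed + variable + modifiable (1 - e * capture)`; policy cost stays at
#'   the baseline `R (1 - m)` (volume, hence policy-level cost, is
#'   unchanged), so the policy margin is flat in `e`.
#'
#' @param baseline A [period_summary()] for the reference period.
#' @param scenario An [efficiency_scenario()].
#' @param params A [model_params()] object.
#' @return An object of class `scenario_point`: `e`, `kind`, projected
#'   `volume`, `ed_los`, `revenue`, [framework_result()]s `hm` and
#'   `policy`, and `margin_delta` (named numeric, each framework's margin
#'   minus the baseline margin `m * R`).
#' @examples
#' base <- period_summary(81464, 138309296, 311)
#' project_scenario(base, efficiency_scenario("capacity_constrained", 0.05))
#' @export
project_scenario <- function(baseline, scenario, params = model_params()) {
  stopifnot(inherits(baseline, "period_summary"),
            inherits(scenario, "efficiency_scenario"),
            inherits(params, "model_params"))
  e <- scenario$e
  base_cost <- baseline_cost(baseline$total_revenue, params)
  base_margin <- baseline$total_revenue - base_cost$total

  if (scenario$kind == "capacity_constrained") {
    volume <- baseline$n_visits * (1 + e)
    ed_los <- baseline$median_ed_los * (1 - e)
    revenue <- baseline$total_revenue * (1 + e)
    hm <- base_cost$fixed + base_cost$variable * (1 + e) +
      base_cost$modifiable * (1 + e) * (1 - e)
    pol <- policy_cost(revenue, params)
  } else {
    volume <- baseline$n_visits
    ed_los <- baseline$median_ed_los * (1 - e)
    revenue <- baseline$total_revenue
    hm <- base_cost$fixed + base_cost$variable +
      base_cost$modifiable * (1 - e * scenario$modifiable_capture)
    # revenue and policy-level cost are both unchanged at stable volume,
    # so the policy margin delta is zero for any e
    pol <- policy_cost(baseline$total_revenue, params)
  }

  hm_res <- framework_result("hospital_management", revenue, hm)
  pol_res <- framework_result("public_policy", revenue, pol)
  structure(
    list(e = e, kind = scenario$kind,
         modifiable_capture = scenario$modifiable_capture,
         volume = volume, ed_los = ed_los, revenue = revenue,
         baseline = baseline, baseline_cost = base_cost,
         hm = hm_res, policy = pol_res,
         margin_delta = c(hospital_management = hm_res$margin - base_margin,
                          public_policy = pol_res$margin - base_margin)),
    class = "scenario_point"
  )
}

#' @export
print.scenario_point <- function(x, ...) {
  cat(sprintf("Scenario point (%s, e = %+.2f)\n", x$kind, x$e))
  cat(sprintf("  volume %.0f, median ED LOS %.1f min, revenue $%s\n",
              x$volume, x$ed_los, fmt_usd(x$revenue)))
  cat(sprintf("  HM:     cost $%s, margin $%s (%+.1f%% pts delta $%s)\n",
              fmt_usd(x$hm$cost), fmt_usd(x$hm$margin),
              100 * x$hm$margin_rate,
              fmt_usd(x$margin_delta[["hospital_management"]])))
  cat(sprintf("  Policy: cost $%s, margin $%s (%+.1f%% pts delta $%s)\n",
              fmt_usd(x$policy$cost), fmt_usd(x$policy$margin),
              100 * x$policy$margin_rate,
              fmt_usd(x$margin_delta[["public_policy"]])))
  invisible(x)
}

#' Break-even intervention cost per visit
#'
#' The per-visit price at which an efficiency intervention's cost exactly
#' offsets the operating-margin gain it enables:
#' `B = (margin_scenario - margin_baseline) / post_visits`.
#' A negative `B` (margin loss) means there is no sustainable tool cost;
#' it is reported as-is, flagged, and never clamped to zero.
#'
#' @param margin_baseline Baseline operating margin, US $.
#' @param margin_scenario Scenario (or post-period) operating margin, US $.
#' @param post_visits Total visit count in the scenario period (> 0).
#' @return An object of class `break_even_result` with `break_even` (US $
#'   per visit), `margin_delta`, `post_visits`, and `sustainable`
#'   (`break_even >= 0`).
#' @examples
#' break_even(8021939, 13667102, 85537)
#' @export
break_even <- function(margin_baseline, margin_scenario, post_visits) {
  stopifnot(is.numeric(margin_baseline), is.numeric(margin_scenario),
            is.numeric(post_visits))
  if (post_visits <= 0) {
    stop("`post_visits` must be > 0", call. = FALSE)
  }
  delta <- margin_scenario - margin_baseline
  structure(
    list(break_even = delta / post_visits, margin_delta = delta,
         post_visits = post_visits, sustainable = delta >= 0),
    class = "break_even_result"
  )
}

#' @export
print.break_even_result <- function(x, ...) {
  if (x$sustainable) {
    cat(sprintf("Break-even tool cost: $%.2f per visit (margin delta $%s over %s visits)\n",
                x$break_even, fmt_usd(x$margin_delta), fmt_usd(x$post_visits)))
  } else {
    cat(sprintf("No sustainable tool cost: margin falls by $%s ($%.2f per visit)\n",
                fmt_usd(-x$margin_delta), x$break_even))
  }
  invisible(x)
}

#' Sensitivity sweep over an efficiency grid
#'
#' Evaluates [project_scenario()] on a grid of efficiency changes (default
#' -10% to +10% in 1-point steps, 21 points) and attaches per-visit
#' break-even tool costs for both frameworks at each point.
#'
#' @param baseline A [period_summary()].
#' @param kind Scenario kind, as in [efficiency_scenario()].
#' @param params A [model_params()] object.
#' @param e_grid Numeric grid of efficiency changes, each with
#'   `|e| <= 0.5`.
#' @param modifiable_capture Capture fraction for the volume-stable
#'   scenario.
#' @return A tibble with one row per grid point: `e`, `ed_los`, `volume`,
#'   `revenue`, `hm_cost`, `hm_margin`, `hm_margin_rate`, `policy_cost`,
#'   `policy_margin`, `policy_margin_rate`, `hm_break_even`,
#'   `policy_break_even`.
#' @examples
#' base <- period_summary(81464, 138309296, 311)
#' sweep_scenarios(base, "capacity_constrained")
#' @export
sweep_scenarios <- function(baseline,
                            kind = c("capacity_constrained", "volume_stable"),
                            params = model_params(),
                            e_grid = seq(-0.10, 0.10, by = 0.01),
                            modifiable_capture = 1) {
  kind <- match.arg(kind)
  if (!length(e_grid)) stop("`e_grid` must not be empty", call. = FALSE)
  base_margin <- baseline$total_revenue *
    params$margin_rate # revenue - revenue(1-m)
  rows <- lapply(e_grid, function(e) {
    pt <- project_scenario(baseline,
                           efficiency_scenario(kind, e, modifiable_capture),
                           params)
    hm_be <- break_even(base_margin, pt$hm$margin, pt$volume)
    pol_be <- break_even(base_margin, pt$policy$margin, pt$volume)
    tibble::tibble(
      e = e, ed_los = pt$ed_los, volume = pt$volume, revenue = pt$revenue,
      hm_cost = pt$hm$cost, hm_margin = pt$hm$margin,
      hm_margin_rate = pt$hm$margin_rate,
      policy_cost = pt$policy$cost, policy_margin = pt$policy$margin,
      policy_margin_rate = pt$policy$margin_rate,
      hm_break_even = hm_be$break_even,
      policy_break_even = pol_be$break_even
    )
  })
  dplyr::bind_rows(rows)
}

#' Plot a sensitivity sweep
#'
#' Operating margin against efficiency change for both costing frameworks.
#'
#' @param sweep A tibble from [sweep_scenarios()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  stopifnot(is.data.frame(sweep),
            all(c("e", "hm_margin", "policy_margin") %in% names(sweep)))
  long <- tibble::tibble(
    e = rep(sweep$e, 2L),
    framework = rep(c("Hospital management", "Public policy"),
                    each = nrow(sweep)),
    margin = c(sweep$hm_margin, sweep$policy_margin)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$e, y = .data$margin / 1e6,
                                     colour = .data$framework)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Efficiency change e (LOS x (1 - e))",
                  y = "Operating margin (US $ millions)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
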