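#' Economic model parameters
#'
#' Bundles the baseline operating-margin rate and the fixed/variable/
#' modifiable cost shares of the hospital-management costing framework.
#' Defaults reflect a 5.8% baseline margin rate and a 70/20/10 cost
#' partition; both are institution-adjustable.
#'
#' @param margin_rate Baseline operating margin rate, a fraction in `[0, 1)`.
#'   Baseline cost is derived from revenue as `revenue * (1 - margin_rate)`.
#' @param fixed_share,variable_share,modifiable_share Cost shares, each in
#'   `[0, 1]` and summing to 1: fixed standby cost (labor, facility,
#'   equipment, overhead), volume-variable cost (supplies, pharmaceuticals),
#'   and modifiable labor cost (contract labor, overtime) that flexes with
#'   care hours.
#' @return An object of class `model_params`.
#' @examples
#' model_params()
#' model_params(margin_rate = 0.04, fixed_share = 0.75,
#'              variable_share = 0.15, modifiable_share = 0.10)
#' @export
model_params <- function(margin_rate = 0.058,
                         fixed_share = 0.70,
                         variable_share = 0.20,
                         modifiable_share = 0.10) {
  stopifnot(is.numeric(margin_rate), length(margin_rate) == 1L)
  if (is.na(margin_rate) || margin_rate < 0 || margin_rate >= 1) {
    stop("`margin_rate` must be a fraction in [0, 1)", call. = FALSE)
  }
  shares <- c(fixed = fixed_share, variable = variable_share,
              modifiable = modifiable_share)
  if (anyNA(shares) || any(shares < 0) || any(shares > 1)) {
    stop("cost shares must each lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(shares) - 1) > 1e-12) {
    stop("cost shares must sum to 1 (got ", format(sum(shares), digits = 15),
         ")", call. = FALSE)
  }
  structure(
    list(margin_rate = margin_rate, shares = shares),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Economic model parameters\n")
  cat(sprintf("  margin rate: %.1f%%\n", 100 * x$margin_rate))
  cat(sprintf("  cost shares: fixed %.0f%% / variable %.0f%% / modifiable %.0f%%\n",
              100 * x$shares[["fixed"]], 100 * x$shares[["variable"]],
              100 * x$shares[["modifiable"]]))
  invisible(x)
}

#' Cost structure: total cost and its fixed/variable/modifiable partition
#'
#' @param total Total cost in US $.
#' @param fixed,variable,modifiable Component costs in US $; must be
#'   non-negative and sum to `total` within cent tolerance.
#' @return An object of class `cost_structure`.
#' @seealso [baseline_cost()] which derives one from revenue.
#' @export
cost_structure <- function(total, fixed, variable, modifiable) {
  comps <- c(fixed = fixed, variable = variable, modifiable = modifiable)
  stopifnot(is.numeric(total), length(total) == 1L, is.numeric(comps))
  if (any(comps < 0) || total < 0) {
    stop("cost components must be non-negative", call. = FALSE)
  }
  if (abs(sum(comps) - total) > 0.01) {
    stop("cost components must sum to total within one cent", call. = FALSE)
  }
  structure(
    list(total = total, fixed = fixed, variable = variable,
         modifiable = modifiable),
    class = "cost_structure"
  )
}

#' @export
print.cost_structure <- function(x, ...) {
  cat("Cost structure (US $)\n")
  cat(sprintf("  total:      %s\n", format(round(x$total), big.mark = ",")))
  cat(sprintf("  fixed:      %s\n", format(round(x$fixed), big.mark = ",")))
  cat(sprintf("  variable:   %s\n", format(round(x$variable), big.mark = ",")))
  cat(sprintf("  modifiable: %s\n", format(round(x$modifiable), big.mark = ",")))
  invisible(x)
}

#' Operating margin and margin rate
#'
#' Operating margin is revenue minus cost; the margin rate is
#' `(revenue - cost) / revenue`.
#'
#' @param revenue Revenue in US $.
#' @param cost Cost in US $.
#' @param rate If `TRUE` (default), also compute the margin rate; requires
#'   `revenue > 0` (the rate is undefined at zero revenue and requesting it
#'   is an error).
#' @return A list with elements `margin` (US $) and `rate` (fraction;
#'   `NULL` when `rate = FALSE`).
#' @examples
#' margin(138309296, 130287357)
#' @export
margin <- function(revenue, cost, rate = TRUE) {
  stopifnot(is.numeric(revenue), is.numeric(cost),
            length(revenue) == 1L, length(cost) == 1L)
  m <- revenue - cost
  if (!rate) {
    return(list(margin = m, rate = NULL))
  }
  if (revenue == 0) {
    stop("margin rate is undefined when revenue is zero", call. = FALSE)
  }
  list(margin = m, rate = m / revenue)
}

#' Financial result under one costing framework
#'
#' @param framework `"hospital_management"` or `"public_policy"`.
#' @param revenue,cost Revenue and cost in US $ (`revenue > 0`).
#' @return An object of class `framework_result` with fields `framework`,
#'   `revenue`, `cost`, `margin`, and `margin_rate`.
#' @export
framework_result <- function(framework = c("hospital_management", "public_policy"),
                             revenue, cost) {
  framework <- match.arg(framework)
  mg <- margin(revenue, cost)
  structure(
    list(framework = framework, revenue = revenue, cost = cost,
         margin = mg$margin, margin_rate = mg$rate),
    class = "framework_result"
  )
}

#' @export
print.framework_result <- function(x, ...) {
  lab <- c(hospital_management = "Hospital management",
           public_policy = "Public policy")[[x$framework]]
  cat(sprintf("%s framework result (US $)\n", lab))
  cat(sprintf("  revenue: %s\n", format(round(x$revenue), big.mark = ",")))
  cat(sprintf("  cost:    %s\n", format(round(x$cost), big.mark = ",")))
  cat(sprintf("  margin:  %s (%.1f%%)\n",
              format(round(x$margin), big.mark = ","), 100 * x$margin_rate))
  invisible(x)
}

#' Aggregate summary of one study period
#'
#' Holds the aggregate state the economic model consumes: visit count,
#' total attributed revenue, and median ED length of stay.
#'
#' @param n_visits Number of ED visits in the period (positive integer).
#' @param total_revenue Total revenue, US $ (non-negative).
#' @param median_ed_los Median ED length of stay in minutes (positive).
#' @return An object of class `period_summary` with the three inputs plus
#'   `revenue_per_visit`.
#' @examples
#' period_summary(81464, 138309296, 311)
#' @export
period_summary <- function(n_visits, total_revenue, median_ed_los) {
  stopifnot(is.numeric(n_visits), is.numeric(total_revenue),
            is.numeric(median_ed_los))
  if (n_visits <= 0 || n_visits != round(n_visits)) {
    stop("`n_visits` must be a positive whole number", call. = FALSE)
  }
  if (total_revenue < 0) stop("`total_revenue` must be >= 0", call. = FALSE)
  if (median_ed_los <= 0) stop("`median_ed_los` must be > 0", call. = FALSE)
  structure(
    list(n_visits = as.numeric(n_visits),
         total_revenue = total_revenue,
         median_ed_los = median_ed_los,
         revenue_per_visit = total_revenue / n_visits),
    class = "period_summary"
  )
}

#' @export
print.period_summary <- function(x, ...) {
  cat("Period summary\n")
  cat(sprintf("  visits:            %s\n", format(x$n_visits, big.mark = ",")))
  cat(sprintf("  total revenue:     $%s\n",
              format(round(x$total_revenue), big.mark = ",")))
  cat(sprintf("  median ED LOS:     %.0f min\n", x$median_ed_los))
  cat(sprintf("  revenue per visit: $%.2f\n", x$revenue_per_visit))
  invisible(x)
}
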