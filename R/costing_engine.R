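# Core costing computation: cost = unit cost x target population x
# coverage, with aggregation by intervention, category, region and
# scenario, percentage shares, and the per-child package rate.

intervention_categories <- c("counselling", "supplementation",
                             "micronutrient_deworming", "health",
                             "fortification", "cash_transfer", "bcc")

#' Construct an intervention
#'
#' @param id unique identifier within a scenario.
#' @param name human-readable name.
#' @param category one of `counselling`, `supplementation`,
#'   `micronutrient_deworming`, `health`, `fortification`,
#'   `cash_transfer`, `bcc`.
#' @param target_rule a [target_rule()].
#' @param unit_cost a [unit_cost()].
#' @param coverage delivered fraction of the target population, in
#'   `[0,1]`; full coverage (1.0) by default.
#' @return An object of class `intervention`.
#' @export
intervention <- function(id, name, category, target_rule, unit_cost, coverage = 1.0) {
  nc_check(is.character(id) && length(id) == 1L && nzchar(id),
           "intervention id must be a non-empty string", "nutricost_config_error")
  nc_check(is.character(name) && length(name) == 1L,
           "intervention name must be a string", "nutricost_config_error")
  nc_check(category %in% intervention_categories,
           sprintf("category must be one of: %s",
                   paste(intervention_categories, collapse = ", ")),
           "nutricost_config_error")
  stopifnot(inherits(target_rule, "target_rule"), inherits(unit_cost, "unit_cost"))
  nc_check(is_fraction(coverage), "coverage must be in [0,1]", "nutricost_config_error")
  structure(list(id = id, name = name, category = category,
                 target_rule = target_rule, unit_cost = unit_cost,
                 coverage = coverage),
            class = "intervention")
}

#' Compute one intervention x region cost line
#'
#' The elementary costing product: annual cost in US$ million equals
#' target population x coverage x annual unit cost / 1e6. Full precision
#' is carried in the line; rounding to 0.01 US$ million happens only when
#' reports are printed or written.
#'
#' @param iv an [intervention()].
#' @param tp resolved target population (persons, possibly fractional).
#' @param ctx a [currency_context()].
#' @param region_id region label for the line.
#' @return One-row data frame with columns `intervention_id`, `name`,
#'   `category`, `region_id`, `target_population`, `annual_unit_cost`,
#'   `coverage`, `cost_usd_million`.
#' @export
#' @examples
#' iv <- intervention("vita", "Vitamin A", "micronutrient_deworming",
#'                    target_rule("children_6_59m"),
#'                    unit_cost(0.07, "USD", "per_beneficiary_year"))
#' compute_cost_line(iv, 108.1e6)
compute_cost_line <- function(iv, tp, ctx = currency_context(), region_id = "national") {
  stopifnot(inherits(iv, "intervention"))
  nc_check(is_scalar_number(tp) && tp >= 0, "target population must be non-negative")
  auc <- annualize(iv$unit_cost, ctx)
  data.frame(intervention_id = iv$id, name = iv$name, category = iv$category,
             region_id = region_id, target_population = tp,
             annual_unit_cost = auc, coverage = iv$coverage,
             cost_usd_million = tp * iv$coverage * auc / 1e6,
             stringsAsFactors = FALSE)
}

#' Cost a scenario
#'
#' The package's main computation. For each region, beneficiary cohorts
#' are derived with [derive_cohorts()] and every intervention's target
#' rule is resolved (in dependency order so subtraction rules see their
#' antecedents); `target_overrides` replace rule-derived targets wherever
#' provided, which is how packaged fixture targets back-derived from
#' published costs take precedence over the stationary cohort formulas.
#' Each intervention x region pair then yields one cost line.
#'
#' @param scenario a [scenario()] (or the result of [load_scenario()]).
#' @param regions list of [region_demographics()], or `NULL` to run purely
#'   from `target_overrides` as a single national computation.
#' @param target_overrides named numeric vector, intervention id ->
#'   target population (persons); applied after rule resolution.
#' @param target_year projection year (default 2014).
#' @param region_id label used when `regions` is `NULL`.
#' @return An object of class `cost_report`.
#' @export
cost_scenario <- function(scenario, regions = NULL, target_overrides = NULL,
                          target_year = 2014, region_id = "national") {
  stopifnot(inherits(scenario, "scenario"))
  overrides <- unlist(target_overrides) %||% numeric()
  if (length(overrides)) {
    nc_check(is.numeric(overrides) && !is.null(names(overrides)) && all(overrides >= 0),
             "target_overrides must be a named non-negative numeric vector")
    unknown <- setdiff(names(overrides), vapply(scenario$interventions, `[[`, "", "id"))
    nc_check(length(unknown) == 0L,
             sprintf("target_overrides for unknown intervention(s): %s",
                     paste(unknown, collapse = ", ")), "nutricost_config_error")
  }
  ivs <- scenario$interventions
  rules <- lapply(ivs, `[[`, "target_rule")
  names(rules) <- vapply(ivs, `[[`, "", "id")
  order_ids <- topological_rule_order(rules)

  resolve_region <- function(demo, rid) {
    resolved <- numeric()
    if (!is.null(demo)) cohorts <- derive_cohorts(demo, target_year)
    for (id in order_ids) {
      if (id %in% names(overrides)) {
        resolved[[id]] <- overrides[[id]]
      } else if (is.null(demo)) {
        nc_stop(sprintf(
          "no demographics supplied and no target override for intervention '%s'", id),
          "nutricost_resolution_error")
      } else {
        resolved[[id]] <- resolve_target(rules[[id]], cohorts, demo, resolved)
      }
    }
    do.call(rbind, lapply(ivs, function(iv) {
      compute_cost_line(iv, resolved[[iv$id]], scenario$currency_ctx, rid)
    }))
  }

  lines <- if (is.null(regions)) {
    resolve_region(NULL, region_id)
  } else {
    nc_check(length(regions) > 0 &&
               all(vapply(regions, inherits, logical(1), "region_demographics")),
             "regions must be a non-empty list of region_demographics")
    do.call(rbind, lapply(regions, function(demo) resolve_region(demo, demo$region_id)))
  }
  rownames(lines) <- NULL
  new_cost_report(scenario$name, lines)
}

new_cost_report <- function(scenario_name, lines) {
  stopifnot(is.data.frame(lines))
  bad <- abs(lines$cost_usd_million -
               lines$target_population * lines$coverage * lines$annual_unit_cost / 1e6) >
    1e-6 * pmax(1, abs(lines$cost_usd_million))
  nc_check(!any(bad), "cost line inconsistent with tp x coverage x unit cost")
  structure(list(scenario = scenario_name, lines = lines), class = "cost_report")
}

#' Aggregate a cost report
#'
#' Exact sums of full-precision line costs per grouping key; the grand
#' total is identical over any complete partition.
#'
#' @param report a `cost_report`.
#' @param by grouping key: `intervention`, `category`, `region` or
#'   `scenario`.
#' @return Named numeric vector of US$ million per group, in first-appearance
#'   order.
#' @export
cost_aggregate <- function(report, by = c("intervention", "category", "region", "scenario")) {
  stopifnot(inherits(report, "cost_report"))
  by <- match.arg(by)
  nc_check(nrow(report$lines) > 0, "cost report has no lines")
  key <- switch(by,
                intervention = report$lines$intervention_id,
                category = report$lines$category,
                region = report$lines$region_id,
                scenario = rep(report$scenario, nrow(report$lines)))
  key <- factor(key, levels = unique(key))
  out <- tapply(report$lines$cost_usd_million, key, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Percentage cost shares
#'
#' `100 x group cost / grand total`, reported to two decimals (half-up).
#'
#' @param report a `cost_report`.
#' @param level `intervention` or `category`.
#' @return Named numeric vector of percentages.
#' @export
cost_shares <- function(report, level = c("intervention", "category")) {
  level <- match.arg(level)
  agg <- cost_aggregate(report, by = level)
  total <- sum(agg)
  if (total <= 0) {
    nc_stop("cost shares undefined: grand total is zero", "nutricost_invalid_input")
  }
  round_half_up(100 * agg / total, 2)
}

#' Per-child package cost
#'
#' Sums per-child (0-24 months) per-year component costs into the single
#' budgeting rule-of-thumb rate for the full package.
#'
#' @param component_costs named non-negative numeric vector, US$ per child
#'   per year by component.
#' @return Total US$ per child (0-24 months) per year.
#' @export
#' @examples
#' per_child_package_cost(c(food = 54.2, cash = 68.4, counselling = 6.8,
#'                          micronutrient = 4.7, health = 5.9))
per_child_package_cost <- function(component_costs) {
  nc_check(is.numeric(component_costs) && all(component_costs >= 0),
           "component costs must be non-negative")
  sum(component_costs)
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("Scenario: %s\n", x$scenario))
  cat(sprintf("%d cost line(s), %d region(s)\n\n",
              nrow(x$lines), length(unique(x$lines$region_id))))
  df <- x$lines
  shown <- data.frame(intervention = df$intervention_id, region = df$region_id,
                      `target (persons)` = signif(df$target_population, 6),
                      `UC (US$/yr)` = df$annual_unit_cost,
                      coverage = df$coverage,
                      `cost (US$M/yr)` = round_half_up(df$cost_usd_million, 2),
                      check.names = FALSE)
  print(shown, row.names = FALSE)
  cat(sprintf("\nTotal: %.2f US$ million/yr\n", round_half_up(sum(df$cost_usd_million), 2)))
  invisible(x)
}

#' @export
summary.cost_report <- function(object, ...) {
  structure(list(scenario = object$scenario,
                 n_lines = nrow(object$lines),
                 n_regions = length(unique(object$lines$region_id)),
                 total = sum(object$lines$cost_usd_million),
                 by_category = cost_aggregate(object, "category"),
                 category_shares = cost_shares(object, "category"),
                 intervention_shares = cost_shares(object, "intervention")),
            class = "summary.cost_report")
}

#' @export
print.summary.cost_report <- function(x, ...) {
  cat(sprintf("Scenario: %s  (%d lines, %d regions)\n", x$scenario, x$n_lines, x$n_regions))
  cat(sprintf("Total annual cost: %.2f US$ million\n\nBy category (US$ million, share %%):\n",
              round_half_up(x$total, 2)))
  tab <- data.frame(category = names(x$by_category),
                    `cost (US$M/yr)` = round_half_up(as.numeric(x$by_category), 2),
                    `share (%)` = as.numeric(x$category_shares[names(x$by_category)]),
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.cost_report <- function(x, ...) x$lines

#' @export
plot.cost_report <- function(x, ...) {
  agg <- cost_aggregate(x, "category")
  graphics::barplot(agg, ylab = "Cost (US$ million/yr)",
                    main = sprintf("%s: annual cost by category", x$scenario),
                    las = 2, ...)
  invisible(x)
}
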