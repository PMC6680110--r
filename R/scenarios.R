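# Scenario definition, loading from declarative YAML configuration,
# comparison and one-way sensitivity swaps.

#' Construct a scenario
#'
#' @param name scenario name.
#' @param interventions non-empty list of [intervention()] with unique ids.
#' @param currency_ctx a [currency_context()].
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, interventions, currency_ctx = currency_context()) {
  nc_check(is.character(name) && length(name) == 1L && nzchar(name),
           "scenario name must be a non-empty string", "nutricost_config_error")
  nc_check(is.list(interventions) && length(interventions) > 0 &&
             all(vapply(interventions, inherits, logical(1), "intervention")),
           "interventions must be a non-empty list of intervention objects",
           "nutricost_config_error")
  ids <- vapply(interventions, `[[`, "", "id")
  nc_check(!anyDuplicated(ids),
           sprintf("duplicate intervention id(s): %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")),
           "nutricost_config_error")
  stopifnot(inherits(currency_ctx, "currency_context"))
  names(interventions) <- ids
  structure(list(name = name, interventions = interventions,
                 currency_ctx = currency_ctx), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: %d interventions\n", x$name, length(x$interventions)))
  for (iv in x$interventions) {
    cat(sprintf("  %-18s %-24s US$%.2f/beneficiary-yr, coverage %.0f%%\n",
                iv$id, paste0("[", iv$category, "]"),
                annualize(iv$unit_cost, x$currency_ctx), 100 * iv$coverage))
  }
  invisible(x)
}

config_fail <- function(path, msgs) {
  nc_stop(sprintf("invalid scenario config '%s':\n  - %s",
                  path, paste(msgs, collapse = "\n  - ")),
          "nutricost_config_error")
}

#' Load a scenario from a YAML configuration
#'
#' A scenario config is declarative data: a `scenario` section (name), a
#' `currency` section (`inr_per_usd`, `inflation_factor`), a `unit_costs`
#' registry (named unit-cost entries with `amount`, `currency`, `basis`
#' and the basis's convention field) and an `interventions` section (named
#' entries with `name`, `category`, `unit_cost` registry reference,
#' optional `coverage`, and a `target` rule with the [target_rule()]
#' fields). Two configs ship with the package:
#' `system.file("extdata", "sun.yaml", package = "nutricost")` (the
#' ten-intervention global package) and `india_plus.yaml` (the
#' fifteen-intervention India package).
#'
#' @param path path to the YAML file, or one of the shorthand names
#'   `"sun"` / `"india_plus"` for the packaged configs.
#' @return A [scenario()].
#' @export
#' @examples
#' scn <- load_scenario("sun")
#' length(scn$interventions)  # 10
load_scenario <- function(path) {
  if (path %in% c("sun", "india_plus")) {
    path <- system.file("extdata", paste0(path, ".yaml"), package = "nutricost")
  }
  nc_check(file.exists(path), sprintf("scenario config not found: %s", path),
           "nutricost_config_error")
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) config_fail(path, conditionMessage(e)))
  msgs <- character()
  note <- function(m) msgs <<- c(msgs, m)

  for (sec in c("scenario", "unit_costs", "interventions")) {
    if (is.null(cfg[[sec]])) note(sprintf("missing section '%s'", sec))
  }
  if (length(msgs)) config_fail(path, msgs)
  if (is.null(cfg$scenario$name)) note("scenario.name is required")

  cur <- cfg$currency %||% list()
  ctx <- tryCatch(
    currency_context(inr_per_usd = cur$inr_per_usd %||% 62.0,
                     inflation_factor = cur$inflation_factor %||% 1.0),
    nutricost_error = function(e) { note(paste0("currency: ", conditionMessage(e))); NULL })

  ucs <- list()
  for (uid in names(cfg$unit_costs)) {
    u <- cfg$unit_costs[[uid]]
    ucs[[uid]] <- tryCatch(
      unit_cost(amount = u$amount, currency = u$currency %||% "USD",
                basis = u$basis %||% "per_beneficiary_year",
                days_per_year = u$days_per_year,
                visits_per_year = u$visits_per_year,
                children_per_household = u$children_per_household,
                source = u$source %||% ""),
      error = function(e) { note(sprintf("unit_costs.%s: %s", uid, conditionMessage(e))); NULL })
  }

  ivs <- list()
  for (iid in names(cfg$interventions)) {
    e <- cfg$interventions[[iid]]
    if (is.null(e$unit_cost) || !e$unit_cost %in% names(ucs)) {
      note(sprintf("interventions.%s: unit_cost must reference a unit_costs entry", iid))
      next
    }
    t <- e$target %||% list()
    rule <- tryCatch(
      target_rule(cohort = t$cohort %||% NA_character_,
                  prevalence_filter = t$prevalence_filter,
                  incidence_multiplier = t$incidence_multiplier %||% 1,
                  inpatient_fraction = t$inpatient_fraction %||% 1,
                  exclusion_fraction = t$exclusion_fraction %||% 0,
                  endemic_only = t$endemic_only %||% FALSE,
                  exclude_govt_workers = t$exclude_govt_workers %||% FALSE,
                  subtract_rule = t$subtract_rule,
                  expected_reduction = t$expected_reduction %||% 0),
      error = function(err) {
        note(sprintf("interventions.%s.target: %s", iid, conditionMessage(err))); NULL })
    if (is.null(rule) || is.null(ucs[[e$unit_cost]])) next
    ivs[[iid]] <- tryCatch(
      intervention(id = iid, name = e$name %||% iid,
                   category = e$category %||% NA_character_,
                   target_rule = rule, unit_cost = ucs[[e$unit_cost]],
                   coverage = e$coverage %||% 1.0),
      error = function(err) {
        note(sprintf("interventions.%s: %s", iid, conditionMessage(err))); NULL })
  }
  if (length(msgs)) config_fail(path, msgs)
  sub_targets <- unlist(lapply(ivs, function(iv) iv$target_rule$subtract_rule))
  bad <- setdiff(sub_targets, names(ivs))
  if (length(bad)) {
    config_fail(path, sprintf("subtract_rule references unknown intervention(s): %s",
                              paste(bad, collapse = ", ")))
  }
  scenario(cfg$scenario$name, unname(ivs), ctx)
}

#' Compare two cost reports by category
#'
#' Side-by-side group totals with differences `b - a`; categories present
#' in only one report appear with zero in the other.
#'
#' @param a,b `cost_report` objects.
#' @param level grouping level, `category` (default) or `intervention`.
#' @return A data frame of class `cost_comparison` with columns `group`,
#'   `cost_a`, `cost_b`, `difference` (US$ million/yr) plus a final total
#'   row.
#' @export
compare_scenarios <- function(a, b, level = c("category", "intervention")) {
  stopifnot(inherits(a, "cost_report"), inherits(b, "cost_report"))
  level <- match.arg(level)
  agg_a <- cost_aggregate(a, level)
  agg_b <- cost_aggregate(b, level)
  groups <- union(names(agg_a), names(agg_b))
  ca <- stats::setNames(rep(0, length(groups)), groups); ca[names(agg_a)] <- agg_a
  cb <- stats::setNames(rep(0, length(groups)), groups); cb[names(agg_b)] <- agg_b
  out <- data.frame(group = c(groups, "total"),
                    cost_a = c(as.numeric(ca), sum(ca)),
                    cost_b = c(as.numeric(cb), sum(cb)),
                    stringsAsFactors = FALSE)
  out$difference <- out$cost_b - out$cost_a
  structure(out, class = c("cost_comparison", "data.frame"),
            scenario_a = a$scenario, scenario_b = b$scenario)
}

#' @export
print.cost_comparison <- function(x, ...) {
  cat(sprintf("Cost comparison (US$ million/yr): %s vs %s\n",
              attr(x, "scenario_a"), attr(x, "scenario_b")))
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round_half_up, 2)
  names(df)[2:3] <- c(attr(x, "scenario_a"), attr(x, "scenario_b"))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.cost_comparison <- function(x, ...) {
  df <- as.data.frame(x)
  df <- df[df$group != "total", ]
  m <- t(as.matrix(df[, c("cost_a", "cost_b")]))
  colnames(m) <- df$group
  rownames(m) <- c(attr(x, "scenario_a"), attr(x, "scenario_b"))
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m), las = 2,
                    ylab = "Cost (US$ million/yr)", ...)
  invisible(x)
}

#' One-way sensitivity swap
#'
#' Recomputes a single cost line with a replacement unit cost and/or
#' target population; every other line of the baseline report is carried
#' over unchanged (bit-identical).
#'
#' @param scn the [scenario()] that produced `report`.
#' @param intervention_id id of the line to perturb.
#' @param new_unit_cost optional replacement [unit_cost()].
#' @param new_target optional replacement target population (persons).
#' @param report the baseline `cost_report` (single-region).
#' @return A new `cost_report`.
#' @export
#' @examples
#' \dontrun{
#' fix <- india_2014_fixture()
#' base <- cost_scenario(fix$scenarios$sun, target_overrides = fix$targets$sun)
#' swapped <- sensitivity_swap(fix$scenarios$sun, "sun_cf",
#'                             new_unit_cost = unit_cost(29, "USD", "per_beneficiary_year"),
#'                             new_target = 32.2e6, report = base)
#' }
sensitivity_swap <- function(scn, intervention_id, new_unit_cost = NULL,
                             new_target = NULL, report) {
  stopifnot(inherits(scn, "scenario"), inherits(report, "cost_report"))
  nc_check(!is.null(new_unit_cost) || !is.null(new_target),
           "at least one of new_unit_cost or new_target must be given",
           "nutricost_config_error")
  if (!intervention_id %in% names(scn$interventions)) {
    nc_stop(sprintf("unknown intervention id '%s'", intervention_id),
            "nutricost_config_error")
  }
  idx <- which(report$lines$intervention_id == intervention_id)
  nc_check(length(idx) == 1L,
           "sensitivity_swap expects a single-region report containing the intervention",
           "nutricost_config_error")
  iv <- scn$interventions[[intervention_id]]
  if (!is.null(new_unit_cost)) {
    stopifnot(inherits(new_unit_cost, "unit_cost"))
    iv$unit_cost <- new_unit_cost
  }
  tp <- new_target %||% report$lines$target_population[idx]
  lines <- report$lines
  lines[idx, ] <- compute_cost_line(iv, tp, scn$currency_ctx,
                                    lines$region_id[idx])
  new_cost_report(report$scenario, lines)
}
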