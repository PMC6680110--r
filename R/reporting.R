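# Report writers (CSV + JSON, lossless), combined input reading, and the
# command-line entry point.

#' Read and validate scenario plus demographics inputs
#'
#' @param scenario_path scenario config path or shorthand (`"sun"`,
#'   `"india_plus"`); may be a vector.
#' @param demographics_path path to a region demographics CSV (see
#'   [read_demographics()]), or `NULL`.
#' @return List with `scenarios` (named list of [scenario()]) and
#'   `regions` (named list of [region_demographics()], possibly empty).
#' @export
read_inputs <- function(scenario_path, demographics_path = NULL) {
  scenarios <- lapply(scenario_path, load_scenario)
  names(scenarios) <- vapply(scenarios, `[[`, "", "name")
  regions <- if (is.null(demographics_path)) list() else read_demographics(demographics_path)
  list(scenarios = scenarios, regions = regions)
}

#' Write a cost report to CSV and/or JSON
#'
#' The CSV has the fixed column order `intervention`, `category`,
#' `region`, `target_population`, `unit_cost_usd_yr`, `coverage`,
#' `cost_usd_million`, `share_pct` plus a final `Total` row whose cost is
#' the grand total (monetary columns in US$ million/yr). The JSON nests
#' scenario -> category -> intervention and is lossless:
#' [read_report_json()] reconstructs an equal report.
#'
#' @param report a `cost_report`.
#' @param dir output directory (created if absent).
#' @param formats subset of `c("csv", "json")`.
#' @param basename file stem (default: scenario name, slugified).
#' @return Named character vector of files written, invisibly.
#' @export
write_report <- function(report, dir, formats = c("csv", "json"), basename = NULL) {
  stopifnot(inherits(report, "cost_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  nc_check(length(formats) > 0, "at least one output format required",
           "nutricost_config_error")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- basename %||% gsub("[^a-z0-9]+", "_", tolower(report$scenario))
  df <- report$lines
  shares <- cost_shares(report, "intervention")
  written <- character()
  if ("csv" %in% formats) {
    out <- data.frame(intervention = df$intervention_id, category = df$category,
                      region = df$region_id, target_population = df$target_population,
                      unit_cost_usd_yr = df$annual_unit_cost, coverage = df$coverage,
                      cost_usd_million = round_half_up(df$cost_usd_million, 2),
                      share_pct = as.numeric(shares[df$intervention_id]),
                      stringsAsFactors = FALSE)
    out <- rbind(out, data.frame(intervention = "Total", category = "", region = "",
                                 target_population = NA, unit_cost_usd_yr = NA,
                                 coverage = NA,
                                 cost_usd_million = round_half_up(sum(df$cost_usd_million), 2),
                                 share_pct = 100))
    path <- file.path(dir, paste0(stem, ".csv"))
    utils::write.csv(out, path, row.names = FALSE, na = "")
    written["csv"] <- path
  }
  if ("json" %in% formats) {
    nested <- list(scenario = report$scenario, units = "US$ million/yr",
                   categories = list())
    for (cat in unique(df$category)) {
      sub <- df[df$category == cat, ]
      ivs <- list()
      for (id in unique(sub$intervention_id)) {
        rows <- sub[sub$intervention_id == id, ]
        ivs[[id]] <- list(
          name = rows$name[1],
          lines = lapply(seq_len(nrow(rows)), function(i) list(
            region = rows$region_id[i],
            target_population = rows$target_population[i],
            annual_unit_cost = rows$annual_unit_cost[i],
            coverage = rows$coverage[i],
            cost_usd_million = rows$cost_usd_million[i]
          )))
      }
      nested$categories[[cat]] <- ivs
    }
    path <- file.path(dir, paste0(stem, ".json"))
    jsonlite::write_json(nested, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written["json"] <- path
  }
  invisible(written)
}

#' Reconstruct a cost report from its JSON form
#'
#' @param path JSON file written by [write_report()].
#' @return A `cost_report` equal to the one written.
#' @export
read_report_json <- function(path) {
  nc_check(file.exists(path), sprintf("report not found: %s", path),
           "nutricost_validation_error")
  x <- jsonlite::read_json(path)
  rows <- list()
  for (cat in names(x$categories)) {
    for (id in names(x$categories[[cat]])) {
      iv <- x$categories[[cat]][[id]]
      for (ln in iv$lines) {
        rows[[length(rows) + 1L]] <- data.frame(
          intervention_id = id, name = iv$name, category = cat,
          region_id = ln$region, target_population = ln$target_population,
          annual_unit_cost = ln$annual_unit_cost, coverage = ln$coverage,
          cost_usd_million = ln$cost_usd_million, stringsAsFactors = FALSE)
      }
    }
  }
  new_cost_report(x$scenario, do.call(rbind, rows))
}

cli_log <- function(level, fmt, ..., verbosity = 1L) {
  if (verbosity > 0L) message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

cli_usage <- function() {
  message(paste(
    "usage: nutricost <command> [options]",
    "commands:",
    "  cost        --scenario <name|path> [--fixture | --demographics <csv>]",
    "              [--out <dir>] [--format csv,json] [--target-year <yr>]",
    "  compare     --a <name|path> --b <name|path> --fixture [--out <dir>]",
    "  sensitivity --scenario <name|path> --fixture --intervention <id>",
    "              [--unit-cost <usd/yr>] [--target <persons>] [--out <dir>]",
    "  synth       --seed <int> --n <int> --out <csv>",
    "  fixture     --out <dir>",
    "Reports are written to files; logs go to standard error.",
    sep = "\n"))
}

cli_parse <- function(argv) {
  opts <- list(flags = character())
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) nc_stop(sprintf("unexpected argument '%s'", a),
                                      "nutricost_cli_error")
    key <- sub("^--", "", a)
    if (key %in% c("fixture", "quiet")) {
      opts$flags <- c(opts$flags, key)
      i <- i + 1L
    } else {
      nc_check(i < length(argv), sprintf("option --%s requires a value", key),
               "nutricost_cli_error")
      opts[[key]] <- argv[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

cli_targets <- function(opts, scn_key, fix) {
  if ("fixture" %in% opts$flags) {
    nc_check(scn_key %in% names(fix$targets),
             "--fixture requires the packaged 'sun' or 'india_plus' scenario",
             "nutricost_cli_error")
    fix$targets[[scn_key]]
  } else NULL
}

#' Command-line entry point
#'
#' Subcommands: `cost` (run one scenario and write reports), `compare`
#' (category comparison of two scenarios), `sensitivity` (one-way swap of
#' a unit cost and/or target), `synth` (write synthetic demographics,
#' deterministic under `--seed`), `fixture` (export the packaged fixture
#' tables). Reports go to files; diagnostics to standard error; exit code
#' 0 on success, 2 on usage errors, 1 on validation/computation errors.
#'
#' @param argv character vector of arguments (excluding the program name).
#' @return Integer exit code, invisibly.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L || argv[1] %in% c("-h", "--help", "help")) {
    cli_usage()
    return(invisible(if (length(argv)) 0L else 2L))
  }
  cmd <- argv[1]
  if (!cmd %in% c("cost", "compare", "sensitivity", "synth", "fixture")) {
    message(sprintf("unknown subcommand '%s'", cmd))
    cli_usage()
    return(invisible(2L))
  }
  result <- tryCatch({
    opts <- cli_parse(argv[-1])
    verbosity <- if ("quiet" %in% opts$flags) 0L else 1L
    out_dir <- opts$out %||% "."
    switch(cmd,
      cost = {
        nc_check(!is.null(opts$scenario), "cost: --scenario is required",
                 "nutricost_cli_error")
        scn <- load_scenario(opts$scenario)
        target_year <- as.numeric(opts[["target-year"]] %||% 2014)
        if ("fixture" %in% opts$flags) {
          fix <- india_2014_fixture()
          rep <- cost_scenario(scn, target_overrides = cli_targets(opts, opts$scenario, fix),
                               target_year = target_year, region_id = "India")
        } else {
          nc_check(!is.null(opts$demographics),
                   "cost: either --fixture or --demographics <csv> is required",
                   "nutricost_cli_error")
          regions <- read_demographics(opts$demographics)
          rep <- cost_scenario(scn, regions = regions, target_year = target_year)
        }
        formats <- strsplit(opts$format %||% "csv,json", ",")[[1]]
        files <- write_report(rep, out_dir, formats = formats)
        cli_log("info", "scenario '%s': total %.2f US$ million/yr; wrote %s",
                rep$scenario, sum(rep$lines$cost_usd_million),
                paste(files, collapse = ", "), verbosity = verbosity)
      },
      compare = {
        nc_check(!is.null(opts$a) && !is.null(opts$b),
                 "compare: --a and --b are required", "nutricost_cli_error")
        fix <- india_2014_fixture()
        reps <- lapply(c(a = opts$a, b = opts$b), function(s) {
          cost_scenario(load_scenario(s), target_overrides = cli_targets(opts, s, fix),
                        region_id = "India")
        })
        cmp <- compare_scenarios(reps$a, reps$b)
        path <- file.path(out_dir, "comparison.csv")
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        utils::write.csv(as.data.frame(cmp), path, row.names = FALSE)
        cli_log("info", "comparison written to %s (difference in totals: %.2f US$M/yr)",
                path, cmp$difference[cmp$group == "total"], verbosity = verbosity)
      },
      sensitivity = {
        nc_check(!is.null(opts$scenario) && !is.null(opts$intervention),
                 "sensitivity: --scenario and --intervention are required",
                 "nutricost_cli_error")
        fix <- india_2014_fixture()
        scn <- load_scenario(opts$scenario)
        base <- cost_scenario(scn, target_overrides = cli_targets(opts, opts$scenario, fix),
                              region_id = "India")
        new_uc <- if (!is.null(opts[["unit-cost"]])) {
          unit_cost(as.numeric(opts[["unit-cost"]]), "USD", "per_beneficiary_year")
        }
        swapped <- sensitivity_swap(scn, opts$intervention, new_unit_cost = new_uc,
                                    new_target = if (!is.null(opts$target)) as.numeric(opts$target),
                                    report = base)
        files <- write_report(swapped, out_dir, basename = paste0(
          gsub("[^a-z0-9]+", "_", tolower(swapped$scenario)), "_sensitivity"))
        cli_log("info", "sensitivity total %.2f US$M/yr (baseline %.2f); wrote %s",
                sum(swapped$lines$cost_usd_million), sum(base$lines$cost_usd_million),
                paste(files, collapse = ", "), verbosity = verbosity)
      },
      synth = {
        nc_check(!is.null(opts$out), "synth: --out <csv> is required", "nutricost_cli_error")
        params <- generator_params(seed = as.integer(opts$seed %||% 1),
                                   n_regions = as.integer(opts$n %||% 10))
        write_demographics(generate_regions(params), opts$out)
        cli_log("info", "wrote %d synthetic regions to %s", params$n_regions, opts$out,
                verbosity = verbosity)
      },
      fixture = {
        fix <- india_2014_fixture()
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        utils::write.csv(fix$states, file.path(out_dir, "india2014_states.csv"),
                         row.names = FALSE)
        utils::write.csv(fix$printed_costs, file.path(out_dir, "india2014_printed_costs.csv"),
                         row.names = FALSE)
        utils::write.csv(fix$reconciliation, file.path(out_dir, "india2014_reconciliation.csv"),
                         row.names = FALSE)
        cli_log("info", "fixture tables written to %s", out_dir, verbosity = verbosity)
      })
    0L
  },
  nutricost_cli_error = function(e) { message(conditionMessage(e)); cli_usage(); 2L },
  error = function(e) { message(sprintf("error: %s", conditionMessage(e))); 1L })
  invisible(result)
}
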