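# Demographic projection and cohort derivation.
#
# Census-style inputs (base-year population by age band and sex, crude
# birth rate, average growth rate) are projected to a target year and
# reduced to the beneficiary cohorts the costing rules reference:
# child age bands in months, pregnant and lactating women, adolescents,
# households with an under-five, and the general population.

cohort_names <- c(
  "children_0_6m", "children_6_12m", "children_6_23m", "children_2_59m",
  "children_6_36m", "children_6_59m", "children_12_59m", "children_0_59m",
  "adolescents_11_18y", "pregnant_women", "lactating_mothers_0_6m",
  "households_with_u5", "general_population"
)

#' Region demographic record
#'
#' One region's census-style model inputs: base-year population by
#' half-open age band `[lo, hi)` and sex, vital rates, under-five
#' anthropometric prevalences, the fraction of women 18-50 in government
#' employment (used to exclude already-covered women from the maternity
#' cash transfer) and a malaria-endemicity flag (used to restrict
#' bed-net provision).
#'
#' @param region_id region identifier (non-empty string).
#' @param base_year calendar year of the population counts.
#' @param population_by_band data frame with columns `lo`, `hi` (years,
#'   half-open bands covering `[0, 100)` without overlap), `m` and `f`
#'   (persons, non-negative).
#' @param crude_birth_rate births per 1000 persons per year.
#' @param growth_rate annual population growth as a fraction (> -1).
#' @param prev_whz_lt_m3 prevalence of severe wasting (WHZ < -3), in `[0,1]`.
#' @param prev_whz_lt_m2 prevalence of wasting (WHZ < -2), must be >=
#'   `prev_whz_lt_m3`.
#' @param prev_waz_lt_m3 prevalence of severe underweight (WAZ < -3).
#' @param frac_women_govt fraction of women 18-50 in government employment.
#' @param malaria_endemic logical flag.
#' @return An object of class `region_demographics`.
#' @export
#' @examples
#' bands <- data.frame(lo = c(0, 5), hi = c(5, 100), m = c(60, 440), f = c(55, 445))
#' region_demographics("toy", 2011, bands, crude_birth_rate = 20,
#'                     growth_rate = 0.01, prev_whz_lt_m3 = 0.05,
#'                     prev_whz_lt_m2 = 0.15, prev_waz_lt_m3 = 0.1,
#'                     frac_women_govt = 0.02, malaria_endemic = FALSE)
region_demographics <- function(region_id, base_year, population_by_band,
                                crude_birth_rate, growth_rate,
                                prev_whz_lt_m3, prev_whz_lt_m2, prev_waz_lt_m3,
                                frac_women_govt, malaria_endemic = FALSE) {
  nc_check(is.character(region_id) && length(region_id) == 1L && nzchar(region_id),
           "region_id must be a non-empty string")
  nc_check(is_scalar_number(base_year), "base_year must be a number")
  bands <- validate_band_table(population_by_band)
  nc_check(is_scalar_number(crude_birth_rate) && crude_birth_rate >= 0,
           "crude_birth_rate must be non-negative")
  nc_check(is_scalar_number(growth_rate) && growth_rate > -1,
           "growth_rate must be a number > -1")
  for (p in c("prev_whz_lt_m3", "prev_whz_lt_m2", "prev_waz_lt_m3", "frac_women_govt")) {
    nc_check(is_fraction(get(p)), sprintf("%s must be a fraction in [0,1]", p))
  }
  nc_check(prev_whz_lt_m3 <= prev_whz_lt_m2,
           "severe wasting prevalence (WHZ<-3) cannot exceed wasting prevalence (WHZ<-2)")
  nc_check(is.logical(malaria_endemic) && length(malaria_endemic) == 1L &&
             !is.na(malaria_endemic), "malaria_endemic must be TRUE or FALSE")
  structure(list(
    region_id = region_id, base_year = base_year, population_by_band = bands,
    crude_birth_rate = crude_birth_rate, growth_rate = growth_rate,
    prev_whz_lt_m3 = prev_whz_lt_m3, prev_whz_lt_m2 = prev_whz_lt_m2,
    prev_waz_lt_m3 = prev_waz_lt_m3, frac_women_govt = frac_women_govt,
    malaria_endemic = malaria_endemic
  ), class = "region_demographics")
}

validate_band_table <- function(bands) {
  nc_check(is.data.frame(bands) && all(c("lo", "hi", "m", "f") %in% names(bands)),
           "population_by_band must be a data frame with columns lo, hi, m, f")
  bands <- bands[order(bands$lo), c("lo", "hi", "m", "f")]
  nc_check(all(bands$lo < bands$hi), "age bands must satisfy lo < hi")
  nc_check(all(bands$m >= 0) && all(bands$f >= 0), "band populations must be non-negative")
  nc_check(bands$lo[1] == 0 && bands$hi[nrow(bands)] == 100 &&
             all(bands$hi[-nrow(bands)] == bands$lo[-1]),
           "age bands must be non-overlapping and cover [0, 100) exactly")
  rownames(bands) <- NULL
  bands
}

#' @export
print.region_demographics <- function(x, ...) {
  cat(sprintf("<region_demographics> %s (base %d): %.4g persons, CBR %.3g/1000, growth %.3g%%/yr%s\n",
              x$region_id, as.integer(x$base_year),
              sum(x$population_by_band$m + x$population_by_band$f),
              x$crude_birth_rate, 100 * x$growth_rate,
              if (x$malaria_endemic) ", malaria-endemic" else ""))
  invisible(x)
}

#' Exponential population projection
#'
#' Projects a base population forward with the average annual growth rate:
#' `base_pop * (1 + growth_rate)^elapsed_years`.
#'
#' @param base_pop non-negative base population (persons).
#' @param growth_rate annual growth fraction (> -1).
#' @param elapsed_years non-negative years elapsed.
#' @return Projected population.
#' @export
#' @examples
#' project_population(1000, 0.01, 1)  # 1010
project_population <- function(base_pop, growth_rate, elapsed_years) {
  nc_check(is.numeric(base_pop) && all(base_pop >= 0), "base_pop must be non-negative")
  nc_check(is.numeric(growth_rate) && all(growth_rate > -1), "growth_rate must be > -1")
  nc_check(is.numeric(elapsed_years) && all(elapsed_years >= 0),
           "elapsed_years must be non-negative")
  base_pop * (1 + growth_rate)^elapsed_years
}

#' Annual births from the crude birth rate
#'
#' @param population persons.
#' @param cbr crude birth rate, births per 1000 persons per year.
#' @return Births per year.
#' @export
#' @examples
#' annual_births(1e6, 20)  # 20000
annual_births <- function(population, cbr) {
  nc_check(is.numeric(population) && all(population >= 0), "population must be non-negative")
  nc_check(is.numeric(cbr) && all(cbr >= 0), "cbr must be non-negative")
  population * cbr / 1000
}

#' Stationary child cohort from the annual birth flow
#'
#' Size of the age cohort `[lo_months, hi_months)` under a stationary
#' approximation: the annual birth flow times the window width in years.
#' Under-five mortality is deliberately ignored (the source cost norms
#' target nominal cohort sizes); packaged fixture values override this
#' formula where published back-derivations exist.
#'
#' @param births_per_year annual births.
#' @param lo_months,hi_months half-open age window in months, `0 <= lo < hi`.
#' @return Persons in the cohort.
#' @export
#' @examples
#' age_cohort_size(12, 0, 12)  # one full birth cohort
age_cohort_size <- function(births_per_year, lo_months, hi_months) {
  nc_check(is.numeric(births_per_year) && all(births_per_year >= 0),
           "births_per_year must be non-negative")
  nc_check(is_scalar_number(lo_months) && is_scalar_number(hi_months) && lo_months >= 0,
           "age window must be numeric with lo_months >= 0")
  if (hi_months <= lo_months) {
    nc_stop("invalid age interval: hi_months must exceed lo_months",
            "nutricost_invalid_interval")
  }
  births_per_year * (hi_months - lo_months) / 12
}

#' Population in an age range from a banded table
#'
#' Sums fully covered bands and interpolates partially covered bands
#' assuming a uniform age distribution within each band. Half-open
#' `[lo_years, hi_years)` convention.
#'
#' @param population_by_band band table (see [region_demographics()]).
#' @param lo_years,hi_years requested age range in years.
#' @param sex `"both"` (default), `"m"` or `"f"`.
#' @return Persons aged `[lo_years, hi_years)`.
#' @export
#' @examples
#' bands <- data.frame(lo = c(10, 15), hi = c(15, 20), m = c(50, 50), f = c(50, 50))
#' # within-band uniform interpolation: 80 + 60
#' cohort_from_age_bands(rbind(data.frame(lo = 0, hi = 10, m = 0, f = 0), bands,
#'                             data.frame(lo = 20, hi = 100, m = 0, f = 0)), 11, 18)
cohort_from_age_bands <- function(population_by_band, lo_years, hi_years,
                                  sex = c("both", "m", "f")) {
  sex <- match.arg(sex)
  bands <- validate_band_table(population_by_band)
  nc_check(is_scalar_number(lo_years) && is_scalar_number(hi_years) && lo_years < hi_years,
           "age range must satisfy lo_years < hi_years")
  if (lo_years < min(bands$lo) || hi_years > max(bands$hi)) {
    nc_stop(sprintf("requested age range [%g, %g) outside band coverage [%g, %g)",
                    lo_years, hi_years, min(bands$lo), max(bands$hi)),
            "nutricost_coverage_error")
  }
  persons <- switch(sex, both = bands$m + bands$f, m = bands$m, f = bands$f)
  overlap <- pmax(0, pmin(bands$hi, hi_years) - pmax(bands$lo, lo_years))
  sum(persons * overlap / (bands$hi - bands$lo))
}

#' Cohort table
#'
#' Named cohort sizes for one region and target year. Validates
#' non-negativity, the nesting of child age cohorts and the consistency
#' of lactating mothers with pregnancies.
#'
#' @param region_id region identifier.
#' @param target_year calendar year the cohorts refer to.
#' @param cohorts named numeric vector or list over the canonical cohort
#'   names (see Details).
#' @param pregnancy_multiplier consistency factor linking pregnancies to
#'   births (lactating mothers cannot exceed
#'   `pregnant_women / pregnancy_multiplier` beyond numerical tolerance).
#'
#' @details Canonical cohort names: `children_0_6m`, `children_6_12m`,
#' `children_6_23m`, `children_2_59m`, `children_6_36m`, `children_6_59m`,
#' `children_12_59m`, `children_0_59m`, `adolescents_11_18y`,
#' `pregnant_women`, `lactating_mothers_0_6m`, `households_with_u5`,
#' `general_population`. Child cohort names use months of age with
#' half-open windows (`6_23m` is `[6, 24)` months).
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(region_id, target_year, cohorts, pregnancy_multiplier = 1.0) {
  cohorts <- unlist(cohorts)
  nc_check(is.numeric(cohorts) && !is.null(names(cohorts)),
           "cohorts must be a named numeric vector")
  unknown <- setdiff(names(cohorts), cohort_names)
  nc_check(length(unknown) == 0L,
           sprintf("unknown cohort name(s): %s", paste(unknown, collapse = ", ")))
  nc_check(all(cohorts >= 0), "all cohorts must be non-negative")
  tol <- 1e-9 * max(1, max(cohorts))
  chain <- c("children_6_12m", "children_6_23m", "children_6_36m",
             "children_6_59m", "children_0_59m")
  present <- chain[chain %in% names(cohorts)]
  if (length(present) > 1L) {
    nc_check(all(diff(cohorts[present]) >= -tol),
             "nested child cohorts must be monotone non-decreasing")
  }
  if (all(c("lactating_mothers_0_6m", "pregnant_women") %in% names(cohorts))) {
    nc_check(cohorts[["lactating_mothers_0_6m"]] <=
               cohorts[["pregnant_women"]] / pregnancy_multiplier + tol,
             "lactating mothers inconsistent with pregnancies")
  }
  structure(list(region_id = region_id, target_year = target_year,
                 cohorts = cohorts, pregnancy_multiplier = pregnancy_multiplier),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %s, %d\n", x$region_id, as.integer(x$target_year)))
  print(round(x$cohorts))
  invisible(x)
}

#' Derive beneficiary cohorts for a target year
#'
#' Projects the region's total population to `target_year`, derives the
#' annual birth flow from the crude birth rate, and builds every cohort
#' the costing rules reference. Child cohorts follow the stationary
#' approximation of [age_cohort_size()]; adolescents come from the age-band
#' table; pregnancies are `births * pregnancy_multiplier`; lactating
#' mothers equal the annual birth flow (each mother enters the six-month
#' postpartum window once per birth); households with an under-five divide
#' the under-five cohort by `children_per_household`.
#'
#' @param demo a [region_demographics()].
#' @param target_year projection year (>= base year).
#' @param pregnancy_multiplier pregnancies per live birth (default 1).
#' @param children_per_household average under-five children per household
#'   (default 2).
#' @return A [cohort_table()].
#' @export
derive_cohorts <- function(demo, target_year,
                           pregnancy_multiplier = 1.0, children_per_household = 2) {
  stopifnot(inherits(demo, "region_demographics"))
  nc_check(is_scalar_number(target_year) && target_year >= demo$base_year,
           "target_year must be >= base_year")
  nc_check(is_scalar_number(pregnancy_multiplier) && pregnancy_multiplier >= 0,
           "pregnancy_multiplier must be non-negative")
  nc_check(is_scalar_number(children_per_household) && children_per_household > 0,
           "children_per_household must be positive")
  bands <- demo$population_by_band
  base_pop <- sum(bands$m + bands$f)
  elapsed <- target_year - demo$base_year
  pop_t <- project_population(base_pop, demo$growth_rate, elapsed)
  scale_t <- if (base_pop > 0) pop_t / base_pop else 0
  births <- annual_births(pop_t, demo$crude_birth_rate)
  u5 <- age_cohort_size(births, 0, 60)
  cohorts <- c(
    children_0_6m = age_cohort_size(births, 0, 6),
    children_6_12m = age_cohort_size(births, 6, 12),
    children_6_23m = age_cohort_size(births, 6, 24),
    children_2_59m = age_cohort_size(births, 2, 60),
    children_6_36m = age_cohort_size(births, 6, 36),
    children_6_59m = age_cohort_size(births, 6, 60),
    children_12_59m = age_cohort_size(births, 12, 60),
    children_0_59m = u5,
    adolescents_11_18y = scale_t * cohort_from_age_bands(bands, 11, 19),
    pregnant_women = births * pregnancy_multiplier,
    lactating_mothers_0_6m = births,
    households_with_u5 = u5 / children_per_household,
    general_population = pop_t
  )
  cohort_table(demo$region_id, target_year, cohorts, pregnancy_multiplier)
}

#' Read region demographics from CSV
#'
#' One row per region, UTF-8, dot decimal. Required columns: `region_id`,
#' `base_year`, `crude_birth_rate`, `growth_rate`, `prev_whz_lt_m3`,
#' `prev_whz_lt_m2`, `prev_waz_lt_m3`, `frac_women_govt`,
#' `malaria_endemic` (0/1 or TRUE/FALSE), plus age-band columns
#' `pop_m_<lo>_<hi>` and `pop_f_<lo>_<hi>` whose bands tile `[0, 100)`.
#'
#' @param path CSV file path.
#' @return A named list of [region_demographics()] objects.
#' @export
read_demographics <- function(path) {
  nc_check(file.exists(path), sprintf("demographics file not found: %s", path),
           "nutricost_validation_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) {
    nc_stop(sprintf("%s: no region rows", path), "nutricost_schema_error")
  }
  required <- c("region_id", "base_year", "crude_birth_rate", "growth_rate",
                "prev_whz_lt_m3", "prev_whz_lt_m2", "prev_waz_lt_m3",
                "frac_women_govt", "malaria_endemic")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    nc_stop(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")),
            "nutricost_schema_error")
  }
  band_cols <- grep("^pop_[mf]_[0-9]+_[0-9]+$", names(df), value = TRUE)
  if (length(band_cols) == 0L) {
    nc_stop(sprintf("%s: no age-band columns (pop_m_<lo>_<hi> / pop_f_<lo>_<hi>)", path),
            "nutricost_schema_error")
  }
  if (anyDuplicated(df$region_id)) {
    nc_stop(sprintf("%s: duplicated region_id: %s", path,
                    paste(unique(df$region_id[duplicated(df$region_id)]), collapse = ", ")),
            "nutricost_validation_error")
  }
  parts <- do.call(rbind, strsplit(band_cols, "_"))
  band_meta <- data.frame(col = band_cols, sex = parts[, 2],
                          lo = as.numeric(parts[, 3]), hi = as.numeric(parts[, 4]))
  regions <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    bands_m <- band_meta[band_meta$sex == "m", ]
    bands_f <- band_meta[band_meta$sex == "f", ]
    key_m <- paste(bands_m$lo, bands_m$hi)
    key_f <- paste(bands_f$lo, bands_f$hi)
    if (!setequal(key_m, key_f)) {
      nc_stop(sprintf("%s row %d: male and female age bands differ", path, i),
              "nutricost_schema_error")
    }
    bands_f <- bands_f[match(key_m, key_f), ]
    bands <- data.frame(lo = bands_m$lo, hi = bands_m$hi,
                        m = as.numeric(row[, bands_m$col]),
                        f = as.numeric(row[, bands_f$col]))
    tryCatch(
      region_demographics(
        region_id = as.character(row$region_id), base_year = row$base_year,
        population_by_band = bands, crude_birth_rate = row$crude_birth_rate,
        growth_rate = row$growth_rate, prev_whz_lt_m3 = row$prev_whz_lt_m3,
        prev_whz_lt_m2 = row$prev_whz_lt_m2, prev_waz_lt_m3 = row$prev_waz_lt_m3,
        frac_women_govt = row$frac_women_govt,
        malaria_endemic = as.logical(row$malaria_endemic)
      ),
      nutricost_error = function(e) {
        nc_stop(sprintf("%s row %d (region '%s'): %s", path, i, row$region_id,
                        conditionMessage(e)), "nutricost_validation_error")
      }
    )
  })
  names(regions) <- df$region_id
  regions
}

#' Write region demographics to CSV
#'
#' Inverse of [read_demographics()]; used by the synthetic generator CLI.
#'
#' @param regions list of [region_demographics()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_demographics <- function(regions, path) {
  stopifnot(length(regions) > 0, all(vapply(regions, inherits, logical(1), "region_demographics")))
  rows <- lapply(regions, function(r) {
    b <- r$population_by_band
    vals <- c(as.list(b$m), as.list(b$f))
    names(vals) <- c(sprintf("pop_m_%g_%g", b$lo, b$hi), sprintf("pop_f_%g_%g", b$lo, b$hi))
    c(list(region_id = r$region_id, base_year = r$base_year,
           crude_birth_rate = r$crude_birth_rate, growth_rate = r$growth_rate,
           prev_whz_lt_m3 = r$prev_whz_lt_m3, prev_whz_lt_m2 = r$prev_whz_lt_m2,
           prev_waz_lt_m3 = r$prev_waz_lt_m3, frac_women_govt = r$frac_women_govt,
           malaria_endemic = as.integer(r$malaria_endemic)), vals)
  })
  df <- do.call(rbind, lapply(rows, function(x) as.data.frame(x, check.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
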