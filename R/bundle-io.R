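#' Construct an input bundle
#'
#' An input bundle is the complete parameter set consumed by the projection
#' engine: population counts and projected newborns, smoking-state
#' prevalences, annual smoking transition probabilities, COPD prevalence and
#' incidence, all-cause mortality, and relative risks of smoking on COPD and
#' on total mortality. All per-age tables cover single years of age 0--95 for
#' both sexes.
#'
#' @param population tibble with columns `sex`, `age`, `count`: persons per
#'   (sex, age) at baseline.
#' @param newborns tibble with columns `sex`, `year`, `count`: projected
#'   age-0 entrants per simulated year (`year` = 1..`horizon_years`).
#' @param smoking tibble with columns `sex`, `age`, `p_never`, `p_current`,
#'   `p_former`: smoking-state proportions, summing to 1 at every (sex, age).
#' @param transitions tibble with columns `sex`, `age`, `region`,
#'   `initiation`, `cessation`, `restart`: annual transition probabilities
#'   (never to current, current to former, former to current) for each of the
#'   two European regions.
#' @param copd tibble with columns `sex`, `age`, `prevalence`, `incidence`:
#'   COPD prevalence proportion and annual incidence probability; both zero
#'   below age 40.
#' @param mortality tibble with columns `sex`, `age`, `rate`: annual all-cause
#'   death probability.
#' @param rr_copd tibble with columns `sex`, `age`, `rr_current`, `rr_former`:
#'   relative risks of current and former smoking on COPD incidence
#'   (current vs never, former vs never), expanded to single years of age.
#' @param rr_mort tibble with columns `sex`, `rr_current`, `rr_former`:
#'   relative risks of smoking on total mortality, one row per sex.
#' @param region `"north"` or `"south"`: selects the transition-rate slice
#'   used throughout a simulation.
#' @param horizon_years integer simulation horizon (default 40 annual cycles).
#' @param base_year calendar label of year 0 (default 2018).
#' @param disability_weight scalar in `[0, 1]` applied to years lived with
#'   COPD in disability-adjusted life expectancy.
#' @param validate if `TRUE` (default), abort on any invariant violation.
#'
#' @return An object of class `copd_bundle`: a named list of the tables and
#'   scalars above.
#' @seealso [validate_bundle()], [load_bundle()], [write_bundle()],
#'   [generate_bundle()]
#' @export
new_bundle <- function(population, newborns, smoking, transitions, copd,
                       mortality, rr_copd, rr_mort,
                       region = "north", horizon_years = 40L,
                       base_year = 2018L, disability_weight = 0.2,
                       validate = TRUE) {
  bundle <- structure(
    list(
      population = as_tibble(population),
      newborns = as_tibble(newborns),
      smoking = as_tibble(smoking),
      transitions = as_tibble(transitions),
      copd = as_tibble(copd),
      mortality = as_tibble(mortality),
      rr_copd = as_tibble(rr_copd),
      rr_mort = as_tibble(rr_mort),
      region = region,
      horizon_years = as.integer(horizon_years),
      base_year = as.integer(base_year),
      disability_weight = disability_weight
    ),
    class = "copd_bundle"
  )
  if (validate) {
    problems <- validate_bundle(bundle)
    if (nrow(problems) > 0) {
      abort(c("invalid input bundle",
              utils::head(format_violations(problems), 15)),
            class = "copdhia_validation_error")
    }
  }
  bundle
}

format_violations <- function(problems) {
  paste0(
    problems$table,
    ifelse(is.na(problems$sex), "", paste0(" [", problems$sex,
                                           ifelse(is.na(problems$age), "",
                                                  paste0(", age ", problems$age)),
                                           "]")),
    ": ", problems$message
  )
}

violation <- function(table, message, sex = NA_character_, age = NA_integer_) {
  tibble(table = table, sex = sex, age = as.integer(age), message = message)
}

#' Validate an input bundle
#'
#' Checks every structural invariant of the data model: complete (sex, age)
#' grids, value ranges, smoking-state proportions summing to one, age
#' eligibility zeros (no smoking below 11, no former smokers below 16, no
#' restart below 22, no COPD below 40), and relative-risk ordering
#' (current >= former >= 1). Never mutates the bundle.
#'
#' @param bundle a `copd_bundle`.
#' @return A tibble with columns `table`, `sex`, `age`, `message`; zero rows
#'   means the bundle is valid.
#' @export
validate_bundle <- function(bundle) {
  out <- list()
  add <- function(v) out[[length(out) + 1]] <<- v

  grid_check <- function(df, table, by_region = FALSE) {
    want <- if (by_region) length(.ages) * 2L * 2L else length(.ages) * 2L
    keys <- if (by_region) paste(df$sex, df$age, df$region) else paste(df$sex, df$age)
    full <- if (by_region) {
      g <- expand.grid(sex = .sexes, age = .ages, region = .regions,
                       stringsAsFactors = FALSE)
      paste(g$sex, g$age, g$region)
    } else {
      g <- expand.grid(sex = .sexes, age = .ages, stringsAsFactors = FALSE)
      paste(g$sex, g$age)
    }
    if (nrow(df) != want || anyDuplicated(keys) || !all(full %in% keys)) {
      add(violation(table, sprintf(
        "must contain exactly one row per (sex, age%s) over ages 0..95",
        if (by_region) ", region" else "")))
      return(FALSE)
    }
    TRUE
  }

  range_check <- function(df, table, col, lo = 0, hi = 1) {
    x <- df[[col]]
    bad <- which(is.na(x) | x < lo | x > hi)
    for (i in bad) {
      add(violation(table,
                    sprintf("%s = %s out of [%g, %g]", col,
                            format(x[i]), lo, hi),
                    df$sex[i],
                    if ("age" %in% names(df)) df$age[i] else NA_integer_))
    }
  }

  zero_below <- function(df, table, col, min_age, what) {
    bad <- which(df$age < min_age & !is.na(df[[col]]) & df[[col]] != 0)
    for (i in bad) {
      add(violation(table, sprintf("%s before age %d", what, min_age),
                    df$sex[i], df$age[i]))
    }
  }

  # population
  if (grid_check(bundle$population, "population")) {
    range_check(bundle$population, "population", "count", 0, Inf)
  }

  # newborns must cover every simulated year for both sexes
  nb <- bundle$newborns
  want_years <- seq_len(bundle$horizon_years)
  keys <- paste(nb$sex, nb$year)
  full <- as.vector(outer(.sexes, want_years, paste))
  if (anyDuplicated(keys) || !all(full %in% keys)) {
    add(violation("newborns",
                  "must contain one row per (sex, year) for years 1..horizon"))
  } else {
    range_check(nb, "newborns", "count", 0, Inf)
  }

  # smoking prevalences
  sm <- bundle$smoking
  if (grid_check(sm, "smoking_prevalence")) {
    for (col in c("p_never", "p_current", "p_former")) {
      range_check(sm, "smoking_prevalence", col)
    }
    s <- sm$p_never + sm$p_current + sm$p_former
    bad <- which(abs(s - 1) > 1e-9)
    for (i in bad) {
      add(violation("smoking_prevalence",
                    sprintf("proportions sum to %.12g, not 1", s[i]),
                    sm$sex[i], sm$age[i]))
    }
    zero_below(sm, "smoking_prevalence", "p_current", .age_min_smoking,
               "current smoking")
    zero_below(sm, "smoking_prevalence", "p_former", .age_min_former,
               "former smoking")
  }

  # transition probabilities
  tr <- bundle$transitions
  if (grid_check(tr, "transitions", by_region = TRUE)) {
    for (col in c("initiation", "cessation", "restart")) {
      range_check(tr, "transitions", col)
    }
    zero_below(tr, "transitions", "initiation", .age_min_smoking, "initiation")
    zero_below(tr, "transitions", "cessation", .age_min_former, "cessation")
    zero_below(tr, "transitions", "restart", .age_min_restart, "restart")
  }

  # COPD inputs
  cp <- bundle$copd
  if (grid_check(cp, "copd")) {
    range_check(cp, "copd", "prevalence")
    range_check(cp, "copd", "incidence")
    zero_below(cp, "copd", "prevalence", .age_min_copd, "COPD")
    zero_below(cp, "copd", "incidence", .age_min_copd, "COPD")
  }

  # mortality
  mt <- bundle$mortality
  if (grid_check(mt, "mortality")) {
    range_check(mt, "mortality", "rate")
  }

  # relative risks: current >= former >= 1
  rc <- bundle$rr_copd
  if (grid_check(rc, "relative_risks")) {
    bad <- which(is.na(rc$rr_former) | is.na(rc$rr_current) |
                   rc$rr_former < 1 | rc$rr_current < rc$rr_former)
    for (i in bad) {
      add(violation("relative_risks",
                    "requires rr_current >= rr_former >= 1",
                    rc$sex[i], rc$age[i]))
    }
  }
  rm_ <- bundle$rr_mort
  if (nrow(rm_) != 2 || !setequal(rm_$sex, .sexes)) {
    add(violation("relative_risks", "mortality RRs must have one row per sex"))
  } else {
    bad <- which(is.na(rm_$rr_former) | is.na(rm_$rr_current) |
                   rm_$rr_former < 1 | rm_$rr_current < rm_$rr_former)
    for (i in bad) {
      add(violation("relative_risks",
                    "mortality requires rr_current >= rr_former >= 1",
                    rm_$sex[i]))
    }
  }

  # scalars
  if (!bundle$region %in% .regions) {
    add(violation("config", sprintf("region '%s' not in {north, south}",
                                    bundle$region)))
  }
  if (is.na(bundle$horizon_years) || bundle$horizon_years < 0) {
    add(violation("config", "horizon_years must be a nonnegative integer"))
  }
  if (is.na(bundle$disability_weight) || bundle$disability_weight < 0 ||
      bundle$disability_weight > 1) {
    add(violation("config", "disability_weight must lie in [0, 1]"))
  }

  if (length(out) == 0) {
    tibble(table = character(), sex = character(), age = integer(),
           message = character())
  } else {
    dplyr::bind_rows(out)
  }
}

# Numbers are serialised with %.17g so that a write/read cycle reproduces
# every double exactly and repeated writes are byte-identical.
fmt_num <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  sub("^(-?[0-9]+)\\.0*$", "\\1", out)
}

write_table_csv <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), fmt_num))
  readr::write_csv(df, path)
}

#' Write an input bundle to a directory of CSV files
#'
#' Writes `population.csv`, `newborns.csv`, `smoking_prevalence.csv`,
#' `transitions.csv`, `copd.csv`, `mortality.csv`, `relative_risks.csv` and a
#' `config.yaml` holding the scalar settings. The serialisation preserves
#' doubles exactly, so [load_bundle()] returns a bundle equal to the input,
#' and repeated writes of the same bundle produce identical bytes.
#'
#' @param bundle a valid `copd_bundle`.
#' @param dir target directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  problems <- validate_bundle(bundle)
  if (nrow(problems) > 0) {
    abort(c("refusing to write an invalid bundle",
            utils::head(format_violations(problems), 10)))
  }
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create directory '%s'", dir))
  }
  rr <- dplyr::bind_rows(
    dplyr::mutate(bundle$rr_copd, measure = "copd", .before = 1),
    dplyr::mutate(bundle$rr_mort, measure = "mortality", age = NA_integer_,
                  .before = 1)
  )
  tables <- list(
    population.csv = bundle$population,
    newborns.csv = bundle$newborns,
    smoking_prevalence.csv = bundle$smoking,
    transitions.csv = bundle$transitions,
    copd.csv = bundle$copd,
    mortality.csv = bundle$mortality,
    relative_risks.csv = rr
  )
  paths <- character(0)
  for (name in names(tables)) {
    p <- file.path(dir, name)
    tryCatch(write_table_csv(tables[[name]], p),
             error = function(e) abort(sprintf("cannot write '%s': %s", p,
                                               conditionMessage(e))))
    paths <- c(paths, p)
  }
  cfg <- file.path(dir, "config.yaml")
  yaml::write_yaml(
    list(base_year = bundle$base_year,
         horizon_years = bundle$horizon_years,
         region = bundle$region,
         disability_weight = bundle$disability_weight),
    cfg
  )
  invisible(c(paths, cfg))
}

read_table_csv <- function(dir, name, cols) {
  path <- file.path(dir, name)
  if (!file.exists(path)) {
    abort(sprintf("input file not found: '%s'", path),
          class = "copdhia_io_error")
  }
  df <- readr::read_csv(path, col_types = cols, progress = FALSE)
  missing <- setdiff(names(cols$cols), names(df))
  if (length(missing) > 0) {
    abort(sprintf("'%s' is missing column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "copdhia_validation_error")
  }
  df
}

#' Load an input bundle from a directory
#'
#' Reads the CSV tables written by [write_bundle()] (or prepared by hand in
#' the same layout) plus `config.yaml`, expands any age-group-level relative
#' risks to single years of age (the same value applied to all ages in the
#' group), and validates every invariant before returning.
#'
#' Relative risks may be given either per single year of age (`age` column)
#' or per age band (`age_low`, `age_high` columns); mortality RR rows apply
#' to all ages and need no age columns.
#'
#' @param dir directory containing the bundle files.
#' @param config path to the YAML configuration; defaults to
#'   `config.yaml` inside `dir`.
#' @return A validated `copd_bundle`.
#' @export
load_bundle <- function(dir, config = file.path(dir, "config.yaml")) {
  if (!dir.exists(dir)) {
    abort(sprintf("bundle directory not found: '%s'", dir),
          class = "copdhia_io_error")
  }
  if (!file.exists(config)) {
    abort(sprintf("configuration file not found: '%s'", config),
          class = "copdhia_io_error")
  }
  cfg <- yaml::read_yaml(config)

  cc <- readr::cols
  population <- read_table_csv(dir, "population.csv",
                               cc(sex = "c", age = "i", count = "d"))
  newborns <- read_table_csv(dir, "newborns.csv",
                             cc(sex = "c", year = "i", count = "d"))
  smoking <- read_table_csv(dir, "smoking_prevalence.csv",
                            cc(sex = "c", age = "i", p_never = "d",
                               p_current = "d", p_former = "d"))
  transitions <- read_table_csv(dir, "transitions.csv",
                                cc(sex = "c", age = "i", region = "c",
                                   initiation = "d", cessation = "d",
                                   restart = "d"))
  copd <- read_table_csv(dir, "copd.csv",
                         cc(sex = "c", age = "i", prevalence = "d",
                            incidence = "d"))
  mortality <- read_table_csv(dir, "mortality.csv",
                              cc(sex = "c", age = "i", rate = "d"))

  rr_path <- file.path(dir, "relative_risks.csv")
  if (!file.exists(rr_path)) {
    abort(sprintf("input file not found: '%s'", rr_path),
          class = "copdhia_io_error")
  }
  rr <- readr::read_csv(rr_path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  parsed <- parse_relative_risks(rr)

  new_bundle(
    population = population,
    newborns = newborns,
    smoking = smoking,
    transitions = transitions,
    copd = copd,
    mortality = mortality,
    rr_copd = parsed$rr_copd,
    rr_mort = parsed$rr_mort,
    region = cfg$region %||% "north",
    horizon_years = cfg$horizon_years %||% 40L,
    base_year = cfg$base_year %||% 2018L,
    disability_weight = cfg$disability_weight %||% 0.2
  )
}

# Accepts per-age rows (age column) or banded rows (age_low/age_high) for the
# COPD measure; bands are expanded so the same value applies to every age in
# the band. Ages outside any band default to RR = 1 (no excess risk).
parse_relative_risks <- function(rr) {
  need <- c("measure", "sex", "rr_current", "rr_former")
  missing <- setdiff(need, names(rr))
  if (length(missing) > 0) {
    abort(sprintf("relative_risks.csv is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "copdhia_validation_error")
  }
  rr$rr_current <- as.numeric(rr$rr_current)
  rr$rr_former <- as.numeric(rr$rr_former)

  mort <- rr[rr$measure == "mortality", ]
  rr_mort <- tibble(sex = mort$sex, rr_current = mort$rr_current,
                    rr_former = mort$rr_former)

  cop <- rr[rr$measure == "copd", ]
  if (nrow(cop) == 0) {
    abort("relative_risks.csv contains no COPD rows",
          class = "copdhia_validation_error")
  }
  if ("age" %in% names(cop) && !all(is.na(cop$age))) {
    rr_copd <- tibble(sex = cop$sex, age = as.integer(cop$age),
                      rr_current = cop$rr_current, rr_former = cop$rr_former)
  } else if (all(c("age_low", "age_high") %in% names(cop))) {
    cop$age_low <- as.integer(cop$age_low)
    cop$age_high <- as.integer(cop$age_high)
    rr_copd <- purrr::pmap_dfr(cop, function(sex, age_low, age_high,
                                             rr_current, rr_former, ...) {
      tibble(sex = sex, age = seq(age_low, age_high),
             rr_current = rr_current, rr_former = rr_former)
    })
  } else {
    abort("relative_risks.csv COPD rows need an 'age' or 'age_low'/'age_high' column",
          class = "copdhia_validation_error")
  }
  # fill ages not covered by any band with RR = 1
  full <- tidyr::expand_grid(sex = .sexes, age = .ages)
  rr_copd <- dplyr::left_join(full, rr_copd, by = c("sex", "age"))
  rr_copd$rr_current[is.na(rr_copd$rr_current)] <- 1
  rr_copd$rr_former[is.na(rr_copd$rr_former)] <- 1
  list(rr_copd = dplyr::arrange(rr_copd, .data$sex, .data$age),
       rr_mort = rr_mort)
}

#' @export
print.copd_bundle <- function(x, ...) {
  cat("<copd_bundle>\n")
  cat(sprintf("  region: %s   base year: %d   horizon: %d years\n",
              x$region, x$base_year, x$horizon_years))
  cat(sprintf("  population: %s persons (%d sex x age cells)\n",
              format(round(sum(x$population$count)), big.mark = ",",
                     scientific = FALSE),
              nrow(x$population)))
  ov <- dplyr::inner_join(x$population, x$smoking, by = c("sex", "age"))
  cur <- sum(ov$count * ov$p_current) / sum(ov$count)
  cpd <- dplyr::inner_join(x$population, x$copd, by = c("sex", "age"))
  prv <- sum(cpd$count * cpd$prevalence) / sum(cpd$count)
  cat(sprintf("  overall current smoking: %.1f%%   overall COPD prevalence: %.2f%%\n",
              100 * cur, 100 * prv))
  invisible(x)
}

#' Tidy an input bundle into one long table
#'
#' @param x a `copd_bundle`.
#' @param ... unused.
#' @return A tibble with columns `table`, `sex`, `age`, `name`, `value`
#'   stacking every per-age input.
#' @method tidy copd_bundle
#' @export
tidy.copd_bundle <- function(x, ...) {
  region_tr <- dplyr::filter(x$transitions, .data$region == x$region)
  dplyr::bind_rows(
    tidyr::pivot_longer(x$population, "count", names_to = "name") |>
      dplyr::mutate(table = "population"),
    tidyr::pivot_longer(x$smoking, dplyr::starts_with("p_"), names_to = "name") |>
      dplyr::mutate(table = "smoking_prevalence"),
    tidyr::pivot_longer(dplyr::select(region_tr, -"region"),
                        c("initiation", "cessation", "restart"),
                        names_to = "name") |>
      dplyr::mutate(table = "transitions"),
    tidyr::pivot_longer(x$copd, c("prevalence", "incidence"),
                        names_to = "name") |>
      dplyr::mutate(table = "copd"),
    tidyr::pivot_longer(x$mortality, "rate", names_to = "name") |>
      dplyr::mutate(table = "mortality"),
    tidyr::pivot_longer(x$rr_copd, dplyr::starts_with("rr_"),
                        names_to = "name") |>
      dplyr::mutate(table = "relative_risks")
  ) |>
    dplyr::select("table", "sex", "age", "name", "value")
}
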