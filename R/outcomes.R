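#' Smoking-state prevalence at given simulated years
#'
#' @param traj a `copd_trajectory`.
#' @param years integer vector of year indices `0..horizon`; default all.
#' @return A tibble with columns `year`, `smoking`, `percent`; the three
#'   percentages sum to 100 at every year.
#' @export
smoking_prevalence <- function(traj, years = 0:traj$horizon) {
  stopifnot(all(years >= 0 & years <= traj$horizon))
  purrr::map_dfr(years, function(y) {
    st <- traj$states[[y + 1]]
    total <- sum(st)
    if (total <= 0) abort(sprintf("empty population at year %d", y))
    by_state <- apply(st, 3, sum)
    tibble(year = y, smoking = .smoking_states,
           percent = 100 * unname(by_state[.smoking_states]) / total)
  })
}

#' COPD prevalence at given simulated years
#'
#' Whole-population denominator (all ages), expressed in percent.
#'
#' @inheritParams smoking_prevalence
#' @return A tibble with columns `year`, `percent`.
#' @export
copd_prevalence <- function(traj, years = 0:traj$horizon) {
  stopifnot(all(years >= 0 & years <= traj$horizon))
  purrr::map_dfr(years, function(y) {
    st <- traj$states[[y + 1]]
    total <- sum(st)
    if (total <= 0) abort(sprintf("empty population at year %d", y))
    tibble(year = y, percent = 100 * sum(st[, , , 2]) / total)
  })
}

#' COPD incidence rate at given simulated years
#'
#' Cases per 1000 person-years; person-years are the mid-year population
#' (start-of-year alive minus half the deaths of that year). The rate is
#' defined for year indices `0..horizon-1` only: no incidence is computed
#' for the final year of the simulation.
#'
#' @param traj a `copd_trajectory`.
#' @param years integer vector of year indices in `0..horizon-1`; default
#'   all.
#' @return A tibble with columns `year`, `rate_per_1000`.
#' @export
copd_incidence_rate <- function(traj, years = seq_len(traj$horizon) - 1) {
  if (any(years < 0 | years > traj$horizon - 1)) {
    abort(sprintf(
      "incidence is defined for years 0..%d; no rate is computed for the final simulated year",
      traj$horizon - 1))
  }
  purrr::map_dfr(years, function(y) {
    alive <- sum(traj$states[[y + 1]])
    py <- alive - sum(traj$deaths[, , y + 1]) / 2
    if (py <= 0) abort(sprintf("empty population at year %d", y))
    tibble(year = y,
           rate_per_1000 = 1000 * sum(traj$incident[, , y + 1]) / py)
  })
}

#' Cumulative COPD incident cases saved by an intervention
#'
#' Sum over all simulated years of the reference-minus-intervention incident
#' COPD cases.
#'
#' @param reference,intervention `copd_trajectory` objects with the same
#'   horizon and base population.
#' @return A single number of persons (0 when comparing a trajectory with
#'   itself).
#' @export
cumulative_cases_saved <- function(reference, intervention) {
  if (reference$horizon != intervention$horizon) {
    abort("trajectories have different horizons")
  }
  sum(reference$incident) - sum(intervention$incident)
}

#' Cohort life expectancy under a price scenario
#'
#' Follows a closed single-sex cohort of the given baseline age through the
#' simulation (no newborns, no other ages) up to age 95, using state-specific
#' rates frozen from the reference bundle and the scenario's adjusted
#' prevalences and transition probabilities. Person-years use a half-cycle
#' correction (deaths contribute half a year); survivors reaching age 95
#' receive a terminal tail of `1 / M(95, sex)` further years, where `M` is
#' the input all-cause death probability. COPD status for weighting is the
#' within-cycle (post-transition, post-incidence) status.
#'
#' Modes: `"overall"` counts all person-years; `"copd_free"` counts only
#' COPD-free person-years; `"disability_adjusted"` weights COPD years by
#' `1 - disability_weight`.
#'
#' @param bundle a valid `copd_bundle`.
#' @param scenario a [price_scenario()] or `NULL` for the reference.
#' @param age baseline age (0--95).
#' @param sex `"male"` or `"female"`.
#' @param mode `"overall"`, `"copd_free"` or `"disability_adjusted"`.
#' @return Expected age at death (years).
#' @export
cohort_life_expectancy <- function(bundle, scenario = NULL, age, sex,
                                   mode = c("overall", "copd_free",
                                            "disability_adjusted")) {
  mode <- match.arg(mode)
  sex <- match.arg(sex, .sexes)
  if (length(age) != 1 || is.na(age) || age < 0 || age > 95) {
    abort("age must be a single value in 0..95")
  }
  if (is.null(scenario)) scenario <- price_scenario(0)
  dw <- bundle$disability_weight

  rates <- build_state_rates(bundle)
  adj <- apply_intervention(bundle, scenario)
  m <- bundle_matrices(adj)
  si <- match(sex, .sexes)

  # occupancy: 3 smoking x 2 copd, one person at baseline
  ai <- age + 1
  p_sm <- c(m$p_never[si, ai], m$p_current[si, ai], m$p_former[si, ai])
  prev0 <- if (age >= .age_min_copd) m$copd_prev[si, ai] else 0
  n <- cbind(no = p_sm * (1 - prev0), yes = p_sm * prev0)

  w_yes <- switch(mode, overall = 1, copd_free = 0,
                  disability_adjusted = 1 - dw)
  le_years <- 0
  a <- age
  while (a < 95) {
    i <- a + 1
    up <- m$initiation[si, i]; qt <- m$cessation[si, i]
    rs <- m$restart[si, i]
    moved <- rbind(n[1, ] * (1 - up),
                   n[2, ] * (1 - qt) + n[1, ] * up + n[3, ] * rs,
                   n[3, ] * (1 - rs) + n[2, ] * qt)
    inc <- rates$incidence[si, i, ]
    new_cases <- moved[, 1] * inc
    moved[, 1] <- moved[, 1] - new_cases
    moved[, 2] <- moved[, 2] + new_cases
    mk <- rates$mortality[si, i, ]
    d <- moved * mk
    py <- colSums(moved) - colSums(d) / 2
    le_years <- le_years + py[["no"]] + w_yes * py[["yes"]]
    n <- moved - d
    a <- a + 1
  }
  m95 <- m$mort[si, 96]
  if (m95 > 0) {
    tail_py <- (sum(n[, 1]) + w_yes * sum(n[, 2])) / m95
    le_years <- le_years + tail_py
  }
  age + le_years
}

#' Gain in cohort life expectancy vs the reference scenario
#'
#' @inheritParams cohort_life_expectancy
#' @return [cohort_life_expectancy()] under `scenario` minus the same
#'   quantity under the 0% reference scenario (exactly 0 for a 0% scenario).
#' @export
le_gain <- function(bundle, scenario, age, sex,
                    mode = c("overall", "copd_free", "disability_adjusted")) {
  mode <- match.arg(mode)
  cohort_life_expectancy(bundle, scenario, age, sex, mode) -
    cohort_life_expectancy(bundle, NULL, age, sex, mode)
}

#' Cost savings from prevented COPD cases
#'
#' Each prevented case avoids `annual_cost` (plus optional annual
#' `productivity_cost`) euros per year over the assumed `duration` years
#' lived with the disease.
#'
#' @param cases_saved prevented incident COPD cases (persons).
#' @param annual_cost mean direct annual management cost per patient
#'   (euros/year; default 5700).
#' @param duration assumed years lived with the disease (default 10).
#' @param productivity_cost mean annual work-productivity loss per patient
#'   (euros/year; default 0).
#' @return Euros saved.
#' @export
cost_savings <- function(cases_saved, annual_cost = 5700, duration = 10,
                         productivity_cost = 0) {
  args <- c(cases_saved, annual_cost, duration, productivity_cost)
  if (any(is.na(args)) || any(args < 0)) {
    abort("all cost inputs must be nonnegative")
  }
  cases_saved * (annual_cost + productivity_cost) * duration
}

# ---------------------------------------------------------------------------
# Scenario-set comparison

#' Run a reference-plus-interventions scenario set
#'
#' Runs the reference (0%) scenario and one intervention per requested price
#' on the same bundle and elasticity schedule.
#'
#' @param bundle a valid `copd_bundle`.
#' @param prices vector of one-time price increases in percent; 0 (the
#'   reference) is always included.
#' @param schedule an [elasticity_schedule()].
#' @return A `copd_comparison`: list with `trajectories` (named by scenario
#'   label), `prices`, `schedule` and the `bundle`.
#' @export
simulate_scenarios <- function(bundle, prices = c(0, 5, 10, 20),
                               schedule = default_schedule()) {
  prices <- sort(unique(c(0, prices)))
  scenarios <- lapply(prices, price_scenario, schedule = schedule)
  trajectories <- lapply(scenarios, function(sc) run_simulation(bundle, sc))
  names(trajectories) <- vapply(scenarios, `[[`, "", "label")
  structure(list(trajectories = trajectories, prices = prices,
                 schedule = schedule, bundle = bundle),
            class = "copd_comparison")
}

#' @export
print.copd_comparison <- function(x, ...) {
  cat(sprintf("<copd_comparison> %d scenarios (prices: %s%%), horizon %d years\n",
              length(x$trajectories), paste(x$prices, collapse = ", "),
              x$bundle$horizon_years))
  print(cases_saved_table(x))
  invisible(x)
}

#' Cumulative cases saved per scenario
#'
#' @param comparison a `copd_comparison` from [simulate_scenarios()].
#' @return A tibble with columns `scenario`, `price_increase_percent`,
#'   `cases_saved` (vs the reference scenario).
#' @export
cases_saved_table <- function(comparison) {
  ref <- comparison$trajectories[["reference"]]
  purrr::imap_dfr(comparison$trajectories, function(tr, label) {
    tibble(scenario = label,
           price_increase_percent = tr$price_increase_percent,
           cases_saved = cumulative_cases_saved(ref, tr))
  })
}

#' Tidy outcome report for a scenario set
#'
#' One row per (year, scenario, measure): smoking-state prevalences (%),
#' COPD prevalence (%) and COPD incidence (cases per 1000 person-years; not
#' reported for the final simulated year).
#'
#' @param comparison a `copd_comparison`.
#' @return A tibble with columns `year`, `scenario`, `measure`, `value`.
#' @export
outcome_report <- function(comparison) {
  purrr::imap_dfr(comparison$trajectories, function(tr, label) {
    sp <- smoking_prevalence(tr) |>
      dplyr::mutate(measure = paste0("smoking_", .data$smoking),
                    value = .data$percent) |>
      dplyr::select("year", "measure", "value")
    cp <- copd_prevalence(tr) |>
      dplyr::mutate(measure = "copd_prevalence_percent",
                    value = .data$percent) |>
      dplyr::select("year", "measure", "value")
    ir <- copd_incidence_rate(tr) |>
      dplyr::mutate(measure = "copd_incidence_per_1000py",
                    value = .data$rate_per_1000) |>
      dplyr::select("year", "measure", "value")
    dplyr::bind_rows(sp, cp, ir) |>
      dplyr::mutate(scenario = label, .after = "year")
  })
}

#' @method tidy copd_comparison
#' @export
tidy.copd_comparison <- function(x, ...) outcome_report(x)

#' @method glance copd_comparison
#' @export
glance.copd_comparison <- function(x, ...) {
  dplyr::bind_rows(lapply(x$trajectories, glance)) |>
    dplyr::left_join(cases_saved_table(x),
                     by = c("scenario", "price_increase_percent"))
}

#' Life-expectancy gain table for a scenario set
#'
#' Cohort life expectancy and its gain vs the reference, by baseline age,
#' sex, scenario and mode.
#'
#' @param bundle a valid `copd_bundle`.
#' @param ages baseline ages (default 20, 40, 60).
#' @param sexes default both.
#' @param prices intervention price increases in percent (default 5, 10, 20).
#' @param schedule an [elasticity_schedule()].
#' @param modes life-expectancy modes to report (default all three).
#' @return A tibble with columns `age`, `sex`, `scenario`, `mode`,
#'   `le_reference`, `le`, `gain`.
#' @export
life_expectancy_table <- function(bundle, ages = c(20, 40, 60),
                                  sexes = .sexes, prices = c(5, 10, 20),
                                  schedule = default_schedule(),
                                  modes = c("overall", "copd_free",
                                            "disability_adjusted")) {
  grid <- tidyr::expand_grid(age = ages, sex = sexes, price = prices,
                             mode = modes)
  ref <- tidyr::expand_grid(age = ages, sex = sexes, mode = modes) |>
    dplyr::mutate(le_reference = purrr::pmap_dbl(
      list(.data$age, .data$sex, .data$mode),
      function(a, s, md) cohort_life_expectancy(bundle, NULL, a, s, md)))
  grid |>
    dplyr::mutate(le = purrr::pmap_dbl(
      list(.data$age, .data$sex, .data$price, .data$mode),
      function(a, s, pr, md) {
        cohort_life_expectancy(bundle, price_scenario(pr, schedule), a, s, md)
      })) |>
    dplyr::left_join(ref, by = c("age", "sex", "mode")) |>
    dplyr::mutate(scenario = sprintf("price+%g%%", .data$price),
                  gain = .data$le - .data$le_reference) |>
    dplyr::select("age", "sex", "scenario", "mode", "le_reference", "le",
                  "gain")
}

# ---------------------------------------------------------------------------
# Plots

#' Plot scenario trajectories
#'
#' @param object a `copd_comparison`.
#' @param measure which series to draw: COPD incidence (default), COPD
#'   prevalence, or current-smoking prevalence.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot copd_comparison
#' @export
autoplot.copd_comparison <- function(object,
                                     measure = c("copd_incidence",
                                                 "copd_prevalence",
                                                 "smoking_current"), ...) {
  measure <- match.arg(measure)
  key <- switch(measure, copd_incidence = "copd_incidence_per_1000py",
                copd_prevalence = "copd_prevalence_percent",
                smoking_current = "smoking_current")
  ylab <- switch(measure,
                 copd_incidence = "COPD incidence (cases / 1000 person-years)",
                 copd_prevalence = "COPD prevalence (%)",
                 smoking_current = "Current smoking prevalence (%)")
  df <- outcome_report(object) |>
    dplyr::filter(.data$measure == key) |>
    dplyr::mutate(calendar_year = .data$year + object$bundle$base_year)
  ggplot2::ggplot(df, ggplot2::aes(.data$calendar_year, .data$value,
                                   colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = ylab, colour = "Scenario") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.copd_comparison
#' @param comparison a `copd_comparison`.
#' @export
plot_copd_burden <- function(comparison) {
  autoplot(comparison, measure = "copd_incidence")
}

#' Plot smoking-state prevalences over time for every scenario
#'
#' @param comparison a `copd_comparison`.
#' @return A ggplot object faceted by smoking state.
#' @export
plot_smoking_prevalence <- function(comparison) {
  df <- outcome_report(comparison) |>
    dplyr::filter(startsWith(.data$measure, "smoking_")) |>
    dplyr::mutate(state = sub("smoking_", "", .data$measure),
                  calendar_year = .data$year + comparison$bundle$base_year)
  ggplot2::ggplot(df, ggplot2::aes(.data$calendar_year, .data$value,
                                   colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "Year", y = "Prevalence (%)", colour = "Scenario") +
    ggplot2::theme_minimal()
}

#' Plot a trajectory's age pyramid of COPD cases at a given year
#'
#' @param object a `copd_trajectory`.
#' @param year year index (default final year).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot copd_trajectory
#' @export
autoplot.copd_trajectory <- function(object, year = object$horizon, ...) {
  st <- object$states[[year + 1]]
  df <- as.data.frame.table(apply(st[, , , 2], c(1, 2), sum),
                            responseName = "cases",
                            stringsAsFactors = FALSE)
  names(df)[1:2] <- c("sex", "age")
  df$age <- as.integer(df$age)
  ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$cases,
                                   fill = .data$sex)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Age", y = sprintf("COPD cases at year %d", year)) +
    ggplot2::theme_minimal()
}
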