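#' Elasticity schedules and price-increase scenarios
#'
#' A one-time tobacco price increase acts on the population through the price
#' elasticity of demand (the percentage change in consumption per 1% price
#' increase, a negative number). Elasticities are age-banded: adolescents,
#' with little disposable income, respond more strongly than adults. The
#' default schedule uses -1.5 below age 19, -0.75 at 19--29 and -0.5 from
#' age 30; a uniform -0.5 schedule is provided for sensitivity analyses.
#'
#' @param bands tibble with columns `age_low`, `age_high`, `elasticity`; the
#'   bands must partition ages 11..95 with no overlap and all elasticities
#'   must be `<= 0`.
#' @return An `elasticity_schedule` (a classed tibble).
#' @export
elasticity_schedule <- function(bands) {
  bands <- as_tibble(bands)
  stopifnot(all(c("age_low", "age_high", "elasticity") %in% names(bands)))
  bands <- dplyr::arrange(bands, .data$age_low)
  covered <- unlist(purrr::map2(bands$age_low, bands$age_high, seq))
  if (anyDuplicated(covered) ||
      !setequal(covered, seq(.age_min_smoking, max(.ages)))) {
    abort("elasticity bands must partition ages 11..95 with no overlap")
  }
  if (any(bands$elasticity > 0)) {
    abort("price elasticities must be <= 0")
  }
  structure(bands, class = c("elasticity_schedule", class(bands)))
}

#' @describeIn elasticity_schedule The default age-banded schedule:
#'   -1.5 for ages 11--18, -0.75 for 19--29, -0.5 for 30--95.
#' @export
default_schedule <- function() {
  elasticity_schedule(tibble(
    age_low = c(11L, 19L, 30L),
    age_high = c(18L, 29L, 95L),
    elasticity = c(-1.5, -0.75, -0.5)
  ))
}

#' @describeIn elasticity_schedule The uniform sensitivity-analysis schedule:
#'   -0.5 at every age 11--95.
#' @export
sensitivity_schedule <- function() {
  elasticity_schedule(tibble(age_low = 11L, age_high = 95L,
                             elasticity = -0.5))
}

#' Look up the elasticity applying at given ages
#'
#' @param schedule an `elasticity_schedule`.
#' @param age integer vector of ages; ages below 11 (where no smoking state
#'   other than never exists) return 0.
#' @return Numeric vector of elasticities.
#' @export
elasticity_at <- function(schedule, age) {
  out <- rep(0, length(age))
  for (i in seq_len(nrow(schedule))) {
    sel <- age >= schedule$age_low[i] & age <= schedule$age_high[i]
    out[sel] <- schedule$elasticity[i]
  }
  out
}

#' Define a price-increase scenario
#'
#' @param price_increase_percent one-time percentage increase in the tobacco
#'   price, applied at the beginning of the simulation (0 = reference
#'   scenario).
#' @param schedule an [elasticity_schedule()]; defaults to
#'   [default_schedule()].
#' @param label optional text label; defaults to e.g. `"price+20%"` or
#'   `"reference"`.
#' @return A `price_scenario` object.
#' @export
price_scenario <- function(price_increase_percent,
                           schedule = default_schedule(),
                           label = NULL) {
  if (length(price_increase_percent) != 1 || is.na(price_increase_percent) ||
      price_increase_percent < 0) {
    abort("price_increase_percent must be a single nonnegative number")
  }
  stopifnot(inherits(schedule, "elasticity_schedule"))
  if (is.null(label)) {
    label <- if (price_increase_percent == 0) "reference" else
      sprintf("price+%g%%", price_increase_percent)
  }
  structure(list(price_increase_percent = price_increase_percent,
                 schedule = schedule, label = label),
            class = "price_scenario")
}

#' @export
print.price_scenario <- function(x, ...) {
  cat(sprintf("<price_scenario> %s: one-time price increase %g%%, %d elasticity band(s)\n",
              x$label, x$price_increase_percent, nrow(x$schedule)))
  invisible(x)
}

#' Shift smoking-state prevalences for a price increase
#'
#' Never- and former-smoking prevalences rise by the same relative amount,
#' `|elasticity| * price_pct` percent; current smoking is recomputed as the
#' complement. If the scaled never + former prevalences would exceed 1 they
#' are rescaled proportionally (preserving the never:former ratio) and
#' current smoking is set to 0. A zero price (or zero elasticity) returns the
#' input exactly.
#'
#' @param p data frame with columns `p_never`, `p_current`, `p_former`
#'   (proportions summing to 1 per row), e.g. the `smoking` table of a
#'   bundle.
#' @param elasticity scalar or per-row vector of price elasticities (<= 0).
#' @param price_pct one-time price increase in percent (>= 0).
#' @return `p` with the three columns adjusted; other columns untouched.
#' @export
adjust_prevalence <- function(p, elasticity, price_pct) {
  if (length(price_pct) != 1 || is.na(price_pct) || price_pct < 0) {
    abort("price_pct must be a single nonnegative number")
  }
  f <- 1 + abs(elasticity) * price_pct / 100
  nv <- p$p_never * f
  fm <- p$p_former * f
  over <- nv + fm > 1
  scale <- ifelse(over, 1 / (nv + fm), 1)
  nv <- nv * scale
  fm <- fm * scale
  cur <- pmax(1 - nv - fm, 0)
  cur[over] <- 0
  keep <- f == 1  # untouched rows stay bit-identical
  p$p_never <- ifelse(keep, p$p_never, nv)
  p$p_former <- ifelse(keep, p$p_former, fm)
  p$p_current <- ifelse(keep, p$p_current, cur)
  p
}

#' Shift smoking transition probabilities for a price increase
#'
#' With `f = |elasticity(age)| * price_pct / 100`: initiation and restart
#' probabilities are multiplied by `1 - f`, cessation by `1 + f`; results are
#' clamped to `[0, 1]`. Structural zeros (no cessation below 16, no restart
#' below 22) are preserved automatically.
#'
#' @param transitions the `transitions` table of a bundle (columns `sex`,
#'   `age`, `region`, `initiation`, `cessation`, `restart`).
#' @param schedule an [elasticity_schedule()].
#' @param price_pct one-time price increase in percent (>= 0).
#' @return The adjusted transitions table.
#' @export
adjust_rates <- function(transitions, schedule, price_pct) {
  if (length(price_pct) != 1 || is.na(price_pct) || price_pct < 0) {
    abort("price_pct must be a single nonnegative number")
  }
  f <- abs(elasticity_at(schedule, transitions$age)) * price_pct / 100
  transitions$initiation <- pmin(pmax(transitions$initiation * (1 - f), 0), 1)
  transitions$cessation <- pmin(pmax(transitions$cessation * (1 + f), 0), 1)
  transitions$restart <- pmin(pmax(transitions$restart * (1 - f), 0), 1)
  transitions
}

#' Apply a price-increase scenario to an input bundle
#'
#' Adjusts the baseline smoking-state prevalences (all ages >= 11) and the
#' smoking transition probabilities once, before year 0 of the simulation;
#' all other fields are returned unchanged. A 0% price increase (or an
#' all-zero schedule) returns the bundle exactly as given.
#'
#' @param bundle a valid `copd_bundle`.
#' @param scenario a [price_scenario()].
#' @return A new validated `copd_bundle`.
#' @export
apply_intervention <- function(bundle, scenario) {
  stopifnot(inherits(scenario, "price_scenario"))
  price <- scenario$price_increase_percent
  if (price == 0 || all(scenario$schedule$elasticity == 0)) {
    return(bundle)
  }
  eps <- elasticity_at(scenario$schedule, bundle$smoking$age)
  bundle$smoking <- adjust_prevalence(bundle$smoking, eps, price)
  bundle$transitions <- adjust_rates(bundle$transitions, scenario$schedule,
                                     price)
  problems <- validate_bundle(bundle)
  if (nrow(problems) > 0) {
    abort(c("intervention produced an invalid bundle",
            utils::head(format_violations(problems), 10)))
  }
  bundle
}
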