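#' Parameters for the synthetic input-bundle generator
#'
#' Bundles generated from these parameters have the statistical structure a
#' national tobacco/COPD dataset would show: a smooth age pyramid, smoking
#' uptake concentrated in adolescence with current-smoking prevalence peaking
#' in middle age, cessation rising and relapse declining with age, COPD
#' appearing only from age 40 and rising steeply thereafter, Gompertz-like
#' all-cause mortality, and relative risks of smoking on COPD by age band and
#' on total mortality by sex.
#'
#' @param seed integer seed; a fixed seed yields a byte-identical bundle.
#' @param total_population persons across all ages and sexes (default 1e6).
#' @param pyramid_shape annual growth rate of past birth cohorts; negative
#'   values give an older (top-heavy) pyramid, positive a younger one.
#' @param peak_current_prevalence peak of the current-smoking prevalence
#'   curve, averaged over sexes (default 0.20, reached in middle age; males
#'   are set 25% above, females 25% below this level).
#' @param initiation_peak_age age at which smoking initiation peaks
#'   (default 16; uptake is concentrated at ages 11--20).
#' @param gompertz_alpha,gompertz_beta baseline level and log-slope of the
#'   Gompertz all-cause mortality curve for males (the female level is 55%
#'   of the male level).
#' @param copd_incidence_at_80 annual COPD incidence probability at age 80
#'   (exponential in age from 40; zero below 40).
#' @param rr_copd_by_ageband tibble with columns `sex`, `age_low`,
#'   `age_high`, `rr_current` giving the relative risk of current smoking on
#'   COPD per age band; values must lie within \[8.13, 19.83\].
#'   `rr_former` is derived as `1 + 0.5 * (rr_current - 1)`.
#' @param rr_mort named vector `c(male = , female = )` of relative risks of
#'   current smoking on total mortality (defaults 2.07 and 1.74);
#'   former-smoker RRs are again `1 + 0.5 * (rr - 1)`.
#' @param restart0,restart_decay level at age 22 and exponential decay per
#'   year of age of the relapse (former to current) probability.
#' @param region region tag selecting the transition slice (`"north"` or
#'   `"south"`); the other region is generated alongside with slightly
#'   shifted initiation/cessation.
#' @param horizon_years,base_year,disability_weight passed to the bundle.
#'
#' @return An object of class `synthetic_params`.
#' @seealso [generate_bundle()], [synthetic_profile()]
#' @export
synthetic_params <- function(seed = 1L,
                             total_population = 1e6,
                             pyramid_shape = -0.003,
                             peak_current_prevalence = 0.20,
                             initiation_peak_age = 16,
                             gompertz_alpha = 3e-5,
                             gompertz_beta = 0.095,
                             copd_incidence_at_80 = 0.005,
                             rr_copd_by_ageband = NULL,
                             rr_mort = c(male = 2.07, female = 1.74),
                             restart0 = 0.06,
                             restart_decay = 0.05,
                             region = "north",
                             horizon_years = 40L,
                             base_year = 2018L,
                             disability_weight = 0.2) {
  if (is.null(rr_copd_by_ageband)) {
    rr_copd_by_ageband <- tibble(
      sex = rep(.sexes, each = 3),
      age_low = rep(c(40L, 60L, 80L), 2),
      age_high = rep(c(59L, 79L, 95L), 2),
      rr_current = c(16.0, 11.0, 8.5, 19.83, 13.0, 8.13)
    )
  }
  p <- structure(
    list(seed = as.integer(seed), total_population = total_population,
         pyramid_shape = pyramid_shape,
         peak_current_prevalence = peak_current_prevalence,
         initiation_peak_age = initiation_peak_age,
         gompertz_alpha = gompertz_alpha, gompertz_beta = gompertz_beta,
         copd_incidence_at_80 = copd_incidence_at_80,
         rr_copd_by_ageband = as_tibble(rr_copd_by_ageband),
         rr_mort = rr_mort, restart0 = restart0,
         restart_decay = restart_decay, region = region,
         horizon_years = as.integer(horizon_years),
         base_year = as.integer(base_year),
         disability_weight = disability_weight),
    class = "synthetic_params"
  )
  if (total_population <= 0) abort("total_population must be positive")
  if (peak_current_prevalence <= 0 || peak_current_prevalence >= 0.5) {
    abort("peak_current_prevalence must lie in (0, 0.5)")
  }
  rrc <- p$rr_copd_by_ageband$rr_current
  if (any(rrc < 8.13 - 1e-9) || any(rrc > 19.83 + 1e-9)) {
    abort("COPD relative risks must lie within [8.13, 19.83]")
  }
  if (any(rr_mort < 1)) abort("mortality relative risks must be >= 1")
  if (!region %in% .regions) abort("region must be 'north' or 'south'")
  if (copd_incidence_at_80 <= 0 || copd_incidence_at_80 > 0.2) {
    abort("copd_incidence_at_80 must lie in (0, 0.2]")
  }
  p
}

#' Preset country-like parameter profiles
#'
#' Three illustrative profiles contrasting a populous, high-smoking, ageing
#' southern country with a mid-size northern one and a small, low-smoking
#' northern one. Values are illustrative, not calibrated to any national
#' statistics.
#'
#' @param profile one of `"italy-like"`, `"england-like"`, `"sweden-like"`.
#' @param seed integer seed.
#' @return A `synthetic_params` object.
#' @export
synthetic_profile <- function(profile = c("italy-like", "england-like",
                                          "sweden-like"),
                              seed = 1L) {
  profile <- match.arg(profile)
  switch(profile,
    "italy-like" = synthetic_params(
      seed = seed, total_population = 60e6, pyramid_shape = -0.010,
      peak_current_prevalence = 0.25, region = "south"),
    "england-like" = synthetic_params(
      seed = seed, total_population = 56e6, pyramid_shape = -0.002,
      peak_current_prevalence = 0.22, region = "north"),
    "sweden-like" = synthetic_params(
      seed = seed, total_population = 10e6, pyramid_shape = 0.000,
      peak_current_prevalence = 0.14, region = "north")
  )
}

# Run code with a private RNG stream; the global .Random.seed is untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

# Gompertz-like all-cause mortality with a small infant component.
synthetic_mortality_curve <- function(params, sex) {
  alpha <- params$gompertz_alpha * if (sex == "male") 1 else 0.55
  m <- alpha * exp(params$gompertz_beta * .ages) + 0.002 * exp(-.ages)
  pmin(m, 0.7)
}

# Smoking-state prevalence curves for one sex. Uptake (pnorm ramp centred on
# initiation_peak_age) is concentrated in adolescence, with a small slow
# residual component through mid-adulthood; the fraction of ever-smokers who
# have quit ramps in from age 16 and rises steeply in old age. The curves are
# rescaled so current smoking peaks at the requested per-sex level, in middle
# age.
synthetic_smoking_curves <- function(params, sex) {
  peak <- params$peak_current_prevalence * if (sex == "male") 1.25 else 0.75
  mu <- params$initiation_peak_age
  a <- .ages

  ramp <- function(x, mu, sd) {
    # initiation CDF truncated below the minimum smoking age
    raw <- (pnorm(x, mu, sd) - pnorm(.age_min_smoking, mu, sd)) /
      (1 - pnorm(.age_min_smoking, mu, sd))
    out <- pmax(raw, 0)
    out[x < .age_min_smoking] <- 0
    out
  }
  ever <- 1.05 * ramp(a, mu, 2.5) + 0.25 * ramp(a, 30, 9)

  # former fraction among ever-smokers: zero before 16, gentle linear ramp to
  # a low adult plateau by 30, then a steep rise around age 70
  h <- 0.08 * pmin(pmax((a - .age_min_former) / 14, 0), 1) +
    0.70 * pnorm(a, 70, 9)
  h[a < .age_min_former] <- 0

  current_raw <- ever * (1 - h)
  scale <- peak / max(current_raw)
  ever <- ever * scale
  current <- current_raw * scale
  former <- ever - current
  tibble(sex = sex, age = a,
         p_never = 1 - ever, p_current = current, p_former = former)
}

# Derive initiation and cessation probabilities from the prevalence curves
# via the closed cohort recursion, with an assumed declining relapse curve,
# so that prevalences are stationary under the reference dynamics (exactly,
# up to smoking-differential mortality).
synthetic_transition_curves <- function(params, smoking, sex) {
  sm <- smoking[smoking$sex == sex, ]
  a <- .ages
  nev <- sm$p_never
  cur <- sm$p_current
  fmr <- sm$p_former

  restart <- params$restart0 *
    exp(-params$restart_decay * (a - .age_min_restart))
  restart[a < .age_min_restart] <- 0

  initiation <- rep(0, length(a))
  cessation <- rep(0, length(a))
  for (i in seq_len(length(a) - 1)) {
    if (a[i] >= .age_min_smoking && nev[i] > 0) {
      initiation[i] <- max(0, 1 - nev[i + 1] / nev[i])
    }
    if (a[i] >= .age_min_former && cur[i] > 0) {
      cessation[i] <-
        (fmr[i + 1] - fmr[i] * (1 - restart[i])) / cur[i]
    }
  }
  initiation <- pmin(pmax(initiation, 0), 1)
  cessation <- pmin(pmax(cessation, 0), 1)
  restart <- pmin(pmax(restart, 0), 1)
  tibble(sex = sex, age = a, initiation = initiation,
         cessation = cessation, restart = restart)
}

#' Generate a synthetic country-like input bundle
#'
#' Builds a complete, validated [new_bundle()] from [synthetic_params()].
#' Population counts and projected newborns carry seeded log-normal noise;
#' all rate and prevalence curves are smooth deterministic functions of the
#' parameters. Smoking prevalences and transition probabilities are mutually
#' consistent: the prevalence curves are (up to mortality differentials by
#' smoking state) the stationary age profile of the generated initiation,
#' cessation and relapse probabilities, so reference-scenario prevalence
#' drift reflects demography rather than inconsistent inputs.
#'
#' @param params a `synthetic_params` object (default `synthetic_params()`).
#' @return A validated `copd_bundle`.
#' @examples
#' b <- generate_bundle(synthetic_params(seed = 1))
#' nrow(validate_bundle(b)) == 0
#' @export
generate_bundle <- function(params = synthetic_params()) {
  stopifnot(inherits(params, "synthetic_params"))
  with_seed(params$seed, {
    a <- .ages

    # --- demographics: stationary-population pyramid with birth-cohort trend
    pyramids <- lapply(.sexes, function(sex) {
      m <- synthetic_mortality_curve(params, sex)
      surv <- cumprod(c(1, (1 - m)[-length(m)]))
      base <- surv * (1 + params$pyramid_shape)^(-a)
      noise <- exp(stats::rnorm(length(a), 0, 0.02))
      share <- if (sex == "male") 0.512 else 0.488
      tibble(sex = sex, age = a, count = base * noise * share)
    })
    population <- dplyr::bind_rows(pyramids)
    population$count <- population$count *
      params$total_population / sum(population$count)

    # --- newborns: continue the birth trend with mild noise
    nb0 <- population$count[population$age == 0]
    names(nb0) <- population$sex[population$age == 0]
    newborns <- tidyr::expand_grid(sex = .sexes,
                                   year = seq_len(params$horizon_years))
    trend <- (1 + params$pyramid_shape)^newborns$year
    newborns$count <- nb0[newborns$sex] * trend *
      exp(stats::rnorm(nrow(newborns), 0, 0.01))

    # --- smoking prevalences and consistent transition probabilities
    smoking <- dplyr::bind_rows(lapply(.sexes, function(sex) {
      synthetic_smoking_curves(params, sex)
    }))
    base_tr <- dplyr::bind_rows(lapply(.sexes, function(sex) {
      synthetic_transition_curves(params, smoking, sex)
    }))
    # the selected region carries the consistent rates; the other region is a
    # shifted variant (higher uptake, lower quitting)
    other <- setdiff(.regions, params$region)
    shifted <- dplyr::mutate(
      base_tr,
      initiation = pmin(.data$initiation * 1.15, 1),
      cessation = .data$cessation * 0.85
    )
    transitions <- dplyr::bind_rows(
      dplyr::mutate(base_tr, region = params$region),
      dplyr::mutate(shifted, region = other)
    )

    # --- COPD prevalence and incidence: zero before 40, exponential in age
    copd <- tidyr::expand_grid(sex = .sexes, age = a) |>
      dplyr::mutate(
        prevalence = ifelse(.data$age < .age_min_copd, 0,
                            0.028 * exp(0.045 * (.data$age - 80)) *
                              ifelse(.data$sex == "male", 1.15, 0.85)),
        incidence = ifelse(.data$age < .age_min_copd, 0,
                           params$copd_incidence_at_80 *
                             exp(0.055 * (.data$age - 80)) *
                             ifelse(.data$sex == "male", 1.15, 0.85))
      )

    # --- mortality
    mortality <- dplyr::bind_rows(lapply(.sexes, function(sx) {
      rate <- synthetic_mortality_curve(params, sx)
      tibble(sex = sx, age = a, rate = rate)
    }))

    # --- relative risks: COPD by age band (expanded), mortality by sex;
    #     former-smoker RR is halfway between never and current
    rr_copd <- purrr::pmap_dfr(
      params$rr_copd_by_ageband,
      function(sex, age_low, age_high, rr_current) {
        tibble(sex = sex, age = seq(age_low, age_high),
               rr_current = rr_current,
               rr_former = 1 + 0.5 * (rr_current - 1))
      }) |>
      dplyr::right_join(tidyr::expand_grid(sex = .sexes, age = a),
                        by = c("sex", "age")) |>
      dplyr::mutate(rr_current = dplyr::coalesce(.data$rr_current, 1),
                    rr_former = dplyr::coalesce(.data$rr_former, 1)) |>
      dplyr::arrange(.data$sex, .data$age)
    rr_mort <- tibble(sex = names(params$rr_mort),
                      rr_current = unname(params$rr_mort),
                      rr_former = 1 + 0.5 * (unname(params$rr_mort) - 1))

    new_bundle(
      population = population, newborns = newborns, smoking = smoking,
      transitions = transitions, copd = copd, mortality = mortality,
      rr_copd = rr_copd, rr_mort = rr_mort,
      region = params$region, horizon_years = params$horizon_years,
      base_year = params$base_year,
      disability_weight = params$disability_weight
    )
  })
}

#' Generate a single-cohort bundle
#'
#' Returns a bundle identical to `generate_bundle(params)` except that the
#' population is concentrated in a single (age, sex) cell and no newborns
#' enter, supporting closed-cohort life-expectancy runs.
#'
#' @param age baseline age of the cohort (0--95).
#' @param sex `"male"` or `"female"`.
#' @param params a `synthetic_params` object.
#' @param cohort_size persons in the cell (default 1e5; results per person
#'   are invariant to this).
#' @return A validated `copd_bundle`.
#' @export
generate_cohort_bundle <- function(age, sex, params = synthetic_params(),
                                   cohort_size = 1e5) {
  if (length(age) != 1 || is.na(age) || age < 0 || age > 95) {
    abort("age must be a single integer in 0..95")
  }
  sex <- match.arg(sex, .sexes)
  bundle <- generate_bundle(params)
  as_cohort_bundle(bundle, age, sex, cohort_size)
}

# Restrict an existing bundle to a single-cell closed cohort.
as_cohort_bundle <- function(bundle, age, sex, cohort_size = 1e5) {
  bundle$population$count <- ifelse(
    bundle$population$age == age & bundle$population$sex == sex,
    cohort_size, 0)
  bundle$newborns$count <- rep(0, nrow(bundle$newborns))
  bundle
}
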