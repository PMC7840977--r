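#' Attributable-risk decomposition of a population rate
#'
#' Splits a population-average annual probability (of COPD incidence or of
#' death) into never/current/former-smoker-specific probabilities using
#' relative risks, such that the smoking-distribution-weighted average of the
#' state-specific rates reproduces the population rate:
#' `rate_never = total / (p_never + p_former * rr_former + p_current * rr_current)`,
#' `rate_former = rr_former * rate_never`, `rate_current = rr_current *
#' rate_never`, each clamped to at most 1. An empty denominator returns
#' zeros.
#'
#' All arguments may be vectors (recycled together).
#'
#' @param total population-average annual probability in `[0, 1]`.
#' @param p_never,p_current,p_former smoking-state proportions (sum to 1).
#' @param rr_current,rr_former relative risks vs never smokers (>= 1).
#' @return A tibble with columns `never`, `current`, `former`.
#' @export
decompose_rate <- function(total, p_never, p_current, p_former,
                           rr_current, rr_former) {
  denom <- p_never + p_former * rr_former + p_current * rr_current
  base <- ifelse(denom > 0, total / denom, 0)
  tibble(never = pmin(base, 1),
         current = pmin(base * rr_current, 1),
         former = pmin(base * rr_former, 1))
}

#' @rdname decompose_rate
#' @param smoking_dist length-3 numeric vector `(never, current, former)`;
#'   convenience scalar interface.
#' @export
decompose_incidence <- function(total, smoking_dist, rr_current, rr_former) {
  decompose_rate(total, smoking_dist[1], smoking_dist[2], smoking_dist[3],
                 rr_current, rr_former)
}

#' @rdname decompose_rate
#' @export
decompose_mortality <- decompose_incidence

# ---------------------------------------------------------------------------
# Internal array representation: counts are arrays [sex 2, age 96, smoking 3,
# copd 2]; per-(sex, age) rates are 2 x 96 matrices; per-smoking rates are
# [2, 96, 3] arrays. Matrix-vs-array products below rely on R recycling over
# trailing dimensions, which is exact because the leading dims always match.

state_dims <- function() {
  list(dim = c(2L, 96L, 3L, 2L),
       dimnames = list(sex = .sexes, age = as.character(.ages),
                       smoking = .smoking_states, copd = .copd_states))
}

empty_state <- function() {
  d <- state_dims()
  array(0, dim = d$dim, dimnames = d$dimnames)
}

# Pivot a (sex, age, value...) tibble into 2 x 96 matrices, one per column.
rate_matrix <- function(df, col) {
  df <- dplyr::arrange(df, match(.data$sex, .sexes), .data$age)
  matrix(df[[col]], nrow = 2, ncol = 96, byrow = TRUE,
         dimnames = list(.sexes, as.character(.ages)))
}

bundle_matrices <- function(bundle) {
  tr <- dplyr::filter(bundle$transitions, .data$region == bundle$region)
  list(
    pop = rate_matrix(bundle$population, "count"),
    p_never = rate_matrix(bundle$smoking, "p_never"),
    p_current = rate_matrix(bundle$smoking, "p_current"),
    p_former = rate_matrix(bundle$smoking, "p_former"),
    initiation = rate_matrix(tr, "initiation"),
    cessation = rate_matrix(tr, "cessation"),
    restart = rate_matrix(tr, "restart"),
    copd_prev = rate_matrix(bundle$copd, "prevalence"),
    copd_inc = rate_matrix(bundle$copd, "incidence"),
    mort = rate_matrix(bundle$mortality, "rate"),
    rr_copd_cur = rate_matrix(bundle$rr_copd, "rr_current"),
    rr_copd_for = rate_matrix(bundle$rr_copd, "rr_former")
  )
}

#' Derive frozen state-specific rates from a reference bundle
#'
#' Computes, for every (sex, age), the never/current/former-specific COPD
#' incidence and mortality probabilities by [decompose_rate()] applied to the
#' bundle's population rates and its *reference* (unadjusted) smoking
#' distribution. These rates are frozen: intervention runs reuse them
#' unchanged, so a price scenario affects COPD and mortality only through the
#' smoking-state occupancy it induces.
#'
#' @param bundle a valid `copd_bundle` (the reference bundle, before any
#'   intervention).
#' @return A `copd_state_rates` object holding `incidence` and `mortality`
#'   arrays with dimensions (sex, age, smoking state).
#' @export
build_state_rates <- function(bundle) {
  m <- bundle_matrices(bundle)
  rrm <- bundle$rr_mort
  rr_mort_cur <- matrix(rrm$rr_current[match(.sexes, rrm$sex)], 2, 96,
                        dimnames = list(.sexes, as.character(.ages)))
  rr_mort_for <- matrix(rrm$rr_former[match(.sexes, rrm$sex)], 2, 96,
                        dimnames = list(.sexes, as.character(.ages)))

  inc <- decompose_rate(c(m$copd_inc), c(m$p_never), c(m$p_current),
                        c(m$p_former), c(m$rr_copd_cur), c(m$rr_copd_for))
  mor <- decompose_rate(c(m$mort), c(m$p_never), c(m$p_current),
                        c(m$p_former), c(rr_mort_cur), c(rr_mort_for))

  shape <- function(df) {
    array(c(df$never, df$current, df$former), dim = c(2L, 96L, 3L),
          dimnames = list(sex = .sexes, age = as.character(.ages),
                          smoking = .smoking_states))
  }
  structure(list(incidence = shape(inc), mortality = shape(mor)),
            class = "copd_state_rates")
}

# Initial joint state: baseline population split by the bundle's smoking
# prevalences, with COPD occupancy applied independently of smoking state.
initial_state <- function(bundle) {
  m <- bundle_matrices(bundle)
  st <- empty_state()
  for (k in seq_along(.smoking_states)) {
    pk <- switch(.smoking_states[k], never = m$p_never,
                 current = m$p_current, former = m$p_former)
    st[, , k, 1] <- m$pop * pk * (1 - m$copd_prev)
    st[, , k, 2] <- m$pop * pk * m$copd_prev
  }
  st
}

#' Advance the population one annual cycle
#'
#' Applies, in this fixed order: (1) smoking transitions (initiation,
#' cessation, restart), (2) COPD incidence among the COPD-free using
#' post-transition smoking states (COPD is absorbing), (3) mortality by
#' smoking state (identical for COPD yes/no), (4) ageing by one year, with
#' survivors of age 95 leaving the modelled range and newborns entering at
#' age 0 as never-smokers without COPD.
#'
#' @param state counts array (sex, age, smoking, copd).
#' @param rates a `copd_state_rates` object.
#' @param trans list of 2 x 96 matrices `initiation`, `cessation`, `restart`.
#' @param newborns length-2 named vector of age-0 entrants (male, female).
#' @return A list with elements `state` (next year's counts), `incident`
#'   (new COPD cases, 2 x 96) and `deaths` (2 x 96), both indexed by the age
#'   held during the cycle.
#' @export
step_year <- function(state, rates, trans, newborns) {
  nev <- state[, , 1, , drop = FALSE]
  cur <- state[, , 2, , drop = FALSE]
  fmr <- state[, , 3, , drop = FALSE]

  # (1) smoking transitions; the rate matrices recycle over the copd dim
  up <- c(trans$initiation)
  qt <- c(trans$cessation)
  rs <- c(trans$restart)
  state[, , 1, ] <- nev * (1 - up)
  state[, , 2, ] <- cur * (1 - qt) + nev * up + fmr * rs
  state[, , 3, ] <- fmr * (1 - rs) + cur * qt

  # (2) COPD incidence among the COPD-free (zero below age 40 by input)
  new_cases_k <- state[, , , 1] * rates$incidence
  state[, , , 1] <- state[, , , 1] - new_cases_k
  state[, , , 2] <- state[, , , 2] + new_cases_k
  incident <- apply(new_cases_k, c(1, 2), sum)

  # (3) mortality by smoking state, same for both disease states
  deaths_k <- state * c(rates$mortality)
  state <- state - deaths_k
  deaths <- apply(deaths_k, c(1, 2), sum)

  if (any(state < -1e-9)) {
    abort("internal consistency error: negative counts after annual cycle")
  }

  # (4) ageing and newborn entry
  nxt <- empty_state()
  nxt[, 2:96, , ] <- state[, 1:95, , ]
  nxt[, 1, 1, 1] <- newborns[.sexes]

  list(state = nxt, incident = incident, deaths = deaths)
}

#' Run the full multi-state projection
#'
#' Builds frozen state-specific rates from the unadjusted bundle
#' ([build_state_rates()]), applies the scenario's one-time price shift
#' ([apply_intervention()]) to the baseline prevalences and transition
#' probabilities, then iterates [step_year()] over the bundle's horizon.
#' Fully deterministic: identical inputs give identical trajectories.
#'
#' @param bundle a valid `copd_bundle`.
#' @param scenario a [price_scenario()]; `NULL` (default) runs the reference
#'   scenario with no price change.
#' @return A `copd_trajectory`: list with `states` (length `horizon + 1` list
#'   of counts arrays), `incident` and `deaths` (sex x age x year arrays for
#'   years `0..horizon-1`), and run metadata.
#' @export
run_simulation <- function(bundle, scenario = NULL) {
  if (is.null(scenario)) scenario <- price_scenario(0)
  rates <- build_state_rates(bundle)
  adj <- apply_intervention(bundle, scenario)
  m <- bundle_matrices(adj)
  horizon <- bundle$horizon_years

  nb <- adj$newborns
  states <- vector("list", horizon + 1)
  incident <- array(0, dim = c(2, 96, max(horizon, 1)),
                    dimnames = list(.sexes, as.character(.ages), NULL))
  deaths <- incident

  states[[1]] <- initial_state(adj)
  trans <- list(initiation = m$initiation, cessation = m$cessation,
                restart = m$restart)
  for (t in seq_len(horizon)) {
    nbt <- setNames(nb$count[nb$year == t][match(.sexes,
                                                 nb$sex[nb$year == t])],
                    .sexes)
    stp <- step_year(states[[t]], rates, trans, nbt)
    states[[t + 1]] <- stp$state
    incident[, , t] <- stp$incident
    deaths[, , t] <- stp$deaths
  }
  if (horizon == 0) {
    incident <- incident[, , 0, drop = FALSE]
    deaths <- deaths[, , 0, drop = FALSE]
  }

  structure(
    list(states = states, incident = incident, deaths = deaths,
         horizon = horizon, base_year = bundle$base_year,
         scenario = scenario$label,
         price_increase_percent = scenario$price_increase_percent),
    class = "copd_trajectory"
  )
}

#' @export
print.copd_trajectory <- function(x, ...) {
  cat(sprintf("<copd_trajectory> scenario '%s', years %d..%d (%d cycles)\n",
              x$scenario, x$base_year, x$base_year + x$horizon, x$horizon))
  cat(sprintf("  population: %s at year 0, %s at year %d\n",
              format(round(sum(x$states[[1]])), big.mark = ","),
              format(round(sum(x$states[[x$horizon + 1]])), big.mark = ","),
              x$horizon))
  invisible(x)
}

#' Tidy a trajectory into a long tibble
#'
#' @param x a `copd_trajectory`.
#' @param ... unused.
#' @return A tibble with columns `year` (0-based index), `sex`, `age`,
#'   `smoking`, `copd`, `count`.
#' @method tidy copd_trajectory
#' @export
tidy.copd_trajectory <- function(x, ...) {
  purrr::imap_dfr(x$states, function(st, i) {
    df <- as.data.frame.table(st, responseName = "count",
                              stringsAsFactors = FALSE)
    names(df)[1:4] <- c("sex", "age", "smoking", "copd")
    df$age <- as.integer(df$age)
    df$year <- i - 1L
    as_tibble(df[, c("year", "sex", "age", "smoking", "copd", "count")])
  })
}

#' One-row summary of a trajectory
#'
#' @param x a `copd_trajectory`.
#' @param ... unused.
#' @return A tibble with the scenario label, horizon, initial and final
#'   population, and total deaths and incident COPD cases over the run.
#' @method glance copd_trajectory
#' @export
glance.copd_trajectory <- function(x, ...) {
  tibble(
    scenario = x$scenario,
    price_increase_percent = x$price_increase_percent,
    horizon = x$horizon,
    population_start = sum(x$states[[1]]),
    population_end = sum(x$states[[x$horizon + 1]]),
    total_deaths = sum(x$deaths),
    total_incident_cases = sum(x$incident)
  )
}

# Alive persons by (sex, age) at the start of a given year index (0-based).
alive_matrix <- function(traj, year) {
  apply(traj$states[[year + 1]], c(1, 2), sum)
}
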