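# Shared fixtures, built in code. The seed-1 default bundle is memoised per
# test run since many tests read from it (none mutate it in place).

base_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_bundle(synthetic_params(seed = 1))
    cache
  }
})

# A bundle whose dynamics are trivially predictable: no transitions, no
# disease, no deaths, no newborns. Pure ageing.
inert_bundle <- function(horizon = 3L) {
  b <- base_bundle()
  b$horizon_years <- as.integer(horizon)
  b$newborns <- b$newborns[b$newborns$year <= horizon, ]
  b$newborns$count <- rep(0, nrow(b$newborns))
  b$mortality$rate <- rep(0, nrow(b$mortality))
  b$copd$incidence <- rep(0, nrow(b$copd))
  b$transitions$initiation <- rep(0, nrow(b$transitions))
  b$transitions$cessation <- rep(0, nrow(b$transitions))
  b$transitions$restart <- rep(0, nrow(b$transitions))
  b
}

# Set every relative risk to 1 (smoking has no effect on anything).
flatten_rr <- function(b) {
  b$rr_copd$rr_current <- rep(1, nrow(b$rr_copd))
  b$rr_copd$rr_former <- rep(1, nrow(b$rr_copd))
  b$rr_mort$rr_current <- rep(1, nrow(b$rr_mort))
  b$rr_mort$rr_former <- rep(1, nrow(b$rr_mort))
  b
}

# Concentrate the population on a few (sex, age) cells; everything else zero.
restrict_population <- function(b, ages, sexes = "male", count = 1000) {
  keep <- b$population$age %in% ages & b$population$sex %in% sexes
  b$population$count <- ifelse(keep, count, 0)
  b$newborns$count <- rep(0, nrow(b$newborns))
  b
}

alive_by_sex_age <- function(traj, year) {
  apply(traj$states[[year + 1]], c(1, 2), sum)
}

# Period life expectancy at birth from an age-specific mortality vector,
# with half-cycle correction and a 1/m tail at the top age.
life_table_le <- function(m) {
  l <- cumprod(c(1, 1 - m))
  sum((l[-length(l)] + l[-1]) / 2) + if (m[length(m)] > 0)
    l[length(l)] / m[length(m)] else 0
}
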