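# Independent dense-matrix oracle for the annual cycle: builds, from the
# bundle tables alone (closed-form rate decomposition, explicit destination
# bookkeeping), the one-year transition matrix over the full
# (age, smoking, copd) state space plus an absorbing "gone" state, powers it
# over the horizon, and returns the expected final counts per sex. Written
# without reference to the engine's internals.
oracle_final_state <- function(b, horizon = b$horizon_years) {
  idx <- function(a, k, c) a * 6 + (k - 1) * 2 + c
  n_states <- 96 * 6 + 1
  gone <- n_states

  out <- list()
  for (s in c("male", "female")) {
    sm <- b$smoking[b$smoking$sex == s, ]
    tr <- b$transitions[b$transitions$sex == s &
                          b$transitions$region == b$region, ]
    cp <- b$copd[b$copd$sex == s, ]
    mt <- b$mortality[b$mortality$sex == s, ]
    rc <- b$rr_copd[b$rr_copd$sex == s, ]
    rm <- b$rr_mort[b$rr_mort$sex == s, ]

    A <- matrix(0, n_states, n_states)
    A[gone, gone] <- 1
    for (a in 0:95) {
      i <- a + 1
      denom_i <- sm$p_never[i] + sm$p_former[i] * rc$rr_former[i] +
        sm$p_current[i] * rc$rr_current[i]
      ibase <- if (denom_i > 0) cp$incidence[i] / denom_i else 0
      inc <- pmin(ibase * c(1, rc$rr_current[i], rc$rr_former[i]), 1)
      denom_m <- sm$p_never[i] + sm$p_former[i] * rm$rr_former +
        sm$p_current[i] * rm$rr_current
      mbase <- if (denom_m > 0) mt$rate[i] / denom_m else 0
      mor <- pmin(mbase * c(1, rm$rr_current, rm$rr_former), 1)

      for (k in 1:3) {
        move <- switch(k,
                       c(1 - tr$initiation[i], tr$initiation[i], 0),
                       c(0, 1 - tr$cessation[i], tr$cessation[i]),
                       c(0, tr$restart[i], 1 - tr$restart[i]))
        for (k2 in 1:3) {
          p <- move[k2]
          if (p == 0) next
          surv <- p * (1 - mor[k2])
          dead <- p * mor[k2]
          tgt_no <- if (a < 95) idx(a + 1, k2, 1) else gone
          tgt_yes <- if (a < 95) idx(a + 1, k2, 2) else gone
          A[tgt_yes, idx(a, k, 1)] <- A[tgt_yes, idx(a, k, 1)] +
            surv * inc[k2]
          A[tgt_no, idx(a, k, 1)] <- A[tgt_no, idx(a, k, 1)] +
            surv * (1 - inc[k2])
          A[gone, idx(a, k, 1)] <- A[gone, idx(a, k, 1)] + dead
          A[tgt_yes, idx(a, k, 2)] <- A[tgt_yes, idx(a, k, 2)] + surv
          A[gone, idx(a, k, 2)] <- A[gone, idx(a, k, 2)] + dead
        }
      }
    }

    pop <- b$population[b$population$sex == s, ]
    v <- numeric(n_states)
    for (a in 0:95) {
      i <- a + 1
      pk <- c(sm$p_never[i], sm$p_current[i], sm$p_former[i])
      for (k in 1:3) {
        v[idx(a, k, 1)] <- pop$count[i] * pk[k] * (1 - cp$prevalence[i])
        v[idx(a, k, 2)] <- pop$count[i] * pk[k] * cp$prevalence[i]
      }
    }
    for (t in seq_len(horizon)) v <- A %*% v

    arr <- array(0, dim = c(96, 3, 2))
    for (a in 0:95) {
      for (k in 1:3) {
        for (c2 in 1:2) arr[a + 1, k, c2] <- v[idx(a, k, c2)]
      }
    }
    out[[s]] <- arr
  }
  out
}
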