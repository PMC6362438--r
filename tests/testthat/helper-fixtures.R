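# Shared fixture builders. Everything is generated in code at test time.

# random but valid parameter set (for property-style tests)
random_params <- function() {
  rp <- function(n) runif(n, 0.02, 0.98)
  psi <- function() { s <- rp(2); matrix(c(1 - s[1], s[2], s[1], 1 - s[2]), 2, 2) }
  annual_params(
    b = matrix(rp(4), 2, 2), fled = matrix(runif(4, 0.6, 3), 2, 2),
    phi_fl = rp(2), phi_succ = matrix(rp(4), 2, 2),
    phi_fail = matrix(rp(4), 2, 2),
    psi_fl = psi(), psi_succ = psi(), psi_fail = psi(),
    p = rp(1), c = rp(1)
  )
}

# small-population configuration used by fit-level tests
small_config <- function(years = 10, seed = 42, ...) {
  sim_config(years = years, init_nb = c(12, 8, 20, 12),
             imm_mean = c(5, 3, 4, 3), seed = seed, ...)
}

# hand-built realized series: a single occupied class (Old-Short), no
# recruitment, no movement -- growth reduces to a scalar survival chain
scalar_series <- function(TT = 4, b = c(0.7, 0.8, 0.6), phs = 0.6, phf = 0.3,
                          N0 = 100) {
  TTm <- TT - 1
  bm <- matrix(0.5, 4, TT); bm[3, 1:TTm] <- b
  fled <- matrix(0.6, 4, TT)
  pfl <- matrix(0, 2, TTm)         # no recruitment
  ps <- matrix(phs, 4, TTm); pf <- matrix(phf, 4, TTm)
  NB <- matrix(0, 4, TT); NB[3, 1] <- N0
  Im <- matrix(0, 4, TT)
  psi_id <- list(psi_fl = diag(2), psi_succ = diag(2), psi_fail = diag(2))
  list(b = bm, fled = fled, pfl = pfl, ps = ps, pf = pf,
       NB = NB, Im = Im, psi = psi_id)
}

# brute-force path-enumeration likelihood for one adult history:
# sums over all hidden-state paths, the independent oracle for the
# forward algorithm
enumerate_history_loglik <- function(first, state, events, params_yearly) {
  TT <- length(params_yearly)
  ts <- seq.int(first + 1L, TT)
  n_steps <- length(ts)
  OB <- adult_observation_matrix(params_yearly[[1]]$p, params_yearly[[1]]$c)
  TRs <- lapply(ts, function(t)
    adult_transition_matrix(params_yearly[[t - 1]], params_yearly[[t]]))
  paths <- as.matrix(expand.grid(rep(list(1:9), n_steps)))
  pr <- TRs[[1]][state, paths[, 1]] * OB[cbind(paths[, 1], events[1] + 1L)]
  if (n_steps > 1) for (j in 2:n_steps) {
    pr <- pr * TRs[[j]][cbind(paths[, j - 1], paths[, j])] *
      OB[cbind(paths[, j], events[j] + 1L)]
  }
  log(sum(pr))
}

# all event sequences of a given length in the adult dialect
all_event_sequences <- function(len) {
  as.matrix(expand.grid(rep(list(0:6), len)))
}
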