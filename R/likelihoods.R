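#' Breeding-success log-likelihood
#'
#' Binomial submodel: the number of successful sites `B` among the `R`
#' monitored sites of each year, age class and habitat, with success
#' probability `b[a,h,t]`.
#'
#' @param table data frame with columns `year`, `age` (1 = Young,
#'   2 = Old), `hab` (1 = Short, 2 = Tall), `R`, `B`.
#' @param params_yearly list of [annual_params()], one per year.
#' @return Summed binomial log-pmf.
#' @export
breeding_success_loglik <- function(table, params_yearly) {
  if (any(table$B > table$R) || any(table$B < 0))
    stop("breeding table invalid: need 0 <= B <= R")
  ll <- 0
  for (i in seq_len(nrow(table))) {
    if (table$R[i] == 0) next
    b <- params_yearly[[table$year[i]]]$b[table$age[i], table$hab[i]]
    ll <- ll + dbinom(table$B[i], table$R[i], b, log = TRUE)
  }
  ll
}

#' Fledgling-count log-likelihood
#'
#' Shifted-Poisson submodel: at `S` successful sites with known brood
#' size producing `F` fledglings in total (both sexes),
#' `F - S ~ Poisson(S (2 fled - 1))`, since every successful brood has
#' at least one fledgling and `2 fled` is the mean total brood size
#' (`fled` counts the modelled sex under an even sex ratio).
#'
#' @param table data frame with columns `year`, `age`, `hab`, `S`, `F`.
#' @inheritParams breeding_success_loglik
#' @return Summed Poisson log-pmf over rows with `S >= 1`.
#' @export
fledgling_loglik <- function(table, params_yearly) {
  if (any(table$F < table$S))
    stop("fledgling table invalid: need F >= S (>= 1 fledgling per successful site)")
  ll <- 0
  for (i in seq_len(nrow(table))) {
    if (table$S[i] == 0) next
    fled <- params_yearly[[table$year[i]]]$fled[table$age[i], table$hab[i]]
    rate <- table$S[i] * (2 * fled - 1)
    ll <- ll + dpois(table$F[i] - table$S[i], rate, log = TRUE)
  }
  ll
}

#' Adult state-transition matrix of the multi-event model
#'
#' 9x9 row-stochastic matrix over the hidden states (age x habitat x
#' breeding success for live birds, plus dead). From state `(a, h, s)`
#' in year `t` a bird survives with the success-matched apparent
#' survival, moves with the success-matched habitat transition, is Old
#' next year, and its next success is drawn with `b[O, h']` of year
#' `t + 1`. Dead is absorbing.
#'
#' State order: Y_S_succ, Y_S_fail, Y_T_succ, Y_T_fail, O_S_succ,
#' O_S_fail, O_T_succ, O_T_fail, dead.
#'
#' @param params_t [annual_params()] of year `t` (survival, movement).
#' @param params_next [annual_params()] of year `t + 1` (breeding
#'   success of the arrival year).
#' @return 9x9 numeric matrix, rows summing to one.
#' @export
adult_transition_matrix <- function(params_t, params_next) {
  M <- matrix(0, 9, 9)
  for (a in 1:2) for (h in 1:2) for (s in 1:2) {
    from <- (a - 1L) * 4L + (h - 1L) * 2L + s
    phi <- if (s == 1) params_t$phi_succ[a, h] else params_t$phi_fail[a, h]
    psi <- if (s == 1) params_t$psi_succ else params_t$psi_fail
    for (h2 in 1:2) {
      b2 <- params_next$b[2, h2]
      to_succ <- 4L + (h2 - 1L) * 2L + 1L
      M[from, to_succ] <- M[from, to_succ] + phi * psi[h, h2] * b2
      M[from, to_succ + 1L] <- M[from, to_succ + 1L] + phi * psi[h, h2] * (1 - b2)
    }
    M[from, 9] <- 1 - phi
  }
  M[9, 9] <- 1
  M
}

#' Adult observation (event) matrix
#'
#' 9x7 row-stochastic matrix linking hidden states to event codes
#' 0-6 (columns 1-7): 0 = not seen, 1/2/3 = seen on Short with
#' success/failure/unknown status, 4/5/6 = the same on Tall. A live
#' bird is seen with probability `p`; its success status is recorded
#' with probability `c`, else coded unknown. Dead birds are never seen.
#'
#' @param p resighting probability.
#' @param c state-certainty probability.
#' @return 9x7 numeric matrix, rows summing to one.
#' @export
adult_observation_matrix <- function(p, c) {
  if (p < 0 || p > 1 || c < 0 || c > 1) stop("p and c must lie in [0, 1]")
  M <- matrix(0, 9, 7)
  for (a in 1:2) for (h in 1:2) for (s in 1:2) {
    from <- (a - 1L) * 4L + (h - 1L) * 2L + s
    M[from, 1] <- 1 - p
    M[from, 1L + (h - 1L) * 3L + s] <- p * c
    M[from, 1L + (h - 1L) * 3L + 3L] <- p * (1 - c)
  }
  M[9, 1] <- 1
  M
}

#' Adult multi-event capture-mark-resight log-likelihood
#'
#' Hidden-state forward algorithm, conditioned on the fully known state
#' at first capture (age class, habitat and breeding success), over the
#' yearly transition ([adult_transition_matrix()]) and observation
#' ([adult_observation_matrix()]) matrices. Unobserved birds may be
#' alive and present throughout.
#'
#' @param histories list with `first` (first-capture year per bird),
#'   `state` (hidden-state index 1-8 at first capture) and `events`
#'   (matrix, one row per bird, event codes 0-6 from the year after
#'   first capture onwards; entries before/at first capture are ignored).
#' @inheritParams breeding_success_loglik
#' @return Summed log-likelihood over birds.
#' @export
adult_multievent_loglik <- function(histories, params_yearly) {
  TT <- length(params_yearly)
  ev <- histories$events
  if (!is.matrix(ev) || ncol(ev) != TT)
    stop("event matrix must have one column per year")
  codes <- ev[!is.na(ev)]
  if (length(codes) && (any(codes < 0) || any(codes > 6)))
    stop("invalid adult event code (dialect is 0-6)")
  TRs <- vector("list", TT - 1)
  for (t in seq_len(TT - 1))
    TRs[[t]] <- adult_transition_matrix(params_yearly[[t]], params_yearly[[t + 1]])
  OB <- adult_observation_matrix(params_yearly[[1]]$p, params_yearly[[1]]$c)
  ll <- 0
  for (i in seq_along(histories$first)) {
    f <- histories$first[i]
    if (f >= TT) next
    alpha <- numeric(9)
    alpha[histories$state[i]] <- 1
    for (t in seq.int(f + 1L, TT)) {
      e <- ev[i, t]
      if (is.na(e)) stop(sprintf("missing event for bird %d, year %d", i, t))
      alpha <- as.numeric(alpha %*% TRs[[t - 1]]) * OB[, e + 1L]
    }
    ll <- ll + log(sum(alpha))
  }
  ll
}

#' Juvenile recruitment log-likelihood
#'
#' Single-occasion resighting of ringed fledglings the year after
#' fledging: a bird from natal habitat `h` of cohort `t` is seen
#' breeding in habitat `h'` with probability
#' `phi_fl[h, t] * psi_fl[h -> h'] * p` and not seen with probability
#' `1 - phi_fl[h, t] * p` (settlement marginalised).
#'
#' @param histories data frame with columns `cohort` (fledging year),
#'   `natal` (1 = Short, 2 = Tall) and `event` (0 = not seen,
#'   1 = seen breeding Short, 2 = seen breeding Tall).
#' @inheritParams breeding_success_loglik
#' @return Summed log-probability.
#' @export
juvenile_recruitment_loglik <- function(histories, params_yearly) {
  if (any(!histories$event %in% 0:2))
    stop("invalid juvenile event code (dialect is 0-2)")
  ll <- 0
  for (i in seq_len(nrow(histories))) {
    t <- histories$cohort[i]
    pp <- params_yearly[[t]]
    phi <- pp$phi_fl[histories$natal[i]]
    e <- histories$event[i]
    pr <- if (e == 0) 1 - phi * pp$p
          else phi * pp$psi_fl[histories$natal[i], e] * pp$p
    ll <- ll + log(pr)
  }
  unname(ll)
}

#' Count state-space log-likelihood
#'
#' Joint log-probability of the latent demographic process and the
#' observed class counts. The process draws, per year transition:
#' successful breeders `succ ~ Bin(NB, b)`; survivors
#' `svS ~ Bin(succ, phi_succ)`, `svF ~ Bin(NB - succ, phi_fail)`;
#' habitat switchers `mvS ~ Bin(svS, psi_succ[h -> h'])`,
#' `mvF ~ Bin(svF, psi_fail[h -> h'])`; locally produced recruits
#' `recY[h'] ~ Poisson(sum_k NB[k] b fled phi_fl psi_fl)` pooled over
#' origins; immigrants `Im ~ Poisson(max(imm_mean, 0))`; and first-year
#' sizes `NB[ ,1] ~ Poisson(lam1)`. Observed counts are
#' `y ~ Poisson(NB)`.
#'
#' @param counts 4 x T matrix of observed class counts (class order
#'   [class_order()]).
#' @param latent list with `nb` (4 x T), `im` (4 x T), `succ`, `svS`,
#'   `svF`, `mvS`, `mvF` (4 x T-1) and `recY` (2 x T-1).
#' @param imm_mean 4 x T matrix of expected immigrant numbers (column 1
#'   ignored).
#' @param lam1 length-4 positive means of the initial class sizes.
#' @inheritParams breeding_success_loglik
#' @return Total log-probability (process + observation), `-Inf` for
#'   inconsistent latent states.
#' @export
count_state_space_loglik <- function(counts, latent, params_yearly,
                                     imm_mean, lam1) {
  TT <- ncol(counts)
  nb <- latent$nb
  if (any(nb < 0) || any(latent$im < 0)) stop("negative latent counts")
  ll <- sum(dpois(nb[, 1], lam1, log = TRUE))
  for (t in seq_len(TT - 1)) {
    pp <- params_yearly[[t]]
    a <- c(1, 1, 2, 2); h <- c(1, 2, 1, 2)
    b <- pp$b[cbind(a, h)]; fs <- pp$phi_succ[cbind(a, h)]
    ff <- pp$phi_fail[cbind(a, h)]
    # impossible configurations have probability zero, not NaN
    if (any(latent$succ[, t] > nb[, t]) ||
        any(latent$svS[, t] > latent$succ[, t]) ||
        any(latent$svF[, t] > nb[, t] - latent$succ[, t]) ||
        any(latent$mvS[, t] > latent$svS[, t]) ||
        any(latent$mvF[, t] > latent$svF[, t])) return(-Inf)
    psw_s <- pp$psi_succ[cbind(h, 3 - h)]
    psw_f <- pp$psi_fail[cbind(h, 3 - h)]
    ll <- ll + sum(dbinom(latent$succ[, t], nb[, t], b, log = TRUE)) +
      sum(dbinom(latent$svS[, t], latent$succ[, t], fs, log = TRUE)) +
      sum(dbinom(latent$svF[, t], nb[, t] - latent$succ[, t], ff, log = TRUE)) +
      sum(dbinom(latent$mvS[, t], latent$svS[, t], psw_s, log = TRUE)) +
      sum(dbinom(latent$mvF[, t], latent$svF[, t], psw_f, log = TRUE))
    rate <- numeric(2)
    for (h2 in 1:2)
      rate[h2] <- sum(nb[, t] * b * pp$fled[cbind(a, h)] *
                        pp$phi_fl[h] * pp$psi_fl[cbind(h, rep(h2, 4))])
    ll <- ll + sum(dpois(latent$recY[, t], rate, log = TRUE)) +
      sum(dpois(latent$im[, t + 1], pmax(imm_mean[, t + 1], 0), log = TRUE))
    # deterministic bookkeeping must hold exactly
    stay <- latent$svS[, t] + latent$svF[, t] - latent$mvS[, t] - latent$mvF[, t]
    mv <- latent$mvS[, t] + latent$mvF[, t]
    oldS <- stay[1] + stay[3] + mv[2] + mv[4]
    oldT <- stay[2] + stay[4] + mv[1] + mv[3]
    expect <- c(latent$recY[1, t] + latent$im[1, t + 1],
                latent$recY[2, t] + latent$im[2, t + 1],
                oldS + latent$im[3, t + 1],
                oldT + latent$im[4, t + 1])
    if (any(expect != nb[, t + 1])) return(-Inf)
  }
  ll + sum(dpois(counts, nb, log = TRUE))
}

#' Joint IPM log-likelihood
#'
#' Sum of the submodel components sharing parameters: breeding trials,
#' fledgling counts, adult multi-event histories, juvenile recruitment
#' histories, and the count state-space model.
#'
#' @param dataset an `ipm_dataset` (see [observe_dataset()]).
#' @param latent,imm_mean,lam1 as in [count_state_space_loglik()].
#' @inheritParams breeding_success_loglik
#' @return Total log-likelihood.
#' @export
ipm_joint_loglik <- function(dataset, params_yearly, latent, imm_mean, lam1) {
  breeding_success_loglik(dataset$breeding, params_yearly) +
    fledgling_loglik(dataset$fledglings, params_yearly) +
    adult_multievent_loglik(dataset$adult_histories, params_yearly) +
    juvenile_recruitment_loglik(dataset$juvenile_histories, params_yearly) +
    count_state_space_loglik(dataset$counts, latent, params_yearly,
                             imm_mean, lam1)
}
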