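const_params <- function(ap, TT) rep(list(ap), TT)

test_that("breeding-success likelihood: closed forms and binomial oracle", {
  ap <- default_params(); ap$b[] <- 1
  tab <- data.frame(year = 1, age = 1, hab = 1, R = 1, B = 1)
  expect_equal(breeding_success_loglik(tab, const_params(ap, 1)), 0)

  ap$b[] <- 0.5
  tab <- data.frame(year = 1, age = 1, hab = 1, R = 2, B = 1)
  expect_equal(breeding_success_loglik(tab, const_params(ap, 1)), log(0.5))

  set.seed(4)
  pars <- lapply(1:24, function(t) random_params())
  tab <- expand.grid(year = 1:24, age = 1:2, hab = 1:2)
  tab$R <- rpois(nrow(tab), 30)
  tab$B <- rbinom(nrow(tab), tab$R, 0.7)
  oracle <- sum(vapply(seq_len(nrow(tab)), function(i) {
    if (tab$R[i] == 0) return(0)
    bb <- pars[[tab$year[i]]]$b[tab$age[i], tab$hab[i]]
    lchoose(tab$R[i], tab$B[i]) + tab$B[i] * log(bb) +
      (tab$R[i] - tab$B[i]) * log(1 - bb)
  }, numeric(1)))
  expect_equal(breeding_success_loglik(tab, pars), oracle, tolerance = 1e-10)

  tab$B[1] <- tab$R[1] + 1
  expect_error(breeding_success_loglik(tab, pars), "B <= R")
})

test_that("fledgling likelihood: closed forms, boundary, Poisson oracle", {
  ap <- default_params(); ap$fled[] <- 1.5
  tab <- data.frame(year = 1, age = 1, hab = 1, S = 1, F = 3)
  expect_equal(fledgling_loglik(tab, const_params(ap, 1)),
               dpois(2, 2, log = TRUE))
  expect_equal(fledgling_loglik(tab, const_params(ap, 1)), log(2 * exp(-2)))

  ap$fled[] <- 0.5 + 1e-12
  tab <- data.frame(year = 1, age = 1, hab = 1, S = 10, F = 10)
  expect_equal(fledgling_loglik(tab, const_params(ap, 1)), 0,
               tolerance = 1e-9)

  set.seed(5)
  pars <- lapply(1:10, function(t) random_params())
  tab <- expand.grid(year = 1:10, age = 1:2, hab = 1:2)
  tab$S <- rpois(nrow(tab), 12)
  tab$F <- tab$S + rpois(nrow(tab), 15)
  oracle <- sum(vapply(seq_len(nrow(tab)), function(i) {
    if (tab$S[i] == 0) return(0)
    fl <- pars[[tab$year[i]]]$fled[tab$age[i], tab$hab[i]]
    lam <- tab$S[i] * (2 * fl - 1)
    x <- tab$F[i] - tab$S[i]
    x * log(lam) - lam - lgamma(x + 1)
  }, numeric(1)))
  expect_equal(fledgling_loglik(tab, pars), oracle, tolerance = 1e-10)

  tab$F[1] <- tab$S[1] - 1
  expect_error(fledgling_loglik(tab, pars), "F >= S")
})

test_that("adult transition matrix: degenerate cases, stochasticity, path oracle", {
  ap <- default_params()
  ap0 <- ap; ap0$phi_succ[] <- 0; ap0$phi_fail[] <- 0
  M <- adult_transition_matrix(ap0, ap)
  expect_equal(M[, 9], rep(1, 9))

  ap1 <- ap
  ap1$phi_succ[] <- 1; ap1$phi_fail[] <- 1
  ap1$psi_succ <- diag(2); ap1$psi_fail <- diag(2)
  apn <- ap; apn$b[2, ] <- 1
  M <- adult_transition_matrix(ap1, apn)
  # (Y,S,succ) -> (O,S,succ) and (Y,T,fail) -> (O,T,succ) with certainty
  expect_equal(M[1, 5], 1)
  expect_equal(M[4, 7], 1)

  set.seed(6)
  for (i in 1:50) {
    p1 <- random_params(); p2 <- random_params()
    M <- adult_transition_matrix(p1, p2)
    expect_equal(rowSums(M), rep(1, 9), tolerance = 1e-12)
    # brute-force enumeration of survive x move x next-success paths
    for (a in 1:2) for (h in 1:2) for (s in 1:2) {
      from <- (a - 1) * 4 + (h - 1) * 2 + s
      phi <- if (s == 1) p1$phi_succ[a, h] else p1$phi_fail[a, h]
      psi <- if (s == 1) p1$psi_succ else p1$psi_fail
      for (h2 in 1:2) {
        expect_equal(M[from, 4 + (h2 - 1) * 2 + 1],
                     phi * psi[h, h2] * p2$b[2, h2], tolerance = 1e-12)
        expect_equal(M[from, 4 + (h2 - 1) * 2 + 2],
                     phi * psi[h, h2] * (1 - p2$b[2, h2]), tolerance = 1e-12)
      }
      expect_equal(M[from, 9], 1 - phi, tolerance = 1e-12)
    }
  }
})

test_that("observation matrix: degenerate cases and row-stochasticity", {
  M <- adult_observation_matrix(0, 0.5)
  expect_equal(M[, 1], rep(1, 9))

  M <- adult_observation_matrix(1, 1)
  expect_equal(M[1, 2], 1)  # Y_S_succ emits code 1
  expect_equal(M[4, 6], 1)  # Y_T_fail emits code 5
  set.seed(8)
  for (i in 1:50) {
    p <- runif(1); cc <- runif(1)
    M <- adult_observation_matrix(p, cc)
    expect_equal(rowSums(M), rep(1, 9), tolerance = 1e-12)
    # state (O,T,fail) = row 8: seen-T-fail code 5 (col 6), unknown-T code 6
    expect_equal(M[8, 6], p * cc, tolerance = 1e-12)
    expect_equal(M[8, 7], p * (1 - cc), tolerance = 1e-12)
    expect_equal(M[8, 1], 1 - p, tolerance = 1e-12)
  }
})

test_that("forward likelihood equals exhaustive path enumeration", {
  set.seed(9)
  pars <- lapply(1:4, function(t) random_params())
  # all histories of length <= 3 (first capture + up to 2 events)
  for (len in 1:2) {
    seqs <- all_event_sequences(len)
    for (state in 1:8) {
      first <- 4 - len
      lls <- vapply(seq_len(nrow(seqs)), function(i) {
        ev <- matrix(NA_integer_, 1, 4)
        ev[1, (first + 1):4] <- seqs[i, ]
        adult_multievent_loglik(list(first = first, state = state,
                                     events = ev), pars)
      }, numeric(1))
      oracle <- vapply(seq_len(nrow(seqs)), function(i)
        enumerate_history_loglik(first, state, seqs[i, ], pars), numeric(1))
      expect_equal(lls, oracle, tolerance = 1e-10)
    }
  }
})

test_that("forward likelihood closed forms: single path and certain death", {
  ap <- default_params(); ap$p <- 1; ap$c <- 1
  pars <- const_params(ap, 2)
  # seen next year on Short as a successful breeder, released as (O,S,succ)
  ev <- matrix(c(NA, 1L), 1, 2)
  ll <- adult_multievent_loglik(list(first = 1, state = 5, events = ev), pars)
  hand <- log(ap$phi_succ[2, 1] * ap$psi_succ[1, 1] * ap$b[2, 1])
  expect_equal(ll, hand, tolerance = 1e-12)

  apd <- default_params(); apd$phi_succ[] <- 0; apd$phi_fail[] <- 0
  ev <- matrix(c(NA, 0L, 0L), 1, 3)
  ll <- adult_multievent_loglik(list(first = 1, state = 5, events = ev),
                                const_params(apd, 3))
  expect_equal(ll, 0)  # death certain, non-detection certain
})

test_that("juvenile recruitment likelihood: degenerate cases and oracle", {
  ap <- default_params(); ap$phi_fl[] <- 0
  jh <- data.frame(cohort = c(1, 1, 2), natal = c(1, 2, 1), event = c(0, 0, 0))
  expect_equal(juvenile_recruitment_loglik(jh, const_params(ap, 3)), 0)

  ap <- default_params(); ap$phi_fl[] <- 1; ap$psi_fl <- diag(2); ap$p <- 1
  jh <- data.frame(cohort = 1, natal = 1, event = 1)
  expect_equal(juvenile_recruitment_loglik(jh, const_params(ap, 2)), 0)

  set.seed(10)
  pars <- lapply(1:6, function(t) random_params())
  jh <- data.frame(cohort = sample(1:5, 200, TRUE),
                   natal = sample(1:2, 200, TRUE),
                   event = sample(0:2, 200, TRUE))
  oracle <- sum(vapply(seq_len(nrow(jh)), function(i) {
    pp <- pars[[jh$cohort[i]]]
    h <- jh$natal[i]; e <- jh$event[i]
    pr <- if (e == 0) 1 - pp$phi_fl[h] * pp$p else
      pp$phi_fl[h] * pp$psi_fl[h, e] * pp$p
    log(pr)
  }, numeric(1)))
  expect_equal(juvenile_recruitment_loglik(jh, pars), oracle, tolerance = 1e-12)
  jh$event[1] <- 5
  expect_error(juvenile_recruitment_loglik(jh, pars), "invalid juvenile")
})

test_that("count state-space likelihood: bookkeeping, zero-process, Poisson mode", {
  TT <- 3
  pars <- const_params(default_params(), TT)
  mk_latent <- function() {
    nb <- matrix(10L, 4, TT); im <- matrix(2L, 4, TT); im[, 1] <- 0L
    succ <- svS <- svF <- mvS <- mvF <- matrix(0L, 4, TT - 1)
    recY <- matrix(2L, 2, TT - 1)
    # build forward so every binomial chain stays feasible
    for (t in 1:(TT - 1)) {
      succ[, t] <- pmin(6L, nb[, t])
      svS[, t] <- pmin(3L, succ[, t])
      svF[, t] <- pmin(1L, nb[, t] - succ[, t])
      mvS[, t] <- pmin(1L, svS[, t])
      stay <- svS[, t] + svF[, t] - mvS[, t] - mvF[, t]
      mv <- mvS[, t] + mvF[, t]
      nb[, t + 1] <- c(recY[1, t] + im[1, t + 1], recY[2, t] + im[2, t + 1],
                       stay[1] + stay[3] + mv[2] + mv[4] + im[3, t + 1],
                       stay[2] + stay[4] + mv[1] + mv[3] + im[4, t + 1])
    }
    list(nb = nb, im = im, succ = succ, svS = svS, svF = svF,
         mvS = mvS, mvF = mvF, recY = recY)
  }
  lat <- mk_latent()
  imm_mean <- matrix(2, 4, TT)
  counts <- lat$nb
  ll <- count_state_space_loglik(counts, lat, pars, imm_mean, lam1 = rep(10, 4))
  expect_true(is.finite(ll))

  # inconsistent bookkeeping is impossible
  bad <- lat; bad$nb[1, 2] <- bad$nb[1, 2] + 1L
  expect_equal(count_state_space_loglik(counts, bad, pars, imm_mean, rep(10, 4)),
               -Inf)

  # the observation term is maximised at y = NB over integer counts
  # (the Poisson pmf ties at NB - 1, hence non-strict there)
  base <- count_state_space_loglik(lat$nb, lat, pars, imm_mean, rep(10, 4))
  for (shift in c(-2L, -1L, 1L, 2L)) {
    y2 <- lat$nb; y2[2, 2] <- y2[2, 2] + shift
    expect_lte(count_state_space_loglik(y2, lat, pars, imm_mean, rep(10, 4)),
               base)
  }
  y2 <- lat$nb; y2[2, 2] <- y2[2, 2] + 2L
  expect_lt(count_state_space_loglik(y2, lat, pars, imm_mean, rep(10, 4)), base)

  # no survival and no immigration: any later population is impossible
  apz <- default_params()
  apz$phi_succ[] <- 0; apz$phi_fail[] <- 0; apz$phi_fl[] <- 0
  parz <- const_params(apz, TT)
  expect_equal(count_state_space_loglik(counts, lat, parz,
                                        matrix(0, 4, TT), rep(10, 4)), -Inf)
})

test_that("joint likelihood is the sum of the shared-parameter submodels", {
  set.seed(12)
  d <- simulate_ipm_dataset(small_config(years = 6, seed = 77))
  pars <- d$truth$params
  TT <- 6
  # assemble a consistent latent bundle from the truth records
  lat <- list(nb = d$truth$nb, im = d$truth$im,
              succ = matrix(0L, 4, TT - 1), svS = matrix(0L, 4, TT - 1),
              svF = matrix(0L, 4, TT - 1), mvS = matrix(0L, 4, TT - 1),
              mvF = matrix(0L, 4, TT - 1), recY = matrix(0L, 2, TT - 1))
  st <- d$truth$state; su <- d$truth$success
  for (t in 1:(TT - 1)) {
    for (k in 1:4) {
      alive <- which(st[, t] == k)
      s <- su[alive, t]
      lat$succ[k, t] <- sum(s == 1)
      surv <- st[alive, t + 1] > 0
      h <- (k - 1) %% 2 + 1
      moved <- surv & ((st[alive, t + 1] - 1) %% 2 + 1) != h
      lat$svS[k, t] <- sum(surv & s == 1)
      lat$svF[k, t] <- sum(surv & s == 0)
      lat$mvS[k, t] <- sum(moved & s == 1)
      lat$mvF[k, t] <- sum(moved & s == 0)
    }
    lat$recY[, t] <- d$truth$recruits_in[1:2, t + 1]
  }
  imm_mean <- d$truth$imm_mean
  lam1 <- pmax(d$truth$nb[, 1], 1)
  total <- ipm_joint_loglik(d$observed, pars, lat, imm_mean, lam1)
  parts <- breeding_success_loglik(d$observed$breeding, pars) +
    fledgling_loglik(d$observed$fledglings, pars) +
    adult_multievent_loglik(d$observed$adult_histories, pars) +
    juvenile_recruitment_loglik(d$observed$juvenile_histories, pars) +
    count_state_space_loglik(d$observed$counts, lat, pars, imm_mean, lam1)
  expect_equal(total, parts, tolerance = 1e-10)
  expect_true(is.finite(total))
})
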