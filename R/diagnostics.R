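#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor per scalar parameter:
#' `sqrt(((n-1)/n W + B/n) / W)` with `W` the mean within-chain
#' variance and `B/n` the variance of the chain means. Values above
#' 1.1 are flagged as unconverged.
#'
#' @param draws an `ipm_fit`, or a numeric array with dimensions
#'   `(iteration, chain)` or `(iteration, chain, parameter)`.
#' @param threshold flag limit (default 1.1).
#' @return A data frame with columns `parameter`, `rhat`, `flagged`.
#' @export
rhat_diagnostic <- function(draws, threshold = 1.1) {
  if (inherits(draws, "ipm_fit")) {
    # diagnose the reported blocks: hyper-means/SDs, constants, and the
    # latent trajectory
    blocks <- c("mu", "sd", "psi_succ_sw", "psi_fail_sw", "psi_fl_sw",
                "p", "c", "lam1")
    out <- do.call(rbind, lapply(blocks, function(bl) {
      x <- draws_block(draws, bl)
      if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
      rh <- apply(x, 3, rhat_scalar)
      data.frame(parameter = paste0(bl, "[", seq_along(rh), "]"),
                 rhat = rh)
    }))
    out$flagged <- is.finite(out$rhat) & out$rhat > threshold
    return(out)
  }
  x <- draws
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  if (length(dim(x)) != 3) stop("draws must be (iteration, chain[, parameter])")
  if (dim(x)[2] < 2) stop("at least two chains are required for R-hat")
  rh <- apply(x, 3, rhat_scalar)
  data.frame(parameter = seq_along(rh), rhat = rh,
             flagged = is.finite(rh) & rh > threshold)
}

rhat_scalar <- function(x) {
  # x: iterations x chains
  n <- nrow(x); m <- ncol(x)
  if (n < 2 || m < 2) return(NA_real_)
  W <- mean(apply(x, 2, var))
  B_n <- var(colMeans(x))           # = B/n
  if (W <= 0) return(if (B_n <= 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B_n) / W)
}

#' Posterior predictive checks per submodel
#'
#' For a subsample of posterior draws, replicate each data stream from
#' the fitted parameters (and latent states where applicable) and
#' compare a discrepancy computed on the observed data with the same
#' discrepancy on the replicates. Counts, breeding trials, fledgling
#' counts and juvenile resightings use the Freeman-Tukey statistic
#' `sum (sqrt(obs) - sqrt(expected))^2`; the adult multi-event stream
#' uses the model deviance `-2 log L`. The Bayesian p-value is the
#' proportion of draws in which the replicate discrepancy exceeds the
#' observed one.
#'
#' @param fit an `ipm_fit`.
#' @param dataset the `ipm_dataset` that was fitted.
#' @param n_draws number of posterior draws to use.
#' @return A data frame with one row per submodel: `submodel`,
#'   `p_value`, `d_obs_mean`, `d_rep_mean`.
#' @export
posterior_predictive_check <- function(fit, dataset, n_draws = 100) {
  TT <- fit$years
  n_save <- nrow(fit$chains[[1]])
  n_ch <- length(fit$chains)
  total <- n_save * n_ch
  pick <- round(seq(1, total, length.out = min(n_draws, total)))
  ft <- function(obs, expd) sum((sqrt(obs) - sqrt(pmax(expd, 0)))^2)

  acc <- list(counts = c(0, 0), breeding = c(0, 0), fledglings = c(0, 0),
              juveniles = c(0, 0), adults = c(0, 0))
  dsum <- list(counts = c(0, 0), breeding = c(0, 0), fledglings = c(0, 0),
               juveniles = c(0, 0), adults = c(0, 0))
  bump <- function(nm, d_obs, d_rep) {
    acc[[nm]] <<- acc[[nm]] + c(d_rep > d_obs, 1)
    dsum[[nm]] <<- dsum[[nm]] + c(d_obs, d_rep)
  }

  ah <- dataset$adult_histories
  keep <- ah$first < TT
  fc0 <- as.integer(ah$first[keep] - 1L)
  st00 <- as.integer(ah$state[keep] - 1L)
  ev <- ah$events[keep, , drop = FALSE]
  ev[is.na(ev)] <- 0L

  for (ix in pick) {
    ch <- (ix - 1) %/% n_save + 1
    dr <- (ix - 1) %% n_save + 1
    pars <- params_from_draw(fit, dr, ch)
    NB <- draws_block(fit, "NB")[dr, ch, , ]

    if (fit$include["counts"]) {
      y_obs <- dataset$counts
      y_rep <- matrix(rpois(length(NB), pmax(NB, 1e-12)), 4, TT)
      bump("counts", ft(y_obs, NB), ft(y_rep, NB))
    }
    if (fit$include["breeding"]) {
      tab <- dataset$breeding
      bvec <- vapply(seq_len(nrow(tab)), function(i)
        pars[[tab$year[i]]]$b[tab$age[i], tab$hab[i]], numeric(1))
      expd <- tab$R * bvec
      B_rep <- rbinom(nrow(tab), tab$R, bvec)
      bump("breeding", ft(tab$B, expd), ft(B_rep, expd))
    }
    if (fit$include["fledglings"]) {
      tab <- dataset$fledglings
      fvec <- vapply(seq_len(nrow(tab)), function(i)
        pars[[tab$year[i]]]$fled[tab$age[i], tab$hab[i]], numeric(1))
      rate <- tab$S * (2 * fvec - 1)
      x_obs <- tab$F - tab$S
      x_rep <- rpois(nrow(tab), rate)
      bump("fledglings", ft(x_obs, rate), ft(x_rep, rate))
    }
    if (fit$include["juveniles"]) {
      jh <- dataset$juvenile_histories
      d_obs <- 0; d_rep <- 0
      for (t in unique(jh$cohort)) for (h in 1:2) {
        sel <- jh$cohort == t & jh$natal == h
        n <- sum(sel)
        if (n == 0) next
        pp <- pars[[t]]
        pr <- c(pp$phi_fl[h] * pp$psi_fl[h, 1] * pp$p,
                pp$phi_fl[h] * pp$psi_fl[h, 2] * pp$p)
        pr <- c(pr, 1 - sum(pr))
        obs <- c(sum(jh$event[sel] == 1), sum(jh$event[sel] == 2),
                 sum(jh$event[sel] == 0))
        rep_ <- as.integer(rmultinom(1, n, pr))
        d_obs <- d_obs + ft(obs, n * pr)
        d_rep <- d_rep + ft(rep_, n * pr)
      }
      bump("juveniles", d_obs, d_rep)
    }
    if (fit$include["adults"] && length(fc0)) {
      trs <- tr_flat(pars)
      OB <- adult_observation_matrix(pars[[1]]$p, pars[[1]]$c)
      d_obs <- -2 * sum(cpp_adult_forward(fc0, st00, ev, trs, OB, TT))
      ev_rep <- simulate_adult_events(fc0, st00, pars, TT)
      d_rep <- -2 * sum(cpp_adult_forward(fc0, st00, ev_rep, trs, OB, TT))
      bump("adults", d_obs, d_rep)
    }
  }

  rows <- names(acc)[vapply(acc, function(a) a[2] > 0, logical(1))]
  data.frame(
    submodel = rows,
    p_value = vapply(rows, function(nm) acc[[nm]][1] / acc[[nm]][2], numeric(1)),
    d_obs_mean = vapply(rows, function(nm) dsum[[nm]][1] / acc[[nm]][2], numeric(1)),
    d_rep_mean = vapply(rows, function(nm) dsum[[nm]][2] / acc[[nm]][2], numeric(1)),
    row.names = NULL
  )
}

# internal: flattened per-year transition matrices for the C++ forward pass
tr_flat <- function(params_yearly) {
  TT <- length(params_yearly)
  trs <- numeric((TT - 1) * 81)
  for (t in seq_len(TT - 1)) {
    M <- adult_transition_matrix(params_yearly[[t]], params_yearly[[t + 1]])
    trs[(t - 1) * 81 + seq_len(81)] <- as.numeric(t(M))  # row-major
  }
  trs
}

# internal: simulate replicate adult multi-event histories
simulate_adult_events <- function(fc0, st00, pars, TT) {
  n <- length(fc0)
  ev <- matrix(0L, n, TT)
  z <- rep(9L, n)  # 1..8 live, 9 dead
  state <- st00 + 1L
  OB <- adult_observation_matrix(pars[[1]]$p, pars[[1]]$c)
  TRs <- lapply(seq_len(TT - 1), function(t)
    adult_transition_matrix(pars[[t]], pars[[t + 1]]))
  alive_from <- fc0 + 1L  # 0-based first year -> 1-based
  zz <- state
  for (t in seq_len(TT)) {
    started <- alive_from < t       # transitions happen after first year
    if (any(started)) {
      znew <- zz
      for (s in 1:9) {
        idx <- which(started & zz == s & t > 1)
        if (!length(idx)) next
        # move from year t-1 to t
        pr <- TRs[[t - 1]][s, ]
        znew[idx] <- sample.int(9, length(idx), replace = TRUE, prob = pr)
      }
      zz <- znew
      idx <- which(started)
      for (s in sort(unique(zz[idx]))) {
        ii <- idx[zz[idx] == s]
        pr <- OB[s, ]
        ev[cbind(ii, t)] <- sample.int(7, length(ii), replace = TRUE, prob = pr) - 1L
      }
    }
  }
  ev
}

# internal: rebuild per-year annual_params from one posterior draw;
# final-year survival/recruitment (not identified by any transition)
# repeats the last interval's values.
params_from_draw <- function(fit, draw, chain) {
  TT <- fit$years
  g <- function(bl) {
    x <- draws_block(fit, bl)
    if (length(dim(x)) == 4) x[draw, chain, , ] else
      if (length(dim(x)) == 3) x[draw, chain, ] else x[draw, chain]
  }
  b <- g("b"); fled <- g("fled")
  ps <- g("phi_succ"); pf <- g("phi_fail"); pfl <- g("phi_fl")
  sw_s <- g("psi_succ_sw"); sw_f <- g("psi_fail_sw"); sw_fl <- g("psi_fl_sw")
  p <- g("p"); cc <- g("c")
  mk_psi <- function(sw) matrix(c(1 - sw[1], sw[2], sw[1], 1 - sw[2]), 2, 2)
  lapply(seq_len(TT), function(t) {
    tp <- min(t, TT - 1)
    annual_params(
      b = matrix(c(b[1, t], b[3, t], b[2, t], b[4, t]), 2, 2),
      fled = matrix(c(fled[1, t], fled[3, t], fled[2, t], fled[4, t]), 2, 2),
      phi_fl = pfl[, tp],
      phi_succ = matrix(c(ps[1, tp], ps[3, tp], ps[2, tp], ps[4, tp]), 2, 2),
      phi_fail = matrix(c(pf[1, tp], pf[3, tp], pf[2, tp], pf[4, tp]), 2, 2),
      psi_fl = mk_psi(sw_fl), psi_succ = mk_psi(sw_s), psi_fail = mk_psi(sw_f),
      p = p, c = cc
    )
  })
}
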