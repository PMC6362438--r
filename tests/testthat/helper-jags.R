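# Independent-oracle fit of the identical IPM in JAGS (latent-state
# formulation, no marginalisation), used to cross-check the package's
# sampler on small datasets. Class order and priors match the package.

jags_ipm_model <- "
model {
  for (k in 1:4) {
    mub[k] ~ dnorm(0, 0.001);  sdb[k] ~ dunif(0, 10)
    muf[k] ~ dnorm(0, 0.001);  sdf[k] ~ dunif(0, 10)
    mups[k] ~ dnorm(0, 0.001); sdps[k] ~ dunif(0, 10)
    mupf[k] ~ dnorm(0, 0.001); sdpf[k] ~ dunif(0, 10)
    taub[k] <- pow(sdb[k], -2);  tauf[k] <- pow(sdf[k], -2)
    taups[k] <- pow(sdps[k], -2); taupf[k] <- pow(sdpf[k], -2)
  }
  for (h in 1:2) {
    mupfl[h] ~ dnorm(0, 0.001); sdpfl[h] ~ dunif(0, 10)
    taupfl[h] <- pow(sdpfl[h], -2)
    lpsi_s[h] ~ dnorm(0, 0.001); psw_s[h] <- ilogit(lpsi_s[h])
    lpsi_f[h] ~ dnorm(0, 0.001); psw_f[h] <- ilogit(lpsi_f[h])
    lpsi_fl[h] ~ dnorm(0, 0.001); psw_fl[h] <- ilogit(lpsi_fl[h])
  }
  p ~ dunif(0, 1)
  cc ~ dunif(0, 1)
  for (k in 1:4) {
    for (t in 1:TT) {
      xb[k, t] ~ dnorm(mub[k], taub[k]);  b[k, t] <- ilogit(xb[k, t])
      xf[k, t] ~ dnorm(muf[k], tauf[k]);  fled[k, t] <- exp(xf[k, t])
    }
    for (t in 1:(TT - 1)) {
      xps[k, t] ~ dnorm(mups[k], taups[k]); ps[k, t] <- ilogit(xps[k, t])
      xpf[k, t] ~ dnorm(mupf[k], taupf[k]); pf[k, t] <- ilogit(xpf[k, t])
    }
  }
  for (h in 1:2) { for (t in 1:(TT - 1)) {
    xpfl[h, t] ~ dnorm(mupfl[h], taupfl[h]); pfl[h, t] <- ilogit(xpfl[h, t])
  } }

  # breeding trials and fledgling counts (rows with data only)
  for (i in 1:nbr) { Bv[i] ~ dbin(b[kb[i], tb[i]], Rv[i]) }
  for (i in 1:nfl) { Dv[i] ~ dpois(Sv[i] * (2 * fled[kf[i], tf[i]] - 1) + 1.0E-10) }

  # juvenile recruitment (multinomial per natal habitat and cohort)
  for (i in 1:njv) {
    prj[i, 1] <- pfl[hj[i], tj[i]] *
      (equals(hj[i], 1) * (1 - psw_fl[1]) + equals(hj[i], 2) * psw_fl[2]) * p
    prj[i, 2] <- pfl[hj[i], tj[i]] *
      (equals(hj[i], 1) * psw_fl[1] + equals(hj[i], 2) * (1 - psw_fl[2])) * p
    prj[i, 3] <- 1 - pfl[hj[i], tj[i]] * p
    Jm[i, 1:3] ~ dmulti(prj[i, 1:3], Jn[i])
  }

  # adult multi-event state and observation processes
  for (a in 1:2) { for (h in 1:2) { for (s in 1:2) {
    swx[(a-1)*4 + (h-1)*2 + s] <- equals(s,1)*psw_s[h] + equals(s,2)*psw_f[h]
  } } }
  for (t in 1:(TT - 1)) {
    for (a in 1:2) { for (h in 1:2) { for (s in 1:2) {
      phx[t, (a-1)*4 + (h-1)*2 + s] <-
        equals(s,1) * ps[(a-1)*2 + h, t] + equals(s,2) * pf[(a-1)*2 + h, t]
      for (h2 in 1:2) {
        TR[t, (a-1)*4 + (h-1)*2 + s, 4 + (h2-1)*2 + 1] <-
          phx[t, (a-1)*4 + (h-1)*2 + s] *
          (equals(h,h2) * (1 - swx[(a-1)*4 + (h-1)*2 + s]) +
           (1 - equals(h,h2)) * swx[(a-1)*4 + (h-1)*2 + s]) *
          b[2 + h2, t + 1]
        TR[t, (a-1)*4 + (h-1)*2 + s, 4 + (h2-1)*2 + 2] <-
          phx[t, (a-1)*4 + (h-1)*2 + s] *
          (equals(h,h2) * (1 - swx[(a-1)*4 + (h-1)*2 + s]) +
           (1 - equals(h,h2)) * swx[(a-1)*4 + (h-1)*2 + s]) *
          (1 - b[2 + h2, t + 1])
      }
      for (s2 in 1:4) { TR[t, (a-1)*4 + (h-1)*2 + s, s2] <- 0 }
      TR[t, (a-1)*4 + (h-1)*2 + s, 9] <- 1 - phx[t, (a-1)*4 + (h-1)*2 + s]
    } } }
    for (s2 in 1:8) { TR[t, 9, s2] <- 0 }
    TR[t, 9, 9] <- 1
  }
  for (s in 1:8) {
    for (e in 1:7) {
      OB[s, e] <- (1 - p) * equals(e, 1) + p * cc * OBknown[s, e] +
        p * (1 - cc) * OBunk[s, e]
    }
  }
  for (e in 2:7) { OB[9, e] <- 0 }
  OB[9, 1] <- 1
  for (i in 1:nind) {
    for (t in (fc[i] + 1):TT) {
      z[i, t] ~ dcat(TR[t - 1, z[i, t - 1], 1:9])
      eve[i, t] ~ dcat(OB[z[i, t], 1:7])
    }
  }

  # count state-space process
  for (k in 1:4) {
    lam1[k] ~ dnorm(y1[k], 0.01) T(0,)
    NB1s[k] ~ dpois(lam1[k])
    NB[k, 1] <- NB1s[k]
  }
  for (t in 1:(TT - 1)) {
    for (k in 1:4) {
      succ[k, t] ~ dbin(b[k, t], NB[k, t])
      svS[k, t] ~ dbin(ps[k, t], succ[k, t])
      svF[k, t] ~ dbin(pf[k, t], NB[k, t] - succ[k, t])
      mvS[k, t] ~ dbin(psw_s[hab[k]], svS[k, t])
      mvF[k, t] ~ dbin(psw_f[hab[k]], svF[k, t])
      M[k, t] ~ dunif(-5, 20)
      Im[k, t] ~ dpois(max(M[k, t], 1.0E-10))
    }
    for (h2 in 1:2) {
      rrate[h2, t] <-
        NB[1,t]*b[1,t]*fled[1,t]*pfl[1,t]*(equals(1,h2)*(1-psw_fl[1]) + (1-equals(1,h2))*psw_fl[1]) +
        NB[2,t]*b[2,t]*fled[2,t]*pfl[2,t]*(equals(2,h2)*(1-psw_fl[2]) + (1-equals(2,h2))*psw_fl[2]) +
        NB[3,t]*b[3,t]*fled[3,t]*pfl[1,t]*(equals(1,h2)*(1-psw_fl[1]) + (1-equals(1,h2))*psw_fl[1]) +
        NB[4,t]*b[4,t]*fled[4,t]*pfl[2,t]*(equals(2,h2)*(1-psw_fl[2]) + (1-equals(2,h2))*psw_fl[2])
      recY[h2, t] ~ dpois(rrate[h2, t] + 1.0E-10)
      NB[h2, t + 1] <- recY[h2, t] + Im[h2, t]
    }
    NB[3, t + 1] <- svS[1,t] + svF[1,t] - mvS[1,t] - mvF[1,t] +
      svS[3,t] + svF[3,t] - mvS[3,t] - mvF[3,t] +
      mvS[2,t] + mvF[2,t] + mvS[4,t] + mvF[4,t] + Im[3, t]
    NB[4, t + 1] <- svS[2,t] + svF[2,t] - mvS[2,t] - mvF[2,t] +
      svS[4,t] + svF[4,t] - mvS[4,t] - mvF[4,t] +
      mvS[1,t] + mvF[1,t] + mvS[3,t] + mvF[3,t] + Im[4, t]
  }
  for (k in 1:4) { for (t in 1:TT) { y[k, t] ~ dpois(NB[k, t] + 1.0E-10) } }
}
"

# assemble the JAGS data list from an ipm_dataset
jags_ipm_data <- function(dataset) {
  TT <- dataset$years
  br <- dataset$breeding[dataset$breeding$R > 0, ]
  fl <- dataset$fledglings[dataset$fledglings$S > 0, ]
  jh <- dataset$juvenile_histories
  jrows <- list()
  for (t in sort(unique(jh$cohort))) for (h in 1:2) {
    sel <- jh$cohort == t & jh$natal == h
    if (!any(sel)) next
    jrows[[length(jrows) + 1]] <- c(h, t, sum(jh$event[sel] == 1),
                                    sum(jh$event[sel] == 2),
                                    sum(jh$event[sel] == 0))
  }
  jm <- do.call(rbind, jrows)
  ah <- dataset$adult_histories
  keep <- ah$first < TT
  fc <- ah$first[keep]
  ev <- ah$events[keep, , drop = FALSE]
  eve <- matrix(NA_integer_, nrow(ev), TT)
  for (i in seq_len(nrow(ev)))
    if (fc[i] < TT) eve[i, (fc[i] + 1):TT] <- ev[i, (fc[i] + 1):TT] + 1L
  zdat <- matrix(NA_integer_, nrow(ev), TT)
  zdat[cbind(seq_len(nrow(ev)), fc)] <- ah$state[keep]
  OBknown <- matrix(0, 8, 7); OBunk <- matrix(0, 8, 7)
  for (s in 1:8) {
    h <- ((s - 1) %/% 2) %% 2 + 1
    su <- (s - 1) %% 2            # 0 succ, 1 fail
    OBknown[s, 1 + (h - 1) * 3 + su + 1] <- 1
    OBunk[s, 1 + (h - 1) * 3 + 3] <- 1
  }
  list(
    TT = TT,
    nbr = nrow(br), kb = (br$age - 1L) * 2L + br$hab, tb = br$year,
    Rv = br$R, Bv = br$B,
    nfl = nrow(fl), kf = (fl$age - 1L) * 2L + fl$hab, tf = fl$year,
    Sv = fl$S, Dv = fl$F - fl$S,
    njv = nrow(jm), hj = jm[, 1], tj = jm[, 2],
    Jm = jm[, 3:5, drop = FALSE], Jn = rowSums(jm[, 3:5, drop = FALSE]),
    nind = nrow(ev), fc = fc, eve = eve, z = zdat,
    OBknown = OBknown, OBunk = OBunk,
    hab = c(1, 2, 1, 2),
    y = matrix(as.integer(dataset$counts), 4, TT),
    y1 = as.integer(dataset$counts[, 1])
  )
}

# feasible initial values (same construction idea as the package's)
jags_ipm_inits <- function(jd, seed) {
  set.seed(seed)
  TT <- jd$TT
  z <- jd$z
  for (i in seq_len(jd$nind)) {
    f <- jd$fc[i]
    seen <- which(!is.na(jd$eve[i, ]) & jd$eve[i, ] > 1)
    last <- if (length(seen)) max(seen) else f
    for (t in (f + 1):TT) {
      if (t <= last) {
        e <- jd$eve[i, t]
        h <- if (e %in% c(2, 3, 4)) 1 else if (e %in% c(5, 6, 7)) 2 else
          ((z[i, t - 1] - 1) %/% 2) %% 2 + 1
        su <- if (e %in% c(2, 5)) 0 else 1
        z[i, t] <- 4 + (h - 1) * 2 + su + 1
      } else z[i, t] <- 9
    }
  }
  z[!is.na(jd$z)] <- NA  # data slots must stay NA in inits
  y <- jd$y
  NB1 <- pmax(y[, 1], 1L)
  succ <- svS <- svF <- mvS <- mvF <- matrix(0L, 4, TT - 1)
  recY <- matrix(0L, 2, TT - 1)
  Im <- matrix(0L, 4, TT - 1)
  NB <- matrix(0L, 4, TT); NB[, 1] <- NB1
  for (t in seq_len(TT - 1)) {
    succ[, t] <- rbinom(4, NB[, t], 0.7)
    svS[, t] <- rbinom(4, succ[, t], 0.5)
    svF[, t] <- rbinom(4, NB[, t] - succ[, t], 0.4)
    mvS[, t] <- rbinom(4, svS[, t], 0.2)
    mvF[, t] <- rbinom(4, svF[, t], 0.2)
    recY[, t] <- rpois(2, 3)
    stay <- svS[, t] + svF[, t] - mvS[, t] - mvF[, t]
    mv <- mvS[, t] + mvF[, t]
    local <- c(recY[1, t], recY[2, t],
               stay[1] + stay[3] + mv[2] + mv[4],
               stay[2] + stay[4] + mv[1] + mv[3])
    Im[, t] <- pmax(pmax(y[, t + 1], 1L) - local, 0L)
    NB[, t + 1] <- local + Im[, t]
  }
  list(
    mub = rnorm(4, 0.8, 0.1), muf = rnorm(4, 0.3, 0.05),
    mups = rnorm(4, -0.2, 0.1), mupf = rnorm(4, -0.4, 0.1),
    mupfl = rnorm(2, -2.3, 0.1),
    sdb = runif(4, 0.2, 0.4), sdf = runif(4, 0.05, 0.15),
    sdps = runif(4, 0.2, 0.4), sdpf = runif(4, 0.2, 0.4),
    sdpfl = runif(2, 0.2, 0.5),
    lpsi_s = rnorm(2, -1.5, 0.2), lpsi_f = rnorm(2, -1, 0.2),
    lpsi_fl = rnorm(2, -1, 0.2),
    p = runif(1, 0.7, 0.95), cc = runif(1, 0.8, 0.95),
    z = z, lam1 = NB1 + 0.5,
    succ = succ, svS = svS, svF = svF, mvS = mvS, mvF = mvF,
    recY = recY, Im = Im, M = matrix(runif(4 * (TT - 1), 2, 6), 4, TT - 1),
    .RNG.name = "base::Mersenne-Twister", .RNG.seed = seed
  )
}

# run the oracle and return posterior means of headline quantities
run_jags_oracle <- function(dataset, n_adapt = 1000, n_burn = 1000,
                            n_iter = 4000, chains = 2, seed = 1) {
  jd <- jags_ipm_data(dataset)
  inits <- lapply(seq_len(chains), function(j) jags_ipm_inits(jd, seed + j))
  for (j in seq_len(chains)) inits[[j]]$NB1s <- pmax(jd$y[, 1], 1L)
  m <- rjags::jags.model(textConnection(jags_ipm_model), data = jd,
                         inits = inits, n.chains = chains,
                         n.adapt = n_adapt, quiet = TRUE)
  stats::update(m, n_burn, progress.bar = "none")
  samp <- rjags::coda.samples(m, c("b", "fled", "ps", "pf", "pfl",
                                   "psw_s", "psw_f", "psw_fl", "p", "cc",
                                   "NB", "Im"),
                              n.iter = n_iter, thin = 2,
                              progress.bar = "none")
  mat <- do.call(rbind, lapply(samp, as.matrix))
  colMeans(mat)
}

# helper: across-year mean of a k-by-time JAGS block from named means
jags_block_mean <- function(means, name, k, times) {
  vals <- vapply(times, function(t) means[sprintf("%s[%d,%d]", name, k, t)],
                 numeric(1))
  mean(vals)
}
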