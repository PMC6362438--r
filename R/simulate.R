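#' Simulation configuration
#'
#' Defines the study conditions emulated by the individual-based
#' simulator: number of years, mean vital rates, link-scale temporal
#' standard deviations (logit for probabilities, log for fledgling
#' numbers and immigration means), expected immigrant numbers per
#' class-year, initial class counts, and the monitoring/marking
#' protocol. Defaults mirror the 24-year study population: about 90
#' occupied territories, Table-style vital-rate means, and an apparent
#' immigration rate near 0.45 of the population.
#'
#' @param years number of breeding seasons (>= 3).
#' @param mean_params an [annual_params()] object with across-year mean
#'   vital rates (on the natural scale).
#' @param sd_b,sd_phi_succ,sd_phi_fail 2x2 matrices of logit-scale
#'   temporal SDs (age by habitat).
#' @param sd_fled 2x2 matrix of log-scale temporal SDs.
#' @param sd_phi_fl length-2 logit-scale temporal SDs by natal habitat.
#' @param imm_mean length-4 expected immigrants per class-year, class
#'   order [class_order()].
#' @param imm_sd_log log-scale temporal SD of the immigration means
#'   (year-specific immigration pressure).
#' @param init_nb length-4 initial breeder counts.
#' @param monitor_frac_success share of breeder-years whose breeding
#'   success is determined (enters the breeding-trial table).
#' @param monitor_frac_fled share of successful monitored sites whose
#'   exact fledgling number is known.
#' @param mark_frac_new probability that a previously unringed breeder
#'   (initial cohort or immigrant) is colour-ringed at first detection.
#' @param juv_mark_frac share of modelled-sex fledglings ringed.
#' @param count_exact if `TRUE` the count table reports the true class
#'   counts (perfect-observation limit) instead of Poisson-noised counts.
#' @param seed master seed for the simulation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(years = 24,
                       mean_params = default_params(),
                       sd_b = matrix(c(0.30, 0.35, 0.30, 0.50), 2, 2),
                       sd_fled = matrix(c(0.05, 0.02, 0.07, 0.04), 2, 2),
                       sd_phi_fl = c(0.50, 0.27),
                       sd_phi_succ = matrix(0.25, 2, 2),
                       sd_phi_fail = matrix(c(0.55, 0.54, 0.63, 0.46), 2, 2),
                       imm_mean = c(13, 8.5, 10, 7.5),
                       imm_sd_log = 0.7,
                       init_nb = c(18, 14, 36, 20),
                       monitor_frac_success = 0.91,
                       monitor_frac_fled = 0.55,
                       mark_frac_new = 1.0,
                       juv_mark_frac = 1.0,
                       count_exact = FALSE,
                       seed = 20190205) {
  stopifnot(years >= 3)
  fr <- c(monitor_frac_success, monitor_frac_fled, mark_frac_new, juv_mark_frac)
  if (any(fr < 0 | fr > 1)) stop("monitoring/marking fractions must lie in [0,1]")
  sds <- c(sd_b, sd_fled, sd_phi_fl, sd_phi_succ, sd_phi_fail, imm_sd_log)
  if (any(sds < 0)) stop("temporal SDs must be non-negative")
  validate_annual_params(mean_params)
  structure(list(
    years = as.integer(years), mean_params = mean_params,
    sd_b = sd_b, sd_fled = sd_fled, sd_phi_fl = sd_phi_fl,
    sd_phi_succ = sd_phi_succ, sd_phi_fail = sd_phi_fail,
    imm_mean = setNames(as.numeric(imm_mean), CLASS_ORDER),
    imm_sd_log = imm_sd_log,
    init_nb = setNames(as.numeric(init_nb), CLASS_ORDER),
    monitor_frac_success = monitor_frac_success,
    monitor_frac_fled = monitor_frac_fled,
    mark_frac_new = mark_frac_new, juv_mark_frac = juv_mark_frac,
    count_exact = count_exact, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Draw year-specific parameter realisations
#'
#' Adds independent normal year effects on the link scale (logit for
#' probabilities, log for fledgling numbers) around the configured
#' means; transition probabilities, detection and state certainty stay
#' constant across years. Immigration means get log-normal year effects.
#'
#' @param config a [sim_config()].
#' @return A list with `params` (list of `years` [annual_params()]
#'   objects) and `imm_mean` (4 x years matrix of immigration means).
#' @export
draw_year_effects <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mp <- config$mean_params
  TT <- config$years
  per_year <- vector("list", TT)
  ab <- function(mean_mat, sd_mat) {
    matrix(plogis(qlogis(mean_mat) + rnorm(4) * sd_mat), 2, 2,
           dimnames = dimnames(mean_mat))
  }
  for (t in seq_len(TT)) {
    per_year[[t]] <- annual_params(
      b = ab(mp$b, config$sd_b),
      fled = pmax(exp(log(mp$fled) + rnorm(4) * config$sd_fled), 0.5),
      phi_fl = plogis(qlogis(mp$phi_fl) + rnorm(2) * config$sd_phi_fl),
      phi_succ = ab(mp$phi_succ, config$sd_phi_succ),
      phi_fail = ab(mp$phi_fail, config$sd_phi_fail),
      psi_fl = mp$psi_fl, psi_succ = mp$psi_succ, psi_fail = mp$psi_fail,
      omega = mp$omega, p = mp$p, c = mp$c
    )
  }
  imm <- matrix(exp(log(pmax(config$imm_mean, 1e-12)) +
                      rnorm(4 * TT) * config$imm_sd_log),
                4, TT, dimnames = list(CLASS_ORDER, NULL))
  imm[config$imm_mean == 0, ] <- 0
  list(params = per_year, imm_mean = imm)
}

#' Simulate the true population process
#'
#' Individual-based forward simulation of the four-class breeding
#' population with demographic stochasticity: per-breeder Bernoulli
#' breeding success, per-brood fledgling numbers `1 + Poisson(2 fled - 1)`
#' split to the modelled sex by a fair binomial, Bernoulli recruitment
#' and survival, success-conditional habitat movement, deterministic
#' ageing Young -> Old, and Poisson immigration per class.
#'
#' @param config a [sim_config()].
#' @param effects optional result of [draw_year_effects()] (drawn
#'   internally when omitted).
#' @return A list of class `sim_truth`; see Details.
#' @details The returned truth bundle contains the realized annual
#'   parameters, the class-count trajectory `nb` (4 x years), immigrant
#'   numbers `im`, per-year arrival decomposition (`recruits_in`,
#'   `survivors_in`), an adult individual table with per-year class and
#'   success states, a juvenile cohort table, and per-breeder-year brood
#'   records. Extinction is flagged (`extinct`), not an error.
#' @export
simulate_population <- function(config, effects = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(effects)) effects <- draw_year_effects(config)
  pars <- effects$params
  TT <- config$years

  nb <- matrix(0L, 4, TT, dimnames = list(CLASS_ORDER, NULL))
  im <- matrix(0L, 4, TT, dimnames = list(CLASS_ORDER, NULL))
  recruits_in <- matrix(0L, 4, TT, dimnames = list(CLASS_ORDER, NULL))
  survivors_in <- matrix(0L, 4, TT, dimnames = list(CLASS_ORDER, NULL))

  # adult individual pool (grows over time)
  n0 <- sum(config$init_nb)
  cap <- n0 + as.integer(sum(config$imm_mean) * TT * 3 + 200) + 50L
  id_entry <- integer(0); id_origin <- character(0)
  # per-year adult state: 0 absent/dead, 1..4 class; success NA/0/1
  st <- matrix(0L, 0, TT); su <- matrix(NA_integer_, 0, TT)
  natal_hab <- integer(0)  # 0 for non-local adults, 1/2 for local recruits

  add_adults <- function(n, cls, year, origin, natal = 0L) {
    if (n == 0) return(invisible(NULL))
    id_entry <<- c(id_entry, rep.int(year, n))
    id_origin <<- c(id_origin, rep.int(origin, n))
    natal_hab <<- c(natal_hab, rep.int(natal, n))
    st <<- rbind(st, matrix(0L, n, TT))
    su <<- rbind(su, matrix(NA_integer_, n, TT))
    st[seq.int(nrow(st) - n + 1, nrow(st)), year] <<- cls
    invisible(NULL)
  }
  for (k in seq_len(4)) add_adults(config$init_nb[k], k, 1L, "initial")

  # brood records: one row per breeder-year (filled as we go)
  broods <- vector("list", TT)
  # juvenile cohorts: one row per modelled-sex fledgling
  juv <- vector("list", TT)

  for (t in seq_len(TT)) {
    p_t <- pars[[t]]
    alive <- which(st[, t] > 0L)
    if (length(alive) == 0L) {
      # local extinction this year: no broods, but immigration continues
      broods[[t]] <- data.frame(id = integer(0), year = integer(0),
                                age = integer(0), hab = integer(0),
                                success = integer(0), fled_total = integer(0),
                                fled_male = integer(0))
      if (t < TT) {
        juv[[t]] <- data.frame(cohort = integer(0), natal = integer(0),
                               recruited = integer(0), dest = integer(0))
        n_im <- rpois(4, pmax(effects$imm_mean[, t + 1L], 0))
        im[, t + 1L] <- n_im
        for (k in seq_len(4)) add_adults(n_im[k], k, t + 1L, "immigrant")
      }
      next
    }
    cls <- st[alive, t]
    age <- (cls > 2L) + 1L           # 1 = Y, 2 = O
    hab <- ((cls - 1L) %% 2L) + 1L   # 1 = S, 2 = T
    nb[, t] <- tabulate(cls, 4L)

    # breeding success
    bvec <- p_t$b[cbind(age, hab)]
    succ <- rbinom(length(alive), 1L, bvec)
    su[alive, t] <- succ

    # broods: total fledglings ~ 1 + Pois(2 fled - 1), males ~ Bin(total, 1/2)
    fl_tot <- integer(length(alive)); fl_m <- integer(length(alive))
    is_succ <- succ == 1L
    if (any(is_succ)) {
      rate <- 2 * p_t$fled[cbind(age[is_succ], hab[is_succ])] - 1
      fl_tot[is_succ] <- 1L + rpois(sum(is_succ), pmax(rate, 0))
      fl_m[is_succ] <- rbinom(sum(is_succ), fl_tot[is_succ], 0.5)
    }
    broods[[t]] <- data.frame(
      id = alive, year = t, age = age, hab = hab,
      success = succ, fled_total = fl_tot, fled_male = fl_m
    )

    if (t < TT) {
      # juvenile fates: recruit with phi_fl[natal], settle via psi_fl
      nat <- rep.int(hab[is_succ], fl_m[is_succ])
      n_juv <- length(nat)
      if (n_juv > 0) {
        rec <- rbinom(n_juv, 1L, p_t$phi_fl[nat]) == 1L
        dest <- integer(n_juv)
        dest[rec] <- 1L + (runif(sum(rec)) < p_t$psi_fl[cbind(nat[rec], 2L)])
        juv[[t]] <- data.frame(cohort = t, natal = nat,
                               recruited = as.integer(rec), dest = dest)
        # recruits enter next year's Young classes
        for (h2 in 1:2) {
          kk <- which(rec & dest == h2)
          recruits_in[h2, t + 1L] <- length(kk)
          add_adults(length(kk), h2, t + 1L, "recruit", natal = 0L)
          # record natal habitat of those recruit rows
          if (length(kk)) {
            rows <- seq.int(nrow(st) - length(kk) + 1L, nrow(st))
            natal_hab[rows] <- nat[kk]
          }
        }
      } else {
        juv[[t]] <- data.frame(cohort = integer(0), natal = integer(0),
                               recruited = integer(0), dest = integer(0))
      }

      # adult survival + movement, conditional on success
      phi <- ifelse(succ == 1L, p_t$phi_succ[cbind(age, hab)],
                    p_t$phi_fail[cbind(age, hab)])
      surv <- rbinom(length(alive), 1L, phi) == 1L
      if (any(surv)) {
        psw <- ifelse(succ[surv] == 1L,
                      p_t$psi_succ[cbind(hab[surv], 2L)] * (hab[surv] == 1L) +
                        p_t$psi_succ[cbind(hab[surv], 1L)] * (hab[surv] == 2L),
                      p_t$psi_fail[cbind(hab[surv], 2L)] * (hab[surv] == 1L) +
                        p_t$psi_fail[cbind(hab[surv], 1L)] * (hab[surv] == 2L))
        moved <- runif(sum(surv)) < psw
        h_new <- ifelse(moved, 3L - hab[surv], hab[surv])
        cls_new <- 2L + h_new  # all survivors are Old next year
        st[cbind(alive[surv], t + 1L)] <- cls_new
        survivors_in[, t + 1L] <- survivors_in[, t + 1L] + tabulate(cls_new, 4L)
      }

      # immigration
      n_im <- rpois(4, pmax(effects$imm_mean[, t + 1L], 0))
      im[, t + 1L] <- n_im
      for (k in seq_len(4)) add_adults(n_im[k], k, t + 1L, "immigrant")
    }
  }
  im[, 1L] <- 0L  # initial breeders are not counted as immigrants

  structure(list(
    config = config, params = pars, imm_mean = effects$imm_mean,
    nb = nb, im = im, recruits_in = recruits_in, survivors_in = survivors_in,
    adults = data.frame(id = seq_along(id_entry), entry = id_entry,
                        origin = id_origin, natal = natal_hab),
    state = st, success = su,
    broods = do.call(rbind, broods), juveniles = do.call(rbind, juv),
    extinct = any(colSums(nb) == 0)
  ), class = "sim_truth")
}

#' Realized habitat productivity from truth records
#'
#' For each year pair and habitat: modelled-sex recruits produced by
#' broods of that habitat that entered the breeding population the next
#' year, plus adults of that habitat apparently surviving to the next
#' year, divided by breeders in that habitat.
#'
#' @param truth a `sim_truth` object.
#' @return A (years-1) x 2 matrix of productivities (columns S, T).
#' @export
truth_productivity <- function(truth) {
  TT <- truth$config$years
  out <- matrix(NA_real_, TT - 1, 2, dimnames = list(NULL, HABITATS))
  st <- truth$state
  for (t in seq_len(TT - 1)) {
    jv <- truth$juveniles[truth$juveniles$cohort == t, ]
    alive_next <- st[, t + 1] > 0
    for (h in 1:2) {
      n_h <- sum(truth$nb[c(h, h + 2), t])
      if (n_h == 0) next
      rec_h <- sum(jv$recruited[jv$natal == h])
      from_h <- st[, t] %in% c(h, h + 2)
      surv_h <- sum(from_h & alive_next)
      out[t, h] <- habitat_productivity(rec_h, surv_h, n_h)
    }
  }
  out
}

#' Observe a simulated population
#'
#' Generates the four observed data streams from a truth simulation:
#' breeding-success trials (monitored subsample), fledgling counts at
#' successful sites with known brood size, adult multi-event
#' mark-resight histories (detection `p`, state certainty `c`),
#' single-occasion juvenile recruitment resightings, and Poisson-noised
#' class counts.
#'
#' @param truth a `sim_truth` from [simulate_population()].
#' @param config the [sim_config()] used (defaults to `truth$config`).
#' @return A list of class `ipm_dataset` with elements `breeding`,
#'   `fledglings`, `adult_histories`, `juvenile_histories`, `counts`,
#'   and `years`.
#' @export
observe_dataset <- function(truth, config = truth$config) {
  TT <- config$years
  pars <- truth$params
  p <- config$mean_params$p; cc <- config$mean_params$c

  # --- breeding success and fledgling tables -------------------------
  br <- truth$broods
  monitored <- runif(nrow(br)) < config$monitor_frac_success
  brm <- br[monitored, ]
  breeding <- aggregate_table(brm, TT, count = "success")
  fl_known <- brm$success == 1L & runif(nrow(brm)) < config$monitor_frac_fled
  brf <- brm[fl_known, ]
  fled_tab <- aggregate_fled(brf, TT)

  # --- adult multi-event histories -----------------------------------
  ad <- truth$adults
  st <- truth$state; su <- truth$success
  new_mark <- ad$origin %in% c("initial", "immigrant") &
    runif(nrow(ad)) < config$mark_frac_new
  rec_mark <- ad$origin == "recruit"   # local recruits carry rings
  marked <- new_mark | rec_mark
  idx <- which(marked & ad$entry < TT) # a first-capture-only history is uninformative
  n_m <- length(idx)
  ev <- matrix(NA_integer_, n_m, TT)
  fc <- integer(n_m); fc_state <- integer(n_m)
  for (i in seq_len(n_m)) {
    id <- ad$id[idx[i]]
    f <- ad$entry[idx[i]]
    fc[i] <- f
    cls <- st[id, f]
    fc_state[i] <- cmr_state(cls, su[id, f])
    if (f < TT) for (t in seq.int(f + 1L, TT)) {
      cls_t <- st[id, t]
      if (cls_t == 0L) { ev[i, t] <- 0L; next }
      if (runif(1) > p) { ev[i, t] <- 0L; next }
      h <- ((cls_t - 1L) %% 2L) + 1L
      if (runif(1) < cc) ev[i, t] <- (h - 1L) * 3L + ifelse(su[id, t] == 1L, 1L, 2L)
      else ev[i, t] <- (h - 1L) * 3L + 3L
    }
  }
  adult_histories <- list(first = fc, state = fc_state, events = ev)

  # --- juvenile single-occasion histories ----------------------------
  jv <- truth$juveniles
  jm <- jv[runif(nrow(jv)) < config$juv_mark_frac, ]
  seen <- jm$recruited == 1L & runif(nrow(jm)) < p
  jev <- ifelse(seen, jm$dest, 0L)
  juvenile_histories <- data.frame(cohort = jm$cohort, natal = jm$natal,
                                   event = jev)

  # --- counts --------------------------------------------------------
  y <- truth$nb
  if (!config$count_exact) {
    y <- matrix(rpois(length(y), as.numeric(truth$nb)), 4, TT,
                dimnames = dimnames(truth$nb))
  }
  counts <- y

  structure(list(breeding = breeding, fledglings = fled_tab,
                 adult_histories = adult_histories,
                 juvenile_histories = juvenile_histories,
                 counts = counts, years = TT),
            class = "ipm_dataset")
}

# CMR state index from class (1..4) and success (0/1):
# 1 Y_S_succ, 2 Y_S_fail, 3 Y_T_succ, 4 Y_T_fail,
# 5 O_S_succ, 6 O_S_fail, 7 O_T_succ, 8 O_T_fail, 9 dead.
cmr_state <- function(cls, success) {
  age <- (cls > 2L) + 1L
  hab <- ((cls - 1L) %% 2L) + 1L
  (age - 1L) * 4L + (hab - 1L) * 2L + ifelse(success == 1L, 1L, 2L)
}

aggregate_table <- function(df, TT, count = "success") {
  out <- expand.grid(year = seq_len(TT), age = 1:2, hab = 1:2)
  key <- with(df, paste(year, age, hab))
  okey <- with(out, paste(year, age, hab))
  out$R <- as.integer(table(factor(key, levels = okey)))
  s <- tapply(df[[count]], factor(key, levels = okey), sum)
  out$B <- as.integer(ifelse(is.na(s), 0L, s))
  out
}

aggregate_fled <- function(df, TT) {
  out <- expand.grid(year = seq_len(TT), age = 1:2, hab = 1:2)
  key <- with(df, paste(year, age, hab))
  okey <- with(out, paste(year, age, hab))
  out$S <- as.integer(table(factor(key, levels = okey)))
  f <- tapply(df$fled_total, factor(key, levels = okey), sum)
  out$F <- as.integer(ifelse(is.na(f), 0L, f))
  out
}

#' Simulate a full dataset (truth + observations)
#'
#' Convenience wrapper: seeds the RNG from the config, draws year
#' effects, simulates the population and observes it.
#'
#' @param config a [sim_config()].
#' @return A list with `truth` (class `sim_truth`) and `observed`
#'   (class `ipm_dataset`).
#' @export
simulate_ipm_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  truth <- simulate_population(config)
  observed <- observe_dataset(truth, config)
  list(truth = truth, observed = observed)
}

#' Even-sex-ratio assignment of unsexed marked juveniles
#'
#' Nestlings never resighted cannot be sexed; they are randomly
#' attributed a sex so that the sex ratio among all ringed nestlings is
#' even. The counts are deterministic (males are topped up to
#' `floor(total/2)`, females to `ceiling(total/2)`, the extra bird on an
#' odd total being female); which individuals receive which sex is
#' random.
#'
#' @param total_marked total number of ringed nestlings.
#' @param resighted_males,resighted_females numbers later resighted and
#'   hence of known sex.
#' @return A list with `assigned_males`, `assigned_females`,
#'   `total_males`, `total_females`, and `assignment` (a random 0/1
#'   vector over the unresighted birds; 1 = male).
#' @examples
#' assign_unknown_sexes(4993, 296, 235)[c("assigned_males", "assigned_females")]
#' @export
assign_unknown_sexes <- function(total_marked, resighted_males,
                                 resighted_females) {
  stopifnot(resighted_males >= 0, resighted_females >= 0)
  if (resighted_males + resighted_females > total_marked)
    stop("more resighted birds than marked birds")
  target_m <- floor(total_marked / 2)
  target_f <- ceiling(total_marked / 2)
  am <- target_m - resighted_males
  af <- target_f - resighted_females
  if (am < 0 || af < 0)
    stop("even sex ratio infeasible: resighted birds of one sex exceed half the total")
  n_un <- total_marked - resighted_males - resighted_females
  assignment <- integer(n_un)
  if (n_un > 0) assignment[sample.int(n_un, am)] <- 1L
  list(assigned_males = am, assigned_females = af,
       total_males = target_m, total_females = target_f,
       assignment = assignment)
}
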