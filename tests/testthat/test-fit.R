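test_that("fit returns draws of the documented shape, within parameter bounds", {
  d <- simulate_ipm_dataset(small_config(years = 8, seed = 1))
  fit <- fit_ipm(d$observed, chains = 2, iter = 300, burnin = 200, seed = 2)
  expect_s3_class(fit, "ipm_fit")
  b <- draws_block(fit, "b")
  expect_equal(dim(b), c(300, 2, 4, 8))
  expect_true(all(b > 0 & b < 1))
  ps <- draws_block(fit, "phi_succ")
  expect_equal(dim(ps), c(300, 2, 4, 7))
  expect_true(all(draws_block(fit, "fled") >= 0.5))
  expect_true(all(draws_block(fit, "NB") >= 0))
  expect_true(all(draws_block(fit, "p") > 0 & draws_block(fit, "p") < 1))
})

test_that("with no data a parameter reverts to its vague prior", {
  d <- simulate_ipm_dataset(small_config(years = 6, seed = 3))
  # keep only the breeding submodel and empty its table: b sees no data
  d$observed$breeding$R <- 0L
  d$observed$breeding$B <- 0L
  fit <- fit_ipm(d$observed, chains = 2, iter = 800, burnin = 400, seed = 4,
                 include = c(fledglings = FALSE, adults = FALSE,
                             juveniles = FALSE, counts = FALSE))
  mu_b <- draws_block(fit, "mu", collapse = TRUE)[, 1:4]
  # prior SD on the logit scale is sqrt(1000) ~ 31.6; posterior must stay wide
  expect_gt(mean(apply(mu_b, 2, sd)), 5)
})

test_that("perfect observation at large N recovers breeding success closely", {
  mp <- default_params(); mp$p <- 1; mp$c <- 1
  cfg <- sim_config(years = 8, mean_params = mp,
                    sd_b = matrix(0, 2, 2), sd_fled = matrix(0, 2, 2),
                    sd_phi_fl = c(0, 0), sd_phi_succ = matrix(0, 2, 2),
                    sd_phi_fail = matrix(0, 2, 2), imm_sd_log = 0,
                    init_nb = c(60, 45, 120, 70), imm_mean = c(25, 18, 20, 15),
                    monitor_frac_success = 1, monitor_frac_fled = 1,
                    count_exact = TRUE, seed = 5)
  d <- simulate_ipm_dataset(cfg)
  fit <- fit_ipm(d$observed, chains = 2, iter = 800, burnin = 500, seed = 6)
  est_b <- apply(draws_block(fit, "b", collapse = TRUE), 2, mean)
  truth_b <- as.numeric(mp$b)[c(1, 3, 2, 4)]  # to class order
  expect_true(all(abs(est_b - truth_b) < 0.03))
})

test_that("immigration is identifiable from the count residual", {
  mp <- default_params(); mp$p <- 1; mp$c <- 1
  cfg <- sim_config(years = 10, mean_params = mp, imm_mean = rep(5, 4),
                    imm_sd_log = 0, monitor_frac_success = 1,
                    monitor_frac_fled = 1, count_exact = TRUE,
                    init_nb = c(20, 15, 35, 20), seed = 7)
  d <- simulate_ipm_dataset(cfg)
  true_inflow <- mean(colSums(d$truth$im[, -1]))
  fit <- fit_ipm(d$observed, chains = 2, iter = 1200, burnin = 600, seed = 8)
  Im <- draws_block(fit, "Im", collapse = TRUE)
  est_inflow <- mean(apply(Im[, , -1], 1, sum)) / (cfg$years - 1)
  expect_lt(abs(est_inflow - true_inflow) / true_inflow, 0.3)

  # dropping the count stream removes the immigration signal entirely:
  # credible intervals on yearly immigrant numbers must widen
  fit0 <- fit_ipm(d$observed, chains = 2, iter = 1200, burnin = 600, seed = 9,
                  include = c(counts = FALSE))
  M1 <- draws_block(fit, "M", collapse = TRUE)[, , -1]
  M0 <- draws_block(fit0, "M", collapse = TRUE)[, , -1]
  width <- function(M) mean(apply(M, c(2, 3), function(x)
    diff(quantile(x, c(0.025, 0.975)))))
  expect_gt(width(M0), width(M1))
})

test_that("posterior matches an independent MCMC engine on a small dataset", {
  skip_if_not_installed("rjags")
  d <- simulate_ipm_dataset(small_config(years = 8, seed = 42))
  fit <- fit_ipm(d$observed, chains = 3, iter = 5000, burnin = 1500,
                 thin = 2, seed = 5)
  jm <- run_jags_oracle(d$observed, n_adapt = 800, n_burn = 800,
                        n_iter = 3000, chains = 2, seed = 9)
  TT <- 8
  mine_mean <- function(bl) apply(draws_block(fit, bl, collapse = TRUE), 2, mean)
  jags_mean <- function(nm, nk, times)
    vapply(seq_len(nk), function(k) jags_block_mean(jm, nm, k, times),
           numeric(1))
  expect_true(all(abs(mine_mean("b") - jags_mean("b", 4, 1:TT)) < 0.05))
  expect_true(all(abs(mine_mean("fled") - jags_mean("fled", 4, 1:TT)) < 0.08))
  expect_true(all(abs(mine_mean("phi_succ") - jags_mean("ps", 4, 1:(TT - 1))) < 0.06))
  expect_true(all(abs(mine_mean("phi_fail") - jags_mean("pf", 4, 1:(TT - 1))) < 0.06))
  expect_true(all(abs(mine_mean("phi_fl") - jags_mean("pfl", 2, 1:(TT - 1))) < 0.03))
  expect_lt(abs(mean(draws_block(fit, "p", collapse = TRUE)) - jm["p"]), 0.03)
  expect_lt(abs(mean(draws_block(fit, "c", collapse = TRUE)) - jm["cc"]), 0.03)
  expect_true(all(abs(colMeans(draws_block(fit, "psi_succ_sw", collapse = TRUE)) -
                        jm[c("psw_s[1]", "psw_s[2]")]) < 0.05))
  expect_true(all(abs(colMeans(draws_block(fit, "psi_fail_sw", collapse = TRUE)) -
                        jm[c("psw_f[1]", "psw_f[2]")]) < 0.06))
  expect_true(all(abs(colMeans(draws_block(fit, "psi_fl_sw", collapse = TRUE)) -
                        jm[c("psw_fl[1]", "psw_fl[2]")]) < 0.05))
  # latent population size and immigrant inflow
  NB <- draws_block(fit, "NB", collapse = TRUE)
  mineNB <- colMeans(apply(NB, c(1, 3), sum))
  jagsNB <- vapply(1:TT, function(t)
    sum(vapply(1:4, function(k) jm[sprintf("NB[%d,%d]", k, t)], numeric(1))),
    numeric(1))
  expect_true(all(abs(mineNB - jagsNB) / jagsNB < 0.06))
  Im <- draws_block(fit, "Im", collapse = TRUE)
  mineIm <- mean(apply(Im[, , -1], 1, sum))
  jagsIm <- sum(vapply(1:4, function(k)
    sum(vapply(1:(TT - 1), function(t) jm[sprintf("Im[%d,%d]", k, t)],
               numeric(1))), numeric(1)))
  expect_lt(abs(mineIm - jagsIm) / jagsIm, 0.1)
})

test_that("split-free Gelman-Rubin statistic: limits and hand-computed oracle", {
  set.seed(31)
  base <- rnorm(400)
  same <- array(c(base, base), c(400, 2))
  expect_lt(abs(rhat_scalar(same) - 1), 0.01)

  shifted <- array(c(rnorm(400), rnorm(400, 5)), c(400, 2))
  expect_gt(rhat_scalar(shifted), 1.1)

  x <- array(rnorm(60), c(10, 6))
  W <- mean(apply(x, 2, var))
  B_n <- var(colMeans(x))
  expect_equal(rhat_scalar(x), sqrt(((10 - 1) / 10 * W + B_n) / W),
               tolerance = 1e-12)

  expect_error(rhat_diagnostic(array(rnorm(10), c(10, 1))), "two chains")
})

test_that("summary statistics follow from the draws by plain arithmetic", {
  d <- simulate_ipm_dataset(small_config(years = 6, seed = 11))
  fit <- fit_ipm(d$observed, chains = 2, iter = 200, burnin = 150, seed = 12)
  s <- summarize_posterior(fit)
  b <- draws_block(fit, "b", collapse = TRUE)
  m <- rowMeans(b[, 1, ])
  expect_equal(s$mean[s$parameter == "b_Y_S"], mean(m), tolerance = 1e-10)
  expect_equal(s$cv_mean[s$parameter == "b_Y_S"],
               mean(apply(b[, 1, ], 1, sd) / m), tolerance = 1e-10)
  # f reported on the total-brood scale
  fl <- draws_block(fit, "fled", collapse = TRUE)
  expect_equal(s$mean[s$parameter == "f_O_T"], mean(2 * rowMeans(fl[, 4, ])),
               tolerance = 1e-10)
  expect_true(all(is.na(s$cv_mean[s$parameter %in% c("p", "c")])))
})
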