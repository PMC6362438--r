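test_that("year effects: zero SD collapses to the means, seeds reproduce", {
  cfg <- sim_config(sd_b = matrix(0, 2, 2), sd_fled = matrix(0, 2, 2),
                    sd_phi_fl = c(0, 0), sd_phi_succ = matrix(0, 2, 2),
                    sd_phi_fail = matrix(0, 2, 2), imm_sd_log = 0,
                    years = 5)
  set.seed(1)
  eff <- draw_year_effects(cfg)
  for (t in 1:5) {
    expect_equal(eff$params[[t]]$b, cfg$mean_params$b)
    expect_equal(eff$params[[t]]$phi_succ, cfg$mean_params$phi_succ)
    expect_equal(unname(eff$imm_mean[, t]), unname(cfg$imm_mean))
  }
  cfg2 <- sim_config(years = 6)
  set.seed(99); a <- draw_year_effects(cfg2)
  set.seed(99); b <- draw_year_effects(cfg2)
  expect_identical(a, b)
})

test_that("year effects are centred on the configured link-scale means", {
  cfg <- sim_config(years = 4000, sd_b = matrix(1, 2, 2))
  set.seed(5)
  eff <- draw_year_effects(cfg)
  x <- vapply(eff$params, function(p) qlogis(p$b[2, 1]), numeric(1))
  se <- 1 / sqrt(4000)
  expect_lt(abs(mean(x) - qlogis(cfg$mean_params$b[2, 1])), 3 * se)
})

test_that("population goes extinct without survival, recruitment or immigration", {
  mp <- default_params()
  mp$phi_fl[] <- 0; mp$phi_succ[] <- 0; mp$phi_fail[] <- 0
  cfg <- sim_config(years = 4, mean_params = mp, imm_mean = rep(0, 4),
                    sd_phi_fl = c(0, 0), sd_phi_succ = matrix(0, 2, 2),
                    sd_phi_fail = matrix(0, 2, 2))
  set.seed(8)
  tr <- simulate_population(cfg)
  expect_true(tr$extinct)
  expect_equal(sum(tr$nb[, 2:4]), 0)
})

test_that("arrivals decompose exactly into recruits, survivors and immigrants", {
  set.seed(31)
  tr <- simulate_population(small_config(years = 12))
  for (t in 2:12)
    expect_equal(tr$nb[, t],
                 tr$recruits_in[, t] + tr$survivors_in[, t] + tr$im[, t])
})

test_that("one-step class growth matches the projection expectation at large N", {
  mp <- default_params()
  cfg <- sim_config(years = 3, mean_params = mp,
                    sd_b = matrix(0, 2, 2), sd_fled = matrix(0, 2, 2),
                    sd_phi_fl = c(0, 0), sd_phi_succ = matrix(0, 2, 2),
                    sd_phi_fail = matrix(0, 2, 2), imm_sd_log = 0,
                    imm_mean = rep(0, 4),
                    init_nb = c(4000, 3000, 8000, 5000))
  set.seed(13)
  tr <- simulate_population(cfg)
  A <- projection_matrix(mp)
  expected <- as.numeric(A %*% cfg$init_nb)
  # per-class Monte-Carlo SE: binomial/Poisson sums, conservatively
  # bounded by sqrt of the expectation
  se <- sqrt(expected)
  expect_true(all(abs(tr$nb[, 2] - expected) < 4 * se))
})

test_that("realized immigrant inflow tracks the configured means", {
  cfg <- sim_config(years = 24, imm_sd_log = 0)
  set.seed(44)
  tr <- simulate_population(cfg)
  inflow <- rowMeans(tr$im[, -1])
  se <- sqrt(cfg$imm_mean / 23)
  expect_true(all(abs(inflow - cfg$imm_mean) < 4 * se))
})

test_that("perfect observation reproduces the truth", {
  mp <- default_params(); mp$p <- 1; mp$c <- 1
  cfg <- small_config(years = 8, mean_params = mp,
                      monitor_frac_success = 1, monitor_frac_fled = 1,
                      count_exact = TRUE)
  set.seed(3)
  tr <- simulate_population(cfg)
  obs <- observe_dataset(tr, cfg)
  expect_equal(unname(obs$counts), unname(tr$nb))
  # every breeder-year is monitored: trials equal class counts
  Rk <- with(obs$breeding, tapply(R, year, sum))
  expect_equal(as.numeric(Rk), unname(colSums(tr$nb)))
  # with c = 1 no unknown-status codes occur, and with p = 1 every
  # alive marked bird-year is coded seen
  ev <- obs$adult_histories$events
  expect_false(any(ev %in% c(3, 6), na.rm = TRUE))
  st <- tr$state
  alive_years <- sum(vapply(seq_len(nrow(tr$adults)), function(i) {
    e <- tr$adults$entry[i]
    if (e >= 8) 0L else sum(st[i, (e + 1):8] > 0L)
  }, integer(1)))
  expect_equal(sum(ev > 0, na.rm = TRUE), alive_years)
})

test_that("zero detection yields all-unseen histories; resighting rate matches p", {
  mp <- default_params(); mp$p <- 0
  cfg <- small_config(years = 6, mean_params = mp)
  set.seed(9)
  tr <- simulate_population(cfg)
  obs <- observe_dataset(tr, cfg)
  expect_true(all(obs$adult_histories$events == 0, na.rm = TRUE))

  # binomial check on the resighting fraction of known-alive birds
  mp2 <- default_params(); mp2$p <- 0.9
  cfg2 <- sim_config(years = 8, mean_params = mp2, init_nb = c(60, 40, 120, 70),
                     imm_mean = c(25, 18, 20, 15), seed = 1)
  set.seed(1)
  tr2 <- simulate_population(cfg2)
  obs2 <- observe_dataset(tr2, cfg2)
  ev <- obs2$adult_histories$events
  total_seen <- sum(ev > 0, na.rm = TRUE)
  # total alive marked bird-years after first capture:
  alive_years <- 0
  st <- tr2$state
  for (i in seq_len(nrow(tr2$adults))) {
    e <- tr2$adults$entry[i]
    if (e >= 8) next
    alive_years <- alive_years + sum(st[i, (e + 1):8] > 0)
  }
  phat <- total_seen / alive_years
  se <- sqrt(0.9 * 0.1 / alive_years)
  expect_lt(abs(phat - 0.9), 3 * se)
})

test_that("identical config and seed give identical datasets", {
  cfg <- small_config(years = 7, seed = 555)
  a <- simulate_ipm_dataset(cfg)
  b <- simulate_ipm_dataset(cfg)
  expect_identical(a$observed, b$observed)
  expect_identical(a$truth$nb, b$truth$nb)
})

test_that("even-sex-ratio assignment: worked example, edge cases, feasibility", {
  r <- assign_unknown_sexes(4993, 296, 235)
  expect_equal(r$assigned_males, 2200)
  expect_equal(r$assigned_females, 2262)
  expect_equal(r$total_males, 2496)
  expect_equal(r$total_females, 2497)

  r <- assign_unknown_sexes(10, 5, 5)
  expect_equal(c(r$assigned_males, r$assigned_females), c(0, 0))

  r <- assign_unknown_sexes(7, 0, 0)
  expect_equal(c(r$assigned_males, r$assigned_females), c(3, 4))

  expect_error(assign_unknown_sexes(10, 6, 0), "infeasible")
  expect_error(assign_unknown_sexes(4, 3, 2), "more resighted")

  set.seed(1)
  r <- assign_unknown_sexes(100, 10, 20)
  expect_equal(sum(r$assignment), r$assigned_males)
  expect_equal(length(r$assignment), 70)
})
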