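zero_phi_params <- function() {
  ap <- default_params()
  ap$phi_fl[] <- 0; ap$phi_succ[] <- 0; ap$phi_fail[] <- 0
  ap
}

test_that("projection matrix degenerate cases: no survival and no movement", {
  A <- projection_matrix(zero_phi_params())
  expect_equal(A, matrix(0, 4, 4, dimnames = list(class_order(), class_order())))

  ap <- default_params()
  ap$psi_fl <- diag(2); ap$psi_succ <- diag(2); ap$psi_fail <- diag(2)
  A <- projection_matrix(ap)
  # no between-habitat entries: S classes only feed S classes
  expect_true(all(A[c(2, 4), c(1, 3)] == 0))
  expect_true(all(A[c(1, 3), c(2, 4)] == 0))
})

test_that("projection entries equal the spelled-out products at study means", {
  ap <- default_params()
  A <- projection_matrix(ap)
  # fecundity entry (O_S -> Y_S): b * fled * phi_fl * psi_fl[S,S]
  expect_equal(A["Y_S", "O_S"],
               0.81 * (2.82 / 2) * 0.09 * ap$psi_fl["S", "S"],
               tolerance = 1e-12)
  # fecundity entry (Y_T -> Y_S): natal-habitat recruitment then settlement
  expect_equal(A["Y_S", "Y_T"],
               0.60 * (2.32 / 2) * 0.06 * ap$psi_fl["T", "S"],
               tolerance = 1e-12)
  # adult entry (O_S -> O_S): success-conditional survival then movement
  expect_equal(A["O_S", "O_S"],
               0.81 * 0.55 * ap$psi_succ["S", "S"] +
                 (1 - 0.81) * 0.31 * ap$psi_fail["S", "S"],
               tolerance = 1e-12)
  expect_equal(A["O_T", "Y_S"],
               0.71 * 0.46 * ap$psi_succ["S", "T"] +
                 (1 - 0.71) * 0.49 * ap$psi_fail["S", "T"],
               tolerance = 1e-12)
})

test_that("matrix entries are non-negative and adult rows bounded by survival", {
  set.seed(7)
  for (i in 1:100) {
    ap <- random_params()
    A <- projection_matrix(ap)
    expect_true(all(A >= 0))
    for (j in 1:4) {
      a <- c("Y", "Y", "O", "O")[j]; h <- c("S", "T", "S", "T")[j]
      bound <- max(ap$phi_succ[a, h], ap$phi_fail[a, h])
      expect_lte(max(A[3:4, j]), bound + 1e-12)
    }
  }
})

test_that("projection recursion: immigration-only, bookkeeping, and oracle product", {
  s <- population_state(c(5, 5, 5, 5))
  out <- project_state(s, matrix(0, 4, 4), immigrants = c(3, 1, 2, 0))
  expect_equal(unname(out$nb), c(3, 1, 2, 0))
  expect_equal(out$year, 2L)

  # perfect survival without movement or fecundity: Young age into Old
  ageA <- matrix(0, 4, 4); ageA[3, c(1, 3)] <- 1; ageA[4, c(2, 4)] <- 1
  out <- project_state(population_state(c(4, 3, 2, 1)), ageA)
  expect_equal(unname(out$nb), c(0, 0, 6, 4))
  expect_equal(sum(out$nb), 10)

  A <- projection_matrix(default_params())
  nb <- c(20, 16, 41, 23)
  expect_equal(unname(project_state(population_state(nb), A)$nb),
               unname(as.numeric(A %*% nb)))
  expect_error(project_state(s, A, immigrants = c(-1, 0, 0, 0)), "non-negative")
})

test_that("projection is linear in the population state", {
  set.seed(21)
  A <- projection_matrix(random_params())
  s1 <- rpois(4, 15); s2 <- rpois(4, 8)
  expect_equal(unname(project_state(population_state(s1 + s2), A)$nb),
               unname(project_state(population_state(s1), A)$nb +
                        project_state(population_state(s2), A)$nb),
               tolerance = 1e-12)
})

test_that("realized growth rates and geometric mean", {
  states <- lapply(1:5, function(t) population_state(c(10, 10, 10, 10), year = t))
  g <- realized_growth(states)
  expect_equal(g$lambda_t, rep(1, 4))
  expect_equal(g$geometric_mean, 1)

  m <- matrix(c(25, 25, 25, 25, 12, 13, 12, 13, 25, 25, 25, 25), 3, 4,
              byrow = TRUE)
  g <- realized_growth(m)
  expect_equal(g$lambda_t, c(0.5, 2), tolerance = 1e-12)
  expect_equal(g$geometric_mean, 1, tolerance = 1e-12)

  set.seed(3)
  traj <- matrix(rpois(24 * 4, 25) + 1, 24, 4)
  g <- realized_growth(traj)
  tot <- rowSums(traj)
  expect_equal(g$geometric_mean, exp(mean(log(tot[-1] / tot[-24]))),
               tolerance = 1e-12)
  expect_error(realized_growth(matrix(0, 3, 4)), "zero")
})

test_that("habitat productivity definition and guards", {
  expect_equal(habitat_productivity(0, 0, 10), 0)
  expect_equal(habitat_productivity(5, 15, 20), 1)
  expect_error(habitat_productivity(1, 1, 0), "undefined")
})
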