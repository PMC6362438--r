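# helpers to build synthetic realized-parameter series for the LTRE
# machinery without a fit
base_theta <- function() {
  ap <- default_params()
  stats::setNames(c(as.numeric(ap$b)[c(1, 3, 2, 4)],
                    as.numeric(ap$fled)[c(1, 3, 2, 4)],
                    ap$phi_fl,
                    as.numeric(ap$phi_succ)[c(1, 3, 2, 4)],
                    as.numeric(ap$phi_fail)[c(1, 3, 2, 4)],
                    c(0.20, 0.16, 0.41, 0.23),
                    c(0.14, 0.09, 0.11, 0.08)),
                  hsipm:::ltre_par_names())
}
default_psis <- function() {
  ap <- default_params()
  list(psi_fl = ap$psi_fl, psi_succ = ap$psi_succ, psi_fail = ap$psi_fail)
}

test_that("lambda parameterization: unit immigration sensitivity, matrix terms", {
  th <- base_theta()
  ps <- default_psis()
  s <- transient_sensitivities(th, ps$psi_fl, ps$psi_succ, ps$psi_fail)
  # per-capita immigration enters additively with unit coefficient
  for (k in class_order())
    expect_equal(unname(s[paste0("omega_", k)]), 1, tolerance = 1e-6)
  # structure sensitivities equal the matrix column sums
  ap <- default_params()
  A <- projection_matrix(ap)
  for (j in 1:4)
    expect_equal(unname(s[paste0("n_", class_order()[j])]),
                 unname(colSums(A)[j]), tolerance = 1e-5)
  # vital-rate sensitivity against the symbolic product-form derivative:
  # d lambda / d phi_fl_S = sum_a n[a,S] b fled (settlement rows sum to 1)
  nS <- th[c("n_Y_S", "n_O_S")]
  hand <- sum(nS * c(ap$b[1, 1] * ap$fled[1, 1], ap$b[2, 1] * ap$fled[2, 1]))
  expect_equal(unname(s["phi_fl_S"]), unname(hand), tolerance = 1e-5)
})

test_that("variance decomposition: single source, silence, and matrix oracle", {
  set.seed(5)
  ps <- default_psis()
  TTm <- 20
  th <- matrix(rep(base_theta(), each = TTm), TTm,
               dimnames = list(NULL, hsipm:::ltre_par_names()))
  # all parameters constant: all contributions zero
  s <- transient_sensitivities(colMeans(th), ps$psi_fl, ps$psi_succ, ps$psi_fail)
  expect_true(all(variance_contributions(th, s) == 0))

  # one varying parameter: its contribution recovers var(lambda) to
  # first order; all others stay exactly zero
  th1 <- th
  th1[, "phi_fl_S"] <- base_theta()["phi_fl_S"] + rnorm(TTm, 0, 0.01)
  s1 <- transient_sensitivities(colMeans(th1), ps$psi_fl, ps$psi_succ,
                                ps$psi_fail)
  cv <- variance_contributions(th1, s1)
  lam <- apply(th1, 1, hsipm:::ltre_lambda, ps$psi_fl, ps$psi_succ, ps$psi_fail)
  expect_equal(unname(cv["phi_fl_S"]), var(lam), tolerance = 0.02 * var(lam))
  expect_true(all(cv[names(cv) != "phi_fl_S"] == 0))
})

test_that("contributions equal the quadratic-form oracle on a 3-parameter toy", {
  set.seed(9)
  TTm <- 200
  ps <- default_psis()
  th <- matrix(rep(base_theta(), each = TTm), TTm,
               dimnames = list(NULL, hsipm:::ltre_par_names()))
  vary <- c("b_O_S", "phi_succ_O_S", "omega_Y_S")
  Sigma <- matrix(c(4, 1.5, 0.5, 1.5, 2, 0.2, 0.5, 0.2, 1) * 1e-4, 3, 3)
  L <- chol(Sigma)
  th[, vary] <- th[, vary] + matrix(rnorm(TTm * 3), TTm, 3) %*% L
  s <- transient_sensitivities(colMeans(th), ps$psi_fl, ps$psi_succ, ps$psi_fail)
  cv <- variance_contributions(th, s)
  V <- cov(th[, vary])
  oracle <- colSums(V * outer(s[vary], s[vary]))
  expect_equal(unname(cv[vary]), unname(oracle), tolerance = 1e-10)
  expect_equal(sum(cv), unname(t(s[vary]) %*% V %*% s[vary])[1, 1],
               tolerance = 1e-10)
})

test_that("yearly contributions: arithmetic and first-order Taylor consistency", {
  ps <- default_psis()
  nm <- hsipm:::ltre_par_names()
  TTm <- 4
  th <- matrix(rep(base_theta(), each = TTm), TTm, dimnames = list(NULL, nm))
  sens_t <- t(apply(th, 1, transient_sensitivities,
                    ps$psi_fl, ps$psi_succ, ps$psi_fail))
  yc <- yearly_contributions(th, sens_t)
  expect_true(all(yc == 0))

  # single-parameter step: contribution = delta * sensitivity
  th2 <- th
  th2[2, "b_O_S"] <- th2[1, "b_O_S"] + 0.1
  sens_t2 <- t(apply(th2, 1, transient_sensitivities,
                     ps$psi_fl, ps$psi_succ, ps$psi_fail))
  yc2 <- yearly_contributions(th2, sens_t2)
  expect_equal(yc2[1, "b_O_S"], 0.1 * sens_t2[1, "b_O_S"], tolerance = 1e-10)

  # summed contributions approximate the lambda change, with error
  # shrinking quadratically in the perturbation size
  err <- vapply(c(0.04, 0.02, 0.01), function(eps) {
    set.seed(7)
    th3 <- th
    th3[2, ] <- th3[1, ] + rnorm(ncol(th3), 0, eps) *
      pmax(abs(th3[1, ]), 0.05)
    lam <- apply(th3, 1, hsipm:::ltre_lambda, ps$psi_fl, ps$psi_succ,
                 ps$psi_fail)
    s3 <- t(apply(th3, 1, transient_sensitivities,
                  ps$psi_fl, ps$psi_succ, ps$psi_fail))
    yc3 <- yearly_contributions(th3, s3)
    abs(sum(yc3[1, ]) - (lam[2] - lam[1]))
  }, numeric(1))
  expect_lt(err[2], err[1] / 2.5)
  expect_lt(err[3], err[2] / 2.5)
})

test_that("group labels partition the parameter set", {
  grp <- hsipm:::ltre_groups()
  expect_setequal(unique(grp), c("short", "tall", "structure", "immigration"))
  expect_equal(sum(grp == "structure"), 4)
  expect_equal(sum(grp == "immigration"), 4)
  expect_equal(sum(grp == "short"), 9)
  expect_equal(sum(grp == "tall"), 9)
})
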