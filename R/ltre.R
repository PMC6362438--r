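# Transient LTRE machinery.
#
# The realized growth rate is written as a deterministic function of the
# year's realized demographic parameters theta_t, the class-proportion
# vector n_t, and the per-capita apparent immigration omega'_t
# (immigrants arriving at t+1 per breeder at t):
#
#   lambda(theta_t) = sum_j colsum_j(A(theta_t)) n_{t,j} + sum_k omega'_{t,k}
#
# Sensitivities are central finite differences at the across-year means;
# the variance decomposition weights temporal covariances of the
# realized annual values with sensitivity products (first-order
# approximation, including parameter covariation).

# the LTRE parameter vector: 18 vital rates + 4 structure + 4 immigration
ltre_par_names <- function() {
  cls <- CLASS_ORDER
  c(paste0("b_", cls), paste0("fled_", cls), paste0("phi_fl_", HABITATS),
    paste0("phi_succ_", cls), paste0("phi_fail_", cls),
    paste0("n_", cls), paste0("omega_", cls))
}

ltre_groups <- function() {
  nm <- ltre_par_names()
  grp <- character(length(nm))
  grp[grepl("_S$|_S_|phi_fl_S", nm)] <- "short"
  grp[grepl("_T$|phi_fl_T", nm)] <- "tall"
  grp[grepl("_Y_S|_O_S", nm)] <- "short"
  grp[grepl("_Y_T|_O_T", nm)] <- "tall"
  grp[grepl("^n_", nm)] <- "structure"
  grp[grepl("^omega_", nm)] <- "immigration"
  grp
}

# lambda as a function of a named LTRE parameter vector (psi held fixed)
ltre_lambda <- function(theta, psi_fl, psi_succ, psi_fail) {
  g <- function(stub) matrix(c(theta[paste0(stub, "_Y_S")],
                               theta[paste0(stub, "_O_S")],
                               theta[paste0(stub, "_Y_T")],
                               theta[paste0(stub, "_O_T")]), 2, 2)
  ap <- annual_params(
    b = pmin(pmax(g("b"), 0), 1), fled = pmax(g("fled"), 0.5),
    phi_fl = pmin(pmax(c(theta["phi_fl_S"], theta["phi_fl_T"]), 0), 1),
    phi_succ = pmin(pmax(g("phi_succ"), 0), 1),
    phi_fail = pmin(pmax(g("phi_fail"), 0), 1),
    psi_fl = psi_fl, psi_succ = psi_succ, psi_fail = psi_fail
  )
  A <- projection_matrix(ap)
  n <- theta[paste0("n_", CLASS_ORDER)]
  omega <- theta[paste0("omega_", CLASS_ORDER)]
  sum(colSums(A) * n) + sum(omega)
}

#' Transient sensitivities of realized growth
#'
#' Partial derivatives of the realized-growth function
#' `lambda(theta) = 1' A(theta) n + sum(omega)` with respect to each
#' vital rate, class proportion and per-capita immigration rate,
#' evaluated (by central finite differences, step `1e-6`) at the
#' across-year means of one posterior draw's realized annual values.
#'
#' @param theta_bar named vector of across-year means (names
#'   `ltre_par_names()`).
#' @param psi_fl,psi_succ,psi_fail 2x2 habitat transition matrices
#'   (constant over time).
#' @param step finite-difference step.
#' @return Named vector of sensitivities.
#' @export
transient_sensitivities <- function(theta_bar, psi_fl, psi_succ, psi_fail,
                                    step = 1e-6) {
  nm <- ltre_par_names()
  out <- setNames(numeric(length(nm)), nm)
  for (j in nm) {
    up <- theta_bar; up[j] <- up[j] + step
    dn <- theta_bar; dn[j] <- dn[j] - step
    out[j] <- (ltre_lambda(up, psi_fl, psi_succ, psi_fail) -
                 ltre_lambda(dn, psi_fl, psi_succ, psi_fail)) / (2 * step)
  }
  out
}

#' Covariance-weighted LTRE variance contributions
#'
#' Contribution of parameter `i` to the temporal variance of realized
#' growth: `sum_j cov(theta_i, theta_j) s_i s_j`, using the temporal
#' covariances of the realized annual values and sensitivities at the
#' temporal means. Contributions over all parameters sum to the
#' first-order approximation of `var(lambda_t)`.
#'
#' @param theta_t matrix of realized annual values (years x parameters,
#'   columns named `ltre_par_names()`).
#' @param sens named sensitivity vector (from
#'   [transient_sensitivities()]).
#' @return Named vector of contributions.
#' @export
variance_contributions <- function(theta_t, sens) {
  if (nrow(theta_t) < 3) stop("need at least 3 years of realized values")
  V <- cov(theta_t)
  s <- sens[colnames(theta_t)]
  contr <- as.numeric((V * outer(s, s)) %*% rep(1, length(s)))
  setNames(contr, colnames(theta_t))
}

#' Year-specific LTRE contributions
#'
#' First-order contribution of parameter `i` to the change in realized
#' growth between consecutive years:
#' `c[i, t] = (theta[i, t+1] - theta[i, t]) * s[i, t]` with the
#' sensitivity evaluated at year `t`'s realized values.
#'
#' @param theta_t years x parameters matrix of realized values.
#' @param sens_t years x parameters matrix of year-specific
#'   sensitivities (evaluated at each year's values).
#' @return (years-1) x parameters matrix of contributions.
#' @export
yearly_contributions <- function(theta_t, sens_t) {
  TTm <- nrow(theta_t)
  if (TTm < 2) stop("need at least 2 years")
  (theta_t[-1, , drop = FALSE] - theta_t[-TTm, , drop = FALSE]) *
    sens_t[-TTm, , drop = FALSE]
}

# internal: realized LTRE parameter matrix (years-1 x npar) for one draw
ltre_theta_draw <- function(fit, draw, chain) {
  TT <- fit$years
  g <- function(bl) {
    x <- draws_block(fit, bl)
    if (length(dim(x)) == 4) x[draw, chain, , ] else x[draw, chain, ]
  }
  b <- g("b"); fled <- g("fled"); pfl <- g("phi_fl")
  ps <- g("phi_succ"); pf <- g("phi_fail")
  NB <- g("NB"); Im <- g("Im")
  Ntot <- colSums(NB)
  Tm <- TT - 1
  th <- matrix(NA_real_, Tm, length(ltre_par_names()),
               dimnames = list(NULL, ltre_par_names()))
  for (t in seq_len(Tm)) {
    th[t, ] <- c(b[, t], fled[, t], pfl[, t], ps[, t], pf[, t],
                 NB[, t] / Ntot[t], Im[, t + 1] / Ntot[t])
  }
  th
}

# internal: psi matrices of one draw
psi_from_draw <- function(fit, draw, chain) {
  mk <- function(sw) matrix(c(1 - sw[1], sw[2], sw[1], 1 - sw[2]), 2, 2)
  list(psi_fl = mk(draws_block(fit, "psi_fl_sw")[draw, chain, ]),
       psi_succ = mk(draws_block(fit, "psi_succ_sw")[draw, chain, ]),
       psi_fail = mk(draws_block(fit, "psi_fail_sw")[draw, chain, ]))
}

#' Transient LTRE decomposition of a fitted IPM
#'
#' For each posterior draw: computes the realized annual parameter
#' values (vital rates, class proportions, per-capita immigration),
#' sensitivities at their temporal means, covariance-weighted variance
#' contributions, grouped sums (Short demography, Tall demography,
#' population structure, apparent immigration) and year-specific
#' contributions; then summarises across draws with means and 95%
#' credible intervals.
#'
#' @param fit an `ipm_fit`.
#' @param n_draws number of posterior draws used.
#' @return A list of class `ipm_ltre` with elements `contributions`
#'   (per-parameter data frame), `groups` (grouped contributions and
#'   normalized shares), `yearly` (mean year-specific group
#'   contributions), and `var_lambda` (posterior summary of the
#'   temporal variance of lambda and its first-order approximation).
#' @export
ltre <- function(fit, n_draws = 200) {
  n_save <- nrow(fit$chains[[1]])
  n_ch <- length(fit$chains)
  total <- n_save * n_ch
  pick <- round(seq(1, total, length.out = min(n_draws, total)))
  nm <- ltre_par_names()
  grp <- ltre_groups()
  contr <- matrix(NA_real_, length(pick), length(nm),
                  dimnames = list(NULL, nm))
  vl <- vl_approx <- numeric(length(pick))
  TTm <- fit$years - 1
  yearly_grp <- array(0, c(length(pick), 4, TTm - 1),
                      dimnames = list(NULL, c("short", "tall", "structure",
                                              "immigration"), NULL))
  for (ii in seq_along(pick)) {
    ch <- (pick[ii] - 1) %/% n_save + 1
    dr <- (pick[ii] - 1) %% n_save + 1
    th <- ltre_theta_draw(fit, dr, ch)
    psi <- psi_from_draw(fit, dr, ch)
    tb <- colMeans(th)
    s <- transient_sensitivities(tb, psi$psi_fl, psi$psi_succ, psi$psi_fail)
    cv <- variance_contributions(th, s)
    contr[ii, ] <- cv
    lam <- apply(th, 1, ltre_lambda, psi$psi_fl, psi$psi_succ, psi$psi_fail)
    vl[ii] <- var(lam)
    vl_approx[ii] <- sum(cv)
    # year-specific contributions with year-specific sensitivities
    sens_t <- t(vapply(seq_len(TTm), function(t)
      transient_sensitivities(th[t, ], psi$psi_fl, psi$psi_succ,
                              psi$psi_fail), numeric(length(nm))))
    yc <- yearly_contributions(th, sens_t)
    for (g in colnames(yearly_grp)) {
      sel <- grp == g
      yearly_grp[ii, g, ] <- rowSums(yc[, sel, drop = FALSE])
    }
  }
  ci <- function(x) quantile(x, c(0.025, 0.975), names = FALSE)
  per_par <- data.frame(
    parameter = nm, group = grp,
    contribution = colMeans(contr),
    l95 = apply(contr, 2, function(x) ci(x)[1]),
    u95 = apply(contr, 2, function(x) ci(x)[2])
  )
  gsum <- vapply(unique(grp), function(g)
    rowSums(contr[, grp == g, drop = FALSE]), numeric(nrow(contr)))
  tot <- rowSums(contr)
  shares <- gsum / tot
  local <- gsum[, "short"] + gsum[, "tall"] + gsum[, "structure"]
  groups <- data.frame(
    group = colnames(gsum),
    contribution = colMeans(gsum),
    l95 = apply(gsum, 2, function(x) ci(x)[1]),
    u95 = apply(gsum, 2, function(x) ci(x)[2]),
    share = colMeans(shares),
    share_l95 = apply(shares, 2, function(x) ci(x)[1]),
    share_u95 = apply(shares, 2, function(x) ci(x)[2])
  )
  # headline shares: local demography vs immigration, and recruitment
  # from Short within local demography
  rec_short <- contr[, "phi_fl_S"]
  headline <- c(
    local_share = mean(local / tot),
    immigration_share = mean(gsum[, "immigration"] / tot),
    short_within_local = mean(gsum[, "short"] / local),
    structure_within_local = mean(gsum[, "structure"] / local),
    recruitment_short_within_local = mean(rec_short / local)
  )
  structure(list(
    contributions = per_par, groups = groups, headline = headline,
    yearly = apply(yearly_grp, c(2, 3), mean),
    var_lambda = c(mean = mean(vl), approx_mean = mean(vl_approx),
                   ratio = mean(vl_approx / vl))
  ), class = "ipm_ltre")
}

#' @export
print.ipm_ltre <- function(x, ...) {
  cat("transient LTRE decomposition of var(lambda_t)\n")
  print(x$groups[, c("group", "contribution", "share")], row.names = FALSE)
  cat(sprintf("local demography share: %.2f; immigration share: %.2f\n",
              x$headline["local_share"], x$headline["immigration_share"]))
  cat(sprintf("first-order completeness (sum contr / var lambda): %.2f\n",
              x$var_lambda["ratio"]))
  invisible(x)
}
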