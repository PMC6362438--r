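#' Table-style posterior summary
#'
#' Per parameter: the posterior mean and 95% equal-tailed credible
#' interval of (i) the across-year arithmetic mean of the annual
#' realisations and (ii) their coefficient of temporal variation
#' (sd/mean within each draw). Fledgling numbers are reported on the
#' total-brood scale `f = 2 fled` (the field's printed convention) as
#' well as derived quantities: class proportions `n`, per-class
#' apparent-immigration rates `omega = Im / N`, annual-growth geometric
#' mean, and habitat productivities (geometric means and arithmetic
#' CVs).
#'
#' @param fit an `ipm_fit`.
#' @return A data frame with columns `parameter`, `mean`, `l95`, `u95`,
#'   `cv_mean`, `cv_l95`, `cv_u95` (CV columns `NA` for constants).
#' @export
summarize_posterior <- function(fit) {
  ci <- function(x) quantile(x, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  rows <- list()
  add <- function(name, per_draw_mean, per_draw_cv = NULL) {
    q <- ci(per_draw_mean)
    cvq <- if (is.null(per_draw_cv)) c(NA, NA) else ci(per_draw_cv)
    rows[[length(rows) + 1]] <<- data.frame(
      parameter = name, mean = mean(per_draw_mean, na.rm = TRUE),
      l95 = q[1], u95 = q[2],
      cv_mean = if (is.null(per_draw_cv)) NA_real_ else
        mean(per_draw_cv, na.rm = TRUE),
      cv_l95 = cvq[1], cv_u95 = cvq[2]
    )
  }
  cls <- class_order()

  tv_block <- function(bl, names, scale = 1) {
    x <- draws_block(fit, bl, collapse = TRUE)  # draw x k x T
    for (k in seq_along(names)) {
      xa <- x[, k, ] * scale
      m <- rowMeans(xa)
      cv <- apply(xa, 1, sd) / m
      add(names[k], m, cv)
    }
  }
  tv_block("b", paste0("b_", cls))
  tv_block("fled", paste0("f_", cls), scale = 2)
  tv_block("phi_fl", paste0("phi_fl_", HABITATS))
  tv_block("phi_succ", paste0("phi_succ_", cls))
  tv_block("phi_fail", paste0("phi_fail_", cls))

  NB <- draws_block(fit, "NB", collapse = TRUE)   # draw x 4 x T
  Im <- draws_block(fit, "Im", collapse = TRUE)
  Ntot <- apply(NB, c(1, 3), sum)                 # draw x T
  TT <- fit$years

  # class proportions across years
  for (k in 1:4) {
    nk <- NB[, k, ] / Ntot
    add(paste0("n_", cls[k]), rowMeans(nk), apply(nk, 1, sd) / rowMeans(nk))
  }
  # immigration rates relative to the total population (years 2..T)
  for (k in 1:4) {
    ok <- Im[, k, -1] / Ntot[, -1]
    add(paste0("omega_", cls[k]), rowMeans(ok),
        apply(ok, 1, sd) / rowMeans(ok))
  }
  add("omega_total", rowMeans(apply(Im[, , -1], c(1, 3), sum) / Ntot[, -1]))

  # constants
  for (bl in c("psi_succ_sw", "psi_fail_sw", "psi_fl_sw")) {
    x <- draws_block(fit, bl, collapse = TRUE)
    add(paste0(sub("_sw", "", bl), "_S_T"), x[, 1])
    add(paste0(sub("_sw", "", bl), "_T_S"), x[, 2])
  }
  add("p", draws_block(fit, "p", collapse = TRUE))
  add("c", draws_block(fit, "c", collapse = TRUE))

  # realized growth
  lam <- Ntot[, -1] / Ntot[, -TT]
  add("lambda_geomean", exp(rowMeans(log(lam))))

  # habitat productivity (expected, per draw and year)
  pr <- productivity_draws(fit)
  for (h in 1:2) {
    g <- exp(rowMeans(log(pmax(pr[, h, ], 1e-12))))
    cv <- apply(pr[, h, ], 1, sd) / rowMeans(pr[, h, ])
    add(paste0("prod_", HABITATS[h]), g, cv)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-draw expected habitat productivity
#'
#' Expected productivity of each habitat for every posterior draw and
#' year pair, computed from the draw's annual vital rates and latent
#' class counts via [expected_productivity()].
#'
#' @param fit an `ipm_fit`.
#' @return Array `(draw, habitat, year_pair)`.
#' @export
productivity_draws <- function(fit) {
  TT <- fit$years
  b <- draws_block(fit, "b", collapse = TRUE)
  fled <- draws_block(fit, "fled", collapse = TRUE)
  pfl <- draws_block(fit, "phi_fl", collapse = TRUE)
  ps <- draws_block(fit, "phi_succ", collapse = TRUE)
  pf <- draws_block(fit, "phi_fail", collapse = TRUE)
  NB <- draws_block(fit, "NB", collapse = TRUE)
  n_d <- dim(b)[1]
  out <- array(NA_real_, c(n_d, 2, TT - 1))
  for (h in 1:2) {
    kz <- c(h, h + 2)  # Young and Old classes of habitat h
    n_h <- NB[, kz[1], 1:(TT - 1)] + NB[, kz[2], 1:(TT - 1)]
    rec <- sur <- 0
    for (k in kz) {
      age <- if (k <= 2) 1 else 2
      rec <- rec + NB[, k, 1:(TT - 1)] * b[, k, 1:(TT - 1)] *
        fled[, k, 1:(TT - 1)] * pfl[, h, ]
      sur <- sur + NB[, k, 1:(TT - 1)] *
        (b[, k, 1:(TT - 1)] * ps[, k, ] +
           (1 - b[, k, 1:(TT - 1)]) * pf[, k, ])
    }
    out[, h, ] <- (rec + sur) / pmax(n_h, 1e-12)
  }
  out
}
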