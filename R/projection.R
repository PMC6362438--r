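#' Annual projection matrix of the four breeder categories
#'
#' Builds the 4x4 matrix `A_t` mapping breeder numbers in year `t`
#' (class order [class_order()]) to expected locally produced breeders
#' in year `t + 1`. Recruitment rows (into Young classes) compose
#' breeding success, modelled-sex fledgling number, natal-habitat
#' recruitment and natal-to-breeding habitat choice:
#' `b[a,h] * fled[a,h] * phi_fl[h] * psi_fl[h -> h']`.
#' Adult rows (into Old classes) compose success-conditional apparent
#' survival with the success-matched movement:
#' `b[a,h] * phi_succ[a,h] * psi_succ[h -> h'] +
#'  (1 - b[a,h]) * phi_fail[a,h] * psi_fail[h -> h']`.
#'
#' @param params an [annual_params()] object.
#' @return 4x4 numeric matrix, rows = destination class, columns =
#'   source class.
#' @examples
#' A <- projection_matrix(default_params())
#' colSums(A)  # per-capita contribution of each class
#' @export
projection_matrix <- function(params) {
  validate_annual_params(params)
  A <- matrix(0, 4, 4, dimnames = list(CLASS_ORDER, CLASS_ORDER))
  for (j in seq_len(4)) {
    a <- c(1L, 1L, 2L, 2L)[j]  # 1 = Young, 2 = Old
    h <- c(1L, 2L, 1L, 2L)[j]  # 1 = Short, 2 = Tall
    for (h2 in 1:2) {
      # recruitment rows -> Y_S, Y_T
      A[h2, j] <- params$b[a, h] * params$fled[a, h] *
        params$phi_fl[h] * params$psi_fl[h, h2]
      # adult rows -> O_S, O_T
      A[2 + h2, j] <- params$b[a, h] * params$phi_succ[a, h] *
        params$psi_succ[h, h2] +
        (1 - params$b[a, h]) * params$phi_fail[a, h] * params$psi_fail[h, h2]
    }
  }
  A
}

#' Deterministic one-year projection
#'
#' Expected population next year: `A %*% nb + im`, with `im` the
#' apparent immigrants joining in year `t + 1`. The stochastic
#' realisation of this recursion lives in the simulator.
#'
#' @param state a [population_state()] (or length-4 breeder vector).
#' @param A 4x4 projection matrix from [projection_matrix()].
#' @param immigrants length-4 non-negative vector of immigrants
#'   entering at `t + 1`, class order [class_order()].
#' @return A [population_state()] with real-valued expected counts.
#' @export
project_state <- function(state, A, immigrants = rep(0, 4)) {
  nb <- if (inherits(state, "population_state")) state$nb else as.numeric(state)
  year <- if (inherits(state, "population_state")) state$year else 1L
  immigrants <- as.numeric(immigrants)
  if (any(immigrants < 0)) stop("immigrant numbers must be non-negative")
  stopifnot(length(nb) == 4, all(dim(A) == c(4, 4)))
  out <- as.numeric(A %*% nb) + immigrants
  population_state(out, im = immigrants, year = year + 1L)
}

#' Realized annual growth rates and their geometric mean
#'
#' @param series a list of [population_state()] objects, or a numeric
#'   matrix with one row per year and four columns of class counts.
#' @return A list of class `growth_series` with elements `lambda_t`
#'   (length `T - 1`), `geometric_mean`, and `totals`.
#' @export
realized_growth <- function(series) {
  totals <- if (is.matrix(series)) rowSums(series) else
    vapply(series, function(s) sum(s$nb), numeric(1))
  if (length(totals) < 2) stop("need at least two years")
  if (any(totals <= 0)) stop("zero total population: growth undefined")
  lambda <- totals[-1] / totals[-length(totals)]
  structure(list(lambda_t = unname(lambda),
                 geometric_mean = exp(mean(log(lambda))),
                 totals = unname(totals)),
            class = "growth_series")
}

#' @export
print.growth_series <- function(x, ...) {
  cat("realized growth over", length(x$lambda_t), "year pairs;",
      "geometric mean", round(x$geometric_mean, 4), "\n")
  invisible(x)
}

#' Habitat productivity
#'
#' Number of first-year recruits produced by breeders of a habitat plus
#' the apparently surviving adults from that habitat, divided by the
#' number of breeders there: the per-capita contribution of the habitat
#' to next year's breeding population.
#'
#' @param recruits_from_h first-year recruits (next year) born in the
#'   habitat.
#' @param surviving_adults_from_h adults from the habitat apparently
#'   surviving to breed next year (in either habitat).
#' @param adults_in_h breeders in the habitat this year (> 0).
#' @return Productivity (non-negative real).
#' @export
habitat_productivity <- function(recruits_from_h, surviving_adults_from_h,
                                 adults_in_h) {
  if (any(adults_in_h <= 0))
    stop("productivity undefined with no breeders in habitat")
  (recruits_from_h + surviving_adults_from_h) / adults_in_h
}

#' Expected habitat productivity under a parameter set
#'
#' Deterministic productivity implied by annual parameters and a
#' population state: recruits are `sum_a nb[a,h] b fled phi_fl` and
#' survivors `sum_a nb[a,h] (b phi_succ + (1-b) phi_fail)`.
#'
#' @param params an [annual_params()] object.
#' @param nb length-4 breeder counts in class order.
#' @return Named length-2 vector of productivities for S and T.
#' @export
expected_productivity <- function(params, nb) {
  nb <- setNames(as.numeric(nb), CLASS_ORDER)
  out <- numeric(2)
  for (i in 1:2) {
    h <- HABITATS[i]
    cls <- paste(AGES, h, sep = "_")
    n_h <- nb[cls]
    if (sum(n_h) <= 0) { out[i] <- NA_real_; next }
    rec <- sum(n_h * params$b[, h] * params$fled[, h] * params$phi_fl[h])
    sur <- sum(n_h * (params$b[, h] * params$phi_succ[, h] +
                        (1 - params$b[, h]) * params$phi_fail[, h]))
    out[i] <- (rec + sur) / sum(n_h)
  }
  setNames(out, HABITATS)
}
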