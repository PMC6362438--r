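#' Annual demographic parameter set
#'
#' Bundles every vital rate and observation parameter that defines the
#' population process for one year: breeding success `b`, modelled-sex
#' fledglings per successful brood `fled`, fledgling recruitment
#' `phi_fl`, success-conditional adult apparent survival `phi_succ` /
#' `phi_fail`, habitat transition probabilities `psi_*`, per-capita
#' apparent-immigration rates `omega`, resighting probability `p` and
#' state certainty `c`.
#'
#' Age-by-habitat parameters are 2x2 matrices with rows `c("Y","O")` and
#' columns `c("S","T")`; transition matrices are 2x2 row-stochastic with
#' both dimensions `c("S","T")` (from, to). `fled` counts only the
#' modelled sex, so a successful brood contributes at least half a
#' fledgling on average (`fled >= 0.5`).
#'
#' @param b 2x2 matrix of breeding-success probabilities.
#' @param fled 2x2 matrix of mean modelled-sex fledglings per successful
#'   brood (`>= 0.5`).
#' @param phi_fl length-2 vector, fledgling-to-Young apparent recruitment
#'   probability by natal habitat.
#' @param phi_succ,phi_fail 2x2 matrices of adult apparent survival for
#'   successful and failed breeders.
#' @param psi_fl,psi_succ,psi_fail 2x2 row-stochastic habitat transition
#'   matrices (natal-to-breeding, and between-year for successful/failed
#'   breeders).
#' @param omega 2x2 matrix of apparent-immigration rates relative to the
#'   total population (used for reporting and LTRE; the count process
#'   models immigrant numbers directly).
#' @param p resighting probability.
#' @param c state-certainty probability (a detected bird's breeding
#'   success is recorded rather than coded unknown).
#'
#' @return An object of class `annual_params`.
#' @examples
#' ap <- default_params()
#' projection_matrix(ap)
#' @export
annual_params <- function(b, fled, phi_fl, phi_succ, phi_fail,
                          psi_fl, psi_succ, psi_fail,
                          omega = matrix(0, 2, 2), p = 1, c = 1) {
  dimn <- list(AGES, HABITATS)
  as_ah <- function(x, nm) {
    x <- matrix(as.numeric(x), 2, 2, dimnames = dimn)
    x
  }
  as_hh <- function(x, nm) {
    x <- matrix(as.numeric(x), 2, 2, dimnames = list(HABITATS, HABITATS))
    if (any(abs(rowSums(x) - 1) > 1e-8))
      stop(sprintf("'%s' rows must sum to 1 (two-habitat system)", nm))
    x
  }
  obj <- structure(list(
    b = as_ah(b, "b"), fled = as_ah(fled, "fled"),
    phi_fl = setNames(as.numeric(phi_fl), HABITATS),
    phi_succ = as_ah(phi_succ, "phi_succ"),
    phi_fail = as_ah(phi_fail, "phi_fail"),
    psi_fl = as_hh(psi_fl, "psi_fl"),
    psi_succ = as_hh(psi_succ, "psi_succ"),
    psi_fail = as_hh(psi_fail, "psi_fail"),
    omega = as_ah(omega, "omega"),
    p = as.numeric(p), c = as.numeric(c)
  ), class = "annual_params")
  validate_annual_params(obj)
  obj
}

validate_annual_params <- function(x) {
  probs <- c(x$b, x$phi_fl, x$phi_succ, x$phi_fail,
             x$psi_fl, x$psi_succ, x$psi_fail, x$omega, x$p, x$c)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (any(!is.finite(x$fled)) || any(x$fled < 0.5))
    stop("'fled' must be >= 0.5 (a successful brood has >= 1 fledgling in total)")
  invisible(x)
}

#' @export
print.annual_params <- function(x, ...) {
  cat("annual demographic parameters (ages Y/O, habitats S/T)\n")
  cat("  b:        ", format(round(t(x$b)[c(1, 3, 2, 4)], 3)), "\n")
  cat("  fled:     ", format(round(t(x$fled)[c(1, 3, 2, 4)], 3)), "\n")
  cat("  phi_fl:   ", format(round(x$phi_fl, 3)), "\n")
  cat("  phi_succ: ", format(round(t(x$phi_succ)[c(1, 3, 2, 4)], 3)), "\n")
  cat("  phi_fail: ", format(round(t(x$phi_fail)[c(1, 3, 2, 4)], 3)), "\n")
  cat("  p:", round(x$p, 3), " c:", round(x$c, 3), "\n")
  invisible(x)
}

#' Flatten annual parameters to named key-value form
#'
#' Serialises an [annual_params()] object to a flat named numeric vector
#' with keys such as `b_Y_S`, `psi_succ_S_T`, `omega_O_T`, `p`, `c`
#' (the canonical interchange format), or rebuilds the object from such
#' a vector.
#'
#' @param params an `annual_params` object.
#' @return `flatten_params()`: a named numeric vector;
#'   `unflatten_params()`: an `annual_params` object.
#' @export
flatten_params <- function(params) {
  stopifnot(inherits(params, "annual_params"))
  out <- c()
  for (nm in c("b", "fled", "phi_succ", "phi_fail", "omega")) {
    m <- params[[nm]]
    for (a in AGES) for (h in HABITATS)
      out[paste(nm, a, h, sep = "_")] <- m[a, h]
  }
  for (h in HABITATS) out[paste0("phi_fl_", h)] <- params$phi_fl[h]
  for (nm in c("psi_fl", "psi_succ", "psi_fail")) {
    m <- params[[nm]]
    for (h in HABITATS) for (h2 in HABITATS)
      out[paste(nm, h, h2, sep = "_")] <- m[h, h2]
  }
  out["p"] <- params$p
  out["c"] <- params$c
  out
}

#' @param keys named numeric vector as produced by `flatten_params()`.
#' @rdname flatten_params
#' @export
unflatten_params <- function(keys) {
  g <- function(nm) matrix(c(keys[paste(nm, "Y", "S", sep = "_")],
                             keys[paste(nm, "O", "S", sep = "_")],
                             keys[paste(nm, "Y", "T", sep = "_")],
                             keys[paste(nm, "O", "T", sep = "_")]), 2, 2)
  gh <- function(nm) matrix(c(keys[paste(nm, "S", "S", sep = "_")],
                              keys[paste(nm, "T", "S", sep = "_")],
                              keys[paste(nm, "S", "T", sep = "_")],
                              keys[paste(nm, "T", "T", sep = "_")]), 2, 2)
  annual_params(
    b = g("b"), fled = g("fled"),
    phi_fl = c(keys["phi_fl_S"], keys["phi_fl_T"]),
    phi_succ = g("phi_succ"), phi_fail = g("phi_fail"),
    psi_fl = gh("psi_fl"), psi_succ = gh("psi_succ"),
    psi_fail = gh("psi_fail"),
    omega = g("omega"), p = keys["p"], c = keys["c"]
  )
}

#' Study-scale default parameter values
#'
#' Point values matching the posterior means reported for the male
#' northern wheatear population (breeding success, fledglings halved to
#' the modelled sex, recruitment, success-conditional survival), with
#' transition, detection and certainty values documented in the methods
#' vignette. Used as generating truth by the simulator defaults.
#'
#' @return An `annual_params` object.
#' @export
default_params <- function() {
  annual_params(
    b        = matrix(c(0.71, 0.81, 0.60, 0.66), 2, 2),
    fled     = matrix(c(2.58, 2.82, 2.32, 2.47), 2, 2) / 2,
    phi_fl   = c(0.09, 0.06),
    phi_succ = matrix(c(0.46, 0.55, 0.40, 0.40), 2, 2),
    phi_fail = matrix(c(0.49, 0.31, 0.37, 0.30), 2, 2),
    psi_fl   = matrix(c(0.75, 0.50, 0.25, 0.50), 2, 2),
    psi_succ = matrix(c(0.90, 0.20, 0.10, 0.80), 2, 2),
    psi_fail = matrix(c(0.70, 0.45, 0.30, 0.55), 2, 2),
    omega    = matrix(c(0.14, 0.11, 0.09, 0.08), 2, 2),
    p = 0.9, c = 0.91
  )
}

#' Population state: breeders and apparent immigrants by class
#'
#' Integer counts of breeding males per category (class order
#' [class_order()]) together with the apparent immigrants that joined
#' the population in that year.
#'
#' @param nb numeric length-4 vector of breeder counts (Y_S, Y_T, O_S, O_T).
#' @param im numeric length-4 vector of apparent immigrants included in
#'   `nb` for that year.
#' @param year integer year index.
#' @return An object of class `population_state`.
#' @export
population_state <- function(nb, im = rep(0, 4), year = 1L) {
  nb <- setNames(as.numeric(nb), CLASS_ORDER)
  im <- setNames(as.numeric(im), CLASS_ORDER)
  if (any(nb < 0) || any(im < 0)) stop("counts must be non-negative")
  structure(list(year = as.integer(year), nb = nb, im = im),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat("population state, year", x$year, "\n")
  print(rbind(breeders = x$nb, immigrants = x$im))
  invisible(x)
}

#' Proportion of occupied sites in each age-habitat class
#'
#' @param state a [population_state()] or a length-4 numeric vector of
#'   breeder counts in class order.
#' @return Length-4 numeric vector summing to one.
#' @export
class_proportions <- function(state) {
  nb <- if (inherits(state, "population_state")) state$nb else
    setNames(as.numeric(state), CLASS_ORDER)
  tot <- sum(nb)
  if (tot <= 0) stop("total population is zero; proportions undefined")
  nb / tot
}
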