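#' Stage-specific demographic rates
#'
#' Bundles the demographic parameters of the female-only, birth-pulse life
#' cycle used throughout the package: fecundity of a successful breeder,
#' stage-specific breeding probabilities, and stage-specific six-month
#' survival probabilities covering the interval from the birth pulse to a
#' winter survey. Defaults are representative woodland caribou rates.
#'
#' Stages are: calf (age 0), yearling (age 1, non-reproductive),
#' subadult (age 2, occasionally reproductive) and adult (age 3+).
#'
#' @param f Number of offspring produced per female that breeds
#'   successfully. Must be a non-negative integer; the estimator itself is
#'   invariant to `f` because it cancels from the kinship probabilities.
#' @param b_s,b_a Breeding probability of a subadult / adult female.
#' @param phi_c,phi_y,phi_s,phi_a Six-month survival probability of a
#'   calf / yearling / subadult / adult.
#'
#' @return An object of class `demographic_rates` (a named list).
#' @examples
#' demographic_rates()
#' demographic_rates(phi_c = 0.5)
#' @export
demographic_rates <- function(f = 1, b_s = 0.15, b_a = 0.90,
                              phi_c = 0.35, phi_y = 0.894,
                              phi_s = 0.894, phi_a = 0.922) {
  probs <- c(b_s = b_s, b_a = b_a, phi_c = phi_c, phi_y = phi_y,
             phi_s = phi_s, phi_a = phi_a)
  if (!all(is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all breeding and survival probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (!is.finite(f) || f < 0 || f != as.integer(f)) {
    stop("`f` must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(f = as.integer(f), b_s = b_s, b_a = b_a,
         phi_c = phi_c, phi_y = phi_y, phi_s = phi_s, phi_a = phi_a),
    class = "demographic_rates"
  )
}

#' @export
print.demographic_rates <- function(x, ...) {
  cat("<demographic_rates>\n")
  cat(sprintf("  offspring per breeder (f): %d\n", x$f))
  cat(sprintf("  breeding prob.   subadult %.3f, adult %.3f\n", x$b_s, x$b_a))
  cat(sprintf("  6-month survival calf %.3f, yearling %.3f, subadult %.3f, adult %.3f\n",
              x$phi_c, x$phi_y, x$phi_s, x$phi_a))
  invisible(x)
}

#' Configuration of a simulated population
#'
#' Describes the initial composition of a simulated female population just
#' before the summer birth pulse. The population holds `n_reproductive`
#' reproductive females (subadults plus adults, the estimand \eqn{N_F}) and
#' a yearling cohort sized relative to \eqn{N_F}; no calves exist before
#' the pulse.
#'
#' Stage counts are formed by round-half-up on the fractional targets, with
#' adults absorbing the remainder, so that e.g. \eqn{N_F = 50} yields
#' 6 subadults, 44 adults and 8 yearlings (58 females in total) and
#' \eqn{N_F = 1000} yields a total of 1150.
#'
#' @param n_reproductive Target number of reproductive females \eqn{N_F}
#'   (positive integer).
#' @param subadult_fraction Share of the reproductive females that are
#'   subadults (default 0.12; the rest are adults).
#' @param yearling_fraction Yearlings as a share of `n_reproductive`
#'   (default 0.15).
#' @param rates A [demographic_rates()] object.
#'
#' @return An object of class `population_config` (a named list).
#' @examples
#' population_config(250)
#' @export
population_config <- function(n_reproductive,
                              subadult_fraction = 0.12,
                              yearling_fraction = 0.15,
                              rates = demographic_rates()) {
  if (!is.numeric(n_reproductive) || length(n_reproductive) != 1 ||
      !is.finite(n_reproductive) || n_reproductive < 1 ||
      n_reproductive != as.integer(n_reproductive)) {
    stop("`n_reproductive` must be a positive integer", call. = FALSE)
  }
  fr <- c(subadult_fraction, yearling_fraction)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)) {
    stop("stage fractions must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(inherits(rates, "demographic_rates"))
  structure(
    list(n_reproductive = as.integer(n_reproductive),
         subadult_fraction = subadult_fraction,
         yearling_fraction = yearling_fraction,
         rates = rates),
    class = "population_config"
  )
}

#' @export
print.population_config <- function(x, ...) {
  cat("<population_config>\n")
  cat(sprintf("  reproductive females (N_F): %d (%.0f%% subadult)\n",
              x$n_reproductive, 100 * x$subadult_fraction))
  cat(sprintf("  yearlings: %.0f%% of N_F\n", 100 * x$yearling_fraction))
  print(x$rates)
  invisible(x)
}

# round-half-up; base round() is round-half-even and would give 7 yearlings
# for N_F = 50 instead of the 8 required to make the 58-female population
round_half_up <- function(x) floor(x + 0.5)
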