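#' Per-comparison kinship probabilities
#'
#' Probability that a single calf x reproductive-female pairwise comparison
#' yields a mother-calf pair, by the female's stage, at candidate abundance
#' `n_f`. The denominator is the total expected reproductive output across
#' all potentially reproductive females:
#' \deqn{q_s = \frac{b_s f}{N_F\,(b_s f (1-A) + b_a f A)}, \qquad
#'       q_a = \frac{b_a f}{N_F\,(b_s f (1-A) + b_a f A)},}
#' where `A` is the proportion of adults among the sampled reproductive
#' females. Fecundity `f` cancels, and the probabilities satisfy
#' \eqn{(1-A) q_s + A q_a = 1/N_F}.
#'
#' @param n_f Candidate reproductive female abundance (vectorized, > 0).
#' @param rates A [demographic_rates()] object.
#' @param A Proportion of adults among the sampled reproductive females.
#' @return A tibble with columns `n_f`, `q_s`, `q_a`.
#' @examples
#' kinship_probabilities(100, demographic_rates(), A = 1)
#' @export
kinship_probabilities <- function(n_f, rates = demographic_rates(), A) {
  if (any(n_f <= 0)) stop("`n_f` must be positive", call. = FALSE)
  if (length(A) != 1 || is.na(A) || A < 0 || A > 1) {
    stop("`A` must be a single value in [0, 1]", call. = FALSE)
  }
  if (rates$b_s == 0 && rates$b_a == 0) {
    stop("degenerate model: both breeding probabilities are zero",
         call. = FALSE)
  }
  q <- kinship_prob_vec(n_f, rates, A)
  tibble(n_f = n_f, q_s = q$q_s, q_a = q$q_a)
}

# plain-list version of kinship_probabilities() for likelihood loops
kinship_prob_vec <- function(n_f, rates, A) {
  mix <- rates$b_s * (1 - A) + rates$b_a * A
  list(q_s = rates$b_s / (n_f * mix), q_a = rates$b_a / (n_f * mix))
}

#' Multinomial log pseudolikelihood of the comparison counts
#'
#' Log pseudolikelihood of a [comparison_table()] at candidate abundance
#' `n_f`, up to an additive constant:
#' \deqn{\ell(N_F) = y_1 \log q_s + y_2 \log(1-q_s)
#'                 + y_3 \log q_a + y_4 \log(1-q_a).}
#' Because the pair/non-pair probabilities sum to one within each stage,
#' the four-category multinomial factorizes into two stage-stratified
#' binomials; this per-comparison reading is what is implemented.
#' Candidates so small that a required probability reaches 1 are
#' infeasible and return `-Inf` rather than erroring.
#'
#' @param comparisons A one-row [comparison_table()].
#' @param n_f Candidate abundance (vectorized, > 0).
#' @param rates A [demographic_rates()] object.
#' @return A double vector, one log-likelihood per element of `n_f`.
#' @examples
#' tab <- comparison_table(0, 176, 0, 0, 8, 168, A = 1)
#' log_pseudolikelihood(tab, c(15, 22, 30))
#' @export
log_pseudolikelihood <- function(comparisons, n_f,
                                 rates = demographic_rates()) {
  stopifnot(inherits(comparisons, "comparison_table"))
  if (comparisons$n == 0) return(rep(0, length(n_f)))
  if (any(n_f <= 0)) stop("`n_f` must be positive", call. = FALSE)
  if (rates$b_s == 0 && rates$b_a == 0) {
    stop("degenerate model: both breeding probabilities are zero",
         call. = FALSE)
  }
  q <- kinship_prob_vec(n_f, rates, comparisons$A)
  # pmax() keeps log() off negative arguments (q > 1 at tiny candidates);
  # those candidates are overwritten with -Inf below anyway
  term <- function(y, p) if (y > 0) y * log(pmax(p, 0)) else 0
  ll <- term(comparisons$y1, q$q_s) + term(comparisons$y2, 1 - q$q_s) +
    term(comparisons$y3, q$q_a) + term(comparisons$y4, 1 - q$q_a)
  # candidates too small for the model: some required probability >= 1
  infeasible <- (comparisons$n_s > 0 & q$q_s >= 1) |
    (comparisons$n_a > 0 & q$q_a >= 1)
  ll[infeasible | is.nan(ll)] <- -Inf
  ll
}

new_ckmr_fit <- function(comparisons, rates, n_hat, log_lik, search_low,
                         search_high, at_lower_bound, at_upper_bound,
                         flat_likelihood, ci_low = NA_real_,
                         ci_high = NA_real_, ci_level = NA_real_,
                         ci_low_clamped = NA, ci_high_clamped = NA) {
  structure(
    list(n_hat = n_hat, log_lik = log_lik,
         ci_low = ci_low, ci_high = ci_high, ci_level = ci_level,
         ci_low_clamped = ci_low_clamped, ci_high_clamped = ci_high_clamped,
         search_low = search_low, search_high = search_high,
         at_lower_bound = at_lower_bound, at_upper_bound = at_upper_bound,
         flat_likelihood = flat_likelihood,
         comparisons = comparisons, rates = rates),
    class = "ckmr_fit"
  )
}

#' Maximize the pseudolikelihood for reproductive female abundance
#'
#' Bounded one-dimensional continuous maximization of
#' [log_pseudolikelihood()] over `[search_low, search_high]` (Brent-style
#' via [stats::optimize()], tolerance 1e-6). Two degenerate cases are
#' resolved analytically: with comparisons but zero observed pairs the
#' likelihood increases monotonically in `n_f`, so the estimate sits at
#' the upper search bound (`at_upper_bound` flag); with no comparisons at
#' all the likelihood is flat and the upper bound is returned with the
#' `flat_likelihood` flag as well.
#'
#' @param comparisons A one-row [comparison_table()].
#' @param rates A [demographic_rates()] object.
#' @param search_low,search_high Search bounds for \eqn{N_F}. The
#'   conventional design is `search_low = 10` and `search_high` ten times
#'   the abundance the design anticipates; in application mode the upper
#'   bound must be chosen by the analyst.
#' @return An object of class `ckmr_fit`; see [tidy.ckmr_fit()].
#' @examples
#' tab <- comparison_table(0, 176, 0, 0, 8, 168, A = 1)
#' fit <- maximize_pseudolikelihood(tab, search_high = 1000)
#' fit$n_hat  # 176 / 8 = 22
#' @export
maximize_pseudolikelihood <- function(comparisons,
                                      rates = demographic_rates(),
                                      search_low = 10, search_high) {
  stopifnot(inherits(comparisons, "comparison_table"))
  if (!is.finite(search_low) || !is.finite(search_high) ||
      search_low <= 0 || search_low >= search_high) {
    stop("need 0 < search_low < search_high", call. = FALSE)
  }
  if (comparisons$n == 0) {
    return(new_ckmr_fit(comparisons, rates, n_hat = search_high,
                        log_lik = 0, search_low, search_high,
                        at_lower_bound = FALSE, at_upper_bound = TRUE,
                        flat_likelihood = TRUE))
  }
  if (comparisons$y1 + comparisons$y3 == 0) {
    ll <- log_pseudolikelihood(comparisons, search_high, rates)
    return(new_ckmr_fit(comparisons, rates, n_hat = search_high,
                        log_lik = ll, search_low, search_high,
                        at_lower_bound = FALSE, at_upper_bound = TRUE,
                        flat_likelihood = FALSE))
  }
  f <- function(x) log_pseudolikelihood(comparisons, x, rates)
  opt <- stats::optimize(f, c(search_low, search_high), maximum = TRUE,
                         tol = 1e-6)
  cand <- c(opt$maximum, search_low, search_high)
  ll <- c(opt$objective, f(search_low), f(search_high))
  best <- which.max(ll)
  new_ckmr_fit(comparisons, rates, n_hat = cand[best], log_lik = ll[best],
               search_low, search_high,
               at_lower_bound = best == 2L,
               at_upper_bound = best == 3L,
               flat_likelihood = FALSE)
}

#' Profile-likelihood confidence interval for the abundance estimate
#'
#' Finds the two abundances whose log pseudolikelihood lies
#' \eqn{\chi^2_{1,level}/2} units (1.92 for 95%) below the maximum, by
#' bracketed root finding on `[search_low, n_hat]` and
#' `[n_hat, search_high]`. A side on which no root exists (the likelihood
#' never drops far enough before the search bound) is clamped to that
#' bound and flagged; a flat likelihood yields the full search range,
#' flagged on both sides.
#'
#' @param fit A `ckmr_fit` from [maximize_pseudolikelihood()].
#' @param level Confidence level (default 0.95).
#' @return The fit with `ci_low`, `ci_high`, `ci_level` and the
#'   `ci_*_clamped` flags filled in.
#' @examples
#' tab <- comparison_table(0, 176, 0, 0, 8, 168, A = 1)
#' fit <- maximize_pseudolikelihood(tab, search_high = 1000) |>
#'   profile_confidence_interval()
#' c(fit$ci_low, fit$ci_high)  # about (12, 48)
#' @export
profile_confidence_interval <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "ckmr_fit"))
  drop <- stats::qchisq(level, df = 1) / 2
  fit$ci_level <- level
  if (fit$flat_likelihood) {
    fit$ci_low <- fit$search_low
    fit$ci_high <- fit$search_high
    fit$ci_low_clamped <- TRUE
    fit$ci_high_clamped <- TRUE
    return(fit)
  }
  target <- fit$log_lik - drop
  g <- function(x) log_pseudolikelihood(fit$comparisons, x, fit$rates) - target
  root_or_clamp <- function(lo, hi, clamp_at) {
    flo <- g(lo); fhi <- g(hi)
    if (is.finite(flo) && is.finite(fhi) && flo * fhi < 0) {
      list(value = stats::uniroot(g, c(lo, hi), tol = 1e-8)$root,
           clamped = FALSE)
    } else if (!is.finite(flo) && is.finite(fhi) && fhi > 0) {
      # likelihood -Inf at the bound (infeasibly small candidate): step in
      lo2 <- lo
      for (i in 1:60) {
        lo2 <- (lo2 + hi) / 2
        if (is.finite(g(lo2))) break
      }
      f2 <- g(lo2)
      if (is.finite(f2) && f2 < 0) {
        list(value = stats::uniroot(g, c(lo2, hi), tol = 1e-8)$root,
             clamped = FALSE)
      } else {
        list(value = clamp_at, clamped = TRUE)
      }
    } else {
      list(value = clamp_at, clamped = TRUE)
    }
  }
  if (fit$at_lower_bound) {
    lower <- list(value = fit$search_low, clamped = TRUE)
  } else {
    lower <- root_or_clamp(fit$search_low, fit$n_hat, fit$search_low)
  }
  if (fit$at_upper_bound) {
    upper <- list(value = fit$search_high, clamped = TRUE)
  } else {
    upper <- root_or_clamp(fit$n_hat, fit$search_high, fit$search_high)
    if (upper$clamped) upper$value <- fit$search_high
  }
  fit$ci_low <- lower$value
  fit$ci_high <- upper$value
  fit$ci_low_clamped <- lower$clamped
  fit$ci_high_clamped <- upper$clamped
  fit
}

#' Estimate reproductive female abundance from comparison counts
#'
#' One-call wrapper: [maximize_pseudolikelihood()] followed by
#' [profile_confidence_interval()].
#'
#' @inheritParams maximize_pseudolikelihood
#' @inheritParams profile_confidence_interval
#' @return A `ckmr_fit` with point estimate and profile interval.
#' @examples
#' comparison_table(0, 176, 0, 0, 8, 168, A = 1) |>
#'   estimate_abundance(search_high = 1000) |>
#'   tidy()
#' @export
estimate_abundance <- function(comparisons, rates = demographic_rates(),
                               search_low = 10, search_high,
                               level = 0.95) {
  maximize_pseudolikelihood(comparisons, rates, search_low, search_high) |>
    profile_confidence_interval(level = level)
}

#' @export
print.ckmr_fit <- function(x, ...) {
  cat("<ckmr_fit>  stage-stratified mother-offspring pseudolikelihood\n")
  cat(sprintf("  N_F estimate: %.2f  (search range [%g, %g])\n",
              x$n_hat, x$search_low, x$search_high))
  if (!is.na(x$ci_level)) {
    cat(sprintf("  %d%% profile CI: (%.2f, %.2f)%s\n",
                round(100 * x$ci_level), x$ci_low, x$ci_high,
                if (isTRUE(x$ci_low_clamped) || isTRUE(x$ci_high_clamped))
                  "  [clamped at search bound]" else ""))
  }
  if (x$flat_likelihood) cat("  flat likelihood: no comparisons observed\n")
  else if (x$at_upper_bound) cat("  estimate at upper search bound\n")
  else if (x$at_lower_bound) cat("  estimate at lower search bound\n")
  invisible(x)
}

#' Tidy a CKMR pseudolikelihood fit
#'
#' @param x A `ckmr_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the estimate, profile interval and
#'   boundary/degeneracy flags.
#' @method tidy ckmr_fit
#' @export
tidy.ckmr_fit <- function(x, ...) {
  tibble(term = "n_f", estimate = x$n_hat,
         ci_low = x$ci_low, ci_high = x$ci_high,
         at_lower_bound = x$at_lower_bound,
         at_upper_bound = x$at_upper_bound,
         flat_likelihood = x$flat_likelihood)
}

#' Glance at a CKMR pseudolikelihood fit
#'
#' @param x A `ckmr_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the maximized log pseudolikelihood,
#'   comparison count, observed pair count and search bounds.
#' @method glance ckmr_fit
#' @export
glance.ckmr_fit <- function(x, ...) {
  tibble(log_lik = x$log_lik,
         n_comparisons = x$comparisons$n,
         n_pairs = x$comparisons$y1 + x$comparisons$y3,
         search_low = x$search_low, search_high = x$search_high)
}

#' Plot the log pseudolikelihood profile of a fit
#'
#' Draws the log pseudolikelihood over the search range with the point
#' estimate and, when computed, the profile-interval cutoff 1.92 units
#' below the maximum.
#'
#' @param object A `ckmr_fit`.
#' @param n_points Number of grid points for the curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ckmr_fit
#' @export
autoplot.ckmr_fit <- function(object, n_points = 400, ...) {
  grid <- exp(seq(log(object$search_low), log(object$search_high),
                  length.out = n_points))
  df <- tibble(
    n_f = grid,
    log_lik = log_pseudolikelihood(object$comparisons, grid, object$rates)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$n_f, y = .data$log_lik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$n_hat, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(N[F]), y = "log pseudolikelihood")
  if (!is.na(object$ci_level)) {
    cutoff <- object$log_lik - stats::qchisq(object$ci_level, 1) / 2
    p <- p + ggplot2::geom_hline(yintercept = cutoff, colour = "grey50")
  }
  p
}
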