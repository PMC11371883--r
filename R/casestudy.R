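#' Tonquin annual survey counts
#'
#' Per-winter counts from the 2006-2015 non-invasive fecal-DNA surveys of
#' the Tonquin woodland caribou herd (Jasper National Park, Alberta):
#' sampled calves (both sexes), sampled potential mothers (females not
#' excluded by a known age under 3 at the cohort's birth), the resulting
#' pairwise comparisons, mother-calf pairs found by pedigree inference,
#' known-age exclusions, and total individuals sampled.
#'
#' @return A tibble with columns `year`, `n_calves`, `n_mothers`,
#'   `n_comparisons`, `mop`, `n_excluded`, `n_sampled_total`.
#' @examples
#' tonquin_counts()
#' @export
tonquin_counts <- function() {
  readr::read_csv(
    system.file("extdata", "tonquin_annual_counts.csv",
                package = "kinabund", mustWork = TRUE),
    show_col_types = FALSE
  )
}

#' Published capture-mark-recapture estimates for the Tonquin herd
#'
#' Robust-design CMR abundance estimates for the same herd and years,
#' shipped for comparison plots only; nothing in this package is fitted to
#' them.
#'
#' @return A tibble with the annual CMR female and total abundance
#'   estimates and their 95% interval bounds.
#' @export
tonquin_cmr_estimates <- function() {
  readr::read_csv(
    system.file("extdata", "tonquin_cmr_estimates.csv",
                package = "kinabund", mustWork = TRUE),
    show_col_types = FALSE
  )
}

#' Assemble one survey year's comparison counts from individual tables
#'
#' Applies the single-survey pooling and exclusion rules to raw tables of
#' sampled individuals and inferred mother-offspring pairs:
#' all sampling occasions within winter `year` are treated as one event;
#' calves of the year are individuals with `birth_year == year`; candidate
#' mothers are females sampled that year excluding calves of the year and
#' any female whose known birth year implies age under 3 at the cohort's
#' birth; pairs count only when mother and offspring were both sampled in
#' `year` and the offspring belongs to that year's cohort (no cross-year
#' comparisons).
#'
#' @param individuals A data frame with columns `id`, `year`, `stage`
#'   (`"calf"` or `"non-calf"` at that year's capture), `sex` (`"F"` /
#'   `"M"`), `birth_year` (integer or `NA` when unknown). One row per
#'   individual per survey year.
#' @param pairs A data frame with columns `mother_id`, `offspring_id`,
#'   `offspring_birth_year`.
#' @param year The survey winter to assemble.
#' @return A one-row tibble with the same columns as [tonquin_counts()]
#'   (without `n_sampled_total`).
#' @examples
#' inds <- tibble::tibble(
#'   id = 1:4, year = 2011,
#'   stage = c("calf", "non-calf", "non-calf", "non-calf"),
#'   sex = c("F", "F", "F", "M"),
#'   birth_year = c(2011, NA, 2010, NA))
#' prs <- tibble::tibble(mother_id = 2, offspring_id = 1,
#'                       offspring_birth_year = 2011)
#' assemble_annual_record(inds, prs, 2011)
#' @export
assemble_annual_record <- function(individuals, pairs, year) {
  individuals <- as_tibble(individuals)
  pairs <- as_tibble(pairs)
  yr <- individuals[individuals$year == year, , drop = FALSE]
  if (!nrow(yr)) {
    stop(sprintf("no individuals sampled in year %s", year), call. = FALSE)
  }
  is_cohort_calf <- !is.na(yr$birth_year) & yr$birth_year == year
  calves <- yr$id[is_cohort_calf]
  females <- yr[yr$sex == "F" & !is_cohort_calf, , drop = FALSE]
  known_age <- !is.na(females$birth_year)
  too_young <- known_age & (year - females$birth_year) < 3
  mothers <- females$id[!too_young]
  keep <- pairs$offspring_birth_year == year &
    pairs$offspring_id %in% calves &
    pairs$mother_id %in% mothers
  tibble(
    year = year,
    n_calves = length(calves),
    n_mothers = length(mothers),
    n_comparisons = length(calves) * length(mothers),
    mop = sum(keep),
    n_excluded = sum(too_young)
  )
}

# profile-likelihood interval for a binomial proportion: the set of p with
# log-likelihood within qchisq(level, 1)/2 (1.92 at 95%) of the maximum
binom_profile <- function(k, n, level = 0.95) {
  drop <- stats::qchisq(level, df = 1) / 2
  ll <- function(p) k * log(p) + (n - k) * log1p(-p)
  p_hat <- k / n
  if (k == 0) {
    # ll = n log(1 - p), maximal at p -> 0; only an upper p bound exists
    return(c(lower = 0, upper = 1 - exp(-drop / n)))
  }
  if (k == n) {
    # ll = n log(p), maximal at p = 1; lower root is exp(-drop/n)
    return(c(lower = exp(-drop / n), upper = 1))
  }
  target <- ll(p_hat) - drop
  f <- function(p) ll(p) - target
  lower <- stats::uniroot(f, c(.Machine$double.xmin, p_hat),
                          tol = .Machine$double.eps^0.75)$root
  upper <- stats::uniroot(f, c(p_hat, 1 - .Machine$double.eps),
                          tol = .Machine$double.eps^0.75)$root
  c(lower = lower, upper = upper)
}

#' Binomial point estimate of annual reproductive female abundance
#'
#' Single-year estimator treating the number of mother-calf pairs as
#' \eqn{MO_t \sim \mathrm{Binom}(n_{c,t}\, n_{f,t},\; 1/N_{f,t})}: every
#' potential mother contributes expected relative reproductive output
#' \eqn{1/N_f}, so the MLE is
#' \eqn{\hat N_f = n_{c}\, n_{f} / MO}. The reported estimate is rounded
#' half-up to an integer; the unrounded MLE is kept alongside.
#'
#' @param record A one-row data frame with columns `n_comparisons` and
#'   `mop` (e.g. a row of [tonquin_counts()] or an
#'   [assemble_annual_record()] result).
#' @return A one-row tibble with `estimate` (integer-reported), `mle`
#'   (unrounded) and the input counts; `year` is carried through when
#'   present.
#' @examples
#' binomial_point_estimate(dplyr::filter(tonquin_counts(), year == 2011))
#' @export
binomial_point_estimate <- function(record) {
  record <- as_tibble(record)
  stopifnot(nrow(record) == 1,
            all(c("n_comparisons", "mop") %in% names(record)))
  if (record$mop < 1) {
    stop(paste("no mother-offspring pairs observed: the abundance",
               "estimate is unbounded"), call. = FALSE)
  }
  mle <- record$n_comparisons / record$mop
  out <- tibble(estimate = round_half_up(mle), mle = mle,
                n_comparisons = record$n_comparisons, mop = record$mop)
  if ("year" %in% names(record)) {
    out <- dplyr::bind_cols(tibble(year = record$year), out)
  }
  out
}

#' Profile confidence interval for the annual binomial estimate
#'
#' Profiles the binomial likelihood on the pair probability
#' \eqn{p = MO/(n_c n_f)} (log-likelihood drop of 1.92 units at the 95%
#' level), inverts the bounds as \eqn{N = 1/p}, orders them, and rounds
#' half-up to integers. With `mop = 0` the point estimate is undefined
#' and only a finite lower abundance bound exists; the upper bound is
#' reported as `Inf` with `open_upper = TRUE`.
#'
#' @inheritParams binomial_point_estimate
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: the [binomial_point_estimate()] columns plus
#'   `ci_low`, `ci_high`, `level` and `open_upper` (`estimate` and `mle`
#'   are `NA` when `mop = 0`).
#' @examples
#' binomial_profile_ci(dplyr::filter(tonquin_counts(), year == 2011))
#' @export
binomial_profile_ci <- function(record, level = 0.95) {
  record <- as_tibble(record)
  stopifnot(nrow(record) == 1,
            all(c("n_comparisons", "mop") %in% names(record)))
  p_ci <- binom_profile(record$mop, record$n_comparisons, level)
  if (record$mop == 0) {
    out <- tibble(estimate = NA_real_, mle = NA_real_,
                  n_comparisons = record$n_comparisons, mop = record$mop,
                  ci_low = round_half_up(1 / p_ci[["upper"]]),
                  ci_high = Inf, level = level, open_upper = TRUE)
    if ("year" %in% names(record)) {
      out <- dplyr::bind_cols(tibble(year = record$year), out)
    }
    return(out)
  }
  est <- binomial_point_estimate(record)
  dplyr::mutate(est,
                ci_low = round_half_up(1 / p_ci[["upper"]]),
                ci_high = round_half_up(1 / p_ci[["lower"]]),
                level = level, open_upper = FALSE)
}

#' Annual abundance estimates for a multi-year survey table
#'
#' Applies the single-year binomial estimator with its profile interval to
#' every row of a per-year counts table, adding the percentage of
#' comparisons that yielded a pair.
#'
#' @param counts A data frame with one row per survey year and columns
#'   `year`, `n_comparisons`, `mop` (e.g. [tonquin_counts()]).
#' @param level Confidence level.
#' @return A tibble with one row per year: counts, `pct_pairs`,
#'   `estimate`, `mle`, `ci_low`, `ci_high`, `open_upper`.
#' @examples
#' annual_abundance(tonquin_counts())
#' @export
annual_abundance <- function(counts, level = 0.95) {
  counts <- as_tibble(counts)
  est <- purrr::map(seq_len(nrow(counts)), function(i) {
    binomial_profile_ci(counts[i, ], level = level)
  }) |>
    dplyr::bind_rows() |>
    dplyr::select(!dplyr::any_of(c("n_comparisons", "mop", "level")))
  counts |>
    dplyr::mutate(pct_pairs = 100 * .data$mop / .data$n_comparisons) |>
    dplyr::left_join(est, by = "year")
}

#' Mean of annual abundance estimates over a span of years
#'
#' Arithmetic mean of the integer-reported annual point estimates,
#' optionally restricted to a subset of years.
#'
#' @param estimates A tibble from [annual_abundance()] (or any table with
#'   `year` and `estimate` columns).
#' @param years Optional vector of years to include (default: all).
#' @return A one-row tibble with `n_years` and `mean_estimate`.
#' @examples
#' est <- annual_abundance(tonquin_counts())
#' multi_year_summary(est)              # 45.9 over 2006-2015
#' multi_year_summary(est, 2009:2015)   # 22.43
#' @export
multi_year_summary <- function(estimates, years = NULL) {
  estimates <- as_tibble(estimates)
  if (!is.null(years)) {
    estimates <- estimates[estimates$year %in% years, , drop = FALSE]
  }
  if (!nrow(estimates)) stop("no years selected", call. = FALSE)
  tibble(n_years = nrow(estimates),
         mean_estimate = mean(estimates$estimate))
}

#' Plot annual CKMR estimates (optionally against CMR estimates)
#'
#' @param estimates A tibble from [annual_abundance()].
#' @param cmr Optional comparison table, e.g. [tonquin_cmr_estimates()].
#' @return A ggplot object.
#' @export
plot_annual_estimates <- function(estimates, cmr = NULL) {
  p <- ggplot2::ggplot(
    estimates,
    ggplot2::aes(x = .data$year, y = .data$estimate)
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      colour = "firebrick"
    ) +
    ggplot2::labs(x = "survey year",
                  y = "reproductive female abundance")
  if (!is.null(cmr)) {
    p <- p + ggplot2::geom_pointrange(
      data = cmr,
      ggplot2::aes(x = .data$year, y = .data$cmr_n_f,
                   ymin = .data$cmr_n_f_low, ymax = .data$cmr_n_f_high),
      colour = "steelblue",
      position = ggplot2::position_nudge(x = 0.2)
    )
  }
  p
}
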