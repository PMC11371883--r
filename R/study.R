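#' Run one simulate-sample-estimate replicate
#'
#' Composes the full single-survey pipeline: [init_population()],
#' [birth_pulse()], [survival_step()], [draw_sample()],
#' [tabulate_comparisons()], [maximize_pseudolikelihood()] and
#' [profile_confidence_interval()]. Deterministic given `seed`.
#'
#' @param config A [population_config()]; its `n_reproductive` is the true
#'   abundance being recovered.
#' @param proportion Sampling fraction in (0, 1].
#' @param seed Integer seed for this replicate.
#' @param search_low,search_high Search bounds for the estimator;
#'   `search_high` defaults to ten times the configured true abundance.
#' @param compute_ci Compute the profile interval (set `FALSE` to skip the
#'   root finding when only point estimates are needed).
#' @param estimate Maximize the pseudolikelihood at all (set `FALSE` when
#'   only the observed pair count is of interest).
#' @return A one-row tibble with the truth, observed pair and comparison
#'   counts, the estimate, interval, coverage indicator and flags.
#' @examples
#' run_replicate(population_config(250), 0.5, seed = 1)
#' @export
run_replicate <- function(config, proportion, seed,
                          search_low = 10,
                          search_high = 10 * config$n_reproductive,
                          compute_ci = TRUE, estimate = TRUE) {
  res <- replicate_core(config, proportion, seed, search_low, search_high,
                        compute_ci, estimate)
  new_tibble(as.list(res), nrow = 1L)
}

# numeric-vector core shared by run_replicate() and run_cell(); avoids
# building a tibble per replicate inside Monte-Carlo loops
replicate_core <- function(config, proportion, seed, search_low,
                           search_high, compute_ci, estimate) {
  set.seed(seed)
  pop <- simulate_population(config)
  smp <- draw_sample(pop, proportion)
  tab <- tabulate_comparisons(pop, smp)
  mop <- tab$y1 + tab$y3
  out <- list(true_n_f = as.double(config$n_reproductive),
              proportion = proportion, seed = as.double(seed),
              n_comparisons = tab$n, mop = mop,
              n_hat = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              covered = NA, at_upper_bound = NA, flat_likelihood = NA)
  if (!estimate) return(out)
  fit <- maximize_pseudolikelihood(tab, config$rates, search_low,
                                   search_high)
  out$n_hat <- fit$n_hat
  out$at_upper_bound <- fit$at_upper_bound
  out$flat_likelihood <- fit$flat_likelihood
  if (compute_ci) {
    fit <- profile_confidence_interval(fit)
    out$ci_low <- fit$ci_low
    out$ci_high <- fit$ci_high
    out$covered <- fit$ci_low <= config$n_reproductive &
      config$n_reproductive <= fit$ci_high
  }
  out
}

#' Monte-Carlo summary of one (population size, sampling fraction) cell
#'
#' Runs `replicates` independent replicates of the single-survey pipeline
#' and summarizes accuracy, precision and interval coverage. Replicate
#' seeds are `master_seed + 1, ..., master_seed + replicates`.
#'
#' @inheritParams run_replicate
#' @param replicates Number of Monte-Carlo replicates (>= 2).
#' @param master_seed Integer; base of the per-replicate seed sequence.
#' @param keep_replicates Also return the per-replicate table.
#' @return A one-row tibble with columns `n_f`, `proportion`,
#'   `replicates`, `flat_fraction`, `mean_mop`, `mean_n_hat`, `sd_n_hat`,
#'   `cv`, `q2_5`, `q97_5` (central 95% band of the estimates),
#'   `mean_bias`, `median_bias` (proportional relative bias,
#'   (est - truth)/truth) and `coverage`. With `keep_replicates = TRUE`,
#'   a list with elements `summary` and `replicates`.
#'
#'   Replicates whose sample contained no calf x reproductive-female
#'   comparison at all have a flat likelihood and carry no information
#'   about abundance; they enter `mean_mop` (their pair count is a true
#'   zero) but are excluded from all estimator summaries, and their share
#'   is reported as `flat_fraction`.
#' @examples
#' run_cell(population_config(250), 0.5, replicates = 50, master_seed = 1)
#' @export
run_cell <- function(config, proportion, replicates, master_seed,
                     search_low = 10,
                     search_high = 10 * config$n_reproductive,
                     compute_ci = TRUE, estimate = TRUE,
                     keep_replicates = FALSE) {
  stopifnot(replicates >= 2)
  rows <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    rows[[i]] <- replicate_core(config, proportion, master_seed + i,
                                search_low, search_high, compute_ci,
                                estimate)
  }
  rep_tbl <- dplyr::bind_rows(rows)
  n_f <- config$n_reproductive
  # replicates whose sample held no calf x female comparison carry no
  # information about abundance (flat likelihood); they are excluded from
  # the estimator summaries but kept in the pair-count mean
  est_tbl <- rep_tbl[!isTRUE_vec(rep_tbl$flat_likelihood), , drop = FALSE]
  bias <- (est_tbl$n_hat - n_f) / n_f
  qs <- if (all(is.na(est_tbl$n_hat))) c(NA_real_, NA_real_) else
    stats::quantile(est_tbl$n_hat, c(0.025, 0.975), names = FALSE,
                    na.rm = TRUE, type = 7)
  summary <- tibble(
    n_f = as.double(n_f), proportion = proportion,
    replicates = as.double(replicates),
    flat_fraction = mean(isTRUE_vec(rep_tbl$flat_likelihood)),
    mean_mop = mean(rep_tbl$mop),
    mean_n_hat = mean(est_tbl$n_hat),
    sd_n_hat = stats::sd(est_tbl$n_hat),
    cv = stats::sd(est_tbl$n_hat) / mean(est_tbl$n_hat),
    q2_5 = qs[1], q97_5 = qs[2],
    mean_bias = mean(bias),
    median_bias = stats::median(bias),
    coverage = if (estimate && compute_ci) mean(est_tbl$covered)
               else NA_real_
  )
  if (keep_replicates) list(summary = summary, replicates = rep_tbl)
  else summary
}

isTRUE_vec <- function(x) !is.na(x) & x %in% TRUE

#' Run a grid of simulation-study cells
#'
#' Evaluates [run_cell()] on every combination of population size and
#' sampling fraction and binds the summaries into one long-format tibble
#' (one row per cell). Cell seeds are derived from `master_seed` so that
#' no two cells share replicate seeds. If `out_csv` is given, each cell is
#' appended to the file as it completes and already-present cells are
#' skipped on a rerun, making long grids resumable.
#'
#' @param population_sizes Integer vector of true abundances \eqn{N_F}.
#' @param proportions Vector of sampling fractions in (0, 1).
#' @param replicates Replicates per cell.
#' @param master_seed Integer master seed.
#' @param subadult_fraction,yearling_fraction,rates Passed to
#'   [population_config()] for every cell.
#' @param compute_ci,estimate Passed to [run_cell()].
#' @param out_csv Optional path for incremental long-format CSV output.
#' @return A tibble of cell summaries (see [run_cell()]).
#' @examples
#' run_grid(c(100, 250), c(0.25, 0.5), replicates = 20, master_seed = 1)
#' @export
run_grid <- function(population_sizes, proportions, replicates,
                     master_seed, subadult_fraction = 0.12,
                     yearling_fraction = 0.15,
                     rates = demographic_rates(),
                     compute_ci = TRUE, estimate = TRUE, out_csv = NULL) {
  cells <- tidyr::expand_grid(n_f = as.integer(population_sizes),
                              proportion = as.double(proportions))
  done <- NULL
  if (!is.null(out_csv) && file.exists(out_csv)) {
    done <- readr::read_csv(out_csv, show_col_types = FALSE)
    done$coverage <- as.double(done$coverage)  # all-NA column reads logical
  }
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    if (!is.null(done) &&
        any(done$n_f == cells$n_f[i] &
            abs(done$proportion - cells$proportion[i]) < 1e-12)) {
      out[[i]] <- done[done$n_f == cells$n_f[i] &
                         abs(done$proportion - cells$proportion[i]) < 1e-12, ]
      next
    }
    cfg <- population_config(cells$n_f[i], subadult_fraction,
                             yearling_fraction, rates)
    cell <- run_cell(cfg, cells$proportion[i], replicates,
                     master_seed = master_seed + (i - 1) * replicates,
                     compute_ci = compute_ci, estimate = estimate)
    if (!is.null(out_csv)) {
      readr::write_csv(cell, out_csv, append = file.exists(out_csv))
    }
    out[[i]] <- cell
  }
  dplyr::bind_rows(out)
}

#' Plot a simulation-study grid summary
#'
#' Line plot of one summary metric against the sampling fraction, one
#' colour per population size; the natural companion to [run_grid()].
#'
#' @param grid_summary A tibble from [run_grid()].
#' @param metric Column to plot (default `"mean_bias"`).
#' @return A ggplot object.
#' @export
plot_grid_summary <- function(grid_summary, metric = "mean_bias") {
  stopifnot(metric %in% names(grid_summary))
  ggplot2::ggplot(
    grid_summary,
    ggplot2::aes(x = .data$proportion, y = .data[[metric]],
                 colour = factor(.data$n_f), group = factor(.data$n_f))
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "proportion of survivors sampled", y = metric,
                  colour = expression(N[F]))
}
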