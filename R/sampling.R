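#' Draw the single winter survey sample
#'
#' Samples a uniform random subset, without replacement, of all survivors
#' (all stages, calves included) at the nominal sampling fraction. The
#' realized sample size is round-half-up of `proportion` times the number
#' of survivors.
#'
#' @param population A population tibble in phase `"post_survival"`.
#' @param proportion Nominal sampling fraction in (0, 1].
#' @return A tibble of the sampled individuals (rows of `population`,
#'   sorted by id) with attributes `proportion` and `sample_size`.
#' @examples
#' set.seed(7)
#' pop <- simulate_population(population_config(100))
#' smp <- draw_sample(pop, 0.25)
#' nrow(smp)
#' @export
draw_sample <- function(population, proportion) {
  check_phase(population, "post_survival", "draw_sample")
  if (!is.numeric(proportion) || length(proportion) != 1 ||
      !is.finite(proportion) || proportion <= 0 || proportion > 1) {
    stop("`proportion` must lie in (0, 1]", call. = FALSE)
  }
  survivors <- which(population$alive)
  if (!length(survivors)) {
    stop("no survivors to sample from", call. = FALSE)
  }
  size <- round_half_up(proportion * length(survivors))
  take <- sort(survivors[sample.int(length(survivors), size)])
  out <- population[take, ]
  attr(out, "phase") <- NULL
  attr(out, "proportion") <- proportion
  attr(out, "sample_size") <- size
  class(out) <- setdiff(class(out), "kinabund_population")
  out
}

#' Tabulate pairwise kinship comparisons from a survey sample
#'
#' Forms every pairwise comparison between the sampled calves and the
#' sampled reproductive females (subadults and adults); sampled yearlings
#' are excluded because they are neither part of the calf cohort nor able
#' to have bred. A comparison is a mother-calf pair iff the calf's
#' `mother_id` equals the female's id. Comparisons are partitioned by the
#' female's stage into the four outcome categories of the multinomial
#' pseudolikelihood.
#'
#' @param population The post-survival population (pedigree source).
#' @param sample A sample drawn with [draw_sample()], or any subset of the
#'   population's rows.
#' @return A one-row tibble with columns
#'   `n_s`, `n_a` (comparisons involving a sampled subadult / adult),
#'   `y1`, `y2` (subadult-comparison pairs / non-pairs),
#'   `y3`, `y4` (adult-comparison pairs / non-pairs),
#'   `A` (proportion of adults among sampled reproductive females; `NA`
#'   when none is sampled) and `n` (total comparisons).
#' @examples
#' set.seed(7)
#' pop <- simulate_population(population_config(250))
#' tabulate_comparisons(pop, draw_sample(pop, 0.5))
#' @export
tabulate_comparisons <- function(population, sample) {
  check_phase(population, "post_survival", "tabulate_comparisons")
  calves <- sample[sample$stage == "calf", , drop = FALSE]
  sub_ids <- sample$id[sample$stage == "subadult"]
  ad_ids <- sample$id[sample$stage == "adult"]
  n_c <- nrow(calves)
  n_sub <- length(sub_ids)
  n_ad <- length(ad_ids)
  y1 <- sum(calves$mother_id %in% sub_ids)
  y3 <- sum(calves$mother_id %in% ad_ids)
  n_s <- n_c * n_sub
  n_a <- n_c * n_ad
  comparison_table(
    n_s = n_s, n_a = n_a,
    y1 = y1, y2 = n_s - y1, y3 = y3, y4 = n_a - y3,
    A = if (n_sub + n_ad > 0) n_ad / (n_sub + n_ad) else NA_real_
  )
}

#' Build a comparison table from counts
#'
#' Assembles the stage-stratified comparison counts consumed by
#' [log_pseudolikelihood()] and [maximize_pseudolikelihood()] directly,
#' e.g. for field data where the counts are already tabulated. For a
#' single-stage (adults only) survey set `n_s = 0` and `A = 1`.
#'
#' @param n_s,n_a Number of comparisons involving a sampled subadult /
#'   adult female.
#' @param y1,y2 Subadult comparisons that are / are not mother-calf pairs
#'   (`y1 + y2` must equal `n_s`).
#' @param y3,y4 Adult comparisons that are / are not mother-calf pairs
#'   (`y3 + y4` must equal `n_a`).
#' @param A Proportion of adults among the sampled reproductive females.
#' @return A one-row tibble of class `comparison_table`.
#' @examples
#' comparison_table(n_s = 0, n_a = 176, y1 = 0, y2 = 0, y3 = 8, y4 = 168,
#'                  A = 1)
#' @export
comparison_table <- function(n_s, n_a, y1, y2, y3, y4, A) {
  counts <- c(n_s, n_a, y1, y2, y3, y4)
  if (any(counts < 0)) stop("comparison counts must be >= 0", call. = FALSE)
  if (y1 + y2 != n_s || y3 + y4 != n_a) {
    stop("counts inconsistent: need y1 + y2 == n_s and y3 + y4 == n_a",
         call. = FALSE)
  }
  if (!is.na(A) && (A < 0 || A > 1)) {
    stop("`A` must lie in [0, 1]", call. = FALSE)
  }
  new_tibble(
    list(n_s = as.double(n_s), n_a = as.double(n_a),
         y1 = as.double(y1), y2 = as.double(y2),
         y3 = as.double(y3), y4 = as.double(y4),
         A = as.double(A), n = as.double(n_s + n_a)),
    nrow = 1L, class = "comparison_table"
  )
}

#' Expected number of sampled mother-offspring pairs
#'
#' Closed-form expectation of the number of mother-calf pairs with both
#' members sampled, under an independent-sampling approximation: each of
#' the two pair members is sampled with probability `proportion`, a
#' reproductive female of stage s produces `f` calves with probability
#' `b_s`, survives with probability `phi_s`, and each calf survives with
#' probability `phi_c`:
#' \deqn{E[MOP] = p^2 \, f\, \phi_c \sum_s n_s\, b_s\, \phi_s.}
#' Used as the analytic oracle for the Monte-Carlo mean of observed pairs.
#'
#' @param config A [population_config()].
#' @param proportion Sampling fraction in \[0, 1\].
#' @return Expected pair count (double).
#' @examples
#' expected_mop(population_config(1000), 0.25)  # about 16.3
#' @export
expected_mop <- function(config, proportion) {
  stopifnot(inherits(config, "population_config"))
  if (proportion < 0 || proportion > 1) {
    stop("`proportion` must lie in [0, 1]", call. = FALSE)
  }
  r <- config$rates
  n_sub <- round_half_up(config$n_reproductive * config$subadult_fraction)
  n_ad <- config$n_reproductive - n_sub
  proportion^2 * r$f * r$phi_c *
    (n_sub * r$b_s * r$phi_s + n_ad * r$b_a * r$phi_a)
}
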