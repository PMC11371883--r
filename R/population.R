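#' @importFrom tibble tibble as_tibble new_tibble
NULL

STAGES <- c("calf", "yearling", "subadult", "adult")
PHASES <- c("pre_birth", "post_birth", "post_survival")

new_population <- function(id, stage, alive, mother_id, phase) {
  out <- new_tibble(
    list(id = as.integer(id), stage = stage, alive = alive,
         mother_id = as.integer(mother_id)),
    nrow = length(id),
    class = "kinabund_population"
  )
  attr(out, "phase") <- phase
  out
}

#' Coerce a data frame of individuals to a population state
#'
#' Validates and tags a data frame of individual records (columns `id`,
#' `stage`, `alive`, `mother_id`) so it can be used with [birth_pulse()],
#' [survival_step()] and [draw_sample()]. `mother_id` is `NA` for founders
#' and must resolve to a reproductive female for calves.
#'
#' @param x A data frame with columns `id` (unique integers), `stage`
#'   (one of `"calf"`, `"yearling"`, `"subadult"`, `"adult"`), `alive`
#'   (logical) and `mother_id` (integer or `NA`).
#' @param phase Annual-cycle phase of the snapshot: `"pre_birth"`,
#'   `"post_birth"` or `"post_survival"`.
#' @return A population tibble (one row per individual).
#' @examples
#' as_population(
#'   data.frame(id = 1:2, stage = c("adult", "calf"),
#'              alive = TRUE, mother_id = c(NA, 1L)),
#'   phase = "post_birth"
#' )
#' @export
as_population <- function(x, phase = c("pre_birth", "post_birth",
                                       "post_survival")) {
  phase <- match.arg(phase)
  x <- as_tibble(x)
  required <- c("id", "stage", "alive", "mother_id")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("missing population columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$id)) stop("individual ids must be unique", call. = FALSE)
  if (!all(x$stage %in% STAGES)) {
    stop("`stage` must be one of: ", paste(STAGES, collapse = ", "),
         call. = FALSE)
  }
  is_calf <- x$stage == "calf"
  if (phase == "pre_birth" && any(is_calf)) {
    stop("a pre-birth population cannot contain calves", call. = FALSE)
  }
  if (any(is.na(x$mother_id[is_calf]))) {
    stop("every calf must carry a `mother_id`", call. = FALSE)
  }
  if (any(!is.na(x$mother_id[!is_calf]))) {
    stop("`mother_id` must be NA for non-calves (founders)", call. = FALSE)
  }
  mothers <- match(x$mother_id[is_calf], x$id)
  if (any(is.na(mothers)) ||
      !all(x$stage[mothers] %in% c("subadult", "adult"))) {
    stop("each calf's `mother_id` must refer to a subadult or adult female",
         call. = FALSE)
  }
  new_population(x$id, x$stage, as.logical(x$alive), x$mother_id, phase)
}

#' Annual-cycle phase of a population snapshot
#'
#' @param population A population tibble.
#' @return `"pre_birth"`, `"post_birth"` or `"post_survival"`.
#' @export
population_phase <- function(population) {
  phase <- attr(population, "phase", exact = TRUE)
  if (is.null(phase)) stop("not a population state; see `as_population()`",
                           call. = FALSE)
  phase
}

check_phase <- function(population, expected, op) {
  phase <- population_phase(population)
  if (phase != expected) {
    stop(sprintf("`%s()` requires a %s population, got %s",
                 op, expected, phase), call. = FALSE)
  }
  invisible(phase)
}

#' Initialize a population just before the birth pulse
#'
#' Creates the founder females of one simulated annual cycle: subadults and
#' adults (together the \eqn{N_F} reproductive females) plus
#' non-reproductive yearlings, all alive, with no calves yet. Stage counts
#' are round-half-up on the configured fractions with adults absorbing the
#' remainder. Ids are assigned 1..N in order subadult, adult, yearling.
#'
#' @param config A [population_config()].
#' @return A population tibble in phase `"pre_birth"`.
#' @examples
#' pop <- init_population(population_config(100))
#' table(pop$stage)
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  n_f <- config$n_reproductive
  n_sub <- round_half_up(n_f * config$subadult_fraction)
  n_ad <- n_f - n_sub
  n_yr <- round_half_up(n_f * config$yearling_fraction)
  n <- n_sub + n_ad + n_yr
  new_population(
    id = seq_len(n),
    stage = rep(c("subadult", "adult", "yearling"), c(n_sub, n_ad, n_yr)),
    alive = rep(TRUE, n),
    mother_id = rep(NA_integer_, n),
    phase = "pre_birth"
  )
}

#' Simulate the summer birth pulse
#'
#' Each living reproductive female breeds independently: a subadult with
#' probability `b_s`, an adult with probability `b_a`, yearlings never.
#' Every successful breeder produces exactly `f` calves that carry her id
#' as `mother_id`. Founders are unchanged; calves are appended with ids
#' above all existing ids.
#'
#' Bernoulli breeding draws consume the R random stream in ascending-id
#' order, so results are bit-reproducible under [set.seed()].
#'
#' @param population A population tibble in phase `"pre_birth"`.
#' @param rates A [demographic_rates()] object.
#' @return A population tibble in phase `"post_birth"`.
#' @examples
#' set.seed(1)
#' pop <- init_population(population_config(100)) |>
#'   birth_pulse(demographic_rates())
#' sum(pop$stage == "calf")
#' @export
birth_pulse <- function(population, rates = demographic_rates()) {
  check_phase(population, "pre_birth", "birth_pulse")
  stopifnot(inherits(rates, "demographic_rates"))
  ord <- order(population$id)
  stage <- population$stage[ord]
  alive <- population$alive[ord]
  id <- population$id[ord]
  repro <- alive & stage %in% c("subadult", "adult")
  p <- ifelse(stage[repro] == "subadult", rates$b_s, rates$b_a)
  bred <- stats::rbinom(sum(repro), 1L, p) == 1L
  mothers <- id[repro][bred]
  n_calves <- length(mothers) * rates$f
  calf_mothers <- rep(mothers, each = rates$f)
  next_id <- if (length(id)) max(id) else 0L
  new_population(
    id = c(id, next_id + seq_len(n_calves)),
    stage = c(stage, rep("calf", n_calves)),
    alive = c(alive, rep(TRUE, n_calves)),
    mother_id = c(population$mother_id[ord], calf_mothers),
    phase = "post_birth"
  )
}

#' Simulate six months of survival up to the winter survey
#'
#' Each individual survives independently with its stage-specific six-month
#' probability. Dead individuals are retained with `alive = FALSE` so that
#' the maternity link of a surviving calf to a dead mother remains
#' resolvable. No stage transitions occur within the cycle. Survival draws
#' consume the random stream in ascending-id order.
#'
#' @param population A population tibble in phase `"post_birth"`.
#' @param rates A [demographic_rates()] object.
#' @return A population tibble in phase `"post_survival"`.
#' @export
survival_step <- function(population, rates = demographic_rates()) {
  check_phase(population, "post_birth", "survival_step")
  stopifnot(inherits(rates, "demographic_rates"))
  ord <- order(population$id)
  stage <- population$stage[ord]
  alive <- population$alive[ord]
  phi <- c(calf = rates$phi_c, yearling = rates$phi_y,
           subadult = rates$phi_s, adult = rates$phi_a)[stage]
  survived <- stats::rbinom(length(stage), 1L, phi) == 1L
  new_population(
    id = population$id[ord],
    stage = stage,
    alive = alive & survived,
    mother_id = population$mother_id[ord],
    phase = "post_survival"
  )
}

#' Run one full annual cycle
#'
#' Convenience wrapper composing [init_population()], [birth_pulse()] and
#' [survival_step()] into the complete simulated cycle: founders just
#' before the birth pulse, calving, then six months of mortality up to the
#' winter survey.
#'
#' @param config A [population_config()].
#' @return A population tibble in phase `"post_survival"`.
#' @examples
#' set.seed(42)
#' pop <- simulate_population(population_config(250))
#' dplyr::count(pop, stage, alive)
#' @export
simulate_population <- function(config) {
  init_population(config) |>
    birth_pulse(config$rates) |>
    survival_step(config$rates)
}
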