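test_that("initial stage composition follows round-half-up with adults absorbing the remainder", {
  cases <- list(
    list(n_f = 100, sub = 12, ad = 88, yr = 15, total = 115),
    list(n_f = 50, sub = 6, ad = 44, yr = 8, total = 58),
    list(n_f = 1000, sub = 120, ad = 880, yr = 150, total = 1150)
  )
  for (cs in cases) {
    pop <- init_population(population_config(cs$n_f))
    counts <- table(pop$stage)
    expect_equal(unname(counts[["subadult"]]), cs$sub)
    expect_equal(unname(counts[["adult"]]), cs$ad)
    expect_equal(unname(counts[["yearling"]]), cs$yr)
    expect_equal(nrow(pop), cs$total)
    expect_true(all(pop$alive))
    expect_identical(population_phase(pop), "pre_birth")
    expect_false(anyDuplicated(pop$id) > 0)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(population_config(0), "positive integer")
  expect_error(population_config(-5), "positive integer")
  expect_error(population_config(10, subadult_fraction = 1.2), "\\[0, 1\\]")
  expect_error(demographic_rates(b_a = 1.5), "\\[0, 1\\]")
  expect_error(demographic_rates(f = 0.5), "non-negative integer")
})

test_that("degenerate breeding rates give deterministic calf counts", {
  cfg <- population_config(10)
  pop <- init_population(cfg)
  none <- birth_pulse(pop, demographic_rates(b_s = 0, b_a = 0))
  expect_equal(sum(none$stage == "calf"), 0)
  all_breed <- birth_pulse(pop, demographic_rates(b_s = 1, b_a = 1))
  calves <- all_breed[all_breed$stage == "calf", ]
  expect_equal(nrow(calves), 10)
  expect_equal(sort(calves$mother_id),
               sort(pop$id[pop$stage %in% c("subadult", "adult")]))
  expect_identical(population_phase(all_breed), "post_birth")
})

test_that("birth pulse conserves founders and adds one calf per breeder", {
  cfg <- population_config(200)
  for (seed in 1:5) {
    set.seed(seed)
    pre <- init_population(cfg)
    post <- birth_pulse(pre, cfg$rates)
    n_calves <- sum(post$stage == "calf")
    expect_equal(nrow(post), nrow(pre) + n_calves)
    founders <- post[post$stage != "calf", ]
    expect_equal(founders$id, pre$id)
    expect_equal(founders$stage, pre$stage)
    # every calf's mother resolves to exactly one reproductive founder
    calves <- post[post$stage == "calf", ]
    m <- match(calves$mother_id, post$id)
    expect_false(anyNA(m))
    expect_true(all(post$stage[m] %in% c("subadult", "adult")))
  }
})

test_that("phase contract is enforced", {
  cfg <- population_config(20)
  pre <- init_population(cfg)
  expect_error(survival_step(pre, cfg$rates), "post_birth")
  post <- birth_pulse(pre, cfg$rates)
  expect_error(birth_pulse(post, cfg$rates), "pre_birth")
  expect_error(draw_sample(post, 0.5), "post_survival")
})

test_that("survival step retains the dead and respects degenerate rates", {
  cfg <- population_config(50)
  set.seed(1)
  post_birth <- birth_pulse(init_population(cfg), cfg$rates)
  immortal <- survival_step(post_birth, demographic_rates(
    phi_c = 1, phi_y = 1, phi_s = 1, phi_a = 1))
  expect_true(all(immortal$alive))
  expect_equal(nrow(immortal), nrow(post_birth))
  no_calves <- survival_step(post_birth, demographic_rates(phi_c = 0))
  expect_equal(sum(no_calves$alive & no_calves$stage == "calf"), 0)
  expect_equal(nrow(no_calves), nrow(post_birth))  # dead rows retained
  expect_identical(population_phase(no_calves), "post_survival")
})

test_that("Monte-Carlo means of breeders and survivors match binomial expectations", {
  cfg <- population_config(1000)
  reps <- 400
  calves <- survivors <- numeric(reps)
  for (i in seq_len(reps)) {
    set.seed(i)
    pop <- birth_pulse(init_population(cfg), cfg$rates)
    calves[i] <- sum(pop$stage == "calf")
    pop <- survival_step(pop, cfg$rates)
    survivors[i] <- sum(pop$alive & pop$stage == "calf")
  }
  # E[calves] = 120 * 0.15 + 880 * 0.90 = 810; E[surviving calves] = 283.5
  expect_lt(abs(mean(calves) - 810), 3 * sd(calves) / sqrt(reps))
  expect_lt(abs(mean(survivors) - 283.5), 3 * sd(survivors) / sqrt(reps))
})

test_that("the full annual cycle is reproducible under a fixed seed", {
  cfg <- population_config(150)
  set.seed(99)
  a <- simulate_population(cfg)
  set.seed(99)
  b <- simulate_population(cfg)
  expect_identical(a, b)
})

test_that("as_population validates pedigree and phase consistency", {
  expect_error(
    as_population(data.frame(id = 1:2, stage = c("adult", "calf"),
                             alive = TRUE, mother_id = c(NA, 1L)),
                  phase = "pre_birth"),
    "cannot contain calves")
  expect_error(
    as_population(data.frame(id = 1:2, stage = c("yearling", "calf"),
                             alive = TRUE, mother_id = c(NA, 1L)),
                  phase = "post_birth"),
    "subadult or adult")
  expect_error(
    as_population(data.frame(id = c(1, 1), stage = "adult", alive = TRUE,
                             mother_id = NA_integer_)),
    "unique")
})
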