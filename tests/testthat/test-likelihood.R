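test_that("kinship probabilities match direct substitution and normalize to 1/N_F", {
  r <- demographic_rates()
  q <- kinship_probabilities(100, r, A = 1)
  expect_equal(q$q_a, 1 / 100)            # denominator reduces to N_F b_a f
  expect_equal(q$q_s, 0.15 / (100 * 0.9))  # = 1/600
  # normalization holds for arbitrary valid inputs, to machine precision
  set.seed(42)
  for (i in 1:25) {
    n_f <- runif(1, 5, 5000)
    A <- runif(1)
    qq <- kinship_probabilities(n_f, r, A)
    expect_equal((1 - A) * qq$q_s + A * qq$q_a, 1 / n_f,
                 tolerance = 1e-12)
    expect_true(qq$q_s <= qq$q_a)
  }
})

test_that("fecundity cancels from probabilities and from the estimate", {
  A <- 0.8
  q1 <- kinship_probabilities(300, demographic_rates(f = 1), A)
  q2 <- kinship_probabilities(300, demographic_rates(f = 2), A)
  expect_equal(q1$q_s, q2$q_s)
  expect_equal(q1$q_a, q2$q_a)
  tab <- comparison_table(40, 160, 1, 39, 6, 154, A = 0.8)
  f1 <- maximize_pseudolikelihood(tab, demographic_rates(f = 1),
                                  search_high = 2000)
  f2 <- maximize_pseudolikelihood(tab, demographic_rates(f = 3),
                                  search_high = 2000)
  expect_equal(f1$n_hat, f2$n_hat, tolerance = 1e-6)
})

test_that("degenerate rates are rejected", {
  expect_error(kinship_probabilities(100, demographic_rates(b_s = 0, b_a = 0),
                                     A = 0.5),
               "degenerate")
})

test_that("log pseudolikelihood reduces to a binomial at A = 1 and is flat at n = 0", {
  tab <- adult_table(100, 7)
  grid <- c(20, 50, 120)
  ll <- log_pseudolikelihood(tab, grid)
  binom <- 7 * log(1 / grid) + 93 * log(1 - 1 / grid)
  expect_equal(ll, binom)
  empty <- comparison_table(0, 0, 0, 0, 0, 0, A = NA)
  expect_equal(log_pseudolikelihood(empty, grid), rep(0, 3))
})

test_that("infeasibly small candidates return -Inf, not an error", {
  tab <- adult_table(50, 5)
  expect_identical(log_pseudolikelihood(tab, 0.5), -Inf)
  # subadult-heavy mixture: q_s exceeds 1 for small n_f
  mix <- comparison_table(30, 10, 2, 28, 1, 9, A = 0.25)
  ll <- log_pseudolikelihood(mix, c(0.05, 500))
  expect_identical(ll[1], -Inf)
  expect_true(is.finite(ll[2]))
})

test_that("maximizer recovers the closed-form single-stage MLE n/k", {
  cases <- list(c(100, 4, 25), c(176, 8, 22), c(96, 3, 32), c(250, 10, 25))
  for (cs in cases) {
    fit <- maximize_pseudolikelihood(adult_table(cs[1], cs[2]),
                                     search_high = 5000)
    expect_equal(fit$n_hat, cs[3], tolerance = 1e-3)
    expect_false(fit$at_upper_bound)
  }
})

test_that("continuous optimizer agrees with an exhaustive fine-grid search", {
  set.seed(7)
  r <- demographic_rates()
  for (i in 1:8) {
    n_s <- sample(0:150, 1)
    n_a <- sample(10:350, 1)
    y1 <- rbinom(1, min(n_s, 5), 0.5)
    y3 <- rbinom(1, min(n_a, 12), 0.5) + 1  # at least one pair
    A <- n_a / (n_s + n_a)
    tab <- comparison_table(n_s, n_a, y1, n_s - y1, y3, n_a - y3, A = A)
    fit <- maximize_pseudolikelihood(tab, r, search_high = 3000)
    grid <- seq(10, 3000, by = 0.01)
    ll <- log_pseudolikelihood(tab, grid, r)
    expect_lt(abs(fit$n_hat - grid[which.max(ll)]), 0.1)
  }
})

test_that("more observed pairs never increase the estimate", {
  prev <- Inf
  for (k in c(1, 2, 4, 8, 16)) {
    fit <- maximize_pseudolikelihood(adult_table(400, k), search_high = 5000)
    expect_lte(fit$n_hat, prev + 1e-6)
    prev <- fit$n_hat
  }
})

test_that("zero pairs and empty tables hit the upper search bound with flags", {
  no_pairs <- maximize_pseudolikelihood(adult_table(140, 0),
                                        search_high = 500)
  expect_equal(no_pairs$n_hat, 500)
  expect_true(no_pairs$at_upper_bound)
  expect_false(no_pairs$flat_likelihood)
  flat <- maximize_pseudolikelihood(comparison_table(0, 0, 0, 0, 0, 0, NA),
                                    search_high = 500)
  expect_equal(flat$n_hat, 500)
  expect_true(flat$flat_likelihood)
  ci <- profile_confidence_interval(flat)
  expect_equal(c(ci$ci_low, ci$ci_high), c(10, 500))
  expect_true(ci$ci_low_clamped && ci$ci_high_clamped)
  expect_error(maximize_pseudolikelihood(adult_table(10, 1),
                                         search_low = 50, search_high = 10),
               "search_low < search_high")
})

test_that("profile interval brackets the 1.92-unit drop on both sides", {
  fit <- estimate_abundance(adult_table(176, 8), search_high = 2000)
  expect_equal(round(fit$ci_low), 12)
  expect_equal(round(fit$ci_high), 48)
  drop <- qchisq(0.95, 1) / 2
  for (b in c(fit$ci_low, fit$ci_high)) {
    expect_equal(log_pseudolikelihood(fit$comparisons, b) ,
                 fit$log_lik - drop, tolerance = 1e-6)
  }
  expect_true(fit$ci_low <= fit$n_hat && fit$n_hat <= fit$ci_high)
  # a single observed pair gives an upper bound of order 10^3
  wide <- estimate_abundance(adult_table(140, 1), search_high = 1e5)
  expect_gt(wide$ci_high, 1000)
  expect_lt(wide$ci_high, 1e4)
})

test_that("all-pairs tables are handled at the lower search bound", {
  fit <- estimate_abundance(adult_table(12, 12), search_low = 1.5,
                            search_high = 100)
  expect_true(fit$at_lower_bound)
  expect_equal(fit$ci_low, 1.5)
  expect_true(fit$ci_low_clamped)
  expect_gt(fit$ci_high, fit$n_hat)
})

test_that("tidy, glance and autoplot expose the fit", {
  fit <- estimate_abundance(adult_table(176, 8), search_high = 2000)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "ci_low", "ci_high",
                     "at_lower_bound", "at_upper_bound",
                     "flat_likelihood"))
  expect_equal(td$estimate, fit$n_hat)
  gl <- glance(fit)
  expect_equal(gl$n_pairs, 8)
  expect_s3_class(autoplot(fit), "ggplot")
})
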