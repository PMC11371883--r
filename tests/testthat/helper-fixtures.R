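# small hand-built population snapshots for exact, enumerable checks

# post-survival population: two adults (one mothered the calf), one calf,
# one subadult, one yearling, one dead adult
toy_post_survival <- function() {
  as_population(
    data.frame(
      id = 1:6,
      stage = c("adult", "adult", "subadult", "yearling", "calf", "adult"),
      alive = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
      mother_id = c(NA, NA, NA, NA, 1L, NA)
    ),
    phase = "post_survival"
  )
}

# a post-survival population with exactly n alive yearlings (no pedigree)
plain_survivors <- function(n) {
  as_population(
    data.frame(id = seq_len(n), stage = "yearling", alive = TRUE,
               mother_id = NA_integer_),
    phase = "post_survival"
  )
}

# single-stage comparison table: n adult comparisons, k pairs
adult_table <- function(n, k) {
  comparison_table(n_s = 0, n_a = n, y1 = 0, y2 = 0, y3 = k, y4 = n - k,
                   A = 1)
}
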