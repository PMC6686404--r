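# helper: hand-built depth-2 tree shaped like the published two-tone rule
toy_two_tone_tree <- function() {
  samples <- data.frame(
    hz500 = c(30, 30, 60, 50, 30, 55),
    hz1000 = c(30, 30, 60, 50, 30, 55),
    hz2000 = c(30, 40, 60, 50, 35, 55),
    hz4000 = c(30, 40, 60, 55, 35, 60),
    label = factor(c("negative", "negative", "positive", "positive",
                     "negative", "positive"),
                   levels = c("negative", "positive")))
  fit_tree(samples)
}

test_that("tone levels are floored split thresholds by default", {
  x <- cbind(0, 0, c(40, 40, 45, 45), 0)  # 2 kHz split at midpoint 42.5
  tr <- fit_tree(x, c(0, 0, 1, 1))
  expect_equal(tr$root$freq_khz, 2)
  expect_equal(tr$root$threshold, 42.5)
  rule <- extract_rule(tr)
  expect_equal(rule$root$freq_khz, 2)
  expect_equal(rule$root$level, 42)
  # nearest rounding rounds the midpoint up
  expect_equal(extract_rule(tr, "nearest")$root$level, 42)
  expect_equal(extract_rule(tr, "exact")$root$level, 42.5)

  x2 <- cbind(c(45, 45, 50, 50), 0, 0, 0)  # 0.5 kHz split at midpoint 47.5
  tr2 <- fit_tree(x2, c(0, 0, 1, 1))
  expect_equal(extract_rule(tr2)$root$level, 47)
})

test_that("tree branch polarity maps onto heard/not-heard correctly", {
  # threshold <= level means the tone is heard and the subject passes when
  # the leaf on the left (low-threshold side) is negative
  x <- cbind(0, 0, c(40, 40, 45, 45), 0)
  tr <- fit_tree(x, c(0, 0, 1, 1))
  rule <- extract_rule(tr)
  expect_equal(rule$root$heard$decision, "pass")
  expect_equal(rule$root$not_heard$decision, "refer")
})

test_that("a single-leaf tree yields a zero-tone constant rule", {
  tr <- fit_tree(matrix(60, 3, 4), c(1, 1, 1))
  rule <- extract_rule(tr)
  expect_equal(rule$root$type, "decision")
  res <- apply_rule(rule, c(0, 0, 0, 0))
  expect_equal(res$decision, "refer")
  expect_equal(res$tones, 0)
})

test_that("rules deeper than two tones are refused", {
  set.seed(9)
  samples <- random_samples(400, seed = 9)
  tr3 <- fit_tree(samples, max_depth = 3)
  skip_if(tree_depth(tr3) <= 2)  # random data nearly always gives depth 3
  expect_error(extract_rule(tr3), "depth")
})

test_that("administering the two-step protocol follows hearing responses", {
  rule <- fixed_cutoff_rule(c("2" = 42, "0.5" = 47), combine = "all")
  # hears the first tone: pass after one presentation
  r1 <- apply_rule(rule, audiogram(c(30, 30, 40, 50)))
  expect_equal(r1, list(decision = "pass", tones = 1L))
  # misses both tones: refer after two presentations
  r2 <- apply_rule(rule, audiogram(c(60, 55, 55, 60)))
  expect_equal(r2, list(decision = "refer", tones = 2L))
  # misses the first, hears the second: pass after two presentations
  r3 <- apply_rule(rule, audiogram(c(45, 40, 55, 60)))
  expect_equal(r3, list(decision = "pass", tones = 2L))
})

test_that("exact-level rules reproduce tree predictions everywhere", {
  for (s in 1:3) {
    co <- generate_cohort(small_profile(n = 250), seed = 40 + s)
    samples <- make_labeled_samples(co, "better")
    tr <- fit_tree(samples)
    rule <- extract_rule(tr, "exact")
    dec <- screen_cohort(rule, co, "better")$decision
    pred <- as.character(predict(tr, samples))
    expect_equal(dec == "refer", pred == "positive")
  }
})

test_that("floored levels stay decision-identical on 5-dB-quantized data", {
  # exhaustive sweep: all quantized threshold values against all midpoint
  # split positions representable on quantized data
  co <- generate_cohort(small_profile(n = 300), seed = 77)
  samples <- make_labeled_samples(co, "worse")
  tr <- fit_tree(samples)
  rule_f <- extract_rule(tr, "floor")
  rule_e <- extract_rule(tr, "exact")
  grid <- as.matrix(expand.grid(hz500 = seq(-10, 120, 5), hz1000 = 40,
                                hz2000 = seq(-10, 120, 5), hz4000 = 60))
  for (i in seq_len(nrow(grid))) {
    expect_identical(apply_rule(rule_f, grid[i, ])$decision,
                     apply_rule(rule_e, grid[i, ])$decision)
  }
})

test_that("fixed-cutoff combination semantics and dominance hold", {
  all_rule <- fixed_cutoff_rule(c("2" = 40, "1" = 40), combine = "all")
  any_rule <- fixed_cutoff_rule(c("2" = 40, "1" = 40), combine = "any")
  # misses both -> refer under both semantics
  expect_equal(apply_rule(all_rule, c(30, 45, 45, 50))$decision, "refer")
  # hears 1 kHz only -> pass under "all", refer under "any"
  expect_equal(apply_rule(all_rule, c(30, 35, 45, 50))$decision, "pass")
  expect_equal(apply_rule(any_rule, c(30, 35, 45, 50))$decision, "refer")
  # referral set of "any" contains that of "all" on a whole cohort
  co <- generate_cohort(small_profile(n = 300), seed = 13)
  d_all <- screen_cohort(all_rule, co, "better")$decision
  d_any <- screen_cohort(any_rule, co, "better")$decision
  expect_true(all(d_any[d_all == "refer"] == "refer"))
  expect_gte(sum(d_any == "refer"), sum(d_all == "refer"))
  expect_error(fixed_cutoff_rule(numeric(0)), "1-4")
  expect_error(fixed_cutoff_rule(c("3" = 40)), "frequencies")
})

test_that("depth-2 rules never present more than two tones", {
  co <- generate_cohort(small_profile(n = 200), seed = 21)
  tr <- fit_tree(make_labeled_samples(co, "better"))
  dec <- screen_cohort(extract_rule(tr), co, "better")
  expect_true(all(dec$tones_presented <= 2))
  expect_true(all(dec$tones_presented >= 1))
})

test_that("screening rules survive JSON serialization", {
  tr <- toy_two_tone_tree()
  rule <- extract_rule(tr, ear_mode = "better")
  f <- withr::local_tempfile(fileext = ".json")
  write_rule(rule, f)
  back <- read_rule(f)
  probe <- random_samples(50, seed = 3)
  for (i in 1:10) {
    v <- as.numeric(probe[i, 1:4])
    expect_identical(apply_rule(back, v), apply_rule(rule, v))
  }
  expect_equal(back$ear_mode, "better")
})
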