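test_that("standardization centers and scales with the n-1 SD convention", {
  tab <- data.frame(x = c(1, 2, 3), y = c(0, 0, 0))
  d <- study_design("y", singles = "x")
  st <- standardization_stats(tab, d)
  out <- standardize(tab, d, st)
  expect_equal(out$x, c(-1, 0, 1))  # sd(1,2,3) = 1 with n-1 denominator
  expect_equal(out$y, tab$y)        # outcome untouched
})

test_that("snp columns are exempt and restandardization is idempotent", {
  tab <- data.frame(y = rnorm(4), g = c(0, 1, 2, 2), x = rnorm(4))
  d <- study_design("y", singles = "x", categories = list(gen = "g"),
                    var_types = c(g = "snp"))
  st <- standardization_stats(tab, d)
  out <- standardize(tab, d, st)
  expect_identical(out$g, tab$g)
  # standardizing an already-standardized column with its own stats: no-op
  st2 <- standardization_stats(out, d)
  out2 <- standardize(out, d, st2)
  expect_equal(out2$x, out$x, tolerance = 1e-12)
})

test_that("frozen stats commute with subsetting (no leakage)", {
  tab <- toy_table(50)
  d <- toy_design()
  st <- standardization_stats(tab, d)
  whole <- standardize(tab, d, st)[1:20, ]
  part <- standardize(tab[1:20, ], d, st)
  expect_equal(whole, part)
})

test_that("a constant reference column maps to zeros and is flagged", {
  tab <- toy_table(20)
  tab$current <- 0
  d <- toy_design()
  st <- standardization_stats(tab, d)
  expect_true(st$degenerate[st$variable == "current"])
  out <- standardize(tab, d, st)
  expect_equal(out$current, rep(0, 20))
  expect_equal(attr(out, "degenerate"), "current")
})

test_that("bootstrap replicate 0 is the original table", {
  tab <- toy_table(30)
  expect_identical(bootstrap_resample(tab, 0, seed = 1), tab)
})

test_that("bootstrap resamples are reproducible and never invent values", {
  tab <- toy_table(40)
  a <- bootstrap_resample(tab, 3, seed = 9)
  b <- bootstrap_resample(tab, 3, seed = 9)
  expect_identical(a, b)
  expect_equal(nrow(a), nrow(tab))
  expect_true(all(a$no2 %in% tab$no2))
  expect_false(identical(a$no2, tab$no2))
})

test_that("fraction of distinct originals approaches 1 - 1/e", {
  n <- 547
  tab <- data.frame(y = seq_len(n))
  d <- vapply(1:20, function(b) {
    r <- bootstrap_resample(tab, b, seed = 4)
    length(unique(r$y)) / n
  }, numeric(1))
  expect_lt(abs(mean(d) - (1 - exp(-1))), 0.02)
})

test_that("train/test split sizes follow round-half-away-from-zero", {
  tab <- data.frame(y = rnorm(510))
  sp <- split_train_test(tab, 0.6, seed = 2)
  expect_equal(c(nrow(sp$train), nrow(sp$test)), c(306, 204))
  sp5 <- split_train_test(data.frame(y = 1:5), 0.6, seed = 2)
  expect_equal(c(nrow(sp5$train), nrow(sp5$test)), c(3, 2))
})

test_that("the split is a disjoint exhaustive partition", {
  tab <- data.frame(id = 1:97, y = rnorm(97))
  sp <- split_train_test(tab, 0.6, seed = 5)
  got <- sort(c(sp$train$id, sp$test$id))
  expect_equal(got, tab$id)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
})
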