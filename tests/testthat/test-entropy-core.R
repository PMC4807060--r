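test_that("embed_templates windows, truncates and centers correctly", {
  expect_equal(embed_templates(c(1, 2, 3, 4), 2),
               rbind(c(1, 2), c(2, 3)))
  expect_equal(embed_templates(c(1, 2, 3, 4), 2, center = TRUE),
               rbind(c(-0.5, 0.5), c(-0.5, 0.5)))
  expect_equal(embed_templates(rep(5, 5), 3, center = TRUE),
               matrix(0, nrow = 2, ncol = 3))
  # order-m and order-(m+1) template counts are equal when requested
  x <- rnorm(20)
  expect_equal(nrow(embed_templates(x, 3)), 17)
  expect_equal(nrow(embed_templates(x, 4, n_templates = 17)), 17)
  expect_error(embed_templates(c(1, 2), 2), "too short")
})

test_that("chebyshev distance is the max absolute component difference", {
  expect_equal(chebyshev_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(chebyshev_distance(c(0, 0, 0), c(0.1, -0.3, 0.2)), 0.3)
  expect_equal(chebyshev_distance(c(1, 4), c(2, 2)), 2)
  expect_equal(chebyshev_distance(c(1, 4), c(2, 2)),
               chebyshev_distance(c(2, 2), c(1, 4)))
  expect_error(chebyshev_distance(1:2, 1:3), "equal dimension")
})

test_that("similarity functions follow their definitions", {
  # Heaviside comparison is strict: d == r is not a match
  expect_equal(heaviside_similarity(0.05, 0.1), 1)
  expect_equal(heaviside_similarity(0.1, 0.1), 0)
  expect_equal(heaviside_similarity(0, 5), 1)
  # fuzzy membership exp(-d^n/r)
  expect_equal(fuzzy_similarity(0, r = 0.3), 1)
  expect_equal(fuzzy_similarity(0.2, r = 0.04, n = 2), exp(-1))
  d <- sort(runif(50, 0, 2))
  expect_true(all(diff(fuzzy_similarity(d, r = 0.2)) <= 0))
  expect_true(all(fuzzy_similarity(d, r = 0.2) > 0))
})

test_that("both entropies agree with the brute-force reference", {
  set.seed(101)
  for (k in 1:50) {
    N <- sample(10:30, 1)
    m <- sample(1:3, 1)
    r <- runif(1, 0.05, 0.5)
    u <- rnorm(N)
    v <- rnorm(N)
    cf <- cross_fuzzy_entropy(u, v, m = m, r = r)
    expect_equal(cf$value, oracle_cross_entropy(u, v, m, r, fuzzy = TRUE),
                 tolerance = 1e-10)
    cs <- cross_sample_entropy(u, v, m = m, r = r)
    expect_equal(ifelse(cs$defined, cs$value, NA_real_),
                 oracle_cross_entropy(u, v, m, r, fuzzy = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("entropies are symmetric under argument swap", {
  set.seed(202)
  for (k in 1:200) {
    u <- rnorm(20)
    v <- rnorm(20)
    expect_equal(cross_fuzzy_entropy(u, v, m = 2, r = 0.2)$value,
                 cross_fuzzy_entropy(v, u, m = 2, r = 0.2)$value,
                 tolerance = 1e-12)
    a <- cross_sample_entropy(u, v, m = 2, r = 0.5)
    b <- cross_sample_entropy(v, u, m = 2, r = 0.5)
    expect_equal(a$value, b$value, tolerance = 1e-12)
    expect_identical(a$defined, b$defined)
  }
})

test_that("C-FuzzyEn is always defined, even at tiny r and minimal N", {
  set.seed(7)
  for (r in c(1e-4, 1e-3, 0.01, 0.1, 1)) {
    for (m in 1:3) {
      u <- rnorm(m + 2)
      v <- rnorm(m + 2)
      res <- cross_fuzzy_entropy(u, v, m = m, r = r)
      expect_true(res$defined)
      expect_true(is.finite(res$value))
    }
  }
})

test_that("C-SampleEn is nonnegative when defined and UNDEFINED otherwise", {
  set.seed(8)
  n_def <- 0
  for (k in 1:100) {
    u <- runif(25)
    v <- runif(25)
    res <- cross_sample_entropy(u, v, m = 2, r = runif(1, 0.02, 0.6))
    if (res$defined) {
      n_def <- n_def + 1
      expect_gte(res$value, 0)
      expect_lte(res$phi_m1, res$phi_m)
    } else {
      expect_true(is.na(res$value))
    }
  }
  expect_gt(n_def, 0)
  # tiny r on independent series: no matches, flagged not thrown
  set.seed(9)
  res <- cross_sample_entropy(runif(50), runif(50), m = 2, r = 0.01)
  expect_false(res$defined)
})

test_that("degenerate limits behave as the definitions dictate", {
  # all-match limit: identical ramps with huge r
  res <- cross_sample_entropy(1:6, 1:6, m = 1, r = 100)
  expect_equal(res$phi_m, 1)
  expect_equal(res$phi_m1, 1)
  expect_equal(res$value, 0)
  # constant series: centered templates are zero vectors -> entropy exactly 0
  expect_equal(cross_fuzzy_entropy(rep(2, 10), rep(7, 10),
                                   m = 2, r = 0.15)$value, 0)
})

test_that("C-FuzzyEn vanishes as the tolerance grows", {
  pair <- synthetic_gait_pair(coupling = 0.5, noise_sd = 0.03, seed = 33)
  lo <- cross_fuzzy_entropy(pair$u, pair$v, m = 1, r = 0.01)$value
  hi <- cross_fuzzy_entropy(pair$u, pair$v, m = 1, r = 10)$value
  expect_lt(hi, lo)
  expect_lt(abs(hi), 0.01)
})

test_that("C-FuzzyEn tends to decrease with embedding dimension", {
  # m = 1 is excluded: a centered one-component template is identically
  # zero, so phi_m = 1 there and the m = 1 value sits below the rest by
  # construction; the decreasing tendency applies from m = 2 on
  set.seed(44)
  vals <- sapply(1:50, function(k) {
    pair <- synthetic_gait_pair(n_strides = 120, coupling = 0.6,
                                noise_sd = 0.03, seed = 1000 + k)
    sapply(2:6, function(m)
      cross_fuzzy_entropy(pair$u, pair$v, m = m, r = 0.004)$value)
  })
  med <- apply(vals, 1, median)
  expect_true(all(diff(med) <= 2e-3))  # non-increasing up to sampling noise
  expect_lt(med[length(med)], med[1])  # strict decrease end to end
})

test_that("tolerance profile matches per-r evaluation", {
  set.seed(55)
  u <- rnorm(80)
  v <- rnorm(80)
  rs <- c(0.001, 0.01, 0.1, 1)
  prof <- cfuzzyen_profile(u, v, r_values = rs, m = 1)
  single <- sapply(rs, function(r) cross_fuzzy_entropy(u, v, m = 1, r = r)$value)
  expect_equal(prof, single, tolerance = 1e-12)
})

test_that("input contracts are enforced", {
  expect_error(cross_fuzzy_entropy(1:5, 1:4, m = 1, r = 0.1), "equal length")
  expect_error(cross_fuzzy_entropy(c(1, NA, 3, 4), c(1, 2, 3, 4), m = 1, r = 0.1),
               "finite")
  expect_error(cross_sample_entropy(1:3, 1:3, m = 2, r = 0.1), "m \\+ 2")
})
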