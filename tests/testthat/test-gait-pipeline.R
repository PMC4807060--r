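write_gait_fixture <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

test_that("gait files round-trip through the reader", {
  set.seed(1)
  l <- round(rnorm(10, 1.1, 0.05), 4)
  r <- round(rnorm(10, 1.12, 0.05), 4)
  path <- write_gait_fixture(paste(seq_len(10), l, r))
  rec <- read_gait_file(path)
  expect_s3_class(rec, "gait_record")
  expect_equal(rec$left_stride, l)
  expect_equal(rec$right_stride, r)
  # comma-separated with header works too
  path2 <- write_gait_fixture(c("t,left,right", paste(1:10, l, r, sep = ",")))
  rec2 <- read_gait_file(path2)
  expect_equal(rec2$left_stride, l)
})

test_that("reader trims trailing gaps and errors on bad input", {
  l <- sprintf("%.3f", rnorm(10, 1.1, 0.02))
  lines <- paste(1:10, l, c(sprintf("%.3f", rnorm(8, 1.1, 0.02)), "", ""))
  rec <- read_gait_file(write_gait_fixture(trimws(lines)))
  expect_equal(length(rec$left_stride), 8)   # trimmed to common length
  expect_equal(length(rec$right_stride), 8)
  expect_error(read_gait_file(write_gait_fixture(paste(1:5, "1.1", "1.2")),
                              right_col = 7),
               "column 7")
  expect_error(read_gait_file(write_gait_fixture(c("1 1.1 1.2", "2 oops 1.2",
                                                   "3 1.1 1.2"))),
               "non-numeric")
  expect_error(read_gait_file(tempfile()), "not found")
})

test_that("outlier screening removes exactly the injected spikes", {
  set.seed(2)
  clean <- rnorm(200, 1.1, 0.05)
  spiked <- clean
  pos <- c(10, 50, 90, 130, 170)
  spiked[pos] <- 4.0
  res <- remove_outliers(spiked)
  expect_equal(sort(res$removed), pos)
  expect_equal(res$n_removed, 5)
  expect_equal(res$series, spiked[-pos])
  # no-op on clean data
  expect_equal(remove_outliers(clean)$n_removed, 0)
  # near-constant series with one spike: spike removed
  x <- c(rep(1.1, 30), 3)
  expect_equal(remove_outliers(x)$removed, 31)
  expect_error(remove_outliers(rnorm(5)), "too short")
})

test_that("paired preprocessing removes the same indices from both limbs", {
  set.seed(3)
  rec <- gait_record("s1", "CO", c(rnorm(100, 1.1, 0.03), 4.4),
                     c(4.2, rnorm(100, 1.1, 0.03)))
  pre <- preprocess_gait_record(rec)
  expect_equal(length(pre$left_stride), length(pre$right_stride))
  expect_equal(attr(pre, "n_outliers_removed"), 2)
  expect_equal(length(pre$left_stride), 99)
})

test_that("ASI follows its formula and symmetries", {
  expect_equal(asi(1.0, 1.2), 100 * 0.2 / 1.1)
  # antisymmetry under limb swap
  expect_equal(asi(1.3, 0.9), -asi(0.9, 1.3))
  # scale invariance
  expect_equal(asi(2 * 1.05, 2 * 1.18), asi(1.05, 1.18))
  expect_equal(asi(1.1, 1.1), 0)
})

test_that("symmetry features honour the window and the symmetry limit", {
  pair <- synthetic_gait_pair(coupling = 1, noise_sd = 0.02, seed = 4)
  rec <- gait_record("s2", "CO", pair$u, pair$v)
  ft <- symmetry_features(rec, N_use = 150)
  expect_equal(ft$asi, 0)
  expect_equal(ft$n_used, 150)
  self_val <- cross_fuzzy_entropy(pair$u[1:150], pair$u[1:150],
                                  m = 1, r = 0.004)$value
  expect_equal(ft$cfuzzyen, self_val)
  short <- gait_record("s3", "CO", rnorm(100, 1.1, 0.02), rnorm(100, 1.1, 0.02))
  expect_error(symmetry_features(short, N_use = 150), "s3")
})

test_that("feature table is deterministic given the cohort", {
  coh <- synthetic_gait_cohort(n_pd = 3, n_co = 3, seed = 6)
  expect_identical(gait_feature_table(coh), gait_feature_table(coh))
  ft <- gait_feature_table(coh)
  expect_equal(nrow(ft), 6)
  expect_true(all(is.finite(ft$cfuzzyen)))
})

test_that("Mann-Whitney matches enumeration and rank invariances", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  # identical multisets: no evidence, p = 1
  expect_equal(mann_whitney_u(c(1, 2, 2, 5), c(1, 2, 2, 5))$p_value, 1)
  # agreement with the enumeration oracle on random small groups with ties
  set.seed(7)
  for (k in 1:20) {
    a <- sample(1:6, sample(3:6, 1), replace = TRUE)
    b <- sample(1:6, sample(3:6, 1), replace = TRUE)
    expect_equal(mann_whitney_u(a, b)$p_value, oracle_mw_exact(a, b))
  }
  # monotone-transform invariance (rank-based)
  a <- rnorm(12)
  b <- rnorm(15) + 0.8
  expect_equal(mann_whitney_u(a, b)$p_value,
               mann_whitney_u(exp(a), exp(b))$p_value)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("large-sample Mann-Whitney approximation tracks the reference
           implementation", {
  set.seed(8)
  a <- rnorm(15)
  b <- rnorm(16) + 0.7
  ours <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  # and with ties
  a2 <- round(rnorm(12), 1)
  b2 <- round(rnorm(14) + 0.5, 1)
  expect_equal(mann_whitney_u(a2, b2)$p_value,
               stats::wilcox.test(a2, b2, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("min-max normalisation maps onto [0, 1] preserving order", {
  expect_equal(min_max_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  x <- rnorm(30)
  y <- min_max_normalize(x)
  expect_equal(range(y), c(0, 1))
  expect_equal(order(y), order(x))
  expect_error(min_max_normalize(rep(3, 5)), "identical")
})

test_that("select_r screens the grid and recovers group separation", {
  coh <- synthetic_gait_cohort(seed = 9)
  sel <- select_r(coh)
  expect_equal(nrow(sel$table), length(gait_r_grid()))
  expect_equal(min(sel$table$p_value), sel$best_p)
  expect_lt(sel$best_p, 0.05)
  # degenerate single-point grid returns that r
  sel1 <- select_r(coh, r_values = 0.004)
  expect_equal(sel1$best_r, 0.004)
  # group contracts
  small <- synthetic_gait_cohort(n_pd = 2, n_co = 5, seed = 10)
  expect_error(select_r(small), "at least 3")
})

test_that("null cohorts do not produce spurious separation too often", {
  # both groups drawn from the same generator settings; with 19 tested r
  # values some small p can occur, so require the minimum p not to be
  # extreme in most repetitions
  hits <- sapply(1:5, function(s) {
    coh <- synthetic_gait_cohort(seed = 600 + s,
                                 pd_coupling = 0.9, pd_noise_sd = 0.025,
                                 co_coupling = 0.9, co_noise_sd = 0.025)
    select_r(coh)$best_p
  })
  expect_gte(sum(hits > 0.01), 3)
})
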