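# Fold assignment, normalized RMSE, the cross-validation protocols,
# window scanning, model comparison, and the correlation helper.

test_that("fold assignment partitions the records with near-equal sizes", {
  for (case in list(c(1000, 10), c(10, 10), c(37, 5), c(23, 4))) {
    f <- make_folds(case[1], k = case[2], seed = 99)
    sizes <- tabulate(f$fold, f$k)
    expect_equal(sum(sizes), case[1])          # coverage
    expect_lte(diff(range(sizes)), 1)          # balance
  }
  expect_equal(tabulate(make_folds(1000, 10, seed = 1)$fold, 10), rep(100, 10))
  # leave-one-out corner and determinism
  expect_equal(sort(make_folds(10, 10, seed = 2)$fold), 1:10)
  expect_identical(make_folds(50, 5, seed = 7)$fold, make_folds(50, 5, seed = 7)$fold)
  expect_error(make_folds(5, 1), "at least 2")
})

test_that("normalized RMSE matches hand computations and the mean-predictor baseline", {
  obs <- c(0, 2)
  expect_equal(normalized_rmse(c(1, 1), obs), 1 / sqrt(2))
  expect_equal(normalized_rmse(obs, obs), 0)
  # mean predictor: sqrt((n-1)/n) with the sample-sd normalization
  set.seed(12); y <- rnorm(50)
  expect_equal(normalized_rmse(rep(mean(y), 50), y), sqrt(49 / 50))
  expect_error(normalized_rmse(c(1, 2), c(3, 3, 3)), "equal")
  expect_error(normalized_rmse(c(1, 2), c(3, 3)), "constant")
})

test_that("the training-mean predictor concentrates near RMSE 1 on large folds", {
  set.seed(4)
  y <- rnorm(2000)
  f <- make_folds(2000, 10, seed = 4)
  rmse <- vapply(1:10, function(j)
    normalized_rmse(rep(mean(y[f$fold != j]), sum(f$fold == j)), y[f$fold == j]),
    numeric(1))
  expect_true(all(abs(rmse - 1) < 0.1))
})

test_that("MS cross-validation follows the median-alpha two-pass protocol", {
  sim <- simulate_spot_array(n_peptides = 150, lengths = 9, window_size = 3,
                             noise_sd = 0, seed = 5)
  cv <- crossval(sim$records, "ms", 3, k = 5, fold_seed = 2,
                 profile = "fixed_alanine", n_restarts = 2, seed = 2)
  expect_equal(cv$alpha, median(cv$fold_alpha))
  expect_length(cv$fold_rmse, 5)
  expect_lt(cv$mean_rmse, 0.05)          # noiseless: near-perfect prediction
  expect_false(cv$incomplete)
})

test_that("MS cross-validated error sits at the noise floor for a true MS signal", {
  sim <- simulate_spot_array(n_peptides = 200, lengths = 9, window_size = 3,
                             noise_sd = 0.1, seed = 6)
  cv <- crossval(sim$records, "ms", 3, k = 5, fold_seed = 3,
                 profile = "fixed_alanine", n_restarts = 2, seed = 3)
  floor <- 0.1 / sd(sim$records$pseudo_energy)
  expect_gte(cv$mean_rmse, 0.8 * floor)
  expect_lt(cv$mean_rmse, 1)
})

test_that("SS cross-validation recovers the true representative site", {
  sim <- simulate_spot_array(n_peptides = 250, lengths = 9, window_size = 3,
                             truth = "ss", site = 3, noise_sd = 0.05, seed = 9)
  cv <- crossval(sim$records, "ss", 3, k = 5, fold_seed = 11,
                 profile = "fixed_alanine")
  expect_equal(cv$site, 3)
  expect_equal(nrow(cv$site_table), 9 - 3 + 1)
  expect_lt(cv$mean_rmse, 0.5)
})

test_that("window scans mark the best size and feed a coherent comparison", {
  sim <- simulate_spot_array(n_peptides = 150, lengths = 8, window_size = 3,
                             noise_sd = 0.1, seed = 13)
  folds <- make_folds(150, k = 5, seed = 8)
  ms_scan <- scan_windows(sim$records, "ms", c(2, 3), folds = folds,
                          profile = "fixed_alanine", n_restarts = 1, seed = 4)
  ss_scan <- suppressWarnings(
    scan_windows(sim$records, "ss", c(2, 3), folds = folds,
                 profile = "fixed_alanine"))
  expect_equal(ms_scan$best_S,
               ms_scan$table$window_size[which.min(ms_scan$table$mean_rmse)])
  expect_equal(ms_scan$best_S, 3)        # model-selection recovery of true S

  cmp <- compare_models(ms_scan, ss_scan)
  # stored percent decrease is consistent with the stored fold RMSEs
  expect_equal(cmp$fold_decrease,
               100 * (cmp$fold_ss_rmse - cmp$fold_ms_rmse) / cmp$fold_ss_rmse)
  # antisymmetry under swapping model labels (sign flips, SS-relative scale)
  swapped <- 100 * (cmp$fold_ms_rmse - cmp$fold_ss_rmse) / cmp$fold_ms_rmse
  expect_equal(sign(mean(swapped)), -sign(cmp$mean_decrease))

  # identical scans -> exactly 0% decrease
  self_cmp <- compare_models(ms_scan, ms_scan)
  expect_equal(self_cmp$mean_decrease, 0)

  # fold mismatch is an error
  other <- scan_windows(sim$records, "ms", 3, folds = make_folds(150, 5, seed = 9),
                        profile = "fixed_alanine", n_restarts = 1, seed = 4)
  expect_error(compare_models(other, ss_scan), "identical fold")

  # single-S scan: best is that S
  expect_equal(other$best_S, 3)
  expect_error(scan_windows(sim$records, "ms", integer(0)), "non-empty")
})

test_that("full-length windows are excluded from the MS best-S choice", {
  # construct a scan where the full-length size nominally wins
  sim <- simulate_spot_array(n_peptides = 160, lengths = 6, window_size = 6,
                             noise_sd = 0.05, seed = 40)
  folds <- make_folds(160, k = 4, seed = 2)
  scan <- scan_windows(sim$records, "ms", c(2, 6), folds = folds,
                       profile = "fixed_alanine", n_restarts = 1, seed = 6)
  expect_equal(scan$best_S, 2)   # S = 6 is full-length here, so ineligible
})

test_that("correlate validates and matches hand-computed Pearson values", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlate(x, 2 * x + 1), 1)
  expect_equal(correlate(x, -x), -1)
  expect_equal(correlate(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(correlate(c(1, 2), c(1, 2)), "length")
  expect_error(correlate(c(1, 2, 3), c(2, 2, 2)), "constant")
})
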