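# Parameter estimation: SS closed-form regression, MS nonlinear least
# squares with restarts, and their agreement where the models coincide.

test_that("SS fit recovers a noise-free linear truth exactly", {
  set.seed(21)
  S <- 3; r <- 2
  J <- make_J(S); J[aa20 != "A", ] <- rnorm(19 * S, sd = 0.8)
  truth <- ss_model(J, J0 = 1.2, site = r, profile = ala_profile(S))
  peps <- random_peptides(400, 8, seed = 22)
  dat <- data.frame(sequence = peps, pseudo_energy = unname(predict(truth, peps)))
  fit <- suppressWarnings(ss_fit(dat, S, site = r, profile = "fixed_alanine"))
  expect_lt(max(abs(fit$residuals)), 1e-10)
  expect_equal(fit$J0, 1.2, tolerance = 1e-8)
  # observed residues recover their J exactly; unobserved are zeroed
  obs <- colSums(encode_windows(substring(peps, r + 1, r + S),
                                ala_profile(S), intercept = FALSE)) > 0
  th_t <- spotms:::J_to_theta(truth$J, truth$profile)
  th_f <- spotms:::J_to_theta(fit$J, fit$profile)
  expect_equal(th_f[obs], th_t[obs], tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(th_f[!obs] == 0))
})

test_that("SS regression degenerate designs behave as documented", {
  # intercept-only: identical site sequences -> J0 = mean, all J = 0
  dat <- data.frame(sequence = rep("CCCC", 6),
                    pseudo_energy = c(1, 2, 3, 1, 2, 3))
  fit <- suppressWarnings(ss_fit(dat, 2, site = 1, profile = "fixed_alanine"))
  expect_equal(fit$J0 + fit$J["C", 1] + fit$J["C", 2], 2, tolerance = 1e-10)
  expect_equal(unname(predict(fit, "CCCC")), 2, tolerance = 1e-10)

  # S=1 two-group means: A at -1, C at +1 -> J0 = -1, J(1,C) = +2
  dat2 <- data.frame(sequence = c("A", "A", "C", "C"),
                     pseudo_energy = c(-1, -1, 1, 1))
  fit2 <- suppressWarnings(ss_fit(dat2, 1, site = 0, profile = "fixed_alanine"))
  expect_equal(fit2$J0, -1, tolerance = 1e-10)
  expect_equal(fit2$J["C", 1], 2, tolerance = 1e-10)

  expect_error(ss_fit(dat2[1, , drop = FALSE], 1), "at least 2")
})

test_that("MS fit recovers a known model from noiseless data", {
  sim <- simulate_spot_array(n_peptides = 500, lengths = 10, window_size = 4,
                             noise_sd = 0, seed = 101)
  fit <- ms_fit(sim$records, 4, profile = "fixed_alanine",
                n_restarts = 3, seed = 17)
  expect_lt(fit$sse, 1e-6)
  th_t <- spotms:::J_to_theta(sim$truth$J, sim$truth$profile)
  th_f <- spotms:::J_to_theta(fit$J, fit$profile)
  expect_lt(max(abs(th_f - th_t)), 1e-3)
  expect_equal(fit$alpha, sim$truth$alpha, tolerance = 1e-4)
  # the reported SSE is consistent with the returned model's predictions
  expect_equal(fit$sse, sum((sim$records$pseudo_energy -
                               predict(fit, sim$records))^2),
               tolerance = 1e-8)
})

test_that("MS fit degenerates gracefully when all sequences are identical", {
  set.seed(77)
  dat <- data.frame(sequence = rep("CDEFG", 45),
                    pseudo_energy = rnorm(45, mean = 1, sd = 0.1))
  fit <- ms_fit(dat, 2, profile = "fixed_alanine", n_restarts = 2, seed = 3)
  # only the offset is identified: the best attainable SSE is the total
  # sum of squares about the mean of the replicate energies
  expect_equal(fit$sse, sum((dat$pseudo_energy - mean(dat$pseudo_energy))^2),
               tolerance = 1e-8)
})

test_that("restart selection is best-of-k and reproducible", {
  sim <- simulate_spot_array(n_peptides = 120, lengths = 7, window_size = 3,
                             noise_sd = 0.2, seed = 33)
  f1 <- ms_fit(sim$records, 3, profile = "fixed_alanine", n_restarts = 1, seed = 5)
  f4 <- ms_fit(sim$records, 3, profile = "fixed_alanine", n_restarts = 4, seed = 5)
  # restart r of the k-run uses the same initialization sequence, so the
  # best-of-k SSE is non-increasing in k
  expect_lte(f4$sse, f1$sse)
  expect_equal(f4$restart_sse[1], f1$restart_sse[1], tolerance = 1e-12)

  # identical (data, config) -> identical fit
  g4 <- ms_fit(sim$records, 3, profile = "fixed_alanine", n_restarts = 4, seed = 5)
  expect_identical(coef(f4), coef(g4))
  expect_identical(f4$sse, g4$sse)
})

test_that("MS and SS reach the same optimum when every peptide has one window", {
  sim <- simulate_spot_array(n_peptides = 200, lengths = 4, window_size = 4,
                             noise_sd = 0.1, seed = 3)
  f_ms <- ms_fit(sim$records, 4, profile = "fixed_alanine", n_restarts = 2, seed = 1)
  f_ss <- suppressWarnings(ss_fit(sim$records, 4, site = 0, profile = "fixed_alanine"))
  expect_equal(f_ms$sse, f_ss$sse, tolerance = 1e-6)
})

test_that("fit input contracts: short peptides skipped, bad energies fatal", {
  set.seed(61)
  dat <- data.frame(sequence = c(random_peptides(90, 7, seed = 62), "AC"),
                    pseudo_energy = rnorm(91))
  suppressWarnings(   # pure-noise fit may also warn about hitting maxiter
    expect_warning(fit <- ms_fit(dat, 3, profile = "fixed_alanine",
                                 n_restarts = 1, seed = 1),
                   "skipped"))
  expect_equal(fit$n, 90)

  dat$pseudo_energy[1] <- NaN
  expect_error(suppressWarnings(ms_fit(dat, 3)), "non-finite pseudo-energy")
  expect_error(ms_fit(dat[0, ], 3), "sequence|usable|non-empty")
})

test_that("fixed-alpha fitting holds the offset and still fits J", {
  sim <- simulate_spot_array(n_peptides = 200, lengths = 8, window_size = 3,
                             noise_sd = 0.05, seed = 55)
  fit <- ms_fit(sim$records, 3, profile = "fixed_alanine", n_restarts = 2,
                seed = 2, fixed_alpha = sim$truth$alpha)
  expect_identical(fit$alpha, sim$truth$alpha)
  th_t <- spotms:::J_to_theta(sim$truth$J, sim$truth$profile)
  th_f <- spotms:::J_to_theta(fit$J, fit$profile)
  expect_gt(cor(th_f, th_t), 0.95)
})
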