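test_that("the mix design implements the G0-fraction bookkeeping", {
  d <- build_mix_design(1e4, 0.55, 0.1, 0.6, replicates = 1)
  expect_equal(d$n_q, 1e4 * (0.55 * 0.1 + 0.45 * 0.6))  # 3250
  expect_equal(d$n_p + d$n_q, d$total)
  # pure 8-h extract: N_Q = totals * g0_8h
  d1 <- build_mix_design(1e4, 1, 0.1, 0.6, replicates = 1)
  expect_equal(d1$n_q, 1000)
  # 8 fractions x 3 replicates = 24 rows per condition
  d24 <- build_mix_design(1e4, mixing_fractions(), 0.1, 0.6,
                          replicates = 3)
  expect_equal(nrow(d24), 24)
  expect_error(build_mix_design(1e4, mixing_fractions(), 0.3, 0.3),
               "rank-deficient")
})

test_that("the block design matrix has the documented shape and ordering", {
  conds <- data.frame(cell_line = c("A", "B"), stimulus = "starv")
  d <- build_mix_design(1e4, mixing_fractions(), 0.1, 0.6,
                        conditions = conds, replicates = 3)
  X <- build_design_matrix(d)
  expect_equal(dim(X), c(48, 4))
  expect_true(all(rowSums(X != 0) == 2))
  expect_equal(attr(X, "population"), c("P", "Q", "P", "Q"))
  # one condition: 24 x 2
  X1 <- build_design_matrix(d[d$cell_line == "A", ])
  expect_equal(dim(X1), c(24, 2))
  expect_equal(unname(X1[, 1]), d$n_p[d$cell_line == "A"])
})

test_that("constrained fits match the normal-equations oracle on interior blocks", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    d <- build_mix_design(1e4, mixing_fractions(),
                          runif(1, 0.05, 0.3), runif(1, 0.5, 0.9),
                          replicates = 3)
    X <- build_design_matrix(d)
    a <- runif(2, 0.5, 5)
    y <- drop(X %*% a) + rnorm(nrow(X), 0, 100)
    ref <- normal_equations(X, y)
    if (any(ref < 0)) next
    fit <- nnls_fit(X, y)$coefficients
    worst <- max(worst, max(abs(fit - ref) / abs(ref)))
  }
  expect_lt(worst, 1e-10)
})

test_that("active constraints zero coefficients exactly, matching brute force", {
  set.seed(7)
  d <- build_mix_design(1e4, mixing_fractions(), 0.1, 0.6, replicates = 3)
  X <- build_design_matrix(d)
  n_zero <- 0
  for (i in 1:50) {
    y <- drop(X %*% c(runif(1, 0.5, 2), 0)) + rnorm(nrow(X), 0, 5000)
    fit <- nnls_fit(X, y)$coefficients
    ref <- brute_nnls2(X, y)
    expect_equal(fit, ref, tolerance = 1e-9)
    if (fit[2] == 0) n_zero <- n_zero + 1
  }
  expect_gt(n_zero, 0)  # the constraint really was active sometimes
})

test_that("the solver agrees with an independent NNLS implementation", {
  skip_if_not_installed("pracma")
  set.seed(3)
  for (i in 1:25) {
    X <- matrix(rexp(24 * 2, 1e-3), 24, 2)
    y <- drop(X %*% c(runif(1), -0.2 + runif(1))) + rnorm(24, 0, 50)
    a <- nnls_fit(X, y)
    b <- pracma::lsqnonneg(X, y)
    expect_equal(a$coefficients, unname(b$x), tolerance = 1e-8)
  }
})

test_that("noise-free deconvolution recovers the planted truth and scales correctly", {
  fx <- noisefree_experiment(20, background = 50, seed = 2)
  fit <- fit_alphas(fx$exper$intensities, fx$exper$design, background = 50)
  co <- fit$coefficients
  aP <- co$alpha[co$population == "P"]
  aQ <- co$alpha[co$population == "Q"]
  expect_lt(max(abs(aP - fx$truth$alpha_P[, 1]) / fx$truth$alpha_P[, 1]),
            1e-8)
  expect_lt(max(abs(aQ - fx$truth$alpha_Q[, 1]) / fx$truth$alpha_Q[, 1]),
            1e-8)
  # scale equivariance: intensities and background both scaled by c
  c0 <- 7.5
  fit2 <- fit_alphas(fx$exper$intensities$intensity * c0, fx$exper$design,
                     background = 50 * c0)
  expect_equal(fit2$coefficients$alpha, co$alpha * c0, tolerance = 1e-9)
})

test_that("conditions are fitted independently (block separability)", {
  conds <- data.frame(cell_line = c("A", "B"), stimulus = "starv")
  fx <- noisefree_experiment(5, background = 0, seed = 6,
                             conditions = conds)
  I <- fx$exper$intensities$intensity
  fit <- fit_alphas(I, fx$exper$design)
  I2 <- I
  rows_b <- fx$exper$design$cell_line == "B"
  I2[rows_b, ] <- I2[rows_b, ] * 3  # corrupt condition B only
  fit2 <- fit_alphas(I2, fx$exper$design)
  sel_a <- fit$coefficients$cell_line == "A"
  expect_equal(fit2$coefficients$alpha[sel_a],
               fit$coefficients$alpha[sel_a])
  sel_b <- fit$coefficients$cell_line == "B"
  expect_false(isTRUE(all.equal(fit2$coefficients$alpha[sel_b],
                                fit$coefficients$alpha[sel_b])))
})

test_that("bootstrap errors are zero for exact fits, reproducible, and guarded", {
  fx <- noisefree_experiment(5, background = 20, seed = 3)
  fit <- fit_alphas(fx$exper$intensities, fx$exper$design, background = 20)
  bs <- bootstrap_errors(fit, n_reps = 10, seed = 1)
  expect_lt(max(bs$coefficients$sd), 1e-10)
  expect_equal(unique(bs$coefficients$n_bootstrap), 10)
  # fixed seed reproduces the SDs on noisy data
  tr <- true_population_profile(5, seed = 4)
  ex <- simulate_mix_experiment(tr, model = measurement_model(
    noise_cv = 0.1, seed = 5))
  f <- fit_alphas(ex$intensities, ex$design)
  expect_identical(bootstrap_errors(f, 25, seed = 2)$coefficients$sd,
                   bootstrap_errors(f, 25, seed = 2)$coefficients$sd)
  expect_error(bootstrap_errors(f, n_reps = 1), "n_reps")
})

test_that("bootstrap SDs track analytic standard errors on interior solutions", {
  tr <- true_population_profile(60, mean_log10_alpha = 0.5,
                                sd_log10_alpha = 0.2,
                                frac_differential = 0, seed = 5)
  ex <- simulate_mix_experiment(tr, model = measurement_model(
    noise_floor_sd = 300, seed = 8))
  fit <- bootstrap_errors(fit_alphas(ex$intensities, ex$design),
                          n_reps = 100, seed = 9)
  X <- build_design_matrix(ex$design)
  se <- 300 * sqrt(diag(solve(crossprod(X))))
  ratio <- fit$coefficients$sd / rep(se, 60)
  expect_lt(abs(median(ratio) - 1), 0.3)
})

test_that("purification returns planted per-cell abundances and flags negatives", {
  fx <- noisefree_experiment(10, background = 0, seed = 2)
  ex <- fx$exper
  fit <- fit_alphas(ex$intensities, ex$design)
  rows <- which(ex$design$fraction == 0)  # pure 96-h samples
  pu <- purify_intensities(ex$intensities$intensity[rows, , drop = FALSE],
                           ex$design[rows, ], fit, focal = "Q")
  expect_equal(unname(pu$per_cell[1, ]), unname(fx$truth$alpha_Q[, 1]),
               tolerance = 1e-9)
  # mixed sample purifies to the same per-cell value
  mixed <- which(ex$design$fraction == 0.55)[1]
  pu2 <- purify_intensities(ex$intensities$intensity[mixed, , drop = FALSE],
                            ex$design[mixed, ], fit, focal = "Q")
  expect_equal(unname(pu2$per_cell[1, ]), unname(fx$truth$alpha_Q[, 1]),
               tolerance = 1e-8)
  # alpha_P = 0 makes purification the identity
  fit0 <- fit
  fit0$coefficients$alpha[fit0$coefficients$population == "P"] <- 0
  pu3 <- purify_intensities(ex$intensities$intensity[mixed, , drop = FALSE],
                            ex$design[mixed, ], fit0, focal = "Q")
  expect_equal(pu3$purified[1, ], ex$intensities$intensity[mixed, ])
  # zero focal cells refused
  d0 <- ex$design[mixed, ]
  d0$n_q <- 0
  expect_error(purify_intensities(
    ex$intensities$intensity[mixed, , drop = FALSE], d0, fit,
    focal = "Q"), "zero cells")
  # flooring flag fires when the subtracted contribution overshoots
  fit_big <- fit
  fit_big$coefficients$alpha <- fit_big$coefficients$alpha * 100
  pu4 <- purify_intensities(ex$intensities$intensity[mixed, , drop = FALSE],
                            ex$design[mixed, ], fit_big, focal = "Q")
  expect_true(all(pu4$floored))
  expect_true(all(pu4$purified == 0))
})

test_that("reference comparison yields perfect correlation on self and a centered null", {
  set.seed(13)
  prof <- matrix(rlnorm(40 * 5, 2, 1), 40, 5,
                 dimnames = list(sprintf("ion%02d", 1:40),
                                 paste0("CL", 1:5)))
  cmp <- compare_to_reference(prof, prof, n_perm = 200, seed = 1)
  expect_equal(cmp$correlations$rho, rep(1, 40))
  expect_lt(abs(mean(cmp$null_rho)), 3 / sqrt(length(cmp$null_rho)) + 0.02)
  # characteristic-ion rule keeps only high-variance ions
  errs <- matrix(1e6, 40, 5, dimnames = dimnames(prof))
  errs[1:10, ] <- 1e-6
  cmp2 <- compare_to_reference(prof, prof, errors = errs, n_perm = 10)
  expect_true(all(cmp2$correlations$characteristic[1:10]))
  expect_false(any(cmp2$correlations$characteristic[11:40]))
  expect_error(compare_to_reference(prof[, 1:2], prof[, 1:2]), "3 shared")
})
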