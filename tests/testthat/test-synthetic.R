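test_that("mixture intensities follow the linear model exactly without noise", {
  tr <- true_population_profile(1, seed = 1)
  tr$alpha_P[, 1] <- 2
  tr$alpha_Q[, 1] <- 5
  ex <- simulate_mix_experiment(tr, totals = 1e4, fractions = 0,
                                g0_at_8h = 0.1, g0_at_96h = 0.6,
                                replicates = 1,
                                model = measurement_model(background = 100))
  expect_equal(ex$design$n_q, 6000)
  expect_equal(ex$design$n_p, 4000)
  expect_equal(unname(ex$intensities$intensity[1, 1]),
               2 * 4000 + 5 * 6000 + 100)

  # identical populations: intensity independent of the mixing fraction
  tr2 <- true_population_profile(3, seed = 1)
  tr2$alpha_Q <- tr2$alpha_P
  ex2 <- simulate_mix_experiment(tr2, totals = 1e4, replicates = 1,
                                 model = measurement_model())
  for (j in 1:3)
    expect_equal(max(ex2$intensities$intensity[, j]) -
                   min(ex2$intensities$intensity[, j]), 0,
                 tolerance = 1e-9)
  expect_equal(unname(ex2$intensities$intensity[1, 1]),
               unname(tr2$alpha_P[1, 1] * 1e4))
})

test_that("the eight-point design emits 8 rows per replicate and validates inputs", {
  expect_equal(mixing_fractions(),
               c(1.00, 0.85, 0.70, 0.55, 0.40, 0.25, 0.10, 0))
  tr <- true_population_profile(2, seed = 1)
  ex <- simulate_mix_experiment(tr, replicates = 3)
  expect_equal(nrow(ex$design), 24)
  expect_equal(nrow(ex$intensities$intensity), 24)
  tr$alpha_P[1, 1] <- -1
  expect_error(simulate_mix_experiment(tr), "non-negative")
  expect_error(simulate_mix_experiment(true_population_profile(2, seed = 1),
                                       fractions = c(0.5, 1.2)))
})

test_that("generation is deterministic and bounded", {
  tr <- true_population_profile(5, seed = 3)
  m <- measurement_model(background = 10, noise_cv = 0.2,
                         noise_floor_sd = 50, saturation = 5e4, seed = 11)
  a <- simulate_mix_experiment(tr, model = m)$intensities$intensity
  b <- simulate_mix_experiment(tr, model = m)$intensities$intensity
  expect_identical(a, b)
  expect_true(all(a >= 0))
  expect_true(all(a <= 5e4))
  # noise-free generation is bit-identical too
  m0 <- measurement_model(background = 10)
  expect_identical(simulate_mix_experiment(tr, model = m0)$intensities,
                   simulate_mix_experiment(tr, model = m0)$intensities)
})

test_that("the mean of many noisy replicates converges to the noise-free value", {
  tr <- true_population_profile(1, seed = 4)
  tr$alpha_P[, 1] <- 1
  tr$alpha_Q[, 1] <- 2
  mu0 <- simulate_mix_experiment(
    tr, fractions = 0.5, replicates = 1,
    model = measurement_model(background = 100))$intensities$intensity[1, 1]
  m <- measurement_model(background = 100, noise_cv = 0.1,
                         noise_floor_sd = 20, seed = 5)
  noisy <- simulate_mix_experiment(tr, fractions = 0.5, replicates = 1500,
                                   model = m)$intensities$intensity[, 1]
  se <- stats::sd(noisy) / sqrt(length(noisy))
  expect_lt(abs(mean(noisy) - mu0), 3 * se)
})

test_that("spike-in series are linear until the saturation clip", {
  sp <- default_spike_amounts(8)
  st <- simulate_spikein_series(5000, sp, 1000,
                                measurement_model(saturation = 1e6),
                                replicates = 1)
  pred <- pmin(5000 + 1000 * sp, 1e6)
  expect_equal(unname(st$intensity[, 1]), pred)
  # zero spike reproduces the base level
  st0 <- simulate_spikein_series(7000, c(0, 1, 2, 5, 10), 100,
                                 replicates = 1)
  expect_equal(unname(st0$intensity[1, 1]), 7000)
  expect_error(simulate_spikein_series(1, c(3, 2, 5), 1), "increasing")
  # requested default grid spans three decades (3 pmol to 3 nmol style)
  expect_equal(range(default_spike_amounts()), c(3, 3000))
})

test_that("cytometry clouds land at the planted DNA peaks with known labels", {
  ev <- simulate_cytometry_events(1e4, seed = 6)
  planted <- c(G0 = 0.4, G1 = 0.3, S = 0.2, G2M = 0.1)
  emp <- table(ev$label)[names(planted)] / nrow(ev)
  se <- sqrt(planted * (1 - planted) / nrow(ev))
  expect_true(all(abs(emp - planted) < 3 * se))
  # 4n cluster at twice the 2n location
  expect_equal(median(ev$dna[ev$label == "G2M"]), 200, tolerance = 0.02)
  expect_equal(median(ev$dna[ev$label %in% c("G0", "G1")]), 100,
               tolerance = 0.02)
  # G0 RNA strictly below proliferating phases
  expect_lt(quantile(ev$rna[ev$label == "G0"], 0.99),
            quantile(ev$rna[ev$label != "G0"], 0.01))
  ev0 <- simulate_cytometry_events(500, c(G0 = 1, G1 = 0, S = 0, G2M = 0),
                                   seed = 1)
  expect_true(all(ev0$label == "G0"))
  expect_equal(median(ev0$dna), 100, tolerance = 0.05)
  expect_error(simulate_cytometry_events(100, rna_scale = 0), "scale")
  expect_error(simulate_cytometry_events(100,
                                         c(G0 = 0.5, G1 = 0.4, S = 0.2,
                                           G2M = 0.1)))
})

test_that("confluence curves follow lag-exponential-plateau kinetics on the grid", {
  cv <- simulate_confluence_curve(0.05, 0.01, lag = 0, t_max = 96, dt = 1.5)
  expect_equal(nrow(cv), 65)  # 96 / 1.5 + 1 points
  keep <- cv$confluence < 1
  fit <- stats::lm(log10(confluence) ~ time_h, data = cv[keep, ])
  expect_equal(unname(coef(fit)), c(log10(0.05), 0.01), tolerance = 1e-10)
  # zero rate: constant
  flat <- simulate_confluence_curve(0.2, 0, t_max = 48)
  expect_true(all(flat$confluence == 0.2))
  # lag phase is flat at c0
  lagged <- simulate_confluence_curve(0.1, 0.02, lag = 30, t_max = 96)
  expect_true(all(lagged$confluence[lagged$time_h < 30] == 0.1))
  expect_error(simulate_confluence_curve(0.5, 0.01, plateau = 0.4))
})
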