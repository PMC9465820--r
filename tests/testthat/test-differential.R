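test_that("effect sizes follow the pooled-SD standardization", {
  # hand-evaluated: pooled = sqrt((9 + 16)/2), d = 6 / 3.5355...
  expect_equal(effect_size(10, 4, 4, 3), 6 / sqrt(12.5), tolerance = 1e-12)
  expect_equal(round(effect_size(10, 4, 4, 3), 4), 1.6971)
  expect_equal(effect_size(5, 5, 1, 2), 0)
  # antisymmetry under swapping the populations
  expect_equal(effect_size(3, 8, 1, 2), -effect_size(8, 3, 2, 1))
  # undefined for zero pooled SD
  expect_true(is.na(effect_size(3, 1, 0, 0)))
  # invariant to a common positive rescaling
  expect_equal(effect_size(10, 4, 4, 3), effect_size(10e3, 4e3, 4e3, 3e3))
})

test_that("effect-size tables pair the condition coefficients correctly", {
  conds <- data.frame(cell_line = c("A", "B"), stimulus = "starv")
  tr <- true_population_profile(4, conditions = conds, seed = 4)
  ex <- simulate_mix_experiment(tr, model = measurement_model(
    noise_cv = 0.05, seed = 6))
  fit <- bootstrap_errors(fit_alphas(ex$intensities, ex$design),
                          n_reps = 30, seed = 1)
  eff <- effect_size_table(fit)
  expect_equal(nrow(eff), 4 * 2)
  co <- fit$coefficients
  i <- which(eff$ion == "ion0001" & eff$cell_line == "A")
  aQ <- co$alpha[co$ion == "ion0001" & co$cell_line == "A" &
                   co$population == "Q"]
  aP <- co$alpha[co$ion == "ion0001" & co$cell_line == "A" &
                   co$population == "P"]
  expect_equal(sign(eff$d[i]), sign(aQ - aP))
  expect_error(effect_size_table(fit_alphas(ex$intensities, ex$design)),
               "bootstrap")
})

test_that("hypergeometric tail probabilities match exhaustive enumeration", {
  # toy case: 40 pooled entries, 10 beyond the threshold, 18 drawn, 9 hit
  expect_equal(mixdeconv:::hyper_upper_tail(9, 10, 40, 18),
               enum_hyper_tail(9, 10, 40, 18), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:300) {
    N <- sample(5:60, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(mixdeconv:::hyper_upper_tail(k, K, N, n),
                 enum_hyper_tail(k, K, N, n), tolerance = 1e-12)
  }
})

test_that("quiescence association scores consistent ions and degenerate cases", {
  set.seed(5)
  d <- matrix(rnorm(50 * 18, 0, 2), 50, 18,
              dimnames = list(sprintf("ion%02d", 1:50), NULL))
  d[1, ] <- abs(rnorm(18, 8, 1))     # strongly, consistently up
  d[2, ] <- -abs(rnorm(18, 8, 1))    # strongly, consistently down
  res <- g0_association(d, thresholds = 3:6)
  expect_equal(res$direction[1], 1)
  expect_equal(res$direction[2], -1)
  expect_equal(res$g0_association[1], 1)
  expect_equal(res$g0_association[2], -1)
  expect_lt(res$p_adjusted[1], 0.01)
  expect_true(all(res$threshold %in% 3:6))
  # an ion passing nothing gets association 0, p = 1
  d0 <- d
  d0[3, ] <- 0.1
  res0 <- g0_association(d0, thresholds = 3:6)
  expect_equal(res0$g0_association[3], 0)
  expect_equal(res0$p_value[3], 1)
  # degenerate pool: every entry beyond the threshold forces p = 1
  dall <- matrix(10, 5, 18)
  resall <- g0_association(dall, thresholds = 3)
  expect_true(all(resall$p_value == 1))
  expect_true(all(resall$g0_association == 1))
})

test_that("association p-values reproduce a direct hypergeometric computation", {
  # small fixed table checked against the enumeration oracle
  d <- rbind(c(5, 6, 7, -1, 4, 5),
             c(0.5, 1, -2, 0.2, 0.1, -0.5),
             c(4, 4, 4, 4, 4, 4),
             c(-6, -7, -5, 1, 2, -8))
  rownames(d) <- paste0("i", 1:4)
  res <- g0_association(d, thresholds = 3)
  pos_pool <- d[d > 0]
  K <- sum(pos_pool > 3)          # positive entries beyond the threshold
  N <- length(pos_pool)           # all positive entries pooled
  p1 <- enum_hyper_tail(5, K, N, min(6, N))
  expect_equal(res$p_value[1], p1, tolerance = 1e-12)
  neg_pool <- d[d < 0]
  p4 <- enum_hyper_tail(4, sum(neg_pool < -3), length(neg_pool),
                        min(6, length(neg_pool)))
  expect_equal(res$p_value[4], p4, tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up rule and excludes NAs from m", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  out <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], stats::p.adjust(c(0.01, 0.04), "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)))
})

test_that("stimulus ANOVA detects planted shifts and stays calibrated under the null", {
  set.seed(9)
  grid <- expand.grid(stimulus = c("starv", "contact", "gln"),
                      rep = 1:6, stringsAsFactors = FALSE)
  null_p <- replicate(200, {
    d <- data.frame(ion = "x", stimulus = grid$stimulus,
                    value = rnorm(nrow(grid)))
    stimulus_anova(d)$p_value
  })
  expect_lt(abs(mean(null_p < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / 200))
  shifted <- data.frame(ion = "x", stimulus = grid$stimulus,
                        value = rnorm(nrow(grid), 0, 0.1) +
                          ifelse(grid$stimulus == "gln", 5, 0))
  expect_lt(stimulus_anova(shifted)$p_adjusted, 0.05)
  tiny <- data.frame(ion = "x", stimulus = c("a", "b", "b"),
                     value = c(1, 2, 3))
  expect_error(stimulus_anova(tiny), ">= 2")
})

test_that("dynamic fold-changes are zero on-model and recover planted depletion", {
  set.seed(14)
  conf_ss <- seq(0.2, 0.9, length.out = 12)
  slope <- c(1000, 500)
  inter <- c(200, 100)
  steady <- cbind(inter[1] + slope[1] * conf_ss,
                  inter[2] + slope[2] * conf_ss)
  conf_tc <- c(0.3, 0.5, 0.7, 0.3, 0.5, 0.7)
  treated <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expected <- cbind(inter[1] + slope[1] * conf_tc,
                    inter[2] + slope[2] * conf_tc)
  measured <- expected
  measured[treated, 1] <- expected[treated, 1] / 4   # planted 4x depletion
  measured[treated, 2] <- expected[treated, 2] * 2   # planted 2x increase
  fc <- dynamic_fold_change(measured, conf_tc, treated, steady, conf_ss)
  expect_equal(unname(fc$log2fc[!treated, ]), matrix(0, 3, 2),
               tolerance = 1e-9)
  expect_equal(unname(fc$log2fc[treated, 1]), rep(-2, 3), tolerance = 1e-9)
  expect_equal(unname(fc$log2fc[treated, 2]), rep(1, 3), tolerance = 1e-9)
  expect_false(any(fc$extrapolated))
  fc2 <- dynamic_fold_change(measured, conf_tc + 1, treated, steady,
                             conf_ss)
  expect_true(all(fc2$extrapolated))
})
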