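# A generated cohort with enough smokers per cell to exercise the balanced
# samplers: flat 45% smoking, even sexes.
feasible_cohort <- function(n = 30000, seed = 2)
  gen_cohort("B", n = n, seed = seed,
             smoking = list(overall = 0.45, men_ratio = 1, age_shape = "flat"))

test_that("cell-balanced down-sampling yields exact per-cell counts", {
  coh <- feasible_cohort()
  sub <- downsample_balanced(coh, total_n = 268, seed = 5, balance = "cell")
  expect_equal(nrow(sub), 268L)
  tab <- table(sub$age, sub$sex, sub$smoker)
  expect_true(all(tab[as.character(18:84), , ] == 1L))
  expect_equal(mean(sub$smoker), 0.5)
  expect_equal(mean(sub$sex == "man"), 0.5)
  # determinism
  sub2 <- downsample_balanced(coh, total_n = 268, seed = 5, balance = "cell")
  expect_identical(as.data.frame(sub), as.data.frame(sub2))
})

test_that("down-sampling errors are loud and specific", {
  coh <- feasible_cohort(n = 4000)
  expect_error(downsample_balanced(coh, total_n = 270, balance = "cell"),
               "multiple of 4 x 67")
  expect_error(downsample_balanced(coh, total_n = 4 * 67 * 20,
                                   balance = "cell"),
               "cell age=.*need 20")
  expect_error(downsample_balanced(coh, total_n = 3999, balance = "group"),
               "multiple of 4")
  expect_error(downsample_balanced(coh, total_n = 4000, balance = "group"),
               "group sex=.*need 1000")
})

test_that("group-balanced down-sampling equalizes the four groups", {
  coh <- gen_cohort("B", n = 30000, seed = 3)
  sub <- downsample_balanced(coh, total_n = 2000, seed = 9)
  expect_equal(as.numeric(table(sub$sex, sub$smoker)), rep(500, 4))
})

test_that("FWL focal refits equal full OLS refits exactly", {
  coh <- gen_cohort("A", n = 1500, seed = 20)
  pert <- inject_error(coh, rate = 0.10, seed = 1)
  fit_ref <- pal_lm(pert)
  study <- error_injection_study(coh, rates = 0.10, reps = 1L,
                                 seed = 1, mode = "invert")
  got <- study$replicates
  for (tm in c("smokerTRUE", "smokerTRUE:sexman")) {
    expect_equal(got$beta[got$term == tm],
                 term_estimate(fit_ref, tm)$beta, tolerance = 1e-10)
    expect_equal(got$p[got$term == tm],
                 term_estimate(fit_ref, tm)$p, tolerance = 1e-10)
  }
})

test_that("error injection at rate zero reproduces the unperturbed fit", {
  coh <- gen_cohort("A", n = 2000, seed = 21)
  expect_identical(inject_error(coh, 0, seed = 3), coh)
  st <- error_injection_study(coh, rates = 0, reps = 2L, seed = 3)
  fit <- pal_lm(coh)
  expect_equal(unique(st$replicates$p[st$replicates$term == "smokerTRUE"]),
               term_estimate(fit, "smokerTRUE")$p, tolerance = 1e-12)
})

test_that("inject_error flips exactly the requested fraction, reproducibly", {
  coh <- gen_cohort("A", n = 10000, seed = 22)
  a <- inject_error(coh, 0.10, seed = 4)
  b <- inject_error(coh, 0.10, seed = 4)
  expect_identical(a, b)
  expect_equal(sum(a$smoker != coh$smoker), 1000L)
  c2 <- inject_error(coh, 0.10, seed = 5)
  expect_false(identical(a, c2))
  expect_error(inject_error(coh, 0.2), "max_rate")
  expect_error(inject_error(coh, -0.1), "rate")
  expect_silent(inject_error(coh, 0.2, max_rate = 0.5))
})

test_that("label inversion mixes prevalence and attenuates per closed form", {
  # labeled prevalence: 0.9 p + 0.1 (1 - p)
  coh <- gen_cohort("A", n = 60000, seed = 23)
  p0 <- mean(coh$smoker)
  lab <- mean(inject_error(coh, 0.10, seed = 6)$smoker)
  expect_equal(lab, 0.9 * p0 + 0.1 * (1 - p0), tolerance = 0.01)
  # attenuation factor from independent probability algebra
  p <- 0.079; r <- 0.10
  p_ls <- (1 - r) * p + r * (1 - p)
  oracle <- (1 - r) * p / p_ls - r * p / (1 - p_ls)
  expect_equal(attenuation_factor(0.10, 0.079), oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.427, tolerance = 0.005)
  # Monte Carlo oracle: a pure two-group mean difference shrinks by the factor
  set.seed(7)
  n <- 200000; delta <- 3
  s <- runif(n) < 0.079
  y <- delta * s + rnorm(n, 0, 1)
  flip <- sample.int(n, n / 10)
  s2 <- s; s2[flip] <- !s2[flip]
  est <- mean(y[s2]) - mean(y[!s2])
  expect_equal(est, delta * attenuation_factor(0.10, 0.079),
               tolerance = 0.05)
})

test_that("power curve is calibrated under the null and rises with size", {
  nul <- gen_cohort("NULL", n = 20000, seed = 30)
  pc0 <- power_curve(nul, sizes = 2000, reps = 300, seed = 31)
  expect_gt(pc0$summary$fraction_significant, 0.015)
  expect_lt(pc0$summary$fraction_significant, 0.10)
  cohB <- gen_cohort("B", n = 20000, seed = 30)
  pc <- power_curve(cohB, sizes = c(400, 1200, 2000), reps = 300, seed = 32)
  fr <- pc$summary$fraction_significant
  expect_gt(fr[3], fr[1] - 0.02)  # monotone within Monte Carlo error
  expect_equal(pc$summary$reps, rep(300, 3))
})

test_that("significant sign flips appear at small balanced sizes", {
  cohB <- gen_cohort("B", n = 20000, seed = 33)
  pc <- power_curve(cohB, sizes = 268, reps = 2000, seed = 34)
  expect_gt(pc$summary$sign_flips, 0)
  expect_lt(pc$summary$sign_flips / 2000, 0.05)
})

test_that("min_n_for_power follows its definition", {
  fake <- structure(list(summary = data.frame(
    size = c(5000, 10000, 13000),
    fraction_significant = c(0.3, 0.55, 0.7))), class = "power_curve")
  expect_equal(min_n_for_power(fake, 0.5), 10000)
  fake$summary$fraction_significant <- c(0.1, 0.2, 0.3)
  expect_message(out <- min_n_for_power(fake, 0.5), "not reached")
  expect_true(is.na(out))
  expect_error(min_n_for_power(fake, 1.5), "threshold")
})

test_that("permutation p matches exhaustive enumeration on a tiny cohort", {
  pal <- c(5L, 9L, 30L, 22L, 17L, 12L, 26L)
  coh <- toy_cohort(7, smoker = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                                  FALSE), pal = pal)
  spec <- model_spec(by = NULL, interaction = FALSE, covariates = "age")
  # exhaustive oracle over all C(7,3) = 35 label arrangements
  combos <- combn(7, 3)
  tstat <- function(sm) {
    f <- summary(lm(pal_total ~ smoker + age, data = as.data.frame(coh) |>
                      transform(smoker = sm)))
    f$coefficients["smokerTRUE", "t value"]
  }
  t_obs <- tstat(coh$smoker)
  t_all <- apply(combos, 2, function(ix) tstat(seq_len(7) %in% ix))
  exact_p <- mean(abs(t_all) >= abs(t_obs) - 1e-12)
  pt <- permutation_test(coh, spec, term = "smokerTRUE",
                         permutations = 4000, seed = 40)
  expect_equal(pt$observed_t, t_obs, tolerance = 1e-10)
  expect_equal(pt$p_empirical, exact_p, tolerance = 0.03)
})

test_that("permutation p is uniform under the null and matches parametric p", {
  nul <- gen_cohort("NULL", n = 3000, seed = 41)
  ps <- sapply(1:20, function(s) {
    sub <- gen_cohort("NULL", n = 3000, seed = 600 + s)
    permutation_test(sub, term = "smokerTRUE", permutations = 199,
                     seed = s)$p_empirical
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.005)
  big <- gen_cohort("NULL", n = 20000, seed = 42)
  pt <- permutation_test(big, term = "smokerTRUE", permutations = 400,
                         seed = 43)
  par_p <- term_estimate(pal_lm(big), "smokerTRUE")$p
  expect_lt(abs(pt$p_empirical - par_p), 0.1)
  expect_gt(pt$p_empirical, 0); expect_lte(pt$p_empirical, 1)
})

test_that("degenerate permutation inputs error", {
  coh <- toy_cohort(40)
  expect_error(permutation_test(coh, model_spec(by = NULL,
                                                interaction = FALSE,
                                                covariates = "age"),
                                permutations = 10),
               "constant")
})
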