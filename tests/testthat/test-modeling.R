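test_that("the default design expands to 30 non-intercept columns", {
  coh <- gen_cohort("A", n = 300, seed = 1)
  d <- build_design(coh)
  expect_equal(ncol(d$X), 31L)
  expect_equal(colnames(d$X)[1], "(Intercept)")
  expect_setequal(colnames(d$X)[d$focal_cols],
                  c("smokerTRUE", "smokerTRUE:sexman"))
  # a small spec counts as expected: intercept + exposure + 2 covariates
  small <- model_spec(by = NULL, interaction = FALSE,
                      covariates = c("age", "diabetes"))
  expect_equal(ncol(build_design(coh, small)$X), 4L)
})

test_that("constant columns raise a rank-deficiency error naming them", {
  coh <- as.data.frame(gen_cohort("A", n = 200, seed = 1))
  coh$diabetes <- FALSE
  expect_error(
    build_design(coh, model_spec(by = NULL, interaction = FALSE,
                                 covariates = c("age", "diabetes"))),
    "collinear.*diabetes")
})

test_that("pal_lm reproduces stats::lm and the normal equations exactly", {
  coh <- gen_cohort("A", n = 800, seed = 13)
  fit <- pal_lm(coh)
  ref <- lm(pal_total ~ smoker + sex + age + race + ethnicity +
              marital_status + handedness + education + daily_medications +
              diabetes + seizures + cancer + stroke + hypertension +
              heart_disease + family_history_ad + drug_abuse +
              loss_of_consciousness + dizziness + smoker:sex,
            data = as.data.frame(coh))
  s <- summary(ref)
  cf <- s$coefficients[fit$terms$term, ]
  expect_equal(fit$terms$beta, unname(cf[, 1]), tolerance = 1e-10)
  expect_equal(fit$terms$se, unname(cf[, 2]), tolerance = 1e-10)
  expect_equal(fit$terms$t, unname(cf[, 3]), tolerance = 1e-10)
  expect_equal(fit$terms$p, unname(cf[, 4]), tolerance = 1e-10)
  expect_equal(fit$F, unname(s$fstatistic[1]), tolerance = 1e-10)
  expect_equal(fit$df2, fit$n - (fit$df1 + 1L))
  # normal-equations oracle on the same design
  d <- build_design(coh)
  beta_ne <- solve(t(d$X) %*% d$X, t(d$X) %*% d$y)
  expect_equal(fit$terms$beta, as.numeric(beta_ne), tolerance = 1e-8)
})

test_that("with a balanced 2x2 design the interaction is the diff-in-diff", {
  pal <- c(10L, 12L, 20L, 14L, 11L, 13L, 21L, 15L)
  coh <- toy_cohort(8,
                    smoker = rep(c(TRUE, TRUE, FALSE, FALSE), 2),
                    sex = rep(c("woman", "man"), 4),
                    pal = pal)
  fit <- pal_lm(coh, model_spec(covariates = character(0)))
  cells <- tapply(coh$pal_total, list(coh$smoker, coh$sex), mean)
  did <- (cells["TRUE", "man"] - cells["FALSE", "man"]) -
    (cells["TRUE", "woman"] - cells["FALSE", "woman"])
  expect_equal(term_estimate(fit, "smokerTRUE:sexman")$beta, did,
               tolerance = 1e-10)
})

test_that("zero-noise fits recover configured truths exactly and fix signs", {
  cfg <- scenario_config("A", noise_sd = 1e-9, clip_and_round = FALSE)
  # the CVD sum effects are deliberately non-additive in the four booleans;
  # zero them so the outcome lies exactly in the model span
  cfg$outcome_effects$cvd <- list(woman = c(0, 0, 0), man = c(0, 0, 0))
  coh <- generate_cohort(cfg, n = 4000, seed = 2)
  fit <- pal_lm(coh)
  # man = 1 coding: smoker main effect is the women's effect; the positive
  # interaction says smoking is less negative for men
  expect_equal(term_estimate(fit, "smokerTRUE")$beta, -1.01,
               tolerance = 1e-5)
  expect_equal(term_estimate(fit, "smokerTRUE:sexman")$beta,
               -0.27 - (-1.01), tolerance = 1e-5)
  se <- simple_effects(coh)
  bw <- term_estimate(se$woman, "smokerTRUE")$beta
  bm <- term_estimate(se$man, "smokerTRUE")$beta
  expect_equal(bw, -1.01, tolerance = 1e-5)
  expect_equal(bm, -0.27, tolerance = 1e-5)
  # pooled interaction equals the difference of stratified effects
  expect_equal(term_estimate(fit, "smokerTRUE:sexman")$beta, bm - bw,
               tolerance = 1e-5)
  # all-zero truth: focal estimates vanish
  nul <- generate_cohort(scenario_config("NULL", noise_sd = 1e-9,
                                         clip_and_round = FALSE),
                         n = 2000, seed = 2)
  fit0 <- pal_lm(nul)
  expect_lt(abs(term_estimate(fit0, "smokerTRUE")$beta), 1e-6)
  expect_lt(abs(term_estimate(fit0, "smokerTRUE:sexman")$beta), 1e-6)
})

test_that("stratified simple effects equal manual per-stratum refits", {
  coh <- gen_cohort("A", n = 3000, seed = 6)
  se <- simple_effects(coh)
  for (s in c("woman", "man")) {
    sub <- as.data.frame(coh)[coh$sex == s, ]
    man <- pal_lm(sub, model_spec(by = NULL, interaction = FALSE))
    expect_equal(se[[s]]$terms, man$terms, tolerance = 1e-12)
  }
  expect_error(simple_effects(coh, stratifier = "race"), "binary")
})

test_that("cvd_composite sums and caps groups as defined", {
  rec <- list(heart_disease = FALSE, hypertension = TRUE, diabetes = FALSE,
              stroke = FALSE)
  expect_equal(cvd_composite(rec)$sum, 1L)
  expect_equal(as.character(cvd_composite(rec)$group), "1")
  all4 <- list(heart_disease = TRUE, hypertension = TRUE, diabetes = TRUE,
               stroke = TRUE)
  expect_equal(cvd_composite(all4)$sum, 4L)
  expect_equal(as.character(cvd_composite(all4)$group), "3+")
  none <- lapply(all4, function(x) FALSE)
  expect_equal(as.character(cvd_composite(none)$group), "0")
})

test_that("the CVD model uses group 0 as reference and flags empty groups", {
  coh <- gen_cohort("cvd", n = 20000, seed = 6)
  fit <- fit_cvd_model(coh)
  expect_equal(fit$df1, 12L)
  expect_true(all(c("cvd_group1:sexman", "cvd_group3+:sexman") %in%
                    fit$terms$term))
  # zero effects, zero noise: group estimates vanish
  cfg <- scenario_config("NULL", noise_sd = 1e-9, clip_and_round = FALSE)
  fit0 <- fit_cvd_model(generate_cohort(cfg, n = 5000, seed = 3))
  expect_lt(max(abs(fit0$terms$beta[grepl("cvd_group", fit0$terms$term)])),
            1e-6)
  # a cohort with no 3+ participants errors with the group sizes
  small <- as.data.frame(gen_cohort("A", n = 400, seed = 8))
  s4 <- cvd_composite(small)$sum
  small <- small[s4 < 3, ]
  expect_error(fit_cvd_model(small), "empty CVD group")
})

test_that("scenario-cvd recovers the configured interaction and 3+ effects", {
  coh <- gen_cohort("cvd", n = 81701, seed = 4)
  fit <- fit_cvd_model(coh)
  g1 <- term_estimate(fit, "cvd_group1:sexman")
  expect_lt(abs(g1$beta - (-0.84)), 2 * 0.14)
  men <- fit_cvd_model(coh, stratum = "man")
  g3 <- term_estimate(men, "cvd_group3+")
  expect_lt(abs(g3$beta - (-1.80)), 2 * 0.41)
})

test_that("stability selection keeps real covariates and drops pure noise", {
  coh <- gen_cohort("A", n = 81701, seed = 11)
  sel <- stability_selection(coh, subsamples = 25L, seed = 11)
  expect_true(all(sel$frequency >= 0.7))
  expect_setequal(sel$retained, covariate_names())
  # under the all-zero scenario every covariate is pure noise; with a
  # conservative penalty its selection frequency stays far below the cutoff
  nul <- gen_cohort("NULL", n = 40000, seed = 10)
  sel0 <- stability_selection(nul, subsamples = 20L, seed = 10,
                              lambda_scale = 1.0)
  expect_lt(mean(sel0$frequency), 0.3)
  expect_lt(length(sel0$retained), 3L)
  small <- gen_cohort("A", n = 2000, seed = 1)
  expect_error(stability_selection(small, cutoff = 1.5), "cutoff")
  expect_error(stability_selection(small, subsamples = 1L), "subsamples")
})
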