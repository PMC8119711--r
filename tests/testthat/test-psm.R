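# Women-only confounded config: smoking depends on covariates, so matching
# has real work to do.
confounded_women <- function(n = 20000, seed = 1, effect = -0.54)
  generate_cohort(
    scenario_config("A", p_woman = 1,
                    outcome_effects = utils::modifyList(
                      default_effects(), list(smoking_woman = effect)),
                    confounding = list(age = -0.03, education = -0.25,
                                       daily_medications = 0.10,
                                       drug_abuse = 1.0)),
    n = n, seed = seed)

test_that("propensity scores collapse to the prevalence without confounding", {
  coh <- gen_cohort("A", n = 8000, seed = 50,
                    smoking = list(overall = 0.079, men_ratio = 1,
                                   age_shape = "flat"))
  ps <- estimate_propensity(coh)
  expect_equal(mean(ps), mean(coh$smoker), tolerance = 1e-6)
  expect_lt(sd(ps), 0.05)
  expect_true(all(ps > 0 & ps < 1))
  # deterministic: no RNG involved
  expect_identical(ps, estimate_propensity(coh))
})

test_that("propensity equals cell rates for a saturated single covariate", {
  n <- 200
  drug <- rep(c(TRUE, FALSE), c(40, 160))
  smoker <- c(rep(c(TRUE, FALSE), c(20, 20)),   # 50% among drug users
              rep(c(TRUE, FALSE), c(16, 144)))  # 10% among the rest
  coh <- toy_cohort(n, smoker = smoker)
  coh$drug_abuse <- drug
  ps <- estimate_propensity(coh, covariates = "drug_abuse")
  expect_equal(unique(round(ps[drug], 8)), 0.5)
  expect_equal(unique(round(ps[!drug], 8)), 0.1)
})

test_that("matching reproduces the enumerable toy assignment", {
  coh <- toy_cohort(4, smoker = c(TRUE, TRUE, FALSE, FALSE))
  scores <- c(0.9, 0.1, 0.8, 0.2)
  m <- match_smokers(coh, scores)
  expect_equal(m$pairs$smoker_row[order(m$pairs$smoker_row)], c(1, 2))
  got <- m$pairs$nonsmoker_row[order(m$pairs$smoker_row)]
  expect_equal(got, c(3, 4))  # 0.9<->0.8 and 0.1<->0.2
  expect_equal(m$unmatched, 0L)
})

test_that("matching achieves balance with overlap and flags its absence", {
  coh <- confounded_women(n = 12000, seed = 51)
  ps <- estimate_propensity(coh)
  m <- match_smokers(coh, ps)
  bal <- m$balance
  psrow <- bal[bal$covariate == "propensity_score", ]
  expect_lte(abs(psrow$smd_after), abs(psrow$smd_before) + 1e-8)
  expect_lt(abs(psrow$smd_after), 0.05)
  expect_equal(nrow(m$pairs), sum(coh$smoker))
  # disjoint score supports: matching cannot balance, diagnostics say so
  toy <- toy_cohort(40, smoker = rep(c(TRUE, FALSE), each = 20))
  scores <- ifelse(toy$smoker, 0.95, 0.05)
  m2 <- match_smokers(toy, scores)
  ps2 <- m2$balance[m2$balance$covariate == "propensity_score", ]
  expect_gt(abs(ps2$smd_after), 1)
})

test_that("a caliper leaves distant smokers unmatched and counted", {
  coh <- toy_cohort(6, smoker = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  scores <- c(0.9, 0.5, 0.1, 0.52, 0.48, 0.11)
  m <- match_smokers(coh, scores, caliper = 0.5)
  expect_equal(m$unmatched, 1L)  # the 0.9 smoker has no close candidate
  expect_equal(sort(m$unmatched_rows), 1L)
})

test_that("matched_effect is exact on zero-noise data and draw counts guard", {
  coh <- toy_cohort(40, smoker = rep(c(TRUE, FALSE), 20),
                    pal = as.integer(20 - 3 * rep(c(TRUE, FALSE), 20)))
  ps <- rep(0.5, 40)
  m <- match_smokers(coh, ps, covariates = "age")
  eff <- suppressWarnings(  # lm warns about the perfect fit, by design here
    matched_effect(m, draws = 500, seed = 3, include_covariates = FALSE))
  expect_equal(eff$beta, -3, tolerance = 1e-10)
  expect_lt(eff$ci["upper"] - eff$ci["lower"], 1e-8)
  expect_error(matched_effect(m, draws = 50), "draws")
})

test_that("credible interval matches the normal-theory CI with many draws", {
  coh <- confounded_women(n = 8000, seed = 52)
  ps <- estimate_propensity(coh)
  m <- match_smokers(coh, ps)
  eff <- matched_effect(m, draws = 20000, seed = 4)
  # normal-theory oracle from the same matched regression
  fit <- lm(stats::reformulate(c("smoker", m$covariates), "pal_total"),
            data = m$data)
  se <- summary(fit)$coefficients["smokerTRUE", "Std. Error"]
  b <- coef(fit)[["smokerTRUE"]]
  expect_equal(eff$beta, b, tolerance = 1e-10)
  expect_lt(abs(eff$ci["lower"] - (b - 1.96 * se)), 0.1 * se)
  expect_lt(abs(eff$ci["upper"] - (b + 1.96 * se)), 0.1 * se)
  expect_true(eff$ci["lower"] <= eff$beta && eff$beta <= eff$ci["upper"])
})

test_that("matched effect agrees with the regression fit when unconfounded", {
  coh <- gen_cohort("A", n = 20000, seed = 53, p_woman = 1)
  ps <- estimate_propensity(coh)
  m <- match_smokers(coh, ps)
  eff <- matched_effect(m, draws = 1000, seed = 5)
  reg <- term_estimate(pal_lm(coh, model_spec(by = NULL,
                                              interaction = FALSE)),
                       "smokerTRUE")
  se_match <- (eff$ci["upper"] - eff$ci["lower"]) / (2 * 1.96)
  expect_lt(abs(eff$beta - reg$beta),
            2 * sqrt(se_match^2 + reg$se^2))
})

test_that("sex-stratified PSM equals manual per-stratum runs", {
  coh <- gen_cohort("A", n = 12000, seed = 54)
  both <- psm_by_sex(coh, draws = 300, seed = 9)
  for (s in c("woman", "man")) {
    sub <- as.data.frame(coh)[coh$sex == s, , drop = FALSE]
    rownames(sub) <- NULL
    class(sub) <- c("cohort", "data.frame")
    ps <- estimate_propensity(sub, setdiff(covariate_names(), "sex"))
    m <- match_smokers(sub, ps, covariates = setdiff(covariate_names(),
                                                     "sex"))
    eff <- matched_effect(m, draws = 300, seed = child_seed(9, "psm"))
    expect_equal(both[[s]]$effect$beta, eff$beta, tolerance = 1e-12)
    expect_equal(both[[s]]$effect$ci, eff$ci, tolerance = 1e-12)
  }
})
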