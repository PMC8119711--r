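# Shared fixtures, built in code.

# A hand-built, fully deterministic toy cohort. All covariates cycle through
# their level sets so nothing is constant; outcome is supplied or zero.
toy_cohort <- function(n, smoker = rep(c(TRUE, FALSE), length.out = n),
                       sex = rep(c("woman", "man"), length.out = n),
                       pal = rep(18L, n), age = rep(18:85, length.out = n)) {
  sc <- cohort_schema()
  cyc <- function(lv) rep(lv, length.out = n)
  df <- data.frame(
    age = age, sex = sex, smoker = smoker,
    education = cyc(sc$levels$education),
    race = cyc(sc$levels$race),
    ethnicity = cyc(sc$levels$ethnicity),
    marital_status = cyc(sc$levels$marital_status),
    handedness = cyc(sc$levels$handedness),
    daily_medications = rep(0:4, length.out = n),
    diabetes = rep(c(FALSE, FALSE, TRUE), length.out = n),
    seizures = rep(c(FALSE, TRUE), length.out = n),
    cancer = rep(c(TRUE, FALSE, FALSE), length.out = n),
    stroke = rep(c(FALSE, FALSE, FALSE, TRUE), length.out = n),
    hypertension = rep(c(TRUE, FALSE), length.out = n),
    heart_disease = rep(c(FALSE, TRUE, FALSE), length.out = n),
    family_history_ad = rep(c(TRUE, FALSE, FALSE, FALSE), length.out = n),
    drug_abuse = rep(c(FALSE, FALSE, FALSE, FALSE, TRUE), length.out = n),
    loss_of_consciousness = rep(c(FALSE, TRUE, FALSE), length.out = n),
    dizziness = rep(c(TRUE, FALSE, FALSE, FALSE), length.out = n),
    pal_total = pal)
  as_cohort(df, sc)
}

# Small generated cohort, cached per (scenario, n, seed) within a test run.
.gen_cache <- new.env(parent = emptyenv())
gen_cohort <- function(scenario = "A", n = 10000L, seed = 1L, ...) {
  key <- paste(scenario, n, seed, length(list(...)), sep = "_")
  if (length(list(...)) == 0 && !is.null(.gen_cache[[key]]))
    return(.gen_cache[[key]])
  coh <- generate_cohort(scenario_config(scenario, ...), n = n, seed = seed)
  if (length(list(...)) == 0) .gen_cache[[key]] <- coh
  coh
}

# Textbook Pearson chi-square on a contingency table (independent oracle).
pearson_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
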