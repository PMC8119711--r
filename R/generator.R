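# Synthetic cohort generator: composition-calibrated covariates, a latent
# linear outcome model with sex-specific exposure effects, and noise/effect
# calibration utilities.

#' Generator configuration
#'
#' All knobs of the synthetic cohort generator. Defaults reproduce the
#' composition of a large web-recruited cohort: 64.3% women, 7.9% current
#' smokers overall (men's rate above women's at every age), and per-sex
#' cardiovascular-disease (CVD) sum distributions of 77.4/17.9/4.1/0.6%
#' (women) and 78.1/16.6/4.3/1.0% (men) for sums 0/1/2/3+. The outcome is a
#' latent Gaussian paired-associate learning score, clipped to [0, 36] and
#' rounded by default.
#'
#' @param n Cohort size.
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @param p_woman Proportion of women.
#' @param smoking List: `overall` mean smoking prevalence, `men_ratio`
#'   (men's rate / women's rate at every age, >= 1), `age_shape` either
#'   `"logistic_decline"` (rates fall with age, midpoint `age_mid`, scale
#'   `age_scale`) or `"flat"`.
#' @param age_probs Probabilities over ages 18..85 (default uniform).
#' @param covariate_prevalences Named list of category probabilities for the
#'   non-CVD covariates (stand-ins; the source tables are not public).
#' @param cvd_target_distribution List with `woman` and `man`: probabilities
#'   of CVD sums 0/1/2/3+ over heart disease, hypertension, diabetes, stroke.
#' @param p_sum4_given_3plus Probability that a "3+" participant has all
#'   four conditions rather than three.
#' @param outcome_effects Named list of word-pair-unit coefficients: see
#'   Details.
#' @param noise_sd Residual standard deviation of the latent score, in word
#'   pairs; a scalar or a named vector `c(woman = , man = )`.
#' @param clip_and_round Clip the latent score to [0, 36] and round to an
#'   integer (the observed score has a floor and a ceiling). Disable for
#'   exact-recovery tests.
#' @param confounding `NULL` (smoking independent of the covariates given
#'   age and sex) or a named list of logistic coefficients on covariates
#'   (e.g. `list(age = 0.02, drug_abuse = 0.8)`) that makes smoking depend
#'   on them; the intercept is solved so the overall prevalence is kept.
#'
#' @details `outcome_effects` components: `intercept` (latent mean for an
#' 18-year-old woman with all reference levels), `age_slope` (per year),
#' `sex_offset` (men vs women), `smoking_woman`/`smoking_man`,
#' `cvd` = list(woman=, man=) of length-3 vectors (CVD groups 1/2/3+ vs 0),
#' and per-covariate nuisance effects (`education`, `race`, `ethnicity`,
#' `marital_status`, `handedness` as per-level vectors with the reference
#' first and equal in length to the level set; `daily_medications` slope;
#' scalars for the six non-CVD booleans).
#'
#' @return An object of class `generator_config` (a named list).
#' @seealso [scenario_config()] for the named presets.
#' @export
generator_config <- function(n = 81701,
                             seed = 1L,
                             p_woman = 0.643,
                             smoking = list(overall = 0.079, men_ratio = 1.3,
                                            age_shape = "logistic_decline",
                                            age_mid = 60, age_scale = 12),
                             age_probs = rep(1 / 68, 68),
                             covariate_prevalences = default_prevalences(),
                             cvd_target_distribution = list(
                               woman = c(0.774, 0.179, 0.041, 0.006),
                               man = c(0.781, 0.166, 0.043, 0.010)),
                             p_sum4_given_3plus = 0.2,
                             outcome_effects = default_effects(),
                             noise_sd = 8.26,
                             clip_and_round = TRUE,
                             confounding = NULL) {
  cfg <- list(n = n, seed = seed, p_woman = p_woman, smoking = smoking,
              age_probs = age_probs,
              covariate_prevalences = covariate_prevalences,
              cvd_target_distribution = cvd_target_distribution,
              p_sum4_given_3plus = p_sum4_given_3plus,
              outcome_effects = outcome_effects, noise_sd = noise_sd,
              clip_and_round = clip_and_round, confounding = confounding,
              schema = cohort_schema())
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' Default covariate category prevalences
#'
#' Plausible stand-ins for a web cohort's covariate composition (the
#' source study's supplemental tables are not public); every entry is
#' configurable through [generator_config()].
#' @return Named list of probability vectors.
#' @export
default_prevalences <- function() {
  list(education = c(0.25, 0.30, 0.30, 0.10, 0.05),
       race = c(0.80, 0.06, 0.06, 0.02, 0.06),
       ethnicity = c(0.92, 0.08),
       marital_status = c(0.35, 0.45, 0.12, 0.05, 0.03),
       handedness = c(0.88, 0.10, 0.02),
       daily_medications = local({
         p <- 0.55 ^ (0:10); p / sum(p)
       }),
       seizures = 0.03, cancer = 0.06, family_history_ad = 0.25,
       drug_abuse = 0.04, loss_of_consciousness = 0.08, dizziness = 0.10)
}

#' Default outcome effects (word pairs)
#'
#' Nuisance covariate effects are moderate and nonzero so that covariate
#' selection procedures have real signal to find; focal smoking/CVD effects
#' default to the stratified-truth preset (see [scenario_config()]).
#' @return Named list of coefficients.
#' @export
default_effects <- function() {
  list(intercept = 24, age_slope = -0.10, sex_offset = -2.0,
       smoking_woman = -1.01, smoking_man = -0.27,
       cvd = list(woman = c(-0.5, -0.9, -1.5), man = c(-0.5, -0.9, -1.5)),
       education = c(0, 0.8, 1.6, 2.2, 2.6),
       race = c(0, -0.6, -0.4, -0.5, -0.3),
       ethnicity = c(0, -0.4),
       marital_status = c(0, 0.3, -0.2, -0.5, -0.4),
       handedness = c(0, -0.3, -0.5),
       daily_medications = -0.12,
       seizures = -1.0, cancer = -0.5, family_history_ad = -0.3,
       drug_abuse = -0.9, loss_of_consciousness = -0.7, dizziness = -0.8)
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$n) || length(cfg$n) != 1L || cfg$n < 0 ||
      cfg$n != floor(cfg$n))
    abort_check("config error: n must be a non-negative integer")
  if (!is_prob(cfg$p_woman))
    abort_check("config error: p_woman must be a probability in [0, 1]")
  if (!is_prob(cfg$smoking$overall))
    abort_check("config error: smoking$overall must be in [0, 1]")
  if (cfg$smoking$men_ratio < 1)
    abort_check("config error: smoking$men_ratio must be >= 1 ",
                "(men's rate is at least women's at every age)")
  if (length(cfg$age_probs) != 68L || !is_prob(cfg$age_probs) ||
      abs(sum(cfg$age_probs) - 1) > 1e-8)
    abort_check("config error: age_probs must be 68 probabilities ",
                "(ages 18..85) summing to 1")
  for (s in c("woman", "man")) {
    p <- cfg$cvd_target_distribution[[s]]
    if (length(p) != 4L || !is_prob(p) || abs(sum(p) - 1) > 1e-6)
      abort_check("config error: cvd_target_distribution$", s,
                  " must be 4 probabilities summing to 1")
  }
  pv <- cfg$covariate_prevalences
  for (nm in c("education", "race", "ethnicity", "marital_status",
               "handedness")) {
    p <- pv[[nm]]
    if (is.null(p) || !is_prob(p) || abs(sum(p) - 1) > 1e-6 ||
        length(p) != length(cfg$schema$levels[[nm]]))
      abort_check("config error: covariate_prevalences$", nm,
                  " must match the schema levels and sum to 1")
  }
  for (nm in c("seizures", "cancer", "family_history_ad", "drug_abuse",
               "loss_of_consciousness", "dizziness"))
    if (!is_prob(pv[[nm]]) || length(pv[[nm]]) != 1L)
      abort_check("config error: covariate_prevalences$", nm,
                  " must be a probability")
  if (any(cfg$noise_sd <= 0))
    abort_check("config error: noise_sd must be > 0")
  invisible(cfg)
}

#' @method print generator_config
#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("<generator_config> n = %d, seed = %d\n",
                     "  women %.1f%%, smokers %.1f%% overall, noise sd %s\n",
                     "  clip_and_round = %s, confounded smoking = %s\n"),
              x$n, x$seed, 100 * x$p_woman, 100 * x$smoking$overall,
              paste(signif(x$noise_sd, 4), collapse = "/"),
              x$clip_and_round, !is.null(x$confounding)))
  invisible(x)
}

# per-sex noise sd vector c(woman, man)
noise_by_sex <- function(noise_sd) {
  if (length(noise_sd) == 1L) c(woman = noise_sd, man = noise_sd)
  else c(woman = noise_sd[["woman"]], man = noise_sd[["man"]])
}

smoking_base_rate <- function(cfg) {
  # women's scale constant c so that E_age,sex[p(age,sex)] = overall
  shp <- smoking_shape(18:85, cfg)
  e_shape <- sum(cfg$age_probs * shp)
  cfg$smoking$overall /
    (e_shape * (cfg$p_woman + (1 - cfg$p_woman) * cfg$smoking$men_ratio))
}

smoking_shape <- function(age, cfg) {
  if (identical(cfg$smoking$age_shape, "flat")) rep(1, length(age))
  else 1 / (1 + exp((age - cfg$smoking$age_mid) / cfg$smoking$age_scale))
}

#' Smoking prevalence as a function of age and sex
#'
#' The configured probability that a participant of the given age and sex is
#' a current smoker. The default curve declines with age, keeps men's rate
#' a fixed ratio above women's at every age, and integrates to the overall
#' prevalence (7.9% by default) under the configured age/sex distribution.
#'
#' @param age Ages in years, 18..85.
#' @param sex `"woman"` or `"man"` (recycled against `age`).
#' @param config A [generator_config()].
#' @return Probabilities.
#' @export
smoking_prevalence_curve <- function(age, sex, config = generator_config()) {
  if (any(age < 18 | age > 85)) abort_check("age out of range [18, 85]")
  sex <- as.character(sex)
  if (!all(sex %in% c("woman", "man"))) abort_check("sex must be woman/man")
  base <- smoking_base_rate(config)
  ratio <- ifelse(sex == "man", config$smoking$men_ratio, 1)
  p <- base * ratio * smoking_shape(age, config)
  pmin(p, 1)
}

# combinations of k of the 4 CVD conditions, used to spread component flags
# uniformly given a target sum
.cvd_combos <- local({
  out <- list()
  for (k in 0:4) {
    if (k == 0) out[[k + 1]] <- matrix(FALSE, 1, 4)
    else {
      cmb <- utils::combn(4, k)
      m <- matrix(FALSE, ncol(cmb), 4)
      for (j in seq_len(ncol(cmb))) m[j, cmb[, j]] <- TRUE
      out[[k + 1]] <- m
    }
  }
  out
})

#' Generate a synthetic cohort
#'
#' Draws `n` participant records per the configuration: demographics and
#' covariates from their prevalence tables, the four CVD booleans jointly so
#' the per-sex sum distribution matches its target, smoking from the
#' age/sex prevalence curve (or a logistic confounding model), and
#' `pal_total = round(clip(linear predictor + N(0, noise_sd), 0, 36))`.
#'
#' @param config A [generator_config()].
#' @param n,seed Optional overrides of the config's size and seed.
#' @return A validated `cohort` (when `clip_and_round` is `FALSE` the
#'   returned object carries the raw latent score in `pal_total` and the
#'   attribute `unclipped = TRUE`).
#' @export
generate_cohort <- function(config = generator_config(), n = config$n,
                            seed = config$seed) {
  validate_generator_config(config)
  schema <- config$schema
  eff <- config$outcome_effects
  with_seed(seed, {
    if (n == 0L) {
      empty <- stats::setNames(
        as.data.frame(matrix(nrow = 0, ncol = length(schema$columns))),
        schema$columns)
      for (nm in names(schema$levels))
        empty[[nm]] <- factor(character(), schema$levels[[nm]])
      for (nm in schema$booleans) empty[[nm]] <- logical()
      for (nm in names(schema$integers)) empty[[nm]] <- integer()
      return(as_cohort(empty, schema))
    }
    sex <- factor(ifelse(stats::runif(n) < config$p_woman, "woman", "man"),
                  schema$levels$sex)
    man <- sex == "man"
    age <- sample(18:85, n, replace = TRUE, prob = config$age_probs)
    pv <- config$covariate_prevalences
    draw_cat <- function(nm)
      factor(sample(schema$levels[[nm]], n, replace = TRUE, prob = pv[[nm]]),
             schema$levels[[nm]])
    education <- draw_cat("education")
    race <- draw_cat("race")
    ethnicity <- draw_cat("ethnicity")
    marital_status <- draw_cat("marital_status")
    handedness <- draw_cat("handedness")
    meds <- sample(0:10, n, replace = TRUE, prob = pv$daily_medications)
    seizures <- stats::runif(n) < pv$seizures
    cancer <- stats::runif(n) < pv$cancer
    family_history_ad <- stats::runif(n) < pv$family_history_ad
    drug_abuse <- stats::runif(n) < pv$drug_abuse
    loss_of_consciousness <- stats::runif(n) < pv$loss_of_consciousness
    dizziness <- stats::runif(n) < pv$dizziness

    # CVD: draw the per-sex sum group, then the component set uniformly
    grp <- integer(n)
    for (s in c("woman", "man")) {
      idx <- which(as.character(sex) == s)
      grp[idx] <- sample(0:3, length(idx), replace = TRUE,
                         prob = config$cvd_target_distribution[[s]])
    }
    csum <- grp
    is3 <- grp == 3L
    csum[is3] <- 3L + (stats::runif(sum(is3)) < config$p_sum4_given_3plus)
    flags <- matrix(FALSE, n, 4) # heart_disease, hypertension, diabetes, stroke
    for (k in 1:4) {
      idx <- which(csum == k)
      if (!length(idx)) next
      cmb <- .cvd_combos[[k + 1L]]
      pick <- sample.int(nrow(cmb), length(idx), replace = TRUE)
      flags[idx, ] <- cmb[pick, , drop = FALSE]
    }
    heart_disease <- flags[, 1]; hypertension <- flags[, 2]
    diabetes <- flags[, 3]; stroke <- flags[, 4]

    if (is.null(config$confounding)) {
      p_smoke <- smoking_prevalence_curve(age, as.character(sex), config)
      smoker <- stats::runif(n) < p_smoke
    } else {
      sc <- confounding_score(config$confounding, age, education, meds,
                              drug_abuse, man)
      a <- stats::uniroot(function(a) mean(stats::plogis(a + sc)) -
                            config$smoking$overall,
                          interval = c(-30, 30))$root
      smoker <- stats::runif(n) < stats::plogis(a + sc)
    }

    mu <- eff$intercept + eff$age_slope * (age - 18) +
      eff$sex_offset * man +
      ifelse(man, eff$smoking_man, eff$smoking_woman) * smoker +
      eff$education[as.integer(education)] +
      eff$race[as.integer(race)] +
      eff$ethnicity[as.integer(ethnicity)] +
      eff$marital_status[as.integer(marital_status)] +
      eff$handedness[as.integer(handedness)] +
      eff$daily_medications * meds +
      eff$seizures * seizures + eff$cancer * cancer +
      eff$family_history_ad * family_history_ad +
      eff$drug_abuse * drug_abuse +
      eff$loss_of_consciousness * loss_of_consciousness +
      eff$dizziness * dizziness
    cvd_eff_w <- c(0, eff$cvd$woman)
    cvd_eff_m <- c(0, eff$cvd$man)
    mu <- mu + ifelse(man, cvd_eff_m[grp + 1L], cvd_eff_w[grp + 1L])
    sds <- noise_by_sex(config$noise_sd)
    latent <- mu + stats::rnorm(n, 0, ifelse(man, sds["man"], sds["woman"]))

    df <- data.frame(age = age, sex = sex, smoker = smoker,
                     education = education, race = race,
                     ethnicity = ethnicity,
                     marital_status = marital_status,
                     handedness = handedness, daily_medications = meds,
                     diabetes = diabetes, seizures = seizures,
                     cancer = cancer, stroke = stroke,
                     hypertension = hypertension,
                     heart_disease = heart_disease,
                     family_history_ad = family_history_ad,
                     drug_abuse = drug_abuse,
                     loss_of_consciousness = loss_of_consciousness,
                     dizziness = dizziness)
    if (config$clip_and_round) {
      df$pal_total <- as.integer(round(pmin(36, pmax(0, latent))))
      as_cohort(df, schema)
    } else {
      df$pal_total <- latent
      attr(df, "schema") <- schema
      attr(df, "unclipped") <- TRUE
      attr(df, "latent_mean") <- mu
      class(df) <- c("cohort", "data.frame")
      df
    }
  })
}

confounding_score <- function(conf, age, education, meds, drug_abuse, man) {
  sc <- rep(0, length(age))
  if (!is.null(conf$age)) sc <- sc + conf$age * (age - mean(age))
  if (!is.null(conf$education))
    sc <- sc + conf$education * (as.integer(education) - 1L)
  if (!is.null(conf$daily_medications))
    sc <- sc + conf$daily_medications * meds
  if (!is.null(conf$drug_abuse)) sc <- sc + conf$drug_abuse * drug_abuse
  if (!is.null(conf$sex)) sc <- sc + conf$sex * man
  sc
}

#' Scenario presets
#'
#' Named, complete generator configurations:
#' \describe{
#'   \item{"A"}{stratified truth: women's smoking effect -1.01 word pairs,
#'     men's -0.27, per-sex noise so the stratified standard errors are
#'     0.14 (women) and 0.18 (men) at n = 81,701.}
#'   \item{"B"}{interaction truth: the pooled sex-by-smoking contrast is
#'     0.99 word pairs (women -1.01, men -0.02), noise so the pooled
#'     interaction standard error is 0.22 at n = 81,701.}
#'   \item{"NULL"}{all outcome effects zero: pure-noise outcome for type-I
#'     error calibration.}
#'   \item{"cvd"}{sex-specific CVD group effects: women -0.41/-0.67/-1.27
#'     for groups 1/2/3+, men -1.25/-2.05/-1.80, so the pooled group-1
#'     sex-by-CVD interaction is -0.84 and the men's stratified 3+ effect
#'     is -1.80.}
#' }
#' The shipped noise values were calibrated with [calibrate_noise()] under
#' the default composition; re-calibrate after changing any prevalence.
#'
#' @param name One of `"A"`, `"B"`, `"NULL"`, `"cvd"`.
#' @param ... Overrides passed to [generator_config()].
#' @return A `generator_config` with attribute `scenario`.
#' @export
scenario_config <- function(name = c("A", "B", "NULL", "cvd"), ...) {
  name <- match.arg(name)
  eff <- default_effects()
  args <- list(...)
  if (name == "A") {
    eff$smoking_woman <- -1.01; eff$smoking_man <- -0.27
    base <- list(outcome_effects = eff,
                 noise_sd = c(woman = 8.26, man = 8.92))
  } else if (name == "B") {
    eff$smoking_woman <- -1.01; eff$smoking_man <- -0.02
    base <- list(outcome_effects = eff, noise_sd = 8.26)
  } else if (name == "NULL") {
    eff <- lapply(eff, function(x) if (is.list(x)) lapply(x, function(y) y * 0)
                  else x * 0)
    eff$intercept <- 18
    base <- list(outcome_effects = eff, noise_sd = 8.26)
  } else { # cvd
    eff$smoking_woman <- -1.01; eff$smoking_man <- -0.27
    eff$cvd <- list(woman = c(-0.41, -0.67, -1.27),
                    man = c(-1.25, -2.05, -1.80))
    base <- list(outcome_effects = eff, noise_sd = 7.2)
  }
  cfg <- do.call(generator_config, utils::modifyList(base, args))
  attr(cfg, "scenario") <- name
  cfg
}

#' Expected standard error of the interaction in a balanced 2x2 design
#'
#' In a balanced two-by-two design with n/4 observations per cell and no
#' covariates, the difference-in-differences (interaction) estimator has
#' variance 16 sigma^2 / n, hence SE = 4 sigma / sqrt(n). Useful as the
#' closed-form branch of noise calibration and as a test oracle.
#'
#' @param noise_sd Residual standard deviation.
#' @param n Total sample size.
#' @return The standard error.
#' @export
balanced_interaction_se <- function(noise_sd, n) 4 * noise_sd / sqrt(n)

#' Calibrate outcome noise to a target coefficient standard error
#'
#' Finds the `noise_sd` at which the named model coefficient's standard
#' error equals `target_se` at size `n`. Because the standard error is
#' proportional to the residual sigma for a fixed design (exactly so without
#' clipping, approximately under mild floor/ceiling clipping), the search is
#' iterated proportional rescaling on simulated fits; it converges in 2-3
#' rounds. For the balanced 2x2 no-covariate design the closed form
#' `noise_sd = target_se * sqrt(n) / 4` applies (see
#' [balanced_interaction_se()]).
#'
#' @param config A [generator_config()].
#' @param term Coefficient name in the fitted model (e.g.
#'   `"sexman:smokerTRUE"` or `"smokerTRUE"`).
#' @param target_se Target standard error, word pairs.
#' @param n Size at which to calibrate (default `config$n`).
#' @param model `"smoking"` for the full covariate model, `"cvd"` for the
#'   CVD composite model.
#' @param stratum Optional sex stratum (`"woman"`/`"man"`): calibrates the
#'   stratified model's coefficient, rescaling that stratum's noise only.
#' @param iterations Rescaling rounds.
#' @param seed Seed for the simulated fits.
#' @param tol Relative tolerance on the achieved standard error.
#' @return The calibrated `noise_sd` (scalar or per-sex vector, matching the
#'   config), with attribute `achieved_se`.
#' @export
calibrate_noise <- function(config, term, target_se, n = config$n,
                            model = c("smoking", "cvd"), stratum = NULL,
                            iterations = 3L, seed = 1L, tol = 0.1) {
  model <- match.arg(model)
  if (!is.numeric(target_se) || length(target_se) != 1L || target_se <= 0)
    abort_check("target_se must be a positive number")
  sd_cur <- config$noise_sd
  achieved <- NA_real_
  for (it in seq_len(iterations)) {
    config$noise_sd <- sd_cur
    coh <- generate_cohort(config, n = n, seed = child_seed(seed, it))
    fit <- if (model == "smoking") {
      if (is.null(stratum)) pal_lm(coh)
      else pal_lm(coh[coh$sex == stratum, , drop = FALSE],
                  model_spec(interaction = FALSE, by = NULL))
    } else {
      if (is.null(stratum)) fit_cvd_model(coh)
      else fit_cvd_model(coh, stratum = stratum)
    }
    est <- fit$terms
    if (!term %in% est$term)
      abort_check("term '", term, "' not in the fitted model; available: ",
                  paste(est$term, collapse = ", "))
    achieved <- est$se[est$term == term]
    ratio <- target_se / achieved
    if (!is.null(stratum) && length(sd_cur) > 1L)
      sd_cur[stratum] <- sd_cur[stratum] * ratio
    else sd_cur <- sd_cur * ratio
    if (any(sd_cur > 1e3 * noise_by_sex(config$noise_sd)))
      abort_check("target_se ", target_se, " unreachable: required noise ",
                  "diverges (achieved SE ", signif(achieved, 3),
                  " at noise sd ", signif(max(sd_cur), 3), ")")
  }
  if (abs(achieved - target_se) / target_se > tol)
    abort_check("calibration did not converge: achieved SE ",
                signif(achieved, 4), " vs target ", target_se)
  attr(sd_cur, "achieved_se") <- achieved
  sd_cur
}

#' Floor/ceiling attenuation factor of the clipped outcome
#'
#' With clipping to [0, 36], a small shift of the latent mean moves the
#' observed mean by the interior Gaussian mass
#' `P(0 < latent < 36)` averaged over the cohort; regression coefficients on
#' the clipped score are attenuated by roughly this factor. Computed
#' analytically from the latent means of a generated cohort.
#'
#' @param config A [generator_config()].
#' @param n Monte Carlo size for the latent-mean distribution.
#' @param seed Seed.
#' @return The attenuation factor in (0, 1].
#' @export
clip_attenuation <- function(config, n = 20000L, seed = 1L) {
  cfg <- config
  cfg$clip_and_round <- FALSE
  coh <- generate_cohort(cfg, n = n, seed = seed)
  sds <- noise_by_sex(config$noise_sd)
  s <- ifelse(coh$sex == "man", sds["man"], sds["woman"])
  mu <- attr(coh, "latent_mean")
  mean(stats::pnorm((36 - mu) / s) - stats::pnorm((0 - mu) / s))
}

#' Calibrate a configured effect so the realized fitted coefficient matches
#' a target
#'
#' The simulation studies around a published analysis take as their input a
#' cohort whose *fitted* focal coefficient equals the published one (the
#' published cohort is the single realization those studies ran on). Given
#' a generation seed, this adjusts the configured latent effect so the
#' coefficient fitted on the cohort generated with that seed equals
#' `target`: because the fitted value is affine in the configured effect
#' for a fixed seed, one or two corrections converge.
#'
#' @param config A [generator_config()].
#' @param term `"smokerTRUE"` (adjusts the women's smoking effect) or
#'   `"smokerTRUE:sexman"` (adjusts the men's, shifting the interaction
#'   without moving the women's coefficient).
#' @param target Target fitted coefficient, word pairs.
#' @param seed The generation seed of the evaluation cohort.
#' @param n Cohort size.
#' @param stratum Optional sex stratum: calibrates the stratified model's
#'   coefficient instead of the pooled model's.
#' @param iterations Correction rounds.
#' @return The adjusted config.
#' @export
calibrate_fitted <- function(config, term, target, seed, n = config$n,
                             stratum = NULL, iterations = 2L) {
  knob <- if (grepl(":", term)) "smoking_man" else "smoking_woman"
  a <- if (config$clip_and_round) clip_attenuation(config, seed = seed) else 1
  for (it in seq_len(iterations)) {
    coh <- generate_cohort(config, n = n, seed = seed)
    fit <- if (is.null(stratum)) pal_lm(coh)
    else pal_lm(coh[coh$sex == stratum, , drop = FALSE],
                model_spec(by = NULL, interaction = FALSE))
    got <- term_estimate(fit, term)$beta
    config$outcome_effects[[knob]] <-
      config$outcome_effects[[knob]] + (target - got) / a
  }
  config
}

#' Rescale focal effects to compensate clipping attenuation
#'
#' Divides the configured smoking and CVD effects by the clip attenuation
#' factor so that coefficients fitted on the clipped, rounded score match
#' the configured targets (needed when a study design requires the fitted
#' values, not the latent truths, to equal published coefficients).
#'
#' @param config A [generator_config()].
#' @param n,seed Passed to [clip_attenuation()].
#' @return The config with rescaled focal effects; attenuation in attribute
#'   `attenuation`.
#' @export
calibrate_effect <- function(config, n = 20000L, seed = 1L) {
  if (!config$clip_and_round) return(config)
  a <- clip_attenuation(config, n = n, seed = seed)
  eff <- config$outcome_effects
  eff$smoking_woman <- eff$smoking_woman / a
  eff$smoking_man <- eff$smoking_man / a
  eff$cvd <- lapply(eff$cvd, function(v) v / a)
  config$outcome_effects <- eff
  attr(config, "attenuation") <- a
  config
}
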