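# Propensity-score matching of smokers to non-smokers: logistic propensity
# model, greedy 1:1 nearest-neighbour matching on the logit scale, balance
# diagnostics, and matched-set effect estimation with simulation-based 95%
# credible intervals.

#' Estimate smoking propensity scores
#'
#' Logistic regression of smoker status on the adjustment covariates;
#' returns each record's fitted probability of being a smoker.
#'
#' @param cohort A `cohort`.
#' @param covariates Covariate names (default the full adjustment set).
#' @return Numeric vector of probabilities in (0, 1); a warning reports any
#'   fitted values pinned at 0/1 (separation).
#' @export
estimate_propensity <- function(cohort, covariates = covariate_names()) {
  if (is.null(cohort$smoker)) abort_check("smoker column missing")
  bad <- setdiff(covariates, names(cohort))
  if (length(bad))
    abort_check("covariate(s) not in cohort: ", paste(bad, collapse = ", "))
  f <- stats::reformulate(covariates, response = "smoker")
  fit <- stats::glm(f, data = as.data.frame(cohort),
                    family = stats::binomial())
  p <- stats::fitted(fit)
  eps <- 1e-8
  pinned <- sum(p < eps | p > 1 - eps)
  if (pinned > 0)
    warning(pinned, " fitted propensity value(s) pinned at 0/1 (separation)")
  unname(p)
}

# Standardized mean difference of a numeric vector between two index sets,
# using the pooled pre-match sd as denominator.
smd <- function(x, treated, control, denom_sd) {
  d <- mean(x[treated]) - mean(x[control])
  if (denom_sd <= 0) return(0)
  d / denom_sd
}

# Expand covariates into numeric columns (dummies for factors, 0/1 for
# logicals) for balance diagnostics.
balance_columns <- function(cohort, covariates) {
  out <- list()
  for (nm in covariates) {
    x <- cohort[[nm]]
    if (is.factor(x)) {
      for (lev in levels(x)[-1L])
        out[[paste0(nm, lev)]] <- as.numeric(x == lev)
    } else out[[nm]] <- as.numeric(x)
  }
  out
}

#' Greedy 1:1 nearest-neighbour matching on the propensity score
#'
#' Matches each smoker to the nearest unused non-smoker by the distance on
#' the logit of the propensity score, processing smokers in descending
#' score order; no caliper by default. Distance ties are broken by record
#' order. Smokers with no remaining candidate (only possible with a
#' caliper) are left unmatched and counted.
#'
#' @param cohort A `cohort`.
#' @param scores Propensity scores from [estimate_propensity()].
#' @param caliper Optional maximum logit-scale distance.
#' @param covariates Covariates for the balance diagnostics (and carried
#'   into effect estimation).
#' @return An object of class `matched_cohort`: `pairs` (smoker and
#'   non-smoker row indices with their scores), `unmatched` count, `data`
#'   (the matched records), and `balance` (per-covariate standardized mean
#'   differences before/after, plus the propensity score itself).
#' @export
match_smokers <- function(cohort, scores, caliper = NULL,
                          covariates = covariate_names()) {
  n <- nrow(cohort)
  stopifnot(length(scores) == n)
  treated <- which(cohort$smoker)
  control <- which(!cohort$smoker)
  if (!length(treated) || !length(control))
    abort_check("both smokers and non-smokers must be present")
  lo <- stats::qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))

  ord_c <- control[order(lo[control], control)]  # ties by record order
  cl <- lo[ord_c]
  nc <- length(ord_c)
  nxt <- c(seq_len(nc)[-1L], NA_integer_)
  prv <- c(NA_integer_, seq_len(nc)[-nc])
  used <- logical(nc)
  first_alive <- 1L

  ord_t <- treated[order(-lo[treated], treated)]
  pair_t <- integer(0); pair_c <- integer(0)
  unmatched <- integer(0)
  pos_hint <- findInterval(lo[ord_t], cl)

  alive_left <- function(j) {  # nearest not-used position <= j
    while (!is.na(j) && j >= 1L && used[j]) j <- prv[j]
    if (is.na(j) || j < 1L) NA_integer_ else j
  }
  alive_right <- function(j) {
    while (!is.na(j) && j <= nc && used[j]) j <- nxt[j]
    if (is.na(j) || j > nc) NA_integer_ else j
  }

  for (i in seq_along(ord_t)) {
    t_idx <- ord_t[i]
    x <- lo[t_idx]
    jl <- alive_left(min(pos_hint[i], nc))
    jr <- alive_right(max(pos_hint[i] + 1L, 1L))
    dl <- if (is.na(jl)) Inf else abs(x - cl[jl])
    dr <- if (is.na(jr)) Inf else abs(x - cl[jr])
    if (is.infinite(dl) && is.infinite(dr)) { unmatched <- c(unmatched, t_idx); next }
    pick <- if (dl < dr) jl
    else if (dr < dl) jr
    else if (ord_c[jl] <= ord_c[jr]) jl else jr  # tie: record order
    dist <- min(dl, dr)
    if (!is.null(caliper) && dist > caliper) {
      unmatched <- c(unmatched, t_idx)
      next
    }
    used[pick] <- TRUE
    if (!is.na(prv[pick])) nxt[prv[pick]] <- nxt[pick]
    if (!is.na(nxt[pick])) prv[nxt[pick]] <- prv[pick]
    pair_t <- c(pair_t, t_idx)
    pair_c <- c(pair_c, ord_c[pick])
  }

  pairs <- data.frame(smoker_row = pair_t, nonsmoker_row = pair_c,
                      smoker_score = scores[pair_t],
                      nonsmoker_score = scores[pair_c])
  keep <- c(pair_t, pair_c)
  data <- as.data.frame(cohort)[keep, , drop = FALSE]
  rownames(data) <- NULL

  cols <- balance_columns(cohort, covariates)
  cols$propensity_score <- scores
  bal <- do.call(rbind, lapply(names(cols), function(nm) {
    x <- cols[[nm]]
    denom <- stats::sd(x)
    data.frame(covariate = nm,
               smd_before = smd(x, treated, control, denom),
               smd_after = if (length(pair_t))
                 smd(x, pair_t, pair_c, denom) else NA_real_)
  }))
  rownames(bal) <- NULL

  structure(list(pairs = pairs, unmatched = length(unmatched),
                 unmatched_rows = unmatched, data = data,
                 covariates = covariates, balance = bal,
                 n_treated = length(treated), n_control = length(control)),
            class = "matched_cohort")
}

#' @method print matched_cohort
#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("Matched cohort: %d pairs (%d smokers unmatched of %d)\n",
              nrow(x$pairs), x$unmatched, x$n_treated))
  ps <- x$balance[x$balance$covariate == "propensity_score", ]
  cat(sprintf("Propensity-score SMD before %.3f -> after %.3f\n",
              ps$smd_before, ps$smd_after))
  invisible(x)
}

#' Write matched pairs as CSV
#' @param matched A `matched_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matched_pairs <- function(matched, path) {
  stopifnot(inherits(matched, "matched_cohort"))
  utils::write.csv(matched$pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Matched-set smoking effect with a simulated credible interval
#'
#' Least-squares regression of the PAL score on the smoker indicator (plus,
#' by default, the matching covariates) over the matched records; `draws`
#' coefficient vectors are then simulated from the fit's estimated sampling
#' distribution (multivariate normal at the coefficient mean and
#' covariance) and the 95% credible interval is read off the 2.5/97.5
#' percentiles of the smoker-coefficient draws.
#'
#' @param matched A [match_smokers()] result with at least 2 pairs.
#' @param draws Number of coefficient draws (>= 100).
#' @param seed Seed for the draws.
#' @param include_covariates Adjust for the matching covariates in the
#'   matched-set regression (default) or use the smoker indicator alone.
#' @return An object of class `psm_effect`: `beta` (word pairs), `ci`
#'   (lower, upper), `draws`, `n_pairs`.
#' @export
matched_effect <- function(matched, draws = 1000L, seed = 1L,
                           include_covariates = TRUE) {
  stopifnot(inherits(matched, "matched_cohort"))
  if (nrow(matched$pairs) < 2L) abort_check("need at least 2 matched pairs")
  if (draws < 100L) abort_check("draws must be >= 100 (interval unstable)")
  d <- matched$data
  rhs <- if (include_covariates) c("smoker", matched$covariates) else "smoker"
  # drop constant factors (possible in small matched sets)
  rhs <- rhs[vapply(rhs, function(nm) {
    x <- d[[nm]]
    length(unique(x)) > 1L
  }, logical(1))]
  if (!"smoker" %in% rhs) abort_check("smoker constant in matched data")
  f <- stats::reformulate(rhs, response = "pal_total")
  fit <- stats::lm(f, data = d)
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  sim <- with_seed(seed, MASS::mvrnorm(draws, mu = cf, Sigma = V))
  sm_col <- grep("^smoker", names(cf), value = TRUE)[1L]
  qs <- stats::quantile(sim[, sm_col], c(0.025, 0.975), names = FALSE)
  structure(list(beta = unname(cf[sm_col]), ci = c(lower = qs[1L],
                                                   upper = qs[2L]),
                 draws = draws, n_pairs = nrow(matched$pairs),
                 unmatched = matched$unmatched),
            class = "psm_effect")
}

#' @method print psm_effect
#' @export
print.psm_effect <- function(x, ...) {
  cat(sprintf(paste0("Matched smoking effect: beta = %.3f word pairs ",
                     "(95%% credible interval %.3f to %.3f; %d pairs, ",
                     "%d draws)\n"),
              x$beta, x$ci["lower"], x$ci["upper"], x$n_pairs, x$draws))
  invisible(x)
}

#' Sex-stratified propensity-score analysis
#'
#' Runs propensity estimation, matching and matched-effect estimation
#' separately within each sex (the matched analysis is collapsed across
#' age within stratum).
#'
#' @param cohort A `cohort`.
#' @param draws,seed,caliper,include_covariates Passed through.
#' @param covariates Matching covariates.
#' @return Named list (`woman`, `man`) of lists with `matched` and `effect`.
#' @export
psm_by_sex <- function(cohort, draws = 1000L, seed = 1L, caliper = NULL,
                       covariates = setdiff(covariate_names(), "sex"),
                       include_covariates = TRUE) {
  out <- lapply(c(woman = "woman", man = "man"), function(s) {
    sub <- as.data.frame(cohort)[cohort$sex == s, , drop = FALSE]
    rownames(sub) <- NULL
    class(sub) <- c("cohort", "data.frame")
    ps <- estimate_propensity(sub, covariates)
    m <- match_smokers(sub, ps, caliper = caliper, covariates = covariates)
    list(matched = m,
         effect = matched_effect(m, draws = draws,
                                 seed = child_seed(seed, "psm"),
                                 include_covariates = include_covariates))
  })
  out
}
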