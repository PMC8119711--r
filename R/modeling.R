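# Linear models: design construction, the full covariate-adjusted fit with a
# sex-by-exposure interaction, stratified simple effects, the CVD composite
# model, and lasso stability selection.

#' Model specification
#'
#' Describes a covariate-adjusted linear model of the PAL total score with a
#' focal exposure, an optional sex interaction, and treatment-coded
#' categorical covariates (reference = first declared level; for `sex` the
#' indicator is `man = 1`, so a positive exposure-by-sex coefficient means
#' the exposure effect is less negative in men).
#'
#' @param outcome Outcome column, default `"pal_total"`.
#' @param exposure Focal exposure: `"smoker"` or `"cvd_group"`.
#' @param by Moderator (default `"sex"`), or `NULL` for stratified fits.
#' @param interaction Include `exposure:by`?
#' @param covariates Adjustment covariates; defaults to the full 17-covariate
#'   set for the smoking model.
#' @param schema A [cohort_schema()].
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome = "pal_total", exposure = "smoker",
                       by = "sex", interaction = !is.null(by),
                       covariates = covariate_names(),
                       schema = cohort_schema()) {
  if (interaction && is.null(by))
    abort_check("interaction = TRUE requires a moderator ('by')")
  known <- c(schema$columns, "cvd_group")
  bad <- setdiff(c(outcome, exposure, by, covariates), known)
  if (length(bad))
    abort_check("unknown variable(s) in model spec: ",
                paste(bad, collapse = ", "))
  structure(list(outcome = outcome, exposure = exposure, by = by,
                 interaction = interaction,
                 covariates = setdiff(covariates, c(exposure, by)),
                 schema = schema),
            class = "model_spec")
}

#' Specification of the CVD composite model
#'
#' PAL ~ CVD group (0 reference) * sex + age + education.
#' @return A `model_spec`.
#' @export
cvd_model_spec <- function() {
  model_spec(exposure = "cvd_group", covariates = c("age", "education"))
}

#' CVD composite score and group
#'
#' Sum of heart disease, hypertension, diabetes and stroke history (0-4);
#' sums of 3 and 4 are combined into group "3+".
#'
#' @param x A `cohort` (or any data frame with the four CVD booleans), or a
#'   single-record list.
#' @return A data frame with integer `sum` (0-4) and factor `group`
#'   (levels "0", "1", "2", "3+").
#' @export
cvd_composite <- function(x) {
  if (!is.data.frame(x)) x <- as.data.frame(x)
  s <- as.integer(x$heart_disease) + as.integer(x$hypertension) +
    as.integer(x$diabetes) + as.integer(x$stroke)
  grp <- factor(c("0", "1", "2", "3+")[pmin(s, 3L) + 1L],
                levels = c("0", "1", "2", "3+"))
  data.frame(sum = s, group = grp)
}

# Add the cvd_group column when the spec needs it.
prepare_model_data <- function(cohort, spec) {
  d <- as.data.frame(cohort)
  if (identical(spec$exposure, "cvd_group") && is.null(d$cvd_group))
    d$cvd_group <- cvd_composite(d)$group
  d
}

model_formula <- function(spec) {
  rhs <- c(spec$exposure, spec$by, spec$covariates,
           if (spec$interaction) paste0(spec$exposure, ":", spec$by))
  stats::reformulate(rhs, response = spec$outcome)
}

#' Build the design matrix for a model specification
#'
#' Full-rank matrix with intercept; categoricals expanded by treatment
#' coding against the declared reference levels; `age` and
#' `daily_medications` enter as raw continuous values. Column names are
#' deterministic. The default full smoking specification expands to 30
#' non-intercept columns.
#'
#' @param cohort A `cohort`.
#' @param spec A [model_spec()].
#' @return A list with the matrix `X`, outcome `y`, `assign` (term index per
#'   column), `term_labels`, and `focal_cols` (indices of the exposure and
#'   interaction columns).
#' @export
build_design <- function(cohort, spec = model_spec()) {
  d <- prepare_model_data(cohort, spec)
  f <- model_formula(spec)
  mf <- stats::model.frame(f, data = d)
  X <- stats::model.matrix(f, mf)
  y <- stats::model.response(mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort_check("rank-deficient design: collinear column(s) ",
                paste(drop_cols, collapse = ", "))
  }
  labels <- attr(stats::terms(f), "term.labels")
  assign <- attr(X, "assign")
  focal_terms <- c(spec$exposure,
                   if (spec$interaction) paste0(spec$exposure, ":", spec$by))
  focal_cols <- which(labels[pmax(assign, 1L)] %in% focal_terms & assign > 0L)
  list(X = X, y = y, assign = assign, term_labels = labels,
       focal_cols = focal_cols, spec = spec, n = nrow(X))
}

# OLS with coefficient table from the Cholesky factor of X'X. With
# `drop_aliased` (used by the resampling engines, whose small subsamples can
# zero out rare dummy columns) aliased columns are removed as stats::lm
# does, and their estimates reported as NA.
ols_fit <- function(X, y, drop_aliased = FALSE) {
  if (drop_aliased) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      keep <- sort(qrX$pivot[seq_len(qrX$rank)])
      sub <- ols_fit(X[, keep, drop = FALSE], y)
      pad <- function(v) {
        out <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
        out[keep] <- v
        out
      }
      sub$beta <- pad(sub$beta); sub$se <- pad(sub$se)
      sub$t <- pad(sub$t); sub$p <- pad(sub$p)
      return(sub)
    }
  }
  n <- nrow(X); p <- ncol(X)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  ch <- tryCatch(chol(XtX),
                 error = function(e) abort_check(
                   "degenerate design in OLS: ", conditionMessage(e)))
  beta <- drop(backsolve(ch, forwardsolve(t(ch), Xty)))
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  df <- n - p
  if (df <= 0) abort_check("n must exceed the number of design columns")
  sigma2 <- rss / df
  se <- sqrt(sigma2 * diag(chol2inv(ch)))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  list(beta = beta, se = se, t = tval, p = pval, df = df, rss = rss,
       sigma = sqrt(sigma2), fitted = fitted, residuals = res)
}

#' Fit the covariate-adjusted linear model
#'
#' Ordinary least squares of the PAL score on the focal exposure, sex, their
#' interaction and the adjustment covariates. Two-sided p-values from the t
#' distribution on the residual degrees of freedom; the omnibus F compares
#' against the intercept-only model. Coefficients are reported in raw
#' word-pair units.
#'
#' @param cohort A `cohort` (or data frame with the model columns).
#' @param spec A [model_spec()].
#' @param alpha Significance level carried in the result.
#' @return An object of class `pal_fit`: term estimates (term, beta, se, t,
#'   p), omnibus `F` with `df1`/`df2`, `n`, residual `sigma`.
#' @export
pal_lm <- function(cohort, spec = model_spec(), alpha = 0.05) {
  d <- build_design(cohort, spec)
  if (d$n <= ncol(d$X))
    abort_check("n (", d$n, ") must exceed the number of design columns (",
                ncol(d$X), ")")
  fit <- ols_fit(d$X, d$y)
  tss <- sum((d$y - mean(d$y))^2)
  df1 <- ncol(d$X) - 1L
  df2 <- fit$df
  Fstat <- if (df1 > 0) ((tss - fit$rss) / df1) / (fit$rss / df2) else NA_real_
  terms <- data.frame(term = names(fit$beta), beta = unname(fit$beta),
                      se = unname(fit$se), t = unname(fit$t),
                      p = unname(fit$p), row.names = NULL)
  structure(list(terms = terms, F = Fstat, df1 = df1, df2 = df2, n = d$n,
                 sigma = fit$sigma, alpha = alpha, spec = spec,
                 focal_cols = d$focal_cols,
                 p_omnibus = stats::pf(Fstat, df1, df2, lower.tail = FALSE)),
            class = "pal_fit")
}

#' @method print pal_fit
#' @export
print.pal_fit <- function(x, ...) {
  cat(sprintf("Linear model of %s (n = %d)\n", x$spec$outcome, x$n))
  cat(sprintf("Omnibus F(%d, %d) = %.2f, p = %.3g; residual sd = %.3f\n",
              x$df1, x$df2, x$F, x$p_omnibus, x$sigma))
  tab <- x$terms
  focal <- unique(c(1L, x$focal_cols,
                    which(grepl(x$spec$exposure, tab$term, fixed = TRUE))))
  cat("Focal terms:\n")
  show <- tab[sort(unique(focal)), , drop = FALSE]
  show$beta <- signif(show$beta, 4); show$se <- signif(show$se, 3)
  show$t <- signif(show$t, 4); show$p <- signif(show$p, 3)
  print(show, row.names = FALSE)
  invisible(x)
}

#' @method summary pal_fit
#' @export
summary.pal_fit <- function(object, ...) {
  cat(sprintf("Linear model of %s (n = %d)\n", object$spec$outcome, object$n))
  cat(sprintf("Omnibus F(%d, %d) = %.2f, p = %.3g\n",
              object$df1, object$df2, object$F, object$p_omnibus))
  tab <- object$terms
  tab$beta <- signif(tab$beta, 4); tab$se <- signif(tab$se, 3)
  tab$t <- signif(tab$t, 4); tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(object)
}

#' @method coef pal_fit
#' @export
coef.pal_fit <- function(object, ...)
  stats::setNames(object$terms$beta, object$terms$term)

#' Extract one term's estimate from a fit
#'
#' @param fit A `pal_fit`.
#' @param term Coefficient name.
#' @return One-row data frame (term, beta, se, t, p).
#' @export
term_estimate <- function(fit, term) {
  stopifnot(inherits(fit, "pal_fit"))
  row <- fit$terms[fit$terms$term == term, , drop = FALSE]
  if (!nrow(row))
    abort_check("term '", term, "' not found; available: ",
                paste(fit$terms$term, collapse = ", "))
  row
}

#' Write a fit's coefficient table as TSV
#' @param fit A `pal_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "pal_fit"))
  utils::write.table(fit$terms, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Stratified simple effects
#'
#' Refits the full model separately within each stratum of a binary
#' moderator (dropping the moderator and its interaction), the reading under
#' which per-stratum exposure effects and a pooled interaction can both be
#' reported: stratified fits free every covariate slope to differ between
#' strata.
#'
#' @param cohort A `cohort`.
#' @param spec A [model_spec()] for the pooled model.
#' @param stratifier Binary stratifying covariate, default the spec's `by`.
#' @return A named list of `pal_fit` (one per stratum), class
#'   `simple_effects`.
#' @export
simple_effects <- function(cohort, spec = model_spec(),
                           stratifier = spec$by) {
  if (is.null(stratifier)) abort_check("no stratifier given")
  g <- cohort[[stratifier]]
  if (is.logical(g)) g <- factor(ifelse(g, "yes", "no"), c("no", "yes"))
  g <- droplevels(as.factor(g))
  if (nlevels(g) != 2L) abort_check("stratifier must be binary")
  sub_spec <- model_spec(outcome = spec$outcome, exposure = spec$exposure,
                         by = NULL, interaction = FALSE,
                         covariates = setdiff(spec$covariates, stratifier),
                         schema = spec$schema)
  out <- lapply(levels(g), function(lev) {
    idx <- which(g == lev)
    if (!length(idx)) abort_check("empty stratum: ", lev)
    pal_lm(cohort[idx, , drop = FALSE], sub_spec)
  })
  names(out) <- levels(g)
  class(out) <- "simple_effects"
  out
}

#' @method print simple_effects
#' @export
print.simple_effects <- function(x, ...) {
  for (nm in names(x)) {
    cat("== stratum:", nm, "==\n")
    print(x[[nm]])
  }
  invisible(x)
}

#' Fit the CVD composite model
#'
#' PAL ~ CVD group + sex + sex:CVD group + age + education, with group 0 as
#' the control/reference; or the stratified version within one sex.
#'
#' @param cohort A `cohort` carrying the four CVD booleans.
#' @param stratum `NULL` for the pooled model with the sex interaction, or
#'   `"woman"`/`"man"` for a stratified refit.
#' @return A `pal_fit`.
#' @export
fit_cvd_model <- function(cohort, stratum = NULL) {
  d <- as.data.frame(cohort)
  d$cvd_group <- cvd_composite(d)$group
  sizes <- table(d$cvd_group)
  if (any(sizes == 0L))
    abort_check("empty CVD group(s): ",
                paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "))
  if (is.null(stratum)) {
    pal_lm(d, cvd_model_spec())
  } else {
    idx <- which(as.character(d$sex) == stratum)
    if (!length(idx)) abort_check("empty stratum: ", stratum)
    pal_lm(d[idx, , drop = FALSE],
           model_spec(exposure = "cvd_group", by = NULL, interaction = FALSE,
                      covariates = c("age", "education")))
  }
}

#' Lasso stability selection over the model covariates
#'
#' For each of `subsamples` subsamples (drawn without replacement, size
#' `fraction * n`), an L1-penalized linear model is fitted over a log-spaced
#' penalty path (focal exposure/moderator columns unpenalized). A covariate
#' counts as selected in a subsample if any of its design columns is nonzero
#' at any penalty at or above the per-subsample selected penalty
#' `lambda_scale * sigma_hat * sqrt(2 log(p) / n_sub)`, where `sigma_hat` is
#' the unpenalized residual standard deviation on that subsample (a
#' universal-threshold heuristic). The retained set keeps covariates whose
#' selection frequency reaches `cutoff` (default 0.70).
#'
#' @param cohort A `cohort`.
#' @param spec A [model_spec()].
#' @param subsamples Number of subsamples (>= 2).
#' @param fraction Subsample fraction in (0, 1).
#' @param cutoff Retention cutoff in (0, 1].
#' @param lambda_scale Scale constant of the penalty heuristic.
#' @param nlambda Penalty-path length.
#' @param seed Seed.
#' @return An object of class `stability_selection`: per-covariate
#'   `frequency`, the `cutoff` and the `retained` covariate names.
#' @export
stability_selection <- function(cohort, spec = model_spec(),
                                subsamples = 50L, fraction = 0.5,
                                cutoff = 0.70, lambda_scale = 0.35,
                                nlambda = 50L, seed = 1L) {
  if (subsamples < 2L) abort_check("subsamples must be >= 2")
  if (fraction <= 0 || fraction >= 1) abort_check("fraction must be in (0,1)")
  if (cutoff <= 0 || cutoff > 1) abort_check("cutoff must be in (0, 1]")
  d <- build_design(cohort, spec)
  Xc <- d$X[, -1L, drop = FALSE]  # glmnet supplies its own intercept
  assign <- d$assign[-1L]
  labels <- d$term_labels
  col_term <- labels[assign]
  focal_terms <- c(spec$exposure, spec$by,
                   if (spec$interaction) paste0(spec$exposure, ":", spec$by))
  pen <- ifelse(col_term %in% focal_terms, 0, 1)
  cov_terms <- setdiff(unique(col_term), focal_terms)
  n <- nrow(Xc)
  m <- floor(fraction * n)
  counts <- stats::setNames(numeric(length(cov_terms)), cov_terms)
  with_seed(seed, {
    for (b in seq_len(subsamples)) {
      idx <- sample.int(n, m)
      Xs <- Xc[idx, , drop = FALSE]
      ys <- d$y[idx]
      sd_hat <- ols_fit(cbind(1, Xs), ys)$sigma
      lam_sel <- lambda_scale * sd_hat * sqrt(2 * log(ncol(Xs)) / m)
      gfit <- glmnet::glmnet(Xs, ys, family = "gaussian",
                             penalty.factor = pen, nlambda = nlambda)
      keep_l <- which(gfit$lambda >= lam_sel)
      if (!length(keep_l)) keep_l <- 1L
      cf <- as.matrix(gfit$beta[, keep_l, drop = FALSE])
      nz <- rowSums(abs(cf) > 0) > 0
      sel_terms <- unique(col_term[nz])
      hit <- intersect(sel_terms, cov_terms)
      counts[hit] <- counts[hit] + 1
    }
  })
  freq <- counts / subsamples
  structure(list(frequency = freq, cutoff = cutoff,
                 retained = names(freq)[freq >= cutoff],
                 subsamples = subsamples, fraction = fraction),
            class = "stability_selection")
}

#' @method print stability_selection
#' @export
print.stability_selection <- function(x, ...) {
  cat(sprintf("Stability selection: %d subsamples, fraction %.2f, cutoff %.2f\n",
              x$subsamples, x$fraction, x$cutoff))
  print(round(sort(x$frequency, decreasing = TRUE), 2))
  cat("Retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}
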