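# Resampling engines: balanced down-sampling power curves, smoking-status
# misclassification Monte Carlo, and permutation tests. The error-injection
# and permutation engines refit only the smoker-dependent design columns via
# the Frisch-Waugh-Lovell decomposition on a cached QR of the fixed columns;
# the resulting coefficient, SE and t are exactly those of the full OLS
# refit (asserted in the test suite).

# Engine over a design with some columns depending on the smoker labels.
# Returns a function(Z) giving exact full-model stats for the Z columns.
focal_refit_engine <- function(X, y, moving_cols) {
  Xf <- X[, -moving_cols, drop = FALSE]
  qrF <- qr(Xf)
  ey <- qr.resid(qrF, y)
  syy <- sum(ey^2)
  n <- nrow(X); kf <- ncol(Xf)
  function(Z) {
    Z <- as.matrix(Z)
    EZ <- qr.resid(qrF, Z)
    G <- crossprod(EZ)
    gy <- crossprod(EZ, ey)
    ch <- chol(G)
    b <- drop(backsolve(ch, forwardsolve(t(ch), gy)))
    rss <- syy - sum(b * gy)
    df <- n - kf - ncol(Z)
    sigma2 <- rss / df
    se <- sqrt(sigma2 * diag(chol2inv(ch)))
    tval <- b / se
    list(beta = b, se = se, t = tval,
         p = 2 * stats::pt(-abs(tval), df), df = df)
  }
}

# Columns of the design that change when smoker labels change, and a builder
# mapping a smoker vector to those columns.
smoker_moving_columns <- function(design, cohort) {
  nm <- colnames(design$X)
  moving <- grep("smoker", nm)
  if (!length(moving)) abort_check("model has no smoker term")
  man <- as.numeric(cohort$sex == "man")
  has_int <- any(grepl(":", nm[moving]))
  builder <- function(s) {
    s <- as.numeric(s)
    if (has_int) cbind(s, s * man) else cbind(s)
  }
  list(cols = moving, build = builder)
}

#' Balanced down-sampling of a cohort
#'
#' Draws a subsample balanced over smoking and sex. Two balance modes:
#' \describe{
#'   \item{"cell"}{equal counts per (age, sex, smoker) cell over single-year
#'     age bins (default ages 18-84, i.e. 67 bins); `total_n` must be a
#'     multiple of 4 x bins. Errors loudly, naming the cell, when any cell
#'     lacks records -- there is no silent rebalancing.}
#'   \item{"group"}{equal counts (`total_n`/4) per (sex, smoker) group,
#'     sampled uniformly without replacement within group. This is the only
#'     mode executable near `total_n = 10,000` under the default cohort
#'     composition (about 2,700 male smokers exist in total, so 37+ per
#'     single year of age is arithmetically unattainable); see the methods
#'     vignette.}
#' }
#'
#' @param cohort A `cohort`.
#' @param total_n Total subsample size.
#' @param seed Seed.
#' @param balance `"cell"` or `"group"`.
#' @param ages Age window (default 18:84).
#' @return The subsampled `cohort`.
#' @export
downsample_balanced <- function(cohort, total_n, seed = 1L,
                                balance = c("group", "cell"),
                                ages = 18:84) {
  balance <- match.arg(balance)
  idx <- with_seed(seed,
                   balanced_indices(cohort, total_n, balance, ages))
  out <- as.data.frame(cohort)[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "schema") <- attr(cohort, "schema")
  class(out) <- c("cohort", "data.frame")
  out
}

balanced_indices <- function(cohort, total_n, balance, ages) {
  in_window <- cohort$age %in% ages
  man <- cohort$sex == "man"
  smoker <- cohort$smoker
  if (balance == "cell") {
    nb <- length(ages)
    if (total_n %% (4L * nb) != 0L)
      abort_check("total_n must be a multiple of 4 x ", nb, " age bins")
    k <- total_n %/% (4L * nb)
    idx <- integer(0)
    for (a in ages) for (s in c(FALSE, TRUE)) for (m in c(FALSE, TRUE)) {
      cell <- which(cohort$age == a & man == s & smoker == m)
      if (length(cell) < k)
        abort_check(sprintf(
          "cell age=%d, sex=%s, smoker=%s has %d records, need %d",
          a, if (s) "man" else "woman", m, length(cell), k))
      idx <- c(idx, if (length(cell) == k) cell
               else sample(cell, k))
    }
    idx
  } else {
    if (total_n %% 4L != 0L) abort_check("total_n must be a multiple of 4")
    k <- total_n %/% 4L
    idx <- integer(0)
    for (s in c(FALSE, TRUE)) for (m in c(FALSE, TRUE)) {
      grp <- which(in_window & man == s & smoker == m)
      if (length(grp) < k)
        abort_check(sprintf(
          "group sex=%s, smoker=%s has %d records, need %d",
          if (s) "man" else "woman", m, length(grp), k))
      idx <- c(idx, if (length(grp) == k) grp else sample(grp, k))
    }
    idx
  }
}

#' Down-sampling power curve
#'
#' For each size, `reps` independent balanced subsamples are drawn and the
#' full model refitted; the curve records each replicate's focal coefficient
#' and p-value, the fraction significant at `alpha`, and how many
#' significant replicates carried the sign opposite to the full-cohort
#' estimate (possible at small sizes).
#'
#' @param cohort A `cohort`.
#' @param sizes Vector of total subsample sizes.
#' @param reps Replicates per size.
#' @param spec A [model_spec()].
#' @param term Focal coefficient name (default the sex-by-smoking
#'   interaction column).
#' @param seed Seed.
#' @param alpha Significance level.
#' @param balance,ages Passed to the balanced sampler.
#' @return An object of class `power_curve`: `summary` (size, reps,
#'   fraction_significant, sign_flips), `replicates` (per-replicate rows),
#'   and the full-cohort reference estimate.
#' @export
power_curve <- function(cohort, sizes, reps = 200L, spec = model_spec(),
                        term = "smokerTRUE:sexman", seed = 1L, alpha = 0.05,
                        balance = c("group", "cell"), ages = 18:84) {
  balance <- match.arg(balance)
  d <- build_design(cohort, spec)
  cidx <- match(term, colnames(d$X))
  if (is.na(cidx)) abort_check("term '", term, "' not in the design")
  full <- ols_fit(d$X, d$y)
  ref_beta <- full$beta[cidx]
  rep_rows <- vector("list", length(sizes) * reps)
  r <- 0L
  with_seed(seed, {
    for (sz in sizes) {
      for (b in seq_len(reps)) {
        idx <- balanced_indices(cohort, sz, balance, ages)
        f <- ols_fit(d$X[idx, , drop = FALSE], d$y[idx],
                     drop_aliased = TRUE)
        r <- r + 1L
        rep_rows[[r]] <- data.frame(size = sz, rep = b,
                                     beta = unname(f$beta[cidx]),
                                     p = unname(f$p[cidx]))
      }
    }
  })
  repl <- do.call(rbind, rep_rows)
  repl$significant <- repl$p < alpha
  repl$sign_flip <- repl$significant & sign(repl$beta) != sign(ref_beta)
  agg <- do.call(rbind, lapply(split(repl, repl$size), function(g)
    data.frame(size = g$size[1L], reps = nrow(g),
               fraction_significant = mean(g$significant),
               sign_flips = sum(g$sign_flip))))
  agg <- agg[order(agg$size), ]
  rownames(agg) <- NULL
  structure(list(summary = agg, replicates = repl, term = term,
                 reference_beta = unname(ref_beta), alpha = alpha,
                 balance = balance),
            class = "power_curve")
}

#' @method print power_curve
#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("Down-sampling power curve for %s (alpha = %.2f, %s balance)\n",
              x$term, x$alpha, x$balance))
  cat(sprintf("Full-cohort reference beta = %.3f\n", x$reference_beta))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @method plot power_curve
#' @export
plot.power_curve <- function(x, ...) {
  repl <- x$replicates
  graphics::plot(jitter(repl$size, amount = diff(range(repl$size)) / 80),
                 repl$beta,
                 col = ifelse(repl$significant, "forestgreen", "black"),
                 pch = 16, cex = 0.4, xlab = "total subsample size",
                 ylab = sprintf("%s (word pairs)", x$term), ...)
  graphics::abline(h = x$reference_beta, col = "red")
  invisible(x)
}

#' Smallest size reaching a target power
#'
#' @param curve A [power_curve()] result.
#' @param threshold Target fraction significant, in (0, 1).
#' @return The smallest evaluated size whose fraction significant reaches
#'   the threshold, or `NA` (with a message) when no evaluated size does.
#' @export
min_n_for_power <- function(curve, threshold = 0.5) {
  stopifnot(inherits(curve, "power_curve"))
  if (threshold <= 0 || threshold >= 1)
    abort_check("threshold must be in (0, 1)")
  ok <- curve$summary$size[curve$summary$fraction_significant >= threshold]
  if (!length(ok)) {
    message("target power not reached at any evaluated size")
    return(NA_integer_)
  }
  min(ok)
}

#' Inject misclassification error into smoker labels
#'
#' Inverts the smoker status of a uniformly chosen fraction of records (the
#' hard-inversion semantics; a redraw-from-the-marginal variant, which
#' roughly halves the effective error rate, is available via `mode`). All
#' other fields are untouched.
#'
#' @param cohort A `cohort`.
#' @param rate Fraction of records perturbed, in [0, `max_rate`].
#' @param seed Seed.
#' @param mode `"invert"` or `"redraw"`.
#' @param max_rate Guard rail (default 0.10, the largest rate studied);
#'   raise it explicitly for wider sweeps.
#' @return The perturbed `cohort`.
#' @export
inject_error <- function(cohort, rate, seed = 1L,
                         mode = c("invert", "redraw"), max_rate = 0.10) {
  mode <- match.arg(mode)
  if (!is.numeric(rate) || rate < 0 || rate > 1)
    abort_check("rate must be in [0, 1]")
  if (rate > max_rate)
    abort_check("rate ", rate, " exceeds max_rate ", max_rate,
                " (raise max_rate to allow)")
  n <- nrow(cohort)
  m <- round(rate * n)
  if (m == 0L) return(cohort)
  with_seed(seed, {
    idx <- sample.int(n, m)
    if (mode == "invert") cohort$smoker[idx] <- !cohort$smoker[idx]
    else cohort$smoker[idx] <- stats::runif(m) < mean(cohort$smoker)
  })
  cohort
}

#' Closed-form attenuation under label inversion
#'
#' Non-differential inversion of a fraction `rate` of labels attenuates a
#' two-group mean difference by `P(true smoker | labeled smoker) - P(true
#' smoker | labeled non-smoker)`; at rate 0.10 and prevalence 0.079 the
#' factor is about 0.427.
#'
#' @param rate Inversion rate.
#' @param prevalence True smoker prevalence.
#' @return Attenuation factor in [0, 1].
#' @export
attenuation_factor <- function(rate, prevalence) {
  p <- prevalence; r <- rate
  p_ls <- p * (1 - r) + (1 - p) * r
  p * (1 - r) / p_ls - p * r / (1 - p_ls)
}

#' Misclassification-error Monte Carlo study
#'
#' Per error rate, `reps` independent label perturbations followed by an
#' exact full-model refit of the smoker-dependent terms; records the
#' p-value distribution and fraction significant per focal term. Rate 0
#' reproduces the unperturbed p-values exactly.
#'
#' @param cohort A `cohort`.
#' @param rates Error rates (default 1%..10% in 1% steps).
#' @param reps Replicates per rate.
#' @param spec A [model_spec()].
#' @param terms Focal coefficient names; default all smoker-dependent
#'   columns.
#' @param seed Seed.
#' @param alpha Significance level.
#' @param mode Perturbation semantics, see [inject_error()].
#' @return An object of class `error_injection`: `summary` (rate, term,
#'   fraction_significant) and `replicates` (rate, rep, term, beta, p).
#' @export
error_injection_study <- function(cohort, rates = seq(0.01, 0.10, by = 0.01),
                                  reps = 200L, spec = model_spec(),
                                  terms = NULL, seed = 1L, alpha = 0.05,
                                  mode = c("invert", "redraw")) {
  mode <- match.arg(mode)
  if (reps < 1L) abort_check("reps must be >= 1")
  d <- build_design(cohort, spec)
  mv <- smoker_moving_columns(d, cohort)
  engine <- focal_refit_engine(d$X, d$y, mv$cols)
  term_names <- colnames(d$X)[mv$cols]
  if (is.null(terms)) terms <- term_names
  sel <- match(terms, term_names)
  if (anyNA(sel))
    abort_check("term(s) not smoker-dependent: ",
                paste(terms[is.na(sel)], collapse = ", "))
  s0 <- cohort$smoker
  n <- length(s0)
  rows <- vector("list", length(rates) * reps)
  r <- 0L
  with_seed(seed, {
    for (rate in rates) {
      m <- round(rate * n)
      for (b in seq_len(reps)) {
        s <- s0
        if (m > 0L) {
          idx <- sample.int(n, m)
          if (mode == "invert") s[idx] <- !s[idx]
          else s[idx] <- stats::runif(m) < mean(s0)
        }
        st <- engine(mv$build(s))
        r <- r + 1L
        rows[[r]] <- data.frame(rate = rate, rep = b, term = terms,
                                 beta = st$beta[sel], p = st$p[sel])
      }
    }
  })
  repl <- do.call(rbind, rows)
  rownames(repl) <- NULL
  repl$significant <- repl$p < alpha
  agg <- do.call(rbind, lapply(split(repl, list(repl$rate, repl$term)),
                               function(g) if (!nrow(g)) NULL else
                                 data.frame(rate = g$rate[1L],
                                            term = g$term[1L],
                                            reps = nrow(g),
                                            fraction_significant =
                                              mean(g$significant))))
  agg <- agg[order(agg$term, agg$rate), ]
  rownames(agg) <- NULL
  structure(list(summary = agg, replicates = repl, alpha = alpha,
                 mode = mode),
            class = "error_injection")
}

#' @method print error_injection
#' @export
print.error_injection <- function(x, ...) {
  cat(sprintf("Misclassification Monte Carlo (%s mode, alpha = %.2f)\n",
              x$mode, x$alpha))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @method plot error_injection
#' @export
plot.error_injection <- function(x, term = unique(x$replicates$term)[1L],
                                 ...) {
  repl <- x$replicates[x$replicates$term == term, ]
  graphics::boxplot(p ~ rate, data = repl, xlab = "error rate",
                    ylab = "p-value", main = term, ...)
  graphics::abline(h = x$alpha, col = "red", lty = 2)
  invisible(x)
}

#' Permutation test of a smoker-related coefficient
#'
#' Permutes the smoker labels across records (preserving the smoker count),
#' refits the complete model per permutation, and reports the two-sided
#' exceedance count of |t| and the empirical p-value with the (k+1)/(B+1)
#' correction.
#'
#' @param cohort A `cohort`.
#' @param spec A [model_spec()].
#' @param term Focal coefficient name.
#' @param permutations Number of permutations.
#' @param seed Seed.
#' @param alpha Significance level (carried in the result).
#' @return An object of class `permutation_test`: `observed_t`, `perm_t`,
#'   `exceedances`, `p_empirical`.
#' @export
permutation_test <- function(cohort, spec = model_spec(),
                             term = "smokerTRUE", permutations = 1000L,
                             seed = 1L, alpha = 0.05) {
  if (permutations < 1L) abort_check("permutations must be >= 1")
  if (stats::sd(cohort$pal_total) == 0)
    abort_check("degenerate fit: outcome is constant")
  d <- build_design(cohort, spec)
  mv <- smoker_moving_columns(d, cohort)
  engine <- focal_refit_engine(d$X, d$y, mv$cols)
  term_names <- colnames(d$X)[mv$cols]
  sel <- match(term, term_names)
  if (is.na(sel))
    abort_check("term '", term, "' is not a smoker-dependent column (",
                paste(term_names, collapse = ", "), ")")
  s0 <- cohort$smoker
  t_obs <- engine(mv$build(s0))$t[sel]
  perm_t <- numeric(permutations)
  with_seed(seed, {
    for (b in seq_len(permutations)) {
      s <- s0[sample.int(length(s0))]
      perm_t[b] <- engine(mv$build(s))$t[sel]
    }
  })
  k <- sum(abs(perm_t) >= abs(t_obs))
  structure(list(observed_t = unname(t_obs), perm_t = perm_t,
                 exceedances = k,
                 p_empirical = (k + 1) / (permutations + 1),
                 permutations = permutations, term = term, alpha = alpha),
            class = "permutation_test")
}

#' @method print permutation_test
#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(paste0("Permutation test for %s: observed t = %.3f, ",
                     "%d/%d permuted |t| >= |observed|, empirical p = %.3g\n"),
              x$term, x$observed_t, x$exceedances, x$permutations,
              x$p_empirical))
  invisible(x)
}

#' @method plot permutation_test
#' @export
plot.permutation_test <- function(x, ...) {
  graphics::hist(x$perm_t, breaks = 50, main = x$term,
                 xlab = "permuted t",
                 xlim = range(c(x$perm_t, x$observed_t)), ...)
  graphics::abline(v = x$observed_t, lty = 2)
  invisible(x)
}
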