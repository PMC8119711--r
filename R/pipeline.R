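# Run configuration, the end-to-end pipeline, and figure rendering.

.known_config_keys <- c("scenario", "generator", "stages", "alpha", "seed",
                        "out_dir", "sizes", "reps", "psm", "permutations",
                        "power_term", "error_rates")
.known_stages <- c("generate", "fit", "psm", "power", "error", "permute")

#' Validate a run configuration
#'
#' Accepts a YAML/JSON file path or a plain list; fills defaults, rejects
#' unknown keys (no silent ignoring), and bounds-checks generator
#' overrides.
#'
#' @param config File path or named list. Recognised keys: `scenario`
#'   (preset name, default "A"), `generator` (named overrides passed to
#'   [generator_config()]), `stages` (subset of generate/fit/psm/power/
#'   error/permute), `alpha`, `seed`, `out_dir`, `sizes` (down-sampling
#'   sizes), `reps` (list with `power`, `error`), `permutations`,
#'   `psm` (list with `draws`), `power_term`, `error_rates`.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_check("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort_check("config must be a list or file path")
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown))
    abort_check("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- list(
    scenario = config$scenario %||% "A",
    generator = config$generator %||% list(),
    stages = config$stages %||% .known_stages,
    alpha = config$alpha %||% 0.05,
    seed = config$seed %||% 1L,
    out_dir = config$out_dir,
    sizes = config$sizes %||% c(2680L, 5360L, 8040L, 9916L),
    reps = utils::modifyList(list(power = 100L, error = 200L),
                             config$reps %||% list()),
    permutations = config$permutations %||% 1000L,
    psm = utils::modifyList(list(draws = 1000L), config$psm %||% list()),
    power_term = config$power_term %||% "smokerTRUE:sexman",
    error_rates = config$error_rates %||% c(0.05, 0.10))
  if (!out$scenario %in% c("A", "B", "NULL", "cvd"))
    abort_check("unknown scenario: ", out$scenario)
  bad_stage <- setdiff(out$stages, .known_stages)
  if (length(bad_stage))
    abort_check("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  for (nm in intersect(names(out$generator), c("p_woman")))
    if (!is_prob(out$generator[[nm]]))
      abort_check("generator$", nm, " must be a probability in [0, 1]")
  if (!is.null(out$generator$smoking$overall) &&
      !is_prob(out$generator$smoking$overall))
    abort_check("generator$smoking$overall must be a probability in [0, 1]")
  if (out$alpha <= 0 || out$alpha >= 1)
    abort_check("alpha must be in (0, 1)")
  class(out) <- "run_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Generates (or accepts) one cohort, then runs the enabled stages in
#' order: model fits (pooled with sex interaction, simple effects, CVD
#' composite), sex-stratified propensity matching, the down-sampling power
#' curve, the misclassification Monte Carlo, and the permutation test. All
#' stage randomness is derived from the config seed through [child_seed()],
#' so the report is regenerable from config + seed alone. When `out_dir`
#' is set, TSV/JSON artifacts are written there.
#'
#' @param config A [validate_config()]-acceptable configuration.
#' @param cohort Optional pre-built `cohort` (skips generation).
#' @return An object of class `run_report`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  cfg <- validate_config(unclass(config))
  t0 <- proc.time()[["elapsed"]]
  gen <- do.call(scenario_config,
                 c(list(name = cfg$scenario), cfg$generator))
  timings <- c()
  tick <- function(nm) {
    t1 <- proc.time()[["elapsed"]]
    timings[nm] <<- t1 - t0
    t0 <<- t1
  }
  report <- list(config = cfg, scenario = cfg$scenario, seed = cfg$seed)
  if (is.null(cohort) && "generate" %in% cfg$stages) {
    cohort <- generate_cohort(gen, seed = child_seed(cfg$seed, "generate"))
    tick("generate")
  }
  if (is.null(cohort)) abort_check("no cohort: enable the generate stage ",
                                   "or pass one explicitly")
  report$n <- nrow(cohort)
  if ("fit" %in% cfg$stages) {
    report$fit <- tryCatch({
      full <- pal_lm(cohort, alpha = cfg$alpha)
      list(full = full, simple = simple_effects(cohort),
           cvd = fit_cvd_model(cohort))
    }, error = function(e) abort_check("stage 'fit' failed: ",
                                       conditionMessage(e)))
    tick("fit")
  }
  if ("psm" %in% cfg$stages) {
    report$psm <- tryCatch(
      psm_by_sex(cohort, draws = cfg$psm$draws,
                 seed = child_seed(cfg$seed, "psm")),
      error = function(e) abort_check("stage 'psm' failed: ",
                                      conditionMessage(e)))
    tick("psm")
  }
  if ("power" %in% cfg$stages) {
    report$power <- tryCatch(
      power_curve(cohort, sizes = cfg$sizes, reps = cfg$reps$power,
                  term = cfg$power_term, alpha = cfg$alpha,
                  seed = child_seed(cfg$seed, "power")),
      error = function(e) abort_check("stage 'power' failed: ",
                                      conditionMessage(e)))
    tick("power")
  }
  if ("error" %in% cfg$stages) {
    report$error <- tryCatch(
      error_injection_study(cohort, rates = cfg$error_rates,
                            reps = cfg$reps$error, alpha = cfg$alpha,
                            seed = child_seed(cfg$seed, "error")),
      error = function(e) abort_check("stage 'error' failed: ",
                                      conditionMessage(e)))
    tick("error")
  }
  if ("permute" %in% cfg$stages) {
    report$permutation <- tryCatch(
      permutation_test(cohort, term = "smokerTRUE",
                       permutations = cfg$permutations, alpha = cfg$alpha,
                       seed = child_seed(cfg$seed, "permute")),
      error = function(e) abort_check("stage 'permute' failed: ",
                                      conditionMessage(e)))
    tick("permute")
  }
  report$timings <- timings
  report$version <- as.character(utils::packageVersion("palcohort"))
  class(report) <- "run_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @method print run_report
#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> scenario %s, seed %d, n = %d (palcohort %s)\n",
              x$scenario, x$seed, x$n %||% NA_integer_, x$version))
  if (!is.null(x$fit)) {
    int <- x$fit$full$terms
    int <- int[grepl(":", int$term), , drop = FALSE]
    if (nrow(int))
      cat(sprintf("  interaction %s: beta %.3f (SE %.3f), p %.3g\n",
                  int$term[1], int$beta[1], int$se[1], int$p[1]))
  }
  if (!is.null(x$psm))
    cat(sprintf("  PSM women: %.3f (%.3f, %.3f)\n",
                x$psm$woman$effect$beta, x$psm$woman$effect$ci["lower"],
                x$psm$woman$effect$ci["upper"]))
  if (!is.null(x$power))
    cat(sprintf("  power at n=%d: %.2f\n",
                max(x$power$summary$size),
                x$power$summary$fraction_significant[
                  which.max(x$power$summary$size)]))
  if (!is.null(x$permutation))
    cat(sprintf("  permutation p = %.3g (%d exceedances)\n",
                x$permutation$p_empirical, x$permutation$exceedances))
  invisible(x)
}

# JSON-ready summary of a run report
report_summary <- function(report) {
  out <- list(version = report$version, scenario = report$scenario,
              seed = report$seed, n = report$n)
  if (!is.null(report$fit)) {
    out$fit <- list(
      omnibus_F = report$fit$full$F, df1 = report$fit$full$df1,
      df2 = report$fit$full$df2,
      terms = report$fit$full$terms,
      simple = lapply(report$fit$simple, function(f)
        f$terms[f$terms$term == "smokerTRUE", ]),
      cvd_terms = report$fit$cvd$terms)
  }
  if (!is.null(report$psm))
    out$psm <- lapply(report$psm, function(s)
      list(beta = s$effect$beta, ci = unname(s$effect$ci),
           n_pairs = s$effect$n_pairs))
  if (!is.null(report$power)) out$power <- report$power$summary
  if (!is.null(report$error)) out$error <- report$error$summary
  if (!is.null(report$permutation))
    out$permutation <- list(
      observed_t = report$permutation$observed_t,
      exceedances = report$permutation$exceedances,
      p_empirical = report$permutation$p_empirical)
  out
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort_check("cannot create ", out_dir)
  if (!is.null(report$fit)) {
    write_fit(report$fit$full, file.path(out_dir, "fit_full.tsv"))
    write_fit(report$fit$cvd, file.path(out_dir, "fit_cvd.tsv"))
  }
  if (!is.null(report$power))
    utils::write.table(report$power$replicates,
                       file.path(out_dir, "power_replicates.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$error))
    utils::write.table(report$error$replicates,
                       file.path(out_dir, "error_replicates.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report_summary(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' Render the report's figures
#'
#' Writes the figures for whichever stages the report contains: the power
#' scatter against subsample size, per-rate p-value boxplots, and the
#' permutation histogram with the observed statistic marked. Absent stages
#' are skipped with a message.
#'
#' @param report A `run_report`.
#' @param outdir Output directory.
#' @return Character vector of written file paths.
#' @export
render_figures <- function(report, outdir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  draw <- function(name, code) {
    path <- file.path(outdir, name)
    grDevices::png(path, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    code()
    files <<- c(files, path)
  }
  if (!is.null(report$power))
    draw("power_scatter.png", function() plot(report$power))
  else message("power stage absent; figure skipped")
  if (!is.null(report$error))
    draw("error_pvalues.png", function() plot(report$error))
  else message("error stage absent; figure skipped")
  if (!is.null(report$permutation))
    draw("permutation_hist.png", function() plot(report$permutation))
  else message("permutation stage absent; figure skipped")
  files
}
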