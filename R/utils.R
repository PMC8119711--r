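# Internal helpers shared across modules.

#' Derive a stage-specific child seed from a global seed
#'
#' Pipeline stages draw their randomness from child seeds so each stage is
#' independently reproducible from one global seed. The splitting rule is a
#' fixed affine hash modulo 2^31 - 1 (so results fit in an R integer).
#'
#' @param seed Integer global seed.
#' @param stage Integer stage index (>= 1) or a known stage name.
#' @return An integer seed in [1, 2^31 - 2].
#' @export
child_seed <- function(seed, stage) {
  if (is.character(stage)) {
    idx <- match(stage, .stage_names)
    if (is.na(idx)) stop("unknown stage name: ", stage)
    stage <- idx
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stage), stage >= 1)
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(seed) %% m)
  as.integer(((s * 48271 + stage * 1000003) %% (m - 1)) + 1)
}

.stage_names <- c("generate", "fit", "psm", "power", "error", "permute",
                  "calibrate")

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with a consistent prefix for user-facing validation failures
abort_check <- function(...) stop(..., call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
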