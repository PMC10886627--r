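# Internal helpers: seed handling and small shared utilities.

# Evaluate `expr` under a temporary R RNG seed, restoring the caller's RNG
# state afterwards so package functions never disturb the session stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive a stage-specific sub-seed from a master seed
#'
#' Stages of the pipeline (cohort generation, splitting, model
#' initialization, augmentation) each consume their own deterministic
#' sub-seed so that any stage can be re-run in isolation and reproduce its
#' original output.
#'
#' @param master integer master seed.
#' @param stage character stage tag (e.g. `"cohort"`, `"split"`).
#' @param index optional integer distinguishing repeats of one stage.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  val <- (as.double(master) %% 2147483647) * 69621 + h * 7919 + index * 104729
  as.integer(val %% 2147483647)
}

# quantize intensities onto the 16-bit grid used by the TIFF writer
quantize16 <- function(x) round(x * 65535) / 65535

`%||%` <- function(a, b) if (is.null(a)) b else a
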