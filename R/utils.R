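# Seed plumbing: one global seed fans out to per-stage seeds so every stage
# is independently reproducible. Stage codes are fixed small integers; the
# derived seed stays inside 32-bit integer range.
STAGE_CODES <- c(simulate = 11L, raters = 12L, split = 21L, init = 31L,
                 train = 32L, predict = 41L)

#' Derive a per-stage seed from a global seed
#'
#' `(seed * 7919 + stage_code * 1299709 + index) mod (2^31 - 1)`, a fixed
#' documented fan-out so that stages (and per-fold repetitions) of one run are
#' independently reproducible from the global seed.
#'
#' @param seed global integer seed.
#' @param stage one of `"simulate"`, `"raters"`, `"split"`, `"init"`,
#'   `"train"`, `"predict"`.
#' @param index optional per-item index (e.g. fold number), default 0.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  code <- STAGE_CODES[[stage]]
  as.integer((as.numeric(seed) * 7919 + as.numeric(code) * 1299709 +
                as.numeric(index)) %% (2^31 - 1))
}

# Evaluate expr with a temporarily-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
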