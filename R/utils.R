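# Per-stage RNG streams derived from one master seed, kept inside the 32-bit
# integer range R requires of set.seed().
stage_seed <- function(seed, stage) {
  stages <- c("emission", "detection", "misc")
  k <- match(stage, stages)
  if (is.na(k)) abort(paste0("unknown RNG stage: ", stage))
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * k
}

# Evaluate `code` under a temporary RNG state; assignments inside propagate
# to the caller's frame.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  eval(substitute(code), envir = parent.frame())
}
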