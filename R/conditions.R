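# Classed error conditions so callers (and the CLI) can distinguish validation
# failures from internal-consistency failures.

impt_abort <- function(msg, class, call. = FALSE, ...) {
  stop(errorCondition(msg, ..., class = c(class, "impt_error")))
}

impt_check <- function(cond, msg, class) {
  if (!isTRUE(cond)) impt_abort(msg, class)
  invisible(TRUE)
}

# Evaluate `expr` under a temporary RNG state so package functions never
# disturb the caller's random stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
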