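# Internal helpers: classed errors and locally scoped RNG.

abort_invalid <- function(field, msg) {
  stop(structure(
    class = c("chromodyn_validation_error", "error", "condition"),
    list(message = sprintf("invalid `%s`: %s", field, msg), call = sys.call(-1),
         field = field)
  ))
}

abort_analysis <- function(msg) {
  stop(structure(
    class = c("chromodyn_analysis_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_that <- function(cond, field, msg) {
  if (!isTRUE(cond)) abort_invalid(field, msg)
  invisible(TRUE)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# Generators take one explicit integer seed per call; no global state leaks.
with_seed <- function(seed, expr) {
  check_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
             "seed", "must be a single finite number")
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

`%||%` <- function(a, b) if (is.null(a)) b else a
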