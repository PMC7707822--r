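# Typed condition helpers. Every user-facing failure in the package is one of
# a small set of classed errors so callers (and the CLI) can branch on them:
#   locoresp_validation_error  -- data violates a type invariant
#   locoresp_parameter_error   -- a function argument is out of range
#   locoresp_format_error      -- a file does not follow its dialect
#   locoresp_config_error      -- the session configuration is incomplete/wrong
#   locoresp_io_error          -- filesystem failure
# All inherit from locoresp_error.

stop_locoresp <- function(subclass, msg, ...) {
  stop(structure(
    class = c(subclass, "locoresp_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_validation <- function(msg, ...) stop_locoresp("locoresp_validation_error", msg, ...)
stop_parameter  <- function(msg, ...) stop_locoresp("locoresp_parameter_error", msg, ...)
stop_format     <- function(msg, ...) stop_locoresp("locoresp_format_error", msg, ...)
stop_config     <- function(msg, ...) stop_locoresp("locoresp_config_error", msg, ...)
stop_io         <- function(msg, ...) stop_locoresp("locoresp_io_error", msg, ...)

# scalar checks used throughout
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Run an expression with a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
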