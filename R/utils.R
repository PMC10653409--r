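#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can distinguish bad user input
# from bad configuration from degenerate data.
ccsa_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ccsa_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_validation <- function(msg, ...) ccsa_abort("ccsa_validation_error", msg, ...)
abort_config     <- function(msg, ...) ccsa_abort("ccsa_config_error", msg, ...)
abort_degenerate <- function(msg, ...) ccsa_abort("ccsa_degenerate_error", msg, ...)
abort_parameter  <- function(msg, ...) ccsa_abort("ccsa_parameter_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a private RNG state, leaving the caller's untouched.
with_preserved_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
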