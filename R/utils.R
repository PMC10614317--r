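#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish configuration mistakes from
# numeric failures.
incrisk_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "incrisk_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

config_error <- function(msg, ...) incrisk_error(msg, "incrisk_config_error", ...)
data_error <- function(msg, ...) incrisk_error(msg, "incrisk_data_error", ...)

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards so
# generator calls do not perturb an enclosing simulation.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x, digits = 3) formatC(x, digits = digits, format = "f")
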