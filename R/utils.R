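#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif sd pbinom rbinom
#' @importFrom utils head
NULL

# Internal error helpers: every user-facing failure carries a condition class
# so callers (and the CLI) can distinguish configuration, schema and analysis
# errors programmatically.
stop_config <- function(msg) abort(msg, class = "proxiscore_config_error")
stop_value <- function(msg) abort(msg, class = "proxiscore_value_error")
stop_schema <- function(msg) abort(msg, class = "proxiscore_schema_error")
stop_integrity <- function(msg) abort(msg, class = "proxiscore_integrity_error")
stop_analysis <- function(msg) abort(msg, class = "proxiscore_analysis_error")
stop_generation <- function(msg) abort(msg, class = "proxiscore_generation_error")

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_value(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    stop_value(sprintf("`%s` must be > 0 (got %g)", name, x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_scalar_number(x, name)
  if (x != as.integer(x) || x < min) {
    stop_value(sprintf("`%s` must be an integer >= %d (got %g)", name, min, x))
  }
  invisible(as.integer(x))
}

#' Deterministic per-stream seed derivation
#'
#' Derives a child seed from a root seed and a sequence of string labels by a
#' stable polynomial hash, so that each (stage, condition, sample) tuple gets
#' its own reproducible random stream and adding a sample never perturbs the
#' streams of existing ones.
#'
#' @param seed integer root seed.
#' @param ... character labels identifying the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
stream_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)),
                  collapse = "")
  h <- 0
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((abs(as.numeric(seed)) + h) %% 2147483647)
}

# Evaluate `expr` under a derived seed, restoring the caller's RNG state.
with_stream <- function(seed, labels, expr) {
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
  set.seed(do.call(stream_seed, c(list(seed), as.list(labels))))
  expr
}

# Round half away from zero to `digits` decimals (round() rounds half to even,
# which would turn e.g. 0.25 into 0.2).
round_half_away <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
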