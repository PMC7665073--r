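# Internal input checkers shared across modules.

stop_invalid <- function(...) {
  stop(structure(
    class = c("algafeed_invalid_input", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    stop_invalid("`", name, "` must be positive and non-missing")
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop_invalid("`", name, "` must be non-negative and non-missing")
  }
  invisible(x)
}

check_scalar_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_invalid("a single integer `seed` is required")
  }
  as.integer(seed)
}
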