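# Internal helpers shared across modules.

# Fail with a classed condition so callers/tests can distinguish bad inputs
# from genuine runtime errors.
stop_invalid <- function(msg, class = "neurophenor_invalid_config") {
  rlang::abort(msg, class = class)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop_invalid(sprintf("`%s` must be finite and >= 0", name))
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_invalid(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Metrics that are undefined (e.g. mean rate over an empty active set) are
# reported as NA, never as 0.
undefined_metric <- function() NA_real_
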