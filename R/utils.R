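# internal helpers shared across modules

# run `code` under a fixed RNG seed without disturbing the caller's RNG state;
# seed = NULL leaves the RNG stream alone
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "iopgrs_config_error", ...)
}

abort_schema <- function(msg, ...) {
  rlang::abort(msg, class = "iopgrs_schema_error", ...)
}

abort_contract <- function(msg, ...) {
  rlang::abort(msg, class = "iopgrs_contract_error", ...)
}

abort_infeasible <- function(msg, ...) {
  rlang::abort(msg, class = "iopgrs_infeasible_error", ...)
}

abort_collinearity <- function(msg, ...) {
  rlang::abort(msg, class = "iopgrs_collinearity_error", ...)
}

abort_degenerate <- function(msg, ...) {
  rlang::abort(msg, class = "iopgrs_degenerate_error", ...)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

`%||%` <- rlang::`%||%`
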