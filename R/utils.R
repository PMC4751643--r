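# Internal helpers: error conditions, seeding, small numeric utilities.

#' @useDynLib ovcortex, .registration = TRUE
NULL

# Structured conditions so the CLI can map error classes to exit codes
# (2 = configuration error, 3 = data error).
stop_config <- function(msg, ...) {
  stop(structure(class = c("ovcortex_config_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_data <- function(msg, ...) {
  stop(structure(class = c("ovcortex_data_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Evaluate `code` under `seed` when non-NULL, restoring the caller's RNG
# state afterwards; with seed = NULL the current stream is used as-is.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Derive per-replicate seeds from one master seed, kept within 32-bit range.
derive_seeds <- function(seed, n) {
  with_seed_if(seed, sample.int(.Machine$integer.max - 1L, n))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
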