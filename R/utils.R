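# Internal helpers: classed conditions and small numeric utilities.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = "gaitdose_invalid_input"))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = "gaitdose_invalid_config"))
}

stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = "gaitdose_schema_error"))
}

warn_gd <- function(...) {
  warning(warningCondition(paste0(...), class = "gaitdose_warning"))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Truncated Gaussian jitter: rejection sampling at +/- trunc_sd standard
# deviations so perturbed event times stay ordered for reasonable SDs.
rtruncnorm0 <- function(n, sd, trunc_sd = 3) {
  if (sd == 0 || n == 0L) return(numeric(n))
  out <- stats::rnorm(n, 0, sd)
  bad <- abs(out) > trunc_sd * sd
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(out) > trunc_sd * sd
  }
  out
}

# Deterministic child seed derived from a user seed and a stage label,
# kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
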