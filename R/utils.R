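# Internal helpers shared across modules.

# Classed error so callers/tests can distinguish failure modes:
# "mozage_config_error", "mozage_input_error", "mozage_data_error",
# "mozage_design_error", "mozage_model_error".
.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mozage_error")))
}

.check <- function(cond, msg, class = "mozage_input_error") {
  if (!isTRUE(cond)) .err(msg, class)
}

.is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Deterministic child seed derived from a master seed and a string id, so
# per-sample randomness is reproducible and independent of sample order.
# Polynomial string hash modulo a prime < 2^31.
.child_seed <- function(seed, id) {
  mod <- 2147483563
  h <- 0
  for (ch in utf8ToInt(as.character(id))) h <- (h * 31 + ch) %% mod
  as.integer((as.numeric(seed) %% mod + h) %% mod)
}

# Format a numeric vector for the plain-text model/manifest serialization;
# %.17g round-trips doubles exactly through decimal.
.fmt_num <- function(x) sprintf("%.17g", x)
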