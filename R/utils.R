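# Internal helpers shared across modules.

#' @keywords internal
plan_type_levels <- c("balanced", "copay", "coinsurance", "deductible")

# Deterministic sub-seed for a named random substream.  All randomness in the
# package flows from one master seed through this, so stages can be re-run in
# isolation and still reproduce.  Result stays below 2^31 - 1.
substream_seed <- function(master, name) {
  ch <- utf8ToInt(name)
  h <- sum(ch * seq_along(ch)) %% 104729
  as.integer((as.numeric(master) %% 2146319 * 1000003 + h) %% 2147483629)
}

# Round half away from zero (R's round() is banker's rounding).  Used where
# printed-percent style rounding is wanted.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Mode of a numeric vector with deterministic tie-break: among equally
# frequent values the smallest wins.
stat_mode <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  tab <- table(x)
  vals <- as.numeric(names(tab))
  cand <- vals[tab == max(tab)]
  min(cand)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
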