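# Internal helpers shared across modules.

# Reproducible stage-local RNG: every stochastic operation draws under a
# seed derived from the master seed plus a stage tag, so outputs depend
# only on (config, stage), never on call order.  Offsets stay well below
# .Machine$integer.max.
stage_seed <- function(seed, stage) {
  offsets <- c(
    panel = 11L, truth = 17L, sumstats = 23L, lifestyle = 37L, disease = 51L,
    split = 67L, pipeline = 83L
  )
  off <- offsets[[stage]]
  if (is.null(off)) abort(paste0("unknown RNG stage: ", stage))
  as.integer((as.numeric(seed) + off) %% 2147483647)
}

check_prob <- function(x, name, open = TRUE) {
  ok <- if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!all(is.finite(x)) || !ok) {
    abort(paste0("`", name, "` must lie in ", if (open) "(0, 1)" else "[0, 1]"))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
    abort(paste0("`", name, "` must be a single integer >= ", min))
  }
  invisible(as.integer(x))
}

# Wald CI on the exponentiated (OR/HR) scale.
wald_ci <- function(est, se, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(low = est - z * se, high = est + z * se)
}
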