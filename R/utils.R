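# internal helpers

# run a block under a local RNG state so generators are reproducible without
# disturbing the caller's stream
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (length(x) != 1 || !is.finite(x) || (positive && x <= 0))
    stop(sprintf("'%s' must be a finite %sscalar", name,
                 if (positive) "positive " else ""), call. = FALSE)
  invisible(x)
}

# double-exponential transient shape: peak location and unit-peak waveform
transientPeakOffset <- function(rise_tau, decay_tau) {
  rise_tau * log((rise_tau + decay_tau) / rise_tau)
}

transientShape <- function(t, onset, rise_tau, decay_tau) {
  u <- t - onset
  s <- numeric(length(t))
  pos <- u > 0
  up <- transientPeakOffset(rise_tau, decay_tau)
  peak <- (1 - exp(-up / rise_tau)) * exp(-up / decay_tau)
  s[pos] <- (1 - exp(-u[pos] / rise_tau)) * exp(-u[pos] / decay_tau) / peak
  s
}
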