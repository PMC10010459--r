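# build an EventTable directly from event descriptions (times in seconds)
makeEventTable <- function(df, duration = 60, samplingRate = 10) {
  base <- data.frame(roi_id = 1L, onset_time = 0, peak_time = 0,
                     span_start = NA_real_, span_end = NA_real_,
                     amplitude = 1, rise_time = 0.1, decay_time = 0.1,
                     decay_censored = FALSE, window_label = NA_character_)
  if (nrow(df) == 0) {
    out <- base[0, ]
    return(new("EventTable", events = out, duration = duration,
               samplingRate = samplingRate))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    row <- base
    for (nm in names(df)) row[[nm]] <- df[[nm]][i]
    row
  }))
  if (all(is.na(out$span_start))) out$span_start <- out$onset_time
  if (all(is.na(out$span_end))) out$span_end <- out$peak_time
  new("EventTable", events = out, duration = duration,
      samplingRate = samplingRate)
}

# build a BinaryRaster from a 0/1 matrix (ROIs x bins)
makeRaster <- function(m, binRate = 2, window = NULL) {
  if (is.null(window)) window <- c(0, ncol(m) / binRate)
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(seq_len(nrow(m)))
  new("BinaryRaster", mat = m, binRate = binRate, window = window)
}

# brute-force alternation count: explicit triple loop over triads
bruteAlternations <- function(entries) {
  n <- length(entries)
  cnt <- 0L
  if (n >= 3)
    for (i in 1:(n - 2)) {
      a <- entries[i]; b <- entries[i + 1]; c <- entries[i + 2]
      if (a != b && b != c && a != c) cnt <- cnt + 1L
    }
  cnt
}

# single-transient recovery experiment shared by unit and acceptance tests
eventRecovery <- function(nTraces, amplitude = 0.5, noiseSd = 0.02,
                          seedOffset = 0) {
  hits <- falses <- 0
  ampErr <- numeric(0)
  for (s in seq_len(nTraces)) {
    sim <- simTraces(list(data.frame(amplitude = amplitude, rise_tau = 2,
                                     decay_tau = 6, onset_time = 60)),
                     duration = 180, samplingRate = 10, noiseSd = noiseSd,
                     seed = s + seedOffset)
    dff <- computeDff(sim$traces[, 1], sim$time, c(0, 50))
    et <- events(detectEvents(dff, sim$time, c(0, 50), minDuration = 2))
    match <- abs(et$peak_time - sim$truth$peak_time) < 3
    hits <- hits + any(match)
    falses <- falses + sum(!match)
    if (any(match))
      ampErr <- c(ampErr, abs(et$amplitude[match][1] - 100 * amplitude) /
                    (100 * amplitude))
  }
  list(sensitivity = hits / nTraces, false_frac = falses / nTraces,
       median_amp_err = stats::median(ampErr))
}
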