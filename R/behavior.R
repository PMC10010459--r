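#' Count spontaneous alternations in an arm-entry sequence
#'
#' An alternation is a sliding triplet of consecutive entries
#' `(i, i+1, i+2)` whose three arm labels are pairwise distinct. Overlapping
#' triplets all count, which is what makes the percent-alternation
#' denominator `entries - 2`. Repeated consecutive entries into the same arm
#' are retained.
#'
#' @param entries character (or factor) vector of arm labels over
#'   `{A, B, C}`.
#' @return integer alternation count (0 for sequences shorter than 3).
#' @export
countAlternations <- function(entries) {
  entries <- as.character(entries)
  n <- length(entries)
  if (n < 3) return(0L)
  a <- entries[1:(n - 2)]; b <- entries[2:(n - 1)]; c <- entries[3:n]
  sum(a != b & b != c & a != c)
}

#' Percent spontaneous alternation
#'
#' `% Alternation = alternations / (entries - 2) * 100`. The score is
#' invariant under any relabeling of the three arms and always lies in
#' `[0, 100]`.
#'
#' @param entries character vector of arm labels (>= 3 entries).
#' @return percent alternation; `NA` with attribute `flagged = TRUE` for
#'   sequences shorter than 3.
#' @export
percentAlternation <- function(entries) {
  n <- length(entries)
  if (n < 3) {
    out <- NA_real_; attr(out, "flagged") <- TRUE
    return(out)
  }
  countAlternations(entries) / (n - 2) * 100
}
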