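# shared helpers

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), the convention used for
#' all reported percentages. Base `round()` rounds half to even, which would
#' turn e.g. 8.65 into 8.6.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# case-sensitive exact-or-glob matcher over names (* and ? wildcards)
glob_match <- function(x, pattern) {
  grepl(glob2rx(pattern), x)
}

# reverse complement of an ACGTN string
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# validate a DNA string over {A,C,G,T,N}; error names the first bad position
check_dna <- function(s, what = "sequence") {
  if (length(s) != 1 || is.na(s) || nchar(s) == 0) {
    stop(what, " must be a non-empty DNA string", call. = FALSE)
  }
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0) {
    stop(what, " contains non-IUPAC character '", substr(s, bad, bad),
         "' at position ", bad, call. = FALSE)
  }
  invisible(s)
}

# random DNA of length n under the current RNG state
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
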