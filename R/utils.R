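# internal helpers shared across modules

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' @noRd
ionmut_error <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "ionmut_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Round half away from zero (base round() is banker's rounding).
#' @noRd
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Validate and normalise a nucleotide string; returns uppercased string.
#' @noRd
normalize_seq <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    ionmut_error(sprintf("%s must be a single character string", what),
                 "ionmut_bad_sequence")
  }
  x <- toupper(x)
  if (nchar(x) == 0L) {
    ionmut_error(sprintf("%s is empty", what), "ionmut_bad_sequence")
  }
  bad <- gsub("[ACGTN]", "", x)
  if (nchar(bad) > 0L) {
    ionmut_error(sprintf("%s contains non-ACGTN characters: '%s'",
                         what, substr(bad, 1, 10)),
                 "ionmut_bad_sequence")
  }
  x
}

# Longest common prefix / suffix lengths of two strings (byte-wise).
#' @noRd
lcp_len <- function(x, y) {
  a <- utf8ToInt(x); b <- utf8ToInt(y)
  m <- min(length(a), length(b))
  if (m == 0L) return(0L)
  neq <- which(a[seq_len(m)] != b[seq_len(m)])
  if (length(neq) == 0L) m else neq[1L] - 1L
}

#' @noRd
lcs_len <- function(x, y) {
  a <- rev(utf8ToInt(x)); b <- rev(utf8ToInt(y))
  m <- min(length(a), length(b))
  if (m == 0L) return(0L)
  neq <- which(a[seq_len(m)] != b[seq_len(m)])
  if (length(neq) == 0L) m else neq[1L] - 1L
}

#' @noRd
check_scalar_number <- function(x, name, positive = FALSE,
                                nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x)) {
    ionmut_error(sprintf("%s must be numeric and non-missing", name),
                 "ionmut_domain_error")
  }
  if (positive && any(x <= 0)) {
    ionmut_error(sprintf("%s must be > 0", name), "ionmut_domain_error")
  }
  if (nonnegative && any(x < 0)) {
    ionmut_error(sprintf("%s must be >= 0", name), "ionmut_domain_error")
  }
  invisible(x)
}

#' Reverse-complement a nucleotide string
#'
#' @param x a single A/C/G/T/N string (case-insensitive).
#' @return the reverse complement, uppercased.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  x <- normalize_seq(x)
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
}
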