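#' Validate a CAS registry number
#'
#' A CAS number has the form `NNNNNNN-NN-N` (2 to 7 digits, 2 digits, 1
#' check digit). The check digit equals the sum of the other digits, each
#' multiplied by its 1-based position counted from the rightmost non-check
#' digit, taken modulo 10. For benzene, 71-43-2:
#' (4*7 + 3*1 + 2*4 + 1*3) mod 10 = 2.
#'
#' @param cas Character vector of candidate CAS strings.
#' @return Logical vector, `TRUE` where the pattern and check digit are
#'   both valid. Malformed input never errors; it returns `FALSE`.
#' @examples
#' validate_cas("71-43-2")   # TRUE  (benzene)
#' validate_cas("71-43-3")   # FALSE (bad check digit)
#' @export
validate_cas <- function(cas) {
  vapply(as.character(cas), .validate_cas1, logical(1), USE.NAMES = FALSE)
}

.validate_cas1 <- function(cas) {
  if (is.na(cas) || !grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", cas)) {
    return(FALSE)
  }
  digits <- as.integer(strsplit(gsub("-", "", cas), "")[[1]])
  n <- length(digits)
  check <- digits[n]
  body <- rev(digits[-n])            # rightmost non-check digit first
  sum(body * seq_along(body)) %% 10 == check
}

# Append the correct check digit to a digit-only body string, e.g.
# "7143" -> "71-43-2". Used by the synthetic database generator.
cas_from_body <- function(body) {
  stopifnot(grepl("^[0-9]{4,9}$", body))
  digits <- as.integer(strsplit(body, "")[[1]])
  check <- sum(rev(digits) * seq_along(digits)) %% 10
  n <- nchar(body)
  sprintf("%s-%s-%d", substr(body, 1, n - 2), substr(body, n - 1, n), check)
}
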