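#' Pseudo-log transform of raw fluorescence
#'
#' Cytometers emit negative raw FITC-A values for dim cells, so raw signal is
#' shifted by +1000 A.U. before taking log10, and 3 log10 units are
#' subtracted so that raw 0 maps to 0:
#' `pseudolog(x) = log10(x + 1000) - 3`.
#'
#' @param raw numeric vector of raw FITC-A values (A.U.), must exceed -1000.
#' @return pseudo-log A.U. values.
#' @seealso [pseudolog_inv()]
#' @examples
#' pseudolog(c(0, 99000))   # 0, 2
#' @export
pseudolog <- function(raw) {
  if (any(!is.na(raw) & raw <= -1000)) {
    stopf("pseudolog: raw values must be > -1000 A.U.")
  }
  log10(raw + 1000) - 3
}

#' Inverse of the pseudo-log transform
#'
#' @param x pseudo-log A.U. values.
#' @return raw A.U. values such that `pseudolog(pseudolog_inv(x)) == x`.
#' @export
pseudolog_inv <- function(x) {
  10^(x + 3) - 1000
}
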