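#' Convert chemical shieldings to chemical shifts
#'
#' Applies the standard NMR referencing convention delta = offset - shielding
#' with a per-element offset (defaults: 30.78 ppm for 1H, 170.04 ppm for 13C).
#' The conversion is affine and order-reversing: larger shielding means
#' smaller shift.
#'
#' @param shielding numeric vector of shieldings in ppm.
#' @param element element symbol(s), length 1 or the length of
#'   \code{shielding}.
#' @param ref a \linkS4class{ShiftReferencing} object.
#' @return numeric vector of chemical shifts in ppm.
#' @examples
#' shieldingToShift(30.78, "H")   # 0
#' shieldingToShift(0, "C")       # 170.04
#' @export
shieldingToShift <- function(shielding, element, ref = shiftReferencing()) {
  element <- rep_len(element, length(shielding))
  unknown <- setdiff(unique(element), names(ref@offsets))
  if (length(unknown))
    stop("no referencing offset for element(s): ",
         paste(unknown, collapse = ", "))
  unname(ref@offsets[element]) - shielding
}
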