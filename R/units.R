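# Unit conversions used throughout: glucose mg/dL <-> mmol/L and
# HbA1c NGSP % <-> IFCC mmol/mol.

#' Molar-mass divisor relating glucose mg/dL to mmol/L
#'
#' mmol/L = mg/dL / 18.016 (glucose molar mass 180.16 g/mol, divided by 10
#' for the dL -> L change). Exported as a constant so reports and tests pin
#' the same divisor.
#' @keywords internal
GLUCOSE_MGDL_PER_MMOLL <- 18.016

#' Convert glucose between mg/dL and mmol/L
#'
#' Uses the conventional divisor 18.016 (glucose molar mass / 10), the value
#' consistent with standard dual-unit reporting such as 250 mg/dL = 13.9
#' mmol/L and 54 mg/dL = 3.0 mmol/L.
#'
#' @param value Numeric vector of non-negative glucose values.
#' @param direction One of `"mgdl_to_mmoll"` or `"mmoll_to_mgdl"`.
#' @param round_result If `TRUE`, round mmol/L output to 1 decimal (the
#'   conventional reporting precision). mg/dL output is rounded to the
#'   nearest integer. Defaults to `FALSE` (full precision).
#' @return Numeric vector of converted values.
#' @examples
#' convert_glucose(250, "mgdl_to_mmoll", round_result = TRUE)  # 13.9
#' convert_glucose(54, "mgdl_to_mmoll", round_result = TRUE)   # 3.0
#' @export
convert_glucose <- function(value,
                            direction = c("mgdl_to_mmoll", "mmoll_to_mgdl"),
                            round_result = FALSE) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(value))
  if (any(value < 0, na.rm = TRUE)) {
    stop("glucose values must be non-negative", call. = FALSE)
  }
  out <- if (direction == "mgdl_to_mmoll") {
    value / GLUCOSE_MGDL_PER_MMOLL
  } else {
    value * GLUCOSE_MGDL_PER_MMOLL
  }
  if (round_result) {
    out <- if (direction == "mgdl_to_mmoll") round(out, 1) else round(out)
  }
  out
}

#' Convert A1c between NGSP percent and IFCC mmol/mol
#'
#' NGSP master equation: IFCC mmol/mol = 10.929 * (NGSP% - 2.15), and its
#' inverse. Reporting convention rounds IFCC to the nearest integer
#' (half-up), e.g. 13.5% -> 124 mmol/mol and 7.5% -> 58 mmol/mol.
#'
#' @param value Numeric vector of non-negative A1c values.
#' @param direction One of `"ngsp_to_ifcc"` or `"ifcc_to_ngsp"`.
#' @param round_result If `TRUE`, round IFCC output to the nearest integer
#'   (half-up) and NGSP output to 1 decimal. Defaults to `FALSE`.
#' @return Numeric vector of converted values.
#' @examples
#' convert_a1c(13.5, "ngsp_to_ifcc", round_result = TRUE)  # 124
#' @export
convert_a1c <- function(value,
                        direction = c("ngsp_to_ifcc", "ifcc_to_ngsp"),
                        round_result = FALSE) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(value))
  if (any(value < 0, na.rm = TRUE)) {
    stop("A1c values must be non-negative", call. = FALSE)
  }
  out <- if (direction == "ngsp_to_ifcc") {
    10.929 * (value - 2.15)
  } else {
    value / 10.929 + 2.15
  }
  if (round_result) {
    out <- if (direction == "ngsp_to_ifcc") {
      # round half-up, not banker's rounding
      floor(out + 0.5)
    } else {
      round(out, 1)
    }
  }
  out
}
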