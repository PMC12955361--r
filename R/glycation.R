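# Kinetic glycation model: apparent glycation ratio (AGR) estimation,
# forward A1c prediction, personalized A1c (pA1c), the reference-glycator
# curve, and the mean-glucose inverse.
#
# Steady-state model. With MG the mean glucose (mg/dL), K_M the Michaelis
# constant of RBC glucose transport (472 mg/dL) and AGR the subject's
# apparent glycation ratio (mL/mg):
#
#   X(MG)      = 1/MG + 1/K_M                     (apparent-glucose term)
#   AGR        = 1e5 * X(MG) / (100/A1c - 1)      (calibration)
#   A1c        = 100 / (1 + 1e5 * X(MG) / AGR)    (forward model)
#   pA1c       = 100 / (1 + (AGR/AGR_ref) * (100/A1c - 1))
#
# pA1c rescales a measured A1c onto the scale of a "reference glycator"
# with AGR_ref = 65.1 mL/mg; for that subject pA1c == A1c identically.

#' Kinetic-model constants
#'
#' Container for the two constants of the glycation model: the Michaelis
#' constant of RBC glucose transport `k_m` (mg/dL) and the reference
#' glycation rate constant `agr_ref` (mL/mg). Defaults are the standard
#' published values, 472 mg/dL and 65.1 mL/mg.
#'
#' @param k_m Michaelis constant, mg/dL. Must be > 0.
#' @param agr_ref Reference-glycator AGR, mL/mg. Must be > 0.
#' @return An object of class `glycation_constants` (a named list).
#' @export
glycation_constants <- function(k_m = 472, agr_ref = 65.1) {
  stopifnot(is.numeric(k_m), length(k_m) == 1L,
            is.numeric(agr_ref), length(agr_ref) == 1L)
  if (k_m <= 0 || agr_ref <= 0) {
    stop("k_m and agr_ref must be strictly positive", call. = FALSE)
  }
  structure(list(k_m = k_m, agr_ref = agr_ref),
            class = "glycation_constants")
}

#' @export
print.glycation_constants <- function(x, ...) {
  cat("Glycation constants: K_M =", x$k_m, "mg/dL, AGR_ref =",
      x$agr_ref, "mL/mg\n")
  invisible(x)
}

.check_mg <- function(mg) {
  if (!is.numeric(mg) || any(!is.finite(mg)) || any(mg <= 0)) {
    stop("mean glucose must be finite and strictly positive (mg/dL)",
         call. = FALSE)
  }
}

.check_a1c <- function(a1c) {
  if (!is.numeric(a1c) || any(!is.finite(a1c)) ||
      any(a1c <= 0) || any(a1c >= 100)) {
    stop("A1c must lie strictly inside (0, 100) NGSP %", call. = FALSE)
  }
}

.check_agr <- function(agr) {
  if (!is.numeric(agr) || any(!is.finite(agr)) || any(agr <= 0)) {
    stop("AGR must be finite and strictly positive (mL/mg)", call. = FALSE)
  }
}

#' Apparent-glucose term of the kinetic model
#'
#' X(MG) = 1/MG + 1/K_M, the composite concentration term (dL/mg) that the
#' glycation rate is proportional to. As MG grows it saturates towards
#' 1/K_M, encoding Michaelis-Menten RBC glucose transport.
#'
#' @param mg Mean glucose, mg/dL (vectorised, all > 0).
#' @param constants A [glycation_constants()] object.
#' @return X(MG) in dL/mg.
#' @export
apparent_glucose <- function(mg, constants = glycation_constants()) {
  .check_mg(mg)
  1 / mg + 1 / constants$k_m
}

#' Apparent glycation ratio from calibration mean glucose and A1c
#'
#' AGR = 1e5 * X(MG) / (100/A1c - 1). The AGR (mL/mg) summarises a
#' subject's glycation tendency: higher AGR means higher A1c for the same
#' mean glucose. It is estimated once from a calibration window (pooled
#' CGM mean glucose and the laboratory A1c drawn at its end) and then
#' treated as a personal constant.
#'
#' @param mg Calibration mean glucose, mg/dL (> 0).
#' @param a1c Calibration A1c, NGSP % in (0, 100).
#' @param constants A [glycation_constants()] object.
#' @return AGR in mL/mg; strictly increasing in `a1c`, decreasing in `mg`.
#' @examples
#' compute_agr(154, 7.0)  # about 64.8, close to the reference 65.1
#' @export
compute_agr <- function(mg, a1c, constants = glycation_constants()) {
  .check_mg(mg)
  .check_a1c(a1c)
  1e5 * apparent_glucose(mg, constants) / (100 / a1c - 1)
}

#' Steady-state A1c predicted from mean glucose and AGR
#'
#' A1c = 100 / (1 + 1e5 * X(MG) / AGR), the algebraic inverse of
#' [compute_agr()]. Strictly increasing in both arguments, bounded above by
#' the saturation asymptote 100 / (1 + 1e5 / (AGR * K_M)).
#'
#' @param mg Mean glucose, mg/dL (> 0).
#' @param agr Apparent glycation ratio, mL/mg (> 0).
#' @param constants A [glycation_constants()] object.
#' @return A1c in NGSP %, in (0, 100).
#' @examples
#' forward_a1c(154, 65.1)  # about 7.0
#' @export
forward_a1c <- function(mg, agr, constants = glycation_constants()) {
  .check_mg(mg)
  .check_agr(agr)
  100 / (1 + 1e5 * apparent_glucose(mg, constants) / agr)
}

#' Personalized A1c (pA1c)
#'
#' pA1c = 100 / (1 + (AGR/AGR_ref) * (100/A1c - 1)). Maps a measured A1c
#' onto the reference-glycator scale using the subject's AGR, so that the
#' result tracks mean glucose the way a reference glycator's A1c would.
#' When `agr == agr_ref` the transform is the identity.
#'
#' @param a1c_measured Measured A1c, NGSP % in (0, 100).
#' @param agr Subject's apparent glycation ratio, mL/mg (> 0).
#' @param constants A [glycation_constants()] object.
#' @return pA1c in NGSP %, in (0, 100); increasing in `a1c_measured`,
#'   decreasing in `agr`.
#' @examples
#' compute_pa1c(10.0, 65.1)   # 10.0 (reference glycator)
#' compute_pa1c(10.1, 67.52)  # about 9.77
#' @export
compute_pa1c <- function(a1c_measured, agr,
                         constants = glycation_constants()) {
  .check_a1c(a1c_measured)
  .check_agr(agr)
  100 / (1 + (agr / constants$agr_ref) * (100 / a1c_measured - 1))
}

#' Reference-glycator A1c curve
#'
#' The A1c a reference glycator (AGR = `agr_ref`) would have at a given
#' mean glucose; equivalently `forward_a1c(mg, constants$agr_ref)`. The
#' model's central identity is that `compute_pa1c(a, compute_agr(mg, a))`
#' equals `reference_ea1c(mg)` for every `a` — the personalization removes
#' the dependence on the individual A1c and leaves only the MG signal.
#'
#' @param mg Mean glucose, mg/dL (> 0).
#' @param constants A [glycation_constants()] object.
#' @return A1c in NGSP %.
#' @examples
#' reference_ea1c(154)  # about 7.0
#' @export
reference_ea1c <- function(mg, constants = glycation_constants()) {
  forward_a1c(mg, constants$agr_ref, constants)
}

#' Mean glucose implied by an A1c and an AGR
#'
#' Inverts the forward model: MG = 1 / ((100/A1c - 1) * AGR/1e5 - 1/K_M).
#' A finite solution only exists below the saturation asymptote
#' 100 / (1 + 1e5 / (AGR * K_M)); above it the requested A1c is
#' unreachable at any glucose for that AGR.
#'
#' @param a1c A1c, NGSP % in (0, 100).
#' @param agr Apparent glycation ratio, mL/mg (> 0).
#' @param constants A [glycation_constants()] object.
#' @return Mean glucose in mg/dL.
#' @examples
#' estimate_mg(forward_a1c(300, 50), 50)  # 300
#' @export
estimate_mg <- function(a1c, agr, constants = glycation_constants()) {
  .check_a1c(a1c)
  .check_agr(agr)
  denom <- (100 / a1c - 1) * agr / 1e5 - 1 / constants$k_m
  if (any(denom <= 0)) {
    stop("A1c too high for this AGR under the kinetic model ",
         "(at or above the saturation asymptote)", call. = FALSE)
  }
  1 / denom
}
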