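#' Composite (rule-of-mixtures) model parameters
#'
#' Defaults follow the worked bundle examples: ECM modulus ~1 MPa, a
#' homogeneous-fiber modulus of ~20 kPa, and, for the basement-membrane
#' shell model, a stiff membrane of constant thickness around a softer
#' contractile core.
#'
#' @param E_ECM_kPa Extracellular-matrix modulus (kPa), default 1000.
#' @param E_fiber_kPa Homogeneous fiber modulus (kPa), default 20.
#' @param E_core_kPa Contractile-core modulus for the shell model (kPa),
#'   default 15.
#' @param E_bm_kPa Basement-membrane modulus (kPa), default 1000.
#' @param t_bm_um Basement-membrane thickness (um), default 0.5, constant
#'   across fiber sizes.
#' @return An object of class `composite_params`.
#' @export
composite_params <- function(E_ECM_kPa = 1000, E_fiber_kPa = 20,
                             E_core_kPa = 15, E_bm_kPa = 1000,
                             t_bm_um = 0.5) {
  stopifnot(E_ECM_kPa > 0, E_fiber_kPa > 0, E_core_kPa > 0, E_bm_kPa > 0,
            t_bm_um >= 0)
  structure(
    list(E_ECM_kPa = E_ECM_kPa, E_fiber_kPa = E_fiber_kPa,
         E_core_kPa = E_core_kPa, E_bm_kPa = E_bm_kPa, t_bm_um = t_bm_um),
    class = "composite_params"
  )
}

#' Rule-of-mixtures bundle modulus
#'
#' E_bundle = f_ECM * E_ECM + (1 - f_ECM) * E_fiber: a bundle is treated as
#' a two-phase composite of homogeneous ECM and homogeneous fibers loaded
#' in parallel. With E_ECM = 1 MPa and E_fiber = 20 kPa, a 5% ECM fraction
#' gives 69 kPa.
#'
#' @param f_ECM ECM area fraction in `[0, 1]`.
#' @param E_ECM_kPa,E_fiber_kPa Constituent moduli (kPa), > 0.
#' @return Bundle modulus in kPa, bounded by the two constituent moduli.
#' @export
rule_of_mixtures <- function(f_ECM, E_ECM_kPa = 1000, E_fiber_kPa = 20) {
  if (anyNA(f_ECM) || any(f_ECM < 0) || any(f_ECM > 1)) {
    stop("f_ECM must lie in [0, 1]")
  }
  stopifnot(E_ECM_kPa > 0, E_fiber_kPa > 0)
  f_ECM * E_ECM_kPa + (1 - f_ECM) * E_fiber_kPa
}

#' Invert the rule of mixtures for the ECM fraction
#'
#' Algebraic inverse: f = (E_bundle - E_fiber) / (E_ECM - E_fiber).
#'
#' @param E_bundle_kPa Measured bundle modulus (kPa), between the two
#'   constituent moduli.
#' @inheritParams rule_of_mixtures
#' @return ECM fraction in `[0, 1]`.
#' @export
invert_rule_of_mixtures <- function(E_bundle_kPa, E_ECM_kPa = 1000,
                                    E_fiber_kPa = 20) {
  if (E_ECM_kPa == E_fiber_kPa) {
    stop("degenerate: ECM and fiber moduli are equal, fraction is undetermined")
  }
  lo <- min(E_ECM_kPa, E_fiber_kPa); hi <- max(E_ECM_kPa, E_fiber_kPa)
  if (any(E_bundle_kPa < lo) || any(E_bundle_kPa > hi)) {
    stop("bundle modulus outside the range spanned by the constituent moduli")
  }
  (E_bundle_kPa - E_fiber_kPa) / (E_ECM_kPa - E_fiber_kPa)
}

#' Fiber modulus under the basement-membrane shell model
#'
#' Each fiber is a circular contractile core wrapped in a basement membrane
#' of constant thickness t. The membrane cross-section (an annulus) scales
#' with diameter d while the core scales with d^2, so the membrane area
#' fraction phi = 1 - ((d - 2t)/d)^2 falls with fiber size and a stiff
#' membrane makes small fibers stiffer -- the fiber-level size effect.
#'
#' @param diameter_um Fiber diameter (um), > 2 * t_bm.
#' @param t_bm_um Membrane thickness (um), >= 0.
#' @param E_bm_kPa Membrane modulus (kPa).
#' @param E_core_kPa Core modulus (kPa).
#' @param thin_shell If `TRUE`, use the thin-shell approximation
#'   phi ~ 4 t / d instead of the exact annulus fraction (for comparison
#'   only; the exact form is the default).
#' @return Fiber modulus in kPa.
#' @export
shell_fiber_modulus <- function(diameter_um, t_bm_um, E_bm_kPa, E_core_kPa,
                                thin_shell = FALSE) {
  stopifnot(t_bm_um >= 0, E_bm_kPa > 0, E_core_kPa > 0)
  if (any(diameter_um <= 2 * t_bm_um)) {
    stop("fiber diameter must exceed twice the membrane thickness")
  }
  phi <- if (thin_shell) {
    4 * t_bm_um / diameter_um
  } else {
    1 - ((diameter_um - 2 * t_bm_um) / diameter_um)^2
  }
  phi * E_bm_kPa + (1 - phi) * E_core_kPa
}

#' ECM-fraction scaling with bundle size
#'
#' Perimeter-bound ECM scales with the bundle boundary while the bundle
#' area scales with fiber count, so the ECM area fraction is modeled as
#' f(n) = f_inf + c / sqrt(n), decreasing in the number of fibers. The
#' packaged default calibrates (f_inf, c) to the measured collagen-I
#' fractions of an 8-fiber (5.3%) and a 25-fiber (3.4%) bundle.
#'
#' @param f_inf Asymptotic ECM fraction for very large bundles.
#' @param c Boundary-scaling coefficient (fraction * sqrt(fibers)).
#' @return An object of class `ecm_scaling_params`.
#' @export
ecm_scaling_params <- function(f_inf = NULL, c = NULL) {
  if (is.null(f_inf) || is.null(c)) {
    cal <- calibrate_ecm_scaling(n = c(8L, 25L), f = c(0.053, 0.034))
    if (is.null(f_inf)) f_inf <- cal$f_inf
    if (is.null(c)) c <- cal$c
  }
  stopifnot(f_inf >= 0, c >= 0)
  structure(list(f_inf = f_inf, c = c), class = "ecm_scaling_params")
}

#' Calibrate the ECM scaling law to two measured bundles
#'
#' Solves f_i = f_inf + c / sqrt(n_i) for the two parameters from two
#' (fiber count, ECM fraction) observations.
#'
#' @param n Integer vector of two fiber counts.
#' @param f Numeric vector of two ECM fractions.
#' @return List with `f_inf` and `c`.
#' @export
calibrate_ecm_scaling <- function(n, f) {
  stopifnot(length(n) == 2L, length(f) == 2L, all(n >= 1), all(f >= 0))
  s <- 1 / sqrt(n)
  c_hat <- (f[1L] - f[2L]) / (s[1L] - s[2L])
  list(f_inf = f[2L] - c_hat * s[2L], c = c_hat)
}

#' ECM fraction of a bundle of n fibers
#'
#' @param n_fibers Number of fibers, >= 1.
#' @param params An [ecm_scaling_params()].
#' @return ECM fraction, clipped to `[0, 1]`.
#' @export
ecm_fraction <- function(n_fibers, params = ecm_scaling_params()) {
  if (any(n_fibers < 1)) stop("n_fibers must be >= 1")
  pmin(1, pmax(0, params$f_inf + params$c / sqrt(n_fibers)))
}

#' Predicted bundle modulus from size and composition
#'
#' Composes the sub-models: the ECM fraction comes from the size-scaling
#' law (or is supplied directly as a measurement), the fiber-phase modulus
#' from the basement-membrane shell model (or the homogeneous fiber
#' modulus when no mean fiber diameter is given), then the rule of
#' mixtures combines the two phases.
#'
#' @param n_fibers Number of fibers in the bundle (used by the scaling law
#'   when `f_ECM` is not supplied).
#' @param mean_fiber_diameter_um Mean fiber diameter (um); when given, the
#'   fiber phase uses [shell_fiber_modulus()], otherwise `E_fiber_kPa`.
#' @param comp A [composite_params()].
#' @param scaling An [ecm_scaling_params()].
#' @param f_ECM Directly measured ECM fraction; overrides the scaling law.
#' @return Bundle modulus in kPa (unrounded).
#' @export
predict_bundle_modulus <- function(n_fibers = NULL,
                                   mean_fiber_diameter_um = NULL,
                                   comp = composite_params(),
                                   scaling = ecm_scaling_params(),
                                   f_ECM = NULL) {
  if (is.null(f_ECM)) {
    if (is.null(n_fibers)) stop("supply either f_ECM or n_fibers")
    f_ECM <- ecm_fraction(n_fibers, scaling)
  }
  E_fib <- if (is.null(mean_fiber_diameter_um)) {
    comp$E_fiber_kPa
  } else {
    shell_fiber_modulus(mean_fiber_diameter_um, comp$t_bm_um,
                        comp$E_bm_kPa, comp$E_core_kPa)
  }
  rule_of_mixtures(f_ECM, comp$E_ECM_kPa, E_fib)
}
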