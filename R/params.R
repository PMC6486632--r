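#' Binding-isotherm parameters
#'
#' Parameters of the hyperbolic binding isotherm used to quantify band-shift
#' (EMSA) titrations: percent bound = bmax * \[P\] / (kd_app + \[P\]).
#'
#' @param kd_app Apparent dissociation constant of the protein-RNA complex
#'   (uM, > 0).
#' @param bmax Maximal percent bound. Fixed at 100 by default because the
#'   densitometric signal is normalised to total RNA; must be in (0, 100].
#' @return An object of class `binding_params`.
#' @export
#' @examples
#' binding_params(kd_app = 1.39)
binding_params <- function(kd_app, bmax = 100) {
  stopifnot(is.numeric(kd_app), length(kd_app) == 1L,
            is.numeric(bmax), length(bmax) == 1L)
  if (!is.finite(kd_app) || kd_app <= 0)
    stop("`kd_app` must be a finite positive concentration (uM)", call. = FALSE)
  if (!is.finite(bmax) || bmax <= 0 || bmax > 100)
    stop("`bmax` must lie in (0, 100] percent", call. = FALSE)
  structure(list(kd_app = kd_app, bmax = bmax), class = "binding_params")
}

#' Inhibition-curve parameters
#'
#' @param ic50 Inhibitor (RNA) concentration at half-maximal activity
#'   (uM, > 0).
#' @return An object of class `inhibition_params`.
#' @export
inhibition_params <- function(ic50) {
  stopifnot(is.numeric(ic50), length(ic50) == 1L)
  if (!is.finite(ic50) || ic50 <= 0)
    stop("`ic50` must be a finite positive concentration (uM)", call. = FALSE)
  structure(list(ic50 = ic50), class = "inhibition_params")
}

#' Kinetic parameters of the inhibition rate laws
#'
#' Parameter set shared by the Michaelis-Menten, substrate-inhibition and
#' hyperbolic competitive inhibition rate laws. All concentrations are in uM;
#' velocities carry arbitrary (absorbance-based) units, so only ratios of
#' velocities and the concentration-valued constants are meaningful.
#'
#' @param vmax Maximal velocity (arbitrary units, > 0).
#' @param km Michaelis constant of the varied substrate (uM, > 0).
#' @param ki_thf Substrate-inhibition constant for the folate substrate
#'   (uM, > 0), or `NULL` when the rate law carries no substrate inhibition.
#' @param ki Inhibitor (RNA) dissociation constant from the free enzyme
#'   (uM, > 0), or `NULL`.
#' @param alpha Dimensionless factor by which the inhibitor constant changes
#'   when substrate is bound (> 0), or `NULL`. `alpha = 1` means the
#'   inhibitor does not perturb substrate affinity; the pure-competitive
#'   limit (`alpha` infinite) is expressed through [velocity_variant()]
#'   rather than a numeric infinity.
#' @return An object of class `kinetic_params`.
#' @export
#' @examples
#' kinetic_params(vmax = 1, km = 50, ki_thf = 200, ki = 0.031, alpha = 18.8)
kinetic_params <- function(vmax, km, ki_thf = NULL, ki = NULL, alpha = NULL) {
  chk <- function(x, nm) {
    if (is.null(x)) return(invisible(NULL))
    stopifnot(is.numeric(x), length(x) == 1L)
    if (!is.finite(x) || x <= 0)
      stop(sprintf("`%s` must be finite and strictly positive", nm),
           call. = FALSE)
  }
  chk(vmax, "vmax"); chk(km, "km"); chk(ki_thf, "ki_thf")
  chk(ki, "ki"); chk(alpha, "alpha")
  structure(list(vmax = vmax, km = km, ki_thf = ki_thf,
                 ki = ki, alpha = alpha),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (uM; velocity in arbitrary units):\n")
  for (nm in names(x))
    if (!is.null(x[[nm]])) cat(sprintf("  %-7s %g\n", nm, x[[nm]]))
  invisible(x)
}

# shared argument checks -------------------------------------------------

check_nonneg <- function(x, nm) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stop(sprintf("`%s` must be non-negative and numeric", nm), call. = FALSE)
  invisible(x)
}

require_param <- function(params, fields, fn) {
  missing <- fields[vapply(params[fields], is.null, logical(1))]
  if (length(missing))
    stop(sprintf("%s() requires kinetic parameter(s): %s",
                 fn, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(params)
}
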