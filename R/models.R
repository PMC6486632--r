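#' Fraction of RNA bound in an EMSA titration
#'
#' Hyperbolic single-site binding isotherm,
#' \deqn{\%bound = B_{max} [P] / (K_d + [P]),}
#' used to estimate apparent dissociation constants from band-shift
#' densitometry. Strictly increasing in protein concentration and saturating
#' at `bmax`.
#'
#' @param p_conc Protein concentration(s), uM, >= 0.
#' @param params A [binding_params()] object.
#' @return Percent bound, same length as `p_conc`.
#' @export
#' @examples
#' fraction_bound(9.6, binding_params(kd_app = 1.39))
fraction_bound <- function(p_conc, params) {
  stopifnot(inherits(params, "binding_params"))
  check_nonneg(p_conc, "p_conc")
  params$bmax * p_conc / (params$kd_app + p_conc)
}

#' Residual activity as a function of inhibitor concentration
#'
#' \deqn{\%activity = 100 (1 - [I]/([I] + IC_{50})),}
#' the empirical inhibition curve fitted to percent-activity measurements at
#' fixed substrate concentrations while the RNA concentration is varied.
#' Strictly decreasing in `i_conc` and tending to zero at saturating
#' inhibitor.
#'
#' @param i_conc Inhibitor (RNA) concentration(s), uM, >= 0.
#' @param params An [inhibition_params()] object.
#' @return Percent activity, same length as `i_conc`.
#' @export
percent_activity <- function(i_conc, params) {
  stopifnot(inherits(params, "inhibition_params"))
  check_nonneg(i_conc, "i_conc")
  100 * (1 - i_conc / (i_conc + params$ic50))
}

# substrate-inhibition multiplier on the S term: 1 + S/KiTHF (1 when absent)
si_factor <- function(s, ki_thf) {
  if (is.null(ki_thf)) rep(1, length(s)) else 1 + s / ki_thf
}

#' Initial velocity with folate substrate inhibition
#'
#' Modified Michaelis-Menten rate law with a non-productive second
#' substrate-binding event:
#' \deqn{v = V_{max} S / (K_m + S (1 + S/K_{i,THF})).}
#' The velocity has a unique interior maximum at
#' \eqn{S^* = \sqrt{K_m K_{i,THF}}}, the changepoint used by the
#' substrate-inhibition exclusion diagnostic.
#'
#' @param thf Substrate (THF) concentration(s), uM, >= 0.
#' @param params A [kinetic_params()] object with `ki_thf` present.
#' @return Velocity (arbitrary units), same length as `thf`.
#' @export
velocity_substrate_inhibition <- function(thf, params) {
  stopifnot(inherits(params, "kinetic_params"))
  require_param(params, c("vmax", "km", "ki_thf"),
                "velocity_substrate_inhibition")
  check_nonneg(thf, "thf")
  params$vmax * thf / (params$km + thf * (1 + thf / params$ki_thf))
}

#' Initial velocity under hyperbolic (partial) competitive inhibition
#'
#' Rate law combining folate substrate inhibition with hyperbolic
#' competitive inhibition by RNA:
#' \deqn{v = V_{max} S \Big/ \Big(K_m \frac{1 + I/K_i}{1 + I/(\alpha K_i)}
#'   + S (1 + S/K_{i,THF})\Big).}
#' The inhibitor multiplies the effective Michaelis constant by a factor that
#' saturates at \eqn{\alpha} as \eqn{I \to \infty}, so the limiting velocity
#' at infinite inhibitor is nonzero (see [limiting_velocity()]). Reduces
#' exactly to [velocity_substrate_inhibition()] at `i_conc = 0` or
#' `alpha = 1`.
#'
#' @param thf Substrate (THF) concentration(s), uM, >= 0.
#' @param i_conc Inhibitor (RNA) concentration(s), uM, >= 0. Recycled
#'   against `thf`.
#' @param params A [kinetic_params()] object with `ki_thf`, `ki` and `alpha`
#'   present.
#' @return Velocity (arbitrary units).
#' @export
velocity_hyperbolic_competitive <- function(thf, i_conc, params) {
  stopifnot(inherits(params, "kinetic_params"))
  require_param(params, c("vmax", "km", "ki_thf", "ki", "alpha"),
                "velocity_hyperbolic_competitive")
  check_nonneg(thf, "thf"); check_nonneg(i_conc, "i_conc")
  kmf <- (1 + i_conc / params$ki) / (1 + i_conc / (params$alpha * params$ki))
  params$vmax * thf /
    (params$km * kmf + thf * (1 + thf / params$ki_thf))
}

#' Textbook rate-law variants used as alternative hypotheses
#'
#' Standard inhibition rate laws needed for model discrimination against the
#' hyperbolic competitive law:
#' \describe{
#'   \item{`michaelis_menten`}{\eqn{v = V_{max} S/(K_m + S)}; the inhibitor
#'     concentration is ignored.}
#'   \item{`pure_competitive`}{\eqn{v = V_{max} S/(K_m (1 + I/K_i) +
#'     S (1 + S/K_{i,THF}))}; the \eqn{\alpha \to \infty} limit of the
#'     hyperbolic law. The substrate-inhibition term is retained when
#'     `ki_thf` is present and dropped otherwise.}
#'   \item{`pure_mixed`}{\eqn{v = V_{max} S/(K_m (1 + I/K_i) +
#'     S (1 + S/K_{i,THF} + I/(\alpha K_i)))}; slope factor \eqn{1 + I/K_i}
#'     and intercept factor \eqn{1 + I/(\alpha K_i)}, both linear in I. With
#'     `alpha = 1` this is the noncompetitive limit, in which the apparent
#'     Vmax is halved at `i_conc = ki`.}
#' }
#'
#' @param s Substrate concentration(s), uM, >= 0.
#' @param i_conc Inhibitor concentration(s), uM, >= 0.
#' @param params A [kinetic_params()] object carrying the constants the
#'   chosen variant requires.
#' @param variant One of `"michaelis_menten"`, `"pure_competitive"`,
#'   `"pure_mixed"`.
#' @return Velocity (arbitrary units).
#' @export
velocity_variant <- function(s, i_conc, params,
                             variant = c("pure_competitive", "pure_mixed",
                                         "michaelis_menten")) {
  stopifnot(inherits(params, "kinetic_params"))
  variant <- match.arg(variant)
  check_nonneg(s, "s"); check_nonneg(i_conc, "i_conc")
  switch(variant,
    michaelis_menten = {
      require_param(params, c("vmax", "km"), "velocity_variant")
      params$vmax * s / (params$km + s)
    },
    pure_competitive = {
      require_param(params, c("vmax", "km", "ki"), "velocity_variant")
      params$vmax * s /
        (params$km * (1 + i_conc / params$ki) + s * si_factor(s, params$ki_thf))
    },
    pure_mixed = {
      require_param(params, c("vmax", "km", "ki", "alpha"), "velocity_variant")
      params$vmax * s /
        (params$km * (1 + i_conc / params$ki) +
           s * (si_factor(s, params$ki_thf) +
                  i_conc / (params$alpha * params$ki)))
    }
  )
}

#' Limiting velocity at saturating inhibitor
#'
#' The infinite-inhibitor limit of the hyperbolic competitive rate law,
#' \deqn{v_\infty = V_{max} S / (\alpha K_m + S (1 + S/K_{i,THF})),}
#' which is strictly positive for any `thf > 0`. A nonzero limiting velocity
#' is the kinetic signature distinguishing partial (hyperbolic) from pure
#' competitive inhibition.
#'
#' @inheritParams velocity_hyperbolic_competitive
#' @return Velocity (arbitrary units).
#' @export
limiting_velocity <- function(thf, params) {
  stopifnot(inherits(params, "kinetic_params"))
  require_param(params, c("vmax", "km", "ki_thf", "ki", "alpha"),
                "limiting_velocity")
  check_nonneg(thf, "thf")
  params$vmax * thf /
    (params$alpha * params$km + thf * (1 + thf / params$ki_thf))
}
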