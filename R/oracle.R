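#' Rapid-equilibrium binding scheme specification
#'
#' Specification of the equilibrium scheme behind the hyperbolic competitive
#' rate law. At saturating amino acid the enzyme E (already carrying the
#' amino acid) binds the folate substrate S (dissociation constant `ks`,
#' identified with Km under rapid equilibrium) and the RNA inhibitor R
#' (dissociation constant `ki`). Each bound ligand lowers the affinity for
#' the other by the same factor `alpha` (thermodynamic cycle closure), so
#' the ternary complex E.R.S forms with constants `alpha * ks` from E.R and
#' `alpha * ki` from E.S. Optionally a second, non-productive substrate
#' molecule binds either productive complex (E.S + S giving E.S.S and
#' E.R.S + S giving E.R.S.S, shared constant `ki_thf`), reproducing folate
#' substrate inhibition. Both E.S and E.R.S turn over with rate constant
#' `kcat`; the dead-end complexes do not.
#'
#' @param ks E + S dissociation constant, uM.
#' @param ki E + R dissociation constant, uM.
#' @param alpha Dimensionless cross-affinity factor, > 0.
#' @param kcat Turnover number (1/s) shared by E.S and E.R.S.
#' @param e_total,s_total,r_total Total enzyme, substrate and RNA
#'   concentrations, uM (`r_total` may be 0).
#' @param ki_thf Dead-end second-substrate dissociation constant, uM, or
#'   `NULL` for no substrate inhibition.
#' @return An object of class `scheme_spec`.
#' @export
scheme_spec <- function(ks, ki, alpha, kcat, e_total, s_total, r_total,
                        ki_thf = NULL) {
  pos <- function(x, nm, zero_ok = FALSE) {
    stopifnot(is.numeric(x), length(x) == 1L)
    if (!is.finite(x) || x < 0 || (!zero_ok && x == 0))
      stop(sprintf("`%s` must be %s", nm,
                   if (zero_ok) "finite and non-negative"
                   else "finite and strictly positive"), call. = FALSE)
  }
  pos(ks, "ks"); pos(ki, "ki"); pos(alpha, "alpha"); pos(kcat, "kcat")
  pos(e_total, "e_total"); pos(s_total, "s_total")
  pos(r_total, "r_total", zero_ok = TRUE)
  if (!is.null(ki_thf)) pos(ki_thf, "ki_thf")
  structure(list(ks = ks, ki = ki, alpha = alpha, kcat = kcat,
                 e_total = e_total, s_total = s_total, r_total = r_total,
                 ki_thf = ki_thf),
            class = "scheme_spec")
}

# species concentrations given free ligand concentrations (s, r).
# The dead-end second-substrate site is available on both productive
# complexes (E.S + S -> E.S.S and E.R.S + S -> E.R.S.S, same constant):
# this is the scheme whose rapid-equilibrium rate law is exactly the
# closed-form hyperbolic competitive law with the (1 + S/KiTHF) factor.
scheme_species <- function(spec, s, r) {
  dead_end <- !is.null(spec$ki_thf)
  es <- s / spec$ks
  er <- r / spec$ki
  ers <- s * r / (spec$alpha * spec$ks * spec$ki)
  ess <- if (dead_end) es * s / spec$ki_thf else 0
  erss <- if (dead_end) ers * s / spec$ki_thf else 0
  e <- spec$e_total / (1 + es + er + ers + ess + erss)
  list(
    E    = e,
    ES   = e * es,
    ER   = e * er,
    ERS  = e * ers,
    ESS  = e * ess,
    ERSS = e * erss,
    S    = s,
    R    = r
  )
}

# relative mass-balance residuals for the ligands with nonzero totals
scheme_residuals <- function(spec, s, r) {
  sp <- scheme_species(spec, s, r)
  s_calc <- sp$S + sp$ES + sp$ERS + 2 * sp$ESS + 2 * sp$ERSS
  r_calc <- sp$R + sp$ER + sp$ERS + sp$ERSS
  out <- s_calc / spec$s_total - 1
  if (spec$r_total > 0) out <- c(out, r_calc / spec$r_total - 1)
  out
}

#' Solve the rapid-equilibrium species balance
#'
#' Finds the unique non-negative equilibrium concentrations of all enzyme
#' species and free ligands satisfying the mass-action relations of the
#' scheme together with mass balance on enzyme, substrate and RNA. The root
#' is found by damped Newton iteration on the log-transformed free-ligand
#' concentrations (guaranteeing positivity) with deterministic
#' initialisation at the ligand totals; each mass balance of the returned
#' state holds to better than 1e-9 relative.
#'
#' @param spec A [scheme_spec()] object.
#' @param tol Convergence tolerance on the maximum relative mass-balance
#'   residual.
#' @param max_iter Iteration cap before a convergence error is raised.
#' @return An object of class `species_state`: a list of concentrations
#'   (`E`, `ES`, `ER`, `ERS`, `ESS`, `ERSS`, `S`, `R`, all uM) with attributes
#'   `residuals` and `iterations`.
#' @export
solve_equilibrium <- function(spec, tol = 1e-12, max_iter = 200L) {
  stopifnot(inherits(spec, "scheme_spec"))
  with_r <- spec$r_total > 0
  x <- log(if (with_r) c(spec$s_total, spec$r_total) else spec$s_total)
  fval <- function(x) {
    v <- exp(x)
    scheme_residuals(spec, v[1], if (with_r) v[2] else 0)
  }
  f <- fval(x)
  iter <- 0L
  while (max(abs(f)) > tol && iter < max_iter) {
    iter <- iter + 1L
    # numeric Jacobian in log space
    h <- 1e-7
    J <- vapply(seq_along(x), function(j) {
      xp <- x; xp[j] <- xp[j] + h
      (fval(xp) - f) / h
    }, numeric(length(f)))
    step <- tryCatch(-solve(J, f), error = function(e) -f)
    # damped update: halve the step until the residual norm decreases
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      fn <- fval(xn)
      if (sum(fn^2) < sum(f^2) || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    x <- xn; f <- fn
  }
  if (max(abs(f)) > 1e-9)
    stop(sprintf(paste0("equilibrium solver did not converge: max relative ",
                        "residual %.3e after %d iterations"),
                 max(abs(f)), iter), call. = FALSE)
  v <- exp(x)
  sp <- scheme_species(spec, v[1], if (with_r) v[2] else 0)
  structure(sp, class = "species_state",
            residuals = scheme_residuals(spec, sp$S, sp$R),
            iterations = iter)
}

#' Brute-force oracle velocity from the equilibrium scheme
#'
#' Turnover-weighted sum of the productive complexes,
#' \eqn{v = k_{cat}([E.S] + [E.R.S])}, computed from the numerically solved
#' species balance. In the excess-ligand regime (enzyme total far below both
#' Km and Ki, so totals equal free concentrations) this reproduces the
#' closed-form hyperbolic competitive rate law; with appreciable enzyme the
#' oracle quantifies the free-ligand depletion that the closed form ignores.
#'
#' @param spec A [scheme_spec()] object.
#' @param ... Passed to [solve_equilibrium()].
#' @return A single velocity (uM/s when `kcat` is in 1/s).
#' @export
oracle_velocity <- function(spec, ...) {
  st <- solve_equilibrium(spec, ...)
  spec$kcat * (st$ES + st$ERS)
}
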