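#' @importFrom stats approx lm pf quantile coef anova setNames median
#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

# ---- generic least-squares engine --------------------------------------

# Levenberg-Marquardt least squares on log-transformed parameters.
# Working in log space enforces positivity of every kinetic constant and
# makes the optimiser insensitive to the (arbitrary) concentration scale.
ls_fit_log <- function(resid_fn, start, model, data, refit = NULL) {
  pn <- names(start)
  stopifnot(length(pn) == length(start), all(start > 0))
  out <- suppressWarnings(minpack.lm::nls.lm(
    par = log(start),
    fn = function(lp) resid_fn(stats::setNames(exp(lp), pn)),
    control = minpack.lm::nls.lm.control(
      ftol = 1e-13, ptol = 1e-13, gtol = 0, maxiter = 1000,
      maxfev = 100000)))
  est <- stats::setNames(exp(out$par), pn)
  r <- resid_fn(est)
  rss <- sum(r^2)
  n <- length(r)
  converged <- out$info %in% c(1L, 2L, 3L, 4L, 6L, 7L, 8L)
  warnings <- character()
  if (!converged)
    warnings <- sprintf("optimizer did not converge (info %d): %s",
                        out$info, out$message)
  # delta-method standard errors from a numeric Jacobian in log space
  se <- rep(NA_real_, length(est))
  names(se) <- pn
  if (n > length(est)) {
    h <- 1e-6
    J <- vapply(seq_along(est), function(j) {
      ej <- est
      ej[j] <- ej[j] * exp(h)
      (resid_fn(ej) - r) / h
    }, numeric(n))
    sigma2 <- rss / (n - length(est))
    cov_log <- tryCatch(solve(crossprod(J)) * sigma2,
                        error = function(e) NULL)
    if (is.null(cov_log)) {
      warnings <- c(warnings, sprintf(
        "parameter(s) unidentifiable (singular information matrix): %s",
        paste(pn, collapse = ", ")))
    } else {
      se_log <- sqrt(pmax(diag(cov_log), 0))
      se <- est * se_log
      bad <- is.finite(se_log) & se_log > 100
      if (any(bad))
        warnings <- c(warnings, sprintf("parameter(s) unidentifiable: %s",
                                        paste(pn[bad], collapse = ", ")))
    }
  }
  fit_result(model = model, estimates = est, se = se, rss = rss, n = n,
             converged = converged, warnings = warnings, data = data,
             refit = refit)
}

#' Construct a fit-result object
#'
#' Container for any nonlinear least-squares fit in the package: point
#' estimates with delta-method standard errors, residual sum of squares,
#' convergence status, recorded warnings (identifiability, convergence),
#' the data fitted, and an optional bootstrap block added by
#' [bootstrap_ci()]. Non-convergence is always surfaced here as a flag,
#' never as an exception, so batch simulations can tally failures.
#'
#' @param model Model identifier string.
#' @param estimates Named numeric vector of parameter estimates.
#' @param se Named numeric vector of standard errors (NA when not
#'   estimable).
#' @param rss Residual sum of squares.
#' @param n Number of fitted points.
#' @param converged Logical convergence flag.
#' @param warnings Character vector of recorded warnings.
#' @param data The data the fit used.
#' @param refit Internal closure used for bootstrap refitting.
#' @param seed Seed used, if any.
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(model, estimates, se, rss, n, converged,
                       warnings = character(), data = NULL, refit = NULL,
                       seed = NA_integer_) {
  structure(list(model = model, estimates = estimates, se = se, rss = rss,
                 n = n, converged = converged, warnings = warnings,
                 data = data, refit = refit, seed = seed, boot = NULL),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Least-squares fit: %s (%d points, RSS %.4g, %s)\n",
              x$model, x$n, x$rss,
              if (x$converged) "converged" else "NOT CONVERGED"))
  tab <- data.frame(estimate = x$estimates, std.error = x$se)
  if (!is.null(x$boot)) {
    tab$ci_lower <- x$boot$ci[1, names(x$estimates)]
    tab$ci_upper <- x$boot$ci[2, names(x$estimates)]
  }
  print(tab, digits = 4)
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

# ---- binding isotherm ---------------------------------------------------

#' Fit the EMSA binding isotherm
#'
#' Estimates the apparent dissociation constant from a percent-bound versus
#' protein-concentration titration by least squares on the hyperbolic
#' isotherm. `bmax` is fixed at 100 percent by default (the densitometric
#' signal is normalised); set `fit_bmax = TRUE` to estimate it.
#'
#' @param data Data frame with columns `protein_conc_uM` and
#'   `percent_bound` (replicate rows allowed).
#' @param fit_bmax Estimate the maximal binding instead of fixing it.
#' @param bmax Fixed maximal binding (percent) when `fit_bmax = FALSE`.
#' @param start Optional named start values (`kd_app`, and `bmax` when
#'   fitted).
#' @return A [fit_result()] with estimate `kd_app` (uM).
#' @export
fit_binding_isotherm <- function(data, fit_bmax = FALSE, bmax = 100,
                                 start = NULL) {
  stopifnot(is.data.frame(data),
            all(c("protein_conc_uM", "percent_bound") %in% names(data)))
  p <- data$protein_conc_uM
  pb <- data$percent_bound
  check_nonneg(p, "protein_conc_uM")
  if (max(pb) < 0.05 * bmax)
    stop("identifiability: no binding signal (all percent-bound near zero)",
         call. = FALSE)
  if (min(pb[p > 0]) > 0.9 * bmax)
    stop("identifiability: titration is saturated at every concentration; ",
         "no information below the dissociation constant", call. = FALSE)
  warnings <- character()
  if (length(unique(p)) < 4L)
    warnings <- c(warnings,
                  "fewer than 4 distinct protein concentrations")
  if (is.null(start)) {
    half <- p[p > 0][which.min(abs(pb[p > 0] - bmax / 2))]
    start <- c(kd_app = unname(half))
    if (fit_bmax) start <- c(start, bmax = max(pb))
  }
  resid_fn <- function(th) {
    bm <- if (fit_bmax) th[["bmax"]] else bmax
    bm * p / (th[["kd_app"]] + p) - pb
  }
  fit <- ls_fit_log(resid_fn, start, model = "binding_isotherm", data = data,
                    refit = function(d, s = NULL)
                      fit_binding_isotherm(d, fit_bmax = fit_bmax,
                                           bmax = bmax, start = s))
  fit$warnings <- c(warnings, fit$warnings)
  fit
}

# ---- inhibition curve ---------------------------------------------------

#' Fit the IC50 inhibition curve
#'
#' Estimates the half-maximal inhibitory concentration from percent-activity
#' measurements over an inhibitor (RNA) titration, using
#' \eqn{\%activity = 100(1 - I/(I + IC_{50}))}. The fitted curve passes
#' through 100 percent at zero inhibitor by construction.
#'
#' @param data Data frame with columns `inhibitor_conc_uM` and
#'   `percent_activity`.
#' @param start Optional named start value (`ic50`).
#' @return A [fit_result()] with estimate `ic50` (uM).
#' @export
fit_inhibition_curve <- function(data, start = NULL) {
  stopifnot(is.data.frame(data),
            all(c("inhibitor_conc_uM", "percent_activity") %in% names(data)))
  i <- data$inhibitor_conc_uM
  a <- data$percent_activity
  check_nonneg(i, "inhibitor_conc_uM")
  if (diff(range(a)) < 5)
    stop("identifiability: no inhibition signal (activity range < 5 ",
         "percentage points)", call. = FALSE)
  if (is.null(start)) {
    ipos <- i[i > 0]
    s0 <- if (any(a[i > 0] < 75))
      ipos[which.min(abs(a[i > 0] - 50))]
    else exp(mean(log(ipos)))
    start <- c(ic50 = unname(s0))
  }
  resid_fn <- function(th) 100 * th[["ic50"]] / (i + th[["ic50"]]) - a
  ls_fit_log(resid_fn, start, model = "inhibition_curve", data = data,
             refit = function(d, s = NULL) fit_inhibition_curve(d, start = s))
}

# ---- single-curve saturation fits --------------------------------------

#' Fit a single substrate-saturation curve
#'
#' Least-squares estimation of (`vmax`, `km`) for the plain
#' Michaelis-Menten law, or (`vmax`, `km`, `ki_thf`) for the
#' substrate-inhibition law, from one velocity series. When the
#' substrate-inhibition model is requested but the design contains no point
#' above the fitted velocity optimum \eqn{\sqrt{K_m K_{i,THF}}}, an
#' identifiability warning is recorded in the result.
#'
#' @param series Data frame with columns `substrate_conc_uM` and `velocity`.
#' @param model `"michaelis_menten"` or `"substrate_inhibition"` (substrate inhibition).
#' @param start Optional named start values.
#' @return A [fit_result()].
#' @export
fit_saturation <- function(series, model = c("michaelis_menten", "substrate_inhibition"),
                           start = NULL) {
  model <- match.arg(model)
  stopifnot(is.data.frame(series),
            all(c("substrate_conc_uM", "velocity") %in% names(series)))
  s <- series$substrate_conc_uM
  v <- series$velocity
  check_nonneg(s, "substrate_conc_uM")
  if (is.null(start)) {
    vmax0 <- max(v)
    km0 <- s[which.min(abs(v - vmax0 / 2))]
    if (km0 <= 0) km0 <- stats::median(s[s > 0])
    start <- c(vmax = unname(vmax0), km = unname(km0))
    if (model == "substrate_inhibition") start <- c(start, ki_thf = max(s))
  }
  resid_fn <- if (model == "michaelis_menten") {
    function(th) th[["vmax"]] * s / (th[["km"]] + s) - v
  } else {
    function(th) th[["vmax"]] * s /
      (th[["km"]] + s * (1 + s / th[["ki_thf"]])) - v
  }
  fit <- ls_fit_log(resid_fn, start, model = model, data = series,
                    refit = function(d, st = NULL)
                      fit_saturation(d, model = model, start = st))
  if (model == "substrate_inhibition") {
    s_star <- sqrt(fit$estimates[["km"]] * fit$estimates[["ki_thf"]])
    if (max(s) < s_star)
      fit$warnings <- c(fit$warnings, sprintf(
        "identifiability: no substrate concentration above the fitted optimum %.3g uM; ki_thf is weakly determined",
        s_star))
  }
  fit
}

# ---- global multi-series fit -------------------------------------------

# fast internal predictor shared by the global models; `p` is a named list
# with vmax, km, ki (alpha, ki_thf optional / NULL)
predict_global <- function(model, s, i, p) {
  si <- si_factor(s, p$ki_thf)
  switch(model,
    eq_hyperbolic = {
      kmf <- (1 + i / p$ki) / (1 + i / (p$alpha * p$ki))
      p$vmax * s / (p$km * kmf + s * si)
    },
    pure_competitive =
      p$vmax * s / (p$km * (1 + i / p$ki) + s * si),
    pure_mixed =
      p$vmax * s / (p$km * (1 + i / p$ki) +
                      s * (si + i / (p$alpha * p$ki))),
    stop("unknown global model: ", model, call. = FALSE)
  )
}

as_velocity_table <- function(series_set) {
  if (is.data.frame(series_set)) series_set
  else do.call(rbind, series_set)
}

#' Global fit across inhibitor series
#'
#' Joint least-squares estimation over all velocity series, sharing
#' (`vmax`, `km`, and optionally `ki_thf`) across series and estimating the
#' inhibition constants (`ki`, and `alpha` where the model has one)
#' globally. Models:
#' \describe{
#'   \item{`eq_hyperbolic`}{hyperbolic (partial) competitive inhibition
#'     with substrate inhibition — the rate law of
#'     [velocity_hyperbolic_competitive()].}
#'   \item{`pure_competitive`}{its \eqn{\alpha \to \infty} limit.}
#'   \item{`pure_mixed`}{linear mixed inhibition (see
#'     [velocity_variant()]).}
#' }
#' Estimation is a deterministic multistart: `vmax`, `km` and `ki_thf`
#' start from data heuristics (maximum velocity, half-maximal substrate
#' concentration of the uninhibited series, largest substrate
#' concentration) while the optimiser is launched from a logarithmic grid
#' over `ki` (1e-3 to 10 uM) crossed with `alpha` in (3, 10, 60); the best
#' final optimum is returned. The inhibition constants are the parameters
#' with multiple least-squares basins, so the multistart guards against
#' the degenerate large-`alpha` basin that mimics pure competition.
#'
#' @param series_set A velocity table (data frame with columns
#'   `inhibitor_conc_uM`, `substrate_conc_uM`, `velocity`) or a list of
#'   per-series data frames.
#' @param model Global model to fit.
#' @param substrate_inhibition Include the `ki_thf` substrate-inhibition
#'   term (drop for substrates that show none, e.g. serine).
#' @param fix Named list of parameters to hold fixed (e.g.
#'   `list(alpha = 1)`); fixed parameters are removed from the optimisation.
#' @param start Optional named start values for the free parameters.
#' @return A [fit_result()].
#' @export
fit_global <- function(series_set,
                       model = c("eq_hyperbolic", "pure_competitive",
                                 "pure_mixed"),
                       substrate_inhibition = TRUE, fix = list(),
                       start = NULL) {
  model <- match.arg(model)
  tab <- as_velocity_table(series_set)
  stopifnot(all(c("inhibitor_conc_uM", "substrate_conc_uM", "velocity")
                %in% names(tab)))
  ilev <- sort(unique(tab$inhibitor_conc_uM))
  if (length(ilev) < 3L || min(ilev) > 0)
    stop("identifiability: a global fit needs at least 3 inhibitor levels ",
         "including an uninhibited (0) series", call. = FALSE)
  pn <- c("vmax", "km",
          if (substrate_inhibition) "ki_thf",
          "ki",
          if (model %in% c("eq_hyperbolic", "pure_mixed")) "alpha")
  fixed <- fix[names(fix) %in% pn]
  free <- setdiff(pn, names(fixed))
  s <- tab$substrate_conc_uM
  i <- tab$inhibitor_conc_uM
  v <- tab$velocity
  plist <- function(th) {
    full <- as.list(c(th[free], unlist(fixed)))
    if (!substrate_inhibition) full$ki_thf <- NULL
    full
  }
  resid_fn <- function(th) predict_global(model, s, i, plist(th)) - v
  refit_fn <- function(d, st = NULL)
    fit_global(d, model = model,
               substrate_inhibition = substrate_inhibition,
               fix = fix, start = st)
  if (!is.null(start)) {
    return(ls_fit_log(resid_fn, start[free], model = model, data = tab,
                      refit = refit_fn))
  }
  # deterministic multistart: heuristic (vmax, km, ki_thf) crossed with a
  # log grid over ki and alpha; the inhibition constants are the ones with
  # multiple least-squares basins (an alpha -> Inf, inflated-ki basin
  # mimicking pure competition exists for noisy data), so the best final
  # optimum over the grid is kept
  base <- tab[tab$inhibitor_conc_uM == 0, ]
  vmax0 <- max(v)
  km0 <- base$substrate_conc_uM[
    which.min(abs(base$velocity - max(base$velocity) / 2))]
  if (km0 <= 0) km0 <- stats::median(s[s > 0])
  heur <- c(vmax = unname(vmax0), km = unname(km0),
            ki_thf = max(s), ki = 0.1, alpha = 10)
  ki_grid <- if ("ki" %in% free) 10^c(-3, -1, 1) else NA
  a_grid <- if ("alpha" %in% free) c(3, 10, 60) else NA
  fit <- NULL
  for (ki0 in ki_grid) for (a0 in a_grid) {
    st <- heur
    if (!is.na(ki0)) st[["ki"]] <- ki0
    if (!is.na(a0)) st[["alpha"]] <- a0
    cand <- ls_fit_log(resid_fn, st[free], model = model, data = tab,
                       refit = refit_fn)
    if (is.null(fit) || cand$rss < fit$rss) fit <- cand
  }
  fit
}

# ---- bootstrap ----------------------------------------------------------

#' Bootstrap confidence intervals for a fit
#'
#' Case-resampling bootstrap, stratified by inhibitor series when the data
#' carry an `inhibitor_conc_uM` column (each series is resampled within
#' itself, preserving the design), with percentile intervals. Refits are
#' warm-started at the original estimates. Results are reproducible given
#' `seed`, which is mandatory.
#'
#' @param result A converged [fit_result()] carrying a refit closure.
#' @param data Data to resample; defaults to the data stored in `result`.
#' @param n_resamples Number of bootstrap resamples (a warning is recorded
#'   below 100).
#' @param seed Integer seed controlling the resampling.
#' @param level Confidence level for the percentile interval.
#' @return `result` with a `boot` element: percentile interval matrix
#'   (`ci`), the resampled estimates (`draws`), `n_resamples`, `n_failed`
#'   and the seed.
#' @export
bootstrap_ci <- function(result, data = NULL, n_resamples = 1000L, seed,
                         level = 0.95) {
  stopifnot(inherits(result, "fit_result"))
  if (!result$converged)
    stop("bootstrap requires a converged fit", call. = FALSE)
  if (is.null(result$refit))
    stop("fit result carries no refit closure", call. = FALSE)
  if (missing(seed)) stop("a seed is mandatory for the bootstrap",
                          call. = FALSE)
  if (is.null(data)) data <- result$data
  warnings <- character()
  if (n_resamples < 100L)
    warnings <- c(warnings,
                  "fewer than 100 resamples: intervals will be unstable")
  strata <- if ("inhibitor_conc_uM" %in% names(data))
    data$inhibitor_conc_uM else rep(1L, nrow(data))
  idx_by <- split(seq_len(nrow(data)), strata)
  pn <- names(result$estimates)
  draws <- matrix(NA_real_, nrow = n_resamples, ncol = length(pn),
                  dimnames = list(NULL, pn))
  n_failed <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(n_resamples)) {
      take <- unlist(lapply(idx_by, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]),
        use.names = FALSE)
      bfit <- tryCatch(result$refit(data[take, , drop = FALSE],
                                    result$estimates),
                       error = function(e) NULL)
      if (is.null(bfit) || !bfit$converged) {
        n_failed <- n_failed + 1L
      } else {
        draws[b, ] <- bfit$estimates[pn]
      }
    }
  })
  ok <- stats::complete.cases(draws)
  a <- (1 - level) / 2
  ci <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(a, 1 - a), names = FALSE)
  rownames(ci) <- c("lower", "upper")
  result$boot <- list(ci = ci, draws = draws[ok, , drop = FALSE],
                      n_resamples = n_resamples, n_failed = n_failed,
                      seed = seed, level = level)
  result$seed <- seed
  result$warnings <- c(result$warnings, warnings)
  result
}

# ---- model comparison ---------------------------------------------------

#' Corrected Akaike information criterion for a least-squares fit
#'
#' \eqn{AICc = n \log(RSS/n) + 2k + 2k(k+1)/(n-k-1)} with `k` the number of
#' mean (regression) parameters. Returns `Inf` when the small-sample
#' correction denominator is non-positive, i.e. the model is too rich for
#' the data.
#'
#' @param rss Residual sum of squares.
#' @param n Number of points.
#' @param k Number of fitted mean parameters.
#' @return The AICc value.
#' @export
aicc <- function(rss, n, k) {
  if (n - k - 1 <= 0) return(Inf)
  n * log(max(rss, .Machine$double.xmin) / n) + 2 * k +
    2 * k * (k + 1) / (n - k - 1)
}

f_test_nested <- function(rss_small, k_small, rss_big, k_big, n) {
  df1 <- k_big - k_small
  df2 <- n - k_big
  if (df1 <= 0 || df2 <= 0) return(c(F = NA_real_, p = NA_real_))
  if (rss_big <= 0)
    return(c(F = Inf, p = 0))
  f <- max(0, (rss_small - rss_big) / df1) / (rss_big / df2)
  c(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Compare competing model fits of the same data
#'
#' Ranks models fitted to identical data by AICc and runs the
#' extra-sum-of-squares F-test for every nested pair (models whose
#' parameter sets are strict subsets). The preferred model is the one with
#' the lowest AICc when it leads by more than 2 units; otherwise a tie is
#' reported.
#'
#' @param fits List of [fit_result()] objects fitted to the same data.
#' @return An object of class `model_comparison` with elements `table`
#'   (per-model k, RSS, AICc, delta), `nested_tests` and `preferred`.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "fit_result")))
  for (f in fits[-1])
    if (!identical(f$data, fits[[1]]$data))
      stop("all fits must share identical data", call. = FALSE)
  nms <- vapply(fits, `[[`, character(1), "model")
  if (anyDuplicated(nms))
    nms <- make.unique(nms)
  k <- vapply(fits, function(f) length(f$estimates), integer(1))
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  n <- fits[[1]]$n
  ic <- vapply(seq_along(fits), function(j) aicc(rss[j], n, k[j]), numeric(1))
  tab <- data.frame(model = nms, k = k, rss = rss, aicc = ic,
                    delta_aicc = ic - min(ic))
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL
  tests <- list()
  for (a in seq_along(fits)) for (b in seq_along(fits)) {
    pa <- names(fits[[a]]$estimates); pb <- names(fits[[b]]$estimates)
    if (length(pa) < length(pb) && all(pa %in% pb)) {
      ft <- f_test_nested(rss[a], k[a], rss[b], k[b], n)
      note <- if (rss[b] > rss[a] + 1e-12 * max(rss[a], 1))
        "nested RSS ordering violated (larger model fits worse)" else ""
      tests[[length(tests) + 1L]] <- data.frame(
        smaller = nms[a], larger = nms[b],
        F = ft[["F"]], p = ft[["p"]], note = note)
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(smaller = character(), larger = character(),
               F = numeric(), p = numeric(), note = character())
  preferred <- if (nrow(tab) > 1 && tab$delta_aicc[2] > 2)
    tab$model[1] else "tie"
  structure(list(table = tab, nested_tests = tests, preferred = preferred,
                 n = n),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison on", x$n, "points\n")
  print(x$table, digits = 4)
  if (nrow(x$nested_tests)) {
    cat("Nested extra-sum-of-squares F-tests:\n")
    print(x$nested_tests, digits = 4)
  }
  cat("Preferred:", x$preferred, "\n")
  invisible(x)
}
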