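#' Exclude the substrate-inhibition portion of a velocity series
#'
#' Removes points above the velocity optimum \eqn{S^* = \sqrt{K_m
#' K_{i,THF}}} of a previously fitted substrate-inhibition curve, the
#' natural changepoint beyond which velocities bend down and a
#' double-reciprocal transformation is no longer linear. Points exactly at
#' the optimum are kept. When the fit carries no `ki_thf` the series is
#' returned unchanged. Removing more than half of the distinct substrate
#' grid records an identifiability warning (attribute `warning`); fewer
#' than 3 surviving points is an error.
#'
#' @param series Data frame with columns `substrate_conc_uM` and
#'   `velocity`.
#' @param si_fit A converged [fit_result()] from
#'   `fit_saturation(model = "substrate_inhibition")` (or any fit whose
#'   estimates include `km` and `ki_thf`).
#' @return The filtered series with attribute `s_star` (and possibly
#'   `warning`).
#' @export
exclude_substrate_inhibition <- function(series, si_fit) {
  stopifnot(is.data.frame(series), inherits(si_fit, "fit_result"))
  if (!si_fit$converged)
    stop("substrate-inhibition fit did not converge; cannot locate the ",
         "velocity optimum", call. = FALSE)
  est <- si_fit$estimates
  if (!all(c("km", "ki_thf") %in% names(est))) {
    attr(series, "s_star") <- Inf
    return(series)
  }
  s_star <- sqrt(est[["km"]] * est[["ki_thf"]])
  keep <- series$substrate_conc_uM <= s_star * (1 + 1e-9)
  out <- series[keep, , drop = FALSE]
  n_all <- length(unique(series$substrate_conc_uM))
  n_keep <- length(unique(out$substrate_conc_uM))
  if (n_keep < 3L)
    stop(sprintf(paste0("fewer than 3 substrate concentrations survive the ",
                        "substrate-inhibition exclusion at S* = %.3g uM"),
                 s_star), call. = FALSE)
  attr(out, "s_star") <- unname(s_star)
  if (n_all - n_keep > n_all / 2)
    attr(out, "warning") <-
      "exclusion removed more than half the substrate grid"
  out
}

#' Double-reciprocal (Lineweaver-Burk) line fits
#'
#' Averages replicate velocities per (inhibitor, substrate) cell, then fits
#' an ordinary least-squares straight line to 1/v versus 1/\[S\] within each
#' inhibitor series. For noiseless Michaelis-Menten input the slope is
#' exactly Km/Vmax and the intercept 1/Vmax. Non-positive velocities cannot
#' be transformed and are dropped with a warning. When replicates are
#' present, slope/intercept standard errors are computed from the pooled
#' replicate coefficient of variation propagated through the line fit
#' (delta method); otherwise from the line's own residuals.
#'
#' @param series_set A velocity table (data frame) or list of per-series
#'   data frames, with columns `inhibitor_conc_uM`, `substrate_conc_uM`,
#'   `velocity` (typically after [exclude_substrate_inhibition()]).
#' @return A data frame of class `reciprocal_fits` with one row per
#'   inhibitor level: `inhibitor_conc_uM`, `slope`, `intercept`, their
#'   standard errors (`slope_se`, `intercept_se`), `r_squared`,
#'   `n_points`.
#' @export
double_reciprocal <- function(series_set) {
  tab <- as_velocity_table(series_set)
  stopifnot(all(c("inhibitor_conc_uM", "substrate_conc_uM", "velocity")
                %in% names(tab)))
  # average replicates per cell before transforming; keep per-cell spread
  agg <- stats::aggregate(velocity ~ inhibitor_conc_uM + substrate_conc_uM,
                          data = tab,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  agg <- cbind(agg[1:2], as.data.frame(agg$velocity))
  bad <- agg$mean <= 0 | agg$substrate_conc_uM <= 0
  if (any(bad)) {
    warning(sprintf("%d cell(s) with non-positive velocity or substrate ",
                    sum(bad)), "dropped from the reciprocal transformation",
            call. = FALSE)
    agg <- agg[!bad, , drop = FALSE]
  }
  # Pooled squared CV across all replicated cells. Under the constant-CV
  # error model of these assays this single scale, propagated through each
  # line fit, gives far steadier slope/intercept standard errors than the
  # 3-point residuals of an individual line.
  rep_df <- pmax(agg$n - 1L, 0L)
  pooled_cv2 <- if (sum(rep_df) > 0 && any(agg$sd > 0, na.rm = TRUE))
    sum(rep_df * (agg$sd / agg$mean)^2, na.rm = TRUE) / sum(rep_df)
  else NA_real_
  out <- lapply(split(agg, agg$inhibitor_conc_uM), function(d) {
    if (nrow(d) < 3L)
      stop("each reciprocal line needs at least 3 points", call. = FALSE)
    y <- 1 / d$mean
    x <- 1 / d$substrate_conc_uM
    fit <- stats::lm(y ~ x)
    # summary() warns on numerically perfect (noiseless) fits
    sm <- suppressWarnings(summary(fit))
    if (is.finite(pooled_cv2)) {
      # known-variance (sandwich) standard errors of the unweighted line:
      # var(1/vbar) ~ (cv^2 / n_rep) * (1/vbar)^2 by the delta method
      X <- cbind(1, x)
      A <- solve(crossprod(X)) %*% t(X)
      V <- diag((pooled_cv2 / d$n) * y^2, nrow = length(y))
      ses <- sqrt(diag(A %*% V %*% t(A)))
    } else {
      ses <- sm$coefficients[, 2]
    }
    data.frame(inhibitor_conc_uM = d$inhibitor_conc_uM[1],
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               slope_se = ses[2],
               intercept_se = ses[1],
               r_squared = sm$r.squared,
               n_points = nrow(d))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$inhibitor_conc_uM), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("reciprocal_fits", "data.frame")
  out
}

#' Slope and intercept replots against inhibitor concentration
#'
#' Extracts the classical replot tables from per-inhibitor reciprocal
#' lines: apparent Km/Vmax (slope) and 1/Vmax (intercept) as functions of
#' inhibitor concentration. Duplicate inhibitor levels are merged by
#' averaging with a note.
#'
#' @param fits A `reciprocal_fits` data frame from [double_reciprocal()].
#' @return A list of class `replot_tables` with data frames `slope` and
#'   `intercept`, each with columns `inhibitor_conc_uM` and `value`,
#'   ordered by inhibitor concentration.
#' @export
replot <- function(fits) {
  stopifnot(inherits(fits, "reciprocal_fits") || is.data.frame(fits))
  if (anyDuplicated(fits$inhibitor_conc_uM)) {
    message("duplicate inhibitor levels merged by averaging")
    fits <- stats::aggregate(
      cbind(slope, intercept, slope_se, intercept_se) ~ inhibitor_conc_uM,
      data = as.data.frame(fits), FUN = mean)
  }
  fits <- fits[order(fits$inhibitor_conc_uM), , drop = FALSE]
  structure(list(
    slope = data.frame(inhibitor_conc_uM = fits$inhibitor_conc_uM,
                       value = fits$slope, se = fits$slope_se),
    intercept = data.frame(inhibitor_conc_uM = fits$inhibitor_conc_uM,
                           value = fits$intercept, se = fits$intercept_se)),
    class = "replot_tables")
}

# ---- shape tests --------------------------------------------------------

# Nested-shape decision shared by both replots: the richer shape is called
# only when AICc (delta > 2) and the extra-sum-of-squares F-test (p < 0.05)
# agree; when both prefer the simpler shape it is called; a split verdict
# is "indeterminate". For nested least-squares fits both statistics are
# monotone in the RSS ratio, so disagreement is confined to a narrow band.
shape_verdict <- function(rss_simple, k_simple, rss_complex, k_complex, n,
                          simple_label, complex_label) {
  ft <- f_test_nested(rss_simple, k_simple, rss_complex, k_complex, n)
  d_aicc <- aicc(rss_complex, n, k_complex) - aicc(rss_simple, n, k_simple)
  f_says_complex <- is.finite(ft[["p"]]) && ft[["p"]] < 0.05
  aicc_says_complex <- d_aicc < -2
  shape <- if (f_says_complex && aicc_says_complex) complex_label
  else if (!f_says_complex && !aicc_says_complex) simple_label
  else "indeterminate"
  list(shape = shape, F = ft[["F"]], p = ft[["p"]], delta_aicc = d_aicc)
}

# Precision weights for the replot shape tests. The reciprocal-line
# estimates entering a replot have hugely unequal precision (velocities at
# high inhibitor are small, so their reciprocal-space estimates are noisy)
# and the noisiest points sit at the highest leverage, so unweighted shape
# tests are driven by them alone. The line fits supply standard errors;
# weighting by 1/se^2 is the corresponding generalized-least-squares test.
# Noiseless input yields (numerically) zero standard errors; equal weights
# are used then.
replot_weights <- function(tab) {
  if (!("se" %in% names(tab)) || anyNA(tab$se) ||
      max(tab$se) <= 1e-8 * max(abs(tab$value)))
    return(rep(1, nrow(tab)))
  se <- pmax(tab$se, 1e-8 * max(tab$se))
  1 / se^2
}

# affine vs saturating-hyperbola fit of the slope replot
slope_shape_test <- function(slope_tab) {
  x <- slope_tab$inhibitor_conc_uM
  y <- slope_tab$value
  n <- length(x)
  w <- replot_weights(slope_tab)
  sw <- sqrt(w)
  lin <- stats::lm(y ~ x, weights = w)
  rss_lin <- sum(w * stats::resid(lin)^2)
  # y = y0 + amp * I / (I + K): saturates at y0 + amp as I -> Inf
  hyp <- ls_fit_log(
    function(th) sw * (th[["y0"]] + th[["amp"]] * x / (x + th[["K"]]) - y),
    start = c(y0 = max(min(y), 1e-8 * max(y)),
              amp = max(diff(range(y)), 1e-6 * max(y)),
              K = max(stats::median(x[x > 0]), 1e-6)),
    model = "slope_hyperbola", data = slope_tab)
  v <- shape_verdict(rss_lin, 2L, hyp$rss, 3L, n, "linear", "hyperbolic")
  v$hyperbola <- hyp
  v$linear_fit <- lin
  v
}

# constant vs straight-line fit of the intercept replot
intercept_shape_test <- function(int_tab) {
  x <- int_tab$inhibitor_conc_uM
  y <- int_tab$value
  n <- length(x)
  w <- replot_weights(int_tab)
  lin <- stats::lm(y ~ x, weights = w)
  rss_lin <- sum(w * stats::resid(lin)^2)
  ybar <- sum(w * y) / sum(w)
  rss_const <- sum(w * (y - ybar)^2)
  v <- shape_verdict(rss_const, 1L, rss_lin, 2L, n, "flat", "linear")
  v$linear_fit <- lin
  v
}

#' Classify the inhibition mechanism from replot shapes
#'
#' Implements the replot-based inference chain: the slope replot is tested
#' for linear versus saturating-hyperbolic dependence on inhibitor
#' concentration, the intercept replot for flat versus linear, and the
#' shape pair is mapped to a mechanism:
#' \itemize{
#'   \item slope hyperbolic + intercept flat: `hyperbolic_competitive`
#'   \item slope linear + intercept flat: `pure_competitive`
#'   \item slope linear + intercept linear: `pure_mixed`
#'   \item anything else: `indeterminate`
#' }
#' Each shape call requires AICc (delta > 2) and the nested F-test
#' (p < 0.05) to agree; a split verdict yields an indeterminate shape. For
#' a hyperbolic slope replot the asymptotic slope is finite, so the
#' velocity at saturating inhibitor is nonzero: the ratio of limiting to
#' uninhibited velocity, evaluated at the apparent uninhibited Km (where
#' the ratio is \eqn{2/(1 + slope_\infty/slope_0)}), is reported, together
#' with whether it excludes zero (it does exactly when the hyperbolic shape
#' is supported). For a linear slope replot the ratio is 0.
#'
#' @param replots A `replot_tables` object from [replot()].
#' @return An object of class `mechanism_call`: `label`, `slope_shape`,
#'   `intercept_shape`, `limiting_velocity_ratio`,
#'   `limiting_excludes_zero`, and `statistics` (per-replot F, p and
#'   delta-AICc).
#' @export
classify_mechanism <- function(replots) {
  stopifnot(inherits(replots, "replot_tables"))
  n <- nrow(replots$slope)
  if (n < 4L)
    return(structure(list(label = "indeterminate",
                          slope_shape = NA_character_,
                          intercept_shape = NA_character_,
                          limiting_velocity_ratio = NA_real_,
                          limiting_excludes_zero = NA,
                          statistics = NULL,
                          reason = "fewer than 4 inhibitor levels"),
                     class = "mechanism_call"))
  ss <- slope_shape_test(replots$slope)
  is_ <- intercept_shape_test(replots$intercept)
  label <- if (ss$shape == "hyperbolic" && is_$shape == "flat")
    "hyperbolic_competitive"
  else if (ss$shape == "linear" && is_$shape == "flat")
    "pure_competitive"
  else if (ss$shape == "linear" && is_$shape == "linear")
    "pure_mixed"
  else "indeterminate"
  if (ss$shape == "hyperbolic") {
    est <- ss$hyperbola$estimates
    slope0 <- est[["y0"]]
    slope_inf <- est[["y0"]] + est[["amp"]]
    lv_ratio <- 2 / (1 + slope_inf / slope0)
  } else {
    lv_ratio <- 0
  }
  structure(list(
    label = label,
    slope_shape = ss$shape,
    intercept_shape = is_$shape,
    limiting_velocity_ratio = unname(lv_ratio),
    limiting_excludes_zero = ss$shape == "hyperbolic",
    statistics = data.frame(
      replot = c("slope", "intercept"),
      F = c(ss$F, is_$F), p = c(ss$p, is_$p),
      delta_aicc = c(ss$delta_aicc, is_$delta_aicc)),
    reason = NULL),
    class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("Mechanism call:", x$label, "\n")
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  if (!is.na(x$slope_shape))
    cat(sprintf("  slope replot: %s; intercept replot: %s\n",
                x$slope_shape, x$intercept_shape))
  if (!is.na(x$limiting_velocity_ratio))
    cat(sprintf("  limiting/uninhibited velocity at apparent Km: %.3f (%s)\n",
                x$limiting_velocity_ratio,
                if (isTRUE(x$limiting_excludes_zero)) "excludes zero"
                else "consistent with zero"))
  if (!is.null(x$statistics)) print(x$statistics, digits = 3)
  invisible(x)
}

#' Run the full mechanism-diagnostic chain on a velocity dataset
#'
#' Convenience wrapper: fits the substrate-inhibition law to the
#' uninhibited series to locate the velocity optimum, excludes the
#' substrate-inhibition portion of every series at that optimum, builds the
#' double-reciprocal lines and replots, and classifies the mechanism.
#'
#' @param series_set Velocity table or list of per-series data frames.
#' @param substrate_inhibition Whether the varied substrate shows substrate
#'   inhibition (exclusion is skipped when `FALSE`, as for serine).
#' @return A `mechanism_call` with attributes `reciprocal_fits`, `replots`
#'   and `s_star`.
#' @export
diagnose_mechanism <- function(series_set, substrate_inhibition = TRUE) {
  tab <- as_velocity_table(series_set)
  if (substrate_inhibition) {
    base <- tab[tab$inhibitor_conc_uM == 0, , drop = FALSE]
    si_fit <- fit_saturation(base, model = "substrate_inhibition")
    tab <- do.call(rbind, lapply(split(tab, tab$inhibitor_conc_uM),
                                 exclude_substrate_inhibition,
                                 si_fit = si_fit))
    s_star <- sqrt(si_fit$estimates[["km"]] * si_fit$estimates[["ki_thf"]])
  } else {
    s_star <- Inf
  }
  rf <- double_reciprocal(tab)
  rp <- replot(rf)
  call <- classify_mechanism(rp)
  attr(call, "reciprocal_fits") <- rf
  attr(call, "replots") <- rp
  attr(call, "s_star") <- s_star
  call
}
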