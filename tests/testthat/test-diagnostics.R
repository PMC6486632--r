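test_that("substrate-inhibition exclusion cuts at the velocity optimum", {
  si_fit <- fit_result("substrate_inhibition",
                       estimates = c(vmax = 1, km = 50, ki_thf = 200),
                       se = c(NA, NA, NA), rss = 0, n = 18, converged = TRUE)
  grid <- c(10, 25, 50, 100, 244, 488)
  series <- data.frame(substrate_conc_uM = grid, velocity = 1)
  out <- exclude_substrate_inhibition(series, si_fit)
  expect_equal(out$substrate_conc_uM, c(10, 25, 50, 100))  # S* = 100 kept
  expect_equal(attr(out, "s_star"), 100)
  # no substrate-inhibition constant: series unchanged
  mm_fit <- fit_result("michaelis_menten", c(vmax = 1, km = 50),
                       c(NA, NA), 0, 6, TRUE)
  expect_equal(exclude_substrate_inhibition(series, mm_fit)$substrate_conc_uM,
               grid)
  # all points below the optimum: unchanged
  low <- data.frame(substrate_conc_uM = c(10, 25, 50), velocity = 1)
  expect_equal(exclude_substrate_inhibition(low, si_fit)$substrate_conc_uM,
               c(10, 25, 50))
  # too few survivors is an error
  high <- data.frame(substrate_conc_uM = c(150, 244, 488), velocity = 1)
  expect_error(exclude_substrate_inhibition(high, si_fit), "fewer than 3")
})

test_that("reciprocal lines are exact for noiseless Michaelis-Menten data", {
  s <- c(10, 25, 50, 100, 200)
  tab <- data.frame(inhibitor_conc_uM = 0, substrate_conc_uM = s,
                    velocity = 1 * s / (50 + s))
  rf <- double_reciprocal(tab)
  expect_equal(rf$slope, 50, tolerance = 1e-9)
  expect_equal(rf$intercept, 1, tolerance = 1e-9)
  # replicate rows averaged: same line as single-replicate input
  tab3 <- tab[rep(1:5, each = 3), ]
  rf3 <- double_reciprocal(tab3)
  expect_equal(rf3$slope, rf$slope)
  expect_equal(rf3$intercept, rf$intercept)
})

test_that("retained substrate-inhibition curvature offsets intercepts evenly", {
  # the (1 + S/ki_thf) term kept below the optimum biases every
  # reciprocal-line intercept upward by the same bounded amount, because
  # all series share the retained substrate grid: the intercept replot
  # stays flat, which is what the mechanism call relies on
  d <- noiseless("thf_trna_matrix")
  tab <- generate_velocity_matrix(d, truth_hyperbolic())
  base <- tab[tab$inhibitor_conc_uM == 0, ]
  si_fit <- fit_saturation(base, "substrate_inhibition")
  kept_all <- lapply(split(tab, tab$inhibitor_conc_uM),
                     exclude_substrate_inhibition, si_fit = si_fit)
  rf <- double_reciprocal(do.call(rbind, kept_all))
  s_max <- max(kept_all[[1]]$substrate_conc_uM)
  expect_true(all(rf$intercept > 1))                    # 1/vmax = 1
  expect_true(all(rf$intercept < 1 + s_max / 200))      # bounded by S/ki_thf
  expect_lt(diff(range(rf$intercept)) / mean(rf$intercept), 1e-6)
  # the bias vanishes as substrate inhibition weakens
  tr_weak <- kinetic_params(1, 50, ki_thf = 5e4, ki = 0.031, alpha = 18.8)
  tab_w <- generate_velocity_matrix(d, tr_weak)
  rf_w <- double_reciprocal(tab_w[tab_w$inhibitor_conc_uM == 0, ])
  expect_equal(rf_w$intercept, 1, tolerance = 5e-3)
})

test_that("replots are keyed and ordered by inhibitor concentration", {
  d <- noiseless("thf_trna_matrix")
  tab <- generate_velocity_matrix(d, truth_hyperbolic())
  mc <- diagnose_mechanism(tab)
  rp <- attr(mc, "replots")
  expect_equal(nrow(rp$slope), 6)
  expect_equal(rp$slope$inhibitor_conc_uM,
               sort(unique(tab$inhibitor_conc_uM)))
  # slopes grow with inhibitor, as the apparent Km rises
  expect_true(all(diff(rp$slope$value) > 0))
})

test_that("pure-competitive slopes are affine in inhibitor concentration", {
  d <- noiseless("thf_trna_matrix")
  tab <- generate_velocity_matrix(d, truth_competitive(),
                                  model = "pure_competitive")
  mc <- diagnose_mechanism(tab)
  rp <- attr(mc, "replots")
  lf <- lm(value ~ inhibitor_conc_uM, data = rp$slope)
  expect_gt(suppressWarnings(summary(lf)$r.squared), 1 - 1e-6)
  expect_equal(mc$label, "pure_competitive")
  expect_equal(mc$limiting_velocity_ratio, 0)
})

test_that("hyperbolic slopes extrapolate to the alpha-fold Km ceiling", {
  d <- noiseless("thf_trna_matrix")
  tab <- generate_velocity_matrix(d, truth_hyperbolic())
  mc <- diagnose_mechanism(tab)
  expect_equal(mc$label, "hyperbolic_competitive")
  expect_true(mc$limiting_excludes_zero)
  st <- rnakin:::slope_shape_test(attr(mc, "replots")$slope)
  asym <- st$hyperbola$estimates[["y0"]] + st$hyperbola$estimates[["amp"]]
  # true asymptotic slope is alpha * km / vmax = 940
  expect_equal(asym, 18.8 * 50 / 1, tolerance = 0.02)
})

test_that("the serine-varied mixed-inhibition layout is called pure mixed", {
  d <- noiseless("serine_trna_matrix")
  tab <- generate_velocity_matrix(d, truth_mixed_serine(),
                                  model = "pure_mixed")
  mc <- diagnose_mechanism(tab, substrate_inhibition = FALSE)
  expect_equal(mc$label, "pure_mixed")
  expect_equal(mc$intercept_shape, "linear")
})

test_that("too few inhibitor levels yield an indeterminate call", {
  d <- noiseless("thf_trna_matrix")
  tab <- generate_velocity_matrix(d, truth_hyperbolic())
  sub <- tab[tab$inhibitor_conc_uM %in% c(0, 0.44, 1.77), ]
  mc <- diagnose_mechanism(sub)
  expect_equal(mc$label, "indeterminate")
  expect_match(mc$reason, "fewer than 4")
})

test_that("classification recovers the generating mechanism under noise", {
  d <- builtin_design("thf_trna_matrix")
  n_h <- sum(vapply(1:25, function(s) {
    tab <- quiet(generate_velocity_matrix(d, truth_hyperbolic(), seed = s))
    diagnose_mechanism(tab)$label == "hyperbolic_competitive"
  }, logical(1)))
  n_c <- sum(vapply(1:25, function(s) {
    tab <- quiet(generate_velocity_matrix(d, truth_competitive(),
                                          model = "pure_competitive",
                                          seed = 200 + s))
    diagnose_mechanism(tab)$label == "pure_competitive"
  }, logical(1)))
  expect_gte(n_h, 20)
  expect_gte(n_c, 20)
})
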