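test_that("noiseless titrations recover the reported dissociation constants", {
  d <- noiseless("emsa_titration")
  for (kd in c(1.39, 3.0)) {
    dat <- generate_binding_dataset(d, binding_params(kd))
    fit <- quiet(fit_binding_isotherm(dat))
    expect_true(fit$converged)
    expect_equal(fit$estimates[["kd_app"]], kd, tolerance = 1e-6)
  }
})

test_that("two exact points on a hyperbola are interpolated exactly", {
  dat <- data.frame(protein_conc_uM = c(1, 4),
                    percent_bound = 100 * c(1, 4) / (2.5 + c(1, 4)))
  fit <- quiet(fit_binding_isotherm(dat))
  expect_equal(fit$estimates[["kd_app"]], 2.5, tolerance = 1e-8)
  expect_match(paste(fit$warnings, collapse = " "), "fewer than 4")
})

test_that("degenerate binding data raise identifiability errors", {
  p <- 0.3 * 2^(0:5)
  expect_error(fit_binding_isotherm(
    data.frame(protein_conc_uM = p, percent_bound = rep(0.5, 6))),
    "identifiability")
  expect_error(fit_binding_isotherm(
    data.frame(protein_conc_uM = p, percent_bound = rep(99, 6))),
    "identifiability")
})

test_that("noiseless inhibition curves recover forward and reverse IC50s", {
  d <- noiseless("ic50_curve")
  for (ic in c(0.033, 4)) {
    dat <- generate_inhibition_curve(d, inhibition_params(ic))
    fit <- fit_inhibition_curve(dat)
    expect_equal(fit$estimates[["ic50"]], ic, tolerance = 1e-6)
    # the fitted curve passes through 100 % at zero inhibitor
    expect_equal(percent_activity(0, inhibition_params(fit$estimates[["ic50"]])),
                 100)
  }
  expect_error(fit_inhibition_curve(
    data.frame(inhibitor_conc_uM = 10^(-3:1),
               percent_activity = rep(99, 5))),
    "identifiability")
})

test_that("saturation fits recover generating parameters without noise", {
  d <- noiseless("thf_trna_matrix")
  tr <- truth_hyperbolic()
  tab <- generate_velocity_matrix(d, tr)
  base <- tab[tab$inhibitor_conc_uM == 0, ]
  fit <- fit_saturation(base, "substrate_inhibition")
  expect_equal(unname(fit$estimates[c("vmax", "km", "ki_thf")]),
               c(1, 50, 200), tolerance = 1e-4)
  # plain Michaelis-Menten on Michaelis-Menten data is exact
  mm <- data.frame(substrate_conc_uM = d$substrate_grid,
                   velocity = d$substrate_grid / (50 + d$substrate_grid))
  fmm <- fit_saturation(mm, "michaelis_menten")
  expect_equal(unname(fmm$estimates), c(1, 50), tolerance = 1e-8)
})

test_that("ignoring substrate inhibition biases Vmax downward", {
  d <- noiseless("thf_trna_matrix")
  tab <- generate_velocity_matrix(d, truth_hyperbolic())
  base <- tab[tab$inhibitor_conc_uM == 0, ]
  fmm <- fit_saturation(base, "michaelis_menten")
  expect_lt(fmm$estimates[["vmax"]], 1)
})

test_that("saturation fit warns when the design misses the optimum", {
  s <- c(5, 10, 20, 40, 80)  # all below sqrt(km * ki_thf) = 100
  dat <- data.frame(substrate_conc_uM = s,
                    velocity = velocity_substrate_inhibition(
                      s, kinetic_params(1, 50, 200)))
  fit <- fit_saturation(dat, "substrate_inhibition")
  expect_match(paste(fit$warnings, collapse = " "), "optimum")
})

test_that("noiseless global fit recovers all five shared parameters", {
  d <- noiseless("thf_trna_matrix")
  tr <- truth_hyperbolic()
  tab <- generate_velocity_matrix(d, tr)
  fit <- fit_global(tab, "eq_hyperbolic")
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates[c("vmax", "km", "ki_thf", "ki", "alpha")]),
               c(1, 50, 200, 0.031, 18.8), tolerance = 1e-3)
})

test_that("global fit demands enough inhibitor levels", {
  d <- noiseless("thf_trna_matrix")
  tab <- generate_velocity_matrix(d, truth_hyperbolic())
  two <- tab[tab$inhibitor_conc_uM %in% c(0, 1.77), ]
  expect_error(fit_global(two, "eq_hyperbolic"), "identifiability")
})

test_that("fixing alpha at 1 degenerates the law and flags ki", {
  d <- noiseless("thf_trna_matrix")
  tab <- generate_velocity_matrix(d, truth_hyperbolic())
  fit <- fit_global(tab, "eq_hyperbolic", fix = list(alpha = 1))
  expect_match(paste(fit$warnings, collapse = " "), "unidentifiable")
  expect_false("alpha" %in% names(fit$estimates))
})

test_that("global fit is invariant to concentration-unit rescaling", {
  d <- noiseless("thf_trna_matrix")
  tab <- generate_velocity_matrix(d, truth_hyperbolic())
  tab_nm <- tab
  tab_nm$substrate_conc_uM <- tab$substrate_conc_uM * 1000
  tab_nm$inhibitor_conc_uM <- tab$inhibitor_conc_uM * 1000
  f_um <- fit_global(tab, "eq_hyperbolic")
  f_nm <- fit_global(tab_nm, "eq_hyperbolic")
  expect_equal(f_nm$estimates[["km"]], 1000 * f_um$estimates[["km"]],
               tolerance = 1e-4)
  expect_equal(f_nm$estimates[["ki"]], 1000 * f_um$estimates[["ki"]],
               tolerance = 1e-4)
  expect_equal(f_nm$estimates[["alpha"]], f_um$estimates[["alpha"]],
               tolerance = 1e-4)
})

test_that("the optimum is independent of the starting point (3x3 grid)", {
  d <- builtin_design("thf_trna_matrix")
  tab <- generate_velocity_matrix(d, truth_hyperbolic(), seed = 7)
  ref <- fit_global(tab, "eq_hyperbolic")
  for (ki0 in c(0.005, 0.05, 0.5)) for (a0 in c(2, 15, 80)) {
    st <- c(vmax = max(tab$velocity), km = 40,
            ki_thf = max(tab$substrate_conc_uM), ki = ki0, alpha = a0)
    f <- fit_global(tab, "eq_hyperbolic", start = st)
    expect_equal(f$estimates, ref$estimates, tolerance = 1e-4)
  }
})

test_that("bootstrap is seeded, degenerate without noise, and width shrinks", {
  # determinism: identical seeds give identical intervals
  d <- builtin_design("ic50_curve")
  dat <- generate_inhibition_curve(d, inhibition_params(0.033), seed = 3)
  fit <- fit_inhibition_curve(dat)
  b1 <- bootstrap_ci(fit, n_resamples = 120, seed = 99)
  b2 <- bootstrap_ci(fit, n_resamples = 120, seed = 99)
  expect_identical(b1$boot$ci, b2$boot$ci)
  # noiseless data: resampled fits all identical, zero-width interval
  dat0 <- generate_inhibition_curve(noiseless("ic50_curve"),
                                    inhibition_params(0.033))
  f0 <- fit_inhibition_curve(dat0)
  b0 <- bootstrap_ci(f0, n_resamples = 120, seed = 1)
  expect_equal(unname(diff(b0$boot$ci[, "ic50"])), 0, tolerance = 1e-9)
  # quadrupling replication shrinks the interval
  d12 <- builtin_design("ic50_curve", replicates = 12)
  dat12 <- generate_inhibition_curve(d12, inhibition_params(0.033), seed = 3)
  f12 <- fit_inhibition_curve(dat12)
  b12 <- bootstrap_ci(f12, n_resamples = 120, seed = 99)
  expect_lt(diff(b12$boot$ci[, "ic50"]), diff(b1$boot$ci[, "ic50"]))
  # under-resampling is surfaced, not silent
  b_small <- bootstrap_ci(fit, n_resamples = 50, seed = 1)
  expect_match(paste(b_small$warnings, collapse = " "), "resamples")
})

test_that("model comparison ranks by AICc with nested F-tests", {
  d <- builtin_design("thf_trna_matrix")
  tab <- generate_velocity_matrix(d, truth_hyperbolic(), seed = 21)
  f_h <- fit_global(tab, "eq_hyperbolic")
  f_c <- fit_global(tab, "pure_competitive")
  cmp <- compare_models(list(f_h, f_c))
  expect_equal(cmp$preferred, "eq_hyperbolic")
  expect_true(all(c("smaller", "larger", "F", "p") %in%
                    names(cmp$nested_tests)))
  expect_lt(cmp$nested_tests$p[1], 0.05)
  # identical duplicate fits tie
  cmp_tie <- compare_models(list(f_h, f_h))
  expect_equal(cmp_tie$preferred, "tie")
  # mismatched data is a usage error
  tab2 <- generate_velocity_matrix(d, truth_hyperbolic(), seed = 22)
  f_other <- fit_global(tab2, "eq_hyperbolic")
  expect_error(compare_models(list(f_h, f_other)), "identical data")
})

test_that("competitive data do not get overfitted as hyperbolic", {
  d <- builtin_design("thf_trna_matrix")
  tab <- generate_velocity_matrix(d, truth_competitive(),
                                  model = "pure_competitive", seed = 5)
  f_h <- fit_global(tab, "eq_hyperbolic")
  f_c <- fit_global(tab, "pure_competitive")
  cmp <- compare_models(list(f_h, f_c))
  expect_equal(cmp$preferred, "pure_competitive")
})
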