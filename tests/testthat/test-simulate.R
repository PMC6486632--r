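test_that("built-in designs carry the published layouts", {
  d <- builtin_design("thf_trna_matrix")
  expect_equal(range(d$substrate_grid), c(10, 488))
  expect_length(d$substrate_grid, 8)
  expect_equal(d$inhibitor_grid, c(0, 0.11, 0.22, 0.44, 0.88, 1.77))
  expect_equal(d$cosubstrate_conc_uM, 10000)
  ds <- builtin_design("serine_trna_matrix")
  expect_equal(range(ds$substrate_grid), c(156.25, 10000))
  expect_equal(ds$cosubstrate_conc_uM, 80)
  expect_match(ds$note, "unit slip")
  expect_equal(builtin_design("emsa_titration")$substrate_grid,
               c(0.3, 0.6, 1.2, 2.4, 4.8, 9.6))
  expect_length(builtin_design("ic50_curve")$substrate_grid, 10)
})

test_that("noiseless generation returns exact model values on the full grid", {
  d <- noiseless("thf_trna_matrix")
  tr <- truth_hyperbolic()
  tab <- generate_velocity_matrix(d, tr)
  expect_equal(nrow(tab), 6 * 8 * 3)  # inhibitors x substrates x replicates
  expect_equal(tab$velocity,
               velocity_hyperbolic_competitive(tab$substrate_conc_uM,
                                               tab$inhibitor_conc_uM, tr))
  # binding half-saturation point is exact
  de <- noiseless("emsa_titration")
  bd <- generate_binding_dataset(de, binding_params(kd_app = 0.6))
  expect_equal(bd$percent_bound[bd$protein_conc_uM == 0.6], rep(50, 3))
  # inhibition grid reproduces the curve exactly
  di <- noiseless("ic50_curve")
  ic <- generate_inhibition_curve(di, inhibition_params(0.033))
  expect_equal(ic$percent_activity,
               percent_activity(ic$inhibitor_conc_uM,
                                inhibition_params(0.033)))
})

test_that("generation is deterministic given a seed, and requires one", {
  d <- builtin_design("thf_trna_matrix")
  tr <- truth_hyperbolic()
  a <- generate_velocity_matrix(d, tr, seed = 42)
  b <- generate_velocity_matrix(d, tr, seed = 42)
  expect_identical(a, b)
  expect_false(identical(
    a, generate_velocity_matrix(d, tr, seed = 43)))
  expect_error(generate_velocity_matrix(d, tr), "seed")
  # byte-identical files from identical runs
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_velocity_table(a, f1); write_velocity_table(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
  # binding generator determinism
  de <- builtin_design("emsa_titration")
  expect_identical(generate_binding_dataset(de, binding_params(1.39), seed = 5),
                   generate_binding_dataset(de, binding_params(1.39), seed = 5))
})

test_that("multiplicative noise realises the requested CV", {
  d <- experiment_design("cv-check", "THF",
                         substrate_grid = seq(20, 480, length.out = 200),
                         inhibitor_name = "tRNA",
                         inhibitor_grid = c(0, 0.11, 0.22, 0.44, 0.88),
                         replicates = 3, cv = 0.05)
  tab <- generate_velocity_matrix(d, truth_hyperbolic(), seed = 8)
  mu <- velocity_hyperbolic_competitive(tab$substrate_conc_uM,
                                        tab$inhibitor_conc_uM,
                                        truth_hyperbolic())
  # 1000 cells x 3 replicates; pooled empirical CV of the residual ratio
  expect_equal(nrow(tab), 1000 * 3)
  emp_cv <- sd(tab$velocity / mu)
  expect_gt(emp_cv, 0.04)
  expect_lt(emp_cv, 0.06)
})

test_that("oracle-backed generation matches the closed form without noise", {
  d <- experiment_design("oracle-check", "THF",
                         substrate_grid = c(10, 52.9, 160.8, 488),
                         inhibitor_name = "tRNA",
                         inhibitor_grid = c(0, 0.22, 0.88),
                         replicates = 1, cv = 0)
  tr <- truth_hyperbolic()
  t_cf <- generate_velocity_matrix(d, tr, generator = "closed_form")
  t_or <- generate_velocity_matrix(d, tr, generator = "oracle",
                                   e_total = min(tr$km, tr$ki) * 1e-8)
  expect_equal(t_or$velocity, t_cf$velocity, tolerance = 1e-6)
})

test_that("round trips: every generator/fitter pair recovers its truth", {
  # binding
  bf <- quiet(fit_binding_isotherm(
    generate_binding_dataset(noiseless("emsa_titration"),
                             binding_params(1.39))))
  expect_equal(bf$estimates[["kd_app"]], 1.39, tolerance = 1e-6)
  # inhibition
  cf <- fit_inhibition_curve(
    generate_inhibition_curve(noiseless("ic50_curve"),
                              inhibition_params(0.033)))
  expect_equal(cf$estimates[["ic50"]], 0.033, tolerance = 1e-6)
  # velocity matrix under each generating rate law
  d <- noiseless("thf_trna_matrix")
  gf <- fit_global(generate_velocity_matrix(d, truth_hyperbolic()),
                   "eq_hyperbolic")
  expect_equal(gf$estimates[["ki"]], 0.031, tolerance = 1e-3)
  gc_ <- fit_global(generate_velocity_matrix(d, truth_competitive(),
                                             model = "pure_competitive"),
                    "pure_competitive")
  expect_equal(gc_$estimates[["ki"]], 0.031, tolerance = 1e-3)
})

test_that("simulated signals are clipped to their physical ranges", {
  de <- builtin_design("emsa_titration", cv = 0.5, replicates = 20)
  bd <- quiet(generate_binding_dataset(de, binding_params(0.3), seed = 2))
  expect_true(all(bd$percent_bound >= 0 & bd$percent_bound <= 100))
  di <- builtin_design("ic50_curve", cv = 0.3, replicates = 20)
  ic <- quiet(generate_inhibition_curve(di, inhibition_params(0.01),
                                        seed = 2))
  expect_true(all(ic$percent_activity <= 100 * (1 + 5 * 0.3)))
})

test_that("degenerate designs are rejected", {
  expect_error(experiment_design("bad", "THF", numeric(0)), "substrate_grid")
  expect_error(experiment_design("bad", "THF", c(10, -5)), "positive")
  expect_error(experiment_design("bad", "THF", 10, replicates = 0), ">= 1")
  d <- builtin_design("emsa_titration")
  expect_error(generate_velocity_matrix(d, truth_hyperbolic(), seed = 1),
               "inhibitor grid")
})
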