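# Calibration unit tests run on deliberately small designs (2-3 sizes, 3
# pressures) so the whole file stays in the seconds range; the full-table
# fit quality is exercised in the acceptance suite.

small_design <- list(sizes = c(27, 54), pressures = c(7.5, 22.5, 75))

test_that("a noiseless table is fit back to its generating parameters", {
  truth <- test_stack()
  tab <- gen_calibration_dataset(truth, sizes = small_design$sizes,
                                 pressures = small_design$pressures,
                                 noise_cv = 0, seed = 4, flare = 1.3)
  fit <- fit_materials(tab, fit_flare = FALSE, flare = 1.3, seed = 1,
                       n_starts = 3, maxiter = 60)
  est <- c(fit$stack$mucosa$c_kpa, fit$stack$mucosa$a_dimless,
           fit$stack$muscularis$c_kpa, fit$stack$muscularis$a_dimless)
  tru <- c(truth$mucosa$c_kpa, truth$mucosa$a_dimless,
           truth$muscularis$c_kpa, truth$muscularis$a_dimless)
  expect_lt(max(abs(est - tru) / tru), 0.01)
  expect_lt(stats::median(abs(fit$relative_error)), 1e-3)
})

test_that("the fit is reproducible and descends from its initial point", {
  truth <- test_stack()
  tab <- gen_calibration_dataset(truth, sizes = small_design$sizes,
                                 pressures = small_design$pressures,
                                 noise_cv = 0.05, seed = 21, flare = 1.3)
  init <- material_stack(layer_material("mucosa", 3, 0.8),
                         layer_material("muscularis", 10, 0.8))
  f1 <- fit_materials(tab, init = init, fit_flare = FALSE, flare = 1.3,
                      seed = 5, n_starts = 2, maxiter = 25)
  f2 <- fit_materials(tab, init = init, fit_flare = FALSE, flare = 1.3,
                      seed = 5, n_starts = 2, maxiter = 25)
  expect_identical(f1$stack, f2$stack)
  expect_identical(f1$objective, f2$objective)
  # descent relative to the supplied initial stack
  r0 <- sleevemech:::.calib_residuals(
    sleevemech:::.par_pack(init, 1.3, FALSE), tab, FALSE, 1.3, 50,
    stats::setNames(
      lapply(small_design$sizes, function(fr) {
        build_sleeve(bougie_spec(fr), flare = 1.3)
      }),
      as.character(small_design$sizes)
    )
  )
  expect_lte(f1$objective, sum(r0^2))
})

test_that("duplicating every row leaves the fit unchanged and doubles the loss", {
  truth <- test_stack()
  tab <- gen_calibration_dataset(truth, sizes = small_design$sizes,
                                 pressures = small_design$pressures,
                                 noise_cv = 0.05, seed = 31, flare = 1.3)
  fit1 <- fit_materials(tab, init = truth, fit_flare = FALSE, flare = 1.3,
                        seed = 2, n_starts = 1, maxiter = 40)
  fit2 <- fit_materials(rbind(tab, tab), init = truth, fit_flare = FALSE,
                        flare = 1.3, seed = 2, n_starts = 1, maxiter = 40)
  expect_equal(fit2$stack$mucosa$c_kpa, fit1$stack$mucosa$c_kpa,
               tolerance = 1e-4)
  expect_equal(fit2$stack$muscularis$a_dimless,
               fit1$stack$muscularis$a_dimless, tolerance = 1e-4)
  expect_equal(fit2$objective, 2 * fit1$objective, tolerance = 1e-4)
})

test_that("fitted volumes preserve the table's ordering across sizes and pressures", {
  tab <- read_table1()
  fit <- fit_materials(tab, init = default_stack(), fit_flare = FALSE,
                       flare = default_flare(), seed = 1, n_starts = 1,
                       maxiter = 2)
  v_model <- tab$volume_ml * (1 + fit$relative_error)
  for (p in unique(tab$pressure_mmhg)) {
    i <- tab$pressure_mmhg == p
    ord <- order(tab$bougie_fr[i])
    expect_true(all(diff(v_model[i][ord]) > 0))
  }
  for (fr in unique(tab$bougie_fr)) {
    i <- tab$bougie_fr == fr
    ord <- order(tab$pressure_mmhg[i])
    expect_true(all(diff(v_model[i][ord]) > 0))
  }
})

test_that("invalid calibration inputs are rejected", {
  tab <- data.frame(bougie_fr = 27, pressure_mmhg = 7.5, volume_ml = -1)
  expect_error(fit_materials(tab), "positive")
  expect_error(fit_materials(data.frame(x = 1)), "columns")
  good <- data.frame(bougie_fr = 27, pressure_mmhg = 7.5, volume_ml = 3)
  expect_error(fit_materials(good, bounds = list(c_kpa = c(-1, 10),
                                                 a_dimless = c(0.1, 1),
                                                 flare = c(1, 1.5))),
               "positive")
})

test_that("recovery audit reports near-zero error in the noiseless limit", {
  truth <- test_stack()
  rep <- recovery_report(truth, noise_sd = 0, n_replicates = 2, seed = 3,
                         sizes = small_design$sizes,
                         pressures = small_design$pressures,
                         flare = 1.3, n_starts = 2, maxiter = 60)
  expect_identical(nrow(rep), 4L)
  expect_true(all(abs(rep$bias_rel) < 0.01))
  expect_true(all(rep$rmse_rel < 0.01))
  expect_error(recovery_report(truth, n_replicates = 1), ">= 2")
})
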