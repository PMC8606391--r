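test_that("pressure schedules are validated", {
  expect_s3_class(pressure_schedule(), "pressure_schedule")
  expect_error(pressure_schedule(c(10, 5)), "increasing")
  expect_error(pressure_schedule(c(-1, 5)), "non-negative")
  expect_error(pressure_schedule(c(10, 90)), "75")
})

test_that("ring solve is exact at zero load and inverts the forward map", {
  ring <- ring_spec(6)
  st <- test_stack()
  expect_identical(solve_ring(ring, st, 0), 1)
  for (lam_true in c(1.05, 1.2, 1.5)) {
    p <- ring_pressure(ring, st, lam_true)
    lam_hat <- solve_ring(ring, st, p)
    expect_lt(abs(lam_hat - lam_true), 1e-8)
    expect_lt(abs(ring_pressure(ring, st, lam_hat) - p), 1e-8)
  }
})

test_that("stiffer walls stretch less at the same pressure", {
  ring <- ring_spec(6)
  st <- test_stack()
  st2 <- material_stack(
    layer_material("mucosa", 2 * st$mucosa$c_kpa, st$mucosa$a_dimless),
    layer_material("muscularis", 2 * st$muscularis$c_kpa,
                   st$muscularis$a_dimless)
  )
  p <- 3
  expect_lt(solve_ring(ring, st2, p), solve_ring(ring, st, p))
})

test_that("a hopelessly soft wall reports failure to reach pressure", {
  soft <- material_stack(layer_material("mucosa", 1e-4, 0.05),
                         layer_material("muscularis", 1e-4, 0.05))
  expect_error(solve_ring(ring_spec(6), soft, 50), "too soft")
})

test_that("end fixity pins the junctions and leaves the interior alone", {
  g <- uniform_sleeve(27, length_mm = 300)
  lam <- rep(1.4, length(g$z_mm))
  att <- apply_end_fixity(lam, g)
  n <- length(att)
  expect_identical(att[1], 1)
  expect_identical(att[n], 1)
  expect_true(all(att <= lam + 1e-15))
  mid <- which.min(abs(g$z_mm - 150))
  expect_lt(abs(att[mid] - 1.4) / 1.4, 1e-6)
  expect_error(apply_end_fixity(lam[-1], g), "station count")
})

test_that("zero load gives zero insufflated volume and zero strain", {
  g <- uniform_sleeve(27)
  res <- inflate(g, test_stack(), pressure_schedule(0))
  expect_equal(res$volumes_ml, 0)
  expect_true(all(res$samples$strain_percent == 0))
  expect_true(all(res$lambda_inner == 1))
})

test_that("uniform-ring inflation matches the closed-form cylinder volume", {
  g <- uniform_sleeve(27)
  st <- test_stack()
  res <- inflate(g, st, pressure_schedule(22.5), end_fixity = FALSE)
  lam <- solve_ring(ring_spec(4.5), st, mmhg_to_kpa(22.5))
  closed <- pi * ((lam * 4.5)^2 - 4.5^2) * 150 / 1000
  expect_equal(res$volumes_ml, closed, tolerance = 1e-6)
})

test_that("volumes are non-negative, increase with pressure, and the total convention offsets by the reference volume", {
  g <- build_sleeve(bougie_spec(42))
  st <- test_stack()
  sched <- pressure_schedule(c(7.5, 22.5, 37.5, 75))
  res <- inflate(g, st, sched)
  expect_true(all(res$volumes_ml >= 0))
  expect_true(all(diff(res$volumes_ml) > 0))
  res_tot <- inflate(g, st, sched, volume_convention = "total")
  expect_equal(res_tot$volumes_ml,
               res$volumes_ml + reference_lumen_volume(g), tolerance = 1e-9)
})

test_that("strain sample bookkeeping covers stations x layers x through-wall points", {
  g <- build_sleeve(bougie_spec(36))
  res <- inflate(g, test_stack(), pressure_schedule(c(15, 37.5)))
  n_st <- length(g$z_mm)
  expect_identical(nrow(res$samples), 2L * n_st * 2L * 4L)
  expect_true(all(is.finite(res$samples$strain_percent)))
  expect_true(all(res$samples$weight > 0))
})

test_that("quasi-static continuation is path independent", {
  g <- build_sleeve(bougie_spec(48))
  st <- test_stack()
  res_all <- inflate(g, st, pressure_schedule(c(7.5, 22.5, 75)))
  for (i in seq_along(res_all$pressures_mmhg)) {
    res_one <- inflate(g, st, pressure_schedule(res_all$pressures_mmhg[i]))
    expect_equal(res_one$volumes_ml, res_all$volumes_ml[i], tolerance = 1e-9)
  }
})

test_that("strain summaries are volume-weighted and ordered as the wall mechanics demands", {
  g <- build_sleeve(bougie_spec(40))
  res <- inflate(g, test_stack(), pressure_schedule(c(22.5)))
  groups <- strain_summary_table(res, 22.5)
  m <- stats::setNames(groups$mean_percent, groups$grouping)
  expect_gte(m[["mucosa"]], m[["muscularis"]])
  expect_gt(m[["antrum"]], m[["corpus"]]) # default flare > 1
  expect_gt(m[["whole"]], min(m[["mucosa"]], m[["muscularis"]]) - 1e-12)
  expect_lt(m[["whole"]], max(m[["mucosa"]], m[["muscularis"]]) + 1e-12)
  expect_true(all(groups$sd_percent >= 0))
  expect_error(strain_summary(res, 22.5, "fundus"), "arg")
  expect_error(strain_summary(res, 60, "whole"), "not present")
})

test_that("halving the station spacing changes the volume by less than 0.5%", {
  st <- test_stack()
  v2 <- pv_curve(build_sleeve(bougie_spec(40), spacing_mm = 2), st, 37.5)$volume_ml
  v1 <- pv_curve(build_sleeve(bougie_spec(40), spacing_mm = 1), st, 37.5)$volume_ml
  expect_lt(abs(v2 - v1) / v1, 0.005)
})

test_that("the pressure-volume curve is convex increasing beyond the low-pressure toe", {
  g <- build_sleeve(bougie_spec(40))
  cv <- pv_curve(g, test_stack(), seq(5, 75, by = 5))
  expect_true(all(diff(cv$volume_ml) > 0))
  # exponential stiffening: pressure as a function of volume has
  # increasing slope once past the initial compliant toe (below ~15 mmHg
  # the incompressible ring is briefly sub-linear because dV/dlambda
  # itself grows with stretch)
  cv15 <- cv[cv$pressure_mmhg >= 15, ]
  slopes <- diff(cv15$pressure_mmhg) / diff(cv15$volume_ml)
  expect_true(all(diff(slopes) > 0))
})
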