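test_that("vent endmember flux matches Q x c", {
  expect_equal(vent_flux(12, 15.6), 187.2)
  expect_equal(vent_flux(10, 15.6), 156.0)
  expect_equal(vent_flux(0, 15.6), 0)
  expect_error(vent_flux(-1, 15.6), ">= 0")
})

test_that("basin seepage flux upscales areal fluxes over trough areas", {
  areas <- c(1e8, 2e8)
  expect_equal(basin_seepage_flux(13.52, areas), 4.056, tolerance = 1e-6)
  expect_equal(basin_seepage_flux(4.33, areas), 1.299, tolerance = 1e-6)
  expect_error(basin_seepage_flux(1, numeric(0)), "non-empty")
  expect_error(basin_seepage_flux(1, c(1e8, 0)), "> 0")
})

test_that("seepage fraction brackets around the observed share", {
  expect_equal(seepage_fraction(187.2, 187.2), 100)
  expect_equal(seepage_fraction(0, 156), 0)
  expect_equal(seepage_fraction(4.056, 187.2), 2.2, tolerance = 0.02)
  expect_equal(seepage_fraction(1.299, 156.0), 0.83, tolerance = 0.01)
  expect_error(seepage_fraction(1, 0), "> 0")
})

test_that("biomass and productivity translations match hand arithmetic", {
  expect_equal(biomass_support(0), 0)
  expect_equal(biomass_support(4.1),
               4.1 * (106 / 16) * 12.011 * 3.156e7 / 1000,
               tolerance = 1e-12)
  expect_equal(biomass_support(4.1), 1.03e7, tolerance = 0.01)
  expect_equal(biomass_support(8.2), 2 * biomass_support(4.1))

  expect_equal(productivity_support(4.1, 1.405e10) * 1e3, 61,
               tolerance = 0.005)
  expect_equal(productivity_support(1.3, 1.405e10) * 1e3, 19.3,
               tolerance = 0.005)
  expect_equal(productivity_support(0, 1.405e10), 0)
  expect_error(productivity_support(1, 0), "> 0")
})

test_that("export-production percentages match for seepage and venting", {
  expect_equal(pct_export(0.0610, 4.8), 1.27, tolerance = 0.01)
  expect_equal(pct_export(0.0193, 4.8), 0.40, tolerance = 0.01)
  expect_equal(pct_export(4.8, 4.8), 100)

  expect_equal(vent_pct_export(187.2, 1.405e10, 4.8), 58.0,
               tolerance = 0.01)
  expect_equal(vent_pct_export(156.0, 1.405e10, 4.8), 48.4,
               tolerance = 0.01)
  expect_equal(vent_pct_export(0, 1.405e10, 4.8), 0)
})

test_that("budget quantities are homogeneous of degree 1 in their flux", {
  for (k in c(0.5, 2, 10)) {
    expect_equal(basin_seepage_flux(k * 4.33, c(3e8)),
                 k * basin_seepage_flux(4.33, c(3e8)))
    expect_equal(biomass_support(k * 1.3), k * biomass_support(1.3))
    expect_equal(productivity_support(k * 1.3, 1.405e10),
                 k * productivity_support(1.3, 1.405e10))
    expect_equal(vent_pct_export(k * 156, 1.405e10, 4.8),
                 k * vent_pct_export(156, 1.405e10, 4.8))
  }
})

test_that("dual-scale loss fluxes are unit-consistent (umol vs nmol)", {
  # the same sedimentary loss is quoted as 0.00433-0.0135 umol m-2 s-1
  # and 4.33-13.52 nmol m-2 s-1; conversion must agree within rounding
  expect_equal(0.00433 * 1e3, 4.33, tolerance = 1e-12)
  umol <- c(0.00433, 0.0135)
  nmol <- c(4.33, 13.52)
  expect_equal(umol * 1e3, nmol, tolerance = 0.01)
})

test_that("assembled budget satisfies its cross-identities", {
  fit <- list(f_loss = 0.54, y0 = 1.1)
  b <- flux_budget(fit)
  const <- seep_constants()
  expect_equal(unname(b$basin_seepage),
               unname(b$areal * 1e-9 * (const$area_S + const$area_N)),
               tolerance = 1e-12)
  expect_equal(unname(b$vent),
               c(const$Q_low, const$Q_high) * const$c_endmember)
  expect_equal(unname(b$pct_export),
               unname(100 * b$productivity_mol_C_m2_yr / const$export_prod),
               tolerance = 1e-12)
  # vent share equals seepage share scaled by the flux ratio
  expect_equal(b$vent_pct_export[["high"]],
               b$pct_export[["high"]] * b$vent[["high"]] /
                 b$basin_seepage[["high"]],
               tolerance = 1e-9)
  expect_true(all(b$seepage_fraction_pct > 0 &
                    b$seepage_fraction_pct < 100))
})
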