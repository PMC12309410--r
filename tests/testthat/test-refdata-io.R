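test_that("packaged reference tables satisfy their invariants", {
  ucc <- load_reference("UCC")
  expect_true("Al" %in% names(ucc$values))
  expect_gt(ucc$values[["Al"]], 1e4)  # wt%-scale aluminium
  expect_true("Ag" %in% names(ucc$values))

  paas <- load_reference("PAAS")
  expect_setequal(names(paas$values), ree_elements())
  expect_length(paas$values, 14)

  sw <- load_reference("SEAWATER")
  expect_true(all(c("K", "Na", "Mg", "Ca", "S") %in% names(sw$values)))
  expect_equal(sw$values[["K"]], 0.399, tolerance = 1e-6)
  expect_true(all(unlist(lapply(list(ucc, paas, sw),
                                function(r) r$values)) > 0))

  expect_error(load_reference("MORB"), "unknown reference")
})

test_that("constants validate bounds and reject unknown fields", {
  const <- seep_constants()
  expect_equal(const$redfield_C_to_N, 106 / 16)
  expect_lte(const$SR_low, const$SR_high)
  expect_error(seep_constants(SR_low = 0.3, SR_high = 0.1), "SR_low")
  expect_error(seep_constants(rho_dry = -1), "positive")
  expect_error(seep_constants(bogus = 1), "unknown constant")
  expect_equal(seep_constants(Q_high = 15)$Q_high, 15)
})

test_that("profile constructors enforce depth and concentration invariants", {
  expect_s3_class(tiny_sediment(), "sediment_profile")
  expect_error(tiny_sediment(depth = c(5, 3, 9)), "strictly increasing")
  expect_error(tiny_sediment(depth = c(0, 3, 9)), "> 0")
  expect_error(tiny_sediment(tn = c(1, -0.1, 0.5)), ">= 0")
  expect_error(
    porewater_profile("P", data.frame(depth_cm = c(1, 3),
                                      nh4_mM = c(3, -1))),
    "nh4_mM")
  expect_error(
    thermal_profile("T", data.frame(depth_m = 0.1, temp_c = 5)),
    ">= 2 records")
  expect_error(
    thermal_profile("T", data.frame(depth_m = c(0, 0.1),
                                    temp_c = c(-3, 5))),
    "-2")
})

test_that("CSV round trip is lossless for all three schemas", {
  dir <- withr::local_tempdir()
  params <- synth_params(seed = 7L)
  sed <- make_sediment(params)
  pw <- make_porewater(params)
  th <- make_thermal(params)

  paths <- simulate_core_set(params, dir)
  sed2 <- read_profiles(paths[["sediment"]], "sediment")
  pw2 <- read_profiles(paths[["porewater"]], "porewater")
  th2 <- read_profiles(paths[["thermal"]], "thermal")

  expect_equal(sed2$core_id, sed$core_id)
  expect_equal(sed2$data[names(sed$data)], sed$data, tolerance = 1e-12)
  expect_equal(pw2$data, pw$data, tolerance = 1e-12)
  expect_equal(th2$data, th$data, tolerance = 1e-12)

  # Second round trip: canonical-unit conversion is idempotent.
  write_profiles(sed2, file.path(dir, "sed_again.csv"))
  sed3 <- read_profiles(file.path(dir, "sed_again.csv"), "sediment")
  expect_equal(sed3$data, sed2$data, tolerance = 1e-12)
})

test_that("sediment reader converts Al_wt_pct to ppm", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "sed.csv")
  writeLines(c(
    "core_id,depth_cm,toc_wt_pct,tn_wt_pct,d13c_permil,d15n_permil,Al_wt_pct,K_ppm",
    "C1,1,4.2,0.2,-22,8,8.15,20000",
    "C1,3,4.0,0.19,-22,8.1,8.0,19000"
  ), f)
  p <- read_profiles(f, "sediment")
  expect_equal(p$data$Al, c(81500, 80000))
  expect_equal(p$data$K, c(20000, 19000))
})

test_that("reader rejects schema violations with informative errors", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.csv")
  writeLines(c("core_id,depth_cm,toc_wt_pct",
               "C1,1,4.2"), f)
  expect_error(read_profiles(f, "sediment"), "tn_wt_pct")

  writeLines(c(
    "core_id,depth_cm,toc_wt_pct,tn_wt_pct,d13c_permil,d15n_permil",
    "C1,5,4,0.2,-22,8", "C1,3,4,0.2,-22,8", "C1,9,4,0.2,-22,8"), f)
  expect_error(read_profiles(f, "sediment"), "strictly increasing")

  writeLines(c("core_id,depth_cm,nh4_mM",
               "C1,1,3.5", "C1,3,-0.2"), f)
  expect_error(read_profiles(f, "porewater"), "nh4_mM")

  expect_error(read_profiles(file.path(dir, "nope.csv"), "thermal"),
               "not found")
})

test_that("multi-core files split into named profile lists", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "th.csv")
  writeLines(c("core_id,depth_cm,temp_c",
               "A,0,3", "A,10,10", "A,20,20",
               "B,0,3", "B,10,8", "B,20,14"), f)
  out <- read_profiles(f, "thermal")
  expect_named(out, c("A", "B"))
  expect_equal(out$A$data$depth_m, c(0, 0.1, 0.2))  # cm -> m canonical
})

test_that("run configuration merges section overrides onto defaults", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "run.yaml")
  writeLines(c(
    "seed: 42",
    "simulate: guaymas_demo",
    "constants:",
    "  rho_dry: 0.5",
    "basin:",
    "  Q_high: 14",
    "flow:",
    "  lambda_s: 1.0"
  ), f)
  cfg <- read_run_config(f)
  expect_equal(cfg$seed, 42L)
  expect_equal(cfg$constants$rho_dry, 0.5)
  expect_equal(cfg$constants$Q_high, 14)
  expect_equal(cfg$constants$lambda_s, 1.0)
  expect_equal(cfg$constants$M_N, 14.007)  # untouched default
})
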