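ucc <- load_reference("UCC")
paas <- load_reference("PAAS")
sw <- load_reference("SEAWATER")

test_that("enrichment factor reproduces reference and hand-computed values", {
  # sample with the UCC ratio itself
  expect_equal(
    enrichment_factor(ucc$values[["Cu"]], ucc$values[["Al"]], "Cu", ucc),
    1.0)
  # hand arithmetic with a synthetic UCC pairing
  fake_ucc <- structure(list(name = "UCC",
                             values = c(Al = 80000, X = 2)),
                        class = "reference_composition")
  expect_equal(enrichment_factor(10, 40000, "X", fake_ucc), 10.0)
  expect_error(enrichment_factor(10, 0, "Cu", ucc), "> 0")
  expect_error(enrichment_factor(10, 40000, "Xx", ucc), "absent")
})

test_that("ore-grade Ag enrichment back-solves to the expected Al content", {
  # Brute-force inversion: find the Al concentration at which a 120 ppm Ag
  # sample reaches EF = 9368 under the packaged UCC ratios.
  target <- 9368
  al <- uniroot(function(al_ppm) {
    enrichment_factor(120, al_ppm, "Ag", ucc) - target
  }, interval = c(1000, 2e5), tol = 1e-8)$root
  expect_equal(al / 1e4, 1.97, tolerance = 0.01)  # ~1.97 wt% Al
  expect_equal(enrichment_factor(120, al, "Ag", ucc), target,
               tolerance = 1e-6)
})

test_that("enrichment factor is dilution-invariant", {
  for (scale in c(0.1, 0.5, 2, 10)) {
    expect_equal(
      enrichment_factor(12 * scale, 50000 * scale, "Zn", ucc),
      enrichment_factor(12, 50000, "Zn", ucc))
  }
})

test_that("Eu anomaly matches flat, constructed and scaled patterns", {
  v <- paas$values
  expect_equal(eu_anomaly(v[["Eu"]], v[["Sm"]], v[["Gd"]], paas), 1.0)
  # shale-normalized values Eu=2, Sm=1, Gd=1
  expect_equal(eu_anomaly(2 * v[["Eu"]], v[["Sm"]], v[["Gd"]], paas), 2.0)
  # the maximum observed in oily seep sediment
  expect_equal(eu_anomaly(4.7 * v[["Eu"]], v[["Sm"]], v[["Gd"]], paas),
               4.7)
  # invariance under common REE rescaling
  for (k in c(0.2, 3, 50)) {
    expect_equal(eu_anomaly(k * 1.5, k * 4.1, k * 3.9, paas),
                 eu_anomaly(1.5, 4.1, 3.9, paas))
  }
  expect_true(is.na(eu_anomaly(1, 0, 0, paas)))
})

test_that("REE summary sums lanthanides and normalizes Pr/Yb", {
  zero <- setNames(rep(0, 14), ree_elements())
  expect_equal(ree_summary(zero, paas)$sum_ree, 0)
  ones <- setNames(rep(1, 14), ree_elements())
  expect_equal(ree_summary(ones, paas)$sum_ree, 14)
  expect_equal(
    ree_summary(c(Pr = paas$values[["Pr"]], Yb = paas$values[["Yb"]]),
                paas)$pr_yb_sn, 1.0)
  expect_true(is.na(ree_summary(c(Pr = 1, Yb = 0), paas)$pr_yb_sn))
})

test_that("C/N ratios cover mass, molar, Redfield and degenerate cases", {
  r <- cn_ratios(4.2, 0.2)
  expect_equal(r$cn, 21.0)
  expect_equal(r$cn * r$nc, 1.0)

  # Redfield biomass: C:N molar 106:16 -> N/C mass ratio ~0.176 (~0.18)
  const <- seep_constants()
  toc <- 106 * const$M_C
  tn <- 16 * const$M_N
  red <- cn_ratios(toc, tn)
  expect_equal(red$nc, (16 * 14.007) / (106 * 12.011), tolerance = 1e-12)
  expect_equal(red$nc, 0.18, tolerance = 0.03)
  expect_equal(cn_ratios(toc, tn, mode = "molar")$cn, 106 / 16,
               tolerance = 1e-12)

  deg <- cn_ratios(c(4, 0), c(0, 0))
  expect_true(is.na(deg$cn[1]))
  expect_equal(deg$nc[1], 0)
  expect_true(is.na(deg$cn[2]) && is.na(deg$nc[2]))
})

test_that("salt correction subtracts porewater salt and floors at zero", {
  expect_equal(as.numeric(salt_correct(500, "K", 0, sw)), 500)
  got <- salt_correct(20000, "K", 1.0, sw)
  expect_equal(as.numeric(got), 20000 - 399)
  expect_false(any(attr(got, "floored")))

  floored <- salt_correct(100, "K", 1.0, sw)
  expect_equal(as.numeric(floored), 0)
  expect_true(attr(floored, "floored"))

  skipped <- salt_correct(50, "Ag", 1.0, sw)  # not a seawater major ion
  expect_equal(as.numeric(skipped), 50)
  expect_true(attr(skipped, "skipped"))

  # monotone non-increasing in the porewater mass fraction
  pw <- seq(0, 2, by = 0.25)
  vals <- as.numeric(salt_correct(rep(1000, length(pw)), "K", pw, sw))
  expect_true(all(diff(vals) <= 0))
})

test_that("isotope summary flags IQR outliers without dropping them silently", {
  mk <- function(d15n) sediment_profile("S", data.frame(
    depth_cm = seq_along(d15n), toc = 4, tn = 0.2, d13c = -22,
    d15n = d15n))
  flat <- summarize_isotopes(mk(rep(8, 5)))
  expect_equal(flat$d15n$sd, 0)
  expect_equal(nrow(flat$outliers), 0)

  s <- summarize_isotopes(mk(c(8, 8, 8, 8, 2)))
  expect_equal(nrow(s$outliers), 1)
  expect_equal(s$outliers$d15n, 2)
  expect_equal(s$d15n$mean, 8)
  expect_equal(s$n, 4)

  # below 3 samples no outlier screening is attempted
  few <- summarize_isotopes(mk(c(8, 2)))
  expect_equal(few$n, 2)
  expect_equal(nrow(few$outliers), 0)
})

test_that("linear R-squared handles exact, flat and noise-only relations", {
  x <- 0:10
  exact <- linear_r2(x, 2 * x + 1)
  expect_equal(exact$r2, 1.0)
  expect_gt(exact$slope, 0)

  flat <- linear_r2(c(0, 1, 2), c(0, 1, 0))
  expect_equal(flat$r2, 0, tolerance = 1e-12)
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  set.seed(11)
  noise <- linear_r2(seq_len(1000), rnorm(1000))
  expect_lt(noise$r2, 0.05)

  expect_true(linear_r2(rep(1, 5), 1:5)$flag)
  expect_error(linear_r2(1:2, 1:2), ">= 3")
})

test_that("index table equals row-wise computation (no cross-row coupling)", {
  sed <- make_sediment(synth_params(seed = 3L))
  full <- index_table(sed, salt_correct = TRUE)
  expect_equal(nrow(full), nrow(sed$data))
  for (i in c(1, 7, nrow(sed$data))) {
    one <- sediment_profile("row", sed$data[i, , drop = FALSE])
    row_i <- index_table(one, salt_correct = TRUE)
    expect_equal(unlist(row_i), unlist(full[i, ]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_true(all(full$ef_K > 0))
  expect_true(all(full$sum_ree > 0))
})
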