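test_that("step scenario encodes the simplified abundance changes", {
  sc <- step_scenario()
  at <- function(h) sc$abundance[which.min(abs(sc$height - h)), ]
  expect_equal(unname(at(49)), c(1, 1))
  expect_equal(unname(at(55)), c(0.5, 0))       # inside the 10-cm gap
  expect_equal(unname(at(65)), c(0.5, 0.025))   # beyond the gap
  expect_error(step_scenario(onset_cm = 150), "outside")
  expect_equal(sc$iso$mixed_layer$mean_pre, 3.1)
  expect_equal(sc$iso$thermocline$sd, 0.12)
})

test_that("ramp scenario interpolates mean and abundance linearly over the onset", {
  sc0 <- ramp_scenario(0)
  mu0 <- isotope_mean_at(sc0$iso$mixed_layer, sc0$height)
  expect_true(all(mu0 %in% c(3.1, 0)))          # step change: no intermediates
  sc <- ramp_scenario(10, ws = 0.5)
  expect_equal(sc$iso$mixed_layer$ramp_cm, 5)
  mid <- sc$onset_height + 2.5
  expect_equal(isotope_mean_at(sc$iso$mixed_layer, mid), 1.55)
  i <- which.min(abs(sc$height - mid))
  expect_equal(unname(sc$abundance[i, "mixed_layer"]), 0.75,
               tolerance = 0.03)
  expect_equal(ramp_scenario(5, ws = 0.5)$iso$mixed_layer$ramp_cm, 2.5)
  expect_error(ramp_scenario(-1), ">= 0")
})

test_that("bulk scenario collapses abundance below one percent after the onset", {
  sc <- bulk_scenario()
  at <- function(h) unname(sc$abundance[which.min(abs(sc$height - h)), 1])
  expect_equal(at(40), 1)
  expect_lt(at(55), 0.01)
  expect_equal(at(70), 0.025)
})

test_that("covariate regressions evaluate and clip as printed", {
  expect_equal(coarse_fraction_from_caco3(85), 6.2508)
  expect_equal(coarse_fraction_from_caco3(0), 0)            # clipped
  expect_lt(coarse_fraction_from_caco3(39.07), 1e-3)        # root of the line
  expect_equal(fragmentation_from_caco3(85), 12.6895)
  expect_equal(fragmentation_from_caco3(0), 40.051)
  expect_equal(fragmentation_from_caco3(100), 7.861)
  expect_error(coarse_fraction_from_caco3(101), "\\[0, 100\\]")
  expect_error(fragmentation_from_caco3(-5), "\\[0, 100\\]")
  # exact linearity away from the clip: three collinear inputs stay collinear
  x <- c(50, 60, 70)
  y <- coarse_fraction_from_caco3(x)
  expect_equal(y[2] - y[1], y[3] - y[2], tolerance = 1e-12)
  z <- fragmentation_from_caco3(x)
  expect_equal(z[2] - z[1], z[3] - z[2], tolerance = 1e-12)
})

test_that("sedimentary abundance normalises, imputes and logs provenance", {
  tb <- data.frame(
    depth_mbsf = c(170.50, 170.52, 170.54, 170.56, 170.58),
    pct_subbotina = c(60, 40, 30, 20, NA),
    pct_acarinina = c(60, 40, 30, 30, NA),
    caco3 = c(85, 80, NA, 90, 70),
    coarse_fraction = c(NA, 5, 4, 1, 2),
    fragmentation = c(10, NA, 20, 30, 15))
  expect_warning(out <- sedimentary_abundance(tb), "without genus data")
  expect_equal(nrow(out), 4L)
  expect_equal(out$norm_pct_subbotina, c(50, 50, 50, 40))
  # missing coarse fraction imputed from CaCO3 = 85
  expect_equal(out$coarse_fraction[out$depth_mbsf == 170.50], 6.2508)
  expect_equal(out$prov_coarse[out$depth_mbsf == 170.50],
               "regression-imputed")
  # missing CaCO3 imputed as the mean of adjacent depths (80 and 90)
  expect_equal(out$caco3[out$depth_mbsf == 170.54], 85)
  expect_equal(out$prov_caco3[out$depth_mbsf == 170.54], "neighbor-averaged")
  expect_true(length(attr(out, "log")) >= 3)
  # scale consistency: doubling both genus percentages changes nothing
  tb2 <- tb; tb2$pct_subbotina <- tb$pct_subbotina * 2
  tb2$pct_acarinina <- tb$pct_acarinina * 2
  out2 <- suppressWarnings(sedimentary_abundance(tb2))
  expect_equal(out2$sed_pct_subbotina, out$sed_pct_subbotina)
  # over100 mode leaves compliant rows untouched
  tb3 <- tb[2, ]; tb3$pct_subbotina <- 30; tb3$pct_acarinina <- 20
  out3 <- sedimentary_abundance(tb3, normalize = "over100")
  expect_equal(out3$norm_pct_subbotina, 30)
})

test_that("unfragmented weight supports both the complement and literal readings", {
  tb <- data.frame(depth_mbsf = 170.5, pct_subbotina = 50,
                   pct_acarinina = 50, caco3 = 85, coarse_fraction = 10,
                   fragmentation = 20)
  a <- sedimentary_abundance(tb)
  b <- sedimentary_abundance(tb, unfragmented = "literal")
  expect_equal(a$unfrag_wt, 10 * 80 / 100)
  expect_equal(b$unfrag_wt, 10 * 20 / 100)
})
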