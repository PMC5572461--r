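test_that("zero covariate noise reproduces the imputation regressions exactly", {
  cfg <- synthetic_config(noise_sd = 0, caco3_noise_sd = 0, mask_frac = 0.2,
                          kernel = test_kernel_ws25, seed = 5)
  ds <- generate_dataset(cfg, profile = test_profile_ws25)
  tb <- ds$table
  ok <- !is.na(tb$caco3) & !is.na(tb$coarse_fraction)
  fit <- lm(coarse_fraction ~ caco3, data = tb[ok, ])
  expect_equal(unname(coef(fit)), c(-5.3177, 0.1361), tolerance = 1e-9)
  ok2 <- !is.na(tb$caco3) & !is.na(tb$fragmentation)
  fit2 <- lm(fragmentation ~ caco3, data = tb[ok2, ])
  expect_equal(unname(coef(fit2)), c(40.051, -0.3219), tolerance = 1e-9)
})

test_that("generation is bit-identical under a fixed seed and respects bounds", {
  cfg <- synthetic_config(kernel = test_kernel_ws25, seed = 9)
  d1 <- generate_dataset(cfg, profile = test_profile_ws25)
  d2 <- generate_dataset(cfg, profile = test_profile_ws25)
  expect_identical(d1$table, d2$table)
  expect_identical(d1$individuals, d2$individuals)
  tb <- d1$table
  for (col in c("pct_subbotina", "pct_acarinina", "caco3",
                "coarse_fraction", "fragmentation"))
    expect_true(all(tb[[col]] >= 0 & tb[[col]] <= 100, na.rm = TRUE))
  # carbonate declines from a >85 wt% pre-event plateau to lows near 60
  pre <- tb$caco3[tb$depth_mbsf > cfg$onset_mbsf + 0.05]
  post <- tb$caco3[tb$depth_mbsf < cfg$onset_mbsf - 0.05]
  expect_gt(mean(pre, na.rm = TRUE), 85)
  expect_lt(min(post, na.rm = TRUE), 65)
  # masking leaves NAs for the imputation paths
  expect_gt(sum(is.na(tb$coarse_fraction)), 0)
  # normalized genus percentages sum to <= 100 after the pipeline
  out <- suppressWarnings(sedimentary_abundance(tb, normalize = "over100"))
  expect_true(all(out$norm_pct_subbotina + out$norm_pct_acarinina
                  <= 100 + 1e-9))
})

test_that("a step-change truth yields no intermediates beyond the Gaussian floor", {
  cfg <- synthetic_config(kernel = test_kernel_ws25, seed = 13)
  ds <- generate_dataset(cfg, profile = test_profile_ws25)
  dr <- ds$individuals
  n_flag <- 0L
  for (cl in unique(dr$clade)) {
    i <- dr$clade == cl
    n_flag <- n_flag + attr(flag_intermediates(dr$d13c[i],
                                               ds$truth$iso[[cl]]), "count")
  }
  # binomial upper bound at the 3-s.d. tail rate
  expect_lte(n_flag, qbinom(0.999, nrow(dr), 2 * pnorm(-3)))
})

test_that("the full pipeline recovers the true abundance history from generated data", {
  cfg <- synthetic_config(noise_sd = 1, caco3_noise_sd = 0.5,
                          mask_frac = 0.1, mask_frac_caco3 = 0.02,
                          kernel = test_kernel_ws25, seed = 17)
  ds <- generate_dataset(cfg, profile = test_profile_ws25)
  out <- suppressWarnings(
    sedimentary_abundance(ds$table, normalize = "over100"))
  h <- (cfg$depth_base - out$depth_mbsf) * 100
  for (cl in c("acarinina", "subbotina")) {
    segs <- cfg[[cl]]
    bp <- (cfg$depth_base - c(segs$from_mbsf[1], segs$to_mbsf)) * 100
    target <- out[[paste0("sed_pct_", cl)]]
    fit <- fit_unmixed_abundance(h, target, test_profile_ws25, bp)
    scale <- if (cl == "acarinina") cfg$scale_aca else cfg$scale_sub
    truth <- segs$level * scale
    big <- truth > 0.5
    expect_true(all(abs(fit$history$level_pct[big] - truth[big]) /
                      truth[big] < 0.10))
    expect_true(all(fit$history$level_pct[!big] < 0.5))
  }
})

test_that("fixture sets are written in the pipeline's formats", {
  dir <- tempfile("fixtures")
  cfg <- synthetic_config(kernel = test_kernel_ws25, seed = 3)
  make_fixture_set(dir, cfg, profile = test_profile_ws25)
  expect_true(file.exists(file.path(dir, "abundance_table.csv")))
  expect_true(file.exists(file.path(dir, "individual_d13c.csv")))
  truth <- yaml::read_yaml(file.path(dir, "truth.yml"))
  expect_equal(truth$onset_mbsf, 170.74)
})
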