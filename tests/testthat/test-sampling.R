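test_that("the 3-s.d. intermediate rule is exclusive and symmetric in the clouds", {
  iso <- isotope_model("ml", 3.1, 0, 0.30)
  expect_true(flag_intermediates(1.5, iso)[1])     # between 0.9 and 2.2
  expect_false(flag_intermediates(3.0, iso)[1])
  expect_false(flag_intermediates(0.9, iso)[1])    # boundary is exclusive
  expect_false(flag_intermediates(2.2, iso)[1])
  f <- flag_intermediates(c(1.0, 2.0, 2.5), iso)
  expect_equal(attr(f, "count"), 2L)
  # overlapping clouds make intermediates undetectable
  wide <- isotope_model("ml", 1, 0, 0.5)
  expect_warning(fw <- flag_intermediates(0.5, wide), "overlap")
  expect_false(fw[1])
})

test_that("false-positive intermediates from a pure cloud match the Gaussian tail", {
  iso <- isotope_model("ml", 3.1, 0, 0.30)
  set.seed(1)
  v <- rnorm(1e6, 3.1, 0.30)
  rate <- mean(flag_intermediates(v, iso))
  p_tail <- pnorm((2.2 - 3.1) / 0.30) - pnorm((0.9 - 3.1) / 0.30)
  expect_lt(rate, 0.00135 * 1.1)
  expect_equal(rate, p_tail, tolerance = 0.1)
})

test_that("draws follow the local source distribution", {
  sc <- step_scenario(length_cm = 40, onset_cm = 20)
  col <- form_record(sc, delta_profile())
  cfg <- sampling_config(spacing = 2, n_per_clade = 2000)
  dr <- draw_individuals(col, cfg, seed = 2)
  pre <- dr[dr$height_cm < 18 & dr$clade == "mixed_layer", ]
  expect_equal(mean(pre$d13c), 3.1, tolerance = 0.05)
  expect_equal(sd(pre$d13c), 0.30, tolerance = 0.05)
  # within the unmixed thermocline gap there is no mass, hence no draws
  gap <- dr[dr$height_cm > 21 & dr$height_cm < 29 &
              dr$clade == "thermocline", ]
  expect_equal(nrow(gap), 0L)
  # determinism under a fixed seed
  expect_identical(dr, draw_individuals(col, cfg, seed = 2))
})

test_that("zero-s.d. draws reproduce the source means exactly", {
  ab <- matrix(1, 50, 1, dimnames = list(NULL, "x"))
  sc <- stratmix:::new_scenario(
    ab, list(x = isotope_model("x", 3.1, 0, 0, 5)),   # sd = 0, step at 5 cm
    dz = 0.2, ws = 2.5, onset_height = 5)
  col <- form_record(sc, delta_profile())
  cfg <- sampling_config(spacing = 2, thickness = 0.2, n_per_clade = 10)
  dr <- draw_individuals(col, cfg, seed = 3)
  expect_true(all(dr$d13c %in% c(3.1, 0)))
  one <- dr[dr$sample == 1, ]
  expect_true(all(one$d13c == one$d13c[1]))   # single-source sample
})

test_that("observed onset duration measures qualifying runs of flagged samples", {
  cfg1 <- sampling_config(spacing = 2, min_run = 1)
  cfg2 <- sampling_config(spacing = 2, min_run = 2)
  expect_equal(observed_onset_duration(c(0, 0, 0), cfg1, 0.5), 0)
  expect_equal(observed_onset_duration(integer(0), cfg1, 0.5), 0)
  expect_equal(observed_onset_duration(c(0, 1, 1, 0), cfg1, 0.5), 8)
  expect_equal(observed_onset_duration(c(0, 1, 1, 0), cfg2, 0.5), 8)
  # only the longest run counts under the default rule
  expect_equal(observed_onset_duration(c(1, 0, 1, 1, 1), cfg1, 0.5), 12)
  # an isolated flagged sample defines no interval at min_run = 2
  expect_equal(observed_onset_duration(c(0, 1, 0, 0), cfg2, 0.5), 0)
  expect_equal(observed_onset_duration(c(0, 1, 0, 0), cfg1, 0.5), 4)
  first <- sampling_config(spacing = 2, min_run = 1, run_rule = "first")
  expect_equal(observed_onset_duration(c(1, 0, 1, 1, 1), first, 0.5), 4)
})

test_that("a step-change record with zero spread never yields intermediates", {
  sc <- ramp_scenario(0, ws = 0.5, sd = 0)
  col <- form_record(sc, test_profile_ws05)
  cfg <- sampling_config(n_per_clade = 20, min_run = 1)
  dr <- draw_individuals(col, cfg, seed = 11)
  cnt <- count_intermediates(dr, sc$iso)
  expect_equal(sum(cnt$n_intermediate), 0L)
})
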