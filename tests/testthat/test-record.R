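test_that("the delta profile is the identity convolution", {
  sc <- step_scenario(length_cm = 30, onset_cm = 15)
  col <- form_record(sc, delta_profile())
  s <- column_summary(col)
  expect_equal(s$mixed_layer_mass, s$mixed_layer_unmixed)
  expect_equal(s$thermocline_mass, s$thermocline_unmixed)
})

test_that("form_record conserves mass per clade and rejects grid mismatches", {
  sc <- step_scenario(length_cm = 40, onset_cm = 20)
  col <- form_record(sc, test_profile_ws25)
  for (cl in col$clades)
    expect_equal(sum(col$mass[[cl]]), sum(col$src_abundance[, cl]),
                 tolerance = 1e-6)
  # single nonzero source increment: total mass equals the deposited mass
  ab <- matrix(0, 100, 1, dimnames = list(NULL, "mixed_layer"))
  ab[50, 1] <- 0.7
  sc1 <- stratmix:::new_scenario(
    ab, list(mixed_layer = isotope_model("mixed_layer", 3.1, 0, 0.3, 10)),
    dz = 0.2, ws = 2.5, onset_height = 10)
  col1 <- form_record(sc1, test_profile_ws25)
  expect_equal(sum(col1$mass$mixed_layer), 0.7, tolerance = 1e-9)
  bad <- test_profile_ws25
  attr(bad, "dz") <- 0.5
  expect_error(form_record(sc, bad), "spacing")
})

test_that("convolution is linear in the deposited abundances", {
  mk <- function(lv) {
    ab <- matrix(lv, 50, 1, dimnames = list(NULL, "x"))
    stratmix:::new_scenario(
      ab, list(x = isotope_model("x", 3.1, 0, 0.3, 5)),
      dz = 0.2, ws = 2.5, onset_height = 5)
  }
  a <- runif(50); b <- runif(50)
  ca <- form_record(mk(a), test_profile_ws25)$mass$x
  cb <- form_record(mk(b), test_profile_ws25)$mass$x
  cab <- form_record(mk(pmin(0.3 * a + 0.6 * b, 1)), test_profile_ws25)$mass$x
  expect_equal(cab, 0.3 * ca + 0.6 * cb, tolerance = 1e-9)
})

test_that("mixing smears pre-event material up-core and excursion material down-core", {
  sc <- step_scenario(length_cm = 80, onset_cm = 40)
  col <- form_record(sc, test_profile_ws25)
  pre_src <- col$src_height < sc$onset_height
  w <- col$window
  h <- col$dest_height[w]
  M <- col$mass$mixed_layer[w, , drop = FALSE]
  above <- h > sc$onset_height + 2 & h < sc$onset_height + 8
  below <- h < sc$onset_height - 2 & h > sc$onset_height - 8
  # pre-event (older) individuals present above the onset ...
  expect_gt(sum(M[above, pre_src]), 0)
  # ... and excursion individuals carried below their depositional depth
  expect_gt(sum(M[below, !pre_src]), 0)
  # but each zone is still dominated by its in-place population
  expect_gt(sum(M[below, pre_src]), sum(M[below, !pre_src]))
  expect_gt(sum(M[above, !pre_src]), sum(M[above, pre_src]))
})

test_that("bulk d13C is the mass-weighted mean of source-time means", {
  toy <- list(dz = 0.2, ws = 2.5, clades = "bulk",
              src_height = c(0, 0.2), src_abundance = cbind(bulk = c(1, 1)),
              src_mu = list(bulk = c(1.6, -0.4)),
              dest_height = 0, mass = list(bulk = matrix(c(0.75, 0.25), 1)),
              window = 1L,
              scenario = list(ref_mbsf = NA_real_, n = 1L, height = 0,
                              abundance = cbind(bulk = 1)),
              method = "convolution")
  class(toy) <- "mixed_column"
  expect_equal(bulk_carbonate_profile(toy)$d13c, 0.75 * 1.6 + 0.25 * -0.4)
  # zero-mass bins are missing values
  toy$mass$bulk <- matrix(c(0, 0), 1)
  expect_true(is.na(bulk_carbonate_profile(toy)$d13c))
  # and the bulk value is always bounded by the two population means
  sc <- bulk_scenario(length_cm = 60, onset_cm = 30)
  b <- bulk_carbonate_profile(form_record(sc, test_profile_ws25))
  expect_true(all(b$d13c <= 1.6 + 1e-9 & b$d13c >= -0.4 - 1e-9, na.rm = TRUE))
})

test_that("direct simulation reduces to the unmixed scenario when K0 = 0", {
  sc <- step_scenario(length_cm = 10, onset_cm = 5)
  p <- mixing_params(K0 = 0, n_particles = 200, T = 10000)
  col <- direct_simulation_oracle(sc, p, seed = 5)
  s <- column_summary(col)
  expect_equal(s$mixed_layer_mass, s$mixed_layer_unmixed, tolerance = 1e-9)
  expect_equal(s$thermocline_mass, s$thermocline_unmixed, tolerance = 1e-9)
})

test_that("direct simulation keeps a constant scenario uniform in the interior", {
  n_inc <- 120
  ab <- matrix(1, n_inc, 1, dimnames = list(NULL, "x"))
  sc <- stratmix:::new_scenario(
    ab, list(x = isotope_model("x", 3.1, 0, 0.3, 0)),
    dz = 0.2, ws = 2.5, onset_height = 0)
  p <- mixing_params(n_particles = 400, seed = 3)
  col <- direct_simulation_oracle(sc, p, seed = 31)
  tot <- rowSums(col$mass$x)
  # interior: bins reachable from simulated sources only
  off <- round((test_profile_ws25$displacement - 0.1) / 0.2)
  lo <- max(off) + 1; hi <- n_inc + min(off)
  idx <- which(col$dest_height >= lo * 0.2 & col$dest_height <= hi * 0.2)
  interior <- tot[idx]
  se <- sd(interior)
  expect_lt(max(abs(interior - mean(interior))), 5 * se + 0.2)
  expect_equal(mean(interior), 1, tolerance = 0.05)
})
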