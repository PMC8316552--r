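# Synthetic-scene and table generators: determinism, placement laws,
# conservation, and the noise-free ground-truth identities.

test_that("fixed seed gives bit-identical scenes; params validate", {
  p <- small_lysosome_params(seed = 5)
  a <- generate_lysosome_scene(p)
  b <- generate_lysosome_scene(p)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$puncta, b$truth$puncta)
  t1 <- generate_tandem_scene(small_tandem_params(seed = 9))
  t2 <- generate_tandem_scene(small_tandem_params(seed = 9))
  expect_identical(t1$stack$data, t2$stack$data)

  expect_error(scene_params(ring_weights = c(0.5, 0.5, 0.1, -0.1)),
               "ring_weights")
  expect_error(scene_params(ring_weights = c(0.3, 0.3, 0.3, 0.3)),
               "ring_weights")
  expect_error(scene_params(n_puncta = -1), "n_puncta")
  expect_error(scene_params(spot_sigma = 0), "spot_sigma")
  expect_error(scene_params(shape = c(0, 10)), "shape")
})

test_that("generators do not disturb the caller's RNG state", {
  set.seed(123); expected <- runif(3)
  set.seed(123)
  generate_lysosome_scene(small_lysosome_params(seed = 2))
  generate_vacuole_table(10, seed = 3)
  expect_identical(runif(3), expected)
})

test_that("uniform placement law realizes ~equal ring intensity fractions", {
  # multinomial oracle: with 400 draws at p = 0.25 the realized fraction
  # has sd ~ sqrt(.25*.75/400) ~ 0.022, so 0.05 is a ~2.3 sigma band
  p <- scene_params(n_puncta = 400L, background = 0, gradient_amplitude = 0,
                    poisson_noise = FALSE, read_noise_sd = 0, seed = 21)
  sc <- generate_lysosome_scene(p)
  expect_true(all(abs(sc$truth$ring_fractions - 0.25) < 0.05))
  expect_equal(sum(sc$truth$ring_fractions), 1, tolerance = 1e-9)
})

test_that("degenerate law (0,0,0,1) puts every punctum in the inner ring", {
  p <- small_lysosome_params(seed = 3, ring_weights = c(0, 0, 0, 1))
  sc <- generate_lysosome_scene(p)
  expect_true(all(sc$truth$puncta$ring == 4))
  lab <- sc$truth$partition$labels
  at <- lab[cbind(round(sc$truth$puncta$row) + 1,
                  round(sc$truth$puncta$col) + 1)]
  expect_true(all(at == 4))
})

test_that("clean marker image integrates to the recorded ring fractions", {
  p <- scene_params(shape = c(160L, 160L), n_puncta = 50L, background = 0,
                    gradient_amplitude = 0, poisson_noise = FALSE,
                    read_noise_sd = 0, seed = 13)
  sc <- generate_lysosome_scene(p)
  img <- get_channel(sc$stack, "marker")
  lab <- sc$truth$partition$labels
  f <- vapply(1:4, function(k) sum(img[lab == k]), numeric(1))
  expect_equal(f / sum(f), sc$truth$ring_fractions, tolerance = 1e-6)
  expect_equal(nrow(sc$truth$puncta), p$n_puncta)  # conservation
})

test_that("tandem composition is deterministic and hits the boundaries", {
  all_apg <- generate_tandem_scene(small_tandem_params(seed = 2,
                                                       apg_fraction = 1))
  expect_true(all(all_apg$truth$puncta$apg))

  none <- generate_tandem_scene(small_tandem_params(seed = 2,
                                                    apg_fraction = 0,
                                                    background = 3,
                                                    poisson_noise = FALSE,
                                                    read_noise_sd = 0,
                                                    gradient_amplitude = 0))
  expect_false(any(none$truth$puncta$apg))
  # green channel is background only
  expect_lt(max(get_channel(none$stack, "green")), 3 + 1e-9)

  mixed <- generate_tandem_scene(small_tandem_params(seed = 4, n_puncta = 50L,
                                                     apg_fraction = 0.4))
  expect_identical(mixed$truth$n_apg, as.integer(round(0.4 * 50)))
  expect_identical(mixed$truth$n_apg + mixed$truth$n_al, 50L)
})

test_that("every punctum center lies inside the true cell mask", {
  for (seed in 1:5) {
    sc <- generate_lysosome_scene(small_lysosome_params(seed = seed))
    at <- sc$truth$cell_mask[cbind(round(sc$truth$puncta$row) + 1,
                                   round(sc$truth$puncta$col) + 1)]
    expect_true(all(at))
  }
})

test_that("z-stack mode renders planes the projection collapses correctly", {
  p <- scene_params(shape = c(160L, 160L), n_puncta = 60L, nz = 3L, seed = 5)
  sc <- generate_lysosome_scene(p)
  expect_identical(dim(sc$stack$data)[2], 3L)
  expect_equal(sc$stack$z_step, 0.5)
  mip <- max_intensity_projection(sc$stack)
  expect_identical(dim(mip$data)[2], 1L)
  res <- analyze_cell_rings(sc$stack)   # projects internally
  expect_equal(sum(res$profile$f), 1, tolerance = 1e-9)
  expect_true(all(sc$truth$puncta$z %in% 1:3))
})

test_that("vacuole tables honor mix, gate and determinism", {
  tab <- generate_vacuole_table(200, c(APG = 0.5, AUT = 0.5),
                                sub_threshold_fraction = 0, seed = 8)
  cls <- classify_vacuoles(tab)
  expect_identical(cls$class, tab$true_class)   # rule recovers truth exactly

  sub <- generate_vacuole_table(100, sub_threshold_fraction = 0.3, seed = 2)
  expect_true(all(sub$diameter_um[sub$true_class == "excluded"] < 0.5))
  expect_true(all(sub$diameter_um[sub$true_class != "excluded"] >= 0.5))

  expect_identical(nrow(generate_vacuole_table(0)), 0L)
  expect_identical(generate_vacuole_table(25, seed = 4),
                   generate_vacuole_table(25, seed = 4))
  expect_error(generate_vacuole_table(-1), "n")
  expect_error(generate_vacuole_table(10, c(APG = 0.7, AUT = 0.5)),
               "class_mix")
})

test_that("band tables carry exact truth at zero noise, unbiased otherwise", {
  exact <- generate_band_table(c(ctrl = 1, trt = 2), n_lanes = 4,
                               noise_sd = 0, seed = 1)
  res <- analyze_bands(exact, control = "ctrl")
  fc <- tapply(res$per_lane$fold_change, res$per_lane$group, mean)
  expect_equal(unname(fc[["trt"]]), 2.0, tolerance = 1e-12)

  # Monte-Carlo oracle: mean estimated fold change within 5% of truth
  est <- vapply(1:200, function(i) {
    tab <- generate_band_table(c(ctrl = 1, trt = 2), n_lanes = 6,
                               noise_sd = 0.15, seed = 1000 + i)
    r <- analyze_bands(tab, control = "ctrl")
    mean(r$per_lane$fold_change[r$per_lane$group == "trt"])
  }, numeric(1))
  expect_lt(abs(mean(est) - 2) / 2, 0.05)

  expect_identical(generate_band_table(seed = 7), generate_band_table(seed = 7))
  expect_error(generate_band_table(c(a = 1, b = -2)), "positive")
})
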