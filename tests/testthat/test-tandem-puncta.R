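# LoG punctum detection and tandem-reporter classification.

gaussian_spot <- function(img, r0, c0, amp = 100, sigma = 2) {
  rows <- matrix(0:(nrow(img) - 1), nrow(img), ncol(img))
  cols <- t(matrix(0:(ncol(img) - 1), ncol(img), nrow(img)))
  img + amp * exp(-((rows - r0)^2 + (cols - c0)^2) / (2 * sigma^2))
}

test_that("detection: blank image, single spot, many spots", {
  expect_identical(nrow(detect_puncta(matrix(0, 50, 50))), 0L)

  img <- gaussian_spot(matrix(0, 100, 100), 50, 60)
  d <- detect_puncta(img, sigma = 2, threshold = 0.1)
  expect_identical(nrow(d), 1L)
  expect_lt(sqrt((d$row - 50)^2 + (d$col - 60)^2), 1)

  # 5 x 5 grid of well-separated spots on a noisy background (SNR ~ 20)
  set.seed(3)
  grid <- expand.grid(r = seq(10, 90, 20), c = seq(10, 90, 20))
  img2 <- matrix(rnorm(100 * 100, 0, 1), 100, 100)
  for (i in seq_len(nrow(grid)))
    img2 <- gaussian_spot(img2, grid$r[i], grid$c[i], amp = 20)
  d2 <- detect_puncta(pmax(img2, 0), sigma = 2, threshold = 0.2)
  expect_identical(nrow(d2), 25L)
  dist <- sqrt(outer(d2$row, grid$r, `-`)^2 + outer(d2$col, grid$c, `-`)^2)
  expect_lt(max(apply(dist, 2, min)), 1)

  expect_error(detect_puncta(matrix(0, 10, 10), sigma = -1), "sigma")
  expect_error(detect_puncta(matrix(0, 10, 10), threshold = 0), "threshold")
})

test_that("tandem rule: worked example and red-only boundary", {
  red <- data.frame(row = c(10, 40, 70), col = c(10, 40, 70))
  green <- data.frame(row = 10.5, col = 10.4)  # within radius of A only
  s <- classify_tandem(red, green, match_radius = 2)
  expect_identical(c(s$AV, s$APG, s$AL), c(3L, 1L, 2L))

  none <- classify_tandem(red[0, ], green, match_radius = 2)
  expect_identical(c(none$AV, none$APG, none$AL), c(0L, 0L, 0L))
  expect_error(classify_tandem(red, green, match_radius = 0), "match_radius")
})

test_that("greedy matching takes globally nearest pairs, each green once", {
  # two reds compete for one green; the nearer red must win
  red <- data.frame(row = c(20, 20), col = c(20, 26))
  green <- data.frame(row = 20, col = 25)
  s <- classify_tandem(red, green, match_radius = 6)
  expect_identical(s$APG, 1L)
  # with two greens both reds pair up
  green2 <- data.frame(row = c(20, 20), col = c(25, 19))
  s2 <- classify_tandem(red, green2, match_radius = 6)
  expect_identical(s2$APG, 2L)
})

test_that("AV = APG + AL holds on random inputs", {
  set.seed(5)
  for (i in 1:20) {
    nr <- sample(0:30, 1); ng <- sample(0:30, 1)
    red <- data.frame(row = runif(nr, 0, 100), col = runif(nr, 0, 100))
    green <- data.frame(row = runif(ng, 0, 100), col = runif(ng, 0, 100))
    s <- classify_tandem(red, green, match_radius = 5)
    expect_identical(s$AV, s$APG + s$AL)
    expect_gte(s$APG, 0L)
    expect_lte(s$APG, min(nrow(red), nrow(green)))
  }
})

test_that("high-SNR tandem scenes recover APG/AL within 10%", {
  p <- scene_params(n_puncta = 50L, apg_fraction = 0.4, spot_amplitude = 200,
                    seed = 11)
  sc <- generate_tandem_scene(p)   # 20 APG + 30 AL by construction
  res <- analyze_tandem_scene(sc$stack)
  expect_identical(res$summary$AV, res$summary$APG + res$summary$AL)
  expect_lte(abs(res$summary$APG - sc$truth$n_apg), 0.1 * sc$truth$n_apg)
  expect_lte(abs(res$summary$AL - sc$truth$n_al), 0.1 * sc$truth$n_al)
})

test_that("intensity green mode agrees on a clean scene", {
  p <- scene_params(n_puncta = 40L, apg_fraction = 0.5, spot_amplitude = 200,
                    seed = 12)
  sc <- generate_tandem_scene(p)
  cfg <- default_config()
  cfg$puncta$green_mode <- "intensity"
  res <- analyze_tandem_scene(sc$stack, cfg)
  expect_lte(abs(res$summary$APG - sc$truth$n_apg), 0.1 * p$n_puncta)
})

test_that("flux summaries: closed forms and generator fraction recovery", {
  one <- data.frame(cell = "c1", AV = 10L, APG = 4L, AL = 6L,
                    match_radius = 4)
  s1 <- summarize_flux(one)
  expect_equal(s1$flux, 6)

  two <- rbind(one, data.frame(cell = "c2", AV = 9L, APG = 5L, AL = 4L,
                               match_radius = 4))
  s2 <- summarize_flux(two)
  expect_equal(s2$flux, 5)
  expect_equal(s2$AL_sem, 1)
  expect_error(summarize_flux(list()), "summaries")

  # 50 simulated cells at APG fraction 0.4
  summaries <- lapply(1:50, function(i) {
    p <- scene_params(shape = c(128L, 128L), n_puncta = 20L,
                      apg_fraction = 0.4, spot_amplitude = 200,
                      cell_radius_frac = 0.45, seed = 400 + i)
    sc <- generate_tandem_scene(p)
    analyze_tandem_scene(sc$stack, cell_id = paste0("c", i))$summary
  })
  agg <- summarize_flux(summaries)
  expect_lt(abs(agg$apg_fraction - 0.4), 0.05)
})
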