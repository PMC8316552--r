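# Shared fixtures, all built in code.

# centered disk cell with concentric disk nucleus; exact geometry with a
# closed-form equal-area solution
disk_geometry <- function(R = 100, Rn = 25, pad = 10) {
  n <- 2 * (R + pad) + 1
  ctr <- (n - 1) / 2
  rows <- matrix(seq_len(n) - 1, n, n)
  cols <- t(rows)
  d2 <- (rows - ctr)^2 + (cols - ctr)^2
  cell_geometry(d2 <= R^2, d2 <= Rn^2)
}

# small, fast scene parameter sets for tests
small_lysosome_params <- function(seed = 1, ...) {
  scene_params(shape = c(160L, 160L), n_puncta = 60L, seed = seed, ...)
}

small_tandem_params <- function(seed = 1, n_puncta = 30L, ...) {
  scene_params(shape = c(160L, 160L), n_puncta = n_puncta,
               spot_amplitude = 200, seed = seed, ...)
}

# random star-shaped mask with a random interior centroid, for the
# equal-area property tests
random_star_geometry <- function(seed, n = 140) {
  set.seed(seed)
  ctr <- (n - 1) / 2
  R <- 0.38 * n
  rows <- matrix(seq_len(n) - 1, n, n)
  cols <- t(rows)
  theta <- atan2(rows - ctr, cols - ctr)
  rad <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  m <- 2:5
  amp <- runif(4, 0, 0.15)
  phi <- runif(4, 0, 2 * pi)
  mod <- Reduce(`+`, lapply(seq_along(m), function(i)
    amp[i] * cos(m[i] * theta + phi[i])))
  cell <- rad <= R * (1 + mod)
  # random nucleus center well inside the cell
  repeat {
    off <- runif(2, -0.2 * R, 0.2 * R)
    nd2 <- (rows - ctr - off[1])^2 + (cols - ctr - off[2])^2
    nuc <- nd2 <= (0.22 * R)^2
    if (all(cell[nuc])) break
  }
  cell_geometry(cell, nuc)
}

expect_valid_geometry <- function(g) {
  expect_s3_class(g, "CellGeometry")
  expect_true(all(g$cell_mask[g$nucleus_mask]))
  ci <- round(g$centroid) + 1
  expect_true(g$cell_mask[ci[1], ci[2]])
  expect_equal(g$cell_area, sum(g$cell_mask))
}

python_bin <- function() Sys.which("python")

# one-row vacuole annotation table with explicit criteria
vacuole_row <- function(diameter, apg = rep(FALSE, 4), aut = rep(FALSE, 3),
                        cell = "cell1", id = "v1") {
  df <- data.frame(vacuole = id, cell = cell, diameter_um = diameter,
                   area_um2 = pi * (diameter / 2)^2,
                   stringsAsFactors = FALSE)
  nm <- c("double_membrane", "no_attached_ribosomes",
          "luminal_density_similar_to_cytosol",
          "identifiable_organelles_in_lumen",
          "single_membrane_or_lt40pct_double",
          "luminal_density_lower_than_cytosol",
          "multivesicular_amorphous_content")
  for (j in 1:4) df[[nm[j]]] <- apg[j]
  for (j in 1:3) df[[nm[4 + j]]] <- aut[j]
  df
}
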