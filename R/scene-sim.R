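# Synthetic fluorescence scenes and annotation tables with full ground
# truth. The generator emulates the package's real inputs -- single cells
# with a nucleus, marker puncta placed with a controllable radial bias,
# two-channel tandem-reporter puncta, smooth background plus shot noise,
# and per-vacuole / band-intensity tables -- so every analysis stage can
# be verified without microscope data.

#' Synthetic scene parameters
#'
#' Defaults describe a realistic confocal acquisition of one cultured cell:
#' a 256 x 256 field at 0.05 um/px (the 50 nm lateral voxel of a 63x
#' confocal stack), a mildly lobed star-shaped cell filling ~80% of the
#' field, a round nucleus of a quarter of the cell radius, diffraction-
#' limited puncta (Gaussian sigma 2 px ~ 100 nm), camera background with a
#' weak illumination gradient, Poisson shot noise and Gaussian read noise.
#'
#' @param shape image size `c(rows, cols)` in px.
#' @param pixel_size um per px.
#' @param cell_shape `"disk"`, `"ellipse"` or `"star"` (radial harmonics).
#' @param cell_radius_frac cell radius as a fraction of `min(shape)`.
#' @param nucleus_radius_frac nucleus radius as a fraction of cell radius.
#' @param n_puncta marker puncta per scene.
#' @param spot_sigma Gaussian width of a punctum, px.
#' @param spot_amplitude peak amplitude of a punctum.
#' @param ring_weights length-4 non-negative placement probabilities per
#'   target ring (ring 1 = peripheral .. ring 4 = perinuclear); must sum
#'   to 1.
#' @param apg_fraction fraction of dual-positive (autophagosome) puncta in
#'   tandem scenes.
#' @param min_separation minimum distance between punctum centers, px
#'   (`NA` = 4 * `spot_sigma` for tandem scenes, 0 for lysosome scenes).
#' @param background constant background level.
#' @param gradient_amplitude peak-to-corner amplitude of a smooth linear
#'   illumination gradient.
#' @param poisson_noise apply Poisson shot noise to the signal.
#' @param read_noise_sd Gaussian read-noise sigma.
#' @param nz number of z planes (1 = single projected plane; > 1 renders a
#'   stack with the anisotropic 500 nm z step to exercise projection).
#' @param z_step um between planes.
#' @param seed integer random seed; fixed seed gives bit-identical scenes.
#' @return object of class `SceneParams` (named list, validated).
#' @export
scene_params <- function(shape = c(256L, 256L), pixel_size = 0.05,
                         cell_shape = "star", cell_radius_frac = 0.42,
                         nucleus_radius_frac = 0.25,
                         n_puncta = 120L, spot_sigma = 2.0,
                         spot_amplitude = 100,
                         ring_weights = c(0.25, 0.25, 0.25, 0.25),
                         apg_fraction = 0.5, min_separation = NA_real_,
                         background = 5, gradient_amplitude = 2,
                         poisson_noise = TRUE, read_noise_sd = 1,
                         nz = 1L, z_step = 0.5, seed = 1L) {
  p <- list(shape = as.integer(shape), pixel_size = pixel_size,
            cell_shape = match.arg(cell_shape, c("disk", "ellipse", "star")),
            cell_radius_frac = cell_radius_frac,
            nucleus_radius_frac = nucleus_radius_frac,
            n_puncta = as.integer(n_puncta), spot_sigma = spot_sigma,
            spot_amplitude = spot_amplitude,
            ring_weights = as.numeric(ring_weights),
            apg_fraction = apg_fraction, min_separation = min_separation,
            background = background, gradient_amplitude = gradient_amplitude,
            poisson_noise = isTRUE(poisson_noise),
            read_noise_sd = read_noise_sd, nz = as.integer(nz),
            z_step = z_step, seed = as.integer(seed))
  validate_scene_params(p)
  structure(p, class = "SceneParams")
}

validate_scene_params <- function(p) {
  if (length(p$shape) != 2 || any(p$shape <= 0))
    stop("`shape` must be two positive integers", call. = FALSE)
  w <- p$ring_weights
  if (length(w) != 4 || any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("`ring_weights` must be 4 non-negative values summing to 1",
         call. = FALSE)
  if (p$n_puncta < 0) stop("`n_puncta` must be >= 0", call. = FALSE)
  if (p$spot_sigma <= 0) stop("`spot_sigma` must be > 0", call. = FALSE)
  if (p$apg_fraction < 0 || p$apg_fraction > 1)
    stop("`apg_fraction` must lie in [0, 1]", call. = FALSE)
  if (p$nz < 1) stop("`nz` must be >= 1", call. = FALSE)
  invisible(p)
}

# run code with the global RNG seeded locally, restoring any previous
# state afterwards -- generators never leak RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Geometry -------------------------------------------------------------

# rasterize the cell and nucleus; star cells use low-order radial
# harmonics r(theta) = R (1 + sum a_m cos(m theta + phi_m))
simulate_cell_masks <- function(p) {
  nr <- p$shape[1]; nc <- p$shape[2]
  ctr <- c((nr - 1) / 2, (nc - 1) / 2)
  R <- p$cell_radius_frac * min(nr, nc)
  rows <- matrix(seq_len(nr) - 1, nr, nc)
  cols <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  dy <- rows - ctr[1]; dx <- cols - ctr[2]
  rad <- sqrt(dy^2 + dx^2)
  theta <- atan2(dy, dx)
  boundary <- switch(p$cell_shape,
    disk = matrix(R, nr, nc),
    ellipse = {
      ecc <- stats::runif(1, 0.6, 0.85)
      phi <- stats::runif(1, 0, pi)
      a <- R / sqrt(ecc); b <- R * sqrt(ecc)
      th <- theta - phi
      a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
    },
    star = {
      m <- 2:5
      amp <- stats::runif(4, 0, 0.12)
      phi <- stats::runif(4, 0, 2 * pi)
      mod <- Reduce(`+`, lapply(seq_along(m), function(i)
        amp[i] * cos(m[i] * theta + phi[i])))
      R * (1 + mod)
    })
  cell <- rad <= boundary
  # nucleus: disk, offset a little from the cell center but kept inside
  Rn <- p$nucleus_radius_frac * R
  off <- stats::runif(2, -0.15 * R, 0.15 * R)
  nctr <- ctr + off
  nucleus <- (rows - nctr[1])^2 + (cols - nctr[2])^2 <= Rn^2
  nucleus <- nucleus & cell
  list(cell = cell, nucleus = nucleus)
}

## Rendering ------------------------------------------------------------

# add isotropic 2-D Gaussian spots, truncated at 4 sigma, onto `img`
render_spots <- function(img, centers, amplitude, sigma) {
  if (nrow(centers) == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  w <- ceiling(4 * sigma)
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]
    rs <- max(1, floor(r0 - w) + 1):min(nr, ceiling(r0 + w) + 1)
    cs <- max(1, floor(c0 - w) + 1):min(nc, ceiling(c0 + w) + 1)
    d2 <- outer((rs - 1 - r0)^2, (cs - 1 - c0)^2, `+`)
    g <- amplitude * exp(-d2 / (2 * sigma^2))
    g[d2 > (4 * sigma)^2] <- 0
    img[rs, cs] <- img[rs, cs] + g
  }
  img
}

smooth_background <- function(p) {
  nr <- p$shape[1]; nc <- p$shape[2]
  rows <- matrix(seq_len(nr) - 1, nr, nc) / max(1, nr - 1)
  cols <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE) / max(1, nc - 1)
  cf <- stats::runif(3, -1, 1)
  grad <- cf[1] * rows + cf[2] * cols + cf[3] * rows * cols
  grad <- grad - min(grad)
  if (max(grad) > 0) grad <- grad / max(grad)
  p$background + p$gradient_amplitude * grad
}

apply_noise <- function(img, p) {
  if (p$poisson_noise) {
    lam <- pmax(img, 0)
    img <- matrix(stats::rpois(length(lam), lam), nrow(img), ncol(img))
  }
  if (p$read_noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, p$read_noise_sd),
                        nrow(img), ncol(img))
  pmax(img, 0)
}

# sample punctum centers: ring index per the placement law, then a uniform
# pixel of that true ring plus sub-pixel jitter
sample_punctum_centers <- function(p, partition, n = p$n_puncta,
                                   min_sep = 0) {
  ring_pixels <- lapply(seq_len(partition$n_rings), function(k)
    which(partition$labels == k, arr.ind = TRUE))
  rings <- sample.int(4L, n, replace = TRUE, prob = p$ring_weights)
  centers <- matrix(0, n, 2)
  taken <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    for (attempt in 1:200) {
      px <- ring_pixels[[rings[i]]]
      j <- sample.int(nrow(px), 1)
      cand <- c(px[j, 1] - 1 + stats::runif(1, -0.5, 0.5),
                px[j, 2] - 1 + stats::runif(1, -0.5, 0.5))
      if (min_sep <= 0 || nrow(taken) == 0 ||
          min(sqrt((taken[, 1] - cand[1])^2 + (taken[, 2] - cand[2])^2)) >=
            min_sep) break
    }
    centers[i, ] <- cand
    taken <- rbind(taken, cand)
  }
  list(centers = centers, rings = rings)
}

## Scene generators -----------------------------------------------------

#' Generate a synthetic lysosome-distribution scene
#'
#' Renders a three-channel cell image (`dapi` = nucleus fill, `marker` =
#' puncta, `tracer` = cell fill) with puncta placed by first sampling a
#' target ring from the radial-placement law and then a uniform position
#' inside that ring of the true equal-area partition of the true geometry.
#' The ground truth records the realized per-ring intensity fractions of
#' the clean (noise- and background-free) marker image.
#'
#' @param params a [scene_params()].
#' @return list with `stack` (an `ImageStack`) and `truth` (class
#'   `SceneGroundTruth`): `cell_mask`, `nucleus_mask`, `centroid`,
#'   `partition`, `puncta` (data frame `row`, `col`, `ring`, `channel`),
#'   `ring_fractions` (length 4), `params`.
#' @export
generate_lysosome_scene <- function(params) {
  validate_scene_params(params)
  p <- params
  with_seed(p$seed, {
    masks <- simulate_cell_masks(p)
    geom <- cell_geometry(masks$cell, masks$nucleus, p$pixel_size)
    part <- compute_ring_partition(geom, 4)
    sp <- sample_punctum_centers(p, part,
                                 min_sep = if (is.na(p$min_separation)) 0
                                           else p$min_separation)
    nr <- p$shape[1]; nc <- p$shape[2]

    clean_marker <- matrix(0, nr, nc)
    if (p$nz > 1) {
      zs <- sample.int(p$nz, p$n_puncta, replace = TRUE)
      planes <- lapply(seq_len(p$nz), function(zi)
        render_spots(matrix(0, nr, nc),
                     sp$centers[zs == zi, , drop = FALSE],
                     p$spot_amplitude, p$spot_sigma))
      clean_marker <- Reduce(pmax, planes)
    } else {
      zs <- rep(1L, p$n_puncta)
      planes <- list(render_spots(clean_marker, sp$centers,
                                  p$spot_amplitude, p$spot_sigma))
      clean_marker <- planes[[1]]
    }

    in_cell <- sum(clean_marker[part$labels > 0])
    ring_fractions <- vapply(1:4, function(k)
      sum(clean_marker[part$labels == k]) / in_cell, numeric(1))

    bg <- smooth_background(p)
    dapi <- gaussian_blur(masks$nucleus * 80, 1.5)
    tracer <- gaussian_blur(masks$cell * 60, 1.5)

    data <- array(0, c(3, p$nz, nr, nc))
    for (zi in seq_len(p$nz)) {
      data[1, zi, , ] <- apply_noise(dapi + bg, p)
      data[2, zi, , ] <- apply_noise(planes[[zi]] + bg, p)
      data[3, zi, , ] <- apply_noise(tracer + bg, p)
    }
    stack <- image_stack(data, channels = c("dapi", "marker", "tracer"),
                         pixel_size = p$pixel_size,
                         z_step = if (p$nz > 1) p$z_step else NA_real_,
                         provenance = sprintf("simulated lysosome scene (seed %d)",
                                              p$seed))
    truth <- structure(list(
      cell_mask = masks$cell, nucleus_mask = masks$nucleus,
      centroid = geom$centroid, partition = part,
      puncta = data.frame(row = sp$centers[, 1], col = sp$centers[, 2],
                          z = zs, ring = sp$rings, channel = "marker",
                          stringsAsFactors = FALSE),
      ring_fractions = ring_fractions, params = p), class = "SceneGroundTruth")
    list(stack = stack, truth = truth)
  })
}

#' Generate a synthetic tandem mCherry-GFP-LC3 scene
#'
#' Every punctum appears in the red (mCherry) channel; a deterministic
#' count `round(apg_fraction * n_puncta)` of them (autophagosomes) also
#' appears in green (GFP) at the same position. Red-only puncta emulate
#' autolysosomes, whose acidic lumen quenches GFP.
#'
#' @param params a [scene_params()]; `apg_fraction` and `n_puncta` control
#'   the composition.
#' @return list with `stack` (channels `red`, `green`) and `truth`
#'   (`puncta` has a logical `apg` column; `n_apg`/`n_al` counts).
#' @export
generate_tandem_scene <- function(params) {
  validate_scene_params(params)
  p <- params
  with_seed(p$seed, {
    masks <- simulate_cell_masks(p)
    geom <- cell_geometry(masks$cell, masks$nucleus, p$pixel_size)
    part <- compute_ring_partition(geom, 4)
    min_sep <- if (is.na(p$min_separation)) 4 * p$spot_sigma else p$min_separation
    sp <- sample_punctum_centers(p, part, min_sep = min_sep)
    n <- p$n_puncta
    n_apg <- round(p$apg_fraction * n)
    apg <- rep(FALSE, n)
    if (n_apg > 0) apg[sample.int(n, n_apg)] <- TRUE

    nr <- p$shape[1]; nc <- p$shape[2]
    red <- render_spots(matrix(0, nr, nc), sp$centers,
                        p$spot_amplitude, p$spot_sigma)
    green <- render_spots(matrix(0, nr, nc),
                          sp$centers[apg, , drop = FALSE],
                          p$spot_amplitude, p$spot_sigma)
    bg <- smooth_background(p)
    data <- array(0, c(2, 1, nr, nc))
    data[1, 1, , ] <- apply_noise(red + bg, p)
    data[2, 1, , ] <- apply_noise(green + bg, p)
    stack <- image_stack(data, channels = c("red", "green"),
                         pixel_size = p$pixel_size,
                         provenance = sprintf("simulated tandem scene (seed %d)",
                                              p$seed))
    truth <- structure(list(
      cell_mask = masks$cell, nucleus_mask = masks$nucleus,
      centroid = geom$centroid, partition = part,
      puncta = data.frame(row = sp$centers[, 1], col = sp$centers[, 2],
                          ring = sp$rings, apg = apg,
                          stringsAsFactors = FALSE),
      n_apg = sum(apg), n_al = n - sum(apg), params = p),
      class = "SceneGroundTruth")
    list(stack = stack, truth = truth)
  })
}

#' Generate a synthetic per-vacuole annotation table
#'
#' Emulates the per-vacuole observations of a TEM morphometric analysis.
#' True autophagosome (APG) rows satisfy at least two of the four APG
#' criteria and no autolysosome criterion; true autolysosome (AUT) rows
#' satisfy at least one AUT criterion and at most one APG criterion. A
#' stated fraction of vacuoles is drawn below the 0.5 um diameter gate
#' (true class `excluded`).
#'
#' @param n number of vacuoles.
#' @param class_mix named proportions for `APG` and `AUT` (must sum to 1).
#' @param sub_threshold_fraction fraction of vacuoles below the size gate.
#' @param n_cells number of cells the vacuoles are spread over.
#' @param seed integer seed.
#' @return data frame with one row per vacuole: ids, `diameter_um`,
#'   `area_um2`, the seven criterion booleans, and `true_class`.
#' @export
generate_vacuole_table <- function(n, class_mix = c(APG = 0.5, AUT = 0.5),
                                   sub_threshold_fraction = 0.1,
                                   n_cells = 4, seed = 1L) {
  if (n < 0) stop("`n` must be >= 0", call. = FALSE)
  if (abs(sum(class_mix) - 1) > 1e-9 || any(class_mix < 0))
    stop("`class_mix` proportions must be non-negative and sum to 1",
         call. = FALSE)
  cols <- c("double_membrane", "no_attached_ribosomes",
            "luminal_density_similar_to_cytosol",
            "identifiable_organelles_in_lumen",
            "single_membrane_or_lt40pct_double",
            "luminal_density_lower_than_cytosol",
            "multivesicular_amorphous_content")
  empty <- data.frame(vacuole = character(), cell = character(),
                      diameter_um = numeric(), area_um2 = numeric(),
                      stringsAsFactors = FALSE)
  for (cn in cols) empty[[cn]] <- logical()
  empty$true_class <- character()
  if (n == 0) return(empty)

  with_seed(seed, {
    true_class <- sample(names(class_mix), n, replace = TRUE,
                         prob = class_mix)
    sub <- stats::runif(n) < sub_threshold_fraction
    # sizes: lognormal around ~0.9 um for APG, ~1.3 um for AUT (typical
    # mature vacuoles are larger); sub-gate vesicles uniform in 0.2-0.45 um
    diameter <- ifelse(true_class == "APG",
                       stats::rlnorm(n, log(0.9), 0.25),
                       stats::rlnorm(n, log(1.3), 0.25))
    diameter <- pmax(diameter, 0.55)
    diameter[sub] <- stats::runif(sum(sub), 0.2, 0.45)

    apg_crit <- matrix(FALSE, n, 4)
    aut_crit <- matrix(FALSE, n, 3)
    for (i in seq_len(n)) {
      if (true_class[i] == "APG") {
        k <- sample(2:4, 1, prob = c(0.5, 0.35, 0.15))
        apg_crit[i, sample.int(4, k)] <- TRUE
      } else {
        k <- sample(1:3, 1, prob = c(0.5, 0.35, 0.15))
        aut_crit[i, sample.int(3, k)] <- TRUE
        if (stats::runif(1) < 0.3) apg_crit[i, sample.int(4, 1)] <- TRUE
      }
    }
    true_class[sub] <- "excluded"

    out <- data.frame(
      vacuole = sprintf("v%03d", seq_len(n)),
      cell = sprintf("cell%d", 1 + (seq_len(n) - 1) %% n_cells),
      diameter_um = diameter, area_um2 = pi * (diameter / 2)^2,
      stringsAsFactors = FALSE)
    for (j in 1:4) out[[cols[j]]] <- apg_crit[, j]
    for (j in 1:3) out[[cols[4 + j]]] <- aut_crit[, j]
    out$true_class <- true_class
    out
  })
}

#' Generate a synthetic densitometry band table
#'
#' Emulates immunoblot band intensities for several groups of lanes with
#' known true fold changes of the marker/loading-control ratio relative to
#' the first (control) group. Multiplicative lognormal noise models
#' lane-to-lane variability.
#'
#' @param fold_changes named numeric vector, one true fold change per
#'   group; the first entry is the control and is conventionally 1.
#' @param n_lanes lanes (replicates) per group.
#' @param noise_sd sigma of the lognormal multiplicative noise (0 = exact).
#' @param seed integer seed.
#' @return data frame `lane`, `group`, `marker`, `loading`; the true fold
#'   changes are attached as attribute `true_fold`.
#' @export
generate_band_table <- function(fold_changes = c(control = 1, treated = 2),
                                n_lanes = 6, noise_sd = 0.1, seed = 1L) {
  if (any(fold_changes <= 0))
    stop("true fold changes must be positive", call. = FALSE)
  if (n_lanes < 1) stop("`n_lanes` must be >= 1", call. = FALSE)
  with_seed(seed, {
    groups <- rep(names(fold_changes), each = n_lanes)
    n <- length(groups)
    loading <- stats::rlnorm(n, log(100), 0.15)  # loading varies per lane
    base_ratio <- 0.8
    noise <- if (noise_sd > 0) stats::rlnorm(n, 0, noise_sd) else rep(1, n)
    marker <- loading * base_ratio * fold_changes[groups] * noise
    out <- data.frame(lane = sprintf("lane%02d", seq_len(n)), group = groups,
                      marker = as.numeric(marker), loading = loading,
                      stringsAsFactors = FALSE)
    attr(out, "true_fold") <- fold_changes
    out
  })
}

#' Write a simulated scene to disk
#'
#' Stack as multi-channel TIFF, masks as 8-bit TIFFs, punctum ground truth
#' as CSV and the generator parameters as a JSON sidecar.
#' @param scene result of [generate_lysosome_scene()] or
#'   [generate_tandem_scene()].
#' @param dir output directory (created if missing).
#' @param name basename for the scene files.
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    stack = file.path(dir, paste0(name, ".tif")),
    cell = file.path(dir, paste0(name, "_cell_mask.tif")),
    nucleus = file.path(dir, paste0(name, "_nucleus_mask.tif")),
    puncta = file.path(dir, paste0(name, "_puncta.csv")),
    params = file.path(dir, paste0(name, "_params.json")))
  write_stack(scene$stack, paths[["stack"]])
  write_mask(scene$truth$cell_mask, paths[["cell"]])
  write_mask(scene$truth$nucleus_mask, paths[["nucleus"]])
  write_table_csv(scene$truth$puncta, paths[["puncta"]])
  pj <- scene$truth$params
  class(pj) <- NULL
  jsonlite::write_json(pj, paths[["params"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
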