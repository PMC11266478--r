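#' Parametric vegetation endmember
#'
#' A canopy reflectance spectrum built from the canonical visible-NIR
#' features: a green reflectance peak near 550 nm, a chlorophyll-absorption
#' red valley near 680 nm, a logistic red edge rising to a NIR plateau, and
#' a water-absorption dip near 960 nm.
#'
#' @param base_vis visible baseline reflectance.
#' @param green_peak_amp,green_peak_width_nm Gaussian green-peak amplitude / sd.
#' @param red_valley_depth,red_valley_width_nm Gaussian absorption at 680 nm.
#' @param red_edge_pos_nm,red_edge_width_nm logistic midpoint / scale.
#' @param nir_plateau plateau reflectance level (must exceed `base_vis`).
#' @param water_dip_depth,water_dip_width_nm Gaussian absorption at 960 nm.
#' @return object of class `endmember_params`.
#' @export
endmember_params <- function(base_vis = 0.05,
                             green_peak_amp = 0.07, green_peak_width_nm = 25,
                             red_valley_depth = 0.04, red_valley_width_nm = 18,
                             red_edge_pos_nm = 720, red_edge_width_nm = 12,
                             nir_plateau = 0.50,
                             water_dip_depth = 0.08, water_dip_width_nm = 30) {
  p <- list(base_vis = base_vis,
            green_peak_amp = green_peak_amp,
            green_peak_width_nm = green_peak_width_nm,
            red_valley_depth = red_valley_depth,
            red_valley_width_nm = red_valley_width_nm,
            red_edge_pos_nm = red_edge_pos_nm,
            red_edge_width_nm = red_edge_width_nm,
            nir_plateau = nir_plateau,
            water_dip_depth = water_dip_depth,
            water_dip_width_nm = water_dip_width_nm)
  if (p$nir_plateau + p$base_vis <= p$base_vis) stop("NIR plateau must exceed the visible baseline")
  structure(p, class = "endmember_params")
}

#' Evaluate an endmember on a spectral axis
#'
#' \deqn{\rho(\lambda) = clip(base + g\,N(550) - v\,N(680) +
#'   plateau\,logistic((\lambda - edge)/width) - dip\,N(960),\ 0,\ 1)}
#'
#' The default parameters yield the vegetation template ordering: a local
#' maximum in 530-570 nm, a local minimum in 660-700 nm, and the global
#' maximum on the 740-930 nm NIR shoulder.
#'
#' @param params an [endmember_params].
#' @param axis a [spectral_axis] covering 400-1000 nm.
#' @return per-band reflectance in [0, 1].
#' @export
make_endmember <- function(params = endmember_params(), axis) {
  stopifnot(inherits(params, "endmember_params"))
  w <- as.numeric(axis)
  if (min(w) > 400 || max(w) < 1000) {
    stop("axis must cover 400-1000 nm for a vegetation endmember")
  }
  gauss <- function(mu, sd) exp(-((w - mu)^2) / (2 * sd^2))
  s <- params$base_vis +
    params$green_peak_amp * gauss(550, params$green_peak_width_nm) -
    params$red_valley_depth * gauss(680, params$red_valley_width_nm) +
    params$nir_plateau * stats::plogis((w - params$red_edge_pos_nm) /
                                         params$red_edge_width_nm) -
    params$water_dip_depth * gauss(960, params$water_dip_width_nm)
  pmin(pmax(s, 0), 1)
}

#' Default 14-treatment specification
#'
#' Fourteen nutrient-stress treatment classes (A..N) derived from one common
#' vegetation template. The classes mimic an NPK factorial qualitatively:
#' each treatment's N/P/K levels (0 = extreme deficit, 1 = low, 2 = normal,
#' 3 = excess) shift the endmember parameters in directions consistent with
#' field observations — nitrogen deficit raises green/red reflectance and
#' lowers the NIR plateau, phosphorus stress shifts the red edge and NIR
#' level, potassium stress deepens the water dip. A small seeded jitter adds
#' idiosyncratic class character. All offsets scale linearly with
#' `separability`; at 0 the classes are identical.
#'
#' @param separability nonnegative scalar scaling inter-class spread.
#' @param seed integer seed for the jitter component.
#' @return list of 14 treatment specs, each a list with `class_id`, `name`,
#'   `endmember` ([endmember_params]) and `within_class_sd`.
#' @export
default_treatments <- function(separability = 1, seed = 1) {
  if (separability < 0) stop("separability must be nonnegative")
  # treatment codes: N, P, K levels per class A..N (2 = reference level)
  lv <- list(A = c(0, 0, 2), B = c(0, 2, 2), C = c(1, 2, 2), D = c(2, 0, 2),
             E = c(2, 1, 2), F = c(2, 2, 2), G = c(2, 3, 2), H = c(2, 2, 0),
             I = c(2, 2, 1), J = c(2, 2, 3), K = c(3, 2, 2), L = c(1, 1, 2),
             M = c(1, 2, 1), N = c(2, 1, 1))
  nm <- names(lv)
  labels <- vapply(seq_along(lv), function(i)
    sprintf("%s (N%dP%dK%d)", nm[i], lv[[i]][1], lv[[i]][2], lv[[i]][3]),
    character(1))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  jit <- matrix(stats::rnorm(14 * 4, sd = 0.2), 14, 4)
  tmpl <- endmember_params()
  out <- vector("list", 14)
  for (i in seq_along(lv)) {
    dn <- lv[[i]][1] - 2; dp <- lv[[i]][2] - 2; dk <- lv[[i]][3] - 2
    s <- separability
    p <- tmpl
    # N deficit (dn < 0): chlorotic canopy -> brighter green/red, darker NIR.
    # Multiplicative factors are clamped at small positive values so extreme
    # separability settings keep the endmember parameters physically valid.
    clamp <- function(x, lo = 0.02) pmax(x, lo)
    p$green_peak_amp   <- tmpl$green_peak_amp   * clamp(1 - s * (0.22 * dn + 0.05 * jit[i, 1]))
    p$red_valley_depth <- tmpl$red_valley_depth * clamp(1 + s * (0.28 * dn - 0.05 * jit[i, 2]))
    p$nir_plateau      <- tmpl$nir_plateau      * clamp(1 + s * (0.10 * dn + 0.04 * dp + 0.03 * jit[i, 3]), 0.15)
    # P stress: red-edge shift and slight baseline change
    p$red_edge_pos_nm  <- tmpl$red_edge_pos_nm + s * (3.0 * dp + 1.0 * jit[i, 4])
    p$base_vis         <- tmpl$base_vis * clamp(1 - s * 0.05 * dp)
    # K stress: water-status dip
    p$water_dip_depth  <- tmpl$water_dip_depth * clamp(1 - s * (0.20 * dk - 0.05 * jit[i, 1]))
    out[[i]] <- list(class_id = i, name = labels[i], endmember = p,
                     within_class_sd = 0.12)
  }
  out
}

#' Synthetic scene configuration
#'
#' Defines a labelled canopy scene: spatially contiguous single-class plots
#' over a non-vegetation background (water and soil archetypes). Defaults
#' emulate the geometry of a 204-band visible-NIR sensor.
#'
#' @param height,width scene size in pixels.
#' @param n_bands number of spectral bands (default 204).
#' @param wavelength_range_nm length-2 numeric, default c(400, 1000).
#' @param treatments list of treatment specs ([default_treatments()]).
#' @param background_fraction approximate fraction of background pixels.
#' @param plot_layout `"grid"` (rectangular plots) or `"voronoi"`.
#' @param sensor_noise_sd additive Gaussian band noise sd (default 0.01).
#' @param separability passed to [default_treatments()] when `treatments`
#'   is not supplied.
#' @param seed integer seed; identical (config, seed) pairs regenerate
#'   bit-identical scenes.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(height = 64, width = 64, n_bands = 204,
                         wavelength_range_nm = c(400, 1000),
                         treatments = NULL, background_fraction = 0.15,
                         plot_layout = c("grid", "voronoi"),
                         sensor_noise_sd = 0.01, separability = 1,
                         seed = 1) {
  plot_layout <- match.arg(plot_layout)
  if (background_fraction < 0 || background_fraction >= 1) {
    stop("background_fraction must lie in [0, 1)")
  }
  if (is.null(treatments)) treatments <- default_treatments(separability, seed = seed)
  ids <- vapply(treatments, `[[`, numeric(1), "class_id")
  if (anyDuplicated(ids)) stop("treatment class_ids must be unique")
  structure(list(height = height, width = width, n_bands = n_bands,
                 wavelength_range_nm = wavelength_range_nm,
                 treatments = treatments,
                 background_fraction = background_fraction,
                 plot_layout = plot_layout,
                 sensor_noise_sd = sensor_noise_sd,
                 separability = separability, seed = seed),
            class = "scene_config")
}

# Partition the image plane into a background frame plus contiguous plots.
# Returns an integer matrix: 0 background, 1..Z plots.
scene_layout <- function(config) {
  h <- config$height; w <- config$width
  z <- length(config$treatments)
  lab <- matrix(0L, h, w)
  # border frame sized to hit the background fraction
  bf <- config$background_fraction
  t_frame <- 0L
  if (bf > 0) {
    # solve (1 - (h-2t)(w-2t)/(hw)) ~= bf for the frame width t
    t_frame <- max(1L, round((h + w - sqrt((h + w)^2 - 4 * bf * h * w)) / 4))
  }
  r0 <- t_frame + 1L; r1 <- h - t_frame; c0 <- t_frame + 1L; c1 <- w - t_frame
  ih <- r1 - r0 + 1L; iw <- c1 - c0 + 1L
  if (ih < z || iw < 1) stop("scene too small for the requested treatments")
  if (config$plot_layout == "grid") {
    # factor pair closest to square with rows*cols >= z
    rows <- max(1L, floor(sqrt(z)))
    while (z %% rows != 0 && rows > 1) rows <- rows - 1L
    cols <- z %/% rows
    if (rows * cols < z) { rows <- ceiling(sqrt(z)); cols <- ceiling(z / rows) }
    rb <- floor(seq(0, ih, length.out = rows + 1))
    cb <- floor(seq(0, iw, length.out = cols + 1))
    k <- 0L
    for (i in seq_len(rows)) for (j in seq_len(cols)) {
      k <- k + 1L
      if (k > z) next # leftover cells stay background
      lab[(r0 + rb[i]):(r0 + rb[i + 1] - 1), (c0 + cb[j]):(c0 + cb[j + 1] - 1)] <- k
    }
  } else {
    centers <- cbind(stats::runif(z, r0, r1), stats::runif(z, c0, c1))
    rr <- rep(r0:r1, times = iw); cc <- rep(c0:c1, each = ih)
    d <- outer(rr, centers[, 1], function(a, b) (a - b)^2) +
         outer(cc, centers[, 2], function(a, b) (a - b)^2)
    lab[cbind(rr, cc)] <- max.col(-d)
  }
  lab
}

background_archetypes <- function(w) {
  wn <- (w - min(w)) / diff(range(w))
  list(water = 0.08 - 0.06 * wn,           # monotone decreasing, low NIR
       soil  = 0.06 + 0.24 * wn)           # monotone increasing, low curvature
}

#' Generate a labelled synthetic canopy scene
#'
#' Pixel spectra are the class endmember scaled by a pixel-level lognormal
#' biological-variability factor (median 1, log-sd `within_class_sd`), plus
#' independent additive Gaussian sensor noise per band, clipped to [0, 1].
#' Background pixels carry water/soil archetype spectra and label 0; the
#' vegetation mask equals `label > 0`.
#'
#' @param config a [scene_config].
#' @return list with elements `cube` ([hsi_cube]), `labels` ([label_map])
#'   and `mask` (logical matrix).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  if (length(config$treatments) == 0) stop("no treatments configured")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  axis <- spectral_axis(seq(config$wavelength_range_nm[1],
                            config$wavelength_range_nm[2],
                            length.out = config$n_bands))
  w <- as.numeric(axis)
  lab <- scene_layout(config)
  h <- config$height; wd <- config$width; nb <- config$n_bands
  npix <- h * wd
  ems <- vapply(config$treatments, function(tr) make_endmember(tr$endmember, axis),
                numeric(nb)) # nb x Z
  sds <- vapply(config$treatments, `[[`, numeric(1), "within_class_sd")
  bg <- background_archetypes(w)

  flat <- matrix(0, npix, nb)
  labv <- as.vector(lab)
  bg_idx <- which(labv == 0L)
  if (length(bg_idx)) {
    # contiguous background split: water on the upper half, soil below
    rows <- ((bg_idx - 1L) %% h) + 1L
    is_water <- rows <= h / 2
    flat[bg_idx[is_water], ]  <- matrix(bg$water, sum(is_water), nb, byrow = TRUE)
    flat[bg_idx[!is_water], ] <- matrix(bg$soil, sum(!is_water), nb, byrow = TRUE)
  }
  for (k in seq_along(config$treatments)) {
    idx <- which(labv == k)
    if (!length(idx)) next
    fac <- exp(stats::rnorm(length(idx), 0, sds[k])) # lognormal, median 1
    flat[idx, ] <- fac %o% ems[, k]
  }
  if (config$sensor_noise_sd > 0) {
    flat <- flat + matrix(stats::rnorm(npix * nb, 0, config$sensor_noise_sd),
                          npix, nb)
  }
  flat <- pmin(pmax(flat, 0), 1)

  cube <- hsi_cube(array(flat, c(h, wd, nb)), axis, kind = "reflectance",
                   metadata = list(generator = "hsistress synthetic scene",
                                   seed = as.character(config$seed)))
  lm <- label_map(lab, vapply(config$treatments, `[[`, character(1), "name"))
  list(cube = cube, labels = lm, mask = lab > 0L)
}

#' Generate a multi-scene, two-"year" dataset
#'
#' Draws `n_scenes` independent scenes (seeds derived deterministically from
#' the config seed) and applies a global multiplicative illumination drift
#' `(1 + year_shift)` to the second half of the scenes, emulating
#' inter-season covariate shift between collection years.
#'
#' @param config a [scene_config]; per-scene seeds are
#'   `config$seed + 1000 * (scene index)`.
#' @param n_scenes number of scenes (>= 1).
#' @param year_shift relative illumination drift of year-2 scenes.
#' @return list of scene triples (as from [generate_scene()]), each with a
#'   `year` element (1 or 2).
#' @export
generate_dataset <- function(config, n_scenes = 2, year_shift = 0) {
  stopifnot(inherits(config, "scene_config"), n_scenes >= 1)
  out <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    ci <- config
    ci$seed <- config$seed + 1000L * i
    sc <- generate_scene(ci)
    year <- if (i > n_scenes / 2) 2L else 1L
    if (year == 2L && year_shift != 0) {
      v <- pmin(pmax(sc$cube$values * (1 + year_shift), 0), 1)
      sc$cube <- hsi_cube(v, sc$cube$axis, kind = "reflectance",
                          metadata = sc$cube$metadata)
    }
    sc$year <- year
    out[[i]] <- sc
  }
  out
}

#' Generate a plot-trial image collection (one treatment per scene)
#'
#' Field campaigns over plot trials photograph each plot separately, so every
#' image contains a single treatment (plus background); the image library
#' then holds `reps x years` scenes per class. This generator mirrors that
#' collection design: each scene is a single-treatment canopy over a
#' water/soil background frame, with an optional global multiplicative
#' illumination drift applied to year-2 scenes.
#'
#' @param treatments list of treatment specs ([default_treatments()]).
#' @param height,width,n_bands scene geometry (defaults 32 x 32 x 204).
#' @param reps_per_year scenes per class per year.
#' @param years number of collection years (1 or 2).
#' @param year_shift relative illumination drift of year-2 scenes.
#' @param background_fraction,sensor_noise_sd as in [scene_config()].
#' @param seed integer seed; every scene derives its own seed from it.
#' @return list of scene triples (as [generate_scene()]) with elements
#'   `year` and `class_id`; labels carry the treatment's class id and the
#'   full class-name vector.
#' @export
generate_plot_trial <- function(treatments, height = 32, width = 32,
                                n_bands = 204, reps_per_year = 1, years = 2,
                                year_shift = 0, background_fraction = 0.2,
                                sensor_noise_sd = 0.01, seed = 1) {
  class_names <- vapply(treatments, `[[`, character(1), "name")
  out <- list()
  i <- 0L
  for (yr in seq_len(years)) for (rep in seq_len(reps_per_year)) {
    for (k in seq_along(treatments)) {
      i <- i + 1L
      tr <- treatments[[k]]
      tr$class_id <- 1L
      cfg <- scene_config(height = height, width = width, n_bands = n_bands,
                          treatments = list(tr),
                          background_fraction = background_fraction,
                          sensor_noise_sd = sensor_noise_sd,
                          seed = seed + 997L * i)
      sc <- generate_scene(cfg)
      if (yr == 2L && year_shift != 0) {
        v <- pmin(pmax(sc$cube$values * (1 + year_shift), 0), 1)
        sc$cube <- hsi_cube(v, sc$cube$axis, kind = "reflectance",
                            metadata = sc$cube$metadata)
      }
      lab <- sc$labels$labels
      lab[lab == 1L] <- k
      sc$labels <- label_map(lab, class_names)
      sc$mask <- lab > 0L
      sc$year <- yr
      sc$class_id <- k
      out[[i]] <- sc
    }
  }
  out
}

#' Write a dataset manifest
#'
#' Records the generating configuration and per-scene seeds as YAML so a
#' dataset can be regenerated exactly.
#'
#' @param config a [scene_config].
#' @param n_scenes,year_shift as passed to [generate_dataset()].
#' @param path output YAML path.
#' @export
write_manifest <- function(config, n_scenes, year_shift, path) {
  cfg <- unclass(config)
  cfg$treatments <- lapply(cfg$treatments, function(tr) {
    list(class_id = tr$class_id, name = tr$name,
         within_class_sd = tr$within_class_sd,
         endmember = unclass(tr$endmember))
  })
  yaml::write_yaml(list(config = cfg, n_scenes = n_scenes,
                        year_shift = year_shift,
                        scene_seeds = cfg$seed + 1000L * seq_len(n_scenes)),
                   path)
  invisible(path)
}
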