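## Synthetic VNIR scene generator. Every downstream stage (calibration,
## masking, MCR-ALS, statistics) is validated against the ground truth these
## functions carry along.

.logistic <- function(wl, center, slope) 1 / (1 + exp(-(wl - center) / slope))
.gauss <- function(wl, center, width) exp(-0.5 * ((wl - center) / width)^2)

#' Build a parametric VNIR spectral library
#'
#' Returns reflectance-like component spectra emulating the features of
#' vegetation and background signals: two chlorophyll-dominated plant
#' components that differ in their red-edge position (control-like inflection
#' near 705 nm; stress-like left-shifted near 695 nm with a steeper slope,
#' a broader blue shoulder and a reduced-NIR dip), three smooth broadband
#' background components whose band ratios deliberately fail the plant
#' decision rule, a constant baseline, and condition-specific stress
#' components (one salt-like, one copper-like, two cesium-like). Shapes are
#' sums of Gaussian bumps/dips on a logistic red edge; a seeded +/-5%
#' amplitude jitter makes libraries distinct across seeds but deterministic
#' for a fixed seed.
#'
#' @param grid_spec list with `min_nm`, `max_nm`, `bands` (>= 20).
#' @param condition_set stress conditions to include components for; any of
#'   `"NaCl"`, `"CuCl2"`, `"CsCl"` (cesium contributes two components).
#' @param seed integer seed.
#' @return an object of class `spectral_library`: `wavelengths_nm`,
#'   `spectra` (bands x K), `labels`, `roles`.
#' @export
build_library <- function(grid_spec = list(min_nm = 400, max_nm = 1000,
                                           bands = 301),
                          condition_set = c("NaCl", "CuCl2", "CsCl"),
                          seed = 1L) {
  if (grid_spec$bands < 20) stop("invalid grid: need at least 20 bands")
  if (grid_spec$min_nm < 380 || grid_spec$max_nm > 1050 ||
      grid_spec$min_nm >= grid_spec$max_nm)
    stop("invalid grid: wavelengths must be increasing within [380, 1050] nm")
  condition_set <- match.arg(condition_set, c("NaCl", "CuCl2", "CsCl"),
                             several.ok = TRUE)
  wl <- seq(grid_spec$min_nm, grid_spec$max_nm, length.out = grid_spec$bands)
  set.seed(seed)
  j <- function() stats::runif(1, 0.95, 1.05)   # per-feature amplitude jitter

  ## control-like plant component: green peak 520-560, chlorophyll trough at
  ## 680, logistic red edge centred ~705 nm completing by 760, NIR plateau
  chl1 <- 0.04 + 0.10 * j() * .gauss(wl, 540, 22) +
    0.68 * j() * .logistic(wl, 705, 11)
  ## stress-like plant component: blue shoulder 400-430, broader green/orange
  ## 500-640, left-shifted steeper red edge (~695 nm), dip >710 nm, reduced
  ## NIR around 925 nm
  chl2 <- 0.05 + 0.05 * j() * .gauss(wl, 415, 14) +
    0.16 * j() * .gauss(wl, 570, 45) +
    0.58 * j() * .logistic(wl, 695, 7) -
    0.06 * j() * .gauss(wl, 730, 15) -
    0.07 * j() * .gauss(wl, 925, 18)

  ## backgrounds: smooth and broadband, with their distinguishing structure
  ## placed between the decision-rule windows (410-450, 550-600, 750-850 nm)
  ## so the window band ratios stay safely in the non-plant region
  x <- (wl - grid_spec$min_nm) / (grid_spec$max_nm - grid_spec$min_nm)
  bg1 <- 0.35 * j() - 0.14 * j() * .gauss(wl, 500, 170) +
    0.30 * j() * .gauss(wl, 505, 18)
  bg2 <- 0.40 * j() - 0.18 * j() * x + 0.30 * j() * .gauss(wl, 660, 26)
  bg3 <- 0.20 * j() + 0.15 * j() * .gauss(wl, 740, 120) +
    0.30 * j() * .gauss(wl, 925, 35)

  nacl <- 0.10 + 0.22 * j() * .gauss(wl, 495, 24) +
    0.28 * j() * .gauss(wl, 680, 16) + 0.30 * j() * .logistic(wl, 718, 10)
  cucl2 <- 0.16 + 0.18 * j() * .gauss(wl, 488, 32) +
    0.22 * j() * .gauss(wl, 676, 22) + 0.34 * j() * .logistic(wl, 708, 14)
  cscl1 <- 0.08 + 0.34 * j() * .gauss(wl, 600, 55) +
    0.14 * j() * .logistic(wl, 700, 12)
  cscl2 <- (0.08 + 0.42 * j() * .gauss(wl, 680, 12) +
              0.33 * j() * .logistic(wl, 698, 8)) *
    (1 - 0.30 * .logistic(wl, 850, 55))

  spectra <- cbind(chl_1 = chl1, chl_2 = chl2,
                   bg_1 = bg1, bg_2 = bg2, bg_3 = bg3)
  roles <- c("plant_healthy", "plant_stressed_chl",
             "background", "background", "background")
  if ("NaCl" %in% condition_set) {
    spectra <- cbind(spectra, NaCl = nacl); roles <- c(roles, "stress")
  }
  if ("CuCl2" %in% condition_set) {
    spectra <- cbind(spectra, CuCl2 = cucl2); roles <- c(roles, "stress")
  }
  if ("CsCl" %in% condition_set) {
    spectra <- cbind(spectra, CsCl_1 = cscl1, CsCl_2 = cscl2)
    roles <- c(roles, "stress", "stress")
  }
  spectra <- pmax(spectra, 0)
  spectra <- cbind(spectra, baseline = rep(1, length(wl)))
  roles <- c(roles, "baseline")
  structure(list(wavelengths_nm = wl, spectra = spectra,
                 labels = colnames(spectra), roles = roles, seed = seed),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d bands (%.0f-%.0f nm), components: %s\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Rasterize a rotated ellipse onto a pixel lattice
#'
#' @param height,width frame size in pixels.
#' @param center `(row, col)` of the ellipse centre.
#' @param semi_axes `(a, b)` semi-axis lengths in pixels.
#' @param angle rotation (radians) of the major axis.
#' @return logical matrix marking lattice points strictly inside the ellipse.
#' @export
ellipse_mask <- function(height, width, center, semi_axes, angle = 0) {
  rr <- matrix(seq_len(height), height, width) - center[1]
  cc <- matrix(seq_len(width), height, width, byrow = TRUE) - center[2]
  u <- cos(angle) * rr + sin(angle) * cc
  v <- -sin(angle) * rr + cos(angle) * cc
  (u / semi_axes[1])^2 + (v / semi_axes[2])^2 < 1
}

#' Generate a rosette layout as a union of leaf ellipses
#'
#' Leaves radiate from the frame centre at evenly spaced, jittered angles;
#' each leaf is an ellipse whose major axis points outward.
#'
#' @param height,width frame size in pixels.
#' @param n_leaves number of leaves (>= 1).
#' @param scale overall size multiplier (base leaf semi-major axis 10 px).
#' @param seed integer seed.
#' @return an object of class `scene_layout`: logical `grid`,
#'   `leaf_pixel_count`.
#' @export
generate_rosette <- function(height, width, n_leaves, scale = 1, seed = 1L) {
  if (n_leaves < 1) stop("need at least one leaf")
  set.seed(seed)
  center <- c(height / 2, width / 2)
  grid <- matrix(FALSE, height, width)
  for (i in seq_len(n_leaves)) {
    theta <- 2 * pi * (i - 1) / n_leaves + stats::runif(1, -0.15, 0.15)
    a <- 10 * scale * stats::runif(1, 0.85, 1.15)
    b <- 0.45 * a * stats::runif(1, 0.9, 1.1)
    d <- 0.8 * a
    ctr <- center + d * c(sin(theta), cos(theta))
    if (ctr[1] - a < 1 || ctr[1] + a > height ||
        ctr[2] - a < 1 || ctr[2] + a > width)
      stop("layout overflow: leaf ellipse extends outside the frame")
    grid <- grid | ellipse_mask(height, width, ctr, c(a, b), angle = theta)
  }
  structure(list(grid = grid, leaf_pixel_count = sum(grid)),
            class = "scene_layout")
}

## smooth positive low-order polynomial field on [-1,1]^2, seeded
.smooth_field <- function(height, width, amplitude = 0.15) {
  x <- matrix(seq(-1, 1, length.out = width), height, width, byrow = TRUE)
  y <- matrix(seq(-1, 1, length.out = height), height, width)
  a <- stats::runif(5, -amplitude, amplitude)
  pmax(1 + a[1] * x + a[2] * y + a[3] * x * y + a[4] * x^2 + a[5] * y^2, 0.2)
}

#' Build ground-truth concentration maps for one scene
#'
#' The healthy plant component dominates the rosette centre, the stressed
#' chlorophyll component the leaf margins; background components live outside
#' the plant with an optional bleed into plant pixels (emulating multiple
#' reflections from the surroundings); stress components are confined to the
#' plant, concentrated near the centre/veins; the baseline coefficient is a
#' constant offset.
#'
#' @param library a [build_library()] result.
#' @param layout a [generate_rosette()] result.
#' @param condition one of `control`, `NaCl`, `CuCl2`, `CsCl`, `CsCl_K`.
#' @param day imaging day (integer).
#' @param replicate_id replicate index.
#' @param stress_level stress-component amplitude for this scene (>= 0).
#' @param background_bleed fraction of outside background amplitude present
#'   inside plant pixels (default 0, i.e. none).
#' @param baseline_level constant baseline coefficient.
#' @param seed integer seed.
#' @return an object of class `scene_truth` with per-component
#'   `concentration_maps`, the layout grid, `leaf_pixel_count`,
#'   `condition_label`, `day`, `replicate_id`.
#' @export
build_scene_truth <- function(library, layout, condition, day = 0L,
                              replicate_id = 1L, stress_level = 0,
                              background_bleed = 0, baseline_level = 0.02,
                              seed = 1L) {
  condition <- match.arg(condition,
                         c("control", "NaCl", "CuCl2", "CsCl", "CsCl_K"))
  if (stress_level < 0) stop("stress_level must be >= 0")
  set.seed(seed)
  g <- layout$grid
  h <- nrow(g); w <- ncol(g)
  rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  rad <- sqrt((rr - h / 2)^2 + (cc - w / 2)^2)
  rad <- rad / max(rad[g], 1)

  maps <- list()
  ## chlorophyll split shifts toward the stressed component with stress
  frac2 <- pmin(0.25 + 0.5 * rad + 0.35 * min(stress_level, 1), 0.9)
  tot <- 0.95 * .smooth_field(h, w, 0.08)
  maps$chl_1 <- ifelse(g, tot * (1 - frac2), 0)
  maps$chl_2 <- ifelse(g, tot * frac2, 0)

  for (bg in intersect(c("bg_1", "bg_2", "bg_3"), library$labels)) {
    amp <- switch(bg, bg_1 = 0.5, bg_2 = 0.4, bg_3 = 0.35)
    ## per-scene amplitude jitter + a strongly varying spatial field, so the
    ## background contribution inside the plant is well above the noise floor
    f <- amp * stats::runif(1, 0.7, 1.3) * .smooth_field(h, w, 0.4)
    maps[[bg]] <- ifelse(g, background_bleed * f, f)
  }

  active <- switch(condition,
    control = character(0),
    NaCl = "NaCl", CuCl2 = "CuCl2",
    CsCl = c("CsCl_1", "CsCl_2"), CsCl_K = c("CsCl_1", "CsCl_2"))
  for (sc in intersect(setdiff(library$labels, "baseline"), library$labels)) {
    if (library$roles[match(sc, library$labels)] != "stress") next
    if (sc %in% active && stress_level > 0) {
      ## paired stress components occupy distinct tissue: the second of a
      ## pair sits near the stem and primary veins, the first toward the
      ## leaf margins, so the pair is spatially (not only spectrally)
      ## separable
      pat <- if (sc == "CsCl_1")
        (0.15 + rad^1.5) * .smooth_field(h, w, 0.15)
      else
        exp(-2.5 * rad) * .smooth_field(h, w, 0.15)
      maps[[sc]] <- ifelse(g, stress_level * pat, 0)
    } else {
      maps[[sc]] <- matrix(0, h, w)
    }
  }
  maps$baseline <- matrix(baseline_level, h, w)
  maps <- maps[library$labels]
  structure(list(concentration_maps = maps, plant_layout = g,
                 leaf_pixel_count = layout$leaf_pixel_count,
                 condition_label = condition, day = as.integer(day),
                 replicate_id = as.integer(replicate_id)),
            class = "scene_truth")
}

#' Render a raw acquisition from library + truth
#'
#' The noiseless reflectance at each pixel is the library spectra mixed by
#' the truth concentration maps. Gaussian noise of standard deviation
#' `noise_sd` (reflectance units) is added, then the scene is converted to
#' digital numbers: `raw = dark + gain * white_shape * reflectance`, where
#' `white_shape` is a smooth halogen-like illumination spectrum. The white
#' frame corresponds to a perfect (reflectance 1) target under the same
#' illumination, so white/dark calibration recovers the noisy reflectance
#' exactly.
#'
#' @param library a [build_library()] result.
#' @param truth a [build_scene_truth()] result.
#' @param noise_sd Gaussian noise standard deviation in reflectance units.
#' @param gain detector gain (DN per unit radiance).
#' @param seed integer seed for the noise draw.
#' @return an object of class `raw_acquisition`: `raw_cube` ([hyper_cube()]
#'   of digital numbers), `white_frame`, `dark_frame`, `truth`.
#' @export
render_scene <- function(library, truth, noise_sd = 0, gain = 4000,
                         seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!identical(names(truth$concentration_maps), library$labels))
    stop("truth maps do not match library components")
  wl <- library$wavelengths_nm
  h <- nrow(truth$plant_layout); w <- ncol(truth$plant_layout)
  nb <- length(wl)
  C <- vapply(truth$concentration_maps, as.vector, numeric(h * w))
  refl <- C %*% t(library$spectra)           # (h*w) x bands mixture
  if (noise_sd > 0) {
    set.seed(seed)
    refl <- refl + matrix(stats::rnorm(length(refl), 0, noise_sd),
                          nrow(refl), ncol(refl))
  }
  white_shape <- 0.5 + 0.5 * .logistic(wl, 560, 130)  # halogen-like
  dark <- rep(100, nb)
  white <- dark + gain * white_shape
  raw <- sweep(refl, 2L, gain * white_shape, "*")
  raw <- sweep(raw, 2L, dark, "+")
  cube <- hyper_cube(array(raw, dim = c(h, w, nb)), wl,
                     meta = list(condition = truth$condition_label,
                                 day = truth$day,
                                 replicate = truth$replicate_id))
  structure(list(raw_cube = cube, white_frame = white, dark_frame = dark,
                 truth = truth),
            class = "raw_acquisition")
}

#' Default synthetic-experiment configuration
#'
#' Defaults encode the emulated study design: five replicates per condition,
#' imaging at treatment start and after nine days of exposure, growing
#' control rosettes and flat/shrinking stressed ones, rising stress-component
#' amplitudes, per-condition variance multipliers forcing heteroscedastic
#' group effects, and background signal bleeding weakly into plant pixels so
#' that plant-masked data still require the background components.
#'
#' @param conditions condition labels to simulate.
#' @param replicates replicates per condition.
#' @param days imaging days.
#' @param frame `(lines, samples)` of each cube.
#' @param grid wavelength grid (`min_nm`, `max_nm`, `bands`).
#' @param noise_sd reflectance noise standard deviation.
#' @param gain detector gain.
#' @param background_bleed in-plant background amplitude fraction.
#' @param stress_level_max day-`max(days)` mean stress amplitude.
#' @param variance_mult named per-condition multipliers on the
#'   between-replicate stress-amplitude standard deviation.
#' @param k_suppression multiplier applied to cesium stress amplitudes under
#'   the high-potassium arm; the default 0 encodes a complete rescue of the
#'   stress response by potassium supplementation (set a small positive value
#'   for a partial rescue).
#' @param rosette_scale base rosette size multiplier.
#' @return a named list (class `experiment_config`).
#' @export
experiment_config <- function(conditions = c("control", "NaCl", "CuCl2",
                                             "CsCl", "CsCl_K"),
                              replicates = 5L,
                              days = c(0L, 9L),
                              frame = c(96L, 96L),
                              grid = list(min_nm = 400, max_nm = 1000,
                                          bands = 301L),
                              noise_sd = 0.005,
                              gain = 4000,
                              background_bleed = 0.25,
                              stress_level_max = 0.6,
                              variance_mult = c(control = 1, NaCl = 2,
                                                CuCl2 = 4, CsCl = 3,
                                                CsCl_K = 1.5),
                              k_suppression = 0,
                              rosette_scale = 1.5) {
  cfg <- list(conditions = conditions, replicates = as.integer(replicates),
              days = as.integer(days), frame = as.integer(frame), grid = grid,
              noise_sd = noise_sd, gain = gain,
              background_bleed = background_bleed,
              stress_level_max = stress_level_max,
              variance_mult = variance_mult, k_suppression = k_suppression,
              rosette_scale = rosette_scale)
  class(cfg) <- "experiment_config"
  cfg
}

#' Read an experiment configuration from a YAML file
#'
#' Unspecified keys fall back to [experiment_config()] defaults.
#'
#' @param path YAML file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- experiment_config()
  for (k in names(y)) {
    if (!k %in% names(cfg)) stop("unknown config key: ", k)
    v <- y[[k]]
    if (k == "variance_mult") v <- unlist(v)
    if (k %in% c("replicates", "days", "frame")) v <- as.integer(unlist(v))
    if (k == "conditions") v <- as.character(unlist(v))
    cfg[[k]] <- v
  }
  cfg
}

#' Generate a full synthetic experiment
#'
#' One scene per condition x replicate x day. Control rosettes grow over
#' days; stressed rosettes stay flat or shrink while their stress-component
#' amplitude rises linearly with day. Between-replicate stress amplitudes are
#' Gaussian with per-condition variance multipliers (heteroscedastic groups).
#' Every noiseless render is verified against the plant decision rule: plant
#' pixels must classify as plant and background pixels must not.
#'
#' @param config an [experiment_config()].
#' @param seed master integer seed.
#' @param verify check the mask rule on each noiseless scene (default TRUE).
#' @return list with `scenes` (list of `raw_acquisition`), `library`,
#'   `config`, `seed`.
#' @export
generate_experiment <- function(config = experiment_config(), seed = 1L,
                                verify = TRUE) {
  known <- c("control", "NaCl", "CuCl2", "CsCl", "CsCl_K")
  bad <- setdiff(config$conditions, known)
  if (length(bad)) stop("unknown condition label(s): ",
                        paste(bad, collapse = ", "))
  library <- build_library(config$grid, seed = seed)
  set.seed(seed)
  max_day <- max(config$days)
  scenes <- list()
  for (cond in config$conditions) {
    mult <- config$variance_mult[[cond]]
    if (is.null(mult)) mult <- 1
    for (rep_i in seq_len(config$replicates)) {
      sub <- sample.int(2^20, 3L)
      ## replicate-level stress amplitude: heteroscedastic across conditions
      z <- stats::rnorm(1, 0, 0.12 * mult)
      amp_rep <- max(config$stress_level_max * (1 + z), 0)
      if (cond == "CsCl_K") amp_rep <- amp_rep * config$k_suppression
      for (day in config$days) {
        grow <- if (cond == "control") 1 + 0.35 * day / max(max_day, 1)
                else 1 - 0.08 * day / max(max_day, 1)
        layout <- generate_rosette(config$frame[1], config$frame[2],
                                   n_leaves = 6L + (rep_i %% 4L),
                                   scale = config$rosette_scale * grow,
                                   seed = sub[1] + day)
        stress_level <- if (cond == "control") 0 else
          amp_rep * day / max(max_day, 1)
        truth <- build_scene_truth(
          library, layout, condition = cond, day = day,
          replicate_id = rep_i, stress_level = stress_level,
          background_bleed = config$background_bleed, seed = sub[2] + day)
        acq <- render_scene(library, truth, noise_sd = config$noise_sd,
                            gain = config$gain, seed = sub[3] + day)
        if (verify) {
          clean <- render_scene(library, truth, noise_sd = 0,
                                gain = config$gain, seed = 1L)
          refl <- calibrate_reflectance(clean$raw_cube, clean$white_frame,
                                        clean$dark_frame)
          m <- build_mask(refl)
          if (!identical(m$grid == 1L, truth$plant_layout))
            stop("generated scene violates the plant decision rule (",
                 cond, ", replicate ", rep_i, ", day ", day, ")")
        }
        scenes[[length(scenes) + 1L]] <- acq
      }
    }
  }
  list(scenes = scenes, library = library, config = config, seed = seed)
}
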