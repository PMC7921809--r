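## shared fixtures, all generated in code

random_cube <- function(lines = 4, samples = 5, bands = 6, seed = 1) {
  set.seed(seed)
  hyper_cube(array(runif(lines * samples * bands), c(lines, samples, bands)),
             wavelengths_nm = seq(400, 1000, length.out = bands))
}

## one small calibrated control scene plus its truth
small_scene <- function(seed = 7, condition = "control", stress_level = 0,
                        bleed = 0.25, noise_sd = 0) {
  lib <- build_library(seed = seed)
  lay <- generate_rosette(64, 64, n_leaves = 6, scale = 1, seed = seed + 1)
  tr <- build_scene_truth(lib, lay, condition, stress_level = stress_level,
                          background_bleed = bleed, seed = seed + 2)
  acq <- render_scene(lib, tr, noise_sd = noise_sd, seed = seed + 3)
  refl <- calibrate_reflectance(acq$raw_cube, acq$white_frame, acq$dark_frame)
  list(library = lib, truth = tr, acq = acq, refl = refl)
}

## principal angles (radians) between the column spaces of A and B
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  acos(pmin(pmax(svd(crossprod(qa, qb))$d, -1), 1))
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
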