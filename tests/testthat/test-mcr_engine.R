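test_that("unfold concatenates masked pixels with a usable provenance index", {
  wl <- seq(400, 1000, length.out = 6)
  c1 <- hyper_cube(array(runif(2 * 2 * 6), c(2, 2, 6)), wl,
                   meta = list(condition = "control", replicate = 1, day = 0))
  c2 <- hyper_cube(array(runif(2 * 2 * 6), c(2, 2, 6)), wl,
                   meta = list(condition = "NaCl", replicate = 2, day = 9))
  m1 <- mask_file(matrix(c(1, 0, 0, 0), 2))
  m2 <- mask_file(matrix(c(1, 1, 0, 1), 2))
  um <- unfold(list(c1, c2), list(m1, m2))
  expect_identical(nrow(um$data), 4L)
  expect_identical(um$index$condition, c("control", rep("NaCl", 3)))
  ## refolding a column via the index puts zeros off-mask
  refold <- matrix(0, 2, 2)
  rows <- um$index$cube == 2
  refold[cbind(um$index$line[rows], um$index$sample[rows])] <-
    um$data[rows, 3]
  expect_equal(refold[m2$grid == 1L],
               c2$values[, , 3][m2$grid == 1L])
  expect_equal(max(abs(refold[m2$grid == 0L])), 0)

  expect_error(unfold(list(c1), list(m1, m2)), "one mask per cube")
  expect_error(unfold(list(c1, c2), list(m1, mask_file(matrix(0, 3, 3)))),
               "spatial grid")
  bad <- hyper_cube(array(1, c(2, 2, 6)), wl + 5)
  expect_error(unfold(list(c1, bad), list(m1, m2)), "incompatible")
  expect_error(unfold(list(c1), list(mask_file(matrix(0, 2, 2)))), "empty")
})

test_that("scree eigenvalues match a closed-form construction", {
  set.seed(10)
  n <- 200; bands <- 30; r <- 4
  sigma <- c(9, 5, 2, 0.5)
  ## left factors orthonormal and orthogonal to the ones vector, so column
  ## centring leaves the construction intact
  M <- cbind(1, matrix(rnorm(n * r), n, r))
  U <- qr.Q(qr(M))[, 2:(r + 1)]
  V <- qr.Q(qr(matrix(rnorm(bands * r), bands, r)))
  X <- U %*% diag(sigma) %*% t(V)
  got <- scree(X, k_max = 8)
  expect_equal(got$eigenvalues[1:4], sigma^2 / (n - 1), tolerance = 1e-10)
  expect_lt(got$eigenvalues[5] / got$eigenvalues[1], 1e-10)
  ## noiseless rank-3 synthetic: trailing eigenvalues vanish
  X3 <- matrix(runif(100 * 3), 100, 3) %*% matrix(runif(3 * 20), 3, 20)
  ev <- scree(X3, k_max = 10)$eigenvalues
  expect_true(all(ev[4:10] <= 1e-10 * ev[1]))
  ## duplicating every row rescales eigenvalues but not the elbow
  expect_identical(scree(rbind(X3, X3))$suggested_rank,
                   scree(X3)$suggested_rank)
  expect_error(scree(X3[1, , drop = FALSE]), "insufficient")
})

test_that("pick_elbow matches a brute-force distance oracle", {
  ## oracle: explicit point-to-line distance via vector projection
  elbow_oracle <- function(ev) {
    ev <- sort(ev, decreasing = TRUE)
    le <- log10(pmax(ev, .Machine$double.eps))
    m <- length(le)
    p1 <- c(1, le[1]); p2 <- c(m, le[m])
    u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    d <- vapply(seq_len(m), function(i) {
      v <- c(i, le[i]) - p1
      sqrt(max(sum(v^2) - sum(v * u)^2, 0))
    }, 1)
    which.max(d)
  }
  ## frozen from the oracle: after the cliff, the first noise-floor point
  ## carries the largest perpendicular distance on this profile
  expect_identical(elbow_oracle(c(100, 50, 20, 1e-6, 9e-7, 8e-7)), 4L)
  expect_identical(pick_elbow(c(100, 50, 20, 1e-6, 9e-7, 8e-7)), 4L)
  set.seed(3)
  for (i in 1:25) {
    ev <- sort(10^runif(12, -8, 2), decreasing = TRUE)
    expect_identical(pick_elbow(ev), as.integer(elbow_oracle(ev)))
    ## input order is irrelevant
    expect_identical(pick_elbow(sample(ev)), pick_elbow(ev))
  }
  ## geometric decay has no bend yet the arg-max is still defined
  expect_true(pick_elbow(2^-(1:10)) %in% 1:10)
  expect_error(pick_elbow(c(2, 1)), "at least 3")
})

test_that("init_components copies fixed columns and normalises free ones", {
  fx <- matrix(runif(40 * 5), 40, 5)
  ini <- init_components(0, 40, seed = 2, fixed_spectra = fx)
  expect_identical(ncol(ini$S), 6L)
  expect_identical(ini$S[, 1:5], fx, ignore_attr = TRUE)
  expect_equal(var(ini$S[, 6]), 0)

  i1 <- init_components(3, 40, seed = 9)
  i2 <- init_components(3, 40, seed = 9)
  expect_identical(i1$S, i2$S)
  expect_equal(colSums(i1$S[, 1:3]^2), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(init_components(2, 30, fixed_spectra = fx), "grid")
})

test_that("fit_mcr solves noiseless rank-2 factorizations to machine accuracy", {
  for (sd0 in 1:3) {
    set.seed(sd0)
    wl <- seq(0, 3, length.out = 60)
    S_true <- cbind(abs(sin(wl)) + 0.1, exp(-wl))
    C_true <- matrix(runif(400 * 2), 400, 2)
    X <- C_true %*% t(S_true)
    set.seed(100 + sd0)
    S0 <- matrix(runif(60 * 2), 60, 2)
    S0 <- sweep(S0, 2, sqrt(colSums(S0^2)), "/")
    fit <- fit_mcr(X, S0, c(FALSE, FALSE), fit_options(seed = sd0),
                   baseline_col = NA)
    expect_lt(tail(fit$rss_history, 1), 1e-10 * sum(X^2))
    expect_lt(max(principal_angles(S_true, fit$S)), 1e-4)
    ## monotone RSS at every recorded iteration
    expect_true(all(diff(fit$rss_history) <= 1e-12 * fit$rss_history[1]))
    ## unit-norm free spectra
    expect_equal(colSums(fit$S^2), c(1, 1), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("equality-constrained columns are returned bit-identical", {
  set.seed(12)
  S_true <- matrix(runif(50 * 3), 50, 3)
  C_true <- matrix(runif(300 * 3), 300, 3)
  X <- C_true %*% t(S_true) + matrix(rnorm(300 * 50, 0, 0.01), 300, 50)
  fixed <- S_true[, 1:2]
  colnames(fixed) <- c("a", "b")
  ini <- init_components(2, 50, seed = 5, fixed_spectra = fixed)
  fit <- fit_mcr(X, ini$S, ini$fixed_flags, fit_options(seed = 5),
                 ini$baseline_col)
  expect_identical(fit$S[, "a"], fixed[, "a"])
  expect_identical(fit$S[, "b"], fixed[, "b"])
  ## baseline column constant
  expect_equal(var(fit$S[, fit$baseline_col]), 0)
  ## non-negativity where promised
  expect_true(all(fit$C[, -fit$baseline_col] >= -1e-12))
})

test_that("residual diagnostics separate clean fits, noise, and omitted signal", {
  set.seed(20)
  n <- 1500; bands <- 80
  wl <- seq(0, 1, length.out = bands)
  S3 <- cbind(exp(-(wl - 0.3)^2 / 0.02), exp(-(wl - 0.7)^2 / 0.02),
              0.5 + 0.5 * sin(3 * wl))
  C3 <- matrix(runif(n * 3), n, 3)
  mk_model <- function(S, C) {
    structure(list(S = S, C = C, fixed_flags = rep(TRUE, ncol(S)),
                   baseline_col = NA_integer_,
                   labels = paste0("c", seq_len(ncol(S))),
                   options = fit_options()), class = "mcr_model")
  }
  ## exact model: clean with ~zero residual eigenvalues
  X <- C3 %*% t(S3)
  rp <- residual_pca(mk_model(S3, C3), X)
  expect_identical(rp$verdict, "clean")
  expect_lt(rp$residual_eigenvalues[1], 1e-12 * sum(X^2))
  ## pure white residuals: structure score near zero
  Xn <- X + matrix(rnorm(n * bands, 0, 0.05), n, bands)
  rp2 <- residual_pca(mk_model(S3, C3), Xn)
  expect_lt(abs(rp2$structure_score), 3 / sqrt(bands))
  expect_identical(rp2$verdict, "clean")
  ## omitting a smooth component leaves autocorrelated residual loadings
  rp3 <- residual_pca(mk_model(S3[, 1:2], C3[, 1:2]), Xn)
  expect_gt(rp3$structure_score, 0.5)
  expect_identical(rp3$verdict, "unmodeled_signal")
})

test_that("null-component detection flags empty and noise-like columns only", {
  set.seed(21)
  bands <- 60
  S <- cbind(smooth1 = exp(-(seq_len(bands) - 20)^2 / 50),
             smooth2 = exp(-(seq_len(bands) - 40)^2 / 80),
             noiselike = runif(bands),
             empty = exp(-(seq_len(bands) - 30)^2 / 60),
             baseline = rep(1, bands))
  C <- cbind(runif(500, 0.5, 1), runif(500, 0.5, 1), runif(500, 0.5, 1),
             rep(0, 500), runif(500, -0.1, 0.1))
  model <- structure(list(S = S, C = C, fixed_flags = rep(FALSE, 5),
                          baseline_col = 5L, labels = colnames(S),
                          options = fit_options()), class = "mcr_model")
  flags <- detect_null_components(model)
  expect_false(flags[["smooth1"]])
  expect_false(flags[["smooth2"]])
  expect_true(flags[["noiselike"]])
  expect_true(flags[["empty"]])
  expect_false(flags[["baseline"]])

  ## an exactly fitted 2-component model has no null components
  sc <- small_scene(seed = 30)
  lib <- sc$library
  model2 <- structure(list(
    S = lib$spectra[, c("chl_1", "chl_2")],
    C = vapply(sc$truth$concentration_maps[c("chl_1", "chl_2")], as.vector,
               numeric(64 * 64)),
    fixed_flags = c(FALSE, FALSE), baseline_col = NA_integer_,
    labels = c("chl_1", "chl_2"), options = fit_options()),
    class = "mcr_model")
  expect_false(any(detect_null_components(model2)))
})

test_that("map_concentrations recovers truth maps and scales linearly", {
  sc <- small_scene(seed = 33)
  lib <- sc$library
  model <- structure(list(
    S = lib$spectra, C = NULL, fixed_flags = rep(TRUE, ncol(lib$spectra)),
    baseline_col = ncol(lib$spectra), labels = lib$labels,
    options = fit_options(), wavelengths_nm = lib$wavelengths_nm),
    class = "mcr_model")
  mask <- build_mask(sc$refl)
  maps <- map_concentrations(model, sc$refl, mask)
  g <- mask$grid == 1L
  for (nm in c("chl_1", "chl_2", "bg_1")) {
    expect_equal(maps[[nm]][g], sc$truth$concentration_maps[[nm]][g],
                 tolerance = 1e-6, label = nm)
    expect_equal(max(abs(maps[[nm]][!g])), 0)
  }
  ## doubling reflectance doubles non-baseline concentrations
  twice <- hyper_cube(sc$refl$values * 2, sc$refl$wavelengths_nm)
  maps2 <- map_concentrations(model, twice, mask)
  expect_equal(maps2$chl_1[g], 2 * maps$chl_1[g], tolerance = 1e-6)
  ## grid mismatch rejected
  off <- hyper_cube(sc$refl$values, sc$refl$wavelengths_nm + 1)
  expect_error(map_concentrations(model, off, mask), "incompatible")
})

test_that("model files round-trip through the columnar text format", {
  set.seed(40)
  sc <- small_scene(seed = 41)
  um <- unfold(list(sc$refl), list(build_mask(sc$refl)))
  ini <- init_components(2, 301, seed = 4)
  fit <- fit_mcr(um, ini$S, ini$fixed_flags,
                 fit_options(seed = 4, max_iterations = 30),
                 ini$baseline_col)
  path <- tempfile(fileext = ".tsv")
  write_mcr_model(fit, path)
  back <- read_mcr_model(path)
  expect_equal(back$S, fit$S, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$labels, fit$labels)
  expect_identical(back$fixed_flags, fit$fixed_flags)
  expect_identical(back$baseline_col, fit$baseline_col)
  expect_equal(back$wavelengths_nm, fit$wavelengths_nm)
})
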