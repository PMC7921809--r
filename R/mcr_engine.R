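## Equality-constrained MCR-ALS: alternating non-negative least squares with
## frozen (equality-constrained) spectral columns, a signed constant-offset
## baseline, and data-driven model-order selection by scree elbow, residual
## PCA and null-component detection.

#' ALS fit options
#'
#' @param max_iterations maximum ALS iterations.
#' @param rel_tol convergence threshold on the relative RSS change.
#' @param seed integer seed used for random spectral initialisation.
#' @param nonneg_spectra constrain free, non-baseline spectra to be >= 0.
#' @param nonneg_concentrations constrain non-baseline concentrations >= 0.
#' @return a named list of options (class `fit_options`).
#' @export
fit_options <- function(max_iterations = 500L, rel_tol = 1e-8, seed = 1L,
                        nonneg_spectra = TRUE, nonneg_concentrations = TRUE) {
  if (rel_tol <= 0 || max_iterations < 1) stop("invalid fit options")
  structure(list(max_iterations = as.integer(max_iterations),
                 rel_tol = rel_tol, seed = as.integer(seed),
                 nonneg_spectra = isTRUE(nonneg_spectra),
                 nonneg_concentrations = isTRUE(nonneg_concentrations)),
            class = "fit_options")
}

#' Unfold masked cubes into a pixels x bands matrix
#'
#' Concatenates the mask-positive pixel spectra of one or more reflectance
#' cubes into a single matrix, keeping a per-row provenance index (cube
#' number, replicate, condition, day, line, sample) so concentration columns
#' can be refolded into images.
#'
#' @param cubes list of [hyper_cube()]s sharing one wavelength grid.
#' @param masks list of [mask_file()]s aligned with `cubes`.
#' @return an object of class `unfolded_matrix`: `data` (n_pixels x bands),
#'   `index` (data.frame), `wavelengths_nm`.
#' @export
unfold <- function(cubes, masks) {
  if (length(cubes) != length(masks)) stop("one mask per cube required")
  if (!length(cubes)) stop("no cubes supplied")
  wl <- cubes[[1]]$wavelengths_nm
  rows <- list(); idx <- list()
  for (i in seq_along(cubes)) {
    cube <- cubes[[i]]; mask <- masks[[i]]
    if (!isTRUE(all.equal(cube$wavelengths_nm, wl)))
      stop("incompatible cubes: wavelength grids differ")
    d <- dim(cube$values)
    if (!identical(dim(mask$grid), d[1:2]))
      stop("mask ", i, " does not match its cube's spatial grid")
    sel <- which(mask$grid == 1L, arr.ind = TRUE)
    if (!nrow(sel)) next
    flat <- matrix(cube$values, d[1] * d[2], d[3])
    rows[[length(rows) + 1L]] <- flat[(sel[, 2] - 1L) * d[1] + sel[, 1], ,
                                      drop = FALSE]
    meta <- cube$meta
    pick <- function(k) if (is.null(meta[[k]])) NA else meta[[k]]
    idx[[length(idx) + 1L]] <- data.frame(
      cube = i, replicate = pick("replicate"), condition = pick("condition"),
      day = pick("day"), line = sel[, 1], sample = sel[, 2],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("empty matrix: no mask-positive pixels")
  structure(list(data = do.call(rbind, rows), index = do.call(rbind, idx),
                 wavelengths_nm = wl),
            class = "unfolded_matrix")
}

#' @export
print.unfolded_matrix <- function(x, ...) {
  cat(sprintf("<unfolded_matrix> %d pixels x %d bands from %d cube(s)\n",
              nrow(x$data), ncol(x$data), length(unique(x$index$cube))))
  invisible(x)
}

.as_data_matrix <- function(x) {
  if (inherits(x, "unfolded_matrix")) x$data else as.matrix(x)
}

#' Eigenvalue scree of a data matrix
#'
#' Eigenvalues of the mean-centred covariance of the pixel spectra, sorted
#' descending, with an elbow-based rank suggestion.
#'
#' @param matrix an [unfold()]ed matrix or plain numeric matrix.
#' @param k_max number of leading eigenvalues to keep.
#' @return list (class `scree_result`): `eigenvalues`, `suggested_rank`.
#' @export
scree <- function(matrix, k_max = 12L) {
  X <- .as_data_matrix(matrix)
  if (nrow(X) < 2L) stop("insufficient data: need at least 2 pixel spectra")
  Xc <- sweep(X, 2L, colMeans(X), "-")
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev <- ev[seq_len(min(k_max, length(ev)))]
  structure(list(eigenvalues = ev, suggested_rank = pick_elbow(ev)),
            class = "scree_result")
}

#' Elbow of an eigenvalue profile
#'
#' The elbow is the point of maximum perpendicular distance from the straight
#' line joining the first and last log10-eigenvalues. Non-positive
#' eigenvalues are floored at machine epsilon before taking logs; input is
#' sorted descending internally. With fewer than three eigenvalues, or a
#' profile with no bend (e.g. exact geometric decay), the arg-max is still
#' defined and returned.
#'
#' @param eigenvalues numeric vector.
#' @return integer rank estimate.
#' @export
pick_elbow <- function(eigenvalues) {
  ev <- sort(eigenvalues, decreasing = TRUE)
  m <- length(ev)
  if (m < 3L) stop("need at least 3 eigenvalues")
  le <- log10(pmax(ev, .Machine$double.eps))
  i <- seq_len(m)
  ## perpendicular distance from the chord (1, le[1]) -- (m, le[m])
  d <- abs((le[m] - le[1]) * (i - 1) - (m - 1) * (le - le[1])) /
    sqrt((m - 1)^2 + (le[m] - le[1])^2)
  as.integer(which.max(d))
}

#' Initialise a spectral component matrix
#'
#' Fixed columns are copied verbatim; free columns are drawn uniform(0, 1)
#' per band and scaled to unit Euclidean norm; a constant baseline column is
#' appended last.
#'
#' @param k_free number of randomly initialised free components.
#' @param bands number of wavelength bands.
#' @param seed integer seed.
#' @param fixed_spectra optional bands x m matrix of equality-constrained
#'   spectra.
#' @return list: `S` (bands x (m + k_free + 1)), `fixed_flags`,
#'   `baseline_col`.
#' @export
init_components <- function(k_free, bands, seed = 1L, fixed_spectra = NULL) {
  if (k_free < 0) stop("k_free must be >= 0")
  nf <- 0L
  S <- NULL
  if (!is.null(fixed_spectra)) {
    fixed_spectra <- as.matrix(fixed_spectra)
    if (nrow(fixed_spectra) != bands)
      stop("fixed spectra are on an incompatible wavelength grid")
    nf <- ncol(fixed_spectra)
    S <- fixed_spectra
    if (is.null(colnames(S))) colnames(S) <- paste0("fixed_", seq_len(nf))
  }
  set.seed(seed)
  if (k_free > 0L) {
    Fr <- matrix(stats::runif(bands * k_free), bands, k_free)
    Fr <- sweep(Fr, 2L, sqrt(colSums(Fr^2)), "/")
    colnames(Fr) <- paste0("free_", seq_len(k_free))
    S <- cbind(S, Fr)
  }
  S <- cbind(S, baseline = rep(1, bands))
  list(S = S,
       fixed_flags = c(rep(TRUE, nf), rep(FALSE, k_free), TRUE),
       baseline_col = ncol(S))
}

#' Equality-constrained MCR-ALS
#'
#' Alternates (i) solving the concentration matrix `C` given the spectra `S`
#' by least squares, non-negative on non-baseline columns, and (ii) solving
#' the free columns of `S` given `C`, non-negative, leaving
#' equality-constrained columns untouched; free spectra carry a
#' unit-Euclidean-norm convention on return. Stops when
#' the relative RSS change drops below `options$rel_tol` or after
#' `options$max_iterations`. Components are reordered on return: fixed
#' columns first (input order), free columns by explained signal, baseline
#' last.
#'
#' @param matrix an [unfold()]ed matrix or n_pixels x bands matrix.
#' @param S_init initial bands x K spectral matrix (see [init_components()]).
#' @param fixed_flags logical length-K: equality-constrained columns
#'   (including the baseline).
#' @param options a [fit_options()].
#' @param baseline_col index of the constant baseline column in `S_init`
#'   (NA for none).
#' @return an object of class `mcr_model`: `S`, `C`, `fixed_flags`,
#'   `baseline_col`, `rss_history`, `converged`, `options`,
#'   `wavelengths_nm` (when available).
#' @export
fit_mcr <- function(matrix, S_init, fixed_flags, options = fit_options(),
                    baseline_col = ncol(S_init)) {
  X <- .as_data_matrix(matrix)
  S <- as.matrix(S_init)
  K <- ncol(S)
  if (length(fixed_flags) != K) stop("fixed_flags length must match S")
  if (!is.na(baseline_col) && !fixed_flags[baseline_col])
    stop("the baseline column must be equality-constrained")
  free <- which(!fixed_flags)
  fixed <- which(fixed_flags)
  labels <- colnames(S)
  if (is.null(labels)) labels <- paste0("comp_", seq_len(K))
  c_uncon <- if (options$nonneg_concentrations) {
    if (is.na(baseline_col)) integer(0) else baseline_col
  } else seq_len(K)
  s_uncon <- if (options$nonneg_spectra) integer(0) else seq_along(free)
  total_ss <- sum(X^2)
  rss_history <- numeric(0)
  rss_prev <- Inf
  converged <- FALSE
  ridged <- FALSE
  C <- NULL
  reseeds <- integer(K)   # dead-component revivals, capped per column
  for (it in seq_len(options$max_iterations)) {
    ## C-step: X' ~ S C'
    XS <- X %*% S                                   # n x K
    sol <- fcnnls(crossprod(S), t(XS), unconstrained = c_uncon)
    ridged <- sol$ridged
    C <- t(sol$X)
    ## S-step on free columns only; the fixed-column contribution is removed
    ## through Gram identities rather than an n x bands residual matrix
    CtX <- crossprod(C, X)                          # K x bands
    if (length(free)) {
      CtC <- crossprod(C)
      AtB <- CtX[free, , drop = FALSE] -
        CtC[free, fixed, drop = FALSE] %*% t(S[, fixed, drop = FALSE])
      sol <- fcnnls(CtC[free, free, drop = FALSE], AtB,
                    unconstrained = s_uncon)
      ridged <- ridged || sol$ridged
      S[, free] <- t(sol$X)
    }
    ## revive dead free components: a free column whose concentrations were
    ## all clipped to zero contributes nothing, so its spectrum is reseeded
    ## from the dominant residual loading (leaves C.S' and the RSS unchanged)
    reseeded <- FALSE
    if (length(free)) {
      cmax <- max(colSums(abs(C)), 1e-300)
      dead <- free[colSums(abs(C[, free, drop = FALSE])) < 1e-12 * cmax]
      dead <- dead[reseeds[dead] < 3L]
      if (length(dead) && it < options$max_iterations) {
        R <- X - C %*% t(S)
        Rc <- sweep(R, 2L, colMeans(R), "-")
        ee <- eigen(crossprod(Rc), symmetric = TRUE)
        for (di in seq_along(dead)) {
          v <- ee$vectors[, min(di, ncol(ee$vectors))]
          if (sum(v) < 0) v <- -v
          v <- pmax(v, 0) + 1e-3
          S[, dead[di]] <- v / sqrt(sum(v^2))
          reseeds[dead[di]] <- reseeds[dead[di]] + 1L
        }
        reseeded <- TRUE
      }
    }
    ## RSS via the Gram identity ||X - C S'||^2 =
    ## ||X||^2 - 2 tr(S' X' C) + tr(S'S C'C); CtX is S-independent so it
    ## remains valid for the updated spectra
    rss <- max(total_ss - 2 * sum(t(CtX) * S) +
                 sum(crossprod(S) * crossprod(C)), 0)
    rss_history <- c(rss_history, rss)
    if (!reseeded && is.finite(rss_prev) &&
        (rss_prev - rss) <= options$rel_tol * max(rss_prev, total_ss * 1e-16)) {
      converged <- TRUE
      break
    }
    rss_prev <- rss
  }
  ## `ridged` reflects the final iteration only: transient rank deficiency
  ## during startup (e.g. a dead component before reseeding) is expected
  if (ridged)
    warning("rank-deficient spectral matrix at convergence; ",
            "ridge-regularised solves were used")
  ## unit-norm convention on free spectra (the product C S' is invariant)
  if (length(free)) {
    nrm <- sqrt(colSums(S[, free, drop = FALSE]^2))
    ok <- which(nrm > 1e-12)
    if (length(ok)) {
      S[, free[ok]] <- sweep(S[, free[ok], drop = FALSE], 2L, nrm[ok], "/")
      C[, free[ok]] <- sweep(C[, free[ok], drop = FALSE], 2L, nrm[ok], "*")
    }
  }
  ## canonical ordering: fixed (input order), free by explained signal,
  ## baseline last
  expl <- sqrt(colSums(C^2)) * sqrt(colSums(S^2))
  free_ord <- free[order(expl[free], decreasing = TRUE)]
  fixed_nb <- setdiff(fixed, baseline_col)
  ord <- c(fixed_nb, free_ord,
           if (!is.na(baseline_col)) baseline_col)
  model <- structure(list(
    S = S[, ord, drop = FALSE], C = C[, ord, drop = FALSE],
    fixed_flags = fixed_flags[ord],
    baseline_col = if (is.na(baseline_col)) NA_integer_ else length(ord),
    labels = labels[ord], rss_history = rss_history,
    converged = converged, options = options,
    wavelengths_nm = if (inherits(matrix, "unfolded_matrix"))
      matrix$wavelengths_nm else NULL),
    class = "mcr_model")
  colnames(model$S) <- model$labels
  colnames(model$C) <- model$labels
  model
}

#' @export
print.mcr_model <- function(x, ...) {
  cat(sprintf(
    "<mcr_model> %d components (%d fixed, %d free + baseline), %d pixels\n",
    ncol(x$S), sum(x$fixed_flags) - !is.na(x$baseline_col),
    sum(!x$fixed_flags), nrow(x$C)))
  cat(sprintf("  RSS %.4g after %d iterations (%s)\n",
              utils::tail(x$rss_history, 1), length(x$rss_history),
              if (x$converged) "converged" else "iteration limit"))
  invisible(x)
}

## lag-1 autocorrelation of a vector (1 for constant vectors)
.lag1 <- function(v) {
  v <- v - mean(v)
  s <- sum(v^2)
  if (s < .Machine$double.xmin) return(1)
  sum(v[-1] * v[-length(v)]) / s
}

#' PCA diagnostics of the fit residuals
#'
#' Computes the principal components of `matrix - C S'`. Smooth (spectrally
#' autocorrelated) top residual loadings indicate unmodeled signal; white
#' loadings indicate a clean fit. When the top residual eigenvalue is
#' negligible against the data variance the verdict is clean regardless of
#' the loading shape.
#'
#' @param model a fitted [fit_mcr()] model.
#' @param matrix the data it was fitted on.
#' @param structure_threshold lag-1 autocorrelation above which the verdict
#'   is `unmodeled_signal`.
#' @return list (class `residual_report`): `residual_eigenvalues`,
#'   `top_residual_loading`, `structure_score`, `verdict`.
#' @export
residual_pca <- function(model, matrix, structure_threshold = 0.5) {
  X <- .as_data_matrix(matrix)
  R <- X - model$C %*% t(model$S)
  Rc <- sweep(R, 2L, colMeans(R), "-")
  ee <- eigen(crossprod(Rc) / (nrow(R) - 1), symmetric = TRUE)
  ev <- pmax(ee$values, 0)
  loading <- ee$vectors[, 1]
  Xc <- sweep(X, 2L, colMeans(X), "-")
  data_var <- sum(Xc^2) / (nrow(X) - 1)
  score <- if (ev[1] <= 1e-12 * data_var) 0 else .lag1(loading)
  structure(list(residual_eigenvalues = ev, top_residual_loading = loading,
                 structure_score = score,
                 verdict = if (score > structure_threshold)
                   "unmodeled_signal" else "clean"),
            class = "residual_report")
}

#' Flag null or noise-like components
#'
#' A component is flagged when its share of the explained signal
#' (`||C_k|| * ||S_k||` relative to the non-baseline total) falls below
#' `share_floor`, or when its spectrum's lag-1 autocorrelation is below
#' `smoothness_floor` (noise-like). The baseline is exempt.
#'
#' @param model a fitted [fit_mcr()] model.
#' @param share_floor minimum explained-signal share (default 1%).
#' @param smoothness_floor minimum spectral lag-1 autocorrelation.
#' @return named logical vector, one flag per component.
#' @export
detect_null_components <- function(model, share_floor = 0.01,
                                   smoothness_floor = 0.5) {
  expl <- sqrt(colSums(model$C^2)) * sqrt(colSums(model$S^2))
  nb <- seq_len(ncol(model$S))
  if (!is.na(model$baseline_col)) nb <- nb[-model$baseline_col]
  total <- sum(expl[nb])
  share <- if (total > 0) expl / total else rep(0, length(expl))
  smooth <- apply(model$S, 2L, .lag1)
  flags <- share < share_floor | smooth < smoothness_floor
  if (!is.na(model$baseline_col)) flags[model$baseline_col] <- FALSE
  stats::setNames(flags, model$labels)
}

#' Automatic model-order selection for MCR-ALS
#'
#' Starts from the scree-elbow rank estimate (minus the number of fixed
#' components) and refits, incrementing the free-component count while the
#' residual PCA reports unmodeled signal and decrementing while any free
#' component is flagged null, until the model is both clean and null-free;
#' a final parsimony descent then confirms that no smaller order is also
#' clean and null-free (an over-specified fit can spread real signal over
#' all components without leaving an obvious null). If the search oscillates
#' between adjacent orders the smaller one is returned with a warning.
#'
#' @param matrix an [unfold()]ed matrix or plain matrix.
#' @param fixed_spectra optional bands x m matrix of equality-constrained
#'   (e.g. control) components; the baseline is always added separately.
#' @param options a [fit_options()]; the init seed for a fit with k free
#'   components is `options$seed + k`.
#' @param k_max largest free-component count explored.
#' @return the selected [fit_mcr()] model, with the search recorded in
#'   `$order_trace` (data.frame: k_free, verdict, n_null).
#' @export
select_model_order <- function(matrix, fixed_spectra = NULL,
                               options = fit_options(), k_max = 12L) {
  X <- .as_data_matrix(matrix)
  nf <- if (is.null(fixed_spectra)) 0L else ncol(as.matrix(fixed_spectra))
  sug <- scree(matrix, k_max = k_max)$suggested_rank
  k <- min(max(sug - nf, 0L), k_max)
  cache <- list()
  trace <- data.frame(k_free = integer(0), verdict = character(0),
                      n_null = integer(0))
  fit_k <- function(k) {
    key <- as.character(k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    init <- init_components(k, ncol(X), seed = options$seed + k,
                            fixed_spectra = fixed_spectra)
    m <- fit_mcr(matrix, init$S, init$fixed_flags, options = options,
                 baseline_col = init$baseline_col)
    cache[[key]] <<- m
    m
  }
  visited <- integer(0)
  diagnose <- function(k) {
    model <- fit_k(k)
    rp <- residual_pca(model, matrix)
    nulls <- detect_null_components(model) & !model$fixed_flags
    trace <<- rbind(trace, data.frame(k_free = k, verdict = rp$verdict,
                                      n_null = sum(nulls)))
    list(model = model, clean = rp$verdict == "clean",
         any_null = any(nulls))
  }
  repeat {
    dg <- diagnose(k)
    model <- dg$model
    visited <- c(visited, k)
    k_next <-
      if (dg$any_null) k - 1L
      else if (!dg$clean && k < k_max) k + 1L
      else k
    if (k_next == k) {
      if (!dg$clean)
        warning("model-order search hit k_max with residual structure ",
                "remaining")
      break
    }
    if (k_next < 0L) break
    if (k_next %in% visited) {
      warning("model-order search oscillated between ", min(k, k_next),
              " and ", max(k, k_next), " free components; returning the ",
              "smaller order")
      k <- min(k, k_next)
      model <- fit_k(k)
      break
    }
    k <- k_next
  }
  ## parsimony descent: an over-specified fit can redistribute real signal
  ## over all components without leaving a null, so verify minimality by
  ## stepping down while the smaller model is still clean and null-free
  while (k > 0L && !(k - 1L) %in% visited) {
    dg <- diagnose(k - 1L)
    visited <- c(visited, k - 1L)
    if (dg$clean && !dg$any_null) {
      k <- k - 1L
      model <- dg$model
    } else break
  }
  model$order_trace <- trace
  model
}

#' Map a fitted model's concentrations onto a cube
#'
#' Solves the concentration coefficients of a cube's mask-positive pixels
#' against the frozen spectral matrix (same constraints as the fit) and
#' refolds each component column to an image; off-mask pixels are zero.
#'
#' @param model a fitted [fit_mcr()] model.
#' @param cube a reflectance [hyper_cube()] on the model's wavelength grid.
#' @param mask a [mask_file()] aligned with the cube.
#' @return named list of lines x samples concentration images.
#' @export
map_concentrations <- function(model, cube, mask) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (!is.null(model$wavelengths_nm) &&
      !isTRUE(all.equal(cube$wavelengths_nm, model$wavelengths_nm)))
    stop("cube wavelength grid is incompatible with the model")
  if (dim(cube$values)[3] != nrow(model$S))
    stop("cube band count is incompatible with the model")
  um <- unfold(list(cube), list(mask))
  c_uncon <- if (model$options$nonneg_concentrations) {
    if (is.na(model$baseline_col)) integer(0) else model$baseline_col
  } else seq_len(ncol(model$S))
  sol <- fcnnls(crossprod(model$S), t(um$data %*% model$S),
                unconstrained = c_uncon)
  C <- t(sol$X)
  d <- dim(cube$values)
  out <- lapply(seq_len(ncol(C)), function(k) {
    img <- matrix(0, d[1], d[2])
    img[cbind(um$index$line, um$index$sample)] <- C[, k]
    img
  })
  stats::setNames(out, model$labels)
}

#' Write / read an MCR model as columnar text
#'
#' The format is a tab-separated table (wavelength + one column per spectral
#' component) preceded by `#`-prefixed header lines recording labels, fixed
#' flags and the baseline column. Concentrations are not serialized.
#'
#' @param model a fitted [fit_mcr()] model.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_mcr_model <- function(model, path) {
  hdr <- c(paste0("# labels\t", paste(model$labels, collapse = "\t")),
           paste0("# fixed\t", paste(as.integer(model$fixed_flags),
                                     collapse = "\t")),
           paste0("# baseline_col\t", model$baseline_col))
  wl <- model$wavelengths_nm
  if (is.null(wl)) wl <- seq_len(nrow(model$S))
  tab <- cbind(wavelength_nm = wl, model$S)
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  utils::write.table(format(tab, digits = 17, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mcr_model
#' @export
read_mcr_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key))]
    strsplit(sub(paste0("# ", key, "\t"), "", ln), "\t")[[1]]
  }
  labels <- get("labels")
  fixed <- as.logical(as.integer(get("fixed")))
  bcol <- as.integer(get("baseline_col"))
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t")
  S <- as.matrix(tab[, -1, drop = FALSE])
  colnames(S) <- labels
  structure(list(S = S, C = NULL, fixed_flags = fixed, baseline_col = bcol,
                 labels = labels, rss_history = numeric(0), converged = NA,
                 options = fit_options(),
                 wavelengths_nm = tab[[1]]),
            class = "mcr_model")
}
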