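## End-to-end study orchestration: simulate -> calibrate -> mask -> control
## model -> per-condition constrained extension -> intensity tables ->
## Games-Howell statistics -> predominant-component stress classification.

.stress_conditions <- c(NaCl = "NaCl", CuCl2 = "CuCl2", CsCl = "CsCl")

#' Classify replicates by their predominant stress component
#'
#' Each replicate's predicted label is the stress component with the largest
#' per-plant mean intensity, mapped to its condition; if every stress
#' intensity falls below `floor` the replicate is called control. The default
#' floor is the 95th percentile of the control replicates' stress
#' intensities (learned from the control group).
#'
#' @param per_plant_intensities data.frame with columns `replicate`,
#'   `condition`, `component`, `mean_intensity` (one row per replicate x
#'   stress component).
#' @param floor intensity floor below which a replicate is called control;
#'   `NULL` learns it from the control group.
#' @param component_labels named map from stress-component name to predicted
#'   condition label. Components not in the map (e.g. the first cesium
#'   component, whose sibling is the stronger indicator) are ignored.
#' @return data.frame: `replicate`, `condition` (true label), `predicted`,
#'   `floor`.
#' @export
classify_stress <- function(per_plant_intensities, floor = NULL,
                            component_labels = c(NaCl = "NaCl",
                                                 CuCl2 = "CuCl2",
                                                 CsCl_2 = "CsCl")) {
  need <- c("replicate", "condition", "component", "mean_intensity")
  miss <- setdiff(need, names(per_plant_intensities))
  if (length(miss)) stop("intensity table lacks column(s): ",
                         paste(miss, collapse = ", "))
  d <- per_plant_intensities[per_plant_intensities$component %in%
                               names(component_labels), ]
  miss <- setdiff(names(component_labels), unique(d$component))
  if (length(miss)) stop("intensity table lacks stress component(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(floor)) {
    ctrl <- d$mean_intensity[d$condition == "control"]
    floor <- if (length(ctrl)) unname(stats::quantile(ctrl, 0.95, type = 7))
             else 0
  }
  keys <- unique(d[, c("condition", "replicate")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- d[d$condition == keys$condition[i] &
               d$replicate == keys$replicate[i], ]
    ints <- stats::setNames(sub$mean_intensity, sub$component)[
      names(component_labels)]
    pred <- if (all(ints < floor)) "control"
            else unname(component_labels[which.max(ints)])
    data.frame(replicate = keys$replicate[i], condition = keys$condition[i],
               predicted = pred, floor = floor, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Render up to three concentration maps as an RGB image file
#'
#' Channel intensity is proportional to concentration, normalised to the
#' image's 99th percentile (per component); off-mask pixels (zero
#' concentration) are black.
#'
#' @param maps named list of 1-3 concentration matrices.
#' @param channels character vector assigning each map to `"red"`,
#'   `"green"` or `"blue"` (same length/order as `maps`).
#' @param path output PNG path.
#' @return invisibly, `path`.
#' @export
render_component_map <- function(maps, channels, path) {
  if (length(maps) > 3L) stop("invalid assignment: at most 3 components")
  channels <- match.arg(channels, c("red", "green", "blue"),
                        several.ok = TRUE)
  if (length(channels) != length(maps) || anyDuplicated(channels))
    stop("invalid assignment: one distinct channel per component")
  d <- dim(maps[[1]])
  img <- array(0, dim = c(d[1], d[2], 3L))
  ch_idx <- c(red = 1L, green = 2L, blue = 3L)
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    top <- stats::quantile(m, 0.99, type = 7)
    if (top > 0) m <- m / top
    img[, , ch_idx[channels[i]]] <- pmin(pmax(m, 0), 1)
  }
  png::writePNG(img, target = path)
  invisible(path)
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full simulated study
#'
#' Executes, in order: scene generation, white/dark calibration, plant
#' masking, model-order selection on the pooled control pixels, constrained
#' per-condition extension (control components frozen; for the
#' high-potassium arm the cesium stress components are frozen too),
#' concentration mapping, per-plant mean intensities, Games-Howell
#' comparisons per stress component, and predominant-component stress
#' classification.
#'
#' @param config an [experiment_config()].
#' @param seed master integer seed; all randomness derives from it.
#' @param output_dir optional directory; when given, intensity/comparison/
#'   classification tables (TSV), the model files and per-replicate stress
#'   overlay PNGs are written there.
#' @param fit a [fit_options()] template (its seed is replaced by `seed`).
#' @param alpha significance level for the pairwise comparisons.
#' @param k_max largest free-component count explored per stage.
#' @return list: `control_model`, `stress_models`, `combined_model`,
#'   `intensities`, `comparisons`, `classification`, `accuracy`, `masks`,
#'   `library`, `config`, `seed`.
#' @export
run_full_study <- function(config = experiment_config(), seed = 1L,
                           output_dir = NULL, fit = fit_options(),
                           alpha = 0.05, k_max = 8L) {
  fit$seed <- as.integer(seed)
  ex <- generate_experiment(config, seed = seed)
  scenes <- ex$scenes
  refl <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    refl[[i]] <- calibrate_reflectance(scenes[[i]]$raw_cube,
                                       scenes[[i]]$white_frame,
                                       scenes[[i]]$dark_frame)
    ## raw digital numbers are no longer needed; keep memory bounded
    scenes[[i]]$raw_cube <- NULL
    ex$scenes[[i]]$raw_cube <- NULL
  }
  masks <- lapply(refl, build_mask)
  cond_of <- vapply(scenes, function(s) s$truth$condition_label, "")
  day_of <- vapply(scenes, function(s) s$truth$day, 1L)
  rep_of <- vapply(scenes, function(s) s$truth$replicate_id, 1L)

  sel_fit <- function(cond, fixed = NULL) {
    idx <- which(cond_of == cond)
    if (!length(idx)) return(NULL)
    um <- unfold(refl[idx], masks[idx])
    select_model_order(um, fixed_spectra = fixed, options = fit,
                       k_max = k_max)
  }

  if (!"control" %in% cond_of) stop("config must include a control condition")
  control_model <- sel_fit("control")
  ctrl_S <- control_model$S[, !is_baseline(control_model), drop = FALSE]
  colnames(ctrl_S) <- paste0("control_", seq_len(ncol(ctrl_S)))

  stress_models <- list()
  stress_S <- NULL
  for (cond in intersect(names(.stress_conditions), unique(cond_of))) {
    m <- sel_fit(cond, fixed = ctrl_S)
    new_cols <- which(!m$fixed_flags)
    if (length(new_cols)) {
      Sn <- m$S[, new_cols, drop = FALSE]
      colnames(Sn) <- paste0(cond, "_", seq_along(new_cols))
      stress_S <- cbind(stress_S, Sn)
    }
    stress_models[[cond]] <- m
  }
  if ("CsCl_K" %in% cond_of) {
    cs_cols <- grep("^CsCl_", colnames(stress_S) %||% character(0))
    fixed_k <- cbind(ctrl_S, stress_S[, cs_cols, drop = FALSE])
    stress_models[["CsCl_K"]] <- sel_fit("CsCl_K", fixed = fixed_k)
  }

  ## combined frozen model for mapping all components onto every scene
  all_S <- cbind(ctrl_S, stress_S, baseline = rep(1, nrow(ctrl_S)))
  combined <- structure(list(
    S = all_S, C = NULL, fixed_flags = rep(TRUE, ncol(all_S)),
    baseline_col = ncol(all_S), labels = colnames(all_S),
    rss_history = numeric(0), converged = TRUE, options = fit,
    wavelengths_nm = refl[[1]]$wavelengths_nm), class = "mcr_model")

  final_day <- max(day_of)
  rows <- list()
  overlay <- list()
  for (i in which(day_of == final_day)) {
    cmaps <- map_concentrations(combined, refl[[i]], masks[[i]])
    overlay[[i]] <- cmaps
    for (comp in setdiff(colnames(all_S), "baseline")) {
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep_of[i], condition = cond_of[i], day = day_of[i],
        component = comp,
        mean_intensity = per_plant_mean(cmaps[[comp]], masks[[i]]),
        stringsAsFactors = FALSE)
    }
  }
  intensities <- do.call(rbind, rows)

  stress_comps <- setdiff(colnames(stress_S) %||% character(0), NULL)
  comparisons <- list()
  for (comp in stress_comps) {
    sub <- intensities[intensities$component == comp, ]
    grp <- split(sub$mean_intensity, sub$condition)
    grp <- grp[vapply(grp, length, 1L) >= 2L]
    if (length(grp) >= 2L) {
      gh <- games_howell(grp, alpha = alpha)
      gh <- cbind(component = comp, gh)
      comparisons[[comp]] <- gh
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons)
                 else NULL

  classification <- if (length(stress_comps)) {
    ## every fitted stress component votes for its condition of origin
    lab_map <- character(0)
    for (cond in names(.stress_conditions)) {
      comps <- grep(paste0("^", cond, "_"), stress_comps, value = TRUE)
      lab_map[comps] <- cond
    }
    classify_stress(intensities, component_labels = lab_map)
  } else NULL
  accuracy <- NA_real_
  if (!is.null(classification)) {
    stressed <- classification$condition %in% names(.stress_conditions)
    if (any(stressed))
      accuracy <- mean(classification$predicted[stressed] ==
                         classification$condition[stressed])
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(intensities, file.path(output_dir, "intensities.tsv"))
    if (!is.null(comparisons))
      .write_tsv(comparisons, file.path(output_dir, "comparisons.tsv"))
    if (!is.null(classification))
      .write_tsv(classification, file.path(output_dir, "classification.tsv"))
    write_mcr_model(control_model, file.path(output_dir, "control_model.tsv"))
    for (cond in names(stress_models))
      write_mcr_model(stress_models[[cond]],
                      file.path(output_dir, paste0(cond, "_model.tsv")))
    writeLines(as.character(seed), file.path(output_dir, "seed.txt"))
    rgb_comps <- intersect(c("CuCl2_1", "NaCl_1", "CsCl_2"), stress_comps)
    for (i in which(day_of == final_day)) {
      if (length(rgb_comps) >= 1L) {
        maps <- overlay[[i]][rgb_comps]
        render_component_map(
          maps, channels = c("green", "blue", "red")[seq_along(maps)],
          path = file.path(output_dir,
                           sprintf("stress_overlay_%s_rep%d.png",
                                   cond_of[i], rep_of[i])))
      }
    }
  }

  list(control_model = control_model, stress_models = stress_models,
       combined_model = combined, intensities = intensities,
       comparisons = comparisons, classification = classification,
       accuracy = accuracy, masks = masks, library = ex$library,
       config = config, seed = seed)
}

## which columns of a model are the baseline
is_baseline <- function(model) {
  flags <- rep(FALSE, ncol(model$S))
  if (!is.na(model$baseline_col)) flags[model$baseline_col] <- TRUE
  flags
}

`%||%` <- function(a, b) if (is.null(a)) b else a
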