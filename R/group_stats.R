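#' Per-plant mean signal intensity
#'
#' The replicate-level statistic: the mean of one component's concentration
#' over the mask-positive (plant) pixels of one image.
#'
#' @param concentration_map lines x samples numeric matrix.
#' @param mask a [mask_file()] or binary matrix.
#' @return scalar mean.
#' @export
per_plant_mean <- function(concentration_map, mask) {
  if (!inherits(mask, "mask_file")) mask <- mask_file(mask)
  if (mask$plant_pixel_count == 0L)
    stop("undefined mean: the mask selects no pixels")
  mean(concentration_map[mask$grid == 1L])
}

#' Upper tail of the studentized range distribution
#'
#' @param q non-negative quantile (studentized-range scale).
#' @param k number of groups (>= 2).
#' @param df degrees of freedom (> 0).
#' @return `P(Q > q)`.
#' @export
studentized_range_sf <- function(q, k, df) {
  if (any(q < 0) || any(k < 2) || any(df <= 0))
    stop("domain error: need q >= 0, k >= 2, df > 0")
  stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
}

#' Games-Howell pairwise comparisons
#'
#' Post-hoc pairwise tests for groups with unequal variances and sizes. For
#' each pair the statistic is
#' `q = |m_i - m_j| / sqrt((s_i^2/n_i + s_j^2/n_j) / 2)`, referred to the
#' studentized range distribution with `k` groups and Welch-Satterthwaite
#' degrees of freedom. When both groups have zero variance and equal means,
#' p = 1 by convention.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha family significance level.
#' @return data.frame with one row per pair: `group1`, `group2`,
#'   `mean_diff`, `q_statistic`, `df`, `p_value`, `significant`.
#' @export
games_howell <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(names(groups)) || anyNA(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  n <- vapply(groups, length, 1L)
  if (any(n < 2L)) stop("invalid group: every group needs n >= 2")
  m <- vapply(groups, mean, 1)
  v <- vapply(groups, stats::var, 1)
  if (any(!is.finite(v))) stop("non-finite group variance")
  k <- length(groups)
  pairs <- utils::combn(k, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    se2 <- v[i] / n[i] + v[j] / n[j]
    diff <- m[i] - m[j]
    if (se2 == 0) {
      q <- if (diff == 0) 0 else Inf
      df <- n[i] + n[j] - 2
      pv <- if (diff == 0) 1 else 0
    } else {
      q <- abs(diff) / sqrt(se2 / 2)
      df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                       (v[j] / n[j])^2 / (n[j] - 1))
      pv <- studentized_range_sf(q, k, df)
    }
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               mean_diff = diff, q_statistic = q, df = df, p_value = pv,
               significant = pv < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-sample equal-variance t-test
#'
#' Pooled-variance two-sided t-test with `n_a + n_b - 2` degrees of freedom.
#' Zero pooled variance with equal means yields p = 1 by convention.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return list: `t`, `df`, `p_value`.
#' @export
t_test_equal_var <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  df <- length(a) + length(b) - 2
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    df
  if (sp2 == 0) {
    d <- mean(a) - mean(b)
    return(list(t = if (d == 0) 0 else sign(d) * Inf, df = df,
                p_value = if (d == 0) 1 else 0))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Box-and-whisker summary with 1.5 x IQR outliers
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). Whiskers extend to the most extreme data
#' within 1.5 interquartile ranges of the box; points beyond are outliers.
#'
#' @param values numeric vector (n >= 1).
#' @return list (class `box_summary`): `q25`, `median`, `q75`,
#'   `whisker_low`, `whisker_high`, `outliers`.
#' @export
boxplot_summary <- function(values) {
  if (!length(values)) stop("need at least one value")
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- qs[3] - qs[1]
  lo_fence <- qs[1] - 1.5 * iqr
  hi_fence <- qs[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  structure(list(q25 = qs[1], median = qs[2], q75 = qs[3],
                 whisker_low = min(values[inside]),
                 whisker_high = max(values[inside]),
                 outliers = values[!inside]),
            class = "box_summary")
}
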