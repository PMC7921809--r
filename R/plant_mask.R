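#' Spectral windows used by the plant-pixel decision rule
#'
#' Window membership is inclusive of both endpoints. The blue-green lower
#' bound is configurable because the published rule does not pin it; the
#' default is 400 nm.
#'
#' @param blue_green_lower lower bound (nm) of the blue-green window.
#' @return named list of `(lower, upper)` windows in nm.
#' @export
band_windows <- function(blue_green_lower = 400) {
  w <- list(red = c(750, 850), orange = c(550, 600), blue = c(410, 450),
            blue_green = c(blue_green_lower, 450))
  for (nm in names(w)) if (w[[nm]][1] >= w[[nm]][2])
    stop("window `", nm, "` has lower >= upper")
  w
}

#' Decision thresholds for plant-pixel classification
#'
#' All comparisons in the rule are strict ("greater than").
#'
#' @param red_cutoff reflectance threshold on the red-window average.
#' @param orange_to_blue threshold on the orange/blue ratio.
#' @param red_to_blue_green threshold on the red/blue-green ratio.
#' @return named list of thresholds.
#' @export
mask_thresholds <- function(red_cutoff = 0.5, orange_to_blue = 1.5,
                            red_to_blue_green = 3.0) {
  th <- list(red_cutoff = red_cutoff, orange_to_blue = orange_to_blue,
             red_to_blue_green = red_to_blue_green)
  if (any(unlist(th) <= 0)) stop("thresholds must be strictly positive")
  th
}

#' Mean reflectance over a wavelength window
#'
#' Arithmetic mean of the bands whose wavelength lies inside
#' `[window[1], window[2]]` (inclusive).
#'
#' @param spectrum numeric reflectance vector.
#' @param wavelengths wavelengths (nm), same length as `spectrum`.
#' @param window numeric `(lower, upper)` in nm.
#' @return scalar mean reflectance.
#' @export
band_average <- function(spectrum, wavelengths, window) {
  sel <- wavelengths >= window[1] & wavelengths <= window[2]
  if (!any(sel)) stop("no bands fall inside window [", window[1], ", ",
                      window[2], "] nm")
  mean(spectrum[sel])
}

## quotient with the +Inf convention for zero denominators, so threshold
## comparisons stay defined for bright-NIR / zero-blue pixels
.safe_ratio <- function(num, den) {
  r <- num / den
  r[den == 0] <- Inf
  r
}

#' The seven per-pixel properties of the plant decision rule
#'
#' @param spectrum numeric reflectance vector for one pixel.
#' @param wavelengths wavelengths (nm).
#' @param windows see [band_windows()].
#' @param thresholds see [mask_thresholds()].
#' @return named list: the four window averages, the two ratios, and the
#'   red-cutoff flag.
#' @export
pixel_properties <- function(spectrum, wavelengths,
                             windows = band_windows(),
                             thresholds = mask_thresholds()) {
  red <- band_average(spectrum, wavelengths, windows$red)
  orange <- band_average(spectrum, wavelengths, windows$orange)
  blue <- band_average(spectrum, wavelengths, windows$blue)
  blue_green <- band_average(spectrum, wavelengths, windows$blue_green)
  list(red_avg = red, orange_avg = orange, blue_avg = blue,
       blue_green_avg = blue_green,
       orange_to_blue = .safe_ratio(orange, blue),
       red_to_blue_green = .safe_ratio(red, blue_green),
       red_cutoff_flag = red > thresholds$red_cutoff)
}

#' Plant-pixel decision rule
#'
#' A pixel is plant if the red cutoff holds AND (the orange/blue ratio
#' exceeds its threshold OR the red/blue-green ratio exceeds its threshold).
#'
#' @param props output of [pixel_properties()].
#' @param thresholds see [mask_thresholds()].
#' @return logical scalar.
#' @export
is_plant_pixel <- function(props, thresholds = mask_thresholds()) {
  props$red_cutoff_flag &&
    (props$orange_to_blue > thresholds$orange_to_blue ||
       props$red_to_blue_green > thresholds$red_to_blue_green)
}

#' Build a plant mask from a reflectance cube
#'
#' Applies the pixel decision rule independently to every pixel. Vectorised
#' over pixels: window averages are computed by band subsetting, so the
#' result is identical to looping [is_plant_pixel()] over all spectra.
#'
#' @param cube a [hyper_cube()] of reflectance.
#' @param windows see [band_windows()].
#' @param thresholds see [mask_thresholds()].
#' @return a [mask_file()].
#' @export
build_mask <- function(cube, windows = band_windows(),
                       thresholds = mask_thresholds()) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$values)
  flat <- matrix(cube$values, nrow = d[1] * d[2], ncol = d[3])
  wl <- cube$wavelengths_nm
  win_mean <- function(window) {
    sel <- wl >= window[1] & wl <= window[2]
    if (!any(sel)) stop("no bands fall inside window [", window[1], ", ",
                        window[2], "] nm")
    rowMeans(flat[, sel, drop = FALSE])
  }
  red <- win_mean(windows$red)
  orange <- win_mean(windows$orange)
  blue <- win_mean(windows$blue)
  blue_green <- win_mean(windows$blue_green)
  plant <- (red > thresholds$red_cutoff) &
    (.safe_ratio(orange, blue) > thresholds$orange_to_blue |
       .safe_ratio(red, blue_green) > thresholds$red_to_blue_green)
  mask_file(matrix(as.integer(plant), nrow = d[1], ncol = d[2]))
}

#' Leaf area from a plant mask
#'
#' @param mask a [mask_file()] (or binary matrix).
#' @param pixel_area_cm2 area of one pixel in cm^2; default 0.000112.
#' @return leaf area in cm^2.
#' @export
leaf_area <- function(mask, pixel_area_cm2 = 0.000112) {
  if (!inherits(mask, "mask_file")) mask <- mask_file(mask)
  if (pixel_area_cm2 <= 0) stop("pixel area must be positive")
  mask$plant_pixel_count * pixel_area_cm2
}

#' Root area from a grayscale root photograph
#'
#' Binarizes a grayscale image (white roots on black background), optionally
#' drops particles below a minimum size, and converts the foreground pixel
#' count to cm^2.
#'
#' @param gray_image numeric matrix in `[0, 1]`.
#' @param threshold binarization threshold; `NULL` (default) uses Otsu's
#'   method.
#' @param scale_cm_per_px image scale; foreground area is
#'   `count * scale^2`.
#' @param min_particle_px connected components smaller than this are removed
#'   (default 5 px; 0 disables filtering).
#' @return root area in cm^2.
#' @export
root_area <- function(gray_image, threshold = NULL, scale_cm_per_px,
                      min_particle_px = 5L) {
  gray_image <- as.matrix(gray_image)
  if (!length(gray_image)) stop("empty image")
  if (scale_cm_per_px <= 0) stop("scale must be positive")
  if (is.null(threshold)) {
    img <- EBImage::Image(gray_image)
    threshold <- EBImage::otsu(img, range = c(0, 1))
  }
  bin <- gray_image > threshold
  if (!any(bin)) return(0)
  if (min_particle_px > 0) {
    lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
    sizes <- tabulate(as.integer(EBImage::imageData(lab)))
    keep <- which(sizes >= min_particle_px)
    bin <- matrix(as.integer(EBImage::imageData(lab)) %in% keep,
                  nrow = nrow(bin))
  }
  sum(bin) * scale_cm_per_px^2
}
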