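# Intensity-distribution statistics: centrosome enrichment ratio over 20x20
# px ROIs and the radial cumulative-integrated-density radius (r80) used to
# quantify vesicle dispersion around the MTOC.

#' Centrosome enrichment ratio
#'
#' Mean intensity of a square ROI centered on the centrosome divided by the
#' mean of the per-site means of three (or more) equally sized cytoplasmic
#' ROIs.
#'
#' @param img `gray_image` or numeric matrix.
#' @param centrosome_xy Centrosome `c(x, y)`, pixels.
#' @param cytoplasm_xys List of at least three `c(x, y)` cytoplasmic sites, or
#'   an n x 2 matrix (columns x, y).
#' @param roi_px ROI side length in pixels (default 20). All ROIs must lie
#'   fully inside the image.
#' @return The enrichment ratio (dimensionless).
#' @export
centrosome_ratio <- function(img, centrosome_xy, cytoplasm_xys, roi_px = 20) {
  px <- img_pixels(img)
  if (is.matrix(cytoplasm_xys)) cytoplasm_xys <- asplit(cytoplasm_xys, 1)
  if (length(cytoplasm_xys) < 3) abort("at least 3 cytoplasmic sites are required")
  roi_mean <- function(xy) {
    half <- roi_px / 2
    r0 <- round(xy[2] - half + 1); r1 <- round(xy[2] + half)
    c0 <- round(xy[1] - half + 1); c1 <- round(xy[1] + half)
    if (r0 < 1 || c0 < 1 || r1 > nrow(px) || c1 > ncol(px))
      abort("ROI extends outside the image")
    mean(px[r0:r1, c0:c1])
  }
  cen <- roi_mean(centrosome_xy)
  cyt <- mean(vapply(cytoplasm_xys, roi_mean, numeric(1)))
  cen / cyt
}

#' Radial profile of integrated density
#'
#' Integrated density (sum of intensities) in concentric 1-px rings around
#' `center`; each pixel belongs to the ring containing its center-to-center
#' distance (`[r, r + 1)`). The cumulative fraction is monotone and ends at 1
#' over the profiled region.
#'
#' @param img `gray_image` or numeric matrix.
#' @param center `c(x, y)` in pixels; must lie inside the image.
#' @param r_max Outermost radius, pixels; defaults to the largest distance
#'   from `center` to any (masked) pixel.
#' @param mask Optional logical matrix restricting the profiled pixels.
#' @return A `radial_profile` object: tibble with `r_inner`, `r_outer`,
#'   `integrated_density`, `cumulative_fraction`, plus attributes `center`
#'   and `total_density`.
#' @export
radial_profile <- function(img, center, r_max = NULL, mask = NULL) {
  px <- img_pixels(img)
  if (center[1] < 1 || center[1] > ncol(px) || center[2] < 1 || center[2] > nrow(px))
    abort("`center` must lie inside the image")
  d <- sqrt(outer((seq_len(nrow(px)) - center[2])^2,
                  (seq_len(ncol(px)) - center[1])^2, "+"))
  keep <- if (is.null(mask)) rep(TRUE, length(px)) else as.vector(mask)
  r_max <- r_max %||% max(d[keep])
  if (r_max <= 0) abort("`r_max` must be positive")
  n_rings <- ceiling(r_max + 1e-9)
  keep <- keep & as.vector(d) < n_rings
  ring <- floor(d[keep])
  dens <- tapply(px[keep], factor(ring, levels = 0:(n_rings - 1)), sum)
  dens[is.na(dens)] <- 0
  total <- sum(dens)
  cumfrac <- if (total != 0) cumsum(dens) / total else cumsum(dens) * 0
  out <- tibble(r_inner = 0:(n_rings - 1), r_outer = 1:n_rings,
                integrated_density = as.numeric(dens),
                cumulative_fraction = as.numeric(cumfrac))
  structure(out, center = center, total_density = total,
            pixel_size_um = img_pixel_size(img),
            class = c("radial_profile", class(out)))
}

#' Radius enclosing a given fraction of cumulative integrated density
#'
#' Smallest radius at which the cumulative fraction reaches `fraction`,
#' linearly interpolated inside the crossing ring. With the default
#' `fraction = 0.8` this is the r80 dispersion readout.
#'
#' @param profile A [radial_profile()].
#' @param fraction Target cumulative fraction in (0, 1].
#' @return Radius in pixels (attribute `um` carries the calibrated value).
#' @export
radius_at_fraction <- function(profile, fraction = 0.8) {
  if (attr(profile, "total_density") == 0)
    abort("profile of an all-zero image has no defined radius")
  cf <- profile$cumulative_fraction
  if (max(cf) < fraction) abort("cumulative fraction never reaches `fraction`")
  i <- which(cf >= fraction)[1]
  prev <- if (i == 1) 0 else cf[i - 1]
  r <- profile$r_inner[i] + (fraction - prev) / (cf[i] - prev)
  structure(r, um = r * attr(profile, "pixel_size_um"))
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %d rings around (%.1f, %.1f), total density %.4g\n",
              nrow(x), attr(x, "center")[1], attr(x, "center")[2],
              attr(x, "total_density")))
  NextMethod()
}
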