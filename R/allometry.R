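#' Crown-radius allometry coefficient sets
#'
#' Crown radius is predicted from stem girth as
#' \eqn{cr = a + b\sqrt{gbh}} with \eqn{cr} in m and \eqn{gbh} in cm.
#' Three published coefficient sets are available: the pooled 17-species
#' regression (\code{"published17"}, the default used throughout),
#' the 8-abundant-species regression (\code{"published8"}), and the
#' rounded two-digit form (\code{"rounded"}) used in worked size tables.
#'
#' @param variant one of \code{"published17"}, \code{"published8"},
#'   \code{"rounded"}, or a numeric length-2 vector \code{c(intercept, slope)}
#'   for a custom (e.g. per-species) allometry.
#' @return an object of class \code{allometry_coefficients}:
#'   list with \code{intercept} (m) and \code{slope} (m cm^-1/2).
#' @export
#' @examples
#' allometry_coefficients("rounded")
allometry_coefficients <- function(variant = "published17") {
  if (is.numeric(variant)) {
    stopifnot(length(variant) == 2)
    out <- list(intercept = variant[[1]], slope = variant[[2]],
                variant = "custom")
  } else {
    out <- switch(match.arg(variant, c("published17", "published8", "rounded")),
      published17 = list(intercept = -1.003, slope = 0.523,
                         variant = "published17"),
      published8  = list(intercept = -0.959, slope = 0.516,
                         variant = "published8"),
      rounded     = list(intercept = -1.0, slope = 0.52, variant = "rounded")
    )
  }
  if (out$slope <= 0) stop("allometry slope must be positive")
  class(out) <- "allometry_coefficients"
  out
}

#' Stem basal area from girth
#'
#' \eqn{ba = gbh^2 / (4\pi)}: the cross-sectional area of a circular stem
#' of circumference \code{gbh}.
#'
#' @param gbh girth at breast height, cm (vectorized, must be >= 0).
#' @return basal area in cm^2.
#' @export
#' @examples
#' basal_area(10)   # 7.958 cm^2
#' basal_area(300)  # 7162 cm^2
basal_area <- function(gbh) {
  if (any(gbh < 0, na.rm = TRUE)) stop("gbh must be non-negative")
  gbh^2 / (4 * pi)
}

#' Girth from basal area (inverse of \code{basal_area})
#' @param ba basal area, cm^2.
#' @return gbh in cm.
#' @export
gbh_from_basal_area <- function(ba) {
  if (any(ba < 0, na.rm = TRUE)) stop("ba must be non-negative")
  sqrt(4 * pi * ba)
}

#' Crown radius from girth
#'
#' Linear allometry on square-root girth, clamped at zero (the linear
#' predictor crosses zero near gbh 3.7 cm, below the usual 10 cm census
#' floor, so the clamp is rarely active).
#'
#' @param gbh girth at breast height, cm (vectorized, > 0).
#' @param coeffs an \code{allometry_coefficients} object (or variant name).
#' @return crown radius in m.
#' @export
#' @examples
#' crown_radius(50)                # 2.7 m
#' crown_radius(300, "rounded")    # 8.007 m
crown_radius <- function(gbh, coeffs = allometry_coefficients()) {
  if (!inherits(coeffs, "allometry_coefficients"))
    coeffs <- allometry_coefficients(coeffs)
  if (any(gbh <= 0, na.rm = TRUE)) stop("gbh must be positive")
  pmax(0, coeffs$intercept + coeffs$slope * sqrt(gbh))
}

#' Crown (canopy) area from crown radius
#'
#' @param cr crown radius, m (vectorized, >= 0).
#' @return crown area in m^2 (\eqn{\pi cr^2}).
#' @export
crown_area <- function(cr) {
  if (any(cr < 0, na.rm = TRUE)) stop("cr must be non-negative")
  pi * cr^2
}

#' Plot-level canopy cover and fold-overlap (LAI)
#'
#' Sums predicted individual crown areas over all alive stems, with no
#' subtraction of crown overlap, so the ratio cover / land area is a
#' fold-overlap (leaf area index style) number that may exceed 1.
#'
#' @param trees census data frame with columns \code{gbh} (cm) and
#'   optionally \code{status} (only rows with status "alive" are counted;
#'   if absent all rows count).
#' @param plot_area_ha land surface area in hectares.
#' @param coeffs allometry coefficients.
#' @return list with \code{cover_ha} (summed crown area, ha) and
#'   \code{lai} (cover / plot area).
#' @export
canopy_cover <- function(trees, plot_area_ha,
                         coeffs = allometry_coefficients()) {
  stopifnot(plot_area_ha > 0)
  g <- trees$gbh
  if (!is.null(trees$status)) g <- g[trees$status == "alive"]
  g <- g[!is.na(g)]
  cover_m2 <- if (length(g)) sum(crown_area(crown_radius(g, coeffs))) else 0
  cover_ha <- cover_m2 / 1e4
  list(cover_ha = cover_ha, lai = cover_ha / plot_area_ha)
}
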