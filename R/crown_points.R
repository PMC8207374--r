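# Crown point clouds: each tree's zone of influence as a disc of weighted
# random points. Seeding contract: a master seed plus a deterministic
# per-tree substream derived from (seed, tree_id), so per-tree clouds do
# not depend on the order trees are processed in.

# Deterministic 31-bit stream id from a master seed and a string key.
# Horner hash mod (2^31 - 1); all intermediates stay below 2^53 so the
# arithmetic is exact in doubles.
substream_seed <- function(seed, key, salt = "") {
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(paste(key, salt, sep = "\r"))) h <- (h * 31 + c) %% m
  as.integer((h + (seed %% m) * 48271) %% m)
}

# round half away from zero (base round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

#' Fill one tree's crown with weighted random points
#'
#' Two filling modes: \code{"equal"} places a constant density of points
#' per m^2 of crown area (default 10), \code{"larsm"} places as many
#' points as the tree's basal area in cm^2, so larger trees get
#' disproportionally denser crowns. Every point carries weight
#' \code{ba / n_points}, making the summed weight exactly the tree's
#' basal area in both modes. Points are uniform on the disc
#' (radius = cr * sqrt(u) transform). A tree with \code{cr = 0} degenerates
#' to a single stem point of weight \code{ba} (the nonspatial limit).
#'
#' @param tree_id identifier (also keys the random substream).
#' @param x,y stem coordinates, m.
#' @param gbh girth at breast height, cm.
#' @param species species code (carried for neighbor classification).
#' @param coeffs allometry coefficients (see
#'   \code{\link{allometry_coefficients}}).
#' @param fill_mode \code{"equal"} or \code{"larsm"}.
#' @param density points per m^2 crown area for \code{"equal"} (default 10).
#' @param seed master seed.
#' @param cr_zero force the crown radius to zero (nonspatial limit: one
#'   stem point of weight \code{ba}).
#' @return object of class \code{crown_cloud}: list with \code{tree_id},
#'   \code{species}, \code{gbh}, \code{ba}, \code{center}, \code{cr},
#'   \code{x}, \code{y}, \code{weight} (per point, uniform),
#'   \code{shaded} (logical per point), \code{fill_mode}.
#' @export
fill_crown <- function(tree_id, x, y, gbh, species = NA_character_,
                       coeffs = allometry_coefficients(),
                       fill_mode = c("larsm", "equal"), density = 10,
                       seed = 1L, cr_zero = FALSE) {
  fill_mode <- match.arg(fill_mode)
  ba <- basal_area(gbh)
  cr <- if (cr_zero) 0 else crown_radius(gbh, coeffs)
  if (cr <= 0) {
    n <- 1L
    px <- x
    py <- y
  } else {
    n <- if (fill_mode == "equal")
      max(1L, round_half_up(density * crown_area(cr)))
    else
      max(1L, round_half_up(ba))
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(substream_seed(seed, tree_id, "fill"))
    theta <- stats::runif(n, 0, 2 * pi)
    rad <- cr * sqrt(stats::runif(n))
    px <- x + rad * cos(theta)
    py <- y + rad * sin(theta)
  }
  structure(list(tree_id = tree_id, species = species, gbh = gbh, ba = ba,
                 center = c(x, y), cr = cr, x = px, y = py,
                 weight = ba / n, shaded = rep(FALSE, n),
                 fill_mode = fill_mode),
            class = "crown_cloud")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Fill every tree's crown in a plot
#'
#' One master seed; each tree draws from its own substream keyed by
#' \code{(seed, tree_id)}, so the result is independent of row order.
#' Only trees alive at the given census (with a recorded gbh) get a cloud.
#'
#' @param trees census data frame (canonical columns).
#' @param census census index whose gbh/status are used.
#' @param cr_zero force all crown radii to zero (the nonspatial limit).
#' @inheritParams fill_crown
#' @return named list of \code{crown_cloud} objects keyed by tree_id.
#' @export
fill_plot <- function(trees, census = 1, coeffs = allometry_coefficients(),
                      fill_mode = c("larsm", "equal"), density = 10,
                      seed = 1L, cr_zero = FALSE) {
  fill_mode <- match.arg(fill_mode)
  g <- trees[[gbh_col(census)]]
  st <- trees[[status_col(census)]]
  keep <- which(st %in% "alive" & !is.na(g))
  clouds <- lapply(keep, function(i)
    fill_crown(trees$tree_id[i], trees$x[i], trees$y[i], g[i],
               trees$species[i], coeffs, fill_mode, density, seed,
               cr_zero = cr_zero))
  names(clouds) <- trees$tree_id[keep]
  clouds
}

#' Construct a crown cloud from explicit points
#'
#' Low-level constructor for worked examples and tests: a cloud with the
#' given point coordinates, total weight \code{ba} spread uniformly.
#'
#' @inheritParams fill_crown
#' @param px,py point coordinates, m.
#' @param ba total weight (basal area, cm^2); defaults to
#'   \code{basal_area(gbh)}.
#' @param cr nominal crown radius, m.
#' @return a \code{crown_cloud}.
#' @export
crown_cloud <- function(tree_id, x, y, gbh, species = NA_character_,
                        px, py, ba = basal_area(gbh), cr = NA_real_) {
  stopifnot(length(px) == length(py), length(px) >= 1)
  structure(list(tree_id = tree_id, species = species, gbh = gbh, ba = ba,
                 center = c(x, y), cr = cr, x = px, y = py,
                 weight = ba / length(px),
                 shaded = rep(FALSE, length(px)), fill_mode = "manual"),
            class = "crown_cloud")
}

#' Assemble a canopy from clouds without overlap adjustment
#'
#' Wraps a cloud list as a \code{zoi_canopy} (as produced by
#' \code{\link{adjust_plot}}) with no shading applied; useful for the
#' dd = 0 case and for constructed examples.
#'
#' @param clouds list of \code{crown_cloud}.
#' @return a \code{zoi_canopy}.
#' @export
as_canopy <- function(clouds) {
  names(clouds) <- vapply(clouds, `[[`, "", "tree_id")
  structure(list(clouds = clouds,
                 vanished = names(clouds)[vapply(clouds, function(cl)
                   length(cl$x) == 0, logical(1))],
                 points = cloud_table(clouds),
                 config = list(dd_con = 0, dd_het = 0,
                               adjust_mode = "none", seed = NA)),
            class = "zoi_canopy")
}

#' Flatten a list of crown clouds to a per-point table
#'
#' @param clouds list of \code{crown_cloud}.
#' @return data frame with one row per point: \code{tree_id},
#'   \code{species}, \code{gbh}, \code{x}, \code{y}, \code{weight},
#'   \code{shaded}.
#' @export
cloud_table <- function(clouds) {
  clouds <- clouds[vapply(clouds, function(cl) length(cl$x) > 0, logical(1))]
  if (!length(clouds))
    return(data.frame(tree_id = character(), species = character(),
                      gbh = numeric(), x = numeric(), y = numeric(),
                      weight = numeric(), shaded = logical()))
  n <- vapply(clouds, function(cl) length(cl$x), integer(1))
  data.frame(
    tree_id = rep(vapply(clouds, `[[`, "", "tree_id"), n),
    species = rep(vapply(clouds, `[[`, "", "species"), n),
    gbh = rep(vapply(clouds, `[[`, 0, "gbh"), n),
    x = unlist(lapply(clouds, `[[`, "x"), use.names = FALSE),
    y = unlist(lapply(clouds, `[[`, "y"), use.names = FALSE),
    weight = rep(vapply(clouds, `[[`, 0, "weight"), n),
    shaded = unlist(lapply(clouds, `[[`, "shaded"), use.names = FALSE),
    stringsAsFactors = FALSE)
}

#' Dump a plot's point clouds to CSV (for visualization)
#' @param clouds list of \code{crown_cloud}.
#' @param path output CSV.
#' @export
write_cloud_table <- function(clouds, path) {
  utils::write.csv(cloud_table(clouds), path, row.names = FALSE)
  invisible(path)
}
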