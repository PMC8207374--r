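# Neighborhood basal-area predictors. For a focal tree, the CON / HET /
# ALL predictors are distance-decayed sums of point weights (basal area,
# cm^2) of all larger surviving neighbors whose points fall within radius
# r of the focal position. Radii run 1-20 m; the focal position is the
# stem or the centroid of the tree's (adjusted) crown.

decay_factor <- function(d, decay = c("linear", "none", "squared")) {
  decay <- match.arg(decay)
  d <- pmax(d, 0.1)  # floor at coordinate resolution to bound weights
  switch(decay, none = rep(1, length(d)), linear = 1 / d, squared = 1 / d^2)
}

# ordered cumulative sums over a radius grid; closed boundary (d <= r).
# Contributions are sorted by (distance, id) so that alternative routes to
# the same set of contributions sum in identical floating-point order.
sum_over_radii <- function(d, w, id, radii, decay) {
  if (!length(d)) return(rep(0, length(radii)))
  ord <- order(d, id, method = "radix")
  d <- d[ord]
  cw <- cumsum(w[ord] * decay_factor(d, decay))
  c(0, cw)[findInterval(radii, d) + 1]
}

survived_map <- function(trees, period) {
  out <- trees[[status_col(period$end)]] %in% "alive"
  names(out) <- trees$tree_id
  out
}

#' Focal tree position: stem or unshaded-crown centroid
#'
#' \code{"stem"} returns the mapped stem coordinates. \code{"crown"}
#' returns the mean (x, y) of the tree's unshaded (post-adjustment) crown
#' points - the centroid of the part of the crown with best light access -
#' falling back to the stem when the cloud is empty. For the largest tree
#' in a plot the two coincide in expectation.
#'
#' @param focal_id tree id.
#' @param trees census data frame.
#' @param canopy a \code{zoi_canopy} (required for \code{"crown"}).
#' @param position_mode \code{"stem"} or \code{"crown"}.
#' @return numeric (x, y) in m.
#' @export
focal_position <- function(focal_id, trees, canopy = NULL,
                           position_mode = c("stem", "crown")) {
  position_mode <- match.arg(position_mode)
  i <- match(focal_id, trees$tree_id)
  if (is.na(i)) stop("unknown focal_id: ", focal_id)
  stem <- c(trees$x[i], trees$y[i])
  if (position_mode == "stem") return(stem)
  cl <- canopy$clouds[[focal_id]]
  if (is.null(cl) || !length(cl$x)) return(stem)
  c(mean(cl$x), mean(cl$y))
}

neighbor_class_filter <- function(species, focal_species,
                                  class = c("ALL", "CON", "HET")) {
  switch(match.arg(class),
         ALL = rep(TRUE, length(species)),
         CON = species == focal_species,
         HET = species != focal_species)
}

#' Spatially extended neighborhood sum
#'
#' Sums the decayed weights of all crown points of larger surviving
#' neighbors within radius \code{r} of the focal position. Neighbors are
#' trees (excluding the focal itself) with gbh at the period start at
#' least the focal's that are alive at the period end.
#'
#' @param focal_id focal tree id.
#' @param canopy a \code{zoi_canopy} built for the period-start census.
#' @param trees census data frame.
#' @param period \code{period_spec}.
#' @param r neighborhood radius in m (vectorized).
#' @param decay \code{"none"}, \code{"linear"} (1/d) or \code{"squared"}
#'   (1/d^2); distances are floored at 0.1 m.
#' @param class \code{"ALL"}, \code{"CON"} or \code{"HET"}.
#' @param position_mode focal position convention (see
#'   \code{\link{focal_position}}).
#' @return numeric vector of sums, same length as \code{r}
#'   (cm^2, scaled by the decay).
#' @export
neighbor_sum_spatial <- function(focal_id, canopy, trees, period, r,
                                 decay = "linear", class = "ALL",
                                 position_mode = "stem") {
  i <- match(focal_id, trees$tree_id)
  pos <- focal_position(focal_id, trees, canopy, position_mode)
  surv <- survived_map(trees, period)
  pts <- canopy$points
  keep <- pts$tree_id != focal_id &
    pts$gbh >= trees[[gbh_col(period$start)]][i] &
    surv[pts$tree_id] %in% TRUE &
    neighbor_class_filter(pts$species, trees$species[i], class)
  pts <- pts[keep, , drop = FALSE]
  d <- sqrt((pts$x - pos[1])^2 + (pts$y - pos[2])^2)
  sum_over_radii(d, pts$weight, pts$tree_id, r, decay)
}

#' Classical (nonspatial) neighborhood sum
#'
#' Trees as points: a neighbor contributes its whole basal area, decayed
#' by the stem-to-stem distance, when that distance is <= r (closed
#' boundary).
#'
#' @inheritParams neighbor_sum_spatial
#' @export
neighbor_sum_nonspatial <- function(focal_id, trees, period, r,
                                    decay = "linear", class = "ALL") {
  i <- match(focal_id, trees$tree_id)
  if (is.na(i)) stop("unknown focal_id: ", focal_id)
  g1 <- trees[[gbh_col(period$start)]]
  alive1 <- trees[[status_col(period$start)]] %in% "alive"
  surv <- trees[[status_col(period$end)]] %in% "alive"
  keep <- trees$tree_id != focal_id & alive1 & !is.na(g1) &
    g1 >= g1[i] & surv &
    neighbor_class_filter(trees$species, trees$species[i], class)
  d <- sqrt((trees$x[keep] - trees$x[i])^2 + (trees$y[keep] - trees$y[i])^2)
  sum_over_radii(d, basal_area(g1[keep]), trees$tree_id[keep], r, decay)
}

#' Neighborhood predictor table over a radius grid
#'
#' For every focal tree and radius, the CON and HET sums and their
#' ln(1 + sum) transforms (1 cm^2 is added before logging to handle empty
#' neighborhoods). ALL is the exact sum CON + HET. Spatial when a canopy
#' is supplied, nonspatial (stem points, full basal area) when
#' \code{canopy} is \code{NULL}.
#'
#' @param focal focal subset of the census (see \code{\link{focal_subset}}).
#' @param trees full census data frame (neighbors are not
#'   border-restricted).
#' @param period \code{period_spec}.
#' @param canopy \code{zoi_canopy} or \code{NULL} for nonspatial.
#' @param radii radius grid in m (default 1:20).
#' @param decay distance decay (default \code{"linear"}).
#' @param position_mode focal position convention.
#' @return data frame: \code{focal_id}, \code{r}, \code{sum_con},
#'   \code{sum_het}, \code{sum_all}, \code{ln_con}, \code{ln_het},
#'   \code{ln_all}.
#' @export
predictor_table <- function(focal, trees, period, canopy = NULL,
                            radii = 1:20, decay = "linear",
                            position_mode = "stem") {
  nonspatial <- is.null(canopy)
  if (nonspatial) {
    g1 <- trees[[gbh_col(period$start)]]
    alive1 <- trees[[status_col(period$start)]] %in% "alive"
    keep <- alive1 & !is.na(g1)
    pts <- data.frame(tree_id = trees$tree_id[keep],
                      species = trees$species[keep],
                      gbh = g1[keep], x = trees$x[keep], y = trees$y[keep],
                      weight = basal_area(g1[keep]),
                      stringsAsFactors = FALSE)
  } else pts <- canopy$points
  surv <- survived_map(trees, period)
  pts <- pts[surv[pts$tree_id] %in% TRUE, , drop = FALSE]
  ord <- order(pts$x, method = "radix")
  pts <- pts[ord, , drop = FALSE]
  rmax <- max(radii)
  g1 <- trees[[gbh_col(period$start)]]
  out <- vector("list", nrow(focal))
  for (j in seq_len(nrow(focal))) {
    fid <- focal$tree_id[j]
    pos <- if (nonspatial || position_mode == "stem")
      c(focal$x[j], focal$y[j])
    else focal_position(fid, trees, canopy, position_mode)
    fg <- g1[match(fid, trees$tree_id)]
    lo <- findInterval(pos[1] - rmax, pts$x) + 1L
    hi <- findInterval(pos[1] + rmax, pts$x)
    if (hi < lo) {
      sc <- sh <- rep(0, length(radii))
    } else {
      sl <- lo:hi
      keep <- sl[pts$tree_id[sl] != fid & pts$gbh[sl] >= fg &
                   abs(pts$y[sl] - pos[2]) <= rmax]
      d <- sqrt((pts$x[keep] - pos[1])^2 + (pts$y[keep] - pos[2])^2)
      con <- pts$species[keep] == focal$species[j]
      sc <- sum_over_radii(d[con], pts$weight[keep][con],
                           pts$tree_id[keep][con], radii, decay)
      sh <- sum_over_radii(d[!con], pts$weight[keep][!con],
                           pts$tree_id[keep][!con], radii, decay)
    }
    out[[j]] <- data.frame(focal_id = fid, r = radii, sum_con = sc,
                           sum_het = sh, sum_all = sc + sh,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out$ln_con <- log1p(out$sum_con)
  out$ln_het <- log1p(out$sum_het)
  out$ln_all <- log1p(out$sum_all)
  rownames(out) <- NULL
  out
}
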