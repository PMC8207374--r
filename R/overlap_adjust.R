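# Crown overlap and plasticity. A point of a smaller tree's crown is
# "shaded" when a point of a strictly larger tree's crown lies within a
# tolerance dd (dd_con for conspecific, dd_het for heterospecific pairs).
# Shaded points are removed (pruning) or relocated into the contour of the
# tree's unshaded points (plasticity). Adjustment is hierarchical, from the
# largest tree downwards, each tree being flagged against the
# already-adjusted clouds of all larger trees.

# dd grid used throughout: 0.0 to 1.2 m in 0.2 m steps
#' @export
dd_grid <- function() seq(0, 1.2, by = 0.2)

# flags for the points of one cloud against pooled points of other trees
flag_against_pool <- function(cl, px, py, pspecies, pgbh, dd_con, dd_het) {
  n <- length(cl$x)
  flags <- rep(FALSE, n)
  if (!n || !length(px)) return(flags)
  larger <- pgbh > cl$gbh
  if (!any(larger)) return(flags)
  for (cls in c("con", "het")) {
    dd <- if (cls == "con") dd_con else dd_het
    if (dd <= 0) next
    sel <- larger & (if (cls == "con") pspecies == cl$species
                     else pspecies != cl$species)
    # bounding-box pruning before the exact distance check
    sel <- sel & px >= min(cl$x) - dd & px <= max(cl$x) + dd &
      py >= min(cl$y) - dd & py <= max(cl$y) + dd
    if (!any(sel)) next
    flags <- flags | cpp_any_within(cl$x, cl$y, px[sel], py[sel], dd)
  }
  flags
}

#' Flag shaded crown points (single pass)
#'
#' Flags every point that has a point of a strictly larger tree's current
#' cloud within the species-dependent tolerance. \code{dd = 0} flags
#' nothing (exact coincidence has probability zero). This is the
#' non-sequential flag computation; \code{\link{adjust_plot}} performs the
#' hierarchical version in which larger trees are adjusted first.
#'
#' @param clouds named list of \code{crown_cloud}.
#' @param dd_con,dd_het overlap tolerances in m (conspecific /
#'   heterospecific larger neighbors).
#' @return named list of logical vectors, one per cloud.
#' @export
flag_shaded <- function(clouds, dd_con, dd_het) {
  pool <- cloud_table(clouds)
  out <- lapply(clouds, function(cl) {
    keep <- pool$tree_id != cl$tree_id
    flag_against_pool(cl, pool$x[keep], pool$y[keep], pool$species[keep],
                      pool$gbh[keep], dd_con, dd_het)
  })
  names(out) <- names(clouds)
  out
}

#' Remove flagged points from a cloud
#'
#' Surviving points keep their weight, so the tree's effective basal area
#' shrinks by the flagged fraction; a fully flagged tree vanishes as a
#' neighbor.
#'
#' @param cloud a \code{crown_cloud}.
#' @param flags logical vector over the cloud's points.
#' @return the pruned \code{crown_cloud} (with \code{n_flagged} recorded).
#' @export
adjust_removal <- function(cloud, flags) {
  stopifnot(length(flags) == length(cloud$x))
  cloud$x <- cloud$x[!flags]
  cloud$y <- cloud$y[!flags]
  cloud$shaded <- rep(FALSE, length(cloud$x))
  cloud$n_flagged <- sum(flags)
  cloud
}

in_any_polygon <- function(x, y, contours) {
  inside <- rep(FALSE, length(x))
  for (ct in contours) {
    todo <- which(!inside)
    if (!length(todo)) break
    inside[todo] <- pracma::inpolygon(x[todo], y[todo], ct$x, ct$y,
                                      boundary = TRUE)
  }
  inside
}

# outermost (lowest positive density) kde contour of a point set;
# NULL when the kde or contour is degenerate
unshaded_contour <- function(ux, uy) {
  if (length(ux) < 3) return(NULL)
  if (abs(stats::var(ux)) < 1e-12 || abs(stats::var(uy)) < 1e-12)
    return(NULL)  # collinear along an axis or coincident
  # collinearity in a general direction: rank of centered coordinates
  if (qr(cbind(ux - mean(ux), uy - mean(uy)))$rank < 2) return(NULL)
  hx <- MASS::bandwidth.nrd(ux)
  hy <- MASS::bandwidth.nrd(uy)
  if (!is.finite(hx) || !is.finite(hy) || hx <= 0 || hy <= 0) return(NULL)
  k <- MASS::kde2d(ux, uy, h = c(hx, hy), n = 25,
                   lims = c(min(ux) - hx, max(ux) + hx,
                            min(uy) - hy, max(uy) + hy))
  pos <- k$z[k$z > 0]
  if (!length(pos)) return(NULL)
  ct <- grDevices::contourLines(k$x, k$y, k$z, levels = min(pos))
  if (!length(ct)) return(NULL)
  ct
}

#' Relocate flagged points into the unshaded crown contour
#'
#' Flagged points are re-sampled uniformly inside the lowest-density
#' contour polygon of the tree's unshaded points (2-D normal-kernel
#' density, normal-reference bandwidth, 25 x 25 grid padded by one
#' bandwidth) - mimicking crown plasticity. The contour may extend beyond
#' the original disc. Point count and summed weight are conserved. With a
#' degenerate unshaded set (fewer than 3 non-collinear points) the
#' fallback places relocated points on jittered copies of unshaded points
#' (Gaussian jitter, sd = 5\% of the crown radius).
#'
#' @inheritParams adjust_removal
#' @param seed master seed (tree-specific substream is derived from it).
#' @return the adjusted \code{crown_cloud}.
#' @export
adjust_relocation <- function(cloud, flags, seed = 1L) {
  stopifnot(length(flags) == length(cloud$x))
  cloud$n_flagged <- sum(flags)
  if (!any(flags)) {
    cloud$shaded <- rep(FALSE, length(cloud$x))
    return(cloud)
  }
  if (all(flags)) {  # nowhere to relocate: the tree vanishes as a neighbor
    cloud$x <- numeric(0)
    cloud$y <- numeric(0)
    cloud$shaded <- logical(0)
    return(cloud)
  }
  ux <- cloud$x[!flags]
  uy <- cloud$y[!flags]
  nmove <- sum(flags)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, cloud$tree_id, "reloc"))
  ct <- unshaded_contour(ux, uy)
  nx <- ny <- numeric(0)
  if (!is.null(ct)) {
    xr <- range(unlist(lapply(ct, `[[`, "x")))
    yr <- range(unlist(lapply(ct, `[[`, "y")))
    tries <- 0L
    while (length(nx) < nmove && tries < 60L) {
      m <- max(200L, 4L * nmove)
      cx <- stats::runif(m, xr[1], xr[2])
      cy <- stats::runif(m, yr[1], yr[2])
      ok <- in_any_polygon(cx, cy, ct)
      nx <- c(nx, cx[ok])
      ny <- c(ny, cy[ok])
      tries <- tries + 1L
    }
  }
  if (length(nx) < nmove) {  # degenerate contour: jittered unshaded copies
    need <- nmove - length(nx)
    sd <- max(0.05 * cloud$cr, 0.01)
    pick <- sample.int(length(ux), need, replace = TRUE)
    nx <- c(nx, ux[pick] + stats::rnorm(need, 0, sd))
    ny <- c(ny, uy[pick] + stats::rnorm(need, 0, sd))
  }
  cloud$x[flags] <- nx[seq_len(nmove)]
  cloud$y[flags] <- ny[seq_len(nmove)]
  cloud$shaded <- rep(FALSE, length(cloud$x))
  cloud
}

#' Hierarchically adjust all crowns in a plot
#'
#' Trees are processed in descending gbh order (ties by tree_id; equal-gbh
#' trees never shade each other). Each tree's points are flagged against
#' the already-adjusted clouds of all strictly larger trees, then removed
#' or relocated. The result is reused for every focal-tree neighborhood at
#' this (dd_con, dd_het) setting.
#'
#' @param clouds named list of filled \code{crown_cloud}
#'   (see \code{\link{fill_plot}}).
#' @param dd_con,dd_het overlap tolerances, m.
#' @param adjust_mode \code{"removal"} or \code{"relocation"}.
#' @param seed master seed (relocation substreams derive from it).
#' @return object of class \code{zoi_canopy}: list with \code{clouds}
#'   (adjusted), \code{vanished} (tree ids that lost all points),
#'   \code{points} (flat per-point table), \code{config}.
#' @export
adjust_plot <- function(clouds, dd_con = 0, dd_het = 0,
                        adjust_mode = c("removal", "relocation"),
                        seed = 1L) {
  adjust_mode <- match.arg(adjust_mode)
  if (dd_con <= 0 && dd_het <= 0) {
    # nothing can be flagged: the canopy is the filled one
    adjusted <- lapply(clouds, function(cl) { cl$n_flagged <- 0L; cl })
  } else {
    gbh <- vapply(clouds, `[[`, 0, "gbh")
    ord <- order(-gbh, vapply(clouds, `[[`, "", "tree_id"),
                 method = "radix")
    adjusted <- vector("list", length(clouds))
    names(adjusted) <- names(clouds)
    # pooled points of already-adjusted (larger) trees, preallocated
    cap <- sum(vapply(clouds, function(cl) length(cl$x), integer(1)))
    px <- py <- pg <- numeric(cap)
    ps <- character(cap)
    m <- 0L
    for (i in ord) {
      cl <- clouds[[i]]
      flags <- flag_against_pool(cl, px[seq_len(m)], py[seq_len(m)],
                                 ps[seq_len(m)], pg[seq_len(m)],
                                 dd_con, dd_het)
      cl <- if (adjust_mode == "removal") adjust_removal(cl, flags)
      else adjust_relocation(cl, flags, seed)
      adjusted[[cl$tree_id]] <- cl
      np <- length(cl$x)
      if (np) {
        at <- m + seq_len(np)
        px[at] <- cl$x; py[at] <- cl$y
        ps[at] <- cl$species; pg[at] <- cl$gbh
        m <- m + np
      }
    }
    adjusted <- adjusted[names(clouds)]
  }
  vanished <- names(adjusted)[vapply(adjusted, function(cl)
    length(cl$x) == 0, logical(1))]
  structure(list(clouds = adjusted, vanished = vanished,
                 points = cloud_table(adjusted),
                 config = list(dd_con = dd_con, dd_het = dd_het,
                               adjust_mode = adjust_mode, seed = seed)),
            class = "zoi_canopy")
}
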